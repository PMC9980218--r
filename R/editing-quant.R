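#' Calling thresholds for editing-site detection
#'
#' The depth/evidence thresholds are deliberately permissive defaults — the
#' read-based discovery this mirrors used a qualitative low-stringency SNP
#' filter — and every threshold is user-configurable.
#'
#' @param min_depth minimum total read depth at a position (default 10)
#' @param min_edited_reads minimum reads carrying the edited base (default 2)
#' @param min_efficiency minimum edited fraction (default 0.01)
#' @param include_multimapped keep MAPQ-0 / secondary alignments (default
#'   `TRUE`, so sites on the inverted-repeat copy of ndhB-like genes remain
#'   detectable)
#' @return a `call_thresholds` list
#' @export
call_thresholds <- function(min_depth = 10, min_edited_reads = 2,
                            min_efficiency = 0.01, include_multimapped = TRUE) {
  if (min_depth < 1) stopf("min_depth must be >= 1")
  if (min_efficiency < 0 || min_efficiency > 1) stopf("min_efficiency must be in [0, 1]")
  structure(list(min_depth = min_depth, min_edited_reads = min_edited_reads,
                 min_efficiency = min_efficiency,
                 include_multimapped = isTRUE(include_multimapped)),
            class = "call_thresholds")
}

.pileup_once <- function(bam, refname, include_multimapped) {
  flag <- if (include_multimapped)
    Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  else
    Rsamtools::scanBamFlag(isUnmappedQuery = FALSE, isSecondaryAlignment = FALSE)
  sbp <- Rsamtools::ScanBamParam(flag = flag,
                                 mapqFilter = if (include_multimapped) 0L else 1L)
  pp <- Rsamtools::PileupParam(max_depth = 1000000L, min_base_quality = 0L,
                               min_mapq = 0L, min_nucleotide_depth = 1L,
                               distinguish_strands = FALSE,
                               distinguish_nucleotides = TRUE,
                               include_deletions = FALSE,
                               include_insertions = FALSE)
  p <- Rsamtools::pileup(bam, scanBamParam = sbp, pileupParam = pp)
  if (nrow(p) == 0)
    return(data.frame(position = integer(0), A = integer(0), C = integer(0),
                      G = integer(0), T = integer(0), other = integer(0),
                      depth = integer(0)))
  pos <- sort(unique(p$pos))
  out <- data.frame(position = pos, A = 0L, C = 0L, G = 0L, T = 0L, other = 0L)
  idx <- match(p$pos, pos)
  nuc <- as.character(p$nucleotide)
  for (b in BASES) {
    sel <- nuc == b
    if (any(sel)) {
      agg <- tapply(p$count[sel], idx[sel], sum)
      out[[b]][as.integer(names(agg))] <- as.integer(agg)
    }
  }
  sel <- !(nuc %in% BASES)
  if (any(sel)) {
    agg <- tapply(p$count[sel], idx[sel], sum)
    out$other[as.integer(names(agg))] <- as.integer(agg)
  }
  out$depth <- out$A + out$C + out$G + out$T + out$other
  out
}

#' Build a per-position base-count pileup from SAM alignments
#'
#' Tallies forward-reference-strand base counts at every covered position.
#' Unmapped reads and soft-clipped bases are never counted. With
#' `include_multimapped = FALSE`, secondary alignments and MAPQ-0 records are
#' excluded, which is how the inverted-repeat multi-mapping policy is
#' toggled. The returned table also carries `n_multimapped`, the per-position
#' depth contributed by multi-mapping records.
#'
#' @param sam path to a SAM (or BAM) file aligned to `ref`
#' @param ref a `plastome` (used to check the reference name and length)
#' @param include_multimapped count MAPQ-0/secondary records (default `TRUE`)
#' @return data.frame: position, A, C, G, T, other, depth, n_multimapped
#' @export
build_pileup <- function(sam, ref, include_multimapped = TRUE) {
  stopifnot(inherits(ref, "plastome"))
  bam <- if (grepl("\\.bam$", sam)) {
    sam
  } else {
    dest <- tempfile(fileext = "")
    Rsamtools::asBam(sam, dest, overwrite = TRUE, indexDestination = TRUE)
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (!(ref$name %in% names(hdr)))
    stopf("alignment reference '%s' does not match plastome '%s'",
          paste(names(hdr), collapse = ","), ref$name)
  all_p <- .pileup_once(bam, ref$name, include_multimapped = TRUE)
  uniq_p <- .pileup_once(bam, ref$name, include_multimapped = FALSE)
  keep <- if (include_multimapped) all_p else uniq_p
  mm <- all_p$depth - ifelse(is.na(match(all_p$position, uniq_p$position)), 0L,
                             uniq_p$depth[match(all_p$position, uniq_p$position)])
  keep$n_multimapped <- mm[match(keep$position, all_p$position)]
  keep$n_multimapped[is.na(keep$n_multimapped)] <- 0L
  keep
}

#' Editing efficiency from edited/unedited read counts
#'
#' The core statistic: the fraction of reads carrying the edited base out of
#' edited plus unedited reads at a site, `T/(C+T)` on the coding strand.
#' When both counts are zero the efficiency is undefined and `NA` is
#' returned, distinct from a true 0.
#'
#' @param edited,unedited non-negative read counts (vectorized)
#' @return efficiency in `[0, 1]`, or `NA` where `edited + unedited == 0`
#' @examples
#' editing_efficiency(50, 50)           # 0.5
#' format_percent(editing_efficiency(543, 9457))  # "5.43%"
#' @export
editing_efficiency <- function(edited, unedited) {
  if (any(edited < 0 | unedited < 0)) stopf("counts must be non-negative")
  tot <- edited + unedited
  ifelse(tot == 0, NA_real_, edited / tot)
}

#' Call C-to-U editing sites from a pileup, strand-aware
#'
#' A position is called iff the coding-strand reference base is C — a forward
#' reference C inside a plus-strand gene (edited evidence T), or a forward
#' reference G inside a minus-strand gene (edited evidence A) — with depth,
#' edited-read-count and efficiency above the thresholds. Efficiency uses
#' coding-strand C/T (equivalently G/A) counts only; other bases at the
#' position are ignored as sequencing noise. Positions outside annotated
#' genes are scanned in both orientations and reported with
#' `gene = "intergenic"`.
#'
#' @param pileup output of [build_pileup()]
#' @param ref a `plastome` (reference sequence + gene annotation)
#' @param thresholds a [call_thresholds()]
#' @param exclude optional [GenomicRanges::GRanges] of positions to mask
#'   (e.g. known SNPs or RT artifacts)
#' @return data.frame of named sites: site_id, gene, position, strand,
#'   edited_count, unedited_count, efficiency, depth, n_multimapped
#' @export
call_editing_sites <- function(pileup, ref, thresholds = call_thresholds(),
                               exclude = NULL) {
  stopifnot(inherits(ref, "plastome"))
  if (nrow(pileup) == 0) return(.empty_sites())
  th <- thresholds
  seq_chr <- as.character(ref$seq)
  refbase <- substring(seq_chr, pileup$position, pileup$position)

  pos_gr <- GenomicRanges::GRanges(ref$name,
                                   IRanges::IRanges(pileup$position, width = 1))
  ov <- GenomicRanges::findOverlaps(pos_gr, ref$genes, ignore.strand = TRUE)
  gene_of <- rep(NA_character_, nrow(pileup))
  strand_of <- rep(NA_character_, nrow(pileup))
  gene_of[S4Vectors::queryHits(ov)] <-
    S4Vectors::mcols(ref$genes)$gene_id[S4Vectors::subjectHits(ov)]
  strand_of[S4Vectors::queryHits(ov)] <-
    as.character(GenomicRanges::strand(ref$genes))[S4Vectors::subjectHits(ov)]

  if (!is.null(exclude)) {
    drop <- S4Vectors::queryHits(
      GenomicRanges::findOverlaps(pos_gr, exclude, ignore.strand = TRUE))
    if (length(drop)) {
      pileup <- pileup[-drop, , drop = FALSE]
      refbase <- refbase[-drop]; gene_of <- gene_of[-drop]
      strand_of <- strand_of[-drop]
    }
  }

  mk <- function(sel, strand, edited, unedited, gene) {
    if (!any(sel)) return(NULL)
    data.frame(gene = gene, position = pileup$position[sel], strand = strand,
               edited_count = edited, unedited_count = unedited,
               efficiency = editing_efficiency(edited, unedited),
               depth = pileup$depth[sel],
               n_multimapped = pileup$n_multimapped[sel],
               stringsAsFactors = FALSE)
  }
  out <- list()
  ## plus-strand genes: reference C, edited base T
  sel <- !is.na(gene_of) & strand_of == "+" & refbase == "C"
  out$p <- mk(sel, "+", pileup$T[sel], pileup$C[sel], gene_of[sel])
  ## minus-strand genes: forward reference G, edited evidence A
  sel <- !is.na(gene_of) & strand_of == "-" & refbase == "G"
  out$m <- mk(sel, "-", pileup$A[sel], pileup$G[sel], gene_of[sel])
  ## intergenic, both orientations
  sel <- is.na(gene_of) & refbase == "C"
  out$ip <- mk(sel, "+", pileup$T[sel], pileup$C[sel], "intergenic")
  sel <- is.na(gene_of) & refbase == "G"
  out$im <- mk(sel, "-", pileup$A[sel], pileup$G[sel], "intergenic")

  sites <- do.call(rbind, Filter(Negate(is.null), out))
  if (is.null(sites) || nrow(sites) == 0) return(.empty_sites())
  keep <- sites$depth >= th$min_depth &
    sites$edited_count >= th$min_edited_reads &
    !is.na(sites$efficiency) & sites$efficiency >= th$min_efficiency
  sites <- sites[keep, , drop = FALSE]
  sites <- sites[order(sites$position), , drop = FALSE]
  rownames(sites) <- NULL
  name_sites(sites, ref$genes)
}

.empty_sites <- function() {
  data.frame(site_id = character(0), gene = character(0),
             position = integer(0), strand = character(0),
             edited_count = integer(0), unedited_count = integer(0),
             efficiency = numeric(0), depth = integer(0),
             n_multimapped = integer(0), stringsAsFactors = FALSE)
}

#' Name editing sites by gene and 5'-to-3' transcript order
#'
#' Within each gene, sites are numbered 1..k in transcript order (ascending
#' genome coordinate on plus-strand genes, descending on minus-strand genes)
#' and named `<gene>-<k>`; a gene with a single site gets the bare gene name
#' (e.g. `psbL`). Intergenic sites are named `intergenic-<position>`.
#'
#' @param sites data.frame with gene, position, strand columns
#' @param annotation [GenomicRanges::GRanges] of genes (used to compute the
#'   transcript offset of each site within its gene placement)
#' @return `sites` with a `site_id` column prepended
#' @export
name_sites <- function(sites, annotation) {
  if (nrow(sites) == 0) return(.empty_sites())
  offs <- rep(NA_real_, nrow(sites))
  gid <- S4Vectors::mcols(annotation)$gene_id
  st <- as.character(GenomicRanges::strand(annotation))
  s0 <- GenomicRanges::start(annotation); e0 <- GenomicRanges::end(annotation)
  for (i in seq_len(nrow(sites))) {
    if (sites$gene[i] == "intergenic") next
    j <- which(gid == sites$gene[i] & st == sites$strand[i] &
                 s0 <= sites$position[i] & e0 >= sites$position[i])[1]
    if (is.na(j)) next
    offs[i] <- if (st[j] == "+") sites$position[i] - s0[j] + 1L
               else e0[j] - sites$position[i] + 1L
  }
  ord <- order(sites$gene, offs, sites$position)
  sites <- sites[ord, , drop = FALSE]
  offs <- offs[ord]
  k <- stats::ave(seq_len(nrow(sites)), sites$gene, FUN = seq_along)
  n <- stats::ave(seq_len(nrow(sites)), sites$gene, FUN = length)
  id <- ifelse(sites$gene == "intergenic",
               paste0("intergenic-", sites$position),
               ifelse(n == 1, sites$gene, paste0(sites$gene, "-", k)))
  sites <- cbind(site_id = id, sites, stringsAsFactors = FALSE)
  sites <- sites[order(sites$position), , drop = FALSE]
  rownames(sites) <- NULL
  sites
}

#' Editing efficiency from Sanger trace peak heights
#'
#' For a coding-strand trace the efficiency is `height_T / (height_C +
#' height_T)`; for a trace read off the antisense strand the complementary
#' channels are used, `height_A / (height_G + height_A)`.
#'
#' @param peaks named numeric vector with channels A, C, G, T
#' @param strand `"+"` for a coding-strand (sense) trace, `"-"` for antisense
#' @return efficiency in `[0, 1]`, `NA` if both relevant channels are zero
#' @examples
#' sanger_efficiency(c(A = 0, C = 100, G = 0, T = 100))       # 0.5
#' sanger_efficiency(c(A = 70, C = 0, G = 30, T = 0), "-")    # 0.7
#' @export
sanger_efficiency <- function(peaks, strand = "+") {
  stopifnot(all(c("A", "C", "G", "T") %in% names(peaks)))
  if (strand == "+") {
    edited <- peaks[["T"]]; unedited <- peaks[["C"]]
  } else {
    edited <- peaks[["A"]]; unedited <- peaks[["G"]]
  }
  if (edited + unedited <= 0) return(NA_real_)
  edited / (edited + unedited)
}

#' Write a called-site table as TSV
#' @param sites data.frame from [call_editing_sites()]
#' @param path output path
#' @export
write_site_table <- function(sites, path) {
  write.table(sites, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
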