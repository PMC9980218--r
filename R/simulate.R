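#' Simulation configuration for a synthetic plastome experiment
#'
#' Collects the knobs of the synthetic-data generator: a toy circular plastome
#' with annotated genes on both strands (optionally one gene duplicated in
#' inverted-repeat orientation, as ndhB is in real plastomes), paired-end
#' read simulation with planted per-site editing fractions, and a fixed seed
#' for byte-identical reproducibility.
#'
#' Defaults emulate the study design this package targets: a ~20 kb toy
#' plastome stand-in, 250-nt paired-end reads, and 3 replicates per condition
#' (the experiment this mirrors used three control and four silenced
#' libraries; [run_demo()] uses that 3-vs-4 structure explicitly).
#'
#' @param genome_length genome size in bases (>= 1000)
#' @param n_genes number of genes to place (non-overlapping)
#' @param ir_gene if `TRUE`, one gene is additionally placed a second time in
#'   reverse-complement (inverted-repeat) orientation, so its reads multi-map
#' @param read_length read length in bases (default 250)
#' @param mean_depth target mean per-base read depth
#' @param error_rate per-base substitution error probability, in `[0, 0.1)`
#' @param replicates_per_condition default replicate count per condition
#' @param seed integer RNG seed; fixed seed implies byte-identical outputs
#' @return an object of class `sim_config` (a validated list)
#' @examples
#' cfg <- sim_config(genome_length = 5000, n_genes = 4, seed = 1)
#' @export
sim_config <- function(genome_length = 20000, n_genes = 12, ir_gene = TRUE,
                       read_length = 250, mean_depth = 100,
                       error_rate = 0.001, replicates_per_condition = 3,
                       seed = 1L) {
  if (genome_length < 1000) stopf("genome_length must be >= 1000, got %d", genome_length)
  if (error_rate < 0 || error_rate >= 0.1) stopf("error_rate must be in [0, 0.1), got %g", error_rate)
  if (read_length >= genome_length) stopf("read_length must be < genome_length")
  if (n_genes < 0) stopf("n_genes must be >= 0")
  structure(list(genome_length = as.integer(genome_length),
                 n_genes = as.integer(n_genes), ir_gene = isTRUE(ir_gene),
                 read_length = as.integer(read_length),
                 mean_depth = mean_depth, error_rate = error_rate,
                 replicates_per_condition = as.integer(replicates_per_condition),
                 seed = as.integer(seed)),
            class = "sim_config")
}

## plastome-flavoured gene name pool; the IR-duplicated gene is ndhB-like
.gene_pool <- c("ndhB", "psbA", "rbcL", "ndhD", "rpoA", "rpoB", "atpA", "atpF",
                "ndhG", "psbE", "psbL", "rps2", "rpoC2", "matK", "ndhA",
                "petB", "psbB", "rps14", "atpB", "ycf3")

#' Simulate a toy plastome reference with gene annotation
#'
#' Generates an AT-rich random genome and places `n_genes` non-overlapping
#' genes on alternating strands. When `config$ir_gene` is `TRUE` the first
#' gene (ndhB-like) is placed a second time near the 3' end of the genome as
#' an exact reverse complement, mimicking a plastome inverted repeat.
#'
#' @param config a [sim_config()]
#' @param outdir if non-`NULL`, the reference FASTA (`plastome.fa`) and GFF3
#'   annotation (`genes.gff3`) are written there
#' @return an object of class `plastome`: list with `name`, `seq`
#'   (a [Biostrings::DNAString]), `genes` (a [GenomicRanges::GRanges] with
#'   metadata columns `gene_id` and `copy`), and `config`
#' @examples
#' ref <- simulate_plastome(sim_config(genome_length = 5000, n_genes = 3, seed = 2))
#' @export
simulate_plastome <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  L <- config$genome_length
  ## plastomes are AT-rich (~62% AT)
  seq_chr <- paste(sample(BASES, L, replace = TRUE,
                          prob = c(0.31, 0.19, 0.19, 0.31)), collapse = "")

  n <- config$n_genes
  gene_len <- if (n > 0) sample(500:1200, n, replace = TRUE) else integer(0)
  gaps <- if (n > 0) sample(80:200, n, replace = TRUE) else integer(0)
  starts <- integer(n); ends <- integer(n)
  pos <- 100L
  for (i in seq_len(n)) {
    starts[i] <- pos + gaps[i]
    ends[i] <- starts[i] + gene_len[i] - 1L
    pos <- ends[i]
  }
  ## reserve tail space for the IR copy of gene 1
  tail_needed <- if (config$ir_gene && n >= 1) gene_len[1] + 200L else 100L
  if (n > 0 && ends[n] > L - tail_needed)
    stopf("cannot pack %d genes into a %d-base genome", n, L)

  ids <- .gene_pool[seq_len(max(n, 0))]
  if (n > length(.gene_pool)) ids <- c(.gene_pool, paste0("orf", seq_len(n - length(.gene_pool))))[seq_len(n)]
  strands <- if (n > 0) rep(c("+", "-"), length.out = n) else character(0)
  copy <- rep(1L, n)

  if (config$ir_gene && n >= 1) {
    ## duplicate gene 1 in reverse-complement near the genome end
    ir_start <- L - 100L - gene_len[1] + 1L
    g1 <- substr(seq_chr, starts[1], ends[1])
    substr(seq_chr, ir_start, ir_start + gene_len[1] - 1L) <- revcomp_chr(g1)
    starts <- c(starts, ir_start)
    ends <- c(ends, ir_start + gene_len[1] - 1L)
    ids <- c(ids, ids[1])
    strands <- c(strands, if (strands[1] == "+") "-" else "+")
    copy <- c(copy, 2L)
  }

  genes <- GenomicRanges::GRanges(
    seqnames = rep("synthPt", length(starts)),
    ranges = IRanges::IRanges(start = starts, end = ends),
    strand = strands, gene_id = ids, copy = copy,
    seqlengths = c(synthPt = L))

  ref <- structure(list(name = "synthPt",
                        seq = Biostrings::DNAString(seq_chr),
                        genes = genes, config = config),
                   class = "plastome")
  if (!is.null(outdir)) write_plastome(ref, outdir)
  ref
}

#' Write a plastome reference to FASTA + GFF3
#' @param ref a `plastome`
#' @param outdir output directory (created if missing)
#' @return invisibly, a list with the `fasta` and `gff` paths
#' @export
write_plastome <- function(ref, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(outdir, "plastome.fa")
  gff <- file.path(outdir, "genes.gff3")
  ss <- Biostrings::DNAStringSet(ref$seq)
  names(ss) <- ref$name
  Biostrings::writeXStringSet(ss, fa)
  g <- ref$genes
  S4Vectors::mcols(g)$type <- rep("gene", length(g))
  S4Vectors::mcols(g)$ID <- sprintf("%s_%d", S4Vectors::mcols(g)$gene_id,
                                    S4Vectors::mcols(g)$copy)
  S4Vectors::mcols(g)$Name <- S4Vectors::mcols(g)$gene_id
  if (length(g) > 0) {
    rtracklayer::export(g, gff, format = "gff3")
  } else {
    writeLines(c("##gff-version 3",
                 sprintf("##sequence-region %s 1 %d", ref$name,
                         length(ref$seq))), gff)
  }
  invisible(list(fasta = fa, gff = gff))
}

#' Read a plastome reference from FASTA + GFF3
#'
#' The GFF3 `strand` column is authoritative for gene orientation. Gene
#' identity is taken from the `Name` attribute when present, else `ID`.
#'
#' @param fasta path to single-sequence FASTA
#' @param gff path to GFF3 with gene records
#' @return a `plastome` object
#' @export
read_plastome <- function(fasta, gff) {
  ss <- Biostrings::readDNAStringSet(fasta)
  if (length(ss) != 1) stopf("expected a single-sequence reference FASTA, got %d", length(ss))
  g <- rtracklayer::import(gff, format = "gff3")
  mc <- S4Vectors::mcols(g)
  gid <- if (!is.null(mc$Name)) as.character(mc$Name) else as.character(mc$ID)
  genes <- GenomicRanges::GRanges(sub(" .*", "", names(ss)[1]),
                                  IRanges::ranges(g),
                                  strand = GenomicRanges::strand(g),
                                  gene_id = gid,
                                  copy = as.integer(stats::ave(seq_along(gid), gid, FUN = seq_along)))
  structure(list(name = sub(" .*", "", names(ss)[1]),
                 seq = ss[[1]], genes = genes, config = NULL),
            class = "plastome")
}

## positions of all placements of a gene; offset is 1-based along the
## transcript (5'->3'), so on '-' genes it counts down from the range end
.gene_offset_to_pos <- function(gr_row, offset) {
  w <- IRanges::width(gr_row)
  if (offset < 1 || offset > w) stopf("offset %d outside gene of width %d", offset, w)
  if (as.character(GenomicRanges::strand(gr_row)) == "+")
    GenomicRanges::start(gr_row) + offset - 1L
  else
    GenomicRanges::end(gr_row) - offset + 1L
}

#' Plant C-to-U editing sites with known per-condition fractions
#'
#' Marks positions within genes as editing sites with planted editing
#' fractions per condition, guaranteeing (by local substitution when needed)
#' that the coding-strand reference base is C. On minus-strand genes the
#' forward reference strand therefore carries a G at the site, and editing
#' shows up as G->A in forward coordinates. A gene with two inverted-repeat
#' placements gets the site planted at both placements (mirrored
#' coordinates), keeping the two copies exact reverse complements.
#'
#' @param ref a `plastome`
#' @param sites data.frame with columns `gene`, `offset` (1-based position
#'   along the transcript), and one numeric column per condition holding the
#'   planted edited fraction in `[0, 1]`
#' @param substitute if `TRUE` (default) a non-C coding-strand base at the
#'   requested offset is substituted to C in the reference; if `FALSE` that
#'   situation is an error
#' @param truth_file if non-`NULL`, the truth table is written there as TSV
#' @return list with `ref` (possibly modified reference) and `truth`, a
#'   long-format data.frame: site_id, gene, position, strand, condition,
#'   fraction
#' @export
plant_editing_sites <- function(ref, sites, substitute = TRUE, truth_file = NULL) {
  stopifnot(inherits(ref, "plastome"), is.data.frame(sites))
  cond_cols <- setdiff(names(sites), c("gene", "offset"))
  if (nrow(sites) == 0) {
    truth <- data.frame(site_id = character(0), gene = character(0),
                        position = integer(0), strand = character(0),
                        condition = character(0), fraction = numeric(0))
    if (!is.null(truth_file))
      write.table(truth, truth_file, sep = "\t", quote = FALSE, row.names = FALSE)
    return(list(ref = ref, truth = truth))
  }
  if (length(cond_cols) == 0) stopf("sites needs at least one condition fraction column")
  if (any(vapply(sites[cond_cols], function(x) any(x < 0 | x > 1), logical(1))))
    stopf("planted fractions must be in [0, 1]")

  seq_chr <- as.character(ref$seq)
  rows <- list()
  for (i in seq_len(nrow(sites))) {
    gene <- sites$gene[i]; offset <- as.integer(sites$offset[i])
    hits <- which(S4Vectors::mcols(ref$genes)$gene_id == gene)
    if (length(hits) == 0) stopf("gene '%s' not found in annotation", gene)
    ## a gene with two inverted-repeat placements gets the site at both
    for (h in hits) {
      gr <- ref$genes[h]
      pos <- .gene_offset_to_pos(gr, offset)
      strand <- as.character(GenomicRanges::strand(gr))
      want <- if (strand == "+") "C" else "G"   # coding-strand C
      have <- substr(seq_chr, pos, pos)
      if (have != want) {
        if (!substitute)
          stopf("coding-strand base at %s offset %d is %s, not C", gene, offset, have)
        substr(seq_chr, pos, pos) <- want
      }
      for (cc in cond_cols) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene = gene, offset = offset, position = pos, strand = strand,
          condition = cc, fraction = sites[[cc]][i],
          stringsAsFactors = FALSE)
      }
    }
  }
  truth <- do.call(rbind, rows)
  ## number sites per gene in 5'->3' transcript order over all placements —
  ## the same rule name_sites() applies, so truth ids match called ids
  upos <- unique(truth[, c("gene", "offset", "position")])
  upos <- upos[order(upos$gene, upos$offset, upos$position), , drop = FALSE]
  k <- stats::ave(seq_len(nrow(upos)), upos$gene, FUN = seq_along)
  n <- stats::ave(seq_len(nrow(upos)), upos$gene, FUN = length)
  upos$site_id <- ifelse(n == 1, upos$gene, paste0(upos$gene, "-", k))
  truth$site_id <- upos$site_id[match(paste(truth$gene, truth$position),
                                      paste(upos$gene, upos$position))]
  truth <- truth[, c("site_id", "gene", "position", "strand", "condition",
                     "fraction")]
  truth <- truth[order(truth$position, truth$condition), , drop = FALSE]
  rownames(truth) <- NULL
  ref$seq <- Biostrings::DNAString(seq_chr)
  if (!is.null(truth_file))
    write.table(truth, truth_file, sep = "\t", quote = FALSE, row.names = FALSE)
  list(ref = ref, truth = truth)
}

## secondary-alignment coordinates: map read interval [a,b] inside IR copy
## [s1,e1] to the mirrored interval inside the other copy [s2,e2]
.mirror_start <- function(a, b, s1, e1, s2) s2 + (e1 - b)

#' Simulate paired-end reads with truth alignments
#'
#' Draws sequencing fragments uniformly from the (linearized) plastome, from
#' both strands with equal probability (unstranded random-primed library).
#' For each fragment, every planted site it covers is edited independently
#' with the site's planted fraction for the requested condition — both mates
#' of a fragment share the molecule's edit state. Per-base substitution
#' errors are added at `config$error_rate`. Reads fully contained in an
#' inverted-repeat gene copy are written as multi-mapping: a MAPQ-0 primary
#' record at the true position plus a MAPQ-0 secondary record at the mirrored
#' position in the other copy.
#'
#' @param ref a `plastome` (after [plant_editing_sites()])
#' @param truth long-format truth table from [plant_editing_sites()], or
#'   `NULL` for no editing
#' @param config a [sim_config()]
#' @param outdir output directory for FASTQ pair and truth SAM
#' @param condition which condition's fractions to use (default: the single
#'   condition present)
#' @param seed RNG seed for this library (default `config$seed`); use a
#'   different seed per replicate
#' @param prefix file-name prefix (default the condition)
#' @return list with paths `fastq1`, `fastq2`, `sam` and `n_fragments`
#' @export
simulate_reads <- function(ref, truth, config, outdir,
                           condition = NULL, seed = config$seed,
                           prefix = NULL) {
  stopifnot(inherits(ref, "plastome"), inherits(config, "sim_config"))
  if (config$mean_depth <= 0) stopf("mean_depth must be > 0")
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)

  L <- config$genome_length
  rl <- config$read_length
  if (!is.null(truth)) {
    conds <- unique(truth$condition)
    if (is.null(condition)) {
      if (length(conds) > 1) stopf("truth has multiple conditions; pick one")
      condition <- conds
    }
    tr <- truth[truth$condition == condition, , drop = FALSE]
  } else {
    tr <- NULL
    condition <- condition %||% "sim"
  }
  prefix <- prefix %||% condition

  n_frag <- max(1L, round(L * config$mean_depth / (2 * rl)))
  fl <- sample(max(300L, rl):max(500L, rl + 50L), n_frag, replace = TRUE)
  fl <- pmin(fl, L)
  ## vectorized uniform placement
  fstart <- 1L + as.integer(floor(runif(n_frag) * (L - fl + 1L)))
  fend <- fstart + fl - 1L
  sense <- sample(c("+", "-"), n_frag, replace = TRUE)

  frags <- substring(as.character(ref$seq), fstart, fend)

  ## plant edits per fragment per covered site (molecule-level, shared by mates)
  if (!is.null(tr) && nrow(tr) > 0) {
    for (i in seq_len(nrow(tr))) {
      p <- tr$position[i]
      cov <- which(fstart <= p & fend >= p)
      if (length(cov) == 0) next
      ed <- cov[runif(length(cov)) < tr$fraction[i]]
      if (length(ed) == 0) next
      newb <- if (tr$strand[i] == "+") "T" else "A"   # C->U on coding strand
      off <- p - fstart[ed] + 1L
      for (j in seq_along(ed)) substr(frags[ed[j]], off[j], off[j]) <- newb
    }
  }

  ## reads in reference orientation: left mate and right mate of each fragment
  left <- substr(frags, 1L, rl)
  right <- substr(frags, fl - rl + 1L, fl)
  lpos <- fstart
  rpos <- fend - rl + 1L

  add_errors <- function(seqs) {
    n_err <- rbinom(1L, length(seqs) * rl, config$error_rate)
    if (n_err == 0) return(seqs)
    ridx <- sample.int(length(seqs), n_err, replace = TRUE)
    pidx <- sample.int(rl, n_err, replace = TRUE)
    for (k in seq_len(n_err)) {
      old <- substr(seqs[ridx[k]], pidx[k], pidx[k])
      substr(seqs[ridx[k]], pidx[k], pidx[k]) <- sample(setdiff(BASES, old), 1L)
    }
    seqs
  }
  left <- add_errors(left)
  right <- add_errors(right)

  ## multi-mapping bookkeeping for inverted-repeat copies
  mc <- S4Vectors::mcols(ref$genes)
  dup_gene <- unique(mc$gene_id[duplicated(mc$gene_id)])
  ir <- NULL
  if (length(dup_gene) == 1) {
    rows <- which(mc$gene_id == dup_gene)
    ir <- list(s1 = GenomicRanges::start(ref$genes[rows[1]]),
               e1 = GenomicRanges::end(ref$genes[rows[1]]),
               s2 = GenomicRanges::start(ref$genes[rows[2]]),
               e2 = GenomicRanges::end(ref$genes[rows[2]]))
  }
  in_copy <- function(a, b) {
    if (is.null(ir)) return(rep(0L, length(a)))
    ifelse(a >= ir$s1 & b <= ir$e1, 1L, ifelse(a >= ir$s2 & b <= ir$e2, 2L, 0L))
  }
  left_copy <- in_copy(lpos, lpos + rl - 1L)
  right_copy <- in_copy(rpos, rpos + rl - 1L)

  qname <- sprintf("frag%07d", seq_len(n_frag))
  qual <- strrep("I", rl)

  ## mate roles: read1 is the 5'-most read on the fragment's sense strand
  r1_is_left <- sense == "+"
  flag_left <- ifelse(r1_is_left, 99L, 163L)    # paired,proper,mate-rev,(first|second)
  flag_right <- ifelse(r1_is_left, 147L, 83L)   # paired,proper,rev,(second|first)
  mapq_left <- ifelse(left_copy > 0L, 0L, 60L)
  mapq_right <- ifelse(right_copy > 0L, 0L, 60L)

  cigar <- paste0(rl, "M")
  sam_line <- function(qn, fl_, pos, mapq, seq, pnext, tlen) {
    paste(qn, fl_, ref$name, pos, mapq, cigar, "=", pnext, tlen, seq, qual,
          sep = "\t")
  }
  rec_left <- sam_line(qname, flag_left, lpos, mapq_left, left, rpos, fl)
  rec_right <- sam_line(qname, flag_right, rpos, mapq_right, right, lpos, -fl)

  sec_rec <- function(copy, pos, seqs, primary_rev) {
    idx <- which(copy > 0L)
    if (length(idx) == 0) return(character(0))
    a <- pos[idx]; b <- pos[idx] + rl - 1L
    s1 <- ifelse(copy[idx] == 1L, ir$s1, ir$s2)
    e1 <- ifelse(copy[idx] == 1L, ir$e1, ir$e2)
    s2 <- ifelse(copy[idx] == 1L, ir$s2, ir$s1)
    npos <- .mirror_start(a, b, s1, e1, s2)
    ## mirrored alignment is on the opposite strand of the primary
    fl2 <- 256L + ifelse(primary_rev[idx], 0L, 16L)
    paste(qname[idx], fl2, ref$name, npos, 0L, cigar, "*", 0L, 0L,
          revcomp_chr(seqs[idx]), qual, sep = "\t")
  }
  ## left-mate primaries are always forward-aligned, right-mate always reverse
  rec_sec <- c(sec_rec(left_copy, lpos, left, primary_rev = rep(FALSE, n_frag)),
               sec_rec(right_copy, rpos, right, primary_rev = rep(TRUE, n_frag)))

  sam <- file.path(outdir, paste0(prefix, ".sam"))
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", ref$name, L),
              "@PG\tID:plastedit\tPN:plastedit")
  writeLines(c(header, rec_left, rec_right, rec_sec), sam)

  ## FASTQ in sequencing orientation (reverse-aligned reads are flipped back)
  r1_seq <- ifelse(r1_is_left, left, revcomp_chr(right))
  r2_seq <- ifelse(r1_is_left, revcomp_chr(right), left)
  fq <- function(path, seqs) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(paste0("@", qname, "\n", seqs, "\n+\n", qual), con)
  }
  fq1 <- file.path(outdir, paste0(prefix, "_R1.fastq"))
  fq2 <- file.path(outdir, paste0(prefix, "_R2.fastq"))
  fq(fq1, r1_seq)
  fq(fq2, r2_seq)

  list(fastq1 = fq1, fastq2 = fq2, sam = sam, n_fragments = n_frag)
}

#' Simulate Sanger trace channel peak heights at an editing site
#'
#' Produces the four-channel peak heights a bulk Sanger trace would show at a
#' partially edited position: the T channel carries `fraction` of the signal
#' and the C channel the rest (A and G are background). With `noise_sd = 0`
#' the recovered efficiency `T/(C+T)` equals `fraction` exactly.
#'
#' @param fraction edited fraction in `[0, 1]`
#' @param noise_sd Gaussian channel noise SD, on the unit total-signal scale
#' @param seed optional RNG seed
#' @return named numeric vector of heights for channels A, C, G, T
#' @export
simulate_trace <- function(fraction, noise_sd = 0, seed = NULL) {
  if (fraction < 0 || fraction > 1) stopf("fraction must be in [0, 1]")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  h <- c(A = 0, C = 1 - fraction, G = 0, T = fraction)
  if (noise_sd > 0) h <- pmax(h + rnorm(4, 0, noise_sd), 0)
  h
}
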