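#' Parse a PLS-motif table for a PPR protein
#'
#' Reads the ordered motif list of a PLS-type PPR protein. Each motif is
#' characterized by the residues that specify its nucleotide preference in
#' the PPR recognition code: position 6 of the motif and position 1' (the
#' first residue of the next motif towards the C terminus). Rows whose class
#' is an E, E+, E1, E2 or DYW region are dropped — only P/L/S-type motifs
#' contribute PWM columns.
#'
#' @param table path to a TSV with columns `index`, `class`, `aa6`, `aa1p`,
#'   or an equivalent data.frame
#' @return data.frame of motifs ordered N- to C-terminal
#' @export
parse_motifs <- function(table) {
  m <- if (is.data.frame(table)) table else read.delim(table, stringsAsFactors = FALSE)
  need <- c("index", "class", "aa6", "aa1p")
  if (!all(need %in% names(m)))
    stopf("motif table must have columns %s", paste(need, collapse = ", "))
  if (nrow(m) == 0) stopf("empty motif table: no scannable model")
  m <- m[order(m$index), , drop = FALSE]
  if (!all(diff(m$index) == 1))
    stopf("motif indices must be contiguous")
  m <- m[!(toupper(m$class) %in% c("E", "E+", "E1", "E2", "DYW")), , drop = FALSE]
  if (nrow(m) == 0) stopf("no P/L/S motifs left after excluding E/DYW regions")
  m$aa6 <- toupper(m$aa6)
  m$aa1p <- toupper(m$aa1p)
  rownames(m) <- NULL
  m
}

#' Load a PPR-code nucleotide preference table
#'
#' The table maps an (aa6, aa1') residue pair to a probability vector over
#' A, C, G, U. The packaged default (`system.file("extdata", "ppr_code.tsv",
#' package = "plastedit")`) transcribes the canonical published preferences
#' of the PPR code for the common residue combinations and is editable —
#' users can supply their own weighting. Pairs absent from the table fall
#' back to a uniform column.
#'
#' @param path TSV with columns aa6, aa1p, pA, pC, pG, pU (default: packaged
#'   table)
#' @return data.frame code table; rows validated to sum to 1
#' @export
read_code_table <- function(path = NULL) {
  path <- path %||% system.file("extdata", "ppr_code.tsv", package = "plastedit")
  ct <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("aa6", "aa1p", "pA", "pC", "pG", "pU")
  if (!all(need %in% names(ct)))
    stopf("code table must have columns %s", paste(need, collapse = ", "))
  s <- rowSums(ct[, c("pA", "pC", "pG", "pU")])
  if (any(abs(s - 1) > 1e-6))
    stopf("malformed code table: row(s) %s do not sum to 1",
          paste(which(abs(s - 1) > 1e-6), collapse = ","))
  if (any(ct[, c("pA", "pC", "pG", "pU")] < 0))
    stopf("malformed code table: negative probabilities")
  ct$aa6 <- toupper(ct$aa6)
  ct$aa1p <- toupper(ct$aa1p)
  ct
}

#' Build a binding-preference PWM from PPR motifs and the PPR code
#'
#' One PWM column per P/L/S motif, in N-to-C order — the N-terminal motif
#' pairs with the 5'-most base of the RNA target. Each column is the code
#' table's probability vector for the motif's (aa6, aa1') pair; pairs not in
#' the table (including gap residues) get the uniform fallback column. A
#' pseudocount is mixed into every column before taking log2 odds against
#' the background, so scores stay finite.
#'
#' @param motifs data.frame from [parse_motifs()]
#' @param code data.frame from [read_code_table()]
#' @param background named nucleotide background probabilities (A, C, G, T
#'   order; default uniform). Estimate from the scanned genome with
#'   [genome_background()] for FIMO-like behavior on AT-rich plastomes.
#' @param pseudocount mixed into columns before log-odds (default 0.01)
#' @return object of class `ppr_pwm`: list with `probs` (4 x L matrix, rows
#'   A/C/G/T with U kept as T), `log_odds`, `background`, `length`
#' @export
build_pwm <- function(motifs, code = read_code_table(),
                      background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                      pseudocount = 0.01) {
  stopifnot(is.data.frame(motifs), nrow(motifs) >= 1)
  background <- background[BASES]
  if (any(is.na(background)) || abs(sum(background) - 1) > 1e-6)
    stopf("background must be named probabilities over A,C,G,T summing to 1")
  if (pseudocount < 0) stopf("pseudocount must be >= 0")
  rs <- rowSums(code[, c("pA", "pC", "pG", "pU")])
  if (any(abs(rs - 1) > 1e-6) || any(code[, c("pA", "pC", "pG", "pU")] < 0))
    stopf("malformed code table: probability rows must be >= 0 and sum to 1")
  key <- paste(code$aa6, code$aa1p)
  probs <- vapply(seq_len(nrow(motifs)), function(i) {
    j <- match(paste(motifs$aa6[i], motifs$aa1p[i]), key)
    if (is.na(j)) rep(0.25, 4)
    else unlist(code[j, c("pA", "pC", "pG", "pU")], use.names = FALSE)
  }, numeric(4))
  rownames(probs) <- BASES   # U stored as T: scanning is over the DNA genome
  padded <- (probs + pseudocount) / (1 + 4 * pseudocount)
  log_odds <- log2(padded / background)
  structure(list(probs = probs, log_odds = log_odds,
                 background = background, pseudocount = pseudocount,
                 length = ncol(probs)),
            class = "ppr_pwm")
}

#' 0-order background frequencies of a genome
#' @param genome a [Biostrings::DNAString], `plastome`, or character string
#' @return named probability vector over A, C, G, T
#' @export
genome_background <- function(genome) {
  s <- .as_dnastring(genome)
  f <- Biostrings::letterFrequency(s, BASES)
  f / sum(f)
}

.as_dnastring <- function(genome) {
  if (inherits(genome, "plastome")) genome$seq
  else if (is(genome, "DNAString")) genome
  else Biostrings::DNAString(as.character(genome))
}

#' Consensus sequence of a PWM (highest-probability base per column)
#' @param pwm a `ppr_pwm`
#' @return character string over A/C/G/T
#' @export
pwm_consensus <- function(pwm) {
  paste(BASES[apply(pwm$probs, 2, which.max)], collapse = "")
}

#' Exact null score distribution of a PWM by dynamic programming
#'
#' Discretizes each column's log-odds scores to integer bins (granularity =
#' total score range / `bins`) and convolves the per-column background score
#' distributions, giving the exact probability mass function of the total
#' score of a random background sequence of PWM length. P-values of scan
#' hits are upper-tail sums of this pmf, the standard exact-P-value
#' construction used by motif scanners.
#'
#' @param pwm a `ppr_pwm`
#' @param bins number of discretization bins across the total score range
#'   (default 1000)
#' @return object of class `pwm_null`: `pmf`, `cum_ge` (P(S >= bin)),
#'   `int_scores` (4 x L integer matrix), `granularity`, `min_score`
#' @export
exact_null <- function(pwm, bins = 1000) {
  stopifnot(inherits(pwm, "ppr_pwm"))
  if (bins <= 0) stopf("granularity: bins must be > 0")
  lo <- pwm$log_odds
  colmin <- apply(lo, 2, min)
  rng <- sum(apply(lo, 2, max)) - sum(colmin)
  g <- if (rng <= 0) 1 else rng / bins
  int_scores <- round(sweep(lo, 2, colmin) / g)
  maxi <- sum(apply(int_scores, 2, max))
  pmf <- numeric(maxi + 1L)
  pmf[1] <- 1
  bg <- pwm$background
  for (j in seq_len(ncol(lo))) {
    new <- numeric(maxi + 1L)
    for (b in 1:4) {
      sh <- int_scores[b, j]
      nz <- which(pmf > 0)
      new[nz + sh] <- new[nz + sh] + pmf[nz] * bg[b]
    }
    pmf <- new
  }
  stopifnot(abs(sum(pmf) - 1) < 1e-9)
  cum_ge <- rev(cumsum(rev(pmf)))
  structure(list(pmf = pmf, cum_ge = cum_ge, int_scores = int_scores,
                 granularity = g, min_score = sum(colmin)),
            class = "pwm_null")
}

#' Exact P-value of a score under a PWM null distribution
#' @param null a `pwm_null`
#' @param int_score integer (binned) total score, as produced by summing the
#'   null's `int_scores` over a window
#' @return P(S >= int_score) under the background, in (0, 1]
#' @export
null_pvalue <- function(null, int_score) {
  i <- pmax(0L, pmin(as.integer(int_score), length(null$cum_ge) - 1L))
  null$cum_ge[i + 1L]
}

#' Scan a genome with a PPR PWM on both strands
#'
#' Scores every window of PWM length on the requested strands with the
#' log-odds matrix and assigns each window an exact P-value from
#' [exact_null()]. Minus-strand windows are scored on the reverse complement
#' and reported in forward coordinates with strand `"-"`; `sequence` is
#' always the matched (scanned-strand) sequence. Ambiguous bases contribute
#' the background-weighted average score of their column.
#'
#' @param pwm a `ppr_pwm`
#' @param genome `plastome`, [Biostrings::DNAString] or character
#' @param strands `"both"` (default), `"+"` or `"-"`
#' @param null optional precomputed [exact_null()] (recomputed otherwise)
#' @return data.frame: start, end, strand, sequence, score, p_value
#' @export
scan_genome <- function(pwm, genome, strands = c("both", "+", "-"), null = NULL) {
  strands <- match.arg(strands)
  s <- .as_dnastring(genome)
  L <- length(s)
  w <- pwm$length
  if (L < w) stopf("genome length %d shorter than PWM length %d", L, w)
  null <- null %||% exact_null(pwm)

  lo <- pwm$log_odds
  bg <- pwm$background
  amb_lo <- colSums(lo * bg)                         # background-weighted column mean
  amb_int <- round((amb_lo - apply(lo, 2, min)) / null$granularity)
  lo_ext <- rbind(lo, amb = amb_lo)
  int_ext <- rbind(null$int_scores, amb = as.integer(amb_int))

  scan_one <- function(seq_chr, strand) {
    codes <- match(strsplit(seq_chr, "")[[1]], BASES)
    codes[is.na(codes)] <- 5L
    nw <- nchar(seq_chr) - w + 1L
    sc <- numeric(nw); isc <- integer(nw)
    for (j in seq_len(w)) {
      cj <- codes[j:(j + nw - 1L)]
      sc <- sc + lo_ext[cbind(cj, j)]
      isc <- isc + int_ext[cbind(cj, j)]
    }
    seqs <- substring(seq_chr, seq_len(nw), seq_len(nw) + w - 1L)
    if (strand == "+") {
      data.frame(start = seq_len(nw), end = seq_len(nw) + w - 1L,
                 strand = "+", sequence = seqs, score = sc,
                 p_value = null_pvalue(null, isc), stringsAsFactors = FALSE)
    } else {
      ## window i on the reverse complement covers forward [L-i-w+2, L-i+1]
      fstart <- L - seq_len(nw) - w + 2L
      data.frame(start = fstart, end = fstart + w - 1L,
                 strand = "-", sequence = seqs, score = sc,
                 p_value = null_pvalue(null, isc), stringsAsFactors = FALSE)
    }
  }
  chr <- as.character(s)
  out <- list()
  if (strands %in% c("both", "+")) out$p <- scan_one(chr, "+")
  if (strands %in% c("both", "-"))
    out$m <- scan_one(as.character(Biostrings::reverseComplement(s)), "-")
  hits <- do.call(rbind, out)
  rownames(hits) <- NULL
  hits
}

#' Top-k binding-site predictions ranked by P-value
#'
#' Orders hits by ascending P-value, breaking ties by descending score, then
#' ascending start coordinate, then strand (`+` before `-`), and returns at
#' most `k` rows — the "ten top-predicted sites" convention by default.
#'
#' @param hits data.frame from [scan_genome()]
#' @param k maximum rows (default 10)
#' @return `hits` head with a `rank` column prepended
#' @export
rank_hits <- function(hits, k = 10) {
  if (k < 1) stopf("k must be >= 1")
  ord <- order(hits$p_value, -hits$score, hits$start,
               match(hits$strand, c("+", "-")))
  top <- hits[ord, , drop = FALSE][seq_len(min(k, nrow(hits))), , drop = FALSE]
  top <- cbind(rank = seq_len(nrow(top)), top)
  rownames(top) <- NULL
  top
}
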