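## fixtures and independent oracles, built in code at test time

## hand-built plastome object from a sequence string and a gene table
toy_plastome <- function(seq_chr, genes = NULL, name = "toy") {
  gr <- if (is.null(genes) || nrow(genes) == 0) {
    GenomicRanges::GRanges(seqnames = character(0),
                           ranges = IRanges::IRanges(),
                           gene_id = character(0), copy = integer(0))
  } else {
    GenomicRanges::GRanges(
      seqnames = name,
      ranges = IRanges::IRanges(genes$start, genes$end),
      strand = genes$strand, gene_id = genes$gene_id,
      copy = genes$copy %||% rep(1L, nrow(genes)),
      seqlengths = setNames(nchar(seq_chr), name))
  }
  structure(list(name = name, seq = Biostrings::DNAString(seq_chr),
                 genes = gr, config = NULL), class = "plastome")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## hand-written SAM from a record table (qname, flag, pos, mapq, seq)
write_toy_sam <- function(path, refname, reflen, rec) {
  header <- c("@HD\tVN:1.6", sprintf("@SQ\tSN:%s\tLN:%d", refname, reflen))
  body <- if (is.null(rec) || nrow(rec) == 0) character(0) else
    sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t%s",
            rec$qname, rec$flag, refname, rec$pos, rec$mapq,
            nchar(rec$seq), rec$seq, strrep("I", nchar(rec$seq)))
  writeLines(c(header, body), path)
  path
}

## mirror a plastome and a matching SAM into reverse-complement coordinates
flip_plastome <- function(ref) {
  L <- length(ref$seq)
  g <- ref$genes
  genes <- data.frame(
    gene_id = S4Vectors::mcols(g)$gene_id,
    start = L - GenomicRanges::end(g) + 1L,
    end = L - GenomicRanges::start(g) + 1L,
    strand = ifelse(as.character(GenomicRanges::strand(g)) == "+", "-", "+"),
    copy = S4Vectors::mcols(g)$copy)
  toy_plastome(as.character(Biostrings::reverseComplement(ref$seq)), genes,
               name = ref$name)
}

flip_sam <- function(sam_in, sam_out, L) {
  lines <- readLines(sam_in)
  is_hdr <- startsWith(lines, "@")
  out <- lines
  for (i in which(!is_hdr)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    rl <- as.integer(sub("M$", "", f[6]))
    pos <- as.integer(f[4])
    f[4] <- as.character(L - (pos + rl - 1L) + 1L)
    flag <- as.integer(f[2])
    f[2] <- as.character(bitwXor(flag, bitwOr(16L, if (bitwAnd(flag, 1L)) 32L else 0L)))
    f[10] <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(f[10])))
    pnext <- as.integer(f[8])
    if (pnext > 0) f[8] <- as.character(L - (pnext + rl - 1L) + 1L)
    f[9] <- as.character(-as.integer(f[9]))
    out[i] <- paste(f, collapse = "\t")
  }
  writeLines(out, sam_out)
  sam_out
}

## closed-form Welch t-test oracle (textbook formulas, one-tailed)
welch_oracle <- function(a, b, direction = "less") {
  ## statistic oriented as mean(b) - mean(a), like welch_one_tailed
  va <- sum((a - mean(a))^2) / (length(a) - 1)
  vb <- sum((b - mean(b))^2) / (length(b) - 1)
  se2 <- va / length(a) + vb / length(b)
  t <- (mean(b) - mean(a)) / sqrt(se2)
  df <- se2^2 / ((va / length(a))^2 / (length(a) - 1) +
                 (vb / length(b))^2 / (length(b) - 1))
  p <- switch(direction,
              less = stats::pt(t, df),
              greater = stats::pt(t, df, lower.tail = FALSE),
              two.sided = 2 * stats::pt(-abs(t), df))
  list(t = t, df = df, p = p)
}

## random PWM over a random 0-order background
random_pwm <- function(L, seed) {
  set.seed(seed)
  probs <- matrix(rgamma(4 * L, 1), 4, L)
  probs <- sweep(probs, 2, colSums(probs), "/")
  bg <- rgamma(4, 2); bg <- bg / sum(bg)
  motifs <- data.frame(index = seq_len(L), class = "P", aa6 = "X", aa1p = "X")
  pwm <- build_pwm(motifs, background = setNames(bg, c("A", "C", "G", "T")))
  pwm$probs <- probs
  padded <- (probs + pwm$pseudocount) / (1 + 4 * pwm$pseudocount)
  pwm$log_odds <- log2(padded / pwm$background)
  rownames(pwm$log_odds) <- rownames(pwm$probs) <- c("A", "C", "G", "T")
  pwm
}

## brute-force null: enumerate all 4^L sequences, weight by background.
## returns total real scores and their probabilities
brute_force_null <- function(pwm) {
  sc <- 0; pr <- 1
  for (j in seq_len(pwm$length)) {
    sc <- as.vector(outer(sc, pwm$log_odds[, j], "+"))
    pr <- as.vector(outer(pr, pwm$background, "*"))
  }
  list(score = sc, prob = pr)
}

## brute-force exact tail probability P(S >= s)
brute_force_pvalue <- function(bf, s, tol = 1e-12) {
  sum(bf$prob[bf$score >= s - tol])
}

## additive distance matrix from a random binary tree with known topology
additive_matrix <- function(n_taxa, seed) {
  set.seed(seed)
  tree <- ape::rtree(n_taxa, rooted = FALSE,
                     br = function(n) runif(n, 0.05, 0.5))
  d <- ape::cophenetic.phylo(tree)
  d <- d[sort(rownames(d)), sort(colnames(d))]
  list(tree = tree, d = d)
}
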