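test_that("sim_config enforces its invariants", {
  expect_error(sim_config(genome_length = 500), "genome_length")
  expect_error(sim_config(error_rate = 0.2), "error_rate")
  expect_error(sim_config(genome_length = 1000, read_length = 1000), "read_length")
  cfg <- sim_config(seed = 7)
  expect_equal(cfg$read_length, 250L)
})

test_that("simulate_plastome handles the empty case and is deterministic", {
  cfg <- sim_config(genome_length = 2000, n_genes = 0, ir_gene = FALSE, seed = 1)
  d1 <- file.path(tempdir(), "sim_a"); d2 <- file.path(tempdir(), "sim_b")
  ref <- simulate_plastome(cfg, outdir = d1)
  expect_equal(length(ref$genes), 0L)
  expect_equal(length(ref$seq), 2000L)
  simulate_plastome(cfg, outdir = d2)
  expect_identical(readBin(file.path(d1, "plastome.fa"), "raw", 1e6),
                   readBin(file.path(d2, "plastome.fa"), "raw", 1e6))
})

test_that("the inverted-repeat gene is placed twice as an exact reverse complement", {
  ref <- simulate_plastome(sim_config(genome_length = 10000, n_genes = 4,
                                      ir_gene = TRUE, seed = 5))
  gid <- S4Vectors::mcols(ref$genes)$gene_id
  dup <- unique(gid[duplicated(gid)])
  expect_length(dup, 1)
  rows <- which(gid == dup)
  expect_length(rows, 2)
  s <- as.character(ref$seq)
  g1 <- substr(s, GenomicRanges::start(ref$genes[rows[1]]),
               GenomicRanges::end(ref$genes[rows[1]]))
  g2 <- substr(s, GenomicRanges::start(ref$genes[rows[2]]),
               GenomicRanges::end(ref$genes[rows[2]]))
  expect_identical(g2, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(g1))))
  expect_false(as.character(GenomicRanges::strand(ref$genes[rows[1]])) ==
                 as.character(GenomicRanges::strand(ref$genes[rows[2]])))
})

test_that("simulate_plastome rejects infeasible gene packing", {
  expect_error(simulate_plastome(sim_config(genome_length = 1500, n_genes = 5,
                                            read_length = 100, seed = 1)),
               "pack")
})

test_that("plant_editing_sites plants coding-strand C sites with exact fractions", {
  ref <- simulate_plastome(sim_config(genome_length = 8000, n_genes = 4,
                                      ir_gene = FALSE, seed = 9))
  gid <- S4Vectors::mcols(ref$genes)$gene_id
  st <- as.character(GenomicRanges::strand(ref$genes))
  minus_gene <- gid[st == "-"][1]
  plus_gene <- gid[st == "+"][1]
  sites <- data.frame(gene = c(plus_gene, minus_gene),
                      offset = c(40, 25),
                      control = c(1.0, 0.0543))
  pl <- plant_editing_sites(ref, sites)
  tr <- pl$truth
  expect_equal(tr$fraction[tr$gene == plus_gene], 1.0)
  expect_equal(tr$fraction[tr$gene == minus_gene], 0.0543)
  ## a coding-strand C on a minus-strand gene is a G on the forward strand
  pm <- tr$position[tr$gene == minus_gene]
  expect_identical(substr(as.character(pl$ref$seq), pm, pm), "G")
  pp <- tr$position[tr$gene == plus_gene]
  expect_identical(substr(as.character(pl$ref$seq), pp, pp), "C")
  expect_error(plant_editing_sites(ref, data.frame(gene = plus_gene,
                                                   offset = 1e6, control = 0.5)),
               "offset")
  ## find an offset whose coding-strand base is not C
  prow <- ref$genes[gid == plus_gene]
  gene_seq <- substr(as.character(ref$seq), GenomicRanges::start(prow),
                     GenomicRanges::end(prow))
  off_not_c <- which(strsplit(gene_seq, "")[[1]] != "C")[1]
  expect_error(plant_editing_sites(ref, data.frame(gene = plus_gene,
                                                   offset = off_not_c,
                                                   control = 0.5),
                                   substitute = FALSE),
               "not C")
})

test_that("simulated reads carry planted edits at the planted rate", {
  cfg <- sim_config(genome_length = 2000, n_genes = 1, ir_gene = FALSE,
                    read_length = 250, mean_depth = 2000, error_rate = 0, seed = 21)
  ref <- simulate_plastome(cfg)
  g <- S4Vectors::mcols(ref$genes)$gene_id[1]
  pl <- plant_editing_sites(ref, data.frame(gene = g, offset = c(30, 60),
                                            control = c(0.5, 0.0)))
  sim <- simulate_reads(pl$ref, pl$truth, cfg, tempdir(), condition = "control",
                        seed = 31)
  p <- build_pileup(sim$sam, pl$ref)
  called <- call_editing_sites(p, pl$ref)
  pos_half <- pl$truth$position[pl$truth$fraction == 0.5]
  row <- called[called$position == pos_half, ]
  expect_equal(nrow(row), 1)
  ## within 3 binomial SD of the planted fraction
  expect_lt(abs(row$efficiency - 0.5), 3 * sqrt(0.25 / row$depth))
  ## fraction 0 with error 0: zero edited reads at the site
  pos_zero <- pl$truth$position[pl$truth$fraction == 0]
  pr <- p[p$position == pos_zero, ]
  expect_equal(pr$T, 0L)
})

test_that("simulated FASTQ reads have the configured 250-nt length and outputs are byte-reproducible", {
  cfg <- sim_config(genome_length = 2000, n_genes = 0, ir_gene = FALSE,
                    mean_depth = 5, seed = 4)
  s1 <- simulate_reads(simulate_plastome(cfg), NULL, cfg,
                       file.path(tempdir(), "rr1"), condition = "x", seed = 8)
  s2 <- simulate_reads(simulate_plastome(cfg), NULL, cfg,
                       file.path(tempdir(), "rr2"), condition = "x", seed = 8)
  fq <- readLines(s1$fastq1)
  expect_true(all(nchar(fq[seq(2, length(fq), by = 4)]) == 250L))
  expect_identical(readLines(s1$fastq1), readLines(s2$fastq1))
  expect_identical(readLines(s1$sam), readLines(s2$sam))
  expect_error(simulate_reads(simulate_plastome(cfg), NULL,
                              sim_config(genome_length = 2000, mean_depth = 0),
                              tempdir()),
               "mean_depth")
})

test_that("mean per-base depth is within 10% of the configured depth", {
  cfg <- sim_config(genome_length = 20000, n_genes = 0, ir_gene = FALSE,
                    mean_depth = 30, error_rate = 0, seed = 13)
  ref <- simulate_plastome(cfg)
  sim <- simulate_reads(ref, NULL, cfg, tempdir(), condition = "cov", seed = 13)
  p <- build_pileup(sim$sam, ref)
  mean_depth <- sum(p$depth) / cfg$genome_length
  expect_lt(abs(mean_depth - 30) / 30, 0.10)
})

test_that("simulate_trace inverts exactly without noise and approximately with noise", {
  h <- simulate_trace(0.5, 0)
  expect_equal(h[["C"]], h[["T"]])
  expect_equal(simulate_trace(1.0, 0)[["C"]], 0)
  expect_error(simulate_trace(0.5, -1), "noise_sd")
  expect_error(simulate_trace(1.5, 0), "fraction")
  set.seed(7)
  rec <- replicate(100, sanger_efficiency(simulate_trace(0.25, 0.01)))
  expect_lt(abs(mean(rec) - 0.25), 0.05)
})
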