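seq20 <- strrep("ACGT", 75)  # 300 bp toy reference

test_that("pileup tallies hand-written reads exactly", {
  ## 3 reads over position 11 (reference C): two carry T, one carries C
  ref <- toy_plastome(paste0("AAAAAAAAAACAAAAAAAAA", strrep("A", 280)),
                      data.frame(gene_id = "g1", start = 1, end = 100,
                                 strand = "+"))
  rd <- function(base) paste0("AAAAAAAAAA", base, "AAAAAAAAA")
  rec <- data.frame(qname = c("r1", "r2", "r3"), flag = 0L, pos = 1L,
                    mapq = 60L, seq = c(rd("T"), rd("T"), rd("C")))
  sam <- write_toy_sam(tempfile(fileext = ".sam"), "toy", 300, rec)
  p <- build_pileup(sam, ref)
  row <- p[p$position == 11, ]
  expect_equal(row$T, 2L)
  expect_equal(row$C, 1L)
  expect_equal(row$depth, 3L)
  ## tally conservation: total depth equals reads x aligned bases
  expect_equal(sum(p$depth), 3L * 20L)
})

test_that("empty SAM gives an empty pileup and empty call set", {
  ref <- toy_plastome(seq20, data.frame(gene_id = "g1", start = 1, end = 300,
                                        strand = "+"))
  sam <- write_toy_sam(tempfile(fileext = ".sam"), "toy", 300, NULL)
  p <- build_pileup(sam, ref)
  expect_equal(nrow(p), 0)
  expect_equal(nrow(call_editing_sites(p, ref)), 0)
})

test_that("build_pileup refuses a mismatching reference name", {
  ref <- toy_plastome(seq20)
  sam <- write_toy_sam(tempfile(fileext = ".sam"), "otherRef", 300, NULL)
  expect_error(build_pileup(sam, ref), "otherRef")
})

test_that("editing efficiency is T/(C+T) with an undefined-zero distinction", {
  expect_equal(editing_efficiency(50, 50), 0.5)
  expect_equal(editing_efficiency(0, 10), 0)
  expect_true(is.na(editing_efficiency(0, 0)))
  expect_error(editing_efficiency(-1, 5), "non-negative")
  expect_identical(format_percent(0.0543), "5.43%")
})

test_that("sites below depth or evidence thresholds are not called", {
  ref <- toy_plastome(paste0("AAAAAAAAAACAAAAAAAAA", strrep("A", 280)),
                      data.frame(gene_id = "g1", start = 1, end = 100,
                                 strand = "+"))
  rd <- function(base) paste0("AAAAAAAAAA", base, "AAAAAAAAA")
  rec <- data.frame(qname = paste0("r", 1:5), flag = 0L, pos = 1L, mapq = 60L,
                    seq = c(rd("T"), rd("T"), rd("T"), rd("C"), rd("C")))
  sam <- write_toy_sam(tempfile(fileext = ".sam"), "toy", 300, rec)
  p <- build_pileup(sam, ref)
  expect_equal(nrow(call_editing_sites(p, ref, call_thresholds(min_depth = 10))), 0)
  called <- call_editing_sites(p, ref, call_thresholds(min_depth = 5))
  expect_equal(called$efficiency, 0.6)
  expect_identical(called$site_id, "g1")   # single-site gene: bare name
})

test_that("site naming follows 5'->3' transcript order on both strands", {
  ann <- GenomicRanges::GRanges("toy",
                                IRanges::IRanges(c(1, 200), c(100, 300)),
                                strand = c("+", "-"),
                                gene_id = c("ndhD", "petB"), copy = 1L)
  sites <- data.frame(gene = c("ndhD", "ndhD", "petB", "petB", "psbL"),
                      position = c(10, 50, 220, 280, 150),
                      strand = c("+", "+", "-", "-", "+"),
                      edited_count = 5L, unedited_count = 5L,
                      efficiency = 0.5, depth = 10L, n_multimapped = 0L)
  sites$gene[5] <- "intergenic"
  named <- name_sites(sites, ann)
  expect_identical(named$site_id[named$position == 10], "ndhD-1")
  expect_identical(named$site_id[named$position == 50], "ndhD-2")
  ## minus strand: 5'->3' is descending genome coordinate
  expect_identical(named$site_id[named$position == 280], "petB-1")
  expect_identical(named$site_id[named$position == 220], "petB-2")
  expect_identical(named$site_id[named$position == 150], "intergenic-150")
})

test_that("a single planted site in a gene is called with its bare gene name", {
  cfg <- sim_config(genome_length = 5000, n_genes = 3, ir_gene = FALSE,
                    mean_depth = 100, error_rate = 0, seed = 17)
  ref <- simulate_plastome(cfg)
  gid <- S4Vectors::mcols(ref$genes)$gene_id
  pl <- plant_editing_sites(ref, data.frame(gene = gid[2], offset = 77,
                                            control = 1.0))
  sim <- simulate_reads(pl$ref, pl$truth, cfg, tempdir(), seed = 18)
  called <- call_editing_sites(build_pileup(sim$sam, pl$ref), pl$ref)
  expect_equal(nrow(called), 1)
  expect_identical(called$site_id, gid[2])
  expect_equal(called$efficiency, 1.0)
})

test_that("calling is invariant under reverse-complementing the reference", {
  cfg <- sim_config(genome_length = 6000, n_genes = 4, ir_gene = FALSE,
                    mean_depth = 80, error_rate = 0, seed = 23)
  ref <- simulate_plastome(cfg)
  gid <- S4Vectors::mcols(ref$genes)$gene_id
  pl <- plant_editing_sites(ref, data.frame(gene = gid[1:3],
                                            offset = c(33, 90, 140),
                                            cond = c(0.9, 0.4, 0.05)))
  sim <- simulate_reads(pl$ref, pl$truth, cfg, tempdir(), seed = 24)
  called <- call_editing_sites(build_pileup(sim$sam, pl$ref), pl$ref)

  flipped_ref <- flip_plastome(pl$ref)
  flipped_sam <- flip_sam(sim$sam, tempfile(fileext = ".sam"), cfg$genome_length)
  called_f <- call_editing_sites(build_pileup(flipped_sam, flipped_ref), flipped_ref)

  expect_identical(sort(called$site_id), sort(called_f$site_id))
  m <- match(called$site_id, called_f$site_id)
  expect_equal(called$efficiency, called_f$efficiency[m])
  expect_equal(called$position, cfg$genome_length - called_f$position[m] + 1L)
})

test_that("excluding multi-mappers changes IR depth by exactly the MAPQ-0 records", {
  cfg <- sim_config(genome_length = 12000, n_genes = 4, ir_gene = TRUE,
                    mean_depth = 60, error_rate = 0, seed = 29)
  ref <- simulate_plastome(cfg)
  gid <- S4Vectors::mcols(ref$genes)$gene_id
  ir_gene <- gid[duplicated(gid)][1]
  pl <- plant_editing_sites(ref, data.frame(gene = ir_gene, offset = 55,
                                            cond = 0.4))
  sim <- simulate_reads(pl$ref, pl$truth, cfg, tempdir(), seed = 30)

  with_mm <- build_pileup(sim$sam, pl$ref, include_multimapped = TRUE)
  no_mm <- build_pileup(sim$sam, pl$ref, include_multimapped = FALSE)

  ## count MAPQ-0 records overlapping each planted position in the raw SAM
  lines <- readLines(sim$sam)
  lines <- lines[!startsWith(lines, "@")]
  f <- strsplit(lines, "\t", fixed = TRUE)
  pos <- vapply(f, function(x) as.integer(x[4]), integer(1))
  mapq <- vapply(f, function(x) as.integer(x[5]), integer(1))
  rl <- cfg$read_length
  for (p in unique(pl$truth$position)) {
    n_mapq0 <- sum(mapq == 0 & pos <= p & pos + rl - 1L >= p)
    d_all <- with_mm$depth[with_mm$position == p]
    d_uniq <- no_mm$depth[no_mm$position == p]
    if (length(d_uniq) == 0) d_uniq <- 0L
    expect_equal(d_all - d_uniq, n_mapq0)
    expect_equal(with_mm$n_multimapped[with_mm$position == p], n_mapq0)
  }

  ## proportionally planted IR copies: efficiency unchanged by the toggle
  called_mm <- call_editing_sites(with_mm, pl$ref)
  called_un <- call_editing_sites(no_mm, pl$ref)
  m <- match(called_mm$position, called_un$position)
  expect_true(all(abs(called_mm$efficiency - called_un$efficiency[m]) < 0.12))
})

test_that("no sites are called without planted editing at error rate zero", {
  cfg <- sim_config(genome_length = 8000, n_genes = 4, ir_gene = TRUE,
                    mean_depth = 50, error_rate = 0, seed = 37)
  ref <- simulate_plastome(cfg)
  sim <- simulate_reads(ref, NULL, cfg, tempdir(), condition = "none", seed = 38)
  called <- call_editing_sites(build_pileup(sim$sam, ref), ref)
  expect_equal(nrow(called), 0)
})

test_that("an exclusion mask removes sites from the call set", {
  cfg <- sim_config(genome_length = 5000, n_genes = 3, ir_gene = FALSE,
                    mean_depth = 60, error_rate = 0, seed = 41)
  ref <- simulate_plastome(cfg)
  gid <- S4Vectors::mcols(ref$genes)$gene_id
  pl <- plant_editing_sites(ref, data.frame(gene = gid[1], offset = c(20, 120),
                                            cond = c(0.8, 0.8)))
  sim <- simulate_reads(pl$ref, pl$truth, cfg, tempdir(), seed = 42)
  pile <- build_pileup(sim$sam, pl$ref)
  mask <- GenomicRanges::GRanges(ref$name,
                                 IRanges::IRanges(pl$truth$position[1], width = 1))
  called <- call_editing_sites(pile, pl$ref, exclude = mask)
  expect_equal(nrow(called), 1)
  expect_false(pl$truth$position[1] %in% called$position)
})

test_that("sanger efficiency uses the coding-strand channels and complements antisense traces", {
  expect_equal(sanger_efficiency(c(A = 0, C = 100, G = 0, T = 100)), 0.5)
  expect_equal(sanger_efficiency(c(A = 70, C = 0, G = 30, T = 0), strand = "-"), 0.7)
  expect_true(is.na(sanger_efficiency(c(A = 5, C = 0, G = 9, T = 0))))
  ## inverse of the trace simulator, noise-free
  for (f in c(0, 0.25, 0.0543, 1)) {
    expect_equal(sanger_efficiency(simulate_trace(f, 0)), f)
  }
})
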