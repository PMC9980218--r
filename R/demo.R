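#' One-command synthetic end-to-end analysis
#'
#' Runs the whole pipeline on synthetic data with planted truth: simulates a
#' plastome with an inverted-repeat gene, plants editing sites with known
#' per-condition fractions, simulates a 3-replicate control and 4-replicate
#' silenced ("IPI1") read set, calls and names editing sites per library,
#' tests each site for differential editing, classifies signatures, scans the
#' genome with the packaged synthetic PPR model for binding-site predictions,
#' and builds the bootstrap NJ tree of the packaged synthetic ortholog
#' alignment. All tables, a newick tree and a run log (seed, parameters,
#' input checksums) are written to `outdir`.
#'
#' The returned report reconciles planted truth with calls: per planted site
#' and condition, the planted fraction, the mean called efficiency, and the
#' differential-test verdict.
#'
#' @param outdir output directory
#' @param seed master seed; per-library seeds are derived from it
#' @param config a [sim_config()]; the default uses a 20 kb plastome,
#'   250-nt reads and mean depth 120 (enough for well-resolved efficiencies
#'   at every planted fraction)
#' @param sites planted-site specification: data.frame with columns `gene`,
#'   `offset`, `control`, `IPI1` (fractions per condition); default plants 6
#'   sites of which 3 are strongly reduced under IPI1 silencing
#' @param alpha significance level for the differential test
#' @param k top-k binding-site predictions to keep
#' @param n_boot bootstrap replicates for the tree
#' @return invisibly, a list with the report data.frame, all result tables
#'   and output paths
#' @export
run_demo <- function(outdir, seed = 1, config = NULL, sites = NULL,
                     alpha = 0.05, k = 10, n_boot = 1000) {
  t0 <- Sys.time()
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  config <- config %||% sim_config(genome_length = 20000, n_genes = 8,
                                   ir_gene = TRUE, read_length = 250,
                                   mean_depth = 120, error_rate = 0.001,
                                   seed = seed)
  ref <- simulate_plastome(config, outdir = file.path(outdir, "ref"))

  if (is.null(sites)) {
    gids <- unique(S4Vectors::mcols(ref$genes)$gene_id)
    ## ndhB (IR gene) gets two sites; three sites reduced under silencing
    sites <- data.frame(
      gene = c(gids[1], gids[1], gids[2], gids[3], gids[4], gids[5]),
      offset = c(120, 300, 200, 150, 400, 90),
      control = c(0.90, 0.60, 0.95, 0.40, 0.85, 0.0543),
      IPI1 = c(0.30, 0.60, 0.35, 0.40, 0.25, 0.0543))
  }
  planted <- plant_editing_sites(ref, sites,
                                 truth_file = file.path(outdir, "truth.tsv"))
  ref <- planted$ref
  truth <- planted$truth

  conds <- list(control = 3L, IPI1 = 4L)
  th <- call_thresholds()
  eff_tables <- list()
  for (cond in names(conds)) {
    rows <- list()
    for (r in seq_len(conds[[cond]])) {
      lib_seed <- (seed * 1000L + match(cond, names(conds)) * 100L + r) %% .Machine$integer.max
      sim <- simulate_reads(ref, truth, config, outdir = file.path(outdir, "reads"),
                            condition = cond, seed = lib_seed,
                            prefix = sprintf("%s_rep%d", cond, r))
      pl <- build_pileup(sim$sam, ref, include_multimapped = th$include_multimapped)
      called <- call_editing_sites(pl, ref, th)
      write_site_table(called, file.path(outdir,
                                         sprintf("sites_%s_rep%d.tsv", cond, r)))
      if (nrow(called)) {
        ## key sites by planted truth id where possible so that rare
        ## noise calls inside a gene cannot shift the numbering of planted
        ## sites between replicates
        tid <- truth$site_id[match(called$position, truth$position)]
        sid <- ifelse(is.na(tid),
                      paste0(called$gene, "@", called$position), tid)
        rows[[r]] <- data.frame(site_id = sid, replicate = r,
                                efficiency = called$efficiency,
                                stringsAsFactors = FALSE)
      }
    }
    eff_tables[[cond]] <- do.call(rbind, rows)
  }

  no_sites <- is.null(eff_tables$control) || is.null(eff_tables$IPI1)
  if (!no_sites) {
    diff <- compare_conditions(eff_tables$control, eff_tables$IPI1, alpha = alpha)
    write.table(diff, file.path(outdir, "diff.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    sig <- suppressWarnings(classify_signatures(list(IPI1 = diff)))
    write.table(sig, file.path(outdir, "signatures.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  } else {
    diff <- data.frame(site_id = character(0), delta = numeric(0),
                       p_one_tailed = numeric(0), significant = logical(0),
                       direction = character(0))
    sig <- data.frame(site_id = character(0), label = character(0))
    write.table(diff, file.path(outdir, "diff.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(sig, file.path(outdir, "signatures.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  ## PPR-code binding-site prediction on the simulated plastome
  motifs <- parse_motifs(system.file("extdata", "ipi1_motifs_synthetic.tsv",
                                     package = "plastedit"))
  pwm <- build_pwm(motifs, background = genome_background(ref))
  hits <- rank_hits(scan_genome(pwm, ref), k = k)
  write.table(hits, file.path(outdir, "predicted_sites.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  ## ortholog phylogeny from the packaged synthetic alignment
  afa <- system.file("extdata", "ipi1_orthologs_synthetic.afa",
                     package = "plastedit")
  bs <- bootstrap_support(read_protein_alignment(afa), n_reps = n_boot,
                          seed = seed)
  nwk <- file.path(outdir, "ipi1_orthologs.nwk")
  ape::write.tree(bs$tree, nwk)

  ## reconcile planted truth with calls and differential results
  report <- NULL
  if (!no_sites) {
    tw <- unique(truth[, c("site_id", "gene", "position", "strand")])
    tw <- tw[!duplicated(tw$site_id), ]
    frac <- stats::reshape(unique(truth[, c("site_id", "condition", "fraction")]),
                           idvar = "site_id", timevar = "condition",
                           direction = "wide")
    names(frac) <- sub("^fraction\\.", "planted_", names(frac))
    mean_eff <- function(tab) {
      v <- tapply(tab$efficiency, tab$site_id, mean)
      data.frame(site_id = names(v), called = as.numeric(v))
    }
    report <- merge(tw, frac, by = "site_id")
    for (cond in names(conds)) {
      me <- mean_eff(eff_tables[[cond]])
      names(me)[2] <- paste0("called_", cond)
      report <- merge(report, me, by = "site_id", all.x = TRUE)
    }
    report <- merge(report,
                    diff[, c("site_id", "delta", "p_one_tailed", "significant",
                             "direction")], by = "site_id", all.x = TRUE)
    report <- merge(report, sig, by = "site_id", all.x = TRUE)
    report <- report[order(report$position), ]
    rownames(report) <- NULL
    write.table(report, file.path(outdir, "report.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }

  log_lines <- c(
    sprintf("plastedit demo | %s", format(t0)),
    sprintf("plastedit version: %s", as.character(utils::packageVersion("plastedit"))),
    sprintf("R version: %s", R.version.string),
    sprintf("seed: %d", seed),
    sprintf("genome_length: %d  n_genes: %d  ir_gene: %s", config$genome_length,
            config$n_genes, config$ir_gene),
    sprintf("read_length: %d  mean_depth: %g  error_rate: %g",
            config$read_length, config$mean_depth, config$error_rate),
    sprintf("replicates: control=%d IPI1=%d", conds$control, conds$IPI1),
    sprintf("alpha: %g  k: %d  n_boot: %d", alpha, k, n_boot),
    "input checksums:",
    sprintf("  %s  %s", tools::md5sum(file.path(outdir, "ref", "plastome.fa")),
            "ref/plastome.fa"),
    sprintf("  %s  %s", tools::md5sum(file.path(outdir, "truth.tsv")), "truth.tsv"),
    sprintf("elapsed: %.1f s", as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  writeLines(log_lines, file.path(outdir, "run_log.txt"))

  invisible(list(report = report, truth = truth, diff = diff, signatures = sig,
                 predicted = hits, tree = bs$tree, support = bs$support,
                 efficiencies = eff_tables, outdir = outdir,
                 ref = ref, config = config))
}
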