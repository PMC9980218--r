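#' One-tailed Welch t-test for a difference in editing efficiency
#'
#' Welch's unequal-variance t statistic for `test` versus `control` replicate
#' efficiencies, with Welch–Satterthwaite degrees of freedom and a one-tailed
#' p-value. The statistic is oriented as `mean(test) - mean(control)`, so
#' `direction = "less"` asks whether editing is *reduced* in the test
#' condition. If both samples have zero variance and equal means, `t = 0` and
#' `p = 0.5` by convention.
#'
#' @param control,test numeric replicate vectors, each of length >= 2
#' @param direction `"less"` (test < control), `"greater"`, or `"two.sided"`
#' @return list with `t`, `df`, `p`
#' @examples
#' welch_one_tailed(c(0.9, 0.92, 0.88), c(0.3, 0.35, 0.25), "less")
#' @export
welch_one_tailed <- function(control, test, direction = c("less", "greater", "two.sided")) {
  direction <- match.arg(direction)
  if (length(control) < 2 || length(test) < 2)
    stopf("each sample needs >= 2 replicates (got %d and %d)",
          length(control), length(test))
  if (var(control) == 0 && var(test) == 0) {
    if (mean(test) == mean(control))
      return(list(t = 0, df = length(control) + length(test) - 2,
                  p = if (direction == "two.sided") 1 else 0.5))
    return(list(t = sign(mean(test) - mean(control)) * Inf,
                df = length(control) + length(test) - 2,
                p = {
                  d <- mean(test) - mean(control)
                  if (direction == "two.sided") 0
                  else if ((direction == "less") == (d < 0)) 0 else 1
                }))
  }
  res <- t.test(test, control, alternative = direction, var.equal = FALSE)
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

.cond_long <- function(x, what) {
  if (!is.data.frame(x) || !all(c("site_id", "efficiency") %in% names(x)))
    stopf("%s must be a data.frame with site_id and efficiency columns", what)
  if (any(x$efficiency < 0 | x$efficiency > 1, na.rm = TRUE))
    stopf("%s efficiencies must be in [0, 1]", what)
  x
}

#' Differential editing between two conditions
#'
#' Per shared site, compares replicate editing efficiencies of a test
#' condition (e.g. VIGS-silenced) against a control with a one-tailed Welch
#' t-test ([welch_one_tailed()]). The tail is taken from the sign of the
#' observed difference, so both significant decreases and significant
#' increases can be reported, matching analyses that flag either direction at
#' raw p < alpha. No multiple-testing correction is applied by default;
#' Benjamini–Hochberg is available via `adjust = "BH"`.
#'
#' @param control,test long-format data.frames with columns `site_id` and
#'   `efficiency` (one row per replicate; a `replicate` column is allowed and
#'   ignored)
#' @param alpha significance level for the `significant` flag (default 0.05)
#' @param mode `"one.tailed"` (default; tail follows the observed delta) or
#'   `"two.tailed"`; or a fixed tail `"less"`/`"greater"` applied to every site
#' @param adjust p-value adjustment method for [stats::p.adjust] (default
#'   `"none"`)
#' @return data.frame with one row per shared site: site_id, n_control,
#'   n_test, mean_control, mean_test, delta, t_stat, df, p_one_tailed,
#'   significant, direction; a `summary` attribute holds the counts of
#'   increased/decreased/significant sites
#' @export
compare_conditions <- function(control, test, alpha = 0.05,
                               mode = c("one.tailed", "two.tailed", "less", "greater"),
                               adjust = "none") {
  mode <- match.arg(mode)
  control <- .cond_long(control, "control")
  test <- .cond_long(test, "test")
  shared <- intersect(unique(control$site_id), unique(test$site_id))
  if (length(shared) == 0) stopf("no shared site_ids between conditions")
  rows <- lapply(shared, function(s) {
    a <- control$efficiency[control$site_id == s]
    b <- test$efficiency[test$site_id == s]
    delta <- mean(b) - mean(a)
    dir_tail <- switch(mode,
                       one.tailed = if (delta < 0) "less" else "greater",
                       two.tailed = "two.sided",
                       mode)
    w <- welch_one_tailed(a, b, dir_tail)
    data.frame(site_id = s, n_control = length(a), n_test = length(b),
               mean_control = mean(a), mean_test = mean(b), delta = delta,
               t_stat = w$t, df = w$df, p_one_tailed = w$p,
               direction = if (delta < 0) "decreased"
                           else if (delta > 0) "increased" else "unchanged",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- p.adjust(out$p_one_tailed, method = adjust)
  out$significant <- out$p_adj < alpha
  out <- out[order(out$p_one_tailed, out$site_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "summary") <- c(
    n_sites = nrow(out),
    n_increased = sum(out$direction == "increased"),
    n_decreased = sum(out$direction == "decreased"),
    n_significant = sum(out$significant),
    n_significant_decreased = sum(out$significant & out$direction == "decreased"),
    n_significant_increased = sum(out$significant & out$direction == "increased"))
  out
}

#' Leaf-age trend in editing efficiency
#'
#' Compares the oldest against the youngest leaf class per site. Leaves are
#' numbered from the bottom of the plant, so lower numbers are older; by
#' default the lowest-numbered class is "old" and the highest-numbered is
#' "young", and the one-tailed test asks per site whether editing changed in
#' the older leaf. Sites then get a trend label: `decreased`/`increased` if
#' significant, else `unaffected` — allowing the per-site heterogeneity in
#' which some sites lose editing with leaf age and others do not.
#'
#' @param tables named list of long-format tables (as in
#'   [compare_conditions()]), names coercible to leaf numbers
#' @param old,young leaf numbers to compare (defaults: min and max)
#' @param alpha significance level
#' @return the [compare_conditions()] result for old-vs-young with an added
#'   `trend` column
#' @export
age_trend <- function(tables, old = NULL, young = NULL, alpha = 0.05) {
  leaves <- suppressWarnings(as.numeric(names(tables)))
  if (length(tables) < 2 || any(is.na(leaves)))
    stopf("need >= 2 leaf classes with numeric names")
  old <- old %||% min(leaves)
  young <- young %||% max(leaves)
  res <- compare_conditions(control = tables[[as.character(young)]],
                            test = tables[[as.character(old)]],
                            alpha = alpha)
  res$trend <- ifelse(res$significant, res$direction, "unaffected")
  res
}

#' Classify per-site editing signatures across silencing conditions
#'
#' Given differential results for several silenced conditions (each versus a
#' common non-silenced control) and the name of a general-chlorosis stress
#' control (a PDS-like silencing that bleaches leaves without touching the
#' editing machinery directly), labels each site:
#' * `general_stress` — significant in the stress control, i.e. the editing
#'   change is likely a secondary effect of chloroplast dysfunction;
#' * `specific:<condition>` — significant in exactly one non-control
#'   condition;
#' * `shared` — significant in two or more non-control conditions;
#' * `unaffected` — significant nowhere.
#'
#' @param results named list of [compare_conditions()] data.frames, one per
#'   condition
#' @param stress_control name of the stress-control condition in `results`,
#'   or `NULL` (then labels are restricted to specific/shared/unaffected,
#'   with a warning)
#' @return data.frame: site_id, label; every site gets exactly one label
#' @export
classify_signatures <- function(results, stress_control = NULL) {
  stopifnot(is.list(results), !is.null(names(results)))
  if (!is.null(stress_control) && !(stress_control %in% names(results))) {
    warning("stress control '", stress_control,
            "' not among results; labels restricted to specific/shared/unaffected")
    stress_control <- NULL
  }
  all_sites <- sort(unique(unlist(lapply(results, `[[`, "site_id"))))
  sig_in <- lapply(results, function(r) r$site_id[r$significant])
  non_ctrl <- setdiff(names(results), stress_control)
  label <- vapply(all_sites, function(s) {
    if (!is.null(stress_control) && s %in% sig_in[[stress_control]])
      return("general_stress")
    hits <- non_ctrl[vapply(non_ctrl, function(cc) s %in% sig_in[[cc]], logical(1))]
    if (length(hits) == 0) "unaffected"
    else if (length(hits) == 1) paste0("specific:", hits)
    else "shared"
  }, character(1))
  data.frame(site_id = all_sites, label = unname(label), stringsAsFactors = FALSE)
}

#' Cross-species conservation of editing sites
#'
#' Intersects two species' editing-site tables by a shared key — gene plus
#' within-gene offset — and reports how many sites are conserved and how many
#' are unique to each species.
#'
#' @param sites_a,sites_b data.frames carrying the key columns
#' @param key character vector of key columns (default `c("gene", "offset")`)
#' @return list: `n_conserved`, `n_unique_a`, `n_unique_b`, and `table`, the
#'   full outer join with a `status` column
#' @examples
#' a <- data.frame(gene = c("ndhB", "ndhB", "rpoA"), offset = c(10, 50, 7))
#' b <- data.frame(gene = c("ndhB", "rpoA"), offset = c(10, 7))
#' conservation_compare(a, b)$n_conserved  # 2
#' @export
conservation_compare <- function(sites_a, sites_b, key = c("gene", "offset")) {
  for (nm in list(a = sites_a, b = sites_b)) {
    if (!all(key %in% names(nm))) stopf("key columns %s missing",
                                        paste(key, collapse = ","))
  }
  ka <- do.call(paste, c(sites_a[key], sep = "\r"))
  kb <- do.call(paste, c(sites_b[key], sep = "\r"))
  if (anyDuplicated(ka)) stopf("duplicate keys in sites_a")
  if (anyDuplicated(kb)) stopf("duplicate keys in sites_b")
  conserved <- intersect(ka, kb)
  all_k <- union(ka, kb)
  parts <- do.call(rbind, strsplit(all_k, "\r", fixed = TRUE))
  tab <- data.frame(parts, stringsAsFactors = FALSE)
  names(tab) <- key
  tab$status <- ifelse(all_k %in% conserved, "conserved",
                       ifelse(all_k %in% ka, "unique_a", "unique_b"))
  list(n_conserved = length(conserved),
       n_unique_a = sum(!(ka %in% kb)),
       n_unique_b = sum(!(kb %in% ka)),
       table = tab)
}
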