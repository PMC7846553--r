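#' Run the full two-group analysis pipeline
#'
#' Orchestrates every stage on one dataset: the three per-probe criteria
#' (ME, CD, SE) with BH-FDR; power/critical-value calibration for the
#' tests used; per-group correlation matrices, the nine correlation-bin
#' networks with graph summaries of the high-correlation bins, specific
#' (non-shared-node) networks; Fisher r-to-z differential-edge networks
#' and the correlation-difference density; and the differential
#' multiple-regression screen. All randomness flows from one `seed`.
#'
#' The all-pairs stages are quadratic in the probe count; inputs larger
#' than `max_probes` are refused unless the cap is raised explicitly.
#'
#' @param ds an [expression_dataset()], or `NULL` to generate one from
#'   `config`.
#' @param config optional [synthetic_config()] used when `ds` is `NULL`
#'   (supplying both is a configuration error).
#' @param alpha significance level for the per-probe criteria.
#' @param n_bins entropy grid bins.
#' @param n_boot SE bootstrap resamples.
#' @param diff_alphas significance levels for the differential networks.
#' @param mra options list for [screen_relations()] (fields
#'   `pairs_per_class`, `third_probe_samples`), or `NULL` to skip the
#'   screen.
#' @param max_probes guard on the all-pairs computation.
#' @param seed integer root seed.
#' @param out_dir optional directory; when given, all result tables and
#'   networks are written there together with a run manifest
#'   (`manifest.json` when the jsonlite package is available, otherwise
#'   `manifest.tsv`).
#' @return object of class `dcna_run`: list with `metrics`,
#'   `criteria_correlations`, `power` (critical-value/power table),
#'   `bin_counts`, `high_summaries`, `specific_summaries`,
#'   `differential` ([differential_edges()] result),
#'   `correlation_pdf`, `mra` ([screen_relations()] result or `NULL`),
#'   `truth` (when synthetic), `params`, `manifest`.
#' @export
run_pipeline <- function(ds = NULL, config = NULL, alpha = 0.05,
                         n_bins = 10L, n_boot = 1000L,
                         diff_alphas = c(0.05), mra = list(),
                         max_probes = 5000L, seed = 1L, out_dir = NULL) {
  if (!is.null(ds) && !is.null(config))
    stop("supply either a dataset or a synthetic config, not both")
  truth <- NULL
  if (is.null(ds)) {
    if (is.null(config)) config <- synthetic_config(seed = seed)
    gen <- generate_dataset(config)
    ds <- gen$dataset; truth <- gen$truth
  }
  stopifnot(inherits(ds, "expression_dataset"))
  if (nrow(ds$values) > max_probes)
    stop("dataset has ", nrow(ds$values), " probes; raise `max_probes` ",
         "to allow the quadratic all-pairs stages at this size")
  ns <- n_samples(ds)

  metrics <- probe_metrics(ds, alpha = alpha, n_bins = n_bins,
                           n_boot = n_boot, seed = seed)
  crit_cor <- criteria_correlations(metrics)

  power_tab <- data.frame(
    quantity = c(sprintf("critical_rho_n%d", ns[1L]),
                 sprintf("critical_rho_n%d", ns[2L]),
                 "power_coverage_10pct_90"),
    value = c(correlation_critical_value(ns[1L]),
              correlation_critical_value(ns[2L]),
              power_coverage(ds)$coverage),
    stringsAsFactors = FALSE)

  corr1 <- group_correlation_matrix(ds, 1L)
  corr2 <- group_correlation_matrix(ds, 2L)
  bins1 <- bin_networks(corr1, bins = c(1L, 9L))
  bins2 <- bin_networks(corr2, bins = c(1L, 9L))
  bin_counts <- merge(bins1$counts, bins2$counts,
                      by = c("bin", "label", "high"),
                      suffixes = c("_group1", "_group2"))
  bin_counts <- bin_counts[order(bin_counts$bin), , drop = FALSE]

  summarize_high <- function(nets, group) {
    out <- list()
    for (k in c(1L, 9L)) {
      g <- nets$networks[[k]]
      if (!is.null(g) && igraph::vcount(g) > 0L)
        out[[correlation_bins()$label[k]]] <- graph_summary(g)
    }
    out
  }
  high1 <- summarize_high(bins1, 1L)
  high2 <- summarize_high(bins2, 2L)

  specific <- list()
  for (lab in union(names(high1), names(high2))) {
    k <- match(lab, correlation_bins()$label)
    ga <- bins1$networks[[k]]; gb <- bins2$networks[[k]]
    if (is.null(ga) || is.null(gb)) next
    sp <- specific_networks(ga, gb)
    specific[[lab]] <- list(
      group1 = if (igraph::vcount(sp$a) > 0L) graph_summary(sp$a),
      group2 = if (igraph::vcount(sp$b) > 0L) graph_summary(sp$b))
  }

  diff <- differential_edges(corr1, corr2, alphas = diff_alphas)
  cpdf <- correlation_difference_pdf(corr1, corr2)

  mra_res <- NULL
  if (!is.null(mra)) {
    args <- c(list(ds = ds, corr1 = corr1, corr2 = corr2,
                   alpha = alpha, seed = seed), mra)
    mra_res <- do.call(screen_relations, args)
  }

  params <- list(alpha = alpha, n_bins = n_bins, n_boot = n_boot,
                 diff_alphas = diff_alphas, seed = seed,
                 n_probes = nrow(ds$values), n_samples = as.list(ns))
  run <- structure(list(metrics = metrics,
                        criteria_correlations = crit_cor,
                        power = power_tab,
                        bin_counts = bin_counts,
                        high_summaries = list(group1 = high1,
                                              group2 = high2),
                        specific_summaries = specific,
                        differential = diff,
                        correlation_pdf = cpdf,
                        mra = mra_res,
                        truth = truth,
                        params = params,
                        manifest = NULL),
                   class = "dcna_run")
  if (!is.null(out_dir)) run <- write_run(run, ds, out_dir)
  run
}

write_run <- function(run, ds, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  put <- function(obj, name) {
    p <- file.path(out_dir, name)
    utils::write.table(obj, p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    files <<- c(files, name)
  }
  put(run$metrics, "probe_metrics.tsv")
  put(run$power, "power_table.tsv")
  put(run$bin_counts, "bin_counts.tsv")
  sm <- list()
  for (g in names(run$high_summaries))
    for (lab in names(run$high_summaries[[g]]))
      sm[[length(sm) + 1L]] <- cbind(group = g, bin = lab,
        as.data.frame(run$high_summaries[[g]][[lab]]))
  if (length(sm) > 0L) put(do.call(rbind, sm), "graph_summaries.tsv")
  for (nm in names(run$differential$networks)) {
    p <- sprintf("differential_%s.graphml", nm)
    export_network(run$differential$networks[[nm]],
                   file.path(out_dir, p))
    files <- c(files, p)
  }
  if (!is.null(run$mra)) {
    put(run$mra$selected, "mra_selected.tsv")
    put(run$mra$per_class, "mra_per_class.tsv")
  }
  ed_path <- file.path(out_dir, "expression.tsv")
  write_expression_dataset(ds, ed_path,
                           file.path(out_dir, "sample_sheet.tsv"))
  files <- c(files, "expression.tsv", "sample_sheet.tsv")
  manifest <- list(files = as.list(files), params = run$params,
                   created = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  if (requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
  } else {
    utils::write.table(data.frame(file = files),
                       file.path(out_dir, "manifest.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  run$manifest <- manifest
  run
}

#' @export
print.dcna_run <- function(x, ...) {
  cat("<dcna_run> ", x$params$n_probes, " probes, groups ",
      paste(unlist(x$params$n_samples), collapse = "/"), "\n", sep = "")
  cat("ME significant (adj p < ", x$params$alpha, "): ",
      sum(x$metrics$me_significant, na.rm = TRUE), "\n", sep = "")
  cat("KS significant (raw p): ",
      sum(x$metrics$ks_significant_raw, na.rm = TRUE),
      "; SE significant (adj p): ",
      sum(x$metrics$se_significant, na.rm = TRUE), "\n", sep = "")
  cat("criteria correlations: ",
      paste(sprintf("%s = %.3f", names(x$criteria_correlations),
                    x$criteria_correlations), collapse = ", "), "\n",
      sep = "")
  invisible(x)
}

#' @export
summary.dcna_run <- function(object, ...) {
  print(object)
  cat("\nCorrelation-bin pair counts:\n")
  print(object$bin_counts, row.names = FALSE)
  cat("\nDifferential networks:\n")
  for (nm in names(object$differential$networks))
    cat("  ", nm, ": ",
        igraph::gsize(object$differential$networks[[nm]]),
        " edges\n", sep = "")
  if (!is.null(object$mra)) {
    cat("\nMRA screen:\n"); print(object$mra$per_class,
                                  row.names = FALSE)
  }
  invisible(object)
}

#' @export
plot.dcna_run <- function(x, which = c("profiles", "pdf"), ...) {
  which <- match.arg(which)
  if (which == "profiles") {
    old <- graphics::par(mfrow = c(1, 3))
    on.exit(graphics::par(old))
    for (cr in c("me", "cd", "se"))
      plot(relative_profile(x$metrics, cr), main = toupper(cr))
  } else {
    plot(x$correlation_pdf, ...)
  }
  invisible(x)
}
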