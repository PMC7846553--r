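#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, a documented front end to
#' `stats::p.adjust(method = "BH")`. Output is monotone, clipped at 1 and
#' never smaller than the input.
#'
#' @param p numeric vector of p-values in `[0, 1]` (`NA` allowed and
#'   propagated).
#' @return adjusted p-values, same length and order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Common discretization grid
#'
#' Equal-width bin grid over `[lower, upper]`, shared between the two groups
#' of a probe so that their entropies are computed over the same outcome
#' space.
#'
#' @param lower,upper grid bounds, `lower < upper`.
#' @param n_bins number of equal-width bins (>= 2).
#' @return list of class `discretization_grid` with `lower`, `upper`,
#'   `n_bins`, `edges`.
#' @export
discretization_grid <- function(lower, upper, n_bins = 10L) {
  if (!is.finite(lower) || !is.finite(upper) || lower >= upper)
    stop("need finite lower < upper")
  n_bins <- as.integer(n_bins)
  if (n_bins < 2L) stop("n_bins must be >= 2")
  structure(list(lower = lower, upper = upper, n_bins = n_bins,
                 edges = seq(lower, upper, length.out = n_bins + 1L)),
            class = "discretization_grid")
}

bin_assign <- function(x, grid) {
  if (any(x < grid$lower | x > grid$upper))
    stop("values outside the discretization grid bounds")
  findInterval(x, grid$edges, rightmost.closed = TRUE, all.inside = TRUE)
}

#' Area under the empirical CDF
#'
#' Exact integral of the right-continuous empirical distribution function of
#' `series` over `[lower, upper]`, computed by step summation. For data
#' inside the bounds this equals `upper - mean(series)` analytically; the
#' step summation is kept as the definitionally faithful form.
#'
#' @param series numeric vector, all values within `[lower, upper]`.
#' @param lower,upper integration bounds.
#' @return the area, in expression-units x probability.
#' @examples
#' ecdf_area(c(0, 1), 0, 1)   # 0.5
#' @export
ecdf_area <- function(series, lower, upper) {
  if (length(series) == 0L) stop("empty series")
  if (any(!is.finite(series))) stop("series must be finite")
  if (lower >= upper) stop("need lower < upper")
  if (any(series < lower | series > upper))
    stop("values outside the integration bounds")
  n <- length(series)
  knots <- c(lower, sort(series), upper)
  lev <- seq(0, n) / n            # F on [knot_i, knot_{i+1})
  sum(lev * diff(knots))
}

#' Shannon entropy of a discretized series
#'
#' Bin frequencies over a common grid, then `-sum f_i log2 f_i` (with
#' `0 log 0 = 0`), in bits. Bounded by `log2(n_bins)`.
#'
#' @param series numeric vector inside the grid bounds.
#' @param grid a [discretization_grid()].
#' @return entropy in bits.
#' @examples
#' g <- discretization_grid(0, 1, 10)
#' shannon_entropy(seq(0.05, 0.95, by = 0.1), g)   # log2(10)
#' @export
shannon_entropy <- function(series, grid) {
  if (length(series) == 0L) stop("empty series")
  cnt <- tabulate(bin_assign(series, grid), nbins = grid$n_bins)
  f <- cnt / sum(cnt)
  f <- f[f > 0]
  -sum(f * log2(f))
}

probe_group_stats <- function(ds) {
  x1 <- group_values(ds, 1L); x2 <- group_values(ds, 2L)
  n1 <- ncol(x1); n2 <- ncol(x2)
  list(x1 = x1, x2 = x2, n1 = n1, n2 = n2,
       m1 = rowMeans(x1), m2 = rowMeans(x2),
       v1 = apply(x1, 1L, stats::var), v2 = apply(x2, 1L, stats::var))
}

#' Mean-expression differential criterion (ME)
#'
#' Per-probe Welch two-sample t-test (two-sided, unequal variances) of the
#' group means, with Benjamini-Hochberg adjustment across probes. The
#' direction is the sign of `mean(group2) - mean(group1)`. Probes with zero
#' variance in both groups cannot be tested and are flagged degenerate.
#'
#' @param ds an [expression_dataset()].
#' @param alpha significance level applied to the adjusted p-values.
#' @return data.frame with one row per probe: `probe_id`, `me_group1`,
#'   `me_group2`, `me_delta`, `me_t`, `me_p`, `me_p_adj`, `me_significant`,
#'   `me_direction` (`"up"`/`"down"`), `degenerate`.
#' @export
me_differential <- function(ds, alpha = 0.05) {
  st <- probe_group_stats(ds)
  se2 <- st$v1 / st$n1 + st$v2 / st$n2
  degen <- se2 == 0
  tval <- ifelse(degen, NA_real_, (st$m2 - st$m1) / sqrt(se2))
  df <- se2^2 / ((st$v1 / st$n1)^2 / (st$n1 - 1) +
                   (st$v2 / st$n2)^2 / (st$n2 - 1))
  p <- 2 * stats::pt(-abs(tval), df)
  p_adj <- bh_adjust(p)
  data.frame(probe_id = ds$probe_ids,
             me_group1 = st$m1, me_group2 = st$m2,
             me_delta = st$m2 - st$m1,
             me_t = tval, me_p = p, me_p_adj = p_adj,
             me_significant = !is.na(p_adj) & p_adj < alpha,
             me_direction = ifelse(st$m2 >= st$m1, "up", "down"),
             degenerate = degen,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' CDF-area differential criterion (CD)
#'
#' Per probe, both groups' areas under the empirical CDF over the probe's
#' pooled range (a common support, mirroring the entropy grid), plus
#' two-sided Kolmogorov-Smirnov and Wilcoxon rank-sum tests of equal
#' distributions. Raw and BH-adjusted p-values are both reported, because
#' FDR calibration for these nonparametric tests is less settled than for
#' the t-test.
#'
#' @param ds an [expression_dataset()].
#' @param alpha significance level.
#' @return data.frame per probe: `cd_group1`, `cd_group2`, `cd_delta`
#'   (group2 - group1), `ks_d`, `ks_p`, `ks_p_adj`, `wilcoxon_p`,
#'   `wilcoxon_p_adj`, significance flags at `alpha` for raw and adjusted
#'   KS p-values, and `degenerate` for constant probes.
#' @export
cd_differential <- function(ds, alpha = 0.05) {
  x1 <- group_values(ds, 1L); x2 <- group_values(ds, 2L)
  P <- nrow(x1)
  cd1 <- cd2 <- ksd <- ksp <- wp <- rep(NA_real_, P)
  degen <- logical(P)
  for (i in seq_len(P)) {
    a <- x1[i, ]; b <- x2[i, ]
    lo <- min(a, b); hi <- max(a, b)
    if (lo == hi) { degen[i] <- TRUE; next }
    cd1[i] <- ecdf_area(a, lo, hi)
    cd2[i] <- ecdf_area(b, lo, hi)
    ks <- suppressWarnings(stats::ks.test(a, b))
    ksd[i] <- unname(ks$statistic); ksp[i] <- ks$p.value
    # midranks with normal approximation under ties
    wp[i] <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value)
  }
  data.frame(probe_id = ds$probe_ids,
             cd_group1 = cd1, cd_group2 = cd2, cd_delta = cd2 - cd1,
             ks_d = ksd, ks_p = ksp, ks_p_adj = bh_adjust(ksp),
             wilcoxon_p = wp, wilcoxon_p_adj = bh_adjust(wp),
             ks_significant_raw = !is.na(ksp) & ksp < alpha,
             ks_significant = !is.na(ksp) & bh_adjust(ksp) < alpha,
             degenerate = degen,
             row.names = NULL, stringsAsFactors = FALSE)
}

# bootstrap entropies of one group via the multinomial identity:
# resampling n observations with replacement and re-binning is distributed
# exactly as Multinomial(n, empirical bin frequencies)
boot_entropies <- function(bin_counts, n, n_boot) {
  cnt <- stats::rmultinom(n_boot, n, bin_counts / n)
  p <- cnt / n
  -colSums(ifelse(p > 0, p * log2(p), 0))
}

# permutation null of the plug-in entropy difference: group-1 bin counts
# under label permutation follow a multivariate hypergeometric draw from
# the pooled bin counts, sampled bin by bin with rhyper
perm_entropy_delta <- function(pool, n1, n_perm) {
  k <- length(pool); n <- sum(pool)
  c1 <- matrix(0, k, n_perm)
  left <- rep.int(n1, n_perm)       # balls still to place in group 1
  rest <- n - cumsum(pool)          # pooled counts in later bins
  for (j in seq_len(k)) {
    c1[j, ] <- stats::rhyper(n_perm, pool[j], rest[j], left)
    left <- left - c1[j, ]
  }
  c2 <- pool - c1
  h <- function(cnt, nn) { p <- cnt / nn
    -colSums(ifelse(p > 0, p * log2(p), 0)) }
  h(c2, n - n1) - h(c1, n1)
}

plug_in_entropy <- function(cnt) {
  f <- cnt / sum(cnt); f <- f[f > 0]
  -sum(f * log2(f))
}

#' Bootstrap Shannon-entropy differential criterion (SE)
#'
#' Per probe, a common equal-width grid is built over the pooled min/max of
#' both groups, each group's expression series is discretized, and `n_boot`
#' with-replacement resamples of each group yield a bootstrap distribution
#' of the group's entropy. The mean bootstrap entropy per group and their
#' difference are reported; significance of the difference is assessed by
#' one of three methods and BH-adjusted across probes:
#'
#' * `"permutation"` (default): exact permutation test of the plug-in
#'   entropy difference under group-label exchange. Calibrated at the
#'   nominal level by construction.
#' * `"boot-z"`: z-test of the bootstrap-bias-corrected entropies using the
#'   bootstrap variances as the variance estimate (approximately
#'   calibrated).
#' * `"collection"`: Welch t-test between the two collections of `n_boot`
#'   bootstrap entropies. Note this treats resamples as independent
#'   observations and is strongly anticonservative on two independent
#'   samples; it is provided for comparability only.
#'
#' @param ds an [expression_dataset()].
#' @param n_bins bins of the common grid.
#' @param n_boot bootstrap resamples per probe and group (>= 2).
#' @param alpha significance level on adjusted p-values.
#' @param seed integer seed making the resampling reproducible.
#' @param method significance method, see above.
#' @param n_perm label permutations for `method = "permutation"`.
#' @return data.frame per probe: `se_group1`, `se_group2` (mean bootstrap
#'   entropy, bits), `se_sd_group1`, `se_sd_group2`, `se_delta`, `se_p`,
#'   `se_p_adj`, `se_significant`, `se_direction` (`"gain"`/`"loss"`),
#'   `degenerate` for constant probes.
#' @export
se_bootstrap_differential <- function(ds, n_bins = 10L, n_boot = 1000L,
                                      alpha = 0.05, seed = 1L,
                                      method = c("permutation", "boot-z",
                                                 "collection"),
                                      n_perm = 500L) {
  method <- match.arg(method)
  if (n_boot < 2L) stop("n_boot must be >= 2")
  x1 <- group_values(ds, 1L); x2 <- group_values(ds, 2L)
  n1 <- ncol(x1); n2 <- ncol(x2); P <- nrow(x1)
  set.seed(as.integer(seed))
  se1 <- se2 <- sd1 <- sd2 <- pv <- rep(NA_real_, P)
  degen <- logical(P)
  for (i in seq_len(P)) {
    a <- x1[i, ]; b <- x2[i, ]
    lo <- min(a, b); hi <- max(a, b)
    if (lo == hi) { degen[i] <- TRUE; next }
    grid <- discretization_grid(lo, hi, n_bins)
    c1 <- tabulate(bin_assign(a, grid), nbins = n_bins)
    c2 <- tabulate(bin_assign(b, grid), nbins = n_bins)
    h1 <- boot_entropies(c1, n1, n_boot)
    h2 <- boot_entropies(c2, n2, n_boot)
    se1[i] <- mean(h1); se2[i] <- mean(h2)
    sd1[i] <- stats::sd(h1); sd2[i] <- stats::sd(h2)
    if (method == "collection") {
      pv[i] <- stats::t.test(h2, h1)$p.value
    } else if (method == "boot-z") {
      e1 <- 2 * plug_in_entropy(c1) - se1[i]   # bootstrap bias correction
      e2 <- 2 * plug_in_entropy(c2) - se2[i]
      v <- stats::var(h1) * n1 / (n1 - 1) + stats::var(h2) * n2 / (n2 - 1)
      pv[i] <- 2 * stats::pnorm(-abs((e2 - e1) / sqrt(v)))
    } else {
      obs <- plug_in_entropy(c2) - plug_in_entropy(c1)
      null <- perm_entropy_delta(c1 + c2, n1, n_perm)
      pv[i] <- (1 + sum(abs(null) >= abs(obs) - 1e-12)) / (n_perm + 1)
    }
  }
  p_adj <- bh_adjust(pv)
  data.frame(probe_id = ds$probe_ids,
             se_group1 = se1, se_group2 = se2,
             se_sd_group1 = sd1, se_sd_group2 = sd2,
             se_delta = se2 - se1,
             se_p = pv, se_p_adj = p_adj,
             se_significant = !is.na(p_adj) & p_adj < alpha,
             se_direction = ifelse(se2 >= se1, "gain", "loss"),
             degenerate = degen,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Full per-probe metric table
#'
#' Convenience wrapper running [me_differential()], [cd_differential()] and
#' [se_bootstrap_differential()] on one dataset and merging the records.
#'
#' @inheritParams se_bootstrap_differential
#' @param alpha significance level shared by the three criteria.
#' @param ... further arguments to [se_bootstrap_differential()].
#' @return merged per-probe data.frame.
#' @export
probe_metrics <- function(ds, alpha = 0.05, n_bins = 10L, n_boot = 1000L,
                          seed = 1L, ...) {
  me <- me_differential(ds, alpha)
  cd <- cd_differential(ds, alpha)
  se <- se_bootstrap_differential(ds, n_bins = n_bins, n_boot = n_boot,
                                  alpha = alpha, seed = seed, ...)
  me$degenerate <- NULL; cd$degenerate <- NULL
  out <- merge(merge(me, cd, by = "probe_id", sort = FALSE),
               se, by = "probe_id", sort = FALSE)
  out[match(ds$probe_ids, out$probe_id), , drop = FALSE]
}

#' Cross-correlations between the three criteria
#'
#' Pearson correlations of the per-probe relative changes
#' (group2 / group1) of the CD, ME and SE criteria, quantifying how
#' independent the three views of the data are.
#'
#' @param records data.frame from [probe_metrics()] (needs the
#'   `me_*`, `cd_*`, `se_*` group-value columns).
#' @return named numeric vector: `cd_me`, `se_me`, `se_cd`.
#' @export
criteria_correlations <- function(records) {
  rel <- function(a, b) ifelse(b != 0, a / b, NA_real_)
  me <- rel(records$me_group2, records$me_group1)
  cd <- rel(records$cd_group2, records$cd_group1)
  se <- rel(records$se_group2, records$se_group1)
  ok <- is.finite(me) & is.finite(cd) & is.finite(se)
  if (sum(ok) < 3L) stop("fewer than 3 usable probes")
  c(cd_me = stats::cor(cd[ok], me[ok]),
    se_me = stats::cor(se[ok], me[ok]),
    se_cd = stats::cor(se[ok], cd[ok]))
}

#' Ordered relative-value profile of one criterion
#'
#' Normalizes each probe's group-2 value by its group-1 (reference) value
#' and sorts the ratios in decreasing order, carrying the significance flag
#' along; the reference group is the horizontal line at 1 in the resulting
#' curve. Probes with a zero reference value are excluded with a warning.
#'
#' @param records data.frame from [probe_metrics()] (or the single-criterion
#'   tables, as long as the needed columns are present).
#' @param criterion `"me"`, `"cd"` or `"se"`.
#' @return data.frame (`probe_id`, `relative`, `significant`) sorted by
#'   decreasing `relative`; class `relative_profile` for plotting.
#' @export
relative_profile <- function(records, criterion = c("me", "cd", "se")) {
  criterion <- match.arg(criterion)
  g1 <- records[[paste0(criterion, "_group1")]]
  g2 <- records[[paste0(criterion, "_group2")]]
  sig <- switch(criterion,
                me = records$me_significant,
                cd = records$ks_significant_raw,
                se = records$se_significant)
  bad <- !is.finite(g1) | g1 == 0 | !is.finite(g2)
  if (any(bad))
    warning(sum(bad), " probe(s) with zero/non-finite reference excluded")
  out <- data.frame(probe_id = records$probe_id[!bad],
                    relative = g2[!bad] / g1[!bad],
                    significant = sig[!bad],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$relative), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("relative_profile", "data.frame")
  out
}

#' @export
plot.relative_profile <- function(x, ...) {
  graphics::plot(seq_len(nrow(x)), x$relative, type = "l", col = "darkgreen",
                 xlab = "probe rank", ylab = "relative value (group2/group1)",
                 ...)
  graphics::abline(h = 1, col = "blue")
  if (any(x$significant))
    graphics::points(which(x$significant), x$relative[x$significant],
                     col = "red", pch = ".", cex = 2)
  invisible(x)
}

#' Hierarchical clustering order (Euclidean, complete linkage)
#'
#' Row clustering used for the heatmap views: optional row z-scoring,
#' Euclidean distances, complete-linkage agglomeration. Zero-variance rows
#' cannot be z-scored and are left untransformed with a flag.
#'
#' @param m numeric matrix with >= 2 rows.
#' @param zscore_rows transform each row to mean 0, SD 1 first?
#' @return list: `order` (leaf order), `merge`, `height` (hclust encoding),
#'   `hclust` (the full `stats::hclust` object), `zscore_skipped` (indices
#'   of zero-variance rows left raw).
#' @export
hierarchical_order <- function(m, zscore_rows = FALSE) {
  if (!is.matrix(m) || nrow(m) < 2L) stop("need a matrix with >= 2 rows")
  skipped <- integer(0)
  if (zscore_rows) {
    sds <- apply(m, 1L, stats::sd)
    skipped <- which(sds == 0)
    if (length(skipped) > 0L)
      warning(length(skipped), " zero-variance row(s): z-score skipped")
    keep <- sds > 0
    m[keep, ] <- (m[keep, , drop = FALSE] -
                    rowMeans(m[keep, , drop = FALSE])) / sds[keep]
  }
  hc <- stats::hclust(stats::dist(m, method = "euclidean"),
                      method = "complete")
  list(order = hc$order, merge = hc$merge, height = hc$height,
       hclust = hc, zscore_skipped = skipped)
}
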