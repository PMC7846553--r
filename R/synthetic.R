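#' Configuration for the synthetic two-group generator
#'
#' Describes a synthetic probes x samples study with two groups of samples
#' (defaults 42 vs 71, the nulliparous/parous shape of the motivating
#' breast-tissue study) and planted per-probe and probe-cluster effects.
#' Background probes are i.i.d. Gaussian on a log-like intensity scale,
#' identically distributed in both groups; each block plants one kind of
#' departure in group 2 relative to group 1:
#'
#' * `mean_shift_block`: pure location shifts of `effect_size` baseline SDs,
#'   a fraction `fraction_up` of them upward.
#' * `shape_shift_block`: equal means, group-2 variance multiplied by
#'   `variance_ratio` (a distributional change invisible to the mean
#'   criterion).
#' * `entropy_shift_block`: equal means and a group-2 uniform distribution
#'   whose spread is `dispersion_ratio` baseline SDs, so that discretized
#'   Shannon entropy changes while the mean does not.
#' * `module_block`: `n_modules` disjoint modules of `module_size` probes
#'   sharing one latent factor per group, with factor loading chosen so the
#'   expected pairwise within-module correlation equals the configured value
#'   per group (loading `a` with unit noise gives `rho = a^2/(a^2+1)`).
#' * `quadruplet_block`: 4-probe linear relations
#'   `p1 = p2 + p3 + p4 + eps`, with `sd(eps)` per group controlling the
#'   per-group R^2 of the regression of p1 on the others. The first
#'   regressor p2 carries a larger variance so the (p1, p2) pair is also a
#'   strong correlation pair in the low-noise group.
#'
#' Set any block `count`/`n_modules` to 0 to omit the block; the all-zero
#' configuration is the global null (both groups share one distribution).
#'
#' @param n_probes total number of probes.
#' @param n_group1,n_group2 group sample sizes (reference group first).
#' @param baseline_mean,baseline_sd background Gaussian parameters
#'   (log-scale expression units).
#' @param mean_shift_block list(count, effect_size, fraction_up).
#' @param shape_shift_block list(count, variance_ratio > 1).
#' @param entropy_shift_block list(count, dispersion_ratio).
#' @param module_block list(n_modules, module_size,
#'   within_correlation_group1, within_correlation_group2), correlations in
#'   `[0, 1)`.
#' @param quadruplet_block list(count, noise_sd_group1, noise_sd_group2).
#' @param seed integer seed; one global seed drives an independent
#'   substream per block, so adding a block does not perturb the others.
#' @return a validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_probes = 2000L,
                             n_group1 = 42L,
                             n_group2 = 71L,
                             baseline_mean = 8,
                             baseline_sd = 1,
                             mean_shift_block = list(count = 100L,
                                                     effect_size = 1,
                                                     fraction_up = 0.68),
                             shape_shift_block = list(count = 100L,
                                                      variance_ratio = 9),
                             entropy_shift_block = list(count = 100L,
                                                        dispersion_ratio = 3),
                             module_block = list(n_modules = 2L,
                                                 module_size = 10L,
                                                 within_correlation_group1 = 0,
                                                 within_correlation_group2 = 0.9),
                             quadruplet_block = list(count = 10L,
                                                     noise_sd_group1 = 40,
                                                     noise_sd_group2 = 0.8),
                             seed = 1L) {
  cfg <- list(n_probes = as.integer(n_probes),
              n_group1 = as.integer(n_group1),
              n_group2 = as.integer(n_group2),
              baseline_mean = baseline_mean, baseline_sd = baseline_sd,
              mean_shift_block = mean_shift_block,
              shape_shift_block = shape_shift_block,
              entropy_shift_block = entropy_shift_block,
              module_block = module_block,
              quadruplet_block = quadruplet_block,
              seed = as.integer(seed))
  if (cfg$n_probes < 1L) stop("n_probes must be positive")
  if (cfg$n_group1 < 1L || cfg$n_group2 < 1L)
    stop("group sizes must be positive")
  if (cfg$baseline_sd <= 0) stop("baseline_sd must be positive")
  mb <- cfg$module_block
  if (mb$within_correlation_group1 < 0 || mb$within_correlation_group1 >= 1 ||
      mb$within_correlation_group2 < 0 || mb$within_correlation_group2 >= 1)
    stop("within-module correlations must lie in [0, 1)")
  if (cfg$shape_shift_block$count > 0 &&
      cfg$shape_shift_block$variance_ratio <= 0)
    stop("variance_ratio must be > 0")
  if (cfg$entropy_shift_block$count > 0 &&
      cfg$entropy_shift_block$dispersion_ratio <= 0)
    stop("dispersion_ratio must be > 0")
  used <- cfg$mean_shift_block$count + cfg$shape_shift_block$count +
    cfg$entropy_shift_block$count + mb$n_modules * mb$module_size +
    4L * cfg$quadruplet_block$count
  if (used > cfg$n_probes)
    stop("planted blocks need ", used, " probes but n_probes = ",
         cfg$n_probes)
  class(cfg) <- "synthetic_config"
  cfg
}

# Deterministic per-block substream: reseeds from the global seed and a
# fixed block offset, so each block's draws are independent of the others'
# presence or size.
block_seed <- function(seed, offset) {
  (as.integer(seed) * 97L + offset * 1009L) %% 2147483647L
}

#' Generate a synthetic two-group dataset with known ground truth
#'
#' Draws a dataset from a [synthetic_config()] and returns it together with
#' the planted structure needed for parameter-recovery testing. Output is
#' byte-identical for a fixed seed.
#'
#' @param config a [synthetic_config()].
#' @return list with elements:
#'   * `dataset`: an [expression_dataset()] with groups `group1`/`group2`;
#'   * `truth`: list with `probe_class` (per-probe label: `none`,
#'     `mean_shift_up`, `mean_shift_down`, `shape_shift`, `entropy_shift`,
#'     `module:<i>`, `quadruplet:<i>`), `modules` (per-module probe ids and
#'     expected within-group correlations) and `quadruplets` (per-relation
#'     probe ids, regressand first, and expected per-group R^2).
#' @examples
#' out <- generate_dataset(synthetic_config(n_probes = 200, seed = 7))
#' table(out$truth$probe_class)
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  cfg <- config
  n1 <- cfg$n_group1; n2 <- cfg$n_group2; n <- n1 + n2
  P <- cfg$n_probes
  mu <- cfg$baseline_mean; sg <- cfg$baseline_sd
  g1 <- seq_len(n1); g2 <- n1 + seq_len(n2)

  m <- matrix(NA_real_, P, n)
  probe_class <- rep("none", P)
  next_probe <- 1L
  take <- function(k) {
    idx <- seq.int(next_probe, length.out = k)
    next_probe <<- next_probe + k
    idx
  }

  # background: everything, overwritten below where blocks are planted
  set.seed(block_seed(cfg$seed, 1L))
  m[] <- stats::rnorm(P * n, mu, sg)

  # mean shifts: group-2 location moved by +/- effect_size baseline SDs
  msb <- cfg$mean_shift_block
  if (msb$count > 0L) {
    idx <- take(msb$count)
    set.seed(block_seed(cfg$seed, 2L))
    n_up <- round(msb$fraction_up * msb$count)
    up <- rep(c(TRUE, FALSE), c(n_up, msb$count - n_up))
    delta <- ifelse(up, 1, -1) * msb$effect_size * sg
    m[idx, ] <- stats::rnorm(msb$count * n, mu, sg)
    m[idx, g2] <- m[idx, g2, drop = FALSE] + delta
    probe_class[idx] <- ifelse(up, "mean_shift_up", "mean_shift_down")
  }

  # shape shifts: equal means, group-2 variance scaled
  ssb <- cfg$shape_shift_block
  if (ssb$count > 0L) {
    idx <- take(ssb$count)
    set.seed(block_seed(cfg$seed, 3L))
    m[idx, g1] <- stats::rnorm(ssb$count * n1, mu, sg)
    m[idx, g2] <- stats::rnorm(ssb$count * n2, mu,
                               sg * sqrt(ssb$variance_ratio))
    probe_class[idx] <- "shape_shift"
  }

  # entropy shifts: equal-mean Gaussian vs wide uniform, so the common-grid
  # discretized entropy separates while the mean stays put
  esb <- cfg$entropy_shift_block
  if (esb$count > 0L) {
    idx <- take(esb$count)
    set.seed(block_seed(cfg$seed, 4L))
    half <- esb$dispersion_ratio * sg * sqrt(3)
    m[idx, g1] <- stats::rnorm(esb$count * n1, mu, sg)
    m[idx, g2] <- stats::runif(esb$count * n2, mu - half, mu + half)
    probe_class[idx] <- "entropy_shift"
  }

  # correlated modules: one latent factor per module per group,
  # x = a f + e with rho = a^2 / (a^2 + 1), rescaled to baseline variance
  mb <- cfg$module_block
  modules <- list()
  if (mb$n_modules > 0L && mb$module_size > 0L) {
    set.seed(block_seed(cfg$seed, 5L))
    for (k in seq_len(mb$n_modules)) {
      idx <- take(mb$module_size)
      for (g in 1:2) {
        rho <- if (g == 1L) mb$within_correlation_group1 else
          mb$within_correlation_group2
        cols <- if (g == 1L) g1 else g2
        a <- sqrt(rho / (1 - rho))
        f <- stats::rnorm(length(cols))
        e <- matrix(stats::rnorm(mb$module_size * length(cols)),
                    mb$module_size)
        x <- (a * matrix(f, mb$module_size, length(cols), byrow = TRUE) +
                e) / sqrt(a^2 + 1)
        m[idx, cols] <- mu + sg * x
      }
      probe_class[idx] <- sprintf("module:%d", k)
      modules[[k]] <- list(id = k, probes = idx,
                           rho_group1 = mb$within_correlation_group1,
                           rho_group2 = mb$within_correlation_group2)
    }
  }

  # quadruplets: p1 = p2 + p3 + p4 + eps, p2 on a wider scale so (p1, p2)
  # is a high-correlation seed pair in the low-noise group
  qb <- cfg$quadruplet_block
  quadruplets <- list()
  if (qb$count > 0L) {
    set.seed(block_seed(cfg$seed, 6L))
    sd2 <- 4 * sg  # seed-regressor scale
    for (k in seq_len(qb$count)) {
      idx <- take(4L)
      p2 <- stats::rnorm(n, 0, sd2)
      p3 <- stats::rnorm(n, 0, sg)
      p4 <- stats::rnorm(n, 0, sg)
      eps <- c(stats::rnorm(n1, 0, qb$noise_sd_group1 * sg),
               stats::rnorm(n2, 0, qb$noise_sd_group2 * sg))
      m[idx[1L], ] <- mu + p2 + p3 + p4 + eps
      m[idx[2L], ] <- mu + p2
      m[idx[3L], ] <- mu + p3
      m[idx[4L], ] <- mu + p4
      probe_class[idx] <- sprintf("quadruplet:%d", k)
      sig <- sd2^2 + 2 * sg^2
      quadruplets[[k]] <- list(
        id = k, probes = idx,
        r2_group1 = sig / (sig + (qb$noise_sd_group1 * sg)^2),
        r2_group2 = sig / (sig + (qb$noise_sd_group2 * sg)^2))
    }
  }

  rownames(m) <- sprintf("probe_%05d", seq_len(P))
  colnames(m) <- c(sprintf("g1_s%02d", seq_len(n1)),
                   sprintf("g2_s%02d", seq_len(n2)))
  ds <- expression_dataset(m, rep(c("group1", "group2"), c(n1, n2)))
  names(probe_class) <- rownames(m)
  list(dataset = ds,
       truth = list(probe_class = probe_class,
                    modules = modules,
                    quadruplets = quadruplets,
                    config = cfg))
}

#' Write generator ground truth as TSV
#'
#' @param truth the `truth` element returned by [generate_dataset()].
#' @param path output TSV path (columns `probe_id`, `class`).
#' @return invisibly, `path`.
#' @export
write_ground_truth <- function(truth, path) {
  tab <- data.frame(probe_id = names(truth$probe_class),
                    class = unname(truth$probe_class),
                    stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
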