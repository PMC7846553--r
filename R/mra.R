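#' Classify seed pairs for the differential regression screen
#'
#' Selects probe pairs with a strong correlation (|rho| > `r_high`) in one
#' group that collapses in the other, and assigns each to one of four
#' classes (`rho1` = reference group, `rho2` = second group):
#' * `A`: rho2 >  r_high and rho1 <  r_low
#' * `B`: rho1 >  r_high and rho2 <  r_low
#' * `C`: rho2 < -r_high and rho1 > -r_low
#' * `D`: rho1 < -r_high and rho2 > -r_low
#'
#' A pair must additionally change its correlation by more than
#' `delta_rho` in absolute value (with the printed class thresholds this is
#' implied, but the filter is applied conjunctively and is tunable).
#' Classes are made mutually exclusive by first-match precedence in the
#' order A, B, C, D: the rare pair that is strongly correlated in both
#' groups with opposite signs satisfies two of the raw inequalities and is
#' assigned to the earlier class. All other pairs are `none` and omitted.
#'
#' @param corr1,corr2 [group_correlation_matrix()] results on the same
#'   probe set (reference group first).
#' @param r_high,r_low,delta_rho class thresholds.
#' @return data.frame: `probe1`, `probe2`, `r_group1`, `r_group2`,
#'   `class` (factor A/B/C/D).
#' @export
classify_seed_pairs <- function(corr1, corr2, r_high = 0.8, r_low = 0.4,
                                delta_rho = 0.4) {
  stopifnot(inherits(corr1, "corr_matrix"), inherits(corr2, "corr_matrix"))
  if (!identical(corr1$probe_ids, corr2$probe_ids))
    stop("correlation matrices must share one probe set")
  p1 <- corr_pairs(corr1); p2 <- corr_pairs(corr2)
  rN <- p1$r; rP <- p2$r    # reference group first, second group "P"
  # first match in printed order wins: the raw inequalities can overlap
  # when both groups are strongly correlated with opposite signs
  cls <- rep(NA_character_, length(rN))
  put <- function(cond, lab) cls[is.na(cls) & cond] <<- lab
  put(rP >  r_high & rN <  r_low, "A")
  put(rN >  r_high & rP <  r_low, "B")
  put(rP < -r_high & rN > -r_low, "C")
  put(rN < -r_high & rP > -r_low, "D")
  cls[!is.na(cls) & abs(rP - rN) <= delta_rho] <- NA_character_
  keep <- !is.na(cls)
  data.frame(probe1 = p1$probe_ids[p1$i[keep]],
             probe2 = p1$probe_ids[p1$j[keep]],
             r_group1 = rN[keep], r_group2 = rP[keep],
             class = factor(cls[keep], levels = c("A", "B", "C", "D")),
             stringsAsFactors = FALSE)
}

#' Ordinary least squares fit of one 4-probe relation in one group
#'
#' Regresses the regressand probe on three regressor probes (with
#' intercept) using only the chosen group's samples.
#'
#' @param ds an [expression_dataset()].
#' @param group group level (name or 1/2), sample size > 5.
#' @param regressand probe id of the response.
#' @param regressors character vector of 3 distinct regressor probe ids.
#' @return list: `r_squared`, `coefficients`, `degenerate` (TRUE when the
#'   design is rank-deficient, in which case `r_squared` is `NA`).
#' @export
fit_quadruplet <- function(ds, group, regressand, regressors) {
  probes <- c(regressand, regressors)
  if (length(regressors) != 3L || anyDuplicated(probes))
    stop("need a regressand and 3 distinct regressors")
  if (!all(probes %in% ds$probe_ids))
    stop("unknown probe id")
  x <- group_values(ds, group)
  if (ncol(x) <= 5L) stop("group sample size must exceed 5")
  y <- x[regressand, ]
  X <- cbind(1, t(x[regressors, , drop = FALSE]))
  qx <- qr(X)
  if (qx$rank < ncol(X))
    return(list(r_squared = NA_real_, coefficients = NULL,
                degenerate = TRUE))
  fit <- stats::lm.fit(X, y)
  rss <- sum(fit$residuals^2)
  tss <- sum((y - mean(y))^2)
  list(r_squared = if (tss > 0) 1 - rss / tss else NA_real_,
       coefficients = stats::setNames(fit$coefficients,
                                      c("(Intercept)", regressors)),
       degenerate = FALSE)
}

# connected-component labels of the high-|rho| graph of one group,
# as a named vector over all probe ids (probes outside the graph get
# their own singleton component)
high_corr_components <- function(corr, r_high = 0.8) {
  pp <- corr_pairs(corr)
  sel <- abs(pp$r) > r_high
  comp <- stats::setNames(paste0("iso_", seq_along(corr$probe_ids)),
                          corr$probe_ids)
  if (any(sel)) {
    g <- igraph::graph_from_data_frame(
      data.frame(from = pp$probe_ids[pp$i[sel]],
                 to = pp$probe_ids[pp$j[sel]]), directed = FALSE)
    m <- igraph::components(g)$membership
    comp[names(m)] <- paste0("c_", m)
  }
  comp
}

# batch R^2 of y ~ x1 + z + candidate, candidate sweeping the columns of
# Z; residualize against [1, x1, z] once, then R^2 gain per candidate
sweep_r2 <- function(y, x1, z, Z) {
  X0 <- cbind(1, x1, z)
  q0 <- qr(X0)
  ry <- qr.resid(q0, y)
  tss <- sum((y - mean(y))^2)
  r2_0 <- 1 - sum(ry^2) / tss
  RZ <- qr.resid(q0, Z)               # residualized candidates, columnwise
  num <- as.vector(crossprod(RZ, ry))
  den <- colSums(RZ^2) * sum(ry^2)
  gain <- ifelse(den > 0, num^2 / den, 0)
  r2_0 + (1 - r2_0) * gain
}

#' Differential multiple-regression screen for 4-probe relations
#'
#' Screens for linear relations among four probes that are strong in one
#' group and vanish in the other. Seed pairs come from
#' [classify_seed_pairs()]; for each sampled pair the first probe is the
#' regressand and the second the first regressor, a sampled third probe is
#' the second regressor, and the third regressor sweeps over every
#' remaining probe. A fit is kept when all four selection criteria hold:
#'
#' 1. `r2_transition`: R^2 lies in `[r2_high, 1)` in one group and in
#'    `[0, r2_low]` in the other;
#' 2. `me_stable`: at least one of the four probes shows no significant
#'    mean change (Welch t, raw p >= alpha);
#' 3. `not_same_network`: the four probes do NOT all lie in one connected
#'    component of the high-|rho| network of the group where R^2 is high;
#' 4. `not_homogeneous`: the six pairwise correlation changes among the
#'    four probes do NOT all share one sign while all exceeding
#'    `delta_rho` in magnitude.
#'
#' @param ds an [expression_dataset()].
#' @param corr1,corr2 per-group correlation matrices (reference first).
#' @param classes optional precomputed [classify_seed_pairs()] table.
#' @param pairs_per_class named or unnamed vector of pair counts sampled
#'   per class A-D (recycled); `Inf` examines every pair of the class.
#' @param third_probe_samples random third probes per seed pair.
#' @param r2_high,r2_low R^2 transition thresholds.
#' @param delta_rho homogeneity threshold on correlation changes.
#' @param alpha level of the mean-stability test.
#' @param r_high high-correlation network threshold for criterion 3.
#' @param seed integer seed for the pair/third-probe sampling.
#' @return list of class `mra_screen`: `selected` (data.frame of kept
#'   fits: probes, class, per-group R^2, the four criterion flags),
#'   `per_class` (examined/kept counts by class), `n_fits_examined`,
#'   `classes` (the seed-pair table used).
#' @export
screen_relations <- function(ds, corr1, corr2, classes = NULL,
                             pairs_per_class = c(A = 3, B = 4, C = 4,
                                                 D = 4),
                             third_probe_samples = 1L,
                             r2_high = 0.8, r2_low = 0.4,
                             delta_rho = 0.4, alpha = 0.05,
                             r_high = 0.8, seed = 1L) {
  if (is.null(classes)) classes <- classify_seed_pairs(corr1, corr2)
  if (is.null(names(pairs_per_class)))
    names(pairs_per_class) <- c("A", "B", "C", "D")[
      seq_along(pairs_per_class)]
  me <- me_differential(ds, alpha)
  stable <- stats::setNames(!is.na(me$me_p) & me$me_p >= alpha,
                            me$probe_id)
  comp1 <- high_corr_components(corr1, r_high)
  comp2 <- high_corr_components(corr2, r_high)
  rmat1 <- corr1$r; rmat2 <- corr2$r
  dmat <- rmat2 - rmat1
  probe_ids <- corr1$probe_ids
  xa <- group_values(ds, 1L)
  xb <- group_values(ds, 2L)
  set.seed(as.integer(seed))

  res <- list(); n_examined <- 0L
  examined_by_class <- stats::setNames(integer(4), c("A", "B", "C", "D"))
  for (cl in c("A", "B", "C", "D")) {
    sub <- classes[classes$class == cl, , drop = FALSE]
    if (nrow(sub) == 0L) next
    k <- pairs_per_class[[cl]]
    rows <- if (is.infinite(k) || k >= nrow(sub)) seq_len(nrow(sub)) else
      sample(nrow(sub), k)
    for (ri in rows) {
      regressand <- sub$probe1[ri]; reg1 <- sub$probe2[ri]
      pool <- setdiff(probe_ids, c(regressand, reg1))
      thirds <- sample(pool, min(third_probe_samples, length(pool)))
      for (third in thirds) {
        cand <- setdiff(pool, third)
        trio <- c(regressand, reg1, third)
        r2_1 <- sweep_r2(xa[regressand, ], xa[reg1, ], xa[third, ],
                         t(xa[cand, , drop = FALSE]))
        r2_2 <- sweep_r2(xb[regressand, ], xb[reg1, ], xb[third, ],
                         t(xb[cand, , drop = FALSE]))
        n_examined <- n_examined + length(cand)
        examined_by_class[cl] <- examined_by_class[cl] + length(cand)
        hi1 <- r2_1 >= r2_high & r2_1 < 1
        hi2 <- r2_2 >= r2_high & r2_2 < 1
        trans <- (hi1 & r2_2 <= r2_low) | (hi2 & r2_1 <= r2_low)
        if (!any(trans)) next
        # vectorized criteria over the candidate fourth regressors
        same_net <- ifelse(hi1,
          comp1[regressand] == comp1[reg1] &
            comp1[reg1] == comp1[third] & comp1[cand] == comp1[reg1],
          comp2[regressand] == comp2[reg1] &
            comp2[reg1] == comp2[third] & comp2[cand] == comp2[reg1])
        d_trio <- dmat[trio, trio][upper.tri(diag(3))]
        d_cand <- dmat[cand, trio, drop = FALSE]
        base_pos <- all(d_trio > delta_rho)
        base_neg <- all(d_trio < -delta_rho)
        homog <- (base_pos & rowSums(d_cand > delta_rho) == 3L) |
                 (base_neg & rowSums(d_cand < -delta_rho) == 3L)
        me_count <- sum(stable[trio]) + as.integer(stable[cand])
        keep <- trans & me_count >= 1L & !same_net & !homog
        if (any(keep))
          res[[length(res) + 1L]] <- data.frame(
            regressand = regressand, regressor1 = reg1,
            regressor2 = third, regressor3 = cand[keep],
            class = cl,
            r2_group1 = r2_1[keep], r2_group2 = r2_2[keep],
            r2_transition = TRUE,
            me_stable_count = me_count[keep],
            same_network = FALSE,
            homogeneous_change = FALSE,
            stringsAsFactors = FALSE)
      }
    }
  }
  selected <- if (length(res) > 0L) do.call(rbind, res) else
    data.frame(regressand = character(0), regressor1 = character(0),
               regressor2 = character(0), regressor3 = character(0),
               class = character(0), r2_group1 = numeric(0),
               r2_group2 = numeric(0), r2_transition = logical(0),
               me_stable_count = integer(0), same_network = logical(0),
               homogeneous_change = logical(0))
  per_class <- data.frame(
    class = c("A", "B", "C", "D"),
    n_pairs = as.vector(table(classes$class)),
    n_fits_examined = as.vector(examined_by_class),
    n_selected = as.vector(table(factor(selected$class,
                                        levels = c("A", "B", "C", "D")))))
  per_class$selected_fraction <- ifelse(per_class$n_fits_examined > 0,
                                        per_class$n_selected /
                                          per_class$n_fits_examined, 0)
  structure(list(selected = selected, per_class = per_class,
                 n_fits_examined = n_examined, classes = classes),
            class = "mra_screen")
}

#' @export
print.mra_screen <- function(x, ...) {
  cat("<mra_screen> ", x$n_fits_examined, " fits examined, ",
      nrow(x$selected), " selected\n", sep = "")
  print(x$per_class, row.names = FALSE)
  invisible(x)
}

#' Extrapolate a screened count to the full search space
#'
#' Scales a count observed on an examined subset to the total search-space
#' size: `found * total / examined`.
#'
#' @param found relations found (<= examined).
#' @param examined fits examined (> 0).
#' @param total total fits in the full space.
#' @return list: `estimate`, `sampling_fraction`.
#' @export
extrapolate_relation_counts <- function(found, examined, total) {
  if (examined <= 0) stop("examined must be positive")
  if (found > examined) stop("found cannot exceed examined")
  list(estimate = found * total / examined,
       sampling_fraction = examined / total)
}
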