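# Brute-force graph oracles, independent of the igraph-based implementation.
# All take a (possibly weighted) symmetric adjacency matrix with zero
# diagonal; metrics that are defined unweighted binarize internally.

oracle_bfs_dist <- function(B, from) {
  n <- nrow(B)
  d <- rep(Inf, n); d[from] <- 0
  frontier <- from
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (v in frontier) {
      nb <- which(B[v, ] > 0)
      new <- nb[d[nb] == Inf]
      d[new] <- d[v] + 1
      nxt <- c(nxt, new)
    }
    frontier <- nxt
  }
  d
}

# components via repeated BFS
oracle_components <- function(B) {
  n <- nrow(B); comp <- rep(NA_integer_, n); k <- 0L
  for (v in seq_len(n)) {
    if (!is.na(comp[v])) next
    k <- k + 1L
    comp[is.finite(oracle_bfs_dist(B, v))] <- k
  }
  comp
}

oracle_graph_metrics <- function(A) {
  B <- (A != 0) * 1
  n <- nrow(B)
  deg <- rowSums(B)
  links <- sum(B) / 2
  comp <- oracle_components(B)
  big <- which(comp == which.max(tabulate(comp)))
  Bl <- B[big, big, drop = FALSE]
  dists <- t(sapply(seq_along(big), function(i) oracle_bfs_dist(Bl, i)))
  off <- dists[upper.tri(dists)]
  cpl <- if (length(off) > 0) mean(off) else 0
  diam <- if (length(off) > 0) max(off) else 0
  loc <- vapply(seq_len(n), function(v) {
    nb <- which(B[v, ] > 0)
    k <- length(nb)
    if (k < 2) return(0)
    sum(B[nb, nb]) / 2 / (k * (k - 1) / 2)
  }, numeric(1))
  list(number_of_links = links,
       average_node_degree = mean(deg),
       characteristic_path_length = cpl,
       diameter = diam,
       average_clustering_coefficient = mean(loc))
}

# exact maximum modularity by dynamic programming over vertex subsets:
# Q is additive over communities, so best(S) = max over the sub-block T
# containing the lowest vertex of S of q(T) + best(S \ T). Feasible for
# n <= ~14 (3^n submask enumeration).
oracle_modularity_opt <- function(A) {
  A <- abs(A)
  n <- nrow(A)
  stopifnot(n <= 14)
  m2 <- sum(A)
  if (m2 == 0) return(0)
  deg <- rowSums(A)
  full <- bitwShiftL(1L, n) - 1L
  nS <- full + 1L
  eS <- numeric(nS); dS <- numeric(nS)   # indexed by mask + 1
  bit <- bitwShiftL(1L, 0:(n - 1L))
  for (S in 1:full) {
    i <- which(bitwAnd(S, bit) != 0)[1L]          # lowest vertex
    rest <- bitwAnd(S, bitwNot(bit[i]))
    members <- which(bitwAnd(rest, bit) != 0)
    eS[S + 1L] <- eS[rest + 1L] + 2 * sum(A[i, members])
    dS[S + 1L] <- dS[rest + 1L] + deg[i]
  }
  qS <- eS / m2 - (dS / m2)^2
  best <- numeric(nS); best[1L] <- 0
  for (S in 1:full) {
    lowest <- bitwAnd(S, -S)
    b <- -Inf
    Tm <- S                                        # submasks containing lowest
    repeat {
      if (bitwAnd(Tm, lowest) != 0) {
        v <- qS[Tm + 1L] + best[bitwAnd(S, bitwNot(Tm)) + 1L]
        if (v > b) b <- v
      }
      if (Tm == 0L) break
      Tm <- bitwAnd(Tm - 1L, S)
    }
    best[S + 1L] <- b
  }
  best[full + 1L]
}

oracle_eigencentrality_mean <- function(A) {
  A <- abs(A)
  v <- eigen(A, symmetric = TRUE)$vectors[, 1]
  v <- abs(v)
  mean(v / max(v))
}

# direct O(n^3) complete-linkage agglomeration on Euclidean row distances
oracle_complete_linkage <- function(m) {
  n <- nrow(m)
  d <- as.matrix(stats::dist(m))
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  merges <- list()
  while (length(clusters) > 1) {
    k <- length(clusters)
    bestv <- Inf; bi <- bj <- NA
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      cd <- max(d[clusters[[i]], clusters[[j]]])
      if (cd < bestv) { bestv <- cd; bi <- i; bj <- j }
    }
    heights <- c(heights, bestv)
    merges[[length(merges) + 1L]] <-
      sort(c(clusters[[bi]], clusters[[bj]]))   # member sets, canonical
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  list(heights = heights, merged_sets = merges)
}

# member sets at each merge of an hclust tree, for comparison with the
# oracle above
hclust_merged_sets <- function(hc) {
  sets <- list()
  out <- list()
  for (s in seq_len(nrow(hc$merge))) {
    take <- function(x) if (x < 0) -x else sets[[x]]
    sets[[s]] <- c(take(hc$merge[s, 1]), take(hc$merge[s, 2]))
    out[[s]] <- sort(sets[[s]])
  }
  out
}

random_test_graph <- function(n, p, weighted = TRUE, connected = FALSE) {
  repeat {
    A <- matrix(0, n, n)
    up <- upper.tri(A)
    edges <- stats::runif(sum(up)) < p
    w <- if (weighted) stats::runif(sum(up), -1, 1) else 1
    A[up] <- edges * w
    A <- A + t(A)
    if (sum(A != 0) == 0) next
    if (!connected || all(oracle_components((A != 0) * 1) == 1)) return(A)
  }
}

graph_from_adjacency <- function(A) {
  g <- igraph::graph_from_adjacency_matrix(abs(A) != 0, mode = "undirected")
  igraph::V(g)$name <- sprintf("v%d", seq_len(nrow(A)))
  w <- A[upper.tri(A)]
  ed <- igraph::as_edgelist(g, names = FALSE)
  igraph::E(g)$weight <- A[cbind(ed[, 1], ed[, 2])]
  g
}

# small two-group dataset helper used across test files
tiny_dataset <- function(P = 20, n1 = 10, n2 = 12, seed = 42) {
  set.seed(seed)
  m <- matrix(rnorm(P * (n1 + n2)), nrow = P)
  expression_dataset(m, rep(c("g1", "g2"), c(n1, n2)))
}

null_config <- function(n_probes = 2000L, seed = 1L, ...) {
  synthetic_config(
    n_probes = n_probes,
    mean_shift_block = list(count = 0L, effect_size = 1, fraction_up = 0.5),
    shape_shift_block = list(count = 0L, variance_ratio = 9),
    entropy_shift_block = list(count = 0L, dispersion_ratio = 3),
    module_block = list(n_modules = 0L, module_size = 0L,
                        within_correlation_group1 = 0,
                        within_correlation_group2 = 0),
    quadruplet_block = list(count = 0L, noise_sd_group1 = 1,
                            noise_sd_group2 = 1),
    seed = seed, ...)
}
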