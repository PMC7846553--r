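#' Per-group Pearson correlation matrix
#'
#' Product-moment correlations between all probe pairs within one group's
#' samples. Probes with zero within-group variance have no defined
#' correlation and are excluded with a warning. Spearman rank correlation
#' is available behind the `method` flag.
#'
#' @param ds an [expression_dataset()].
#' @param group group level (name or 1/2).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return object of class `corr_matrix`: list with `r` (symmetric matrix,
#'   unit diagonal), `probe_ids`, `group`, `n` (sample size used),
#'   `excluded` (zero-variance probe ids).
#' @export
group_correlation_matrix <- function(ds, group,
                                     method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x <- group_values(ds, group)
  if (ncol(x) < 4L) stop("need >= 4 samples in the group")
  sds <- apply(x, 1L, stats::sd)
  excluded <- rownames(x)[sds == 0]
  if (length(excluded) > 0L) {
    warning(length(excluded), " zero-variance probe(s) excluded")
    x <- x[sds > 0, , drop = FALSE]
  }
  r <- stats::cor(t(x), method = method)
  lv <- levels(ds$groups)
  structure(list(r = r, probe_ids = rownames(x),
                 group = if (is.numeric(group)) lv[group] else group,
                 n = ncol(x), excluded = excluded),
            class = "corr_matrix")
}

#' @export
print.corr_matrix <- function(x, ...) {
  cat("<corr_matrix> ", length(x$probe_ids), " probes, group ", x$group,
      " (n = ", x$n, ")\n", sep = "")
  invisible(x)
}

#' The nine correlation bins
#'
#' The 0.2-step thresholding scheme partitioning `[-1, 1]` into nine
#' intervals; the two extreme bins (|rho| > 0.8) are the high-correlation
#' bins. Positive bins are right-closed, negative bins left-closed, the
#' central bin `[-0.2, 0.2]` closed on both sides, so every correlation
#' falls in exactly one bin.
#'
#' @return data.frame with columns `bin` (index), `label`, `lower`,
#'   `upper`, `high` (logical).
#' @export
correlation_bins <- function() {
  data.frame(
    bin = 1:9,
    label = c("(0.8,1]", "(0.6,0.8]", "(0.4,0.6]", "(0.2,0.4]",
              "[-0.2,0.2]", "[-0.4,-0.2)", "[-0.6,-0.4)", "[-0.8,-0.6)",
              "[-1,-0.8)"),
    lower = c(0.8, 0.6, 0.4, 0.2, -0.2, -0.4, -0.6, -0.8, -1),
    upper = c(1, 0.8, 0.6, 0.4, 0.2, -0.2, -0.4, -0.6, -0.8),
    high = c(TRUE, rep(FALSE, 7L), TRUE),
    stringsAsFactors = FALSE)
}

#' Assign correlations to bins
#'
#' @param r numeric vector of correlations in `[-1, 1]`.
#' @return integer bin index (1..9, in [correlation_bins()] order).
#' @export
assign_correlation_bin <- function(r) {
  if (any(r < -1 - 1e-9 | r > 1 + 1e-9, na.rm = TRUE))
    stop("correlations must lie in [-1, 1]")
  ifelse(r > 0.8, 1L,
  ifelse(r > 0.6, 2L,
  ifelse(r > 0.4, 3L,
  ifelse(r > 0.2, 4L,
  ifelse(r >= -0.2, 5L,
  ifelse(r >= -0.4, 6L,
  ifelse(r >= -0.6, 7L,
  ifelse(r >= -0.8, 8L, 9L))))))))
}

# upper-triangle pair list of a corr_matrix: integer index pairs + r values
corr_pairs <- function(corr) {
  r <- corr$r
  P <- nrow(r)
  idx <- which(upper.tri(r))
  j <- ((idx - 1L) %/% P) + 1L
  i <- idx - (j - 1L) * P
  list(i = i, j = j, r = r[idx], probe_ids = corr$probe_ids)
}

#' Correlation-bin networks (the nine per-group networks)
#'
#' Assigns every unordered probe pair to its correlation bin and builds one
#' undirected network per bin, edges weighted by the correlation, nodes
#' restricted to probes with at least one in-bin edge. Also returns the
#' per-bin pair counts and percentages (the Table-style summary).
#'
#' @param corr a [group_correlation_matrix()] result.
#' @param build_graphs build the igraph objects (set `FALSE` for a
#'   counts-only pass on large matrices)?
#' @param bins integer bin indices to materialize as graphs (default all 9).
#' @return list of class `bin_networks`: `counts` (data.frame with `bin`,
#'   `label`, `count`, `percentage`, `high`), `networks` (list of 9 igraph
#'   objects or `NULL` where not built), `n_pairs`, `group`.
#' @export
bin_networks <- function(corr, build_graphs = TRUE, bins = 1:9) {
  stopifnot(inherits(corr, "corr_matrix"))
  pp <- corr_pairs(corr)
  b <- assign_correlation_bin(pp$r)
  spec <- correlation_bins()
  cnt <- tabulate(b, nbins = 9L)
  counts <- data.frame(spec[, c("bin", "label")],
                       count = cnt,
                       percentage = 100 * cnt / length(b),
                       high = spec$high,
                       stringsAsFactors = FALSE)
  networks <- vector("list", 9L)
  if (build_graphs) {
    for (k in intersect(1:9, bins)) {
      sel <- b == k
      if (!any(sel)) {
        networks[[k]] <- igraph::make_empty_graph(0, directed = FALSE)
      } else {
        ed <- data.frame(from = pp$probe_ids[pp$i[sel]],
                         to = pp$probe_ids[pp$j[sel]],
                         weight = pp$r[sel],
                         stringsAsFactors = FALSE)
        networks[[k]] <- igraph::graph_from_data_frame(ed,
                                                       directed = FALSE)
      }
      igraph::graph_attr(networks[[k]], "bin") <- spec$label[k]
      igraph::graph_attr(networks[[k]], "group") <- corr$group
    }
  }
  structure(list(counts = counts, networks = networks,
                 n_pairs = length(b), group = corr$group),
            class = "bin_networks")
}

#' @export
print.bin_networks <- function(x, ...) {
  cat("<bin_networks> group ", x$group, ", ", x$n_pairs, " pairs\n",
      sep = "")
  print(x$counts, row.names = FALSE)
  invisible(x)
}

best_louvain <- function(net, w, n_restarts) {
  best <- NULL; bq <- -Inf
  for (i in seq_len(max(1L, n_restarts))) {
    cl <- igraph::cluster_louvain(net, weights = w)
    q <- igraph::modularity(net, igraph::membership(cl), weights = w)
    if (q > bq) { bq <- q; best <- igraph::membership(cl) }
  }
  list(membership = best, q = bq)
}

graph_communities <- function(net, method = c("auto", "louvain", "exact"),
                              n_restarts = 5L, exact_max_nodes = 15L) {
  method <- match.arg(method)
  w <- if ("weight" %in% igraph::edge_attr_names(net))
    abs(igraph::E(net)$weight) else rep(1, igraph::gsize(net))
  if (method == "auto")
    method <- if (igraph::vcount(net) <= exact_max_nodes) "exact" else
      "louvain"
  if (method == "exact") {
    cl <- igraph::cluster_optimal(net, weights = w)
    list(membership = igraph::membership(cl),
         q = igraph::modularity(net, igraph::membership(cl), weights = w),
         method = "exact")
  } else {
    c(best_louvain(net, w, n_restarts), method = "louvain")
  }
}

#' Graph-theory summary of one network
#'
#' The seven descriptive parameters used to characterize each correlation
#' network: number of links, average node degree, characteristic path
#' length, diameter, average (local, unweighted) clustering coefficient,
#' modularity and mean eigenvector centrality.
#'
#' Path length and diameter are computed with unweighted breadth-first
#' shortest paths; on a disconnected network they are taken on the largest
#' connected component and flagged. Modularity maximization uses absolute
#' edge weights: exact optimization for graphs with at most
#' `exact_max_nodes` nodes, Louvain (best of `n_restarts` random restarts,
#' resolution 1) above, or force either via `modularity_method`.
#' Eigenvector centrality uses absolute weights, normalizes the leading
#' vector to unit maximum and reports the mean over nodes.
#'
#' @param net an igraph undirected network (nonempty).
#' @param modularity_method `"auto"`, `"louvain"` or `"exact"`.
#' @param n_restarts Louvain restarts.
#' @param exact_max_nodes size cap for exact modularity under `"auto"`.
#' @return list of class `graph_summary` with the seven parameters plus
#'   `n_nodes`, `lcc_used` (logical: integration metrics restricted to the
#'   largest component), `membership` (community assignment),
#'   `modularity_method` (method actually used).
#' @export
graph_summary <- function(net, modularity_method = "auto",
                          n_restarts = 5L, exact_max_nodes = 15L) {
  if (!igraph::is_igraph(net)) stop("`net` must be an igraph object")
  if (igraph::vcount(net) == 0L) stop("empty network")
  deg <- igraph::degree(net)
  comp <- igraph::components(net)
  lcc_used <- comp$no > 1L
  lcc <- if (lcc_used)
    igraph::induced_subgraph(net, which(comp$membership ==
                                          which.max(comp$csize)))
  else net
  d <- igraph::distances(lcc, weights = NA)
  off <- d[upper.tri(d)]
  cpl <- if (length(off) > 0L) mean(off) else 0
  diam <- if (length(off) > 0L) max(off) else 0
  loc <- igraph::transitivity(net, type = "local", isolates = "zero")
  comm <- graph_communities(net, modularity_method, n_restarts,
                            exact_max_nodes)
  w <- if ("weight" %in% igraph::edge_attr_names(net))
    abs(igraph::E(net)$weight) else NULL
  ec <- if (igraph::gsize(net) == 0L) rep(0, igraph::vcount(net)) else
    igraph::eigen_centrality(net, weights = w)$vector
  structure(list(number_of_links = igraph::gsize(net),
                 average_node_degree = mean(deg),
                 characteristic_path_length = cpl,
                 diameter = diam,
                 average_clustering_coefficient = mean(loc),
                 modularity = comm$q,
                 eigenvector_centrality = mean(ec),
                 n_nodes = igraph::vcount(net),
                 lcc_used = lcc_used,
                 membership = comm$membership,
                 modularity_method = comm$method),
            class = "graph_summary")
}

#' @export
print.graph_summary <- function(x, ...) {
  cat("<graph_summary> ", x$n_nodes, " nodes\n", sep = "")
  v <- unlist(x[c("number_of_links", "average_node_degree",
                  "characteristic_path_length", "diameter",
                  "average_clustering_coefficient", "modularity",
                  "eigenvector_centrality")])
  print(round(v, 4))
  if (x$lcc_used)
    cat("(integration metrics on the largest connected component)\n")
  invisible(x)
}

#' @export
as.data.frame.graph_summary <- function(x, ...) {
  data.frame(number_of_links = x$number_of_links,
             average_node_degree = x$average_node_degree,
             characteristic_path_length = x$characteristic_path_length,
             diameter = x$diameter,
             average_clustering_coefficient =
               x$average_clustering_coefficient,
             modularity = x$modularity,
             eigenvector_centrality = x$eigenvector_centrality,
             n_nodes = x$n_nodes, lcc_used = x$lcc_used)
}

#' Group-specific (non-shared-node) networks
#'
#' Restricts two same-bin networks to the nodes each does not share with
#' the other: any node present in both networks is removed, every edge with
#' a shared endpoint drops out, and nodes left without edges are dropped.
#'
#' @param netA,netB igraph networks of the same correlation bin for the two
#'   groups.
#' @return list `a`, `b`: the two induced specific networks.
#' @export
specific_networks <- function(netA, netB) {
  shared <- intersect(igraph::V(netA)$name, igraph::V(netB)$name)
  strip <- function(g) {
    g <- igraph::delete_vertices(g, intersect(shared,
                                              igraph::V(g)$name))
    igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  }
  list(a = strip(netA), b = strip(netB))
}

metric_value <- function(g, metric, n_restarts = 2L) {
  switch(metric,
         average_node_degree = mean(igraph::degree(g)),
         average_clustering_coefficient =
           mean(igraph::transitivity(g, type = "local",
                                     isolates = "zero")),
         modularity = {
           w <- if ("weight" %in% igraph::edge_attr_names(g))
             abs(igraph::E(g)$weight) else rep(1, igraph::gsize(g))
           if (igraph::gsize(g) == 0L) NA_real_ else
             best_louvain(g, w, n_restarts)$q
         },
         eigenvector_centrality = {
           w <- if ("weight" %in% igraph::edge_attr_names(g))
             abs(igraph::E(g)$weight) else NULL
           if (igraph::gsize(g) == 0L) 0 else
             mean(igraph::eigen_centrality(g, weights = w)$vector)
         },
         stop("metric not available for subsampling: ", metric))
}

#' Node-subsampling test for a graph metric
#'
#' Compares one graph metric between two networks by repeatedly sampling a
#' fraction of each network's nodes, recomputing the metric on the induced
#' subgraphs, and applying a two-sample Student t-test to the two metric
#' distributions. Integration metrics (path length, diameter) are not
#' offered, nor is the raw link count; eligible metrics are average node
#' degree, average clustering coefficient, modularity and eigenvector
#' centrality.
#'
#' @param netA,netB igraph networks (>= 10 nodes each).
#' @param metric one of `"average_node_degree"`,
#'   `"average_clustering_coefficient"`, `"modularity"`,
#'   `"eigenvector_centrality"`.
#' @param fraction node fraction per subsample.
#' @param reps subsamples per network.
#' @param seed integer seed.
#' @return list of class `subsample_test`: `metric`, `t`, `p`,
#'   `values_a`, `values_b`, `mean_a`, `mean_b`.
#' @export
subsample_metric_test <- function(netA, netB, metric,
                                  fraction = 0.9, reps = 100L, seed = 1L) {
  metric <- match.arg(metric,
                      c("average_node_degree",
                        "average_clustering_coefficient",
                        "modularity", "eigenvector_centrality"))
  if (igraph::vcount(netA) < 10L || igraph::vcount(netB) < 10L)
    stop("both networks need >= 10 nodes")
  set.seed(as.integer(seed))
  sub_vals <- function(g) {
    k <- ceiling(fraction * igraph::vcount(g))
    replicate(reps, {
      vs <- sample(igraph::vcount(g), k)
      metric_value(igraph::induced_subgraph(g, vs), metric)
    })
  }
  va <- sub_vals(netA); vb <- sub_vals(netB)
  tt <- stats::t.test(va, vb, var.equal = TRUE)
  structure(list(metric = metric, t = unname(tt$statistic),
                 p = tt$p.value, values_a = va, values_b = vb,
                 mean_a = mean(va), mean_b = mean(vb)),
            class = "subsample_test")
}

#' @export
print.subsample_test <- function(x, ...) {
  cat("<subsample_test> ", x$metric, ": ",
      sprintf("%.4f vs %.4f, t = %.3f, p = %.4g", x$mean_a, x$mean_b,
              x$t, x$p), "\n", sep = "")
  invisible(x)
}

#' Differential-correlation edges (Fisher r-to-z)
#'
#' For every probe pair, tests whether the correlation differs between the
#' two groups with the Fisher r-to-z statistic
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))` and a
#' two-sided normal p-value. For each requested significance level a
#' network of the significant edges is built (edge weight = correlation
#' change, node attributes `degree` and `community` from Louvain on the
#' absolute changes, ready for size/color-coded export). Pairs with
#' |r| = 1 in either group have an infinite transform and are excluded
#' with a report.
#'
#' @param corr1,corr2 [group_correlation_matrix()] results on the same
#'   probe set (sample sizes > 3).
#' @param alphas significance levels, one differential network each.
#' @param build_graphs build the per-alpha igraph networks?
#' @return list of class `differential_edges`: `records` (data.frame
#'   `probe1`, `probe2`, `r_group1`, `r_group2`, `z`, `p` and one
#'   `significant_<alpha>` flag per level), `networks` (named list of
#'   igraph objects), `n_excluded`.
#' @export
differential_edges <- function(corr1, corr2, alphas = 0.05,
                               build_graphs = TRUE) {
  stopifnot(inherits(corr1, "corr_matrix"), inherits(corr2, "corr_matrix"))
  if (!identical(corr1$probe_ids, corr2$probe_ids))
    stop("correlation matrices must share one probe set")
  if (corr1$n <= 3L || corr2$n <= 3L) stop("sample sizes must exceed 3")
  p1 <- corr_pairs(corr1); p2 <- corr_pairs(corr2)
  ok <- abs(p1$r) < 1 & abs(p2$r) < 1
  n_excluded <- sum(!ok)
  if (n_excluded > 0L)
    warning(n_excluded, " pair(s) with |r| = 1 excluded from the z test")
  se <- sqrt(1 / (corr1$n - 3) + 1 / (corr2$n - 3))
  z <- (atanh(p1$r) - atanh(p2$r)) / se
  z[!ok] <- NA_real_
  p <- 2 * stats::pnorm(-abs(z))
  rec <- data.frame(probe1 = p1$probe_ids[p1$i],
                    probe2 = p1$probe_ids[p1$j],
                    r_group1 = p1$r, r_group2 = p2$r,
                    z = z, p = p, stringsAsFactors = FALSE)
  networks <- list()
  for (a in alphas) {
    flag <- !is.na(p) & p < a
    rec[[sprintf("significant_%g", a)]] <- flag
    if (build_graphs) {
      if (!any(flag)) {
        g <- igraph::make_empty_graph(0, directed = FALSE)
      } else {
        ed <- data.frame(from = rec$probe1[flag], to = rec$probe2[flag],
                         weight = rec$r_group2[flag] - rec$r_group1[flag],
                         stringsAsFactors = FALSE)
        g <- igraph::graph_from_data_frame(ed, directed = FALSE)
        igraph::V(g)$degree <- igraph::degree(g)
        igraph::V(g)$community <- as.integer(
          best_louvain(g, abs(igraph::E(g)$weight), 2L)$membership)
      }
      igraph::graph_attr(g, "alpha") <- a
      networks[[sprintf("alpha_%g", a)]] <- g
    }
  }
  structure(list(records = rec, networks = networks,
                 n_excluded = n_excluded),
            class = "differential_edges")
}

#' @export
print.differential_edges <- function(x, ...) {
  cat("<differential_edges> ", nrow(x$records), " pairs",
      if (x$n_excluded > 0) sprintf(" (%d excluded)", x$n_excluded),
      "\n", sep = "")
  for (nm in names(x$networks))
    cat("  ", nm, ": ", igraph::gsize(x$networks[[nm]]),
        " significant edges\n", sep = "")
  invisible(x)
}

#' Pairs with changed correlation but stable means
#'
#' Counts probe pairs whose two member probes show no significant mean
#' change (Welch t, raw p >= alpha for both) while the pair's correlation
#' changes significantly between groups (Fisher r-to-z, p < alpha),
#' computed on a random probe subsample and extrapolated to the full
#' pair count by the ratio of total to sampled pairs.
#'
#' @param ds an [expression_dataset()].
#' @param subsample_size probes to sample (capped at the probe count).
#' @param alpha significance level for both tests.
#' @param seed integer seed for the probe subsample.
#' @return list: `count` (pairs found in the subsample), `extrapolated`,
#'   `n_pairs_examined`, `n_pairs_total`, `sampling_fraction`,
#'   `probe_sample`.
#' @export
changed_corr_stable_mean_pairs <- function(ds, subsample_size = 3000L,
                                           alpha = 0.05, seed = 1L) {
  P <- nrow(ds$values)
  if (subsample_size > P) subsample_size <- P
  set.seed(as.integer(seed))
  probes <- sort(sample(P, subsample_size))
  sub <- expression_dataset(ds$values[probes, , drop = FALSE], ds$groups)
  me <- me_differential(sub, alpha)
  stable <- !is.na(me$me_p) & me$me_p >= alpha
  c1 <- group_correlation_matrix(sub, 1L)
  c2 <- group_correlation_matrix(sub, 2L)
  de <- differential_edges(c1, c2, alphas = alpha, build_graphs = FALSE)
  rec <- de$records
  st <- stats::setNames(stable, me$probe_id)
  hit <- !is.na(rec$p) & rec$p < alpha &
    st[rec$probe1] & st[rec$probe2]
  count <- sum(hit)
  n_sub <- choose(length(c1$probe_ids), 2)
  n_tot <- choose(P, 2)
  list(count = count,
       extrapolated = count * n_tot / n_sub,
       n_pairs_examined = n_sub, n_pairs_total = n_tot,
       sampling_fraction = n_sub / n_tot,
       probe_sample = ds$probe_ids[probes])
}

#' Density summary of correlations and their difference
#'
#' Kernel density estimates of the two groups' pairwise correlations and of
#' their elementwise difference, with standard deviations and the
#' cross-group covariance; the compactness of the difference distribution
#' relative to `sqrt(Var1 + Var2)` reflects how positively coupled the two
#' correlation structures are
#' (`Var(diff) = Var1 + Var2 - 2 Cov` exactly).
#'
#' @param corr1,corr2 matched [group_correlation_matrix()] results.
#' @return list of class `corr_diff_pdf`: `density_group1`,
#'   `density_group2`, `density_diff`, `sd_group1`, `sd_group2`, `sd_diff`,
#'   `covariance`.
#' @export
correlation_difference_pdf <- function(corr1, corr2) {
  stopifnot(identical(corr1$probe_ids, corr2$probe_ids))
  r1 <- corr_pairs(corr1)$r
  r2 <- corr_pairs(corr2)$r
  dif <- r2 - r1
  structure(list(density_group1 = stats::density(r1),
                 density_group2 = stats::density(r2),
                 density_diff = stats::density(dif),
                 sd_group1 = stats::sd(r1), sd_group2 = stats::sd(r2),
                 sd_diff = stats::sd(dif),
                 covariance = stats::cov(r1, r2)),
            class = "corr_diff_pdf")
}

#' @export
plot.corr_diff_pdf <- function(x, ...) {
  xl <- range(x$density_group1$x, x$density_group2$x, x$density_diff$x)
  yl <- c(0, max(x$density_group1$y, x$density_group2$y,
                 x$density_diff$y))
  graphics::plot(x$density_group1, col = "darkorange", xlim = xl,
                 ylim = yl, main = "pairwise correlation densities",
                 xlab = "correlation / difference", ...)
  graphics::lines(x$density_group2, col = "darkgreen")
  graphics::lines(x$density_diff, col = "blue")
  graphics::legend("topright", legend = c("group1", "group2",
                                          "difference"),
                   col = c("darkorange", "darkgreen", "blue"), lty = 1,
                   bty = "n")
  invisible(x)
}

#' Export a network to file
#'
#' Writes a network as GraphML (with node `degree` and `community`
#' attributes attached for external layout/visualization tools) or as a
#' plain edge-list TSV (`from`, `to`, `weight`).
#'
#' @param net an igraph network.
#' @param path output path.
#' @param format `"graphml"` or `"edgelist"`.
#' @return invisibly, `path`.
#' @seealso [import_network()]
#' @export
export_network <- function(net, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (!igraph::is_igraph(net)) stop("`net` must be an igraph object")
  if (igraph::vcount(net) > 0L) {
    igraph::V(net)$degree <- igraph::degree(net)
    if (!"community" %in% igraph::vertex_attr_names(net)) {
      w <- if ("weight" %in% igraph::edge_attr_names(net))
        abs(igraph::E(net)$weight) else rep(1, igraph::gsize(net))
      igraph::V(net)$community <- if (igraph::gsize(net) > 0L)
        as.integer(best_louvain(net, w, 2L)$membership) else
          seq_len(igraph::vcount(net))
    }
  }
  if (format == "graphml") {
    igraph::write_graph(net, path, format = "graphml")
  } else {
    ed <- igraph::as_data_frame(net, what = "edges")
    if (nrow(ed) == 0L)
      ed <- data.frame(from = character(0), to = character(0),
                       weight = numeric(0))
    utils::write.table(ed, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Read a network written by [export_network()]
#'
#' @param path file path.
#' @param format `"graphml"` or `"edgelist"`.
#' @return an igraph network.
#' @export
import_network <- function(path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::read_graph(path, format = "graphml")
  } else {
    ed <- utils::read.delim(path, stringsAsFactors = FALSE)
    igraph::graph_from_data_frame(ed, directed = FALSE)
  }
}
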