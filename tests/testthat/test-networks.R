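# convenience: wrap a correlation matrix in the container the network
# stage consumes, for tests that need exact correlation values
fake_corr <- function(r, n, group = "g", ids = NULL) {
  if (is.null(ids)) ids <- sprintf("p%d", seq_len(nrow(r)))
  dimnames(r) <- list(ids, ids)
  structure(list(r = r, probe_ids = ids, group = group, n = n,
                 excluded = character(0)), class = "corr_matrix")
}

corr2 <- function(r12, n) fake_corr(matrix(c(1, r12, r12, 1), 2), n)

test_that("correlation matrix: duplicates, negation, zero-variance exclusion", {
  set.seed(41)
  m <- matrix(rnorm(4 * 16), 4)
  m[2, ] <- m[1, ]
  m[3, ] <- -m[1, ]
  m[4, ] <- 7
  ds <- expression_dataset(m, rep(c("a", "b"), each = 8))
  expect_warning(cm <- group_correlation_matrix(ds, 1), "zero-variance")
  expect_identical(cm$excluded, "probe_4")
  expect_equal(cm$r["probe_1", "probe_2"], 1)
  expect_equal(cm$r["probe_1", "probe_3"], -1)
  expect_equal(cm$r, t(cm$r))
  expect_equal(unname(diag(cm$r)), rep(1, 3))
  expect_identical(cm$n, 8L)
  expect_error(group_correlation_matrix(
    expression_dataset(matrix(rnorm(12), 2), rep(c("a", "b"), each = 3)),
    1), ">= 4 samples")
})

test_that("the nine bins partition [-1, 1] with the printed boundary conventions", {
  bins <- correlation_bins()
  expect_identical(nrow(bins), 9L)
  expect_identical(sum(bins$high), 2L)
  # boundary values land where the interval notation says
  cases <- c("1" = 1L, "0.8001" = 1L, "0.8" = 2L, "0.6" = 3L,
             "0.4" = 4L, "0.2001" = 4L, "0.2" = 5L, "0" = 5L,
             "-0.2" = 5L, "-0.2001" = 6L, "-0.4" = 6L, "-0.4001" = 7L,
             "-0.6" = 7L, "-0.8" = 8L, "-0.8001" = 9L, "-1" = 9L)
  got <- assign_correlation_bin(as.numeric(names(cases)))
  expect_identical(got, unname(cases))
  # every value in exactly one bin
  set.seed(42)
  x <- runif(2000, -1, 1)
  expect_true(all(assign_correlation_bin(x) %in% 1:9))
  expect_error(assign_correlation_bin(1.5), "\\[-1, 1\\]")
})

test_that("bin networks conserve pairs and tag the extreme bins", {
  ds <- tiny_dataset(25, 10, 12, seed = 43)
  cm <- group_correlation_matrix(ds, 2)
  bn <- bin_networks(cm)
  expect_length(bn$networks, 9L)
  expect_equal(sum(bn$counts$count), choose(25, 2))
  expect_equal(sum(bn$counts$percentage), 100)
  edge_total <- sum(sapply(bn$networks, igraph::gsize))
  expect_equal(edge_total, choose(25, 2))
  for (k in 1:9) {
    g <- bn$networks[[k]]
    if (igraph::gsize(g) == 0) next
    w <- igraph::E(g)$weight
    expect_true(all(assign_correlation_bin(w) == k))
    expect_true(all(igraph::degree(g) >= 1))
  }
  # all off-diagonal 0.9: every pair in the top bin
  r <- matrix(0.9, 6, 6); diag(r) <- 1
  bn2 <- bin_networks(fake_corr(r, 20))
  expect_identical(bn2$counts$count, c(15L, rep(0L, 8L)))
})

test_that("graph summary: closed-form values on canonical graphs", {
  tri <- igraph::make_full_graph(3)
  igraph::V(tri)$name <- c("a", "b", "c")
  gs <- graph_summary(tri)
  expect_equal(gs$number_of_links, 3)
  expect_equal(gs$average_node_degree, 2)
  expect_equal(gs$characteristic_path_length, 1)
  expect_equal(gs$diameter, 1)
  expect_equal(gs$average_clustering_coefficient, 1)
  expect_false(gs$lcc_used)

  p4 <- igraph::make_ring(4, circular = FALSE)
  igraph::V(p4)$name <- letters[1:4]
  gp <- graph_summary(p4)
  expect_equal(gp$diameter, 3)
  expect_equal(gp$average_clustering_coefficient, 0)

  # two disconnected equal cliques: Q = sum(e_ii - a_i^2) = 0.5
  cl2 <- igraph::disjoint_union(igraph::make_full_graph(5),
                                igraph::make_full_graph(5))
  igraph::V(cl2)$name <- sprintf("n%d", 1:10)
  g2 <- graph_summary(cl2)
  expect_equal(g2$modularity, 0.5)
  expect_true(g2$lcc_used)
  expect_error(graph_summary(igraph::make_empty_graph(0,
                                                      directed = FALSE)),
               "empty")
})

test_that("graph summary agrees with brute-force oracles on random graphs", {
  set.seed(44)
  for (i in 1:6) {
    n <- sample(8:40, 1)
    A <- random_test_graph(n, runif(1, 0.1, 0.4))
    gs <- graph_summary(graph_from_adjacency(A),
                        modularity_method = "louvain")
    or <- oracle_graph_metrics(A)
    expect_identical(as.integer(gs$number_of_links),
                     as.integer(or$number_of_links))
    expect_equal(gs$average_node_degree, or$average_node_degree)
    expect_equal(gs$characteristic_path_length,
                 or$characteristic_path_length)
    expect_equal(gs$diameter, or$diameter)
    expect_equal(gs$average_clustering_coefficient,
                 or$average_clustering_coefficient, tolerance = 1e-12)
  }
  # exact modularity equals the subset-partition optimum on small graphs
  for (i in 1:4) {
    n <- sample(5:11, 1)
    A <- random_test_graph(n, 0.45)
    gs <- graph_summary(graph_from_adjacency(A))   # auto -> exact here
    expect_identical(gs$modularity_method, "exact")
    expect_equal(gs$modularity, oracle_modularity_opt(A),
                 tolerance = 1e-9)
  }
  # eigenvector centrality against a direct eigen-decomposition
  for (i in 1:4) {
    A <- random_test_graph(12, 0.5, connected = TRUE)
    gs <- graph_summary(graph_from_adjacency(A))
    expect_equal(gs$eigenvector_centrality,
                 oracle_eigencentrality_mean(A), tolerance = 1e-6)
  }
})

test_that("specific networks implement non-shared-node subtraction", {
  ga <- igraph::graph_from_literal(a - b, b - c, c - d)
  gb <- igraph::graph_from_literal(c - d, d - e)
  sp <- specific_networks(ga, gb)
  # shared nodes c, d removed everywhere; isolated leftovers dropped
  expect_setequal(igraph::V(sp$a)$name, c("a", "b"))
  expect_equal(igraph::gsize(sp$a), 1)
  expect_equal(igraph::vcount(sp$b), 0)

  same <- specific_networks(ga, ga)
  expect_equal(igraph::vcount(same$a), 0)
  expect_equal(igraph::vcount(same$b), 0)

  gc <- igraph::graph_from_literal(x - y, y - z)
  dis <- specific_networks(ga, gc)
  expect_setequal(igraph::V(dis$a)$name, igraph::V(ga)$name)
  expect_equal(igraph::gsize(dis$a), igraph::gsize(ga))
})

test_that("subsampling test separates structurally different graphs and is seeded", {
  clq <- igraph::make_full_graph(30)
  igraph::V(clq)$name <- sprintf("c%d", 1:30)
  pth <- igraph::make_ring(30, circular = FALSE)
  igraph::V(pth)$name <- sprintf("p%d", 1:30)
  st <- subsample_metric_test(clq, pth, "average_node_degree",
                              reps = 40, seed = 7)
  expect_lt(st$p, 0.001)
  expect_gt(st$mean_a, st$mean_b)
  st2 <- subsample_metric_test(clq, pth, "average_node_degree",
                               reps = 40, seed = 7)
  expect_identical(st$p, st2$p)
  expect_error(subsample_metric_test(igraph::make_full_graph(5), clq,
                                     "modularity"), ">= 10 nodes")
  expect_error(subsample_metric_test(clq, pth, "characteristic_path_length"))
})

test_that("Fisher r-to-z differential edges: null, worked value, exclusions", {
  same <- fake_corr(matrix(c(1, .5, .5, 1), 2), 40)
  de0 <- differential_edges(same, fake_corr(same$r, 60), alphas = 0.05)
  expect_equal(de0$records$z, 0)
  expect_equal(de0$records$p, 1)

  # atanh(0.9) / sqrt(1/68 + 1/39)
  de <- differential_edges(corr2(0.9, 71), corr2(0, 42), alphas = 0.05)
  expect_equal(de$records$z, atanh(0.9) / sqrt(1 / 68 + 1 / 39),
               tolerance = 1e-12)
  expect_equal(round(de$records$z, 2), 7.33)
  expect_true(de$records$significant_0.05)

  expect_warning(
    dex <- differential_edges(corr2(1, 30), corr2(0.2, 30)),
    "excluded")
  expect_identical(dex$n_excluded, 1L)
  expect_true(is.na(dex$records$z))

  expect_error(differential_edges(corr2(0.1, 3), corr2(0.1, 30)),
               "exceed 3")
})

test_that("differential networks carry degree and community attributes per alpha", {
  set.seed(46)
  out <- generate_dataset(synthetic_config(
    n_probes = 60, seed = 46,
    mean_shift_block = list(count = 0, effect_size = 1, fraction_up = .5),
    shape_shift_block = list(count = 0, variance_ratio = 9),
    entropy_shift_block = list(count = 0, dispersion_ratio = 3),
    module_block = list(n_modules = 1, module_size = 8,
                        within_correlation_group1 = 0,
                        within_correlation_group2 = 0.9),
    quadruplet_block = list(count = 0, noise_sd_group1 = 1,
                            noise_sd_group2 = 1)))
  c1 <- group_correlation_matrix(out$dataset, 1)
  c2 <- group_correlation_matrix(out$dataset, 2)
  de <- differential_edges(c1, c2, alphas = c(0.05, 1e-6))
  expect_named(de$networks, c("alpha_0.05", "alpha_1e-06"))
  g <- de$networks[["alpha_1e-06"]]
  expect_gt(igraph::gsize(g), 0)
  expect_identical(igraph::V(g)$degree,
                   unname(igraph::degree(g)))
  expect_true(all(igraph::V(g)$community >= 1))
  expect_lte(igraph::gsize(g),
             igraph::gsize(de$networks[["alpha_0.05"]]))
})

test_that("changed-correlation stable-mean pairs: construction and extrapolation", {
  out <- generate_dataset(synthetic_config(
    n_probes = 120, seed = 47,
    mean_shift_block = list(count = 0, effect_size = 1, fraction_up = .5),
    shape_shift_block = list(count = 0, variance_ratio = 9),
    entropy_shift_block = list(count = 0, dispersion_ratio = 3),
    module_block = list(n_modules = 1, module_size = 8,
                        within_correlation_group1 = 0,
                        within_correlation_group2 = 0.9),
    quadruplet_block = list(count = 0, noise_sd_group1 = 1,
                            noise_sd_group2 = 1)))
  full <- changed_corr_stable_mean_pairs(out$dataset,
                                         subsample_size = 120, seed = 3)
  # equal-mean module pairs with rho 0.9 vs 0 are all detected
  expect_gte(full$count, choose(8, 2))
  expect_equal(full$extrapolated, full$count)      # no subsampling here
  sub <- changed_corr_stable_mean_pairs(out$dataset,
                                        subsample_size = 60, seed = 3)
  expect_equal(sub$extrapolated,
               sub$count * choose(120, 2) / choose(60, 2))
  expect_equal(sub$sampling_fraction, choose(60, 2) / choose(120, 2))
})

test_that("correlation difference density obeys the variance identity", {
  set.seed(48)
  ds <- tiny_dataset(30, 12, 14, seed = 48)
  c1 <- group_correlation_matrix(ds, 1)
  c2 <- group_correlation_matrix(ds, 2)
  pdf <- correlation_difference_pdf(c1, c2)
  expect_equal(pdf$sd_diff^2,
               pdf$sd_group1^2 + pdf$sd_group2^2 - 2 * pdf$covariance,
               tolerance = 1e-12)
  zero <- correlation_difference_pdf(c1, c1)
  expect_equal(zero$sd_diff, 0)
  # independent matrices: Var(diff) ~ Var1 + Var2
  ds2 <- tiny_dataset(30, 12, 14, seed = 148)
  c2i <- group_correlation_matrix(ds2, 2)
  ind <- correlation_difference_pdf(c1, c2i)
  expect_lt(abs(ind$sd_diff^2 -
                  (ind$sd_group1^2 + ind$sd_group2^2)) /
              ind$sd_diff^2, 0.25)
})

test_that("network export/import round-trips graphs in both formats", {
  set.seed(49)
  A <- random_test_graph(12, 0.4)
  g <- graph_from_adjacency(A)
  for (fmt in c("graphml", "edgelist")) {
    path <- tempfile(fileext = paste0(".", fmt))
    export_network(g, path, fmt)
    h <- import_network(path, fmt)
    expect_setequal(igraph::V(h)$name, igraph::V(g)$name[
      igraph::degree(g) > 0 | fmt == "graphml"])
    eg <- igraph::as_data_frame(g, what = "edges")
    eh <- igraph::as_data_frame(h, what = "edges")
    key <- function(d) paste(pmin(d$from, d$to), pmax(d$from, d$to))
    expect_setequal(key(eh), key(eg))
    expect_equal(sort(eh$weight), sort(eg$weight), tolerance = 1e-9)
    if (fmt == "graphml")
      expect_equal(sort(unname(igraph::V(h)$degree)),
                   sort(unname(igraph::degree(g))))
  }
  # empty network still yields a valid file
  e <- igraph::make_empty_graph(0, directed = FALSE)
  p <- tempfile(fileext = ".graphml")
  export_network(e, p, "graphml")
  expect_equal(igraph::gsize(import_network(p, "graphml")), 0)
  expect_error(export_network(g, tempfile(), "gexfx"))
})
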