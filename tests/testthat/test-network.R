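path3 <- function() {
  w <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  w["a", "b"] <- w["b", "a"] <- 1
  w["b", "c"] <- w["c", "b"] <- 1
  network_from_weights(w)
}

test_that("edge weights are |r|^3 with the sign stored separately", {
  # three samples-by-genes columns engineered for exact correlations
  x <- cbind(g1 = c(1, 2, 3, 4), g2 = c(2, 4, 6, 8), g3 = c(4, 3, 2, 1))
  net <- build_network(expr_tibble(x))
  edges <- tidy(net)
  e12 <- edges[edges$gene_i == "g1" & edges$gene_j == "g2", ]
  e13 <- edges[edges$gene_i == "g1" & edges$gene_j == "g3", ]
  expect_equal(e12$r, 1)
  expect_equal(e12$weight, 1)
  expect_equal(e12$sign, "+")
  expect_equal(e13$r, -1)
  expect_equal(e13$weight, 1)
  expect_equal(e13$sign, "-")

  w <- matrix(0.5^3, 2, 2) # direct weight check: r = 0.5 -> w = 0.125
  expect_equal(abs(-0.8)^3, 0.512)
  expect_equal(abs(0.5)^3, 0.125)
})

test_that("zero-variance genes are excluded with a warning", {
  x <- cbind(g1 = rnorm(6), g2 = rnorm(6), g3 = rnorm(6), g4 = rep(7, 6))
  expect_warning(net <- build_network(expr_tibble(x)), "g4")
  expect_setequal(net$genes, c("g1", "g2", "g3"))
})

test_that("density follows mean weighted degree over n - 1", {
  w3 <- matrix(0.5, 3, 3)
  diag(w3) <- 0
  expect_equal(network_density(network_from_weights(w3)), 0.5)

  complete <- matrix(1, 5, 5)
  diag(complete) <- 0
  expect_equal(network_density(network_from_weights(complete)), 1)

  expect_equal(network_density(network_from_weights(matrix(0, 4, 4))), 0)
})

test_that("clustering matches the closed-form triangle and path cases", {
  triangle <- matrix(1, 3, 3)
  diag(triangle) <- 0
  expect_equal(as.numeric(network_clustering(network_from_weights(triangle))), 1)

  clus_p3 <- network_clustering(path3())
  expect_equal(as.numeric(clus_p3), 0) # node b has no triangle
  expect_equal(attr(clus_p3, "n_excluded"), 2L) # a and c have one neighbour

  # no node with two neighbours -> undefined
  pair <- matrix(0, 3, 3)
  pair[1, 2] <- pair[2, 1] <- 1
  expect_error(
    network_clustering(network_from_weights(pair)),
    class = "fcg_degenerate"
  )
})

test_that("assortativity matches closed-form star, path, and regular cases", {
  star <- matrix(0, 4, 4)
  star[1, 2:4] <- star[2:4, 1] <- 1
  expect_equal(network_assortativity(network_from_weights(star)), -1)

  expect_equal(network_assortativity(path3()), -1)

  c4 <- matrix(0, 4, 4)
  c4[cbind(1:4, c(2, 3, 4, 1))] <- 1
  c4 <- pmax(c4, t(c4))
  r <- network_assortativity(network_from_weights(c4))
  expect_true(is.na(r))
  expect_true(isTRUE(attr(r, "undefined")))

  single <- matrix(0, 3, 3)
  single[1, 2] <- single[2, 1] <- 0.5
  expect_error(
    network_assortativity(network_from_weights(single)),
    class = "fcg_degenerate"
  )
})

test_that("graph statistics agree with brute-force oracles on random graphs", {
  set.seed(77)
  for (i in 1:20) {
    n <- sample(5:9, 1)
    w <- random_weight_matrix(n)
    net <- network_from_weights(w)
    expect_equal(
      as.numeric(network_clustering(net)), oracle_clustering(w),
      tolerance = 1e-12
    )
    expect_equal(
      as.numeric(network_assortativity(net)), oracle_assortativity(w),
      tolerance = 1e-9
    )
  }
})

test_that("properties are invariant under node relabeling", {
  set.seed(3)
  w <- random_weight_matrix(7)
  perm <- sample(7)
  net1 <- network_from_weights(w)
  net2 <- network_from_weights(w[perm, perm])
  expect_equal(network_density(net1), network_density(net2), tolerance = 1e-12)
  expect_equal(
    as.numeric(network_clustering(net1)),
    as.numeric(network_clustering(net2)),
    tolerance = 1e-12
  )
  expect_equal(
    as.numeric(network_assortativity(net1)),
    as.numeric(network_assortativity(net2)),
    tolerance = 1e-12
  )
})

test_that("density and clustering are monotone in any single edge weight", {
  set.seed(8)
  for (i in 1:10) {
    w <- random_weight_matrix(6) * 0.8
    i1 <- sample(5, 1)
    i2 <- sample((i1 + 1):6, 1)
    w2 <- w
    w2[i1, i2] <- w2[i2, i1] <- w[i1, i2] + 0.1
    expect_gt(
      network_density(network_from_weights(w2)),
      network_density(network_from_weights(w))
    )
    expect_gte(
      as.numeric(network_clustering(network_from_weights(w2))) + 1e-12,
      as.numeric(network_clustering(network_from_weights(w)))
    )
  }
})

test_that("permutation comparison of a group with itself gives delta 0, p = 1", {
  sim <- simulate_study(tiny_config(), seed = 4)
  expr <- quantify_expression(sim$ct, c("Actb", "Gapdh"))
  ids <- sim$design$sample_id[1:8]
  cmp <- compare_networks(expr, ids, ids,
    properties = "density",
    n_perm = 49, seed = 1
  )
  tab <- tidy(cmp)
  expect_equal(tab$delta, 0)
  expect_equal(tab$p, 1)
})

test_that("permutation p-values are reproducible bit-for-bit given a seed", {
  sim <- simulate_study(tiny_config(), seed = 4)
  expr <- quantify_expression(sim$ct, c("Actb", "Gapdh"))
  ids_a <- sim$design$sample_id[sim$design$gonadal_sex == "testes"]
  ids_b <- sim$design$sample_id[sim$design$gonadal_sex == "ovaries"]
  c1 <- compare_networks(expr, ids_a, ids_b, n_perm = 99, seed = 5)
  c2 <- compare_networks(expr, ids_a, ids_b, n_perm = 99, seed = 5)
  c3 <- compare_networks(expr, ids_a, ids_b, n_perm = 99, seed = 6)
  expect_identical(tidy(c1), tidy(c2))
  expect_identical(c1$null_delta, c2$null_delta)
  expect_false(identical(c1$null_delta, c3$null_delta))
  expect_true(all(tidy(c1)$p > 0 & tidy(c1)$p <= 1))
})

test_that("reference projection keeps the edge set, recomputing the weights", {
  sim <- simulate_study(tiny_config(), seed = 9)
  expr <- quantify_expression(sim$ct, c("Actb", "Gapdh"))
  ids_m <- sim$design$sample_id[sim$design$gonadal_sex == "testes"]
  ids_f <- sim$design$sample_id[sim$design$gonadal_sex == "ovaries"]
  ref <- build_network(expr, ids_m, tau = 0.05, group = "testes")

  self_proj <- project_reference(ref, expr, ids_m, group = "testes")
  expect_equal(self_proj$w, ref$w, tolerance = 1e-12)
  expect_equal(self_proj$r, ref$r, tolerance = 1e-12)

  proj <- project_reference(ref, expr, ids_f, group = "ovaries")
  expect_true(all(proj$w[ref$w <= ref$tau] == 0))
  own_f <- build_network(expr, ids_f, group = "ovaries")
  kept <- ref$w > ref$tau
  expect_equal(proj$w[kept], own_f$w[kept], tolerance = 1e-12)

  # a reference with every edge thresholded away projects to an empty graph
  ref_empty <- build_network(expr, ids_m, tau = 0.999999, group = "testes")
  ref_empty$w[] <- 0
  proj_empty <- project_reference(ref_empty, expr, ids_f)
  expect_true(all(proj_empty$w == 0))

  expect_error(
    project_reference(ref, dplyr::select(expr, -Sst), ids_f),
    regexp = "Sst", class = "fcg_invalid_input"
  )
})

test_that("edge-list and GraphML exports round-trip through igraph", {
  sim <- simulate_study(tiny_config(), seed = 2)
  expr <- quantify_expression(sim$ct, c("Actb", "Gapdh"))
  net <- build_network(expr, group = "all")
  tsv <- tempfile(fileext = ".tsv")
  gml <- tempfile(fileext = ".graphml")
  write_network_edges(net, tsv)
  write_network_graphml(net, gml)
  edges <- readr::read_tsv(tsv, show_col_types = FALSE)
  expect_equal(nrow(edges), choose(length(net$genes), 2))
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::vcount(g), length(net$genes))
  expect_equal(
    sort(igraph::V(g)$degree),
    sort(unname(weighted_degrees(net))),
    tolerance = 1e-6
  )
})
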