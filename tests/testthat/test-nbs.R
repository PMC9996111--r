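# Network-Based Statistics core: edge GLM t, component extraction,
# Freedman-Lane permutation null, threshold sweep.

simple_design <- function(score) {
  nbs_design(cbind(intercept = 1, score = score), c(0, 1))
}

test_that("edge GLM t equals the closed-form correlation t", {
  set.seed(5)
  n <- 24
  score <- rnorm(n)
  Y <- matrix(rnorm(n * 30), n)
  colnames(Y) <- paste(0, seq_len(ncol(Y)), sep = "-")
  fit <- edge_glm_tstats(Y, simple_design(score))
  r <- cor(score, Y)[1, ]
  t_oracle <- unname(r * sqrt((n - 2) / (1 - r^2)))
  expect_equal(unname(fit$t), t_oracle, tolerance = 1e-10)
  expect_equal(fit$df, n - 2)
})

test_that("orthogonal scores give t = 0 and noiseless effects give t = Inf", {
  set.seed(6)
  n <- 16
  score <- scale(rnorm(n))[, 1]
  y_orth <- residuals(lm(rnorm(n) ~ score))
  Y <- cbind(`0-1` = y_orth)
  expect_equal(unname(edge_glm_tstats(Y, simple_design(score))$t), 0,
               tolerance = 1e-8)
  Y2 <- cbind(`0-1` = 0.4 + 0.05 * score)
  expect_warning(fit <- edge_glm_tstats(Y2, simple_design(score)),
                 "zero residual variance")
  expect_identical(unname(fit$t), Inf)
})

test_that("t to p conversion matches the Student t tail", {
  expect_equal(round(t_to_p(3.5, 39), 3), 0.001)
  expect_equal(t_to_p(0, 10), 1)
  expect_lt(t_to_p(50, 10), 1e-10)
  expect_equal(t_to_p(2, 20, "one"), t_to_p(2, 20) / 2)
  expect_error(t_to_p(1, 0.5), "df")
})

test_that("component extraction agrees with the DFS oracle on random graphs", {
  set.seed(12)
  has_igraph <- requireNamespace("igraph", quietly = TRUE)
  for (rep in 1:60) {
    n_nodes <- sample(3:8, 1)
    pairs <- t(combn(n_nodes, 2))
    keep <- runif(nrow(pairs)) < 0.35
    if (!any(keep)) next
    edges <- data.frame(node_a = pairs[keep, 1], node_b = pairs[keep, 2])
    tstats <- rep(1, nrow(edges))
    comps <- threshold_components(tstats, edges, 0.5)
    got <- canonical_partition(lapply(comps, `[[`, "nodes"))
    want <- canonical_partition(oracle_components(edges))
    expect_identical(got, want)
    expect_equal(sum(vapply(comps, `[[`, integer(1), "n_edges")),
                 nrow(edges))
    if (has_igraph) {
      g <- igraph::graph_from_data_frame(edges, directed = FALSE)
      expect_equal(length(comps),
                   igraph::components(g)$no)
    }
  }
})

test_that("thresholding is inclusive and empty results are empty lists", {
  edges <- data.frame(node_a = c(1, 2, 4), node_b = c(2, 3, 5))
  comps <- threshold_components(c(3.5, 2, -3.5), edges, 3.5)
  expect_equal(length(comps), 1)           # tie at threshold is kept
  expect_equal(comps[[1]]$nodes, c(1, 2))
  neg <- threshold_components(c(3.5, 2, -3.5), edges, 3.5, sign = "negative")
  expect_equal(neg[[1]]$nodes, c(4, 5))
  both <- threshold_components(c(3.5, 2, -3.5), edges, 3.5,
                               sidedness = "two")
  expect_equal(length(both), 2)
  expect_identical(threshold_components(c(1, 1, 1), edges, 3.5), list())
  # non-finite statistics are kept out of the graph
  expect_identical(threshold_components(c(Inf, NaN, 1), edges, 3.5), list())
})

test_that("the published subnetwork edge lists form single components", {
  drs <- read_subnetwork_edges("DRS")
  comps <- threshold_components(drs$t, drs, 3.5)
  expect_equal(length(comps), 1)
  expect_identical(canonical_partition(lapply(comps, `[[`, "nodes")),
                   canonical_partition(oracle_components(drs)))
})

test_that("with no nuisance columns Freedman-Lane permutes the raw rows", {
  set.seed(30)
  n <- 12
  score <- rnorm(n)
  pairs <- t(combn(5, 2))
  Y <- matrix(rnorm(n * nrow(pairs), 0.4, 0.05), n)
  colnames(Y) <- paste(pairs[, 1], pairs[, 2], sep = "-")
  d <- simple_design(score)
  res <- nbs_fwer(Y, d, t_threshold = 1.5, n_permutations = 150, seed = 77)
  # manual raw-row permutation with the identical seeded sampler
  X <- d$X
  cvec <- d$contrast
  xtx_inv <- chol2inv(chol(crossprod(X)))
  w <- drop(t(cvec) %*% xtx_inv %*% t(X))
  M <- diag(n) - X %*% xtx_inv %*% t(X)
  cxc <- drop(t(cvec) %*% xtx_inv %*% cvec)
  set.seed(77)
  manual <- vapply(1:150, function(p) {
    Ys <- Y[sample.int(n), ]
    tt <- drop(w %*% Ys) / sqrt(colSums((M %*% Ys)^2) / (n - 2) * cxc)
    supra <- which(is.finite(tt) & tt >= 1.5)
    if (!length(supra)) return(0L)
    cl <- oracle_components(data.frame(node_a = pairs[supra, 1],
                                       node_b = pairs[supra, 2]))
    sub <- data.frame(node_a = pairs[supra, 1], node_b = pairs[supra, 2])
    max(vapply(cl, function(nodes) {
      sum(sub$node_a %in% nodes & sub$node_b %in% nodes)
    }, integer(1)))
  }, integer(1))
  expect_identical(res$null_max_size, manual)
})

test_that("NBS inference is invariant to subject order and nuisance sign", {
  ds <- make_test_dataset(n_subjects = 30, seed = 41)
  st <- stack_from_sim(ds$atlas, ds$sim)
  d <- build_design(ds$sim$cohort, "DRS")
  res <- nbs_fwer(st, d, 3.5, n_permutations = 200, seed = 5)
  # reorder subjects coherently: observed t and components are unchanged
  ord <- rev(seq_len(nrow(st$x)))
  d2 <- build_design(ds$sim$cohort[ord, ], "DRS")
  fit1 <- edge_glm_tstats(st$x, d)
  fit2 <- edge_glm_tstats(st$x[ord, ], d2)
  expect_equal(fit1$t, fit2$t, tolerance = 1e-10)
  # flipping the PCA sign convention of the nuisance column changes nothing
  d3 <- d
  d3$X[, "acq_pc1"] <- -d3$X[, "acq_pc1"]
  res3 <- nbs_fwer(st, d3, 3.5, n_permutations = 200, seed = 5)
  expect_equal(res$tstats, res3$tstats, tolerance = 1e-10)
  expect_identical(res$null_max_size, res3$null_max_size)
  expect_equal(vapply(res$components, `[[`, numeric(1), "p"),
               vapply(res3$components, `[[`, numeric(1), "p"))
})

test_that("degenerate inputs are refused", {
  ds <- make_test_dataset(n_subjects = 10, seed = 2)
  st <- stack_from_sim(ds$atlas, ds$sim)
  d <- build_design(ds$sim$cohort, "DRS")
  expect_error(nbs_fwer(st, d, 3.5, n_permutations = 0), "n_permutations")
  empty <- st
  empty$x <- st$x[, 0, drop = FALSE]
  empty$edges <- st$edges[0, ]
  expect_error(nbs_fwer(empty, d), "no valid edges")
  expect_error(nbs_fwer(unname(st$x[, 1, drop = FALSE]), d), "edge index")
})

test_that("the threshold sweep is monotone and shares its seed", {
  ds <- make_test_dataset(n_subjects = 40, seed = 3)
  st <- stack_from_sim(ds$atlas, ds$sim)
  d <- build_design(ds$sim$cohort, "DRS")
  sweep_res <- threshold_sweep(st, d, thresholds = c(2.5, 3.0, 3.5, 10, 200),
                               n_permutations = 100, seed = 9)
  expect_equal(length(sweep_res), 5)
  largest <- vapply(sweep_res, function(r) {
    if (!length(r$components)) 0L else r$components[[1]]$n_edges
  }, integer(1))
  expect_true(all(diff(largest) <= 0))
  # an empty high-threshold result reports no suprathreshold connections
  expect_identical(sweep_res[["t=200.00"]]$components, list())
  expect_output(print(sweep_res[["t=200.00"]]), "No suprathreshold")
})
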