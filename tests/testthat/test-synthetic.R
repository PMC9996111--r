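# Synthetic-data generators: determinism, self-labelled ground truth, and
# forward-model consistency with the analysis the pipeline runs.

test_that("toy atlas writes its own ground truth and is deterministic", {
  atlas <- make_toy_atlas(12, c(24, 24, 24), seed = 7)
  expect_s3_class(atlas, "bundle_atlas")
  designed <- attr(atlas, "designed_retained")
  kept <- consistent_edges(atlas, 0.8)
  expect_equal(kept[c("node_a", "node_b")], designed,
               ignore_attr = TRUE)
  # both consistency filters have something to act on
  expect_true(any(atlas$edges$presence < 0.8))
  expect_true(any(unlist(lapply(atlas$bundles, `[[`, "prob")) < 0.9))
  expect_true(any(atlas$edges$presence == 0.8))   # inclusive-rule probe
  expect_identical(atlas, make_toy_atlas(12, c(24, 24, 24), seed = 7))
  expect_false(identical(atlas, make_toy_atlas(12, c(24, 24, 24), seed = 8)))
})

test_that("toy atlas rejects a grid too small for its nodes", {
  expect_error(make_toy_atlas(30, c(6, 6, 6), seed = 1), "too small")
})

test_that("an all-probability-one bundle keeps every voxel", {
  atlas <- mini_atlas(probs = rep(1, 10))
  vox <- consistent_voxels(atlas, c(0, 1), 0.9)
  expect_equal(nrow(vox), 10)
})

test_that("noiseless cohorts reproduce the designed edge values exactly", {
  atlas <- make_toy_atlas(8, c(20, 20, 20), seed = 5)
  ring <- attr(atlas, "designed_retained")
  # zero effect, zero noise, zero nuisance: connectome == baseline everywhere
  cfg0 <- cohort_config(n_subjects = 8, planted_edges = ring[1, ],
                        effect_slope = 0, noise_sd = 0,
                        nuisance_slopes = c(age = 0, sex = 0, acq = 0),
                        seed = 2)
  sim0 <- simulate_cohort(atlas, cfg0)
  st0 <- stack_from_sim(atlas, sim0)
  expect_true(all(st0$x == 0.5))
  # planted slope, zero noise: edge-wise OLS on z(score) recovers beta exactly
  planted <- as.matrix(ring[1:5, ])
  cfg <- cohort_config(n_subjects = 12, planted_edges = planted,
                       effect_slope = 0.05, noise_sd = 0,
                       nuisance_slopes = c(age = 0, sex = 0, acq = 0),
                       seed = 4)
  sim <- simulate_cohort(atlas, cfg)
  st <- stack_from_sim(atlas, sim)
  z <- scale(sim$truth$score)[, 1]
  slopes <- apply(st$x, 2, function(y) coef(lm(y ~ z))[2])
  planted_keys <- paste(planted[, 1], planted[, 2], sep = "-")
  expect_equal(unname(slopes[planted_keys]), rep(0.05, 5), tolerance = 1e-10)
  expect_equal(unname(slopes[setdiff(names(slopes), planted_keys)]),
               rep(0, length(slopes) - 5), tolerance = 1e-10)
})

test_that("noisy edge-wise OLS slopes are unbiased over replicates", {
  # brute-force Monte-Carlo oracle: the replicate mean of the OLS slope on
  # the planted edges should approach beta
  atlas <- make_toy_atlas(6, c(12, 12, 12), seed = 9)
  ring <- attr(atlas, "designed_retained")
  planted <- as.matrix(ring[1:2, ])
  planted_keys <- paste(planted[, 1], planted[, 2], sep = "-")
  beta <- 0.05
  n_rep <- 200
  est <- matrix(NA_real_, n_rep, 2)
  for (r in seq_len(n_rep)) {
    cfg <- cohort_config(n_subjects = 40, planted_edges = planted,
                         effect_slope = beta, noise_sd = 0.02,
                         nuisance_slopes = c(age = 0, sex = 0, acq = 0),
                         seed = 5000 + r)
    sim <- simulate_cohort(atlas, cfg)
    st <- stack_from_sim(atlas, sim)
    z <- scale(sim$truth$score)[, 1]
    est[r, ] <- apply(st$x[, planted_keys], 2,
                      function(y) coef(lm(y ~ z))[2])
  }
  # per-edge noise ~ noise_sd/sqrt(bundle size); 3 MC standard errors
  mc_tol <- 3 * sd(est) / sqrt(n_rep)
  expect_lt(abs(mean(est) - beta), mc_tol)
})

test_that("clipping never triggers under default generator conditions", {
  ds <- make_test_dataset(n_subjects = 10, seed = 6)
  vals <- unlist(ds$sim$fa)
  expect_true(all(vals > 0 & vals < 1))
})

test_that("planted edges must exist in the atlas", {
  atlas <- make_toy_atlas(8, c(20, 20, 20), seed = 5)
  cfg <- cohort_config(n_subjects = 8, planted_edges = rbind(c(0, 7), c(2, 6)))
  expect_error(simulate_cohort(atlas, cfg), "absent from the atlas")
})

test_that("diffusion signal forward model matches its closed form", {
  gs <- gradient_scheme(12, n_b0 = 2, seed = 1)
  d <- 0.7e-3
  s <- simulate_dwi_signals(diag(c(d, d, d)), gs$bvals, gs$bvecs, s0 = 2)
  expect_equal(s[gs$bvals == 0], rep(2, 2))             # b = 0 gives S0
  expect_equal(s[gs$bvals > 0], rep(2 * exp(-1000 * d), 12))
  s1 <- simulate_dwi_signals(diag(c(2, 1, 1)) * 1e-3, 1000,
                             matrix(c(1, 0, 0), 1))
  expect_equal(s1, exp(-2))
  expect_error(simulate_dwi_signals(diag(3) * 1e-3, 1000,
                                    matrix(c(1, 1, 0), 1)),
               "unit vectors")
  expect_error(simulate_dwi_signals(diag(3) * 1e-3, -10,
                                    matrix(c(1, 0, 0), 1)),
               "negative b-value")
  noisy1 <- simulate_dwi_signals(diag(3) * 1e-3, gs$bvals, gs$bvecs,
                                 noise_sd = 0.05, seed = 3)
  noisy2 <- simulate_dwi_signals(diag(3) * 1e-3, gs$bvals, gs$bvecs,
                                 noise_sd = 0.05, seed = 3)
  expect_identical(noisy1, noisy2)
})

test_that("QC generator plants exactly the failures the screen finds", {
  none <- simulate_qc_metrics(25, 0, seed = 2)
  expect_true(all(qc_screen(none) == "keep"))
  all_fail <- simulate_qc_metrics(25, 1, seed = 2)
  expect_true(all(qc_screen(all_fail) == "exclude"))
  some <- simulate_qc_metrics(100, 0.1, seed = 4)
  screened <- qc_screen(some)
  expect_identical(screened == "exclude", attr(some, "planted_fail"))
  expect_equal(sum(screened == "exclude"), 10)
})

test_that("cohort generation is deterministic in the seed", {
  a <- make_test_dataset(n_subjects = 8, seed = 11)
  b <- make_test_dataset(n_subjects = 8, seed = 11)
  expect_identical(a$sim, b$sim)
})
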