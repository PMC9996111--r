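# Synthetic-data generators: toy probabilistic bundle atlas, FA phantoms with
# planted score effects, diffusion-weighted signals from known tensors,
# cohort tables and quality-control metrics. The generators write their own
# ground truth, so every downstream module can be tested without any
# patient data or atlas download.

#' Generate a toy probabilistic bundle atlas
#'
#' Emulates, at desk scale, a population-derived white-matter bundle atlas:
#' nodes are placed on a circle inside the voxel grid, a designed subset of
#' node pairs gets a contiguous voxel tube with per-voxel occupancy
#' probabilities, and every edge gets a population presence fraction. Ring
#' edges are given presence >= 0.85 (the designed retained set at the default
#' 80% presence filter) while chord edges get presence in \[0.5, 0.75\] so the
#' filter has something to drop; about 20% of each bundle's voxels get
#' occupancy < 0.9 to exercise the voxel filter. Bundle voxel sets are made
#' disjoint so planted edge effects stay exactly recoverable.
#'
#' @param n_nodes Number of parcellation nodes (>= 4).
#' @param grid_shape Voxel grid dimensions (3 integers).
#' @param seed RNG seed; identical seeds give bit-identical atlases.
#' @param voxel_size Isotropic voxel size in mm.
#' @return A [bundle_atlas()] with attribute `designed_retained`, the edge
#'   index the generator intends the 80% presence filter to keep.
#' @export
make_toy_atlas <- function(n_nodes = 12, grid_shape = c(24, 24, 24), seed = 1,
                           voxel_size = 2) {
  stopifnot(n_nodes >= 4, length(grid_shape) == 3)
  grid_shape <- as.integer(grid_shape)
  .with_seed(seed, {
    centre <- (grid_shape + 1) / 2
    radius <- (min(grid_shape) - 4) / 2
    ang <- 2 * pi * (seq_len(n_nodes) - 1) / n_nodes
    pos <- cbind(round(centre[1] + radius * cos(ang)),
                 round(centre[2] + radius * sin(ang)),
                 round(centre[3] + (radius / 3) * sin(2 * ang)))
    if (anyDuplicated(pos) || any(pos < 1) ||
        any(sweep(pos, 2, grid_shape, ">") != 0)) {
      stop("grid too small to place ", n_nodes, " disjoint node seeds",
           call. = FALSE)
    }
    nodes <- data.frame(
      id = 0:(n_nodes - 1),
      name = sprintf("region_%02d", 0:(n_nodes - 1)),
      hemisphere = ifelse(pos[, 1] <= centre[1], "L", "R"),
      x = (pos[, 1] - centre[1]) * voxel_size,
      y = (pos[, 2] - centre[2]) * voxel_size,
      z = (pos[, 3] - centre[3]) * voxel_size)

    # ring edges are the designed retained set; chords are designed drop-outs
    ring <- cbind(0:(n_nodes - 1), c(1:(n_nodes - 1), 0))
    chords <- cbind(seq(0, n_nodes - 3, by = 2), seq(2, n_nodes - 1, by = 2))
    pairs <- rbind(ring, chords)
    pairs <- cbind(pmin(pairs[, 1], pairs[, 2]), pmax(pairs[, 1], pairs[, 2]))
    retained <- rep(c(TRUE, FALSE), c(nrow(ring), nrow(chords)))
    presence <- ifelse(retained, runif(nrow(pairs), 0.85, 1),
                       runif(nrow(pairs), 0.5, 0.75))
    presence[1] <- 0.8   # sits exactly on the inclusive 80% rule

    taken <- array(FALSE, grid_shape)
    bundles <- list()
    keep_edge <- logical(nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      a <- pairs[i, 1]; b <- pairs[i, 2]
      p0 <- pos[a + 1, ]; p1 <- pos[b + 1, ]
      steps <- max(2L, 4L * as.integer(ceiling(sqrt(sum((p1 - p0)^2)))))
      tt <- seq(0, 1, length.out = steps)
      line <- unique(round(cbind(p0[1] + tt * (p1[1] - p0[1]),
                                 p0[2] + tt * (p1[2] - p0[2]),
                                 p0[3] + tt * (p1[3] - p0[3]))))
      # thicken to a 2-voxel-wide tube
      tube <- unique(rbind(line,
                           sweep(line, 2, c(1, 0, 0), "+"),
                           sweep(line, 2, c(0, 1, 0), "+")))
      inside <- tube[, 1] >= 1 & tube[, 1] <= grid_shape[1] &
        tube[, 2] >= 1 & tube[, 2] <= grid_shape[2] &
        tube[, 3] >= 1 & tube[, 3] <= grid_shape[3]
      tube <- tube[inside, , drop = FALSE]
      free <- !taken[tube]
      tube <- tube[free, , drop = FALSE]
      if (nrow(tube) < 4L) next   # fully shadowed by earlier bundles
      taken[tube] <- TRUE
      lin <- (tube[, 3] - 1) * grid_shape[1] * grid_shape[2] +
        (tube[, 2] - 1) * grid_shape[1] + tube[, 1]
      tube <- tube[order(lin), , drop = FALSE]
      k <- nrow(tube)
      prob <- runif(k, 0.92, 1)
      low <- runif(k) < 0.2
      low[1:3] <- FALSE            # keep >= 3 voxels past the 90% filter
      prob[low] <- runif(sum(low), 0.3, 0.85)
      bundles[[.edge_key(a, b)]] <- list(
        voxels = matrix(as.integer(tube), ncol = 3,
                        dimnames = list(NULL, c("i", "j", "k"))),
        prob = prob)
      keep_edge[i] <- TRUE
    }
    edges <- data.frame(node_a = as.integer(pairs[keep_edge, 1]),
                        node_b = as.integer(pairs[keep_edge, 2]),
                        presence = presence[keep_edge])
    atlas <- bundle_atlas(
      nodes, edges, bundles,
      grid = list(shape = grid_shape,
                  pixdim = rep(voxel_size, 3),
                  affine = diag(c(rep(voxel_size, 3), 1))))
    attr(atlas, "designed_retained") <-
      edges[edges$presence >= 0.8, c("node_a", "node_b")]
    atlas
  })
}

#' Configuration for a synthetic cohort
#'
#' Defines the data-generating conditions for [simulate_cohort()]: edge FA is
#' linear in the z-scored clinical score on the planted edges, with additive
#' nuisance effects of age, sex and a latent acquisition factor, plus
#' i.i.d. Gaussian voxel noise.
#'
#' @param n_subjects Cohort size (>= 7: design rank 5 plus 2).
#' @param planted_edges Node pairs carrying the score effect: 2-column
#'   matrix/data frame or list of pairs.
#' @param effect_slope FA units per standard deviation of the score (beta);
#'   negative values emulate the DRS direction (higher FA, lower disability).
#' @param baseline_fa Baseline bundle FA in \[0, 1\] (scalar, or one value per
#'   atlas edge).
#' @param noise_sd Voxel-level i.i.d. Gaussian noise, FA units. Edge noise
#'   then shrinks with bundle size.
#' @param edge_noise_sd Optional bundle-level (shared across the bundle's
#'   voxels) noise, FA units.
#' @param nuisance_slopes Named vector: FA units per SD of age, per unit of
#'   sex (0 = female, 1 = male), per SD of the latent acquisition factor.
#' @param score_name Which clinical scale the planted score emulates;
#'   `"DRS"` (0-29) or `"CRSR"` (0-23).
#' @param score_range Integer bounds for the simulated score.
#' @param background_fa FA painted outside every bundle.
#' @param qc_fail_fraction Fraction of subjects planted to fail the
#'   [qc_screen()] rule.
#' @param seed RNG seed.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_subjects = 40,
                          planted_edges,
                          effect_slope = -0.05,
                          baseline_fa = 0.5,
                          noise_sd = 0.02,
                          edge_noise_sd = 0,
                          nuisance_slopes = c(age = -0.01, sex = 0.005,
                                              acq = 0.005),
                          score_name = c("DRS", "CRSR"),
                          score_range = NULL,
                          background_fa = 0.25,
                          qc_fail_fraction = 0,
                          seed = 1) {
  score_name <- match.arg(score_name)
  if (is.null(score_range)) {
    score_range <- if (score_name == "DRS") c(0L, 29L) else c(0L, 23L)
  }
  if (is.list(planted_edges) && !is.data.frame(planted_edges)) {
    planted_edges <- do.call(rbind, planted_edges)
  }
  planted_edges <- as.matrix(planted_edges)
  stopifnot(ncol(planted_edges) == 2, n_subjects >= 7,
            baseline_fa >= 0, baseline_fa <= 1, noise_sd >= 0,
            qc_fail_fraction >= 0, qc_fail_fraction <= 1)
  structure(list(n_subjects = as.integer(n_subjects),
                 planted_edges = cbind(pmin(planted_edges[, 1],
                                            planted_edges[, 2]),
                                       pmax(planted_edges[, 1],
                                            planted_edges[, 2])),
                 effect_slope = effect_slope, baseline_fa = baseline_fa,
                 noise_sd = noise_sd, edge_noise_sd = edge_noise_sd,
                 nuisance_slopes = nuisance_slopes, score_name = score_name,
                 score_range = as.integer(score_range),
                 background_fa = background_fa,
                 qc_fail_fraction = qc_fail_fraction, seed = seed),
            class = "cohort_config")
}

#' Simulate a cohort of FA volumes with a planted subnetwork effect
#'
#' Forward model of the edge-level regression the pipeline estimates: for
#' subject i and atlas edge e, the painted bundle FA is
#' `baseline + planted(e) * beta * z(score_i) + a_age*z(age_i) + a_sex*sex_i
#' + a_acq*f_i (+ edge noise)`, painted uniformly over all of the bundle's
#' voxels, after which i.i.d. Gaussian voxel noise is added and the volume is
#' clipped to \[0, 1\]. Painting uniformly makes the bundle-mean edge value
#' exactly the painted value, so with zero noise the built connectomes equal
#' the ground truth on retained edges.
#'
#' The cohort table emulates the clinical/demographic structure of an acute
#' neurorehabilitation cohort (age, sex, aetiology, admission diagnosis,
#' discharge DRS/CRS-R, scan intervals), four correlated acquisition
#' parameters driven by a one-factor latent model (TR, TE, number of
#' diffusion directions, interslice gap), and the three QC metrics.
#'
#' @param atlas A [bundle_atlas()], typically from [make_toy_atlas()].
#' @param config A [cohort_config()]; every planted edge must be an atlas
#'   edge.
#' @return List with `fa` (list of 3-D arrays, one per subject), `cohort`
#'   (data frame of subject records), and `truth` (planted edges, the
#'   edge-by-subject matrix of painted bundle FA, the score vector, the
#'   covariate table including the latent acquisition factor, and the config).
#' @export
simulate_cohort <- function(atlas, config) {
  stopifnot(inherits(atlas, "bundle_atlas"), inherits(config, "cohort_config"))
  edge_keys <- .edge_key(atlas$edges$node_a, atlas$edges$node_b)
  planted_keys <- .edge_key(config$planted_edges[, 1],
                            config$planted_edges[, 2])
  missing_e <- setdiff(planted_keys, edge_keys)
  if (length(missing_e)) {
    stop("planted edge(s) absent from the atlas: ",
         paste(missing_e, collapse = ", "), call. = FALSE)
  }
  n <- config$n_subjects
  n_edges <- nrow(atlas$edges)
  baseline <- rep(config$baseline_fa, length.out = n_edges)
  .with_seed(config$seed, {
    # --- clinical and demographic covariates -------------------------------
    score <- sample(seq.int(config$score_range[1], config$score_range[2]),
                    n, replace = TRUE)
    age <- rnorm(n, 53.5, 16.4)
    while (any(bad <- age < 16 | age > 84)) {
      age[bad] <- rnorm(sum(bad), 53.5, 16.4)
    }
    age <- round(age)
    sex <- rbinom(n, 1, 0.6)           # 0 = female, 1 = male
    etiology <- sample(c("CVA", "TBI", "ANOX", "ENC", "LEUCO"), n,
                       replace = TRUE, prob = c(18, 15, 4, 2, 1) / 40)
    diagnosis <- sample(c("COMA", "VS/UWS", "MCS"), n, replace = TRUE,
                        prob = c(13, 16, 11) / 40)
    int1 <- pmax(1L, round(rlnorm(n, log(29.5), 0.6)))
    int2 <- pmax(1L, round(rlnorm(n, log(27), 0.6)))
    if (config$score_name == "DRS") {
      drs <- score
      crsr <- pmin(23L, pmax(0L, round(23 * (1 - drs / 29) + rnorm(n, 0, 2))))
    } else {
      crsr <- score
      drs <- pmin(29L, pmax(0L, round(29 * (1 - crsr / 23) + rnorm(n, 0, 2))))
    }
    # --- acquisition parameters: one-factor latent model -------------------
    f <- rnorm(n)
    tr_ms <- round(6700 + 1400 * f + rnorm(n, 0, 350))
    te_ms <- round(78 + 11 * f + rnorm(n, 0, 2.5), 1)
    n_directions <- as.integer(pmin(30, pmax(18, round(24 + 3 * f +
                                                         rnorm(n, 0, 0.8)))))
    gap_mm <- round(2.45 + 0.42 * f + rnorm(n, 0, 0.1), 2)
    qc <- simulate_qc_metrics(n, config$qc_fail_fraction, seed = NULL)

    # --- painted edge values (the ground truth) ----------------------------
    zscore <- (score - mean(score)) / sd(score)
    zage <- (age - mean(age)) / sd(age)
    sl <- config$nuisance_slopes
    subject_shift <- sl[["age"]] * zage + sl[["sex"]] * sex + sl[["acq"]] * f
    planted <- edge_keys %in% planted_keys
    edge_fa <- outer(baseline, rep(1, n)) +
      outer(ifelse(planted, config$effect_slope, 0), zscore) +
      outer(rep(1, n_edges), subject_shift)
    if (config$edge_noise_sd > 0) {
      edge_fa <- edge_fa + matrix(rnorm(n_edges * n, 0, config$edge_noise_sd),
                                  n_edges, n)
    }
    rownames(edge_fa) <- edge_keys

    # --- paint volumes -----------------------------------------------------
    shape <- atlas$grid$shape
    lin_idx <- lapply(edge_keys, function(k) {
      v <- atlas$bundles[[k]]$voxels
      (v[, 3] - 1) * shape[1] * shape[2] + (v[, 2] - 1) * shape[1] + v[, 1]
    })
    fa <- vector("list", n)
    for (i in seq_len(n)) {
      vol <- array(config$background_fa, shape)
      for (e in seq_len(n_edges)) vol[lin_idx[[e]]] <- edge_fa[e, i]
      if (config$noise_sd > 0) {
        vol <- vol + array(rnorm(prod(shape), 0, config$noise_sd), shape)
      }
      fa[[i]] <- pmin(pmax(vol, 0), 1)   # clip; argument order keeps dims
    }

    cohort <- data.frame(
      subject_id = sprintf("S%02d", seq_len(n)),
      sex = ifelse(sex == 1, "m", "f"),
      age = age,
      interval_injury_mri = int1,
      interval_mri_discharge = int2,
      etiology = etiology,
      diagnosis_admission = diagnosis,
      drs_discharge = drs,
      crsr_discharge = crsr,
      tr_ms = tr_ms, te_ms = te_ms, n_directions = n_directions,
      gap_mm = gap_mm,
      avg_abs_motion = qc$avg_abs_motion,
      avg_rel_motion = qc$avg_rel_motion,
      outlier_pct = qc$outlier_pct)

    list(fa = fa,
         cohort = cohort,
         truth = list(planted_edges = config$planted_edges,
                      edge_fa = edge_fa,
                      score = score,
                      covariates = data.frame(age = age, sex = sex,
                                              acq_factor = f),
                      config = config))
  })
}

#' Write a simulated cohort to disk
#'
#' FA volumes as NIfTI-1 (`.nii.gz`, double precision, atlas grid), the
#' cohort table as TSV, and the ground truth as JSON.
#'
#' @param sim Result of [simulate_cohort()].
#' @param atlas The atlas the cohort was simulated on.
#' @param path Output directory.
#' @return `path`, invisibly.
#' @export
write_cohort_data <- function(sim, atlas, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(sim$fa)) {
    img <- RNifti::asNifti(sim$fa[[i]])
    RNifti::pixdim(img) <- atlas$grid$pixdim
    RNifti::writeNifti(img, file.path(path, sprintf("%s_fa.nii.gz",
                                                    sim$cohort$subject_id[i])),
                       datatype = "double")
  }
  write.table(sim$cohort, file.path(path, "cohort.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth <- sim$truth
  truth$edge_fa <- as.data.frame(truth$edge_fa)
  truth$config <- unclass(truth$config)
  truth$config$planted_edges <- NULL
  jsonlite::write_json(truth, file.path(path, "ground_truth.json"),
                       digits = NA, dataframe = "columns")
  invisible(path)
}

#' Simulate diffusion-weighted signals from a known tensor
#'
#' Forward model `S = S0 * exp(-b g' D g)` with optional additive Gaussian
#' noise.
#'
#' @param tensor 3 x 3 symmetric positive-semidefinite tensor (mm^2/s).
#' @param bvals b-values in s/mm^2.
#' @param bvecs m x 3 directions; unit vectors where `bvals > 0`.
#' @param s0 Non-diffusion-weighted signal.
#' @param noise_sd Additive Gaussian noise SD, signal units.
#' @param seed RNG seed for the noise.
#' @return Signal vector, one value per gradient.
#' @export
#' @examples
#' g <- rbind(c(0, 0, 0), c(1, 0, 0))
#' simulate_dwi_signals(diag(c(2, 1, 1)) * 1e-3, c(0, 1000), g)  # 1, exp(-2)
simulate_dwi_signals <- function(tensor, bvals, bvecs, s0 = 1, noise_sd = 0,
                                 seed = NULL) {
  bvecs <- .check_gradients(bvals, bvecs)
  stopifnot(is.matrix(tensor), identical(dim(tensor), c(3L, 3L)),
            isTRUE(all.equal(tensor, t(tensor))), s0 > 0, noise_sd >= 0)
  ev <- eigen(tensor, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < -1e-12)) {
    stop("tensor must be positive semidefinite", call. = FALSE)
  }
  quad <- rowSums((bvecs %*% tensor) * bvecs)
  s <- s0 * exp(-bvals * quad)
  if (noise_sd > 0) {
    s <- .with_seed(seed, s + rnorm(length(s), 0, noise_sd))
  }
  s
}

#' A reproducible diffusion gradient table
#'
#' Quasi-uniform unit directions (normalised Gaussian draws under a fixed
#' seed) at a single shell, preceded by `n_b0` b = 0 measurements.
#'
#' @param n_directions Number of diffusion-weighted directions.
#' @param n_b0 Number of b = 0 measurements.
#' @param bval Shell b-value, s/mm^2.
#' @param seed RNG seed.
#' @return List with `bvals` and `bvecs` (zero rows for b = 0).
#' @export
gradient_scheme <- function(n_directions = 30, n_b0 = 1, bval = 1000,
                            seed = 42) {
  stopifnot(n_directions >= 1, n_b0 >= 0)
  .with_seed(seed, {
    g <- matrix(rnorm(3 * n_directions), ncol = 3)
    g <- g / sqrt(rowSums(g^2))
    list(bvals = c(rep(0, n_b0), rep(bval, n_directions)),
         bvecs = rbind(matrix(0, n_b0, 3), g))
  })
}

#' Simulate quality-control metric tables
#'
#' Generates the three automated QC metrics (average absolute motion, average
#' relative motion, outlier percentage). A planted fraction of subjects is
#' pushed over at least two thresholds so [qc_screen()] excludes exactly the
#' planted failures; the planted labels are attached as attribute
#' `planted_fail`.
#'
#' @param n_subjects Number of subjects.
#' @param fail_fraction Fraction of subjects planted to fail (0 to 1).
#' @param seed RNG seed (`NULL` to draw from the current RNG state).
#' @return Data frame with the three metric columns and attribute
#'   `planted_fail`.
#' @export
simulate_qc_metrics <- function(n_subjects, fail_fraction = 0, seed = 1) {
  stopifnot(n_subjects >= 1, fail_fraction >= 0, fail_fraction <= 1)
  .with_seed(seed, {
    n_fail <- round(fail_fraction * n_subjects)
    fail <- rep(FALSE, n_subjects)
    if (n_fail > 0) fail[sample.int(n_subjects, n_fail)] <- TRUE
    abs_m <- runif(n_subjects, 0.1, 1.5)
    rel_m <- runif(n_subjects, 0.05, 0.4)
    out_p <- runif(n_subjects, 0, 1.5)
    for (i in which(fail)) {
      over <- sample(3, sample(2:3, 1))   # push 2 or 3 metrics over
      if (1 %in% over) abs_m[i] <- runif(1, 2, 4)
      if (2 %in% over) rel_m[i] <- runif(1, 0.5, 1.2)
      if (3 %in% over) out_p[i] <- runif(1, 2, 8)
    }
    qc <- data.frame(avg_abs_motion = round(abs_m, 3),
                     avg_rel_motion = round(rel_m, 3),
                     outlier_pct = round(out_p, 3))
    attr(qc, "planted_fail") <- fail
    qc
  })
}
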