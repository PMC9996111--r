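# Independent oracles and shared fixtures for the test suite. The oracles are
# deliberately naive (depth-first search, full permutation enumeration,
# closed forms) and share no code with the implementation they check.

# brute-force connected components by iterative depth-first search;
# returns a list of sorted node vectors, one per component
oracle_components <- function(edges) {
  nodes <- unique(c(edges$node_a, edges$node_b))
  key <- as.character(nodes)
  adj <- lapply(nodes, function(v) {
    unique(c(edges$node_b[edges$node_a == v],
             edges$node_a[edges$node_b == v]))
  })
  names(adj) <- key
  seen <- stats::setNames(rep(FALSE, length(nodes)), key)
  comps <- list()
  for (v in nodes) {
    if (seen[[as.character(v)]]) next
    frontier <- list(v)
    members <- c()
    while (length(frontier)) {
      u <- frontier[[length(frontier)]]
      frontier[[length(frontier)]] <- NULL
      cu <- as.character(u)
      if (seen[[cu]]) next
      seen[[cu]] <- TRUE
      members <- c(members, u)
      for (w in adj[[cu]]) {
        if (!seen[[as.character(w)]]) frontier <- c(frontier, w)
      }
    }
    comps[[length(comps) + 1L]] <- sort(members)
  }
  comps
}

# canonical form of a component list for set comparison
canonical_partition <- function(comps) {
  out <- lapply(comps, function(x) sort(as.character(x)))
  out[order(vapply(out, paste, character(1), collapse = "|"))]
}

# all permutations of 1:n (n! x n matrix), by recursion
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  p <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, p + (p >= k))
  }))
}

# closed-form FA, written independently of the package implementation
oracle_fa <- function(l1, l2, l3) {
  sqrt(0.5) * sqrt(((l1 - l2)^2 + (l2 - l3)^2 + (l3 - l1)^2) /
                     (l1^2 + l2^2 + l3^2))
}

# random symmetric positive-definite diffusion tensor (units ~1e-3 mm^2/s)
random_spd_tensor <- function() {
  q <- qr.Q(qr(matrix(rnorm(9), 3)))
  q %*% diag(runif(3, 0.2, 2.5) * 1e-3) %*% t(q)
}

# a tiny two-node atlas with one bundle, for hand-computed cases
mini_atlas <- function(probs = c(1, 0.95, 0.5), presence = 0.9) {
  vox <- cbind(1:length(probs), 1L, 1L)
  bundle_atlas(
    nodes = data.frame(id = 0:1, name = c("A", "B"), hemisphere = "L",
                       x = c(0, 4), y = 0, z = 0),
    edges = data.frame(node_a = 0L, node_b = 1L, presence = presence),
    bundles = list("0-1" = list(
      voxels = matrix(as.integer(vox), ncol = 3), prob = probs)),
    grid = list(shape = c(max(4L, length(probs)), 4L, 2L),
                pixdim = c(1, 1, 1), affine = diag(4)))
}

# shared small synthetic dataset: toy atlas + cohort with a planted 6-edge
# path, built once per test run
planted_path_edges <- cbind(0:5, 1:6)

make_test_dataset <- function(n_subjects = 40, effect_slope = -0.05,
                              noise_sd = 0.02, nuisance = TRUE, seed = 3,
                              atlas_seed = 7) {
  atlas <- make_toy_atlas(12, c(24, 24, 24), seed = atlas_seed)
  cfg <- cohort_config(
    n_subjects = n_subjects, planted_edges = planted_path_edges,
    effect_slope = effect_slope, noise_sd = noise_sd,
    nuisance_slopes = if (nuisance) c(age = -0.01, sex = 0.005, acq = 0.005)
    else c(age = 0, sex = 0, acq = 0),
    seed = seed)
  sim <- simulate_cohort(atlas, cfg)
  list(atlas = atlas, cfg = cfg, sim = sim)
}

stack_from_sim <- function(atlas, sim) {
  cons <- lapply(seq_along(sim$fa), function(i) {
    build_connectome(sim$fa[[i]], atlas,
                     subject_id = sim$cohort$subject_id[i])
  })
  stack_cohort(cons)
}
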