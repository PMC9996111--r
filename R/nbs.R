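# Network-Based Statistics: edge-wise GLM contrast t-statistics,
# suprathreshold connected components, and family-wise-error-corrected
# component p-values from a Freedman-Lane permutation null of maximal
# component size.

# connected components of an undirected edge list (union-find with path
# halving); node labels may be integers or strings
.graph_components <- function(a, b) {
  nodes <- unique(c(a, b))
  parent <- seq_along(nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ia <- match(a, nodes); ib <- match(b, nodes)
  for (k in seq_along(ia)) {
    ra <- find(ia[k]); rb <- find(ib[k])
    if (ra != rb) parent[ra] <- rb
  }
  roots <- vapply(seq_along(nodes), find, integer(1))
  comp_of_node <- match(roots, unique(roots))
  list(nodes = nodes, node_comp = comp_of_node, edge_comp = comp_of_node[ia])
}

# largest suprathreshold component size (edge count); returns 0 when empty
.max_component_size <- function(tstats, edges_a, edges_b, t_threshold, sign,
                                sidedness) {
  supra <- .suprathreshold(tstats, t_threshold, sign, sidedness)
  if (!any(supra)) return(0L)
  comp <- .graph_components(edges_a[supra], edges_b[supra])
  max(tabulate(comp$edge_comp))
}

.suprathreshold <- function(tstats, t_threshold, sign, sidedness) {
  ok <- is.finite(tstats)
  if (sidedness == "two") {
    ok & abs(tstats) >= t_threshold
  } else if (sign == "negative") {
    ok & tstats <= -t_threshold
  } else {
    ok & tstats >= t_threshold
  }
}

#' Edge-wise GLM contrast t-statistics
#'
#' Every edge of the cohort stack is tested univariately: the edge values are
#' regressed on the design by OLS and the contrast t-statistic
#' `t = c'b / sqrt(s2 * c'(X'X)^-1 c)` computed, with
#' `s2 = RSS / (n - rank)`. Edges with zero residual variance (degenerate
#' noiseless synthetic data) get signed infinite t with a warning.
#'
#' @param stack A `connectome_stack` from [stack_cohort()], or a plain
#'   subject-by-edge numeric matrix.
#' @param design An [nbs_design()].
#' @return List with `t` (named per edge), `df`, and `contrast_estimate`.
#' @export
edge_glm_tstats <- function(stack, design) {
  Y <- if (inherits(stack, "connectome_stack")) stack$x else as.matrix(stack)
  stopifnot(inherits(design, "nbs_design"), all(is.finite(Y)))
  X <- design$X
  if (nrow(Y) != nrow(X)) {
    stop("stack and design disagree in number of subjects", call. = FALSE)
  }
  cvec <- design$contrast
  xtx_inv <- chol2inv(chol(crossprod(X)))
  beta <- xtx_inv %*% crossprod(X, Y)
  res <- Y - X %*% beta
  rss <- colSums(res^2)
  df <- design$df_residual
  cxc <- drop(t(cvec) %*% xtx_inv %*% cvec)
  est <- drop(cvec %*% beta)
  tt <- est / sqrt(rss / df * cxc)
  degenerate <- rss <= .Machine$double.eps * nrow(Y) * colSums(Y^2)
  if (any(degenerate)) {
    tt[degenerate] <- sign(est[degenerate]) * Inf
    warning(sum(degenerate), " edge(s) with zero residual variance; ",
            "t set to signed infinity", call. = FALSE)
  }
  names(tt) <- colnames(Y)
  list(t = tt, df = df, contrast_estimate = est)
}

#' Student-t tail probability for a contrast statistic
#'
#' @param t t-statistic.
#' @param df Degrees of freedom (>= 1).
#' @param sidedness `"two"` (default; tail probability doubled) or `"one"`.
#' @return p-value.
#' @export
#' @examples
#' t_to_p(3.5, 39)  # ~0.00117, i.e. 0.001 at 3 decimals
t_to_p <- function(t, df, sidedness = c("two", "one")) {
  sidedness <- match.arg(sidedness)
  if (any(df < 1)) stop("df must be >= 1", call. = FALSE)
  if (sidedness == "two") 2 * pt(-abs(t), df) else pt(-abs(t), df)
}

#' Suprathreshold connected components
#'
#' Forms the graph of edges whose t-statistic meets the primary threshold
#' (inclusive: a tie at the threshold is suprathreshold) and returns its
#' connected components. Component size is the edge count (the NBS "extent").
#' Non-finite t-statistics are excluded from the graph.
#'
#' @param tstats t-statistic per edge.
#' @param edges Data frame with `node_a`, `node_b` (one row per statistic);
#'   node labels may be ids or names.
#' @param t_threshold Primary threshold (> 0).
#' @param sign `"positive"` (t >= threshold) or `"negative"`
#'   (t <= -threshold); ignored when `sidedness = "two"`.
#' @param sidedness `"one"` or `"two"` (|t| >= threshold).
#' @return List of components, largest first; each has `nodes` (sorted),
#'   `edges` (with t), `n_nodes`, `n_edges`.
#' @export
threshold_components <- function(tstats, edges, t_threshold,
                                 sign = c("positive", "negative"),
                                 sidedness = c("one", "two")) {
  sign <- match.arg(sign)
  sidedness <- match.arg(sidedness)
  stopifnot(t_threshold > 0, nrow(edges) == length(tstats))
  supra <- .suprathreshold(tstats, t_threshold, sign, sidedness)
  if (!any(supra)) return(list())
  ea <- edges$node_a[supra]; eb <- edges$node_b[supra]
  et <- tstats[supra]
  comp <- .graph_components(ea, eb)
  sizes <- tabulate(comp$edge_comp)
  ord <- order(-sizes)
  lapply(ord, function(ci) {
    sel <- comp$edge_comp == ci
    ed <- data.frame(node_a = ea[sel], node_b = eb[sel], t = unname(et[sel]))
    ed <- ed[order(ed$node_a, ed$node_b), , drop = FALSE]
    rownames(ed) <- NULL
    list(nodes = sort(comp$nodes[comp$node_comp == ci]),
         edges = ed,
         n_nodes = sum(comp$node_comp == ci),
         n_edges = sizes[ci])
  })
}

#' Network-Based Statistics with permutation FWER control
#'
#' Runs the full NBS inference on a cohort stack: edge-wise contrast
#' t-statistics, suprathreshold components of the observed data, and a null
#' distribution of the maximal component size built by Freedman-Lane
#' permutation — the reduced (nuisance-only) model is fitted, its residuals
#' are permuted with a seeded RNG and recombined with the nuisance fit, and
#' the full-model t-statistics and maximal component size recomputed for each
#' permutation. Each observed component's family-wise-error-corrected p-value
#' is `(1 + #{null max size >= observed size}) / (1 + n_permutations)` (the
#' +1 correction keeps p valid and nonzero); the null comparison uses `>=`
#' (conservative). Edges with non-finite t are excluded from the
#' suprathreshold graph rather than crashing the permutation loop.
#'
#' @param stack A `connectome_stack` or subject-by-edge matrix.
#' @param design An [nbs_design()].
#' @param t_threshold Primary component-forming threshold (default 3.5).
#' @param n_permutations Number of permutations (default 10000).
#' @param alpha FWER level for flagging significance (default 0.05).
#' @param sidedness `"one"` (default; the contrast is directed) or `"two"`.
#' @param seed RNG seed for the permutation sampler. Permutations are drawn
#'   independently without deduplication.
#' @return An `nbs_result`: `tstats`, `df`, `components` (each with FWER `p`
#'   and `significant` flag), `null_max_size`, `edges`, `config`.
#' @export
nbs_fwer <- function(stack, design, t_threshold = 3.5, n_permutations = 10000,
                     alpha = 0.05, sidedness = c("one", "two"), seed = NULL) {
  sidedness <- match.arg(sidedness)
  stopifnot(t_threshold > 0, alpha > 0, alpha < 1)
  if (n_permutations < 1) stop("n_permutations must be >= 1", call. = FALSE)
  Y <- if (inherits(stack, "connectome_stack")) stack$x else as.matrix(stack)
  edges <- if (inherits(stack, "connectome_stack")) {
    stack$edges
  } else if (!is.null(colnames(Y))) {
    key <- strsplit(colnames(Y), "-", fixed = TRUE)
    data.frame(node_a = vapply(key, `[`, character(1), 1),
               node_b = vapply(key, `[`, character(1), 2))
  } else {
    stop("stack must carry an edge index (connectome_stack or named columns)",
         call. = FALSE)
  }
  if (ncol(Y) == 0L) stop("no valid edges in the stack", call. = FALSE)
  # the contrast is directed, so a one-sided test always looks at t >= thr
  sign <- "positive"

  obs <- suppressWarnings(edge_glm_tstats(Y, design))
  components <- threshold_components(obs$t, edges, t_threshold,
                                     sign = sign, sidedness = sidedness)

  X <- design$X
  cvec <- design$contrast
  n <- nrow(Y)
  xtx_inv <- chol2inv(chol(crossprod(X)))
  cxc <- drop(t(cvec) %*% xtx_inv %*% cvec)
  w <- drop(t(cvec) %*% xtx_inv %*% t(X))        # t numerator weights (1 x n)
  M <- diag(n) - X %*% xtx_inv %*% t(X)          # residual maker
  df <- design$df_residual
  # reduced (nuisance-only) model for Freedman-Lane
  nuis <- which(cvec == 0)
  if (length(nuis)) {
    Z <- X[, nuis, drop = FALSE]
    Zg <- Z %*% qr.coef(qr(Z), Y)
    Zg[is.na(Zg)] <- 0
  } else {
    Zg <- matrix(0, n, ncol(Y))                  # no nuisance: permute raw data
  }
  Rz <- Y - Zg

  ea <- edges$node_a; eb <- edges$node_b
  null_max <- .with_seed(seed, {
    vapply(seq_len(n_permutations), function(p) {
      perm <- sample.int(n)
      Ys <- Zg + Rz[perm, , drop = FALSE]
      num <- drop(w %*% Ys)
      rss <- colSums((M %*% Ys)^2)
      tt <- num / sqrt(rss / df * cxc)
      .max_component_size(tt, ea, eb, t_threshold, sign, sidedness)
    }, integer(1))
  })

  for (i in seq_along(components)) {
    s <- components[[i]]$n_edges
    p <- (1 + sum(null_max >= s)) / (1 + n_permutations)
    components[[i]]$p <- p
    components[[i]]$significant <- p <= alpha
  }
  structure(list(tstats = obs$t, df = df, components = components,
                 null_max_size = null_max, edges = edges,
                 config = list(t_threshold = t_threshold,
                               n_permutations = n_permutations,
                               alpha = alpha, sidedness = sidedness,
                               seed = seed)),
            class = "nbs_result")
}

#' @export
print.nbs_result <- function(x, ...) {
  cat(sprintf("NBS at t >= %.2f (%s-sided, %d permutations, df = %d)\n",
              x$config$t_threshold, x$config$sidedness,
              x$config$n_permutations, x$df))
  if (!length(x$components)) {
    cat("No suprathreshold connections were found.\n")
  } else {
    for (i in seq_along(x$components)) {
      cm <- x$components[[i]]
      cat(sprintf("  component %d: %d nodes, %d edges, FWER p = %.4g%s\n",
                  i, cm$n_nodes, cm$n_edges, cm$p,
                  if (cm$significant) " *" else ""))
    }
  }
  invisible(x)
}

#' NBS across a sweep of primary thresholds
#'
#' The component-forming threshold trades off extent against focality and
#' has no standard value, so the subnetwork extent is assessed across
#' several thresholds. All runs share the permutation seed.
#'
#' @inheritParams nbs_fwer
#' @param thresholds Positive thresholds, sorted ascending.
#' @return Named list of `nbs_result`, one per threshold.
#' @export
threshold_sweep <- function(stack, design, thresholds = c(3.3, 3.5, 3.7),
                            n_permutations = 10000, alpha = 0.05,
                            sidedness = c("one", "two"), seed = NULL) {
  stopifnot(all(thresholds > 0), !is.unsorted(thresholds))
  sidedness <- match.arg(sidedness)
  out <- lapply(thresholds, function(th) {
    nbs_fwer(stack, design, t_threshold = th,
             n_permutations = n_permutations, alpha = alpha,
             sidedness = sidedness, seed = seed)
  })
  names(out) <- sprintf("t=%.2f", thresholds)
  out
}
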