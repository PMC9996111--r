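# Per-subject structural connectomes: bundle-mean FA over the atlas's
# consistent voxels, and the cohort stack that group analysis operates on.

#' Mean FA of one bundle
#'
#' Unweighted arithmetic mean of the FA volume over the edge's consistent
#' voxels ([consistent_voxels()]). Voxels are summed in sorted linear-index
#' order, so the value does not depend on voxel enumeration order even in
#' floating point. An empty consistent-voxel set yields `NA` (the invalid
#' marker).
#'
#' @param fa 3-D FA array on the atlas grid.
#' @param atlas A [bundle_atlas()].
#' @param edge Edge as `c(a, b)` or `"a-b"`.
#' @param occupancy_threshold Voxel consistency cut-off (see
#'   [consistent_voxels()]).
#' @return Mean FA, or `NA` if no voxel survives the filter.
#' @export
edge_mean_fa <- function(fa, atlas, edge, occupancy_threshold = 0.9) {
  if (!isTRUE(all.equal(as.integer(dim(fa)),
                        as.integer(atlas$grid$shape)))) {
    stop("FA volume grid ", paste(dim(fa), collapse = "x"),
         " does not match the atlas grid ",
         paste(atlas$grid$shape, collapse = "x"), call. = FALSE)
  }
  vox <- consistent_voxels(atlas, edge, occupancy_threshold)
  if (nrow(vox) == 0L) return(NA_real_)
  mean(fa[vox])
}

#' Build a structural connectome from an FA volume
#'
#' Projects a subject's FA map onto the atlas: for every edge retained by the
#' population presence filter, the connectivity strength is the bundle-mean
#' FA over the consistent voxels. Edges dropped by the presence filter, and
#' retained edges whose consistent voxel set is empty, are invalid (`NA` in
#' the matrix, `FALSE` in the mask).
#'
#' @param fa 3-D FA array on the atlas grid.
#' @param atlas A [bundle_atlas()].
#' @param presence_threshold Edge consistency cut-off ([consistent_edges()]).
#' @param occupancy_threshold Voxel consistency cut-off
#'   ([consistent_voxels()]).
#' @param subject_id Optional subject label.
#' @return A `connectome`: symmetric N x N `matrix` of bundle-mean FA with
#'   `NA` on invalid entries and the diagonal, logical `valid` mask, `nodes`
#'   table, `subject_id`.
#' @export
build_connectome <- function(fa, atlas, presence_threshold = 0.8,
                             occupancy_threshold = 0.9, subject_id = NULL) {
  n <- nrow(atlas$nodes)
  m <- matrix(NA_real_, n, n,
              dimnames = list(atlas$nodes$id, atlas$nodes$id))
  valid <- matrix(FALSE, n, n, dimnames = dimnames(m))
  kept <- consistent_edges(atlas, presence_threshold)
  for (i in seq_len(nrow(kept))) {
    a <- kept$node_a[i]; b <- kept$node_b[i]
    v <- edge_mean_fa(fa, atlas, c(a, b), occupancy_threshold)
    if (!is.na(v)) {
      if (v < 0 || v > 1) {
        stop("bundle-mean FA outside [0, 1] on edge ", .edge_key(a, b),
             call. = FALSE)
      }
      m[a + 1, b + 1] <- m[b + 1, a + 1] <- v
      valid[a + 1, b + 1] <- valid[b + 1, a + 1] <- TRUE
    }
  }
  structure(list(matrix = m, valid = valid, nodes = atlas$nodes,
                 subject_id = subject_id),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("Connectome%s: %d nodes, %d valid edges\n",
              if (is.null(x$subject_id)) "" else paste0(" ", x$subject_id),
              nrow(x$matrix), sum(x$valid[upper.tri(x$valid)])))
  invisible(x)
}

#' Write a connectome as TSV
#'
#' The N x N matrix (tab-separated, node labels as header row and column)
#' plus a sibling `*_valid.tsv` mask.
#'
#' @param x A `connectome`.
#' @param path Output file path for the matrix TSV.
#' @return `path`, invisibly.
#' @export
write_connectome <- function(x, path) {
  stopifnot(inherits(x, "connectome"))
  write.table(x$matrix, path, sep = "\t", quote = FALSE, col.names = NA)
  write.table(x$valid * 1L, sub("\\.tsv$", "_valid.tsv", path), sep = "\t",
              quote = FALSE, col.names = NA)
  invisible(path)
}

#' Stack per-subject connectomes into a cohort matrix
#'
#' Vectorises the upper triangle (row-major: (0,1), (0,2), ..., (1,2), ...)
#' of each connectome into one subject-by-edge matrix. An edge enters the
#' stack only if it is valid in every subject (complete-case at the edge
#' level); with a shared atlas and grid the per-subject masks coincide
#' anyway.
#'
#' @param connectomes List of `connectome` objects sharing one parcellation.
#' @return A `connectome_stack`: `x` (subjects x edges matrix, columns named
#'   `"a-b"`), `edges` (node pair table in vectorisation order), `nodes`,
#'   `subject_ids`.
#' @export
stack_cohort <- function(connectomes) {
  stopifnot(length(connectomes) >= 1,
            all(vapply(connectomes, inherits, logical(1), "connectome")))
  nodes <- connectomes[[1]]$nodes
  for (cn in connectomes) {
    if (!identical(cn$nodes$id, nodes$id)) {
      stop("connectomes use different parcellations", call. = FALSE)
    }
  }
  n <- nrow(nodes)
  shared <- Reduce(`&`, lapply(connectomes, `[[`, "valid"))
  ut <- which(upper.tri(shared), arr.ind = TRUE)
  ut <- ut[order(ut[, 1], ut[, 2]), , drop = FALSE]   # row-major upper triangle
  keep <- shared[ut]
  ut <- ut[keep, , drop = FALSE]
  edges <- data.frame(node_a = nodes$id[ut[, 1]], node_b = nodes$id[ut[, 2]])
  x <- t(vapply(connectomes, function(cn) cn$matrix[ut],
                numeric(nrow(ut))))
  if (nrow(ut) == 1L) x <- matrix(x, ncol = 1L)
  colnames(x) <- .edge_key(edges$node_a, edges$node_b)
  ids <- vapply(seq_along(connectomes), function(i) {
    id <- connectomes[[i]]$subject_id
    if (is.null(id)) sprintf("S%02d", i) else as.character(id)
  }, character(1))
  rownames(x) <- ids
  structure(list(x = x, edges = edges, nodes = nodes, subject_ids = ids),
            class = "connectome_stack")
}

#' @export
print.connectome_stack <- function(x, ...) {
  cat(sprintf("Connectome stack: %d subjects x %d edges (%d nodes)\n",
              nrow(x$x), ncol(x$x), nrow(x$nodes)))
  invisible(x)
}

#' Rebuild one subject's connectome matrix from a stack
#'
#' Inverse of the vectorisation in [stack_cohort()] (restricted to the
#' stacked edges).
#'
#' @param stack A `connectome_stack`.
#' @param subject Row index or subject id.
#' @return Symmetric N x N matrix with `NA` off the stacked edges.
#' @export
unstack_connectome <- function(stack, subject) {
  stopifnot(inherits(stack, "connectome_stack"))
  if (is.character(subject)) subject <- match(subject, stack$subject_ids)
  n <- nrow(stack$nodes)
  m <- matrix(NA_real_, n, n,
              dimnames = list(stack$nodes$id, stack$nodes$id))
  for (i in seq_len(nrow(stack$edges))) {
    a <- stack$edges$node_a[i]; b <- stack$edges$node_b[i]
    m[a + 1, b + 1] <- m[b + 1, a + 1] <- stack$x[subject, i]
  }
  m
}
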