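# Probabilistic bundle atlas: data model, container I/O, consistency filters.
#
# The atlas gives, for every pair of grey-matter parcellation regions (nodes),
# the voxels that the connecting white-matter bundle occupies and how
# consistently it does so across the atlas population: a per-voxel occupancy
# probability in (0, 1] and a per-edge population presence fraction in [0, 1].

.edge_key <- function(a, b) sprintf("%d-%d", pmin(a, b), pmax(a, b))

# normalise an edge given as c(a, b), "a-b", or a 1-row data frame
.as_edge <- function(edge) {
  if (is.data.frame(edge)) edge <- c(edge$node_a[1], edge$node_b[1])
  if (is.character(edge) && length(edge) == 1L) {
    edge <- as.integer(strsplit(edge, "-", fixed = TRUE)[[1]])
  }
  edge <- as.integer(edge)
  if (length(edge) != 2L || anyNA(edge)) {
    stop("an edge must be a pair of node ids", call. = FALSE)
  }
  c(min(edge), max(edge))
}

#' Construct and validate a probabilistic bundle atlas
#'
#' @param nodes Data frame with columns `id` (integer, contiguous from 0),
#'   `name`, `hemisphere`, and representative coordinates `x`, `y`, `z` (mm).
#' @param edges Data frame with columns `node_a`, `node_b` (`node_a < node_b`)
#'   and `presence` (fraction of the atlas population in which the bundle
#'   exists, in \[0, 1\]).
#' @param bundles Named list, one entry per edge keyed `"a-b"`, each a list
#'   with `voxels` (k x 3 integer matrix of 1-based voxel indices) and `prob`
#'   (length-k occupancy probabilities in (0, 1\]).
#' @param grid List with `shape` (3 integers), `pixdim` (voxel size, mm) and
#'   `affine` (4 x 4 voxel-to-world matrix).
#' @return A `bundle_atlas` object.
#' @export
bundle_atlas <- function(nodes, edges, bundles, grid) {
  x <- structure(list(nodes = nodes, edges = edges, bundles = bundles,
                      grid = grid),
                 class = "bundle_atlas")
  validate_bundle_atlas(x)
}

#' @rdname bundle_atlas
#' @param x A `bundle_atlas`.
#' @export
validate_bundle_atlas <- function(x) {
  nodes <- x$nodes; edges <- x$edges
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  ids <- sort(nodes$id)
  if (anyDuplicated(ids) || !identical(as.integer(ids),
                                       seq.int(0L, length(ids) - 1L))) {
    stop("node ids must be unique and contiguous from 0", call. = FALSE)
  }
  if (nrow(edges)) {
    if (any(edges$node_a >= edges$node_b)) {
      stop("edges must satisfy node_a < node_b", call. = FALSE)
    }
    unknown <- setdiff(c(edges$node_a, edges$node_b), nodes$id)
    if (length(unknown)) {
      stop("edge references unknown node id(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    if (any(edges$presence < 0 | edges$presence > 1)) {
      stop("presence fractions must be in [0, 1]", call. = FALSE)
    }
    keys <- .edge_key(edges$node_a, edges$node_b)
    if (!setequal(keys, names(x$bundles)) || anyDuplicated(keys)) {
      stop("bundle list must be keyed by the edge index", call. = FALSE)
    }
    shape <- x$grid$shape
    for (k in keys) {
      b <- x$bundles[[k]]
      if (!is.matrix(b$voxels) || ncol(b$voxels) != 3L) {
        stop("bundle voxels must be a k x 3 index matrix", call. = FALSE)
      }
      if (length(b$prob) != nrow(b$voxels)) {
        stop("bundle ", k, ": one probability per voxel required",
             call. = FALSE)
      }
      if (any(b$prob <= 0 | b$prob > 1)) {
        stop("bundle ", k, ": occupancy probabilities must be in (0, 1]",
             call. = FALSE)
      }
      if (nrow(b$voxels) && (any(b$voxels < 1) ||
                             any(sweep(b$voxels, 2, shape, ">") != 0))) {
        stop("bundle ", k, ": voxel index outside the grid", call. = FALSE)
      }
    }
  }
  invisible(x)
}

#' @export
print.bundle_atlas <- function(x, ...) {
  cat(sprintf("Probabilistic bundle atlas: %d nodes, %d edges, grid %s\n",
              nrow(x$nodes), nrow(x$edges),
              paste(x$grid$shape, collapse = "x")))
  invisible(x)
}

#' Edges retained by the population-presence consistency filter
#'
#' Restricts the atlas to connections present in at least
#' `presence_threshold` of the atlas population (inclusive rule, so an edge at
#' exactly the threshold is retained).
#'
#' @param atlas A [bundle_atlas()].
#' @param presence_threshold Presence fraction cut-off in (0, 1\].
#' @return The subset of `atlas$edges` meeting the threshold.
#' @export
consistent_edges <- function(atlas, presence_threshold = 0.8) {
  stopifnot(inherits(atlas, "bundle_atlas"),
            presence_threshold > 0, presence_threshold <= 1)
  atlas$edges[atlas$edges$presence >= presence_threshold, , drop = FALSE]
}

#' Voxels retained by the occupancy consistency filter
#'
#' Returns the voxels of one bundle that belong to it in at least
#' `occupancy_threshold` of the atlas population (inclusive), sorted by linear
#' grid index so downstream averages are reproducible bit for bit.
#'
#' @inheritParams consistent_edges
#' @param edge Edge as `c(a, b)` or `"a-b"`.
#' @param occupancy_threshold Occupancy probability cut-off in (0, 1\].
#' @return A k x 3 matrix of voxel indices (possibly 0-row).
#' @export
consistent_voxels <- function(atlas, edge, occupancy_threshold = 0.9) {
  stopifnot(inherits(atlas, "bundle_atlas"),
            occupancy_threshold > 0, occupancy_threshold <= 1)
  edge <- .as_edge(edge)
  key <- .edge_key(edge[1], edge[2])
  b <- atlas$bundles[[key]]
  if (is.null(b)) stop("edge ", key, " is not in the atlas", call. = FALSE)
  keep <- b$prob >= occupancy_threshold
  vox <- b$voxels[keep, , drop = FALSE]
  if (nrow(vox) > 1L) {
    shape <- atlas$grid$shape
    lin <- (vox[, 3] - 1) * shape[1] * shape[2] + (vox[, 2] - 1) * shape[1] +
      vox[, 1]
    vox <- vox[order(lin), , drop = FALSE]
  }
  vox
}

#' Write a bundle atlas to its container directory
#'
#' The container holds `nodes.tsv` (id, name, hemisphere, x, y, z),
#' `edges.tsv` (node_a, node_b, presence_fraction) and one NIfTI occupancy
#' probability map per edge (`edge_<a>_<b>.nii.gz`, double precision; zero
#' outside the bundle). Any atlas exported to this layout loads identically.
#'
#' @param atlas A [bundle_atlas()].
#' @param path Directory to create/overwrite into.
#' @return `path`, invisibly.
#' @export
write_bundle_atlas <- function(atlas, path) {
  validate_bundle_atlas(atlas)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write.table(atlas$nodes, file.path(path, "nodes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  edges_out <- data.frame(node_a = atlas$edges$node_a,
                          node_b = atlas$edges$node_b,
                          presence_fraction = atlas$edges$presence)
  write.table(edges_out, file.path(path, "edges.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  for (i in seq_len(nrow(atlas$edges))) {
    a <- atlas$edges$node_a[i]; b <- atlas$edges$node_b[i]
    bun <- atlas$bundles[[.edge_key(a, b)]]
    arr <- array(0, atlas$grid$shape)
    arr[bun$voxels] <- bun$prob
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- atlas$grid$pixdim
    RNifti::writeNifti(img, file.path(path, sprintf("edge_%03d_%03d.nii.gz",
                                                    a, b)),
                       datatype = "double")
  }
  invisible(path)
}

#' Load a bundle atlas from its container directory
#'
#' @param path Directory written by [write_bundle_atlas()] (or a real atlas
#'   exported to the same layout).
#' @return A [bundle_atlas()].
#' @export
load_bundle_atlas <- function(path) {
  nodes <- read.delim(file.path(path, "nodes.tsv"))
  edges_in <- read.delim(file.path(path, "edges.tsv"))
  edges <- data.frame(node_a = as.integer(edges_in$node_a),
                      node_b = as.integer(edges_in$node_b),
                      presence = as.numeric(edges_in$presence_fraction))
  grid <- NULL
  bundles <- list()
  for (i in seq_len(nrow(edges))) {
    a <- edges$node_a[i]; b <- edges$node_b[i]
    f <- file.path(path, sprintf("edge_%03d_%03d.nii.gz", a, b))
    if (!file.exists(f)) stop("missing probability map: ", f, call. = FALSE)
    img <- RNifti::readNifti(f)
    this_grid <- list(shape = dim(img),
                      pixdim = RNifti::pixdim(img),
                      affine = unclass(RNifti::xform(img)))
    if (is.null(grid)) {
      grid <- this_grid
    } else if (!isTRUE(all.equal(grid$shape, this_grid$shape)) ||
               !isTRUE(all.equal(grid$pixdim, this_grid$pixdim))) {
      stop("probability maps do not share a common grid (", f, ")",
           call. = FALSE)
    }
    arr <- as.array(img)
    idx <- which(arr > 0, arr.ind = TRUE)
    bundles[[.edge_key(a, b)]] <- list(
      voxels = matrix(as.integer(idx), ncol = 3,
                      dimnames = list(NULL, c("i", "j", "k"))),
      prob = arr[idx])
  }
  if (is.null(grid)) {
    # an empty edge list is a valid (if useless) atlas; grid is nominal
    grid <- list(shape = c(1L, 1L, 1L), pixdim = c(1, 1, 1),
                 affine = diag(4))
  }
  bundle_atlas(nodes = nodes, edges = edges, bundles = bundles, grid = grid)
}
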