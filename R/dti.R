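# Minimal diffusion-tensor machinery: log-linear OLS tensor fit, fractional
# anisotropy, whole-volume FA maps, and the motion/outlier QC exclusion rule.

# 7-column log-signal design for the second-order tensor model:
# ln S = ln S0 - b g' D g, unknowns (ln S0, Dxx, Dyy, Dzz, Dxy, Dxz, Dyz)
.tensor_design <- function(bvals, bvecs) {
  gx <- bvecs[, 1]; gy <- bvecs[, 2]; gz <- bvecs[, 3]
  cbind(ln_s0 = 1,
        dxx = -bvals * gx^2,
        dyy = -bvals * gy^2,
        dzz = -bvals * gz^2,
        dxy = -2 * bvals * gx * gy,
        dxz = -2 * bvals * gx * gz,
        dyz = -2 * bvals * gy * gz)
}

.check_gradients <- function(bvals, bvecs) {
  bvecs <- as.matrix(bvecs)
  if (ncol(bvecs) != 3L) stop("bvecs must be an m x 3 matrix", call. = FALSE)
  if (length(bvals) != nrow(bvecs)) {
    stop("bvals and bvecs disagree in length", call. = FALSE)
  }
  if (any(bvals < 0)) stop("negative b-value", call. = FALSE)
  dw <- bvals > 0
  if (any(dw)) {
    nrm <- sqrt(rowSums(bvecs[dw, , drop = FALSE]^2))
    if (any(abs(nrm - 1) > 1e-6)) {
      stop("diffusion-weighted gradient directions must be unit vectors",
           call. = FALSE)
    }
  }
  bvecs
}

#' Ordinary least-squares diffusion tensor fit
#'
#' Fits the second-order tensor model by OLS on the log-signal against the
#' seven-column design (`ln S0` plus the six unique tensor components). No
#' weighting and no input clamping: non-positive signals and rank-deficient
#' gradient schemes are errors.
#'
#' @param signals Measured signals, one per gradient (all > 0).
#' @param bvals b-values in s/mm^2 (>= 1 must be 0).
#' @param bvecs m x 3 gradient directions; unit vectors where `bvals > 0`.
#' @return A `tensor_fit`: `tensor` (3 x 3, mm^2/s), `eigenvalues` (sorted
#'   descending, unclamped), `s0`.
#' @export
fit_tensor_ols <- function(signals, bvals, bvecs) {
  bvecs <- .check_gradients(bvals, bvecs)
  if (length(signals) != length(bvals)) {
    stop("signals and gradient table disagree in length", call. = FALSE)
  }
  if (any(!is.finite(signals)) || any(signals <= 0)) {
    stop("all signals must be positive and finite for the log-linear fit",
         call. = FALSE)
  }
  if (length(signals) < 7L) {
    stop("at least 7 measurements are required (6 directions plus b=0)",
         call. = FALSE)
  }
  X <- .tensor_design(bvals, bvecs)
  qx <- qr(X)
  if (qx$rank < 7L) {
    stop("rank-deficient gradient scheme: need >= 6 independent directions ",
         "plus a b=0 measurement", call. = FALSE)
  }
  beta <- qr.coef(qx, log(signals))
  D <- matrix(c(beta["dxx"], beta["dxy"], beta["dxz"],
                beta["dxy"], beta["dyy"], beta["dyz"],
                beta["dxz"], beta["dyz"], beta["dzz"]), 3, 3)
  ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
  structure(list(tensor = D, eigenvalues = ev, s0 = unname(exp(beta[1]))),
            class = "tensor_fit")
}

#' Fractional anisotropy from tensor eigenvalues
#'
#' FA = sqrt(1/2) * sqrt(((l1-l2)^2 + (l2-l3)^2 + (l3-l1)^2) /
#' (l1^2 + l2^2 + l3^2)). Eigenvalues must already be nonnegative (clamping of
#' noisy fits happens upstream, in [fa_volume()]); the all-zero triple is
#' defined as FA = 0 so background voxels do not produce 0/0.
#'
#' @param eigenvalues Numeric vector of 3 nonnegative eigenvalues.
#' @return FA in \[0, 1\].
#' @export
fractional_anisotropy <- function(eigenvalues) {
  stopifnot(length(eigenvalues) == 3L, all(is.finite(eigenvalues)))
  if (any(eigenvalues < 0)) {
    stop("negative eigenvalue: clamp before computing FA", call. = FALSE)
  }
  ss <- sum(eigenvalues^2)
  if (ss == 0) return(0)
  l <- eigenvalues
  fa <- sqrt(0.5 * ((l[1] - l[2])^2 + (l[2] - l[3])^2 + (l[3] - l[1])^2) / ss)
  min(fa, 1)
}

#' Voxel-wise FA map from a 4-D diffusion-weighted volume
#'
#' Fits the tensor at every in-mask voxel ([fit_tensor_ols()]), clamps
#' negative eigenvalues from noisy fits to zero, and evaluates
#' [fractional_anisotropy()]. Voxels outside the mask are 0. The number of
#' voxels needing eigenvalue clamping is attached as attribute `n_clamped`.
#'
#' @param dwi 4-D array, last dimension indexing the gradient table.
#' @param bvals,bvecs Gradient table, as in [fit_tensor_ols()].
#' @param mask Logical 3-D array on the same grid; default: all voxels.
#' @return 3-D FA array with attribute `n_clamped`.
#' @export
fa_volume <- function(dwi, bvals, bvecs, mask = NULL) {
  stopifnot(length(dim(dwi)) == 4L)
  bvecs <- .check_gradients(bvals, bvecs)
  shape <- dim(dwi)[1:3]
  if (dim(dwi)[4] != length(bvals)) {
    stop("image and gradient table disagree: ", dim(dwi)[4], " volumes vs ",
         length(bvals), " gradients", call. = FALSE)
  }
  if (is.null(mask)) mask <- array(TRUE, shape)
  stopifnot(identical(dim(mask), as.integer(shape)) ||
              isTRUE(all.equal(dim(mask), shape)))
  X <- .tensor_design(bvals, bvecs)
  qx <- qr(X)
  if (qx$rank < 7L || length(bvals) < 7L) {
    stop("rank-deficient gradient scheme", call. = FALSE)
  }
  idx <- which(mask)
  fa <- array(0, shape)
  n_clamped <- 0L
  if (length(idx)) {
    smat <- matrix(aperm(dwi, c(4, 1, 2, 3)), nrow = dim(dwi)[4])[, idx,
                                                                  drop = FALSE]
    if (any(smat <= 0)) {
      stop("non-positive signal inside the mask", call. = FALSE)
    }
    beta <- qr.coef(qx, log(smat))   # 7 x n_voxels
    vals <- numeric(length(idx))
    for (v in seq_along(idx)) {
      b <- beta[, v]
      D <- matrix(c(b[2], b[5], b[6], b[5], b[3], b[7], b[6], b[7], b[4]),
                  3, 3)
      ev <- eigen(D, symmetric = TRUE, only.values = TRUE)$values
      if (any(ev < 0)) {
        n_clamped <- n_clamped + 1L
        ev <- pmax(ev, 0)
      }
      vals[v] <- fractional_anisotropy(ev)
    }
    fa[idx] <- vals
  }
  attr(fa, "n_clamped") <- n_clamped
  fa
}

#' Quality-control screen on motion and outlier metrics
#'
#' A subject is excluded when at least two of the three automated
#' quality-control metrics meet or exceed their threshold: average absolute
#' motion >= 2 mm, average relative motion >= 0.5 mm, outlier percentage
#' >= 2%. Comparisons are inclusive, and a single offending metric keeps the
#' subject.
#'
#' @param metrics Data frame (or single named vector) with columns
#'   `avg_abs_motion` (mm), `avg_rel_motion` (mm), `outlier_pct` (%). Missing
#'   values are an error; no imputation is done.
#' @param thresholds Named numeric vector of the three cut-offs.
#' @return Character vector, `"keep"` or `"exclude"` per subject.
#' @export
#' @examples
#' qc_screen(data.frame(avg_abs_motion = c(2.5, 0.3, 2.1),
#'                      avg_rel_motion = c(0.6, 0.1, 0.2),
#'                      outlier_pct    = c(1.0, 0.5, 1.9)))
qc_screen <- function(metrics,
                      thresholds = c(avg_abs_motion = 2,
                                     avg_rel_motion = 0.5,
                                     outlier_pct = 2)) {
  if (!is.data.frame(metrics)) metrics <- as.data.frame(as.list(metrics))
  need <- names(thresholds)
  missing_cols <- setdiff(need, names(metrics))
  if (length(missing_cols)) {
    stop("missing QC metric(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  m <- as.matrix(metrics[need])
  if (anyNA(m) || any(!is.finite(m)) || any(m < 0)) {
    stop("QC metrics must be finite and nonnegative, with no missing values",
         call. = FALSE)
  }
  n_over <- rowSums(sweep(m, 2, thresholds[need], ">=") * 1)
  ifelse(n_over >= 2, "exclude", "keep")
}
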