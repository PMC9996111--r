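# Regression design for the edge-wise GLM: clinical score of interest plus
# nuisance covariates (age, sex, and a PCA compression of the collinear
# acquisition parameters), with the directed contrast the NBS run tests.

#' First principal component of the acquisition parameters
#'
#' The retrospective acquisition parameters (TR, TE, number of diffusion
#' directions, interslice gap) are strongly interdependent; to avoid
#' multicollinearity they are compressed into a single nuisance covariate:
#' the columns are z-scored (their units are incommensurate, so PCA is done
#' on the correlation structure), the principal components computed, and the
#' first-component score per subject returned. PCA scores are sign-ambiguous,
#' so the sign is fixed by requiring a nonnegative loading on the first
#' column; any fixed convention leaves the regression invariant.
#'
#' @param params Subject-by-parameter numeric table (>= 2 columns, >= 2
#'   rows, no missing values, no constant column).
#' @return First-component score vector, with attributes `loadings` and
#'   `var_explained`.
#' @export
acquisition_pc1 <- function(params) {
  x <- as.matrix(params)
  stopifnot(is.numeric(x), ncol(x) >= 2, nrow(x) >= 2)
  if (anyNA(x)) stop("acquisition parameters contain missing values",
                     call. = FALSE)
  sds <- apply(x, 2, sd)
  if (any(sds == 0)) {
    stop("constant acquisition column(s) cannot be z-scored: ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  }
  p <- prcomp(x, center = TRUE, scale. = TRUE)
  scores <- p$x[, 1]
  load1 <- p$rotation[, 1]
  if (load1[1] < 0) {
    scores <- -scores
    load1 <- -load1
  }
  structure(unname(scores),
            loadings = load1,
            var_explained = unname(p$sdev[1]^2 / sum(p$sdev^2)))
}

#' Construct and validate an edge-GLM design
#'
#' @param X Subject-by-predictor numeric matrix with named columns.
#' @param contrast Numeric contrast vector over the columns (at least one
#'   nonzero entry).
#' @return An `nbs_design` with `X`, `contrast` and `df_residual = n - rank`.
#' @export
nbs_design <- function(X, contrast) {
  X <- as.matrix(X)
  stopifnot(is.numeric(X), length(contrast) == ncol(X))
  if (all(contrast == 0)) {
    stop("contrast must have at least one nonzero entry", call. = FALSE)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dependent <- colnames(X)[qx$pivot[seq.int(qx$rank + 1, ncol(X))]]
    stop("design matrix is rank deficient; offending column(s): ",
         paste(dependent, collapse = ", "), call. = FALSE)
  }
  if (nrow(X) <= ncol(X)) {
    stop("need more subjects than design columns", call. = FALSE)
  }
  structure(list(X = X, contrast = as.numeric(contrast),
                 df_residual = nrow(X) - qx$rank),
            class = "nbs_design")
}

#' @export
print.nbs_design <- function(x, ...) {
  cat(sprintf("Edge-GLM design: %d subjects x %d predictors (%s); df = %d\n",
              nrow(x$X), ncol(x$X), paste(colnames(x$X), collapse = ", "),
              x$df_residual))
  cat("contrast:", paste(x$contrast, collapse = " "), "\n")
  invisible(x)
}

#' Build the clinical-score regression design from subject records
#'
#' Columns are `(intercept, score, age, sex, acq_pc1)` with sex coded
#' 0 = female, 1 = male and `acq_pc1` the [acquisition_pc1()] compression of
#' TR, TE, number of diffusion directions and interslice gap. The contrast is
#' the unit vector on the score column, negated for `direction = "negative"`.
#' By default the DRS is tested with the negative direction (a better outcome
#' is a lower DRS, so stronger connectivity shows as a negative slope) and
#' the CRS-R with the positive one.
#'
#' @param records Subject table with columns `age`, `sex` (`"f"`/`"m"` or
#'   0/1), the score column (`drs_discharge` or `crsr_discharge`), and the
#'   four acquisition columns `tr_ms`, `te_ms`, `n_directions`, `gap_mm`.
#' @param score `"DRS"` or `"CRSR"`.
#' @param direction `"positive"` or `"negative"`; default depends on the
#'   score.
#' @return An [nbs_design()].
#' @export
build_design <- function(records, score = c("DRS", "CRSR"),
                         direction = NULL) {
  score <- match.arg(score)
  if (is.null(direction)) {
    direction <- if (score == "DRS") "negative" else "positive"
  }
  direction <- match.arg(direction, c("positive", "negative"))
  score_col <- if (score == "DRS") "drs_discharge" else "crsr_discharge"
  acq_cols <- c("tr_ms", "te_ms", "n_directions", "gap_mm")
  need <- c(score_col, "age", "sex", acq_cols)
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    stop("records lack column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  if (!all(complete.cases(records[need]))) {
    stop("records contain missing values in design columns", call. = FALSE)
  }
  if (nrow(records) < 7) {
    stop("need at least 7 subjects (design rank 5 plus 2)", call. = FALSE)
  }
  sex <- records$sex
  if (is.character(sex) || is.factor(sex)) {
    sex <- as.integer(as.character(sex) == "m")
  }
  X <- cbind(intercept = 1,
             score = as.numeric(records[[score_col]]),
             age = as.numeric(records$age),
             sex = as.numeric(sex),
             acq_pc1 = as.numeric(acquisition_pc1(records[acq_cols])))
  contrast <- c(0, if (direction == "negative") -1 else 1, 0, 0, 0)
  d <- nbs_design(X, contrast)
  d$score <- score
  d$direction <- direction
  d
}
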