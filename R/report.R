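# Reporting: subnetwork summaries (degrees, per-subject subnetwork FA,
# Spearman correlation with the clinical score), cohort descriptive
# statistics, and BrainNet Viewer interchange export.

# accept a component (from threshold_components / nbs_fwer) or a bare edge
# data frame with node_a/node_b
.component_edges <- function(component) {
  if (is.data.frame(component)) return(component)
  if (is.list(component) && !is.null(component$edges)) return(component$edges)
  stop("component must be an edge data frame or a component list",
       call. = FALSE)
}

#' Nodal degrees of a subnetwork
#'
#' Degree = number of component edges incident to the node.
#'
#' @param component A component from [threshold_components()]/[nbs_fwer()],
#'   or a data frame with `node_a`, `node_b`.
#' @return Named integer vector of degrees, sorted decreasing.
#' @export
nodal_degrees <- function(component) {
  ed <- .component_edges(component)
  if (!nrow(ed)) stop("component is empty", call. = FALSE)
  tab <- table(c(as.character(ed$node_a), as.character(ed$node_b)))
  deg <- sort(as.integer(tab), decreasing = TRUE)
  names(deg) <- names(tab)[order(as.integer(tab), decreasing = TRUE)]
  deg
}

#' Per-subject mean FA across a subnetwork
#'
#' Unweighted mean of the component's edge values, per subject; the summary
#' that is correlated with the clinical score when reporting a subnetwork.
#'
#' @param stack A `connectome_stack` (or subject-by-edge matrix with `"a-b"`
#'   column names).
#' @param component As in [nodal_degrees()].
#' @return Numeric vector, one mean per subject.
#' @export
subnetwork_mean_fa <- function(stack, component) {
  Y <- if (inherits(stack, "connectome_stack")) stack$x else as.matrix(stack)
  ed <- .component_edges(component)
  keys <- .edge_key(as.integer(ed$node_a), as.integer(ed$node_b))
  missing_e <- setdiff(keys, colnames(Y))
  if (length(missing_e)) {
    stop("component edge(s) missing from the stack: ",
         paste(missing_e, collapse = ", "), call. = FALSE)
  }
  rowMeans(Y[, keys, drop = FALSE])
}

#' Spearman rank correlation with a t-approximation p-value
#'
#' Rank correlation with average ranks for ties;
#' `t = rho * sqrt((n-2)/(1-rho^2))` referred to a Student t with n-2 degrees
#' of freedom (two-sided). `|rho| = 1` gives p = 0.
#'
#' @param x,y Numeric vectors of equal length >= 3; neither constant.
#' @return List with `rho`, `p`, `n`.
#' @export
#' @examples
#' spearman_rho(1:5, c(1, 3, 2, 5, 4))  # rho = 0.8
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (anyNA(x) || anyNA(y)) stop("missing values", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0) {
    stop("constant vector: rank correlation undefined", call. = FALSE)
  }
  n <- length(x)
  rho <- cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * pt(-abs(tt), n - 2)
  }
  list(rho = rho, p = p, n = n)
}

# Tukey hinges, the quartile convention under which the published summaries
# reproduce exactly
.hinge_iqr <- function(x) {
  f <- stats::fivenum(x)
  f[4] - f[2]
}

.ks_normal <- function(x) {
  if (length(x) < 3 || sd(x) == 0) return(list(D = NA_real_, p = NA_real_))
  k <- suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))
  list(D = unname(k$statistic), p = unname(k$p.value))
}

#' Cohort descriptive statistics
#'
#' Mean and SD (n-1 denominator) of age; medians and interquartile ranges
#' (Tukey hinges) of the discharge scores and scan intervals; a one-sample
#' Kolmogorov-Smirnov statistic against a normal with the sample mean and SD
#' for each continuous variable; counts by sex, aetiology and admission
#' diagnosis (`"MCS-"` rows are tallied as MCS). A single-row table reports
#' SD and KS as absent (`NA`).
#'
#' @param records Subject table (see [read_cohort_table()] for the expected
#'   columns; only the columns present are summarised).
#' @return A `cohort_summary` list.
#' @export
cohort_descriptives <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  out <- list(n = nrow(records))
  if ("sex" %in% names(records)) {
    out$n_female <- sum(records$sex %in% c("f", "F", "female"))
    out$n_male <- out$n - out$n_female
  }
  if ("age" %in% names(records)) {
    age <- records$age
    ks <- .ks_normal(age)
    out$age <- list(mean = mean(age),
                    sd = if (length(age) > 1) sd(age) else NA_real_,
                    min = min(age), max = max(age),
                    ks_d = ks$D, ks_p = ks$p)
  }
  med_vars <- c(drs = "drs_discharge", crsr = "crsr_discharge",
                interval_injury_mri = "interval_injury_mri",
                interval_mri_discharge = "interval_mri_discharge")
  for (nm in names(med_vars)) {
    col <- med_vars[[nm]]
    if (col %in% names(records)) {
      x <- records[[col]]
      ks <- .ks_normal(x)
      out[[nm]] <- list(median = median(x),
                        iqr = if (length(x) > 1) .hinge_iqr(x) else NA_real_,
                        ks_d = ks$D, ks_p = ks$p)
    }
  }
  if ("etiology" %in% names(records)) {
    out$etiology <- table(records$etiology)
  }
  if ("diagnosis_admission" %in% names(records)) {
    dx <- sub("^MCS-$", "MCS", records$diagnosis_admission)
    out$diagnosis <- table(dx)
  }
  structure(out, class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort: n = %d", x$n))
  if (!is.null(x$n_female)) cat(sprintf(" (%d female)", x$n_female))
  cat("\n")
  if (!is.null(x$age)) {
    cat(sprintf("  age: mean %.1f, SD %.1f, range %g-%g (KS D = %.2f)\n",
                x$age$mean, x$age$sd, x$age$min, x$age$max, x$age$ks_d))
  }
  for (nm in c("drs", "crsr", "interval_injury_mri",
               "interval_mri_discharge")) {
    if (!is.null(x[[nm]])) {
      cat(sprintf("  %s: median %g, IQR %g (KS D = %.2f)\n", nm,
                  x[[nm]]$median, x[[nm]]$iqr, x[[nm]]$ks_d))
    }
  }
  if (!is.null(x$diagnosis)) {
    cat("  diagnosis:", paste(names(x$diagnosis), x$diagnosis, sep = "=",
                              collapse = ", "), "\n")
  }
  if (!is.null(x$etiology)) {
    cat("  etiology:", paste(names(x$etiology), x$etiology, sep = "=",
                             collapse = ", "), "\n")
  }
  invisible(x)
}

#' Read a cohort clinical table
#'
#' TSV with one row per subject. The packaged fixture
#' `table1_cohort.tsv` transcribes the demographic and clinical table of a
#' 40-patient acute-neurorehabilitation cohort (sex, age, scan intervals,
#' aetiology, admission diagnosis, discharge DRS and CRS-R).
#'
#' @param path TSV path; defaults to the packaged fixture.
#' @return Data frame of subject records.
#' @export
read_cohort_table <- function(path = connatlas_example("table1_cohort.tsv")) {
  read.delim(path, stringsAsFactors = FALSE)
}

#' Read a published subnetwork edge list
#'
#' The packaged fixture `table2_subnetworks.tsv` transcribes the significant
#' nodal pairs (with their edge t-values) of the DRS- and CRS-R-associated
#' subnetworks at the primary threshold t > 3.5.
#'
#' @param score `"DRS"` or `"CRSR"`: which subnetwork's edges to return.
#' @param path TSV path; defaults to the packaged fixture.
#' @return Data frame with `node_a`, `node_b` (region names) and `t`.
#' @export
read_subnetwork_edges <- function(score = c("DRS", "CRSR"),
                                  path =
                                    connatlas_example("table2_subnetworks.tsv")) {
  score <- match.arg(score)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  col <- if (score == "DRS") "t_drs" else "t_crsr"
  keep <- !is.na(tab[[col]])
  data.frame(node_a = tab$region_a[keep], node_b = tab$region_b[keep],
             t = tab[[col]][keep])
}

#' Export a subnetwork in the BrainNet Viewer convention
#'
#' Writes `<prefix>.node` (one row per parcellation node: x, y, z, colour
#' code, size, label — size is the nodal degree, colour 1 inside the
#' component and 0 outside) and `<prefix>.edge` (N x N matrix of edge
#' t-values, zero off the component), whitespace-delimited. No rendering is
#' done.
#'
#' @param component As in [nodal_degrees()]; node labels must be parcellation
#'   ids.
#' @param nodes Parcellation node table with `id`, `name`, `x`, `y`, `z`.
#' @param prefix Output path prefix.
#' @return Character vector of the two file paths, invisibly.
#' @export
export_brainnet <- function(component, nodes, prefix) {
  ed <- .component_edges(component)
  ids <- nodes$id
  comp_nodes <- unique(c(ed$node_a, ed$node_b))
  if (!all(comp_nodes %in% ids)) {
    stop("component node(s) missing from the parcellation table",
         call. = FALSE)
  }
  coords <- nodes[c("x", "y", "z")]
  if (anyNA(coords[match(comp_nodes, ids), ])) {
    stop("component node(s) lack coordinates", call. = FALSE)
  }
  deg <- rep(0L, length(ids))
  dtab <- nodal_degrees(ed)
  deg[match(as.integer(names(dtab)), ids)] <- dtab
  node_df <- data.frame(x = coords$x, y = coords$y, z = coords$z,
                        colour = as.integer(ids %in% comp_nodes),
                        size = deg,
                        label = gsub("\\s+", "-", nodes$name))
  node_path <- paste0(prefix, ".node")
  edge_path <- paste0(prefix, ".edge")
  write.table(node_df, node_path, sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  m <- matrix(0, length(ids), length(ids))
  ia <- match(ed$node_a, ids); ib <- match(ed$node_b, ids)
  tvals <- if (!is.null(ed$t)) ed$t else rep(1, nrow(ed))
  m[cbind(ia, ib)] <- tvals
  m[cbind(ib, ia)] <- tvals
  write.table(m, edge_path, sep = " ", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(c(node_path, edge_path))
}

#' JSON summary of an NBS result
#'
#' Writes the subnetwork summary (per-component nodes, edges with t-values,
#' degrees, FWER p) together with the per-subject subnetwork mean FA and its
#' Spearman correlation with a clinical score.
#'
#' @param result An `nbs_result`.
#' @param stack The stack the result was computed on.
#' @param score Numeric clinical score per subject.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_nbs_report <- function(result, stack, score, path) {
  stopifnot(inherits(result, "nbs_result"))
  comps <- lapply(result$components, function(cm) {
    fa <- subnetwork_mean_fa(stack, cm)
    sp <- spearman_rho(fa, score)
    list(n_nodes = cm$n_nodes, n_edges = cm$n_edges, p_fwer = cm$p,
         significant = cm$significant,
         nodes = cm$nodes, edges = cm$edges,
         degrees = as.list(nodal_degrees(cm)),
         subject_mean_fa = fa,
         spearman = sp)
  })
  jsonlite::write_json(
    list(config = result$config, df = result$df, components = comps),
    path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
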