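#' Replicate phenotype-correlated genes across two independent cohorts
#'
#' Discovery cohort 1 supplies genes passing the permutation-FDR gate;
#' cohort 2 confirms each one when it is measured there, associates with
#' the same sign, and reaches a nominal two-sided regression p-value of at
#' most `confirm_p`. This discovery-then-confirmation design is what allows
#' an age- or phenotype-correlated gene list to be called reproducible.
#'
#' @param r1 a `qsam_result` for the discovery cohort.
#' @param r2 a `score_table` (from [quantitative_score()]) for the
#'   confirmation cohort, same phenotype.
#' @param gate discovery FDR gate (default 0.05).
#' @param confirm_p confirmation two-sided p-value threshold (default
#'   0.05).
#' @return A `replicated_set` data.frame: `gene`, `sign`, `q1` (discovery
#'   q-value), `p2` (confirmation p-value), with attributes `gate` and
#'   `confirm_p`.
#' @export
replicate_across_cohorts <- function(r1, r2, gate = 0.05, confirm_p = 0.05) {
  stopifnot(inherits(r1, "qsam_result"))
  s1 <- r1$scores
  if (!length(intersect(s1$gene, r2$gene)))
    ps_stop("cohort gene universes are disjoint")
  disc <- s1[s1$q <= gate, , drop = FALSE]
  idx <- match(disc$gene, r2$gene)
  found <- !is.na(idx)
  same_sign <- found & disc$sign == r2$sign[idx] & disc$sign != 0
  confirmed <- same_sign & r2$p.value[idx] <= confirm_p
  out <- data.frame(gene = disc$gene[confirmed],
                    sign = disc$sign[confirmed],
                    q1 = disc$q[confirmed],
                    p2 = r2$p.value[idx[confirmed]],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "gate") <- gate
  attr(out, "confirm_p") <- confirm_p
  class(out) <- c("replicated_set", "data.frame")
  ps_log("replicate_across_cohorts: %d discovered at q <= %g; %d replicated (sign-consistent, p2 <= %g)",
         nrow(disc), gate, nrow(out), confirm_p)
  out
}

#' Robust-scale a variables-by-subjects table for PCA
#'
#' Each variable (row) is centered on its median and divided by its MAD
#' (Gaussian-consistent constant 1.4826), bringing heterogeneous
#' physiological and expression variables onto one robust, comparable
#' scale. Constant variables (MAD = 0) are rejected by name.
#'
#' @param table numeric matrix or data.frame, variables in rows, subjects
#'   in columns.
#' @return A numeric matrix of the same shape with row medians 0 and MADs
#'   1.
#' @export
scale_for_pca <- function(table) {
  m <- as.matrix(table)
  if (!is.numeric(m)) ps_stop("table must be numeric")
  if (is.null(rownames(m))) rownames(m) <- paste0("V", seq_len(nrow(m)))
  med <- apply(m, 1, median)
  madv <- apply(m, 1, mad)
  if (any(madv == 0))
    ps_stop("variable(s) with zero MAD cannot be scaled: %s",
            paste(head(rownames(m)[madv == 0], 5), collapse = ", "))
  (m - med) / madv
}

#' Principal component analysis of a scaled variable table
#'
#' Singular value decomposition of the column-centered subjects-by-variables
#' matrix (subjects are observations, variables features). Variance
#' fractions come from the squared singular values; for a reproducible sign
#' convention, each loading vector is flipped so its largest-magnitude
#' entry is positive.
#'
#' @param table numeric matrix, variables in rows and subjects in columns
#'   (as from [scale_for_pca()]).
#' @return A `pca_result` list: `loadings` (variables x components),
#'   `scores` (subjects x components), `variance_fraction`, `center`, and
#'   `data` (the input table) for downstream reporting.
#' @export
run_pca <- function(table) {
  m <- as.matrix(table)
  if (nrow(m) < 2) ps_stop("need >= 2 variables for PCA")
  if (ncol(m) < 3) ps_stop("need >= 3 subjects for PCA")
  if (is.null(rownames(m))) rownames(m) <- paste0("V", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("S", seq_len(ncol(m)))
  pc <- prcomp(t(m), center = TRUE, scale. = FALSE)
  if (all(pc$sdev == 0)) ps_stop("matrix has rank 0 after centering")
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  flip <- apply(pc$rotation, 2, function(v) if (v[which.max(abs(v))] < 0) -1 else 1)
  loadings <- sweep(pc$rotation, 2, flip, "*")
  scores <- sweep(pc$x, 2, flip, "*")
  structure(list(loadings = loadings, scores = scores,
                 variance_fraction = vf, center = pc$center, data = m),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  vf <- x$variance_fraction
  cat(sprintf("pca_result: %d variables x %d subjects; PC1 %.1f%%, PC2 %.1f%% of variance\n",
              nrow(x$loadings), nrow(x$scores), 100 * vf[1],
              if (length(vf) > 1) 100 * vf[2] else 0))
  invisible(x)
}

#' Report variance shared between a focus variable and the others
#'
#' For each reported component: the focus variable's loading, every other
#' variable's loading, and the squared correlation of that variable with
#' the focus variable across subjects. The component carrying the largest
#' absolute focus loading is flagged — when the focus phenotype loads on a
#' component where no other variable does, the phenotype's variation is
#' unexplained by the measured covariates.
#'
#' @param p a `pca_result`.
#' @param focus_variable name of the focus variable (row of the input
#'   table).
#' @param n_components number of components to report (default all).
#' @return A data.frame with one row per (component, variable):
#'   `component`, `variable`, `loading`, `focus_loading`, `r2_with_focus`;
#'   attribute `dominant_component` is the component with the largest
#'   |focus loading|.
#' @export
shared_variance_report <- function(p, focus_variable, n_components = NULL) {
  stopifnot(inherits(p, "pca_result"))
  vars <- rownames(p$loadings)
  if (!focus_variable %in% vars)
    ps_stop("focus variable '%s' not in table", focus_variable)
  nc <- if (is.null(n_components)) ncol(p$loadings)
        else min(n_components, ncol(p$loadings))
  fv <- p$data[focus_variable, ]
  r2 <- vapply(vars, function(v) cor(p$data[v, ], fv)^2, numeric(1))
  out <- do.call(rbind, lapply(seq_len(nc), function(j) {
    data.frame(component = colnames(p$loadings)[j], variable = vars,
               loading = p$loadings[, j],
               focus_loading = p$loadings[focus_variable, j],
               r2_with_focus = r2, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  dom <- which.max(abs(p$loadings[focus_variable, seq_len(nc)]))
  attr(out, "dominant_component") <- colnames(p$loadings)[dom]
  ps_log("shared_variance_report: focus '%s' loads most on %s",
         focus_variable, colnames(p$loadings)[dom])
  out
}
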