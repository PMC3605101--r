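#' Construct an ExpressionMatrix
#'
#' A light container for a genes x samples matrix of normalized log2
#' intensities, optionally carrying a detection-call ("Present") mask of the
#' same shape. Rows are genes (or probe sets before collapsing), columns are
#' samples. Identifiers must be unique and every intensity finite; missing
#' values are rejected rather than imputed because the chips this pipeline
#' consumes are complete after preprocessing.
#'
#' @param values numeric matrix of log2 intensities with unique rownames
#'   (gene/probe ids) and unique colnames (sample ids).
#' @param present optional logical matrix, same dimensions and dimnames as
#'   `values`; `TRUE` where the transcript was called Present.
#' @return An object of class `ExpressionMatrix`: a list with elements
#'   `values` and `present`.
#' @examples
#' m <- expression_matrix(matrix(rnorm(6), 3, 2,
#'   dimnames = list(paste0("g", 1:3), c("s1", "s2"))))
#' dim(m)
#' @export
expression_matrix <- function(values, present = NULL) {
  if (!is.matrix(values) || !is.numeric(values))
    ps_stop("'values' must be a numeric matrix")
  ids <- rownames(values)
  samples <- colnames(values)
  if (is.null(ids) || is.null(samples))
    ps_stop("'values' must carry rownames (gene ids) and colnames (sample ids)")
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    ps_stop("duplicate gene identifier(s): %s", paste(head(dup, 5), collapse = ", "))
  dup <- unique(samples[duplicated(samples)])
  if (length(dup))
    ps_stop("duplicate sample identifier(s): %s", paste(head(dup, 5), collapse = ", "))
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    ps_stop("non-finite expression value at gene '%s', sample '%s'",
            ids[bad[1]], samples[bad[2]])
  }
  if (!is.null(present)) {
    if (!is.matrix(present) || !is.logical(present))
      ps_stop("'present' must be a logical matrix")
    if (!identical(dim(present), dim(values)))
      ps_stop("presence mask dimensions (%d x %d) do not match values (%d x %d)",
              nrow(present), ncol(present), nrow(values), ncol(values))
    dimnames(present) <- dimnames(values)
  }
  structure(list(values = values, present = present),
            class = "ExpressionMatrix")
}

#' @export
dim.ExpressionMatrix <- function(x) dim(x$values)

#' @export
dimnames.ExpressionMatrix <- function(x) dimnames(x$values)

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$present)) "" else " (with presence mask)"))
  invisible(x)
}

#' @export
`[.ExpressionMatrix` <- function(x, i, j, ...) {
  v <- x$values[i, j, drop = FALSE]
  p <- if (is.null(x$present)) NULL else x$present[i, j, drop = FALSE]
  expression_matrix(v, p)
}

#' Gene identifiers of an ExpressionMatrix
#' @param x an `ExpressionMatrix`.
#' @return Character vector of gene ids in row order.
#' @export
gene_ids <- function(x) rownames(x$values)

#' Sample identifiers of an ExpressionMatrix
#' @param x an `ExpressionMatrix`.
#' @return Character vector of sample ids in column order.
#' @export
sample_ids <- function(x) colnames(x$values)

as_expression_values <- function(x) {
  if (inherits(x, "ExpressionMatrix")) x$values
  else if (is.matrix(x) && is.numeric(x)) x
  else ps_stop("expected an ExpressionMatrix or a numeric matrix")
}
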