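#' Read a normalized expression matrix from tab-separated text
#'
#' Expects a header row of sample identifiers and a first column of gene (or
#' probe-set) identifiers; remaining cells are normalized log2 intensities.
#' An optional companion presence file holds the detection calls of the same
#' layout, coded `A` (absent), `M` (marginal) or `P` (present); only `P`
#' counts as detected.
#'
#' @param path path to the expression TSV.
#' @param presence_path optional path to the A/M/P detection-call TSV.
#' @return An [expression_matrix()] with row/column order as in the file.
#' @export
read_expression <- function(path, presence_path = NULL) {
  raw <- read.delim(path, check.names = FALSE, colClasses = "character")
  if (ncol(raw) < 2) ps_stop("'%s': need a gene-id column plus >=1 sample column", path)
  ids <- raw[[1]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    ps_stop("'%s': duplicate gene identifier(s): %s", path,
            paste(head(dup, 5), collapse = ", "))
  vals <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
    if (!nrow(bad)) bad <- which(is.na(num), arr.ind = TRUE)
    ps_stop("'%s': non-numeric value '%s' at gene '%s', sample '%s'",
            path, vals[bad[1, 1], bad[1, 2]], ids[bad[1, 1]],
            colnames(vals)[bad[1, 2]])
  }
  dimnames(num) <- list(ids, colnames(vals))
  present <- NULL
  if (!is.null(presence_path)) {
    pr <- read.delim(presence_path, check.names = FALSE, colClasses = "character")
    pm <- as.matrix(pr[, -1, drop = FALSE])
    if (!identical(dim(pm), dim(num)))
      ps_stop("presence file '%s' is %d x %d but expression is %d x %d",
              presence_path, nrow(pm), ncol(pm), nrow(num), ncol(num))
    if (!identical(pr[[1]], ids))
      ps_stop("presence file '%s': gene ids differ from expression file", presence_path)
    bad <- setdiff(unique(as.vector(pm)), c("A", "M", "P"))
    if (length(bad))
      ps_stop("presence file '%s': invalid detection code(s): %s",
              presence_path, paste(head(bad, 5), collapse = ", "))
    present <- pm == "P"
    dimnames(present) <- dimnames(num)
  }
  m <- expression_matrix(num, present)
  ps_log("read_expression: %d genes x %d samples from %s%s",
         nrow(num), ncol(num), path,
         if (is.null(present)) "" else " (+presence mask)")
  m
}

#' Write an expression matrix (and optionally its presence mask) to TSV
#'
#' @param m an `ExpressionMatrix`.
#' @param path output TSV path; first column `gene_id`, then one column per
#'   sample.
#' @param presence_path optional output path for the A/P detection-call TSV
#'   (marginal calls are not reconstructed; `TRUE` is written as `P`,
#'   `FALSE` as `A`).
#' @return Invisibly, `path`.
#' @export
write_expression <- function(m, path, presence_path = NULL) {
  df <- data.frame(gene_id = gene_ids(m), m$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(presence_path)) {
    if (is.null(m$present))
      ps_stop("no presence mask to write")
    pm <- ifelse(m$present, "P", "A")
    pdf <- data.frame(gene_id = gene_ids(m), pm,
                      check.names = FALSE, stringsAsFactors = FALSE)
    write.table(pdf, presence_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read a per-subject phenotype table
#'
#' TSV with columns `subject_id`, `cohort`, `timepoint` (one of `pre`,
#' `post`, `single`) followed by one numeric column per phenotype
#' (lean-mass change in %, age in years, ...). Each (subject, timepoint)
#' pair must be unique and all phenotype values finite.
#'
#' @param path path to the phenotype TSV.
#' @return A `data.frame` in file order.
#' @export
read_phenotypes <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("subject_id", "cohort", "timepoint")
  miss <- setdiff(need, names(df))
  if (length(miss))
    ps_stop("'%s': missing required column(s): %s", path, paste(miss, collapse = ", "))
  bad <- setdiff(unique(df$timepoint), c("pre", "post", "single"))
  if (length(bad))
    ps_stop("'%s': invalid timepoint value(s): %s", path, paste(bad, collapse = ", "))
  key <- paste(df$subject_id, df$timepoint)
  if (anyDuplicated(key))
    ps_stop("'%s': duplicated (subject, timepoint) pair(s): %s", path,
            paste(head(unique(key[duplicated(key)]), 5), collapse = "; "))
  pheno_cols <- setdiff(names(df), need)
  for (pc in pheno_cols) {
    if (!is.numeric(df[[pc]]) || !all(is.finite(df[[pc]])))
      ps_stop("'%s': phenotype column '%s' must be numeric and finite", path, pc)
  }
  ps_log("read_phenotypes: %d rows, %d phenotype column(s) from %s",
         nrow(df), length(pheno_cols), path)
  df
}

#' Read a signed regulator-to-target network
#'
#' TSV with columns `regulator`, `target`, `sign`; `sign` is `+1` when
#' activation of the regulator increases the target's RNA and `-1` when it
#' decreases it. This is the user-supplied stand-in for a literature-curated
#' mediator network. Duplicate (regulator, target) edges are rejected.
#'
#' @param path path to the network TSV.
#' @return A `data.frame` with columns `regulator`, `target`, `sign`
#'   (integer +1/-1).
#' @export
read_network <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("regulator", "target", "sign")
  miss <- setdiff(need, names(df))
  if (length(miss))
    ps_stop("'%s': missing required column(s): %s", path, paste(miss, collapse = ", "))
  sgn <- suppressWarnings(as.integer(df$sign))
  if (anyNA(sgn) || !all(sgn %in% c(-1L, 1L)))
    ps_stop("'%s': 'sign' must be +1 or -1", path)
  df$sign <- sgn
  key <- paste(df$regulator, df$target)
  if (anyDuplicated(key))
    ps_stop("'%s': duplicate (regulator, target) edge(s): %s", path,
            paste(head(unique(key[duplicated(key)]), 5), collapse = "; "))
  ps_log("read_network: %d edges, %d regulators from %s",
         nrow(df), length(unique(df$regulator)), path)
  df[, need]
}

#' Write a signed regulator network to TSV
#' @param net data.frame with columns `regulator`, `target`, `sign`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_network <- function(net, path) {
  write.table(net[, c("regulator", "target", "sign")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene genomic coordinates from BED
#'
#' A 4+ column BED file (chrom, start, end, gene_id) with the usual BED
#' convention of 0-based half-open coordinates on disk; in memory the
#' annotation is a [GenomicRanges::GRanges] (1-based closed, converted by
#' rtracklayer). Gene ids must be unique genome-wide.
#'
#' @param path path to the BED file.
#' @return A `GRanges` with gene ids as names.
#' @export
read_genome <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  nm <- gr$name
  if (is.null(nm) || anyNA(nm))
    ps_stop("'%s': BED column 4 (gene id) is required for every record", path)
  dup <- unique(nm[duplicated(nm)])
  if (length(dup))
    ps_stop("'%s': duplicate gene id(s): %s", path, paste(head(dup, 5), collapse = ", "))
  names(gr) <- nm
  ps_log("read_genome: %d genes on %d sequence(s) from %s",
         length(gr), length(unique(as.character(GenomicRanges::seqnames(gr)))), path)
  gr
}

#' Write a gene annotation to BED
#' @param ann a `GRanges` with gene ids as names (as from [read_genome()] or
#'   [simulate_genome()]).
#' @param path output BED path (written 0-based half-open by rtracklayer).
#' @return Invisibly, `path`.
#' @export
write_genome <- function(ann, path) {
  gr <- ann
  gr$name <- names(gr)
  gr$score <- NULL
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a probe-set to gene-symbol mapping table
#'
#' TSV with columns `probe_id` and `gene_symbol`; many probes may map to one
#' gene, probes absent from the table are unmapped. Probe ids must be unique.
#'
#' @param path path to the mapping TSV.
#' @return A `data.frame` with columns `probe_id`, `gene_symbol`.
#' @export
read_probe_map <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("probe_id", "gene_symbol")
  miss <- setdiff(need, names(df))
  if (length(miss))
    ps_stop("'%s': missing required column(s): %s", path, paste(miss, collapse = ", "))
  dup <- unique(df$probe_id[duplicated(df$probe_id)])
  if (length(dup))
    ps_stop("'%s': duplicate probe id(s): %s", path, paste(head(dup, 5), collapse = ", "))
  df[, need]
}

#' Filter genes by detection-call fraction
#'
#' Retains genes called Present in at least `min_fraction` of samples, the
#' PA-filtering step applied before scoring. Row order is preserved.
#'
#' @param m an `ExpressionMatrix` carrying a presence mask.
#' @param min_fraction minimum fraction of samples (in `[0, 1]`) with a
#'   Present call; default 0.25.
#' @return The filtered `ExpressionMatrix`.
#' @export
filter_present <- function(m, min_fraction = 0.25) {
  if (is.null(m$present))
    ps_stop(paste("no presence mask available; load one via read_expression(...,",
                  "presence_path=) or skip PA filtering explicitly"))
  if (!is.numeric(min_fraction) || min_fraction < 0 || min_fraction > 1)
    ps_stop("'min_fraction' must lie in [0, 1]")
  keep <- rowMeans(m$present) >= min_fraction
  out <- m[keep, ]
  ps_log("filter_present: kept %d / %d genes (min_fraction = %g)",
         sum(keep), nrow(m$values), min_fraction)
  out
}

row_iqr <- function(v) {
  q <- apply(v, 1, quantile, probs = c(0.25, 0.75), names = FALSE, type = 7)
  q[2, ] - q[1, ]
}

#' Collapse probe-set rows to one row per gene symbol
#'
#' For each gene symbol the representative probe is the one with the largest
#' interquartile range across samples (`method = "iqr"`, the default), which
#' avoids averaging probes of different hybridization affinity; `method =
#' "mean"` averages all probes of a gene instead. Unmapped probes are
#' dropped. Surviving rows keep their relative input order (the
#' representative's position for `"iqr"`, the first probe's position for
#' `"mean"`).
#'
#' @param m an `ExpressionMatrix` whose rows are probe ids.
#' @param map a probe-to-gene table as from [read_probe_map()].
#' @param method `"iqr"` (max-IQR representative) or `"mean"`.
#' @return An `ExpressionMatrix` with one row per gene symbol. The presence
#'   mask, if any, follows the representative probe for `"iqr"` and is
#'   dropped for `"mean"`.
#' @export
collapse_probes <- function(m, map, method = c("iqr", "mean")) {
  method <- match.arg(method)
  idx <- match(gene_ids(m), map$probe_id)
  mapped <- !is.na(idx)
  if (!any(mapped))
    ps_stop("no probe id in the matrix is present in the mapping table")
  sym <- map$gene_symbol[idx[mapped]]
  sub <- m$values[mapped, , drop = FALSE]
  pres <- if (is.null(m$present)) NULL else m$present[mapped, , drop = FALSE]
  if (method == "iqr") {
    iqr <- row_iqr(sub)
    ord <- split(seq_len(nrow(sub)), sym)
    rep_row <- vapply(ord, function(rows) rows[which.max(iqr[rows])], integer(1))
    rep_row <- sort(rep_row)  # preserve input row order
    vals <- sub[rep_row, , drop = FALSE]
    rownames(vals) <- sym[rep_row]
    out_pres <- if (is.null(pres)) NULL else {
      p <- pres[rep_row, , drop = FALSE]; rownames(p) <- sym[rep_row]; p
    }
  } else {
    first_row <- vapply(split(seq_len(nrow(sub)), sym), min, integer(1))
    genes_in_order <- sym[sort(first_row)]
    vals <- do.call(rbind, lapply(genes_in_order, function(g)
      colMeans(sub[sym == g, , drop = FALSE])))
    rownames(vals) <- genes_in_order
    out_pres <- NULL
    if (!is.null(pres)) ps_log("collapse_probes: presence mask dropped under mean collapse")
  }
  ps_log("collapse_probes: %d probes -> %d genes (%d unmapped probe(s) dropped, method = %s)",
         nrow(m$values), nrow(vals), sum(!mapped), method)
  expression_matrix(vals, out_pres)
}

#' Write a result table to TSV
#'
#' Generic writer used by every stage for its tabular output; columns are
#' written with headers, tab-separated, unquoted.
#'
#' @param df a data.frame.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_result <- function(df, path) {
  write.table(as.data.frame(df), path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
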