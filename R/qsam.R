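#' Quantitative SAM score: regression of expression on a continuous phenotype
#'
#' For each gene, fits simple least squares of expression on the phenotype
#' and forms the regularized SAM statistic `d = b / (s + s0)`, where `b` is
#' the slope, `s` its standard error and `s0` the fudge factor that keeps
#' low-variance genes from dominating. With `s0 = 0`, `d` is exactly the
#' regression t-statistic.
#'
#' @param x an `ExpressionMatrix` (or numeric matrix), genes x samples.
#' @param y numeric phenotype, one value per sample, not constant.
#' @param s0 non-negative fudge factor (same units as `s`); default 0.
#' @param .check_collinear internal; when `FALSE`, genes with zero standard
#'   error are tolerated (used while assembling raw slopes/errors before a
#'   positive `s0` is applied).
#' @return A `score_table` data.frame with columns `gene`, `b`, `s`, `d`,
#'   `sign`, `t`, `p.value`, and attributes `s0`, `df`, `mode`. The
#'   unregularized `t = b/s` and its two-sided p-value are carried for
#'   downstream confirmation tests.
#' @export
quantitative_score <- function(x, y, s0 = 0, .check_collinear = TRUE) {
  v <- as_expression_values(x)
  n <- ncol(v)
  if (length(y) != n)
    ps_stop("phenotype length (%d) != number of samples (%d)", length(y), n)
  if (!all(is.finite(y))) ps_stop("phenotype contains non-finite values")
  if (n < 3) ps_stop("need >= 3 samples for a regression score")
  yc <- y - mean(y)
  syy <- sum(yc^2)
  if (syy == 0) ps_stop("phenotype is constant; quantitative score undefined")
  b <- drop(v %*% yc) / syy
  ssx <- rowSums(v^2) - n * rowMeans(v)^2
  rss <- pmax(ssx - b^2 * syy, 0)  # guard tiny negative from roundoff
  s <- sqrt(rss / ((n - 2) * syy))
  make_score_table(rownames(v), b, s, s0, df = n - 2, mode = "quantitative",
                   check_collinear = .check_collinear)
}

#' Paired SAM score on pre/post expression differences
#'
#' Per gene, the subject-wise change `z = post - pre` is summarized as
#' `b = mean(z)`, `s = sd(z)/sqrt(n)`, `d = b/(s + s0)`. With `s0 = 0` this
#' is the one-sample t-statistic on differences. Subjects are matched by
#' column name between the two matrices.
#'
#' @param pre,post `ExpressionMatrix` objects with identical gene sets and
#'   matching subject (column) names.
#' @param s0 non-negative fudge factor; default 0.
#' @param .check_collinear internal; see [quantitative_score()].
#' @return A `score_table` (see [quantitative_score()]), `df = n - 1`.
#' @export
paired_score <- function(pre, post, s0 = 0, .check_collinear = TRUE) {
  vp <- as_expression_values(pre); vq <- as_expression_values(post)
  if (!identical(rownames(vp), rownames(vq)))
    ps_stop("pre and post matrices must have identical gene sets and order")
  un1 <- setdiff(colnames(vp), colnames(vq))
  un2 <- setdiff(colnames(vq), colnames(vp))
  if (length(un1) || length(un2))
    ps_stop("unmatched subjects: %s",
            paste(c(un1, un2), collapse = ", "))
  vq <- vq[, colnames(vp), drop = FALSE]
  z <- vq - vp
  n <- ncol(z)
  if (n < 2) ps_stop("need >= 2 matched subjects")
  b <- rowMeans(z)
  sdz <- sqrt(pmax(rowSums(z^2) - n * b^2, 0) / (n - 1))
  s <- sdz / sqrt(n)
  make_score_table(rownames(z), b, s, s0, df = n - 1, mode = "paired",
                   check_collinear = .check_collinear)
}

#' Two-class (unpaired) SAM score
#'
#' Classic two-class SAM: `b` is the group-2 minus group-1 mean difference
#' and `s` the pooled standard error
#' `sqrt((1/n1 + 1/n2) * pooledVar)`; `d = b/(s + s0)` equals the equal
#' -variance two-sample t-statistic when `s0 = 0`.
#'
#' @param x an `ExpressionMatrix` (or matrix), genes x samples.
#' @param groups vector of two distinct labels, one per sample; the
#'   difference is second level minus first (levels in sort order).
#' @param s0 non-negative fudge factor; default 0.
#' @return A `score_table`, `df = n - 2`.
#' @export
two_class_score <- function(x, groups, s0 = 0) {
  v <- as_expression_values(x)
  g <- as.character(groups)
  if (length(g) != ncol(v)) ps_stop("'groups' length must equal sample count")
  lev <- sort(unique(g))
  if (length(lev) != 2) ps_stop("'groups' must have exactly 2 levels")
  i1 <- g == lev[1]; i2 <- g == lev[2]
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2 || n2 < 2) ps_stop("need >= 2 samples per class")
  m1 <- rowMeans(v[, i1, drop = FALSE]); m2 <- rowMeans(v[, i2, drop = FALSE])
  ss1 <- rowSums(v[, i1, drop = FALSE]^2) - n1 * m1^2
  ss2 <- rowSums(v[, i2, drop = FALSE]^2) - n2 * m2^2
  sp2 <- pmax(ss1 + ss2, 0) / (n1 + n2 - 2)
  s <- sqrt((1 / n1 + 1 / n2) * sp2)
  make_score_table(rownames(v), m2 - m1, s, s0, df = n1 + n2 - 2,
                   mode = "two-class")
}

make_score_table <- function(genes, b, s, s0, df, mode, check_collinear = TRUE) {
  if (s0 < 0) ps_stop("s0 must be non-negative")
  if (check_collinear && s0 == 0 && any(s == 0)) {
    bad <- genes[which(s == 0)]
    ps_stop("zero standard error with s0 = 0 for gene(s): %s (perfectly collinear input)",
            paste(head(bad, 5), collapse = ", "))
  }
  d <- ifelse(s + s0 > 0, b / (s + s0), 0)
  tt <- ifelse(s > 0, b / s, sign(b) * Inf)
  tt[s == 0 & b == 0] <- 0
  p <- 2 * pt(-abs(tt), df)
  out <- data.frame(gene = genes, b = b, s = s, d = d,
                    sign = sign(d), t = tt, p.value = p,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "s0") <- s0
  attr(out, "df") <- df
  attr(out, "mode") <- mode
  class(out) <- c("score_table", "data.frame")
  out
}

#' Estimate the SAM fudge factor s0
#'
#' Implements the SAM tuning rule: candidate values of `s0` are the
#' percentiles 0, 5, ..., 100 of the per-gene standard errors `s`. For each
#' candidate, `d = b/(s + s0)` is recomputed, the genes are sliced into
#' windows by quantiles of `s`, and the median absolute deviation of `d` is
#' taken within each window; the chosen `s0` minimizes the coefficient of
#' variation of these window MADs, i.e. it makes the spread of `d` as
#' independent of `s` as possible. Ties go to the smaller percentile.
#'
#' @param scores a `score_table`, or a list/data.frame with numeric `b`
#'   and `s`.
#' @param n_windows number of quantile windows of `s` (default 100, reduced
#'   automatically for small gene counts).
#' @return The selected `s0` (scalar), with the winning percentile as
#'   attribute `"percentile"`.
#' @export
estimate_s0 <- function(scores, n_windows = 100) {
  b <- scores$b; s <- scores$s
  if (length(unique(s)) < 2) {
    warning("fewer than 2 distinct standard errors; using median(s) as s0")
    return(structure(median(s), percentile = NA_real_))
  }
  alphas <- seq(0, 1, by = 0.05)
  cand <- quantile(s, alphas, names = FALSE, type = 7)
  nw <- max(2, min(n_windows, floor(length(s) / 5)))
  br <- unique(quantile(s, seq(0, 1, length.out = nw + 1), names = FALSE))
  win <- cut(s, breaks = br, include.lowest = TRUE)
  cv <- vapply(cand, function(s0c) {
    d <- b / (s + s0c)
    v <- tapply(d, win, mad)
    v <- v[!is.na(v)]
    if (mean(v) == 0) Inf else sd(v) / mean(v)
  }, numeric(1))
  best <- which.min(cv)  # which.min returns the first (smallest percentile) tie
  structure(cand[best], percentile = alphas[best] * 100)
}

## ---- permutation machinery ----------------------------------------------

# derive an independent sub-seed for permutation i so that results do not
# depend on the order in which permutations are evaluated
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(i) * 16807) %% 2147483647)
}

# all permutations of 1..n (n small; used for exact enumeration)
all_permutations <- function(n) {
  if (n == 1) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- vector("list", n * length(sub))
  k <- 0L
  for (p in sub) for (pos in seq_len(n)) {
    k <- k + 1L
    out[[k]] <- append(p, n, after = pos - 1L)
  }
  out
}

#' Permutation-based FDR and q-values for SAM scores
#'
#' Calibrates the observed d-statistics against a null distribution obtained
#' by permuting subject labels: phenotype values are shuffled in
#' quantitative mode, pre/post differences are sign-flipped in paired mode,
#' and group labels are shuffled in two-class mode. When the number of
#' distinct relabelings (n!, 2^n, or choose(n, n1)) does not exceed `B`,
#' all of them are enumerated exactly; otherwise `B` random relabelings are
#' drawn, each from an independent sub-seed of `seed` so the result is
#' reproducible and independent of evaluation order.
#'
#' For a grid of `n_delta` thresholds over `[0, max|d|]`, the called set is
#' all genes with `|d| >= delta` (ties at the boundary are called), the
#' false-call count of each permutation is the number of permuted scores
#' `|d*| >= delta`, and `FDR(delta)` is the mean (default; see Details) of
#' the permutation false-call counts divided by the observed call count,
#' capped at 1 (0/0 is defined as 0). The per-gene q-value is the smallest
#' `FDR(delta)` over thresholds at which the gene is called, which is
#' non-increasing in `|d|` by construction.
#'
#' @details
#' `fdr_summary` chooses how the permutation false-call counts are pooled.
#' `"mean"` (the default) averages over permutations and yields a
#' well-calibrated null — under a global null the expected top-gene FDR is
#' near 1, so pure-noise runs essentially never call genes at a 5% gate.
#' `"median"`, the summary popularized by the original SAM report, is
#' available but is anti-conservative at the extreme tail: for the maximal
#' observed score about half of all null permutations carry no exceedance
#' at all, so the median false-call count (and hence the q-value of the top
#' gene) collapses to zero in roughly half of pure-noise datasets.
#'
#' @param x an `ExpressionMatrix`; in paired mode the *pre* matrix.
#' @param y phenotype vector (quantitative) or group labels (two-class);
#'   ignored in paired mode.
#' @param post the *post* `ExpressionMatrix` (paired mode only).
#' @param mode `"quantitative"`, `"paired"` or `"two-class"`.
#' @param B number of permutations (default 1000); exact enumeration is used
#'   automatically when the total number of relabelings is `<= B`.
#' @param seed integer seed for the permutation draws.
#' @param s0 `"auto"` (tune via [estimate_s0()] on the observed scores) or a
#'   non-negative scalar.
#' @param n_delta number of thresholds in the delta grid (default 100).
#' @param fdr_summary `"mean"` (default) or `"median"` pooling of permutation
#'   false-call counts.
#' @return A `qsam_result` list: `scores` (the observed `score_table` with a
#'   `q` column), `delta_table` (delta, n_called, false_called, fdr), plus
#'   `s0`, `B`, `n_perm_used`, `exact`, `seed`, `mode`, `fdr_summary`.
#' @export
permutation_fdr <- function(x, y = NULL, post = NULL,
                            mode = c("quantitative", "paired", "two-class"),
                            B = 1000, seed = 1, s0 = "auto", n_delta = 100,
                            fdr_summary = c("mean", "median")) {
  mode <- match.arg(mode)
  fdr_summary <- match.arg(fdr_summary)
  if (B < 1) ps_stop("B must be >= 1")
  if (mode == "paired") {
    if (is.null(post)) ps_stop("paired mode needs both 'x' (pre) and 'post'")
    vp <- as_expression_values(x); vq <- as_expression_values(post)
    obs0 <- paired_score(x, post, s0 = 0, .check_collinear = FALSE)
    z <- vq[, colnames(vp), drop = FALSE] - vp
    n <- ncol(z)
  } else {
    v <- as_expression_values(x)
    n <- ncol(v)
    if (is.null(y)) ps_stop("'y' is required in %s mode", mode)
    obs0 <- if (mode == "quantitative")
              quantitative_score(x, y, s0 = 0, .check_collinear = FALSE)
            else two_class_score(x, y, s0 = 0)
  }
  s0_val <- if (identical(s0, "auto")) as.numeric(estimate_s0(obs0)) else {
    if (!is.numeric(s0) || s0 < 0) ps_stop("'s0' must be \"auto\" or a non-negative scalar")
    as.numeric(s0)
  }
  if (s0_val == 0 && any(obs0$s == 0))
    ps_stop("zero standard error with s0 = 0 for gene(s): %s (perfectly collinear input)",
            paste(head(obs0$gene[obs0$s == 0], 5), collapse = ", "))
  d_obs <- obs0$b / (obs0$s + s0_val)

  # permuted |d*| generator ------------------------------------------------
  if (mode == "quantitative") {
    yc <- y - mean(y); syy <- sum(yc^2)
    ssx <- rowSums(v^2) - n * rowMeans(v)^2
    score_perm <- function(idx) {
      ycp <- yc[idx]
      bp <- drop(v %*% ycp) / syy
      sp <- sqrt(pmax(ssx - bp^2 * syy, 0) / ((n - 2) * syy))
      abs(bp / (sp + s0_val))
    }
    n_exact <- if (n <= 10) factorial(n) else Inf
    exact <- n_exact <= B
    perms <- if (exact) all_permutations(n) else lapply(seq_len(B), function(i) {
      set.seed(derive_seed(seed, i)); sample.int(n)
    })
  } else if (mode == "paired") {
    score_flip <- function(fl) {
      zf <- sweep(z, 2, fl, "*")
      bp <- rowMeans(zf)
      sp <- sqrt(pmax(rowSums(zf^2) - n * bp^2, 0) / (n - 1)) / sqrt(n)
      abs(bp / (sp + s0_val))
    }
    n_exact <- if (n <= 30) 2^n else Inf
    exact <- n_exact <= B
    perms <- if (exact) {
      lapply(seq_len(2^n) - 1L, function(m)
        ifelse(bitwAnd(m, bitwShiftL(1L, seq_len(n) - 1L)) > 0, -1, 1))
    } else lapply(seq_len(B), function(i) {
      set.seed(derive_seed(seed, i)); sample(c(-1, 1), n, replace = TRUE)
    })
    score_perm <- score_flip
  } else {  # two-class
    g <- as.character(y); lev <- sort(unique(g))
    n1 <- sum(g == lev[1])
    score_perm <- function(idx1) {
      gi <- rep(lev[2], n); gi[idx1] <- lev[1]
      st <- two_class_score(v, gi, s0 = 0)
      abs(st$b / (st$s + s0_val))
    }
    n_exact <- choose(n, n1)
    exact <- n_exact <= B
    perms <- if (exact) {
      cb <- combn(n, n1)
      lapply(seq_len(ncol(cb)), function(j) cb[, j])
    } else lapply(seq_len(B), function(i) {
      set.seed(derive_seed(seed, i)); sample.int(n, n1)
    })
  }

  deltas <- seq(0, max(abs(d_obs)), length.out = n_delta)
  deltas[n_delta] <- max(abs(d_obs))  # guard seq() endpoint fuzz: top gene is called
  sorted_obs <- sort(abs(d_obs))
  n_genes <- length(d_obs)
  # count of |d| >= delta = n - #(|d| < delta)
  n_called <- n_genes - findInterval(deltas, sorted_obs, left.open = TRUE)
  false_mat <- vapply(perms, function(p) {
    sp <- sort(score_perm(p))
    n_genes - findInterval(deltas, sp, left.open = TRUE)
  }, numeric(length(deltas)))
  false_called <- if (fdr_summary == "mean") rowMeans(false_mat)
                  else apply(false_mat, 1, median)
  fdr <- ifelse(n_called > 0, pmin(1, false_called / n_called), 0)
  # q(gene) = min FDR over deltas <= |d|; prefix-min makes it monotone in |d|
  pref_min <- cummin(fdr)
  gi <- findInterval(abs(d_obs), deltas)
  gi[gi < 1] <- 1
  q <- pref_min[gi]
  scores <- obs0
  scores$d <- d_obs
  scores$sign <- sign(d_obs)
  attr(scores, "s0") <- s0_val
  scores$q <- q
  res <- structure(list(
    scores = scores,
    delta_table = data.frame(delta = deltas, n_called = n_called,
                             false_called = false_called, fdr = fdr),
    s0 = s0_val, B = B, n_perm_used = length(perms), exact = exact,
    seed = as.integer(seed), mode = mode, fdr_summary = fdr_summary),
    class = "qsam_result")
  ps_log("permutation_fdr: %s mode, %d genes, %d permutations (%s), s0 = %.4g",
         mode, n_genes, length(perms),
         if (exact) "exact enumeration" else "sampled", s0_val)
  res
}

#' @export
print.qsam_result <- function(x, ...) {
  cat(sprintf("qsam_result: %s mode, %d genes, %d permutations (%s), s0 = %.4g\n",
              x$mode, nrow(x$scores), x$n_perm_used,
              if (x$exact) "exact" else "sampled", x$s0))
  cat(sprintf("  genes with q <= 0.05: %d\n", sum(x$scores$q <= 0.05)))
  invisible(x)
}

#' Select genes passing an FDR gate
#'
#' @param r a `qsam_result`.
#' @param gate FDR threshold in (0, 1]; genes with `q <= gate` are selected,
#'   the conventional gate being 0.05.
#' @return A `significant_gene_set` data.frame with columns `gene`, `sign`,
#'   `q`, and attribute `gate`.
#' @export
select_significant <- function(r, gate = 0.05) {
  stopifnot(inherits(r, "qsam_result"))
  if (gate <= 0 || gate > 1) ps_stop("'gate' must lie in (0, 1]")
  keep <- r$scores$q <= gate
  out <- r$scores[keep, c("gene", "sign", "q")]
  rownames(out) <- NULL
  attr(out, "gate") <- gate
  class(out) <- c("significant_gene_set", "data.frame")
  ps_log("select_significant: %d / %d genes at FDR <= %g",
         nrow(out), nrow(r$scores), gate)
  out
}

#' Drop non-responding subjects before paired differential analysis
#'
#' Subjects whose phenotype does not exceed `min_value` (strictly) are
#' removed, mirroring the exclusion of subjects without a physiological
#' training response before differential expression analysis.
#'
#' @param phenotypes a phenotype data.frame (see [read_phenotypes()]).
#' @param phenotype name of the phenotype column to threshold.
#' @param min_value retain subjects with value strictly greater than this
#'   (default 0, i.e. any positive response).
#' @return Character vector of retained subject ids (unique).
#' @export
filter_responders <- function(phenotypes, phenotype, min_value = 0) {
  if (!phenotype %in% names(phenotypes))
    ps_stop("phenotype '%s' not found in table", phenotype)
  v <- phenotypes[[phenotype]]
  if (anyNA(v)) ps_stop("phenotype '%s' has missing values", phenotype)
  keep <- v > min_value
  ids <- unique(phenotypes$subject_id[keep])
  removed <- length(unique(phenotypes$subject_id)) - length(ids)
  ps_log("filter_responders: removed %d subject(s) with %s <= %g; %d retained",
         removed, phenotype, min_value, length(ids))
  ids
}
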