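# independent reference implementations ("oracles") shared across test files.
# They are deliberately naive — explicit loops and quantifiers — and never
# call the package code paths they are used to check.

# literal positional-enrichment reference: enumerate EVERY gene-index
# interval, shrink to canonical form, deduplicate, score by pmf summation,
# then apply each of the six rules by explicit quantifier.
pge_oracle <- function(ann_df, interest, baseline = "genome") {
  ann_df <- ann_df[order(ann_df$chrom, ann_df$start, ann_df$end), ]
  N <- nrow(ann_df); K <- length(interest)
  cands <- NULL
  for (ch in unique(ann_df$chrom)) {
    cdf <- ann_df[ann_df$chrom == ch, ]
    pos <- which(cdf$gene_id %in% interest)
    for (i in seq_len(nrow(cdf))) for (j in i:nrow(cdf)) {
      inside <- pos[pos >= i & pos <= j]
      if (!length(inside)) next
      f <- min(inside); l <- max(inside)           # canonical shrink
      cands <- rbind(cands, data.frame(chrom = ch, first = f, last = l,
                                       n = l - f + 1L,
                                       k = sum(pos >= f & pos <= l)))
    }
  }
  cands <- unique(cands)
  cands$p <- mapply(function(n, k) tail_by_summation(N, K, n, k), cands$n, cands$k)
  ok <- logical(nrow(cands))
  for (a in seq_len(nrow(cands))) {
    ca <- cands[a, ]
    keep <- TRUE
    if (ca$k < 2) keep <- FALSE
    if (keep) for (b in seq_len(nrow(cands))) {
      cb <- cands[b, ]
      if (cb$chrom != ca$chrom || a == b) next
      contains_a <- cb$first <= ca$first && cb$last >= ca$last &&
        !(cb$first == ca$first && cb$last == ca$last)
      inside_a <- ca$first <= cb$first && ca$last >= cb$last &&
        !(cb$first == ca$first && cb$last == ca$last)
      if (contains_a && cb$k > ca$k && (cb$n - cb$k) == (ca$n - ca$k)) keep <- FALSE # R3
      if (contains_a && cb$k / cb$n > ca$k / ca$n) keep <- FALSE                     # R4
      if (inside_a && cb$p < ca$p) keep <- FALSE                                     # R5
      expected <- if (baseline == "genome") cb$n * K / N else cb$n * ca$k / ca$n
      if (inside_a && cb$k < expected) keep <- FALSE                                 # R6
    }
    ok[a] <- keep
  }
  cands[ok, c("chrom", "first", "last", "n", "k", "p")]
}

region_key <- function(df) sort(paste(df$chrom, df$first, df$last))

# full-enumeration quantitative SAM reference: per-gene lm fits, every
# permutation of the phenotype generated recursively, the same delta-grid /
# mean-false-count / prefix-min q definitions written as plain loops.
enumerate_perms <- function(n) {
  if (n == 1) return(list(1L))
  out <- list()
  for (sub in enumerate_perms(n - 1L)) for (pos in 0:(n - 1L))
    out[[length(out) + 1L]] <- append(sub, n, after = pos)
  out
}

qsam_oracle <- function(v, y, s0, n_delta = 100) {
  n <- length(y)
  score <- function(yy) {
    vapply(seq_len(nrow(v)), function(g) {
      fit <- stats::lm(v[g, ] ~ yy)
      # a gene tracking the phenotype exactly fits perfectly; the zero
      # residual warning is the expected behaviour here
      cf <- suppressWarnings(summary(fit))$coefficients
      b <- cf["yy", "Estimate"]
      s <- cf["yy", "Std. Error"]
      b / (s + s0)
    }, numeric(1))
  }
  d_obs <- score(y)
  perms <- enumerate_perms(n)
  d_star <- lapply(perms, function(p) score(y[p]))
  deltas <- seq(0, max(abs(d_obs)), length.out = n_delta)
  deltas[n_delta] <- max(abs(d_obs))
  fdr <- numeric(n_delta)
  n_called <- integer(n_delta)
  for (i in seq_len(n_delta)) {
    n_called[i] <- sum(abs(d_obs) >= deltas[i])
    false_counts <- vapply(d_star, function(d) sum(abs(d) >= deltas[i]), numeric(1))
    fdr[i] <- if (n_called[i] == 0) 0 else min(1, mean(false_counts) / n_called[i])
  }
  q <- vapply(seq_len(nrow(v)), function(g) {
    eligible <- deltas <= abs(d_obs[g])
    min(fdr[eligible])
  }, numeric(1))
  list(d = d_obs, q = q, deltas = deltas, n_called = n_called, fdr = fdr,
       n_perms = length(perms))
}
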