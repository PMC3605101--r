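# shared fixture builders; everything is generated in code, no files shipped

options(phenosam.verbose = FALSE)

rand_matrix <- function(ngene, nsamp, seed = 1, sd = 1, mean = 8) {
  set.seed(seed)
  m <- matrix(rnorm(ngene * nsamp, mean, sd), ngene, nsamp,
              dimnames = list(sprintf("g%03d", seq_len(ngene)),
                              sprintf("s%02d", seq_len(nsamp))))
  m
}

rand_em <- function(ngene, nsamp, seed = 1, ...) {
  expression_matrix(rand_matrix(ngene, nsamp, seed, ...))
}

# a small annotation data.frame: one chromosome, unit-spaced genes
line_annotation <- function(n, chrom = "chr1", prefix = "g") {
  data.frame(gene_id = sprintf("%s%03d", prefix, seq_len(n)),
             chrom = chrom,
             start = (seq_len(n) - 1L) * 1000L,
             end = (seq_len(n) - 1L) * 1000L + 500L,
             stringsAsFactors = FALSE)
}

# independent hypergeometric upper tail by explicit pmf summation
tail_by_summation <- function(N, K, n, k) {
  if (k > min(n, K)) return(0)
  i <- k:min(n, K)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# independent per-gene least squares via stats::lm
lm_slope_se <- function(x_row, y) {
  fit <- summary(stats::lm(x_row ~ y))$coefficients
  c(b = fit["y", "Estimate"], s = fit["y", "Std. Error"])
}
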