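## Positional gene enrichment: exhaustive multi-resolution scan for
## chromosomal regions over-represented for genes of interest, pruned by six
## filtering rules. A region is identified by its span of gene indices in
## chromosome sort order; canonical regions start and end on interest genes.

# normalize a GRanges or data.frame annotation to a sorted frame of
# (gene_id, chrom, start, end) in (chrom, start) order
as_annotation_frame <- function(ann) {
  if (methods::is(ann, "GRanges")) {
    df <- data.frame(gene_id = names(ann),
                     chrom = as.character(GenomicRanges::seqnames(ann)),
                     start = GenomicRanges::start(ann) - 1L,  # back to 0-based
                     end = GenomicRanges::end(ann),
                     stringsAsFactors = FALSE)
  } else {
    df <- as.data.frame(ann, stringsAsFactors = FALSE)
    need <- c("gene_id", "chrom", "start", "end")
    miss <- setdiff(need, names(df))
    if (length(miss))
      ps_stop("annotation is missing column(s): %s", paste(miss, collapse = ", "))
  }
  if (anyDuplicated(df$gene_id)) ps_stop("duplicate gene ids in annotation")
  if (any(df$start >= df$end)) ps_stop("annotation has records with start >= end")
  df[order(df$chrom, df$start, df$end), , drop = FALSE]
}

#' Enumerate canonical candidate regions
#'
#' Per chromosome (genes in start-coordinate order), the candidates are
#' exactly the gene-index intervals whose first and last genes are interest
#' genes. Canonical form guarantees that no smaller region contains the same
#' interest genes, so the minimality rule holds by construction; a
#' chromosome with m interest genes yields `choose(m, 2) + m` candidates.
#'
#' @param ann a `GRanges` (or data.frame with `gene_id`, `chrom`, `start`,
#'   `end`) of gene coordinates.
#' @param interest character vector of interest gene ids (subset of the
#'   annotation).
#' @return A data.frame of candidates: `chrom`, `first`, `last` (gene
#'   indices within the chromosome sort order), `start`, `end` (bp span),
#'   `n` (genes inside), `k` (interest genes inside).
#' @export
candidate_regions <- function(ann, interest) {
  df <- as_annotation_frame(ann)
  interest <- unique(interest)
  missing <- setdiff(interest, df$gene_id)
  if (length(missing))
    ps_stop("interest gene(s) absent from annotation: %s",
            paste(head(missing, 5), collapse = ", "))
  if (!length(interest)) {
    warning("empty interest set: no candidate regions")
    return(data.frame(chrom = character(0), first = integer(0),
                      last = integer(0), start = integer(0), end = integer(0),
                      n = integer(0), k = integer(0)))
  }
  out <- lapply(split(df, df$chrom), function(cdf) {
    pos <- which(cdf$gene_id %in% interest)
    m <- length(pos)
    if (!m) return(NULL)
    pairs <- which(upper.tri(matrix(0, m, m), diag = TRUE), arr.ind = TRUE)
    i <- pos[pairs[, "row"]]; j <- pos[pairs[, "col"]]
    data.frame(chrom = cdf$chrom[1], first = i, last = j,
               start = cdf$start[i], end = cdf$end[j],
               n = j - i + 1L,
               k = pairs[, "col"] - pairs[, "row"] + 1L,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Hypergeometric over-representation p-value of a region
#'
#' Upper-tail probability that a region of `n` genes contains at least `k`
#' interest genes when `K` of the `N` genome genes are of interest:
#' `p = sum_{i=k}^{min(n,K)} C(K,i) C(N-K,n-i) / C(N,n)`.
#'
#' @param n genes in the region.
#' @param k interest genes in the region.
#' @param N total annotated genes.
#' @param K total interest genes.
#' @return The upper-tail p-value(s); vectorized over `n`, `k`.
#' @export
region_pvalue <- function(n, k, N, K) {
  if (any(k > pmin(n, K)) || any(n > N) || any(k < 0))
    ps_stop("invalid hypergeometric parameters (need k <= min(n, K), n <= N)")
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

# strict containment of candidate a inside candidate b (gene-index spans,
# same chromosome assumed)
contains_strict <- function(of, ol, if_, il) {
  of <= if_ & ol >= il & !(of == if_ & ol == il)
}

#' Apply the six positional-enrichment filtering rules
#'
#' A candidate region survives iff:
#' \describe{
#'   \item{Rule 1}{it contains at least two interest genes (`k >= 2`);}
#'   \item{Rule 2}{no smaller region contains the same interest genes —
#'     holds by canonical construction;}
#'   \item{Rule 3}{no bigger candidate has more interest genes and the same
#'     number of non-interest genes (regions must be maximal among
#'     cost-free extensions);}
#'   \item{Rule 4}{no strictly containing candidate has a strictly higher
#'     interest fraction `k/n`;}
#'   \item{Rule 5}{no strictly contained candidate has a strictly smaller
#'     p-value;}
#'   \item{Rule 6}{it contains no strictly contained canonical sub-region
#'     with fewer interest genes than its genome-wide expectation
#'     `n_sub * K / N` (`baseline = "genome"`), or than the parent region's
#'     own rate `n_sub * k/n` (`baseline = "parent"`).}
#' }
#' All comparisons are strict, so ties retain both regions. The audit trail
#' records the first failed rule for every rejected candidate.
#'
#' @param cands candidate data.frame from [candidate_regions()].
#' @param N,K genome-wide gene and interest-gene counts.
#' @param baseline expectation baseline for Rule 6: `"genome"` (default) or
#'   `"parent"`.
#' @return A `pge_result` list: `regions` (surviving candidates with `p`),
#'   `rejected` (rejected candidates with `p` and `failed_rule`), `N`, `K`.
#' @export
apply_rules <- function(cands, N, K, baseline = c("genome", "parent")) {
  baseline <- match.arg(baseline)
  cands$p <- region_pvalue(cands$n, cands$k, N, K)
  fail <- rep(NA_character_, nrow(cands))
  for (ch in unique(cands$chrom)) {
    ci <- which(cands$chrom == ch)
    cc <- cands[ci, ]
    for (a in seq_along(ci)) {
      fa <- cc$first[a]; la <- cc$last[a]
      contain_a <- contains_strict(cc$first, cc$last, fa, la)   # others containing a
      within_a <- contains_strict(fa, la, cc$first, cc$last)    # others inside a
      rule <- if (cc$k[a] < 2) "R1"
      else if (any(contain_a & cc$k > cc$k[a] &
                   (cc$n - cc$k) == (cc$n[a] - cc$k[a]))) "R3"
      else if (any(contain_a & cc$k / cc$n > cc$k[a] / cc$n[a])) "R4"
      else if (any(within_a & cc$p < cc$p[a])) "R5"
      else {
        expected_sub <- if (baseline == "genome") cc$n * K / N
                        else cc$n * cc$k[a] / cc$n[a]
        if (any(within_a & cc$k < expected_sub)) "R6" else NA_character_
      }
      fail[ci[a]] <- rule
    }
  }
  keep <- is.na(fail)
  regions <- cands[keep, , drop = FALSE]
  regions <- regions[order(regions$p, regions$chrom, regions$first), , drop = FALSE]
  rejected <- cands[!keep, , drop = FALSE]
  rejected$failed_rule <- fail[!keep]
  rownames(regions) <- rownames(rejected) <- NULL
  structure(list(regions = regions, rejected = rejected, N = N, K = K),
            class = "pge_result")
}

#' Positional gene enrichment scan
#'
#' Full pipeline: enumerate canonical candidates, score each with the
#' genome-wide hypergeometric upper tail, prune with the six rules, and
#' report surviving regions with `p <= p_gate`. Deterministic and
#' independent of input record order. An optional label-permutation null
#' (`perm_fdr > 0` rounds of shuffling which genes are "of interest" while
#' keeping all positions fixed) reports how often a pure-noise interest set
#' yields any gated region.
#'
#' @param ann a `GRanges` or annotation data.frame.
#' @param interest character vector of interest gene ids.
#' @param p_gate p-value gate for reported regions (default 0.01).
#' @param baseline Rule 6 baseline, `"genome"` (default) or `"parent"`.
#' @param perm_fdr number of interest-label permutation rounds (0 = off).
#' @param seed seed for the permutation null.
#' @return A `pge_result` (see [apply_rules()]) whose `regions` are gated at
#'   `p_gate`; all rule-surviving regions are kept in `all_surviving`. When
#'   `perm_fdr > 0`, `perm_null` is a data.frame with one row per round
#'   (`n_regions` gated, `min_p`).
#' @export
pge_scan <- function(ann, interest, p_gate = 0.01,
                     baseline = c("genome", "parent"), perm_fdr = 0, seed = 1) {
  baseline <- match.arg(baseline)
  df <- as_annotation_frame(ann)
  interest <- unique(interest)
  drop_n <- length(setdiff(interest, df$gene_id))
  if (drop_n) {
    ps_log("pge_scan: %d interest gene(s) not in annotation; dropped", drop_n)
    interest <- intersect(interest, df$gene_id)
  }
  N <- nrow(df); K <- length(interest)
  scan_once <- function(int) {
    cands <- candidate_regions(df, int)
    if (!nrow(cands))
      return(structure(list(regions = cands, rejected = cands, N = N, K = K),
                       class = "pge_result"))
    apply_rules(cands, N, K, baseline = baseline)
  }
  res <- scan_once(interest)
  res$all_surviving <- res$regions
  res$regions <- res$regions[res$regions$p <= p_gate, , drop = FALSE]
  res$p_gate <- p_gate
  if (perm_fdr > 0) {
    res$perm_null <- do.call(rbind, lapply(seq_len(perm_fdr), function(r) {
      set.seed(derive_seed(seed, r))
      ri <- sample(df$gene_id, K)
      rr <- scan_once(ri)
      gated <- rr$regions[rr$regions$p <= p_gate, , drop = FALSE]
      data.frame(round = r, n_regions = nrow(gated),
                 min_p = if (nrow(rr$regions)) min(rr$regions$p) else NA_real_)
    }))
    ps_log("pge_scan: permutation null: %d / %d rounds with any region at p <= %g",
           sum(res$perm_null$n_regions > 0), perm_fdr, p_gate)
  }
  ps_log("pge_scan: N = %d, K = %d; %d candidate-surviving, %d at p <= %g",
         N, K, nrow(res$all_surviving), nrow(res$regions), p_gate)
  res
}

#' @export
print.pge_result <- function(x, ...) {
  cat(sprintf("pge_result: N = %d genes, K = %d of interest; %d surviving region(s)\n",
              x$N, x$K, nrow(x$regions)))
  if (nrow(x$regions)) print(as.data.frame(x$regions))
  invisible(x)
}
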