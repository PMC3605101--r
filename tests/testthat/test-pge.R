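test_that("candidate enumeration is combinatorially exact", {
  ann <- line_annotation(12)
  interest <- ann$gene_id[c(2, 5, 9)]
  cands <- candidate_regions(ann, interest)
  expect_identical(nrow(cands), 6L)                    # C(3,2) + 3
  expect_setequal(paste(cands$first, cands$last),
                  c("2 2", "5 5", "9 9", "2 5", "5 9", "2 9"))
  expect_identical(cands$k[cands$first == 2 & cands$last == 9], 3L)
  expect_identical(cands$n[cands$first == 2 & cands$last == 9], 8L)

  # m = 1 -> exactly the singleton
  c1 <- candidate_regions(ann, ann$gene_id[7])
  expect_identical(nrow(c1), 1L)
  expect_identical(c(c1$first, c1$last, c1$n, c1$k), c(7L, 7L, 1L, 1L))

  expect_warning(c0 <- candidate_regions(ann, character(0)), "empty interest")
  expect_identical(nrow(c0), 0L)

  # random chromosome vs brute-force interval enumeration
  set.seed(19)
  ann60 <- line_annotation(60)
  int8 <- sample(ann60$gene_id, 8)
  cands60 <- candidate_regions(ann60, int8)
  expect_identical(nrow(cands60), as.integer(choose(8, 2) + 8))
  pos <- which(ann60$gene_id %in% int8)
  brute <- unique(do.call(rbind, lapply(seq_len(60), function(i)
    do.call(rbind, lapply(i:60, function(j) {
      inside <- pos[pos >= i & pos <= j]
      if (!length(inside)) return(NULL)
      data.frame(first = min(inside), last = max(inside))
    })))))
  expect_setequal(paste(cands60$first, cands60$last),
                  paste(brute$first, brute$last))
})

test_that("region p-values equal explicit hypergeometric summation", {
  expect_equal(region_pvalue(3, 3, 10, 3), 1 / 120, tolerance = 1e-15)
  for (N in c(8, 15, 25, 40)) {
    for (K in unique(c(1, 3, N %/% 2))) {
      for (n in unique(c(1, 2, N %/% 3, N))) {
        for (k in 0:min(n, K)) {
          expect_equal(region_pvalue(n, k, N, K),
                       tail_by_summation(N, K, n, k), tolerance = 1e-12)
        }
      }
    }
  }
  # a region holding exactly its expected count is unremarkable
  expect_gt(region_pvalue(100, 10, 400, 40), 0.3)
  # enlarging a region at fixed k can only worsen p
  p_seq <- region_pvalue(5:20, 3, 200, 15)
  expect_true(all(diff(p_seq) >= 0))
  expect_error(region_pvalue(5, 6, 10, 8), "invalid")
})

test_that("the six rules prune exactly as their definitions demand", {
  # singleton: rejected by Rule 1 with audit
  ann <- line_annotation(20)
  res1 <- apply_rules(candidate_regions(ann, ann$gene_id[4]), N = 100, K = 5)
  expect_identical(nrow(res1$regions), 0L)
  expect_identical(res1$rejected$failed_rule, "R1")

  # two adjacent interest genes, nothing between: survives all rules
  res2 <- apply_rules(candidate_regions(ann, ann$gene_id[c(7, 8)]), N = 100, K = 5)
  surv <- res2$regions
  expect_identical(nrow(surv), 1L)
  expect_identical(c(surv$first, surv$last, surv$n, surv$k), c(7L, 8L, 2L, 2L))
  expect_lt(surv$p, 1)

  # nested candidates: container with worse p is rejected by R5
  # interest at 5,6 (tight pair) and 15: region (5,15) contains (5,6)
  cands <- candidate_regions(ann, ann$gene_id[c(5, 6, 15)])
  res3 <- apply_rules(cands, N = 20, K = 3)
  rej <- res3$rejected
  big <- rej[rej$first == 5 & rej$last == 15, ]
  expect_identical(big$failed_rule, "R5")

  # R3: a pair inside a cost-free triple is rejected as non-maximal
  ann2 <- line_annotation(30)
  cands2 <- candidate_regions(ann2, ann2$gene_id[c(10, 11, 12)])
  res4 <- apply_rules(cands2, N = 400, K = 20)
  rej2 <- res4$rejected
  expect_identical(rej2$failed_rule[rej2$first == 10 & rej2$last == 11], "R3")
  expect_true(any(res4$regions$first == 10 & res4$regions$last == 12))
})

test_that("pge_scan equals the literal all-intervals oracle", {
  set.seed(23)
  for (rep in 1:6) {
    n <- sample(20:60, 1)
    ann <- line_annotation(n)
    m <- sample(3:8, 1)
    interest <- sample(ann$gene_id, m)
    res <- pge_scan(ann, interest, p_gate = 1)
    orc <- pge_oracle(ann, interest)
    expect_identical(region_key(res$all_surviving), region_key(orc))
    # and scoring agrees region by region
    key <- paste(res$all_surviving$chrom, res$all_surviving$first,
                 res$all_surviving$last)
    okey <- paste(orc$chrom, orc$first, orc$last)
    expect_equal(res$all_surviving$p[order(key)], orc$p[order(okey)],
                 tolerance = 1e-12)
  }
})

test_that("the parent-rate Rule 6 baseline is also oracle-consistent", {
  set.seed(29)
  for (rep in 1:3) {
    ann <- line_annotation(40)
    interest <- sample(ann$gene_id, 6)
    res <- pge_scan(ann, interest, p_gate = 1, baseline = "parent")
    orc <- pge_oracle(ann, interest, baseline = "parent")
    expect_identical(region_key(res$all_surviving), region_key(orc))
  }
})

test_that("scan output is invariant to record order and non-interest labels", {
  set.seed(37)
  ann <- line_annotation(50)
  interest <- sample(ann$gene_id, 6)
  res <- pge_scan(ann, interest, p_gate = 1)

  shuf <- ann[sample(nrow(ann)), ]
  res2 <- pge_scan(shuf, interest, p_gate = 1)
  expect_identical(region_key(res$all_surviving), region_key(res2$all_surviving))

  # renaming non-interest genes changes nothing
  ann3 <- ann
  ni <- !ann3$gene_id %in% interest
  ann3$gene_id[ni] <- paste0("renamed_", ann3$gene_id[ni])
  res3 <- pge_scan(ann3, interest, p_gate = 1)
  expect_identical(region_key(res$all_surviving), region_key(res3$all_surviving))
  expect_equal(res$all_surviving$p, res3$all_surviving$p)
})

test_that("a planted cluster is detected and a uniform scatter rarely is", {
  # planted 3-gene cluster among 400 genes with K = 20 interest genes
  cfg <- simulation_config(n_genes = 400, n_subjects = 10, n_planted = 20, seed = 41)
  tr <- simulate_cohort(cfg)$truth
  gs <- simulate_genome(sprintf("G%04d", 1:400), tr, cluster_size = 3, seed = 41)
  res <- pge_scan(gs$annotation, tr$planted_genes$gene_id, p_gate = 0.01)
  reg <- gs$truth$planted_region
  hit <- res$regions$chrom == reg$chrom &
    res$regions$start <= reg$start & res$regions$end >= reg$end
  expect_true(any(hit))
  expect_lt(min(res$regions$p[hit]), 0.01)

  # empirical null: with the interest genes scattered uniformly the best
  # region p is orders of magnitude above the planted cluster's, so the
  # planted signal is clearly separated from chance clustering
  planted_p <- min(res$regions$p[hit])
  null_min_p <- vapply(1:25, function(s) {
    set.seed(s + 5000)
    ann <- line_annotation(400)
    interest <- sample(ann$gene_id, 20)
    r <- pge_scan(ann, interest, p_gate = 1)
    if (nrow(r$all_surviving)) min(r$all_surviving$p) else 1
  }, numeric(1))
  expect_gt(median(null_min_p), 10 * planted_p)
  # and chance clustering at the planted-cluster significance is rare
  expect_lte(mean(null_min_p <= planted_p), 0.2)
})

test_that("surviving regions never nest with a dominated container", {
  set.seed(43)
  ann <- line_annotation(60)
  interest <- sample(ann$gene_id, 8)
  res <- pge_scan(ann, interest, p_gate = 1)
  s <- res$all_surviving
  if (nrow(s) > 1) for (a in seq_len(nrow(s))) for (b in seq_len(nrow(s))) {
    if (a == b || s$chrom[a] != s$chrom[b]) next
    strictly_inside <- s$first[b] <= s$first[a] && s$last[b] >= s$last[a] &&
      !(s$first[b] == s$first[a] && s$last[b] == s$last[a])
    if (strictly_inside) {
      # R5: a surviving container cannot hold a strictly better-p survivor
      expect_false(s$p[a] < s$p[b])
      # R4: a surviving region cannot sit inside a higher-fraction container
      expect_false(s$k[b] / s$n[b] > s$k[a] / s$n[a])
    }
  }
})
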