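test_that("cohort simulation is bit-identical under a fixed seed", {
  cfg <- simulation_config(n_genes = 50, n_subjects = 12, n_planted = 5, seed = 99)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$expression$values, b$expression$values)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$truth, b$truth)

  cfgp <- simulation_config(n_genes = 30, n_subjects = 8, n_planted = 3,
                            paired = TRUE, seed = 99)
  ap <- simulate_cohort(cfgp); bp <- simulate_cohort(cfgp)
  expect_identical(ap$expression$pre$values, bp$expression$pre$values)
  expect_identical(ap$expression$post$values, bp$expression$post$values)

  ns <- simulate_network(gene_ids(a$expression), a$truth, seed = 3,
                         targets_per_regulator = 10)
  ns2 <- simulate_network(gene_ids(a$expression), a$truth, seed = 3,
                          targets_per_regulator = 10)
  expect_identical(ns$network, ns2$network)

  gs <- simulate_genome(gene_ids(a$expression), a$truth, cluster_size = 3, seed = 4)
  gs2 <- simulate_genome(gene_ids(a$expression), a$truth, cluster_size = 3, seed = 4)
  expect_identical(as.data.frame(gs$annotation), as.data.frame(gs2$annotation))
})

test_that("a cohort without planted genes behaves as a correlation null", {
  n_genes <- 200; n_sub <- 30
  # Bonferroni cutoff at family level 0.01: under the null the familywise
  # exceedance probability is ~1%, so nearly every seed stays below it
  crit_t <- qt(1 - 0.01 / n_genes / 2, df = n_sub - 2)
  crit_r <- crit_t / sqrt(crit_t^2 + n_sub - 2)
  below <- vapply(1:100, function(s) {
    cfg <- simulation_config(n_genes = n_genes, n_subjects = n_sub,
                             n_planted = 0, seed = s)
    sim <- simulate_cohort(cfg)
    expect_identical(nrow(sim$truth$planted_genes), 0L)
    r <- cor(t(sim$expression$values), sim$phenotypes$lean_mass_change)
    max(abs(r)) < crit_r
  }, logical(1))
  expect_gte(mean(below), 0.95)
})

test_that("planted genes reach the target population correlation", {
  rs <- vapply(1:1000, function(s) {
    cfg <- simulation_config(n_genes = 2, n_subjects = 40, n_planted = 1,
                             effect_rho = 0.6, seed = s)
    sim <- simulate_cohort(cfg)
    g <- sim$truth$planted_genes$gene_id
    sgn <- sim$truth$planted_genes$sign
    sgn * cor(sim$expression$values[g, ], sim$phenotypes$lean_mass_change)
  }, numeric(1))
  expect_lt(abs(mean(rs) - 0.6), 0.03)
})

test_that("paired simulation places the signal on the change score only", {
  cfg <- simulation_config(n_genes = 100, n_subjects = 40, n_planted = 10,
                           effect_rho = 0.7, paired = TRUE, seed = 5)
  sim <- simulate_cohort(cfg)
  y <- sim$phenotypes$lean_mass_change
  planted <- sim$truth$planted_genes
  ch <- sim$expression$post$values - sim$expression$pre$values
  r_change <- cor(t(ch[planted$gene_id, , drop = FALSE]), y)[, 1]
  expect_true(all(abs(r_change * planted$sign - 0.7) < 0.35))
  r_pre <- cor(t(sim$expression$pre$values[planted$gene_id, , drop = FALSE]), y)[, 1]
  expect_lt(max(abs(r_pre)), 0.5)  # pre is independent baseline noise
})

test_that("invalid simulation configs are rejected", {
  expect_error(simulation_config(n_planted = 20, n_genes = 10), "n_planted")
  expect_error(simulation_config(effect_rho = 1), "effect_rho")
  expect_error(simulation_config(noise_sd = 0), "noise_sd")
  cfg <- simulation_config(n_genes = 10, n_subjects = 6, n_planted = 2, seed = 1)
  tr <- simulate_cohort(cfg)$truth
  expect_error(simulate_network(letters[1:5], tr, targets_per_regulator = 9),
               "exceeds universe")
  expect_error(simulate_genome(sprintf("G%04d", 1:10), tr, cluster_size = 5),
               "cluster_size")
})

test_that("planted network edges are fully sign-consistent at consistency 1", {
  cfg <- simulation_config(n_genes = 200, n_subjects = 20, n_planted = 30, seed = 2)
  tr <- simulate_cohort(cfg)$truth
  ns <- simulate_network(sprintf("G%04d", 1:200), tr, n_regulators = 5,
                         targets_per_regulator = 20, consistency = 1, seed = 8)
  pe <- ns$truth$planted_regulator$edges
  truth_sign <- tr$planted_genes$sign[match(pe$target, tr$planted_genes$gene_id)]
  expect_identical(pe$sign, truth_sign)
})

test_that("consistency 0.5 gives a near-zero activation z for the planted regulator", {
  # Monte-Carlo on the z formula: targets half agree, half disagree
  ok <- vapply(1:100, function(s) {
    cfg <- simulation_config(n_genes = 200, n_subjects = 20, n_planted = 40, seed = s)
    tr <- simulate_cohort(cfg)$truth
    ns <- simulate_network(sprintf("G%04d", 1:200), tr, n_regulators = 1,
                           targets_per_regulator = 30, consistency = 0.5, seed = s)
    pe <- ns$truth$planted_regulator$edges
    truth_sign <- tr$planted_genes$sign[match(pe$target, tr$planted_genes$gene_id)]
    agree <- pe$sign * truth_sign
    z <- sum(agree) / sqrt(length(agree))
    abs(z) < 2
  }, logical(1))
  expect_gte(mean(ok), 0.90)
})

test_that("decoy target overlap with planted genes matches hypergeometric expectation", {
  n_genes <- 400; n_planted <- 40; tpr <- 30
  overlaps <- unlist(lapply(1:40, function(s) {
    cfg <- simulation_config(n_genes = n_genes, n_subjects = 10,
                             n_planted = n_planted, seed = s)
    tr <- simulate_cohort(cfg)$truth
    ns <- simulate_network(sprintf("G%04d", 1:n_genes), tr, n_regulators = 4,
                           targets_per_regulator = tpr, consistency = 1, seed = s)
    decoys <- ns$network[ns$network$regulator != ns$truth$planted_regulator$regulator_id, ]
    vapply(split(decoys$target, decoys$regulator),
           function(tg) sum(tg %in% tr$planted_genes$gene_id), numeric(1))
  }))
  expected <- n_planted * tpr / n_genes               # closed-form expectation
  se <- sqrt(expected * (1 - tpr / n_genes) / length(overlaps))
  expect_lt(abs(mean(overlaps) - expected), 4 * se)
})

test_that("simulated genomes are sorted, non-overlapping, with an intact cluster", {
  cfg <- simulation_config(n_genes = 200, n_subjects = 10, n_planted = 20, seed = 3)
  tr <- simulate_cohort(cfg)$truth
  gs <- simulate_genome(sprintf("G%04d", 1:200), tr, cluster_size = 4, seed = 6)
  df <- as.data.frame(gs$annotation)
  expect_true(all(df$start <= df$end))
  for (ch in unique(df$seqnames)) {
    cdf <- df[df$seqnames == ch, ]
    expect_true(all(diff(cdf$start) > 0))
    expect_true(all(cdf$start[-1] > cdf$end[-nrow(cdf)])) # non-overlapping
  }
  # the planted region holds exactly cluster_size interest genes, consecutive
  reg <- gs$truth$planted_region
  ord <- names(gs$annotation)[as.character(GenomicRanges::seqnames(gs$annotation)) == reg$chrom]
  idx <- which(ord %in% reg$genes)
  expect_identical(length(idx), 4L)
  expect_identical(diff(idx), rep(1L, 3))
  expect_true(all(reg$genes %in% tr$planted_genes$gene_id))
})

test_that("scattered planted genes are placed uniformly along the genome", {
  # pooled normalized slot indices across seeds vs the uniform distribution
  u <- unlist(lapply(1:50, function(s) {
    cfg <- simulation_config(n_genes = 200, n_subjects = 10, n_planted = 12, seed = s)
    tr <- simulate_cohort(cfg)$truth
    gs <- simulate_genome(sprintf("G%04d", 1:200), tr, cluster_size = 3, seed = s)
    scattered <- setdiff(tr$planted_genes$gene_id, gs$truth$planted_region$genes)
    pos <- match(scattered, names(gs$annotation))
    (pos - 0.5) / 200
  }))
  expect_gt(suppressWarnings(ks.test(u, "punif")$p.value), 0.01)
})
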