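#' Configuration for a synthetic cohort
#'
#' Defaults describe the kind of training study the pipeline targets: 44
#' subjects whose phenotype (percent change in upper-leg lean mass) spans a
#' wide continuous range of roughly -3% to +28%, measured on ~1000 genes of
#' which a minority correlate linearly with the phenotype. The phenotype is
#' drawn uniformly over `phenotype_range`, mirroring a deliberately
#' continuum-based recruitment design (a Gaussian option is available in
#' [simulate_cohort()]).
#'
#' The planted effect size is parameterized by the target population Pearson
#' correlation `effect_rho` rather than a raw slope, so statistical power is
#' interpretable independently of `noise_sd`: the slope used is
#' `beta = rho * noise_sd / (sd(y) * sqrt(1 - rho^2))`.
#'
#' @param n_genes number of genes in the simulated universe.
#' @param n_subjects number of subjects.
#' @param n_planted number of genes whose expression (or pre/post change)
#'   correlates with the phenotype.
#' @param effect_rho target population correlation of planted genes with the
#'   phenotype, `|rho| < 1`.
#' @param noise_sd residual standard deviation on the log2 scale.
#' @param paired if `TRUE`, simulate pre/post matrices with the signal on
#'   the change score.
#' @param phenotype_range `c(min, max)` of the uniform phenotype.
#' @param phenotype_name column name for the phenotype (default
#'   `"lean_mass_change"`).
#' @param cohort cohort label stamped into the phenotype table.
#' @param seed integer seed; all outputs are reproducible from it.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_genes = 1000, n_subjects = 44, n_planted = 50,
                              effect_rho = 0.6, noise_sd = 1, paired = FALSE,
                              phenotype_range = c(-3, 28),
                              phenotype_name = "lean_mass_change",
                              cohort = "cohort1", seed = 1) {
  if (n_planted < 0 || n_planted > n_genes)
    ps_stop("need 0 <= n_planted <= n_genes")
  if (abs(effect_rho) >= 1)
    ps_stop("|effect_rho| must be < 1 (a planted correlation of 1 needs zero noise)")
  if (noise_sd <= 0) ps_stop("noise_sd must be > 0")
  if (length(phenotype_range) != 2 || diff(phenotype_range) <= 0)
    ps_stop("phenotype_range must be c(min, max) with min < max")
  structure(list(n_genes = n_genes, n_subjects = n_subjects,
                 n_planted = n_planted, effect_rho = effect_rho,
                 noise_sd = noise_sd, paired = paired,
                 phenotype_range = phenotype_range,
                 phenotype_name = phenotype_name, cohort = cohort,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

new_truth <- function(planted) {
  structure(list(planted_genes = planted, planted_regulator = NULL,
                 planted_region = NULL), class = "cohort_truth")
}

#' Simulate a cohort with planted phenotype-correlated genes
#'
#' The continuous phenotype `y` is drawn uniformly over
#' `cfg$phenotype_range` (or from a Gaussian matched to the same mean and SD
#' when `phenotype = "gaussian"`). Each planted gene i receives
#' `x_ij = mu_i + s_i * beta * y_j + eps_ij` with `eps ~ N(0, noise_sd^2)`,
#' the sign `s_i` drawn as +1/-1, and `beta` set so the population
#' correlation with `y` equals `effect_rho`; non-planted genes are pure
#' noise around their baseline. In paired mode the pre matrix is independent
#' baseline noise and the post matrix is `pre + change` where the change
#' score carries the same planted structure, matching a design that
#' correlates expression *change* with phenotype change.
#'
#' @param cfg a [simulation_config()].
#' @param truth optional `cohort_truth` from a previous call; when supplied,
#'   the same planted gene identities and signs are reused so that an
#'   independent replication cohort shares ground truth.
#' @param phenotype `"uniform"` (default) or `"gaussian"`.
#' @return A list with elements `expression` (an `ExpressionMatrix`, or a
#'   list `pre`/`post` in paired mode), `phenotypes` (data.frame), and
#'   `truth` (`cohort_truth` with `planted_genes`: gene_id, sign).
#' @export
simulate_cohort <- function(cfg, truth = NULL, phenotype = c("uniform", "gaussian")) {
  phenotype <- match.arg(phenotype)
  stopifnot(inherits(cfg, "simulation_config"))
  # generator-specific sub-seed: keeps the cohort, network and genome
  # generators on unrelated RNG streams even when given the same user seed
  set.seed(derive_seed(cfg$seed, 1L))
  genes <- sprintf("G%04d", seq_len(cfg$n_genes))
  subjects <- sprintf("S%03d", seq_len(cfg$n_subjects))
  rng <- cfg$phenotype_range
  y <- if (phenotype == "uniform") runif(cfg$n_subjects, rng[1], rng[2])
       else rnorm(cfg$n_subjects, mean = mean(rng), sd = diff(rng) / sqrt(12))
  if (is.null(truth)) {
    planted_id <- sort(sample(genes, cfg$n_planted))
    signs <- if (cfg$n_planted)
      sample(c(-1L, 1L), cfg$n_planted, replace = TRUE) else integer(0)
    truth <- new_truth(data.frame(gene_id = planted_id, sign = signs,
                                  stringsAsFactors = FALSE))
  } else {
    stopifnot(inherits(truth, "cohort_truth"))
    if (!all(truth$planted_genes$gene_id %in% genes))
      ps_stop("supplied truth refers to genes outside this universe")
  }
  # population SD of the phenotype (gaussian option is matched to the same SD)
  sd_y <- diff(rng) / sqrt(12)
  rho <- cfg$effect_rho
  beta <- rho * cfg$noise_sd / (sd_y * sqrt(1 - rho^2))
  mu <- runif(cfg$n_genes, 4, 12)  # per-gene baseline log2 intensity
  signal <- matrix(0, cfg$n_genes, cfg$n_subjects)
  prow <- match(truth$planted_genes$gene_id, genes)
  if (length(prow))
    signal[prow, ] <- outer(truth$planted_genes$sign * beta, y)
  noise <- function() matrix(rnorm(cfg$n_genes * cfg$n_subjects, sd = cfg$noise_sd),
                             cfg$n_genes, cfg$n_subjects)
  ph <- data.frame(subject_id = subjects, cohort = cfg$cohort,
                   timepoint = if (cfg$paired) NA_character_ else "single",
                   stringsAsFactors = FALSE)
  ph[[cfg$phenotype_name]] <- y
  if (cfg$paired) {
    pre <- mu + noise()
    change <- signal + noise()
    post <- pre + change
    dimnames(pre) <- dimnames(post) <- list(genes, subjects)
    ph$timepoint <- "post"  # phenotype is the pre->post change, anchored at post
    expr <- list(pre = expression_matrix(pre), post = expression_matrix(post))
  } else {
    x <- mu + signal + noise()
    dimnames(x) <- list(genes, subjects)
    expr <- expression_matrix(x)
  }
  ps_log("simulate_cohort: %d genes x %d subjects, %d planted (rho = %g, %s)",
         cfg$n_genes, cfg$n_subjects, nrow(truth$planted_genes), rho,
         if (cfg$paired) "paired" else "single-timepoint")
  list(expression = expr, phenotypes = ph, truth = truth)
}

#' Simulate a signed regulator-target network with one planted regulator
#'
#' The planted regulator's targets are drawn from the planted genes (topped
#' up with random genes if there are fewer planted genes than
#' `targets_per_regulator`), and each planted edge sign matches the planted
#' gene's direction with probability `consistency` (so `consistency = 1`
#' yields a perfectly coherent literature network, 0.5 an uninformative
#' one). Decoy regulators draw targets uniformly from the universe with
#' random signs.
#'
#' @param universe character vector of all gene ids.
#' @param truth a `cohort_truth` with planted genes.
#' @param n_regulators total number of regulators (>= 1; the first is the
#'   planted one when any gene is planted).
#' @param targets_per_regulator targets per regulator.
#' @param consistency probability that a planted edge sign matches the
#'   planted gene sign.
#' @param seed integer seed.
#' @return A list with `network` (data.frame regulator/target/sign) and
#'   `truth` (input truth with `planted_regulator` filled in:
#'   `regulator_id` plus its edge table).
#' @export
simulate_network <- function(universe, truth, n_regulators = 20,
                             targets_per_regulator = 25, consistency = 1,
                             seed = 1) {
  stopifnot(inherits(truth, "cohort_truth"))
  if (targets_per_regulator > length(universe))
    ps_stop("targets_per_regulator (%d) exceeds universe size (%d)",
            targets_per_regulator, length(universe))
  set.seed(derive_seed(as.integer(seed), 2L))
  regs <- sprintf("REG%03d", seq_len(n_regulators))
  planted <- truth$planted_genes
  edges <- vector("list", n_regulators)
  planted_reg <- NULL
  start <- 1L
  if (nrow(planted) > 0) {
    n_from_planted <- min(targets_per_regulator, nrow(planted))
    pk <- planted[sample(nrow(planted), n_from_planted), , drop = FALSE]
    match_sign <- runif(n_from_planted) <= consistency
    sgn <- ifelse(match_sign, pk$sign, -pk$sign)
    tg <- pk$gene_id
    extra <- targets_per_regulator - n_from_planted
    if (extra > 0) {
      pool <- setdiff(universe, tg)
      add <- sample(pool, extra)
      tg <- c(tg, add)
      sgn <- c(sgn, sample(c(-1L, 1L), extra, replace = TRUE))
    }
    edges[[1]] <- data.frame(regulator = regs[1], target = tg,
                             sign = as.integer(sgn), stringsAsFactors = FALSE)
    planted_reg <- list(regulator_id = regs[1], edges = edges[[1]])
    start <- 2L
  }
  for (r in seq(from = start, length.out = n_regulators - start + 1L)) {
    tg <- sample(universe, targets_per_regulator)
    edges[[r]] <- data.frame(regulator = regs[r], target = tg,
                             sign = sample(c(-1L, 1L), targets_per_regulator,
                                           replace = TRUE),
                             stringsAsFactors = FALSE)
  }
  net <- do.call(rbind, edges)
  rownames(net) <- NULL
  truth$planted_regulator <- planted_reg
  ps_log("simulate_network: %d regulators x %d targets (consistency = %g)",
         n_regulators, targets_per_regulator, consistency)
  list(network = net, truth = truth)
}

#' Simulate gene coordinates with one planted cluster of interest genes
#'
#' Genes are laid out on four synthetic chromosomes with equal gene counts
#' as sorted, non-overlapping intervals. `cluster_size` of the planted genes
#' are placed in consecutive slots at one random locus (recorded as the
#' planted region); the remaining planted genes are scattered uniformly over
#' the other slots.
#'
#' @param universe character vector of all gene ids.
#' @param truth a `cohort_truth` with planted genes.
#' @param cluster_size number of planted genes forming the cluster
#'   (`<= n_planted`).
#' @param seed integer seed.
#' @param n_chromosomes number of synthetic chromosomes (default 4).
#' @return A list with `annotation` (a `GRanges`, gene ids as names) and
#'   `truth` with `planted_region` filled in (chrom, start, end, genes).
#' @export
simulate_genome <- function(universe, truth, cluster_size = 3, seed = 1,
                            n_chromosomes = 4) {
  stopifnot(inherits(truth, "cohort_truth"))
  planted <- truth$planted_genes$gene_id
  if (cluster_size > length(planted))
    ps_stop("cluster_size (%d) exceeds number of planted genes (%d)",
            cluster_size, length(planted))
  set.seed(derive_seed(as.integer(seed), 3L))
  n <- length(universe)
  chrom_of <- rep(sprintf("chr%d", seq_len(n_chromosomes)), length.out = n)
  chrom_of <- sort(chrom_of)  # equal-sized blocks chr1..chrK
  # per-chromosome interval scaffold: sorted, non-overlapping
  widths <- sample(5000:20000, n, replace = TRUE)
  gaps <- sample(1000:50000, n, replace = TRUE)
  starts <- integer(n); ends <- integer(n)
  for (ch in unique(chrom_of)) {
    i <- which(chrom_of == ch)
    s <- cumsum(gaps[i] + c(0L, widths[i][-length(i)]))
    starts[i] <- s
    ends[i] <- s + widths[i]
  }
  # slot assignment: cluster of planted genes at a random locus
  slots <- seq_len(n)
  cluster_genes <- if (cluster_size > 0) sample(planted, cluster_size) else character(0)
  scatter_genes <- setdiff(planted, cluster_genes)
  occupied <- logical(n)
  if (cluster_size > 0) {
    ch_sizes <- table(chrom_of)
    ch <- sample(names(ch_sizes)[ch_sizes >= cluster_size], 1)
    i <- which(chrom_of == ch)
    at <- sample(length(i) - cluster_size + 1L, 1)
    cluster_slots <- i[at:(at + cluster_size - 1L)]
    occupied[cluster_slots] <- TRUE
  } else cluster_slots <- integer(0)
  free <- slots[!occupied]
  scatter_slots <- if (length(scatter_genes)) sample(free, length(scatter_genes)) else integer(0)
  occupied[scatter_slots] <- TRUE
  rest <- setdiff(universe, c(cluster_genes, scatter_genes))
  gene_at <- character(n)
  gene_at[cluster_slots] <- cluster_genes
  gene_at[scatter_slots] <- scatter_genes
  gene_at[!occupied] <- sample(rest)
  ann <- GenomicRanges::GRanges(
    seqnames = chrom_of,
    ranges = IRanges::IRanges(start = starts + 1L, end = ends))
  names(ann) <- gene_at
  if (cluster_size > 0) {
    truth$planted_region <- list(
      chrom = chrom_of[cluster_slots[1]],
      start = starts[cluster_slots[1]],
      end = ends[cluster_slots[cluster_size]],
      genes = gene_at[cluster_slots])
  }
  ps_log("simulate_genome: %d genes on %d chromosomes, planted cluster of %d",
         n, n_chromosomes, cluster_size)
  list(annotation = ann, truth = truth)
}

#' Write a full simulation to disk
#'
#' Emits every file in the pipeline's external dialects: expression TSV(s),
#' phenotype TSV, network TSV, gene BED, and a `truth.json` for test
#' harnesses.
#'
#' @param sim result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @param network optional network data.frame to write alongside.
#' @param annotation optional `GRanges` annotation to write alongside.
#' @return Invisibly, the directory path.
#' @export
write_simulation <- function(sim, dir, network = NULL, annotation = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(sim$expression, "ExpressionMatrix")) {
    write_expression(sim$expression, file.path(dir, "expression.tsv"))
  } else {
    write_expression(sim$expression$pre, file.path(dir, "expression_pre.tsv"))
    write_expression(sim$expression$post, file.path(dir, "expression_post.tsv"))
  }
  write.table(sim$phenotypes, file.path(dir, "phenotypes.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(network)) write_network(network, file.path(dir, "network.tsv"))
  if (!is.null(annotation)) write_genome(annotation, file.path(dir, "genes.bed"))
  truth <- sim$truth
  tr <- list(planted_genes = truth$planted_genes,
             planted_regulator = if (is.null(truth$planted_regulator)) NULL else
               truth$planted_regulator$regulator_id,
             planted_region = truth$planted_region)
  jsonlite::write_json(tr, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
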