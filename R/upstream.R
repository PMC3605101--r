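#' Build a directional gene signature against a network background
#'
#' The background universe is the intersection of the measured genes with
#' the network's gene universe (targets plus regulators) — mirroring how
#' only a subset of chip probes can be mapped into a curated mediator
#' database. Signature members are the significant genes inside that
#' background, carrying the sign of their association.
#'
#' @param significant a `significant_gene_set` (from [select_significant()])
#'   or any data.frame with columns `gene` and `sign`.
#' @param network a regulator network data.frame
#'   (`regulator`/`target`/`sign`).
#' @param measured the measured universe: an `ExpressionMatrix`, or a
#'   character vector of gene ids.
#' @return A `gene_signature` list: `members` (data.frame `gene`,
#'   `direction`) and `background` (character).
#' @export
make_signature <- function(significant, network, measured) {
  genes_measured <- if (inherits(measured, "ExpressionMatrix")) gene_ids(measured)
                    else as.character(measured)
  net_universe <- union(network$target, network$regulator)
  background <- intersect(genes_measured, net_universe)
  if (!length(background))
    ps_stop("empty background: no measured gene maps to the network")
  keep <- significant$gene %in% background
  members <- data.frame(gene = significant$gene[keep],
                        direction = as.integer(significant$sign[keep]),
                        stringsAsFactors = FALSE)
  if (anyDuplicated(members$gene)) ps_stop("duplicate genes in signature")
  if (!all(members$direction %in% c(-1L, 1L)))
    ps_stop("signature directions must be +1 or -1")
  ps_log("make_signature: %d / %d significant genes mapped; background = %d genes",
         nrow(members), nrow(significant), length(background))
  structure(list(members = members, background = background),
            class = "gene_signature")
}

#' Right-tailed Fisher overlap p-value for one regulator's target set
#'
#' The probability, under the hypergeometric null, of observing at least
#' the realized overlap between the signature and the regulator's targets
#' within the background universe: `P(X >= k)` with `X ~ Hypergeom(N, K,
#' n)` where `N` is the background size, `K` the regulator's targets in the
#' background and `n` the signature size. This equals the right-tailed
#' Fisher exact test on the 2x2 membership table.
#'
#' @param sig a `gene_signature`.
#' @param targets character vector of one regulator's target genes.
#' @return The overlap p-value (scalar in (0, 1]).
#' @export
overlap_pvalue <- function(sig, targets) {
  bg <- sig$background
  K <- length(intersect(targets, bg))
  n <- nrow(sig$members)
  k <- length(intersect(targets, sig$members$gene))
  N <- length(bg)
  if (K == 0) return(NA_real_)
  phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Activation z-score for one regulator
#'
#' Compares each overlapping target's observed direction with the signed
#' literature edge: a target is consistent when `edge_sign * direction =
#' +1`. The z-score `(N_plus - N_minus) / sqrt(N_plus + N_minus)` is
#' positive when the regulator's activation would reproduce the observed
#' directions (regulator "activated") and negative when its inhibition
#' would ("inhibited").
#'
#' @param sig a `gene_signature`.
#' @param edges data.frame with columns `target` and `sign` for one
#'   regulator.
#' @return A list with `n_plus`, `n_minus` and `z` (`NA` when no target
#'   overlaps the signature).
#' @export
activation_zscore <- function(sig, edges) {
  m <- sig$members
  idx <- match(edges$target, m$gene)
  hit <- !is.na(idx)
  if (!any(hit)) return(list(n_plus = 0L, n_minus = 0L, z = NA_real_))
  agree <- edges$sign[hit] * m$direction[idx[hit]]
  n_plus <- sum(agree == 1L)
  n_minus <- sum(agree == -1L)
  list(n_plus = n_plus, n_minus = n_minus,
       z = (n_plus - n_minus) / sqrt(n_plus + n_minus))
}

#' Scan all regulators of a network against a signature
#'
#' Computes the overlap p-value and activation z-score for every regulator,
#' ranks by p ascending (ties by |z| descending, then regulator id), labels
#' each regulator `activated` (z >= z_gate), `inhibited` (z <= -z_gate) or
#' `undetermined`, and flags those passing both the p and z gates.
#' Regulators with no target in the background are untestable: they are
#' reported with `p_overlap = NA` and excluded from ranking. A
#' Benjamini-Hochberg column over testable regulators is emitted for
#' information only; gating is on the raw p-value as is conventional for
#' this analysis.
#'
#' Sign convention: a *positive* z means the mediator's activity increases
#' with the phenotype (its induced targets correlate positively); an
#' inhibited drug signature means the drug target's regulated genes
#' correlate negatively with the phenotype.
#'
#' @param sig a `gene_signature`.
#' @param network regulator network data.frame.
#' @param p_gate overlap p-value gate (default 0.001).
#' @param z_gate absolute activation z gate (default 2).
#' @return An `upstream_result` data.frame with columns `regulator`,
#'   `n_targets_bg`, `n_overlap`, `n_plus`, `n_minus`, `p_overlap`,
#'   `p_bh`, `z`, `state`, `passes`; ranked, with untestable regulators
#'   last.
#' @export
upstream_scan <- function(sig, network, p_gate = 0.001, z_gate = 2) {
  if (!nrow(sig$members)) ps_stop("empty signature")
  if (p_gate <= 0 || p_gate >= 1) ps_stop("'p_gate' must lie in (0, 1)")
  if (z_gate < 0) ps_stop("'z_gate' must be >= 0")
  bg <- sig$background
  regs <- sort(unique(network$regulator))
  rows <- lapply(regs, function(rg) {
    ed <- network[network$regulator == rg & network$target %in% bg, , drop = FALSE]
    K <- length(unique(ed$target))
    zs <- activation_zscore(sig, ed)
    data.frame(regulator = rg, n_targets_bg = K,
               n_overlap = zs$n_plus + zs$n_minus,
               n_plus = zs$n_plus, n_minus = zs$n_minus,
               p_overlap = overlap_pvalue(sig, ed$target),
               z = zs$z, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  testable <- !is.na(out$p_overlap)
  out$p_bh <- NA_real_
  out$p_bh[testable] <- p.adjust(out$p_overlap[testable], method = "BH")
  out$state <- "undetermined"
  out$state[!is.na(out$z) & out$z >= z_gate] <- "activated"
  out$state[!is.na(out$z) & out$z <= -z_gate] <- "inhibited"
  out$passes <- testable & out$p_overlap <= p_gate &
    !is.na(out$z) & abs(out$z) >= z_gate
  ord <- order(!testable, out$p_overlap, -abs(ifelse(is.na(out$z), 0, out$z)),
               out$regulator)
  out <- out[ord, ]
  rownames(out) <- NULL
  attr(out, "p_gate") <- p_gate
  attr(out, "z_gate") <- z_gate
  class(out) <- c("upstream_result", "data.frame")
  ps_log("upstream_scan: %d regulators (%d untestable); %d pass p <= %g and |z| >= %g",
         nrow(out), sum(!testable), sum(out$passes), p_gate, z_gate)
  out
}
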