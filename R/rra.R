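#' Normalized guide ranks for rank aggregation
#'
#' Pools the guide-level p-values of all treatment replicates into one
#' list per tail, ranks them (ascending p, ties broken by the more
#' extreme LFC, then stable input order) and normalizes the ranks to
#' (0, 1] by dividing by the pooled list length.
#'
#' @param p Pooled p-values (length = n_guides * n_replicates).
#' @param lfc Pooled LFCs used for tie-breaking (same length).
#' @param tail `"depletion"` (smaller LFC is more extreme) or
#'   `"enrichment"`.
#' @return Normalized ranks aligned with the input.
#' @export
normalized_ranks <- function(p, lfc = NULL,
                             tail = c("depletion", "enrichment")) {
  tail <- match.arg(tail)
  if (is.null(lfc)) lfc <- numeric(length(p))
  stopifnot(length(p) == length(lfc))
  key <- if (tail == "depletion") lfc else -lfc
  ord <- order(p, key)
  rk <- integer(length(p))
  rk[ord] <- seq_along(p)
  rk / length(p)
}

#' Gene-level rho statistic of alpha-RRA
#'
#' For a gene with `n` normalized ranks of which the `j` smallest are
#' selected (guide p-value below the alpha cutoff), the statistic is
#' the minimum over k = 1..j of the Beta(k, n - k + 1) cdf evaluated at
#' the k-th smallest rank -- the probability that the k-th order
#' statistic of n uniforms is at most the observed rank. `rho = 1`
#' when no rank is selected.
#'
#' @param norm_ranks Normalized ranks of the gene's guides, in (0, 1].
#' @param selected Logical vector: which guides pass the alpha cutoff.
#' @return The rho statistic in \[0, 1\].
#' @examples
#' rho_statistic(0.2, TRUE)                       # 0.2
#' rho_statistic(c(0.1, 0.2), c(TRUE, TRUE))      # 0.04
#' @export
rho_statistic <- function(norm_ranks, selected = rep(TRUE, length(norm_ranks))) {
  n <- length(norm_ranks)
  stopifnot(length(selected) == n, n >= 1)
  j <- sum(selected)
  if (j == 0) return(1)
  r <- sort(norm_ranks[selected])
  k <- seq_len(j)
  min(pbeta(r, k, n - k + 1))
}

# rho for permuted pseudo-genes: n_perm rows of n uniform ranks,
# a rank is selected iff it falls below `threshold`
permute_rho <- function(n, n_perm, threshold) {
  u <- matrix(runif(n_perm * n), nrow = n_perm)
  us <- t(apply(u, 1, sort))
  b <- vapply(seq_len(n), function(k) pbeta(us[, k], k, n - k + 1),
              numeric(n_perm))
  b <- matrix(b, nrow = n_perm)
  b[us > threshold] <- Inf
  rho <- do.call(pmin, c(as.data.frame(b), list(1)))
  rho
}

#' Permutation p-values for gene rho statistics
#'
#' For every distinct number of ranks per gene, draws `n_perm`
#' pseudo-genes of uniform normalized ranks, applies the same
#' alpha-selection rule as the observed data (a rank is selected iff
#' it falls below the alpha-quantile threshold of the pooled observed
#' rank list) and computes rho. The p-value uses add-one smoothing:
#' `(1 + #\{rho_perm <= rho_obs\}) / (1 + n_perm)`.
#'
#' @param rho Observed rho per gene.
#' @param n_ranks Number of ranks per gene (guides x replicates),
#'   recycled if scalar.
#' @param threshold Normalized-rank selection threshold (the fraction
#'   of pooled guide p-values below alpha).
#' @param n_perm Number of permutations per distinct gene size
#'   (>= 100).
#' @param seed Optional seed for the permutation draws.
#' @return Permutation p-values per gene.
#' @export
permutation_pvalues <- function(rho, n_ranks, threshold, n_perm = 1000,
                                seed = NULL) {
  if (n_perm < 100) stop("`n_perm` must be at least 100", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n_ranks <- rep_len(n_ranks, length(rho))
  p <- numeric(length(rho))
  for (n in unique(n_ranks)) {
    idx <- which(n_ranks == n)
    rp <- sort(permute_rho(n, n_perm, threshold))
    # #{rho_perm <= rho_obs} via binary search on the sorted null
    cnt <- findInterval(rho[idx], rp)
    p[idx] <- (1 + cnt) / (1 + n_perm)
  }
  p
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up false discovery rate adjustment (a thin wrapper
#' around [stats::p.adjust()]).
#'
#' @param p Raw p-values in \[0, 1\].
#' @return Adjusted values, monotone and >= the raw p-values.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Rank genes by permutation p-value
#'
#' Total ordering: ascending p-value; ties broken by the mean gene LFC
#' (ascending for the depletion tail, descending for enrichment), then
#' by gene id.
#'
#' @param gene_id Gene identifiers.
#' @param p Permutation p-values.
#' @param gene_lfc Mean LFC per gene.
#' @param tail `"depletion"` or `"enrichment"`.
#' @return Integer ranks (1 = most significant), aligned with input.
#' @export
rank_genes <- function(gene_id, p, gene_lfc,
                       tail = c("depletion", "enrichment")) {
  tail <- match.arg(tail)
  key <- if (tail == "depletion") gene_lfc else -gene_lfc
  ord <- order(p, key, gene_id)
  rk <- integer(length(p))
  rk[ord] <- seq_along(p)
  rk
}

# full alpha-RRA aggregation for one tail: pooled guide p-values and
# LFCs (guides x replicates matrices), gene ids per guide
aggregate_tail <- function(p_mat, lfc_mat, gene_ids, alpha, n_perm, seed,
                           tail) {
  nr <- ncol(p_mat)
  p_pool <- as.vector(p_mat)
  lfc_pool <- as.vector(lfc_mat)
  gene_pool <- rep(gene_ids, times = nr)
  r <- normalized_ranks(p_pool, lfc_pool, tail)
  sel <- p_pool < alpha
  threshold <- sum(sel) / length(sel)
  idx <- split(seq_along(r), gene_pool)
  rho <- vapply(idx, function(i) rho_statistic(r[i], sel[i]), numeric(1))
  p_perm <- permutation_pvalues(rho, lengths(idx), threshold,
                                n_perm = n_perm, seed = seed)
  data.frame(gene_id = names(idx), rho = unname(rho), p = unname(p_perm),
             fdr = bh_fdr(unname(p_perm)), stringsAsFactors = FALSE)
}
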