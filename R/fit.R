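#' Stratify guides by reference abundance
#'
#' Splits the guides into `n_slices` slices at the 1/n, 2/n, ...
#' quantiles of the reference-sample abundance (10%, 20%, ... by
#' default). Guides with equal abundance always fall in the same
#' slice; if heavy ties collapse slice boundaries the resulting
#' imbalance is reported with a warning.
#'
#' @param ref_abundance gRNA abundance in the reference sample.
#' @param n_slices Number of slices (default 10).
#' @return A list with `stratum` (integer assignment per guide, 1 =
#'   lowest abundance) and `breaks` (the abundance boundaries used).
#' @export
stratify <- function(ref_abundance, n_slices = 10) {
  stopifnot(n_slices >= 1)
  if (length(ref_abundance) <= n_slices) {
    stop("need more guides than slices", call. = FALSE)
  }
  br <- quantile(ref_abundance, seq(0, 1, length.out = n_slices + 1),
                 names = FALSE, type = 7)
  ubr <- unique(br)
  if (length(ubr) < 2) {
    warning("all reference abundances are equal; using a single stratum",
            call. = FALSE)
    return(list(stratum = rep(1L, length(ref_abundance)), breaks = br))
  }
  s <- .bincode(ref_abundance, ubr, right = TRUE, include.lowest = TRUE)
  if (length(ubr) < length(br)) {
    warning("ties in the reference abundance collapsed ",
            length(br) - length(ubr), " stratum boundaries; strata are ",
            "unbalanced", call. = FALSE)
  }
  list(stratum = s, breaks = ubr)
}

#' Fit the stratified skew-normal screen model and rank genes
#'
#' The central modelling function. Guide counts are size-normalized to
#' the reference sample, pseudocounted log2 fold changes are computed
#' for every treatment replicate, guides are stratified by reference
#' abundance, and a skew-normal null is fitted to each stratum of each
#' replicate by trimmed quantile matching ([fit_null()]). Guide-level
#' depletion and enrichment p-values are the null cdf (resp. upper
#' tail) of the observed LFC. Per-gene evidence is aggregated by
#' alpha-RRA: replicate-pooled normalized ranks, Beta order-statistic
#' rho, and permutation p-values, separately for the depletion and
#' enrichment tails.
#'
#' @param counts A [screen_counts] object (e.g. from
#'   [simulate_screen()]`$counts` or [read_counts()]).
#' @param reference,treatments Passed to [lfc_matrix()]; by default the
#'   first library sample is the reference and all T1 samples are
#'   treatments.
#' @param n_strata Number of abundance slices (default 10).
#' @param alpha Guide p-value cutoff of the alpha-RRA selection
#'   (default 0.05).
#' @param n_perm Permutations per distinct gene size for the gene-level
#'   p-value (default 1000).
#' @param q_lo,q_hi,grid_step Trimming band and quantile grid of the
#'   null fit, see [fit_null()].
#' @param fit_method Null-fit objective passed to [fit_null()]
#'   (`"tml"` trimmed maximum likelihood, the default, or
#'   `"quantile"`).
#' @param xi_fixed Freeze the skew parameter (e.g. `1` for the
#'   symmetric-null baseline); `NULL` (default) fits it.
#' @param pool_replicates If `TRUE`, one null per stratum is fitted on
#'   the LFCs pooled across replicates instead of one per replicate.
#' @param collapse_tech If `TRUE` (default) and sample stages are
#'   annotated, technical sequencing replicates are summed per
#'   biological sample before analysis (see [collapse_technical()]);
#'   treating them as independent replicates makes the gene-level
#'   permutation null anti-conservative.
#' @param seed Seed for the permutation draws.
#' @return An object of class `screen_fit` with components `guide`
#'   (per-guide table: LFCs, stratum, p-values and ranks per replicate
#'   and tail), `gene` (per-gene table: rho, permutation p, BH-FDR,
#'   mean LFC and rank for both tails), `null_models` (per
#'   replicate/stratum parameter table), `lfcs`, `strata`, and the
#'   call. Methods: `print`, `summary`, `coef`, `plot`, `predict`,
#'   `simulate`, `residuals`, [gene_results()].
#' @examples
#' p <- sim_params(n_sgrnas = 2000, n_repl_sel = 2, n_repl_pcr = 1,
#'                 n_splittings = 3, rng_seed = 11)
#' fit <- fit_screen(simulate_screen(p)$counts, n_strata = 4,
#'                   n_perm = 100)
#' fit
#' head(gene_results(fit))
#' @export
fit_screen <- function(counts, reference = NULL, treatments = NULL,
                       n_strata = 10, alpha = 0.05, n_perm = 1000,
                       q_lo = 0.10, q_hi = 0.90, grid_step = 0.05,
                       xi_fixed = NULL, fit_method = c("tml", "quantile"),
                       pool_replicates = FALSE,
                       collapse_tech = TRUE, seed = 1L) {
  fit_method <- match.arg(fit_method)
  stopifnot(inherits(counts, "screen_counts"))
  if (collapse_tech && !any(is.na(counts$sample_info$stage)) &&
      any(counts$sample_info$tech > 1, na.rm = TRUE)) {
    counts <- collapse_technical(counts)
    if (!is.null(reference) && !reference %in% colnames(counts$counts)) {
      reference <- sub("_[0-9]+$", "", reference)
    }
    if (!is.null(treatments) && !all(treatments %in% colnames(counts$counts))) {
      treatments <- unique(sub("_[0-9]+$", "", treatments))
    }
  }
  lfcs <- lfc_matrix(counts, reference, treatments)
  m <- unclass(lfcs)
  n_guides <- nrow(m)
  n_repl <- ncol(m)
  strata <- stratify(attr(lfcs, "ref_abundance"), n_strata)
  s <- strata$stratum
  n_s <- max(s)

  # per-replicate (or pooled) skew-normal null per stratum
  fit_one <- function(x) fit_null(x, q_lo, q_hi, grid_step, xi_fixed,
                                  method = fit_method)
  nm <- vector("list", n_s * n_repl)
  p_dep <- p_enr <- matrix(NA_real_, n_guides, n_repl,
                           dimnames = dimnames(m))
  for (k in seq_len(n_s)) {
    rows <- s == k
    pooled_fit <- if (pool_replicates) fit_one(as.vector(m[rows, ])) else NULL
    for (r in seq_len(n_repl)) {
      f <- if (pool_replicates) pooled_fit else fit_one(m[rows, r])
      nm[[(k - 1) * n_repl + r]] <- data.frame(
        stratum = k, replicate = colnames(m)[r], n = sum(rows),
        location = f$location, scale = f$scale, xi = f$xi,
        symmetric_fallback = f$symmetric_fallback,
        stringsAsFactors = FALSE)
      cdf <- pskewnorm(m[rows, r], f$location, f$scale, f$xi)
      p_dep[rows, r] <- cdf
      p_enr[rows, r] <- 1 - cdf
    }
  }
  null_models <- do.call(rbind, nm)

  rank_tail <- function(p_mat, tail) {
    vapply(seq_len(n_repl), function(r) {
      key <- if (tail == "depletion") m[, r] else -m[, r]
      ord <- order(p_mat[, r], key)
      rk <- integer(n_guides); rk[ord] <- seq_len(n_guides); rk
    }, integer(n_guides))
  }
  rank_dep <- rank_tail(p_dep, "depletion")
  rank_enr <- rank_tail(p_enr, "enrichment")

  gene_ids <- attr(lfcs, "guides")$gene_id
  gd <- aggregate_tail(p_dep, m, gene_ids, alpha, n_perm,
                       child_seed(seed, "rra", "dep"), "depletion")
  ge <- aggregate_tail(p_enr, m, gene_ids, alpha, n_perm,
                       child_seed(seed, "rra", "enr"), "enrichment")
  gene_lfc <- vapply(split(seq_len(n_guides), gene_ids),
                     function(i) mean(m[i, ]), numeric(1))
  gene <- data.frame(gene_id = gd$gene_id,
                     rho_neg = gd$rho, p_neg = gd$p, fdr_neg = gd$fdr,
                     rho_pos = ge$rho, p_pos = ge$p, fdr_pos = ge$fdr,
                     gene_lfc = unname(gene_lfc[gd$gene_id]),
                     stringsAsFactors = FALSE)
  gene$rank_neg <- rank_genes(gene$gene_id, gene$p_neg, gene$gene_lfc,
                              "depletion")
  gene$rank_pos <- rank_genes(gene$gene_id, gene$p_pos, gene$gene_lfc,
                              "enrichment")
  rownames(gene) <- NULL

  guide <- data.frame(attr(lfcs, "guides"), stratum = s,
                      stringsAsFactors = FALSE)
  colnames(m) -> trt
  for (r in seq_len(n_repl)) {
    guide[[paste0("lfc.", trt[r])]] <- m[, r]
    guide[[paste0("p_dep.", trt[r])]] <- p_dep[, r]
    guide[[paste0("p_enr.", trt[r])]] <- p_enr[, r]
    guide[[paste0("rank_dep.", trt[r])]] <- rank_dep[, r]
    guide[[paste0("rank_enr.", trt[r])]] <- rank_enr[, r]
  }

  structure(list(guide = guide, gene = gene, null_models = null_models,
                 lfcs = lfcs, strata = strata,
                 p_dep = p_dep, p_enr = p_enr,
                 settings = list(reference = attr(lfcs, "reference"),
                                 treatments = trt, n_strata = n_strata,
                                 alpha = alpha, n_perm = n_perm,
                                 q_lo = q_lo, q_hi = q_hi,
                                 grid_step = grid_step,
                                 xi_fixed = xi_fixed,
                                 fit_method = fit_method,
                                 pool_replicates = pool_replicates,
                                 collapse_tech = collapse_tech,
                                 seed = seed),
                 call = match.call()),
            class = "screen_fit")
}

#' Ranked gene-level results
#'
#' @param fit A [fit_screen()] object.
#' @param tail `"depletion"` (essential genes) or `"enrichment"`
#'   (growth-suppressing genes).
#' @return The gene table ordered by the chosen tail's rank.
#' @export
gene_results <- function(fit, tail = c("depletion", "enrichment")) {
  tail <- match.arg(tail)
  stopifnot(inherits(fit, "screen_fit"))
  g <- fit$gene
  g[order(if (tail == "depletion") g$rank_neg else g$rank_pos), ]
}

#' @export
print.screen_fit <- function(x, ...) {
  cat("Stratified skew-normal screen model\n")
  cat(sprintf("  %d gRNAs, %d genes, %d treatment replicates\n",
              nrow(x$guide), nrow(x$gene), length(x$settings$treatments)))
  cat(sprintf("  reference: %s; %d strata; alpha = %g; %d permutations\n",
              x$settings$reference, max(x$strata$stratum),
              x$settings$alpha, x$settings$n_perm))
  if (!is.null(x$settings$xi_fixed)) {
    cat(sprintf("  skew parameter frozen at %g (symmetric baseline)\n",
                x$settings$xi_fixed))
  }
  cat(sprintf("  genes with FDR < 0.05: %d (depletion), %d (enrichment)\n",
              sum(x$gene$fdr_neg < 0.05), sum(x$gene$fdr_pos < 0.05)))
  invisible(x)
}

#' @export
summary.screen_fit <- function(object, n_top = 10, ...) {
  out <- list(fit = object,
              top_depleted = head(gene_results(object, "depletion"), n_top),
              top_enriched = head(gene_results(object, "enrichment"), n_top),
              null_models = object$null_models)
  class(out) <- "summary.screen_fit"
  out
}

#' @export
print.summary.screen_fit <- function(x, ...) {
  print(x$fit)
  cat("\nTop depleted genes:\n")
  print(x$top_depleted[, c("gene_id", "rho_neg", "p_neg", "fdr_neg",
                           "gene_lfc", "rank_neg")], row.names = FALSE)
  cat("\nTop enriched genes:\n")
  print(x$top_enriched[, c("gene_id", "rho_pos", "p_pos", "fdr_pos",
                           "gene_lfc", "rank_pos")], row.names = FALSE)
  cat("\nNull model parameters (first replicate):\n")
  nm <- x$null_models
  print(nm[nm$replicate == nm$replicate[1], ], row.names = FALSE)
  invisible(x)
}

#' @export
coef.screen_fit <- function(object, ...) {
  object$null_models[, c("stratum", "replicate", "n", "location", "scale",
                         "xi")]
}

#' @export
residuals.screen_fit <- function(object, ...) {
  # observed LFC minus the median of the guide's stratum null
  m <- unclass(object$lfcs)
  nm <- object$null_models
  res <- m
  for (i in seq_len(nrow(nm))) {
    rows <- object$strata$stratum == nm$stratum[i]
    med <- qskewnorm(0.5, nm$location[i], nm$scale[i], nm$xi[i])
    res[rows, nm$replicate[i]] <- m[rows, nm$replicate[i]] - med
  }
  res
}

#' @export
predict.screen_fit <- function(object, lfc, ref_abundance,
                               replicate = 1,
                               tail = c("depletion", "enrichment"), ...) {
  tail <- match.arg(tail)
  br <- object$strata$breaks
  s <- .bincode(pmin(pmax(ref_abundance, br[1]), br[length(br)]), br,
                right = TRUE, include.lowest = TRUE)
  nm <- object$null_models
  repl <- if (is.numeric(replicate)) {
    object$settings$treatments[replicate]
  } else replicate
  nm <- nm[nm$replicate == repl, ]
  nm <- nm[order(nm$stratum), ]
  cdf <- pskewnorm(lfc, nm$location[s], nm$scale[s], nm$xi[s])
  if (tail == "depletion") cdf else 1 - cdf
}

#' @export
simulate.screen_fit <- function(object, nsim = 1, seed = NULL, ...) {
  # draws guide LFCs from the fitted null of each guide's stratum
  if (!is.null(seed)) set.seed(seed)
  nm <- object$null_models
  repl <- object$settings$treatments[1]
  nm <- nm[nm$replicate == repl, ]
  nm <- nm[order(nm$stratum), ]
  s <- object$strata$stratum
  out <- vapply(seq_len(nsim), function(i) {
    rskewnorm(length(s), nm$location[s], nm$scale[s], nm$xi[s])
  }, numeric(length(s)))
  rownames(out) <- object$guide$guide_id
  out
}

#' @export
plot.screen_fit <- function(x, strata = NULL, replicate = 1, ...) {
  m <- unclass(x$lfcs)
  repl <- if (is.numeric(replicate)) {
    x$settings$treatments[replicate]
  } else replicate
  nm <- x$null_models[x$null_models$replicate == repl, ]
  nm <- nm[order(nm$stratum), ]
  if (is.null(strata)) {
    strata <- unique(round(seq(1, nrow(nm), length.out = min(4, nrow(nm)))))
  }
  op <- par(mfrow = c(length(strata), 1), mar = c(3, 3, 2, 1))
  on.exit(par(op))
  for (k in strata) {
    v <- m[x$strata$stratum == k, repl]
    hist(v, breaks = 60, freq = FALSE,
         main = sprintf("stratum %d (n = %d)", k, length(v)),
         xlab = "LFC", col = "grey85", border = "white")
    xs <- seq(min(v), max(v), length.out = 300)
    lines(xs, dskewnorm(xs, nm$location[k], nm$scale[k], nm$xi[k]),
          col = "firebrick", lwd = 2)
  }
  invisible(x)
}

#' Write the per-stratum null-model parameter table
#'
#' Tab-separated diagnostic dump of the fitted skew-normal parameters
#' per replicate and stratum.
#'
#' @param fit A [fit_screen()] object.
#' @param path Output path.
#' @export
write_null_models <- function(fit, path) {
  stopifnot(inherits(fit, "screen_fit"))
  write.table(fit$null_models, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
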