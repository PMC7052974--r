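#' Precision-recall curve against ground truth
#'
#' Precision and recall at every prefix of a ranked gene list.
#'
#' @param ranked_genes Gene ids in ranking order (most significant
#'   first).
#' @param truth Named character vector mapping gene id to fitness
#'   class.
#' @param positive_class The class counted as a true positive
#'   (e.g. `"negative"` for essential genes in the depletion tail).
#' @return A data frame with columns `rank`, `gene_id`, `tp`,
#'   `precision`, `recall`.
#' @export
precision_recall <- function(ranked_genes, truth,
                             positive_class = "negative") {
  if (!all(ranked_genes %in% names(truth))) {
    stop("truth labels missing for some ranked genes", call. = FALSE)
  }
  pos <- truth[ranked_genes] == positive_class
  n_pos <- sum(truth == positive_class)
  if (n_pos == 0) {
    stop("no genes of class `", positive_class, "` in the truth",
         call. = FALSE)
  }
  tp <- cumsum(pos)
  k <- seq_along(ranked_genes)
  data.frame(rank = k, gene_id = ranked_genes, tp = tp,
             precision = tp / k, recall = tp / n_pos,
             stringsAsFactors = FALSE)
}

#' Recall at a fixed precision level
#'
#' The maximum recall over all ranking prefixes whose precision is at
#' least `precision_level`; 0 if no prefix qualifies.
#'
#' @param pr A [precision_recall()] data frame.
#' @param precision_level Precision level in (0, 1].
#' @return The recall.
#' @export
recall_at_precision <- function(pr, precision_level = 0.95) {
  stopifnot(precision_level > 0, precision_level <= 1)
  ok <- pr$precision >= precision_level
  if (!any(ok)) 0 else max(pr$recall[ok])
}

#' Cells required for a target coverage
#'
#' The experiment-design arithmetic: culturing a library of `n_guides`
#' gRNAs at mean coverage `coverage` requires `n_guides * coverage`
#' cells at every bottleneck.
#'
#' @param n_guides Library size.
#' @param coverage Desired mean cells per gRNA.
#' @return The required cell count.
#' @examples
#' cells_required(100000, 500)  # 50 million
#' @export
cells_required <- function(n_guides, coverage) {
  stopifnot(n_guides > 0, coverage > 0)
  n_guides * coverage
}

#' Sweep a simulation parameter and record LFC tail fractions
#'
#' Repeated simulations over a grid of one parameter, recording the
#' fraction of fitness-neutral gRNAs with LFC < -1 and > +1 (T1 vs
#' plasmid library). Reproduces the coverage / doubling-time asymmetry
#' sweeps.
#'
#' @param params Baseline [sim_params()].
#' @param param Name of the swept parameter (e.g. `"cov_cells"`,
#'   `"cov_pcr"`, `"cov_virus"`, `"dupl_time"`, `"lib_width"`).
#' @param values Grid of values.
#' @param n_repeats Independent simulations per grid value (default 5).
#' @param seed Base seed; repeat `j` at value `i` uses a deterministic
#'   child seed, stored in the output for re-execution.
#' @return A data frame with one row per grid cell per repeat:
#'   `param`, `value`, `rep`, `seed`, `frac_neg`, `frac_pos`.
#' @export
sweep_tail_fractions <- function(params, param = "cov_cells", values,
                                 n_repeats = 5, seed = params$rng_seed) {
  stopifnot(inherits(params, "sim_params"),
            param %in% names(unclass(params)))
  rows <- list()
  for (i in seq_along(values)) {
    for (j in seq_len(n_repeats)) {
      p <- unclass(params)
      p[[param]] <- values[i]
      p$rng_seed <- child_seed(seed, "sweep", param, i, j)
      p <- do.call(sim_params, p)
      sim <- simulate_screen(p)
      f <- neutral_tail_fractions(sim)
      rows[[length(rows) + 1]] <- data.frame(
        param = param, value = values[i], rep = j, seed = p$rng_seed,
        frac_neg = f[["frac_neg"]], frac_pos = f[["frac_pos"]],
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Tail fractions of fitness-neutral guides in a simulated screen
#'
#' @param sim A [simulate_screen()] result.
#' @return Named vector `frac_neg`, `frac_pos`: mean over T1 samples of
#'   the fraction of neutral guides with LFC < -1 resp. > +1 against
#'   the plasmid-library reference.
#' @export
neutral_tail_fractions <- function(sim) {
  stopifnot(inherits(sim, "screen_sim"))
  lf <- lfc_matrix(sim$counts)
  neutral <- sim$library$fitness_class == "neutral"
  tail_fractions(lf, guides = neutral)$overall
}

# run one simulate -> fit -> recall cycle
recall_once <- function(params, precision_level, tail, positive_class,
                        fit_args) {
  sim <- simulate_screen(params)
  fit <- do.call(fit_screen, c(list(counts = sim$counts), fit_args))
  ranked <- gene_results(fit, tail)$gene_id
  truth <- setNames(sim$truth$fitness_class, sim$truth$gene_id)
  recall_at_precision(precision_recall(ranked, truth, positive_class),
                      precision_level)
}

#' Benchmark gene-detection recall on simulated screens
#'
#' Simulates `n_repeats` screens from `params`, analyses each with
#' [fit_screen()] and scores recall at a fixed precision against the
#' simulated ground truth.
#'
#' @param params A [sim_params()] object.
#' @param n_repeats Independent simulations (default 5).
#' @param precision_level Precision level (default 0.99).
#' @param tail Ranking tail, `"depletion"` or `"enrichment"`.
#' @param positive_class Truth class scored as positive; defaults to
#'   `"negative"` (essential genes) for the depletion tail and
#'   `"positive"` for enrichment.
#' @param fit_args List of extra arguments for [fit_screen()] (e.g.
#'   `list(xi_fixed = 1)` for the symmetric-null baseline).
#' @param seed Base seed (child seeds per repeat are stored).
#' @return Data frame with one row per repeat: `rep`, `seed`,
#'   `recall`.
#' @export
benchmark_recall <- function(params, n_repeats = 5, precision_level = 0.99,
                             tail = c("depletion", "enrichment"),
                             positive_class = NULL, fit_args = list(),
                             seed = params$rng_seed) {
  tail <- match.arg(tail)
  if (is.null(positive_class)) {
    positive_class <- if (tail == "depletion") "negative" else "positive"
  }
  rows <- lapply(seq_len(n_repeats), function(j) {
    p <- params
    p$rng_seed <- child_seed(seed, "bench", j)
    data.frame(rep = j, seed = p$rng_seed,
               recall = recall_once(p, precision_level, tail,
                                    positive_class, fit_args))
  })
  do.call(rbind, rows)
}

#' Recommend the screening coverage for a library width
#'
#' Sweeps an ascending grid of cell-splitting coverages at a given
#' plasmid-library distribution width, scoring mean recall at a fixed
#' precision over repeated simulate-and-analyse cycles, and returns
#' the smallest coverage meeting the target recall. Narrow libraries
#' need less coverage than wide ones.
#'
#' @param lib_width Library 90/10 width.
#' @param coverages Ascending grid of cell-splitting coverages.
#' @param target_recall Required recall (default 0.95).
#' @param precision_level Precision level (default 0.99).
#' @param params Baseline [sim_params()] (the width and coverage fields
#'   are overridden per cell).
#' @param n_repeats Simulations per grid cell.
#' @param fit_args Extra [fit_screen()] arguments.
#' @param seed Base seed.
#' @param recall_fun Optional function `(params, seed) -> recall`
#'   replacing the built-in simulate-and-analyse cycle (for testing or
#'   plugging in an external analysis tool).
#' @return A list of class `coverage_recommendation`: `recommended`
#'   (smallest adequate coverage, `NA` if the target is unattainable on
#'   the grid), `max_recall`, `profile` (per-cell per-repeat recalls),
#'   `target_recall`, `precision_level`, `lib_width`.
#' @export
recommend_coverage <- function(lib_width, coverages,
                               target_recall = 0.95,
                               precision_level = 0.99,
                               params = sim_params(),
                               n_repeats = 5, fit_args = list(),
                               seed = params$rng_seed,
                               recall_fun = NULL) {
  stopifnot(length(coverages) >= 1, !is.unsorted(coverages))
  profile <- list()
  for (i in seq_along(coverages)) {
    p <- unclass(params)
    p$lib_width <- lib_width
    p$cov_cells <- coverages[i]
    p <- do.call(sim_params, p)
    for (j in seq_len(n_repeats)) {
      pj <- p
      pj$rng_seed <- child_seed(seed, "recommend", i, j)
      rec <- if (is.null(recall_fun)) {
        recall_once(pj, precision_level, "depletion", "negative", fit_args)
      } else {
        recall_fun(pj, pj$rng_seed)
      }
      profile[[length(profile) + 1]] <- data.frame(
        coverage = coverages[i], rep = j, seed = pj$rng_seed, recall = rec)
    }
  }
  profile <- do.call(rbind, profile)
  means <- tapply(profile$recall, profile$coverage, mean)
  means <- means[order(as.numeric(names(means)))]
  ok <- which(means >= target_recall)
  structure(list(
    recommended = if (length(ok)) as.numeric(names(means))[min(ok)] else NA_real_,
    max_recall = max(means), mean_recall = means, profile = profile,
    target_recall = target_recall, precision_level = precision_level,
    lib_width = lib_width), class = "coverage_recommendation")
}

#' @export
print.coverage_recommendation <- function(x, ...) {
  cat(sprintf(
    "Coverage recommendation for library width %g (recall >= %g at %g%% precision)\n",
    x$lib_width, x$target_recall, 100 * x$precision_level))
  for (nm in names(x$mean_recall)) {
    cat(sprintf("  coverage %5s: mean recall %.3f\n", nm, x$mean_recall[[nm]]))
  }
  if (is.na(x$recommended)) {
    cat(sprintf("  target unattainable on this grid (max recall %.3f)\n",
                x$max_recall))
  } else {
    cat(sprintf("  recommended coverage: %g\n", x$recommended))
  }
  invisible(x)
}
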