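#' Generate a plasmid gRNA library
#'
#' Draws the plasmid abundance of every gRNA i.i.d. from a lognormal
#' LN(5, sigma) with sigma chosen via [sigma_for_width()] to match the
#' target library width, then rounds to integer copy numbers (guides
#' rounded to zero are kept at abundance 0).
#'
#' @param params A [sim_params()] object.
#' @param seed Integer seed; defaults to a child stream of
#'   `params$rng_seed`.
#' @return A data frame with columns `guide_id`, `gene_id`,
#'   `plasmid_abundance`.
#' @export
generate_library <- function(params, seed = child_seed(params$rng_seed, "library")) {
  stopifnot(inherits(params, "sim_params"))
  n <- params$n_sgrnas
  n_per <- params$n_sgrnas_per_gene
  n_genes <- n %/% n_per
  gene_id <- rep(sprintf("gene_%05d", seq_len(n_genes)), each = n_per)
  guide_id <- paste0(gene_id, "_sg", rep(seq_len(n_per), times = n_genes))
  set.seed(seed)
  ab <- round(rlnorm(n, meanlog = 5, sdlog = sigma_for_width(params$lib_width)))
  data.frame(guide_id = guide_id, gene_id = gene_id,
             plasmid_abundance = ab, stringsAsFactors = FALSE)
}

#' Assign fitness classes and effect sizes to genes
#'
#' Partitions the genes into negative-fitness (knockout causes a growth
#' defect), positive-fitness (knockout increases growth) and neutral
#' sets of sizes `round(freq_negfc * n_genes)`, `round(freq_posfc *
#' n_genes)` and the remainder. Each non-neutral gene draws an effect
#' magnitude epsilon uniformly from the grid 0, 0.01, ..., 0.2; the
#' per-interval growth factor of its guides is beta * (1 - epsilon)
#' (negative) or beta * (1 + epsilon) (positive), with beta from
#' [growth_factor()].
#'
#' @inheritParams generate_library
#' @return A data frame with one row per gene: `gene_id`,
#'   `fitness_class` (`"neutral"`, `"negative"` or `"positive"`),
#'   `epsilon`, and `growth_rate` (beta_g per splitting interval).
#' @export
assign_fitness <- function(params, seed = child_seed(params$rng_seed, "fitness")) {
  stopifnot(inherits(params, "sim_params"))
  n_genes <- params$n_sgrnas %/% params$n_sgrnas_per_gene
  n_neg <- round(params$freq_negfc * n_genes)
  n_pos <- round(params$freq_posfc * n_genes)
  set.seed(seed)
  idx <- sample.int(n_genes, n_neg + n_pos)
  cls <- rep("neutral", n_genes)
  cls[idx[seq_len(n_neg)]] <- "negative"
  if (n_pos > 0) cls[idx[n_neg + seq_len(n_pos)]] <- "positive"
  eps_grid <- seq(0, 0.2, by = 0.01)
  eps <- numeric(n_genes)
  eps[cls != "neutral"] <- sample(eps_grid, sum(cls != "neutral"),
                                  replace = TRUE)
  beta <- growth_factor(params$split_interval, params$dupl_time)
  beta_g <- beta * ifelse(cls == "negative", 1 - eps,
                          ifelse(cls == "positive", 1 + eps, 1))
  data.frame(gene_id = sprintf("gene_%05d", seq_len(n_genes)),
             fitness_class = cls, epsilon = eps, growth_rate = beta_g,
             stringsAsFactors = FALSE)
}

#' Exponential growth step
#'
#' Multiplies each abundance by exp(beta_g) and truncates to the integer
#' part. Extinct guides (abundance 0) stay extinct.
#'
#' @param abundance Non-negative integer-valued abundance vector.
#' @param beta Growth factor per interval, scalar or per-guide vector.
#' @return The grown abundance vector (integer-valued doubles).
#' @export
grow_pool <- function(abundance, beta) {
  if (any(abundance < 0)) stop("negative abundance", call. = FALSE)
  floor(exp(beta) * abundance)
}

#' Bottleneck subsampling of a cell or read pool
#'
#' Draws `n_draws` items without replacement from the integer pool
#' (multivariate hypergeometric, sampled by iterated conditional
#' univariate hypergeometric draws). When `n_draws` exceeds the pool
#' total -- which happens at the transduction and sequencing steps when
#' the plasmid pool is smaller than the requested coverage -- the
#' behaviour depends on `overdraw`: `"multinomial"` (default, used by
#' the simulator) samples `n_draws` items with replacement from the
#' pool frequencies and emits a message; `"cap"` returns the entire
#' pool (a draw of min(n_draws, total) without replacement).
#'
#' @param abundance Non-negative integer-valued pool vector.
#' @param n_draws Number of draws (>= 0).
#' @param overdraw Overdraw policy, see above.
#' @param stage Stage label used in error messages.
#' @return The subsampled pool vector.
#' @export
subsample_pool <- function(abundance, n_draws,
                           overdraw = c("multinomial", "cap"),
                           stage = "pool") {
  overdraw <- match.arg(overdraw)
  if (any(abundance < 0)) stop("negative abundance", call. = FALSE)
  if (n_draws < 0) stop("`n_draws` must be >= 0", call. = FALSE)
  total <- sum(abundance)
  if (total <= 0) {
    stop("simulation collapse: pool is empty at stage `", stage, "`",
         call. = FALSE)
  }
  if (n_draws == 0) return(numeric(length(abundance)))
  if (n_draws > total) {
    if (overdraw == "cap") return(abundance + 0)
    message("subsample at stage `", stage, "`: ", n_draws,
            " draws exceed pool total ", total,
            "; falling back to multinomial (with replacement)")
    return(drop(rmultinom(1, size = n_draws, prob = abundance / total)) + 0)
  }
  mvhyper_cpp(abundance + 0, n_draws)
}

#' Simulate a complete pooled CRISPR knockout screen
#'
#' Runs the full generative model: plasmid library generation, library
#' sequencing, viral transduction, one growth interval to T0, T0
#' sequencing, then `n_repl_sel` independent proliferation phases of
#' `n_splittings` rounds of cell-splitting bottleneck followed by
#' exponential growth, and T1 sequencing. All subsampling steps draw
#' `coverage * n_sgrnas` items from the current pool without
#' replacement (multinomial fallback on overdraw, see
#' [subsample_pool()]). Sequencing of each sample is repeated for the
#' technical replicates.
#'
#' @param params A [sim_params()] object.
#' @param track_pools If `TRUE`, the intermediate cell-pool abundances
#'   of biological replicate 1 after each splitting round are stored in
#'   the result (`$split_pools`), for diagnostics of distribution
#'   broadening.
#' @return An object of class `screen_sim`: a list with
#'   \describe{
#'     \item{counts}{a [screen_counts] object holding all sequenced
#'       samples (columns `lib_R1_<t>`, `t0_R1_<t>`,
#'       `t1_R<bio>_<t>`);}
#'     \item{library}{the guide library with per-guide fitness class,
#'       epsilon and growth rate;}
#'     \item{truth}{gene-level ground truth (`gene_id`,
#'       `fitness_class`, `epsilon`);}
#'     \item{params}{the parameter object;}
#'     \item{split_pools}{optional matrix of tracked pools.}
#'   }
#' @examples
#' p <- sim_params(n_sgrnas = 400, n_repl_sel = 2, n_repl_pcr = 1,
#'                 n_splittings = 2, rng_seed = 7)
#' sim <- simulate_screen(p)
#' sim
#' @export
simulate_screen <- function(params, track_pools = FALSE) {
  stopifnot(inherits(params, "sim_params"))
  n <- params$n_sgrnas
  seed0 <- params$rng_seed

  lib <- generate_library(params)
  fit <- assign_fitness(params)
  lib <- merge(lib, fit, by = "gene_id", sort = FALSE)
  lib <- lib[order(lib$guide_id), c("guide_id", "gene_id",
                                    "plasmid_abundance", "fitness_class",
                                    "epsilon", "growth_rate")]
  rownames(lib) <- NULL
  beta_g <- lib$growth_rate
  pool_lib <- lib$plasmid_abundance
  if (sum(pool_lib) <= 0) {
    stop("simulation collapse: pool is empty at stage `library`",
         call. = FALSE)
  }

  n_pcr_draws <- params$cov_pcr * n
  seq_sample <- function(pool, tag, n_tech) {
    vapply(seq_len(n_tech), function(t) {
      set.seed(child_seed(seed0, tag, t))
      subsample_pool(pool, n_pcr_draws, stage = paste0(tag, "_", t))
    }, numeric(n))
  }

  # plasmid library sequencing (technical replicates)
  lib_seq <- seq_sample(pool_lib, "libseq", params$n_repl_lib_pcr)
  colnames(lib_seq) <- sprintf("lib_R1_%d", seq_len(params$n_repl_lib_pcr))

  # transduction, then one growth interval to T0
  set.seed(child_seed(seed0, "transduction"))
  pool_trans <- subsample_pool(pool_lib, params$cov_virus * n,
                               stage = "transduction")
  pool_t0 <- grow_pool(pool_trans, beta_g)
  if (sum(pool_t0) <= 0) {
    stop("simulation collapse: pool is empty at stage `t0`", call. = FALSE)
  }
  t0_seq <- seq_sample(pool_t0, "t0seq", params$n_repl_pcr)
  colnames(t0_seq) <- sprintf("t0_R1_%d", seq_len(params$n_repl_pcr))

  # proliferation phase: independent biological replicates
  t1_seq <- matrix(0, nrow = n, ncol = 0)
  split_pools <- NULL
  for (b in seq_len(params$n_repl_sel)) {
    pool <- pool_t0
    for (i in seq_len(params$n_splittings)) {
      set.seed(child_seed(seed0, "split", b, i))
      pool <- subsample_pool(pool, params$cov_cells * n,
                             stage = sprintf("split_%d_%d", b, i))
      pool <- grow_pool(pool, beta_g)
      if (sum(pool) <= 0) {
        stop("simulation collapse: pool is empty at stage `split_", b,
             "_", i, "`", call. = FALSE)
      }
      if (track_pools && b == 1L) {
        split_pools <- cbind(split_pools, pool)
      }
    }
    s <- seq_sample(pool, paste0("t1seq_", b), params$n_repl_pcr)
    colnames(s) <- sprintf("t1_R%d_%d", b, seq_len(params$n_repl_pcr))
    t1_seq <- cbind(t1_seq, s)
  }
  if (!is.null(split_pools)) {
    colnames(split_pools) <- sprintf("split_%d", seq_len(ncol(split_pools)))
  }

  counts <- cbind(lib_seq, t0_seq, t1_seq)
  rownames(counts) <- lib$guide_id
  info <- parse_sample_names(colnames(counts))
  cm <- screen_counts(lib[, c("guide_id", "gene_id")], counts, info)

  truth <- fit[, c("gene_id", "fitness_class", "epsilon")]
  structure(list(counts = cm, library = lib, truth = truth,
                 params = params, split_pools = split_pools),
            class = "screen_sim")
}

#' @export
print.screen_sim <- function(x, ...) {
  cat("Simulated pooled CRISPR screen\n")
  cat(sprintf("  %d gRNAs / %d genes; %d sequenced samples\n",
              nrow(x$counts$counts), nrow(x$truth), ncol(x$counts$counts)))
  tab <- table(x$truth$fitness_class)
  cat("  gene truth:", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' @rdname simulate_screen
#' @param object A `sim_params` object.
#' @param nsim Number of screens to simulate.
#' @param seed Optional master seed overriding `object$rng_seed`;
#'   screen `i` of `nsim` uses `seed + i - 1`.
#' @param ... Unused.
#' @return `simulate()` returns a list of `screen_sim` objects (a
#'   single object if `nsim = 1`).
#' @export
simulate.sim_params <- function(object, nsim = 1, seed = NULL, ...) {
  base <- if (is.null(seed)) object$rng_seed else as.integer(seed)
  sims <- lapply(seq_len(nsim), function(i) {
    p <- object
    p$rng_seed <- base + i - 1L
    simulate_screen(p)
  })
  if (nsim == 1) sims[[1]] else sims
}

parse_sample_names <- function(nms) {
  m <- regmatches(nms, regexec("^([a-zA-Z0-9]+)_R([0-9]+)_([0-9]+)$", nms))
  ok <- lengths(m) == 4
  stage <- ifelse(ok, vapply(m, function(z) z[2], ""), NA_character_)
  bio <- ifelse(ok, as.integer(vapply(m, function(z) z[3], "")), NA_integer_)
  tech <- ifelse(ok, as.integer(vapply(m, function(z) z[4], "")), NA_integer_)
  data.frame(sample = nms, stage = stage, bio = bio, tech = tech,
             stringsAsFactors = FALSE)
}
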