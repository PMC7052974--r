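#' Simulation parameters for a pooled CRISPR knockout screen
#'
#' Constructs the complete parameter set of the generative screen model.
#' Defaults describe a genome-scale negative-selection screen: 50,000
#' gRNAs targeting 12,500 genes (4 gRNAs per gene), 10% of genes with a
#' negative and 1% with a positive fitness effect, a lognormal plasmid
#' library of 90/10-percentile width 7.5, coverage 400 at transduction,
#' cell splitting and sequencing, doubling time 30 h and 7 splittings
#' 72 h apart.
#'
#' @param cov_virus Coverage (mean draws per gRNA) during viral
#'   transduction.
#' @param cov_cells Coverage at each cell-splitting bottleneck; the key
#'   driver of fold-change asymmetry.
#' @param cov_pcr Coverage at PCR amplification / sequencing.
#' @param lib_width Target 90/10-percentile ratio of the plasmid-library
#'   abundance distribution (dimensionless, >= 1).
#' @param dupl_time Cell doubling time in hours.
#' @param freq_negfc,freq_posfc Fractions of genes whose knockout
#'   decreases / increases fitness; must sum to at most 1.
#' @param n_sgrnas Total number of gRNAs; must be divisible by
#'   `n_sgrnas_per_gene`.
#' @param n_sgrnas_per_gene Independent gRNAs per gene.
#' @param n_repl_lib_pcr Technical sequencing replicates of the plasmid
#'   library.
#' @param n_repl_sel Biological replicates of the proliferation phase.
#' @param n_repl_pcr Technical sequencing replicates per cell-pool sample.
#' @param n_splittings Number of cell splittings between T0 and T1.
#' @param split_interval Time between splittings in hours.
#' @param rng_seed Master seed; per-stage child streams are derived from
#'   it deterministically so any replicate is reproducible in isolation.
#'
#' @return An object of class `sim_params` (a validated named list).
#' @seealso [simulate_screen()], [sigma_for_width()], [growth_factor()]
#' @examples
#' p <- sim_params(n_sgrnas = 1000, n_repl_sel = 2)
#' p
#' @export
sim_params <- function(cov_virus = 400,
                       cov_cells = 400,
                       cov_pcr = 400,
                       lib_width = 7.5,
                       dupl_time = 30,
                       freq_negfc = 0.1,
                       freq_posfc = 0.01,
                       n_sgrnas = 50000,
                       n_sgrnas_per_gene = 4,
                       n_repl_lib_pcr = 2,
                       n_repl_sel = 10,
                       n_repl_pcr = 3,
                       n_splittings = 7,
                       split_interval = 72,
                       rng_seed = 1L) {
  p <- list(
    cov_virus = cov_virus, cov_cells = cov_cells, cov_pcr = cov_pcr,
    lib_width = lib_width, dupl_time = dupl_time,
    freq_negfc = freq_negfc, freq_posfc = freq_posfc,
    n_sgrnas = as.integer(n_sgrnas),
    n_sgrnas_per_gene = as.integer(n_sgrnas_per_gene),
    n_repl_lib_pcr = as.integer(n_repl_lib_pcr),
    n_repl_sel = as.integer(n_repl_sel),
    n_repl_pcr = as.integer(n_repl_pcr),
    n_splittings = as.integer(n_splittings),
    split_interval = split_interval,
    rng_seed = as.integer(rng_seed)
  )
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

validate_sim_params <- function(p) {
  pos <- c("cov_virus", "cov_cells", "cov_pcr", "dupl_time",
           "split_interval", "n_sgrnas", "n_sgrnas_per_gene",
           "n_repl_lib_pcr", "n_repl_sel", "n_repl_pcr")
  for (nm in pos) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1 || is.na(p[[nm]]) ||
        p[[nm]] <= 0) {
      stop("invalid parameter: `", nm, "` must be a positive number",
           call. = FALSE)
    }
  }
  if (p$n_splittings < 0) {
    stop("invalid parameter: `n_splittings` must be >= 0", call. = FALSE)
  }
  if (p$lib_width < 1) {
    stop("invalid parameter: `lib_width` must be >= 1", call. = FALSE)
  }
  if (p$freq_negfc < 0 || p$freq_posfc < 0 ||
      p$freq_negfc + p$freq_posfc > 1) {
    stop("invalid parameter: `freq_negfc` + `freq_posfc` must lie in [0, 1]",
         call. = FALSE)
  }
  if (p$n_sgrnas %% p$n_sgrnas_per_gene != 0) {
    stop("invalid parameter: `n_sgrnas` must be divisible by ",
         "`n_sgrnas_per_gene`", call. = FALSE)
  }
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Pooled CRISPR screen simulation parameters\n")
  cat(sprintf("  %d gRNAs, %d per gene (%d genes)\n", x$n_sgrnas,
              x$n_sgrnas_per_gene, x$n_sgrnas %/% x$n_sgrnas_per_gene))
  cat(sprintf("  library width %g; coverage: virus %g, cells %g, PCR %g\n",
              x$lib_width, x$cov_virus, x$cov_cells, x$cov_pcr))
  cat(sprintf("  doubling time %g h, %d splittings every %g h\n",
              x$dupl_time, x$n_splittings, x$split_interval))
  cat(sprintf("  fitness effects: %g%% negative, %g%% positive genes\n",
              100 * x$freq_negfc, 100 * x$freq_posfc))
  cat(sprintf("  replicates: %d biological x %d sequencing (library: %d)\n",
              x$n_repl_sel, x$n_repl_pcr, x$n_repl_lib_pcr))
  cat(sprintf("  rng seed %d\n", x$rng_seed))
  invisible(x)
}

#' Lognormal log-sd matching a target library width
#'
#' The plasmid library is modelled as lognormal LN(mu, sigma) with
#' mu = 5. The 90/10-percentile ratio of LN(mu, sigma) is
#' exp(sigma * (z90 - z10)), so the sigma reproducing a target width L
#' is `log(L) / (qnorm(0.9) - qnorm(0.1))`.
#'
#' @param lib_width Target 90/10-percentile ratio, >= 1.
#' @return The log-scale standard deviation sigma.
#' @examples
#' sigma_for_width(7.5)
#' @export
sigma_for_width <- function(lib_width) {
  if (!is.numeric(lib_width) || any(is.na(lib_width)) || any(lib_width < 1)) {
    stop("invalid parameter: `lib_width` must be >= 1", call. = FALSE)
  }
  log(lib_width) / (qnorm(0.9) - qnorm(0.1))
}

#' Baseline growth factor per splitting interval
#'
#' Exponential growth n(t + dt) = exp(beta) * n(t) with
#' beta = log(2^(dt / tau)) = (dt / tau) * log(2), i.e. one doubling per
#' doubling time tau.
#'
#' @param delta_t Time between splittings in hours.
#' @param tau Cell doubling time in hours.
#' @return The growth factor beta per interval.
#' @examples
#' growth_factor(72, 30)
#' @export
growth_factor <- function(delta_t, tau) {
  if (!is.numeric(delta_t) || !is.numeric(tau) ||
      any(delta_t <= 0) || any(tau <= 0)) {
    stop("invalid parameter: `delta_t` and `tau` must be positive",
         call. = FALSE)
  }
  (delta_t / tau) * log(2)
}

#' Coverage giving 100-fold representation of the low-abundance decile
#'
#' Solves for the coverage C such that C * n_sgrnas draws give the
#' 10th-percentile gRNA of the library a mean representation of
#' `fold` (default 100): C = fold * total / (n_sgrnas * p10).
#'
#' @param lib_abundance Integer plasmid abundances of all gRNAs.
#' @param fold Target representation of the p10 gRNA.
#' @return The required coverage (draws per gRNA).
#' @export
coverage_for_p10 <- function(lib_abundance, fold = 100) {
  p10 <- quantile(lib_abundance, 0.10, names = FALSE, type = 7)
  if (p10 <= 0) stop("10th percentile of library abundance is 0", call. = FALSE)
  fold * sum(lib_abundance) / (length(lib_abundance) * p10)
}

#' Read / write simulation parameters
#'
#' Flat key/value parameter files in DCF format (`key: value` lines)
#' using the same field names as [sim_params()].
#'
#' @param path File path.
#' @return `read_sim_params()` returns a `sim_params` object;
#'   `write_sim_params()` returns `path` invisibly.
#' @export
read_sim_params <- function(path) {
  dcf <- read.dcf(path)
  vals <- as.list(drop(dcf))
  known <- names(formals(sim_params))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown parameter field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  vals <- lapply(vals, function(v) as.numeric(v))
  do.call(sim_params, vals)
}

#' @rdname read_sim_params
#' @param params A `sim_params` object.
#' @export
write_sim_params <- function(params, path) {
  stopifnot(inherits(params, "sim_params"))
  m <- matrix(vapply(unclass(params), format, character(1)), nrow = 1)
  colnames(m) <- names(unclass(params))
  write.dcf(m, path)
  invisible(path)
}

# deterministic child seed for a named simulation stage, kept in
# [0, 2^31 - 2] so set.seed() always accepts it
child_seed <- function(seed, ...) {
  tag <- paste(c(...), collapse = "/")
  h <- 0
  for (k in utf8ToInt(tag)) h <- (h * 31 + k) %% 2147483587
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
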