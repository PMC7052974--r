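#' gRNA count matrix container
#'
#' A light container for a screen count table: a guide annotation data
#' frame (`guide_id`, `gene_id`), a numeric matrix of counts (guides x
#' samples) and a sample-information data frame. Counts must be
#' non-negative and guide ids unique.
#'
#' @param guides Data frame with columns `guide_id` and `gene_id`.
#' @param counts Numeric matrix, one row per guide, one column per
#'   sample.
#' @param sample_info Optional data frame with one row per sample
#'   (columns `sample`, `stage`, `bio`, `tech`); parsed from column
#'   names of the form `<stage>_R<bio>_<tech>` when omitted.
#' @return An object of class `screen_counts`.
#' @export
screen_counts <- function(guides, counts, sample_info = NULL) {
  stopifnot(is.data.frame(guides),
            all(c("guide_id", "gene_id") %in% names(guides)))
  counts <- as.matrix(counts)
  if (nrow(counts) != nrow(guides)) {
    stop("`counts` and `guides` disagree on the number of gRNAs",
         call. = FALSE)
  }
  if (anyDuplicated(guides$guide_id)) {
    stop("duplicate guide ids", call. = FALSE)
  }
  if (any(counts < 0) || any(!is.finite(counts))) {
    stop("counts must be finite and non-negative", call. = FALSE)
  }
  if (is.null(sample_info)) sample_info <- parse_sample_names(colnames(counts))
  rownames(counts) <- guides$guide_id
  structure(list(guides = guides[, c("guide_id", "gene_id")],
                 counts = counts, sample_info = sample_info),
            class = "screen_counts")
}

#' @export
print.screen_counts <- function(x, ...) {
  cat(sprintf("screen_counts: %d gRNAs (%d genes) x %d samples\n",
              nrow(x$counts), length(unique(x$guides$gene_id)),
              ncol(x$counts)))
  cat("  samples:", paste(head(colnames(x$counts), 8), collapse = ", "),
      if (ncol(x$counts) > 8) "..." else "", "\n")
  invisible(x)
}

#' @export
dim.screen_counts <- function(x) dim(x$counts)

#' Sum technical sequencing replicates per biological sample
#'
#' Technical replicates are independent sequencing draws from the same
#' cell or plasmid pool; for analysis they carry no independent
#' biological information and are summed per (stage, biological
#' replicate), which amounts to deeper sequencing of that sample.
#' Collapsed columns are named `<stage>_R<bio>`.
#'
#' @param counts A [screen_counts] object with stage/bio/tech sample
#'   annotations.
#' @return A [screen_counts] object with one column per biological
#'   sample.
#' @export
collapse_technical <- function(counts) {
  stopifnot(inherits(counts, "screen_counts"))
  info <- counts$sample_info
  if (any(is.na(info$stage))) {
    stop("sample stages are not annotated; cannot collapse", call. = FALSE)
  }
  key <- paste0(info$stage, "_R", info$bio)
  ukey <- unique(key)
  m <- vapply(ukey, function(k) {
    rowSums(counts$counts[, key == k, drop = FALSE])
  }, numeric(nrow(counts$counts)))
  colnames(m) <- ukey
  si <- data.frame(sample = ukey,
                   stage = info$stage[match(ukey, key)],
                   bio = info$bio[match(ukey, key)],
                   tech = 1L, stringsAsFactors = FALSE)
  screen_counts(counts$guides, m, si)
}

#' Size normalization to the reference sample total
#'
#' Scales every treatment column so its total equals the total of the
#' reference column; the reference itself is unchanged. Scaled counts
#' are real-valued and are not re-rounded.
#'
#' @param counts A [screen_counts] object or a numeric count matrix.
#' @param reference Name (or index) of the reference sample column.
#' @return The object with normalized (real-valued) counts.
#' @export
size_normalize <- function(counts, reference) {
  m <- if (inherits(counts, "screen_counts")) counts$counts else as.matrix(counts)
  ref_total <- sum(m[, reference])
  if (ref_total <= 0) {
    stop("degenerate sample: reference column total is 0", call. = FALSE)
  }
  totals <- colSums(m)
  if (any(totals <= 0)) {
    stop("degenerate sample: column total is 0 for ",
         paste(colnames(m)[totals <= 0], collapse = ", "), call. = FALSE)
  }
  out <- sweep(m, 2, ref_total / totals, "*")
  if (inherits(counts, "screen_counts")) {
    counts$counts <- out
    counts
  } else {
    out
  }
}

#' Pseudocounted log2 fold change
#'
#' `log2((n_treat + 1) / (n_ref + 1))`. The pseudocount of 1 keeps the
#' value finite for guides that dropped to zero counts.
#'
#' @param n_treat,n_ref Non-negative counts (vectors recycle).
#' @return The log2 fold change.
#' @examples
#' lfc(7, 3)   #  1
#' lfc(0, 0)   #  0
#' @export
lfc <- function(n_treat, n_ref) {
  if (any(n_treat < 0) || any(n_ref < 0)) {
    stop("invalid count: counts must be non-negative", call. = FALSE)
  }
  log2((n_treat + 1) / (n_ref + 1))
}

#' Guide-level log fold changes against a reference sample
#'
#' Size-normalizes to the reference total, then computes the
#' pseudocounted log2 fold change of every treatment column against the
#' reference.
#'
#' @param counts A [screen_counts] object.
#' @param reference Reference column name; defaults to the first
#'   library-stage sample if present, otherwise the first T0 sample
#'   (with a message), otherwise the first column.
#' @param treatments Treatment column names; default all `t1`-stage
#'   samples if stages are annotated, otherwise all non-reference
#'   columns.
#' @return An object of class `lfc_matrix`: a numeric matrix (guides x
#'   treatments) with attributes `reference`, `ref_abundance` (raw
#'   reference counts) and `guides`.
#' @export
lfc_matrix <- function(counts, reference = NULL, treatments = NULL) {
  stopifnot(inherits(counts, "screen_counts"))
  info <- counts$sample_info
  if (is.null(reference)) {
    if (any(info$stage == "lib", na.rm = TRUE)) {
      reference <- info$sample[which(info$stage == "lib")[1]]
    } else if (any(info$stage == "t0", na.rm = TRUE)) {
      reference <- info$sample[which(info$stage == "t0")[1]]
      message("no library sample found; using T0 sample `", reference,
              "` as reference (the plasmid library is the preferred ",
              "reference)")
    } else {
      reference <- colnames(counts$counts)[1]
    }
  }
  if (!reference %in% colnames(counts$counts)) {
    stop("reference sample `", reference, "` not found", call. = FALSE)
  }
  if (is.null(treatments)) {
    if (any(info$stage == "t1", na.rm = TRUE)) {
      treatments <- info$sample[which(info$stage == "t1")]
    } else {
      treatments <- setdiff(colnames(counts$counts), reference)
    }
  }
  if (length(treatments) < 1) stop("no treatment samples", call. = FALSE)
  norm <- size_normalize(counts, reference)$counts
  out <- vapply(treatments, function(s) lfc(norm[, s], norm[, reference]),
                numeric(nrow(norm)))
  dimnames(out) <- list(counts$guides$guide_id, treatments)
  structure(out, class = c("lfc_matrix", "matrix"),
            reference = reference,
            ref_abundance = counts$counts[, reference],
            guides = counts$guides)
}

#' Library distribution width (90/10 percentile ratio)
#'
#' Quantiles use linear interpolation between order statistics
#' (R type 7), the convention fixed throughout this package.
#'
#' @param abundance Vector of gRNA abundances (length >= 10).
#' @return `percentile90 / percentile10`.
#' @examples
#' library_width(c(50, 100, 150, 200, 250, 300, 350, 400, 450, 500, 550))
#' @export
library_width <- function(abundance) {
  if (length(abundance) < 10) {
    stop("need at least 10 abundances to estimate the width", call. = FALSE)
  }
  q <- quantile(abundance, c(0.10, 0.90), names = FALSE, type = 7)
  if (q[1] <= 0) {
    stop("undefined width: 10th percentile of the abundance distribution ",
         "is 0", call. = FALSE)
  }
  q[2] / q[1]
}

#' Tail fractions of the LFC distribution
#'
#' Fractions of guides with LFC below -1 and above +1, overall and
#' within each quintile of the reference-sample abundance, averaged
#' over treatment replicates. This is the diagnostic that exposes the
#' asymmetry of the fold-change null: bottlenecked proliferation makes
#' strong random losses (LFC < -1) more frequent than gains.
#'
#' @param lfcs An [lfc_matrix()].
#' @param guides Logical or integer index of the guides to include
#'   (e.g. the fitness-neutral ones); default all.
#' @param threshold Tail cutoff on the LFC scale (default 1).
#' @return A list with `overall` (named vector `frac_neg`, `frac_pos`)
#'   and `by_quintile` (data frame with per-quintile fractions; empty
#'   quintiles reported as `NA`).
#' @export
tail_fractions <- function(lfcs, guides = NULL, threshold = 1) {
  stopifnot(inherits(lfcs, "lfc_matrix"))
  m <- unclass(lfcs)
  ref <- attr(lfcs, "ref_abundance")
  if (is.null(guides)) guides <- seq_len(nrow(m))
  m <- m[guides, , drop = FALSE]
  ref <- ref[guides]
  if (nrow(m) == 0) stop("empty guide subset", call. = FALSE)
  frac <- function(mm) {
    c(frac_neg = mean(colMeans(mm < -threshold)),
      frac_pos = mean(colMeans(mm > threshold)))
  }
  # quintile assignment by reference abundance, stable order for ties
  qb <- quantile(ref, seq(0.2, 0.8, by = 0.2), names = FALSE, type = 7)
  quint <- findInterval(ref, unique(qb)) + 1L
  by_q <- do.call(rbind, lapply(seq_len(5), function(k) {
    sel <- quint == k
    if (!any(sel)) {
      data.frame(quintile = k, n = 0L, frac_neg = NA_real_,
                 frac_pos = NA_real_)
    } else {
      f <- frac(m[sel, , drop = FALSE])
      data.frame(quintile = k, n = sum(sel), frac_neg = f[["frac_neg"]],
                 frac_pos = f[["frac_pos"]])
    }
  }))
  list(overall = frac(m), by_quintile = by_q)
}

#' Between-replicate correlation of guide LFCs
#'
#' Pearson correlation of per-guide LFCs for every pair of treatment
#' replicates; reports the pairwise values and their mean. Wider
#' plasmid libraries produce lower replicate correlation.
#'
#' @param lfcs An [lfc_matrix()] with at least two treatment columns.
#' @return A list with `pairs` (data frame `sample1`, `sample2`, `r`)
#'   and `mean_r`. Pairs involving a constant column get a missing
#'   correlation (`NA`).
#' @export
replicate_correlation <- function(lfcs) {
  stopifnot(inherits(lfcs, "lfc_matrix"))
  m <- unclass(lfcs)
  if (ncol(m) < 2) stop("need at least two replicates", call. = FALSE)
  cmb <- utils::combn(ncol(m), 2)
  r <- apply(cmb, 2, function(ij) {
    x <- m[, ij[1]]; y <- m[, ij[2]]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else cor(x, y)
  })
  pairs <- data.frame(sample1 = colnames(m)[cmb[1, ]],
                      sample2 = colnames(m)[cmb[2, ]], r = r,
                      stringsAsFactors = FALSE)
  list(pairs = pairs, mean_r = mean(r, na.rm = !all(is.na(r))))
}
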