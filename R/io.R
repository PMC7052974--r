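#' Read a gRNA count table
#'
#' Reads the de-facto screen count dialect: a tab-separated table with
#' header `sgRNA`, `gene`, then one integer column per sample. Lines
#' starting with `#` are treated as comments. Sample roles are parsed
#' from column names of the form `<stage>_R<bio>_<tech>` when present.
#'
#' @param path File path.
#' @return A [screen_counts] object.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 3 || !identical(tolower(names(df)[1:2]), c("sgrna", "gene"))) {
    stop("malformed header in ", path,
         ": expected `sgRNA\tgene\t<sample>...` (line 1)", call. = FALSE)
  }
  guides <- data.frame(guide_id = as.character(df[[1]]),
                       gene_id = as.character(df[[2]]),
                       stringsAsFactors = FALSE)
  dup <- duplicated(guides$guide_id)
  if (any(dup)) {
    stop("duplicate guide id `", guides$guide_id[which(dup)[1]],
         "` (line ", which(dup)[1] + 1, ")", call. = FALSE)
  }
  m <- as.matrix(df[, -(1:2), drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!apply(df[, -(1:2), drop = FALSE], 1,
                        function(r) all(grepl("^[0-9]+$", trimws(r)))))[1]
    stop("non-integer count (line ", bad + 1, ")", call. = FALSE)
  }
  if (any(m < 0)) {
    bad <- which(rowSums(m < 0) > 0)[1]
    stop("negative count (line ", bad + 1, ")", call. = FALSE)
  }
  if (any(m != floor(m))) {
    bad <- which(rowSums(m != floor(m)) > 0)[1]
    stop("non-integer count (line ", bad + 1, ")", call. = FALSE)
  }
  screen_counts(guides, m)
}

#' Write a gRNA count table
#'
#' @param counts A [screen_counts] object.
#' @param path Output path.
#' @param comment Optional character vector of comment lines written
#'   as a `#`-prefixed header.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, comment = NULL) {
  stopifnot(inherits(counts, "screen_counts"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  df <- data.frame(sgRNA = counts$guides$guide_id,
                   gene = counts$guides$gene_id,
                   counts$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read the gene-level ground truth of a simulated screen
#'
#' Two-column tab-separated table mapping gene id to fitness class.
#'
#' @param truth Data frame with columns `gene_id`, `fitness_class`.
#' @param path File path.
#' @export
write_truth <- function(truth, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  write.table(truth[, c("gene_id", "fitness_class")], con, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  df <- read.delim(path, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "fitness_class") %in% names(df)))
  df
}

#' @rdname write_truth
#' @param sim A [simulate_screen()] result.
#' @param prefix Output path prefix; writes `<prefix>_counts.tsv` and
#'   `<prefix>_truth.tsv`, each with a header comment carrying the
#'   parameter hash and seed.
#' @export
write_sim <- function(sim, prefix) {
  stopifnot(inherits(sim, "screen_sim"))
  cm <- paste0("config: ", config_hash(sim$params),
               " seed: ", sim$params$rng_seed)
  write_counts(sim$counts, paste0(prefix, "_counts.tsv"), comment = cm)
  write_truth(sim$truth, paste0(prefix, "_truth.tsv"), comment = cm)
  invisible(prefix)
}

# small FNV-1a-style hash of the serialized configuration, for
# provenance comments in output files
config_hash <- function(x) {
  s <- paste(deparse(unclass(x)), collapse = "")
  h <- 0
  for (k in utf8ToInt(s)) h <- (h * 31 + k) %% 2147483647
  sprintf("%08x", as.integer(h))
}
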