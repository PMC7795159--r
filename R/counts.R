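#' Construct a layered count matrix
#'
#' Light-weight container used throughout the pipeline: a non-negative
#' integer matrix (features in rows, samples in columns) together with the
#' two-group design and an optional set of per-sample normalization factors.
#' Layers are tagged so that downstream engines can dispatch (count layers
#' use the negative-binomial machinery, the protein layer the beta-binomial
#' spectral-count test).
#'
#' @param counts numeric matrix, features x samples, non-negative; rownames
#'   and colnames are required and must be unique.
#' @param groups character or factor of length `ncol(counts)` with exactly
#'   two levels, conventionally `"A"` (PDAC-like) and `"B"` (benign-like);
#'   may be named by sample.
#' @param layer one of `"mirna"`, `"isomir"`, `"mrna"`, `"intron"`,
#'   `"protein"`.
#' @param norm_factors optional positive per-sample scalars with geometric
#'   mean 1 (as produced by [tmm_factors()]).
#' @return An object of class `"count_matrix"`.
#' @export
count_matrix <- function(counts, groups, layer = c("mirna", "isomir", "mrna",
                                                   "intron", "protein"),
                         norm_factors = NULL) {
  layer <- match.arg(layer)
  counts <- as.matrix(counts)
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      is.null(colnames(counts)))
    stop("counts must have feature rownames and sample colnames")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("feature and sample names must be unique")
  if (any(counts < 0)) stop("negative counts are not allowed")
  groups <- as.character(groups)
  if (!is.null(names(groups))) groups <- groups[colnames(counts)]
  if (length(groups) != ncol(counts))
    stop("groups must cover all samples")
  if (length(unique(groups)) != 2L)
    stop("exactly two groups are required")
  names(groups) <- colnames(counts)
  if (!is.null(norm_factors)) {
    norm_factors <- check_norm_factors(norm_factors, colnames(counts))
  }
  structure(list(counts = counts, groups = groups, layer = layer,
                 norm_factors = norm_factors),
            class = "count_matrix")
}

check_norm_factors <- function(nf, samples) {
  if (!is.null(names(nf))) nf <- nf[samples]
  if (length(nf) != length(samples) || any(!is.finite(nf)) || any(nf <= 0))
    stop("norm_factors must be finite positive scalars, one per sample")
  gm <- exp(mean(log(nf)))
  if (abs(gm - 1) > 1e-9)
    stop("norm_factors must have geometric mean 1")
  names(nf) <- samples
  nf
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix [%s]: %d features x %d samples (groups: %s)\n",
              x$layer, nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s=%d", names(table(x$groups)), table(x$groups)),
                    collapse = ", ")))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' Subset a count matrix by features and/or samples
#'
#' @param x a `count_matrix`.
#' @param features,samples character vectors (or indices) to keep; `NULL`
#'   keeps everything. Order of the result follows the order requested.
#' @return A `count_matrix`; norm factors follow a sample subset and are
#'   rescaled to geometric mean 1 (a constant rescaling of all factors
#'   shifts every sample's CPM equally and is inert downstream).
#' @export
subset_counts <- function(x, features = NULL, samples = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  cts <- x$counts
  if (!is.null(features)) cts <- cts[features, , drop = FALSE]
  nf <- x$norm_factors
  if (!is.null(samples)) {
    cts <- cts[, samples, drop = FALSE]
    if (!is.null(nf)) {
      nf <- nf[colnames(cts)]
      nf <- nf / exp(mean(log(nf)))
    }
  }
  grp <- x$groups[colnames(cts)]
  structure(list(counts = cts, groups = grp, layer = x$layer,
                 norm_factors = if (!is.null(nf)) nf[colnames(cts)] else NULL),
            class = "count_matrix")
}

#' Effective library sizes
#'
#' Column sums multiplied by the TMM (or other) normalization factors when
#' present.
#'
#' @param x a `count_matrix`.
#' @return named numeric vector of effective library sizes.
#' @export
effective_lib_sizes <- function(x) {
  ls <- colSums(x$counts)
  if (!is.null(x$norm_factors)) ls <- ls * x$norm_factors
  ls
}

#' Read / write count matrices as TSV
#'
#' Matrices are stored features-in-rows, samples-in-columns with a leading
#' `feature` column. Group labels travel in a separate sample sheet (see
#' [read_sample_sheet()]); provenance comment lines starting with `#` are
#' skipped on read.
#'
#' @param path file path.
#' @param x a `count_matrix` (for writing).
#' @param groups named group vector to attach on read.
#' @param layer layer tag to attach on read.
#' @param header optional character vector of provenance lines (written as
#'   `# ...` comments).
#' @return `read_count_tsv()` returns a `count_matrix`; `write_count_tsv()`
#'   returns the path invisibly.
#' @export
read_count_tsv <- function(path, groups, layer) {
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  count_matrix(m, groups = groups, layer = layer)
}

#' @rdname read_count_tsv
#' @export
write_count_tsv <- function(x, path, header = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  df <- data.frame(feature = rownames(x$counts), x$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the sample sheet
#'
#' Tab-separated with columns `sample`, `group` and optionally `layers`
#' (comma-separated list of layers in which the sample was assayed; the
#' proteomics subset of the PDAC group is smaller than the RNA cohort).
#'
#' @param path file path.
#' @param sheet data.frame with at least `sample` and `group` columns.
#' @return `read_sample_sheet()` returns the data.frame.
#' @export
read_sample_sheet <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("sample", "group") %in% names(df)))
    stop("sample sheet needs 'sample' and 'group' columns")
  df
}

#' @rdname read_sample_sheet
#' @export
write_sample_sheet <- function(sheet, path) {
  utils::write.table(sheet, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
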