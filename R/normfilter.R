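#' Counts per million
#'
#' @param m a [count_matrix()] or a plain non-negative matrix.
#' @param lib_sizes optional library sizes (defaults to column sums;
#'   effective sizes are NOT used here — CPM for filtering is computed on
#'   raw library sizes, normalization happens later).
#' @return numeric matrix of CPM values; every column sums to 1e6.
#' @export
cpm <- function(m, lib_sizes = NULL) {
  cts <- if (inherits(m, "count_matrix")) m$counts else as.matrix(m)
  if (is.null(lib_sizes)) lib_sizes <- colSums(cts)
  zero <- lib_sizes <= 0
  if (any(zero))
    stop("zero-sum column(s): ",
         paste(colnames(cts)[zero], collapse = ", "))
  sweep(cts, 2, lib_sizes, "/") * 1e6
}

#' Presence filter with black-and-white rescue
#'
#' A feature is retained globally when it reaches `min_cpm` CPM in
#' strictly more than `min_frac` of all samples. Features failing the
#' global rule are rescued as "black and white" cases when their pattern
#' is a strict on/off contrast: every sample of one group has zero counts,
#' and within the other ("positive") group at most `bw_max_zero_frac` of
#' the samples are zero. Everything else is dropped.
#'
#' @param m a [count_matrix()].
#' @param min_cpm CPM threshold (default 1).
#' @param min_frac fraction of all samples that must pass, strict
#'   inequality (default 0.40).
#' @param bw_max_zero_frac maximum zero fraction tolerated in the positive
#'   group (default 0.18).
#' @param bw_strict when `TRUE` (default) the non-positive group must be
#'   entirely zero; the permissive reading (`FALSE`) only requires the
#'   positive group to contain all samples passing `min_cpm`.
#' @return data.frame with `feature` and `reason` (`"global"`,
#'   `"black_white"` or `"dropped"`), in input feature order.
#' @export
presence_filter <- function(m, min_cpm = 1, min_frac = 0.40,
                            bw_max_zero_frac = 0.18, bw_strict = TRUE) {
  stopifnot(inherits(m, "count_matrix"))
  cp <- cpm(m)
  cts <- m$counts
  groups <- m$groups
  n <- ncol(cts)
  pass <- cp >= min_cpm
  global <- rowSums(pass) / n > min_frac
  reason <- ifelse(global, "global", "dropped")
  gl <- unique(groups)
  for (i in which(!global)) {
    zero <- cts[i, ] == 0
    for (g in gl) {
      in_g <- groups == g
      other_all_zero <- all(zero[!in_g])
      pos_ok <- if (bw_strict) other_all_zero
                else all(which(pass[i, ]) %in% which(in_g))
      if (pos_ok && any(!zero[in_g]) &&
          mean(zero[in_g]) <= bw_max_zero_frac) {
        reason[i] <- "black_white"
        break
      }
    }
  }
  data.frame(feature = rownames(cts), reason = reason,
             stringsAsFactors = FALSE)
}

#' Apply a presence-filter result
#'
#' @param m a [count_matrix()].
#' @param filter result of [presence_filter()].
#' @return the filtered `count_matrix`, feature order preserved.
#' @export
apply_filter <- function(m, filter) {
  keep <- filter$feature[filter$reason != "dropped"]
  subset_counts(m, features = intersect(rownames(m$counts), keep))
}

#' TMM normalization factors
#'
#' Trimmed mean of M-values: the reference sample is the one whose
#' 75th-percentile CPM is closest to the mean of those percentiles; for
#' every other sample, log2 ratios of proportions (M) and mean log2
#' proportions (A) are computed over features with nonzero counts in both
#' the sample and the reference, doubly trimmed (`trim_m` of the M
#' distribution, `trim_a` of the A distribution, rank-based on both
#' sides), and the factor is 2 to the weighted mean of the surviving M
#' values with inverse asymptotic (delta-method binomial) variance
#' weights. Factors are rescaled to geometric mean 1 so CPMs stay
#' comparable across samples.
#'
#' @param m a [count_matrix()] (already presence-filtered).
#' @param trim_m two-sided trim fraction on M (default 0.30).
#' @param trim_a two-sided trim fraction on A (default 0.05).
#' @return named numeric vector of per-sample factors, geometric mean 1.
#' @export
tmm_factors <- function(m, trim_m = 0.30, trim_a = 0.05) {
  stopifnot(inherits(m, "count_matrix"))
  cts <- m$counts
  if (ncol(cts) < 2L) stop("TMM needs >= 2 samples")
  lib <- colSums(cts)
  f75 <- apply(sweep(cts, 2, lib, "/"), 2, stats::quantile, probs = 0.75)
  ref_i <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(cts)), function(j) {
    tmm_pair(cts[, j], cts[, ref_i], lib[j], lib[ref_i], trim_m, trim_a)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(cts))
}

tmm_pair <- function(obs, ref, n_obs, n_ref, trim_m, trim_a) {
  logR <- log2((obs / n_obs) / (ref / n_ref))
  absE <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / n_obs / obs + (n_ref - ref) / n_ref / ref
  fin <- is.finite(logR) & is.finite(absE)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (length(logR) == 0L || max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * trim_m) + 1; hiL <- n + 1 - loL
  loS <- floor(n * trim_a) + 1; hiS <- n + 1 - loS
  keep <- rank(logR) >= loL & rank(logR) <= hiL &
          rank(absE) >= loS & rank(absE) <= hiS
  if (sum(keep) < 10L) {
    warning("fewer than 10 features survive TMM trimming; factor set to 1")
    return(1)
  }
  f <- sum(logR[keep] / v[keep], na.rm = TRUE) /
       sum(1 / v[keep], na.rm = TRUE)
  if (!is.finite(f)) f <- 0
  2^f
}

#' Normalized expression on effective library sizes
#'
#' CPM computed on effective library sizes (library size times TMM
#' factor), optionally log2-transformed with a +1 pseudo-count.
#'
#' @param m a [count_matrix()]; its `norm_factors` are used when present
#'   (identity otherwise).
#' @param log when `TRUE`, return `log2(norm CPM + 1)`.
#' @return numeric matrix of normalized expression values.
#' @export
normalize_counts <- function(m, log = FALSE) {
  stopifnot(inherits(m, "count_matrix"))
  out <- cpm(m, lib_sizes = effective_lib_sizes(m))
  if (log) out <- log2(out + 1)
  out
}

#' Median-ratio scaling for protein spectral counts
#'
#' The protein layer bypasses CPM/TMM (its differential engine models the
#' per-sample totals directly); for reporting, spectral counts can be
#' scaled so per-sample medians of ratios to the feature-wise reference
#' (geometric-mean profile over positive features) agree — the global
#' median normalization used for spectral-count tables.
#'
#' @param m a [count_matrix()] of the protein layer.
#' @return matrix of scaled spectral counts.
#' @export
median_scale <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  cts <- m$counts
  pos <- rowSums(cts == 0) == 0
  if (!any(pos)) return(cts)
  ref <- exp(rowMeans(log(cts[pos, , drop = FALSE])))
  sf <- apply(cts[pos, , drop = FALSE], 2, function(col)
    stats::median(col / ref))
  sweep(cts, 2, sf, "/")
}
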