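#' Read / write gene-set collections in GMT format
#'
#' Standard tab-separated GMT: set name, description, then member ids.
#' Windows line endings are accepted; malformed lines (fewer than three
#' fields) raise an error naming the line number.
#'
#' @param path GMT file path.
#' @param sets named list of character vectors (for writing).
#' @param descriptions optional descriptions, recycled.
#' @return `read_gmt()` returns a named list of unique member vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop(sprintf("malformed GMT line %d: expected >= 3 tab-separated fields",
                   i))
    members <- unique(f[-(1:2)])
    members <- members[nzchar(members)]
    if (length(members) == 0L)
      stop(sprintf("malformed GMT line %d: empty member list", i))
    sets[[f[1]]] <- members
  }
  sets
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = "na") {
  descriptions <- rep_len(descriptions, length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Ranking statistic for preranked enrichment
#'
#' `-log10(p) * sign(log2FC)`, the signed significance used to order
#' features before the gene-set walk. P-values are floored at 1e-300 so a
#' numerical zero cannot break the ranking.
#'
#' @param de a [differential_table()] result (or any data.frame with `p`
#'   and `log2FC`).
#' @return named numeric vector of ranking values (names = features).
#' @export
rank_stat <- function(de) {
  p <- pmax(de$p, 1e-300)
  stats::setNames(-log10(p) * sign(de$log2FC), de$feature)
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranking from top to bottom; hitting a set member increments
#' the running sum by `|stat|^w / sum(|stat|^w over members)`, missing one
#' decrements it by `1 / (N - n_set)`. The enrichment score is the running
#' sum's largest absolute deviation from zero, signed. Weight `w = 1` is
#' the classic weighted statistic; `w = 0` gives the unweighted KS form.
#'
#' @param ranked named numeric vector of ranking statistics, sorted
#'   decreasingly (it is re-sorted defensively).
#' @param set character vector of member ids; must intersect the ranked
#'   universe without covering it entirely.
#' @param w weight exponent (default 1).
#' @return the signed enrichment score in \[-1, 1\].
#' @export
gsea_es <- function(ranked, set, w = 1) {
  ranked <- sort(ranked, decreasing = TRUE)
  hits <- names(ranked) %in% set
  n_hit <- sum(hits)
  if (n_hit == 0L) stop("set is disjoint from the ranked universe")
  if (n_hit == length(ranked))
    stop("set covers the entire ranked universe")
  es_from_positions(which(hits), abs(ranked), w, length(ranked))
}

# enrichment score from sorted member positions; O(n_set) given the
# absolute stats vector. Extremes of the running sum can only occur just
# after a member increment or just before the next one, so only member
# positions need to be visited.
es_from_positions <- function(pos, abs_stat, w, N) {
  pos <- sort(pos)
  n_set <- length(pos)
  wts <- abs_stat[pos]^w
  denom <- sum(wts)
  if (denom == 0) { wts <- rep(1, n_set); denom <- n_set }
  dec <- 1 / (N - n_set)
  cum <- cumsum(wts / denom)
  i <- seq_len(n_set)
  after <- cum - (pos - i) * dec              # just after hit i
  before <- c(0, cum[-n_set]) - (pos - 1 - (i - 1)) * dec  # just before
  cand <- c(after, before)
  unname(cand[which.max(abs(cand))])
}

#' Preranked permutation GSEA
#'
#' Enrichment scores per set with gene-label permutation nulls preserving
#' set size: `n_perm` random position sets of the same size are scored,
#' the p-value is `(1 + #same-sign permutations with |ES| >= |observed|) /
#' (1 + #same-sign permutations)`, and the normalized enrichment score
#' divides the observed ES by the mean |ES| of same-sign permutations.
#' Deterministic given `seed`.
#'
#' @param ranked named numeric vector of ranking statistics.
#' @param sets named list of gene sets; sets not intersecting the
#'   universe (or covering it) are skipped with a warning.
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed.
#' @param w weight exponent.
#' @param layer optional layer tag copied into the result.
#' @param alpha significance level for the flag (default 0.05).
#' @return data.frame of class `"enrichment_result"`: `set`, `layer`,
#'   `size`, `ES`, `NES`, `p`, `significant`, `direction` (+1/-1).
#' @export
gsea_preranked <- function(ranked, sets, n_perm = 1000L, seed = NULL,
                           w = 1, layer = NA_character_, alpha = 0.05) {
  if (n_perm < 100L) stop("n_perm must be >= 100")
  if (!is.null(seed)) set.seed(seed)
  ranked <- sort(ranked, decreasing = TRUE)
  abs_stat <- abs(ranked)
  N <- length(ranked)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], names(ranked))
    n_set <- length(members)
    if (n_set == 0L || n_set == N) {
      warning("set '", nm, "' skipped: empty or full overlap with universe")
      return(NULL)
    }
    pos <- which(names(ranked) %in% members)
    es <- es_from_positions(pos, abs_stat, w, N)
    perm <- vapply(seq_len(n_perm), function(i)
      es_from_positions(sample.int(N, n_set), abs_stat, w, N), numeric(1))
    same <- sign(perm) == sign(es)
    n_same <- sum(same)
    p <- (1 + sum(same & abs(perm) >= abs(es))) / (1 + n_same)
    nes <- if (n_same > 0) es / mean(abs(perm[same])) else NA_real_
    data.frame(set = nm, layer = layer, size = n_set, ES = es, NES = nes,
               p = p, significant = p < alpha,
               direction = sign(es), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(set = character(0), layer = character(0),
                      size = integer(0), ES = numeric(0), NES = numeric(0),
                      p = numeric(0), significant = logical(0),
                      direction = numeric(0))
  class(out) <- c("enrichment_result", "data.frame")
  rownames(out) <- NULL
  out
}

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability of observing at least the actual overlap
#' between a hit list and a gene set, both inside a finite universe.
#'
#' @param hits character vector, subset of `universe`.
#' @param universe character vector of all testable features.
#' @param set character vector of set members (intersected with the
#'   universe; the intersection must be non-empty).
#' @return p-value in (0, 1].
#' @export
ora_hypergeom <- function(hits, universe, set) {
  hits <- unique(hits); universe <- unique(universe)
  if (!all(hits %in% universe)) stop("hits must be a subset of the universe")
  set_u <- intersect(unique(set), universe)
  if (length(set_u) == 0L) stop("set does not intersect the universe")
  k <- length(intersect(hits, set_u))
  stats::phyper(k - 1, length(set_u), length(universe) - length(set_u),
                length(hits), lower.tail = FALSE)
}

#' miRNA over-representation with the fixed-NES convention
#'
#' Over-representation of differentially expressed miRNAs in annotation
#' sets (the web-tool style analysis miRNAs get instead of a ranked walk,
#' since they lack a natural ranked universe here). Because ORA yields no
#' enrichment score, the NES of every significant set is fixed at 1.5
#' times the direction sign, where the direction is the majority fold
#' change sign of the hit miRNAs in the set.
#'
#' @param de_mirnas character vector of DE miRNA ids (the hits).
#' @param universe all filtered miRNA ids.
#' @param sets named list of miRNA annotation sets (GMT-style).
#' @param de_table optional [differential_table()] rows used to determine
#'   per-set direction; defaults direction to +1 when absent.
#' @param alpha significance level (default 0.05).
#' @return `"enrichment_result"` data.frame (ES is `NA`; NES is
#'   `1.5 * direction` for significant sets, `NA` otherwise).
#' @export
mirna_ora <- function(de_mirnas, universe, sets, de_table = NULL,
                      alpha = 0.05) {
  rows <- lapply(names(sets), function(nm) {
    set_u <- intersect(sets[[nm]], universe)
    if (length(set_u) == 0L) return(NULL)
    p <- ora_hypergeom(de_mirnas, universe, set_u)
    in_set <- intersect(de_mirnas, set_u)
    dir <- 1
    if (!is.null(de_table) && length(in_set) > 0) {
      lfc <- de_table$log2FC[match(in_set, de_table$feature)]
      dir <- if (sum(sign(lfc), na.rm = TRUE) < 0) -1 else 1
    }
    sig <- p < alpha
    data.frame(set = nm, layer = "mirna", size = length(set_u),
               ES = NA_real_, NES = if (sig) 1.5 * dir else NA_real_,
               p = p, significant = sig, direction = dir,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    stop("no annotation set intersects the miRNA universe")
  class(out) <- c("enrichment_result", "data.frame")
  rownames(out) <- NULL
  out
}

#' Terms significant in every layer, with per-layer direction
#'
#' Integrates per-layer enrichment results by retaining only the terms
#' significant (`p < alpha`) in all provided layers, annotating each with
#' its per-layer NES and direction sign — the cross-layer term overlap
#' that asks which programs are maintained across the whole cascade.
#'
#' @param results named list (>= 2 layers) of `"enrichment_result"`
#'   data.frames.
#' @param alpha significance level (default 0.05).
#' @param use_padj apply the threshold to BH-adjusted p-values instead of
#'   raw ones.
#' @return data.frame `term`, `layer`, `NES`, `direction`, long format,
#'   restricted to terms passing in every layer.
#' @export
cross_layer_overlap <- function(results, alpha = 0.05, use_padj = FALSE) {
  if (length(results) < 2L) stop("need >= 2 layers to overlap")
  if (is.null(names(results)) || any(!nzchar(names(results))))
    stop("results must be a named list of layers")
  sig_terms <- lapply(results, function(r) {
    p <- if (use_padj) stats::p.adjust(r$p, "BH") else r$p
    r$set[p < alpha]
  })
  common <- Reduce(intersect, sig_terms)
  out <- do.call(rbind, lapply(names(results), function(ly) {
    r <- results[[ly]]
    r <- r[r$set %in% common, , drop = FALSE]
    if (nrow(r) == 0L) return(NULL)
    data.frame(term = r$set, layer = ly, NES = r$NES,
               direction = r$direction, stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(term = character(0), layer = character(0),
                      NES = numeric(0), direction = numeric(0))
  out[order(out$term, out$layer), , drop = FALSE]
}
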