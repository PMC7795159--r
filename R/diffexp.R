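#' Method-of-moments common NB dispersion
#'
#' Counts are linearly adjusted to a common library size, then for every
#' feature the within-group moment estimate `(s^2 - mu) / mu^2` of the NB
#' dispersion (variance = mu + phi mu^2) is computed and averaged over
#' groups and features; the pooled estimate is floored at zero. A single
#' common dispersion is shared by all features — per-feature
#' empirical-Bayes moderation is deliberately not performed.
#'
#' @param m a [count_matrix()].
#' @return list of class `"dispersion_estimate"` with `phi` (>= 0) and
#'   `method`.
#' @export
estimate_common_dispersion <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  cts <- m$counts
  if (all(cts == 0)) {
    warning("all-zero matrix: dispersion set to 0")
    return(structure(list(phi = 0, method = "moments"),
                     class = "dispersion_estimate"))
  }
  groups <- m$groups
  if (min(table(groups)) < 2L) stop("need >= 2 samples per group")
  lib <- effective_lib_sizes(m)
  adj <- sweep(cts, 2, mean(lib) / lib, "*")
  phis <- sapply(unique(groups), function(g) {
    sub <- adj[, groups == g, drop = FALSE]
    mu <- rowMeans(sub)
    s2 <- apply(sub, 1, stats::var)
    ifelse(mu > 0, (s2 - mu) / mu^2, NA_real_)
  })
  phi <- max(0, mean(phis, na.rm = TRUE))
  structure(list(phi = phi, method = "moments"),
            class = "dispersion_estimate")
}

# log conditional probability of the split (k, S - k) of the group sums,
# Sa ~ NB(size ra, q), Sb ~ NB(size rb, q) independent: the conditional
# given Sa + Sb = S is negative hypergeometric, free of q.
nb_split_logprob <- function(k, S, ra, rb) {
  lgamma(k + ra) - lgamma(k + 1) - lgamma(ra) +
    lgamma(S - k + rb) - lgamma(S - k + 1) - lgamma(rb) -
    (lgamma(S + ra + rb) - lgamma(S + 1) - lgamma(ra + rb))
}

#' Negative-binomial exact test for a two-group count comparison
#'
#' Counts are rescaled to a common (geometric-mean) library size and
#' rounded to pseudo-counts; the group sums are then modeled as negative
#' binomial with means proportional to group size under the null, and the
#' conditional distribution of the split given the total is enumerated
#' exactly. The two-sided p-value sums the probabilities of all splits at
#' most as probable as the observed one (minimum-likelihood ordering).
#' At dispersion zero the conditional law is binomial and the test reduces
#' to the exact conditional Poisson comparison.
#'
#' @param a_counts,b_counts non-negative integer count vectors.
#' @param lib_sizes library sizes, a vector of `length(a) + length(b)`
#'   (a-samples first) or a list with elements `a` and `b`.
#' @param phi common NB dispersion, >= 0.
#' @return two-sided p-value in (0, 1].
#' @export
nb_exact_test <- function(a_counts, b_counts, lib_sizes = NULL, phi = 0) {
  if (phi < 0) stop("phi must be >= 0")
  counts <- c(a_counts, b_counts)
  if (any(counts < 0) || any(abs(counts - round(counts)) > 1e-8))
    stop("counts must be non-negative integers")
  na <- length(a_counts); nb <- length(b_counts)
  if (is.list(lib_sizes)) lib_sizes <- c(lib_sizes$a, lib_sizes$b)
  if (is.null(lib_sizes)) lib_sizes <- rep(1, na + nb)
  if (length(lib_sizes) != na + nb) stop("lib_sizes length mismatch")
  L <- exp(mean(log(lib_sizes)))
  pseudo <- round(counts * L / lib_sizes)
  Sa <- sum(pseudo[seq_len(na)]); Sb <- sum(pseudo[na + seq_len(nb)])
  S <- Sa + Sb
  if (S == 0) return(1)
  if (phi == 0) {
    lp <- stats::dbinom(0:S, S, na / (na + nb), log = TRUE)
    lp_obs <- lp[Sa + 1]
    return(min(1, sum(exp(lp[lp <= lp_obs + 1e-12]))))
  }
  ra <- na / phi; rb <- nb / phi
  if (S <= 50000) {
    lp <- nb_split_logprob(0:S, S, ra, rb)
    lp_obs <- lp[Sa + 1]
    return(min(1, sum(exp(lp[lp <= lp_obs + 1e-12]))))
  }
  nb_exact_test_large(Sa, S, ra, rb)
}

# Large-total branch: the conditional split law is log-concave, hence
# unimodal; locate the mode and the two likelihood-ordering boundaries by
# binary search and accumulate the tails outward-in until convergence.
nb_exact_test_large <- function(Sa, S, ra, rb) {
  lp <- function(k) nb_split_logprob(k, S, ra, rb)
  lp_obs <- lp(Sa)
  # p(k+1)/p(k) >= 1  <=>  (ra+k)(S-k) >= (k+1)(rb+S-k-1)
  ratio_ge1 <- function(k) (ra + k) * (S - k) >= (k + 1) * (rb + S - k - 1)
  lo <- 0; hi <- S - 1
  if (!ratio_ge1(0)) mode_k <- 0
  else if (ratio_ge1(S - 1)) mode_k <- S
  else {
    while (hi - lo > 1) {         # largest k with increasing ratio
      mid <- floor((lo + hi) / 2)
      if (ratio_ge1(mid)) lo <- mid else hi <- mid
    }
    mode_k <- lo + 1
  }
  tol <- 1e-12
  if (lp(mode_k) <= lp_obs + tol) return(1)
  bsearch <- function(lo, hi, pred) {   # largest k in [lo,hi] with pred(k)
    if (!pred(lo)) return(lo - 1)
    while (hi - lo > 1) {
      mid <- floor((lo + hi) / 2)
      if (pred(mid)) lo <- mid else hi <- mid
    }
    if (pred(hi)) hi else lo
  }
  p <- 0
  if (lp(0) <= lp_obs + tol) {        # left tail, increasing toward mode
    k1 <- bsearch(0, mode_k - 1, function(k) lp(k) <= lp_obs + tol)
    p <- p + sum_tail(lp, k1, -1L)
  }
  if (lp(S) <= lp_obs + tol) {        # right tail, decreasing from mode
    k2 <- S - bsearch(0, S - mode_k - 1,
                      function(j) lp(S - j) <= lp_obs + tol)
    p <- p + sum_tail(lp, k2, +1L, kmax = S)
  }
  min(1, p)
}

# sum p(k) from a boundary outward (terms decrease monotonically)
sum_tail <- function(lp, k_from, step, kmax = Inf, chunk = 4096L) {
  total <- 0
  k <- k_from
  repeat {
    if (step < 0) ks <- seq(k, max(0, k - chunk + 1)) else
                  ks <- seq(k, min(kmax, k + chunk - 1))
    if (length(ks) == 0) break
    probs <- exp(lp(ks))
    total <- total + sum(probs)
    if (probs[length(probs)] < total * 1e-17) break
    if (step < 0 && min(ks) == 0) break
    if (step > 0 && max(ks) == kmax) break
    k <- ks[length(ks)] + step
  }
  total
}

bb_loglik <- function(k, n, lpi, lth) {
  pi <- stats::plogis(lpi)
  th <- exp(lth)
  a <- pi / th; b <- (1 - pi) / th
  sum(lchoose(n, k) + lbeta(k + a, n - k + b) - lbeta(a, b))
}

#' Beta-binomial likelihood-ratio test for spectral counts
#'
#' Models each sample's spectral count for one protein as beta-binomial in
#' the sample's total with a common overdispersion, and tests a single
#' success probability for all samples (H0) against group-specific
#' probabilities (H1, shared overdispersion) by likelihood ratio against
#' chi-squared with 1 df. Maximum-likelihood estimates are obtained by
#' bounded quasi-Newton optimization on the (logit pi, log theta) scale.
#'
#' @param k_a,k_b per-sample spectral counts of the feature in the two
#'   groups.
#' @param n_a,n_b per-sample totals (same lengths).
#' @return two-sided p-value; `NaN` with a warning if the optimizer fails.
#' @export
bb_test <- function(k_a, k_b, n_a, n_b) {
  stopifnot(length(k_a) == length(n_a), length(k_b) == length(n_b))
  k <- c(k_a, k_b); n <- c(n_a, n_b)
  if (any(k < 0) || any(k > n)) stop("need 0 <= k <= n per sample")
  if (sum(k) == 0 || sum(n - k) == 0) return(1)
  grp_a <- seq_along(k_a)
  # bounded quasi-Newton with a derivative-free polish: L-BFGS-B can abort
  # its line search on flat beta-binomial likelihood ridges, so a
  # Nelder-Mead pass (clamped to the same box) backs it up.
  fit <- function(par, fn) {
    n_pi <- length(par) - 1L
    lower <- c(rep(-20, n_pi), -12); upper <- c(rep(15, n_pi), 5)
    clamped <- function(p) fn(pmin(pmax(p, lower), upper))
    o1 <- tryCatch(
      stats::optim(par, fn, method = "L-BFGS-B", lower = lower,
                   upper = upper,
                   control = list(fnscale = -1, factr = 1e4, maxit = 500)),
      error = function(e) NULL)
    start2 <- if (!is.null(o1)) o1$par else par
    o2 <- tryCatch(
      stats::optim(start2, clamped, method = "Nelder-Mead",
                   control = list(fnscale = -1, reltol = 1e-12,
                                  maxit = 5000)),
      error = function(e) NULL)
    if (!is.null(o2)) o2$par <- pmin(pmax(o2$par, lower), upper)
    cands <- Filter(function(o) !is.null(o) && o$convergence == 0 &&
                      is.finite(o$value), list(o2, o1))
    if (length(cands) == 0L) return(NULL)
    cands[[which.max(vapply(cands, `[[`, numeric(1), "value"))]]
  }
  lpi0 <- stats::qlogis(min(max(sum(k) / sum(n), 1e-8), 1 - 1e-8))
  f0 <- function(p) bb_loglik(k, n, p[1], p[2])
  f1 <- function(p) bb_loglik(k[grp_a], n[grp_a], p[1], p[3]) +
                    bb_loglik(k[-grp_a], n[-grp_a], p[2], p[3])
  o0 <- fit(c(lpi0, log(0.01)), f0)
  lpa <- stats::qlogis(min(max(sum(k_a) / sum(n_a), 1e-8), 1 - 1e-8))
  lpb <- stats::qlogis(min(max(sum(k_b) / sum(n_b), 1e-8), 1 - 1e-8))
  th0 <- if (!is.null(o0)) o0$par[length(o0$par)] else log(0.01)
  o1 <- fit(c(lpa, lpb, th0), f1)
  if (is.null(o0) || is.null(o1)) {
    warning("beta-binomial optimizer did not converge; p = NaN")
    return(NaN)
  }
  lr <- max(0, 2 * (o1$value - o0$value))
  stats::pchisq(lr, df = 1, lower.tail = FALSE)
}

#' Per-feature differential expression table
#'
#' Runs the layer-appropriate engine over every feature of a filtered
#' (and, for count layers, TMM-normalized) matrix and applies the
#' significance rules: count layers require `p < alpha` and
#' `|log2FC| > lfc_cut`; the protein layer only `p < alpha`. The fold
#' change is `log2((mean normalized abundance in A + 0.5) /
#' (mean in B + 0.5))`, so positive values are up in the PDAC-like group
#' A. A Benjamini-Hochberg column is emitted for reference but plays no
#' role in the significance flags, which threshold raw p-values.
#'
#' @param m a [count_matrix()].
#' @param engine `"nb_exact"` (count layers) or `"bb"` (protein layer).
#' @param phi common dispersion for `"nb_exact"`; estimated from `m` via
#'   [estimate_common_dispersion()] when `NULL`.
#' @param alpha significance level (default 0.05).
#' @param lfc_cut absolute log2FC threshold for count layers (default 1).
#' @return data.frame sorted by p (ties by |log2FC| then feature id) with
#'   columns `feature`, `layer`, `log2FC`, `p`, `padj`, `mean_A`,
#'   `mean_B`, `direction` (`up_A`/`up_B`), `significant`.
#' @export
differential_table <- function(m, engine = c("nb_exact", "bb"), phi = NULL,
                               alpha = 0.05, lfc_cut = 1) {
  stopifnot(inherits(m, "count_matrix"))
  engine <- match.arg(engine)
  cts <- m$counts
  if (nrow(cts) == 0L)
    return(data.frame(feature = character(0), layer = character(0),
                      log2FC = numeric(0), p = numeric(0),
                      padj = numeric(0), mean_A = numeric(0),
                      mean_B = numeric(0), direction = character(0),
                      significant = logical(0)))
  groups <- m$groups
  a_idx <- which(groups == "A"); b_idx <- which(groups == "B")
  if (engine == "nb_exact") {
    if (is.null(phi)) phi <- estimate_common_dispersion(m)$phi
    lib <- effective_lib_sizes(m)
    norm <- normalize_counts(m)
    p <- vapply(seq_len(nrow(cts)), function(i)
      nb_exact_test(cts[i, a_idx], cts[i, b_idx],
                    c(lib[a_idx], lib[b_idx]), phi), numeric(1))
  } else {
    tot <- colSums(cts)
    norm <- median_scale(m)
    p <- vapply(seq_len(nrow(cts)), function(i)
      bb_test(cts[i, a_idx], cts[i, b_idx], tot[a_idx], tot[b_idx]),
      numeric(1))
  }
  mean_a <- rowMeans(norm[, a_idx, drop = FALSE])
  mean_b <- rowMeans(norm[, b_idx, drop = FALSE])
  lfc <- log2((mean_a + 0.5) / (mean_b + 0.5))
  sig <- if (engine == "nb_exact") p < alpha & abs(lfc) > lfc_cut
         else p < alpha
  out <- data.frame(feature = rownames(cts), layer = m$layer,
                    log2FC = lfc, p = p,
                    padj = stats::p.adjust(p, "BH"),
                    mean_A = mean_a, mean_B = mean_b,
                    direction = ifelse(lfc > 0, "up_A", "up_B"),
                    significant = sig & !is.na(p),
                    stringsAsFactors = FALSE)
  out <- out[order(out$p, -abs(out$log2FC), out$feature), ]
  rownames(out) <- NULL
  out
}

#' Write a differential expression table as TSV
#'
#' @param de a [differential_table()] result.
#' @param path output path.
#' @param header optional provenance comment lines.
#' @export
write_de_tsv <- function(de, path, header = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(de, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
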