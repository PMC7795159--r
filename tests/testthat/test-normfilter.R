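test_that("cpm is a per-column normalization to one million", {
  one <- count_matrix(matrix(7, 1, 2, dimnames = list("f", c("a", "b"))),
                      c("A", "B"), "mrna")
  expect_equal(unname(cpm(one)[1, ]), c(1e6, 1e6))

  mat <- matrix(c(1, 3, 2, 2), 2, 2,
                dimnames = list(c("f1", "f2"), c("s1", "s2")))
  cm <- count_matrix(mat, c("A", "B"), "mrna")
  expect_equal(unname(cpm(cm)[, 1]), c(250000, 750000))

  set.seed(8)
  rnd <- random_counts(20, 6)
  expect_equal(unname(colSums(cpm(rnd))), rep(1e6, 6), tolerance = 1e-6)

  z <- mat; z[, 2] <- 0
  zc <- count_matrix(z, c("A", "B"), "mrna")
  expect_error(cpm(zc), "s2")
})

test_that("presence filter applies the global and black-and-white rules", {
  m <- toy_filter_matrix()
  flt <- presence_filter(m)
  reasons <- setNames(flt$reason, flt$feature)
  expect_equal(unname(reasons["f_global"]), "global")
  expect_equal(unname(reasons["f_edge9"]), "global")      # 9/22 = 41% > 40%
  expect_equal(unname(reasons["f_bw"]), "black_white")    # zero-frac 1/11
  expect_equal(unname(reasons["f_fail"]), "dropped")      # 3/11 > 0.18
  expect_equal(unname(reasons["f_edge8"]), "dropped")
  expect_equal(unname(reasons["f_perm"]), "dropped")      # A not all zero
  expect_equal(unname(reasons["f_filler"]), "global")

  kept <- apply_filter(m, flt)
  expect_equal(rownames(kept$counts),
               c("f_global", "f_edge9", "f_bw", "f_filler"))

  # permissive reading rescues f_perm: every sample reaching 1 CPM is in
  # the positive group, whose zero fraction is 1/11
  rel <- presence_filter(m, bw_strict = FALSE)
  expect_equal(rel$reason[rel$feature == "f_perm"], "black_white")
  expect_equal(rel$reason[rel$feature == "f_fail"], "dropped")  # 3/11 > .18
})

test_that("global rule is monotone in passing samples", {
  set.seed(13)
  for (i in 1:5) {
    m <- random_counts(30, 10, mu = 20, seed = 100 + i)
    flt <- presence_filter(m)
    kept_global <- flt$feature[flt$reason == "global"]
    # append a sample in which every feature passes comfortably
    ext <- cbind(m$counts, s_new = pmax(m$counts[, 1], 500))
    m2 <- count_matrix(ext, c(m$groups, s_new = "A"), "mrna")
    flt2 <- presence_filter(m2)
    still <- flt2$feature[flt2$reason != "dropped"]
    expect_true(all(kept_global %in% still))
  }
})

test_that("TMM factors: identity, depth-change and rescaling invariance", {
  base <- random_counts(200, 4, mu = 200, seed = 3)
  same <- count_matrix(matrix(base$counts[, 1], 200, 4,
                              dimnames = dimnames(base$counts)),
                       base$groups, "mrna")
  expect_equal(unname(tmm_factors(same)), rep(1, 4), tolerance = 1e-9)

  # pure depth change: one column doubled, composition unchanged
  dbl <- base$counts
  dbl[, 2] <- dbl[, 1] * 2
  f <- tmm_factors(count_matrix(dbl, base$groups, "mrna"))
  expect_equal(unname(f), rep(1, 4), tolerance = 0.01)

  # global library rescaling leaves factors unchanged
  f0 <- tmm_factors(base)
  f5 <- tmm_factors(count_matrix(base$counts * 5, base$groups, "mrna"))
  expect_equal(f0, f5, tolerance = 1e-9)
})

test_that("TMM matches a direct-formula oracle on a contaminated matrix", {
  set.seed(5)
  cts <- matrix(rpois(6 * 3, 300), 6, 3,
                dimnames = list(paste0("g", 1:6), paste0("s", 1:3)))
  cts["g1", 3] <- 30000   # high-abundance contaminant in sample 3
  cts <- rbind(cts, matrix(rpois(40 * 3, 100), 40, 3,
                           dimnames = list(paste0("h", 1:40),
                                           paste0("s", 1:3))))
  cm <- count_matrix(cts, c("A", "A", "B"), "mrna")

  # independent oracle: direct evaluation of the trimmed weighted mean
  oracle_tmm <- function(counts, trim_m = 0.3, trim_a = 0.05) {
    lib <- colSums(counts)
    p75 <- apply(sweep(counts, 2, lib, "/"), 2, quantile, probs = 0.75)
    ref <- which.min(abs(p75 - mean(p75)))
    f <- sapply(seq_len(ncol(counts)), function(j) {
      ok <- counts[, j] > 0 & counts[, ref] > 0
      o <- counts[ok, j] / lib[j]; r <- counts[ok, ref] / lib[ref]
      M <- log2(o / r); A <- (log2(o) + log2(r)) / 2
      n <- length(M)
      lo <- floor(n * trim_m) + 1; hi <- n + 1 - lo
      loA <- floor(n * trim_a) + 1; hiA <- n + 1 - loA
      keep <- rank(M) >= lo & rank(M) <= hi &
              rank(A) >= loA & rank(A) <= hiA
      if (max(abs(M)) < 1e-6) return(1)
      w <- 1 / ((lib[j] - counts[ok, j]) / (lib[j] * counts[ok, j]) +
                (lib[ref] - counts[ok, ref]) / (lib[ref] * counts[ok, ref]))
      2^(sum((M * w)[keep]) / sum(w[keep]))
    })
    f / exp(mean(log(f)))
  }
  expect_equal(unname(tmm_factors(cm)), oracle_tmm(cts), tolerance = 1e-6)
  # the contaminated sample is compensated downward
  expect_lt(tmm_factors(cm)[["s3"]], 1)
})

test_that("TMM agrees with the edgeR reference implementation", {
  skip_if_not_installed("edgeR")
  set.seed(17)
  for (i in 1:3) {
    m <- random_counts(300, 5, mu = 150, phi = 0.2, seed = 400 + i)
    ours <- tmm_factors(m)
    theirs <- edgeR::calcNormFactors(edgeR::DGEList(m$counts))$samples$norm.factors
    expect_equal(unname(ours), theirs, tolerance = 1e-8)
  }
})

test_that("tiny matrices fall back to unit factors with a warning", {
  cts <- matrix(c(5, 9, 3, 7, 2, 11), 3, 2,
                dimnames = list(paste0("f", 1:3), c("a", "b")))
  cm <- count_matrix(cts, c("A", "B"), "mrna")
  expect_warning(f <- tmm_factors(cm), "fewer than 10")
  expect_equal(unname(f), c(1, 1))
})

test_that("normalization honours factors and is depth-invariant", {
  m <- random_counts(50, 4, seed = 19)
  expect_equal(normalize_counts(m), cpm(m))                 # identity factors
  m2 <- count_matrix(m$counts * 2, m$groups, "mrna")
  expect_equal(normalize_counts(m2), normalize_counts(m))   # doubling inert
  lg <- normalize_counts(m, log = TRUE)
  expect_equal(lg, log2(cpm(m) + 1))
  # order stability through filter + normalize
  flt <- presence_filter(m)
  kept <- apply_filter(m, flt)
  expect_identical(rownames(kept$counts),
                   intersect(rownames(m$counts), rownames(kept$counts)))
})

test_that("median-ratio scaling equalizes sample medians", {
  set.seed(23)
  cts <- matrix(rpois(80 * 4, 50), 80, 4,
                dimnames = list(paste0("p", 1:80), paste0("s", 1:4)))
  cts[, 2] <- cts[, 2] * 3
  cm <- count_matrix(cts, c("A", "A", "B", "B"), "protein")
  sc <- median_scale(cm)
  ref <- exp(rowMeans(log(sc)))
  meds <- apply(sc, 2, function(col) median(col / ref))
  expect_equal(unname(meds), rep(1, 4), tolerance = 0.05)
})
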