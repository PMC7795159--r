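# shared fixtures, all built in code

# 7-feature / 22-sample toy matrix exercising every presence-filter path
# (library ~2e6, so a count of 1 is 0.5 CPM: nonzero yet below min_cpm):
#  f_global   1 CPM reached in 10/22 samples (45% > 40%)
#  f_edge9    passes in 9/22 (40.9% > 40%) -> global
#  f_edge8    passes in 8/22 (36.4%), spread over both groups -> dropped
#  f_bw       zero in all of A; in B: 7 samples at 2 CPM, 3 at 0.5 CPM,
#             1 zero -> global 7/22 fails, zero-frac 1/11 <= 0.18 -> rescue
#  f_fail     zero in all A, 2 CPM in 8/11 B (zero-frac 3/11) -> dropped
#  f_perm     one stray nonzero A sample below 1 CPM; B as f_bw ->
#             dropped under the strict reading, rescued permissively
#  f_filler   abundant everywhere (sets the library size)
toy_filter_matrix <- function() {
  n <- 22L
  m <- matrix(0, 7, n,
              dimnames = list(c("f_global", "f_edge9", "f_edge8", "f_bw",
                                "f_fail", "f_perm", "f_filler"),
                              sprintf("s%02d", 1:n)))
  groups <- rep(c("A", "B"), each = 11)
  m["f_filler", ] <- 2e6
  m["f_global", c(1:5, 12:16)] <- 50
  m["f_edge9", c(1:4, 12:16)] <- 50
  m["f_edge8", c(1:4, 12:15)] <- 50
  m["f_bw", 12:18] <- 4; m["f_bw", 19:21] <- 1
  m["f_fail", 12:19] <- 4
  m["f_perm", 12:18] <- 4; m["f_perm", 19:21] <- 1; m["f_perm", 1] <- 1
  count_matrix(m, groups, "mrna")
}

# a fixed two-entry reference with hand-chosen flanks, used by the
# classify_read example tests
tiny_ref <- function() {
  ref <- data.frame(
    name = c("mir-X", "mir-Y"),
    mature_seq = c("UGAGGUAGUAGGUUGUAUAGUU",   # 22 nt
                   "ACCCGUAGAUCCGAACUUGUGA"),  # 22 nt
    flank5 = c("CCUACG", "GGAUAC"),
    flank3 = c("GGAAAC", "CUUCCA"),
    stringsAsFactors = FALSE)
  class(ref) <- c("mirna_reference", "data.frame")
  ref
}

# random NB count matrix with two groups
random_counts <- function(G = 50, n = 6, mu = 100, phi = 0.1, seed = 1,
                          layer = "mrna") {
  set.seed(seed)
  m <- matrix(rnbinom(G * n, mu = mu, size = 1 / phi), G, n,
              dimnames = list(sprintf("f%03d", 1:G), sprintf("s%02d", 1:n)))
  count_matrix(m, rep(c("A", "B"), length.out = n), layer)
}

with_tmm <- function(m) {
  m$norm_factors <- tmm_factors(m)
  m
}
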