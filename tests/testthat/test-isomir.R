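test_that("classification decision tree labels the canonical cases", {
  ref <- tiny_ref()[1, ]   # mature ...UAUAGUU, flank3 = GGAAAC
  m <- ref$mature_seq

  exact <- classify_read(m, ref)
  expect_equal(exact$class_label, "canonical")
  expect_equal(c(exact$offset5, exact$offset3), c(0L, 0L))
  expect_equal(exact$tail, "")

  # extension templated by the flank -> 3' length variant
  lv <- classify_read(paste0(m, "G"), ref)
  expect_equal(lv$class_label, "lv3p")
  expect_equal(lv$offset3, 1L)
  expect_equal(lv$tail, "")

  # non-templated U tail (flank starts with G) -> nta#T in DNA letters
  nta <- classify_read(paste0(m, "U"), ref)
  expect_equal(nta$class_label, "nta#T")
  expect_equal(nta$tail, "T")
  expect_equal(nta$offset3, 0L)

  # poly-A tail of length 3
  nta3 <- classify_read(paste0(m, "AAA"), ref)
  expect_equal(nta3$class_label, "nta#A")
  expect_equal(nta3$tail, "AAA")

  # both ends trimmed, |offset5| > |offset3| -> mlv5p (tie rule)
  mlv <- classify_read(substr(m, 3, nchar(m) - 1), ref)
  expect_equal(mlv$class_label, "mlv5p")
  expect_equal(c(mlv$offset5, mlv$offset3), c(2L, -1L))
  # symmetric trim -> tie -> mlv5p
  tie <- classify_read(substr(m, 3, nchar(m) - 2), ref)
  expect_equal(tie$class_label, "mlv5p")
  # deeper 3' trim -> mlv3p
  mlv3 <- classify_read(substr(m, 2, nchar(m) - 3), ref)
  expect_equal(mlv3$class_label, "mlv3p")

  # internal substitution, canonical ends -> nve
  sub <- m
  substr(sub, 10, 10) <- if (substr(m, 10, 10) == "A") "C" else "A"
  expect_equal(classify_read(sub, ref)$class_label, "nve")

  # 5' trim plus non-templated tail -> mv
  mv <- classify_read(paste0(substr(m, 2, nchar(m)), "UU"), ref)
  expect_equal(mv$class_label, "mv")

  # templated 5' extension -> lv5p
  lv5 <- classify_read(paste0("G", m), ref)   # flank5 CCUACG ends in G
  expect_equal(lv5$class_label, "lv5p")
  expect_equal(lv5$offset5, -1L)
})

test_that("no-calls: short reads and unanchorable sequences", {
  ref <- tiny_ref()[1, ]
  expect_null(classify_read("ACGUACGUACGUAC", ref))       # 14 nt
  expect_null(classify_read(strrep("ACGU", 6), ref))      # unrelated
  # too many substitutions
  m <- ref$mature_seq
  bad <- m
  substr(bad, 8, 8) <- "C"; substr(bad, 14, 14) <- "C"
  substr(bad, 11, 11) <- "G"
  expect_null(classify_read(bad, ref, max_subs = 1))
})

test_that("classify_read is pure and offsets respect their limits", {
  ref <- tiny_ref()[1, ]
  rd <- paste0(substr(ref$mature_seq, 2, nchar(ref$mature_seq)), "AA")
  a <- classify_read(rd, ref)
  b <- classify_read(rd, ref)
  expect_identical(a, b)
  expect_lte(abs(a$offset5), 3)
  expect_lte(abs(a$offset3), 3)
  expect_null(classify_read(substr(ref$mature_seq, 6, 26), ref,
                            max_offset = 3))
})

test_that("multi-parent ambiguity resolves to fewest modifications then name", {
  base <- tiny_ref()[1, ]
  twin <- base
  twin$name <- "mir-Z"
  # twin differs by one internal base: the exact read of `base` costs 0
  # there and 1 on the twin
  substr(twin$mature_seq, 12, 12) <-
    if (substr(base$mature_seq, 12, 12) == "G") "C" else "G"
  ref2 <- rbind(base, twin)
  class(ref2) <- c("mirna_reference", "data.frame")
  calls <- classify_reads(base$mature_seq, ref2)
  expect_equal(calls$parent, "mir-X")
  expect_true(calls$ambiguous)

  # true tie (identical mature+flanks) -> lexicographically first name
  clone <- base; clone$name <- "mir-A"
  ref3 <- rbind(base, clone)
  class(ref3) <- c("mirna_reference", "data.frame")
  tie <- classify_reads(base$mature_seq, ref3)
  expect_equal(tie$parent, "mir-A")
})

test_that("count matrices aggregate calls and conserve read totals", {
  ref <- tiny_ref()
  reads <- list(s1 = rep(ref$mature_seq[1], 10),
                s2 = rep(ref$mature_seq[2], 7))
  res <- count_isomirs(reads, ref, groups = c(s1 = "A", s2 = "B"))
  expect_equal(res$canonical$counts["mir-X", "s1"], 10)
  expect_equal(res$canonical$counts["mir-Y", "s2"], 7)
  # disjoint miRNAs: zeros off the diagonal
  expect_equal(res$canonical$counts["mir-X", "s2"], 0)
  expect_equal(res$canonical$counts["mir-Y", "s1"], 0)
  expect_null(res$isomir)

  # conservation: canonical column sums + no-calls = reads per sample
  reads2 <- list(s1 = c(rep(ref$mature_seq[1], 5),
                        paste0(ref$mature_seq[2], "U"),
                        "ACGUACGUACGUACGUACGU"),
                 s2 = rep(ref$mature_seq[1], 3))
  res2 <- count_isomirs(reads2, ref, groups = c(s1 = "A", s2 = "B"))
  tot <- colSums(res2$canonical$counts) + res2$qc$n_nocall
  expect_equal(unname(tot), c(7, 3))
  expect_equal(res2$qc$n_nocall, c(1, 0))
  # the nta call lands in the isomiR matrix keyed by parent|class|...
  expect_match(rownames(res2$isomir$counts), "^mir-Y\\|nta#T\\|0\\|0\\|T$")
})

test_that("round-trip: classifier recovers generated classes", {
  ref <- generate_reference(10, c(19, 23), 10, seed = 21)
  rd <- generate_reads(ref, n_samples_per_group = 1,
                       reads_per_sample = 4000, seed = 22)
  for (s in names(rd$samples)) {
    sm <- rd$samples[[s]]
    calls <- classify_reads(sm$sequence, ref)
    mg <- merge(data.frame(sequence = sm$sequence, true = sm$class,
                           stringsAsFactors = FALSE),
                calls, by = "sequence")
    expect_gte(mean(mg$true == mg$class_label), 0.99)
  }
})

test_that("class profile reflects the group mixtures", {
  ref <- generate_reference(10, c(19, 23), 10, seed = 31)
  rd <- generate_reads(ref, n_samples_per_group = 3,
                       reads_per_sample = 4000, seed = 32)
  cn <- count_isomirs(rd$samples, ref, rd$groups)
  prof <- class_frequency(cn$isomir, de_mirnas = ref$name)
  fa <- prof$freq[prof$freq$group == "A", ]
  fb <- prof$freq[prof$freq$group == "B", ]
  expect_equal(fa$class[which.max(fa$frequency)], "lv3p")    # PDAC-like
  expect_equal(fb$class[which.max(fb$frequency)], "nta#G")   # benign-like
  expect_equal(sum(fa$frequency), 1, tolerance = 1e-9)
  # heatmap values are finite log2(CPM + 1)
  expect_true(all(is.finite(prof$heat$mean_log2_cpm)))

  # single-class isomiR matrix -> indicator frequency vector
  one <- count_matrix(matrix(c(5, 3), 1, 2,
                             dimnames = list("mir-1|nta#G|0|0|G",
                                             c("x", "y"))),
                      c(x = "A", y = "B"), "isomir")
  p1 <- class_frequency(one, "mir-1")
  expect_equal(p1$freq$frequency[p1$freq$class == "nta#G"], c(1, 1))
  expect_error(class_frequency(one, character(0)), "non-empty")
})
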