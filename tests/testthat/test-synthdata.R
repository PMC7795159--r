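test_that("generator config validates probability vectors and ranges", {
  expect_s3_class(generator_config(), "generator_config")
  bad_probs <- default_class_probs()
  bad_probs$A["canonical"] <- bad_probs$A[["canonical"]] + 0.05
  expect_error(generator_config(class_probs_by_group = bad_probs),
               "sum to 1")
  expect_error(generator_config(frac_de = 1.2), "frac_de")
  expect_error(generator_config(nb_dispersion = -0.1), "dispersion")
  expect_error(generator_config(n_hub_regulators = 3), ">= 5")
  expect_error(generator_config(n_protein_samples_a = 20),
               "n_protein_samples_a")
})

test_that("synthetic reference respects length, flank and naming contracts", {
  one <- generate_reference(1, c(21, 21), 8, seed = 1)
  expect_equal(nchar(one$mature_seq), 21)
  expect_equal(nchar(one$flank5), 8)
  expect_equal(nchar(one$flank3), 8)
  again <- generate_reference(1, c(21, 21), 8, seed = 1)
  expect_identical(one, again)

  big <- generate_reference(344, c(18, 24), 10, seed = 7)
  expect_equal(nrow(big), 344)
  expect_equal(anyDuplicated(big$name), 0)
  expect_true(all(nchar(big$mature_seq) >= 18 & nchar(big$mature_seq) <= 24))
  expect_false(any(grepl("[^ACGU]", big$mature_seq)))

  expect_error(generate_reference(5, c(10, 21), 8), "\\[18, 26\\]")
  expect_error(generate_reference(5, c(20, 21), 3), "flank_len")
})

test_that("expression generator is deterministic and truth-consistent", {
  cfg <- generator_config(seed = 42)
  a <- generate_expression(cfg)
  b <- generate_expression(cfg)
  expect_identical(a$layers$mrna$counts, b$layers$mrna$counts)
  expect_identical(a$truth$de_features, b$truth$de_features)
  expect_false(identical(
    a$layers$mrna$counts,
    generate_expression(generator_config(seed = 43))$layers$mrna$counts))

  expect_named(a$layers, c("mirna", "isomir", "mrna", "intron", "protein"))
  # proteomics design: 8 group-A samples vs 11 group-B
  expect_equal(as.integer(table(a$layers$protein$groups)[c("A", "B")]),
               c(8L, 11L))
  # every planted DE feature exists in its layer
  for (ly in names(a$truth$de_features))
    expect_true(all(names(a$truth$de_features[[ly]]) %in%
                      rownames(a$layers[[ly]]$counts)))
  # hub has >= 5 distinct planted regulators
  hub <- a$truth$hub_transcript
  n_reg <- sum(vapply(a$truth$target_map, function(t) hub %in% t,
                      logical(1)))
  expect_gte(n_reg, 5)
})

test_that("uncoupled generator plants no correlation and no DE truth", {
  # a fully-null world also needs identical class mixtures, otherwise the
  # mixture contrast itself is an honest planted isomiR group effect
  flat <- default_class_probs()
  flat$A <- flat$B <- (flat$A + flat$B) / 2
  cfg <- generator_config(seed = 9, repression_beta = 0,
                          protein_coupling = 0, frac_de = 0,
                          class_probs_by_group = flat)
  sim <- generate_expression(cfg)
  expect_true(all(lengths(sim$truth$de_features) == 0))
  # sample-wise miRNA-target correlations centred at zero
  set.seed(1)
  lm_ <- log2(cpm(sim$layers$mirna) + 1)
  lg <- log2(cpm(sim$layers$mrna) + 1)
  rs <- replicate(100, cor(lm_[sample(nrow(lm_), 1), ],
                           lg[sample(nrow(lg), 1), ]))
  expect_lt(abs(mean(rs)), 0.1)
})

test_that("planted fold changes are recoverable from the counts", {
  # couplings off: this isolates the fold-change planting itself (a
  # repressed target's arithmetic mean is dominated by its repression
  # swing, which is the network module's concern, not this one's)
  abs_est <- unlist(lapply(1:6, function(s) {
    sim <- generate_expression(generator_config(seed = 300 + s,
                                                repression_beta = 0,
                                                protein_coupling = 0))
    tru <- unlist(sim$truth$de_features$mrna)
    tru <- tru[abs(tru) == generator_config()$planted_lfc]
    norm <- cpm(sim$layers$mrna)
    g <- sim$layers$mrna$groups
    est <- log2((rowMeans(norm[names(tru), g == "A", drop = FALSE]) + 0.5) /
                (rowMeans(norm[names(tru), g == "B", drop = FALSE]) + 0.5))
    abs(est)
  }))
  expect_lt(abs(mean(abs_est) - 2), 0.3)
})

test_that("repression plants negative miRNA-target correlation", {
  meds <- vapply(1:4, function(s) {
    sim <- generate_expression(generator_config(seed = 500 + s,
                                                repression_beta = 1))
    lm_ <- log2(cpm(sim$layers$mirna) + 1)
    lg <- log2(cpm(sim$layers$mrna) + 1)
    tm <- sim$truth$target_map
    rs <- unlist(lapply(names(tm), function(mir)
      vapply(tm[[mir]], function(g) cor(lm_[mir, ], lg[g, ]), numeric(1))))
    stats::median(rs)
  }, numeric(1))
  expect_true(all(meds < 0))
})

test_that("read generator conserves counts and honours degenerate mixtures", {
  ref <- generate_reference(8, c(19, 23), 10, seed = 3)
  canon_only <- lapply(default_class_probs(), function(p) {
    p[] <- 0; p["canonical"] <- 1; p
  })
  rd <- generate_reads(ref, canon_only, n_samples_per_group = 2,
                       reads_per_sample = 300, seed = 4)
  expect_true(all(vapply(rd$samples, nrow, integer(1)) == 300))
  for (s in rd$samples)
    expect_true(all(s$sequence ==
                      ref$mature_seq[match(s$parent, ref$name)]))

  nta_only <- lapply(default_class_probs(), function(p) {
    p[] <- 0; p["nta#T"] <- 1; p
  })
  rdt <- generate_reads(ref, nta_only, n_samples_per_group = 1,
                        reads_per_sample = 200, seed = 5)
  s <- rdt$samples[[1]]
  mature <- ref$mature_seq[match(s$parent, ref$name)]
  flank3 <- ref$flank3[match(s$parent, ref$name)]
  expect_true(all(startsWith(s$sequence, mature)))
  tails <- substr(s$sequence, nchar(mature) + 1, nchar(s$sequence))
  expect_true(all(grepl("^U+$", tails)))
  # the tail base is never templated by the flank
  expect_true(all(substr(flank3, 1, 1) != "U"))
})

test_that("identical seeds give bit-identical read sets", {
  ref <- generate_reference(6, c(19, 23), 10, seed = 11)
  r1 <- generate_reads(ref, reads_per_sample = 500,
                       n_samples_per_group = 2, seed = 12)
  r2 <- generate_reads(ref, reads_per_sample = 500,
                       n_samples_per_group = 2, seed = 12)
  expect_identical(r1$samples, r2$samples)
})

test_that("truth serializes through JSON unchanged where it matters", {
  sim <- generate_expression(generator_config(seed = 77))
  path <- tempfile(fileext = ".json")
  write_truth(sim$truth, path)
  back <- read_truth(path)
  expect_equal(back$hub_transcript, sim$truth$hub_transcript)
  expect_equal(sort(names(back$de_features$mrna)),
               sort(names(sim$truth$de_features$mrna)))
  expect_equal(unlist(back$de_features$mrna[names(sim$truth$de_features$mrna)]),
               unlist(sim$truth$de_features$mrna), tolerance = 1e-12)
})
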