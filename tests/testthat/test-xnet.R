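test_that("correlate_pair matches the analytic t-test", {
  n <- 11
  x <- seq_len(n)
  self <- correlate_pair(x, x)
  expect_equal(self$r, 1)
  expect_lt(self$p, 1e-10)
  anti <- correlate_pair(x, -2 * x + 3)
  expect_equal(anti$r, -1)

  # hand-checkable oracle: cor.test itself
  x5 <- c(1, 2, 3, 4, 5); y5 <- c(2, 1, 4, 3, 5)
  got <- correlate_pair(x5, y5)
  ct <- cor.test(x5, y5)
  expect_equal(got$r, unname(ct$estimate), tolerance = 1e-10)
  expect_equal(got$p, ct$p.value, tolerance = 1e-10)

  sp <- correlate_pair(x5, y5, method = "spearman")
  expect_equal(sp$r, unname(cor.test(x5, y5, method = "spearman")$estimate),
               tolerance = 1e-10)

  expect_error(correlate_pair(1:3, 1:3), ">= 4")
  expect_null(correlate_pair(rep(1, 6), 1:6))   # zero variance skipped
})

test_that("vectorized correlations agree with cor.test pair by pair", {
  set.seed(71)
  mx <- matrix(rnorm(4 * 9), 4, 9, dimnames = list(paste0("m", 1:4), NULL))
  my <- matrix(rnorm(3 * 9), 3, 9, dimnames = list(paste0("g", 1:3), NULL))
  cm <- tepomics:::cor_matrix(mx, my)
  for (i in 1:4) for (j in 1:3) {
    ct <- cor.test(mx[i, ], my[j, ])
    expect_equal(cm$r[i, j], unname(ct$estimate), tolerance = 1e-12)
    expect_equal(cm$p[i, j], ct$p.value, tolerance = 1e-12)
  }
})

test_that("expected networks satisfy sign rules and tripartite structure", {
  sim <- generate_expression(generator_config(seed = 81))
  nets <- build_all_networks(sim$layers, de_tables = NULL, alpha = 0.05)
  expect_length(nets, 8)
  expect_setequal(names(nets),
                  c(t(outer(c("A", "B"),
                            c("canonical_mrna", "canonical_intron",
                              "isomir_mrna", "isomir_intron"),
                            paste, sep = "_"))))
  for (net in nets) {
    e <- net$edges
    mg <- e[e$relation == "mirna_gene", ]
    gp <- e[e$relation == "gene_protein", ]
    expect_true(all(mg$r < 0))
    expect_true(all(gp$r > 0))
    expect_true(all(e$p < 0.05))
    expect_true(all(mg$source_type == "mirna" &
                      mg$target_type == "transcript"))
    expect_true(all(gp$source_type == "transcript" &
                      gp$target_type == "protein"))
    # isolated nodes were dropped
    expect_setequal(net$nodes$id, unique(c(e$source, e$target)))
  }
  # isomiR nodes display their parent miRNA
  iso_nodes <- nets$A_isomir_mrna$nodes
  mirs <- iso_nodes[iso_nodes$type == "mirna", ]
  expect_true(all(mirs$display == parse_isomir_ids(mirs$id)$parent))
})

test_that("a positively coupled miRNA-gene pair never becomes an edge", {
  set.seed(82)
  n <- 11
  sm <- paste0("s", 1:(2 * n))
  x <- rpois(2 * n, 500)
  mirna <- count_matrix(matrix(x, 1, dimnames = list("mirUP", sm)),
                        rep(c("A", "B"), each = n), "mirna")
  gene <- count_matrix(matrix(round(x * 2) + rpois(2 * n, 5), 1,
                              dimnames = list("geneUP", sm)),
                       rep(c("A", "B"), each = n), "mrna")
  net <- build_expected_network("A", mirna, gene, protein_m = NULL)
  expect_equal(nrow(net$edges), 0)
})

test_that("planted repression produces the expected edge", {
  hits <- vapply(1:5, function(s) {
    sim <- generate_expression(generator_config(seed = 900 + s))
    net <- build_expected_network("A", sim$layers$mirna, sim$layers$mrna,
                                  de_sets = list())
    tm <- sim$truth$target_map
    pairs <- do.call(rbind, lapply(names(tm), function(m)
      data.frame(m = m, g = tm[[m]], stringsAsFactors = FALSE)))
    found <- mapply(function(m, g)
      any(net$edges$source == m & net$edges$target == g), pairs$m, pairs$g)
    mean(found)
  }, numeric(1))
  expect_gte(mean(hits), 0.9)
})

test_that("sample-sharing preconditions are enforced", {
  sim <- generate_expression(generator_config(seed = 83,
                                              n_samples_per_group = 3,
                                              n_protein_samples_a = 2))
  expect_error(build_expected_network("A", sim$layers$mirna,
                                      sim$layers$mrna, sim$layers$protein),
               "4 shared samples")
})

test_that("node degrees rank correctly with deterministic ties", {
  fake <- structure(list(
    group = "A", mirna_layer = "canonical", gene_layer = "mrna",
    nodes = data.frame(id = c("h", paste0("m", 1:4), "z"),
                       type = c("transcript", rep("mirna", 4),
                                "transcript"),
                       display = c("h", paste0("m", 1:4), "z")),
    edges = data.frame(source = c(paste0("m", 1:4), "m1"),
                       source_type = "mirna",
                       target = c(rep("h", 4), "z"),
                       target_type = "transcript",
                       r = -0.9, p = 0.001, relation = "mirna_gene")),
    class = "omics_network")
  dg <- node_degrees(fake)
  expect_equal(dg$node[1], "h")
  expect_equal(dg$degree[1], 4)
  expect_equal(node_degrees(fake, type = "transcript")$node, c("h", "z"))
  # ties broken by node id
  tied <- dg[dg$degree == 1, ]
  expect_identical(tied$node, sort(tied$node))

  empty <- fake; empty$edges <- fake$edges[0, ]
  expect_equal(nrow(node_degrees(empty)), 0)
})

test_that("cross-network core is the transcript intersection", {
  mk <- function(group, ml, gl, transcripts) {
    structure(list(group = group, mirna_layer = ml, gene_layer = gl,
                   nodes = data.frame(id = c(transcripts, "mirZ"),
                                      type = c(rep("transcript",
                                                   length(transcripts)),
                                               "mirna"),
                                      display = c(transcripts, "mirZ")),
                   edges = data.frame()),
              class = "omics_network")
  }
  four <- list(mk("A", "canonical", "mrna", c("t1", "t2")),
               mk("A", "canonical", "intron", c("t1", "t3")),
               mk("A", "isomir", "mrna", c("t1", "t2", "t4")),
               mk("A", "isomir", "intron", c("t1", "t5")))
  expect_equal(cross_network_core(four), "t1")

  disjoint <- four
  disjoint[[4]] <- mk("A", "isomir", "intron", "t9")
  expect_length(cross_network_core(disjoint), 0)

  expect_error(cross_network_core(four[1:3]), "four networks")
  mixed <- four; mixed[[1]]$group <- "B"
  expect_error(cross_network_core(mixed), "one group")
  dup <- four; dup[[2]] <- four[[1]]
  expect_error(cross_network_core(dup), "distinct")
})

test_that("network export round-trips the edge list", {
  sim <- generate_expression(generator_config(seed = 84))
  net <- build_expected_network("A", sim$layers$mirna, sim$layers$mrna,
                                sim$layers$protein, de_sets = list())
  tsv <- tempfile(fileext = ".tsv")
  gml <- tempfile(fileext = ".graphml")
  write_network(net, tsv = tsv, graphml = gml, header = "test")
  back <- read.delim(tsv, comment.char = "#")
  expect_equal(nrow(back), nrow(net$edges))
  expect_equal(back$r, net$edges$r, tolerance = 1e-9)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gorder(g), nrow(net$nodes))
  expect_equal(igraph::gsize(g), nrow(net$edges))
})
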