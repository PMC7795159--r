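#' Pearson correlation with analytic two-sided p-value
#'
#' The classic t transform: `t = r sqrt((n-2)/(1-r^2))` referred to a t
#' distribution with `n - 2` degrees of freedom (the test performed by
#' `cor.test`); Spearman is available by rank-transforming first.
#'
#' @param x,y paired per-sample values (>= 4 finite pairs).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return list with `r` and `p`; `NULL` when either vector has zero
#'   variance (the pair is skipped upstream, with a log entry).
#' @export
correlate_pair <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4L) stop("need >= 4 paired observations")
  if (method == "spearman") { x <- rank(x); y <- rank(y) }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NULL)
  r <- stats::cor(x, y)
  r <- max(-1, min(1, r))
  if (abs(r) == 1) return(list(r = r, p = 0))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tt), df = n - 2))
}

# vectorized correlation of every row of mx against every row of my,
# with the same t-based p-values; rows with zero variance yield NA
cor_matrix <- function(mx, my, method = "pearson") {
  if (method == "spearman") {
    mx <- t(apply(mx, 1, rank))
    my <- t(apply(my, 1, rank))
  }
  n <- ncol(mx)
  r <- suppressWarnings(stats::cor(t(mx), t(my)))
  r[!is.finite(r)] <- NA
  r <- pmin(pmax(r, -1), 1)
  tt <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-300))
  p <- 2 * stats::pt(-abs(tt), df = n - 2)
  p[abs(r) == 1] <- 0
  list(r = r, p = p, n = n)
}

edges_from_cor <- function(cm, sign, relation, alpha) {
  hit <- which(!is.na(cm$r) & cm$p < alpha &
                 (if (sign < 0) cm$r < 0 else cm$r > 0), arr.ind = TRUE)
  if (nrow(hit) == 0L)
    return(data.frame(source = character(0), target = character(0),
                      r = numeric(0), p = numeric(0),
                      relation = character(0), stringsAsFactors = FALSE))
  data.frame(source = rownames(cm$r)[hit[, 1]],
             target = colnames(cm$r)[hit[, 2]],
             r = cm$r[hit], p = cm$p[hit], relation = relation,
             stringsAsFactors = FALSE)
}

#' Build one expected-correlation network
#'
#' For one patient group and one (miRNA layer, gene layer) combination,
#' computes all pairwise correlations between the candidate miRNA-layer
#' features and gene-layer features, and between gene-layer features and
#' proteins, keeping only "expected" edges: miRNA-gene edges must be
#' negative and gene-protein edges positive, both at `p < alpha`.
#' Candidates default to the differentially expressed features of each
#' layer. Gene-protein correlations are restricted to the samples present
#' in both layers (the proteomics subset); isolated nodes are dropped.
#' isomiR features are collapsed to their parent miRNA node for display,
#' but edges stay per-isomiR, so parallel edges between one miRNA and one
#' gene represent distinct isomiR classes.
#'
#' @param group `"A"` or `"B"`.
#' @param mirna_m miRNA-layer [count_matrix()] (canonical or isomiR).
#' @param gene_m gene-layer [count_matrix()] (mRNA or intron).
#' @param protein_m protein-layer [count_matrix()], or `NULL` to omit the
#'   gene-protein half.
#' @param de_sets named list of candidate feature ids per layer, e.g. the
#'   `feature` columns of significant [differential_table()] rows, with
#'   names `mirna`, `gene`, `protein`; `NULL` entries mean
#'   all-filtered-features mode.
#' @param alpha edge significance level (default 0.05).
#' @param method correlation method, `"pearson"` or `"spearman"`.
#' @return object of class `"omics_network"`: `group`, `mirna_layer`,
#'   `gene_layer`, `nodes` (data.frame `id`, `type`, `display` with the
#'   isomiR-to-parent collapsing), `edges` (data.frame `source`,
#'   `source_type`, `target`, `target_type`, `r`, `p`, `relation`),
#'   `skipped` (zero-variance pairs logged).
#' @export
build_expected_network <- function(group, mirna_m, gene_m,
                                   protein_m = NULL, de_sets = list(),
                                   alpha = 0.05, method = "pearson") {
  stopifnot(inherits(mirna_m, "count_matrix"),
            inherits(gene_m, "count_matrix"))
  mirna_layer <- if (mirna_m$layer == "isomir") "isomir" else "canonical"
  gene_layer <- gene_m$layer
  g_samp <- function(m) names(m$groups)[m$groups == group]
  rna_samples <- intersect(g_samp(mirna_m), g_samp(gene_m))
  if (length(rna_samples) < 4L) stop("< 4 shared samples for miRNA-gene")
  # normalized log expression on the FULL layer (library sizes and TMM
  # factors belong to the whole repertoire), candidate rows subset after
  log_cpm <- function(m, samples, ids) {
    full <- normalize_counts(subset_counts(m, samples = samples),
                             log = TRUE)
    if (is.null(ids)) full
    else full[intersect(rownames(full), ids), , drop = FALSE]
  }
  mg <- cor_matrix(log_cpm(mirna_m, rna_samples, de_sets$mirna),
                   log_cpm(gene_m, rna_samples, de_sets$gene), method)
  edges <- edges_from_cor(mg, sign = -1, relation = "mirna_gene", alpha)
  skipped <- sum(is.na(mg$r))
  if (!is.null(protein_m)) {
    gp_samples <- intersect(g_samp(gene_m), g_samp(protein_m))
    if (length(gp_samples) < 4L) stop("< 4 shared samples for gene-protein")
    gp <- cor_matrix(log_cpm(gene_m, gp_samples, de_sets$gene),
                     log_cpm(protein_m, gp_samples, de_sets$protein),
                     method)
    edges <- rbind(edges,
                   edges_from_cor(gp, sign = +1, relation = "gene_protein",
                                  alpha))
    skipped <- skipped + sum(is.na(gp$r))
  }
  mir_nodes <- unique(edges$source[edges$relation == "mirna_gene"])
  gene_nodes <- unique(c(edges$target[edges$relation == "mirna_gene"],
                         edges$source[edges$relation == "gene_protein"]))
  prot_nodes <- unique(edges$target[edges$relation == "gene_protein"])
  display <- function(ids, type) {
    if (type == "mirna" && mirna_layer == "isomir")
      parse_isomir_ids(ids)$parent else ids
  }
  nodes <- rbind(
    if (length(mir_nodes)) data.frame(id = mir_nodes, type = "mirna",
      display = display(mir_nodes, "mirna"), stringsAsFactors = FALSE),
    if (length(gene_nodes)) data.frame(id = gene_nodes, type = "transcript",
      display = gene_nodes, stringsAsFactors = FALSE),
    if (length(prot_nodes)) data.frame(id = prot_nodes, type = "protein",
      display = prot_nodes, stringsAsFactors = FALSE))
  if (is.null(nodes)) nodes <- data.frame(id = character(0),
                                          type = character(0),
                                          display = character(0))
  type_of <- stats::setNames(nodes$type, nodes$id)
  edges$source_type <- unname(type_of[edges$source])
  edges$target_type <- unname(type_of[edges$target])
  edges <- edges[, c("source", "source_type", "target", "target_type",
                     "r", "p", "relation")]
  structure(list(group = group, mirna_layer = mirna_layer,
                 gene_layer = gene_layer, nodes = nodes, edges = edges,
                 alpha = alpha, skipped_pairs = skipped),
            class = "omics_network")
}

#' @export
print.omics_network <- function(x, ...) {
  cat(sprintf("omics_network [group %s, %s x %s]: %d nodes, %d edges\n",
              x$group, x$mirna_layer, x$gene_layer, nrow(x$nodes),
              nrow(x$edges)))
  invisible(x)
}

#' Build all eight expected-correlation networks
#'
#' Two patient groups times two miRNA layers (canonical, isomiR) times two
#' gene layers (mRNA, intron-spanning): eight networks.
#'
#' @param layers named list of [count_matrix()] objects: `mirna`,
#'   `isomir`, `mrna`, `intron`, `protein`.
#' @param de_tables named list of [differential_table()] results per
#'   layer, used to define candidate features; `NULL` for
#'   all-features mode.
#' @param alpha,method passed to [build_expected_network()].
#' @return named list of 8 `"omics_network"` objects, names like
#'   `"A_canonical_mrna"`.
#' @export
build_all_networks <- function(layers, de_tables = NULL, alpha = 0.05,
                               method = "pearson") {
  sig_set <- function(layer) {
    if (is.null(de_tables)) return(NULL)
    d <- de_tables[[layer]]
    d$feature[d$significant]
  }
  out <- list()
  for (group in c("A", "B"))
    for (ml in c("canonical", "isomir"))
      for (gl in c("mrna", "intron")) {
        mm <- if (ml == "canonical") layers$mirna else layers$isomir
        de_sets <- list(
          mirna = sig_set(if (ml == "canonical") "mirna" else "isomir"),
          gene = sig_set(gl), protein = sig_set("protein"))
        out[[paste(group, ml, gl, sep = "_")]] <-
          build_expected_network(group, mm, layers[[gl]], layers$protein,
                                 de_sets = de_sets, alpha = alpha,
                                 method = method)
      }
  out
}

#' Node degrees of a network, ranked
#'
#' @param net an `"omics_network"`.
#' @param type optional node type filter (`"mirna"`, `"transcript"`,
#'   `"protein"`).
#' @return data.frame `node`, `type`, `degree` in descending degree order,
#'   ties by node id.
#' @export
node_degrees <- function(net, type = NULL) {
  stopifnot(inherits(net, "omics_network"))
  if (nrow(net$edges) == 0L)
    return(data.frame(node = character(0), type = character(0),
                      degree = integer(0)))
  inc <- c(net$edges$source, net$edges$target)
  tb <- table(inc)
  out <- data.frame(node = names(tb), degree = as.integer(tb),
                    stringsAsFactors = FALSE)
  out$type <- net$nodes$type[match(out$node, net$nodes$id)]
  if (!is.null(type)) out <- out[out$type == type, , drop = FALSE]
  out <- out[order(-out$degree, out$node), c("node", "type", "degree")]
  rownames(out) <- NULL
  out
}

#' Transcripts shared by all four networks of one group
#'
#' The cross-network core: the intersection of the transcript node sets of
#' the four (miRNA layer x gene layer) networks of one patient group.
#'
#' @param networks list of exactly four `"omics_network"` objects of one
#'   group covering all four layer combinations.
#' @return character vector of transcript ids present in all four.
#' @export
cross_network_core <- function(networks) {
  if (length(networks) != 4L)
    stop("exactly four networks of one group are required")
  groups <- unique(vapply(networks, `[[`, character(1), "group"))
  if (length(groups) != 1L) stop("networks must all be of one group")
  combos <- vapply(networks, function(n)
    paste(n$mirna_layer, n$gene_layer), character(1))
  if (length(unique(combos)) != 4L)
    stop("the four layer combinations must all be distinct")
  Reduce(intersect, lapply(networks, function(n)
    n$nodes$id[n$nodes$type == "transcript"]))
}

#' Export a network as edge-list TSV and GraphML
#'
#' @param net an `"omics_network"`.
#' @param tsv,graphml output paths (either may be `NULL` to skip).
#' @param header optional provenance comment lines for the TSV.
#' @export
write_network <- function(net, tsv = NULL, graphml = NULL, header = NULL) {
  label <- paste(net$group, net$mirna_layer, net$gene_layer, sep = "_")
  if (!is.null(tsv)) {
    con <- file(tsv, open = "wt")
    ed <- net$edges
    ed$network <- label
    if (!is.null(header)) writeLines(paste0("# ", header), con)
    utils::write.table(ed, con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    close(con)
  }
  if (!is.null(graphml)) {
    g <- igraph::graph_from_data_frame(
      net$edges[, c("source", "target", "r", "p", "relation")],
      directed = TRUE, vertices = net$nodes)
    igraph::write_graph(g, graphml, format = "graphml")
  }
  invisible(label)
}
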