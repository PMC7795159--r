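#' Pipeline configuration
#'
#' Thresholds, engine options and data sources for a full run. Defaults
#' are the study's thresholds: edge and DE significance at `alpha = 0.05`,
#' `|log2FC| > 1` for count layers, presence filter at 1 CPM in more than
#' 40% of samples with the 18% black-and-white rescue.
#'
#' @param outdir output directory (created if missing).
#' @param seed integer seed controlling every stochastic stage.
#' @param simulate when `TRUE` inputs are generated by the synthetic
#'   module; otherwise `inputs` must name files on disk.
#' @param generator a [generator_config()] for simulate mode (its own
#'   `seed` field is overridden by `seed`).
#' @param reads_per_sample synthetic small-RNA reads per sample.
#' @param alpha,lfc_cut,min_cpm,min_frac,bw_max_zero_frac thresholds.
#' @param cor_method `"pearson"` or `"spearman"` for network edges.
#' @param w,n_perm GSEA weight exponent and permutation count.
#' @param max_offset,max_tail,max_subs isomiR classification limits.
#' @param inputs named list of file paths for non-simulate mode:
#'   `reference_fasta`, `reference_flanks`, `reads` (named vector of
#'   per-sample collapsed TSVs), `mrna`, `intron`, `protein` (count
#'   TSVs), `sample_sheet`, `gene_sets` (GMT), `mirna_sets` (GMT).
#' @param stages character vector of stages to run, a subset of
#'   `c("simulate", "classify", "filter", "de", "network", "enrich",
#'   "profile")` in pipeline order.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(outdir = tempfile("tepomics_run_"),
                            seed = 1L, simulate = TRUE,
                            generator = generator_config(),
                            reads_per_sample = 2000L,
                            alpha = 0.05, lfc_cut = 1, min_cpm = 1,
                            min_frac = 0.40, bw_max_zero_frac = 0.18,
                            cor_method = "pearson", w = 1,
                            n_perm = 1000L, max_offset = 3L,
                            max_tail = 3L, max_subs = 1L,
                            inputs = list(),
                            stages = c("simulate", "classify", "filter",
                                       "de", "network", "enrich",
                                       "profile")) {
  stopifnot(alpha > 0, alpha < 1, lfc_cut >= 0, min_cpm >= 0,
            min_frac >= 0, min_frac < 1,
            bw_max_zero_frac >= 0, bw_max_zero_frac < 1, n_perm >= 100)
  cfg <- list(outdir = outdir, seed = as.integer(seed),
              simulate = simulate, generator = generator,
              reads_per_sample = as.integer(reads_per_sample),
              alpha = alpha, lfc_cut = lfc_cut, min_cpm = min_cpm,
              min_frac = min_frac, bw_max_zero_frac = bw_max_zero_frac,
              cor_method = cor_method, w = w, n_perm = as.integer(n_perm),
              max_offset = as.integer(max_offset),
              max_tail = as.integer(max_tail),
              max_subs = as.integer(max_subs),
              inputs = inputs, stages = stages)
  class(cfg) <- "pipeline_config"
  cfg
}

# hash of the analytic configuration; the output location does not alter
# results, so two runs of one config into different directories produce
# identical manifests
config_hash <- function(cfg) {
  cfg <- unclass(cfg)
  cfg$outdir <- NULL
  rlang::hash(cfg)
}

provenance <- function(cfg) {
  c(sprintf("tepomics %s", as.character(utils::packageVersion("tepomics"))),
    sprintf("seed=%d config=%s", cfg$seed, config_hash(cfg)))
}

run_stage <- function(name, outdir, expr) {
  tryCatch(expr, error = function(e) {
    try(file.create(file.path(outdir, paste0(name, ".partial"))),
        silent = TRUE)
    stop(sprintf("stage %s failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

# synthetic gene-set collections over the simulated universe: random sets
# plus one set matching the planted DE features, so integration has a
# concordant term to find
synth_gene_sets <- function(ids, planted, n_sets = 12L, prefix = "SET") {
  sizes <- pmin(pmax(5L, stats::rpois(n_sets, 15)), max(5L, length(ids)))
  sets <- lapply(sizes, function(s) sample(ids, s))
  names(sets) <- sprintf("%s_%02d", prefix, seq_len(n_sets))
  if (length(planted) >= 3L) sets[[paste0(prefix, "_PLANTED")]] <-
    unique(planted)
  sets
}

#' Run the full pipeline (or selected stages)
#'
#' Executes the workflow in order — simulate (or load), classify small-RNA
#' reads, presence-filter and TMM-normalize the count layers,
#' differential expression on all five layers, the eight
#' expected-correlation networks, enrichment integration and the isomiR
#' class profile — writing every table with a provenance header and
#' returning (and writing) a manifest of per-stage counts. A stage
#' failure aborts with the failing stage named and leaves a
#' `<stage>.partial` marker in the output directory.
#'
#' @param cfg a [pipeline_config()].
#' @return the manifest, invisibly a list written to
#'   `manifest.json`: seed, config hash, per-layer feature counts before
#'   and after filtering, DE counts, network node/edge counts, overlap
#'   term count, output paths.
#' @export
run_pipeline <- function(cfg = pipeline_config()) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  hdr <- provenance(cfg)
  manifest <- list(seed = cfg$seed, config = config_hash(cfg),
                   package = as.character(utils::packageVersion("tepomics")),
                   stages = cfg$stages)
  layers <- NULL; truth <- NULL; reads <- NULL; reference <- NULL
  gene_sets <- NULL; mirna_sets <- NULL

  ## ---- simulate / load ---------------------------------------------------
  if (cfg$simulate && "simulate" %in% cfg$stages) {
    run_stage("simulate", cfg$outdir, {
      gen <- cfg$generator
      gen$seed <- cfg$seed
      sim <- generate_expression(gen)
      layers <- sim$layers
      truth <- sim$truth
      reference <- generate_reference(gen$n_mirna, c(18L, 24L), 10L,
                                       seed = cfg$seed + 1L)
      reads <- generate_reads(reference, gen$class_probs_by_group,
                               gen$n_samples_per_group,
                               cfg$reads_per_sample, seed = cfg$seed + 2L)
      # one shared term vocabulary across layers: gene membership for the
      # ranked layers, miRNA membership for the ORA layer, so the
      # cross-layer term intersection is meaningful; the planted term
      # collects the concordant (up-in-A) planted features of each layer
      de_g <- truth$de_features$mrna
      up_genes <- names(de_g)[unlist(de_g) > 0]
      gene_sets <- synth_gene_sets(rownames(layers$mrna$counts),
                                   up_genes, prefix = "GO")
      mir_ids <- rownames(layers$mirna$counts)
      de_m <- truth$de_features$mirna
      up_mirs <- names(de_m)[unlist(de_m) > 0]
      mirna_sets <- lapply(gene_sets, function(s)
        sample(mir_ids, min(8L, length(mir_ids))))
      if ("GO_PLANTED" %in% names(mirna_sets) && length(up_mirs) >= 3L)
        mirna_sets$GO_PLANTED <- up_mirs
      write_truth(truth, file.path(cfg$outdir, "truth.json"))
      write_reference(reference, file.path(cfg$outdir, "reference.fasta"),
                      file.path(cfg$outdir, "reference_flanks.tsv"))
      for (ly in names(layers))
        write_count_tsv(layers[[ly]],
                        file.path(cfg$outdir, paste0(ly, "_counts.tsv")),
                        header = hdr)
      sheet <- data.frame(sample = names(layers$mrna$groups),
                          group = unname(layers$mrna$groups))
      sheet$layers <- ifelse(sheet$sample %in% colnames(layers$protein$counts),
                             "rna,protein", "rna")
      write_sample_sheet(sheet, file.path(cfg$outdir, "samples.tsv"))
      write_gmt(gene_sets, file.path(cfg$outdir, "gene_sets.gmt"))
      write_gmt(mirna_sets, file.path(cfg$outdir, "mirna_sets.gmt"))
    })
  } else {
    run_stage("load", cfg$outdir, {
      inp <- cfg$inputs
      sheet <- read_sample_sheet(inp$sample_sheet)
      grp <- stats::setNames(sheet$group, sheet$sample)
      reference <- read_reference(inp$reference_fasta,
                                   inp$reference_flanks)
      layers <- list(
        mrna = read_count_tsv(inp$mrna, grp, "mrna"),
        intron = read_count_tsv(inp$intron, grp, "intron"),
        protein = if (!is.null(inp$protein))
          read_count_tsv(inp$protein, grp, "protein") else NULL)
      if (!is.null(inp$reads))
        reads <- list(samples = lapply(inp$reads, read_reads_tsv),
                       groups = grp[names(inp$reads)])
      if (!is.null(inp$gene_sets)) gene_sets <- read_gmt(inp$gene_sets)
      if (!is.null(inp$mirna_sets)) mirna_sets <- read_gmt(inp$mirna_sets)
    })
  }

  ## ---- classify ----------------------------------------------------------
  classified <- NULL
  if ("classify" %in% cfg$stages && !is.null(reads)) {
    classified <- run_stage("classify", cfg$outdir, {
      cn <- count_isomirs(reads$samples, reference, reads$groups,
                          cfg$max_offset, cfg$max_tail, cfg$max_subs)
      utils::write.table(cn$qc, file.path(cfg$outdir, "classify_qc.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      write_count_tsv(cn$canonical,
                      file.path(cfg$outdir, "classified_mirna_counts.tsv"),
                      header = hdr)
      if (!is.null(cn$isomir))
        write_count_tsv(cn$isomir,
                        file.path(cfg$outdir, "classified_isomir_counts.tsv"),
                        header = hdr)
      cn
    })
    # in non-simulate mode the small-RNA layers come from classification
    if (!cfg$simulate) {
      layers$mirna <- classified$canonical
      layers$isomir <- classified$isomir
    }
    manifest$classify <- list(
      n_reads = sum(classified$qc$n_reads),
      n_nocall = sum(classified$qc$n_nocall),
      n_ambiguous = sum(classified$qc$n_ambiguous))
  }

  ## ---- filter + normalize ------------------------------------------------
  count_layers <- intersect(c("mirna", "isomir", "mrna", "intron"),
                            names(layers))
  filters <- list()
  if ("filter" %in% cfg$stages) {
    run_stage("filter", cfg$outdir, {
      for (ly in count_layers) {
        flt <- presence_filter(layers[[ly]], cfg$min_cpm, cfg$min_frac,
                               cfg$bw_max_zero_frac)
        filters[[ly]] <- flt
        before <- nrow(layers[[ly]]$counts)
        kept <- apply_filter(layers[[ly]], flt)
        kept$norm_factors <- tmm_factors(kept)
        layers[[ly]] <- kept
        manifest$filter[[ly]] <- list(before = before,
                                       after = nrow(kept$counts))
        utils::write.table(flt,
          file.path(cfg$outdir, paste0(ly, "_filter.tsv")),
          sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(
          data.frame(sample = names(kept$norm_factors),
                     factor = unname(kept$norm_factors)),
          file.path(cfg$outdir, paste0(ly, "_tmm_factors.tsv")),
          sep = "\t", quote = FALSE, row.names = FALSE)
      }
    })
  }

  ## ---- differential expression -------------------------------------------
  de_tables <- NULL
  if ("de" %in% cfg$stages) {
    de_tables <- run_stage("de", cfg$outdir, {
      out <- list()
      for (ly in count_layers) {
        out[[ly]] <- differential_table(layers[[ly]], "nb_exact",
                                        alpha = cfg$alpha,
                                        lfc_cut = cfg$lfc_cut)
        write_de_tsv(out[[ly]],
                     file.path(cfg$outdir, paste0("de_", ly, ".tsv")), hdr)
      }
      if (!is.null(layers$protein)) {
        out$protein <- differential_table(layers$protein, "bb",
                                          alpha = cfg$alpha)
        write_de_tsv(out$protein,
                     file.path(cfg$outdir, "de_protein.tsv"), hdr)
      }
      out
    })
    manifest$de <- lapply(de_tables, function(d)
      list(n = nrow(d), n_significant = sum(d$significant),
           up_A = sum(d$significant & d$direction == "up_A"),
           up_B = sum(d$significant & d$direction == "up_B")))
  }

  ## ---- networks ----------------------------------------------------------
  networks <- NULL
  if ("network" %in% cfg$stages) {
    networks <- run_stage("network", cfg$outdir, {
      if (is.null(layers$protein))
        stop("gene_protein correlations need a protein matrix")
      nets <- build_all_networks(layers, de_tables, alpha = cfg$alpha,
                                 method = cfg$cor_method)
      for (nm in names(nets)) {
        write_network(nets[[nm]],
                      tsv = file.path(cfg$outdir,
                                      paste0("network_", nm, ".tsv")),
                      graphml = file.path(cfg$outdir,
                                          paste0("network_", nm,
                                                 ".graphml")),
                      header = hdr)
      }
      nets
    })
    manifest$network <- lapply(networks, function(n)
      list(nodes = nrow(n$nodes), edges = nrow(n$edges)))
    manifest$n_networks <- length(networks)
    for (g in c("A", "B")) {
      sub <- networks[grepl(paste0("^", g, "_"), names(networks))]
      manifest$core[[g]] <- cross_network_core(sub)
    }
  }

  ## ---- enrichment ----------------------------------------------------------
  if ("enrich" %in% cfg$stages && !is.null(de_tables) &&
      !is.null(gene_sets)) {
    run_stage("enrich", cfg$outdir, {
      res <- list()
      for (ly in intersect(c("mrna", "intron", "protein"),
                           names(de_tables))) {
        rs <- rank_stat(de_tables[[ly]])
        if (ly == "protein") names(rs) <- sub("^prot_", "", names(rs))
        res[[ly]] <- gsea_preranked(rs, gene_sets, cfg$n_perm,
                                    seed = cfg$seed + 10L, w = cfg$w,
                                    layer = ly, alpha = cfg$alpha)
      }
      if (!is.null(mirna_sets) && "mirna" %in% names(de_tables)) {
        dmt <- de_tables$mirna
        de_mir <- dmt$feature[dmt$significant]
        if (length(de_mir) > 0)
          res$mirna <- mirna_ora(de_mir, dmt$feature, mirna_sets,
                                 de_table = dmt, alpha = cfg$alpha)
      }
      for (nm in names(res))
        utils::write.table(res[[nm]],
          file.path(cfg$outdir, paste0("enrich_", nm, ".tsv")),
          sep = "\t", quote = FALSE, row.names = FALSE)
      if (length(res) >= 2) {
        ov <- cross_layer_overlap(res, alpha = cfg$alpha)
        utils::write.table(ov, file.path(cfg$outdir, "overlap_terms.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        manifest$enrich <- list(layers = names(res),
                                 n_overlap_terms = length(unique(ov$term)))
      }
    })
  }

  ## ---- isomiR class profile ----------------------------------------------
  if ("profile" %in% cfg$stages && !is.null(classified) &&
      !is.null(classified$isomir) && !is.null(de_tables$mirna)) {
    run_stage("profile", cfg$outdir, {
      de_mir <- de_tables$mirna$feature[de_tables$mirna$significant]
      if (length(de_mir) == 0) {
        warning("no DE canonical miRNAs: class profile skipped")
      } else {
        prof <- class_frequency(classified$isomir, de_mir)
        write_class_profile(prof,
                            file.path(cfg$outdir, "class_frequency.tsv"),
                            file.path(cfg$outdir, "class_heatmap.tsv"))
        manifest$profile <- list(n_de_mirnas = length(de_mir))
      }
    })
  }

  manifest$outputs <- sort(list.files(cfg$outdir))
  jsonlite::write_json(manifest, file.path(cfg$outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
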