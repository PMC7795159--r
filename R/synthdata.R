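#' Configuration for the synthetic multi-omics generator
#'
#' Bundles and validates every knob of the generative model that emulates
#' the platelet study design: two groups of 11 samples (the proteomics
#' subset of the PDAC-like group A has 8 samples), negative-binomial counts
#' with log-normal library sizes, planted fold changes, miRNA-to-target
#' repression couplings, mRNA-to-protein positive couplings, and per-group
#' isomiR class mixtures.
#'
#' Group conventions: `"A"` is the PDAC-like group, `"B"` the benign-like
#' group. Planted log2 fold changes are recorded A-versus-B, matching the
#' sign convention of [differential_table()].
#'
#' @param n_samples_per_group samples per group for the RNA layers.
#' @param n_protein_samples_a protein-layer samples in group A (the
#'   proteomics design is 8 vs 11).
#' @param n_mirna,n_mrna,n_intron,n_protein feature counts per layer; the
#'   intron layer is a subset of the mRNA genes (intron-spanning reads of
#'   the same genes), the protein layer maps 1:1 onto a subset of genes.
#' @param lib_size_log_mean,lib_size_log_sd log-scale library size
#'   distribution (natural log).
#' @param nb_dispersion NB dispersion phi >= 0 (variance = mu + phi mu^2);
#'   0 gives Poisson counts.
#' @param frac_de fraction of features with a planted fold change, in
#'   \[0, 1\].
#' @param planted_lfc magnitude of the planted log2 fold change.
#' @param repression_beta coupling strength of a regulator miRNA on its
#'   target gene's mean (log-linear in the regulator's standardized
#'   abundance; positive beta plants negative sample-wise correlation).
#' @param protein_coupling coefficient of standardized log mRNA abundance
#'   in the protein log-mean (positive plants positive correlation).
#' @param class_probs_by_group named list with elements `A` and `B`, each a
#'   probability vector over the 11 isomiR classes (see
#'   [isomir_classes()]), summing to 1.
#' @param n_hub_regulators number of miRNAs repressing the planted hub
#'   transcript (>= 5, the SPARC-like multi-regulator node).
#' @param isomirs_per_mirna isomiR features per canonical miRNA in the
#'   isomiR count layer.
#' @param target_frac fraction of non-hub miRNAs that each repress one
#'   distinct gene.
#' @param bio_sd per-sample biological log-noise SD on latent abundances.
#' @param seed RNG seed.
#' @return validated list of class `"generator_config"`.
#' @export
generator_config <- function(n_samples_per_group = 11L,
                             n_protein_samples_a = 8L,
                             n_mirna = 60L, n_mrna = 120L, n_intron = 80L,
                             n_protein = 60L,
                             lib_size_log_mean = log(3e5),
                             lib_size_log_sd = 0.3,
                             nb_dispersion = 0.1,
                             frac_de = 0.1,
                             planted_lfc = 2,
                             repression_beta = 1.5,
                             protein_coupling = 0.7,
                             class_probs_by_group = default_class_probs(),
                             n_hub_regulators = 6L,
                             isomirs_per_mirna = 3L,
                             target_frac = 0.5,
                             bio_sd = 0.5,
                             seed = NULL) {
  cfg <- list(n_samples_per_group = as.integer(n_samples_per_group),
              n_protein_samples_a = as.integer(n_protein_samples_a),
              n_mirna = as.integer(n_mirna), n_mrna = as.integer(n_mrna),
              n_intron = as.integer(n_intron),
              n_protein = as.integer(n_protein),
              lib_size_log_mean = lib_size_log_mean,
              lib_size_log_sd = lib_size_log_sd,
              nb_dispersion = nb_dispersion, frac_de = frac_de,
              planted_lfc = planted_lfc,
              repression_beta = repression_beta,
              protein_coupling = protein_coupling,
              class_probs_by_group = class_probs_by_group,
              n_hub_regulators = as.integer(n_hub_regulators),
              isomirs_per_mirna = as.integer(isomirs_per_mirna),
              target_frac = target_frac, bio_sd = bio_sd, seed = seed)
  validate_generator_config(cfg)
  class(cfg) <- "generator_config"
  cfg
}

validate_generator_config <- function(cfg) {
  with(cfg, {
    if (n_samples_per_group < 2L) stop("need >= 2 samples per group")
    if (n_protein_samples_a < 2L || n_protein_samples_a > n_samples_per_group)
      stop("n_protein_samples_a must be in [2, n_samples_per_group]")
    if (any(c(n_mirna, n_mrna, n_intron, n_protein) < 1L))
      stop("feature counts must be positive")
    if (n_intron > n_mrna) stop("intron layer is a subset of the genes")
    if (n_protein > n_mrna) stop("protein layer maps onto a subset of genes")
    if (nb_dispersion < 0) stop("nb_dispersion must be >= 0")
    if (lib_size_log_sd < 0 || bio_sd < 0) stop("SDs must be >= 0")
    if (frac_de < 0 || frac_de > 1) stop("frac_de must be in [0, 1]")
    if (target_frac < 0 || target_frac > 1)
      stop("target_frac must be in [0, 1]")
    if (n_hub_regulators < 5L)
      stop("the hub transcript needs >= 5 distinct regulators")
    if (n_hub_regulators >= n_mirna)
      stop("n_hub_regulators must leave room for non-hub miRNAs")
    if (!all(c("A", "B") %in% names(class_probs_by_group)))
      stop("class_probs_by_group needs elements 'A' and 'B'")
    for (g in c("A", "B")) {
      p <- class_probs_by_group[[g]]
      if (!setequal(names(p), isomir_classes()))
        stop("class probabilities must cover exactly the 11 isomiR classes")
      if (any(p < 0)) stop("class probabilities must be non-negative")
      if (abs(sum(p) - 1) > 1e-9)
        stop("class probabilities must sum to 1")
    }
  })
  invisible(cfg)
}

#' The 11 supported isomiR classes
#'
#' Canonical plus 3'/5' length variants (templated trimming or extension),
#' multiple length variants at both ends, the mixed-variant catch-all,
#' internal nucleotide variants, and non-templated 3' additions of each
#' base (tail bases reported in the DNA alphabet, so a poly-U tail is
#' `nta#T`).
#'
#' @return character vector of class labels.
#' @export
isomir_classes <- function() {
  c("canonical", "lv3p", "lv5p", "mlv3p", "mlv5p", "mv", "nve",
    "nta#A", "nta#C", "nta#G", "nta#T")
}

#' Default per-group isomiR class mixtures
#'
#' Qualitative pattern reported for platelet small-RNA repertoires: the
#' benign-like group is enriched for non-templated G additions, while the
#' PDAC-like group nearly loses nta#G and gains 3' length variants and
#' non-templated U (reported as T) additions.
#'
#' @return named list with probability vectors `A` (PDAC-like) and `B`
#'   (benign-like) over [isomir_classes()].
#' @export
default_class_probs <- function() {
  a <- c(canonical = 0.30, lv3p = 0.20, lv5p = 0.06, mlv3p = 0.04,
         mlv5p = 0.06, mv = 0.04, nve = 0.04,
         `nta#A` = 0.07, `nta#C` = 0.03, `nta#G` = 0.01, `nta#T` = 0.15)
  b <- c(canonical = 0.35, lv3p = 0.05, lv5p = 0.05, mlv3p = 0.05,
         mlv5p = 0.05, mv = 0.05, nve = 0.05,
         `nta#A` = 0.05, `nta#C` = 0.03, `nta#G` = 0.25, `nta#T` = 0.02)
  list(A = a, B = b)
}

rnb <- function(n, mu, phi) {
  mu <- pmax(mu, 1e-12)
  if (phi <= 0) return(stats::rpois(n, mu))
  stats::rnbinom(n, mu = mu, size = 1 / phi)
}

# Standardize each row of a log-abundance matrix within each group.
# Networks are built per group, so the planted couplings act on
# within-group variation and do not leak random group-mean shifts into
# target features.
standardize_within_group <- function(m, groups) {
  z <- m
  for (g in unique(groups)) {
    idx <- which(groups == g)
    sub <- m[, idx, drop = FALSE]
    mu <- rowMeans(sub)
    sd <- apply(sub, 1, stats::sd)
    sd[sd == 0] <- 1
    z[, idx] <- (sub - mu) / sd
  }
  z
}

#' Generate multi-omics count layers with planted ground truth
#'
#' Draws five coupled count layers (canonical miRNA, isomiR,
#' intron-spanning, mRNA, protein spectral counts) from a hierarchical
#' gamma-Poisson model: log-normal library sizes, skewed baseline
#' abundances, per-sample log-normal biological noise, NB observation
#' noise. Planted structure, all recorded in the returned truth object:
#'
#' * a fraction `frac_de` of features per layer receives a signed log2
#'   fold change of magnitude `planted_lfc` (A versus B);
#' * each regulator miRNA represses its target gene's latent mean by
#'   `exp(-repression_beta * z)` where `z` is the regulator's standardized
#'   log abundance in that sample (negative sample-wise correlation);
#' * one hub transcript is repressed by `n_hub_regulators` miRNAs acting
#'   through a shared latent factor (a co-regulated miRNA cluster), making
#'   it the intended top-degree transcript of isomiR networks;
#' * protein log-means are `protein_coupling` times the standardized log
#'   abundance of the matched gene plus independent noise (positive
#'   correlation), drawn Poisson;
#' * isomiR features are children of their parent miRNA (shared latent)
#'   with group-specific class-mixture multipliers.
#'
#' @param cfg a [generator_config()].
#' @return list with `layers` (named list of [count_matrix()] objects:
#'   `mirna`, `isomir`, `mrna`, `intron`, `protein`) and `truth` (class
#'   `"synthetic_truth"`: per-layer `de_features` maps of planted signed
#'   log2FC, `target_map`, `protein_map`, `class_mixture`,
#'   `hub_transcript`, `hub_regulators`).
#' @export
generate_expression <- function(cfg = generator_config()) {
  validate_generator_config(cfg)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_samples_per_group
  samples <- c(sprintf("A%02d", seq_len(n)), sprintf("B%02d", seq_len(n)))
  groups <- stats::setNames(rep(c("A", "B"), each = n), samples)
  phi <- cfg$nb_dispersion

  mir_ids <- sprintf("syn-mir-%03d", seq_len(cfg$n_mirna))
  gene_ids <- sprintf("gene%04d", seq_len(cfg$n_mrna))

  ## --- regulatory wiring -------------------------------------------------
  regulators <- mir_ids[seq_len(cfg$n_hub_regulators)]
  others <- setdiff(mir_ids, regulators)
  hub <- gene_ids[1]
  n_single <- round(cfg$target_frac * length(others))
  single_regs <- if (n_single > 0) sample(others, n_single) else character(0)
  free_genes <- setdiff(gene_ids, hub)
  single_targets <- if (n_single > 0) sample(free_genes, n_single)
                    else character(0)
  target_map <- c(stats::setNames(as.list(rep(hub, length(regulators))),
                                  regulators),
                  stats::setNames(as.list(single_targets), single_regs))
  target_map <- lapply(target_map, as.character)

  ## --- planted DE assignment --------------------------------------------
  pick_de <- function(ids, forced = character(0), forced_sign = NULL) {
    n_de <- round(cfg$frac_de * length(ids))
    chosen <- forced
    pool <- setdiff(ids, forced)
    extra <- max(0, n_de - length(forced))
    if (extra > 0) chosen <- c(chosen, sample(pool, min(extra, length(pool))))
    if (length(chosen) == 0) return(stats::setNames(numeric(0), character(0)))
    sgn <- sample(c(-1, 1), length(chosen), replace = TRUE)
    if (!is.null(forced_sign) && length(forced) > 0)
      sgn[seq_along(forced)] <- forced_sign
    stats::setNames(sgn * cfg$planted_lfc, chosen)
  }
  de_mir <- if (cfg$frac_de > 0)
    pick_de(mir_ids, forced = regulators, forced_sign = rep(1, length(regulators)))
  else stats::setNames(numeric(0), character(0))
  # hub transcript down in the PDAC-like group, mirroring a repressed
  # target; six up-regulated regulators compound, so its magnitude is
  # 1.5x the standard plant
  de_gene <- if (cfg$frac_de > 0) pick_de(gene_ids, forced = hub,
                                          forced_sign = -1)
             else stats::setNames(numeric(0), character(0))
  if (hub %in% names(de_gene)) de_gene[hub] <- -1.5 * cfg$planted_lfc

  # group-B multiplier implementing an A-vs-B log2FC
  de_mult <- function(ids, de_map) {
    lfc <- stats::setNames(rep(0, length(ids)), ids)
    lfc[names(de_map)] <- de_map
    outer(lfc, groups == "B", function(l, b) ifelse(b, 2^(-l), 1))
  }

  ## --- canonical miRNA layer --------------------------------------------
  base_m <- exp(stats::rnorm(cfg$n_mirna, 0, 1.25))
  names(base_m) <- mir_ids
  # regulators sit at mid-range abundance: a planted regulator that
  # dominated the layer would drive the CPM denominator and cancel its own
  # signal out of every feature's relative abundance
  base_m[regulators] <- exp(stats::rnorm(length(regulators), 0, 0.5))
  u <- stats::rnorm(2 * n)   # shared factor of the tight regulator cluster
  rho <- 0.95
  eps <- matrix(stats::rnorm(cfg$n_mirna * 2 * n, 0, cfg$bio_sd),
                cfg$n_mirna, 2 * n, dimnames = list(mir_ids, samples))
  # regulating miRNAs swing with twice the baseline biological amplitude
  # (the dynamically modulated species): strong sample-to-sample
  # modulation is what makes the planted repression detectable at
  # n = 11 per group. The hub's cluster additionally shares a factor.
  eps[regulators, ] <- 2 * cfg$bio_sd *
    (rho * matrix(u, length(regulators), 2 * n, byrow = TRUE) +
       sqrt(1 - rho^2) * matrix(stats::rnorm(length(regulators) * 2 * n),
                                length(regulators), 2 * n))
  if (length(single_regs) > 0)
    eps[single_regs, ] <- 2 * eps[single_regs, , drop = FALSE]
  latent_m <- base_m * exp(eps) * de_mult(mir_ids, de_mir)
  lib_m <- exp(stats::rnorm(2 * n, cfg$lib_size_log_mean,
                            cfg$lib_size_log_sd))
  prop_m <- sweep(latent_m, 2, colSums(latent_m), "/")
  counts_m <- matrix(rnb(length(prop_m), sweep(prop_m, 2, lib_m, "*"), phi),
                     nrow(prop_m), dimnames = dimnames(prop_m))

  z_m <- standardize_within_group(log(latent_m), groups)
  z_u <- standardize_within_group(matrix(u, 1, 2 * n,
                                         dimnames = list("u", samples)),
                                  groups)[1, ]

  ## --- isomiR layer ------------------------------------------------------
  iso_classes <- setdiff(isomir_classes(), "canonical")
  # average mixture over groups, renormalized over non-canonical classes
  avg_p <- (cfg$class_probs_by_group$A + cfg$class_probs_by_group$B) / 2
  avg_p <- avg_p[iso_classes] / sum(avg_p[iso_classes])
  iso_parent <- rep(mir_ids, each = cfg$isomirs_per_mirna)
  iso_class <- sample(iso_classes, length(iso_parent), replace = TRUE,
                      prob = avg_p)
  iso_ids <- sprintf("%s|%s|v%d", iso_parent, iso_class,
                     stats::ave(seq_along(iso_parent), iso_parent,
                                FUN = seq_along))
  # group-specific class multiplier: relative weight of the class in the
  # group's mixture (renormalized over non-canonical classes)
  class_w <- sapply(c("A", "B"), function(g) {
    p <- cfg$class_probs_by_group[[g]][iso_classes]
    p / sum(p)
  })
  mult_iso <- class_w[iso_class, groups[samples]]
  dimnames(mult_iso) <- list(iso_ids, samples)
  base_w <- exp(stats::rnorm(length(iso_ids), -1, 0.6))
  latent_i <- base_w * latent_m[iso_parent, , drop = FALSE] *
    exp(matrix(stats::rnorm(length(iso_ids) * 2 * n, 0, 0.2),
               length(iso_ids), 2 * n)) * mult_iso
  dimnames(latent_i) <- list(iso_ids, samples)
  lib_i <- exp(stats::rnorm(2 * n, cfg$lib_size_log_mean,
                            cfg$lib_size_log_sd))
  prop_i <- sweep(latent_i, 2, colSums(latent_i), "/")
  counts_i <- matrix(rnb(length(prop_i), sweep(prop_i, 2, lib_i, "*"), phi),
                     nrow(prop_i), dimnames = dimnames(prop_i))
  de_iso <- stats::setNames(rep(0, length(iso_ids)), iso_ids)
  de_iso[iso_parent %in% names(de_mir)] <-
    de_mir[iso_parent[iso_parent %in% names(de_mir)]]
  de_iso <- de_iso + log2(class_w[iso_class, "A"] / class_w[iso_class, "B"])
  de_iso <- de_iso[abs(de_iso) > 1e-9]

  ## --- gene (mRNA + intron) layers ---------------------------------------
  base_g <- exp(stats::rnorm(cfg$n_mrna, 0, 1.25))
  names(base_g) <- gene_ids
  base_g[hub] <- exp(stats::rnorm(1, 0.5, 0.5))  # hub never count-starved
  rep_term <- matrix(0, cfg$n_mrna, 2 * n, dimnames = list(gene_ids, samples))
  rep_term[hub, ] <- -cfg$repression_beta * z_u
  if (length(single_regs) > 0)
    rep_term[single_targets, ] <- -cfg$repression_beta *
      z_m[single_regs, , drop = FALSE]
  latent_g <- base_g * exp(rep_term) * de_mult(gene_ids, de_gene) *
    exp(matrix(stats::rnorm(cfg$n_mrna * 2 * n, 0, cfg$bio_sd),
               cfg$n_mrna, 2 * n))
  dimnames(latent_g) <- list(gene_ids, samples)
  lib_g <- exp(stats::rnorm(2 * n, cfg$lib_size_log_mean,
                            cfg$lib_size_log_sd))
  prop_g <- sweep(latent_g, 2, colSums(latent_g), "/")
  counts_g <- matrix(rnb(length(prop_g), sweep(prop_g, 2, lib_g, "*"), phi),
                     nrow(prop_g), dimnames = dimnames(prop_g))

  intron_ids <- gene_ids[seq_len(cfg$n_intron)]   # includes the hub
  latent_n <- latent_g[intron_ids, , drop = FALSE] *
    exp(stats::rnorm(cfg$n_intron, -0.7, 0.4)) *
    exp(matrix(stats::rnorm(cfg$n_intron * 2 * n, 0, 0.2),
               cfg$n_intron, 2 * n))
  lib_n <- exp(stats::rnorm(2 * n, cfg$lib_size_log_mean,
                            cfg$lib_size_log_sd))
  prop_n <- sweep(latent_n, 2, colSums(latent_n), "/")
  counts_n <- matrix(rnb(length(prop_n), sweep(prop_n, 2, lib_n, "*"), phi),
                     nrow(prop_n), dimnames = dimnames(prop_n))
  de_intron <- de_gene[names(de_gene) %in% intron_ids]

  ## --- protein layer ------------------------------------------------------
  prot_genes <- gene_ids[seq_len(cfg$n_protein)]  # includes the hub
  prot_ids <- paste0("prot_", prot_genes)
  prot_samples <- c(samples[seq_len(cfg$n_protein_samples_a)],
                    samples[n + seq_len(n)])
  prot_groups <- groups[prot_samples]
  z_g <- standardize_within_group(log(latent_g[prot_genes, prot_samples,
                                               drop = FALSE]), prot_groups)
  base_p <- exp(stats::rnorm(cfg$n_protein, log(30), 1))
  de_prot_full <- stats::setNames(rep(0, cfg$n_protein), prot_genes)
  idx <- intersect(names(de_gene), prot_genes)
  de_prot_full[idx] <- de_gene[idx] * cfg$protein_coupling
  bshift <- outer(de_prot_full, prot_groups == "B",
                  function(l, b) ifelse(b, 2^(-l), 1))
  mu_p <- base_p * exp(cfg$protein_coupling * z_g +
                         matrix(stats::rnorm(cfg$n_protein *
                                               length(prot_samples), 0, 0.3),
                                cfg$n_protein, length(prot_samples))) * bshift
  counts_p <- matrix(stats::rpois(length(mu_p), mu_p), nrow(mu_p),
                     dimnames = list(prot_ids, prot_samples))
  de_prot <- stats::setNames(de_prot_full, prot_ids)
  de_prot <- de_prot[abs(de_prot) > 1e-9]
  protein_map <- stats::setNames(prot_ids, prot_genes)

  truth <- structure(list(
    de_features = list(mirna = as.list(de_mir), isomir = as.list(de_iso),
                       mrna = as.list(de_gene), intron = as.list(de_intron),
                       protein = as.list(de_prot)),
    target_map = target_map,
    protein_map = as.list(protein_map),
    class_mixture = cfg$class_probs_by_group,
    hub_transcript = hub,
    hub_regulators = regulators), class = "synthetic_truth")
  validate_truth(truth, layers = list(
    mirna = rownames(counts_m), isomir = rownames(counts_i),
    mrna = rownames(counts_g), intron = rownames(counts_n),
    protein = rownames(counts_p)))

  list(layers = list(
         mirna = count_matrix(counts_m, groups, "mirna"),
         isomir = count_matrix(counts_i, groups, "isomir"),
         mrna = count_matrix(counts_g, groups, "mrna"),
         intron = count_matrix(counts_n, groups, "intron"),
         protein = count_matrix(counts_p, prot_groups, "protein")),
       truth = truth)
}

validate_truth <- function(truth, layers) {
  for (ly in names(truth$de_features)) {
    bad <- setdiff(names(truth$de_features[[ly]]), layers[[ly]])
    if (length(bad) > 0)
      stop("planted DE features missing from layer ", ly, ": ",
           paste(utils::head(bad, 3), collapse = ", "))
  }
  n_reg <- sum(vapply(truth$target_map, function(t)
    truth$hub_transcript %in% t, logical(1)))
  if (n_reg < 5)
    stop("hub transcript must have >= 5 distinct planted regulators")
  invisible(truth)
}

#' Serialize / load the ground-truth object
#'
#' Truth is written as JSON next to the generated data so that validation
#' never has to re-derive the plantings.
#'
#' @param truth a `"synthetic_truth"` object.
#' @param path JSON file path.
#' @return `read_truth()` returns the `"synthetic_truth"` object.
#' @export
write_truth <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE,
                           simplifyDataFrame = FALSE)
  x$de_features <- lapply(x$de_features, as.list)
  structure(x, class = "synthetic_truth")
}

#' Generate synthetic small-RNA reads with known isomiR classes
#'
#' Builds per-sample read multisets from a mature-miRNA reference: each
#' read picks a random parent, draws its class from the group's mixture
#' and applies the corresponding modification — templated trimming or
#' extension from the flanks for length variants, a uniform-base
#' non-templated 3' tail for `nta#X` (re-drawing the parent when the flank
#' would template the tail base), an internal substitution for `nve`, and
#' combined modifications for `mlv*`/`mv`. Reads are emitted in the RNA
#' alphabet; true class labels are recorded per read.
#'
#' @param reference a `mirna_reference` (see [generate_reference()]).
#' @param class_probs_by_group named list (`A`, `B`) of probability
#'   vectors over exactly the 11 classes of [isomir_classes()].
#' @param n_samples_per_group samples per group.
#' @param reads_per_sample reads drawn for every sample.
#' @param seed RNG seed.
#' @return list with `samples` (named list of data.frames `sequence`,
#'   `parent`, `class` — one row per read), `groups` (named vector) and
#'   `redraws` (count of impossible-modification re-draws, logged, not
#'   silent).
#' @export
generate_reads <- function(reference, class_probs_by_group = default_class_probs(),
                           n_samples_per_group = 11L,
                           reads_per_sample = 5000L, seed = NULL) {
  validate_reference(reference)
  for (g in names(class_probs_by_group)) {
    p <- class_probs_by_group[[g]]
    if (!setequal(names(p), isomir_classes()))
      stop("class_probs must cover exactly the 11 supported classes")
    if (abs(sum(p) - 1) > 1e-9) stop("class_probs must sum to 1")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- n_samples_per_group
  samples <- c(sprintf("A%02d", seq_len(n)), sprintf("B%02d", seq_len(n)))
  groups <- stats::setNames(rep(c("A", "B"), each = n), samples)
  redraws <- 0L
  out <- lapply(samples, function(s) {
    p <- class_probs_by_group[[groups[[s]]]][isomir_classes()]
    cls <- sample(isomir_classes(), reads_per_sample, replace = TRUE,
                  prob = p)
    parent <- sample(reference$name, reads_per_sample, replace = TRUE)
    seqs <- character(reads_per_sample)
    for (i in seq_len(reads_per_sample)) {
      made <- make_read(reference, parent[i], cls[i])
      redraws <<- redraws + made$redraws
      parent[i] <- made$parent
      seqs[i] <- made$seq
    }
    data.frame(sequence = seqs, parent = parent, class = cls,
               stringsAsFactors = FALSE)
  })
  names(out) <- samples
  list(samples = out, groups = groups, redraws = redraws)
}

str_rev_tail <- function(s, k) substr(s, nchar(s) - k + 1, nchar(s))

# Build one read of a given class; re-draw the parent (logged) when the
# requested modification is impossible there, e.g. nta#G under a flank
# starting with G, which would be indistinguishable from a templated
# extension.
make_read <- function(reference, parent, cls, max_tries = 25L) {
  rna_bases <- c("A", "C", "G", "U")
  redraws <- 0L
  repeat {
    row <- reference[reference$name == parent, ]
    m <- row$mature_seq; f5 <- row$flank5; f3 <- row$flank3
    L <- nchar(m)
    shift5 <- function(s, o5) {          # o5 > 0: trim; o5 < 0: extend
      if (o5 >= 0) substr(s, o5 + 1, nchar(s))
      else paste0(str_rev_tail(f5, -o5), s)
    }
    shift3 <- function(s, o3) {          # o3 > 0: extend; o3 < 0: trim
      if (o3 <= 0) substr(s, 1, nchar(s) + o3)
      else paste0(s, substr(f3, 1, o3))
    }
    seq <- switch(cls,
      canonical = m,
      lv3p = shift3(m, sample(c(-2:-1, 1:2), 1)),
      lv5p = shift5(m, sample(c(-2:-1, 1:2), 1)),
      mlv5p = {
        a5 <- sample(1:3, 1); a3 <- sample(seq_len(a5), 1)
        shift3(shift5(m, a5 * sample(c(-1, 1), 1)), a3 * sample(c(-1, 1), 1))
      },
      mlv3p = {
        a3 <- sample(2:3, 1); a5 <- sample(seq_len(a3 - 1), 1)
        shift3(shift5(m, a5 * sample(c(-1, 1), 1)), a3 * sample(c(-1, 1), 1))
      },
      nve = {
        pos <- sample(6:(L - 5), 1)
        base <- substr(m, pos, pos)
        sub <- sample(setdiff(rna_bases, base), 1)
        paste0(substr(m, 1, pos - 1), sub, substr(m, pos + 1, L))
      },
      nve_impossible = NULL,
      {
        if (startsWith(cls, "nta#")) {
          x <- sub("nta#", "", cls)
          x_rna <- if (x == "T") "U" else x
          if (substr(f3, 1, 1) == x_rna) NULL
          else paste0(m, strrep(x_rna, sample(1:3, 1)))
        } else if (cls == "mv") {
          # 5' trim plus a short non-templated uniform tail
          x_rna <- sample(setdiff(rna_bases, substr(f3, 1, 1)), 1)
          paste0(substr(m, 2, L), strrep(x_rna, sample(1:2, 1)))
        } else stop("unknown class: ", cls)
      })
    if (!is.null(seq) && nchar(seq) >= 15)
      return(list(seq = seq, parent = parent, redraws = redraws))
    redraws <- redraws + 1L
    if (redraws > max_tries)
      stop("could not realize class ", cls, " on any parent")
    parent <- sample(reference$name, 1)
  }
}
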