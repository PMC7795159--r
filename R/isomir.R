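#' Classify a small-RNA read against one mature miRNA
#'
#' Anchors the read to the extended template (5' flank + mature + 3'
#' flank), allowing templated shifts of both ends within `max_offset`, up
#' to `max_subs` internal substitutions within the mature region, and a 3'
#' non-templated tail of up to `max_tail` nt. Shifted or extended bases
#' must match the genomic template; the tail by definition does not. Among
#' all valid anchorings the one with the fewest modifications is chosen
#' (ties prefer the longer templated core, i.e. the shorter tail), and the
#' class label follows a fixed decision tree:
#'
#' 1. exact match: `canonical`;
#' 2. internal substitutions only, ends canonical: `nve`;
#' 3. uniform-base non-templated 3' tail, ends otherwise canonical:
#'    `nta#X` with `X` the tail base (DNA alphabet, so poly-U reads as
#'    `nta#T`);
#' 4. a single templated end shift: `lv5p` / `lv3p`;
#' 5. both ends shifted, no tail or substitutions: `mlv5p` when
#'    `|offset5| >= |offset3|`, else `mlv3p`;
#' 6. any other combination (tail plus shift, substitution plus shift,
#'    mixed-base tail): `mv`.
#'
#' Offset conventions: `offset5 > 0` means 5' trimming, `< 0` templated 5'
#' extension; `offset3 > 0` means templated 3' extension, `< 0` trimming.
#'
#' @param read read sequence (RNA alphabet; DNA input is converted).
#' @param ref one-row `mirna_reference` entry (or a list with
#'   `name`, `mature_seq`, `flank5`, `flank3`).
#' @param max_offset maximum end shift in nt (default 3).
#' @param max_tail maximum non-templated tail length (default 3).
#' @param max_subs maximum internal substitutions (default 1).
#' @return list of class `"isomir_call"` with fields `read_seq`, `parent`,
#'   `class_label`, `offset5`, `offset3`, `tail` (DNA alphabet), `n_subs`,
#'   `cost`; or `NULL` when the read cannot be anchored within the limits
#'   (no-call). Reads shorter than 15 nt are always no-calls.
#' @export
classify_read <- function(read, ref, max_offset = 3L, max_tail = 3L,
                          max_subs = 1L) {
  read <- toupper(gsub("T", "U", read))
  if (nchar(read) < 15L) return(NULL)
  anchor <- best_anchoring(read, ref, max_offset, max_tail, max_subs)
  if (is.null(anchor)) return(NULL)
  label_call(read, ref, anchor)
}

best_anchoring <- function(read, ref, max_offset, max_tail, max_subs) {
  m <- ref$mature_seq; f5 <- ref$flank5; f3 <- ref$flank3
  template <- strsplit(paste0(f5, m, f3), "")[[1]]
  rd <- strsplit(read, "")[[1]]
  n_read <- length(rd)
  s0 <- nchar(f5) + 1L
  e0 <- nchar(f5) + nchar(m)
  best <- NULL
  for (off5 in -max_offset:max_offset) {
    p <- s0 + off5
    if (p < 1L) next
    for (off3 in -max_offset:max_offset) {
      q <- e0 + off3
      if (q > length(template) || q < p) next
      core_len <- q - p + 1L
      tail_len <- n_read - core_len
      if (tail_len < 0L || tail_len > max_tail) next
      tpl <- template[p:q]
      mism <- which(rd[seq_len(core_len)] != tpl)
      # extension bases (outside the mature interval) must be templated
      pos_in_template <- p:q
      in_mature <- pos_in_template >= s0 & pos_in_template <= e0
      if (any(!in_mature[mism])) next
      n_subs <- length(mism)
      if (n_subs > max_subs) next
      cost <- n_subs + tail_len + abs(off5) + abs(off3)
      cand <- list(off5 = off5, off3 = off3, tail_len = tail_len,
                   n_subs = n_subs, cost = cost)
      if (is.null(best) || anchor_less(cand, best)) best <- cand
    }
  }
  best
}

anchor_less <- function(a, b) {
  ka <- c(a$cost, a$tail_len, a$n_subs, abs(a$off5) + abs(a$off3),
          a$off5, a$off3)
  kb <- c(b$cost, b$tail_len, b$n_subs, abs(b$off5) + abs(b$off3),
          b$off5, b$off3)
  d <- ka - kb
  nz <- which(d != 0)
  length(nz) > 0 && d[nz[1]] < 0
}

label_call <- function(read, ref, a) {
  n_read <- nchar(read)
  tail_rna <- if (a$tail_len > 0)
    substr(read, n_read - a$tail_len + 1L, n_read) else ""
  tail_dna <- gsub("U", "T", tail_rna)
  off5 <- a$off5; off3 <- a$off3
  no_shift <- off5 == 0L && off3 == 0L
  uniform <- a$tail_len > 0 &&
    length(unique(strsplit(tail_dna, "")[[1]])) == 1L
  cls <-
    if (no_shift && a$n_subs == 0L && a$tail_len == 0L) "canonical"
    else if (no_shift && a$n_subs > 0L && a$tail_len == 0L) "nve"
    else if (no_shift && a$n_subs == 0L && uniform)
      paste0("nta#", substr(tail_dna, 1, 1))
    else if (a$tail_len == 0L && a$n_subs == 0L && xor(off5 != 0L, off3 != 0L))
      if (off5 != 0L) "lv5p" else "lv3p"
    else if (a$tail_len == 0L && a$n_subs == 0L)
      if (abs(off5) >= abs(off3)) "mlv5p" else "mlv3p"
    else "mv"
  structure(list(read_seq = read, parent = ref$name, class_label = cls,
                 offset5 = off5, offset3 = off3, tail = tail_dna,
                 n_subs = a$n_subs, cost = a$cost),
            class = "isomir_call")
}

# k-mer index over extended templates: maps each 8-mer to the reference
# rows containing it, so that only plausible parents are scored per read.
build_template_index <- function(reference, k = 8L) {
  tpl <- paste0(reference$flank5, reference$mature_seq, reference$flank3)
  kmers <- lapply(tpl, function(t) {
    n <- nchar(t)
    if (n < k) return(character(0))
    unique(substring(t, 1:(n - k + 1), k:n))
  })
  idx <- split(rep(seq_along(tpl), lengths(kmers)), unlist(kmers))
  list(index = idx, k = k)
}

candidate_parents <- function(read, index) {
  n <- nchar(read)
  k <- index$k
  if (n < k) return(integer(0))
  km <- unique(substring(read, 1:(n - k + 1), k:n))
  sort(unique(unlist(index$index[km], use.names = FALSE)))
}

#' Classify many reads against a full reference
#'
#' Unique sequences are classified once (reads form a multiset); candidate
#' parents are pre-selected with an 8-mer index over the extended
#' templates. When a read is classifiable against several reference
#' entries, it is assigned to the parent requiring the fewest
#' modifications, ties broken lexicographically by name; such ambiguities
#' are counted, never silently dropped.
#'
#' @param reads character vector of read sequences (repeats allowed) or a
#'   collapsed data.frame (`sequence`, `count`).
#' @param reference a `mirna_reference`.
#' @param max_offset,max_tail,max_subs classification limits, see
#'   [classify_read()].
#' @return data.frame with one row per unique sequence: `sequence`,
#'   `count`, `parent`, `class_label`, `offset5`, `offset3`, `tail`,
#'   `n_subs`, `ambiguous` (logical); no-calls carry `NA` in the call
#'   columns.
#' @export
classify_reads <- function(reads, reference, max_offset = 3L, max_tail = 3L,
                           max_subs = 1L) {
  validate_reference(reference)
  df <- collapse_reads(reads)
  idx <- build_template_index(reference)
  brute <- nrow(reference) <= 20L
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    rd <- df$sequence[i]
    cand <- if (brute) seq_len(nrow(reference))
            else candidate_parents(gsub("T", "U", toupper(rd)), idx)
    calls <- list()
    for (j in cand) {
      cl <- classify_read(rd, reference[j, ], max_offset, max_tail, max_subs)
      if (!is.null(cl)) calls[[length(calls) + 1L]] <- cl
    }
    if (length(calls) == 0L) {
      out[[i]] <- data.frame(sequence = rd, count = df$count[i],
                             parent = NA_character_,
                             class_label = NA_character_,
                             offset5 = NA_integer_, offset3 = NA_integer_,
                             tail = NA_character_, n_subs = NA_integer_,
                             ambiguous = FALSE, stringsAsFactors = FALSE)
      next
    }
    costs <- vapply(calls, `[[`, numeric(1), "cost")
    best <- which(costs == min(costs))
    ambiguous <- length(calls) > 1L
    if (length(best) > 1L) {   # fewest modifications, then name
      nms <- vapply(calls[best], `[[`, character(1), "parent")
      best <- best[order(nms)][1]
    }
    cl <- calls[[best[1]]]
    out[[i]] <- data.frame(sequence = rd, count = df$count[i],
                           parent = cl$parent, class_label = cl$class_label,
                           offset5 = cl$offset5, offset3 = cl$offset3,
                           tail = cl$tail, n_subs = cl$n_subs,
                           ambiguous = ambiguous, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Build canonical-miRNA and isomiR count matrices from reads
#'
#' Classifies every sample's reads against one shared reference and
#' tabulates two layers: the canonical matrix aggregates all calls per
#' parent miRNA (canonical reads and all its variants — canonical miRNA
#' expression sums its whole isoform family), and the isomiR matrix keys
#' non-canonical calls by `parent|class|offset5|offset3|tail`. No-calls
#' are excluded from both and tallied in a QC report.
#'
#' @param reads_by_sample named list (sample -> read character vector,
#'   collapsed data.frame, or the per-sample data.frames produced by
#'   [generate_reads()]).
#' @param reference a `mirna_reference`.
#' @param groups named group labels covering the samples.
#' @param max_offset,max_tail,max_subs see [classify_read()].
#' @return list with `canonical` and `isomir` ([count_matrix()] objects),
#'   `qc` (per-sample data.frame: `sample`, `n_reads`, `n_nocall`,
#'   `n_ambiguous`) and `calls` (per-sample classified data.frames).
#' @export
count_isomirs <- function(reads_by_sample, reference, groups,
                          max_offset = 3L, max_tail = 3L, max_subs = 1L) {
  if (length(reads_by_sample) == 0L) stop("no samples provided")
  samples <- names(reads_by_sample)
  calls <- lapply(reads_by_sample, function(r) {
    if (is.data.frame(r) && "sequence" %in% names(r) &&
        !"count" %in% names(r)) r <- r$sequence
    classify_reads(r, reference, max_offset, max_tail, max_subs)
  })
  if (all(vapply(calls, nrow, integer(1)) == 0L))
    warning("empty read set: returning empty matrices")
  qc <- data.frame(
    sample = samples,
    n_reads = vapply(calls, function(d) sum(d$count), numeric(1)),
    n_nocall = vapply(calls, function(d) sum(d$count[is.na(d$parent)]),
                      numeric(1)),
    n_ambiguous = vapply(calls, function(d) sum(d$count[d$ambiguous]),
                         numeric(1)),
    stringsAsFactors = FALSE)
  rownames(qc) <- NULL

  canon_tab <- lapply(calls, function(d) {
    d <- d[!is.na(d$parent), , drop = FALSE]
    tapply(d$count, d$parent, sum)
  })
  canon_feats <- reference$name
  canon <- sapply(canon_tab, function(tb) {
    v <- stats::setNames(rep(0, length(canon_feats)), canon_feats)
    v[names(tb)] <- tb
    v
  })
  canon <- matrix(canon, nrow = length(canon_feats),
                  dimnames = list(canon_feats, samples))

  iso_tab <- lapply(calls, function(d) {
    d <- d[!is.na(d$parent) & d$class_label != "canonical", , drop = FALSE]
    if (nrow(d) == 0L) return(stats::setNames(numeric(0), character(0)))
    key <- paste(d$parent, d$class_label, d$offset5, d$offset3, d$tail,
                 sep = "|")
    tapply(d$count, key, sum)
  })
  iso_feats <- sort(unique(unlist(lapply(iso_tab, names))))
  iso_cm <- NULL
  if (length(iso_feats) > 0) {
    iso <- vapply(iso_tab, function(tb) {
      v <- stats::setNames(rep(0, length(iso_feats)), iso_feats)
      if (length(tb) > 0) v[names(tb)] <- tb
      v
    }, numeric(length(iso_feats)))
    iso <- matrix(iso, nrow = length(iso_feats),
                  dimnames = list(iso_feats, samples))
    iso_cm <- count_matrix(iso, groups, "isomir")
  }

  list(canonical = count_matrix(canon, groups, "mirna"),
       isomir = iso_cm, qc = qc, calls = calls)
}

#' Parse isomiR feature keys back into parent and class
#'
#' @param ids character vector of `parent|class|...` isomiR feature keys.
#' @return data.frame with `feature`, `parent`, `class`.
#' @export
parse_isomir_ids <- function(ids) {
  parts <- strsplit(ids, "|", fixed = TRUE)
  data.frame(feature = ids,
             parent = vapply(parts, `[`, character(1), 1),
             class = vapply(parts, `[`, character(1), 2),
             stringsAsFactors = FALSE)
}

#' Per-group isomiR class frequency profile
#'
#' Restricts the isomiR layer to isoforms of differentially expressed
#' canonical miRNAs and profiles, per group: the frequency of each isomiR
#' class (read-count weighted, so the profile reflects how the sequencing
#' mass distributes over classes) and, for the heatmap view, the mean
#' log2(CPM + 1) expression per (miRNA, class, group). The pseudo-count
#' avoids minus infinity for classes absent from a group.
#'
#' @param isomir a [count_matrix()] of the isomiR layer with
#'   `parent|class|...` feature keys.
#' @param de_mirnas non-empty character vector of DE canonical miRNA names.
#' @return list of class `"class_profile"` with `freq` (data.frame
#'   `group`, `class`, `frequency`; frequencies sum to 1 within group) and
#'   `heat` (data.frame `mirna`, `class`, `group`, `mean_log2_cpm`).
#' @export
class_frequency <- function(isomir, de_mirnas) {
  stopifnot(inherits(isomir, "count_matrix"))
  if (length(de_mirnas) == 0L) stop("de_mirnas must be non-empty")
  meta <- parse_isomir_ids(rownames(isomir$counts))
  keep <- meta$parent %in% de_mirnas
  if (!any(keep)) stop("no isomiR features belong to the given DE miRNAs")
  cts <- isomir$counts[keep, , drop = FALSE]
  meta <- meta[keep, , drop = FALSE]
  cpm_m <- cpm(count_matrix(cts, isomir$groups, "isomir"))
  classes <- setdiff(isomir_classes(), "canonical")
  freq <- do.call(rbind, lapply(unique(isomir$groups), function(g) {
    tot <- rowSums(cts[, isomir$groups == g, drop = FALSE])
    by_class <- tapply(tot, factor(meta$class, levels = classes), sum,
                       default = 0)
    f <- by_class / max(sum(by_class), 1)
    data.frame(group = g, class = classes, frequency = as.numeric(f),
               stringsAsFactors = FALSE)
  }))
  heat <- do.call(rbind, lapply(unique(isomir$groups), function(g) {
    sub <- cpm_m[, isomir$groups == g, drop = FALSE]
    key <- paste(meta$parent, meta$class, sep = "\r")
    mu <- tapply(rowMeans(sub), key, sum)   # classes pool their isoforms
    parts <- strsplit(names(mu), "\r", fixed = TRUE)
    data.frame(mirna = vapply(parts, `[`, character(1), 1),
               class = vapply(parts, `[`, character(1), 2),
               group = g, mean_log2_cpm = log2(as.numeric(mu) + 1),
               stringsAsFactors = FALSE)
  }))
  rownames(freq) <- rownames(heat) <- NULL
  structure(list(freq = freq, heat = heat), class = "class_profile")
}

#' Write a class profile to TSV
#'
#' Two files: per-(group, class) frequencies and per-(miRNA, class, group)
#' mean expression.
#'
#' @param profile a `"class_profile"`.
#' @param freq_path,heat_path output paths.
#' @export
write_class_profile <- function(profile, freq_path, heat_path) {
  utils::write.table(profile$freq, freq_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(profile$heat, heat_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(freq_path)
}
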