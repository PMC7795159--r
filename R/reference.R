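#' Generate a synthetic mature-miRNA reference with genomic flanks
#'
#' Produces uniquely named mature miRNA sequences in the RNA alphabet
#' together with 5' and 3' genomic flanking sequence, the template against
#' which isomiRs are called: templated length variants extend into the
#' flanks, whereas non-templated additions by definition do not match them.
#'
#' @param n_mirna number of reference entries.
#' @param length_range integer length-2 vector; mature lengths are drawn
#'   uniformly from this interval, which must lie within \[18, 26\].
#' @param flank_len flank length on each side (>= 5 nt).
#' @param seed RNG seed; identical seeds give identical references.
#' @return data.frame with columns `name`, `mature_seq`, `flank5`, `flank3`
#'   (all RNA alphabet `A/C/G/U`), of class `c("mirna_reference","data.frame")`.
#' @examples
#' ref <- generate_reference(3, c(20, 22), flank_len = 10, seed = 1)
#' nchar(ref$mature_seq)
#' @export
generate_reference <- function(n_mirna, length_range = c(18L, 24L),
                               flank_len = 10L, seed = NULL) {
  if (length(length_range) != 2L || any(!is.finite(length_range)))
    stop("length_range must be a length-2 numeric interval")
  length_range <- as.integer(sort(length_range))
  if (length_range[1] < 18L || length_range[2] > 26L)
    stop("length_range must lie within [18, 26]")
  if (flank_len < 5L) stop("flank_len must be >= 5")
  if (n_mirna < 1L) stop("n_mirna must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  rna <- c("A", "C", "G", "U")
  rand_seq <- function(len) paste(sample(rna, len, replace = TRUE),
                                  collapse = "")
  lens <- length_range[1] +
    sample.int(length_range[2] - length_range[1] + 1L, n_mirna,
               replace = TRUE) - 1L
  out <- data.frame(
    name = sprintf("syn-mir-%03d", seq_len(n_mirna)),
    mature_seq = vapply(lens, rand_seq, character(1)),
    flank5 = vapply(rep(flank_len, n_mirna), rand_seq, character(1)),
    flank3 = vapply(rep(flank_len, n_mirna), rand_seq, character(1)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("mirna_reference", "data.frame")
  validate_reference(out)
  out
}

validate_reference <- function(ref) {
  stopifnot(is.data.frame(ref),
            all(c("name", "mature_seq", "flank5", "flank3") %in% names(ref)))
  if (anyDuplicated(ref$name)) stop("reference names must be unique")
  seqs <- c(ref$mature_seq, ref$flank5, ref$flank3)
  if (any(grepl("[^ACGU]", seqs)))
    stop("reference sequences must be over the RNA alphabet {A,C,G,U}")
  if (any(nchar(ref$flank5) == 0) || any(nchar(ref$flank3) == 0))
    stop("flanks must be non-empty")
  invisible(ref)
}

#' Read / write a miRNA reference (FASTA + flank table)
#'
#' The mature sequences travel as FASTA (via Biostrings); the flanks as a
#' three-column TSV (`name`, `flank5`, `flank3`).
#'
#' @param ref a `mirna_reference` data.frame.
#' @param fasta,flanks file paths for the two components.
#' @return `read_reference()` returns the `mirna_reference`.
#' @export
write_reference <- function(ref, fasta, flanks) {
  validate_reference(ref)
  ss <- Biostrings::RNAStringSet(ref$mature_seq)
  names(ss) <- ref$name
  Biostrings::writeXStringSet(ss, fasta)
  utils::write.table(ref[, c("name", "flank5", "flank3")], flanks,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(fasta)
}

#' @rdname write_reference
#' @export
read_reference <- function(fasta, flanks) {
  ss <- Biostrings::readRNAStringSet(fasta)
  fl <- utils::read.delim(flanks, stringsAsFactors = FALSE)
  ref <- data.frame(name = names(ss),
                    mature_seq = as.character(ss),
                    stringsAsFactors = FALSE)
  ref <- merge(ref, fl, by = "name", sort = FALSE)
  rownames(ref) <- NULL
  class(ref) <- c("mirna_reference", "data.frame")
  validate_reference(ref)
  ref
}

#' Read / write per-sample small-RNA reads
#'
#' Reads are exchanged either as per-sample FASTA or as a collapsed TSV with
#' columns `sequence` and `count` (the multiset representation used
#' internally).
#'
#' @param reads character vector of read sequences (a multiset; repeats
#'   allowed) or a collapsed data.frame with `sequence`/`count` columns.
#' @param path file path.
#' @return `read_reads_tsv()`/`read_reads_fasta()` return a collapsed
#'   data.frame (`sequence`, `count`).
#' @export
write_reads_tsv <- function(reads, path) {
  df <- collapse_reads(reads)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_reads_tsv
#' @export
read_reads_tsv <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("sequence", "count") %in% names(df)))
    stop("collapsed read TSV needs 'sequence' and 'count' columns")
  df$count <- as.integer(df$count)
  df
}

#' @rdname write_reads_tsv
#' @export
write_reads_fasta <- function(reads, path) {
  df <- collapse_reads(reads)
  ss <- Biostrings::RNAStringSet(df$sequence)
  names(ss) <- sprintf("read%06d_x%d", seq_len(nrow(df)), df$count)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' @rdname write_reads_tsv
#' @export
read_reads_fasta <- function(path) {
  ss <- Biostrings::readRNAStringSet(path)
  cnt <- suppressWarnings(as.integer(sub(".*_x(\\d+)$", "\\1", names(ss))))
  cnt[is.na(cnt)] <- 1L
  stats::aggregate(count ~ sequence,
                   data.frame(sequence = as.character(ss), count = cnt,
                              stringsAsFactors = FALSE),
                   FUN = sum)
}

collapse_reads <- function(reads) {
  if (is.data.frame(reads)) {
    stopifnot(all(c("sequence", "count") %in% names(reads)))
    return(reads[, c("sequence", "count")])
  }
  tb <- table(reads)
  data.frame(sequence = names(tb), count = as.integer(tb),
             stringsAsFactors = FALSE)
}
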