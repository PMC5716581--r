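#' Genome sequence container
#'
#' A minimal in-memory genome: a named set of contig sequences over the
#' alphabet A, C, G, T, N (uppercase). All positions used throughout the
#' package are 1-based and inclusive, matching HGVS g. notation and GFF3.
#'
#' @param contigs named character vector or list of nucleotide strings.
#' @return An object of class `genome_sequence`.
#' @examples
#' g <- genome_sequence(c(chr1 = "ACGTACGT"))
#' get_seq(g, "chr1", 2, 4)
#' @export
genome_sequence <- function(contigs) {
  contigs <- vapply(contigs, as.character, character(1))
  assert_that(length(contigs) > 0, "genome must contain at least one contig")
  assert_that(!is.null(names(contigs)) && all(nzchar(names(contigs))),
              "every contig needs a name")
  assert_that(!anyDuplicated(names(contigs)),
              "duplicate contig id: ",
              paste(names(contigs)[duplicated(names(contigs))], collapse = ", "))
  contigs <- toupper(contigs)
  for (id in names(contigs)) {
    assert_that(nzchar(contigs[[id]]), "contig '", id, "' is empty")
    bad <- setdiff(unique(chars(contigs[[id]])), DNA_ALPHABET)
    assert_that(length(bad) == 0,
                "contig '", id, "' contains invalid character(s): ",
                paste(bad, collapse = ", "))
  }
  structure(list(contigs = as.list(contigs)), class = "genome_sequence")
}

#' @export
print.genome_sequence <- function(x, ...) {
  cat("<genome_sequence> ", length(x$contigs), " contig(s)\n", sep = "")
  for (id in names(x$contigs)) {
    cat("  ", id, ": ", nchar(x$contigs[[id]]), " bp\n", sep = "")
  }
  invisible(x)
}

#' @export
names.genome_sequence <- function(x) names(x$contigs)

#' Extract a subsequence from a genome
#'
#' @param genome a [genome_sequence()].
#' @param contig contig id.
#' @param start,end 1-based inclusive positions.
#' @return A nucleotide string of exactly `end - start + 1` characters.
#' @export
get_seq <- function(genome, contig, start, end) {
  stopifnot(inherits(genome, "genome_sequence"))
  seq <- genome$contigs[[contig]]
  assert_that(!is.null(seq), "unknown contig: ", contig)
  assert_that(is_scalar_int(start) && is_scalar_int(end) && start <= end,
              "invalid range [", start, ", ", end, "]")
  assert_that(start >= 1 && end <= nchar(seq),
              "range [", start, ", ", end, "] out of bounds for contig '",
              contig, "' (length ", nchar(seq), ")")
  substr(seq, start, end)
}

#' @rdname get_seq
#' @export
contig_length <- function(genome, contig) {
  stopifnot(inherits(genome, "genome_sequence"))
  seq <- genome$contigs[[contig]]
  assert_that(!is.null(seq), "unknown contig: ", contig)
  nchar(seq)
}

#' Read a genome from a (possibly gzipped) FASTA file
#'
#' One entry per record; sequences are uppercased and the description after
#' the first whitespace is dropped from the contig id. Characters outside
#' A/C/G/T/N are rejected with an error naming the offender.
#'
#' @param path path to a FASTA file (plain or gzip).
#' @return A [genome_sequence()].
#' @export
read_genome_fasta <- function(path) {
  assert_that(file.exists(path), "file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) {
      stop("FASTA parse error in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  assert_that(length(set) > 0, "no FASTA records in '", path, "'")
  ids <- sub("\\s.*$", "", names(set))
  assert_that(!anyDuplicated(ids),
              "duplicate contig id in '", path, "': ",
              paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- as.character(set)
  names(seqs) <- ids
  genome_sequence(seqs)
}

#' Write a genome to a FASTA file
#'
#' @param genome a [genome_sequence()].
#' @param path output path (plain text).
#' @param width line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path, width = 70L) {
  stopifnot(inherits(genome, "genome_sequence"))
  set <- Biostrings::DNAStringSet(unlist(genome$contigs))
  Biostrings::writeXStringSet(set, filepath = path, width = width)
  invisible(path)
}

## Apply an edit at genome level; internal, used by apply_mutation().
#' @noRd
edit_contig <- function(genome, contig, start, end, replacement) {
  seq <- genome$contigs[[contig]]
  new <- paste0(
    if (start > 1) substr(seq, 1L, start - 1L) else "",
    replacement,
    if (end < nchar(seq)) substr(seq, end + 1L, nchar(seq)) else ""
  )
  genome$contigs[[contig]] <- new
  genome
}
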