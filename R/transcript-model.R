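#' Transcript model
#'
#' A gene's exon structure on a genomic contig. Exons are 1-based inclusive
#' genomic intervals stored in transcription order (ascending genomic
#' coordinate on `+`, descending on `-`), so "exon 2" is always the second
#' transcribed exon regardless of strand, matching the field's "exon 34",
#' "intron 33-34" nomenclature (intron k lies between exons k and k+1).
#' `cds_start`/`cds_end` are 1-based positions within the spliced mRNA and
#' span the start codon through the stop codon inclusive.
#'
#' @param gene_id,transcript_id identifiers.
#' @param contig contig id the model lives on.
#' @param strand `"+"` or `"-"`.
#' @param exons two-column matrix or data.frame of genomic `start`, `end`,
#'   in transcription order.
#' @param cds_start,cds_end CDS bounds in spliced-transcript coordinates.
#' @param strict when `TRUE` (default) the CDS length must be divisible by 3,
#'   as holds for wildtype models; internal edited models may relax this.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(gene_id, transcript_id, contig, strand,
                             exons, cds_start, cds_end, strict = TRUE) {
  strand <- match.arg(strand, c("+", "-"))
  exons <- as.matrix(exons)
  storage.mode(exons) <- "integer"
  assert_that(ncol(exons) == 2 && nrow(exons) >= 1,
              "exons must be an n x 2 matrix of start, end")
  colnames(exons) <- c("start", "end")
  assert_that(all(exons[, "start"] <= exons[, "end"]),
              "exon start must not exceed end")
  n <- nrow(exons)
  if (n > 1) {
    if (strand == "+") {
      gaps <- exons[-1, "start"] - exons[-n, "end"] - 1L
    } else {
      gaps <- exons[-n, "start"] - exons[-1, "end"] - 1L
    }
    assert_that(all(gaps >= 4),
                "introns must be >= 4 nt (room for GT...AG); found gap(s): ",
                paste(gaps[gaps < 4], collapse = ", "))
  }
  splen <- sum(exons[, "end"] - exons[, "start"] + 1L)
  assert_that(is_scalar_int(cds_start) && is_scalar_int(cds_end),
              "cds_start/cds_end must be integers")
  assert_that(cds_start >= 1 && cds_start <= cds_end && cds_end <= splen,
              "CDS bounds [", cds_start, ", ", cds_end,
              "] invalid for spliced length ", splen)
  if (strict) {
    assert_that((cds_end - cds_start + 1L) %% 3L == 0L,
                "CDS length not divisible by 3 (", cds_end - cds_start + 1L,
                " nt); use strict = FALSE for edited models")
  }
  structure(
    list(gene_id = as.character(gene_id),
         transcript_id = as.character(transcript_id),
         contig = as.character(contig), strand = strand, exons = exons,
         cds_start = as.integer(cds_start), cds_end = as.integer(cds_end)),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("<transcript_model> ", x$transcript_id, " (gene ", x$gene_id, ")\n",
      "  ", x$contig, ":", min(x$exons), "-", max(x$exons), " (", x$strand,
      "), ", n_exons(x), " exon(s), spliced ", spliced_length(x),
      " nt, CDS ", x$cds_start, "-", x$cds_end, "\n", sep = "")
  invisible(x)
}

#' Basic transcript accessors
#' @param model a [transcript_model()].
#' @return `n_exons`: exon count; `exon_lengths`: integer vector in
#'   transcription order; `spliced_length`: total mRNA length;
#'   `genomic_span`: c(min, max) genomic coordinates.
#' @export
n_exons <- function(model) nrow(model$exons)

#' @rdname n_exons
#' @export
exon_lengths <- function(model) {
  unname(model$exons[, "end"] - model$exons[, "start"] + 1L)
}

#' @rdname n_exons
#' @export
spliced_length <- function(model) sum(exon_lengths(model))

#' @rdname n_exons
#' @export
genomic_span <- function(model) c(min(model$exons), max(model$exons))

## Genomic interval of intron i (between exons i and i+1), plus the genomic
## coordinates of its donor-side first base and acceptor-side last base in
## transcript orientation.
#' @noRd
intron_bounds <- function(model, i) {
  n <- n_exons(model)
  assert_that(is_scalar_int(i) && i >= 1 && i <= n - 1,
              "intron index ", i, " out of range (1..", n - 1, ")")
  if (model$strand == "+") {
    lo <- unname(model$exons[i, "end"]) + 1L
    hi <- unname(model$exons[i + 1L, "start"]) - 1L
    list(lo = lo, hi = hi, donor_g = lo, acceptor_g = hi,
         length = hi - lo + 1L)
  } else {
    lo <- unname(model$exons[i + 1L, "end"]) + 1L
    hi <- unname(model$exons[i, "start"]) - 1L
    list(lo = lo, hi = hi, donor_g = hi, acceptor_g = lo,
         length = hi - lo + 1L)
  }
}

#' @rdname n_exons
#' @export
intron_lengths <- function(model) {
  n <- n_exons(model)
  if (n < 2) return(integer())
  vapply(seq_len(n - 1L), function(i) intron_bounds(model, i)$length,
         integer(1))
}

#' Map a genomic position into spliced-transcript coordinates
#'
#' @param model a [transcript_model()].
#' @param gpos genomic position (1-based).
#' @return The 1-based transcript position, or `NA` if `gpos` is intronic or
#'   outside the transcript.
#' @export
genomic_to_transcript <- function(model, gpos) {
  ex <- model$exons
  cum <- c(0L, cumsum(exon_lengths(model)))
  for (i in seq_len(nrow(ex))) {
    if (gpos >= ex[i, "start"] && gpos <= ex[i, "end"]) {
      off <- if (model$strand == "+") gpos - ex[i, "start"] + 1L
             else ex[i, "end"] - gpos + 1L
      return(unname(cum[i] + off))
    }
  }
  NA_integer_
}

#' Map a spliced-transcript position back to the genome
#'
#' @param model a [transcript_model()].
#' @param tpos 1-based transcript position.
#' @return The genomic position.
#' @export
transcript_to_genomic <- function(model, tpos) {
  assert_that(is_scalar_int(tpos) && tpos >= 1 && tpos <= spliced_length(model),
              "transcript position ", tpos, " out of range")
  cum <- c(0L, cumsum(exon_lengths(model)))
  i <- findInterval(tpos, cum + 1L)
  off <- tpos - cum[i]
  unname(if (model$strand == "+") model$exons[i, "start"] + off - 1L
         else model$exons[i, "end"] - off + 1L)
}

## Describe where a genomic position falls relative to the model: an exon
## (with exon index and transcript position), an intron (with index, offset
## from the donor side, and negative offset from the acceptor side), or
## outside the transcript span.
#' @noRd
locate_position <- function(model, gpos) {
  ex <- model$exons
  for (i in seq_len(nrow(ex))) {
    if (gpos >= ex[i, "start"] && gpos <= ex[i, "end"]) {
      return(list(region = "exon", exon_index = i,
                  tpos = genomic_to_transcript(model, gpos)))
    }
  }
  n <- n_exons(model)
  if (n > 1) {
    for (i in seq_len(n - 1L)) {
      b <- intron_bounds(model, i)
      if (gpos >= b$lo && gpos <= b$hi) {
        donor_off <- if (model$strand == "+") gpos - b$donor_g + 1L
                     else b$donor_g - gpos + 1L
        acceptor_off <- if (model$strand == "+") gpos - b$acceptor_g - 1L
                        else b$acceptor_g - gpos - 1L
        ## donor_off: 1 = first intron base; acceptor_off: -1 = last.
        return(list(region = "intron", intron_index = i,
                    donor_offset = donor_off, acceptor_offset = acceptor_off))
      }
    }
  }
  list(region = "outside")
}

#' Spliced mRNA and junction map of a transcript
#'
#' Concatenates exon sequences in transcription order (reverse-complemented
#' for minus-strand models). Junctions are the transcript positions of the
#' last base of each non-terminal exon: the final element is the "last
#' exon-exon junction" of the NMD 50-55 nt rule.
#'
#' @param model a [transcript_model()].
#' @param genome a [genome_sequence()].
#' @return A list with `mrna` (nucleotide string) and `junctions` (integer
#'   vector of length `n_exons - 1`; empty for single-exon models).
#' @export
spliced_sequence <- function(model, genome) {
  ex <- model$exons
  pieces <- character(nrow(ex))
  for (i in seq_len(nrow(ex))) {
    s <- get_seq(genome, model$contig, ex[i, "start"], ex[i, "end"])
    pieces[i] <- if (model$strand == "+") s else revcomp(s)
  }
  lens <- nchar(pieces)
  junctions <- if (length(lens) > 1) cumsum(lens)[-length(lens)] else integer()
  list(mrna = paste(pieces, collapse = ""), junctions = as.integer(junctions))
}

#' Sequence of intron k in transcript orientation
#'
#' Intron k lies between exons k and k+1. The first two characters of the
#' returned string are the donor dinucleotide (canonically GT) and the last
#' two the acceptor dinucleotide (canonically AG).
#'
#' @param model a [transcript_model()].
#' @param genome a [genome_sequence()].
#' @param intron_index intron number, 1-based in transcription order.
#' @return A nucleotide string.
#' @export
intron_sequence <- function(model, genome, intron_index) {
  b <- intron_bounds(model, intron_index)
  s <- get_seq(genome, model$contig, b$lo, b$hi)
  if (model$strand == "+") s else revcomp(s)
}

#' Check that every intron has canonical GT/AG ends
#'
#' @param model a [transcript_model()].
#' @param genome a [genome_sequence()].
#' @return A character vector of warnings, one per non-canonical site; empty
#'   when all introns are canonical.
#' @export
validate_splice_sites <- function(model, genome) {
  n <- n_exons(model)
  out <- character()
  if (n < 2) return(out)
  for (i in seq_len(n - 1L)) {
    s <- intron_sequence(model, genome, i)
    donor <- substr(s, 1L, 2L)
    acceptor <- substr(s, nchar(s) - 1L, nchar(s))
    if (donor != "GT") {
      out <- c(out, sprintf(
        "intron %d-%d of %s: non-canonical donor '%s' (expected GT)",
        i, i + 1L, model$transcript_id, donor))
    }
    if (acceptor != "AG") {
      out <- c(out, sprintf(
        "intron %d-%d of %s: non-canonical acceptor '%s' (expected AG)",
        i, i + 1L, model$transcript_id, acceptor))
    }
  }
  out
}
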