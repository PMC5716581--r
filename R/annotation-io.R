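## Annotation reading/writing. Parsing of GFF3/GTF is delegated to
## rtracklayer; this file only groups features into transcript_model objects
## and converts CDS features to spliced-transcript coordinates.

#' @noRd
detect_annotation_format <- function(path) {
  base <- sub("\\.(gz|bgz)$", "", path, ignore.case = TRUE)
  ext <- tolower(tools::file_ext(base))
  if (ext %in% c("gff", "gff3")) return("gff3")
  if (ext == "gtf") return("gtf")
  con <- gzfile(path, "rt")
  on.exit(close(con))
  lines <- readLines(con, n = 50L)
  if (any(grepl("^##gff-version\\s*3", lines))) return("gff3")
  feat <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (length(feat) && grepl("gene_id \"", feat[1], fixed = TRUE)) return("gtf")
  "gff3"
}

#' @noRd
first_or_na <- function(x) {
  x <- as.character(unlist(x))
  if (length(x) == 0 || is.na(x[1])) NA_character_ else x[1]
}

#' Read transcript models from a GFF3 or GTF annotation
#'
#' The dialect is auto-detected from the file extension or content. Exons
#' are grouped per transcript and sorted in transcription order; CDS
#' features are converted to spliced-transcript coordinates, so minus-strand
#' models behave identically to plus-strand ones downstream. Transcripts
#' with no exons are skipped with a warning; a CDS not contained in the
#' transcript's exons is an error.
#'
#' @param path path to a GFF3/GTF file (plain or gzip).
#' @param genome optional [genome_sequence()]; when supplied, exon bounds are
#'   checked against contig lengths.
#' @param require_cds when `TRUE` (default) transcripts without CDS features
#'   are skipped with a warning; when `FALSE` they are kept with a nominal
#'   CDS spanning the transcript (useful for pure exon-structure analyses).
#' @return A named list of [transcript_model()] objects (names are
#'   transcript ids).
#' @export
read_annotation <- function(path, genome = NULL, require_cds = TRUE) {
  assert_that(file.exists(path), "file not found: ", path)
  fmt <- detect_annotation_format(path)
  gr <- rtracklayer::import(path, format = fmt)
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)

  if (fmt == "gtf") {
    tx_of <- as.character(mc$transcript_id)
    gene_of <- as.character(mc$gene_id)
  } else {
    parent <- if ("Parent" %in% names(mc)) {
      vapply(mc$Parent, first_or_na, character(1))
    } else rep(NA_character_, length(gr))
    parent <- sub("^transcript:", "", parent)
    tx_of <- parent
    gene_of <- if ("gene_id" %in% names(mc)) as.character(mc$gene_id)
               else rep(NA_character_, length(gr))
    ## fall back to transcript-feature Parent for the gene id
    is_tx <- type %in% c("mRNA", "transcript")
    if (any(is_tx)) {
      ids <- as.character(mc$ID[is_tx])
      genes <- sub("^gene:", "",
                   vapply(mc$Parent[is_tx], first_or_na, character(1)))
      lookup <- stats::setNames(genes, ids)
      miss <- is.na(gene_of) & tx_of %in% names(lookup)
      gene_of[miss] <- lookup[tx_of[miss]]
    }
  }

  is_exon <- type == "exon"
  is_cds <- type == "CDS"
  tx_ids <- unique(stats::na.omit(tx_of[is_exon | is_cds]))
  models <- list()
  for (tid in tx_ids) {
    ex_i <- which(is_exon & tx_of == tid)
    if (length(ex_i) == 0) {
      warning("transcript '", tid, "' has zero exons; skipped", call. = FALSE)
      next
    }
    strand <- as.character(BiocGenerics::strand(gr[ex_i[1]]))
    if (!strand %in% c("+", "-")) strand <- "+"
    contig <- as.character(GenomicRanges::seqnames(gr[ex_i[1]]))
    starts <- BiocGenerics::start(gr[ex_i])
    ends <- BiocGenerics::end(gr[ex_i])
    ord <- if (strand == "+") order(starts) else order(starts,
                                                       decreasing = TRUE)
    exons <- cbind(start = starts[ord], end = ends[ord])
    if (!is.null(genome)) {
      assert_that(max(exons) <= contig_length(genome, contig),
                  "transcript '", tid, "': exon out of contig bounds")
    }
    gene <- gene_of[ex_i[1]]
    if (is.na(gene)) gene <- tid

    cds_i <- which(is_cds & tx_of == tid)
    splen <- sum(exons[, 2] - exons[, 1] + 1L)
    dummy <- transcript_model(gene, tid, contig, strand, exons,
                              1L, splen, strict = FALSE)
    if (length(cds_i) > 0) {
      c_start <- BiocGenerics::start(gr[cds_i])
      c_end <- BiocGenerics::end(gr[cds_i])
      t5 <- if (strand == "+") genomic_to_transcript(dummy, min(c_start))
            else genomic_to_transcript(dummy, max(c_end))
      t3 <- if (strand == "+") genomic_to_transcript(dummy, max(c_end))
            else genomic_to_transcript(dummy, min(c_start))
      assert_that(!is.na(t5) && !is.na(t3),
                  "transcript '", tid, "': CDS not contained in exons")
      ## every CDS base must be exonic
      cds_len <- sum(c_end - c_start + 1L)
      assert_that(cds_len == t3 - t5 + 1L,
                  "transcript '", tid, "': CDS not contained in exons")
      models[[tid]] <- transcript_model(gene, tid, contig, strand, exons,
                                        t5, t3, strict = FALSE)
    } else if (require_cds) {
      warning("transcript '", tid, "' has no CDS features; skipped",
              call. = FALSE)
    } else {
      models[[tid]] <- transcript_model(gene, tid, contig, strand, exons,
                                        1L, max(3L, splen - splen %% 3L),
                                        strict = FALSE)
    }
  }
  models
}

## Genomic intervals covered by the CDS, in transcription order.
#' @noRd
cds_genomic_intervals <- function(model) {
  cum <- c(0L, cumsum(exon_lengths(model)))
  out <- NULL
  for (i in seq_len(n_exons(model))) {
    t_lo <- max(model$cds_start, cum[i] + 1L)
    t_hi <- min(model$cds_end, cum[i + 1L])
    if (t_lo > t_hi) next
    g1 <- transcript_to_genomic(model, t_lo)
    g2 <- transcript_to_genomic(model, t_hi)
    out <- rbind(out, c(start = min(g1, g2), end = max(g1, g2)))
  }
  out
}

#' Write transcript models to a GFF3 file
#'
#' Emits mRNA, exon and CDS features with `ID`/`Parent` attributes such that
#' [read_annotation()] recovers a field-wise identical model set.
#'
#' @param models a list of [transcript_model()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(models, path) {
  if (inherits(models, "transcript_model")) models <- list(models)
  rows <- list()
  for (m in models) {
    span <- genomic_span(m)
    rows[[length(rows) + 1L]] <- data.frame(
      seqnames = m$contig, start = span[1], end = span[2], strand = m$strand,
      type = "mRNA", ID = m$transcript_id, Parent = NA_character_,
      gene_id = m$gene_id, phase = NA_integer_, stringsAsFactors = FALSE)
    for (i in seq_len(n_exons(m))) {
      rows[[length(rows) + 1L]] <- data.frame(
        seqnames = m$contig, start = m$exons[i, "start"],
        end = m$exons[i, "end"], strand = m$strand, type = "exon",
        ID = NA_character_, Parent = m$transcript_id, gene_id = m$gene_id,
        phase = NA_integer_, stringsAsFactors = FALSE)
    }
    cds <- cds_genomic_intervals(m)
    preceding <- 0L
    for (i in seq_len(nrow(cds))) {
      rows[[length(rows) + 1L]] <- data.frame(
        seqnames = m$contig, start = cds[i, "start"], end = cds[i, "end"],
        strand = m$strand, type = "CDS", ID = NA_character_,
        Parent = m$transcript_id, gene_id = m$gene_id,
        phase = (3L - preceding %% 3L) %% 3L,
        stringsAsFactors = FALSE)
      preceding <- preceding + cds[i, "end"] - cds[i, "start"] + 1L
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqnames,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = df$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- IRanges::CharacterList(
    lapply(df$Parent, function(p) if (is.na(p)) character() else p))
  S4Vectors::mcols(gr)$gene_id <- df$gene_id
  S4Vectors::mcols(gr)$phase <- df$phase
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}
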