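#' Construct a mutation
#'
#' A genomic edit: a single-base substitution or a small deletion. Positions
#' are 1-based inclusive; `start == end` for substitutions. `ref` may be
#' empty for deletions parsed from HGVS notation (the reference bases are
#' not part of the `del` form) and is then not checked on application.
#'
#' @param kind `"substitution"` or `"deletion"` (insertions are reserved).
#' @param start,end genomic positions.
#' @param ref,alt reference and alternate bases (`alt` empty for deletions).
#' @param contig optional contig id (usually supplied alongside the HGVS
#'   string, which does not carry one).
#' @return An object of class `mutation`.
#' @export
mutation <- function(kind, start, end, ref = "", alt = "",
                     contig = NA_character_) {
  kind <- match.arg(kind, c("substitution", "deletion", "insertion"))
  assert_that(is_scalar_int(start) && is_scalar_int(end),
              "start/end must be integers")
  assert_that(start >= 1 && end >= start,
              "invalid mutation span [", start, ", ", end, "] (end < start?)")
  if (kind == "substitution") {
    assert_that(start == end && nchar(ref) == 1 && nchar(alt) == 1,
                "substitutions are single-base: |ref| = |alt| = 1")
  }
  if (kind == "deletion") {
    assert_that(nchar(alt) == 0, "deletions carry no alt allele")
  }
  structure(list(kind = kind, contig = as.character(contig),
                 start = as.integer(start), end = as.integer(end),
                 ref = toupper(ref), alt = toupper(alt)),
            class = "mutation")
}

#' @export
print.mutation <- function(x, ...) {
  desc <- switch(x$kind,
    substitution = sprintf("g.%d%s>%s", x$start, x$ref, x$alt),
    deletion = if (x$start == x$end) sprintf("g.%ddel", x$start)
               else sprintf("g.%d_%ddel", x$start, x$end),
    sprintf("g.%d_%dins%s", x$start, x$end, x$alt))
  cat("<mutation> ", desc,
      if (!is.na(x$contig)) paste0(" on ", x$contig), "\n", sep = "")
  invisible(x)
}

#' @rdname mutation
#' @export
deletion_length <- function(mut) {
  stopifnot(inherits(mut, "mutation"))
  if (mut$kind != "deletion") return(0L)
  mut$end - mut$start + 1L
}

#' Parse an HGVS-like genomic variant description
#'
#' Supports the subset `g.<pos><REF>><ALT>` (substitution) and
#' `g.<start>_<end>del` / `g.<pos>del` (deletion). Other HGVS forms (dup,
#' ins, delins, ...) are rejected with an "unsupported notation" error.
#'
#' @param text e.g. `"g.3431G>A"` or `"g.6948_6955del"`.
#' @param contig optional contig id to attach.
#' @return A [mutation()].
#' @examples
#' parse_hgvs_g("g.3431G>A")
#' parse_hgvs_g("g.6948_6954del")
#' @export
parse_hgvs_g <- function(text, contig = NA_character_) {
  assert_that(is.character(text) && length(text) == 1,
              "expected a single HGVS string")
  text <- trimws(text)
  m <- regmatches(text, regexec("^g\\.([0-9]+)([ACGTacgt])>([ACGTacgt])$",
                                text))[[1]]
  if (length(m) == 4) {
    pos <- as.integer(m[2])
    return(mutation("substitution", pos, pos, ref = m[3], alt = m[4],
                    contig = contig))
  }
  m <- regmatches(text, regexec("^g\\.([0-9]+)_([0-9]+)del$", text))[[1]]
  if (length(m) == 3) {
    s <- as.integer(m[2]); e <- as.integer(m[3])
    assert_that(e >= s, "invalid deletion span in '", text, "': end < start")
    return(mutation("deletion", s, e, contig = contig))
  }
  m <- regmatches(text, regexec("^g\\.([0-9]+)del$", text))[[1]]
  if (length(m) == 2) {
    pos <- as.integer(m[2])
    return(mutation("deletion", pos, pos, contig = contig))
  }
  if (grepl("(dup|ins|delins|inv)", text)) {
    stop("unsupported notation: '", text,
         "' (only g.<pos>REF>ALT and g.<start>_<end>del are supported)",
         call. = FALSE)
  }
  stop("cannot parse HGVS g. string: '", text, "'", call. = FALSE)
}

#' Apply a mutation to a genome
#'
#' For substitutions the reference base is verified against the genome and a
#' mismatch is an error (so applying the same substitution twice fails on
#' the second attempt). Deletions shorten the contig by the deleted length;
#' use [lift_model()] to shift annotation coordinates accordingly.
#'
#' @param genome a [genome_sequence()].
#' @param mut a [mutation()] with a resolvable contig (either in the object
#'   or via `contig`).
#' @param contig contig override when the mutation carries none.
#' @return The edited [genome_sequence()].
#' @export
apply_mutation <- function(genome, mut, contig = NULL) {
  stopifnot(inherits(genome, "genome_sequence"), inherits(mut, "mutation"))
  ctg <- contig %||% mut$contig
  assert_that(!is.na(ctg), "mutation has no contig; supply one")
  found <- get_seq(genome, ctg, mut$start, mut$end)
  if (nzchar(mut$ref)) {
    assert_that(found == mut$ref,
                "reference mismatch at ", ctg, ":", mut$start,
                " (expected '", mut$ref, "', found '", found, "')")
  }
  replacement <- switch(mut$kind,
    substitution = mut$alt,
    deletion = "",
    stop("insertions are not supported", call. = FALSE))
  edit_contig(genome, ctg, mut$start, mut$end, replacement)
}

#' Lift a genomic position across a mutation
#'
#' Positions strictly downstream of a deletion shift left by the deleted
#' length; positions inside the deleted interval return `NA`.
#'
#' @param mut a [mutation()].
#' @param pos genomic position on the unmutated genome.
#' @return The corresponding position on the mutated genome.
#' @export
lift_position <- function(mut, pos) {
  stopifnot(inherits(mut, "mutation"))
  if (mut$kind != "deletion") return(pos)
  len <- deletion_length(mut)
  ifelse(pos < mut$start, pos,
         ifelse(pos > mut$end, pos - len, NA_integer_))
}

#' Lift a transcript model across a mutation
#'
#' Exon boundaries strictly downstream of a deletion shift left by the
#' deletion length, and the CDS bounds shrink by the number of deleted
#' coding bases. A deletion overlapping an exon boundary (or an essential
#' splice-site dinucleotide) is rejected as unsupported.
#'
#' @param model a [transcript_model()].
#' @param mut a [mutation()].
#' @return A [transcript_model()] aligned to the mutated genome (built with
#'   `strict = FALSE`: a frameshifting deletion leaves a CDS whose length is
#'   not divisible by 3).
#' @export
lift_model <- function(model, mut) {
  stopifnot(inherits(model, "transcript_model"), inherits(mut, "mutation"))
  if (mut$kind != "deletion") return(model)
  len <- deletion_length(mut)
  ex <- model$exons
  inside <- function(lo, hi) mut$start >= lo && mut$end <= hi
  overlaps <- function(lo, hi) mut$end >= lo && mut$start <= hi
  hit_exon <- which(vapply(seq_len(nrow(ex)), function(i)
    overlaps(ex[i, "start"], ex[i, "end"]), logical(1)))
  if (length(hit_exon) > 0) {
    assert_that(length(hit_exon) == 1 &&
                  inside(ex[hit_exon, "start"], ex[hit_exon, "end"]),
                "deletion overlaps an exon boundary; unsupported")
  } else {
    ## fully intronic: must not touch the ESS dinucleotides
    for (i in seq_len(n_exons(model) - 1L)) {
      b <- intron_bounds(model, i)
      if (overlaps(b$lo, b$hi)) {
        ess <- c(b$donor_g,
                 b$donor_g + if (model$strand == "+") 1L else -1L,
                 b$acceptor_g,
                 b$acceptor_g - if (model$strand == "+") 1L else -1L)
        assert_that(!any(ess >= mut$start & ess <= mut$end),
                    "deletion removes an essential splice-site dinucleotide; ",
                    "unsupported")
      }
    }
  }
  cds_start <- model$cds_start
  cds_end <- model$cds_end
  if (length(hit_exon) == 1) {
    ## transcript-coordinate span of the deleted bases
    ta <- genomic_to_transcript(model, mut$start)
    tb <- genomic_to_transcript(model, mut$end)
    t1 <- min(ta, tb); t2 <- max(ta, tb)
    del_before_cds <- max(0L, min(t2, cds_start - 1L) - t1 + 1L)
    coding_del <- max(0L, min(t2, cds_end) - max(t1, cds_start) + 1L)
    cds_start <- cds_start - del_before_cds
    cds_end <- cds_end - del_before_cds - coding_del
  }
  ex[, "start"] <- ifelse(ex[, "start"] > mut$end, ex[, "start"] - len,
                          ex[, "start"])
  ex[, "end"] <- ifelse(ex[, "end"] > mut$end, ex[, "end"] - len,
                        ex[, "end"])
  transcript_model(model$gene_id, model$transcript_id, model$contig,
                   model$strand, ex, cds_start, cds_end, strict = FALSE)
}

#' Classify a mutation relative to a transcript
#'
#' Intron positions +1/+2 (donor GT) give `ESS_donor`, positions -2/-1
#' (acceptor AG) give `ESS_acceptor`. Exonic substitutions are compared
#' codon-wise in the transcript's wildtype reading frame (`exonic_nonsense`
#' when the mutant codon is a stop and the wildtype codon is not). Exonic
#' deletions are `exonic_indel_frameshift` unless their length is divisible
#' by 3.
#'
#' @param model a [transcript_model()].
#' @param genome the wildtype [genome_sequence()].
#' @param mut a [mutation()] lying within the transcript's genomic span.
#' @return An object of class `mutation_classification` with fields
#'   `category`, `affected_intron_index`, `affected_exon_index`,
#'   `codon_change` and the `mutation` itself.
#' @export
classify_mutation <- function(model, genome, mut) {
  stopifnot(inherits(model, "transcript_model"), inherits(mut, "mutation"))
  span <- genomic_span(model)
  assert_that(mut$start >= span[1] && mut$end <= span[2],
              "mutation at ", mut$start, " lies outside the transcript span [",
              span[1], ", ", span[2], "]")
  res <- list(category = NA_character_, affected_intron_index = NA_integer_,
              affected_exon_index = NA_integer_, codon_change = NULL,
              mutation = mut)

  if (mut$kind == "substitution") {
    loc <- locate_position(model, mut$start)
    if (loc$region == "intron") {
      res$affected_intron_index <- loc$intron_index
      res$category <- if (loc$donor_offset %in% c(1L, 2L)) "ESS_donor"
        else if (loc$acceptor_offset %in% c(-1L, -2L)) "ESS_acceptor"
        else "intronic_other"
    } else {
      res$affected_exon_index <- loc$exon_index
      tpos <- loc$tpos
      if (tpos < model$cds_start || tpos > model$cds_end) {
        res$category <- "utr"
      } else {
        sp <- spliced_sequence(model, genome)
        ci <- (tpos - model$cds_start) %/% 3L
        cstart <- model$cds_start + 3L * ci
        wt_codon <- substr(sp$mrna, cstart, cstart + 2L)
        alt_t <- if (model$strand == "+") mut$alt else comp_base(mut$alt)
        mut_chars <- chars(wt_codon)
        mut_chars[tpos - cstart + 1L] <- alt_t
        mut_codon <- paste(mut_chars, collapse = "")
        res$codon_change <- c(wt = wt_codon, mut = mut_codon)
        res$category <-
          if (mut_codon %in% STOP_CODONS && !(wt_codon %in% STOP_CODONS)) {
            "exonic_nonsense"
          } else if (translate_codon(wt_codon) == translate_codon(mut_codon)) {
            "exonic_silent"
          } else {
            "exonic_missense"
          }
      }
    }
  } else if (mut$kind == "deletion") {
    ex <- model$exons
    hit <- which(vapply(seq_len(nrow(ex)), function(i)
      mut$end >= ex[i, "start"] && mut$start <= ex[i, "end"], logical(1)))
    if (length(hit) == 0) {
      loc1 <- locate_position(model, mut$start)
      loc2 <- locate_position(model, mut$end)
      if (loc1$region == "intron" && loc2$region == "intron" &&
          loc1$intron_index == loc2$intron_index) {
        res$affected_intron_index <- loc1$intron_index
        ess_hit <- min(loc1$donor_offset, loc2$donor_offset) <= 2L ||
          max(loc1$acceptor_offset, loc2$acceptor_offset) >= -2L
        assert_that(!ess_hit,
                    "deletion removes an essential splice-site dinucleotide; ",
                    "unsupported")
        res$category <- "intronic_other"
      } else {
        stop("deletion outside exons and introns of the transcript",
             call. = FALSE)
      }
    } else {
      assert_that(length(hit) == 1 &&
                    mut$start >= ex[hit, "start"] && mut$end <= ex[hit, "end"],
                  "deletion overlaps an exon boundary; unsupported")
      res$affected_exon_index <- hit
      res$category <- if (deletion_length(mut) %% 3L == 0L)
        "exonic_indel_inframe" else "exonic_indel_frameshift"
    }
  } else {
    stop("insertions are not supported", call. = FALSE)
  }
  structure(res, class = "mutation_classification")
}

#' @export
print.mutation_classification <- function(x, ...) {
  cat("<mutation_classification> ", x$category, sep = "")
  if (!is.na(x$affected_intron_index)) {
    cat(" (intron ", x$affected_intron_index, "-",
        x$affected_intron_index + 1L, ")", sep = "")
  }
  if (!is.na(x$affected_exon_index)) {
    cat(" (exon ", x$affected_exon_index, ")", sep = "")
  }
  if (!is.null(x$codon_change)) {
    cat(" ", x$codon_change[["wt"]], "->", x$codon_change[["mut"]], sep = "")
  }
  cat("\n")
  invisible(x)
}
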