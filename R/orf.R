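#' NMD classifier parameters
#'
#' Nonsense-mediated decay cannot act on a premature termination codon (PTC)
#' that lies in the last exon or within roughly 50-55 nt upstream of the
#' last exon-exon junction. The default threshold is 55 nt, the upper end of
#' that range, so junction-adjacent PTCs are robustly called escape; values
#' outside 50-55 are accepted with a warning.
#'
#' @param escape_threshold_nt escape distance in nucleotides.
#' @return An object of class `nmd_params`.
#' @export
nmd_params <- function(escape_threshold_nt = 55L) {
  assert_that(is_scalar_int(escape_threshold_nt) && escape_threshold_nt >= 0,
              "escape_threshold_nt must be a non-negative integer")
  if (escape_threshold_nt < 50 || escape_threshold_nt > 55) {
    warning("escape_threshold_nt = ", escape_threshold_nt,
            " is outside the standard 50-55 nt range", call. = FALSE)
  }
  structure(list(escape_threshold_nt = as.integer(escape_threshold_nt)),
            class = "nmd_params")
}

#' Classify a PTC as NMD-degraded or NMD-escaping
#'
#' Escape iff the PTC lies downstream of the last exon-exon junction (i.e.
#' in the terminal exon) or within `escape_threshold_nt` upstream of it;
#' degraded otherwise. Single-exon transcripts (no junctions) always escape.
#'
#' @param ptc_pos 1-based transcript position of the first base of the
#'   premature stop codon.
#' @param junctions integer vector of junction positions (the `junctions`
#'   element of [spliced_sequence()]).
#' @param params an [nmd_params()].
#' @return `"escape"` or `"degraded"`.
#' @export
classify_nmd <- function(ptc_pos, junctions, params = nmd_params()) {
  assert_that(is_scalar_int(ptc_pos) && ptc_pos >= 1, "invalid ptc_pos")
  if (length(junctions) == 0) return("escape")
  dist <- max(junctions) - ptc_pos
  if (dist <= params$escape_threshold_nt) "escape" else "degraded"
}

## Translate an mRNA from a start position to the first in-frame stop.
## Returns the protein (without the stop), the transcript position of the
## stop codon's first base (NA when no stop is reached) and a no_stop flag.
#' @noRd
translate_orf <- function(mrna, start) {
  n <- nchar(mrna)
  avail <- n - start + 1L
  n_codons <- avail %/% 3L
  if (n_codons < 1L) {
    return(list(protein = "", stop_tpos = NA_integer_, no_stop = TRUE))
  }
  cds <- substr(mrna, start, start + 3L * n_codons - 1L)
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(cds), if.fuzzy.codon = "X",
    no.init.codon = TRUE))
  stop_at <- regexpr("*", aa, fixed = TRUE)
  if (stop_at > 0) {
    list(protein = substr(aa, 1L, stop_at - 1L),
         stop_tpos = start + 3L * (as.integer(stop_at) - 1L),
         no_stop = FALSE)
  } else {
    list(protein = aa, stop_tpos = NA_integer_, no_stop = TRUE)
  }
}

#' Wildtype ORF reference for a transcript
#'
#' Computes the spliced mRNA, junction map, wildtype protein and the genomic
#' anchors (first base of the start codon, first base of the stop codon)
#' against which mutant outcomes are compared.
#'
#' @param model a [transcript_model()].
#' @param genome the wildtype [genome_sequence()].
#' @return An object of class `orf_reference`.
#' @export
orf_reference <- function(model, genome) {
  sp <- spliced_sequence(model, genome)
  tr <- translate_orf(sp$mrna, model$cds_start)
  stop_tpos <- model$cds_end - 2L
  structure(list(
    model = model, mrna = sp$mrna, junctions = sp$junctions,
    protein = tr$protein,
    cds_start_g = transcript_to_genomic(model, model$cds_start),
    stop_g = transcript_to_genomic(model, stop_tpos),
    stop_tpos = stop_tpos), class = "orf_reference")
}

#' Compare two proteins by longest common prefix/suffix
#'
#' Decomposes wildtype and mutant proteins into a shared prefix, a shared
#' suffix, and removed/gained middles. The protein-level frame call is
#' `"maintained"` when no novel residues are gained (pure deletion or
#' truncation) and `"frameshift"` otherwise; [consequence()] refines this
#' with coding-length arithmetic.
#'
#' @param wt_protein,mut_protein amino-acid strings.
#' @return A list with `aa_removed`, `aa_gained`, `removed_residues` (the
#'   removed residue identities when 1-3 residues are removed, else `NA`),
#'   `frame_status`, and the `lcp`/`lcs` lengths.
#' @export
diff_protein <- function(wt_protein, mut_protein) {
  w <- chars(wt_protein)
  m <- chars(mut_protein)
  nmin <- min(length(w), length(m))
  lcp <- 0L
  while (lcp < nmin && w[lcp + 1L] == m[lcp + 1L]) lcp <- lcp + 1L
  lcs <- 0L
  while (lcs < nmin - lcp &&
         w[length(w) - lcs] == m[length(m) - lcs]) lcs <- lcs + 1L
  aa_removed <- length(w) - lcp - lcs
  aa_gained <- length(m) - lcp - lcs
  removed_residues <- if (aa_removed >= 1 && aa_removed <= 3) {
    paste(w[(lcp + 1L):(lcp + aa_removed)], collapse = "")
  } else NA_character_
  list(aa_removed = aa_removed, aa_gained = aa_gained,
       removed_residues = removed_residues,
       frame_status = if (aa_gained == 0L) "maintained" else "frameshift",
       lcp = lcp, lcs = lcs)
}

## Net change in coding nucleotides between the (lifted) wildtype exon
## structure and an outcome's exon structure, restricted to the CDS span,
## plus the mutation's own exonic indel contribution. The result mod 3
## decides frame status deterministically.
#' @noRd
coding_delta <- function(model, outcome, mutation = NULL) {
  ir_wt <- IRanges::IRanges(model$exons[, "start"], model$exons[, "end"])
  mod <- outcome$modified_exons
  ir_mut <- IRanges::IRanges(mod[, "start"], mod[, "end"])
  cds <- cds_genomic_intervals(model)
  ir_cds <- IRanges::IRanges(cds[, "start"], cds[, "end"])
  cds_span <- IRanges::IRanges(min(cds), max(cds))
  removed <- IRanges::setdiff(ir_wt, ir_mut)
  added <- IRanges::setdiff(ir_mut, ir_wt)
  removed_coding <- sum(IRanges::width(IRanges::intersect(removed, ir_cds)))
  ## bases newly included (intronic retention/extension) count as coding when
  ## they fall inside the genomic CDS span: they are transcribed in frame
  ## ahead of the wildtype stop.
  added_coding <- sum(IRanges::width(IRanges::intersect(added, cds_span)))
  mut_del <- 0L
  if (!is.null(mutation) && inherits(mutation, "mutation") &&
      mutation$kind == "deletion") {
    ## the model passed here is already lifted; reconstruct the deleted
    ## coding length from the deletion span itself (fully exonic by the
    ## lift_model contract when it touched an exon).
    mut_del <- attr(mutation, "coding_del") %||% deletion_length(mutation)
  }
  as.integer(added_coding - removed_coding - mut_del)
}

#' Derive the ORF consequence of a splice outcome
#'
#' Rebuilds the mature mRNA from the outcome's exon structure on the mutated
#' genome, re-maps the wildtype start codon onto it, translates with the
#' standard genetic code, locates a premature termination codon (the first
#' in-frame stop strictly upstream of the wildtype stop), and applies the
#' NMD last-junction rule. When the outcome removes the start codon the
#' consequence is flagged `start_lost` (no downstream-start rescue is
#' attempted). `no_rescue` outcomes carry no ORF prediction: they are
#' reported as reduced with a caveat flag.
#'
#' @param outcome a `splice_outcome`.
#' @param model the [transcript_model()] aligned to `mutated_genome`
#'   ([lift_model()] result for deletions).
#' @param mutated_genome the genome after [apply_mutation()].
#' @param wildtype an [orf_reference()] built from the unmutated model and
#'   genome.
#' @param params an [nmd_params()].
#' @param mutation the applied [mutation()] (needed to lift genomic anchors
#'   across deletions and to account for the indel's own frame effect).
#' @return An object of class `orf_consequence`.
#' @export
consequence <- function(outcome, model, mutated_genome, wildtype,
                        params = nmd_params(), mutation = NULL) {
  stopifnot(inherits(outcome, "splice_outcome"),
            inherits(wildtype, "orf_reference"))
  flags <- "pseudo_exon_not_evaluated"
  base <- function(...) {
    structure(list(mature_mrna = NA_character_, protein = "",
                   frame_status = NA_character_, novel_orf_aa = NA_integer_,
                   ptc_transcript_pos = NA_integer_,
                   ptc_distance_to_last_junction = NA_integer_,
                   nmd_predicted = "not_applicable", aa_removed = NA_integer_,
                   aa_gained = NA_integer_, removed_residues = NA_character_,
                   transcript_level_class = "WT_like", outcome = outcome,
                   flags = flags, ...), class = "orf_consequence")
  }

  if (outcome$kind == "no_rescue") {
    res <- base()
    res$flags <- c(flags, "no_rescue")
    res$transcript_level_class <- "reduced"
    return(res)
  }

  mut_model <- transcript_model(
    model$gene_id, model$transcript_id, model$contig, model$strand,
    outcome$modified_exons, 1L, 3L, strict = FALSE)
  sp <- spliced_sequence(mut_model, mutated_genome)

  start_g <- if (is.null(mutation)) wildtype$cds_start_g
             else lift_position(mutation, wildtype$cds_start_g)
  t_start <- if (is.na(start_g)) NA_integer_
             else genomic_to_transcript(mut_model, start_g)
  if (is.na(t_start)) {
    res <- base()
    res$mature_mrna <- sp$mrna
    res$flags <- c(flags, "start_lost")
    return(res)
  }

  tr <- translate_orf(sp$mrna, t_start)
  stop_g <- if (is.null(mutation)) wildtype$stop_g
            else lift_position(mutation, wildtype$stop_g)
  t_wt_stop <- if (is.na(stop_g)) NA_integer_
               else genomic_to_transcript(mut_model, stop_g)

  is_ptc <- !tr$no_stop &&
    (is.na(t_wt_stop) || tr$stop_tpos < t_wt_stop)
  if (tr$no_stop) flags <- c(flags, "no_stop_found")

  dp <- diff_protein(wildtype$protein, tr$protein)
  cdelta <- coding_delta(model, outcome, mutation)
  frame_status <- if (cdelta %% 3L == 0L) "maintained" else "frameshift"

  ptc_pos <- if (is_ptc) tr$stop_tpos else NA_integer_
  ptc_dist <- if (is_ptc && length(sp$junctions) > 0) {
    max(sp$junctions) - ptc_pos
  } else NA_integer_
  nmd <- if (!is_ptc) "not_applicable"
         else classify_nmd(ptc_pos, sp$junctions, params)

  structure(list(
    mature_mrna = sp$mrna, protein = tr$protein,
    frame_status = frame_status,
    novel_orf_aa = if (frame_status == "frameshift") {
      ## residues translated beyond the point of divergence from wildtype
      nchar(tr$protein) - dp$lcp
    } else 0L,
    ptc_transcript_pos = ptc_pos,
    ptc_distance_to_last_junction = ptc_dist,
    nmd_predicted = nmd,
    aa_removed = dp$aa_removed, aa_gained = dp$aa_gained,
    removed_residues = dp$removed_residues,
    transcript_level_class = if (identical(nmd, "degraded")) "reduced"
                             else "WT_like",
    outcome = outcome, flags = flags,
    diff = dp), class = "orf_consequence")
}

#' @export
print.orf_consequence <- function(x, ...) {
  cat("<orf_consequence> ", x$outcome$kind, ": frame ",
      x$frame_status %||% "NA",
      ", PTC ", if (is.na(x$ptc_transcript_pos)) "none"
                else paste0("at ", x$ptc_transcript_pos,
                            " (", x$ptc_distance_to_last_junction,
                            " nt from last junction)"),
      ", NMD ", x$nmd_predicted,
      ", class ", x$transcript_level_class, "\n", sep = "")
  invisible(x)
}

#' Wildtype residues contributed by one exon that a mutant protein lacks
#'
#' Counts the wildtype residues whose codon *starts* inside the given exon
#' and that are absent from the mutant protein (not part of the common
#' prefix/suffix shared with wildtype). Used e.g. to quantify the loss of a
#' terminal exon's coding content after an upstream frameshift.
#'
#' @param wildtype an [orf_reference()].
#' @param cons an `orf_consequence`.
#' @param exon_index exon of interest, 1-based in transcription order.
#' @return Integer count of missing residues.
#' @export
exon_aa_missing <- function(wildtype, cons, exon_index) {
  model <- wildtype$model
  cum <- c(0L, cumsum(exon_lengths(model)))
  t_lo <- cum[exon_index] + 1L
  t_hi <- cum[exon_index + 1L]
  n_aa <- nchar(wildtype$protein)
  codon_start <- model$cds_start + 3L * (seq_len(n_aa) - 1L)
  in_exon <- which(codon_start >= t_lo & codon_start <= t_hi)
  dp <- diff_protein(wildtype$protein, cons$protein)
  preserved <- in_exon <= dp$lcp | in_exon > n_aa - dp$lcs
  sum(!preserved)
}
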