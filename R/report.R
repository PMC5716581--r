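#' Run the full prediction pipeline for one mutation
#'
#' Classifies the mutation, applies it to the genome, enumerates candidate
#' processing outcomes, evaluates the ORF/NMD consequence of each, and
#' (when ESE matrices are supplied and the mutation is an exonic
#' substitution) annotates whether the lesion falls inside a predicted
#' exonic splice enhancer. The result mirrors a per-line summary table: one
#' row per outcome with a generated outcome phrase and a predicted
#' transcript-level class.
#'
#' @param genome the wildtype [genome_sequence()].
#' @param model a [transcript_model()].
#' @param mut a [mutation()] or HGVS string (e.g. `"g.3431G>A"`).
#' @param params a [scan_params()].
#' @param nmd an [nmd_params()].
#' @param ese_matrices optional list of [ese_matrix()] objects.
#' @return An object of class `prediction_report`.
#' @export
predict_outcomes <- function(genome, model, mut, params = scan_params(),
                             nmd = nmd_params(), ese_matrices = NULL) {
  if (is.character(mut)) mut <- parse_hgvs_g(mut, contig = model$contig)
  classification <- classify_mutation(model, genome, mut)
  mutated <- apply_mutation(genome, mut, contig = model$contig)
  lifted <- lift_model(model, mut)
  wildtype <- orf_reference(model, genome)
  outcomes <- enumerate_outcomes(lifted, mutated, classification, params)
  consequences <- lapply(outcomes, consequence, model = lifted,
                         mutated_genome = mutated, wildtype = wildtype,
                         params = nmd, mutation = mut)

  ese <- NULL
  if (!is.null(ese_matrices) &&
      classification$category %in% c("exonic_nonsense", "exonic_missense",
                                     "exonic_silent")) {
    k <- classification$affected_exon_index
    ex <- model$exons[k, , drop = FALSE]
    wt_seq <- get_seq(genome, model$contig, ex[1, "start"], ex[1, "end"])
    mut_seq <- get_seq(mutated, model$contig, ex[1, "start"], ex[1, "end"])
    if (model$strand == "-") {
      wt_seq <- revcomp(wt_seq)
      mut_seq <- revcomp(mut_seq)
    }
    off <- if (model$strand == "+") mut$start - ex[1, "start"] + 1L
           else ex[1, "end"] - mut$start + 1L
    ese <- mutation_in_ese(wt_seq, mut_seq, off, ese_matrices)
    ese$exon_index <- k
  }

  structure(list(
    transcript_id = model$transcript_id, gene_id = model$gene_id,
    mutation = mut, classification = classification,
    outcomes = outcomes, consequences = consequences, ese = ese,
    wildtype = wildtype), class = "prediction_report")
}

## Residue one-letter -> full-name lookup for report phrases.
#' @noRd
AA_NAMES <- c(A = "Alanine", R = "Arginine", N = "Asparagine",
              D = "Aspartate", C = "Cysteine", Q = "Glutamine",
              E = "Glutamate", G = "Glycine", H = "Histidine",
              I = "Isoleucine", L = "Leucine", K = "Lysine",
              M = "Methionine", F = "Phenylalanine", P = "Proline",
              S = "Serine", T = "Threonine", W = "Tryptophan",
              Y = "Tyrosine", V = "Valine")

## Deterministic outcome phrase, templated on the structured fields only.
#' @noRd
outcome_phrase <- function(outcome, cons) {
  frame_txt <- if (identical(cons$frame_status, "maintained")) {
    "frame maintained"
  } else "frame shift"
  ptc_txt <- if (!is.na(cons$ptc_transcript_pos)) ", PTC" else ""
  if ("start_lost" %in% cons$flags) return("start codon lost")
  switch(outcome$kind,
    exon_skip = sprintf("skipped exon (%d bp), %s%s", abs(outcome$delta_nt),
                        frame_txt, ptc_txt),
    no_rescue = "terminal-exon acceptor lost, no rescue enumerated",
    cryptic_donor = ,
    cryptic_acceptor = {
      dirn <- if (outcome$site_offset > 0) "downstream" else "upstream"
      loss <- if (!is.na(cons$aa_removed) && cons$aa_removed >= 1 &&
                  cons$aa_removed <= 3 && !is.na(cons$removed_residues) &&
                  identical(cons$frame_status, "maintained")) {
        nm <- AA_NAMES[chars(cons$removed_residues)]
        if (cons$aa_removed == 1) {
          sprintf(", loss of single %s", nm)
        } else {
          sprintf(", loss of %s", paste(nm, collapse = "+"))
        }
      } else ""
      sprintf("%s cryptic splice site used%s, %s%s", dirn, loss, frame_txt,
              ptc_txt)
    },
    intron_retention = sprintf("intron retained (%d bp), %s%s",
                               outcome$delta_nt, frame_txt, ptc_txt),
    unspliced_ptc = if (nzchar(outcome$note) &&
                        startsWith(outcome$note, "splice")) {
      sprintf("(deletion) %s%s", frame_txt, ptc_txt)
    } else {
      sprintf("nonsense codon retained, %s%s", frame_txt, ptc_txt)
    },
    outcome$kind)
}

#' Tabulate a prediction report
#'
#' @param x a `prediction_report`.
#' @param row.names,optional,... standard [as.data.frame()] arguments
#'   (unused).
#' @return A data.frame with one row per outcome: rank, kind, delta_nt,
#'   site_offset, frame_status, PTC fields, NMD call, phrase, predicted
#'   transcript-level class and caveat flags.
#' @export
as.data.frame.prediction_report <- function(x, row.names = NULL,
                                            optional = FALSE, ...) {
  rows <- lapply(seq_along(x$outcomes), function(i) {
    o <- x$outcomes[[i]]
    cn <- x$consequences[[i]]
    data.frame(
      transcript_id = x$transcript_id,
      mutation = format_hgvs(x$mutation),
      category = x$classification$category,
      rank = o$rank, kind = o$kind, delta_nt = o$delta_nt,
      site_offset = o$site_offset,
      frame_status = cn$frame_status %||% NA_character_,
      aa_removed = cn$aa_removed, aa_gained = cn$aa_gained,
      removed_residues = cn$removed_residues,
      ptc_transcript_pos = cn$ptc_transcript_pos,
      ptc_distance_to_last_junction = cn$ptc_distance_to_last_junction,
      nmd_predicted = cn$nmd_predicted,
      outcome_phrase = outcome_phrase(o, cn),
      transcript_level_class = sub("_", "-", cn$transcript_level_class),
      in_ese = if (is.null(x$ese)) NA else x$ese$in_ese,
      flags = paste(cn$flags, collapse = ";"),
      stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  df
}

#' @noRd
format_hgvs <- function(mut) {
  switch(mut$kind,
    substitution = sprintf("g.%d%s>%s", mut$start, mut$ref, mut$alt),
    deletion = if (mut$start == mut$end) sprintf("g.%ddel", mut$start)
               else sprintf("g.%d_%ddel", mut$start, mut$end),
    sprintf("g.%d_%dins", mut$start, mut$end))
}

#' @export
print.prediction_report <- function(x, ...) {
  cat("<prediction_report> ", x$transcript_id, " ",
      format_hgvs(x$mutation), " [", x$classification$category, "]\n",
      sep = "")
  df <- as.data.frame(x)
  print.data.frame(df[, c("rank", "kind", "delta_nt", "frame_status",
                          "nmd_predicted", "outcome_phrase",
                          "transcript_level_class")], row.names = FALSE)
  if (!is.null(x$ese)) {
    cat("ESE: mutation ", if (x$ese$in_ese) "inside" else "outside",
        " a predicted enhancer (", nrow(x$ese$lost_hits),
        " hit(s) lost)\n", sep = "")
  }
  cat("note: pseudo-exon outcomes not evaluated\n")
  invisible(x)
}

#' Write a prediction report as TSV and/or JSON
#'
#' The two renderings carry identical structured values.
#'
#' @param report a `prediction_report`.
#' @param tsv,json output paths (`NULL` to skip either).
#' @return The report, invisibly.
#' @export
write_report <- function(report, tsv = NULL, json = NULL) {
  stopifnot(inherits(report, "prediction_report"))
  df <- as.data.frame(report)
  if (!is.null(tsv)) {
    utils::write.table(df, tsv, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(df, json, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA, na = "null")
  }
  invisible(report)
}

#' Batch prediction over a mutations table
#'
#' Runs [predict_outcomes()] per row of a table with columns `contig`,
#' `transcript_id`, `hgvs_g`. Per-row failures do not abort the batch: the
#' returned table carries a `status` column (`ok` or the error message).
#'
#' @param genome a [genome_sequence()].
#' @param models named list of [transcript_model()] objects.
#' @param mutations data.frame (or TSV path) with the three columns above.
#' @param ... passed to [predict_outcomes()].
#' @return A data.frame: the row-bound per-outcome tables plus `status`.
#' @export
predict_batch <- function(genome, models, mutations, ...) {
  if (is.character(mutations)) {
    mutations <- utils::read.delim(mutations, stringsAsFactors = FALSE)
  }
  need <- c("contig", "transcript_id", "hgvs_g")
  assert_that(all(need %in% names(mutations)),
              "mutations table needs columns: ", paste(need, collapse = ", "))
  out <- list()
  for (i in seq_len(nrow(mutations))) {
    row <- mutations[i, ]
    res <- tryCatch({
      m <- models[[row$transcript_id]]
      assert_that(!is.null(m), "unknown transcript: ", row$transcript_id)
      rep_ <- predict_outcomes(genome, m,
                               parse_hgvs_g(row$hgvs_g, row$contig), ...)
      df <- as.data.frame(rep_)
      df$status <- "ok"
      df
    }, error = function(e) {
      data.frame(transcript_id = row$transcript_id, mutation = row$hgvs_g,
                 category = NA, rank = NA, kind = NA, delta_nt = NA,
                 site_offset = NA, frame_status = NA, aa_removed = NA,
                 aa_gained = NA, removed_residues = NA,
                 ptc_transcript_pos = NA,
                 ptc_distance_to_last_junction = NA, nmd_predicted = NA,
                 outcome_phrase = NA, transcript_level_class = NA,
                 in_ese = NA, flags = NA,
                 status = paste0("error: ", conditionMessage(e)),
                 stringsAsFactors = FALSE)
    })
    out[[i]] <- res
  }
  do.call(rbind, out)
}

#' Pre-design checklist for a target exon
#'
#' The checks recommended before committing to a mutant design: (1) cryptic
#' GT/AG dinucleotides near the exon's splice sites, (2) ESE hits that
#' candidate nonsense positions would fall into (when matrices are
#' supplied), (3) whether the exon length is divisible by 3 (a
#' "skip-tolerant" exon can be skipped without a frame shift), and (4) the
#' flanking intron lengths, with a retention-risk flag for short upstream
#' introns.
#'
#' @param genome a [genome_sequence()].
#' @param model a [transcript_model()].
#' @param exon_index target exon.
#' @param params a [scan_params()].
#' @param ese_matrices optional list of [ese_matrix()] objects.
#' @return An object of class `design_checklist`.
#' @export
design_checklist <- function(genome, model, exon_index,
                             params = scan_params(), ese_matrices = NULL) {
  n <- n_exons(model)
  assert_that(is_scalar_int(exon_index) && exon_index >= 1 && exon_index <= n,
              "exon_index must be in 1..", n)
  len <- exon_lengths(model)[exon_index]
  upstream_intron <- if (exon_index > 1) {
    intron_bounds(model, exon_index - 1L)$length
  } else NA_integer_
  downstream_intron <- if (exon_index < n) {
    intron_bounds(model, exon_index)$length
  } else NA_integer_

  near_acceptor <- if (exon_index > 1) {
    ctx <- site_context(model, genome, exon_index - 1L, "acceptor",
                        params$window_nt)
    scan_cryptic_sites(ctx$seq, params$acceptor_motif, ctx$anchor,
                       params$window_nt)
  } else NULL
  near_donor <- if (exon_index < n) {
    ctx <- site_context(model, genome, exon_index, "donor", params$window_nt)
    scan_cryptic_sites(ctx$seq, params$donor_motif, ctx$anchor,
                       params$window_nt)
  } else NULL

  ex <- model$exons[exon_index, , drop = FALSE]
  seq <- get_seq(genome, model$contig, ex[1, "start"], ex[1, "end"])
  if (model$strand == "-") seq <- revcomp(seq)
  ese_hits <- if (!is.null(ese_matrices)) scan_ese(seq, ese_matrices)
              else NULL

  structure(list(
    transcript_id = model$transcript_id, exon_index = exon_index,
    exon_length = len, divisible_by_3 = len %% 3L == 0L,
    skip_tolerance = if (len %% 3L == 0L) "divisible by 3: skip-tolerant"
                     else sprintf("not divisible by 3 (remainder %d): %s",
                                  len %% 3L, "skip causes a frame shift"),
    upstream_intron_nt = upstream_intron,
    downstream_intron_nt = downstream_intron,
    retention_risk = !is.na(upstream_intron) &&
      upstream_intron <= params$intron_retention_max_nt,
    cryptic_near_acceptor = near_acceptor,
    cryptic_near_donor = near_donor,
    ese_hits = ese_hits), class = "design_checklist")
}

#' @export
print.design_checklist <- function(x, ...) {
  cat("<design_checklist> ", x$transcript_id, " exon ", x$exon_index,
      " (", x$exon_length, " nt)\n", sep = "")
  cat("  - ", x$skip_tolerance, "\n", sep = "")
  cat("  - flanking introns: upstream ",
      x$upstream_intron_nt %||% NA, " nt, downstream ",
      x$downstream_intron_nt %||% NA, " nt",
      if (isTRUE(x$retention_risk)) " [retention risk: short upstream intron]",
      "\n", sep = "")
  for (side in c("cryptic_near_acceptor", "cryptic_near_donor")) {
    h <- x[[side]]
    if (!is.null(h)) {
      cat("  - ", sub("cryptic_near_", "", side), "-side cryptic sites: ",
          if (nrow(h) == 0) "none in window"
          else paste(h$offset, collapse = ", "), "\n", sep = "")
    }
  }
  if (!is.null(x$ese_hits)) {
    cat("  - ESE hits in exon: ", nrow(x$ese_hits), "\n", sep = "")
  }
  invisible(x)
}
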