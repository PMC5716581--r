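#' Scan parameters for cryptic splice-site search
#'
#' @param window_nt distance scanned on each side of a lost splice site.
#'   The cryptic sites observed in practice lie within a few tens of
#'   nucleotides of the destroyed site; 100 nt is generous while keeping
#'   reports short.
#' @param intron_retention_max_nt intron length up to which retention is
#'   proposed as a candidate outcome (retention is always proposed for the
#'   terminal intron, which lacks a downstream splice unit).
#' @param donor_motif,acceptor_motif the splice-site dinucleotides.
#' @return An object of class `scan_params`.
#' @export
scan_params <- function(window_nt = 100L, intron_retention_max_nt = 1000L,
                        donor_motif = "GT", acceptor_motif = "AG") {
  assert_that(is_scalar_int(window_nt) && window_nt >= 1,
              "window_nt must be a positive integer")
  assert_that(is_scalar_int(intron_retention_max_nt) &&
                intron_retention_max_nt >= 1,
              "intron_retention_max_nt must be a positive integer")
  assert_that(nchar(donor_motif) == 2 && nchar(acceptor_motif) == 2,
              "splice-site motifs are dinucleotides")
  structure(list(window_nt = as.integer(window_nt),
                 intron_retention_max_nt = as.integer(intron_retention_max_nt),
                 donor_motif = toupper(donor_motif),
                 acceptor_motif = toupper(acceptor_motif)),
            class = "scan_params")
}

#' Find cryptic splice-site motifs near an anchor position
#'
#' Every occurrence of `motif` whose first base lies within `window` of
#' `anchor` is reported, nearest first. Offsets are measured from the first
#' base of the wildtype site (`anchor`) to the first base of the motif;
#' the anchor position itself (offset 0) is excluded. Matches overlapping an
#' `N` base never arise because the motif alphabet is ACGT.
#'
#' @param sequence nucleotide string to scan.
#' @param motif dinucleotide, e.g. `"GT"` or `"AG"`.
#' @param anchor 1-based position of the first base of the wildtype site.
#' @param window maximum |offset| considered.
#' @param direction `"both"` (default), `"downstream"` (positive offsets) or
#'   `"upstream"` (negative offsets).
#' @return A data.frame with columns `offset` and `position`, ordered by
#'   |offset| (ties: upstream first; reordered by callers as needed).
#' @export
scan_cryptic_sites <- function(sequence, motif, anchor, window,
                               direction = c("both", "downstream",
                                             "upstream")) {
  direction <- match.arg(direction)
  assert_that(anchor >= 1 && anchor <= nchar(sequence),
              "anchor outside sequence")
  pos <- motif_positions(sequence, toupper(motif))
  off <- pos - anchor
  keep <- off != 0L & abs(off) <= window
  if (direction == "downstream") keep <- keep & off > 0L
  if (direction == "upstream") keep <- keep & off < 0L
  pos <- pos[keep]; off <- off[keep]
  ord <- order(abs(off), off)
  data.frame(offset = as.integer(off[ord]), position = as.integer(pos[ord]))
}

## One candidate outcome. modified_exons is the full exon matrix of the
## predicted mature transcript (transcription order, genomic coordinates on
## the mutated genome).
#' @noRd
splice_outcome <- function(kind, modified_exons, delta_nt,
                           site_offset = NA_integer_, rank = NA_integer_,
                           intron_index = NA_integer_,
                           exon_index = NA_integer_, note = "") {
  structure(list(kind = kind, modified_exons = modified_exons,
                 delta_nt = as.integer(delta_nt),
                 site_offset = as.integer(site_offset),
                 rank = as.integer(rank),
                 intron_index = as.integer(intron_index),
                 exon_index = as.integer(exon_index), note = note),
            class = "splice_outcome")
}

#' @export
print.splice_outcome <- function(x, ...) {
  cat("<splice_outcome> rank ", x$rank, ": ", x$kind,
      " (delta ", sprintf("%+d", x$delta_nt), " nt",
      if (!is.na(x$site_offset)) paste0(", site offset ", x$site_offset),
      ")\n", sep = "")
  invisible(x)
}

#' Tabulate a list of splice outcomes
#'
#' @param x list of `splice_outcome` objects (as returned by
#'   [enumerate_outcomes()]).
#' @param ... unused.
#' @return A data.frame with one row per outcome.
#' @export
outcomes_table <- function(x, ...) {
  do.call(rbind, lapply(x, function(o) {
    data.frame(rank = o$rank, kind = o$kind, delta_nt = o$delta_nt,
               site_offset = o$site_offset,
               n_exons = nrow(o$modified_exons),
               exons = paste(sprintf("%d-%d", o$modified_exons[, "start"],
                                     o$modified_exons[, "end"]),
                             collapse = ";"),
               stringsAsFactors = FALSE)
  }))
}

## Sequence context around a splice site of intron k, in transcript
## orientation, together with the genomic coordinate of each local position.
## side = "donor": exon k (tail) then the start of intron k; anchor = first
## intron base. side = "acceptor": end of intron k then exon k+1 (head);
## anchor = first base of the acceptor dinucleotide (second-to-last intron
## base).
#' @noRd
site_context <- function(model, genome, intron_index, side, window) {
  b <- intron_bounds(model, intron_index)
  step <- if (model$strand == "+") 1L else -1L
  if (side == "donor") {
    ex <- model$exons[intron_index, , drop = FALSE]
    ex_len <- ex[1, "end"] - ex[1, "start"] + 1L
    keep_ex <- min(ex_len, window + 2L)
    keep_in <- min(b$length, window + 2L)
    ex_3p <- if (model$strand == "+") ex[1, "end"] else ex[1, "start"]
    g <- c(seq(ex_3p - step * (keep_ex - 1L), ex_3p, by = step),
           seq(b$donor_g, b$donor_g + step * (keep_in - 1L), by = step))
    anchor <- keep_ex + 1L
  } else {
    ex <- model$exons[intron_index + 1L, , drop = FALSE]
    ex_len <- ex[1, "end"] - ex[1, "start"] + 1L
    keep_ex <- min(ex_len, window + 2L)
    keep_in <- min(b$length, window + 2L)
    ex_5p <- if (model$strand == "+") ex[1, "start"] else ex[1, "end"]
    g <- c(seq(b$acceptor_g - step * (keep_in - 1L), b$acceptor_g, by = step),
           seq(ex_5p, ex_5p + step * (keep_ex - 1L), by = step))
    anchor <- keep_in - 1L  # first base of the acceptor AG
  }
  seq <- paste(vapply(g, function(p) {
    s <- get_seq(genome, model$contig, p, p)
    if (model$strand == "+") s else comp_base(s)
  }, character(1)), collapse = "")
  list(seq = seq, gpos = g, anchor = anchor, exon_keep = keep_ex,
       intron_keep = keep_in)
}

## Replace the 3'-end boundary of exon i so its last transcribed base sits at
## genomic position g_last.
#' @noRd
set_exon_3p <- function(exons, i, g_last, strand) {
  if (strand == "+") exons[i, "end"] <- g_last else exons[i, "start"] <- g_last
  exons
}

#' @noRd
set_exon_5p <- function(exons, i, g_first, strand) {
  if (strand == "+") exons[i, "start"] <- g_first
  else exons[i, "end"] <- g_first
  exons
}

#' Enumerate candidate alternative processing outcomes
#'
#' Given a classified lesion, proposes the alternative outcomes reported for
#' splice-site mutations, ranked in their observed frequency order: exon
#' skipping first, then cryptic splice-site use (nearest site first; ties
#' report the exonic side first), then intron retention (proposed for short
#' or terminal introns). A donor loss skips the upstream exon; an acceptor
#' loss skips the downstream exon, or yields a `no_rescue` candidate when
#' that exon is terminal. Nonsense mutations yield the unspliced
#' (PTC-retaining) transcript plus the nonsense-associated skip of the
#' affected exon; exonic indels yield the unspliced transcript only (see
#' [neighbor_exon_scan()] for the opt-in neighbouring-exon cryptic scan).
#' Pseudo-exon creation is not enumerated and is flagged as not evaluated
#' in reports.
#'
#' @param model a [transcript_model()] aligned to `mutated_genome` (pass the
#'   [lift_model()] result for deletions).
#' @param mutated_genome the genome after [apply_mutation()].
#' @param classification a `mutation_classification`.
#' @param params a [scan_params()].
#' @return A list of `splice_outcome` objects with unique ranks 1..n.
#' @export
enumerate_outcomes <- function(model, mutated_genome, classification,
                               params = scan_params()) {
  stopifnot(inherits(classification, "mutation_classification"))
  cat_ <- classification$category
  ex <- model$exons
  n <- n_exons(model)
  wt_len <- spliced_length(model)
  out <- list()

  add <- function(o) out[[length(out) + 1L]] <<- o

  if (cat_ %in% c("ESS_donor", "ESS_acceptor")) {
    k <- classification$affected_intron_index
    b <- intron_bounds(model, k)
    if (cat_ == "ESS_donor") {
      ## skip the upstream exon (exon k)
      add(splice_outcome("exon_skip", ex[-k, , drop = FALSE],
                         -exon_lengths(model)[k], intron_index = k,
                         exon_index = k))
      ctx <- site_context(model, mutated_genome, k, "donor", params$window_nt)
      hits <- scan_cryptic_sites(ctx$seq, params$donor_motif, ctx$anchor,
                                 params$window_nt)
      for (j in seq_len(nrow(hits))) {
        p <- hits$position[j]; off <- hits$offset[j]
        if (p < 2L) next  # would leave an empty exon
        new_last <- ctx$gpos[p - 1L]
        ## exonic hit truncates exon k; intronic hit extends it
        mod <- set_exon_3p(ex, k, new_last, model$strand)
        ## retained(+) or removed(-) nt at the exon 3' end: the last retained
        ## base is local p-1, the wildtype last exon base is local anchor-1.
        delta <- (p - 1L) - (ctx$anchor - 1L)
        add(splice_outcome("cryptic_donor", mod, delta, site_offset = off,
                           intron_index = k, exon_index = k))
      }
    } else {
      skip_idx <- k + 1L
      if (skip_idx == n) {
        add(splice_outcome("no_rescue", ex, 0L, intron_index = k,
                           exon_index = skip_idx,
                           note = "terminal-exon acceptor lost"))
      } else {
        add(splice_outcome("exon_skip", ex[-skip_idx, , drop = FALSE],
                           -exon_lengths(model)[skip_idx], intron_index = k,
                           exon_index = skip_idx))
      }
      ctx <- site_context(model, mutated_genome, k, "acceptor",
                          params$window_nt)
      hits <- scan_cryptic_sites(ctx$seq, params$acceptor_motif, ctx$anchor,
                                 params$window_nt)
      for (j in seq_len(nrow(hits))) {
        p <- hits$position[j]; off <- hits$offset[j]
        if (p + 2L > nchar(ctx$seq)) next  # no exon base left downstream
        new_first <- ctx$gpos[p + 2L]
        mod <- set_exon_5p(ex, k + 1L, new_first, model$strand)
        ## wildtype exon 5' local position is intron_keep + 1
        delta <- (ctx$intron_keep + 1L) - (p + 2L)
        if (delta == 0L) next
        add(splice_outcome("cryptic_acceptor", mod, delta, site_offset = off,
                           intron_index = k, exon_index = k + 1L))
      }
    }
    ## intron retention for short or terminal introns
    if (b$length <= params$intron_retention_max_nt || k == n - 1L) {
      merged <- ex
      if (model$strand == "+") {
        merged[k, "end"] <- merged[k + 1L, "end"]
      } else {
        merged[k, "start"] <- merged[k + 1L, "start"]
      }
      merged <- merged[-(k + 1L), , drop = FALSE]
      add(splice_outcome("intron_retention", merged, b$length,
                         intron_index = k))
    }
  } else if (cat_ == "exonic_nonsense") {
    k <- classification$affected_exon_index
    add(splice_outcome("unspliced_ptc", ex, 0L, exon_index = k,
                       note = "PTC retained in the normal transcript"))
    add(splice_outcome("exon_skip", ex[-k, , drop = FALSE],
                       -exon_lengths(model)[k], exon_index = k,
                       note = "nonsense-associated skip"))
  } else if (cat_ %in% c("exonic_indel_frameshift", "exonic_indel_inframe")) {
    k <- classification$affected_exon_index
    add(splice_outcome("unspliced_ptc", ex, 0L, exon_index = k,
                       note = "splice structure unchanged"))
  } else {
    stop("no outcome enumeration for classification '", cat_, "'",
         call. = FALSE)
  }

  rank_outcomes(out, wt_len)
}

## Order outcomes by kind priority, then |site offset| (exonic side first on
## ties), and assign unique ranks. Also checks the delta/exon consistency
## invariant.
#' @noRd
rank_outcomes <- function(out, wt_len) {
  if (length(out) == 0) return(out)
  prio <- vapply(out, function(o) switch(o$kind,
    exon_skip = 1, no_rescue = 1, unspliced_ptc = 1,
    cryptic_donor = 2, cryptic_acceptor = 2, intron_retention = 3,
    4), numeric(1))
  absoff <- vapply(out, function(o) {
    if (is.na(o$site_offset)) 0L else abs(o$site_offset)
  }, integer(1))
  ## exonic side first on equidistant ties: donor-exonic offsets are
  ## negative, acceptor-exonic offsets positive
  exonic_first <- vapply(out, function(o) {
    if (is.na(o$site_offset)) 0L
    else if (o$kind == "cryptic_donor" && o$site_offset < 0) 0L
    else if (o$kind == "cryptic_acceptor" && o$site_offset > 0) 0L
    else 1L
  }, integer(1))
  ord <- order(prio, absoff, exonic_first)
  out <- out[ord]
  for (i in seq_along(out)) {
    out[[i]]$rank <- i
    got <- sum(out[[i]]$modified_exons[, "end"] -
                 out[[i]]$modified_exons[, "start"] + 1L)
    assert_that(got == wt_len + out[[i]]$delta_nt,
                "internal error: outcome delta_nt inconsistent with exons")
  }
  out
}

#' Cryptic-acceptor scan inside a neighbouring exon
#'
#' Exonic lesions have been observed to correlate with the use of cryptic
#' splice acceptors inside a *different*, unmutated exon, 5'-truncating it.
#' Because only the correlation (not a mechanism) is established, this scan
#' is a separate opt-in rather than part of [enumerate_outcomes()]. Each
#' acceptor-motif occurrence inside the exon, within the scan window of its
#' wildtype acceptor, yields a truncation outcome whose `delta_nt` is minus
#' the number of 5' bases removed.
#'
#' @param model a [transcript_model()] aligned to `mutated_genome`.
#' @param mutated_genome the genome after [apply_mutation()].
#' @param exon_index index of the exon to scan (must have an upstream
#'   intron, i.e. `exon_index >= 2`).
#' @param params a [scan_params()].
#' @return A list of `splice_outcome` objects of kind `cryptic_acceptor`,
#'   nearest site first.
#' @export
neighbor_exon_scan <- function(model, mutated_genome, exon_index,
                               params = scan_params()) {
  n <- n_exons(model)
  assert_that(is_scalar_int(exon_index) && exon_index >= 2 &&
                exon_index <= n, "exon_index must be in 2..", n)
  ex <- model$exons
  exon_seq <- {
    s <- get_seq(mutated_genome, model$contig, ex[exon_index, "start"],
                 ex[exon_index, "end"])
    if (model$strand == "+") s else revcomp(s)
  }
  hits <- motif_positions(exon_seq, params$acceptor_motif)
  ## offset from the first base of the wildtype acceptor AG (just upstream of
  ## the exon) to the first base of the internal motif: exon position p is
  ## p + 1 bases downstream of it.
  hits <- hits[hits + 1L <= params$window_nt]
  hits <- hits[hits + 1L < nchar(exon_seq)]  # keep at least one exon base
  out <- list()
  for (p in sort(hits)) {
    removed <- p + 1L
    step <- if (model$strand == "+") 1L else -1L
    ex_5p <- if (model$strand == "+") ex[exon_index, "start"]
             else ex[exon_index, "end"]
    mod <- set_exon_5p(ex, exon_index, ex_5p + step * removed, model$strand)
    out[[length(out) + 1L]] <- splice_outcome(
      "cryptic_acceptor", mod, -removed, site_offset = p + 1L,
      exon_index = exon_index, note = "neighbouring-exon scan")
  }
  rank_outcomes(out, spliced_length(model))
}
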