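## Seeded synthetic fixtures mimicking the seven mutant lines.
##
## Design notes. Every fixture is built on the + strand (minus-strand
## behaviour is covered by strand-symmetry property tests). The structural
## parameters that carry the expected outcome (exon lengths, cryptic-site
## offsets, planted stop codons, motif placements, the genomic coordinate of
## the lesion) are engineered exactly; all remaining sequence is random
## filler drawn under local constraints:
##   - coding sequence is generated base-by-base with a global reading-frame
##     tracker so no in-frame stop can arise anywhere in the wildtype ORF;
##   - windows that the cryptic-site scanner will inspect are generated
##     free of the scanned motif, so the planted site (when any) is the only
##     candidate - this realises the "no closer unintended site" invariant
##     by construction rather than by rejection, and an independent
##     post-build verification errors out if it is ever violated;
##   - stretches that a frameshifted ribosome will traverse ahead of a
##     planted premature stop are generated T-free (no stop codon exists
##     without T), which makes the PTC position deterministic for any seed.

## Generate a coding sequence from constraint segments. Each segment is
## either list(literal=) or list(len=, alphabet=, forbid=); the generator
## tracks the global codon frame and never completes an in-frame stop
## (unless allow_stop for a literal, used for the terminal stop codon).
#' @noRd
gen_cds <- function(segments) {
  total <- sum(vapply(segments, function(s) {
    if (!is.null(s$literal)) nchar(s$literal) else s$len
  }, numeric(1)))
  out <- character(total)
  prev <- ""
  pos <- 0L
  for (seg in segments) {
    if (!is.null(seg$literal)) {
      for (ch in chars(seg$literal)) {
        pos <- pos + 1L
        out[pos] <- ch
        if (pos %% 3L == 0L && !isTRUE(seg$allow_stop)) {
          codon <- paste(out[(pos - 2L):pos], collapse = "")
          assert_that(!(codon %in% STOP_CODONS),
                      "internal: literal CDS segment creates a premature ",
                      "in-frame stop at position ", pos)
        }
        prev <- ch
      }
    } else {
      alphabet <- seg$alphabet %||% c("A", "C", "G", "T")
      forbid <- seg$forbid %||% character()
      for (i in seq_len(seg$len)) {
        pos <- pos + 1L
        banned <- character()
        for (m in forbid) {
          if (substr(m, 1L, 1L) == prev) banned <- c(banned, substr(m, 2L, 2L))
        }
        if (pos %% 3L == 0L) {
          pre <- paste(out[(pos - 2L):(pos - 1L)], collapse = "")
          for (s in STOP_CODONS) {
            if (substr(s, 1L, 2L) == pre) banned <- c(banned, substr(s, 3L, 3L))
          }
        }
        pool <- setdiff(alphabet, banned)
        assert_that(length(pool) > 0,
                    "internal: CDS constraints left no admissible base")
        out[pos] <- sample(pool, 1L)
        prev <- out[pos]
      }
    }
  }
  paste(out, collapse = "")
}

## Intron with canonical GT...AG ends. mode controls the interior:
## "free" random; "donor_clean"/"acceptor_clean" keep the interior free of
## GT / AG respectively (so a destroyed natural site has no unintended
## nearby competitor); head = literal bases inserted right after the donor
## GT (used to plant a cryptic donor).
#' @noRd
make_intron <- function(len, mode = "free", head = "") {
  assert_that(len >= 4 + nchar(head), "intron too short")
  interior_len <- len - 4L - nchar(head)
  prev <- if (nzchar(head)) substr(head, nchar(head), nchar(head)) else "T"
  interior <- switch(mode,
    free = rand_seq(interior_len),
    donor_clean = rand_seq_avoiding(interior_len, "GT", prev = prev),
    acceptor_clean = rand_seq_avoiding(interior_len, "AG", prev = prev),
    stop("unknown intron mode: ", mode, call. = FALSE))
  paste0("GT", head, interior, "AG")
}

## Assemble a plus-strand gene: contig = flank5 | e1 i1 e2 ... en | flank3.
## cds is sliced into the exons by coding_lengths; exon 1 additionally
## carries utr5, the last exon utr3.
#' @noRd
assemble_gene <- function(name, cds, coding_lengths, introns, utr5, utr3,
                          flank5_len, flank3_len = 60L) {
  assert_that(sum(coding_lengths) == nchar(cds),
              "internal: coding lengths do not add up to the CDS")
  n <- length(coding_lengths)
  assert_that(length(introns) == n - 1L, "internal: need n-1 introns")
  cuts <- cumsum(coding_lengths)
  starts <- c(1L, head(cuts, -1L) + 1L)
  slices <- substring(cds, starts, cuts)
  exon_seqs <- slices
  exon_seqs[1] <- paste0(utr5, slices[1])
  exon_seqs[n] <- paste0(slices[n], utr3)
  flank5 <- rand_seq(flank5_len)
  flank3 <- rand_seq(flank3_len)
  contig <- flank5
  exons <- matrix(0L, nrow = n, ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  pos <- nchar(flank5)
  for (i in seq_len(n)) {
    exons[i, "start"] <- pos + 1L
    pos <- pos + nchar(exon_seqs[i])
    exons[i, "end"] <- pos
    contig <- paste0(contig, exon_seqs[i])
    if (i < n) {
      contig <- paste0(contig, introns[[i]])
      pos <- pos + nchar(introns[[i]])
    }
  }
  contig <- paste0(contig, flank3)
  genome <- genome_sequence(stats::setNames(list(contig), name))
  splen <- sum(nchar(exon_seqs))
  model <- transcript_model(
    gene_id = sub("_mimic$", "", name), transcript_id = paste0(name, "_tx"),
    contig = name, strand = "+", exons = exons,
    cds_start = nchar(utr5) + 1L, cds_end = nchar(utr5) + nchar(cds))
  list(genome = genome, model = model)
}

#' Names of the available mutant-line mimics
#' @return Character vector of fixture names accepted by [build_mimic()].
#' @export
mimic_names <- function() {
  c("abca1b_mimic", "slc27a2a_mimic", "abca1a_mimic", "cd36_mimic",
    "pla2g12b_mimic", "creb3l3a_mimic", "smyd1a_mimic")
}

#' Build a synthetic mutant-line fixture
#'
#' Generates, deterministically for a given seed, a genome + transcript
#' model + mutation triple whose structural parameters (exon lengths,
#' cryptic-site offsets, motif placements, lesion coordinate) reproduce one
#' of the seven studied mutant lines, together with an expectation record
#' stating the anticipated outcome for use in end-to-end tests. Exact
#' flanking sequences of the real genes are not reproduced: only structure
#' is planted, so sequence-dependent quantities (e.g. the residue content of
#' novel ORFs) are fixture-specific.
#'
#' @param name one of [mimic_names()].
#' @param seed integer seed; the same seed always yields byte-identical
#'   fixtures.
#' @return An object of class `mimic_fixture`: a list with `name`, `seed`,
#'   `genome`, `model`, `mutation`, `hgvs`, `expect` (expectation record),
#'   `ese_matrices` (creb3l3a only) and `notes`.
#' @export
build_mimic <- function(name, seed = 1L) {
  name <- match.arg(name, mimic_names())
  assert_that(is_scalar_int(seed), "seed must be an integer")
  fx <- withr::with_seed(as.integer(seed), switch(name,
    slc27a2a_mimic = mimic_slc27a2a(),
    abca1b_mimic = mimic_abca1b(),
    abca1a_mimic = mimic_abca1a(),
    cd36_mimic = mimic_cd36(),
    pla2g12b_mimic = mimic_pla2g12b(),
    creb3l3a_mimic = mimic_creb3l3a(),
    smyd1a_mimic = mimic_smyd1a()))
  fx$name <- name
  fx$seed <- as.integer(seed)
  fx$mutation <- parse_hgvs_g(fx$hgvs, contig = name)
  if (!is.null(fx$ref_base)) fx$mutation$ref <- fx$ref_base
  class(fx) <- "mimic_fixture"
  verify_mimic(fx)
  fx
}

#' @export
print.mimic_fixture <- function(x, ...) {
  cat("<mimic_fixture> ", x$name, " (seed ", x$seed, "): ", x$hgvs, ", ",
      n_exons(x$model), " exons, contig ",
      contig_length(x$genome, x$name), " bp\n", sep = "")
  invisible(x)
}

## ---- per-line builders (all called inside with_seed) ----------------------

#' @noRd
mimic_slc27a2a <- function() {
  ## donor G>A in intron 2-3 at g.3431; exon 2 = 210 nt (70 codons) and
  ## divisible by 3, so its skip keeps the frame.
  cds <- gen_cds(list(
    list(literal = "ATG"), list(len = 57L),
    list(len = 210L, forbid = "GT"),      # exon 2: donor-window clean
    list(len = 120L), list(len = 90L),
    list(literal = "TAA", allow_stop = TRUE)))
  introns <- list(make_intron(154L), make_intron(154L, mode = "donor_clean"),
                  make_intron(154L))
  g <- assemble_gene("slc27a2a_mimic", cds, c(60L, 210L, 120L, 93L), introns,
                     utr5 = rand_seq(30L), utr3 = rand_seq(30L),
                     flank5_len = 3431L - 455L)
  list(genome = g$genome, model = g$model, hgvs = "g.3431G>A", ref_base = "G",
       expect = list(category = "ESS_donor", intron = 2L,
                     top_kind = "exon_skip", top_delta = -210L,
                     aa_removed = 70L, frame = "maintained", ptc = FALSE,
                     nmd = "not_applicable", class = "WT_like",
                     phrase = "skipped exon (210 bp), frame maintained"),
       notes = "exon 2 length and divisibility per the studied line")
}

#' @noRd
mimic_abca1b <- function() {
  ## acceptor G>T in intron 33-34 at g.64427; exon 34 = 116 nt, so its skip
  ## shifts the frame; a stop is planted in the post-skip frame 13 codons
  ## into exon 35 (T-free flanks make it the first reachable stop).
  c_mid <- rep(81L, 32L)                     # exons 2..33
  cds <- gen_cds(c(
    list(list(literal = "ATG"), list(len = 57L)),
    lapply(c_mid, function(l) list(len = l)),
    list(list(len = 114L, forbid = "AG"),    # exon 34 body, acceptor-clean
         list(literal = "CC"),               # exon 34 tail (phase guard)
         list(len = 39L, alphabet = c("A", "C", "G")),  # exon 35 head
         list(literal = "TAA"),              # stop in the post-skip frame
         list(len = 39L, alphabet = c("A", "C", "G"))), # exon 35 tail
    lapply(rep(81L, 10L), function(l) list(len = l)),   # exons 36..45
    list(list(len = 58L), list(literal = "TAA", allow_stop = TRUE))))
  coding <- c(60L, c_mid, 116L, 81L, rep(81L, 10L), 61L)
  introns <- c(lapply(seq_len(32L), function(i) make_intron(154L)),
               list(make_intron(200L, mode = "acceptor_clean")),
               lapply(seq_len(12L), function(i) make_intron(154L)))
  offset <- 90L + 32L * 81L + 32L * 154L + 200L   # last base of intron 33-34
  g <- assemble_gene("abca1b_mimic", cds, coding, introns,
                     utr5 = rand_seq(30L), utr3 = rand_seq(30L),
                     flank5_len = 64427L - offset)
  list(genome = g$genome, model = g$model, hgvs = "g.64427G>T",
       ref_base = "G",
       expect = list(category = "ESS_acceptor", intron = 33L,
                     top_kind = "exon_skip", top_delta = -116L,
                     frame = "frameshift", ptc = TRUE, nmd = "degraded",
                     class = "reduced",
                     phrase = "skipped exon (116 bp), frame shift, PTC"),
       notes = "exon 34 length per the studied line")
}

#' @noRd
mimic_abca1a <- function() {
  ## acceptor G>A in intron 29-30 at g.48320; exon 30 begins TAGC, so the
  ## only nearby cryptic AG sits at exon bases 2-3: using it removes TAG,
  ## which spans two Ser codons (TCT|AGC -> TCC) - one Serine lost in frame.
  c_mid <- rep(81L, 27L)                     # exons 2..28
  cds <- gen_cds(c(
    list(list(literal = "ATG"), list(len = 57L)),
    lapply(c_mid, function(l) list(len = l)),
    list(list(len = 78L), list(literal = "TC"),          # exon 29 (80 nt)
         list(literal = "TAGC"),                         # exon 30 head
         list(len = 96L, forbid = "AG")),                # exon 30 body
    list(list(len = 57L), list(literal = "TAA", allow_stop = TRUE))))
  coding <- c(60L, c_mid, 80L, 100L, 60L)
  introns <- c(lapply(seq_len(28L), function(i) make_intron(154L)),
               list(make_intron(200L, mode = "acceptor_clean")),
               list(make_intron(154L)))
  offset <- 90L + 27L * 81L + 80L + 28L * 154L + 200L
  g <- assemble_gene("abca1a_mimic", cds, coding, introns,
                     utr5 = rand_seq(30L), utr3 = rand_seq(30L),
                     flank5_len = 48320L - offset)
  list(genome = g$genome, model = g$model, hgvs = "g.48320G>A",
       ref_base = "G",
       expect = list(category = "ESS_acceptor", intron = 29L,
                     cryptic_kind = "cryptic_acceptor", cryptic_delta = -3L,
                     cryptic_offset = 3L, aa_removed = 1L,
                     removed_residues = "S", frame = "maintained",
                     ptc = FALSE, nmd = "not_applicable", class = "WT_like"),
       notes = "cryptic AG at exon-30 bases 2-3; single Serine loss")
}

#' @noRd
mimic_cd36 <- function() {
  ## donor G>A in intron 10-11 at g.11242; the wildtype intron begins
  ## GTATGT, so the mutant intron begins ATATGT and the nearest cryptic GT
  ## sits 4 nt downstream: ATAT is retained, shifting the frame. Exon 11
  ## (52 nt) is built so the shifted frame reads 18 novel codons and then a
  ## stop whose first base lies 1 nt upstream of the last junction (escape);
  ## exon 12 encodes exactly 154 wildtype residues.
  cds <- gen_cds(c(
    list(list(literal = "ATG"), list(len = 57L)),
    lapply(rep(81L, 8L), function(l) list(len = l)),      # exons 2..9
    list(list(len = 81L, forbid = "GT"),                  # exon 10
         list(literal = "C"),                             # exon 11 head
         list(len = 49L, alphabet = c("A", "C", "G")),    # exon 11 body
         list(literal = "TA"),                            # exon 11 tail
         list(literal = "AC"),                            # exon 12 head
         list(len = 462L),                                # 154 codons
         list(literal = "TAA", allow_stop = TRUE))))
  coding <- c(60L, rep(81L, 8L), 81L, 52L, 467L)
  introns <- c(lapply(seq_len(9L), function(i) make_intron(154L)),
               list(make_intron(300L, mode = "donor_clean", head = "ATGT")),
               list(make_intron(154L)))
  offset <- 90L + 9L * 154L + 8L * 81L + 81L + 1L       # first intron base
  g <- assemble_gene("cd36_mimic", cds, coding, introns,
                     utr5 = rand_seq(30L), utr3 = rand_seq(60L),
                     flank5_len = 11242L - offset)
  list(genome = g$genome, model = g$model, hgvs = "g.11242G>A",
       ref_base = "G",
       expect = list(category = "ESS_donor", intron = 10L,
                     cryptic_kind = "cryptic_donor", cryptic_delta = 4L,
                     cryptic_offset = 4L, frame = "frameshift", ptc = TRUE,
                     ptc_junction_distance = 1L, nmd = "escape",
                     class = "WT_like", novel_aa = 18L,
                     terminal_exon_aa = 154L,
                     mutant_intron_prefix = "ATATGT"),
       notes = "terminal exon encodes 154 residues; PTC at last junction")
}

#' @noRd
mimic_pla2g12b <- function() {
  ## acceptor A>T in intron 3-4 at g.10194; exon 4 is terminal, so no skip
  ## candidate exists: the enumeration reports no_rescue plus retention of
  ## the (terminal) intron 3-4.
  cds <- gen_cds(list(
    list(literal = "ATG"), list(len = 57L),
    list(len = 81L), list(len = 81L),
    list(len = 99L, forbid = "AG"),          # exon 4 head, acceptor-clean
    list(len = 42L),
    list(literal = "TAA", allow_stop = TRUE)))
  introns <- list(make_intron(154L), make_intron(154L),
                  make_intron(200L, mode = "acceptor_clean"))
  offset <- 90L + 154L + 81L + 154L + 81L + 200L - 1L   # the acceptor A
  g <- assemble_gene("pla2g12b_mimic", cds, c(60L, 81L, 81L, 144L), introns,
                     utr5 = rand_seq(30L), utr3 = rand_seq(50L),
                     flank5_len = 10194L - offset)
  list(genome = g$genome, model = g$model, hgvs = "g.10194A>T",
       ref_base = "A",
       expect = list(category = "ESS_acceptor", intron = 3L,
                     kinds = c("no_rescue", "intron_retention"),
                     class = "reduced"),
       notes = "terminal-exon acceptor: skip cannot be proposed")
}

#' @noRd
mimic_creb3l3a <- function() {
  ## nonsense C>T at g.357 in exon 2 of 10: codon CAA -> TAA. The mutated
  ## base sits at position 5 of a planted 7-mer ESE consensus GCTCCAA, so
  ## the wildtype hit is lost in the mutant. Exon 2 = 114 nt (38 codons),
  ## divisible by 3: the nonsense-associated skip keeps the frame.
  cds <- gen_cds(c(
    list(list(literal = "ATG"), list(len = 57L),
         list(len = 62L), list(literal = "GCTC"), list(literal = "CAA"),
         list(len = 45L)),                                # exon 2 = 114
    lapply(rep(81L, 7L), function(l) list(len = l)),      # exons 3..9
    list(list(len = 57L), list(literal = "TAA", allow_stop = TRUE))))
  coding <- c(60L, 114L, rep(81L, 7L), 60L)
  introns <- c(list(make_intron(170L)),
               lapply(seq_len(8L), function(i) make_intron(154L)))
  offset <- 90L + 170L + 67L                              # the C of CAA
  g <- assemble_gene("creb3l3a_mimic", cds, coding, introns,
                     utr5 = rand_seq(30L), utr3 = rand_seq(30L),
                     flank5_len = 357L - offset)
  ese <- ese_matrix("SYN_ESE1",
                    consensus_pwm("GCTCCAA"), threshold = 6.5)
  list(genome = g$genome, model = g$model, hgvs = "g.357C>T", ref_base = "C",
       ese_matrices = list(ese),
       expect = list(category = "exonic_nonsense", exon = 2L,
                     skip_delta = -114L, aa_removed = 38L,
                     frame = "maintained", skip_class = "WT_like",
                     unspliced_nmd = "degraded", in_ese = TRUE,
                     lost_hits = 1L),
       notes = "nonsense codon inside a planted ESE consensus")
}

#' @noRd
mimic_smyd1a <- function() {
  ## 7-nt deletion in exon 3 (frameshift; a planted stop 10 codons into the
  ## shifted frame makes the PTC deterministic). Exon 2 carries internal
  ## cryptic acceptor AGs at offsets 12-13 and 39-40 and is otherwise
  ## AG-free, yielding 13- and 40-nt 5' truncations in the neighbour scan.
  ## The published deletion span g.6948_6955del (8 positions) conflicts with
  ## the stated 7-bp length; the fixture plants 7 nt (g.6948_6954del) and
  ## records the discrepancy here.
  cds <- gen_cds(list(
    list(literal = "ATG"), list(len = 57L),
    list(len = 11L, alphabet = c("A", "C", "G"), forbid = "AG"),
    list(literal = "AG"),
    list(len = 25L, alphabet = c("A", "C", "G"), forbid = "AG"),
    list(literal = "AG"),
    list(len = 80L, forbid = "AG"),          # rest of exon 2 (120 total)
    list(len = 30L), list(len = 7L),         # exon 3 start; deletion target
    list(len = 30L, alphabet = c("A", "C", "G")),
    list(literal = "TAA"),                   # stop in the post-deletion frame
    list(len = 80L),                         # rest of exon 3 (150 total)
    list(len = 81L),
    list(len = 57L), list(literal = "TAA", allow_stop = TRUE)))
  introns <- list(make_intron(154L, mode = "acceptor_clean"),
                  make_intron(154L), make_intron(154L), make_intron(154L))
  g <- assemble_gene("smyd1a_mimic", cds, c(60L, 120L, 150L, 81L, 60L),
                     introns, utr5 = rand_seq(30L), utr3 = rand_seq(30L),
                     flank5_len = 6948L - 549L)
  list(genome = g$genome, model = g$model, hgvs = "g.6948_6954del",
       expect = list(category = "exonic_indel_frameshift", exon = 3L,
                     frame = "frameshift", ptc = TRUE, nmd = "degraded",
                     class = "reduced",
                     truncations = c(13L, 40L)),
       notes = paste("published span g.6948_6955del (8 nt) conflicts with",
                     "the stated 7-bp deletion; 7 nt planted"))
}

#' Weight-matrix with weight 1 for each consensus base, 0 otherwise
#' @param consensus nucleotide string.
#' @return An L x 4 numeric matrix (columns A, C, G, T).
#' @export
consensus_pwm <- function(consensus) {
  cs <- chars(toupper(consensus))
  w <- matrix(0, nrow = length(cs), ncol = 4,
              dimnames = list(NULL, c("A", "C", "G", "T")))
  w[cbind(seq_along(cs), match(cs, colnames(w)))] <- 1
  w
}

## Independent post-build verification of the fixture invariants: canonical
## wildtype splice sites, the planted lesion applying cleanly, and no
## unintended scan-window motif closer to the lost site than the planted
## cryptic site. Errors suggest retrying with a different seed, although
## the construction is designed to satisfy the invariants for every seed.
#' @noRd
verify_mimic <- function(fx) {
  fail <- function(...) {
    stop("fixture '", fx$name, "' (seed ", fx$seed, ") failed verification: ",
         ..., "; try a different seed", call. = FALSE)
  }
  if (length(validate_splice_sites(fx$model, fx$genome)) > 0) {
    fail("non-canonical wildtype splice site")
  }
  mg <- tryCatch(apply_mutation(fx$genome, fx$mutation),
                 error = function(e) fail(conditionMessage(e)))
  ex <- fx$expect
  if (!is.null(ex$intron)) {
    mm <- lift_model(fx$model, fx$mutation)
    window <- scan_params()$window_nt
    side <- if (ex$category == "ESS_donor") "donor" else "acceptor"
    motif <- if (side == "donor") "GT" else "AG"
    ctx <- site_context(mm, mg, ex$intron, side, window)
    hits <- scan_cryptic_sites(ctx$seq, motif, ctx$anchor, window)
    planted <- ex$cryptic_offset
    if (is.null(planted)) {
      if (nrow(hits) > 0) fail("unintended ", motif, " in the scan window")
    } else {
      if (nrow(hits) == 0 || hits$offset[1] != planted) {
        fail("nearest ", motif, " is not the planted cryptic site")
      }
      if (sum(abs(hits$offset) == abs(planted)) > 1) {
        fail("equidistant unintended ", motif, " beside the planted site")
      }
    }
  }
  if (!is.null(ex$truncations)) {
    ## internal cryptic acceptors of the neighbouring exon, checked by a
    ## direct dinucleotide scan independent of the scanner under test
    mm <- lift_model(fx$model, fx$mutation)
    k <- 2L
    e2 <- get_seq(mg, fx$name, mm$exons[k, "start"], mm$exons[k, "end"])
    ag <- motif_positions(e2, "AG")
    ag <- ag[ag + 1L <= scan_params()$window_nt]
    if (!identical(as.integer(ag + 1L), as.integer(ex$truncations))) {
      fail("planted exon-2 AG positions not recovered")
    }
  }
  invisible(TRUE)
}

#' Write a mimic fixture to disk
#'
#' Emits `genome.fa`, `annotation.gff3`, `mutations.tsv` (columns contig,
#' transcript_id, hgvs_g) and `expectations.json` under `dir`.
#'
#' @param fixture a [build_mimic()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mimic <- function(fixture, dir) {
  stopifnot(inherits(fixture, "mimic_fixture"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genome_fasta(fixture$genome, file.path(dir, "genome.fa"))
  write_annotation(list(fixture$model), file.path(dir, "annotation.gff3"))
  utils::write.table(
    data.frame(contig = fixture$name,
               transcript_id = fixture$model$transcript_id,
               hgvs_g = fixture$hgvs),
    file.path(dir, "mutations.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  jsonlite::write_json(
    c(list(name = fixture$name, seed = fixture$seed, notes = fixture$notes),
      fixture$expect),
    file.path(dir, "expectations.json"), auto_unbox = TRUE, pretty = TRUE)
  if (!is.null(fixture$ese_matrices)) {
    write_ese_matrices(fixture$ese_matrices, file.path(dir, "ese.tsv"))
  }
  invisible(dir)
}
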