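## Shared fixtures and independent oracles for the test suite.

## A small hand-written 3-exon plus-strand gene with known content:
##   contig: AAA | CC ATG GCA | GTACGCAG | GCTGCTGCT | GTTTTTAG | GCATAA GG | TTT
##            flank  exon1       intron1     exon2      intron2    exon3   flank
## CDS: ATG GCA GCT GCT GCT GCA TAA (spliced positions 3..23).
toy_fixture <- function() {
  e1 <- "CCATGGCA"; i1 <- "GTACGCAG"; e2 <- "GCTGCTGCT"
  i2 <- "GTTTTTAG"; e3 <- "GCATAAGG"
  contig <- paste0("AAA", e1, i1, e2, i2, e3, "TTT")
  genome <- genome_sequence(c(chrT = contig))
  s1 <- 4L
  exons <- cbind(start = c(s1, s1 + 16L, s1 + 33L),
                 end = c(s1 + 7L, s1 + 24L, s1 + 40L))
  model <- transcript_model("toygene", "toytx", "chrT", "+", exons,
                            cds_start = 3L, cds_end = 23L)
  list(genome = genome, model = model)
}

## Mirror a fixture onto the minus strand: reverse-complement the contig and
## flip all coordinates. The spliced mRNA and all downstream behaviour must
## be identical.
flip_fixture <- function(genome, model) {
  contig <- genome$contigs[[model$contig]]
  L <- nchar(contig)
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(contig)))
  g2 <- genome_sequence(stats::setNames(list(rc), model$contig))
  ex <- model$exons
  ex2 <- cbind(start = L - ex[, "end"] + 1L, end = L - ex[, "start"] + 1L)
  m2 <- transcript_model(model$gene_id, model$transcript_id, model$contig,
                         "-", ex2, model$cds_start, model$cds_end,
                         strict = FALSE)
  list(genome = g2, model = m2)
}

## Independent mutation-position flip for strand tests.
flip_mutation <- function(mut, L) {
  comp <- function(x) chartr("ACGT", "TGCA", x)
  mutation(mut$kind, L - mut$end + 1L, L - mut$start + 1L,
           ref = if (nzchar(mut$ref)) comp(mut$ref) else "",
           alt = if (nzchar(mut$alt)) comp(mut$alt) else "",
           contig = mut$contig)
}

## Row of a prediction report's table at a given rank.
outcome_row <- function(rep_, rank) {
  df <- as.data.frame(rep_)
  df[df$rank == rank, , drop = FALSE]
}

## Oracle: naive position-by-position dinucleotide search.
naive_dinuc_scan <- function(sequence, motif, anchor, window) {
  hits <- integer()
  for (p in seq_len(nchar(sequence) - 1L)) {
    if (substr(sequence, p, p + 1L) == motif && p != anchor &&
        abs(p - anchor) <= window) {
      hits <- c(hits, p)
    }
  }
  hits[order(abs(hits - anchor), hits - anchor)]
}

## Oracle: brute-force codon-table walk using a literal codon map.
codon_walk_translate <- function(cds) {
  tab <- as.list(Biostrings::GENETIC_CODE)
  out <- character()
  i <- 1L
  while (i + 2L <= nchar(cds)) {
    aa <- tab[[substr(cds, i, i + 2L)]]
    if (aa == "*") return(paste(out, collapse = ""))
    out <- c(out, aa)
    i <- i + 3L
  }
  paste(out, collapse = "")
}

## Random sense-codon string (no internal stop) for translation fixtures.
random_cds <- function(n_codons) {
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  sense <- setdiff(all3, c("TAA", "TAG", "TGA"))
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

## Random multi-exon gene with sequence, canonical splice sites and a clean
## ORF, built independently of the synthetic-data module.
random_gene <- function(n_exons = 4L, coding_lengths = NULL) {
  if (is.null(coding_lengths)) {
    coding_lengths <- sample(c(30L, 45L, 60L, 75L, 90L), n_exons,
                             replace = TRUE)
  }
  total <- sum(coding_lengths)
  total_codons <- (total - 6L) %/% 3L
  cds <- paste0("ATG", random_cds(total_codons), "TAA")
  stopifnot(nchar(cds) == total)
  cuts <- cumsum(coding_lengths)
  starts <- c(1L, head(cuts, -1L) + 1L)
  slices <- substring(cds, starts, cuts)
  rand <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                            collapse = "")
  introns <- replicate(n_exons - 1L,
                       paste0("GT", rand(sample(20:60, 1L)), "AG"))
  contig <- rand(10L)
  exons <- matrix(0L, n_exons, 2L, dimnames = list(NULL, c("start", "end")))
  for (i in seq_len(n_exons)) {
    exons[i, 1L] <- nchar(contig) + 1L
    contig <- paste0(contig, slices[i])
    exons[i, 2L] <- nchar(contig)
    if (i < n_exons) contig <- paste0(contig, introns[[i]])
  }
  contig <- paste0(contig, rand(10L))
  genome <- genome_sequence(c(chrR = contig))
  model <- transcript_model("rgene", "rtx", "chrR", "+", exons,
                            cds_start = 1L, cds_end = total)
  list(genome = genome, model = model, cds = cds,
       coding_lengths = coding_lengths)
}
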