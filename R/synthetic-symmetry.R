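#' Generate random transcript models with a controlled exon-symmetry excess
#'
#' Exon lengths are drawn so that P(length mod 3 == 0) = 1/3 +
#' `symmetry_excess`, with the remaining probability split evenly between
#' remainders 1 and 2. Base lengths are uniform on `exon_length_range`
#' before the remainder adjustment; exon counts per gene are uniform on
#' `exons_per_gene`. Only the exon structure matters for symmetry analyses,
#' so no genome sequence is produced; models are placed end to end on one
#' synthetic contig with fixed 100-nt introns. Deterministic per seed.
#'
#' @param n_genes number of transcripts to generate.
#' @param exons_per_gene integer range (length-2 vector) of exon counts.
#' @param exon_length_range integer range of exon lengths (minimum >= 10).
#' @param symmetry_excess probability bonus for remainder-0 lengths, in
#'   `[0, 2/3]`.
#' @param seed integer seed.
#' @return A list of [transcript_model()] objects.
#' @export
build_symmetry_genome <- function(n_genes, exons_per_gene = c(4L, 8L),
                                  exon_length_range = c(50L, 250L),
                                  symmetry_excess = 0, seed = 1L) {
  assert_that(is_scalar_int(n_genes) && n_genes >= 1, "invalid n_genes")
  assert_that(symmetry_excess >= 0 && symmetry_excess <= 2 / 3,
              "symmetry_excess must be in [0, 2/3]")
  assert_that(exon_length_range[1] >= 10, "exons shorter than 10 nt not ",
              "supported by the generator")
  withr::with_seed(as.integer(seed), {
    ex_vals <- seq(exons_per_gene[1], exons_per_gene[2])
    n_ex <- ex_vals[sample.int(length(ex_vals), n_genes, replace = TRUE)]
    total <- sum(n_ex)
    base <- sample(seq(exon_length_range[1], exon_length_range[2]), total,
                   replace = TRUE)
    p0 <- 1 / 3 + symmetry_excess
    rem <- sample(0:2, total, replace = TRUE,
                  prob = c(p0, (1 - p0) / 2, (1 - p0) / 2))
    len <- base - base %% 3L + rem
    len <- ifelse(len < exon_length_range[1], len + 3L, len)
    idx <- rep(seq_len(n_genes), n_ex)
    len_by_gene <- split(len, idx)
    pos <- 1L
    models <- vector("list", n_genes)
    for (g in seq_len(n_genes)) {
      lens <- len_by_gene[[g]]
      starts <- integer(length(lens))
      ends <- integer(length(lens))
      for (i in seq_along(lens)) {
        starts[i] <- pos
        ends[i] <- pos + lens[i] - 1L
        pos <- ends[i] + 101L  # fixed 100-nt introns / intergenic gap
      }
      splen <- sum(lens)
      models[[g]] <- transcript_model(
        gene_id = sprintf("simgene%05d", g),
        transcript_id = sprintf("simtx%05d", g),
        contig = "sim_contig", strand = "+",
        exons = cbind(start = starts, end = ends),
        cds_start = 1L, cds_end = max(3L, splen - splen %% 3L),
        strict = FALSE)
    }
    models
  })
}
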