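test_that("translation agrees with a brute-force codon walk", {
  withr::with_seed(51, {
    for (rep in 1:1000) {
      n <- sample(5:100, 1)
      cds <- paste0(random_cds(n), sample(c("TAA", "TAG", "TGA"), 1))
      rg_mrna <- paste0("CC", cds, "GGAA")  # 2-nt leader, trailer
      wt <- orf_reference(
        transcript_model("g", "t", "c1", "+",
                         cbind(start = 1, end = nchar(rg_mrna)),
                         cds_start = 3, cds_end = 2 + nchar(cds)),
        genome_sequence(c(c1 = rg_mrna)))
      expect_identical(wt$protein, codon_walk_translate(cds))
    }
  })
})

test_that("protein diff decomposes removals and gains", {
  d <- diff_protein("MKSLV", "MKLV")
  expect_identical(d$aa_removed, 1L)
  expect_identical(d$removed_residues, "S")
  expect_identical(d$frame_status, "maintained")

  d2 <- diff_protein("MKSLV", "MKSLV")
  expect_identical(c(d2$aa_removed, d2$aa_gained), c(0L, 0L))

  d3 <- diff_protein("MKSLVAAAQ", "MKSLVR")
  expect_identical(d3$frame_status, "frameshift")
  expect_identical(d3$aa_gained, 1L)
})

test_that("NMD classification flips exactly once across the threshold", {
  junctions <- c(100L, 400L, 700L)
  calls <- vapply(1:100, function(d) {
    classify_nmd(700L - d, junctions)
  }, character(1))
  expect_identical(unique(calls[1:55]), "escape")
  expect_identical(unique(calls[56:100]), "degraded")
  expect_identical(sum(calls[-1] != calls[-length(calls)]), 1L)

  ## 1 nt upstream of the last junction: escape; far upstream: degraded
  expect_identical(classify_nmd(699L, junctions), "escape")
  expect_identical(classify_nmd(500L, junctions), "degraded")
  ## downstream of the last junction (terminal exon): escape
  expect_identical(classify_nmd(750L, junctions), "escape")
  ## single-exon transcripts always escape
  expect_identical(classify_nmd(10L, integer()), "escape")
})

test_that("moving a PTC upstream never flips degraded back to escape", {
  junctions <- c(120L, 300L)
  prev <- "escape"
  for (d in 1:200) {
    cur <- classify_nmd(300L - d + 1L, junctions)
    expect_false(prev == "degraded" && cur == "escape")
    prev <- cur
  }
})

test_that("a configurable threshold shifts the flip point", {
  junctions <- c(50L, 200L)
  p <- nmd_params(50L)
  expect_identical(classify_nmd(150L, junctions, p), "escape")   # 50 nt
  expect_identical(classify_nmd(149L, junctions, p), "degraded") # 51 nt
  expect_warning(nmd_params(80L), "outside the standard")
})

test_that("the wildtype structure reproduces the wildtype protein exactly", {
  withr::with_seed(52, {
    for (rep in 1:10) {
      rg <- random_gene(n_exons = sample(2:5, 1))
      wt <- orf_reference(rg$model, rg$genome)
      identity <- splicefate:::splice_outcome("unspliced_ptc",
                                              rg$model$exons, 0L)
      cn <- consequence(identity, rg$model, rg$genome, wt)
      expect_identical(cn$protein, wt$protein)
      expect_identical(cn$frame_status, "maintained")
      expect_identical(cn$aa_removed, 0L)
      expect_identical(cn$nmd_predicted, "not_applicable")
      expect_identical(cn$transcript_level_class, "WT_like")
    }
  })
})

test_that("exon-skip frame status follows mod-3 arithmetic", {
  withr::with_seed(53, {
    for (rep in 1:20) {
      ## in-frame and frameshifting middle exons (junction codons unchanged
      ## for multiples of 3 because exon boundaries are codon-aligned here)
      lens <- sample(c(30L, 45L, 60L), 3L, replace = TRUE)
      shift_len <- sample(c(31L, 44L, 61L), 1L)
      l2 <- if (rep %% 2) lens[2] else shift_len
      partial <- lens[1] + l2 + lens[3]
      l4 <- 33L + (3L - partial %% 3L) %% 3L
      rg <- random_gene(n_exons = 4L,
                        coding_lengths = c(lens[1], l2, lens[3], l4))
      skipped_len <- rg$coding_lengths[2]
      skip <- splicefate:::splice_outcome(
        "exon_skip", rg$model$exons[-2, , drop = FALSE], -skipped_len)
      wt <- orf_reference(rg$model, rg$genome)
      cn <- consequence(skip, rg$model, rg$genome, wt)
      expect_identical(cn$frame_status,
                       if (skipped_len %% 3L == 0L) "maintained"
                       else "frameshift",
                       info = paste("skipped", skipped_len))
      if (skipped_len %% 3L == 0L) {
        expect_identical(cn$aa_removed, skipped_len %/% 3L)
        expect_identical(cn$aa_gained, 0L)
      }
    }
  })
})

test_that("skipping the start-codon exon flags start-lost", {
  withr::with_seed(54, {
    rg <- random_gene(n_exons = 3, coding_lengths = c(30L, 60L, 30L))
    skip1 <- splicefate:::splice_outcome(
      "exon_skip", rg$model$exons[-1, , drop = FALSE], -30L)
    wt <- orf_reference(rg$model, rg$genome)
    cn <- consequence(skip1, rg$model, rg$genome, wt)
    expect_true("start_lost" %in% cn$flags)
    expect_identical(cn$protein, "")
    expect_identical(cn$nmd_predicted, "not_applicable")
  })
})
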