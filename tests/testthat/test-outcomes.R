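test_that("cryptic-site scanning matches a brute-force dinucleotide oracle", {
  withr::with_seed(41, {
    for (rep in 1:1000) {
      n <- sample(50:300, 1)
      seq <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                   collapse = "")
      motif <- sample(c("GT", "AG"), 1)
      anchor <- sample(seq_len(n), 1)
      window <- sample(c(10L, 50L, 100L), 1)
      got <- scan_cryptic_sites(seq, motif, anchor, window)
      expect_identical(got$position,
                       naive_dinuc_scan(seq, motif, anchor, window))
      expect_identical(got$offset, got$position - anchor)
    }
  })
})

test_that("scanning an empty window yields an empty result", {
  got <- scan_cryptic_sites("CCCCCCCCCC", "GT", 5, 4)
  expect_identical(nrow(got), 0L)
})

test_that("donor loss proposes skip of the upstream exon first", {
  fx <- build_mimic("slc27a2a_mimic", seed = 1)
  cl <- classify_mutation(fx$model, fx$genome, fx$mutation)
  expect_identical(cl$category, "ESS_donor")
  expect_identical(cl$affected_intron_index, 2L)
  mg <- apply_mutation(fx$genome, fx$mutation)
  out <- enumerate_outcomes(fx$model, mg, cl)
  expect_identical(out[[1]]$kind, "exon_skip")
  expect_identical(out[[1]]$rank, 1L)
  expect_identical(out[[1]]$delta_nt, -210L)
  ## window is clean by construction: no cryptic candidates
  expect_false(any(vapply(out, function(o) startsWith(o$kind, "cryptic"),
                          logical(1))))
  ## ranks unique and sequential
  expect_identical(vapply(out, `[[`, integer(1), "rank"),
                   seq_along(out))
})

test_that("acceptor loss before a terminal exon yields no skip candidate", {
  fx <- build_mimic("pla2g12b_mimic", seed = 1)
  cl <- classify_mutation(fx$model, fx$genome, fx$mutation)
  expect_identical(cl$category, "ESS_acceptor")
  mg <- apply_mutation(fx$genome, fx$mutation)
  out <- enumerate_outcomes(fx$model, mg, cl)
  kinds <- vapply(out, `[[`, character(1), "kind")
  expect_identical(sort(kinds), c("intron_retention", "no_rescue"))
  expect_identical(kinds[1], "no_rescue")
})

test_that("cryptic candidates carry the planted offsets and deltas", {
  ## acceptor side: AG at exon bases 2-3, offset 3, removes 3 nt
  fx <- build_mimic("abca1a_mimic", seed = 2)
  cl <- classify_mutation(fx$model, fx$genome, fx$mutation)
  mg <- apply_mutation(fx$genome, fx$mutation)
  out <- enumerate_outcomes(fx$model, mg, cl)
  ca <- Filter(function(o) o$kind == "cryptic_acceptor", out)
  expect_length(ca, 1)
  expect_identical(ca[[1]]$site_offset, 3L)
  expect_identical(ca[[1]]$delta_nt, -3L)

  ## donor side: mutant intron ATATGT..., GT at +4, retains 4 nt
  fx <- build_mimic("cd36_mimic", seed = 2)
  mg <- apply_mutation(fx$genome, fx$mutation)
  expect_identical(substr(intron_sequence(fx$model, mg, 10), 1, 6), "ATATGT")
  cl <- classify_mutation(fx$model, fx$genome, fx$mutation)
  out <- enumerate_outcomes(fx$model, mg, cl)
  cd <- Filter(function(o) o$kind == "cryptic_donor", out)
  expect_length(cd, 1)
  expect_identical(cd[[1]]$site_offset, 4L)
  expect_identical(cd[[1]]$delta_nt, 4L)
})

test_that("every outcome's exons reconstruct a length consistent with delta", {
  for (nm in c("slc27a2a_mimic", "abca1b_mimic", "abca1a_mimic",
               "cd36_mimic")) {
    fx <- build_mimic(nm, seed = 3)
    cl <- classify_mutation(fx$model, fx$genome, fx$mutation)
    mg <- apply_mutation(fx$genome, fx$mutation)
    wt_len <- spliced_length(fx$model)
    for (o in enumerate_outcomes(fx$model, mg, cl)) {
      got <- sum(o$modified_exons[, "end"] - o$modified_exons[, "start"] + 1L)
      expect_identical(got, wt_len + o$delta_nt, info = paste(nm, o$kind))
    }
  }
})

test_that("nonsense mutations enumerate the unspliced PTC and the skip", {
  fx <- build_mimic("creb3l3a_mimic", seed = 1)
  cl <- classify_mutation(fx$model, fx$genome, fx$mutation)
  expect_identical(cl$category, "exonic_nonsense")
  mg <- apply_mutation(fx$genome, fx$mutation)
  out <- enumerate_outcomes(fx$model, mg, cl)
  kinds <- vapply(out, `[[`, character(1), "kind")
  expect_identical(kinds, c("unspliced_ptc", "exon_skip"))
  expect_identical(out[[2]]$delta_nt, -114L)
})

test_that("unsupported classifications are rejected explicitly", {
  fx <- toy_fixture()
  cl <- classify_mutation(fx$model, fx$genome,
    mutation("substitution", 15, 15, "C", "G", contig = "chrT"))
  expect_identical(cl$category, "intronic_other")
  expect_error(enumerate_outcomes(fx$model, fx$genome, cl),
               "no outcome enumeration")
})

test_that("intron retention is proposed for short and terminal introns only", {
  withr::with_seed(42, {
    rg <- random_gene(n_exons = 3, coding_lengths = c(30L, 60L, 30L))
    ## mutate donor of intron 1 (short: always proposed)
    ex <- rg$model$exons
    dpos <- ex[1, "end"] + 1L
    mut <- mutation("substitution", dpos, dpos, "G", "A", contig = "chrR")
    cl <- classify_mutation(rg$model, rg$genome, mut)
    mg <- apply_mutation(rg$genome, mut)
    out <- enumerate_outcomes(rg$model, mg, cl)
    expect_true("intron_retention" %in%
                  vapply(out, `[[`, character(1), "kind"))
    ## with a tiny retention threshold, intron 1 (non-terminal) is dropped
    out2 <- enumerate_outcomes(rg$model, mg, cl,
                               scan_params(intron_retention_max_nt = 5L))
    expect_false("intron_retention" %in%
                   vapply(out2, `[[`, character(1), "kind"))
    ## but the terminal intron is always proposed
    apos <- ex[3, "start"] - 1L
    mut2 <- mutation("substitution", apos, apos, "G", "A", contig = "chrR")
    cl2 <- classify_mutation(rg$model, rg$genome, mut2)
    mg2 <- apply_mutation(rg$genome, mut2)
    out3 <- enumerate_outcomes(rg$model, mg2, cl2,
                               scan_params(intron_retention_max_nt = 5L))
    expect_true("intron_retention" %in%
                  vapply(out3, `[[`, character(1), "kind"))
  })
})

test_that("the neighbour-exon scan equals a brute-force AG enumeration", {
  fx <- build_mimic("smyd1a_mimic", seed = 4)
  mg <- apply_mutation(fx$genome, fx$mutation)
  mm <- lift_model(fx$model, fx$mutation)
  out <- neighbor_exon_scan(mm, mg, 2L)
  expect_identical(vapply(out, `[[`, integer(1), "delta_nt"),
                   c(-13L, -40L))
  expect_identical(vapply(out, `[[`, integer(1), "site_offset"),
                   c(13L, 40L))
  ## oracle: direct dinucleotide check over the exon sequence
  ex <- mm$exons
  eseq <- get_seq(mg, mm$contig, ex[2, "start"], ex[2, "end"])
  expected <- integer()
  for (p in seq_len(nchar(eseq) - 2L)) {
    if (substr(eseq, p, p + 1L) == "AG" && p + 1L <= 100L) {
      expected <- c(expected, p + 1L)
    }
  }
  expect_identical(vapply(out, `[[`, integer(1), "site_offset"), expected)

  ## no AG within a tighter window (nearest planted site is at offset 13)
  out2 <- neighbor_exon_scan(mm, mg, 2L, scan_params(window_nt = 10L))
  expect_length(out2, 0)
})
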