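## minimal models with prescribed exon lengths, for summary tests
length_models <- function(length_sets) {
  lapply(seq_along(length_sets), function(i) {
    lens <- length_sets[[i]]
    starts <- cumsum(c(1L, head(lens, -1L) + 100L))
    splen <- sum(lens)
    transcript_model(sprintf("g%d", i), sprintf("t%d", i), "c1", "+",
                     cbind(start = starts, end = starts + lens - 1L),
                     1L, max(3L, splen - splen %% 3L), strict = FALSE)
  })
}

test_that("remainder counts per exon index match known exon lengths", {
  models <- length_models(list(c(90L, 114L, 60L), c(90L, 210L, 60L),
                               c(90L, 116L, 60L)))
  s <- summarize_symmetry(models, max_index = 3)
  i2 <- s[s$exon_index == 2, ]
  expect_identical(c(i2$count_r0, i2$count_r1, i2$count_r2), c(2L, 0L, 1L))
  expect_identical(i2$n_exons, 3L)
  ## all-divisible exons give pct_r0 = 100 everywhere
  s2 <- summarize_symmetry(length_models(list(c(3L, 3L), c(3L, 3L))),
                           max_index = 2)
  expect_identical(s2$pct_r0, c(100, 100))
})

test_that("percentages sum to 100 and counts to n at every index", {
  models <- build_symmetry_genome(200, seed = 71)
  s <- summarize_symmetry(models)
  ok <- !is.na(s$pct_r0)
  expect_true(all(abs(s$pct_r0[ok] + s$pct_r1[ok] + s$pct_r2[ok] - 100) <
                    0.01))
  expect_identical(s$count_r0 + s$count_r1 + s$count_r2, s$n_exons)
})

test_that("chi-squared statistic matches hand computation and chisq.test", {
  u <- chi_squared_uniform(c(10, 10, 10))
  expect_identical(u$statistic, 0)
  expect_identical(u$p_value, 1)

  h <- chi_squared_uniform(c(20, 10, 0))
  expect_equal(h$statistic, 20.0)
  expect_identical(h$df, 2L)

  ## independent cross-check against stats::chisq.test
  withr::with_seed(72, {
    for (rep in 1:20) {
      counts <- sample(0:50, 3, replace = TRUE)
      if (sum(counts) == 0) next
      mine <- chi_squared_uniform(counts)
      ref <- suppressWarnings(stats::chisq.test(counts, p = rep(1 / 3, 3)))
      expect_equal(mine$statistic, unname(ref$statistic))
      expect_equal(mine$p_value, unname(ref$p.value))
    }
  })
  expect_error(chi_squared_uniform(c(0, 0, 0)), "zero total")
})

test_that("df = 2 p-values equal the closed form exp(-x/2)", {
  withr::with_seed(74, {
    for (rep in 1:50) {
      counts <- sample(1:60, 3, replace = TRUE)
      u <- chi_squared_uniform(counts)
      expect_equal(u$p_value, exp(-u$statistic / 2), tolerance = 1e-10)
    }
  })
  for (x in c(0.1, 1, 5, 20)) {
    expect_equal(stats::pchisq(x, 2, lower.tail = FALSE), exp(-x / 2),
                 tolerance = 1e-12)
  }
})

test_that("excess over chance reproduces the reference percentages", {
  models <- length_models(list(c(90L, 114L), c(90L, 210L), c(90L, 117L)))
  s <- summarize_symmetry(models, max_index = 2)
  expect_equal(excess_over_chance(s, 2), 100 - 33.33)
  ## direct arithmetic checks on the definition
  expect_equal(38.43 - 33.33, 5.1, tolerance = 1e-9)
  expect_equal(40.53 - 33.33, 7.2, tolerance = 1e-9)
})

test_that("the summary is invariant under transcript order", {
  models <- build_symmetry_genome(100, seed = 73)
  s1 <- summarize_symmetry(models)
  s2 <- summarize_symmetry(rev(models))
  expect_equal(s1, s2, ignore_attr = TRUE)
})

test_that("cds-only mode measures coding widths", {
  ## one model: exon spans 90/114/60 but CDS covers only part of exons 1,3
  m <- transcript_model("g", "t", "c1", "+",
                        cbind(start = c(1L, 200L, 400L),
                              end = c(90L, 313L, 459L)),
                        cds_start = 31L, cds_end = 234L, strict = FALSE)
  s_full <- summarize_symmetry(list(m), max_index = 3)
  s_cds <- summarize_symmetry(list(m), max_index = 3, cds_only = TRUE)
  expect_identical(s_full$n_exons, c(1L, 1L, 1L))
  ## coding widths: exon1 90-30=60, exon2 114, exon3 234-204=30
  expect_identical(s_cds$count_r0, c(1L, 1L, 1L))
})

test_that("gene-level deduplication keeps one transcript per gene", {
  m1 <- length_models(list(c(90L, 114L)))[[1]]
  m2 <- m1; m2$transcript_id <- "t1b"; m2$exons[2, ] <- c(301L, 401L)
  s <- summarize_symmetry(list(m1, m2), max_index = 2, dedupe_genes = TRUE)
  expect_identical(s$n_exons, c(1L, 1L))
})
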