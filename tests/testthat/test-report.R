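test_that("end-to-end prediction renders the summary-table phrases", {
  fx <- build_mimic("slc27a2a_mimic", seed = 1)
  rep_ <- predict_outcomes(fx$genome, fx$model, fx$mutation)
  df <- as.data.frame(rep_)
  expect_identical(df$outcome_phrase[df$rank == 1],
                   "skipped exon (210 bp), frame maintained")
  expect_identical(df$transcript_level_class[df$rank == 1], "WT-like")

  fx <- build_mimic("abca1b_mimic", seed = 1)
  rep_ <- predict_outcomes(fx$genome, fx$model, fx$mutation)
  df <- as.data.frame(rep_)
  expect_match(df$outcome_phrase[df$rank == 1], "frame shift, PTC")
  expect_identical(df$transcript_level_class[df$rank == 1], "reduced")

  fx <- build_mimic("abca1a_mimic", seed = 1)
  rep_ <- predict_outcomes(fx$genome, fx$model, fx$mutation)
  df <- as.data.frame(rep_)
  cr <- df[df$kind == "cryptic_acceptor", ]
  expect_identical(cr$outcome_phrase, paste0(
    "downstream cryptic splice site used, loss of single Serine, ",
    "frame maintained"))
})

test_that("reports carry the fixed caveat flag and ESE annotation", {
  fx <- build_mimic("creb3l3a_mimic", seed = 1)
  rep_ <- predict_outcomes(fx$genome, fx$model, fx$mutation,
                           ese_matrices = fx$ese_matrices)
  df <- as.data.frame(rep_)
  expect_true(all(grepl("pseudo_exon_not_evaluated", df$flags)))
  expect_true(all(df$in_ese))
  expect_identical(nrow(rep_$ese$lost_hits), 1L)
})

test_that("TSV and JSON renderings contain identical structured values", {
  fx <- build_mimic("cd36_mimic", seed = 1)
  rep_ <- predict_outcomes(fx$genome, fx$model, fx$mutation)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  json <- withr::local_tempfile(fileext = ".json")
  write_report(rep_, tsv = tsv, json = json)
  df_tsv <- utils::read.delim(tsv)
  df_json <- jsonlite::fromJSON(json)
  for (col in c("rank", "kind", "delta_nt", "frame_status", "nmd_predicted",
                "transcript_level_class")) {
    expect_equal(df_tsv[[col]], df_json[[col]], info = col)
  }
})

test_that("re-running a prediction yields identical output", {
  fx <- build_mimic("pla2g12b_mimic", seed = 3)
  r1 <- as.data.frame(predict_outcomes(fx$genome, fx$model, fx$mutation))
  r2 <- as.data.frame(predict_outcomes(fx$genome, fx$model, fx$mutation))
  expect_identical(r1, r2)
})

test_that("batch prediction survives a malformed row", {
  fx <- build_mimic("slc27a2a_mimic", seed = 1)
  models <- stats::setNames(list(fx$model), fx$model$transcript_id)
  muts <- data.frame(
    contig = fx$name, transcript_id = fx$model$transcript_id,
    hgvs_g = c("g.3431G>A", "g.10_9del"), stringsAsFactors = FALSE)
  df <- predict_batch(fx$genome, models, muts)
  expect_true(any(df$status == "ok"))
  bad <- df[df$status != "ok", ]
  expect_identical(nrow(bad), 1L)
  expect_match(bad$status, "end < start")
})

test_that("the design checklist reports the four pre-design checks", {
  fx <- build_mimic("slc27a2a_mimic", seed = 1)
  cl <- design_checklist(fx$genome, fx$model, 2)
  expect_identical(cl$exon_length, 210L)
  expect_true(cl$divisible_by_3)
  expect_match(cl$skip_tolerance, "skip-tolerant")
  expect_identical(cl$upstream_intron_nt, 154L)
  expect_true(cl$retention_risk)   # short upstream intron

  fx2 <- build_mimic("abca1b_mimic", seed = 1)
  cl2 <- design_checklist(fx2$genome, fx2$model, 34)
  expect_identical(cl2$exon_length, 116L)
  expect_false(cl2$divisible_by_3)
  expect_match(cl2$skip_tolerance, "not divisible")
  ## window around exon 34's splice sites is engineered AG-free upstream
  expect_identical(nrow(cl2$cryptic_near_acceptor), 0L)
})

test_that("the command-line wrapper runs fixtures and predict", {
  script <- system.file("cli", "splicefate.R", package = "splicefate")
  expect_true(nzchar(script))
  dir <- withr::local_tempdir()
  out <- system2("Rscript", c(script, "fixtures", "--out-dir",
                              shQuote(dir), "--seed", "1", "--name",
                              "slc27a2a_mimic"),
                 stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(file.path(dir, "slc27a2a_mimic", "genome.fa")))
  tsv <- file.path(dir, "predict.tsv")
  out2 <- system2("Rscript", c(
    script, "predict",
    "--genome", file.path(dir, "slc27a2a_mimic", "genome.fa"),
    "--annotation", file.path(dir, "slc27a2a_mimic", "annotation.gff3"),
    "--transcript", "slc27a2a_mimic_tx", "--mutation", shQuote("g.3431G>A"),
    "--out-tsv", tsv), stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(tsv))
  df <- utils::read.delim(tsv)
  expect_identical(df$outcome_phrase[df$rank == 1],
                   "skipped exon (210 bp), frame maintained")
})
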