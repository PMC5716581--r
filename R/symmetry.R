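#' Chi-squared goodness-of-fit against a uniform 1/3 split
#'
#' For remainder counts (r0, r1, r2): statistic = sum (O - N/3)^2 / (N/3),
#' df = 2, p from the chi-squared survival function. With 2 degrees of
#' freedom the p-value has the closed form exp(-statistic / 2).
#'
#' @param counts three non-negative integers (remainders 0, 1, 2).
#' @return A list with `statistic`, `df` (always 2) and `p_value`.
#' @export
chi_squared_uniform <- function(counts) {
  assert_that(length(counts) == 3 && all(counts >= 0),
              "counts must be three non-negative numbers")
  total <- sum(counts)
  assert_that(total > 0, "zero total count")
  expected <- total / 3
  statistic <- sum((counts - expected)^2 / expected)
  list(statistic = statistic, df = 2L,
       p_value = stats::pchisq(statistic, df = 2, lower.tail = FALSE))
}

#' Exon length mod-3 symmetry summary
#'
#' For each exon index i (1..`max_index`), every transcript with at least i
#' exons contributes the length of its i-th exon; lengths are reduced mod 3
#' and the remainder distribution is tested against the uniform 1/3 split.
#' An exon divisible by 3 is "symmetric": its skip preserves the reading
#' frame. By default the annotated exon span (including any UTR portion) is
#' measured; `cds_only = TRUE` instead measures each exon's coding width
#' (exons without coding sequence are dropped). Exons shared by several
#' transcripts count once per transcript; pass `dedupe_genes = TRUE` to
#' count each gene's i-th exon once (first transcript per gene).
#'
#' @param models list of [transcript_model()] objects.
#' @param max_index largest exon index summarised.
#' @param cds_only measure coding widths instead of full exon spans.
#' @param dedupe_genes keep one transcript per gene.
#' @return A data.frame of class `symmetry_summary` with one row per exon
#'   index: `exon_index`, `n_exons`, `count_r0/1/2`, `pct_r0/1/2`,
#'   `chi2_stat`, `p_value`, `excess_r0` (pct_r0 - 33.33).
#' @export
summarize_symmetry <- function(models, max_index = 10L, cds_only = FALSE,
                               dedupe_genes = FALSE) {
  assert_that(length(models) > 0, "no transcript models supplied")
  if (dedupe_genes) {
    genes <- vapply(models, `[[`, character(1), "gene_id")
    models <- models[!duplicated(genes)]
  }
  len_list <- lapply(models, function(m) {
    if (!cds_only) {
      exon_lengths(m)
    } else {
      cum <- c(0L, cumsum(exon_lengths(m)))
      w <- vapply(seq_len(n_exons(m)), function(i) {
        max(0L, min(m$cds_end, cum[i + 1L]) - max(m$cds_start, cum[i] + 1L) +
              1L)
      }, integer(1))
      w
    }
  })
  rows <- lapply(seq_len(max_index), function(i) {
    lens <- unlist(lapply(len_list, function(v) {
      if (length(v) >= i && v[i] > 0) v[i] else NULL
    }))
    if (length(lens) == 0) {
      return(data.frame(exon_index = i, n_exons = 0L, count_r0 = 0L,
                        count_r1 = 0L, count_r2 = 0L, pct_r0 = NA_real_,
                        pct_r1 = NA_real_, pct_r2 = NA_real_,
                        chi2_stat = NA_real_, p_value = NA_real_,
                        excess_r0 = NA_real_))
    }
    counts <- tabulate(lens %% 3L + 1L, nbins = 3L)
    pct <- 100 * counts / sum(counts)
    chi <- chi_squared_uniform(counts)
    data.frame(exon_index = i, n_exons = sum(counts),
               count_r0 = counts[1], count_r1 = counts[2],
               count_r2 = counts[3], pct_r0 = pct[1], pct_r1 = pct[2],
               pct_r2 = pct[3], chi2_stat = chi$statistic,
               p_value = chi$p_value, excess_r0 = pct[1] - 33.33)
  })
  structure(do.call(rbind, rows),
            class = c("symmetry_summary", "data.frame"))
}

#' Percentage-point excess of symmetric exons over chance
#'
#' @param summary a [summarize_symmetry()] result.
#' @param index exon index of interest.
#' @return `pct_r0 - 33.33` at that index, in percentage points.
#' @export
excess_over_chance <- function(summary, index) {
  stopifnot(inherits(summary, "symmetry_summary"))
  row <- summary[summary$exon_index == index, ]
  assert_that(nrow(row) == 1, "exon index ", index, " not in summary")
  row$pct_r0 - 33.33
}

#' @export
print.symmetry_summary <- function(x, ...) {
  y <- as.data.frame(x)
  y$p_value <- ifelse(!is.na(y$p_value) & y$p_value < 2.2e-16, "< 2.2e-16",
                      format(y$p_value, digits = 3))
  for (col in c("pct_r0", "pct_r1", "pct_r2", "chi2_stat", "excess_r0")) {
    y[[col]] <- round(y[[col]], 2)
  }
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Write a symmetry summary as TSV
#'
#' p-values below 2.2e-16 are written as "< 2.2e-16" in the text output by
#' convention; use [jsonlite::write_json()] on the data.frame for exact
#' values.
#'
#' @param summary a [summarize_symmetry()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_symmetry_tsv <- function(summary, path) {
  stopifnot(inherits(summary, "symmetry_summary"))
  y <- as.data.frame(summary)
  y$p_value <- ifelse(!is.na(y$p_value) & y$p_value < 2.2e-16, "< 2.2e-16",
                      format(y$p_value, digits = 6))
  utils::write.table(y, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Bar chart of remainder percentages per exon index
#'
#' @param summary a [summarize_symmetry()] result.
#' @param ... passed to [graphics::barplot()].
#' @return The summary, invisibly.
#' @export
plot_symmetry <- function(summary, ...) {
  stopifnot(inherits(summary, "symmetry_summary"))
  m <- t(as.matrix(summary[, c("pct_r0", "pct_r1", "pct_r2")]))
  graphics::barplot(m, beside = TRUE, names.arg = summary$exon_index,
                    xlab = "exon index", ylab = "% of exons",
                    legend.text = c("remainder 0", "remainder 1",
                                    "remainder 2"), ...)
  graphics::abline(h = 100 / 3, lty = 2)
  invisible(summary)
}
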