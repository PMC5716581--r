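#' Exonic splice enhancer position-weight matrix
#'
#' A simple additive PWM: the score of a window is the sum of the
#' per-position weights of its bases, and a window is a hit when its score
#' reaches the matrix threshold (the usage pattern of web-based ESE
#' prediction tools). No log-odds conversion is applied.
#'
#' @param name matrix name.
#' @param weights numeric L x 4 matrix, columns A, C, G, T, L >= 4.
#' @param threshold hit cutoff.
#' @return An object of class `ese_matrix`.
#' @export
ese_matrix <- function(name, weights, threshold) {
  weights <- as.matrix(weights)
  assert_that(ncol(weights) == 4, "weights must have 4 columns (A,C,G,T)")
  assert_that(nrow(weights) >= 4, "ESE matrices must have length >= 4")
  assert_that(is.numeric(threshold) && length(threshold) == 1 &&
                !is.na(threshold), "threshold must be a number")
  assert_that(!anyNA(weights), "all four bases must be scored at every ",
              "position")
  colnames(weights) <- c("A", "C", "G", "T")
  structure(list(name = as.character(name), weights = weights,
                 threshold = as.numeric(threshold)), class = "ese_matrix")
}

#' @export
print.ese_matrix <- function(x, ...) {
  cat("<ese_matrix> ", x$name, ": length ", nrow(x$weights),
      ", threshold ", x$threshold, "\n", sep = "")
  invisible(x)
}

#' Consensus sequence of an ESE matrix (argmax base per position)
#' @param matrix an [ese_matrix()].
#' @return A nucleotide string.
#' @export
ese_consensus <- function(matrix) {
  paste(colnames(matrix$weights)[apply(matrix$weights, 1, which.max)],
        collapse = "")
}

#' Load ESE matrices from a tab-delimited file
#'
#' Format: each matrix starts with a header line `>NAME<TAB>THRESHOLD`,
#' followed by L rows of four tab-separated scores in A, C, G, T order.
#' Multiple matrices may share one file.
#'
#' @param path path to the matrix file.
#' @return A list of [ese_matrix()] objects.
#' @export
load_ese_matrices <- function(path) {
  assert_that(file.exists(path), "file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines)]
  out <- list()
  cur_name <- NULL
  cur_thresh <- NULL
  cur_rows <- list()
  flush <- function() {
    if (is.null(cur_name)) return()
    assert_that(length(cur_rows) >= 4,
                "matrix '", cur_name, "' has fewer than 4 positions")
    out[[length(out) + 1L]] <<- ese_matrix(
      cur_name, do.call(rbind, cur_rows), cur_thresh)
  }
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln))) next
    if (startsWith(ln, ">")) {
      flush()
      fields <- strsplit(sub("^>", "", ln), "\t", fixed = TRUE)[[1]]
      assert_that(length(fields) >= 2 && !is.na(suppressWarnings(
        as.numeric(fields[2]))),
        "line ", i, ": matrix header needs '>NAME<TAB>THRESHOLD'")
      cur_name <- fields[1]
      cur_thresh <- as.numeric(fields[2])
      cur_rows <- list()
    } else {
      vals <- suppressWarnings(
        as.numeric(strsplit(ln, "\t", fixed = TRUE)[[1]]))
      assert_that(length(vals) == 4 && !anyNA(vals),
                  "line ", i, ": expected 4 tab-separated scores, got '",
                  ln, "'")
      cur_rows[[length(cur_rows) + 1L]] <- vals
    }
  }
  flush()
  assert_that(length(out) > 0, "no matrices found in '", path, "'")
  out
}

#' Write ESE matrices in the package's tab-delimited format
#' @param matrices list of [ese_matrix()] objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ese_matrices <- function(matrices, path) {
  if (inherits(matrices, "ese_matrix")) matrices <- list(matrices)
  con <- file(path, "wt")
  on.exit(close(con))
  for (m in matrices) {
    writeLines(paste0(">", m$name, "\t", m$threshold), con)
    utils::write.table(m$weights, con, sep = "\t", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' Scan a sequence with ESE matrices
#'
#' Slides each matrix over the sequence; every window whose additive score
#' reaches the matrix threshold is reported. Windows containing bases
#' outside A/C/G/T (e.g. N) are excluded.
#'
#' @param sequence nucleotide string (length >= matrix length).
#' @param matrices a list of [ese_matrix()] objects (or a single one).
#' @return A data.frame with columns `matrix_name`, `start` (1-based window
#'   start), `score`, ordered by start then name (independent of the input
#'   matrix order).
#' @export
scan_ese <- function(sequence, matrices) {
  if (inherits(matrices, "ese_matrix")) matrices <- list(matrices)
  sequence <- toupper(sequence)
  cs <- chars(sequence)
  res <- list()
  for (m in matrices) {
    L <- nrow(m$weights)
    if (nchar(sequence) < L) next
    idx <- match(cs, c("A", "C", "G", "T"))
    for (s in seq_len(nchar(sequence) - L + 1L)) {
      b <- idx[s:(s + L - 1L)]
      if (anyNA(b)) next
      score <- sum(m$weights[cbind(seq_len(L), b)])
      if (score >= m$threshold) {
        res[[length(res) + 1L]] <- data.frame(
          matrix_name = m$name, start = s, score = score,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(res) == 0) {
    return(data.frame(matrix_name = character(), start = integer(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, res)
  out[order(out$start, out$matrix_name), , drop = FALSE]
}

#' Does a point mutation disrupt a predicted exonic splice enhancer?
#'
#' Scans the wildtype exon sequence, keeps the hits whose window covers the
#' mutated offset, and reports which of them drop below their matrix
#' threshold in the mutant sequence (lost hits).
#'
#' @param exon_seq_wt,exon_seq_mut wildtype and mutant exon sequences; must
#'   differ at exactly one position.
#' @param mutation_offset 1-based offset of the difference.
#' @param matrices list of [ese_matrix()] objects.
#' @return A list with `in_ese` (TRUE when some wildtype hit covers the
#'   offset) and `lost_hits` (data.frame of wildtype hits that fall below
#'   threshold in the mutant).
#' @export
mutation_in_ese <- function(exon_seq_wt, exon_seq_mut, mutation_offset,
                            matrices) {
  assert_that(nchar(exon_seq_wt) == nchar(exon_seq_mut),
              "wildtype and mutant sequences differ in length")
  diffs <- which(chars(exon_seq_wt) != chars(exon_seq_mut))
  assert_that(length(diffs) == 1,
              "sequences must differ at exactly one position (found ",
              length(diffs), ")")
  assert_that(diffs == mutation_offset,
              "sequences differ at ", diffs, ", not at mutation_offset = ",
              mutation_offset)
  if (inherits(matrices, "ese_matrix")) matrices <- list(matrices)
  wt_hits <- scan_ese(exon_seq_wt, matrices)
  lens <- stats::setNames(
    vapply(matrices, function(m) nrow(m$weights), integer(1)),
    vapply(matrices, function(m) m$name, character(1)))
  covering <- wt_hits[wt_hits$start <= mutation_offset &
                        wt_hits$start + lens[wt_hits$matrix_name] - 1L >=
                          mutation_offset, , drop = FALSE]
  lost <- covering[0, , drop = FALSE]
  by_name <- stats::setNames(matrices,
                             vapply(matrices, `[[`, character(1), "name"))
  for (r in seq_len(nrow(covering))) {
    m <- by_name[[covering$matrix_name[r]]]
    L <- nrow(m$weights)
    win <- substr(exon_seq_mut, covering$start[r], covering$start[r] + L - 1L)
    b <- match(chars(win), c("A", "C", "G", "T"))
    score <- if (anyNA(b)) -Inf else sum(m$weights[cbind(seq_len(L), b)])
    if (score < m$threshold) lost <- rbind(lost, covering[r, , drop = FALSE])
  }
  list(in_ese = nrow(covering) > 0, lost_hits = lost)
}
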