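## Internal helpers shared across modules.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")
STOP_CODONS <- c("TAA", "TAG", "TGA")

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

## Reverse-complement of a plain character string (delegates to Biostrings).
#' @noRd
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' @noRd
comp_base <- function(x) {
  chartr("ACGTN", "TGCAN", x)
}

## Split a string into single characters.
#' @noRd
chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

#' @noRd
is_scalar_int <- function(x) {
  is.numeric(x) && length(x) == 1L && !is.na(x) && x == as.integer(x)
}

#' @noRd
assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop(..., call. = FALSE)
  invisible(TRUE)
}

## The 61 sense codons (all codons minus the three stops).
#' @noRd
sense_codons <- function() {
  b <- c("A", "C", "G", "T")
  all3 <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all3, STOP_CODONS)
}

## Random nucleotide string of length n (uses the session RNG; callers wrap
## in withr::with_seed for determinism).
#' @noRd
rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  if (n <= 0) return("")
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

## Random string avoiding any occurrence of the forbidden dinucleotides,
## including across the boundary with `prev` (the base immediately upstream).
#' @noRd
rand_seq_avoiding <- function(n, forbid, alphabet = c("A", "C", "G", "T"),
                              prev = "") {
  if (n <= 0) return("")
  out <- character(n)
  last <- prev
  f1 <- substr(forbid, 1L, 1L)
  f2 <- substr(forbid, 2L, 2L)
  for (i in seq_len(n)) {
    banned <- f2[f1 == last]
    pool <- setdiff(alphabet, banned)
    out[i] <- sample(pool, 1L)
    last <- out[i]
  }
  paste(out, collapse = "")
}

## Random run of sense codons, optionally avoiding dinucleotide motifs across
## the whole stretch (frame-internal and codon-boundary occurrences alike).
#' @noRd
rand_codons <- function(n_codons, forbid = character(), prev = "",
                        alphabet = c("A", "C", "G", "T"), max_tries = 1000L) {
  if (n_codons <= 0) return("")
  pool <- sense_codons()
  keep <- vapply(pool, function(cd) all(chars(cd) %in% alphabet), logical(1))
  pool <- pool[keep]
  if (length(forbid)) {
    pool <- pool[!vapply(pool, function(cd) {
      any(vapply(forbid, function(m) grepl(m, cd, fixed = TRUE), logical(1)))
    }, logical(1))]
  }
  assert_that(length(pool) > 0, "no admissible codons under the constraints")
  out <- character(n_codons)
  last <- prev
  for (i in seq_len(n_codons)) {
    for (k in seq_len(max_tries)) {
      cd <- sample(pool, 1L)
      boundary <- paste0(last, substr(cd, 1L, 1L))
      if (!length(forbid) || last == "" ||
          !any(forbid == boundary)) break
      cd <- NA_character_
    }
    assert_that(!is.na(cd), "codon sampling exceeded retry budget")
    out[i] <- cd
    last <- substr(cd, 3L, 3L)
  }
  paste(out, collapse = "")
}

## Single-codon lookup in the standard genetic code ("*" for stops).
#' @noRd
translate_codon <- function(codon) {
  unname(Biostrings::GENETIC_CODE[codon])
}

## All start positions of a dinucleotide motif inside a string (overlap-safe).
#' @noRd
motif_positions <- function(sequence, motif) {
  n <- nchar(sequence)
  if (n < nchar(motif)) return(integer())
  cs <- chars(sequence)
  m <- chars(motif)
  idx <- seq_len(n - length(m) + 1L)
  hit <- rep(TRUE, length(idx))
  for (j in seq_along(m)) {
    hit <- hit & cs[idx + j - 1L] == m[j]
  }
  idx[hit]
}
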