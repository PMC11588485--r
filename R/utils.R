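# Low-level sequence helpers shared across modules.  All internal coordinates
# in this package are 0-based half-open [start, end); GenBank I/O converts at
# the boundary.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Vectorised over its input; `N` is preserved.
#'
#' @param x Character vector of DNA strings (A/C/G/T/N).
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp("ACGTN")
revcomp <- function(x) {
  stringr::str_to_upper(x) |>
    chartr(old = "ACGTN", new = "TGCAN") |>
    stringi_rev()
}

# stringi is not a declared dependency; base reversal is fast enough here.
stringi_rev <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(s, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# Split a scalar DNA string into a character vector of single bases.
seq_chars <- function(s) {
  strsplit(s, "", fixed = TRUE)[[1]]
}

#' GC content of a DNA string
#'
#' Computed as (G+C)/(A+C+G+T); `N` is excluded from the denominator.
#'
#' @param x Character vector of DNA strings.
#' @return Numeric vector of fractions in \[0, 1\].
#' @export
gc_content <- function(x) {
  vapply(x, function(s) {
    ch <- seq_chars(s)
    gc <- sum(ch == "G" | ch == "C")
    acgt <- sum(ch %in% DNA_BASES)
    if (acgt == 0L) return(NA_real_)
    gc / acgt
  }, numeric(1), USE.NAMES = FALSE)
}

# Extract a circular substring [start, end) in 0-based half-open coordinates;
# end may exceed the genome length, in which case the slice wraps the origin.
circular_substr <- function(s, start, end) {
  n <- nchar(s)
  stopifnot(end >= start, end - start <= n)
  a <- start %% n
  b <- a + (end - start)
  if (b <= n) {
    substr(s, a + 1L, b)
  } else {
    paste0(substr(s, a + 1L, n), substr(s, 1L, b - n))
  }
}

# Does the circular interval [start, len) contain 0-based position p?
circ_contains <- function(start, len, p, n) {
  ((p - start) %% n) < len
}

# Signed distance from a to b going forward on a circle of size n, mapped to
# (-n/2, n/2].
circ_signed_dist <- function(from, to, n) {
  d <- (to - from) %% n
  if (d > n / 2) d - n else d
}

# Validate and normalise a DNA string: uppercase, restricted alphabet.
# Ambiguity codes other than N are rejected unless coerce = TRUE.
normalize_dna <- function(s, coerce = FALSE, what = "sequence") {
  s <- stringr::str_to_upper(s)
  s <- gsub("[^A-Z]", "", s)
  if (grepl("[^ACGTN]", s)) {
    if (coerce) {
      s <- gsub("[^ACGTN]", "N", s)
    } else {
      bad <- unique(seq_chars(gsub("[ACGTN]", "", s)))
      abort(sprintf(
        "%s contains ambiguity codes other than N (%s); use coerce_ambiguous = TRUE to convert them to N",
        what, paste(bad, collapse = ", ")
      ))
    }
  }
  s
}
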