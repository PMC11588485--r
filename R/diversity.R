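# Alignment-based variation statistics: nucleotide-pair frequencies,
# nucleotide diversity, Tajima's D, indel events and the sequence-
# variability (SV) index used for hotspot ranking.

#' Build an alignment object
#'
#' An alignment is a named character vector of equal-length gapped sequences
#' over A/C/G/T/N/-.  This helper validates and uppercases the rows.
#'
#' @param rows Named character vector (or tibble with `name`/`sequence`).
#' @return A named character vector of class `dna_alignment`.
#' @export
as_alignment <- function(rows) {
  if (is.data.frame(rows)) rows <- setNames(rows$sequence, rows$name)
  if (is.null(names(rows)) || any(names(rows) == "")) {
    names(rows) <- paste0("seq", seq_along(rows))
  }
  rows <- toupper(rows)
  if (length(unique(nchar(rows))) != 1) abort("alignment rows differ in length")
  if (length(rows) < 2) abort("an alignment needs at least 2 sequences")
  if (any(grepl("[^ACGTN-]", rows))) abort("alignment rows contain characters outside A/C/G/T/N/-")
  structure(rows, class = "dna_alignment")
}

# Character matrix view (n_seq x n_col) of an alignment.
aln_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(unclass(aln), "", fixed = TRUE))
  rownames(m) <- names(aln)
  m
}

transition_pair <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}

#' Nucleotide-pair frequencies of an alignment
#'
#' Over all sequence pairs and all columns where both residues are bases,
#' classifies each residue pair as identical, transitional (A-G, C-T) or
#' transversional, and reports percentages of the compared pairs.  With
#' `deletion = "complete"` only columns free of gaps and `N` in every row
#' are compared; with `"pairwise"` (default) each pair uses all columns
#' where both of its own residues are bases.
#'
#' @param aln A [as_alignment()] object (or coercible input).
#' @param deletion Gap treatment, `"pairwise"` or `"complete"`.
#' @return A one-row tibble: `identical_pct`, `transition_pct`,
#'   `transversion_pct`, `n_pairs_compared`.
#' @export
pair_frequencies <- function(aln, deletion = c("pairwise", "complete")) {
  aln <- as_alignment(aln)
  deletion <- rlang::arg_match(deletion)
  m <- aln_matrix(aln)
  if (deletion == "complete") {
    keep <- colSums(m == "-" | m == "N") == 0
    m <- m[, keep, drop = FALSE]
  }
  n <- nrow(m)
  ident <- ts <- tv <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- m[i, ]; b <- m[j, ]
      ok <- a %in% DNA_BASES & b %in% DNA_BASES
      a <- a[ok]; b <- b[ok]
      ident <- ident + sum(a == b)
      ts <- ts + sum(transition_pair(a, b))
      tv <- tv + sum(a != b & !transition_pair(a, b))
    }
  }
  tot <- ident + ts + tv
  if (tot == 0) abort("no comparable residue pairs in the alignment")
  tibble(
    identical_pct = 100 * ident / tot,
    transition_pct = 100 * ts / tot,
    transversion_pct = 100 * tv / tot,
    n_pairs_compared = tot
  )
}

#' Nucleotide diversity (pi)
#'
#' Average over all sequence pairs of the per-site proportion of differing
#' sites.  Columns containing any gap or `N` are excluded alignment-wide
#' (complete deletion) before comparison.
#'
#' @param aln An alignment.
#' @return Per-site nucleotide diversity (a single number).
#' @export
nucleotide_diversity <- function(aln) {
  aln <- as_alignment(aln)
  m <- complete_deletion(aln)
  L <- ncol(m)
  if (L == 0) abort("no gap- and N-free columns to compare")
  n <- nrow(m)
  diffs <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) diffs <- diffs + sum(m[i, ] != m[j, ])
  }
  n_pairs <- n * (n - 1) / 2
  (diffs / n_pairs) / L
}

complete_deletion <- function(aln) {
  m <- aln_matrix(aln)
  m[, colSums(m == "-" | m == "N") == 0, drop = FALSE]
}

#' Tajima's D
#'
#' Contrasts mean pairwise differences with the Watterson estimator from
#' segregating sites, under complete deletion.  Returns `NA` (undefined)
#' when there are no segregating sites.
#'
#' @param aln An alignment with at least 2 (>= 4 recommended) sequences.
#' @return Tajima's D, or `NA_real_` when S = 0.
#' @export
tajimas_d <- function(aln) {
  aln <- as_alignment(aln)
  m <- complete_deletion(aln)
  n <- nrow(m)
  if (ncol(m) == 0) abort("no gap- and N-free columns to compare")
  S <- sum(apply(m, 2, function(col) length(unique(col)) > 1))
  if (S == 0) return(NA_real_)
  k <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) k <- k + sum(m[i, ] != m[j, ])
  }
  k <- k / (n * (n - 1) / 2)
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (k - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

#' Count indel events in a gapped alignment
#'
#' An indel event is a distinct maximal gap run: a maximal stretch of `-` in
#' one row, merged with runs at identical column coordinates in other rows,
#' counts once.
#'
#' @param aln An alignment.
#' @return Integer event count.
#' @export
count_indel_events <- function(aln) {
  aln <- as_alignment(aln)
  m <- aln_matrix(aln)
  runs <- character(0)
  for (i in seq_len(nrow(m))) {
    r <- rle(m[i, ] == "-")
    if (!any(r$values)) next
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- c(runs, sprintf("%d-%d", starts[r$values], ends[r$values]))
  }
  length(unique(runs))
}

#' Sequence variability (SV)
#'
#' The hotspot index
#' `SV = (mutations + indel events) / (conserved sites + mutations + indel
#' events) * 100`, where mutations are gap-free polymorphic columns (a
#' column with 3+ states still counts once by default), conserved sites are
#' gap-free monomorphic columns, and indel events follow
#' [count_indel_events()].  Columns containing `N` are excluded from the
#' site counts.
#'
#' @param aln An alignment.
#' @param per_mutation Count a k-state column as k-1 mutations instead of 1.
#' @return A one-row tibble: `sv`, `n_mutations`, `n_indel_events`,
#'   `n_conserved`.
#' @export
sequence_variability <- function(aln, per_mutation = FALSE) {
  aln <- as_alignment(aln)
  m <- aln_matrix(aln)
  gapfree <- colSums(m == "-" | m == "N") == 0
  mg <- m[, gapfree, drop = FALSE]
  states <- apply(mg, 2, function(col) length(unique(col)))
  n_mut <- if (per_mutation) sum(pmax(states - 1L, 0L)) else sum(states > 1)
  n_cons <- sum(states == 1)
  n_indel <- count_indel_events(aln)
  denom <- n_cons + n_mut + n_indel
  if (denom == 0) abort("SV undefined: no conserved sites, mutations or indel events")
  tibble(
    sv = 100 * (n_mut + n_indel) / denom,
    n_mutations = as.integer(n_mut),
    n_indel_events = as.integer(n_indel),
    n_conserved = as.integer(n_cons)
  )
}

#' All diversity statistics of an alignment in one row
#'
#' Convenience wrapper combining [pair_frequencies()],
#' [nucleotide_diversity()], [tajimas_d()] and [sequence_variability()].
#'
#' @param aln An alignment.
#' @param deletion Gap treatment for the pair frequencies.
#' @return A one-row tibble.
#' @export
diversity_stats <- function(aln, deletion = "pairwise") {
  aln <- as_alignment(aln)
  dplyr::bind_cols(
    pair_frequencies(aln, deletion = deletion),
    tibble(pi = nucleotide_diversity(aln), tajima_d = tajimas_d(aln)),
    sequence_variability(aln)
  )
}
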