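# Deterministic center-star multiple alignment.  Pairwise global alignments
# (match +1, mismatch -1, gap open -4, gap extend -1) are computed with
# Biostrings; the center sequence is chosen by shared-k-mer similarity and
# the pairwise alignments are merged on the center's coordinate system.

#' Multiple alignment of homologous locus sequences
#'
#' Progressive center-star alignment: the center sequence (highest total
#' k-mer similarity to the rest, ties broken by name order) is globally
#' aligned to every other sequence with affine gap penalties (match +1,
#' mismatch -1, gap open -4, gap extend -1); the pairwise alignments are
#' merged by taking, between consecutive center positions, the union of
#' insertions.  Deterministic for fixed input (row order never changes the
#' columns).
#'
#' @param seqs Named character vector of 2-20 ungapped DNA sequences, or a
#'   tibble with `name`/`sequence` columns (genome names).
#' @return A [as_alignment()] object whose rows are in the input order.
#' @export
align_locus <- function(seqs) {
  if (is.data.frame(seqs)) {
    nm <- if ("genome" %in% names(seqs)) seqs$genome else seqs$name
    seqs <- setNames(seqs$sequence, nm)
  }
  if (length(seqs) < 2) abort("need at least 2 sequences to align")
  if (any(nchar(seqs) == 0)) abort("cannot align an empty sequence")
  seqs <- toupper(seqs)
  input_order <- names(seqs)

  # identical inputs need no DP
  if (length(unique(seqs)) == 1) return(as_alignment(seqs))

  center <- pick_center(seqs)
  others <- setdiff(names(seqs), center)

  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  aligned_center <- list(); aligned_other <- list()
  for (nm in others) {
    pa <- Biostrings::pairwiseAlignment(
      pattern = seqs[[nm]], subject = seqs[[center]],
      substitutionMatrix = mat, gapOpening = 3, gapExtension = 1,
      type = "global"
    )
    aligned_other[[nm]] <- as.character(Biostrings::alignedPattern(pa))
    aligned_center[[nm]] <- as.character(Biostrings::alignedSubject(pa))
  }

  # per pairwise alignment, the number of inserted columns after each center
  # position (index 0 = before the first center base)
  L <- nchar(seqs[[center]])
  ins <- matrix(0L, nrow = length(others), ncol = L + 1L,
                dimnames = list(others, NULL))
  for (nm in others) {
    cc <- seq_chars(aligned_center[[nm]])
    pos <- cumsum(cc != "-")          # center position at/before each column
    gap_cols <- which(cc == "-")
    if (length(gap_cols) > 0) {
      tab <- table(pos[gap_cols])
      ins[nm, as.integer(names(tab)) + 1L] <- as.integer(tab)
    }
  }
  master_ins <- apply(ins, 2, max)

  expand_row <- function(row_chars, center_chars) {
    # re-space one pairwise alignment onto the master column set: between
    # consecutive center bases, emit this row's insertion block left-aligned
    # and pad with gaps up to the master insertion count
    is_base <- center_chars != "-"
    pos <- cumsum(is_base)                 # center position at each column
    base_at <- row_chars[is_base]          # row char on each center base
    gap_cols <- which(!is_base)
    ins_by_pos <- split(row_chars[gap_cols], pos[gap_cols])  # named by 0..L
    pieces <- character(2L * (L + 1L))
    for (k in seq_len(L + 1L)) {
      b <- ins_by_pos[[as.character(k - 1L)]]
      nb <- length(b)
      pieces[2L * k - 1L] <- paste0(paste(b, collapse = ""),
                                    strrep("-", master_ins[k] - nb))
      if (k <= L) pieces[2L * k] <- base_at[k]
    }
    paste(pieces, collapse = "")
  }

  rows <- setNames(character(length(seqs)), names(seqs))
  # the center row: its own characters with master insertions as gaps
  center_chars <- seq_chars(seqs[[center]])
  pieces <- character(2L * (L + 1L))
  for (k in seq_len(L + 1L)) {
    pieces[2L * k - 1L] <- strrep("-", master_ins[k])
    if (k <= L) pieces[2L * k] <- center_chars[k]
  }
  rows[center] <- paste(pieces, collapse = "")
  for (nm in others) {
    rows[nm] <- expand_row(seq_chars(aligned_other[[nm]]),
                           seq_chars(aligned_center[[nm]]))
  }
  as_alignment(rows[input_order])
}

# Center choice: the sequence with the highest total shared 8-mer count
# against all others; ties resolved by name order.
pick_center <- function(seqs) {
  kmer_sets <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < 8) return(s)
    unique(substring(s, 1:(n - 7), 8:n))
  })
  nms <- sort(names(seqs))
  score <- vapply(nms, function(a) {
    sum(vapply(nms[nms != a], function(b) {
      length(intersect(kmer_sets[[a]], kmer_sets[[b]]))
    }, numeric(1)))
  }, numeric(1))
  nms[which.max(score)]
}
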