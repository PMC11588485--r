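# Codon usage over concatenated CDS: raw counts, RSCU, codon classification,
# amino-acid and third-position base frequencies.

ALL_CODONS <- as.vector(outer(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                                    paste0), c("T", "C", "A", "G"), paste0))

codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE  # standard code; identical to the bacterial/
  # plastid table 11 for elongation codons
  setNames(unname(gc[ALL_CODONS]), ALL_CODONS)
}

#' Count codons across coding sequences
#'
#' Counts frame-0 codons (including stop codons) over a set of CDS.  A
#' sequence whose length is not divisible by 3 triggers a warning and its
#' trailing remainder is dropped; codons containing `N` are tallied in an
#' `ambiguous` bucket and excluded from `counts`.
#'
#' @param cds A tibble with columns `name` and `sequence` (as returned by
#'   [extract_loci()]), or a named character vector of CDS.
#' @return A `codon_profile` object with elements `counts` (named integer
#'   vector over the 64 codons), `total_codons` and `ambiguous`.
#' @export
count_codons <- function(cds) {
  if (is.character(cds)) cds <- tibble(name = names(cds) %||% seq_along(cds), sequence = unname(cds))
  counts <- setNames(integer(64), ALL_CODONS)
  ambiguous <- 0L
  for (i in seq_len(nrow(cds))) {
    s <- cds$sequence[i]
    len <- nchar(s)
    if (len %% 3 != 0) {
      warn(sprintf("CDS '%s' length %d is not divisible by 3; trailing %d base(s) dropped",
                   cds$name[i], len, len %% 3))
      len <- len - len %% 3
      if (len == 0) next
      s <- substr(s, 1, len)
    }
    codons <- substring(s, seq(1, len, 3), seq(3, len, 3))
    known <- codons %in% ALL_CODONS
    ambiguous <- ambiguous + sum(!known)
    tab <- table(codons[known])
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  structure(
    list(counts = counts, total_codons = sum(counts), ambiguous = ambiguous,
         rscu = NULL, classification = NULL, aa_freq = NULL,
         third_pos_freq = third_position_freq(counts)),
    class = "codon_profile"
  )
}

third_position_freq <- function(counts) {
  third <- substr(names(counts), 3, 3)
  tot <- sum(counts)
  if (tot == 0) return(setNames(rep(NA_real_, 4), c("T", "C", "A", "G")))
  vapply(c("T", "C", "A", "G"), function(b) sum(counts[third == b]) / tot, numeric(1))
}

#' Relative synonymous codon usage and codon classification
#'
#' RSCU of a codon is its observed count divided by the mean count of its
#' synonymous family, so family RSCU values sum to the family size and
#' average 1.  Codons are classified as `overrepresented` (RSCU > 1.6),
#' `high-frequency` (RSCU > 1), `underrepresented` (RSCU < 0.6) or `normal`;
#' members of unobserved families get RSCU 0 and class `normal`.  Stop
#' codons form their own family.
#'
#' @param profile A `codon_profile` from [count_codons()].
#' @return The profile with `rscu`, `classification` and `aa_freq` filled.
#' @export
compute_rscu <- function(profile) {
  stopifnot(inherits(profile, "codon_profile"))
  code <- codon_table()
  counts <- profile$counts
  rscu <- setNames(numeric(64), ALL_CODONS)
  fam_observed <- setNames(logical(64), ALL_CODONS)
  for (aa in unique(code)) {
    fam <- names(code)[code == aa]
    tot <- sum(counts[fam])
    if (tot > 0) {
      rscu[fam] <- counts[fam] * length(fam) / tot
      fam_observed[fam] <- TRUE
    }
  }
  classification <- dplyr::case_when(
    !fam_observed ~ "normal",
    rscu > 1.6 ~ "overrepresented",
    rscu > 1 ~ "high-frequency",
    rscu < 0.6 ~ "underrepresented",
    TRUE ~ "normal"
  )
  profile$rscu <- rscu
  profile$classification <- setNames(classification, ALL_CODONS)
  profile$aa_freq <- aa_frequencies(profile)
  profile
}

#' Amino-acid frequencies of a codon profile
#'
#' Percentage of translated (non-stop) codons per amino acid; stop codons
#' are excluded from the denominator.
#'
#' @param profile A `codon_profile`.
#' @return Named numeric vector of percentages summing to 100, or an empty
#'   vector (with a warning) when no translated codons exist.
#' @export
aa_frequencies <- function(profile) {
  stopifnot(inherits(profile, "codon_profile"))
  code <- codon_table()
  counts <- profile$counts
  aa <- setdiff(unique(code), "*")
  tot <- sum(counts[names(code)[code != "*"]])
  if (tot == 0) {
    warn("profile contains no translated codons")
    return(setNames(numeric(0), character(0)))
  }
  freqs <- vapply(aa, function(a) 100 * sum(counts[names(code)[code == a]]) / tot, numeric(1))
  sort(freqs, decreasing = TRUE)
}

#' @export
print.codon_profile <- function(x, ...) {
  cat(sprintf("<codon_profile> %s codons (%d ambiguous skipped)\n",
              format(x$total_codons, big.mark = ","), x$ambiguous))
  if (!is.null(x$classification)) {
    tab <- table(x$classification)
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @describeIn count_codons Tidy a codon profile into a per-codon tibble
#'   (codon, amino acid, count, RSCU, classification).
#' @param x A `codon_profile`.
#' @param ... Unused.
#' @export
tidy.codon_profile <- function(x, ...) {
  code <- codon_table()
  tibble(
    codon = ALL_CODONS,
    amino_acid = unname(code[ALL_CODONS]),
    count = unname(x$counts[ALL_CODONS]),
    rscu = if (is.null(x$rscu)) NA_real_ else unname(x$rscu[ALL_CODONS]),
    classification = if (is.null(x$classification)) NA_character_ else
      unname(x$classification[ALL_CODONS])
  )
}

#' @describeIn count_codons One-row summary (totals, class counts, GC3).
#' @export
glance.codon_profile <- function(x, ...) {
  cls <- x$classification %||% setNames(character(0), character(0))
  tibble(
    total_codons = x$total_codons,
    ambiguous = x$ambiguous,
    n_overrepresented = sum(cls == "overrepresented"),
    n_high_frequency = sum(cls %in% c("overrepresented", "high-frequency")),
    n_underrepresented = sum(cls == "underrepresented"),
    third_pos_T = x$third_pos_freq[["T"]],
    third_pos_C = x$third_pos_freq[["C"]],
    third_pos_A = x$third_pos_freq[["A"]],
    third_pos_G = x$third_pos_freq[["G"]]
  )
}
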