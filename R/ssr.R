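# Perfect microsatellite (SSR) mining, context annotation and summaries.

#' Find perfect SSRs (mono- to hexanucleotide)
#'
#' Detects all maximal perfect tandem repeats of unit length 1-6 whose total
#' tract length meets the per-unit threshold.  A locus is reported at its
#' smallest period only (an `ATATAT...` run is a dinucleotide repeat, never
#' a tetranucleotide one), left-aligned at the start of the maximal periodic
#' run, with whole copies only.  Motifs are reported strand-specifically as
#' they occur on the forward strand; `A` and `T` runs, or `AT` and `TA`
#' repeats, are distinct motifs.  No SSR spans an `N`.
#'
#' @param rec A [plastome_record()] or a DNA string.
#' @param min_total_len Numeric vector of length 6: minimum total tract
#'   length (bp) for unit lengths 1-6.  The default requires 10 bp for every
#'   unit size; together with the whole-copy rule this means >= 10 copies for
#'   mono-, >= 5 for di-, >= 4 for tri-, >= 3 for tetra- and >= 2 for penta-
#'   and hexanucleotide repeats.
#' @return A tibble with columns `genome`, `motif`, `unit_len`, `copies`,
#'   `start`, `end` (0-based half-open), `total_len` and `length_bin`.
#' @export
find_ssrs <- function(rec, min_total_len = rep(10, 6)) {
  if (inherits(rec, "plastome_record")) {
    s <- rec$sequence; id <- rec$id
  } else {
    s <- normalize_dna(rec, coerce = TRUE); id <- "seq"
  }
  stopifnot(length(min_total_len) == 6, all(min_total_len > 0))
  n <- nchar(s)
  ch <- seq_chars(s)
  out <- list()
  for (u in 1:6) {
    if (n < 2 * u) next
    # eq[i] is TRUE when position i matches position i+u (1-based), N never matches
    a <- ch[seq_len(n - u)]
    b <- ch[seq_len(n - u) + u]
    eq <- a == b & a != "N"
    r <- rle(eq)
    pos <- cumsum(c(1L, r$lengths))
    run_starts <- pos[-length(pos)][r$values]
    run_lens <- r$lengths[r$values]
    if (length(run_starts) == 0) next
    total_run <- run_lens + u            # length of the periodic stretch
    copies <- total_run %/% u
    keep <- copies >= 2 & (copies * u) >= min_total_len[u]
    if (!any(keep)) next
    for (ridx in which(keep)) {
      st <- run_starts[ridx]             # 1-based start of the run
      cp <- copies[ridx]
      motif <- substr(s, st, st + u - 1L)
      if (u > 1 && !is_primitive(motif)) next
      out[[length(out) + 1L]] <- list(
        motif = motif, unit_len = u, copies = cp,
        start = st - 1L, end = st - 1L + cp * u
      )
    }
  }
  if (length(out) == 0) {
    return(tibble(genome = character(), motif = character(),
                  unit_len = integer(), copies = integer(), start = integer(),
                  end = integer(), total_len = integer(), length_bin = character()))
  }
  res <- dplyr::bind_rows(lapply(out, as_tibble))
  res <- dplyr::arrange(res, .data$start, .data$unit_len)
  tibble(
    genome = id,
    motif = res$motif,
    unit_len = as.integer(res$unit_len),
    copies = as.integer(res$copies),
    start = as.integer(res$start),
    end = as.integer(res$end),
    total_len = as.integer(res$copies * res$unit_len),
    length_bin = ssr_length_bin(res$copies * res$unit_len)
  )
}

# A motif is primitive when it is not a whole-number repetition of a shorter
# unit; non-primitive motifs are already reported at their smallest period.
is_primitive <- function(motif) {
  u <- nchar(motif)
  for (d in seq_len(u - 1)) {
    if (u %% d != 0) next
    unit <- substr(motif, 1, d)
    if (strrep(unit, u %/% d) == motif) return(FALSE)
  }
  TRUE
}

# The ten length groups, 10 bp apart; tracts of 91 bp and longer fall in the
# open-ended top group.
SSR_LENGTH_BINS <- c("10-20", "21-30", "31-40", "41-50", "51-60",
                     "61-70", "71-80", "81-90", ">91")

ssr_length_bin <- function(total_len) {
  dplyr::case_when(
    total_len < 10 ~ "<10",
    total_len <= 20 ~ "10-20",
    total_len <= 30 ~ "21-30",
    total_len <= 40 ~ "31-40",
    total_len <= 50 ~ "41-50",
    total_len <= 60 ~ "51-60",
    total_len <= 70 ~ "61-70",
    total_len <= 80 ~ "71-80",
    total_len <= 90 ~ "81-90",
    TRUE ~ ">91"
  )
}

#' Assign genomic region and genic context to SSR loci
#'
#' The region (LSC/SSC/IRA/IRB) is assigned by the locus midpoint.  The
#' genic context is assigned by overlap with annotated features using the
#' priority CDS > intron > tRNA > rRNA > intergenic, so a locus touching
#' both a CDS end and intergenic DNA counts as CDS.  Intron intervals are
#' derived from the gaps of multi-part features.
#'
#' @param ssrs Output of [find_ssrs()].
#' @param rec The [plastome_record()] the loci were mined from.
#' @param part The [detect_inverted_repeats()] partition of `rec`.
#' @return `ssrs` with `region` and `context` columns added.
#' @export
annotate_ssr_context <- function(ssrs, rec, part) {
  stopifnot(inherits(rec, "plastome_record"), inherits(part, "region_partition"))
  if (nrow(ssrs) == 0) {
    return(dplyr::mutate(ssrs, region = character(0), context = character(0)))
  }
  mid <- (ssrs$start + ssrs$end - 1L) %/% 2L
  region <- region_at(part, mid)

  ft <- rec$features
  ivs <- list()  # (start, end, class) with class priority order
  for (i in seq_len(nrow(ft))) {
    kind <- ft$kind[i]
    if (kind == "intergenic") next
    cls <- switch(kind, CDS = "CDS", pseudogene = "CDS",
                  tRNA = "tRNA", rRNA = "rRNA", intron = "intron")
    p <- ft$parts[[i]]
    for (j in seq_len(nrow(p))) {
      ivs[[length(ivs) + 1L]] <- list(p[j, 1], p[j, 2], cls)
    }
    if (nrow(p) > 1 && kind != "intergenic") {
      p <- p[order(p[, 1]), , drop = FALSE]
      for (j in seq_len(nrow(p) - 1L)) {
        if (p[j + 1L, 1] > p[j, 2]) {
          ivs[[length(ivs) + 1L]] <- list(p[j, 2], p[j + 1L, 1], "intron")
        }
      }
    }
  }
  context <- rep("intergenic", nrow(ssrs))
  if (length(ivs) > 0) {
    iv_start <- vapply(ivs, function(x) x[[1]], numeric(1))
    iv_end <- vapply(ivs, function(x) x[[2]], numeric(1))
    iv_cls <- vapply(ivs, function(x) x[[3]], character(1))
    prio <- c(CDS = 1, intron = 2, tRNA = 3, rRNA = 4, intergenic = 5)
    for (i in seq_len(nrow(ssrs))) {
      hit <- which(iv_start < ssrs$end[i] & iv_end > ssrs$start[i])
      if (length(hit) > 0) {
        context[i] <- iv_cls[hit[which.min(prio[iv_cls[hit]])]]
      }
    }
  }
  dplyr::mutate(ssrs, region = region, context = context)
}

#' Summarise SSR loci
#'
#' Builds the count/percentage tables behind the usual SSR figures: by motif
#' category (mono-hexa), by motif type, by total-length bin, by genomic
#' region and by genic context.  Tables are per genome when several genomes
#' are present; percentages within each genome sum to 100.
#'
#' @param ssrs Output of [find_ssrs()], optionally annotated by
#'   [annotate_ssr_context()].
#' @return A named list of tibbles: `by_category`, `by_motif`,
#'   `by_length_bin`, and (when the columns exist) `by_region`, `by_context`.
#' @export
summarize_ssrs <- function(ssrs) {
  cat_names <- c("mono", "di", "tri", "tetra", "penta", "hexa")
  one <- function(var, levels = NULL) {
    if (nrow(ssrs) == 0) {
      return(tibble(genome = character(), !!var := character(),
                    n = integer(), pct = numeric()))
    }
    tab <- ssrs |>
      dplyr::count(.data$genome, .data[[var]], name = "n") |>
      dplyr::group_by(.data$genome) |>
      dplyr::mutate(pct = 100 * .data$n / sum(.data$n)) |>
      dplyr::ungroup()
    if (!is.null(levels)) {
      tab[[var]] <- factor(tab[[var]], levels = levels)
      tab <- dplyr::arrange(tab, .data$genome, .data[[var]])
      tab[[var]] <- as.character(tab[[var]])
    }
    tab
  }
  ssrs <- dplyr::mutate(ssrs, category = cat_names[.data$unit_len])
  out <- list(
    by_category = one("category", cat_names),
    by_motif = one("motif"),
    by_length_bin = one("length_bin", SSR_LENGTH_BINS)
  )
  if ("region" %in% names(ssrs)) out$by_region <- one("region", c("LSC", "SSC", "IRA", "IRB"))
  if ("context" %in% names(ssrs)) {
    out$by_context <- one("context", c("CDS", "intron", "tRNA", "rRNA", "intergenic"))
  }
  out
}
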