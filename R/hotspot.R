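# Divergence-hotspot scanning: shared CDS / intergenic loci across genomes,
# per-locus alignment, SV and pi, ranked table.

#' Build homologous locus sets across genomes
#'
#' Homologous loci are matched by shared feature-derived name across the
#' input annotations (CDS by gene symbol, intergenic spacers by their
#' flanking-gene name).  A locus is kept only when it is present in every
#' genome and is at least `min_len` bp in every genome; excluded loci are
#' reported via a message and the `"excluded"` attribute.
#'
#' @param records List of [plastome_record()]s (>= 2).
#' @param kind `"cds"` or `"intergenic"`.
#' @param min_len Minimum locus length in bp, applied per genome.
#' @param partitions Optional list of `region_partition`s matching
#'   `records`, used to disambiguate duplicated IR genes consistently.
#' @return A tibble with columns `locus`, `genome`, `sequence`, `length`.
#' @export
build_locus_sets <- function(records, kind = c("cds", "intergenic"),
                             min_len = 150, partitions = NULL) {
  kind <- rlang::arg_match(kind)
  if (length(records) < 2) abort("need at least 2 records to build locus sets")
  tabs <- lapply(seq_along(records), function(i) {
    loci <- extract_loci(records[[i]], kind = kind, min_len = 0,
                         partition = partitions[[i]] %||% NULL)
    dplyr::mutate(loci, genome = records[[i]]$id, .before = 1)
  })
  all_loci <- dplyr::bind_rows(tabs)
  n_genomes <- length(records)
  status <- all_loci |>
    dplyr::group_by(.data$name) |>
    dplyr::summarise(n = dplyr::n_distinct(.data$genome),
                     min_len_seen = min(.data$length)) |>
    dplyr::mutate(keep = .data$n == n_genomes & .data$min_len_seen >= min_len)
  dropped <- status[!status$keep, , drop = FALSE]
  if (nrow(dropped) > 0) {
    reasons <- ifelse(dropped$n < n_genomes,
                      sprintf("absent from %d genome(s)", n_genomes - dropped$n),
                      sprintf("shorter than %d bp in at least one genome", min_len))
    inform(sprintf("excluding %d locus/loci: %s", nrow(dropped),
                   paste(utils::head(sprintf("%s (%s)", dropped$name, reasons), 5),
                         collapse = "; ")))
  }
  out <- all_loci |>
    dplyr::filter(.data$name %in% status$name[status$keep]) |>
    dplyr::transmute(locus = .data$name, genome = .data$genome,
                     sequence = .data$sequence, length = .data$length) |>
    dplyr::arrange(.data$locus, .data$genome)
  attr(out, "excluded") <- dropped$name
  out
}

#' Scan homologous loci for divergence hotspots
#'
#' Aligns every shared locus with [align_locus()], computes per-locus SV
#' and nucleotide diversity, and ranks loci by SV (descending) with pi as a
#' tie-break and name order as the final tie-break, so the ranking does not
#' depend on genome input order.
#'
#' @param records List of [plastome_record()]s.
#' @param kind `"cds"` or `"intergenic"`.
#' @param min_len Minimum locus length (150 bp mirrors the usual intergenic
#'   screening threshold).
#' @param partitions Optional list of `region_partition`s (see
#'   [build_locus_sets()]).
#' @return A tibble ranked by SV: `rank`, `locus`, `kind`, `n_genomes`,
#'   `length` (alignment columns), `sv`, `pi`, `n_mutations`,
#'   `n_indel_events`, `n_conserved`.
#' @export
scan_hotspots <- function(records, kind = c("cds", "intergenic"),
                          min_len = 150, partitions = NULL) {
  kind <- rlang::arg_match(kind)
  sets <- build_locus_sets(records, kind = kind, min_len = min_len,
                           partitions = partitions)
  if (nrow(sets) == 0) {
    return(tibble(rank = integer(), locus = character(), kind = character(),
                  n_genomes = integer(), length = integer(), sv = numeric(),
                  pi = numeric(), n_mutations = integer(),
                  n_indel_events = integer(), n_conserved = integer()))
  }
  per_locus <- sets |>
    dplyr::group_by(.data$locus) |>
    dplyr::group_map(function(df, key) {
      aln <- align_locus(setNames(df$sequence, df$genome))
      svr <- sequence_variability(aln)
      pi <- tryCatch(nucleotide_diversity(aln), error = function(e) NA_real_)
      tibble(locus = key$locus, kind = kind, n_genomes = nrow(df),
             length = nchar(aln[[1]]), sv = svr$sv, pi = pi,
             n_mutations = svr$n_mutations,
             n_indel_events = svr$n_indel_events,
             n_conserved = svr$n_conserved)
    }) |>
    dplyr::bind_rows()
  per_locus |>
    dplyr::arrange(dplyr::desc(.data$sv), dplyr::desc(.data$pi), .data$locus) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1)
}
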