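# Locus extraction from an annotated record: spliced CDS, introns, tRNAs and
# intergenic spacers.

#' Extract loci of one class from a plastome record
#'
#' * `cds`: spliced, strand-oriented coding sequences (pseudogenes excluded);
#' * `intron`: the gaps between consecutive parts of multi-part features,
#'   strand-oriented, named `<gene>_intron<k>`;
#' * `trna`: tRNA gene sequences;
#' * `intergenic`: maximal intervals not covered by any annotated feature,
#'   named `<left>_<right>` after the flanking features in genome order.  On
#'   a circular record the interval spanning the origin is a single locus.
#'
#' Overlapping genes (e.g. `matK` inside the `trnK` intron) are each emitted
#' in full; intergenic spacers are computed against the union of all feature
#' extents, so nested genes create no spurious spacers.  When a
#' `RegionPartition` is supplied, duplicated genes whose extent lies inside
#' an inverted repeat are renamed with an `_IRA`/`_IRB` suffix; otherwise
#' duplicate names get positional suffixes.
#'
#' @param rec A [plastome_record()].
#' @param kind One of `"cds"`, `"intron"`, `"trna"`, `"intergenic"`.
#' @param min_len Minimum locus length in bp (applied after splicing).
#' @param partition Optional [detect_inverted_repeats()] result used to
#'   disambiguate duplicated IR genes.
#' @return A tibble with columns `name`, `sequence`, `length`, `start`,
#'   `end` (0-based half-open extent; `end` may exceed the genome length for
#'   a locus wrapping the origin).
#' @export
extract_loci <- function(rec, kind = c("cds", "intron", "trna", "intergenic"),
                         min_len = 0, partition = NULL) {
  stopifnot(inherits(rec, "plastome_record"), min_len >= 0)
  kind <- rlang::arg_match(kind)
  ft <- disambiguate_ir_names(rec, partition)
  out <- switch(kind,
    cds = extract_genic(rec, ft, c("CDS")),
    trna = extract_genic(rec, ft, c("tRNA")),
    intron = extract_introns(rec, ft),
    intergenic = extract_intergenic(rec, ft)
  )
  out <- out[out$length >= min_len, , drop = FALSE]
  as_tibble(out)
}

# Rename duplicated genes located inside an IR copy with _IRA/_IRB; any
# remaining duplicates get positional suffixes so names are always unique.
disambiguate_ir_names <- function(rec, partition = NULL) {
  ft <- rec$features
  if (nrow(ft) == 0) return(ft)
  if (!is.null(partition)) {
    n <- rec$length
    dup <- ft$name[duplicated(ft$name)]
    for (i in seq_len(nrow(ft))) {
      if (!ft$name[i] %in% dup) next
      ext <- feature_extent(ft$parts[[i]], ft$wraps_origin[i], n)
      mid <- floor((ext[1] + ext[2]) / 2) %% n
      reg <- region_at(partition, mid)
      if (reg %in% c("IRA", "IRB")) {
        ft$name[i] <- paste0(ft$name[i], "_", reg)
      }
    }
  }
  if (anyDuplicated(ft$name)) {
    ft$name <- make.unique(ft$name, sep = "_")
  }
  ft
}

extract_genic <- function(rec, ft, kinds) {
  keep <- which(ft$kind %in% kinds)
  if (length(keep) == 0) {
    return(tibble(name = character(), sequence = character(),
                  length = integer(), start = integer(), end = integer()))
  }
  rec2 <- rec
  rec2$features <- ft
  seqs <- vapply(keep, function(i) feature_sequence(rec2, i), character(1))
  ext <- t(vapply(keep, function(i) {
    feature_extent(ft$parts[[i]], ft$wraps_origin[i], rec$length)
  }, numeric(2)))
  tibble(
    name = ft$name[keep], sequence = seqs, length = nchar(seqs),
    start = as.integer(ext[, 1]), end = as.integer(ext[, 2])
  )
}

extract_introns <- function(rec, ft) {
  rows <- list()
  for (i in seq_len(nrow(ft))) {
    p <- ft$parts[[i]]
    if (nrow(p) < 2 || ft$kind[i] == "intergenic") next
    p <- p[order(p[, 1]), , drop = FALSE]
    gaps <- lapply(seq_len(nrow(p) - 1L), function(j) c(p[j, 2], p[j + 1L, 1]))
    gaps <- Filter(function(g) g[2] > g[1], gaps)
    if (length(gaps) == 0) next
    # biological numbering: first intron is 5'-most, i.e. last in genome
    # order for a minus-strand gene
    idx <- if (ft$strand[i] == "-") rev(seq_along(gaps)) else seq_along(gaps)
    for (k in seq_along(gaps)) {
      g <- gaps[[k]]
      s <- substr(rec$sequence, g[1] + 1L, g[2])
      if (ft$strand[i] == "-") s <- revcomp(s)
      rows[[length(rows) + 1L]] <- tibble(
        name = sprintf("%s_intron%d", ft$name[i], idx[k]),
        sequence = s, length = nchar(s),
        start = as.integer(g[1]), end = as.integer(g[2])
      )
    }
  }
  if (length(rows) == 0) {
    return(tibble(name = character(), sequence = character(),
                  length = integer(), start = integer(), end = integer()))
  }
  dplyr::bind_rows(rows)
}

extract_intergenic <- function(rec, ft) {
  n <- rec$length
  genic <- ft[ft$kind != "intergenic", , drop = FALSE]
  empty <- tibble(name = character(), sequence = character(),
                  length = integer(), start = integer(), end = integer())
  if (nrow(genic) == 0) return(empty)
  # cover: union of all feature parts (not extents, so long introns stay
  # intergenic-free only if annotated; gene extents are used for naming)
  ivs <- do.call(rbind, lapply(seq_len(nrow(genic)), function(i) {
    ext <- feature_extent(genic$parts[[i]], genic$wraps_origin[i], n)
    if (ext[2] <= n) {
      matrix(ext, ncol = 2)
    } else {
      rbind(c(ext[1], n), c(0, ext[2] - n))
    }
  }))
  ord <- order(ivs[, 1], ivs[, 2])
  ivs <- ivs[ord, , drop = FALSE]
  # merge overlapping/nested extents
  merged <- list()
  cur <- ivs[1, ]
  for (i in seq_len(nrow(ivs))[-1]) {
    if (ivs[i, 1] <= cur[2]) {
      cur[2] <- max(cur[2], ivs[i, 2])
    } else {
      merged[[length(merged) + 1L]] <- cur
      cur <- ivs[i, ]
    }
  }
  merged[[length(merged) + 1L]] <- cur
  m <- do.call(rbind, merged)

  # gaps between consecutive covered blocks; on a circular molecule the
  # last-to-first gap wraps the origin and is a single locus
  gaps <- list()
  for (i in seq_len(nrow(m) - 1L)) {
    if (m[i + 1L, 1] > m[i, 2]) gaps[[length(gaps) + 1L]] <- c(m[i, 2], m[i + 1L, 1])
  }
  if (rec$circular) {
    wrap_len <- (m[1, 1] - m[nrow(m), 2]) %% n
    if (wrap_len > 0 && !(nrow(m) == 1 && m[1, 1] == 0 && m[1, 2] == n)) {
      gaps[[length(gaps) + 1L]] <- c(m[nrow(m), 2], m[nrow(m), 2] + wrap_len)
    }
  } else {
    if (m[1, 1] > 0) gaps <- c(list(c(0, m[1, 1])), gaps)
    if (m[nrow(m), 2] < n) gaps[[length(gaps) + 1L]] <- c(m[nrow(m), 2], n)
  }
  if (length(gaps) == 0) return(empty)

  ends <- vapply(seq_len(nrow(genic)), function(i) {
    feature_extent(genic$parts[[i]], genic$wraps_origin[i], n)[2] %% n
  }, numeric(1))
  starts <- vapply(seq_len(nrow(genic)), function(i) {
    feature_extent(genic$parts[[i]], genic$wraps_origin[i], n)[1] %% n
  }, numeric(1))

  rows <- lapply(gaps, function(g) {
    gap_start <- g[1] %% n
    glen <- g[2] - g[1]
    left <- genic$name[which.min((gap_start - ends) %% n)]
    right <- genic$name[which.min((starts - ((gap_start + glen) %% n)) %% n)]
    tibble(
      name = sprintf("%s_%s", left, right),
      sequence = circular_substr(rec$sequence, gap_start, gap_start + glen),
      length = as.integer(glen),
      start = as.integer(gap_start), end = as.integer(gap_start + glen)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (anyDuplicated(out$name)) out$name <- make.unique(out$name, sep = "_")
  out
}
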