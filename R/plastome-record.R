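#' Annotated plastome records
#'
#' A `plastome_record` bundles one circular (or linear) genome sequence with
#' its feature annotation.  Features live in a tibble with one row per
#' feature; multi-part features (spliced CDS, trans-spliced genes) carry
#' their exon intervals in the `parts` list-column.  All coordinates are
#' 0-based half-open; GenBank input/output converts to and from the 1-based
#' inclusive convention at the file boundary.
#'
#' @param id Accession-like identifier.
#' @param sequence Uppercase DNA string over A/C/G/T/N.
#' @param features Feature tibble with columns `name`, `kind` (one of
#'   `"CDS"`, `"tRNA"`, `"rRNA"`, `"intron"`, `"intergenic"`,
#'   `"pseudogene"`), `strand` (`"+"`/`"-"`), `parts` (list of two-column
#'   integer matrices, 0-based half-open) and `wraps_origin` (logical).
#' @param circular Is the molecule circular?
#' @param coerce_ambiguous Convert IUPAC ambiguity codes other than N to N
#'   instead of failing.
#'
#' @return A `plastome_record` object.
#' @export
plastome_record <- function(id, sequence, features = empty_features(),
                            circular = TRUE, coerce_ambiguous = FALSE) {
  sequence <- normalize_dna(sequence, coerce = coerce_ambiguous,
                            what = sprintf("record '%s'", id))
  features <- as_tibble(features)
  needed <- c("name", "kind", "strand", "parts", "wraps_origin")
  missing <- setdiff(needed, names(features))
  if (length(missing) > 0) {
    abort(paste0("feature table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  rec <- structure(
    list(
      id = as.character(id),
      sequence = sequence,
      length = nchar(sequence),
      circular = isTRUE(circular),
      features = features
    ),
    class = "plastome_record"
  )
  validate_plastome_record(rec)
}

#' @rdname plastome_record
#' @param x,rec A `plastome_record`.
#' @export
features <- function(rec) {
  stopifnot(inherits(rec, "plastome_record"))
  rec$features
}

empty_features <- function() {
  tibble(
    name = character(), kind = character(), strand = character(),
    parts = list(), wraps_origin = logical()
  )
}

# Build one feature row; parts is a list of c(start, end) 0-based half-open.
feature_row <- function(name, kind, strand, parts, wraps_origin = FALSE) {
  tibble(
    name = name, kind = kind, strand = strand,
    parts = list(do.call(rbind, lapply(parts, function(p) {
      matrix(as.integer(p), ncol = 2, dimnames = list(NULL, c("start", "end")))
    }))),
    wraps_origin = wraps_origin
  )
}

validate_plastome_record <- function(rec) {
  if (nchar(rec$sequence) != rec$length) abort("length does not match sequence")
  ft <- rec$features
  if (nrow(ft) > 0) {
    ok_kind <- ft$kind %in% c("CDS", "tRNA", "rRNA", "intron", "intergenic", "pseudogene")
    if (!all(ok_kind)) {
      abort(paste0("unknown feature kind: ", paste(unique(ft$kind[!ok_kind]), collapse = ", ")))
    }
    for (i in seq_len(nrow(ft))) {
      p <- ft$parts[[i]]
      if (is.null(p) || nrow(p) == 0) {
        abort(sprintf("feature '%s' has no parts", ft$name[i]))
      }
      if (any(p[, 1] >= p[, 2])) {
        abort(sprintf("feature '%s' has an empty or reversed part", ft$name[i]))
      }
      if (any(p < 0) || any(p[, 2] > rec$length)) {
        abort(sprintf("feature '%s' has coordinates outside the sequence [0, %d)",
                      ft$name[i], rec$length))
      }
    }
  }
  rec
}

#' @export
print.plastome_record <- function(x, ...) {
  cat(sprintf("<plastome_record> %s: %s bp, %s, %d features\n",
              x$id, format(x$length, big.mark = ","),
              if (x$circular) "circular" else "linear",
              nrow(x$features)))
  if (nrow(x$features) > 0) {
    tab <- table(x$features$kind)
    cat("  ", paste(sprintf("%s: %d", names(tab), tab), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.plastome_record <- function(x) x$length

# Total extent [start, end) of a feature on the forward axis; for a feature
# that wraps the origin, end exceeds the genome length (end = start + span).
feature_extent <- function(parts, wraps_origin, n) {
  s <- min(parts[, 1]); e <- max(parts[, 2])
  if (!wraps_origin) return(c(s, e))
  # wrapped: parts near the end of the genome come first biologically
  hi <- parts[parts[, 1] >= n / 2, , drop = FALSE]
  lo <- parts[parts[, 1] < n / 2, , drop = FALSE]
  if (nrow(hi) == 0 || nrow(lo) == 0) return(c(s, e))
  c(min(hi[, 1]), max(lo[, 2]) + n)
}

# Spliced, strand-oriented sequence of a feature.
feature_sequence <- function(rec, i) {
  ft <- rec$features[i, ]
  p <- ft$parts[[1]]
  pieces <- vapply(seq_len(nrow(p)), function(j) {
    substr(rec$sequence, p[j, 1] + 1L, p[j, 2])
  }, character(1))
  s <- paste(pieces, collapse = "")
  if (ft$strand == "-") revcomp(s) else s
}

#' Rotate the origin of a circular record
#'
#' Shifts the sequence so that the base at 0-based position `offset` becomes
#' the new first base, remapping all feature coordinates.  Used to verify
#' rotation invariance of downstream analyses.
#'
#' @param rec A `plastome_record`.
#' @param offset 0-based position that becomes the new origin.
#' @return A rotated `plastome_record`.
#' @export
rotate_record <- function(rec, offset) {
  stopifnot(inherits(rec, "plastome_record"), rec$circular)
  n <- rec$length
  offset <- offset %% n
  if (offset == 0) return(rec)
  seq2 <- paste0(substr(rec$sequence, offset + 1L, n), substr(rec$sequence, 1L, offset))
  ft <- rec$features
  if (nrow(ft) > 0) {
    for (i in seq_len(nrow(ft))) {
      p <- ft$parts[[i]]
      newp <- list()
      wraps <- FALSE
      for (j in seq_len(nrow(p))) {
        a <- (p[j, 1] - offset) %% n
        b <- a + (p[j, 2] - p[j, 1])
        if (b <= n) {
          newp[[length(newp) + 1L]] <- c(a, b)
        } else {
          # part now spans the new origin: split it
          newp[[length(newp) + 1L]] <- c(a, n)
          newp[[length(newp) + 1L]] <- c(0, b - n)
          wraps <- TRUE
        }
      }
      ft$parts[[i]] <- matrix(as.integer(unlist(lapply(newp, as.integer))),
                              ncol = 2, byrow = TRUE,
                              dimnames = list(NULL, c("start", "end")))
      ft$wraps_origin[i] <- wraps
    }
  }
  plastome_record(rec$id, seq2, ft, circular = TRUE)
}
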