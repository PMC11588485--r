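# GenBank flat-file input/output.  Only the parts of the format a plastome
# record needs are supported: LOCUS, the FEATURES table (CDS/tRNA/rRNA/intron
# keys with join/complement locations and /gene, /pseudo qualifiers) and the
# ORIGIN sequence block.  1-based inclusive file coordinates are converted to
# the package's 0-based half-open convention on the way in and back on the
# way out.

#' Read a GenBank flat file into a plastome record
#'
#' @param path Path to a GenBank flat file containing one record.
#' @param coerce_ambiguous Convert IUPAC ambiguity codes other than N to N
#'   instead of failing.
#' @return A [plastome_record()].
#' @export
read_genbank <- function(path, coerce_ambiguous = FALSE) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0) abort(sprintf("'%s' is empty", path))

  locus_i <- grep("^LOCUS", lines)
  if (length(locus_i) == 0) abort("no LOCUS line found")
  locus <- strsplit(trimws(lines[locus_i[1]]), "\\s+")[[1]]
  id <- locus[2]
  circular <- any(tolower(locus) == "circular")

  origin_i <- grep("^ORIGIN", lines)
  if (length(origin_i) == 0) abort("no ORIGIN sequence block found")
  end_i <- grep("^//\\s*$", lines)
  end_i <- end_i[end_i > origin_i[1]]
  if (length(end_i) == 0) abort("truncated file: ORIGIN block not terminated by '//'")
  seq_lines <- lines[(origin_i[1] + 1L):(end_i[1] - 1L)]
  sequence <- gsub("[0-9 ]", "", paste(seq_lines, collapse = ""))
  if (nchar(sequence) == 0) abort("ORIGIN block contains no sequence")

  ft_i <- grep("^FEATURES", lines)
  features <- empty_features()
  if (length(ft_i) > 0) {
    block <- lines[(ft_i[1] + 1L):(origin_i[1] - 1L)]
    features <- parse_feature_block(block)
  }

  rec <- plastome_record(id, sequence, features, circular = circular,
                         coerce_ambiguous = coerce_ambiguous)
  if (grepl("^\\d+$", locus[3] %||% "")) {
    declared <- as.integer(locus[3])
    if (declared != rec$length) {
      warn(sprintf("LOCUS declares %d bp but sequence has %d", declared, rec$length))
    }
  }
  rec
}

# Split the FEATURES block into (key, location, qualifiers) entries.
parse_feature_block <- function(block) {
  # a new feature starts at column 6 with a non-blank key
  starts <- grep("^ {4,6}\\S", block)
  if (length(starts) == 0) return(empty_features())
  out <- list()
  for (k in seq_along(starts)) {
    from <- starts[k]
    to <- if (k < length(starts)) starts[k + 1L] - 1L else length(block)
    entry <- block[from:to]
    header <- trimws(entry[1])
    key <- sub("\\s.*$", "", header)
    rest <- trimws(sub("^\\S+\\s*", "", header))
    body <- if (length(entry) > 1) trimws(entry[-1]) else character()
    # location may continue over lines until the first qualifier
    qual_start <- grep("^/", body)
    loc_extra <- if (length(qual_start) > 0) {
      body[seq_len(min(qual_start) - 1L)]
    } else body
    quals <- if (length(qual_start) > 0) body[min(qual_start):length(body)] else character()
    location <- paste(c(rest, loc_extra), collapse = "")

    kind <- switch(key,
      CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA", intron = "intron",
      misc_feature = NA_character_, gene = NA_character_, NA_character_
    )
    if (is.na(kind)) next
    qtxt <- paste(quals, collapse = " ")
    if (grepl("/pseudo\\b", qtxt) || grepl("/pseudogene=", qtxt)) kind <- "pseudogene"
    name <- qualifier_value(quals, "gene") %||%
      qualifier_value(quals, "standard_name") %||%
      qualifier_value(quals, "label") %||%
      sprintf("%s_%d", key, k)
    loc <- parse_location(location, feature = name)
    out[[length(out) + 1L]] <- feature_row(
      name = name, kind = kind, strand = loc$strand, parts = loc$parts,
      wraps_origin = loc$wraps_origin
    )
  }
  if (length(out) == 0) return(empty_features())
  dplyr::bind_rows(out)
}

qualifier_value <- function(quals, key) {
  pat <- paste0("^/", key, "=")
  hit <- grep(pat, quals, value = TRUE)
  if (length(hit) == 0) return(NULL)
  v <- sub(pat, "", hit[1])
  gsub('^"|"$', "", v)
}

# Parse a GenBank location string into parts + strand.  Supported grammar:
# a..b, a, complement(X), join(X,Y,...), order(...).  Coordinates are
# converted from 1-based inclusive to 0-based half-open.
parse_location <- function(loc, feature = "?") {
  loc <- gsub("[<> ]", "", loc)
  strand <- "+"
  parse_node <- function(s) {
    if (grepl("^complement\\(", s)) {
      inner <- sub("^complement\\((.*)\\)$", "\\1", s)
      strand <<- if (strand == "+") "-" else "+"
      return(parse_node(inner))
    }
    if (grepl("^(join|order)\\(", s)) {
      inner <- sub("^(join|order)\\((.*)\\)$", "\\2", s)
      pieces <- split_toplevel(inner)
      return(do.call(rbind, lapply(pieces, parse_node)))
    }
    if (grepl("^\\d+\\.\\.\\d+$", s)) {
      ab <- as.integer(strsplit(s, "..", fixed = TRUE)[[1]])
      return(matrix(c(ab[1] - 1L, ab[2]), ncol = 2))
    }
    if (grepl("^\\d+$", s)) {
      p <- as.integer(s)
      return(matrix(c(p - 1L, p), ncol = 2))
    }
    abort(sprintf("cannot parse location '%s' of feature '%s'", s, feature))
  }
  parts_mat <- parse_node(loc)
  # a join whose starts are not increasing spans the origin (file order is
  # biological order); internal storage is genome-forward sorted either way
  wraps <- nrow(parts_mat) > 1 && is.unsorted(parts_mat[, 1], strictly = FALSE)
  parts_mat <- parts_mat[order(parts_mat[, 1]), , drop = FALSE]
  parts <- lapply(seq_len(nrow(parts_mat)), function(i) parts_mat[i, ])
  list(parts = parts, strand = strand, wraps_origin = wraps)
}

# Split "a,b,c" at top-level commas only (not inside parentheses).
split_toplevel <- function(s) {
  ch <- seq_chars(s)
  depth <- cumsum((ch == "(") - (ch == ")"))
  cuts <- which(ch == "," & depth == 0)
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts - 1L, length(ch))
  vapply(seq_along(starts), function(i) {
    paste(ch[starts[i]:ends[i]], collapse = "")
  }, character(1))
}

#' Write a plastome record as a GenBank flat file
#'
#' Emits LOCUS, a FEATURES table and the ORIGIN block; coordinates are
#' converted back to GenBank's 1-based inclusive convention, with
#' `join()`/`complement()` for multi-part and minus-strand features.
#'
#' @param rec A [plastome_record()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(rec, path) {
  stopifnot(inherits(rec, "plastome_record"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s PLN %s",
                     rec$id, rec$length,
                     if (rec$circular) "circular" else "linear",
                     format(Sys.Date(), "%d-%b-%Y")), con)
  writeLines(sprintf("DEFINITION  %s synthetic plastome record.", rec$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", rec$length), con)
  ft <- rec$features
  for (i in seq_len(nrow(ft))) {
    key <- switch(ft$kind[i], CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                  intron = "intron", pseudogene = "CDS", intergenic = "misc_feature")
    loc <- format_location(ft$parts[[i]], ft$strand[i], ft$wraps_origin[i])
    writeLines(sprintf("     %-15s %s", key, loc), con)
    writeLines(sprintf('                     /gene="%s"', ft$name[i]), con)
    if (ft$kind[i] == "pseudogene") writeLines("                     /pseudo", con)
  }
  writeLines("ORIGIN", con)
  s <- tolower(rec$sequence)
  pos <- seq(1L, nchar(s), by = 60L)
  for (p in pos) {
    chunk <- substr(s, p, min(p + 59L, nchar(s)))
    tens <- substring(chunk, seq(1, nchar(chunk), 10), pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    writeLines(sprintf("%9d %s", p, paste(tens, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

format_location <- function(parts, strand, wraps_origin) {
  if (wraps_origin && nrow(parts) > 1) {
    # biological order starts after the largest inter-part gap (the wrap point)
    gaps <- parts[-1, 1] - parts[-nrow(parts), 2]
    first <- which.max(gaps) + 1L
    parts <- parts[c(first:nrow(parts), 1:(first - 1L)), , drop = FALSE]
  }
  spans <- sprintf("%d..%d", parts[, 1] + 1L, parts[, 2])
  loc <- if (length(spans) > 1) sprintf("join(%s)", paste(spans, collapse = ",")) else spans
  if (strand == "-") loc <- sprintf("complement(%s)", loc)
  loc
}
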