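# FASTA input/output, delegated to Biostrings.

#' Read a FASTA file into a tibble
#'
#' @param path Path to a (possibly gapped) FASTA file.
#' @return A tibble with columns `name`, `sequence` and `length`.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  seqs <- unname(toupper(as.character(set)))
  tibble(
    name = sub("\\s.*$", "", names(set)),
    sequence = seqs,
    length = nchar(seqs)
  )
}

#' Write named sequences to a FASTA file
#'
#' Sequences are wrapped at 60 columns.  An empty input writes an empty file
#' with a warning; duplicate names are an error so that round-tripping is
#' lossless.
#'
#' @param items A tibble/data frame with columns `name` and `sequence`, or a
#'   named character vector.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(items, path) {
  if (is.character(items)) {
    items <- tibble(name = names(items) %||% abort("sequences must be named"),
                    sequence = unname(items))
  }
  if (nrow(items) == 0) {
    warn(sprintf("writing empty FASTA file '%s'", path))
    file.create(path)
    return(invisible(path))
  }
  if (anyDuplicated(items$name)) {
    abort(paste0("duplicate sequence names: ",
                 paste(unique(items$name[duplicated(items$name)]), collapse = ", ")))
  }
  set <- Biostrings::BStringSet(setNames(items$sequence, items$name))
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}
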