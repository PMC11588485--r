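# End-to-end comparative pipeline and report rendering.

#' Run the full comparative plastome analysis
#'
#' Orchestrates every stage over a set of annotated genomes: quadripartite
#' partition and junction report, SSR mining with context annotation and
#' summaries, codon usage / RSCU per genome, whole-genome diversity
#' statistics, CDS and intergenic divergence-hotspot scans, and the
#' SNP-based NJ phylogeny.  Stages whose preconditions are not met (e.g. a
#' single input genome, or fewer than three for a tree) or that fail are
#' skipped with a recorded reason and the bundle is marked partial.
#'
#' Whole-genome multiple alignment by the built-in aligner is quadratic in
#' sequence length; for full-size (~150 kb) plastomes supply a pre-computed
#' alignment via `alignment`.
#'
#' @param inputs List of [plastome_record()]s, or paths to GenBank files.
#' @param min_ir_len Minimum IR length for [detect_inverted_repeats()].
#' @param ssr_min_total_len Per-unit SSR length thresholds ([find_ssrs()]).
#' @param hotspot_min_len Minimum homologous-locus length (bp).
#' @param count_ir_duplicates Count IR-duplicated genes twice in the codon
#'   profile instead of once per distinct gene.
#' @param alignment Optional pre-computed whole-genome alignment (named
#'   gapped character vector, tibble, or FASTA path); computed with
#'   [align_locus()] when absent.
#' @param reference Reference genome for SNP coordinates (default: first).
#' @param bootstrap Bootstrap replicates for the tree.
#' @param seed RNG seed (bootstrap resampling); fixed seed makes the whole
#'   bundle deterministic.
#' @return A `plastome_report` bundle (list of sections + `skipped`).
#' @export
run_compare <- function(inputs, min_ir_len = 1000,
                        ssr_min_total_len = rep(10, 6),
                        hotspot_min_len = 150,
                        count_ir_duplicates = FALSE,
                        alignment = NULL, reference = NULL,
                        bootstrap = 500, seed = NULL) {
  records <- lapply(inputs, function(x) {
    if (inherits(x, "plastome_record")) x else read_genbank(x)
  })
  if (length(records) == 0) abort("no input records")
  ids <- vapply(records, function(r) r$id, character(1))
  skipped <- list()
  note_skip <- function(section, reason) skipped[[section]] <<- reason

  # --- per-genome stages --------------------------------------------------
  partitions <- lapply(records, function(r) {
    tryCatch(detect_inverted_repeats(r, min_ir_len = min_ir_len),
             error = function(e) NULL)
  })
  genome_summary <- dplyr::bind_rows(lapply(seq_along(records), function(i) {
    rec <- records[[i]]; part <- partitions[[i]]
    ft <- rec$features
    genic <- ft[ft$kind != "intergenic", , drop = FALSE]
    row <- tibble(
      genome = rec$id,
      length_bp = rec$length,
      gc_pct = 100 * gc_content(rec$sequence),
      n_genes = dplyr::n_distinct(genic$name),
      n_cds = dplyr::n_distinct(genic$name[genic$kind == "CDS"]),
      n_trna = dplyr::n_distinct(genic$name[genic$kind == "tRNA"]),
      n_rrna = dplyr::n_distinct(genic$name[genic$kind == "rRNA"]),
      n_pseudo = dplyr::n_distinct(genic$name[genic$kind == "pseudogene"])
    )
    if (!is.null(part)) {
      region_seq <- function(iv) circular_substr(rec$sequence, iv[1], iv[1] + iv[2])
      row <- dplyr::bind_cols(row, tibble(
        lsc_bp = part$lsc_len, ssc_bp = part$ssc_len, ir_bp = part$ir_len,
        gc_lsc_pct = 100 * gc_content(region_seq(part$lsc)),
        gc_ssc_pct = 100 * gc_content(region_seq(part$ssc)),
        gc_ir_pct = 100 * gc_content(region_seq(part$ira))
      ))
    }
    row
  }))

  junctions <- NULL
  if (all(!vapply(partitions, is.null, logical(1)))) {
    junctions <- dplyr::bind_rows(lapply(seq_along(records), function(i) {
      tryCatch(junction_report(records[[i]], partitions[[i]]),
               error = function(e) NULL)
    }))
  } else {
    note_skip("junctions", "no IR partition for at least one genome")
  }

  ssr_loci <- dplyr::bind_rows(lapply(seq_along(records), function(i) {
    loci <- find_ssrs(records[[i]], min_total_len = ssr_min_total_len)
    if (!is.null(partitions[[i]])) {
      loci <- annotate_ssr_context(loci, records[[i]], partitions[[i]])
    }
    loci
  }))
  ssr_summaries <- summarize_ssrs(ssr_loci)

  rscu <- lapply(seq_along(records), function(i) {
    cds <- extract_loci(records[[i]], "cds", partition = partitions[[i]])
    if (!count_ir_duplicates) {
      base_name <- sub("_IR[AB]$", "", cds$name)
      cds <- cds[!duplicated(base_name), , drop = FALSE]
    }
    compute_rscu(count_codons(cds))
  })
  names(rscu) <- ids
  rscu_table <- dplyr::bind_rows(lapply(ids, function(id) {
    dplyr::mutate(tidy(rscu[[id]]), genome = id, .before = 1)
  }))

  # --- comparative stages -------------------------------------------------
  aln <- NULL
  diversity <- NULL
  if (length(records) >= 2) {
    aln <- tryCatch({
      if (is.null(alignment)) {
        align_locus(setNames(vapply(records, function(r) r$sequence, character(1)), ids))
      } else if (is.character(alignment) && length(alignment) == 1 &&
                 file.exists(alignment)) {
        as_alignment(read_fasta(alignment))
      } else {
        as_alignment(alignment)
      }
    }, error = function(e) { note_skip("diversity", conditionMessage(e)); NULL })
    if (!is.null(aln)) {
      diversity <- tryCatch(diversity_stats(aln),
                            error = function(e) { note_skip("diversity", conditionMessage(e)); NULL })
    }
  } else {
    note_skip("diversity", "needs at least 2 genomes")
  }

  hotspots_cds <- hotspots_intergenic <- NULL
  if (length(records) >= 2) {
    hotspots_cds <- tryCatch(
      scan_hotspots(records, "cds", min_len = hotspot_min_len, partitions = partitions),
      error = function(e) { note_skip("hotspots_cds", conditionMessage(e)); NULL })
    hotspots_intergenic <- tryCatch(
      scan_hotspots(records, "intergenic", min_len = hotspot_min_len, partitions = partitions),
      error = function(e) { note_skip("hotspots_intergenic", conditionMessage(e)); NULL })
  } else {
    note_skip("hotspots_cds", "needs at least 2 genomes")
    note_skip("hotspots_intergenic", "needs at least 2 genomes")
  }

  phylo <- NULL
  if (length(records) >= 3 && !is.null(aln)) {
    phylo <- tryCatch(
      plastome_phylogeny(aln, reference = reference %||% ids[1],
                         replicates = bootstrap, seed = seed),
      error = function(e) { note_skip("phylo", conditionMessage(e)); NULL })
  } else {
    note_skip("phylo", "needs at least 3 aligned genomes")
  }

  structure(
    list(
      genome_summary = genome_summary,
      partitions = setNames(partitions, ids),
      junctions = junctions,
      ssr_loci = ssr_loci,
      ssr_summaries = ssr_summaries,
      rscu = rscu,
      rscu_table = rscu_table,
      alignment = aln,
      diversity = diversity,
      hotspots_cds = hotspots_cds,
      hotspots_intergenic = hotspots_intergenic,
      phylo = phylo,
      skipped = skipped,
      partial = length(skipped) > 0,
      seed = seed
    ),
    class = "plastome_report"
  )
}

#' @export
print.plastome_report <- function(x, ...) {
  cat(sprintf("<plastome_report> %d genome(s)%s\n", nrow(x$genome_summary),
              if (x$partial) " [partial]" else ""))
  cat("  sections:", paste(names(report_tables(x)), collapse = ", "), "\n")
  if (length(x$skipped) > 0) {
    for (nm in names(x$skipped)) cat(sprintf("  skipped %s: %s\n", nm, x$skipped[[nm]]))
  }
  invisible(x)
}

# Rounded, column-stable tables shared by every output format: GC to 2
# decimals, SV to 3, pi to 6.
report_tables <- function(bundle) {
  stopifnot(inherits(bundle, "plastome_report"))
  round_cols <- function(df, digits_map) {
    for (nm in names(digits_map)) {
      hit <- grep(nm, names(df), value = TRUE)
      for (h in hit) df[[h]] <- round(df[[h]], digits_map[[nm]])
    }
    df
  }
  out <- list()
  out$genome_summary <- round_cols(bundle$genome_summary, c("gc_" = 2, "^gc_pct$" = 2))
  if (!is.null(bundle$junctions)) out$junctions <- bundle$junctions
  out$ssr_loci <- bundle$ssr_loci
  for (nm in names(bundle$ssr_summaries)) {
    out[[paste0("ssr_", nm)]] <- round_cols(bundle$ssr_summaries[[nm]], c("pct" = 2))
  }
  out$rscu <- dplyr::mutate(bundle$rscu_table, rscu = round(.data$rscu, 3))
  if (!is.null(bundle$diversity)) {
    out$diversity <- bundle$diversity |>
      dplyr::mutate(dplyr::across(dplyr::ends_with("_pct"), ~ round(.x, 2)),
                    pi = round(.data$pi, 6),
                    tajima_d = round(.data$tajima_d, 4),
                    sv = round(.data$sv, 3))
  }
  for (nm in c("hotspots_cds", "hotspots_intergenic")) {
    if (!is.null(bundle[[nm]])) {
      out[[nm]] <- bundle[[nm]] |>
        dplyr::mutate(sv = round(.data$sv, 3), pi = round(.data$pi, 6))
    }
  }
  if (!is.null(bundle$phylo)) {
    out$phylo_glance <- glance(bundle$phylo)
    out$newick <- tibble(newick = bundle$phylo$newick)
  }
  out
}

#' Render a report bundle to files
#'
#' Writes every section with stable column order and fixed rounding (GC to
#' 2 decimals, SV to 3, pi to 6) so the TSV, JSON and markdown renderings
#' contain identical numbers.  Skipped sections are annotated with their
#' reason.
#'
#' @param bundle A `plastome_report` from [run_compare()].
#' @param dir Output directory.
#' @param format `"tsv"`, `"json"` or `"markdown"`.
#' @return Character vector of written paths, invisibly.
#' @export
render_reports <- function(bundle, dir, format = c("tsv", "json", "markdown")) {
  format <- rlang::arg_match(format)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  tables <- report_tables(bundle)
  paths <- character(0)
  if (format == "tsv") {
    for (nm in names(tables)) {
      p <- file.path(dir, paste0(nm, ".tsv"))
      utils::write.table(as.data.frame(tables[[nm]]), p, sep = "\t",
                         quote = FALSE, row.names = FALSE)
      paths <- c(paths, p)
    }
    if (length(bundle$skipped) > 0) {
      p <- file.path(dir, "skipped.tsv")
      utils::write.table(
        data.frame(section = names(bundle$skipped),
                   reason = unlist(bundle$skipped)),
        p, sep = "\t", quote = FALSE, row.names = FALSE)
      paths <- c(paths, p)
    }
  } else if (format == "json") {
    p <- file.path(dir, "report.json")
    payload <- c(lapply(tables, function(t) as.data.frame(t)),
                 list(skipped = bundle$skipped))
    jsonlite::write_json(payload, p, auto_unbox = TRUE, digits = NA, null = "null")
    paths <- p
  } else {
    p <- file.path(dir, "report.md")
    con <- file(p, "w")
    on.exit(close(con))
    writeLines("# Comparative plastome report\n", con)
    for (nm in names(tables)) {
      writeLines(sprintf("## %s\n", nm), con)
      writeLines(md_table(tables[[nm]]), con)
      writeLines("", con)
    }
    if (length(bundle$skipped) > 0) {
      writeLines("## skipped\n", con)
      for (s in names(bundle$skipped)) {
        writeLines(sprintf("- %s: skipped: %s", s, bundle$skipped[[s]]), con)
      }
    }
    paths <- p
  }
  invisible(paths)
}

md_table <- function(df) {
  df <- as.data.frame(df)
  if (nrow(df) == 0) return("(empty)")
  vals <- vapply(df, function(col) format(col, trim = TRUE), character(nrow(df)))
  vals <- matrix(vals, nrow = nrow(df))
  header <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  body <- apply(vals, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(header, sep, body)
}
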