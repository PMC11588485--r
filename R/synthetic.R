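# Synthetic plastome generator: circular genomes with an exact inverted-
# repeat pair, annotated genes (including intron-bearing, nested and
# junction-spanning ones), planted maximal SSR loci and seeded mutation,
# all described by a ground-truth manifest.

#' Generate a synthetic annotated plastome
#'
#' Builds a circular genome laid out LSC - IRB - SSC - IRA (so the IR copy
#' downstream of the SSC is IRA, as in the standard quadripartite
#' convention), with `seq[IRA] == revcomp(seq[IRB])` exactly.  The gene set
#' always contains an intron-bearing CDS, a gene nested inside another
#' gene's intron, duplicated IR genes and a CDS spanning the IRB/SSC
#' junction (JSB); filler CDS are added or dropped to approach `n_genes`.
#' Planted SSR loci have their flanking bases adjusted so each locus is a
#' maximal perfect tandem repeat in context.
#'
#' @param lsc_len,ssc_len,ir_len Region lengths in bp.  The defaults are a
#'   1/10-scale model of a typical ~152 kb plastome (LSC 8.2 kb, SSC
#'   1.7 kb, IR 2.6 kb).
#' @param n_genes Approximate number of distinct genes (structural genes
#'   are always present).
#' @param n_ssrs Number of planted SSR loci (or supply `ssr_plan`).
#' @param gc GC fraction of the random background (default 0.366, a
#'   typical plastome value).
#' @param id Record identifier.
#' @param ssr_plan Optional tibble overriding the SSR plan, with columns
#'   `motif`, `copies`, `context` (`"intergenic"`, `"CDS"`, `"intron"`,
#'   `"tRNA"`) and `region` (`"LSC"`, `"SSC"`, `"IRB"`; intergenic only).
#' @param seed RNG seed; the same seed reproduces the genome and manifest
#'   byte-identically.
#' @return A list with `record` (a [plastome_record()]) and `truth`, the
#'   manifest: `seed`, `config`, `regions`, `junctions`, `genes`, `ssrs`.
#' @export
generate_plastome <- function(lsc_len = 8200, ssc_len = 1700, ir_len = 2600,
                              n_genes = 17, n_ssrs = 12, gc = 0.366,
                              id = "synthA", ssr_plan = NULL, seed = NULL) {
  stopifnot(lsc_len > 0, ssc_len > 0, ir_len > 0, gc > 0, gc < 1)
  if (!is.null(seed)) set.seed(seed)
  n <- lsc_len + ssc_len + 2L * ir_len
  lsc <- c(0L, lsc_len)
  irb <- c(lsc_len, ir_len)
  ssc <- c(lsc_len + ir_len, ssc_len)
  ira <- c(lsc_len + ir_len + ssc_len, ir_len)

  base_prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  g <- sample(DNA_BASES, n, replace = TRUE, prob = base_prob)

  put <- function(start, x) {  # write string x at 0-based start
    chs <- seq_chars(x)
    g[(start + 1L):(start + length(chs))] <<- chs
    invisible(NULL)
  }
  rand_dna <- function(len) {
    paste(sample(DNA_BASES, len, replace = TRUE, prob = base_prob), collapse = "")
  }
  rand_cds <- function(len) {
    stopifnot(len %% 3 == 0, len >= 9)
    paste0("ATG", rand_dna(len - 6L), "TAA")
  }

  genes <- list()
  gaps <- list()  # free intergenic intervals (region-labelled) for SSR planting
  add_gene <- function(name, kind, strand, parts, region) {
    genes[[length(genes) + 1L]] <<- list(name = name, kind = kind,
                                         strand = strand, parts = parts,
                                         region = region)
  }

  # --- sequential placement within a region -------------------------------
  place_region <- function(plan, from, to, region) {
    cursor <- from
    for (item in plan) {
      gap <- sample(30:180, 1)
      cursor <- cursor + gap
      glen <- sum(vapply(item$lens, function(x) x, numeric(1)))
      total <- glen + sum(item$introns %||% 0)
      if (cursor + total > to) {
        abort(sprintf("cannot place gene '%s' in %s without overlap", item$name, region))
      }
      parts <- list()
      p <- cursor
      for (k in seq_along(item$lens)) {
        parts[[k]] <- c(p, p + item$lens[k])
        p <- p + item$lens[k] + (item$introns[k] %||% 0)
      }
      gaps[[length(gaps) + 1L]] <<- list(start = cursor - gap, end = cursor, region = region)
      # write the gene sequence (spliced for multi-part)
      seq_len_total <- sum(item$lens)
      gene_seq <- if (item$kind == "CDS") rand_cds(seq_len_total) else rand_dna(seq_len_total)
      oriented <- if (item$strand == "-") revcomp(gene_seq) else gene_seq
      # oriented sequence is written across parts in genome order
      off <- 0L
      for (k in seq_along(parts)) {
        plen <- parts[[k]][2] - parts[[k]][1]
        put(parts[[k]][1], substr(oriented, off + 1L, off + plen))
        off <- off + plen
      }
      add_gene(item$name, item$kind, item$strand, parts, region)
      # nested gene inside the intron of a host
      if (!is.null(item$nested)) {
        nst <- item$nested
        istart <- parts[[1]][2]; iend <- parts[[2]][1]
        pad <- ((iend - istart) - nst$len) %/% 2L
        nstart <- istart + pad
        nseq <- if (nst$kind == "CDS") rand_cds(nst$len) else rand_dna(nst$len)
        put(nstart, if (nst$strand == "-") revcomp(nseq) else nseq)
        add_gene(nst$name, nst$kind, nst$strand, list(c(nstart, nstart + nst$len)), region)
      }
      cursor <- cursor + total
    }
    gaps[[length(gaps) + 1L]] <<- list(start = cursor, end = to, region = region)
    invisible(NULL)
  }

  gene1 <- function(name, kind, strand, len) {
    list(name = name, kind = kind, strand = strand, lens = len, introns = NULL)
  }

  lsc_plan <- list(
    gene1("psbA", "CDS", "+", 510),
    list(name = "trnK-UUU", kind = "tRNA", strand = "-", lens = c(36, 36),
         introns = c(600, 0),
         nested = list(name = "matK", kind = "CDS", strand = "+", len = 480)),
    gene1("rpoB", "CDS", "-", 690),
    list(name = "rpoC1", kind = "CDS", strand = "+", lens = c(300, 399),
         introns = c(201, 0)),
    gene1("atpA", "CDS", "+", 480),
    gene1("trnG-GCC", "tRNA", "+", 72),
    gene1("rbcL", "CDS", "+", 570),
    gene1("petA", "CDS", "-", 420),
    gene1("trnT-GGU", "tRNA", "-", 75),
    gene1("psbB", "CDS", "+", 510),
    gene1("rpl16", "CDS", "-", 399),
    gene1("clpP", "CDS", "+", 591)
  )
  filler_names <- paste0("orf", seq_len(50))
  n_struct <- length(lsc_plan) + 1 + 3 + 1  # LSC + SSC + IR set + spanning
  if (n_genes > n_struct) {
    extra <- n_genes - n_struct
    for (e in seq_len(extra)) {
      lsc_plan[[length(lsc_plan) + 1L]] <- gene1(filler_names[e], "CDS",
                                                 sample(c("+", "-"), 1), 330)
    }
  } else if (n_genes < n_struct) {
    droppable <- c(12, 11, 10, 8, 7, 5, 3)  # filler-ish LSC entries, last first
    ndrop <- min(n_struct - n_genes, length(droppable))
    if (ndrop > 0) lsc_plan <- lsc_plan[-droppable[seq_len(ndrop)]]
  }

  ssc_plan <- list(
    gene1("ccsA", "CDS", "+", 330)
  )
  irb_plan <- list(
    gene1("rrn16", "rRNA", "+", 900),
    gene1("trnV-GAC", "tRNA", "+", 72),
    gene1("rpl2", "CDS", "-", 570)
  )

  place_region(lsc_plan, lsc[1] + 40L, lsc[1] + lsc[2] - 40L, "LSC")
  # leave room at the IRB end for the junction-spanning gene
  jsb <- irb[1] + irb[2]           # 0-based JSB position (first SSC base)
  span_ir <- 210L
  span_ssc <- if (ssc_len >= 1700) 840L else max(120L, ssc_len %/% 3)
  span_ssc <- span_ssc + (3L - (span_ssc + span_ir) %% 3L) %% 3L  # keep CDS in frame
  place_region(irb_plan, irb[1] + 40L, jsb - span_ir - 40L, "IRB")
  place_region(ssc_plan, jsb + span_ssc + 40L, ssc[1] + ssc[2] - 40L, "SSC")

  # junction-spanning CDS across JSB (an ndhF-like gene)
  put(jsb - span_ir, revcomp(rand_cds(span_ir + span_ssc)))
  add_gene("ndhF", "CDS", "-", list(c(jsb - span_ir, jsb + span_ssc)), "JSB")

  # --- SSR planting -------------------------------------------------------
  if (is.null(ssr_plan)) ssr_plan <- default_ssr_plan(n_ssrs)
  ssr_truth <- list()
  free_gaps <- Filter(function(gp) gp$end - gp$start >= 8, gaps)
  pick_host <- function(kind, region = NULL) {
    cand <- Filter(function(ge) ge$kind == kind &&
                     (is.null(region) || ge$region == region) &&
                     ge$region %in% c("LSC", "SSC"), genes)
    if (length(cand) == 0) abort(sprintf("no %s host available for an SSR", kind))
    cand[[sample.int(length(cand), 1)]]
  }
  used_iv <- list()  # planted SSR intervals (padded) to keep loci disjoint
  clashes <- function(s, e) {
    any(vapply(used_iv, function(iv) s < iv[2] + 3L && e + 3L > iv[1], logical(1)))
  }
  for (i in seq_len(nrow(ssr_plan))) {
    motif <- ssr_plan$motif[i]; copies <- ssr_plan$copies[i]
    ctx <- ssr_plan$context[i]; region <- ssr_plan$region[i]
    u <- nchar(motif); total <- u * copies
    if (ctx == "intergenic") {
      ok <- which(vapply(free_gaps, function(gp) {
        gp$region == region && (gp$end - gp$start) >= total + 6L
      }, logical(1)))
      if (length(ok) == 0) abort(sprintf("no free %s gap for a %d bp SSR", region, total))
      gi <- ok[sample.int(length(ok), 1)]
      s0 <- free_gaps[[gi]]$start + 3L
      free_gaps[[gi]] <- NULL
    } else {
      if (ctx == "intron") {
        host <- Filter(function(ge) ge$kind == "CDS" && length(ge$parts) > 1,
                       genes)[[1]]
        lo <- host$parts[[1]][2] + 2L; hi <- host$parts[[2]][1] - 2L
      } else if (ctx == "CDS") {
        hosts <- Filter(function(ge) ge$kind == "CDS" && length(ge$parts) == 1 &&
                          ge$region == "LSC" &&
                          ge$parts[[1]][2] - ge$parts[[1]][1] >= total + 20L, genes)
        if (length(hosts) == 0) abort("no CDS host available for an SSR")
        host <- hosts[[sample.int(length(hosts), 1)]]
        lo <- host$parts[[1]][1] + 6L; hi <- host$parts[[1]][2] - 6L
      } else {
        host <- pick_host("tRNA")
        lo <- host$parts[[1]][1] + 4L; hi <- host$parts[[1]][2] - 4L
      }
      if (hi - lo < total + 2L) abort(sprintf("host too small for SSR %d", i))
      found <- FALSE
      for (try in seq_len(50)) {
        s0 <- lo + sample.int(max(hi - lo - total - 1L, 1L), 1) - 1L
        if (!clashes(s0, s0 + total)) { found <- TRUE; break }
      }
      if (!found) abort(sprintf("cannot place SSR %d without overlap after bounded retries", i))
    }
    used_iv[[length(used_iv) + 1L]] <- c(s0, s0 + total)
    put(s0, strrep(motif, copies))
    # maximality: break the period just outside both ends
    left_req <- g[s0 + u]          # base at s0 + u - 1 (0-based s0+u-1)
    alt <- setdiff(DNA_BASES, left_req)
    g[s0] <- alt[sample.int(3, 1)]                  # 0-based s0 - 1
    right_req <- g[s0 + total - u + 1L]             # base at end - u
    alt2 <- setdiff(DNA_BASES, right_req)
    g[s0 + total + 1L] <- alt2[sample.int(3, 1)]    # 0-based end
    ssr_truth[[length(ssr_truth) + 1L]] <- tibble(
      motif = motif, unit_len = u, copies = copies,
      start = s0, end = s0 + total, total_len = total,
      region = if (ctx == "intergenic") region else "LSC",
      context = ctx
    )
  }

  # --- mirror IRB into IRA (exact inverted repeat) ------------------------
  irb_seq <- paste(g[(irb[1] + 1L):(irb[1] + irb[2])], collapse = "")
  put(ira[1], revcomp(irb_seq))
  # make the planted IR pair maximal: break the reverse-complement match
  # just outside both IR ends so greedy boundary extension stops exactly at
  # the planted junctions
  comp1 <- c(A = "T", C = "G", G = "C", T = "A")
  if (g[jsb + 1L] == comp1[[g[ira[1]]]]) {
    g[jsb + 1L] <- setdiff(DNA_BASES, comp1[[g[ira[1]]]])[sample.int(3, 1)]
  }
  if (g[lsc_len] == comp1[[g[1L]]]) {
    g[lsc_len] <- setdiff(DNA_BASES, comp1[[g[1L]]])[sample.int(3, 1)]
  }
  # mirrored annotations for genes wholly inside IRB
  mirror_pos <- function(p) ira[1] + (irb[1] + irb[2] - p)
  for (ge in genes) {
    if (ge$region != "IRB") next
    mparts <- lapply(rev(ge$parts), function(pp) c(mirror_pos(pp[2]), mirror_pos(pp[1])))
    add_gene(ge$name, ge$kind, if (ge$strand == "+") "-" else "+", mparts, "IRA")
  }

  ft <- dplyr::bind_rows(lapply(genes, function(ge) {
    feature_row(ge$name, ge$kind, ge$strand, ge$parts)
  }))
  rec <- plastome_record(id, paste(g, collapse = ""), ft, circular = TRUE)

  ssrs <- if (length(ssr_truth) > 0) dplyr::bind_rows(ssr_truth) else
    tibble(motif = character(), unit_len = integer(), copies = integer(),
           start = integer(), end = integer(), total_len = integer(),
           region = character(), context = character())
  # SSR truth region by midpoint (CDS-context loci may sit anywhere in LSC/SSC)
  truth <- list(
    seed = seed,
    config = list(lsc_len = lsc_len, ssc_len = ssc_len, ir_len = ir_len,
                  n_genes = n_genes, n_ssrs = nrow(ssrs), gc = gc),
    regions = list(lsc = lsc, ssc = ssc, ira = ira, irb = irb),
    junctions = c(JLA = 0L, JLB = lsc_len, JSB = jsb, JSA = ira[1]),
    genes = dplyr::bind_rows(lapply(genes, function(ge) {
      ext <- range(unlist(ge$parts))
      tibble(name = ge$name, kind = ge$kind, strand = ge$strand,
             start = ext[1], end = ext[2], n_parts = length(ge$parts),
             region = ge$region)
    })),
    ssrs = ssrs,
    mutations = NULL, indels = NULL
  )
  list(record = rec, truth = truth)
}

default_ssr_plan <- function(n_ssrs) {
  base <- tibble(
    motif = c("A", "T", "AT", "TA", "AAT", "TTC", "AATC", "A", "AT", "TA", "AAG", "T"),
    copies = c(12L, 11L, 7L, 6L, 5L, 4L, 3L, 13L, 8L, 7L, 4L, 12L),
    context = c("intergenic", "intergenic", "intergenic", "intergenic",
                "intergenic", "intergenic", "intergenic", "CDS", "CDS",
                "intron", "tRNA", "intergenic"),
    region = c("LSC", "LSC", "LSC", "LSC", "SSC", "IRB", "LSC", "LSC",
               "LSC", "LSC", "LSC", "LSC")
  )
  if (n_ssrs <= nrow(base)) return(base[seq_len(n_ssrs), , drop = FALSE])
  extra_n <- n_ssrs - nrow(base)
  extra <- tibble(
    motif = rep(c("A", "T", "AT", "TA", "TAA", "ATT"), length.out = extra_n),
    copies = rep(c(11L, 12L, 6L, 5L, 4L, 4L), length.out = extra_n),
    context = "intergenic",
    region = rep(c("LSC", "LSC", "LSC", "SSC", "LSC", "LSC"), length.out = extra_n)
  )
  dplyr::bind_rows(base, extra)
}

#' Mutate a synthetic plastome
#'
#' Applies seeded substitutions (transition probability `ts_tv_ratio /
#' (ts_tv_ratio + 1)`) and short indels (1-5 bp, insertions and deletions
#' equally likely) to a generated genome.  The IR copies are co-mutated:
#' substitutions are drawn for LSC, SSC and IRB and IRA is re-synchronised
#' to the exact reverse complement of IRB, as plastome IRs evolve in
#' concert.  Indels are restricted to single-copy intergenic DNA outside
#' planted SSRs, so gene models and SSR truth stay exact; feature and SSR
#' coordinates are remapped through the indels.
#'
#' @param rec A generated [plastome_record()].
#' @param truth Its manifest from [generate_plastome()].
#' @param sub_rate Per-site substitution probability (0-0.1).
#' @param ts_tv_ratio Expected transition/transversion count ratio.
#' @param indel_rate Per-site indel initiation probability (0-0.1).
#' @param per_locus_multipliers Named numeric vector: gene or locus names
#'   from the manifest whose extent mutates at `multiplier * sub_rate`
#'   (used to plant divergence hotspots).
#' @param id Identifier of the derived genome.
#' @param seed RNG seed.
#' @return A list with the mutated `record` and the updated `truth`
#'   (substitutions in ancestor coordinates with `mirrored` flags, indels,
#'   remapped genes/SSRs).
#' @export
mutate_plastome <- function(rec, truth, sub_rate, ts_tv_ratio = 2,
                            indel_rate = 0, per_locus_multipliers = NULL,
                            id = paste0(rec$id, "m"), seed = NULL) {
  stopifnot(sub_rate >= 0, sub_rate <= 0.1, indel_rate >= 0, indel_rate <= 0.1,
            ts_tv_ratio > 0)
  if (!is.null(seed)) set.seed(seed)
  n <- rec$length
  g <- seq_chars(rec$sequence)
  ira <- truth$regions$ira; irb <- truth$regions$irb

  rate <- rep(sub_rate, n)
  if (!is.null(per_locus_multipliers)) {
    for (nm in names(per_locus_multipliers)) {
      hit <- truth$genes[truth$genes$name == nm, , drop = FALSE]
      if (nrow(hit) == 0) abort(sprintf("unknown locus '%s' in per_locus_multipliers", nm))
      for (r in seq_len(nrow(hit))) {
        rate[(hit$start[r] + 1L):hit$end[r]] <- sub_rate * per_locus_multipliers[[nm]]
      }
    }
  }
  # draw substitutions everywhere except IRA (kept in concert with IRB)
  in_ira <- rep(FALSE, n)
  in_ira[(ira[1] + 1L):(ira[1] + ira[2])] <- TRUE
  hits <- which(stats::runif(n) < rate & !in_ira)
  p_ts <- ts_tv_ratio / (ts_tv_ratio + 1)
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  muts <- NULL
  if (length(hits) > 0) {
    is_ts <- stats::runif(length(hits)) < p_ts
    from <- g[hits]
    to <- character(length(hits))
    to[is_ts] <- ts_map[from[is_ts]]
    for (k in which(!is_ts)) {
      tv <- setdiff(DNA_BASES, c(from[k], ts_map[[from[k]]]))
      to[k] <- tv[sample.int(2, 1)]
    }
    g[hits] <- to
    muts <- tibble(pos = hits - 1L, from = from, to = to,
                   transition = is_ts, mirrored = FALSE)
  }
  # re-synchronise IRA from IRB and record the mirrored substitutions
  if (!is.null(muts)) {
    in_irb <- muts$pos >= irb[1] & muts$pos < irb[1] + irb[2]
    if (any(in_irb)) {
      mpos <- ira[1] + (irb[1] + irb[2] - 1L - muts$pos[in_irb])
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      mirr <- tibble(pos = mpos,
                     from = unname(comp[muts$from[in_irb]]),
                     to = unname(comp[muts$to[in_irb]]),
                     transition = muts$transition[in_irb], mirrored = TRUE)
      muts <- dplyr::bind_rows(muts, mirr)
    }
  }
  irb_seq <- paste(g[(irb[1] + 1L):(irb[1] + irb[2])], collapse = "")
  g[(ira[1] + 1L):(ira[1] + ira[2])] <- seq_chars(revcomp(irb_seq))

  # --- indels in single-copy intergenic DNA outside planted SSRs ----------
  indels <- NULL
  new_genes <- truth$genes
  new_ssrs <- truth$ssrs
  if (indel_rate > 0) {
    lsc <- truth$regions$lsc; ssc <- truth$regions$ssc
    eligible <- rep(FALSE, n)
    eligible[(lsc[1] + 1L):(lsc[1] + lsc[2])] <- TRUE
    eligible[(ssc[1] + 1L):(ssc[1] + ssc[2])] <- TRUE
    for (r in seq_len(nrow(truth$genes))) {
      gi <- truth$genes[r, ]
      eligible[max(gi$start - 3L, 1L):min(gi$end + 4L, n)] <- FALSE
    }
    for (r in seq_len(nrow(truth$ssrs))) {
      si <- truth$ssrs[r, ]
      eligible[max(si$start - 3L, 1L):min(si$end + 4L, n)] <- FALSE
    }
    ipos <- which(stats::runif(n) < indel_rate & eligible)
    if (length(ipos) > 0) {
      ilen <- sample(1:5, length(ipos), replace = TRUE)
      itype <- sample(c("ins", "del"), length(ipos), replace = TRUE)
      # drop deletions that would run past their eligible stretch
      keep <- itype == "ins" |
        vapply(seq_along(ipos), function(k) {
          all(eligible[ipos[k]:min(ipos[k] + ilen[k] - 1L, n)])
        }, logical(1))
      ipos <- ipos[keep]; ilen <- ilen[keep]; itype <- itype[keep]
    }
    if (length(ipos) > 0) {
      indels <- tibble(pos = ipos - 1L, len = ilen, type = itype)
      # apply right-to-left so earlier coordinates stay valid
      for (k in order(ipos, decreasing = TRUE)) {
        if (itype[k] == "del") {
          g <- g[-(ipos[k]:(ipos[k] + ilen[k] - 1L))]
        } else {
          g <- append(g, sample(DNA_BASES, ilen[k], replace = TRUE), after = ipos[k])
        }
      }
      shift_of <- function(p) {  # ancestor 0-based -> derived 0-based shift
        s <- 0L
        for (k in seq_along(ipos)) {
          p0 <- ipos[k] - 1L
          if (p0 < p) s <- s + if (itype[k] == "del") -min(ilen[k], p - p0) else ilen[k]
        }
        as.integer(s)
      }
      remap <- function(p) as.integer(p) + vapply(p, shift_of, integer(1))
      new_genes$start <- remap(new_genes$start)
      new_genes$end <- remap(new_genes$end)
      if (nrow(new_ssrs) > 0) {
        new_ssrs$start <- remap(new_ssrs$start)
        new_ssrs$end <- remap(new_ssrs$end)
      }
    }
  }

  # rebuild the feature table by shifting the original parts
  ft <- rec$features
  if (!is.null(indels) && nrow(ft) > 0) {
    shift_one <- function(p) {
      s <- 0L
      for (k in seq_along(indels$pos)) {
        if (indels$pos[k] < p) s <- s + if (indels$type[k] == "del") -indels$len[k] else indels$len[k]
      }
      p + s
    }
    for (i in seq_len(nrow(ft))) {
      pm <- ft$parts[[i]]
      pm[] <- vapply(as.vector(pm), shift_one, numeric(1))
      ft$parts[[i]] <- matrix(as.integer(pm), ncol = 2,
                              dimnames = list(NULL, c("start", "end")))
    }
  }

  rec2 <- plastome_record(id, paste(g, collapse = ""), ft, circular = TRUE)
  truth2 <- truth
  truth2$parent <- rec$id
  truth2$mutations <- muts %||% tibble(pos = integer(), from = character(),
                                       to = character(), transition = logical(),
                                       mirrored = logical())
  truth2$indels <- indels %||% tibble(pos = integer(), len = integer(), type = character())
  truth2$genes <- new_genes
  truth2$ssrs <- new_ssrs
  truth2$mutation_params <- list(sub_rate = sub_rate, ts_tv_ratio = ts_tv_ratio,
                                 indel_rate = indel_rate,
                                 per_locus_multipliers = as.list(per_locus_multipliers %||% list()),
                                 seed = seed)
  if (!is.null(indels)) {
    delta <- sum(ifelse(indels$type == "ins", indels$len, -indels$len))
    truth2$config$derived_length <- n + delta
  }
  list(record = rec2, truth = truth2)
}

#' Generate a seeded multi-genome study set
#'
#' One ancestral genome plus `n_genomes` independently mutated derivatives,
#' emulating a set of congeneric plastomes.  Optionally plants a divergence
#' hotspot by multiplying the substitution rate inside one locus.
#'
#' @param n_genomes Number of derived genomes.
#' @param sub_rate,ts_tv_ratio,indel_rate Passed to [mutate_plastome()].
#' @param hotspot_locus,hotspot_multiplier Optional planted hotspot.
#' @param seed Master seed; derived genomes use `seed + 1 ... seed + n`.
#' @param ... Passed to [generate_plastome()].
#' @return List with `ancestor` (record), `records` (list of derived
#'   records) and `truths` (their manifests).
#' @export
generate_study_set <- function(n_genomes = 4, sub_rate = 0.002,
                               ts_tv_ratio = 2, indel_rate = 0,
                               hotspot_locus = NULL, hotspot_multiplier = 5,
                               seed = 1, ...) {
  base <- generate_plastome(id = "anc", seed = seed, ...)
  mult <- if (!is.null(hotspot_locus)) setNames(hotspot_multiplier, hotspot_locus)
  out <- lapply(seq_len(n_genomes), function(i) {
    mutate_plastome(base$record, base$truth, sub_rate = sub_rate,
                    ts_tv_ratio = ts_tv_ratio, indel_rate = indel_rate,
                    per_locus_multipliers = mult,
                    id = sprintf("sp%d", i), seed = seed + i)
  })
  list(
    ancestor = base$record, ancestor_truth = base$truth,
    records = lapply(out, `[[`, "record"),
    truths = lapply(out, `[[`, "truth")
  )
}

#' Write a fixture directory for a set of synthetic genomes
#'
#' Emits one GenBank and one FASTA file per genome plus a JSON manifest;
#' the GenBank files round-trip losslessly through [read_genbank()].
#'
#' @param records List of [plastome_record()]s.
#' @param truths List of manifests, same length.
#' @param dir Output directory (created if needed).
#' @return Tibble of written paths, invisibly.
#' @export
emit_fixture <- function(records, truths, dir) {
  stopifnot(length(records) == length(truths))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!dir.exists(dir)) abort(sprintf("cannot create directory '%s'", dir))
  }
  paths <- list()
  for (i in seq_along(records)) {
    rec <- records[[i]]
    gb <- file.path(dir, paste0(rec$id, ".gb"))
    fa <- file.path(dir, paste0(rec$id, ".fasta"))
    write_genbank(rec, gb)
    write_fasta(tibble(name = rec$id, sequence = rec$sequence), fa)
    paths[[length(paths) + 1L]] <- tibble(genome = rec$id, genbank = gb, fasta = fa)
  }
  manifest <- lapply(seq_along(truths), function(i) {
    tr <- truths[[i]]
    tr$genes <- as.list(tr$genes)
    tr$ssrs <- as.list(tr$ssrs)
    if (!is.null(tr$mutations)) tr$mutations <- as.list(tr$mutations)
    if (!is.null(tr$indels)) tr$indels <- as.list(tr$indels)
    tr
  })
  names(manifest) <- vapply(records, function(r) r$id, character(1))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dplyr::bind_rows(paths))
}
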