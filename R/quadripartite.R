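# Quadripartite structure: detect the inverted-repeat pair, partition the
# circular genome into LSC/SSC/IRA/IRB and report the four junctions.

#' Detect the inverted-repeat pair and partition the genome
#'
#' Finds the maximal-length pair of disjoint segments on the circular genome
#' where one is the reverse complement of the other, by seed-and-extend on
#' k-mer matches between the sequence and its reverse complement (collinear
#' seeds share an anti-diagonal), followed by greedy boundary extension.
#' The two single-copy segments between the IR copies are labelled LSC
#' (longer) and SSC (shorter).  Following the usual plastome convention the
#' IR copy immediately downstream of the SSC is IRA, the copy downstream of
#' the LSC is IRB, and the four junctions are JSA (SSC/IRA), JLA (IRA/LSC),
#' JLB (LSC/IRB) and JSB (IRB/SSC).
#'
#' The partition is reported in the record's own rotation (region lengths
#' are rotation-invariant; coordinates are not re-rotated to LSC-first).
#'
#' @param rec A [plastome_record()].
#' @param min_ir_len Minimum IR length in bp to accept (>= 1000 recommended
#'   for real plastomes).
#' @param max_mismatch_frac Maximum tolerated mismatch fraction between the
#'   two IR copies during extension; the default 0 requires exact reverse
#'   complements.
#' @param k Seed k-mer length.
#' @return A `region_partition` object with elements `ira`, `irb`, `lsc`,
#'   `ssc` (each `c(start, length)`, 0-based), `junctions` (named 0-based
#'   positions of the first base of the downstream region), and the region
#'   lengths `ir_len`, `lsc_len`, `ssc_len`.
#' @export
detect_inverted_repeats <- function(rec, min_ir_len = 1000,
                                    max_mismatch_frac = 0, k = 25) {
  stopifnot(inherits(rec, "plastome_record"))
  s <- rec$sequence
  n <- rec$length
  if (n < 2 * min_ir_len + 2) {
    abort("no_ir_found: sequence shorter than two IR copies", class = "no_ir_found")
  }
  ch <- seq_chars(s)
  comp <- chartr("ACGTN", "TGCAN", ch)

  s2 <- paste0(s, s)
  rc2 <- revcomp(s2)
  # forward k-mers at circular positions 0..n-1 (1-based substring on s2)
  idx <- seq_len(n)
  fw <- substring(s2, idx, idx + k - 1L)
  # reverse complement of the k-mer starting at 0-based j is the substring
  # of rc2 beginning at 2n - j - k (0-based)
  rk <- substring(rc2, 2L * n - idx + 1L - k + 1L, 2L * n - idx + 1L)

  # join on k-mer value; mask hyper-abundant (low-complexity) seeds, the
  # extension step recovers boundaries through them
  tab <- table(fw)
  busy <- names(tab)[tab > 50]
  keep_f <- !(fw %in% busy) & !grepl("N", fw, fixed = TRUE)
  keep_r <- !(rk %in% busy) & !grepl("N", rk, fixed = TRUE)
  f_split <- split(idx[keep_f] - 1L, fw[keep_f])
  r_split <- split(idx[keep_r] - 1L, rk[keep_r])
  common <- intersect(names(f_split), names(r_split))
  if (length(common) == 0) {
    abort(sprintf("no_ir_found: no inverted repeat of length >= %d detected", min_ir_len),
          class = "no_ir_found")
  }
  seeds_i <- integer(0); seeds_j <- integer(0)
  for (km in common) {
    ii <- f_split[[km]]; jj <- r_split[[km]]
    grid <- expand.grid(i = ii, j = jj)
    seeds_i <- c(seeds_i, grid$i); seeds_j <- c(seeds_j, grid$j)
  }
  ok <- seeds_i != seeds_j
  seeds_i <- seeds_i[ok]; seeds_j <- seeds_j[ok]
  if (length(seeds_i) == 0) {
    abort(sprintf("no_ir_found: no inverted repeat of length >= %d detected", min_ir_len),
          class = "no_ir_found")
  }

  diag_id <- (seeds_i + seeds_j) %% n
  best <- NULL
  for (d in unique(diag_id)) {
    ii <- sort(unique(seeds_i[diag_id == d]))
    # split into clusters of nearby seeds
    cl <- cumsum(c(1L, diff(ii) > k))
    for (g in unique(cl)) {
      i0 <- ii[cl == g][1]
      j0 <- (d - i0) %% n
      cand <- extend_ir(ch, comp, n, i0, j0, k, max_mismatch_frac)
      if (is.null(cand)) next
      if (is.null(best) || cand$len > best$len ||
          (cand$len == best$len && min(cand$a1, cand$b1) < min(best$a1, best$b1))) {
        if (!is.null(best) && cand$len == best$len &&
            !same_pair(cand, best, n)) {
          warn("tie between equal-length candidate IR pairs; choosing the pair with the smaller start")
        }
        if (is.null(best) || cand$len > best$len ||
            (cand$len == best$len && min(cand$a1, cand$b1) < min(best$a1, best$b1))) {
          best <- cand
        }
      }
    }
  }
  if (is.null(best) || best$len < min_ir_len) {
    abort(sprintf("no_ir_found: no inverted repeat of length >= %d detected", min_ir_len),
          class = "no_ir_found")
  }
  partition_from_pair(rec, best, max_mismatch_frac)
}

same_pair <- function(a, b, n) {
  identical(sort(c(a$a1 %% n, a$b1 %% n)), sort(c(b$a1 %% n, b$b1 %% n)))
}

# Greedy extension of a seed (i0, j0, k) where S[i0..i0+k) is the reverse
# complement of S[j0..j0+k).  Returns 0-based circular starts a1, b1 and the
# common length, or NULL if the copies collide during extension.
extend_ir <- function(ch, comp, n, i0, j0, k, max_mm) {
  a1 <- i0; a2 <- i0 + k      # A = [a1, a2)
  b1 <- j0; b2 <- j0 + k      # B = [b1, b2), revcomp-matched to A
  mm <- 0L
  at <- function(p) ch[(p %% n) + 1L]
  cat_ <- function(p) comp[(p %% n) + 1L]
  len <- function() a2 - a1
  gap_right <- function() (b1 - a2) %% n   # forward gap from A end to B start
  gap_left <- function() (a1 - b2) %% n    # forward gap from B end to A start
  # extend right: a2++, b1--
  repeat {
    if (gap_right() <= 0 || len() + gap_left() + len() + gap_right() > n) break
    if (gap_right() == 0) break
    match <- at(a2) == cat_(b1 - 1) && at(a2) != "N"
    if (match) {
      a2 <- a2 + 1L; b1 <- b1 - 1L
    } else if (max_mm > 0 && (mm + 1L) / (len() + 1L) <= max_mm && gap_right() > 1) {
      mm <- mm + 1L; a2 <- a2 + 1L; b1 <- b1 - 1L
    } else break
    if (gap_right() == 0) break
  }
  # extend left: a1--, b2++
  repeat {
    if (gap_left() == 0) break
    match <- at(a1 - 1) == cat_(b2) && at(a1 - 1) != "N"
    if (match) {
      a1 <- a1 - 1L; b2 <- b2 + 1L
    } else if (max_mm > 0 && (mm + 1L) / (len() + 1L) <= max_mm && gap_left() > 1) {
      mm <- mm + 1L; a1 <- a1 - 1L; b2 <- b2 + 1L
    } else break
    if (gap_left() == 0) break
  }
  if (2L * len() >= n) return(NULL)
  list(a1 = a1 %% n, b1 = b1 %% n, len = len())
}

partition_from_pair <- function(rec, pair, max_mismatch_frac) {
  n <- rec$length
  L <- pair$len
  a <- pair$a1; b <- pair$b1
  gap_ab <- (b - (a + L)) %% n   # single-copy gap following segment A
  gap_ba <- (a - (b + L)) %% n   # single-copy gap following segment B
  if (gap_ab == 0 && gap_ba == 0) abort("degenerate partition: no single-copy regions")
  # label the longer gap LSC, the shorter SSC
  if (gap_ab >= gap_ba) {
    lsc <- c((a + L) %% n, gap_ab); ssc <- c((b + L) %% n, gap_ba)
    ira <- c(a %% n, L); irb <- c(b %% n, L)
  } else {
    lsc <- c((b + L) %% n, gap_ba); ssc <- c((a + L) %% n, gap_ab)
    ira <- c(b %% n, L); irb <- c(a %% n, L)
  }
  # IRA is the IR copy immediately downstream of the SSC
  if (((ssc[1] + ssc[2]) %% n) != ira[1]) {
    tmp <- ira; ira <- irb; irb <- tmp
  }
  junctions <- c(
    JSA = ira[1],
    JLA = (ira[1] + L) %% n,
    JLB = irb[1],
    JSB = (irb[1] + L) %% n
  )
  part <- structure(
    list(
      genome = rec$id, n = n,
      ira = ira, irb = irb, lsc = lsc, ssc = ssc,
      ir_len = L, lsc_len = lsc[2], ssc_len = ssc[2],
      junctions = junctions,
      max_mismatch_frac = max_mismatch_frac
    ),
    class = "region_partition"
  )
  if (part$lsc_len + part$ssc_len + 2L * part$ir_len != n) {
    abort("internal error: regions do not tile the genome")
  }
  part
}

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf("<region_partition> %s (%d bp): LSC %d, SSC %d, IR %d x2\n",
              x$genome, x$n, x$lsc_len, x$ssc_len, x$ir_len))
  cat(sprintf("  junctions: %s\n",
              paste(sprintf("%s=%d", names(x$junctions), x$junctions + 1L), collapse = " ")))
  invisible(x)
}

#' @export
tidy.region_partition <- function(x, ...) {
  tibble(
    genome = x$genome,
    region = c("LSC", "SSC", "IRA", "IRB"),
    start = c(x$lsc[1], x$ssc[1], x$ira[1], x$irb[1]) + 1L,
    length = c(x$lsc_len, x$ssc_len, x$ir_len, x$ir_len)
  )
}

#' Which region contains a position
#'
#' @param part A `region_partition`.
#' @param pos 0-based position(s).
#' @return Character vector of `"LSC"`, `"SSC"`, `"IRA"` or `"IRB"`.
#' @export
region_at <- function(part, pos) {
  stopifnot(inherits(part, "region_partition"))
  vapply(pos, function(p) {
    p <- p %% part$n
    if (circ_contains(part$lsc[1], part$lsc[2], p, part$n)) return("LSC")
    if (circ_contains(part$ssc[1], part$ssc[2], p, part$n)) return("SSC")
    if (circ_contains(part$ira[1], part$ira[2], p, part$n)) return("IRA")
    "IRB"
  }, character(1))
}

#' tabular junction report
#'
#' For each of the four junctions, reports the nearest annotated gene on
#' each side and whether a gene spans the junction.  For a spanning gene the
#' two distances are its overhangs into the upstream and downstream regions;
#' otherwise they are the (non-negative) distances from the junction to the
#' nearest gene end on each side, with 0 meaning the gene abuts the junction
#' exactly.  Duplicated genes lying inside an IR copy are labelled with an
#' `_IRA`/`_IRB` suffix.
#'
#' @param rec A [plastome_record()].
#' @param part The [detect_inverted_repeats()] partition of `rec`.
#' @return A tibble with columns `genome`, `junction`, `position` (1-based
#'   position of the first base of the downstream region), `left_gene`,
#'   `left_dist`, `right_gene`, `right_dist`, `spans`.
#' @export
junction_report <- function(rec, part) {
  stopifnot(inherits(rec, "plastome_record"), inherits(part, "region_partition"))
  if (part$n != rec$length) abort("partition was not computed on this record")
  n <- rec$length
  ft <- disambiguate_ir_names(rec, part)
  ft <- ft[ft$kind %in% c("CDS", "tRNA", "rRNA", "pseudogene"), , drop = FALSE]
  if (nrow(ft) == 0) abort("record has no annotated genes")
  ext <- t(vapply(seq_len(nrow(ft)), function(i) {
    feature_extent(ft$parts[[i]], ft$wraps_origin[i], n)
  }, numeric(2)))
  g_start <- ext[, 1] %% n
  g_len <- ext[, 2] - ext[, 1]

  rows <- lapply(c("JLA", "JLB", "JSA", "JSB"), function(jname) {
    p <- part$junctions[[jname]]
    inside <- ((p - g_start) %% n)
    spans_i <- which(inside > 0 & inside < g_len)
    if (length(spans_i) > 0) {
      i <- spans_i[which.max(g_len[spans_i])]
      tibble(
        genome = rec$id, junction = jname, position = p + 1L,
        left_gene = ft$name[i], left_dist = as.integer(inside[i]),
        right_gene = ft$name[i], right_dist = as.integer(g_len[i] - inside[i]),
        spans = TRUE
      )
    } else {
      d_left <- (p - (g_start + g_len)) %% n
      d_right <- (g_start - p) %% n
      li <- which.min(d_left); ri <- which.min(d_right)
      tibble(
        genome = rec$id, junction = jname, position = p + 1L,
        left_gene = ft$name[li], left_dist = as.integer(d_left[li]),
        right_gene = ft$name[ri], right_dist = as.integer(d_right[ri]),
        spans = FALSE
      )
    }
  })
  dplyr::bind_rows(rows)
}
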