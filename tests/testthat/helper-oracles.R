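# Independent oracles used to cross-check the implementation.  These are
# deliberately written with different algorithms from the package code.

# Exhaustive SSR scan: tests every (start, unit) pair with explicit
# copy-by-copy comparison.  Same locus definition as the miner: maximal
# perfect tandem, left-aligned at the run start, primitive motif, whole
# copies, no N.
brute_force_ssrs <- function(s, min_total = rep(10, 6)) {
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(ch)
  out <- list()
  for (u in 1:6) {
    if (n < 2 * u) next
    for (st in seq_len(n - 2 * u + 1)) {
      run_start <- st == 1 ||
        ch[st - 1] != ch[st - 1 + u] || ch[st - 1] == "N"
      if (!run_start) next
      motif <- ch[st:(st + u - 1)]
      if (any(motif == "N")) next
      cp <- 1L
      repeat {
        nxt <- st + cp * u
        if (nxt + u - 1 > n) break
        blk <- ch[nxt:(nxt + u - 1)]
        if (any(blk != motif) || any(blk == "N")) break
        cp <- cp + 1L
      }
      if (cp < 2 || cp * u < min_total[u]) next
      mstr <- paste(motif, collapse = "")
      if (!oracle_primitive(mstr)) next
      out[[length(out) + 1L]] <- data.frame(
        motif = mstr, unit_len = u, copies = cp,
        start = st - 1L, end = st - 1L + cp * u
      )
    }
  }
  if (length(out) == 0) {
    return(data.frame(motif = character(), unit_len = integer(),
                      copies = integer(), start = integer(), end = integer()))
  }
  res <- do.call(rbind, out)
  res[order(res$start, res$unit_len), , drop = FALSE]
}

oracle_primitive <- function(m) {
  u <- nchar(m)
  for (d in seq_len(u - 1)) {
    if (u %% d == 0 && strrep(substr(m, 1, d), u / d) == m) return(FALSE)
  }
  TRUE
}

# Gotoh global alignment score with match +1 / mismatch -1 and affine gaps
# (first gap base -4, each further -1), for tiny sequences.
gotoh_score <- function(a, b, match = 1, mismatch = -1, open = -4, extend = -1) {
  x <- strsplit(a, "")[[1]]; y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1); X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1, 1] <- open + extend * (i - 1)
  for (j in seq_len(m)) Y[1, j + 1] <- open + extend * (j - 1)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (x[i] == y[j]) match else mismatch
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] + open, X[i, j + 1] + extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] + open, Y[i + 1, j] + extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# Score a gapped pairwise alignment under the same scheme.
score_pairwise <- function(r1, r2, match = 1, mismatch = -1, open = -4, extend = -1) {
  a <- strsplit(r1, "")[[1]]; b <- strsplit(r2, "")[[1]]
  sc <- 0; in_gap <- FALSE
  for (k in seq_along(a)) {
    if (a[k] == "-" || b[k] == "-") {
      sc <- sc + if (in_gap) extend else open
      in_gap <- TRUE
    } else {
      sc <- sc + if (a[k] == b[k]) match else mismatch
      in_gap <- FALSE
    }
  }
  sc
}

# Indel events by direct column scanning (no rle).
count_indels_oracle <- function(rows) {
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  keys <- character(0)
  for (i in seq_len(nrow(m))) {
    s <- NA
    for (j in seq_len(ncol(m) + 1)) {
      gap <- j <= ncol(m) && m[i, j] == "-"
      if (gap && is.na(s)) s <- j
      if (!gap && !is.na(s)) {
        keys <- c(keys, paste(s, j - 1))
        s <- NA
      }
    }
  }
  length(unique(keys))
}

random_dna <- function(n, gc = 0.4, with_n = 0) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2, 0)
  p[5] <- with_n
  p <- p / sum(p)
  paste(sample(c("A", "C", "G", "T", "N"), n, replace = TRUE, prob = p),
        collapse = "")
}
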