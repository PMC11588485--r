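# SNP calling from a whole-genome alignment, Kimura 2-parameter distances,
# hand-rolled neighbor joining with deterministic tie-breaks, bootstrap
# supports over SNP columns, Newick output.

#' Call SNPs against a reference from a multiple alignment
#'
#' Retains alignment columns with no gaps or `N` in any row and at least
#' two states among A/C/G/T, and reports their positions in ungapped
#' 1-based reference coordinates.
#'
#' @param aln An [as_alignment()] object (or coercible).
#' @param reference Name of the reference row.
#' @return An `snp_matrix`: list with `taxa`, `positions` and `states`
#'   (taxa x positions character matrix).
#' @export
call_snps <- function(aln, reference = names(aln)[1]) {
  aln <- as_alignment(aln)
  if (!reference %in% names(aln)) {
    abort(sprintf("reference '%s' is not among the alignment rows", reference))
  }
  m <- aln_matrix(aln)
  clean <- colSums(m == "-" | m == "N") == 0
  poly <- apply(m, 2, function(col) length(unique(col)) > 1)
  keep <- which(clean & poly)
  ref_pos <- cumsum(m[reference, ] != "-")
  structure(
    list(
      taxa = names(aln),
      reference = reference,
      positions = as.integer(ref_pos[keep]),
      states = m[, keep, drop = FALSE]
    ),
    class = "snp_matrix"
  )
}

#' @export
print.snp_matrix <- function(x, ...) {
  cat(sprintf("<snp_matrix> %d SNPs x %d taxa (reference %s)\n",
              length(x$positions), length(x$taxa), x$reference))
  invisible(x)
}

#' @export
tidy.snp_matrix <- function(x, ...) {
  if (length(x$positions) == 0) {
    return(tibble(position = integer(), taxon = character(), state = character()))
  }
  tidyr::expand_grid(position = x$positions, taxon = x$taxa) |>
    dplyr::mutate(state = mapply(function(p, t) {
      x$states[t, which(x$positions == p)[1]]
    }, .data$position, .data$taxon))
}

#' Kimura 2-parameter distance between two aligned rows
#'
#' `d = -1/2 log((1 - 2P - Q) sqrt(1 - 2Q))` with `P` and `Q` the transition
#' and transversion fractions over sites where both rows carry a base.
#'
#' @param seq_i,seq_j Aligned sequences (strings or character vectors).
#' @return The K2P distance (a single non-negative number).
#' @export
k2p_distance <- function(seq_i, seq_j) {
  a <- if (length(seq_i) == 1) seq_chars(toupper(seq_i)) else toupper(seq_i)
  b <- if (length(seq_j) == 1) seq_chars(toupper(seq_j)) else toupper(seq_j)
  if (length(a) != length(b)) abort("rows differ in length")
  ok <- a %in% DNA_BASES & b %in% DNA_BASES
  if (!any(ok)) abort("no comparable sites")
  a <- a[ok]; b <- b[ok]
  P <- mean(transition_pair(a, b))
  Q <- mean(a != b & !transition_pair(a, b))
  k2p_from_pq(P, Q)
}

k2p_from_pq <- function(P, Q, fallback = FALSE) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    if (fallback) return(P + Q)  # raw divergence; preserves ordering for NJ
    abort(sprintf("K2P distance saturated (P = %.3f, Q = %.3f): log argument <= 0", P, Q))
  }
  -0.5 * log(w1 * sqrt(w2))
}

#' Pairwise K2P distance matrix of an alignment
#'
#' @param aln An alignment.
#' @param fallback Replace saturated pairs by their raw divergence `P + Q`
#'   instead of failing (used internally for bootstrap replicates).
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
k2p_matrix <- function(aln, fallback = FALSE) {
  aln <- as_alignment(aln)
  m <- aln_matrix(aln)
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(names(aln), names(aln)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- m[i, ]; b <- m[j, ]
      ok <- a %in% DNA_BASES & b %in% DNA_BASES
      if (!any(ok)) abort("no comparable sites for a sequence pair")
      P <- mean(transition_pair(a[ok], b[ok]))
      Q <- mean(a[ok] != b[ok] & !transition_pair(a[ok], b[ok]))
      d[i, j] <- d[j, i] <- k2p_from_pq(P, Q, fallback = fallback)
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining with two determinism/robustness conventions:
#' ties in the Q criterion are broken by (sorted) taxon-name order, and a
#' negative branch length is clamped to 0 with the deficit moved to its
#' sister branch so path lengths are preserved.  On an additive matrix the
#' generating topology and branch lengths are recovered exactly.
#'
#' @param dist Symmetric numeric matrix with dimnames, n >= 3.
#' @return An unrooted `ape::phylo` tree.
#' @export
nj_tree <- function(dist) {
  if (!is.matrix(dist)) dist <- as.matrix(dist)
  if (nrow(dist) < 3) abort("neighbor joining needs at least 3 taxa")
  if (max(abs(dist - t(dist))) > 1e-8) abort("distance matrix is not symmetric")
  labs <- rownames(dist) %||% paste0("t", seq_len(nrow(dist)))
  ord <- order(labs)
  d <- dist[ord, ord, drop = FALSE]
  node <- labs[ord]          # newick fragment per active node
  leaf_name <- labs[ord]     # tie-break key: smallest leaf name under node

  fmt <- function(x) sprintf("%.10g", x)
  while (nrow(d) > 3) {
    N <- nrow(d)
    r <- rowSums(d)
    best <- NULL
    for (i in seq_len(N - 1)) {
      for (j in (i + 1):N) {
        q <- (N - 2) * d[i, j] - r[i] - r[j]
        if (is.null(best) || q < best$q - 1e-12) best <- list(q = q, i = i, j = j)
      }
    }
    i <- best$i; j <- best$j
    li <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (N - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    li <- max(li, 0); lj <- max(lj, 0)
    merged <- sprintf("(%s:%s,%s:%s)", node[i], fmt(li), node[j], fmt(lj))
    dk <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(N), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    node <- c(node[keep], merged)
    leaf_name <- c(leaf_name[keep], min(leaf_name[c(i, j)]))
    # keep active nodes sorted by their smallest leaf so tie-breaks follow
    # taxon-name order
    o <- order(leaf_name)
    d <- d2[o, o, drop = FALSE]
    node <- node[o]
    leaf_name <- leaf_name[o]
  }
  la <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  lb <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  lc <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);",
                    node[1], fmt(max(la, 0)), node[2], fmt(max(lb, 0)),
                    node[3], fmt(max(lc, 0)))
  ape::read.tree(text = newick)
}

#' Bootstrap supports for the internal edges of a tree
#'
#' Resamples SNP columns with replacement, rebuilds a neighbor-joining tree
#' per replicate from K2P distances over the resampled columns (saturated
#' pairs fall back to raw divergence), and reports for each internal node
#' of the point-estimate tree the percentage of replicates containing its
#' bipartition.
#'
#' @param snps An `snp_matrix` from [call_snps()].
#' @param tree The point-estimate tree whose bipartitions are scored; when
#'   `NULL` it is built from the full SNP matrix.
#' @param replicates Number of bootstrap replicates.
#' @param seed Optional RNG seed for reproducibility.
#' @return Numeric vector of supports in \[0, 100\], one per internal node
#'   of `tree` (the root entry counts the trivial full split).
#' @export
bootstrap_support <- function(snps, tree = NULL, replicates = 500, seed = NULL) {
  stopifnot(inherits(snps, "snp_matrix"), replicates >= 1)
  ncols <- ncol(snps$states)
  if (ncols == 0) abort("empty SNP matrix: nothing to resample")
  if (!is.null(seed)) set.seed(seed)
  snp_dist <- function(cols) {
    sub <- snps$states[, cols, drop = FALSE]
    n <- nrow(sub)
    d <- matrix(0, n, n, dimnames = list(snps$taxa, snps$taxa))
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        a <- sub[i, ]; b <- sub[j, ]
        P <- mean(transition_pair(a, b))
        Q <- mean(a != b & !transition_pair(a, b))
        d[i, j] <- d[j, i] <- k2p_from_pq(P, Q, fallback = TRUE)
      }
    }
    d
  }
  if (is.null(tree)) tree <- nj_tree(snp_dist(seq_len(ncols)))
  boots <- lapply(seq_len(replicates), function(b) {
    nj_tree(snp_dist(sample.int(ncols, ncols, replace = TRUE)))
  })
  counts <- ape::prop.clades(tree, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0
  100 * counts / replicates
}

#' SNP-based distance phylogeny of aligned genomes
#'
#' End-to-end wrapper: calls SNPs against the reference, computes the K2P
#' distance matrix over the full alignment, builds the neighbor-joining
#' tree, attaches bootstrap supports from SNP-column resampling, and
#' renders Newick with supports as internal node labels.  The tree is built
#' unrooted; `outgroup` only affects the rooting of the output tree.
#'
#' @param aln Whole-genome multiple alignment (>= 3 rows).
#' @param reference Reference row name for SNP coordinates.
#' @param replicates Bootstrap replicates (500 is the conventional default).
#' @param seed Optional RNG seed.
#' @param outgroup Optional taxon to root the output tree on.
#' @return A `plastome_phylo` object: `snps`, `dist`, `tree` (with
#'   `node.label` supports), `newick`, `replicates`.
#' @export
plastome_phylogeny <- function(aln, reference = names(aln)[1],
                               replicates = 500, seed = NULL, outgroup = NULL) {
  aln <- as_alignment(aln)
  if (length(aln) < 3) abort("need at least 3 genomes for a tree")
  snps <- call_snps(aln, reference = reference)
  dist <- k2p_matrix(aln)
  tree <- nj_tree(dist)
  supports <- bootstrap_support(snps, tree = tree, replicates = replicates, seed = seed)
  tree$node.label <- as.character(round(supports))
  if (!is.null(outgroup)) {
    if (!outgroup %in% tree$tip.label) abort(sprintf("outgroup '%s' not in tree", outgroup))
    tree <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  }
  structure(
    list(snps = snps, dist = dist, tree = tree,
         newick = ape::write.tree(tree), replicates = replicates),
    class = "plastome_phylo"
  )
}

#' @export
print.plastome_phylo <- function(x, ...) {
  cat(sprintf("<plastome_phylo> %d taxa, %d SNPs, %d bootstrap replicates\n",
              length(x$snps$taxa), length(x$snps$positions), x$replicates))
  cat("  ", x$newick, "\n")
  invisible(x)
}

#' @export
tidy.plastome_phylo <- function(x, ...) {
  tr <- x$tree
  ntip <- length(tr$tip.label)
  tibble(
    parent = tr$edge[, 1],
    node = tr$edge[, 2],
    branch_length = tr$edge.length,
    label = ifelse(tr$edge[, 2] <= ntip, tr$tip.label[tr$edge[, 2]],
                   (tr$node.label %||% rep(NA_character_, tr$Nnode))[tr$edge[, 2] - ntip]),
    is_tip = tr$edge[, 2] <= ntip
  )
}

#' @export
glance.plastome_phylo <- function(x, ...) {
  sup <- suppressWarnings(as.numeric(x$tree$node.label))
  tibble(
    n_taxa = length(x$snps$taxa),
    n_snps = length(x$snps$positions),
    replicates = x$replicates,
    min_support = if (all(is.na(sup))) NA_real_ else min(sup, na.rm = TRUE),
    mean_k2p = mean(x$dist[upper.tri(x$dist)])
  )
}

#' @export
plot.plastome_phylo <- function(x, ...) {
  ape::plot.phylo(x$tree, ...)
  if (!is.null(x$tree$node.label)) ape::nodelabels(x$tree$node.label, frame = "none", adj = -0.2)
  invisible(x)
}
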