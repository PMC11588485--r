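test_that("SNP calling keeps clean polymorphic columns in reference coordinates", {
  ident <- setNames(rep("ACGTACGT", 3), c("r", "a", "b"))
  expect_length(call_snps(ident, "r")$positions, 0)
  rows <- c(r = "ACGTAC", a = "ACGTAC", b = "ACGTAC", c = "ACGTGC")
  sn <- call_snps(rows, "r")
  expect_equal(sn$positions, 5L)
  expect_equal(unname(sn$states[, 1]), c("A", "A", "A", "G"))
  # gap and N columns are excluded; positions follow ungapped reference
  rows2 <- c(r = "A-CGT", a = "ATCGT", b = "ATCGA", c = "ATCGA")
  sn2 <- call_snps(rows2, "r")
  expect_equal(sn2$positions, 4L)
  expect_error(call_snps(rows2, "zz"), "not among")
})

test_that("planted substitutions are recovered from the study alignment", {
  st <- study_fixture()   # substitution-only, so columns equal ancestor sites
  rows <- c(
    setNames(st$ancestor$sequence, "anc"),
    setNames(vapply(st$records, function(r) r$sequence, character(1)),
             vapply(st$records, function(r) r$id, character(1)))
  )
  sn <- call_snps(as_alignment(rows), reference = "anc")
  manifest <- sort(unique(unlist(lapply(st$truths, function(t) t$mutations$pos)))) + 1L
  expect_identical(sn$positions, as.integer(manifest))
})

test_that("K2P distances match the closed form", {
  expect_equal(k2p_distance("ACGTACGT", "ACGTACGT"), 0)
  # P = 0.1, Q = 0.05 over 20 sites: 2 transitions + 1 transversion
  x <- strrep("A", 20)
  y <- paste0("GG", "T", strrep("A", 17))
  expect_equal(k2p_distance(x, y), -0.5 * log(0.75 * sqrt(0.9)), tolerance = 1e-12)
  expect_equal(k2p_distance(x, y), 0.17017, tolerance = 1e-4)
  # P = 0, Q = 0.25 over 8 sites: 2 transversions
  x2 <- strrep("A", 8); y2 <- paste0("TT", strrep("A", 6))
  expect_equal(k2p_distance(x2, y2), -0.5 * log(0.75 * sqrt(0.5)), tolerance = 1e-12)
  # transition-only limit
  x3 <- strrep("A", 10); y3 <- paste0("GG", strrep("A", 8))
  expect_equal(k2p_distance(x3, y3), -0.5 * log((1 - 0.4) * 1), tolerance = 1e-12)
  expect_error(k2p_distance("AAAA", "GGGG"), "saturated")
})

test_that("K2P matrix agrees with an established implementation", {
  st <- study_fixture()
  rows <- setNames(vapply(st$records, function(r) substr(r$sequence, 1, 8000),
                          character(1)),
                   vapply(st$records, function(r) r$id, character(1)))
  d1 <- k2p_matrix(as_alignment(rows))
  bin <- ape::as.DNAbin(do.call(rbind, strsplit(tolower(rows), "")))
  d2 <- as.matrix(ape::dist.dna(bin, model = "K80"))
  expect_equal(d1, d2[rownames(d1), colnames(d1)], tolerance = 1e-10)
})

test_that("neighbor joining recovers additive trees exactly", {
  # tree ((a:2,b:3):1,(c:4,d:5)) -> path-length matrix
  labs <- c("a", "b", "c", "d")
  d <- matrix(0, 4, 4, dimnames = list(labs, labs))
  d["a", "b"] <- d["b", "a"] <- 5
  d["a", "c"] <- d["c", "a"] <- 7
  d["a", "d"] <- d["d", "a"] <- 8
  d["b", "c"] <- d["c", "b"] <- 8
  d["b", "d"] <- d["d", "b"] <- 9
  d["c", "d"] <- d["d", "c"] <- 9
  tr <- nj_tree(d)
  expect_equal(as.matrix(ape::cophenetic.phylo(tr))[labs, labs], d,
               tolerance = 1e-9)
  ref <- ape::read.tree(text = "((a:2,b:3):1,(c:4,d:5):0);")
  expect_equal(ape::dist.topo(ape::unroot(tr), ape::unroot(ref)), 0,
               ignore_attr = TRUE)
})

test_that("three taxa give the closed-form star lengths", {
  labs <- c("x", "y", "z")
  d <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3, dimnames = list(labs, labs))
  tr <- nj_tree(d)
  cp <- as.matrix(ape::cophenetic.phylo(tr))[labs, labs]
  expect_equal(cp, d, tolerance = 1e-9)
  el <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(el[c("x", "y", "z")]), c(1, 2, 3))
})

test_that("NJ topology matches ape::nj and is invariant to taxon order", {
  set.seed(71)
  st <- study_fixture()
  rows <- setNames(vapply(st$records, function(r) substr(r$sequence, 1, 6000),
                          character(1)),
                   vapply(st$records, function(r) r$id, character(1)))
  d <- k2p_matrix(as_alignment(rows))
  t1 <- nj_tree(d)
  t2 <- nj_tree(d[c(3, 1, 4, 2), c(3, 1, 4, 2)])
  expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t2)), 0,
               ignore_attr = TRUE)
  t3 <- ape::nj(as.dist(d))
  expect_equal(ape::dist.topo(ape::unroot(t1), ape::unroot(t3)), 0,
               ignore_attr = TRUE)
  expect_error(nj_tree(matrix(c(0, 1, 2, 0), 2, 2)), "at least 3")
  dd <- d; dd[1, 2] <- dd[1, 2] + 1
  expect_error(nj_tree(dd), "symmetric")
})

test_that("bootstrap saturates on well-separated clades and is reproducible", {
  block <- function(a, b) paste0(strrep(a, 30), strrep(b, 30))
  rows <- c(a1 = block("A", "C"), a2 = block("A", "C"),
            b1 = block("G", "T"), b2 = block("G", "T"))
  rows <- vapply(seq_along(rows), function(i) {
    s <- rows[[i]]
    substr(s, i, i) <- "T"   # private states so all pairs are distinct
    s
  }, character(1)) |> setNames(names(rows))
  sn <- call_snps(as_alignment(rows), "a1")
  sup <- bootstrap_support(sn, replicates = 100, seed = 4)
  expect_equal(unname(sup[length(sup)]), 100)  # the a|b split
  sup2 <- bootstrap_support(sn, replicates = 100, seed = 4)
  expect_identical(sup, sup2)
  empty <- call_snps(setNames(rep("AAAA", 3), c("x", "y", "z")), "x")
  expect_error(bootstrap_support(empty), "empty")
})

test_that("an 8-taxon radiation has all true clades strongly supported", {
  set.seed(72)
  base <- generate_plastome(lsc_len = 4000, ssc_len = 1500, ir_len = 2600,
                            n_genes = 8, n_ssrs = 4, seed = 801)
  # two rounds of divergence: 4 subclades of 2 tips each
  mk <- function(rec, truth, rate, id, seed) {
    mutate_plastome(rec, truth, sub_rate = rate, id = id, seed = seed)
  }
  clades <- lapply(1:4, function(k) mk(base$record, base$truth, 0.01,
                                       sprintf("cl%d", k), 900 + 17 * k))
  tips <- list()
  for (k in 1:4) {
    for (j in 1:2) {
      tips[[length(tips) + 1L]] <- mk(clades[[k]]$record, clades[[k]]$truth,
                                      0.002, sprintf("t%d%d", k, j),
                                      1300 + 29 * (2 * k + j))
    }
  }
  rows <- setNames(vapply(tips, function(t) t$record$sequence, character(1)),
                   vapply(tips, function(t) t$record$id, character(1)))
  ph <- plastome_phylogeny(as_alignment(rows), replicates = 200, seed = 5)
  sup <- suppressWarnings(as.numeric(ph$tree$node.label))
  # every true 2-tip clade must appear with strong support
  for (k in 1:4) {
    pair <- sprintf("t%d%d", k, 1:2)
    mrca <- ape::getMRCA(ph$tree, pair)
    tips_below <- ape::extract.clade(ph$tree, mrca)$tip.label
    expect_setequal(tips_below, pair)
    expect_gte(sup[mrca - length(ph$tree$tip.label)], 90)
  }
})

test_that("doubling bootstrap replicates moves no support more than 10 points", {
  st <- study_fixture()
  rows <- setNames(vapply(st$records, function(r) r$sequence, character(1)),
                   vapply(st$records, function(r) r$id, character(1)))
  sn <- call_snps(as_alignment(rows), names(rows)[1])
  tr <- nj_tree(k2p_matrix(as_alignment(rows)))
  s1 <- bootstrap_support(sn, tree = tr, replicates = 200, seed = 31)
  s2 <- bootstrap_support(sn, tree = tr, replicates = 400, seed = 32)
  expect_true(all(abs(s1 - s2) <= 10))
})
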