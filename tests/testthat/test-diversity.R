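test_that("pair frequencies classify identical, transition and transversion pairs", {
  expect_equal(pair_frequencies(c(a = "ACGT", b = "ACGT"))$identical_pct, 100)
  pf <- pair_frequencies(c(a = "ACGT", b = "ACGA"))
  expect_equal(c(pf$identical_pct, pf$transition_pct, pf$transversion_pct),
               c(75, 0, 25))
  pf2 <- pair_frequencies(c(a = "AG", b = "GG"))
  expect_equal(c(pf2$identical_pct, pf2$transition_pct, pf2$transversion_pct),
               c(50, 50, 0))
  expect_error(pair_frequencies(c(a = "--", b = "AA")), "no comparable")
})

test_that("identical + transition + transversion always total 100", {
  st <- study_fixture()
  aln <- as_alignment(setNames(
    vapply(st$records, function(r) r$sequence, character(1)),
    vapply(st$records, function(r) r$id, character(1))
  ))
  for (mode in c("pairwise", "complete")) {
    pf <- pair_frequencies(aln, deletion = mode)
    expect_equal(pf$identical_pct + pf$transition_pct + pf$transversion_pct,
                 100, tolerance = 0.01)
  }
})

test_that("nucleotide diversity matches hand-enumerated values", {
  a <- c(s1 = paste0(strrep("A", 99), "A"), s2 = paste0(strrep("A", 99), "C"))
  expect_equal(nucleotide_diversity(a), 0.01)
  ident <- setNames(rep(strrep("ACGT", 5), 4), paste0("s", 1:4))
  expect_equal(nucleotide_diversity(ident), 0)
  # 10 sites, one site split 2/2 -> (4/6)/10
  rows <- c(s1 = "AAAAAAAAAA", s2 = "AAAAAAAAAA", s3 = "AAAAAAAAAT", s4 = "AAAAAAAAAT")
  expect_equal(nucleotide_diversity(rows), (4 / 6) / 10)
  # complete deletion: gap column excluded in every pair
  gapped <- c(s1 = "A-AAA", s2 = "ACAAA", s3 = "ACAAT")
  expect_equal(nucleotide_diversity(gapped), (2 / 3) / 4)
})

test_that("Tajima's D is undefined at S = 0 and matches the frozen closed form", {
  ident <- setNames(rep("ACGTACGT", 4), paste0("s", 1:4))
  expect_true(is.na(tajimas_d(ident)))
  # n = 4, L = 10, S = 3 fixture evaluated by hand from the standard
  # a1/a2/b1/b2/c1/c2/e1/e2 constants: D = 0.16765
  rows <- c(t1 = "AAAAAAAAAA",
            t2 = "AAAAAAAAGA",
            t3 = "AAAAAAATAA",
            t4 = "AAAAAAATAC")
  expect_equal(tajimas_d(rows), 0.16765, tolerance = 1e-4)
})

test_that("duplicating every column preserves the sign of D", {
  rows <- c(t1 = "AAAAAAAAAA",
            t2 = "AAAAAAAAGA",
            t3 = "AAAAAAATAA",
            t4 = "AAAAAAATAC")
  d1 <- tajimas_d(rows)
  doubled <- vapply(strsplit(rows, ""), function(ch) {
    paste(rep(ch, each = 2), collapse = "")
  }, character(1))
  d2 <- tajimas_d(doubled)
  expect_equal(sign(d1), sign(d2))
})

test_that("indel events merge identical gap runs across rows", {
  expect_equal(count_indel_events(c(a = "AC--GT", b = "ACTTGT")), 1)
  expect_equal(count_indel_events(c(a = "A--C", b = "A--C", c = "ATTC")), 1)
  expect_equal(count_indel_events(c(a = "A--C", b = "AT-C")), 2)
  set.seed(51)
  for (rep in 1:20) {
    rows <- vapply(1:4, function(i) {
      ch <- sample(c("A", "C", "G", "T", "-"), 60, replace = TRUE,
                   prob = c(0.22, 0.22, 0.22, 0.22, 0.12))
      paste(ch, collapse = "")
    }, character(1))
    names(rows) <- paste0("s", 1:4)
    expect_equal(count_indel_events(rows), count_indels_oracle(rows))
  }
})

test_that("SV follows its defining formula", {
  # 102 conserved + 3 mutation columns + 2 indel events -> 5/107 * 100
  base <- strrep("A", 100)
  r1 <- paste0(base, "CCC", "GG", "AAAA")
  r2 <- paste0(base, "TTT", "--", "AAAA")
  r3 <- paste0(base, "CCC", "GG", "--AA")
  sv <- sequence_variability(c(a = r1, b = r2, c = r3))
  expect_equal(sv$n_conserved, 102)
  expect_equal(sv$n_mutations, 3)
  expect_equal(sv$n_indel_events, 2)
  expect_equal(sv$sv, 100 * 5 / 107, tolerance = 1e-9)
})

test_that("SV matches hand-tallied counts on a fixture alignment", {
  rows <- c(
    a = "AAAAAAAAAACGTAC--GTA",
    b = "AAAAAAAAAACGAAC--GTA",
    c = "AAAAAAAAAACGTTCTTGTA"
  )
  # gap-free columns: 18; polymorphic: col 13 (T/A/T) and col 14 (A/A/T);
  # indel events: the shared run counts once
  sv <- sequence_variability(rows)
  expect_equal(sv$n_indel_events, 1)
  expect_equal(sv$n_mutations, 2)
  expect_equal(sv$n_conserved, 16)
  expect_equal(sv$sv, 100 * (2 + 1) / (16 + 2 + 1), tolerance = 1e-9)
  expect_equal(sequence_variability(c(a = "ACGT", b = "ACGT"))$sv, 0)
})

test_that("SV never decreases as mutation columns are added", {
  base <- setNames(rep(strrep("A", 50), 3), c("x", "y", "z"))
  prev <- sequence_variability(base)$sv
  rows <- base
  for (k in 1:5) {
    substr(rows["y"], k, k) <- "G"
    cur <- sequence_variability(rows)$sv
    expect_gte(cur, prev)
    prev <- cur
  }
})

test_that("pi and D are invariant under row reordering and column permutation", {
  set.seed(53)
  st <- study_fixture()
  rows <- setNames(vapply(st$records, function(r) substr(r$sequence, 1, 3000),
                          character(1)),
                   vapply(st$records, function(r) r$id, character(1)))
  p0 <- nucleotide_diversity(rows); d0 <- tajimas_d(rows)
  perm <- sample(4)
  expect_equal(nucleotide_diversity(rows[perm]), p0)
  expect_equal(tajimas_d(rows[perm]), d0)
  cols <- sample(3000)
  shuffled <- vapply(rows, function(s) {
    paste(strsplit(s, "")[[1]][cols], collapse = "")
  }, character(1))
  expect_equal(nucleotide_diversity(shuffled), p0)
  expect_equal(tajimas_d(shuffled), d0)
})
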