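test_that("mononucleotide runs are found with motif, copies and length", {
  s <- paste0("G", strrep("A", 12), "C")
  hit <- find_ssrs(s)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$motif, "A")
  expect_equal(hit$copies, 12L)
  expect_equal(hit$total_len, 12L)
  expect_equal(c(hit$start, hit$end), c(1L, 13L))
  expect_equal(hit$length_bin, "10-20")
})

test_that("periodic runs are reported at their smallest period only", {
  hit <- find_ssrs("ATATATATAT")
  expect_equal(nrow(hit), 1)
  expect_equal(hit$motif, "AT")
  expect_equal(hit$copies, 5L)
  expect_equal(hit$unit_len, 2L)
})

test_that("no SSR spans an N", {
  s <- paste0(strrep("A", 6), "N", strrep("A", 6))
  expect_equal(nrow(find_ssrs(s)), 0)
  s2 <- paste0(strrep("A", 11), "N", strrep("A", 4))
  hit <- find_ssrs(s2)
  expect_equal(nrow(hit), 1)
  expect_equal(hit$copies, 11L)
})

test_that("the miner set-equals the exhaustive oracle on random sequences", {
  set.seed(31)
  for (rep in 1:6) {
    s <- random_dna(20000, gc = 0.3)
    got <- as.data.frame(find_ssrs(s)[, c("motif", "unit_len", "copies", "start", "end")])
    want <- brute_force_ssrs(s)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want)
  }
  # AT-rich sequences are SSR-dense
  s <- random_dna(20000, gc = 0.12)
  got <- as.data.frame(find_ssrs(s)[, c("motif", "unit_len", "copies", "start", "end")])
  want <- brute_force_ssrs(s)
  rownames(got) <- rownames(want) <- NULL
  expect_gt(nrow(got), 20)
  expect_equal(got, want)
})

test_that("reported loci are maximal: one more unit on either side breaks the tandem", {
  set.seed(32)
  s <- random_dna(30000, gc = 0.2)
  ch <- strsplit(s, "")[[1]]
  hits <- find_ssrs(s)
  for (i in seq_len(nrow(hits))) {
    u <- hits$unit_len[i]; st <- hits$start[i]; en <- hits$end[i]
    motif <- strsplit(hits$motif[i], "")[[1]]
    if (st - u >= 0) {
      expect_false(all(ch[(st - u + 1):st] == motif))
    }
    if (en + u <= nchar(s)) {
      expect_false(all(ch[(en + 1):(en + u)] == motif))
    }
  }
})

test_that("with exact IRs every SSR inside IRA has a twin inside IRB", {
  g <- synth_fixture()
  part <- detect_inverted_repeats(g$record)
  ssrs <- annotate_ssr_context(find_ssrs(g$record), g$record, part)
  inside <- function(reg, iv) {
    ssrs[ssrs$start >= iv[1] & ssrs$end <= iv[1] + iv[2], ]
  }
  a <- inside("IRA", part$ira); b <- inside("IRB", part$irb)
  key <- function(df) sort(paste(df$unit_len, df$copies, df$total_len))
  expect_gt(nrow(b), 0)
  expect_identical(key(a), key(b))
})

test_that("planted SSR contexts and regions are recovered", {
  g <- synth_fixture()
  part <- detect_inverted_repeats(g$record)
  ssrs <- annotate_ssr_context(find_ssrs(g$record), g$record, part)
  planted <- g$truth$ssrs
  for (i in seq_len(nrow(planted))) {
    hit <- ssrs[ssrs$start == planted$start[i], ]
    expect_equal(nrow(hit), 1)
    expect_equal(hit$motif, planted$motif[i])
    expect_equal(hit$copies, planted$copies[i])
    want_ctx <- if (planted$context[i] == "intergenic") "intergenic" else planted$context[i]
    expect_equal(hit$context, want_ctx)
    expect_equal(hit$region, planted$region[i])
  }
})

test_that("context priority prefers CDS over intergenic on overlap", {
  ft <- feature_row("geneA", "CDS", "+", list(c(20, 50)))
  s <- paste0(random_dna(45), strrep("A", 12), random_dna(60))
  # locus [45, 57) overlaps the CDS end (50) and intergenic DNA
  rec <- plastome_record("t", s, ft, circular = FALSE)
  ssrs <- find_ssrs(rec)
  ssrs <- ssrs[ssrs$motif == "A" & ssrs$start <= 46, ]
  part <- structure(list(genome = "t", n = rec$length,
                         lsc = c(0, rec$length), ssc = c(0, 0),
                         ira = c(0, 0), irb = c(0, 0),
                         ir_len = 0, lsc_len = rec$length, ssc_len = 0,
                         junctions = c(JLA = 0, JLB = 0, JSA = 0, JSB = 0)),
                    class = "region_partition")
  ann <- annotate_ssr_context(ssrs, rec, part)
  expect_equal(ann$context, "CDS")
})

test_that("summary tables count correctly and percentages sum to 100", {
  g <- synth_fixture()
  part <- detect_inverted_repeats(g$record)
  ssrs <- annotate_ssr_context(find_ssrs(g$record), g$record, part)
  sums <- summarize_ssrs(ssrs)
  for (nm in names(sums)) {
    tab <- sums[[nm]]
    expect_equal(sum(tab$n), nrow(ssrs), info = nm)
    expect_equal(sum(tab$pct), 100, tolerance = 0.01)
  }
  # category percentages on a constructed locus table
  toy <- tibble::tibble(
    genome = "g", motif = c(rep("A", 4), rep("AT", 4), rep("AAT", 2)),
    unit_len = c(rep(1L, 4), rep(2L, 4), rep(3L, 2)),
    copies = 10L, start = seq(0, 900, 100)[1:10], end = seq(0, 900, 100)[1:10] + 10L,
    total_len = 10L, length_bin = "10-20"
  )
  cat_tab <- summarize_ssrs(toy)$by_category
  expect_equal(cat_tab$pct[match(c("mono", "di", "tri"), cat_tab$category)],
               c(40, 40, 20))
  empty <- summarize_ssrs(toy[0, ])
  expect_equal(nrow(empty$by_category), 0)
})
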