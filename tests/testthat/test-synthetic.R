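test_that("generated genomes have the requested region arithmetic", {
  g <- generate_plastome(lsc_len = 8000, ssc_len = 2000, ir_len = 3000,
                         seed = 55)
  expect_equal(g$record$length, 16000)
  part <- detect_inverted_repeats(g$record)
  expect_equal(part$ir_len, 3000)
  expect_equal(part$lsc_len, 8000)
  expect_equal(part$ssc_len, 2000)
})

test_that("the same seed reproduces genome and manifest byte-identically", {
  g1 <- generate_plastome(seed = 99)
  g2 <- generate_plastome(seed = 99)
  expect_identical(g1$record$sequence, g2$record$sequence)
  expect_identical(g1$truth$genes, g2$truth$genes)
  expect_identical(g1$truth$ssrs, g2$truth$ssrs)
  m1 <- mutate_plastome(g1$record, g1$truth, 0.005, seed = 100)
  m2 <- mutate_plastome(g2$record, g2$truth, 0.005, seed = 100)
  expect_identical(m1$record$sequence, m2$record$sequence)
})

test_that("a requested SSR is planted and recovered exactly", {
  plan <- tibble::tibble(motif = "AT", copies = 8L,
                         context = "intergenic", region = "LSC")
  g <- generate_plastome(ssr_plan = plan, seed = 7)
  hits <- find_ssrs(g$record)
  planted <- g$truth$ssrs
  hit <- hits[hits$start == planted$start, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$motif, "AT")
  expect_equal(hit$copies, 8L)
  expect_equal(hit$end, planted$end)
})

test_that("impossible placement requests raise a generation error", {
  expect_error(generate_plastome(lsc_len = 1500, ssc_len = 400, ir_len = 2600,
                                 seed = 1),
               "cannot place")
})

test_that("zero substitution rate is the identity", {
  g <- synth_fixture()
  m <- mutate_plastome(g$record, g$truth, sub_rate = 0, seed = 5)
  expect_identical(m$record$sequence, g$record$sequence)
  expect_equal(nrow(m$truth$mutations), 0)
})

test_that("substitution counts follow the binomial model over 20 seeds", {
  g <- synth_fixture()
  n_eff <- g$record$length - g$truth$regions$ira[2]  # IRA mirrors IRB draws
  rate <- 0.01
  counts <- vapply(1:20, function(i) {
    m <- mutate_plastome(g$record, g$truth, sub_rate = rate, seed = 7000 + 31 * i)
    sum(!m$truth$mutations$mirrored)
  }, numeric(1))
  expected <- n_eff * rate
  se <- sqrt(n_eff * rate * (1 - rate) / 20)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("the transition fraction matches ts/(ts+tv) within sampling error", {
  g <- synth_fixture()
  ts <- tot <- 0
  for (i in 1:10) {
    m <- mutate_plastome(g$record, g$truth, sub_rate = 0.01, ts_tv_ratio = 2,
                         seed = 7500 + 37 * i)
    mu <- m$truth$mutations[!m$truth$mutations$mirrored, ]
    ts <- ts + sum(mu$transition); tot <- tot + nrow(mu)
  }
  p <- ts / tot
  se <- sqrt(2 / 3 * 1 / 3 / tot)
  expect_lt(abs(p - 2 / 3), 3 * se)
})

test_that("manifest substitutions exactly describe the derived sequence", {
  g <- synth_fixture()
  m <- mutate_plastome(g$record, g$truth, sub_rate = 0.005, seed = 77)
  a <- strsplit(g$record$sequence, "")[[1]]
  b <- strsplit(m$record$sequence, "")[[1]]
  diff_pos <- which(a != b) - 1L
  expect_setequal(diff_pos, m$truth$mutations$pos)
  mu <- m$truth$mutations
  expect_identical(a[mu$pos + 1L], mu$from)
  expect_identical(b[mu$pos + 1L], mu$to)
})

test_that("IR copies stay exact reverse complements after mutation", {
  g <- synth_fixture()
  m <- mutate_plastome(g$record, g$truth, sub_rate = 0.01, indel_rate = 2e-4,
                       seed = 78)
  part <- detect_inverted_repeats(m$record)
  expect_equal(part$ir_len, g$truth$regions$ira[2])
})

test_that("indels stay out of genes and SSRs and coordinates are remapped", {
  g <- synth_fixture()
  m <- mutate_plastome(g$record, g$truth, sub_rate = 0, indel_rate = 1e-3,
                       seed = 79)
  expect_gt(nrow(m$truth$indels), 0)
  delta <- sum(ifelse(m$truth$indels$type == "ins", m$truth$indels$len,
                      -m$truth$indels$len))
  expect_equal(m$record$length, g$record$length + delta)
  # remapped CDS still splice to in-frame ATG...TAA sequences
  cds <- extract_loci(m$record, "cds")
  expect_true(all(cds$length %% 3 == 0))
  expect_true(all(substr(cds$sequence, 1, 3) == "ATG"))
  # remapped SSR coordinates still hold the planted tandems
  for (i in seq_len(nrow(m$truth$ssrs))) {
    s <- m$truth$ssrs[i, ]
    obs <- substr(m$record$sequence, s$start + 1, s$end)
    expect_identical(obs, strrep(s$motif, s$copies))
  }
})

test_that("fixture emission round-trips through the GenBank reader", {
  st <- study_fixture()
  dir <- file.path(tempdir(), "fixture-test")
  paths <- emit_fixture(st$records[1:2], st$truths[1:2], dir)
  expect_true(all(file.exists(paths$genbank)))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_genbank(paths$genbank[1])
  expect_identical(back$sequence, st$records[[1]]$sequence)
  expect_equal(nrow(features(back)), nrow(features(st$records[[1]])))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_named(man, vapply(st$records[1:2], function(r) r$id, character(1)))
})
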