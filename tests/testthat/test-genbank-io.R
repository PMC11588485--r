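test_that("GenBank locations convert to 0-based half-open coordinates", {
  rec <- read_genbank(write_toy_genbank())
  expect_equal(rec$length, 120)
  expect_true(rec$circular)
  ft <- features(rec)
  genA <- ft[ft$name == "genA", ]
  expect_equal(unname(genA$parts[[1]][, "start"]), c(9, 29))
  expect_equal(unname(genA$parts[[1]][, "end"]), c(18, 38))
  expect_equal(genA$strand, "+")
  genB <- ft[ft$name == "genB", ]
  expect_equal(genB$strand, "-")
  expect_equal(unname(genB$parts[[1]][1, ]), c(49, 70))
  expect_equal(ft$kind[ft$name == "ycf15"], "pseudogene")
})

test_that("malformed GenBank input is rejected with a parse error", {
  lines <- toy_genbank_text()
  trunc <- lines[seq_len(which(lines == "ORIGIN") + 1)]  # no terminator
  tf <- tempfile(fileext = ".gb")
  writeLines(trunc, tf)
  expect_error(read_genbank(tf), "truncated")
  writeLines(lines[!grepl("^ORIGIN|^//|^ ", lines)], tf)
  expect_error(read_genbank(tf), "ORIGIN")
})

test_that("coordinates and sequence round-trip through GenBank output", {
  g <- synth_fixture()
  tf <- tempfile(fileext = ".gb")
  write_genbank(g$record, tf)
  rec2 <- read_genbank(tf)
  expect_identical(rec2$sequence, g$record$sequence)
  expect_identical(rec2$length, g$record$length)
  ft1 <- features(g$record); ft2 <- features(rec2)
  expect_equal(nrow(ft1), nrow(ft2))
  o1 <- order(ft1$name, vapply(ft1$parts, function(p) p[1, 1], numeric(1)))
  o2 <- order(ft2$name, vapply(ft2$parts, function(p) p[1, 1], numeric(1)))
  expect_identical(ft1$name[o1], ft2$name[o2])
  expect_identical(ft1$strand[o1], ft2$strand[o2])
  expect_identical(lapply(ft1$parts[o1], unname), lapply(ft2$parts[o2], unname))
})

test_that("ambiguity codes other than N are rejected unless coerced", {
  expect_error(plastome_record("x", "ACGTRY"), "ambiguity")
  rec <- plastome_record("x", "ACGTRY", coerce_ambiguous = TRUE)
  expect_identical(rec$sequence, "ACGTNN")
})

test_that("extract_loci returns spliced CDS, introns and filtered spacers", {
  # toy: two adjacent genes 200 bp apart
  ft <- rbind(
    feature_row("geneA", "CDS", "+", list(c(10, 110))),
    feature_row("geneB", "CDS", "+", list(c(310, 400)))
  )
  rec <- plastome_record("toy", random_dna(500), ft, circular = FALSE)
  ig <- extract_loci(rec, "intergenic", min_len = 150)
  hit <- ig[ig$name == "geneA_geneB", ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$length, 200)
  expect_equal(c(hit$start, hit$end), c(110, 310))
  expect_equal(nrow(extract_loci(rec, "intergenic", min_len = 250)[
    extract_loci(rec, "intergenic", min_len = 250)$name == "geneA_geneB", ]), 0)
  expect_error(extract_loci(rec, "exon"), "must be one of")
})

test_that("CDS are strand-oriented and in frame on the synthetic genome", {
  g <- synth_fixture()
  cds <- extract_loci(g$record, "cds")
  expect_true(all(cds$length %% 3 == 0))
  expect_true(all(substr(cds$sequence, 1, 3) == "ATG"))
  expect_true(all(substr(cds$sequence, cds$length - 2, cds$length) == "TAA"))
  introns <- extract_loci(g$record, "intron")
  expect_setequal(introns$name, c("trnK-UUU_intron1", "rpoC1_intron1"))
})

test_that("intergenic extraction matches an interval-complement oracle", {
  g <- synth_fixture()
  rec <- g$record
  n <- rec$length
  ivs <- g$truth$genes[, c("start", "end")]
  ivs <- ivs[order(ivs$start), ]
  merged <- list(); cur <- c(ivs$start[1], ivs$end[1])
  for (i in seq_len(nrow(ivs))[-1]) {
    if (ivs$start[i] <= cur[2]) cur[2] <- max(cur[2], ivs$end[i])
    else { merged[[length(merged) + 1]] <- cur; cur <- c(ivs$start[i], ivs$end[i]) }
  }
  merged[[length(merged) + 1]] <- cur
  m <- do.call(rbind, merged)
  gaps <- cbind(m[, 2], c(m[-1, 1], m[1, 1] + n))     # circular complement
  exp_len <- gaps[, 2] - gaps[, 1]
  keep <- exp_len >= 150
  got <- extract_loci(rec, "intergenic", min_len = 150)
  expect_equal(sort(got$start), sort(gaps[keep, 1] %% n))
  expect_equal(sort(got$length), sort(as.integer(exp_len[keep])))
})

test_that("nested genes create no spurious intergenic loci", {
  g <- synth_fixture()
  ig <- extract_loci(g$record, "intergenic")
  ft <- features(g$record)
  trnK <- ft[ft$name == "trnK-UUU", ]$parts[[1]]
  # no spacer inside the trnK extent (where matK sits in the intron)
  inside <- ig$start >= trnK[1, 1] & ig$end <= trnK[2, 2]
  expect_equal(sum(inside), 0)
})

test_that("FASTA writing round-trips and rejects duplicate names", {
  set.seed(5)
  items <- tibble::tibble(
    name = paste0("s", 1:300),
    sequence = vapply(sample(1:200, 300, TRUE), random_dna, character(1))
  )
  tf <- tempfile(fileext = ".fasta")
  write_fasta(items, tf)
  back <- read_fasta(tf)
  expect_identical(back$name, items$name)
  expect_identical(back$sequence, items$sequence)
  expect_error(write_fasta(tibble::tibble(name = c("a", "a"), sequence = c("A", "C")),
                           tf), "duplicate")
  expect_warning(write_fasta(items[0, ], tf), "empty")
  expect_equal(file.size(tf), 0)
})

test_that("single-sequence FASTA has the canonical layout", {
  tf <- tempfile(fileext = ".fasta")
  write_fasta(tibble::tibble(name = "x", sequence = "ACGT"), tf)
  expect_identical(readLines(tf), c(">x", "ACGT"))
})
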