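# Shared fixtures, generated once per test run.

.fixture_cache <- new.env(parent = emptyenv())

# Default mini plastome with manifest (deterministic).
synth_fixture <- function() {
  if (is.null(.fixture_cache$base)) {
    .fixture_cache$base <- generate_plastome(seed = 421)
  }
  .fixture_cache$base
}

# Four-genome mutated study set (substitutions only; already aligned
# column-for-column because the genomes are indel-free).
study_fixture <- function() {
  if (is.null(.fixture_cache$study)) {
    .fixture_cache$study <- generate_study_set(
      n_genomes = 4, sub_rate = 0.002, hotspot_locus = "rbcL",
      hotspot_multiplier = 5, seed = 9000
    )
  }
  .fixture_cache$study
}

# A small handcrafted GenBank record exercising join/complement/pseudo.
toy_genbank_text <- function() {
  c(
    "LOCUS       TOY1 120 bp    DNA     circular PLN 01-JAN-2024",
    "DEFINITION  toy record.",
    "FEATURES             Location/Qualifiers",
    "     source          1..120",
    "     CDS             join(10..18,30..38)",
    '                     /gene="genA"',
    "     CDS             complement(50..70)",
    '                     /gene="genB"',
    "     tRNA            80..100",
    '                     /gene="trnX"',
    "     CDS             105..110",
    '                     /gene="ycf15"',
    "                     /pseudo",
    "ORIGIN",
    paste0("        1 ", paste(substring(strrep("acgtacgtac", 6), seq(1, 51, 10),
                                         seq(10, 60, 10)), collapse = " ")),
    paste0("       61 ", paste(substring(strrep("ttggccaatt", 6), seq(1, 51, 10),
                                         seq(10, 60, 10)), collapse = " ")),
    "//"
  )
}

write_toy_genbank <- function(path = tempfile(fileext = ".gb")) {
  writeLines(toy_genbank_text(), path)
  path
}
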