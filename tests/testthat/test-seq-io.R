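test_that("FASTA round trip parses sequences and header metadata", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">seq1|Platyhelminthes|parasite", "ATGAAATTT",
               ">seq2|Chordata|free-living", "ATGAAAGG-"), f)
  aln <- read_marker_fasta(f)
  expect_equal(nrow(aln), 2L)
  expect_equal(alignment_length(aln), 9L)
  expect_true(aln$parasitic[[1]])
  expect_false(aln$parasitic[[2]])
  expect_equal(aln$lineage, c("Platyhelminthes", "Chordata"))

  out <- withr::local_tempfile(fileext = ".fasta")
  write_marker_fasta(aln, out)
  expect_equal(read_marker_fasta(out)$seq, aln$seq)
})

test_that("metadata sidecar overrides header fields", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a|X|parasite", "AAA", ">b|Y|parasite", "CCC"), f)
  m <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tlineage\tparasitic", "a\tZ\t0", "b\tY\tNA"), m)
  aln <- read_marker_fasta(f, metadata = m)
  expect_equal(aln$lineage, c("Z", "Y"))
  expect_false(aln$parasitic[[1]])
  expect_true(is.na(aln$parasitic[[2]]))
})

test_that("malformed alignments are rejected", {
  expect_error(marker_alignment(c("AAAAAAAAA", "AAAAAAAAAAAA")), "unequal")
  expect_error(marker_alignment(c("AAA", "AAA"), id = c("x", "x")), "unique")
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), f)
  expect_error(read_marker_fasta(f))
})

test_that("quality filter applies the strict ambiguity threshold", {
  bad <- paste0(strrep("A", 651), strrep("N", 7))   # 7/658 >= 1%
  good <- paste0(strrep("A", 652), strrep("N", 6))  # 6/658 < 1%
  aln <- marker_alignment(c(bad, good), id = c("bad", "good"))
  kept <- filter_quality(aln, 0.01)
  expect_equal(kept$id, "good")
  clean <- marker_alignment(c(strrep("A", 12), strrep("C", 12)))
  expect_equal(nrow(filter_quality(clean, 0.01)), 2L)
  expect_equal(nrow(filter_quality(clean, 0.01, required_length = 12L)), 2L)
  suppressWarnings(
    expect_equal(nrow(filter_quality(clean, 0.01, required_length = 10L)), 0L))
})

test_that("lowering the ambiguity threshold never adds records", {
  set.seed(42)
  seqs <- replicate(20, paste(sample(c(NT4, "N"), 60, replace = TRUE,
                                     prob = c(rep(0.24, 4), 0.04)),
                              collapse = ""))
  aln <- marker_alignment(seqs)
  thresholds <- c(0.10, 0.05, 0.02, 0.01, 0)
  kept <- purrr::map(thresholds,
                     ~ suppressWarnings(filter_quality(aln, .x)$id))
  for (i in seq_len(length(kept) - 1)) {
    expect_true(all(kept[[i + 1]] %in% kept[[i]]))
  }
})

test_that("haplotype collapsing keeps first-seen representatives", {
  aln <- marker_alignment(c("AAA", "AAA", "AAA", "CCC"),
                          id = c("a", "b", "c", "d"))
  coll <- collapse_haplotypes(aln)
  expect_equal(nrow(coll$alignment), 2L)
  expect_equal(coll$alignment$id, c("a", "d"))
  expect_setequal(coll$haplotype_map$id, aln$id)
  expect_equal(coll$haplotype_map$representative,
               c("a", "a", "a", "d"))

  distinct_aln <- marker_alignment(c("AAA", "CCC", "GGG"))
  expect_equal(nrow(collapse_haplotypes(distinct_aln)$alignment), 3L)

  again <- collapse_haplotypes(coll$alignment)
  expect_equal(again$alignment$seq, coll$alignment$seq)
})

test_that("collapsing preserves the multiset of distinct sequences", {
  set.seed(7)
  seqs <- sample(c("ATG", "CCG", "TTA"), 15, replace = TRUE)
  aln <- marker_alignment(seqs)
  coll <- collapse_haplotypes(aln)
  expect_setequal(coll$alignment$seq, unique(seqs))
  expect_lte(nrow(coll$alignment), nrow(aln))
})

test_that("translation follows the selected genetic code", {
  aln <- marker_alignment("ATA")
  expect_equal(translate_alignment(aln, genetic_code(5), 0)$aa, "M")
  expect_equal(translate_alignment(aln, genetic_code(1), 0)$aa, "I")
  # AGA: R in the standard code, S in the invertebrate mitochondrial code
  aga <- marker_alignment("AGA")
  expect_equal(translate_alignment(aga, genetic_code(1), 0)$aa, "R")
  expect_equal(translate_alignment(aga, genetic_code(5), 0)$aa, "S")
})

test_that("a 658-nt in-frame barcode translates to 219 residues", {
  aln <- marker_alignment(barcode_658())
  raln <- translate_alignment(aln, genetic_code(5), 0)
  expect_equal(alignment_length(raln), 219L)
  expect_equal(nchar(raln$aa), 219L)
})

test_that("gapped codons translate to gap or X and frames auto-detect", {
  aln <- marker_alignment(c("A-AATG---"))
  raln <- translate_alignment(aln, genetic_code(5), 0)
  expect_equal(raln$aa, "XM-")
  # frame 0 hits an internal stop; frames 1 and 2 tie, lowest offset wins
  shifted <- marker_alignment("TAAATGCTT")
  auto <- translate_alignment(shifted, genetic_code(5), "auto")
  expect_equal(attr(auto, "frame_offset"), 1L)
  expect_equal(auto$aa, "KC")
})

test_that("nucleotide composition is a per-position probability table", {
  aln <- marker_alignment("ATGATG")
  comp <- nucleotide_composition(aln, 0L)
  p1 <- comp[comp$codon_position == "1", ]
  expect_equal(p1$freq[p1$base == "A"], 1)
  p2 <- comp[comp$codon_position == "2", ]
  expect_equal(p2$freq[p2$base == "T"], 1)
  p3 <- comp[comp$codon_position == "3", ]
  expect_equal(p3$freq[p3$base == "G"], 1)
  expect_equal(at_content(marker_alignment("AATT")), 1)

  set.seed(11)
  rnd <- marker_alignment(replicate(5, paste(sample(NT4, 30, TRUE),
                                             collapse = "")))
  rcomp <- nucleotide_composition(rnd, 0L)
  sums <- tapply(rcomp$freq, rcomp$codon_position, sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_error(nucleotide_composition(marker_alignment("AAA")[0, ]), "Empty")
})

test_that("amino acid composition partitions into biochemical groups", {
  all_l <- fake_raln(c("LLL", "LLL"))
  comp <- aa_composition(all_l)
  expect_equal(comp$freq[comp$residue == "L"], 1)
  expect_equal(group_composition(all_l)$freq[
    group_composition(all_l)$group == "nonpolar_aliphatic"], 1)

  half <- fake_raln(c("LS", "LS"))
  gc <- group_composition(half)
  expect_equal(gc$freq[gc$group == "nonpolar_aliphatic"], 0.5)
  expect_equal(gc$freq[gc$group == "polar_uncharged"], 0.5)
  expect_equal(sum(aa_composition(half)$freq), 1, tolerance = 1e-9)
})
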