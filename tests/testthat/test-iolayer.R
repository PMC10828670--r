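test_that("FASTA reading handles wrapping, case, ids and stop characters", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ACDE"), f)
  s <- read_fasta(f)
  expect_equal(s$id, "s1")
  expect_equal(s$residues, "ACDE")

  writeLines(c(">a desc", "ac", "de", ">b", "WWWW"), f)
  s <- read_fasta(f)
  expect_equal(s$id, c("a", "b"))
  expect_equal(s$residues[1], "ACDE")

  writeLines(c(">stop", "ACDE*"), f)
  expect_equal(read_fasta(f)$residues, "ACDE")

  writeLines(c(">meta species=Gecarcinus_lateralis taxon=Brachyura fragment=1",
               "ACDE"), f)
  s <- read_fasta(f)
  expect_equal(s$species, "Gecarcinus_lateralis")
  expect_equal(s$taxon_group, "Brachyura")
  expect_true(s$is_fragment)
})

test_that("FASTA reading rejects bad input with informative errors", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">x", "ACJDE"), f)
  err <- tryCatch(read_fasta(f), error = identity)
  expect_s3_class(err, "cfrc_format_error")
  expect_match(conditionMessage(err), "position 3")
  expect_match(conditionMessage(err), "'x'")

  writeLines(character(), f)
  expect_error(read_fasta(f), class = "cfrc_format_error")
})

test_that("FASTA write/read round trip preserves ids, residues and metadata", {
  seqs <- protein_sequences(
    id = c("r1", "r2", "r3"),
    residues = c("ACDEFGHIKLMNPQRSTVWYX", "WWWW", "MKTAYIAKQR"),
    species = c("sp1", NA, "sp2"),
    taxon_group = c("Brachyura", NA, "Caridea"),
    is_fragment = c(FALSE, FALSE, TRUE))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, f)
  back <- read_fasta(f)
  expect_equal(back$id, seqs$id)
  expect_equal(back$residues, seqs$residues)
  expect_equal(back$species, seqs$species)
  expect_equal(back$taxon_group, seqs$taxon_group)
  expect_equal(back$is_fragment, seqs$is_fragment)
})

test_that("hit tables parse e-values, dimensions and tri-state metadata", {
  f <- withr::local_tempfile(fileext = ".tsv")
  base <- c("q1", "s1", "98.5", "200", "3", "0", "1", "200", "5", "204")
  writeLines(c(
    paste(c(base, "1e-30", "500"), collapse = "\t"),
    paste(c("q1", "s2", "90", "180", "9", "1", "1", "180", "1", "180",
            "0.0", "300", "spA", "Brachyura", "1", "7"), collapse = "\t"),
    paste(c("q1", "s3", "80", "150", "20", "2", "1", "150", "1", "150",
            "2e-3", "100", "spB", "Caridea", "NA", "NA"), collapse = "\t")
  ), f)
  h <- read_hit_table(f)
  expect_equal(nrow(h), 3)
  expect_equal(h$evalue, c(1e-30, 0, 2e-3))
  expect_equal(h$aln_length, c(200L, 180L, 150L))
  expect_equal(h$has_7tm1, c(NA, TRUE, NA))
  expect_equal(h$n_tm_predicted, c(NA_integer_, 7L, NA_integer_))
  expect_equal(h$species, c(NA, "spA", "spB"))
  expect_equal(h$sequence_ref, c("s1", "s2", "s3"))

  writeLines(paste(base[1:10], collapse = "\t"), f)  # 10 columns only
  expect_error(read_hit_table(f), class = "cfrc_format_error")

  writeLines(paste(c(base, "not-a-number", "500"), collapse = "\t"), f)
  err <- tryCatch(read_hit_table(f), error = identity)
  expect_s3_class(err, "cfrc_format_error")
  expect_match(conditionMessage(err), "row 1")
})

test_that("topology labels parse, uppercase, and join-time checks fire", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(">p1", "ooomMMMiii"), f)
  labs <- read_topology_labels(f)
  expect_equal(unname(labs["p1"]), "OOOMMMMIII")

  writeLines(c(">p1", "OOOXMMM"), f)
  expect_error(read_topology_labels(f), class = "cfrc_format_error")

  # length mismatch is detected when joining with the sequence
  expect_error(assign_regions(strrep("A", 20), labels = "OOMMII"),
               class = "cfrc_consistency_error")
  # parsed fine, but region assignment flags the broken architecture
  expect_error(assign_regions("AAAAAA", labels = "OMIOMI"),
               class = "cfrc_not7tm")
})

test_that("the packaged motif library parses with anchors where required", {
  lib <- read_motif_library()
  expect_length(lib, 22)
  subs <- unique(vapply(lib, `[[`, character(1), "subclade"))
  expect_setequal(subs, decapod_subclades())
  for (entry in lib) {
    if (entry$region == "ECL2") {
      expect_false(is.na(entry$pattern$anchor))
      expect_identical(entry$pattern$sites[[entry$pattern$anchor]]$allowed, "C")
    } else {
      expect_true(is.na(entry$pattern$anchor))
    }
  }
  p <- lib[["A24β1|ECL2"]]$pattern
  expect_equal(p$anchor, 18L)
  p3 <- lib[["A34β3|ECL3"]]$pattern
  expect_setequal(p3$sites[[2]]$allowed, c("E", "D"))
})

test_that("motif library validation rejects broken entries", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("motifs:",
               "  - clade: A2", "    subclade: bad", "    region: ECL2",
               "    pattern: \"AB(CxxK\""), f)
  expect_error(read_motif_library(f), class = "cfrc_parse_error")
  writeLines(c("motifs:",
               "  - clade: A2", "    subclade: bad", "    region: ECL2",
               "    pattern: \"ACxxK\""), f)  # no anchor on an ECL2 entry
  expect_error(read_motif_library(f), class = "cfrc_validation_error")
})
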