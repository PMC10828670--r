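test_that("the e-value screen is strict and order-preserving", {
  h <- candidate_hits(query_id = "q", subject_id = c("a", "b", "c"),
                      evalue = c(1e-5, 1e-10, 1e-30))
  kept <- filter_evalue(h, 1e-10)
  expect_equal(kept$subject_id, "c")  # the threshold value itself is removed
  expect_equal(nrow(filter_evalue(candidate_hits(), 1e-10)), 0)
  h0 <- candidate_hits(query_id = "q", subject_id = c("a", "b"),
                       evalue = c(0, 0))
  expect_equal(nrow(filter_evalue(h0, 1e-10)), 2)  # 0 < threshold
  # idempotent, subset of input
  expect_equal(filter_evalue(kept, 1e-10), kept)
})

test_that("the domain filter keeps 7tm_1 hits and exempt fragments only", {
  h <- candidate_hits(query_id = "q",
                      subject_id = c("ok", "bfrag", "car", "unk"),
                      taxon_group = c("Caridea", "Brachyura", "Caridea",
                                      "Astacidea"),
                      evalue = 1e-20,
                      has_7tm1 = c(TRUE, FALSE, FALSE, NA))
  frags <- c(ok = FALSE, bfrag = TRUE, car = FALSE, unk = FALSE)
  res <- filter_domain(h, exempt_taxa = "Brachyura", fragments = frags)
  expect_setequal(res$kept$sequence_ref, c("ok", "bfrag"))
  expect_true(res$kept$exempted[res$kept$sequence_ref == "bfrag"])
  expect_false(res$kept$exempted[res$kept$sequence_ref == "ok"])
  expect_equal(res$removed$reason[res$removed$id == "unk"], "unannotated")
  expect_equal(res$removed$reason[res$removed$id == "car"], "no 7tm_1 domain")
})

test_that("the TM-count filter applies the fewer-than-six rule with exemptions", {
  h <- candidate_hits(query_id = "q",
                      subject_id = c("tm7", "tm5", "tm6", "bfrag", "notopo"),
                      taxon_group = c("Caridea", "Caridea", "Caridea",
                                      "Brachyura", "Caridea"),
                      evalue = 1e-20, has_7tm1 = TRUE,
                      n_tm_predicted = c(7L, 5L, 6L, 3L, NA))
  frags <- c(bfrag = TRUE)
  res <- filter_tm_count(h, min_tm = 6, exempt_taxa = "Brachyura",
                         fragments = frags)
  expect_setequal(res$kept$sequence_ref, c("tm7", "tm6", "bfrag"))
  expect_true(res$kept$exempted[res$kept$sequence_ref == "bfrag"])
  expect_equal(res$removed$reason[res$removed$id == "notopo"], "no topology")
  expect_match(res$removed$reason[res$removed$id == "tm5"], "5 transmembrane")

  # unknown annotation falls back to counting membrane runs in labels
  res2 <- filter_tm_count(h, min_tm = 6, fragments = frags,
                          topologies = c(notopo = strrep("OMIMOMIMOMIMOM", 5)))
  expect_true("notopo" %in% res2$kept$sequence_ref)
})

test_that("pairwise identity matches brute-force optimal alignments", {
  expect_equal(pairwise_identity("ACDEFG", "ACDEFG"), 1)
  expect_equal(pairwise_identity("AAAA", "AAAT"), 0.75)
  expect_equal(pairwise_identity("AAAA", "WWWW"), 0)
  expect_equal(pairwise_identity("ACDE", "ACDE"),
               pairwise_identity("ACDE", "ACDE"))
  set.seed(77)
  for (k in 1:15) {
    a <- random_region(sample(2:5, 1))
    b <- random_region(sample(2:5, 1))
    p <- pairwise_identity(a, b)
    expect_true(any(abs(oracle_identity_set(a, b) - p) < 1e-9),
                info = paste(a, b, p))
    expect_equal(p, pairwise_identity(b, a))  # symmetric
  }
})

test_that("same-species redundancy removal keeps one representative per cluster", {
  # identical same-species sequences: keep-longest with lexicographic ties
  s <- protein_sequences(c("b", "a"), c("ACDEACDE", "ACDEACDE"),
                         species = "sp1")
  res <- dedupe_same_species(s, 0.95)
  expect_equal(res$retained, "a")
  expect_equal(res$removed$id, "b")
  expect_match(res$removed$reason, "redundant with a")

  # identical sequences from different species both survive
  s <- protein_sequences(c("x", "y"), c("ACDEACDE", "ACDEACDE"),
                         species = c("sp1", "sp2"))
  expect_setequal(dedupe_same_species(s, 0.95)$retained, c("x", "y"))

  # a mutually similar chain collapses to a single representative
  base <- strrep("ACDEFGHIKLMNPQRSTVWY", 3)
  v1 <- base
  v2 <- paste0(substr(base, 1, 55), "AAAAA")   # ~92% to v1
  v3 <- paste0(substr(base, 1, 57), "AAA")
  s <- protein_sequences(c("s1", "s2", "s3"), c(v1, v2, v3), species = "sp")
  res <- dedupe_same_species(s, 0.9)
  expect_length(res$retained, 1)
  expect_equal(nrow(res$removed), 2)

  # dedupe never removes the last sequence of a species
  set.seed(88)
  s <- protein_sequences(paste0("q", 1:6),
                         replicate(6, random_region(40)),
                         species = rep(c("spA", "spB", "spC"), each = 2))
  res <- dedupe_same_species(s, 0.5)
  expect_true(all(c("spA", "spB", "spC") %in%
                  s$species[s$id %in% res$retained]))
})

test_that("the full curation chain partitions input ids and matches planted truth", {
  b <- generate_benchmark(synthetic_spec(seed = 3, n_per_subclade = 2))
  rep <- curate(b$hits, b$seqs, b$topologies)
  # partition: every id exactly once
  ids <- c(rep$retained, rep$removed$id)
  expect_setequal(ids, b$hits$sequence_ref)
  expect_equal(length(ids), length(unique(ids)))
  # planted truth reproduced
  tr <- b$truth
  expect_setequal(rep$retained, tr$id[tr$expected_retained])
  stage <- merge(rep$removed, tr, by = "id")
  expect_equal(stage$stage, stage$expected_stage)

  # empty hit list: complete, empty report
  rep0 <- curate(candidate_hits(), b$seqs, b$topologies)
  expect_length(rep0$retained, 0)
  expect_equal(nrow(rep0$removed), 0)

  # hits referencing missing sequences are a consistency error
  bad <- b$hits; bad$sequence_ref[1] <- "ghost"; bad$subject_id[1] <- "ghost"
  expect_error(curate(bad, b$seqs, b$topologies),
               class = "cfrc_consistency_error")

  # when every hit fails the e-value screen the report is still complete
  hh <- b$hits; hh$evalue <- 1
  repx <- curate(hh, b$seqs, b$topologies)
  expect_length(repx$retained, 0)
  expect_equal(sort(repx$removed$id), sort(b$hits$sequence_ref))
  expect_true(all(repx$removed$stage == "evalue"))
})
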