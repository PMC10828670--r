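test_that("the degenerate motif grammar parses by token arithmetic", {
  # bracket group = one site; '(C)' = anchored cysteine site
  p <- parse_motif("QYGIVYxxx[L-]PxGxDxPxxSx(C)xxKxxxx")
  expect_length(p$sites, 29)
  expect_identical(p$sites[[10]]$allowed, "L")
  expect_true(p$sites[[10]]$gap)
  expect_equal(p$anchor, 22L)
  expect_identical(p$sites[[22]]$allowed, "C")

  p <- parse_motif("x[ED]xxxxPxWFxx")
  expect_setequal(p$sites[[2]]$allowed, c("E", "D"))
  expect_false(p$sites[[2]]$gap)
  expect_null(p$sites[[1]]$allowed)

  p <- parse_motif("[x-]A")
  expect_null(p$sites[[1]]$allowed)
  expect_true(p$sites[[1]]$gap)

  expect_error(parse_motif("(A)xx"), class = "cfrc_parse_error")
  expect_error(parse_motif("A[CD"), class = "cfrc_parse_error")
  expect_error(parse_motif("A]C"), class = "cfrc_parse_error")
  expect_error(parse_motif("A[[CD]]"), class = "cfrc_parse_error")
  expect_error(parse_motif("A[]C"), class = "cfrc_parse_error")
  expect_error(parse_motif("xxx"), class = "cfrc_parse_error")  # no conserved site
  expect_error(parse_motif("(C)x(C)"), class = "cfrc_parse_error")
})

test_that("anchored matching finds planted realizations and honors anchors", {
  lib <- default_motif_library()
  p <- lib[["A24β1|ECL2"]]$pattern
  realization <- "YSTTVSIAYANAEIRRGCFLLWPDGATSASYAEY"
  m <- match_motif(p, realization)
  expect_equal(m$score, 1)
  expect_equal(m$start, 1L)
  expect_equal(m$anchored_position, 18L)
  o <- oracle_match(p, realization)
  expect_equal(o$score, 1)
  expect_equal(o$start, 1L)

  # anchor unsatisfiable: no cysteine in the region
  m <- match_motif(p, gsub("C", "A", realization))
  expect_equal(m$score, 0)
  expect_true(is.na(m$anchored_position))

  # unanchored pattern, exact placement
  m <- match_motif("AC", "XXAC")
  expect_equal(m$start, 3L)
  expect_equal(m$score, 1)

  # pattern longer than the region is a score-0 match, not an error
  m <- match_motif(p, "AC")
  expect_equal(m$score, 0)
})

test_that("matching equals the exhaustive oracle on random regions", {
  lib <- default_motif_library()
  set.seed(101)
  for (entry in lib) {
    for (k in 1:8) {
      reg <- random_region(sample(15:60, 1))
      a <- match_motif(entry$pattern, reg)
      b <- oracle_match(entry$pattern, reg)
      expect_equal(a$score, b$score, tolerance = 1e-12)
      expect_equal(as.integer(a$start), as.integer(b$start))
    }
  }
})

test_that("one extra mismatch at a matched conserved site never raises the score", {
  lib <- default_motif_library()
  set.seed(202)
  for (k in 1:60) {
    entry <- lib[[sample(length(lib), 1)]]
    reg <- random_region(sample(25:60, 1))
    m <- match_motif(entry$pattern, reg)
    if (is.na(m$start) || m$score == 0) next
    # corrupt one currently-matched conserved site in the region
    keep <- setdiff(seq_along(entry$pattern$sites), m$deletions)
    cons <- keep[vapply(entry$pattern$sites[keep],
                        function(s) !is.null(s$allowed), logical(1))]
    hitsites <- cons[m$site_matches]
    if (length(hitsites) == 0) next
    j <- hitsites[sample(length(hitsites), 1)]
    pos <- m$start + match(j, keep) - 1L
    allowed <- entry$pattern$sites[[j]]$allowed
    repl <- setdiff(c("G", "P", "K", "D"), allowed)[1]
    reg2 <- reg
    substr(reg2, pos, pos) <- repl
    expect_lte(match_motif(entry$pattern, reg2)$score, m$score + 1e-12)
  }
})

test_that("anchored clade diagnostics fire on realized subclade loops", {
  lib <- default_motif_library()
  e2_a24b1 <- as.character(realize_motif(lib[["A24β1|ECL2"]]$pattern))
  r <- make_receptor(ecl2 = e2_a24b1)
  f <- clade_features(r$regions, r$seq)
  expect_true(f$has_WPDG_at_plus4)
  expect_true(f$has_TT_upstream)
  expect_false(f$has_W_at_minus8)
  expect_equal(f$ecl2_cys_count, 1L)
  expect_equal(f$anchor_pos, 18L)

  e2_a34b1 <- as.character(realize_motif(lib[["A34β1|ECL2"]]$pattern))
  r <- make_receptor(ecl2 = e2_a34b1)
  f <- clade_features(r$regions, r$seq)
  expect_true(f$has_W_at_minus8)
  expect_true(f$has_R_at_minus15)
  expect_true(f$has_second_ecl2_cys)
  expect_false(f$has_WPDG_at_plus4)

  e2_a2a1 <- as.character(realize_motif(lib[["A2α1|ECL2"]]$pattern))
  r <- make_receptor(ecl2 = e2_a2a1)
  expect_true(clade_features(r$regions, r$seq)$has_PxGxDxP)

  r <- make_receptor(ecl2 = "AAAA")
  f <- clade_features(r$regions, r$seq)
  expect_equal(f$ecl2_cys_count, 0L)
  expect_false(any(unlist(f[c("has_PxGxDxP", "has_TT_upstream",
                              "has_WPDG_at_plus4", "has_W_at_minus8",
                              "has_R_at_minus15")])))

  # planted 12-residue ECL2 reports its exact length
  r <- make_receptor(ecl2 = strrep("S", 12))
  expect_equal(unname(region_lengths(r$regions)["ECL2"]), 12L)
})

test_that("noiseless planted receptors classify to their subclade with full score", {
  lib <- default_motif_library()
  for (s in c("A2β", "A24α", "A34β2")) {
    e2 <- as.character(realize_motif(lib[[paste0(s, "|ECL2")]]$pattern))
    e3 <- as.character(realize_motif(lib[[paste0(s, "|ECL3")]]$pattern))
    r <- make_receptor(ecl2 = e2, ecl3 = e3)
    call <- classify_subclade(r$regions, r$seq, lib)
    expect_equal(call$status, "classified")
    expect_equal(call$subclade, s)
    expect_equal(call$combined_score, 1)
    expect_equal(call$clade, cfrckit:::subclade_clade(s))
  }

  # no ECL2 cysteine: unclassifiable
  r <- make_receptor(ecl2 = strrep("S", 20))
  call <- classify_subclade(r$regions, r$seq, lib)
  expect_equal(call$status, "unclassified")
  expect_equal(call$subclade, "none")

  expect_error(classify_subclade(r$regions, r$seq,
                                 structure(list(), class = "cfrc_motif_library")),
               class = "cfrc_config_error")
})

test_that("a chimeric receptor scores by the stated ECL2/ECL3 weighting", {
  lib <- default_motif_library()
  # ECL2 from A34β1, ECL3 from A34β2
  e2 <- as.character(realize_motif(lib[["A34β1|ECL2"]]$pattern))
  e3 <- as.character(realize_motif(lib[["A34β2|ECL3"]]$pattern))
  r <- make_receptor(ecl2 = e2, ecl3 = e3)
  call <- classify_subclade(r$regions, r$seq, lib)
  # recompute the two combined scores by hand from the weights
  hand <- function(s) {
    0.7 * match_motif(lib[[paste0(s, "|ECL2")]]$pattern,
                      cfrckit:::padded_region(r$regions, r$seq, "ECL2", 5))$score +
    0.3 * match_motif(lib[[paste0(s, "|ECL3")]]$pattern,
                      cfrckit:::padded_region(r$regions, r$seq, "ECL3", 5))$score
  }
  expect_equal(unname(call$scores["A34β1"]), hand("A34β1"))
  expect_equal(unname(call$scores["A34β2"]), hand("A34β2"))
  expect_setequal(call$top2, c("A34β1", "A34β2"))
  # the call must follow the threshold/margin rule applied to those scores
  best2 <- sort(call$scores, decreasing = TRUE)[1:2]
  want <- if (best2[1] < 0.70) "unclassified"
          else if (best2[1] - best2[2] >= 0.05) "classified" else "ambiguous"
  expect_equal(call$status, want)
})

test_that("Class A signature motifs are located in their topological windows", {
  tm <- replicate(7, strrep("L", 21))
  substr(tm[3], 19, 21) <- "DRY"
  substr(tm[2], 8, 10) <- "TAP"
  substr(tm[6], 8, 11) <- "CWLP"
  substr(tm[6], 14, 14) <- "F"
  substr(tm[7], 15, 19) <- "NPAAY"
  r <- make_receptor(tm = tm, ecl1 = "SSAWAFSSSS")
  sig <- scan_classA_signatures(r$regions, r$seq)
  expect_true(sig$DRY$found);  expect_equal(sig$DRY$variant, "DRY")
  expect_true(sig$TxP$found);  expect_equal(sig$TxP$variant, "TAP")
  expect_true(sig$CWxP$found); expect_equal(sig$CWxP$variant, "CWLP")
  expect_true(sig$CWxP$f_downstream)
  expect_true(sig$NPxxY$found)
  expect_true(sig$ECL1_WxF$found)
  tm3 <- r$regions[r$regions$region == "TMM3", ]
  expect_true(sig$DRY$position >= tm3$end - 5 && sig$DRY$position <= tm3$end + 3)

  # the GRF variant is reported verbatim when E/DRY is absent
  substr(tm[3], 19, 21) <- "GRF"
  r <- make_receptor(tm = tm)
  sig <- scan_classA_signatures(r$regions, r$seq)
  expect_false(sig$DRY$found)
  expect_equal(sig$DRY$variant, "GRF")
})
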