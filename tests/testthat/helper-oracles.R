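# Independent brute-force oracles used across the suite. These deliberately
# share no matching/alignment code with the package internals.

# Naive exhaustive motif matching: loop over every deletion bitmask of
# gap-allowed sites, every start offset, and every site. Returns the best
# (score, start, n_deleted, anchored_position) under the tie rules
# max score -> smallest start -> fewest deletions.
oracle_match <- function(pattern, region) {
  if (is.character(pattern)) pattern <- parse_motif(pattern)
  r <- strsplit(toupper(region), "")[[1]]
  gaps <- which(vapply(pattern$sites, `[[`, logical(1), "gap"))
  best <- list(score = 0, start = NA_integer_, ndel = NA_integer_,
               anchored_position = NA_integer_)
  nmask <- 2^length(gaps)
  for (mask in 0:(nmask - 1)) {
    del <- gaps[bitwAnd(mask, 2^(seq_along(gaps) - 1)) > 0]
    keep <- setdiff(seq_along(pattern$sites), del)
    if (!is.na(pattern$anchor) && !(pattern$anchor %in% keep)) next
    m <- length(keep)
    if (m == 0 || m > length(r)) next
    for (off in 1:(length(r) - m + 1)) {
      nc <- 0L; hit <- 0L; apos <- NA_integer_; ok <- TRUE
      for (j in seq_len(m)) {
        site <- pattern$sites[[keep[j]]]
        ch <- r[off + j - 1]
        if (!is.na(pattern$anchor) && keep[j] == pattern$anchor) {
          apos <- off + j - 1L
          if (ch != "C") { ok <- FALSE; break }
        }
        if (!is.null(site$allowed)) {
          nc <- nc + 1L
          if (ch %in% site$allowed) hit <- hit + 1L
        }
      }
      if (!ok || nc == 0L) next
      sc <- hit / nc
      better <-
        if (is.na(best$start)) TRUE  # any valid candidate beats none
        else sc > best$score + 1e-12 ||
          (abs(sc - best$score) <= 1e-12 &&
           (off < best$start ||
            (off == best$start && length(del) < best$ndel)))
      if (better) best <- list(score = sc, start = off, ndel = length(del),
                               anchored_position = apos)
    }
  }
  best
}

# Brute-force identity oracle for tiny sequences: enumerate EVERY global
# alignment recursively, score with match=1/mismatch=0 and affine gaps
# (open 5, extend 1, i.e. a gap of length L costs 5 + L), and return the
# set of trimmed identities achieved by maximum-score alignments. With a
# zero mismatch penalty the optimum can be degenerate, so the package value
# must fall in this set. Only feasible for lengths up to ~6.
oracle_identity_set <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  results <- list()
  recurse <- function(i, j, pa, pb, score, last) {
    if (i > length(A) && j > length(B)) {
      results[[length(results) + 1]] <<- list(pa = pa, pb = pb, score = score)
      return(invisible())
    }
    if (i <= length(A) && j <= length(B))
      recurse(i + 1, j + 1, c(pa, A[i]), c(pb, B[j]),
              score + (A[i] == B[j]), "M")
    if (i <= length(A))
      recurse(i + 1, j, c(pa, A[i]), c(pb, "-"),
              score - (if (last == "X") 1 else 6), "X")
    if (j <= length(B))
      recurse(i, j + 1, c(pa, "-"), c(pb, B[j]),
              score - (if (last == "Y") 1 else 6), "Y")
  }
  recurse(1, 1, character(), character(), 0, "M")
  scores <- vapply(results, `[[`, numeric(1), "score")
  opt <- results[scores >= max(scores) - 1e-9]
  ids <- vapply(opt, function(al) {
    gap <- al$pa == "-" | al$pb == "-"
    nongap <- which(!gap)
    if (length(nongap) == 0) return(0)
    keep <- seq(min(nongap), max(nongap))
    sum(al$pa[keep] == al$pb[keep] & al$pa[keep] != "-") / length(keep)
  }, numeric(1))
  sort(unique(round(ids, 9)))
}

# Random protein region with cysteines present at roughly natural frequency.
random_region <- function(len) {
  paste(sample(c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y"), len, TRUE),
        collapse = "")
}
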