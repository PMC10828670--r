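## Degenerate motif grammar, anchored matching, clade-level positional
## diagnostics and subclade classification.
##
## Grammar: an uppercase residue letter is a conserved (singleton) site; 'x'
## is a wildcard; '[AB]' allows either residue; a '-' inside brackets marks
## the site as deletable (indel); '[x-]' is a deletable wildcard; '(C)' marks
## the anchor site, which must align to a cysteine in the target region.

#' Parse a degenerate motif pattern
#'
#' @param text Pattern string (see grammar above).
#' @return An object of class `cfrc_motif`: a list with `sites` (each site a
#'   list with `allowed`, a character vector or `NULL` for wildcards, and
#'   `gap`, whether the site may be deleted), `anchor` (site index of the
#'   anchor cysteine or `NA`) and `text`.
#' @export
#' @examples
#' p <- parse_motif("x[ED]xxxxPxWFxx")
#' p$sites[[2]]$allowed  # "E" "D"
parse_motif <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  chars <- strsplit(text, "")[[1]]
  sites <- list()
  anchor <- NA_integer_
  i <- 1
  fail <- function(tok, why)
    cfrc_error(sprintf("cannot parse motif '%s': %s at token '%s'", text, why, tok),
               "cfrc_parse_error")
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "x") {
      sites[[length(sites) + 1]] <- list(allowed = NULL, gap = FALSE)
      i <- i + 1
    } else if (ch %in% AA20) {
      sites[[length(sites) + 1]] <- list(allowed = ch, gap = FALSE)
      i <- i + 1
    } else if (ch == "(") {
      j <- which(chars == ")" & seq_along(chars) > i)[1]
      if (is.na(j)) fail("(", "unclosed anchor marker")
      inner <- paste(chars[(i + 1):(j - 1)], collapse = "")
      if (inner != "C") fail(paste0("(", inner, ")"), "anchor must be C")
      if (!is.na(anchor)) fail("(C)", "multiple anchors")
      sites[[length(sites) + 1]] <- list(allowed = "C", gap = FALSE)
      anchor <- length(sites)
      i <- j + 1
    } else if (ch == "[") {
      j <- which(chars == "]" & seq_along(chars) > i)[1]
      if (is.na(j)) fail("[", "unclosed bracket")
      inner <- chars[(i + 1):(j - 1)]
      if (any(inner == "[")) fail("[", "nested brackets")
      gap <- "-" %in% inner
      wild <- "x" %in% inner
      members <- inner[!inner %in% c("-", "x")]
      if (length(bad <- setdiff(members, AA20)))
        fail(bad[1], "not an amino-acid code")
      if (!wild && length(members) == 0) fail("[]", "empty residue set")
      sites[[length(sites) + 1]] <-
        list(allowed = if (wild) NULL else members, gap = gap)
      i <- j + 1
    } else if (ch == "]") {
      fail("]", "unbalanced bracket")
    } else {
      fail(ch, "unexpected character")
    }
  }
  if (length(sites) == 0) fail(text, "empty pattern")
  conserved <- vapply(sites, function(s) !is.null(s$allowed), logical(1))
  if (!any(conserved))
    cfrc_error(sprintf("motif '%s' has no conserved site", text), "cfrc_parse_error")
  structure(list(sites = sites, anchor = anchor, text = text),
            class = "cfrc_motif")
}

## All deletion on/off combinations over the gap-allowed sites of a pattern.
## Returns a list of integer vectors of deleted site indices (first = none).
gap_subsets <- function(pattern) {
  g <- which(vapply(pattern$sites, `[[`, logical(1), "gap"))
  if (length(g) == 0) return(list(integer()))
  subs <- list(integer())
  for (k in seq_along(g)) {
    ## combn over indices (safe for length-1 g, where combn(g, k) would
    ## misread the scalar as seq_len(g))
    idx <- utils::combn(length(g), k, simplify = FALSE)
    subs <- c(subs, lapply(idx, function(i) g[i]))
  }
  subs
}

#' Match a degenerate motif against a region sequence
#'
#' Exhaustively enumerates all start offsets and all deletion on/off
#' combinations over gap-allowed sites. A candidate placement is valid only
#' if the pattern fits inside the region and, when an anchor exists, the
#' anchor site aligns to a cysteine. The score of a placement is the
#' fraction of evaluated non-wildcard sites whose residue is allowed;
#' wildcards carry no reward. The best-scoring valid placement is returned
#' (ties broken by smallest start, then fewest deletions); when no valid
#' placement exists the match has score 0.
#'
#' @param pattern A `cfrc_motif` (or pattern string, parsed on the fly).
#' @param region_seq Region sequence (non-empty string).
#' @return A list of class `cfrc_match` with fields `start` (1-based offset
#'   in the region, `NA` if unmatched), `deletions` (site indices deleted),
#'   `site_matches` (logical per retained non-wildcard site), `score` and
#'   `anchored_position` (region index matched by the anchor, or `NA`).
#' @export
match_motif <- function(pattern, region_seq) {
  if (is.character(pattern)) pattern <- parse_motif(pattern)
  stopifnot(inherits(pattern, "cfrc_motif"), nzchar(region_seq))
  r <- strsplit(toupper(region_seq), "")[[1]]
  L <- length(r)
  no_match <- structure(
    list(start = NA_integer_, deletions = integer(),
         site_matches = logical(), score = 0, anchored_position = NA_integer_),
    class = "cfrc_match")

  best <- NULL
  for (del in gap_subsets(pattern)) {
    keep <- setdiff(seq_along(pattern$sites), del)
    m <- length(keep)
    if (m == 0 || m > L) next
    sites <- pattern$sites[keep]
    apos <- if (!is.na(pattern$anchor)) match(pattern$anchor, keep) else NA_integer_
    if (!is.na(pattern$anchor) && is.na(apos)) next  # anchor deleted: invalid
    offs <- seq_len(L - m + 1)
    if (!is.na(apos)) offs <- offs[r[offs + apos - 1L] == "C"]
    if (length(offs) == 0) next
    cons <- which(vapply(sites, function(s) !is.null(s$allowed), logical(1)))
    if (length(cons) == 0) next
    hits <- matrix(FALSE, nrow = length(offs), ncol = length(cons))
    for (k in seq_along(cons)) {
      j <- cons[k]
      hits[, k] <- r[offs + j - 1L] %in% sites[[j]]$allowed
    }
    scores <- rowSums(hits) / length(cons)
    ibest <- which.max(scores)  # first max = smallest start within this subset
    cand <- list(start = offs[ibest], deletions = sort(del),
                 site_matches = hits[ibest, ], score = scores[ibest],
                 anchored_position = if (is.na(apos)) NA_integer_
                                     else offs[ibest] + apos - 1L)
    if (is.null(best) ||
        cand$score > best$score + 1e-12 ||
        (abs(cand$score - best$score) <= 1e-12 &&
         (cand$start < best$start ||
          (cand$start == best$start &&
           length(cand$deletions) < length(best$deletions))))) {
      best <- cand
    }
  }
  if (is.null(best)) return(no_match)
  class(best) <- "cfrc_match"
  best
}

#' Clade-level positional diagnostics around the ECL2 anchor cysteine
#'
#' Evaluates the diagnostic features that separate the A2, A24 and A34
#' clades, expressed relative to the conserved ECL2 cysteine: the A2
#' `PxGxDxP` stretch upstream of the anchor; the A24 threonine pair upstream
#' of the anchor and the `WPDG...S` block starting four residues C-terminal
#' to it (with the serine eight residues after the tryptophan); the A34
#' tryptophan eight residues N-terminal and arginine fifteen residues
#' N-terminal to the anchor. When ECL2 contains several cysteines, every one
#' is evaluated as a candidate anchor and the best-supported anchor is kept.
#'
#' @param regions A `cfrc_regions` partition (see [assign_regions()]).
#' @param seq Full receptor sequence string.
#' @param loop_pad Residues by which the ECL2 window is widened into the
#'   flanking transmembrane intervals before evaluation (default 0: exact
#'   loop boundaries).
#' @return A list of class `cfrc_features`: `ecl2_cys_count`,
#'   `has_second_ecl2_cys`, `anchor_pos` (ECL2-local, `NA` if no cysteine),
#'   the boolean diagnostics `has_PxGxDxP`, `has_TT_upstream`,
#'   `has_WPDG_at_plus4`, `has_W_at_minus8`, `has_R_at_minus15`, and the
#'   region lengths `ecl2_len`, `ecl3_len`, `icl3_len`.
#' @export
clade_features <- function(regions, seq, loop_pad = 0L) {
  ecl2 <- padded_region(regions, seq, "ECL2", loop_pad)
  lens <- region_lengths(regions)
  base <- list(
    has_PxGxDxP = FALSE, has_TT_upstream = FALSE, has_WPDG_at_plus4 = FALSE,
    has_W_at_minus8 = FALSE, has_R_at_minus15 = FALSE,
    ecl2_cys_count = 0L, has_second_ecl2_cys = FALSE, anchor_pos = NA_integer_,
    ecl2_len = unname(lens["ECL2"]), ecl3_len = unname(lens["ECL3"]),
    icl3_len = unname(lens["ICL3"])
  )
  chars <- strsplit(ecl2, "")[[1]]
  cys <- which(chars == "C")
  base$ecl2_cys_count <- length(cys)
  base$has_second_ecl2_cys <- length(cys) >= 2
  if (length(cys) == 0) return(structure(base, class = "cfrc_features"))

  at <- function(pos) if (pos >= 1 && pos <= length(chars)) chars[pos] else ""
  eval_anchor <- function(a) {
    ## TT pair upstream: the reference-alignment offset (-19/-18) compresses
    ## to -15..-11 in ungapped loop sequences; searched over -20..-11.
    tt <- any(vapply((a - 20):(a - 12), function(p)
      at(p) == "T" && at(p + 1) == "T", logical(1)))
    wpdg <- a + 7 <= length(chars) &&
      paste(chars[(a + 4):(a + 7)], collapse = "") == "WPDG" &&
      at(a + 12) == "S"
    w8 <- any(vapply((a - 9):(a - 7), function(p) at(p) == "W", logical(1)))
    r15 <- any(vapply((a - 16):(a - 14), function(p) at(p) == "R", logical(1)))
    up <- if (a > 1) paste(chars[1:(a - 1)], collapse = "") else ""
    pgp <- grepl("P.G.D.P", up)
    list(has_PxGxDxP = pgp, has_TT_upstream = tt, has_WPDG_at_plus4 = wpdg,
         has_W_at_minus8 = w8, has_R_at_minus15 = r15)
  }
  evals <- lapply(cys, eval_anchor)
  support <- vapply(evals, function(e) sum(unlist(e)), numeric(1))
  k <- which.max(support)  # ties: first (smallest position)
  base[names(evals[[k]])] <- evals[[k]]
  base$anchor_pos <- cys[k]
  structure(base, class = "cfrc_features")
}

#' Classification thresholds for subclade calls
#'
#' @param call_threshold Minimum combined score for a confident call.
#' @param margin Minimum lead of the best subclade over the runner-up.
#' @param w_ecl2,w_ecl3 Weights of the ECL2 and ECL3 motif scores in the
#'   combined score; when a subclade has no ECL3 pattern (or the receptor's
#'   ECL3 is empty) the ECL3 weight is folded into ECL2.
#' @return A list of class `cfrc_thresholds`.
#' @export
classification_thresholds <- function(call_threshold = 0.70, margin = 0.05,
                                      w_ecl2 = 0.7, w_ecl3 = 0.3) {
  stopifnot(call_threshold > 0, call_threshold <= 1, margin >= 0,
            w_ecl2 > 0, w_ecl3 >= 0)
  structure(list(call_threshold = call_threshold, margin = margin,
                 w_ecl2 = w_ecl2, w_ecl3 = w_ecl3),
            class = "cfrc_thresholds")
}

#' Classify a receptor into a CFRC subclade
#'
#' Two-stage classification. Stage 1 votes for a clade from the anchored
#' ECL2 diagnostics: `PxGxDxP` upstream of the anchor for A2, the
#' `WPDG`-at-anchor+4 block for A24, the tryptophan at anchor-8 for A34.
#' A single unambiguous vote restricts stage 2 to that clade's subclades;
#' otherwise every subclade in the library is evaluated. Stage 2 scores each
#' candidate subclade by anchored motif matching:
#' `combined = w_ecl2 * ecl2_score + w_ecl3 * ecl3_score`, with the ECL3
#' weight folded into ECL2 when no ECL3 pattern or region is available. The
#' receptor is `classified` when the best combined score reaches the call
#' threshold with the required margin over the runner-up, `ambiguous` when
#' the threshold is met but not the margin (top two reported), and
#' `unclassified` otherwise.
#'
#' @param regions A `cfrc_regions` partition.
#' @param seq Full receptor sequence string.
#' @param library A `cfrc_motif_library`; defaults to the packaged decapod
#'   library.
#' @param thresholds A `cfrc_thresholds` object.
#' @param loop_pad Residues by which the ECL2/ECL3 windows are widened into
#'   their flanking transmembrane intervals before matching, absorbing
#'   loop-boundary jitter from topology prediction (default 5).
#' @return A list of class `cfrc_call`: `clade`, `subclade`, `ecl2_score`,
#'   `ecl3_score`, `combined_score`, `status`, `evidence` (the
#'   `cfrc_features`), `top2` (labels) and `scores` (named vector over all
#'   evaluated subclades).
#' @export
classify_subclade <- function(regions, seq, library = default_motif_library(),
                              thresholds = classification_thresholds(),
                              loop_pad = 5L) {
  if (length(library) == 0)
    cfrc_error("empty motif library", "cfrc_config_error")
  feats <- clade_features(regions, seq, loop_pad = loop_pad)
  ecl2 <- padded_region(regions, seq, "ECL2", loop_pad)
  ecl3 <- padded_region(regions, seq, "ECL3", loop_pad)

  unclassified <- function() structure(
    list(clade = "none", subclade = "none", ecl2_score = 0, ecl3_score = 0,
         combined_score = 0, status = "unclassified", evidence = feats,
         top2 = character(), scores = numeric()),
    class = "cfrc_call")
  if (feats$ecl2_cys_count == 0) return(unclassified())

  all_subs <- library_subclades(library)
  evaluate <- function(subs) {
    e2s <- e3s <- comb <- stats::setNames(numeric(length(subs)), subs)
    for (s in subs) {
      p2 <- library[[paste0(s, "|ECL2")]]
      p3 <- library[[paste0(s, "|ECL3")]]
      e2 <- if (!is.null(p2) && nzchar(ecl2)) match_motif(p2$pattern, ecl2)$score else 0
      if (!is.null(p3) && nzchar(ecl3)) {
        e3 <- match_motif(p3$pattern, ecl3)$score
        cb <- thresholds$w_ecl2 * e2 + thresholds$w_ecl3 * e3
      } else {
        e3 <- 0
        cb <- e2  # ECL3 weight folded into ECL2
      }
      e2s[s] <- e2; e3s[s] <- e3; comb[s] <- cb
    }
    ord <- order(-comb, subs)
    best <- subs[ord[1]]
    second <- if (length(subs) > 1) comb[ord[2]] else -Inf
    status <-
      if (comb[best] >= thresholds$call_threshold &&
          comb[best] - second >= thresholds$margin) "classified"
      else if (comb[best] >= thresholds$call_threshold) "ambiguous"
      else "unclassified"
    list(best = best, status = status, e2s = e2s, e3s = e3s, comb = comb,
         ord = ord, subs = subs)
  }

  votes <- c(A2 = feats$has_PxGxDxP, A24 = feats$has_WPDG_at_plus4,
             A34 = feats$has_W_at_minus8)
  subs <- all_subs
  if (sum(votes) == 1) {
    in_clade <- all_subs[subclade_clade(all_subs) == names(votes)[votes]]
    if (length(in_clade) > 0) subs <- in_clade
  }
  res <- evaluate(subs)
  ## a clade vote is a heuristic restriction; when it fails to produce a
  ## confident call, fall back to the full library
  if (res$status != "classified" && length(subs) < length(all_subs))
    res <- evaluate(all_subs)

  best <- res$best; status <- res$status
  structure(list(
    clade = if (status == "unclassified") "none" else subclade_clade(best),
    subclade = if (status == "unclassified") "none" else best,
    ecl2_score = unname(res$e2s[best]), ecl3_score = unname(res$e3s[best]),
    combined_score = unname(res$comb[best]), status = status, evidence = feats,
    top2 = res$subs[res$ord[seq_len(min(2, length(res$subs)))]],
    scores = res$comb), class = "cfrc_call")
}

## Region subsequence widened by `pad` residues into its neighbours
## (clamped to the sequence); absorbs loop-boundary jitter.
padded_region <- function(regions, seq, name, pad = 0L) {
  row <- regions[regions$region == name, ]
  if (nrow(row) != 1) cfrc_error(paste0("unknown region: ", name), "cfrc_format_error")
  s <- max(1L, row$start - pad)
  e <- min(nchar(seq), row$end + pad)
  if (e < s) return("")
  substr(seq, s, e)
}

## Search a regex inside a global coordinate window of the sequence.
## Returns list(found, position (global), variant) or not-found.
scan_window <- function(chars, from, to, regex) {
  from <- max(1, from); to <- min(length(chars), to)
  if (from > to) return(list(found = FALSE, position = NA_integer_, variant = NA_character_))
  s <- paste(chars[from:to], collapse = "")
  m <- regexpr(regex, s)
  if (m < 0) return(list(found = FALSE, position = NA_integer_, variant = NA_character_))
  list(found = TRUE, position = from + as.integer(m) - 1L,
       variant = substr(s, m, m + attr(m, "match.length") - 1L))
}

#' Scan the Class A (rhodopsin-like) signature motifs
#'
#' Reports the canonical Class A signatures at their expected topological
#' locations: `E/DRY` near the TMM3/ICL2 boundary (with the `xRx` variant,
#' e.g. `GRF`, reported verbatim when the consensus form is absent but the
#' central arginine is present), `TxP` in TMM2, `CWxP` in TMM6 together with
#' a phenylalanine within eight residues downstream inside TMM6, `NPxxY`
#' near the TMM7/C-terminus boundary, and the ECL1 `[YH]xWxF` / `xWxF`
#' motifs.
#'
#' @param regions A `cfrc_regions` partition.
#' @param seq Full receptor sequence string.
#' @return A list of class `cfrc_signatures` with one element per signature
#'   (`DRY`, `TxP`, `CWxP`, `NPxxY`, `ECL1_WxF`), each holding `found`,
#'   `position` (global, 1-based) and `variant`; `CWxP` additionally has
#'   `f_downstream`.
#' @export
scan_classA_signatures <- function(regions, seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  iv <- function(name) {
    row <- regions[regions$region == name, ]
    c(row$start, row$end)
  }
  tm2 <- iv("TMM2"); tm3 <- iv("TMM3"); tm6 <- iv("TMM6"); tm7 <- iv("TMM7")
  ecl1 <- iv("ECL1")

  dry <- scan_window(chars, tm3[2] - 5, tm3[2] + 3, "[ED]RY")
  if (!dry$found) {
    alt <- scan_window(chars, tm3[2] - 5, tm3[2] + 3, ".R.")
    if (alt$found) dry$variant <- alt$variant
  }
  txp <- scan_window(chars, tm2[1], tm2[2], "T.P")
  cwxp <- scan_window(chars, tm6[1], tm6[2], "CW.P")
  cwxp$f_downstream <- FALSE
  if (cwxp$found) {
    after <- cwxp$position + 4
    fwin <- scan_window(chars, after, min(after + 7, tm6[2]), "F")
    cwxp$f_downstream <- fwin$found
  }
  npxxy <- scan_window(chars, tm7[2] - 8, tm7[2] + 2, "NP..Y")
  e1 <- scan_window(chars, ecl1[1], ecl1[2], "[YH].W.F")
  if (!e1$found) e1 <- scan_window(chars, ecl1[1], ecl1[2], ".W.F")
  structure(list(DRY = dry, TxP = txp, CWxP = cwxp, NPxxY = npxxy,
                 ECL1_WxF = e1), class = "cfrc_signatures")
}
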