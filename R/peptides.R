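## CHH-superfamily peptide typing: six-cysteine framework, canonical
## disulfide connectivity, Type I/II classification by the conserved glycine
## five positions after the first cysteine, mature-peptide extraction from
## Type I precursors, and identity against family consensus patterns.

#' Locate the cysteine framework and canonical disulfide pairing
#'
#' CHH-superfamily mature peptides carry six conserved cysteines forming
#' three intramolecular disulfide bridges with the canonical connectivity
#' C1-C5, C2-C4, C3-C6 (a family convention, not a structure prediction).
#'
#' @param seq Peptide sequence string.
#' @return A list with `cys_positions` (1-based positions of all cysteines),
#'   `disulfide_pairs` (3x2 integer matrix when exactly six cysteines are
#'   present, otherwise a 0-row matrix) and `valid` (exactly six cysteines).
#' @export
#' @examples
#' ref <- chh_reference_set()
#' cys_framework(ref$peptides$residues[ref$peptides$id == "Gl-MIH"])
cys_framework <- function(seq) {
  stopifnot(nzchar(seq))
  chars <- strsplit(toupper(seq), "")[[1]]
  cys <- which(chars == "C")
  valid <- length(cys) == 6
  pairs <- if (valid) {
    m <- rbind(cys[c(1, 5)], cys[c(2, 4)], cys[c(3, 6)])
    colnames(m) <- c("from", "to")
    m
  } else {
    matrix(integer(), ncol = 2, dimnames = list(NULL, c("from", "to")))
  }
  list(cys_positions = cys, disulfide_pairs = pairs, valid = valid)
}

#' Classify a CHH-family peptide as Type I or Type II
#'
#' Type II peptides (MIH/GIH/MOIH) carry a conserved glycine inserted at the
#' fifth position after the first cysteine (Gly12 in the canonical
#' numbering, where the first cysteine is Cys7); Type I peptides (CHH/ITP)
#' lack it. The rule is applied relative to the first framework cysteine so
#' it transfers to peptides whose N-terminal trimming differs.
#'
#' @param seq Peptide sequence with a valid six-cysteine framework.
#' @return `"II"`, `"I"`, or `"invalid"` when the framework is not six
#'   cysteines.
#' @export
classify_type <- function(seq) {
  fw <- cys_framework(seq)
  if (!fw$valid) return("invalid")
  pos <- fw$cys_positions[1] + 5L
  if (pos > nchar(seq)) return("I")
  if (substr(toupper(seq), pos, pos) == "G") "II" else "I"
}

#' Extract the mature peptide span from a precursor
#'
#' Type I precursors are organized as signal peptide, precursor-related
#' peptide, a dibasic KR cleavage site, and the mature peptide. The mature
#' span starts right after the last `KR` whose downstream sequence contains
#' a valid six-cysteine framework. Inputs without any `KR` are treated as
#' already mature (the Type II convention), spanning the whole input.
#'
#' @param precursor_seq Precursor (or mature) sequence string.
#' @return A list with `start`, `end` (1-based span of the mature peptide in
#'   the precursor) and `mature` (the spanned sequence).
#' @export
extract_mature <- function(precursor_seq) {
  s <- toupper(precursor_seq)
  L <- nchar(s)
  kr <- gregexpr("KR", s)[[1]]
  if (kr[1] == -1) return(list(start = 1L, end = L, mature = s))
  for (p in rev(as.integer(kr))) {
    suffix <- substr(s, p + 2, L)
    if (nzchar(suffix) && cys_framework(suffix)$valid)
      return(list(start = p + 2L, end = L, mature = suffix))
  }
  cfrc_error("KR cleavage site(s) present but no downstream six-cysteine framework",
             "cfrc_extraction_error")
}

#' Identity of a peptide against a family consensus pattern
#'
#' The peptide is aligned to the consensus without gaps, anchored so that
#' its first cysteine coincides with the first conserved cysteine of the
#' consensus (shorter overhangs are ignored). The returned identity is the
#' fraction of overlapping consensus non-wildcard sites whose residue the
#' peptide matches.
#'
#' @param seq Peptide sequence (must contain a cysteine).
#' @param consensus Consensus pattern string in the motif grammar (e.g. from
#'   [chh_reference_set()]), or a parsed `cfrc_motif`.
#' @return Fraction in `[0, 1]`.
#' @export
consensus_identity <- function(seq, consensus) {
  s <- strsplit(toupper(seq), "")[[1]]
  c1_seq <- which(s == "C")[1]
  if (is.na(c1_seq))
    cfrc_error("sequence contains no cysteine to anchor on", "cfrc_format_error")
  pat <- if (inherits(consensus, "cfrc_motif")) consensus else parse_motif(consensus)
  cons_sites <- pat$sites
  c1_pat <- which(vapply(cons_sites, function(x) identical(x$allowed, "C"),
                         logical(1)))[1]
  if (is.na(c1_pat))
    cfrc_error("consensus contains no conserved cysteine site", "cfrc_format_error")
  offset <- c1_seq - c1_pat  # seq position = site index + offset
  matched <- 0L; evaluated <- 0L
  for (j in seq_along(cons_sites)) {
    allowed <- cons_sites[[j]]$allowed
    if (is.null(allowed)) next
    p <- j + offset
    if (p < 1 || p > length(s)) next
    evaluated <- evaluated + 1L
    if (s[p] %in% allowed) matched <- matched + 1L
  }
  if (evaluated == 0L) return(0)
  matched / evaluated
}

#' Full peptide report
#'
#' Runs mature-peptide extraction, the cysteine framework, Type I/II typing
#' and consensus identities against the packaged MIH and CHH consensus
#' patterns. C-terminal basic extensions (e.g. a trailing RKKK) are retained
#' for framework and typing, and flagged.
#'
#' @param seq Precursor or mature peptide sequence.
#' @param reference Reference set as returned by [chh_reference_set()].
#' @return A list of class `cfrc_peptide_report` with `mature_span`,
#'   `cys_positions`, `disulfide_pairs`, `type_call`, `gly_after_c1`,
#'   `c_terminal_basic` and `consensus_identity` (named vector).
#' @export
peptide_report <- function(seq, reference = chh_reference_set()) {
  mat <- extract_mature(seq)
  fw <- cys_framework(mat$mature)
  type <- classify_type(mat$mature)
  gly <- FALSE
  if (length(fw$cys_positions) >= 1) {
    p <- fw$cys_positions[1] + 5L
    gly <- p <= nchar(mat$mature) && substr(mat$mature, p, p) == "G"
  }
  ids <- vapply(reference$consensus, function(pat) {
    tryCatch(consensus_identity(mat$mature, pat), error = function(e) NA_real_)
  }, numeric(1))
  structure(list(
    mature_span = c(start = mat$start, end = mat$end),
    cys_positions = fw$cys_positions,
    disulfide_pairs = fw$disulfide_pairs,
    type_call = if (fw$valid) type else "invalid",
    gly_after_c1 = gly,
    c_terminal_basic = grepl("[KR]{3,}$", mat$mature),
    consensus_identity = ids
  ), class = "cfrc_peptide_report")
}
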