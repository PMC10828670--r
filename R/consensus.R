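## Alignment column statistics (logo data) and consensus derivation in the
## degenerate motif grammar.

#' Per-column residue proportions of an alignment
#'
#' For every column, the proportion of each residue among non-gap entries
#' and the gap fraction. This is the data behind proportional sequence-logo
#' plots: per site, stack heights are residue proportions among the
#' sequences present at that site.
#'
#' @param alignment An `AAStringSet`/`BStringSet` of equal-width rows, a
#'   character vector of aligned strings, or a `cfrc_seqs` table of aligned
#'   sequences (gaps as `-`).
#' @return A list of class `cfrc_profiles` with `prop` (residue x column
#'   matrix of proportions over non-gap symbols; all-gap columns are all
#'   zero), `gap_fraction` (per column) and `n_sequences`.
#' @export
column_profiles <- function(alignment) {
  if (inherits(alignment, "cfrc_seqs")) alignment <- alignment$residues
  if (is.character(alignment)) {
    if (length(alignment) < 1) cfrc_error("empty alignment", "cfrc_format_error")
    if (length(unique(nchar(alignment))) != 1)
      cfrc_error("ragged alignment: rows differ in length", "cfrc_format_error")
    alignment <- Biostrings::BStringSet(toupper(alignment))
  }
  if (length(alignment) < 1) cfrc_error("empty alignment", "cfrc_format_error")
  if (length(unique(Biostrings::width(alignment))) != 1)
    cfrc_error("ragged alignment: rows differ in length", "cfrc_format_error")
  cm <- Biostrings::consensusMatrix(alignment)
  n <- length(alignment)
  gaps <- if ("-" %in% rownames(cm)) cm["-", ] else rep(0, ncol(cm))
  res_rows <- intersect(rownames(cm), AA_ALPHABET)
  counts <- cm[res_rows, , drop = FALSE]
  other <- setdiff(rownames(cm), c(res_rows, "-"))
  if (length(other) > 0 && any(cm[other, ] > 0))
    cfrc_error("alignment contains symbols outside the amino-acid alphabet",
               "cfrc_format_error")
  present <- n - gaps
  prop <- sweep(counts, 2, pmax(present, 1), "/")
  prop[, present == 0] <- 0
  structure(list(prop = prop, gap_fraction = unname(gaps) / n,
                 n_sequences = n),
            class = "cfrc_profiles")
}

#' Consensus-derivation thresholds
#'
#' @param residue_threshold Proportion at or above which the top residue is
#'   written as a conserved site (default 0.7).
#' @param pair_threshold When the top two residues each reach this
#'   proportion (but neither reaches `residue_threshold`), the site is
#'   written as a bracket pair, e.g. `[ED]` for residues seen in near-equal
#'   proportions (default 0.4).
#' @param gap_bracket_threshold Gap fraction at or above which a site is
#'   marked as a possible indel with a `-` inside the brackets (default
#'   0.2).
#' @return A list of class `cfrc_consensus_config`.
#' @export
consensus_config <- function(residue_threshold = 0.7, pair_threshold = 0.4,
                             gap_bracket_threshold = 0.2) {
  stopifnot(residue_threshold > 0, residue_threshold <= 1,
            2 * pair_threshold <= 1 + 1e-9,
            gap_bracket_threshold >= 0, gap_bracket_threshold < 1)
  structure(list(residue_threshold = residue_threshold,
                 pair_threshold = pair_threshold,
                 gap_bracket_threshold = gap_bracket_threshold),
            class = "cfrc_consensus_config")
}

#' Build a consensus string in the motif grammar
#'
#' Per column: the top residue when its proportion reaches the residue
#' threshold (bracketed with `-` when the gap fraction marks a possible
#' indel); a bracket pair `[R1R2]` when the top two residues each reach the
#' pair threshold without either dominating; `[x-]` for unconserved sites
#' with substantial gaps; plain `x` otherwise.
#'
#' @param profiles A `cfrc_profiles` object from [column_profiles()].
#' @param config A `cfrc_consensus_config`.
#' @return Consensus string in the grammar of [parse_motif()].
#' @export
build_consensus <- function(profiles, config = consensus_config()) {
  prop <- profiles$prop
  stopifnot(ncol(prop) > 0)
  out <- character(ncol(prop))
  for (j in seq_len(ncol(prop))) {
    p <- sort(prop[, j], decreasing = TRUE)
    top <- p[1]; top_res <- names(p)[1]
    gapped <- profiles$gap_fraction[j] >= config$gap_bracket_threshold
    if (top >= config$residue_threshold) {
      out[j] <- if (gapped) paste0("[", top_res, "-]") else top_res
    } else if (length(p) >= 2 && p[2] >= config$pair_threshold) {
      pair <- names(p)[1:2]
      ## deterministic order: by proportion, ties alphabetical
      if (abs(p[1] - p[2]) < 1e-12) pair <- sort(pair)
      out[j] <- paste0("[", pair[1], pair[2], "]")
    } else if (gapped) {
      out[j] <- "[x-]"
    } else {
      out[j] <- "x"
    }
  }
  paste(out, collapse = "")
}

#' Zero-gap consensus round-trip check
#'
#' Realizes `n` sequences from a pattern (conserved sites kept with
#' probability `1 - per_site_noise`, wildcards random), stacks them as a
#' trivial equal-length alignment, rebuilds the consensus with default
#' thresholds, and reports whether every conserved single-residue site of
#' the source pattern is recovered at its position.
#'
#' @param pattern Pattern string or `cfrc_motif`.
#' @param n Number of realizations (>= 2).
#' @param per_site_noise Per-site corruption probability for conserved
#'   sites.
#' @param config Consensus thresholds used for the rebuild.
#' @return `TRUE` when all conserved non-bracket sites are recovered.
#' @export
roundtrip_check <- function(pattern, n, per_site_noise = 0,
                            config = consensus_config()) {
  if (is.character(pattern)) pattern <- parse_motif(pattern)
  stopifnot(n >= 2, per_site_noise >= 0, per_site_noise <= 1)
  sites <- pattern$sites
  L <- length(sites)
  rows <- vapply(seq_len(n), function(i) {
    chars <- vapply(sites, function(s) {
      if (is.null(s$allowed)) sample(AA20, 1)
      else if (stats::runif(1) < per_site_noise) sample(AA20, 1)
      else if (length(s$allowed) == 1) s$allowed
      else sample(s$allowed, 1)
    }, character(1))
    paste(chars, collapse = "")
  }, character(1))
  cons <- build_consensus(column_profiles(rows), config)
  ## a fully unconserved consensus (possible under heavy noise) cannot
  ## recover anything
  rebuilt <- tryCatch(parse_motif(cons), error = function(e) NULL)
  if (is.null(rebuilt)) return(FALSE)
  if (length(rebuilt$sites) != L) return(FALSE)
  for (j in seq_len(L)) {
    s <- sites[[j]]
    if (is.null(s$allowed) || length(s$allowed) != 1 || s$gap) next
    r <- rebuilt$sites[[j]]
    if (is.null(r$allowed) || !identical(r$allowed, s$allowed)) return(FALSE)
  }
  TRUE
}

#' Proportional sequence-logo plot
#'
#' Stacked per-column residue proportions (no information-content scaling):
#' column heights show the proportion of each residue among the sequences
#' present at that site.
#'
#' @param profiles A `cfrc_profiles` object.
#' @return A `ggplot` object.
#' @export
plot_logo <- function(profiles) {
  prop <- profiles$prop
  df <- data.frame(
    position = rep(seq_len(ncol(prop)), each = nrow(prop)),
    residue = rep(rownames(prop), times = ncol(prop)),
    proportion = as.vector(prop),
    stringsAsFactors = FALSE
  )
  df <- df[df$proportion > 0, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$position, y = .data$proportion, fill = .data$residue)) +
    ggplot2::geom_col(width = 0.9, colour = "grey30", linewidth = 0.1) +
    ggplot2::scale_x_continuous(breaks = pretty) +
    ggplot2::labs(x = "alignment position",
                  y = "residue proportion (non-gap)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
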