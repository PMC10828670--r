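## Species x subclade presence/absence matrices, summary statistics,
## taxonomic-restriction checks, and the CFRC nomenclature.

presence_template <- function(species, infraorder) {
  m <- as.data.frame(matrix(FALSE, nrow = length(species),
                            ncol = length(DECAPOD_SUBCLADES)),
                     stringsAsFactors = FALSE)
  names(m) <- DECAPOD_SUBCLADES
  out <- cbind(data.frame(species = species, infraorder = infraorder,
                          stringsAsFactors = FALSE), m)
  class(out) <- c("cfrc_presence", "data.frame")
  out
}

#' Read a species x subclade presence matrix
#'
#' TSV with columns `species`, `infraorder` and the 11 decapod subclade
#' labels; cells are 0/1.
#'
#' @param path Path to the TSV file.
#' @return A data frame of class `cfrc_presence`.
#' @export
read_presence_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  need <- c("species", "infraorder", DECAPOD_SUBCLADES)
  if (!identical(names(df), need))
    cfrc_error(paste0("presence matrix columns must be exactly: ",
                      paste(need, collapse = ", ")), "cfrc_format_error")
  if (any(is.na(df$infraorder) | !nzchar(df$infraorder)))
    cfrc_error("every species row needs an infraorder", "cfrc_format_error")
  for (s in DECAPOD_SUBCLADES) df[[s]] <- as.logical(as.integer(df[[s]]))
  class(df) <- c("cfrc_presence", "data.frame")
  df
}

#' Packaged decapod presence/absence matrix
#'
#' The packaged species x subclade matrix for 37 decapod species across six
#' infraorders (cells mark subclades with at least one identified sequence
#' in that species).
#'
#' @return A `cfrc_presence` data frame.
#' @export
decapod_presence_matrix <- function() {
  read_presence_matrix(system.file("extdata", "table4_presence.tsv",
                                   package = "cfrckit", mustWork = TRUE))
}

#' Build a presence matrix from classification calls
#'
#' Only calls with status `classified` contribute; ambiguous and
#' unclassified calls are skipped (and reported in the `skipped` attribute).
#' A cell is set when the species has at least one classified call of that
#' subclade, so repeated calls are idempotent.
#'
#' @param calls Data frame with columns `species`, `infraorder`, `subclade`
#'   and `status`.
#' @return A `cfrc_presence` data frame (attribute `skipped`: row indices of
#'   non-classified calls).
#' @export
build_matrix <- function(calls) {
  stopifnot(all(c("species", "infraorder", "subclade", "status") %in% names(calls)))
  use <- calls$status == "classified"
  bad <- setdiff(unique(calls$subclade[use]), DECAPOD_SUBCLADES)
  if (length(bad) > 0)
    cfrc_error(paste0("unknown subclade label(s): ", paste(bad, collapse = ", ")),
               "cfrc_format_error")
  keyed <- unique(calls[use, c("species", "infraorder")])
  keyed <- keyed[order(keyed$species), , drop = FALSE]
  out <- presence_template(keyed$species, keyed$infraorder)
  for (i in which(use)) {
    r <- match(calls$species[i], out$species)
    out[r, calls$subclade[i]] <- TRUE
  }
  attr(out, "skipped") <- which(!use)
  out
}

#' Summary statistics of a presence matrix
#'
#' @param matrix A `cfrc_presence` data frame.
#' @param pairs Optional list of `c(subclade_a, subclade_b, infraorder)`
#'   triples (infraorder may be `NA` for all species) for which species
#'   co-occurrence counts are reported.
#' @return A list of class `cfrc_matrix_stats`: `total_presences`,
#'   `n_species`, `n_subclades_present`, `per_subclade` (named counts),
#'   `per_species` (named counts), `min`/`max` per-species counts with
#'   `argmins`/`argmax` species, `restricted_to` (per subclade: the single
#'   infraorder holding all its presences, else `NA`), and `co_occurrence`
#'   (named counts for the requested pairs).
#' @export
matrix_stats <- function(matrix, pairs = list()) {
  cells <- as.matrix(matrix[, DECAPOD_SUBCLADES])
  rownames(cells) <- matrix$species
  per_subclade <- colSums(cells)
  per_species <- rowSums(cells)
  restricted <- vapply(DECAPOD_SUBCLADES, function(s) {
    inf <- unique(matrix$infraorder[cells[, s]])
    if (length(inf) == 1) inf else NA_character_
  }, character(1))
  co <- numeric(0)
  if (length(pairs) > 0) {
    co <- vapply(pairs, function(p) {
      sel <- cells[, p[1]] & cells[, p[2]]
      if (length(p) >= 3 && !is.na(p[3])) sel <- sel & matrix$infraorder == p[3]
      sum(sel)
    }, numeric(1))
    names(co) <- vapply(pairs, function(p) {
      nm <- paste0(p[1], "&", p[2])
      if (length(p) >= 3 && !is.na(p[3])) paste0(nm, "|", p[3]) else nm
    }, character(1))
  }
  structure(list(
    total_presences = sum(cells),
    n_species = nrow(cells),
    n_subclades_present = sum(per_subclade > 0),
    per_subclade = per_subclade,
    per_species = per_species,
    min = if (nrow(cells) > 0) min(per_species) else 0L,
    max = if (nrow(cells) > 0) max(per_species) else 0L,
    argmins = names(per_species)[per_species == suppressWarnings(min(per_species))],
    argmax = names(per_species)[per_species == suppressWarnings(max(per_species))],
    restricted_to = restricted,
    co_occurrence = co
  ), class = "cfrc_matrix_stats")
}

#' CFRC nomenclature for a classified call
#'
#' Builds the proposed receptor name `<species prefix>-CFRC-<subclade>`
#' (e.g. `Gl-CFRC-A34β1`). Ambiguous or unclassified calls are an error.
#'
#' @param species_prefix Two-letter species prefix (e.g. `"Gl"`).
#' @param call A `cfrc_call`, or any list with `status` and `subclade`.
#' @return Character name.
#' @export
nomenclature <- function(species_prefix, call) {
  if (!identical(call$status, "classified"))
    cfrc_error(paste0("cannot name a call with status '", call$status, "'"),
               "cfrc_format_error")
  paste0(species_prefix, "-CFRC-", call$subclade)
}
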