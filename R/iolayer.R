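## IO layer: FASTA sequences, homology hit tables, per-residue topology
## labels, and the degenerate motif library. Coordinates are 1-based
## inclusive throughout the package.

#' Construct a protein sequence table
#'
#' The package-wide container for protein sequences is a plain data frame
#' with one row per sequence and columns `id`, `species`, `taxon_group`,
#' `residues` and `is_fragment`. Residues are uppercased and validated
#' against the 20 standard amino acids plus `X`.
#'
#' @param id Character vector of unique sequence identifiers.
#' @param residues Character vector of residue strings.
#' @param species Optional species label per sequence.
#' @param taxon_group Optional higher-taxon label (e.g. infraorder).
#' @param is_fragment Logical; whether the sequence is a known fragment.
#' @return A data frame of class `cfrc_seqs`.
#' @export
#' @examples
#' protein_sequences("s1", "ACDE")
protein_sequences <- function(id, residues, species = NA_character_,
                              taxon_group = NA_character_,
                              is_fragment = FALSE) {
  stopifnot(length(id) == length(residues))
  residues <- toupper(residues)
  for (i in seq_along(residues)) {
    if (!nzchar(residues[i]))
      cfrc_error(sprintf("record '%s': empty sequence", id[i]), "cfrc_format_error")
    bad <- regexpr(sprintf("[^%s]", paste(AA_ALPHABET, collapse = "")), residues[i])
    if (bad > 0)
      cfrc_error(sprintf(
        "record '%s': illegal residue '%s' at position %d",
        id[i], substr(residues[i], bad, bad), bad), "cfrc_format_error")
  }
  out <- data.frame(
    id = as.character(id),
    species = rep_len(as.character(species), length(id)),
    taxon_group = rep_len(as.character(taxon_group), length(id)),
    residues = residues,
    is_fragment = rep_len(as.logical(is_fragment), length(id)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("cfrc_seqs", "data.frame")
  out
}

## Parse "key=value" metadata tokens from a FASTA description.
parse_header_meta <- function(desc) {
  meta <- list(species = NA_character_, taxon = NA_character_, fragment = FALSE)
  if (!nzchar(desc)) return(meta)
  toks <- strsplit(desc, "[[:space:]]+")[[1]]
  for (tk in toks) {
    if (grepl("^species=", tk)) meta$species <- sub("^species=", "", tk)
    if (grepl("^taxon=", tk))   meta$taxon   <- sub("^taxon=", "", tk)
    if (grepl("^fragment=", tk)) meta$fragment <- sub("^fragment=", "", tk) %in% c("1", "true", "TRUE")
  }
  meta
}

#' Read protein sequences from a FASTA file
#'
#' Headers are split at the first whitespace: the leading token becomes the
#' sequence `id`; optional `species=`, `taxon=` and `fragment=` key-value
#' tokens in the remainder populate the metadata columns. Residues are
#' uppercased; trailing `*` stop characters are stripped; any other character
#' outside the amino-acid alphabet raises a format error naming the record
#' and position.
#'
#' @param path Path to a FASTA file.
#' @return A `cfrc_seqs` data frame (see [protein_sequences()]).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) cfrc_error(paste0("no such file: ", path), "cfrc_format_error")
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) cfrc_error(
                    paste0("not parseable as FASTA: ", conditionMessage(e)),
                    "cfrc_format_error"))
  if (length(set) == 0) cfrc_error("empty FASTA file", "cfrc_format_error")
  headers <- names(set)
  ids <- sub("[[:space:]].*$", "", headers)
  descs <- ifelse(grepl("[[:space:]]", headers),
                  sub("^[^[:space:]]+[[:space:]]+", "", headers), "")
  res <- toupper(as.character(set))
  res <- sub("\\*+$", "", res)  # stop codons stripped from the end only
  meta <- lapply(descs, parse_header_meta)
  protein_sequences(
    id = ids, residues = res,
    species = vapply(meta, `[[`, character(1), "species"),
    taxon_group = vapply(meta, `[[`, character(1), "taxon"),
    is_fragment = vapply(meta, `[[`, logical(1), "fragment")
  )
}

#' Write protein sequences to a FASTA file
#'
#' Inverse of [read_fasta()]: metadata columns are embedded as `key=value`
#' header tokens so that a read/write round trip preserves ids, residues and
#' metadata.
#'
#' @param seqs A `cfrc_seqs` data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  hdr <- seqs$id
  extra <- character(nrow(seqs))
  add <- function(extra, key, val, keep) ifelse(keep, paste0(extra, " ", key, "=", val), extra)
  extra <- add(extra, "species", seqs$species, !is.na(seqs$species))
  extra <- add(extra, "taxon", seqs$taxon_group, !is.na(seqs$taxon_group))
  extra <- add(extra, "fragment", "1", seqs$is_fragment %in% TRUE)
  set <- Biostrings::BStringSet(seqs$residues)
  names(set) <- paste0(hdr, extra)
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}

#' Read a tabular homology-search hit table
#'
#' Consumes the standard 12-column tab-separated hit format (query id,
#' subject id, percent identity, alignment length, mismatches, gap opens,
#' query start/end, subject start/end, e-value, bit score), optionally
#' extended by four named metadata columns: `species`, `taxon_group`,
#' `has_7tm1` (0/1/NA) and `n_tm_predicted` (integer/NA). Unknown metadata is
#' recorded as `NA` (tri-state), never defaulted to a pass or fail value.
#'
#' @param path Path to the tab-separated file.
#' @return A data frame of class `cfrc_hits` with one row per hit; columns
#'   `query_id`, `subject_id`, `species`, `taxon_group`, `evalue`,
#'   `aln_length`, `has_7tm1` (logical, `NA` = unannotated),
#'   `n_tm_predicted` (integer, `NA` = unannotated) and `sequence_ref`.
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) cfrc_error(paste0("no such file: ", path), "cfrc_format_error")
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0) return(candidate_hits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  rows <- vector("list", length(fields))
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 12)
      cfrc_error(sprintf("row %d: expected >= 12 tab-separated columns, found %d",
                         i, length(f)), "cfrc_format_error")
    ev <- suppressWarnings(as.numeric(f[11]))
    if (is.na(ev))
      cfrc_error(sprintf("row %d: non-numeric e-value '%s'", i, f[11]),
                 "cfrc_format_error")
    if (ev < 0)
      cfrc_error(sprintf("row %d: negative e-value", i), "cfrc_format_error")
    len <- suppressWarnings(as.integer(f[4]))
    if (is.na(len) || len < 1)
      cfrc_error(sprintf("row %d: alignment length must be a positive integer", i),
                 "cfrc_format_error")
    opt <- function(k) if (length(f) >= k && nzchar(f[k]) && f[k] != "NA") f[k] else NA_character_
    tm1 <- opt(15)
    tm1 <- if (is.na(tm1)) NA else tm1 == "1"
    ntm <- opt(16)
    ntm <- if (is.na(ntm)) NA_integer_ else as.integer(ntm)
    rows[[i]] <- data.frame(
      query_id = f[1], subject_id = f[2],
      species = opt(13), taxon_group = opt(14),
      evalue = ev, aln_length = len,
      has_7tm1 = tm1, n_tm_predicted = ntm,
      sequence_ref = f[2], stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cfrc_hits", "data.frame")
  out
}

#' Construct an empty or in-memory hit table
#'
#' @param query_id,subject_id,species,taxon_group,evalue,aln_length,has_7tm1,n_tm_predicted,sequence_ref
#'   Column vectors, recycled to a common length.
#' @return A `cfrc_hits` data frame.
#' @export
candidate_hits <- function(query_id = character(), subject_id = character(),
                           species = NA_character_, taxon_group = NA_character_,
                           evalue = numeric(), aln_length = 1L,
                           has_7tm1 = NA, n_tm_predicted = NA_integer_,
                           sequence_ref = subject_id) {
  n <- max(length(query_id), length(subject_id), length(evalue))
  out <- data.frame(
    query_id = rep_len(as.character(query_id), n),
    subject_id = rep_len(as.character(subject_id), n),
    species = rep_len(as.character(species), n),
    taxon_group = rep_len(as.character(taxon_group), n),
    evalue = rep_len(as.numeric(evalue), n),
    aln_length = rep_len(as.integer(aln_length), n),
    has_7tm1 = rep_len(as.logical(has_7tm1), n),
    n_tm_predicted = rep_len(as.integer(n_tm_predicted), n),
    sequence_ref = rep_len(as.character(sequence_ref), n),
    stringsAsFactors = FALSE
  )
  if (n > 0 && any(out$evalue < 0)) cfrc_error("e-values must be >= 0", "cfrc_format_error")
  class(out) <- c("cfrc_hits", "data.frame")
  out
}

#' Read per-residue topology labels
#'
#' FASTA-like pairing of an id line with a label string over the alphabet
#' `O` (outside/extracellular), `M` (membrane) and `I` (inside/cytosolic),
#' as emitted by external topology predictors. Lowercase labels are
#' accepted and uppercased. Length consistency against the paired sequence
#' is checked later, at region assignment.
#'
#' @param path Path to the label file.
#' @return Named character vector mapping id to label string.
#' @export
read_topology_labels <- function(path) {
  if (!file.exists(path)) cfrc_error(paste0("no such file: ", path), "cfrc_format_error")
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) cfrc_error(
                    paste0("not parseable as FASTA-like labels: ", conditionMessage(e)),
                    "cfrc_format_error"))
  if (length(set) == 0) cfrc_error("empty topology file", "cfrc_format_error")
  labs <- toupper(as.character(set))
  for (i in seq_along(labs)) {
    bad <- regexpr("[^OMI]", labs[i])
    if (bad > 0)
      cfrc_error(sprintf("record '%s': label '%s' at position %d not in {O,M,I}",
                         names(set)[i], substr(labs[i], bad, bad), bad),
                 "cfrc_format_error")
  }
  names(labs) <- sub("[[:space:]].*$", "", names(set))
  labs
}

#' Read a degenerate motif library
#'
#' Parses a YAML motif library listing, per entry, `clade`, `subclade`,
#' `region` (`ECL2` or `ECL3`) and a `pattern` string in the grammar of
#' [parse_motif()]. Every ECL2 pattern must carry the `(C)` anchor marker on
#' its conserved cysteine; ECL3 patterns need no anchor.
#'
#' @param path Path to a YAML file; defaults to the packaged decapod library
#'   of 11 subclades x 2 regions.
#' @return A list of class `cfrc_motif_library`; each element has fields
#'   `clade`, `subclade`, `region`, `text` and `pattern` (a parsed
#'   `cfrc_motif`). Elements are named `"<subclade>|<region>"`.
#' @export
#' @examples
#' lib <- read_motif_library()
#' length(lib)  # 22 patterns for decapods
read_motif_library <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "motifs_decapod.yaml", package = "cfrckit",
                        mustWork = TRUE)
  doc <- yaml::read_yaml(path)
  if (is.null(doc$motifs) || length(doc$motifs) == 0)
    cfrc_error("motif library lists no motifs", "cfrc_format_error")
  out <- list()
  for (entry in doc$motifs) {
    for (fld in c("clade", "subclade", "region", "pattern"))
      if (is.null(entry[[fld]]))
        cfrc_error(paste0("motif entry missing field '", fld, "'"), "cfrc_format_error")
    if (!entry$region %in% c("ECL2", "ECL3"))
      cfrc_error(paste0("motif region must be ECL2 or ECL3, got ", entry$region),
                 "cfrc_format_error")
    pat <- parse_motif(entry$pattern)
    if (entry$region == "ECL2" && is.na(pat$anchor))
      cfrc_error(sprintf("ECL2 pattern for %s lacks the (C) anchor marker",
                         entry$subclade), "cfrc_validation_error")
    key <- paste0(entry$subclade, "|", entry$region)
    out[[key]] <- list(clade = entry$clade, subclade = entry$subclade,
                       region = entry$region, text = entry$pattern, pattern = pat)
  }
  class(out) <- "cfrc_motif_library"
  out
}

## Cache for the packaged default library.
.cfrc_env <- new.env(parent = emptyenv())

#' Packaged decapod motif library
#'
#' @return The parsed default library (see [read_motif_library()]), cached
#'   after first use.
#' @export
default_motif_library <- function() {
  if (is.null(.cfrc_env$library)) .cfrc_env$library <- read_motif_library()
  .cfrc_env$library
}

## Subclades present in a library, preserving canonical order where possible.
library_subclades <- function(library) {
  subs <- unique(vapply(library, `[[`, character(1), "subclade"))
  known <- DECAPOD_SUBCLADES[DECAPOD_SUBCLADES %in% subs]
  c(known, setdiff(subs, known))
}

#' Packaged CHH-superfamily reference peptides and consensus patterns
#'
#' Returns the packaged brachyuran reference set: the Gl-MIH and Gl-CHH
#' mature peptides and the MIH/CHH family consensus strings (degenerate
#' motif grammar, six conserved cysteines each).
#'
#' @return A list with elements `peptides` (a `cfrc_seqs` data frame) and
#'   `consensus` (named character vector of consensus patterns, names `MIH`
#'   and `CHH`).
#' @export
chh_reference_set <- function() {
  path <- system.file("extdata", "chh_consensus.yaml", package = "cfrckit",
                      mustWork = TRUE)
  doc <- yaml::read_yaml(path)
  peps <- protein_sequences(
    id = vapply(doc$peptides, `[[`, character(1), "id"),
    residues = vapply(doc$peptides, `[[`, character(1), "sequence")
  )
  peps$family <- vapply(doc$peptides, `[[`, character(1), "family")
  cons <- vapply(doc$consensus, `[[`, character(1), "pattern")
  names(cons) <- vapply(doc$consensus, `[[`, character(1), "family")
  list(peptides = peps, consensus = cons)
}
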