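## Candidate curation: e-value screen, Class A / 7tm_1 domain check,
## transmembrane-count filter with brachyuran fragment exemptions, and
## same-species redundancy removal. Every filter is deterministic and the
## final report accounts for every input id exactly once.

#' Curation parameters
#'
#' @param evalue_threshold Hits are kept iff `evalue < evalue_threshold`
#'   (strict); default `1e-10`.
#' @param min_tm Minimum number of predicted transmembrane segments; default
#'   6 (fewer than six are discarded).
#' @param exempt_taxa Taxon groups whose known fragments are exempt from the
#'   domain and TM-count stages; default `"Brachyura"`.
#' @param redundancy_identity Pairwise identity at or above which two
#'   same-species sequences are considered redundant; default 0.95.
#' @return A list of class `cfrc_curation_config`.
#' @export
curation_config <- function(evalue_threshold = 1e-10, min_tm = 6L,
                            exempt_taxa = "Brachyura",
                            redundancy_identity = 0.95) {
  stopifnot(evalue_threshold > 0, min_tm >= 1,
            redundancy_identity > 0, redundancy_identity <= 1)
  structure(list(evalue_threshold = evalue_threshold, min_tm = as.integer(min_tm),
                 exempt_taxa = as.character(exempt_taxa),
                 redundancy_identity = redundancy_identity),
            class = "cfrc_curation_config")
}

#' E-value screen
#'
#' @param hits A `cfrc_hits` data frame.
#' @param threshold Strict upper bound on the e-value (a hit exactly at the
#'   threshold is removed).
#' @return The subset of `hits` with `evalue < threshold`, input order
#'   preserved.
#' @export
filter_evalue <- function(hits, threshold = 1e-10) {
  stopifnot(threshold > 0)
  hits[hits$evalue < threshold, , drop = FALSE]
}

## TRUE where a hit may bypass the domain/TM stages: exempt taxon + fragment.
is_exempt <- function(hits, exempt_taxa, fragments) {
  frag <- fragments[hits$sequence_ref]
  frag[is.na(frag)] <- FALSE
  (!is.na(hits$taxon_group) & hits$taxon_group %in% exempt_taxa) & frag
}

#' Class A / 7tm_1 domain filter
#'
#' Keeps hits annotated as carrying the seven-transmembrane Class A domain
#' (`has_7tm1 = TRUE`). Hits with a negative or missing annotation are kept
#' only under the fragment exemption (taxon in `exempt_taxa` and the
#' sequence flagged as a fragment); otherwise they are removed, missing
#' annotations with reason `"unannotated"`.
#'
#' @param hits A `cfrc_hits` data frame (tri-state `has_7tm1`).
#' @param exempt_taxa Character vector of exempt taxon groups.
#' @param fragments Named logical vector keyed by sequence id (fragment
#'   status); defaults to no fragments.
#' @return A list with `kept` (hits, plus a logical `exempted` column) and
#'   `removed` (data frame `id`, `reason`).
#' @export
filter_domain <- function(hits, exempt_taxa = "Brachyura",
                          fragments = logical()) {
  ex <- is_exempt(hits, exempt_taxa, fragments)
  pass <- hits$has_7tm1 %in% TRUE
  keep <- pass | ex
  kept <- hits[keep, , drop = FALSE]
  kept$exempted <- ex[keep] & !pass[keep]
  rem <- hits[!keep, , drop = FALSE]
  reason <- ifelse(is.na(rem$has_7tm1), "unannotated", "no 7tm_1 domain")
  list(kept = kept,
       removed = data.frame(id = rem$sequence_ref, reason = reason,
                            stringsAsFactors = FALSE))
}

#' Transmembrane-count filter
#'
#' Keeps records whose predicted TM count is at least `min_tm`; records
#' below the bound are removed unless the fragment exemption applies.
#' Records with no TM annotation fall back, in order, to counting membrane
#' runs in supplied topology labels and to the built-in hydropathy
#' segmentation of the sequence; if no topology can be derived the record is
#' removed with reason `"no topology"`.
#'
#' @param hits A `cfrc_hits` data frame.
#' @param min_tm Minimum TM count (a count of exactly `min_tm` is kept).
#' @param exempt_taxa Character vector of exempt taxon groups.
#' @param fragments Named logical vector keyed by sequence id.
#' @param topologies Named character vector of O/M/I label strings.
#' @param seqs Optional `cfrc_seqs` table used for the hydropathy fallback.
#' @param hydro_config A `cfrc_hydropathy_config` for the fallback.
#' @return A list with `kept` and `removed` as in [filter_domain()].
#' @export
filter_tm_count <- function(hits, min_tm = 6L, exempt_taxa = "Brachyura",
                            fragments = logical(), topologies = character(),
                            seqs = NULL,
                            hydro_config = hydropathy_config()) {
  ex <- is_exempt(hits, exempt_taxa, fragments)
  n <- nrow(hits)
  ntm <- hits$n_tm_predicted
  for (i in seq_len(n)) {
    if (!is.na(ntm[i])) next
    id <- hits$sequence_ref[i]
    if (id %in% names(topologies)) {
      ntm[i] <- count_tm_from_labels(topologies[[id]])
    } else if (!is.null(seqs) && id %in% seqs$id) {
      s <- seqs$residues[match(id, seqs$id)]
      if (nchar(s) >= hydro_config$window)
        ntm[i] <- nrow(segment_tm(hydropathy_profile(s, hydro_config$window),
                                  hydro_config))
    }
  }
  pass <- !is.na(ntm) & ntm >= min_tm
  keep <- pass | ex
  kept <- hits[keep, , drop = FALSE]
  kept$n_tm_effective <- ntm[keep]
  kept$exempted <- ex[keep] & !pass[keep]
  rem <- hits[!keep, , drop = FALSE]
  reason <- ifelse(is.na(ntm[!keep]), "no topology",
                   sprintf("%d transmembrane segments (< %d)", ntm[!keep], min_tm))
  list(kept = kept,
       removed = data.frame(id = rem$sequence_ref, reason = reason,
                            stringsAsFactors = FALSE))
}

#' Pairwise global identity between two protein sequences
#'
#' Identity is matches divided by aligned columns, excluding terminal
#' overhangs, under the optimal global alignment with match 1, mismatch 0,
#' gap open -5 and gap extension -1 (the score is used only to pick the
#' alignment).
#'
#' @param a,b Non-empty sequence strings.
#' @return Fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  stopifnot(nzchar(a), nzchar(b))
  alpha <- AA_ALPHABET
  submat <- matrix(0, length(alpha), length(alpha),
                   dimnames = list(alpha, alpha))
  diag(submat) <- 1
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    type = "global", substitutionMatrix = submat,
    gapOpening = 5, gapExtension = 1)
  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  pb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  gap <- pa == "-" | pb == "-"
  ## trim terminal overhang columns (leading/trailing gap stretches)
  nongap <- which(!gap)
  if (length(nongap) == 0) return(0)
  ## terminal overhang = gap columns before the first / after the last
  ## column where both sequences have residues
  keep <- seq(min(nongap), max(nongap))
  pa <- pa[keep]; pb <- pb[keep]
  sum(pa == pb & pa != "-") / length(keep)
}

#' Remove redundant same-species sequences
#'
#' Greedy clustering within each species: sequences are visited by
#' descending length (ties by lexicographic id) and join the first existing
#' cluster whose representative is at least `identity_threshold` identical;
#' otherwise they found a new cluster. Cluster representatives (the longest
#' member, ties to the lexicographically smallest id) are retained; other
#' members are removed with reason `"redundant with <representative>"`.
#' Sequences from different species are never compared.
#'
#' @param seqs A `cfrc_seqs` data frame with species labels.
#' @param identity_threshold Identity fraction in `(0, 1]`.
#' @return A list with `retained` (ids) and `removed` (data frame `id`,
#'   `reason`).
#' @export
dedupe_same_species <- function(seqs, identity_threshold = 0.95) {
  retained <- character()
  removed <- data.frame(id = character(), reason = character(),
                        stringsAsFactors = FALSE)
  key <- ifelse(is.na(seqs$species), "\001<unlabelled>", seqs$species)
  for (k in unique(key)) {
    grp <- seqs[key == k, , drop = FALSE]
    ord <- order(-nchar(grp$residues), grp$id)
    grp <- grp[ord, , drop = FALSE]
    reps <- integer()  # row indices of cluster representatives
    for (i in seq_len(nrow(grp))) {
      placed <- FALSE
      for (r in reps) {
        if (pairwise_identity(grp$residues[r], grp$residues[i]) >=
            identity_threshold) {
          removed <- rbind(removed, data.frame(
            id = grp$id[i],
            reason = paste0("redundant with ", grp$id[r]),
            stringsAsFactors = FALSE))
          placed <- TRUE
          break
        }
      }
      if (!placed) reps <- c(reps, i)
    }
    retained <- c(retained, grp$id[reps])
  }
  list(retained = retained, removed = removed)
}

#' Run the full curation chain
#'
#' Applies, in order: the e-value screen, the 7tm_1 domain filter, the
#' TM-count filter and same-species redundancy removal. The report accounts
#' for every input id exactly once, either as retained or as removed at a
#' named stage with a reason.
#'
#' @param hits A `cfrc_hits` data frame.
#' @param seqs A `cfrc_seqs` data frame covering every `sequence_ref`.
#' @param topologies Optional named character vector of O/M/I labels.
#' @param config A `cfrc_curation_config`.
#' @return A list of class `cfrc_curation` with `retained` (ids), `removed`
#'   (data frame `id`, `stage`, `reason`), `counts` (per-stage survivor
#'   counts) and `exempted` (ids kept through the fragment exemption).
#' @export
curate <- function(hits, seqs, topologies = character(),
                   config = curation_config()) {
  missing_ids <- setdiff(hits$sequence_ref, seqs$id)
  if (length(missing_ids) > 0)
    cfrc_error(paste0("hit references missing sequences: ",
                      paste(missing_ids, collapse = ", ")),
               "cfrc_consistency_error")
  removed <- data.frame(id = character(), stage = character(),
                        reason = character(), stringsAsFactors = FALSE)
  note <- function(ids, stage, reason) {
    if (length(ids) > 0)
      removed <<- rbind(removed, data.frame(id = ids, stage = stage,
                                            reason = reason,
                                            stringsAsFactors = FALSE))
  }
  fragments <- stats::setNames(seqs$is_fragment, seqs$id)

  s1 <- filter_evalue(hits, config$evalue_threshold)
  note(setdiff(hits$sequence_ref, s1$sequence_ref), "evalue",
       sprintf("e-value >= %g", config$evalue_threshold))

  s2 <- filter_domain(s1, config$exempt_taxa, fragments)
  if (nrow(s2$removed) > 0)
    removed <- rbind(removed, cbind(s2$removed[, "id", drop = FALSE],
                                    stage = "domain",
                                    reason = s2$removed$reason))

  s3 <- filter_tm_count(s2$kept, config$min_tm, config$exempt_taxa, fragments,
                        topologies, seqs)
  if (nrow(s3$removed) > 0)
    removed <- rbind(removed, cbind(s3$removed[, "id", drop = FALSE],
                                    stage = "tm_count",
                                    reason = s3$removed$reason))

  surv <- seqs[seqs$id %in% s3$kept$sequence_ref, , drop = FALSE]
  s4 <- dedupe_same_species(surv, config$redundancy_identity)
  if (nrow(s4$removed) > 0)
    removed <- rbind(removed, cbind(s4$removed[, "id", drop = FALSE],
                                    stage = "redundancy",
                                    reason = s4$removed$reason))

  exempted <- unique(c(
    s2$kept$sequence_ref[s2$kept$exempted],
    s3$kept$sequence_ref[s3$kept$exempted]))
  structure(list(
    retained = s4$retained,
    removed = removed,
    counts = c(input = nrow(hits), evalue = nrow(s1), domain = nrow(s2$kept),
               tm_count = nrow(s3$kept), retained = length(s4$retained)),
    exempted = exempted[exempted %in% s4$retained]
  ), class = "cfrc_curation")
}

#' @export
print.cfrc_curation <- function(x, ...) {
  cat("CFRC curation report\n")
  cat(sprintf("  input: %d  retained: %d  removed: %d\n",
              x$counts[["input"]], length(x$retained), nrow(x$removed)))
  cat("  survivors per stage:",
      paste(names(x$counts), x$counts, sep = "=", collapse = "  "), "\n")
  invisible(x)
}
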