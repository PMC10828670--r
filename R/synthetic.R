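## Seeded synthetic benchmark generator. Emits labeled 7-TM receptor
## sequences carrying subclade-specific ECL2/ECL3 motifs, decoys for every
## curation failure mode, paired topology labels and hit-table rows, and
## CHH-family peptides realized from the packaged consensus patterns. All
## randomness flows from the spec seed.

TM_ALPHABET <- c("L", "I", "V", "F", "A", "M")
LOOP_ALPHABET <- c("D", "E", "K", "R", "N", "Q", "S", "T", "G", "H", "P")

#' Synthetic benchmark specification
#'
#' @param seed Integer seed fixing all randomness.
#' @param n_per_subclade Receptors generated per subclade (default 5).
#' @param mutation_rate Per-site mutation probability applied to the
#'   realized ECL2/ECL3 motifs (the anchor cysteine is never mutated).
#' @param decoy_fractions Named fractions (of the receptor count) of decoys
#'   per class: `non_gpcr`, `few_tm`, `fragment`, `wrong_species_dup`.
#' @param loop_length_jitter Maximum +/- jitter on plain loop lengths.
#' @param evalue_range Log-uniform sampling range for hit e-values; the
#'   default straddles the curation threshold so the e-value screen is
#'   exercised on both sides.
#' @return A list of class `cfrc_synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1L, n_per_subclade = 5L, mutation_rate = 0,
                           decoy_fractions = c(non_gpcr = 0.1, few_tm = 0.1,
                                               fragment = 0.1,
                                               wrong_species_dup = 0.1),
                           loop_length_jitter = 0L,
                           evalue_range = c(1e-30, 1e-5)) {
  stopifnot(mutation_rate >= 0, mutation_rate <= 1,
            all(decoy_fractions >= 0), all(decoy_fractions <= 1),
            loop_length_jitter >= 0, evalue_range[1] <= evalue_range[2])
  df <- c(non_gpcr = 0, few_tm = 0, fragment = 0, wrong_species_dup = 0)
  df[names(decoy_fractions)] <- decoy_fractions
  structure(list(seed = as.integer(seed),
                 n_per_subclade = as.integer(n_per_subclade),
                 mutation_rate = mutation_rate, decoy_fractions = df,
                 loop_length_jitter = as.integer(loop_length_jitter),
                 evalue_range = evalue_range),
            class = "cfrc_synthetic_spec")
}

#' Realize a sequence from a degenerate motif pattern
#'
#' Deterministic mode emits `A` for wildcards, the first member of a
#' residue set, and keeps gap-allowed sites. Random mode (using the current
#' RNG stream) samples wildcards uniformly from the 20 amino acids, samples
#' set members uniformly, and deletes gap-allowed sites with probability
#' 0.5. The anchor site always emits `C`.
#'
#' @param pattern Pattern string or `cfrc_motif`.
#' @param random Use the RNG (default `FALSE` = deterministic).
#' @return Realized string with attributes `anchor_pos` (position of the
#'   anchor in the realization, `NA` when unanchored) and `deleted_sites`.
#' @export
#' @examples
#' realize_motif("YSTTVSIxYxNxEIRRG(C)FLLWPDGxTSxSYxEY")
realize_motif <- function(pattern, random = FALSE) {
  if (is.character(pattern)) pattern <- parse_motif(pattern)
  chars <- character(0)
  deleted <- integer(0)
  anchor_pos <- NA_integer_
  for (j in seq_along(pattern$sites)) {
    s <- pattern$sites[[j]]
    if (s$gap && random && stats::runif(1) < 0.5) {
      deleted <- c(deleted, j)
      next
    }
    res <-
      if (is.null(s$allowed)) { if (random) sample(AA20, 1) else "A" }
      else if (length(s$allowed) == 1) s$allowed
      else if (random) sample(s$allowed, 1) else s$allowed[1]
    chars <- c(chars, res)
    if (!is.na(pattern$anchor) && j == pattern$anchor)
      anchor_pos <- length(chars)
  }
  structure(paste(chars, collapse = ""),
            anchor_pos = anchor_pos, deleted_sites = deleted)
}

## Point mutations at `rate`, never touching `protect` positions and never
## introducing the avoided residues.
mutate_residues <- function(seq, rate, protect = integer(), avoid = character()) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  pool <- setdiff(AA20, avoid)
  hit <- stats::runif(length(chars)) < rate
  hit[protect] <- FALSE
  for (i in which(hit)) {
    chars[i] <- sample(setdiff(pool, chars[i]), 1)
  }
  paste(chars, collapse = "")
}

rand_str <- function(n, alphabet) paste(sample(alphabet, n, replace = TRUE),
                                        collapse = "")

SPECIES_POOL <- data.frame(
  species = c("sp_brachy1", "sp_brachy2", "sp_astac1", "sp_carid1",
              "sp_anomu1", "sp_palin1"),
  taxon = c("Brachyura", "Brachyura", "Astacidea", "Caridea",
            "Anomura", "Palinuroidea"),
  stringsAsFactors = FALSE
)

#' Generate one labeled synthetic receptor
#'
#' Builds a hydrophilic N-terminus, seven 21-residue transmembrane blocks
#' drawn from a fixed hydrophobic alphabet alternating with hydrophilic
#' loops, with the ECL2 and ECL3 loops carrying realized subclade motifs
#' (mutated at the spec rate, anchor cysteine protected). Paired O/M/I
#' topology labels, planted coordinates and a hit-table row are emitted.
#' Uses the current RNG stream.
#'
#' @param subclade Subclade label present in `library`.
#' @param spec A `cfrc_synthetic_spec`.
#' @param library A `cfrc_motif_library`.
#' @param id Sequence id.
#' @return A list with `seq` (one-row `cfrc_seqs`), `labels`, `hit` (one-row
#'   `cfrc_hits`) and `truth` (list: subclade, tm matrix, ecl2/ecl3 global
#'   spans, anchor position).
#' @export
generate_receptor <- function(subclade, spec = synthetic_spec(),
                              library = default_motif_library(),
                              id = "rec001") {
  p2 <- library[[paste0(subclade, "|ECL2")]]
  p3 <- library[[paste0(subclade, "|ECL3")]]
  if (is.null(p2)) cfrc_error(paste0("unknown subclade: ", subclade),
                              "cfrc_format_error")
  j <- spec$loop_length_jitter
  jit <- function(n) max(4L, n + if (j > 0) sample(-j:j, 1) else 0L)
  ecl2 <- realize_motif(p2$pattern, random = TRUE)
  anchor_local <- attr(ecl2, "anchor_pos")
  ecl2 <- mutate_residues(as.character(ecl2), spec$mutation_rate,
                          protect = if (is.na(anchor_local)) integer()
                                    else anchor_local)
  ecl3 <- if (!is.null(p3)) {
    e3 <- realize_motif(p3$pattern, random = TRUE)
    mutate_residues(as.character(e3), spec$mutation_rate)
  } else rand_str(jit(10L), LOOP_ALPHABET)

  segs <- list(N_term = rand_str(jit(18L), LOOP_ALPHABET))
  loops <- c(ICL1 = NA, ECL1 = NA, ICL2 = NA, ECL2 = NA, ICL3 = NA, ECL3 = NA)
  for (i in 1:7) {
    segs[[paste0("TMM", i)]] <- rand_str(21L, TM_ALPHABET)
    if (i < 7) {
      loop_name <- names(loops)[i]
      segs[[loop_name]] <- switch(loop_name,
        ECL2 = ecl2, ECL3 = ecl3, rand_str(jit(10L), LOOP_ALPHABET))
    }
  }
  segs$C_term <- rand_str(jit(18L), LOOP_ALPHABET)

  order_names <- REGION_ORDER
  widths <- vapply(segs[order_names], nchar, integer(1))
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  seq <- paste(unlist(segs[order_names]), collapse = "")
  side <- c("O", "M", "I", "M", "O", "M", "I", "M", "O", "M", "I", "M", "O",
            "M", "I")
  labels <- paste(rep(side, times = widths), collapse = "")
  tm_idx <- grep("^TMM", order_names)
  tms <- cbind(start = starts[tm_idx], end = ends[tm_idx])

  sp <- SPECIES_POOL[sample(nrow(SPECIES_POOL), 1), ]
  ev <- exp(stats::runif(1, log(spec$evalue_range[1]), log(spec$evalue_range[2])))
  e2i <- match("ECL2", order_names)
  e3i <- match("ECL3", order_names)
  list(
    seq = protein_sequences(id, seq, species = sp$species,
                            taxon_group = sp$taxon, is_fragment = FALSE),
    labels = stats::setNames(labels, id),
    hit = candidate_hits(query_id = paste0("BNGR-", subclade_clade(subclade)),
                         subject_id = id, species = sp$species,
                         taxon_group = sp$taxon, evalue = ev,
                         aln_length = nchar(seq), has_7tm1 = TRUE,
                         n_tm_predicted = NA_integer_),
    truth = list(subclade = subclade, tms = tms,
                 ecl2_span = c(starts[e2i], ends[e2i]),
                 ecl3_span = c(starts[e3i], ends[e3i]),
                 anchor_global = starts[e2i] + anchor_local - 1L)
  )
}

#' Generate a labeled CHH-family peptide
#'
#' Realizes a mature peptide from the packaged family consensus (wildcards
#' sample non-cysteine residues so the six-cysteine framework is
#' preserved), mutates non-cysteine sites at `mutation_rate` (never into a
#' cysteine), and optionally wraps it as a Type I precursor with signal
#' peptide, precursor-related peptide and a KR cleavage site. Uses the
#' current RNG stream.
#'
#' @param family `"MIH"` or `"CHH"`.
#' @param mutation_rate Per-site mutation probability.
#' @param precursor Wrap as a precursor (signal + PRP + KR + mature).
#' @param reference Reference set from [chh_reference_set()].
#' @return A list with `sequence`, `mature`, `mature_start`, `family` and
#'   `expected_type` (`"II"` for MIH, `"I"` for CHH).
#' @export
generate_peptide <- function(family = c("MIH", "CHH"), mutation_rate = 0,
                             precursor = FALSE,
                             reference = chh_reference_set()) {
  family <- match.arg(family)
  pat <- parse_motif(reference$consensus[[family]])
  chars <- vapply(pat$sites, function(s) {
    if (is.null(s$allowed)) sample(setdiff(AA20, "C"), 1)
    else if (length(s$allowed) == 1) s$allowed
    else sample(s$allowed, 1)
  }, character(1))
  mature <- paste(chars, collapse = "")
  cys <- which(chars == "C")
  mature <- mutate_residues(mature, mutation_rate, protect = cys, avoid = "C")
  ## no spurious dibasic site upstream of the first cysteine, so mature
  ## extraction from a wrapped precursor is exact
  repeat {
    head <- substr(mature, 1, cys[1])
    k <- regexpr("KR", head)
    if (k < 0) break
    substr(mature, k, k) <- sample(setdiff(AA20, c("C", "K", "R")), 1)
  }
  out <- list(mature = mature, family = family,
              expected_type = if (family == "MIH") "II" else "I")
  if (precursor) {
    signal <- paste0("M", rand_str(14L, setdiff(TM_ALPHABET, "C")))
    prp <- rand_str(10L, setdiff(LOOP_ALPHABET, c("K", "R")))
    out$sequence <- paste0(signal, prp, "KR", mature)
    out$mature_start <- nchar(signal) + nchar(prp) + 3L
  } else {
    out$sequence <- mature
    out$mature_start <- 1L
  }
  out
}

#' Generate a full labeled benchmark bundle
#'
#' Produces `n_per_subclade` receptors for every subclade in the library
#' plus decoys of each configured class (non-GPCR sequences, 5-TM
#' receptors, fragments from exempt and non-exempt taxa, same-species
#' near-duplicates), with cross-consistent sequences, topology labels, hit
#' rows and a truth table sufficient to score curation and classification
#' end to end. All randomness is derived from `spec$seed`; the caller's RNG
#' state is preserved.
#'
#' @param spec A `cfrc_synthetic_spec`.
#' @param library A `cfrc_motif_library`.
#' @return A list of class `cfrc_benchmark`: `seqs`, `topologies`, `hits`,
#'   `truth` (data frame: id, class, subclade, species, taxon_group,
#'   evalue, is_fragment, expected_retained, expected_stage, anchor_global,
#'   tm starts/ends as comma strings).
#' @export
generate_benchmark <- function(spec = synthetic_spec(),
                               library = default_motif_library()) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(spec$seed)

  subs <- library_subclades(library)
  seq_rows <- list(); hit_rows <- list(); truth_rows <- list()
  topo <- character(0)
  counter <- 0L
  nid <- function() { counter <<- counter + 1L; sprintf("rec%04d", counter) }
  ethr <- 1e-10  # default curation threshold, used for expected outcomes

  receptors <- list()
  for (s in subs) for (k in seq_len(spec$n_per_subclade)) {
    r <- generate_receptor(s, spec, library, id = nid())
    receptors[[r$seq$id]] <- r
    seq_rows[[length(seq_rows) + 1]] <- r$seq
    hit_rows[[length(hit_rows) + 1]] <- r$hit
    topo <- c(topo, r$labels)
    truth_rows[[length(truth_rows) + 1]] <- data.frame(
      id = r$seq$id, class = "receptor", subclade = s,
      species = r$seq$species, taxon_group = r$seq$taxon_group,
      evalue = r$hit$evalue, is_fragment = FALSE,
      expected_retained = r$hit$evalue < ethr,
      expected_stage = if (r$hit$evalue < ethr) "retained" else "evalue",
      anchor_global = r$truth$anchor_global,
      tm_starts = paste(r$truth$tms[, "start"], collapse = ","),
      tm_ends = paste(r$truth$tms[, "end"], collapse = ","),
      stringsAsFactors = FALSE)
  }
  n_rec <- length(receptors)
  ndec <- function(cls) round(spec$decoy_fractions[[cls]] * n_rec)
  pass_ev <- function() exp(stats::runif(1, log(spec$evalue_range[1]),
                                         log(min(ethr * 0.99, spec$evalue_range[2]))))

  add <- function(seqrow, labels, hitrow, truthrow) {
    seq_rows[[length(seq_rows) + 1]] <<- seqrow
    hit_rows[[length(hit_rows) + 1]] <<- hitrow
    topo <<- c(topo, labels)
    truth_rows[[length(truth_rows) + 1]] <<- truthrow
  }
  decoy_truth <- function(id, cls, sp, taxon, ev, frag, retained, stage)
    data.frame(id = id, class = cls, subclade = "none", species = sp,
               taxon_group = taxon, evalue = ev, is_fragment = frag,
               expected_retained = retained, expected_stage = stage,
               anchor_global = NA_integer_, tm_starts = "", tm_ends = "",
               stringsAsFactors = FALSE)

  for (k in seq_len(ndec("non_gpcr"))) {
    id <- nid()
    s <- rand_str(280L, LOOP_ALPHABET)
    ev <- pass_ev()
    add(protein_sequences(id, s, species = "sp_carid1", taxon_group = "Caridea"),
        stats::setNames(strrep("O", nchar(s)), id),
        candidate_hits("BNGR-A24", id, species = "sp_carid1",
                       taxon_group = "Caridea", evalue = ev,
                       aln_length = nchar(s), has_7tm1 = FALSE),
        decoy_truth(id, "non_gpcr", "sp_carid1", "Caridea", ev, FALSE,
                    FALSE, "domain"))
  }
  for (k in seq_len(ndec("few_tm"))) {
    id <- nid()
    parts <- character(0); side <- character(0)
    parts <- c(parts, rand_str(15L, LOOP_ALPHABET)); side <- c(side, "O")
    for (i in 1:5) {
      parts <- c(parts, rand_str(21L, TM_ALPHABET)); side <- c(side, "M")
      inner <- if (i %% 2 == 1) "I" else "O"
      parts <- c(parts, rand_str(10L, LOOP_ALPHABET)); side <- c(side, inner)
    }
    s <- paste(parts, collapse = "")
    labels <- paste(rep(side, times = nchar(parts)), collapse = "")
    ev <- pass_ev()
    add(protein_sequences(id, s, species = "sp_astac1", taxon_group = "Astacidea"),
        stats::setNames(labels, id),
        candidate_hits("BNGR-A34", id, species = "sp_astac1",
                       taxon_group = "Astacidea", evalue = ev,
                       aln_length = nchar(s), has_7tm1 = TRUE),
        decoy_truth(id, "few_tm", "sp_astac1", "Astacidea", ev, FALSE,
                    FALSE, "tm_count"))
  }
  nfrag <- ndec("fragment")
  for (k in seq_len(nfrag)) {
    id <- nid()
    exempt <- k %% 2 == 1  # alternate exempt/non-exempt taxa
    taxon <- if (exempt) "Brachyura" else "Caridea"
    sp <- paste0("sp_frag", k)  # own species so dedupe is not involved
    base <- generate_receptor(subs[1 + (k - 1) %% length(subs)], spec,
                              library, id = id)
    cut <- base$truth$tms[3, "end"]  # keep the first three TM blocks
    s <- substr(base$seq$residues, 1, cut)
    labels <- substr(base$labels, 1, cut)
    ev <- pass_ev()
    add(protein_sequences(id, s, species = sp, taxon_group = taxon,
                          is_fragment = TRUE),
        stats::setNames(labels, id),
        candidate_hits("BNGR-A24", id, species = sp, taxon_group = taxon,
                       evalue = ev, aln_length = nchar(s), has_7tm1 = NA),
        decoy_truth(id, "fragment", sp, taxon, ev, TRUE,
                    exempt, if (exempt) "retained" else "domain"))
  }
  ## same-species near-duplicates of receptors that pass the e-value screen
  passing <- names(receptors)[vapply(receptors, function(r)
    r$hit$evalue < ethr, logical(1))]
  for (k in seq_len(ndec("wrong_species_dup"))) {
    if (length(passing) == 0) break
    base_id <- passing[1 + (k - 1) %% length(passing)]
    base <- receptors[[base_id]]
    id <- nid()
    trim <- nchar(base$seq$residues) - 5L
    s <- mutate_residues(substr(base$seq$residues, 1, trim), 0.02)
    ev <- pass_ev()
    add(protein_sequences(id, s, species = base$seq$species,
                          taxon_group = base$seq$taxon_group),
        stats::setNames(substr(base$labels, 1, trim), id),
        candidate_hits(base$hit$query_id, id, species = base$seq$species,
                       taxon_group = base$seq$taxon_group, evalue = ev,
                       aln_length = nchar(s), has_7tm1 = TRUE,
                       n_tm_predicted = 7L),
        decoy_truth(id, "wrong_species_dup", base$seq$species,
                    base$seq$taxon_group, ev, FALSE, FALSE, "redundancy"))
  }

  seqs <- do.call(rbind, seq_rows)
  class(seqs) <- c("cfrc_seqs", "data.frame")
  hits <- do.call(rbind, hit_rows)
  class(hits) <- c("cfrc_hits", "data.frame")
  structure(list(seqs = seqs, topologies = topo, hits = hits,
                 truth = do.call(rbind, truth_rows), spec = spec),
            class = "cfrc_benchmark")
}

#' Write a benchmark bundle to disk
#'
#' Emits the four cross-consistent files: `benchmark.fasta`,
#' `topology.txt`, `hits.tsv` (12 standard columns plus the four metadata
#' columns) and `truth.tsv`.
#'
#' @param bundle A `cfrc_benchmark`.
#' @param outdir Output directory (created if missing).
#' @return Invisibly, the four file paths.
#' @export
write_benchmark <- function(bundle, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(outdir, c("benchmark.fasta", "topology.txt", "hits.tsv",
                               "truth.tsv"))
  write_fasta(bundle$seqs, paths[1])
  writeLines(paste0(">", names(bundle$topologies), "\n", bundle$topologies),
             paths[2])
  h <- bundle$hits
  lines <- sprintf("%s\t%s\t100.00\t%d\t0\t0\t1\t%d\t1\t%d\t%s\t%.1f\t%s\t%s\t%s\t%s",
                   h$query_id, h$subject_id, h$aln_length, h$aln_length,
                   h$aln_length, sprintf("%.6e", h$evalue), 200,
                   ifelse(is.na(h$species), "NA", h$species),
                   ifelse(is.na(h$taxon_group), "NA", h$taxon_group),
                   ifelse(is.na(h$has_7tm1), "NA", as.integer(h$has_7tm1)),
                   ifelse(is.na(h$n_tm_predicted), "NA", h$n_tm_predicted))
  writeLines(lines, paths[3])
  utils::write.table(bundle$truth, paths[4], sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(paths)
}
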