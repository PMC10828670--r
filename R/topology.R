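## Seven-transmembrane topology: hydropathy fallback, TM segmentation and
## region naming. Orientation is fixed to the Class A convention: N-terminus
## extracellular, C-terminus cytosolic.

## Kyte-Doolittle hydropathy scale; the ambiguity code X is treated as
## neutral (0).
KD_SCALE <- c(
  A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
  L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2,
  X =  0.0
)

REGION_ORDER <- c("N_term", "TMM1", "ICL1", "TMM2", "ECL1", "TMM3", "ICL2",
                  "TMM4", "ECL2", "TMM5", "ICL3", "TMM6", "ECL3", "TMM7",
                  "C_term")

#' Hydropathy segmentation parameters
#'
#' @param window Odd sliding-window width (residues); default 19, the
#'   conventional width for transmembrane-helix detection.
#' @param tm_threshold Mean windowed hydropathy above which a position is
#'   considered membrane-embedded; default 1.6.
#' @param min_tm_len,max_tm_len Bounds on emitted TM interval lengths
#'   (defaults 17 and 25 residues).
#' @return A list of class `cfrc_hydropathy_config`.
#' @export
hydropathy_config <- function(window = 19, tm_threshold = 1.6,
                              min_tm_len = 17, max_tm_len = 25) {
  stopifnot(window >= 5, window %% 2 == 1, min_tm_len <= max_tm_len,
            min_tm_len >= 1)
  structure(list(window = window, tm_threshold = tm_threshold,
                 min_tm_len = min_tm_len, max_tm_len = max_tm_len),
            class = "cfrc_hydropathy_config")
}

#' Per-residue sliding-window hydropathy profile
#'
#' Centered moving average of the Kyte-Doolittle scale; windows are
#' truncated at the sequence ends.
#'
#' @param seq Protein sequence string (length >= `window`).
#' @param window Odd window width.
#' @return Numeric vector, one value per residue.
#' @export
hydropathy_profile <- function(seq, window = 19) {
  stopifnot(window >= 1, window %% 2 == 1)
  chars <- strsplit(toupper(seq), "")[[1]]
  if (length(chars) < window)
    cfrc_error(sprintf("sequence length %d shorter than window %d",
                       length(chars), window), "cfrc_format_error")
  vals <- KD_SCALE[chars]
  if (anyNA(vals))
    cfrc_error("sequence contains residues outside the amino-acid alphabet",
               "cfrc_format_error")
  h <- (window - 1) / 2
  cs <- cumsum(c(0, unname(vals)))
  L <- length(vals)
  lo <- pmax(1, seq_len(L) - h)
  hi <- pmin(L, seq_len(L) + h)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' Segment transmembrane intervals from a hydropathy profile
#'
#' Maximal runs of positions at or above the threshold are the candidate
#' helices. Adjacent runs separated by fewer than 3 residues are merged
#' before length rules. Window smoothing erodes the flanks of genuine
#' helices, so runs shorter than `min_tm_len` (but at least 5 positions) are
#' extended symmetrically to `min_tm_len`; shorter runs are discarded as
#' noise. Runs longer than `max_tm_len` are split at their minimum-profile
#' position and the pieces re-examined.
#'
#' @param profile Numeric hydropathy profile (from [hydropathy_profile()]).
#' @param config A `cfrc_hydropathy_config`.
#' @return Integer matrix with columns `start`, `end`; zero rows when no TM
#'   is found. Intervals are disjoint and sorted.
#' @export
segment_tm <- function(profile, config = hydropathy_config()) {
  stopifnot(length(profile) > 0)
  L <- length(profile)
  above <- profile >= config$tm_threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- cbind(start = starts[r$values], end = ends[r$values])
  if (nrow(runs) == 0)
    return(matrix(integer(), ncol = 2, dimnames = list(NULL, c("start", "end"))))

  ## merge runs separated by < 3 residues
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) for (i in 2:nrow(runs)) {
    if (runs[i, "start"] - merged[nrow(merged), "end"] - 1 < 3)
      merged[nrow(merged), "end"] <- runs[i, "end"]
    else merged <- rbind(merged, runs[i, , drop = FALSE])
  }

  ## length rules: drop noise, extend short runs, split long runs
  out <- list()
  queue <- lapply(seq_len(nrow(merged)),
                  function(i) c(merged[[i, "start"]], merged[[i, "end"]]))
  while (length(queue) > 0) {
    iv <- queue[[1]]; queue <- queue[-1]
    s <- iv[1]; e <- iv[2]
    len <- e - s + 1
    if (len < 5) next
    if (len > config$max_tm_len) {
      ## split at the minimum-profile position, restricted to the central
      ## stretch that leaves room for a helix on both sides (a plateau's
      ## minimum is taken at its middle)
      lo2 <- s + config$min_tm_len - 1L
      hi2 <- e - config$min_tm_len + 1L
      if (hi2 < lo2) { lo2 <- s + 1L; hi2 <- e - 1L }
      cand <- lo2:hi2
      plateau <- cand[profile[cand] <= min(profile[cand]) + 1e-9]
      m <- plateau[ceiling(length(plateau) / 2)]
      queue <- c(list(c(s, m - 1), c(m + 1, e)), queue)
      next
    }
    ## emit an interval of clamped length centered on the run's upper-half
    ## mass centroid (profile mass above halfway between threshold and run
    ## maximum). The smoothed profile is near its maximum only where the
    ## window lies inside the helix, so this center estimate resists
    ## one-sided shoulders from partly hydrophobic loop content.
    ## short runs (smoothing erodes helix flanks) are extended to the
    ## central target length; in-range runs keep their own length
    target <- (config$min_tm_len + config$max_tm_len) %/% 2
    len_eff <- if (len < config$min_tm_len) target
               else min(len, config$max_tm_len)
    seg <- profile[s:e]
    w <- pmax(seg - (config$tm_threshold +
                     0.5 * (max(seg) - config$tm_threshold)), 0)
    center <- if (sum(w) > 0) sum(w * (s:e)) / sum(w) else (s + e) / 2
    s <- round(center) - floor((len_eff - 1) / 2)
    e <- s + len_eff - 1L
    if (s < 1) { e <- e + (1 - s); s <- 1L }
    if (e > L) { s <- max(1L, s - (e - L)); e <- L }
    out[[length(out) + 1]] <- c(s, e)
  }
  if (length(out) == 0)
    return(matrix(integer(), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  tms <- do.call(rbind, out)
  colnames(tms) <- c("start", "end")
  tms <- tms[order(tms[, "start"]), , drop = FALSE]
  ## extension may touch a neighbour; trim overlaps
  if (nrow(tms) > 1) for (i in 2:nrow(tms)) {
    if (tms[i, "start"] <= tms[i - 1, "end"])
      tms[i, "start"] <- tms[i - 1, "end"] + 1
  }
  storage.mode(tms) <- "integer"
  tms
}

## Build the region table from 7 TM intervals, assuming N-out orientation.
regions_from_tms <- function(tms, seq_len) {
  n <- nrow(tms)
  if (n != 7)
    cfrc_error(sprintf("not a 7TM architecture: %d transmembrane segments", n),
               "cfrc_not7tm", count = n)
  loops <- c("ICL1", "ECL1", "ICL2", "ECL2", "ICL3", "ECL3")
  region <- character(0); start <- integer(0); end <- integer(0)
  push <- function(nm, s, e) {
    region <<- c(region, nm); start <<- c(start, as.integer(s)); end <<- c(end, as.integer(e))
  }
  push("N_term", 1L, tms[1, "start"] - 1L)
  for (i in 1:7) {
    push(paste0("TMM", i), tms[i, "start"], tms[i, "end"])
    if (i < 7) push(loops[i], tms[i, "end"] + 1L, tms[i + 1, "start"] - 1L)
  }
  push("C_term", tms[7, "end"] + 1L, seq_len)
  out <- data.frame(region = region, start = start, end = end,
                    stringsAsFactors = FALSE)
  attr(out, "seq_len") <- as.integer(seq_len)
  attr(out, "orientation") <- "N_out"
  class(out) <- c("cfrc_regions", "data.frame")
  out
}

#' Assign the seven-transmembrane region partition
#'
#' Partitions a receptor sequence into N-terminus, TMM1-TMM7, the three
#' intracellular and three extracellular loops, and C-terminus, in the fixed
#' Class A order with an extracellular N-terminus. Input is either a set of
#' 7 TM intervals (e.g. from [segment_tm()]) or a per-residue O/M/I label
#' string; labels must alternate consistently (extracellular before TMM1,
#' then inside/outside in turn) or an alternation-violation error is raised,
#' and labels implying an intracellular N-terminus raise an orientation
#' error.
#'
#' @param seq Receptor sequence string.
#' @param tms Integer matrix of TM intervals (columns `start`, `end`).
#' @param labels Per-residue label string over `{O,M,I}` (alternative to
#'   `tms`); must have the same length as `seq`.
#' @return A data frame of class `cfrc_regions` with columns `region`,
#'   `start`, `end` (1-based inclusive; empty loops have `end = start - 1`),
#'   tiling the sequence exactly.
#' @export
assign_regions <- function(seq, tms = NULL, labels = NULL) {
  L <- nchar(seq)
  if (is.null(tms) == is.null(labels))
    cfrc_error("provide exactly one of 'tms' or 'labels'", "cfrc_format_error")
  if (!is.null(labels)) {
    labels <- toupper(labels)
    if (nchar(labels) != L)
      cfrc_error(sprintf("label string length %d does not match sequence length %d",
                         nchar(labels), L), "cfrc_consistency_error")
    lab <- strsplit(labels, "")[[1]]
    if (any(!lab %in% c("O", "M", "I")))
      cfrc_error("topology labels must be over {O,M,I}", "cfrc_format_error")
    r <- rle(lab)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
    mruns <- which(r$values == "M")
    if (length(mruns) != 7)
      cfrc_error(sprintf("not a 7TM architecture: %d transmembrane segments",
                         length(mruns)), "cfrc_not7tm", count = length(mruns))
    if (r$values[1] == "I")
      cfrc_error("labels imply an intracellular N-terminus (orientation violation)",
                 "cfrc_orientation_error")
    ## between consecutive M runs the side must be uniform and alternate I/O,
    ## starting intracellular after TMM1; termini must sit on the right side
    expected <- rep(c("I", "O"), length.out = 6)
    for (k in seq_len(7)) {
      lo <- mruns[k] + 1
      hi <- if (k < 7) mruns[k + 1] - 1 else length(r$values)
      seg <- if (lo <= hi) r$values[lo:hi] else character()
      want <- if (k < 7) expected[k] else "I"
      if (length(seg) > 1 || (length(seg) == 1 && seg != want))
        cfrc_error(sprintf(
          "topology labels violate I/O alternation after transmembrane segment %d", k),
          "cfrc_alternation_error")
    }
    if (mruns[1] > 1 && any(r$values[seq_len(mruns[1] - 1)] != "O"))
      cfrc_error("labels before the first transmembrane segment must be extracellular",
                 "cfrc_alternation_error")
    tms <- cbind(start = starts[mruns], end = ends[mruns])
  }
  tms <- as.matrix(tms)
  if (is.null(colnames(tms))) colnames(tms) <- c("start", "end")
  regions_from_tms(tms, L)
}

#' Region lengths
#'
#' @param regions A `cfrc_regions` partition.
#' @return Named integer vector of interval widths, in region order.
#' @export
region_lengths <- function(regions) {
  stats::setNames(pmax(0L, regions$end - regions$start + 1L), regions$region)
}

#' Extract the subsequence of one region
#'
#' @param regions A `cfrc_regions` partition.
#' @param seq The full sequence the partition refers to.
#' @param name Region name (e.g. `"ECL2"`).
#' @return Character string (empty for zero-width regions).
#' @export
region_sequence <- function(regions, seq, name) {
  row <- regions[regions$region == name, ]
  if (nrow(row) != 1) cfrc_error(paste0("unknown region: ", name), "cfrc_format_error")
  if (row$end < row$start) return("")
  substr(seq, row$start, row$end)
}

## Count TM segments in a label string (used by the curation TM filter).
count_tm_from_labels <- function(labels) {
  lab <- strsplit(toupper(labels), "")[[1]]
  r <- rle(lab)
  sum(r$values == "M")
}
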