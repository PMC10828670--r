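# In-code fixtures shared across tests.

# Deterministic 7-TM receptor with controllable loop content. Plain loops
# are serine/glutamine runs; TM blocks are leucine runs (strongly
# hydrophobic). Returns the sequence, matching O/M/I labels, and the exact
# region table.
make_receptor <- function(ecl2 = strrep("S", 12), ecl3 = strrep("S", 10),
                          n_term = strrep("Q", 15), c_term = strrep("Q", 15),
                          tm = replicate(7, strrep("L", 21)),
                          icl1 = strrep("S", 10), ecl1 = strrep("S", 10),
                          icl2 = strrep("S", 10), icl3 = strrep("S", 12)) {
  parts <- c(N_term = n_term, TMM1 = tm[1], ICL1 = icl1, TMM2 = tm[2],
             ECL1 = ecl1, TMM3 = tm[3], ICL2 = icl2, TMM4 = tm[4],
             ECL2 = ecl2, TMM5 = tm[5], ICL3 = icl3, TMM6 = tm[6],
             ECL3 = ecl3, TMM7 = tm[7], C_term = c_term)
  side <- c("O", "M", "I", "M", "O", "M", "I", "M", "O", "M", "I", "M", "O",
            "M", "I")
  seq <- paste(parts, collapse = "")
  labels <- paste(rep(side, times = nchar(parts)), collapse = "")
  regions <- assign_regions(seq, labels = labels)
  list(seq = seq, labels = labels, regions = regions, parts = parts)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}
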