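# Shared fixtures, built in code.

# Two-gene toy table exercising all three curation rules by hand:
# gene A: 3 benign (af 0.02), 2 pathogenic (af 0.001), 1 conflicting;
# gene B: 1 likely_pathogenic (af 0.001), 3 VUS.
toy_raw_table <- function() {
  data.frame(
    gene = c(rep("A", 6), rep("B", 4)),
    protein_id = c(rep("PA", 6), rep("PB", 4)),
    position = 1:10,
    wt_aa = c("R", "G", "A", "L", "S", "C", "W", "K", "D", "F"),
    mut_aa = c("H", "D", "V", "P", "T", "Y", "R", "E", "N", "L"),
    clin_sig = c("benign", "benign", "benign", "pathogenic", "pathogenic",
                 "conflicting", "likely_pathogenic", "vus", "vus", "vus"),
    allele_freq = c(0.02, 0.02, 0.02, 0.001, 0.001, 0.5,
                    0.001, 0.1, 0.1, 0.1),
    stringsAsFactors = FALSE)
}

# Fast CV protocol for tests; the statistical protocol is unchanged, only
# the grid and repeat counts are scaled down.
quick_protocol <- function(seed = 1, repeats = 2,
                           c_grid = c(0.01, 1, 100)) {
  split_protocol(repeats = repeats, c_grid = c_grid, seed = seed)
}

# Independent brute-force oracle for the MCC-optimal threshold: with the
# pathogenic_if_le rule every achievable confusion table corresponds to a
# threshold at one of the observed scores or below all of them.
brute_force_best_mcc <- function(scores, labels) {
  cands <- c(min(scores) - 1, sort(unique(scores)))
  max(vapply(cands, function(t) {
    mcc(confusion_counts(scores, labels, t, "pathogenic_if_le"))
  }, numeric(1)))
}
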