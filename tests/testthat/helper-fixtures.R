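# Shared fixtures and independent oracles. Everything is generated in code
# under fixed seeds; no data files.

# Element specs at the scales of the four reference elements.
spec_op1 <- function() element_spec(169, 245, 3468, 1608,
                                    triad = triad_spec(892, 1056, "E", 40))
spec_ce1 <- function() element_spec(26, 246, 1032, 240,
                                    triad = triad_spec(100, 220, "E", 34))
# a mid-sized element used for planted-genome round trips
spec_mid <- function() element_spec(40, 120, 1032, 150,
                                    triad = triad_spec(100, 220, "E", 40))

random_nt <- function(n, seed) {
  set.seed(seed)
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

random_aa <- function(n, seed, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  set.seed(seed)
  paste0(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Brute-force longest-terminal-inverted-repeat oracle (naive scan over all
# admissible lengths; independent of the cumulative-identity implementation).
brute_tir_len <- function(region, min_len, max_len, min_id) {
  n <- nchar(region)
  best <- NULL
  for (l in min_len:min(max_len, n %/% 2)) {
    pre <- substr(region, 1, l)
    suf <- substr(region, n - l + 1, n)
    if (min_id >= 1 && (grepl("N", pre) || grepl("N", suf))) next
    rcs <- revcomp(suf)
    id <- mean(strsplit(pre, "")[[1]] == strsplit(rcs, "")[[1]])
    if (id >= min_id) best <- l
  }
  best
}

# Brute-force triple-loop triad oracle (positions only, unsorted).
brute_triads <- function(protein, spacing_set, last_residues = c("D", "E"),
                         d1_d2_range = c(50, 250)) {
  ch <- strsplit(protein, "")[[1]]
  dpos <- which(ch == "D")
  lpos <- which(ch %in% last_residues)
  out <- list()
  for (d1 in dpos) for (d2 in dpos) for (la in lpos) {
    if (!(d1 < d2 && d2 < la)) next
    if (!((la - d2 - 1) %in% spacing_set)) next
    gap <- d2 - d1 - 1
    if (gap < d1_d2_range[1] || gap > d1_d2_range[2]) next
    out[[length(out) + 1]] <- c(d1, d2, la)
  }
  out
}

# Aligned pair realizing exact (identical, positive, columns) counts under
# BLOSUM62: A/A identical, D/E positive non-identical, G/W negative.
aligned_pair_with_counts <- function(n_identical, n_positive, n_cols) {
  stopifnot(n_identical <= n_positive, n_positive <= n_cols)
  a <- c(rep("A", n_identical), rep("D", n_positive - n_identical),
         rep("G", n_cols - n_positive))
  b <- c(rep("A", n_identical), rep("E", n_positive - n_identical),
         rep("W", n_cols - n_positive))
  list(a = paste0(a, collapse = ""), b = paste0(b, collapse = ""))
}

# Default planted-genome simulation used by the recovery round trips:
# 3 full copies (copy 2 diverged by 46 SNPs + one 3-bp in-frame deletion,
# copy 3 broken by a 41-bp frameshift insertion), one 50% truncation and one
# solo TIR in a 20-kb background.
make_round_trip_sim <- function(seed) {
  set.seed(seed * 13 + 1)
  ins41 <- paste0(sample(c("A", "C", "G", "T"), 41, replace = TRUE),
                  collapse = "")
  plan <- plant_plan(n_full = 3, partial = 0.5, n_solo_tir = 1,
                     divergence = list(n_snps = 46, indel_lengths = 3),
                     frameshift_insertions = list(list(at = NULL, seq = ins41)))
  plant_elements(20000, spec_mid(), plan, rng_seed = seed)
}

copy_by_note <- function(sim, note) {
  Filter(function(cp) identical(cp$note, note), sim$detail$copies)[[1]]
}
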