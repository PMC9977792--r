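test_that("translation arithmetic matches the printed ORF/protein pairs", {
  b <- build_element(spec_op1(), rng_seed = 11)
  expect_identical(nchar(translate_orf(b$segments$orf)), 1155L)   # 3468 bp
  b2 <- build_element(spec_ce1(), rng_seed = 12)
  expect_identical(nchar(translate_orf(b2$segments$orf)), 343L)   # 1032 bp
  expect_identical(translate_orf("ATGTAA"), "M")
  expect_error(translate_orf("ATGAA"), class = "tc1scout_validation_error")
  expect_error(translate_orf("ATGTAAGGGTAA"),
               class = "tc1scout_validation_error")   # internal stop
  expect_error(translate_orf("ATGGGGGGG"),
               class = "tc1scout_validation_error")   # no terminal stop
})

test_that("find_orfs reports maximal ORFs with deterministic ordering", {
  b <- build_element(spec_op1(), rng_seed = 13)
  top <- find_orfs(b$seq, min_aa = 100)[[1]]
  expect_identical(top$length_nt, 3468L)
  expect_identical(top$length_aa, 1155L)
  expect_identical(top$start_codon, "ATG")
  expect_identical(top$protein, b$protein)
  expect_identical(top$interval$start, b$orf_start)

  # alternative TGG start 48 bp upstream in frame extends the call by 16 aa
  s <- b$seq
  up <- b$orf_start - 48L
  filler <- paste0(rep("GCT", 15), collapse = "")
  substr(s, up, b$orf_start - 1L) <- paste0("TGG", filler)
  substr(s, up - 3L, up - 1L) <- "TAA"        # guard stop above the TGG
  with_tgg <- find_orfs(s, min_aa = 100, start_codons = c("ATG", "TGG"))[[1]]
  expect_identical(with_tgg$length_nt, 3516L)
  expect_identical(with_tgg$start_codon, "TGG")
  atg_only <- find_orfs(s, min_aa = 100)[[1]]
  expect_identical(atg_only$length_nt, 3468L)

  one <- find_orfs("ATGTAA", min_aa = 1, strands = "+")
  expect_length(one, 1)
  expect_identical(one[[1]]$protein, "M")
})

test_that("minus-strand ORFs are found with plus-strand coordinates", {
  b <- build_element(spec_ce1(), rng_seed = 14)
  g <- paste0(random_nt(500, 1), revcomp(b$seq), random_nt(500, 2))
  hits <- find_orfs(g, min_aa = 300)
  top <- hits[[1]]
  expect_identical(top$interval$strand, "-")
  expect_identical(top$length_nt, 1032L)
  expect_identical(top$protein, b$protein)
  # maps to the reverse complement slice
  expect_identical(revcomp(substr(g, top$interval$start, top$interval$end)),
                   b$segments$orf)
})

test_that("length_aa invariant holds for every call", {
  g <- random_nt(6000, 33)
  for (o in find_orfs(g, min_aa = 10))
    expect_identical(o$length_aa, o$length_nt %/% 3L - 1L)
})

test_that("a planted 41-bp insertion is removed exactly under guidance", {
  sim <- make_round_trip_sim(21)
  c3 <- copy_by_note(sim, "full_frameshift")
  region <- extract_interval(sim$genome, c3$orf_interval)
  rr <- repair_frameshifts(region, max_insert_len = 50,
                           reference_protein = sim$detail$element$protein,
                           min_identity = 1)
  expect_true(rr$success)
  expect_identical(rr$total_removed, 41L)
  expect_length(rr$removed_segments, 1)
  expect_identical(rr$repaired_orf$protein, sim$detail$element$protein)
  # the repaired region equals the pre-insertion ORF segment
  expect_identical(rr$repaired_seq, sim$detail$element$segments$orf)
})

test_that("two single-A insertions are removed as two segments", {
  sim <- plant_elements(8000, spec_mid(),
                        plant_plan(n_full = 1, frameshift_insertions =
                          list(list(at = 301, seq = "A"),
                               list(at = 316, seq = "A"))),
                        rng_seed = 22)
  c1 <- sim$detail$copies[[1]]
  region <- extract_interval(sim$genome, c1$orf_interval)
  rr <- repair_frameshifts(region, max_insert_len = 50,
                           reference_protein = sim$detail$element$protein,
                           min_identity = 1)
  expect_true(rr$success)
  expect_identical(rr$total_removed, 2L)
  expect_length(rr$removed_segments, 2)
  expect_identical(rr$repaired_orf$protein, sim$detail$element$protein)
})

test_that("repair is a no-op on intact regions and idempotent", {
  b <- build_element(spec_mid(), rng_seed = 23)
  r0 <- repair_frameshifts(b$segments$orf)
  expect_true(r0$success)
  expect_identical(r0$total_removed, 0L)
  expect_length(r0$removed_segments, 0)

  sim <- make_round_trip_sim(24)
  c3 <- copy_by_note(sim, "full_frameshift")
  rr <- repair_frameshifts(extract_interval(sim$genome, c3$orf_interval), 50,
                           reference_protein = sim$detail$element$protein,
                           min_identity = 1)
  again <- repair_frameshifts(rr$repaired_seq)
  expect_true(again$success)
  expect_identical(again$total_removed, 0L)
})

test_that("an impossible repair is a failure signal, not an exception", {
  sim <- make_round_trip_sim(25)
  c3 <- copy_by_note(sim, "full_frameshift")
  region <- extract_interval(sim$genome, c3$orf_interval)
  rr <- repair_frameshifts(region, max_insert_len = 20,
                           reference_protein = sim$detail$element$protein,
                           min_identity = 1)
  expect_false(rr$success)
  expect_type(rr$message, "character")
})

test_that("guided repair recovers planted insertion sets across seeds", {
  for (seed in 1:6) {
    set.seed(seed + 400)
    k <- sample(c(1, 2, 5, 10, 20, 41), 1)
    ins <- paste0(sample(c("A", "C", "G", "T"), k, replace = TRUE),
                  collapse = "")
    sim <- plant_elements(8000, spec_mid(),
                          plant_plan(n_full = 1, frameshift_insertions =
                            list(list(at = NULL, seq = ins))),
                          rng_seed = seed + 500)
    c1 <- sim$detail$copies[[1]]
    region <- extract_interval(sim$genome, c1$orf_interval)
    rr <- repair_frameshifts(region, max_insert_len = 50,
                             reference_protein = sim$detail$element$protein,
                             min_identity = 1)
    if (k %% 3 == 0) {
      # an in-frame insertion never breaks the ORF: nothing to repair unless
      # it happens to introduce a stop codon
      expect_true(rr$success)
    } else {
      expect_true(rr$success)
      expect_identical(rr$total_removed, as.integer(k))
      expect_identical(rr$repaired_orf$protein, sim$detail$element$protein)
    }
  }
})
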