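test_that("planted full copies are found full-length at truth coordinates", {
  sim <- plant_elements(15000, spec_mid(), plant_plan(n_full = 2), rng_seed = 71)
  hits <- find_copies(sim$genome, sim$detail$element$seq)
  full <- Filter(function(h) h$full_length, hits)
  expect_length(full, 2)
  tru <- sim$truth[sim$truth$type == "full", ]
  expect_identical(sort(vapply(full, function(h) h$interval$start, 1L)),
                   sort(tru$start))
  expect_identical(sort(vapply(full, function(h) h$interval$end, 1L)),
                   sort(tru$end))
  expect_true(all(vapply(full, function(h) h$identity, 1) == 1))
})

test_that("truncated copies report fractional coverage, not full length", {
  sim <- plant_elements(25000, spec_mid(),
                        plant_plan(n_full = 3, partial = 0.5), rng_seed = 72)
  hits <- find_copies(sim$genome, sim$detail$element$seq)
  expect_identical(sum(vapply(hits, function(h) h$full_length, TRUE)), 3L)
  part <- Filter(function(h) !h$full_length, hits)
  expect_length(part, 1)
  expect_lt(abs(part[[1]]$coverage - 0.5), 0.02)
})

test_that("the >90% full-length rule is strict at the boundary", {
  ref <- random_nt(1000, 81)
  piece <- substr(ref, 1, 900)                     # exactly 90.0% coverage
  g <- genome_sequence("g", paste0(random_nt(2000, 82), piece,
                                   random_nt(2000, 83)))
  hits <- find_copies(g, ref)
  expect_length(hits, 1)
  expect_equal(hits[[1]]$coverage, 0.9, tolerance = 1e-12)
  expect_false(hits[[1]]$full_length)
  # one base more crosses the strict threshold
  g2 <- genome_sequence("g2", paste0(random_nt(2000, 84), substr(ref, 1, 901),
                                     random_nt(2000, 85)))
  expect_true(find_copies(g2, ref)[[1]]$full_length)
})

test_that("the reference finds itself with perfect coverage and identity", {
  ref <- build_element(spec_mid(), rng_seed = 73)$seq
  g <- genome_sequence("self", ref)
  hits <- find_copies(g, ref)
  expect_length(hits, 1)
  expect_identical(hits[[1]]$coverage, 1)
  expect_identical(hits[[1]]$identity, 1)
  expect_true(hits[[1]]$full_length)
})

test_that("minus-strand copies are located", {
  b <- build_element(spec_mid(), rng_seed = 74)
  g <- genome_sequence("g", paste0(random_nt(3000, 86), revcomp(b$seq),
                                   random_nt(3000, 87)))
  hits <- find_copies(g, b$seq)
  full <- Filter(function(h) h$full_length, hits)
  expect_length(full, 1)
  expect_identical(full[[1]]$interval$strand, "-")
  expect_identical(full[[1]]$interval$start, 3001L)
})

test_that("solo TIRs are reported outside copy hits, on either strand", {
  sim <- plant_elements(20000, spec_mid(),
                        plant_plan(n_full = 2, n_solo_tir = 1), rng_seed = 75)
  tir <- sim$detail$element$segments$tir5
  hits <- find_copies(sim$genome, sim$detail$element$seq)
  solo <- find_solo_tirs(sim$genome, tir, exclude = hits)
  expect_length(solo, 1)
  tru <- sim$truth[sim$truth$type == "solo_tir", ]
  expect_identical(solo[[1]]$start, tru$start)
  # none planted -> empty
  sim0 <- plant_elements(12000, spec_mid(), plant_plan(n_full = 1), rng_seed = 76)
  expect_length(find_solo_tirs(sim0$genome, tir,
                               exclude = find_copies(sim0$genome,
                                                     sim$detail$element$seq)), 0)
  # minus-strand solo TIR: brute-force string search confirms
  g <- genome_sequence("g", paste0(random_nt(1000, 88), revcomp(tir),
                                   random_nt(1000, 89)))
  sm <- find_solo_tirs(g, tir)
  expect_length(sm, 1)
  expect_identical(sm[[1]]$strand, "-")
  expect_identical(sm[[1]]$start,
                   as.integer(regexpr(revcomp(tir), g$seq, fixed = TRUE)))
})

test_that("copy comparison recovers planted SNP and indel counts exactly", {
  sim <- make_round_trip_sim(77)
  g <- sim$genome
  c1 <- copy_by_note(sim, "full")
  c2 <- copy_by_note(sim, "full_diverged")
  cd <- compare_copies(extract_interval(g, c1$interval),
                       extract_interval(g, c2$interval),
                       orf = interval("e", sim$detail$element$orf_start,
                                      sim$detail$element$orf_end))
  expect_identical(cd$n_snps, 46L)
  expect_identical(nrow(cd$indels), 1L)
  expect_identical(cd$indels$type, "del")
  expect_identical(cd$indels$length, 3L)
  expect_identical(cd$aa_consequence, "deletion of 1 aa (M)")
})

test_that("identical copies compare clean and comparison is symmetric", {
  a <- build_element(spec_mid(), rng_seed = 78)$seq
  cd0 <- compare_copies(a, a)
  expect_identical(cd0$n_snps, 0L)
  expect_identical(nrow(cd0$indels), 0L)

  sim <- make_round_trip_sim(79)
  s1 <- extract_interval(sim$genome, copy_by_note(sim, "full")$interval)
  s2 <- extract_interval(sim$genome, copy_by_note(sim, "full_diverged")$interval)
  ab <- compare_copies(s1, s2)
  ba <- compare_copies(s2, s1)
  expect_identical(ab$n_snps, ba$n_snps)
  expect_identical(sort(ab$indels$length), sort(ba$indels$length))
  swap <- c(del = "ins", ins = "del")
  expect_identical(sort(unname(swap[ab$indels$type])), sort(ba$indels$type))
})
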