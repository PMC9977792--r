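test_that("detect_tirs equals the brute-force oracle on regions <= 2 kb", {
  for (i in 1:20) {
    tl <- sample(10:80, 1)
    tir <- random_nt(tl, seed = 3000 + i)
    core <- random_nt(sample(100:1800, 1), seed = 3100 + i)
    reg <- paste0(tir, core, revcomp(tir))
    got <- detect_tirs(reg, 10, 100, 1.0)
    exp <- brute_tir_len(reg, 10, 100, 1.0)
    expect_identical(got$length, as.integer(exp))
    expect_identical(interval_length(got$tir5), got$length)
    expect_identical(interval_length(got$tir3), got$length)
  }
})

test_that("detect_tirs recovers planted 169-bp TIRs and reports absence", {
  b <- build_element(spec_op1(), rng_seed = 31)
  tp <- detect_tirs(b$seq)
  expect_identical(tp$length, 169L)
  expect_identical(tp$identity, 1)
  # plain random sequence: agree with the oracle (usually absent)
  for (i in 1:10) {
    reg <- random_nt(400, seed = 3200 + i)
    got <- detect_tirs(reg, 10, 150, 1.0)
    exp <- brute_tir_len(reg, 10, 150, 1.0)
    if (is.null(exp)) expect_null(got) else expect_identical(got$length, as.integer(exp))
  }
  # short palindromic anchor
  reg4 <- paste0("CAGT", random_nt(100, seed = 3301), "ACTG")
  expect_identical(detect_tirs(reg4, 4, 10, 1.0)$length,
                   as.integer(brute_tir_len(reg4, 4, 10, 1.0)))
  expect_error(detect_tirs("ACGTACGT", 5, 10), class = "tc1scout_validation_error")
})

test_that("degenerate TIRs pass at relaxed identity but not exact", {
  tir <- random_nt(40, seed = 3400)
  tir_mut <- tir
  substr(tir_mut, 20, 20) <- if (substr(tir, 20, 20) == "A") "C" else "A"
  reg <- paste0(tir, random_nt(300, seed = 3401), revcomp(tir_mut))
  exact <- detect_tirs(reg, 30, 60, 1.0)
  if (!is.null(exact)) expect_lt(exact$length, 40L)
  relaxed <- detect_tirs(reg, 30, 60, 0.95)
  expect_identical(relaxed$length,
                   as.integer(brute_tir_len(reg, 30, 60, 0.95)))
  expect_gte(relaxed$length, 40L)
  expect_lt(relaxed$identity, 1)
})

test_that("excision sites reproduce both printed boundary patterns", {
  # Tc1 pattern: TACA| ... |TGTA
  g1 <- genome_sequence("g1", paste0("GGGTA", "CA", random_nt(50, 1), "TG", "TAGGG"))
  iv1 <- interval("g1", 6, 6 + 54 - 1)
  ex1 <- check_excision_sites(g1, iv1, "TA")
  expect_true(ex1$excision_ok)
  expect_identical(ex1$flank5_4mer, "TACA")
  expect_identical(ex1$flank3_4mer, "TGTA")
  # IS630 pattern: TA|TA ... TA|TA
  g2 <- genome_sequence("g2", paste0("GGGTA", "TA", random_nt(50, 2), "TA", "TAGGG"))
  iv2 <- interval("g2", 6, 6 + 54 - 1)
  ex2 <- check_excision_sites(g2, iv2, "TA")
  expect_true(ex2$excision_ok)
  expect_identical(ex2$flank5_4mer, "TATA")
  expect_identical(ex2$flank3_4mer, "TATA")
  # broken symmetry
  g3 <- genome_sequence("g3", paste0("GGGTA", "CA", random_nt(50, 3), "AA", "AAGGG"))
  iv3 <- interval("g3", 6, 6 + 54 - 1)
  expect_false(check_excision_sites(g3, iv3, "TA")$excision_ok)
  # element at the sequence edge -> insufficient-flank signal
  g4 <- genome_sequence("g4", "ACGTACGTAC")
  expect_error(check_excision_sites(g4, interval("g4", 1, 6)),
               class = "tc1scout_flank_error")
})

test_that("annotate_layout derives the five segments by subtraction", {
  sim <- plant_elements(12000, spec_mid(), plant_plan(n_full = 1), rng_seed = 32)
  cp <- sim$detail$copies[[1]]
  region <- extract_interval(sim$genome, cp$interval)
  tir <- detect_tirs(region)
  tir$tir5 <- interval(sim$genome$id, cp$interval$start,
                       cp$interval$start + tir$length - 1L)
  tir$tir3 <- interval(sim$genome$id, cp$interval$end - tir$length + 1L,
                       cp$interval$end)
  orf <- find_orfs(sim$genome, min_aa = 300, strands = "+")[[1]]
  lay <- annotate_layout(sim$genome, cp$interval, tir, orf)
  expect_identical(c(lay$tir5_len, lay$utr5_len, lay$orf_len, lay$utr3_len,
                     lay$tir3_len), c(40L, 120L, 1032L, 150L, 40L))
  expect_identical(layout_total_length(lay), interval_length(cp$interval))
  expect_true(lay$excision_ok)
})

test_that("zero-length TIR convention keeps the segment-sum invariant", {
  # IS630-like: no TIRs, boundaries carried by the excision sites alone
  lay <- element_layout(0, 23, 858, 3, 0)
  expect_identical(layout_total_length(lay), 884L)
  lay2 <- element_layout(0, 0, 858, 0, 0)
  expect_identical(layout_total_length(lay2), 858L)
  expect_error(element_layout(10, 10, 100, 10, 10,
                              element = interval("x", 1, 100)),
               class = "tc1scout_validation_error")
})

test_that("printed layout sums are reproduced", {
  expect_identical(layout_total_length(element_layout(169, 245, 3468, 1608, 169)), 5659L)
  expect_identical(layout_total_length(element_layout(141, 60, 1305, 41, 141)), 1688L)
  expect_identical(layout_total_length(element_layout(26, 246, 1032, 240, 26)), 1570L)
  expect_identical(layout_total_length(element_layout(0, 23, 858, 3, 0)), 884L)
  expect_identical(layout_total_length(element_layout(0, 0, 3, 0, 0)), 3L)
})

test_that("ORF overlapping a TIR is a layout error", {
  g <- genome_sequence("g", random_nt(500, 41))
  el <- interval("g", 101, 400)
  tir <- structure(list(tir5 = interval("g", 101, 140),
                        tir3 = interval("g", 361, 400),
                        length = 40L, identity = 1),
                   class = "tir_pair")
  orf <- list(interval = interval("g", 120, 340))
  expect_error(annotate_layout(g, el, tir, orf),
               class = "tc1scout_validation_error")
  orf_out <- list(interval = interval("g", 50, 340))
  expect_error(annotate_layout(g, el, tir, orf_out),
               class = "tc1scout_validation_error")
})

test_that("boundary inference recovers a planted segment from group comparison", {
  base <- random_nt(1200, 51)
  seg <- random_nt(886, 52)
  at <- 400
  carrier <- paste0(substr(base, 1, at), seg, substr(base, at + 1, 1200))
  bc <- infer_insertion_interval(list(carrier, carrier, carrier),
                                 list(base, base, base))
  expect_identical(interval_length(bc$interval), 886L)
  expect_identical(bc$interval$start, as.integer(at + 1))
  expect_identical(bc$support_with, 3L)
  expect_identical(bc$support_without, 3L)
})

test_that("boundary inference endpoints are exact across seeds", {
  for (i in 1:5) {
    base <- random_nt(900, 5300 + i)
    len <- sample(c(1, 50, 300), 1)
    at <- sample(200:600, 1)
    # unique flanks: the segment must not share its boundary bases with the
    # adjacent background, or the gap placement is genuinely ambiguous
    seed <- 5400 + i
    repeat {
      seg <- random_nt(len, seed)
      if (substr(seg, 1, 1) != substr(base, at + 1, at + 1) &&
          substr(seg, len, len) != substr(base, at, at)) break
      seed <- seed + 1000
    }
    carrier <- paste0(substr(base, 1, at), seg, substr(base, at + 1, 900))
    bc <- infer_insertion_interval(list(carrier), list(base))
    expect_identical(interval_length(bc$interval), as.integer(len))
    expect_identical(bc$interval$start, as.integer(at + 1))
  }
})

test_that("boundary inference signals missing or inconsistent evidence", {
  base <- random_nt(800, 61)
  carrier <- paste0(substr(base, 1, 300), random_nt(200, 62),
                    substr(base, 301, 800))
  expect_error(infer_insertion_interval(list(carrier, carrier), list()),
               class = "tc1scout_ambiguous_boundary_error")
  # a without-region with no deletion at all
  expect_error(infer_insertion_interval(list(carrier), list(carrier)),
               class = "tc1scout_ambiguous_boundary_error")
})
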