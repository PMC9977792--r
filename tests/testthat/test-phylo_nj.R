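test_that("p-distances match per-pair brute-force counts", {
  aln <- c(s1 = "AAAA", s2 = "AAAT", s3 = "TTTT")
  dm <- p_distance_matrix(aln)
  expect_identical(dm["s1", "s2"], 0.25)
  expect_identical(dm["s1", "s3"], 1)
  expect_identical(diag(dm), c(s1 = 0, s2 = 0, s3 = 0))
  # random gapped alignment vs counting oracle
  set.seed(111)
  aln2 <- vapply(1:5, function(i)
    paste0(sample(c("A", "R", "N", "D", "-"), 60, replace = TRUE),
           collapse = ""), "")
  names(aln2) <- paste0("t", 1:5)
  dm2 <- p_distance_matrix(aln2)
  ch <- strsplit(aln2, "")
  for (i in 1:4) for (j in (i + 1):5) {
    comp <- ch[[i]] != "-" & ch[[j]] != "-"
    expect_identical(dm2[i, j], mean(ch[[i]][comp] != ch[[j]][comp]))
    expect_identical(dm2[i, j], dm2[j, i])
  }
  # identical rows -> zero
  expect_identical(p_distance_matrix(c(a = "MKT", b = "MKT", c = "MKV"))["a", "b"], 0)
})

test_that("pairs with no comparable columns are an error naming the pair", {
  aln <- c(x = "AA--", y = "--TT", z = "AATT")
  expect_error(p_distance_matrix(aln), "x.*y",
               class = "tc1scout_validation_error")
})

test_that("poisson correction applies -log(1 - p)", {
  aln <- c(a = "AAAA", b = "AAAT", c = "AATT")
  dp <- p_distance_matrix(aln)
  dq <- p_distance_matrix(aln, model = "poisson")
  expect_equal(dq["a", "b"], -log(1 - dp["a", "b"]))
})

test_that("the 3-taxon tree solves the three-point formulas", {
  dm <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(dm)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl["a"]), (3 + 5 - 6) / 2)
  expect_equal(unname(bl["b"]), (3 + 6 - 5) / 2)
  expect_equal(unname(bl["c"]), (5 + 6 - 3) / 2)
})

test_that("NJ recovers additive quartet topologies", {
  dm <- matrix(c(0, 2, 7, 7,
                 2, 0, 7, 7,
                 7, 7, 0, 2,
                 7, 7, 2, 0), 4, 4,
               dimnames = list(letters[1:4], letters[1:4]))
  tr <- nj_tree(dm)
  ref <- ape::read.tree(text = "((a,b),(c,d));")
  expect_identical(as.numeric(ape::dist.topo(ape::unroot(tr), ape::unroot(ref))), 0)
})

test_that("NJ agrees with the ape reference on additive matrices", {
  for (i in 1:8) {
    set.seed(120 + i)
    rt <- ape::rtree(sample(5:9, 1))
    dm <- cophenetic(rt)
    ord <- sort(rownames(dm))
    dm <- dm[ord, ord]
    t1 <- nj_tree(dm)
    t2 <- ape::nj(as.dist(dm))
    expect_identical(as.numeric(ape::dist.topo(ape::unroot(t1), ape::unroot(t2))), 0)
    expect_true(all(t1$edge.length >= 0))   # clamping
  }
})

test_that("total tree length is invariant under leaf-order permutation", {
  set.seed(130)
  rt <- ape::rtree(8)
  dm <- cophenetic(rt)
  t1 <- nj_tree(dm)
  perm <- sample(rownames(dm))
  t2 <- nj_tree(dm[perm, perm])
  expect_equal(sum(t1$edge.length), sum(t2$edge.length), tolerance = 1e-9)
})

test_that("newick output re-parses to the same leaves and branch lengths", {
  set.seed(131)
  dm <- cophenetic(ape::rtree(6))
  tr <- nj_tree(dm)
  tf <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, tf)
  back <- ape::read.tree(tf)
  expect_setequal(back$tip.label, tr$tip.label)
  expect_equal(sort(back$edge.length), sort(tr$edge.length), tolerance = 1e-9)
})

test_that("outgroup rooting is idempotent and errors on unknown leaves", {
  set.seed(132)
  dm <- cophenetic(ape::rtree(6))
  tr <- nj_tree(dm)
  out <- tr$tip.label[1]
  r1 <- root_with_outgroup(tr, out)
  r2 <- root_with_outgroup(r1, out)
  expect_true(ape::all.equal.phylo(r1, r2))
  expect_error(root_with_outgroup(tr, "nope"),
               class = "tc1scout_validation_error")
})

test_that("planted two-clade simulations are recovered as monophyletic", {
  mutate_aa <- function(s, k, seed) {
    set.seed(seed)
    ch <- strsplit(s, "")[[1]]
    idx <- sample(seq_along(ch), k)
    aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
    for (i in idx) ch[i] <- sample(setdiff(aa, ch[i]), 1)
    paste0(ch, collapse = "")
  }
  for (rep in 1:5) {
    ancA <- random_aa(120, seed = 140 + rep)
    ancB <- mutate_aa(ancA, 45, seed = 150 + rep)   # distinct ancestors
    outg <- mutate_aa(ancA, 70, seed = 160 + rep)
    aln <- c(A1 = mutate_aa(ancA, 4, 170 + rep),
             A2 = mutate_aa(ancA, 4, 180 + rep),
             A3 = mutate_aa(ancA, 4, 190 + rep),
             B1 = mutate_aa(ancB, 4, 200 + rep),
             B2 = mutate_aa(ancB, 4, 210 + rep),
             OUT = outg)
    tr <- nj_tree(p_distance_matrix(aln))
    clades <- lapply(ingroup_clades(tr, "OUT"), sort)
    expect_length(clades, 2)
    expect_true(any(vapply(clades, identical, TRUE, c("A1", "A2", "A3"))))
    expect_true(any(vapply(clades, identical, TRUE, c("B1", "B2"))))
  }
})
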