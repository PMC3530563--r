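test_that("K2P distances follow the closed form and dominate p-distance", {
  s1 <- paste(rep("A", 650), collapse = "")
  s2 <- paste(c(rep("G", 65), rep("A", 585)), collapse = "")
  D <- pairwise_distances(as_sequence_set(c(x = s1, y = s2)), "K2P")
  expect_equal(D["x", "y"], -0.5 * log(0.8), tolerance = 1e-12)
  expect_equal(diag(D), c(x = 0, y = 0))
  # identical sequences
  D0 <- pairwise_distances(as_sequence_set(c(a = s1, b = s1)), "K2P")
  expect_equal(D0["a", "b"], 0)
  # random sequences: agree with an established K80 implementation and
  # never fall below the uncorrected distance
  set.seed(10)
  for (i in 1:5) {
    s <- rand_seq(400)
    seqs <- as_sequence_set(c(a = s, b = mutate_at(s, sample(400, 25)),
                              c = mutate_at(s, sample(400, 60))))
    D <- pairwise_distances(seqs, "K2P")
    Dref <- as.matrix(ape::dist.dna(fecalpop:::as_DNAbin(seqs),
                                    model = "K80"))
    expect_equal(unclass(D), Dref[rownames(D), colnames(D)],
                 tolerance = 1e-9, ignore_attr = TRUE)
    P <- pairwise_distances(seqs, "p_distance")
    expect_true(all(unclass(D) >= unclass(P) - 1e-12))
    expect_equal(unclass(D), t(unclass(D)))
  }
})

test_that("gaps and ambiguity codes are pairwise-deleted", {
  s1 <- "ACGTACGTAC"
  s2 <- "ACGTNCGT-C"
  D <- pairwise_distances(as_sequence_set(c(a = s1, b = s2)), "p_distance")
  expect_equal(D["a", "b"], 0)  # all comparable sites identical
  s3 <- "AGGTNCGT-C"
  D2 <- pairwise_distances(as_sequence_set(c(a = s1, b = s3)), "p_distance")
  expect_equal(D2["a", "b"], 1 / 8)
})

test_that("HKY distances nest Jukes-Cantor and track K2P", {
  set.seed(20)
  s <- rand_seq(500)
  sv <- mutate_at(s, sample(500, 50))
  seqs <- as_sequence_set(c(x = s, y = sv))
  p <- sum(strsplit(s, "")[[1]] != strsplit(sv, "")[[1]]) / 500
  jc <- -0.75 * log(1 - 4 * p / 3)
  Dh <- pairwise_distances(seqs, "HKY_ML", kappa = 1,
                           base_freqs = rep(0.25, 4))
  expect_equal(Dh["x", "y"], jc, tolerance = 1e-6)
  # kappa estimation yields a usable positive ratio
  expect_gt(estimate_kappa(seqs), 0)
  Dfree <- pairwise_distances(seqs, "HKY_ML")
  expect_gt(Dfree["x", "y"], 0)
  expect_equal(Dfree["x", "y"], pairwise_distances(seqs, "K2P")["x", "y"],
               tolerance = 0.05)
})

test_that("neighbour joining recovers trees exactly from additive distances", {
  set.seed(30)
  for (i in 1:30) {
    n <- sample(4:12, 1)
    tr <- ape::rtree(n, rooted = FALSE)
    D <- ape::cophenetic.phylo(tr)
    got <- neighbour_joining(D)
    expect_equal(ape::dist.topo(ape::unroot(tr), got), 0,
                 ignore_attr = TRUE)
    # branch lengths reproduce the generating metric
    expect_equal(ape::cophenetic.phylo(got)[rownames(D), colnames(D)],
                 D, tolerance = 1e-6)
  }
})

test_that("degenerate and tied NJ inputs are handled deterministically", {
  # three taxa: closed-form branch lengths
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbour_joining(D)
  expect_equal(sort(tr$tip.label), c("A", "B", "C"))
  pat <- ape::cophenetic.phylo(tr)
  expect_equal(pat[rownames(D), colnames(D)], D, tolerance = 1e-9)
  # two taxa and one taxon
  D2 <- matrix(c(0, 2, 2, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- neighbour_joining(D2)
  expect_equal(sum(t2$edge.length), 2)
  expect_equal(write_newick(neighbour_joining(
    matrix(0, 1, 1, dimnames = list("A", "A")))), "A;")
  # equal distances: deterministic under label order
  De <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(De) <- 0
  e1 <- neighbour_joining(De)
  perm <- c(3, 1, 4, 2)
  e2 <- neighbour_joining(De[perm, perm])
  expect_equal(write_newick(e1), write_newick(e2))
})

test_that("negative NJ branch lengths are clamped and logged", {
  D <- matrix(c(0, 1, 5, 5,
                1, 0, 5, 5,
                5, 5, 0, 1,
                5, 5, 1, 0), 4,
              dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  D["A", "B"] <- D["B", "A"] <- 6  # violates additivity
  tr <- neighbour_joining(D)
  expect_true(all(tr$edge.length >= 0))
  expect_true(attr(tr, "clamped") >= 0)
})

test_that("bootstrap supports are reproducible and detect a clean split", {
  set.seed(40)
  base <- rand_seq(300)
  other <- mutate_at(base, 1:60)
  seqs <- as_sequence_set(c(a1 = base, a2 = mutate_at(base, 290),
                            a3 = mutate_at(base, 295),
                            b1 = other, b2 = mutate_at(other, 280),
                            b3 = mutate_at(other, 285)))
  t1 <- bootstrap_support(seqs, n_boot = 100, seed = 5)
  t2 <- bootstrap_support(seqs, n_boot = 100, seed = 5)
  expect_identical(t1$node.label, t2$node.label)
  expect_true(all(t1$node.label >= 0 & t1$node.label <= 100))
  # the a|b bipartition carries overwhelming signal
  expect_gte(max(t1$node.label, na.rm = TRUE), 99)
  # an alignment whose columns are all identical has no variation to
  # resample: every replicate reproduces the same tree
  mono <- as_sequence_set(setNames(rep(paste(rep("ACGT", 25),
                                             collapse = ""), 4),
                                   c("w", "x", "y", "z")))
  tm <- bootstrap_support(mono, n_boot = 20, seed = 2)
  expect_true(length(unique(tm$node.label)) == 1L)
})

test_that("clade assignment uses nearest references and reports ties", {
  set.seed(50)
  base <- rand_seq(300)
  c4 <- mutate_at(base, 1:50)
  seqs <- as_sequence_set(c(ref1 = base, ref4 = c4,
                            q_same = base, q_west = mutate_at(c4, 299),
                            q_mid = base))
  tr <- neighbour_joining(pairwise_distances(seqs, "K2P"))
  cm <- c(ref1 = "clade1", ref4 = "clade4")
  asg <- assign_clades(tr, cm,
                       populations = c(q_same = "east", q_west = "west",
                                       q_mid = "east"))
  expect_equal(asg$clade[asg$leaf == "q_same"], "clade1")
  expect_equal(asg$clade[asg$leaf == "q_west"], "clade4")
  expect_true(!is.null(attr(asg, "composition")))
  # tie: equidistant to both references is reported, not resolved
  Dt <- matrix(c(0, 2, 1, 2, 0, 1, 1, 1, 0), 3,
               dimnames = list(c("refA", "refB", "q"),
                               c("refA", "refB", "q")))
  tt <- neighbour_joining(Dt)
  asg2 <- assign_clades(tt, c(refA = "A", refB = "B"))
  expect_true(is.na(asg2$clade[asg2$leaf == "q"]))
  expect_match(asg2$tie[asg2$leaf == "q"], ";")
  expect_warning(assign_clades(tt, c(nope = "X")), "skipped")
})
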