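test_that("diversity indices match hand computation on toys", {
  # identical homozygotes
  g0 <- data.frame(individual_id = c("a", "b"), locus_id = "L1",
                   allele_a = 100, allele_b = 100)
  d0 <- diversity(g0, c(a = "P", b = "P"))
  expect_equal(d0$H_O, 0)
  expect_equal(d0$H_E, 0)
  expect_equal(d0$A, 1)
  # two identical heterozygotes: H_O = 1, unbiased H_E = (4/3)(1/2)
  g1 <- data.frame(individual_id = c("a", "b"), locus_id = "L1",
                   allele_a = 100, allele_b = 120)
  d1 <- diversity(g1, c(a = "P", b = "P"))
  expect_equal(d1$H_O, 1)
  expect_equal(d1$H_E, 2 / 3)
  # nucleotide diversity: enumerate the pairs
  s <- rand_seq(650)
  s2 <- mutate_at(s, 1)
  seqs <- as_sequence_set(c(a = s, b = s, c = s2, d = s2))
  g4 <- data.frame(individual_id = letters[1:4], locus_id = "L1",
                   allele_a = 100, allele_b = 100)
  pops <- setNames(rep("P", 4), letters[1:4])
  d4 <- diversity(g4, pops, sequences = seqs)
  expect_equal(d4$pi_percent, 100 * (4 * (1 / 650)) / 6, tolerance = 1e-12)
  expect_warning(
    diversity(rbind(g1, data.frame(individual_id = "z", locus_id = "L1",
                                   allele_a = 1, allele_b = 2)),
              c(a = "P", b = "P", z = "solo")),
    "single individual")
})

test_that("HWE exact test flags only genuine departures", {
  a <- rep(c(1L, 1L, 2L), c(25, 50, 25))
  b <- rep(c(1L, 2L, 2L), c(25, 50, 25))
  p_null <- hwe_test(a, b)
  expect_gt(p_null, 0.5)
  p_bad <- hwe_test(rep(c(1L, 2L), c(50, 50)), rep(c(1L, 2L), c(50, 50)))
  expect_lt(p_bad, 0.001)
  p_mono <- hwe_test(rep(1L, 10), rep(1L, 10))
  expect_equal(as.numeric(p_mono), 1)
  expect_match(attr(p_mono, "method"), "monomorphic")
  # Monte-Carlo route agrees with enumeration on a biallelic table
  set.seed(8)
  av <- rep(c(1L, 1L, 2L), c(6, 8, 6))
  bv <- rep(c(1L, 2L, 2L), c(6, 8, 6))
  p_enum <- hwe_test(av, bv)
  # force the MC route by relabelling one homozygote pair as a third
  # allele? no -- instead check a triallelic locus is calibrated under
  # the null
  g <- hwe_draw(60, c(0.5, 0.3, 0.2))
  p_tri <- hwe_test(g[, 1], g[, 2], n_mc = 500)
  expect_gt(p_tri, 0.001)
})

test_that("linkage disequilibrium G-test separates linked from independent loci", {
  set.seed(12)
  g1 <- hwe_draw(80, c(0.5, 0.5))
  g2 <- hwe_draw(80, c(0.5, 0.5))
  p_ind <- ld_test(g1[, 1], g1[, 2], g2[, 1], g2[, 2], n_perm = 300)
  expect_gt(p_ind, 0.01)
  p_link <- ld_test(g1[, 1], g1[, 2], g1[, 1], g1[, 2], n_perm = 300)
  expect_lt(p_link, 0.01)
  expect_equal(as.numeric(ld_test(rep(1, 10), rep(1, 10),
                                  g2[1:10, 1], g2[1:10, 2])), 1)
  expect_equal(bonferroni(c(0.01, 0.04)), c(0.02, 0.08))
})

test_that("Weir-Cockerham theta equals the literal variance-component oracle", {
  set.seed(33)
  # hand-listed toy: 2 populations x 5 individuals, one locus
  popA <- matrix(c(1, 1, 1, 2, 2, 2, 1, 2, 3, 1), 5, 2, byrow = TRUE)
  popB <- matrix(c(2, 2, 2, 3, 3, 3, 2, 3, 3, 2), 5, 2, byrow = TRUE)
  g <- long_geno(list(i1 = popA[1, , drop = FALSE]))  # placeholder shape
  mats <- c(lapply(1:5, function(i) popA[i, , drop = FALSE]),
            lapply(1:5, function(i) popB[i, , drop = FALSE]))
  names(mats) <- sprintf("i%02d", 1:10)
  g <- long_geno(mats)
  pops <- setNames(rep(c("A", "B"), each = 5), names(mats))
  theta <- wc_theta(g, pops)
  expect_equal(as.numeric(theta),
               wc_theta_oracle(list(popA, popB)), tolerance = 1e-9)
  # random multi-locus tables against the oracle
  for (rep in 1:5) {
    n1 <- sample(4:8, 1); n2 <- sample(4:8, 1)
    m1 <- hwe_draw(n1, c(0.2, 0.5, 0.3))
    m2 <- hwe_draw(n2, c(0.5, 0.3, 0.2))
    mats <- c(lapply(seq_len(n1), function(i) m1[i, , drop = FALSE]),
              lapply(seq_len(n2), function(i) m2[i, , drop = FALSE]))
    names(mats) <- sprintf("x%02d", seq_along(mats))
    g <- long_geno(mats)
    pops <- setNames(rep(c("A", "B"), c(n1, n2)), names(mats))
    expect_equal(as.numeric(wc_theta(g, pops)),
                 wc_theta_oracle(list(m1, m2)), tolerance = 1e-9)
  }
})

test_that("theta hits its limits and is label/order invariant", {
  mats <- c(lapply(1:10, function(i) matrix(c(100, 100), 1)),
            lapply(1:10, function(i) matrix(c(200, 200), 1)))
  names(mats) <- sprintf("i%02d", 1:20)
  g <- long_geno(mats)
  pops <- setNames(rep(c("A", "B"), each = 10), names(mats))
  expect_equal(as.numeric(wc_theta(g, pops)), 1)
  # identical frequencies: theta near zero
  set.seed(44)
  m <- hwe_draw(200, c(0.4, 0.3, 0.3))
  mats2 <- lapply(seq_len(200), function(i) m[i, , drop = FALSE])
  names(mats2) <- sprintf("j%03d", 1:200)
  g2 <- long_geno(mats2)
  pops2 <- setNames(rep(c("A", "B"), each = 100), names(mats2))
  expect_lt(abs(wc_theta(g2, pops2)), 0.02)
  # invariance to population label order and row order
  t1 <- wc_theta(g, pops)
  t2 <- wc_theta(g[sample(nrow(g)), ],
                 pops[sample(names(pops))])
  expect_equal(as.numeric(t1), as.numeric(t2))
  g_mono <- long_geno(list(a = matrix(c(1, 1), 1), b = matrix(c(1, 1), 1)))
  expect_error(wc_theta(g_mono, c(a = "A", b = "B")), "no polymorphic")
})

test_that("permutation p-values behave under null and structure", {
  set.seed(55)
  m <- hwe_draw(40, c(0.4, 0.3, 0.3))
  mats <- lapply(seq_len(40), function(i) m[i, , drop = FALSE])
  names(mats) <- sprintf("i%02d", 1:40)
  g <- long_geno(mats)
  pops <- setNames(rep(c("A", "B"), each = 20), names(mats))
  r <- fst_microsat(g, pops, "A", "B", n_perm = 199)
  expect_gt(r$p, 0.01)
  mats2 <- c(lapply(1:10, function(i) matrix(c(1, 1), 1)),
             lapply(1:10, function(i) matrix(c(2, 2), 1)))
  names(mats2) <- sprintf("k%02d", 1:20)
  g2 <- long_geno(mats2)
  pops2 <- setNames(rep(c("A", "B"), each = 10), names(mats2))
  r2 <- fst_microsat(g2, pops2, "A", "B", n_perm = 199)
  expect_equal(r2$estimate, 1)
  expect_lt(r2$p, 0.02)
})

test_that("Phi_ST equals the literal sum-of-squares oracle on a toy", {
  set.seed(66)
  base <- rand_seq(120)
  h1 <- base
  h2 <- mutate_at(base, 1:2)
  h3 <- mutate_at(base, 11:18)
  seqs <- as_sequence_set(c(a1 = h1, a2 = h1, a3 = h2,
                            b1 = h3, b2 = h3, b3 = h2))
  pops <- setNames(rep(c("A", "B"), each = 3), names(seqs))
  r <- phi_st_mtdna(seqs, pops, distance_model = "p_distance", n_perm = 99)
  D <- pairwise_distances(seqs, "p_distance")
  expect_equal(r$estimate, phi_st_oracle(unclass(D), unname(pops)),
               tolerance = 1e-9)
})

test_that("Phi_ST limits: disjoint pools, shared pool, identical sequences", {
  set.seed(77)
  base <- rand_seq(300)
  east <- c(base, mutate_at(base, 1), mutate_at(base, 2))
  west <- c(mutate_at(base, 50:75), mutate_at(base, c(50:75, 80)))
  seqs <- as_sequence_set(setNames(c(east[c(1, 2, 3, 1)],
                                     west[c(1, 2, 1, 2)]),
                                   sprintf("s%d", 1:8)))
  pops <- setNames(rep(c("E", "W"), each = 4), names(seqs))
  r <- phi_st_mtdna(seqs, pops, n_perm = 99)
  expect_gt(r$estimate, 0.8)
  # both drawn from one pool
  pool <- c(base, mutate_at(base, 1), mutate_at(base, 2))
  set.seed(1)
  draws <- sample(pool, 16, TRUE)
  seqs2 <- as_sequence_set(setNames(draws, sprintf("t%d", 1:16)))
  pops2 <- setNames(rep(c("E", "W"), each = 8), names(seqs2))
  r2 <- phi_st_mtdna(seqs2, pops2, n_perm = 99)
  expect_lt(abs(r2$estimate), 0.25)
  # identical everywhere
  seqs3 <- as_sequence_set(setNames(rep(base, 6), sprintf("u%d", 1:6)))
  pops3 <- setNames(rep(c("E", "W"), each = 3), names(seqs3))
  r3 <- phi_st_mtdna(seqs3, pops3)
  expect_equal(r3$estimate, 0)
  expect_equal(r3$p, 1)
})

test_that("pairwise matrices are symmetric and printable", {
  set.seed(88)
  m <- hwe_draw(30, c(0.4, 0.4, 0.2))
  mats <- lapply(seq_len(30), function(i) m[i, , drop = FALSE])
  names(mats) <- sprintf("i%02d", 1:30)
  g <- long_geno(mats)
  pops <- setNames(rep(c("A", "B", "C"), each = 10), names(mats))
  th <- pairwise_theta(g, pops, n_perm = 49)
  expect_equal(th$estimate, t(th$estimate))
  expect_equal(th$p, t(th$p))
  expect_output(print(th), "estimates below")
  f <- tempfile(fileext = ".csv")
  write_pairwise_fst(th, f)
  expect_true(file.exists(f))
})

test_that("regional subdivision isolates a divergent region", {
  set.seed(99)
  base <- rand_seq(300)
  same <- c(base, mutate_at(base, 1))
  far <- mutate_at(base, 30:60)
  ids <- sprintf("r%02d", 1:24)
  seqs <- as_sequence_set(setNames(
    c(sample(same, 18, TRUE), rep(far, 6)), ids))
  populations <- setNames(rep("SE", 24), ids)
  regions <- setNames(rep(c("NSE", "WSE", "CSE", "SSE"), each = 6), ids)
  r <- regional_subdivision(seqs, populations, regions, n_perm = 199)
  expect_equal(sort(rownames(r$estimate)), sort(unique(regions)))
  # the seeded southern region stands out from every other region
  expect_true(all(r$estimate["SSE", c("NSE", "WSE", "CSE")] > 0.5))
  expect_true(all(r$p["SSE", c("NSE", "WSE", "CSE")] < 0.05))
  # a single unit yields an empty matrix
  r1 <- suppressWarnings(regional_subdivision(
    seqs[1:6], populations[1:6], regions[1:6], n_perm = 9))
  expect_equal(dim(r1$estimate), c(1L, 1L))
})
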