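tab_from <- function(reps) {
  # reps: list of integer vectors (0, 1 or 2 calls)
  reps <- lapply(reps, as.integer)
  genotype_table(rep("s1", length(reps)), rep("L1", length(reps)),
                 seq_along(reps),
                 vapply(reps, function(o) if (length(o)) o[1] else NA_integer_,
                        integer(1)),
                 vapply(reps, function(o) if (length(o) == 2) o[2]
                        else NA_integer_, integer(1)))
}

okey <- function(o) if (length(o)) paste(o, collapse = "/") else "none"

test_that("multiple-tubes thresholds call the documented examples", {
  het <- call_consensus(tab_from(list(c(100, 120), c(100, 120))))
  expect_equal(het$call, "het")
  expect_equal(c(het$allele_a, het$allele_b, het$n_support), c(100, 120, 2))
  hom <- call_consensus(tab_from(rep(list(c(100, 100)), 5)))
  expect_equal(hom$call, "hom")
  expect_equal(c(hom$allele_a, hom$allele_b), c(100, 100))
  # four homozygous replicates plus one contradicting pair: het support
  # 1 < 2 and the homozygote is contradicted
  mixed <- tab_from(c(rep(list(c(100, 100)), 4), list(c(100, 120))))
  out <- call_consensus(mixed)
  expect_equal(nrow(out), 0L)  # the sample has no called locus left
  expect_equal(attr(out, "discarded")$sample_id, "s1")
})

test_that("the calling rule matches a literal oracle over all small multisets", {
  # all replicate outcome types over alleles {1,2,3}
  types <- c(list(integer(0)),
             lapply(1:3, identity),
             lapply(1:3, function(a) c(a, a)),
             list(c(1L, 2L), c(1L, 3L), c(2L, 3L)))
  sizes <- 1:6
  n_checked <- 0L
  mismatches <- character(0)
  for (size in sizes) {
    combos <- utils::combn(length(types) + size - 1L, size)
    # multisets via stars-and-bars on sorted type indices
    for (ci in seq_len(ncol(combos))) {
      idx <- combos[, ci] - seq_len(size) + 1L
      obs <- types[idx]
      oracle <- consensus_rule_oracle(obs)
      got <- fecalpop:::call_one_locus(
        vapply(obs, function(o) if (length(o)) o[1] else NA_integer_,
               integer(1)),
        vapply(obs, function(o) if (length(o) == 2) o[2] else NA_integer_,
               integer(1)),
        2L, 5L)
      bad <- !identical(got$call, oracle$call) ||
        (oracle$call != "failed" &&
           !identical(as.integer(c(got$a, got$b)),
                      as.integer(c(oracle$a, oracle$b))))
      if (bad) {
        mismatches <- c(mismatches, paste(
          vapply(obs, paste, character(1), collapse = "."),
          collapse = " | "))
      }
      n_checked <- n_checked + 1L
    }
  }
  expect_gt(n_checked, 5000L)
  expect_equal(mismatches, character(0))
})

test_that("replicate outcome probabilities match the generative process", {
  set.seed(91)
  ladder <- c(100L, 120L, 140L)
  for (truth in list(c(100L, 120L), c(100L, 100L))) {
    for (pars in list(c(0.3, 0.1), c(0.05, 0.3))) {
      d <- pars[1]; f <- pars[2]
      dist <- outcome_dist_oracle(truth, ladder, d, f)
      tot <- 0
      for (key in names(dist)) {
        obs <- if (key != "none")
          as.integer(strsplit(key, "/", fixed = TRUE)[[1]]) else integer(0)
        p <- replicate_outcome_prob(obs, truth, ladder, d, f)
        expect_equal(p, dist[[key]], tolerance = 1e-12)
        tot <- tot + p
      }
      expect_equal(tot, 1, tolerance = 1e-12)
      # and against a Monte-Carlo run of an independent simulator
      n <- 20000
      draws <- table(vapply(seq_len(n), function(i)
        okey(sim_replicate_oracle(truth, ladder, d, f)), character(1)))
      for (key in names(draws)) {
        obs <- if (key != "none")
          as.integer(strsplit(key, "/", fixed = TRUE)[[1]]) else integer(0)
        p <- replicate_outcome_prob(obs, truth, ladder, d, f)
        se <- sqrt(p * (1 - p) / n)
        expect_lt(abs(draws[[key]] / n - p), 4 * se + 1e-4)
      }
    }
  }
})

test_that("reliability is certain without error and increases with replication", {
  tab <- tab_from(list(c(100, 120), c(100, 120)))
  cons <- call_consensus(tab)
  expect_equal(genotype_reliability(cons, tab, 0, 0)$reliability, 1)
  # monotone in the number of consistent replicates
  rel_at <- function(n) {
    tb <- tab_from(rep(list(c(100, 120)), n))
    genotype_reliability(call_consensus(tb), tb, 0.2, 0.05)$reliability
  }
  rels <- vapply(2:6, rel_at, numeric(1))
  expect_true(all(diff(rels) >= -1e-12))
  expect_error(genotype_reliability(cons, tab, 1.2, 0), "error rates")
})

test_that("homozygote reliability equals brute-force Bayes", {
  d <- 0.2; f <- 0.02
  tab <- tab_from(rep(list(c(100, 100)), 5))
  cons <- call_consensus(tab)
  got <- genotype_reliability(cons, tab, d, f)$reliability
  # candidates: hom(100) and het(100, unseen); uniform prior; replicate
  # universe is the observed allele plus the unseen token
  ladder <- c(100L, fecalpop:::UNSEEN_ALLELE)
  lik <- function(truth) {
    dist <- outcome_dist_oracle(truth, ladder, d, f)
    dist[["100/100"]]^5
  }
  l_hom <- lik(c(100L, 100L))
  l_het <- lik(c(100L, fecalpop:::UNSEEN_ALLELE))
  expect_equal(got, l_hom / (l_hom + l_het), tolerance = 1e-12)
  expect_lt(got, 1)
})

test_that("per-locus reliability is calibrated on simulated data", {
  cfg <- sim_config(deme_sizes = c(20, 20, 10, 15, 15), seed = 29)
  mp <- simulate_metapopulation(cfg)
  d <- sample_dung(mp)
  cons <- call_consensus(d$genotypes)
  rel <- genotype_reliability(cons, d$genotypes, cfg$dropout_rate,
                              cfg$false_allele_rate)
  pl <- attr(rel, "per_locus")
  truth_g <- mp$genotypes
  ind_of <- d$truth$individual_id[match(pl$sample_id, d$truth$sample_id)]
  gi <- match(paste(ind_of, pl$locus_id),
              paste(truth_g$individual_id, truth_g$locus_id))
  called <- cons[cons$call != "failed", ]
  ok <- called$allele_a == truth_g$allele_a[gi] &
    called$allele_b == truth_g$allele_b[gi]
  # among high-confidence calls the empirical accuracy matches the
  # stated posterior
  hi <- pl$posterior >= 0.95
  expect_gt(sum(hi), 200)
  expect_lt(abs(mean(ok[hi]) - mean(pl$posterior[hi])), 0.03)
})

test_that("error-rate estimation recovers concordance and rejects single replicates", {
  tab <- genotype_table(rep(c("s1", "s2"), each = 6),
                        rep(rep(c("L1", "L2", "L3"), each = 2), 2),
                        rep(1:2, 6),
                        rep(rep(c(100, 104, 108), each = 2), 2),
                        rep(rep(c(102, 104, 110), each = 2), 2))
  est <- estimate_error_rates(tab)
  expect_equal(unname(est["d"]), 0)
  expect_equal(unname(est["f"]), 0)
  single <- genotype_table("s1", "L1", 1, 100, 102)
  expect_error(estimate_error_rates(single), ">= 2 replicates")
})

test_that("error-free consensus equals truth everywhere with no failed loci", {
  cfg <- sim_config(deme_sizes = c(6, 6, 4, 6, 6), dropout_rate = 0,
                    false_allele_rate = 0, seed = 31)
  mp <- simulate_metapopulation(cfg)
  d <- sample_dung(mp)
  cons <- call_consensus(d$genotypes)
  expect_true(all(cons$call != "failed"))
  expect_equal(nrow(cons), length(unique(d$truth$sample_id)) * cfg$n_loci)
  g <- mp$genotypes
  gi <- match(paste(d$truth$individual_id[match(cons$sample_id,
                                                d$truth$sample_id)],
                    cons$locus_id),
              paste(g$individual_id, g$locus_id))
  expect_true(all(cons$allele_a == g$allele_a[gi] &
                    cons$allele_b == g$allele_b[gi]))
})
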