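test_that("probability of identity matches exhaustive enumeration", {
  # biallelic 0.5/0.5 locus
  pid <- probability_of_identity(list(L1 = c(a = 0.5, b = 0.5)))
  expect_equal(pid$p_id, 0.375)
  expect_equal(pid$p_id_sib, 0.59375)
  expect_equal(pid$p_id, pid_enum(c(0.5, 0.5)))
  expect_equal(pid$p_id_sib, pid_sib_enum(c(0.5, 0.5)))
  # a skewed three-allele locus against the same enumerations
  p3 <- c(0.6, 0.3, 0.1)
  pid3 <- probability_of_identity(list(L = setNames(p3, letters[1:3])))
  expect_equal(pid3$p_id, pid_enum(p3), tolerance = 1e-12)
  expect_equal(pid3$p_id_sib, pid_sib_enum(p3), tolerance = 1e-12)
  # monomorphic locus
  pid1 <- probability_of_identity(list(L = c(a = 1)))
  expect_equal(pid1$p_id, 1)
  expect_equal(pid1$p_id_sib, 1)
})

test_that("identity statistics obey their invariants", {
  set.seed(5)
  freqs <- lapply(1:6, function(i) {
    p <- rgamma(sample(3:8, 1), 1)
    setNames(p / sum(p), seq_along(p))
  })
  names(freqs) <- sprintf("L%d", 1:6)
  pid <- probability_of_identity(freqs)
  expect_true(all(pid$p_id > 0 & pid$p_id <= 1))
  expect_true(all(pid$p_id <= pid$p_id_sib))
  cum <- attr(pid, "cumulative")
  expect_equal(unname(cum["p_id"]), prod(pid$p_id))
  expect_equal(unname(cum["p_id_sib"]), prod(pid$p_id_sib))
  expect_error(probability_of_identity(list(L = c(a = 0.5, b = 0.6))),
               "sum to 1")
})

test_that("sex assignment follows the confirmation rules", {
  expect_equal(assign_sex(c("two_bands", "two_bands")), "M")
  expect_equal(assign_sex(rep("one_band", 3)), "F")
  # a single two-band call vetoes female and is not yet male
  expect_equal(assign_sex(c("one_band", "two_bands", "one_band")), "unknown")
  expect_equal(assign_sex(c("one_band", "two_bands", "one_band",
                            "two_bands")), "M")
  expect_equal(assign_sex(c("one_band", "one_band")), "unknown")
  expect_equal(assign_sex(rep("fail", 4)), "unknown")
  md <- sample_metadata(c("a", "b"), c("P", "P"),
                        sex_replicates = c("two_bands;two_bands",
                                           "one_band;one_band;one_band"))
  expect_equal(unname(assign_sex(md)), c("M", "F"))
})

# build a consensus_calls object directly from per-sample genotype rows
cons_of <- function(genos) {
  # genos: named list, sample -> data.frame(locus_id, allele_a, allele_b)
  df <- do.call(rbind, lapply(names(genos), function(s) {
    g <- genos[[s]]
    data.frame(sample_id = s, locus_id = g$locus_id,
               call = ifelse(g$allele_a == g$allele_b, "hom", "het"),
               allele_a = g$allele_a, allele_b = g$allele_b,
               n_support = 2L, n_replicates = 2L, stringsAsFactors = FALSE)
  }))
  class(df) <- c("consensus_calls", "data.frame")
  df
}

g12 <- function(alleles) {
  data.frame(locus_id = sprintf("L%02d", seq_along(alleles)),
             allele_a = vapply(alleles, min, numeric(1)),
             allele_b = vapply(alleles, max, numeric(1)))
}

test_that("recapture matching follows the exact and one-mismatch rules", {
  base <- lapply(1:12, function(i) c(100 + 2 * i, 104 + 2 * i))
  one_off <- base; one_off[[3]] <- c(base[[3]][1], base[[3]][1])
  two_off <- one_off; two_off[[7]] <- c(base[[7]][1], base[[7]][1])
  pops <- c(s1 = "CCA", s2 = "CCA", s3 = "CCA")
  # identical genotypes merge regardless of the flag
  cons <- cons_of(list(s1 = g12(base), s2 = g12(base)))
  ind <- match_samples(cons, pops[1:2])
  expect_equal(nrow(ind), 1L)
  expect_equal(ind$n_samples, 2L)
  # one allele at one locus apart: merges only with the flag and
  # matching sexes
  cons2 <- cons_of(list(s1 = g12(base), s2 = g12(one_off)))
  sex_ff <- c(s1 = "F", s2 = "F")
  m_on <- match_samples(cons2, pops[1:2], sex_ff,
                        one_mismatch_pops = "CCA")
  expect_equal(nrow(m_on), 1L)
  expect_match(attr(m_on, "merge_log")$rule, "one_mismatch")
  m_off <- match_samples(cons2, pops[1:2], sex_ff)
  expect_equal(nrow(m_off), 2L)
  # sexes must match for the one-mismatch rule
  m_fm <- match_samples(cons2, pops[1:2], c(s1 = "F", s2 = "M"),
                        one_mismatch_pops = "CCA")
  expect_equal(nrow(m_fm), 2L)
  # two loci apart never merges
  cons3 <- cons_of(list(s1 = g12(base), s2 = g12(two_off)))
  m2 <- match_samples(cons3, pops[1:2], sex_ff, one_mismatch_pops = "CCA")
  expect_equal(nrow(m2), 2L)
})

test_that("both one-allele mismatch cases qualify and are logged", {
  base <- lapply(1:12, function(i) c(100 + 2 * i, 104 + 2 * i))
  # het vs het sharing one allele: (a,b) vs (a,c)
  alt <- base; alt[[5]] <- c(base[[5]][1], base[[5]][2] + 2)
  cons <- cons_of(list(s1 = g12(base), s2 = g12(alt)))
  m <- match_samples(cons, c(s1 = "CCA", s2 = "CCA"),
                     c(s1 = "M", s2 = "M"), one_mismatch_pops = "CCA")
  expect_equal(nrow(m), 1L)
  expect_equal(attr(m, "merge_log")$rule, "one_mismatch:het_vs_het")
})

test_that("conflicting sex or haplotype blocks merges and is reported", {
  base <- lapply(1:12, function(i) c(100 + 2 * i, 104 + 2 * i))
  cons <- cons_of(list(s1 = g12(base), s2 = g12(base)))
  pops <- c(s1 = "AM", s2 = "AM")
  m <- match_samples(cons, pops, c(s1 = "M", s2 = "F"))
  expect_equal(nrow(m), 2L)
  expect_match(attr(m, "conflicts")$reason[1], "sex conflict")
  m2 <- match_samples(cons, pops, haplotypes = c(s1 = "H01", s2 = "H02"))
  expect_equal(nrow(m2), 2L)
  expect_match(attr(m2, "conflicts")$reason[1], "haplotype conflict")
  # haplotype conflicts can be waived explicitly
  m3 <- match_samples(cons, pops, haplotypes = c(s1 = "H01", s2 = "H02"),
                      require_haplotype_match = FALSE)
  expect_equal(nrow(m3), 1L)
})

test_that("matching needs enough mutually called loci", {
  base <- lapply(1:12, function(i) c(100 + 2 * i, 104 + 2 * i))
  few <- g12(base)[1:5, ]   # only 5 shared loci
  cons <- cons_of(list(s1 = few, s2 = few))
  m <- match_samples(cons, c(s1 = "AM", s2 = "AM"))
  expect_equal(nrow(m), 2L)
  m2 <- match_samples(cons, c(s1 = "AM", s2 = "AM"), min_shared_loci = 5L)
  expect_equal(nrow(m2), 1L)
})

test_that("matching is invariant to sample order", {
  set.seed(17)
  base <- lapply(1:12, function(i) c(100 + 2 * i, 104 + 2 * i))
  genos <- list(s1 = g12(base), s2 = g12(base), s3 = g12(base))
  alt <- base; alt[[2]] <- c(200, 204)
  genos$s4 <- g12(alt); genos$s5 <- g12(alt)
  pops <- setNames(rep("AM", 5), paste0("s", 1:5))
  cons <- cons_of(genos)
  m1 <- match_samples(cons, pops)
  cons_shuf <- cons[sample(nrow(cons)), ]
  class(cons_shuf) <- class(cons)
  m2 <- match_samples(cons_shuf, pops)
  map1 <- attr(m1, "sample_map"); map2 <- attr(m2, "sample_map")
  expect_equal(ari(map1[paste0("s", 1:5)], map2[paste0("s", 1:5)]), 1)
  expect_equal(nrow(m1), 2L)
})

test_that("error-free simulated samples recover the true individuals exactly", {
  cfg <- sim_config(deme_sizes = c(8, 8, 6, 8, 8), dropout_rate = 0,
                    false_allele_rate = 0, seed = 37)
  mp <- simulate_metapopulation(cfg)
  d <- sample_dung(mp)
  cons <- call_consensus(d$genotypes)
  pops <- setNames(d$metadata$population, d$metadata$sample_id)
  haps <- haplotype_ids(d$sequences)
  ind <- match_samples(cons, pops, assign_sex(d$metadata), haps,
                       one_mismatch_pops = "CCA", table = d$genotypes)
  map <- attr(ind, "sample_map")
  truth <- setNames(d$truth$individual_id, d$truth$sample_id)
  expect_equal(ari(map[names(truth)], truth), 1)
  # component consensus equals the true genotype
  g <- attr(ind, "genotypes")
  expect_equal(nrow(ind), length(unique(truth)))
})
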