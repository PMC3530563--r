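# Independent oracles used across the suite.  These deliberately
# re-derive quantities by direct enumeration / literal formula
# transcription, separate from the package's implementation paths.

# adjusted Rand index between two partitions (label vectors)
ari <- function(x, y) {
  tab <- table(x, y)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  n <- sum(tab)
  expected <- b * cc / choose(n, 2)
  maxi <- (b + cc) / 2
  if (maxi == expected) return(1)
  (a - expected) / (maxi - expected)
}

# P_ID by enumeration: probability two independent HWE draws share the
# same unordered genotype
pid_enum <- function(p) {
  k <- length(p)
  tot <- 0
  for (i in 1:k) for (j in 1:k) for (u in 1:k) for (v in 1:k) {
    g1 <- sort(c(i, j)); g2 <- sort(c(u, v))
    if (all(g1 == g2)) tot <- tot + p[i] * p[j] * p[u] * p[v]
  }
  tot
}

# P_ID(sib) by enumeration over parental genotypes: two full sibs each
# draw one allele from each HWE parent
pid_sib_enum <- function(p) {
  k <- length(p)
  tot <- 0
  for (m1 in 1:k) for (m2 in 1:k) for (f1 in 1:k) for (f2 in 1:k) {
    pg <- p[m1] * p[m2] * p[f1] * p[f2]
    for (c1m in c(m1, m2)) for (c1f in c(f1, f2)) {
      for (c2m in c(m1, m2)) for (c2f in c(f1, f2)) {
        if (all(sort(c(c1m, c1f)) == sort(c(c2m, c2f)))) {
          tot <- tot + pg / 16
        }
      }
    }
  }
  tot
}

# Weir & Cockerham (1984) theta by literal per-allele transcription
wc_theta_oracle <- function(geno_by_pop) {
  # geno_by_pop: list of n_i x 2 matrices of allele labels, one per pop
  r <- length(geno_by_pop)
  ni <- vapply(geno_by_pop, nrow, numeric(1))
  nbar <- mean(ni)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  alleles <- sort(unique(unlist(geno_by_pop)))
  num <- den <- 0
  for (A in alleles) {
    pi_ <- hi <- numeric(r)
    for (i in seq_len(r)) {
      m <- geno_by_pop[[i]]
      pi_[i] <- sum(m == A) / (2 * ni[i])
      hi[i] <- sum(m[, 1] != m[, 2] & (m[, 1] == A | m[, 2] == A)) / ni[i]
    }
    pbar <- sum(ni * pi_) / (r * nbar)
    s2 <- sum(ni * (pi_ - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(ni * hi) / (r * nbar)
    a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# Phi_ST by literal sum-of-squares decomposition over the individual
# pairwise distance matrix
phi_st_oracle <- function(D_ind, pop) {
  N <- nrow(D_ind)
  P <- length(unique(pop))
  sst <- 0
  for (i in 1:(N - 1)) for (j in (i + 1):N) sst <- sst + D_ind[i, j]^2
  sst <- sst / N
  ssw <- 0
  for (p in unique(pop)) {
    idx <- which(pop == p)
    s <- 0
    if (length(idx) > 1) {
      for (i in idx) for (j in idx) if (i < j) s <- s + D_ind[i, j]^2
    }
    ssw <- ssw + s / length(idx)
  }
  ssa <- sst - ssw
  ni <- as.numeric(table(pop))
  msw <- ssw / (N - P)
  nprime <- (N - sum(ni^2) / N) / (P - 1)
  sa <- (ssa / (P - 1) - msw) / nprime
  sa / (sa + msw)
}

# one replicate of the two-parameter error process, written
# independently of the package generator
sim_replicate_oracle <- function(truth, ladder, d, f) {
  surv <- truth[runif(2) >= d]
  if (length(surv) && runif(1) < f) {
    i <- sample.int(length(surv), 1)
    surv[i] <- sample(setdiff(ladder, surv[i]), 1)
  }
  sort(surv)
}

# exact outcome distribution of the error model by explicit event
# enumeration (drop pattern x false-replacement choice)
outcome_dist_oracle <- function(truth, ladder, d, f) {
  probs <- list()
  `%||%` <- function(a, b) if (is.null(a)) b else a
  add <- function(o, p) {
    key <- if (length(o)) paste(o, collapse = "/") else "none"
    probs[[key]] <<- (probs[[key]] %||% 0) + p
  }
  for (k1 in 0:1) for (k2 in 0:1) {
    dp <- d^(k1 + k2) * (1 - d)^(2 - k1 - k2)
    S <- truth[c(k1, k2) == 0]
    if (!length(S)) { add(integer(0), dp); next }
    add(sort(S), dp * (1 - f))
    for (i in seq_along(S)) for (x in setdiff(ladder, S[i])) {
      S2 <- S; S2[i] <- x
      add(sort(S2), dp * f / (length(S) * (length(ladder) - 1)))
    }
  }
  probs
}

# literal transcription of the multiple-tubes calling contract
consensus_rule_oracle <- function(obs_list, het_min = 2, hom_min = 5) {
  seen <- unlist(lapply(obs_list, unique))
  pair_keys <- vapply(obs_list, function(o) {
    u <- unique(o)
    if (length(u) == 2) paste(sort(u), collapse = "/") else NA_character_
  }, character(1))
  pc <- table(pair_keys[!is.na(pair_keys)])
  if (length(pc) && max(pc) >= het_min) {
    best <- names(pc)[pc == max(pc)]
    if (length(best) > 1) return(list(call = "failed"))
    al <- as.integer(strsplit(best, "/")[[1]])
    return(list(call = "het", a = al[1], b = al[2]))
  }
  ac <- table(seen)
  if (length(ac) == 1 && max(ac) >= hom_min) {
    a <- as.integer(names(ac))
    return(list(call = "hom", a = a, b = a))
  }
  list(call = "failed")
}

# random DNA tools
rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")
mutate_at <- function(s, pos) {
  ch <- strsplit(s, "")[[1]]
  for (p in pos) ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
  paste(ch, collapse = "")
}

# long genotype data.frame from a list of per-individual 2-column
# matrices
long_geno <- function(mats, loci = NULL) {
  ids <- names(mats)
  L <- nrow(mats[[1]])
  if (is.null(loci)) loci <- sprintf("L%02d", seq_len(L))
  do.call(rbind, lapply(ids, function(id) {
    data.frame(individual_id = id, locus_id = loci,
               allele_a = pmin(mats[[id]][, 1], mats[[id]][, 2]),
               allele_b = pmax(mats[[id]][, 1], mats[[id]][, 2]),
               stringsAsFactors = FALSE)
  }))
}

# HWE genotype draw
hwe_draw <- function(n, p, alleles = seq_along(p)) {
  cbind(sample(alleles, n, TRUE, p), sample(alleles, n, TRUE, p))
}

# a 7-allele dinucleotide ladder for locus l (bp sizes)
allele_bp_seq <- function(l) 100L + (l - 1L) * 30L + 2L * (0:6)
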