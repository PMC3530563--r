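## Population diversity and differentiation statistics.

#' Per-population diversity indices
#'
#' Observed heterozygosity `H_O` (fraction of heterozygous individuals
#' per locus, averaged over loci), unbiased expected heterozygosity
#' `H_E = (2n/(2n-1)) (1 - sum p_i^2)` per locus averaged over loci,
#' mean allele count `A`, and -- when sequences are supplied -- percent
#' nucleotide diversity `pi` (average pairwise sequence distance within
#' the population, expressed as a percentage).
#'
#' @param genotypes long data.frame (`individual_id` or `sample_id`,
#'   `locus_id`, `allele_a`, `allele_b`).
#' @param populations named vector id -> population label.
#' @param sequences optional `sequence_set`, one entry per individual
#'   (names matching genotype ids or `seq_populations` given).
#' @param seq_populations optional named vector sequence id -> pop.
#' @param pi_model distance model for nucleotide diversity.
#' @return data.frame of class `diversity_report`: one row per
#'   population with `n`, `A`, `H_E`, `H_O`, `pi_percent`.
#' @export
diversity <- function(genotypes, populations, sequences = NULL,
                      seq_populations = NULL,
                      pi_model = c("p_distance", "K2P")) {
  pi_model <- match.arg(pi_model)
  idcol <- if ("individual_id" %in% names(genotypes)) "individual_id"
           else "sample_id"
  g <- genotypes[!is.na(genotypes$allele_a) & !is.na(genotypes$allele_b), ]
  g$pop <- unname(populations[g[[idcol]]])
  sizes <- tapply(g[[idcol]], g$pop, function(x) length(unique(x)))
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warning("excluding populations with a single individual: ",
            paste(small, collapse = ", "))
    g <- g[!g$pop %in% small, ]
  }
  if (!nrow(g)) stop("no population with >= 2 individuals")
  pops <- sort(unique(g$pop))
  rows <- lapply(pops, function(p) {
    gp <- g[g$pop == p, ]
    per_locus <- lapply(split(gp, gp$locus_id), function(gl) {
      n <- nrow(gl)
      al <- c(gl$allele_a, gl$allele_b)
      pfreq <- as.numeric(table(al)) / (2 * n)
      he <- if (n > 0) (2 * n / (2 * n - 1)) * (1 - sum(pfreq^2)) else NA
      c(A = length(unique(al)), H_E = he,
        H_O = mean(gl$allele_a != gl$allele_b), n = n)
    })
    m <- do.call(rbind, per_locus)
    pi_pct <- NA_real_
    if (!is.null(sequences)) {
      sp <- seq_populations
      if (is.null(sp)) sp <- populations[names(sequences)]
      ss <- sequences[!is.na(sp) & sp == p]
      if (length(ss) >= 2L) {
        D <- pairwise_distances(as_sequence_set(ss), model =
          if (pi_model == "K2P") "K2P" else "p_distance")
        pi_pct <- mean(D[upper.tri(D)]) * 100
      }
    }
    data.frame(population = p, n = max(m[, "n"]),
               A = mean(m[, "A"]), H_E = mean(m[, "H_E"]),
               H_O = mean(m[, "H_O"]), pi_percent = pi_pct,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("diversity_report", "data.frame")
  out
}

#' Exact test of Hardy-Weinberg proportions
#'
#' Conditional exact test on the genotype table given allele counts:
#' the p-value is the total probability of tables no more probable
#' than the observed one.  For two alleles the table space is
#' enumerated completely; otherwise the null distribution is sampled
#' by Monte-Carlo re-pairing of the allele vector.
#'
#' @param allele_a,allele_b integer allele vectors (one entry per
#'   individual); `NA` pairs are dropped.
#' @param n_mc Monte-Carlo re-pairings for multi-allelic loci.
#' @return p-value; `attr(, "method")` records the route, monomorphic
#'   loci return 1 with a note.
#' @export
hwe_test <- function(allele_a, allele_b, n_mc = 2000L) {
  keep <- !is.na(allele_a) & !is.na(allele_b)
  a <- allele_a[keep]; b <- allele_b[keep]
  n <- length(a)
  if (n < 1L) stop("no genotypes")
  alleles <- sort(unique(c(a, b)))
  if (length(alleles) < 2L) {
    p <- 1
    attr(p, "method") <- "monomorphic locus: p = 1"
    return(p)
  }
  log_table_prob <- function(av, bv) {
    # P(table | allele counts) = n! 2^h prod(a_j!) / (prod n_ij! (2n)!)
    het <- sum(av != bv)
    gt <- table(paste(pmin(av, bv), pmax(av, bv)))
    ac <- table(c(av, bv))
    lgamma(n + 1) + het * log(2) + sum(lgamma(ac + 1)) -
      sum(lgamma(gt + 1)) - lgamma(2 * n + 1)
  }
  obs <- log_table_prob(a, b)
  if (length(alleles) == 2L) {
    n1 <- sum(c(a, b) == alleles[1L])
    hs <- seq(n1 %% 2L, min(n1, 2L * n - n1), by = 2L)
    logp <- vapply(hs, function(h) {
      n11 <- (n1 - h) / 2; n22 <- n - n11 - h
      lgamma(n + 1) + h * log(2) + lgamma(n1 + 1) + lgamma(2 * n - n1 + 1) -
        lgamma(n11 + 1) - lgamma(h + 1) - lgamma(n22 + 1) - lgamma(2 * n + 1)
    }, numeric(1L))
    p <- sum(exp(logp)[logp <= obs + 1e-9])
    attr(p, "method") <- "complete enumeration (2 alleles)"
    return(p)
  }
  pool <- c(a, b)
  hits <- 0L
  for (i in seq_len(n_mc)) {
    perm <- sample(pool)
    av <- perm[seq_len(n)]; bv <- perm[n + seq_len(n)]
    if (log_table_prob(av, bv) <= obs + 1e-9) hits <- hits + 1L
  }
  p <- (hits + 1) / (n_mc + 1)
  attr(p, "method") <- sprintf("Monte-Carlo re-pairing (%d draws)", n_mc)
  p
}

#' Permutation G-test of linkage disequilibrium
#'
#' G statistic on the contingency table of composite (unordered)
#' genotypes at two loci, with a Monte-Carlo permutation null obtained
#' by shuffling one locus's genotypes across individuals.
#'
#' @param a1,b1 genotypes at the first locus.
#' @param a2,b2 genotypes at the second locus.
#' @param n_perm permutations.
#' @return p-value with `attr(, "G")`.
#' @export
ld_test <- function(a1, b1, a2, b2, n_perm = 1000L) {
  keep <- !is.na(a1) & !is.na(b1) & !is.na(a2) & !is.na(b2)
  g1 <- paste(pmin(a1, b1), pmax(a1, b1))[keep]
  g2 <- paste(pmin(a2, b2), pmax(a2, b2))[keep]
  if (length(unique(g1)) < 2L || length(unique(g2)) < 2L) {
    p <- 1
    attr(p, "method") <- "monomorphic composite genotypes: p = 1"
    return(p)
  }
  gstat <- function(x, y) {
    tab <- table(x, y)
    e <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    keep <- tab > 0
    2 * sum(tab[keep] * log(tab[keep] / e[keep]))
  }
  obs <- gstat(g1, g2)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    if (gstat(g1, sample(g2)) >= obs - 1e-12) hits <- hits + 1L
  }
  p <- (hits + 1) / (n_perm + 1)
  attr(p, "G") <- obs
  p
}

#' Bonferroni adjustment of a p-value family
#' @param p numeric vector of p-values.
#' @return adjusted p-values (capped at 1).
#' @export
bonferroni <- function(p) p.adjust(p, method = "bonferroni")

## ---- Weir-Cockerham theta -------------------------------------------

# genotypes: long df; populations: named vector id -> pop
# returns list(per-locus matrices) used by theta computations
theta_prepare <- function(genotypes, populations) {
  idcol <- if ("individual_id" %in% names(genotypes)) "individual_id"
           else "sample_id"
  g <- genotypes[!is.na(genotypes$allele_a) & !is.na(genotypes$allele_b), ]
  ids <- g[[idcol]]
  pop <- unname(populations[ids])
  keep <- !is.na(pop)
  g <- g[keep, ]; ids <- ids[keep]; pop <- pop[keep]
  lapply(split(seq_len(nrow(g)), g$locus_id), function(rows) {
    list(mat = cbind(g$allele_a[rows], g$allele_b[rows]),
         pop = pop[rows], id = ids[rows])
  })
}

# Weir & Cockerham (1984) variance components for one locus,
# vectorised over alleles; pop is an integer code vector in 1..r
# (permutation loops call this heavily)
wc_components_locus <- function(mat, pop, r = max(pop)) {
  ni <- tabulate(pop, r)
  if (r < 2L || any(ni < 1L)) return(NULL)
  alleles <- sort(unique(as.vector(mat)))
  if (length(alleles) < 2L) return(NULL)
  m <- nrow(mat)
  av <- match(mat[, 1L], alleles)
  bv <- match(mat[, 2L], alleles)
  A <- length(alleles)
  M <- matrix(0, m, A)
  idx <- cbind(seq_len(m), av)
  M[idx] <- M[idx] + 1
  idx <- cbind(seq_len(m), bv)
  M[idx] <- M[idx] + 1
  het <- av != bv
  H <- M
  H[!het, ] <- 0
  cnt <- rowsum(M, pop)         # r x A allele counts (2 per hom ind)
  hcnt <- rowsum(H, pop)        # r x A heterozygote-carrier counts
  ni <- as.numeric(ni)
  nbar <- mean(ni)
  if (nbar <= 1) return(NULL)
  nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
  p <- cnt / (2 * ni)
  h <- hcnt / ni
  pbar <- colSums(ni * p) / (r * nbar)
  s2 <- colSums(ni * (p - rep(pbar, each = r))^2) / ((r - 1) * nbar)
  hbar <- colSums(ni * h) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (1 / (nbar - 1)) *
       (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
       ((2 * nbar - 1) / (4 * nbar)) * hbar)
  cc <- hbar / 2
  cbind(a = a, b = b, c = cc)
}

theta_from_prep <- function(prep, popmap) {
  levs <- sort(unique(unname(popmap)))
  codes <- setNames(match(unname(popmap), levs), names(popmap))
  total <- c(a = 0, b = 0, c = 0)
  any_poly <- FALSE
  for (pl in prep) {
    comp <- wc_components_locus(pl$mat, unname(codes[pl$id]),
                                length(levs))
    if (is.null(comp)) next
    any_poly <- TRUE
    total <- total + colSums(comp)
  }
  if (!any_poly) stop("theta undefined: no polymorphic loci")
  theta <- total[["a"]] / sum(total)
  attr(theta, "components") <- total
  theta
}

# fast two-population theta on integer pop assignments: the per-locus
# allele indicator matrices are permutation-invariant, so only the
# rowsum grouping changes between permutations
theta_precompute <- function(prep, ids) {
  lapply(prep, function(pl) {
    alleles <- sort(unique(as.vector(pl$mat)))
    if (length(alleles) < 2L) return(NULL)
    m <- nrow(pl$mat)
    av <- match(pl$mat[, 1L], alleles)
    bv <- match(pl$mat[, 2L], alleles)
    M <- matrix(0, m, length(alleles))
    idx <- cbind(seq_len(m), av)
    M[idx] <- M[idx] + 1
    idx <- cbind(seq_len(m), bv)
    M[idx] <- M[idx] + 1
    H <- M
    H[av == bv, ] <- 0
    list(M = M, H = H, ii = match(pl$id, ids))
  })
}

theta_codes <- function(pre, assign, r) {
  total_a <- total_rest <- 0
  any_poly <- FALSE
  for (pl in pre) {
    if (is.null(pl)) next
    pop <- assign[pl$ii]
    ni <- tabulate(pop, r)
    if (any(ni < 1L)) next
    cnt <- rowsum(pl$M, pop)
    hcnt <- rowsum(pl$H, pop)
    ni <- as.numeric(ni)
    nbar <- mean(ni)
    if (nbar <= 1) next
    nc <- (r * nbar - sum(ni^2) / (r * nbar)) / (r - 1)
    p <- cnt / (2 * ni)
    h <- hcnt / ni
    pbar <- colSums(ni * p) / (r * nbar)
    s2 <- colSums(ni * (p - rep(pbar, each = r))^2) / ((r - 1) * nbar)
    hbar <- colSums(ni * h) / (r * nbar)
    a <- (nbar / nc) *
      (s2 - (1 / (nbar - 1)) *
         (pbar * (1 - pbar) - ((r - 1) / r) * s2 - hbar / 4))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - ((r - 1) / r) * s2 -
         ((2 * nbar - 1) / (4 * nbar)) * hbar)
    cc <- hbar / 2
    any_poly <- TRUE
    total_a <- total_a + sum(a)
    total_rest <- total_rest + sum(b) + sum(cc)
  }
  if (!any_poly) return(NA_real_)
  total_a / (total_a + total_rest)
}

#' Multi-locus Weir-Cockerham theta
#'
#' The standard unbiased \eqn{F_{ST}} estimator: per-allele, per-locus
#' variance components \eqn{a} (among populations), \eqn{b} (among
#' individuals within populations) and \eqn{c} (within individuals),
#' combined as \eqn{\theta = \sum a / \sum (a+b+c)} over all alleles
#' and loci.  Negative estimates are reported as computed.
#'
#' @param genotypes long genotype data.frame.
#' @param populations named vector id -> population label.
#' @return theta, with the summed components in
#'   `attr(, "components")`.
#' @export
wc_theta <- function(genotypes, populations) {
  prep <- theta_prepare(genotypes, populations)
  theta_from_prep(prep, populations)
}

#' Pairwise theta with permutation significance
#'
#' @param genotypes,populations as in [wc_theta()].
#' @param pop_a,pop_b the two populations compared.
#' @param n_perm permutations of individuals between the two
#'   populations.
#' @return list `estimate`, `p`, `n_perm`; the p-value is the fraction
#'   of permutations reaching the observed theta, with the +1
#'   correction.
#' @export
fst_microsat <- function(genotypes, populations, pop_a, pop_b,
                         n_perm = 10000L) {
  ids <- unique(names(populations)[populations %in% c(pop_a, pop_b)])
  sub <- populations[ids]
  if (length(table(sub)) < 2L || min(table(sub)) < 2L) {
    stop("need >= 2 individuals per population")
  }
  prep <- theta_prepare(genotypes, sub)
  obs <- theta_from_prep(prep, sub)
  pre <- theta_precompute(prep, ids)
  assign0 <- as.integer(factor(unname(sub[ids]),
                               levels = sort(unique(unname(sub)))))
  hits <- 0L
  for (i in seq_len(n_perm)) {
    if (theta_codes(pre, sample(assign0), 2L) >= obs - 1e-12) {
      hits <- hits + 1L
    }
  }
  list(estimate = as.numeric(obs), p = (hits + 1) / (n_perm + 1),
       n_perm = n_perm)
}

## ---- AMOVA Phi_ST ----------------------------------------------------

phi_from_counts <- function(C, D2) {
  # C: pops x haplotypes count matrix; D2: squared distance matrix
  ni <- rowSums(C)
  N <- sum(ni)
  P <- nrow(C)
  cross <- C %*% D2 %*% t(C)
  ss_total <- sum(colSums(C) * (D2 %*% colSums(C))) / (2 * N)
  ss_within <- sum(diag(cross) / (2 * ni))
  ss_among <- ss_total - ss_within
  df_a <- P - 1
  df_w <- N - P
  if (df_w <= 0) return(NA_real_)
  ms_w <- ss_within / df_w
  n_prime <- (N - sum(ni^2) / N) / df_a
  sigma_a <- (ss_among / df_a - ms_w) / n_prime
  denom <- sigma_a + ms_w
  if (abs(denom) < 1e-300) return(0)
  sigma_a / denom
}

#' AMOVA Phi_ST for mtDNA haplotypes
#'
#' Distance-based analogue of \eqn{F_{ST}}: the among-population share
#' of molecular variance computed from the sum-of-squares
#' decomposition of squared inter-haplotype distances (Kimura
#' two-parameter by default), with a permutation test that shuffles
#' individuals among populations.
#'
#' @param sequences aligned `sequence_set`, one entry per individual.
#' @param populations named vector sequence id -> population label.
#' @param distance_model `"K2P"` or `"p_distance"`.
#' @param n_perm permutations.
#' @return list `estimate`, `p`, `n_perm`.
#' @export
phi_st_mtdna <- function(sequences, populations,
                         distance_model = c("K2P", "p_distance"),
                         n_perm = 10000L) {
  distance_model <- match.arg(distance_model)
  sequences <- as_sequence_set(sequences)
  pop <- populations[names(sequences)]
  keep <- !is.na(pop)
  sequences <- sequences[keep]; pop <- unname(pop[keep])
  class(sequences) <- "sequence_set"
  if (min(table(pop)) < 2L) stop("need >= 2 sequences per population")
  hid <- haplotype_ids(sequences)
  haps <- attr(hid, "haplotypes")
  if (length(haps) < 2L) {
    return(list(estimate = 0, p = 1, n_perm = 0L,
                note = "all sequences identical"))
  }
  D <- pairwise_distances(haps, model = distance_model)
  D2 <- D^2
  z <- factor(unname(hid[names(sequences)]), levels = rownames(D))
  make_C <- function(g) {
    t(vapply(levels(factor(g)), function(p)
      tabulate(z[g == p], nbins = nlevels(z)), numeric(nlevels(z))))
  }
  obs <- phi_from_counts(make_C(pop), D2)
  hits <- 0L
  for (i in seq_len(n_perm)) {
    if (phi_from_counts(make_C(sample(pop)), D2) >= obs - 1e-12) {
      hits <- hits + 1L
    }
  }
  list(estimate = obs, p = (hits + 1) / (n_perm + 1), n_perm = n_perm)
}

## ---- pairwise matrices ----------------------------------------------

new_pairwise_fst <- function(est, p, n_perm, marker) {
  out <- list(estimate = est, p = p, n_perm = n_perm, marker = marker)
  class(out) <- "pairwise_fst"
  out
}

#' Pairwise differentiation matrices
#'
#' `pairwise_theta()` computes every pairwise microsatellite
#' Weir-Cockerham theta; `pairwise_phist()` every pairwise mtDNA
#' Phi_ST.  Both return a `pairwise_fst` object whose print method
#' shows estimates below the diagonal and permutation p-values above
#' it.
#'
#' @param genotypes,populations,sequences,distance_model,n_perm as in
#'   [fst_microsat()] / [phi_st_mtdna()].
#' @return a `pairwise_fst` object.
#' @export
pairwise_theta <- function(genotypes, populations, n_perm = 1000L) {
  pops <- sort(unique(unname(populations)))
  k <- length(pops)
  est <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  pv <- est
  if (k >= 2L) for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    r <- fst_microsat(genotypes, populations, pops[i], pops[j], n_perm)
    est[i, j] <- est[j, i] <- r$estimate
    pv[i, j] <- pv[j, i] <- r$p
  }
  new_pairwise_fst(est, pv, n_perm, "microsatellite_theta")
}

#' @rdname pairwise_theta
#' @export
pairwise_phist <- function(sequences, populations,
                           distance_model = c("K2P", "p_distance"),
                           n_perm = 1000L) {
  distance_model <- match.arg(distance_model)
  pop <- populations[names(sequences)]
  counts <- table(pop)
  small <- names(counts)[counts < 2L]
  if (length(small)) {
    warning("excluding units with < 2 sequences: ",
            paste(small, collapse = ", "))
  }
  pops <- sort(setdiff(names(counts), small))
  k <- length(pops)
  est <- matrix(NA_real_, k, k, dimnames = list(pops, pops))
  pv <- est
  if (k >= 2L) for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    ids <- names(pop)[pop %in% c(pops[i], pops[j])]
    r <- phi_st_mtdna(sequences[names(sequences) %in% ids],
                      populations, distance_model, n_perm)
    est[i, j] <- est[j, i] <- r$estimate
    pv[i, j] <- pv[j, i] <- r$p
  }
  new_pairwise_fst(est, pv, n_perm, "mtdna_phi_st")
}

#' Regional subdivision analysis
#'
#' Re-runs pairwise mtDNA Phi_ST after splitting one population into
#' sampling regions, against the remaining populations: the design
#' used to localise within-park structure (e.g. a southern region that
#' differentiates from the rest of its park but not from the park
#' across the barrier).
#'
#' @param sequences aligned `sequence_set` per individual.
#' @param populations named vector sequence id -> population.
#' @param regions named vector (subset of sequence ids) -> region
#'   label; these replace the population label for those individuals.
#' @param ... passed to [pairwise_phist()].
#' @return a `pairwise_fst` object (empty matrices when fewer than two
#'   units remain).
#' @export
regional_subdivision <- function(sequences, populations, regions, ...) {
  lab <- populations
  lab[names(regions)] <- regions
  pairwise_phist(sequences, lab, ...)
}

#' @export
print.pairwise_fst <- function(x, digits = 4, ...) {
  cat("Pairwise", if (x$marker == "microsatellite_theta")
    "Weir-Cockerham theta (microsatellites)" else "Phi_ST (mtDNA)",
    "-", x$n_perm, "permutations\n")
  cat("estimates below the diagonal, p-values above\n")
  m <- x$estimate
  show <- matrix("", nrow(m), ncol(m), dimnames = dimnames(m))
  for (i in seq_len(nrow(m))) for (j in seq_len(ncol(m))) {
    if (i > j) show[i, j] <- formatC(m[i, j], digits = digits, format = "f")
    if (i < j) show[i, j] <- formatC(x$p[i, j], digits = digits, format = "f")
  }
  print(as.data.frame(show), right = TRUE)
  invisible(x)
}

#' Export a pairwise matrix in combined lower/upper-triangle form
#' @param x a `pairwise_fst` object.
#' @param path CSV path.
#' @export
write_pairwise_fst <- function(x, path) {
  m <- x$estimate
  out <- m
  out[upper.tri(out)] <- x$p[upper.tri(x$p)]
  diag(out) <- NA
  write.csv(cbind(data.frame(population = rownames(m)), out), path,
            row.names = FALSE)
  invisible(path)
}
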