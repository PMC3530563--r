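## Multiple-tubes consensus genotyping.
##
## A replicate's observation is the multiset of surviving allele calls:
## (a,b) both seen, (a,a) a homozygous-looking double call, (a,NA) a
## half-call, (NA,NA) a failed reaction.

obs_multiset <- function(a, b) {
  if (is.na(a)) integer(0) else if (is.na(b)) a else c(a, b)
}

call_one_locus <- function(reps_a, reps_b, het_threshold, hom_threshold) {
  obs <- mapply(obs_multiset, reps_a, reps_b, SIMPLIFY = FALSE)
  seen <- unlist(lapply(obs, unique))
  if (!length(seen)) {
    return(list(call = "failed", a = NA_integer_, b = NA_integer_,
                n_support = 0L))
  }
  allele_count <- table(seen)  # replicates in which each allele appears
  # heterozygous: some unordered pair {a,b} co-observed often enough
  pairs <- vapply(obs, function(o) {
    u <- unique(o)
    if (length(u) == 2L) paste(sort(u), collapse = "/") else NA_character_
  }, character(1L))
  pair_count <- table(pairs[!is.na(pairs)])
  if (length(pair_count) && max(pair_count) >= het_threshold) {
    best <- names(pair_count)[pair_count == max(pair_count)]
    if (length(best) > 1L) {
      # two equally supported conflicting heterozygotes: ambiguous
      return(list(call = "failed", a = NA_integer_, b = NA_integer_,
                  n_support = 0L))
    }
    al <- as.integer(strsplit(best, "/", fixed = TRUE)[[1L]])
    return(list(call = "het", a = al[1L], b = al[2L],
                n_support = as.integer(max(pair_count))))
  }
  # homozygous: a single allele, never contradicted, seen often enough
  if (length(allele_count) == 1L &&
      max(allele_count) >= hom_threshold) {
    a <- as.integer(names(allele_count))
    return(list(call = "hom", a = a, b = a,
                n_support = as.integer(allele_count[[1L]])))
  }
  list(call = "failed", a = NA_integer_, b = NA_integer_, n_support = 0L)
}

#' Call consensus genotypes from replicate data
#'
#' Implements the multiple-tubes acceptance rules: a locus is called
#' heterozygous `(a,b)` when the two alleles are observed *together* in
#' at least `het_threshold` replicates; homozygous `(a,a)` when `a` is
#' the only allele ever observed and it appears in at least
#' `hom_threshold` replicates; otherwise the locus fails.  Alleles seen
#' only once and never replicated are putative false alleles: they can
#' never enter a call (a singleton cannot reach the heterozygote
#' threshold) but they do contradict a homozygote.  Samples whose loci
#' all fail are excluded and reported in `attr(, "discarded")`.
#'
#' @param table a replicate [genotype_table()].
#' @param het_threshold minimum replicates co-showing both alleles of a
#'   heterozygote (default 2).
#' @param hom_threshold minimum replicates showing the single allele of
#'   a homozygote (default 5).
#' @return data.frame of class `consensus_calls` with columns
#'   `sample_id`, `locus_id`, `call` (`het`/`hom`/`failed`),
#'   `allele_a`, `allele_b`, `n_support`, `n_replicates`.
#' @export
call_consensus <- function(table, het_threshold = 2L, hom_threshold = 5L) {
  table <- validate_genotype_table(table)
  key <- interaction(table$sample_id, table$locus_id, drop = TRUE, sep = "\r")
  groups <- split(seq_len(nrow(table)), key)
  out <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    rows <- groups[[i]]
    res <- call_one_locus(table$allele_a[rows], table$allele_b[rows],
                          het_threshold, hom_threshold)
    out[[i]] <- data.frame(sample_id = table$sample_id[rows[1L]],
                           locus_id = table$locus_id[rows[1L]],
                           call = res$call, allele_a = res$a,
                           allele_b = res$b, n_support = res$n_support,
                           n_replicates = length(rows),
                           stringsAsFactors = FALSE)
  }
  cons <- do.call(rbind, out)
  rownames(cons) <- NULL
  ok <- tapply(cons$call != "failed", cons$sample_id, any)
  discarded <- names(ok)[!ok]
  if (length(discarded)) {
    cons <- cons[!cons$sample_id %in% discarded, ]
  }
  attr(cons, "discarded") <- data.frame(
    sample_id = discarded,
    reason = rep("all loci failed replication thresholds",
                 length(discarded)),
    stringsAsFactors = FALSE)
  attr(cons, "thresholds") <- c(het = het_threshold, hom = hom_threshold)
  class(cons) <- c("consensus_calls", "data.frame")
  cons
}

#' Exact outcome probability of one replicate under the error model
#'
#' Enumerates the latent events of the two-parameter model: each true
#' allele copy drops independently with probability `d`; with
#' probability `f` one surviving call (uniform) is replaced by a
#' uniform other allele from `alleles`.  The returned probability is
#' the total mass of the observed call multiset.
#'
#' @param obs integer vector: the observed calls (`integer(0)` for a
#'   failed reaction, one value for a half-call, two values otherwise).
#' @param truth length-2 integer vector: the candidate true genotype.
#' @param alleles the allele universe used for false-allele
#'   replacement.
#' @param d,f dropout and false-allele rates.
#' @return probability in \[0, 1\].
#' @export
replicate_outcome_prob <- function(obs, truth, alleles, d, f) {
  obs <- sort(obs)
  same <- function(x) length(x) == length(obs) && all(sort(x) == obs)
  total <- 0
  for (k1 in 0:1) for (k2 in 0:1) {
    dp <- d^(k1 + k2) * (1 - d)^(2 - k1 - k2)
    S <- truth[c(k1, k2) == 0L]
    if (!length(S)) {
      if (!length(obs)) total <- total + dp
      next
    }
    if (same(S)) total <- total + dp * (1 - f)
    if (f > 0) {
      for (i in seq_along(S)) {
        repl <- setdiff(alleles, S[i])
        if (!length(repl)) next
        for (x in repl) {
          S2 <- S; S2[i] <- x
          if (same(S2)) {
            total <- total + dp * f / length(S) / length(repl)
          }
        }
      }
    }
  }
  total
}

UNSEEN_ALLELE <- -1L

candidate_truths <- function(observed_alleles, call) {
  al <- sort(observed_alleles)
  cands <- list()
  for (i in seq_along(al)) for (j in i:length(al)) {
    cands[[length(cands) + 1L]] <- c(al[i], al[j])
  }
  for (a in al) cands[[length(cands) + 1L]] <- c(a, UNSEEN_ALLELE)
  cands
}

#' Maximum-likelihood reliability of consensus genotypes
#'
#' For each called locus the posterior probability that the consensus
#' call is the true genotype, given every replicate outcome under the
#' dropout/false-allele model, with a uniform prior over a candidate
#' truth set restricted to genotypes composed of the alleles observed
#' at that sample-locus plus one "unseen allele" pseudo-candidate.
#' A sample's reliability `R` is the product over its called loci;
#' samples below `threshold` are flagged for further replication.
#'
#' @param consensus a [call_consensus()] result.
#' @param table the replicate [genotype_table()] behind it.
#' @param d,f dropout / false-allele rate estimates (see
#'   [estimate_error_rates()]).
#' @param threshold flag samples with `R` below this (default 0.99).
#' @return data.frame `sample_id`, `reliability`, `n_called`,
#'   `flagged`; per-locus posteriors in `attr(, "per_locus")`.
#' @export
genotype_reliability <- function(consensus, table, d, f, threshold = 0.99) {
  if (d < 0 || d >= 1 || f < 0 || f >= 1) {
    stop("error rates d and f must lie in [0, 1)")
  }
  called <- consensus[consensus$call != "failed", ]
  per_locus <- numeric(nrow(called))
  for (i in seq_len(nrow(called))) {
    rows <- table$sample_id == called$sample_id[i] &
      table$locus_id == called$locus_id[i]
    obs_list <- mapply(obs_multiset, table$allele_a[rows],
                       table$allele_b[rows], SIMPLIFY = FALSE)
    seen <- sort(unique(unlist(obs_list)))
    universe <- c(seen, UNSEEN_ALLELE)
    cands <- candidate_truths(seen, called$call[i])
    lik <- vapply(cands, function(tr) {
      prod(vapply(obs_list, replicate_outcome_prob, numeric(1L),
                  truth = tr, alleles = universe, d = d, f = f))
    }, numeric(1L))
    target <- c(called$allele_a[i], called$allele_b[i])
    hit <- vapply(cands, function(tr) all(sort(tr) == sort(target)),
                  logical(1L))
    per_locus[i] <- if (sum(lik) > 0) sum(lik[hit]) / sum(lik) else 0
  }
  pl <- data.frame(sample_id = called$sample_id,
                   locus_id = called$locus_id,
                   posterior = per_locus, stringsAsFactors = FALSE)
  rel <- tapply(per_locus, called$sample_id, prod)
  out <- data.frame(sample_id = names(rel),
                    reliability = as.numeric(rel),
                    n_called = as.integer(table(called$sample_id)[names(rel)]),
                    stringsAsFactors = FALSE)
  out$flagged <- out$reliability < threshold
  attr(out, "per_locus") <- pl
  rownames(out) <- NULL
  out
}

# Symbolic outcome probability: coefficients of the polynomial
#   P(obs | truth) = (1-f) * sum_k nf[k] d^(k-1) (1-d)^(3-k)
#                  +    f  * sum_k fa[k] d^(k-1) (1-d)^(3-k)
# over the drop-count k-1 in {0,1,2}, with the false-allele event
# replacing one surviving call by one of (m-1) alternatives.
outcome_poly <- function(obs, truth, m) {
  obs <- sort(obs)
  nf <- fa <- numeric(3L)
  same <- function(x) length(x) == length(obs) && all(sort(x) == obs)
  pool <- unique(c(obs, truth))
  for (k1 in 0:1) for (k2 in 0:1) {
    k <- k1 + k2 + 1L
    S <- truth[c(k1, k2) == 0L]
    if (!length(S)) {
      if (!length(obs)) { nf[k] <- nf[k] + 1; fa[k] <- fa[k] + 1 }
      next
    }
    if (same(S)) nf[k] <- nf[k] + 1
    for (i in seq_along(S)) {
      for (x in setdiff(pool, S[i])) {
        S2 <- S; S2[i] <- x
        if (same(S2)) fa[k] <- fa[k] + 1 / (length(S) * (m - 1))
      }
    }
  }
  c(nf, fa)
}

#' Estimate genotyping error rates from replicate discordance
#'
#' Without truth: maximum-likelihood estimates of the dropout rate `d`
#' and false-allele rate `f` from the full replicate data, with the
#' unknown true genotype of every (sample, locus) marginalised over a
#' candidate set built from its observed alleles (all homozygotes and
#' heterozygotes, plus an unseen-allele heterozygote), weighted by a
#' jointly estimated heterozygosity parameter.  Marginalising rather
#' than conditioning on the consensus call avoids the survivorship
#' bias of using only loci that passed the replication thresholds.
#' With simulation truth (`truth` + `metapop`), plug-in empirical
#' rates are returned via [empirical_error_rates()].
#'
#' @param table a replicate [genotype_table()].
#' @param consensus ignored (kept for call compatibility).
#' @param truth,metapop optional simulation truth.
#' @return named vector `c(d = , f = )`, with the heterozygosity
#'   nuisance estimate in `attr(, "h")`.
#' @export
estimate_error_rates <- function(table, consensus = NULL,
                                 truth = NULL, metapop = NULL) {
  if (!is.null(truth) && !is.null(metapop)) {
    return(empirical_error_rates(table, truth, metapop))
  }
  key <- paste(table$sample_id, table$locus_id, sep = "\r")
  counts <- table(key)
  use <- names(counts)[counts >= 2L]
  if (!length(use)) {
    stop("error-rate estimation needs >= 2 replicates for some (sample, locus)")
  }
  m_by_locus <- vapply(
    split(c(table$allele_a, table$allele_b),
          rep(table$locus_id, 2L)),
    function(x) max(length(unique(x[!is.na(x)])) + 1L, 2L), numeric(1L))
  idx <- split(seq_len(nrow(table)), key)[use]
  if (length(idx) > 3000L) idx <- idx[seq_len(3000L)]
  NF <- FA <- list(); gc_id <- integer(0)
  cand_group <- integer(0); cand_is_het <- logical(0)
  gc <- 0L
  for (g in seq_along(idx)) {
    rows <- idx[[g]]
    locus <- table$locus_id[rows[1L]]
    m <- m_by_locus[[locus]]
    obs_list <- mapply(obs_multiset, table$allele_a[rows],
                       table$allele_b[rows], SIMPLIFY = FALSE)
    u <- sort(unique(unlist(obs_list)))
    cands <- list()
    if (length(u)) {
      for (i in seq_along(u)) for (j in i:length(u)) {
        cands[[length(cands) + 1L]] <- c(u[i], u[j])
      }
      for (a in u) cands[[length(cands) + 1L]] <- c(a, UNSEEN_ALLELE)
    } else {
      cands[[1L]] <- c(UNSEEN_ALLELE, UNSEEN_ALLELE)
    }
    for (ci in seq_along(cands)) {
      gc <- gc + 1L
      cand_group[gc] <- g
      cand_is_het[gc] <- cands[[ci]][1L] != cands[[ci]][2L]
      for (o in obs_list) {
        po <- outcome_poly(o, cands[[ci]], m)
        NF[[length(NF) + 1L]] <- po[1:3]
        FA[[length(FA) + 1L]] <- po[4:6]
        gc_id[length(NF)] <- gc
      }
    }
  }
  NF <- do.call(rbind, NF); FA <- do.call(rbind, FA)
  n_group <- length(idx)
  # per-group candidate-count normalisers for the mixture weights
  n_het <- tabulate(cand_group[cand_is_het], nbins = n_group)
  n_hom <- tabulate(cand_group[!cand_is_het], nbins = n_group)
  negll <- function(par) {
    d <- par[1L]; f <- par[2L]; h <- par[3L]
    dvec <- c((1 - d)^2, d * (1 - d), d^2)
    p <- (1 - f) * (NF %*% dvec) + f * (FA %*% dvec)
    ll_gc <- rowsum(log(pmax(p, 1e-300)), gc_id)
    w <- ifelse(cand_is_het,
                h / pmax(n_het[cand_group], 1L),
                (1 - h) / pmax(n_hom[cand_group], 1L))
    w[cand_is_het & n_hom[cand_group] == 0L] <-
      1 / n_het[cand_group][cand_is_het & n_hom[cand_group] == 0L]
    w[!cand_is_het & n_het[cand_group] == 0L] <-
      1 / n_hom[cand_group][!cand_is_het & n_het[cand_group] == 0L]
    mx <- tapply(ll_gc[, 1L], cand_group, max)[cand_group]
    s <- rowsum(w * exp(ll_gc[, 1L] - mx), cand_group)
    -sum(log(pmax(s[, 1L], 1e-300)) +
           tapply(ll_gc[, 1L], cand_group, max))
  }
  # the mixture surface can be multimodal on small data: multistart
  starts <- list(c(0.1, 0.02, 0.5), c(0.01, 0.005, 0.7),
                 c(0.3, 0.1, 0.4))
  fits <- lapply(starts, function(s)
    optim(s, negll, method = "L-BFGS-B",
          lower = c(1e-6, 1e-6, 0.01), upper = c(0.6, 0.4, 0.99)))
  fit <- fits[[which.min(vapply(fits, `[[`, numeric(1L), "value"))]]
  est <- fit$par
  # snap boundary solutions from fully concordant data to zero
  est[1:2][est[1:2] < 2e-6] <- 0
  out <- c(d = est[1L], f = est[2L])
  attr(out, "h") <- est[3L]
  out
}
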