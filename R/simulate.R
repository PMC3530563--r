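#' Simulation configuration
#'
#' Defines a five-deme metapopulation split by a dispersal barrier
#' (rift-valley style): nuclear differentiation is weak (male-mediated
#' gene flow; island-model target \eqn{F_{ST}} around 0.01), while
#' mtDNA haplotype pools are near-disjoint between the two sides
#' (female philopatry: `female_migration_rate = 0`).  Defaults mirror a
#' savannah-elephant study design: 12 microsatellite loci with up to 7
#' alleles each, a 650 bp control-region fragment, allelic dropout 0.2
#' and false-allele rate 0.05 per replicate, four PCR replicates per
#' sample, and heavy recapture sampling concentrated in one focal deme
#' (the colonised community conservation area, `CCA`).
#'
#' `freq_groups` maps demes to gene pools: demes sharing a group share
#' nuclear allele frequencies and mtDNA haplotype frequencies.  By
#' default the focal `CCA` deme shares the western pool (its animals
#' are recent colonists from the west side), so the two western parks
#' and the CCA are effectively one panmictic unit while the two eastern
#' demes are distinct.
#'
#' @param n_demes number of demes.
#' @param deme_sizes integer vector (recycled) of individuals per deme.
#' @param deme_names deme labels.
#' @param barrier_assignment named vector deme -> `"east"`/`"west"`.
#' @param freq_groups named vector deme -> gene-pool label.
#' @param n_loci,alleles_per_locus microsatellite design.
#' @param migration_rate nuclear migration proportion per generation
#'   `m`; used to derive the island-model target
#'   \eqn{F_{ST} = 1/(1+4Nm)} when `target_fst` is `NULL`.
#' @param target_fst directly parameterised nuclear target
#'   \eqn{F_{ST}} (overrides `migration_rate`).
#' @param female_migration_rate probability an individual's maternal
#'   lineage crossed the barrier (0 = complete philopatry).
#' @param n_haplotypes_per_side mtDNA haplotypes in each side's pool.
#' @param haplotype_divergence substitutions between the two side
#'   ancestors.
#' @param within_divergence substitutions between a haplotype and its
#'   side ancestor (between/within divergence defaults to 10x).
#' @param seq_length control-region fragment length (bp).
#' @param dropout_rate per-allele, per-replicate dropout probability.
#' @param false_allele_rate per-replicate spurious-allele probability.
#' @param recapture_mean mean samples per captured individual.
#' @param recapture_override named per-deme overrides of
#'   `recapture_mean` (exhaustive sampling of the focal deme).
#' @param replicates_per_sample PCR replicates per sample per locus.
#' @param max_replicates replication cap of the adaptive multiple-tubes
#'   protocol: an unresolved locus (no heterozygote pair seen twice, no
#'   uncontradicted homozygote seen five times) is replicated again up
#'   to this total before being abandoned.
#' @param sex_replicates_per_sample sexing replicates per sample.
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_demes = 5L,
                       deme_sizes = c(47L, 55L, 112L, 39L, 59L),
                       deme_names = c("AM", "TA", "CCA", "MM", "SE"),
                       barrier_assignment = c(AM = "east", TA = "east",
                                              CCA = "west", MM = "west",
                                              SE = "west"),
                       freq_groups = c(AM = "AM", TA = "TA",
                                       CCA = "west", MM = "west",
                                       SE = "west"),
                       n_loci = 12L, alleles_per_locus = 7L,
                       migration_rate = NULL, target_fst = 0.01,
                       female_migration_rate = 0,
                       n_haplotypes_per_side = 6L,
                       haplotype_divergence = 30L,
                       within_divergence = 3L,
                       seq_length = 650L,
                       dropout_rate = 0.2, false_allele_rate = 0.05,
                       recapture_mean = 1.15,
                       recapture_override = c(CCA = 2.8),
                       replicates_per_sample = 4L,
                       max_replicates = 8L,
                       sex_replicates_per_sample = 4L,
                       seed = NULL) {
  deme_sizes <- rep_len(as.integer(deme_sizes), n_demes)
  if (length(deme_names) != n_demes) {
    deme_names <- paste0("deme", seq_len(n_demes))
  }
  if (!all(deme_names %in% names(barrier_assignment))) {
    stop("barrier_assignment must cover every deme")
  }
  if (!all(deme_names %in% names(freq_groups))) {
    freq_groups <- setNames(deme_names, deme_names)
  }
  rates <- c(dropout_rate, false_allele_rate, female_migration_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("rates (dropout, false allele, female migration) must lie in [0, 1]")
  }
  if (any(deme_sizes < 2L)) stop("deme sizes must be >= 2")
  if (seq_length < 1L) stop("seq_length must be >= 1")
  if (is.null(target_fst)) {
    if (is.null(migration_rate)) stop("give migration_rate or target_fst")
    if (migration_rate < 0 || migration_rate > 1) {
      stop("migration_rate must lie in [0, 1]")
    }
    target_fst <- 1 / (1 + 4 * mean(deme_sizes) * migration_rate)
  }
  if (target_fst < 0 || target_fst > 1) {
    stop("unreachable target F_ST: ", target_fst)
  }
  cfg <- list(n_demes = n_demes, deme_sizes = deme_sizes,
              deme_names = deme_names,
              barrier_assignment = barrier_assignment[deme_names],
              freq_groups = freq_groups[deme_names],
              n_loci = as.integer(n_loci),
              alleles_per_locus = as.integer(alleles_per_locus),
              target_fst = target_fst,
              female_migration_rate = female_migration_rate,
              n_haplotypes_per_side = as.integer(n_haplotypes_per_side),
              haplotype_divergence = as.integer(haplotype_divergence),
              within_divergence = as.integer(within_divergence),
              seq_length = as.integer(seq_length),
              dropout_rate = dropout_rate,
              false_allele_rate = false_allele_rate,
              recapture_mean = recapture_mean,
              recapture_override = recapture_override,
              replicates_per_sample = as.integer(replicates_per_sample),
              max_replicates = as.integer(max_replicates),
              sex_replicates_per_sample = as.integer(sex_replicates_per_sample),
              seed = seed)
  class(cfg) <- "sim_config"
  cfg
}

locus_names <- function(cfg) sprintf("L%02d", seq_len(cfg$n_loci))

# bp size of allele j at locus l: dinucleotide ladder per locus
allele_bp <- function(l, j) 100L + (l - 1L) * 30L + 2L * (j - 1L)

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g[which.max(alpha)] <- 1
  g / sum(g)
}

mutate_sites <- function(seq_chars, n_sites) {
  if (n_sites < 1L) return(seq_chars)
  pos <- sample.int(length(seq_chars), n_sites)
  for (p in pos) {
    seq_chars[p] <- sample(setdiff(c("A", "C", "G", "T"), seq_chars[p]), 1L)
  }
  seq_chars
}

#' Simulate a structured metapopulation
#'
#' Nuclear genotypes are drawn under Hardy-Weinberg proportions from
#' gene-pool allele frequencies parameterised directly by the
#' island-model target \eqn{F_{ST}}: pool frequencies are Dirichlet
#' distributed about the ancestral frequencies with concentration
#' \eqn{(1-F_{ST})/F_{ST}}, whose realised among-pool variance matches
#' the target in expectation.  mtDNA haplotypes are generated by
#' mutating a random root sequence: the two sides of the barrier carry
#' disjoint haplotype pools separated by `haplotype_divergence`
#' substitutions, with `within_divergence` substitutions inside each
#' pool; a maternal lineage crosses sides with probability
#' `female_migration_rate`.  Sexes are Bernoulli(0.5).
#'
#' @param config a [sim_config()].
#' @return list of class `metapopulation` with elements `individuals`
#'   (data.frame: individual_id, deme, side, sex, haplotype_id),
#'   `genotypes` (long data.frame of true per-locus allele pairs in
#'   bp), `haplotypes` (a `sequence_set` of the unique haplotype
#'   sequences), `pool_freqs` and `hap_freqs` (the generating
#'   frequencies), and `config`.
#' @export
simulate_metapopulation <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.null(config$seed)) set.seed(config$seed)
  J <- config$alleles_per_locus
  L <- config$n_loci
  loci <- locus_names(config)
  groups <- unique(config$freq_groups)
  fst <- config$target_fst

  # ancestral and pool frequencies per locus
  anc <- lapply(seq_len(L), function(l) rdirichlet1(rep(2, J)))
  pool_freqs <- lapply(setNames(groups, groups), function(g) {
    lapply(seq_len(L), function(l) {
      if (fst < 1e-6) return(anc[[l]])
      if (fst > 1 - 1e-9) {
        p <- numeric(J); p[sample.int(J, 1L, prob = anc[[l]])] <- 1
        return(p)
      }
      rdirichlet1(anc[[l]] * (1 - fst) / fst)
    })
  })

  # haplotype pools
  root <- sample(c("A", "C", "G", "T"), config$seq_length, replace = TRUE)
  side_anc <- list(east = root,
                   west = mutate_sites(root, config$haplotype_divergence))
  hap_seqs <- list()
  hap_side <- character(0)
  for (side in c("east", "west")) {
    for (h in seq_len(config$n_haplotypes_per_side)) {
      id <- sprintf("%s%d", toupper(substr(side, 1, 1)), h)
      hap_seqs[[id]] <- paste(mutate_sites(side_anc[[side]],
                                           config$within_divergence),
                              collapse = "")
      hap_side[id] <- side
    }
  }
  hap_freqs <- lapply(setNames(groups, groups), function(g) {
    # haplotype frequencies are pool-specific but confined to the side
    demes <- config$deme_names[config$freq_groups == g]
    side <- unique(config$barrier_assignment[demes])[1L]
    ids <- names(hap_side)[hap_side == side]
    setNames(rdirichlet1(rep(1.5, length(ids))), ids)
  })

  ind <- list()
  gen <- list()
  n_total <- sum(config$deme_sizes)
  idx <- 0L
  for (d in seq_len(config$n_demes)) {
    deme <- config$deme_names[d]
    g <- config$freq_groups[deme]
    side <- config$barrier_assignment[deme]
    other <- setdiff(c("east", "west"), side)
    for (k in seq_len(config$deme_sizes[d])) {
      idx <- idx + 1L
      id <- sprintf("I%04d", idx)
      # maternal lineage: philopatric unless a (rare) cross-barrier migrant
      if (runif(1) < config$female_migration_rate) {
        pool <- names(hap_side)[hap_side == other]
        hap <- sample(pool, 1L)
      } else {
        hf <- hap_freqs[[g]]
        hap <- sample(names(hf), 1L, prob = hf)
      }
      a <- integer(config$n_loci); b <- integer(config$n_loci)
      for (l in seq_len(config$n_loci)) {
        p <- pool_freqs[[g]][[l]]
        al <- sample.int(J, 2L, replace = TRUE, prob = p)
        a[l] <- allele_bp(l, min(al)); b[l] <- allele_bp(l, max(al))
      }
      ind[[idx]] <- data.frame(individual_id = id, deme = deme,
                               side = unname(side),
                               sex = sample(c("M", "F"), 1L),
                               haplotype_id = hap,
                               stringsAsFactors = FALSE)
      gen[[idx]] <- data.frame(individual_id = id, locus_id = loci,
                               allele_a = a, allele_b = b,
                               stringsAsFactors = FALSE)
    }
  }
  out <- list(individuals = do.call(rbind, ind),
              genotypes = do.call(rbind, gen),
              haplotypes = as_sequence_set(unlist(hap_seqs)),
              pool_freqs = pool_freqs, hap_freqs = hap_freqs,
              config = config)
  class(out) <- "metapopulation"
  out
}

#' @export
print.metapopulation <- function(x, ...) {
  cat("Simulated metapopulation:", nrow(x$individuals), "individuals in",
      x$config$n_demes, "demes;", x$config$n_loci, "loci;",
      length(x$haplotypes), "mtDNA haplotypes\n")
  print(table(x$individuals$deme))
  invisible(x)
}

# one replicate's observed calls for a true genotype (bp values),
# given the locus allele ladder
replicate_calls <- function(a, b, ladder, d, f) {
  survivors <- c(a, b)[runif(2) >= d]
  if (length(survivors) && runif(1) < f) {
    i <- sample.int(length(survivors), 1L)
    survivors[i] <- sample(setdiff(ladder, survivors[i]), 1L)
  }
  if (length(survivors) == 2L) c(min(survivors), max(survivors))
  else if (length(survivors) == 1L) c(survivors, NA_integer_)
  else c(NA_integer_, NA_integer_)
}

#' Simulate non-invasive (dung) sampling of a metapopulation
#'
#' Each individual is captured in one or more dung samples (a shifted
#' Poisson number, concentrated in the focal deme via
#' `recapture_override`); each sample yields `replicates_per_sample`
#' replicate genotypes per locus under the two-parameter non-invasive
#' error model: every true allele copy drops out independently with
#' probability `dropout_rate` (a heterozygote then appears homozygous
#' or as a half-call), and with probability `false_allele_rate` one
#' surviving call is replaced by a uniformly chosen other allele from
#' the locus ladder.  Molecular-sexing replicates suffer the same
#' dropout on the Y-band (males can read as females, never the
#' reverse), and a whole-reaction failure with probability
#' `dropout_rate^2`.
#'
#' @param metapop a [simulate_metapopulation()] result.
#' @param config optionally override the embedded [sim_config()].
#' @return list with `genotypes` (a [genotype_table()] of replicate
#'   calls), `metadata` (a [sample_metadata()]), `sequences`
#'   (a `sequence_set`, one control-region sequence per sample), and
#'   `truth` (data.frame sample_id -> individual_id).
#' @export
sample_dung <- function(metapop, config = metapop$config) {
  stopifnot(inherits(metapop, "metapopulation"))
  if (!is.null(config$seed)) set.seed(config$seed + 10000L)
  d <- config$dropout_rate; f <- config$false_allele_rate
  ladders <- lapply(seq_len(config$n_loci),
                    function(l) allele_bp(l, seq_len(config$alleles_per_locus)))
  loci <- locus_names(config)
  ind <- metapop$individuals
  gen <- split(metapop$genotypes, metapop$genotypes$individual_id)

  rows <- vector("list", 0L)
  meta <- vector("list", 0L)
  seqs <- character(0)
  truth <- vector("list", 0L)
  s_idx <- 0L
  for (i in seq_len(nrow(ind))) {
    deme <- ind$deme[i]
    mu <- config$recapture_mean
    if (deme %in% names(config$recapture_override)) {
      mu <- config$recapture_override[[deme]]
    }
    n_samp <- 1L + rpois(1L, max(mu - 1, 0))
    g <- gen[[ind$individual_id[i]]]
    g <- g[match(loci, g$locus_id), ]
    for (s in seq_len(n_samp)) {
      s_idx <- s_idx + 1L
      sid <- sprintf("S%05d", s_idx)
      for (l in seq_len(config$n_loci)) {
        reps <- lapply(seq_len(config$replicates_per_sample), function(r)
          replicate_calls(g$allele_a[l], g$allele_b[l], ladders[[l]], d, f))
        # adaptive multiple-tubes protocol: keep replicating an
        # unresolved locus (heterozygotes need 2 concordant replicates,
        # homozygotes 5) up to the replication cap
        cap <- config$max_replicates %||% config$replicates_per_sample
        while (length(reps) < cap) {
          aa <- vapply(reps, `[[`, integer(1L), 1L)
          bb <- vapply(reps, `[[`, integer(1L), 2L)
          if (call_one_locus(aa, bb, 2L, 5L)$call != "failed") break
          reps[[length(reps) + 1L]] <-
            replicate_calls(g$allele_a[l], g$allele_b[l], ladders[[l]], d, f)
        }
        for (r in seq_along(reps)) {
          rows[[length(rows) + 1L]] <- c(sid, loci[l], r,
                                         reps[[r]][1L], reps[[r]][2L])
        }
      }
      sex_calls <- vapply(seq_len(config$sex_replicates_per_sample),
        function(r) {
          if (runif(1) < d^2) return("fail")
          if (ind$sex[i] == "M" && runif(1) >= d) "two_bands" else "one_band"
        }, character(1L))
      meta[[s_idx]] <- data.frame(sample_id = sid, population = deme,
                                  sex_replicates = paste(sex_calls,
                                                         collapse = ";"),
                                  stringsAsFactors = FALSE)
      seqs[sid] <- unclass(metapop$haplotypes)[[ind$haplotype_id[i]]]
      truth[[s_idx]] <- data.frame(sample_id = sid,
                                   individual_id = ind$individual_id[i],
                                   stringsAsFactors = FALSE)
    }
  }
  m <- do.call(rbind, rows)
  tab <- genotype_table(m[, 1L], m[, 2L], as.integer(m[, 3L]),
                        as.integer(m[, 4L]), as.integer(m[, 5L]))
  md <- do.call(rbind, meta)
  list(genotypes = tab,
       metadata = sample_metadata(md$sample_id, md$population,
                                  sex_replicates = md$sex_replicates),
       sequences = as_sequence_set(seqs),
       truth = do.call(rbind, truth))
}

#' Empirical error rates from simulation truth
#'
#' Plug-in estimates of the dropout and false-allele rates by
#' comparing replicate calls with the known true genotypes: for
#' heterozygous-truth replicates the probability of seeing both true
#' alleles is \eqn{(1-d)^2(1-f)}, inverted for \eqn{d}; the
#' false-allele rate is the fraction of informative replicates showing
#' an allele absent from the truth (corrected for replacements that
#' coincide with a true allele).
#'
#' @param table a replicate [genotype_table()].
#' @param truth data.frame `sample_id` -> `individual_id`.
#' @param metapop the generating [simulate_metapopulation()] result.
#' @return named vector `c(d = , f = )`.
#' @export
empirical_error_rates <- function(table, truth, metapop) {
  g <- metapop$genotypes
  key <- paste(truth$individual_id[match(table$sample_id, truth$sample_id)],
               table$locus_id)
  gi <- match(key, paste(g$individual_id, g$locus_id))
  ta <- g$allele_a[gi]; tb <- g$allele_b[gi]
  seen <- !is.na(table$allele_a)
  spur <- seen & ((table$allele_a != ta & table$allele_a != tb) |
                  (!is.na(table$allele_b) &
                   table$allele_b != ta & table$allele_b != tb))
  f_hat <- mean(spur[seen])
  het <- ta != tb
  both <- het & !is.na(table$allele_b) &
    table$allele_a == ta & table$allele_b == tb
  p_both <- sum(both) / sum(het)
  d_hat <- 1 - sqrt(max(p_both, 0) / max(1 - f_hat, 1e-12))
  c(d = unname(d_hat), f = unname(f_hat))
}
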