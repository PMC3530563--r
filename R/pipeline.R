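## End-to-end pipeline: simulate -> consensus -> individuals -> stats
## -> phylo -> structure -> assign, with a run manifest.

#' Pipeline configuration
#'
#' A plain list (optionally read from YAML via [read_pipeline_config()])
#' with stage toggles and per-stage parameters.  The global `seed` is
#' propagated to every stochastic stage with a fixed per-stage offset,
#' so any stage can be re-run in isolation and reproduce its output
#' bit for bit.
#'
#' @param out_dir output directory (created if needed).
#' @param seed global integer seed.
#' @param stages character vector of stages to run, in dependency
#'   order; any subset of
#'   `c("simulate","consensus","individuals","stats","phylo",
#'   "structure","assign")`.
#' @param sim a [sim_config()] (stage `simulate`).
#' @param het_threshold,hom_threshold consensus thresholds.
#' @param reliability_min flagging threshold for genotype reliability.
#' @param one_mismatch_pops,min_shared_loci recapture-matching
#'   parameters.
#' @param n_perm permutations for the differentiation tests.
#' @param distance_model mtDNA distance model.
#' @param n_boot bootstrap replicates for the haplotype tree.
#' @param sampler a [sampler_config()] (stage `structure`).
#' @param focal_population focal population for source assignment.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            stages = c("simulate", "consensus",
                                       "individuals", "stats", "phylo",
                                       "structure", "assign"),
                            sim = sim_config(),
                            het_threshold = 2L, hom_threshold = 5L,
                            reliability_min = 0.99,
                            one_mismatch_pops = "CCA",
                            min_shared_loci = 8L,
                            n_perm = 1000L,
                            distance_model = "K2P",
                            n_boot = 200L,
                            sampler = sampler_config(K_range = 1:3,
                                                     replicates_per_K = 3L,
                                                     burn_in = 500L,
                                                     run_length = 2000L,
                                                     use_location_prior = TRUE),
                            focal_population = "CCA") {
  cfg <- list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
              sim = sim, het_threshold = het_threshold,
              hom_threshold = hom_threshold,
              reliability_min = reliability_min,
              one_mismatch_pops = one_mismatch_pops,
              min_shared_loci = min_shared_loci, n_perm = n_perm,
              distance_model = distance_model, n_boot = n_boot,
              sampler = sampler, focal_population = focal_population)
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname pipeline_config
#' @param path YAML file with (a subset of) the [pipeline_config()]
#'   fields; `sim` and `sampler` sub-lists are passed to their
#'   constructors.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("reading YAML configs requires the 'yaml' package")
  }
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) y$sim <- do.call(sim_config, y$sim)
  if (!is.null(y$sampler)) y$sampler <- do.call(sampler_config, y$sampler)
  do.call(pipeline_config, y)
}

stage_seed <- function(cfg, stage) {
  offsets <- c(simulate = 0L, consensus = 101L, individuals = 202L,
               stats = 303L, phylo = 404L, structure = 505L,
               assign = 606L)
  cfg$seed + offsets[[stage]]
}

#' Run the pipeline
#'
#' Executes the enabled stages in dependency order, writing versioned
#' outputs and a manifest (file, stage, md5 checksum, status) under
#' `out_dir`.  A stage failure halts downstream stages but preserves
#' partial outputs; a rerun with the same config reproduces
#' deterministic outputs bit for bit.
#'
#' @param config a [pipeline_config()].
#' @return the manifest data.frame (class `pipeline_manifest`),
#'   invisibly writable via its attached `path`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- data.frame(stage = character(0), file = character(0),
                         md5 = character(0), status = character(0),
                         stringsAsFactors = FALSE)
  state <- new.env(parent = emptyenv())
  note_file <- function(stage, file) {
    manifest[nrow(manifest) + 1L, ] <<- list(
      stage, basename(file),
      unname(tools::md5sum(file)), "ok")
  }
  outp <- function(f) file.path(config$out_dir, f)

  stages <- list(
    simulate = function() {
      sim <- config$sim
      sim$seed <- stage_seed(config, "simulate")
      state$metapop <- simulate_metapopulation(sim)
      state$dung <- sample_dung(state$metapop)
      write_genotype_table(state$dung$genotypes, outp("replicates.csv"))
      write_sample_metadata(state$dung$metadata, outp("metadata.csv"))
      write_fasta(state$dung$sequences, outp("sequences.fasta"))
      write_fasta(state$metapop$haplotypes, outp("haplotypes.fasta"))
      write.csv(state$dung$truth, outp("truth.csv"), row.names = FALSE)
      for (f in c("replicates.csv", "metadata.csv", "sequences.fasta",
                  "haplotypes.fasta", "truth.csv")) {
        note_file("simulate", outp(f))
      }
    },
    consensus = function() {
      d <- state$dung
      state$consensus <- call_consensus(d$genotypes, config$het_threshold,
                                        config$hom_threshold)
      rates <- estimate_error_rates(d$genotypes, state$consensus)
      state$rates <- rates
      rel <- genotype_reliability(state$consensus, d$genotypes,
                                  rates[["d"]], rates[["f"]],
                                  config$reliability_min)
      write.csv(as.data.frame(state$consensus), outp("consensus.csv"),
                row.names = FALSE)
      write.csv(rel, outp("reliability.csv"), row.names = FALSE)
      write.csv(data.frame(rate = names(rates), estimate = rates),
                outp("error_rates.csv"), row.names = FALSE)
      for (f in c("consensus.csv", "reliability.csv", "error_rates.csv")) {
        note_file("consensus", outp(f))
      }
    },
    individuals = function() {
      d <- state$dung
      pops <- setNames(d$metadata$population, d$metadata$sample_id)
      sexes <- assign_sex(d$metadata)
      haps <- haplotype_ids(d$sequences)
      state$individuals <- match_samples(
        state$consensus, pops, sexes, haps,
        one_mismatch_pops = config$one_mismatch_pops,
        min_shared_loci = config$min_shared_loci,
        table = d$genotypes)
      state$haplotype_seqs <- attr(haps, "haplotypes")
      write.csv(as.data.frame(state$individuals), outp("individuals.csv"),
                row.names = FALSE)
      write.csv(attr(state$individuals, "merge_log"),
                outp("merge_audit.csv"), row.names = FALSE)
      for (f in c("individuals.csv", "merge_audit.csv")) {
        note_file("individuals", outp(f))
      }
    },
    stats = function() {
      set.seed(stage_seed(config, "stats"))
      ind <- state$individuals
      g <- attr(ind, "genotypes")
      pops <- setNames(ind$population, ind$individual_id)
      ind_seqs <- setNames(
        unclass(state$haplotype_seqs)[ind$haplotype_id],
        ind$individual_id)
      ok <- !is.na(ind_seqs)
      ind_seqs <- as_sequence_set(ind_seqs[ok])
      div <- diversity(g, pops, sequences = ind_seqs)
      write.csv(div, outp("diversity.csv"), row.names = FALSE)
      th <- pairwise_theta(g, pops, n_perm = config$n_perm)
      write_pairwise_fst(th, outp("fst_microsat.csv"))
      ph <- pairwise_phist(ind_seqs, pops,
                           distance_model = config$distance_model,
                           n_perm = config$n_perm)
      write_pairwise_fst(ph, outp("phist_mtdna.csv"))
      state$theta <- th; state$phist <- ph
      for (f in c("diversity.csv", "fst_microsat.csv", "phist_mtdna.csv")) {
        note_file("stats", outp(f))
      }
    },
    phylo = function() {
      haps <- state$haplotype_seqs
      if (length(haps) >= 3L) {
        tr <- bootstrap_support(haps, model = config$distance_model,
                                n_boot = config$n_boot,
                                seed = stage_seed(config, "phylo"))
      } else {
        tr <- neighbour_joining(pairwise_distances(haps,
                                                   config$distance_model))
      }
      writeLines(write_newick(tr), outp("haplotypes.nwk"))
      note_file("phylo", outp("haplotypes.nwk"))
    },
    structure = function() {
      ind <- state$individuals
      g <- attr(ind, "genotypes")
      pops <- setNames(ind$population, ind$individual_id)
      sc <- config$sampler
      sc$seed <- stage_seed(config, "structure")
      state$scan <- run_admixture_sampler(g, sc, locations = pops)
      lnpd <- data.frame(
        K = vapply(state$scan$runs, `[[`, integer(1L), "K"),
        replicate = vapply(state$scan$runs, `[[`, integer(1L), "replicate"),
        lnPD = vapply(state$scan$runs, `[[`, numeric(1L), "lnPD"))
      write.csv(lnpd, outp("structure_lnpd.csv"), row.names = FALSE)
      ev <- try(evanno_select(state$scan), silent = TRUE)
      if (!inherits(ev, "try-error")) {
        write.csv(as.data.frame(ev), outp("evanno.csv"), row.names = FALSE)
        note_file("structure", outp("evanno.csv"))
        bestK <- attr(ev, "selected_K")
      } else {
        bestK <- max(lnpd$K[which.max(lnpd$lnPD)])
      }
      if (is.na(bestK)) bestK <- config$sampler$K_range[1L]
      cand <- state$scan$runs[vapply(state$scan$runs, `[[`, integer(1L),
                                     "K") == bestK]
      best <- cand[[which.max(vapply(cand, `[[`, numeric(1L), "lnPD"))]]
      write_qmatrix(best$Q, outp("qmatrix.csv"), populations = pops)
      note_file("structure", outp("structure_lnpd.csv"))
      note_file("structure", outp("qmatrix.csv"))
    },
    assign = function() {
      ind <- state$individuals
      g <- attr(ind, "genotypes")
      pops <- setNames(ind$population, ind$individual_id)
      haps <- setNames(ind$haplotype_id, ind$individual_id)
      focal <- ind$individual_id[ind$population == config$focal_population]
      if (!length(focal)) stop("no individuals in focal population ",
                               config$focal_population)
      refs <- population_references(g, pops, haps, exclude = focal)
      asg <- assign_source(g[g$individual_id %in% focal, ], refs,
                           haplotypes = haps)
      write.csv(as.data.frame(asg), outp("source_assignment.csv"),
                row.names = FALSE)
      note_file("assign", outp("source_assignment.csv"))
    })

  order_all <- c("simulate", "consensus", "individuals", "stats",
                 "phylo", "structure", "assign")
  for (st in order_all) {
    if (!st %in% config$stages) next
    res <- tryCatch({ stages[[st]](); "ok" },
                    error = function(e) conditionMessage(e))
    if (!identical(res, "ok")) {
      manifest[nrow(manifest) + 1L, ] <- list(st, NA_character_,
                                              NA_character_,
                                              paste("failed:", res))
      warning("stage '", st, "' failed: ", res,
              "; downstream stages skipped")
      break
    }
  }
  write.csv(manifest, file.path(config$out_dir, "manifest.csv"),
            row.names = FALSE)
  class(manifest) <- c("pipeline_manifest", "data.frame")
  attr(manifest, "path") <- config$out_dir
  manifest
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  cat("pipeline run at", attr(x, "path"), "-", nrow(x), "outputs\n")
  print.data.frame(x)
  invisible(x)
}
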