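#' Allele frequencies per locus
#'
#' @param genotypes long data.frame with `locus_id`, `allele_a`,
#'   `allele_b` (one row per individual per locus; `NA` alleles and
#'   failed calls are skipped).
#' @return named list per locus: named numeric frequency vector with
#'   the number of typed individuals in `attr(, "n")`.
#' @export
allele_freqs <- function(genotypes) {
  g <- genotypes[!is.na(genotypes$allele_a) & !is.na(genotypes$allele_b), ]
  out <- lapply(split(g, g$locus_id), function(gl) {
    al <- c(gl$allele_a, gl$allele_b)
    p <- table(al) / length(al)
    p <- setNames(as.numeric(p), names(p))
    attr(p, "n") <- nrow(gl)
    p
  })
  out
}

#' Probability of identity (random and sibling)
#'
#' Per-locus probabilities that two random individuals (under HWE) or
#' two full siblings share an identical genotype:
#' \deqn{P_{ID} = \sum_i p_i^4 + \sum_{i<j} (2 p_i p_j)^2}
#' \deqn{P_{IDsib} = 0.25 + 0.5\sum_i p_i^2 +
#'   0.5\left(\sum_i p_i^2\right)^2 - 0.25 \sum_i p_i^4}
#' Cumulative values are products across loci; they quantify how safely
#' matching multilocus genotypes can be declared recaptures.
#'
#' @param freqs an [allele_freqs()] result (list of per-locus
#'   frequency vectors, each summing to 1).
#' @param tol tolerance for the sum-to-one check.
#' @return data.frame of class `identity_stats` with per-locus `p_id`
#'   and `p_id_sib`; cumulative products in
#'   `attr(, "cumulative")`.
#' @export
probability_of_identity <- function(freqs, tol = 1e-6) {
  if (!is.list(freqs)) freqs <- list(locus = freqs)
  bad <- vapply(freqs, function(p) abs(sum(p) - 1) > tol, logical(1L))
  if (any(bad)) {
    stop("allele frequencies at locus '", names(freqs)[bad][1L],
         "' do not sum to 1")
  }
  per <- t(vapply(freqs, function(p) {
    s2 <- sum(p^2); s4 <- sum(p^4)
    pid <- s4 + sum((2 * outer(p, p))[upper.tri(outer(p, p))]^2)
    sib <- 0.25 + 0.5 * s2 + 0.5 * s2^2 - 0.25 * s4
    c(p_id = pid, p_id_sib = sib)
  }, numeric(2L)))
  out <- data.frame(locus_id = names(freqs), p_id = per[, "p_id"],
                    p_id_sib = per[, "p_id_sib"],
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "cumulative") <- c(p_id = prod(out$p_id),
                               p_id_sib = prod(out$p_id_sib))
  class(out) <- c("identity_stats", "data.frame")
  out
}

#' @export
print.identity_stats <- function(x, ...) {
  cat("Probability of identity over", nrow(x), "loci\n")
  print.data.frame(x, digits = 4)
  cum <- attr(x, "cumulative")
  cat(sprintf("cumulative: P(ID) = %.3g, P(ID)sib = %.3g\n",
              cum["p_id"], cum["p_id_sib"]))
  invisible(x)
}

#' Assign sex from replicate band calls
#'
#' A sample is male when at least two replicates show both bands (the
#' Y band cannot appear by dropout), female when at least three
#' replicates show a single band and none show two (a male can read as
#' single-band through Y dropout, so any two-band call vetoes a female
#' assignment), and `unknown` otherwise.
#'
#' @param calls character vector of band calls (`one_band`,
#'   `two_bands`, `fail`), or a [sample_metadata()] to process all
#'   samples at once.
#' @return `"M"`, `"F"` or `"unknown"` (named vector for metadata
#'   input).
#' @export
assign_sex <- function(calls) {
  if (inherits(calls, "sample_metadata")) {
    return(vapply(sex_replicate_list(calls), assign_sex, character(1L)))
  }
  calls <- calls[nzchar(calls)]
  n2 <- sum(calls == "two_bands")
  n1 <- sum(calls == "one_band")
  if (n2 >= 2L) return("M")
  if (n1 >= 3L && n2 == 0L) return("F")
  "unknown"
}

#' Collapse aligned sequences to haplotype identifiers
#'
#' Identical sequences (after trimming to the common aligned window)
#' share a haplotype id; ids are assigned in decreasing frequency
#' (`H01` most common).
#'
#' @param seqs a `sequence_set` (aligned).
#' @return named character vector sequence id -> haplotype id; the
#'   unique haplotype sequences are in `attr(, "haplotypes")`.
#' @export
haplotype_ids <- function(seqs) {
  seqs <- as_sequence_set(seqs)
  len <- min(nchar(seqs))
  trimmed <- substr(unclass(seqs), 1L, len)
  freq <- sort(table(trimmed), decreasing = TRUE)
  ids <- setNames(sprintf("H%02d", seq_along(freq)), names(freq))
  out <- setNames(unname(ids[trimmed]), names(seqs))
  haps <- setNames(names(freq), unname(ids))
  attr(out, "haplotypes") <- as_sequence_set(haps)
  out
}

# allele-difference count between two sorted genotype pairs
# 0 = identical, 1 = one allele apart (dropout-compatible), 2 = both differ
pair_allele_diff <- function(a1, b1, a2, b2) {
  ifelse(a1 == a2 & b1 == b2, 0L,
         ifelse(a1 == a2 | b1 == b2 | a1 == b2 | b1 == a2, 1L, 2L))
}

#' Collapse samples to unique individuals (recapture matching)
#'
#' Builds a match graph over samples: an edge joins two samples when
#' their consensus genotypes are identical at every mutually called
#' locus (with at least `min_shared_loci` loci compared), or -- for
#' populations listed in `one_mismatch_pops`, where exhaustive
#' recapture sampling makes dropout-induced single-allele differences
#' likely -- when they differ by exactly one allele at exactly one
#' locus and their sexes match.  Known-sex conflicts always block an
#' edge, as do mtDNA haplotype conflicts when
#' `require_haplotype_match` is set; blocked exact matches are
#' reported, never silently merged.  Individuals are the connected
#' components; when the replicate `table` is supplied each
#' individual's genotype is re-called from its pooled replicates.
#'
#' @param consensus a [call_consensus()] result.
#' @param populations named vector sample id -> population label.
#' @param sexes named vector sample id -> `M`/`F`/`unknown`
#'   (see [assign_sex()]).
#' @param haplotypes optional named vector sample id -> haplotype id
#'   (see [haplotype_ids()]).
#' @param one_mismatch_pops populations in which the one-allele
#'   mismatch rule is active.
#' @param min_shared_loci minimum mutually called loci for any merge.
#' @param require_haplotype_match block merges on haplotype conflict.
#' @param table optional replicate [genotype_table()] for re-deriving
#'   each individual's consensus from pooled replicates.
#' @return data.frame of class `individuals`: `individual_id`,
#'   `n_samples`, `sample_ids` (`;`-joined), `population`, `sex`,
#'   `haplotype_id`.  Attributes: `genotypes` (per-individual long
#'   consensus genotypes), `merge_log`, `conflicts`.
#' @export
match_samples <- function(consensus, populations, sexes = NULL,
                          haplotypes = NULL,
                          one_mismatch_pops = character(0),
                          min_shared_loci = 8L,
                          require_haplotype_match = TRUE,
                          table = NULL) {
  called <- consensus[consensus$call != "failed", ]
  samples <- sort(unique(called$sample_id))
  loci <- sort(unique(called$locus_id))
  n <- length(samples)
  A <- matrix(NA_integer_, n, length(loci), dimnames = list(samples, loci))
  B <- A
  si <- match(called$sample_id, samples)
  li <- match(called$locus_id, loci)
  A[cbind(si, li)] <- called$allele_a
  B[cbind(si, li)] <- called$allele_b
  if (is.null(sexes)) sexes <- setNames(rep("unknown", n), samples)
  sex <- unname(sexes[samples]); sex[is.na(sex)] <- "unknown"
  hap <- if (is.null(haplotypes)) rep(NA_character_, n)
         else unname(haplotypes[samples])
  pop <- unname(populations[samples])

  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  merge_log <- list()
  conflicts <- list()
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    shared <- !is.na(A[i, ]) & t(!is.na(A[js, , drop = FALSE]))  # L x m
    for (jj in seq_along(js)) {
      j <- js[jj]
      sh <- which(shared[, jj])
      if (length(sh) < min_shared_loci) next
      dd <- pair_allele_diff(A[i, sh], B[i, sh], A[j, sh], B[j, sh])
      n_diff_loci <- sum(dd > 0L)
      sex_conflict <- sex[i] != "unknown" && sex[j] != "unknown" &&
        sex[i] != sex[j]
      hap_conflict <- !is.na(hap[i]) && !is.na(hap[j]) && hap[i] != hap[j]
      if (n_diff_loci == 0L) {
        if (sex_conflict || (require_haplotype_match && hap_conflict)) {
          conflicts[[length(conflicts) + 1L]] <- data.frame(
            sample_a = samples[i], sample_b = samples[j],
            reason = if (sex_conflict) "sex conflict on exact genotype match"
                     else "haplotype conflict on exact genotype match",
            stringsAsFactors = FALSE)
          next
        }
        parent[find(j)] <- find(i)
        merge_log[[length(merge_log) + 1L]] <- data.frame(
          sample_a = samples[i], sample_b = samples[j], rule = "exact",
          n_shared = length(sh), stringsAsFactors = FALSE)
      } else if (n_diff_loci == 1L && dd[dd > 0L] == 1L &&
                 pop[i] %in% one_mismatch_pops &&
                 pop[j] %in% one_mismatch_pops) {
        sex_match <- sex[i] != "unknown" && sex[i] == sex[j]
        if (!sex_match) next
        if (require_haplotype_match && hap_conflict) next
        locus_d <- loci[sh][dd > 0L]
        case <- if (A[i, locus_d] == B[i, locus_d] ||
                    A[j, locus_d] == B[j, locus_d])
          "het_vs_hom" else "het_vs_het"
        parent[find(j)] <- find(i)
        merge_log[[length(merge_log) + 1L]] <- data.frame(
          sample_a = samples[i], sample_b = samples[j],
          rule = paste0("one_mismatch:", case),
          n_shared = length(sh), stringsAsFactors = FALSE)
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1L))
  comp_ids <- sort(unique(comp))
  ind <- vector("list", length(comp_ids))
  geno <- vector("list", length(comp_ids))
  for (k in seq_along(comp_ids)) {
    mem <- samples[comp == comp_ids[k]]
    id <- sprintf("IND%04d", k)
    msex <- unique(sex[comp == comp_ids[k]])
    msex <- setdiff(msex, "unknown")
    mhap <- unique(hap[comp == comp_ids[k]])
    mhap <- mhap[!is.na(mhap)]
    if (length(mhap) > 1L) {
      conflicts[[length(conflicts) + 1L]] <- data.frame(
        sample_a = mem[1L], sample_b = mem[2L],
        reason = "haplotype conflict within merged individual",
        stringsAsFactors = FALSE)
    }
    if (length(msex) > 1L) {
      conflicts[[length(conflicts) + 1L]] <- data.frame(
        sample_a = mem[1L], sample_b = mem[2L],
        reason = "sex conflict within merged individual",
        stringsAsFactors = FALSE)
    }
    ind[[k]] <- data.frame(
      individual_id = id, n_samples = length(mem),
      sample_ids = paste(mem, collapse = ";"),
      population = names(sort(table(pop[comp == comp_ids[k]]),
                              decreasing = TRUE))[1L],
      sex = if (length(msex) == 1L) msex else "unknown",
      haplotype_id = if (length(mhap) == 1L) mhap else NA_character_,
      stringsAsFactors = FALSE)
    if (!is.null(table)) {
      sub <- table[table$sample_id %in% mem, ]
      sub$sample_id <- id
      sub$replicate <- seq_len(nrow(sub))  # reindexed within pooled set
      thr <- attr(consensus, "thresholds") %||% c(het = 2L, hom = 5L)
      cc <- suppressWarnings(call_consensus(sub, thr[["het"]], thr[["hom"]]))
      geno[[k]] <- cc[cc$call != "failed",
                      c("sample_id", "locus_id", "allele_a", "allele_b")]
      names(geno[[k]])[1L] <- "individual_id"
    } else {
      rep_s <- mem[1L]
      sub <- called[called$sample_id == rep_s,
                    c("sample_id", "locus_id", "allele_a", "allele_b")]
      names(sub)[1L] <- "individual_id"
      sub$individual_id <- id
      geno[[k]] <- sub
    }
  }
  out <- do.call(rbind, ind)
  rownames(out) <- NULL
  attr(out, "genotypes") <- do.call(rbind, geno)
  attr(out, "merge_log") <- if (length(merge_log))
    do.call(rbind, merge_log) else
    data.frame(sample_a = character(0), sample_b = character(0),
               rule = character(0), n_shared = integer(0))
  attr(out, "conflicts") <- if (length(conflicts))
    do.call(rbind, conflicts) else
    data.frame(sample_a = character(0), sample_b = character(0),
               reason = character(0))
  attr(out, "sample_map") <- setNames(
    rep(out$individual_id, out$n_samples),
    unlist(strsplit(out$sample_ids, ";", fixed = TRUE)))
  class(out) <- c("individuals", "data.frame")
  out
}

#' @export
print.individuals <- function(x, ...) {
  cat(nrow(x), "unique individuals from",
      sum(x$n_samples), "samples\n")
  tab <- stats::aggregate(cbind(samples = n_samples) ~ population,
                          data = as.data.frame(x), FUN = sum)
  tab$individuals <- as.integer(table(x$population)[tab$population])
  print(tab, row.names = FALSE)
  invisible(x)
}
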