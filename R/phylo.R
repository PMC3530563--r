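## Distance-based haplotype phylogenetics.

seq_char_matrix <- function(seqs) {
  seqs <- as_sequence_set(seqs)
  if (length(unique(nchar(seqs))) != 1L) {
    stop("sequences must be aligned (uniform length)")
  }
  m <- do.call(rbind, strsplit(unclass(seqs), ""))
  rownames(m) <- names(seqs)
  m
}

TRANSITIONS <- c(A = "G", G = "A", C = "T", T = "C")
SATURATION_CAP <- 10

k2p_pair <- function(x, y) {
  ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  n <- sum(ok)
  if (n == 0L) return(NA_real_)
  diff <- ok & x != y
  ts <- sum(diff & TRANSITIONS[x] == y, na.rm = TRUE)
  tv <- sum(diff) - ts
  P <- ts / n; Q <- tv / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    warning("K2P saturation; distance capped")
    return(SATURATION_CAP)
  }
  -0.5 * log(w1) - 0.25 * log(w2)
}

p_dist_pair <- function(x, y) {
  ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  if (!sum(ok)) return(NA_real_)
  sum(ok & x != y) / sum(ok)
}

# HKY rate matrix (rows/cols A,C,G,T), scaled to one expected
# substitution per unit time
hky_eigen <- function(pi, kappa) {
  bases <- c("A", "C", "G", "T")
  Q <- matrix(0, 4, 4, dimnames = list(bases, bases))
  for (i in bases) for (j in bases) {
    if (i == j) next
    Q[i, j] <- pi[j] * if (TRANSITIONS[i] == j) kappa else 1
  }
  diag(Q) <- -rowSums(Q)
  mu <- -sum(pi * diag(Q))
  Q <- Q / mu
  e <- eigen(Q)
  list(U = e$vectors, Uinv = solve(e$vectors), lambda = e$values)
}

hky_pmat <- function(eg, t) {
  P <- Re(eg$U %*% diag(exp(eg$lambda * t)) %*% eg$Uinv)
  P[P < 0] <- 0
  P
}

hky_pair <- function(x, y, eg, pi) {
  bases <- c("A", "C", "G", "T")
  ok <- x %in% bases & y %in% bases
  if (!sum(ok)) return(NA_real_)
  counts <- table(factor(x[ok], bases), factor(y[ok], bases))
  if (sum(counts[row(counts) != col(counts)]) == 0L) return(0)
  nll <- function(t) {
    P <- hky_pmat(eg, t)
    lik <- outer(pi, rep(1, 4)) * P
    -sum(counts * log(pmax(lik, 1e-300)))
  }
  opt <- optimize(nll, c(1e-8, SATURATION_CAP), tol = 1e-10)
  if (opt$minimum > SATURATION_CAP * 0.99) {
    warning("HKY saturation; distance capped")
  }
  opt$minimum
}

#' Estimate the transition/transversion rate ratio
#'
#' Moment estimate of kappa from the alignment-wide transition and
#' transversion distance components of the Kimura two-parameter model.
#'
#' @param seqs aligned `sequence_set`.
#' @return kappa (>= 0.5, finite).
#' @export
estimate_kappa <- function(seqs) {
  m <- seq_char_matrix(seqs)
  n <- nrow(m)
  Ps <- Qs <- ns <- 0
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    x <- m[i, ]; y <- m[j, ]
    ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
    diff <- ok & x != y
    ts <- sum(diff & TRANSITIONS[x] == y, na.rm = TRUE)
    Ps <- Ps + ts; Qs <- Qs + sum(diff) - ts; ns <- ns + sum(ok)
  }
  P <- Ps / ns; Q <- Qs / ns
  w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) return(2)
  ds <- -0.5 * log(w1) + 0.25 * log(w2)   # transition component
  dv <- -0.5 * log(w2)                    # transversion component
  if (dv <= 0) return(2)
  max(2 * ds / dv, 0.5)
}

#' Pairwise evolutionary distances
#'
#' Kimura two-parameter distances use the closed form
#' \eqn{d = -\tfrac12 \ln[(1-2P-Q)\sqrt{1-2Q}]} with transition and
#' transversion proportions \eqn{P, Q}; `HKY_ML` distances maximise
#' the pairwise likelihood under the HKY substitution model
#' (empirical base frequencies, kappa fixed or moment-estimated from
#' the alignment) by one-dimensional optimisation of the branch
#' length.  Gaps and ambiguity codes are pairwise-deleted; saturated
#' pairs are capped at 10 substitutions/site with a warning.
#'
#' @param seqs aligned `sequence_set`.
#' @param model `"K2P"`, `"p_distance"` or `"HKY_ML"`.
#' @param kappa fixed transition/transversion ratio for HKY; `NULL` to
#'   estimate from the alignment.
#' @param base_freqs base frequencies (A, C, G, T) for HKY; `NULL` for
#'   empirical frequencies from the alignment.
#' @return symmetric matrix of class `dist_matrix` with the model in
#'   `attr(, "model")`.
#' @export
pairwise_distances <- function(seqs, model = c("K2P", "p_distance", "HKY_ML"),
                               kappa = NULL, base_freqs = NULL) {
  model <- match.arg(model)
  m <- seq_char_matrix(seqs)
  n <- nrow(m)
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (model == "HKY_ML") {
    if (is.null(base_freqs)) {
      tabs <- table(factor(as.vector(m), c("A", "C", "G", "T")))
      pi <- as.numeric(tabs) / sum(tabs)
    } else {
      pi <- base_freqs
    }
    names(pi) <- c("A", "C", "G", "T")
    pi[pi == 0] <- 1e-6
    pi <- pi / sum(pi)
    if (is.null(kappa)) kappa <- estimate_kappa(seqs)
    eg <- hky_eigen(pi, kappa)
  }
  for (i in seq_len(max(n - 1L, 0L))) for (j in (i + 1L):n) {
    d <- switch(model,
                K2P = k2p_pair(m[i, ], m[j, ]),
                p_distance = p_dist_pair(m[i, ], m[j, ]),
                HKY_ML = hky_pair(m[i, ], m[j, ], eg, pi))
    D[i, j] <- D[j, i] <- d
  }
  attr(D, "model") <- model
  class(D) <- c("dist_matrix", class(D))
  D
}

#' Neighbour-joining tree
#'
#' Saitou-Nei agglomeration on a distance matrix (exact on additive
#' distances).  Labels are ordered lexicographically before
#' clustering, so ties break deterministically by label order;
#' negative branch lengths are clamped to zero and the clamped total
#' recorded in `attr(, "clamped")`.
#'
#' @param D symmetric distance matrix with labelled rows.
#' @return an [ape::phylo] tree (a labelled stub for < 2 taxa).
#' @export
neighbour_joining <- function(D) {
  labs <- rownames(D)
  if (is.null(labs)) stop("distance matrix must have labels")
  if (length(labs) == 1L) {
    out <- labs
    attr(out, "note") <- "single taxon: degenerate tree"
    return(out)
  }
  ord <- order(labs)
  D <- unclass(D)[ord, ord]
  if (length(labs) == 2L) {
    tr <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2L, byrow = TRUE),
               tip.label = rownames(D), edge.length = rep(D[1, 2] / 2, 2L),
               Nnode = 1L)
    class(tr) <- "phylo"
    attr(tr, "note") <- "two taxa: single split"
    return(tr)
  }
  tr <- ape::nj(as.dist(D))
  clamped <- -sum(tr$edge.length[tr$edge.length < 0])
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "clamped") <- clamped
  tr
}

#' Bootstrap support for the NJ haplotype tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree
#' for each pseudo-alignment, counts bipartition frequencies, and maps
#' them onto the point-estimate tree as percentages in
#' `tree$node.label`.
#'
#' @param seqs aligned `sequence_set` (>= 3 sequences).
#' @param model distance model (see [pairwise_distances()]).
#' @param n_boot bootstrap replicates.
#' @param seed optional seed for reproducibility.
#' @param kappa passed to [pairwise_distances()].
#' @return the point-estimate tree with percentage supports.
#' @export
bootstrap_support <- function(seqs, model = "K2P", n_boot = 1000L,
                              seed = NULL, kappa = NULL) {
  if (!is.null(seed)) set.seed(seed)
  m <- seq_char_matrix(seqs)
  point <- neighbour_joining(pairwise_distances(seqs, model, kappa = kappa))
  boots <- vector("list", n_boot)
  for (b in seq_len(n_boot)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    bs <- as_sequence_set(setNames(apply(m[, cols, drop = FALSE], 1L,
                                         paste, collapse = ""),
                                   rownames(m)))
    boots[[b]] <- suppressWarnings(
      neighbour_joining(pairwise_distances(bs, model, kappa = kappa)))
  }
  counts <- ape::prop.clades(point, boots, rooted = FALSE)
  counts[is.na(counts)] <- 0L
  point$node.label <- round(100 * counts / n_boot)
  point
}

#' Assign query haplotypes to reference clades
#'
#' Each query leaf takes the clade of its nearest reference (smallest
#' patristic distance to any reference of that clade); ties are
#' reported, not silently resolved.  When `populations` is supplied,
#' the per-population clade composition table is attached, the pattern
#' used to read geographic clade structure off the tree.
#'
#' @param tree a phylo tree whose tips include the reference labels.
#' @param clade_map named vector reference label -> clade name.
#' @param populations optional named vector query label -> population.
#' @return data.frame `leaf`, `clade`, `distance`, `tie`
#'   (`;`-separated tied clades or `NA`); composition table in
#'   `attr(, "composition")`.
#' @export
assign_clades <- function(tree, clade_map, populations = NULL) {
  refs <- intersect(names(clade_map), tree$tip.label)
  if (!length(refs)) {
    warning("no reference labels present in tree; assignment skipped")
    return(NULL)
  }
  pat <- ape::cophenetic.phylo(tree)
  queries <- setdiff(tree$tip.label, refs)
  clades <- unique(unname(clade_map[refs]))
  rows <- lapply(queries, function(q) {
    d <- vapply(clades, function(cl) {
      min(pat[q, refs[clade_map[refs] == cl]])
    }, numeric(1L))
    best <- min(d)
    tied <- clades[d <= best + 1e-12]
    data.frame(leaf = q,
               clade = if (length(tied) == 1L) tied else NA_character_,
               distance = best,
               tie = if (length(tied) > 1L)
                 paste(tied, collapse = ";") else NA_character_,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(populations) && !is.null(out)) {
    attr(out, "composition") <- table(
      population = unname(populations[out$leaf]), clade = out$clade)
  }
  out
}
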