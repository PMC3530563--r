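#' @title Genotype tables and their on-disk formats
#' @description A genotype table is the raw unit of the multiple-tubes
#'   protocol: one row per PCR replicate per sample per locus, holding
#'   the two allele calls in base pairs.  Half-calls (one allele seen)
#'   are stored as `(allele_a, NA)`; a failed replicate is `(NA, NA)`.
#' @name genotype-table
NULL

#' Construct and validate a genotype table
#'
#' @param sample_id character vector of sample identifiers.
#' @param locus_id character vector of locus identifiers.
#' @param replicate positive integer replicate index, unique within
#'   each (sample, locus).
#' @param allele_a,allele_b integer allele sizes in bp, or `NA`.
#'   Alleles are stored ordered so that `allele_a <= allele_b`; a
#'   half-call keeps its single allele in `allele_a`.
#' @return A `data.frame` of class `genotype_table`.
#' @export
genotype_table <- function(sample_id, locus_id, replicate, allele_a, allele_b) {
  tab <- data.frame(
    sample_id = as.character(sample_id),
    locus_id = as.character(locus_id),
    replicate = as.integer(replicate),
    allele_a = as.integer(allele_a),
    allele_b = as.integer(allele_b),
    stringsAsFactors = FALSE
  )
  validate_genotype_table(tab)
}

#' @rdname genotype_table
#' @param tab a data.frame with the five genotype-table columns.
#' @export
validate_genotype_table <- function(tab) {
  need <- c("sample_id", "locus_id", "replicate", "allele_a", "allele_b")
  miss <- setdiff(need, names(tab))
  if (length(miss)) {
    stop("genotype table is missing columns: ", paste(miss, collapse = ", "))
  }
  if (any(!is.na(tab$replicate) & tab$replicate < 1)) {
    stop("replicate indices must be positive integers")
  }
  # a half-call must occupy allele_a
  swap <- !is.na(tab$allele_b) & is.na(tab$allele_a)
  tab$allele_a[swap] <- tab$allele_b[swap]
  tab$allele_b[swap] <- NA_integer_
  both <- !is.na(tab$allele_a) & !is.na(tab$allele_b)
  a <- pmin(tab$allele_a[both], tab$allele_b[both])
  b <- pmax(tab$allele_a[both], tab$allele_b[both])
  tab$allele_a[both] <- a
  tab$allele_b[both] <- b
  key <- paste(tab$sample_id, tab$locus_id, tab$replicate, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("duplicate (sample, locus, replicate) entry: ",
         gsub("\r", " / ", dup, fixed = TRUE))
  }
  class(tab) <- c("genotype_table", "data.frame")
  tab
}

#' Read a genotype table
#'
#' Two dialects are supported: `long_csv`, a documented long-form CSV
#' with header `sample_id,locus_id,replicate,allele_a,allele_b`, and
#' `genepop`, the classic Genepop file (title line, one locus name per
#' line or a comma-separated list, `Pop` separators, then
#' `id , 0101 0202 ...` rows with 2- or 3-digit allele codes;
#' all-zero codes are missing).  Genepop carries no replicate
#' structure, so every row gets replicate 1, and the population blocks
#' are returned in `attr(x, "populations")` (a named character vector,
#' sample id to population label).
#'
#' @param path file to read.
#' @param dialect `"long_csv"` or `"genepop"`.
#' @return a [genotype_table()].
#' @export
read_genotype_table <- function(path, dialect = c("long_csv", "genepop")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(dialect,
    long_csv = read_genotype_long_csv(path),
    genepop = read_genepop(path)
  )
}

read_genotype_long_csv <- function(path) {
  lines <- readLines(path)
  if (!length(lines)) stop("empty genotype file: ", path)
  header <- strsplit(lines[1L], ",", fixed = TRUE)[[1L]]
  header <- trimws(header)
  need <- c("sample_id", "locus_id", "replicate", "allele_a", "allele_b")
  if (!all(need %in% header)) {
    stop("long CSV header must contain: ", paste(need, collapse = ", "))
  }
  idx <- match(need, header)
  body <- lines[-1L]
  body <- body[nzchar(trimws(body))]
  parse_int <- function(x, line, col) {
    x <- trimws(x)
    out <- suppressWarnings(as.integer(x))
    bad <- which(!is.na(x) & nzchar(x) & is.na(out))
    if (length(bad)) {
      stop(sprintf("parse error at line %d: '%s' is not an integer (%s)",
                   line[bad[1L]], x[bad[1L]], col))
    }
    out
  }
  fields <- strsplit(body, ",", fixed = TRUE)
  # trailing empty allele fields are legitimate (missing calls)
  fields <- lapply(fields, function(f) {
    if (length(f) %in% c(length(header) - 2L, length(header) - 1L)) {
      f <- c(f, rep("", length(header) - length(f)))
    }
    f
  })
  nf <- lengths(fields)
  if (any(nf < length(header))) {
    stop(sprintf("parse error at line %d: expected %d fields, found %d",
                 which(nf < length(header))[1L] + 1L, length(header),
                 nf[which(nf < length(header))[1L]]))
  }
  mat <- do.call(rbind, lapply(fields, function(f) f[idx]))
  lineno <- seq_along(body) + 1L
  genotype_table(
    sample_id = trimws(mat[, 1L]),
    locus_id = trimws(mat[, 2L]),
    replicate = parse_int(mat[, 3L], lineno, "replicate"),
    allele_a = parse_int(mat[, 4L], lineno, "allele_a"),
    allele_b = parse_int(mat[, 5L], lineno, "allele_b")
  )
}

#' Write a genotype table as long-form CSV
#'
#' @param tab a [genotype_table()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genotype_table <- function(tab, path) {
  tab <- validate_genotype_table(tab)
  write.csv(as.data.frame(tab)[, c("sample_id", "locus_id", "replicate",
                                   "allele_a", "allele_b")],
            path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

read_genepop <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) | seq_along(lines) == 1L]
  if (length(lines) < 3L) stop("not a Genepop file (too short): ", path)
  is_pop <- toupper(trimws(lines)) == "POP"
  first_pop <- which(is_pop)[1L]
  if (is.na(first_pop)) stop("not a Genepop file: no 'Pop' line")
  locus_lines <- lines[2:(first_pop - 1L)]
  loci <- trimws(unlist(strsplit(locus_lines, ",", fixed = TRUE)))
  loci <- loci[nzchar(loci)]
  pop_of <- character(0)
  rows <- list()
  pop_idx <- 0L
  for (i in seq(first_pop, length(lines))) {
    ln <- lines[i]
    if (toupper(trimws(ln)) == "POP") {
      pop_idx <- pop_idx + 1L
      next
    }
    parts <- strsplit(ln, ",", fixed = TRUE)[[1L]]
    if (length(parts) < 2L) {
      stop(sprintf("parse error at line %d: missing ',' separator", i))
    }
    id <- trimws(parts[1L])
    calls <- strsplit(trimws(paste(parts[-1L], collapse = " ")), "[ \t]+")[[1L]]
    calls <- calls[nzchar(calls)]
    if (length(calls) != length(loci)) {
      stop(sprintf("parse error at line %d: %d genotype fields for %d loci",
                   i, length(calls), length(loci)))
    }
    if (any(!grepl("^[0-9]+$", calls))) {
      stop(sprintf("parse error at line %d: non-numeric genotype code", i))
    }
    w <- nchar(calls)
    if (any(!w %in% c(4L, 6L))) {
      stop(sprintf("parse error at line %d: genotype codes must be 4 or 6 digits", i))
    }
    half <- w %/% 2L
    a <- as.integer(substr(calls, 1L, half))
    b <- as.integer(substr(calls, half + 1L, w))
    a[a == 0L] <- NA_integer_
    b[b == 0L] <- NA_integer_
    rows[[length(rows) + 1L]] <- data.frame(
      sample_id = id, locus_id = loci, replicate = 1L,
      allele_a = a, allele_b = b, stringsAsFactors = FALSE
    )
    pop_of[id] <- paste0("Pop", pop_idx)
  }
  tab <- validate_genotype_table(do.call(rbind, rows))
  attr(tab, "populations") <- pop_of
  tab
}

#' Write a genotype table in Genepop format
#'
#' Raw fragment sizes (bp) are binned to compact codes by rank order
#' within each locus; the allele map used is returned as
#' `attr(, "allele_map")` and optionally written alongside the file so
#' the coding is persistent and invertible.  The table must hold a
#' single replicate (e.g. consensus genotypes) per (sample, locus).
#'
#' @param tab a [genotype_table()] with one replicate per sample/locus.
#' @param path output file.
#' @param populations named character vector (sample id to population
#'   label); samples sharing a label form one `Pop` block.  Defaults to
#'   a single population.
#' @param title title line; first line of the file.
#' @param digits 2 or 3 digit allele codes (default 3).
#' @param map_path optional CSV path for the locus/bp/code allele map.
#' @return `path` invisibly, with the allele map attached as an
#'   attribute.
#' @export
write_genepop <- function(tab, path, populations = NULL,
                          title = "fecalpop export", digits = 3L,
                          map_path = NULL) {
  tab <- validate_genotype_table(tab)
  if (anyDuplicated(paste(tab$sample_id, tab$locus_id, sep = "\r"))) {
    stop("Genepop export requires one genotype per (sample, locus); ",
         "collapse replicates first (see call_consensus)")
  }
  samples <- unique(tab$sample_id)
  loci <- unique(tab$locus_id)
  if (is.null(populations)) {
    populations <- setNames(rep("Pop1", length(samples)), samples)
  }
  map <- do.call(rbind, lapply(loci, function(l) {
    al <- sort(unique(c(tab$allele_a[tab$locus_id == l],
                        tab$allele_b[tab$locus_id == l])))
    al <- al[!is.na(al)]
    if (length(al) >= 10^digits) stop("too many alleles for ", digits,
                                      "-digit Genepop codes at locus ", l)
    if (!length(al)) return(NULL)
    data.frame(locus_id = l, allele_bp = al, code = seq_along(al))
  }))
  code_of <- function(l, bp) {
    out <- rep(0L, length(bp))
    m <- map[map$locus_id == l, ]
    ok <- !is.na(bp)
    out[ok] <- m$code[match(bp[ok], m$allele_bp)]
    out
  }
  fmt <- function(x) formatC(x, width = digits, flag = "0")
  lines <- c(title, loci)
  for (pop in unique(populations[samples])) {
    lines <- c(lines, "Pop")
    for (s in samples[populations[samples] == pop]) {
      sub <- tab[tab$sample_id == s, ]
      entry <- vapply(loci, function(l) {
        r <- sub[sub$locus_id == l, ]
        if (!nrow(r)) return(paste0(fmt(0L), fmt(0L)))
        a <- code_of(l, r$allele_a[1L])
        b <- code_of(l, r$allele_b[1L])
        # a half-call is exported as missing: Genepop cannot express it
        if (is.na(r$allele_b[1L]) && !is.na(r$allele_a[1L])) b <- 0L
        if (is.na(r$allele_a[1L])) a <- 0L
        paste0(fmt(a), fmt(b))
      }, character(1L))
      lines <- c(lines, paste0(s, " , ", paste(entry, collapse = " ")))
    }
  }
  writeLines(lines, path)
  if (!is.null(map_path)) write.csv(map, map_path, row.names = FALSE)
  out <- path
  attr(out, "allele_map") <- map
  invisible(out)
}

## ---- sequences -------------------------------------------------------

#' Read / write DNA sequence sets (FASTA)
#'
#' Sequences are returned as a named character vector of upper-case
#' IUPAC DNA strings (alphabet `A,C,G,T,N,-`), the in-memory form used
#' throughout the package.  `write_fasta(read_fasta(x))` reproduces the
#' file up to line wrapping.
#'
#' @param path FASTA file.
#' @return named character vector of class `sequence_set`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  dn <- suppressWarnings(ape::read.FASTA(path))
  if (is.null(dn) || !length(dn)) stop("empty FASTA file: ", path)
  seqs <- vapply(as.character(dn), function(s) paste(s, collapse = ""),
                 character(1L))
  as_sequence_set(setNames(seqs, names(dn)))
}

#' @rdname read_fasta
#' @param seqs a `sequence_set` (or named character vector of DNA).
#' @param width line-wrap width.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  seqs <- as_sequence_set(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' @rdname read_fasta
#' @param x named character vector of DNA strings.
#' @export
as_sequence_set <- function(x) {
  if (inherits(x, "DNAbin")) {
    x <- setNames(vapply(as.character(x), paste, character(1L), collapse = ""),
                  labels(x))
  }
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    stop("sequences must be named")
  }
  if (anyDuplicated(names(x))) {
    stop("duplicate sequence id: ", names(x)[duplicated(names(x))][1L])
  }
  x <- toupper(unlist(x))
  bad <- grepl("[^ACGTN-]", x)
  if (any(bad)) {
    ch <- regmatches(x[bad][1L], regexpr("[^ACGTN-]", x[bad][1L]))
    stop("invalid character '", ch, "' in sequence ", names(x)[bad][1L])
  }
  class(x) <- "sequence_set"
  x
}

as_DNAbin <- function(seqs) {
  seqs <- unclass(seqs)
  ape::as.DNAbin(lapply(strsplit(tolower(seqs), ""), identity))
}

#' @export
print.sequence_set <- function(x, ...) {
  cat(length(x), "DNA sequences,",
      if (length(unique(nchar(x))) == 1L)
        paste(nchar(x[[1L]]), "bp (aligned)") else "varying length", "\n")
  invisible(x)
}

## ---- trees and Q matrices -------------------------------------------

#' Serialise a tree to Newick text
#'
#' Branch lengths are always written; internal-node bootstrap labels
#' (if present in `tree$node.label`) are written as internal node
#' labels.  Single-leaf and two-leaf trees are handled without error.
#'
#' @param tree an [ape::phylo] object, or a one-leaf stub (a character
#'   scalar label).
#' @return Newick string (with trailing `;`).
#' @export
write_newick <- function(tree) {
  if (is.character(tree) && length(tree) == 1L) {
    return(paste0(tree, ";"))
  }
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree)
}

#' Write / read an ancestry (Q) matrix
#'
#' CSV with columns `individual_id`, `population`, then one `Q<k>`
#' column per cluster; each row sums to 1.
#'
#' @param q matrix (individuals x K) of ancestry proportions with
#'   rownames, or an `admixture_fit`.
#' @param path output CSV.
#' @param populations optional named vector of population labels.
#' @export
write_qmatrix <- function(q, path, populations = NULL) {
  if (inherits(q, "admixture_fit")) {
    if (is.null(populations)) populations <- q$populations
    q <- q$Q
  }
  stopifnot(is.matrix(q))
  if (is.null(rownames(q))) rownames(q) <- paste0("ind", seq_len(nrow(q)))
  if (max(abs(rowSums(q) - 1)) > 1e-9) stop("Q rows must sum to 1")
  df <- data.frame(individual_id = rownames(q),
                   population = if (is.null(populations)) NA_character_
                                else unname(populations[rownames(q)]),
                   stringsAsFactors = FALSE)
  colnames(q) <- paste0("Q", seq_len(ncol(q)))
  write.csv(cbind(df, as.data.frame(q)), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_qmatrix
#' @export
read_qmatrix <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  qc <- grep("^Q[0-9]+$", names(df))
  q <- as.matrix(df[, qc, drop = FALSE])
  rownames(q) <- df$individual_id
  attr(q, "populations") <- setNames(df$population, df$individual_id)
  q
}

## ---- sample metadata -------------------------------------------------

#' Sample metadata
#'
#' One row per sample: population label, optional collection date and
#' GPS (decimal degrees, WGS84; carried as metadata, unused by the
#' statistics), and the molecular-sexing replicate band calls as a
#' `;`-separated string of `one_band` / `two_bands` / `fail`.
#'
#' @param sample_id,population character vectors.
#' @param collection_date optional `Date` (or parseable string).
#' @param lat,lon optional decimal degrees.
#' @param sex_replicates list of character vectors of band calls, or a
#'   `;`-joined string per sample.
#' @return data.frame of class `sample_metadata`.
#' @export
sample_metadata <- function(sample_id, population, collection_date = NA,
                            lat = NA_real_, lon = NA_real_,
                            sex_replicates = "") {
  if (anyDuplicated(sample_id)) {
    stop("duplicate sample_id: ", sample_id[duplicated(sample_id)][1L])
  }
  if (is.list(sex_replicates)) {
    sex_replicates <- vapply(sex_replicates, paste, character(1L),
                             collapse = ";")
  }
  calls <- unlist(strsplit(sex_replicates, ";", fixed = TRUE))
  ok <- calls %in% c("one_band", "two_bands", "fail") | !nzchar(calls)
  if (!all(ok)) stop("invalid sex band call: ", calls[!ok][1L])
  md <- data.frame(sample_id = as.character(sample_id),
                   population = as.character(population),
                   collection_date = as.character(collection_date),
                   lat = as.numeric(lat), lon = as.numeric(lon),
                   sex_replicates = sex_replicates,
                   stringsAsFactors = FALSE)
  class(md) <- c("sample_metadata", "data.frame")
  md
}

#' @rdname sample_metadata
#' @param path CSV file to read/write.
#' @export
read_sample_metadata <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  sample_metadata(df$sample_id, df$population,
                  collection_date = df$collection_date %||% NA,
                  lat = df$lat %||% NA_real_, lon = df$lon %||% NA_real_,
                  sex_replicates = df$sex_replicates %||% "")
}

#' @rdname sample_metadata
#' @param md a `sample_metadata` object.
#' @export
write_sample_metadata <- function(md, path) {
  write.csv(as.data.frame(md), path, row.names = FALSE, na = "")
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Split sex-replicate strings into band-call vectors
#' @param md a `sample_metadata` object.
#' @return named list, sample id to character vector of band calls.
#' @export
sex_replicate_list <- function(md) {
  out <- strsplit(md$sex_replicates, ";", fixed = TRUE)
  out <- lapply(out, function(x) x[nzchar(x)])
  setNames(out, md$sample_id)
}
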