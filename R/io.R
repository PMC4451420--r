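#' Read genotypes from PLINK text PED/MAP files
#'
#' Reads a whitespace-delimited PED/MAP pair plus a two-column population
#' table (sample_id, population). The allele code `0` marks a missing
#' allele; a call with either allele missing becomes a missing genotype.
#' Genotypes are recoded as counts of the alternate allele, where the
#' reference allele is the first distinct allele observed for the variant
#' reading the PED file top to bottom and the alternate is the second
#' (PLINK text files carry no allele column in the MAP).
#'
#' @param ped_path path to the PED file (6 leading columns, then two
#'   allele columns per variant).
#' @param map_path path to the MAP file (chrom, id, cM, pos).
#' @param pop_table path to a TSV with columns `sample_id`, `population`
#'   (header optional); every PED sample must appear.
#' @return a [genotype_dataset()] with variants sorted by (chrom, pos).
#' @export
read_genotypes <- function(ped_path, map_path, pop_table) {
  map_lines <- readLines(map_path)
  map_lines <- map_lines[nzchar(trimws(map_lines))]
  map <- lapply(seq_along(map_lines), function(i) {
    f <- strsplit(trimws(map_lines[i]), "[ \t]+")[[1]]
    if (length(f) < 4L)
      stop("malformed MAP line ", i, ": expected 4 fields, got ", length(f))
    f
  })
  variants <- data.frame(
    id = vapply(map, `[`, "", 2L),
    chrom = vapply(map, `[`, "", 1L),
    pos_bp = as.integer(vapply(map, `[`, "", 4L)),
    stringsAsFactors = FALSE)
  if (anyNA(variants$pos_bp))
    stop("malformed MAP line ", which(is.na(variants$pos_bp))[1],
         ": non-integer position")
  m <- nrow(variants)

  ped_lines <- readLines(ped_path)
  ped_lines <- ped_lines[nzchar(trimws(ped_lines))]
  n <- length(ped_lines)
  samples <- character(n)
  a1 <- matrix("0", n, m)
  a2 <- matrix("0", n, m)
  for (i in seq_len(n)) {
    f <- strsplit(trimws(ped_lines[i]), "[ \t]+")[[1]]
    if (length(f) != 6L + 2L * m)
      stop("malformed PED line ", i, ": expected ", 6L + 2L * m,
           " fields, got ", length(f))
    samples[i] <- f[2L]
    al <- f[-(1:6)]
    a1[i, ] <- al[seq(1L, 2L * m, by = 2L)]
    a2[i, ] <- al[seq(2L, 2L * m, by = 2L)]
  }

  pops <- read_population_table(pop_table)
  miss <- setdiff(samples, names(pops))
  if (length(miss))
    stop("samples absent from population table: ",
         paste(utils::head(miss, 5), collapse = ", "))

  calls <- matrix(NA_integer_, n, m)
  ref <- character(m)
  alt <- character(m)
  for (j in seq_len(m)) {
    obs <- rbind(a1[, j], a2[, j])        # column-interleaved: PED row order
    seen <- unique(as.vector(obs)[as.vector(obs) != "0"])
    if (length(seen) > 2L)
      stop("variant ", variants$id[j], " has >2 alleles: ",
           paste(seen, collapse = ", "))
    ref[j] <- if (length(seen) >= 1L) seen[1L] else "A"
    alt[j] <- if (length(seen) >= 2L) seen[2L] else "."
    ok <- a1[, j] != "0" & a2[, j] != "0"
    calls[ok, j] <- (a1[ok, j] == alt[j]) + (a2[ok, j] == alt[j])
  }
  variants$allele_ref <- ref
  variants$allele_alt <- alt
  genotype_dataset(calls, variants, samples, pops)
}

read_population_table <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "",
                          stringsAsFactors = FALSE,
                          col.names = c("sample_id", "population"))
  if (identical(tolower(df$sample_id[1]), "sample_id"))
    df <- df[-1L, , drop = FALSE]
  stats::setNames(as.character(df$population), df$sample_id)
}

KNOWN_BIOTYPES <- c("protein_coding", "miRNA", "snoRNA", "snRNA",
                    "rRNA", "pseudogene")

normalize_biotype <- function(x) {
  x <- as.character(x)
  out <- rep("other", length(x))
  hit <- match(tolower(x), tolower(KNOWN_BIOTYPES))
  out[!is.na(hit)] <- KNOWN_BIOTYPES[hit[!is.na(hit)]]
  out
}

#' Read gene features from BED or GFF3
#'
#' BED intervals (0-based half-open) are converted to 1-based inclusive
#' coordinates on read; GFF3 coordinates are kept as-is. The biotype is
#' taken from the 5th BED column when it matches a known biotype label,
#' or from a `biotype=`/`gene_biotype=` GFF3 attribute; anything else
#' becomes `other`.
#'
#' @param path file path.
#' @param fmt `"bed"` or `"gff3"`.
#' @return data frame with columns `id`, `chrom`, `start_bp`, `end_bp`,
#'   `biotype`; empty files give a zero-row frame.
#' @export
read_features <- function(path, fmt = c("bed", "gff3")) {
  fmt <- match.arg(fmt)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  empty <- data.frame(id = character(), chrom = character(),
                      start_bp = integer(), end_bp = integer(),
                      biotype = character(), stringsAsFactors = FALSE)
  if (!length(lines)) return(empty)
  rows <- lapply(seq_along(lines), function(i) {
    f <- strsplit(lines[i], "[ \t]+")[[1]]
    if (fmt == "bed") {
      if (length(f) < 3L)
        stop("malformed BED line ", i, ": fewer than 3 fields")
      start0 <- suppressWarnings(as.integer(f[2L]))
      end0 <- suppressWarnings(as.integer(f[3L]))
      if (is.na(start0) || is.na(end0))
        stop("malformed BED line ", i, ": non-integer coordinates")
      id <- if (length(f) >= 4L) f[4L] else paste0("feature", i)
      bt <- if (length(f) >= 5L) normalize_biotype(f[5L]) else "other"
      data.frame(id = id, chrom = f[1L], start_bp = start0 + 1L,
                 end_bp = end0, biotype = bt, stringsAsFactors = FALSE)
    } else {
      f <- strsplit(lines[i], "\t")[[1]]
      if (length(f) < 9L)
        stop("malformed GFF3 line ", i, ": fewer than 9 fields")
      start1 <- suppressWarnings(as.integer(f[4L]))
      end1 <- suppressWarnings(as.integer(f[5L]))
      if (is.na(start1) || is.na(end1))
        stop("malformed GFF3 line ", i, ": non-integer coordinates")
      attrs <- strsplit(f[9L], ";")[[1]]
      kv <- strsplit(trimws(attrs), "=")
      keys <- vapply(kv, `[`, "", 1L)
      vals <- vapply(kv, function(x) if (length(x) > 1L) x[2L] else "", "")
      getattr <- function(k) {
        hit <- match(tolower(k), tolower(keys))
        if (is.na(hit)) NA_character_ else vals[hit]
      }
      id <- getattr("ID")
      if (is.na(id)) id <- getattr("Name")
      if (is.na(id)) id <- paste0("feature", i)
      bt <- getattr("biotype")
      if (is.na(bt)) bt <- getattr("gene_biotype")
      data.frame(id = id, chrom = f[1L], start_bp = start1,
                 end_bp = end1, biotype = normalize_biotype(bt),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  if (any(out$start_bp > out$end_bp))
    stop("feature with start > end: ",
         out$id[which(out$start_bp > out$end_bp)[1]])
  if (any(out$start_bp < 1L))
    stop("feature with start < 1: ", out$id[which(out$start_bp < 1L)[1]])
  out[order(out$chrom, out$start_bp), , drop = FALSE]
}

#' Read phased haplotypes from a HAPS-style text file
#'
#' One row per variant: `chrom id pos allele_ref allele_alt` followed by
#' one 0/1 allele per haplotype; haplotype count must be even.
#'
#' @param path file path.
#' @param samples optional sample ids.
#' @return a [haplotype_set()].
#' @export
read_haplotypes <- function(path, samples = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty haplotype file: ", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (length(unique(nf)) != 1L)
    stop("ragged haplotype file: line ",
         which(nf != nf[1])[1], " has ", nf[which(nf != nf[1])[1]],
         " fields, expected ", nf[1])
  n_hap <- nf[1] - 5L
  if (n_hap < 2L || n_hap %% 2L != 0L)
    stop("haplotype count must be even and >= 2, got ", n_hap)
  variants <- data.frame(
    chrom = vapply(fields, `[`, "", 1L),
    id = vapply(fields, `[`, "", 2L),
    pos_bp = as.integer(vapply(fields, `[`, "", 3L)),
    allele_ref = vapply(fields, `[`, "", 4L),
    allele_alt = vapply(fields, `[`, "", 5L),
    stringsAsFactors = FALSE)
  al <- t(vapply(fields, function(f) {
    a <- f[-(1:5)]
    if (!all(a %in% c("0", "1")))
      stop("haplotype allele not in {0,1}: '",
           a[which(!(a %in% c("0", "1")))[1]], "'")
    as.integer(a)
  }, integer(n_hap)))
  haplotype_set(t(al), variants, samples = samples)
}

#' @rdname read_haplotypes
#' @param hapset a `haplotype_set` to write.
#' @export
write_haplotypes <- function(hapset, path) {
  stopifnot(inherits(hapset, "haplotype_set"))
  v <- hapset$variants
  body <- apply(hapset$haplotypes, 2L, paste, collapse = " ")
  lines <- paste(v$chrom, v$id, v$pos_bp, v$allele_ref, v$allele_alt, body)
  writeLines(lines, path)
  invisible(path)
}

#' Write a square PHYLIP-style distance matrix
#'
#' @param d a `dist` object or square symmetric matrix with labels.
#' @param path file path.
#' @export
write_dist_phylip <- function(d, path) {
  m <- as.matrix(d)
  labs <- rownames(m)
  lines <- c(sprintf("%5d", nrow(m)),
             vapply(seq_len(nrow(m)), function(i) {
               paste(formatC(labs[i], width = -10),
                     paste(sprintf("%.6f", m[i, ]), collapse = " "))
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' Published per-breed cattle diversity table
#'
#' The per-breed summary shipped with the package: breed abbreviation and
#' name, species assignment (taxon), dataset of origin, sample size,
#' observed heterozygosity and inbreeding coefficient for 46 cattle
#' breeds plus outgroup species (NA rows where too few animals were
#' typed). Used for group-level comparisons between taurine and indicine
#' breeds.
#'
#' @return data frame with columns `abb`, `name`, `tax`, `dataset`, `n`,
#'   `ho`, `fis`.
#' @export
cattle_diversity_table <- function() {
  path <- system.file("extdata", "table1_breeds.tsv", package = "bovidemog",
                      mustWork = TRUE)
  utils::read.delim(path, stringsAsFactors = FALSE)
}
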