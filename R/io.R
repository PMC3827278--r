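#' Read a GenomeStudio-style "Final Report" export
#'
#' Long-format, tab-separated, one row per (sample, SNP), with columns
#' `sample_id`, `snp_id`, `allele1`, `allele2` (call characters in `A`/`B`,
#' or `-` for a missing call), `gencall` (score in \[0, 1\]) and the two
#' normalized channel intensities `x` (allele A) and `y` (allele B).
#' The dosage is the count of B alleles: AA = 0, AB/BA = 1, BB = 2,
#' `- -` = missing. Intensities are stored even when the call is missing.
#'
#' @param path path to the TSV file.
#' @return a list with components `genotypes` (a [genotype_table()]) and
#'   `intensities` (an [intensity_table()]); sample and SNP orderings are the
#'   order of first appearance and are identical between the two tables.
#' @export
read_final_report <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(), snp_id = readr::col_character(),
    allele1 = readr::col_character(), allele2 = readr::col_character(),
    gencall = readr::col_double(), x = readr::col_double(), y = readr::col_double()
  ), progress = FALSE)
  required <- c("sample_id", "snp_id", "allele1", "allele2", "gencall", "x", "y")
  if (!all(required %in% names(df))) {
    stop("final report must contain columns: ", paste(required, collapse = ", "))
  }
  key <- paste(df$sample_id, df$snp_id, sep = "\r")
  dup <- anyDuplicated(key)
  if (dup) {
    stop(sprintf("duplicate (sample, SNP) row: (%s, %s)", df$sample_id[dup], df$snp_id[dup]))
  }
  bad <- which(!is.finite(df$gencall) | df$gencall < 0 | df$gencall > 1)
  if (length(bad)) stop(sprintf("gencall outside [0, 1] at data row %d", bad[1]))
  bad <- which(!is.finite(df$x) | df$x < 0 | !is.finite(df$y) | df$y < 0)
  if (length(bad)) stop(sprintf("negative or non-finite intensity at data row %d", bad[1]))
  bad <- which(!(df$allele1 %in% c("A", "B", "-")) | !(df$allele2 %in% c("A", "B", "-")))
  if (length(bad)) stop(sprintf("allele character outside {A, B, -} at data row %d", bad[1]))
  miss1 <- df$allele1 == "-"
  if (any(miss1 != (df$allele2 == "-"))) {
    bad <- which(miss1 != (df$allele2 == "-"))[1]
    stop(sprintf("half-missing call at data row %d: both alleles must be '-' or neither", bad))
  }

  samples <- unique(df$sample_id)
  snps <- unique(df$snp_id)
  if (nrow(df) != length(samples) * length(snps)) {
    stop("final report is not rectangular: every (sample, SNP) pair must appear exactly once")
  }
  dosage <- ifelse(miss1, NA_real_, (df$allele1 == "B") + (df$allele2 == "B"))
  i <- match(df$sample_id, samples)
  j <- match(df$snp_id, snps)
  mk <- function(v) {
    m <- matrix(NA_real_, length(samples), length(snps), dimnames = list(samples, snps))
    m[cbind(i, j)] <- v
    m
  }
  list(
    genotypes = genotype_table(mk(dosage), mk(df$gencall)),
    intensities = intensity_table(mk(df$x), mk(df$y))
  )
}

#' Write a final report TSV
#'
#' Inverse of [read_final_report()]; the write -> read round trip is the
#' identity on dosages and reproduces scores and intensities to 1e-6.
#'
#' @param genotypes a [genotype_table()].
#' @param intensities an [intensity_table()] with identical dimnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_final_report <- function(genotypes, intensities, path) {
  stopifnot(inherits(genotypes, "genotype_table"), inherits(intensities, "intensity_table"))
  if (!identical(dimnames(genotypes$dosage), dimnames(intensities$x))) {
    stop("genotype and intensity tables must share sample/SNP orderings")
  }
  g <- tidy(genotypes)
  i <- tidy(intensities)
  a1 <- dplyr::case_when(is.na(g$dosage) ~ "-", g$dosage >= 1 ~ "B", TRUE ~ "A")
  a2 <- dplyr::case_when(is.na(g$dosage) ~ "-", g$dosage == 2 ~ "B", TRUE ~ "A")
  out <- tibble::tibble(
    sample_id = g$sample_id, snp_id = g$snp_id,
    allele1 = a1, allele2 = a2,
    gencall = sprintf("%.6f", g$gencall),
    x = sprintf("%.6f", i$x), y = sprintf("%.6f", i$y)
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read a SNP manifest
#'
#' Tab-separated with a header; required columns `snp_id`, `gentrain`
#' (per-SNP clustering quality score in \[0, 1\]), `chrom` and `pos`
#' (1-based). Records are returned sorted by (chrom, pos); extra columns are
#' preserved but ignored by the pipeline.
#'
#' @param path path to the TSV file.
#' @return a tibble sorted by (chrom, pos).
#' @export
read_snp_manifest <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    snp_id = readr::col_character(), gentrain = readr::col_character(),
    chrom = readr::col_character(), pos = readr::col_double(),
    .default = readr::col_character()
  ), progress = FALSE)
  required <- c("snp_id", "gentrain", "chrom", "pos")
  if (!all(required %in% names(df))) {
    stop("manifest must contain columns: ", paste(required, collapse = ", "))
  }
  dup <- anyDuplicated(df$snp_id)
  if (dup) stop(sprintf("duplicate snp_id in manifest: %s", df$snp_id[dup]))
  gt <- suppressWarnings(as.numeric(df$gentrain))
  if (any(is.na(gt))) {
    stop(sprintf("non-numeric gentrain score for SNP %s", df$snp_id[which(is.na(gt))[1]]))
  }
  if (any(gt < 0 | gt > 1)) stop("gentrain scores must lie in [0, 1]")
  if (any(is.na(df$pos) | df$pos < 1 | df$pos != round(df$pos))) {
    stop("pos must be a positive integer (1-based)")
  }
  df$gentrain <- gt
  df$pos <- as.integer(df$pos)
  dplyr::arrange(df, .data$chrom, .data$pos)
}

#' Write a SNP manifest
#'
#' @param manifest tibble with at least `snp_id`, `gentrain`, `chrom`, `pos`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_snp_manifest <- function(manifest, path) {
  readr::write_tsv(manifest, path, progress = FALSE)
  invisible(path)
}

#' Read a sample-to-taxon map
#'
#' Two-column TSV (`sample_id`, `taxon`); a header line is detected and
#' skipped if its first field is `sample_id`. Duplicate consistent rows
#' collapse to one entry; duplicate samples with conflicting labels are an
#' error.
#'
#' @param path path to the TSV file.
#' @return a tibble with columns `sample_id` and `taxon`.
#' @export
read_species_map <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2)) stop("species map must have two tab-separated columns")
  df <- tibble::tibble(
    sample_id = vapply(parts, `[[`, "", 1),
    taxon = vapply(parts, `[[`, "", 2)
  )
  if (nrow(df) && df$sample_id[1] == "sample_id") df <- df[-1, ]
  df <- dplyr::distinct(df)
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup)) {
    stop(sprintf("sample %s mapped to conflicting taxon labels", dup[1]))
  }
  df
}

#' Write a sample-to-taxon map
#' @param map tibble with columns `sample_id` and `taxon`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_species_map <- function(map, path) {
  readr::write_tsv(map[, c("sample_id", "taxon")], path, progress = FALSE)
  invisible(path)
}

# Pad/truncate labels to the 10-character PHYLIP field, disambiguating
# truncation collisions deterministically by replacing the tail with a
# sequence number.
phylip_labels <- function(labels) {
  short <- substr(labels, 1, 10)
  while (anyDuplicated(short)) {
    d <- which(duplicated(short) | duplicated(short, fromLast = TRUE))
    grp <- split(d, short[d])
    for (idx in grp) {
      for (k in seq_along(idx)) {
        tag <- sprintf("_%d", k)
        short[idx[k]] <- paste0(substr(short[idx[k]], 1, 10 - nchar(tag)), tag)
      }
    }
  }
  gsub(" ", "_", formatC(short, width = 10, flag = "-"))
}

#' Write a labeled distance matrix in PHYLIP square format
#'
#' First line is the taxon count; each following line is a 10-character
#' label field then the full row of distances. Labels longer than 10
#' characters are truncated and disambiguated deterministically.
#'
#' @param m symmetric labeled matrix (zero diagonal, symmetric within 1e-9).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(m, path) {
  m <- check_distance_matrix(m, tol = 1e-9)
  labs <- phylip_labels(rownames(m))
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste0(labs[i], paste(sprintf("%.6f", m[i, ]), collapse = " "))
  }, "")
  readr::write_lines(c(sprintf("%5d", nrow(m)), rows), path)
  invisible(path)
}

#' Read a PHYLIP square distance matrix
#'
#' Paired reader for [write_distance_matrix()]; recovers entries to 1e-6.
#'
#' @param path path to the PHYLIP file.
#' @return symmetric labeled matrix.
#' @export
read_distance_matrix <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  n <- as.integer(trimws(lines[1]))
  if (is.na(n) || n < 2) stop("invalid PHYLIP count line")
  if (length(lines) < n + 1) stop("truncated PHYLIP matrix")
  labs <- character(n)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    line <- lines[i + 1]
    labs[i] <- trimws(substr(line, 1, 10))
    vals <- as.numeric(strsplit(trimws(substr(line, 11, nchar(line))), "\\s+")[[1]])
    if (length(vals) != n) stop(sprintf("row %d has %d values, expected %d", i, length(vals), n))
    m[i, ] <- vals
  }
  dimnames(m) <- list(labs, labs)
  check_distance_matrix(m, tol = 1e-5)
  m
}
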