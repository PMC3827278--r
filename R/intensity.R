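#' The seven intensity summary statistics
#'
#' @format character vector of the recognized kinds: `X`, `Y`, `X_PLUS_Y`,
#'   `X_FRAC` (X/(X+Y)), `LN_X_FRAC` (ln X/(X+Y)), `LN_Y_FRAC`
#'   (ln Y/(X+Y)), `LN_XY` (ln X/Y).
#' @export
SUMMARY_STAT_KINDS <- c("X", "Y", "X_PLUS_Y", "X_FRAC",
                        "LN_X_FRAC", "LN_Y_FRAC", "LN_XY")

#' Summary statistic of a two-channel intensity pair
#'
#' The quantitative-genotype transforms of the allele-A channel `x` and
#' allele-B channel `y`. Inputs must be strictly positive (an intensity
#' floor upstream guarantees this), so the log statistics are finite without
#' pseudocounts. `LN_XY` equals `LN_X_FRAC - LN_Y_FRAC` exactly.
#'
#' @param x,y positive numerics (vectorized).
#' @param kind one of [SUMMARY_STAT_KINDS].
#' @return numeric vector of the same length.
#' @export
summary_statistic <- function(x, y, kind = "LN_XY") {
  kind <- match.arg(kind, SUMMARY_STAT_KINDS)
  if (any(x <= 0) || any(y <= 0)) {
    stop("intensities must be strictly positive (floor violated)")
  }
  switch(kind,
    X = x,
    Y = y,
    X_PLUS_Y = x + y,
    X_FRAC = x / (x + y),
    LN_X_FRAC = log(x / (x + y)),
    LN_Y_FRAC = log(y / (x + y)),
    LN_XY = log(x / y)
  )
}

#' Per-species median profiles of an intensity summary statistic
#'
#' The "quantitative genotype" of a species: for each SNP, the median of the
#' chosen summary statistic over that taxon's samples (even counts: mean of
#' the two central order statistics). All array SNPs enter -- no genotype
#' filters apply to the intensity route -- and intensities are used even for
#' samples whose genotype call is missing.
#'
#' @param intensities an [intensity_table()].
#' @param species_map tibble `sample_id`, `taxon`.
#' @param kind one of [SUMMARY_STAT_KINDS].
#' @return object of class `species_profiles`: list with `values`
#'   (SNP x taxon matrix), `n_samples` (named vector), `kind`.
#' @export
species_median_profiles <- function(intensities, species_map, kind = "LN_XY") {
  stopifnot(inherits(intensities, "intensity_table"))
  kind <- match.arg(kind, SUMMARY_STAT_KINDS)
  map <- species_map[match(intensities$sample_id, species_map$sample_id), ]
  if (anyNA(map$taxon)) stop("species map does not cover all samples")
  v <- summary_statistic(intensities$x, intensities$y, kind)
  dim(v) <- dim(intensities$x)
  taxa <- sort(unique(map$taxon))
  values <- vapply(taxa, function(tx) {
    apply(v[map$taxon == tx, , drop = FALSE], 2, median)
  }, numeric(ncol(v)))
  rownames(values) <- intensities$snp_id
  n_samples <- vapply(taxa, function(tx) sum(map$taxon == tx), 0L)
  structure(list(values = values, n_samples = n_samples, kind = kind),
            class = "species_profiles")
}

#' @export
print.species_profiles <- function(x, ...) {
  cat(sprintf("<species_profiles> %s over %d SNPs x %d taxa\n",
              x$kind, nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' @method tidy species_profiles
#' @export
tidy.species_profiles <- function(x, ...) {
  tibble::as_tibble(x$values, rownames = "snp_id") |>
    tidyr::pivot_longer(-"snp_id", names_to = "taxon", values_to = "value") |>
    dplyr::mutate(kind = x$kind)
}

#' Euclidean distances between species profiles
#'
#' \eqn{d(i, j) = \sqrt{\sum_k (v_{ik} - v_{jk})^2}} over the SNP profile
#' vectors of each taxon pair.
#'
#' @param profiles a `species_profiles` object, or a SNP x taxon matrix.
#' @return symmetric labeled distance matrix with zero diagonal.
#' @export
euclidean_species_distance <- function(profiles) {
  v <- if (inherits(profiles, "species_profiles")) profiles$values else profiles
  if (any(!is.finite(v))) stop("profiles must be finite")
  m <- as.matrix(stats::dist(t(v), method = "euclidean"))
  check_distance_matrix(m)
  m
}

#' Write species profiles as TSV (SNP x taxon)
#' @param profiles a `species_profiles`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_species_profiles <- function(profiles, path) {
  readr::write_tsv(tibble::as_tibble(profiles$values, rownames = "snp_id"),
                   path, progress = FALSE)
  invisible(path)
}
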