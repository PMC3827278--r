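#' Genotype table
#'
#' A rectangular container of biallelic array genotypes: a samples x SNPs
#' dosage matrix counting copies of allele B (0/1/2, `NA` = missing call) and
#' a parallel matrix of per-call GenCall-style quality scores in \[0, 1\].
#'
#' @param dosage integer-valued matrix (samples x SNPs) with dimnames; values
#'   in 0/1/2 or `NA` for missing calls.
#' @param gencall numeric matrix of the same shape with per-call scores in
#'   \[0, 1\]; defaults to 1 everywhere.
#' @return an object of class `genotype_table`.
#' @export
genotype_table <- function(dosage, gencall = NULL) {
  if (!is.matrix(dosage)) stop("dosage must be a matrix")
  if (is.null(rownames(dosage)) || is.null(colnames(dosage))) {
    stop("dosage matrix needs sample rownames and SNP colnames")
  }
  ok <- is.na(dosage) | dosage %in% c(0, 1, 2)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  if (is.null(gencall)) {
    gencall <- matrix(1, nrow(dosage), ncol(dosage), dimnames = dimnames(dosage))
  }
  if (!identical(dim(gencall), dim(dosage))) stop("gencall and dosage shapes differ")
  if (any(gencall < 0 | gencall > 1, na.rm = TRUE)) stop("gencall scores must lie in [0, 1]")
  structure(
    list(dosage = dosage, gencall = gencall,
         sample_id = rownames(dosage), snp_id = colnames(dosage)),
    class = "genotype_table"
  )
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("<genotype_table> %d samples x %d SNPs (%.1f%% missing calls)\n",
              length(x$sample_id), length(x$snp_id),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' @export
dim.genotype_table <- function(x) dim(x$dosage)

#' Intensity table
#'
#' Two samples x SNPs matrices of nonnegative normalized channel intensities:
#' `x` for the allele-A channel and `y` for the allele-B channel. Intensities
#' are observed for every (sample, SNP) pair, including pairs whose genotype
#' call is missing.
#'
#' @param x,y numeric matrices (samples x SNPs) with identical dimnames;
#'   entries must be nonnegative.
#' @return an object of class `intensity_table`.
#' @export
intensity_table <- function(x, y) {
  if (!is.matrix(x) || !is.matrix(y)) stop("x and y must be matrices")
  if (!identical(dimnames(x), dimnames(y)) || !identical(dim(x), dim(y))) {
    stop("x and y must have identical shape and dimnames")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    stop("intensity matrices need sample rownames and SNP colnames")
  }
  if (any(!is.finite(x)) || any(!is.finite(y))) stop("intensities must be finite")
  if (any(x < 0) || any(y < 0)) stop("intensities must be nonnegative")
  structure(
    list(x = x, y = y, sample_id = rownames(x), snp_id = colnames(x)),
    class = "intensity_table"
  )
}

#' @export
print.intensity_table <- function(x, ...) {
  cat(sprintf("<intensity_table> %d samples x %d SNPs\n",
              length(x$sample_id), length(x$snp_id)))
  invisible(x)
}

#' @export
dim.intensity_table <- function(x) dim(x$x)

#' Subset a genotype or intensity table
#'
#' @param tab a `genotype_table` or `intensity_table`.
#' @param samples,snps character vectors (or logical/integer indices) of rows
#'   and columns to keep; `NULL` keeps all.
#' @return a table of the same class.
#' @export
subset_table <- function(tab, samples = NULL, snps = NULL) {
  samples <- samples %||% tab$sample_id
  snps <- snps %||% tab$snp_id
  if (inherits(tab, "genotype_table")) {
    genotype_table(tab$dosage[samples, snps, drop = FALSE],
                   tab$gencall[samples, snps, drop = FALSE])
  } else if (inherits(tab, "intensity_table")) {
    intensity_table(tab$x[samples, snps, drop = FALSE],
                    tab$y[samples, snps, drop = FALSE])
  } else {
    stop("not a genotype_table or intensity_table")
  }
}

#' Tidy a genotype table into long format
#'
#' @param x a `genotype_table`.
#' @param ... unused.
#' @return tibble with columns `sample_id`, `snp_id`, `dosage`, `gencall`.
#' @method tidy genotype_table
#' @export
tidy.genotype_table <- function(x, ...) {
  tibble::tibble(
    sample_id = rep(x$sample_id, times = length(x$snp_id)),
    snp_id = rep(x$snp_id, each = length(x$sample_id)),
    dosage = as.vector(x$dosage),
    gencall = as.vector(x$gencall)
  )
}

#' Tidy an intensity table into long format
#'
#' @param x an `intensity_table`.
#' @param ... unused.
#' @return tibble with columns `sample_id`, `snp_id`, `x`, `y`.
#' @method tidy intensity_table
#' @export
tidy.intensity_table <- function(x, ...) {
  xv <- as.vector(x$x)
  yv <- as.vector(x$y)
  tibble::tibble(
    sample_id = rep(x$sample_id, times = length(x$snp_id)),
    snp_id = rep(x$snp_id, each = length(x$sample_id)),
    x = xv,
    y = yv
  )
}
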