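#' Apply genotype quality filters
#'
#' Rules are applied in a fixed order, because order changes survivor counts:
#' 1. calls with GenCall score `< gencall_min` are set to missing;
#' 2. SNPs with GenTrain score `< gentrain_min` are dropped (needs a
#'    manifest; skipped with a note when `manifest` is `NULL`);
#' 3. SNPs with missing-call fraction `> missing_max` are dropped;
#' 4. SNPs with minor allele frequency `< maf_min` (computed over the
#'    remaining samples, missing calls excluded) are dropped.
#'
#' All comparisons are strict, so a SNP sitting exactly on a threshold is
#' kept. Intensity data are never filtered: the intensity route deliberately
#' uses every array SNP.
#'
#' @param g a [genotype_table()].
#' @param manifest tibble with `snp_id` and `gentrain`, or `NULL`.
#' @param gencall_min,gentrain_min,maf_min,missing_max thresholds in \[0, 1\].
#' @return list with `genotypes` (filtered table) and `report`
#'   (a `filter_report`).
#' @export
apply_genotype_filters <- function(g, manifest = NULL,
                                   gencall_min = 0.2, gentrain_min = 0.3,
                                   maf_min = 0.05, missing_max = 0.20) {
  thr <- c(gencall_min, gentrain_min, maf_min, missing_max)
  if (any(thr < 0 | thr > 1)) stop("filter thresholds must lie in [0, 1]")
  stopifnot(inherits(g, "genotype_table"))
  n_snps_in <- length(g$snp_id)
  n_samples_in <- length(g$sample_id)

  dosage <- g$dosage
  masked <- !is.na(dosage) & g$gencall < gencall_min
  dosage[masked] <- NA_real_

  keep <- rep(TRUE, n_snps_in)
  removed_gentrain <- 0L
  if (!is.null(manifest)) {
    gt <- manifest$gentrain[match(g$snp_id, manifest$snp_id)]
    if (anyNA(gt)) stop("manifest is missing gentrain scores for some SNPs")
    drop <- gt < gentrain_min
    removed_gentrain <- sum(drop)
    keep[drop] <- FALSE
  } else {
    message("no manifest supplied; GenTrain filter skipped")
  }

  miss_frac <- colMeans(is.na(dosage))
  drop <- keep & miss_frac > missing_max
  removed_missing <- sum(drop)
  keep[drop] <- FALSE

  p <- colSums(dosage, na.rm = TRUE) / (2 * colSums(!is.na(dosage)))
  maf <- pmin(p, 1 - p)
  maf[is.nan(maf)] <- 0  # all-missing SNPs have no definable MAF
  drop <- keep & maf < maf_min
  removed_maf <- sum(drop)
  keep[drop] <- FALSE

  out <- genotype_table(dosage[, keep, drop = FALSE], g$gencall[, keep, drop = FALSE])
  report <- structure(list(
    n_snps_in = n_snps_in, n_snps_out = sum(keep),
    n_samples_in = n_samples_in, n_samples_out = n_samples_in,
    calls_masked_gencall = sum(masked),
    snps_removed_gentrain = removed_gentrain,
    snps_removed_missing = removed_missing,
    snps_removed_maf = removed_maf,
    thresholds = list(gencall_min = gencall_min, gentrain_min = gentrain_min,
                      maf_min = maf_min, missing_max = missing_max)
  ), class = "filter_report")
  list(genotypes = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<filter_report> SNPs %d -> %d (GenTrain -%d, missingness -%d, MAF -%d);",
    " %d calls masked by GenCall\n"),
    x$n_snps_in, x$n_snps_out, x$snps_removed_gentrain,
    x$snps_removed_missing, x$snps_removed_maf, x$calls_masked_gencall))
  invisible(x)
}

#' @method tidy filter_report
#' @export
tidy.filter_report <- function(x, ...) {
  tibble::tibble(
    rule = c("gencall_mask", "gentrain", "missingness", "maf"),
    removed = c(x$calls_masked_gencall, x$snps_removed_gentrain,
                x$snps_removed_missing, x$snps_removed_maf),
    unit = c("calls", "snps", "snps", "snps"),
    threshold = c(x$thresholds$gencall_min, x$thresholds$gentrain_min,
                  x$thresholds$missing_max, x$thresholds$maf_min)
  )
}

#' Write a filter report as JSON
#' @param report a `filter_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_filter_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Windowed LD pruning of SNPs
#'
#' PLINK-style `--indep-pairwise` pruning on dosages: within each window of
#' `window` SNPs (in map order), pairs are scanned in index order and when
#' the squared Pearson correlation of dosages (over samples non-missing in
#' both; composite LD, genotypes being unphased) exceeds `r2_max`, the
#' member with the lower MAF is removed (ties: the higher index). The window
#' start then shifts by `step` SNPs; passes repeat until no window changes.
#' Monomorphic SNPs have undefined r-squared and are treated as
#' uncorrelated.
#'
#' @param g a [genotype_table()].
#' @param manifest optional tibble with `snp_id`, `chrom`, `pos`; when given,
#'   SNPs are scanned in (chrom, pos) order, otherwise in column order.
#' @param window window size in SNPs.
#' @param step window shift in SNPs.
#' @param r2_max removal threshold (strictly greater removes).
#' @return list with `kept` and `removed` character vectors of SNP ids.
#' @export
ld_prune <- function(g, manifest = NULL, window = 10, step = 3, r2_max = 0.5) {
  stopifnot(inherits(g, "genotype_table"))
  snps <- g$snp_id
  if (length(snps) < 2) return(list(kept = snps, removed = character(0)))
  if (!is.null(manifest)) {
    ord <- manifest$snp_id[manifest$snp_id %in% snps]
    if (!setequal(ord, snps)) stop("manifest does not cover the genotype SNPs")
    snps <- ord
  }
  dos <- g$dosage[, snps, drop = FALSE]
  p <- colSums(dos, na.rm = TRUE) / (2 * colSums(!is.na(dos)))
  maf <- pmin(p, 1 - p)

  kept <- seq_along(snps)
  repeat {
    removed_any <- FALSE
    alive <- rep(TRUE, length(kept))
    s <- 1
    while (s <= length(kept)) {
      win <- s:min(s + window - 1, length(kept))
      if (length(win) >= 2) {
        for (ai in seq_len(length(win) - 1)) {
          a <- win[ai]
          if (!alive[a]) next
          for (bi in (ai + 1):length(win)) {
            b <- win[bi]
            if (!alive[b]) next
            r <- suppressWarnings(
              cor(dos[, kept[a]], dos[, kept[b]], use = "pairwise.complete.obs"))
            if (!is.na(r) && r^2 > r2_max) {
              victim <- if (maf[kept[a]] < maf[kept[b]]) a
                        else if (maf[kept[b]] < maf[kept[a]]) b
                        else max(a, b)
              alive[victim] <- FALSE
              removed_any <- TRUE
              if (victim == a) break
            }
          }
        }
      }
      s <- s + step
    }
    kept <- kept[alive]
    if (!removed_any) break
  }
  list(kept = snps[kept], removed = setdiff(snps, snps[kept]))
}

#' Principal components of a genotype table
#'
#' Missing dosages are mean-imputed per SNP; columns are centered but not
#' scaled; coordinates come from the top-`k` singular directions. Axis signs
#' follow the convention that the largest-magnitude SNP loading on each axis
#' is positive, so results are reproducible across platforms.
#'
#' @param g a [genotype_table()] (typically post-filter, post-LD-prune).
#' @param k number of axes.
#' @return an object of class `pca_result`: `scores` (samples x k),
#'   `loadings` (SNPs x k), `explained` (variance fractions, all axes of the
#'   decomposition), `k`.
#' @export
genotype_pca <- function(g, k = 5) {
  stopifnot(inherits(g, "genotype_table"))
  X <- g$dosage
  if (k > min(dim(X))) stop("k exceeds min(samples, SNPs)")
  mu <- colMeans(X, na.rm = TRUE)
  mu[is.nan(mu)] <- 0
  idx <- which(is.na(X), arr.ind = TRUE)
  if (nrow(idx)) X[idx] <- mu[idx[, 2]]
  X <- sweep(X, 2, colMeans(X))
  sv <- svd(X)
  expl <- sv$d^2 / sum(sv$d^2)
  scores <- sv$u[, seq_len(k), drop = FALSE] %*% diag(sv$d[seq_len(k)], k)
  loadings <- sv$v[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    i <- which.max(abs(loadings[, j]))
    if (loadings[i, j] < 0) {
      loadings[, j] <- -loadings[, j]
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(scores) <- list(g$sample_id, paste0("PC", seq_len(k)))
  dimnames(loadings) <- list(g$snp_id, paste0("PC", seq_len(k)))
  structure(list(scores = scores, loadings = loadings, explained = expl, k = k),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("<pca_result> %d samples, %d axes; explained: %s\n",
              nrow(x$scores), x$k,
              paste(sprintf("%.1f%%", 100 * x$explained[seq_len(x$k)]), collapse = " ")))
  invisible(x)
}

#' @method tidy pca_result
#' @export
tidy.pca_result <- function(x, ...) {
  tibble::as_tibble(x$scores, rownames = "sample_id")
}

#' @method glance pca_result
#' @export
glance.pca_result <- function(x, ...) {
  tibble::tibble(axis = seq_len(x$k),
                 explained_variance = x$explained[seq_len(x$k)])
}

#' Flag putative curation errors from PCA coordinates
#'
#' Codifies the by-eye screen for mislabeled accessions: in the top-`m_axes`
#' PC space, a sample is flagged iff the nearest taxon centroid is not its
#' assigned taxon *and* the distance to its own centroid (computed
#' leave-one-out) exceeds `margin` times the distance to the nearest foreign
#' centroid. Taxa with a single sample can never be flagged (their
#' leave-one-out centroid is undefined); a warning notes them.
#'
#' @param pca a `pca_result`.
#' @param species_map tibble `sample_id`, `taxon`.
#' @param m_axes number of leading axes used.
#' @param margin multiplicative margin (> 1 demands clear misplacement).
#' @return tibble with one row per sample: `sample_id`, `taxon`,
#'   `nearest_taxon`, `dist_own`, `dist_nearest`, `flagged`.
#' @export
flag_curation_errors <- function(pca, species_map, m_axes = 5, margin = 1.5) {
  m <- min(m_axes, ncol(pca$scores))
  coords <- pca$scores[, seq_len(m), drop = FALSE]
  map <- species_map[match(rownames(coords), species_map$sample_id), ]
  if (anyNA(map$taxon)) stop("species map does not cover all samples in the PCA")
  taxa <- sort(unique(map$taxon))
  counts <- table(map$taxon)
  if (any(counts == 1)) {
    warning("taxa with a single sample cannot be screened: ",
            paste(names(counts)[counts == 1], collapse = ", "))
  }
  sums <- rowsum(coords, map$taxon)          # taxon x axes
  centroids <- sums / as.vector(counts[rownames(sums)])

  n <- nrow(coords)
  dist_own <- rep(NA_real_, n)
  nearest <- character(n)
  dist_nearest <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    tx <- map$taxon[i]
    d_for <- vapply(taxa, function(t2) {
      if (t2 == tx) return(Inf)
      sqrt(sum((coords[i, ] - centroids[t2, ])^2))
    }, 0)
    j <- which.min(d_for)
    nearest[i] <- taxa[j]
    dist_nearest[i] <- d_for[j]
    if (counts[[tx]] >= 2) {
      loo <- (sums[tx, ] - coords[i, ]) / (counts[[tx]] - 1)
      dist_own[i] <- sqrt(sum((coords[i, ] - loo)^2))
    }
  }
  flagged <- !is.na(dist_own) & dist_nearest < dist_own &
    dist_own > margin * dist_nearest
  tibble::tibble(sample_id = rownames(coords), taxon = map$taxon,
                 nearest_taxon = nearest, dist_own = dist_own,
                 dist_nearest = dist_nearest, flagged = flagged)
}
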