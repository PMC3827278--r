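#' Per-species allele statistics
#'
#' For each SNP and taxon with at least one non-missing call: the number of
#' non-missing diploids `n`, the allele-B frequency `p` (B dosage sum over
#' `2n`), the observed heterozygote proportion `h` (dosage-1 count over `n`)
#' and the minor allele frequency `maf = min(p, 1 - p)`. (taxon, SNP)
#' combinations with no calls are absent from the result, not zero.
#'
#' @param g a [genotype_table()].
#' @param species_map tibble `sample_id`, `taxon`.
#' @return tibble with columns `snp_id`, `taxon`, `n`, `p`, `h`, `maf`,
#'   of class `species_allele_stats`.
#' @export
species_allele_stats <- function(g, species_map) {
  stopifnot(inherits(g, "genotype_table"))
  map <- species_map[match(g$sample_id, species_map$sample_id), ]
  if (anyNA(map$taxon)) stop("species map does not cover all genotyped samples")
  taxa <- sort(unique(map$taxon))
  dos <- g$dosage
  res <- lapply(taxa, function(tx) {
    d <- dos[map$taxon == tx, , drop = FALSE]
    n <- colSums(!is.na(d))
    p <- colSums(d, na.rm = TRUE) / (2 * n)
    h <- colSums(!is.na(d) & d == 1) / n
    tibble::tibble(snp_id = g$snp_id, taxon = tx, n = as.integer(unname(n)),
                   p = unname(p), h = unname(h))
  })
  out <- dplyr::bind_rows(res)
  out <- dplyr::filter(out, .data$n > 0)
  out$maf <- pmin(out$p, 1 - out$p)
  class(out) <- c("species_allele_stats", class(out))
  out
}

# stats tibble -> aligned per-taxon matrices (SNP x taxon), NA where absent.
stats_matrices <- function(stats) {
  snps <- unique(stats$snp_id)
  taxa <- sort(unique(stats$taxon))
  mk <- function(col) {
    m <- matrix(NA_real_, length(snps), length(taxa), dimnames = list(snps, taxa))
    m[cbind(match(stats$snp_id, snps), match(stats$taxon, taxa))] <- stats[[col]]
    m
  }
  list(n = mk("n"), p = mk("p"), h = mk("h"))
}

#' Minor allele frequency spectrum of one taxon
#'
#' Histogram over SNPs with a defined MAF for the taxon; `breaks` must
#' partition \[0, 0.5\]. Bins are left-closed, right-open, except the last
#' which includes 0.5. The counts sum to the number of defined-MAF SNPs.
#'
#' @param stats a [species_allele_stats()] tibble.
#' @param taxon taxon label.
#' @param breaks increasing break points from 0 to 0.5.
#' @return tibble with `bin_lo`, `bin_hi`, `count`, `taxon`.
#' @export
maf_spectrum <- function(stats, taxon, breaks = seq(0, 0.5, by = 0.05)) {
  if (abs(breaks[1]) > 1e-12 || abs(breaks[length(breaks)] - 0.5) > 1e-12 ||
      any(diff(breaks) <= 0)) {
    stop("breaks must increase from 0 to 0.5")
  }
  maf <- stats$maf[stats$taxon == taxon]
  if (!length(maf)) stop(sprintf("no SNPs with defined MAF for taxon %s", taxon))
  idx <- findInterval(maf, breaks, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- tabulate(idx, nbins = length(breaks) - 1)
  tibble::tibble(bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
                 count = counts, taxon = taxon)
}

#' Count SNPs fixed for the same allele in two taxa
#'
#' A SNP counts iff both taxa are monomorphic there (`p` is exactly 0 or 1)
#' *and* fixed for the same allele; opposite fixation does not count.
#'
#' @param stats a [species_allele_stats()] tibble.
#' @param taxon_a,taxon_b taxon labels.
#' @return integer count.
#' @export
count_shared_monomorphic <- function(stats, taxon_a, taxon_b) {
  sm <- stats_matrices(stats)
  pa <- sm$p[, taxon_a]
  pb <- sm$p[, taxon_b]
  ok <- !is.na(pa) & !is.na(pb)
  sum(ok & (pa == 0 | pa == 1) & pb == pa)
}

#' Pairwise shared-monomorphic count table
#'
#' @param stats a [species_allele_stats()] tibble.
#' @return tibble with `taxon_a`, `taxon_b`, `n_shared_monomorphic` for each
#'   unordered taxon pair.
#' @export
shared_monomorphic_table <- function(stats) {
  taxa <- sort(unique(stats$taxon))
  pairs <- utils::combn(taxa, 2)
  sm <- stats_matrices(stats)
  counts <- apply(pairs, 2, function(pr) {
    pa <- sm$p[, pr[1]]; pb <- sm$p[, pr[2]]
    sum(!is.na(pa) & !is.na(pb) & (pa == 0 | pa == 1) & pb == pa)
  })
  tibble::tibble(taxon_a = pairs[1, ], taxon_b = pairs[2, ],
                 n_shared_monomorphic = as.integer(counts))
}

#' Weir--Cockerham variance components for one taxon pair
#'
#' Per-locus moment components of the two-population (r = 2) diploid
#' estimator: with sample sizes `n1`, `n2`, allele frequencies `p1`, `p2`
#' and observed heterozygosities `h1`, `h2`,
#' \deqn{\bar n = (n_1+n_2)/2,\quad
#'   n_c = 2\bar n - (n_1^2+n_2^2)/(2\bar n),\quad
#'   \bar p = (n_1 p_1 + n_2 p_2)/(2\bar n),}
#' \deqn{s^2 = [n_1(p_1-\bar p)^2 + n_2(p_2-\bar p)^2]/\bar n,\quad
#'   \bar h = (n_1 h_1 + n_2 h_2)/(2\bar n),}
#' and the among-population (`a`), among-individual (`b`) and
#' within-individual (`c`) components
#' \deqn{a = \frac{\bar n}{n_c}\left[s^2 - \frac{1}{\bar n - 1}
#'   \left(\bar p(1-\bar p) - \frac{s^2}{2} - \frac{\bar h}{4}\right)\right],}
#' \deqn{b = \frac{\bar n}{\bar n - 1}\left[\bar p(1-\bar p) -
#'   \frac{s^2}{2} - \frac{2\bar n - 1}{4\bar n}\bar h\right],\qquad
#'   c = \bar h / 2.}
#'
#' @param n1,n2 non-missing diploid counts (vectors over loci).
#' @param p1,p2 allele-B frequencies.
#' @param h1,h2 observed heterozygote proportions.
#' @return tibble with columns `a`, `b`, `c`.
#' @export
fst_components <- function(n1, p1, h1, n2, p2, h2) {
  nbar <- (n1 + n2) / 2
  nc <- 2 * nbar - (n1^2 + n2^2) / (2 * nbar)
  pbar <- (n1 * p1 + n2 * p2) / (2 * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  hbar <- (n1 * h1 + n2 * h2) / (2 * nbar)
  a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - s2 / 2 - hbar * (2 * nbar - 1) / (4 * nbar))
  cc <- hbar / 2
  tibble::tibble(a = a, b = b, c = cc)
}

#' Weighted pairwise F_ST between one pair of taxa
#'
#' Ratio-of-sums ("weighted average") estimator over loci:
#' \eqn{\theta = \sum_l a_l / \sum_l (a_l + b_l + c_l)}. Loci require at
#' least two non-missing diploids in each taxon; loci monomorphic for the
#' same allele in both taxa contribute 0/0 and are excluded from both sums.
#' Negative estimates are retained, not clamped.
#'
#' @param stats a [species_allele_stats()] tibble (or the matrices from the
#'   internal helper).
#' @param taxon_a,taxon_b taxon labels.
#' @return scalar theta estimate.
#' @export
pairwise_fst <- function(stats, taxon_a, taxon_b) {
  sm <- if (is.list(stats) && !is.data.frame(stats)) stats else stats_matrices(stats)
  pairwise_fst_from_matrices(sm, taxon_a, taxon_b)
}

pairwise_fst_from_matrices <- function(sm, taxon_a, taxon_b) {
  n1 <- sm$n[, taxon_a]; p1 <- sm$p[, taxon_a]; h1 <- sm$h[, taxon_a]
  n2 <- sm$n[, taxon_b]; p2 <- sm$p[, taxon_b]; h2 <- sm$h[, taxon_b]
  ok <- !is.na(n1) & !is.na(n2) & n1 >= 2 & n2 >= 2
  both_mono_same <- ok & (p1 == 0 | p1 == 1) & p2 == p1 & h1 == 0 & h2 == 0
  ok <- ok & !both_mono_same
  if (!any(ok)) {
    stop(sprintf("no informative loci for taxon pair (%s, %s)", taxon_a, taxon_b))
  }
  comp <- fst_components(n1[ok], p1[ok], h1[ok], n2[ok], p2[ok], h2[ok])
  denom <- sum(comp$a + comp$b + comp$c)
  if (denom <= 0) {
    stop(sprintf("degenerate F_ST denominator for taxon pair (%s, %s)", taxon_a, taxon_b))
  }
  sum(comp$a) / denom
}

#' Pairwise F_ST distance matrix over taxa
#'
#' Applies [pairwise_fst()] to every unordered taxon pair. The diagonal is
#' zero; negative estimates are retained (apply [shift_nonnegative()] before
#' tree building).
#'
#' @param stats a [species_allele_stats()] tibble.
#' @param taxa taxon labels to include (default: all in `stats`).
#' @return symmetric labeled matrix of theta estimates.
#' @export
pairwise_fst_matrix <- function(stats, taxa = NULL) {
  taxa <- taxa %||% sort(unique(stats$taxon))
  sm <- stats_matrices(stats)
  m <- matrix(0, length(taxa), length(taxa), dimnames = list(taxa, taxa))
  for (i in seq_len(length(taxa) - 1)) {
    for (j in (i + 1):length(taxa)) {
      th <- pairwise_fst_from_matrices(sm, taxa[i], taxa[j])
      m[i, j] <- m[j, i] <- th
    }
  }
  m
}
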