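#' Mantel permutation test between two labeled distance matrices
#'
#' The statistic is the Pearson correlation of the lower-triangle vectors
#' (after aligning `m2` to `m1`'s label order). Each permutation applies a
#' simultaneous row/column relabeling to `m2`. The one-sided (positive
#' association) p-value uses the add-one estimator
#' \eqn{p = (\#\{r_{perm} \ge r_{obs}\} + 1)/(P + 1)}, so `p >= 1/(P+1)`
#' always.
#'
#' @param m1,m2 symmetric labeled matrices over the same label set, n >= 4.
#' @param permutations number of permutations P.
#' @param seed RNG seed for the permutation stream.
#' @return object of class `mantel_result`.
#' @export
mantel_test <- function(m1, m2, permutations = 10000, seed = 1L) {
  m1 <- check_distance_matrix(m1, tol = 1e-8)
  m2 <- check_distance_matrix(m2, tol = 1e-8)
  if (!setequal(rownames(m1), rownames(m2))) stop("label sets differ")
  if (nrow(m1) < 4) stop("Mantel test needs at least 4 labels")
  m2 <- m2[rownames(m1), rownames(m1)]
  v1 <- m1[lower.tri(m1)]
  v2 <- m2[lower.tri(m2)]
  if (sd(v1) == 0 || sd(v2) == 0) stop("constant distance matrix: correlation undefined")
  r_obs <- cor(v1, v2)
  n <- nrow(m1)
  lt <- lower.tri(m2)
  perm_r <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(permutations), function(k) {
      pm <- sample.int(n)
      cor(v1, m2[pm, pm][lt])
    }, 0)
  })
  p <- (sum(perm_r >= r_obs) + 1) / (permutations + 1)
  structure(list(statistic = r_obs, p_value = p, permutations = permutations,
                 seed = as.integer(seed), n = n),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("<mantel_result> r = %.4f, one-sided p = %.4g (%d permutations)\n",
              x$statistic, x$p_value, x$permutations))
  invisible(x)
}

#' @method tidy mantel_result
#' @export
tidy.mantel_result <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, p_value = x$p_value,
                 permutations = x$permutations, n = x$n)
}

#' @method glance mantel_result
#' @export
glance.mantel_result <- tidy.mantel_result

#' Classical multidimensional scaling (principal coordinates)
#'
#' Double-centers the squared-distance matrix, eigendecomposes, and scales
#' eigenvectors by the square roots of the positive eigenvalues. Axes are
#' ordered by eigenvalue and signed so the largest-magnitude coordinate on
#' each axis is positive. If fewer than `k` positive eigenvalues exist the
#' result is truncated with a warning.
#'
#' @param m symmetric labeled distance matrix, n >= 3.
#' @param k number of axes requested.
#' @return object of class `mds_result`: `coords` (labels x axes),
#'   `eigenvalues` (all), `k`.
#' @export
classical_mds <- function(m, k = 2) {
  m <- check_distance_matrix(m, tol = 1e-8)
  if (nrow(m) < 2) stop("MDS needs at least 2 labels")
  res <- cmdscale(m, k = min(k, nrow(m) - 1), eig = TRUE)
  npos <- sum(res$eig > 1e-12)
  if (npos < k) {
    warning(sprintf("only %d positive eigenvalues; returning %d axes", npos, npos))
  }
  kk <- min(k, npos)
  coords <- res$points[, seq_len(kk), drop = FALSE]
  for (j in seq_len(ncol(coords))) {
    i <- which.max(abs(coords[, j]))
    if (coords[i, j] < 0) coords[, j] <- -coords[, j]
  }
  colnames(coords) <- paste0("axis", seq_len(ncol(coords)))
  structure(list(coords = coords, eigenvalues = res$eig, k = kk),
            class = "mds_result")
}

#' @export
print.mds_result <- function(x, ...) {
  cat(sprintf("<mds_result> %d labels on %d axes\n", nrow(x$coords), x$k))
  invisible(x)
}

#' @method tidy mds_result
#' @export
tidy.mds_result <- function(x, ...) {
  tibble::as_tibble(x$coords, rownames = "label")
}

#' Focal elevation statistic for two distance matrices
#'
#' Operationalizes "distances involving the focal taxa are systematically
#' elevated in one matrix relative to the other" as a scale-free rank
#' statistic: the off-diagonal entries of each matrix are rank-transformed
#' to \[0, 1\] (average ranks for ties), and the statistic is the mean of
#' `rank(m_int) - rank(m_fst)` over the taxon pairs involving at least one
#' focal taxon. Positive values mean the intensity route elevates
#' focal-involving distances relative to the genotype route; identical
#' matrices give exactly 0.
#'
#' @param m_int,m_fst symmetric labeled matrices over the same labels.
#' @param focal_taxa character vector of focal labels (>= 1); at least two
#'   non-focal labels are required.
#' @return scalar statistic in \[-1, 1\].
#' @export
focal_elevation_statistic <- function(m_int, m_fst, focal_taxa) {
  m_int <- check_distance_matrix(m_int, tol = 1e-8)
  m_fst <- check_distance_matrix(m_fst, tol = 1e-8)
  if (!setequal(rownames(m_int), rownames(m_fst))) stop("label sets differ")
  labs <- rownames(m_int)
  m_fst <- m_fst[labs, labs]
  if (!any(focal_taxa %in% labs)) stop("no focal taxa present in the matrices")
  if (length(setdiff(labs, focal_taxa)) < 2) stop("need at least two non-focal taxa")
  pr <- which(lower.tri(m_int), arr.ind = TRUE)
  involves_focal <- labs[pr[, 1]] %in% focal_taxa | labs[pr[, 2]] %in% focal_taxa
  if (!any(involves_focal)) stop("no focal-involving pairs")
  r_int <- unit_rank(m_int[lower.tri(m_int)])
  r_fst <- unit_rank(m_fst[lower.tri(m_fst)])
  mean(r_int[involves_focal] - r_fst[involves_focal])
}

#' Topology-distance table over a set of trees
#'
#' Pairwise Penny--Hendy distances between trees built from different
#' distance measures (e.g. the seven intensity summary statistics).
#'
#' @param trees named list of `phylo` trees on identical leaf sets.
#' @return symmetric integer matrix with zero diagonal.
#' @export
topology_distance_table <- function(trees) {
  stopifnot(is.list(trees), !is.null(names(trees)))
  k <- length(trees)
  m <- matrix(0L, k, k, dimnames = list(names(trees), names(trees)))
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      m[i, j] <- m[j, i] <- as.integer(tree_topology_distance(trees[[i]], trees[[j]]))
    }
  }
  m
}
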