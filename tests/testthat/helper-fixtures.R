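# Shared fixtures, all built in code.

# a small genotype table from a plain matrix
make_gt <- function(dosage, gencall = NULL) {
  if (is.null(rownames(dosage))) rownames(dosage) <- sprintf("s%02d", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage))) colnames(dosage) <- sprintf("snp%03d", seq_len(ncol(dosage)))
  if (!is.null(gencall)) dimnames(gencall) <- dimnames(dosage)
  genotype_table(dosage, gencall)
}

# a small simulation: 6 taxa, few samples, quick to generate
tiny_config <- function(seed = 42, ...) {
  sim_config(n_species = 6, samples_per_species = 8, n_candidate_snps = 400,
             seed = seed, ...)
}

# random labeled distance matrix from points in the plane
random_dist <- function(n, seed, labels = sprintf("t%02d", seq_len(n))) {
  withr::with_seed(seed, {
    pts <- matrix(rnorm(2 * n), n, 2)
  })
  m <- as.matrix(dist(pts))
  dimnames(m) <- list(labels, labels)
  m
}

# random binary unrooted tree with positive branch lengths
random_tree <- function(n, seed) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n, rooted = FALSE)
    tr$edge.length <- runif(length(tr$edge.length), 0.1, 2)
  })
  tr
}

expect_tree_equal_topology <- function(t1, t2) {
  expect_identical(tree_topology_distance(t1, t2), 0L)
}
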