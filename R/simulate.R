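#' Generate (or parse) the species tree for a simulation
#'
#' With `cfg$newick` set, the tree is parsed and must carry branch lengths on
#' every edge. Otherwise a pure-birth tree on `cfg$n_species` leaves is
#' simulated, rescaled so the deepest root-to-tip path equals
#' `cfg$tree_depth`, and branch lengths are floored at `cfg$min_branch`.
#' Leaves are labeled `sp01`, `sp02`, ... in the simulated case.
#'
#' @param cfg a [sim_config()].
#' @param seed RNG seed (default: derived from `cfg$seed`).
#' @return a rooted `phylo` tree with positive branch lengths.
#' @export
generate_species_tree <- function(cfg, seed = NULL) {
  if (!is.null(cfg$newick)) {
    tr <- parse_newick(cfg$newick)
    if (is.null(tr$edge.length) || anyNA(tr$edge.length)) {
      stop("species tree newick must carry a branch length on every edge")
    }
    if (any(tr$edge.length <= 0)) stop("species tree branch lengths must be positive")
    return(tr)
  }
  seed <- seed %||% derive_seeds(cfg$seed, 6)[1]
  tr <- withr::with_seed(seed, ape::rphylo(cfg$n_species, birth = cfg$birth_rate, death = 0))
  depth <- max(ape::node.depth.edgelength(tr)[seq_len(cfg$n_species)])
  tr$edge.length <- tr$edge.length * (cfg$tree_depth / depth)
  tr$edge.length <- pmax(tr$edge.length, cfg$min_branch)
  tr$tip.label <- sprintf("sp%02d", seq_len(cfg$n_species))
  tr
}

#' Evolve allele-B frequencies along a species tree
#'
#' Per SNP, the root frequency is drawn uniformly from
#' `cfg$ancestral_maf_range`; along each branch of length `t` the child
#' frequency is drawn from the Balding--Nichols drift law with fixation index
#' `F = 1 - exp(-t)`:
#' \deqn{p_{child} \sim Beta(p(1-F)/F,\; (1-p)(1-F)/F),}
#' which has mean `p` and variance `p(1-p)F`. Frequencies sampled within
#' `cfg$absorb_eps` of 0/1 are absorbed at the boundary, and an absorbed
#' frequency is inherited unchanged by all descendants. A zero-length branch
#' copies the parent exactly; negative branch lengths are an error.
#'
#' @param tree rooted `phylo` with branch lengths.
#' @param cfg a [sim_config()].
#' @param n_snps number of SNPs (default `cfg$n_candidate_snps`).
#' @param seed RNG seed.
#' @return matrix `n_snps` x n_leaves of allele-B frequencies, columns named
#'   by tip label.
#' @export
evolve_allele_frequencies <- function(tree, cfg, n_snps = cfg$n_candidate_snps, seed = NULL) {
  if (any(tree$edge.length < 0)) stop("branch lengths must be nonnegative")
  seed <- seed %||% derive_seeds(cfg$seed, 6)[2]
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  tr <- stats::reorder(tree, "cladewise")  # parents precede children
  eps <- cfg$absorb_eps
  withr::with_seed(seed, {
    freq <- matrix(NA_real_, n_snps, nnode)
    freq[, root] <- runif(n_snps, cfg$ancestral_maf_range[1], cfg$ancestral_maf_range[2])
    for (e in seq_len(nrow(tr$edge))) {
      parent <- tr$edge[e, 1]
      child <- tr$edge[e, 2]
      t <- tr$edge.length[e]
      p <- freq[, parent]
      q <- drift_child_frequency(p, t, eps)
      freq[, child] <- q
    }
  })
  out <- freq[, seq_len(ntip), drop = FALSE]
  colnames(out) <- tree$tip.label
  out
}

# Balding-Nichols child frequency for a vector of parent frequencies and a
# single branch length. Exposed internally so moment tests can target it.
drift_child_frequency <- function(p, t, eps = 1e-4) {
  if (t < 0) stop("branch length must be nonnegative")
  if (t == 0) return(p)
  FST <- 1 - exp(-t)
  q <- p
  seg <- which(p > 0 & p < 1)
  if (length(seg)) {
    k <- (1 - FST) / FST
    q[seg] <- rbeta(length(seg), p[seg] * k, (1 - p[seg]) * k)
  }
  q[q < eps] <- 0
  q[q > 1 - eps] <- 1
  q
}

#' Ascertain candidate SNPs through a discovery panel
#'
#' Panel individuals are drawn per taxon from the true frequencies (two
#' binomial allele draws per diploid); a candidate SNP is retained iff its
#' minor allele frequency *in the sampled panel* is at least
#' `cfg$panel_maf_min`. Using sampled panel genotypes (not true frequencies)
#' means panel size and composition matter, as in real SNP discovery.
#'
#' @param freqs matrix of per-taxon allele-B frequencies
#'   (from [evolve_allele_frequencies()]).
#' @param cfg a [sim_config()].
#' @param focal focal taxon label (for the default panel composition).
#' @param seed RNG seed.
#' @return logical vector over candidate SNPs with attributes
#'   `panel` (composition used) and `panel_maf` (sampled panel MAF).
#' @export
ascertain_snps <- function(freqs, cfg, focal, seed = NULL) {
  seed <- seed %||% derive_seeds(cfg$seed, 6)[3]
  panel <- panel_composition(cfg$panel_composition, colnames(freqs), focal)
  n_snps <- nrow(freqs)
  withr::with_seed(seed, {
    b_count <- rep(0, n_snps)
    for (tx in names(panel)) {
      b_count <- b_count + rbinom(n_snps, 2L * panel[[tx]], freqs[, tx])
    }
  })
  total <- 2L * sum(panel)
  maf <- pmin(b_count, total - b_count) / total
  keep <- maf >= cfg$panel_maf_min
  if (!any(keep)) {
    stop("no candidate SNP passed panel ascertainment; increase n_candidate_snps")
  }
  attr(keep, "panel") <- panel
  attr(keep, "panel_maf") <- maf
  keep
}

#' Simulate genotype calls
#'
#' Per sample, the dosage at a SNP is Binomial(2, p) on that taxon's true
#' allele-B frequency; completely-at-random missingness masks calls at
#' `cfg$missing_rate`. True dosages are retained alongside the observed
#' (masked) ones so intensities can be generated for missing calls too.
#'
#' @param freqs per-taxon frequency matrix restricted to ascertained SNPs.
#' @param species_map tibble `sample_id`, `taxon`.
#' @param cfg a [sim_config()].
#' @param seed RNG seed.
#' @return list with `true_dosage` (matrix) and `observed` (matrix with NA).
#' @export
simulate_genotypes <- function(freqs, species_map, cfg, seed = NULL) {
  seed <- seed %||% derive_seeds(cfg$seed, 6)[4]
  n_snps <- nrow(freqs)
  snp_ids <- rownames(freqs) %||% sprintf("snp%05d", seq_len(n_snps))
  withr::with_seed(seed, {
    g <- matrix(NA_real_, nrow(species_map), n_snps,
                dimnames = list(species_map$sample_id, snp_ids))
    for (i in seq_len(nrow(species_map))) {
      g[i, ] <- rbinom(n_snps, 2L, freqs[, species_map$taxon[i]])
    }
    mask <- matrix(runif(length(g)) < cfg$missing_rate, nrow(g), ncol(g))
  })
  observed <- g
  observed[mask] <- NA_real_
  list(true_dosage = g, observed = observed)
}

#' Simulate two-channel hybridization intensities and quality scores
#'
#' Probe affinity for a sample of taxon s is `alpha = exp(-lambda * d_s)`
#' with `d_s` the tree path distance from the focal (array-design) taxon;
#' an off-target variant (OTV) at a (taxon, SNP) multiplies affinity by
#' `1 - delta`. OTVs arise as probe-site mutations on the branches of the
#' path focal -> taxon (Bernoulli `1 - exp(-mu * t)` per branch per SNP), so
#' the marginal OTV probability is `1 - exp(-mu * d_s)` and OTVs are shared
#' along the tree. Channels are
#' \deqn{X = max(\epsilon_0,\; \alpha S (2-g)/2 + b + N(0, \sigma^2)),\quad
#'       Y = max(\epsilon_0,\; \alpha S g/2 + b + N(0, \sigma^2)),}
#' with g the *true* dosage (missing calls still hybridize).
#'
#' A GenCall-like per-call score is `exp(-dmin / tau)`, `tau = sigma +
#' epsilon_0`, where `dmin` is the distance of (X, Y) to the nearest
#' noise-free cluster centroid at the taxon-level affinity (OTV excluded:
#' systematic decay is absorbed by cluster retraining, OTV-shifted points
#' fall off-cluster and score low). A GenTrain-like per-SNP score is
#' `gap / (gap + 4 sigma)` with `gap` the smallest distance between the
#' empirical dosage-class centroids of the SNP (1 when fewer than two
#' classes are observed).
#'
#' @param freqs ascertained frequency matrix (for dimension checks).
#' @param true_dosage matrix from [simulate_genotypes()].
#' @param species_map tibble `sample_id`, `taxon`.
#' @param d_s named per-taxon path distance from the focal taxon.
#' @param cfg a [sim_config()].
#' @param tree the species tree (for OTV branch sharing).
#' @param focal focal taxon label.
#' @param seed RNG seed.
#' @return list with `intensities` (an [intensity_table()]), `gencall`
#'   (matrix), `gentrain` (named vector) and `otv` (taxa x SNPs logical).
#' @export
simulate_intensities <- function(freqs, true_dosage, species_map, d_s, cfg,
                                 tree, focal, seed = NULL) {
  if (cfg$channel_noise < 0) stop("channel noise sd must be nonnegative")
  seed <- seed %||% derive_seeds(cfg$seed, 6)[5]
  n_snps <- ncol(true_dosage)
  snp_ids <- colnames(true_dosage)
  taxa <- colnames(freqs)
  S <- cfg$signal; b <- cfg$background; sig <- cfg$channel_noise
  eps0 <- cfg$intensity_floor

  # OTV events: per-SNP Bernoulli mutation on each branch, a taxon carries
  # the OTV iff any mutated branch lies on its path from the focal leaf.
  inc <- path_edge_incidence(tree, focal)          # taxa x edges
  withr::with_seed(seed, {
    pmut <- 1 - exp(-cfg$mu * tree$edge.length)
    M <- matrix(rbinom(length(pmut) * n_snps, 1L, rep(pmut, n_snps)),
                nrow = length(pmut), ncol = n_snps)  # edges x SNPs
    otv <- (inc %*% M) > 0                           # taxa x SNPs
    dimnames(otv) <- list(rownames(inc), snp_ids)

    alpha_tax <- exp(-cfg$lambda * d_s[taxa])
    names(alpha_tax) <- taxa
    tax_of <- species_map$taxon
    a_base <- alpha_tax[tax_of]                      # per sample
    otv_s <- otv[tax_of, snp_ids, drop = FALSE]      # samples x SNPs
    alpha <- matrix(a_base, nrow(true_dosage), n_snps) * ifelse(otv_s, 1 - cfg$delta, 1)

    g <- true_dosage
    mx <- alpha * S * (2 - g) / 2 + b
    my <- alpha * S * g / 2 + b
    X <- pmax(mx + rnorm(length(mx), 0, sig), eps0)
    Y <- pmax(my + rnorm(length(my), 0, sig), eps0)
  })
  dimnames(X) <- dimnames(Y) <- dimnames(true_dosage)

  # GenCall-like score: distance to nearest noise-free centroid at the
  # taxon-level affinity (no OTV penalty).
  tau <- sig + eps0
  a_mat <- matrix(alpha_tax[species_map$taxon], nrow(X), n_snps)
  dmin <- matrix(Inf, nrow(X), n_snps)
  for (gp in 0:2) {
    cx <- a_mat * S * (2 - gp) / 2 + b
    cy <- a_mat * S * gp / 2 + b
    dmin <- pmin(dmin, sqrt((X - cx)^2 + (Y - cy)^2))
  }
  gencall <- exp(-dmin / tau)
  dimnames(gencall) <- dimnames(true_dosage)

  gentrain <- gentrain_scores(X, Y, true_dosage, sig)
  names(gentrain) <- snp_ids

  list(intensities = intensity_table(X, Y), gencall = gencall,
       gentrain = gentrain, otv = otv[, snp_ids, drop = FALSE])
}

# Empirical per-SNP cluster separation score: smallest pairwise distance
# between dosage-class centroids, mapped to (0, 1] by gap / (gap + 4 sigma).
gentrain_scores <- function(X, Y, dosage, sigma) {
  n_snps <- ncol(X)
  cls <- lapply(0:2, function(gp) !is.na(dosage) & dosage == gp)
  cnt <- lapply(cls, function(m) colSums(m))
  cx <- lapply(cls, function(m) colSums(X * m) / pmax(colSums(m), 1))
  cy <- lapply(cls, function(m) colSums(Y * m) / pmax(colSums(m), 1))
  pairs <- list(c(1, 2), c(2, 3), c(1, 3))
  gap <- rep(Inf, n_snps)
  for (pr in pairs) {
    i <- pr[1]; j <- pr[2]
    present <- cnt[[i]] > 0 & cnt[[j]] > 0
    d <- sqrt((cx[[i]] - cx[[j]])^2 + (cy[[i]] - cy[[j]])^2)
    gap[present] <- pmin(gap[present], d[present])
  }
  ifelse(is.finite(gap), gap / (gap + 4 * sigma), 1)
}

# taxa x edges incidence of the tree path focal -> each leaf.
path_edge_incidence <- function(tree, focal) {
  tips <- tree$tip.label
  focal_i <- match(focal, tips)
  if (is.na(focal_i)) stop("focal taxon is not a leaf of the tree")
  edge_key <- paste(tree$edge[, 1], tree$edge[, 2])
  inc <- matrix(0, length(tips), nrow(tree$edge), dimnames = list(tips, NULL))
  for (k in seq_along(tips)) {
    if (k == focal_i) next
    np <- ape::nodepath(tree, from = focal_i, to = k)
    for (s in seq_len(length(np) - 1)) {
      e <- match(paste(np[s], np[s + 1]), edge_key)
      if (is.na(e)) e <- match(paste(np[s + 1], np[s]), edge_key)
      inc[k, e] <- 1
    }
  }
  inc
}

#' Simulate a complete ascertained-array dataset
#'
#' Runs the whole generator: species tree, Balding--Nichols frequency drift,
#' discovery-panel ascertainment, genotype calls, and two-channel
#' intensities with quality scores. Deterministic given `cfg$seed`.
#'
#' @param cfg a [sim_config()].
#' @return an object of class `array_sim`: a list with `truth` (tree,
#'   frequencies, divergences `d_s`, ascertainment mask, OTV events, focal
#'   and outgroup labels), `genotypes` (observed calls, a
#'   [genotype_table()]), `true_dosage`, `intensities`, `manifest` (tibble),
#'   `species_map` (tibble) and `config`.
#' @export
simulate_array_dataset <- function(cfg = sim_config()) {
  validate_sim_config(cfg)
  seeds <- derive_seeds(cfg$seed, 6)
  tree <- generate_species_tree(cfg, seed = seeds[1])
  taxa <- tree$tip.label

  focal <- cfg$focal_taxon %||% taxa[1]
  if (!focal %in% taxa) stop("focal taxon is not a leaf of the species tree")
  coph <- ape::cophenetic.phylo(tree)
  d_s <- coph[focal, ]
  outgroup <- cfg$outgroup %||% names(which.max(d_s))[1]

  freqs <- evolve_allele_frequencies(tree, cfg, seed = seeds[2])
  rownames(freqs) <- sprintf("cand%05d", seq_len(nrow(freqs)))
  keep <- ascertain_snps(freqs, cfg, focal, seed = seeds[3])
  asc <- freqs[keep, , drop = FALSE]
  rownames(asc) <- sprintf("snp%05d", seq_len(nrow(asc)))

  nper <- cfg$samples_per_species
  if (length(nper) == 1) nper <- setNames(rep(nper, length(taxa)), taxa)
  if (is.null(names(nper))) names(nper) <- taxa
  species_map <- tibble::tibble(
    taxon = rep(names(nper), nper),
    sample_id = unlist(lapply(names(nper), function(tx) {
      sprintf("%s_%02d", tx, seq_len(nper[[tx]]))
    }))
  )[, c("sample_id", "taxon")]

  geno <- simulate_genotypes(asc, species_map, cfg, seed = seeds[4])
  inten <- simulate_intensities(asc, geno$true_dosage, species_map, d_s, cfg,
                                tree, focal, seed = seeds[5])

  manifest <- tibble::tibble(
    snp_id = rownames(asc),
    gentrain = round(inten$gentrain[rownames(asc)], 6),
    chrom = "chr01",
    pos = seq_len(nrow(asc)) * 1000L
  )

  structure(list(
    truth = list(tree = tree, frequencies = asc, candidate_frequencies = freqs,
                 ascertained = keep, d_s = d_s, otv = inten$otv,
                 focal = focal, outgroup = outgroup),
    genotypes = genotype_table(geno$observed, inten$gencall),
    true_dosage = geno$true_dosage,
    intensities = inten$intensities,
    manifest = manifest,
    species_map = species_map,
    config = cfg
  ), class = "array_sim")
}

#' @export
print.array_sim <- function(x, ...) {
  cat(sprintf(paste0(
    "<array_sim> %d taxa, %d samples, %d/%d candidate SNPs ascertained\n",
    "  focal = %s, outgroup = %s, seed = %d\n"),
    length(x$truth$tree$tip.label), nrow(x$species_map),
    sum(x$truth$ascertained), length(x$truth$ascertained),
    x$truth$focal, x$truth$outgroup, x$config$seed))
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Emits the final report, SNP manifest, species map, the true tree as
#' newick, and a JSON truth record (config, divergences, ascertainment
#' summary, seeds). Re-reading the files reproduces the in-memory tables.
#'
#' @param sim an `array_sim` from [simulate_array_dataset()].
#' @param outdir output directory.
#' @param force overwrite a non-empty directory.
#' @return named character vector of written paths, invisibly.
#' @export
emit_dataset <- function(sim, outdir, force = FALSE) {
  if (dir.exists(outdir) && length(dir(outdir)) > 0 && !force) {
    stop("output directory exists and is not empty (use force = TRUE)")
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    final_report = file.path(outdir, "final_report.tsv"),
    manifest = file.path(outdir, "snp_manifest.tsv"),
    species_map = file.path(outdir, "species_map.tsv"),
    truth_tree = file.path(outdir, "truth_tree.nwk"),
    truth = file.path(outdir, "truth.json")
  )
  write_final_report(sim$genotypes, sim$intensities, paths["final_report"])
  write_snp_manifest(sim$manifest, paths["manifest"])
  write_species_map(sim$species_map, paths["species_map"])
  readr::write_lines(write_newick(sim$truth$tree), paths["truth_tree"])
  truth_rec <- list(
    config = unclass(sim$config),
    focal = sim$truth$focal, outgroup = sim$truth$outgroup,
    d_s = as.list(round(sim$truth$d_s, 10)),
    n_candidate_snps = length(sim$truth$ascertained),
    n_ascertained = sum(sim$truth$ascertained),
    ascertained_index = which(sim$truth$ascertained)
  )
  jsonlite::write_json(truth_rec, paths["truth"], auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}
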