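#' Simulation configuration for the synthetic ascertained array
#'
#' Defines the study conditions for the generator: a species tree, per-taxon
#' sampling, a discovery panel used to ascertain SNPs, and the two-channel
#' intensity model with divergence-dependent probe-affinity decay.
#'
#' Defaults describe a 12-taxon genus surveyed at 20 diploid samples per
#' taxon with 2000 candidate SNPs ascertained in a 17-member discovery panel
#' dominated by one focal taxon (11 focal individuals plus 1 individual from
#' each of 6 other taxa) -- the design of crop-oriented genotyping arrays
#' applied genus-wide.
#'
#' @param n_species number of taxa (ignored when `newick` is given).
#' @param samples_per_species integer scalar or named vector of diploid
#'   samples genotyped per taxon.
#' @param n_candidate_snps candidate SNPs offered to the ascertainment step.
#' @param newick optional newick string (with branch lengths) for the species
#'   tree; `NULL` simulates a pure-birth tree.
#' @param birth_rate pure-birth speciation rate.
#' @param tree_depth the simulated tree is rescaled so the maximum
#'   root-to-tip path length equals this (drift units; the per-branch
#'   fixation index is `1 - exp(-t)`).
#' @param min_branch minimum branch length after rescaling; species-level
#'   divergence implies no effectively zero-length branches.
#' @param focal_taxon label of the array-design taxon; `NULL` = first leaf.
#' @param outgroup label used for rooting; `NULL` = leaf farthest from the
#'   focal taxon.
#' @param panel_composition named integer vector (taxon -> number of panel
#'   individuals) or one of `"focal_dominated"` (11 focal + 1 each from 6
#'   other taxa) / `"all_taxa"` (1 individual from every taxon).
#' @param panel_maf_min minimum minor allele frequency in the sampled panel
#'   for a candidate SNP to be put on the array.
#' @param ancestral_maf_range range of the uniform ancestral allele-B
#'   frequency at the root.
#' @param absorb_eps frequencies sampled within this distance of 0/1 are
#'   absorbed at the boundary.
#' @param lambda probe-affinity decay rate per unit tree distance from the
#'   focal taxon (shared two-channel decay, `alpha = exp(-lambda * d)`).
#' @param mu off-target-variant (OTV) mutation rate per unit branch length on
#'   the path from the focal taxon; the marginal OTV probability for a taxon
#'   at distance `d` is `1 - exp(-mu * d)`.
#' @param delta multiplicative affinity penalty of an OTV (in \[0, 1\]).
#' @param signal full-scale signal amplitude S of one channel.
#' @param background additive background intensity b of each channel.
#' @param channel_noise Gaussian noise sd per channel.
#' @param intensity_floor positive floor applied to both channels (keeps the
#'   log summary statistics finite).
#' @param missing_rate completely-at-random missing-call rate.
#' @param seed master seed; stage seeds are derived via [derive_seeds()].
#' @return an object of class `sim_config` (a named list).
#' @export
sim_config <- function(n_species = 12,
                       samples_per_species = 20,
                       n_candidate_snps = 2000,
                       newick = NULL,
                       birth_rate = 1,
                       tree_depth = 1,
                       min_branch = 0.05,
                       focal_taxon = NULL,
                       outgroup = NULL,
                       panel_composition = "focal_dominated",
                       panel_maf_min = 0.10,
                       ancestral_maf_range = c(0.05, 0.95),
                       absorb_eps = 1e-4,
                       lambda = 0.5,
                       mu = 0.3,
                       delta = 0.5,
                       signal = 1,
                       background = 0.05,
                       channel_noise = 0.04,
                       intensity_floor = 0.02,
                       missing_rate = 0.01,
                       seed = 1L) {
  cfg <- list(
    n_species = as.integer(n_species),
    samples_per_species = samples_per_species,
    n_candidate_snps = as.integer(n_candidate_snps),
    newick = newick, birth_rate = birth_rate,
    tree_depth = tree_depth, min_branch = min_branch,
    focal_taxon = focal_taxon, outgroup = outgroup,
    panel_composition = panel_composition,
    panel_maf_min = panel_maf_min,
    ancestral_maf_range = ancestral_maf_range,
    absorb_eps = absorb_eps,
    lambda = lambda, mu = mu, delta = delta,
    signal = signal, background = background,
    channel_noise = channel_noise,
    intensity_floor = intensity_floor,
    missing_rate = missing_rate,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  num_nonneg <- c("lambda", "mu", "missing_rate", "channel_noise", "panel_maf_min")
  for (f in num_nonneg) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || is.na(cfg[[f]]) || cfg[[f]] < 0) {
      stop(sprintf("config field '%s' must be a nonnegative number", f))
    }
  }
  if (cfg$channel_noise < 0) stop("channel_noise must be nonnegative")
  if (cfg$intensity_floor <= 0) stop("intensity_floor must be positive")
  if (cfg$signal <= 0 || cfg$background <= 0) stop("signal and background must be positive")
  if (cfg$delta < 0 || cfg$delta > 1) stop("delta must lie in [0, 1]")
  if (cfg$panel_maf_min > 0.5) stop("panel_maf_min must lie in [0, 0.5]")
  if (cfg$n_candidate_snps < 1) stop("need at least one candidate SNP")
  if (any(cfg$samples_per_species < 1)) stop("samples_per_species must be >= 1")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "<sim_config> %d taxa, %s samples/taxon, %d candidate SNPs\n",
    "  panel: %s (MAF >= %.2f); lambda = %g, mu = %g, delta = %g; seed = %d\n"),
    x$n_species,
    if (length(x$samples_per_species) == 1) x$samples_per_species else "varying",
    x$n_candidate_snps,
    if (is.character(x$panel_composition)) x$panel_composition else "custom",
    x$panel_maf_min, x$lambda, x$mu, x$delta, x$seed))
  invisible(x)
}

#' Read / write a simulation config as YAML
#'
#' @param path YAML file path.
#' @return for `read_sim_config`, a [sim_config()]; for `write_sim_config`,
#'   `path` invisibly.
#' @export
read_sim_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) stop("unknown config fields: ", paste(unknown, collapse = ", "))
  if (!is.null(vals$panel_composition) && is.list(vals$panel_composition)) {
    vals$panel_composition <- unlist(vals$panel_composition)
  }
  do.call(sim_config, vals)
}

#' @rdname read_sim_config
#' @param cfg a [sim_config()].
#' @export
write_sim_config <- function(cfg, path) {
  vals <- unclass(cfg)
  if (is.numeric(vals$panel_composition)) {
    vals$panel_composition <- as.list(vals$panel_composition)
  }
  yaml::write_yaml(vals, path)
  invisible(path)
}

#' Resolve a panel composition specification
#'
#' @param spec `"focal_dominated"`, `"all_taxa"`, or a named integer vector.
#' @param taxa taxon labels.
#' @param focal focal taxon label.
#' @return named integer vector of panel individuals per taxon.
#' @export
panel_composition <- function(spec, taxa, focal) {
  if (is.numeric(spec)) {
    if (is.null(names(spec)) || !all(names(spec) %in% taxa)) {
      stop("custom panel composition must be named by taxon labels")
    }
    return(spec[spec > 0])
  }
  spec <- match.arg(spec, c("focal_dominated", "all_taxa"))
  if (spec == "all_taxa") {
    return(setNames(rep(1L, length(taxa)), taxa))
  }
  others <- setdiff(sort(taxa), focal)
  others <- head(others, 6)
  setNames(c(11L, rep(1L, length(others))), c(focal, others))
}

#' Bundled grapevine accession design
#'
#' Loads a plain-text design table bundled with the package: accession counts
#' per taxon for a grapevine germplasm collection genotyped on a 9k SNP
#' array (18 taxa retained after quality control, with highly unequal sample
#' sizes), plus the collection-level totals used for curation bookkeeping.
#'
#' @return a list with components `table` (tibble: `subgenus`, `region`,
#'   `taxon`, `n_genotyped`, `n_after_qc`), `n_genotyped_total` and
#'   `n_curation_errors`.
#' @export
load_grapevine_accessions <- function() {
  path <- system.file("extdata", "grapevine_accessions.tsv", package = "arrayphylo")
  tab <- readr::read_tsv(path, col_types = readr::cols(
    subgenus = readr::col_character(), region = readr::col_character(),
    taxon = readr::col_character(), n_genotyped = readr::col_integer(),
    n_after_qc = readr::col_integer()
  ), progress = FALSE)
  meta <- jsonlite::read_json(system.file("extdata", "grapevine_qc_summary.json",
                                          package = "arrayphylo"))
  list(table = tab,
       n_genotyped_total = meta$n_genotyped_total,
       n_curation_errors = meta$n_curation_errors)
}
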