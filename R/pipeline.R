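#' Run both analysis routes on one dataset
#'
#' Internal engine shared by [run_pipeline()] and
#' [run_replicate_experiment()]: genotype route (filters -> allele stats ->
#' pairwise F_ST -> NJ -> outgroup rooting) and intensity route (summary
#' statistic -> species medians -> Euclidean distances -> NJ -> rooting).
#' The genotype route uses post-filter SNPs; the intensity route uses every
#' array SNP -- the asymmetry is intentional.
#' @noRd
run_routes <- function(genotypes, intensities, manifest, species_map,
                       outgroup, kind = "LN_XY") {
  filt <- apply_genotype_filters(genotypes, manifest)
  stats <- species_allele_stats(filt$genotypes, species_map)
  fst <- pairwise_fst_matrix(stats)
  fst_shifted <- suppressMessages(shift_nonnegative(fst))
  gtree <- suppressMessages(neighbor_joining(fst_shifted))
  gtree_rooted <- root_with_outgroup(gtree, outgroup)

  profiles <- species_median_profiles(intensities, species_map, kind)
  idist <- euclidean_species_distance(profiles)
  itree <- suppressMessages(neighbor_joining(idist))
  itree_rooted <- root_with_outgroup(itree, outgroup)

  list(filter_report = filt$report, stats = stats,
       fst = fst, fst_shifted = fst_shifted,
       genotype_tree = gtree_rooted,
       profiles = profiles, intensity_dist = idist,
       intensity_tree = itree_rooted)
}

#' Run the full array-phylogeny pipeline
#'
#' Simulates (or reads) an array dataset, applies the genotype-route QC
#' (call filters, LD pruning, PCA, curation screen), builds both distance
#' matrices and both rooted NJ trees, and computes the comparison
#' diagnostics: Mantel test between the two matrices, MDS of both, MAF
#' spectra, shared-monomorphic counts, the focal elevation statistic and the
#' topology-distance table across all seven intensity summary statistics.
#' All artifacts are written under `outdir` together with a run manifest
#' recording seeds and versions; a failing stage leaves partial outputs and
#' a `FAILED` marker naming the stage.
#'
#' @param cfg a [sim_config()] (simulation mode) or a list with components
#'   `final_report`, `manifest`, `species_map`, `outgroup`, `focal`
#'   (real-data mode: file paths plus labels).
#' @param outdir artifact directory.
#' @param seed master seed (default `cfg$seed` in simulation mode).
#' @param force overwrite a non-empty `outdir`.
#' @param mantel_permutations permutations for the Mantel test.
#' @return invisibly, a list of in-memory results plus `paths`.
#' @export
run_pipeline <- function(cfg, outdir, seed = NULL, force = FALSE,
                         mantel_permutations = 10000) {
  if (dir.exists(outdir) && length(dir(outdir)) > 0 && !force) {
    stop("output directory exists and is not empty (use force = TRUE)")
  }
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  stage <- "setup"
  on_fail <- function(e) {
    readr::write_lines(sprintf("stage: %s\nerror: %s", stage, conditionMessage(e)),
                       file.path(outdir, "FAILED"))
    stop(sprintf("pipeline failed at stage '%s': %s", stage, conditionMessage(e)),
         call. = FALSE)
  }
  tryCatch({
    sim_mode <- inherits(cfg, "sim_config")
    if (sim_mode) {
      if (!is.null(seed)) cfg$seed <- as.integer(seed)
      stage <- "simulate"
      sim <- simulate_array_dataset(cfg)
      genotypes <- sim$genotypes; intensities <- sim$intensities
      manifest <- sim$manifest; species_map <- sim$species_map
      outgroup <- sim$truth$outgroup; focal <- sim$truth$focal
      master_seed <- cfg$seed
    } else {
      stage <- "read_inputs"
      fr <- read_final_report(cfg$final_report)
      genotypes <- fr$genotypes; intensities <- fr$intensities
      manifest <- read_snp_manifest(cfg$manifest)
      species_map <- read_species_map(cfg$species_map)
      outgroup <- cfg$outgroup; focal <- cfg$focal
      master_seed <- as.integer(seed %||% 1L)
      sim <- NULL
    }
    seeds <- derive_seeds(master_seed, 3)

    stage <- "qc"
    filt <- apply_genotype_filters(genotypes, manifest)
    pruned <- ld_prune(filt$genotypes, manifest)
    pca_tab <- subset_table(filt$genotypes, snps = pruned$kept)
    pca <- genotype_pca(pca_tab, k = min(5, min(dim(pca_tab)) - 1))
    flags <- flag_curation_errors(pca, species_map)
    keep_samples <- flags$sample_id[!flags$flagged]
    genotypes_cur <- subset_table(genotypes, samples = keep_samples)
    intensities_cur <- subset_table(intensities, samples = keep_samples)
    map_cur <- species_map[species_map$sample_id %in% keep_samples, ]

    stage <- "routes"
    routes <- run_routes(genotypes_cur, intensities_cur, manifest, map_cur,
                         outgroup)

    stage <- "comparisons"
    mantel <- mantel_test(routes$intensity_dist, routes$fst,
                          permutations = mantel_permutations, seed = seeds[1])
    mds_g <- classical_mds(shift_nonnegative(routes$fst), k = 2)
    mds_i <- classical_mds(routes$intensity_dist, k = 2)
    taxa <- sort(unique(map_cur$taxon))
    spectra <- dplyr::bind_rows(lapply(taxa, function(tx) {
      maf_spectrum(routes$stats, tx)
    }))
    mono <- shared_monomorphic_table(routes$stats)
    elevation <- focal_elevation_statistic(routes$intensity_dist, routes$fst, focal)
    stat_trees <- lapply(SUMMARY_STAT_KINDS, function(kd) {
      pr <- species_median_profiles(intensities_cur, map_cur, kd)
      suppressMessages(root_with_outgroup(
        neighbor_joining(euclidean_species_distance(pr)), outgroup))
    })
    names(stat_trees) <- SUMMARY_STAT_KINDS
    topo_table <- topology_distance_table(stat_trees)

    stage <- "write_artifacts"
    paths <- c(
      filter_report = file.path(outdir, "filter_report.json"),
      pca_coords = file.path(outdir, "pca_coords.tsv"),
      curation_flags = file.path(outdir, "curation_flags.tsv"),
      fst_matrix = file.path(outdir, "fst_matrix.phy"),
      intensity_matrix = file.path(outdir, "intensity_matrix.phy"),
      genotype_tree = file.path(outdir, "genotype_tree.nwk"),
      intensity_tree = file.path(outdir, "intensity_tree.nwk"),
      mantel = file.path(outdir, "mantel.json"),
      mds_genotype = file.path(outdir, "mds_genotype.tsv"),
      mds_intensity = file.path(outdir, "mds_intensity.tsv"),
      maf_spectra = file.path(outdir, "maf_spectra.tsv"),
      shared_monomorphic = file.path(outdir, "shared_monomorphic.tsv"),
      elevation = file.path(outdir, "elevation.json"),
      topology_table = file.path(outdir, "topology_distance_table.tsv"),
      run_manifest = file.path(outdir, "run_manifest.json")
    )
    write_filter_report(filt$report, paths["filter_report"])
    readr::write_tsv(tidy(pca), paths["pca_coords"], progress = FALSE)
    readr::write_tsv(flags, paths["curation_flags"], progress = FALSE)
    write_distance_matrix(routes$fst_shifted, paths["fst_matrix"])
    write_distance_matrix(routes$intensity_dist, paths["intensity_matrix"])
    readr::write_lines(write_newick(routes$genotype_tree), paths["genotype_tree"])
    readr::write_lines(write_newick(routes$intensity_tree), paths["intensity_tree"])
    jsonlite::write_json(unclass(tidy(mantel)), paths["mantel"],
                         auto_unbox = TRUE, pretty = TRUE)
    readr::write_tsv(tidy(mds_g), paths["mds_genotype"], progress = FALSE)
    readr::write_tsv(tidy(mds_i), paths["mds_intensity"], progress = FALSE)
    readr::write_tsv(spectra, paths["maf_spectra"], progress = FALSE)
    readr::write_tsv(mono, paths["shared_monomorphic"], progress = FALSE)
    jsonlite::write_json(list(focal = focal, statistic = elevation),
                         paths["elevation"], auto_unbox = TRUE, pretty = TRUE)
    readr::write_tsv(tibble::as_tibble(topo_table, rownames = "statistic"),
                     paths["topology_table"], progress = FALSE)
    manifest_rec <- list(
      package_version = as.character(utils::packageVersion("arrayphylo")),
      r_version = paste(R.version$major, R.version$minor, sep = "."),
      master_seed = master_seed, stage_seeds = seeds,
      mode = if (sim_mode) "simulation" else "real_data",
      focal = focal, outgroup = outgroup,
      n_samples = nrow(species_map), n_samples_kept = length(keep_samples),
      n_snps = length(genotypes$snp_id),
      n_snps_post_filter = filt$report$n_snps_out,
      n_snps_post_ld = length(pruned$kept),
      mantel_permutations = mantel_permutations
    )
    jsonlite::write_json(manifest_rec, paths["run_manifest"],
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)

    invisible(list(
      sim = sim, routes = routes, pca = pca, flags = flags, pruned = pruned,
      mantel = mantel, mds_genotype = mds_g, mds_intensity = mds_i,
      spectra = spectra, shared_monomorphic = mono, elevation = elevation,
      topology_table = topo_table, paths = paths
    ))
  }, error = on_fail)
}

#' Replicate experiment: which route recovers the true tree?
#'
#' Repeats the full simulate-and-infer cycle `n_reps` times with fresh seeds
#' derived from `seed`. Per replicate it records the Penny--Hendy distance
#' of each route's rooted tree to the true species tree and whether each
#' route recovers the focal taxon's true sister group. The summary reports
#' per-route mean distances and a paired sign test on the per-replicate
#' differences (one- and two-sided).
#'
#' @param cfg a [sim_config()]; per-replicate seeds overwrite `cfg$seed`.
#' @param n_reps number of replicates (>= 5).
#' @param seed master seed for the replicate seed stream.
#' @return object of class `replicate_experiment`: `replicates` (tibble) and
#'   `summary` (list).
#' @export
run_replicate_experiment <- function(cfg = sim_config(), n_reps = 50, seed = 1L) {
  if (n_reps < 5) stop("need at least 5 replicates for a meaningful summary")
  rep_seeds <- derive_seeds(seed, n_reps)
  rows <- vector("list", n_reps)
  for (k in seq_len(n_reps)) {
    cfg$seed <- rep_seeds[k]
    sim <- simulate_array_dataset(cfg)
    routes <- run_routes(sim$genotypes, sim$intensities, sim$manifest,
                         sim$species_map, sim$truth$outgroup)
    true_rooted <- root_with_outgroup(sim$truth$tree, sim$truth$outgroup)
    rf_g <- tree_topology_distance(routes$genotype_tree, true_rooted)
    rf_i <- tree_topology_distance(routes$intensity_tree, true_rooted)
    sister <- focal_sister_set(true_rooted, sim$truth$focal)
    rows[[k]] <- tibble::tibble(
      replicate = k, seed = rep_seeds[k],
      rf_genotype = rf_g, rf_intensity = rf_i,
      focal_correct_genotype = has_clade(routes$genotype_tree,
                                         c(sim$truth$focal, sister)),
      focal_correct_intensity = has_clade(routes$intensity_tree,
                                          c(sim$truth$focal, sister))
    )
  }
  reps <- dplyr::bind_rows(rows)
  n_int_better <- sum(reps$rf_intensity < reps$rf_genotype)
  n_gen_better <- sum(reps$rf_genotype < reps$rf_intensity)
  n_informative <- n_int_better + n_gen_better
  if (n_informative > 0) {
    p_one <- binom.test(n_int_better, n_informative, alternative = "greater")$p.value
    p_two <- binom.test(n_int_better, n_informative, alternative = "two.sided")$p.value
  } else {
    p_one <- p_two <- 1
  }
  summary <- list(
    n_reps = n_reps,
    mean_rf_genotype = mean(reps$rf_genotype),
    mean_rf_intensity = mean(reps$rf_intensity),
    focal_correct_rate_genotype = mean(reps$focal_correct_genotype),
    focal_correct_rate_intensity = mean(reps$focal_correct_intensity),
    n_intensity_better = n_int_better,
    n_genotype_better = n_gen_better,
    sign_test_p_one_sided = p_one,
    sign_test_p_two_sided = p_two
  )
  structure(list(replicates = reps, summary = summary, seed = as.integer(seed)),
            class = "replicate_experiment")
}

# leaf labels of the smallest true clade containing the focal taxon,
# minus the focal taxon itself (its sister group in the rooted tree).
focal_sister_set <- function(rooted_tree, focal) {
  tips <- rooted_tree$tip.label
  tip <- match(focal, tips)
  parent <- rooted_tree$edge[rooted_tree$edge[, 2] == tip, 1]
  children <- rooted_tree$edge[rooted_tree$edge[, 1] == parent, 2]
  sib <- setdiff(children, tip)
  unlist(lapply(sib, function(nd) {
    if (nd <= length(tips)) tips[nd] else ape::extract.clade(rooted_tree, nd)$tip.label
  }))
}

# does the tree contain a split isolating exactly `group`?
has_clade <- function(tree, group) {
  tips <- tree$tip.label
  if (length(group) >= length(tips) - 1) return(TRUE)  # complement trivial: holds in any tree
  if (length(group) < 2) return(TRUE)  # a single-leaf "clade" is trivially present
  bs <- bipartition_set(tree)
  target <- sort(group)
  any(vapply(bs$splits, function(sp) {
    identical(sp[[1]], target) || identical(sp[[2]], target)
  }, TRUE))
}

#' @export
print.replicate_experiment <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0(
    "<replicate_experiment> %d replicates\n",
    "  mean tree distance to truth: genotype %.2f, intensity %.2f\n",
    "  intensity better in %d, genotype better in %d (sign test, one-sided p = %.4g)\n",
    "  focal placement correct: genotype %.0f%%, intensity %.0f%%\n"),
    s$n_reps, s$mean_rf_genotype, s$mean_rf_intensity,
    s$n_intensity_better, s$n_genotype_better, s$sign_test_p_one_sided,
    100 * s$focal_correct_rate_genotype, 100 * s$focal_correct_rate_intensity))
  invisible(x)
}

#' @method tidy replicate_experiment
#' @export
tidy.replicate_experiment <- function(x, ...) x$replicates

#' @method glance replicate_experiment
#' @export
glance.replicate_experiment <- function(x, ...) {
  tibble::as_tibble(x$summary)
}
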