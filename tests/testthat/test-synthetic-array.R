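test_that("species tree generation is deterministic with correct leaf and edge counts", {
  cfg <- sim_config(n_species = 12, seed = 7)
  t1 <- generate_species_tree(cfg)
  t2 <- generate_species_tree(cfg)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_equal(length(t1$tip.label), 12)
  unrooted <- ape::unroot(t1)
  expect_equal(nrow(unrooted$edge), 2 * 12 - 3)
  expect_true(all(t1$edge.length > 0))

  cfg2 <- sim_config(newick = "((A:1,B:1):1,(C:1,D:1):1);")
  t4 <- generate_species_tree(cfg2)
  expect_setequal(t4$tip.label, c("A", "B", "C", "D"))
  expect_equal(length(bipartition_set(t4)$keys), 1)
  expect_error(generate_species_tree(sim_config(newick = "((A,B),(C,D));")),
               "branch length")
})

test_that("Balding-Nichols drift has the exact mean and variance and absorbs at bounds", {
  # no drift on a zero-length branch
  p <- c(0, 0.3, 0.7, 1)
  expect_identical(arrayphylo:::drift_child_frequency(p, 0), p)
  # absorbed frequencies are inherited
  withr::with_seed(1, {
    q <- arrayphylo:::drift_child_frequency(rep(0, 1000), 1.5)
  })
  expect_true(all(q == 0))
  # moment oracle: child variance = p (1 - p) F with F = 1 - exp(-t)
  FST <- 0.2
  t <- -log(1 - FST)
  withr::with_seed(99, {
    q <- arrayphylo:::drift_child_frequency(rep(0.5, 1e5), t, eps = 0)
  })
  expect_equal(mean(q), 0.5, tolerance = 0.01)
  expect_equal(var(q), 0.5 * 0.5 * FST, tolerance = 0.05)
  expect_error(arrayphylo:::drift_child_frequency(0.5, -1), "nonnegative")
})

test_that("panel ascertainment applies the sampled-panel MAF rule reproducibly", {
  # fixed frequencies: 17-diploid panel arithmetic
  cfg <- tiny_config()
  taxa <- sprintf("sp%02d", 1:6)
  freqs <- matrix(0.5, 10, 6, dimnames = list(NULL, taxa))
  freqs[1, ] <- 1  # fixed everywhere -> excluded
  keep <- ascertain_snps(freqs, cfg, focal = "sp01", seed = 11)
  expect_false(keep[1])
  maf <- attr(keep, "panel_maf")
  expect_identical(as.logical(keep), unname(maf >= cfg$panel_maf_min))

  # oracle replay: same seed, brute-force re-simulation of the binomial draws
  panel <- panel_composition(cfg$panel_composition, taxa, "sp01")
  expect_equal(sum(panel), 16)  # 11 focal + 1 each from 5 others (6 taxa total)
  withr::with_seed(11, {
    cnt <- rep(0, 10)
    for (tx in names(panel)) cnt <- cnt + rbinom(10, 2 * panel[[tx]], freqs[, tx])
  })
  maf_oracle <- pmin(cnt, 2 * sum(panel) - cnt) / (2 * sum(panel))
  expect_equal(unname(maf), maf_oracle)

  # a 17-diploid panel with 5 B alleles: MAF 5/34 >= 0.10 -> retained
  expect_gte(5 / 34, 0.10)
  freqs0 <- matrix(0, 5, 6, dimnames = list(NULL, taxa))
  expect_error(ascertain_snps(freqs0, cfg, focal = "sp01", seed = 1),
               "no candidate SNP")
})

test_that("genotype simulation matches binomial moments and degenerate frequencies", {
  cfg <- tiny_config(missing_rate = 0)
  map <- tibble::tibble(sample_id = sprintf("a_%04d", 1:10000), taxon = "a")
  freqs <- matrix(c(1, 0, 0.3), 3, 1, dimnames = list(NULL, "a"))
  g <- simulate_genotypes(freqs, map, cfg, seed = 5)
  expect_true(all(g$true_dosage[, 1] == 2))
  expect_true(all(g$true_dosage[, 2] == 0))
  m <- mean(g$true_dosage[, 3])
  se <- sqrt(2 * 0.3 * 0.7 / 10000)
  expect_lt(abs(m - 0.6), 3 * se)
})

test_that("intensity channels follow the affinity model exactly in the noise-free case", {
  tree <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
  map <- tibble::tibble(sample_id = c("A_1", "B_1", "C_1", "D_1"),
                        taxon = c("A", "B", "C", "D"))
  d_s <- ape::cophenetic.phylo(tree)["A", ]
  freqs <- matrix(0.5, 1, 4, dimnames = list("snp00001", c("A", "B", "C", "D")))
  dos <- matrix(c(1, 1, 2, 0), 4, 1, dimnames = list(map$sample_id, "snp00001"))

  cfg0 <- sim_config(n_species = 4, lambda = 0, mu = 0, delta = 0,
                     channel_noise = 0, signal = 1, background = 0.05,
                     intensity_floor = 0.01)
  res <- simulate_intensities(freqs, dos, map, d_s, cfg0, tree, focal = "A", seed = 2)
  # lambda = 0, sigma = 0: heterozygote gives X = Y = S/2 + b = 0.55
  expect_equal(res$intensities$x["A_1", 1], 0.55)
  expect_equal(res$intensities$y["A_1", 1], 0.55)
  expect_equal(summary_statistic(res$intensities$x["A_1", 1],
                                 res$intensities$y["A_1", 1], "LN_XY"), 0)
  # homozygote BB: X = b, Y = S + b
  expect_equal(res$intensities$x["C_1", 1], 0.05)
  expect_equal(res$intensities$y["C_1", 1], 1.05)
  expect_error(
    simulate_intensities(freqs, dos, map, d_s,
                         sim_config(n_species = 4, channel_noise = -1),
                         tree, focal = "A", seed = 2),
    "nonnegative")
})

test_that("mean heterozygote total intensity decays as exp(-lambda d)", {
  tree <- parse_newick("((A:0.5,B:1.5):0.5,(C:1,D:1):0.5);")
  d_s <- ape::cophenetic.phylo(tree)["A", ]
  n <- 10000
  map <- tibble::tibble(sample_id = sprintf("B_%05d", 1:1), taxon = "B")
  freqs <- matrix(0.5, n, 4, dimnames = list(NULL, c("A", "B", "C", "D")))
  dos <- matrix(1, 1, n, dimnames = list(map$sample_id, sprintf("snp%05d", 1:n)))
  lambda <- 0.5
  cfg <- sim_config(n_species = 4, lambda = lambda, mu = 0, delta = 0,
                    channel_noise = 0.04, signal = 1, background = 0.05)
  res <- simulate_intensities(freqs, dos, map, d_s, cfg, tree, focal = "A", seed = 8)
  expected <- exp(-lambda * d_s[["B"]]) * 1 + 2 * 0.05
  got <- mean(res$intensities$x + res$intensities$y)
  expect_equal(got, expected, tolerance = 3 * 0.04 * sqrt(2) / sqrt(n) / expected)
})

test_that("OTV marginal probability is 1 - exp(-mu d) and events are tree-shared", {
  cfg <- sim_config(n_species = 6, n_candidate_snps = 3000, mu = 0.4, seed = 21)
  sim <- simulate_array_dataset(cfg)
  otv <- sim$truth$otv
  d_s <- sim$truth$d_s[rownames(otv)]
  rate <- rowMeans(otv)
  expected <- 1 - exp(-cfg$mu * d_s)
  # binomial error over ascertained SNPs
  n <- ncol(otv)
  for (tx in rownames(otv)) {
    se <- sqrt(expected[tx] * (1 - expected[tx]) / n)
    expect_lt(abs(rate[tx] - expected[tx]), 4 * se + 1e-9)
  }
  expect_true(all(otv[sim$truth$focal, ] == FALSE))
})

test_that("dataset emission round trips and is byte-identical under a fixed seed", {
  cfg <- tiny_config(seed = 13)
  sim <- simulate_array_dataset(cfg)
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  paths1 <- emit_dataset(sim, out1, force = TRUE)
  paths2 <- emit_dataset(simulate_array_dataset(cfg), out2, force = TRUE)
  for (nm in names(paths1)) {
    expect_identical(readr::read_lines(paths1[[nm]]), readr::read_lines(paths2[[nm]]),
                     info = nm)
  }
  back <- read_final_report(paths1[["final_report"]])
  expect_identical(back$genotypes$dosage, sim$genotypes$dosage)
  truth_back <- parse_newick(readr::read_lines(paths1[["truth_tree"]])[1])
  expect_tree_equal_topology(truth_back, sim$truth$tree)
  expect_error(emit_dataset(sim, out1), "force")
})

test_that("ascertainment inflates intermediate-frequency MAF mass in the focal taxon", {
  cfg <- sim_config(seed = 31)  # defaults: focal-dominated panel, >= 1000 SNPs retained
  sim <- simulate_array_dataset(cfg)
  expect_gte(sum(sim$truth$ascertained), 1000)
  truth_p <- sim$truth$frequencies
  focal <- sim$truth$focal
  panel_taxa <- names(panel_composition(cfg$panel_composition,
                                        colnames(truth_p), focal))
  absent <- setdiff(colnames(truth_p), panel_taxa)
  inter_mass <- function(p) {
    maf <- pmin(p, 1 - p)
    mean(maf >= 0.2 & maf <= 0.5)
  }
  focal_mass <- inter_mass(truth_p[, focal])
  for (tx in absent) {
    expect_gt(focal_mass, inter_mass(truth_p[, tx]))
  }
})

test_that("pairs involving the focal taxon share fewer monomorphic SNPs", {
  sim <- simulate_array_dataset(sim_config(seed = 31))
  stats <- species_allele_stats(sim$genotypes, sim$species_map)
  mono <- shared_monomorphic_table(stats)
  focal <- sim$truth$focal
  inv <- mono$taxon_a == focal | mono$taxon_b == focal
  expect_lt(mean(mono$n_shared_monomorphic[inv]),
            mean(mono$n_shared_monomorphic[!inv]))
})

test_that("switching off all bias sources removes the intensity elevation", {
  # clean negative control: no affinity decay, no OTVs, and a panel covering
  # every taxon (ascertainment alone depresses focal F_ST ranks, which the
  # rank statistic would register even with unbiased intensities); the
  # statistic is a mean of 11 rank differences with Monte-Carlo noise of a
  # few hundredths, so average over 6 simulations
  elev <- vapply(17:22, function(s) {
    cfg <- sim_config(lambda = 0, mu = 0, panel_composition = "all_taxa", seed = s)
    sim <- simulate_array_dataset(cfg)
    filt <- apply_genotype_filters(sim$genotypes, sim$manifest)
    stats <- species_allele_stats(filt$genotypes, sim$species_map)
    fst <- pairwise_fst_matrix(stats)
    prof <- species_median_profiles(sim$intensities, sim$species_map, "LN_XY")
    focal_elevation_statistic(euclidean_species_distance(prof), fst,
                              sim$truth$focal)
  }, 0)
  expect_lte(abs(mean(elev)), 0.05)
})
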