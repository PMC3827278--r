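test_that("genotype filters apply the four rules in order with strict thresholds", {
  # 10 samples x 6 SNPs designed so each rule removes a known SNP
  dos <- cbind(
    ok        = c(0, 1, 2, 0, 1, 2, 0, 1, 2, 1),
    gentrain_low = c(0, 1, 2, 0, 1, 2, 0, 1, 2, 1),
    missing30 = c(NA, NA, NA, 0, 1, 2, 0, 1, 2, 1),   # 30% missing > 20%
    rare      = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0),      # MAF 0 < 0.05
    maf_edge  = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 1),      # MAF exactly 0.05 -> kept
    masked    = c(2, 2, 2, 2, 2, 2, 2, 0, 0, 0)
  )
  gc <- matrix(1, 10, 6)
  gc[1:3, 6] <- 0.1   # GenCall < 0.2 -> masked, making SNP 6 30% missing
  g <- make_gt(dos, gc)
  manifest <- tibble::tibble(snp_id = g$snp_id,
                             gentrain = c(0.9, 0.29, 0.9, 0.9, 0.9, 0.9),
                             chrom = "chr01", pos = 1:6)
  res <- apply_genotype_filters(g, manifest)
  expect_setequal(res$genotypes$snp_id, c("ok", "maf_edge"))
  expect_equal(res$report$snps_removed_gentrain, 1)
  expect_equal(res$report$snps_removed_missing, 2)  # missing30 and masked
  expect_equal(res$report$snps_removed_maf, 1)
  expect_equal(res$report$calls_masked_gencall, 3)
  expect_equal(res$report$n_snps_in - res$report$n_snps_out,
               res$report$snps_removed_gentrain + res$report$snps_removed_missing +
                 res$report$snps_removed_maf)
  expect_error(apply_genotype_filters(g, manifest, maf_min = 1.2), "thresholds")
})

test_that("filters are idempotent", {
  sim <- simulate_array_dataset(tiny_config(seed = 2))
  once <- apply_genotype_filters(sim$genotypes, sim$manifest)
  twice <- apply_genotype_filters(once$genotypes, sim$manifest)
  expect_identical(twice$genotypes$dosage, once$genotypes$dosage)
  expect_equal(twice$report$n_snps_out, once$report$n_snps_out)
})

test_that("filters match a brute-force reapplication of the four rules", {
  sim <- simulate_array_dataset(tiny_config(seed = 6))
  g <- sim$genotypes
  man <- sim$manifest
  res <- apply_genotype_filters(g, man)
  # independent oracle: literal rule-by-rule scan
  dos <- g$dosage
  dos[g$gencall < 0.2] <- NA
  keep <- character(0)
  for (s in g$snp_id) {
    if (man$gentrain[man$snp_id == s] < 0.3) next
    col <- dos[, s]
    if (mean(is.na(col)) > 0.20) next
    p <- sum(col, na.rm = TRUE) / (2 * sum(!is.na(col)))
    if (min(p, 1 - p) < 0.05) next
    keep <- c(keep, s)
  }
  expect_setequal(res$genotypes$snp_id, keep)
})

test_that("LD pruning removes exactly one of a duplicated pair (higher index) and keeps independent SNPs", {
  withr::with_seed(10, {
    base <- matrix(rbinom(500 * 20, 2, 0.4), 500, 20)
  })
  dup <- cbind(base, base[, 3])  # column 21 duplicates column 3 (r2 = 1, equal MAF)
  g <- make_gt(dup)
  # duplicated pair sits in the same scan window only if adjacent; reorder via manifest
  man <- tibble::tibble(snp_id = g$snp_id, gentrain = 1, chrom = "chr01",
                        pos = c(seq(10, 200, by = 10), 35L))
  man <- dplyr::arrange(man, pos)  # duplicate lands right after snp003
  res <- ld_prune(g, man)
  expect_true(xor("snp003" %in% res$kept, "snp021" %in% res$kept))
  expect_identical(res$removed, "snp021")  # tie -> higher (later) index removed
})

test_that("LD pruning retains nearly all mutually independent SNPs", {
  withr::with_seed(77, {
    dos <- matrix(rbinom(500 * 60, 2, runif(60, 0.2, 0.8)[rep(1:60, each = 500)]),
                  500, 60)
  })
  g <- make_gt(dos)
  res <- ld_prune(g)
  expect_gte(length(res$kept) / 60, 0.95)
})

test_that("LD pruning agrees with an exhaustive windowed oracle on a correlated triple", {
  withr::with_seed(4, {
    a <- rbinom(300, 2, 0.5)
    noise <- function() ifelse(runif(300) < 0.05, sample(0:2, 300, TRUE), a)
    dos <- cbind(a, noise(), noise(),
                 matrix(rbinom(300 * 9, 2, 0.5), 300, 9))
  })
  colnames(dos) <- sprintf("m%02d", 1:12)
  g <- make_gt(dos)
  res <- ld_prune(g, window = 10, step = 3, r2_max = 0.5)

  # oracle: independent literal implementation of the same scan rule
  maf <- apply(dos, 2, function(v) { p <- sum(v) / (2 * length(v)); min(p, 1 - p) })
  kept <- 1:12
  repeat {
    changed <- FALSE
    alive <- rep(TRUE, length(kept))
    s <- 1
    while (s <= length(kept)) {
      win <- s:min(s + 9, length(kept))
      for (ai in seq_along(win)) for (bi in seq_along(win)) {
        if (ai >= bi) next
        a2 <- win[ai]; b2 <- win[bi]
        if (!alive[a2] || !alive[b2]) next
        r2 <- suppressWarnings(cor(dos[, kept[a2]], dos[, kept[b2]]))^2
        if (!is.na(r2) && r2 > 0.5) {
          v <- if (maf[kept[a2]] < maf[kept[b2]]) a2
               else if (maf[kept[b2]] < maf[kept[a2]]) b2 else max(a2, b2)
          alive[v] <- FALSE; changed <- TRUE
        }
      }
      s <- s + 3
    }
    kept <- kept[alive]
    if (!changed) break
  }
  expect_identical(res$kept, colnames(dos)[kept])
})

test_that("LD pruning is invariant to sample order", {
  sim <- simulate_array_dataset(tiny_config(seed = 9))
  g <- sim$genotypes
  res1 <- ld_prune(g, sim$manifest)
  perm <- withr::with_seed(1, sample(g$sample_id))
  res2 <- ld_prune(subset_table(g, samples = perm), sim$manifest)
  expect_identical(res1$kept, res2$kept)
})

test_that("genotype PCA matches a direct eigendecomposition up to sign", {
  withr::with_seed(12, {
    dos <- matrix(rbinom(20 * 50, 2, 0.5), 20, 50)
  })
  g <- make_gt(dos)
  pca <- genotype_pca(g, k = 5)
  Xc <- scale(dos, center = TRUE, scale = FALSE)
  eig <- eigen(Xc %*% t(Xc) / 1)  # spectral oracle on the sample Gram matrix
  for (j in 1:5) {
    v <- eig$vectors[, j] * sqrt(eig$values[j])
    expect_equal(abs(unname(pca$scores[, j])), abs(v), tolerance = 1e-8)
  }
  expect_lte(sum(pca$explained), 1 + 1e-12)
  expect_true(all(diff(pca$explained) <= 1e-12))
  expect_error(genotype_pca(g, k = 21), "exceeds")
})

test_that("PCA separates constructed clusters on PC1 and mean-imputes missing calls", {
  dos <- rbind(matrix(0, 10, 30), matrix(2, 10, 30))
  dos[1, 1] <- NA
  g <- make_gt(dos)
  pca <- genotype_pca(g, k = 2)
  grp <- rep(c(1, 2), each = 10)
  expect_true(max(pca$scores[grp == 1, 1]) < min(pca$scores[grp == 2, 1]) ||
              min(pca$scores[grp == 1, 1]) > max(pca$scores[grp == 2, 1]))
  expect_gt(pca$explained[1], pca$explained[2])
})

test_that("curation screen flags samples at foreign centroids and spares centered ones", {
  # two tight, well-separated taxa in PC space via constructed genotypes
  dos <- rbind(matrix(0, 6, 40), matrix(2, 6, 40))
  withr::with_seed(3, dos[cbind(sample(1:12, 30, TRUE), sample(1:40, 30, TRUE))] <- 1)
  g <- make_gt(dos)
  map <- tibble::tibble(sample_id = g$sample_id,
                        taxon = rep(c("a", "b"), each = 6))
  map$taxon[1] <- "b"  # sample s01 actually sits with taxon a but is labeled b
  pca <- genotype_pca(g, k = 3)
  flags <- flag_curation_errors(pca, map, m_axes = 3)
  expect_true(flags$flagged[flags$sample_id == "s01"])
  expect_false(any(flags$flagged[flags$sample_id != "s01"]))
})

test_that("curation screen recovers planted label swaps with few false flags", {
  cfg <- sim_config(n_species = 6, samples_per_species = 30,
                    n_candidate_snps = 2000, seed = 15)
  sim <- simulate_array_dataset(cfg)
  filt <- apply_genotype_filters(sim$genotypes, sim$manifest)
  map <- sim$species_map
  n <- nrow(map)
  n_swap <- round(0.05 * n)
  withr::with_seed(8, {
    swap_idx <- sample(n, n_swap)
    taxa <- sort(unique(map$taxon))
    wrong <- map
    for (i in swap_idx) {
      wrong$taxon[i] <- sample(setdiff(taxa, map$taxon[i]), 1)
    }
  })
  pca <- genotype_pca(filt$genotypes, k = 5)
  flags <- flag_curation_errors(pca, wrong)
  truth <- seq_len(n) %in% swap_idx
  recall <- sum(flags$flagged & truth) / n_swap
  false_rate <- sum(flags$flagged & !truth) / sum(!truth)
  expect_gte(recall, 0.8)
  expect_lte(false_rate, 0.02)
})

test_that("singleton taxa are never flaggable and trigger a warning", {
  dos <- rbind(matrix(0, 5, 20), matrix(2, 1, 20))
  g <- make_gt(dos)
  map <- tibble::tibble(sample_id = g$sample_id, taxon = c(rep("a", 5), "b"))
  pca <- genotype_pca(g, k = 2)
  expect_warning(flags <- flag_curation_errors(pca, map), "single sample")
  expect_false(flags$flagged[flags$taxon == "b"])
})
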