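test_that("zero-SE soil parameters collapse every sample onto the group mean", {
  tab <- soilReferenceTable()
  tab$se <- 0
  meta <- simulateSoil(soilSimParams(table = tab, n_per_group = 3, seed = 5))
  for (v in unique(tab$variable)) {
    for (g in c("KC", "NT", "RS")) {
      expect_equal(unique(meta[[v]][meta$group == g]),
                   tab$mean[tab$variable == v & tab$group == g])
    }
  }
})

test_that("soil draws reproduce the reference means and SE-implied spread", {
  meta <- simulateSoil(soilSimParams(n_per_group = 2000, seed = 11))
  na_kc <- meta$Na[meta$group == "KC"]
  expect_lt(abs(mean(na_kc) / 5728.9 - 1), 0.02)
  # SD should approach SE * sqrt(6)
  expect_lt(abs(sd(na_kc) / (451.97 * sqrt(6)) - 1), 0.1)
  expect_true(all(meta$Na >= 0))
})

test_that("fumigation pairs reconstruct the drawn biomass exactly", {
  meta <- simulateSoil(soilSimParams(seed = 3))
  expect_equal(suppressWarnings(
    microbialBiomass(meta$DOC_fum, meta$DOC_nonfum, "C")), meta$MBC,
    tolerance = 1e-9)
  expect_equal(suppressWarnings(
    microbialBiomass(meta$TN_fum, meta$TN_nonfum, "N")), meta$MBN,
    tolerance = 1e-9)
  expect_equal(suppressWarnings(
    microbialBiomass(meta$TP_fum, meta$TP_nonfum, "P")), meta$MBP,
    tolerance = 1e-9)
})

test_that("simulation output is bit-identical under a fixed seed", {
  a <- simulateSoil(soilSimParams(seed = 9))
  b <- simulateSoil(soilSimParams(seed = 9))
  expect_identical(a, b)
  s1 <- simulateOtuTables(networkSimParams(n_bacterial_otus = 20,
                                           n_fungal_otus = 10,
                                           n_samples = 6, seed = 9))
  s2 <- simulateOtuTables(networkSimParams(n_bacterial_otus = 20,
                                           n_fungal_otus = 10,
                                           n_samples = 6, seed = 9))
  expect_identical(otuCounts(s1$bacteria), otuCounts(s2$bacteria))
  expect_identical(s1$truth$pairs, s2$truth$pairs)
})

test_that("planted blocks impose perfect latent rank association at strength 1", {
  blk <- list(list(members = c("B001", "F001"), signs = c(1, 1), strength = 1))
  par <- networkSimParams(n_bacterial_otus = 4, n_fungal_otus = 2,
                          n_samples = 20, blocks = blk, noise_sd = 0,
                          seed = 21)
  sim <- simulateOtuTables(par)
  expect_equal(cor(sim$latent[, "B001"], sim$latent[, "F001"],
                   method = "spearman"), 1)
  blk2 <- list(list(members = c("B001", "F001"), signs = c(1, -1),
                    strength = 1))
  sim2 <- simulateOtuTables(networkSimParams(
    n_bacterial_otus = 4, n_fungal_otus = 2, n_samples = 20, blocks = blk2,
    noise_sd = 0, seed = 21))
  expect_equal(cor(sim2$latent[, "B001"], sim2$latent[, "F001"],
                   method = "spearman"), -1)
})

test_that("truth lists exactly the planted pairs with product signs", {
  blk <- list(list(members = c("B001", "B002", "F001"), signs = c(1, -1, 1),
                   strength = 0.8),
              list(members = c("B003", "B004"), signs = c(1, 1),
                   strength = 0.5))
  sim <- simulateOtuTables(networkSimParams(
    n_bacterial_otus = 6, n_fungal_otus = 2, n_samples = 8, blocks = blk,
    seed = 2))
  tp <- sim$truth$pairs
  expect_identical(nrow(tp), 4L)  # choose(3,2) + choose(2,2)
  expect_equal(tp$sign[tp$otu1 == "B001" & tp$otu2 == "B002"], -1)
  expect_equal(tp$sign[tp$otu1 == "B002" & tp$otu2 == "F001"], -1)
  expect_equal(tp$sign[tp$otu1 == "B001" & tp$otu2 == "F001"], 1)
  expect_error(networkSimParams(blocks = list(list(
    members = c("B001", "ZZZ"), signs = c(1, 1), strength = 1))), "unknown")
  expect_error(networkSimParams(blocks = list(
    list(members = c("B001", "B002"), signs = c(1, 1), strength = 1),
    list(members = c("B002", "B003"), signs = c(1, 1), strength = 1))),
    "disjoint")
})

test_that("strength-0 blocks produce almost no spurious strong edges", {
  # null calibration: over replicate datasets, the fraction of OTU pairs
  # passing |rho| > 0.9 and p < 0.01 stays at or below 1%
  n_rep <- 200
  hits <- 0; pairs_total <- 0
  for (r in seq_len(n_rep)) {
    blk <- list(list(members = c("B001", "B002", "B003"), signs = c(1, 1, 1),
                     strength = 0))
    sim <- simulateOtuTables(networkSimParams(
      n_bacterial_otus = 6, n_fungal_otus = 4, n_samples = 10, blocks = blk,
      baseline_sd = 1, seed = 1000 + r))
    m <- cbind(relValues(relativeAbundance(sim$bacteria)),
               relValues(relativeAbundance(sim$fungi)))
    rho <- suppressWarnings(cor(m, method = "spearman"))
    ut <- upper.tri(rho)
    cand <- which(ut & abs(rho) > 0.9, arr.ind = TRUE)
    pairs_total <- pairs_total + sum(ut)
    for (k in seq_len(nrow(cand))) {
      st <- spearmanTest(m[, cand[k, 1]], m[, cand[k, 2]])
      if (!is.na(st$p) && st$p < 0.01) hits <- hits + 1
    }
  }
  expect_lte(hits / pairs_total, 0.01)
})

test_that("latent path data obey the planted structural equations", {
  # beta = 0: fitted association vanishes at large n
  p0 <- plsSimParams(blocks = list(x = 1, y = 1),
                     path = matrix(c(0, 0, 0, 0), 2, 2,
                                   dimnames = list(c("x", "y"),
                                                   c("x", "y"))),
                     n = 2000, seed = 4)
  d0 <- simulatePlspmData(p0)
  expect_lt(abs(cor(d0$truth$latents[, 1], d0$truth$latents[, 2])), 0.05)
  # single-indicator blocks, vanishing noise: indicator correlation -> beta
  pb <- plsSimParams(blocks = list(x = 1, y = 1),
                     path = matrix(c(0, 0.6, 0, 0), 2, 2, byrow = FALSE),
                     indicator_noise_sd = 1e-8, n = 4000, seed = 5)
  db <- simulatePlspmData(pb)
  expect_lt(abs(cor(db$data$x_1, db$data$y_1) - 0.6), 0.05)
  # two exogenous -> one endogenous: OLS on the true latents recovers beta
  P <- matrix(0, 3, 3)
  P[3, 1] <- 0.5; P[3, 2] <- -0.3
  pr <- plsSimParams(blocks = list(a = 1, b = 1, c = 1), path = P,
                     n = 2000, seed = 6)
  dr <- simulatePlspmData(pr)
  cf <- coef(lm(dr$truth$latents[, 3] ~ dr$truth$latents[, 1] +
                  dr$truth$latents[, 2]))
  expect_lt(abs(cf[2] - 0.5), 0.05)
  expect_lt(abs(cf[3] + 0.3), 0.05)
  # cyclic inner matrix is rejected
  bad <- matrix(0, 2, 2); bad[1, 2] <- 0.5; bad[2, 1] <- 0.5
  expect_error(plsSimParams(blocks = list(x = 1, y = 1), path = bad),
               "triangular")
})

test_that("library sizes follow the requested log-normal support", {
  sim <- simulateOtuTables(networkSimParams(
    n_bacterial_otus = 30, n_fungal_otus = 10, n_samples = 12,
    lib_meanlog = log(5000), lib_sdlog = 0.1, seed = 8))
  libs <- rowSums(otuCounts(sim$bacteria))
  expect_true(all(libs > 5000 * exp(-0.5)) && all(libs < 5000 * exp(0.5)))
})
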