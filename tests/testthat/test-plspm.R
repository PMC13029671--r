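twoBlockSpec <- function(scheme = "centroid") {
  plspmSpec(blocks = list(X = "x_1", Y = "y_1"),
            edges = data.frame(from = "X", to = "Y"), scheme = scheme)
}

test_that("two single-indicator blocks reduce to the Pearson correlation", {
  set.seed(1)
  x <- rnorm(120)
  y <- 0.7 * x + rnorm(120, 0, 0.5)
  d <- data.frame(x_1 = x, y_1 = y)
  for (scheme in c("centroid", "factorial", "path")) {
    fit <- fitPlspm(d, twoBlockSpec(scheme))
    expect_equal(fit@paths$coef, cor(x, y), tolerance = 1e-9)
    expect_equal(unname(fit@r2["Y"]), cor(x, y)^2, tolerance = 1e-9)
  }
})

test_that("single-indicator models equal the OLS path-analysis oracle", {
  set.seed(2)
  n <- 150
  a <- rnorm(n)
  b <- 0.5 * a + rnorm(n, 0, 0.8)
  c <- -0.4 * a + 0.6 * b + rnorm(n, 0, 0.6)
  d <- data.frame(A_1 = a, B_1 = b, C_1 = c)
  spec <- plspmSpec(
    blocks = list(A = "A_1", B = "B_1", C = "C_1"),
    edges = data.frame(from = c("A", "A", "B"), to = c("B", "C", "C")))
  fit <- fitPlspm(d, spec)
  za <- scale(a); zb <- scale(b); zc <- scale(c)
  o1 <- coef(lm(zb ~ za))[2]
  o2 <- coef(lm(zc ~ za + zb))[-1]
  pc <- fit@paths
  expect_equal(pc$coef[pc$from == "A" & pc$to == "B"], unname(o1),
               tolerance = 1e-6)
  expect_equal(pc$coef[pc$from == "A" & pc$to == "C"], unname(o2[1]),
               tolerance = 1e-6)
  expect_equal(pc$coef[pc$from == "B" & pc$to == "C"], unname(o2[2]),
               tolerance = 1e-6)
  expect_equal(unname(fit@r2["C"]),
               summary(lm(zc ~ za + zb))$r.squared, tolerance = 1e-6)
  # latent scores are exactly unit variance
  expect_equal(unname(apply(fit@scores, 2, sd)), rep(1, 3),
               tolerance = 1e-12)
})

test_that("a spec with no inner edges yields principal-axis latents", {
  set.seed(3)
  eta <- rnorm(100)
  d <- data.frame(X_1 = 0.9 * eta + rnorm(100, 0, 0.3),
                  X_2 = 0.8 * eta + rnorm(100, 0, 0.4),
                  X_3 = 0.7 * eta + rnorm(100, 0, 0.5),
                  Y_1 = rnorm(100))
  spec <- plspmSpec(blocks = list(X = c("X_1", "X_2", "X_3"), Y = "Y_1"),
                    edges = matrix(FALSE, 2, 2))
  fit <- fitPlspm(d, spec)
  expect_identical(nrow(fit@paths), 0L)
  expect_identical(length(fit@r2), 0L)
  pc1 <- prcomp(scale(d[, 1:3]))$x[, 1]
  expect_gt(abs(cor(fit@scores[, "X"], pc1)), 1 - 1e-6)
})

test_that("planted path coefficients are recovered from indicator data", {
  P <- matrix(0, 3, 3)
  P[2, 1] <- 0.6
  P[3, 2] <- -0.4
  ok_signs <- 0; close_enough <- 0
  n_seeds <- 20
  k <- 6  # indicators per block; composite attenuation shrinks with k
  for (s in seq_len(n_seeds)) {
    par <- plsSimParams(
      blocks = list(A = rep(0.9, k), B = rep(0.9, k), C = rep(0.9, k)),
      path = P, n = 500, seed = 100 + s)
    sim <- simulatePlspmData(par)
    spec <- plspmSpec(
      blocks = list(A = paste0("A_", 1:k), B = paste0("B_", 1:k),
                    C = paste0("C_", 1:k)),
      edges = data.frame(from = c("A", "B"), to = c("B", "C")))
    fit <- fitPlspm(sim$data, spec)
    pc <- fit@paths
    ab <- pc$coef[pc$from == "A" & pc$to == "B"]
    bc <- pc$coef[pc$from == "B" & pc$to == "C"]
    if (ab > 0 && bc < 0) ok_signs <- ok_signs + 1
    if (abs(ab - 0.6) <= 0.1 && abs(bc + 0.4) <= 0.1)
      close_enough <- close_enough + 1
  }
  expect_gte(ok_signs / n_seeds, 0.95)
  expect_gte(close_enough / n_seeds, 0.95)
})

test_that("positive indicator scaling leaves the fit unchanged; negation flips one loading", {
  set.seed(4)
  eta <- rnorm(200)
  d <- data.frame(X_1 = 0.9 * eta + rnorm(200, 0, 0.3),
                  X_2 = 0.8 * eta + rnorm(200, 0, 0.4),
                  X_3 = 0.7 * eta + rnorm(200, 0, 0.5),
                  Y_1 = 0.5 * eta + rnorm(200, 0, 0.8))
  spec <- plspmSpec(blocks = list(X = c("X_1", "X_2", "X_3"), Y = "Y_1"),
                    edges = data.frame(from = "X", to = "Y"))
  base <- fitPlspm(d, spec)
  d2 <- d; d2$X_1 <- d2$X_1 * 37
  scaled <- fitPlspm(d2, spec)
  expect_equal(scaled@paths$coef, base@paths$coef, tolerance = 1e-7)
  expect_equal(scaled@loadings, base@loadings, tolerance = 1e-7)
  # negate a minority indicator: its loading flips, nothing else moves
  d3 <- d; d3$X_3 <- -d3$X_3
  flipped <- fitPlspm(d3, spec)
  expect_equal(unname(flipped@loadings["X_3"]),
               -unname(base@loadings["X_3"]), tolerance = 1e-6)
  expect_equal(unname(flipped@loadings[c("X_1", "X_2")]),
               unname(base@loadings[c("X_1", "X_2")]), tolerance = 1e-6)
  expect_equal(flipped@paths$coef, base@paths$coef, tolerance = 1e-6)
})

test_that("the default halophyte spec is acyclic with nine paths", {
  spec <- defaultPlspmSpec(dominant_phyla = c("Proteobacteria",
                                              "Actinobacteriota"))
  P <- spec@path
  expect_false(any(P[upper.tri(P, diag = TRUE)]))
  expect_identical(sum(P), 9L)
  expect_identical(names(spec@blocks)[1], "physical")
  # every indicator of the pipeline's merged table is assigned once
  ind <- unlist(spec@blocks)
  expect_identical(anyDuplicated(ind), 0L)
  expect_true(all(c("pH", "MBC", "NCI", "shannon_fungi") %in% ind))
})

test_that("bootstrap intervals behave at the null and under signal", {
  # degenerate data: duplicated rows only -> SE collapses
  set.seed(5)
  base_row <- data.frame(x_1 = rnorm(1), y_1 = rnorm(1))
  # build a two-point dataset replicated many times; resampling cannot
  # change the empirical distribution much
  d0 <- data.frame(x_1 = rep(c(1, -1), 60), y_1 = rep(c(0.8, -0.8), 60))
  bs0 <- bootstrapPaths(d0, twoBlockSpec(), n_boot = 100, seed = 6)
  expect_lt(bs0$boot_se, 0.05)
  # strong signal: p < 0.01 nearly always
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    x <- rnorm(120); y <- 0.7 * x + rnorm(120, 0, 0.3)
    bs <- bootstrapPaths(data.frame(x_1 = x, y_1 = y), twoBlockSpec(),
                         n_boot = 120, seed = s)
    bs$p < 0.01
  }, TRUE)
  expect_gte(mean(hits), 0.95)
  # null path: the 95% CI covers zero at roughly the nominal rate
  cover <- vapply(1:30, function(s) {
    set.seed(s)
    x <- rnorm(100); y <- rnorm(100)
    bs <- bootstrapPaths(data.frame(x_1 = x, y_1 = y), twoBlockSpec(),
                         n_boot = 120, seed = 1000 + s)
    bs$ci_lo <= 0 && 0 <= bs$ci_hi
  }, TRUE)
  expect_gte(mean(cover), 0.8)
})

test_that("spec validation rejects malformed models", {
  expect_error(plspmSpec(blocks = list(X = "x", Y = "x"),
                         edges = data.frame(from = "X", to = "Y")),
               "only one block")
  expect_error(plspmSpec(blocks = list(X = "x", Y = "y"),
                         edges = data.frame(from = "Y", to = "X")),
               "triangular")
  expect_error(plspmSpec(blocks = list(X = "x", Y = "y"),
                         edges = data.frame(from = "X", to = "Z")),
               "unknown block")
  spec <- twoBlockSpec()
  expect_error(fitPlspm(data.frame(x_1 = rnorm(10)), spec), "y_1")
  expect_error(fitPlspm(data.frame(x_1 = rep(1, 10), y_1 = rnorm(10)), spec),
               "constant")
})
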