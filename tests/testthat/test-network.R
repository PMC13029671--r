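relPair <- function(m, kingdom = "bacteria") {
  relAbundanceTable(m / rowSums(m), kingdom)
}

# small helper: hand-built network with unit distances
unitNetwork <- function(edge_mat, nv, kingdoms = NULL) {
  ids <- sprintf("n%02d", seq_len(nv))
  if (is.null(kingdoms)) kingdoms <- rep("bacteria", nv)
  edges <- data.frame(source = ids[edge_mat[, 1]], target = ids[edge_mat[, 2]],
                      rho = 0.95, sign = 1, p = 1e-4,
                      stringsAsFactors = FALSE)
  correlationNetwork(
    data.frame(otu_id = ids, kingdom = kingdoms, phylum = "unclassified",
               stringsAsFactors = FALSE),
    edges,
    params = list(rho_threshold = 0.9, p_threshold = 0.01,
                  weight_scheme = "unit"))
}

test_that("a perfectly co-ranked pair at n = 6 forms a positive edge via exact p", {
  set.seed(1)
  base <- sort(runif(6, 0.02, 0.2))
  # filler columns absorb the compositional remainder so the named OTUs
  # keep their planted rank orders exactly
  mb <- cbind(b1 = base, b2 = base * 1.7 + 0.01, b3 = runif(6, 0.01, 0.05))
  mb <- cbind(mb, b_rest = 1 - rowSums(mb))
  mf <- cbind(f1 = rev(base), f2 = runif(6, 0.01, 0.05))
  mf <- cbind(mf, f_rest = 1 - rowSums(mf))
  rownames(mb) <- rownames(mf) <- paste0("s", 1:6)
  net <- spearmanEdges(relAbundanceTable(mb, "bacteria"),
                       relAbundanceTable(mf, "fungi"),
                       prevalence_min = 1)
  ed <- networkEdges(net)
  pos <- ed[ed$source == "b1" & ed$target == "b2", ]
  expect_identical(nrow(pos), 1L)
  expect_equal(pos$rho, 1)
  expect_equal(pos$p, 2 / 720, tolerance = 1e-12)
  expect_equal(pos$sign, 1)
  neg <- ed[ed$source == "b1" & ed$target == "f1", ]
  expect_equal(neg$sign, -1)
  expect_identical(networkParams(net)$p_method, "exact")
})

test_that("strong but sub-threshold correlations never become edges", {
  # rank-8 pair with rho = 1 - 6*10/504 = 0.881 (< 0.9 threshold)
  x <- (1:8) / 100
  y <- c(3, 1, 2, 4, 6, 5, 8, 7) / 100
  expect_lt(abs(cor(x, y, method = "spearman")), 0.9)
  mb <- cbind(b1 = x, b2 = y)
  mb <- cbind(mb, b_rest = 1 - rowSums(mb))
  mf <- cbind(f1 = runif(8, 0.2, 0.8))
  mf <- cbind(mf, f_rest = 1 - rowSums(mf))
  rownames(mb) <- rownames(mf) <- paste0("s", 1:8)
  net <- spearmanEdges(relAbundanceTable(mb, "bacteria"),
                       relAbundanceTable(mf, "fungi"),
                       prevalence_min = 1)
  ed <- networkEdges(net)
  expect_false(any(ed$source == "b1" & ed$target == "b2"))
})

test_that("edges are invariant to strictly monotone abundance transforms", {
  # transform one OTU's abundance vector monotonically, absorbing the
  # difference in a filler OTU so both tables stay valid compositions;
  # edges not involving the filler must be identical
  set.seed(2)
  n <- 8
  core <- matrix(runif(n * 4, 0.02, 0.1), n,
                 dimnames = list(paste0("s", 1:n), paste0("b", 1:4)))
  mkRel <- function(core) {
    rest <- 1 - rowSums(core)
    relAbundanceTable(cbind(core, rest = rest), "bacteria")
  }
  vf <- matrix(runif(n * 2, 0.1, 0.9), n,
               dimnames = list(paste0("s", 1:n), paste0("f", 1:2)))
  fun <- relAbundanceTable(vf / rowSums(vf), "fungi")
  key <- function(net) {
    ed <- networkEdges(net)
    ed <- ed[ed$source != "rest" & ed$target != "rest", ]
    sort(paste(pmin(ed$source, ed$target), pmax(ed$source, ed$target),
               ed$sign))
  }
  net1 <- spearmanEdges(mkRel(core), fun, prevalence_min = 1,
                        rho_threshold = 0.5, p_threshold = 0.2)
  core2 <- core
  core2[, "b2"] <- core2[, "b2"]^3 * 5  # strictly monotone on (0, 1)
  net2 <- spearmanEdges(mkRel(core2), fun, prevalence_min = 1,
                        rho_threshold = 0.5, p_threshold = 0.2)
  expect_identical(key(net1), key(net2))
})

test_that("planted association blocks are recovered with high precision/recall", {
  blocks <- list(
    list(members = c(sprintf("B%03d", 1:4), "F001"),
         signs = c(1, 1, -1, 1, 1), strength = 0.95),
    list(members = c(sprintf("B%03d", 5:7), "F002"),
         signs = c(1, -1, 1, -1), strength = 0.95))
  sim <- simulateOtuTables(networkSimParams(
    n_samples = 20, blocks = blocks, noise_sd = 0.05, baseline_sd = 0.5,
    seed = 7))
  net <- spearmanEdges(sim$bacteria, sim$fungi, prevalence_min = 3)
  ed <- networkEdges(net)
  found <- paste(pmin(ed$source, ed$target), pmax(ed$source, ed$target))
  tp <- sim$truth$pairs
  truth <- paste(pmin(tp$otu1, tp$otu2), pmax(tp$otu1, tp$otu2))
  recall <- mean(truth %in% found)
  precision <- mean(found %in% truth)
  expect_gte(recall, 0.9)
  expect_gte(precision, 0.9)
  # recovered signs match the planted ones
  m <- match(found, truth)
  expect_true(all(ed$sign[!is.na(m)] == tp$sign[m[!is.na(m)]]))
})

test_that("triangle, disjoint triangles and stars give textbook topology", {
  tri <- unitNetwork(rbind(c(1, 2), c(2, 3), c(1, 3)), 3)
  mt <- networkTopology(tri)
  expect_equal(mt$density, 1)
  expect_equal(mt$clustering_coefficient, 1)
  expect_equal(mt$diameter, 1)
  expect_equal(mt$avg_path_length, 1)
  two <- unitNetwork(rbind(c(1, 2), c(2, 3), c(1, 3),
                           c(4, 5), c(5, 6), c(4, 6)), 6)
  m2 <- networkTopology(two)
  expect_equal(m2$modularity, 0.5)
  expect_equal(oracleModularityQ(6, data.frame(v1 = c(1, 2, 1, 4, 5, 4),
                                               v2 = c(2, 3, 3, 5, 6, 6)),
                                 c(1, 1, 1, 2, 2, 2)), 0.5)
  expect_identical(m2$n_modules, 2L)
  star <- unitNetwork(cbind(1, 2:6), 6)
  expect_equal(networkTopology(star)$betweenness_centralization, 1)
})

test_that("edge sign counts always decompose the total", {
  for (seed in 1:5) {
    rn <- randomNetwork(10, 0.4, seed)
    m <- networkTopology(rn$net)
    expect_identical(m$positive_edges + m$negative_edges, m$edges)
    if (m$negative_edges > 0)
      expect_equal(m$pos_neg_ratio, m$positive_edges / m$negative_edges)
  }
})

test_that("every topology metric matches brute force on random graphs", {
  n_checked <- 0
  for (seed in 1:25) {
    rn <- randomNetwork(sample(5:12, 1), runif(1, 0.15, 0.6), seed)
    if (!nrow(networkEdges(rn$net))) next
    n_checked <- n_checked + 1
    m <- networkTopology(rn$net)
    expect_equal(m$density, oracleDensity(rn$nv, rn$edges_int))
    expect_equal(m$clustering_coefficient,
                 oracleTransitivity(rn$nv, rn$edges_int))
    D <- oracleFloydWarshall(rn$nv, rn$edges_int, rn$dist_w)
    off <- D[upper.tri(D)]
    fin <- off[is.finite(off)]
    expect_equal(m$avg_path_length, mean(fin), tolerance = 1e-10)
    expect_equal(m$diameter, max(fin), tolerance = 1e-10)
    expect_equal(m$betweenness_centralization,
                 oracleCentralization(rn$nv, rn$edges_int), tolerance = 1e-10)
    # modularity equals a direct evaluation of Q on the returned partition
    g <- asIgraph(rn$net)
    memb <- as.integer(igraph::membership(
      igraph::cluster_fast_greedy(g, weights = NULL)))
    names(memb) <- igraph::V(g)$name
    ids <- networkNodes(rn$net)$otu_id
    expect_equal(m$modularity,
                 oracleModularityQ(rn$nv, rn$edges_int, memb[ids]),
                 tolerance = 1e-10)
  }
  expect_gte(n_checked, 15)
})

test_that("sample subnetworks are induced subgraphs of the parent", {
  rn <- randomNetwork(5, 0.8, seed = 11)
  ids <- networkNodes(rn$net)$otu_id
  cnt <- matrix(0, 2, 5, dimnames = list(c("sAll", "sSome"), ids))
  cnt["sAll", ] <- 5
  cnt["sSome", ids[1:3]] <- c(2, 1, 4)
  tab <- otuTable(cnt, "bacteria")
  full <- sampleSubnetwork(rn$net, tab, "sAll")
  expect_equal(networkEdges(full), networkEdges(rn$net), ignore_attr = TRUE)
  expect_equal(networkTopology(full), networkTopology(rn$net))
  sub <- sampleSubnetwork(rn$net, tab, "sSome")
  expect_setequal(networkNodes(sub)$otu_id, ids[1:3])
  ed <- networkEdges(rn$net)
  manual <- ed[ed$source %in% ids[1:3] & ed$target %in% ids[1:3], ]
  expect_equal(networkEdges(sub), manual, ignore_attr = TRUE)
  expect_lte(nrow(networkEdges(sub)), nrow(ed))
  # absent sample errors; empty-presence sample warns and returns empty
  expect_error(sampleSubnetwork(rn$net, tab, "nope"), "unknown sample")
  cnt2 <- rbind(cnt, sNone = 0)
  expect_warning(emp <- sampleSubnetwork(rn$net, otuTable(cnt2, "bacteria"),
                                         "sNone"), "no network OTUs")
  expect_identical(nrow(networkNodes(emp)), 0L)
})

test_that("subnetwork-environment correlations hit exact endpoints", {
  metrics <- data.frame(sample_id = paste0("s", 1:6),
                        nodes = c(3, 9, 5, 11, 7, 13),
                        edges = c(2, 8, 4, 10, 6, 12),
                        density = runif(6),
                        clustering_coefficient = runif(6),
                        diameter = runif(6),
                        avg_path_length = rep(1, 6))
  meta <- data.frame(sample_id = paste0("s", 1:6),
                     Na = c(3, 9, 5, 11, 7, 13), TC = rnorm(6))
  res <- subnetworkEnvCorrelation(metrics, meta,
                                  variables = c("Na", "TC"))
  expect_equal(res$rho[res$metric == "nodes" & res$variable == "Na"], 1)
  expect_equal(res$p[res$metric == "nodes" & res$variable == "Na"], 2 / 720,
               tolerance = 1e-12)
  expect_true(is.na(res$rho[res$metric == "avg_path_length" &
                              res$variable == "Na"]))
  # monotone 6-sample pair matches the enumeration oracle
  x <- metrics$edges; y <- meta$Na
  expect_equal(res$p[res$metric == "edges" & res$variable == "Na"],
               oracleSpearmanExactP(x, y), tolerance = 1e-12)
})

test_that("an empty network yields missing metrics with a warning", {
  nodes <- data.frame(otu_id = character(), kingdom = character(),
                      phylum = character())
  net <- correlationNetwork(nodes, data.frame(
    source = character(), target = character(), rho = numeric(),
    sign = numeric(), p = numeric()))
  expect_warning(m <- networkTopology(net), "empty")
  expect_true(all(is.na(unlist(m))))
})
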