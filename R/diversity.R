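#' Shannon diversity of one sample
#'
#' H = -sum p_i log p_i over the observed (nonzero) taxa. Natural log by
#' default (nats); pass `base = 2` for bits.
#'
#' @param counts non-negative abundance vector with positive total.
#' @param base logarithm base.
#' @return Shannon index.
#' @examples
#' shannonIndex(c(5, 5))  # log(2)
#' @export
shannonIndex <- function(counts, base = exp(1)) {
  if (any(counts < 0)) stop("negative counts")
  total <- sum(counts)
  if (total == 0) stop("all-zero sample")
  p <- counts[counts > 0] / total
  -sum(p * log(p, base = base))
}

#' ACE richness estimate of one sample
#'
#' Abundance-based coverage estimator: species with counts above
#' `rare_threshold` are counted directly; the rare group is extrapolated
#' through its sample coverage C_ACE = 1 - F1/N_rare and the rare-class
#' coefficient of variation (floored at 0). When every rare individual is
#' a singleton the coverage is zero and the estimator falls back to
#' bias-corrected Chao1, flagged in the returned method.
#'
#' @param counts non-negative integer abundance vector.
#' @param rare_threshold rare/abundant split (counts <= threshold are rare).
#' @return list with `ace` (estimated richness) and `method` (`"ACE"` or
#'   `"Chao1"`).
#' @export
aceIndex <- function(counts, rare_threshold = 10) {
  counts <- counts[counts > 0]
  if (!length(counts)) stop("all-zero sample")
  rare <- counts[counts <= rare_threshold]
  s_abund <- sum(counts > rare_threshold)
  s_rare <- length(rare)
  if (!s_rare) return(list(ace = s_abund, method = "ACE"))
  n_rare <- sum(rare)
  f <- tabulate(rare, nbins = rare_threshold)  # f[i] = # species with count i
  c_ace <- 1 - f[1] / n_rare
  if (c_ace == 0) {
    f2 <- sum(counts == 2)
    chao <- length(counts) + f[1] * (f[1] - 1) / (2 * (f2 + 1))
    return(list(ace = chao, method = "Chao1"))
  }
  i <- seq_len(rare_threshold)
  gamma2 <- max(s_rare / c_ace * sum(i * (i - 1) * f) /
                  (n_rare * (n_rare - 1)) - 1, 0)
  list(ace = s_abund + s_rare / c_ace + f[1] / c_ace * gamma2, method = "ACE")
}

#' Alpha diversity table for an OTU table
#'
#' @param x an [OtuTable-class].
#' @param base Shannon log base.
#' @param rare_threshold ACE rare/abundant split.
#' @return data.frame: `sample_id`, `shannon`, `ace`, `ace_method`.
#' @export
alphaDiversity <- function(x, base = exp(1), rare_threshold = 10) {
  cnt <- otuCounts(x)
  ace <- lapply(seq_len(nrow(cnt)), function(i)
    aceIndex(cnt[i, ], rare_threshold))
  data.frame(
    sample_id = rownames(cnt),
    shannon = apply(cnt, 1, shannonIndex, base = base),
    ace = vapply(ace, `[[`, 0, "ace"),
    ace_method = vapply(ace, `[[`, "", "method"),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Rarefy an OTU table to even depth
#'
#' Optional normalisation: subsamples each sample's counts without
#' replacement to a common depth. Off by default in the pipeline; provided
#' because amplicon studies differ on whether to rarefy before diversity
#' and network analysis.
#'
#' @param x an [OtuTable-class].
#' @param depth target depth; default the minimum library size.
#' @param seed RNG seed.
#' @return an [OtuTable-class] at even depth.
#' @export
rarefyTable <- function(x, depth = NULL, seed = NULL) {
  cnt <- otuCounts(x)
  lib <- rowSums(cnt)
  if (is.null(depth)) depth <- min(lib)
  if (any(lib < depth)) stop("library size below rarefaction depth")
  if (!is.null(seed)) set.seed(seed)
  out <- t(apply(cnt, 1, function(v) {
    pool <- rep(seq_along(v), v)
    tabulate(sample(pool, depth), nbins = length(v))
  }))
  dimnames(out) <- dimnames(cnt)
  otuTable(out, kingdom(x))
}

#' Bray-Curtis dissimilarity matrix
#'
#' d(i, j) = sum |x_i - x_j| / sum (x_i + x_j) between sample abundance
#' vectors.
#'
#' @param x a [RelAbundanceTable-class] (or numeric samples x taxa matrix).
#' @return symmetric dissimilarity matrix with zero diagonal.
#' @export
brayCurtis <- function(x) {
  v <- if (is(x, "RelAbundanceTable")) relValues(x) else as.matrix(x)
  if (nrow(v) < 2) stop("need at least two samples")
  as.matrix(vegan::vegdist(v, method = "bray"))
}

#' Non-metric multidimensional scaling
#'
#' Kruskal stress-1 minimisation with monotone regression and random
#' restarts (vegan's monoMDS engine under metaMDS restart management).
#' Coordinates are centred. An all-tied dissimilarity matrix carries no
#' rank information; it is flagged degenerate and returned with zero
#' coordinates and zero stress rather than fitted.
#'
#' @param d symmetric dissimilarity matrix (or dist).
#' @param k embedding dimension.
#' @param n_restarts random restarts (best solution kept).
#' @param max_iter iterations per restart.
#' @param seed RNG seed.
#' @return list: `points` (samples x k), `stress` (stress-1 in \[0, 1\]),
#'   `converged`, `n_restarts`, `degenerate`.
#' @export
nmdsOrdination <- function(d, k = 2, n_restarts = 20, max_iter = 200,
                           seed = NULL) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (n < k + 2) stop("need at least k + 2 samples")
  off <- dm[lower.tri(dm)]
  if (max(off) - min(off) < 1e-12) {
    warning("all dissimilarities equal; ordination is degenerate")
    pts <- matrix(0, n, k, dimnames = list(rownames(dm), paste0("NMDS", 1:k)))
    return(list(points = pts, stress = 0, converged = FALSE,
                n_restarts = 0L, degenerate = TRUE))
  }
  if (!is.null(seed)) set.seed(seed)
  fit <- vegan::metaMDS(as.dist(dm), k = k, trymax = n_restarts, trace = 0,
                        maxit = max_iter, autotransform = FALSE,
                        wascores = FALSE)
  pts <- scale(fit$points, scale = FALSE)  # centred
  colnames(pts) <- paste0("NMDS", seq_len(k))
  list(points = pts, stress = fit$stress, converged = fit$converged > 0,
       n_restarts = n_restarts, degenerate = FALSE)
}

#' PERMANOVA-style group separation test
#'
#' Permutation test of a pseudo-F for group differences on a dissimilarity
#' matrix (vegan::adonis2), reported alongside NMDS stress since ordination
#' stress itself carries no significance.
#'
#' @param d dissimilarity matrix or dist.
#' @param group group label per sample.
#' @param n_perm permutations.
#' @param seed RNG seed.
#' @return list with `F`, `R2`, `p`, `n_perm`.
#' @export
groupPermanova <- function(d, group, n_perm = 999, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  group <- factor(group)
  fit <- vegan::adonis2(as.dist(d) ~ group, permutations = n_perm)
  list(F = fit$F[1], R2 = fit$R2[1], p = fit$`Pr(>F)`[1], n_perm = n_perm)
}

#' Mantel test between two distance matrices
#'
#' r is the (rank) correlation of the lower-triangle vectors; significance
#' comes from jointly permuting rows and columns of the second matrix.
#' One-sided (positive association), p = (1 + #\{perm r >= r_obs\}) /
#' (n_perm + 1). With `exact = TRUE` all n! relabelings are enumerated
#' (n <= 8) and p is the exact fraction of permutations, observed
#' arrangement included, reaching r_obs.
#'
#' @param d1,d2 symmetric matrices of equal size.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @param n_perm random permutations when `exact = FALSE`.
#' @param seed RNG seed.
#' @param exact enumerate all permutations instead.
#' @return list: `r`, `p`, `n_perm`, `method`.
#' @export
mantelTest <- function(d1, d2, method = c("spearman", "pearson"),
                       n_perm = 999, seed = NULL, exact = FALSE) {
  method <- match.arg(method)
  d1 <- as.matrix(d1); d2 <- as.matrix(d2)
  stopifnot(all(dim(d1) == dim(d2)))
  n <- nrow(d1)
  ij <- which(lower.tri(d1), arr.ind = TRUE)
  v1 <- d1[ij]; v2 <- d2[ij]
  if (sd(v1) == 0 || sd(v2) == 0)
    stop("constant off-diagonal entries; Mantel r is undefined")
  if (method == "spearman") v1 <- rank(v1)
  statf <- function(v2p)
    if (method == "spearman") cor(v1, rank(v2p)) else cor(v1, v2p)
  r_obs <- statf(v2)
  eps <- 1e-12
  if (exact) {
    P <- allPermutations(n)
    r_perm <- vapply(seq_len(nrow(P)), function(b) {
      pm <- P[b, ]
      statf(d2[cbind(pm[ij[, 1]], pm[ij[, 2]])])
    }, 0)
    p <- mean(r_perm >= r_obs - eps)
    n_perm <- nrow(P)
  } else {
    if (!is.null(seed)) set.seed(seed)
    r_perm <- vapply(seq_len(n_perm), function(b) {
      pm <- sample.int(n)
      statf(d2[cbind(pm[ij[, 1]], pm[ij[, 2]])])
    }, 0)
    p <- (1 + sum(r_perm >= r_obs - eps)) / (n_perm + 1)
  }
  list(r = r_obs, p = p, n_perm = n_perm, method = method)
}

#' Correlate ordination axes with environmental variables
#'
#' Spearman rho and p (exact at small n) for every (axis, variable) pair;
#' constant variables give NA rows.
#'
#' @param ord result of [nmdsOrdination()] (or a samples x axes matrix).
#' @param meta metadata data.frame aligned to the ordination's samples.
#' @param variables numeric columns to use; default all numeric.
#' @return data.frame: `axis`, `variable`, `rho`, `p`.
#' @export
axisEnvCorrelation <- function(ord, meta, variables = NULL) {
  pts <- if (is.list(ord) && !is.data.frame(ord)) ord$points else as.matrix(ord)
  env <- .numericEnv(meta, variables)
  stopifnot(nrow(pts) == nrow(env))
  sm <- spearmanMatrix(pts, env)
  data.frame(
    axis = rep(colnames(pts), times = ncol(env)),
    variable = rep(colnames(env), each = ncol(pts)),
    rho = as.vector(sm$rho), p = as.vector(sm$p),
    row.names = NULL, stringsAsFactors = FALSE)
}

.numericEnv <- function(meta, variables = NULL) {
  if (is.null(variables)) {
    variables <- setdiff(names(meta), c("sample_id", "group"))
    variables <- variables[vapply(meta[variables], is.numeric, TRUE)]
    variables <- grep("_fum$|_nonfum$", variables, invert = TRUE, value = TRUE)
  }
  as.matrix(meta[, variables, drop = FALSE])
}
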