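#' Define a PLS path model
#'
#' Blocks are reflective (mode A) sets of indicator columns; the inner
#' model is a directed acyclic graph over blocks, given either as a
#' two-column `from`/`to` table or as a logical matrix (`path[j, i]`:
#' block i points at block j). Blocks must be ordered so the matrix is
#' strictly lower triangular, which guarantees acyclicity.
#'
#' @param blocks named list of indicator-name character vectors.
#' @param edges data.frame or 2-column matrix of `from`, `to` block names,
#'   or an already-built logical matrix.
#' @param scheme inner weighting scheme: `"centroid"` (default, the
#'   conventional default of PLS-PM software), `"factorial"` or `"path"`.
#' @param max_iter,tol outer-weight iteration controls.
#' @return a [PlsPmSpec-class].
#' @export
plspmSpec <- function(blocks, edges, scheme = c("centroid", "factorial",
                                                "path"),
                      max_iter = 300, tol = 1e-7) {
  scheme <- match.arg(scheme)
  bn <- names(blocks)
  if (is.matrix(edges) && is.logical(edges)) {
    P <- edges
    dimnames(P) <- list(bn, bn)
  } else {
    edges <- as.data.frame(edges)
    names(edges)[1:2] <- c("from", "to")
    if (!all(c(edges$from, edges$to) %in% bn))
      stop("edge references unknown block")
    P <- matrix(FALSE, length(bn), length(bn), dimnames = list(bn, bn))
    P[cbind(match(edges$to, bn), match(edges$from, bn))] <- TRUE
  }
  new("PlsPmSpec", blocks = blocks, path = P, scheme = scheme,
      max_iter = max_iter, tol = tol)
}

#' Default halophyte-rhizosphere path model
#'
#' Blocks: soil physical (pH, SWC, Na, K), soil chemical (TC, TOC, TN, TP,
#' AN, OP), microbial biomass (MBC, MBN, MBP), microbial diversity
#' (bacterial and fungal Shannon and ACE), dominant phyla (caller-supplied
#' abundance columns) and network complexity (the NCI). Nine inner paths:
#' physical -> chemical, biomass, diversity; chemical -> biomass,
#' diversity; biomass -> network complexity; diversity -> dominant phyla
#' and network complexity; dominant phyla -> network complexity. The edge
#' set is a configuration default, overridable via [plspmSpec()].
#'
#' @param dominant_phyla indicator column names of the dominant-phyla
#'   block.
#' @param diversity indicator column names of the diversity block.
#' @param nci indicator column name(s) of the complexity block.
#' @param scheme,max_iter,tol passed to [plspmSpec()].
#' @return a [PlsPmSpec-class].
#' @export
defaultPlspmSpec <- function(dominant_phyla,
                             diversity = c("shannon_bacteria",
                                           "ace_bacteria",
                                           "shannon_fungi", "ace_fungi"),
                             nci = "NCI", scheme = "centroid",
                             max_iter = 300, tol = 1e-7) {
  blocks <- list(
    physical = c("pH", "SWC", "Na", "K"),
    chemical = c("TC", "TOC", "TN", "TP", "AN", "OP"),
    biomass = c("MBC", "MBN", "MBP"),
    diversity = diversity,
    dominant_phyla = dominant_phyla,
    network_complexity = nci)
  edges <- data.frame(
    from = c("physical", "physical", "physical", "chemical", "chemical",
             "biomass", "diversity", "diversity", "dominant_phyla"),
    to = c("chemical", "biomass", "diversity", "biomass", "diversity",
           "network_complexity", "dominant_phyla", "network_complexity",
           "network_complexity"),
    stringsAsFactors = FALSE)
  plspmSpec(blocks, edges, scheme = scheme, max_iter = max_iter, tol = tol)
}

#' Fit a PLS path model (Lohmöller algorithm)
#'
#' Indicators are standardized; outer weights start equal; then the
#' algorithm alternates (i) outer estimation — each latent is the weighted
#' sum of its indicators, standardized to unit variance — (ii) inner
#' estimation under the chosen scheme (centroid: sign of the correlation
#' between connected latents; factorial: the correlation; path: regression
#' coefficients for predecessors, correlations for successors) and
#' (iii) mode-A outer-weight update, weight = correlation(indicator,
#' inner proxy), until the largest outer-weight change falls below `tol`.
#' Structural coefficients are then OLS of each endogenous latent on its
#' predecessors, with per-block R-squared.
#'
#' @param data data.frame holding every indicator column.
#' @param spec a [PlsPmSpec-class].
#' @return a [PlsPmResult-class].
#' @export
fitPlspm <- function(data, spec) {
  stopifnot(is(spec, "PlsPmSpec"))
  bn <- names(spec@blocks)
  B <- length(bn)
  ind <- unlist(spec@blocks, use.names = FALSE)
  missing <- setdiff(ind, names(data))
  if (length(missing))
    stop("indicator column(s) not in data: ", paste(missing, collapse = ", "))
  n <- nrow(data)
  if (n <= B) stop("need more samples than blocks")
  X <- as.matrix(data[, ind, drop = FALSE])
  if (any(apply(X, 2, sd) == 0))
    stop("constant indicator column(s)")
  X <- scale(X)
  idx <- split(seq_along(ind), rep(seq_len(B), lengths(spec@blocks)))
  P <- spec@path
  C <- P | t(P)
  w <- lapply(idx, function(ii) {
    v <- rep(1, length(ii))
    v / sd(X[, ii, drop = FALSE] %*% v)
  })
  latent <- function(w) {
    Y <- vapply(seq_len(B), function(j)
      as.vector(X[, idx[[j]], drop = FALSE] %*% w[[j]]), numeric(n))
    colnames(Y) <- bn
    Y
  }
  Y <- latent(w)
  iter <- 0
  repeat {
    iter <- iter + 1
    R <- cor(Y)
    E <- matrix(0, B, B, dimnames = list(bn, bn))
    for (j in seq_len(B)) {
      conn <- which(C[j, ])
      if (!length(conn)) next
      if (spec@scheme == "centroid") E[j, conn] <- sign(R[j, conn])
      else if (spec@scheme == "factorial") E[j, conn] <- R[j, conn]
      else {
        preds <- which(P[j, ])
        succs <- setdiff(conn, preds)
        if (length(preds)) {
          cf <- coef(lm(Y[, j] ~ Y[, preds, drop = FALSE]))[-1]
          E[j, preds] <- cf
        }
        if (length(succs)) E[j, succs] <- R[j, succs]
      }
    }
    Z <- Y %*% t(E)
    w_new <- lapply(seq_len(B), function(j) {
      # an isolated block uses its own latent as proxy, which makes the
      # mode-A update a power iteration towards the block's first
      # principal axis
      z <- if (all(E[j, ] == 0)) Y[, j] else Z[, j]
      v <- as.vector(cor(X[, idx[[j]], drop = FALSE], z))
      if (sum(v * w[[j]]) < 0) v <- -v  # resolve sign indeterminacy
      v / sd(X[, idx[[j]], drop = FALSE] %*% v)
    })
    delta <- max(abs(unlist(w_new) - unlist(w)))
    w <- w_new
    Y <- latent(w)
    if (delta < spec@tol) break
    if (iter >= spec@max_iter)
      stop(sprintf("no convergence in %d iterations (last delta %.3g)",
                   spec@max_iter, delta))
  }
  # orient each latent so the sum of its loadings is positive; this makes
  # the solution invariant to sign flips of a minority of indicators
  for (j in seq_len(B)) {
    ld <- as.vector(cor(X[, idx[[j]], drop = FALSE], Y[, j]))
    if (sum(ld) < 0) {
      w[[j]] <- -w[[j]]
      Y[, j] <- -Y[, j]
    }
  }
  # structural model: OLS of each endogenous latent on its predecessors
  paths <- data.frame(from = character(), to = character(), coef = numeric(),
                      stringsAsFactors = FALSE)
  r2 <- numeric(0)
  for (j in seq_len(B)) {
    preds <- which(P[j, ])
    if (!length(preds)) next
    Xp <- Y[, preds, drop = FALSE]
    if (qr(Xp)$rank < length(preds))
      stop("rank-deficient predecessor set for block ", bn[j])
    fit <- lm(Y[, j] ~ Xp)
    cf <- coef(fit)[-1]
    paths <- rbind(paths, data.frame(
      from = bn[preds], to = bn[j], coef = unname(cf),
      stringsAsFactors = FALSE))
    r2[bn[j]] <- summary(fit)$r.squared
  }
  loadings <- setNames(numeric(length(ind)), ind)
  weights <- setNames(unlist(w), ind)
  for (j in seq_len(B))
    loadings[idx[[j]]] <- as.vector(cor(X[, idx[[j]], drop = FALSE], Y[, j]))
  new("PlsPmResult", weights = weights, loadings = loadings, scores = Y,
      paths = paths, r2 = r2, iterations = iter, boot = NULL, spec = spec)
}

#' Bootstrap significance of PLS-PM path coefficients
#'
#' Resamples rows with replacement and refits. Each replicate's latent
#' orientations are aligned to the full-sample solution by the sign of the
#' inner product of its block loadings with the full-sample loadings
#' (preventing artifactual bimodality), then path coefficients are
#' summarised: bootstrap mean, SE, percentile CI, and a two-sided normal
#' p-value from the standardized coefficient (full-sample estimate over
#' bootstrap SE).
#'
#' @param data data.frame of indicators.
#' @param spec a [PlsPmSpec-class].
#' @param n_boot bootstrap replicates (>= 100).
#' @param conf CI level.
#' @param seed RNG seed.
#' @return data.frame: `from`, `to`, `coef`, `boot_mean`, `boot_se`,
#'   `ci_lo`, `ci_hi`, `p`. Errors if more than 20% of replicates fail to
#'   converge.
#' @export
bootstrapPaths <- function(data, spec, n_boot = 500, conf = 0.95,
                           seed = NULL) {
  if (n_boot < 100) stop("need n_boot >= 100")
  full <- fitPlspm(data, spec)
  bn <- names(spec@blocks)
  if (!is.null(seed)) set.seed(seed)
  mat <- matrix(NA_real_, n_boot, nrow(full@paths))
  fails <- 0L
  for (b in seq_len(n_boot)) {
    rows <- sample.int(nrow(data), replace = TRUE)
    fit <- tryCatch(fitPlspm(data[rows, , drop = FALSE], spec),
                    error = function(e) NULL)
    if (is.null(fit)) { fails <- fails + 1L; next }
    s <- vapply(bn, function(blk) {
      ii <- spec@blocks[[blk]]
      d <- sum(fit@loadings[ii] * full@loadings[ii])
      if (d < 0) -1 else 1
    }, 0)
    mat[b, ] <- fit@paths$coef * s[fit@paths$from] * s[fit@paths$to]
  }
  if (fails > 0.2 * n_boot)
    stop(fails, " of ", n_boot, " bootstrap replicates failed to converge")
  a <- (1 - conf) / 2
  boot_se <- apply(mat, 2, sd, na.rm = TRUE)
  z <- full@paths$coef / boot_se
  data.frame(
    from = full@paths$from, to = full@paths$to, coef = full@paths$coef,
    boot_mean = colMeans(mat, na.rm = TRUE), boot_se = boot_se,
    ci_lo = apply(mat, 2, quantile, a, na.rm = TRUE),
    ci_hi = apply(mat, 2, quantile, 1 - a, na.rm = TRUE),
    p = ifelse(boot_se < 1e-12, NA_real_, 2 * pnorm(-abs(z))),
    row.names = NULL, stringsAsFactors = FALSE)
}
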