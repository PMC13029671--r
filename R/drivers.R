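#' Select dominant taxa
#'
#' Two deterministic rules: every phylum with mean relative abundance above
#' 1% (`"phylum_1pct"`), or the ten genera with the largest mean relative
#' abundance (`"top10_genus"`, ties broken lexicographically). If fewer
#' than `top_n` genera exist, all are returned and the result is flagged.
#'
#' @param x a [RelAbundanceTable-class] aggregated at the matching rank.
#' @param rule selection rule.
#' @param threshold phylum-rule abundance cut (proportion).
#' @param top_n genus-rule count.
#' @return list: `rank`, `rule`, `taxa` (data.frame `taxon`,
#'   `mean_abundance`, descending), `flagged`, `tie_broken` (taxa kept by
#'   the lexicographic tie rule, for provenance).
#' @export
selectDominant <- function(x, rule = c("phylum_1pct", "top10_genus"),
                           threshold = 0.01, top_n = 10) {
  rule <- match.arg(rule)
  mn <- colMeans(relValues(x))
  ord <- order(-mn, names(mn))
  mn <- mn[ord]
  flagged <- FALSE; tie_broken <- character()
  if (rule == "phylum_1pct") {
    sel <- mn[mn > threshold]
    rank <- "phylum"
  } else {
    rank <- "genus"
    if (length(mn) < top_n) {
      sel <- mn; flagged <- TRUE
    } else {
      sel <- mn[seq_len(top_n)]
      cut <- sel[top_n]
      tied <- names(mn)[mn == cut]
      if (length(tied) > 1) tie_broken <- intersect(names(sel), tied)
    }
  }
  list(rank = rank, rule = rule,
       taxa = data.frame(taxon = names(sel), mean_abundance = unname(sel),
                         stringsAsFactors = FALSE),
       flagged = flagged, tie_broken = tie_broken)
}

#' Random-forest explanatory power of the environment for one taxon
#'
#' Regression forest predicting a taxon's relative abundance from the soil
#' variables. Percent explained is the out-of-bag pseudo-R-squared x 100,
#' floored at 0; significance comes from refitting after permuting the
#' response. The modelling direction (taxon as response) yields one
#' percent-explained value per taxon; the reverse direction can be had by
#' swapping the arguments.
#'
#' @param y taxon abundance per sample (non-constant, >= 6 samples).
#' @param env numeric samples x variables matrix or data.frame.
#' @param n_trees trees per forest.
#' @param n_perm response permutations for the p-value.
#' @param seed RNG seed.
#' @return list: `percent_explained`, `p`, `importance` (named vector,
#'   IncNodePurity), `oob_r2` (unfloored), `n_trees`, `n_perm`.
#' @export
rfExplained <- function(y, env, n_trees = 500, n_perm = 99, seed = NULL) {
  env <- as.data.frame(env)
  if (length(y) < 6) stop("need at least 6 samples")
  if (sd(y) == 0) stop("constant response")
  if (!is.null(seed)) set.seed(seed)
  oobR2 <- function(resp) {
    rf <- randomForest::randomForest(x = env, y = resp, ntree = n_trees)
    1 - rf$mse[n_trees] / mean((resp - mean(resp))^2)
  }
  rf <- randomForest::randomForest(x = env, y = y, ntree = n_trees,
                                   importance = FALSE)
  obs <- 1 - rf$mse[n_trees] / mean((y - mean(y))^2)
  perm <- vapply(seq_len(n_perm), function(b) oobR2(sample(y)), 0)
  list(percent_explained = max(obs, 0) * 100,
       p = (1 + sum(perm >= obs)) / (n_perm + 1),
       importance = setNames(rf$importance[, 1], rownames(rf$importance)),
       oob_r2 = obs, n_trees = n_trees, n_perm = n_perm)
}

#' Variation partitioning across physical, chemical and biomass sets
#'
#' Redundancy-analysis variance decomposition of a (Hellinger-transformed)
#' multivariate abundance response into unique and shared fractions of up
#' to three predictor sets, with Ezekiel-adjusted R-squared. Individual
#' fractions may be negative; all fractions plus the residual sum to 1.
#'
#' @param Y samples x taxa abundance matrix (dominant genera).
#' @param X1,X2,X3 predictor data.frames/matrices; X2/X3 may be NULL, in
#'   which case the result degenerates to plain adjusted R-squared of
#'   Y ~ X1 (and, with two sets, the two-set partition).
#' @param hellinger apply the Hellinger transform to Y first (recommended
#'   for compositional abundances).
#' @param labels names of the predictor sets.
#' @return list: `fractions` (named numeric: unique/shared adjusted
#'   fractions), `residual`, `total_adj_r2`, `labels`.
#' @export
variationPartitioning <- function(Y, X1, X2 = NULL, X3 = NULL,
                                  hellinger = TRUE,
                                  labels = c("physical", "chemical",
                                             "biomass")) {
  Y <- as.matrix(Y)
  if (hellinger) Y <- vegan::decostand(Y, method = "hellinger")
  sets <- Filter(Negate(is.null), list(X1, X2, X3))
  sets <- lapply(sets, as.data.frame)
  labels <- labels[seq_along(sets)]
  if (length(sets) == 1) {
    adj <- vegan::RsquareAdj(vegan::rda(Y ~ ., data = sets[[1]]))$adj.r.squared
    fr <- setNames(adj, paste0("unique_", labels[1]))
    return(list(fractions = fr, residual = 1 - adj, total_adj_r2 = adj,
                labels = labels))
  }
  vp <- if (length(sets) == 2)
    vegan::varpart(Y, sets[[1]], sets[[2]])
  else
    vegan::varpart(Y, sets[[1]], sets[[2]], sets[[3]])
  ind <- vp$part$indfract$Adj.R.square
  if (length(sets) == 2) {
    fr <- setNames(ind[1:3],
                   c(paste0("unique_", labels[1]),
                     paste0("unique_", labels[2]),
                     paste0("shared_", labels[1], "_", labels[2])))
    resid <- ind[4]
  } else {
    fr <- setNames(ind[1:7], c(
      paste0("unique_", labels),
      paste0("shared_", labels[1], "_", labels[2]),
      paste0("shared_", labels[2], "_", labels[3]),
      paste0("shared_", labels[1], "_", labels[3]),
      paste0("shared_", labels[1], "_", labels[2], "_", labels[3])))
    resid <- ind[8]
  }
  list(fractions = fr, residual = resid, total_adj_r2 = sum(fr),
       labels = labels)
}

#' Default soil variable-set membership
#'
#' Physical = pH, SWC, EC (if present), Na, K; chemical = TC, TOC, TN, TP,
#' AN, OP; biomass = MBC, MBN, MBP. Used by variation partitioning and the
#' default path model; membership is configurable at every call site.
#'
#' @param meta metadata data.frame (sets are intersected with its columns).
#' @return named list of column-name vectors.
#' @export
soilVariableSets <- function(meta = NULL) {
  sets <- list(physical = c("pH", "SWC", "EC", "Na", "K"),
               chemical = c("TC", "TOC", "TN", "TP", "AN", "OP"),
               biomass = c("MBC", "MBN", "MBP"))
  if (!is.null(meta)) sets <- lapply(sets, intersect, names(meta))
  sets
}

#' Spearman heatmap table: taxa vs environment
#'
#' Pairwise tie-corrected Spearman rho with exact small-n p-values for
#' every (taxon, variable) pair; raw p by default (matching significance
#' stars computed on unadjusted p), Benjamini-Hochberg by flag.
#'
#' @param taxa [RelAbundanceTable-class] or samples x taxa matrix.
#' @param meta metadata data.frame aligned to the samples.
#' @param variables metadata columns; default all numeric soil variables.
#' @param adjust `"none"` (default) or a [stats::p.adjust()] method.
#' @return data.frame: `taxon`, `variable`, `rho`, `p`.
#' @export
taxaEnvSpearman <- function(taxa, meta, variables = NULL, adjust = "none") {
  M <- if (is(taxa, "RelAbundanceTable")) relValues(taxa) else as.matrix(taxa)
  env <- .numericEnv(meta, variables)
  stopifnot(nrow(M) == nrow(env))
  sm <- spearmanMatrix(M, env, adjust = adjust)
  data.frame(
    taxon = rep(colnames(M), times = ncol(env)),
    variable = rep(colnames(env), each = ncol(M)),
    rho = as.vector(sm$rho), p = as.vector(sm$p),
    row.names = NULL, stringsAsFactors = FALSE)
}
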