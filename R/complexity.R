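#' Network complexity index (NCI)
#'
#' PCA (by singular value decomposition of the z-scored columns) over a
#' per-sample matrix of subnetwork parameters — nodes, edges, average
#' density, transitivity, diameter and average path length — pooling all
#' samples into one decomposition. The NCI of a sample is its score on the
#' first principal component, with the sign oriented so that NCI
#' correlates positively with the edge count: higher NCI = more complex,
#' stable across runs.
#'
#' @param metrics data.frame from [subnetworkMetrics()] (or any per-sample
#'   parameter table with a `sample_id` column).
#' @param columns parameter columns to use; defaults to the six complexity
#'   parameters.
#' @param orient_by column used for the sign rule (default `"edges"`;
#'   falls back to the first used column if absent).
#' @return an [NciResult-class]. Samples with missing parameters are
#'   dropped with a warning, as are constant columns.
#' @export
networkComplexityIndex <- function(metrics,
                                   columns = c("nodes", "edges", "density",
                                               "clustering_coefficient",
                                               "diameter",
                                               "avg_path_length"),
                                   orient_by = "edges") {
  stopifnot("sample_id" %in% names(metrics))
  columns <- intersect(columns, names(metrics))
  M <- as.matrix(metrics[, columns, drop = FALSE])
  mode(M) <- "numeric"
  rownames(M) <- metrics$sample_id
  ok <- complete.cases(M)
  if (!all(ok)) {
    warning(sum(!ok), " sample(s) with missing metrics dropped")
    M <- M[ok, , drop = FALSE]
  }
  if (nrow(M) < 3) stop("need >= 3 samples with complete metrics")
  sds <- apply(M, 2, sd)
  dropped <- colnames(M)[sds == 0]
  if (length(dropped)) {
    warning("constant column(s) dropped: ", paste(dropped, collapse = ", "))
    M <- M[, sds > 0, drop = FALSE]
  }
  if (!ncol(M)) stop("all parameter columns are constant")
  pc <- prcomp(M, center = TRUE, scale. = TRUE)
  scores <- pc$x[, 1]
  if (!orient_by %in% colnames(M)) orient_by <- colnames(M)[1]
  orient <- cor(scores, M[, orient_by])
  flip <- if (!is.na(orient) && orient < 0) -1 else 1
  loadings <- pc$rotation
  loadings[, 1] <- flip * loadings[, 1]
  new("NciResult",
      scores = setNames(flip * scores, rownames(M)),
      loadings = loadings,
      var_pct = 100 * pc$sdev^2 / sum(pc$sdev^2),
      metrics = scale(M),
      dropped = dropped)
}

#' Compare NCI between plant groups
#'
#' One-way ANOVA with Tukey HSD and a compact letter display over the
#' per-sample NCI scores (see [anovaLetters()]). A single group returns
#' the letter "a" without a test.
#'
#' @param nci an [NciResult-class] (or named numeric score vector).
#' @param group group label per sample (matched by sample id when `nci`
#'   carries names and `group` does too).
#' @param alpha significance level.
#' @return as [anovaLetters()]; for a single group, a one-row summary.
#' @export
nciGroupTest <- function(nci, group, alpha = 0.05) {
  scores <- if (is(nci, "NciResult")) nci@scores else nci
  if (!is.null(names(scores)) && !is.null(names(group)))
    group <- group[names(scores)]
  group <- as.character(group)
  if (length(unique(group)) == 1) {
    return(list(summary = data.frame(
      group = group[1], n = length(scores), mean = mean(scores),
      se = sd(scores) / sqrt(length(scores)), letters = "a",
      stringsAsFactors = FALSE),
      anova = c(F = NA_real_, p = NA_real_), tukey = NULL, alpha = alpha))
  }
  anovaLetters(scores, group, alpha = alpha)
}

#' Linear regression of a dominant phylum on the NCI
#'
#' Ordinary least squares of per-sample phylum relative abundance on the
#' network complexity index, with two-sided slope test.
#'
#' @param abundance phylum relative abundance per sample.
#' @param nci NCI score per sample (non-constant), aligned.
#' @return list: `slope`, `intercept`, `r_squared`, `p`, `n`.
#' @export
phylumVsNci <- function(abundance, nci) {
  if (is(nci, "NciResult")) nci <- nci@scores
  stopifnot(length(abundance) == length(nci))
  if (length(nci) < 3) stop("need at least 3 samples")
  if (sd(nci) == 0) stop("NCI has zero variance")
  fit <- lm(abundance ~ nci)
  sm <- summary(fit)
  list(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
       r_squared = sm$r.squared,
       p = sm$coefficients[2, 4], n = length(nci))
}
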