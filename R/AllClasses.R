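#' @import methods
#' @importFrom stats cor sd var aov TukeyHSD lm coef pnorm pt qnorm rnorm runif
#'   rmultinom rlnorm prcomp as.dist dist p.adjust anova quantile rbinom
#'   complete.cases setNames predict
#' @importFrom utils read.delim write.table combn head packageVersion
NULL

.KINGDOMS <- c("bacteria", "fungi")

#' OtuTable: a validated OTU count matrix for one kingdom
#'
#' Stores non-negative integer counts with samples as rows and OTUs as
#' columns, tagged by the marker-gene kingdom (16S bacteria or ITS fungi).
#' Row and column names are the sample and OTU identifiers and must be
#' unique.
#'
#' @slot counts numeric matrix of non-negative integer-valued counts,
#'   samples x OTUs, with unique dimnames.
#' @slot kingdom either `"bacteria"` or `"fungi"`.
#'
#' @seealso [otuTable()], [readOtuTable()], [relativeAbundance()]
#' @exportClass OtuTable
setClass("OtuTable",
  representation(counts = "matrix", kingdom = "character"),
  validity = function(object) {
    msg <- character()
    cnt <- object@counts
    if (!is.numeric(cnt)) msg <- c(msg, "counts must be a numeric matrix")
    if (is.null(rownames(cnt)) || is.null(colnames(cnt)))
      msg <- c(msg, "counts must have sample (row) and OTU (column) names")
    else {
      if (anyDuplicated(rownames(cnt))) msg <- c(msg, "duplicate sample ids")
      if (anyDuplicated(colnames(cnt))) msg <- c(msg, "duplicate OTU ids")
    }
    if (is.numeric(cnt)) {
      if (anyNA(cnt)) msg <- c(msg, "counts contain missing values")
      else {
        if (any(cnt < 0)) msg <- c(msg, "negative counts are not allowed")
        if (any(abs(cnt - round(cnt)) > 1e-8))
          msg <- c(msg, "counts must be integer-valued")
      }
    }
    if (length(object@kingdom) != 1L || !object@kingdom %in% .KINGDOMS)
      msg <- c(msg, "kingdom must be one of 'bacteria', 'fungi'")
    if (length(msg)) msg else TRUE
  }
)

#' RelAbundanceTable: per-sample proportions
#'
#' Same axes as [OtuTable-class] but each row holds proportions summing to
#' one; produced by [relativeAbundance()] and consumed by ordination,
#' dominant-taxon selection and network inference.
#'
#' @slot values numeric matrix in \[0, 1\], each row summing to 1 within 1e-9.
#' @slot kingdom `"bacteria"` or `"fungi"`.
#' @exportClass RelAbundanceTable
setClass("RelAbundanceTable",
  representation(values = "matrix", kingdom = "character"),
  validity = function(object) {
    msg <- character()
    v <- object@values
    if (!is.numeric(v)) msg <- c(msg, "values must be numeric")
    if (is.null(rownames(v)) || is.null(colnames(v)))
      msg <- c(msg, "values must have sample and taxon names")
    if (is.numeric(v) && !anyNA(v)) {
      if (any(v < -1e-12) || any(v > 1 + 1e-12))
        msg <- c(msg, "values must lie in [0, 1]")
      rs <- rowSums(v)
      if (any(abs(rs - 1) > 1e-9))
        msg <- c(msg, sprintf("row sums deviate from 1 (max |dev| = %.3g)",
                              max(abs(rs - 1))))
    }
    if (length(object@kingdom) != 1L || !object@kingdom %in% .KINGDOMS)
      msg <- c(msg, "kingdom must be one of 'bacteria', 'fungi'")
    if (length(msg)) msg else TRUE
  }
)

#' CorrelationNetwork: a signed Spearman co-occurrence network
#'
#' Undirected graph over bacterial and fungal OTUs whose edges passed the
#' correlation-magnitude and significance thresholds. Node and edge tables
#' are plain data frames so the object serializes to TSV/GraphML without
#' loss; convert with [asIgraph()] for graph algorithms.
#'
#' @slot nodes data.frame with columns `otu_id`, `kingdom`, `phylum`.
#' @slot edges data.frame with columns `source`, `target`, `rho`, `sign`,
#'   `p`; one row per unordered OTU pair, no self-loops.
#' @slot params list of build parameters (`rho_threshold`, `p_threshold`,
#'   `prevalence_min`, `n_samples`, `p_method`, `weight_scheme`).
#' @exportClass CorrelationNetwork
setClass("CorrelationNetwork",
  representation(nodes = "data.frame", edges = "data.frame", params = "list"),
  validity = function(object) {
    msg <- character()
    nd <- object@nodes; ed <- object@edges
    if (!all(c("otu_id", "kingdom", "phylum") %in% names(nd)))
      msg <- c(msg, "nodes must have otu_id, kingdom, phylum columns")
    if (!all(c("source", "target", "rho", "sign", "p") %in% names(ed)))
      msg <- c(msg, "edges must have source, target, rho, sign, p columns")
    if (length(msg)) return(msg)
    if (anyDuplicated(nd$otu_id)) msg <- c(msg, "duplicate node ids")
    if (nrow(ed)) {
      if (any(ed$source == ed$target)) msg <- c(msg, "self-loops not allowed")
      key <- paste(pmin(ed$source, ed$target), pmax(ed$source, ed$target))
      if (anyDuplicated(key)) msg <- c(msg, "duplicate edges")
      if (!all(c(ed$source, ed$target) %in% nd$otu_id))
        msg <- c(msg, "edge endpoints missing from node table")
      if (any(abs(ed$rho) > 1 + 1e-12)) msg <- c(msg, "|rho| must be <= 1")
      if (!all(ed$sign %in% c(-1, 1))) msg <- c(msg, "edge sign must be -1 or 1")
      rt <- object@params$rho_threshold
      pt <- object@params$p_threshold
      if (!is.null(rt) && any(abs(ed$rho) <= rt))
        msg <- c(msg, "edge with |rho| at or below the rho threshold")
      if (!is.null(pt) && any(ed$p >= pt))
        msg <- c(msg, "edge with p at or above the p threshold")
    }
    if (length(msg)) msg else TRUE
  }
)

#' PlsPmSpec: blocks and inner path matrix for a PLS path model
#'
#' @slot blocks named list; each element is a character vector of indicator
#'   column names forming one reflective (mode A) block.
#' @slot path square logical matrix in block order; `path[j, i] = TRUE`
#'   means block i is a predecessor of block j. Must be lower triangular
#'   (acyclic in the given order).
#' @slot scheme inner weighting scheme: `"centroid"`, `"factorial"` or
#'   `"path"`.
#' @slot max_iter,tol outer-weight iteration controls.
#' @exportClass PlsPmSpec
setClass("PlsPmSpec",
  representation(blocks = "list", path = "matrix", scheme = "character",
                 max_iter = "numeric", tol = "numeric"),
  validity = function(object) {
    msg <- character()
    b <- object@blocks; P <- object@path
    if (!length(b) || is.null(names(b)) || anyDuplicated(names(b)))
      msg <- c(msg, "blocks must be a non-empty uniquely named list")
    if (any(!vapply(b, length, 1L)))
      msg <- c(msg, "every block needs at least one indicator")
    ind <- unlist(b, use.names = FALSE)
    if (anyDuplicated(ind))
      msg <- c(msg, "an indicator may belong to only one block")
    if (!is.logical(P) || nrow(P) != length(b) || ncol(P) != length(b))
      msg <- c(msg, "path must be a logical blocks x blocks matrix")
    else if (any(P[upper.tri(P, diag = TRUE)]))
      msg <- c(msg, "path matrix must be strictly lower triangular (acyclic)")
    if (!object@scheme %in% c("centroid", "factorial", "path"))
      msg <- c(msg, "scheme must be centroid, factorial or path")
    if (length(msg)) msg else TRUE
  }
)

#' PlsPmResult: a fitted PLS path model
#'
#' @slot weights,loadings named numeric vectors per indicator.
#' @slot scores samples x blocks matrix of unit-variance latent scores.
#' @slot paths data.frame (`from`, `to`, `coef`) of structural coefficients.
#' @slot r2 named numeric, R-squared per endogenous block.
#' @slot iterations outer iterations used.
#' @slot boot bootstrap summary data.frame or NULL.
#' @slot spec the [PlsPmSpec-class] that produced the fit.
#' @exportClass PlsPmResult
setClass("PlsPmResult",
  representation(weights = "numeric", loadings = "numeric", scores = "matrix",
                 paths = "data.frame", r2 = "numeric", iterations = "numeric",
                 boot = "ANY", spec = "PlsPmSpec"))

#' NciResult: network complexity index from a PCA of topology metrics
#'
#' @slot scores named numeric vector: NCI (oriented first-component score)
#'   per sample.
#' @slot loadings variables x components matrix of PCA loadings.
#' @slot var_pct percent variance per component (sums to 100).
#' @slot metrics the (z-scored source columns of the) parameter matrix used.
#' @slot dropped character vector of constant columns removed, if any.
#' @exportClass NciResult
setClass("NciResult",
  representation(scores = "numeric", loadings = "matrix", var_pct = "numeric",
                 metrics = "matrix", dropped = "character"))
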