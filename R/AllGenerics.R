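#' Accessors for rhizonet classes
#'
#' `otuCounts()` returns the samples x OTUs count matrix; `relValues()` the
#' proportion matrix; `kingdom()` the kingdom tag; `sampleIDs()` /
#' `otuIDs()` the axis identifiers; `networkNodes()`, `networkEdges()` and
#' `networkParams()` the components of a [CorrelationNetwork-class].
#'
#' @param x an object of the appropriate class.
#' @return The slot contents (matrices, character vectors, data frames).
#' @name accessors
#' @aliases otuCounts relValues kingdom sampleIDs otuIDs networkNodes
#'   networkEdges networkParams
NULL

#' @rdname accessors
#' @export
setGeneric("otuCounts", function(x) standardGeneric("otuCounts"))
#' @rdname accessors
#' @export
setGeneric("relValues", function(x) standardGeneric("relValues"))
#' @rdname accessors
#' @export
setGeneric("kingdom", function(x) standardGeneric("kingdom"))
#' @rdname accessors
#' @export
setGeneric("sampleIDs", function(x) standardGeneric("sampleIDs"))
#' @rdname accessors
#' @export
setGeneric("otuIDs", function(x) standardGeneric("otuIDs"))
#' @rdname accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
#' @rdname accessors
#' @export
setGeneric("networkParams", function(x) standardGeneric("networkParams"))

#' Convert a CorrelationNetwork to an igraph graph
#'
#' Nodes carry `kingdom` and `phylum` attributes; edges carry `rho`, `sign`,
#' `p` and a `distance` weight under the network's weight scheme
#' (default `1 - |rho|`, so stronger correlations are shorter).
#'
#' @param x a [CorrelationNetwork-class].
#' @param ... unused.
#' @return an [igraph::igraph] object.
#' @export
setGeneric("asIgraph", function(x, ...) standardGeneric("asIgraph"))

setMethod("otuCounts", "OtuTable", function(x) x@counts)
setMethod("relValues", "RelAbundanceTable", function(x) x@values)
setMethod("kingdom", "OtuTable", function(x) x@kingdom)
setMethod("kingdom", "RelAbundanceTable", function(x) x@kingdom)
setMethod("sampleIDs", "OtuTable", function(x) rownames(x@counts))
setMethod("sampleIDs", "RelAbundanceTable", function(x) rownames(x@values))
setMethod("otuIDs", "OtuTable", function(x) colnames(x@counts))
setMethod("otuIDs", "RelAbundanceTable", function(x) colnames(x@values))
setMethod("networkNodes", "CorrelationNetwork", function(x) x@nodes)
setMethod("networkEdges", "CorrelationNetwork", function(x) x@edges)
setMethod("networkParams", "CorrelationNetwork", function(x) x@params)

setMethod("show", "OtuTable", function(object) {
  cnt <- object@counts
  cat(sprintf("OtuTable (%s): %d samples x %d OTUs, total count %s\n",
              object@kingdom, nrow(cnt), ncol(cnt),
              format(sum(cnt), big.mark = ",")))
})

setMethod("show", "RelAbundanceTable", function(object) {
  v <- object@values
  cat(sprintf("RelAbundanceTable (%s): %d samples x %d taxa\n",
              object@kingdom, nrow(v), ncol(v)))
})

setMethod("show", "CorrelationNetwork", function(object) {
  nd <- object@nodes; ed <- object@edges; pp <- object@params
  cat(sprintf(
    "CorrelationNetwork: %d nodes (%d bacterial, %d fungal), %d edges (%d +, %d -)\n",
    nrow(nd), sum(nd$kingdom == "bacteria"), sum(nd$kingdom == "fungi"),
    nrow(ed), sum(ed$sign > 0), sum(ed$sign < 0)))
  if (!is.null(pp$rho_threshold))
    cat(sprintf("  thresholds: |rho| > %s, p < %s (%s p-values, n = %s)\n",
                pp$rho_threshold, pp$p_threshold,
                if (is.null(pp$p_method)) "?" else pp$p_method,
                if (is.null(pp$n_samples)) "?" else pp$n_samples))
})

setMethod("show", "PlsPmResult", function(object) {
  cat(sprintf("PlsPmResult: %d blocks, %d paths, converged in %d iterations\n",
              ncol(object@scores), nrow(object@paths), object@iterations))
  if (nrow(object@paths)) {
    cat("  paths:\n")
    for (i in seq_len(nrow(object@paths)))
      cat(sprintf("    %s -> %s: %+.3f\n", object@paths$from[i],
                  object@paths$to[i], object@paths$coef[i]))
  }
  if (length(object@r2))
    cat("  R2:", paste(sprintf("%s = %.3f", names(object@r2), object@r2),
                       collapse = ", "), "\n")
})

setMethod("show", "NciResult", function(object) {
  cat(sprintf("NciResult: %d samples, PC1 explains %.1f%% of variance\n",
              length(object@scores), object@var_pct[1]))
})

setMethod("asIgraph", "CorrelationNetwork", function(x, ...) {
  scheme <- x@params$weight_scheme
  if (is.null(scheme)) scheme <- "one_minus_abs_rho"
  ed <- x@edges
  if (nrow(ed)) {
    ed$distance <- switch(scheme,
      unit = rep(1, nrow(ed)),
      one_minus_abs_rho = 1 - abs(ed$rho),
      inv_abs_rho = 1 / abs(ed$rho),
      stop("unknown weight scheme: ", scheme))
  } else ed$distance <- numeric(0)
  igraph::graph_from_data_frame(ed, directed = FALSE, vertices = x@nodes)
})
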