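#' Build a bacterial-fungal Spearman co-occurrence network
#'
#' Every OTU pair (within and between kingdoms) passing a prevalence filter
#' is tested with tie-corrected Spearman correlation; an edge is kept when
#' |rho| exceeds `rho_threshold` and p falls below `p_threshold`. At the
#' small per-group sample sizes of rhizosphere studies (n = 6) p-values are
#' computed by exact enumeration of all n! rank permutations — the
#' t-approximation is unreliable there — switching to the t-approximation
#' above `exact_max` samples. Isolated nodes are dropped.
#'
#' @param bacteria,fungi [RelAbundanceTable-class] (or [OtuTable-class],
#'   converted internally) over the same samples. Correlations are computed
#'   on relative abundances; pass rarefied counts through
#'   [relativeAbundance()] first if preferred.
#' @param taxonomy optional taxonomy data.frame ([readTaxonomy()]) to
#'   annotate node phyla.
#' @param prevalence_min minimum number of samples in which an OTU must be
#'   present (abundance > 0) to be tested. With n = 6 samples, pairs
#'   dominated by zeros otherwise produce spurious perfect correlations.
#' @param rho_threshold,p_threshold edge criteria (defaults |rho| > 0.9,
#'   p < 0.01).
#' @param exact_max largest n for exact permutation p-values.
#' @param weight_scheme edge length used later for weighted paths:
#'   `"one_minus_abs_rho"` (default; stronger correlation = shorter),
#'   `"unit"` or `"inv_abs_rho"`.
#' @return a [CorrelationNetwork-class].
#' @export
spearmanEdges <- function(bacteria, fungi, taxonomy = NULL,
                          prevalence_min = 3, rho_threshold = 0.9,
                          p_threshold = 0.01, exact_max = 7,
                          weight_scheme = "one_minus_abs_rho") {
  if (is(bacteria, "OtuTable")) bacteria <- relativeAbundance(bacteria)
  if (is(fungi, "OtuTable")) fungi <- relativeAbundance(fungi)
  if (!setequal(sampleIDs(bacteria), sampleIDs(fungi)))
    stop("bacterial and fungal tables cover different samples")
  vb <- relValues(bacteria)
  vf <- relValues(fungi)[sampleIDs(bacteria), , drop = FALSE]
  m <- cbind(vb, vf)
  king <- c(rep("bacteria", ncol(vb)), rep("fungi", ncol(vf)))
  names(king) <- colnames(m)
  n <- nrow(m)
  if (n < 4) stop("need at least 4 shared samples")
  keep <- colSums(m > 0) >= prevalence_min
  m <- m[, keep, drop = FALSE]
  king <- king[keep]
  edges <- .emptyEdges()
  if (ncol(m) >= 2) {
    rho <- suppressWarnings(cor(m, method = "spearman"))
    cand <- which(upper.tri(rho) & abs(rho) > rho_threshold & !is.na(rho),
                  arr.ind = TRUE)
    if (nrow(cand)) {
      if (n <= exact_max) {
        perms <- allPermutations(n)
        pvals <- vapply(seq_len(nrow(cand)), function(k)
          .spearmanExactP(m[, cand[k, 1]], m[, cand[k, 2]],
                          alternative = "two.sided", perms = perms), 0)
        p_method <- "exact"
      } else {
        pvals <- vapply(seq_len(nrow(cand)), function(k)
          .spearmanApproxP(rho[cand[k, 1], cand[k, 2]], n), 0)
        p_method <- "t-approximation"
      }
      hit <- pvals < p_threshold
      if (any(hit)) {
        cand <- cand[hit, , drop = FALSE]
        r <- rho[cand]
        edges <- data.frame(
          source = colnames(m)[cand[, 1]],
          target = colnames(m)[cand[, 2]],
          rho = r, sign = ifelse(r > 0, 1, -1), p = pvals[hit],
          stringsAsFactors = FALSE)
      }
    } else p_method <- if (n <= exact_max) "exact" else "t-approximation"
  } else p_method <- if (n <= exact_max) "exact" else "t-approximation"
  used <- sort(unique(c(edges$source, edges$target)))
  phylum <- rep("unclassified", length(used))
  if (!is.null(taxonomy) && length(used)) {
    hitx <- match(used, taxonomy$otu_id)
    phylum[!is.na(hitx)] <- taxonomy$phylum[hitx[!is.na(hitx)]]
  }
  nodes <- data.frame(otu_id = used, kingdom = unname(king[used]),
                      phylum = phylum, stringsAsFactors = FALSE)
  correlationNetwork(nodes, edges, params = list(
    rho_threshold = rho_threshold, p_threshold = p_threshold,
    prevalence_min = prevalence_min, n_samples = n, p_method = p_method,
    weight_scheme = weight_scheme))
}

.NA_METRICS <- function() data.frame(
  nodes = NA_integer_, bacterial_nodes = NA_integer_,
  fungal_nodes = NA_integer_, edges = NA_integer_,
  positive_edges = NA_integer_, negative_edges = NA_integer_,
  pos_neg_ratio = NA_real_, modularity = NA_real_, n_modules = NA_integer_,
  avg_path_length = NA_real_, diameter = NA_real_, density = NA_real_,
  clustering_coefficient = NA_real_, betweenness_centralization = NA_real_)

#' Topology statistics of a co-occurrence network
#'
#' One row of network parameters: node counts per kingdom; total, positive
#' and negative edge counts and their ratio; modularity and module count by
#' greedy (CNM) modularity maximisation on the unweighted graph; average
#' path length and diameter on the network's distance weights (default
#' 1 - |rho|), averaged/maximised over connected pairs only; unweighted
#' density and global transitivity; Freeman betweenness centralization
#' (unweighted, normalised so a star scores 1).
#'
#' @param net a [CorrelationNetwork-class].
#' @return one-row data.frame of metrics; an empty network returns all-NA
#'   values with a warning.
#' @export
networkTopology <- function(net) {
  ed <- networkEdges(net)
  nd <- networkNodes(net)
  if (!nrow(nd) || !nrow(ed)) {
    warning("empty network; metrics are undefined")
    return(.NA_METRICS())
  }
  g <- asIgraph(net)
  nv <- igraph::vcount(g)
  ne <- igraph::ecount(g)
  cl <- igraph::cluster_fast_greedy(g, weights = NULL)
  memb <- igraph::membership(cl)  # Q is reported for this exact partition
  dm <- igraph::distances(g, weights = igraph::E(g)$distance)
  off <- dm[upper.tri(dm)]
  fin <- off[is.finite(off)]
  btw <- igraph::betweenness(g, directed = FALSE, weights = NA)
  denom <- (nv - 1)^2 * (nv - 2) / 2
  data.frame(
    nodes = as.integer(nv),
    bacterial_nodes = sum(nd$kingdom == "bacteria"),
    fungal_nodes = sum(nd$kingdom == "fungi"),
    edges = as.integer(ne),
    positive_edges = sum(ed$sign > 0),
    negative_edges = sum(ed$sign < 0),
    pos_neg_ratio = if (any(ed$sign < 0))
      sum(ed$sign > 0) / sum(ed$sign < 0) else NA_real_,
    modularity = igraph::modularity(g, memb),
    n_modules = length(unique(as.integer(memb))),
    avg_path_length = if (length(fin)) mean(fin) else NA_real_,
    diameter = if (length(fin)) max(fin) else NA_real_,
    density = 2 * ne / (nv * (nv - 1)),
    clustering_coefficient = igraph::transitivity(g, type = "global"),
    betweenness_centralization = if (nv > 2) sum(max(btw) - btw) / denom
      else NA_real_)
}

#' Induced subnetwork of the OTUs present in one sample
#'
#' Nodes are restricted to OTUs with count >= `presence_min` in the given
#' sample (looked up across the supplied tables); edges are inherited from
#' the parent network.
#'
#' @param net parent [CorrelationNetwork-class].
#' @param tables an [OtuTable-class] or list of them (e.g. bacteria and
#'   fungi) supplying per-sample counts.
#' @param sample_id sample to extract.
#' @param presence_min minimum count for presence.
#' @return a [CorrelationNetwork-class]; empty (with a warning) when the
#'   sample contains none of the parent's OTUs.
#' @export
sampleSubnetwork <- function(net, tables, sample_id, presence_min = 1) {
  if (is(tables, "OtuTable")) tables <- list(tables)
  present <- character()
  found <- FALSE
  for (tab in tables) {
    cnt <- otuCounts(tab)
    if (!sample_id %in% rownames(cnt)) next
    found <- TRUE
    v <- cnt[sample_id, ]
    present <- c(present, colnames(cnt)[v >= presence_min])
  }
  if (!found) stop("unknown sample: ", sample_id)
  nd <- networkNodes(net)
  ed <- networkEdges(net)
  keep_nodes <- nd[nd$otu_id %in% present, , drop = FALSE]
  keep_edges <- ed[ed$source %in% keep_nodes$otu_id &
                     ed$target %in% keep_nodes$otu_id, , drop = FALSE]
  if (!nrow(keep_nodes))
    warning("sample ", sample_id, " contains no network OTUs")
  params <- networkParams(net)
  params$subnetwork_of <- sample_id
  correlationNetwork(keep_nodes, if (nrow(keep_edges)) keep_edges
                     else .emptyEdges(), params)
}

#' Topology metrics of every per-sample subnetwork
#'
#' @param net parent [CorrelationNetwork-class].
#' @param tables [OtuTable-class] or list of them; the union of their
#'   samples defines the rows.
#' @param presence_min minimum count for presence.
#' @return data.frame with `sample_id` plus the [networkTopology()]
#'   columns, one row per sample.
#' @export
subnetworkMetrics <- function(net, tables, presence_min = 1) {
  if (is(tables, "OtuTable")) tables <- list(tables)
  samples <- unique(unlist(lapply(tables, sampleIDs)))
  rows <- lapply(samples, function(s) {
    sub <- suppressWarnings(sampleSubnetwork(net, tables, s, presence_min))
    cbind(sample_id = s,
          suppressWarnings(networkTopology(sub)),
          stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Correlate subnetwork metrics with soil variables
#'
#' Spearman rho and p (exact at small n) for every (metric, variable)
#' pair; constant metrics give NA entries.
#'
#' @param metrics data.frame from [subnetworkMetrics()] (needs
#'   `sample_id`).
#' @param meta metadata data.frame with `sample_id`.
#' @param metric_cols metric columns to use; default the six complexity
#'   parameters (nodes, edges, density, clustering_coefficient, diameter,
#'   avg_path_length).
#' @param variables metadata columns; default all numeric soil variables.
#' @return data.frame: `metric`, `variable`, `rho`, `p`.
#' @export
subnetworkEnvCorrelation <- function(metrics, meta, metric_cols = NULL,
                                     variables = NULL) {
  if (is.null(metric_cols))
    metric_cols <- c("nodes", "edges", "density", "clustering_coefficient",
                     "diameter", "avg_path_length")
  shared <- intersect(metrics$sample_id, meta$sample_id)
  if (length(shared) < 5) stop("need >= 5 samples with metrics and metadata")
  M <- as.matrix(metrics[match(shared, metrics$sample_id), metric_cols,
                         drop = FALSE])
  env <- .numericEnv(meta[match(shared, meta$sample_id), , drop = FALSE],
                     variables)
  sm <- spearmanMatrix(M, env)
  data.frame(
    metric = rep(metric_cols, times = ncol(env)),
    variable = rep(colnames(env), each = length(metric_cols)),
    rho = as.vector(sm$rho), p = as.vector(sm$p),
    row.names = NULL, stringsAsFactors = FALSE)
}
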