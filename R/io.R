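#' Construct an OtuTable
#'
#' @param counts numeric matrix of non-negative integer counts, samples x
#'   OTUs, with dimnames.
#' @param kingdom `"bacteria"` or `"fungi"`.
#' @return a validated [OtuTable-class].
#' @examples
#' m <- matrix(c(1, 2, 3, 4), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("OTU1", "OTU2")))
#' otuTable(m, "bacteria")
#' @export
otuTable <- function(counts, kingdom = c("bacteria", "fungi")) {
  kingdom <- match.arg(kingdom)
  new("OtuTable", counts = as.matrix(counts), kingdom = kingdom)
}

#' Construct a RelAbundanceTable
#'
#' @param values numeric matrix of per-sample proportions (rows sum to 1).
#' @param kingdom `"bacteria"` or `"fungi"`.
#' @return a validated [RelAbundanceTable-class].
#' @export
relAbundanceTable <- function(values, kingdom = c("bacteria", "fungi")) {
  kingdom <- match.arg(kingdom)
  new("RelAbundanceTable", values = as.matrix(values), kingdom = kingdom)
}

#' Construct a CorrelationNetwork from node and edge tables
#'
#' @param nodes data.frame with `otu_id`, `kingdom`, `phylum`.
#' @param edges data.frame with `source`, `target`, `rho`, `sign`, `p`.
#' @param params list of build parameters (thresholds, weight scheme, ...).
#' @return a validated [CorrelationNetwork-class].
#' @export
correlationNetwork <- function(nodes, edges, params = list()) {
  new("CorrelationNetwork", nodes = as.data.frame(nodes),
      edges = as.data.frame(edges), params = params)
}

.emptyEdges <- function() {
  data.frame(source = character(), target = character(), rho = numeric(),
             sign = numeric(), p = numeric(), stringsAsFactors = FALSE)
}

#' Read an OTU count table from tab-separated text
#'
#' Accepts both layout dialects: OTUs as rows with samples as columns (the
#' common QIIME-style export, recognised by a first header cell starting
#' with `#OTU`) or samples as rows. The returned object is always
#' normalised to samples x OTUs.
#'
#' @param path TSV file; first column holds the ids of whichever axis is in
#'   rows.
#' @param kingdom `"bacteria"` or `"fungi"`.
#' @param orientation `"auto"` (header detection), `"otus_as_rows"` or
#'   `"samples_as_rows"` to force a layout.
#' @return an [OtuTable-class].
#' @export
readOtuTable <- function(path, kingdom = c("bacteria", "fungi"),
                         orientation = c("auto", "otus_as_rows",
                                         "samples_as_rows")) {
  kingdom <- match.arg(kingdom)
  orientation <- match.arg(orientation)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (orientation == "auto")
    orientation <- if (grepl("^#?OTU", header[1], ignore.case = TRUE))
      "otus_as_rows" else "samples_as_rows"
  raw <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    comment.char = "")
  ids <- as.character(raw[[1]])
  mat <- as.matrix(raw[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(mat), nrow(mat),
                                 dimnames = list(ids, colnames(mat))))
  bad <- which(!is.finite(num) | num < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("non-numeric or negative count at row '%s', column '%s'",
                 ids[bad[1, 1]], colnames(mat)[bad[1, 2]]))
  }
  mat <- num
  if (orientation == "otus_as_rows") mat <- t(mat)
  otuTable(mat, kingdom)
}

#' Write an OTU count table as tab-separated text
#'
#' @param x an [OtuTable-class].
#' @param path output file.
#' @param orientation layout to write; `"samples_as_rows"` (default) or the
#'   QIIME-style `"otus_as_rows"` whose header starts with `#OTU ID`.
#' @return `path`, invisibly.
#' @export
writeOtuTable <- function(x, path,
                          orientation = c("samples_as_rows", "otus_as_rows")) {
  orientation <- match.arg(orientation)
  cnt <- otuCounts(x)
  if (orientation == "otus_as_rows") {
    df <- data.frame(`#OTU ID` = colnames(cnt), t(cnt), check.names = FALSE)
  } else {
    df <- data.frame(sample_id = rownames(cnt), cnt, check.names = FALSE)
  }
  .writeTsv(df, path)
}

.writeTsv <- function(df, path) {
  con <- file(path, open = "wb")  # enforce LF on every platform
  on.exit(close(con))
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              fileEncoding = "UTF-8", eol = "\n")
  invisible(path)
}

.TAX_RANKS <- c("kingdom", "phylum", "class", "order", "family", "genus")

#' Read a taxonomy table
#'
#' Expects a TSV with an `otu_id` column plus any of the ranks kingdom,
#' phylum, class, order, family, genus. Missing ranks and empty cells are
#' filled with the literal string `"unclassified"` so grouping keys stay
#' stable.
#'
#' @param path TSV file.
#' @return data.frame with `otu_id` and all six rank columns.
#' @export
readTaxonomy <- function(path) {
  tax <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"otu_id" %in% names(tax)) stop("taxonomy file needs an 'otu_id' column")
  for (r in .TAX_RANKS) {
    if (!r %in% names(tax)) tax[[r]] <- "unclassified"
    tax[[r]][is.na(tax[[r]]) | tax[[r]] == ""] <- "unclassified"
  }
  if (anyDuplicated(tax$otu_id)) stop("duplicate otu_id in taxonomy")
  tax[, c("otu_id", .TAX_RANKS)]
}

#' Read and validate a sample-metadata table
#'
#' @param path TSV with `sample_id`, `group` and numeric soil columns
#'   (pH, SWC, Na, K, TC, TOC, TN, TP, AN, OP, MBC, MBN, MBP, optional EC,
#'   TIC and fumigation pairs).
#' @param groups allowed group labels; defaults to the three halophyte
#'   rhizospheres KC, NT, RS.
#' @return data.frame.
#' @export
readSampleMetadata <- function(path, groups = c("KC", "NT", "RS")) {
  meta <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("sample_id", "group") %in% names(meta)))
    stop("metadata needs 'sample_id' and 'group' columns")
  if (anyDuplicated(meta$sample_id)) stop("duplicate sample_id in metadata")
  if (!is.null(groups) && !all(meta$group %in% groups))
    stop("unknown group label(s): ",
         paste(setdiff(meta$group, groups), collapse = ", "))
  num <- setdiff(names(meta), c("sample_id", "group"))
  neg <- num[vapply(meta[num], function(v) any(v < 0, na.rm = TRUE), TRUE)]
  neg <- setdiff(neg, grep("_fum|_nonfum", num, value = TRUE))
  if (length(neg)) stop("negative concentrations in: ",
                        paste(neg, collapse = ", "))
  meta
}

#' Match samples between an abundance table and metadata
#'
#' Exact string matching; a mismatch is an error unless `intersect = TRUE`,
#' in which case both are subset to the shared samples (in table order).
#'
#' @param x an [OtuTable-class] or [RelAbundanceTable-class].
#' @param meta metadata data.frame with `sample_id`.
#' @param intersect allow silent intersection instead of an error.
#' @return list with the aligned `table` and `meta`.
#' @export
alignSamples <- function(x, meta, intersect = FALSE) {
  ids <- sampleIDs(x)
  if (!intersect && !setequal(ids, meta$sample_id))
    stop("sample ids differ between table and metadata; ",
         "use intersect = TRUE to take the common subset")
  shared <- intersect(ids, meta$sample_id)
  if (!length(shared)) stop("no shared samples")
  meta <- meta[match(shared, meta$sample_id), , drop = FALSE]
  if (is(x, "OtuTable"))
    x <- otuTable(otuCounts(x)[shared, , drop = FALSE], kingdom(x))
  else
    x <- relAbundanceTable(relValues(x)[shared, , drop = FALSE], kingdom(x))
  list(table = x, meta = meta)
}

#' Convert counts to relative abundances
#'
#' Each sample's counts are divided by its library size.
#'
#' @param x an [OtuTable-class]; every sample must have a positive total.
#' @return a [RelAbundanceTable-class].
#' @examples
#' m <- matrix(c(2, 0, 2, 5), 2, 2,
#'             dimnames = list(c("s1", "s2"), c("a", "b")))
#' relValues(relativeAbundance(otuTable(m, "fungi")))
#' @export
relativeAbundance <- function(x) {
  cnt <- otuCounts(x)
  lib <- rowSums(cnt)
  if (any(lib == 0))
    stop("sample(s) with zero total count: ",
         paste(rownames(cnt)[lib == 0], collapse = ", "))
  relAbundanceTable(cnt / lib, kingdom(x))
}

#' Aggregate relative abundances to a taxonomic rank
#'
#' Sums proportions within each taxon per sample; OTUs whose rank is
#' `"unclassified"` are pooled into an `"unclassified"` taxon so per-sample
#' totals are conserved.
#'
#' @param x a [RelAbundanceTable-class] at OTU level.
#' @param taxonomy data.frame as returned by [readTaxonomy()].
#' @param rank `"phylum"` or `"genus"`.
#' @return a [RelAbundanceTable-class] over taxa at `rank`.
#' @export
aggregateByRank <- function(x, taxonomy, rank = c("phylum", "genus")) {
  rank <- match.arg(rank)
  v <- relValues(x)
  missing <- setdiff(colnames(v), taxonomy$otu_id)
  if (length(missing))
    stop("OTUs missing from taxonomy: ", paste(missing, collapse = ", "))
  taxon <- taxonomy[[rank]][match(colnames(v), taxonomy$otu_id)]
  agg <- t(rowsum(t(v), group = taxon))
  relAbundanceTable(agg[rownames(v), , drop = FALSE], kingdom(x))
}

#' Write a network as an edge-list TSV (plus node table and GraphML)
#'
#' The edge list holds `source`, `target`, `rho`, `sign`, `p`; node
#' attributes go to a companion TSV so the export is lossless, and a
#' GraphML file importable by Cytoscape can be written as well.
#'
#' @param net a [CorrelationNetwork-class].
#' @param path edge-list TSV path.
#' @param nodes_path node TSV path; default replaces the extension with
#'   `_nodes.tsv`.
#' @param graphml_path optional GraphML output path.
#' @return `path`, invisibly.
#' @export
writeEdgeList <- function(net, path, nodes_path = NULL, graphml_path = NULL) {
  if (is.null(nodes_path))
    nodes_path <- sub("(\\.[^.]*)?$", "_nodes.tsv", path)
  .writeTsv(networkEdges(net), path)
  .writeTsv(networkNodes(net), nodes_path)
  if (!is.null(graphml_path))
    igraph::write_graph(asIgraph(net), graphml_path, format = "graphml")
  invisible(path)
}

#' Re-read a network written by [writeEdgeList()]
#'
#' @param path edge-list TSV.
#' @param nodes_path node TSV (default as in [writeEdgeList()]).
#' @param params build-parameter list to attach.
#' @return a [CorrelationNetwork-class].
#' @export
readEdgeList <- function(path, nodes_path = NULL, params = list()) {
  if (is.null(nodes_path))
    nodes_path <- sub("(\\.[^.]*)?$", "_nodes.tsv", path)
  ed <- read.delim(path, stringsAsFactors = FALSE)
  if (!nrow(ed)) ed <- .emptyEdges()
  ed$source <- as.character(ed$source); ed$target <- as.character(ed$target)
  nd <- read.delim(nodes_path, stringsAsFactors = FALSE)
  nd$otu_id <- as.character(nd$otu_id)
  correlationNetwork(nd, ed, params)
}

#' Bundled reference summaries of the halophyte field study
#'
#' `soilReferenceTable()` returns the per-group mean and standard error of
#' each rhizosphere soil variable (pH, SWC, Na, K, TC, TOC, TN, TP, AN, OP
#' and the fumigation-derived MBC/MBN/MBP) for the three halophytes
#' *Kalidium cuspidatum* (KC), *Nitraria tangutorum* (NT) and *Reaumuria
#' soongarica* (RS), n = 6 composite samples per group. These are the
#' default generative parameters of [simulateSoil()].
#' `networkReferenceTable()` returns the published whole-network parameters
#' (node/edge counts and topology statistics) of the three rhizosphere
#' co-occurrence networks.
#'
#' @return data.frame in long (`variable`, `group`, `mean`, `se`) or wide
#'   (`parameter`, `KC`, `NT`, `RS`) form respectively.
#' @export
soilReferenceTable <- function() {
  read.delim(system.file("extdata", "soil_reference.tsv",
                         package = "rhizonet"), stringsAsFactors = FALSE)
}

#' @rdname soilReferenceTable
#' @export
networkReferenceTable <- function() {
  read.delim(system.file("extdata", "network_reference.tsv",
                         package = "rhizonet"), stringsAsFactors = FALSE)
}
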