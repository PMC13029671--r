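.PIPE_STAGES <- c("simulate", "soil", "diversity", "drivers", "network",
                  "nci", "plspm")

.defaultConfig <- function() {
  list(
    n_per_group = 6,
    sim = list(),
    rho_threshold = 0.9, p_threshold = 0.01, prevalence_min = 3,
    dominance_threshold = 0.01, top_n = 10,
    n_perm = 199, rf_trees = 300, rf_perm = 49,
    scheme = "centroid", n_boot = 200,
    weight_scheme = "one_minus_abs_rho")
}

.mergeConfig <- function(config) {
  base <- .defaultConfig()
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (nm in names(config)) {
    if (is.list(config[[nm]]) && is.list(base[[nm]]))
      base[[nm]][names(config[[nm]])] <- config[[nm]]
    else base[[nm]] <- config[[nm]]
  }
  base
}

.need <- function(outdir, file, stage) {
  path <- file.path(outdir, file)
  if (!file.exists(path))
    stop("missing artifact '", file, "'; run the '", stage, "' stage first")
  path
}

.log <- function(level, ...) {
  message(sprintf("[%s] %s %s", level,
                  format(Sys.time(), "%H:%M:%S"), paste0(...)))
}

#' Run the analysis pipeline
#'
#' Orchestrates all stages over file-based artifacts in `outdir`, so each
#' stage is independently runnable and resumable: `simulate` writes
#' synthetic metadata, OTU tables, taxonomy and truth; `soil` the group
#' summary table; `diversity` alpha/beta diversity, NMDS, PERMANOVA and
#' per-variable Mantel tests; `drivers` dominant taxa, random-forest
#' explanatory power, variation partitioning and the genus-environment
#' heatmap; `network` one co-occurrence network per plant group plus
#' per-sample subnetwork metrics and their soil correlations; `nci` the
#' pooled network complexity index, its group test and phylum
#' regressions; `plspm` the bootstrapped path model. A YAML manifest
#' records the configuration, seeds and per-stage row counts. One
#' top-level seed is split deterministically into per-stage substreams.
#'
#' @param stages character vector of stages, or `"all"`.
#' @param outdir output directory (created if needed).
#' @param config named list (or YAML file path) overriding
#'   defaults: thresholds (`rho_threshold`, `p_threshold`,
#'   `prevalence_min`, `dominance_threshold`), simulation sizes (`sim`),
#'   `scheme`, `n_boot`, `n_perm`, `rf_trees`, `rf_perm`.
#' @param seed top-level integer seed.
#' @param log_level `"info"` or `"quiet"`.
#' @return invisibly, the manifest list.
#' @export
runPipeline <- function(stages = "all", outdir, config = list(), seed = 1,
                        log_level = c("info", "quiet")) {
  log_level <- match.arg(log_level)
  say <- if (log_level == "info") .log else function(...) invisible()
  cfg <- .mergeConfig(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  if (identical(stages, "all")) stages <- .PIPE_STAGES
  bad <- setdiff(stages, .PIPE_STAGES)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  manifest_path <- file.path(outdir, "manifest.yaml")
  manifest <- if (file.exists(manifest_path)) yaml::read_yaml(manifest_path)
    else list()
  manifest$seed <- seed
  manifest$config <- .deClass(cfg)
  if (is.null(manifest$stages)) manifest$stages <- list()
  for (st in .PIPE_STAGES) {
    if (!st %in% stages) next
    say("info", "stage ", st)
    counts <- switch(st,
      simulate = .stageSimulate(outdir, cfg, .stageSeed(seed, "simulate")),
      soil = .stageSoil(outdir, cfg),
      diversity = .stageDiversity(outdir, cfg, .stageSeed(seed, "diversity")),
      drivers = .stageDrivers(outdir, cfg, .stageSeed(seed, "drivers")),
      network = .stageNetwork(outdir, cfg),
      nci = .stageNci(outdir, cfg),
      plspm = .stagePlspm(outdir, cfg, .stageSeed(seed, "plspm")))
    manifest$stages[[st]] <- counts
  }
  yaml::write_yaml(manifest, manifest_path)
  invisible(manifest)
}

.stageSimulate <- function(outdir, cfg, seed) {
  soil_par <- soilSimParams(n_per_group = cfg$n_per_group, seed = seed)
  meta <- simulateSoil(soil_par)
  net_par <- do.call(networkSimParams, c(cfg$sim, list(
    n_samples = nrow(meta), seed = seed + 1L)))
  sim <- simulateOtuTables(net_par)
  # tie OTU-table samples to the soil samples, in group order
  for (kd in c("bacteria", "fungi")) {
    cnt <- otuCounts(sim[[kd]])
    rownames(cnt) <- meta$sample_id
    sim[[kd]] <- otuTable(cnt, kd)
  }
  .writeTsv(meta, file.path(outdir, "metadata.tsv"))
  writeOtuTable(sim$bacteria, file.path(outdir, "otu_bacteria.tsv"))
  writeOtuTable(sim$fungi, file.path(outdir, "otu_fungi.tsv"))
  .writeTsv(sim$taxonomy, file.path(outdir, "taxonomy.tsv"))
  .writeTsv(sim$truth$pairs, file.path(outdir, "truth_pairs.tsv"))
  list(samples = nrow(meta),
       bacterial_otus = ncol(otuCounts(sim$bacteria)),
       fungal_otus = ncol(otuCounts(sim$fungi)),
       true_pairs = nrow(sim$truth$pairs))
}

.readStageInputs <- function(outdir, need_otus = TRUE) {
  meta <- readSampleMetadata(.need(outdir, "metadata.tsv", "simulate"))
  out <- list(meta = meta)
  if (need_otus) {
    out$bacteria <- readOtuTable(.need(outdir, "otu_bacteria.tsv", "simulate"),
                                 "bacteria")
    out$fungi <- readOtuTable(.need(outdir, "otu_fungi.tsv", "simulate"),
                              "fungi")
    out$taxonomy <- readTaxonomy(.need(outdir, "taxonomy.tsv", "simulate"))
  }
  out
}

.stageSoil <- function(outdir, cfg) {
  meta <- readSampleMetadata(.need(outdir, "metadata.tsv", "simulate"))
  res <- soilSummaryTable(meta)
  .writeTsv(res$table, file.path(outdir, "soil_summary.tsv"))
  av <- data.frame(
    variable = names(res$stats),
    F = vapply(res$stats, function(s) s$anova[["F"]], 0),
    p = vapply(res$stats, function(s) s$anova[["p"]], 0))
  .writeTsv(av, file.path(outdir, "soil_anova.tsv"))
  list(variables = nrow(res$table))
}

.stageDiversity <- function(outdir, cfg, seed) {
  inp <- .readStageInputs(outdir)
  meta <- inp$meta
  rows <- 0
  for (kd in c("bacteria", "fungi")) {
    tab <- inp[[kd]]
    alpha <- alphaDiversity(tab)
    .writeTsv(alpha, file.path(outdir, paste0("alpha_", kd, ".tsv")))
    bc <- brayCurtis(relativeAbundance(tab))
    .writeTsv(data.frame(sample_id = rownames(bc), bc, check.names = FALSE),
              file.path(outdir, paste0("bray_", kd, ".tsv")))
    ord <- nmdsOrdination(bc, seed = seed)
    perm <- groupPermanova(bc, meta$group[match(rownames(bc),
                                                meta$sample_id)],
                           n_perm = cfg$n_perm, seed = seed + 1L)
    .writeTsv(data.frame(sample_id = rownames(ord$points), ord$points,
                         check.names = FALSE),
              file.path(outdir, paste0("nmds_", kd, ".tsv")))
    .writeTsv(data.frame(kingdom = kd, stress = ord$stress,
                         converged = ord$converged, permanova_F = perm$F,
                         permanova_p = perm$p),
              file.path(outdir, paste0("nmds_stats_", kd, ".tsv")))
    env <- .numericEnv(meta)
    mt <- do.call(rbind, lapply(colnames(env), function(v) {
      m <- mantelTest(bc, as.matrix(dist(scale(env[, v]))),
                      n_perm = cfg$n_perm, seed = seed + 2L)
      data.frame(kingdom = kd, variable = v, r = m$r, p = m$p)
    }))
    .writeTsv(mt, file.path(outdir, paste0("mantel_", kd, ".tsv")))
    axe <- axisEnvCorrelation(ord, meta[match(rownames(ord$points),
                                              meta$sample_id), ])
    .writeTsv(axe, file.path(outdir, paste0("axis_env_", kd, ".tsv")))
    rows <- rows + nrow(alpha)
  }
  list(alpha_rows = rows)
}

.stageDrivers <- function(outdir, cfg, seed) {
  inp <- .readStageInputs(outdir)
  meta <- inp$meta
  env <- .numericEnv(meta)
  counts <- list()
  for (kd in c("bacteria", "fungi")) {
    rel <- relativeAbundance(inp[[kd]])
    phyla <- aggregateByRank(rel, inp$taxonomy, "phylum")
    genera <- aggregateByRank(rel, inp$taxonomy, "genus")
    dom_ph <- selectDominant(phyla, "phylum_1pct",
                             threshold = cfg$dominance_threshold)
    dom_gn <- selectDominant(genera, "top10_genus", top_n = cfg$top_n)
    .writeTsv(dom_ph$taxa,
              file.path(outdir, paste0("dominant_phyla_", kd, ".tsv")))
    .writeTsv(dom_gn$taxa,
              file.path(outdir, paste0("dominant_genera_", kd, ".tsv")))
    .writeTsv(data.frame(sample_id = sampleIDs(phyla), relValues(phyla),
                         check.names = FALSE),
              file.path(outdir, paste0("phyla_", kd, ".tsv")))
    rf <- do.call(rbind, lapply(dom_ph$taxa$taxon, function(tx) {
      r <- rfExplained(relValues(phyla)[, tx], env, n_trees = cfg$rf_trees,
                       n_perm = cfg$rf_perm, seed = seed)
      data.frame(kingdom = kd, taxon = tx,
                 percent_explained = r$percent_explained, p = r$p)
    }))
    .writeTsv(rf, file.path(outdir, paste0("rf_", kd, ".tsv")))
    sets <- soilVariableSets(meta)
    gmat <- relValues(genera)[, dom_gn$taxa$taxon, drop = FALSE]
    vp <- variationPartitioning(gmat, meta[, sets$physical],
                                meta[, sets$chemical], meta[, sets$biomass])
    .writeTsv(data.frame(kingdom = kd,
                         fraction = c(names(vp$fractions), "residual",
                                      "total"),
                         adj_r2 = c(vp$fractions, vp$residual,
                                    vp$total_adj_r2)),
              file.path(outdir, paste0("varpart_", kd, ".tsv")))
    hm <- taxaEnvSpearman(gmat, meta)
    .writeTsv(hm, file.path(outdir, paste0("heatmap_", kd, ".tsv")))
    counts[[kd]] <- nrow(dom_ph$taxa)
  }
  list(dominant_phyla = counts)
}

.stageNetwork <- function(outdir, cfg) {
  inp <- .readStageInputs(outdir)
  meta <- inp$meta
  groups <- unique(meta$group)
  metrics <- list()
  sub_rows <- list()
  for (g in groups) {
    ids <- meta$sample_id[meta$group == g]
    bsub <- otuTable(otuCounts(inp$bacteria)[ids, , drop = FALSE], "bacteria")
    fsub <- otuTable(otuCounts(inp$fungi)[ids, , drop = FALSE], "fungi")
    net <- spearmanEdges(bsub, fsub, taxonomy = inp$taxonomy,
                         prevalence_min = cfg$prevalence_min,
                         rho_threshold = cfg$rho_threshold,
                         p_threshold = cfg$p_threshold,
                         weight_scheme = cfg$weight_scheme)
    writeEdgeList(net, file.path(outdir, paste0("edges_", g, ".tsv")),
                  graphml_path = file.path(outdir,
                                           paste0("network_", g, ".graphml")))
    metrics[[g]] <- cbind(group = g, suppressWarnings(networkTopology(net)))
    sm <- subnetworkMetrics(net, list(bsub, fsub))
    sub_rows[[g]] <- cbind(group = g, sm)
  }
  .writeTsv(do.call(rbind, metrics), file.path(outdir,
                                               "network_metrics.tsv"))
  subs <- do.call(rbind, sub_rows)
  .writeTsv(subs, file.path(outdir, "subnetwork_metrics.tsv"))
  se <- subnetworkEnvCorrelation(subs, meta)
  .writeTsv(se, file.path(outdir, "subnet_env.tsv"))
  list(networks = length(groups), subnetwork_rows = nrow(subs))
}

.stageNci <- function(outdir, cfg) {
  subs <- read.delim(.need(outdir, "subnetwork_metrics.tsv", "network"),
                     stringsAsFactors = FALSE)
  meta <- readSampleMetadata(.need(outdir, "metadata.tsv", "simulate"))
  res <- networkComplexityIndex(subs)
  nci_df <- data.frame(
    sample_id = names(res@scores),
    group = meta$group[match(names(res@scores), meta$sample_id)],
    nci = unname(res@scores), stringsAsFactors = FALSE)
  .writeTsv(nci_df, file.path(outdir, "nci.tsv"))
  gt <- nciGroupTest(res, setNames(nci_df$group, nci_df$sample_id))
  .writeTsv(gt$summary, file.path(outdir, "nci_groups.tsv"))
  .writeTsv(data.frame(component = seq_along(res@var_pct),
                       var_pct = res@var_pct),
            file.path(outdir, "nci_variance.tsv"))
  # linear fits of dominant bacterial phyla against the pooled NCI
  fits <- list()
  for (kd in c("bacteria", "fungi")) {
    pf <- .need(outdir, paste0("phyla_", kd, ".tsv"), "drivers")
    ph <- read.delim(pf, check.names = FALSE, stringsAsFactors = FALSE)
    dom <- read.delim(.need(outdir, paste0("dominant_phyla_", kd, ".tsv"),
                            "drivers"), stringsAsFactors = FALSE)
    rows <- match(nci_df$sample_id, ph$sample_id)
    for (tx in dom$taxon) {
      f <- phylumVsNci(ph[[tx]][rows], nci_df$nci)
      fits[[paste(kd, tx)]] <- data.frame(
        kingdom = kd, taxon = tx, slope = f$slope, r_squared = f$r_squared,
        p = f$p)
    }
  }
  .writeTsv(do.call(rbind, fits), file.path(outdir, "nci_fits.tsv"))
  list(nci_rows = nrow(nci_df))
}

.stagePlspm <- function(outdir, cfg, seed) {
  meta <- readSampleMetadata(.need(outdir, "metadata.tsv", "simulate"))
  nci <- read.delim(.need(outdir, "nci.tsv", "nci"), stringsAsFactors = FALSE)
  df <- meta
  for (kd in c("bacteria", "fungi")) {
    a <- read.delim(.need(outdir, paste0("alpha_", kd, ".tsv"), "diversity"),
                    stringsAsFactors = FALSE)
    rows <- match(df$sample_id, a$sample_id)
    df[[paste0("shannon_", kd)]] <- a$shannon[rows]
    df[[paste0("ace_", kd)]] <- a$ace[rows]
  }
  ph <- read.delim(.need(outdir, "phyla_bacteria.tsv", "drivers"),
                   check.names = FALSE, stringsAsFactors = FALSE)
  dom <- read.delim(.need(outdir, "dominant_phyla_bacteria.tsv", "drivers"),
                    stringsAsFactors = FALSE)
  dom_cols <- head(dom$taxon, 3)
  rows <- match(df$sample_id, ph$sample_id)
  for (tx in dom_cols) df[[tx]] <- ph[[tx]][rows]
  df$NCI <- nci$nci[match(df$sample_id, nci$sample_id)]
  spec <- defaultPlspmSpec(dominant_phyla = dom_cols, scheme = cfg$scheme)
  fit <- fitPlspm(df, spec)
  boot <- bootstrapPaths(df, spec, n_boot = max(cfg$n_boot, 100),
                         seed = seed)
  boot$stars <- cut(boot$p, c(-Inf, 0.001, 0.01, 0.05, Inf),
                    labels = c("***", "**", "*", ""))
  .writeTsv(boot, file.path(outdir, "plspm_paths.tsv"))
  .writeTsv(data.frame(block = names(fit@r2), r2 = unname(fit@r2)),
            file.path(outdir, "plspm_r2.tsv"))
  list(paths = nrow(boot))
}
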