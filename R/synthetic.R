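#' Parameters for the soil simulator
#'
#' Defaults are the reference field-study group summaries bundled with the
#' package ([soilReferenceTable()]): per-group mean and standard error of
#' each soil variable for the three halophyte rhizospheres, n = 6. The
#' group standard deviation is taken as SE * sqrt(6), reproducing the
#' dispersion implied by the mean +/- SE reporting convention.
#'
#' @param table long data.frame (`variable`, `group`, `mean`, `se`).
#' @param n_per_group samples per group (>= 2).
#' @param seed RNG seed.
#' @param reporting_n the n behind the SEs (SD = se * sqrt(reporting_n)).
#' @return a validated `SoilSimParams` list.
#' @export
soilSimParams <- function(table = soilReferenceTable(), n_per_group = 6,
                          seed = 1, reporting_n = 6) {
  stopifnot(all(c("variable", "group", "mean", "se") %in% names(table)),
            all(table$se >= 0), n_per_group >= 2)
  structure(list(table = table, n_per_group = n_per_group, seed = seed,
                 reporting_n = reporting_n), class = "SoilSimParams")
}

# draw from Normal(mean, sd) truncated at 0 by resampling (not clipping),
# keeping the distribution smooth near the boundary
.rnormPos <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  out <- rnorm(n, mean, sd)
  for (i in 1:100) {
    neg <- out < 0
    if (!any(neg)) return(out)
    out[neg] <- rnorm(sum(neg), mean, sd)
  }
  stop("truncation failed: mean ", mean, " with sd ", sd,
       " is almost entirely negative")
}

#' Simulate soil metadata with consistent fumigation pairs
#'
#' Per group and variable, draws Normal(mean, SE * sqrt(n)) truncated at
#' zero by resampling. Raw chloroform-fumigation extract pairs (DOC, TN,
#' TP, fumigated and non-fumigated) are constructed so that applying the
#' biomass formulas ([microbialBiomass()]) recovers the drawn MBC/MBN/MBP
#' exactly: the non-fumigated extract is drawn from a baseline
#' distribution and the fumigated value set to baseline + k * biomass.
#'
#' @param params a [soilSimParams()] list.
#' @return metadata data.frame (`sample_id`, `group`, soil variables,
#'   `*_fum`/`*_nonfum` pairs) with the generating params in
#'   `attr(, "params")`.
#' @export
simulateSoil <- function(params = soilSimParams()) {
  stopifnot(inherits(params, "SoilSimParams"))
  set.seed(params$seed)
  tab <- params$table
  groups <- unique(tab$group)
  vars <- unique(tab$variable)
  n <- params$n_per_group
  rows <- lapply(groups, function(g) {
    df <- data.frame(sample_id = paste0(g, seq_len(n)), group = g,
                     stringsAsFactors = FALSE)
    for (v in vars) {
      par <- tab[tab$variable == v & tab$group == g, ]
      df[[v]] <- .rnormPos(n, par$mean, par$se * sqrt(params$reporting_n))
    }
    df
  })
  meta <- do.call(rbind, rows)
  k <- biomassCoefficients()
  base <- list(DOC = c(50, 5), TNex = c(10, 1), TPex = c(5, 0.5))
  if (all(c("MBC", "MBN", "MBP") %in% vars)) {
    meta$DOC_nonfum <- .rnormPos(nrow(meta), base$DOC[1], base$DOC[2])
    meta$DOC_fum <- meta$DOC_nonfum + k[["C"]] * meta$MBC
    meta$TN_nonfum <- .rnormPos(nrow(meta), base$TNex[1], base$TNex[2])
    meta$TN_fum <- meta$TN_nonfum + k[["N"]] * meta$MBN
    meta$TP_nonfum <- .rnormPos(nrow(meta), base$TPex[1], base$TPex[2])
    meta$TP_fum <- meta$TP_nonfum + k[["P"]] * meta$MBP
  }
  attr(meta, "params") <- params
  meta
}

#' Parameters for the planted-association OTU simulator
#'
#' Defines compositional count tables with known positive/negative
#' association blocks. A block is a set of OTUs sharing one latent factor;
#' same-sign members co-vary positively, opposite-sign members negatively,
#' with coupling set by `strength` in \[0, 1\].
#'
#' @param n_bacterial_otus,n_fungal_otus OTUs per kingdom (ids `B001`...,
#'   `F001`...).
#' @param n_samples number of samples (>= 4).
#' @param blocks list of `list(members, signs, strength)`; members must be
#'   disjoint across blocks. `NULL` gives four default mixed
#'   bacterial-fungal blocks at strength 0.95 with some negative members.
#' @param noise_sd latent log-abundance noise on top of the block signal.
#' @param baseline_sd spread of per-OTU baseline log-abundances. The
#'   default (2.5) makes low-baseline OTUs drop in and out of individual
#'   samples, emulating the sparsity of real amplicon tables — without it
#'   every OTU is present everywhere and per-sample subnetworks carry no
#'   information.
#' @param lib_meanlog,lib_sdlog log-normal library-size distribution
#'   (default median 3e4 reads).
#' @param seed RNG seed.
#' @return a validated `NetworkSimParams` list.
#' @export
networkSimParams <- function(n_bacterial_otus = 120, n_fungal_otus = 60,
                             n_samples = 18, blocks = NULL, noise_sd = 0.2,
                             baseline_sd = 2.5, lib_meanlog = log(3e4),
                             lib_sdlog = 0.2, seed = 1) {
  ids <- c(sprintf("B%03d", seq_len(n_bacterial_otus)),
           sprintf("F%03d", seq_len(n_fungal_otus)))
  if (is.null(blocks)) {
    blocks <- lapply(0:3, function(b) {
      members <- c(sprintf("B%03d", b * 4 + 1:4),
                   sprintf("F%03d", b * 2 + 1:2))
      list(members = members, signs = c(1, 1, 1, -1, 1, -1), strength = 0.95)
    })
  }
  all_members <- unlist(lapply(blocks, `[[`, "members"))
  if (anyDuplicated(all_members)) stop("blocks must be disjoint")
  if (!all(all_members %in% ids)) stop("block references unknown OTU: ",
    paste(setdiff(all_members, ids), collapse = ", "))
  for (b in blocks) {
    stopifnot(length(b$signs) == length(b$members),
              all(b$signs %in% c(-1, 1)),
              b$strength >= 0, b$strength <= 1)
  }
  if (n_samples < 4) stop("need n_samples >= 4")
  structure(list(n_bacterial_otus = n_bacterial_otus,
                 n_fungal_otus = n_fungal_otus, n_samples = n_samples,
                 blocks = blocks, noise_sd = noise_sd,
                 baseline_sd = baseline_sd, lib_meanlog = lib_meanlog,
                 lib_sdlog = lib_sdlog, seed = seed),
            class = "NetworkSimParams")
}

.BACT_PHYLA <- c("Proteobacteria", "Firmicutes", "Actinobacteriota",
                 "Gemmatimonadota", "Desulfobacterota", "Acidobacteriota",
                 "Bacteroidota", "Chloroflexi")
.FUNG_PHYLA <- c("Ascomycota", "Mucoromycota", "Basidiomycota",
                 "Mortierellomycota")

#' Simulate bacterial and fungal OTU tables with planted associations
#'
#' Latent log-abundance of OTU k in sample s is
#' baseline_k + strength * sign_k * factor_(block, s) + noise, with
#' standard-normal block factors. Counts are drawn multinomially per sample
#' and kingdom from the softmax of the latent row, with log-normal library
#' sizes, emulating compositional amplicon data. The truth table lists
#' exactly the within-block OTU pairs with the sign of their planted
#' association (product of member signs).
#'
#' @param params a [networkSimParams()] list.
#' @return list: `bacteria` and `fungi` ([OtuTable-class]), `taxonomy`
#'   (data.frame), `truth` (list with `pairs` data.frame and `params`),
#'   `latent` (samples x OTUs latent log-abundance matrix).
#' @export
simulateOtuTables <- function(params = networkSimParams()) {
  stopifnot(inherits(params, "NetworkSimParams"))
  set.seed(params$seed)
  nb <- params$n_bacterial_otus; nf <- params$n_fungal_otus
  ns <- params$n_samples
  ids <- c(sprintf("B%03d", seq_len(nb)), sprintf("F%03d", seq_len(nf)))
  samples <- sprintf("S%02d", seq_len(ns))
  baseline <- rnorm(length(ids), 0, params$baseline_sd)
  latent <- matrix(rnorm(ns * length(ids), 0, params$noise_sd), ns,
                   dimnames = list(samples, ids))
  latent <- sweep(latent, 2, baseline, `+`)
  pairs <- list()
  for (bi in seq_along(params$blocks)) {
    b <- params$blocks[[bi]]
    f <- rnorm(ns)
    for (j in seq_along(b$members))
      latent[, b$members[j]] <- latent[, b$members[j]] +
        b$strength * b$signs[j] * f
    pr <- t(combn(seq_along(b$members), 2))
    pairs[[bi]] <- data.frame(
      otu1 = b$members[pr[, 1]], otu2 = b$members[pr[, 2]],
      sign = b$signs[pr[, 1]] * b$signs[pr[, 2]], block = bi,
      stringsAsFactors = FALSE)
  }
  truth_pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(otu1 = character(), otu2 = character(), sign = numeric(),
               block = integer())
  drawCounts <- function(cols, kd) {
    lib <- round(rlnorm(ns, params$lib_meanlog, params$lib_sdlog))
    cnt <- t(vapply(seq_len(ns), function(s) {
      lam <- exp(latent[s, cols])
      rmultinom(1, size = lib[s], prob = lam / sum(lam))[, 1]
    }, numeric(length(cols))))
    dimnames(cnt) <- list(samples, cols)
    otuTable(cnt, kd)
  }
  bact <- drawCounts(ids[seq_len(nb)], "bacteria")
  fung <- drawCounts(ids[nb + seq_len(nf)], "fungi")
  taxonomy <- data.frame(
    otu_id = ids,
    kingdom = c(rep("bacteria", nb), rep("fungi", nf)),
    phylum = c(rep_len(.BACT_PHYLA, nb), rep_len(.FUNG_PHYLA, nf)),
    class = "unclassified", order = "unclassified", family = "unclassified",
    genus = c(rep_len(sprintf("bgen_%02d", 1:12), nb),
              rep_len(sprintf("fgen_%02d", 1:12), nf)),
    stringsAsFactors = FALSE)
  list(bacteria = bact, fungi = fung, taxonomy = taxonomy,
       truth = list(pairs = truth_pairs, params = params), latent = latent)
}

#' Parameters for the latent-path simulator
#'
#' @param blocks named list; each element a numeric vector of indicator
#'   loadings in (0, 1\].
#' @param path numeric blocks x blocks matrix, strictly lower triangular in
#'   block order; `path[j, i]` is the structural coefficient of block i on
#'   block j. A non-lower-triangular (cyclic) matrix is rejected.
#' @param indicator_noise_sd noise added to `loading * latent`; `NULL`
#'   uses sqrt(1 - loading^2) so indicators have unit variance.
#' @param n sample size.
#' @param seed RNG seed.
#' @return a validated `PlsSimParams` list.
#' @export
plsSimParams <- function(blocks, path, indicator_noise_sd = NULL, n = 200,
                         seed = 1) {
  B <- length(blocks)
  stopifnot(!is.null(names(blocks)), is.matrix(path),
            nrow(path) == B, ncol(path) == B)
  if (any(path[upper.tri(path, diag = TRUE)] != 0))
    stop("path matrix must be strictly lower triangular (acyclic)")
  lam <- unlist(blocks)
  if (any(lam <= 0 | lam > 1)) stop("loadings must lie in (0, 1]")
  structure(list(blocks = blocks, path = path,
                 indicator_noise_sd = indicator_noise_sd, n = n, seed = seed),
            class = "PlsSimParams")
}

#' Simulate indicator data from a latent path model
#'
#' Latent scores are generated recursively along the (acyclic) path
#' equations with Gaussian disturbances scaled to keep each latent near
#' unit variance; indicators are loading * latent + Gaussian noise.
#'
#' @param params a [plsSimParams()] list.
#' @return list: `data` (data.frame of indicators, named `block_i`),
#'   `truth` (list with `latents`, `path`, `blocks`).
#' @export
simulatePlspmData <- function(params) {
  stopifnot(inherits(params, "PlsSimParams"))
  set.seed(params$seed)
  B <- length(params$blocks)
  n <- params$n
  eta <- matrix(0, n, B, dimnames = list(NULL, names(params$blocks)))
  for (j in seq_len(B)) {
    pred <- as.vector(eta %*% params$path[j, ])
    vres <- 1 - var(pred)
    if (vres <= 0)
      stop("path coefficients into block '", names(params$blocks)[j],
           "' imply latent variance above 1")
    eta[, j] <- pred + rnorm(n, 0, sqrt(vres))
  }
  cols <- list()
  for (j in seq_len(B)) {
    lam <- params$blocks[[j]]
    for (i in seq_along(lam)) {
      nm <- paste0(names(params$blocks)[j], "_", i)
      nsd <- if (is.null(params$indicator_noise_sd))
        sqrt(max(1 - lam[i]^2, 0)) else params$indicator_noise_sd
      cols[[nm]] <- lam[i] * eta[, j] + rnorm(n, 0, nsd)
    }
  }
  list(data = as.data.frame(cols),
       truth = list(latents = eta, path = params$path,
                    blocks = params$blocks))
}

#' Write a simulation manifest
#'
#' Records every parameter and the seed of a simulation (or pipeline run)
#' as YAML so outputs are reproducible from the manifest alone.
#'
#' @param path output YAML file.
#' @param ... named entries (parameter lists, seeds, row counts).
#' @return `path`, invisibly.
#' @export
writeManifest <- function(path, ...) {
  entries <- list(...)
  entries$package_version <- as.character(packageVersion("rhizonet"))
  yaml::write_yaml(.deClass(entries), path)
  invisible(path)
}

.deClass <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, .deClass)
  } else if (is.matrix(x)) apply(x, 1, as.vector, simplify = FALSE)
  else x
}
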