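#' Chloroform fumigation-extraction efficiency coefficients
#'
#' kC = 0.45, kN = 0.54, kP = 0.40: the fractions of microbial biomass C, N
#' and P rendered extractable by fumigation, used as divisors in the
#' biomass formulas.
#' @export
biomassCoefficients <- function() c(C = 0.45, N = 0.54, P = 0.40)

#' Microbial biomass from fumigation-extraction pairs
#'
#' MB = (fumigated - non-fumigated) / k, with k the element-specific
#' efficiency coefficient (0.45 for C, 0.54 for N, 0.40 for P). A negative
#' difference (non-fumigated extract exceeding the fumigated one) is
#' returned as-is but triggers a warning: it is physically questionable but
#' must stay representable.
#'
#' @param fumigated,nonfumigated extract concentrations, mg/kg; vectors are
#'   recycled pairwise.
#' @param element `"C"`, `"N"` or `"P"`.
#' @return microbial biomass, mg/kg.
#' @examples
#' microbialBiomass(100, 55, "C")  # 45 / 0.45 = 100
#' @export
microbialBiomass <- function(fumigated, nonfumigated, element = c("C", "N", "P")) {
  element <- match.arg(element)
  if (!all(is.finite(fumigated)) || !all(is.finite(nonfumigated)))
    stop("inputs must be finite")
  out <- (fumigated - nonfumigated) / biomassCoefficients()[[element]]
  if (any(out < 0))
    warning(sum(out < 0), " negative biomass value(s); ",
            "non-fumigated extract exceeded the fumigated one")
  out
}

#' Excess of one group mean over another
#'
#' `mode = "times"` gives a/b - 1 ("x times higher"); `mode = "percent"`
#' gives (a/b - 1) * 100 ("x percent higher").
#'
#' @param a,b group means; `b` must be positive.
#' @param mode `"times"` or `"percent"`.
#' @return the excess, unitless or percent.
#' @examples
#' ratioExcess(5728.9, 1384.43, "times")  # ~3.14
#' @export
ratioExcess <- function(a, b, mode = c("times", "percent")) {
  mode <- match.arg(mode)
  if (any(b <= 0)) stop("reference mean must be positive")
  ex <- a / b - 1
  if (mode == "percent") ex * 100 else ex
}

#' One-way ANOVA with Tukey HSD and a compact letter display
#'
#' Groups are compared by one-way ANOVA followed by Tukey's HSD; groups not
#' separated at `alpha` share a letter. Letters are assigned by the
#' insert-absorb algorithm and labelled `a`, `b`, ... in order of
#' descending group mean, so the largest mean always carries `a`.
#'
#' @param values numeric vector of observations.
#' @param group group label per observation (>= 2 groups, >= 2 values each).
#' @param alpha significance level for the letter display.
#' @return list with `summary` (data.frame: group, n, mean, se, letters,
#'   ordered by descending mean), `anova` (F, p), `tukey` (pairwise
#'   data.frame) and `alpha`.
#' @export
anovaLetters <- function(values, group, alpha = 0.05) {
  group <- as.character(group)
  stopifnot(length(values) == length(group))
  tab <- table(group)
  if (length(tab) < 2 || any(tab < 2))
    stop("need >= 2 groups with >= 2 values each")
  if (all(tapply(values, group, stats::sd) == 0))
    stop("zero within-group variance in every group")
  gf <- factor(group)
  fit <- aov(values ~ gf)
  av <- summary(fit)[[1]]
  tk <- TukeyHSD(fit, "gf")$gf
  pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  tukey <- data.frame(group1 = pairs[, 1], group2 = pairs[, 2],
                      diff = tk[, "diff"], p = tk[, "p adj"],
                      row.names = NULL, stringsAsFactors = FALSE)
  means <- tapply(values, group, mean)
  ses <- tapply(values, group, function(v) stats::sd(v) / sqrt(length(v)))
  ord <- names(sort(means, decreasing = TRUE))
  letters_by_group <- .insertAbsorb(ord, tukey, alpha)
  summ <- data.frame(group = ord, n = as.integer(tab[ord]),
                     mean = as.numeric(means[ord]), se = as.numeric(ses[ord]),
                     letters = letters_by_group[ord],
                     row.names = NULL, stringsAsFactors = FALSE)
  list(summary = summ,
       anova = c(F = av[1, "F value"], p = av[1, "Pr(>F)"]),
       tukey = tukey, alpha = alpha)
}

# Insert-absorb compact letter display. `ord` is the group order
# (descending mean); `tukey` supplies pairwise p-values.
.insertAbsorb <- function(ord, tukey, alpha) {
  sets <- list(ord)
  sig <- tukey[tukey$p <= alpha, , drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    g1 <- sig$group1[i]; g2 <- sig$group2[i]
    new_sets <- list()
    for (s in sets) {
      if (all(c(g1, g2) %in% s)) {
        new_sets <- c(new_sets, list(setdiff(s, g1)), list(setdiff(s, g2)))
      } else new_sets <- c(new_sets, list(s))
    }
    # absorb sets contained in another
    keep <- rep(TRUE, length(new_sets))
    for (a in seq_along(new_sets)) for (b in seq_along(new_sets)) {
      if (a != b && keep[a] && keep[b] &&
          all(new_sets[[a]] %in% new_sets[[b]]) &&
          !(length(new_sets[[a]]) == length(new_sets[[b]]) && a > b))
        keep[a] <- FALSE
    }
    sets <- unique(new_sets[keep])
  }
  # order letter sets by the rank of their best (largest-mean) member
  best <- vapply(sets, function(s) min(match(s, ord)), 1)
  sets <- sets[order(best)]
  out <- setNames(rep("", length(ord)), ord)
  for (i in seq_along(sets))
    for (g in sets[[i]]) out[g] <- paste0(out[g], letters[i])
  out
}

#' Group summary table for all soil variables
#'
#' Runs [anovaLetters()] per numeric metadata column and formats a
#' mean +/- SE table with significance letters, one row per variable and
#' one column per group.
#'
#' @param meta metadata data.frame with `sample_id`, `group` and numeric
#'   columns.
#' @param variables columns to summarise; default all numeric columns
#'   except fumigation raw pairs.
#' @param alpha letter-display significance level.
#' @param digits decimals in the formatted strings.
#' @return list with `table` (formatted data.frame) and `stats` (named list
#'   of [anovaLetters()] results).
#' @export
soilSummaryTable <- function(meta, variables = NULL, alpha = 0.05, digits = 2) {
  if (is.null(variables)) {
    variables <- setdiff(names(meta), c("sample_id", "group"))
    variables <- variables[vapply(meta[variables], is.numeric, TRUE)]
    variables <- grep("_fum$|_nonfum$", variables, invert = TRUE, value = TRUE)
  }
  groups <- sort(unique(meta$group))
  stats_list <- list()
  rows <- list()
  for (v in variables) {
    res <- anovaLetters(meta[[v]], meta$group, alpha = alpha)
    stats_list[[v]] <- res
    s <- res$summary
    cells <- setNames(sprintf(paste0("%.", digits, "f ± %.", digits, "f %s"),
                              s$mean, s$se, s$letters), s$group)
    rows[[v]] <- c(variable = v, cells[groups])
  }
  tab <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE,
                       row.names = NULL)
  names(tab) <- c("variable", groups)
  list(table = tab, stats = stats_list)
}
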