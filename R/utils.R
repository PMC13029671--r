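#' All permutations of 1..n
#'
#' Exhaustive enumeration used for exact permutation p-values at the
#' study's small group sizes (n = 6 gives 720 arrangements).
#'
#' @param n integer, kept small (n! rows are materialised; n <= 8 enforced).
#' @return an n! x n integer matrix, one permutation per row.
#' @export
allPermutations <- function(n) {
  stopifnot(n >= 1, n <= 8)
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- allPermutations(n - 1L)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  r <- 0L
  for (k in seq_len(n)) {
    rows <- nrow(sub)
    block <- cbind(rep(k, rows), sub + (sub >= k))
    out[r + seq_len(rows), ] <- block
    r <- r + rows
  }
  out
}

# tie-corrected Spearman rho = Pearson correlation of mid-ranks
.spearmanRho <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  if (sd(rx) == 0 || sd(ry) == 0) return(NA_real_)
  cor(rx, ry)
}

# Exact permutation p for Spearman rho: the fraction of the n!
# rearrangements of y whose |rho| (or signed rho) reaches the observed
# one. The observed arrangement is included, so p >= 1/n!.
.spearmanExactP <- function(x, y, alternative = c("two.sided", "greater"),
                            perms = NULL) {
  alternative <- match.arg(alternative)
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  obs <- cor(rx, ry)
  if (is.null(perms)) perms <- allPermutations(n)
  cx <- (rx - mean(rx)) / sd(rx)
  cy <- (ry - mean(ry)) / sd(ry)
  # rho under every rearrangement of y, in one matrix product
  rho_all <- as.vector(matrix(cy[perms], nrow(perms), n) %*% cx) / (n - 1)
  eps <- 1e-12
  if (alternative == "two.sided") mean(abs(rho_all) >= abs(obs) - eps)
  else mean(rho_all >= obs - eps)
}

# t-approximation with tie-corrected rho (used when n > exact_max)
.spearmanApproxP <- function(rho, n, alternative = c("two.sided", "greater")) {
  alternative <- match.arg(alternative)
  if (abs(rho) >= 1) return(0)
  tstat <- rho * sqrt((n - 2) / (1 - rho^2))
  if (alternative == "two.sided") 2 * pt(-abs(tstat), df = n - 2)
  else pt(tstat, df = n - 2, lower.tail = FALSE)
}

#' Spearman correlation test with exact small-sample p-values
#'
#' Tie-corrected Spearman rho. For n <= `exact_max` the p-value is computed
#' by full enumeration of all n! permutations (the t-approximation is
#' unreliable at the n = 6 group sizes this package targets); above that a
#' t-approximation on n - 2 degrees of freedom is used.
#'
#' @param x,y numeric vectors of equal length.
#' @param alternative `"two.sided"` (default) or `"greater"`.
#' @param exact_max largest n for which the exact route is taken.
#' @return list with `rho`, `p`, `n` and `method` (`"exact"` or
#'   `"t-approximation"`); `rho` and `p` are NA when either vector is
#'   constant.
#' @export
spearmanTest <- function(x, y, alternative = c("two.sided", "greater"),
                         exact_max = 7) {
  alternative <- match.arg(alternative)
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3 || sd(rank(x)) == 0 || sd(rank(y)) == 0)
    return(list(rho = NA_real_, p = NA_real_, n = n, method = "undefined"))
  rho <- .spearmanRho(x, y)
  if (n <= exact_max)
    list(rho = rho, p = .spearmanExactP(x, y, alternative), n = n,
         method = "exact")
  else
    list(rho = rho, p = .spearmanApproxP(rho, n, alternative), n = n,
         method = "t-approximation")
}

#' Spearman rho/p matrices between two sets of variables
#'
#' Applies [spearmanTest()] to every (column of `A`, column of `B`) pair;
#' constant columns yield NA entries.
#'
#' @param A,B numeric matrices or data.frames with aligned rows (samples).
#' @param exact_max passed to [spearmanTest()].
#' @param adjust optional p-adjustment method (e.g. `"BH"`); `"none"` keeps
#'   raw p-values, matching significance stars computed on raw p.
#' @return list of matrices `rho` and `p` (rows = columns of A).
#' @export
spearmanMatrix <- function(A, B, exact_max = 7, adjust = "none") {
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(nrow(A) == nrow(B))
  rho <- matrix(NA_real_, ncol(A), ncol(B),
                dimnames = list(colnames(A), colnames(B)))
  p <- rho
  for (i in seq_len(ncol(A))) for (j in seq_len(ncol(B))) {
    st <- spearmanTest(A[, i], B[, j], exact_max = exact_max)
    rho[i, j] <- st$rho; p[i, j] <- st$p
  }
  if (adjust != "none") {
    p[] <- p.adjust(as.vector(p), method = adjust)
  }
  list(rho = rho, p = p)
}

# deterministic per-stage substream of a single top-level seed;
# kept below 2^31 - 1
.stageSeed <- function(seed, stage) {
  offsets <- c(simulate = 11L, soil = 23L, diversity = 37L, drivers = 53L,
               network = 71L, nci = 89L, plspm = 107L, acceptance = 131L)
  off <- offsets[[stage]]
  as.integer((as.numeric(seed) * 1000003 + off * 7919) %% 2147483647)
}
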