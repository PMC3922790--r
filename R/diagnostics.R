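#' Split-chain Gelman-Rubin diagnostic and effective sample size
#'
#' Computes the split-chain potential scale reduction factor (split R-hat)
#' per coefficient: each chain is cut in half, the halves are treated as
#' separate chains, and R-hat is `sqrt(((n-1)/n * W + B/n) / W)` where `W` is
#' the mean within-chain variance and `B` the between-chain variance of the
#' half-chain means. Splitting makes the diagnostic sensitive to trends
#' within a chain, not only to disagreement between chains. Effective sample
#' size uses the multi-chain autocorrelation estimate
#' `m * n / (1 + 2 * sum(rho_t))` with correlations from the variogram and
#' the sum truncated at the first non-positive paired sum (Geyer's initial
#' positive sequence).
#'
#' Chains that are exact copies of one (non-constant) sequence have `B = 0`
#' and R-hat `sqrt((n-1)/n)`, reported as 1 to numerical rounding. Zero
#' within-chain variance (constant chains) makes the ratio undefined; R-hat
#' is then reported as `Inf` with a note.
#'
#' @param draws Either an iteration x chain x coefficient array, an
#'   iteration x chain matrix (single coefficient), or a list of per-chain
#'   matrices (iteration x coefficient).
#' @return A data frame with columns `coefficient`, `rhat`, `ess`, `note`.
#' @export
gelman_rubin <- function(draws) {
  if (is.list(draws) && !is.array(draws)) {
    stopifnot(length(draws) >= 2)
    dims <- vapply(draws, dim, integer(2))
    stopifnot(length(unique(dims[1, ])) == 1, length(unique(dims[2, ])) == 1)
    arr <- array(NA_real_, c(dims[1, 1], length(draws), dims[2, 1]),
                 dimnames = list(NULL, NULL, colnames(draws[[1]])))
    for (k in seq_along(draws)) arr[, k, ] <- as.matrix(draws[[k]])
    draws <- arr
  }
  if (length(dim(draws)) == 2) {
    draws <- array(draws, c(dim(draws), 1))
  }
  stopifnot(length(dim(draws)) == 3, dim(draws)[2] >= 2, dim(draws)[1] >= 10)
  coefs <- dimnames(draws)[[3]]
  if (is.null(coefs)) coefs <- paste0("coef", seq_len(dim(draws)[3]))
  out <- data.frame(coefficient = coefs, rhat = NA_real_, ess = NA_real_,
                    note = "", stringsAsFactors = FALSE)
  for (p in seq_len(dim(draws)[3])) {
    half <- split_chains(draws[, , p, drop = TRUE])
    r <- rhat_from_chains(half)
    out$rhat[p] <- r$rhat
    out$note[p] <- r$note
    out$ess[p] <- if (is.finite(r$rhat)) ess_from_chains(half, r$var_plus)
                  else NA_real_
  }
  out
}

# Cut each column (chain) in half -> matrix with twice the chains.
split_chains <- function(mat) {
  n <- nrow(mat) %/% 2L
  cbind(mat[seq_len(n), , drop = FALSE],
        mat[n + seq_len(n), , drop = FALSE])
}

rhat_from_chains <- function(chains) {
  n <- nrow(chains); m <- ncol(chains)
  means <- colMeans(chains)
  vars <- apply(chains, 2, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W <= .Machine$double.eps * max(1, abs(mean(means)))^2) {
    if (B <= .Machine$double.eps) {
      # constant chains at a common value: nothing to diagnose
      return(list(rhat = 1, var_plus = 0,
                  note = "constant chains (zero within- and between-chain variance)"))
    }
    return(list(rhat = Inf, var_plus = Inf,
                note = "zero within-chain variance: chains are stuck"))
  }
  var_plus <- (n - 1) / n * W + B / n
  list(rhat = sqrt(var_plus / W), var_plus = var_plus, note = "")
}

ess_from_chains <- function(chains, var_plus) {
  n <- nrow(chains); m <- ncol(chains)
  if (var_plus <= 0) return(n * m)
  max_lag <- min(n - 1L, 1000L)
  # variogram-based multi-chain autocorrelation
  rho <- numeric(max_lag)
  for (t in seq_len(max_lag)) {
    vt <- mean(apply(chains, 2, function(ch) {
      mean((ch[(t + 1):n] - ch[seq_len(n - t)])^2)
    }))
    rho[t] <- 1 - vt / (2 * var_plus)
  }
  # Geyer initial positive sequence over paired sums
  tau <- 1
  t <- 1
  while (t + 1 <= max_lag) {
    pair <- rho[t] + rho[t + 1]
    if (pair <= 0) break
    tau <- tau + 2 * pair
    t <- t + 2
  }
  max(m * n / tau, 1)
}
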