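# SparCC: correlation inference for compositional count data via log-ratio
# variances under a sparsity assumption on the basis correlations.
#
# One estimation pass: draw fractions from a per-sample Dirichlet posterior
# (counts + 1), form the log-ratio variance matrix
# t_ij = Var(log x_i / log x_j) = c_ii + c_jj - 2 c_ij from the covariance c
# of log fractions, solve the approximate linear system for the basis
# variances omega (assuming off-diagonal correlations sum to ~0), convert to
# correlations, then iteratively exclude the strongest correlated pair above
# the exclusion threshold and re-solve.

sparcc_basis <- function(tmat, excluded, var_fallback) {
  d <- nrow(tmat)
  b <- rowSums(tmat)
  # the system matrix is (d-2)I + J minus one (e_i+e_j)(e_i+e_j)' per
  # excluded pair; invert the base analytically and patch the low-rank
  # correction with the Woodbury identity (a dense solve per exclusion
  # round is the runtime bottleneck at hundreds of ASVs)
  a <- d - 2
  m0_inv <- function(v) v / a - sum(v) / (a * (2 * d - 2))
  k <- nrow(excluded)
  if (k) {
    for (l in seq_len(k)) {
      i <- excluded[l, 1]; j <- excluded[l, 2]
      b[i] <- b[i] - tmat[i, j]
      b[j] <- b[j] - tmat[i, j]
    }
    u <- matrix(0, d, k)
    u[cbind(excluded[, 1], seq_len(k))] <- 1
    u[cbind(excluded[, 2], seq_len(k))] <- 1
    m0u <- apply(u, 2, m0_inv)
    core <- solve(diag(k) - crossprod(u, m0u),
                  crossprod(m0u, b))
    omega <- m0_inv(b) + m0u %*% core
    omega <- omega[, 1]
  } else {
    omega <- m0_inv(b)
  }
  # a non-positive solution means the sparsity system is degenerate for
  # that component; fall back to its raw log-fraction variance instead of
  # clamping (a near-zero variance would blow the correlation up to +-1)
  bad <- !is.finite(omega) | omega <= 0
  omega[bad] <- var_fallback[bad]
  so <- sqrt(omega)
  r <- (outer(omega, omega, "+") - tmat) / (2 * outer(so, so))
  r[r > 1] <- 1
  r[r < -1] <- -1
  diag(r) <- 1
  r
}

sparcc_one_draw <- function(counts, blocks, n_exclude_iter, exclude_threshold) {
  # kingdom-blocked Dirichlet posterior draw of fractions, then log-covariance
  d <- ncol(counts)
  frac <- matrix(0, nrow(counts), d)
  for (b in unique(blocks)) {
    cols <- which(blocks == b)
    g <- matrix(stats::rgamma(nrow(counts) * length(cols),
                              shape = t(counts[, cols, drop = FALSE]) + 1),
                nrow = length(cols))
    frac[, cols] <- t(g) / colSums(g)    # per-sample Dirichlet normalization
  }
  lf <- log(frac)
  cv <- stats::cov(lf)
  tmat <- outer(diag(cv), diag(cv), "+") - 2 * cv
  var_fallback <- pmax(diag(cv), 1e-12)
  d <- nrow(tmat)
  excluded <- matrix(integer(), 0, 2)   # one row per excluded pair, i < j
  deg <- integer(d)
  r <- sparcc_basis(tmat, excluded, var_fallback)
  for (it in seq_len(n_exclude_iter)) {
    ra <- abs(r)
    diag(ra) <- 0
    if (nrow(excluded)) {
      ra[excluded] <- 0
      ra[excluded[, 2:1, drop = FALSE]] <- 0
    }
    # a component excluded from almost every pair would make the linear
    # system singular; freeze such components out of further exclusions
    saturated <- deg >= d - 3
    ra[saturated, ] <- 0
    ra[, saturated] <- 0
    top <- arrayInd(which.max(ra), dim(ra))
    if (ra[top] <= exclude_threshold) break
    excluded <- rbind(excluded, sort(top))
    deg <- tabulate(as.vector(excluded), nbins = d)
    r <- sparcc_basis(tmat, excluded, var_fallback)
  }
  r
}

#' SparCC correlations for compositional count data
#'
#' Median basis correlation over `n_inner` Dirichlet-posterior draws, each
#' solved under the sparsity approximation with `n_exclude_iter` rounds of
#' strongest-pair exclusion above `exclude_threshold`. Pseudo p-values come
#' from a bootstrap null in which each ASV's counts are permuted
#' independently across samples `n_boot` times.
#'
#' @param table A `count_table` (>= 10 samples, >= 4 ASVs).
#' @param other Optional second `count_table` on the same samples. When
#'   given, the two tables are concatenated and the Dirichlet draws are
#'   blocked by kingdom; the returned matrices cover all ASVs of both.
#' @param n_inner Dirichlet draws per estimate (default 20).
#' @param n_exclude_iter Exclusion rounds (default 10).
#' @param exclude_threshold Exclusion correlation threshold (default 0.1).
#' @param n_boot Bootstrap null datasets for p-values (default 100); set to
#'   0 to skip p-values. The smallest attainable FDR-adjusted q-value is
#'   bounded below by `n_tests / ((n_boot + 1) * n_discoveries)`, so sparse
#'   networks need `n_boot` well above 100 for edges to survive the 0.05
#'   FDR gate.
#' @param n_inner_boot Dirichlet draws per bootstrap estimate (default 5):
#'   the null only feeds the tail count of `|r|`, which needs less
#'   posterior averaging than the point estimate.
#' @param seed Integer seed.
#' @return List with matrices `r` (clipped to \[-1, 1\]) and `p` (two-sided
#'   pseudo p-values, `NA` diagonal; `NULL` when `n_boot = 0`).
#' @export
sparcc_correlations <- function(table, other = NULL, n_inner = 20,
                                n_exclude_iter = 10, exclude_threshold = 0.1,
                                n_boot = 100, n_inner_boot = 5, seed = 1L) {
  counts <- table$counts
  blocks <- rep(1L, ncol(counts))
  if (!is.null(other)) {
    stopifnot(identical(sample_ids(table), sample_ids(other)))
    counts <- cbind(counts, other$counts)
    blocks <- c(blocks, rep(2L, ncol(other$counts)))
  }
  if (nrow(counts) < 10) stop("need at least 10 samples")
  if (ncol(counts) < 4) stop("need at least 4 ASVs")
  # element-wise median across draws via a vectorized pmin/pmax sorting
  # network (a median() call per matrix cell is far too slow here)
  median_mats <- function(draws) {
    k <- length(draws)
    if (k == 1) return(draws[[1]])
    m <- matrix(unlist(draws), ncol = k)
    for (i in seq_len(k - 1)) for (j in seq_len(k - i)) {
      lo <- pmin(m[, j], m[, j + 1])
      m[, j + 1] <- pmax(m[, j], m[, j + 1])
      m[, j] <- lo
    }
    v <- if (k %% 2) m[, (k + 1) / 2] else (m[, k / 2] + m[, k / 2 + 1]) / 2
    matrix(v, nrow(draws[[1]]), ncol(draws[[1]]))
  }
  estimate <- function(cnt, k) {
    draws <- lapply(seq_len(k), function(b)
      sparcc_one_draw(cnt, blocks, n_exclude_iter, exclude_threshold))
    r <- median_mats(draws)
    dimnames(r) <- list(colnames(cnt), colnames(cnt))
    r
  }
  with_seed(seed, {
    r_obs <- estimate(counts, n_inner)
    p <- NULL
    if (n_boot > 0) {
      exceed <- matrix(0, ncol(counts), ncol(counts))
      for (b in seq_len(n_boot)) {
        shuffled <- apply(counts, 2, sample)
        colnames(shuffled) <- colnames(counts)
        r_null <- estimate(shuffled, n_inner_boot)
        exceed <- exceed + (abs(r_null) >= abs(r_obs))
      }
      p <- (exceed + 1) / (n_boot + 1)
      dimnames(p) <- dimnames(r_obs)
      diag(p) <- NA
    }
    list(r = r_obs, p = p)
  })
}
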