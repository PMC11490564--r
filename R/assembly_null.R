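#' Abundance-weighted environmental optima of ASVs
#'
#' The optimum of ASV i for an environmental variable is its abundance-
#' weighted mean across the time series:
#' \eqn{o_i = \sum_t n_{it} E_t / \sum_t n_{it}}.
#'
#' @param table A `count_table`.
#' @param env Metadata data frame with one row per sample (same order).
#' @param variable Name of the environmental column.
#' @return Named numeric vector of optima; ASVs with zero total count are
#'   dropped with a warning.
#' @export
env_optima <- function(table, env, variable) {
  if (!variable %in% names(env)) stop("unknown variable: ", variable)
  m <- table$counts
  stopifnot(nrow(m) == nrow(env))
  tot <- colSums(m)
  if (any(tot == 0)) {
    warning(sum(tot == 0), " ASV(s) with zero total count dropped")
    m <- m[, tot > 0, drop = FALSE]
    tot <- tot[tot > 0]
  }
  drop(crossprod(m, env[[variable]])[, 1]) / tot
}

#' Mantel correlogram of phylogenetic signal in environmental optima
#'
#' Tests whether closely related ASVs have similar environmental optima,
#' the premise behind the phylogenetic null models. Pairwise distances
#' between optima (`|o_i - o_j|`) are correlated with membership in
#' equal-frequency phylogenetic-distance classes; the per-class statistic is
#' sign-flipped so that positive values mean positive autocorrelation
#' (similar optima) within the class. Permutation p-values (shuffling ASV
#' identities) are corrected progressively (Holm over classes 1..k).
#'
#' @param optima Named per-ASV optima (names must be tree tips).
#' @param tree `ape::phylo` covering the ASVs.
#' @param n_classes Number of distance classes (default 4).
#' @param n_perm Number of permutations (>= 99; default 199).
#' @param seed Integer seed.
#' @return Data frame with per-class bounds, mean distance, Mantel
#'   statistic, permutation `p` and progressively corrected `p_corrected`.
#' @export
mantel_correlogram <- function(optima, tree, n_classes = 4, n_perm = 199,
                               seed = 1L) {
  if (length(optima) < 10) stop("need at least 10 ASVs")
  if (n_perm < 99) stop("n_perm must be >= 99")
  if (stats::sd(optima) == 0) stop("constant optima: zero variance")
  dphy <- ape::cophenetic.phylo(tree)[names(optima), names(optima)]
  n <- length(optima)
  lower <- lower.tri(dphy)
  dp <- dphy[lower]
  breaks <- stats::quantile(dp, probs = seq(0, 1, length.out = n_classes + 1))
  breaks[1] <- 0
  breaks[length(breaks)] <- max(dp)
  breaks <- unique(breaks)            # tied quantiles merge classes
  n_classes <- length(breaks) - 1
  if (n_classes < 1) stop("all phylogenetic distances identical")
  cls <- cut(dp, breaks = breaks, include.lowest = TRUE, labels = FALSE)

  dps <- (dp - mean(dp)) / stats::sd(dp)
  class_stats <- function(o) {
    de <- abs(outer(o, o, "-"))[lower]
    des <- (de - mean(de)) / stats::sd(de)
    # negative correlation with the class indicator = small trait distances
    # within the class => positive autocorrelation; flip the sign so the
    # series reads like a correlogram. A single all-pair class degenerates
    # to the plain Mantel statistic between the two distance matrices.
    vapply(seq_len(n_classes), function(k) {
      ind <- cls == k
      if (all(ind)) return(stats::cor(des, dps))
      -stats::cor(des, as.numeric(ind))
    }, numeric(1))
  }
  obs <- class_stats(optima)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) class_stats(sample(optima)),
           numeric(n_classes))
  })
  perm <- matrix(perm, nrow = n_classes)
  p <- vapply(seq_len(n_classes), function(k)
    (1 + sum(abs(perm[k, ]) >= abs(obs[k]))) / (n_perm + 1), numeric(1))
  p_corr <- vapply(seq_len(n_classes), function(k)
    stats::p.adjust(p[seq_len(k)], method = "holm")[k], numeric(1))
  data.frame(class = seq_len(n_classes),
             d_lower = breaks[-(n_classes + 1)], d_upper = breaks[-1],
             d_mean = tapply(dp, cls, mean)[as.character(seq_len(n_classes))],
             mantel_r = obs, p = p, p_corrected = p_corr)
}

#' Abundance-weighted mean pairwise phylogenetic distance
#' @param f Relative abundances over the pool (zeros for absent ASVs).
#' @param dist Cophenetic distance matrix over the pool.
#' @return MPD in branch-length units.
#' @export
mpd_weighted <- function(f, dist) {
  i <- which(f > 0)
  fi <- f[i] / sum(f[i])
  num <- drop(crossprod(fi, dist[i, i, drop = FALSE] %*% fi))
  den <- 1 - sum(fi^2)
  if (den <= 0) return(NA_real_)
  num / den
}

#' Abundance-weighted mean nearest-taxon distance
#' @param f Relative abundances over the pool (zeros for absent ASVs).
#' @param dist Cophenetic distance matrix over the pool.
#' @return MNTD in branch-length units.
#' @export
mntd_weighted <- function(f, dist) {
  i <- which(f > 0)
  if (length(i) < 2) return(NA_real_)
  fi <- f[i] / sum(f[i])
  d <- dist[i, i, drop = FALSE]
  diag(d) <- Inf
  sum(fi * row_mins(d))
}

#' Standardized effect size of phylogenetic alpha dispersion (NRI / NTI)
#'
#' Computes abundance-weighted MPD or MNTD for one sample and compares it to
#' a taxa-labels null: the tip labels of the distance matrix are shuffled
#' across the full ASV pool `n_null` times. The returned SES is negated
#' (NRI/NTI convention), so positive values mean phylogenetic clustering.
#'
#' @param f Relative abundances over the pool (zeros allowed).
#' @param dist Cophenetic distance matrix over the pool.
#' @param statistic `"MPD"` (-> NRI) or `"MNTD"` (-> NTI).
#' @param n_null Number of null permutations (default 999).
#' @param seed Integer seed.
#' @return List with `obs`, `null_mean`, `null_sd`, `ses`, `degenerate`,
#'   `n_null`.
#' @export
ses_phylo_alpha <- function(f, dist, statistic = c("MPD", "MNTD"),
                            n_null = 999, seed = 1L) {
  statistic <- match.arg(statistic)
  n_pool <- nrow(dist)
  present <- which(f > 0)
  if (length(present) < 2)
    return(list(obs = NA_real_, null_mean = NA_real_, null_sd = NA_real_,
                ses = 0, degenerate = TRUE, n_null = n_null))
  fi <- f[present] / sum(f[present])
  stat_idx <- if (statistic == "MPD") {
    function(idx) {
      d <- dist[idx, idx, drop = FALSE]
      drop(crossprod(fi, d %*% fi)) / (1 - sum(fi^2))
    }
  } else {
    function(idx) {
      d <- dist[idx, idx, drop = FALSE]
      diag(d) <- Inf
      sum(fi * row_mins(d))
    }
  }
  obs <- stat_idx(present)
  # shuffling the labels of the full distance matrix is equivalent to
  # re-drawing the community's index set from the pool (weights attached)
  nulls <- with_seed(seed, vapply(seq_len(n_null), function(b)
    stat_idx(sample.int(n_pool, length(present))), numeric(1)))
  mu <- mean(nulls)
  sdv <- stats::sd(nulls)
  if (!is.finite(sdv) || sdv < 1e-12)
    return(list(obs = obs, null_mean = mu, null_sd = 0, ses = 0,
                degenerate = TRUE, n_null = n_null))
  list(obs = obs, null_mean = mu, null_sd = sdv,
       ses = -(obs - mu) / sdv, degenerate = FALSE, n_null = n_null)
}

#' NRI/NTI series over all samples of a table
#'
#' @param table A `count_table`.
#' @param tree `ape::phylo` whose tips cover the table's ASVs.
#' @param statistic `"MPD"` (NRI) or `"MNTD"` (NTI).
#' @param n_null Null permutations per sample (default 999).
#' @param seed Master seed; per-sample seeds are derived deterministically.
#' @return Data frame with one row per sample: observed statistic, null
#'   moments, `ses` and `degenerate` flag.
#' @export
ses_alpha_series <- function(table, tree, statistic = c("MPD", "MNTD"),
                             n_null = 999, seed = 1L) {
  statistic <- match.arg(statistic)
  dist <- ape::cophenetic.phylo(tree)[asv_ids(table), asv_ids(table)]
  rel <- rel_abundance(table)
  rows <- lapply(seq_len(nrow(rel)), function(i) {
    r <- ses_phylo_alpha(rel[i, ], dist, statistic, n_null,
                         derive_seed(seed, i))
    data.frame(sample_id = rownames(rel)[i], statistic = statistic,
               obs = r$obs, null_mean = r$null_mean, null_sd = r$null_sd,
               ses = r$ses, degenerate = r$degenerate)
  })
  do.call(rbind, rows)
}

#' Between-community mean nearest-taxon distance
#'
#' \eqn{0.5[\sum_{i \in A} f_{iA} \min_{j \in B} d_{ij} +
#' \sum_{j \in B} f_{jB} \min_{i \in A} d_{ij}]}; ASVs shared by both
#' communities have a nearest taxon at distance zero (themselves).
#'
#' @param fA,fB Relative abundances over the pool (zeros for absent ASVs).
#' @param dist Cophenetic distance matrix over the pool.
#' @return Beta-MNTD in branch-length units.
#' @export
beta_mntd <- function(fA, fB, dist) {
  iA <- which(fA > 0)
  iB <- which(fB > 0)
  if (!length(iA) || !length(iB)) stop("empty community")
  d <- dist[iA, iB, drop = FALSE]
  wA <- fA[iA] / sum(fA[iA])
  wB <- fB[iB] / sum(fB[iB])
  0.5 * (sum(wA * row_mins(d)) + sum(wB * row_mins(t(d))))
}

#' Beta nearest-taxon index between two communities
#'
#' Standardized effect size of beta-MNTD against a null that shuffles ASVs
#' across the tips of the whole tree (abundances travel with identities),
#' 999 iterations by default. `|betaNTI| > 2` flags turnover more (or less)
#' phylogenetically structured than expected by chance.
#'
#' @param fA,fB Relative abundances over the pool (zeros for absent ASVs).
#' @param dist Cophenetic distance matrix over all tree tips (the pool).
#' @param n_null Number of tip shuffles (default 999).
#' @param seed Integer seed.
#' @return List with `obs`, `null_mean`, `null_sd`, `bnti`, `significant`,
#'   `degenerate`.
#' @export
bnti <- function(fA, fB, dist, n_null = 999, seed = 1L) {
  obs <- beta_mntd(fA, fB, dist)
  n_pool <- nrow(dist)
  iA <- which(fA > 0)
  iB <- which(fB > 0)
  wA <- fA[iA] / sum(fA[iA])
  wB <- fB[iB] / sum(fB[iB])
  # a joint tip shuffle re-maps both communities through one permutation,
  # so shared ASVs keep their zero self-distance under the null
  nulls <- with_seed(seed, vapply(seq_len(n_null), function(b) {
    perm <- sample.int(n_pool)
    d <- dist[perm[iA], perm[iB], drop = FALSE]
    0.5 * (sum(wA * row_mins(d)) + sum(wB * row_mins(t(d))))
  }, numeric(1)))
  mu <- mean(nulls)
  sdv <- stats::sd(nulls)
  if (!is.finite(sdv) || sdv < 1e-12)
    return(list(obs = obs, null_mean = mu, null_sd = 0, bnti = 0,
                significant = FALSE, degenerate = TRUE))
  val <- (obs - mu) / sdv
  list(obs = obs, null_mean = mu, null_sd = sdv, bnti = val,
       significant = abs(val) > 2, degenerate = FALSE)
}

# One Raup-Crick null draw for a sample: pick the observed richness of ASV
# identities with probability proportional to occupancy, give each one read,
# then distribute the remaining reads multinomially by dataset-wide
# relative abundance.
rc_null_sample <- function(richness, total, occupancy, relabund) {
  n_pool <- length(occupancy)
  if (richness > n_pool) stop("sample richness exceeds pool size")
  idx <- sample.int(n_pool, richness, prob = occupancy)
  counts <- numeric(n_pool)
  counts[idx] <- 1
  extra <- total - richness
  if (extra > 0)
    counts[idx] <- counts[idx] +
      stats::rmultinom(1, extra, relabund[idx])[, 1]
  counts
}

#' Raup-Crick deviation of Bray-Curtis turnover from random assembly
#'
#' Compares the observed Bray-Curtis dissimilarity of two samples with a
#' null in which each sample keeps its ASV richness and read total but the
#' identities (weighted by pool occupancy) and read distribution (weighted
#' by dataset-wide relative abundance) are randomized. The tie-midpoint
#' probability `P(null < obs) + 0.5 P(null = obs)` is rescaled to
#' \[-1, 1\]; `|RC| > 0.95` flags significant deviation from drift.
#'
#' @param countsA,countsB Count vectors over the pool's ASV universe.
#' @param pool `count_table` defining occupancy and relative-abundance
#'   weights (usually the full rarefied table).
#' @param n_null Number of null draws (default 999).
#' @param seed Integer seed.
#' @param uniform_weights If `TRUE`, identities and reads are drawn with
#'   equal weights instead of occupancy/abundance weights.
#' @return List with `obs_bray`, `rc`, `significant`.
#' @export
raup_crick_bray <- function(countsA, countsB, pool, n_null = 999, seed = 1L,
                            uniform_weights = FALSE) {
  m <- pool$counts
  occupancy <- colSums(m > 0)
  relabund <- colSums(m) / sum(m)
  if (uniform_weights) {
    occupancy <- rep(1, ncol(m))
    relabund <- rep(1 / ncol(m), ncol(m))
  }
  obs <- bray_curtis(countsA, countsB)
  rA <- sum(countsA > 0); nA <- sum(countsA)
  rB <- sum(countsB > 0); nB <- sum(countsB)
  nulls <- with_seed(seed, vapply(seq_len(n_null), function(b) {
    a <- rc_null_sample(rA, nA, occupancy, relabund)
    b2 <- rc_null_sample(rB, nB, occupancy, relabund)
    bray_curtis(a, b2)
  }, numeric(1)))
  eps <- 1e-12
  frac <- (sum(nulls < obs - eps) + 0.5 * sum(abs(nulls - obs) <= eps)) /
    n_null
  rc <- 2 * frac - 1
  list(obs_bray = obs, rc = rc, significant = abs(rc) > 0.95)
}

#' Null-model turnover series between successive samples
#'
#' Runs [bnti()] and [raup_crick_bray()] for every consecutive sample pair
#' of a table, with per-pair seeds derived from a master seed.
#'
#' @param table A `count_table` with samples in day order.
#' @param tree `ape::phylo` whose tips cover the table's ASVs.
#' @param n_null Null iterations for both models (default 999).
#' @param seed Master seed.
#' @return Data frame with one row per pair: beta-MNTD observed/null
#'   moments, `bnti`, `obs_bray`, `rc` and the two significance calls.
#' @export
turnover_series <- function(table, tree, n_null = 999, seed = 1L) {
  m <- table$counts
  if (nrow(m) < 2) stop("need at least 2 samples")
  dist <- ape::cophenetic.phylo(tree)[colnames(m), colnames(m)]
  rel <- rel_abundance(table)
  rows <- lapply(seq_len(nrow(m) - 1), function(i) {
    b <- bnti(rel[i, ], rel[i + 1, ], dist, n_null,
              derive_seed(seed, 2L * i))
    r <- raup_crick_bray(m[i, ], m[i + 1, ], table, n_null,
                         derive_seed(seed, 2L * i + 1L))
    data.frame(pair = i, sample_from = rownames(m)[i],
               sample_to = rownames(m)[i + 1],
               beta_mntd_obs = b$obs, beta_mntd_null_mean = b$null_mean,
               beta_mntd_null_sd = b$null_sd, bnti = b$bnti,
               bnti_significant = b$significant, degenerate = b$degenerate,
               obs_bray = r$obs_bray, rc_bray = r$rc,
               rc_significant = r$significant)
  })
  do.call(rbind, rows)
}
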