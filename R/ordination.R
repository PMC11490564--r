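#' Principal coordinates analysis (Gower decomposition)
#'
#' Double-centers `-0.5 * D^2` and eigen-decomposes it. Site coordinates
#' are returned for the positive-eigenvalue axes; negative eigenvalues are
#' retained in the report (no Lingoes/Cailliez correction by default).
#'
#' @param dist Symmetric dissimilarity matrix (or `dist`) with zero
#'   diagonal.
#' @return List with `coordinates` (samples x positive axes),
#'   `eigenvalues` (all, decreasing), `positive_inertia`.
#' @export
pcoa <- function(dist) {
  d <- as.matrix(dist)
  if (nrow(d) < 2) stop("need at least 2 samples")
  if (max(abs(d - t(d))) > 1e-8) stop("dissimilarity matrix not symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("nonzero diagonal")
  n <- nrow(d)
  a <- -0.5 * d^2
  g <- sweep(sweep(a, 1, rowMeans(a)), 2, colMeans(a)) + mean(a)
  e <- eigen(g, symmetric = TRUE)
  pos <- e$values > max(e$values) * 1e-9
  coords <- e$vectors[, pos, drop = FALSE] %*%
    diag(sqrt(e$values[pos]), sum(pos))
  rownames(coords) <- rownames(d)
  list(coordinates = coords, eigenvalues = e$values,
       positive_inertia = sum(e$values[pos]))
}

# Standardized model matrix: numeric columns scaled, factors/characters
# dummy-coded (first level dropped). Collinear columns either error (the
# dbRDA contract) or are dropped (variance partitioning, where overlapping
# sets are the point).
build_predictors <- function(predictors, on_collinear = c("error", "drop")) {
  on_collinear <- match.arg(on_collinear)
  df <- as.data.frame(predictors)
  if (anyNA(df)) stop("predictors contain missing values")
  mm <- stats::model.matrix(~ ., data = df)[, -1, drop = FALSE]
  mm <- scale(mm)
  if (any(!is.finite(mm))) stop("constant predictor column")
  qr_x <- qr(mm)
  if (qr_x$rank < ncol(mm)) {
    aliased <- colnames(mm)[qr_x$pivot[(qr_x$rank + 1):ncol(mm)]]
    if (on_collinear == "error")
      stop("collinear predictors: ", paste(aliased, collapse = ", "))
    mm <- mm[, qr_x$pivot[seq_len(qr_x$rank)], drop = FALSE]
  }
  mm
}

dbrda_r2 <- function(y, x, total) {
  fit <- stats::lm.fit(cbind(1, x), y)
  sum(fit$fitted.values^2) / total
}

#' Distance-based redundancy analysis
#'
#' Embeds the dissimilarity matrix by PCoA, regresses the positive-axis
#' site scores on the (internally standardized) predictors, and reports the
#' constrained fraction of positive inertia with Ezekiel's adjustment and a
#' permutation p-value (rows of the predictor table permuted).
#'
#' @param dist Sample dissimilarity matrix.
#' @param predictors Data frame of explanatory variables (factors allowed).
#' @param n_perm Permutations for the pseudo-F test (default 999; 0 skips).
#' @param seed Integer seed.
#' @return List with `r2`, `adj_r2`, `p`, `pseudo_f`, `site_scores`,
#'   `eigenvalues`, `n`, `rank`.
#' @export
dbrda <- function(dist, predictors, n_perm = 999, seed = 1L) {
  pc <- pcoa(dist)
  y <- pc$coordinates
  x <- build_predictors(predictors)
  n <- nrow(y)
  m <- ncol(x)
  if (n - m - 1 <= 0) stop("more predictors than residual degrees of freedom")
  total <- pc$positive_inertia
  r2 <- dbrda_r2(y, x, total)
  adj <- 1 - (1 - r2) * (n - 1) / (n - m - 1)
  f_obs <- (r2 / m) / ((1 - r2) / (n - m - 1))
  p <- NA_real_
  if (n_perm > 0) {
    f_null <- with_seed(seed, vapply(seq_len(n_perm), function(b) {
      xp <- x[sample.int(n), , drop = FALSE]
      r2b <- dbrda_r2(y, xp, total)
      (r2b / m) / ((1 - r2b) / (n - m - 1))
    }, numeric(1)))
    p <- (1 + sum(f_null >= f_obs)) / (n_perm + 1)
  }
  fit <- stats::lm.fit(cbind(1, x), y)
  list(r2 = r2, adj_r2 = adj, p = p, pseudo_f = f_obs,
       site_scores = fit$fitted.values, eigenvalues = pc$eigenvalues,
       n = n, rank = m)
}

#' Greedy forward selection of dbRDA predictors by permutation test
#'
#' At each step the candidate with the smallest permutation p-value for its
#' marginal contribution (conditional pseudo-F with the candidate's rows
#' permuted) enters, provided p <= `alpha` and the adjusted R2 increases;
#' selection stops otherwise.
#'
#' @param dist Sample dissimilarity matrix.
#' @param candidates Data frame of candidate variables (single columns).
#' @param alpha Entry threshold (default 0.05).
#' @param n_perm Permutations per marginal test (default 199).
#' @param seed Integer seed.
#' @return Character vector of selected variable names (possibly empty).
#' @export
forward_select_predictors <- function(dist, candidates, alpha = 0.05,
                                      n_perm = 199, seed = 1L) {
  stopifnot(ncol(candidates) >= 1)
  pc <- pcoa(dist)
  y <- pc$coordinates
  total <- pc$positive_inertia
  n <- nrow(y)
  selected <- character()
  adj_cur <- 0
  r2_of <- function(vars) {
    if (!length(vars)) return(c(r2 = 0, adj = 0, m = 0))
    x <- build_predictors(candidates[, vars, drop = FALSE])
    m <- ncol(x)
    r2 <- dbrda_r2(y, x, total)
    c(r2 = r2, adj = 1 - (1 - r2) * (n - 1) / (n - m - 1), m = m)
  }
  step <- 0
  repeat {
    step <- step + 1
    remaining <- setdiff(names(candidates), selected)
    if (!length(remaining)) break
    base <- r2_of(selected)
    trial <- lapply(remaining, function(v) {
      full <- r2_of(c(selected, v))
      dfc <- full["m"] - base["m"]
      f_obs <- ((full["r2"] - base["r2"]) / dfc) /
        ((1 - full["r2"]) / (n - full["m"] - 1))
      f_null <- with_seed(derive_seed(seed, step * 131 + match(v, names(candidates))),
        vapply(seq_len(n_perm), function(b) {
          cand <- candidates
          cand[[v]] <- cand[[v]][sample.int(n)]
          x <- build_predictors(cand[, c(selected, v), drop = FALSE])
          r2b <- dbrda_r2(y, x, total)
          ((r2b - base["r2"]) / dfc) / ((1 - r2b) / (n - ncol(x) - 1))
        }, numeric(1)))
      list(v = v, p = (1 + sum(f_null >= f_obs)) / (n_perm + 1),
           adj = unname(full["adj"]))
    })
    ps <- vapply(trial, `[[`, numeric(1), "p")
    best <- trial[[which.min(ps)]]
    if (best$p > alpha || best$adj <= adj_cur) break
    selected <- c(selected, best$v)
    adj_cur <- best$adj
  }
  selected
}

#' Three-way variance partitioning on a dissimilarity matrix
#'
#' Fits dbRDA models for every non-empty subset of the three predictor sets
#' and decomposes the adjusted R2 by inclusion-exclusion into three unique
#' fractions, three pairwise shared fractions, the triple-shared fraction
#' and the residual. Individual fractions may be negative (adjusted-R2
#' convention); everything sums to 1 exactly.
#'
#' @param dist Sample dissimilarity matrix.
#' @param set_abiotic,set_biotic,set_stage Non-empty data frames of
#'   predictors (reactor parameters; the other kingdom's alpha diversity;
#'   granulation stage).
#' @return Data frame with columns `fraction` and `adj_r2`: rows
#'   `abiotic`, `biotic`, `stage` (unique), `abiotic:biotic`,
#'   `abiotic:stage`, `biotic:stage`, `all`, `residual`.
#' @export
variance_partition <- function(dist, set_abiotic, set_biotic, set_stage) {
  sets <- list(abiotic = as.data.frame(set_abiotic),
               biotic = as.data.frame(set_biotic),
               stage = as.data.frame(set_stage))
  stopifnot(all(vapply(sets, ncol, integer(1)) >= 1))
  pc <- pcoa(dist)
  y <- pc$coordinates
  total <- pc$positive_inertia
  n <- nrow(y)
  adj_of <- function(which_sets) {
    df <- do.call(cbind, sets[which_sets])
    x <- build_predictors(df, on_collinear = "drop")
    m <- ncol(x)
    if (n - m - 1 <= 0) stop("rank deficiency: too many predictors")
    r2 <- dbrda_r2(y, x, total)
    1 - (1 - r2) * (n - 1) / (n - m - 1)
  }
  fA <- adj_of("abiotic"); fB <- adj_of("biotic"); fC <- adj_of("stage")
  fAB <- adj_of(c("abiotic", "biotic"))
  fAC <- adj_of(c("abiotic", "stage"))
  fBC <- adj_of(c("biotic", "stage"))
  fABC <- adj_of(c("abiotic", "biotic", "stage"))
  g <- fA + fB + fC - fAB - fAC - fBC + fABC
  out <- data.frame(
    fraction = c("abiotic", "biotic", "stage", "abiotic:biotic",
                 "abiotic:stage", "biotic:stage", "all", "residual"),
    adj_r2 = c(fABC - fBC,                 # unique abiotic
               fABC - fAC,                 # unique biotic
               fABC - fAB,                 # unique stage
               fA + fB - fAB - g,          # shared abiotic&biotic only
               fA + fC - fAC - g,          # shared abiotic&stage only
               fB + fC - fBC - g,          # shared biotic&stage only
               g,                          # shared by all three
               1 - fABC))
  out
}
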