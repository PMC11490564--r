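#' Hill-number alpha diversity of one sample
#'
#' Effective number of ASVs at diversity order `q`: with relative abundances
#' \eqn{p_i}, \eqn{^qTD = (\sum_i p_i^q)^{1/(1-q)}} for \eqn{q \ne 1} and
#' \eqn{\exp(-\sum_i p_i \log p_i)} at the \eqn{q = 1} limit. `q = 0` is
#' richness, `q = 1` the exponential Shannon index, `q = 2` the reciprocal
#' Simpson index.
#'
#' @param counts Non-negative count (or abundance) vector for one sample.
#' @param q Diversity order, `q >= 0`.
#' @return The effective number of ASVs (a single number >= 1).
#' @export
hill_alpha <- function(counts, q) {
  if (q < 0) stop("q must be >= 0")
  if (all(counts == 0)) stop("all-zero sample")
  p <- counts[counts > 0] / sum(counts)
  if (abs(q - 1) < 1e-10) exp(-sum(p * log(p)))
  else sum(p^q)^(1 / (1 - q))
}

#' Hill diversity profile of a count table
#'
#' @param table A `count_table`.
#' @param q_list Diversity orders (default `c(0, 1, 2)`).
#' @return Tidy data frame with columns `sample_id`, `q`, `qTD`.
#' @export
hill_profile <- function(table, q_list = c(0, 1, 2)) {
  m <- table$counts
  out <- expand.grid(sample_id = rownames(m), q = q_list,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$qTD <- mapply(function(s, q) hill_alpha(m[s, ], q),
                    out$sample_id, out$q)
  out[order(match(out$sample_id, rownames(m)), out$q), , drop = FALSE]
}

# Two-assemblage gamma, alpha (Chiu-Jost, equal weights) and beta = gamma/alpha.
hill_beta_raw <- function(pA, pB, q) {
  pbar <- (pA + pB) / 2
  gam <- hill_alpha(pbar, q)
  pij <- c(pA, pB) / 2                       # within-pair weights, sum = 1
  pij <- pij[pij > 0]
  alp <- if (abs(q - 1) < 1e-10) exp(-sum(pij * log(pij)) - log(2))
         else 0.5 * sum(pij^q)^(1 / (1 - q))
  gam / alp
}

#' Bounded beta dissimilarity between two samples (Hill framework)
#'
#' Decomposes pairwise diversity multiplicatively (beta = gamma/alpha with
#' two equally weighted assemblages, so beta lies in \[1, 2\]) and transforms
#' it onto \[0, 1\]. The default `"local"` transform is the Sorensen-type
#' overlap complement \eqn{1 - C_{q2}}; `"regional"` gives the Jaccard-type
#' \eqn{1 - U_{q2}}. Both equal \eqn{\log\beta/\log 2} at `q = 1`.
#'
#' @param countsA,countsB Count vectors on a shared ASV index.
#' @param q Diversity order, `q >= 0`.
#' @param variant `"local"` (default) or `"regional"` overlap complement.
#' @return Dissimilarity in \[0, 1\].
#' @export
hill_beta_dissimilarity <- function(countsA, countsB, q,
                                    variant = c("local", "regional")) {
  variant <- match.arg(variant)
  if (q < 0) stop("q must be >= 0")
  stopifnot(length(countsA) == length(countsB))
  if (all(countsA == 0) || all(countsB == 0)) stop("empty sample")
  pA <- countsA / sum(countsA)
  pB <- countsB / sum(countsB)
  beta <- hill_beta_raw(pA, pB, q)
  beta <- min(max(beta, 1), 2)               # guard tiny numerical overshoot
  ex <- switch(variant, local = q - 1, regional = 1 - q)
  if (abs(q - 1) < 1e-10) return(log(beta) / log(2))
  overlap <- ((1 / beta)^ex - (1 / 2)^ex) / (1 - (1 / 2)^ex)
  1 - overlap
}

#' Beta-dissimilarity series between successive samples
#'
#' One bounded dissimilarity per consecutive sample pair (t, t+1), per
#' diversity order, tracking community turnover along the reactor run.
#'
#' @param table A `count_table` with samples in day order.
#' @param q_list Diversity orders (default `c(0, 1, 2)`).
#' @param variant Overlap variant passed to [hill_beta_dissimilarity()].
#' @return Tidy data frame with columns `pair` (index), `sample_from`,
#'   `sample_to`, `q`, `beta_dis` and raw `beta`.
#' @export
successive_beta_series <- function(table, q_list = c(0, 1, 2),
                                   variant = "local") {
  m <- table$counts
  n <- nrow(m)
  if (n < 2) stop("need at least 2 samples")
  out <- expand.grid(pair = seq_len(n - 1), q = q_list,
                     KEEP.OUT.ATTRS = FALSE)
  out$sample_from <- rownames(m)[out$pair]
  out$sample_to <- rownames(m)[out$pair + 1]
  out$beta_dis <- mapply(function(i, q)
    hill_beta_dissimilarity(m[i, ], m[i + 1, ], q, variant),
    out$pair, out$q)
  out$beta <- mapply(function(i, q)
    hill_beta_raw(m[i, ] / sum(m[i, ]), m[i + 1, ] / sum(m[i + 1, ]), q),
    out$pair, out$q)
  out[order(out$pair, out$q), c("pair", "sample_from", "sample_to",
                                "q", "beta_dis", "beta")]
}

#' Bray-Curtis dissimilarity between two samples
#'
#' \eqn{1 - 2\sum_i \min(n_{iA}, n_{iB}) / (N_A + N_B)} on raw counts.
#'
#' @param countsA,countsB Count vectors on a shared ASV index.
#' @return Dissimilarity in \[0, 1\].
#' @export
bray_curtis <- function(countsA, countsB) {
  if (all(countsA == 0) || all(countsB == 0)) stop("empty sample")
  1 - 2 * sum(pmin(countsA, countsB)) / (sum(countsA) + sum(countsB))
}
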