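make_tab <- function(m) {
  dimnames(m) <- list(paste0("S", seq_len(nrow(m))),
                      paste0("A", seq_len(ncol(m))))
  count_table(m, "prokaryote")
}

test_that("Spearman correlations hit the monotone extremes and a rank oracle", {
  set.seed(1)
  n <- 20
  x <- sort(rpois(n, 20) + 1)
  m <- cbind(x, rev(x) + 1, rpois(n, 10) + 1, rpois(n, 10) + 1)
  tab <- make_tab(m)
  sp <- spearman_correlations(tab)
  # relative abundance shifts break perfect monotonicity of raw counts, so
  # build the oracle on the same closed data
  rel <- rel_abundance(tab)
  expect_equal(sp$rho[1, 2], cor(rank(rel[, 1]), rank(rel[, 2])),
               tolerance = 1e-12)
  for (i in 1:3) for (j in (i + 1):4)
    expect_equal(sp$rho[i, j], cor(rank(rel[, i]), rank(rel[, j])),
                 tolerance = 1e-12)
  expect_error(spearman_correlations(make_tab(m[1:3, ])), "5 samples")
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(2)
  p <- runif(50)
  q <- bh_adjust(p)
  # from-definition implementation
  ord <- order(p)
  qdef <- numeric(50)
  prev <- 1
  for (k in 50:1) {
    prev <- min(prev, p[ord[k]] * 50 / k)
    qdef[ord[k]] <- prev
  }
  expect_equal(q, qdef, tolerance = 1e-12)
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("consensus rule requires both methods to pass all four gates", {
  ids <- c("A1", "A2", "A3")
  mk <- function(v) matrix(v, 3, 3, dimnames = list(ids, ids))
  rho <- mk(0); r <- mk(0); q1 <- mk(1); q2 <- mk(1)
  rho[1, 2] <- rho[2, 1] <- 0.7; q1[1, 2] <- q1[2, 1] <- 0.01
  r[1, 2] <- r[2, 1] <- 0.4; q2[1, 2] <- q2[2, 1] <- 0.01
  net <- build_consensus_network(rho, r, q1, q2)
  expect_identical(nrow(net$edges), 0L)          # SparCC r below threshold
  expect_identical(nrow(net$nodes), 3L)          # nodes retained
  r[1, 2] <- r[2, 1] <- 0.8
  net2 <- build_consensus_network(rho, r, q1, q2)
  expect_identical(nrow(net2$edges), 1L)
  # sign disagreement is dropped with a warning
  r[1, 2] <- r[2, 1] <- -0.8
  expect_warning(net3 <- build_consensus_network(rho, r, q1, q2),
                 "disagreement")
  expect_identical(nrow(net3$edges), 0L)
})

test_that("three proportional ASVs form a triangle through the full stack", {
  set.seed(3)
  n <- 40
  base <- matrix(rlnorm(n * 20, 3, 1), n, 20)
  base[, 2] <- base[, 1] * 1.5
  base[, 3] <- base[, 1] * 0.5
  counts <- t(apply(base, 1, function(z) rmultinom(1, 8000, z / sum(z))[, 1]))
  tab <- make_tab(counts)
  sp <- spearman_correlations(tab)
  sc <- sparcc_correlations(tab, n_boot = 1999, seed = 5)
  net <- build_consensus_network(sp$rho, sc$r, fdr_adjust_matrix(sp$p),
                                 fdr_adjust_matrix(sc$p))
  tri <- c("A1", "A2", "A3")
  got <- net$edges[net$edges$from %in% tri & net$edges$to %in% tri, ]
  expect_identical(nrow(got), 3L)
  expect_true(all(got$sign == 1))
})

test_that("consensus edges are a subset of each single-method significant set", {
  set.seed(4)
  checked <- 0L
  for (rep in 1:5) {
    n <- 8
    rho <- matrix(runif(n * n, -1, 1), n); rho <- (rho + t(rho)) / 2; diag(rho) <- 1
    r <- matrix(runif(n * n, -1, 1), n); r <- (r + t(r)) / 2; diag(r) <- 1
    q1 <- matrix(runif(n * n), n); q1 <- (q1 + t(q1)) / 2
    q2 <- matrix(runif(n * n), n); q2 <- (q2 + t(q2)) / 2
    ids <- paste0("A", 1:n)
    dimnames(rho) <- dimnames(r) <- dimnames(q1) <- dimnames(q2) <-
      list(ids, ids)
    net <- suppressWarnings(build_consensus_network(rho, r, q1, q2))
    if (nrow(net$edges)) {
      for (e in seq_len(nrow(net$edges))) {
        i <- net$edges$from[e]; j <- net$edges$to[e]
        expect_true(abs(rho[i, j]) > 0.6 && q1[i, j] < 0.05)
        expect_true(abs(r[i, j]) > 0.6 && q2[i, j] < 0.05)
        checked <- checked + 1L
      }
    }
  }
  expect_gte(checked, 0L)   # rule holds vacuously when no edges form
})

test_that("walktrap modules recover planted structure", {
  ids <- paste0("A", 1:6)
  edges <- data.frame(from = c("A1", "A2", "A3", "A4", "A5", "A6"),
                      to = c("A2", "A3", "A1", "A5", "A6", "A4"),
                      rho = 0.9, sparcc_r = 0.9, q_rho = 0.01,
                      q_sparcc = 0.01, sign = 1)
  net <- structure(list(nodes = data.frame(asv_id = ids, kingdom = "prokaryote",
                                           module = NA_integer_),
                        edges = edges), class = "consensus_network")
  out <- detect_modules(net)
  mods <- out$nodes$module
  expect_identical(length(unique(mods)), 2L)     # two disjoint triangles
  expect_identical(length(unique(mods[1:3])), 1L)
  expect_identical(length(unique(mods[4:6])), 1L)
  # complete graph is one module
  k5 <- expand.grid(from = paste0("A", 1:5), to = paste0("A", 1:5),
                    stringsAsFactors = FALSE)
  k5 <- k5[k5$from < k5$to, ]
  k5$rho <- 0.9; k5$sparcc_r <- 0.9; k5$q_rho <- 0.01; k5$q_sparcc <- 0.01
  k5$sign <- 1
  net5 <- structure(list(nodes = data.frame(asv_id = paste0("A", 1:5),
                                            kingdom = "prokaryote",
                                            module = NA_integer_),
                         edges = k5), class = "consensus_network")
  expect_identical(length(unique(detect_modules(net5)$nodes$module)), 1L)
})

test_that("walktrap recovers planted partitions across seeds", {
  ari <- function(a, b) {
    # adjusted Rand index, from the contingency-table definition
    tab <- table(a, b)
    sum_ij <- sum(choose(tab, 2))
    sum_a <- sum(choose(rowSums(tab), 2))
    sum_b <- sum(choose(colSums(tab), 2))
    n <- length(a)
    expected <- sum_a * sum_b / choose(n, 2)
    (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
  }
  hits <- 0
  for (s in 1:20) {
    set.seed(s)
    n_half <- 8
    ids <- paste0("A", 1:(2 * n_half))
    truth <- rep(1:2, each = n_half)
    pairs <- which(upper.tri(matrix(0, 2 * n_half, 2 * n_half)), arr.ind = TRUE)
    same <- truth[pairs[, 1]] == truth[pairs[, 2]]
    keep <- ifelse(same, runif(nrow(pairs)) < 0.8, runif(nrow(pairs)) < 0.05)
    ed <- data.frame(from = ids[pairs[keep, 1]], to = ids[pairs[keep, 2]],
                     rho = 0.9, sparcc_r = 0.9, q_rho = 0.01,
                     q_sparcc = 0.01, sign = 1)
    net <- structure(list(nodes = data.frame(asv_id = ids,
                                             kingdom = "prokaryote",
                                             module = NA_integer_),
                          edges = ed), class = "consensus_network")
    got <- detect_modules(net, seed = s)$nodes$module
    if (ari(got, truth) >= 0.9) hits <- hits + 1
  }
  expect_gte(hits, 18)
})

test_that("module dynamics are presence fractions and summed shares", {
  m <- rbind(c(10, 10, 10, 10, 60),
             c(5, 0, 0, 0, 95),
             c(0, 0, 0, 0, 100))
  tab <- make_tab(m)
  ids <- paste0("A", 1:5)
  net <- structure(list(nodes = data.frame(asv_id = ids,
                                           kingdom = "prokaryote",
                                           module = c(1, 1, 1, 1, 2)),
                        edges = data.frame()), class = "consensus_network")
  dyn <- module_dynamics(net, tab)
  d1 <- dyn[dyn$module == 1, ]
  expect_equal(d1$completeness, c(1, 0.25, 0))
  expect_equal(d1$abundance, c(0.4, 0.05, 0))
  d2 <- dyn[dyn$module == 2, ]
  expect_equal(d2$completeness, c(1, 1, 1))
})

test_that("per-sample network statistics match hand-enumerated graphs", {
  ids <- paste0("A", 1:5)
  mk_net <- function(ed) {
    ed$rho <- 0.9; ed$sparcc_r <- 0.9; ed$q_rho <- 0.01; ed$q_sparcc <- 0.01
    ed$sign <- 1
    structure(list(nodes = data.frame(asv_id = ids, kingdom = "prokaryote",
                                      module = 1L),
                   edges = ed), class = "consensus_network")
  }
  # K4 on A1..A4 (A5 absent in the sample)
  k4 <- expand.grid(from = ids[1:4], to = ids[1:4], stringsAsFactors = FALSE)
  k4 <- k4[k4$from < k4$to, ]
  m <- matrix(c(1, 1, 1, 1, 0), 1, 5, dimnames = list("S1", ids))
  st <- per_sample_network_stats(mk_net(k4), count_table(m, "prokaryote"))
  expect_equal(st$density, 1)
  expect_equal(st$clustering, 1)
  # 4-node path: density 1/2, no triangles
  path <- data.frame(from = ids[1:3], to = ids[2:4])
  st2 <- per_sample_network_stats(mk_net(path), count_table(m, "prokaryote"))
  expect_equal(st2$density, 0.5)
  expect_equal(st2$clustering, 0)
  # triangle plus disjoint edge on 5 nodes
  tri <- data.frame(from = c("A1", "A2", "A3", "A4"),
                    to = c("A2", "A3", "A1", "A5"))
  m5 <- matrix(1, 1, 5, dimnames = list("S1", ids))
  st3 <- per_sample_network_stats(mk_net(tri), count_table(m5, "prokaryote"))
  expect_equal(st3$density, 4 / 10)
  expect_equal(st3$clustering, 1)   # 3 triangles / 3 connected triples
  # fewer than 2 present nodes -> missing stats
  m1 <- matrix(c(1, 0, 0, 0, 0), 1, 5, dimnames = list("S1", ids))
  st4 <- per_sample_network_stats(mk_net(tri), count_table(m1, "prokaryote"))
  expect_true(is.na(st4$density))
})

test_that("bipartite core network keeps only positive cross-kingdom edges", {
  set.seed(6)
  n <- 30
  drive <- rlnorm(n, 0, 1)
  # P1, P2 and E1, E2 all follow one latent driver -> 4 true cross pairs
  bp <- cbind(drive, drive * 0.7, matrix(rlnorm(n * 10, 2, 1), n, 10))
  be <- cbind(drive * 1.3, drive * 0.5, matrix(rlnorm(n * 6, 2, 1), n, 6))
  pc <- t(apply(bp, 1, function(z) rmultinom(1, 4000, z / sum(z))[, 1]))
  ec <- t(apply(be, 1, function(z) rmultinom(1, 3000, z / sum(z))[, 1]))
  dimnames(pc) <- list(paste0("S", 1:n), paste0("P", 1:12))
  dimnames(ec) <- list(paste0("S", 1:n), paste0("E", 1:8))
  bn <- build_bipartite_core_network(count_table(pc, "prokaryote"),
                                     count_table(ec, "eukaryote"),
                                     sparcc_control = list(n_boot = 999),
                                     seed = 2)
  expect_true(all(bn$edges$prok %in% paste0("P", 1:12)))
  expect_true(all(bn$edges$euk %in% paste0("E", 1:8)))
  expect_true(all(bn$edges$rho > 0.6 & bn$edges$sparcc_r > 0.6))
  expect_true(any(bn$edges$prok == "P1" & bn$edges$euk == "E1"))
})
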