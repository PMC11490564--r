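test_that("environmental optima are abundance-weighted means", {
  m <- matrix(c(10, 0, 0,
                0, 5, 5), 3, 2,
              dimnames = list(paste0("S", 1:3), c("solo", "even")))
  env <- data.frame(sample_id = paste0("S", 1:3), day = c(0, 50, 200),
                    nitrate = c(12, 4, 6))
  tab <- count_table(m, "prokaryote")
  opt <- env_optima(tab, env, "nitrate")
  expect_equal(unname(opt["solo"]), 12)   # present at a single sample
  expect_equal(unname(opt["even"]), 5)    # equal counts at 4 and 6
  # random table vs a loop oracle
  set.seed(2)
  m2 <- matrix(rpois(50, 6) + 1, 5, 10,
               dimnames = list(paste0("S", 1:5), paste0("A", 1:10)))
  env2 <- data.frame(sample_id = paste0("S", 1:5), day = 1:5,
                     nitrate = rnorm(5, 10))
  o2 <- env_optima(count_table(m2, "prokaryote"), env2, "nitrate")
  for (j in 1:10) {
    acc <- 0; tot <- 0
    for (i in 1:5) { acc <- acc + m2[i, j] * env2$nitrate[i]; tot <- tot + m2[i, j] }
    expect_equal(unname(o2[j]), acc / tot, tolerance = 1e-12)
  }
  expect_error(env_optima(tab, env, "phosphate"), "unknown variable")
})

test_that("Mantel correlogram finds constructed signal and reduces to a plain Mantel", {
  tree <- simulate_tree(40, seed = 6)
  d <- ape::cophenetic.phylo(tree)
  # perfect signal: optima from the leading coordinate of the distances
  opt <- cmdscale(d, k = 1)[, 1]
  res <- mantel_correlogram(opt, tree, n_classes = 4, n_perm = 199, seed = 2)
  expect_gt(res$mantel_r[1], 0)
  expect_lt(res$p_corrected[1], 0.05)
  # single class reproduces a plain Mantel test (statistic equals
  # -cor(trait distances, indicator), indicator constant => NA guard):
  res1 <- mantel_correlogram(opt, tree, n_classes = 1, n_perm = 99, seed = 2)
  expect_identical(nrow(res1), 1L)
  ref <- vegan::mantel(as.dist(abs(outer(opt, opt, "-"))), as.dist(d),
                       permutations = 0)
  expect_equal(res1$mantel_r, ref$statistic, tolerance = 1e-10)
  expect_error(mantel_correlogram(rep(1, 40), tree), "constant")
})

test_that("weighted MPD/MNTD match picante on random communities", {
  skip_if_not_installed("picante")
  set.seed(9)
  tree <- simulate_tree(25, seed = 3)
  d <- ape::cophenetic.phylo(tree)
  for (i in 1:5) {
    x <- rand_comp(25)
    names(x) <- rownames(d)
    f <- x / sum(x)
    # picante's weighted mean runs over all ordered pairs including the
    # zero self-distances; our estimator excludes i = j, so the two agree
    # after rescaling by 1 - sum(f^2) (the SES is invariant to this)
    expect_equal(mpd_weighted(f, d) * (1 - sum(f^2)),
                 picante::mpd(matrix(x, 1, dimnames = list("s", names(x))),
                              d, abundance.weighted = TRUE),
                 tolerance = 1e-12)
    expect_equal(mntd_weighted(f, d),
                 picante::mntd(matrix(x, 1, dimnames = list("s", names(x))),
                               d, abundance.weighted = TRUE),
                 tolerance = 1e-12)
  }
})

test_that("SES null moments match exhaustive label permutation on a 4-tip tree", {
  tree <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  d <- ape::cophenetic.phylo(tree)[letters[1:4], letters[1:4]]
  f <- c(0.5, 0.5, 0, 0)          # two sister tips, equal abundance
  fi <- c(0.5, 0.5)
  stat <- function(perm) {
    idx <- perm[1:2]
    dd <- d[idx, idx]
    sum(outer(fi, fi) * dd) / (1 - sum(fi^2))   # weighted MPD
  }
  exact <- exhaustive_null_moments(stat, 4)
  r <- ses_phylo_alpha(f, d, "MPD", n_null = 999, seed = 5)
  expect_equal(r$null_mean, exact$mean,
               tolerance = 3 * exact$sd / sqrt(999) / exact$mean)
  expect_lt(abs(r$null_sd - exact$sd), 3 * exact$sd / sqrt(2 * 999))
})

test_that("degenerate nulls are flagged with SES zero", {
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  d <- ape::cophenetic.phylo(star)
  r <- ses_phylo_alpha(c(.25, .25, .25, .25), d, "MPD", 99, 1)
  expect_true(r$degenerate)
  expect_equal(r$ses, 0)
  # every pool member present at equal abundance: shuffles do nothing
  tree <- simulate_tree(8, 2)
  d2 <- ape::cophenetic.phylo(tree)
  r2 <- ses_phylo_alpha(rep(1 / 8, 8), d2, "MPD", 99, 1)
  expect_true(r2$degenerate)
  # single present ASV is undefined
  r3 <- ses_phylo_alpha(c(1, 0, 0, 0, 0, 0, 0, 0), d2, "MNTD", 99, 1)
  expect_true(r3$degenerate)
})

test_that("NRI/NTI sign convention: clustered positive, dispersed negative", {
  tree <- simulate_tree(30, seed = 8)
  d <- ape::cophenetic.phylo(tree)
  cl <- cutree(hclust(as.dist(d), "average"), k = 4)
  clade <- which(cl == which.max(table(cl)))
  f_clust <- numeric(30); f_clust[clade] <- 1 / length(clade)
  r_clust <- ses_phylo_alpha(f_clust, d, "MPD", 499, 3)
  expect_gt(r_clust$ses, 0)
  # maximally distant set: greedy far-point packing
  far <- which.max(rowSums(d))
  for (k in 1:5) far <- c(far, which.max(apply(d[, far, drop = FALSE], 1, min)))
  f_disp <- numeric(30); f_disp[unique(far)] <- 1 / length(unique(far))
  r_disp <- ses_phylo_alpha(f_disp, d, "MPD", 499, 3)
  expect_lt(r_disp$ses, 0)
})

test_that("beta-MNTD matches a double-loop oracle and its forced cases", {
  tree <- simulate_tree(15, seed = 5)
  d <- ape::cophenetic.phylo(tree)
  f <- rand_comp(15); f <- f / sum(f)
  expect_equal(beta_mntd(f, f, d), 0)               # nearest taxon is itself
  cherry <- ape::read.tree(text = "(a:1,b:1);")
  dc <- ape::cophenetic.phylo(cherry)
  expect_equal(beta_mntd(c(1, 0), c(0, 1), dc), 2)  # single forced pair
  set.seed(13)
  for (i in 1:5) {
    a <- rand_comp(15); b <- rand_comp(15)
    fa <- a / sum(a); fb <- b / sum(b)
    iA <- which(fa > 0); iB <- which(fb > 0)
    wA <- fa[iA] / sum(fa[iA]); wB <- fb[iB] / sum(fb[iB])
    accA <- 0
    for (u in seq_along(iA)) {
      best <- Inf
      for (v in seq_along(iB)) best <- min(best, d[iA[u], iB[v]])
      accA <- accA + wA[u] * best
    }
    accB <- 0
    for (v in seq_along(iB)) {
      best <- Inf
      for (u in seq_along(iA)) best <- min(best, d[iA[u], iB[v]])
      accB <- accB + wB[v] * best
    }
    expect_equal(beta_mntd(fa, fb, d), 0.5 * (accA + accB),
                 tolerance = 1e-12)
  }
})

test_that("beta-MNTD agrees with picante::comdistnt", {
  skip_if_not_installed("picante")
  tree <- simulate_tree(20, seed = 10)
  d <- ape::cophenetic.phylo(tree)
  set.seed(4)
  a <- rand_comp(20); b <- rand_comp(20)
  comm <- rbind(A = a, B = b)
  colnames(comm) <- rownames(d)
  ours <- beta_mntd(a / sum(a), b / sum(b), d)
  theirs <- as.numeric(picante::comdistnt(comm, d, abundance.weighted = TRUE))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("betaNTI null matches exhaustive tip shuffling on a 5-tip tree", {
  tree <- simulate_tree(5, seed = 12)
  d <- ape::cophenetic.phylo(tree)
  fA <- c(0.6, 0.4, 0, 0, 0)
  fB <- c(0, 0.5, 0.5, 0, 0)
  iA <- which(fA > 0); iB <- which(fB > 0)
  wA <- fA[iA] / sum(fA[iA]); wB <- fB[iB] / sum(fB[iB])
  stat <- function(perm) {
    dd <- d[perm[iA], perm[iB], drop = FALSE]
    0.5 * (sum(wA * apply(dd, 1, min)) + sum(wB * apply(dd, 2, min)))
  }
  exact <- exhaustive_null_moments(stat, 5)
  r <- bnti(fA, fB, d, n_null = 999, seed = 3)
  expect_lt(abs(r$null_mean - exact$mean), 3 * exact$sd / sqrt(999))
  expect_lt(abs(r$null_sd - exact$sd), 3 * exact$sd / sqrt(2 * 999))
  # identical communities: observed 0 is the attainable minimum
  rid <- bnti(fA, fA, d, n_null = 199, seed = 2)
  expect_lte(rid$bnti, 0)
  # determinism
  expect_identical(bnti(fA, fB, d, 199, 7)$bnti, bnti(fA, fB, d, 199, 7)$bnti)
})

test_that("Raup-Crick matches exact enumeration on a 3-ASV universe", {
  # pool with known occupancy/abundance weights; richness-1 samples
  m <- matrix(c(4, 0, 0,
                3, 2, 0,
                5, 3, 1), 3, 3, byrow = TRUE,
              dimnames = list(paste0("S", 1:3), c("x", "y", "z")))
  pool <- count_table(m, "prokaryote")
  occupancy <- colSums(m > 0)            # 3, 2, 1
  relabund <- colSums(m) / sum(m)
  A <- c(7, 0, 0); B <- c(0, 4, 0)       # richness 1, totals 7 and 4
  obs <- bray_curtis(A, B)
  pick <- occupancy / sum(occupancy)
  # null: each sample independently lands all reads on one weighted ASV
  nulls <- expand.grid(i = 1:3, j = 1:3)
  nulls$prob <- pick[nulls$i] * pick[nulls$j]
  nulls$bc <- ifelse(nulls$i == nulls$j, 1 - 2 * 4 / 11, 1)
  p_lt <- sum(nulls$prob[nulls$bc < obs - 1e-12])
  p_eq <- sum(nulls$prob[abs(nulls$bc - obs) <= 1e-12])
  exact_rc <- 2 * (p_lt + 0.5 * p_eq) - 1
  r <- raup_crick_bray(A, B, pool, n_null = 4999, seed = 6)
  expect_equal(r$rc, exact_rc, tolerance = 0.05)
  expect_gte(r$rc, -1); expect_lte(r$rc, 1)
})

test_that("Raup-Crick of identical samples is at the lower extreme", {
  set.seed(5)
  m <- matrix(rpois(80, 5) + 1, 8, 10,
              dimnames = list(paste0("S", 1:8), paste0("A", 1:10)))
  pool <- count_table(m, "prokaryote")
  r <- raup_crick_bray(m[1, ], m[1, ], pool, n_null = 999, seed = 2)
  expect_lte(r$rc, -0.95)
  expect_identical(raup_crick_bray(m[1, ], m[2, ], pool, 199, 9)$rc,
                   raup_crick_bray(m[1, ], m[2, ], pool, 199, 9)$rc)
})

test_that("turnover series yields one record per successive pair", {
  sc <- scenario("neutral", n_samples = 6, n_prok = 20, n_euk = 10,
                 depth_prok = 300, depth_euk = 300, seed = 14)
  sim <- simulate_reactor_series(sc)
  ts <- turnover_series(sim$prok_table, sim$prok_tree, n_null = 99, seed = 3)
  expect_identical(nrow(ts), 5L)
  expect_true(all(ts$rc_bray >= -1 & ts$rc_bray <= 1))
  expect_identical(ts$pair, 1:5)
})
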