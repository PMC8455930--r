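test_that("ld_prune keeps everything at r2_max = 1 and dedups perfect LD", {
  G <- random_genotypes(100, 10, seed = 13)
  ss <- toy_sumstats(G$markers$id, beta = rep(0.1, 10),
                     p = seq(0.01, 0.1, by = 0.01))
  expect_setequal(ld_prune(G, ss, r2_max = 1, window = 21), G$markers$id)
  # duplicate a column: the smaller-P copy must win
  counts <- G$counts
  counts[, 5] <- counts[, 4]
  Gd <- toy_genotypes(counts)
  p <- rep(0.5, 10); p[4] <- 0.2; p[5] <- 0.01
  ssd <- toy_sumstats(Gd$markers$id, beta = rep(0.1, 10), p = p)
  kept <- ld_prune(Gd, ssd, r2_max = 0.5, window = 21)
  expect_true(Gd$markers$id[5] %in% kept)
  expect_false(Gd$markers$id[4] %in% kept)
})

test_that("ld_prune output passes exhaustive pairwise verification", {
  cfg <- sim_config(150, 30, block_size = 10, within_block_rho = 0.9,
                    seed = 14)
  G <- simulate_genotypes(cfg)
  set.seed(14)
  ss <- toy_sumstats(G$markers$id, beta = rnorm(30), p = runif(30))
  for (r2max in c(0.1, 0.5)) {
    kept <- ld_prune(G, ss, r2_max = r2max, window = 30)
    expect_gt(length(kept), 0)
    ki <- match(kept, G$markers$id)
    # every kept pair within the window satisfies the ceiling
    for (a in seq_along(ki)) for (b in seq_along(ki)) {
      if (a >= b || abs(ki[a] - ki[b]) > 15) next
      expect_lt(adjusted_r2(G$counts[, ki[a]], G$counts[, ki[b]]), r2max)
    }
    # P-priority: every dropped marker conflicts with a kept marker of
    # smaller or equal P inside the window (ss rows align with markers)
    for (d in setdiff(seq_len(30), ki)) {
      nb <- ki[abs(ki - d) <= 15]
      conflicts <- nb[vapply(nb, function(k2)
        adjusted_r2(G$counts[, d], G$counts[, k2]) >= r2max, TRUE)]
      expect_gt(length(conflicts), 0)
      expect_lte(min(ss$p[conflicts]), ss$p[d])
    }
  }
})

test_that("p_threshold uses a strict cutoff", {
  ss <- toy_sumstats(sprintf("m%02d", 1:10), beta = rep(0.1, 10),
                     p = c(0.01, 0.02, 0.03, 0.04, 0.2, 0.3, 0.4, 0.6, 0.8, 0.9))
  expect_equal(length(p_threshold(ss, 0.05)), 4)
  expect_setequal(p_threshold(ss, 0.91), ss$id)
  expect_false("m01" %in% p_threshold(ss, 0.01))  # boundary is exclusive
  # the two threshold grids differ only in their upper intermediate steps
  expect_equal(max(default_p_grid("st")), max(default_p_grid("mt")))
  expect_true(all(default_p_grid("mt") %in%
                    c(default_p_grid("st"), 0.75, 0.5)))
})

test_that("st_grs is the allele-count / effect dot product", {
  set.seed(15)
  counts <- matrix(rbinom(40, 2, 0.4), 5, 8)
  G <- toy_genotypes(counts)
  beta <- rnorm(8)
  ss <- toy_sumstats(G$markers$id, beta = beta)
  sc <- st_grs(G, ss)
  expect_equal(sc$score, as.vector(counts %*% beta), tolerance = 1e-12)
  # all-zero effects give all-zero scores
  ss0 <- toy_sumstats(G$markers$id, beta = rep(0, 8))
  expect_equal(st_grs(G, ss0)$score, rep(0, 5))
  # single marker with beta 1 returns the allele count
  sc1 <- st_grs(G, ss, markers = G$markers$id[3])
  expect_equal(sc1$score, counts[, 3] * beta[3])
  # missing genotypes imputed to 2 * af from the training stats
  counts_na <- counts; counts_na[2, 4] <- NA
  Gna <- toy_genotypes(counts_na)
  scna <- st_grs(Gna, ss)
  expected <- sum(counts_na[2, -4] * beta[-4]) + 2 * ss$af[4] * beta[4]
  expect_equal(scna$score[2], expected, tolerance = 1e-12)
  expect_error(st_grs(G, ss, markers = character(0)), "empty")
})

test_that("index_weights solves the scalar and 2x2 cases exactly", {
  # scalar case: arithmetic forced
  iw1 <- index_weights(h2 = 0.3, N = 200000, M = 60000)
  expect_equal(iw1$w, 0.5)
  # 2x2 against an explicit inverse computed by hand
  h2 <- c(0.5, 0.5); N <- c(10000, 10000); M <- 60000; rg <- 0.5
  iw2 <- index_weights(h2, matrix(c(1, rg, rg, 1), 2), N, M)
  v11 <- h2[1] / M + 1 / N[1]
  v22 <- h2[2] / M + 1 / N[2]
  v12 <- rg * sqrt(h2[1] * h2[2]) / M
  det <- v11 * v22 - v12^2
  Vinv <- matrix(c(v22, -v12, -v12, v11), 2) / det
  C <- c(h2[1] / M, rg * sqrt(h2[1] * h2[2]) / M)
  expect_equal(iw2$w, as.vector(Vinv %*% C), tolerance = 1e-12)
  # residual of the linear system is tiny
  expect_lt(max(abs(iw2$V %*% iw2$w - iw2$C)), 1e-10)
  # uncorrelated information traits get exactly zero weight
  rg0 <- diag(3)
  rg0[2, 3] <- rg0[3, 2] <- 0.4
  iw3 <- index_weights(c(0.3, 0.5, 0.5), rg0, N = rep(1e4, 3), M = 60000)
  expect_equal(iw3$w[2:3], c(0, 0))
  expect_gt(iw3$w[1], 0)
})

test_that("index_weights guards against an ill-conditioned V", {
  # wildly mismatched trait scales push the condition number past the guard
  expect_error(index_weights(c(1, 1e-14), matrix(c(1, 0.5, 0.5, 1), 2),
                             N = c(1e16, 1e16), M = 1),
               "ill-conditioned|singular")
  # perfectly duplicated traits are rescued by the rg clamp, not an error
  iw <- index_weights(c(0.5, 0.5), matrix(1, 2, 2), N = c(1e4, 1e4),
                      M = 60000)
  expect_true(all(is.finite(iw$w)))
})

test_that("weight magnitudes track rg and N in a study-like setting", {
  # information traits with larger rg to the focal trait and larger N must
  # receive the larger non-focal weight
  rg <- diag(4)
  rg[1, 2:4] <- rg[2:4, 1] <- c(0.58, 0.55, 0.1)   # BMI-like, medication-like, weak
  off <- rg[2:4, 2:4]; off[row(off) != col(off)] <- 0.3; rg[2:4, 2:4] <- off
  iw <- index_weights(c(0.07, 0.25, 0.3, 0.4), rg,
                      N = c(3e5, 3e5, 3e5, 3e5), M = 60000)
  wk <- abs(iw$w[-1])
  expect_equal(which.max(wk), 1)          # largest-rg trait dominates
  expect_gt(min(wk[1:2]), wk[3])          # both strong traits beat the weak one
})

test_that("mt_adjust_effects computes weighted effect sums", {
  ids <- sprintf("m%02d", 1:6)
  b1 <- c(0.1, -0.2, 0.3, 0, 0.05, -0.1)
  b2 <- c(0.2, 0.1, -0.3, 0.4, 0, 0.1)
  b3 <- c(-0.1, 0, 0.2, 0.1, 0.3, -0.2)
  s1 <- toy_sumstats(ids, b1); s2 <- toy_sumstats(ids, b2)
  s3 <- toy_sumstats(ids, b3)
  w <- c(0.6, 0.3, -0.2)
  adj <- mt_adjust_effects(list(s1, s2, s3), w)
  expect_equal(adj$beta, 0.6 * b1 + 0.3 * b2 - 0.2 * b3, tolerance = 1e-12)
  expect_equal(adj$p, s1$p)  # focal P carried through
  expect_identical(attr(adj, "model"), "index")
  # identity weights reproduce the focal effects
  expect_equal(mt_adjust_effects(list(s1, s2), c(1, 0))$beta, b1)
  # convexity: equal traits, averaging weights
  expect_equal(mt_adjust_effects(list(s1, s1), c(0.5, 0.5))$beta, b1)
  # marker-set mismatch errors
  s4 <- toy_sumstats(rev(ids), b2)
  expect_error(mt_adjust_effects(list(s1, s4), c(0.5, 0.5)), "share")
})

test_that("mt_grs with unit focal weight reproduces st_grs bit for bit", {
  set.seed(16)
  G <- random_genotypes(50, 12, seed = 16)
  ss1 <- toy_sumstats(G$markers$id, rnorm(12), p = runif(12))
  ss2 <- toy_sumstats(G$markers$id, rnorm(12), p = runif(12))
  adj <- mt_adjust_effects(list(ss1, ss2), c(1, 0))
  expect_identical(mt_grs(G, adj)$score, st_grs(G, ss1)$score)
  # positive rescaling of the weights rescales the scores linearly
  adj2 <- mt_adjust_effects(list(ss1, ss2), c(2.5, 0))
  expect_equal(mt_grs(G, adj2)$score, 2.5 * st_grs(G, ss1)$score,
               tolerance = 1e-12)
})

test_that("build_scenario assembles the documented trait sets", {
  mk <- function(tr) toy_sumstats(sprintf("m%02d", 1:5), rnorm(5), trait = tr)
  set.seed(17)
  focal <- mk("t2dm")
  info <- setNames(lapply(paste0("info", 1:7), mk), paste0("info", 1:7))
  ext <- setNames(lapply(c("scott", "zhao"), mk), c("scott", "zhao"))
  s1 <- build_scenario("S1", focal, info)
  expect_equal(length(s1$stats), 8)
  expect_equal(s1$labels[1], "focal")
  s2 <- build_scenario("S2", focal, info, ext, which_external = "scott")
  expect_equal(length(s2$stats), 8)
  expect_equal(s2$labels[1], "scott")
  s3 <- build_scenario("S3", focal, info, ext, which_external = "zhao")
  expect_equal(length(s3$stats), 9)
  s4 <- build_scenario("S4", focal, info, ext)
  expect_equal(length(s4$stats), 10)
  expect_equal(s4$labels[1], "focal")
  expect_error(build_scenario("S2", focal, info), "external")
})
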