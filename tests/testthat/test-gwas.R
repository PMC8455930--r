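test_that("qc_filter_markers applies the standard thresholds per criterion", {
  # 10 markers: 2 below MAF, 1 too-missing, 1 inside an excluded region
  set.seed(1)
  counts <- sapply(c(0.002, 0.004, rep(0.3, 8)), function(f) rbinom(400, 2, f))
  counts[1:40, 3] <- NA                      # 10% missingness
  G <- toy_genotypes(counts)
  reg <- list(c("1", G$markers$pos[7], G$markers$pos[7]))
  out <- qc_filter_markers(G, maf_min = 0.01, miss_max = 0.05,
                           exclude_regions = reg)
  rem <- attr(out, "qc_removed")
  expect_equal(nrow(out$markers), 6)
  expect_equal(unname(rem["maf"]), 2)
  expect_equal(unname(rem["missingness"]), 1)
  expect_equal(unname(rem["region"]), 1)
  expect_equal(unname(rem["total"]), 4)
  # counts can exceed input-minus-output when criteria overlap
  expect_gte(sum(rem[c("maf", "missingness", "region")]),
             nrow(G$markers) - nrow(out$markers))
  # no regions + clean fixture: identity
  clean <- qc_filter_markers(toy_genotypes(counts[, 4:10]))
  expect_equal(clean$markers$id, toy_genotypes(counts[, 4:10])$markers$id)
})

test_that("inverse_rank_normalize uses Blom scores and preserves order", {
  v <- c(3, 1, 4, 1.5, 9)
  out <- inverse_rank_normalize(v)
  # smallest of n=5: qnorm((1 - 3/8) / 5.25)
  expect_equal(out[2], qnorm(0.625 / 5.25), tolerance = 1e-9)
  expect_equal(qnorm(0.625 / 5.25), -1.1798, tolerance = 1e-4)
  expect_identical(order(out), order(v))
  sym <- c(-2, -1, 0, 1, 2)
  expect_equal(sum(inverse_rank_normalize(sym)), 0, tolerance = 1e-12)
  expect_true(all(diff(inverse_rank_normalize(sort(rnorm(50)))) > 0))
  expect_error(inverse_rank_normalize(rep(1, 10)), "distinct")
  # ties share the average rank
  out_t <- inverse_rank_normalize(c(1, 1, 2))
  expect_equal(out_t[1], out_t[2])
})

test_that("adjust_phenotype matches a normal-equations oracle", {
  set.seed(2)
  n <- 60
  covar <- data.frame(sex = rbinom(n, 1, 0.5), age = rnorm(n, 55, 8))
  y <- 0.5 * covar$sex - 0.02 * covar$age + rnorm(n)
  adj <- adjust_phenotype(y, covar)
  X <- cbind(1, covar$sex, covar$age)
  res_oracle <- y - X %*% solve(crossprod(X), crossprod(X, y))
  expect_equal(adj, inverse_rank_normalize(as.vector(res_oracle)),
               tolerance = 1e-10)
  expect_lt(abs(mean(adj)), 0.05)
  expect_equal(sd(adj), 1, tolerance = 0.1)
  # y perfectly linear in a covariate -> degenerate residuals
  expect_error(adjust_phenotype(2 + 3 * covar$age, covar), "constant")
})

test_that("linear marginal_gwas matches the closed-form OLS oracle", {
  set.seed(3)
  G <- random_genotypes(200, 5, seed = 3)
  y <- rnorm(200) + 0.3 * G$counts[, 2]
  ss <- marginal_gwas(G, y, model = "linear")
  for (j in 1:5) {
    x <- G$counts[, j]
    b_oracle <- cov(x, y) / var(x)
    expect_equal(ss$beta[j], b_oracle, tolerance = 1e-10)
  }
  # t statistic equals beta / se and P is the two-sided t tail
  tstat <- ss$beta / ss$se
  expect_equal(ss$p, 2 * pt(-abs(tstat), 200 - 2), tolerance = 1e-12)
})

test_that("linear marginal_gwas with covariates matches lm()", {
  set.seed(4)
  G <- random_genotypes(150, 4, seed = 4, missing_rate = 0.03)
  covar <- data.frame(sex = rbinom(150, 1, 0.5), age = rnorm(150))
  y <- rnorm(150) + 0.2 * covar$age
  ss <- marginal_gwas(G, y, covar, model = "linear")
  for (j in 1:4) {
    d <- data.frame(y = y, g = G$counts[, j], covar)
    fit <- summary(lm(y ~ sex + age + g, data = d))$coefficients
    expect_equal(ss$beta[j], fit["g", "Estimate"], tolerance = 1e-8)
    expect_equal(ss$se[j], fit["g", "Std. Error"], tolerance = 1e-8)
    expect_equal(ss$p[j], fit["g", "Pr(>|t|)"], tolerance = 1e-8)
    expect_equal(ss$n[j], sum(!is.na(G$counts[, j])))
  }
})

test_that("logistic marginal_gwas matches a brute-force likelihood scan", {
  # 2 x 3 genotype-by-case table expanded into individual observations
  tab <- rbind(ctrl = c(50, 30, 10), case = c(20, 25, 15))
  g <- rep(rep(0:2, 2), times = as.vector(t(tab)))
  y <- rep(c(0, 1), times = rowSums(tab))
  G <- toy_genotypes(matrix(g, ncol = 1))
  ss <- marginal_gwas(G, y, model = "logistic")
  ll <- function(a, b) sum(y * (a + b * g) - log(1 + exp(a + b * g)))
  grid_b <- seq(0.2, 1.2, by = 5e-4)
  prof <- vapply(grid_b, function(b) {
    optimize(function(a) -ll(a, b), c(-5, 5))$objective
  }, 0)
  expect_equal(ss$beta[1], grid_b[which.min(prof)], tolerance = 2e-3)
  # and against glm for beta and se
  fit <- summary(glm(y ~ g, family = binomial()))$coefficients
  expect_equal(ss$beta[1], fit["g", "Estimate"], tolerance = 1e-6)
  expect_equal(ss$se[1], fit["g", "Std. Error"], tolerance = 1e-6)
})

test_that("null GWAS is calibrated and monomorphic markers are flagged", {
  set.seed(5)
  G <- random_genotypes(300, 200, seed = 5)
  G$counts[, 7] <- 1L  # monomorphic
  G <- toy_genotypes(G$counts)
  y <- rnorm(300)
  ss <- marginal_gwas(G, y, model = "linear")
  expect_false(ss$valid[7])
  expect_true(is.na(ss$se[7]))
  frac <- mean(ss$p[ss$valid] < 0.05)
  expect_lt(abs(frac - 0.05), 0.05)
})

test_that("or_to_beta inverts the Wald relation", {
  conv <- or_to_beta(1.5, 0.05)
  expect_equal(conv$beta, log(1.5), tolerance = 1e-9)
  expect_equal(conv$se, log(1.5) / qnorm(0.975), tolerance = 1e-6)
  expect_equal(conv$se, 0.2069, tolerance = 1e-3)
  # round trip: z = beta/se -> p
  p_back <- 2 * (1 - pnorm(conv$beta / conv$se))
  expect_equal(p_back, 0.05, tolerance = 1e-9)
  # degenerate cases flagged invalid
  expect_false(or_to_beta(1, 0.5)$valid)
  expect_false(or_to_beta(2, 1)$valid)
  expect_error(or_to_beta(-1, 0.5), "positive")
})

test_that("harmonize aligns orientation and is an involution", {
  ref <- data.frame(id = sprintf("m%02d", 1:10),
                    effect_allele = rep("A", 10), other_allele = rep("G", 10))
  beta0 <- seq(-0.5, 0.4, by = 0.1)
  ea <- rep("A", 10); oa <- rep("G", 10)
  swap <- 5:8
  ea[swap] <- "G"; oa[swap] <- "A"
  ea[9:10] <- "T"; oa[9:10] <- "C"  # incompatible pair
  ext <- toy_sumstats(ref$id, beta0, ea = ea, oa = oa, af = rep(0.2, 10))
  out <- harmonize(ext, ref)
  cnt <- attr(out, "harmonize_counts")
  expect_equal(nrow(out), 8)
  expect_equal(unname(cnt), c(4, 4, 2))
  expect_equal(out$beta[match(sprintf("m%02d", swap), out$id)], -beta0[swap])
  expect_equal(out$af[match(sprintf("m%02d", swap), out$id)],
               rep(0.8, 4))
  # identity case
  same <- toy_sumstats(ref$id[1:4], beta0[1:4])
  expect_equal(harmonize(same, ref)$beta, beta0[1:4])
  # involution: flipping a fully-swapped file twice returns the original
  flipped <- toy_sumstats(ref$id, beta0, ea = rep("G", 10), oa = rep("A", 10))
  once <- harmonize(flipped, ref)
  back <- harmonize(once, data.frame(id = ref$id, effect_allele = "G",
                                     other_allele = "A"))
  expect_equal(back$beta, beta0)
  expect_error(harmonize(toy_sumstats("zz", 0.1), ref), "overlap")
})
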