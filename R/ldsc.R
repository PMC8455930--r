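#' Bias-adjusted squared correlation between two genotype columns
#'
#' The sample squared Pearson correlation overestimates the population
#' r-squared; the small-sample adjustment
#' `r2_adj = r2 - (1 - r2) / (n - 2)` removes the leading bias term. Computed
#' on pairwise-complete samples.
#'
#' @param x,z Numeric genotype vectors of equal length.
#' @param n Sample count used in the adjustment; defaults to the number of
#'   pairwise-complete observations.
#' @return The adjusted squared correlation (can be slightly negative).
#' @export
adjusted_r2 <- function(x, z, n = NULL) {
  ok <- !is.na(x) & !is.na(z)
  x <- x[ok]; z <- z[ok]
  if (is.null(n)) n <- length(x)
  if (n <= 2) stop("adjusted r2 requires n > 2")
  if (sd(x) == 0 || sd(z) == 0) stop("constant genotype column")
  r2 <- cor(x, z)^2
  r2 - (1 - r2) / (n - 2)
}

#' Windowed LD scores
#'
#' The LD score of marker `i` is the sum of bias-adjusted squared
#' correlations between marker `i` and every marker within a window of
#' `window` markers centred on `i` (i.e. `floor(window/2)` markers to each
#' side), including the self term, which is exactly 1. Windows are truncated
#' at chromosome boundaries and never span chromosomes. The default window
#' of 5,000 markers (2,500 to each side) suits dense genome-wide panels;
#' for synthetic data with short LD blocks a much smaller window captures
#' all non-null LD.
#'
#' Missing genotypes are mean-imputed before the correlations are formed
#' (columns are standardized on the full sample), which matches
#' [adjusted_r2()] exactly when there is no missingness.
#'
#' @param G A [genotype_matrix()], markers position-sorted within chromosome.
#' @param window Window size in markers (>= 1; 1 gives `l = 1` everywhere).
#' @return A data frame of class `ld_score_track` with columns `id, chrom,
#'   pos, l` and attributes `window` and `n_ref`.
#' @export
ld_scores <- function(G, window = 5000L) {
  stopifnot(window >= 1)
  n <- length(G$samples)
  if (n <= 2) stop("LD scores require more than 2 samples")
  half <- floor(window / 2)
  mk <- G$markers
  l <- rep(NA_real_, nrow(mk))
  S <- standardize_genotypes(G$counts)
  zero <- attr(S, "zero_var")
  for (ch in unique(mk$chrom)) {
    cols <- which(mk$chrom == ch)
    mc <- length(cols)
    Sc <- S[, cols, drop = FALSE]
    lc <- numeric(mc)
    chunk <- max(1L, min(mc, max(256L, 2L * half)))
    for (a in seq(1L, mc, by = chunk)) {
      b <- min(mc, a + chunk - 1L)
      lo <- max(1L, a - half); hi <- min(mc, b + half)
      R <- crossprod(Sc[, a:b, drop = FALSE],
                     Sc[, lo:hi, drop = FALSE]) / (n - 1)
      r2 <- R^2
      r2a <- r2 - (1 - r2) / (n - 2)
      # mask pairs outside the marker window
      di <- abs(outer(a:b, lo:hi, "-"))
      r2a[di > half] <- 0
      lc[a:b] <- rowSums(r2a)
    }
    l[cols] <- lc
  }
  if (length(zero)) l[zero] <- NA_real_
  out <- data.frame(id = mk$id, chrom = mk$chrom, pos = mk$pos, l = l,
                    stringsAsFactors = FALSE)
  structure(out, class = c("ld_score_track", "data.frame"),
            window = as.integer(window), n_ref = n)
}

#' Effective sample size from summary statistics
#'
#' Recovers the effective number of observations as the median over valid
#' markers of `1 / (2 * af * (1 - af) * se^2)`: for a variance-1 outcome the
#' sampling variance of a marginal allele-count coefficient is approximately
#' `1 / (n * 2 af (1 - af))`, so each marker gives an estimate of `n` and
#' the median is robust to outliers.
#'
#' @param ss A [summary_stats()] object.
#' @return The effective sample size (scalar).
#' @export
estimate_n_eff <- function(ss) {
  ok <- !is.na(ss$af) & ss$af > 0 & ss$af < 1 &
    !is.na(ss$se) & ss$se > 0 & (ss$valid %||% TRUE)
  if (!any(ok)) stop("no valid markers for n_eff estimation")
  median(1 / (2 * ss$af[ok] * (1 - ss$af[ok]) * ss$se[ok]^2))
}

# Align a summary_stats object to an ld_score_track by marker id; returns
# the joined data with invalid rows removed.
.align_ss_ld <- function(ss, ld, ss2 = NULL) {
  idx <- match(ld$id, ss$id)
  keep <- !is.na(idx) & is.finite(ld$l)
  d <- data.frame(l = ld$l[keep], z = (ss$beta / ss$se)[idx[keep]],
                  valid = ss$valid[idx[keep]])
  if (!is.null(ss2)) {
    idx2 <- match(ld$id, ss2$id)
    d$z2 <- (ss2$beta / ss2$se)[idx2[keep]]
    d$valid <- d$valid & !is.na(idx2[keep]) & ss2$valid[idx2[keep]]
  }
  d <- d[d$valid & is.finite(d$z) & (if (is.null(ss2)) TRUE else is.finite(d$z2)), ]
  if (!nrow(d)) stop("no valid aligned markers")
  d
}

#' Heritability by summary-statistic LD-score regression
#'
#' Regresses the squared association z-scores `y = (beta/se)^2` on
#' `Z = n_eff * l / m`. With `intercept = FALSE` (default) the slope is the
#' plain no-intercept least-squares coefficient `(Z'Z)^{-1} Z'y`; with
#' `intercept = TRUE` an intercept absorbs the unit null expectation of a
#' chi-square statistic (`E[z^2] = 1 + Z h2`), which removes the upward bias
#' of the no-intercept form and is the recommended setting for estimation
#' (see the vignette).
#'
#' @param ss A [summary_stats()] object.
#' @param ld An [ld_scores()] track aligned by marker id.
#' @param m Number of markers the polygenic signal is spread over
#'   (default: markers in `ss`).
#' @param n_eff Effective sample size; default [estimate_n_eff()] of `ss`.
#' @param intercept `"none"` (or `FALSE`): the literal no-intercept form;
#'   `"free"` (or `TRUE`): estimate the intercept; `"fixed"`: constrain the
#'   intercept to `intercept_value` and regress `y - intercept_value`
#'   through the origin.
#' @param intercept_value Constrained intercept for `intercept = "fixed"`;
#'   the null expectation of a squared z-score is 1.
#' @return Heritability estimate on the observed scale (unbounded; negative
#'   values possible in noisy data) with attribute `intercept_value`.
#' @export
estimate_h2 <- function(ss, ld, m = NULL, n_eff = NULL, intercept = "none",
                        intercept_value = 1) {
  m <- m %||% nrow(ss)
  stopifnot(m >= 1)
  n_eff <- n_eff %||% estimate_n_eff(ss)
  d <- .align_ss_ld(ss, ld)
  Zv <- n_eff * d$l / m
  y <- d$z^2
  if (all(Zv == 0)) stop("all-zero regressor; check LD scores and n_eff")
  r <- .ldsc_regress(Zv, y, intercept, intercept_value)
  structure(unname(r$slope), intercept_value = r$icpt, n_eff = n_eff)
}

# Shared slope machinery for the three intercept treatments.
.ldsc_regress <- function(Zv, y, intercept, intercept_value = 0) {
  if (is.logical(intercept)) intercept <- if (intercept) "free" else "none"
  intercept <- match.arg(intercept, c("none", "free", "fixed"))
  switch(intercept,
    none = list(slope = sum(Zv * y) / sum(Zv^2), icpt = 0),
    free = {
      cf <- lm.fit(cbind(1, Zv), y)$coefficients
      list(slope = unname(cf[2L]), icpt = unname(cf[1L]))
    },
    fixed = list(slope = sum(Zv * (y - intercept_value)) / sum(Zv^2),
                 icpt = intercept_value))
}

#' Genetic correlation by summary-statistic LD-score regression
#'
#' Regresses the product of the two traits' association z-scores on
#' `Z = sqrt(n1 * n2) * l / m` and divides the slope by
#' `sqrt(h2_1 * h2_2)`. The raw (unbounded) estimate is retained as an
#' attribute; the returned value is clamped to `[-1, 1]`.
#'
#' @param ss1,ss2 [summary_stats()] for the two traits on shared markers.
#' @param ld An [ld_scores()] track.
#' @param h2_1,h2_2 Heritabilities of the two traits (must be positive).
#' @param m Marker count (default: markers in `ss1`).
#' @param n1,n2 Sample sizes; default effective sizes from each file.
#' @param intercept As in [estimate_h2()]. The null expectation of the
#'   z-score product is 0 for independent cohorts; when the two GWAS share
#'   samples it is the phenotypic correlation times the overlap fraction,
#'   which a `"fixed"` intercept can absorb via `intercept_value`.
#' @param intercept_value Constrained intercept for `intercept = "fixed"`.
#' @return Clamped genetic correlation with attribute `raw`.
#' @export
estimate_rg <- function(ss1, ss2, ld, h2_1, h2_2, m = NULL,
                        n1 = NULL, n2 = NULL, intercept = "none",
                        intercept_value = 0) {
  if (h2_1 <= 0 || h2_2 <= 0) stop("heritabilities must be positive")
  m <- m %||% nrow(ss1)
  n1 <- n1 %||% estimate_n_eff(ss1)
  n2 <- n2 %||% estimate_n_eff(ss2)
  d <- .align_ss_ld(ss1, ld, ss2)
  Zv <- sqrt(n1 * n2) * d$l / m
  y <- d$z * d$z2
  if (all(Zv == 0)) stop("all-zero regressor")
  r <- .ldsc_regress(Zv, y, intercept, intercept_value)
  raw <- r$slope / sqrt(h2_1 * h2_2)
  structure(clamp(raw, -1, 1), raw = raw)
}

#' Convert observed-scale heritability to the liability scale
#'
#' For a binary trait analysed as 0/1 in a population sample with case
#' prevalence `K`, the standard transform is
#' `h2_liab = h2_obs * K (1 - K) / phi(Phi^{-1}(1 - K))^2`, where `phi` is
#' the standard-normal density at the liability threshold.
#'
#' @param h2_obs Observed-scale heritability (>= 0).
#' @param K Case prevalence in (0, 1).
#' @return Liability-scale heritability.
#' @export
observed_to_liability <- function(h2_obs, K) {
  if (K <= 0 || K >= 1) stop("K must lie in (0, 1)")
  stopifnot(h2_obs >= 0)
  h2_obs * K * (1 - K) / dnorm(qnorm(1 - K))^2
}
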