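#' QC-filter markers by frequency, missingness and excluded regions
#'
#' Removes markers with minor allele frequency below `maf_min`, genotype
#' missingness above `miss_max`, or position inside any exclusion region
#' (1-based inclusive coordinates; used e.g. to drop the extended MHC).
#' The defaults are the conventional GWAS hard-call thresholds
#' (MAF >= 0.01, missingness <= 5%).
#'
#' @param G A [genotype_matrix()].
#' @param maf_min Minimum minor allele frequency.
#' @param miss_max Maximum per-marker missingness fraction.
#' @param exclude_regions List of `c(chrom, start, end)` triplets (or a
#'   3-column data frame) in 1-based inclusive coordinates.
#' @return The filtered `genotype_matrix`, marker order preserved, with an
#'   attribute `qc_removed`: named counts of markers failing each criterion
#'   (a marker can fail several) and the total removed.
#' @export
qc_filter_markers <- function(G, maf_min = 0.01, miss_max = 0.05,
                              exclude_regions = list()) {
  stopifnot(maf_min >= 0, maf_min <= 0.5, miss_max >= 0, miss_max <= 1)
  mk <- G$markers
  maf <- pmin(mk$af, 1 - mk$af)
  fail_maf <- maf < maf_min
  fail_miss <- mk$missingness > miss_max
  fail_region <- rep(FALSE, nrow(mk))
  if (is.data.frame(exclude_regions))
    exclude_regions <- asplit(exclude_regions, 1L)
  for (reg in exclude_regions) {
    ch <- as.character(reg[[1]])
    lo <- as.numeric(reg[[2]]); hi <- as.numeric(reg[[3]])
    fail_region <- fail_region |
      (mk$chrom == ch & mk$pos >= lo & mk$pos <= hi)
  }
  drop <- fail_maf | fail_miss | fail_region
  if (all(drop)) warning("QC removed every marker")
  out <- subset_genotypes(G, markers = which(!drop))
  attr(out, "qc_removed") <- c(maf = sum(fail_maf), missingness = sum(fail_miss),
                               region = sum(fail_region), total = sum(drop))
  out
}

#' Inverse rank normalization
#'
#' Rank-preserving map to standard-normal quantiles using the Blom offset:
#' `qnorm((rank - 3/8) / (n + 1/4))`, with average ranks for ties. `NA`s are
#' preserved in place and excluded from ranking.
#'
#' @param v Numeric vector with at least two distinct non-missing values.
#' @return Numeric vector of the same length.
#' @export
inverse_rank_normalize <- function(v) {
  ok <- !is.na(v)
  x <- v[ok]
  if (length(unique(x)) < 2L)
    stop("inverse rank normalization requires >= 2 distinct values")
  r <- rank(x, ties.method = "average")
  out <- v
  out[ok] <- qnorm((r - 3 / 8) / (length(x) + 1 / 4))
  out
}

#' Covariate-adjust a quantitative trait
#'
#' Regresses the trait on the covariates by least squares and inverse-rank
#' normalizes the residuals, the standard preparation of quantitative traits
#' before marginal association testing. The result has mean ~0, variance ~1.
#'
#' @param y Numeric trait vector.
#' @param covariates Data frame or matrix of covariates (no intercept
#'   column needed; one is added).
#' @return Numeric vector of adjusted, normalized values.
#' @export
adjust_phenotype <- function(y, covariates) {
  X <- cbind(`(Intercept)` = 1, as.matrix(covariates))
  if (anyNA(X)) stop("missing covariate values are not allowed")
  fit <- lm.fit(X, y)
  res <- fit$residuals
  if (var(res) < .Machine$double.eps^0.5 * max(1, var(y)))
    stop("residuals are (near-)constant; rank normalization undefined")
  inverse_rank_normalize(res)
}

#' Construct a summary-statistics object
#' @param df Data frame with columns `id, chrom, pos, effect_allele,
#'   other_allele, af, beta, se, p, n` (and optionally `valid`).
#' @param trait Trait label.
#' @param model `"linear"`, `"logistic"` or `"index"` (effects re-weighted
#'   across traits).
#' @return The data frame with class `summary_stats` and attributes `trait`
#'   and `model`.
#' @export
summary_stats <- function(df, trait = "trait", model = "linear") {
  need <- c("id", "chrom", "pos", "effect_allele", "other_allele",
            "af", "beta", "se", "p", "n")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("missing summary-stat columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$id)) stop("marker ids must be unique")
  if (is.null(df$valid)) df$valid <- is.finite(df$se) & df$se > 0 &
      is.finite(df$p) & df$p > 0 & df$p <= 1
  structure(as.data.frame(df), class = c("summary_stats", "data.frame"),
            trait = trait, model = model)
}

# Wald stats from one weighted least-squares / IRLS fit.
.wald_from_fit <- function(fit, col) {
  R <- qr.R(fit$qr)
  p <- fit$rank
  if (p < ncol(R) || any(abs(diag(R)) < 1e-10)) return(c(NA_real_, NA_real_))
  cov_unscaled <- chol2inv(R[seq_len(p), seq_len(p), drop = FALSE])
  c(fit$coefficients[col], sqrt(cov_unscaled[col, col]))
}

#' Marginal per-marker association scan
#'
#' Fits, for each marker, `y ~ allele count + covariates` by ordinary least
#' squares (`model = "linear"`) or logistic regression
#' (`model = "logistic"`; IRLS, deviance tolerance 1e-8, at most 50
#' iterations), and reports the marker coefficient (log-odds for logistic),
#' its standard error, the two-sided Wald P-value (Student-t for linear,
#' normal for logistic) and the number of non-missing samples. Samples with
#' a missing genotype are excluded marker by marker. Monomorphic or
#' non-converged markers are emitted with `se = NA` and `valid = FALSE` so
#' downstream stages can drop them.
#'
#' @param G A [genotype_matrix()].
#' @param y Outcome: adjusted quantitative trait, or 0/1 vector for
#'   logistic.
#' @param covariates Optional data frame/matrix of covariates.
#' @param model `"linear"` or `"logistic"`.
#' @param trait Trait label stored on the result.
#' @return A [summary_stats()] object, one row per marker of `G`.
#' @export
marginal_gwas <- function(G, y, covariates = NULL,
                          model = c("linear", "logistic"),
                          trait = "trait") {
  model <- match.arg(model)
  counts <- G$counts
  n <- nrow(counts)
  stopifnot(length(y) == n)
  if (model == "logistic" && !all(y %in% c(0, 1)))
    stop("logistic model requires a 0/1 outcome")
  C <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(covariates)) C <- cbind(C, as.matrix(covariates))
  # drop aliased covariate columns (e.g. all-zero placeholders)
  qrC <- qr(C)
  if (qrC$rank < ncol(C)) {
    C <- C[, qrC$pivot[seq_len(qrC$rank)], drop = FALSE]
    qrC <- qr(C)
  }
  m <- ncol(counts)
  beta <- se <- rep(NA_real_, m)
  nn <- integer(m)
  has_na <- colSums(is.na(counts)) > 0L

  if (model == "linear") {
    clean <- which(!has_na)
    if (length(clean)) {
      # Frisch-Waugh: residualize outcome and genotypes on the covariates,
      # then the marker coefficient is a simple regression of residuals
      yr <- qr.resid(qrC, y)
      Gr <- qr.resid(qrC, counts[, clean, drop = FALSE])
      gg <- colSums(Gr^2)
      poly <- gg > 1e-10
      gy <- as.vector(crossprod(Gr, yr))
      df <- n - ncol(C) - 1L
      b <- ifelse(poly, gy / gg, NA_real_)
      rss <- pmax(0, sum(yr^2) - b^2 * gg)
      s <- sqrt(rss / df / gg)
      beta[clean] <- b
      se[clean] <- ifelse(poly, s, NA_real_)
      nn[clean] <- n
    }
    for (j in which(has_na)) {
      ok <- !is.na(counts[, j])
      nj <- sum(ok)
      nn[j] <- nj
      if (nj <= ncol(C) + 1L) next
      Xj <- cbind(C[ok, , drop = FALSE], g = counts[ok, j])
      if (var(counts[ok, j]) < 1e-10) next
      fit <- lm.fit(Xj, y[ok])
      ws <- .wald_from_fit(fit, ncol(Xj))
      sigma2 <- sum(fit$residuals^2) / (nj - fit$rank)
      beta[j] <- ws[1]; se[j] <- ws[2] * sqrt(sigma2)
    }
    df <- nn - ncol(C) - 1L
    p <- 2 * pt(-abs(beta / se), pmax(df, 1L))
  } else {
    for (j in seq_len(m)) {
      g <- counts[, j]
      ok <- if (has_na[j]) !is.na(g) else rep(TRUE, n)
      nj <- sum(ok)
      nn[j] <- nj
      gj <- g[ok]
      if (var(gj) < 1e-10) next
      Xj <- cbind(C[ok, , drop = FALSE], g = gj)
      fit <- tryCatch(
        glm.fit(Xj, y[ok], family = binomial(),
                control = list(epsilon = 1e-8, maxit = 50L)),
        error = function(e) NULL)
      if (is.null(fit) || !fit$converged) next
      ws <- .wald_from_fit(fit, ncol(Xj))
      beta[j] <- ws[1]; se[j] <- ws[2]
    }
    p <- 2 * pnorm(-abs(beta / se))
  }

  mk <- G$markers
  summary_stats(data.frame(
    id = mk$id, chrom = mk$chrom, pos = mk$pos,
    effect_allele = mk$effect_allele, other_allele = mk$other_allele,
    af = mk$af, beta = beta, se = se, p = p, n = nn,
    stringsAsFactors = FALSE
  ), trait = trait, model = model)
}

#' Convert an odds ratio and P-value to beta and standard error
#'
#' `beta = log(OR)`; the standard error is recovered from the two-sided
#' P-value as `|beta| / z` with `z = qnorm(1 - p/2)`, i.e. by inverting the
#' Wald statistic. `OR = 1` (zero effect) and `p >= 1` (zero quantile) leave
#' the SE undefined; such markers are returned with `valid = FALSE`.
#'
#' @param or_value Odds ratio(s), positive.
#' @param p Two-sided P-value(s) in (0, 1).
#' @return Data frame with columns `beta`, `se`, `valid`.
#' @export
or_to_beta <- function(or_value, p) {
  stopifnot(length(or_value) == length(p))
  if (any(or_value <= 0, na.rm = TRUE)) stop("odds ratios must be positive")
  beta <- log(or_value)
  z <- qnorm(1 - p / 2)
  valid <- is.finite(beta) & is.finite(z) & beta != 0 & z > 0 &
    !is.na(p) & p > 0 & p < 1
  se <- ifelse(valid, abs(beta) / z, NA_real_)
  data.frame(beta = beta, se = se, valid = valid)
}

#' Harmonize external summary statistics to a reference allele orientation
#'
#' Matches markers to the reference by id, keeps the intersection in
#' reference order, and aligns effect alleles: where the external file's
#' effect/other alleles are swapped relative to the reference, the effect is
#' negated and the allele frequency complemented. Pairs matching neither
#' orientation are dropped and counted. Strand-ambiguity (A/T, C/G) is not
#' specially handled; see the package vignette.
#'
#' @param external A [summary_stats()] object.
#' @param reference Data frame of reference marker metadata with columns
#'   `id`, `effect_allele`, `other_allele` (e.g. `G$markers`).
#' @return A `summary_stats` object in reference order with attribute
#'   `harmonize_counts` (`matched`, `flipped`, `dropped`).
#' @export
harmonize <- function(external, reference) {
  idx <- match(reference$id, external$id)
  keep <- !is.na(idx)
  if (!any(keep)) stop("no overlapping markers between external and reference")
  ext <- external[idx[keep], , drop = FALSE]
  ref <- reference[keep, , drop = FALSE]
  same <- ext$effect_allele == ref$effect_allele &
    ext$other_allele == ref$other_allele
  swap <- ext$effect_allele == ref$other_allele &
    ext$other_allele == ref$effect_allele
  bad <- !(same | swap)
  ext$beta[swap] <- -ext$beta[swap]
  ext$af[swap] <- 1 - ext$af[swap]
  ext$effect_allele[swap] <- ref$effect_allele[swap]
  ext$other_allele[swap] <- ref$other_allele[swap]
  out <- ext[!bad, , drop = FALSE]
  rownames(out) <- NULL
  out <- summary_stats(out, trait = attr(external, "trait"),
                       model = attr(external, "model"))
  attr(out, "harmonize_counts") <- c(matched = sum(same), flipped = sum(swap),
                                     dropped = sum(bad) + sum(!keep))
  out
}
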