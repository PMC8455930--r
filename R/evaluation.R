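# Log-likelihood of a fitted binomial glm.fit object.
.binom_ll <- function(y, mu) {
  eps <- 1e-12
  mu <- clamp(mu, eps, 1 - eps)
  sum(y * log(mu) + (1 - y) * log(1 - mu))
}

.logistic_ll <- function(X, y) {
  fit <- glm.fit(X, y, family = binomial(),
                 control = list(epsilon = 1e-10, maxit = 100L))
  if (!fit$converged) stop("logistic model did not converge")
  list(ll = .binom_ll(y, fit$fitted.values), fit = fit)
}

#' Incremental Nagelkerke pseudo-R-squared of a risk score
#'
#' Fits two nested logistic models by maximum likelihood - the full model
#' `y ~ covariates + score` and the reduced model `y ~ covariates` - and
#' returns
#' `R2 = (1 - exp(-LR/n)) / (1 - exp(2 L0 / n))`,
#' where `LR = 2 (l_full - l_reduced)` is the likelihood-ratio statistic and
#' `L0` the reduced model's log-likelihood. This is the Cox-Snell R-squared
#' of the score's contribution rescaled by its attainable maximum, so a
#' completely uninformative score gives exactly 0 and the measure is
#' invariant to affine transformations of the score.
#'
#' @param y 0/1 outcome with both classes present.
#' @param score Numeric score vector or a `risk_score_set`.
#' @param covariates Optional covariate data frame/matrix (the reduced
#'   model; mirrors the covariates used during training).
#' @return The incremental Nagelkerke R-squared in `[0, 1]`, with
#'   attributes `LR` and `L0`.
#' @export
nagelkerke_r2 <- function(y, score, covariates = NULL) {
  if (inherits(score, "risk_score_set")) score <- score$score
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("y must be binary 0/1")
  if (length(unique(y)) < 2L) stop("both outcome classes must be present")
  stopifnot(length(score) == length(y))
  Xr <- matrix(1, length(y), 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(covariates)) Xr <- cbind(Xr, as.matrix(covariates))
  qrX <- qr(Xr)
  if (qrX$rank < ncol(Xr)) Xr <- Xr[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  n <- length(y)
  red <- .logistic_ll(Xr, y)
  if (sd(score) < .Machine$double.eps^0.5) {
    full_ll <- red$ll  # constant score carries no information
  } else {
    full_ll <- .logistic_ll(cbind(Xr, score = score), y)$ll
  }
  LR <- max(0, 2 * (full_ll - red$ll))
  r2 <- (1 - exp(-LR / n)) / (1 - exp(2 * red$ll / n))
  structure(unname(r2), LR = LR, L0 = red$ll)
}

#' Percentile risk stratification with odds ratios
#'
#' Divides the cohort into `n_bins` equal-occupancy score percentiles
#' (ties broken by stable sample order), computes the disease prevalence in
#' each bin, and estimates each bin's odds ratio against the reference bin
#' from a separate logistic model (bin indicator + covariates) so that an
#' empty bin only invalidates its own estimate. The reference bin's OR is 1
#' by construction.
#'
#' @param score Numeric scores or a `risk_score_set`.
#' @param y 0/1 outcome.
#' @param covariates Optional covariates for the OR models.
#' @param reference Reference percentile (default 50).
#' @param n_bins Number of bins (default 100).
#' @return Object of class `evaluation_result`: data frame with columns
#'   `bin, n, cases, prevalence, or`, and attributes `reference`,
#'   `top_decile_prevalence` (prevalence among the top 10% of scores).
#' @export
percentile_stratify <- function(score, y, covariates = NULL,
                                reference = 50L, n_bins = 100L) {
  if (inherits(score, "risk_score_set")) score <- score$score
  n <- length(score)
  stopifnot(length(y) == n, reference >= 1, reference <= n_bins)
  if (n < n_bins) stop("need at least one sample per percentile bin")
  r <- rank(score, ties.method = "first")
  bin <- ceiling(r * n_bins / n)
  tab <- data.frame(bin = seq_len(n_bins))
  tab$n <- tabulate(bin, n_bins)
  tab$cases <- vapply(seq_len(n_bins), function(b) sum(y[bin == b]), 0)
  tab$prevalence <- tab$cases / tab$n
  tab$or <- NA_real_
  tab$or[reference] <- 1
  ref_idx <- bin == reference
  Xc <- if (!is.null(covariates)) as.matrix(covariates)
  for (b in setdiff(seq_len(n_bins), reference)) {
    sel <- bin == b | ref_idx
    yb <- y[sel]
    ib <- as.numeric(bin[sel] == b)
    if (sum(yb[ib == 1]) == 0 || sum(yb[ib == 0]) == 0) next  # non-estimable
    X <- cbind(1, ib, if (!is.null(Xc)) Xc[sel, , drop = FALSE])
    fit <- tryCatch(glm.fit(X, yb, family = binomial(),
                            control = list(epsilon = 1e-8, maxit = 50L)),
                    error = function(e) NULL)
    if (is.null(fit) || !fit$converged) next
    tab$or[b] <- exp(fit$coefficients[2L])
  }
  top <- bin > n_bins - n_bins %/% 10L
  structure(tab, class = c("evaluation_result", "data.frame"),
            reference = reference,
            top_decile_prevalence = mean(y[top]))
}

#' Cross-validated single- and multi-trait risk scoring
#'
#' Orchestrates the full pipeline under k-fold cross-validation. For each
#' fold: (1) marginal GWAS of every trait on the training folds
#' (quantitative traits are covariate-adjusted and rank-normalized first;
#' the binary focal trait is analysed by logistic regression with the same
#' covariates); (2) LD scores on the training genotypes; (3) per-trait
#' effective sample sizes and heritabilities and the pairwise genetic
#' correlation matrix by LD-score regression; (4) for every grid cell
#' (scenario x LD ceiling x P threshold), clumping-and-thresholding marker
#' selection on the focal statistics, selection-index weights, single- and
#' multi-trait scores of the held-out fold, and incremental Nagelkerke
#' R-squared against the covariate-only model. The marker subset is chosen
#' once from the focal-trait statistics and reused across traits.
#'
#' @param G A [genotype_matrix()] for the whole cohort.
#' @param phenos A `phenotype_table` (or data frame) with one column per
#'   trait plus the covariate columns.
#' @param traits Character vector of trait column names, focal first.
#' @param trait_types Character vector (`"binary"` for the focal disease).
#' @param covariate_cols Covariate column names (default `c("sex", "age")`).
#' @param scenarios Scenarios to evaluate; `"ST"` is always included.
#' @param external Optional named list of external focal-trait
#'   [summary_stats()] (pre-harmonized) for S2-S4.
#' @param r2_grid LD-pruning ceilings.
#' @param p_grid P-value thresholds.
#' @param k_folds Number of folds.
#' @param focal_frac Fraction of the training samples used for the focal
#'   trait's GWAS (default 1). Values below 1 emulate the common setting
#'   where the focal disease GWAS is case-limited while the
#'   information-trait GWAS draw on a larger cohort; the information traits
#'   always use the full training folds.
#' @param M Effective chromosomal segments for [index_weights()].
#' @param window_ld,window_prune Marker windows for LD scores and pruning.
#' @param ldsc_intercept Intercept treatment for [estimate_h2()] /
#'   [estimate_rg()]; the default `"fixed"` constrains each intercept to
#'   its null expectation (1 for squared z-scores; the training-sample
#'   phenotypic correlation for z-score products, since all internal GWAS
#'   share the same samples), which is the lowest-variance consistent
#'   choice in the absence of confounding. `"free"`/`TRUE` estimates the
#'   intercepts; `"none"`/`FALSE` is the literal no-intercept form.
#' @param seed Master seed (drives fold assignment).
#' @return List with `results` (long data frame: fold, scenario, r2_max,
#'   p_max, n_markers, r2_nagelkerke), `summary` (mean and SEM across folds
#'   per grid cell, SEM with k-1 denominator), and `params` (per-fold h2,
#'   n_eff, rg).
#' @export
cross_validate <- function(G, phenos, traits, trait_types,
                           covariate_cols = c("sex", "age"),
                           scenarios = "S1",
                           external = list(),
                           r2_grid = c(0.1, 0.5, 0.9),
                           p_grid = default_p_grid("st"),
                           k_folds = 10L, focal_frac = 1, M = 60000,
                           window_ld = 500L, window_prune = 500L,
                           ldsc_intercept = "fixed", seed = 1L) {
  k <- length(traits)
  stopifnot(k >= 1, length(trait_types) == k)
  if (trait_types[1L] != "binary")
    stop("the focal trait must be binary for Nagelkerke evaluation")
  scenarios <- setdiff(scenarios, "ST")
  fold <- split_folds(G$samples, k_folds, seed)
  covars <- phenos[, covariate_cols, drop = FALSE]
  rows <- list()
  params <- list()
  stopifnot(focal_frac > 0, focal_frac <= 1)
  for (f in seq_len(k_folds)) {
    tr <- which(fold != f)
    va <- which(fold == f)
    tr_focal <- tr[seq_len(ceiling(focal_frac * length(tr)))]
    Gt <- subset_genotypes(G, samples = tr)
    Gv <- subset_genotypes(G, samples = va)
    Ct <- covars[tr, , drop = FALSE]
    ss <- vector("list", k); names(ss) <- traits
    Y <- matrix(NA_real_, length(tr), k)  # outcomes as analysed, for the
                                          # overlap term of the rg intercept
    n_tr <- integer(k)                    # per-trait GWAS sample counts
    for (j in seq_len(k)) {
      yj <- phenos[[traits[j]]]
      trj <- if (j == 1L) tr_focal else tr
      n_tr[j] <- length(trj)
      Gj <- if (j == 1L && focal_frac < 1)
        subset_genotypes(G, samples = trj) else Gt
      Cj <- covars[trj, , drop = FALSE]
      if (trait_types[j] == "quantitative") {
        ya <- adjust_phenotype(yj[trj], Cj)
        ss[[j]] <- marginal_gwas(Gj, ya, Cj, model = "linear",
                                 trait = traits[j])
        Y[match(trj, tr), j] <- ya
      } else {
        ss[[j]] <- marginal_gwas(Gj, yj[trj], Cj, model = "logistic",
                                 trait = traits[j])
        Y[match(trj, tr), j] <- yj[trj]
      }
    }
    ld <- ld_scores(Gt, window = window_ld)
    m_mark <- nrow(Gt$markers)
    all_ss <- c(ss, external)
    kk <- length(all_ss)
    n_eff <- vapply(all_ss, estimate_n_eff, 0)
    # SE-based n_eff assumes a variance-1 outcome; logistic SEs are on the
    # log-odds scale, so for binary traits analysed internally the actual
    # training count is the effective size on the standardized observed
    # scale (and keeps the h2 estimate on that scale)
    n_eff[seq_len(k)][trait_types == "binary"] <-
      n_tr[trait_types == "binary"]
    h2 <- vapply(seq_len(kk), function(j)
      as.numeric(estimate_h2(all_ss[[j]], ld, m = m_mark, n_eff = n_eff[j],
                             intercept = ldsc_intercept)), 0)
    names(h2) <- names(all_ss)
    h2f <- pmax(h2, 1e-6)  # floor for weight construction
    if (any(h2 <= 0))
      warning(sprintf("fold %d: non-positive h2 estimate floored at 1e-6", f))
    rg <- diag(kk)
    dimnames(rg) <- list(names(all_ss), names(all_ss))
    for (a in seq_len(kk - 1L)) for (b in seq(a + 1L, kk)) {
      # internal GWAS pairs share samples: null z-score products centre on
      # rho * n_overlap / sqrt(n_a n_b); external studies are independent (0)
      iv <- 0
      if (a <= k && b <= k) {
        sh <- !is.na(Y[, a]) & !is.na(Y[, b])
        if (sum(sh) > 2)
          iv <- cor(Y[sh, a], Y[sh, b]) * sum(sh) / sqrt(n_tr[a] * n_tr[b])
      }
      rg[a, b] <- rg[b, a] <- as.numeric(
        estimate_rg(all_ss[[a]], all_ss[[b]], ld, h2f[a], h2f[b],
                    m = m_mark, n1 = n_eff[a], n2 = n_eff[b],
                    intercept = ldsc_intercept, intercept_value = iv))
    }
    params[[f]] <- list(h2 = h2, n_eff = n_eff, rg = rg)
    yv <- phenos[[traits[1L]]][va]
    Cv <- covars[va, , drop = FALSE]
    focal <- ss[[1L]]
    for (r2m in r2_grid) {
      pruned <- ld_prune(Gt, focal, r2_max = r2m, window = window_prune)
      for (pm in p_grid) {
        sel <- intersect(pruned, p_threshold(focal, pm))
        if (length(sel) < 1L) next
        sc <- st_grs(Gv, focal, sel)
        rows[[length(rows) + 1L]] <- data.frame(
          fold = f, scenario = "ST", r2_max = r2m, p_max = pm,
          n_markers = length(sel),
          r2_nagelkerke = as.numeric(nagelkerke_r2(yv, sc, Cv)))
        for (sce in scenarios) {
          bs <- build_scenario(sce, focal, ss[-1L], external)
          ord <- match(bs$labels, names(all_ss))
          ord[bs$labels == "focal"] <- 1L
          iw <- index_weights(h2f[ord], rg[ord, ord, drop = FALSE],
                              N = n_eff[ord], M = M, scenario = sce)
          adj <- mt_adjust_effects(lapply(bs$stats, function(s)
            s[match(focal$id, s$id), , drop = FALSE] |>
              summary_stats(trait = attr(s, "trait"),
                            model = attr(s, "model"))), iw)
          scm <- mt_grs(Gv, adj, sel)
          rows[[length(rows) + 1L]] <- data.frame(
            fold = f, scenario = sce, r2_max = r2m, p_max = pm,
            n_markers = length(sel),
            r2_nagelkerke = as.numeric(nagelkerke_r2(yv, scm, Cv)))
        }
      }
    }
  }
  results <- do.call(rbind, rows)
  agg <- aggregate(r2_nagelkerke ~ scenario + r2_max + p_max, results,
                   function(v) c(mean = mean(v),
                                 sem = sd(v) / sqrt(length(v)),
                                 n_folds = length(v)))
  summary <- data.frame(agg[, 1:3],
                        mean_r2 = agg$r2_nagelkerke[, "mean"],
                        sem = agg$r2_nagelkerke[, "sem"],
                        n_folds = agg$r2_nagelkerke[, "n_folds"])
  list(results = results, summary = summary, params = params,
       fold = fold)
}
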