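#' Greedy LD pruning with P-value priority
#'
#' Clumping-style marker selection: markers are visited in ascending
#' P-value order (ties broken by chromosome and position) and a marker is
#' kept only if its bias-adjusted squared correlation with every
#' already-kept marker within `window` markers on the same chromosome is
#' below `r2_max`. The exhaustive guarantee is that no kept pair inside a
#' window has adjusted r-squared at or above the ceiling.
#'
#' @param G A [genotype_matrix()] providing the LD reference.
#' @param ss A [summary_stats()] supplying the priority P-values (focal
#'   trait).
#' @param r2_max LD ceiling in (0, 1].
#' @param window Window size in markers, as in [ld_scores()].
#' @return Character vector of kept marker ids in genomic order.
#' @export
ld_prune <- function(G, ss, r2_max, window = 500L) {
  stopifnot(r2_max > 0, r2_max <= 1)
  mk <- G$markers
  if (!nrow(mk)) stop("empty genotype matrix")
  idx <- match(mk$id, ss$id)
  if (anyNA(idx)) stop("every genotype marker needs a P-value in ss")
  p <- ss$p[idx]
  p[is.na(p) | !(ss$valid[idx])] <- Inf   # invalid markers get lowest priority
  n <- length(G$samples)
  half <- floor(window / 2)
  S <- standardize_genotypes(G$counts)
  ord <- order(p, mk$chrom, mk$pos)
  kept <- logical(nrow(mk))
  for (i in ord) {
    lo <- max(1L, i - half); hi <- min(nrow(mk), i + half)
    nb <- which(kept[lo:hi]) + lo - 1L
    nb <- nb[mk$chrom[nb] == mk$chrom[i]]
    if (length(nb)) {
      r <- as.vector(crossprod(S[, i], S[, nb, drop = FALSE])) / (n - 1)
      r2 <- r^2
      r2a <- r2 - (1 - r2) / (n - 2)
      if (any(r2a >= r2_max)) next
    }
    kept[i] <- TRUE
  }
  mk$id[kept]
}

#' Default P-value thresholding grids
#'
#' The conventional threshold grids for clumping-and-thresholding scores:
#' the single-trait grid tops out at 0.99 with intermediate steps 0.3, 0.7
#' and 0.9; the multi-trait grid replaces those with 0.5 and 0.75. Either
#' can be passed to [cross_validate()] as `p_grid`.
#'
#' @param mode `"st"` or `"mt"`.
#' @return Numeric vector of thresholds.
#' @export
default_p_grid <- function(mode = c("st", "mt")) {
  switch(match.arg(mode),
         st = c(0.001, 0.01, 0.05, 0.1, 0.2, 0.3, 0.5, 0.7, 0.9, 0.99),
         mt = c(0.001, 0.01, 0.05, 0.1, 0.2, 0.5, 0.75, 0.99))
}

#' P-value thresholding
#'
#' Retains markers with `p < p_max` (strict), order preserved. Markers with
#' missing or invalid P-values are dropped.
#'
#' @param ss A [summary_stats()].
#' @param p_max Threshold in (0, 1].
#' @return Character vector of retained marker ids.
#' @export
p_threshold <- function(ss, p_max) {
  stopifnot(p_max > 0, p_max <= 1)
  ss$id[!is.na(ss$p) & ss$valid & ss$p < p_max]
}

#' Single-trait genomic risk score
#'
#' The per-sample weighted sum of effect-allele counts,
#' `GRS_j = sum_i X_ji * beta_i`, over the selected marker subset. Missing
#' genotypes are imputed to twice the training allele frequency reported in
#' `ss`.
#'
#' @param G A [genotype_matrix()] of the samples to score.
#' @param ss A [summary_stats()] holding the marker effects (harmonized to
#'   `G`'s allele orientation).
#' @param markers Marker ids to use (e.g. from [ld_prune()] intersected
#'   with [p_threshold()]).
#' @return A data frame of class `risk_score_set` with columns `sample`,
#'   `score`, and attribute `settings` (marker count and any thresholds the
#'   caller attached).
#' @export
st_grs <- function(G, ss, markers = ss$id) {
  markers <- intersect(markers, intersect(G$markers$id, ss$id))
  if (!length(markers)) stop("empty marker subset")
  gi <- match(markers, G$markers$id)
  si <- match(markers, ss$id)
  X <- G$counts[, gi, drop = FALSE]
  if (anyNA(X)) {
    af2 <- 2 * ss$af[si]
    na_idx <- which(is.na(X), arr.ind = TRUE)
    X[na_idx] <- af2[na_idx[, 2L]]
  }
  b <- ss$beta[si]
  b[is.na(b)] <- 0
  score <- as.vector(X %*% b)
  out <- data.frame(sample = G$samples, score = score,
                    stringsAsFactors = FALSE)
  structure(out, class = c("risk_score_set", "data.frame"),
            settings = list(marker_count = length(markers),
                            trait = attr(ss, "trait")))
}

# Project a symmetric matrix with unit diagonal to the nearest positive
# semi-definite correlation matrix: clip eigenvalues at a small floor and
# rescale the diagonal back to 1. A no-op (up to floating error) for
# matrices that are already PSD.
.nearest_psd_corr <- function(R, eps = 1e-6) {
  es <- eigen(R, symmetric = TRUE)
  if (min(es$values) >= eps) return(R)
  Rp <- es$vectors %*% (pmax(es$values, eps) * t(es$vectors))
  d <- sqrt(diag(Rp))
  Rp <- Rp / outer(d, d)
  diag(Rp) <- 1
  Rp
}

#' Selection-index weights for multi-trait effect adjustment
#'
#' Computes the optimal linear weights `w = V^{-1} C` for combining the
#' marginal marker effects of `k` correlated traits into a predictor of the
#' focal trait's true marker effects (focal trait first). The
#' variance-covariance matrix of estimated effects has diagonal
#' `h2_k / M + 1 / N_k` (polygenic signal spread over `M` effective
#' chromosomal segments plus estimation noise) and off-diagonals
#' `rg_kl h_k h_l / M`; `C` holds the covariances of each trait's estimates
#' with the focal true effects, `rg_fk h_f h_k / M`.
#'
#' @param h2 k-vector of heritabilities (focal first).
#' @param rg k x k genetic correlation matrix. Off-diagonal entries are
#'   clamped to `[-0.999, 0.999]`, and the matrix is projected to the
#'   nearest positive semi-definite correlation matrix (eigenvalue
#'   clipping, diagonal rescaled to 1) before inversion: pairwise LD-score
#'   estimates of rg are noisy and need not be jointly consistent, and a
#'   non-PSD genetic covariance would make the index weights swing wildly.
#' @param N k-vector of per-trait sample counts.
#' @param M Effective number of independent chromosomal segments; 60,000 is
#'   the conventional value for a European-ancestry genotyping array.
#' @param scenario Optional label stored on the result.
#' @return An object of class `index_weights`: list with `w`, `V`, `C`,
#'   `condition` (condition number of `V`), plus the inputs.
#' @export
index_weights <- function(h2, rg = diag(length(h2)), N, M = 60000,
                          scenario = NULL) {
  k <- length(h2)
  rg <- as.matrix(rg)
  stopifnot(length(N) == k, all(dim(rg) == k), M > 0, all(N > 0))
  if (any(h2 < 0)) stop("h2 must be non-negative")
  rgc <- rg
  off <- row(rgc) != col(rgc)
  rgc[off] <- clamp(rgc[off], -0.999, 0.999)
  rgc <- .nearest_psd_corr(rgc)
  h <- sqrt(h2)
  V <- rgc * outer(h, h) / M
  diag(V) <- h2 / M + 1 / N
  C <- rgc[, 1L] * h[1L] * h / M
  C[1L] <- h2[1L] / M
  cond <- kappa(V, exact = TRUE)
  if (!is.finite(cond) || cond > 1e12) {
    offv <- abs(rgc); diag(offv) <- 0
    pair <- which(offv == max(offv), arr.ind = TRUE)[1L, ]
    stop(sprintf(
      "index V matrix is singular/ill-conditioned (kappa = %.3g); largest |rg| between traits %d and %d",
      cond, pair[1L], pair[2L]))
  }
  w <- solve(V, C)
  structure(list(w = as.vector(w), V = V, C = C, condition = cond,
                 h2 = h2, rg = rg, N = N, M = M, scenario = scenario),
            class = "index_weights")
}

#' @export
print.index_weights <- function(x, ...) {
  cat(sprintf("index_weights (k = %d, M = %g%s)\n", length(x$w), x$M,
              if (!is.null(x$scenario)) paste0(", ", x$scenario) else ""))
  print(round(x$w, 4))
  invisible(x)
}

#' Multi-trait adjustment of marker effects
#'
#' Replaces each marker's focal effect with the index-weighted sum across
#' traits, `beta_MT_i = sum_k w_k beta_ki`. All files must be harmonized to
#' an identical marker set, allele orientation and order (the focal trait
#' first, matching the weight vector). Marker metadata and the P-values used
#' for thresholding are carried over from the focal trait.
#'
#' @param stats_list List of `k` [summary_stats()] objects, focal first.
#' @param w An [index_weights()] object (or bare numeric k-vector).
#' @return A `summary_stats` object with adjusted `beta`, model tag
#'   `"index"`.
#' @export
mt_adjust_effects <- function(stats_list, w) {
  if (inherits(w, "index_weights")) w <- w$w
  k <- length(stats_list)
  stopifnot(length(w) == k, k >= 1)
  focal <- stats_list[[1L]]
  for (s in stats_list[-1L]) {
    if (!identical(s$id, focal$id) ||
        !identical(s$effect_allele, focal$effect_allele))
      stop("summary statistics must share marker set, order and orientation")
  }
  B <- vapply(stats_list, function(s) s$beta, numeric(nrow(focal)))
  B <- matrix(B, nrow = nrow(focal))
  out <- focal
  out$beta <- as.vector(B %*% w)
  out$valid <- focal$valid & rowSums(is.na(B)) == 0
  summary_stats(as.data.frame(out), trait = attr(focal, "trait"),
                model = "index")
}

#' Multi-trait genomic risk score
#'
#' [st_grs()] applied to index-adjusted effects: the per-sample sum of
#' allele counts weighted by `beta_MT` over the selected marker subset.
#'
#' @inheritParams st_grs
#' @param adjusted A `summary_stats` object from [mt_adjust_effects()].
#' @return A `risk_score_set`.
#' @export
mt_grs <- function(G, adjusted, markers = adjusted$id) {
  st_grs(G, adjusted, markers)
}

#' Assemble the trait set for a multi-trait weighting scenario
#'
#' The four scenarios differ in which summary statistics feed the index:
#' * S1 - internally estimated focal stats + the information traits;
#' * S2 - one external focal-trait study + the information traits;
#' * S3 - one external focal study + information traits + internal focal;
#' * S4 - internal focal + information traits + all external focal studies.
#' The first element of the returned list is always the trait whose effects
#' are being adjusted (the one the `C` vector refers to).
#'
#' @param scenario `"S1"`, `"S2"`, `"S3"` or `"S4"`.
#' @param focal Internal focal-trait [summary_stats()].
#' @param info Named list of information-trait [summary_stats()].
#' @param external Named list of external focal-trait [summary_stats()]
#'   (required for S2-S4).
#' @param which_external Name or index of the external study for S2/S3.
#' @return List with `stats` (ordered list, focal first), `labels`, and
#'   `scenario`.
#' @export
build_scenario <- function(scenario = c("S1", "S2", "S3", "S4"),
                           focal, info, external = list(),
                           which_external = 1L) {
  scenario <- match.arg(scenario)
  if (!length(info)) stop("information-trait statistics are required")
  if (scenario != "S1" && !length(external))
    stop(scenario, " requires external focal-trait summary statistics")
  info_labels <- names(info) %||% vapply(info, attr, "", "trait")
  ext_labels <- names(external) %||% vapply(external, attr, "", "trait")
  if (is.character(which_external)) {
    which_external <- match(which_external, ext_labels)
    if (is.na(which_external)) stop("unknown external study label")
  }
  stats <- switch(scenario,
    S1 = c(list(focal), info),
    S2 = c(external[which_external], info),
    S3 = c(external[which_external], info, list(focal)),
    S4 = c(list(focal), info, external)
  )
  labels <- switch(scenario,
    S1 = c("focal", info_labels),
    S2 = c(ext_labels[which_external], info_labels),
    S3 = c(ext_labels[which_external], info_labels, "focal"),
    S4 = c("focal", info_labels, ext_labels)
  )
  names(stats) <- labels
  list(stats = stats, labels = labels, scenario = scenario)
}
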