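#' Configuration for the synthetic multi-trait cohort generator
#'
#' Collects and validates every parameter of the generative model: a cohort of
#' unrelated individuals genotyped at biallelic markers arranged in LD blocks,
#' with `k` genetically correlated traits built from an additive polygenic
#' model. Binary traits arise by thresholding a latent liability at the
#' quantile corresponding to the case prevalence `K`.
#'
#' LD within a block follows a latent Gaussian AR(1) copula: two independent
#' haplotype-level Gaussian processes with lag-one correlation
#' `within_block_rho` are thresholded at the allele-frequency quantile and
#' summed, giving Hardy-Weinberg counts whose pairwise correlation decays
#' geometrically with marker distance inside a block and is zero across
#' blocks.
#'
#' @param n_individuals Number of samples.
#' @param n_markers Number of biallelic markers.
#' @param maf_range Length-2 vector; minor allele frequencies are drawn
#'   uniformly from this interval, which must lie in (0, 0.5].
#' @param block_size Markers per LD block.
#' @param within_block_rho AR(1) parameter of the latent haplotype process in
#'   `[0, 1)`; 0 gives mutually independent markers.
#' @param n_causal Number of causal markers (sampled uniformly, shared across
#'   traits).
#' @param h2 Vector of per-trait narrow-sense heritabilities in `[0, 1]`;
#'   its length defines the number of traits `k`.
#' @param rg `k x k` genetic correlation matrix (symmetric, unit diagonal,
#'   positive semi-definite). Default: identity.
#' @param trait_types Character vector of `"quantitative"` / `"binary"`.
#' @param prevalence Case prevalence K in (0,1) for each binary trait
#'   (recycled). Default 0.056, a typical adult type-2-diabetes case fraction.
#' @param covariate_effects Named vector with elements `sex` and `age`: the
#'   liability/phenotype shift per unit of the 0/1 sex indicator and per
#'   standard deviation of age.
#' @param missing_rate Probability that a genotype call is missing. Defaults
#'   to 0: the generator emulates a post-QC hard-call matrix; set a positive
#'   rate to exercise missingness handling and QC filters.
#' @param n_chromosomes Number of chromosome labels the blocks are spread
#'   over (LD windows never span chromosomes).
#' @param seed Master seed; all generator stages derive sub-seeds from it via
#'   [derive_seed()].
#' @return A validated list of class `sim_config`.
#' @seealso [simulate_genotypes()], [simulate_phenotypes()]
#' @export
sim_config <- function(n_individuals,
                       n_markers,
                       maf_range = c(0.05, 0.5),
                       block_size = 20L,
                       within_block_rho = 0.9,
                       n_causal = max(1L, round(n_markers / 10)),
                       h2 = 0.5,
                       rg = NULL,
                       trait_types = NULL,
                       prevalence = 0.056,
                       covariate_effects = c(sex = 0.25, age = 0.3),
                       missing_rate = 0,
                       n_chromosomes = 1L,
                       seed = 1L) {
  stopifnot(n_individuals >= 2, n_markers >= 1)
  if (length(maf_range) != 2L || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5)
    stop("maf_range must be an increasing pair within (0, 0.5]")
  stopifnot(block_size >= 1, within_block_rho >= 0, within_block_rho < 1)
  if (n_causal < 1 || n_causal > n_markers)
    stop("n_causal must be in [1, n_markers]")
  k <- length(h2)
  if (any(h2 < 0 | h2 > 1)) stop("h2 entries must lie in [0, 1]")
  if (is.null(rg)) rg <- diag(k)
  rg <- as.matrix(rg)
  if (!isTRUE(all.equal(dim(rg), c(k, k))))
    stop("rg must be a ", k, "x", k, " matrix")
  if (max(abs(rg - t(rg))) > 1e-8) stop("rg must be symmetric")
  if (max(abs(diag(rg) - 1)) > 1e-8) stop("rg must have unit diagonal")
  ev <- eigen(rg, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) stop("rg must be positive semi-definite")
  if (is.null(trait_types)) trait_types <- rep("quantitative", k)
  trait_types <- match.arg(trait_types, c("quantitative", "binary"),
                           several.ok = TRUE)
  if (length(trait_types) != k) stop("trait_types must have one entry per trait")
  n_bin <- sum(trait_types == "binary")
  prevalence <- rep_len(prevalence, max(1L, n_bin))
  if (any(prevalence <= 0 | prevalence >= 1))
    stop("prevalence must lie in (0, 1)")
  stopifnot(missing_rate >= 0, missing_rate < 1)
  cfg <- list(
    n_individuals = as.integer(n_individuals),
    n_markers = as.integer(n_markers),
    maf_range = maf_range,
    block_size = as.integer(block_size),
    within_block_rho = within_block_rho,
    n_causal = as.integer(n_causal),
    h2 = h2,
    rg = rg,
    trait_types = trait_types,
    prevalence = prevalence,
    covariate_effects = covariate_effects,
    missing_rate = missing_rate,
    n_chromosomes = as.integer(n_chromosomes),
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Construct a genotype matrix object
#'
#' Container for an `n x m` allele-count matrix (entries 0/1/2, `NA` for
#' missing) plus per-marker metadata. Allele frequency and missingness are
#' recomputed from the counts.
#'
#' @param counts Integer matrix of effect-allele counts.
#' @param markers Data frame with columns `chrom`, `pos`, `id`,
#'   `effect_allele`, `other_allele` (one row per column of `counts`).
#' @param samples Character vector of sample ids (rows of `counts`).
#' @return An object of class `genotype_matrix` with elements `counts`,
#'   `markers` (including recomputed `af` and `missingness`), `samples`.
#' @export
genotype_matrix <- function(counts, markers, samples = NULL) {
  counts <- as.matrix(counts)
  if (is.null(samples)) samples <- rownames(counts) %||%
      sprintf("id%05d", seq_len(nrow(counts)))
  stopifnot(nrow(markers) == ncol(counts), length(samples) == nrow(counts))
  if (anyDuplicated(markers$id)) stop("marker ids must be unique")
  ord_ok <- all(tapply(markers$pos, markers$chrom,
                       function(p) all(diff(p) > 0)))
  if (!isTRUE(ord_ok)) stop("pos must be strictly increasing within chrom")
  markers$af <- colMeans(counts, na.rm = TRUE) / 2
  markers$missingness <- colMeans(is.na(counts))
  rownames(counts) <- samples
  colnames(counts) <- markers$id
  structure(list(counts = counts, markers = as.data.frame(markers),
                 samples = samples),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d markers (%d chromosome(s))\n",
              length(x$samples), nrow(x$markers),
              length(unique(x$markers$chrom))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$counts)

#' Subset a genotype matrix by samples and/or markers
#'
#' @param G A `genotype_matrix`.
#' @param samples Sample ids or indices (default: all).
#' @param markers Marker ids or indices (default: all).
#' @return A `genotype_matrix` restricted to the requested rows/columns;
#'   allele frequencies and missingness are recomputed on the subset.
#' @export
subset_genotypes <- function(G, samples = NULL, markers = NULL) {
  ri <- if (is.null(samples)) seq_along(G$samples)
        else if (is.character(samples)) match(samples, G$samples)
        else samples
  ci <- if (is.null(markers)) seq_len(nrow(G$markers))
        else if (is.character(markers)) match(markers, G$markers$id)
        else markers
  if (anyNA(ri)) stop("unknown sample id in subset")
  if (anyNA(ci)) stop("unknown marker id in subset")
  genotype_matrix(G$counts[ri, ci, drop = FALSE],
                  G$markers[ci, setdiff(names(G$markers),
                                        c("af", "missingness")), drop = FALSE],
                  G$samples[ri])
}

#' Simulate genotypes in LD blocks
#'
#' Draws an `n x m` matrix of Hardy-Weinberg allele counts with block-wise
#' linkage disequilibrium. Each marker's minor allele frequency is uniform on
#' `cfg$maf_range`. Within a block of `block_size` consecutive markers, two
#' latent haplotype-level Gaussian AR(1) processes (parameter
#' `within_block_rho`) are thresholded at the frequency quantile and summed,
#' so genotype correlation decays geometrically with marker separation inside
#' the block and vanishes across blocks. Missing calls are then injected
#' independently at `missing_rate`.
#'
#' @param cfg A [sim_config()].
#' @return A [genotype_matrix()] with markers laid out on
#'   `cfg$n_chromosomes` chromosomes at 1 kb spacing.
#' @export
simulate_genotypes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- cfg$n_individuals
  m <- cfg$n_markers
  rho <- cfg$within_block_rho
  with_seed(derive_seed(cfg$seed, 1L), {
    maf <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
    thr <- qnorm(1 - maf)  # P(latent > thr) = maf
    counts <- matrix(0L, n, m)
    block_of <- (seq_len(m) - 1L) %/% cfg$block_size
    for (b in unique(block_of)) {
      idx <- which(block_of == b)
      w <- length(idx)
      for (hap in 1:2) {
        z <- matrix(0, n, w)
        z[, 1L] <- rnorm(n)
        if (w > 1L) {
          innov <- sqrt(1 - rho^2)
          for (j in 2:w) z[, j] <- rho * z[, j - 1L] + innov * rnorm(n)
        }
        counts[, idx] <- counts[, idx] +
          (z > matrix(thr[idx], n, w, byrow = TRUE))
      }
    }
    if (cfg$missing_rate > 0) {
      miss <- runif(n * m) < cfg$missing_rate
      counts[miss] <- NA_integer_
    }
    chrom_of <- as.character(1L + (block_of * cfg$n_chromosomes) %/%
                               max(1L, max(block_of) + 1L))
    pos <- integer(m)
    for (ch in unique(chrom_of)) {
      i <- which(chrom_of == ch)
      pos[i] <- seq_along(i) * 1000L
    }
    markers <- data.frame(
      chrom = chrom_of,
      pos = pos,
      id = sprintf("rs%06d", seq_len(m)),
      effect_allele = "A",
      other_allele = "G",
      stringsAsFactors = FALSE
    )
    G <- genotype_matrix(counts, markers,
                         sprintf("id%05d", seq_len(n)))
    attr(G, "maf_drawn") <- maf
    G
  })
}

#' Simulate correlated phenotypes from a genotype matrix
#'
#' Implements the additive polygenic model: `n_causal` markers (uniformly
#' sampled) receive per-trait effects drawn jointly from a multivariate
#' normal with covariance `rg[k,l] * h_k * h_l / n_causal` on standardized
#' genotypes, so each trait's genetic values have variance `h2[k]` and pairs
#' of traits have genetic correlation `rg[k,l]`. Independent residuals bring
#' the total (covariate-free) variance to 1. Sex (Bernoulli 1/2) and age
#' (normal, mean 57.5 y, sd 8 y) shift the phenotype/liability through
#' `covariate_effects` before any thresholding. Binary traits are the
#' indicator that the liability exceeds its theoretical `1 - K` quantile.
#'
#' @param G A [genotype_matrix()] from [simulate_genotypes()].
#' @param cfg The same [sim_config()] used for the genotypes.
#' @return A data frame of class `phenotype_table` with columns `sample`,
#'   one column per trait (`trait1`, ...), `sex`, `age`, `fold` (`NA` until
#'   assigned). True genetic values, causal indices and true effects are
#'   attached as attributes `genetic_values`, `causal_idx`, `true_effects`.
#' @export
simulate_phenotypes <- function(G, cfg) {
  stopifnot(inherits(cfg, "sim_config"), inherits(G, "genotype_matrix"))
  n <- length(G$samples)
  m <- nrow(G$markers)
  if (n != cfg$n_individuals || m != cfg$n_markers)
    stop("genotype dimensions do not match cfg")
  k <- length(cfg$h2)
  with_seed(derive_seed(cfg$seed, 2L), {
    causal <- sort(sample.int(m, cfg$n_causal))
    h <- sqrt(cfg$h2)
    Sigma <- (cfg$rg * outer(h, h)) / cfg$n_causal
    # matrix square root via eigendecomposition (rg may be singular, e.g. rg = 1)
    es <- eigen(Sigma, symmetric = TRUE)
    S_half <- es$vectors %*% diag(sqrt(pmax(es$values, 0)), k) %*% t(es$vectors)
    B <- matrix(rnorm(cfg$n_causal * k), cfg$n_causal, k) %*% S_half
    Xc <- standardize_genotypes(G$counts[, causal, drop = FALSE])
    gval <- Xc %*% B
    resid_sd <- sqrt(pmax(0, 1 - cfg$h2))
    E <- matrix(rnorm(n * k), n, k) %*% diag(resid_sd, k)
    sex <- rbinom(n, 1L, 0.5)
    age_std <- rnorm(n)
    age <- round(57.5 + 8 * age_std, 1)
    bs <- unname(cfg$covariate_effects["sex"] %||% 0)
    ba <- unname(cfg$covariate_effects["age"] %||% 0)
    if (is.na(bs)) bs <- 0
    if (is.na(ba)) ba <- 0
    liab <- gval + E + outer(sex * bs + age_std * ba, rep(1, k))
    traits <- as.data.frame(liab)
    names(traits) <- sprintf("trait%d", seq_len(k))
    # liability mean/variance from the model, not the sample, so the case
    # fraction carries ordinary binomial noise around K
    mu_l <- bs * 0.5
    sd_l <- sqrt(1 + bs^2 * 0.25 + ba^2)
    bin_i <- 0L
    for (j in which(cfg$trait_types == "binary")) {
      bin_i <- bin_i + 1L
      K <- cfg$prevalence[bin_i]
      thr <- mu_l + sd_l * qnorm(1 - K)
      traits[[j]] <- as.integer(liab[, j] > thr)
    }
    out <- data.frame(sample = G$samples, traits, sex = sex, age = age,
                      fold = NA_integer_, stringsAsFactors = FALSE)
    class(out) <- c("phenotype_table", "data.frame")
    attr(out, "genetic_values") <- gval
    attr(out, "causal_idx") <- causal
    attr(out, "true_effects") <- B
    attr(out, "trait_types") <- cfg$trait_types
    out
  })
}

#' Partition samples into cross-validation folds
#'
#' Randomly partitions the sample ids into `k_folds` disjoint folds whose
#' sizes differ by at most one. Deterministic given `seed`.
#'
#' @param samples Character vector of sample ids.
#' @param k_folds Number of folds (between 2 and `length(samples)`).
#' @param seed Integer seed.
#' @return Integer vector of fold labels in `1:k_folds`, named by sample id.
#' @export
split_folds <- function(samples, k_folds, seed = 1L) {
  n <- length(samples)
  if (k_folds < 2 || k_folds > n)
    stop("k_folds must be between 2 and the number of samples")
  with_seed(derive_seed(seed, 3L), {
    perm <- sample.int(n)
    fold <- integer(n)
    fold[perm] <- rep_len(seq_len(k_folds), n)
    names(fold) <- samples
    fold
  })
}
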