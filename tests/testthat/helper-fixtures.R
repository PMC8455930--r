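# Small fixtures built in code, shared across test files.

# Hand-specifiable genotype matrix from a count matrix.
toy_genotypes <- function(counts, chrom = "1") {
  m <- ncol(counts)
  markers <- data.frame(
    chrom = rep(chrom, length.out = m),
    pos = integer(m), id = sprintf("m%03d", seq_len(m)),
    effect_allele = "A", other_allele = "G", stringsAsFactors = FALSE)
  for (ch in unique(markers$chrom))
    markers$pos[markers$chrom == ch] <- seq_len(sum(markers$chrom == ch)) * 100L
  genotype_matrix(counts, markers)
}

# Random Hardy-Weinberg genotypes, independent markers.
random_genotypes <- function(n, m, maf = NULL, seed = 1, missing_rate = 0) {
  set.seed(seed)
  if (is.null(maf)) maf <- runif(m, 0.1, 0.5)
  counts <- sapply(maf, function(f) rbinom(n, 2L, f))
  if (missing_rate > 0) counts[runif(n * m) < missing_rate] <- NA
  toy_genotypes(matrix(counts, n, m))
}

# Minimal summary_stats wrapper around per-marker vectors.
toy_sumstats <- function(ids, beta, se = rep(0.1, length(ids)),
                         p = rep(0.5, length(ids)),
                         af = rep(0.3, length(ids)),
                         ea = rep("A", length(ids)),
                         oa = rep("G", length(ids)),
                         n = rep(100L, length(ids)), trait = "toy",
                         model = "linear") {
  summary_stats(data.frame(
    id = ids, chrom = "1", pos = seq_along(ids) * 100L,
    effect_allele = ea, other_allele = oa, af = af,
    beta = beta, se = se, p = p, n = n, stringsAsFactors = FALSE),
    trait = trait, model = model)
}

# Default 8-trait correlation structure used by end-to-end tests: a binary
# focal trait plus seven quantitative information traits.
study_rg <- function() {
  k <- 8L
  rgm <- diag(k)
  rgm[1, 2:k] <- rgm[2:k, 1] <- c(0.6, 0.55, 0.5, 0.45, 0.4, 0.35, 0.3)
  off <- rgm[2:k, 2:k]
  off[row(off) != col(off)] <- 0.2
  rgm[2:k, 2:k] <- off
  rgm
}

study_sim_config <- function(n, m, seed) {
  sim_config(n, m, h2 = c(0.3, rep(0.5, 7)), rg = study_rg(),
             trait_types = c("binary", rep("quantitative", 7)),
             prevalence = 0.056, seed = seed)
}
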