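# Delimited-text summary statistics with a documented column alias map.

.ss_aliases <- list(
  id = c("id", "snp", "rsid", "markername", "marker"),
  chrom = c("chrom", "chr", "chromosome"),
  pos = c("pos", "bp", "position", "base_pair_location"),
  effect_allele = c("ea", "a1", "effect_allele", "alt"),
  other_allele = c("oa", "a2", "other_allele", "ref"),
  af = c("af", "frq", "freq", "eaf", "maf", "effect_allele_frequency"),
  beta = c("beta", "b", "effect"),
  or_col = c("or", "odds_ratio"),
  se = c("se", "stderr", "standard_error"),
  p = c("p", "pval", "p_value", "pvalue"),
  n = c("n", "nobs", "samplesize", "n_total")
)

.resolve_col <- function(cols, field) {
  hit <- match(.ss_aliases[[field]], tolower(cols))
  hit <- hit[!is.na(hit)]
  if (length(hit)) cols[hit[1L]] else NA_character_
}

#' Read GWAS summary statistics from delimited text
#'
#' Columns are resolved case-insensitively through an alias map (e.g.
#' `SNP`/`rsid` for the marker id, `A1`/`EA` for the effect allele,
#' `FRQ`/`EAF` for its frequency). Files reporting odds ratios instead of
#' beta are converted through [or_to_beta()]; rows whose required numeric
#' fields do not parse are skipped and counted.
#'
#' @param path Input file (tab- or whitespace-delimited, header required).
#' @param dialect `"auto"` (beta if present, else OR), `"beta"` or `"or"`.
#' @param trait Trait label for the result.
#' @return A [summary_stats()] object with attribute `read_counts`
#'   (`rows`, `skipped`, `or_converted`, `or_invalid`).
#' @export
read_sumstats <- function(path, dialect = c("auto", "beta", "or"),
                          trait = basename(path)) {
  dialect <- match.arg(dialect)
  d <- read.delim(path, sep = "", stringsAsFactors = FALSE,
                  check.names = FALSE)
  cols <- names(d)
  get <- function(field) {
    nm <- .resolve_col(cols, field)
    if (is.na(nm)) NULL else d[[nm]]
  }
  need <- c("id", "effect_allele", "other_allele", "p")
  for (f in need) if (is.na(.resolve_col(cols, f)))
    stop("cannot resolve required column '", f, "' in ", path)
  has_beta <- !is.na(.resolve_col(cols, "beta"))
  has_or <- !is.na(.resolve_col(cols, "or_col"))
  use_or <- switch(dialect,
                   auto = !has_beta && has_or,
                   beta = { if (!has_beta) stop("no beta column"); FALSE },
                   or = { if (!has_or) stop("no OR column"); TRUE })
  out <- data.frame(
    id = as.character(get("id")),
    chrom = as.character(get("chrom") %||% NA),
    pos = suppressWarnings(as.numeric(get("pos") %||% NA)),
    effect_allele = as.character(get("effect_allele")),
    other_allele = as.character(get("other_allele")),
    af = suppressWarnings(as.numeric(get("af") %||% NA)),
    p = suppressWarnings(as.numeric(get("p"))),
    n = suppressWarnings(as.numeric(get("n") %||% NA)),
    stringsAsFactors = FALSE
  )
  or_converted <- 0L; or_invalid <- 0L
  if (use_or) {
    conv <- or_to_beta(suppressWarnings(as.numeric(get("or_col"))), out$p)
    out$beta <- conv$beta
    out$se <- conv$se
    out$valid <- conv$valid
    or_converted <- sum(conv$valid)
    or_invalid <- sum(!conv$valid)
  } else {
    out$beta <- suppressWarnings(as.numeric(get("beta")))
    out$se <- suppressWarnings(as.numeric(get("se") %||% NA))
  }
  bad <- is.na(out$id) | is.na(out$beta) | is.na(out$p)
  skipped <- sum(bad)
  out <- out[!bad, , drop = FALSE]
  rownames(out) <- NULL
  res <- summary_stats(out, trait = trait,
                       model = if (use_or) "logistic" else "linear")
  attr(res, "read_counts") <- c(rows = nrow(out), skipped = skipped,
                                or_converted = or_converted,
                                or_invalid = or_invalid)
  res
}

#' Write summary statistics with the canonical header
#'
#' Canonical columns: `id chr pos ea oa af beta se p n`.
#'
#' @param ss A [summary_stats()] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(ss, path) {
  out <- data.frame(id = ss$id, chr = ss$chrom, pos = ss$pos,
                    ea = ss$effect_allele, oa = ss$other_allele,
                    af = ss$af, beta = ss$beta, se = ss$se,
                    p = ss$p, n = ss$n)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an LD-score track as TSV (`id chr pos l`)
#' @param ld An [ld_scores()] track.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ldscores <- function(ld, path) {
  write.table(data.frame(id = ld$id, chr = ld$chrom, pos = ld$pos, l = ld$l),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
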