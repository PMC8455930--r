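# PLINK1 binary genotype I/O (SNP-major .bed + text .bim/.fam).
#
# 2-bit codes per sample, 4 samples per byte, least-significant bits first:
#   00 -> homozygous A1 (2 copies of the effect allele)
#   01 -> missing
#   10 -> heterozygous
#   11 -> homozygous A2 (0 copies)
# A1 (bim column 5) is the effect allele, A2 (column 6) the other allele.

.bed_magic <- as.raw(c(0x6c, 0x1b, 0x01))

# count -> 2-bit code and back
.count_to_code <- function(cnt) {
  code <- integer(length(cnt))
  code[is.na(cnt)] <- 1L
  code[!is.na(cnt) & cnt == 2L] <- 0L
  code[!is.na(cnt) & cnt == 1L] <- 2L
  code[!is.na(cnt) & cnt == 0L] <- 3L
  code
}

.code_to_count <- c(2L, NA_integer_, 1L, 0L)  # index by code + 1

#' Write a genotype matrix as PLINK1 bed/bim/fam
#'
#' @param G A [genotype_matrix()].
#' @param prefix Output path prefix; writes `prefix.bed`, `prefix.bim`,
#'   `prefix.fam`.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(G, prefix) {
  counts <- G$counts
  n <- nrow(counts); m <- ncol(counts)
  bpm <- ceiling(n / 4)  # bytes per marker
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(.bed_magic, con)
  mult <- c(1L, 4L, 16L, 64L)
  pad <- 4L * bpm - n
  for (j in seq_len(m)) {
    code <- c(.count_to_code(counts[, j]), integer(pad))
    bytes <- as.raw(colSums(matrix(code * mult, nrow = 4L)))
    writeBin(bytes, con)
  }
  mk <- G$markers
  bim <- data.frame(mk$chrom, mk$id, 0L, mk$pos,
                    mk$effect_allele, mk$other_allele)
  write.table(bim, paste0(prefix, ".bim"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  fam <- data.frame(G$samples, G$samples, 0L, 0L, 0L, -9L)
  write.table(fam, paste0(prefix, ".fam"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' Read PLINK1 bed/bim/fam into a genotype matrix
#'
#' Validates the bed magic bytes and that the file size matches the
#' bim/fam row counts before decoding the SNP-major 2-bit genotypes.
#'
#' @param prefix Path prefix of the `.bed`/`.bim`/`.fam` triplet.
#' @return A [genotype_matrix()] (counts of the A1/effect allele; missing
#'   preserved as `NA`).
#' @export
read_plink <- function(prefix) {
  fam <- read.delim(paste0(prefix, ".fam"), header = FALSE, sep = "",
                    stringsAsFactors = FALSE)
  bim <- read.delim(paste0(prefix, ".bim"), header = FALSE, sep = "",
                    stringsAsFactors = FALSE)
  names(bim) <- c("chrom", "id", "cm", "pos", "a1", "a2")
  n <- nrow(fam); m <- nrow(bim)
  if (anyDuplicated(bim$id)) stop("duplicate marker ids in bim")
  bed_path <- paste0(prefix, ".bed")
  sz <- file.info(bed_path)$size
  bpm <- ceiling(n / 4)
  if (is.na(sz) || sz != 3 + bpm * m)
    stop(sprintf("bed size %s inconsistent with %d samples x %d markers",
                 sz, n, m))
  con <- file(bed_path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3L)
  if (!identical(magic, .bed_magic))
    stop("not a SNP-major PLINK1 bed file (magic bytes mismatch)")
  raw <- readBin(con, "raw", bpm * m)
  ints <- as.integer(raw)
  # extract the four 2-bit fields of every byte
  codes <- rbind(ints %% 4L, (ints %/% 4L) %% 4L,
                 (ints %/% 16L) %% 4L, ints %/% 64L)
  dim(codes) <- c(4L * bpm, m)
  counts <- matrix(.code_to_count[codes[seq_len(n), , drop = FALSE] + 1L],
                   n, m)
  markers <- data.frame(chrom = as.character(bim$chrom), pos = bim$pos,
                        id = bim$id, effect_allele = bim$a1,
                        other_allele = bim$a2, stringsAsFactors = FALSE)
  genotype_matrix(counts, markers, as.character(fam[[2L]]))
}

#' Write a phenotype/covariate table as TSV
#' @param phenos Data frame with a `sample` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(phenos, path) {
  write.table(phenos, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phenotype/covariate TSV
#' @param path Input path (header required; `sample` column required).
#' @return A data frame of class `phenotype_table`.
#' @export
read_phenotypes <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  if (!"sample" %in% names(d)) stop("phenotype file needs a 'sample' column")
  d$sample <- as.character(d$sample)
  class(d) <- c("phenotype_table", "data.frame")
  d
}
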