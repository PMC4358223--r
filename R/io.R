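#' Read and write PLINK PED/MAP text genotypes
#'
#' Genotypes are stored as allele doses (count of the A1/reference allele).
#' On write, doses 0/1/2 become the allele pairs `B B`, `A B`, `A A` and
#' missing becomes `0 0`; on read, any biallelic coding is accepted and the
#' dose counts the A1 allele listed in the per-SNP allele summary (the first
#' allele seen, consistent across animals).
#'
#' @param prefix path prefix; `<prefix>.ped` and `<prefix>.map` are used.
#' @param geno allele-dose matrix with rownames = animal ids and a `map`
#'   attribute (see [gene_drop()]).
#' @param sex optional per-animal sex vector ("M"/"F") written to the PED sex
#'   column (1 = male, 2 = female).
#' @return `read_plink()`: a dose matrix with `map` attribute;
#'   `write_plink()`: the prefix, invisibly.
#' @export
write_plink <- function(geno, prefix, sex = NULL) {
  map <- snp_map(geno)
  n <- nrow(geno)
  sexcode <- if (is.null(sex)) rep(0L, n) else ifelse(sex == "M", 1L, 2L)
  alleles <- matrix("0", n, 2L * ncol(geno))
  a1 <- c("B", "A", "A"); a2 <- c("B", "B", "A")
  for (j in seq_len(ncol(geno))) {
    dose <- geno[, j]
    ok <- !is.na(dose)
    alleles[ok, 2L * j - 1L] <- a1[dose[ok] + 1L]
    alleles[ok, 2L * j] <- a2[dose[ok] + 1L]
  }
  ped <- cbind("FAM", rownames(geno), 0L, 0L, sexcode, -9L, alleles)
  write.table(ped, paste0(prefix, ".ped"), quote = FALSE, sep = " ",
              row.names = FALSE, col.names = FALSE)
  write.table(map[, c("chr", "snp", "pos")],
              paste0(prefix, ".map"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  invisible(prefix)
}

#' @rdname write_plink
#' @export
read_plink <- function(prefix) {
  map <- read.table(paste0(prefix, ".map"), header = FALSE,
                    col.names = c("chr", "snp", "pos"),
                    colClasses = c("character", "character", "integer"))
  ped <- read.table(paste0(prefix, ".ped"), header = FALSE,
                    colClasses = "character")
  ids <- ped[[2]]
  al <- as.matrix(ped[, -(1:6), drop = FALSE])
  m <- ncol(al) / 2L
  if (m != nrow(map)) stop("PED/MAP column mismatch")
  geno <- matrix(NA_integer_, nrow(al), m)
  for (j in seq_len(m)) {
    x1 <- al[, 2L * j - 1L]; x2 <- al[, 2L * j]
    miss <- x1 == "0" | x2 == "0"
    seen <- unique(c(x1[!miss], x2[!miss]))
    if (length(seen) > 2) stop("SNP ", map$snp[j], " is not biallelic")
    ref <- if (all(seen %in% c("A", "B"))) "A" else seen[1] # A/B coding counts A
    geno[, j] <- (x1 == ref) + (x2 == ref)
    geno[miss, j] <- NA_integer_
  }
  dimnames(geno) <- list(ids, map$snp)
  attr(geno, "map") <- map
  geno
}

#' Write a pedigree as CSV
#'
#' Columns `id`, `sire`, `dam`, `sex`, `cohort`; unknown parents coded 0.
#' @param ped a `ped` data frame.
#' @param path output file.
#' @export
write_pedigree <- function(ped, path) {
  write.table(as.data.frame(ped), path, quote = FALSE, sep = ",",
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_pedigree
#' @export
read_pedigree <- function(path) {
  ped <- read.table(path, header = TRUE, sep = ",",
                    stringsAsFactors = FALSE)
  class(ped) <- c("ped", "data.frame")
  validate_pedigree(ped)
  ped
}
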