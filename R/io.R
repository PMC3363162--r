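## File readers and writers.  Conventions: TSV with header; NA = missing
## phenotype; 0 = unknown parent; map positions in Morgan internally and
## centiMorgan in PLINK .map files; genotype codes 0/1/2.

#' Write / read a genotype matrix as TSV
#'
#' Rows = individuals (first column `id`), remaining columns one per SNP.
#'
#' @param geno `geno_matrix` or 0/1/2 matrix with dimnames.
#' @param path output file.
#' @export
write_genotypes_tsv <- function(geno, path) {
  M <- if (inherits(geno, "geno_matrix")) geno$geno else geno
  df <- data.frame(id = rownames(M), M, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_genotypes_tsv
#' @param map optional map data.frame to attach to the returned object.
#' @return `read_genotypes_tsv()`: a `geno_matrix` (without phase).
#' @export
read_genotypes_tsv <- function(path, map = NULL) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (anyDuplicated(df$id)) stop("duplicate individual id in ", path)
  M <- as.matrix(df[, -1, drop = FALSE])
  bad <- which(!(is.na(M) | M %in% c(0, 1, 2)), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("invalid genotype code at row %d (id %s), SNP %s",
                 bad[1, 1], df$id[bad[1, 1]], colnames(M)[bad[1, 2]]))
  storage.mode(M) <- "integer"
  rownames(M) <- as.character(df$id)
  if (!is.null(map) && nrow(map) != ncol(M))
    stop("SNP count mismatch between genotype file and map")
  structure(list(geno = M, pat = NULL, mat = NULL, map = map),
            class = "geno_matrix")
}

#' Write / read PLINK-style ped/map files
#'
#' `.map` columns: chromosome, SNP id, position in centiMorgan, bp (0).
#' `.ped` columns: family (0), id, sire, dam, sex (0), phenotype (-9),
#' then two allele columns per SNP coded A/B (B = counted allele).
#'
#' @param geno `geno_matrix`.
#' @param ped pedigree data.frame aligned with the genotype rows.
#' @param prefix path prefix (writes `prefix.ped`, `prefix.map`).
#' @export
write_plink <- function(geno, ped, prefix) {
  M <- geno$geno
  map <- geno$map
  write.table(data.frame(map$chr, map$snp, map$pos * 100, 0L),
              paste0(prefix, ".map"), sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  a1 <- matrix("A", nrow(M), ncol(M)); a2 <- a1
  a1[M >= 1] <- "B"; a2[M == 2] <- "B"
  inter <- matrix("", nrow(M), 2 * ncol(M))
  inter[, seq(1, 2 * ncol(M), 2)] <- a1
  inter[, seq(2, 2 * ncol(M), 2)] <- a2
  out <- cbind(0L, rownames(M), ped$sire, ped$dam, 0L, -9L, inter)
  write.table(out, paste0(prefix, ".ped"), sep = " ", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
}

#' @rdname write_plink
#' @return `read_plink()`: a `geno_matrix` with codes = counts of the B
#'   allele (allele ordering is deterministic: the first-seen allele per
#'   SNP is the reference).
#' @export
read_plink <- function(prefix) {
  map <- read.table(paste0(prefix, ".map"), sep = "\t",
                    col.names = c("chr", "snp", "cm", "bp"),
                    stringsAsFactors = FALSE)
  map <- data.frame(snp = map$snp, chr = map$chr, pos = map$cm / 100,
                    stringsAsFactors = FALSE)
  ped <- read.table(paste0(prefix, ".ped"), sep = " ",
                    stringsAsFactors = FALSE, colClasses = "character")
  m <- nrow(map)
  if (ncol(ped) != 6 + 2 * m)
    stop("ped/map mismatch: expected ", 6 + 2 * m, " columns, found ", ncol(ped))
  ids <- ped[[2]]
  al <- as.matrix(ped[, -(1:6), drop = FALSE])
  M <- matrix(0L, length(ids), m)
  for (k in seq_len(m)) {
    pair <- al[, c(2 * k - 1, 2 * k), drop = FALSE]
    ref <- pair[1, 1]   # first-seen allele = reference (code 0)
    M[, k] <- (pair[, 1] != ref) + (pair[, 2] != ref)
  }
  rownames(M) <- ids
  colnames(M) <- map$snp
  structure(list(geno = M, pat = NULL, mat = NULL, map = map),
            class = "geno_matrix")
}

#' Write / read a pedigree TSV (id, sire, dam; 0 = unknown)
#' @param ped pedigree data.frame.
#' @param path file path.
#' @export
write_pedigree_tsv <- function(ped, path) {
  write.table(ped[, c("id", "sire", "dam")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
}

#' @rdname write_pedigree_tsv
#' @export
read_pedigree_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write / read phenotypes (id, phenotype; NA = missing)
#' @param truth data.frame with `id` and `phenotype`.
#' @param path file path.
#' @export
write_phenotypes_tsv <- function(truth, path) {
  write.table(truth[, c("id", "phenotype")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
}

#' @rdname write_phenotypes_tsv
#' @export
read_phenotypes_tsv <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Write simulation truth (id, true breeding value, genetic value)
#' @param truth `true_values`.
#' @param path file path.
#' @export
write_truth_tsv <- function(truth, path) {
  write.table(truth[, c("id", "bv", "gv")], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
}

#' Write a QTL architecture as JSON
#' @param arch `qtl_architecture`.
#' @param path file path.
#' @export
write_architecture_json <- function(arch, path) {
  jsonlite::write_json(
    list(qtl_share = attr(arch, "qtl_share"),
         imprinting = attr(arch, "imprinting"),
         qtl = as.data.frame(arch)),
    path, auto_unbox = TRUE, digits = NA)
}
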