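## SNP quality control and design-matrix coding.

#' Minor allele frequency of one SNP
#'
#' `min(p, 1 - p)` with `p = mean(code) / 2` over non-missing 0/1/2 codes.
#'
#' @param codes integer/numeric vector of allele counts (NA = missing).
#' @return MAF in \[0, 0.5\].
#' @export
compute_maf <- function(codes) {
  codes <- codes[!is.na(codes)]
  if (!length(codes)) stop("all genotypes missing; MAF undefined")
  p <- mean(codes) / 2
  min(p, 1 - p)
}

#' Filter SNPs by monomorphism and MAF
#'
#' Monomorphic SNPs are removed first, then SNPs with MAF below the
#' threshold among the remainder, so the two reported counts are disjoint.
#' SNP order and the genetic map are preserved.  MAF is computed on all
#' genotyped individuals.
#'
#' @param geno `geno_matrix` (or plain 0/1/2 matrix).
#' @param maf_threshold MAF threshold in \[0, 0.5); default 0.01.
#' @return List with `geno` (filtered object of the same kind) and `report`
#'   (class `qc_report`): counts `n_monomorphic`, `n_low_maf`, `n_retained`,
#'   logical `keep`, and per-SNP `maf`.
#' @export
filter_snps <- function(geno, maf_threshold = 0.01) {
  if (maf_threshold < 0 || maf_threshold >= 0.5)
    stop("maf_threshold must lie in [0, 0.5)")
  is_obj <- inherits(geno, "geno_matrix")
  M <- if (is_obj) geno$geno else geno
  if (anyNA(M)) {
    # mean imputation keeps the sampler design dense; flagged to the user
    warning("missing genotypes mean-imputed per SNP")
    for (k in which(colSums(is.na(M)) > 0)) {
      mk <- M[, k]; mk[is.na(mk)] <- mean(mk, na.rm = TRUE); M[, k] <- mk
    }
  }
  maf <- apply(M, 2, compute_maf)
  mono <- apply(M, 2, function(x) length(unique(x)) == 1L)
  low <- !mono & maf < maf_threshold
  keep <- !mono & !low
  report <- structure(list(
    n_monomorphic = sum(mono), n_low_maf = sum(low), n_retained = sum(keep),
    n_input = ncol(M), maf = maf, keep = keep,
    maf_threshold = maf_threshold), class = "qc_report")
  if (is_obj) {
    out <- geno
    out$geno <- M[, keep, drop = FALSE]
    out$map <- geno$map[keep, , drop = FALSE]
    if (!is.null(out$pat)) out$pat <- geno$pat[, keep, drop = FALSE]
    if (!is.null(out$mat)) out$mat <- geno$mat[, keep, drop = FALSE]
  } else {
    out <- M[, keep, drop = FALSE]
  }
  list(geno = out, report = report)
}

#' @exportS3Method base::print
print.qc_report <- function(x, ...) {
  cat(sprintf(
    "SNP QC: %d input; %d monomorphic removed; %d below MAF %.3g removed; %d retained\n",
    x$n_input, x$n_monomorphic, x$n_low_maf, x$maf_threshold, x$n_retained))
  invisible(x)
}

#' Design-matrix coding of SNP genotypes
#'
#' Additive column = allele count; dominance column = heterozygote
#' indicator.  Columns are mean-centered by default (the intercept absorbs
#' the shift, so fitted values are unchanged except through the mean).
#'
#' @param geno `geno_matrix` or 0/1/2 matrix.
#' @param coding `"additive"` or `"additive+dominance"`.
#' @param center center columns (default TRUE).
#' @return Numeric design matrix; with dominance, dominance columns follow
#'   the additive block and carry suffix `_d`.  Attribute `centers` stores
#'   the subtracted column means.
#' @export
code_design <- function(geno, coding = c("additive", "additive+dominance"),
                        center = TRUE) {
  coding <- match.arg(coding)
  M <- if (inherits(geno, "geno_matrix")) geno$geno else geno
  X <- matrix(as.numeric(M), nrow(M), ncol(M), dimnames = dimnames(M))
  if (coding == "additive+dominance") {
    D <- matrix(as.numeric(M == 1), nrow(M), ncol(M))
    colnames(D) <- paste0(colnames(M), "_d")
    X <- cbind(X, D)
  }
  centers <- rep(0, ncol(X))
  if (center) {
    centers <- colMeans(X)
    X <- sweep(X, 2, centers)
  }
  attr(X, "centers") <- centers
  attr(X, "coding") <- coding
  X
}
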