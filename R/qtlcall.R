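## QTL region calling from classified SNPs via LD grouping, and genomic
## breeding-value prediction/validation.

#' Composite LD between two SNPs
#'
#' Squared Pearson correlation of genotype codes (phase-free composite
#' r^2).
#'
#' @param col_a,col_b 0/1/2 genotype code vectors of equal length.
#' @return r^2 in \[0, 1\].
#' @export
ld_r2 <- function(col_a, col_b) {
  if (var(col_a) == 0 || var(col_b) == 0)
    stop("ld_r2 requires both columns polymorphic")
  cor(col_a, col_b)^2
}

#' Group significant/putative SNPs into QTL regions
#'
#' Per chromosome, average-linkage agglomerative clustering on the pairwise
#' r^2 matrix of the classified SNPs: clusters merge while their mean
#' inter-cluster r^2 is at least `r2_threshold` and the map gap between
#' them is at most `max_gap`.  Each resulting cluster is one putative QTL
#' region; the peak SNP is the member with the largest Bayes factor, and
#' the region is "significant" if any member is.
#'
#' @param snp_table per-SNP summary ([summarize_snps()]); only rows with
#'   `class != "none"` are grouped.
#' @param geno `geno_matrix` (or 0/1/2 matrix with columns matching
#'   `snp_table$snp`) supplying genotypes for r^2.
#' @param r2_threshold mean-linkage r^2 threshold; default 0.7.
#' @param max_gap maximum map gap (Morgan) between merged clusters; default
#'   0.1.
#' @param r2_matrix optional precomputed r^2 matrix with dimnames covering
#'   the classified SNP ids; when supplied, genotypes are only used as a
#'   fallback.
#' @return data.frame of class `qtl_calls`: one row per region with
#'   `region`, `chr`, `n_snps`, `members` (comma-separated SNP ids),
#'   `span_lo`, `span_hi`, `peak_snp`, `peak_bf`, `class`.
#' @export
group_snps_to_qtl <- function(snp_table, geno, r2_threshold = 0.7,
                              max_gap = 0.1, r2_matrix = NULL) {
  M <- if (inherits(geno, "geno_matrix")) geno$geno else geno
  hits <- snp_table[snp_table$class != "none", , drop = FALSE]
  if (nrow(hits) == 0L)
    return(structure(data.frame(region = integer(), chr = integer(),
                                n_snps = integer(), members = character(),
                                span_lo = numeric(), span_hi = numeric(),
                                peak_snp = character(), peak_bf = numeric(),
                                class = character(), stringsAsFactors = FALSE),
                     class = c("qtl_calls", "data.frame")))
  hits <- hits[order(hits$chr, hits$pos), , drop = FALSE]
  out <- list(); region <- 0L
  for (c_ in unique(hits$chr)) {
    h <- hits[hits$chr == c_, , drop = FALSE]
    k <- nrow(h)
    R2 <- matrix(1, k, k)
    if (k > 1) {
      if (!is.null(r2_matrix)) {
        R2 <- r2_matrix[h$snp, h$snp]
      } else {
        cols <- match(h$snp, colnames(M))
        if (anyNA(cols)) stop("snp_table contains SNPs absent from the genotypes")
        cc <- suppressWarnings(cor(M[, cols, drop = FALSE]))
        cc[is.na(cc)] <- 0
        R2 <- cc^2
      }
    }
    # average-linkage agglomeration with a map-gap constraint
    clusters <- as.list(seq_len(k))
    repeat {
      if (length(clusters) < 2) break
      best <- NULL; best_r2 <- -Inf
      for (i in seq_len(length(clusters) - 1)) {
        for (j in (i + 1):length(clusters)) {
          ci <- clusters[[i]]; cj <- clusters[[j]]
          gap <- min(abs(outer(h$pos[ci], h$pos[cj], "-")))
          if (gap > max_gap) next
          mr2 <- mean(R2[ci, cj])
          if (mr2 > best_r2) { best_r2 <- mr2; best <- c(i, j) }
        }
      }
      if (is.null(best) || best_r2 < r2_threshold) break
      clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
      clusters[[best[2]]] <- NULL
    }
    for (cl in clusters) {
      cl <- sort(cl)
      region <- region + 1L
      peak <- cl[which.max(h$bf[cl])]
      out[[region]] <- data.frame(
        region = region, chr = c_, n_snps = length(cl),
        members = paste(h$snp[cl], collapse = ","),
        span_lo = min(h$pos[cl]), span_hi = max(h$pos[cl]),
        peak_snp = h$snp[peak], peak_bf = h$bf[peak],
        class = if (any(h$class[cl] == "significant")) "significant" else "putative",
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chr, res$span_lo), , drop = FALSE]
  res$region <- seq_len(nrow(res))
  rownames(res) <- NULL
  class(res) <- c("qtl_calls", "data.frame")
  res
}

#' Genomic estimated breeding values
#'
#' Posterior mean total genetic merit per pedigree individual:
#' `gebv_i = E[a_i | y] + sum_k x_ik E[alpha_k | y]` using the chain's
#' running posterior means (including for the individuals without
#' phenotypes, which is the point of the exercise).
#'
#' @param chain `bvs_chain` from [fit_bvs()].
#' @param geno `geno_matrix` covering all pedigree individuals.
#' @param include_polygenic include the pedigree term (default TRUE; FALSE
#'   gives the SNP-only genomic value).
#' @return data.frame of class `gebv_table`: `id`, `gebv`.
#' @export
predict_gebv <- function(chain, geno, include_polygenic = TRUE) {
  M <- if (inherits(geno, "geno_matrix")) geno$geno else geno
  ids <- chain$ids %||% rownames(M)
  M <- M[ids, chain$snp_ids, drop = FALSE]
  X <- sweep(matrix(as.numeric(M), nrow(M), ncol(M)), 2,
             chain$X_centers %||% rep(0, ncol(M)))
  g_snp <- as.numeric(X %*% chain$alpha_mean)
  gebv <- g_snp + if (include_polygenic) as.numeric(chain$a_mean[ids]) else 0
  structure(data.frame(id = ids, gebv = gebv, stringsAsFactors = FALSE),
            class = c("gebv_table", "data.frame"))
}

#' Validate predicted breeding values against simulated truth
#'
#' @param gebv `gebv_table` from [predict_gebv()].
#' @param truth `true_values` from [simulate_phenotypes()] (or any
#'   data.frame with `id` and a truth column).
#' @param subset optional id vector restricting the comparison (typically
#'   the unphenotyped offspring).
#' @param truth_col column of `truth` to validate against; default `"bv"`.
#' @return List with `correlation` (Pearson), `slope` (regression of truth
#'   on GEBV, a bias check) and `n`.
#' @export
validate_gebv <- function(gebv, truth, subset = NULL, truth_col = "bv") {
  m <- merge(gebv, truth[, c("id", truth_col)], by = "id")
  if (!is.null(subset)) m <- m[m$id %in% subset, , drop = FALSE]
  if (nrow(m) < 3) stop("fewer than 3 overlapping individuals")
  tv <- m[[truth_col]]
  list(correlation = cor(m$gebv, tv),
       slope = if (var(m$gebv) > 0) coef(lm(tv ~ m$gebv))[[2]] else NA_real_,
       n = nrow(m))
}
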