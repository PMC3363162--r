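## Pedigree relationship machinery: numerator relationship matrix A, its
## sparse inverse (Henderson's rules with inbreeding), and genomic kinship.

# Normalize a pedigree data.frame to dense integer ids in topological order.
# Accepts id/sire/dam with 0 (or NA) for unknown parents.
normalize_pedigree <- function(ped) {
  stopifnot(all(c("id", "sire", "dam") %in% names(ped)))
  n <- nrow(ped)
  id <- as.character(ped$id)
  if (anyDuplicated(id)) stop("duplicate individual ids in pedigree")
  lookup <- seq_len(n); names(lookup) <- id
  code <- function(x) {
    x <- as.character(x)
    out <- rep(0L, n)
    known <- !(is.na(x) | x == "0" | x == "")
    miss <- known & !(x %in% id)
    if (any(miss)) stop("parent id(s) not in pedigree: ",
                        paste(unique(x[miss]), collapse = ", "))
    out[known] <- lookup[x[known]]
    out
  }
  s <- code(ped$sire); d <- code(ped$dam)
  if (any(s >= seq_len(n) & s != 0L) || any(d >= seq_len(n) & d != 0L)) {
    ord <- order_pedigree(s, d)
    inv <- integer(n); inv[ord] <- seq_len(n)
    remap <- function(x) ifelse(x == 0L, 0L, inv[pmax(x, 1L)])
    s2 <- remap(s[ord]); d2 <- remap(d[ord])
    s <- s2; d <- d2
    id <- id[ord]
  }
  list(id = id, sire = s, dam = d, n = n)
}

# Kahn-style topological sort; detects cycles.
order_pedigree <- function(s, d) {
  n <- length(s)
  placed <- logical(n); ord <- integer(0)
  repeat {
    ready <- which(!placed &
                   (s == 0L | placed[pmax(s, 1L)]) &
                   (d == 0L | placed[pmax(d, 1L)]))
    if (!length(ready)) break
    placed[ready] <- TRUE
    ord <- c(ord, ready)
  }
  if (length(ord) < n) stop("pedigree contains a cycle (an individual is its own ancestor)")
  ord
}

#' Numerator relationship matrix from a pedigree
#'
#' Tabular method with inbreeding: for individual j with parents s, d,
#' `A[i, j] = (A[i, s] + A[i, d]) / 2` for earlier i and
#' `A[j, j] = 1 + A[s, d] / 2`.  Unknown parents are treated as unrelated
#' non-inbred founders.
#'
#' @param ped data.frame with columns `id`, `sire`, `dam` (0/NA = unknown).
#' @return A dense symmetric matrix with `dimnames` = ids, of class
#'   `relationship_matrix` (attribute `inverse = FALSE`).
#' @export
build_A <- function(ped) {
  p <- normalize_pedigree(ped)
  n <- p$n
  A <- matrix(0, n, n)
  for (j in seq_len(n)) {
    s <- p$sire[j]; d <- p$dam[j]
    if (j > 1L) {
      i <- seq_len(j - 1L)
      as_ <- if (s > 0L) A[i, s] else 0
      ad_ <- if (d > 0L) A[i, d] else 0
      A[i, j] <- (as_ + ad_) / 2
      A[j, i] <- A[i, j]
    }
    A[j, j] <- 1 + (if (s > 0L && d > 0L) A[s, d] / 2 else 0)
  }
  dimnames(A) <- list(p$id, p$id)
  attr(A, "inverse") <- FALSE
  class(A) <- c("relationship_matrix", class(A))
  A
}

# Inbreeding coefficients F_i = A_ii - 1 (diagonal of the tabular A).
inbreeding_coefficients <- function(p) {
  n <- p$n
  # tabular diagonal needs ancestor relationships; reuse build_A economics
  # only when needed: founders-only pedigrees short-circuit to zero.
  if (all(p$sire == 0L & p$dam == 0L)) return(numeric(n))
  A <- matrix(0, n, n)
  f <- numeric(n)
  for (j in seq_len(n)) {
    s <- p$sire[j]; d <- p$dam[j]
    if (j > 1L) {
      i <- seq_len(j - 1L)
      as_ <- if (s > 0L) A[i, s] else 0
      ad_ <- if (d > 0L) A[i, d] else 0
      A[i, j] <- (as_ + ad_) / 2
      A[j, i] <- A[i, j]
    }
    A[j, j] <- 1 + (if (s > 0L && d > 0L) A[s, d] / 2 else 0)
    f[j] <- A[j, j] - 1
  }
  f
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with inbreeding: the Mendelian-sampling variance of
#' individual j is `0.5 - 0.25 (F_s + F_d)` with both parents known,
#' `0.75 - 0.25 F_p` with one parent known, and 1 for founders; its inverse
#' is added to the diagonal and propagated to parent blocks with the usual
#' (1, -1/2, 1/4) pattern.
#'
#' @param ped data.frame with columns `id`, `sire`, `dam`.
#' @return A `Matrix::dsCMatrix` sparse symmetric matrix with attribute
#'   `inverse = TRUE`.
#' @export
build_A_inverse <- function(ped) {
  p <- normalize_pedigree(ped)
  n <- p$n
  f <- inbreeding_coefficients(p)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  push <- function(i, j, x) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, x)
  }
  for (j in seq_len(n)) {
    s <- p$sire[j]; d <- p$dam[j]
    fs <- if (s > 0L) f[s] else 0
    fd <- if (d > 0L) f[d] else 0
    mend <- if (s > 0L && d > 0L) 0.5 - 0.25 * (fs + fd)
            else if (s > 0L || d > 0L) 0.75 - 0.25 * (fs + fd)
            else 1
    al <- 1 / mend
    push(j, j, al)
    for (par in c(s, d)[c(s, d) > 0L]) {
      push(par, j, -al / 2); push(j, par, -al / 2)
      push(par, par, al / 4)
    }
    if (s > 0L && d > 0L && s != d) {
      push(s, d, al / 4); push(d, s, al / 4)
    }
  }
  Ainv <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                               dimnames = list(p$id, p$id))
  Ainv <- Matrix::forceSymmetric(Matrix::drop0(Ainv))
  attr(Ainv, "inverse") <- TRUE
  Ainv
}

#' VanRaden genomic kinship matrix
#'
#' `G = W W' / (2 * sum p (1 - p))` with `W` the genotype matrix centered by
#' twice the observed allele frequency.  Used here as a sanity check that
#' founder groups (e.g. sires vs dams) descend from one population.
#'
#' @param geno `geno_matrix` object or plain 0/1/2 matrix (rows =
#'   individuals).
#' @return A symmetric kinship matrix.
#' @export
genomic_kinship <- function(geno) {
  M <- if (inherits(geno, "geno_matrix")) geno$geno else geno
  stopifnot(is.matrix(M), nrow(M) >= 2)
  p <- colMeans(M) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("all SNPs are monomorphic; kinship undefined")
  W <- sweep(M[, poly, drop = FALSE], 2, 2 * p[poly])
  denom <- 2 * sum(p[poly] * (1 - p[poly]))
  G <- tcrossprod(W) / denom
  dimnames(G) <- list(rownames(M), rownames(M))
  G
}

#' One-population check on kinship group structure
#'
#' Compares mean off-diagonal kinship within and between two groups against
#' a permutation null.  If the groups descend from one population the
#' observed within-vs-between contrast is well inside the permutation
#' spread.
#'
#' @param K kinship matrix.
#' @param groups factor/vector of length nrow(K) with two levels.
#' @param n_perm number of label permutations.
#' @return List with `contrast` (mean within - mean between), `perm_sd`,
#'   `z`, and `p_value` (two-sided permutation p).
#' @export
kinship_group_contrast <- function(K, groups, n_perm = 500) {
  stopifnot(nrow(K) == length(groups))
  groups <- as.factor(groups)
  stopifnot(nlevels(groups) == 2)
  off <- upper.tri(K)
  contrast_of <- function(g) {
    same <- outer(g, g, "==")[off]
    mean(K[off][same]) - mean(K[off][!same])
  }
  obs <- contrast_of(groups)
  perm <- replicate(n_perm, contrast_of(sample(groups)))
  z <- (obs - mean(perm)) / sd(perm)
  p <- (1 + sum(abs(perm - mean(perm)) >= abs(obs - mean(perm)))) / (1 + n_perm)
  list(contrast = obs, perm_sd = sd(perm), z = z, p_value = p)
}
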