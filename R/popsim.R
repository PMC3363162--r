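## Synthetic population generator: genetic map, founder haplotypes with LD,
## pedigree, gene drop, QTL architecture and phenotypes.

#' Build an equally spaced genetic map
#'
#' SNPs are placed at equal intervals on each chromosome, mirroring a
#' simulated dense marker panel (the default full design is 9,990 SNPs
#' equally distributed over 5 chromosomes of 1 Morgan each).
#'
#' @param n_chr number of chromosomes.
#' @param snps_per_chr SNPs per chromosome (equal across chromosomes).
#' @param chr_length chromosome length in Morgan.
#' @return A data.frame with columns `snp`, `chr`, `pos` (Morgan, within
#'   chromosome). Positions are strictly increasing within a chromosome.
#' @export
make_genetic_map <- function(n_chr = 5L, snps_per_chr = 1998L, chr_length = 1) {
  stopifnot(n_chr >= 1, snps_per_chr >= 1, chr_length >= 0)
  m <- n_chr * snps_per_chr
  chr <- rep(seq_len(n_chr), each = snps_per_chr)
  # first marker a half-interval in from the telomere
  pos <- rep(chr_length * (seq_len(snps_per_chr) - 0.5) / snps_per_chr, n_chr)
  map <- data.frame(
    snp = sprintf("snp_%d_%d", chr, rep(seq_len(snps_per_chr), n_chr)),
    chr = chr, pos = pos, stringsAsFactors = FALSE
  )
  attr(map, "chr_length") <- rep(chr_length, n_chr)
  map
}

validate_map <- function(map) {
  stopifnot(is.data.frame(map), all(c("snp", "chr", "pos") %in% names(map)))
  if (nrow(map) == 0L) stop("map contains zero SNPs")
  if (any(map$pos < 0)) stop("map positions must be non-negative")
  for (c_ in unique(map$chr)) {
    p <- map$pos[map$chr == c_]
    if (any(diff(p) < 0)) stop("map positions must be non-decreasing within a chromosome")
    # ties are only admissible on a degenerate zero-length chromosome
    if (any(diff(p) == 0) && max(p) > min(p))
      stop("map positions must be strictly increasing within a chromosome")
  }
  invisible(map)
}

map_chr_arrays <- function(map) {
  chrs <- unique(map$chr)
  start <- integer(length(chrs)); end <- integer(length(chrs))
  len <- attr(map, "chr_length")
  if (is.null(len)) len <- vapply(chrs, function(c_) max(map$pos[map$chr == c_]), 0)
  for (i in seq_along(chrs)) {
    idx <- which(map$chr == chrs[i])
    start[i] <- min(idx) - 1L   # 0-based [start, end)
    end[i] <- max(idx)
  }
  list(pos = map$pos, chr_len = as.numeric(len), chr_start = start, chr_end = end)
}

#' Simulate LD-bearing founder haplotypes
#'
#' Approximates a long-history outbred population by a two-phase forward
#' random-mating simulation: a long phase at moderate population size builds
#' background linkage disequilibrium and an allele-frequency spectrum
#' (including monomorphic and rare SNPs, which gives the QC filters work to
#' do), then a short bottleneck at small size sharpens short-range LD —
#' mirroring, at reduced scale, a large historical population followed by a
#' recent bottleneck of 30 generations of 150 individuals.  Keeping the long
#' phase at moderate size matters: it keeps the founders' mutual relatedness
#' low, so the pedigree's assumption of unrelated founders is approximately
#' true, as it is in the emulated population.  With `n_burn_generations = 0`
#' and `n_bottleneck_generations = 0` the haplotypes are drawn independently
#' (linkage equilibrium).
#'
#' @param n_founders number of founder individuals to output (>= 2).
#' @param map genetic map from [make_genetic_map()].
#' @param n_burn_generations long-phase generations (default 300).
#' @param pop_size long-phase population size (default 500).
#' @param n_bottleneck_generations bottleneck generations (default 30).
#' @param bottleneck_size bottleneck population size (default 150).
#' @param init_freq length-2 range from which initial allele frequencies are
#'   drawn uniformly, or a single frequency applied to every SNP.
#' @param seed integer seed (optional).
#' @return Object of class `founder_haps`: list with `haps`
#'   (2*n_founders x m binary matrix) and `freq` (realized allele
#'   frequencies).
#' @export
simulate_founder_haplotypes <- function(n_founders, map,
                                        n_burn_generations = 300L,
                                        pop_size = 500L,
                                        n_bottleneck_generations = 30L,
                                        bottleneck_size = 150L,
                                        init_freq = c(0.05, 0.95),
                                        seed = NULL) {
  validate_map(map)
  stopifnot(n_founders >= 2)
  if (n_burn_generations < 0 || n_bottleneck_generations < 0)
    stop("generation counts must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  m <- nrow(map)
  f0 <- if (length(init_freq) == 1L) rep(init_freq, m) else runif(m, init_freq[1], init_freq[2])
  arr <- map_chr_arrays(map)
  # n_burn_generations = 0 means "no shared history at all": haplotypes are
  # independent draws and the bottleneck is skipped too
  n_gen_total <- if (n_burn_generations == 0L) 0L
                 else n_burn_generations + n_bottleneck_generations
  if (n_gen_total == 0L) {
    haps <- matrix(rbinom(2L * n_founders * m, 1L, rep(f0, each = 2L * n_founders)),
                   nrow = 2L * n_founders, ncol = m)
  } else {
    start_n <- if (n_burn_generations > 0L) pop_size else bottleneck_size
    haps <- matrix(rbinom(2L * start_n * m, 1L, rep(f0, each = 2L * start_n)),
                   nrow = 2L * start_n, ncol = m)
    if (n_burn_generations > 0L) {
      n_out1 <- if (n_bottleneck_generations > 0L) bottleneck_size else n_founders
      haps <- .evolve_founders_cpp(haps, arr$pos, arr$chr_len,
                                   arr$chr_start, arr$chr_end,
                                   as.integer(n_burn_generations),
                                   as.integer(pop_size), as.integer(n_out1))
    }
    if (n_bottleneck_generations > 0L) {
      haps <- .evolve_founders_cpp(haps, arr$pos, arr$chr_len,
                                   arr$chr_start, arr$chr_end,
                                   as.integer(n_bottleneck_generations),
                                   as.integer(bottleneck_size),
                                   as.integer(n_founders))
    }
  }
  structure(list(haps = haps, freq = colMeans(haps), map = map),
            class = "founder_haps")
}

#' Build a sire x dam x offspring mating-design pedigree
#'
#' Founders (sires then dams) are listed first with unknown parents; every
#' offspring has one sire and one dam.  The default full design is 20 sires
#' each mated to 10 dams with 15 offspring per dam: 3,220 individuals in
#' total, 3,000 of them offspring.
#'
#' @param n_sires,n_dams_per_sire,n_offspring_per_dam design counts (>= 1).
#' @return A data.frame with columns `id`, `sire`, `dam` (0 = unknown),
#'   `role` ("sire"/"dam"/"offspring") and `family` (dam index; NA for
#'   founders).  Ids are dense integers in chronological (topological) order.
#' @export
build_pedigree <- function(n_sires, n_dams_per_sire, n_offspring_per_dam) {
  stopifnot(n_sires >= 1, n_dams_per_sire >= 1, n_offspring_per_dam >= 1)
  n_dams <- n_sires * n_dams_per_sire
  n_off <- n_dams * n_offspring_per_dam
  n <- n_sires + n_dams + n_off
  id <- seq_len(n)
  sire <- integer(n); dam <- integer(n)
  role <- c(rep("sire", n_sires), rep("dam", n_dams), rep("offspring", n_off))
  family <- rep(NA_integer_, n)
  k <- n_sires + n_dams
  fam <- 0L
  for (s in seq_len(n_sires)) {
    for (d in seq_len(n_dams_per_sire)) {
      fam <- fam + 1L
      dam_id <- n_sires + fam
      for (o in seq_len(n_offspring_per_dam)) {
        k <- k + 1L
        sire[k] <- s
        dam[k] <- dam_id
        family[k] <- fam
      }
    }
  }
  data.frame(id = id, sire = sire, dam = dam, role = role, family = family,
             stringsAsFactors = FALSE)
}

#' Drop founder haplotypes down a pedigree
#'
#' Each non-founder receives a paternal gamete recombined from its sire's
#' two haplotypes and a maternal gamete from its dam's (Haldane model:
#' Poisson crossover counts, uniform positions).  Phase is retained so
#' parent-of-origin (imprinting) effects can be simulated.
#'
#' @param ped pedigree from [build_pedigree()] (or any topologically ordered
#'   id/sire/dam data.frame with integer ids).
#' @param founders `founder_haps` object; founder count must be at least the
#'   number of pedigree founders.
#' @param map genetic map (must match the founder haplotypes).
#' @param seed integer seed (optional).
#' @return Object of class `geno_matrix`: list with `geno` (n x m 0/1/2
#'   matrix, rownames = ids), `pat`/`mat` phased haplotype matrices, `map`,
#'   and crossover bookkeeping (`n_crossovers`, `n_meioses`).
#' @export
drop_genotypes <- function(ped, founders, map, seed = NULL) {
  validate_map(map)
  stopifnot(inherits(founders, "founder_haps"), nrow(map) == ncol(founders$haps))
  if (!is.null(seed)) set.seed(seed)
  sire0 <- as.integer(ped$sire) - 1L   # -1 = unknown
  dam0 <- as.integer(ped$dam) - 1L
  n_f <- sum(ped$sire == 0 & ped$dam == 0)
  if (nrow(founders$haps) < 2L * n_f)
    stop("pedigree has ", n_f, " founders but only ",
         nrow(founders$haps) %/% 2L, " founder individuals were simulated")
  arr <- map_chr_arrays(map)
  res <- .gene_drop_cpp(sire0, dam0, founders$haps, arr$pos, arr$chr_len,
                        arr$chr_start, arr$chr_end)
  geno <- res$pat + res$mat
  rownames(geno) <- as.character(ped$id)
  colnames(geno) <- map$snp
  structure(list(geno = geno, pat = res$pat, mat = res$mat, map = map,
                 n_crossovers = res$n_crossovers, n_meioses = res$n_meioses),
            class = "geno_matrix")
}

#' Default QTL architecture configuration
#'
#' @param qtl_share share of total genetic variance explained jointly by the
#'   QTL (remainder is polygenic); default 0.7.
#' @param min_maf minimum allele frequency for a SNP to host a QTL.
#' @param repulsion_gap maximum map distance (Morgan) between the two
#'   linked-in-repulsion QTL.
#' @param imprinting parental origin expressing the imprinted QTL.
#' @param n_qtl_chr integer vector: additive QTL per chromosome for
#'   chromosomes that carry plain additive QTL.
#' @return A list of class `qtl_config`.
#' @export
qtl_config <- function(qtl_share = 0.7, min_maf = 0.15, repulsion_gap = 0.05,
                       imprinting = c("paternal", "maternal"),
                       n_qtl_chr = c(1L, 2L)) {
  imprinting <- match.arg(imprinting)
  stop_if_not_scalar_prob(qtl_share, "qtl_share")
  structure(list(qtl_share = qtl_share, min_maf = min_maf,
                 repulsion_gap = repulsion_gap, imprinting = imprinting,
                 n_qtl_chr = n_qtl_chr),
            class = "qtl_config")
}

#' Assign a QTL architecture on the map
#'
#' Default architecture over five chromosomes: one additive QTL on
#' chromosome 1, two on chromosome 2, two tightly linked QTL in repulsion on
#' chromosome 3 (opposite-sign effects whose increasing alleles sit on
#' opposite haplotypes, so marginal signals partially cancel), one imprinted
#' QTL on chromosome 4 (paternally expressed by default) and one
#' additive-by-additive epistatic pair on chromosome 5 — seven QTL entries in
#' total.  Relative effect sizes are set so each architecture component
#' contributes equal genetic variance; the absolute scale is fixed later by
#' [simulate_phenotypes()] so the QTL jointly explain `config$qtl_share` of
#' the genetic variance.
#'
#' @param geno `geno_matrix` from [drop_genotypes()] (used to pick
#'   sufficiently polymorphic SNPs and to phase the repulsion pair).
#' @param config a [qtl_config()].
#' @param seed integer seed (optional).
#' @return A data.frame of class `qtl_architecture`: one row per QTL entry
#'   with columns `qtl`, `chr`, `snp` (index), `snp2` (partner index for the
#'   epistatic pair, NA otherwise), `mode`, `effect`, `component`.
#' @export
assign_qtl_architecture <- function(geno, config = qtl_config(), seed = NULL) {
  stopifnot(inherits(geno, "geno_matrix"))
  if (!is.null(seed)) set.seed(seed)
  map <- geno$map
  chrs <- sort(unique(map$chr))
  if (length(chrs) < 5)
    stop("the default architecture needs 5 chromosomes; got ", length(chrs))
  p <- colMeans(geno$geno) / 2
  maf <- pmin(p, 1 - p)
  eligible <- function(c_) {
    idx <- which(map$chr == c_ & maf >= config$min_maf)
    # keep away from chromosome ends
    rng <- range(map$pos[map$chr == c_])
    idx[map$pos[idx] > rng[1] + 0.1 * diff(rng) &
        map$pos[idx] < rng[2] - 0.1 * diff(rng)]
  }
  pick_spread <- function(idx, k, min_gap) {
    # sample k SNPs at least min_gap Morgan apart
    for (try in 1:200) {
      cand <- sort(sample(idx, k))
      if (k == 1L || min(diff(map$pos[cand])) >= min_gap) return(cand)
    }
    stop("could not place ", k, " QTL with the requested spacing")
  }
  rows <- list(); comp <- 0L
  add_row <- function(chr, snp, snp2, mode, effect, component)
    data.frame(chr = chr, snp = snp, snp2 = snp2, mode = mode,
               effect = effect, component = component)
  # chromosomes 1..2: plain additive QTL
  for (i in seq_along(config$n_qtl_chr)) {
    k <- config$n_qtl_chr[i]
    if (k < 1L) next
    idx <- eligible(chrs[i])
    if (length(idx) < k) stop("not enough polymorphic SNPs on chromosome ", chrs[i])
    for (s in pick_spread(idx, k, 0.25)) {
      comp <- comp + 1L
      rows[[length(rows) + 1L]] <- add_row(chrs[i], s, NA_integer_, "additive", 1, comp)
    }
  }
  # chromosome 3: linked pair in repulsion (one variance component)
  idx3 <- eligible(chrs[3])
  ok <- FALSE
  for (try in 1:500) {
    s1 <- sample(idx3, 1L)
    near <- idx3[idx3 != s1 & map$chr[idx3] == map$chr[s1] &
                 abs(map$pos[idx3] - map$pos[s1]) <= config$repulsion_gap]
    if (length(near)) {
      # avoid near-perfect LD: complete cancellation would leave no variance
      rr <- abs(suppressWarnings(cor(geno$geno[, s1], geno$geno[, near, drop = FALSE])))
      near <- near[!is.na(rr) & rr < 0.95]
      if (length(near)) {
        s2 <- near[which.max(abs(map$pos[near] - map$pos[s1]))]
        ok <- TRUE; break
      }
    }
  }
  if (!ok) stop("could not place the linked repulsion pair on chromosome ", chrs[3])
  comp <- comp + 1L
  # repulsion: signs chosen against the local LD so the two marginal single-SNP
  # signals partially cancel (increasing alleles on opposite haplotypes)
  r12 <- suppressWarnings(cor(geno$geno[, s1], geno$geno[, s2]))
  sgn <- if (is.na(r12) || r12 >= 0) -1 else 1
  rows[[length(rows) + 1L]] <- add_row(chrs[3], min(s1, s2), NA_integer_, "additive", 1, comp)
  rows[[length(rows) + 1L]] <- add_row(chrs[3], max(s1, s2), NA_integer_, "additive", sgn, comp)
  # chromosome 4: imprinted QTL
  idx4 <- eligible(chrs[4])
  comp <- comp + 1L
  rows[[length(rows) + 1L]] <- add_row(chrs[4], sample(idx4, 1L), NA_integer_,
                                       "imprinted", 1, comp)
  # chromosome 5: epistatic pair (single entry, two SNP indices)
  idx5 <- eligible(chrs[5])
  pair <- pick_spread(idx5, 2L, 0.2)
  comp <- comp + 1L
  rows[[length(rows) + 1L]] <- add_row(chrs[5], pair[1], pair[2], "epistatic", 1, comp)
  arch <- do.call(rbind, rows)
  arch$qtl <- seq_len(nrow(arch))
  arch <- arch[, c("qtl", "chr", "snp", "snp2", "mode", "effect", "component")]
  attr(arch, "qtl_share") <- config$qtl_share
  attr(arch, "imprinting") <- config$imprinting
  class(arch) <- c("qtl_architecture", "data.frame")
  arch
}

#' Empty QTL architecture (pure polygenic trait)
#' @return A zero-row `qtl_architecture`.
#' @export
empty_architecture <- function() {
  arch <- data.frame(qtl = integer(), chr = integer(), snp = integer(),
                     snp2 = integer(), mode = character(), effect = numeric(),
                     component = integer(), stringsAsFactors = FALSE)
  attr(arch, "qtl_share") <- 0
  attr(arch, "imprinting") <- "paternal"
  class(arch) <- c("qtl_architecture", "data.frame")
  arch
}

# Per-individual QTL genetic values for one architecture component.
# Returns the raw (unit-effect) value vector; scaling happens in
# simulate_phenotypes.  Also returns the additive (transmissible) part used
# for true breeding values.
qtl_component_values <- function(geno, arch_rows, imprinting) {
  n <- nrow(geno$geno)
  gv <- numeric(n); bv <- numeric(n)
  for (r in seq_len(nrow(arch_rows))) {
    row <- arch_rows[r, ]
    if (row$mode == "additive") {
      g <- geno$geno[, row$snp]
      gv <- gv + row$effect * (g - mean(g))
      bv <- bv + row$effect * (g - mean(g))
    } else if (row$mode == "imprinted") {
      h <- if (imprinting == "paternal") geno$pat[, row$snp] else geno$mat[, row$snp]
      gv <- gv + row$effect * (h - mean(h))
      # transmissible expectation: half the effect per allele copy
      g <- geno$geno[, row$snp]
      bv <- bv + 0.5 * row$effect * (g - mean(g))
    } else if (row$mode == "epistatic") {
      ga <- geno$geno[, row$snp] - 1
      gb <- geno$geno[, row$snp2] - 1
      v <- ga * gb
      gv <- gv + row$effect * (v - mean(v))
      # additive-by-additive interaction on centered codes: no marginal
      # additive part beyond allele-frequency leakage, which we fold into gv
    } else stop("unknown QTL mode: ", row$mode)
  }
  list(gv = gv, bv = bv)
}

#' Simulate a partially phenotyped quantitative trait
#'
#' Genetic value = scaled QTL effects (additive + imprinting + epistasis) +
#' a polygenic term simulated down the pedigree (founder effects N(0,
#' sigma_a^2); offspring = parent average + Mendelian sampling deviation
#' with variance sigma_a^2/2 for non-inbred parents).  Total genetic
#' variance is normalized to 1 trait unit; residual variance is then set
#' from the realized genetic variance among offspring so the realized
#' heritability matches `h2`.  Only `phenotyped_per_family` offspring per
#' full-sib family receive phenotypes; parents are never phenotyped.
#'
#' @param geno `geno_matrix` for the full pedigree.
#' @param ped pedigree from [build_pedigree()].
#' @param arch `qtl_architecture` (may be empty).
#' @param h2 target narrow-sense heritability in (0,1); default 0.30.
#' @param phenotyped_per_family offspring phenotyped per full-sib family.
#' @param seed integer seed (optional).
#' @return A data.frame of class `true_values`: `id`, `bv` (true breeding
#'   value), `gv` (total genetic value), `phenotype` (NA if unphenotyped),
#'   `phenotyped`.  Attribute `sigma_e2` records the residual variance used.
#' @export
simulate_phenotypes <- function(geno, ped, arch, h2 = 0.30,
                                phenotyped_per_family = NULL, seed = NULL) {
  stopifnot(inherits(geno, "geno_matrix"))
  stop_if_not_scalar_prob(h2, "h2", open_left = TRUE, open_right = TRUE)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(ped)
  qtl_share <- attr(arch, "qtl_share") %||% 0
  if (nrow(arch) == 0) qtl_share <- 0
  polygenic_share <- 1 - qtl_share

  # --- QTL part, scaled so each component contributes equal variance and
  #     the total across offspring is qtl_share (genetic variance unit = 1)
  off <- which(ped$sire != 0 | ped$dam != 0)
  if (length(off) == 0L) off <- seq_len(n)
  gv_q <- numeric(n); bv_q <- numeric(n)
  scaled_effects <- arch$effect
  if (nrow(arch) > 0 && qtl_share > 0) {
    comps <- unique(arch$component)
    per_comp <- qtl_share / length(comps)
    for (cc in comps) {
      rows <- arch[arch$component == cc, , drop = FALSE]
      vals <- qtl_component_values(geno, rows, attr(arch, "imprinting"))
      v <- var(vals$gv[off])
      if (v <= 0) stop("degenerate QTL component ", cc, ": no genetic variance")
      sc <- sqrt(per_comp / v)
      scaled_effects[arch$component == cc] <- rows$effect * sc
      gv_q <- gv_q + sc * vals$gv
      bv_q <- bv_q + sc * vals$bv
    }
  }

  # --- polygenic term down the pedigree
  sigma_a2 <- polygenic_share
  a <- numeric(n)
  if (sigma_a2 > 0) {
    for (i in seq_len(n)) {
      if (ped$sire[i] == 0 && ped$dam[i] == 0) {
        a[i] <- rnorm(1, 0, sqrt(sigma_a2))
      } else {
        pa <- (a[ped$sire[i]] + a[ped$dam[i]]) / 2
        a[i] <- pa + rnorm(1, 0, sqrt(sigma_a2 / 2))
      }
    }
  }

  gv <- gv_q + a
  bv <- bv_q + a
  vg <- var(gv[off])
  if (vg <= 0) stop("degenerate genetic variance: all genotypes identical and no polygenic variance")
  sigma_e2 <- vg * (1 - h2) / h2
  phe <- gv + rnorm(n, 0, sqrt(sigma_e2))

  phenotyped <- rep(FALSE, n)
  fams <- unique(ped$family[!is.na(ped$family)])
  if (length(fams)) {
    for (f in fams) {
      members <- which(!is.na(ped$family) & ped$family == f)
      k <- phenotyped_per_family %||% length(members)
      k <- min(k, length(members))
      phenotyped[sample(members, k)] <- TRUE
    }
  } else {
    phenotyped[off] <- TRUE
  }
  phe[!phenotyped] <- NA_real_

  out <- data.frame(id = ped$id, bv = bv, gv = gv, phenotype = phe,
                    phenotyped = phenotyped, stringsAsFactors = FALSE)
  attr(out, "sigma_e2") <- sigma_e2
  attr(out, "sigma_a2") <- sigma_a2
  attr(out, "scaled_effects") <- scaled_effects
  class(out) <- c("true_values", "data.frame")
  out
}

#' Simulate a complete study population
#'
#' One call wires the whole generator: map, founder haplotypes, pedigree,
#' gene drop, QTL architecture and phenotypes, each stage seeded from one
#' master seed.  Two presets are provided: `"full"` emulates the reference
#' design (20 sires x 10 dams x 15 offspring, 9,990 SNPs on 5 x 1 Morgan
#' chromosomes, 10/15 offspring phenotyped, h2 = 0.30) and `"desk"` is a
#' reduced design of the same shape (20 sires x 5 dams x 6 offspring, 1,000
#' SNPs, 4/6 phenotyped) for fast exercises.
#'
#' @param preset `"desk"` or `"full"`.
#' @param h2 target heritability (default 0.30).
#' @param config QTL architecture configuration ([qtl_config()]), or `NULL`
#'   for a pure polygenic trait (no QTL).
#' @param seed master seed.
#' @param n_burn_generations long-phase founder burn-in generations (the
#'   30-generation bottleneck is appended automatically; see
#'   [simulate_founder_haplotypes()]).
#' @return A list of class `sim_population` with elements `map`, `founders`,
#'   `ped`, `geno`, `arch`, `truth`, `seed`, `preset`.
#' @export
simulate_population <- function(preset = c("desk", "full"), h2 = 0.30,
                                config = qtl_config(), seed = 1L,
                                n_burn_generations = 300L) {
  preset <- match.arg(preset)
  des <- switch(preset,
    desk = list(snps_per_chr = 200L, n_sires = 20L, n_dams = 5L, n_off = 6L,
                phen = 4L),
    full = list(snps_per_chr = 1998L, n_sires = 20L, n_dams = 10L, n_off = 15L,
                phen = 10L))
  map <- make_genetic_map(5L, des$snps_per_chr, 1)
  ped <- build_pedigree(des$n_sires, des$n_dams, des$n_off)
  n_founders <- sum(ped$sire == 0 & ped$dam == 0)
  founders <- simulate_founder_haplotypes(
    n_founders, map, n_burn_generations = n_burn_generations,
    seed = derive_seed(seed, 1L))
  geno <- drop_genotypes(ped, founders, map, seed = derive_seed(seed, 2L))
  arch <- if (is.null(config)) empty_architecture()
          else assign_qtl_architecture(geno, config, seed = derive_seed(seed, 3L))
  truth <- simulate_phenotypes(geno, ped, arch, h2 = h2,
                               phenotyped_per_family = des$phen,
                               seed = derive_seed(seed, 4L))
  structure(list(map = map, founders = founders, ped = ped, geno = geno,
                 arch = arch, truth = truth, seed = seed, preset = preset),
            class = "sim_population")
}
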