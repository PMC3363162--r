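test_that("pedigree counts follow the mating-design closed form", {
  ped <- build_pedigree(20, 10, 15)
  expect_equal(nrow(ped), 3220)
  expect_equal(sum(ped$role == "offspring"), 3000)
  expect_equal(sum(ped$sire == 0 & ped$dam == 0), 220)

  expect_equal(nrow(build_pedigree(1, 1, 1)), 3)
  expect_equal(nrow(build_pedigree(2, 3, 4)), 2 + 6 + 24)

  for (i in 1:10) {
    ns <- sample(1:5, 1); nd <- sample(1:4, 1); no <- sample(1:6, 1)
    ped <- build_pedigree(ns, nd, no)
    expect_equal(nrow(ped), ns + ns * nd + ns * nd * no)
    # every offspring has both parents among earlier individuals
    off <- ped[ped$sire != 0, ]
    expect_true(all(off$sire < off$id & off$dam < off$id))
  }
})

test_that("genetic map is equally spaced and strictly increasing per chromosome", {
  map <- make_genetic_map(5, 100, 1)
  expect_equal(nrow(map), 500)
  expect_equal(as.vector(table(map$chr)), rep(100, 5))
  for (c_ in 1:5) {
    p <- map$pos[map$chr == c_]
    expect_true(all(diff(p) > 0))
    expect_true(max(p) <= 1)
  }
})

test_that("founder haplotypes: no burn-in gives linkage equilibrium, burn-in builds LD that decays with distance", {
  map <- make_genetic_map(1, 60, 1)
  f0 <- simulate_founder_haplotypes(200, map, n_burn_generations = 0,
                                    init_freq = 0.5, seed = 1)
  expect_equal(dim(f0$haps), c(400, 60))
  expect_true(all(f0$haps %in% 0:1))
  g <- f0$haps[seq(1, 399, 2), ] + f0$haps[seq(2, 400, 2), ]
  adj <- sapply(seq_len(ncol(g) - 1), function(k) cor(g[, k], g[, k + 1])^2)
  expect_lt(mean(adj, na.rm = TRUE), 0.05)

  # LD decay after burn-in, averaged over seeds
  map2 <- make_genetic_map(1, 200, 0.1)  # adjacent spacing 0.0005 M
  near <- c(); far <- c()
  for (s in 1:5) {
    fh <- simulate_founder_haplotypes(100, map2, n_burn_generations = 100,
                                      pop_size = 100, seed = s)
    g <- fh$haps[seq(1, 199, 2), ] + fh$haps[seq(2, 200, 2), ]
    keep <- apply(g, 2, var) > 0
    cc <- suppressWarnings(cor(g[, keep]))^2
    pos <- map2$pos[keep]
    dd <- abs(outer(pos, pos, "-"))
    near <- c(near, mean(cc[dd > 0 & dd < 0.002], na.rm = TRUE))
    far <- c(far, mean(cc[dd > 0.05], na.rm = TRUE))
  }
  expect_gt(mean(near), mean(far))
})

test_that("gene drop is Mendelian-consistent, phase-aware, and Haldane-calibrated", {
  map <- make_genetic_map(2, 50, 1)
  ped <- build_pedigree(4, 3, 5)  # 4+12+60 individuals, 120 meioses
  fh <- simulate_founder_haplotypes(16, map, n_burn_generations = 0,
                                    init_freq = 0.5, seed = 2)
  g <- drop_genotypes(ped, fh, map, seed = 3)
  expect_true(all(g$geno %in% 0:2))
  expect_equal(g$geno, g$pat + g$mat, ignore_attr = TRUE)
  # trio consistency: offspring cannot carry an allele absent in a parent
  off <- which(ped$sire != 0)
  for (i in off) {
    s <- ped$sire[i]; d <- ped$dam[i]
    expect_false(any(g$geno[i, ] == 2 & (g$geno[s, ] == 0 | g$geno[d, ] == 0)))
    expect_false(any(g$geno[i, ] == 0 & (g$geno[s, ] == 2 | g$geno[d, ] == 2)))
    # paternal haplotype allele must exist in the sire
    expect_true(all(g$pat[i, ] <= pmin(g$pat[s, ] + g$mat[s, ], 1)))
  }

  # zero-length map: gametes are unrecombined copies of one parental haplotype
  map0 <- make_genetic_map(1, 20, 0)
  fh0 <- simulate_founder_haplotypes(2, map0, n_burn_generations = 0, seed = 4)
  ped0 <- data.frame(id = 1:3, sire = c(0, 0, 1), dam = c(0, 0, 2))
  g0 <- drop_genotypes(ped0, fh0, map0, seed = 5)
  pat_matches <- sapply(1:2, function(h)
    all(g0$pat[3, ] == fh0$haps[h, ]))
  expect_true(any(pat_matches))

  # crossover rate: ~1 per Morgan of transmitted chromosome
  map1 <- make_genetic_map(1, 50, 1)
  ped1 <- build_pedigree(10, 5, 12)  # 600 offspring -> 1200 meioses
  fh1 <- simulate_founder_haplotypes(60, map1, n_burn_generations = 0, seed = 6)
  g1 <- drop_genotypes(ped1, fh1, map1, seed = 7)
  rate <- g1$n_crossovers / g1$n_meioses
  expect_gt(rate, 0.9); expect_lt(rate, 1.1)
})

test_that("gene drop is deterministic under a fixed seed", {
  map <- make_genetic_map(1, 30, 1)
  ped <- build_pedigree(2, 2, 3)
  fh <- simulate_founder_haplotypes(6, map, n_burn_generations = 10,
                                    pop_size = 20, seed = 8)
  g1 <- drop_genotypes(ped, fh, map, seed = 9)
  g2 <- drop_genotypes(ped, fh, map, seed = 9)
  expect_identical(g1$geno, g2$geno)
  s1 <- simulate_population("desk", seed = 42)
  s2 <- simulate_population("desk", seed = 42)
  expect_identical(s1$geno$geno, s2$geno$geno)
  expect_identical(s1$truth$phenotype, s2$truth$phenotype)
})

test_that("default QTL architecture spans chromosomes 1-5 with seven entries", {
  sim <- simulate_population("desk", seed = 11)
  arch <- sim$arch
  expect_equal(nrow(arch), 7)
  expect_equal(sort(unique(arch$chr)), 1:5)
  expect_equal(sum(arch$mode == "imprinted"), 1)
  expect_equal(sum(arch$mode == "epistatic"), 1)
  # repulsion pair: two QTL on chr 3 close together, one variance component
  ch3 <- arch[arch$chr == 3, ]
  expect_equal(nrow(ch3), 2)
  expect_equal(length(unique(ch3$component)), 1)
  pos <- sim$map$pos[ch3$snp]
  expect_lte(abs(diff(pos)), 0.05)
  # epistatic entry references two distinct SNPs
  ep <- arch[arch$mode == "epistatic", ]
  expect_false(is.na(ep$snp2))
  expect_true(ep$snp != ep$snp2)

  # empty architecture
  expect_equal(nrow(empty_architecture()), 0)
})

test_that("imprinted QTL produce a parent-of-origin contrast that a permuted phase destroys", {
  sim <- simulate_population("desk", seed = 13, config = NULL)
  geno <- sim$geno; ped <- sim$ped
  # architecture with only one imprinted QTL
  p <- colMeans(geno$geno) / 2
  snp <- which.min(abs(p - 0.5))
  arch <- data.frame(qtl = 1L, chr = geno$map$chr[snp], snp = snp,
                     snp2 = NA_integer_, mode = "imprinted", effect = 1,
                     component = 1L)
  attr(arch, "qtl_share") <- 0.9
  attr(arch, "imprinting") <- "paternal"
  class(arch) <- c("qtl_architecture", "data.frame")
  tr <- simulate_phenotypes(geno, ped, arch, h2 = 0.8,
                            phenotyped_per_family = 6, seed = 14)
  # among heterozygotes: compare phenotype by parental origin of the allele
  off <- which(ped$sire != 0)
  het <- off[geno$geno[off, snp] == 1 & !is.na(tr$phenotype[off])]
  origin <- geno$pat[het, snp]  # 1 = paternal copy carries the allele
  contrast <- mean(tr$phenotype[het[origin == 1]]) -
              mean(tr$phenotype[het[origin == 0]])
  perm <- replicate(200, {
    o <- sample(origin)
    mean(tr$phenotype[het[o == 1]]) - mean(tr$phenotype[het[o == 0]])
  })
  expect_gt(abs(contrast - mean(perm)) / sd(perm), 3)
})

test_that("realized heritability matches the target and phenotyping design", {
  sim <- simulate_population("desk", seed = 15)
  tr <- sim$truth; ped <- sim$ped
  expect_equal(sum(tr$phenotyped), 400)           # 4 of 6 per family
  expect_equal(sum(!tr$phenotyped & ped$sire != 0), 200)
  expect_true(all(is.na(tr$phenotype[ped$sire == 0])))  # parents unphenotyped

  # realized h2 across phenotype redraws of one genotype drop
  h2s <- sapply(1:6, function(s) {
    t2 <- simulate_phenotypes(sim$geno, ped, sim$arch, h2 = 0.30,
                              phenotyped_per_family = 4, seed = 100 + s)
    ph <- t2$phenotyped
    var(t2$gv[ph]) / var(t2$phenotype[ph])
  })
  expect_lt(abs(mean(h2s) - 0.30), 0.03)
})

test_that("degenerate genetic variance is rejected", {
  map <- make_genetic_map(1, 10, 1)
  ped <- build_pedigree(2, 1, 2)
  fh <- simulate_founder_haplotypes(4, map, n_burn_generations = 0,
                                    init_freq = 0, seed = 1)  # all monomorphic
  g <- drop_genotypes(ped, fh, map, seed = 2)
  arch <- data.frame(qtl = 1L, chr = 1L, snp = 1L, snp2 = NA_integer_,
                     mode = "additive", effect = 1, component = 1L)
  attr(arch, "qtl_share") <- 1  # no polygenic variance either
  class(arch) <- c("qtl_architecture", "data.frame")
  expect_error(simulate_phenotypes(g, ped, arch, h2 = 0.3,
                                   phenotyped_per_family = 2, seed = 3),
               "degenerate")
})
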