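test_that("Dxy enumerates the four cross pairs in repeat units", {
  ## identical homozygotes
  g0 <- make_geno(matrix(c(10, 10), 1), matrix(c(10, 10), 1),
                  unit_length = 2, ref_repeats = 5)
  expect_equal(dxy(g0, 1, 2), 0)
  ## homozygote pair (10,10) vs (12,12) bp, dinucleotide, N = 1
  g1 <- make_geno(matrix(c(10, 12), 1), matrix(c(10, 12), 1),
                  unit_length = 2, ref_repeats = 5)
  expect_equal(dxy(g1, 1, 2), 1.0)
  ## symmetry and oracle equality on random cohorts
  set.seed(31)
  for (rep in 1:10) {
    g <- rand_geno(12, 6, unit_length = sample(2:4, 1), missing_rate = 0.15)
    x <- sample(6, 1); y <- sample(setdiff(1:6, x), 1)
    expect_equal(dxy(g, x, y), dxy(g, y, x))
    expect_equal(dxy(g, x, y), oracle_dxy(g, x, y), tolerance = 1e-12)
  }
  ## translation invariance: +c repeats everywhere at a locus
  g2 <- rand_geno(5, 4)
  g3 <- str_genotypes(g2$loci, g2$samples, g2$a1 + 2 * 3, g2$a2 + 2 * 3)
  expect_equal(dxy(g2, 1, 2), dxy(g3, 1, 2), tolerance = 1e-12)
})

test_that("the distance matrix matches per-pair recomputation", {
  set.seed(32)
  g <- rand_geno(25, 8, missing_rate = 0.1)
  D <- distance_matrix(g, major_freq_max = 1, major_freq_min = 0)
  expect_true(isSymmetric(D$D))
  for (x in 1:7) for (y in (x + 1):8) {
    expect_equal(D$D[x, y], oracle_dxy(g, x, y), tolerance = 1e-12)
  }
  ## two identical homozygous samples have distance zero
  gh <- make_geno(matrix(20, 3, 2), matrix(20, 3, 2))
  ## (monomorphic loci pass no screen; disable it)
  Dh <- distance_matrix(gh, major_freq_max = 1, major_freq_min = 0)
  expect_equal(Dh$D[1, 2], 0)
  ## a pair sharing no locus is an error naming the pair
  a <- matrix(c(20, NA, NA, 20), 2, 2)
  gn <- make_geno(a, a)
  expect_error(distance_matrix(gn, major_freq_max = 1, major_freq_min = 0),
               "share no non-missing locus")
})

test_that("neighbour joining solves three taxa exactly and recovers additive trees", {
  D <- matrix(c(0, 5, 9,
                5, 0, 10,
                9, 10, 0), 3, dimnames = list(letters[1:3], letters[1:3]))
  tr <- neighbor_joining(D)
  ## three-point closed form: x = (d12+d13-d23)/2, etc.
  bl <- sort(tr$edge.length)
  expect_equal(bl, sort(c((5 + 9 - 10) / 2, (5 + 10 - 9) / 2, (9 + 10 - 5) / 2)))
  ## additive matrices from random trees: exact topology recovery
  skip_if_not_installed("phangorn")
  set.seed(33)
  for (rep in 1:20) {
    n <- sample(5:8, 1)
    true <- ape::rtree(n)
    Dm <- ape::cophenetic.phylo(true)
    rec <- neighbor_joining(Dm)
    expect_equal(phangorn::RF.dist(ape::unroot(true), rec), 0)
    ## taxon-order permutation leaves the topology unchanged
    perm <- sample(n)
    rec2 <- neighbor_joining(Dm[perm, perm])
    expect_equal(phangorn::RF.dist(rec, rec2), 0)
  }
  ## invalid matrices are rejected
  bad <- D; bad[1, 2] <- 99
  expect_error(neighbor_joining(bad), "symmetric")
  neg <- D; neg[1, 2] <- neg[2, 1] <- -1
  expect_error(neighbor_joining(neg), "non-negative")
  expect_error(neighbor_joining(D[1:2, 1:2]), "at least 3")
})

test_that("indicator encoding drops the major allele and keeps copy counts", {
  ## biallelic locus reduces to the minor-allele dosage
  a1 <- matrix(c(20, 20, 22), 1); a2 <- matrix(c(20, 22, 22), 1)
  g <- make_geno(a1, a2)
  enc <- indicator_encode(g)
  expect_equal(ncol(enc$M), 1)
  expect_equal(unname(enc$M[, 1]), c(0, 1, 2))
  expect_equal(enc$key$allele, 22)
  ## three-allele locus: one copy of each non-reference allele -> (1, 1)
  a1 <- matrix(c(20, 20, 20, 22), 1); a2 <- matrix(c(20, 20, 24, 24), 1)
  g3 <- make_geno(a1, a2)
  enc3 <- indicator_encode(g3)
  expect_equal(ncol(enc3$M), 2)
  expect_equal(unname(enc3$M[4, ]), c(1, 1))
  ## completeness: full n columns (dropped allele included) sum to 2
  set.seed(34)
  gr <- rand_geno(15, 10, repeat_range = c(8, 11))
  encr <- indicator_encode(gr)
  for (lid in unique(encr$key$locus_id)) {
    cols <- encr$key$column[encr$key$locus_id == lid]
    i <- match(lid, gr$loci$locus_id)
    sp <- allele_spectrum(gr, i)
    ref_allele <- as.numeric(names(sp$freqs))[order(-sp$freqs, as.numeric(names(sp$freqs)))][1]
    ref_count <- (gr$a1[i, ] == ref_allele) + (gr$a2[i, ] == ref_allele)
    expect_equal(unname(rowSums(encr$M[, cols, drop = FALSE]) + ref_count),
                 rep(2, 10))
  }
  ## monomorphic loci contribute no columns
  gm <- make_geno(matrix(20, 2, 3), matrix(20, 2, 3))
  expect_error(indicator_encode(gm), "no polymorphic locus")
})

test_that("PCA scores behave under duplication, reordering and rank limits", {
  set.seed(35)
  M <- matrix(rnorm(40 * 12), 40, 12, dimnames = list(paste0("s", 1:40), NULL))
  p <- str_pca(M, k = 5)
  expect_true(all(diff(p$eigenvalues) <= 1e-9))
  ## duplicated sample gets identical scores
  M2 <- rbind(M, dup = M[1, ])
  p2 <- str_pca(M2, k = 3)
  expect_equal(unname(p2$scores["dup", ]), unname(p2$scores["s1", ]))
  ## row reordering permutes scores identically (sign fixed by convention)
  perm <- sample(40)
  pp <- str_pca(M[perm, ], k = 3)
  expect_equal(abs(pp$scores[rownames(M), ]), abs(p$scores[, 1:3]),
               tolerance = 1e-8, ignore_attr = TRUE)
  ## k above rank is reduced with a warning
  low <- matrix(rnorm(6 * 3), 6, 3) %*% matrix(1, 3, 8)
  expect_warning(pl <- str_pca(low, k = 5), "rank")
  expect_lte(ncol(pl$scores), 3)
})

test_that("PC1 separates two diverged simulated populations", {
  cfg <- sim_config(n_populations = 2, samples_per_pop = 12, n_loci = 80,
                    divergence_generations = 600, pop_size = 50, seed = 36)
  sim <- simulate_str_cohort(cfg)
  g <- filter_call_rate(sim$geno)
  pc1 <- str_pca(indicator_encode(g), k = 2)$scores[, 1]
  pops <- match_populations(g, sim$pm)
  m1 <- pc1[pops == "pop01"]; m2 <- pc1[pops == "pop02"]
  gap <- abs(mean(m1) - mean(m2))
  expect_gt(gap, sd(m1) + sd(m2))   # clear separation along PC1
})

test_that("samples co-cluster with their population in the Dxy tree", {
  ## over seeds, each sample's nearest neighbour and the NJ split
  ## structure follow population membership at moderate divergence
  ok <- sapply(1:5, function(s) {
    cfg <- sim_config(n_populations = 3, samples_per_pop = 8, n_loci = 80,
                      divergence_generations = 600, pop_size = 50, seed = s)
    sim <- simulate_str_cohort(cfg)
    g <- filter_call_rate(sim$geno)
    D <- distance_matrix(g)
    pops <- match_populations(g, sim$pm)
    nn_same <- sapply(seq_along(g$samples), function(i) {
      d <- D$D[i, ]; d[i] <- Inf
      pops[which.min(d)] == pops[i]
    })
    tr <- neighbor_joining(D)
    ## each population forms a split of the unrooted tree
    parts <- ape::prop.part(tr)
    labs <- attr(parts, "labels")
    splits <- lapply(parts, function(ix) sort(labs[ix]))
    mono <- sapply(unique(pops), function(p) {
      members <- sort(names(pops)[pops == p])
      others <- sort(setdiff(labs, members))
      any(vapply(splits, identical, logical(1), y = members)) ||
        any(vapply(splits, identical, logical(1), y = others))
    })
    mean(nn_same) >= 0.9 && all(mono)
  })
  expect_gte(mean(ok), 0.9)
})
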