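test_that("configuration validation rejects impossible settings", {
  expect_error(sim_config(n_loci = 0), "positive")
  expect_error(sim_config(mutation_rate = 1.5), "0, 1")
  expect_error(sim_config(missing_rate = -0.1), "0, 1")
  expect_error(sim_config(ancestral_repeats = 50, unit_lengths = 2), "80 bp")
  expect_error(sim_config(unit_lengths = 7), "2..6")
  expect_error(sim_config(env_effect_loci = data.frame(locus = 999, effect = 1),
                          n_loci = 10), "env_effect_loci")
})

test_that("no mutation leaves every locus monomorphic at the ancestral length", {
  cfg <- sim_config(n_populations = 3, samples_per_pop = 5, n_loci = 20,
                    mutation_rate = 0, divergence_generations = 100,
                    burnin_generations = 50, missing_rate = 0, seed = 2)
  sim <- simulate_str_cohort(cfg)
  expect_true(all(sim$geno$a1 == sim$geno$loci$ref_length))
  expect_true(all(sim$geno$a2 == sim$geno$loci$ref_length))
  expect_equal(unname(sim$truth$ancestral_length),
               sim$geno$loci$ref_length)
})

test_that("the simulator is deterministic and alleles sit on the repeat grid", {
  cfg <- sim_config(n_populations = 2, samples_per_pop = 6, n_loci = 30,
                    divergence_generations = 100, seed = 7)
  s1 <- simulate_str_cohort(cfg)
  s2 <- simulate_str_cohort(cfg)
  expect_identical(s1$geno$a1, s2$geno$a1)
  expect_identical(s1$geno$a2, s2$geno$a2)
  s3 <- simulate_str_cohort(sim_config(n_populations = 2, samples_per_pop = 6,
                                       n_loci = 30,
                                       divergence_generations = 100, seed = 8))
  expect_false(identical(s1$geno$a1, s3$geno$a1))
  ## every allele is a positive multiple of its unit length
  u <- s1$geno$loci$unit_length
  for (m in list(s1$geno$a1, s1$geno$a2)) {
    r <- m / u
    expect_true(all(is.na(r) | (r >= 1 & abs(r - round(r)) < 1e-9)))
  }
})

test_that("missing calls appear at the configured rate", {
  cfg <- sim_config(n_populations = 2, samples_per_pop = 40, n_loci = 80,
                    divergence_generations = 10, burnin_generations = 10,
                    missing_rate = 0.2, seed = 5)
  sim <- simulate_str_cohort(cfg)
  obs <- mean(is.na(sim$geno$a1))
  expect_lt(abs(obs - 0.2), 0.02)
  expect_equal(is.na(sim$geno$a1), is.na(sim$geno$a2))
})

test_that("environment values follow the configured linear construction", {
  base <- list(n_populations = 3, samples_per_pop = 8, n_loci = 20,
               divergence_generations = 150, missing_rate = 0, seed = 3)
  ## no effect loci, zero noise: all populations at 0
  cfg0 <- do.call(sim_config, c(base, list(env_noise_sd = 0)))
  sim <- simulate_str_cohort(cfg0)
  env0 <- simulate_environment(sim$pm, sim$truth, sim$geno, cfg0)
  expect_equal(env0$value, rep(0, 3))
  ## single effect locus, effect 2, zero noise: exact linear construction
  cfg2 <- do.call(sim_config, c(base, list(
    env_effect_loci = data.frame(locus = 4, effect = 2), env_noise_sd = 0)))
  sim2 <- simulate_str_cohort(cfg2)
  env2 <- simulate_environment(sim2$pm, sim2$truth, sim2$geno, cfg2)
  dos <- str_dosage(sim2$geno)
  pops <- match_populations(sim2$geno, sim2$pm)
  dmean <- tapply(dos[4, ], pops, mean)
  expect_equal(diff(env2$value),
               2 * diff(as.numeric(dmean[env2$population])),
               tolerance = 1e-12)
  ## every sample inherits its population's value
  bs <- attr(env2, "by_sample")
  expect_equal(unname(bs[sim2$pm$sample]),
               env2$value[match(sim2$pm$population, env2$population)])
})

test_that("expected heterozygosity rises with the mutation rate", {
  exp_het <- function(mu, s) {
    cfg <- sim_config(n_populations = 2, samples_per_pop = 10, n_loci = 40,
                      mutation_rate = mu, divergence_generations = 0,
                      burnin_generations = 300, pop_size = 50,
                      missing_rate = 0, seed = s)
    sim <- simulate_str_cohort(cfg)
    mean(vapply(seq_len(40), function(i) {
      p <- allele_spectrum(sim$geno, i)$freqs
      1 - sum(p^2)
    }, numeric(1)))
  }
  for (s in 1:3) expect_gt(exp_het(5e-3, s), exp_het(2e-4, s))
})

test_that("a degenerate monomorphic cohort flows through the scan stages", {
  cfg <- sim_config(n_populations = 2, samples_per_pop = 6, n_loci = 15,
                    mutation_rate = 0, missing_rate = 0, seed = 4)
  sim <- simulate_str_cohort(cfg)
  sc <- rst_scan(sim$geno, sim$pm, "pop01", "pop02")
  expect_true(all(is.na(sc$Rst)))
  expect_error(z_transform(sc), "at least two defined")
  flagged <- top_permille(sc)
  expect_equal(sum(flagged$significant), 0)
  expect_equal(nrow(merge_cdr(flagged)$regions), 0)
})

test_that("feature simulation supports empty classes and forced placement", {
  genome <- data.frame(chrom = "chr1", length = 1e6)
  fs0 <- simulate_features(genome, classes = c("CDS", "SINE"),
                           n_per_class = 0, seed = 1)
  expect_equal(nrow(fs0$classes$CDS), 0)
  loci <- suppressMessages(str_loci(rep("chr1", 10), seq(1000, 91000, 1e4),
                                    seq(1000, 91000, 1e4) + 19, rep("ACG", 10)))
  expect_equal(unique(annotate_loci(loci, fs0)), "intergenic")
  ## fraction 1.0 forces every chosen locus into the class
  fs1 <- simulate_features(genome, classes = "CDS", n_per_class = 5,
                           mean_length = 200, loci = loci,
                           enriched = list(class = "CDS", loci = 1:10,
                                           fraction = 1.0), seed = 1)
  expect_equal(annotate_loci(loci, fs1), rep("CDS", 10))
  ## over-filled genomes are rejected
  expect_error(simulate_features(genome, classes = "CDS", n_per_class = 100,
                                 mean_length = 1e5, seed = 1), "exceeds")
})

test_that("SNP simulation is reproducible and respects the divergence parameter", {
  cfg <- sim_config(n_populations = 2, samples_per_pop = 20, seed = 9)
  expect_error(simulate_snps(cfg, divergence = 0), "\\(0, 1\\)")
  expect_error(simulate_snps(cfg, divergence = 1), "\\(0, 1\\)")
  s1 <- simulate_snps(cfg, divergence = 0.2, n_snps = 100)
  s2 <- simulate_snps(cfg, divergence = 0.2, n_snps = 100)
  expect_identical(s1$dosage, s2$dosage)
  ## degenerate base frequencies give monomorphic SNPs
  s0 <- simulate_snps(cfg, divergence = 0.5, n_snps = 50,
                      base_freq_range = c(0, 0))
  expect_true(all(s0$dosage == 0))
  ## higher divergence raises mean Hudson Fst (ranked over seeds)
  mean_fst <- function(div, s) {
    cc <- sim_config(n_populations = 2, samples_per_pop = 20, seed = s)
    sn <- simulate_snps(cc, divergence = div, n_snps = 200)
    pm <- pop_map(sn$samples, sub("_s.*", "", sn$samples))
    mean(snp_fst_scan(sn$dosage, sn$positions, pm, "pop01", "pop02")$fst,
         na.rm = TRUE)
  }
  for (s in 1:5) expect_gt(mean_fst(0.3, s), mean_fst(0.02, s))
})

test_that("simulated cohorts round-trip through the VCF and table writers", {
  cfg <- sim_config(n_populations = 2, samples_per_pop = 4, n_loci = 12,
                    divergence_generations = 100, seed = 6)
  sim <- simulate_str_cohort(cfg)
  vcf <- tempfile(fileext = ".vcf")
  write_str_vcf(sim$geno, vcf)
  back <- read_str_vcf(vcf)
  expect_equal(back$geno$a1, sim$geno$a1)
  expect_equal(back$geno$a2, sim$geno$a2)
  ptab <- tempfile(fileext = ".tsv")
  write_population_table(sim$pm, ptab)
  expect_equal(read_population_table(ptab)$population, sim$pm$population)
  snp <- simulate_snps(cfg, divergence = 0.1, n_snps = 30)
  svcf <- tempfile(fileext = ".vcf")
  write_snp_vcf(snp$dosage, snp$positions, svcf)
  expect_equal(unname(read_snp_vcf(svcf)$dosage), unname(snp$dosage))
})
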