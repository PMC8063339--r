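## Forward-time stepwise-mutation-model (SMM) simulator: diverging
## populations of diploid STR genotypes on a star phylogeny, plus
## population-level environment tables, annotation intervals and
## Balding-Nichols SNP dosages. One master seed; each stage derives a
## fixed child seed so stages can be regenerated independently.

stage_seed <- function(seed, stage) {
  offsets <- c(cohort = 0L, env = 1L, features = 2L, snps = 3L)
  as.integer((as.numeric(seed) + offsets[[stage]] * 1000003) %% 2147483647)
}

#' Simulation configuration
#'
#' Study conditions for the stepwise-mutation-model cohort simulator.
#' Defaults describe a moderately diverged multi-population STR cohort:
#' 8 populations of 15 diploids, 200 loci with 2-6 bp motifs, per-allele
#' per-generation single-step mutation rate 1e-3, 500 generations of
#' independent drift per population branch at diploid size 50, and 2%
#' missing calls.
#'
#' @param n_populations number of populations on the star phylogeny.
#' @param samples_per_pop diploid samples drawn per population.
#' @param n_loci number of STR loci.
#' @param unit_lengths motif lengths in bp (2-6), recycled over loci.
#' @param ancestral_repeats ancestral repeat count per locus (scalar or
#'   vector); `ancestral_repeats * unit_length` must stay at most 80 bp.
#' @param mutation_rate per-allele per-generation probability of a
#'   single-step (+/-1 repeat) mutation.
#' @param divergence_generations generations of independent evolution
#'   per population branch.
#' @param burnin_generations generations the shared ancestral pool
#'   evolves before the star split (default 200), so the cohort is
#'   polymorphic even at zero divergence.
#' @param pop_size diploid Wright-Fisher population size.
#' @param missing_rate per-genotype missingness probability.
#' @param seed master random seed (integer).
#' @param genome data.frame `chrom`, `length` on which loci are placed.
#' @param env_effect_loci data.frame with columns `locus` (index) and
#'   `effect` (environment units per bp of population-mean dosage).
#' @param env_noise_sd SD of the Gaussian noise added to each
#'   population's environment value.
#' @return validated list of class `sim_config`.
#' @export
sim_config <- function(n_populations = 8, samples_per_pop = 15,
                       n_loci = 200, unit_lengths = 2:6,
                       ancestral_repeats = 10, mutation_rate = 1e-3,
                       divergence_generations = 500, burnin_generations = 200,
                       pop_size = 50,
                       missing_rate = 0.02, seed = 1,
                       genome = data.frame(chrom = c("chr1", "chr2"),
                                           length = c(1e7, 1e7)),
                       env_effect_loci = NULL, env_noise_sd = 1) {
  cfg <- list(n_populations = as.integer(n_populations),
              samples_per_pop = as.integer(samples_per_pop),
              n_loci = as.integer(n_loci),
              unit_lengths = as.integer(unit_lengths),
              ancestral_repeats = as.integer(ancestral_repeats),
              mutation_rate = mutation_rate,
              divergence_generations = as.integer(divergence_generations),
              burnin_generations = as.integer(burnin_generations),
              pop_size = as.integer(pop_size),
              missing_rate = missing_rate, seed = as.integer(seed),
              genome = genome, env_effect_loci = env_effect_loci,
              env_noise_sd = env_noise_sd)
  if (cfg$n_loci < 1) stop("n_loci must be positive")
  if (any(c(cfg$n_populations, cfg$samples_per_pop, cfg$pop_size,
            cfg$ancestral_repeats) < 1) || cfg$divergence_generations < 0 ||
      cfg$burnin_generations < 0) {
    stop("counts must be positive")
  }
  for (p in c("mutation_rate", "missing_rate")) {
    if (cfg[[p]] < 0 || cfg[[p]] > 1) stop(p, " must lie in [0, 1]")
  }
  if (cfg$env_noise_sd < 0) stop("env_noise_sd must be non-negative")
  if (any(cfg$unit_lengths < 2 | cfg$unit_lengths > 6)) {
    stop("unit_lengths must lie in 2..6")
  }
  units <- rep_len(cfg$unit_lengths, cfg$n_loci)
  anc <- rep_len(cfg$ancestral_repeats, cfg$n_loci)
  if (any(anc * units > 80)) {
    stop("ancestral_repeats * unit_length must be at most 80 bp")
  }
  if (!is.null(cfg$env_effect_loci)) {
    e <- cfg$env_effect_loci
    if (!all(c("locus", "effect") %in% names(e)) ||
        any(e$locus < 1 | e$locus > cfg$n_loci)) {
      stop("env_effect_loci needs valid 'locus' indices and 'effect' sizes")
    }
  }
  structure(cfg, class = "sim_config")
}

## place n non-overlapping loci on the genome, deterministic under the
## current RNG state: proportional allocation, jittered grid positions
place_loci <- function(cfg) {
  units <- rep_len(cfg$unit_lengths, cfg$n_loci)
  anc <- rep_len(cfg$ancestral_repeats, cfg$n_loci)
  ref_len <- units * anc
  glen <- cfg$genome$length
  n_per <- diff(round(cumsum(c(0, glen)) / sum(glen) * cfg$n_loci))
  chrom <- rep(cfg$genome$chrom, n_per)
  start <- integer(0)
  for (r in seq_len(nrow(cfg$genome))) {
    k <- n_per[r]
    if (k == 0) next
    slot <- glen[r] / k
    jit <- floor(stats::runif(k, 0, max(1, slot - 100)))
    start <- c(start, as.integer((seq_len(k) - 1) * slot + 1 + jit))
  }
  bases <- c("AC", "ACG", "AGAT", "AATGG", "ACAGCC")
  motif <- vapply(units, function(u) bases[[u - 1]], character(1))
  str_loci(chrom = chrom, start = start, end = start + ref_len - 1L,
           motif = motif)
}

## evolve one population's allele pool (repeat units) for g generations
evolve_pool <- function(pool, g, mu) {
  L <- nrow(pool); n <- ncol(pool)
  for (gen in seq_len(g)) {
    idx <- matrix(sample.int(n, L * n, replace = TRUE), L, n)
    pool <- matrix(pool[cbind(rep(seq_len(L), n), as.vector(idx))], L, n)
    nm <- stats::rbinom(1, L * n, mu)
    if (nm > 0) {
      pos <- sample.int(L * n, nm)
      pool[pos] <- pool[pos] + sample(c(-1L, 1L), nm, replace = TRUE)
      pool[pool < 1L] <- 1L   # reflecting boundary at one repeat
    }
  }
  pool
}

#' Simulate an STR cohort under the stepwise mutation model
#'
#' Star phylogeny: a shared ancestral allele pool first evolves for
#' `burnin_generations` generations (building standing variation), then
#' every population evolves independently from it for
#' `divergence_generations` generations of
#' Wright-Fisher resampling with symmetric single-step mutation
#' (allele +/-1 repeat unit with probability `mutation_rate` per allele
#' per generation, reflecting at one repeat). Diploid genotypes are
#' drawn from each population's final pool; missing calls are injected
#' per genotype. Byte-identical given the same configuration and seed.
#'
#' @param cfg a [sim_config()].
#' @return list with `geno` ([str_genotypes()]), `loci`, `pm`
#'   ([pop_map()]) and `truth` (per-locus ancestral length in bp and
#'   realised per-population mean allele lengths).
#' @export
simulate_str_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(stage_seed(cfg$seed, "cohort"))
  loci <- place_loci(cfg)
  L <- nrow(loci)
  units <- loci$unit_length
  anc <- loci$ref_length / units
  n_all <- 2L * cfg$pop_size
  K <- cfg$n_populations
  pops <- sprintf("pop%02d", seq_len(K))
  a1 <- a2 <- matrix(NA_real_, L, 0)
  pop_mean <- matrix(NA_real_, L, K, dimnames = list(loci$locus_id, pops))
  sample_pop <- character(0)
  anc_pool <- matrix(rep(anc, n_all), L, n_all)
  anc_pool <- evolve_pool(anc_pool, cfg$burnin_generations, cfg$mutation_rate)
  for (k in seq_len(K)) {
    pool <- evolve_pool(anc_pool, cfg$divergence_generations, cfg$mutation_rate)
    pop_mean[, k] <- rowMeans(pool) * units
    m <- cfg$samples_per_pop
    i1 <- matrix(sample.int(n_all, L * m, replace = TRUE), L, m)
    i2 <- matrix(sample.int(n_all, L * m, replace = TRUE), L, m)
    g1 <- matrix(pool[cbind(rep(seq_len(L), m), as.vector(i1))], L, m) * units
    g2 <- matrix(pool[cbind(rep(seq_len(L), m), as.vector(i2))], L, m) * units
    if (cfg$missing_rate > 0) {
      mis <- matrix(stats::runif(L * m) < cfg$missing_rate, L, m)
      g1[mis] <- NA; g2[mis] <- NA
    }
    a1 <- cbind(a1, g1); a2 <- cbind(a2, g2)
    sample_pop <- c(sample_pop, rep(pops[k], m))
  }
  samples <- sprintf("%s_s%02d", sample_pop,
                     unlist(lapply(seq_len(K), function(k) seq_len(cfg$samples_per_pop))))
  geno <- str_genotypes(loci, samples, a1, a2)
  pm <- pop_map(samples, sample_pop)
  truth <- list(ancestral_length = stats::setNames(anc * units, loci$locus_id),
                pop_mean_length = pop_mean,
                env_effect_loci = cfg$env_effect_loci)
  list(geno = geno, loci = loci, pm = pm, truth = truth)
}

#' Simulate population-level environment values
#'
#' One value per population: the sum over the configured effect loci of
#' effect size times the population's mean observed dosage, plus
#' Gaussian noise with SD `env_noise_sd`. With no effect loci and zero
#' noise every population receives 0. Every sample inherits its
#' population's value, mirroring population-level environmental
#' assignment (and its pseudo-replication caveat).
#'
#' @param pm a [pop_map()].
#' @param truth truth record from [simulate_str_cohort()] (carries the
#'   effect loci; unused otherwise).
#' @param geno the simulated [str_genotypes()].
#' @param cfg the [sim_config()] used (supplies effect loci, noise SD
#'   and the seed).
#' @return data.frame with `population` and `value`; attribute
#'   `"by_sample"` holds the per-sample named vector.
#' @export
simulate_environment <- function(pm, truth, geno, cfg) {
  set.seed(stage_seed(cfg$seed, "env"))
  pops <- unique(pm$population)
  value <- stats::setNames(rep(0, length(pops)), pops)
  eff <- cfg$env_effect_loci
  if (!is.null(eff) && nrow(eff) > 0) {
    if (any(eff$locus > nrow(geno$loci))) stop("unknown locus index in env_effect_loci")
    dos <- str_dosage(geno)
    gpops <- match_populations(geno, pm)
    for (r in seq_len(nrow(eff))) {
      dmean <- tapply(dos[eff$locus[r], ], gpops, mean, na.rm = TRUE)
      value[names(dmean)] <- value[names(dmean)] + eff$effect[r] * dmean
    }
  }
  if (cfg$env_noise_sd > 0) {
    value <- value + stats::rnorm(length(value), 0, cfg$env_noise_sd)
  }
  out <- data.frame(population = pops, value = unname(value[pops]),
                    stringsAsFactors = FALSE)
  attr(out, "by_sample") <- stats::setNames(
    value[pm$population], pm$sample)
  out
}

#' Simulate annotation feature intervals
#'
#' Places non-overlapping intervals per feature class on the genome;
#' optionally forces a stated fraction of a locus subset to fall inside
#' one class's intervals so enrichment is detectable by construction.
#'
#' @param genome data.frame `chrom`, `length`.
#' @param classes character vector of class names.
#' @param n_per_class intervals per class (recycled).
#' @param mean_length mean interval length in bp (exponential with this
#'   mean, minimum 50 bp).
#' @param loci optional locus table, required when `enriched` is given.
#' @param enriched optional list `list(class =, loci = indices,
#'   fraction =)`: for `fraction` of the given loci an interval of the
#'   class is placed over the locus.
#' @param seed random seed.
#' @return a [feature_set()].
#' @export
simulate_features <- function(genome, classes = c("CDS", "5UTR", "H3K4me3",
                                                  "H3K27ac", "SINE"),
                              n_per_class = 50, mean_length = 1000,
                              loci = NULL, enriched = NULL, seed = 1) {
  set.seed(stage_seed(seed, "features"))
  n_per_class <- rep_len(n_per_class, length(classes))
  if (any(n_per_class * mean_length > sum(genome$length))) {
    stop("requested total feature length exceeds the genome")
  }
  cls <- list()
  for (ci in seq_along(classes)) {
    n <- n_per_class[ci]
    if (n == 0) {
      cls[[classes[ci]]] <- data.frame(chrom = character(), start = integer(),
                                       end = integer())
      next
    }
    chrom <- sample(genome$chrom, n, replace = TRUE,
                    prob = genome$length / sum(genome$length))
    len <- pmax(50, round(stats::rexp(n, 1 / mean_length)))
    glen <- genome$length[match(chrom, genome$chrom)]
    start0 <- floor(stats::runif(n, 0, glen - len))
    cls[[classes[ci]]] <- data.frame(chrom = chrom, start = as.integer(start0),
                                     end = as.integer(start0 + len),
                                     stringsAsFactors = FALSE)
  }
  if (!is.null(enriched)) {
    if (is.null(loci)) stop("enriched placement needs the locus table")
    idx <- enriched$loci
    n_force <- round(enriched$fraction * length(idx))
    if (n_force > 0) {
      pick <- idx[seq_len(n_force)]
      forced <- data.frame(chrom = loci$chrom[pick],
                           start = pmax(0L, loci$start[pick] - 10L),
                           end = loci$end[pick] + 10L,
                           stringsAsFactors = FALSE)
      cls[[enriched$class]] <- rbind(cls[[enriched$class]], forced)
    }
  }
  feature_set(cls, genome)
}

#' Simulate SNP dosages for the same cohort
#'
#' Balding-Nichols-style divergence: per SNP an ancestral frequency is
#' drawn uniformly on `base_freq_range`, each population's frequency is
#' Beta-distributed around it with divergence parameter `divergence`
#' (the Fst-like parameter, in (0, 1)), and dosages are binomial draws.
#' Deterministic given the seed in `cfg`.
#'
#' @param cfg the [sim_config()] describing the cohort (sample layout
#'   and genome).
#' @param divergence Balding-Nichols divergence parameter in (0, 1).
#' @param n_snps number of SNPs.
#' @param base_freq_range range of ancestral allele frequencies.
#' @return list with `dosage` (SNPs x samples), `positions`
#'   (data.frame `snp_id`, `chrom`, `pos`), `samples` matching
#'   [simulate_str_cohort()] sample names.
#' @export
simulate_snps <- function(cfg, divergence = 0.1, n_snps = 1000,
                          base_freq_range = c(0.05, 0.95)) {
  if (divergence <= 0 || divergence >= 1) {
    stop("divergence parameter must lie in (0, 1)")
  }
  set.seed(stage_seed(cfg$seed, "snps"))
  K <- cfg$n_populations
  m <- cfg$samples_per_pop
  pops <- sprintf("pop%02d", seq_len(K))
  samples <- sprintf("%s_s%02d", rep(pops, each = m), rep(seq_len(m), K))
  glen <- cfg$genome$length
  chrom <- sample(cfg$genome$chrom, n_snps, replace = TRUE,
                  prob = glen / sum(glen))
  pos <- as.integer(floor(stats::runif(n_snps, 1, glen[match(chrom, cfg$genome$chrom)])))
  p_anc <- stats::runif(n_snps, base_freq_range[1], base_freq_range[2])
  a <- p_anc * (1 - divergence) / divergence
  b <- (1 - p_anc) * (1 - divergence) / divergence
  dosage <- matrix(NA_real_, n_snps, K * m,
                   dimnames = list(NULL, samples))
  for (k in seq_len(K)) {
    pk <- p_anc
    mid <- p_anc > 0 & p_anc < 1
    pk[mid] <- stats::rbeta(sum(mid), a[mid], b[mid])
    cols <- ((k - 1) * m + 1):(k * m)
    dosage[, cols] <- matrix(stats::rbinom(n_snps * m, 2, rep(pk, m)),
                             n_snps, m)
  }
  ord <- order(chrom, pos)
  positions <- data.frame(snp_id = paste0("snp", seq_len(n_snps)),
                          chrom = chrom[ord], pos = pos[ord],
                          stringsAsFactors = FALSE)
  dosage <- dosage[ord, , drop = FALSE]
  rownames(dosage) <- positions$snp_id
  list(dosage = dosage, positions = positions, samples = samples)
}
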