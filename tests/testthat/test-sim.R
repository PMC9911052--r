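test_that("without historical drift, founder frequencies match the draw", {
  set.seed(71)
  cfg <- sim_config(n_chrom = 5, n_hist = 0, n = 200, m = 300, n_qtl = 20,
                    n_gen = 5)
  pop <- simulate_founders(cfg)
  realized <- rowMeans(pop$hap)[pop$marker_idx]
  expect_gt(cor(realized, pop$init_freq[pop$marker_idx]), 0.95)
  expect_lt(mean(abs(realized - pop$init_freq[pop$marker_idx])), 0.05)
})

test_that("drift is neutral in mean and Wright-Fisher in variance", {
  set.seed(72)
  N <- 100; t <- 10
  cfg <- sim_config(n_chrom = 25, chrom_len = 100, n_hist = 0, n = N,
                    m = 500, n_qtl = 5, n_gen = t, h2 = 0.5)
  pop <- simulate_founders(cfg)
  study <- evolve(pop, cfg, "none")
  p0 <- allele_frequencies(study$geno, 0)
  pt <- allele_frequencies(study$geno, t)
  dp <- pt - p0

  expect_lt(abs(mean(dp)), 0.01)           # neutrality: E[dp] = 0

  # Var(p_t - p_0) = p0 q0 (1 - (1 - 1/(2N))^t), checked as a ratio
  expected <- 1 - (1 - 1 / (2 * N))^t
  ratio <- mean(dp^2) / (mean(p0 * (1 - p0)) * expected)
  expect_gt(ratio, 0.75)
  expect_lt(ratio, 1.3)

  # expected heterozygosity decays by (1 - 1/(2N)) per generation
  h_ratio <- mean(2 * pt * (1 - pt)) / mean(2 * p0 * (1 - p0))
  expect_gt(h_ratio, 0.90)
  expect_lt(h_ratio, 0.99)
})

test_that("with h2 = 1 and no selection, phenotype equals breeding value", {
  set.seed(73)
  cfg <- tiny_config(h2 = 1)
  study <- evolve(simulate_founders(cfg), cfg, "none")
  expect_equal(study$pheno$phenotype, study$pheno$bv)
})

test_that("realized heritability at generation 0 matches the target", {
  set.seed(74)
  h2s <- replicate(10, {
    cfg <- tiny_config(h2 = 0.5, n = 200)
    study <- evolve(simulate_founders(cfg), cfg, "none")
    g0 <- study$pheno[study$pheno$generation == 0, ]
    var(g0$bv) / var(g0$phenotype)
  })
  expect_lt(abs(mean(h2s) - 0.5), 0.05)
})

test_that("truncation selection drives the mean breeding value upward", {
  set.seed(75)
  cfg <- tiny_config(h2 = 0.5, n = 150)
  study <- evolve(simulate_founders(cfg), cfg, "truncation")
  mu <- tapply(study$pheno$bv, study$pheno$generation, mean)
  expect_gt(mu[length(mu)], mu[1] + 1)     # clear cumulative response
  expect_gt(cor(seq_along(mu), mu, method = "spearman"), 0.8)
})

test_that("frequency change at QTL tracks effects only under selection", {
  set.seed(76)
  cors <- sapply(1:6, function(i) {
    study <- simulate_study(tiny_config(n = 120), seed = 760 + i)
    sapply(study[c("A", "B")], function(s) {
      dq <- allele_frequencies(s$qtl_geno, 6) -
        allele_frequencies(s$qtl_geno, 2)
      cor(dq, s$qtl$effect)
    })
  })
  expect_lt(abs(mean(cors["A", ])), 0.25)  # neutral: no association
  expect_gt(mean(cors["B", ]), mean(cors["A", ]) + 0.2)
})

test_that("paired populations share founders and diverge only via selection", {
  study <- simulate_study(tiny_config(), seed = 77)
  a0 <- study$A$geno$dosages[study$A$geno$group == 0, ]
  b0 <- study$B$geno$dosages[study$B$geno$group == 0, ]
  expect_identical(a0, b0)
  aT <- study$A$geno$dosages[study$A$geno$group == 6, ]
  bT <- study$B$geno$dosages[study$B$geno$group == 6, ]
  expect_false(identical(aT, bT))

  # full determinism under a fixed seed
  study2 <- simulate_study(tiny_config(), seed = 77)
  expect_identical(study$B$geno$dosages, study2$B$geno$dosages)
  expect_identical(study$A$pheno, study2$A$pheno)
})

test_that("degenerate selection and ascertainment configurations error", {
  set.seed(78)
  cfg <- tiny_config(selected_fraction = 0.01)
  pop <- simulate_founders(cfg)
  expect_error(evolve(pop, cfg, "truncation"), "fewer than 2 parents")

  cfg2 <- tiny_config(maf_min = 0.49, candidate_factor = 1.02,
                      max_retries = 2)
  expect_error(suppressWarnings(simulate_founders(cfg2)),
               "could not ascertain")
})

test_that("the sweep harness is reproducible and summarises both arms", {
  sw1 <- suppressMessages(
    run_sweep("heritability", levels = 0.5, reps = 2, base = tiny_config(),
              perms = 100, seed = 79, early = 2, late = 6))
  sw2 <- suppressMessages(
    run_sweep("heritability", levels = 0.5, reps = 2, base = tiny_config(),
              perms = 100, seed = 79, early = 2, late = 6))
  expect_equal(sw1$p, sw2$p)
  expect_setequal(sw1$pop, c("A_unselected", "B_selected"))
  s <- summary(sw1)
  expect_equal(sum(s$n), 4)
  expect_true(all(s$reject + s$nonreject == 1))
})

test_that("a simulated study writes and reads back through the io layer", {
  set.seed(80)
  cfg <- tiny_config(n = 40, m = 60)
  study <- evolve(simulate_founders(cfg), cfg, "none")
  dir <- withr::local_tempdir()
  write_study(study, dir)
  g0 <- read_genotypes(file.path(dir, "genotypes_gen00.csv"))
  expect_equal(unname(g0$dosages),
               unname(study$geno$dosages[study$geno$group == 0, ]))
  map <- read_map(file.path(dir, "map.tsv"))
  expect_equal(map$marker, study$geno$map$marker)
  skip_if_not_installed("vcfR")
  gv <- read_genotypes(file.path(dir, "genotypes.vcf"), format = "vcf")
  expect_equal(dim(gv$dosages), dim(study$geno$dosages))
})
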