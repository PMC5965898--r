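# Meta-analysis closed forms, genomic inflation, and the polygenic
# modification score.

test_that("meta-analyzing a result set with itself keeps beta and divides se by sqrt(2)", {
  res <- data.frame(variant_id = c("v1", "v2"),
                    effect_allele = c("G", "T"), other_allele = c("A", "C"),
                    beta = c(-2.8, 1.1), se = c(0.5, 0.3))
  m <- meta_analyze(res, res)
  expect_equal(m$beta, res$beta)
  expect_equal(m$se, res$se / sqrt(2), tolerance = 1e-12)
})

test_that("variants in only one cohort pass through; alleles are flipped when reversed", {
  a <- data.frame(variant_id = c("v1", "v2"), effect_allele = c("G", "T"),
                  other_allele = c("A", "C"), beta = c(-2, 1), se = c(1, 1))
  b <- data.frame(variant_id = "v1", effect_allele = "A",
                  other_allele = "G", beta = 2, se = 1)
  m <- meta_analyze(a, b)
  v1 <- m[m$variant_id == "v1", ]
  # b's +2 on the opposite allele is -2 on a's allele: perfectly concordant
  expect_equal(v1$beta, -2)
  expect_equal(v1$se, 1 / sqrt(2), tolerance = 1e-12)
  v2 <- m[m$variant_id == "v2", ]
  expect_equal(v2$beta, 1)
  expect_equal(v2$n_cohorts, 1L)
  # irreconcilable alleles are dropped
  c_bad <- data.frame(variant_id = "v1", effect_allele = "T",
                      other_allele = "C", beta = 1, se = 1)
  expect_message(m2 <- meta_analyze(a, c_bad), "irreconcilable")
  expect_false(2L %in% m2$n_cohorts[m2$variant_id == "v1"])
})

test_that("combining two cohorts with a shared effect strengthens the evidence", {
  set.seed(81)
  improved <- vapply(1:20, function(i) {
    beta_true <- -2
    a <- data.frame(variant_id = "v", effect_allele = "G",
                    other_allele = "A",
                    beta = rnorm(1, beta_true, 0.6), se = 0.6)
    b <- data.frame(variant_id = "v", effect_allele = "G",
                    other_allele = "A",
                    beta = rnorm(1, beta_true, 0.8), se = 0.8)
    p_a <- 2 * pnorm(-abs(a$beta / a$se))
    p_b <- 2 * pnorm(-abs(b$beta / b$se))
    m <- meta_analyze(a, b)
    m$p < min(p_a, p_b)
  }, logical(1))
  expect_gte(mean(improved), 0.9)
})

test_that("genomic inflation is exact at the null median and directional", {
  expect_equal(genomic_inflation(rep(0.5, 101)), 1.0, tolerance = 1e-12)
  set.seed(82)
  p <- runif(100000)
  expect_gt(genomic_inflation(p), 0.98)
  expect_lt(genomic_inflation(p), 1.02)
  # direction: shrinking p-values inflates lambda, inflating them deflates it
  expect_gt(genomic_inflation(p^2), 1)
  expect_lt(genomic_inflation(sqrt(p)), 1)
  expect_error(genomic_inflation(numeric(0)), "p-values")
  expect_error(genomic_inflation(c(0.5, 0)), "p-values")
})

test_that("score arithmetic: effect-allele count times effect size", {
  model <- structure(
    data.frame(variant_id = "snp00001", effect_allele = "G", beta = -2.8,
               p = 1e-8),
    class = c("scoring_model", "data.frame"))
  d <- matrix(c(2L, 1L, 0L), 3, 1,
              dimnames = list(c("s1", "s2", "s3"), "snp00001"))
  g <- genotype_matrix(d, data.frame(chrom = 1, pos = 1, id = "snp00001",
                                     ref = "A", alt = "G", af = 0.3))
  sc <- apply_modifier_score(model, g)
  expect_equal(unname(sc), c(-5.6, -2.8, 0))
  # effect allele coded as the panel's reference: dosages flip
  model$effect_allele <- "A"
  sc2 <- apply_modifier_score(model, g)
  expect_equal(unname(sc2), c(0, -2.8, -5.6))
})

test_that("greedy selection keeps only independent suggestive SNPs", {
  res <- data.frame(
    variant_id = c("a", "b", "c", "d"),
    chrom = c(1, 1, 1, 2), pos = c(100, 5e5, 2e6, 100),
    effect_allele = "G", other_allele = "A",
    beta = c(-3, -2.9, 2, 1.5),
    se = 0.3, p = c(1e-9, 1e-8, 1e-7, 1e-6))
  # no genotypes: window rule alone; b is within 1 Mb of a -> dropped
  model <- build_modifier_score(res, p_threshold = 1e-5)
  expect_setequal(model$variant_id, c("a", "c", "d"))
  # with genotypes: a correlated neighbour is dropped, an uncorrelated kept
  set.seed(83)
  da <- rbinom(200, 2, 0.4)
  db <- da  # perfect LD with a
  d <- cbind(a = da, b = db, c = rbinom(200, 2, 0.4),
             d = rbinom(200, 2, 0.4))
  rownames(d) <- paste0("s", 1:200)
  g <- genotype_matrix(d, data.frame(chrom = res$chrom, pos = res$pos,
                                     id = res$variant_id, ref = "A",
                                     alt = "G", af = 0.4))
  model2 <- build_modifier_score(res, genotypes = g)
  expect_false("b" %in% model2$variant_id)
  expect_true(all(c("a", "c", "d") %in% model2$variant_id))
  # nothing survives a strict threshold
  expect_warning(empty <- build_modifier_score(res, p_threshold = 1e-20),
                 "empty")
  expect_equal(nrow(empty), 0)
})

test_that("score explains the generative variance in training and nothing under a transfer null", {
  mods <- list(planted_modifier(50, 0.35, -3.5, population = "venezuelan"),
               planted_modifier(250, 0.40, -3.0, population = "venezuelan"))
  cfg <- sim_config(n_subjects = 500, n_families = 20, n_snps = 600,
                    n_chromosomes = 6, onset_noise_sd = 0.12,
                    population_weights = c(venezuelan = 0.5, european = 0.5),
                    modifiers = mods, seed = 84)
  sim <- simulate_cohort(cfg)
  resid_all <- residual_onset(sim$cohort, fit_onset_model(sim$cohort))
  pop <- setNames(sim$cohort$population, sim$cohort$subject_id)
  aff <- sim$cohort$subject_id[sim$cohort$affected]
  train_ids <- aff[pop[aff] == "venezuelan"]
  test_ids <- aff[pop[aff] == "european"]
  resid_tr <- resid_all[resid_all$subject_id %in% train_ids, ]
  g_tr <- subset_genotypes(sim$genotypes, subjects = train_ids)
  train <- run_lmm_gwas(g_tr, resid_tr, kinship = compute_kinship(g_tr))
  sm <- build_modifier_score(train, genotypes = g_tr)
  expect_gte(nrow(sm), 1)
  ev <- evaluate_score(apply_modifier_score(sm, g_tr), resid_tr)
  # generative share: variance of the true modifier contribution over the
  # residual variance
  # generative variance explained: the R-squared the true planted modifier
  # contribution attains in the residual phenotype (the onset-model fit
  # absorbs the family-correlated part of the modifier signal, so the raw
  # variance ratio of the planted component would overstate what any score
  # can recover)
  truth <- sim$truth$residual_components[resid_tr$subject_id]
  r2_gen <- summary(lm(resid_tr$residual ~ truth))$r.squared
  mc_se <- sqrt(4 * r2_gen * (1 - r2_gen)^2 / length(train_ids))
  expect_lt(abs(ev$r2 - r2_gen), 2 * mc_se + 0.02)
  expect_lt(ev$p, 0.05)
  # transfer null: the same score on the modifier-free population
  resid_te <- resid_all[resid_all$subject_id %in% test_ids, ]
  g_te <- subset_genotypes(sim$genotypes, subjects = test_ids)
  ev0 <- evaluate_score(apply_modifier_score(sm, g_te), resid_te)
  expect_lt(ev0$r2, 0.03)
  expect_gt(ev0$p, 0.05)
})
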