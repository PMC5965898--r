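# Mixed-model association engine and the secondary analyses.

# small simulated panel shared across blocks
assoc_sim <- function(seed = 61, ...) {
  simulate_cohort(sim_config(n_subjects = 60, n_families = 4, n_snps = 400,
                             seed = seed, ...))
}

covar_for <- function(sim, subjects) {
  sex <- as.numeric(sim$cohort$sex == "M")
  names(sex) <- sim$cohort$subject_id
  m <- cbind(sex = sex[subjects])
  rownames(m) <- subjects
  m
}

test_that("with identity kinship every statistic equals the OLS normal-equations oracle", {
  sim <- assoc_sim()
  aff <- sim$cohort$subject_id[sim$cohort$affected]
  g <- subset_genotypes(sim$genotypes, subjects = aff)
  set.seed(1)
  y <- setNames(rnorm(length(aff)), aff)
  covar <- covar_for(sim, aff)
  res <- run_lmm_gwas(g, y, covariates = covar, kinship = NULL)
  dos <- g$dosage
  for (i in seq(1, nrow(res), by = 23)) {
    x <- dos[, res$variant_id[i]]
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    X <- cbind(1, covar[, 1], x)
    XtX <- t(X) %*% X
    beta <- solve(XtX, t(X) %*% y)
    r <- y - X %*% beta
    s2 <- sum(r^2) / (length(y) - ncol(X))
    se <- sqrt(s2 * solve(XtX)[3, 3])
    p <- 2 * pt(-abs(beta[3] / se), length(y) - ncol(X))
    expect_equal(res$beta[i], beta[3], tolerance = 1e-6)
    expect_equal(res$se[i], se, tolerance = 1e-6)
    expect_equal(res$p[i], p, tolerance = 1e-6)
  }
})

test_that("with fixed variance ratio the scan equals brute-force GLS on a small cohort", {
  sim <- assoc_sim(seed = 62)
  aff <- sim$cohort$subject_id[sim$cohort$affected][1:40]
  g <- subset_genotypes(sim$genotypes, subjects = aff)
  K <- compute_kinship(g)
  set.seed(2)
  y <- setNames(rnorm(40) + rnorm(1) * 0, aff)
  res <- run_lmm_gwas(g, y, kinship = K)
  lambda <- attr(res, "lambda")
  V <- lambda * K + diag(40)
  Vi <- solve(V)
  for (i in seq(1, nrow(res), by = 31)) {
    x <- g$dosage[, res$variant_id[i]]
    x[is.na(x)] <- mean(x, na.rm = TRUE)
    X <- cbind(1, x)
    XtVX <- t(X) %*% Vi %*% X
    beta <- solve(XtVX, t(X) %*% Vi %*% y)
    r <- y - X %*% beta
    s2 <- as.numeric(t(r) %*% Vi %*% r) / (40 - ncol(X))
    se <- sqrt(s2 * solve(XtVX)[2, 2])
    expect_equal(res$beta[i], beta[2], tolerance = 1e-6)
    expect_equal(res$se[i], se, tolerance = 1e-6)
  }
})

test_that("constant SNPs are skipped and the MAF filter is enforced", {
  sim <- assoc_sim(seed = 63)
  aff <- sim$cohort$subject_id[sim$cohort$affected]
  g <- subset_genotypes(sim$genotypes, subjects = aff)
  g$dosage[, 1] <- 1L  # constant
  set.seed(3)
  y <- setNames(rnorm(length(aff)), aff)
  res <- run_lmm_gwas(g, y, maf_min = 0.05)
  expect_false(g$variants$id[1] %in% res$variant_id)
  expect_true(all(res$maf > 0.05))
})

test_that("the kinship term absorbs family structure under a polygenic null", {
  sim <- simulate_cohort(sim_config(n_subjects = 120, n_families = 4,
                                    n_snps = 4000, n_chromosomes = 4,
                                    seed = 64))
  aff <- sim$cohort$subject_id[sim$cohort$affected]
  g <- subset_genotypes(sim$genotypes, subjects = aff)
  K <- compute_kinship(g)
  dos <- g$dosage
  f <- colMeans(dos, na.rm = TRUE) / 2
  Xc <- sweep(dos, 2, 2 * f)
  Xc[is.na(Xc)] <- 0
  set.seed(5)
  gv <- as.vector(Xc %*% rnorm(ncol(Xc)))
  y <- setNames(gv / sd(gv) + rnorm(length(aff)), aff)
  with_k <- run_lmm_gwas(g, y, kinship = K)
  no_k <- run_lmm_gwas(g, y, kinship = NULL)
  expect_lt(genomic_inflation(with_k$p), genomic_inflation(no_k$p))
  expect_gt(attr(with_k, "lambda"), 0.1)
})

test_that("a planted modifier is recovered within 2 SE and tops the scan", {
  cfg <- sim_config(n_subjects = 250, n_families = 8, n_snps = 500,
                    onset_noise_sd = 0.12,
                    modifiers = list(planted_modifier(250, 0.38, -2.8)),
                    seed = 65)
  sim <- simulate_cohort(cfg)
  model <- fit_onset_model(sim$cohort)
  resid <- residual_onset(sim$cohort, model)
  aff <- sim$cohort$subject_id[sim$cohort$affected]
  g <- subset_genotypes(sim$genotypes, subjects = aff)
  K <- compute_kinship(g)
  res <- run_lmm_gwas(g, resid, covariates = covar_for(sim, aff),
                      kinship = K)
  hit <- res[res$variant_id == "snp00250", ]
  expect_lt(abs(hit$beta - (-2.8)), 2 * hit$se)
  expect_equal(res$variant_id[which.min(res$p)], "snp00250")
})

test_that("conditioning on the top SNP removes its own signal and perfect tags", {
  cfg <- sim_config(n_subjects = 250, n_families = 8, n_snps = 300,
                    onset_noise_sd = 0.12,
                    modifiers = list(planted_modifier(100, 0.38, -2.8)),
                    seed = 66)
  sim <- simulate_cohort(cfg)
  # make two perfect-LD tags of the planted SNP
  sim$genotypes$dosage[, 101] <- sim$genotypes$dosage[, 100]
  sim$genotypes$dosage[, 102] <- sim$genotypes$dosage[, 100]
  model <- fit_onset_model(sim$cohort)
  resid <- residual_onset(sim$cohort, model)
  aff <- sim$cohort$subject_id[sim$cohort$affected]
  g <- subset_genotypes(sim$genotypes, subjects = aff)
  K <- compute_kinship(g)
  res <- run_lmm_gwas(g, resid, kinship = K)
  top <- res$variant_id[which.min(res$p)]
  expect_true(top %in% c("snp00100", "snp00101", "snp00102"))
  cond <- conditional_scan(g, resid, top, kinship = K,
                          region = sprintf("snp%05d", 95:105))
  # the conditioning SNP and its perfect tags are dropped by collinearity
  expect_false(top %in% cond$variant_id)
  expect_true(all(cond$p > 0.01, na.rm = TRUE))
  expect_error(conditional_scan(g, resid, "absent"), "unknown")
})

test_that("a second independent signal survives conditioning on the first", {
  cfg <- sim_config(n_subjects = 200, n_families = 6, n_snps = 300,
                    onset_noise_sd = 0.12,
                    modifiers = list(planted_modifier(100, 0.4, -3.5),
                                     planted_modifier(140, 0.4, -3.0)),
                    seed = 67)
  sim <- simulate_cohort(cfg)
  model <- fit_onset_model(sim$cohort)
  resid <- residual_onset(sim$cohort, model)
  aff <- sim$cohort$subject_id[sim$cohort$affected]
  g <- subset_genotypes(sim$genotypes, subjects = aff)
  K <- compute_kinship(g)
  cond <- conditional_scan(g, resid, "snp00100", kinship = K)
  expect_lt(cond$p[cond$variant_id == "snp00140"], 1e-3)
})

test_that("extreme-dichotomous analysis selects floor(n * fraction) per tail and is sign-concordant", {
  cfg <- sim_config(n_subjects = 374, n_families = 22, n_snps = 300,
                    onset_noise_sd = 0.18,
                    modifiers = list(planted_modifier(150, 0.38, -2.8)),
                    seed = 68)
  sim <- simulate_cohort(cfg)
  model <- fit_onset_model(sim$cohort)
  resid <- residual_onset(sim$cohort, model)
  aff <- sim$cohort$subject_id[sim$cohort$affected]
  g <- subset_genotypes(sim$genotypes, subjects = aff)
  K <- compute_kinship(g)
  ext <- extreme_dichotomous(g, resid, kinship = K, tail_fraction = 0.10)
  expect_equal(attr(ext, "n_cases"), 37)
  expect_equal(attr(ext, "n_controls"), 37)
  expect_equal(unique(ext$n), 74)
  cont <- run_lmm_gwas(g, resid, kinship = K)
  b_cont <- cont$beta[cont$variant_id == "snp00150"]
  b_ext <- ext$beta[ext$variant_id == "snp00150"]
  expect_equal(sign(b_cont), sign(b_ext))
  expect_error(extreme_dichotomous(g, resid, tail_fraction = 0.6), "overlap")
  # plain logistic engine agrees in direction too
  ext_lr <- extreme_dichotomous(g, resid, tail_fraction = 0.10,
                                engine = "logistic")
  expect_equal(sign(ext_lr$beta[ext_lr$variant_id == "snp00150"]),
               sign(b_cont))
})

test_that("stratified scan finds a carrier-only effect in the carrier stratum alone", {
  cfg <- sim_config(n_subjects = 300, n_families = 10, n_snps = 200,
                    onset_noise_sd = 0.10, seed = 69)
  sim <- simulate_cohort(cfg)
  aff <- sim$cohort$subject_id[sim$cohort$affected]
  g <- subset_genotypes(sim$genotypes, subjects = aff)
  # interaction: SNP 50 shifts residual onset only in carriers of SNP 10
  strat <- g$dosage[, 10]
  eff <- g$dosage[, 50]
  set.seed(6)
  y <- setNames(ifelse(strat > 0, eff * -4, 0) + rnorm(length(aff), 0, 2),
                aff)
  K <- compute_kinship(g)
  out <- stratified_interaction_scan(g, y, "snp00010", kinship = K,
                                     top_bottom_fraction = 0.4)
  p_car <- out$carrier$p[out$carrier$variant_id == "snp00050"]
  p_non <- out$non_carrier$p[out$non_carrier$variant_id == "snp00050"]
  expect_lt(p_car, 1e-3)
  expect_gt(p_non, 0.01)
  # a background SNP shows per-stratum effects compatible within 2 combined SE
  bg <- intersect(out$carrier$variant_id, out$non_carrier$variant_id)
  bg <- setdiff(bg, c("snp00050", "snp00010"))[1]
  b1 <- out$carrier[out$carrier$variant_id == bg, ]
  b2 <- out$non_carrier[out$non_carrier$variant_id == bg, ]
  expect_lt(abs(b1$beta - b2$beta), 2 * sqrt(b1$se^2 + b2$se^2))
  g$dosage[, 20] <- 0L
  expect_error(stratified_interaction_scan(g, y, "snp00020"), "stratum")
})

test_that("excluding samples reruns consistently", {
  cfg <- sim_config(n_subjects = 120, n_families = 5, n_snps = 200,
                    onset_noise_sd = 0.15,
                    modifiers = list(planted_modifier(60, 0.4, -4)),
                    seed = 70)
  sim <- simulate_cohort(cfg)
  model <- fit_onset_model(sim$cohort)
  resid <- residual_onset(sim$cohort, model)
  aff <- sim$cohort$subject_id[sim$cohort$affected]
  g <- subset_genotypes(sim$genotypes, subjects = aff)
  both <- exclude_and_rerun(g, resid, exclude = character(0))
  expect_equal(both$full$p, both$reduced$p, tolerance = 1e-12)
  # dropping a random 15% leaves the top hit in place
  set.seed(7)
  drop15 <- sample(aff, round(0.15 * length(aff)))
  rob <- exclude_and_rerun(g, resid, exclude = drop15)
  expect_equal(rob$full$variant_id[which.min(rob$full$p)],
               rob$reduced$variant_id[which.min(rob$reduced$p)])
  # dropping every carrier of the planted allele erases the signal
  carriers <- aff[g$dosage[, 60] > 0]
  lost <- exclude_and_rerun(g, resid, exclude = carriers)
  expect_false("snp00060" %in% lost$reduced$variant_id)
})
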