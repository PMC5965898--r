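# Kinship-corrected genome-wide association on residual age at onset, with
# the secondary analyses: conditional scan, extreme-dichotomous test,
# genotype-stratified scan, and exclusion re-runs.

# Align phenotype, covariates and kinship with the genotype rows; returns the
# pieces the LMM engine needs. `kinship = NULL` means independent subjects
# (K = I), under which the mixed model is exactly OLS.
prepare_assoc_inputs <- function(genotypes, phenotype, covariates = NULL,
                                 kinship = NULL) {
  y_all <- align_phenotype(phenotype,
                           intersect(rownames(genotypes$dosage),
                                     if (is.data.frame(phenotype))
                                       phenotype$subject_id
                                     else names(phenotype)))
  subjects <- names(y_all)
  if (length(subjects) < 3) stop("too few phenotyped subjects", call. = FALSE)
  W <- matrix(1, length(subjects), 1, dimnames = list(subjects, "intercept"))
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)
    if (is.null(rownames(cv))) {
      stop("covariates must have subject ids as rownames", call. = FALSE)
    }
    missing <- setdiff(subjects, rownames(cv))
    if (length(missing) > 0) {
      stop(sprintf("no covariates for subject(s) such as %s", missing[1]),
           call. = FALSE)
    }
    W <- cbind(W, cv[subjects, , drop = FALSE])
  }
  if (is.null(kinship)) {
    K <- diag(length(subjects))
    dimnames(K) <- list(subjects, subjects)
  } else {
    missing <- setdiff(subjects, rownames(kinship))
    if (length(missing) > 0) {
      stop(sprintf("kinship matrix lacks subject(s) such as %s", missing[1]),
           call. = FALSE)
    }
    K <- kinship[subjects, subjects]
  }
  list(y = unname(y_all), W = W, K = K, subjects = subjects)
}

# mean-imputed dosage block restricted to `subjects`, with allele frequencies
prepare_dosage <- function(genotypes, subjects) {
  X <- genotypes$dosage[subjects, , drop = FALSE]
  f <- colMeans(X, na.rm = TRUE) / 2
  if (anyNA(X)) {
    for (j in which(colSums(is.na(X)) > 0)) {
      X[is.na(X[, j]), j] <- 2 * f[j]
    }
  }
  storage.mode(X) <- "double"
  list(X = X, f = f)
}

#' Mixed-model genome-wide association scan
#'
#' Fits, for each SNP passing the MAF filter, the single-variance-component
#' linear mixed model `phenotype = covariates + SNP dosage + u + e` with
#' `u ~ N(0, sigma_g^2 K)`. The variance ratio is estimated once under the
#' covariates-only null model by eigendecomposition-based likelihood
#' profiling; each SNP is then tested by a Wald test under generalized least
#' squares at that ratio. With `kinship = NULL` (or `K = I`) the procedure
#' reduces exactly to ordinary least squares.
#'
#' @param genotypes A [genotype_matrix()].
#' @param phenotype Named numeric vector, or a residual data.frame from
#'   [residual_onset()].
#' @param covariates Optional numeric matrix (subjects x covariates, rownames
#'   = subject ids), e.g. sex plus ancestry components.
#' @param kinship Kinship matrix over (at least) the phenotyped subjects, from
#'   [compute_kinship()]; `NULL` for independent subjects.
#' @param maf_min Minimum minor allele frequency; SNPs at or below it are not
#'   tested (default 0.05).
#' @param reml Use REML instead of ML for the variance ratio.
#' @param extra_covariate_dosage Internal: extra per-subject dosage covariate
#'   (used by [conditional_scan()]).
#' @return data.frame: variant_id, chrom, pos, effect_allele, other_allele,
#'   beta (years per effect allele), se, p, maf, n. Constant or collinear SNPs
#'   are skipped. Attribute `lambda` carries the estimated variance ratio.
#' @export
run_lmm_gwas <- function(genotypes, phenotype, covariates = NULL,
                         kinship = NULL, maf_min = 0.05, reml = FALSE,
                         extra_covariate_dosage = NULL) {
  inp <- prepare_assoc_inputs(genotypes, phenotype, covariates, kinship)
  dos <- prepare_dosage(genotypes, inp$subjects)
  maf <- pmin(dos$f, 1 - dos$f)
  keep <- which(!is.na(maf) & maf > maf_min)
  if (length(keep) == 0) {
    stop("no SNPs pass the MAF filter", call. = FALSE)
  }
  W <- inp$W
  if (!is.null(extra_covariate_dosage)) {
    W <- cbind(W, conditioning_snp = extra_covariate_dosage[inp$subjects])
  }
  null_fit <- fit_lmm_null(inp$y, W, inp$K, reml = reml)
  n <- length(inp$y)
  # rotate SNP blocks into the eigenbasis and scan
  res <- vector("list", length = 0)
  block <- 10000L
  beta <- se <- p <- rep(NA_real_, length(keep))
  gg <- rep(NA_real_, length(keep))
  for (start in seq(1, length(keep), by = block)) {
    idx <- keep[start:min(start + block - 1, length(keep))]
    Gt <- crossprod(null_fit$U, dos$X[, idx, drop = FALSE])
    sc <- lmm_wald_scan(null_fit, Gt)
    at <- start:(start + length(idx) - 1)
    beta[at] <- sc$beta; se[at] <- sc$se; p[at] <- sc$p; gg[at] <- sc$gg
  }
  usable <- gg > n * 1e-10 & is.finite(se) & se > 0
  v <- genotypes$variants[keep, , drop = FALSE]
  out <- data.frame(variant_id = v$id, chrom = v$chrom, pos = v$pos,
                    effect_allele = v$alt, other_allele = v$ref,
                    beta = beta, se = se, p = p,
                    maf = unname(maf[keep]), n = n,
                    stringsAsFactors = FALSE)[usable, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "lambda") <- null_fit$lambda
  attr(out, "n_skipped") <- sum(!usable)
  out
}

#' Conditional association scan
#'
#' Re-runs the mixed-model scan with the dosage of a top SNP added as a fixed
#' covariate; SNPs collinear with the covariates (including the conditioning
#' SNP itself and perfect-LD tags) are skipped.
#'
#' @inheritParams run_lmm_gwas
#' @param top_snp Variant id of the SNP to condition on.
#' @param region Optional variant ids restricting the scan.
#' @return As [run_lmm_gwas()].
#' @export
conditional_scan <- function(genotypes, phenotype, top_snp, covariates = NULL,
                             kinship = NULL, maf_min = 0.05, region = NULL) {
  j <- match(top_snp, genotypes$variants$id)
  if (is.na(j)) stop(sprintf("unknown variant: %s", top_snp), call. = FALSE)
  top_dos <- genotypes$dosage[, j]
  top_dos[is.na(top_dos)] <- mean(top_dos, na.rm = TRUE)
  if (stats::var(top_dos) == 0) {
    stop("conditioning SNP is constant", call. = FALSE)
  }
  g <- if (is.null(region)) genotypes else
    subset_genotypes(genotypes, variants = region)
  run_lmm_gwas(g, phenotype, covariates = covariates, kinship = kinship,
               maf_min = maf_min, extra_covariate_dosage = top_dos)
}

#' Extreme-dichotomous association analysis
#'
#' Labels the `floor(n * tail_fraction)` subjects with the earliest residual
#' onset 0 and the latest 1, drops the middle, and tests each SNP against the
#' binary label -- either with the kinship mixed model applied to the 0/1
#' label (default, keeping the familial correction) or with plain logistic
#' regression.
#'
#' @inheritParams run_lmm_gwas
#' @param tail_fraction Fraction in (0, 0.5) taken from each extreme
#'   (default 0.10).
#' @param engine `"lmm"` (mixed model on the 0/1 label) or `"logistic"`.
#' @return As [run_lmm_gwas()] (beta is on the 0/1 scale or log-odds);
#'   attributes `n_cases` / `n_controls`.
#' @export
extreme_dichotomous <- function(genotypes, phenotype, covariates = NULL,
                                kinship = NULL, tail_fraction = 0.10,
                                maf_min = 0.05,
                                engine = c("lmm", "logistic")) {
  engine <- match.arg(engine)
  if (tail_fraction <= 0 || tail_fraction >= 0.5) {
    stop("tail_fraction must lie in (0, 0.5): tails must not overlap",
         call. = FALSE)
  }
  subjects <- intersect(rownames(genotypes$dosage),
                        if (is.data.frame(phenotype)) phenotype$subject_id
                        else names(phenotype))
  y <- align_phenotype(phenotype, subjects)
  k <- floor(length(y) * tail_fraction)
  if (k < 1) stop("tail_fraction selects no subjects", call. = FALSE)
  ord <- order(y, names(y))  # stable tie-break by subject id
  early <- names(y)[ord[seq_len(k)]]
  late <- names(y)[ord[seq(length(y) - k + 1, length(y))]]
  label <- stats::setNames(c(rep(0, k), rep(1, k)), c(early, late))
  g_sub <- subset_genotypes(genotypes, subjects = names(label))
  out <- if (engine == "lmm") {
    run_lmm_gwas(g_sub, label, covariates = covariates, kinship = kinship,
                 maf_min = maf_min)
  } else {
    logistic_scan(g_sub, label, covariates = covariates, maf_min = maf_min)
  }
  attr(out, "n_cases") <- k
  attr(out, "n_controls") <- k
  out
}

# plain per-SNP logistic regression (no kinship correction)
logistic_scan <- function(genotypes, label, covariates = NULL,
                          maf_min = 0.05) {
  subjects <- names(label)
  dos <- prepare_dosage(genotypes, subjects)
  maf <- pmin(dos$f, 1 - dos$f)
  keep <- which(!is.na(maf) & maf > maf_min)
  W <- if (is.null(covariates)) NULL else
    as.matrix(covariates)[subjects, , drop = FALSE]
  rows <- lapply(keep, function(j) {
    g <- dos$X[, j]
    if (stats::var(g) == 0) return(NULL)
    dat <- data.frame(y = unname(label), g = g)
    form <- "y ~ g"
    if (!is.null(W)) {
      dat <- cbind(dat, W)
      form <- paste("y ~ g +", paste(colnames(W), collapse = " + "))
    }
    fit <- suppressWarnings(stats::glm(stats::as.formula(form), data = dat,
                                       family = stats::binomial()))
    sm <- summary(fit)$coefficients
    if (!"g" %in% rownames(sm)) return(NULL)
    v <- genotypes$variants[j, ]
    data.frame(variant_id = v$id, chrom = v$chrom, pos = v$pos,
               effect_allele = v$alt, other_allele = v$ref,
               beta = sm["g", "Estimate"], se = sm["g", "Std. Error"],
               p = sm["g", "Pr(>|z|)"], maf = unname(maf[j]),
               n = length(label), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Genotype-stratified interaction scan
#'
#' Splits subjects into carriers and non-carriers of a stratifying SNP's minor
#' allele, dichotomizes residual onset at the top/bottom `top_bottom_fraction`
#' within each stratum (dropping the middle), and runs the mixed-model
#' association within each stratum. Differing per-stratum effects flag
#' candidate interactions.
#'
#' @inheritParams run_lmm_gwas
#' @param stratifying_snp Variant id used to define the strata.
#' @param top_bottom_fraction Fraction labelled at each extreme within a
#'   stratum (default 0.40).
#' @return list(carrier = , non_carrier = ) of association data.frames.
#' @export
stratified_interaction_scan <- function(genotypes, phenotype, stratifying_snp,
                                        covariates = NULL, kinship = NULL,
                                        top_bottom_fraction = 0.40,
                                        maf_min = 0.05) {
  if (top_bottom_fraction <= 0 || top_bottom_fraction > 0.5) {
    stop("top_bottom_fraction must lie in (0, 0.5]", call. = FALSE)
  }
  j <- match(stratifying_snp, genotypes$variants$id)
  if (is.na(j)) stop(sprintf("unknown variant: %s", stratifying_snp),
                     call. = FALSE)
  subjects <- intersect(rownames(genotypes$dosage),
                        if (is.data.frame(phenotype)) phenotype$subject_id
                        else names(phenotype))
  y <- align_phenotype(phenotype, subjects)
  dos <- genotypes$dosage[subjects, j]
  f <- mean(dos, na.rm = TRUE) / 2
  minor_count <- if (!is.na(f) && f > 0.5) 2 - dos else dos
  carrier <- subjects[!is.na(minor_count) & minor_count > 0]
  non_carrier <- subjects[!is.na(minor_count) & minor_count == 0]
  if (length(carrier) == 0) stop("empty stratum: carrier", call. = FALSE)
  if (length(non_carrier) == 0) {
    stop("empty stratum: non-carrier", call. = FALSE)
  }
  run_stratum <- function(ids) {
    ys <- y[ids]
    k <- floor(length(ys) * top_bottom_fraction)
    if (k < 1) stop("stratum too small to dichotomize", call. = FALSE)
    ord <- order(ys, names(ys))
    label <- stats::setNames(
      c(rep(0, k), rep(1, k)),
      c(names(ys)[ord[seq_len(k)]],
        names(ys)[ord[seq(length(ys) - k + 1, length(ys))]]))
    run_lmm_gwas(subset_genotypes(genotypes, subjects = names(label)),
                 label, covariates = covariates, kinship = kinship,
                 maf_min = maf_min)
  }
  list(carrier = run_stratum(carrier),
       non_carrier = run_stratum(non_carrier))
}

#' Re-run the association scan after excluding samples
#'
#' Stability check mirroring CNV-carrier exclusion: reruns [run_lmm_gwas()]
#' on the cohort minus an exclusion list and returns before/after results.
#'
#' @inheritParams run_lmm_gwas
#' @param exclude Subject ids to drop.
#' @return list(full = , reduced = ) of association data.frames.
#' @export
exclude_and_rerun <- function(genotypes, phenotype, exclude,
                              covariates = NULL, kinship = NULL,
                              maf_min = 0.05) {
  full <- run_lmm_gwas(genotypes, phenotype, covariates, kinship, maf_min)
  subjects <- intersect(rownames(genotypes$dosage),
                        if (is.data.frame(phenotype)) phenotype$subject_id
                        else names(phenotype))
  keep <- setdiff(subjects, exclude)
  if (length(keep) < 3) {
    stop("exclusion list removes (nearly) the whole cohort", call. = FALSE)
  }
  ph <- if (is.data.frame(phenotype)) {
    phenotype[phenotype$subject_id %in% keep, , drop = FALSE]
  } else phenotype[keep]
  reduced <- run_lmm_gwas(subset_genotypes(genotypes, subjects = keep),
                          ph, covariates, kinship, maf_min)
  list(full = full, reduced = reduced)
}
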