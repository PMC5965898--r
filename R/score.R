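# Polygenic modification score: training-cohort effect sizes of independent
# suggestive SNPs, summed as effect-allele count x effect size per subject,
# then evaluated for transfer as the incremental variance in residual onset it
# explains over sex/ancestry covariates.

#' Build a polygenic modification scoring model
#'
#' Greedy, p-ordered selection of independent SNPs at suggestive significance:
#' candidates are walked in ascending training p-value; a SNP is kept if its
#' p-value is below `p_threshold` and it is independent of every SNP already
#' selected -- outside `window_bp` on the same chromosome, or within the
#' window but with genotype `r^2 < r2_max` (the LD check requires
#' `genotypes`; without them the window rule alone applies).
#'
#' @param train_results Training association results (from [run_lmm_gwas()]).
#' @param p_threshold Suggestive-significance threshold (default 1e-5).
#' @param window_bp Independence window in base pairs (default 1e6).
#' @param r2_max Maximum squared genotype correlation between selected SNPs
#'   within the window (default 0.2).
#' @param genotypes Optional training [genotype_matrix()] for the r^2 rule.
#' @return Object of class `scoring_model`: data.frame(variant_id,
#'   effect_allele, beta, p) with attributes recording the selection rule.
#'   Zero rows (with a warning) when no SNP survives.
#' @export
build_modifier_score <- function(train_results, p_threshold = 1e-5,
                                 window_bp = 1e6, r2_max = 0.2,
                                 genotypes = NULL) {
  cand <- train_results[!is.na(train_results$p) &
                          train_results$p < p_threshold, , drop = FALSE]
  cand <- cand[order(cand$p), , drop = FALSE]
  selected <- integer(0)
  for (i in seq_len(nrow(cand))) {
    ok <- TRUE
    for (s in selected) {
      near <- cand$chrom[i] == cand$chrom[s] &&
        abs(cand$pos[i] - cand$pos[s]) <= window_bp
      if (!near) next
      if (is.null(genotypes)) { ok <- FALSE; break }
      g1 <- genotypes$dosage[, match(cand$variant_id[i],
                                     genotypes$variants$id)]
      g2 <- genotypes$dosage[, match(cand$variant_id[s],
                                     genotypes$variants$id)]
      r2 <- suppressWarnings(stats::cor(g1, g2, use = "complete.obs"))^2
      if (is.na(r2) || r2 >= r2_max) { ok <- FALSE; break }
    }
    if (ok) selected <- c(selected, i)
  }
  model <- cand[selected, c("variant_id", "effect_allele", "beta", "p"),
                drop = FALSE]
  rownames(model) <- NULL
  if (nrow(model) == 0) {
    warning("no SNP passes the significance threshold; empty scoring model",
            call. = FALSE)
  }
  structure(model, class = c("scoring_model", "data.frame"),
            p_threshold = p_threshold, window_bp = window_bp, r2_max = r2_max)
}

#' Apply a polygenic modification score
#'
#' Per-subject score: sum over scoring SNPs of effect-allele count times
#' training effect size. Dosages are counted on the model's effect allele
#' (flipped when the target panel codes the opposite allele); missing dosages
#' are imputed at twice the target-panel allele frequency.
#'
#' @param model A `scoring_model` from [build_modifier_score()].
#' @param genotypes Target [genotype_matrix()].
#' @return Named numeric vector of scores (years).
#' @export
apply_modifier_score <- function(model, genotypes) {
  n <- nrow(genotypes$dosage)
  score <- stats::setNames(rep(0, n), rownames(genotypes$dosage))
  if (nrow(model) == 0) return(score)
  for (i in seq_len(nrow(model))) {
    j <- match(model$variant_id[i], genotypes$variants$id)
    if (is.na(j)) {
      warning(sprintf("scoring SNP %s absent from target panel; skipped",
                      model$variant_id[i]), call. = FALSE)
      next
    }
    dos <- genotypes$dosage[, j]
    dos[is.na(dos)] <- mean(dos, na.rm = TRUE)
    if (model$effect_allele[i] == genotypes$variants$ref[j]) {
      dos <- 2 - dos
    } else if (model$effect_allele[i] != genotypes$variants$alt[j]) {
      warning(sprintf("allele mismatch at %s; skipped", model$variant_id[i]),
              call. = FALSE)
      next
    }
    score <- score + dos * model$beta[i]
  }
  score
}

#' Evaluate a polygenic modification score
#'
#' Regresses residual age at onset on the score plus covariates and reports
#' the incremental R-squared of the score term (over the covariates-only
#' model) and its p-value.
#'
#' @param scores Named numeric vector from [apply_modifier_score()].
#' @param phenotype Named residual vector or residual data.frame.
#' @param covariates Optional covariate matrix (rownames = subject ids).
#' @return list(r2 (incremental), p, coefficient, se, n).
#' @export
evaluate_score <- function(scores, phenotype, covariates = NULL) {
  subjects <- intersect(names(scores),
                        if (is.data.frame(phenotype)) phenotype$subject_id
                        else names(phenotype))
  y <- align_phenotype(phenotype, subjects)
  dat <- data.frame(y = unname(y), score = unname(scores[subjects]))
  form_full <- "y ~ score"
  form_red <- "y ~ 1"
  if (!is.null(covariates)) {
    cv <- as.matrix(covariates)[subjects, , drop = FALSE]
    dat <- cbind(dat, cv)
    form_full <- paste("y ~ score +", paste(colnames(cv), collapse = " + "))
    form_red <- paste("y ~", paste(colnames(cv), collapse = " + "))
  }
  full <- stats::lm(stats::as.formula(form_full), data = dat)
  red <- stats::lm(stats::as.formula(form_red), data = dat)
  r2_full <- summary(full)$r.squared
  r2_red <- summary(red)$r.squared
  sm <- summary(full)$coefficients
  if (!"score" %in% rownames(sm)) {
    return(list(r2 = 0, p = NA_real_, coefficient = NA_real_, se = NA_real_,
                n = length(subjects)))
  }
  list(r2 = r2_full - r2_red,
       p = sm["score", "Pr(>|t|)"],
       coefficient = sm["score", "Estimate"],
       se = sm["score", "Std. Error"],
       n = length(subjects))
}
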