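# Inverse-variance fixed-effects meta-analysis and the genomic inflation
# factor (median method).

#' Inverse-variance fixed-effects meta-analysis
#'
#' Combines two association result sets on shared variants, flipping effect
#' alleles where the cohorts reported opposite alleles. Combined effect is
#' `sum(beta_i / se_i^2) / sum(1 / se_i^2)`, combined SE is
#' `sqrt(1 / sum(1 / se_i^2))`, with a two-sided normal p-value. Variants with
#' irreconcilable alleles are dropped with a message; variants present in only
#' one cohort pass through unchanged.
#'
#' @param results_a,results_b data.frames as from [run_lmm_gwas()] (columns
#'   variant_id, effect_allele, other_allele, beta, se).
#' @return data.frame: variant_id, effect_allele, beta, se, p, n_cohorts,
#'   beta_a, beta_b.
#' @export
meta_analyze <- function(results_a, results_b) {
  a <- results_a; b <- results_b
  shared <- intersect(a$variant_id, b$variant_id)
  ai <- a[match(shared, a$variant_id), , drop = FALSE]
  bi <- b[match(shared, b$variant_id), , drop = FALSE]
  same <- ai$effect_allele == bi$effect_allele &
    ai$other_allele == bi$other_allele
  flipped <- ai$effect_allele == bi$other_allele &
    ai$other_allele == bi$effect_allele
  bad <- !(same | flipped)
  if (any(bad)) {
    message(sprintf("dropping %d variant(s) with irreconcilable alleles",
                    sum(bad)))
  }
  beta_b <- ifelse(flipped, -bi$beta, bi$beta)
  wa <- 1 / ai$se^2; wb <- 1 / bi$se^2
  beta <- (ai$beta * wa + beta_b * wb) / (wa + wb)
  se <- sqrt(1 / (wa + wb))
  combined <- data.frame(variant_id = shared,
                         effect_allele = ai$effect_allele,
                         beta = beta, se = se,
                         p = 2 * stats::pnorm(-abs(beta / se)),
                         n_cohorts = 2L,
                         beta_a = ai$beta, beta_b = beta_b,
                         stringsAsFactors = FALSE)[!bad, , drop = FALSE]
  single <- function(x, which_a) {
    only <- x[!x$variant_id %in% shared, , drop = FALSE]
    if (nrow(only) == 0) return(NULL)
    data.frame(variant_id = only$variant_id,
               effect_allele = only$effect_allele,
               beta = only$beta, se = only$se,
               p = 2 * stats::pnorm(-abs(only$beta / only$se)),
               n_cohorts = 1L,
               beta_a = if (which_a) only$beta else NA_real_,
               beta_b = if (which_a) NA_real_ else only$beta,
               stringsAsFactors = FALSE)
  }
  out <- rbind(combined, single(a, TRUE), single(b, FALSE))
  rownames(out) <- NULL
  out
}

#' Genomic inflation factor (median method)
#'
#' `lambda = median(qchisq(1 - p, df = 1)) / qchisq(0.5, df = 1)`: the median
#' observed association chi-square over its null median (0.4549...). Values
#' near 1 indicate well-calibrated tests; above 1, inflation from uncorrected
#' structure.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return A single number, lambda.
#' @export
genomic_inflation <- function(p_values) {
  p_values <- p_values[!is.na(p_values)]
  if (length(p_values) == 0) stop("no p-values supplied", call. = FALSE)
  if (any(p_values <= 0 | p_values > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  chisq <- stats::qchisq(p_values, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}
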