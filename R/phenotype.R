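# Residual age-at-onset phenotype.
#
# Age at motor onset in HD is strongly determined by the expanded CAG length:
# ln(onset) is close to linear in CAG. Fitting that relationship jointly over
# populations with a shared slope and population-specific intercepts, and
# subtracting the back-transformed prediction from the observed onset, yields
# the residual age at onset -- the quantitative phenotype for modifier GWA.
# Positive residuals mean later-than-expected onset.

#' Construct an onset model from known coefficients
#'
#' Mainly useful for simulation oracles and for applying externally estimated
#' coefficients; [fit_onset_model()] estimates them from data.
#'
#' @param slope Log-years per CAG repeat (negative).
#' @param intercepts Named numeric vector of per-population intercepts
#'   (log-years).
#' @param fit_n Number of subjects behind the coefficients (NA if analytic).
#' @param r_squared Model R-squared on the log scale (NA if analytic).
#' @return An object of class `onset_model`.
#' @export
onset_model <- function(slope, intercepts, fit_n = NA_integer_,
                        r_squared = NA_real_) {
  if (is.null(names(intercepts))) {
    stop("intercepts must be named by population", call. = FALSE)
  }
  structure(list(slope = slope, intercepts = intercepts,
                 fit_n = fit_n, r_squared = r_squared),
            class = "onset_model")
}

#' @export
print.onset_model <- function(x, ...) {
  cat("onset model: ln(onset) = intercept_pop + slope * CAG_long\n")
  cat(sprintf("  slope: %.5f log-years per CAG repeat\n", x$slope))
  for (p in names(x$intercepts)) {
    cat(sprintf("  intercept[%s]: %.4f\n", p, x$intercepts[p]))
  }
  if (!is.na(x$fit_n)) {
    cat(sprintf("  fitted on %d subjects, R-squared %.3f\n",
                x$fit_n, x$r_squared))
  }
  invisible(x)
}

# Affected subjects with usable onset + CAG. Shared by fit/residual/dominance.
onset_fit_frame <- function(cohort) {
  if (!is.data.frame(cohort)) cohort <- cohort$cohort
  keep <- !is.na(cohort$onset) & !is.na(cohort$cag_long)
  if ("affected" %in% names(cohort)) keep <- keep & cohort$affected
  d <- cohort[keep, , drop = FALSE]
  if (any(d$onset <= 0)) {
    stop("validation error: onset must be positive for all subjects",
         call. = FALSE)
  }
  d
}

#' Fit the log-linear CAG to onset model
#'
#' Ordinary least squares of `ln(onset)` on the longer expanded CAG allele
#' with a shared slope and one intercept per population. For subjects with
#' two expanded alleles the longer one is used (onset behaves fully dominant
#' for the longer allele).
#'
#' @param cohort A cohort data.frame (or the list returned by
#'   [simulate_cohort()]) with columns `subject_id`, `population`, `cag_long`,
#'   `onset`; only affected subjects with non-missing onset are used.
#' @return An [onset_model()] with estimated `slope` and `intercepts`.
#' @export
fit_onset_model <- function(cohort) {
  d <- onset_fit_frame(cohort)
  if (length(unique(d$cag_long)) < 2) {
    stop("degenerate design: need at least 2 distinct CAG values",
         call. = FALSE)
  }
  d$population <- factor(d$population)
  if (nlevels(d$population) > 1) {
    fit <- stats::lm(log(onset) ~ 0 + population + cag_long, data = d)
    cf <- stats::coef(fit)
    ints <- cf[startsWith(names(cf), "population")]
    names(ints) <- sub("^population", "", names(ints))
  } else {
    fit <- stats::lm(log(onset) ~ cag_long, data = d)
    cf <- stats::coef(fit)
    ints <- stats::setNames(cf["(Intercept)"], levels(d$population))
  }
  slope <- unname(cf["cag_long"])
  # R-squared relative to the population-means model is not what we want;
  # report the conventional proportion of ln(onset) variance explained.
  r2 <- 1 - sum(stats::residuals(fit)^2) /
    sum((log(d$onset) - mean(log(d$onset)))^2)
  m <- onset_model(slope = slope, intercepts = ints,
                   fit_n = nrow(d), r_squared = r2)
  # coefficient uncertainty, with clean names matching slope/intercepts
  V <- stats::vcov(fit)
  rownames(V) <- colnames(V) <- sub("^population", "",
                                    sub("\\(Intercept\\)",
                                        names(ints)[1], rownames(V)))
  m$vcov <- V
  m$slope_se <- sqrt(V["cag_long", "cag_long"])
  m
}

#' Standard error of the difference between two population intercepts
#'
#' @param model A fitted [onset_model()] carrying a `vcov` component.
#' @param pop_a,pop_b Population labels.
#' @return Standard error of `intercepts[pop_a] - intercepts[pop_b]`.
#' @export
intercept_diff_se <- function(model, pop_a, pop_b) {
  if (is.null(model$vcov)) stop("model carries no vcov", call. = FALSE)
  V <- model$vcov
  sqrt(V[pop_a, pop_a] + V[pop_b, pop_b] - 2 * V[pop_a, pop_b])
}

#' Residual age at onset
#'
#' Predicted onset is `exp(intercept_pop + slope * CAG_long)` (the fitted log
#' model transformed back to the natural scale); the residual is observed
#' minus predicted, in years. Positive residuals indicate onset later than
#' expected for the subject's CAG length.
#'
#' @param cohort As in [fit_onset_model()].
#' @param model An [onset_model()].
#' @param scale `"years"` (default, natural-scale residuals) or `"log"`.
#' @return data.frame: subject_id, observed_onset, predicted_onset, residual.
#' @export
residual_onset <- function(cohort, model, scale = c("years", "log")) {
  scale <- match.arg(scale)
  d <- onset_fit_frame(cohort)
  unknown <- setdiff(unique(d$population), names(model$intercepts))
  if (length(unknown) > 0) {
    stop(sprintf("no intercept for population(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  log_pred <- model$intercepts[d$population] + model$slope * d$cag_long
  pred <- exp(log_pred)
  res <- if (scale == "years") d$onset - pred else log(d$onset) - log_pred
  data.frame(subject_id = d$subject_id,
             observed_onset = d$onset,
             predicted_onset = unname(pred),
             residual = unname(res),
             stringsAsFactors = FALSE)
}

#' Test dominance of the longer expanded allele
#'
#' Among subjects carrying two expanded alleles (both CAG > 35), augments the
#' log-linear onset regression with the shorter expanded allele. Under full
#' dominance of the longer allele the shorter-allele coefficient is
#' indistinguishable from zero.
#'
#' @param cohort As in [fit_onset_model()].
#' @param expanded_min CAG length above which an allele counts as expanded
#'   (default 35).
#' @return data.frame with one row (coefficient, se, p, n_biallelic) or, when
#'   fewer than 2 biallelic subjects are present, a zero-row data.frame with a
#'   warning.
#' @export
dominance_check <- function(cohort, expanded_min = 35) {
  d <- onset_fit_frame(cohort)
  bi <- d[d$cag_short > expanded_min, , drop = FALSE]
  empty <- data.frame(coefficient = numeric(0), se = numeric(0),
                      p = numeric(0), n_biallelic = integer(0))
  if (nrow(bi) < 2) {
    warning(sprintf("only %d subject(s) with two expanded alleles; %s",
                    nrow(bi), "dominance not testable"), call. = FALSE)
    return(empty)
  }
  if (length(unique(bi$cag_short)) < 2 || length(unique(bi$cag_long)) < 2) {
    warning("no variation in expanded alleles among biallelic subjects",
            call. = FALSE)
    return(empty)
  }
  form <- if (length(unique(bi$population)) > 1) {
    log(onset) ~ population + cag_long + cag_short
  } else {
    log(onset) ~ cag_long + cag_short
  }
  fit <- stats::lm(form, data = bi)
  sm <- summary(fit)$coefficients
  data.frame(coefficient = sm["cag_short", "Estimate"],
             se = sm["cag_short", "Std. Error"],
             p = sm["cag_short", "Pr(>|t|)"],
             n_biallelic = nrow(bi))
}
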