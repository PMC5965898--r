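#' @keywords internal
"_PACKAGE"

# Internal validation helpers shared across modules.

stop_config <- function(field, msg) {
  stop(sprintf("invalid configuration: `%s` %s", field, msg), call. = FALSE)
}

check_fraction <- function(x, field, allow_zero = TRUE, allow_one = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x)) {
    stop_config(field, "must be a single number")
  }
  lo <- if (allow_zero) x >= 0 else x > 0
  hi <- if (allow_one) x <= 1 else x < 1
  if (!lo || !hi) stop_config(field, "must lie in [0, 1]")
  invisible(x)
}

check_count <- function(x, field, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x)) {
    stop_config(field, sprintf("must be an integer >= %d", min))
  }
  invisible(as.integer(x))
}

# Align a named phenotype vector (or residual data.frame) with genotype rows.
align_phenotype <- function(phenotype, subjects) {
  if (is.data.frame(phenotype)) {
    if (!all(c("subject_id", "residual") %in% names(phenotype))) {
      stop("phenotype data.frame must have columns `subject_id` and `residual`",
           call. = FALSE)
    }
    y <- stats::setNames(phenotype$residual, phenotype$subject_id)
  } else if (is.numeric(phenotype)) {
    y <- phenotype
    if (is.null(names(y))) {
      if (length(y) != length(subjects)) {
        stop("unnamed phenotype vector must match the number of subjects",
             call. = FALSE)
      }
      names(y) <- subjects
    }
  } else {
    stop("phenotype must be a numeric vector or a residual data.frame",
         call. = FALSE)
  }
  missing <- setdiff(subjects, names(y))
  if (length(missing) > 0) {
    stop(sprintf("no phenotype for %d subject(s), e.g. %s",
                 length(missing), missing[1]), call. = FALSE)
  }
  y[subjects]
}
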