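# Shared fixtures: tiny cohorts and trio genotypes built in code.

# minimal affected-only cohort table for phenotype functions
make_cohort_df <- function(cag_long, onset, population = "venezuelan",
                           cag_short = 19, sex = "F") {
  n <- length(cag_long)
  data.frame(subject_id = sprintf("S%03d", seq_len(n)),
             population = rep_len(population, n),
             sex = rep_len(sex, n),
             cag_long = cag_long,
             cag_short = rep_len(cag_short, n),
             onset = onset,
             affected = TRUE,
             stringsAsFactors = FALSE)
}

# trio from explicit genotype strings like "A/G", "./." for missing
make_trio <- function(father, mother, child, ref = "A", alt = "G") {
  parse <- function(gt) {
    t(vapply(strsplit(gt, "/"), function(a) {
      a[a == "."] <- NA
      a
    }, character(2)))
  }
  n <- length(father)
  trio_genotypes(parse(father), parse(mother), parse(child),
                 sites = data.frame(pos = seq_len(n) * 100L,
                                    ref = rep_len(ref, n),
                                    alt = rep_len(alt, n),
                                    stringsAsFactors = FALSE))
}

# default small simulation used by several test files
small_sim <- function(seed = 11, ...) {
  simulate_cohort(sim_config(n_subjects = 60, n_families = 4, n_snps = 800,
                             seed = seed, ...))
}

# brute-force NGG PAM scan of one strand-annotated sequence pair: returns the
# set of (start, strand) where hap A has a callable NGG/CCN PAM and hap B does
# not. Independent of the package's implementation.
oracle_pam_scan <- function(seq_a, seq_b) {
  a <- strsplit(seq_a, "")[[1]]
  b <- strsplit(seq_b, "")[[1]]
  m <- length(a)
  hits <- list()
  is_pam <- function(x, i, strand) {
    w <- x[i:(i + 2)]
    if (any(!w %in% c("A", "C", "G", "T"))) return(NA)
    if (strand == "+") w[2] == "G" && w[3] == "G" else
      w[1] == "C" && w[2] == "C"
  }
  for (i in seq_len(m - 2)) {
    for (strand in c("+", "-")) {
      pa <- is_pam(a, i, strand)
      pb <- is_pam(b, i, strand)
      if (is.na(pa) || is.na(pb)) next
      if (pa && !pb) {
        hits[[length(hits) + 1]] <- data.frame(pam_start = i - 1,
                                               strand = strand)
      }
    }
  }
  if (length(hits) == 0) {
    return(data.frame(pam_start = integer(0), strand = character(0)))
  }
  out <- do.call(rbind, hits)
  out[order(out$pam_start, out$strand), , drop = FALSE]
}

random_seq <- function(n) {
  paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
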