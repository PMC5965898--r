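# Synthetic family-structured HD cohorts with known ground truth.
#
# The generator emulates the structure of a founder-cluster HD study: a small
# number of families of very unequal size (one family holding about half the
# affected subjects), founder SNP haplotypes drawn from population-labelled
# frequencies, Mendelian transmission with per-site crossovers, an expanded
# CAG repeat (40-55) transmitted down the affected line with mild instability,
# age at motor onset drawn from a log-linear CAG model with population-specific
# intercepts, and optional planted modifier variants that shift onset by a
# fixed number of years per minor allele.

#' Planted modifier variant
#'
#' Describes a variant whose minor allele shifts age at onset additively on
#' the natural (years) scale, mirroring common modifiers of a few years per
#' allele observed in HD modifier studies.
#'
#' @param variant_index Column index of the variant in the simulated panel.
#' @param maf Minor allele frequency used for founder haplotypes at this site,
#'   in (0, 0.5].
#' @param effect_years_per_allele Additive shift in onset, in years per copy
#'   of the minor allele (negative values hasten onset).
#' @param population Optional population label; when set, the effect applies
#'   only to subjects of that population.
#' @return An object of class `planted_modifier`.
#' @export
planted_modifier <- function(variant_index, maf, effect_years_per_allele,
                             population = NULL) {
  check_count(variant_index, "variant_index")
  if (!is.numeric(maf) || length(maf) != 1 || maf <= 0 || maf > 0.5) {
    stop_config("maf", "must lie in (0, 0.5]")
  }
  if (!is.numeric(effect_years_per_allele) || length(effect_years_per_allele) != 1) {
    stop_config("effect_years_per_allele", "must be a single number")
  }
  structure(list(variant_index = as.integer(variant_index), maf = maf,
                 effect_years_per_allele = effect_years_per_allele,
                 population = population),
            class = "planted_modifier")
}

#' Simulation configuration
#'
#' Builds and validates the configuration for [simulate_cohort()]. Defaults
#' reproduce the study conditions of a Venezuelan-style HD cluster: 374
#' affected subjects in 22 families with the largest family holding ~55% of
#' subjects, expanded CAG alleles in 40-55 with a mean normal allele of 19
#' repeats, and a log-linear onset model whose intercepts put mean onset near
#' 35.5 years at the mean expanded CAG of ~46 in the earlier-onset population,
#' about 5 years earlier than the reference population at the same CAG.
#'
#' @param n_subjects Number of affected subjects to generate (unaffected
#'   married-in founders are generated additionally and flagged).
#' @param n_families Number of families.
#' @param family_weights Relative family-size weights; default puts 55% of
#'   subjects in family 1 and splits the rest evenly.
#' @param n_snps Number of biallelic SNPs in the panel.
#' @param n_chromosomes Number of chromosomes the panel is split across
#'   (crossover processes restart at chromosome boundaries).
#' @param allele_freq_range Range the per-site alternate-allele frequencies
#'   are drawn from.
#' @param freq_divergence Half-width of a uniform per-population perturbation
#'   of allele frequencies (0 = both populations share frequencies).
#' @param recomb_rate Per-adjacent-site crossover probability within a
#'   chromosome.
#' @param disease_locus_index Panel index of the SNP marking the disease
#'   locus: affected children are ascertained to receive the affected parent's
#'   disease-carrying chromosome at this site (default: the middle SNP of
#'   chromosome 1).
#' @param cag_expanded_range Integer range of founder expanded CAG lengths.
#' @param cag_normal_mean Mean of the normal CAG allele.
#' @param onset_intercepts Named vector of per-population intercepts on the
#'   log-years scale.
#' @param population_weights Named vector of probabilities with which each
#'   family is assigned to a population; defaults to all families in the
#'   first population named in `onset_intercepts`.
#' @param onset_slope Log-years change in onset per CAG repeat (negative).
#' @param onset_noise_sd SD of Gaussian noise added on the log-years scale.
#' @param modifiers List of [planted_modifier()] objects.
#' @param homozygote_rate Probability an affected subject carries a second
#'   expanded allele.
#' @param cag_instability_rate Probability of a +/-1 repeat step on
#'   transmission of the expanded allele.
#' @param mean_children Mean number of children per sibship.
#' @param panel Optional variant panel (the `variants` data.frame of a
#'   previously simulated cohort): reuses its positions, alleles and founder
#'   frequencies so two cohorts can be simulated on a shared SNP panel (e.g.
#'   training and transfer populations). Overrides `n_snps`/`n_chromosomes`.
#' @param missing_rate,genotype_error_rate Fractions of genotype calls to
#'   blank / perturb after the truth is recorded (see [inject_errors()]).
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 374,
                       n_families = 22,
                       family_weights = NULL,
                       n_snps = 1000,
                       n_chromosomes = 2,
                       allele_freq_range = c(0.05, 0.5),
                       freq_divergence = 0,
                       recomb_rate = 0.01,
                       disease_locus_index = NULL,
                       cag_expanded_range = c(40L, 55L),
                       cag_normal_mean = 19,
                       onset_intercepts = c(venezuelan = 5.87, european = 6.00),
                       population_weights = NULL,
                       onset_slope = -0.05,
                       onset_noise_sd = 0.1,
                       modifiers = list(),
                       homozygote_rate = 0.032,
                       cag_instability_rate = 0.05,
                       mean_children = 3,
                       panel = NULL,
                       missing_rate = 0,
                       genotype_error_rate = 0,
                       seed = 1L) {
  check_count(n_subjects, "n_subjects", min = 2)
  check_count(n_families, "n_families", min = 1)
  check_count(n_snps, "n_snps", min = 1)
  check_count(n_chromosomes, "n_chromosomes", min = 1)
  check_fraction(recomb_rate, "recomb_rate")
  check_fraction(missing_rate, "missing_rate")
  check_fraction(genotype_error_rate, "genotype_error_rate")
  check_fraction(homozygote_rate, "homozygote_rate")
  check_fraction(cag_instability_rate, "cag_instability_rate")
  check_fraction(freq_divergence, "freq_divergence")
  if (length(allele_freq_range) != 2 || any(allele_freq_range <= 0) ||
      any(allele_freq_range >= 1) || diff(allele_freq_range) < 0) {
    stop_config("allele_freq_range", "must be an increasing pair in (0, 1)")
  }
  if (length(cag_expanded_range) != 2 || diff(cag_expanded_range) < 0 ||
      cag_expanded_range[1] <= 35) {
    stop_config("cag_expanded_range", "must be a non-empty range above 35")
  }
  if (!is.numeric(onset_slope) || onset_slope >= 0) {
    stop_config("onset_slope", "must be negative (longer repeats hasten onset)")
  }
  if (is.null(names(onset_intercepts)) || any(names(onset_intercepts) == "")) {
    stop_config("onset_intercepts", "must be a named numeric vector")
  }
  if (onset_noise_sd < 0) stop_config("onset_noise_sd", "must be >= 0")
  if (is.null(family_weights)) {
    family_weights <- if (n_families == 1) 1 else
      c(0.55, rep(0.45 / (n_families - 1), n_families - 1))
  }
  if (length(family_weights) != n_families || any(family_weights <= 0)) {
    stop_config("family_weights", "must be positive, one per family")
  }
  if (is.null(population_weights)) {
    population_weights <- stats::setNames(
      c(1, rep(0, length(onset_intercepts) - 1)), names(onset_intercepts))
  }
  if (!all(names(population_weights) %in% names(onset_intercepts))) {
    stop_config("population_weights", "names must match onset_intercepts")
  }
  for (m in modifiers) {
    if (!inherits(m, "planted_modifier")) {
      stop_config("modifiers", "must be a list of planted_modifier objects")
    }
    if (m$variant_index > n_snps) {
      stop_config("modifiers", "variant_index exceeds n_snps")
    }
    if (!is.null(m$population) && !m$population %in% names(onset_intercepts)) {
      stop_config("modifiers", "population restriction not in onset_intercepts")
    }
  }
  if (!is.null(panel)) {
    need <- c("chrom", "pos", "id", "ref", "alt", "af")
    if (!is.data.frame(panel) || !all(need %in% names(panel))) {
      stop_config("panel", "must be a variants data.frame (chrom, pos, id, ref, alt, af)")
    }
    n_snps <- nrow(panel)
    n_chromosomes <- length(unique(panel$chrom))
  }
  if (!is.null(disease_locus_index)) {
    check_count(disease_locus_index, "disease_locus_index")
    if (disease_locus_index > n_snps) {
      stop_config("disease_locus_index", "exceeds n_snps")
    }
  }
  check_count(seed, "seed", min = 0)
  structure(list(
    n_subjects = as.integer(n_subjects), n_families = as.integer(n_families),
    family_weights = family_weights / sum(family_weights),
    n_snps = as.integer(n_snps), n_chromosomes = as.integer(n_chromosomes),
    allele_freq_range = allele_freq_range, freq_divergence = freq_divergence,
    recomb_rate = recomb_rate,
    disease_locus_index = disease_locus_index,
    cag_expanded_range = as.integer(cag_expanded_range),
    cag_normal_mean = cag_normal_mean,
    onset_intercepts = onset_intercepts,
    population_weights = population_weights / sum(population_weights),
    onset_slope = onset_slope, onset_noise_sd = onset_noise_sd,
    modifiers = modifiers, homozygote_rate = homozygote_rate,
    cag_instability_rate = cag_instability_rate,
    mean_children = mean_children, panel = panel,
    missing_rate = missing_rate, genotype_error_rate = genotype_error_rate,
    seed = as.integer(seed)), class = "sim_config")
}

#' Genotype matrix container
#'
#' A dosage-coded genotype panel: integer matrix of alternate-allele counts
#' (0/1/2, `NA` = missing) with subjects in rows and a variant metadata table.
#'
#' @param dosage Integer matrix, subjects x variants, with rownames.
#' @param variants data.frame with columns `chrom`, `pos`, `id`, `ref`, `alt`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, variants) {
  if (!is.matrix(dosage)) stop("dosage must be a matrix", call. = FALSE)
  if (nrow(variants) != ncol(dosage)) {
    stop("variants table must have one row per dosage column", call. = FALSE)
  }
  if (is.null(rownames(dosage))) {
    rownames(dosage) <- paste0("S", seq_len(nrow(dosage)))
  }
  colnames(dosage) <- variants$id
  structure(list(dosage = dosage, variants = variants),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d subjects x %d variants (%.2f%% missing)\n",
              nrow(x$dosage), ncol(x$dosage),
              100 * mean(is.na(x$dosage))))
  invisible(x)
}

#' Subset a genotype matrix by subject and/or variant
#'
#' @param g A [genotype_matrix()].
#' @param subjects Subject ids to keep (default all).
#' @param variants Variant indices or ids to keep (default all).
#' @return A `genotype_matrix`.
#' @export
subset_genotypes <- function(g, subjects = NULL, variants = NULL) {
  d <- g$dosage
  v <- g$variants
  if (!is.null(subjects)) {
    missing <- setdiff(subjects, rownames(d))
    if (length(missing) > 0) {
      stop(sprintf("unknown subject(s): %s", paste(utils::head(missing, 3),
                                                   collapse = ", ")),
           call. = FALSE)
    }
    d <- d[subjects, , drop = FALSE]
  }
  if (!is.null(variants)) {
    idx <- if (is.character(variants)) match(variants, v$id) else variants
    d <- d[, idx, drop = FALSE]
    v <- v[idx, , drop = FALSE]
  }
  genotype_matrix(d, v)
}

# One gamete from a pair of parental haplotype matrices (sites x 1 vectors).
# Crossovers are independent Bernoulli events between adjacent sites; the
# process restarts (fresh random start haplotype) at each chromosome boundary.
# `force_site`/`force_hap` condition the meiosis on transmitting haplotype 1
# or 2 at one site (ascertainment of affected children, who must receive the
# disease-carrying chromosome): if the sampled path picks the other haplotype
# there, the path labels on that chromosome are swapped, which leaves the
# crossover process unchanged by symmetry.
make_gamete <- function(hap1, hap2, chrom, recomb_rate,
                        force_site = NULL, force_hap = NULL) {
  m <- length(hap1)
  switches <- stats::rbinom(m, 1, recomb_rate)
  # chromosome starts: fresh coin flip, so overwrite the switch with a start
  new_chrom <- c(TRUE, chrom[-1] != chrom[-m])
  switches[new_chrom] <- stats::rbinom(sum(new_chrom), 1, 0.5)
  path <- cumsum(switches) %% 2
  if (!is.null(force_site) && path[force_site] != (force_hap - 1)) {
    on_chrom <- chrom == chrom[force_site]
    path[on_chrom] <- 1 - path[on_chrom]
  }
  ifelse(path == 0, hap1, hap2)
}

# Pedigree of one family: an affected founder marries in an unaffected
# founder spouse; their affected children are ascertained and reproduce in
# turn (breadth-first), each with a new unaffected founder spouse, until the
# target number of affected members is reached.
build_family_pedigree <- function(n_affected, mean_children) {
  father <- integer(0); mother <- integer(0)
  sex <- character(0); affected <- logical(0)
  new_person <- function(f, m, s, aff) {
    father <<- c(father, f); mother <<- c(mother, m)
    sex <<- c(sex, s); affected <<- c(affected, aff)
    length(sex)
  }
  p1 <- new_person(NA, NA, sample(c("M", "F"), 1), TRUE)
  queue <- p1
  n_aff <- 1L
  while (n_aff < n_affected) {
    a <- queue[1]; queue <- queue[-1]
    spouse_sex <- if (sex[a] == "M") "F" else "M"
    sp <- new_person(NA, NA, spouse_sex, FALSE)
    fa <- if (sex[a] == "M") a else sp
    mo <- if (sex[a] == "M") sp else a
    nc <- min(1 + stats::rpois(1, max(mean_children - 1, 0)),
              n_affected - n_aff)
    for (k in seq_len(nc)) {
      ch <- new_person(fa, mo, sample(c("M", "F"), 1), TRUE)
      queue <- c(queue, ch)
      n_aff <- n_aff + 1L
    }
  }
  data.frame(local_id = seq_along(sex), father = father, mother = mother,
             sex = sex, affected = affected)
}

# Integer family sizes from weights: largest-remainder rounding with a
# minimum of 1 affected subject per family.
allocate_family_sizes <- function(n, weights) {
  raw <- n * weights
  sizes <- pmax(floor(raw), 1)
  while (sum(sizes) > n) {
    i <- which.max(sizes)
    sizes[i] <- sizes[i] - 1
  }
  while (sum(sizes) < n) {
    i <- which.max(raw - sizes)
    sizes[i] <- sizes[i] + 1
  }
  as.integer(sizes)
}

#' Simulate a family-structured HD cohort
#'
#' Generates pedigree-consistent genotypes (founder haplotypes drawn from
#' population-labelled frequencies, gametes formed with per-site crossovers),
#' transmits an expanded CAG allele down the affected line with optional +/-1
#' instability, draws age at onset from
#' `exp(intercept_pop + slope * CAG_long + eps)` plus the summed planted
#' modifier effects in years, and records the full ground truth before any
#' error injection.
#'
#' @param config A [sim_config()].
#' @return A list with class `sim_cohort`:
#' \describe{
#'   \item{cohort}{data.frame: subject_id, family_id, population, sex,
#'     father_id, mother_id, affected, cag_long, cag_short, onset
#'     (NA for unaffected married-in founders).}
#'   \item{genotypes}{a [genotype_matrix()] over all subjects (affected and
#'     married-in founders), after error/missing injection if configured.}
#'   \item{truth}{ground truth: `haplotypes` (list of `paternal`/`maternal`
#'     0/1 matrices), `pedigree`, `injected_errors`, `injected_missing`,
#'     `residual_components` (years of planted modifier effect per affected
#'     subject), and the generative `onset_intercepts`/`onset_slope`.}
#' }
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("config must be built with sim_config()", call. = FALSE)
  }
  set.seed(config$seed)
  m <- config$n_snps
  pops <- names(config$onset_intercepts)

  # variant panel: fresh, or reused from a previous simulation
  if (!is.null(config$panel)) {
    chrom <- config$panel$chrom
    pos <- config$panel$pos
    ref <- config$panel$ref
    alt <- config$panel$alt
    af_base <- config$panel$af
  } else {
    chrom <- sort(rep_len(seq_len(config$n_chromosomes), m))
    pos <- unlist(lapply(split(seq_len(m), chrom), function(i) {
      seq_along(i) * 10000L
    }), use.names = FALSE)
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, m, replace = TRUE)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
    af_base <- stats::runif(m, config$allele_freq_range[1],
                            config$allele_freq_range[2])
  }
  for (mod in config$modifiers) af_base[mod$variant_index] <- mod$maf
  af_pop <- sapply(pops, function(p) {
    if (config$freq_divergence > 0) {
      pmin(pmax(af_base + stats::runif(m, -config$freq_divergence,
                                       config$freq_divergence), 0.01), 0.99)
    } else af_base
  })
  for (mod in config$modifiers) af_pop[mod$variant_index, ] <- mod$maf
  variants <- data.frame(chrom = chrom, pos = pos,
                         id = sprintf("snp%05d", seq_len(m)),
                         ref = ref, alt = alt, af = af_base,
                         stringsAsFactors = FALSE)

  disease_site <- config$disease_locus_index
  if (is.null(disease_site)) {
    chr1 <- which(chrom == chrom[1])
    disease_site <- chr1[ceiling(length(chr1) / 2)]
  }

  sizes <- allocate_family_sizes(config$n_subjects, config$family_weights)
  fam_pop <- sample(names(config$population_weights), config$n_families,
                    replace = TRUE, prob = config$population_weights)

  all_rows <- list()
  hap_pat <- list(); hap_mat <- list()
  carrier_all <- list()
  subj_counter <- 0L
  for (f in seq_len(config$n_families)) {
    ped <- build_family_pedigree(sizes[f], config$mean_children)
    n_loc <- nrow(ped)
    pop <- fam_pop[f]
    freqs <- af_pop[, pop]
    hp <- matrix(NA_integer_, n_loc, m)
    hm <- matrix(NA_integer_, n_loc, m)
    cag_exp <- rep(NA_integer_, n_loc)
    founders <- which(is.na(ped$father))
    for (i in founders) {
      hp[i, ] <- stats::rbinom(m, 1, freqs)
      hm[i, ] <- stats::rbinom(m, 1, freqs)
    }
    cag_exp[founders[1]] <- sample(
      seq(config$cag_expanded_range[1], config$cag_expanded_range[2]), 1)
    # which of a carrier's two chromosomes bears the expansion (1 = paternal
    # slot, 2 = maternal slot); the founder's is placed arbitrarily
    carrier <- rep(NA_integer_, n_loc)
    carrier[founders[1]] <- 1L
    for (i in setdiff(seq_len(n_loc), founders)) {
      fa <- ped$father[i]; mo <- ped$mother[i]
      aff_parent <- if (ped$affected[fa]) fa else mo
      # the affected child is ascertained to inherit the disease chromosome
      hp[i, ] <- make_gamete(hp[fa, ], hm[fa, ], chrom, config$recomb_rate,
                             force_site = if (aff_parent == fa) disease_site,
                             force_hap = if (aff_parent == fa) carrier[fa])
      hm[i, ] <- make_gamete(hp[mo, ], hm[mo, ], chrom, config$recomb_rate,
                             force_site = if (aff_parent == mo) disease_site,
                             force_hap = if (aff_parent == mo) carrier[mo])
      carrier[i] <- if (aff_parent == fa) 1L else 2L
      step <- 0L
      if (stats::rbinom(1, 1, config$cag_instability_rate) == 1) {
        step <- sample(c(-1L, 1L), 1)
      }
      cag_exp[i] <- min(max(cag_exp[aff_parent] + step,
                            config$cag_expanded_range[1]),
                        config$cag_expanded_range[2])
    }
    ids <- sprintf("F%02d_%03d", f, ped$local_id)
    all_rows[[f]] <- data.frame(
      subject_id = ids,
      family_id = sprintf("F%02d", f),
      population = pop,
      sex = ped$sex,
      father_id = ifelse(is.na(ped$father), NA, ids[ped$father]),
      mother_id = ifelse(is.na(ped$mother), NA, ids[ped$mother]),
      affected = ped$affected,
      cag_expanded = cag_exp,
      stringsAsFactors = FALSE)
    rownames(hp) <- ids; rownames(hm) <- ids
    hap_pat[[f]] <- hp; hap_mat[[f]] <- hm
    carrier_all[[f]] <- stats::setNames(carrier, ids)
    subj_counter <- subj_counter + n_loc
  }
  cohort <- do.call(rbind, all_rows)
  hp <- do.call(rbind, hap_pat)
  hm <- do.call(rbind, hap_mat)
  n <- nrow(cohort)

  # CAG alleles: affected subjects carry the transmitted expansion plus a
  # normal allele (occasionally a second expansion: HD homozygotes);
  # unaffected married-in founders carry two normal alleles.
  normal1 <- pmin(pmax(round(stats::rnorm(n, config$cag_normal_mean, 2.5)),
                       9L), 30L)
  second <- ifelse(cohort$affected, cohort$cag_expanded, normal1)
  homo <- cohort$affected &
    stats::rbinom(n, 1, config$homozygote_rate) == 1
  other <- normal1
  other[homo] <- sample(seq(config$cag_expanded_range[1],
                            config$cag_expanded_range[2]),
                        sum(homo), replace = TRUE)
  cohort$cag_long <- pmax(second, other)
  cohort$cag_short <- pmin(second, other)
  cohort$cag_expanded <- NULL

  # onset: log-linear in the longer CAG allele, plus modifier years
  dosage <- hp + hm
  modifier_years <- rep(0, n)
  for (mod in config$modifiers) {
    dos <- dosage[, mod$variant_index]
    applies <- if (is.null(mod$population)) rep(TRUE, n) else
      cohort$population == mod$population
    modifier_years <- modifier_years +
      ifelse(applies, dos * mod$effect_years_per_allele, 0)
  }
  log_mu <- config$onset_intercepts[cohort$population] +
    config$onset_slope * cohort$cag_long
  eps <- stats::rnorm(n, 0, config$onset_noise_sd)
  onset <- exp(log_mu + eps) + modifier_years
  onset <- pmax(onset, 0.5)
  onset[!cohort$affected] <- NA
  cohort$onset <- as.numeric(onset)

  rownames(hp) <- cohort$subject_id
  rownames(hm) <- cohort$subject_id
  dimnames(dosage) <- list(cohort$subject_id, variants$id)
  geno <- genotype_matrix(dosage, variants)

  truth <- list(
    haplotypes = list(paternal = hp, maternal = hm),
    pedigree = cohort[, c("subject_id", "family_id", "father_id",
                          "mother_id", "sex", "affected", "population")],
    injected_errors = data.frame(subject_id = character(0),
                                 variant_id = character(0)),
    injected_missing = data.frame(subject_id = character(0),
                                  variant_id = character(0)),
    residual_components = stats::setNames(
      ifelse(cohort$affected, modifier_years, NA), cohort$subject_id),
    disease_locus_index = disease_site,
    carrier_haplotype = unlist(carrier_all),
    onset_intercepts = config$onset_intercepts,
    onset_slope = config$onset_slope)

  if (config$missing_rate > 0 || config$genotype_error_rate > 0) {
    inj <- inject_errors(geno, config$missing_rate,
                         config$genotype_error_rate,
                         seed = config$seed + 1L)
    geno <- inj$genotypes
    truth$injected_errors <- inj$injected_errors
    truth$injected_missing <- inj$injected_missing
  }

  structure(list(cohort = cohort, genotypes = geno, truth = truth),
            class = "sim_cohort")
}

#' Inject genotype missingness and errors
#'
#' Perturbs a genotype matrix after the ground truth has been recorded: each
#' non-missing call is independently blanked with probability `missing_rate`,
#' and otherwise replaced by a different dosage value with probability
#' `error_rate`. Every altered cell is logged; the error and missing logs are
#' disjoint by construction.
#'
#' @param genotypes A [genotype_matrix()].
#' @param missing_rate,error_rate Fractions in `[0, 1]`.
#' @param seed Integer seed.
#' @return list(genotypes, injected_missing, injected_errors), the logs as
#'   data.frames with columns subject_id, variant_id.
#' @export
inject_errors <- function(genotypes, missing_rate, error_rate, seed = 1L) {
  check_fraction(missing_rate, "missing_rate")
  check_fraction(error_rate, "error_rate")
  set.seed(seed)
  d <- genotypes$dosage
  callable <- which(!is.na(d))
  u <- stats::runif(length(callable))
  to_miss <- callable[u < missing_rate]
  rest <- callable[u >= missing_rate]
  to_err <- rest[stats::runif(length(rest)) < error_rate]
  cell_log <- function(cells) {
    data.frame(
      subject_id = rownames(d)[(cells - 1) %% nrow(d) + 1],
      variant_id = colnames(d)[(cells - 1) %/% nrow(d) + 1],
      stringsAsFactors = FALSE)
  }
  if (length(to_err) > 0) {
    # replace with a uniformly chosen different dosage
    old <- d[to_err]
    shift <- sample(1:2, length(to_err), replace = TRUE)
    d[to_err] <- (old + shift) %% 3L
  }
  if (length(to_miss) > 0) d[to_miss] <- NA_integer_
  list(genotypes = genotype_matrix(d, genotypes$variants),
       injected_missing = cell_log(to_miss),
       injected_errors = cell_log(to_err))
}

#' Simulate genotype pairs of known relationship
#'
#' Direct generator of subject pairs for calibrating relatedness estimators:
#' unrelated pairs are independent draws from the founder frequencies,
#' parent-child pairs share exactly one transmitted gamete, and full siblings
#' share two parental meioses.
#'
#' @param n_pairs Number of pairs.
#' @param relationship One of "parent_child", "full_sib", "unrelated".
#' @param n_snps Number of SNPs.
#' @param allele_freq_range Founder frequency range.
#' @param recomb_rate Per-adjacent-site crossover probability.
#' @param seed Integer seed.
#' @return list(genotypes = [genotype_matrix()] of 2*n_pairs subjects,
#'   pairs = data.frame(id1, id2, relationship)).
#' @export
simulate_relative_pairs <- function(n_pairs, relationship = c("parent_child",
                                                              "full_sib",
                                                              "unrelated"),
                                    n_snps = 10000, allele_freq_range = c(0.1, 0.5),
                                    recomb_rate = 0.01, seed = 1L) {
  relationship <- match.arg(relationship)
  check_count(n_pairs, "n_pairs")
  set.seed(seed)
  m <- as.integer(n_snps)
  chrom <- rep(1L, m)
  f <- stats::runif(m, allele_freq_range[1], allele_freq_range[2])
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, m, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), character(1))
  variants <- data.frame(chrom = chrom, pos = seq_len(m) * 1000L,
                         id = sprintf("snp%05d", seq_len(m)),
                         ref = ref, alt = alt, af = f,
                         stringsAsFactors = FALSE)
  draw_hap <- function() stats::rbinom(m, 1, f)
  d <- matrix(NA_integer_, 2 * n_pairs, m)
  for (i in seq_len(n_pairs)) {
    p1 <- draw_hap(); p2 <- draw_hap()
    if (relationship == "unrelated") {
      g1 <- p1 + p2
      g2 <- draw_hap() + draw_hap()
    } else if (relationship == "parent_child") {
      g1 <- p1 + p2
      g2 <- make_gamete(p1, p2, chrom, recomb_rate) + draw_hap()
    } else {
      q1 <- draw_hap(); q2 <- draw_hap()
      g1 <- make_gamete(p1, p2, chrom, recomb_rate) +
        make_gamete(q1, q2, chrom, recomb_rate)
      g2 <- make_gamete(p1, p2, chrom, recomb_rate) +
        make_gamete(q1, q2, chrom, recomb_rate)
    }
    d[2 * i - 1, ] <- g1
    d[2 * i, ] <- g2
  }
  rownames(d) <- sprintf("P%04d_%d", rep(seq_len(n_pairs), each = 2), 1:2)
  list(genotypes = genotype_matrix(d, variants),
       pairs = data.frame(id1 = rownames(d)[seq(1, 2 * n_pairs, 2)],
                          id2 = rownames(d)[seq(2, 2 * n_pairs, 2)],
                          relationship = relationship,
                          stringsAsFactors = FALSE))
}
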