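# End-to-end orchestration: one validated configuration drives
# simulate -> phenotype -> relate -> phase -> gwas -> score -> pam, writing
# plain-text outputs and a checksummed manifest. All randomness flows from a
# single root seed split deterministically per stage.

pipeline_known_keys <- function() {
  list(
    top = c("seed", "out_dir", "stages", "simulate", "phenotype", "relate",
            "phase", "gwas", "score", "pam", "resume"),
    stages = c("simulate", "phenotype", "relate", "phase", "gwas", "score",
               "pam"),
    simulate = c("n_subjects", "n_families", "n_snps", "n_chromosomes",
                 "recomb_rate", "onset_noise_sd", "missing_rate",
                 "genotype_error_rate", "freq_divergence"),
    phenotype = character(0),
    relate = c("pi_hat_threshold", "n_components"),
    phase = c("max_trios"),
    gwas = c("maf_min"),
    score = c("p_threshold", "window_bp", "r2_max"),
    pam = c("hap_a_fasta", "hap_b_fasta", "features_bed"))
}

#' Validate a pipeline configuration
#'
#' Checks a configuration list (e.g. parsed from YAML) against the known keys
#' and fills in defaults. Unknown keys are rejected before any stage runs.
#'
#' @param config Named list, or the path to a YAML file.
#' @return The validated, default-filled configuration.
#' @export
validate_pipeline_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  known <- pipeline_known_keys()
  reject_unknown <- function(x, allowed, where) {
    extra <- setdiff(names(x), allowed)
    if (length(extra) > 0) {
      stop(sprintf("unknown configuration key(s) in %s: %s", where,
                   paste(extra, collapse = ", ")), call. = FALSE)
    }
  }
  reject_unknown(config, known$top, "top level")
  for (sec in intersect(names(config),
                        c("stages", "simulate", "phenotype", "relate",
                          "phase", "gwas", "score", "pam"))) {
    reject_unknown(config[[sec]], known[[sec]], sec)
  }
  defaults <- list(
    seed = 1L, out_dir = ".", resume = FALSE,
    stages = list(simulate = TRUE, phenotype = TRUE, relate = TRUE,
                  phase = TRUE, gwas = TRUE, score = FALSE, pam = FALSE),
    simulate = list(), relate = list(pi_hat_threshold = 0.125,
                                     n_components = 4),
    phase = list(max_trios = 7), gwas = list(maf_min = 0.05),
    score = list(p_threshold = 1e-5, window_bp = 1e6, r2_max = 0.2),
    pam = list())
  out <- utils::modifyList(defaults, config)
  out$stages <- utils::modifyList(defaults$stages,
                                  as.list(config$stages %||% list()))
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the analysis pipeline
#'
#' Executes the enabled stages in order on a simulated cohort, writing each
#' stage's outputs under `out_dir` and a `manifest.json` listing every file
#' with its MD5 checksum. The same configuration and seed produce identical
#' checksums. With `resume = TRUE`, stages whose outputs already exist are
#' skipped.
#'
#' @param config Configuration list or YAML path; see
#'   [validate_pipeline_config()].
#' @return list(status (0 on success), manifest (data.frame file/md5),
#'   out_dir), invisibly on success.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_pipeline_config(config)
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  produced <- character(0)
  # On resume, a stage with all outputs present is skipped; `reload` (when
  # given) restores the in-memory state downstream stages need from the files.
  t_stage <- function(name, outputs, fun, reload = NULL, skippable = TRUE) {
    paths <- file.path(cfg$out_dir, outputs)
    if (isTRUE(cfg$resume) && skippable && all(file.exists(paths))) {
      message(sprintf("[%s] outputs exist; skipped (resume)", name))
      if (!is.null(reload)) reload(paths)
      produced <<- c(produced, paths)
      return(invisible(NULL))
    }
    t0 <- proc.time()[["elapsed"]]
    fun(paths)
    message(sprintf("[%s] done in %.1fs", name,
                    proc.time()[["elapsed"]] - t0))
    produced <<- c(produced, paths)
  }

  sim <- NULL
  residuals <- NULL
  if (isTRUE(cfg$stages$simulate)) {
    t_stage("simulate", c("genotypes.vcf", "pedigree.fam", "phenotype.tsv",
                          "truth.json"), function(paths) {
      sc <- do.call(sim_config, c(cfg$simulate, list(seed = cfg$seed)))
      sim <<- simulate_cohort(sc)
      write_genotypes_vcf(sim$genotypes, paths[1])
      write_fam(sim$cohort, paths[2])
      write_phenotype_tsv(sim$cohort, paths[3])
      truth_small <- list(
        residual_components = as.list(sim$truth$residual_components[
          !is.na(sim$truth$residual_components)]),
        onset_intercepts = as.list(sim$truth$onset_intercepts),
        onset_slope = sim$truth$onset_slope,
        n_injected_errors = nrow(sim$truth$injected_errors),
        n_injected_missing = nrow(sim$truth$injected_missing))
      jsonlite::write_json(truth_small, paths[4], auto_unbox = TRUE,
                           digits = NA)
    }, skippable = FALSE)
  }
  if (is.null(sim)) {
    stop("pipeline currently requires the simulate stage to provide inputs",
         call. = FALSE)
  }
  affected <- sim$cohort$subject_id[sim$cohort$affected]
  geno_aff <- subset_genotypes(sim$genotypes, subjects = affected)

  if (isTRUE(cfg$stages$phenotype)) {
    t_stage("phenotype", "residuals.tsv", function(paths) {
      model <- fit_onset_model(sim$cohort)
      residuals <<- residual_onset(sim$cohort, model)
      utils::write.table(residuals, paths[1], sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }, reload = function(paths) {
      residuals <<- utils::read.table(paths[1], sep = "\t", header = TRUE,
                                      stringsAsFactors = FALSE)
    })
  }
  kin <- NULL
  mds <- NULL
  if (isTRUE(cfg$stages$relate)) {
    t_stage("relate", c("ibd.tsv", "families.tsv", "kinship.tsv", "mds.tsv"),
            function(paths) {
      ibd <- classify_relationship(estimate_ibd_all(geno_aff))
      utils::write.table(ibd, paths[1], sep = "\t", quote = FALSE,
                         row.names = FALSE)
      fams <- build_families(ibd, threshold = cfg$relate$pi_hat_threshold)
      memb <- data.frame(subject_id = names(fams$membership),
                         family_id = unname(fams$membership))
      utils::write.table(memb, paths[2], sep = "\t", quote = FALSE,
                         row.names = FALSE)
      kin <<- compute_kinship(geno_aff)
      utils::write.table(round(kin, 8), paths[3], sep = "\t", quote = FALSE)
      mds <<- compute_ancestry_components(geno_aff,
                                          k = cfg$relate$n_components)
      utils::write.table(round(mds, 8), paths[4], sep = "\t", quote = FALSE)
    }, reload = function(paths) {
      kin <<- as.matrix(utils::read.table(paths[3], sep = "\t",
                                          check.names = FALSE))
      mds <<- as.matrix(utils::read.table(paths[4], sep = "\t",
                                          check.names = FALSE))
    })
  }
  if (isTRUE(cfg$stages$phase)) {
    t_stage("phase", c("consensus.fa", "conflicts.bed", "dispositions.tsv"),
            function(paths) {
      trios <- pedigree_trios(sim$cohort)
      # trios of the largest sibship, phasing the HD parent's transmitted
      # chromosome: every affected child carries the same disease haplotype
      aff <- stats::setNames(sim$cohort$affected, sim$cohort$subject_id)
      couple <- paste(trios$father_id, trios$mother_id)
      top <- names(sort(table(couple), decreasing = TRUE))[1]
      trios <- trios[couple == top, , drop = FALSE]
      trios <- utils::head(trios, cfg$phase$max_trios)
      parent <- if (aff[trios$father_id[1]]) "father" else "mother"
      phased <- lapply(seq_len(nrow(trios)), function(i) {
        phase_trio(trio_from_simulation(sim, trios$father_id[i],
                                        trios$mother_id[i],
                                        trios$child_id[i]), parent)
      })
      cons <- merge_consensus(phased)
      write_consensus_fasta(cons, sim$genotypes$variants$pos - 1L,
                            paths[1], paths[2])
      disp <- do.call(rbind, lapply(seq_along(phased), function(i) {
        cbind(trio = i, phased[[i]][, c("site", "status")])
      }))
      utils::write.table(disp, paths[3], sep = "\t", quote = FALSE,
                         row.names = FALSE)
    })
  }
  gwas_res <- NULL
  if (isTRUE(cfg$stages$gwas)) {
    t_stage("gwas", c("assoc.tsv", "lambda.txt"), function(paths) {
      covar <- pipeline_covariates(sim$cohort, mds, affected)
      gwas_res <<- run_lmm_gwas(geno_aff, residuals, covariates = covar,
                                kinship = kin, maf_min = cfg$gwas$maf_min)
      utils::write.table(gwas_res, paths[1], sep = "\t", quote = FALSE,
                         row.names = FALSE)
      writeLines(sprintf("lambda_median\t%.6f",
                         genomic_inflation(gwas_res$p)), paths[2])
    }, reload = function(paths) {
      gwas_res <<- utils::read.table(paths[1], sep = "\t", header = TRUE,
                                     stringsAsFactors = FALSE)
    })
  }
  if (isTRUE(cfg$stages$score)) {
    t_stage("score", c("score_model.tsv", "scores.tsv", "score_eval.json"),
            function(paths) {
      model <- build_modifier_score(gwas_res,
                                    p_threshold = cfg$score$p_threshold,
                                    window_bp = cfg$score$window_bp,
                                    r2_max = cfg$score$r2_max,
                                    genotypes = geno_aff)
      utils::write.table(model, paths[1], sep = "\t", quote = FALSE,
                         row.names = FALSE)
      scores <- apply_modifier_score(model, geno_aff)
      utils::write.table(data.frame(subject_id = names(scores),
                                    score = unname(scores)),
                         paths[2], sep = "\t", quote = FALSE,
                         row.names = FALSE)
      covar <- pipeline_covariates(sim$cohort, mds, affected)
      ev <- evaluate_score(scores, residuals, covariates = covar)
      jsonlite::write_json(ev, paths[3], auto_unbox = TRUE, digits = NA)
    })
  }
  if (isTRUE(cfg$stages$pam)) {
    t_stage("pam", c("pam_sites.tsv", "excision_pairs.tsv"), function(paths) {
      if (is.null(cfg$pam$hap_a_fasta) || is.null(cfg$pam$hap_b_fasta)) {
        stop("pam stage requires hap_a_fasta and hap_b_fasta", call. = FALSE)
      }
      hap_a <- read_fasta(cfg$pam$hap_a_fasta)[1]
      hap_b <- read_fasta(cfg$pam$hap_b_fasta)[1]
      sites <- find_pam_altering_sites(hap_a, hap_b)
      utils::write.table(sites, paths[1], sep = "\t", quote = FALSE,
                         row.names = FALSE)
      pairs <- if (!is.null(cfg$pam$features_bed)) {
        bed <- utils::read.table(cfg$pam$features_bed, sep = "\t")
        propose_excision_pairs(sites, data.frame(start = bed[[2]],
                                                 end = bed[[3]]))
      } else {
        propose_excision_pairs(sites, data.frame(start = integer(0),
                                                 end = integer(0)))
      }
      utils::write.table(pairs, paths[2], sep = "\t", quote = FALSE,
                         row.names = FALSE)
    })
  }
  manifest <- data.frame(file = basename(produced),
                         md5 = unname(tools::md5sum(produced)),
                         stringsAsFactors = FALSE)
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       digits = NA)
  invisible(list(status = 0L, manifest = manifest, out_dir = cfg$out_dir))
}

# covariate matrix (sex + ancestry components) for the pipeline's GWA stage
pipeline_covariates <- function(cohort, mds, subjects) {
  sex <- stats::setNames(as.numeric(cohort$sex == "M"), cohort$subject_id)
  covar <- cbind(sex = sex[subjects])
  rownames(covar) <- subjects
  if (!is.null(mds) && ncol(mds) > 0) {
    covar <- cbind(covar, mds[subjects, , drop = FALSE])
  }
  covar
}

#' Enumerate parent-parent-child trios from a pedigree
#'
#' @param cohort Cohort (or FAM) data.frame with subject_id, father_id,
#'   mother_id.
#' @return data.frame: father_id, mother_id, child_id, one row per child with
#'   both parents present in the table.
#' @export
pedigree_trios <- function(cohort) {
  has_parents <- !is.na(cohort$father_id) & !is.na(cohort$mother_id) &
    cohort$father_id %in% cohort$subject_id &
    cohort$mother_id %in% cohort$subject_id
  d <- cohort[has_parents, , drop = FALSE]
  data.frame(father_id = d$father_id, mother_id = d$mother_id,
             child_id = d$subject_id, stringsAsFactors = FALSE)
}
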