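# Trio phasing QC: Mendelian-error screening patterns, site exclusions,
# forced-transmission deduction, consensus merging, tag-SNP naming, and the
# codon run-length encoding.

test_that("Mendelian screening flags inconsistent sites within the screenable patterns", {
  # complete trio: hom x hom parents cannot produce a het child carrying G
  trio <- make_trio(c("A/A", "A/G", "A/A"),
                    c("A/A", "A/G", "A/A"),
                    c("A/G", "A/A", "A/A"))
  expect_equal(detect_mendelian_errors(trio), 1L)
  # child complete, missingness confined to one parent (both alleles missing):
  # the complete parent A/A cannot have transmitted either child G allele
  trio2 <- make_trio("A/A", "./.", "G/G")
  expect_equal(detect_mendelian_errors(trio2), 1L)
  # one child allele missing, parents complete and both hom A: child G impossible
  trio3 <- make_trio("A/A", "A/A", "G/.")
  expect_equal(detect_mendelian_errors(trio3), 1L)
})

test_that("errors masked by missingness outside the screenable patterns are not flagged", {
  # missingness in both parents: wildcards always admit an assignment
  trio <- make_trio("A/.", "A/.", "G/G")
  expect_length(detect_mendelian_errors(trio), 0)
  # missing child allele together with a partially missing parent
  trio2 <- make_trio("A/A", "A/.", "G/.")
  expect_length(detect_mendelian_errors(trio2), 0)
})

test_that("screening never fires on clean simulated trios and always catches complete-pattern flips", {
  sim <- simulate_cohort(sim_config(n_subjects = 24, n_families = 2,
                                    n_snps = 300, mean_children = 5,
                                    seed = 41))
  trios <- pedigree_trios(sim$cohort)
  trio <- trio_from_simulation(sim, trios$father_id[1], trios$mother_id[1],
                               trios$child_id[1])
  expect_length(detect_mendelian_errors(trio), 0)
  # flip child genotypes to the opposite homozygote at complete sites where
  # both parents are homozygous for the other allele: always inconsistent
  complete <- which(!apply(is.na(cbind(trio$father, trio$mother,
                                       trio$child)), 1, any))
  hom_ref <- complete[trio$father[complete, 1] == trio$father[complete, 2] &
                        trio$mother[complete, 1] == trio$mother[complete, 2] &
                        trio$father[complete, 1] == trio$mother[complete, 1]]
  target <- hom_ref[1:10]
  bad <- trio
  for (i in target) {
    other <- setdiff(c(trio$sites$ref[i], trio$sites$alt[i]),
                     trio$father[i, 1])
    bad$child[i, ] <- other
  }
  flagged <- detect_mendelian_errors(bad)
  expect_true(all(target %in% flagged))
  expect_setequal(flagged, target)
})

test_that("site exclusion applies the three rules in order", {
  trio <- make_trio(c("A/G", "./.", "A/A", "A/G"),
                    c("A/G", "./.", "A/A", "A/A"),
                    c("A/G", "./.", "A/G", "A/G"))
  disp <- preprocess_trio_sites(trio)
  expect_equal(disp$status,
               c("excluded_triple_het", "excluded_all_missing",
                 "excluded_mendelian_error", "usable"))
})

test_that("transmitted alleles are deduced exactly when forced", {
  # het father, hom mother: child het means father gave G
  trio <- make_trio("A/G", "A/A", "A/G")
  ph <- phase_trio(trio, "father")
  expect_equal(ph$allele, "G")
  expect_true(ph$phased)
  # child homozygote forces the father's allele even with the mother missing
  trio2 <- make_trio("A/G", "./.", "G/G")
  ph2 <- phase_trio(trio2, "father")
  expect_equal(ph2$allele, "G")
  # het everywhere is removed upstream as identically heterozygous
  trio3 <- make_trio("A/G", "A/G", "A/G")
  ph3 <- phase_trio(trio3, "father")
  expect_false(ph3$phased)
  expect_equal(ph3$status, "excluded_triple_het")
  # het father x het mother with hom child: transmitted allele forced
  trio4 <- make_trio("A/G", "A/G", "A/A")
  expect_equal(phase_trio(trio4, "father")$allele, "A")
  # hom father is always phaseable regardless of the others
  trio5 <- make_trio("G/G", "A/G", "A/G")
  expect_equal(phase_trio(trio5, "father")$allele, "G")
  # ambiguous: het father, het mother (different pair impossible at biallelic
  # site) -- het father with het child and het mother is triple het; het
  # father with missing child is unphaseable
  trio6 <- make_trio("A/G", "A/A", "./.")
  ph6 <- phase_trio(trio6, "father")
  expect_false(ph6$phased)
  expect_equal(ph6$status, "unphaseable")
})

test_that("consensus merging follows the two-call support rule", {
  calls <- function(...) c(...)
  cons <- merge_consensus(list(
    calls("G", "G", "G"),
    calls("G", NA, "T"),
    calls(NA, NA, "G"),
    calls(NA, NA, NA),
    calls(NA, NA, "G"),
    calls(NA, NA, NA),
    calls(NA, NA, NA)))
  # site 1: two agreeing calls -> G; site 2: one call -> N;
  # site 3: G,T,G,G conflict -> '?'
  expect_equal(cons$calls, c("G", "N", "?"))
  expect_equal(cons$n_support, c(2, 1, 4))
  expect_equal(cons$coverage, 1 / 3)
  expect_equal(cons$n_determined + cons$n_undetermined + cons$n_conflict,
               cons$n_sites)
  expect_error(merge_consensus(list(c("G", "G"), "G")), "alignment")
})

test_that("error-free trios phase to the truth and consensus covers all sites", {
  sim <- simulate_cohort(sim_config(n_subjects = 18, n_families = 1,
                                    n_snps = 400, n_chromosomes = 1,
                                    mean_children = 7, recomb_rate = 0,
                                    seed = 51))
  trios <- pedigree_trios(sim$cohort)
  aff <- setNames(sim$cohort$affected, sim$cohort$subject_id)
  couple <- paste(trios$father_id, trios$mother_id)
  top <- names(sort(table(couple), decreasing = TRUE))[1]
  trios <- trios[couple == top, ]
  parent <- if (aff[trios$father_id[1]]) "father" else "mother"
  slot <- if (parent == "father") "paternal" else "maternal"
  v <- sim$genotypes$variants
  phased <- lapply(seq_len(nrow(trios)), function(i) {
    ph <- phase_trio(trio_from_simulation(sim, trios$father_id[i],
                                          trios$mother_id[i],
                                          trios$child_id[i]), parent)
    truth <- ifelse(sim$truth$haplotypes[[slot]][trios$child_id[i], ] == 0,
                    v$ref, v$alt)
    expect_identical(ph$allele[ph$phased], truth[ph$phased])
    ph
  })
  cons <- merge_consensus(phased)
  truth <- ifelse(sim$truth$haplotypes[[slot]][trios$child_id[1], ] == 0,
                  v$ref, v$alt)
  det <- !(cons$calls %in% c("N", "?"))
  expect_identical(cons$calls[det], truth[det])
  expect_equal(cons$n_conflict, 0)
  # coverage is non-decreasing in the number of trios merged
  cov_k <- vapply(2:length(phased), function(k) {
    merge_consensus(phased[1:k])$coverage
  }, numeric(1))
  expect_true(all(diff(cov_k) >= 0))
})

test_that("tag-SNP haplotype naming and family assignment follow the dictionary and the modal rule", {
  dict <- c(AAGG = "hap.01", AGGG = "hap.03", GGGG = "hap.08")
  tags <- rbind(c("A", "G", "G", "G"),
                c("A", "A", "G", "G"),
                c("T", "T", "T", "T"))
  expect_equal(assign_tag_haplotypes(tags, dict),
               c("hap.03", "hap.01", "unknown"))
  fams <- family_disease_haplotype(
    c("F1", "F1", "F1", "F1", "F1", "F1", "F2", "F2"),
    c("hap.03", "hap.03", "hap.03", "hap.03", "hap.03", "hap.01",
      "hap.01", "hap.07"))
  f1 <- fams[fams$family_id == "F1", ]
  expect_equal(f1$haplotype, "hap.03")
  expect_equal(f1$count, 5)
  expect_false(f1$tie)
  f2 <- fams[fams$family_id == "F2", ]
  expect_true(f2$tie)
  expect_equal(f2$haplotype, "hap.01")
})

test_that("codon run-length encoding matches the repeat-region structure and round-trips", {
  enc <- encode_repeat_structure("CAGCAGCAGCAACAG")
  expect_equal(enc$codon, c("CAG", "CAA", "CAG"))
  expect_equal(enc$length, c(3, 1, 1))
  # the canonical expanded-repeat structure:
  # (CAG)45 CAA CAG CCG CCA (CCG)7 (CCT)2
  seq <- paste0(strrep("CAG", 45), "CAA", "CAG", "CCG", "CCA",
                strrep("CCG", 7), strrep("CCT", 2))
  enc2 <- encode_repeat_structure(seq)
  expect_equal(enc2$codon, c("CAG", "CAA", "CAG", "CCG", "CCA", "CCG",
                             "CCT"))
  expect_equal(enc2$length, c(45, 1, 1, 1, 1, 7, 2))
  expect_identical(decode_repeat_structure(enc2), seq)
  empty <- encode_repeat_structure("")
  expect_equal(nrow(empty), 0)
  expect_error(encode_repeat_structure("CAGC"), "divisible")
})
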