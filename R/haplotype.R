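# Trio phasing, Mendelian-error screening and consensus reconstruction of the
# disease haplotype; tag-SNP haplotype naming; codon run-length encoding of
# the repeat region.
#
# Each father-mother-child trio is processed independently. Sites are excluded
# when (1) all three genotypes are missing, (2) all three members are
# identically heterozygous, or (3) a Mendelian error is detected. Mendelian
# errors are only called under three data-completeness patterns (complete
# trio; complete child with missingness confined to one parent; one child
# allele missing with complete parents) -- errors at other patterns can be
# missed, by design. At remaining sites the allele transmitted by a designated
# parent is deduced whenever the three genotypes logically force it. Multiple
# independently phased copies of the same transmitted haplotype are merged per
# site: >=2 agreeing calls give the consensus allele, conflicting calls give
# '?', fewer than 2 calls give 'N'.

#' Trio genotype container
#'
#' @param father,mother,child Character matrices (sites x 2) of unordered
#'   alleles; `NA` marks a missing allele.
#' @param sites data.frame with at least columns `pos`, `ref`, `alt` (the
#'   allele universe per site).
#' @return Object of class `trio_genotypes`.
#' @export
trio_genotypes <- function(father, mother, child, sites) {
  dims <- vapply(list(father, mother, child), nrow, 1L)
  if (length(unique(dims)) != 1 || dims[1] != nrow(sites)) {
    stop("father, mother, child and sites must cover the same site list",
         call. = FALSE)
  }
  structure(list(father = father, mother = mother, child = child,
                 sites = sites), class = "trio_genotypes")
}

# site allele universe: observed alleles plus ref/alt metadata
site_alleles <- function(trio, i) {
  obs <- c(trio$father[i, ], trio$mother[i, ], trio$child[i, ],
           trio$sites$ref[i], trio$sites$alt[i])
  unique(obs[!is.na(obs)])
}

# Enumerate transmissions (p = allele from parent P, o = allele from the other
# parent) consistent with the three genotypes; missing alleles act as
# wildcards over the site's allele universe.
consistent_transmissions <- function(p_alleles, o_alleles, child, universe) {
  expand <- function(a) {
    if (all(is.na(a))) return(list(universe, universe))
    lapply(seq_along(a), function(j) if (is.na(a[j])) universe else a[j])
  }
  pa <- expand(p_alleles)
  oa <- expand(o_alleles)
  p_opts <- unique(unlist(pa))
  o_opts <- unique(unlist(oa))
  child_ok <- function(p, o) {
    c1 <- child[1]; c2 <- child[2]
    match1 <- (is.na(c1) || c1 == p) && (is.na(c2) || c2 == o)
    match2 <- (is.na(c1) || c1 == o) && (is.na(c2) || c2 == p)
    match1 || match2
  }
  out <- list()
  for (p in p_opts) {
    for (o in o_opts) {
      if (child_ok(p, o)) out[[length(out) + 1]] <- c(p = p, o = o)
    }
  }
  out
}

# completeness pattern of a trio genotype at one site:
# "complete", "parent_partial" (child complete, missingness in exactly one
# parent), "child_one_missing" (one child allele missing, parents complete),
# or "other"
completeness_pattern <- function(fa, mo, ch) {
  n_fa <- sum(is.na(fa)); n_mo <- sum(is.na(mo)); n_ch <- sum(is.na(ch))
  if (n_fa + n_mo + n_ch == 0) return("complete")
  if (n_ch == 0 && xor(n_fa > 0, n_mo > 0)) return("parent_partial")
  if (n_ch == 1 && n_fa == 0 && n_mo == 0) return("child_one_missing")
  "other"
}

#' Detect Mendelian errors in a trio
#'
#' A site is flagged only when its data-completeness pattern is one of the
#' three screenable patterns (no missing data; complete child with missing
#' alleles confined to one parent; one missing child allele with complete
#' parents) AND no assignment of transmitted alleles is consistent with
#' Mendelian inheritance. Errors at other missingness patterns are never
#' flagged (they can evade this screen).
#'
#' @param trio A [trio_genotypes()].
#' @return Integer vector of flagged site indices.
#' @export
detect_mendelian_errors <- function(trio) {
  n <- nrow(trio$sites)
  flagged <- logical(n)
  for (i in seq_len(n)) {
    fa <- trio$father[i, ]; mo <- trio$mother[i, ]; ch <- trio$child[i, ]
    pat <- completeness_pattern(fa, mo, ch)
    if (pat == "other") next
    if (all(is.na(c(fa, mo, ch)))) next
    uni <- site_alleles(trio, i)
    cons <- consistent_transmissions(fa, mo, ch, uni)
    flagged[i] <- length(cons) == 0
  }
  which(flagged)
}

#' Pre-process trio sites by the three exclusion rules
#'
#' Applies, in order: exclusion of sites with all three genotypes missing,
#' of sites where all three members are identically heterozygous, and of
#' Mendelian-error sites; the remainder are usable for phasing.
#'
#' @param trio A [trio_genotypes()].
#' @return data.frame: site (index), status in {usable, excluded_all_missing,
#'   excluded_triple_het, excluded_mendelian_error}.
#' @export
preprocess_trio_sites <- function(trio) {
  n <- nrow(trio$sites)
  status <- rep("usable", n)
  all_missing <- apply(is.na(trio$father), 1, all) &
    apply(is.na(trio$mother), 1, all) &
    apply(is.na(trio$child), 1, all)
  status[all_missing] <- "excluded_all_missing"
  is_het <- function(g) !is.na(g[, 1]) & !is.na(g[, 2]) & g[, 1] != g[, 2]
  same_pair <- function(a, b) {
    (a[, 1] == b[, 1] & a[, 2] == b[, 2]) |
      (a[, 1] == b[, 2] & a[, 2] == b[, 1])
  }
  triple_het <- is_het(trio$father) & is_het(trio$mother) &
    is_het(trio$child) &
    same_pair(trio$father, trio$mother) & same_pair(trio$father, trio$child)
  triple_het[is.na(triple_het)] <- FALSE
  status[status == "usable" & triple_het] <- "excluded_triple_het"
  mend <- detect_mendelian_errors(trio)
  status[intersect(mend, which(status == "usable"))] <-
    "excluded_mendelian_error"
  data.frame(site = seq_len(n), status = status, stringsAsFactors = FALSE)
}

#' Phase the transmitted haplotype of one parent from a trio
#'
#' At every usable site (after [preprocess_trio_sites()]), the allele the
#' designated parent transmitted to the child is deduced when it is logically
#' forced by the three genotypes; partially missing sites are phased only when
#' the available data still force a unique transmitted allele. Excluded and
#' ambiguous sites are reported as unphased.
#'
#' @param trio A [trio_genotypes()].
#' @param parent `"father"` (default) or `"mother"`: whose transmitted
#'   haplotype to reconstruct.
#' @return data.frame: site, allele (NA if unphased), phased (logical),
#'   status (disposition or "unphaseable").
#' @export
phase_trio <- function(trio, parent = c("father", "mother")) {
  parent <- match.arg(parent)
  disp <- preprocess_trio_sites(trio)
  n <- nrow(trio$sites)
  allele <- rep(NA_character_, n)
  status <- disp$status
  P <- trio[[parent]]
  O <- trio[[if (parent == "father") "mother" else "father"]]
  for (i in which(disp$status == "usable")) {
    uni <- site_alleles(trio, i)
    cons <- consistent_transmissions(P[i, ], O[i, ], trio$child[i, ], uni)
    p_vals <- unique(vapply(cons, `[[`, character(1), "p"))
    if (length(p_vals) == 1) {
      allele[i] <- p_vals
    } else {
      status[i] <- "unphaseable"
    }
  }
  data.frame(site = seq_len(n), allele = allele,
             phased = !is.na(allele), status = status,
             stringsAsFactors = FALSE)
}

#' Merge independently phased haplotypes into a consensus
#'
#' Per site: at least two phased calls that all agree give the consensus
#' allele; two or more calls with any disagreement give `'?'`; fewer than two
#' phased calls give `'N'`. Coverage is the fraction of sites with a
#' determined allele.
#'
#' @param phased List of phased haplotypes (data.frames from [phase_trio()] or
#'   character vectors of alleles with NA for unphased), all site-aligned.
#' @return Object of class `consensus_haplotype`: list(calls (character
#'   vector with alleles, "N", "?"), n_support (phased calls per site),
#'   coverage, n_sites, n_determined, n_undetermined, n_conflict).
#' @export
merge_consensus <- function(phased) {
  calls <- lapply(phased, function(h) {
    if (is.data.frame(h)) h$allele else as.character(h)
  })
  lens <- vapply(calls, length, 1L)
  if (length(unique(lens)) != 1) {
    stop("alignment error: phased haplotypes differ in site count",
         call. = FALSE)
  }
  mat <- do.call(cbind, calls)
  n <- nrow(mat)
  n_support <- rowSums(!is.na(mat))
  consensus <- rep("N", n)
  for (i in which(n_support >= 2)) {
    a <- unique(mat[i, !is.na(mat[i, ])])
    consensus[i] <- if (length(a) == 1) a else "?"
  }
  determined <- !(consensus %in% c("N", "?"))
  structure(list(calls = consensus, n_support = n_support,
                 coverage = sum(determined) / n,
                 n_sites = n, n_determined = sum(determined),
                 n_undetermined = sum(consensus == "N"),
                 n_conflict = sum(consensus == "?")),
            class = "consensus_haplotype")
}

#' @export
print.consensus_haplotype <- function(x, ...) {
  cat(sprintf(
    "consensus haplotype: %d sites, %.2f%% determined (%d N, %d '?')\n",
    x$n_sites, 100 * x$coverage, x$n_undetermined, x$n_conflict))
  invisible(x)
}

#' Name haplotypes from tag-SNP allele vectors
#'
#' Looks phased tag-SNP allele vectors up in a dictionary mapping collapsed
#' allele strings to haplotype names (e.g. "hap.01".."hap.16"); vectors absent
#' from the dictionary are named "unknown".
#'
#' @param tag_alleles Character matrix, chromosomes x tag SNPs.
#' @param dictionary Named character vector: names are collapsed allele
#'   strings (`paste0` of the tag alleles), values are haplotype names.
#' @return Character vector of haplotype names, one per chromosome (row).
#' @export
assign_tag_haplotypes <- function(tag_alleles, dictionary) {
  keys <- apply(tag_alleles, 1, paste0, collapse = "")
  out <- unname(dictionary[keys])
  out[is.na(out)] <- "unknown"
  out
}

#' Assign the disease haplotype of each family
#'
#' All HD subjects in a family share the ancestral disease chromosome, so the
#' most frequent haplotype name within the family is taken as the family's
#' disease haplotype. Ties are broken by the lexically smallest name (lowest
#' hap number) and flagged.
#'
#' @param family_ids Character vector of family ids, one per chromosome.
#' @param hap_names Haplotype names aligned with `family_ids`.
#' @return data.frame: family_id, haplotype, count, tie (logical).
#' @export
family_disease_haplotype <- function(family_ids, hap_names) {
  out <- lapply(split(hap_names, family_ids), function(h) {
    tab <- sort(table(h), decreasing = TRUE)
    top <- names(tab)[tab == max(tab)]
    data.frame(haplotype = sort(top)[1], count = max(tab),
               tie = length(top) > 1, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  res$family_id <- names(out)
  rownames(res) <- NULL
  res[, c("family_id", "haplotype", "count", "tie")]
}

#' Run-length encode a sequence as codons
#'
#' Splits an in-frame nucleotide string into codons and reports maximal runs
#' of identical codons in order -- the representation used for the CAG/CCG
#' repeat-region structure (e.g. 45xCAG, 1xCAA, 1xCAG, 1xCCG, 1xCCA, 7xCCG,
#' 2xCCT).
#'
#' @param sequence Nucleotide string with length divisible by 3.
#' @return data.frame: codon, length (empty for the empty string).
#' @export
encode_repeat_structure <- function(sequence) {
  if (nchar(sequence) %% 3 != 0) {
    stop("sequence length must be divisible by 3", call. = FALSE)
  }
  if (nchar(sequence) == 0) {
    return(data.frame(codon = character(0), length = integer(0)))
  }
  codons <- substring(sequence, seq(1, nchar(sequence), 3),
                      seq(3, nchar(sequence), 3))
  r <- rle(codons)
  data.frame(codon = r$values, length = r$lengths, stringsAsFactors = FALSE)
}

#' Decode a codon run-length encoding back to a sequence
#'
#' Inverse of [encode_repeat_structure()].
#'
#' @param encoding data.frame with columns `codon`, `length`.
#' @return Nucleotide string.
#' @export
decode_repeat_structure <- function(encoding) {
  paste0(rep(encoding$codon, encoding$length), collapse = "")
}

#' Extract a trio's genotypes from a simulated cohort
#'
#' Convenience bridge from [simulate_cohort()] output to [trio_genotypes()]:
#' converts 0/1 haplotype codes to ref/alt bases and honours injected missing
#' calls (a missing dosage blanks both alleles of that genotype).
#'
#' @param sim A `sim_cohort` from [simulate_cohort()].
#' @param father_id,mother_id,child_id Subject ids.
#' @param variants Optional variant index subset.
#' @return A [trio_genotypes()].
#' @export
trio_from_simulation <- function(sim, father_id, mother_id, child_id,
                                 variants = NULL) {
  v <- sim$genotypes$variants
  idx <- if (is.null(variants)) seq_len(nrow(v)) else variants
  code_to_base <- function(h, i) ifelse(h == 0, v$ref[i], v$alt[i])
  member <- function(id) {
    dos <- sim$genotypes$dosage[id, idx]
    hp <- sim$truth$haplotypes$paternal[id, idx]
    hm <- sim$truth$haplotypes$maternal[id, idx]
    a <- cbind(code_to_base(hp, idx), code_to_base(hm, idx))
    # injected errors changed the dosage; represent the erroneous genotype
    obs <- dos
    err <- !is.na(obs) & obs != (hp + hm)
    if (any(err)) {
      for (j in which(err)) {
        alleles <- c(rep(v$ref[idx[j]], 2 - obs[j]), rep(v$alt[idx[j]], obs[j]))
        a[j, ] <- alleles
      }
    }
    a[is.na(obs), ] <- NA_character_
    a
  }
  trio_genotypes(member(father_id), member(mother_id), member(child_id),
                 sites = v[idx, c("pos", "ref", "alt")])
}
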