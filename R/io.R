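# Plain-text interchange: VCF, FAM, phenotype/residual TSV, consensus FASTA
# with a '?'-mask BED.

#' Write genotypes to a VCF file
#'
#' Minimal VCFv4.2 with a GT field; missing genotypes are written `./.`.
#' Dosages are written as unphased genotypes (0 -> 0/0, 1 -> 0/1, 2 -> 1/1).
#'
#' @param genotypes A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(genotypes, path) {
  v <- genotypes$variants
  d <- genotypes$dosage
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gt <- matrix("./.", nrow(d), ncol(d))
  ok <- !is.na(d)
  gt[ok] <- gt_code[as.character(d[ok])]
  lines <- c(
    "##fileformat=VCFv4.2",
    "##source=onsetmod",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(d)), collapse = "\t"),
    paste(v$chrom, v$pos, v$id, v$ref, v$alt, ".", "PASS", ".", "GT",
          apply(gt, 2, paste, collapse = "\t"), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read genotypes from a VCF file
#'
#' Parses biallelic SNV records via the `vcfR` package into a
#' [genotype_matrix()] (alternate-allele dosage; `./.` becomes `NA`).
#'
#' @param path VCF path (plain or gzipped).
#' @return A [genotype_matrix()].
#' @export
read_genotypes_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("reading VCF requires the vcfR package", call. = FALSE)
  }
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  fix <- vcfR::getFIX(vcf)
  allele1 <- substr(gt, 1, 1)
  allele2 <- substr(gt, 3, 3)
  dos <- suppressWarnings(as.integer(allele1) + as.integer(allele2))
  d <- matrix(dos, nrow = nrow(gt), ncol = ncol(gt),
              dimnames = dimnames(gt))
  variants <- data.frame(chrom = fix[, "CHROM"],
                         pos = as.integer(fix[, "POS"]),
                         id = fix[, "ID"],
                         ref = fix[, "REF"], alt = fix[, "ALT"],
                         af = colMeans(t(d), na.rm = TRUE) / 2,
                         stringsAsFactors = FALSE)
  genotype_matrix(t(d), variants)
}

#' Write pedigree metadata as a FAM-style TSV
#'
#' Columns: family id, subject id, father, mother, sex (1 = male, 2 = female),
#' phenotype (2 = affected, 1 = unaffected); unknown parents are `0`.
#'
#' @param cohort Cohort data.frame from [simulate_cohort()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fam <- function(cohort, path) {
  fam <- data.frame(
    family_id = cohort$family_id,
    subject_id = cohort$subject_id,
    father_id = ifelse(is.na(cohort$father_id), "0", cohort$father_id),
    mother_id = ifelse(is.na(cohort$mother_id), "0", cohort$mother_id),
    sex = ifelse(cohort$sex == "M", 1L, 2L),
    phenotype = ifelse(cohort$affected, 2L, 1L))
  utils::write.table(fam, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a FAM-style TSV
#'
#' @param path Path written by [write_fam()] (or PLINK-style .fam).
#' @return data.frame: family_id, subject_id, father_id, mother_id
#'   (NA if unknown), sex ("M"/"F"), affected (logical).
#' @export
read_fam <- function(path) {
  fam <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           col.names = c("family_id", "subject_id",
                                         "father_id", "mother_id",
                                         "sex", "phenotype"),
                           colClasses = c(rep("character", 4),
                                          "integer", "integer"))
  fam$father_id[fam$father_id == "0"] <- NA
  fam$mother_id[fam$mother_id == "0"] <- NA
  fam$sex <- ifelse(fam$sex == 1, "M", "F")
  fam$affected <- fam$phenotype == 2
  fam$phenotype <- NULL
  fam
}

#' Write / read the phenotype table
#'
#' TSV with columns subject_id, population, sex, cag_long, cag_short, onset.
#'
#' @param cohort Cohort data.frame.
#' @param path File path.
#' @return `path` (writer) / data.frame (reader).
#' @export
write_phenotype_tsv <- function(cohort, path) {
  cols <- c("subject_id", "population", "sex", "cag_long", "cag_short",
            "onset")
  utils::write.table(cohort[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotype_tsv
#' @export
read_phenotype_tsv <- function(path) {
  d <- utils::read.table(path, sep = "\t", header = TRUE,
                         stringsAsFactors = FALSE)
  d$affected <- !is.na(d$onset)
  d
}

#' Write a consensus haplotype as FASTA plus a '?'-mask BED
#'
#' Determined alleles are written as-is; both undetermined ('N') and
#' conflicting ('?') sites are written as 'N' in the FASTA (IUPAC), with the
#' conflicting sites additionally listed in a BED file so the two cases stay
#' distinguishable.
#'
#' @param consensus A `consensus_haplotype` from [merge_consensus()].
#' @param positions Genomic positions (0-based) of the sites, one per call.
#' @param fasta_path,bed_path Output paths.
#' @param name Sequence name for the FASTA header and BED.
#' @return list(fasta, bed), invisibly.
#' @export
write_consensus_fasta <- function(consensus, positions, fasta_path, bed_path,
                                  name = "consensus") {
  calls <- consensus$calls
  seq <- ifelse(calls %in% c("N", "?"), "N", calls)
  writeLines(c(paste0(">", name), paste0(seq, collapse = "")), fasta_path)
  conflict <- which(calls == "?")
  bed <- data.frame(chrom = rep(name, length(conflict)),
                    start = positions[conflict],
                    end = positions[conflict] + 1)
  utils::write.table(bed, bed_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(list(fasta = fasta_path, bed = bed_path))
}

#' Read a single-sequence FASTA file
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  lines <- readLines(path)
  headers <- grep("^>", lines)
  if (length(headers) == 0) stop("not a FASTA file", call. = FALSE)
  starts <- headers + 1
  ends <- c(headers[-1] - 1, length(lines))
  seqs <- vapply(seq_along(headers), function(i) {
    paste0(lines[starts[i]:ends[i]], collapse = "")
  }, character(1))
  names(seqs) <- sub("^>\\s*", "", lines[headers])
  seqs
}
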