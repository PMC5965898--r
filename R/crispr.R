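# Allele-specific CRISPR PAM discovery: SNPs that create an NGG PAM on one
# haplotype but not at the homologous position of the other enable
# haplotype-specific Cas9 cutting; two such sites flanking the transcription
# start site and early exons define candidate excision pairs that would
# inactivate only the mutant copy.

#' Build a haplotype sequence from a reference window and variants
#'
#' Substitutes alternate alleles into a reference window. SNVs replace the
#' reference base; deletions are written as '-' so the result stays
#' coordinate-aligned with the reference; undetermined calls (alt `"N"` or
#' `"?"`) are masked as 'N'. Insertions cannot be represented in the aligned
#' coordinate frame and are skipped with a warning.
#'
#' @param reference Reference nucleotide string for the window.
#' @param variants data.frame with columns `pos` (0-based offset into the
#'   window), `ref`, `alt`. Overlapping variants are an error.
#' @param offset Genomic coordinate of the window start (0-based), retained
#'   as an attribute.
#' @return Object of class `haplotype_sequence`: list(seq, offset).
#' @export
build_haplotype_sequence <- function(reference, variants = NULL, offset = 0) {
  s <- strsplit(toupper(reference), "")[[1]]
  if (!is.null(variants) && nrow(variants) > 0) {
    v <- variants[order(variants$pos), , drop = FALSE]
    spans <- cbind(v$pos, v$pos + nchar(v$ref) - 1)
    if (nrow(v) > 1 && any(spans[-1, 1] <= spans[-nrow(v), 2])) {
      bad <- which(spans[-1, 1] <= spans[-nrow(v), 2])
      stop(sprintf("overlapping variants at window offset(s): %s",
                   paste(v$pos[bad + 1], collapse = ", ")), call. = FALSE)
    }
    for (i in seq_len(nrow(v))) {
      p <- v$pos[i] + 1  # 1-based index into the window
      rl <- nchar(v$ref[i]); al <- nchar(v$alt[i])
      if (p + rl - 1 > length(s)) {
        stop(sprintf("variant at offset %d outside the window", v$pos[i]),
             call. = FALSE)
      }
      if (v$alt[i] %in% c("N", "?")) {
        s[p:(p + rl - 1)] <- "N"
      } else if (al == rl) {
        s[p:(p + rl - 1)] <- strsplit(toupper(v$alt[i]), "")[[1]]
      } else if (al < rl && substr(v$ref[i], 1, al) == toupper(v$alt[i])) {
        # deletion: keep the retained prefix, gap the rest
        s[(p + al):(p + rl - 1)] <- "-"
      } else {
        warning(sprintf(
          "insertion/complex variant at offset %d skipped (not representable in aligned coordinates)",
          v$pos[i]), call. = FALSE)
      }
    }
  }
  structure(list(seq = paste0(s, collapse = ""), offset = offset),
            class = "haplotype_sequence")
}

revcomp <- function(s) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# All NGG PAM positions of one strand of an aligned sequence.
# Plus strand: window [i, i+2] with s[i] in ACGT and s[i+1..i+2] == "GG".
# Minus strand PAM appears as CCN on the plus strand: s[i..i+1] == "CC",
# s[i+2] in ACGT.
pam_positions <- function(chars, strand) {
  m <- length(chars)
  if (m < 3) return(integer(0))
  ok_base <- chars %in% c("A", "C", "G", "T")
  if (strand == "+") {
    idx <- which(ok_base[seq_len(m - 2)] &
                   chars[2:(m - 1)] == "G" & chars[3:m] == "G")
  } else {
    idx <- which(chars[seq_len(m - 2)] == "C" &
                   chars[2:(m - 1)] == "C" & ok_base[3:m])
  }
  idx
}

#' Find PAM sites specific to one haplotype
#'
#' Scans two coordinate-aligned haplotype sequences for SpCas9 NGG PAM
#' trinucleotides on both strands and reports every site where the PAM is
#' present on haplotype A but absent at the homologous position of haplotype
#' B, together with the sequence difference responsible and the 20-nt
#' protospacer adjacent to the PAM. Windows containing 'N' or alignment gaps
#' ('-') are skipped. Sites are ordered by position, then strand.
#'
#' @param hap_a,hap_b [build_haplotype_sequence()] objects (or plain strings)
#'   of equal length and identical coordinate frame.
#' @param pam Currently only `"NGG"`.
#' @return data.frame: pam_start (genomic, 0-based), strand, pam_a, pam_b,
#'   variant_pos (genomic position of the first difference inside the PAM
#'   window), protospacer (NA when the window runs off the sequence).
#' @export
find_pam_altering_sites <- function(hap_a, hap_b, pam = "NGG") {
  if (pam != "NGG") stop("only the SpCas9 NGG PAM is supported", call. = FALSE)
  seq_a <- if (inherits(hap_a, "haplotype_sequence")) hap_a$seq else hap_a
  seq_b <- if (inherits(hap_b, "haplotype_sequence")) hap_b$seq else hap_b
  offset <- if (inherits(hap_a, "haplotype_sequence")) hap_a$offset else 0
  if (nchar(seq_a) != nchar(seq_b)) {
    stop("haplotype sequences must be coordinate-aligned (equal length)",
         call. = FALSE)
  }
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  m <- length(a)
  rows <- list()
  for (strand in c("+", "-")) {
    pa <- pam_positions(a, strand)
    pb <- pam_positions(b, strand)
    specific <- setdiff(pa, pb)
    for (i in specific) {
      win <- i:(i + 2)
      # a PAM window containing a gap or N on either haplotype is not callable
      if (any(b[win] %in% c("N", "-")) || any(a[win] %in% c("N", "-"))) next
      diffs <- win[a[win] != b[win]]
      if (length(diffs) == 0) next  # PAM difference must come from a variant
      proto <- NA_character_
      if (strand == "+") {
        if (i - 20 >= 1) proto <- paste0(a[(i - 20):(i - 1)], collapse = "")
      } else {
        if (i + 22 <= m) {
          proto <- revcomp(paste0(a[(i + 3):(i + 22)], collapse = ""))
        }
      }
      if (!is.na(proto) && grepl("[^ACGT]", proto)) proto <- NA_character_
      rows[[length(rows) + 1]] <- data.frame(
        pam_start = as.numeric(offset + i - 1), strand = strand,
        pam_a = paste0(a[win], collapse = ""),
        pam_b = paste0(b[win], collapse = ""),
        variant_pos = as.numeric(offset + diffs[1] - 1),
        protospacer = proto, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(pam_start = numeric(0), strand = character(0),
                      pam_a = character(0), pam_b = character(0),
                      variant_pos = numeric(0), protospacer = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$pam_start, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Propose excision pairs spanning annotated features
#'
#' Enumerates ordered pairs of haplotype-specific PAM sites whose spanned
#' interval contains every requested feature (e.g. the transcription start
#' site and first exons), ranked by spanned length ascending -- the shortest
#' allele-specific excision first.
#'
#' @param sites data.frame from [find_pam_altering_sites()].
#' @param features data.frame with columns `start`, `end` (0-based, half-open)
#'   and optionally `name`.
#' @return data.frame: left_pam, right_pam, left_strand, right_strand,
#'   span_start, span_end, span_length (possibly zero rows).
#' @export
propose_excision_pairs <- function(sites, features) {
  empty <- data.frame(left_pam = integer(0), right_pam = integer(0),
                      left_strand = character(0), right_strand = character(0),
                      span_start = integer(0), span_end = integer(0),
                      span_length = integer(0))
  if (nrow(sites) < 2 || nrow(features) == 0) return(empty)
  rows <- list()
  for (i in seq_len(nrow(sites) - 1)) {
    for (j in seq((i + 1), nrow(sites))) {
      span_start <- sites$pam_start[i]
      span_end <- sites$pam_start[j] + 3L
      if (all(features$start >= span_start & features$end <= span_end)) {
        rows[[length(rows) + 1]] <- data.frame(
          left_pam = sites$pam_start[i], right_pam = sites$pam_start[j],
          left_strand = sites$strand[i], right_strand = sites$strand[j],
          span_start = span_start, span_end = span_end,
          span_length = span_end - span_start, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$span_length, out$left_pam), , drop = FALSE]
  rownames(out) <- NULL
  out
}
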