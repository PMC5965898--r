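# Relatedness: method-of-moments IBD, relationship classification, exhaustive
# family merging, kinship matrix and ancestry components.
#
# Pairwise IBD state probabilities (Z0, Z1, Z2 = probability of sharing 0/1/2
# alleles identical by descent) are estimated from identity-by-state counts
# and cohort allele frequencies by the classical method of moments: observed
# IBS category counts are equated with their expectations given the IBD state
# mixture. PI_HAT = Z1/2 + Z2 summarizes the expected genome fraction shared.
# Families are then the connected components of the PI_HAT > threshold graph,
# merged exhaustively. The kinship matrix for the mixed model is the centered
# genomic relationship matrix.

# Per-site expected IBS-category probabilities conditional on IBD state,
# as functions of the alternate-allele frequency p.
ibs_expectations <- function(p) {
  q <- 1 - p
  list(e0_z0 = 2 * p^2 * q^2,
       e1_z0 = 4 * p^3 * q + 4 * p * q^3,
       e2_z0 = p^4 + q^4 + 4 * p^2 * q^2,
       e1_z1 = 2 * p^2 * q + 2 * p * q^2,
       e2_z1 = p^2 + q^2)
}

# Moment estimator from per-pair IBS counts and per-pair expected sums.
ibd_from_counts <- function(n0, n1, n2, E0, E1_0, E1_1, E2_0, E2_1, Etot) {
  z0 <- n0 / E0
  z1 <- (n1 - z0 * E1_0) / E1_1
  z2 <- (n2 - z0 * E2_0 - z1 * E2_1) / Etot
  raw <- cbind(z0 = z0, z1 = z1, z2 = z2)
  # project onto the probability simplex: clip at zero, renormalize
  cl <- pmax(raw, 0)
  s <- rowSums(cl)
  s[s == 0] <- 1
  cl <- cl / s
  list(raw = raw, clamped = cl)
}

#' Estimate pairwise IBD sharing for all subject pairs
#'
#' Method-of-moments estimation of (Z0, Z1, Z2) from IBS sharing counts and
#' allele frequencies estimated from the cohort itself. Sites missing in
#' either member of a pair are skipped for that pair; monomorphic sites are
#' dropped. Estimates are reported both raw and projected onto the simplex.
#'
#' @param genotypes A [genotype_matrix()].
#' @param subjects Optional subset of subject ids (default: all).
#' @param min_informative Minimum number of informative sites per pair below
#'   which a precision warning is attached (column `low_information`).
#' @return data.frame: id1, id2, z0, z1, z2, pi_hat (simplex-projected),
#'   z0_raw, z1_raw, z2_raw, pi_hat_raw, n_snps, low_information.
#' @export
estimate_ibd_all <- function(genotypes, subjects = NULL,
                             min_informative = 500) {
  d <- genotypes$dosage
  if (!is.null(subjects)) d <- d[subjects, , drop = FALSE]
  if (nrow(d) < 2) stop("need at least two subjects", call. = FALSE)
  p <- colMeans(d, na.rm = TRUE) / 2
  keep <- !is.na(p) & p > 0 & p < 1
  d <- d[, keep, drop = FALSE]
  p <- p[keep]
  if (ncol(d) == 0) stop("no informative (polymorphic) sites", call. = FALSE)
  e <- ibs_expectations(p)

  M <- (!is.na(d)) * 1
  A0 <- (!is.na(d) & d == 0) * 1
  A1 <- (!is.na(d) & d == 1) * 1
  A2 <- (!is.na(d) & d == 2) * 1
  n_ibs0 <- tcrossprod(A0, A2); n_ibs0 <- n_ibs0 + t(n_ibs0)
  n_ibs2 <- tcrossprod(A0) + tcrossprod(A1) + tcrossprod(A2)
  n_tot <- tcrossprod(M)
  n_ibs1 <- n_tot - n_ibs0 - n_ibs2
  esum <- function(ev) tcrossprod(sweep(M, 2, ev, `*`), M)
  E0 <- esum(e$e0_z0); E1_0 <- esum(e$e1_z0); E2_0 <- esum(e$e2_z0)
  E1_1 <- esum(e$e1_z1); E2_1 <- esum(e$e2_z1)

  ut <- which(upper.tri(n_tot), arr.ind = TRUE)
  est <- ibd_from_counts(n_ibs0[ut], n_ibs1[ut], n_ibs2[ut],
                         E0[ut], E1_0[ut], E1_1[ut], E2_0[ut], E2_1[ut],
                         n_tot[ut])
  ids <- rownames(d)
  n_pair <- n_tot[ut]
  out <- data.frame(
    id1 = ids[ut[, 1]], id2 = ids[ut[, 2]],
    z0 = est$clamped[, "z0"], z1 = est$clamped[, "z1"],
    z2 = est$clamped[, "z2"],
    pi_hat = est$clamped[, "z2"] + est$clamped[, "z1"] / 2,
    z0_raw = est$raw[, "z0"], z1_raw = est$raw[, "z1"],
    z2_raw = est$raw[, "z2"],
    pi_hat_raw = est$raw[, "z2"] + est$raw[, "z1"] / 2,
    n_snps = n_pair,
    low_information = n_pair < min_informative,
    stringsAsFactors = FALSE)
  if (any(out$low_information)) {
    warning(sprintf("%d pair(s) have fewer than %d informative sites",
                    sum(out$low_information), min_informative), call. = FALSE)
  }
  out
}

#' Estimate IBD sharing for one pair of subjects
#'
#' @param genotypes A [genotype_matrix()].
#' @param id1,id2 Subject ids.
#' @inheritParams estimate_ibd_all
#' @return One-row data.frame as in [estimate_ibd_all()].
#' @export
estimate_ibd <- function(genotypes, id1, id2, min_informative = 500) {
  # frequencies come from the full cohort, not just the pair
  d <- genotypes$dosage
  p <- colMeans(d, na.rm = TRUE) / 2
  keep <- !is.na(p) & p > 0 & p < 1
  g1 <- d[id1, keep]; g2 <- d[id2, keep]
  p <- p[keep]
  ok <- !is.na(g1) & !is.na(g2)
  g1 <- g1[ok]; g2 <- g2[ok]; p <- p[ok]
  e <- ibs_expectations(p)
  ibs <- 2 - abs(g1 - g2)
  ibs[(g1 == 0 & g2 == 2) | (g1 == 2 & g2 == 0)] <- 0
  est <- ibd_from_counts(sum(ibs == 0), sum(ibs == 1), sum(ibs == 2),
                         sum(e$e0_z0), sum(e$e1_z0), sum(e$e1_z1),
                         sum(e$e2_z0), sum(e$e2_z1), length(p))
  low <- length(p) < min_informative
  if (low) {
    warning(sprintf("only %d informative sites for pair %s-%s",
                    length(p), id1, id2), call. = FALSE)
  }
  data.frame(id1 = id1, id2 = id2,
             z0 = est$clamped[1], z1 = est$clamped[2], z2 = est$clamped[3],
             pi_hat = est$clamped[3] + est$clamped[2] / 2,
             z0_raw = est$raw[1], z1_raw = est$raw[2], z2_raw = est$raw[3],
             pi_hat_raw = est$raw[3] + est$raw[2] / 2,
             n_snps = length(p), low_information = low,
             stringsAsFactors = FALSE)
}

# expected (Z0, Z1, Z2) per relationship class
relationship_centroids <- function() {
  rbind(duplicate = c(0, 0, 1),
        `parent-child` = c(0, 1, 0),
        `full-sibling` = c(0.25, 0.5, 0.25),
        `second-degree` = c(0.5, 0.5, 0),
        unrelated = c(1, 0, 0))
}

#' Classify a relationship from IBD state probabilities
#'
#' Assigns the relationship whose expected (Z0, Z1, Z2) centroid is nearest in
#' Euclidean distance: duplicate (0,0,1), parent-child (0,1,0), full sibling
#' (0.25,0.5,0.25), second degree (0.5,0.5,0), unrelated (1,0,0).
#'
#' @param est A data.frame with columns z0, z1, z2 (one or more rows), e.g.
#'   from [estimate_ibd_all()].
#' @return The input with columns `relationship` and `centroid_distance`
#'   appended.
#' @export
classify_relationship <- function(est) {
  cen <- relationship_centroids()
  z <- as.matrix(est[, c("z0", "z1", "z2")])
  d2 <- outer(rowSums(z^2), rep(1, nrow(cen))) -
    2 * z %*% t(cen) + outer(rep(1, nrow(z)), rowSums(cen^2))
  idx <- apply(d2, 1, which.min)
  est$relationship <- rownames(cen)[idx]
  est$centroid_distance <- sqrt(pmax(d2[cbind(seq_len(nrow(z)), idx)], 0))
  est
}

#' Reconstruct families by exhaustive relatedness merging
#'
#' Groups subjects into families as the connected components of the graph with
#' an edge wherever estimated PI_HAT exceeds `threshold` (default 0.125, first
#' cousin or closer). Merging connected components is the fixed point of the
#' exhaustive pair-merging procedure: any subject related to any member of a
#' family joins that family, repeated until nothing changes. Families are
#' numbered by decreasing size, ties by smallest member id; subjects with no
#' relative above the threshold are left unassigned.
#'
#' @param ibd_table data.frame with columns id1, id2, pi_hat covering all
#'   pairs of included subjects (e.g. from [estimate_ibd_all()]).
#' @param threshold PI_HAT threshold (default 0.125).
#' @param subjects Optional full roster; defaults to all ids in `ibd_table`.
#' @return list(families = named list of member-id vectors,
#'   membership = named vector family-id per subject (NA if unassigned),
#'   unassigned = character vector).
#' @export
build_families <- function(ibd_table, threshold = 0.125, subjects = NULL) {
  if (is.null(subjects)) {
    subjects <- sort(unique(c(ibd_table$id1, ibd_table$id2)))
  }
  edges <- ibd_table[ibd_table$pi_hat > threshold, c("id1", "id2"),
                     drop = FALSE]
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = data.frame(name = subjects))
  comp <- igraph::components(g)
  members <- split(names(comp$membership), comp$membership)
  fams <- members[vapply(members, length, 1L) >= 2]
  # deterministic numbering: descending size, then smallest member id
  ord <- order(-vapply(fams, length, 1L),
               vapply(fams, function(x) min(x), character(1)))
  fams <- lapply(fams[ord], sort)
  names(fams) <- sprintf("FAM%03d", seq_along(fams))
  membership <- stats::setNames(rep(NA_character_, length(subjects)), subjects)
  for (f in names(fams)) membership[fams[[f]]] <- f
  list(families = fams, membership = membership,
       unassigned = subjects[is.na(membership)])
}

#' Kinship matrix from genotypes
#'
#' Centered genomic relationship matrix: missing dosages are mean-imputed per
#' variant, columns are centered at twice the allele frequency, and
#' `K = Xc %*% t(Xc) / p` over the `p` retained variants. The standardized
#' construction additionally scales each column by `sqrt(2 f (1-f))`. If
#' numerical noise produces eigenvalues below `-psd_tol`, the matrix is
#' projected to the nearest PSD matrix by eigenvalue clipping (with a warning).
#'
#' @param genotypes A [genotype_matrix()].
#' @param maf_min Minimum minor allele frequency for a variant to contribute.
#' @param method `"centered"` (default) or `"standardized"`.
#' @param psd_tol Tolerance on negative eigenvalues before projection.
#' @return Symmetric matrix with subject ids as dimnames and attributes
#'   `construction` and `n_variants`.
#' @export
compute_kinship <- function(genotypes, maf_min = 0.01,
                            method = c("centered", "standardized"),
                            psd_tol = 1e-8) {
  method <- match.arg(method)
  d <- genotypes$dosage
  f <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  keep <- !is.na(maf) & maf >= maf_min
  if (!any(keep)) stop("no usable variants after MAF filtering", call. = FALSE)
  d <- d[, keep, drop = FALSE]
  f <- f[keep]
  X <- sweep(d, 2, 2 * f, `-`)
  X[is.na(X)] <- 0  # mean imputation == centered value 0
  if (method == "standardized") {
    X <- sweep(X, 2, sqrt(2 * f * (1 - f)), `/`)
  }
  K <- tcrossprod(X) / ncol(X)
  K <- (K + t(K)) / 2
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -psd_tol) {
    warning("kinship matrix projected to nearest PSD matrix", call. = FALSE)
    eg <- eigen(K, symmetric = TRUE)
    K <- eg$vectors %*% (pmax(eg$values, 0) * t(eg$vectors))
    K <- (K + t(K)) / 2
    dimnames(K) <- list(rownames(d), rownames(d))
  }
  attr(K, "construction") <- method
  attr(K, "n_variants") <- ncol(X)
  K
}

#' Ancestry components from genotypes
#'
#' Top-k principal components of the centered, mean-imputed dosage matrix
#' (the MDS-style ancestry covariates of array GWA). Component signs are fixed
#' by making the largest-magnitude loading positive.
#'
#' @param genotypes A [genotype_matrix()].
#' @param k Number of components (default 4).
#' @param maf_min Minimum minor allele frequency.
#' @return Matrix subjects x k of component scores (columns `MDS1`..).
#' @export
compute_ancestry_components <- function(genotypes, k = 4, maf_min = 0.01) {
  check_count(k, "k")
  d <- genotypes$dosage
  f <- colMeans(d, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  keep <- !is.na(maf) & maf >= maf_min
  X <- sweep(d[, keep, drop = FALSE], 2, 2 * f[keep], `-`)
  X[is.na(X)] <- 0
  if (!any(keep) || all(abs(X) < .Machine$double.eps)) {
    warning("genotypes carry no variation; ancestry components undefined",
            call. = FALSE)
    out <- matrix(0, nrow(d), 0, dimnames = list(rownames(d), NULL))
    return(out)
  }
  sv <- svd(X, nu = min(k, min(dim(X))), nv = 0)
  pos <- sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1]
  avail <- min(k, sum(pos))
  if (avail < k) {
    warning(sprintf("only %d non-degenerate component(s) available", avail),
            call. = FALSE)
  }
  scores <- sv$u[, seq_len(avail), drop = FALSE] %*%
    diag(sv$d[seq_len(avail)], avail)
  for (j in seq_len(avail)) {
    if (scores[which.max(abs(scores[, j])), j] < 0) {
      scores[, j] <- -scores[, j]
    }
  }
  dimnames(scores) <- list(rownames(d), paste0("MDS", seq_len(avail)))
  scores
}
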