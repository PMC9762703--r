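#' Binary activation patterns and their matching-index matrix
#'
#' The recording is divided into non-overlapping bins; each bin yields a
#' binary pattern (cell active in the bin or not). Pattern similarity is
#' the matching index `MI_ij = 2 |Pat_i intersect Pat_j| / (|Pat_i| + |Pat_j|)`,
#' ranging from 0 (no shared active cells) to 1 (identical patterns).
#' Silent patterns (no active cell) are excluded since their MI is 0/0.
#'
#' @param raster `event_raster`.
#' @param bin bin size (frames).
#' @return list: `patterns` (cells x bins binary matrix of the non-silent
#'   patterns), `mi` (matching-index matrix), `bin_index` (original bin
#'   numbers of the kept patterns), `n_bins_total`.
#' @export
matching_index_matrix <- function(raster, bin = 10) {
  use <- which(!raster$excluded)
  mat <- raster$mat[use, , drop = FALSE]
  n_bins <- ncol(mat) %/% bin
  if (n_bins < 1) stop("recording shorter than one bin")
  pat <- vapply(seq_len(n_bins), function(b)
    as.integer(rowSums(mat[, ((b - 1) * bin + 1):(b * bin),
                           drop = FALSE]) > 0),
    integer(length(use)))
  keep <- colSums(pat) > 0
  if (!any(keep)) stop("all patterns are silent")
  pat <- pat[, keep, drop = FALSE]
  sizes <- colSums(pat)
  inter <- crossprod(pat)
  mi <- 2 * inter / outer(sizes, sizes, `+`)
  dimnames(mi) <- NULL
  list(patterns = pat, mi = mi, bin_index = which(keep),
       n_bins_total = n_bins)
}

#' Matching index of two binary patterns
#'
#' @param a,b binary vectors of equal length (1 = active cell).
#' @return `2|a intersect b| / (|a| + |b|)`; `NA` if both are silent.
#' @export
matching_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  denom <- sum(a) + sum(b)
  if (denom == 0) return(NA_real_)
  2 * sum(a & b) / denom
}

#' Motifs of population activity by eigendecomposition of the MI matrix
#'
#' Decomposes the matching-index matrix of the binned activation patterns;
#' the number of motifs is the number of eigenvalues that exceed the 95th
#' percentile of the rank-matched eigenvalues of surrogate MI matrices
#' (cell-wise uniform onset reshuffles, event counts preserved). The
#' leading eigenvalue, normalized by its mean surrogate value, measures
#' global pattern similarity. Patterns are assigned to motifs by
#' thresholded eigenvector loadings: pattern p belongs to a significant
#' eigenvector k if `|v_k(p)| > 2/sqrt(P)` (P = number of patterns), and
#' is assigned to the eigenvector with the largest absolute loading.
#'
#' @param raster `event_raster`.
#' @param bin bin size (frames).
#' @param n_shuffles number of surrogate rasters.
#' @param percentile eigenvalue significance percentile.
#' @param seed RNG seed.
#' @return list of class `motif_result`: `n_motifs`, `eigenvalues`,
#'   `surrogate_crit` (per rank), `membership` (motif id per pattern, NA =
#'   unassigned), `repetition_fraction` (patterns per motif / total
#'   patterns), `global_similarity` (lambda_1 / mean surrogate lambda_1),
#'   `mi` (the empirical MI matrix), `bin_index`.
#' @export
detect_motifs <- function(raster, bin = 10, n_shuffles = 500,
                          percentile = 95, seed = 1) {
  set.seed(seed)
  emp <- matching_index_matrix(raster, bin)
  p_n <- ncol(emp$mi)
  if (p_n < 2) stop("need at least two non-silent patterns")
  eg <- eigen(emp$mi, symmetric = TRUE)
  lam <- eg$values
  valid_idx <- which(raster$valid_frames)
  use <- which(!raster$excluded)
  counts <- rowSums(raster$mat[use, , drop = FALSE])
  n <- ncol(raster$mat)
  sur_lam <- matrix(0, n_shuffles, p_n)
  for (s in seq_len(n_shuffles)) {
    m <- matrix(0L, length(use), n)
    for (i in seq_along(use)) if (counts[i])
      m[i, sample(valid_idx, counts[i])] <- 1L
    sr <- event_raster(m, raster$frame_rate, raster$valid_frames)
    smi <- matching_index_matrix(sr, bin)$mi
    sl <- eigen(smi, symmetric = TRUE, only.values = TRUE)$values
    k <- min(length(sl), p_n)
    sur_lam[s, seq_len(k)] <- sl[seq_len(k)]
  }
  crit <- apply(sur_lam, 2, quantile, probs = percentile / 100)
  # motifs = leading run of significant eigenvalues: the MI matrix has
  # fixed trace, so mid-rank eigenvalues co-vary with the leading ones
  # and isolated mid-rank exceedances carry no motif structure
  exceed <- lam > crit
  n_lead <- if (exceed[1]) {
    first_fail <- which(!exceed)[1]
    if (is.na(first_fail)) p_n else first_fail - 1L
  } else 0L
  signif_k <- seq_len(n_lead)
  membership <- rep(NA_integer_, p_n)
  if (length(signif_k)) {
    v <- eg$vectors[, signif_k, drop = FALSE]
    pass <- abs(v) > 2 / sqrt(p_n)
    loaded <- rowSums(pass) > 0
    membership[loaded] <- apply(abs(v[loaded, , drop = FALSE]), 1, which.max)
  }
  rep_frac <- if (length(signif_k))
    as.numeric(table(factor(membership, levels = seq_along(signif_k)))) / p_n
    else numeric(0)
  structure(list(n_motifs = length(signif_k), eigenvalues = lam,
                 surrogate_crit = crit, membership = membership,
                 repetition_fraction = rep_frac,
                 global_similarity = lam[1] / mean(sur_lam[, 1]),
                 mi = emp$mi, bin_index = emp$bin_index),
            class = "motif_result")
}
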