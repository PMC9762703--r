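#' Classify the operating regime at a candidate fixed point
#'
#' Treats a point of the rate plane as a candidate steady state with
#' stationary plasticity variables and applies three stability criteria:
#' (A) excitatory instability - with the IN rate clamped, the frozen
#' recurrent excitation alone destabilizes the PC population
#' (`G_P J_PP u* x* > 1` at a supra-threshold PC rate); (B) excitatory
#' stability - the complement of (A); (C) overall stability - the 2x2
#' frozen Jacobian at the point has eigenvalues with strictly negative
#' real parts. A point satisfying A and C operates as an
#' inhibition-stabilized network (ISN); B and C give a Non-ISN; anything
#' else is unstable. For excitatory GABA (`J_I < 0`) the ISN notion is
#' undefined and Non-ISN simply means stable.
#'
#' @param A_I,A_P candidate rates (Hz), vectorized.
#' @param params `stp_rnn_params`.
#' @return character vector with values `"ISN"`, `"Non-ISN"`, `"unstable"`.
#' @export
classify_regime <- function(A_I, A_P, params) {
  stopifnot(length(A_I) == length(A_P), all(A_I >= 0), all(A_P >= 0))
  sP <- stationary_stp(A_P, params$U_PP, params$tau_f_PP, params$tau_r_PP)
  sIP <- stationary_stp(A_P, params$U_IP, params$tau_f_IP, params$tau_r_IP)
  sPI <- stationary_stp(A_I, params$U_PI, params$tau_f_PI, params$tau_r_PI)
  sII <- stationary_stp(A_I, params$U_II, params$tau_f_II, params$tau_r_II)
  wPP <- params$J_PP * sP$u * sP$x
  wIP <- params$J_IP * sIP$u * sIP$x
  wPI <- params$J_PI * sPI$u * sPI$x
  wII <- params$J_II * sII$u * sII$x
  supP <- A_P > 0; supI <- A_I > 0
  crit_A <- supP & (params$G_P * wPP > 1)
  # trace/determinant conditions of the 2x2 frozen Jacobian
  a11 <- (-1 + params$G_P * wPP * supP) / params$tau_P
  a12 <- -params$G_P * wPI * supP / params$tau_P
  a21 <- params$G_I * wIP * supI / params$tau_I
  a22 <- (-1 - params$G_I * wII * supI) / params$tau_I
  tr <- a11 + a22
  det2 <- a11 * a22 - a12 * a21
  crit_C <- tr < 0 & det2 > 0
  inhibitory <- params$J_II >= 0
  out <- rep("unstable", length(A_P))
  if (inhibitory) {
    out[crit_A & crit_C] <- "ISN"
    out[!crit_A & crit_C] <- "Non-ISN"
  } else {
    out[crit_C] <- "Non-ISN"
  }
  out
}

## regime intervals along A_P for one A_I column: boundaries are the
## root-refined sign changes of the three switching functions (excitatory
## instability, trace, determinant of the frozen Jacobian)
regime_column <- function(params, A_I, A_P_max, scan_n = 2000) {
  wPI <- with(stationary_stp(A_I, params$U_PI, params$tau_f_PI,
                             params$tau_r_PI), u * x) * params$J_PI
  wII <- with(stationary_stp(A_I, params$U_II, params$tau_f_II,
                             params$tau_r_II), u * x) * params$J_II
  supI <- as.numeric(A_I > 0)
  a12 <- -params$G_P * wPI / params$tau_P
  a21f <- function(aP) params$G_I * params$J_IP *
    with(stationary_stp(aP, params$U_IP, params$tau_f_IP, params$tau_r_IP),
         u * x) * supI / params$tau_I
  a22 <- (-1 - params$G_I * wII * supI) / params$tau_I
  a11f <- function(aP) (-1 + params$G_P * params$J_PP *
    with(stationary_stp(aP, params$U_PP, params$tau_f_PP, params$tau_r_PP),
         u * x)) / params$tau_P
  fns <- list(
    excA = function(aP) params$tau_P * a11f(aP),          # > 0: instability
    tr = function(aP) a11f(aP) + a22,                     # < 0 needed
    det = function(aP) a11f(aP) * a22 - a12 * a21f(aP))   # > 0 needed
  grid <- seq(0, A_P_max, length.out = scan_n + 1)
  cuts <- c(0, A_P_max)
  for (f in fns) {
    v <- f(grid)
    ch <- which(v[-1] * v[-length(v)] < 0)
    for (i in ch)
      cuts <- c(cuts, stats::uniroot(f, c(grid[i], grid[i + 1]),
                                     tol = 1e-12)$root)
  }
  cuts <- sort(unique(cuts))
  mids <- (cuts[-1] + cuts[-length(cuts)]) / 2
  lab <- classify_regime(rep(A_I, length(mids)), mids, params)
  data.frame(lo = cuts[-length(cuts)], hi = cuts[-1], label = lab)
}

#' Map operating regimes over the rate plane
#'
#' Evaluates [classify_regime()] on a regular grid of candidate fixed
#' points (the `labels` matrix, for plotting) and measures the area of
#' each regime's domain. Because the ISN domain narrows to a sliver at
#' high IN rates, areas are not cell-counted: for each of `n_col` IN-rate
#' columns the exact PC-rate intervals of each regime are found by root
#' refinement of the stability-criterion switching functions, and column
#' measures are integrated by the midpoint rule.
#'
#' @param params `stp_rnn_params`.
#' @param A_I_max,A_P_max plane limits (Hz).
#' @param n grid resolution per axis of the label matrix (cell centers).
#' @param n_col number of columns used for the area integration.
#' @return list of class `regime_map`: `labels` (n x n matrix, rows = A_P
#'   values, columns = A_I values), `A_P`, `A_I` (cell-center coordinates),
#'   `areas` (named vector, Hz^2), `isn_A_P_range` (Hz, measure of the
#'   union of PC-rate intervals at which the ISN regime is available for
#'   some IN rate), `limits`.
#' @export
regime_map <- function(params, A_I_max = 50, A_P_max = 50, n = 100,
                       n_col = 200) {
  stopifnot(n >= 50)
  dI <- A_I_max / n; dP <- A_P_max / n
  aI <- (seq_len(n) - 0.5) * dI
  aP <- (seq_len(n) - 0.5) * dP
  g <- expand.grid(A_P = aP, A_I = aI)
  lab <- classify_regime(g$A_I, g$A_P, params)
  labels <- matrix(lab, nrow = n, ncol = n)
  areas <- c(ISN = 0, `Non-ISN` = 0, unstable = 0)
  isn_iv <- list()
  dcol <- A_I_max / n_col
  for (ai in (seq_len(n_col) - 0.5) * dcol) {
    col <- regime_column(params, ai, A_P_max)
    len <- tapply(col$hi - col$lo, col$label, sum)
    areas[names(len)] <- areas[names(len)] + len * dcol
    isn <- col[col$label == "ISN", , drop = FALSE]
    if (nrow(isn)) isn_iv[[length(isn_iv) + 1]] <- isn[, c("lo", "hi")]
  }
  structure(list(labels = labels, A_P = aP, A_I = aI, areas = areas,
                 isn_A_P_range = merged_length(isn_iv),
                 limits = c(A_I_max = A_I_max, A_P_max = A_P_max)),
            class = "regime_map")
}

## total length of the union of a list of (lo, hi) interval tables
merged_length <- function(ivs) {
  if (!length(ivs)) return(0)
  m <- do.call(rbind, ivs)
  m <- m[order(m$lo), , drop = FALSE]
  tot <- 0; cur_lo <- m$lo[1]; cur_hi <- m$hi[1]
  for (i in seq_len(nrow(m))[-1]) {
    if (m$lo[i] > cur_hi) {
      tot <- tot + cur_hi - cur_lo
      cur_lo <- m$lo[i]; cur_hi <- m$hi[i]
    } else cur_hi <- max(cur_hi, m$hi[i])
  }
  tot + cur_hi - cur_lo
}

## span of PC rates at which the ISN regime is available
isn_ap_range <- function(map) map$isn_A_P_range

## scale the efficacies of one synapse class
scale_params <- function(params, target = c("J_I", "J_P"), scale) {
  target <- match.arg(target)
  p <- unclass(params)
  if (target == "J_I") {
    p$J_II <- p$J_II * scale; p$J_PI <- p$J_PI * scale
  } else {
    p$J_PP <- p$J_PP * scale; p$J_IP <- p$J_IP * scale
  }
  class(p) <- "stp_rnn_params"
  p
}
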