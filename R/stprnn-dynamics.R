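#' Integrate the plasticity network with pulse inputs
#'
#' Fixed-step 4th-order Runge-Kutta integration of the 10D model. Inputs
#' are the constant baseline drives plus optional rectangular pulses.
#'
#' @param params `stp_rnn_params`.
#' @param state0 initial 10D state (e.g. from [stationary_state()]).
#' @param t_max end time (s); integration starts at `t = 0`.
#' @param pulses `data.frame` with columns `time`, `e_PC`, `e_IN` and
#'   optionally `duration` (s, default 0.02): excitatory pulse inputs to
#'   the PC and IN populations.
#' @param dt integration step (s).
#' @param record_every keep every n-th step in the returned trajectory.
#' @return A `data.frame` of class `stp_rnn_trajectory`: `time`, the 10
#'   state variables, summed drives `h_P`, `h_I`, and inputs `e_P`, `e_I`.
#' @export
integrate_stprnn <- function(params, state0, t_max,
                             pulses = NULL, dt = 2e-4, record_every = 1L) {
  stopifnot(inherits(params, "stp_rnn_params"), t_max > 0, dt > 0)
  pm <- matrix(numeric(0), ncol = 4)
  if (!is.null(pulses) && nrow(pulses) > 0) {
    dur <- if ("duration" %in% names(pulses)) pulses$duration else 0.02
    pm <- cbind(pulses$time, pulses$time + dur, pulses$e_PC, pulses$e_IN)
    o <- order(pm[, 1])
    pm <- pm[o, , drop = FALSE]
    if (any(pm[-1, 1] < pm[-nrow(pm), 2])) stop("pulses must not overlap")
  }
  res <- .stprnn_integrate_cpp(as.numeric(state0), params, 0, t_max, dt,
                               pm, params$e_P, params$e_I,
                               as.integer(record_every))
  st <- res$state
  colnames(st) <- state_names()
  out <- data.frame(time = res$time, st, h_P = res$h_P, h_I = res$h_I,
                    e_P = res$e_P, e_I = res$e_I)
  class(out) <- c("stp_rnn_trajectory", "data.frame")
  out
}

## residual of the 2-equation reduced steady-state system at rates (aP, aI)
steady_residual <- function(params, aP, aI, e_P, e_I) {
  st <- stationary_state(params, aP, aI)
  h_P <- params$J_PP * st["u_PP"] * st["x_PP"] * aP -
    params$J_PI * st["u_PI"] * st["x_PI"] * aI + e_P
  h_I <- params$J_IP * st["u_IP"] * st["x_IP"] * aP -
    params$J_II * st["u_II"] * st["x_II"] * aI + e_I
  c(-aP + response(h_P, params$theta_P, params$G_P),
    -aI + response(h_I, params$theta_I, params$G_I))
}

## damped Newton on the reduced system restricted to a threshold region;
## supra = c(P, I) logical, sub-threshold populations are pinned at 0
newton_region <- function(params, start, supra, e_P, e_I,
                          tol = 1e-12, max_iter = 100) {
  a <- start
  for (it in seq_len(max_iter)) {
    f <- steady_residual(params, a[1], a[2], e_P, e_I)
    f[!supra] <- a[!supra]          # pin sub-threshold rate at 0
    if (max(abs(f)) < tol) break
    J <- matrix(0, 2, 2)
    h <- pmax(1e-7, 1e-7 * abs(a))
    for (k in 1:2) {
      ap <- a; ap[k] <- ap[k] + h[k]
      am <- a; am[k] <- max(0, am[k] - h[k])
      fp <- steady_residual(params, ap[1], ap[2], e_P, e_I)
      fm <- steady_residual(params, am[1], am[2], e_P, e_I)
      fp[!supra] <- ap[!supra]; fm[!supra] <- am[!supra]
      J[, k] <- (fp - fm) / (ap[k] - am[k])
    }
    step <- tryCatch(solve(J, f), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    # dampen to stay non-negative
    lam <- 1
    while (lam > 1e-6 && any(a - lam * step < -1e-9)) lam <- lam / 2
    a <- pmax(0, a - lam * step)
  }
  f <- steady_residual(params, a[1], a[2], e_P, e_I)
  f[!supra] <- a[!supra]
  if (max(abs(f)) > 1e-9) return(NULL)
  a
}

## numeric Jacobian of the full 10D system at a state
full_jacobian <- function(params, state, e_P, e_I, h = 1e-7) {
  n <- length(state)
  J <- matrix(0, n, n)
  for (k in seq_len(n)) {
    sp <- state; sp[k] <- sp[k] + h
    sm <- state; sm[k] <- sm[k] - h
    J[, k] <- (stp_rnn_derivatives(sp, params, e_P, e_I) -
                 stp_rnn_derivatives(sm, params, e_P, e_I)) / (2 * h)
  }
  J
}

#' Fixed points of the full 10D model
#'
#' Enumerates the four threshold-linear regions (each population above or
#' below its activity threshold), substitutes the closed-form stationary
#' plasticity variables, root-finds the reduced rate equations in each
#' region from a grid of starting points, deduplicates, and verifies each
#' candidate against the full 10D steady-state residual. Stability is read
#' off the eigenvalues of the full 10D Jacobian.
#'
#' @param params `stp_rnn_params`.
#' @param e_P,e_I constant external drives (defaults: the baselines).
#' @param A_max upper bound of the rate search range (Hz).
#' @param n_grid starting-grid resolution per dimension.
#' @return `data.frame` of class `fixed_point_set` with columns `A_P`,
#'   `A_I`, `stable`, `max_re_eig`, `residual`; the full 10D states are
#'   attached as attribute `states` (rows matching the table), the
#'   Jacobian eigenvalues as attribute `eigenvalues` (list).
#' @export
find_fixed_points <- function(params, e_P = params$e_P, e_I = params$e_I,
                              A_max = 100, n_grid = 25) {
  cand <- list()
  # region: both silent
  if (response(e_P, params$theta_P, params$G_P) == 0 &&
      response(e_I, params$theta_I, params$G_I) == 0)
    cand[[length(cand) + 1]] <- c(0, 0)
  grid <- c(0, exp(seq(log(0.05), log(A_max), length.out = n_grid)))
  # region: P active, I silent
  for (a0 in grid[-1]) {
    r <- newton_region(params, c(a0, 0), c(TRUE, FALSE), e_P, e_I)
    if (!is.null(r)) cand[[length(cand) + 1]] <- r
  }
  # region: I active, P silent
  for (a0 in grid[-1]) {
    r <- newton_region(params, c(0, a0), c(FALSE, TRUE), e_P, e_I)
    if (!is.null(r)) cand[[length(cand) + 1]] <- r
  }
  # region: both active
  for (aP in grid[-1]) for (aI in grid[-1]) {
    r <- newton_region(params, c(aP, aI), c(TRUE, TRUE), e_P, e_I)
    if (!is.null(r)) cand[[length(cand) + 1]] <- r
  }
  if (!length(cand)) stop("no fixed point found")
  m <- do.call(rbind, cand)
  m <- m[!duplicated(round(m, 6)), , drop = FALSE]
  keep <- list(); states <- list(); eigs <- list()
  for (i in seq_len(nrow(m))) {
    a <- m[i, ]
    st <- stationary_state(params, a[1], a[2])
    res <- max(abs(stp_rnn_derivatives(st, params, e_P, e_I)))
    if (res > 1e-9) next
    # consistency with the claimed threshold region
    hP <- params$J_PP * st["u_PP"] * st["x_PP"] * a[1] -
      params$J_PI * st["u_PI"] * st["x_PI"] * a[2] + e_P
    hI <- params$J_IP * st["u_IP"] * st["x_IP"] * a[1] -
      params$J_II * st["u_II"] * st["x_II"] * a[2] + e_I
    if (a[1] == 0 && hP > params$theta_P) next
    if (a[2] == 0 && hI > params$theta_I) next
    ev <- eigen(full_jacobian(params, st, e_P, e_I), only.values = TRUE)$values
    keep[[length(keep) + 1]] <- c(a, res, max(Re(ev)))
    states[[length(states) + 1]] <- st
    eigs[[length(eigs) + 1]] <- ev
  }
  k <- do.call(rbind, keep)
  out <- data.frame(A_P = k[, 1], A_I = k[, 2],
                    stable = k[, 4] < 0, max_re_eig = k[, 4],
                    residual = k[, 3])
  o <- order(out$A_P, out$A_I)
  out <- out[o, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "states") <- do.call(rbind, states)[o, , drop = FALSE]
  attr(out, "eigenvalues") <- eigs[o]
  class(out) <- c("fixed_point_set", "data.frame")
  out
}

#' Freeze the synaptic efficacies at a network state
#'
#' Returns the 2D rate system obtained by fixing the plasticity variables
#' at the given state: effective weights `J_ij^frz = J_ij u_ij x_ij`.
#'
#' @param params `stp_rnn_params`.
#' @param state 10D state at which to freeze (named vector or the layout
#'   of [stationary_state()]).
#' @return list of class `frozen_stprnn` with the four frozen weights and
#'   the rate-equation constants.
#' @export
freeze <- function(params, state) {
  s <- as.numeric(state)
  w <- list(
    J_PP = params$J_PP * s[4] * s[3], J_IP = params$J_IP * s[6] * s[5],
    J_PI = params$J_PI * s[8] * s[7], J_II = params$J_II * s[10] * s[9])
  out <- c(w, params[c("tau_P", "tau_I", "theta_P", "theta_I",
                       "G_P", "G_I", "e_P", "e_I")])
  class(out) <- "frozen_stprnn"
  out
}

frozen_jacobian <- function(frz, supra_P, supra_I) {
  sP <- as.numeric(supra_P); sI <- as.numeric(supra_I)
  matrix(c(
    (-1 + frz$G_P * frz$J_PP * sP) / frz$tau_P,
    frz$G_I * frz$J_IP * sI / frz$tau_I,
    -frz$G_P * frz$J_PI * sP / frz$tau_P,
    (-1 - frz$G_I * frz$J_II * sI) / frz$tau_I), 2, 2)
}

#' Fixed points of a frozen (2D) network
#'
#' With constant weights the rate equations are piecewise linear, so the
#' fixed points of each threshold region are solved in closed form and
#' kept when they fall inside their region. Stability follows from the 2x2
#' Jacobian with the threshold-linear slopes of the region.
#'
#' @param frz `frozen_stprnn` from [freeze()].
#' @param e_P,e_I constant external drives.
#' @return `data.frame` with columns `A_P`, `A_I`, `stable`, `max_re_eig`.
#' @export
frozen_fixed_points <- function(frz, e_P = frz$e_P, e_I = frz$e_I) {
  out <- list()
  add <- function(aP, aI, supP, supI) {
    ev <- eigen(frozen_jacobian(frz, supP, supI), only.values = TRUE)$values
    out[[length(out) + 1]] <<- data.frame(
      A_P = aP, A_I = aI, stable = max(Re(ev)) < 0, max_re_eig = max(Re(ev)))
  }
  thP <- frz$theta_P; thI <- frz$theta_I; GP <- frz$G_P; GI <- frz$G_I
  # both silent
  if (e_P <= thP && e_I <= thI) add(0, 0, FALSE, FALSE)
  # P active, I silent: A_P (1 - G J_PP) = G (e_P - theta_P)
  den <- 1 - GP * frz$J_PP
  if (abs(den) > 1e-12) {
    aP <- GP * (e_P - thP) / den
    if (aP > 0 && frz$J_PP * aP + e_P > thP && frz$J_IP * aP + e_I <= thI)
      add(aP, 0, TRUE, FALSE)
  }
  # I active, P silent
  den <- 1 + GI * frz$J_II
  if (abs(den) > 1e-12) {
    aI <- GI * (e_I - thI) / den
    if (aI > 0 && -frz$J_II * aI + e_I > thI && -frz$J_PI * aI + e_P <= thP)
      add(0, aI, FALSE, TRUE)
  }
  # both active: linear 2x2 system
  M <- matrix(c(1 - GP * frz$J_PP, -GI * frz$J_IP,
                GP * frz$J_PI, 1 + GI * frz$J_II), 2, 2)
  rhs <- c(GP * (e_P - thP), GI * (e_I - thI))
  if (abs(det(M)) > 1e-12) {
    a <- solve(M, rhs)
    if (all(a > 0)) {
      hP <- frz$J_PP * a[1] - frz$J_PI * a[2] + e_P
      hI <- frz$J_IP * a[1] - frz$J_II * a[2] + e_I
      if (hP > thP && hI > thI) add(a[1], a[2], TRUE, TRUE)
    }
  }
  res <- do.call(rbind, out)
  res <- unique(res[order(res$A_P, res$A_I), , drop = FALSE])
  rownames(res) <- NULL
  res
}
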