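## locate the spontaneous silent / active stable fixed points
spontaneous_fps <- function(params) {
  fps <- find_fixed_points(params)
  states <- attr(fps, "states")
  silent_i <- which(fps$stable & fps$A_P < 1e-6 & fps$A_I < 1e-6)
  active_i <- which(fps$stable & fps$A_P > 1e-6)
  list(table = fps,
       silent = if (length(silent_i)) states[silent_i[1], ] else NULL,
       active = if (length(active_i))
         states[active_i[which.max(fps$A_P[active_i])], ] else NULL)
}

#' Rate-plane drift field
#'
#' Rate derivatives over the (A_I, A_P) plane, either with plasticity
#' variables at their stationary values for each point (the slow,
#' "stationary dynamics" plane) or frozen at a fixed state (the fast
#' dynamics right after a perturbation).
#'
#' @param params `stp_rnn_params`.
#' @param A_I,A_P coordinate vectors (a grid is formed).
#' @param frozen optional `frozen_stprnn`; if supplied the frozen weights
#'   are used instead of stationary ones.
#' @return list with matrices `dA_P`, `dA_I` (rows = `A_P`, cols = `A_I`).
#' @export
rate_plane_field <- function(params, A_I, A_P, frozen = NULL) {
  g <- expand.grid(A_P = A_P, A_I = A_I)
  if (is.null(frozen)) {
    sP <- stationary_stp(g$A_P, params$U_PP, params$tau_f_PP, params$tau_r_PP)
    sIP <- stationary_stp(g$A_P, params$U_IP, params$tau_f_IP, params$tau_r_IP)
    sPI <- stationary_stp(g$A_I, params$U_PI, params$tau_f_PI, params$tau_r_PI)
    sII <- stationary_stp(g$A_I, params$U_II, params$tau_f_II, params$tau_r_II)
    hP <- params$J_PP * sP$u * sP$x * g$A_P -
      params$J_PI * sPI$u * sPI$x * g$A_I + params$e_P
    hI <- params$J_IP * sIP$u * sIP$x * g$A_P -
      params$J_II * sII$u * sII$x * g$A_I + params$e_I
  } else {
    hP <- frozen$J_PP * g$A_P - frozen$J_PI * g$A_I + frozen$e_P
    hI <- frozen$J_IP * g$A_P - frozen$J_II * g$A_I + frozen$e_I
  }
  dP <- (-g$A_P + response(hP, params$theta_P, params$G_P)) / params$tau_P
  dI <- (-g$A_I + response(hI, params$theta_I, params$G_I)) / params$tau_I
  list(dA_P = matrix(dP, length(A_P), length(A_I)),
       dA_I = matrix(dI, length(A_P), length(A_I)))
}

#' Single-pulse response experiment
#'
#' Integrates the model from a spontaneous stable fixed point, applies one
#' 20-ms excitatory pulse to the PC and IN populations, classifies the
#' asymptotic state, and detects a simulated network burst (simNB): a
#' supra-amplification transient whose post-offset peak of `A_P + A_I`
#' exceeds both the level at input offset and twice the active-state total
#' rate.
#'
#' @param params `stp_rnn_params`.
#' @param start `"silent"`, `"active"`, or a 10D state vector.
#' @param e_PC,e_IN pulse amplitudes.
#' @param pulse_dur pulse duration (s).
#' @param settle_time integration time after the pulse (s); long enough for
#'   the slow depression variables to re-equilibrate.
#' @param dt integration step (s).
#' @param eps convergence tolerance for state classification.
#' @param record_every trajectory thinning factor.
#' @param fps optional precomputed spontaneous fixed points (internal
#'   reuse across grid scans).
#' @return list of class `pulse_experiment`: `trajectory`, `outcome`
#'   (`"to_silent"`, `"to_active"`, `"undecided"`), `simNB` (logical),
#'   `simNB_size` (Hz, peak of `A_P + A_I` after pulse offset), `fps`.
#' @export
pulse_experiment <- function(params, start = c("silent", "active"),
                             e_PC, e_IN, pulse_dur = 0.02,
                             settle_time = 30, dt = 2e-4, eps = 1e-3,
                             record_every = 5L, fps = NULL) {
  sp <- if (is.null(fps)) spontaneous_fps(params) else fps
  if (is.character(start)) {
    start <- match.arg(start)
    state0 <- sp[[start]]
    if (is.null(state0))
      stop("no stable spontaneous ", start, " state for these parameters")
  } else state0 <- start
  pulse_time <- 0.1
  tr <- integrate_stprnn(params, state0, pulse_time + pulse_dur + settle_time,
                         pulses = data.frame(time = pulse_time, e_PC = e_PC,
                                             e_IN = e_IN,
                                             duration = pulse_dur),
                         dt = dt, record_every = record_every)
  classify_end <- function(state_end) {
    for (lab in c("silent", "active")) {
      fp <- sp[[lab]]
      if (!is.null(fp) && max(abs(state_end - fp)) < eps)
        return(paste0("to_", lab))
    }
    "undecided"
  }
  final <- as.numeric(tr[nrow(tr), state_names()])
  off <- pulse_time + pulse_dur
  post <- tr$time >= off
  total <- tr$A_P + tr$A_I
  peak <- max(total[post])
  at_off <- total[which(post)[1]]
  active_total <- if (!is.null(sp$active)) sum(sp$active[1:2]) else 0
  structure(list(trajectory = tr, outcome = classify_end(final),
                 simNB = peak > at_off && peak > 2 * active_total,
                 simNB_size = peak, fps = sp),
            class = "pulse_experiment")
}

#' Input-amplitude transition matrix
#'
#' Runs [pulse_experiment()] for every combination of PC and IN pulse
#' amplitudes and records the transition outcome and simNB flag.
#'
#' @param params `stp_rnn_params`.
#' @param start `"silent"` or `"active"` starting state.
#' @param e_PC_grid,e_IN_grid amplitude grids.
#' @param ... forwarded to [pulse_experiment()].
#' @return list of class `transition_scan` with `outcome` and `simNB`
#'   matrices (rows = `e_PC_grid`, cols = `e_IN_grid`) and the grids.
#' @export
transition_matrix <- function(params, start, e_PC_grid, e_IN_grid, ...) {
  stopifnot(length(e_PC_grid) >= 2, length(e_IN_grid) >= 2)
  outc <- matrix(NA_character_, length(e_PC_grid), length(e_IN_grid),
                 dimnames = list(e_PC_grid, e_IN_grid))
  nb <- matrix(NA, length(e_PC_grid), length(e_IN_grid))
  size <- nb
  sp <- spontaneous_fps(params)
  for (i in seq_along(e_PC_grid)) for (j in seq_along(e_IN_grid)) {
    r <- pulse_experiment(params, start, e_PC_grid[i], e_IN_grid[j],
                          fps = sp, ...)
    outc[i, j] <- r$outcome
    nb[i, j] <- r$simNB
    size[i, j] <- r$simNB_size
  }
  structure(list(outcome = outc, simNB = nb, simNB_size = size,
                 e_PC = e_PC_grid, e_IN = e_IN_grid, start = start),
            class = "transition_scan")
}

## outcome of silencing pulse at t=0 followed by a probe pulse at t = ipi
ipi_outcome <- function(params, state_active, sp, silence, probe, ipi,
                        pulse_dur, settle_time, dt, eps, record_every = 10L) {
  tr <- integrate_stprnn(
    params, state_active, ipi + pulse_dur + settle_time,
    pulses = data.frame(time = c(0, ipi),
                        e_PC = c(silence[1], probe[1]),
                        e_IN = c(silence[2], probe[2]),
                        duration = pulse_dur),
    dt = dt, record_every = record_every)
  final <- as.numeric(tr[nrow(tr), state_names()])
  lab <- "undecided"
  for (nm in c("silent", "active")) {
    fp <- sp[[nm]]
    if (!is.null(fp) && max(abs(final - fp)) < eps) lab <- paste0("to_", nm)
  }
  post <- tr$time >= ipi + pulse_dur
  # plasticity state right before the probe
  pre_i <- max(which(tr$time < ipi))
  list(outcome = lab,
       size = max(tr$A_P[post] + tr$A_I[post]),
       ux_P = tr$x_PP[pre_i] * tr$u_PP[pre_i],
       ux_I = tr$x_II[pre_i] * tr$u_II[pre_i])
}

#' Internal deadline of the silent-to-active transition
#'
#' After silencing the network from its active state with a pulse, a probe
#' pulse can restore the active state only up to an internal deadline: the
#' longest inter-pulse interval (IPI, measured from the silencing pulse
#' onset) for which the probe still drives the network back to the active
#' fixed point. The boundary is bracketed on an IPI grid and refined by
#' bisection. The scan also records simNB size and the non-scaled synaptic
#' efficacies `u x` (glutamatergic `u_P x_P`, GABAergic `u_I x_I`) right
#' before the probe.
#'
#' @param params `stp_rnn_params`.
#' @param silence pulse amplitudes `c(e_PC, e_IN)` that silence the
#'   network from the active state.
#' @param probe probe pulse amplitudes `c(e_PC, e_IN)`.
#' @param ipi_range scanned IPI interval (s).
#' @param n_ipi IPI grid size for the scan.
#' @param tol bisection tolerance on the deadline (s).
#' @param pulse_dur,settle_time,dt,eps as in [pulse_experiment()].
#' @return list of class `deadline_result`: `deadline` (s, `NA` if no IPI
#'   in range restores the active state) and a `scan` data.frame with
#'   columns `ipi`, `outcome`, `simNB_size`, `ux_P`, `ux_I`.
#' @export
deadline_scan <- function(params, silence = c(0.25, 1), probe = c(0.25, 0.25),
                          ipi_range = c(0.2, 2.6), n_ipi = 13, tol = 0.005,
                          pulse_dur = 0.02, settle_time = 30, dt = 2e-4,
                          eps = 1e-3) {
  sp <- spontaneous_fps(params)
  if (is.null(sp$active) || is.null(sp$silent))
    stop("deadline analysis requires a bi-stable parameterization")
  # verify the silencing pulse does silence from the active state
  chk <- pulse_experiment(params, "active", silence[1], silence[2],
                          pulse_dur = pulse_dur, settle_time = settle_time,
                          dt = dt, eps = eps)
  if (chk$outcome != "to_silent")
    stop("silencing pulse does not silence the network from the active state")
  run <- function(ipi) ipi_outcome(params, sp$active, sp, silence, probe,
                                   ipi, pulse_dur, settle_time, dt, eps)
  ipis <- seq(ipi_range[1], ipi_range[2], length.out = n_ipi)
  scan <- lapply(ipis, run)
  out <- data.frame(ipi = ipis,
                    outcome = vapply(scan, `[[`, "", "outcome"),
                    simNB_size = vapply(scan, `[[`, 0, "size"),
                    ux_P = vapply(scan, `[[`, 0, "ux_P"),
                    ux_I = vapply(scan, `[[`, 0, "ux_I"))
  succ <- out$outcome == "to_active"
  deadline <- NA_real_
  if (any(succ)) {
    lo <- ipis[max(which(succ))]
    hi_i <- which(!succ & ipis > lo)
    hi <- if (length(hi_i)) ipis[min(hi_i)] else ipi_range[2]
    if (hi > lo) {
      while (hi - lo > tol) {
        mid <- (lo + hi) / 2
        if (run(mid)$outcome == "to_active") lo <- mid else hi <- mid
      }
      deadline <- (lo + hi) / 2
    } else deadline <- lo
  }
  structure(list(deadline = deadline, scan = out, silence = silence,
                 probe = probe), class = "deadline_result")
}

#' Synaptic-strength scaling experiment
#'
#' Rescales the efficacies of one synapse class (GABAergic `J_I` or
#' glutamatergic `J_P`) and reports, per scale, the operating-regime areas
#' of the rate plane, the span of PC rates at which the ISN regime is
#' available, and the simNB size evoked by a standard probe pulse from the
#' silent (rest) state.
#'
#' @param params base `stp_rnn_params`.
#' @param target `"J_I"` or `"J_P"`.
#' @param scales multiplicative scale factors.
#' @param probe rest-state probe pulse amplitudes `c(e_PC, e_IN)`.
#' @param map_n,A_I_max,A_P_max regime-map grid settings.
#' @param ... forwarded to [pulse_experiment()].
#' @return data.frame with one row per scale: regime areas (`area_isn`,
#'   `area_non_isn`, `area_unstable`, Hz^2), `isn_A_P_range` (Hz), and
#'   `simNB_size` (Hz).
#' @export
scaling_experiment <- function(params, target = c("J_I", "J_P"), scales,
                               probe = c(0.25, 0.25), map_n = 100,
                               A_I_max = 50, A_P_max = 50, ...) {
  target <- match.arg(target)
  rows <- lapply(scales, function(s) {
    p <- scale_params(params, target, s)
    m <- regime_map(p, A_I_max, A_P_max, n = map_n)
    pe <- pulse_experiment(p, "silent", probe[1], probe[2], ...)
    data.frame(scale = s,
               area_isn = unname(m$areas["ISN"]),
               area_non_isn = unname(m$areas["Non-ISN"]),
               area_unstable = unname(m$areas["unstable"]),
               isn_A_P_range = isn_ap_range(m),
               simNB_size = pe$simNB_size)
  })
  do.call(rbind, rows)
}
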