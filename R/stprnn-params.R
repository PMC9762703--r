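#' Parameters of the short-term-plasticity recurrent network model
#'
#' Constructs the parameter set of the two-population (pyramidal cell, PC,
#' and interneuron, IN) Wilson-Cowan-type rate model with short-term
#' synaptic depression and facilitation. Synaptic efficacies and plasticity
#' time constants are indexed by the presynaptic population: `J_P` sets both
#' glutamatergic efficacies (`J_PP = J_IP`), `J_I` both GABAergic ones
#' (`J_II = J_PI`); recovery constants follow the same tying
#' (`tau_r_PP = tau_r_IP = tau_r_P` etc.).
#'
#' Defaults parameterize a developing CA1 network in the second postnatal
#' week: inhibitory GABA (`J_I > 0`) and a non-zero spontaneous active
#' state coexisting with a silent state (bi-stability).
#'
#' @param tau_P,tau_I population rate time constants (s).
#' @param J_P glutamatergic synaptic efficacy (onto PC and IN).
#' @param J_I GABAergic synaptic efficacy (onto PC and IN); negative values
#'   model excitatory GABA.
#' @param tau_r_P,tau_r_I recovery time constants of short-term depression
#'   for glutamatergic / GABAergic synapses (s).
#' @param tau_f_P,tau_f_I facilitation time constants (s).
#' @param U_P,U_I baseline utilization (release-probability analog).
#' @param theta_P,theta_I population activity thresholds.
#' @param G_P,G_I linear gains above threshold.
#' @param e_P,e_I constant baseline external drives.
#' @return An object of class `stp_rnn_params`: a named list with one entry
#'   per synapse-resolved parameter.
#' @examples
#' p <- stp_rnn_params()
#' p$J_PP  # 6.5
#' @export
stp_rnn_params <- function(tau_P = 0.015, tau_I = 0.0075,
                           J_P = 6.5, J_I = 3,
                           tau_r_P = 3, tau_r_I = 2.5,
                           tau_f_P = 0.4, tau_f_I = 0.4,
                           U_P = 0.8, U_I = 0.8,
                           theta_P = 0.22, theta_I = 0.53,
                           G_P = 1, G_I = 1,
                           e_P = 0, e_I = 0) {
  stopifnot(tau_P > 0, tau_I > 0, tau_r_P > 0, tau_r_I > 0,
            tau_f_P > 0, tau_f_I > 0,
            U_P > 0, U_P <= 1, U_I > 0, U_I <= 1)
  p <- list(
    tau_P = tau_P, tau_I = tau_I,
    J_PP = J_P, J_IP = J_P, J_II = J_I, J_PI = J_I,
    tau_r_PP = tau_r_P, tau_r_IP = tau_r_P,
    tau_r_PI = tau_r_I, tau_r_II = tau_r_I,
    tau_f_PP = tau_f_P, tau_f_IP = tau_f_P,
    tau_f_PI = tau_f_I, tau_f_II = tau_f_I,
    U_PP = U_P, U_IP = U_P, U_PI = U_I, U_II = U_I,
    theta_P = theta_P, theta_I = theta_I,
    G_P = G_P, G_I = G_I, e_P = e_P, e_I = e_I)
  class(p) <- "stp_rnn_params"
  p
}

#' Model variants: bi-stable default and mono-stable alternatives
#'
#' `"STP-RNN"` returns the default bi-stable parameterization.
#' `"Mono-RNNi"` lowers the PC activity threshold (`theta_P = -0.18`),
#' which removes the silent fixed point while keeping GABA inhibitory.
#' `"Mono-RNNe"` additionally makes GABA excitatory
#' (`theta_P = -0.3`, `theta_I = -0.1`, `J_I = -1.5`).
#'
#' @param kind one of `"STP-RNN"`, `"Mono-RNNi"`, `"Mono-RNNe"`.
#' @return `stp_rnn_params` object.
#' @export
make_variant <- function(kind = c("STP-RNN", "Mono-RNNi", "Mono-RNNe")) {
  kind <- match.arg(kind)
  switch(kind,
    "STP-RNN" = stp_rnn_params(),
    "Mono-RNNi" = stp_rnn_params(theta_P = -0.18),
    "Mono-RNNe" = stp_rnn_params(theta_P = -0.3, theta_I = -0.1, J_I = -1.5))
}

state_names <- function() {
  c("A_P", "A_I", "x_PP", "u_PP", "x_IP", "u_IP",
    "x_PI", "u_PI", "x_II", "u_II")
}

#' Threshold-linear population response function
#'
#' Output rate for summed input `h`: 0 below the threshold `theta`,
#' `G * (h - theta)` above it (continuous at `theta`).
#'
#' @param h summed synaptic input.
#' @param theta activity threshold.
#' @param G linear gain.
#' @return rate (Hz), vectorized over `h`.
#' @export
response <- function(h, theta, G = 1) {
  ifelse(h > theta, G * (h - theta), 0)
}

#' Steady-state short-term plasticity variables
#'
#' Closed-form stationary depression/facilitation variables of a synapse
#' driven at constant presynaptic rate `A`:
#' `u* = U (1 + tau_f A) / (1 + U tau_f A)` and
#' `x* = 1 / (1 + tau_r u* A)`.
#'
#' @param A presynaptic rate (Hz), vectorized.
#' @param U baseline utilization.
#' @param tau_f facilitation time constant (s).
#' @param tau_r depression recovery time constant (s).
#' @return list with components `u` and `x`.
#' @export
stationary_stp <- function(A, U = 0.8, tau_f = 0.4, tau_r = 3) {
  stopifnot(all(A >= 0))
  u <- U * (1 + tau_f * A) / (1 + U * tau_f * A)
  x <- 1 / (1 + tau_r * u * A)
  list(u = u, x = x)
}

#' Full network state with stationary plasticity variables
#'
#' Builds the 10-dimensional state vector at rates (`A_P`, `A_I`) with all
#' depression/facilitation variables at their closed-form steady states.
#'
#' @param params `stp_rnn_params`.
#' @param A_P,A_I population rates (Hz).
#' @return named numeric vector of length 10.
#' @export
stationary_state <- function(params, A_P, A_I) {
  sP <- stationary_stp(A_P, params$U_PP, params$tau_f_PP, params$tau_r_PP)
  sI <- stationary_stp(A_I, params$U_II, params$tau_f_II, params$tau_r_II)
  # glutamatergic synapses (presyn P) may differ from GABAergic (presyn I)
  sIP <- stationary_stp(A_P, params$U_IP, params$tau_f_IP, params$tau_r_IP)
  sPI <- stationary_stp(A_I, params$U_PI, params$tau_f_PI, params$tau_r_PI)
  st <- c(A_P, A_I, sP$x, sP$u, sIP$x, sIP$u, sPI$x, sPI$u, sI$x, sI$u)
  names(st) <- state_names()
  st
}

#' Time derivatives of the 10D model
#'
#' Right-hand sides of the rate and plasticity equations at a given state,
#' with external drives `e_P`, `e_I` added to the recurrent inputs.
#'
#' @param state named or ordered numeric vector (see [stationary_state()]).
#' @param params `stp_rnn_params`.
#' @param e_P,e_I external inputs (override the baseline drives).
#' @return numeric vector of length 10, same ordering as the state.
#' @export
stp_rnn_derivatives <- function(state, params, e_P = params$e_P,
                                e_I = params$e_I) {
  d <- .stprnn_rhs_cpp(as.numeric(state), params, e_P, e_I)
  names(d) <- state_names()
  d
}
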