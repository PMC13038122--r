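#' Hodgkin-Huxley channel densities per compartment kind
#'
#' Classic squid Na/K/leak kinetics with a Q10 = 3 temperature scaling of
#' the gating rates from the 6.3 C base to the simulation temperature.
#' Densities are S/cm^2 per compartment kind; conductances of a kind can be
#' zeroed (e.g. to quench spiking, see [quench_sodium()]). The default
#' axonal/somatic densities are raised to cortical-axon-like values
#' (0.5 / 0.25 S/cm^2 Na): at 37 C the Q10-accelerated classic kinetics
#' would otherwise heat-block and spikes would not clear 0 mV, whereas
#' with these densities action potentials initiate and propagate robustly,
#' which is the mechanism the axonal stage relies on.
#'
#' @param gna,gk,gl named numeric vectors of maximal conductances (S/cm^2)
#'   with entries for `soma`, `axon`, `basal_dendrite`, `apical_dendrite`
#' @param ena,ek,el reversal potentials, mV
#' @param q10 temperature coefficient of the gating rates
#' @param base_temp base temperature of the kinetics, C
#' @return an object of class `channel_set`
#' @export
hh_channels <- function(gna = c(soma = 0.25, axon = 0.5,
                                basal_dendrite = 0, apical_dendrite = 0),
                        gk = c(soma = 0.05, axon = 0.05,
                               basal_dendrite = 0.002,
                               apical_dendrite = 0.002),
                        gl = c(soma = 3e-4, axon = 3e-4,
                               basal_dendrite = 3e-4,
                               apical_dendrite = 3e-4),
                        ena = 50, ek = -77, el = -70,
                        q10 = 3, base_temp = 6.3) {
  kinds <- c("soma", "axon", "basal_dendrite", "apical_dendrite")
  fill <- function(x) {
    out <- setNames(numeric(4), kinds)
    out[names(x)] <- x
    out
  }
  stopifnot(all(gna >= 0), all(gk >= 0), all(gl >= 0))
  structure(list(gna = fill(gna), gk = fill(gk), gl = fill(gl),
                 ena = ena, ek = ek, el = el, q10 = q10,
                 base_temp = base_temp),
            class = "channel_set")
}

#' Purely passive membrane
#' @param gl leak conductance, S/cm^2
#' @param el leak reversal, mV
#' @return a `channel_set` with `gna = gk = 0` everywhere
#' @export
passive_channels <- function(gl = 3e-4, el = -70) {
  hh_channels(gna = c(soma = 0), gk = c(soma = 0),
              gl = setNames(rep(gl, 4),
                            c("soma", "axon", "basal_dendrite",
                              "apical_dendrite")),
              el = el)
}

#' Zero the sodium conductance on selected compartment kinds
#'
#' Quenching the soma and axon suppresses postsynaptic spiking so that the
#' somatic current reflects synaptic drive alone; dendritic channels are
#' untouched. Idempotent.
#'
#' @param channels a [hh_channels()] set
#' @param kinds compartment kinds to silence
#' @return the modified `channel_set`
#' @export
quench_sodium <- function(channels, kinds = c("soma", "axon")) {
  channels$gna[kinds] <- 0
  channels
}

#' Cable simulation configuration
#'
#' @param dt time step, ms
#' @param duration simulated time, ms
#' @param temperature C (sets the gating-rate Q10 factor)
#' @param v_init initial membrane potential, mV
#' @param settle_step,settle_count giant implicit steps used by
#'   [settle_steady_state()] (defaults: 100 steps of 1e9 ms)
#' @param theta implicit weight of the integrator (1 = backward Euler,
#'   0.5 = Crank-Nicolson)
#' @return an object of class `cable_config`
#' @export
cable_config <- function(dt = 0.025, duration = 3, temperature = 37,
                         v_init = -70, settle_step = 1e9,
                         settle_count = 100, theta = 0.5) {
  stopifnot(dt > 0, duration > 0, settle_step > 0, settle_count >= 1)
  structure(list(dt = dt, duration = duration, temperature = temperature,
                 v_init = v_init, settle_step = settle_step,
                 settle_count = settle_count, theta = theta),
            class = "cable_config")
}

.rate_scale <- function(channels, temperature) {
  channels$q10^((temperature - channels$base_temp) / 10)
}

.per_comp_channels <- function(model, channels) {
  comps <- model$comps
  ## S/cm^2 x um^2 -> uS: 1e-2
  a <- comps$area_membrane * 1e-2
  kind <- comps$kind
  list(gna = channels$gna[kind] * a,
       gk = channels$gk[kind] * a,
       gl = channels$gl[kind] * a,
       cm = comps$area_membrane * 1e-5)  # 1 uF/cm^2 -> nF
}

.empty_syn <- list()

.run_core <- function(model, channels, dt, nsteps, theta, v0, gates,
                      psi = NULL, wave = NULL, syn = NULL, mg = 1,
                      record = NULL, temperature = 37) {
  comps <- model$comps
  pc <- .per_comp_channels(model, channels)
  if (is.null(record)) record <- seq_len(nrow(comps))
  if (is.null(gates)) gates <- matrix(numeric(0), 0, 3)
  psi_arg <- if (is.null(psi)) numeric(0) else psi
  wave_arg <- if (is.null(wave)) numeric(0) else wave
  if (is.null(syn)) {
    syn_g <- .empty_syn
    syn_bin <- rep(-1L, nrow(comps))
    syn_w <- numeric(nrow(comps))
    e_rev <- numeric(0)
  } else {
    syn_g <- syn$bin_g
    syn_bin <- syn$bin - 1L
    syn_w <- syn$weight
    e_rev <- syn$e_rev
  }
  res <- cable_core_integrate(
    parent = as.integer(comps$parent) - 1L,
    g_axial = comps$g_axial, cm = pc$cm, gna = pc$gna, gk = pc$gk,
    gl = pc$gl, ena = channels$ena, ek = channels$ek, el = channels$el,
    rate_scale = .rate_scale(channels, temperature), dt = dt,
    nsteps = as.integer(nsteps), theta = theta, v0 = v0, gate0 = gates,
    psi = psi_arg, wave = wave_arg, syn_bin_g = syn_g,
    syn_bin = as.integer(syn_bin), syn_w = syn_w, e_rev = e_rev, mg = mg,
    nmda_gated = !is.null(syn) && isTRUE(syn$nmda_gated),
    record = as.integer(record) - 1L)
  res$record <- record
  res
}

#' Relax a compartment model to its resting steady state
#'
#' Runs `settle_count` giant backward-Euler steps of `settle_step` ms with
#' no stimulus; gating variables collapse to their voltage-clamped steady
#' states each step, so the result is the true fixed point of the coupled
#' system. Convergence is verified by a residual check.
#'
#' @param model a [compartmentalize()] result
#' @param channels a [hh_channels()] set
#' @param config a [cable_config()]
#' @return object of class `cable_state` with fields `v` (matrix,
#'   compartments x 1), `gates`, `t_grid`
#' @export
settle_steady_state <- function(model, channels, config = cable_config()) {
  n <- nrow(model$comps)
  res <- .run_core(model, channels, dt = config$settle_step,
                   nsteps = config$settle_count, theta = 1,
                   v0 = rep(config$v_init, n), gates = NULL,
                   record = n, temperature = config$temperature)
  if (res$diverged)
    stop("numerical failure while settling (step ", res$fail_step, ")")
  ## residual: one more giant step must not move the state
  res2 <- .run_core(model, channels, dt = config$settle_step, nsteps = 1,
                    theta = 1, v0 = res$v_final, gates = res$gates_final,
                    record = n, temperature = config$temperature)
  resid <- max(abs(res2$v_final - res$v_final)) / config$settle_step
  if (resid >= 1e-9)
    stop("settling did not converge: max|dv/dt| = ", signif(resid, 3),
         " mV/ms")
  structure(list(v = matrix(res$v_final, ncol = 1), gates = res$gates_final,
                 t_grid = 0, model_n = n, record = seq_len(n),
                 resid = resid),
            class = "cable_state")
}

#' Simulate membrane dynamics under stimulation and synaptic drive
#'
#' Integrates the branched cable equation with the theta-method (default
#' Crank-Nicolson): per step, gating advances by exact exponential update
#' and the voltage by one unconditionally stable Hines tree solve. The
#' extracellular potential enters through axial differences of
#' `v_m + v_ext`, so a spatially uniform `v_ext` leaves the dynamics
#' unchanged.
#'
#' @param model a [compartmentalize()] result
#' @param channels a [hh_channels()] set
#' @param config a [cable_config()]
#' @param init a settled [settle_steady_state()] state (built on demand if
#'   `NULL`)
#' @param stimulus optional list with `psi` (per-compartment quasipotential,
#'   mV; see [quasipotential()]) and `waveform` (a [biphasic_waveform()])
#' @param synapses optional synaptic drive as built by the dendritic stage:
#'   list with `bin_g` (list of 4 receptor matrices, bins x time), `bin`
#'   (per-compartment bin index, NA/0 for none), `weight` (A/A_bin),
#'   `e_rev`, `nmda_gated`, `mg`
#' @param record compartment ids to record (default all)
#' @return a `cable_state`: `v` (recorded compartments x time, mV),
#'   `t_grid` (ms), `gates` at the final step
#' @export
simulate_cable <- function(model, channels, config = cable_config(),
                           init = NULL, stimulus = NULL, synapses = NULL,
                           record = NULL) {
  if (is.null(init)) init <- settle_steady_state(model, channels, config)
  nsteps <- round(config$duration / config$dt)
  t_grid <- seq(0, by = config$dt, length.out = nsteps + 1)
  psi <- wave <- NULL
  if (!is.null(stimulus)) {
    psi <- if (inherits(stimulus$psi, "quasipotential")) stimulus$psi$psi
           else stimulus$psi
    wave <- waveform_samples(stimulus$waveform, t_grid)
  }
  mg <- if (!is.null(synapses) && !is.null(synapses$mg)) synapses$mg else 1
  res <- .run_core(model, channels, dt = config$dt, nsteps = nsteps,
                   theta = config$theta, v0 = drop(init$v[, ncol(init$v)]),
                   gates = init$gates, psi = psi, wave = wave,
                   syn = synapses, mg = mg, record = record,
                   temperature = config$temperature)
  if (res$diverged)
    stop("numerical failure at t = ",
         signif(res$fail_step * config$dt, 4), " ms")
  if (any(res$v < -120) || any(res$v > 80))
    warning("membrane potential left the [-120, 80] mV sanity band")
  structure(list(v = res$v, gates = res$gates_final, t_grid = t_grid,
                 model_n = nrow(model$comps), record = res$record),
            class = "cable_state")
}

#' @export
print.cable_state <- function(x, ...) {
  cat("<cable_state> ", nrow(x$v), " recorded compartments x ",
      length(x$t_grid), " samples; v in [",
      round(min(x$v), 1), ", ", round(max(x$v), 1), "] mV\n", sep = "")
  invisible(x)
}

#' Conduction velocity along a straight axon
#'
#' Calibration diagnostic: launches a spike with a brief strong conductance
#' at the proximal end of an unbranched axon and reports the velocity from
#' the 0 mV upward-crossing times at two probe compartments (at 40% and
#' 70% of the cable, away from initiation and sealed-end effects).
#' Returns 0 if the spike does not propagate.
#'
#' @param model compartment model of a straight axon (plus soma root)
#' @param channels a [hh_channels()] set
#' @param config a [cable_config()]
#' @param g_drive drive conductance, uS (0.5 ms pulse, reversal 0 mV)
#' @return velocity in um/ms (0 when no propagation)
#' @export
conduction_velocity <- function(model, channels, config = cable_config(),
                                g_drive = 0.05) {
  axon <- which(model$comps$kind == "axon")
  stopifnot(length(axon) >= 10)
  n <- nrow(model$comps)
  nsteps <- round(config$duration / config$dt)
  gmat <- matrix(0, 1, nsteps + 1)
  gmat[1, seq_len(max(2, round(0.5 / config$dt)))] <- g_drive
  bins <- rep(0L, n); bins[axon[1]] <- 1L
  w <- rep(0, n); w[axon[1]] <- 1
  st <- suppressWarnings(simulate_cable(
    model, channels, config,
    synapses = list(bin_g = list(gmat), bin = bins, weight = w,
                    e_rev = 0, nmda_gated = FALSE, mg = 0)))
  probes <- axon[c(ceiling(0.4 * length(axon)),
                   ceiling(0.7 * length(axon)))]
  tcross <- vapply(probes, function(i) {
    tr <- st$v[match(i, st$record), ]
    up <- which(tr[-1] >= 0 & tr[-length(tr)] < 0)
    if (length(up) == 0) return(NA_real_)
    j <- up[1]
    st$t_grid[j] + config$dt * (0 - tr[j]) / (tr[j + 1] - tr[j])
  }, numeric(1))
  if (anyNA(tcross) || diff(tcross) <= 0) return(0)
  dist <- sum(model$comps$length[axon[(which(axon == probes[1]) + 1):
                                      which(axon == probes[2])]])
  dist / diff(tcross)
}
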