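#' Synaptic receptor constants
#'
#' Double-exponential conductance parameters per receptor: rise and fall
#' time constants (ms), reversal potential (mV) and peak conductance (uS).
#' Defaults are the standard cortical set used for the excitatory
#' (AMPA/NMDA) and inhibitory (GABAa/GABAb) projections.
#'
#' @param ampa,nmda,gabaa,gabab named numeric vectors with entries
#'   `tau_rise`, `tau_fall`, `e_rev`, `g_peak`
#' @return object of class `synapse_params` (list keyed by receptor)
#' @export
synapse_params <- function(ampa = c(tau_rise = 0.05, tau_fall = 5.3,
                                    e_rev = 0, g_peak = 0.1),
                           nmda = c(tau_rise = 15, tau_fall = 150,
                                    e_rev = 0, g_peak = 0.03),
                           gabaa = c(tau_rise = 0.07, tau_fall = 18.2,
                                     e_rev = -80, g_peak = 0.5),
                           gabab = c(tau_rise = 3.5, tau_fall = 260.9,
                                     e_rev = -93, g_peak = 0.5)) {
  p <- list(AMPA = ampa, NMDA = nmda, GABAa = gabaa, GABAb = gabab)
  for (r in names(p)) {
    q <- p[[r]]
    if (!(q[["tau_fall"]] > q[["tau_rise"]] && q[["tau_rise"]] > 0))
      stop(r, ": need tau_fall > tau_rise > 0")
    if (q[["g_peak"]] <= 0) stop(r, ": g_peak must be positive")
  }
  structure(p, class = "synapse_params")
}

#' Synapse-mixture fractions
#'
#' @param f_nmda fraction of NMDA relative to AMPA conductance
#' @param f_gabaa fraction of GABAa relative to GABAb
#' @param f_ex excitatory fraction of all synapses
#' @param mg extracellular magnesium, mmol (NMDA gating)
#' @return object of class `synapse_fractions`
#' @export
synapse_fractions <- function(f_nmda = 0.5, f_gabaa = 0.95, f_ex = 0.5,
                              mg = 1) {
  stopifnot(f_nmda >= 0, f_nmda <= 1, f_gabaa >= 0, f_gabaa <= 1,
            f_ex >= 0, f_ex <= 1, mg >= 0)
  structure(list(f_nmda = f_nmda, f_gabaa = f_gabaa, f_ex = f_ex, mg = mg),
            class = "synapse_fractions")
}

#' Double-exponential conductance kernel
#'
#' `K(t) = (g_peak / N) (exp(-t/tau_fall) - exp(-t/tau_rise))` with the
#' normalizer `N` chosen so the kernel peaks at exactly `g_peak`, at
#' `t_max = tau_rise tau_fall / (tau_fall - tau_rise) *
#' log(tau_fall / tau_rise)`.
#'
#' @param receptor one of `"AMPA"`, `"NMDA"`, `"GABAa"`, `"GABAb"`
#' @param params a [synapse_params()] set
#' @param t_grid times, ms (kernel is 0 for t < 0)
#' @return numeric vector of conductances, uS
#' @export
double_exp_kernel <- function(receptor, params = synapse_params(), t_grid) {
  q <- params[[match.arg(receptor, names(params))]]
  tr <- q[["tau_rise"]]; tf <- q[["tau_fall"]]
  if (tf <= tr) stop("degenerate kernel: tau_fall must exceed tau_rise")
  tmax <- tr * tf / (tf - tr) * log(tf / tr)
  N <- exp(-tmax / tf) - exp(-tmax / tr)
  k <- q[["g_peak"]] / N * (exp(-t_grid / tf) - exp(-t_grid / tr))
  k[t_grid < 0] <- 0
  k
}

#' NMDA magnesium-block gating factor
#'
#' `1 / (1 + 0.28 Mg exp(-0.062 v))`, in (0, 1\], strictly increasing in
#' the membrane potential `v`; identity when `Mg = 0`.
#'
#' @param v membrane potential, mV
#' @param mg magnesium concentration, mmol
#' @return unitless gating factor
#' @export
nmda_gate <- function(v, mg = 1) {
  1 / (1 + 0.28 * mg * exp(-0.062 * v))
}

#' Partial depth integral of a delay kernel
#'
#' Integrates the spike density over the depth window
#' `[z_center - dz/2, z_center + dz/2]` for every time bin. Kernel values
#' are per-bin densities of a histogram (piecewise constant in depth), so
#' the integral is the exact overlap-weighted sum, which conserves spike
#' counts when windows tile the kernel range. A window outside the kernel
#' range yields zeros (with a diagnostic attribute `outside`).
#'
#' @param kernel a [delay_kernel()]
#' @param z_center window centre, um
#' @param dz window width, um (default 50)
#' @return numeric vector over time bins, units 1/ms, with attribute
#'   `t_centers`
#' @export
partial_integral <- function(kernel, z_center, dz = 50) {
  lo <- z_center - dz / 2
  hi <- z_center + dz / 2
  ze <- kernel$z_edges
  overlap <- pmax(0, pmin(hi, ze[-1]) - pmax(lo, ze[-length(ze)]))
  outside <- hi <= ze[1] || lo >= ze[length(ze)]
  out <- as.numeric(crossprod(overlap, kernel$values))
  attr(out, "t_centers") <- .centers(kernel$t_edges)
  attr(out, "outside") <- outside
  out
}

#' Assign compartments of a placed cell to cortical depth bins
#'
#' The cell's soma is placed at cortical depth `soma_depth`; every
#' compartment then sits at `z = soma_depth + z'`. Dendritic compartments
#' are assigned to depth bins of width `dz` and weighted by membrane area
#' over the total membrane area in their bin (weights in a nonempty bin
#' sum to 1).
#'
#' @param model a [compartmentalize()] model
#' @param soma_depth cortical depth of the soma, um (negative below CSF)
#' @param dz bin width, um
#' @param z_range cortical column range, um
#' @return list: `bin` (per-compartment index, NA for non-dendrites or
#'   out-of-column), `weight` (A/A_bin), `bin_centers`, `bin_area`
#' @export
bin_assignment <- function(model, soma_depth, dz = 50,
                           z_range = c(-2700, 0)) {
  comps <- model$comps
  edges <- seq(z_range[1], z_range[2], by = dz)
  z <- soma_depth + comps$z_prime
  dend <- comps$kind %in% c("basal_dendrite", "apical_dendrite")
  bin <- rep(NA_integer_, nrow(comps))
  bin[dend] <- .bin_index(z[dend], edges)
  area <- comps$area_membrane
  bin_area <- rep(0, length(edges) - 1)
  agg <- tapply(area[!is.na(bin)], bin[!is.na(bin)], sum)
  bin_area[as.integer(names(agg))] <- agg
  weight <- rep(0, nrow(comps))
  ok <- !is.na(bin)
  weight[ok] <- area[ok] / bin_area[bin[ok]]
  list(bin = bin, weight = weight, bin_centers = .centers(edges),
       bin_edges = edges, bin_area = bin_area)
}

#' Per-receptor synaptic conductances for one compartment
#'
#' Implements the mixture rules: AMPA gets `(1 - f_nmda) f_ex`, NMDA
#' `f_nmda f_ex` of the excitatory drive; GABAa `f_gabaa (1 - f_ex)`,
#' GABAb `(1 - f_gabaa)(1 - f_ex)` of the inhibitory drive; each drive is
#' the causal convolution (dt-scaled, so units stay uS) of the receptor's
#' double-exponential kernel with the bin's spike-arrival rate, scaled by
#' the compartment's area weight `A / A_bin`.
#'
#' @param k_ex,k_inh excitatory/inhibitory bin spike rates over `t_grid`
#'   (1/ms, from [partial_integral()]), nonnegative
#' @param fractions a [synapse_fractions()]
#' @param area_weight compartment membrane area over bin area
#' @param params a [synapse_params()]
#' @param t_grid uniform time grid, ms
#' @return matrix (length(t_grid) x 4), columns AMPA, NMDA, GABAa, GABAb,
#'   uS
#' @export
compartment_conductances <- function(k_ex, k_inh, fractions, area_weight = 1,
                                     params = synapse_params(),
                                     t_grid) {
  if (any(k_ex < 0) || any(k_inh < 0))
    stop("kernel inputs must be nonnegative")
  dt <- t_grid[2] - t_grid[1]
  pre <- c(AMPA = (1 - fractions$f_nmda) * fractions$f_ex,
           NMDA = fractions$f_nmda * fractions$f_ex,
           GABAa = fractions$f_gabaa * (1 - fractions$f_ex),
           GABAb = (1 - fractions$f_gabaa) * (1 - fractions$f_ex))
  out <- sapply(names(pre), function(r) {
    drive <- if (r %in% c("AMPA", "NMDA")) k_ex else k_inh
    ks <- double_exp_kernel(r, params, t_grid)
    area_weight * pre[[r]] * .causal_conv(ks, drive, dt)
  })
  matrix(out, nrow = length(t_grid), dimnames = list(NULL, names(pre)))
}

## causal discrete convolution truncated to the input window, dt-scaled;
## inputs are nonnegative conductance kernels and spike rates, so FFT
## roundoff below zero is clamped
.causal_conv <- function(k, x, dt) {
  n <- length(x)
  full <- convolve(k, rev(x), type = "open") * dt
  pmax(full[seq_len(n)], 0)
}

#' Somatic axial current from adjacent dendritic compartments
#'
#' `I = -sum_i (A_i / R_i) (V_soma - V_i) / L_i`, summed over dendritic
#' compartments attached to the soma, with `A_i` the cross-sectional area
#' (um^2), `R_i` the axial resistivity (Ohm cm) and `L_i` the
#' centre-to-centre path length (um). Sign convention: current flowing
#' into the soma is positive. Unit bookkeeping gives
#' `I[nA] = 100 * A V / (R L)` in the units above.
#'
#' @param state a [simulate_cable()] state recording the soma and its
#'   dendritic children
#' @param model the corresponding [compartmentalize()] model
#' @return numeric vector I(t) in nA over `state$t_grid`
#' @export
soma_axial_current <- function(state, model) {
  comps <- model$comps
  soma <- which(comps$kind == "soma")[1]
  kids <- which(comps$parent == soma &
                comps$kind %in% c("basal_dendrite", "apical_dendrite"))
  if (length(kids) == 0) {
    warning("soma has no adjacent dendritic compartment; current is 0")
    return(rep(0, length(state$t_grid)))
  }
  rows <- match(c(soma, kids), state$record)
  if (anyNA(rows)) stop("soma/adjacent compartments were not recorded")
  vs <- state$v[rows[1], ]
  I <- rep(0, length(state$t_grid))
  for (j in seq_along(kids)) {
    i <- kids[j]
    L <- (comps$length[soma] + comps$length[i]) / 2   # centre-to-centre, um
    vi <- state$v[rows[j + 1], ]
    I <- I - 100 * comps$area_cross[i] /
      (comps$axial_resistivity[i] * L) * (vs - vi)
  }
  I
}

#' Single synapto-dendritic delay simulation
#'
#' Places a postsynaptic cell at `soma_depth`, converts the excitatory and
#' inhibitory population kernels into per-bin conductance drives
#' (convolution of the receptor kernels with the bin spike rates), runs the
#' sodium-quenched cable simulation, and returns the baseline-subtracted
#' somatic axial current. The baseline is the same simulation with zero
#' synaptic input on the same cell at the same depth, so a zero-input run
#' returns an identically zero current.
#'
#' @param post_model postsynaptic [compartmentalize()] model
#' @param kernel_ex,kernel_inh cortical-domain [delay_kernel()]s
#' @param fractions a [synapse_fractions()]
#' @param soma_depth cortical depth of the soma, um
#' @param channels a [hh_channels()] set (sodium is quenched on soma and
#'   axon before simulating)
#' @param config a [cable_config()] (dendritic default: dt 0.01 ms,
#'   100 ms)
#' @param params a [synapse_params()]
#' @param dz conductance bin width, um
#' @return object of class `dendritic_current`: `t` (ms), `I` (nA,
#'   baseline-subtracted), provenance and the unreceived-input tally
#'   (kernel mass falling in bins with no dendritic membrane)
#' @export
run_dendritic <- function(post_model, kernel_ex, kernel_inh,
                          fractions = synapse_fractions(),
                          soma_depth = -1584,
                          channels = hh_channels(),
                          config = cable_config(dt = 0.01, duration = 100),
                          params = synapse_params(), dz = 50) {
  for (k in list(kernel_ex, kernel_inh))
    if (k$domain != "cortical_z")
      stop("population kernels must be in the cortical (z) domain")
  channels <- quench_sodium(channels)
  nsteps <- round(config$duration / config$dt)
  t_grid <- seq(0, by = config$dt, length.out = nsteps + 1)

  asn <- bin_assignment(post_model, soma_depth, dz = dz)
  nbins <- length(asn$bin_centers)

  ## bin spike rates on the simulation grid
  rate_on_grid <- function(kernel, zc) {
    Kz <- partial_integral(kernel, zc, dz)
    tc <- attr(Kz, "t_centers")
    y <- approx(tc, as.numeric(Kz), xout = t_grid, rule = 1)$y
    y[is.na(y)] <- 0
    pmax(y, 0)
  }
  pre <- c(AMPA = (1 - fractions$f_nmda) * fractions$f_ex,
           NMDA = fractions$f_nmda * fractions$f_ex,
           GABAa = fractions$f_gabaa * (1 - fractions$f_ex),
           GABAb = (1 - fractions$f_gabaa) * (1 - fractions$f_ex))
  kern <- lapply(c("AMPA", "NMDA", "GABAa", "GABAb"), double_exp_kernel,
                 params = params, t_grid = t_grid)
  names(kern) <- names(pre)
  e_rev <- vapply(params, function(q) q[["e_rev"]], numeric(1))

  bin_g <- lapply(names(pre), function(r) matrix(0, nbins, nsteps + 1))
  names(bin_g) <- names(pre)
  occupied <- which(asn$bin_area > 0)
  unreceived <- 0
  for (b in seq_len(nbins)) {
    kz_ex <- rate_on_grid(kernel_ex, asn$bin_centers[b])
    kz_in <- rate_on_grid(kernel_inh, asn$bin_centers[b])
    if (!(b %in% occupied)) {
      unreceived <- unreceived + sum(kz_ex + kz_in) * config$dt
      next
    }
    for (r in names(pre)) {
      drive <- if (r %in% c("AMPA", "NMDA")) kz_ex else kz_in
      bin_g[[r]][b, ] <- pre[[r]] *
        .causal_conv(kern[[r]], drive, config$dt)
    }
  }

  bin_for_core <- ifelse(is.na(asn$bin), 0L, asn$bin)
  syn <- list(bin_g = unname(bin_g), bin = bin_for_core,
              weight = asn$weight, e_rev = unname(e_rev),
              nmda_gated = TRUE, mg = fractions$mg)

  soma <- which(post_model$comps$kind == "soma")[1]
  kids <- which(post_model$comps$parent == soma &
                post_model$comps$kind %in% c("basal_dendrite",
                                             "apical_dendrite"))
  rec <- c(soma, kids)

  init <- settle_steady_state(post_model, channels, config)
  st <- simulate_cable(post_model, channels, config, init = init,
                       synapses = syn, record = rec)
  I <- soma_axial_current(st, post_model)
  st0 <- simulate_cable(post_model, channels, config, init = init,
                        synapses = NULL, record = rec)
  I0 <- soma_axial_current(st0, post_model)

  structure(list(t = t_grid, I = I - I0, baseline = I0,
                 baseline_subtracted = TRUE,
                 soma_depth = soma_depth, fractions = fractions,
                 unreceived_input = unreceived),
            class = "dendritic_current")
}

#' @export
print.dendritic_current <- function(x, ...) {
  cat("<dendritic_current> ", length(x$t), " samples over ",
      max(x$t), " ms; peak ", signif(max(x$I), 4), " nA\n", sep = "")
  invisible(x)
}

#' Density-weighted average of dendritic currents (depths x morphologies)
#'
#' Currents are first averaged over soma depths with weights proportional
#' to the postsynaptic cell density at each sampled depth (weights
#' normalized to 1, so the density's overall scale is irrelevant), then
#' averaged uniformly across morphologies.
#'
#' @param runs list (morphologies) of lists (depths) of
#'   [run_dendritic()] results on a common time grid; a flat list is
#'   treated as a single morphology
#' @param depth_weights density values at the sampled depths (recycled
#'   across morphologies)
#' @return a `dendritic_current` with the averaged trace
#' @export
average_current <- function(runs, depth_weights) {
  if (inherits(runs[[1]], "dendritic_current")) runs <- list(runs)
  stopifnot(all(depth_weights >= 0), sum(depth_weights) > 0)
  t0 <- runs[[1]][[1]]$t
  w <- depth_weights / sum(depth_weights)
  per_morph <- lapply(runs, function(morph_runs) {
    stopifnot(length(morph_runs) == length(w))
    for (r in morph_runs)
      if (length(r$t) != length(t0) || max(abs(r$t - t0)) > 1e-12)
        stop("dendritic currents are on different time grids")
    Reduce(`+`, Map(function(r, wi) r$I * wi, morph_runs, w))
  })
  I <- Reduce(`+`, per_morph) / length(per_morph)
  structure(list(t = t0, I = I, baseline_subtracted = TRUE,
                 n_morph = length(per_morph),
                 n_depths = length(w)),
            class = "dendritic_current")
}

#' Dendritic-current CSV import/export (columns t_ms, I_nA)
#' @param current a `dendritic_current`
#' @param path file path
#' @export
write_current <- function(current, path) {
  write.table(data.frame(t_ms = current$t, I_nA = current$I), path,
              sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_current
#' @export
read_current <- function(path) {
  d <- read.table(path, header = TRUE, sep = ",")
  structure(list(t = d$t_ms, I = d$I_nA, baseline_subtracted = TRUE),
            class = "dendritic_current")
}
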