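#' TMS electric field parameters
#'
#' The induced field at a cell is parameterized in spherical coordinates
#' relative to the somatodendritic axis: polar angle `theta` (degrees,
#' 0-180, angle between field and axis), azimuthal angle `phi` (degrees),
#' intensity `|E|` in V/m, and a relative gradient along z' in %/mm.
#' The magnitude at depth z' is `intensity * (1 + rel_gradient/100 *
#' z'_mm)`, anchored at the soma (z' = 0); the direction is global.
#'
#' @param theta polar angle, degrees in \[0, 180\]
#' @param phi azimuthal angle, degrees
#' @param intensity field magnitude at the soma, V/m (>= 0)
#' @param rel_gradient relative magnitude change per mm along z' (%/mm)
#' @param waveform_id identifier of the waveform used with this field
#' @return an object of class `field_params`
#' @export
field_params <- function(theta = 0, phi = 0, intensity = 100,
                         rel_gradient = 0, waveform_id = "biphasic") {
  stopifnot(theta >= 0, theta <= 180, intensity >= 0)
  structure(list(theta = theta, phi = phi %% 360, intensity = intensity,
                 rel_gradient = rel_gradient, waveform_id = waveform_id),
            class = "field_params")
}

#' Normalized biphasic TMS coil-current waveform
#'
#' A damped sinusoid `w(t) = exp(-t/damping_tau) * sin(2 pi f t)`,
#' peak-normalized so `max |w| = 1` and `w(0) = 0`. The defaults (2.5 kHz,
#' 0.4 ms damping) give one dominant full cycle of about 0.4 ms, the shape
#' of standard figure-of-eight biphasic stimulators.
#'
#' @param frequency carrier frequency, kHz
#' @param damping_tau damping time constant, ms
#' @param dt sample step, ms
#' @param duration waveform support, ms
#' @return object of class `waveform`: `t` (ms), `w` (unitless), plus the
#'   shape parameters
#' @export
biphasic_waveform <- function(frequency = 2.5, damping_tau = 0.4,
                              dt = 0.005, duration = 1.2) {
  stopifnot(frequency > 0, dt > 0, damping_tau > 0, duration > 0)
  if (duration < 1 / frequency)
    warning("waveform duration shorter than one period (", 1 / frequency,
            " ms)")
  t <- seq(0, duration, by = dt)
  w <- exp(-t / damping_tau) * sin(2 * pi * frequency * t)
  w <- w / max(abs(w))
  structure(list(t = t, w = w, dt = dt, duration = duration,
                 family = "biphasic", frequency = frequency,
                 damping_tau = damping_tau),
            class = "waveform")
}

#' Waveform CSV import/export (columns t_ms, w)
#' @param wf a `waveform`
#' @param path file path
#' @return `read_waveform` returns a `waveform`; `write_waveform` its path
#' @export
write_waveform <- function(wf, path) {
  write.table(data.frame(t_ms = wf$t, w = wf$w), path, sep = ",",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_waveform
#' @export
read_waveform <- function(path) {
  d <- read.table(path, header = TRUE, sep = ",")
  dt <- diff(d$t_ms)
  structure(list(t = d$t_ms, w = d$w, dt = dt[1], duration = max(d$t_ms),
                 family = "imported", frequency = NA, damping_tau = NA),
            class = "waveform")
}

#' Field vector at a soma-relative depth
#'
#' @param fp a [field_params()]
#' @param z_prime soma-relative depth(s), um
#' @return matrix (length(z_prime) x 3) of field vectors in V/m, in the
#'   soma-relative frame whose third axis is the somatodendritic axis.
#'   Magnitudes that the gradient would drive negative are clamped to 0
#'   (with a diagnostic attribute `n_clamped`).
#' @export
field_vector <- function(fp, z_prime = 0) {
  th <- fp$theta * pi / 180
  ph <- fp$phi * pi / 180
  dir <- c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  mag <- fp$intensity * (1 + fp$rel_gradient / 100 * z_prime / 1000)
  ncl <- sum(mag < 0)
  mag[mag < 0] <- 0
  out <- outer(mag, dir)
  attr(out, "n_clamped") <- ncl
  out
}

#' Extracellular quasipotential of a compartment model in a field
#'
#' The quasipotential psi is minus the line integral of the induced field
#' along the cable, accumulated from the root through the tree with a
#' midpoint-rule contribution per compartment, and is continuous across
#' branch points. Only differences of psi are physical: any global
#' constant leaves the membrane dynamics unchanged. Units: mV
#' (V/m x um x 1e-3).
#'
#' @param model a [compartmentalize()] result
#' @param fp a [field_params()]
#' @return object of class `quasipotential`: `psi` (mV per compartment at
#'   unit waveform factor) and the field parameters
#' @export
quasipotential <- function(model, fp) {
  comps <- model$comps
  n <- nrow(comps)
  stopifnot(n > 0)
  E <- field_vector(fp, comps$z_prime)        # V/m per compartment (midpoint)
  dirs <- as.matrix(comps[, c("dx", "dy", "dz")])
  ## map morphology frame -> soma-relative frame: the somatodendritic axis
  ## is the third basis vector; build an orthonormal triad around it
  a3 <- model$axis
  ref <- if (abs(a3[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  a1 <- ref - sum(ref * a3) * a3
  a1 <- a1 / sqrt(sum(a1^2))
  a2 <- c(a3[2] * a1[3] - a3[3] * a1[2],
          a3[3] * a1[1] - a3[1] * a1[3],
          a3[1] * a1[2] - a3[2] * a1[1])
  B <- rbind(a1, a2, a3)                      # rows: frame basis in xyz
  dirs_f <- dirs %*% t(B)                     # directions in field frame
  ## -E . dl per compartment (midpoint rule), mV
  dpsi <- -rowSums(E * dirs_f) * comps$length * 1e-3
  psi <- numeric(n)
  for (i in seq_len(n)) {
    p <- comps$parent[i]
    if (p == 0) {
      psi[i] <- 0
    } else {
      ## half steps: parent's second half plus own first half
      pstep <- -sum(E[p, ] * dirs_f[p, ]) * comps$length[p] / 2 * 1e-3
      ostep <- -sum(E[i, ] * dirs_f[i, ]) * comps$length[i] / 2 * 1e-3
      psi[i] <- psi[p] + pstep + ostep
    }
  }
  structure(list(psi = psi, field_params = fp, dpsi = dpsi),
            class = "quasipotential")
}

#' Per-compartment extracellular potential time series
#'
#' `v_ext_i(t) = psi_i * w(t)`; zero outside the waveform support.
#'
#' @param profile a [quasipotential()]
#' @param wf a [biphasic_waveform()] (or imported waveform)
#' @param t_grid time grid, ms (must cover the waveform support)
#' @return matrix (n_compartments x length(t_grid)), mV
#' @export
stimulus_timeseries <- function(profile, wf, t_grid) {
  stopifnot(max(t_grid) >= max(wf$t))
  w <- approx(wf$t, wf$w, xout = t_grid, rule = 1)$y
  w[is.na(w)] <- 0
  outer(profile$psi, w)
}

#' Waveform factor sampled on a time grid (zero outside support)
#' @param wf a waveform
#' @param t_grid times, ms
#' @return numeric vector
#' @export
waveform_samples <- function(wf, t_grid) {
  w <- approx(wf$t, wf$w, xout = t_grid, rule = 1)$y
  w[is.na(w)] <- 0
  w
}
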