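#' Detect action-potential arrivals at axon terminals
#'
#' For every terminal compartment, the first upward crossing of 0 mV after
#' stimulus onset is recorded, with the crossing time linearly interpolated
#' between samples. At most one arrival per terminal (the first); terminals
#' that never cross are omitted.
#'
#' @param state a [simulate_cable()] result covering the terminals
#' @param model the [compartmentalize()] model the state was computed on
#' @return data frame with columns `terminal_id`, `z_prime` (um), `t` (ms)
#' @export
detect_arrivals <- function(state, model) {
  ids <- model$terminal_ids
  rows <- match(ids, state$record)
  if (anyNA(rows)) stop("terminal compartments were not recorded")
  t_grid <- state$t_grid
  out <- lapply(seq_along(ids), function(k) {
    tr <- state$v[rows[k], ]
    up <- which(tr[-1] >= 0 & tr[-length(tr)] < 0)
    if (length(up) == 0) return(NULL)
    j <- up[1]
    tc <- t_grid[j] + (t_grid[j + 1] - t_grid[j]) * (0 - tr[j]) /
      (tr[j + 1] - tr[j])
    data.frame(terminal_id = ids[k],
               z_prime = model$comps$z_prime[ids[k]], t = tc)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(terminal_id = integer(0), z_prime = numeric(0),
                      t = numeric(0))
  out
}

#' Construct a delay-kernel object
#'
#' A delay kernel is a 2D spike-density function over (depth, time): counts
#' per bin divided by the bin area `dz * dt`, so units are 1/(ms um). The
#' depth axis is either soma-relative (`z'`, domain tag
#' `"soma_relative_zprime"`) or cortical depth (`z`, tag `"cortical_z"`).
#'
#' @param values nz x nt density matrix (>= 0)
#' @param z_edges,t_edges strictly increasing bin edges (um, ms)
#' @param domain depth-axis domain tag
#' @param n_cells_averaged,scaling_ratio provenance metadata
#' @param overflow count of arrivals that fell outside the grid
#' @return object of class `delay_kernel`
#' @export
delay_kernel <- function(values, z_edges, t_edges,
                         domain = c("soma_relative_zprime", "cortical_z"),
                         n_cells_averaged = 1, scaling_ratio = 1,
                         overflow = 0) {
  domain <- match.arg(domain)
  values <- as.matrix(values)
  stopifnot(all(diff(z_edges) > 0), all(diff(t_edges) > 0),
            nrow(values) == length(z_edges) - 1,
            ncol(values) == length(t_edges) - 1,
            all(values >= 0))
  structure(list(values = values, z_edges = as.numeric(z_edges),
                 t_edges = as.numeric(t_edges), domain = domain,
                 n_cells_averaged = n_cells_averaged,
                 scaling_ratio = scaling_ratio, overflow = overflow),
            class = "delay_kernel")
}

#' @export
print.delay_kernel <- function(x, ...) {
  cat("<delay_kernel> ", nrow(x$values), " z-bins x ", ncol(x$values),
      " t-bins (", x$domain, ")\n", sep = "")
  cat("  z in [", min(x$z_edges), ", ", max(x$z_edges), "] um; t in [",
      min(x$t_edges), ", ", max(x$t_edges), "] ms; total spikes ",
      signif(kernel_spike_count(x), 6), "\n", sep = "")
  invisible(x)
}

#' Total spike count under a kernel (density x bin area)
#' @param kernel a [delay_kernel()]
#' @return scalar count
#' @export
kernel_spike_count <- function(kernel) {
  dz <- diff(kernel$z_edges)
  dt <- diff(kernel$t_edges)
  sum(kernel$values * outer(dz, dt))
}

#' Bin spike arrivals into a 2D delay histogram
#'
#' Bins are left-closed, right-open, with the final bin right-closed, on
#' both axes. Counts are divided by `dz * dt` to yield density. Arrivals
#' outside the grid are tallied in the `overflow` field, never silently
#' dropped.
#'
#' @param arrivals a [detect_arrivals()] data frame
#' @param z_edges depth-bin edges, um (default the soma-relative grid
#'   \[-2000, 500\] in 100 um steps)
#' @param t_edges time-bin edges, ms (default \[0, 3\] in 0.1 ms steps)
#' @param domain depth-axis domain tag of `z_edges`
#' @return a [delay_kernel()]
#' @export
build_histogram <- function(arrivals, z_edges = seq(-2000, 500, by = 100),
                            t_edges = seq(0, 3, by = 0.1),
                            domain = "soma_relative_zprime") {
  stopifnot(all(diff(z_edges) > 0), all(diff(t_edges) > 0))
  nz <- length(z_edges) - 1L
  nt <- length(t_edges) - 1L
  counts <- matrix(0, nz, nt)
  over <- 0L
  if (nrow(arrivals) > 0) {
    iz <- .bin_index(arrivals$z_prime, z_edges)
    it <- .bin_index(arrivals$t, t_edges)
    ok <- !is.na(iz) & !is.na(it)
    over <- sum(!ok)
    for (k in which(ok)) counts[iz[k], it[k]] <- counts[iz[k], it[k]] + 1
  }
  dens <- counts / outer(diff(z_edges), diff(t_edges))
  delay_kernel(dens, z_edges, t_edges, domain = domain, overflow = over)
}

## left-closed right-open bins; last bin right-closed; NA outside
.bin_index <- function(x, edges) {
  i <- findInterval(x, edges, rightmost.closed = TRUE)
  i[i < 1 | i > length(edges) - 1] <- NA_integer_
  i
}

#' Weighted average of delay kernels on a common grid
#'
#' Used for the azimuthal-rotation average, the within-type morphology
#' average, and the subtype average with relative-frequency weights (which
#' are normalized internally).
#'
#' @param kernels list of [delay_kernel()]s on identical grids
#' @param weights nonnegative weights, not all zero (default equal)
#' @return the weighted-mean `delay_kernel`
#' @export
average_kernels <- function(kernels, weights = NULL) {
  stopifnot(length(kernels) >= 1)
  if (is.null(weights)) weights <- rep(1, length(kernels))
  stopifnot(length(weights) == length(kernels), all(weights >= 0),
            sum(weights) > 0)
  ref <- kernels[[1]]
  for (k in kernels[-1]) {
    if (!isTRUE(all.equal(k$z_edges, ref$z_edges)) ||
        !isTRUE(all.equal(k$t_edges, ref$t_edges)) ||
        k$domain != ref$domain)
      stop("kernel grids/domains do not match")
  }
  w <- weights / sum(weights)
  vals <- Reduce(`+`, Map(function(k, wi) k$values * wi, kernels, w))
  delay_kernel(vals, ref$z_edges, ref$t_edges, domain = ref$domain,
               n_cells_averaged = sum(vapply(kernels,
                                             function(k) k$n_cells_averaged,
                                             numeric(1))),
               overflow = sum(vapply(kernels, function(k) k$overflow,
                                     numeric(1))))
}

#' Resample a delay kernel with monotone (pchip) interpolation
#'
#' Separable piecewise cubic Hermite interpolation on bin centres, first
#' along depth then along time. pchip preserves monotonicity between knots
#' and cannot overshoot, so a nonnegative kernel stays nonnegative and
#' resampling at the original grid reproduces the input.
#'
#' @param kernel a [delay_kernel()]
#' @param dz_out,dt_out output bin widths (um, ms); must not exceed the
#'   input widths
#' @return the resampled `delay_kernel`
#' @export
resample_kernel <- function(kernel, dz_out, dt_out) {
  dz_in <- diff(kernel$z_edges)[1]
  dt_in <- diff(kernel$t_edges)[1]
  stopifnot(dz_out <= dz_in + 1e-12, dt_out <= dt_in + 1e-12)
  zc_in <- .centers(kernel$z_edges)
  tc_in <- .centers(kernel$t_edges)
  z_edges <- seq(min(kernel$z_edges), max(kernel$z_edges), by = dz_out)
  t_edges <- seq(min(kernel$t_edges), max(kernel$t_edges), by = dt_out)
  zc <- .centers(z_edges)
  tc <- .centers(t_edges)
  interp1d <- function(xi, yi, xq) {
    ## pchip needs >= 3 knots; constant/linear fallbacks below
    if (length(xi) == 1) return(rep(yi, length(xq)))
    xq <- pmin(pmax(xq, min(xi)), max(xi))
    if (length(xi) == 2) return(approx(xi, yi, xout = xq)$y)
    pracma::pchip(xi, yi, xq)
  }
  tmp <- apply(kernel$values, 2, function(col) interp1d(zc_in, col, zc))
  tmp <- matrix(tmp, nrow = length(zc))
  out <- t(apply(tmp, 1, function(row) interp1d(tc_in, row, tc)))
  out <- matrix(out, nrow = length(zc))
  out[out < 0] <- 0   # guard against fp noise; pchip itself cannot overshoot
  delay_kernel(out, z_edges, t_edges, domain = kernel$domain,
               n_cells_averaged = kernel$n_cells_averaged,
               scaling_ratio = kernel$scaling_ratio,
               overflow = kernel$overflow)
}

.centers <- function(edges) (edges[-1] + edges[-length(edges)]) / 2

#' Cell-density profile over cortical depth
#'
#' @param density per-bin density values (>= 0) on the cortical z grid
#' @param z_edges cortical-depth bin edges, um (0 at the CSF boundary,
#'   negative downward)
#' @param normalize divide by the sum so that `sum(d) = 1` (required for
#'   spike-count-preserving population kernels)
#' @return object of class `cell_density`
#' @export
cell_density <- function(density, z_edges = seq(-2700, 0, by = 100),
                         normalize = TRUE) {
  stopifnot(length(density) == length(z_edges) - 1, all(density >= 0),
            sum(density) > 0)
  d <- as.numeric(density)
  if (normalize) d <- d / sum(d)
  structure(list(d = d, z_edges = as.numeric(z_edges),
                 normalized = normalize),
            class = "cell_density")
}

#' Truncated-Gaussian layer density
#'
#' A unimodal density over cortical depth, clipped to the layer bounds and
#' zero elsewhere; the default band \[-783, -270\] um is the L2/3 band of a
#' 2700-um human motor cortical column.
#'
#' @param mean,sd Gaussian parameters, um (defaults centre the L2/3 band)
#' @param bounds length-2 layer bounds (um, lower then upper)
#' @param z_edges grid edges, um
#' @return a normalized [cell_density()]
#' @export
layer_density <- function(mean = -526.5, sd = 120,
                          bounds = c(-783, -270),
                          z_edges = seq(-2700, 0, by = 100)) {
  zc <- .centers(z_edges)
  d <- exp(-(zc - mean)^2 / (2 * sd^2))
  d[zc < bounds[1] | zc > bounds[2]] <- 0
  cell_density(d, z_edges)
}

#' Density CSV import/export (columns z_center_um, density)
#' @param density a `cell_density`
#' @param path file path
#' @export
write_density <- function(density, path) {
  write.table(data.frame(z_center_um = .centers(density$z_edges),
                         density = density$d),
              path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_density
#' @export
read_density <- function(path) {
  d <- read.table(path, header = TRUE, sep = ",")
  dz <- diff(d$z_center_um)[1]
  edges <- c(d$z_center_um - dz / 2, max(d$z_center_um) + dz / 2)
  cell_density(d$density, edges)
}

#' Population kernel: depth cross-correlation with the cell density
#'
#' Converts a per-cell kernel r(z', t) into the kernel k(z, t) of a
#' population of identical cells whose somata are distributed over
#' cortical depth with density d(z): per time column,
#' `k_i = sum_n d_(i - n + n0) r_n`, where `n0` is the index of the z' bin
#' containing the soma (z' = 0). A delta density at depth z0 therefore
#' reproduces the cell kernel re-based with its soma at z0, and for z'
#' grids symmetric about 0 the alignment coincides with the centred
#' 'same'-mode crop of the full correlation. The density must be
#' normalized, which preserves the total spike count whenever the
#' correlation support stays inside the cortical grid; mass pushed outside
#' is dropped and reported in the `overflow` field. The result is scaled
#' by the presynaptic/postsynaptic cell-count ratio.
#'
#' @param cell_kernel a soma-relative [delay_kernel()]
#' @param density a normalized [cell_density()] (same bin width as the
#'   kernel's z' grid)
#' @param count_ratio presynaptic-to-postsynaptic cell-count ratio (e.g.
#'   5.04 for an excitatory and 0.40 for an inhibitory projection)
#' @return a cortical-domain `delay_kernel` on the density's z grid
#' @export
population_kernel <- function(cell_kernel, density, count_ratio = 1) {
  stopifnot(inherits(cell_kernel, "delay_kernel"),
            inherits(density, "cell_density"))
  if (cell_kernel$domain != "soma_relative_zprime")
    stop("cell_kernel must be in the soma-relative domain")
  if (!density$normalized || abs(sum(density$d) - 1) > 1e-9)
    stop("density must be normalized (sum to 1)")
  dz_k <- diff(cell_kernel$z_edges)[1]
  dz_d <- diff(density$z_edges)[1]
  if (abs(dz_k - dz_d) > 1e-9)
    stop("kernel and density depth-bin widths differ")
  r <- cell_kernel$values
  nr <- nrow(r)
  nd <- length(density$d)
  n0 <- .bin_index(0, cell_kernel$z_edges)
  if (is.na(n0)) n0 <- (nr - 1L) %/% 2L + 1L  # centred fallback
  ## k_i = sum_n d_(i - (n - n0)) * r_n : accumulate shifted copies of r
  out <- matrix(0, nd, ncol(r))
  lost <- 0
  for (m in seq_len(nd)) {          # density bin m (soma depth)
    if (density$d[m] == 0) next
    i <- m + (seq_len(nr) - n0)     # output bins receiving r rows
    ok <- i >= 1 & i <= nd
    out[i[ok], ] <- out[i[ok], ] + density$d[m] * r[ok, , drop = FALSE]
    lost <- lost + density$d[m] * sum(r[!ok, , drop = FALSE])
  }
  delay_kernel(out * count_ratio, density$z_edges, cell_kernel$t_edges,
               domain = "cortical_z",
               n_cells_averaged = cell_kernel$n_cells_averaged,
               scaling_ratio = count_ratio,
               overflow = lost * prod(dz_k, diff(cell_kernel$t_edges)[1]))
}

#' Collapse the depth axis of a cortical kernel
#'
#' Arithmetic mean over z bins per time bin, producing the time-dependent
#' spike-density profile used for polar summaries and point-neuron drive.
#'
#' @param kernel a cortical-domain [delay_kernel()]
#' @return data frame with `t` (bin centres, ms) and `density`
#' @export
collapse_depth <- function(kernel) {
  if (kernel$domain != "cortical_z")
    stop("collapse_depth expects a cortical-domain kernel")
  data.frame(t = .centers(kernel$t_edges), density = colMeans(kernel$values))
}

#' Kernel CSV serialization (values matrix + JSON sidecar with axes)
#'
#' @param kernel a [delay_kernel()]
#' @param path base path; writes `<path>.csv` and `<path>.json`
#' @export
write_kernel <- function(kernel, path) {
  write.table(kernel$values, paste0(path, ".csv"), sep = ",",
              row.names = FALSE, col.names = FALSE)
  meta <- kernel[c("z_edges", "t_edges", "domain", "n_cells_averaged",
                   "scaling_ratio", "overflow")]
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_kernel
#' @export
read_kernel <- function(path) {
  vals <- as.matrix(read.table(paste0(path, ".csv"), sep = ","))
  dimnames(vals) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  delay_kernel(vals, meta$z_edges, meta$t_edges, domain = meta$domain,
               n_cells_averaged = meta$n_cells_averaged,
               scaling_ratio = meta$scaling_ratio, overflow = meta$overflow)
}
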