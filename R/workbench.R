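#' Default pipeline configuration
#'
#' One nested list holding every physical default the pipeline uses: the
#' inhibitory subtype weights, the excitatory/inhibitory cell-count ratios
#' (5.04 and 0.40 relative to the postsynaptic population), the 2700-um
#' cortical column with its L2/3 band, the synapse constants, the
#' surrogate bounds and truncation, and the numerical settings of both
#' simulation stages.
#'
#' @param n_phi number of azimuthal rotations averaged per morphology
#' @param seed master seed recorded in every manifest
#' @return nested configuration list
#' @export
default_pipeline_config <- function(n_phi = 60L, seed = 1L) {
  list(
    seed = as.integer(seed),
    field = list(theta = c(0, 45, 90, 135, 180), intensity = c(175, 225),
                 rel_gradient = 0,
                 waveform = list(frequency = 2.5, damping_tau = 0.4,
                                 dt = 0.005, duration = 1.2)),
    phi_count = as.integer(n_phi),
    populations = list(
      subtype_weights = c(LBC_dNAC = 0.245, LBC_cSTUT = 0.165,
                          LBC_cACint = 0.117, NBC_dNAC = 0.191,
                          NBC_cACint = 0.053, SBC_bNAC = 0.112,
                          SBC_cACint = 0.117),
      count_ratio_ex = 5.04, count_ratio_inh = 0.40,
      column_depth = 2700, l23_bounds = c(-783, -270),
      n_depth_samples = 25L, n_morph = 30L),
    axonal = list(dt = 0.025, duration = 3, dz = 100, dt_bin = 0.1),
    dendritic = list(dt = 0.01, duration = 100, dz = 50),
    surrogate = list(n_train = 4000L, n_test = 1000L,
                     t_end = 100, dt = 0.2)
  )
}

#' Read/write a pipeline configuration as YAML
#' @param config a configuration list
#' @param path file path
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) yaml::read_yaml(path)

.manifest <- function(stage, config, extra = list()) {
  c(list(stage = stage, package_version = "0.1.0",
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
         seed = config$seed), extra)
}

#' Axonal stage: delay kernels for a set of morphologies and one field
#'
#' For each morphology and each of `n_phi` azimuthal rotations, settles
#' the cell, applies the field through its quasipotential, detects
#' terminal arrivals and histograms them; rotations and morphologies are
#' averaged into the per-cell kernel, which is then correlated with the
#' cell density and scaled by the count ratio into the population kernel.
#'
#' @param morphologies list of [morphology()] objects (one cell type)
#' @param fp a [field_params()]
#' @param density a [cell_density()] for the population stage
#' @param count_ratio presynaptic/postsynaptic cell-count ratio
#' @param n_phi azimuthal rotations (evenly spaced over 360 degrees)
#' @param channels,config cable settings ([hh_channels()],
#'   [cable_config()])
#' @param waveform a [biphasic_waveform()]
#' @param z_edges,t_edges histogram grids
#' @param max_len compartment length cap, um
#' @return list: `cell_kernel` (z' domain), `population_kernel` (z
#'   domain), `manifest`
#' @export
run_axonal_stage <- function(morphologies, fp, density,
                             count_ratio = 5.04, n_phi = 12L,
                             channels = hh_channels(),
                             config = cable_config(),
                             waveform = biphasic_waveform(),
                             z_edges = seq(-2000, 500, by = 100),
                             t_edges = NULL, max_len = 20) {
  if (is.null(t_edges)) t_edges <- seq(0, config$duration, by = 0.1)
  phis <- seq(0, 360 - 360 / n_phi, length.out = n_phi)
  n_runs <- 0L
  per_morph <- lapply(morphologies, function(m) {
    per_phi <- lapply(phis, function(phi) {
      model <- compartmentalize(rotate_azimuthal(m, phi), max_len = max_len)
      init <- settle_steady_state(model, channels, config)
      qp <- quasipotential(model, fp)
      st <- simulate_cable(model, channels, config, init = init,
                           stimulus = list(psi = qp, waveform = waveform),
                           record = model$terminal_ids)
      n_runs <<- n_runs + 1L
      build_histogram(detect_arrivals(st, model), z_edges, t_edges)
    })
    average_kernels(per_phi)
  })
  cell_kernel <- average_kernels(per_morph)
  pop_kernel <- population_kernel(cell_kernel, density, count_ratio)
  list(cell_kernel = cell_kernel, population_kernel = pop_kernel,
       manifest = list(stage = "axonal", n_cable_runs = n_runs,
                       n_phi = n_phi, n_morph = length(morphologies),
                       field = unclass(fp),
                       overflow = cell_kernel$overflow))
}

#' Dendritic stage: density-weighted average somatic current
#'
#' Runs [run_dendritic()] for every (morphology, depth) combination with
#' depths sampled equidistantly over the postsynaptic density's support
#' and averages with density weights.
#'
#' @param post_morphs list of postsynaptic [morphology()]s
#' @param kernel_ex,kernel_inh cortical-domain population kernels
#' @param density postsynaptic [cell_density()]
#' @param n_depths number of equidistant soma-depth samples
#' @param fractions,channels,config,params forwarded to [run_dendritic()]
#' @param max_len compartment length cap, um
#' @return list: `average` (a `dendritic_current`), `runs`, `manifest`
#' @export
run_dendritic_stage <- function(post_morphs, kernel_ex, kernel_inh,
                                density, n_depths = 5L,
                                fractions = synapse_fractions(),
                                channels = hh_channels(),
                                config = cable_config(dt = 0.01,
                                                      duration = 100),
                                params = synapse_params(),
                                max_len = 40) {
  support <- range(.centers(density$z_edges)[density$d > 0])
  depths <- seq(support[1], support[2], length.out = n_depths)
  w <- approx(.centers(density$z_edges), density$d, xout = depths,
              rule = 2)$y
  runs <- lapply(post_morphs, function(m) {
    model <- compartmentalize(m, max_len = max_len)
    lapply(depths, function(zd)
      run_dendritic(model, kernel_ex, kernel_inh, fractions,
                    soma_depth = zd, channels = channels, config = config,
                    params = params))
  })
  avg <- average_current(runs, w)
  unrec <- sum(vapply(unlist(runs, recursive = FALSE),
                      function(r) r$unreceived_input, numeric(1)))
  list(average = avg, runs = runs, depths = depths, weights = w,
       manifest = list(stage = "dendritic",
                       n_runs = length(post_morphs) * n_depths,
                       n_depths = n_depths, n_morph = length(post_morphs),
                       unreceived_input = unrec))
}

#' Surrogate stage: fit, validate and analyse a gPC over a response model
#'
#' @param response_fn function(params_matrix, t_grid) -> responses matrix;
#'   defaults to the packaged analytic current generator
#' @param bounds a [param_bounds()]
#' @param spec a [basis_spec()]
#' @param n_train,n_test training and held-out sample counts
#' @param seed integer seed (train and test draws use offset streams)
#' @param t_grid surrogate time grid
#' @return list: `model`, `nrmsd` (%), `sobol`, `derivatives`, `manifest`
#' @export
run_surrogate_stage <- function(response_fn = analytic_dendritic_current,
                                bounds = param_bounds(),
                                spec = basis_spec(),
                                n_train = 4000L, n_test = 1000L,
                                seed = 1L,
                                t_grid = surrogate_time_grid()) {
  x_tr <- sample_params(bounds, n_train, seed = seed)
  x_te <- sample_params(bounds, n_test, seed = seed + 1000003L)
  y_tr <- response_fn(x_tr, t_grid)
  y_te <- response_fn(x_te, t_grid)
  model <- fit_gpc(x_tr, y_tr, spec, bounds, t_grid = t_grid)
  err <- nrmsd(y_te, predict(model, x_te))
  sob <- sobol_indices(model)
  der <- derivative_sensitivity(model, n_mc = 1e4, seed = seed + 7L)
  list(model = model, nrmsd = as.numeric(err), sobol = sob,
       derivatives = der,
       manifest = list(stage = "surrogate", n_train = n_train,
                       n_test = n_test, n_basis = nrow(model$multi_indices),
                       nrmsd_percent = as.numeric(err), seed = seed,
                       rank_warning = model$rank_warning))
}

#' Smooth analytic dendritic-current generator (synthetic fixture)
#'
#' A closed-form, infinitely differentiable stand-in for the full
#' two-stage simulation, used to exercise the surrogate machinery at
#' scale. Its structure mirrors the simulated physics: a smooth
#' recruitment factor in intensity whose threshold depends on the field
#' angle (parallel and antiparallel fields recruit first), a weak linear
#' gradient modulation, an excitatory double-exponential current whose
#' kinetics slow and whose early amplitude drops as the NMDA fraction
#' grows, and fast/slow inhibitory components split by the GABAa
#' fraction. Intensity and excitatory-inhibitory balance dominate the
#' output variance, with a secondary angle-intensity interaction.
#'
#' @param params matrix (n x 6) with columns theta, rel_gradient,
#'   intensity, f_nmda, f_gabaa, f_ex (natural units), or a length-6
#'   vector
#' @param t_grid times, ms
#' @return matrix (n x length(t_grid)) of currents, nA
#' @export
analytic_dendritic_current <- function(params,
                                       t_grid = surrogate_time_grid()) {
  params <- matrix(params, ncol = 6)
  th <- params[, 1]; gr <- params[, 2]; E <- params[, 3]
  fN <- params[, 4]; fGa <- params[, 5]; fex <- params[, 6]
  uE <- (E - 100) / 300
  cth <- cos(th * pi / 180)
  ## recruitment: lower threshold for fields (anti)parallel to the axis
  thr <- 0.45 - 0.15 * cth^2
  act <- 0.5 * (1 + tanh(4 * (uE - thr)))
  gmod <- 1 + 0.1 * (gr / 20)
  n <- nrow(params)
  bump <- function(t, tr, td) {
    ## peak-normalized double exponential, smooth in tr, td
    tr <- rep(tr, length.out = n)
    td <- rep(td, length.out = n)
    tmax <- tr * td / (td - tr) * log(td / tr)
    (exp(-outer(1 / td, t)) - exp(-outer(1 / tr, t))) /
      (exp(-tmax / td) - exp(-tmax / tr))
  }
  tr_ex <- 1.5 + 3 * fN
  td_ex <- 8 + 25 * fN
  exc <- (1 - 0.35 * fN) * fex * bump(t_grid, tr_ex, td_ex)
  inh <- (1 - fex) * (0.85 * fGa * bump(t_grid, 2, 20) +
                      0.6 * (1 - fGa) * bump(t_grid, 8, 80))
  2.2 * act * gmod * (exc - 0.9 * inh)
}

#' Generate the synthetic fixture bundle
#'
#' Writes (to `dir`): three presynaptic and two postsynaptic SWC
#' morphologies, plus normalized truncated-Gaussian cell densities for the
#' superficial (L2/3 band) and deep (L5) populations, all derived from the
#' given seed. These are synthetic stand-ins generated by
#' [generate_morphology()], not reconstructions.
#'
#' @param seed integer seed
#' @param dir output directory (created if missing)
#' @return list of file paths plus the in-memory objects
#' @export
make_fixtures <- function(seed = 1L, dir = tempfile("fixtures")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pre <- lapply(seq_len(3), function(i)
    generate_morphology(synthetic_morph_spec(
      n_axon_terminals = 16L, rng_seed = seed * 100L + i)))
  post <- lapply(seq_len(2), function(i)
    generate_morphology(synthetic_morph_spec(
      n_axon_terminals = 6L, n_dendrite_tips = 8L,
      rng_seed = seed * 100L + 50L + i)))
  pre_paths <- file.path(dir, sprintf("presynaptic_synthetic_%d.swc", 1:3))
  post_paths <- file.path(dir, sprintf("postsynaptic_synthetic_%d.swc", 1:2))
  Map(write_swc, pre, pre_paths)
  Map(write_swc, post, post_paths)
  d_sup <- layer_density()                               # L2/3 band
  d_deep <- layer_density(mean = -1584, sd = 220, bounds = c(-2000, -1100))
  dens_paths <- file.path(dir, c("density_l23_synthetic.csv",
                                 "density_l5_synthetic.csv"))
  write_density(d_sup, dens_paths[1])
  write_density(d_deep, dens_paths[2])
  list(presynaptic = pre_paths, postsynaptic = post_paths,
       densities = dens_paths, pre = pre, post = post,
       density_sup = d_sup, density_deep = d_deep, dir = dir)
}
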