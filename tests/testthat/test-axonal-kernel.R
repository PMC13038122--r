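test_that("arrival detection interpolates the first upward 0 mV crossing", {
  model <- list(comps = data.frame(id = 1:2, kind = c("soma", "axon"),
                                   z_prime = c(0, -500)),
                terminal_ids = 2L)
  ## trace [-70, -10, +30] at dt = 0.1: crossing at 0.1 + 0.1 * 10/40
  st <- fake_state(matrix(c(-70, -70, -70, -10, -70, 30), nrow = 2),
                   t_grid = c(0, 0.1, 0.2), record = 1:2)
  ar <- detect_arrivals(st, model)
  expect_equal(ar$t, 0.125)
  expect_equal(ar$z_prime, -500)

  ## double crossing: only the first is kept
  st2 <- fake_state(matrix(c(-70, -70, -70, 10, -70, -5, -70, 20),
                           nrow = 2),
                    t_grid = seq(0, 0.3, by = 0.1), record = 1:2)
  ar2 <- detect_arrivals(st2, model)
  expect_equal(nrow(ar2), 1)
  expect_lt(ar2$t, 0.1)

  ## all subthreshold: empty result
  st3 <- fake_state(matrix(-70, 2, 4), t_grid = seq(0, 0.3, by = 0.1),
                    record = 1:2)
  expect_equal(nrow(detect_arrivals(st3, model)), 0)
})

test_that("histogram densities follow count / (dz dt) with overflow
           tallied and left-closed bins", {
  ar <- data.frame(terminal_id = 1:3, z_prime = c(-150, -150, -150),
                   t = c(0.55, 0.52, 0.58))
  k <- build_histogram(ar, z_edges = seq(-300, 0, 100),
                       t_edges = seq(0, 1, 0.1))
  expect_equal(max(k$values), 3 / (100 * 0.1))  # 0.3 spikes / (ms um)
  expect_equal(kernel_spike_count(k), 3)
  expect_equal(k$overflow, 0)

  ## arrival on an interior edge goes to the upper (right) bin
  k2 <- build_histogram(data.frame(terminal_id = 1, z_prime = -100,
                                   t = 0.5),
                        z_edges = seq(-300, 0, 100),
                        t_edges = seq(0, 1, 0.1))
  expect_equal(which(rowSums(k2$values) > 0), 3L)  # bin [-100, 0)
  expect_equal(which(colSums(k2$values) > 0), 6L)  # bin [0.5, 0.6)

  ## outside the grid: overflow, not dropped silently
  k3 <- build_histogram(data.frame(terminal_id = 1:2,
                                   z_prime = c(-150, 50), t = c(0.5, 2)),
                        z_edges = seq(-300, 0, 100),
                        t_edges = seq(0, 1, 0.1))
  expect_equal(k3$overflow, 1)
  expect_equal(kernel_spike_count(k3) + k3$overflow, 2)

  ## empty arrivals: all-zero kernel
  k4 <- build_histogram(detect_arrivals(
    fake_state(matrix(-70, 1, 3), c(0, 0.1, 0.2), record = 1L),
    list(comps = data.frame(id = 1, kind = "axon", z_prime = -1),
         terminal_ids = 1L)))
  expect_true(all(k4$values == 0))
})

test_that("kernel averaging is a normalized weighted mean on a shared
           grid", {
  k1 <- const_kernel(1, domain = "soma_relative_zprime")
  k2 <- const_kernel(3, domain = "soma_relative_zprime")
  expect_equal(average_kernels(list(k1, k1), c(0.2, 5))$values, k1$values)
  expect_equal(average_kernels(list(k1, k2), c(1, 0))$values, k1$values)
  ## inhibitory subtype weights need not be pre-normalized
  w <- c(0.245, 0.165, 0.117, 0.191, 0.053, 0.112, 0.117)
  ks <- lapply(seq_along(w), function(i)
    const_kernel(i, domain = "soma_relative_zprime"))
  avg <- average_kernels(ks, w)
  expect_equal(avg$values[1, 1], sum(w * seq_along(w)) / sum(w),
               tolerance = 1e-12)
  k3 <- const_kernel(1, z_edges = seq(-400, 0, 100),
                     domain = "soma_relative_zprime")
  expect_error(average_kernels(list(k1, k3)), "match")
})

test_that("pchip resampling is exact on the grid, shape preserving and
           nonnegative", {
  set.seed(42)
  vals <- matrix(rexp(10 * 8), 10, 8)
  vals[3, ] <- 0                      # hard edge to tempt overshoot
  k <- delay_kernel(vals, seq(-1000, 0, 100), seq(0, 0.8, 0.1),
                    domain = "cortical_z")
  same <- resample_kernel(k, 100, 0.1)
  expect_equal(same$values, k$values, tolerance = 1e-12)
  fine <- resample_kernel(k, 10, 0.02)
  expect_true(all(fine$values >= 0))
  kc <- const_kernel(2.5)
  expect_true(all(abs(resample_kernel(kc, 20, 0.05)$values - 2.5) < 1e-12))
})

test_that("population kernel matches the brute-force correlation oracle
           and re-bases the soma", {
  ## small grids: 4 z' bins x 2 t bins, 6 z bins
  r <- matrix(c(1, 2, 0, 3, 0.5, 0, 1, 4), 4, 2)
  zk <- seq(-200, 200, 100)           # z' bins: soma bin is [0, 100)
  k <- delay_kernel(r, zk, c(0, 0.1, 0.2), domain = "soma_relative_zprime")
  dvals <- c(0, 0.25, 0.5, 0.25, 0, 0)
  dens <- cell_density(dvals, seq(-600, 0, 100))
  pop <- population_kernel(k, dens, count_ratio = 1)
  ## oracle: soma of a cell at density bin m puts r-row n at output bin
  ## m + (n - n0); n0 = index of the z' bin containing 0
  n0 <- 3
  oracle <- matrix(0, 6, 2)
  for (m in 1:6) for (n in 1:4) {
    i <- m + (n - n0)
    if (i >= 1 && i <= 6)
      oracle[i, ] <- oracle[i, ] + dens$d[m] * r[n, ]
  }
  expect_equal(pop$values, oracle, tolerance = 1e-12)
  expect_equal(pop$domain, "cortical_z")

  ## delta density: the cell kernel re-based so its soma sits at z0
  delta <- cell_density(c(0, 0, 0, 1, 0, 0), seq(-600, 0, 100))
  popd <- population_kernel(k, delta)
  expect_equal(popd$values[4, ], r[n0, ])       # soma bin lands at z0
  expect_equal(popd$values[2:5, ], r)
})

test_that("population kernel preserves spike count and is linear in the
           kernel and the count ratio", {
  set.seed(7)
  r <- matrix(rexp(8), 4, 2)
  k <- delay_kernel(r, seq(-200, 200, 100), c(0, 0.1, 0.2),
                    domain = "soma_relative_zprime")
  ## density with interior support: the correlation cannot push mass
  ## outside the cortical grid, so the count is exactly preserved
  dens <- cell_density(c(0, 0, 0.3, 0.4, 0.3, 0), seq(-600, 0, 100))
  pop <- population_kernel(k, dens, count_ratio = 1)
  expect_equal(kernel_spike_count(pop), kernel_spike_count(k),
               tolerance = 1e-12)
  expect_equal(pop$overflow, 0)
  ## ratio scaling: 5.04 excitatory, 0.40 inhibitory
  for (ratio in c(5.04, 0.40)) {
    ps <- population_kernel(k, dens, count_ratio = ratio)
    expect_equal(kernel_spike_count(ps), ratio * kernel_spike_count(k),
                 tolerance = 1e-12)
    expect_equal(ps$values, ratio * pop$values, tolerance = 1e-12)
  }
  k2 <- delay_kernel(2 * r, k$z_edges, k$t_edges,
                     domain = "soma_relative_zprime")
  expect_equal(population_kernel(k2, dens)$values, 2 * pop$values,
               tolerance = 1e-12)
  ## unnormalized density is rejected
  dun <- cell_density(c(1, 1, 0, 0, 0, 0), seq(-600, 0, 100),
                      normalize = FALSE)
  expect_error(population_kernel(k, dun), "normalized")
})

test_that("depth collapse is the arithmetic mean over z", {
  k <- const_kernel(2)
  prof <- collapse_depth(k)
  expect_equal(prof$density, rep(2, ncol(k$values)))
  vals <- matrix(0, 3, 10)
  vals[2, 4] <- 6
  kd <- delay_kernel(vals, seq(-300, 0, 100), seq(0, 1, 0.1),
                     domain = "cortical_z")
  prof2 <- collapse_depth(kd)
  expect_equal(prof2$density[4], 6 / 3)
  expect_equal(sum(prof2$density), 2)
  expect_equal(collapse_depth(delay_kernel(3 * vals, kd$z_edges,
                                           kd$t_edges,
                                           domain = "cortical_z"))$density,
               3 * prof2$density)
  expect_error(collapse_depth(const_kernel(1,
                                           domain = "soma_relative_zprime")),
               "cortical")
})

test_that("rotation averaging of a rotationally symmetric cell equals a
           single rotation", {
  ## a straight descending axon is phi-symmetric: every rotation gives the
  ## same kernel, so the 8-rotation average equals any single one
  m <- straight_cable(length = 700, npts = 2, diameter = 2)
  ch <- hh_channels()
  cfg <- cable_config(dt = 0.025, duration = 3)
  wf <- biphasic_waveform()
  one <- function(phi) {
    cm <- compartmentalize(rotate_azimuthal(m, phi), 20)
    init <- settle_steady_state(cm, ch, cfg)
    qp <- quasipotential(cm, field_params(theta = 30, intensity = 2500))
    st <- suppressWarnings(simulate_cable(cm, ch, cfg, init = init,
                                          stimulus = list(psi = qp,
                                                          waveform = wf),
                                          record = cm$terminal_ids))
    build_histogram(detect_arrivals(st, cm),
                    z_edges = seq(-1000, 100, 100),
                    t_edges = seq(0, 3, 0.1))
  }
  ks <- lapply(seq(0, 315, by = 45), one)
  avg <- average_kernels(ks)
  expect_equal(avg$values, ks[[1]]$values, tolerance = 1e-6)
})

test_that("kernel and density serialization round-trips", {
  set.seed(3)
  k <- delay_kernel(matrix(rexp(12), 3, 4), seq(-300, 0, 100),
                    seq(0, 0.4, 0.1), domain = "cortical_z",
                    scaling_ratio = 5.04)
  base <- tempfile()
  write_kernel(k, base)
  k2 <- read_kernel(base)
  expect_equal(k2$values, k$values, tolerance = 1e-12)
  expect_equal(k2$z_edges, k$z_edges)
  expect_equal(k2$scaling_ratio, 5.04)

  d <- layer_density()
  expect_equal(sum(d$d), 1, tolerance = 1e-12)
  p <- tempfile(fileext = ".csv")
  write_density(d, p)
  d2 <- read_density(p)
  expect_equal(d2$d, d$d, tolerance = 1e-9)
})
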