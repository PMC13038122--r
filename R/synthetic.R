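## Synthetic stand-in morphologies. Real reconstructions in SWC format can
## be imported with read_swc(); the generator below
## produces branched axonal arbors whose terminals follow a prescribed
## soma-relative depth distribution, plus simple apical/basal dendritic
## trees, so every stage of the pipeline can run self-contained.

#' Specification for a synthetic morphology
#'
#' Axon terminals are placed at soma-relative depths z' drawn from a
#' truncated normal distribution; the arbor connecting them is a recursive
#' binary tree so that branch orders grow logarithmically in the terminal
#' count. Dendrites are an apical trunk with tufts above the soma plus a
#' basal spray, giving the postsynaptic stage membrane area spread over
#' depth.
#'
#' @param n_axon_terminals number of axonal terminals (>= 1)
#' @param terminal_depth_mean,terminal_depth_sd mean and sd of terminal z'
#'   (um); defaults put terminals a few hundred um below the soma, as for
#'   descending cortical axons
#' @param terminal_depth_range length-2 truncation range for z' (um),
#'   within \[-2000, 500\]
#' @param branch_order_max maximum branch order of the axonal tree
#' @param segment_length_mean,segment_length_sd length statistics (um) of
#'   the straight segments making up branches
#' @param axon_diameter,dendrite_diameter cable diameters (um)
#' @param n_dendrite_tips number of apical tuft tips
#' @param dendrite_extent_mean,dendrite_extent_sd apical tip z' statistics
#'   (um, positive above the soma)
#' @param rng_seed integer seed; the generator is deterministic given the
#'   spec
#' @return an object of class `synthetic_morph_spec`
#' @export
synthetic_morph_spec <- function(n_axon_terminals = 20L,
                                 terminal_depth_mean = -600,
                                 terminal_depth_sd = 250,
                                 terminal_depth_range = c(-1400, 200),
                                 branch_order_max = 8L,
                                 segment_length_mean = 60,
                                 segment_length_sd = 15,
                                 axon_diameter = 1,
                                 dendrite_diameter = 2,
                                 n_dendrite_tips = 6L,
                                 dendrite_extent_mean = 350,
                                 dendrite_extent_sd = 80,
                                 rng_seed = 1L) {
  stopifnot(n_axon_terminals >= 1, n_dendrite_tips >= 1,
            branch_order_max >= 1,
            segment_length_mean > 0, axon_diameter > 0, dendrite_diameter > 0)
  if (terminal_depth_range[1] < -2000 || terminal_depth_range[2] > 500 ||
      diff(terminal_depth_range) <= 0)
    stop("terminal_depth_range must be increasing and within [-2000, 500] um")
  if (n_axon_terminals > 2^branch_order_max)
    stop("spec error: ", n_axon_terminals, " terminals not achievable with ",
         "branch order ", branch_order_max)
  structure(as.list(environment()), class = "synthetic_morph_spec")
}

.rtruncnorm <- function(n, mean, sd, range) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- rnorm(2 * (n - length(out)) + 10, mean, sd)
    out <- c(out, x[x >= range[1] & x <= range[2]])
  }
  out[seq_len(n)]
}

#' Generate a synthetic morphology
#'
#' Deterministic for a fixed spec (the spec's `rng_seed` drives a local RNG
#' stream; the caller's RNG state is untouched).
#'
#' @param spec a [synthetic_morph_spec()]
#' @return a [morphology()] with exactly `spec$n_axon_terminals` axonal
#'   leaf sections
#' @export
generate_morphology <- function(spec) {
  stopifnot(inherits(spec, "synthetic_morph_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(spec$rng_seed)

  soma_d <- 15
  secs <- list(section(1L, NA_integer_, "soma", matrix(0, 1, 3), soma_d))
  nid <- 1L
  seglen <- function() max(5, rnorm(1, spec$segment_length_mean,
                                    spec$segment_length_sd))

  ## --- axon: recursive binary tree reaching drawn terminal depths -------
  depths <- sort(.rtruncnorm(spec$n_axon_terminals, spec$terminal_depth_mean,
                             spec$terminal_depth_sd,
                             spec$terminal_depth_range))
  grow <- function(parent_sec, base, targets, order) {
    n <- length(targets)
    if (n == 1L || order >= spec$branch_order_max) {
      ## one branch section per remaining target: an L-shaped polyline that
      ## ends exactly at the target depth with a lateral offset
      for (tz in targets) {
        ang <- runif(1, 0, 2 * pi)
        lat <- seglen() * c(cos(ang), sin(ang), 0)
        elbow <- c(base[1] + lat[1], base[2] + lat[2],
                   (base[3] + tz) / 2)
        tip <- c(elbow[1], elbow[2], tz)
        nid <<- nid + 1L
        secs[[nid]] <<- section(nid, parent_sec, "axon",
                                rbind(base, elbow, tip),
                                rep(spec$axon_diameter, 3))
      }
      return(invisible(NULL))
    }
    split <- sample(seq_len(n - 1), 1)
    groups <- list(targets[seq_len(split)], targets[-seq_len(split)])
    for (g in groups) {
      ang <- runif(1, 0, 2 * pi)
      L <- seglen()
      drop_z <- min(L, max(0, base[3] - max(g)))
      nxt <- base + c(cos(ang) * L / 2, sin(ang) * L / 2, -drop_z)
      nid <<- nid + 1L
      this_sec <- nid
      secs[[nid]] <<- section(nid, parent_sec, "axon", rbind(base, nxt),
                              rep(spec$axon_diameter, 2))
      grow(this_sec, nxt, g, order + 1L)
    }
  }
  grow(1L, c(0, 0, 0), depths, 0L)

  ## --- apical dendrite: trunk up, tuft tips at drawn extents ------------
  tips <- .rtruncnorm(spec$n_dendrite_tips, spec$dendrite_extent_mean,
                      spec$dendrite_extent_sd,
                      c(50, 500))
  trunk_top <- c(0, 0, min(tips) * 0.6)
  nid <- nid + 1L
  trunk <- nid
  secs[[nid]] <- section(nid, 1L, "apical_dendrite",
                         rbind(c(0, 0, 0), trunk_top),
                         rep(spec$dendrite_diameter, 2))
  for (tz in tips) {
    ang <- runif(1, 0, 2 * pi)
    lat <- runif(1, 20, 80)
    tip <- c(lat * cos(ang), lat * sin(ang), tz)
    nid <- nid + 1L
    secs[[nid]] <- section(nid, trunk, "apical_dendrite",
                           rbind(trunk_top, tip),
                           rep(spec$dendrite_diameter * 0.7, 2))
  }
  ## --- basal dendrites: short spray around the soma ---------------------
  for (i in seq_len(4)) {
    ang <- 2 * pi * (i - 1) / 4 + runif(1, 0, 0.5)
    L <- runif(1, 80, 160)
    tip <- c(L * cos(ang), L * sin(ang), runif(1, -80, 20))
    nid <- nid + 1L
    secs[[nid]] <- section(nid, 1L, "basal_dendrite",
                           rbind(c(0, 0, 0), tip),
                           rep(spec$dendrite_diameter * 0.8, 2))
  }
  morphology(secs, soma_center = c(0, 0, 0), axis = c(0, 0, 1))
}
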