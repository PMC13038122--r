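#' Discretize a morphology into a compartment model
#'
#' Each section is split into equal-arc-length compartments no longer than
#' `max_len`. A compartment carries two distinct areas: the lateral
#' membrane area `pi * d * L` (which scales membrane conductances and
#' synaptic weights) and the cross-sectional area `pi * d^2 / 4` (which,
#' with the axial resistivity, sets axial coupling). The soma becomes a
#' single cylindrical compartment with length equal to its diameter.
#'
#' Compartments are emitted parent-before-child (Hines ordering), which the
#' implicit cable solver relies on.
#'
#' @param m a [morphology()]
#' @param max_len maximum compartment length (um)
#' @param axial_resistivity axial resistivity Ra (Ohm cm), default 100
#' @return an object of class `compartment_model`: a list with a
#'   `comps` data frame (geometry, kind, z', parent index, axial
#'   conductance `g_axial` in uS to the parent), `terminal_ids` (axonal
#'   leaves), and the source morphology's frame
#' @export
compartmentalize <- function(m, max_len = 20, axial_resistivity = 100) {
  stopifnot(inherits(m, "morphology"), max_len > 0, axial_resistivity > 0)
  secs <- m$sections
  ids <- vapply(secs, function(s) s$id, integer(1))
  rows <- list()
  sec_first <- sec_last <- integer(length(secs))
  n <- 0L

  add_row <- function(section_id, kind, mid, dir, len, dia, parent) {
    n <<- n + 1L
    rows[[n]] <<- data.frame(
      id = n, section_id = section_id, kind = kind,
      x = mid[1], y = mid[2], z = mid[3],
      dx = dir[1], dy = dir[2], dz = dir[3],
      length = len, diameter = dia,
      area_membrane = pi * dia * len,
      area_cross = pi * dia^2 / 4,
      axial_resistivity = axial_resistivity,
      parent = parent)
    n
  }

  for (i in seq_along(secs)) {
    s <- secs[[i]]
    if (s$kind == "soma") {
      ## single cylinder, length = diameter, oriented along the axis
      d <- s$diameters[1]
      sec_first[i] <- sec_last[i] <-
        add_row(s$id, "soma", s$points[1, ], m$axis, d, d, 0L)
      next
    }
    pts <- s$points
    seglen <- sqrt(rowSums(diff(pts)^2))
    arc <- c(0, cumsum(seglen))
    L <- arc[length(arc)]
    if (L <= 0) stop("section ", s$id, " has zero length")
    ncomp <- max(1L, ceiling(L / max_len))
    bounds <- seq(0, L, length.out = ncomp + 1L)
    at <- function(a) {       # position & diameter at arc length a
      j <- findInterval(a, arc, rightmost.closed = TRUE)
      j <- min(j, length(seglen))
      f <- if (seglen[j] > 0) (a - arc[j]) / seglen[j] else 0
      list(p = pts[j, ] + f * (pts[j + 1, ] - pts[j, ]),
           d = s$diameters[j] + f * (s$diameters[j + 1] - s$diameters[j]))
    }
    parent_comp <- if (is.na(s$parent_id)) 0L else
      sec_last[match(s$parent_id, ids)]
    for (k in seq_len(ncomp)) {
      a0 <- at(bounds[k]); a1 <- at(bounds[k + 1])
      mid <- at((bounds[k] + bounds[k + 1]) / 2)
      dir <- a1$p - a0$p
      nd <- sqrt(sum(dir^2))
      dir <- if (nd > 0) dir / nd else m$axis
      cid <- add_row(s$id, s$kind, mid$p, dir, bounds[k + 1] - bounds[k],
                     mid$d, parent_comp)
      if (k == 1L) sec_first[i] <- cid
      parent_comp <- cid
    }
    sec_last[i] <- parent_comp
  }

  comps <- do.call(rbind, rows)
  comps$z_prime <- z_prime(m, as.matrix(comps[, c("x", "y", "z")]))
  comps$z_prime[comps$kind == "soma"] <- 0

  ## axial conductance to parent: series of half-compartment resistances
  ## r_half(Ohm) = Ra * (L/2) / A_cross with um -> cm conversions
  r_half <- comps$axial_resistivity * (comps$length / 2) /
    comps$area_cross * 1e4                     # Ohm
  g_ax <- numeric(n)
  has_parent <- comps$parent > 0
  g_ax[has_parent] <- 1e6 / (r_half[has_parent] +
                             r_half[comps$parent[has_parent]])  # uS
  comps$g_axial <- g_ax

  is_axon <- comps$kind == "axon"
  has_axon_child <- comps$id %in% comps$parent[is_axon]
  terminal_ids <- comps$id[is_axon & !has_axon_child]

  structure(list(comps = comps, terminal_ids = terminal_ids,
                 soma_center = m$soma_center, axis = m$axis,
                 max_len = max_len),
            class = "compartment_model")
}

#' @export
print.compartment_model <- function(x, ...) {
  cat("<compartment_model> ", nrow(x$comps), " compartments, ",
      length(x$terminal_ids), " axon terminals\n", sep = "")
  cat("  total cable ", round(sum(x$comps$length), 1), " um; z' range [",
      round(min(x$comps$z_prime), 1), ", ", round(max(x$comps$z_prime), 1),
      "] um\n", sep = "")
  invisible(x)
}
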