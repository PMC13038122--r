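#' Neuron morphologies as trees of sections
#'
#' A morphology is a tree of *sections* (straight polyline pieces of cable),
#' each with per-point 3D coordinates (um) and diameters (um), a soma centre
#' and a somatodendritic axis. The soma-relative depth coordinate z' of any
#' point is its projection onto the somatodendritic axis, zero at the soma
#' centre and positive toward the (apical) dendrites.
#'
#' @param sections list of sections as created by [section()]
#' @param soma_center numeric length-3, um
#' @param axis somatodendritic axis (need not be unit length; normalized)
#' @return an object of class `morphology`
#' @seealso [read_swc()], [generate_morphology()], [compartmentalize()]
#' @export
morphology <- function(sections, soma_center = NULL, axis = c(0, 0, 1)) {
  stopifnot(length(sections) >= 1L)
  ids <- vapply(sections, function(s) s$id, integer(1))
  if (anyDuplicated(ids)) stop("duplicate section ids")
  parents <- vapply(sections, function(s) {
    if (is.na(s$parent_id)) NA_integer_ else s$parent_id
  }, integer(1))
  roots <- which(is.na(parents))
  if (length(roots) != 1L) stop("morphology must have exactly one root section")
  if (sections[[roots]]$kind != "soma") stop("root section must be the soma")
  bad <- !is.na(parents) & !(parents %in% ids)
  if (any(bad)) {
    stop("section ", ids[which(bad)[1]], " references missing parent ",
         parents[which(bad)[1]])
  }
  ## acyclicity: walk each section to root
  idx <- match(parents, ids)
  for (i in seq_along(sections)) {
    seen <- integer(0)
    j <- i
    while (!is.na(idx[j])) {
      if (j %in% seen) stop("cycle detected in section parents")
      seen <- c(seen, j)
      j <- idx[j]
    }
  }
  if (is.null(soma_center)) soma_center <- sections[[roots]]$points[1, ]
  axis <- axis / sqrt(sum(axis^2))
  structure(list(sections = sections, soma_center = as.numeric(soma_center),
                 axis = as.numeric(axis)),
            class = "morphology")
}

#' Create a morphology section
#'
#' @param id integer id, unique within the morphology
#' @param parent_id integer id of the parent section, or `NA` for the root
#' @param kind one of `"soma"`, `"axon"`, `"basal_dendrite"`,
#'   `"apical_dendrite"`
#' @param points numeric matrix (n x 3) of coordinates in um; non-soma
#'   sections need at least 2 points
#' @param diameters per-point diameters in um, all positive
#' @export
section <- function(id, parent_id, kind, points, diameters) {
  kind <- match.arg(kind, c("soma", "axon", "basal_dendrite",
                            "apical_dendrite"))
  points <- matrix(as.numeric(points), ncol = 3)
  diameters <- as.numeric(diameters)
  if (length(diameters) != nrow(points))
    stop("diameters must match number of points")
  if (any(diameters <= 0)) stop("diameters must be positive")
  if (kind != "soma" && nrow(points) < 2L)
    stop("non-soma sections need at least 2 points")
  list(id = as.integer(id),
       parent_id = if (is.na(parent_id)) NA_integer_ else as.integer(parent_id),
       kind = kind, points = points, diameters = diameters)
}

#' @export
print.morphology <- function(x, ...) {
  kinds <- vapply(x$sections, function(s) s$kind, character(1))
  cat("<morphology> ", length(x$sections), " sections (",
      paste(names(table(kinds)), table(kinds), sep = ":", collapse = ", "),
      ")\n", sep = "")
  cat("  soma centre: (", paste(signif(x$soma_center, 5), collapse = ", "),
      ") um; axis: (", paste(signif(x$axis, 5), collapse = ", "), ")\n",
      sep = "")
  invisible(x)
}

#' Soma-relative depth of points
#'
#' Projects coordinates onto the somatodendritic axis; z' = 0 at the soma
#' centre, positive toward the dendrites.
#'
#' @param m a `morphology`
#' @param points n x 3 matrix of coordinates (um)
#' @return numeric vector of z' (um)
#' @export
z_prime <- function(m, points) {
  points <- matrix(points, ncol = 3)
  drop(sweep(points, 2, m$soma_center) %*% m$axis)
}

#' Rotate a morphology about its somatodendritic axis
#'
#' Rigid rotation of all coordinates about the axis through the soma centre.
#' Soma-relative depths z' are invariant under this rotation, which is why
#' axonal delay kernels are averaged over it (cortical cells have random
#' azimuthal orientation).
#'
#' @param m a `morphology`
#' @param phi azimuthal angle in degrees
#' @return the rotated `morphology`
#' @export
rotate_azimuthal <- function(m, phi) {
  ang <- phi * pi / 180
  k <- m$axis
  K <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  R <- diag(3) + sin(ang) * K + (1 - cos(ang)) * (K %*% K)
  m$sections <- lapply(m$sections, function(s) {
    ctr <- sweep(s$points, 2, m$soma_center)
    s$points <- ctr %*% t(R) + rep(m$soma_center, each = nrow(s$points))
    s
  })
  m
}

#' Total cable length of a morphology
#' @param m a `morphology`
#' @return total arc length over all sections (um)
#' @export
cable_length <- function(m) {
  sum(vapply(m$sections, function(s) {
    if (nrow(s$points) < 2) return(0)
    sum(sqrt(rowSums(diff(s$points)^2)))
  }, numeric(1)))
}
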