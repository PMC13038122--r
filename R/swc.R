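## SWC import/export. Standard 7-column format: id type x y z radius parent.
## Type codes: 1 soma, 2 axon, 3 basal dendrite, 4 apical dendrite.

.swc_kind <- c("1" = "soma", "2" = "axon", "3" = "basal_dendrite",
               "4" = "apical_dendrite")
.swc_code <- c(soma = 1L, axon = 2L, basal_dendrite = 3L,
               apical_dendrite = 4L)

#' Read a morphology from an SWC file
#'
#' Nodes are regrouped into unbranched sections; a new section starts at the
#' root, at every branch point, and at every type change. Radii are doubled
#' to diameters on import. The soma is collapsed to a single root section
#' (its first sample is taken as the soma centre).
#'
#' @param path path to an SWC file
#' @param axis somatodendritic axis assigned to the imported cell. SWC files
#'   carry no axis information; the default `+y` follows the common
#'   convention of reconstructions stored with the pia "up" the y-axis.
#'   Override when the reconstruction uses another frame.
#' @return a [morphology()]
#' @export
read_swc <- function(path, axis = c(0, 1, 0)) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  raw <- lines[keep]
  lineno <- which(keep)
  if (length(raw) == 0) stop("SWC parse error: no data lines in ", path)
  fields <- strsplit(trimws(raw), "\\s+")
  nf <- lengths(fields)
  if (any(nf != 7)) {
    i <- which(nf != 7)[1]
    stop("SWC parse error at line ", lineno[i], ": expected 7 columns, got ",
         nf[i])
  }
  tab <- matrix(suppressWarnings(as.numeric(unlist(fields))), ncol = 7,
                byrow = TRUE)
  if (anyNA(tab)) {
    i <- which(apply(tab, 1, anyNA))[1]
    stop("SWC parse error at line ", lineno[i], ": non-numeric field")
  }
  id <- as.integer(tab[, 1]); type <- as.integer(tab[, 2])
  xyz <- tab[, 3:5, drop = FALSE]; radius <- tab[, 6]
  parent <- as.integer(tab[, 7])
  if (any(!as.character(type) %in% names(.swc_kind)))
    stop("SWC parse error: unsupported type code ",
         type[!as.character(type) %in% names(.swc_kind)][1])
  orphan <- parent != -1 & !(parent %in% id)
  if (any(orphan))
    stop("SWC structure error: node ", id[which(orphan)[1]],
         " references missing parent ", parent[which(orphan)[1]])
  if (sum(parent == -1) != 1)
    stop("SWC structure error: need exactly one root node")

  pidx <- match(parent, id)            # NA at root
  nchild <- tabulate(pidx[!is.na(pidx)], nbins = length(id))
  soma_nodes <- which(type == 1)
  if (length(soma_nodes) == 0) stop("SWC structure error: no soma node")
  root <- which(parent == -1)
  soma_center <- xyz[soma_nodes[1], ]

  secs <- list(section(1L, NA_integer_, "soma",
                       matrix(soma_center, 1, 3),
                       2 * radius[soma_nodes[1]]))
  node_sec <- integer(length(id))      # section that ends at each node
  node_sec[soma_nodes] <- 1L
  next_id <- 2L

  ## section heads: non-soma nodes whose parent is soma, a branch point,
  ## of different type, or the root itself
  is_head <- type != 1 & (is.na(pidx) | type[pidx] == 1 |
                          nchild[pidx] > 1 | type[pidx] != type)
  ## children list for chain walking
  kids <- split(seq_along(id), factor(pidx, levels = seq_along(id)))
  for (hstart in which(is_head)) {
    chain <- hstart
    repeat {
      last <- chain[length(chain)]
      ch <- kids[[as.character(last)]]
      ch <- ch[type[ch] == type[hstart]]
      if (length(ch) != 1 || nchild[last] != 1) break
      chain <- c(chain, ch)
    }
    p <- pidx[hstart]
    if (is.na(p)) {
      first_pt <- xyz[hstart, , drop = FALSE]  # detached root of this type
      pre <- NULL
      parent_sec <- NA_integer_
    } else {
      first_pt <- xyz[p, , drop = FALSE]
      pre <- if (type[p] == 1) 2 * radius[hstart] else 2 * radius[p]
      parent_sec <- node_sec[p]
    }
    pts <- rbind(first_pt, xyz[chain, , drop = FALSE])
    dia <- c(if (is.null(pre)) 2 * radius[hstart] else pre,
             2 * radius[chain])
    secs[[next_id]] <- section(next_id, parent_sec, .swc_kind[[as.character(type[hstart])]],
                               pts, dia)
    node_sec[chain] <- next_id
    next_id <- next_id + 1L
  }
  ## heads were found in file order; chains starting below a not-yet-built
  ## section cannot occur because SWC requires parents before children
  morphology(secs, soma_center = soma_center, axis = axis)
}

#' Write a morphology to an SWC file
#'
#' Inverse of [read_swc()]: the soma becomes a single type-1 node and each
#' section contributes its points except the first (which it shares with its
#' parent). Diameters are halved back to radii.
#'
#' @param m a [morphology()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_swc <- function(m, path) {
  rows <- list()
  nid <- 0L
  last_node <- integer(length(m$sections))  # node id closing each section
  ids <- vapply(m$sections, function(s) s$id, integer(1))
  for (i in seq_along(m$sections)) {
    s <- m$sections[[i]]
    if (s$kind == "soma") {
      nid <- nid + 1L
      rows[[length(rows) + 1L]] <-
        c(nid, 1, s$points[1, ], s$diameters[1] / 2, -1)
      last_node[i] <- nid
      next
    }
    pid <- if (is.na(s$parent_id)) -1L else last_node[match(s$parent_id, ids)]
    for (j in 2:nrow(s$points)) {
      nid <- nid + 1L
      rows[[length(rows) + 1L]] <-
        c(nid, .swc_code[[s$kind]], s$points[j, ], s$diameters[j] / 2, pid)
      pid <- nid
    }
    last_node[i] <- nid
  }
  tab <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# id type x y z radius parent", con)
  write.table(format(tab, digits = 12, trim = TRUE, scientific = FALSE),
              con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}
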