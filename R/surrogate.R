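#' Uniform parameter bounds for the surrogate
#'
#' Six uniformly distributed parameters: field polar angle theta (deg),
#' relative field gradient (%/mm), field intensity (V/m), and the three
#' synapse-mixture fractions. Defaults are the broad physiological bounds
#' the surrogate is built over.
#'
#' @param bounds 6 x 2 matrix (lower, upper) with rownames `theta`,
#'   `rel_gradient`, `intensity`, `f_nmda`, `f_gabaa`, `f_ex`
#' @return object of class `param_bounds`
#' @export
param_bounds <- function(bounds = NULL) {
  if (is.null(bounds)) {
    bounds <- rbind(theta = c(0, 180), rel_gradient = c(-20, 20),
                    intensity = c(100, 400), f_nmda = c(0.25, 0.75),
                    f_gabaa = c(0.9, 1.0), f_ex = c(0.2, 0.8))
  }
  stopifnot(ncol(bounds) == 2, all(bounds[, 1] < bounds[, 2]))
  structure(bounds, class = c("param_bounds", class(bounds)))
}

#' Anisotropic gPC basis truncation
#'
#' Exponent multi-indices over `n_params` parameters are kept when: the
#' number of interacting (nonzero-order) parameters is at most
#' `max_interaction_order`; a lone parameter's order is at most
#' `max_univariate_order` (or `gradient_param_order` for the designated
#' gradient parameter); and with two or more interacting parameters the
#' nonzero orders sum to at most `max_interaction_sum` (gradient entry
#' still capped). The constant (all-zero) index is always included.
#'
#' @param max_univariate_order cap for single-parameter polynomials
#' @param gradient_param_order reduced cap for the gradient parameter
#' @param max_interaction_order maximum number of interacting parameters
#' @param max_interaction_sum cap on the sum of interacting orders
#' @param gradient_param_index which parameter carries the reduced cap
#' @return object of class `basis_spec`
#' @export
basis_spec <- function(max_univariate_order = 20L,
                       gradient_param_order = 6L,
                       max_interaction_order = 3L,
                       max_interaction_sum = 8L,
                       gradient_param_index = 2L) {
  stopifnot(max_univariate_order >= 1, gradient_param_order >= 1,
            max_interaction_order >= 1, max_interaction_sum >= 1,
            gradient_param_order <= max_univariate_order)
  structure(list(max_univariate_order = as.integer(max_univariate_order),
                 gradient_param_order = as.integer(gradient_param_order),
                 max_interaction_order = as.integer(max_interaction_order),
                 max_interaction_sum = as.integer(max_interaction_sum),
                 gradient_param_index = as.integer(gradient_param_index)),
            class = "basis_spec")
}

#' Enumerate the multi-index basis set
#'
#' @param spec a [basis_spec()]
#' @param n_params number of parameters (default 6)
#' @return integer matrix (N_c x n_params) of polynomial orders, first row
#'   all zeros
#' @export
enumerate_basis <- function(spec = basis_spec(), n_params = 6L) {
  p <- n_params
  gi <- spec$gradient_param_index
  cap <- function(j) if (!is.na(gi) && j == gi) spec$gradient_param_order
                     else spec$max_univariate_order
  rows <- list(integer(p))                       # constant term
  ## single-parameter terms
  for (j in seq_len(p)) {
    for (o in seq_len(cap(j))) {
      a <- integer(p); a[j] <- o
      rows[[length(rows) + 1L]] <- a
    }
  }
  ## interacting terms: choose a support of size 2..max_interaction_order,
  ## then compositions of the order sum over that support
  max_k <- min(spec$max_interaction_order, p)
  if (max_k >= 2) {
    for (k in 2:max_k) {
      supports <- utils::combn(p, k, simplify = FALSE)
      comps <- .compositions(spec$max_interaction_sum, k)
      for (sup in supports) {
        caps <- vapply(sup, cap, integer(1))
        for (cc in comps) {
          if (any(cc > caps)) next
          a <- integer(p); a[sup] <- cc
          rows[[length(rows) + 1L]] <- a
        }
      }
    }
  }
  do.call(rbind, rows)
}

## all k-tuples of positive integers with sum <= total
.compositions <- function(total, k) {
  if (k == 1) return(lapply(seq_len(total), identity))
  out <- list()
  rec <- function(prefix, remaining, slots) {
    if (slots == 0) {
      out[[length(out) + 1L]] <<- prefix
      return(invisible(NULL))
    }
    for (v in seq_len(remaining - slots + 1)) {
      rec(c(prefix, v), remaining - v, slots - 1)
    }
  }
  rec(integer(0), total, k)
  out
}

#' Sample uniform parameter combinations
#'
#' @param bounds a [param_bounds()]
#' @param n number of samples
#' @param seed integer seed (local RNG stream; caller state untouched)
#' @return n x n_params matrix within bounds
#' @export
sample_params <- function(bounds = param_bounds(), n, seed = 1L) {
  stopifnot(n >= 1)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  p <- nrow(bounds)
  u <- matrix(runif(n * p), n, p)
  x <- sweep(sweep(u, 2, bounds[, 2] - bounds[, 1], `*`), 2, bounds[, 1],
             `+`)
  colnames(x) <- rownames(bounds)
  x
}

## Orthonormal Legendre polynomials on [-1, 1] under the uniform measure:
## E[P~_m P~_n] = delta_mn with P~_n = sqrt(2n + 1) P_n.
## Returns matrix length(x) x (max_order + 1), column o+1 = order o.
.legendre_norm <- function(x, max_order) {
  n <- length(x)
  P <- matrix(0, n, max_order + 1)
  P[, 1] <- 1
  if (max_order >= 1) P[, 2] <- x
  if (max_order >= 2) {
    for (k in 2:max_order) {
      P[, k + 1] <- ((2 * k - 1) * x * P[, k] - (k - 1) * P[, k - 1]) / k
    }
  }
  sweep(P, 2, sqrt(2 * seq(0, max_order) + 1), `*`)
}

## derivative d/dx of the orthonormal Legendre, via
## P'_{n+1} = P'_{n-1} + (2n + 1) P_n (on the unnormalized family)
.legendre_norm_deriv <- function(x, max_order) {
  n <- length(x)
  P <- matrix(0, n, max_order + 1)
  D <- matrix(0, n, max_order + 1)
  P[, 1] <- 1
  if (max_order >= 1) {
    P[, 2] <- x
    D[, 2] <- 1
  }
  if (max_order >= 2) {
    for (k in 2:max_order) {
      P[, k + 1] <- ((2 * k - 1) * x * P[, k] - (k - 1) * P[, k - 1]) / k
      D[, k + 1] <- D[, k - 1] + (2 * k - 1) * P[, k]
    }
  }
  sweep(D, 2, sqrt(2 * seq(0, max_order) + 1), `*`)
}

## map parameters to [-1, 1] per bounds
.to_unit <- function(x, bounds) {
  sweep(sweep(x, 2, (bounds[, 1] + bounds[, 2]) / 2), 2,
        (bounds[, 2] - bounds[, 1]) / 2, `/`)
}

## design matrix: products of univariate orthonormal Legendre evaluations
.gpc_design <- function(x, multi_indices, bounds) {
  u <- .to_unit(x, bounds)
  p <- ncol(u)
  maxo <- max(multi_indices)
  uni <- lapply(seq_len(p), function(j) .legendre_norm(u[, j], maxo))
  Psi <- matrix(1, nrow(x), nrow(multi_indices))
  for (i in seq_len(nrow(multi_indices))) {
    a <- multi_indices[i, ]
    for (j in which(a > 0)) Psi[, i] <- Psi[, i] * uni[[j]][, a[j] + 1]
  }
  Psi
}

#' Fit a time-resolved gPC surrogate
#'
#' Builds the product-Legendre design matrix at the training points and
#' solves for all time points at once via the Moore-Penrose pseudoinverse
#' (SVD with relative cutoff 1e-12, no regularization):
#' `C = pinv(Psi) I`. With an orthonormal basis the coefficients are
#' directly the spectral decomposition used for Sobol indices.
#'
#' @param samples n x p parameter matrix ([sample_params()])
#' @param responses n x N_t response matrix (rows match `samples`)
#' @param spec a [basis_spec()]
#' @param bounds a [param_bounds()]
#' @return object of class `gpc_model`: `multi_indices`, `coefficients`
#'   (N_c x N_t), `bounds`, `t_grid` (attached by the caller or NULL),
#'   `rank_warning`
#' @export
fit_gpc <- function(samples, responses, spec = basis_spec(),
                    bounds = param_bounds(), t_grid = NULL) {
  responses <- as.matrix(responses)
  stopifnot(nrow(samples) == nrow(responses), all(is.finite(responses)))
  mi <- enumerate_basis(spec, n_params = ncol(samples))
  Psi <- .gpc_design(samples, mi, bounds)
  rank_warning <- nrow(Psi) < ncol(Psi)
  if (rank_warning)
    warning("fewer samples (", nrow(Psi), ") than basis functions (",
            ncol(Psi), "); pseudoinverse fit is rank-deficient")
  sv <- svd(Psi)
  tol <- max(sv$d) * 1e-12
  pos <- sv$d > tol
  if (!any(pos)) stop("gPC design matrix is singular")
  ## C = V D^+ U' I
  C <- sv$v[, pos, drop = FALSE] %*%
    ((t(sv$u[, pos, drop = FALSE]) %*% responses) / sv$d[pos])
  structure(list(multi_indices = mi, coefficients = C, bounds = bounds,
                 spec = spec, t_grid = t_grid, n_train = nrow(samples),
                 rank_warning = rank_warning),
            class = "gpc_model")
}

#' @export
print.gpc_model <- function(x, ...) {
  cat("<gpc_model> ", nrow(x$multi_indices), " basis functions x ",
      ncol(x$coefficients), " time points; ", x$n_train,
      " training samples\n", sep = "")
  invisible(x)
}

#' Predict from a gPC surrogate
#'
#' @param object a [fit_gpc()] model
#' @param newdata parameter matrix (rows = evaluation points)
#' @param ... unused
#' @return matrix (nrow(newdata) x N_t) of predicted responses
#' @export
predict.gpc_model <- function(object, newdata, ...) {
  newdata <- matrix(newdata, ncol = nrow(object$bounds))
  lo <- object$bounds[, 1]; hi <- object$bounds[, 2]
  if (any(sweep(newdata, 2, lo, `<`)) || any(sweep(newdata, 2, hi, `>`)))
    warning("evaluation points outside the training bounds (extrapolation)")
  Psi <- .gpc_design(newdata, object$multi_indices, object$bounds)
  Psi %*% object$coefficients
}

#' Average normalized root-mean-square deviation (percent)
#'
#' Per time point, the RMS error between reference and approximation over
#' test samples is divided by the reference range at that time point; the
#' result is averaged over time points and reported in percent. Time
#' points with zero reference range are excluded (with a diagnostic
#' attribute `n_excluded`).
#'
#' @param reference,approximation N_test x N_t matrices
#' @return scalar NRMSD in percent
#' @export
nrmsd <- function(reference, approximation) {
  reference <- as.matrix(reference)
  approximation <- as.matrix(approximation)
  stopifnot(all(dim(reference) == dim(approximation)))
  rng <- apply(reference, 2, function(col) max(col) - min(col))
  ok <- rng > 0
  rms <- sqrt(colMeans((reference - approximation)^2))
  out <- mean(rms[ok] / rng[ok]) * 100
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Sobol sensitivity indices from gPC coefficients
#'
#' With an orthonormal basis the output variance at each time point is the
#' sum of squared non-constant coefficients; the index of a parameter
#' support set u is the variance carried by basis functions whose nonzero
#' pattern equals u, normalized by the total. Indices over all supports
#' sum to 1 wherever the variance is nonzero; zero-variance time points
#' are masked (NA).
#'
#' @param model a [fit_gpc()] model
#' @return object of class `sensitivity_result`: `sobol` (supports x
#'   N_t), `support` labels, `sobol_time_avg` (variance-weighted time
#'   average), `variance` per time point
#' @export
sobol_indices <- function(model) {
  mi <- model$multi_indices
  C <- model$coefficients
  nonconst <- rowSums(mi) > 0
  supp <- apply(mi > 0, 1, function(z) paste(which(z), collapse = "x"))
  var_t <- colSums(C[nonconst, , drop = FALSE]^2)
  groups <- split(which(nonconst), supp[nonconst])
  S <- vapply(groups, function(idx)
    colSums(C[idx, , drop = FALSE]^2), numeric(ncol(C)))
  S <- if (is.null(dim(S))) matrix(S, ncol = length(groups)) else S
  S <- t(S)                                   # supports x time points
  Sn <- sweep(S, 2, var_t, `/`)
  Sn[, var_t <= 0] <- NA_real_
  total_var <- sum(var_t)
  avg <- if (total_var > 0) rowSums(S) / total_var else
    rep(NA_real_, nrow(S))
  param_names <- rownames(model$bounds)
  label <- vapply(strsplit(names(groups), "x"), function(ix)
    paste(param_names[as.integer(ix)], collapse = " x "), character(1))
  structure(list(sobol = Sn, support = names(groups), label = label,
                 sobol_time_avg = setNames(avg, label),
                 variance = var_t, t_grid = model$t_grid),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("<sensitivity_result> ", nrow(x$sobol), " parameter supports x ",
      ncol(x$sobol), " time points\n", sep = "")
  top <- sort(x$sobol_time_avg, decreasing = TRUE)
  top <- head(top, 5)
  for (i in seq_along(top))
    cat(sprintf("  %-28s %.4f\n", names(top)[i], top[i]))
  invisible(x)
}

#' Global derivative-based sensitivity coefficients
#'
#' Monte-Carlo estimate of `E[dI/dxi_j]` over the uniform parameter space,
#' using exact analytic derivatives of the basis polynomials (signed
#' averages; chain rule maps from the [-1, 1] reference interval to
#' natural parameter scale). Reproducible for a fixed seed.
#'
#' @param model a [fit_gpc()] model
#' @param n_mc number of Monte-Carlo draws (default 1e4)
#' @param seed integer seed
#' @return matrix (n_params x N_t) of average derivatives, natural units
#' @export
derivative_sensitivity <- function(model, n_mc = 1e4, seed = 1L) {
  stopifnot(n_mc >= 1)
  bounds <- model$bounds
  x <- sample_params(bounds, n_mc, seed = seed)
  u <- .to_unit(x, bounds)
  mi <- model$multi_indices
  p <- ncol(mi)
  maxo <- max(mi)
  uni <- lapply(seq_len(p), function(j) .legendre_norm(u[, j], maxo))
  der <- lapply(seq_len(p), function(j) .legendre_norm_deriv(u[, j], maxo))
  scale <- 2 / (bounds[, 2] - bounds[, 1])       # d(unit)/d(natural)
  out <- matrix(0, p, ncol(model$coefficients))
  for (j in seq_len(p)) {
    ## mean over draws of dPsi_i/dxi_j for every basis function
    dmean <- vapply(seq_len(nrow(mi)), function(i) {
      a <- mi[i, ]
      if (a[j] == 0) return(0)
      v <- der[[j]][, a[j] + 1]
      for (k in which(a > 0)) if (k != j) v <- v * uni[[k]][, a[k] + 1]
      mean(v) * scale[j]
    }, numeric(1))
    out[j, ] <- drop(crossprod(dmean, model$coefficients))
  }
  rownames(out) <- rownames(bounds)
  out
}

#' The surrogate time grid
#'
#' Half-open uniform grid over `[0, t_end)` with step `dt`; the default
#' 0.2 ms step over 100 ms gives exactly 500 points, the resolution the
#' surrogate is fitted at.
#'
#' @param t_end end of the window, ms (excluded)
#' @param dt step, ms
#' @return numeric vector of times
#' @export
surrogate_time_grid <- function(t_end = 100, dt = 0.2) {
  seq(0, t_end - dt, by = dt)
}

#' Resample a simulated current onto the surrogate grid
#'
#' Linear interpolation from the simulation grid (typically 0.01 ms) onto
#' [surrogate_time_grid()].
#'
#' @param current a [run_dendritic()] result
#' @param t_out target grid, ms
#' @return numeric vector on `t_out`
#' @export
resample_current <- function(current, t_out = surrogate_time_grid()) {
  approx(current$t, current$I, xout = t_out, rule = 2)$y
}

#' gPC model CSV/JSON serialization
#'
#' Writes `<path>_coeff.csv` (N_c x N_t), `<path>_indices.csv` and
#' `<path>.json` (bounds, spec, grid, metadata).
#'
#' @param model a [fit_gpc()] model
#' @param path base path
#' @export
write_gpc <- function(model, path) {
  write.table(model$coefficients, paste0(path, "_coeff.csv"), sep = ",",
              row.names = FALSE, col.names = FALSE)
  write.table(model$multi_indices, paste0(path, "_indices.csv"), sep = ",",
              row.names = FALSE, col.names = FALSE)
  meta <- list(bounds = unclass(model$bounds), spec = unclass(model$spec),
               t_grid = model$t_grid, n_train = model$n_train)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, matrix = "rowmajor")
  invisible(path)
}
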