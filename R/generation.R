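# Between-season generation map: Q[u] = K * g(., Phi_tau[u]).
# The season semiflow Phi_tau comes from solve_season; birth is applied
# nodewise; redistribution is a linear discrete convolution with the
# grid-sampled dispersal kernel, zero-padded off-domain (consistent with the
# Dirichlet truncation of the transport step).

#' Discretise a dispersal kernel on a grid
#'
#' Samples the kernel density at grid-spaced offsets covering
#' \code{mean +/- 8 sd} and renormalises so that the discrete integral
#' (sum of weights times spacing) is exactly 1; the raw quadrature defect
#' before renormalisation is retained for diagnostics.  The grid must
#' resolve the kernel (\code{spacing < sd/2}).
#'
#' @param kernel A \code{\link{kernel_spec}}.
#' @param grid A \code{\link{spatial_grid}}.
#' @return An object of class \code{"discrete_kernel"}: \code{offsets},
#'   \code{weights} (densities), \code{window_halfwidth},
#'   \code{raw_defect}.
#' @export
discretize_kernel <- function(kernel, grid) {
  stopifnot(inherits(kernel, "kernel_spec"), is_spatial_grid(grid))
  h <- grid$spacing
  if (h >= kernel$sd / 2)
    stop(sprintf("grid spacing %.3g too coarse for kernel sd %.3g (need < sd/2)",
                 h, kernel$sd), call. = FALSE)
  jmin <- floor((kernel$mean - 8 * kernel$sd) / h)
  jmax <- ceiling((kernel$mean + 8 * kernel$sd) / h)
  offs <- (jmin:jmax) * h
  w <- kernel$fun(offs)
  raw <- sum(w) * h
  w <- w / raw
  structure(
    list(offsets = offs, weights = w, jmin = jmin, jmax = jmax,
         window_halfwidth = max(abs(offs)), raw_defect = abs(raw - 1),
         spacing = h, n = grid$n_nodes),
    class = "discrete_kernel"
  )
}

kernel_conv_plan <- function(dk) {
  make_conv_plan(dk$weights, dk$jmin, dk$n, dk$spacing)
}

#' Apply the birth function nodewise
#'
#' @param birth A \code{\link{birth_spec}}.
#' @param u A \code{\link{density_field}}.
#' @return The \code{density_field} of offspring densities g(x, u(x)).  For
#'   the non-monotone logistic family the input must lie in \code{[0, 1]}
#'   (its invariant range); values outside raise an error.
#' @export
apply_birth <- function(birth, u) {
  stopifnot(inherits(birth, "birth_spec"), inherits(u, "density_field"))
  if (birth$family == "logistic_nonmonotone" && any(u$values > 1 + 1e-12))
    stop("logistic_nonmonotone birth requires u <= 1", call. = FALSE)
  vals <- birth$g(u$grid$nodes, u$values)
  vals[vals < 0 & vals > -1e-12] <- 0
  density_field(u$grid, vals)
}

#' One application of the generation map
#'
#' Composes the season semiflow, the birth function and the kernel
#' redistribution: Q[u] = K * g(., Phi_tau[u]).
#'
#' @param model A \code{\link{model_spec}}.
#' @param u Start-of-season \code{\link{density_field}}.
#' @param dt Season-solver substep (default \code{tau/64}).
#' @return The next start-of-season \code{density_field}.
#' @export
generation_step <- function(model, u, dt = model$tau / 64) {
  w <- season_final(solve_season(model, u, dt = dt))
  b <- apply_birth(model$birth, w)
  dk <- discretize_kernel(model$kernel, u$grid)
  vals <- conv_apply(kernel_conv_plan(dk), b$values)
  vals[vals < 0 & vals > -1e-12] <- 0
  density_field(u$grid, vals)
}

# Internal fast path: precompute all plans once, then step raw value vectors.
make_generation_stepper <- function(model, grid, dt) {
  n_steps <- steps_for(model$tau, dt)
  tplan <- transport_plan(model$D, model$q, dt, grid)
  kplan <- kernel_conv_plan(discretize_kernel(model$kernel, grid))
  alpha_vals <- if (model$reaction$family == "logistic_mortality")
    profile_eval(model$reaction$alpha_profile, grid$nodes) else NULL
  reaction <- model$reaction
  birth <- model$birth
  nodes <- grid$nodes
  nonmono <- birth$family == "logistic_nonmonotone"
  function(v) {
    for (s in seq_len(n_steps)) {
      v <- reaction_substep(reaction, nodes, v, dt / 2, alpha_vals)
      v <- conv_apply(tplan, v)
      v[v < 0] <- 0
      v <- reaction_substep(reaction, nodes, v, dt / 2, alpha_vals)
    }
    if (nonmono && any(v > 1 + 1e-12))
      stop("logistic_nonmonotone birth requires u <= 1", call. = FALSE)
    v <- birth$g(nodes, v)
    v[v < 0] <- 0
    v <- conv_apply(kplan, v)
    v[v < 0] <- 0
    v
  }
}

#' Iterate the generation map across seasons
#'
#' Applies the generation map repeatedly, recording the sup-norm and total
#' mass of every iterate and the full field every \code{record_every}
#' generations (plus the first and last).  Deterministic; aborts if the
#' sup-norm exceeds 1e6 (divergence guard).
#'
#' @param model A \code{\link{model_spec}}.
#' @param u0 Initial \code{\link{density_field}} (generation 0).
#' @param n_gens Number of generations (at least 1).
#' @param dt Season-solver substep.
#' @param record_every Field recording stride (default 10).
#' @return An object of class \code{"generation_trajectory"}:
#'   \code{sup_norms} and \code{masses} (length \code{n_gens + 1}, generation
#'   0 first), \code{fields} (recorded \code{density_field}s),
#'   \code{gens_recorded}, \code{n_total}, \code{model}, \code{grid}.
#' @export
iterate_generations <- function(model, u0, n_gens, dt = model$tau / 64,
                                record_every = 10) {
  stopifnot(inherits(model, "model_spec"), inherits(u0, "density_field"))
  if (n_gens < 1) stop("'n_gens' must be at least 1", call. = FALSE)
  n_gens <- as.integer(n_gens)
  grid <- u0$grid
  step <- make_generation_stepper(model, grid, dt)
  sup_norms <- masses <- numeric(n_gens + 1L)
  gens_recorded <- as.integer(unique(c(seq(0L, n_gens, by = record_every),
                                       n_gens)))
  fields <- vector("list", length(gens_recorded))
  names(fields) <- as.character(gens_recorded)
  v <- u0$values
  h <- grid$spacing
  sup_norms[1L] <- max(v)
  masses[1L] <- h * (sum(v) - (v[1L] + v[length(v)]) / 2)
  if (0L %in% gens_recorded) fields[["0"]] <- u0
  for (n in seq_len(n_gens)) {
    v <- step(v)
    sup_norms[n + 1L] <- max(v)
    masses[n + 1L] <- h * (sum(v) - (v[1L] + v[length(v)]) / 2)
    if (sup_norms[n + 1L] > 1e6)
      stop("divergence guard: sup-norm exceeded 1e6 at generation ", n,
           call. = FALSE)
    if (n %in% gens_recorded)
      fields[[as.character(n)]] <- density_field(grid, v)
  }
  structure(
    list(model = model, grid = grid, sup_norms = sup_norms, masses = masses,
         fields = fields, gens_recorded = gens_recorded, n_total = n_gens,
         dt = dt),
    class = "generation_trajectory"
  )
}

#' @export
print.generation_trajectory <- function(x, ...) {
  cat(sprintf("<generation_trajectory> %d generations, final sup %g\n",
              x$n_total, x$sup_norms[length(x$sup_norms)]))
  invisible(x)
}

#' Final field of a trajectory
#' @param traj A \code{"generation_trajectory"}.
#' @return The last recorded \code{density_field}.
#' @export
trajectory_final <- function(traj) {
  stopifnot(inherits(traj, "generation_trajectory"))
  traj$fields[[as.character(traj$n_total)]]
}

#' Search for a fixed point of the generation map
#'
#' Iterates the generation map until the sup-norm of successive differences
#' drops below \code{tol} (or \code{max_gens} is reached), then measures the
#' residual sup|Q[W] - W| by one extra application.  Zero is always a fixed
#' point; a nontrivial one is approached from any nonzero start when the
#' threshold exceeds one.
#'
#' @param model A \code{\link{model_spec}}.
#' @param u0 Starting \code{\link{density_field}}.
#' @param dt Season-solver substep.
#' @param tol Sup-norm tolerance on successive differences (default 1e-8).
#' @param max_gens Iteration cap (default 2000).
#' @return A list: \code{W} (the approximate fixed point),
#'   \code{residual}, \code{converged}, \code{n_iters}.
#' @export
find_fixed_point <- function(model, u0, dt = model$tau / 64, tol = 1e-8,
                             max_gens = 2000) {
  stopifnot(tol > 0)
  grid <- u0$grid
  step <- make_generation_stepper(model, grid, dt)
  v <- u0$values
  converged <- FALSE
  n_iters <- 0L
  for (n in seq_len(max_gens)) {
    v_new <- step(v)
    n_iters <- n
    if (max(abs(v_new - v)) < tol) {
      v <- v_new
      converged <- TRUE
      break
    }
    v <- v_new
  }
  residual <- max(abs(step(v) - v))
  list(W = density_field(grid, v), residual = residual,
       converged = converged, n_iters = n_iters)
}

#' Export a trajectory summary as a data frame
#'
#' @param traj A \code{"generation_trajectory"}.
#' @return \code{data.frame} with columns \code{generation},
#'   \code{sup_norm}, \code{mass}.
#' @export
trajectory_table <- function(traj) {
  stopifnot(inherits(traj, "generation_trajectory"))
  data.frame(generation = 0:traj$n_total,
             sup_norm = traj$sup_norms, mass = traj$masses)
}
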