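#' Reaction (within-season mortality) specification
#'
#' The within-season dynamics are driven by a density-dependent net growth
#' term f(x, u) with f(x, 0) = 0.  Three families are supported:
#' \describe{
#'   \item{\code{logistic_mortality}}{f(x, u) = -alpha(x) u - u^2, the
#'     quadratic-mortality form; requires \code{alpha_profile}.  Its
#'     linearisation at zero is theta(x) = -alpha(x).}
#'   \item{\code{linear}}{f(x, u) = theta0 u with a spatially constant rate;
#'     useful as an exactly solvable reference.}
#'   \item{\code{custom}}{a user-supplied \code{f(x, u)} with its
#'     linearisation \code{theta(x)} and growth bound.}
#' }
#'
#' \code{bound_K} and \code{bound_Ntilde} are the constants of the standing
#' growth bound f(x, u) <= K u for u >= Ntilde.  For the quadratic-mortality
#' family f <= 0 <= 0*u always, so K = 0, Ntilde = 1 are valid defaults.
#'
#' @param family One of \code{"logistic_mortality"}, \code{"linear"},
#'   \code{"custom"}.
#' @param alpha_profile \code{habitat_profile} for the mortality rate
#'   (logistic_mortality family).
#' @param theta0 Constant per-capita rate (linear family).
#' @param f Function \code{(x, u) -> value}, vectorised (custom family).
#' @param theta Function \code{x -> value}, the u-derivative of f at 0
#'   (custom family).
#' @param bound_K,bound_Ntilde Growth-bound constants (see Details).
#' @return An object of class \code{"reaction_spec"}.
#' @export
reaction_spec <- function(family = c("logistic_mortality", "linear", "custom"),
                          alpha_profile = NULL, theta0 = NULL,
                          f = NULL, theta = NULL,
                          bound_K = NULL, bound_Ntilde = 1) {
  family <- match.arg(family)
  spec <- switch(family,
    logistic_mortality = {
      if (!is_habitat_profile(alpha_profile))
        stop("logistic_mortality requires 'alpha_profile'", call. = FALSE)
      a <- alpha_profile
      list(family = family,
           alpha_profile = a,
           f = function(x, u) -profile_eval(a, x) * u - u^2,
           theta = function(x) -profile_eval(a, x),
           theta_tail_max = -a$tail_min,
           bound_K = if (is.null(bound_K)) 0 else bound_K,
           bound_Ntilde = bound_Ntilde)
    },
    linear = {
      if (is.null(theta0) || !is.finite(theta0))
        stop("linear family requires finite 'theta0'", call. = FALSE)
      force(theta0)
      list(family = family, theta0 = theta0,
           f = function(x, u) theta0 * u,
           theta = function(x) rep_len(theta0, length(x)),
           theta_tail_max = theta0,
           bound_K = if (is.null(bound_K)) theta0 else bound_K,
           bound_Ntilde = bound_Ntilde)
    },
    custom = {
      if (!is.function(f) || !is.function(theta))
        stop("custom family requires functions 'f' and 'theta'", call. = FALSE)
      if (is.null(bound_K))
        stop("custom family requires 'bound_K'", call. = FALSE)
      list(family = family, f = f, theta = theta,
           theta_tail_max = NA_real_,
           bound_K = bound_K, bound_Ntilde = bound_Ntilde)
    })
  structure(spec, class = "reaction_spec")
}

#' Birth (between-season reproduction) specification
#'
#' The impulsive birth g(x, u) converts end-of-season larval density into
#' offspring before kernel redistribution.  Families:
#' \describe{
#'   \item{\code{beverton_holt}}{g(x, u) = r(x) u / (1 + u); monotone and
#'     subhomogeneous.  Linearisation eta(x) = r(x).}
#'   \item{\code{logistic_nonmonotone}}{g(x, u) = r(x) u (1 - u) on the
#'     invariant range u in [0, 1]; non-monotone.}
#'   \item{\code{linear}}{g(x, u) = eta0 u.}
#' }
#' \code{bound_L}, \code{bound_Nbar} are the constants of
#' g(x, u) <= L max(u, Nbar).
#'
#' @param family One of \code{"beverton_holt"}, \code{"logistic_nonmonotone"},
#'   \code{"linear"}.
#' @param r_profile \code{habitat_profile} for the fecundity r(x).
#' @param eta0 Constant low-density fecundity (linear family).
#' @param bound_L,bound_Nbar Bound constants (defaults derived from the
#'   profile peak).
#' @return An object of class \code{"birth_spec"}.
#' @export
birth_spec <- function(family = c("beverton_holt", "logistic_nonmonotone",
                                  "linear"),
                       r_profile = NULL, eta0 = NULL,
                       bound_L = NULL, bound_Nbar = 1) {
  family <- match.arg(family)
  spec <- switch(family,
    beverton_holt = {
      if (!is_habitat_profile(r_profile))
        stop("beverton_holt requires 'r_profile'", call. = FALSE)
      r <- r_profile
      list(family = family, r_profile = r,
           g = function(x, u) profile_eval(r, x) * u / (1 + u),
           eta = function(x) profile_eval(r, x),
           eta_tail_max = r$tail_max,
           monotone = TRUE,
           bound_L = if (is.null(bound_L)) max(r$levels) else bound_L,
           bound_Nbar = bound_Nbar)
    },
    logistic_nonmonotone = {
      if (!is_habitat_profile(r_profile))
        stop("logistic_nonmonotone requires 'r_profile'", call. = FALSE)
      r <- r_profile
      list(family = family, r_profile = r,
           g = function(x, u) profile_eval(r, x) * u * (1 - u),
           eta = function(x) profile_eval(r, x),
           eta_tail_max = r$tail_max,
           monotone = FALSE,
           bound_L = if (is.null(bound_L)) max(r$levels) else bound_L,
           bound_Nbar = bound_Nbar)
    },
    linear = {
      if (is.null(eta0) || !is.finite(eta0) || eta0 < 0)
        stop("linear family requires finite nonnegative 'eta0'", call. = FALSE)
      force(eta0)
      list(family = family, eta0 = eta0,
           g = function(x, u) eta0 * u,
           eta = function(x) rep_len(eta0, length(x)),
           eta_tail_max = eta0,
           monotone = TRUE,
           bound_L = if (is.null(bound_L)) eta0 else bound_L,
           bound_Nbar = bound_Nbar)
    })
  structure(spec, class = "birth_spec")
}

#' Gaussian dispersal kernel specification
#'
#' Probability density of adult dispersal displacement.  Only the Gaussian
#' family is used in the study scenarios; \code{mean} shifts dispersal in the
#' drift direction, \code{sd} sets its spread.
#'
#' @param mean Mean displacement (length units).
#' @param sd Positive standard deviation (length units).
#' @return An object of class \code{"kernel_spec"}.
#' @export
kernel_spec <- function(mean = 0, sd) {
  if (!is.numeric(sd) || length(sd) != 1L || sd <= 0)
    stop("'sd' must be a single positive number", call. = FALSE)
  force(mean); force(sd)
  k <- structure(
    list(family = "gaussian", mean = mean, sd = sd,
         fun = function(offset) stats::dnorm(offset, mean = mean, sd = sd)),
    class = "kernel_spec"
  )
  if (k$fun(0) <= 0)
    warning("kernel density vanishes at zero displacement; ",
            "strong positivity of the generation map is not guaranteed")
  k
}

#' Full model specification
#'
#' Bundles the transport parameters (diffusivity D, drift q, season length
#' tau) with the reaction, birth and dispersal-kernel specifications.
#'
#' @param D Positive diffusivity (area/time).  Default 1.
#' @param q Drift speed (length/time); positive values push downstream.
#' @param tau Positive season length (time).  Default 1.
#' @param reaction A \code{\link{reaction_spec}}.
#' @param birth A \code{\link{birth_spec}}.
#' @param kernel A \code{\link{kernel_spec}}.
#' @return An object of class \code{"model_spec"}.
#' @export
model_spec <- function(D = 1, q = 0, tau = 1, reaction, birth, kernel) {
  if (!is.numeric(D) || length(D) != 1L || D <= 0)
    stop("'D' must be a single positive number", call. = FALSE)
  if (!is.numeric(tau) || length(tau) != 1L || tau <= 0)
    stop("'tau' must be a single positive number", call. = FALSE)
  if (!inherits(reaction, "reaction_spec"))
    stop("'reaction' must be a reaction_spec", call. = FALSE)
  if (!inherits(birth, "birth_spec"))
    stop("'birth' must be a birth_spec", call. = FALSE)
  if (!inherits(kernel, "kernel_spec"))
    stop("'kernel' must be a kernel_spec", call. = FALSE)
  structure(list(D = D, q = q, tau = tau, reaction = reaction,
                 birth = birth, kernel = kernel),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf(paste0("<model_spec> D = %g, q = %g, tau = %g\n",
                     "  reaction: %s | birth: %s | kernel: gaussian(%g, %g)\n"),
              x$D, x$q, x$tau, x$reaction$family, x$birth$family,
              x$kernel$mean, x$kernel$sd))
  invisible(x)
}

#' Sampled-lattice validation of the reaction and birth structure conditions
#'
#' Checks, on a finite lattice, the structural requirements placed on f and
#' g: f(x, 0) = 0, g(x, 0) = 0, g >= 0, and sub-homogeneity (f(x, u)/u and,
#' for the Beverton-Holt family, g(x, u)/u nonincreasing in u).  Sampling
#' replaces symbolic verification; lattice and tolerance are configurable.
#'
#' @param model A \code{\link{model_spec}}.
#' @param xs Positions to sample (default 41 points spanning +-60).
#' @param us Density lattice (default \code{seq(0.1, 10, by = 0.1)}).
#' @param tol Monotonicity slack (default 1e-10).
#' @return Invisibly \code{TRUE}; stops with a message on the first violated
#'   condition.
#' @export
validate_model <- function(model, xs = seq(-60, 60, length.out = 41),
                           us = seq(0.1, 10, by = 0.1), tol = 1e-10) {
  stopifnot(inherits(model, "model_spec"))
  fx0 <- model$reaction$f(xs, rep(0, length(xs)))
  if (any(abs(fx0) > tol)) stop("f(x, 0) = 0 violated", call. = FALSE)
  gx0 <- model$birth$g(xs, rep(0, length(xs)))
  if (any(abs(gx0) > tol)) stop("g(x, 0) = 0 violated", call. = FALSE)
  u_chk <- if (model$birth$family == "logistic_nonmonotone") us[us <= 1] else us
  for (x0 in xs) {
    ratio_f <- model$reaction$f(rep(x0, length(us)), us) / us
    if (any(diff(ratio_f) > tol))
      stop("f(x, u)/u not nonincreasing in u at x = ", x0, call. = FALSE)
    gvals <- model$birth$g(rep(x0, length(u_chk)), u_chk)
    if (any(gvals < -tol)) stop("g(x, u) < 0 at x = ", x0, call. = FALSE)
    if (model$birth$family == "beverton_holt") {
      ratio_g <- gvals / u_chk
      if (any(diff(ratio_g) > tol))
        stop("g(x, u)/u not nonincreasing in u at x = ", x0, call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Check the bounded-favourable-habitat condition
#'
#' The threshold theory assumes the habitat is unfavourable at spatial
#' infinity: limsup eta * exp(limsup theta * tau) < 1, where theta and eta
#' are the linearisations of f and g at zero density.  For plateau profiles
#' the limsup is the constant tail value; for periodic profiles it is the
#' supremum over one period (the correct limsup of a periodic function) --
#' note that fully periodic habitats generally violate the condition, since
#' favourable patches recur arbitrarily far out.
#'
#' @param model A \code{\link{model_spec}}.
#' @return A list with \code{lhs} (the product above) and \code{holds}.
#' @examples
#' m <- model_spec(q = 1,
#'   reaction = reaction_spec("logistic_mortality",
#'                            alpha_profile = plateau_profile("mortality", 5)),
#'   birth = birth_spec("beverton_holt",
#'                      r_profile = plateau_profile("reproduction", 10)),
#'   kernel = kernel_spec(sd = 2))
#' check_assumption_A(m)  # lhs = exp(-1), holds
#' @export
check_assumption_A <- function(model) {
  stopifnot(inherits(model, "model_spec"))
  theta_tail <- model$reaction$theta_tail_max
  eta_tail <- model$birth$eta_tail_max
  if (is.null(theta_tail) || is.na(theta_tail) ||
      is.null(eta_tail) || is.na(eta_tail))
    stop("profiles without computable tail behaviour; supply tail limits",
         call. = FALSE)
  lhs <- eta_tail * exp(theta_tail * model$tau)
  list(holds = lhs < 1, lhs = lhs)
}

#' Invariance bound for the generation map
#'
#' The positive-invariance argument for the generation map yields a constant
#' A(K, M) such that densities starting below (a multiple of) it stay
#' bounded: A = M/K when K > 0, and A = M (Ntilde + 1)/(K + M) when K <= 0
#' (requiring K + M > 0).
#'
#' @param K Growth-bound constant of the reaction term.
#' @param M Auxiliary positive constant.
#' @param Ntilde Threshold density of the growth bound.
#' @return The bound A(K, M).
#' @export
invariance_bound <- function(K, M, Ntilde) {
  stopifnot(is.numeric(K), is.numeric(M), is.numeric(Ntilde))
  if (K > 0) return(M / K)
  if (K + M <= 0)
    stop("for K <= 0 the bound requires K + M > 0", call. = FALSE)
  M * (Ntilde + 1) / (K + M)
}

#' Check the compatibility condition L * exp(K * tau) <= 1
#'
#' The positive-invariance theory assumes L e^{K tau} <= 1 for the bound
#' constants of f and g.  The standard simulation constants (K = 0, L = 2)
#' violate it while the simulations remain well-behaved, so a violation emits
#' a warning rather than an error.
#'
#' @param model A \code{\link{model_spec}}.
#' @return A list with \code{value} = L e^{K tau} and \code{holds}.
#' @export
check_LK_condition <- function(model) {
  stopifnot(inherits(model, "model_spec"))
  K <- model$reaction$bound_K
  L <- model$birth$bound_L
  value <- L * exp(K * model$tau)
  holds <- value <= 1
  if (!holds)
    warning(sprintf(paste0("L*exp(K*tau) = %g > 1: the positive-invariance ",
                           "assumption fails for these bound constants; ",
                           "proceeding anyway"), value), call. = FALSE)
  list(value = value, holds = holds)
}

#' Linearisation of a model at zero density
#'
#' Extracts the pair theta(x) = d f/d u (x, 0), eta(x) = d g/d u (x, 0)
#' together with the transport parameters and the dispersal kernel.  This is
#' the data defining the linearised generation operator
#' L(phi) = K * (eta * P_tau(phi)), where P_tau propagates phi through the
#' linear within-season equation with rate theta.
#'
#' @param model A \code{\link{model_spec}}, or \code{NULL} when building a
#'   homogeneous linearisation directly via \code{eta0}/\code{theta0}.
#' @param eta0,theta0 Constant linearisation values (homogeneous case).
#' @param D,q,tau,kernel Transport parameters and kernel, required when
#'   \code{model} is \code{NULL}.
#' @return An object of class \code{"linearized_model"} with function fields
#'   \code{eta}, \code{theta} and transport parameters.
#' @export
linearize <- function(model = NULL, eta0 = NULL, theta0 = NULL,
                      D = 1, q = 0, tau = 1, kernel = NULL) {
  if (!is.null(model)) {
    stopifnot(inherits(model, "model_spec"))
    out <- list(eta = model$birth$eta, theta = model$reaction$theta,
                D = model$D, q = model$q, tau = model$tau,
                kernel = model$kernel)
  } else {
    if (is.null(eta0) || is.null(theta0) || is.null(kernel))
      stop("without a model, supply eta0, theta0 and kernel", call. = FALSE)
    force(eta0); force(theta0)
    out <- list(eta = function(x) rep_len(eta0, length(x)),
                theta = function(x) rep_len(theta0, length(x)),
                D = D, q = q, tau = tau, kernel = kernel)
  }
  structure(out, class = "linearized_model")
}
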