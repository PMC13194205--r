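#' Habitat profiles
#'
#' Habitat heterogeneity enters the model through two spatial profiles: a
#' reproduction profile r(x) (low-density fecundity, between a baseline of 1
#' far from the favourable patch and a peak of 2 on it) and a mortality
#' profile alpha(x) (location-dependent death rate, 0 on the favourable patch
#' and 1 far away).  Two families are provided: a single central plateau with
#' linear ramps, and a 5*scale-periodic arrangement of the same ramp motif.
#'
#' A profile object carries its evaluator together with the tail behaviour
#' needed by the habitat-type check: \code{tail_max}/\code{tail_min} are the
#' limsup/liminf of the profile at spatial infinity (for periodic profiles,
#' the max/min over one period).
#'
#' @name habitat-profiles
NULL

new_habitat_profile <- function(kind, scale, levels, fun, tail_max, tail_min,
                                period = NA_real_) {
  structure(
    list(kind = kind, scale = scale, levels = levels, fun = fun,
         tail_max = tail_max, tail_min = tail_min, period = period),
    class = "habitat_profile"
  )
}

is_habitat_profile <- function(x) inherits(x, "habitat_profile")

#' Evaluate a habitat profile
#' @param p A \code{habitat_profile}.
#' @param x Numeric vector of positions.
#' @return Profile values at \code{x}.
#' @export
profile_eval <- function(p, x) {
  if (!is_habitat_profile(p)) stop("'p' must be a habitat_profile", call. = FALSE)
  p$fun(x)
}

#' @export
print.habitat_profile <- function(x, ...) {
  cat(sprintf("<habitat_profile> %s, scale %g, levels [%g, %g]\n",
              x$kind, x$scale, min(x$levels), max(x$levels)))
  invisible(x)
}

#' Single-plateau habitat profile
#'
#' Piecewise-linear profile with a central plateau of half-width
#' \code{scale} and linear ramps to a constant tail outside
#' \code{[-2*scale, 2*scale]}.  For \code{role = "reproduction"} the profile
#' ramps 1 -> 2 -> 1 with value 2 on \code{[-scale, scale]}; for
#' \code{role = "mortality"} it ramps 1 -> 0 -> 1 with value 0 on the plateau.
#'
#' @param role \code{"reproduction"} or \code{"mortality"}.
#' @param scale Positive plateau half-width (the l or m of the model).
#' @return A \code{habitat_profile}.
#' @examples
#' r <- plateau_profile("reproduction", 10)
#' profile_eval(r, c(0, 15, 25))   # 2, 1.5, 1
#' @export
plateau_profile <- function(role = c("reproduction", "mortality"), scale) {
  role <- match.arg(role)
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop("'scale' must be a single positive number", call. = FALSE)
  if (role == "reproduction") {
    fun <- function(x) 1 + pmax(0, pmin(1, 2 - abs(x) / scale))
    new_habitat_profile("plateau_reproduction", scale, c(1, 2), fun,
                        tail_max = 1, tail_min = 1)
  } else {
    fun <- function(x) pmax(0, pmin(1, abs(x) / scale - 1))
    new_habitat_profile("plateau_mortality", scale, c(0, 1), fun,
                        tail_max = 1, tail_min = 1)
  }
}

#' Periodic habitat profile
#'
#' A continuous, \code{5*scale}-periodic arrangement of the plateau motif:
#' one favourable plateau per period, flanked by linear ramps and a stretch of
#' baseline habitat.  On the fundamental cell \code{(-scale, 4*scale]} the
#' reproduction profile takes the value 2 on \code{(-scale, scale]}, descends
#' to 1 on \code{(scale, 2*scale]}, stays at 1 on \code{(2*scale, 3*scale]},
#' and ascends back to 2 on \code{(3*scale, 4*scale]} (the ascending branch is
#' the continuity-consistent ramp \code{x/scale - 2}); the mortality profile
#' is the analogous 0/1 motif with ascending branch \code{-x/scale + 4}.
#'
#' @inheritParams plateau_profile
#' @return A \code{habitat_profile} with period \code{5*scale}.
#' @examples
#' r1 <- periodic_profile("reproduction", 15)
#' profile_eval(r1, c(0, 40, 52.5))  # 2, 1, 1.5
#' @export
periodic_profile <- function(role = c("reproduction", "mortality"), scale) {
  role <- match.arg(role)
  if (!is.numeric(scale) || length(scale) != 1L || scale <= 0)
    stop("'scale' must be a single positive number", call. = FALSE)
  period <- 5 * scale
  if (role == "reproduction") {
    fun <- function(x) {
      y <- x %% period  # y in [0, 5*scale)
      ifelse(y <= scale, 2,
        ifelse(y <= 2 * scale, 3 - y / scale,
          ifelse(y <= 3 * scale, 1,
            ifelse(y <= 4 * scale, y / scale - 2, 2))))
    }
    new_habitat_profile("periodic_reproduction", scale, c(1, 2), fun,
                        tail_max = 2, tail_min = 1, period = period)
  } else {
    fun <- function(x) {
      y <- x %% period
      ifelse(y <= scale, 0,
        ifelse(y <= 2 * scale, y / scale - 1,
          ifelse(y <= 3 * scale, 1,
            ifelse(y <= 4 * scale, 4 - y / scale, 0))))
    }
    new_habitat_profile("periodic_mortality", scale, c(0, 1), fun,
                        tail_max = 1, tail_min = 0, period = period)
  }
}

#' Spatially constant profile
#'
#' @param value The constant value.
#' @return A \code{habitat_profile} of kind \code{"constant"}.
#' @export
constant_profile <- function(value) {
  force(value)
  new_habitat_profile("constant", scale = 1, levels = c(value, value),
                      fun = function(x) rep_len(value, length(x)),
                      tail_max = value, tail_min = value)
}

#' User-supplied profile
#'
#' @param fun Vectorised evaluator, position -> value.
#' @param tail_max,tail_min limsup/liminf of the profile at spatial infinity
#'   (\code{NA} if unknown; habitat-type checks then refuse the profile).
#' @param levels Range of the profile values, used only for reporting.
#' @return A \code{habitat_profile} of kind \code{"custom"}.
#' @export
custom_profile <- function(fun, tail_max = NA_real_, tail_min = NA_real_,
                           levels = c(NA_real_, NA_real_)) {
  stopifnot(is.function(fun))
  new_habitat_profile("custom", scale = 1, levels = levels, fun = fun,
                      tail_max = tail_max, tail_min = tail_min)
}

#' Export a profile as a two-column data frame
#'
#' @param p A \code{habitat_profile}.
#' @param grid A \code{\link{spatial_grid}} giving the positions.
#' @return \code{data.frame} with columns \code{position} and \code{value},
#'   suitable for writing as CSV or plotting.
#' @export
profile_table <- function(p, grid) {
  data.frame(position = grid$nodes, value = profile_eval(p, grid$nodes))
}
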