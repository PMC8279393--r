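#' Parametric hazard regimes for synthetic cohorts
#'
#' A `hazard_spec` describes the force of mortality \eqn{\mu(x)} (per year)
#' at ages \eqn{x \ge 105}, used to generate synthetic lifespans and as
#' ground truth in recovery tests:
#'
#' * `hazard_const(level)` — a mortality plateau, \eqn{\mu(x) = \lambda}.
#' * `hazard_gompertz(level, slope)` — \eqn{\mu(x) = \lambda
#'   e^{b (x - 105)}}, with `level` the hazard at age 105 and `slope` the
#'   log-hazard increase per year of age.
#' * `hazard_piecewise(breakpoints, levels)` — piecewise-constant:
#'   `levels[k]` on `[breakpoints[k], breakpoints[k + 1])` (left-closed),
#'   the last level extending to infinity. `breakpoints[1]` must be 105.
#'
#' @param level hazard level, per year (> 0); for Gompertz, the level at 105.
#' @param slope Gompertz log-slope per year of age.
#' @param breakpoints strictly increasing ages (years), starting at 105.
#' @param levels hazard per year on each piece (> 0), same length as
#'   `breakpoints`.
#' @return an object of class `hazard_spec`.
#' @seealso [hazard_value()], [sample_lifespan()]
#' @export
hazard_const <- function(level) {
  stopifnot(is.numeric(level), length(level) == 1L, level > 0)
  structure(list(kind = "constant", level = level), class = "hazard_spec")
}

#' @rdname hazard_const
#' @export
hazard_gompertz <- function(level, slope) {
  stopifnot(is.numeric(level), length(level) == 1L, level > 0,
            is.numeric(slope), length(slope) == 1L, is.finite(slope))
  structure(list(kind = "gompertz", level = level, slope = slope),
            class = "hazard_spec")
}

#' @rdname hazard_const
#' @export
hazard_piecewise <- function(breakpoints, levels) {
  stopifnot(is.numeric(breakpoints), is.numeric(levels),
            length(breakpoints) == length(levels), length(levels) >= 1L,
            all(levels > 0), all(diff(breakpoints) > 0))
  if (breakpoints[1L] != 105) {
    stop("`breakpoints` must start at age 105", call. = FALSE)
  }
  structure(list(kind = "piecewise_constant",
                 breakpoints = as.numeric(breakpoints),
                 levels = as.numeric(levels)),
            class = "hazard_spec")
}

#' @export
print.hazard_spec <- function(x, ...) {
  switch(x$kind,
    constant = cat(sprintf("<hazard_spec> constant plateau: %.3g /year\n",
                           x$level)),
    gompertz = cat(sprintf(
      "<hazard_spec> Gompertz: %.3g /year at 105, slope %.3g /year\n",
      x$level, x$slope)),
    piecewise_constant = cat(sprintf(
      "<hazard_spec> piecewise constant: %s\n",
      paste(sprintf("[%g+) %.3g", x$breakpoints, x$levels),
            collapse = ", "))))
  invisible(x)
}

#' Evaluate a hazard regime at given ages
#'
#' @param spec a [hazard_spec][hazard_const] object.
#' @param age numeric vector of ages in decimal years, all >= 105.
#' @return hazard, per year, at each age.
#' @export
hazard_value <- function(spec, age) {
  stopifnot(inherits(spec, "hazard_spec"))
  if (any(age < 105)) stop("ages below 105 are outside the model's domain",
                           call. = FALSE)
  switch(spec$kind,
    constant = rep_len(spec$level, length(age)),
    gompertz = spec$level * exp(spec$slope * (age - 105)),
    piecewise_constant = {
      idx <- findInterval(age, spec$breakpoints)
      spec$levels[idx]
    })
}

# cumulative hazard at the start of each piece: H(breakpoints[k] - 105)
piece_cum_hazard <- function(spec) {
  K <- length(spec$levels)
  if (K == 1L) 0 else c(0, cumsum(spec$levels[-K] * diff(spec$breakpoints)))
}

# Cumulative hazard over (105, 105 + t], vectorized in t >= 0.
cumulative_hazard <- function(spec, t) {
  stopifnot(inherits(spec, "hazard_spec"), all(t >= 0))
  switch(spec$kind,
    constant = spec$level * t,
    gompertz = {
      b <- spec$slope
      if (b == 0) spec$level * t else spec$level / b * (exp(b * t) - 1)
    },
    piecewise_constant = {
      off <- spec$breakpoints - 105
      cumH <- piece_cum_hazard(spec)
      idx <- findInterval(t, off)
      cumH[idx] + spec$levels[idx] * (t - off[idx])
    })
}

#' Draw lifespans past age 105 from a hazard regime
#'
#' Samples the survival time past the 105th birthday, \eqn{X}, by inverse
#' transform: \eqn{X = H^{-1}(E)} with \eqn{E \sim \mathrm{Exp}(1)} and
#' \eqn{H} the cumulative hazard of `spec`. All three regimes use their
#' closed-form inverse. Uses R's current random stream; seed with
#' [set.seed()] for reproducibility.
#'
#' @param spec a [hazard_spec][hazard_const] object.
#' @param n number of draws.
#' @return numeric vector of lifespans in decimal years past 105.
#' @export
sample_lifespan <- function(spec, n) {
  stopifnot(inherits(spec, "hazard_spec"), n >= 0)
  e <- stats::rexp(n)
  switch(spec$kind,
    constant = e / spec$level,
    gompertz = {
      b <- spec$slope
      if (b < 0) {
        stop("Gompertz with negative slope has a defective survival law; ",
             "lifespans past 105 cannot all be sampled", call. = FALSE)
      }
      if (b == 0) e / spec$level else log1p(b * e / spec$level) / b
    },
    piecewise_constant = {
      off <- spec$breakpoints - 105
      cumH <- piece_cum_hazard(spec)
      # strictly increasing since all levels > 0, so the inverse is exact
      idx <- findInterval(e, cumH)
      off[idx] + (e - cumH[idx]) / spec$levels[idx]
    })
}
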