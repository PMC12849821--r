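#' Default normalization constant of the DoG curve
#'
#' The derivative-of-Gaussian tuning curve used throughout this package is
#' `dog(x) = x * a * w * c * exp(-(w*x)^2)`. With `c = sqrt(2*e)` the
#' amplitude parameter `a` equals the height of the peak (and depth of the
#' valley) of the curve, which is the convention used for all defaults.
#'
#' @return The scalar `sqrt(2 * exp(1))`, approximately 2.33164.
#' @export
#' @examples
#' dog_norm_const()
dog_norm_const <- function() sqrt(2 * exp(1))

#' Parameters of a derivative-of-Gaussian tuning curve
#'
#' Bundles the amplitude `a` (degrees, may be negative: positive values
#' encode attraction toward the past with this package's sign convention),
#' the inverse width `w` (1/degrees) and the normalization constant `c`.
#'
#' @param a Amplitude, in the units of the error axis (degrees for
#'   orientation). Any finite real.
#' @param w Inverse width, per degree. Must be finite and `>= 0`; `w = 0`
#'   degenerates the curve to the zero function and is permitted for
#'   evaluation but rejected by [dog_peak()].
#' @param c Normalization constant, dimensionless, `> 0`. Defaults to
#'   [dog_norm_const()], under which `max_x dog(x) = a`.
#' @return An object of class `"dog_params"`.
#' @export
#' @examples
#' p <- dog_params(a = 4.8, w = 0.03)
#' dog(1, p)
dog_params <- function(a, w, c = dog_norm_const()) {
  if (!is.numeric(a) || length(a) != 1L || !is.finite(a))
    stop("'a' must be a single finite number", call. = FALSE)
  if (!is.numeric(w) || length(w) != 1L || !is.finite(w) || w < 0)
    stop("'w' must be a single finite number >= 0", call. = FALSE)
  if (!is.numeric(c) || length(c) != 1L || !is.finite(c) || c <= 0)
    stop("'c' must be a single finite number > 0", call. = FALSE)
  structure(list(a = a, w = w, c = c), class = "dog_params")
}

#' @export
print.dog_params <- function(x, ...) {
  cat(sprintf("DoG parameters: a = %g, w = %g, c = %g\n", x$a, x$w, x$c))
  invisible(x)
}

as_dog_params <- function(p) {
  if (inherits(p, "dog_params")) return(p)
  if (is.list(p) && all(c("a", "w") %in% names(p)))
    return(dog_params(p$a, p$w, if (is.null(p$c)) dog_norm_const() else p$c))
  if (is.numeric(p) && length(p) >= 2L)
    return(dog_params(p[[1L]], p[[2L]]))
  stop("cannot interpret 'params' as DoG parameters", call. = FALSE)
}

#' Evaluate the derivative-of-Gaussian tuning curve
#'
#' Computes `x * a * w * c * exp(-(w*x)^2)` elementwise. The curve is odd
#' in `x` and, with the default normalization constant, bounded in
#' magnitude by `|a|`.
#'
#' @param x Signed difference(s) in degrees; any finite real vector.
#' @param params A [dog_params()] object (or a list/length-2 numeric that
#'   can be coerced to one).
#' @return Numeric vector of the same length as `x`, in degrees.
#' @export
#' @examples
#' dog(0, dog_params(4.8, 0.03))         # 0: odd function through origin
#' round(dog(1, dog_params(4.8, 0.03)), 2)  # 0.34
dog <- function(x, params) {
  params <- as_dog_params(params)
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("'x' must be numeric and finite", call. = FALSE)
  x * params$a * params$w * params$c * exp(-(params$w * x)^2)
}

#' Peak of the DoG curve
#'
#' The curve attains its maximum at `x = 1/(w*sqrt(2))`; with the default
#' normalization constant the height there equals `a`.
#'
#' @inheritParams dog
#' @return Named numeric vector `c(location = , height = )`, in degrees.
#' @export
#' @examples
#' dog_peak(dog_params(4.8, 0.03))
dog_peak <- function(params) {
  params <- as_dog_params(params)
  if (params$w <= 0)
    stop("dog_peak() requires w > 0", call. = FALSE)
  loc <- 1 / (params$w * sqrt(2))
  c(location = loc, height = dog(loc, params))
}
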