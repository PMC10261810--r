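#' Distribution specifications for exposure parameters
#'
#' Small declarative specs for the stochastic exposure-model inputs
#' (intake rate, body weight, exposure frequency/duration, averaging time,
#' fat fraction). Four families are supported:
#'
#' * `dist_point(value)` — degenerate point mass (the default for
#'   parameters whose survey values are known only as single numbers);
#' * `dist_uniform(min, max)` — uniform on `[min, max]`;
#' * `dist_normal(mean, sd)` — normal truncated to positive support
#'   (exposure factors cannot be negative);
#' * `dist_lognormal(mean, sd)` — lognormal parameterised by its
#'   *arithmetic* mean and SD via [fit_lognormal_moments()].
#'
#' @param value,mean,sd,min,max Family parameters on the natural scale.
#' @return An object of class `dist_spec`.
#' @name dist_spec
#' @examples
#' draw_dist(dist_uniform(15, 70), 5, seed = 1)
NULL

new_dist_spec <- function(family, params) {
  structure(list(family = family, params = params), class = "dist_spec")
}

#' @rdname dist_spec
#' @export
dist_point <- function(value) {
  stopifnot(is.finite(value))
  new_dist_spec("point", list(value = value))
}

#' @rdname dist_spec
#' @export
dist_uniform <- function(min, max) {
  if (min > max) abort("`min` must be <= `max`.")
  new_dist_spec("uniform", list(min = min, max = max))
}

#' @rdname dist_spec
#' @export
dist_normal <- function(mean, sd) {
  if (sd < 0) abort("`sd` must be >= 0.")
  new_dist_spec("normal", list(mean = mean, sd = sd))
}

#' @rdname dist_spec
#' @export
dist_lognormal <- function(mean, sd) {
  fit <- fit_lognormal_moments(mean, sd)
  new_dist_spec("lognormal", list(mean = mean, sd = sd,
                                  mu = fit$mu, sigma = fit$sigma))
}

#' @export
print.dist_spec <- function(x, ...) {
  cat("<dist_spec> ", x$family, "(",
      paste(names(x$params), unlist(x$params), sep = " = ", collapse = ", "),
      ")\n", sep = "")
  invisible(x)
}

as_dist_spec <- function(x, what = "parameter") {
  if (inherits(x, "dist_spec")) return(x)
  if (is.numeric(x) && length(x) == 1) return(dist_point(x))
  abort(paste0("Unknown distribution specification for ", what,
               ": supply a `dist_spec` or a single number."))
}

#' Draw from a distribution specification
#'
#' @param spec A [dist_spec] object (or a single number, taken as a point
#'   mass).
#' @param n Number of draws.
#' @param seed Optional integer seed applied just for this draw.
#' @return Numeric vector of length `n`.
#' @export
draw_dist <- function(spec, n, seed = NULL) {
  spec <- as_dist_spec(spec)
  draw <- function() {
    p <- spec$params
    switch(spec$family,
      point = rep(p$value, n),
      uniform = runif(n, p$min, p$max),
      normal = {
        # truncated to positive support by rejection
        out <- numeric(0)
        while (length(out) < n) {
          x <- rnorm(n - length(out) + 10L, p$mean, p$sd)
          out <- c(out, x[x > 0])
        }
        out[seq_len(n)]
      },
      lognormal = rlnorm(n, p$mu, p$sigma),
      abort(paste0("Unknown distribution family: ", spec$family))
    )
  }
  if (is.null(seed)) draw() else with_stream_seed(seed, spec$family, draw())
}
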