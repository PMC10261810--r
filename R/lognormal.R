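#' Moment-match a lognormal distribution
#'
#' Finds the log-scale parameters (`mu`, `sigma`) of the lognormal whose
#' arithmetic mean and standard deviation equal the supplied values:
#' `sigma^2 = log(1 + (sd/mean)^2)`, `mu = log(mean) - sigma^2/2`.
#' Concentrations of lipophilic residues are strictly positive and
#' right-skewed, which is why the lognormal is the package's default
#' concentration model.
#'
#' @param mean Arithmetic mean (must be > 0), e.g. ng/g fat.
#' @param sd Arithmetic standard deviation (>= 0), same units.
#' @return A tibble with columns `mean`, `sd`, `mu`, `sigma`. Vectorised
#'   over `mean` and `sd`.
#' @seealso [lognormal_moments()] for the inverse map,
#'   [fit_truncated_lognormal()] for moment matching under truncation.
#' @export
#' @examples
#' fit_lognormal_moments(9.98, 2.04)
fit_lognormal_moments <- function(mean, sd) {
  if (any(!is.finite(mean)) || any(mean <= 0)) {
    abort("`mean` must be finite and > 0 to fit a lognormal.")
  }
  if (any(!is.finite(sd)) || any(sd < 0)) {
    abort("`sd` must be finite and >= 0.")
  }
  sigma2 <- log(1 + (sd / mean)^2)
  tibble::tibble(mean = mean, sd = sd,
                 mu = log(mean) - sigma2 / 2, sigma = sqrt(sigma2))
}

#' Arithmetic moments of a lognormal distribution
#'
#' @param mu Log-scale location.
#' @param sigma Log-scale spread (>= 0).
#' @return A tibble with columns `mu`, `sigma`, `mean`, `sd`.
#' @export
#' @examples
#' lognormal_moments(0, 0) # degenerate point mass at 1
lognormal_moments <- function(mu, sigma) {
  if (any(sigma < 0)) abort("`sigma` must be >= 0.")
  m <- exp(mu + sigma^2 / 2)
  v <- (exp(sigma^2) - 1) * exp(2 * mu + sigma^2)
  tibble::tibble(mu = mu, sigma = sigma, mean = m, sd = sqrt(v))
}

#' Mean and SD of a lognormal truncated to an interval
#'
#' Closed-form arithmetic mean and standard deviation of a lognormal with
#' log-scale parameters (`mu`, `sigma`) conditioned on lying in
#' `[lower, upper]`.
#'
#' @param mu,sigma Log-scale parameters; `sigma = 0` is the point mass at
#'   `exp(mu)`.
#' @param lower,upper Truncation bounds, `0 < lower <= upper`.
#' @return A tibble with columns `mean`, `sd` and `mass` (the untruncated
#'   probability of the window).
#' @export
truncated_lognormal_moments <- function(mu, sigma, lower, upper) {
  if (lower > upper) abort("`lower` must be <= `upper`.")
  if (sigma <= 0) {
    return(tibble::tibble(mean = exp(mu), sd = 0,
                          mass = as.numeric(exp(mu) >= lower & exp(mu) <= upper)))
  }
  a <- (log(lower) - mu) / sigma
  b <- (log(upper) - mu) / sigma
  mass <- pnorm(b) - pnorm(a)
  if (!is.finite(mass) || mass <= 0) {
    return(tibble::tibble(mean = NA_real_, sd = NA_real_, mass = 0))
  }
  m1 <- exp(mu + sigma^2 / 2) * (pnorm(b - sigma) - pnorm(a - sigma)) / mass
  m2 <- exp(2 * mu + 2 * sigma^2) * (pnorm(b - 2 * sigma) - pnorm(a - 2 * sigma)) / mass
  tibble::tibble(mean = m1, sd = sqrt(max(m2 - m1^2, 0)), mass = mass)
}

# For fixed sigma, the truncated mean is strictly increasing in mu while the
# window keeps positive mass; root-find the mu that hits `target`. When the
# location sits far outside the window the normal-CDF differences underflow;
# the truncated mean is then pinned at the nearer window edge, which fixes
# the sign of the objective without evaluating it.
mu_matching_truncated_mean <- function(target, sigma, lower, upper) {
  f <- function(mu) {
    m <- truncated_lognormal_moments(mu, sigma, lower, upper)$mean
    m - target
  }
  lo <- log(lower) - 3 * sigma
  hi <- log(upper) + 3 * sigma
  flo <- f(lo)
  if (!is.finite(flo)) flo <- lower - target
  k <- 0
  while (flo > 0 && k < 12) {
    lo <- lo - sigma
    flo <- f(lo)
    if (!is.finite(flo)) flo <- lower - target
    k <- k + 1
  }
  fhi <- f(hi)
  if (!is.finite(fhi)) fhi <- upper - target
  k <- 0
  while (fhi < 0 && k < 12) {
    hi <- hi + sigma
    fhi <- f(hi)
    if (!is.finite(fhi)) fhi <- upper - target
    k <- k + 1
  }
  if (!(flo <= 0 && fhi >= 0)) {
    abort("Could not bracket the truncated-mean root; check the moment spec.")
  }
  uniroot(function(mu) {
    v <- f(mu)
    if (!is.finite(v)) return(lower - target)
    v
  }, c(lo, hi), tol = 1e-12)$root
}

#' Moment-match a lognormal under interval truncation
#'
#' Finds (`mu`, `sigma`) such that the lognormal *restricted to*
#' `[lower, upper]` has arithmetic mean exactly `mean` and standard
#' deviation as close as the family allows to `sd`. Plain moment matching
#' followed by truncation biases the mean (the window clips one tail more
#' than the other), so generation calibrated to printed summary statistics
#' must solve the truncated problem instead.
#'
#' The mean is matched to numerical precision by a monotone root-find on
#' `mu` nested inside a 1-D search over `sigma` that minimises the relative
#' SD error, subject to the truncation window retaining at least
#' `mass_floor` of the untruncated probability mass (narrower windows make
#' rejection sampling arbitrarily slow and the printed SDs are often
#' unattainable on the window anyway; see the methods vignette).
#'
#' @inheritParams fit_lognormal_moments
#' @param lower,upper Truncation bounds with `0 < lower <= mean <= upper`.
#' @param sigma_max Upper bound of the `sigma` search.
#' @param mass_floor Minimum acceptable window probability mass.
#' @return A one-row tibble with columns `mu`, `sigma`, `mean`, `sd`
#'   (achieved truncated moments) and `mass`.
#' @export
#' @examples
#' fit_truncated_lognormal(9.58, 0.93, 8.64, 10.88)
fit_truncated_lognormal <- function(mean, sd, lower, upper,
                                    sigma_max = 2, mass_floor = 0.05) {
  if (!is.finite(mean) || mean <= 0) abort("`mean` must be > 0.")
  if (!is.finite(sd) || sd < 0) abort("`sd` must be >= 0.")
  if (lower > upper) abort("Infeasible bounds: `lower` > `upper`.")
  if (mean < lower || mean > upper) {
    abort("Infeasible bounds: `mean` must lie inside [lower, upper].")
  }
  if (sd == 0 || lower == upper) {
    return(tibble::tibble(mu = log(mean), sigma = 0, mean = mean, sd = 0, mass = 1))
  }
  if (lower <= 0 && !is.finite(upper)) {
    # no effective truncation: the plain moment match is exact
    fit <- fit_lognormal_moments(mean, sd)
    return(tibble::tibble(mu = fit$mu, sigma = fit$sigma,
                          mean = mean, sd = sd, mass = 1))
  }
  if (lower <= 0) lower <- upper * 1e-12
  objective <- function(sigma) {
    mu <- tryCatch(mu_matching_truncated_mean(mean, sigma, lower, upper),
                   error = function(e) NA_real_)
    if (!is.finite(mu)) return(1e6)
    tm <- truncated_lognormal_moments(mu, sigma, lower, upper)
    if (!is.finite(tm$sd) || tm$mass <= 0) return(1e6)
    # log-mass penalty keeps the objective increasing once the window gets
    # improbable, so the search cannot stall on a saturated plateau
    abs(tm$sd - sd) / sd + 10 * max(0, log(mass_floor) - log(tm$mass))
  }
  # coarse log-spaced scan, then local refinement around the best cell
  grid <- exp(seq(log(1e-4), log(sigma_max), length.out = 40))
  vals <- vapply(grid, objective, numeric(1))
  i <- which.min(vals)
  span <- c(grid[max(1, i - 1)], grid[min(length(grid), i + 1)])
  opt <- optimize(objective, span)
  sigma <- if (opt$objective < vals[i]) opt$minimum else grid[i]
  mu <- mu_matching_truncated_mean(mean, sigma, lower, upper)
  tm <- truncated_lognormal_moments(mu, sigma, lower, upper)
  tibble::tibble(mu = mu, sigma = sigma, mean = tm$mean, sd = tm$sd, mass = tm$mass)
}

#' Rejection-sample a truncated lognormal
#'
#' Draws from a lognormal with parameters (`mu`, `sigma`), rejecting and
#' redrawing until all draws lie in `[lower, upper]`. Errors when the
#' window holds less than 0.01% of the untruncated mass.
#'
#' @param n Number of draws.
#' @inheritParams truncated_lognormal_moments
#' @return Numeric vector of length `n`, all in `[lower, upper]`.
#' @export
rlnorm_truncated <- function(n, mu, sigma, lower = 0, upper = Inf) {
  if (lower > upper) abort("Infeasible bounds: `lower` > `upper`.")
  if (sigma <= 0) {
    x <- exp(mu)
    tol <- 1e-9 * max(abs(x), 1e-300)
    if (x < lower - tol || x > upper + tol) {
      abort("Point mass lies outside the truncation window.")
    }
    return(rep(min(max(x, lower), upper), n))
  }
  mass <- pnorm((log(upper) - mu) / sigma) - pnorm((log(lower) - mu) / sigma)
  if (!is.finite(mass) || mass < 1e-4) {
    abort("Truncation window excludes more than 99.99% of the distribution's mass.")
  }
  out <- numeric(0)
  while (length(out) < n) {
    batch <- min(ceiling((n - length(out)) / mass * 1.1) + 100L, 5e6)
    x <- rlnorm(batch, mu, sigma)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

# Deterministic per-stream child seed from a root seed and a label, so that
# adding a congener or product does not perturb the other streams' draws.
# Plain 32-bit multiplicative string hash folded with the root seed.
stream_seed <- function(root_seed, label) {
  h <- 5381
  for (ch in utf8ToInt(label)) h <- (h * 33 + ch) %% 2147483647
  as.integer((h + as.numeric(root_seed) * 97003) %% 2147483647)
}

with_stream_seed <- function(root_seed, label, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(stream_seed(root_seed, label))
  force(expr)
}
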