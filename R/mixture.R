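# Non-parametric two-component RSF mixture and Bayesian-network posteriors.
#
# Observed transitions arise from a chain Theta -> X -> Y: Theta in {1,2}
# encodes the source (1 = non-experimental, 2 = crosslink-induced) with prior
# p(Theta = 1) = lambda; X is the per-position substitution probability drawn
# from the source's RSF density f1 or f2; Y ~ Binomial(z, X) is the observed
# transition count at coverage z. The two densities are estimated
# non-parametrically on a fixed RSF grid: f-hat from the target transition
# type (e.g. T->C), f1 from all other substitution types pooled (which cannot
# be crosslink-induced), and f2 by mixture subtraction
# f2 = (f-hat - lambda * f1) / (1 - lambda).

#' Fit the two-component RSF mixture model
#'
#' Estimates grid densities by binned counting followed by boundary-corrected
#' Gaussian kernel smoothing, sets \eqn{\lambda} to the largest mixing weight
#' keeping the signal component non-negative (the minimum of
#' \eqn{\hat f / f_1} over well-supported grid points), and recovers the
#' signal density \eqn{f_2} by subtraction.
#'
#' @param target Target-transition sites: a \code{data.frame} from
#'   \code{\link{extract_sites}} (columns \code{x}, \code{z}) or a numeric
#'   vector of RSF values in (0, 1].
#' @param background Background sites pooled over all other substitution
#'   types (same formats).
#' @param min_cov Minimum coverage applied to both site sets when \code{z} is
#'   available (default 20).
#' @param grid_step RSF grid resolution on (0, 1] (default 0.001).
#' @param bandwidth Gaussian smoothing bandwidth in RSF units (default 0.01).
#' @param f1_floor Relative density floor: \eqn{\lambda} is estimated only at
#'   grid points where \eqn{f_1} exceeds \code{f1_floor * max(f1)}, keeping
#'   the ratio away from undersampled tails (default 0.01).
#' @param lambda_bandwidth Extra smoothing (RSF units) applied to both
#'   densities before taking the ratio minimum, so the estimate reflects the
#'   local density mass rather than single-grid-point noise (default 0.04).
#' @return An object of class \code{"rsf_mixture"}: list with \code{grid},
#'   \code{f1}, \code{f2}, \code{fhat}, \code{lambda}, \code{grid_step},
#'   \code{bandwidth}, \code{n_target}, \code{n_background}.
#' @export
fit_rsf_mixture <- function(target, background, min_cov = 20L,
                            grid_step = 0.001, bandwidth = 0.01,
                            f1_floor = 0.01, lambda_bandwidth = 0.04) {
  tx <- site_rsf(target, min_cov)
  bx <- site_rsf(background, min_cov)
  if (length(bx) == 0L) {
    stop("cannot estimate non-experimental component: no background sites")
  }
  if (length(tx) == 0L) {
    stop("no target sites after coverage filtering")
  }
  grid <- seq(grid_step, 1, by = grid_step)
  fhat <- grid_density(tx, grid, grid_step, bandwidth)
  f1 <- grid_density(bx, grid, grid_step, bandwidth)

  # ratio minimum on variance-stabilized (additionally smoothed) densities:
  # the mixing weight is a mass ratio, so single-bin fluctuations must not
  # drive the minimum
  fhat_s <- smooth_on_grid(fhat, grid_step, lambda_bandwidth)
  f1_s <- smooth_on_grid(f1, grid_step, lambda_bandwidth)
  ok <- f1_s > f1_floor * max(f1_s)
  lambda <- min(fhat_s[ok] / f1_s[ok])
  lambda <- max(0, lambda)
  if (lambda >= 1 - 1e-9) {
    stop("no experimental signal detected: target RSF distribution is ",
         "explained by the background alone (lambda ~ 1)")
  }
  f2 <- (fhat - lambda * f1) / (1 - lambda)
  f2[f2 < 0] <- 0
  f2 <- f2 / trapz(grid, f2)
  structure(
    list(grid = grid, f1 = f1, f2 = f2, fhat = fhat, lambda = lambda,
         grid_step = grid_step, bandwidth = bandwidth,
         n_target = length(tx), n_background = length(bx)),
    class = "rsf_mixture"
  )
}

#' @noRd
site_rsf <- function(sites, min_cov) {
  if (is.numeric(sites)) {
    x <- sites
  } else {
    sites <- as.data.frame(sites)
    if (!is.null(sites$z)) sites <- sites[sites$z >= min_cov, , drop = FALSE]
    x <- sites$x
  }
  if (any(x <= 0 | x > 1)) stop("RSF values must lie in (0, 1]")
  x
}

# Boundary-corrected Gaussian smoothing of a density already on the grid.
#' @noRd
smooth_on_grid <- function(d, step, bandwidth) {
  if (bandwidth <= 0) return(d)
  n <- length(d)
  half <- max(1L, ceiling(4 * bandwidth / step))
  off <- (-half):half
  w <- dnorm(off * step, sd = bandwidth)
  num <- numeric(n)
  den <- numeric(n)
  for (k in seq_along(off)) {
    src <- seq_len(n) + off[k]
    ok <- src >= 1L & src <= n
    num[ok] <- num[ok] + w[k] * d[src[ok]]
    den[ok] <- den[ok] + w[k]
  }
  num / den
}

# Histogram density on the grid + boundary-corrected Gaussian smoothing.
# Grid points are the right edges of bins ((g - step, g]). Kernel weights are
# renormalized within (0, 1] so no mass leaks past the boundaries; the result
# integrates to 1 (trapezoidal rule) by construction.
#' @noRd
grid_density <- function(x, grid, step, bandwidth) {
  n <- length(grid)
  bin <- pmin(pmax(ceiling(x / step), 1L), n)
  counts <- tabulate(bin, nbins = n)
  d <- counts / (length(x) * step)
  d <- smooth_on_grid(d, step, bandwidth)
  tot <- trapz(grid, d)
  if (tot <= 0) stop("degenerate density estimate (no mass on grid)")
  d / tot
}

#' @export
print.rsf_mixture <- function(x, ...) {
  cat(sprintf(
    "rsf_mixture: lambda = %.4f (n_target = %d, n_background = %d,\n  grid step %g, bandwidth %g)\n",
    x$lambda, x$n_target, x$n_background, x$grid_step, x$bandwidth))
  invisible(x)
}

# Interpolate a grid density at arbitrary x in (0, 1].
#' @noRd
interp_density <- function(model, f, x) {
  approx(model$grid, f, xout = x, rule = 2)$y
}

#' Posterior source probabilities given an RSF value
#'
#' Mixture responsibilities at an observed RSF \code{x}:
#' \deqn{p(\Theta = 2 | x) = \frac{(1-\lambda) f_2(x)}
#'   {\lambda f_1(x) + (1-\lambda) f_2(x)}.}
#' Densities are evaluated by linear interpolation on the model grid.
#'
#' @param model An \code{\link{fit_rsf_mixture}} fit.
#' @param x RSF value(s) in (0, 1].
#' @return A two-column matrix with columns \code{p1}, \code{p2}
#'   (\code{p1 + p2 = 1}).
#' @export
posterior_rsf <- function(model, x) {
  stopifnot(inherits(model, "rsf_mixture"))
  if (any(x <= 0 | x > 1)) stop("RSF values must lie in (0, 1]")
  n1 <- model$lambda * interp_density(model, model$f1, x)
  n2 <- (1 - model$lambda) * interp_density(model, model$f2, x)
  tot <- n1 + n2
  p2 <- ifelse(tot > 0, n2 / tot, 1 - model$lambda)
  cbind(p1 = 1 - p2, p2 = p2)
}

#' Posterior source probabilities given an observed transition count
#'
#' Marginalizes the substitution probability out of the Bayesian network:
#' \deqn{p(\Theta = \theta | Y = y) \propto
#'   p(\theta) \int_0^1 \mathrm{Bin}(y; z, x) f_\theta(x)\, dx,}
#' with the integral evaluated by the trapezoidal rule on the model grid.
#' Unlike \code{\link{posterior_rsf}}, this integrates information over the
#' entire RSF range and therefore accounts for the counting noise at finite
#' coverage.
#'
#' @param model An \code{\link{fit_rsf_mixture}} fit.
#' @param y Transition count(s), \code{0 <= y <= z}.
#' @param z Coverage value(s), \code{z >= 1}; recycled with \code{y}.
#' @return A two-column matrix with columns \code{p1}, \code{p2}.
#' @export
posterior_counts <- function(model, y, z) {
  stopifnot(inherits(model, "rsf_mixture"))
  nn <- max(length(y), length(z))
  y <- rep_len(y, nn)
  z <- rep_len(z, nn)
  if (any(z < 1) || any(y < 0) || any(y > z)) {
    stop("require 0 <= y <= z and z >= 1")
  }
  g <- model$grid
  ng <- length(g)
  dx <- c(0, diff(g))
  # trapezoid weights: (dx[i] + dx[i+1]) / 2 interiorly
  wt <- (dx + c(dx[-1], 0)) / 2
  w1 <- wt * model$lambda * model$f1
  w2 <- wt * (1 - model$lambda) * model$f2
  p2 <- numeric(nn)
  for (i in seq_len(nn)) {
    lik <- dbinom(y[i], z[i], g)
    n1 <- sum(lik * w1)
    n2 <- sum(lik * w2)
    tot <- n1 + n2
    p2[i] <- if (tot > 0) n2 / tot else 1 - model$lambda
  }
  cbind(p1 = 1 - p2, p2 = p2)
}

#' Log-odds that a transition is crosslink-induced
#'
#' \eqn{\log(p(\Theta=2|Y) / p(\Theta=1|Y))} from
#' \code{\link{posterior_counts}}. Infinite values (a posterior of exactly 0
#' or 1 in floating point) are capped at \code{±cap}.
#'
#' @inheritParams posterior_counts
#' @param cap Magnitude cap replacing infinite log-odds (default 700).
#' @return Numeric vector of log-odds.
#' @export
log_odds_counts <- function(model, y, z, cap = 700) {
  p <- posterior_counts(model, y, z)
  lo <- unname(log(p[, "p2"] / p[, "p1"]))
  lo[lo > cap] <- cap
  lo[lo < -cap] <- -cap
  lo
}

#' RSF support interval induced by a posterior cutoff
#'
#' The smallest interval \code{[a, b]} containing all grid points whose
#' RSF-conditional posterior \eqn{p(\Theta = 2 | x)} reaches the cutoff
#' (considering only grid points carrying positive mixture density, where
#' the posterior is defined). Raising the cutoff shrinks the support.
#'
#' @param model An \code{\link{fit_rsf_mixture}} fit.
#' @param cutoff Posterior probability cutoff \eqn{\delta \in (0.5, 1)}.
#' @return Numeric vector \code{c(a, b)}.
#' @export
rsf_support <- function(model, cutoff = 0.9) {
  stopifnot(inherits(model, "rsf_mixture"), cutoff > 0, cutoff < 1)
  p2 <- posterior_rsf(model, model$grid)[, "p2"]
  dens <- model$lambda * model$f1 + (1 - model$lambda) * model$f2
  hit <- which(p2 >= cutoff & dens > 0)
  if (length(hit) == 0L) {
    stop("cutoff too strict for fitted model: empty RSF support")
  }
  c(model$grid[min(hit)], model$grid[max(hit)])
}

#' Classify high-confidence transitions (hcTs)
#'
#' Sites whose RSF falls inside the posterior-cutoff-derived support and
#' whose coverage meets \code{min_cov} are retained and scored with the
#' count-marginalized posterior and log-odds.
#'
#' @param model An \code{\link{fit_rsf_mixture}} fit.
#' @param sites Sites from \code{\link{extract_sites}}.
#' @param cutoff Posterior cutoff \eqn{\delta} (default 0.9).
#' @param min_cov Minimum coverage at hcTs (default 20; the exhaustive
#'   calling mode of the method uses 1 here after fitting at 20).
#' @param cap Log-odds cap, see \code{\link{log_odds_counts}}.
#' @return The subset of \code{sites} that are high-confidence, with added
#'   columns \code{posterior2} and \code{log_odds}; attributes
#'   \code{"support"} (\code{c(a, b)}) and \code{"cutoff"}.
#' @export
classify_hct <- function(model, sites, cutoff = 0.9, min_cov = 20L,
                         cap = 700) {
  sup <- rsf_support(model, cutoff)
  keep <- sites$z >= min_cov & sites$x >= sup[1] & sites$x <= sup[2]
  hct <- sites[keep, , drop = FALSE]
  if (nrow(hct) > 0) {
    p <- posterior_counts(model, hct$y, hct$z)
    hct$posterior2 <- p[, "p2"]
    lo <- log(p[, "p2"] / p[, "p1"])
    lo[lo > cap] <- cap
    lo[lo < -cap] <- -cap
    hct$log_odds <- lo
  } else {
    hct$posterior2 <- numeric(0)
    hct$log_odds <- numeric(0)
  }
  attr(hct, "support") <- sup
  attr(hct, "cutoff") <- cutoff
  hct
}

#' Serialize a fitted mixture model to JSON
#'
#' @param model An \code{\link{fit_rsf_mixture}} fit.
#' @param path Output file path.
#' @return Invisibly, the path.
#' @export
write_rsf_mixture <- function(model, path) {
  stopifnot(inherits(model, "rsf_mixture"))
  jsonlite::write_json(unclass(model), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a mixture model serialized by \code{\link{write_rsf_mixture}}
#'
#' @param path JSON file path.
#' @return An \code{"rsf_mixture"} object.
#' @export
read_rsf_mixture <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(m, class = "rsf_mixture")
}
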