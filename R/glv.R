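#' Mean-field (Lotka–Volterra) approximation of the stochastic dynamics
#'
#' Population-level deterministic counterpart of the replication-trial
#' rules, for a fixed set of strains (no mutation).  With occupancy
#' fractions \eqn{x_\alpha} and total \eqn{X = \sum x_\alpha}, each of the
#' \eqn{N_s} per-generation trials picks strain \eqn{\alpha}'s individual
#' with probability \eqn{x_\alpha/X}, replicates with probability
#' \eqn{r_\alpha}, and the offspring lands on an empty site (fraction
#' \eqn{1-X}), or on a site held by strain \eqn{\beta} (fraction
#' \eqn{x_\beta}) where it wins with probability \eqn{I_{\alpha\beta}}.
#' Per generation this gives the competitive Lotka–Volterra form
#' \deqn{\dot x_\alpha = \frac{r_\alpha x_\alpha}{X}(1 - X)
#'   + \sum_{\beta\neq\alpha}\left[\frac{r_\alpha x_\alpha}{X} x_\beta
#'     I_{\alpha\beta} - \frac{r_\beta x_\beta}{X} x_\alpha
#'     I_{\beta\alpha}\right] - \frac{x_\alpha}{\lambda},}
#' with the \eqn{1/\lambda} mortality term dropped for \eqn{\lambda=\infty}.
#'
#' The \eqn{x_\alpha/\lambda} term treats the Poisson lifespan as a
#' constant per-capita death rate.  This is exact only while competitive
#' replacement is rare: in the stochastic engine every newborn — including
#' one that takes over an occupied site — draws a fresh lifespan, so at
#' appreciable replication rates the death clocks are continually reset
#' and realised lifespan mortality falls below \eqn{x/\lambda} (see the
#' methods vignette).  For \eqn{\lambda=\infty} the correspondence with
#' the engine is quantitative.
#'
#' @param x occupancy fractions, one per strain.
#' @param I fixed interaction matrix (reciprocal, diagonal 0.5).
#' @param r fixed per-strain replication probabilities.
#' @param lambda mean lifespan (`Inf` to drop the mortality term).
#' @return `meanfield_rhs()`: the vector \eqn{dx/dt} (per generation);
#'   identically zero once the community is empty.
#' @export
meanfield_rhs <- function(x, I, r, lambda = Inf) {
  n <- length(x)
  stopifnot(nrow(I) == n, length(r) == n)
  X <- sum(x)
  if (X <= 0) return(numeric(n))
  g <- r * x / X                       # replication flux per strain
  # gains: my offspring beating beta; losses: beta's offspring beating me
  gain <- g * (I %*% x - diag(I) * x)
  loss <- x * (t(I) %*% g - diag(I) * g)
  dx <- g * (1 - X) + as.numeric(gain - loss)
  if (is.finite(lambda)) dx <- dx - x / lambda
  dx
}

#' Integrate the mean-field equations
#'
#' Fixed-step fourth-order Runge–Kutta integration (via
#' \pkg{deSolve}) of [meanfield_rhs()], with occupancies clipped at zero.
#'
#' @inheritParams meanfield_rhs
#' @param x0 initial occupancy fractions.
#' @param times output times in generations (e.g. `seq(0, 100, 1)`).
#' @param dt integration step (must not exceed 1 generation; the dynamics
#'   are smooth and bounded, so the default 0.1 is ample).
#' @return A data frame: column `time` plus one occupancy column per
#'   strain (`x1`, `x2`, ...).
#' @export
glv_integrate <- function(x0, I, r, lambda = Inf, times = seq(0, 100, 1),
                          dt = 0.1) {
  if (dt > 1) stop("integration step dt must not exceed one generation")
  n <- length(x0)
  rhs <- function(t, y, parms) {
    y[y < 0] <- 0
    list(meanfield_rhs(y, I, r, lambda))
  }
  out <- deSolve::rk4(y = stats::setNames(as.numeric(x0),
                                          paste0("x", seq_len(n))),
                      times = sort(unique(c(times, seq(min(times),
                                                       max(times), by = dt)))),
                      func = rhs, parms = NULL)
  out <- as.data.frame(unclass(out))
  out <- out[out$time %in% times, , drop = FALSE]
  names(out)[1] <- "time"
  rownames(out) <- NULL
  for (j in seq(2, ncol(out))) out[[j]] <- pmax(as.numeric(out[[j]]), 0)
  out
}

#' Monomorphic mean-field fixed point
#'
#' For a single strain the mean field reduces to
#' \eqn{\dot x = r(1-x) - x/\lambda} with fixed point
#' \eqn{x^* = r\lambda/(1 + r\lambda)} (\eqn{x^* = 1} for
#' \eqn{\lambda = \infty}).
#'
#' @param r replication probability.
#' @param lambda mean lifespan.
#' @return The equilibrium occupancy fraction.
#' @export
monomorphic_fixed_point <- function(r, lambda = Inf) {
  if (!is.finite(lambda)) return(if (r > 0) 1 else 0)
  r * lambda / (1 + r * lambda)
}
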