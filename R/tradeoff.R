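#' Trade-off between replication and competitive ability
#'
#' Maps competitive ability \eqn{C \in [0,1]} to replication probability
#' \eqn{r \in [0,1]} through a one-parameter family of curves controlled by
#' the trade-off parameter \eqn{\delta \in [0,1)}:
#' \deqn{r(C;\delta) = (1 - C^p)^{1/p}, \qquad p = (1-\delta)/\delta,}
#' the superellipse \eqn{r^p + C^p = 1}.  The family covers every regime of
#' interest: \eqn{\delta = 0} is the degenerate no-trade-off case
#' (\eqn{r \equiv 1}, a "Darwinian Demon" is allowed); \eqn{0<\delta<0.5}
#' gives concave curves (cheap competitive ability); \eqn{\delta = 0.5} the
#' linear trade-off \eqn{r = 1 - C}; \eqn{\delta > 0.5} convex curves where
#' even modest competitive ability is paid for with a large loss of
#' fecundity.  \eqn{r} is continuous, non-increasing in both `C` and
#' `delta`, with \eqn{r(0)=1} and, for \eqn{\delta>0}, \eqn{r(1)=0}.
#'
#' @param C competitive ability, in \eqn{[0, 1]} (vectorised).
#' @param delta trade-off shape parameter, a single value in \eqn{[0, 1)}.
#' @return Replication probability (same length as `C`).
#' @examples
#' replication_probability(0.3, 0.5)   # linear trade-off: 1 - 0.3
#' replication_probability(0.7, 0)     # no trade-off: always 1
#' @export
replication_probability <- function(C, delta) {
  .check_delta(delta)
  if (any(!is.finite(C)) || any(C < 0) || any(C > 1))
    stop("competitive ability C must lie in [0, 1]")
  if (delta == 0) return(rep(1, length(C)))
  p <- (1 - delta) / delta
  r <- (1 - pmin(C^p, 1))^(1 / p)
  r[C >= 1] <- 0
  r
}

.check_delta <- function(delta) {
  if (length(delta) != 1 || !is.finite(delta) || delta < 0 || delta >= 1)
    stop("trade-off parameter delta must be a single value in [0, 1)")
  invisible(delta)
}

#' Qualitative shape of the trade-off curve
#'
#' @inheritParams replication_probability
#' @return One of `"none"` (\eqn{\delta=0}), `"concave"`
#'   (\eqn{0<\delta<0.5}), `"linear"` (\eqn{\delta=0.5}) or `"convex"`
#'   (\eqn{\delta>0.5}).
#' @export
curve_shape <- function(delta) {
  .check_delta(delta)
  if (delta == 0) "none"
  else if (delta < 0.5) "concave"
  else if (delta == 0.5) "linear"
  else "convex"
}

#' Tabulate a trade-off curve
#'
#' Convenience export for plotting curve families: a two-column data frame
#' of `C` and `r` values.
#'
#' @inheritParams replication_probability
#' @param n number of grid points on \eqn{[0, 1]}.
#' @param path optional file; when given, the table is written as TSV.
#' @return A data frame with columns `C` and `r` (invisibly if written).
#' @export
tradeoff_table <- function(delta, n = 101, path = NULL) {
  C <- seq(0, 1, length.out = n)
  tab <- data.frame(C = C, r = replication_probability(C, delta))
  if (!is.null(path)) {
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}
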