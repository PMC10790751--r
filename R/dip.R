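#' Hartigan dip statistic
#'
#' The dip of a sample is the sup-norm distance between its empirical CDF and
#' the closest unimodal CDF (a continuous, nondecreasing convex-then-concave
#' distribution function). It is the test statistic used to decide whether a
#' species' ANI value distribution departs from unimodality, i.e. whether the
#' intra-species identity values fall into separated bands. For a sample of
#' `n` distinct values the dip lies in `[1/(2n), 0.25]`; larger values mean
#' stronger bimodality (two distinct points attain the maximum 0.25).
#'
#' The statistic is computed exactly by bisection on the distance `d`: at a
#' given `d` the ECDF induces a box corridor at each distinct sample value,
#' and a unimodal CDF within `d` exists iff some mode knot admits a convex
#' nondecreasing fit below the mode and a concave nondecreasing fit above it
#' that agree at the mode. See [dip_brute()] for the independent brute-force
#' reference implementation used to validate this routine.
#'
#' @param values numeric vector, at least 2 distinct finite values.
#' @return the dip statistic (a single number).
#' @seealso [dip_test()], [dip_brute()]
#' @export
#' @examples
#' dip_statistic(c(0, 1))                    # 0.25
#' dip_statistic(seq(0, 1, length.out = 10)) # 1/20
dip_statistic <- function(values) {
  if (!is.numeric(values) || any(!is.finite(values)))
    stop("values must be finite numeric")
  n <- length(values)
  if (n < 2L) stop("need at least 2 values")
  x <- sort(values)
  r <- rle(x)
  ux <- r$values
  if (length(ux) < 2L) stop("need at least 2 distinct values")
  Fp <- cumsum(r$lengths) / n
  Fm <- Fp - r$lengths / n
  .dip_ecdf_cpp(ux, Fp, Fm)
}

#' Monte-Carlo dip test of unimodality
#'
#' Compares the sample dip to its null distribution under uniform(0,1) samples
#' of the same size (the classical calibration of the dip test), with a
#' `+1/(n_boot+1)` continuity correction. A small p-value indicates that the
#' distribution of values -- for example intra-species ANI values -- is not
#' unimodal, i.e. that peaks are separated by at least one gap.
#'
#' @param values numeric sample (at least 4 distinct values).
#' @param n_boot number of uniform null samples (ignored when `null_dips` is
#'   supplied).
#' @param seed optional integer seed for the Monte-Carlo draw.
#' @param null_dips optional precomputed null dips from [dip_null()]; use this
#'   to share one null distribution across many tests of the same sample size.
#' @return an object of class `htest` with the dip statistic and p-value.
#' @export
dip_test <- function(values, n_boot = 2000L, seed = NULL, null_dips = NULL) {
  dn <- deparse(substitute(values))
  n <- length(values)
  if (length(unique(values[is.finite(values)])) < 4L)
    stop("dip test needs at least 4 distinct values")
  D <- dip_statistic(values)
  if (is.null(null_dips)) {
    if (n_boot < 100L) warning("n_boot < 100 gives a very coarse p-value")
    null_dips <- dip_null(n, n_boot = n_boot, seed = seed)
  }
  nb <- length(null_dips)
  p <- (1 + sum(null_dips >= D)) / (nb + 1)
  structure(list(statistic = c(D = D), p.value = p,
                 parameter = c(n = n, n_boot = nb),
                 method = "Hartigan dip test of unimodality (Monte Carlo)",
                 data.name = dn),
            class = "htest")
}

#' Null distribution of the dip statistic
#'
#' Dips of `n_boot` uniform(0,1) samples of size `n`, the reference
#' distribution of [dip_test()].
#'
#' @param n sample size.
#' @param n_boot number of null samples.
#' @param seed optional integer seed.
#' @return numeric vector of `n_boot` dip values.
#' @export
dip_null <- function(n, n_boot = 2000L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(seq_len(n_boot), function(i) dip_statistic(runif(n)), numeric(1))
}

#' Brute-force dip statistic (reference implementation)
#'
#' Exhaustive minimisation over continuous piecewise-linear unimodal CDFs with
#' knots at the sample points: for every candidate mode knot, the minimal
#' sup-norm distance is found by bisection, with corridor feasibility of the
#' convex (below-mode) and concave (above-mode) sides established through
#' greatest-convex-minorant / least-concave-majorant envelopes and the shared
#' mode value located by a nested bisection. This routine is deliberately
#' independent of [dip_statistic()]'s C++ path and is used to validate it; it
#' is practical only for small samples.
#'
#' @param values numeric vector (at most 50 values).
#' @param tol bisection tolerance on the statistic.
#' @return the dip statistic.
#' @export
dip_brute <- function(values, tol = 1e-12) {
  n <- length(values)
  if (n < 2L) stop("need at least 2 values")
  if (n > 50L) stop("dip_brute is a brute-force reference; use dip_statistic for n > 50")
  x <- sort(values)
  r <- rle(x)
  ux <- r$values
  if (length(ux) < 2L) stop("need at least 2 distinct values")
  Fp <- cumsum(r$lengths) / n
  Fm <- Fp - r$lengths / n
  K <- length(ux)

  gcm_vals <- function(x, y) {
    m <- length(x)
    ih <- integer(m); k <- 0L
    for (i in seq_len(m)) {
      while (k >= 2L) {
        a <- ih[k - 1L]; b <- ih[k]
        if ((y[b] - y[a]) * (x[i] - x[b]) >= (y[i] - y[b]) * (x[b] - x[a]))
          k <- k - 1L else break
      }
      k <- k + 1L; ih[k] <- i
    }
    v <- numeric(m)
    v[ih[seq_len(k)]] <- y[ih[seq_len(k)]]
    if (k >= 2L) for (j in seq_len(k - 1L)) {
      a <- ih[j]; b <- ih[j + 1L]
      if (b > a + 1L) {
        idx <- (a + 1L):(b - 1L)
        v[idx] <- y[a] + (y[b] - y[a]) * (x[idx] - x[a]) / (x[b] - x[a])
      }
    }
    v
  }
  convex_feas <- function(x, lo, hi) {
    if (any(lo > hi)) return(FALSE)
    env <- rev(cummin(rev(gcm_vals(x, hi))))
    all(env >= lo)
  }
  concave_feas <- function(x, lo, hi) convex_feas(-rev(x), -rev(hi), -rev(lo))

  feas_mode <- function(d, m) {
    lo <- pmax(0, Fp - d); hi <- pmin(1, Fm + d)
    a <- lo[m]; b <- hi[m]
    if (a > b) return(FALSE)
    cvx_p <- function(v) {
      l <- lo[1:m]; h <- hi[1:m]; l[m] <- v; h[m] <- v
      convex_feas(ux[1:m], l, h)
    }
    ccv_p <- function(v) {
      l <- lo[m:K]; h <- hi[m:K]; l[1] <- v; h[1] <- v
      concave_feas(ux[m:K], l, h)
    }
    for (it in 1:70) {
      v <- (a + b) / 2
      cf <- cvx_p(v); gf <- ccv_p(v)
      if (cf && gf) return(TRUE)
      if (!cf && !gf) return(FALSE)
      if (!cf) a <- v else b <- v
    }
    FALSE
  }

  best <- Inf
  for (m in seq_len(K)) {
    a <- 0; b <- min(best, 0.5)
    if (!feas_mode(b, m)) next
    while (b - a > tol) {
      d <- (a + b) / 2
      if (feas_mode(d, m)) b <- d else a <- d
    }
    best <- min(best, b)
  }
  best
}
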