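# Endpoint detrending and IAAFT surrogate generation.

#' Detrend a series so that its end points coincide
#'
#' Subtracts the straight line through zero at the first sample with slope
#' `(x[N] - x[1]) / (N - 1)`, so that the first and last values of the output
#' both equal `x[1]`. Fourier-based surrogate generation implicitly treats the
#' series as one period of a periodic signal; an amplitude mismatch between
#' the end points then leaks spectral power (a periodicity artifact). Equal
#' end points remove the artifact while, unlike trimming, keeping every
#' sample. Within any m-sample window the perturbation is of order
#' `m * sd(x) / N`, negligible for `m << N`.
#'
#' @param x Numeric series, length `>= 2`.
#' @return Numeric series of the same length with equal end values.
#' @examples
#' detrend_endpoints(c(0, 1, 4))
#' @export
detrend_endpoints <- function(x) {
  x <- check_series(x)
  n <- length(x)
  y <- x - (x[n] - x[1]) / (n - 1) * (seq_len(n) - 1)
  y[n] <- y[1]   # exact, not merely up to rounding
  y
}

iaaft_core <- function(x, plan, max_iter, tol = 1e-6) {
  n <- length(x)
  sx <- sort(x)
  amp <- Mod(dft_forward(plan, x))
  y <- sample(x)                              # step 0: random shuffle
  r_prev1 <- NULL
  r_prev2 <- NULL
  for (i in seq_len(max_iter)) {
    # step 1-2: original spectral amplitudes, phases of the current iterate
    yk <- dft_forward(plan, y)
    mod <- Mod(yk)
    phase <- yk / mod
    phase[mod == 0] <- 1 + 0i
    z <- Re(dft_inverse(plan, amp * phase))
    # step 3: rank-remap onto the original amplitude multiset
    r <- rank(z, ties.method = "first")
    y_new <- sx[r]
    delta <- sum((y_new - y)^2)
    y <- y_new
    if (delta < tol * sum(y^2)) {
      return(list(values = y, iterations = i, converged = TRUE))
    }
    # IAAFT can fall into a 2-cycle; a repeated rank ordering means no
    # further progress is possible, so stop there as well
    if (identical(r, r_prev1) || identical(r, r_prev2)) {
      return(list(values = y, iterations = i, converged = TRUE))
    }
    r_prev2 <- r_prev1
    r_prev1 <- r
  }
  list(values = y, iterations = max_iter, converged = FALSE)
}

#' Generate one IAAFT surrogate
#'
#' Iterative amplitude-adjusted Fourier transform surrogate of a series:
#' starting from a random shuffle, each iteration (i) replaces the spectral
#' amplitudes of the current iterate by those of the original while keeping
#' the iterate's phases, and (ii) rank-remaps the result onto the original's
#' sorted values. The surrogate therefore has *exactly* the original's
#' amplitude multiset and approximately its power spectrum (relative spectral
#' discrepancy of order \eqn{N^{-3/2}}), hence approximately its
#' autocorrelation. Iteration stops when the squared distance between
#' consecutive iterates falls below `tol` times the squared norm, when the
#' rank ordering repeats (a fixed point or 2-cycle), or at `max_iter`.
#'
#' The input should already be detrended with [detrend_endpoints()]; the
#' pipeline functions ([make_ensemble()], [estimate_pe_with_uncertainty()])
#' enforce this.
#'
#' @param x Numeric series (detrended), length `>= 2`.
#' @param seed Optional integer seed for the shuffle and iteration.
#' @param max_iter Iteration cap (default 1000). On hitting the cap the
#'   surrogate is returned with `converged = FALSE` and a warning, not an
#'   error.
#' @param tol Relative squared-distance convergence threshold (default 1e-6).
#' @return Numeric vector (the surrogate) with attributes `iterations` and
#'   `converged`.
#' @export
iaaft <- function(x, seed = NULL, max_iter = 1000L, tol = 1e-6) {
  x <- check_series(x)
  seed <- check_seed(seed)
  if (!is.null(seed)) set.seed(seed)
  # degenerate constant (incl. all-zero) input: any shuffle is the series
  # itself and the spectral step cannot change it
  if (all(x == x[1])) {
    return(structure(x, iterations = 0L, converged = TRUE))
  }
  res <- iaaft_core(x, dft_plan(length(x)), max_iter = max_iter, tol = tol)
  if (!res$converged) {
    warning(sprintf("IAAFT did not converge within max_iter = %d iterations",
                    max_iter), call. = FALSE)
  }
  structure(res$values, iterations = res$iterations, converged = res$converged)
}

#' Generate an ensemble of IAAFT surrogates
#'
#' Detrends the input with [detrend_endpoints()], generates `l` IAAFT
#' surrogates (member `i` runs on its own seed `seed + i - 1`, so the
#' ensemble is reproducible given `(x, l, seed)` and members are mutually
#' independent), and detrends each surrogate again so every member has equal
#' end points.
#'
#' @param x Numeric series.
#' @param l Ensemble size, `>= 2` (default 100).
#' @param seed Optional integer master seed.
#' @param max_iter,tol Passed to the IAAFT iteration.
#' @return An object of class `"surrogate_ensemble"`: list with `original`
#'   (the detrended input), `surrogates` (an `N x l` matrix, one surrogate
#'   per column, detrended), `iterations` and `converged` (per member), and
#'   `seed`.
#' @export
make_ensemble <- function(x, l = 100L, seed = NULL, max_iter = 1000L,
                          tol = 1e-6) {
  x <- check_series(x)
  if (length(l) != 1L || !is.numeric(l) || is.na(l) || l != round(l) || l < 2) {
    stop("ensemble size `l` must be a single integer >= 2", call. = FALSE)
  }
  l <- as.integer(l)
  seed <- check_seed(seed)
  x0 <- detrend_endpoints(x)
  plan <- dft_plan(length(x0))
  constant <- all(x0 == x0[1])
  surr <- matrix(0, nrow = length(x0), ncol = l)
  iterations <- integer(l)
  converged <- logical(l)
  for (i in seq_len(l)) {
    if (!is.null(seed)) set.seed(child_seed(seed, i))
    if (constant) {
      res <- list(values = x0, iterations = 0L, converged = TRUE)
    } else {
      res <- iaaft_core(x0, plan, max_iter = max_iter, tol = tol)
    }
    surr[, i] <- detrend_endpoints(res$values)
    iterations[i] <- res$iterations
    converged[i] <- res$converged
  }
  if (!all(converged)) {
    warning(sprintf("%d of %d surrogates did not converge within max_iter = %d",
                    sum(!converged), l, max_iter), call. = FALSE)
  }
  structure(list(original = x0, surrogates = surr, iterations = iterations,
                 converged = converged, seed = seed),
            class = "surrogate_ensemble")
}

#' @export
print.surrogate_ensemble <- function(x, ...) {
  cat(sprintf("IAAFT surrogate ensemble: %d surrogates of a length-%d series\n",
              ncol(x$surrogates), nrow(x$surrogates)))
  cat(sprintf("  iterations: median %d, range [%d, %d]; %d converged\n",
              as.integer(stats::median(x$iterations)), min(x$iterations),
              max(x$iterations), sum(x$converged)))
  if (!is.null(x$seed)) cat(sprintf("  master seed: %d\n", x$seed))
  invisible(x)
}
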