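# Benchmark generators (noisy Lorenz, ARFIMA) and the reference-vs-surrogate
# validation experiment.

# Long-run std of the x coordinate of the noiseless Lorenz attractor at
# (a, b, c) = (10, 8/3, 28) sampled every 0.3 time units. Pinned so that the
# observational-noise amplitude eta keeps its exact meaning (power
# signal-to-noise ratio = eta^-2) run to run instead of being re-estimated.
lorenz_sigma_x <- 7.9252822

#' Simulate the Lorenz attractor with observational noise
#'
#' Integrates \deqn{\dot x = a(y - x),\quad \dot y = x(c - z) - y,\quad
#' \dot z = xy - bz} with a Dormand-Prince 7(8) adaptive integrator
#' (via \pkg{deSolve}; `dt` is the *sampling* interval, the integrator
#' subdivides each interval internally to tolerance `tol`), from an initial
#' state drawn uniformly from \eqn{[-10, 10]^3}. The first `burn_in` samples
#' are discarded to remove the transient, and zero-mean Gaussian noise of
#' standard deviation `eta * 7.9252822` (the pinned long-run std of the
#' noiseless x coordinate) is added to the returned x coordinate; `eta = 0`
#' gives the noiseless series.
#'
#' @param n Number of returned samples (default 10006).
#' @param eta Observational-noise amplitude, `>= 0` (default 0); the power
#'   signal-to-noise ratio of the output is `eta^-2`.
#' @param seed Optional integer seed (initial state and noise).
#' @param a,b,c Lorenz parameters (defaults 10, 8/3, 28).
#' @param dt Sampling interval in time units (default 0.3).
#' @param burn_in Leading samples discarded (default 1000).
#' @param tol Integrator relative and absolute tolerance (default 1e-10).
#' @param init Optional length-3 initial state overriding the random draw.
#' @return Numeric vector of length `n` (the noisy x coordinate).
#' @examples
#' x <- simulate_lorenz(n = 2000, eta = 0.1, seed = 1)
#' @export
simulate_lorenz <- function(n = 10006L, eta = 0, seed = NULL, a = 10,
                            b = 8 / 3, c = 28, dt = 0.3, burn_in = 1000L,
                            tol = 1e-10, init = NULL) {
  if (length(n) != 1L || n < 2 || n != round(n)) {
    stop("`n` must be a single integer >= 2", call. = FALSE)
  }
  if (length(eta) != 1L || !is.numeric(eta) || is.na(eta) || eta < 0) {
    stop("noise amplitude `eta` must be a single number >= 0", call. = FALSE)
  }
  seed <- check_seed(seed)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(init)) init <- runif(3, -10, 10)
  stopifnot(length(init) == 3, all(is.finite(init)))
  times <- seq(0, by = dt, length.out = burn_in + n)
  out <- deSolve::ode(y = as.numeric(init), times = times,
                      func = "lorenz_derivs", parms = c(a, b, c),
                      dllname = "pevar", initfunc = "lorenz_init",
                      method = deSolve::rkMethod("rk78dp"),
                      rtol = tol, atol = tol)
  x <- out[, 2L]
  if (anyNA(x) || any(!is.finite(x)) || length(x) < burn_in + n) {
    stop("Lorenz integration failed (non-finite state)", call. = FALSE)
  }
  x <- x[(burn_in + 1):(burn_in + n)]
  if (eta > 0) x <- x + lorenz_sigma_x * eta * rnorm(n)
  unname(x)
}

#' ARFIMA autoregressive coefficients
#'
#' The truncated fractional-integration weights
#' \deqn{c_k = \rho\,\frac{\Gamma(k - \rho)}{\Gamma(1 - \rho)\,\Gamma(k + 1)},
#'   \qquad k = 1, \dots, k_{max},}
#' computed through `lgamma` to avoid overflow. `rho = 0` gives all-zero
#' coefficients (white noise); `c_1 = rho` for any `rho`.
#'
#' @param rho Memory parameter in `[0, 1)`. Negative values (anti-correlated
#'   processes) are rejected.
#' @param kmax Truncation order (default 100).
#' @return Numeric vector of length `kmax`.
#' @examples
#' arfima_coefficients(0.5, 5)
#' @export
arfima_coefficients <- function(rho, kmax = 100L) {
  if (length(rho) != 1L || !is.numeric(rho) || is.na(rho) || rho < 0 ||
      rho >= 1) {
    stop("`rho` must be a single number in [0, 1)", call. = FALSE)
  }
  if (kmax < 1 || kmax != round(kmax)) {
    stop("`kmax` must be a positive integer", call. = FALSE)
  }
  if (rho == 0) return(numeric(kmax))
  k <- seq_len(kmax)
  rho * exp(lgamma(k - rho) - lgamma(1 - rho) - lgamma(k + 1))
}

#' Simulate an ARFIMA process
#'
#' The truncated long-memory recursion
#' \eqn{x_n = \sum_{k=1}^{k_{max}} c_k x_{n-k} + \epsilon_n} with
#' standard-normal innovations and weights from [arfima_coefficients()].
#' History before the first sample is zero; the first `burn_in` samples are
#' discarded to absorb the initialization. `rho = 0` yields i.i.d. standard
#' normal output; `rho` tunes the autocorrelation time up to long memory as
#' `rho` approaches 1.
#'
#' @param n Number of returned samples (default 10006, so that at `m = 7`
#'   there are exactly 10000 windows).
#' @param rho Memory parameter in `[0, 1)`.
#' @param kmax Truncation order (default 100).
#' @param burn_in Leading samples discarded (default 1000).
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n`.
#' @examples
#' x <- simulate_arfima(n = 1000, rho = 0.5, seed = 1)
#' @export
simulate_arfima <- function(n = 10006L, rho = 0, kmax = 100L,
                            burn_in = 1000L, seed = NULL) {
  if (length(n) != 1L || n < 2 || n != round(n)) {
    stop("`n` must be a single integer >= 2", call. = FALSE)
  }
  seed <- check_seed(seed)
  if (!is.null(seed)) set.seed(seed)
  eps <- rnorm(n + burn_in)
  if (rho == 0) {
    x <- eps
  } else {
    co <- arfima_coefficients(rho, kmax)
    x <- as.numeric(stats::filter(eps, co, method = "recursive"))
  }
  x[(burn_in + 1):(burn_in + n)]
}

simulator_for <- function(system, ...) {
  system <- match.arg(system, c("arfima", "lorenz"))
  args <- list(...)
  function(seed) {
    do.call(switch(system, arfima = simulate_arfima, lorenz = simulate_lorenz),
            c(list(seed = seed), args))
  }
}

#' Reference PE spread across independent realizations
#'
#' The ground-truth PE variability of a synthetic source: generates `l`
#' independent realizations (realization `i` on seed `seed + i - 1`, or on
#' explicitly supplied distinct `seeds`), detrends each with
#' [detrend_endpoints()], computes the PE, and returns the sample mean and
#' the `L - 1`-denominator sample standard deviation. Only available for
#' synthetic systems, where equivalent replicas can be produced at will;
#' surrogate-based estimates ([estimate_pe_with_uncertainty()]) are judged
#' against this spread.
#'
#' @param system `"arfima"` or `"lorenz"`.
#' @param m Pattern dimension.
#' @param l Number of realizations (default 100).
#' @param seed Integer master seed (required unless `seeds` is given).
#' @param seeds Optional explicit vector of `l` *distinct* seeds; identical
#'   seeds would yield identical realizations (zero spread) and are rejected.
#' @param ... Passed to the simulator ([simulate_arfima()] or
#'   [simulate_lorenz()]): e.g. `rho`, `eta`, `n`.
#' @return List with `mean`, `sd`, `pe` (the `l` PE values, nats), and
#'   `seeds`.
#' @export
reference_pe_std <- function(system = c("arfima", "lorenz"), m, l = 100L,
                             seed = NULL, seeds = NULL, ...) {
  system <- match.arg(system)
  m <- check_dimension(m)
  if (l < 2 || l != round(l)) {
    stop("`l` must be an integer >= 2", call. = FALSE)
  }
  if (is.null(seeds)) {
    seed <- check_seed(seed, allow_null = FALSE)
    seeds <- vapply(seq_len(l), function(i) child_seed(seed, i), integer(1))
  }
  if (length(seeds) != l) {
    stop("`seeds` must have length `l`", call. = FALSE)
  }
  if (anyDuplicated(seeds)) {
    stop("realization seeds must be distinct: identical seeds reproduce the ",
         "same realization and the spread degenerates to zero", call. = FALSE)
  }
  sim <- simulator_for(system, ...)
  pe <- vapply(seeds, function(s) {
    x <- detrend_endpoints(sim(s))
    permutation_entropy(ordinal_distribution(x, m))$h
  }, numeric(1))
  list(mean = mean(pe), sd = sd(pe), pe = pe, seeds = seeds)
}

#' Surrogate-vs-reference PE spread ratio
#'
#' The validation experiment behind the \eqn{\Sigma = \alpha s} rule: for a
#' synthetic system it computes (i) the reference PE std across `l`
#' independent realizations ([reference_pe_std()]; realization 0 runs on
#' `seed`) and (ii) the PE std across `l` IAAFT surrogates of realization 0
#' ([make_ensemble()] on seed `seed + l`, so surrogate streams never collide
#' with realization streams), and reports their ratio
#' `s_surrogate / s_reference`. At moderate noise/correlation the ratio
#' falls in `[0.5, 1]`, motivating the default `alpha = 2`.
#'
#' @inheritParams reference_pe_std
#' @param max_iter IAAFT iteration cap.
#' @return An object of class `"ratio_result"`: list with `system`, `params`
#'   (the simulator arguments), `m`, `l`, `seed`, `mean_reference`,
#'   `mean_surrogate`, `s_reference`, `s_surrogate`, `ratio`.
#' @examples
#' \donttest{
#' ratio_experiment("arfima", m = 4, l = 20, seed = 1, rho = 0.5, n = 2048)
#' }
#' @export
ratio_experiment <- function(system = c("arfima", "lorenz"), m, l = 100L,
                             seed = NULL, max_iter = 1000L, ...) {
  system <- match.arg(system)
  m <- check_dimension(m)
  seed <- check_seed(seed, allow_null = FALSE)
  ref <- reference_pe_std(system, m = m, l = l, seed = seed, ...)
  if (ref$sd == 0) {
    stop("degenerate reference: zero PE spread across realizations",
         call. = FALSE)
  }
  x0 <- detrend_endpoints(simulator_for(system, ...)(seed))
  ensemble <- make_ensemble(x0, l = l, seed = child_seed(seed, l + 1),
                            max_iter = max_iter)
  sp <- surrogate_pe_std(ensemble, m)
  structure(
    list(system = system, params = list(...), m = m, l = as.integer(l),
         seed = seed,
         mean_reference = ref$mean, mean_surrogate = sp$mean,
         s_reference = ref$sd, s_surrogate = sp$sd,
         ratio = sp$sd / ref$sd),
    class = "ratio_result")
}

#' @export
print.ratio_result <- function(x, ...) {
  ptxt <- if (length(x$params)) {
    paste(names(x$params), unlist(x$params), sep = " = ", collapse = ", ")
  } else "defaults"
  cat(sprintf("Surrogate-vs-reference PE spread ratio (%s, %s; m = %d, L = %d)\n",
              x$system, ptxt, x$m, x$l))
  cat(sprintf("  reference : mean %.6f, s_X = %.3e\n", x$mean_reference,
              x$s_reference))
  cat(sprintf("  surrogate : mean %.6f, s_Y = %.3e\n", x$mean_surrogate,
              x$s_surrogate))
  cat(sprintf("  ratio s_Y / s_X = %.4f\n", x$ratio))
  invisible(x)
}

#' Sweep the ratio experiment over a noise/correlation grid
#'
#' Runs [ratio_experiment()] over a grid of the system's tuning parameter
#' (noise amplitude `eta` for the Lorenz system, `1 - rho` for ARFIMA, as in
#' the benchmark figures) and pattern dimensions, collecting one row per
#' cell. Cell `i` runs on master seed `seed + (i - 1) * seed_stride`, so
#' cells use disjoint seed ranges as long as `seed_stride > 2 l`.
#'
#' @param system `"arfima"` or `"lorenz"`.
#' @param values Grid of the tuning parameter (`eta`, or `1 - rho`).
#' @param m Vector of pattern dimensions.
#' @param l Ensemble/realization count per cell (default 100).
#' @param seed Integer master seed.
#' @param seed_stride Seed spacing between cells (default 1000).
#' @param ... Further simulator arguments (e.g. `n`, `kmax`).
#' @return A data.frame with columns `system`, `parameter`, `m`, `mean_X`,
#'   `mean_Y`, `s_X`, `s_Y`, `ratio`.
#' @export
ratio_sweep <- function(system = c("arfima", "lorenz"), values, m, l = 100L,
                        seed = NULL, seed_stride = 1000L, ...) {
  system <- match.arg(system)
  seed <- check_seed(seed, allow_null = FALSE)
  grid <- expand.grid(parameter = values, m = m)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    v <- grid$parameter[i]
    args <- c(list(system = system, m = grid$m[i], l = l,
                   seed = child_seed(seed, (i - 1) * seed_stride + 1)),
              if (system == "arfima") list(rho = 1 - v) else list(eta = v),
              list(...))
    r <- do.call(ratio_experiment, args)
    data.frame(system = system, parameter = v, m = grid$m[i],
               mean_X = r$mean_reference, mean_Y = r$mean_surrogate,
               s_X = r$s_reference, s_Y = r$s_surrogate, ratio = r$ratio)
  })
  do.call(rbind, rows)
}

#' Read a sweep configuration file
#'
#' Parses a YAML key-value file describing a ratio sweep, with keys `system`
#' (`arfima` or `lorenz`), `values` (the tuning-parameter grid: `eta` or
#' `1 - rho`), `m` (one or more dimensions), and optionally `l` (default
#' 100) and `seed`.
#'
#' @param path Path to the YAML file.
#' @return A named list suitable for `do.call(ratio_sweep, ...)`.
#' @export
read_sweep_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stop("the `yaml` package is required to read sweep configurations",
         call. = FALSE)
  }
  cfg <- yaml::read_yaml(path)
  need <- c("system", "values", "m")
  miss <- setdiff(need, names(cfg))
  if (length(miss)) {
    stop("sweep config is missing keys: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  keep <- intersect(names(cfg),
                    c("system", "values", "m", "l", "seed", "seed_stride", "n",
                      "kmax"))
  cfg[keep]
}
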