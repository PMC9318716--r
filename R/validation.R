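# Significance tools for PE values carrying uncertainties: two-sided z
# comparison, weighted polynomial drift fit, chi-square(3) reference density.

#' Two-sided z comparison of two PE values
#'
#' Tests the null hypothesis that two PE values, each carrying an
#' uncertainty, differ only by chance:
#' \eqn{z = (h_2 - h_1) / \sqrt{\sigma_1^2 + \sigma_2^2}} with a two-sided
#' normal tail probability. Scale-agnostic: values and uncertainties may be
#' in nats or normalized by `log(m!)`, as long as they match.
#'
#' @param h1,h2 The two PE values.
#' @param sigma1,sigma2 Their (positive) uncertainties.
#' @return An object of class `"htest"` with `statistic` (z) and `p.value`.
#' @examples
#' z_test_pe(0.487, 0.006, 0.507, 0.007)
#' @export
z_test_pe <- function(h1, sigma1, h2, sigma2) {
  vals <- c(h1, sigma1, h2, sigma2)
  if (any(lengths(list(h1, sigma1, h2, sigma2)) != 1L) || anyNA(vals) ||
      !is.numeric(vals)) {
    stop("all four arguments must be single finite numbers", call. = FALSE)
  }
  if (sigma1 <= 0 || sigma2 <= 0) {
    stop("uncertainties must be positive", call. = FALSE)
  }
  z <- (h2 - h1) / sqrt(sigma1^2 + sigma2^2)
  p <- 2 * pnorm(-abs(z))
  structure(
    list(statistic = c(z = z), p.value = p,
         estimate = c(`difference h2 - h1` = h2 - h1),
         method = "Two-sided z test for a difference of permutation entropies",
         data.name = sprintf("h1 = %g +/- %g, h2 = %g +/- %g",
                             h1, sigma1, h2, sigma2)),
    class = "htest")
}

#' Weighted polynomial drift fit of a PE sequence
#'
#' Least-squares fit of a slow drift law \eqn{a + bk + ck^2} (or `a + bk`
#' with `degree = 1`) to a sequence of PE values with uncertainties,
#' minimizing the normalized residual sum
#' \deqn{S(a, b, c) = \sum_k \frac{[h_k - (a + bk + ck^2)]^2}{\sigma_k^2}.}
#' The model is linear in the coefficients, so the minimum is found in
#' closed form via the weighted normal equations (QR-solved). If the
#' uncertainties correctly describe the scatter and the drift law holds,
#' \eqn{S(\hat a, \hat b, \hat c)} is chi-square distributed with
#' \eqn{\nu = n_{points} - n_{coef}} degrees of freedom (\eqn{\nu = 3} for 6
#' points and a quadratic), which the returned tail probability refers to —
#' small `p_tail` flags either a failing drift law or underestimated
#' uncertainties.
#'
#' @param h PE values (at least `degree + 2` points; the canonical use is 6
#'   consecutive segments).
#' @param sigma Positive uncertainties, same length.
#' @param k Abscissae (default `1, 2, ...`).
#' @param degree Drift polynomial degree, 1 or 2 (default 2).
#' @return An object of class `"drift_fit"`: list with `coefficients`
#'   (`a_hat`, `b_hat`, and for `degree = 2` `c_hat`), `fitted`, `s_min`,
#'   `nu`, `p_tail`, plus the inputs.
#' @examples
#' k <- 1:6
#' h <- 0.5 + 0.01 * k - 0.001 * k^2 + rnorm(6, sd = 0.006)
#' quadratic_drift_fit(h, rep(0.006, 6))
#' @export
quadratic_drift_fit <- function(h, sigma, k = seq_along(h), degree = 2L) {
  if (!degree %in% c(1L, 2L)) stop("`degree` must be 1 or 2", call. = FALSE)
  degree <- as.integer(degree)
  n <- length(h)
  if (length(sigma) != n || length(k) != n) {
    stop("`h`, `sigma` and `k` must have equal lengths", call. = FALSE)
  }
  if (n < degree + 2) {
    stop(sprintf("need at least %d points for degree %d", degree + 2, degree),
         call. = FALSE)
  }
  if (any(!is.finite(h)) || any(!is.finite(sigma)) || any(!is.finite(k))) {
    stop("inputs must be finite", call. = FALSE)
  }
  if (any(sigma <= 0)) stop("all uncertainties must be positive", call. = FALSE)
  X <- outer(k, 0:degree, `^`)
  sw <- 1 / sigma
  beta <- qr.coef(qr(X * sw), h * sw)
  fitted <- drop(X %*% beta)
  s_min <- sum(((h - fitted) / sigma)^2)
  nu <- n - (degree + 1L)
  names(beta) <- c("a_hat", "b_hat", "c_hat")[seq_len(degree + 1)]
  structure(
    list(coefficients = beta, fitted = fitted, s_min = s_min, nu = nu,
         p_tail = pchisq(s_min, df = nu, lower.tail = FALSE),
         degree = degree, k = k, h = h, sigma = sigma),
    class = "drift_fit")
}

#' @export
print.drift_fit <- function(x, ...) {
  lab <- if (x$degree == 2) "quadratic" else "linear"
  cat(sprintf("Weighted %s drift fit of %d PE values\n", lab, length(x$h)))
  cat("  coefficients:",
      paste(sprintf("%s = %.6g", names(x$coefficients), x$coefficients),
            collapse = ", "), "\n")
  cat(sprintf("  S_min = %.4f on nu = %d d.o.f., tail p = %.4f\n",
              x$s_min, x$nu, x$p_tail))
  invisible(x)
}

#' Chi-square density with 3 degrees of freedom
#'
#' The reference density for the minimized normalized residual sum of the
#' 6-point quadratic drift fit:
#' \eqn{f_{\chi^2_3}(x) = \sqrt{x / (2\pi)}\, e^{-x/2}}.
#'
#' @param x Non-negative numeric vector.
#' @return Density values.
#' @examples
#' chi2_3_pdf(1)
#' @export
chi2_3_pdf <- function(x) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0)) {
    stop("`x` must be non-negative", call. = FALSE)
  }
  sqrt(x / (2 * pi)) * exp(-x / 2)
}
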