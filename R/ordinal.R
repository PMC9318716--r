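# Ordinal-pattern encoding and permutation entropy.

#' Encode a window as an ordinal pattern
#'
#' Maps a window of `m` consecutive samples to its ordinal pattern: position
#' `j` of the result holds the rank (1 = smallest) of the `j`-th sample within
#' the window. Ties are broken by temporal index, i.e. of two equal values the
#' earlier one receives the smaller rank. Note that this is the rank vector,
#' not its inverse (the argsort): `encode_window(c(4, 7, 2))` is `c(2, 3, 1)`,
#' meaning the first sample is the 2nd smallest, and so on. Confusing the two
#' conventions is a classic off-by-inverse bug in permutation-entropy code.
#'
#' @param window Numeric vector of length `m >= 2`, all values finite.
#' @return Integer vector of length `m`, a permutation of `1:m`.
#' @examples
#' encode_window(c(1, 2, 3))
#' encode_window(c(4, 7, 2))
#' encode_window(c(5, 5, 3))  # tie: earlier 5 gets the smaller rank
#' @export
encode_window <- function(window) {
  window <- check_series(window, min_len = 2L, arg = "window")
  m <- check_dimension(length(window))
  as.integer(rank(window, ties.method = "first"))
}

# Pattern codes for all overlapping windows, vectorized across windows.
# A pattern (r_1, ..., r_m) maps to sum_j (r_j - 1) * m^(j-1); exact in
# doubles for m <= 10. Ranks are built from m^2 pairwise column comparisons
# so that the tie rule (earlier index -> smaller rank) is explicit.
ordinal_codes <- function(x, m) {
  n <- length(x)
  w <- n - m + 1L
  cols <- lapply(seq_len(m), function(j) x[j:(j + w - 1L)])
  code <- numeric(w)
  base <- 1
  for (j in seq_len(m)) {
    r <- rep(0L, w)
    for (i in seq_len(m)) {
      if (i == j) next
      r <- r + (cols[[i]] < cols[[j]]) + (cols[[i]] == cols[[j]] & i < j)
    }
    code <- code + r * base
    base <- base * m
  }
  code
}

decode_pattern <- function(code, m) {
  r <- integer(m)
  for (j in seq_len(m)) {
    r[j] <- as.integer(code %% m) + 1L
    code <- code %/% m
  }
  r
}

new_ordinal_distribution <- function(patterns, counts, m) {
  d <- structure(
    list(m = as.integer(m),
         window_count = as.integer(sum(counts)),
         patterns = patterns,
         counts = as.integer(counts),
         frequencies = as.numeric(counts) / sum(counts)),
    class = "ordinal_distribution")
  validate_ordinal_distribution(d)
  d
}

validate_ordinal_distribution <- function(d) {
  stopifnot(is.matrix(d$patterns), ncol(d$patterns) == d$m)
  if (nrow(d$patterns) < 1 || nrow(d$patterns) > factorial(d$m)) {
    stop("number of visited patterns must lie in [1, m!]", call. = FALSE)
  }
  if (!all(apply(d$patterns, 1L, function(r) identical(sort(as.integer(r)),
                                                       seq_len(d$m))))) {
    stop("every pattern row must be a permutation of 1:m", call. = FALSE)
  }
  if (any(d$counts < 0) || sum(d$counts) != d$window_count) {
    stop("counts must be non-negative and sum to the window count",
         call. = FALSE)
  }
  if (abs(sum(d$frequencies) - 1) > 1e-12) {
    stop("frequencies must sum to 1", call. = FALSE)
  }
  invisible(d)
}

#' Ordinal-pattern distribution of a time series
#'
#' Slides a window of length `m` over the series (stride 1, `N - m + 1`
#' overlapping windows), encodes each window with [encode_window()]'s rank
#' convention, and tabulates the visited patterns.
#'
#' @param x Numeric time series of length `N >= m`.
#' @param m Pattern dimension (integer, `2 <= m <= 10`).
#' @return An object of class `"ordinal_distribution"`: a list with `m`,
#'   `window_count` (`N - m + 1`), `patterns` (one rank vector per row, only
#'   visited patterns), `counts` and `frequencies` (parallel to the rows).
#' @examples
#' ordinal_distribution(c(1, 3, 2, 4), m = 2)
#' @export
ordinal_distribution <- function(x, m) {
  m <- check_dimension(m)
  x <- check_series(x, min_len = m, arg = "x")
  code <- ordinal_codes(x, m)
  tab <- table(code)
  codes <- as.numeric(names(tab))
  patterns <- t(vapply(codes, decode_pattern, integer(m), m = m))
  new_ordinal_distribution(patterns, as.integer(tab), m)
}

#' @export
print.ordinal_distribution <- function(x, ...) {
  cat(sprintf("Ordinal distribution: m = %d, %d windows, %d of %d patterns visited\n",
              x$m, x$window_count, nrow(x$patterns), factorial(x$m)))
  k <- min(nrow(x$patterns), 6L)
  for (i in seq_len(k)) {
    cat(sprintf("  (%s)  count %d  freq %.5f\n",
                paste(x$patterns[i, ], collapse = ","),
                x$counts[i], x$frequencies[i]))
  }
  if (nrow(x$patterns) > k) cat(sprintf("  ... %d more\n", nrow(x$patterns) - k))
  invisible(x)
}

#' Permutation entropy with Miller-Madow correction
#'
#' The PE of an ordinal distribution, in nats:
#' \deqn{\hat H_m = -\sum_S \hat p_S \log \hat p_S +
#'       \frac{\hat M - 1}{2(N - m + 1)},}
#' where the sum runs over the visited patterns only, and the additive
#' Miller-Madow term (with \eqn{\hat M} the number of visited patterns)
#' compensates the negative bias of the plug-in estimator. The normalized
#' value divides by \eqn{\log(m!)}, the white-noise maximum.
#'
#' @param d An `"ordinal_distribution"`.
#' @return An object of class `"pe_estimate"`: list with `h` (nats),
#'   `h_normalized`, `m`, `n` (original series length), `plug_in`,
#'   `mm_correction`, and an uncertainty slot `sigma` (with `sigma_label`
#'   naming the estimator that produced it) which is `NA` until attached.
#' @seealso [estimate_pe_with_uncertainty()] for the surrogate-based
#'   uncertainty, [sigma_memoryless()] and [sigma_harris()] for baselines.
#' @examples
#' permutation_entropy(ordinal_distribution(c(1, 3, 2, 4), m = 2))
#' @export
permutation_entropy <- function(d) {
  stopifnot(inherits(d, "ordinal_distribution"))
  f <- d$frequencies
  plug_in <- -sum(f * log(f))
  mm <- (nrow(d$patterns) - 1) / (2 * d$window_count)
  h <- plug_in + mm
  structure(
    list(h = h,
         h_normalized = h / log(factorial(d$m)),
         m = d$m,
         n = d$window_count + d$m - 1L,
         plug_in = plug_in,
         mm_correction = mm,
         sigma = NA_real_,
         sigma_label = NA_character_),
    class = "pe_estimate")
}

#' @export
print.pe_estimate <- function(x, ...) {
  cat(sprintf("Permutation entropy (m = %d, N = %d)\n", x$m, x$n))
  cat(sprintf("  h            = %.6f nats (plug-in %.6f + Miller-Madow %.6f)\n",
              x$h, x$plug_in, x$mm_correction))
  cat(sprintf("  h / log(m!)  = %.6f\n", x$h_normalized))
  if (!is.na(x$sigma)) {
    cat(sprintf("  sigma        = %.6f nats (%s)\n", x$sigma, x$sigma_label))
  }
  invisible(x)
}

#' Entropy variance coefficient of a distribution
#'
#' The plug-in estimate of the leading-order variance coefficient of the
#' sample Shannon entropy of a multinomial: the population variance of
#' \eqn{-\log p} under the observed frequencies,
#' \eqn{\hat\Lambda_0 = \sum_S \hat p_S \log^2 \hat p_S -
#'      (\sum_S \hat p_S \log \hat p_S)^2 \ge 0}.
#' Zero for any uniform distribution (where \eqn{-\log p} is constant).
#'
#' @inheritParams permutation_entropy
#' @return A single non-negative number.
#' @export
lambda0 <- function(d) {
  stopifnot(inherits(d, "ordinal_distribution"))
  f <- d$frequencies
  lf <- log(f)
  max(0, sum(f * lf^2) - sum(f * lf)^2)
}

#' Memoryless (multinomial) PE uncertainty
#'
#' Leading-order standard deviation of the sample PE under the hypothesis
#' that the pattern stream is a memoryless multinomial process:
#' \eqn{\sqrt{\hat\Lambda_0 / (N - m + 1)}}. The overlap of consecutive
#' windows makes real pattern streams non-memoryless, so this is a
#' comparison baseline, not the recommended uncertainty. It vanishes on a
#' uniform distribution; callers should then fall back to [sigma_harris()].
#'
#' @inheritParams permutation_entropy
#' @return A single non-negative number (nats).
#' @export
sigma_memoryless <- function(d) {
  stopifnot(inherits(d, "ordinal_distribution"))
  sqrt(lambda0(d) / d$window_count)
}

#' Uniform-multinomial (Harris) uncertainty floor
#'
#' Standard deviation of the plug-in entropy in the special case of a uniform
#' multinomial over all `m!` patterns, `sqrt((m! - 1) / 2) / n` — the floor
#' approached when noise makes all patterns equiprobable and the
#' leading-order term of [sigma_memoryless()] vanishes.
#'
#' @param m Pattern dimension.
#' @param n Series length (`n > m`).
#' @return A single positive number (nats).
#' @examples
#' sigma_harris(4, 10006)
#' @export
sigma_harris <- function(m, n) {
  m <- check_dimension(m)
  if (length(n) != 1L || !is.numeric(n) || n <= m) {
    stop("`n` must be a single number > m", call. = FALSE)
  }
  sqrt((factorial(m) - 1) / 2) / n
}
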