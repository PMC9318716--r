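# Discrete Fourier transforms for arbitrary lengths.
#
# Base R's fft() (Singleton's mixed-radix algorithm) costs O(N * p) when N has
# a large prime factor p; the typical series length here, N = 10006 = 2 * 5003
# with 5003 prime, makes each transform ~40 ms — prohibitive inside the IAAFT
# iteration. For such lengths the DFT is re-expressed via Bluestein's chirp-z
# identity as a circular convolution, evaluated with base fft() at a padded
# power-of-2 length. Smooth lengths keep the direct fft() path.

max_prime_factor <- function(n) {
  n <- as.double(n)
  mx <- 1
  p <- 2
  while (n > 1 && p * p <= n) {
    if (n %% p == 0) {
      mx <- max(mx, p)
      while (n %% p == 0) n <- n / p
    }
    p <- p + 1
  }
  max(mx, n)
}

dft_plan <- function(n) {
  if (max_prime_factor(n) <= 127) {
    return(structure(list(n = n, type = "base"), class = "dft_plan"))
  }
  m <- 2^ceiling(log2(2 * n - 1))
  # chirp w_k = exp(-i pi k^2 / n); B is the transform of the wrapped
  # conjugate chirp, precomputed once per length
  w <- exp(-1i * pi * (seq_len(n) - 1)^2 / n)
  b <- c(Conj(w), rep(0 + 0i, m - 2 * n + 1), Conj(w[n:2]))
  structure(list(n = n, type = "bluestein", m = m, w = w, B = fft(b)),
            class = "dft_plan")
}

dft_forward <- function(plan, x) {
  if (plan$type == "base") return(fft(x))
  a <- c(x * plan$w, rep(0 + 0i, plan$m - plan$n))
  conv <- fft(fft(a) * plan$B, inverse = TRUE) / plan$m
  plan$w * conv[seq_len(plan$n)]
}

# unnormalized inverse DFT divided by n, i.e. the true inverse transform
dft_inverse <- function(plan, x) {
  if (plan$type == "base") return(fft(x, inverse = TRUE) / plan$n)
  Conj(dft_forward(plan, Conj(x))) / plan$n
}
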