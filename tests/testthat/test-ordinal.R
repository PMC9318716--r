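# Ordinal-pattern encoding and permutation entropy.

test_that("window encoding follows the rank convention with index tie-breaking", {
  expect_identical(encode_window(c(1, 2, 3)), 1:3)
  expect_identical(encode_window(c(4, 7, 2)), c(2L, 3L, 1L))
  # tie: 3 is smallest, the earlier 5 outranks the later one
  expect_identical(encode_window(c(5, 5, 3)), c(2L, 3L, 1L))
  expect_error(encode_window(c(1, NA, 2)), "non-finite")
  expect_error(encode_window(c(1, Inf, 2)), "non-finite")
  expect_error(encode_window(5), "too short")
})

test_that("encoding is a bijection onto the permutations for m up to 5", {
  for (m in 2:5) {
    perms <- all_permutations(m)
    codes <- apply(perms, 1L, function(w) {
      p <- encode_window(as.numeric(w))
      expect_identical(p, brute_force_pattern(w))
      sum((p - 1) * m^(seq_len(m) - 1))
    })
    expect_identical(length(unique(codes)), nrow(perms))
  }
})

test_that("tied windows match the brute-force oracle", {
  set.seed(11)
  for (i in 1:200) {
    m <- sample(2:6, 1)
    w <- sample(0:3, m, replace = TRUE)   # many ties
    expect_identical(encode_window(w), brute_force_pattern(w))
  }
})

test_that("ordinal distribution counts overlapping windows correctly", {
  d <- ordinal_distribution(c(1, 3, 2, 4), m = 2)
  expect_identical(d$window_count, 3L)
  key <- apply(d$patterns, 1L, paste, collapse = ",")
  counts <- setNames(d$counts, key)
  expect_identical(counts[["1,2"]], 2L)
  expect_identical(counts[["2,1"]], 1L)
  expect_equal(sum(d$frequencies), 1)

  # strictly increasing series: single identity pattern in N - m + 1 windows
  d2 <- ordinal_distribution(seq_len(57), m = 3)
  expect_identical(nrow(d2$patterns), 1L)
  expect_identical(d2$patterns[1, ], 1:3)
  expect_identical(d2$counts, 55L)

  expect_error(ordinal_distribution(c(1, 2), m = 3), "too short")
})

test_that("window overlap restricts which pattern can follow (1,2,3)", {
  # after (1,2,3) the next window still has its first two samples ordered,
  # so in the rank convention only (1,2,3), (1,3,2) or (2,3,1) can follow
  # (in the argsort convention the last reads (3,1,2))
  allowed <- c("1,2,3", "1,3,2", "2,3,1")
  set.seed(5)
  for (rep in 1:30) {
    x <- rnorm(50)
    w <- length(x) - 2
    pat <- vapply(seq_len(w),
                  function(i) paste(encode_window(x[i:(i + 2)]), collapse = ","),
                  character(1))
    after <- pat[which(pat[-w] == "1,2,3") + 1L]
    expect_true(all(after %in% allowed))
  }
})

test_that("permutation entropy combines plug-in and Miller-Madow terms", {
  e <- permutation_entropy(ordinal_distribution(c(1, 3, 2, 4), m = 2))
  expect_equal(e$plug_in, 0.6365142, tolerance = 1e-6)
  expect_equal(e$mm_correction, 1 / 6)
  expect_equal(e$h, 0.8031808, tolerance = 1e-6)
  expect_equal(e$h, e$plug_in + e$mm_correction)
  expect_identical(e$n, 4L)
  expect_true(is.na(e$sigma))

  # monotone series: exactly zero, both terms
  e0 <- permutation_entropy(ordinal_distribution(seq_len(100), m = 4))
  expect_identical(e0$h, 0)
})

test_that("plug-in entropy is bounded by log of the visited-pattern count", {
  set.seed(21)
  for (i in 1:40) {
    m <- sample(2:5, 1)
    x <- rnorm(sample(m:80, 1))
    d <- ordinal_distribution(x, m)
    e <- permutation_entropy(d)
    expect_lte(e$plug_in, log(nrow(d$patterns)) + 1e-12)
    expect_lte(log(nrow(d$patterns)), log(factorial(m)) + 1e-12)
    expect_gte(e$plug_in, 0)
    expect_gte(e$mm_correction, 0)
  }
})

test_that("lambda0 is the population variance of -log p", {
  d <- pevar:::new_ordinal_distribution(rbind(1:2, 2:1), c(75L, 25L), 2L)
  expect_equal(lambda0(d), 0.2263030, tolerance = 1e-6)
  # uniform: -log p constant, variance zero
  du <- pevar:::new_ordinal_distribution(rbind(1:3, c(1L, 3L, 2L), c(3L, 1L, 2L)),
                                         c(10L, 10L, 10L), 3L)
  expect_equal(lambda0(du), 0)
  # single pattern
  d1 <- ordinal_distribution(1:20, 3)
  expect_equal(lambda0(d1), 0)
})

test_that("memoryless sigma scales as the inverse square root of the window count", {
  d100 <- pevar:::new_ordinal_distribution(rbind(1:2, 2:1), c(75L, 25L), 2L)
  expect_equal(sigma_memoryless(d100), 0.04757131, tolerance = 1e-6)
  d400 <- pevar:::new_ordinal_distribution(rbind(1:2, 2:1), c(300L, 100L), 2L)
  expect_equal(sigma_memoryless(d400), sigma_memoryless(d100) / 2)
  # uniform distribution: leading-order term vanishes
  du <- pevar:::new_ordinal_distribution(rbind(1:2, 2:1), c(50L, 50L), 2L)
  expect_identical(sigma_memoryless(du), 0)
})

test_that("Harris floor matches the uniform-multinomial closed form", {
  expect_equal(sigma_harris(4, 10006), 3.389132e-4, tolerance = 1e-6)
  expect_equal(sigma_harris(3, 2000), sigma_harris(3, 1000) / 2)
  expect_error(sigma_harris(1, 100), "m")
  expect_error(sigma_harris(4, 4), "n")
})
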