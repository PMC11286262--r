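test_that("two-proportion z reproduces the published comparisons", {
  a <- two_proportion_z(15, 23, 7, 21)
  expect_equal(a$z, 2.1128, tolerance = 5e-5)
  # the printed p (0.0349) sits 3e-4 from the exact normal p of this z
  expect_equal(a$p.value, 0.0349, tolerance = 0.02)
  b <- two_proportion_z(7, 23, 13, 21)
  expect_equal(b$z, -2.094, tolerance = 5e-4)
  expect_equal(b$p.value, 0.0366, tolerance = 0.02)
  expect_equal(two_proportion_z(5, 10, 10, 20)$z, 0)
})

test_that("two-proportion z is antisymmetric and degenerates gracefully", {
  for (seed in 1:20) {
    set.seed(seed)
    n1 <- sample(5:50, 1); n2 <- sample(5:50, 1)
    x1 <- sample(0:n1, 1); x2 <- sample(0:n2, 1)
    if ((x1 + x2) %in% c(0, n1 + n2)) next
    expect_equal(two_proportion_z(x1, n1, x2, n2)$z,
                 -two_proportion_z(x2, n2, x1, n1)$z, tolerance = 1e-12)
  }
  expect_warning(z0 <- two_proportion_z(0, 10, 0, 12), "degenerate")
  expect_equal(z0$z, 0)
})

test_that("z squared equals the pooled 2x2 chi-square statistic", {
  for (seed in 1:200) {
    set.seed(seed)
    n1 <- sample(3:60, 1); n2 <- sample(3:60, 1)
    x1 <- sample(1:(n1 - 1), 1); x2 <- sample(1:(n2 - 1), 1)
    z <- two_proportion_z(x1, n1, x2, n2)$z
    tab <- matrix(c(x1, n1 - x1, x2, n2 - x2), 2, byrow = TRUE,
                  dimnames = list(c("g", "other"), c("s", "other")))
    chi <- suppressWarnings(enrichment_chi_square(tab, "g", "s"))
    expect_equal(z^2, chi$chi2, tolerance = 1e-9)
    expect_equal(two_proportion_z(x1, n1, x2, n2)$p.value, chi$p.value,
                 tolerance = 1e-9)
  }
})

test_that("enrichment chi-square matches hand computation and edge rules", {
  tab <- matrix(c(20, 5, 5, 20), 2, byrow = TRUE,
                dimnames = list(c("a", "b"), c("x", "y")))
  expect_equal(enrichment_chi_square(tab, "a", "x")$chi2, 18,
               tolerance = 1e-12)

  # identical proportions in every origin: statistic 0
  same <- matrix(c(10, 30, 5, 15), 2, byrow = TRUE,
                 dimnames = list(c("a", "b"), c("x", "y")))
  expect_equal(enrichment_chi_square(same, "a", "x")$chi2, 0,
               tolerance = 1e-12)

  zero <- matrix(c(0, 0, 3, 4), 2, byrow = TRUE,
                 dimnames = list(c("a", "b"), c("x", "y")))
  expect_error(enrichment_chi_square(zero, "a", "x"), "expected count")
})

test_that("one-way ANOVA with Tukey-Kramer matches a from-scratch oracle", {
  g <- list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(10, 11, 12))
  res <- anova_tukey(g)

  # explicit sum-of-squares decomposition
  all_v <- unlist(g); k <- 3; N <- length(all_v)
  gm <- mean(all_v)
  ssb <- sum(vapply(g, function(v) length(v) * (mean(v) - gm)^2, 0))
  ssw <- sum(vapply(g, function(v) sum((v - mean(v))^2), 0))
  Fo <- (ssb / (k - 1)) / (ssw / (N - k))
  expect_equal(res$F, Fo, tolerance = 1e-10)
  expect_equal(res$p.value, pf(Fo, k - 1, N - k, lower.tail = FALSE),
               tolerance = 1e-10)

  # studentized-range p for one pair, Tukey-Kramer SE
  mse <- ssw / (N - k)
  q_ab <- abs(mean(g$b) - mean(g$a)) /
    sqrt(mse / 2 * (1 / 3 + 1 / 3))
  p_ab <- ptukey(q_ab, k, N - k, lower.tail = FALSE)
  got <- res$tukey$p_adj[res$tukey$comparison == "b-a"]
  expect_equal(got, p_ab, tolerance = 1e-8)
  expect_lt(res$tukey$p_adj[res$tukey$comparison == "c-a"], 1e-4)
})

test_that("ANOVA handles degenerate inputs; F equals t^2 for two groups", {
  same <- anova_tukey(list(a = c(1, 1), b = c(1, 1), c = c(1, 1)))
  expect_equal(same$F, 0)
  expect_equal(same$p.value, 1)
  expect_true(all(same$tukey$p_adj == 1))

  set.seed(8)
  g2 <- list(a = rnorm(12), b = rnorm(15, 0.7))
  res <- anova_tukey(g2)
  tt <- t.test(g2$a, g2$b, var.equal = TRUE)
  expect_equal(res$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(res$p.value, tt$p.value, tolerance = 1e-10)
})

test_that("archetypal skewness differs between ataxia and dystonia cohorts", {
  co <- generate_archetypal_cohort(c(ataxia = 20, dystonia = 20), seed = 17)
  f <- featurize_cohort(co$cohort)
  g <- split(f$skewness, f$group_label)
  res <- anova_tukey(g)
  expect_lt(res$tukey$p_adj[1], 0.01)
  expect_gt(mean(g$dystonia), mean(g$ataxia))  # dystonia is the skewed one
})

test_that("tremor peak power finds spectral lines only inside (0, 30] Hz", {
  tt <- seq(0, 30 - 1 / 500, by = 1 / 500)
  pure <- accel_trace(sin(2 * pi * 10 * tt), 500)
  pk <- tremor_peak_power(pure)
  expect_equal(pk$peak_frequency_hz, 10, tolerance = 0.05)

  fast <- accel_trace(sin(2 * pi * 45 * tt), 500)
  pk45 <- tremor_peak_power(fast)
  expect_lte(pk45$peak_frequency_hz, 30)   # only leakage lives in-band
  expect_lt(pk45$peak_power, pk$peak_power / 100)

  noisy <- generate_accel_trace(10, amplitude = 1, noise_sd = 0.3, seed = 2)
  expect_equal(tremor_peak_power(noisy)$peak_frequency_hz, 10,
               tolerance = 0.05)
  expect_error(accel_trace(rnorm(100), 50), "60 Hz")
})

test_that("the periodogram satisfies Parseval within 1 percent", {
  set.seed(4)
  x <- rnorm(60000)
  tr <- accel_trace(x, 500)
  sp <- tremor_peak_power(tr)$spectrum
  # exact one-sided Parseval identity (DC excluded, Nyquist not doubled)
  n <- length(x); w <- 0.5 - 0.5 * cos(2 * pi * seq(0, n - 1) / (n - 1))
  xc <- x - mean(x); X <- fft(w * xc)
  exact <- (n * sum((w * xc)^2) - Mod(X[1])^2 + Mod(X[n / 2 + 1])^2) /
    (n * sum(w^2))
  expect_equal(sum(sp$power), exact, tolerance = 1e-9)
  # and approximates the plain signal variance
  expect_equal(sum(sp$power), var(x) * (n - 1) / n, tolerance = 0.01)
})

test_that("proportion tables are row-normalized with zero-row flags", {
  m <- matrix(c(28, 5), 1, dimnames = list("g", c("x", "y")))
  pr <- proportion_table(m)
  expect_equal(round(unname(pr[1, ]), 3), c(0.848, 0.152))

  oh <- proportion_table(matrix(c(0, 1, 0, 0), 1))
  expect_equal(unname(oh[1, ]), c(0, 1, 0, 0))

  z <- matrix(c(0, 0, 2, 3), 2, byrow = TRUE,
              dimnames = list(c("none", "some"), c("x", "y")))
  pz <- proportion_table(z)
  expect_equal(attr(pz, "zero_rows"), "none")
  expect_equal(unname(rowSums(pz)), c(0, 1))
})
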