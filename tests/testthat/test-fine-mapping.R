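# Wakefield approximate Bayes factors and credible sets.
# Frozen expected values were computed with a 50-digit arbitrary-precision
# oracle (mpmath) for the closed form sqrt(V/(V+w)) * exp(w b^2 / (2V(V+w))).

test_that("ABF matches the extended-precision oracle", {
  expect_equal(approximate_bayes_factor(0, 0.01, 0.04),
               0.447213595499958, tolerance = 1e-12) # sqrt(0.2)
  expect_equal(approximate_bayes_factor(0.5, 0.01, 0.04),
               9850.53496425235, tolerance = 1e-12)
  expect_equal(approximate_bayes_factor(0.3, 0.01, 0.04),
               16.3672280145070, tolerance = 1e-12)
  # log-scale checkpoints, including overflow territory
  expect_equal(approximate_bayes_factor(2, 1e-4, 0.1, log = TRUE),
               19976.5656026303, tolerance = 1e-12)
  expect_equal(approximate_bayes_factor(1.5, 1e-3, 0.01, log = TRUE),
               1021.52832509087, tolerance = 1e-12)
  expect_equal(approximate_bayes_factor(-0.7, 0.5, 0.04, log = TRUE),
               -0.00218422427176787, tolerance = 1e-12)
})

test_that("ABF agrees with direct double-precision evaluation over a grid", {
  grid <- expand.grid(beta = seq(-2, 2, by = 0.25),
                      V = c(1e-4, 1e-3, 1e-2, 0.1, 0.5, 1),
                      omega = c(0.01, 0.04, 0.1))
  direct <- with(grid, sqrt(V / (V + omega)) * exp(omega * beta^2 / (2 * V * (V + omega))))
  ours <- approximate_bayes_factor(grid$beta, grid$V, grid$omega)
  finite <- is.finite(direct) # direct form overflows at extreme z; log form cannot
  expect_true(all(abs(ours[finite] - direct[finite]) / direct[finite] <= 1e-12))
  logdirect <- with(grid, 0.5 * log(V / (V + omega)) + omega * beta^2 / (2 * V * (V + omega)))
  expect_equal(approximate_bayes_factor(grid$beta, grid$V, grid$omega, log = TRUE),
               logdirect, tolerance = 1e-12)
})

test_that("ABF is symmetric in beta, validates inputs, and caps output", {
  b <- seq(0.1, 1.5, by = 0.2)
  expect_identical(approximate_bayes_factor(b, 0.02, 0.04),
                   approximate_bayes_factor(-b, 0.02, 0.04))
  expect_error(approximate_bayes_factor(1, 0, 0.04), "positive")
  expect_error(approximate_bayes_factor(1, 0.01, -1), "positive")
  expect_equal(approximate_bayes_factor(2, 1e-4, 0.1), 1e300) # capped
})

test_that("as_printed form ranks identically under equal V", {
  beta <- c(0.4, -0.6, 0.1, 0.25)
  st <- make_stats(paste0("v", 1:4), beta, se = 0.1)
  cs_sqrt <- credible_set(st, abf_form = "sqrt")
  cs_lit <- credible_set(st, abf_form = "as_printed")
  expect_identical(cs_sqrt$table$variant, cs_lit$table$variant)
  expect_identical(cs_sqrt$members, cs_lit$members)
})

test_that("credible set handles singleton, ties and the three-variant oracle", {
  s1 <- make_stats("only", 0.3, 0.05)
  cs1 <- credible_set(s1)
  expect_equal(cs1$table$posterior, 1)
  expect_equal(cs1$members, "only")

  # identical evidence: posterior 0.5 each, both needed for 99%
  s2 <- make_stats(c("a", "b"), c(0.3, 0.3), c(0.05, 0.05))
  cs2 <- credible_set(s2)
  expect_equal(cs2$table$posterior, c(0.5, 0.5))
  expect_setequal(cs2$members, c("a", "b"))

  # beta (0.5, 0.3, 0.1), V = 0.01, omega = 0.04: lead carries 0.99827
  s3 <- make_stats(c("lead", "mid", "low"), c(0.5, 0.3, 0.1), sqrt(0.01))
  cs3 <- credible_set(s3)
  expect_equal(cs3$table$posterior[1], 0.998273699258, tolerance = 1e-9)
  expect_equal(cs3$members, "lead")
  # minimality: dropping the last member leaves mass <= threshold
  k <- length(cs3$members)
  expect_lte(if (k > 1) cs3$table$cumulative[k - 1] else 0, 0.99)
})

test_that("posteriors normalize exactly in log space at extreme z", {
  set.seed(77)
  n <- 1e5
  se <- rep(0.02, n)
  beta <- rnorm(n, sd = 0.02)
  beta[1] <- 40 * 0.02 # |z| = 40 lead
  cs <- credible_set(make_stats(sprintf("v%06d", 1:n), beta, se))
  expect_lt(abs(sum(cs$table$posterior) - 1), 1e-12)
  expect_equal(cs$table$variant[1], "v000001")
  expect_equal(cs$members, "v000001")
})

test_that("raising |beta| never lowers a variant's posterior or rank", {
  st <- make_stats(paste0("v", 1:5), c(0.05, 0.1, 0.15, 0.2, 0.25), 0.1)
  base <- credible_set(st)
  p0 <- base$table$posterior[base$table$variant == "v2"]
  r0 <- which(base$table$variant == "v2")
  for (b in seq(0.15, 0.6, by = 0.15)) {
    st2 <- st
    st2$beta[2] <- b
    cs <- credible_set(st2)
    expect_gte(cs$table$posterior[cs$table$variant == "v2"], p0)
    expect_lte(which(cs$table$variant == "v2"), r0)
  }
})

test_that("credible set validates inputs and breaks ties by variant id", {
  empty <- data.frame(variant = character(0), beta = numeric(0), se = numeric(0))
  expect_error(credible_set(empty), "empty")
  expect_error(credible_set(make_stats("v", 1, 0.1), mass = 1), "mass")
  tie <- credible_set(make_stats(c("zz", "aa"), c(0.2, 0.2), 0.1))
  expect_identical(tie$table$variant, c("aa", "zz"))
})
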