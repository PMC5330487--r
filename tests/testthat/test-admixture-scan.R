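# Local-ancestry regression scan and Max(T) permutation machinery.

scan_fixture <- function(n = 200, m = 20, seed = 17, effect = 0.3) {
  model <- admixture_model(n_markers = m)
  anc <- simulate_local_ancestry(model, n, seed)
  set.seed(seed + 1)
  diabetes <- rbinom(n, 1, 0.5)
  y <- effect * anc$nam[, (m + 1) %/% 2] + rnorm(n)
  list(anc = anc, y = y, diabetes = diabetes)
}

test_that("scan betas and SEs match the normal-equations oracle", {
  fx <- scan_fixture()
  g <- global_ancestry(fx$anc)
  set.seed(99)
  cond <- matrix(rbinom(200, 2, 0.4), ncol = 1)
  res <- ancestry_scan(fx$anc, fx$y, diabetes = fx$diabetes, condition_on = cond)
  covars <- cbind(g$nam, g$afr, fx$diabetes, cond)
  for (j in seq_len(20)) {
    oracle <- ols_oracle(fx$y, fx$anc$nam[, j], covars)
    expect_lt(abs(res$beta[j] - oracle$beta) / abs(oracle$beta), 1e-10)
    expect_lt(abs(res$se[j] - oracle$se) / oracle$se, 1e-10)
    expect_equal(res$p_asymptotic[j], 2 * pt(-abs(oracle$t), oracle$df),
                 tolerance = 1e-10)
  }
})

test_that("constant phenotype yields zero betas and p = 1", {
  fx <- scan_fixture(n = 60, m = 5)
  res <- ancestry_scan(fx$anc, rep(2.5, 60), diabetes = fx$diabetes)
  expect_equal(res$beta, rep(0, 5))
  expect_equal(res$p_asymptotic, rep(1, 5))
  expect_true(all(res$flag == "constant_phenotype"))
})

test_that("degenerate markers are skipped with the right flags", {
  fx <- scan_fixture(n = 100, m = 6)
  nam <- fx$anc$nam
  nam[, 3] <- 1L # ancestry fixed at this locus
  anc <- make_ancestry(nam)
  res <- ancestry_scan(anc, fx$y, diabetes = fx$diabetes)
  expect_equal(res$flag[3], "constant_ancestry")
  expect_true(is.na(res$beta[3]))

  # conditioning column identical to a tested marker: flagged, no estimate
  res2 <- ancestry_scan(anc, fx$y, diabetes = fx$diabetes,
                        condition_on = nam[, 5, drop = FALSE])
  expect_equal(res2$flag[5], "collinear")
  expect_true(is.na(res2$beta[5]))
})

test_that("all-zero conditioning column reproduces the unconditional scan exactly", {
  fx <- scan_fixture(n = 120, m = 8)
  plain <- ancestry_scan(fx$anc, fx$y, diabetes = fx$diabetes,
                         permutations = 50, seed = 4)
  zero <- ancestry_scan(fx$anc, fx$y, diabetes = fx$diabetes,
                        condition_on = matrix(0, 120, 1),
                        permutations = 50, seed = 4)
  expect_identical(plain$beta, zero$beta)
  expect_identical(plain$p_empirical, zero$p_empirical)
})

test_that("Max(T) empirical p-values honor the (k+1)/(B+1) conventions", {
  fx <- scan_fixture(n = 50, m = 3, effect = 0)
  g <- global_ancestry(fx$anc)
  # overwhelming signal at marker 2: observed |t| beats every permuted max
  y_strong <- fx$anc$nam[, 2] + rnorm(50, sd = 1e-3)
  res <- ancestry_scan(fx$anc, y_strong, permutations = 999, seed = 6)
  expect_equal(res$p_empirical[2], 1 / 1000)

  # |t| = 0 by construction: every permuted max is >= 0, so p = 1
  set.seed(60)
  y0 <- qr.resid(qr(cbind(1, g$nam, g$afr, fx$anc$nam[, 1])), rnorm(50))
  res0 <- ancestry_scan(fx$anc, y0, permutations = 99, seed = 6)
  expect_equal(res0$beta[1], 0, tolerance = 1e-10)
  expect_equal(res0$p_empirical[1], 1)
})

test_that("Monte-Carlo Max(T) matches exhaustive enumeration at n = 6", {
  set.seed(23)
  repeat { # a 6 x 3 fixture where each marker is testable given [1, g_nam]
    nam <- matrix(sample(0:2, 18, replace = TRUE), 6, 3)
    g <- rowMeans(nam) / 2
    ok <- all(apply(nam, 2, var) > 0) &&
      all(vapply(1:3, function(j) qr(cbind(1, g, nam[, j]))$rank == 3L, TRUE))
    if (ok) break
  }
  anc <- make_ancestry(nam)
  y <- c(0.3, -1.2, 0.8, 1.9, -0.4, 0.1)
  g <- global_ancestry(anc)

  # exhaustive oracle over all 720 label permutations, same model per marker
  perms <- as.matrix(expand.grid(rep(list(1:6), 6)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 6), ]
  covars <- cbind(g$nam)
  tmat <- apply(perms, 1, function(p) {
    vapply(1:3, function(j) abs(ols_oracle(y[p], nam[, j], covars)$t), numeric(1))
  })
  maxt <- apply(tmat, 2, max)
  t_obs <- vapply(1:3, function(j) abs(ols_oracle(y, nam[, j], covars)$t), numeric(1))
  p_exact <- vapply(t_obs, function(t) mean(maxt >= t - 1e-12), numeric(1))

  res <- ancestry_scan(anc, y, permutations = 10000, seed = 12)
  expect_lt(max(abs(res$p_empirical - p_exact)), 0.02)
})

test_that("empirical p-values are deterministic, order-invariant and coherent", {
  fx <- scan_fixture(n = 150, m = 12)
  r1 <- ancestry_scan(fx$anc, fx$y, diabetes = fx$diabetes,
                      permutations = 200, seed = 5)
  r2 <- ancestry_scan(fx$anc, fx$y, diabetes = fx$diabetes,
                      permutations = 200, seed = 5)
  expect_identical(r1$p_empirical, r2$p_empirical)

  # reorder markers: per-marker results unchanged
  ord <- rev(seq_len(12))
  anc_rev <- admixscan:::new_ancestry_matrix(
    fx$anc$nam[, ord], fx$anc$map[ord, ], fx$anc$ids,
    eur = fx$anc$eur[, ord], afr = fx$anc$afr[, ord])
  r3 <- ancestry_scan(anc_rev, fx$y, diabetes = fx$diabetes,
                      permutations = 200, seed = 5)
  expect_equal(r3$p_empirical, r1$p_empirical[ord])

  # floor, monotonicity in |t|, and the family-wise minimum property
  expect_true(all(r1$p_empirical >= 1 / 201))
  ord_t <- order(-abs(r1$t))
  expect_true(all(diff(r1$p_empirical[ord_t]) >= 0))
  expect_equal(min(r1$p_empirical), r1$p_empirical[which.max(abs(r1$t))])
})

test_that("scan validates inputs", {
  fx <- scan_fixture(n = 30, m = 4)
  expect_error(ancestry_scan(fx$anc, fx$y[-1]), "length")
  expect_error(ancestry_scan(fx$anc, fx$y, diabetes = c(1, 0)), "length")
  expect_error(ancestry_scan(fx$anc, fx$y, condition_on = matrix(1, 3, 1)),
               "dimension")
  expect_error(maxt_permutation(fx$anc, fx$y, B = 0), "B must be")
  expect_error(ancestry_scan(fx$anc, fx$y, permutations = 10), "seed required")
})
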