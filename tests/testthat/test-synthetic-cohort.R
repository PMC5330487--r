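# Synthetic cohort generator: degenerate cases, analytic moments of the
# single-pulse Markov model, ancestry-conditional genotype frequencies and
# phenotype covariate structure.

test_that("model constructor enforces its invariants", {
  expect_error(admixture_model(proportions = c(0.5, 0.4, 0.2)), "sum to 1")
  expect_error(admixture_model(proportions = c(1.1, -0.1, 0)), "\\[0, 1\\]")
  expect_error(admixture_model(positions = c(0.2, 0.1)), "strictly increasing")
  expect_error(admixture_model(positions = c(0.2, 1.5)), "chr_length")
  expect_error(ancestral_frequencies(matrix(1.5, 2, 3)), "\\[0, 1\\]")
})

test_that("single-ancestry model yields saturated NAM counts", {
  model <- admixture_model(proportions = c(1, 0, 0), n_markers = 25)
  anc <- simulate_local_ancestry(model, 10, seed = 1)
  expect_true(all(anc$nam == 2L))
  expect_equal(unname(global_ancestry(anc)$nam), rep(1, 10))
})

test_that("observed switch count matches the stationary Markov expectation", {
  model <- admixture_model(generations = 15, chr_length = 1, n_markers = 2000)
  anc <- simulate_local_ancestry(model, 2000, seed = 42)
  m <- model$proportions
  expected <- 15 * 1 * (1 - sum(m^2))
  switches <- function(h) rowSums(h[, -1, drop = FALSE] != h[, -2000, drop = FALSE])
  obs <- c(switches(anc$haplotypes$h1), switches(anc$haplotypes$h2))
  mc_se <- sd(obs) / sqrt(length(obs))
  expect_lt(abs(mean(obs) - expected), 3 * mc_se)
})

test_that("cohort mean global NAM ancestry matches the model proportion", {
  model <- admixture_model(n_markers = 200)
  anc <- simulate_local_ancestry(model, 2000, seed = 11)
  g <- global_ancestry(anc)$nam
  se <- sd(g) / sqrt(length(g))
  expect_lt(abs(mean(g) - 0.6486), 3 * se)
})

test_that("marginal ancestry is stationary across positions (chi-square GOF)", {
  model <- admixture_model(n_markers = 5)
  rejections <- 0L
  for (r in 1:50) {
    anc <- simulate_local_ancestry(model, 2000, seed = 100 + r)
    j <- 1L + (r %% 5L) # rotate through positions
    codes <- c(anc$haplotypes$h1[, j], anc$haplotypes$h2[, j])
    p <- suppressWarnings(
      chisq.test(tabulate(codes, 3), p = model$proportions)$p.value)
    if (p < 0.01) rejections <- rejections + 1L
  }
  # Binomial(50, 0.01): P(>4 rejections) < 2e-4
  expect_lte(rejections, 4L)
})

test_that("genotypes follow ancestry-conditional allele frequencies", {
  model <- admixture_model(n_markers = 5)
  anc <- simulate_local_ancestry(model, 2000, seed = 5)
  freqs <- ancestral_frequencies(
    rbind(c(1, 1, 1), c(0.52, 0.12, 0.20), c(0.5, 0.5, 0.5),
          c(0, 0, 0), c(0.9, 0.1, 0.5)))
  gen <- simulate_genotypes(anc, freqs, seed = 5)
  expect_true(all(gen$dosage[, 1] == 2)) # fixed allele
  expect_true(all(gen$dosage[, 4] == 0))

  # cohort frequency at the differentiated marker ~ mixture expectation
  m <- model$proportions
  p_mix <- sum(m * c(0.52, 0.12, 0.20))
  p_obs <- mean(gen$dosage[, 2]) / 2
  se <- sqrt(p_mix * (1 - p_mix) / (2 * 2000))
  expect_lt(abs(p_obs - p_mix), 3 * se)

  # conditioning on NAM-homozygous individuals recovers p_NAM
  hom <- anc$nam[, 2] == 2L
  p_hom <- mean(gen$dosage[hom, 2]) / 2
  se_hom <- sqrt(0.52 * 0.48 / (2 * sum(hom)))
  expect_lt(abs(p_hom - 0.52), 3 * se_hom)
})

test_that("genotype simulation validates inputs", {
  model <- admixture_model(n_markers = 3)
  anc <- simulate_local_ancestry(model, 5, seed = 1)
  expect_error(simulate_genotypes(anc, matrix(0.5, 2, 3), 1), "one row per")
  anc_nohap <- make_ancestry(anc$nam)
  expect_error(simulate_genotypes(anc_nohap, matrix(0.5, 3, 3), 1),
               "haploid truth")
})

test_that("null phenotype has no association with the causal dosage", {
  model <- admixture_model(n_markers = 11)
  cohort <- simulate_cohort(model, pheno_model = phenotype_model(effect = 0),
                            n_individuals = 2000, seed = 3)
  truth <- attr(cohort$phenotypes, "truth")
  fit <- summary(lm(truth$y_std ~ cohort$genotypes$dosage[, truth$causal_index]))
  expect_lt(abs(coef(fit)[2, 1]), 3 * coef(fit)[2, 2])
})

test_that("OLS on the latent trait recovers the planted effect across seeds", {
  model <- admixture_model(n_markers = 11)
  freqs <- sample_ancestral_frequencies(11, 1, causal_index = 6)
  covered <- logical(60)
  for (r in seq_along(covered)) {
    anc <- simulate_local_ancestry(model, 800, seed = 200 + r)
    gen <- simulate_genotypes(anc, freqs, seed = 200 + r)
    phe <- simulate_phenotypes(gen, anc, phenotype_model(effect = 0.25), seed = 200 + r)
    truth <- attr(phe, "truth")
    fit <- summary(lm(truth$y_std ~ gen$dosage[, 6]))
    ci <- coef(fit)[2, 1] + c(-1.96, 1.96) * coef(fit)[2, 2]
    covered[r] <- ci[1] <= 0.25 && 0.25 <= ci[2]
  }
  expect_gte(mean(covered), 0.90)
})

test_that("covariate generator matches the target cohort moments", {
  model <- admixture_model(n_markers = 5)
  cohort <- simulate_cohort(model, n_individuals = 2000, seed = 9)
  phe <- cohort$phenotypes
  expect_lt(abs(mean(phe$age) - 52.78), 3 * sd(phe$age) / sqrt(2000) + 0.05)
  expect_lt(abs(mean(phe$bmi) - 28.64), 3 * sd(phe$bmi) / sqrt(2000) + 0.02)
  expect_true(all(phe[[paste0("tg")]] > 0))
})

test_that("identical master seed gives bit-identical cohorts", {
  model <- admixture_model(n_markers = 20)
  a <- simulate_cohort(model, n_individuals = 50, seed = 77)
  b <- simulate_cohort(model, n_individuals = 50, seed = 77)
  expect_identical(a$ancestry$nam, b$ancestry$nam)
  expect_identical(a$genotypes$dosage, b$genotypes$dosage)
  expect_identical(a$phenotypes$tg, b$phenotypes$tg)
  c <- simulate_cohort(model, n_individuals = 50, seed = 78)
  expect_false(identical(a$genotypes$dosage, c$genotypes$dosage))
})

test_that("phenotype model rejects a non-positive residual SD", {
  expect_error(phenotype_model(resid_sd = 0), "must be > 0")
})
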