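# Synthetic three-way admixed cohort generator.
#
# The generator realizes a single-pulse admixture model: each haploid
# chromosome is a piecewise-constant ancestry path along a genetic map,
# with crossover events Poisson(G per Morgan) and the ancestry of each
# segment drawn i.i.d. from the population admixture proportions. Genotypes
# are drawn Bernoulli per haplotype conditional on the ancestry at the
# marker, and a triglyceride-like trait is built from covariates, a planted
# causal variant and Gaussian noise on a standardized scale, then mapped to
# a positive raw (mg/dl) scale.

#' Single-pulse admixture model
#'
#' Describes the admixed population a synthetic cohort is drawn from: the
#' genome-wide admixture proportions of the three parental populations
#' (Native American, European, African), the number of generations since
#' the admixture pulse, and the genetic map of the simulated chromosome.
#'
#' @param proportions numeric length-3 vector (nam, eur, afr) of admixture
#'   proportions; must sum to 1 within 1e-12. Defaults to the mix typical
#'   of Mexican mestizo cohorts (~0.65/0.32/0.03).
#' @param generations generations since the admixture pulse (crossover rate
#'   per Morgan per haplotype). Default 15.
#' @param chr_length chromosome length in Morgans.
#' @param n_markers number of markers; ignored when `positions` is given.
#' @param positions strictly increasing genetic positions in Morgans within
#'   `[0, chr_length]`. Default: evenly spaced over the chromosome.
#' @param chrom chromosome label used in marker maps.
#' @return an object of class `admixture_model`.
#' @export
admixture_model <- function(proportions = c(nam = 0.6486, eur = 0.3190, afr = 0.0324),
                            generations = 15,
                            chr_length = 1,
                            n_markers = 200,
                            positions = NULL,
                            chrom = "11") {
  if (length(proportions) != 3L) {
    stop("proportions must have three components (nam, eur, afr)", call. = FALSE)
  }
  proportions <- unname(as.numeric(proportions))
  assert_probabilities(proportions, "admixture proportions")
  if (abs(sum(proportions) - 1) > 1e-12) {
    stop("admixture proportions must sum to 1 (within 1e-12)", call. = FALSE)
  }
  stopifnot(is.numeric(generations), generations > 0,
            is.numeric(chr_length), chr_length > 0)
  if (is.null(positions)) {
    stopifnot(n_markers >= 1)
    positions <- seq(0, chr_length, length.out = max(n_markers, 2L))[seq_len(n_markers)]
    if (n_markers == 1L) positions <- chr_length / 2
  }
  positions <- as.numeric(positions)
  if (any(diff(positions) <= 0)) {
    stop("marker positions must be strictly increasing", call. = FALSE)
  }
  if (min(positions) < 0 || max(positions) > chr_length) {
    stop("marker positions must lie in [0, chr_length]", call. = FALSE)
  }
  structure(
    list(proportions = c(nam = proportions[1], eur = proportions[2], afr = proportions[3]),
         generations = generations,
         chr_length = chr_length,
         n_markers = length(positions),
         positions = positions,
         chrom = chrom),
    class = "admixture_model")
}

#' @export
print.admixture_model <- function(x, ...) {
  cat("Single-pulse admixture model\n")
  cat(sprintf("  proportions: NAM %.4f / EUR %.4f / AFR %.4f\n",
              x$proportions[1], x$proportions[2], x$proportions[3]))
  cat(sprintf("  generations: %g, chromosome: %s (%g Morgans), markers: %d\n",
              x$generations, x$chrom, x$chr_length, x$n_markers))
  invisible(x)
}

#' Ancestral coded-allele frequencies
#'
#' A markers x 3 table of coded-allele frequencies in the parental
#' populations (columns nam, eur, afr).
#'
#' @param freqs numeric matrix or data.frame with 3 columns, values in [0,1].
#' @return a numeric matrix with columns nam, eur, afr.
#' @export
ancestral_frequencies <- function(freqs) {
  freqs <- as.matrix(freqs)
  if (ncol(freqs) != 3L) stop("freqs must have 3 columns (nam, eur, afr)", call. = FALSE)
  storage.mode(freqs) <- "double"
  assert_probabilities(freqs, "ancestral allele frequencies")
  colnames(freqs) <- c("nam", "eur", "afr")
  freqs
}

#' Draw background ancestral frequencies with an optional planted causal marker
#'
#' Background markers get frequencies drawn independently per ancestry from
#' Uniform(range); the causal marker is set to the supplied triple, by
#' default the ~0.52 (NAM) / 0.12 (EUR) / 0.20 (AFR) differentiation of a
#' strongly ancestry-informative triglyceride variant.
#'
#' @param n_markers number of markers.
#' @param seed integer seed.
#' @param causal_index index of the causal marker, or NULL for none.
#' @param causal_freqs length-3 vector (nam, eur, afr) for the causal marker.
#' @param range background frequency range.
#' @return matrix as [ancestral_frequencies()].
#' @export
sample_ancestral_frequencies <- function(n_markers, seed,
                                         causal_index = NULL,
                                         causal_freqs = c(nam = 0.52, eur = 0.12, afr = 0.20),
                                         range = c(0.05, 0.95)) {
  set.seed(stream_seed(seed, "ancestral_freqs"))
  f <- matrix(stats::runif(n_markers * 3L, range[1], range[2]), ncol = 3L)
  if (!is.null(causal_index)) {
    stopifnot(causal_index >= 1, causal_index <= n_markers)
    f[causal_index, ] <- as.numeric(causal_freqs)
  }
  ancestral_frequencies(f)
}

ancestry_codes <- c(nam = 1L, eur = 2L, afr = 3L)

new_ancestry_matrix <- function(nam, map, ids, eur = NULL, afr = NULL,
                                haplotypes = NULL) {
  dimnames(nam) <- list(ids, map$marker)
  if (!is.null(eur)) dimnames(eur) <- dimnames(nam)
  if (!is.null(afr)) dimnames(afr) <- dimnames(nam)
  structure(list(ids = ids, map = map, nam = nam, eur = eur, afr = afr,
                 haplotypes = haplotypes),
            class = "ancestry_matrix")
}

#' @export
print.ancestry_matrix <- function(x, ...) {
  cat(sprintf("ancestry_matrix: %d individuals x %d markers (NAM copy counts)\n",
              nrow(x$nam), ncol(x$nam)))
  cat(sprintf("  companion EUR/AFR matrices: %s; haploid truth: %s\n",
              if (!is.null(x$eur)) "yes" else "no",
              if (!is.null(x$haplotypes)) "yes" else "no"))
  invisible(x)
}

validate_ancestry_matrix <- function(x) {
  stopifnot(inherits(x, "ancestry_matrix"))
  if (!all(x$nam %in% 0:2)) stop("NAM copy counts must be 0/1/2", call. = FALSE)
  if (!is.null(x$eur) && !is.null(x$afr)) {
    if (!all(x$nam + x$eur + x$afr == 2L)) {
      stop("ancestry copy counts must sum to 2 across the three ancestries",
           call. = FALSE)
    }
  }
  invisible(x)
}

# one haploid ancestry path evaluated at marker positions
sim_haploid_path <- function(model) {
  lambda <- model$generations * model$chr_length
  nb <- stats::rpois(1L, lambda)
  if (nb == 0L) {
    anc <- sample.int(3L, 1L, prob = model$proportions)
    return(rep.int(anc, model$n_markers))
  }
  bp <- sort(stats::runif(nb, 0, model$chr_length))
  seg <- sample.int(3L, nb + 1L, replace = TRUE, prob = model$proportions)
  seg[findInterval(model$positions, bp) + 1L]
}

#' Simulate diploid local ancestry for a cohort
#'
#' Draws two haploid ancestry paths per individual under the single-pulse
#' Markov model and evaluates them at the marker positions. The returned
#' object carries NAM/EUR/AFR copy-count matrices plus the haploid truth
#' paths needed to simulate ancestry-conditional genotypes.
#'
#' @param model an [admixture_model()].
#' @param n_individuals cohort size.
#' @param seed integer seed (substream "ancestry").
#' @return an object of class `ancestry_matrix`.
#' @export
simulate_local_ancestry <- function(model, n_individuals, seed) {
  stopifnot(inherits(model, "admixture_model"), n_individuals >= 1)
  set.seed(stream_seed(seed, "ancestry"))
  n <- as.integer(n_individuals)
  m <- model$n_markers
  h1 <- matrix(0L, n, m)
  h2 <- matrix(0L, n, m)
  for (i in seq_len(n)) {
    h1[i, ] <- sim_haploid_path(model)
    h2[i, ] <- sim_haploid_path(model)
  }
  ids <- sprintf("id%05d", seq_len(n))
  map <- data.frame(marker = sprintf("mk%05d", seq_len(m)),
                    chrom = model$chrom,
                    pos_bp = as.integer(round(model$positions * 1e8)) + 1L,
                    pos_gen = model$positions,
                    stringsAsFactors = FALSE)
  nam <- (h1 == 1L) + (h2 == 1L)
  eur <- (h1 == 2L) + (h2 == 2L)
  afr <- (h1 == 3L) + (h2 == 3L)
  storage.mode(nam) <- "integer"
  storage.mode(eur) <- "integer"
  storage.mode(afr) <- "integer"
  new_ancestry_matrix(nam, map, ids, eur = eur, afr = afr,
                      haplotypes = list(h1 = h1, h2 = h2))
}

new_dosage_matrix <- function(dosage, map, ids) {
  dimnames(dosage) <- list(ids, map$marker)
  structure(list(ids = ids, map = map, dosage = dosage),
            class = "dosage_matrix")
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat(sprintf("dosage_matrix: %d individuals x %d markers, dosages in [0, 2]\n",
              nrow(x$dosage), ncol(x$dosage)))
  invisible(x)
}

#' Simulate genotypes conditional on local ancestry
#'
#' Each haploid allele is Bernoulli with the coded-allele frequency of the
#' ancestral population that haplotype carries at the marker; the diploid
#' dosage is the sum over the two haplotypes (hard calls in 0/1/2).
#'
#' @param ancestry an `ancestry_matrix` carrying haploid truth paths
#'   (i.e. produced by [simulate_local_ancestry()]).
#' @param freqs ancestral frequency matrix, see [ancestral_frequencies()];
#'   one row per ancestry marker.
#' @param seed integer seed (substream "genotypes").
#' @return an object of class `dosage_matrix`; alleles are coded G (coded,
#'   frequency as given) over C.
#' @export
simulate_genotypes <- function(ancestry, freqs, seed) {
  stopifnot(inherits(ancestry, "ancestry_matrix"))
  if (is.null(ancestry$haplotypes)) {
    stop("ancestry must carry haploid truth paths (use simulate_local_ancestry)",
         call. = FALSE)
  }
  freqs <- ancestral_frequencies(freqs)
  m <- ncol(ancestry$nam)
  n <- nrow(ancestry$nam)
  if (nrow(freqs) != m) {
    stop("freqs must have one row per ancestry marker", call. = FALSE)
  }
  set.seed(stream_seed(seed, "genotypes"))
  jj <- rep(seq_len(m), each = n) # column-major marker index
  p1 <- freqs[cbind(jj, c(ancestry$haplotypes$h1))]
  p2 <- freqs[cbind(jj, c(ancestry$haplotypes$h2))]
  a1 <- stats::rbinom(n * m, 1L, p1)
  a2 <- stats::rbinom(n * m, 1L, p2)
  dosage <- matrix(a1 + a2, n, m)
  storage.mode(dosage) <- "double"
  map <- ancestry$map
  map$coded <- "G"
  map$other <- "C"
  new_dosage_matrix(dosage, map, ancestry$ids)
}

#' Phenotype generation model for the synthetic cohort
#'
#' Coefficients are on the standardized trait scale; covariate moments
#' default to a middle-aged, diabetes-enriched Mexico City-like cohort
#' (age ~ N(52.78, 10.12), BMI ~ N(28.64, 4.91), ~50% male, ~50% T2D).
#' The raw trait is mapped through a lognormal with mean 174.99 and SD
#' 113.39 mg/dl so that it is positive and right-skewed like triglycerides.
#'
#' @param effect per-allele effect of the causal marker, in SD of the
#'   standardized trait. Default 0.25.
#' @param causal_index column index of the causal marker in the dosage
#'   matrix; default: middle marker.
#' @param beta_sex,beta_age,beta_age2,beta_bmi covariate coefficients on
#'   the standardized scale (sex is 0/1 male; age and BMI standardized).
#' @param resid_sd residual SD of the standardized trait; must be > 0.
#' @param med_prob probability an individual is on lipid-lowering
#'   medication; treatment multiplies the measured raw trait by
#'   `med_factor`.
#' @param med_factor multiplicative effect of treatment on the measured
#'   raw value (default 0.85, inverted exactly by the shipped adjustment
#'   rule).
#' @param raw_mean,raw_sd target mean and SD of the raw trait (mg/dl).
#' @param age_mean,age_sd,bmi_mean,bmi_sd,male_prob,diabetes_prob covariate
#'   generator moments.
#' @param trait trait name used for the output columns.
#' @return an object of class `phenotype_model`.
#' @export
phenotype_model <- function(effect = 0.25,
                            causal_index = NULL,
                            beta_sex = 0.15,
                            beta_age = 0.10,
                            beta_age2 = -0.02,
                            beta_bmi = 0.25,
                            resid_sd = 0.94,
                            med_prob = 0.20,
                            med_factor = 0.85,
                            raw_mean = 174.99,
                            raw_sd = 113.39,
                            age_mean = 52.78, age_sd = 10.12,
                            bmi_mean = 28.64, bmi_sd = 4.91,
                            male_prob = 892 / 1787,
                            diabetes_prob = 898 / 1787,
                            trait = "tg") {
  if (resid_sd <= 0) stop("residual standard deviation must be > 0", call. = FALSE)
  stopifnot(med_prob >= 0, med_prob <= 1, med_factor > 0,
            raw_mean > 0, raw_sd > 0, age_sd > 0, bmi_sd > 0)
  structure(as.list(environment()), class = "phenotype_model")
}

#' Simulate a lipid-like phenotype table
#'
#' Builds sex, age, BMI and diabetes covariates, a standardized latent
#' trait (covariates + per-allele causal effect + Gaussian noise), maps it
#' monotonically to a positive raw scale, and applies medication so the
#' medication-adjustment step can invert it exactly.
#'
#' @param genotypes a `dosage_matrix` holding the causal marker.
#' @param ancestry the matching `ancestry_matrix` (ids are taken from it).
#' @param model a [phenotype_model()].
#' @param seed integer seed (substream "phenotypes").
#' @return a data.frame of class `phenotype_table` with columns id, sex,
#'   age, age2, bmi, diabetes, `<trait>` (measured raw value, mg/dl) and
#'   `<trait>_med` (0/1 treatment flag). The standardized latent trait and
#'   the causal-marker truth are attached as attribute "truth".
#' @export
simulate_phenotypes <- function(genotypes, ancestry, model = phenotype_model(), seed) {
  stopifnot(inherits(genotypes, "dosage_matrix"),
            inherits(ancestry, "ancestry_matrix"),
            inherits(model, "phenotype_model"))
  n <- nrow(genotypes$dosage)
  if (n != nrow(ancestry$nam)) stop("genotype/ancestry dimension mismatch", call. = FALSE)
  causal <- model$causal_index %||% ((ncol(genotypes$dosage) + 1L) %/% 2L)
  stopifnot(causal >= 1, causal <= ncol(genotypes$dosage))
  set.seed(stream_seed(seed, "phenotypes"))

  sex <- stats::rbinom(n, 1L, model$male_prob)
  age <- model$age_mean + model$age_sd * stats::rnorm(n)
  age <- pmax(age, 20)
  bmi <- model$bmi_mean + model$bmi_sd * stats::rnorm(n)
  bmi <- pmax(bmi, 15)
  diabetes <- stats::rbinom(n, 1L, model$diabetes_prob)
  z_age <- (age - model$age_mean) / model$age_sd
  z_bmi <- (bmi - model$bmi_mean) / model$bmi_sd
  g <- genotypes$dosage[, causal]

  y <- model$beta_sex * (sex - model$male_prob) +
    model$beta_age * z_age +
    model$beta_age2 * (z_age^2 - 1) +
    model$beta_bmi * z_bmi +
    model$effect * g +
    stats::rnorm(n, sd = model$resid_sd)

  # lognormal moment match: positive, right-skewed raw scale
  sigma2 <- log(1 + (model$raw_sd / model$raw_mean)^2)
  mu <- log(model$raw_mean) - sigma2 / 2
  raw_true <- exp(mu + sqrt(sigma2) * y)
  med <- stats::rbinom(n, 1L, model$med_prob)
  measured <- ifelse(med == 1L, raw_true * model$med_factor, raw_true)

  tab <- data.frame(id = ancestry$ids, sex = sex, age = age, age2 = age^2,
                    bmi = bmi, diabetes = diabetes,
                    stringsAsFactors = FALSE)
  tab[[model$trait]] <- measured
  tab[[paste0(model$trait, "_med")]] <- med
  attr(tab, "truth") <- list(y_std = y,
                             causal_index = causal,
                             causal_marker = genotypes$map$marker[causal],
                             effect = model$effect,
                             med_factor = model$med_factor)
  class(tab) <- c("phenotype_table", "data.frame")
  tab
}

#' Simulate a complete admixed cohort
#'
#' Convenience wrapper chaining [simulate_local_ancestry()],
#' [simulate_genotypes()] and [simulate_phenotypes()] under one master seed
#' with independent named substreams.
#'
#' @param model an [admixture_model()].
#' @param freqs ancestral frequency matrix; default draws a background with
#'   a causal marker planted at the middle position (see
#'   [sample_ancestral_frequencies()]).
#' @param pheno_model a [phenotype_model()].
#' @param n_individuals cohort size.
#' @param seed master integer seed.
#' @return list with elements `ancestry`, `genotypes`, `phenotypes`,
#'   `model`, `freqs`, `seed`.
#' @export
simulate_cohort <- function(model = admixture_model(),
                            freqs = NULL,
                            pheno_model = phenotype_model(),
                            n_individuals = 1787,
                            seed = 1) {
  causal <- pheno_model$causal_index %||% ((model$n_markers + 1L) %/% 2L)
  if (is.null(freqs)) {
    freqs <- sample_ancestral_frequencies(model$n_markers, seed,
                                          causal_index = causal)
  }
  anc <- simulate_local_ancestry(model, n_individuals, seed)
  gen <- simulate_genotypes(anc, freqs, seed)
  phe <- simulate_phenotypes(gen, anc, pheno_model, seed)
  list(ancestry = anc, genotypes = gen, phenotypes = phe,
       model = model, freqs = freqs, seed = seed)
}
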