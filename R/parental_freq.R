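# Extrapolation of a parental-population allele frequency from the observed
# frequency in an admixed cohort: solving p_adm = sum_k m_k p_k for the
# Native American component.

#' Estimate the Native American parental allele frequency
#'
#' Inverts the admixture mixture equation
#' `p_adm = m_nam * p_nam + m_eur * p_eur + m_afr * p_afr`
#' for `p_nam`, given the observed admixed-cohort frequency, the reference
#' parental frequencies for the other ancestries and the cohort admixture
#' proportions. Out-of-range point estimates are clamped to [0, 1] with a
#' warning (sampling noise near the boundary is expected). The standard
#' error is delta-method, treating `p_adm` as a binomial proportion over
#' `2 n` alleles.
#'
#' @param p_adm observed coded-allele frequency in the admixed cohort.
#' @param proportions length-3 admixture proportions (nam, eur, afr),
#'   summing to 1 within 1e-9; the NAM proportion must be >= 0.01.
#' @param p_eur,p_afr reference parental frequencies in [0, 1].
#' @param n cohort size used for the delta-method standard error (optional).
#' @return list of class `parental_freq_estimate`: `estimate` (clamped),
#'   `raw` (unclamped), `se` (NA when `n` missing), `clamped` (logical),
#'   `proportions`.
#' @export
estimate_parental_frequency <- function(p_adm, proportions, p_eur, p_afr = 0,
                                        n = NULL) {
  proportions <- unname(as.numeric(proportions))
  if (length(proportions) != 3L) stop("proportions must be length 3 (nam, eur, afr)",
                                      call. = FALSE)
  assert_probabilities(proportions, "admixture proportions")
  if (abs(sum(proportions) - 1) > 1e-9) {
    stop("admixture proportions must sum to 1 (within 1e-9)", call. = FALSE)
  }
  assert_probabilities(c(p_adm, p_eur, p_afr), "allele frequencies")
  m_nam <- proportions[1]; m_eur <- proportions[2]; m_afr <- proportions[3]
  if (m_nam < 0.01) {
    stop("NAM admixture proportion below 0.01: estimate unstable", call. = FALSE)
  }
  raw <- (p_adm - m_eur * p_eur - m_afr * p_afr) / m_nam
  clamped <- raw < 0 || raw > 1
  if (clamped) {
    warning(sprintf("extrapolated frequency %.4f outside [0, 1]; clamped", raw),
            call. = FALSE)
  }
  est <- min(max(raw, 0), 1)
  se <- NA_real_
  if (!is.null(n)) {
    stopifnot(n >= 1)
    se <- sqrt(p_adm * (1 - p_adm) / (2 * n)) / m_nam
  }
  structure(list(estimate = est, raw = raw, se = se, clamped = clamped,
                 proportions = c(nam = m_nam, eur = m_eur, afr = m_afr)),
            class = "parental_freq_estimate")
}

#' @export
print.parental_freq_estimate <- function(x, ...) {
  cat(sprintf("extrapolated NAM parental frequency: %.4f", x$estimate))
  if (!is.na(x$se)) cat(sprintf(" (SE %.4f)", x$se))
  if (x$clamped) cat(sprintf(" [clamped from %.4f]", x$raw))
  cat("\n")
  invisible(x)
}

#' Ancestry-stratified allele frequency (cross-check estimator)
#'
#' Direct estimate of the NAM parental frequency from individuals carrying
#' two NAM copies at the marker: their coded-allele dosage is an unbiased
#' draw from the NAM parental population. Plays the validating role of
#' direct genotyping in reference samples.
#'
#' @param genotypes a `dosage_matrix`.
#' @param ancestry the matching `ancestry_matrix`.
#' @param marker marker id or column index.
#' @return list with `estimate`, `se` (binomial), `n_homozygous`.
#' @export
ancestry_stratified_frequency <- function(genotypes, ancestry, marker) {
  stopifnot(inherits(genotypes, "dosage_matrix"), inherits(ancestry, "ancestry_matrix"))
  j <- if (is.character(marker)) match(marker, genotypes$map$marker) else as.integer(marker)
  if (is.na(j) || j < 1 || j > ncol(genotypes$dosage)) {
    stop("marker not found", call. = FALSE)
  }
  hom <- ancestry$nam[, j] == 2L
  n_hom <- sum(hom)
  if (n_hom < 1) stop("no NAM-homozygous individuals at this marker", call. = FALSE)
  p <- mean(genotypes$dosage[hom, j]) / 2
  list(estimate = p,
       se = sqrt(p * (1 - p) / (2 * n_hom)),
       n_homozygous = n_hom)
}
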