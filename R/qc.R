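# Marker quality control: minor allele frequency, exact Hardy-Weinberg
# test in controls, per-group missingness, and strand-ambiguous (A/T, C/G)
# filters.

#' QC thresholds
#'
#' @param maf_min minor-allele-frequency floor (markers below are removed);
#'   NULL disables.
#' @param hwe_p_min Hardy-Weinberg p-value floor, evaluated in controls
#'   (default 1e-4; a second-array preset would use 0.01); NULL disables.
#' @param missing_max per-group missingness ceiling; NULL disables.
#' @param drop_ambiguous drop A/T and C/G strand-ambiguous markers.
#' @param hwe_test `"exact"` (default) or `"chisq"`.
#' @return list of class `qc_config`.
#' @export
qc_config <- function(maf_min = 0.01, hwe_p_min = 1e-4, missing_max = 0.05,
                      drop_ambiguous = TRUE, hwe_test = c("exact", "chisq")) {
  hwe_test <- match.arg(hwe_test)
  for (th in list(maf_min, hwe_p_min, missing_max)) {
    if (!is.null(th) && (th <= 0 || th >= 1)) {
      stop("QC thresholds must lie in (0, 1)", call. = FALSE)
    }
  }
  structure(list(maf_min = maf_min, hwe_p_min = hwe_p_min,
                 missing_max = missing_max, drop_ambiguous = drop_ambiguous,
                 hwe_test = hwe_test),
            class = "qc_config")
}

#' Exact Hardy-Weinberg equilibrium test
#'
#' Two-sided exact test: the p-value is the total probability, under the
#' conditional distribution of heterozygote counts given allele counts, of
#' outcomes no more probable than the observed one (no mid-p correction).
#'
#' @param n_het observed heterozygote count.
#' @param n_hom1,n_hom2 observed homozygote counts.
#' @return p-value in (0, 1].
#' @export
hwe_exact_p <- function(n_het, n_hom1, n_hom2) {
  stopifnot(n_het >= 0, n_hom1 >= 0, n_hom2 >= 0)
  n <- n_het + n_hom1 + n_hom2
  if (n == 0) return(1)
  n_rare <- 2 * min(n_hom1, n_hom2) + n_het
  # heterozygote counts share the parity of the rare allele count
  hets <- seq(n_rare %% 2, min(n_rare, 2 * n - n_rare), by = 2)
  logp <- numeric(length(hets))
  for (i in seq_along(hets)) {
    h <- hets[i]
    r_hom <- (n_rare - h) / 2
    c_hom <- n - h - r_hom
    logp[i] <- h * log(2) + lfactorial(n) -
      lfactorial(h) - lfactorial(r_hom) - lfactorial(c_hom) -
      (lfactorial(2 * n) - lfactorial(n_rare) - lfactorial(2 * n - n_rare))
  }
  p <- exp(logp - logsumexp(logp)) # renormalize to guard rounding
  obs <- match(n_het, hets)
  min(sum(p[p <= p[obs] * (1 + 1e-9)]), 1)
}

hwe_chisq_p <- function(n_het, n_hom1, n_hom2) {
  n <- n_het + n_hom1 + n_hom2
  if (n == 0) return(1)
  p <- (2 * n_hom1 + n_het) / (2 * n)
  e <- n * c(p^2, 2 * p * (1 - p), (1 - p)^2)
  o <- c(n_hom1, n_het, n_hom2)
  if (any(e == 0)) return(1)
  stats::pchisq(sum((o - e)^2 / e), df = 1, lower.tail = FALSE)
}

is_strand_ambiguous <- function(coded, other) {
  pair <- paste0(pmin(coded, other), pmax(coded, other))
  pair %in% c("AT", "CG")
}

#' Filter markers by QC rules
#'
#' Applies the enabled rules of a [qc_config()] to hard-call genotypes and
#' returns the surviving markers plus a per-marker pass/fail report (the
#' report fully determines the surviving set). HWE is evaluated in the
#' control group; missingness separately in cases and controls.
#'
#' @param dosages a `dosage_matrix` of hard calls (0/1/2, NA allowed).
#' @param groups vector of "case"/"control" labels (or 0 = control,
#'   1 = case), required when the HWE or missingness rule is enabled.
#' @param config a [qc_config()].
#' @return list with elements `dosages` (filtered `dosage_matrix`) and
#'   `report` (data.frame: marker, maf, maf_pass, hwe_p, hwe_pass,
#'   miss_case, miss_control, miss_pass, ambiguous, ambig_pass, pass).
#' @export
qc_filter_markers <- function(dosages, groups = NULL, config = qc_config()) {
  stopifnot(inherits(dosages, "dosage_matrix"), inherits(config, "qc_config"))
  X <- dosages$dosage
  hard <- X[!is.na(X)]
  if (!all(hard %in% 0:2)) {
    stop("QC requires hard-call genotypes (0/1/2)", call. = FALSE)
  }
  m <- ncol(X)
  need_groups <- !is.null(config$hwe_p_min) || !is.null(config$missing_max)
  if (need_groups) {
    if (is.null(groups)) {
      stop("case/control group labels required for HWE/missingness rules",
           call. = FALSE)
    }
    if (is.numeric(groups)) groups <- ifelse(groups == 1, "case", "control")
    if (!all(groups %in% c("case", "control"))) {
      stop("groups must be 'case'/'control' (or 1/0)", call. = FALSE)
    }
    is_control <- groups == "control"
  }

  af <- colMeans(X, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  maf_pass <- if (is.null(config$maf_min)) rep(TRUE, m) else maf >= config$maf_min

  hwe_p <- rep(NA_real_, m)
  hwe_pass <- rep(TRUE, m)
  if (!is.null(config$hwe_p_min)) {
    ctrl <- X[is_control, , drop = FALSE]
    f <- if (config$hwe_test == "exact") hwe_exact_p else hwe_chisq_p
    for (j in seq_len(m)) {
      g <- ctrl[, j]
      g <- g[!is.na(g)]
      hwe_p[j] <- f(sum(g == 1), sum(g == 2), sum(g == 0))
    }
    hwe_pass <- hwe_p >= config$hwe_p_min
  }

  miss_case <- miss_control <- rep(NA_real_, m)
  miss_pass <- rep(TRUE, m)
  if (!is.null(config$missing_max)) {
    miss_case <- colMeans(is.na(X[!is_control, , drop = FALSE]))
    miss_control <- colMeans(is.na(X[is_control, , drop = FALSE]))
    miss_pass <- miss_case <= config$missing_max & miss_control <= config$missing_max
  }

  ambiguous <- rep(FALSE, m)
  ambig_pass <- rep(TRUE, m)
  if (isTRUE(config$drop_ambiguous) &&
      all(c("coded", "other") %in% names(dosages$map))) {
    ambiguous <- is_strand_ambiguous(dosages$map$coded, dosages$map$other)
    ambig_pass <- !ambiguous
  }

  pass <- maf_pass & hwe_pass & miss_pass & ambig_pass
  report <- data.frame(marker = dosages$map$marker,
                       maf = maf, maf_pass = maf_pass,
                       hwe_p = hwe_p, hwe_pass = hwe_pass,
                       miss_case = miss_case, miss_control = miss_control,
                       miss_pass = miss_pass,
                       ambiguous = ambiguous, ambig_pass = ambig_pass,
                       pass = pass, stringsAsFactors = FALSE)
  filtered <- new_dosage_matrix(X[, pass, drop = FALSE],
                                dosages$map[pass, , drop = FALSE],
                                dosages$ids)
  list(dosages = filtered, report = report)
}
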