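# Phenotype preparation: medication adjustment, covariate residualization
# and the Blom rank-based inverse-normal transform.

#' Shipped medication adjustment rules
#'
#' Default per-trait rules for undoing the effect of lipid-lowering
#' medication on measured concentrations. Treatment is assumed to scale the
#' measurement down, so the adjustment multiplies it back up (the widely
#' used divide-by-factor convention: total cholesterol /0.8, LDL-C /0.7,
#' triglycerides /0.85, HDL-C unchanged). These constants are package
#' defaults, configurable per run, and recorded in the run config.
#'
#' @param traits which traits to return rules for.
#' @return named list of rules, each `list(type, value)` with type
#'   "additive" (value added to treated measurements) or "multiplicative"
#'   (treated measurements multiplied by value).
#' @export
default_medication_rules <- function(traits = c("tg", "tc", "ldl", "hdl")) {
  all <- list(
    tg  = list(type = "multiplicative", value = 1 / 0.85),
    tc  = list(type = "multiplicative", value = 1 / 0.80),
    ldl = list(type = "multiplicative", value = 1 / 0.70),
    hdl = list(type = "multiplicative", value = 1)
  )
  unknown <- setdiff(traits, names(all))
  if (length(unknown)) stop("no default rule for trait(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  all[traits]
}

#' Adjust measured lipid values for lipid-lowering medication
#'
#' For each trait named in `rules`, treated individuals (flag column
#' `<trait>_med` equal to 1) have their measured value replaced by the rule
#' output; untreated values are unchanged. Missing flags are treated as
#' untreated, with a warning reporting the count. A provenance column
#' `<trait>_adj_rule` records which rule fired.
#'
#' @param table a phenotype data.frame with trait and `<trait>_med` columns.
#' @param rules named list of per-trait rules, see
#'   [default_medication_rules()].
#' @return the table with adjusted trait columns and provenance columns.
#' @export
adjust_for_medication <- function(table, rules = default_medication_rules("tg")) {
  stopifnot(is.data.frame(table), is.list(rules), length(rules) >= 1)
  for (trait in names(rules)) {
    if (!trait %in% names(table)) {
      stop(sprintf("unknown trait '%s' in adjustment config", trait), call. = FALSE)
    }
    rule <- rules[[trait]]
    if (!rule$type %in% c("additive", "multiplicative")) {
      stop("rule type must be 'additive' or 'multiplicative'", call. = FALSE)
    }
    flag_col <- paste0(trait, "_med")
    flag <- if (flag_col %in% names(table)) table[[flag_col]] else rep(NA, nrow(table))
    n_missing <- sum(is.na(flag))
    if (n_missing > 0) {
      warning(sprintf("%d individuals with missing %s flag treated as untreated",
                      n_missing, flag_col), call. = FALSE)
      flag[is.na(flag)] <- 0L
    }
    treated <- flag == 1L
    x <- table[[trait]]
    adj <- x
    adj[treated] <- switch(rule$type,
                           additive = x[treated] + rule$value,
                           multiplicative = x[treated] * rule$value)
    if (any(adj < 0, na.rm = TRUE)) {
      stop(sprintf("medication adjustment produced negative %s concentrations", trait),
           call. = FALSE)
    }
    table[[trait]] <- adj
    table[[paste0(trait, "_adj_rule")]] <-
      ifelse(treated, sprintf("%s_%g", rule$type, rule$value), "none")
  }
  table
}

#' Residualize a trait on covariates by ordinary least squares
#'
#' Fits `trait ~ intercept + covariates` on complete cases and stores the
#' residuals in `<trait>_resid` (NA for individuals excluded for
#' missingness). Zero-variance covariates are dropped with a message;
#' remaining rank deficiency is an error naming the collinear columns.
#'
#' @param table phenotype data.frame.
#' @param trait trait column name (typically medication-adjusted).
#' @param covariates character vector of covariate column names.
#' @return the table with a `<trait>_resid` column; the number of excluded
#'   individuals is attached as attribute `"n_excluded"`.
#' @export
residualize_covariates <- function(table, trait,
                                   covariates = c("sex", "age", "age2", "bmi")) {
  stopifnot(is.data.frame(table), trait %in% names(table))
  missing_cov <- setdiff(covariates, names(table))
  if (length(missing_cov)) {
    stop("covariate(s) absent from table: ", paste(missing_cov, collapse = ", "),
         call. = FALSE)
  }
  X <- as.matrix(table[covariates])
  storage.mode(X) <- "double"
  y <- as.numeric(table[[trait]])
  complete <- stats::complete.cases(cbind(y, X))
  n_excluded <- sum(!complete)
  if (n_excluded > 0) {
    message(sprintf("residualize_covariates: %d individuals excluded for missingness",
                    n_excluded))
  }
  Xc <- X[complete, , drop = FALSE]
  constant <- apply(Xc, 2, function(v) stats::var(v) < 1e-12)
  if (any(constant)) {
    message("dropping zero-variance covariate(s): ",
            paste(covariates[constant], collapse = ", "))
    Xc <- Xc[, !constant, drop = FALSE]
  }
  if (sum(complete) < ncol(Xc) + 2) {
    stop("too few complete cases to residualize", call. = FALSE)
  }
  M <- cbind(`(Intercept)` = 1, Xc)
  qrm <- qr(M)
  if (qrm$rank < ncol(M)) {
    bad <- colnames(M)[qrm$pivot[seq.int(qrm$rank + 1L, ncol(M))]]
    stop("rank-deficient covariate matrix; collinear column(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  res <- rep(NA_real_, nrow(table))
  res[complete] <- qr.resid(qrm, y[complete])
  table[[paste0(trait, "_resid")]] <- res
  attr(table, "n_excluded") <- n_excluded
  table
}

#' Blom rank-based inverse-normal transform
#'
#' Maps the value with rank r of n non-missing values to the standard
#' normal quantile at (r - 3/8)/(n + 1/4); ties receive the average of
#' their ranks before mapping, and missing values stay missing.
#'
#' @param values numeric vector, possibly with NAs.
#' @return numeric vector of the same length.
#' @export
blom_transform <- function(values) {
  ok <- !is.na(values)
  n <- sum(ok)
  if (n < 2) stop("need at least 2 non-missing values", call. = FALSE)
  if (diff(range(values[ok])) == 0) {
    stop("all values identical: Blom transform undefined", call. = FALSE)
  }
  r <- rank(values, na.last = "keep", ties.method = "average")
  stats::qnorm((r - 3 / 8) / (n + 1 / 4))
}

#' Run the full phenotype preparation pipeline for one trait
#'
#' Medication adjustment, covariate residualization and Blom transform in
#' sequence; the transformed residual lands in `<trait>_blom`.
#'
#' @inheritParams residualize_covariates
#' @param rules medication rules, or NULL to skip adjustment.
#' @return the table with `<trait>_resid` and `<trait>_blom` columns.
#' @export
prepare_trait <- function(table, trait = "tg",
                          covariates = c("sex", "age", "age2", "bmi"),
                          rules = default_medication_rules(trait)) {
  if (!is.null(rules)) table <- adjust_for_medication(table, rules)
  table <- residualize_covariates(table, trait, covariates)
  resid_col <- paste0(trait, "_resid")
  table[[paste0(trait, "_blom")]] <- blom_transform(table[[resid_col]])
  table
}
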