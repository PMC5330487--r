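# Wakefield approximate Bayes factors and 99% credible sets from regional
# summary statistics. All Bayes-factor arithmetic is done in log space and
# exponentiated only on output, so regions with |z| up to 40 and beyond
# normalize exactly.

LAMBDA_CAP <- 1e300

#' Wakefield approximate Bayes factor
#'
#' Evidence that a variant drives an association signal, computed from its
#' estimated allelic effect beta, the variance of the estimate V (squared
#' standard error) and the prior variance of allelic effects omega:
#'
#' `Lambda = sqrt(V / (V + omega)) * exp(omega * beta^2 / (2 V (V + omega)))`
#'
#' The `as_printed` form replaces the square-root prefactor by
#' `V / (V + omega)`; with equal V across variants the two forms give
#' identical rankings and credible sets.
#'
#' @param beta numeric vector of allelic effects.
#' @param variance numeric vector of effect variances (SE^2), > 0.
#' @param omega prior variance of allelic effects, > 0 (default 0.04).
#' @param form `"sqrt"` (default) or `"as_printed"`.
#' @param log if TRUE return log(Lambda) (never overflows); otherwise
#'   Lambda is capped at 1e300.
#' @return numeric vector of (log) approximate Bayes factors.
#' @export
approximate_bayes_factor <- function(beta, variance, omega = 0.04,
                                     form = c("sqrt", "as_printed"),
                                     log = FALSE) {
  form <- match.arg(form)
  if (any(!is.finite(variance)) || any(variance <= 0)) {
    stop("variance must be positive", call. = FALSE)
  }
  if (any(!is.finite(omega)) || any(omega <= 0)) stop("omega must be positive", call. = FALSE)
  pre <- base::log(variance / (variance + omega))
  if (form == "sqrt") pre <- pre / 2
  loglam <- pre + omega * beta^2 / (2 * variance * (variance + omega))
  if (log) loglam else pmin(exp(loglam), LAMBDA_CAP)
}

#' Credible set of variants for one association signal
#'
#' Computes each variant's approximate Bayes factor, normalizes them into
#' posterior probabilities of driving the signal (log-sum-exp), ranks the
#' variants by Bayes factor (ties broken by variant id), and returns the
#' minimal prefix whose cumulative posterior strictly exceeds `mass`.
#'
#' @param stats a `summary_stats`-style data.frame with columns `variant`,
#'   `beta`, `se` (all from one fine-mapping region).
#' @param omega prior variance of allelic effects (default 0.04).
#' @param mass credible mass threshold (default 0.99).
#' @param abf_form Bayes-factor form, see [approximate_bayes_factor()].
#' @return list of class `credible_set`: `table` (ranked data.frame with
#'   log_lambda, lambda, posterior, cumulative, in_credible_set),
#'   `members` (variant ids in the set), `mass`, `omega`, `abf_form`.
#' @export
credible_set <- function(stats, omega = 0.04, mass = 0.99,
                         abf_form = c("sqrt", "as_printed")) {
  abf_form <- match.arg(abf_form)
  stopifnot(is.data.frame(stats),
            all(c("variant", "beta", "se") %in% names(stats)))
  stats <- stats[!is.na(stats$beta) & !is.na(stats$se), , drop = FALSE]
  if (nrow(stats) < 1) stop("empty fine-mapping region", call. = FALSE)
  if (mass <= 0 || mass >= 1) stop("mass must be in (0, 1)", call. = FALSE)
  loglam <- approximate_bayes_factor(stats$beta, stats$se^2, omega = omega,
                                     form = abf_form, log = TRUE)
  ord <- order(-loglam, stats$variant)
  loglam <- loglam[ord]
  stats <- stats[ord, , drop = FALSE]
  post <- exp(loglam - logsumexp(loglam))
  cum <- cumsum(post)
  k <- match(TRUE, cum > mass)
  if (is.na(k)) k <- length(cum) # floating-point shortfall: take everything
  tab <- data.frame(variant = stats$variant,
                    beta = stats$beta, se = stats$se,
                    log_lambda = loglam,
                    lambda = pmin(exp(loglam), LAMBDA_CAP),
                    posterior = post,
                    cumulative = cum,
                    in_credible_set = seq_along(cum) <= k,
                    stringsAsFactors = FALSE)
  structure(list(table = tab,
                 members = tab$variant[tab$in_credible_set],
                 mass = mass, omega = omega, abf_form = abf_form),
            class = "credible_set")
}

#' @export
print.credible_set <- function(x, ...) {
  cat(sprintf("%g%% credible set (omega = %g, %s ABF form): %d of %d variants\n",
              100 * x$mass, x$omega, x$abf_form,
              length(x$members), nrow(x$table)))
  cat("  members:", paste(utils::head(x$members, 10), collapse = ", "),
      if (length(x$members) > 10) "..." else "", "\n")
  invisible(x)
}
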