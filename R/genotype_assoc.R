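# Additive genotype-dosage association and inverse-variance fixed-effects
# meta-analysis of per-variant summary statistics.

#' Additive dosage association scan
#'
#' Per-marker OLS of the transformed trait on intercept + coded-allele
#' dosage (+ optional covariates). Real-valued dosages in [0, 2] are
#' accepted, approximating the score test on expected dosages. Monomorphic
#' or all-missing markers are flagged and receive no estimate.
#'
#' @param dosages a `dosage_matrix`.
#' @param phenotype numeric transformed-residual vector aligned with rows.
#' @param covariates optional numeric matrix/data.frame of covariates.
#' @param cohort cohort label stored in the output.
#' @return data.frame of class `summary_stats` with columns variant, chrom,
#'   pos_bp, coded, other, freq, beta, se, t, p, n, cohort, flag. A perfect
#'   (zero-residual) fit reports p at the double floor with flag
#'   `perfect_fit`.
#' @export
snp_association_scan <- function(dosages, phenotype, covariates = NULL,
                                 cohort = "cohort1") {
  stopifnot(inherits(dosages, "dosage_matrix"))
  X <- dosages$dosage
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (length(phenotype) != n) stop("phenotype length must match individuals", call. = FALSE)
  C <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (!is.null(covariates)) {
    cm <- as.matrix(covariates)
    storage.mode(cm) <- "double"
    if (nrow(cm) != n) stop("covariates dimension mismatch", call. = FALSE)
    C <- cbind(C, cm)
  }
  base_complete <- stats::complete.cases(cbind(phenotype, C))
  if (sum(base_complete) < 10) stop("need at least 10 complete cases", call. = FALSE)

  m <- ncol(X)
  beta <- se <- tstat <- p <- freq <- rep(NA_real_, m)
  nn <- integer(m)
  flag <- rep("ok", m)
  p_floor <- .Machine$double.xmin

  fit_block <- function(cols, rows) {
    # shared complete-case fit for markers with no missing dosages
    y <- phenotype[rows]
    qrc <- qr(C[rows, , drop = FALSE])
    df <- sum(rows) - qrc$rank - 1L
    Xr <- qr.resid(qrc, X[rows, cols, drop = FALSE])
    yr <- qr.resid(qrc, y)
    sxx <- colSums(Xr^2)
    yy <- sum(yr^2)
    poly <- sxx > VAR_EPS * sum(rows)
    v <- crossprod(Xr, yr)[, 1]
    b <- v / sxx
    sse <- pmax(yy - v^2 / sxx, 0)
    s <- sqrt(sse / df / sxx)
    list(cols = cols, beta = b, se = s, df = df, poly = poly, n = sum(rows))
  }

  has_na <- colSums(is.na(X[base_complete, , drop = FALSE])) > 0
  groups <- list()
  if (any(!has_na)) groups <- c(groups, list(which(!has_na)))
  for (j in which(has_na)) groups <- c(groups, list(j))

  for (g in groups) {
    rows <- base_complete & rowSums(is.na(X[, g, drop = FALSE])) == 0
    if (length(g) == 1L && sum(rows) == 0) {
      flag[g] <- "all_missing"
      next
    }
    if (sum(rows) < 10) {
      flag[g] <- "too_few_cases"
      next
    }
    fb <- fit_block(g, rows)
    nn[g] <- fb$n
    freq[g] <- colMeans(X[rows, g, drop = FALSE]) / 2
    mono <- col_vars(X[rows, g, drop = FALSE]) <= VAR_EPS
    for (k in seq_along(g)) {
      j <- g[k]
      if (mono[k] || !fb$poly[k]) {
        flag[j] <- "monomorphic"
        next
      }
      beta[j] <- fb$beta[k]
      se[j] <- fb$se[k]
      if (fb$se[k] > 0) {
        tstat[j] <- fb$beta[k] / fb$se[k]
        p[j] <- max(2 * stats::pt(-abs(tstat[j]), fb$df), p_floor)
      } else {
        tstat[j] <- sign(fb$beta[k]) * Inf
        p[j] <- p_floor
        flag[j] <- "perfect_fit"
      }
    }
  }

  map <- dosages$map
  out <- data.frame(variant = map$marker, chrom = map$chrom, pos_bp = map$pos_bp,
                    coded = map$coded %||% rep("G", m),
                    other = map$other %||% rep("C", m),
                    freq = freq, beta = beta, se = se, t = tstat, p = p,
                    n = nn, cohort = cohort, flag = flag,
                    stringsAsFactors = FALSE)
  class(out) <- c("summary_stats", "data.frame")
  out
}

#' Inverse-variance fixed-effects meta-analysis
#'
#' Combines per-cohort summary statistics aligned on variant id. Effects
#' are harmonized to the coded/other alleles of the first cohort carrying
#' each variant: a coded/other swap flips the sign of beta (and the
#' frequency); any other allele mismatch drops the variant with a warning.
#' Weights are 1/SE^2; the meta p-value is two-sided normal.
#'
#' @param stats list of `summary_stats` data.frames (or a single one).
#' @return `summary_stats` data.frame with cohort "meta" and additional
#'   Cochran heterogeneity columns q, q_df, q_p (descriptive).
#' @export
inverse_variance_meta <- function(stats) {
  if (is.data.frame(stats)) stats <- list(stats)
  stopifnot(length(stats) >= 1)
  usable <- lapply(stats, function(s) s[!is.na(s$beta) & !is.na(s$se), , drop = FALSE])
  for (s in usable) {
    if (any(s$se <= 0)) stop("standard errors must be > 0", call. = FALSE)
  }
  all_ids <- unique(unlist(lapply(usable, `[[`, "variant")))
  rows <- vector("list", length(all_ids))
  dropped <- character(0)
  for (i in seq_along(all_ids)) {
    v <- all_ids[i]
    per <- lapply(usable, function(s) s[s$variant == v, , drop = FALSE])
    per <- per[vapply(per, nrow, 1L) > 0]
    ref <- per[[1]]
    betas <- ses <- freqs <- ns <- numeric(0)
    bad <- FALSE
    for (s in per) {
      if (s$coded == ref$coded && s$other == ref$other) {
        b <- s$beta; f <- s$freq
      } else if (s$coded == ref$other && s$other == ref$coded) {
        b <- -s$beta; f <- 1 - s$freq
      } else {
        bad <- TRUE
        break
      }
      betas <- c(betas, b); ses <- c(ses, s$se)
      freqs <- c(freqs, f); ns <- c(ns, s$n)
    }
    if (bad) {
      dropped <- c(dropped, v)
      next
    }
    w <- 1 / ses^2
    bm <- sum(w * betas) / sum(w)
    sem <- 1 / sqrt(sum(w))
    z <- bm / sem
    q <- sum(w * (betas - bm)^2)
    q_df <- length(betas) - 1L
    rows[[i]] <- data.frame(
      variant = v, chrom = ref$chrom, pos_bp = ref$pos_bp,
      coded = ref$coded, other = ref$other,
      freq = sum(freqs * ns) / sum(ns),
      beta = bm, se = sem, t = z, p = 2 * stats::pnorm(-abs(z)),
      n = sum(ns), cohort = "meta", flag = "ok",
      q = q, q_df = q_df,
      q_p = if (q_df > 0) stats::pchisq(q, q_df, lower.tail = FALSE) else NA_real_,
      stringsAsFactors = FALSE)
  }
  if (length(dropped)) {
    warning("variant(s) dropped for unharmonizable alleles: ",
            paste(dropped, collapse = ", "), call. = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, TRUE)]
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(variant = character(0), chrom = character(0),
               pos_bp = integer(0), coded = character(0),
               other = character(0), freq = numeric(0), beta = numeric(0),
               se = numeric(0), t = numeric(0), p = numeric(0),
               n = numeric(0), cohort = character(0), flag = character(0),
               q = numeric(0), q_df = integer(0), q_p = numeric(0),
               stringsAsFactors = FALSE)
  class(out) <- c("summary_stats", "data.frame")
  out
}
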