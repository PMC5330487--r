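# Admixture mapping scan: per-marker OLS of the transformed trait on NAM
# locus-ancestry dosage with global-ancestry and diabetes covariates, plus
# Max(T) label-swapping permutation FWER control and conditional scans.
#
# The per-marker fits share one covariate block, so the scan residualizes
# the phenotype and every ancestry column on the covariates once
# (Frisch-Waugh-Lovell) and computes all slopes, standard errors and t
# statistics by vectorized cross-products. The permutation pass reuses the
# same machinery on whole permuted phenotype vectors, exactly reproducing
# per-permutation full-model t statistics.

VAR_EPS <- 1e-12

#' Per-marker local-ancestry association scan with optional Max(T) permutations
#'
#' For each marker, fits `phenotype ~ intercept + NAM copies + global NAM +
#' global AFR + diabetes [+ conditioning dosages]` by OLS and reports the
#' ancestry-dosage coefficient, its standard error, the t statistic and the
#' two-sided asymptotic p-value. With `permutations = B >= 1`, the
#' phenotype vector is permuted as whole labels against the joint regressor
#' rows B times; the maximum |t| over testable markers is recorded per
#' permutation, and each marker's empirical family-wise p-value is
#' `(1 + #{max |t| >= |t_j|}) / (B + 1)`.
#'
#' Markers whose NAM dosage is (near-)constant are skipped with flag
#' `constant_ancestry`; markers collinear with the covariate block
#' (e.g. with a conditioning dosage) are skipped with flag `collinear`.
#' Conditioning columns with zero variance are dropped, so conditioning on
#' an all-zero column reproduces the unconditional scan exactly.
#'
#' @param ancestry an `ancestry_matrix` of NAM copy counts.
#' @param phenotype numeric vector of transformed trait residuals, aligned
#'   with ancestry rows; NAs are excluded (complete-case).
#' @param globals global ancestry data.frame as from [global_ancestry()],
#'   or NULL to derive it from `ancestry`.
#' @param diabetes optional 0/1 vector.
#' @param condition_on optional numeric matrix (or vector) of conditioning
#'   genotype dosages, one column per conditioning marker.
#' @param permutations number of Max(T) permutations B (0 = asymptotic only).
#' @param seed integer seed for the permutation stream; required when
#'   `permutations > 0`.
#' @param perm_block permutations are processed in blocks of this size to
#'   bound memory.
#' @return a data.frame of class `scan_result` with columns marker, chrom,
#'   pos_bp, beta, se, t, p_asymptotic, p_empirical, n_used, flag, and
#'   attributes `permutations`, `seed`, `covariates`, `df`.
#' @export
ancestry_scan <- function(ancestry, phenotype, globals = NULL, diabetes = NULL,
                          condition_on = NULL, permutations = 0, seed = NULL,
                          perm_block = 1000L) {
  stopifnot(inherits(ancestry, "ancestry_matrix"))
  X <- ancestry$nam
  storage.mode(X) <- "double"
  n <- nrow(X)
  if (length(phenotype) != n) stop("phenotype length must match individuals", call. = FALSE)
  if (!is.null(diabetes) && length(diabetes) != n) {
    stop("diabetes length must match individuals", call. = FALSE)
  }
  if (is.null(globals)) globals <- global_ancestry(ancestry)
  if (nrow(globals) != n) stop("globals dimension mismatch", call. = FALSE)

  C <- cbind(`(Intercept)` = rep(1, n), g_nam = globals$nam, g_afr = globals$afr)
  if (!is.null(diabetes)) C <- cbind(C, diabetes = as.numeric(diabetes))
  cond_names <- character(0)
  if (!is.null(condition_on)) {
    condm <- as.matrix(condition_on)
    storage.mode(condm) <- "double"
    if (nrow(condm) != n) stop("condition_on dimension mismatch", call. = FALSE)
    if (is.null(colnames(condm))) colnames(condm) <- paste0("cond", seq_len(ncol(condm)))
    keep <- col_vars(condm) > VAR_EPS
    keep[is.na(keep)] <- FALSE
    condm <- condm[, keep, drop = FALSE]
    cond_names <- colnames(condm)
    if (ncol(condm)) C <- cbind(C, condm)
  }

  complete <- stats::complete.cases(cbind(phenotype, C))
  y <- phenotype[complete]
  Cc <- C[complete, , drop = FALSE]
  Xc <- X[complete, , drop = FALSE]
  n_used <- length(y)

  # drop constant covariates (other than the intercept) to keep full rank
  cov_keep <- c(TRUE, col_vars(Cc[, -1, drop = FALSE]) > VAR_EPS)
  cov_keep[is.na(cov_keep)] <- FALSE
  Cc <- Cc[, cov_keep, drop = FALSE]
  qrc <- qr(Cc)
  if (qrc$rank < ncol(Cc)) {
    bad <- colnames(Cc)[qrc$pivot[seq.int(qrc$rank + 1L, ncol(Cc))]]
    stop("collinear covariates in scan: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  df <- n_used - ncol(Cc) - 1L
  if (df < 2) stop("too few complete cases for the scan", call. = FALSE)

  m <- ncol(X)
  flag <- rep("ok", m)
  flag[col_vars(Xc) <= VAR_EPS] <- "constant_ancestry"

  Xr <- qr.resid(qrc, Xc)
  sxx <- colSums(Xr^2)
  flag[flag == "ok" & sxx <= VAR_EPS * n_used] <- "collinear"
  ok <- flag == "ok"

  yr <- qr.resid(qrc, y)
  yy <- sum(yr^2)
  beta <- se <- tstat <- p_asym <- rep(NA_real_, m)
  if (yy <= VAR_EPS * n_used) {
    # degenerate phenotype: no signal possible
    beta[ok] <- 0
    tstat[ok] <- 0
    p_asym[ok] <- 1
    flag[ok] <- "constant_phenotype"
    ok <- rep(FALSE, m)
  } else if (any(ok)) {
    v <- crossprod(Xr[, ok, drop = FALSE], yr)[, 1]
    b <- v / sxx[ok]
    sse <- pmax(yy - v^2 / sxx[ok], 0)
    s <- sqrt(sse / df / sxx[ok])
    beta[ok] <- b
    se[ok] <- s
    tstat[ok] <- ifelse(s > 0, b / s, sign(b) * Inf)
    p_asym[ok] <- 2 * stats::pt(-abs(tstat[ok]), df)
  }

  p_emp <- rep(NA_real_, m)
  B <- as.integer(permutations)
  if (B >= 1 && any(ok)) {
    if (is.null(seed)) stop("seed required for permutation testing", call. = FALSE)
    set.seed(stream_seed(seed, "permutations"))
    Xok <- Xr[, ok, drop = FALSE]
    sxx_ok <- sxx[ok]
    maxt <- numeric(B)
    done <- 0L
    while (done < B) {
      nb <- min(perm_block, B - done)
      P <- matrix(0, n_used, nb)
      for (b in seq_len(nb)) P[, b] <- y[sample.int(n_used)]
      Pr <- qr.resid(qrc, P)
      yyp <- colSums(Pr^2)
      V <- crossprod(Xok, Pr)                 # m_ok x nb
      T2 <- V^2 / sxx_ok                      # recycles sxx_ok down columns
      SSE <- pmax(sweep(-T2, 2, yyp, `+`), 0) # yyp - V^2/sxx
      Tm <- abs(V) / sqrt(SSE * sxx_ok / df)
      Tm[!is.finite(Tm)] <- Inf
      maxt[done + seq_len(nb)] <- apply(Tm, 2, max)
      done <- done + nb
    }
    geq <- vapply(abs(tstat[ok]), function(tj) sum(maxt >= tj), numeric(1))
    p_emp[ok] <- (1 + geq) / (B + 1)
  }

  out <- data.frame(marker = ancestry$map$marker,
                    chrom = ancestry$map$chrom,
                    pos_bp = ancestry$map$pos_bp,
                    beta = beta, se = se, t = tstat,
                    p_asymptotic = p_asym, p_empirical = p_emp,
                    n_used = n_used, flag = flag,
                    stringsAsFactors = FALSE)
  attr(out, "permutations") <- B
  attr(out, "seed") <- seed
  attr(out, "covariates") <- colnames(Cc)
  attr(out, "condition_on") <- cond_names
  attr(out, "df") <- df
  class(out) <- c("scan_result", "data.frame")
  out
}

#' Max(T) permutation scan
#'
#' Convenience wrapper around [ancestry_scan()] that requires a positive
#' permutation count and returns empirical family-wise p-values.
#'
#' @inheritParams ancestry_scan
#' @param B number of permutations (>= 1).
#' @export
maxt_permutation <- function(ancestry, phenotype, globals = NULL, diabetes = NULL,
                             condition_on = NULL, B = 10000, seed = 1) {
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  ancestry_scan(ancestry, phenotype, globals = globals, diabetes = diabetes,
                condition_on = condition_on, permutations = B, seed = seed)
}
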