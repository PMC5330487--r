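# Shared fixtures and independent oracles used across test files.

# closed-form OLS via the normal equations, independent of the scan code path
ols_oracle <- function(y, x, covars = NULL) {
  M <- cbind(1, covars, x)
  XtX <- t(M) %*% M
  b <- solve(XtX, t(M) %*% y)
  res <- y - M %*% b
  df <- length(y) - ncol(M)
  sigma2 <- sum(res^2) / df
  covb <- sigma2 * solve(XtX)
  k <- ncol(M)
  list(beta = b[k], se = sqrt(covb[k, k]), df = df,
       t = b[k] / sqrt(covb[k, k]))
}

# build an ancestry_matrix directly from a NAM copy-count matrix
make_ancestry <- function(nam, chrom = "11") {
  nam <- as.matrix(nam)
  storage.mode(nam) <- "integer"
  ids <- sprintf("id%05d", seq_len(nrow(nam)))
  map <- data.frame(marker = sprintf("mk%05d", seq_len(ncol(nam))),
                    chrom = chrom,
                    pos_bp = as.integer(seq_len(ncol(nam)) * 1e5),
                    stringsAsFactors = FALSE)
  admixscan:::new_ancestry_matrix(nam, map, ids)
}

# build a dosage_matrix from a plain matrix
make_dosages <- function(x, coded = "G", other = "C") {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  ids <- sprintf("id%05d", seq_len(nrow(x)))
  map <- data.frame(marker = sprintf("mk%05d", seq_len(ncol(x))),
                    chrom = "11",
                    pos_bp = as.integer(seq_len(ncol(x)) * 1e5),
                    coded = coded, other = other,
                    stringsAsFactors = FALSE)
  admixscan:::new_dosage_matrix(x, map, ids)
}

# summary_stats row builder for fine-mapping / meta tests
make_stats <- function(variant, beta, se, coded = "G", other = "C",
                       freq = 0.3, n = 1000, cohort = "c1") {
  out <- data.frame(variant = variant, chrom = "11",
                    pos_bp = seq_along(variant) * 1000L,
                    coded = coded, other = other, freq = freq,
                    beta = beta, se = se, t = beta / se,
                    p = 2 * pnorm(-abs(beta / se)), n = n,
                    cohort = cohort, flag = "ok",
                    stringsAsFactors = FALSE)
  class(out) <- c("summary_stats", "data.frame")
  out
}
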