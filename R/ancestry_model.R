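# Global ancestry derivation and the trait-quartile ancestry contrast.

#' Global ancestry proportions from local ancestry
#'
#' Per-individual genome-average ancestry proportions: the unweighted mean
#' over markers of (copies)/2. When EUR/AFR companion matrices are absent,
#' AFR is taken as 0 and EUR as the complement of NAM.
#'
#' @param ancestry an `ancestry_matrix`.
#' @return data.frame with columns id, nam, eur, afr (each row summing to 1).
#' @export
global_ancestry <- function(ancestry) {
  stopifnot(inherits(ancestry, "ancestry_matrix"))
  if (ncol(ancestry$nam) < 1) stop("empty ancestry matrix", call. = FALSE)
  m_nam <- rowMeans(ancestry$nam) / 2
  m_afr <- if (!is.null(ancestry$afr)) rowMeans(ancestry$afr) / 2 else rep(0, length(m_nam))
  m_eur <- if (!is.null(ancestry$eur)) rowMeans(ancestry$eur) / 2 else 1 - m_nam - m_afr
  data.frame(id = ancestry$ids, nam = m_nam, eur = m_eur, afr = m_afr,
             stringsAsFactors = FALSE)
}

# parse "chr:start-end" (1-based inclusive) into list(chrom, start, end)
parse_region <- function(region) {
  m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
  if (length(m) != 4L) stop("region must be 'chr:start-end'", call. = FALSE)
  list(chrom = m[2], start = as.numeric(m[3]), end = as.numeric(m[4]))
}

region_marker_index <- function(map, region) {
  if (is.null(region)) return(seq_len(nrow(map)))
  r <- if (is.character(region)) parse_region(region) else region
  which(map$chrom == r$chrom & map$pos_bp >= r$start & map$pos_bp <= r$end)
}

#' Ancestry contrast between top and bottom trait quartiles
#'
#' Per marker, the difference in mean NAM ancestry proportion (copies/2)
#' between individuals in the highest and lowest quartiles of the trait.
#' Quartiles are the first and last `floor(n/4)` individuals by trait rank
#' (stable order for ties), so the contrast depends on trait ranks only.
#'
#' @param ancestry an `ancestry_matrix`.
#' @param trait numeric vector aligned with the ancestry rows; typically the
#'   medication-adjusted raw trait. Must be complete.
#' @param region optional "chr:start-end" string (1-based inclusive
#'   positions) restricting the profile.
#' @return data.frame with columns marker, chrom, pos_bp, contrast (in
#'   [-1, 1]).
#' @export
quartile_ancestry_contrast <- function(ancestry, trait, region = NULL) {
  stopifnot(inherits(ancestry, "ancestry_matrix"))
  n <- nrow(ancestry$nam)
  if (length(trait) != n) stop("trait length must match individuals", call. = FALSE)
  if (anyNA(trait)) stop("trait must be complete for included individuals", call. = FALSE)
  if (n < 8) stop("need at least 8 individuals for quartiles", call. = FALSE)
  k <- n %/% 4L
  ord <- order(trait) # stable: ties keep input order
  bottom <- ord[seq_len(k)]
  top <- ord[seq.int(n - k + 1L, n)]
  idx <- region_marker_index(ancestry$map, region)
  if (!length(idx)) stop("no markers in requested region", call. = FALSE)
  contrast <- colMeans(ancestry$nam[top, idx, drop = FALSE]) / 2 -
    colMeans(ancestry$nam[bottom, idx, drop = FALSE]) / 2
  data.frame(marker = ancestry$map$marker[idx],
             chrom = ancestry$map$chrom[idx],
             pos_bp = ancestry$map$pos_bp[idx],
             contrast = unname(contrast),
             stringsAsFactors = FALSE)
}
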