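# Readers and writers for the interchange formats: TSV dosage/ancestry/
# phenotype/summary-stat tables, minimal VCF, RFMix-style per-haplotype
# calls, and YAML configs. All tables round-trip losslessly.

fwrite_tsv <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t", quote = FALSE, na = "NA")
}

fread_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  as.data.frame(data.table::fread(path, sep = "\t", header = TRUE,
                                  na.strings = "NA", data.table = FALSE))
}

#' Write / read a marker map TSV
#'
#' Columns: marker, chrom, pos_bp (1-based), and any extra columns present
#' (pos_gen, coded, other).
#' @param map marker map data.frame.
#' @param path file path.
#' @export
write_marker_map <- function(map, path) fwrite_tsv(map, path)

#' @rdname write_marker_map
#' @export
read_marker_map <- function(path) fread_tsv(path)

matrix_to_table <- function(ids, mat) {
  out <- data.frame(id = ids, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(mat))
}

table_to_matrix <- function(tab) {
  ids <- as.character(tab$id)
  mat <- as.matrix(tab[, setdiff(names(tab), "id"), drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  list(ids = ids, mat = mat)
}

#' Write an ancestry matrix as a NAM-copy dosage TSV (plus marker map)
#'
#' @param ancestry an `ancestry_matrix`.
#' @param path TSV path for the individuals x markers NAM copy counts.
#' @param map_path optional path for the marker map (default: `path` with
#'   a `.map.tsv` suffix).
#' @export
write_ancestry_tsv <- function(ancestry, path, map_path = paste0(path, ".map.tsv")) {
  stopifnot(inherits(ancestry, "ancestry_matrix"))
  fwrite_tsv(matrix_to_table(ancestry$ids, ancestry$nam), path)
  if (!is.null(map_path)) write_marker_map(ancestry$map, map_path)
  invisible(path)
}

#' Write RFMix-style diploid local-ancestry calls
#'
#' One row per marker (marker, chrom, pos_bp), then two columns per
#' individual (`<id>.0`, `<id>.1`) holding ancestry codes 1 = NAM,
#' 2 = EUR, 3 = AFR.
#' @param ancestry `ancestry_matrix` with haploid truth paths.
#' @param path output TSV path.
#' @export
write_rfmix_calls <- function(ancestry, path) {
  stopifnot(inherits(ancestry, "ancestry_matrix"))
  if (is.null(ancestry$haplotypes)) {
    stop("per-haplotype calls require haploid truth paths", call. = FALSE)
  }
  h1 <- t(ancestry$haplotypes$h1)
  h2 <- t(ancestry$haplotypes$h2)
  n <- length(ancestry$ids)
  hap <- matrix(0L, nrow(h1), 2L * n)
  hap[, 2 * seq_len(n) - 1L] <- h1
  hap[, 2 * seq_len(n)] <- h2
  colnames(hap) <- paste0(rep(ancestry$ids, each = 2), c(".0", ".1"))
  out <- cbind(ancestry$map[c("marker", "chrom", "pos_bp")], as.data.frame(hap))
  fwrite_tsv(out, path)
  invisible(path)
}

#' Read local ancestry calls into an `ancestry_matrix`
#'
#' @param path input file.
#' @param dialect `"dosage_tsv"` (individuals x markers NAM copy counts,
#'   as written by [write_ancestry_tsv()]) or `"rfmix_calls"` (markers x
#'   haplotypes ancestry codes, as written by [write_rfmix_calls()]).
#' @param map_path marker map TSV (required for `dosage_tsv` unless the
#'   default sidecar exists).
#' @param legend named integer vector mapping ancestry names to codes.
#' @return an `ancestry_matrix` (with EUR/AFR companions and haploid paths
#'   for the rfmix dialect).
#' @export
read_local_ancestry <- function(path, dialect = c("dosage_tsv", "rfmix_calls"),
                                map_path = paste0(path, ".map.tsv"),
                                legend = c(nam = 1L, eur = 2L, afr = 3L)) {
  dialect <- match.arg(dialect)
  tab <- fread_tsv(path)
  if (dialect == "dosage_tsv") {
    tm <- table_to_matrix(tab)
    if (!all(tm$mat %in% 0:2)) stop("NAM copy counts must be 0/1/2", call. = FALSE)
    storage.mode(tm$mat) <- "integer"
    map <- if (file.exists(map_path)) read_marker_map(map_path) else
      data.frame(marker = colnames(tm$mat), chrom = NA_character_,
                 pos_bp = seq_len(ncol(tm$mat)), stringsAsFactors = FALSE)
    return(new_ancestry_matrix(tm$mat, map, tm$ids))
  }
  # rfmix_calls
  hap_cols <- setdiff(names(tab), c("marker", "chrom", "pos_bp"))
  if (length(hap_cols) %% 2 != 0) {
    stop("odd number of haplotype columns", call. = FALSE)
  }
  hap <- as.matrix(tab[hap_cols])
  bad <- which(!matrix(hap %in% legend, nrow(hap)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("unknown ancestry code '%s' at line %d (marker %s)",
                 hap[bad[1, , drop = FALSE]], bad[1, 1] + 1L,
                 tab$marker[bad[1, 1]]),
         call. = FALSE)
  }
  ids <- unique(sub("\\.[01]$", "", hap_cols))
  h1 <- t(hap[, paste0(ids, ".0"), drop = FALSE])
  h2 <- t(hap[, paste0(ids, ".1"), drop = FALSE])
  storage.mode(h1) <- "integer"
  storage.mode(h2) <- "integer"
  dimnames(h1) <- dimnames(h2) <- NULL
  nam <- (h1 == legend[["nam"]]) + (h2 == legend[["nam"]])
  eur <- (h1 == legend[["eur"]]) + (h2 == legend[["eur"]])
  afr <- (h1 == legend[["afr"]]) + (h2 == legend[["afr"]])
  storage.mode(nam) <- "integer"
  storage.mode(eur) <- "integer"
  storage.mode(afr) <- "integer"
  map <- tab[c("marker", "chrom", "pos_bp")]
  new_ancestry_matrix(nam, map, ids, eur = eur, afr = afr,
                      haplotypes = list(h1 = h1, h2 = h2))
}

#' Write / read a genotype dosage TSV (plus marker map)
#' @param dosages a `dosage_matrix`.
#' @param path TSV path (individuals x markers).
#' @param map_path marker map path (default sidecar).
#' @export
write_dosage_tsv <- function(dosages, path, map_path = paste0(path, ".map.tsv")) {
  stopifnot(inherits(dosages, "dosage_matrix"))
  fwrite_tsv(matrix_to_table(dosages$ids, dosages$dosage), path)
  if (!is.null(map_path)) write_marker_map(dosages$map, map_path)
  invisible(path)
}

#' @rdname write_dosage_tsv
#' @export
read_dosage_tsv <- function(path, map_path = paste0(path, ".map.tsv")) {
  tm <- table_to_matrix(fread_tsv(path))
  if (any(tm$mat < 0 | tm$mat > 2, na.rm = TRUE)) {
    stop("dosages must lie in [0, 2]", call. = FALSE)
  }
  map <- if (file.exists(map_path)) read_marker_map(map_path) else
    data.frame(marker = colnames(tm$mat), chrom = NA_character_,
               pos_bp = seq_len(ncol(tm$mat)),
               coded = "G", other = "C", stringsAsFactors = FALSE)
  new_dosage_matrix(tm$mat, map, tm$ids)
}

#' Write / read a phenotype/covariate TSV
#' @param table phenotype data.frame (one row per individual, header
#'   required).
#' @param path file path.
#' @export
write_phenotype_tsv <- function(table, path) {
  fwrite_tsv(as.data.frame(table), path)
  invisible(path)
}

#' @rdname write_phenotype_tsv
#' @export
read_phenotype_tsv <- function(path) {
  tab <- fread_tsv(path)
  if (!"id" %in% names(tab)) stop("phenotype table needs an 'id' column", call. = FALSE)
  tab$id <- as.character(tab$id)
  class(tab) <- c("phenotype_table", "data.frame")
  tab
}

#' Write / read summary statistics TSV
#' @param stats `summary_stats` data.frame.
#' @param path file path.
#' @export
write_summary_stats <- function(stats, path) {
  fwrite_tsv(as.data.frame(stats), path)
  invisible(path)
}

#' @rdname write_summary_stats
#' @export
read_summary_stats <- function(path) {
  tab <- fread_tsv(path)
  class(tab) <- c("summary_stats", "data.frame")
  tab
}

#' Write hard-call genotypes as a minimal VCF
#'
#' VCFv4.2 with GT (rounded hard call) and DS (the stored dosage) per
#' sample; REF is the other allele, ALT the coded allele, so DS counts ALT
#' copies.
#' @param dosages a `dosage_matrix`.
#' @param path output path (plain text).
#' @export
write_vcf <- function(dosages, path) {
  stopifnot(inherits(dosages, "dosage_matrix"))
  map <- dosages$map
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=admixscan",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               '##FORMAT=<ID=DS,Number=1,Type=Float,Description="Coded allele dosage">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", dosages$ids), collapse = "\t")),
             con)
  gt_codes <- c("0/0", "0/1", "1/1")
  for (j in seq_len(nrow(map))) {
    ds <- dosages$dosage[, j]
    hard <- pmin(pmax(round(ds), 0), 2)
    field <- ifelse(is.na(ds), "./.:.",
                    paste0(gt_codes[hard + 1L], ":",
                           format(ds, trim = TRUE, digits = 15)))
    writeLines(paste(c(map$chrom[j], map$pos_bp[j], map$marker[j],
                       map$other[j], map$coded[j], ".", "PASS", ".",
                       "GT:DS", field), collapse = "\t"), con)
  }
  invisible(path)
}

#' Read genotype dosages from a VCF
#'
#' Uses the DS FORMAT field when present, otherwise converts GT hard calls
#' (ALT-allele count). Multi-allelic records are dropped with a warning.
#' Requires the VariantAnnotation package.
#' @param path VCF path.
#' @return a `dosage_matrix`.
#' @export
read_vcf_dosage <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE)) {
    stop("read_vcf_dosage requires the VariantAnnotation package", call. = FALSE)
  }
  vcf <- VariantAnnotation::readVcf(path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  alt <- VariantAnnotation::alt(vcf)
  multi <- S4Vectors::elementNROWS(alt) > 1
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) dropped", call. = FALSE)
    vcf <- vcf[!multi]
    rr <- rr[!multi]
    alt <- alt[!multi]
  }
  geno <- VariantAnnotation::geno(vcf)
  if ("DS" %in% names(geno)) {
    dm <- t(geno$DS)
  } else {
    gt <- geno$GT
    dm <- t(apply(gt, c(1, 2), function(g) {
      if (g %in% c(".", "./.", ".|.")) return(NA_real_)
      sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
    }))
  }
  storage.mode(dm) <- "double"
  map <- data.frame(marker = names(rr),
                    chrom = as.character(GenomicRanges::seqnames(rr)),
                    pos_bp = GenomicRanges::start(rr),
                    coded = as.character(unlist(alt)),
                    other = as.character(VariantAnnotation::ref(vcf)),
                    stringsAsFactors = FALSE)
  new_dosage_matrix(dm, map, rownames(dm))
}

#' Read / write a YAML run configuration
#' @param path YAML file path.
#' @export
read_config <- function(path) yaml::read_yaml(path)

#' @rdname read_config
#' @param config named list.
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Write a simulated cohort to a directory
#'
#' Emits ancestry dosage TSV (+ map), RFMix-style haplotype calls, genotype
#' dosage TSV (+ map), a minimal VCF, the phenotype TSV and a truth YAML
#' recording seed, causal marker and effect size.
#' @param cohort list from [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_ancestry_tsv(cohort$ancestry, file.path(dir, "ancestry.tsv"))
  write_rfmix_calls(cohort$ancestry, file.path(dir, "rfmix_calls.tsv"))
  write_dosage_tsv(cohort$genotypes, file.path(dir, "dosage.tsv"))
  write_vcf(cohort$genotypes, file.path(dir, "genotypes.vcf"))
  write_phenotype_tsv(cohort$phenotypes, file.path(dir, "phenotypes.tsv"))
  truth <- attr(cohort$phenotypes, "truth")
  write_config(list(seed = cohort$seed,
                    causal_marker = truth$causal_marker,
                    causal_index = truth$causal_index,
                    effect = truth$effect,
                    med_factor = truth$med_factor,
                    proportions = as.list(cohort$model$proportions),
                    generations = cohort$model$generations,
                    chr_length = cohort$model$chr_length),
               file.path(dir, "truth.yaml"))
  invisible(dir)
}

#' Align ancestry, genotype and phenotype sources on shared individual ids
#'
#' Inner-join on id with deterministic (sorted) ordering; per-source
#' dropped-id counts are reported in a message.
#' @param ancestry an `ancestry_matrix`.
#' @param dosages a `dosage_matrix` (optional).
#' @param phenotypes a phenotype data.frame with an `id` column.
#' @return list(ancestry, dosages, phenotypes) with identical sorted ids.
#' @export
align_cohort <- function(ancestry, dosages = NULL, phenotypes) {
  ids <- intersect(ancestry$ids, phenotypes$id)
  if (!is.null(dosages)) ids <- intersect(ids, dosages$ids)
  ids <- sort(ids)
  if (!length(ids)) stop("no shared individual ids across sources", call. = FALSE)
  drops <- c(ancestry = length(ancestry$ids) - length(ids),
             dosages = if (!is.null(dosages)) length(dosages$ids) - length(ids) else 0L,
             phenotypes = length(unique(phenotypes$id)) - length(ids))
  if (any(drops > 0)) {
    message("align_cohort dropped ids: ",
            paste(sprintf("%s=%d", names(drops), drops), collapse = ", "))
  }
  anc <- new_ancestry_matrix(
    ancestry$nam[match(ids, ancestry$ids), , drop = FALSE], ancestry$map, ids,
    eur = if (!is.null(ancestry$eur)) ancestry$eur[match(ids, ancestry$ids), , drop = FALSE],
    afr = if (!is.null(ancestry$afr)) ancestry$afr[match(ids, ancestry$ids), , drop = FALSE])
  dos <- if (!is.null(dosages)) {
    new_dosage_matrix(dosages$dosage[match(ids, dosages$ids), , drop = FALSE],
                      dosages$map, ids)
  }
  phe <- phenotypes[match(ids, phenotypes$id), , drop = FALSE]
  rownames(phe) <- NULL
  list(ancestry = anc, dosages = dos, phenotypes = phe)
}

#' Read and align a cohort bundle from files
#'
#' @param ancestry_path local-ancestry file.
#' @param phenotype_path phenotype TSV.
#' @param dosage_path optional genotype dosage TSV or VCF
#'   (`.vcf` suffix triggers the VCF reader).
#' @param dialect ancestry dialect, see [read_local_ancestry()].
#' @return list(ancestry, dosages, phenotypes), aligned.
#' @export
read_cohort_bundle <- function(ancestry_path, phenotype_path, dosage_path = NULL,
                               dialect = "dosage_tsv") {
  anc <- read_local_ancestry(ancestry_path, dialect = dialect)
  phe <- read_phenotype_tsv(phenotype_path)
  dos <- if (!is.null(dosage_path)) {
    if (grepl("\\.vcf(\\.gz)?$", dosage_path)) read_vcf_dosage(dosage_path)
    else read_dosage_tsv(dosage_path)
  }
  align_cohort(anc, dos, phe)
}
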