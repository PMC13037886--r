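#' Write a genotype matrix to VCF plus a coordinates TSV
#'
#' Emits a minimal VCFv4.2 file of biallelic SNP records (GT field only;
#' sites enumerated on contig "1" at positions 1..L with REF=A, ALT=T) and,
#' if coordinates are present, a tab-separated file of `sample_id`, `x`,
#' `y` (and `deme` when group labels exist).
#'
#' @param gm a [genotype_matrix()].
#' @param vcf_path output VCF path.
#' @param coords_path optional output TSV path.
#' @export
write_vcf <- function(gm, vcf_path, coords_path = NULL) {
  G <- as_dosage(gm)
  n <- nrow(G); L <- ncol(G)
  ids <- rownames(G) %||% sprintf("s%04d", seq_len(n))
  if (is.null(rownames(G))) ids <- sprintf("s%04d", seq_len(n))
  gt <- c("0/0", "0/1", "1/1")[t(G) + 1L]
  gt <- matrix(gt, L, n)
  header <- c("##fileformat=VCFv4.2",
              "##contig=<ID=1>",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", ids), collapse = "\t"))
  body <- paste(
    "1", seq_len(L), sprintf("snp%d", seq_len(L)), "A", "T", ".", "PASS",
    ".", "GT", apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), vcf_path)
  if (!is.null(coords_path) && !is.null(gm$coords)) {
    df <- gm$coords
    if (!is.null(gm$groups)) df$deme <- gm$groups
    write.table(df, coords_path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(vcf_path)
}

#' Read a genotype matrix from VCF (and a coordinates TSV)
#'
#' Parses a VCF with `vcfR`, keeping biallelic SNP records with complete GT
#' fields; multiallelic or missing-genotype records are dropped and counted
#' in a message. Coordinates, if given, are matched to samples by
#' `sample_id`.
#'
#' @param vcf_path VCF file (plain or gzipped).
#' @param coords_path optional TSV with columns `sample_id`, `x`, `y`
#'   (optionally `deme`).
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(vcf_path, coords_path = NULL) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt) | is.na(alt) | alt == "."
  dos <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  clean <- gsub("\\|", "/", gt)
  dos[clean == "0/0"] <- 0L
  dos[clean %in% c("0/1", "1/0")] <- 1L
  dos[clean == "1/1"] <- 2L
  missing_row <- apply(dos, 1, anyNA)
  drop <- multi | missing_row
  if (any(drop))
    message(sprintf("read_vcf: dropped %d multiallelic and %d incomplete-GT records",
                    sum(multi), sum(missing_row & !multi)))
  dos <- dos[!drop, , drop = FALSE]
  if (!nrow(dos)) stopf("no usable biallelic SNP records in %s", vcf_path)
  G <- t(dos)
  coords <- NULL; groups <- NULL
  if (!is.null(coords_path)) {
    co <- read.table(coords_path, header = TRUE, sep = "\t",
                     stringsAsFactors = FALSE)
    idx <- match(rownames(G), co$sample_id)
    if (anyNA(idx)) stopf("coordinates TSV is missing some VCF samples")
    coords <- co[idx, c("sample_id", "x", "y")]
    if ("deme" %in% names(co)) groups <- co$deme[idx]
  }
  genotype_matrix(G, coords = coords, groups = groups)
}

#' Read a run configuration from JSON or YAML
#'
#' @param path file ending in `.json`, `.yaml` or `.yml`.
#' @return a named list.
#' @export
read_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    stopf("config must be .json or .yaml/.yml: %s", path)
  }
}
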