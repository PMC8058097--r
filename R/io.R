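#' Segment profiles
#'
#' A segment profile holds one tumour's allele-specific copy-number
#' segments together with its ploidy, purity and whole-genome-duplication
#' (WGD) status. Coordinates are 1-based inclusive; `n_major`/`n_minor`
#' are integer allele copy numbers with `n_major >= n_minor >= 0`, and
#' segments of one chromosome must not overlap.
#'
#' @param sample_id sample identifier.
#' @param segments data.frame with columns `chromosome`, `start`, `end`,
#'   `n_major`, `n_minor`.
#' @param purity tumour purity in `[0, 1]` or `NA`.
#' @param ploidy supplied ploidy (length-weighted mean total copy number)
#'   or `NA` to derive it later.
#' @param wgd logical WGD flag or `NA` if not yet called.
#' @return object of class `segment_profile`.
#' @export
segment_profile <- function(sample_id, segments, purity = NA_real_,
                            ploidy = NA_real_, wgd = NA) {
  require_columns(segments, c("chromosome", "start", "end",
                              "n_major", "n_minor"),
                  sprintf("segments of sample '%s'", sample_id))
  segments$chromosome <- normalize_chrom(segments$chromosome)
  with(segments, {
    if (any(end < start))
      oa_stop(sprintf("sample '%s': segment end < start", sample_id),
              class = "oncoage_validation_error")
    if (any(n_major < 0 | n_minor < 0 | n_major < n_minor))
      oa_stop(sprintf(
        "sample '%s': allele copy numbers must satisfy n_major >= n_minor >= 0",
        sample_id), class = "oncoage_validation_error")
  })
  if (!is.na(purity) && (purity < 0 || purity > 1))
    oa_stop(sprintf("sample '%s': purity outside [0, 1]", sample_id),
            class = "oncoage_validation_error")
  # per-chromosome overlap check on sorted segments
  for (chrom in unique(segments$chromosome)) {
    seg <- segments[segments$chromosome == chrom, , drop = FALSE]
    seg <- seg[order(seg$start), , drop = FALSE]
    if (nrow(seg) > 1 && any(seg$start[-1] <= seg$end[-nrow(seg)]))
      oa_stop(sprintf("sample '%s': overlapping segments on chromosome %s",
                      sample_id, chrom),
              class = "oncoage_validation_error")
  }
  ord <- order(match(segments$chromosome, .chrom_levels), segments$start)
  structure(list(sample_id = sample_id,
                 segments = segments[ord, , drop = FALSE],
                 purity = purity, ploidy = ploidy, wgd = wgd),
            class = "segment_profile")
}

#' @export
print.segment_profile <- function(x, ...) {
  cat(sprintf("<segment_profile> %s: %d segments, ploidy %s, WGD %s\n",
              x$sample_id, nrow(x$segments),
              ifelse(is.na(x$ploidy), "?", format(x$ploidy, digits = 3)),
              ifelse(is.na(x$wgd), "?", x$wgd)))
  invisible(x)
}

#' Read allele-specific copy-number segments
#'
#' Reads a tab-separated segment table (columns `sample`, `chromosome`,
#' `start`, `end`, `n_major`, `n_minor`; 1-based inclusive coordinates)
#' into one [segment_profile] per sample. Alternative column spellings can
#' be supplied through `column_map`.
#'
#' @param path TSV file path.
#' @param arm_model optional [arm_model]; when supplied, segment
#'   coordinates are checked against chromosome extents.
#' @param column_map named character vector mapping canonical names to the
#'   file's column names, e.g. `c(n_major = "nMajor")`.
#' @return named list of `segment_profile` objects.
#' @export
read_segments <- function(path, arm_model = NULL, column_map = NULL) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  canonical <- c("sample", "chromosome", "start", "end", "n_major", "n_minor")
  if (!is.null(column_map)) {
    for (canon in names(column_map)) {
      names(tab)[names(tab) == column_map[[canon]]] <- canon
    }
  }
  require_columns(tab, canonical, "segment table")
  tab$chromosome <- normalize_chrom(tab$chromosome)
  if (!is.null(arm_model)) {
    lim <- arm_model$length[match(tab$chromosome, arm_model$chromosome)]
    if (any(tab$start < 1 | tab$end > lim))
      oa_stop("segment outside chromosome extent",
              class = "oncoage_validation_error")
  }
  profiles <- lapply(split(tab, tab$sample), function(d) {
    segment_profile(d$sample[1], d[, canonical[-1]])
  })
  profiles[order(names(profiles))]
}

#' Write segment profiles to the canonical TSV dialect
#'
#' @param profiles list of [segment_profile] objects.
#' @param path output path.
#' @export
write_segments <- function(profiles, path) {
  rows <- do.call(rbind, lapply(profiles, function(p) {
    cbind(sample = p$sample_id, p$segments)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a minimal MAF mutation table
#'
#' Loads the five mandatory MAF columns (`Hugo_Symbol`,
#' `Tumor_Sample_Barcode`, `Variant_Classification`, `Reference_Allele`,
#' `Tumor_Seq_Allele2`); any extra columns are ignored. No filtering is
#' applied at read time. A `variant_type` column (SNP/INS/DEL) is derived
#' from the allele strings ("-" denotes the empty allele).
#'
#' @param path tab-separated MAF file; lines starting with `#` are skipped.
#' @return data.frame of class `mutation_table` with columns `sample_id`,
#'   `gene`, `variant_classification`, `reference_allele`, `alt_allele`,
#'   `variant_type`.
#' @export
read_maf_minimal <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#",
                           check.names = FALSE)
  needed <- c("Hugo_Symbol", "Tumor_Sample_Barcode", "Variant_Classification",
              "Reference_Allele", "Tumor_Seq_Allele2")
  require_columns(tab, needed, "MAF")
  mutation_table(data.frame(
    sample_id = tab$Tumor_Sample_Barcode,
    gene = tab$Hugo_Symbol,
    variant_classification = tab$Variant_Classification,
    reference_allele = tab$Reference_Allele,
    alt_allele = tab$Tumor_Seq_Allele2,
    stringsAsFactors = FALSE
  ))
}

#' Construct a mutation table
#'
#' @param records data.frame with columns `sample_id`, `gene`,
#'   `variant_classification`, `reference_allele`, `alt_allele`.
#' @return data.frame of class `mutation_table` with a derived
#'   `variant_type` column.
#' @export
mutation_table <- function(records) {
  require_columns(records, c("sample_id", "gene", "variant_classification",
                             "reference_allele", "alt_allele"),
                  "mutation table")
  ref <- records$reference_allele
  alt <- records$alt_allele
  records$variant_type <- ifelse(
    ref == "-" | nchar(alt) > nchar(ref), "INS",
    ifelse(alt == "-" | nchar(alt) < nchar(ref), "DEL",
           ifelse(nchar(ref) == 1, "SNP", "ONP")))
  class(records) <- c("mutation_table", "data.frame")
  records
}

#' Read a GISTIC-style broad (per-arm) log2 matrix
#'
#' The file layout mirrors GISTIC's `broad_values_by_arm`: first column
#' holds arm labels such as `1p`, `13q`; remaining columns are samples.
#' Arm labels are validated against the arm model; acrocentric chromosomes
#' may legitimately lack a p row.
#'
#' @param path TSV path.
#' @param arm_model an [arm_model] used to validate labels.
#' @return long data.frame with columns `sample`, `arm`, `chromosome`,
#'   `log2_ratio`.
#' @export
read_gistic_broad <- function(path, arm_model) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (ncol(tab) < 2)
    oa_stop("broad matrix needs an arm column plus at least one sample",
            class = "oncoage_schema_error")
  labels <- as.character(tab[[1]])
  parsed <- parse_arm_label(labels, arm_model)
  samples <- names(tab)[-1]
  long <- data.frame(
    sample = rep(samples, each = nrow(tab)),
    arm = rep(paste0(parsed$chromosome, parsed$arm), times = length(samples)),
    chromosome = rep(parsed$chromosome, times = length(samples)),
    log2_ratio = as.numeric(unlist(tab[-1], use.names = FALSE)),
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(long$log2_ratio)))
    oa_stop("non-finite log2 ratio in broad matrix",
            class = "oncoage_validation_error")
  long
}

#' Read or construct a feature-by-sample omics matrix
#'
#' `read_matrix()` reads a TSV whose first column is the feature ID (gene
#' or probe) and remaining columns are samples. `omics_matrix()` validates
#' an in-memory matrix. Expression values must be non-negative;
#' methylation beta values must lie in `[0, 1]`; duplicate feature IDs are
#' rejected.
#'
#' @param path TSV path.
#' @param kind `"expression"` or `"methylation"`.
#' @return numeric matrix (features x samples) with attribute `kind` and
#'   class `omics_matrix`.
#' @export
read_matrix <- function(path, kind = c("expression", "methylation")) {
  kind <- match.arg(kind)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  ids <- as.character(tab[[1]])
  m <- as.matrix(tab[-1])
  rownames(m) <- ids
  omics_matrix(m, kind)
}

#' @rdname read_matrix
#' @param m numeric matrix with feature row names and sample column names.
#' @export
omics_matrix <- function(m, kind = c("expression", "methylation")) {
  kind <- match.arg(kind)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    oa_stop("omics matrix needs feature row names and sample column names",
            class = "oncoage_schema_error")
  if (anyDuplicated(rownames(m)))
    oa_stop("duplicate feature IDs in omics matrix",
            class = "oncoage_validation_error")
  storage.mode(m) <- "double"
  if (kind == "expression" && any(m < 0, na.rm = TRUE))
    oa_stop("negative expression values", class = "oncoage_validation_error")
  if (kind == "methylation" && any(m < 0 | m > 1, na.rm = TRUE))
    oa_stop("methylation beta values outside [0, 1]",
            class = "oncoage_validation_error")
  structure(m, kind = kind, class = c("omics_matrix", class(m)))
}

#' @rdname read_matrix
#' @param feature_col header name used for the feature-ID column on write.
#' @export
write_matrix <- function(m, path, feature_col = "feature") {
  out <- data.frame(rownames(m), as.data.frame(unclass(m)),
                    check.names = FALSE)
  names(out)[1] <- feature_col
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a clinical covariate table
#'
#' One row per sample; `age` must be positive where present, `purity` in
#' `[0, 1]` where present. Empty strings and "NA" placeholders in
#' character columns are normalised to `NA`.
#'
#' @param path TSV path with at least columns `sample_id` and `age`.
#' @return data.frame of class `clinical_table`.
#' @export
read_clinical <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  clinical_table(tab)
}

#' @rdname read_clinical
#' @param tab in-memory clinical data.frame.
#' @export
clinical_table <- function(tab) {
  require_columns(tab, c("sample_id", "age"), "clinical table")
  tab[] <- lapply(tab, normalize_missing)
  tab$age <- as.numeric(tab$age)
  if (anyDuplicated(tab$sample_id))
    oa_stop("duplicate sample_id in clinical table",
            class = "oncoage_validation_error")
  if (any(tab$age <= 0, na.rm = TRUE))
    oa_stop("age must be positive", class = "oncoage_validation_error")
  if ("purity" %in% names(tab)) {
    tab$purity <- as.numeric(tab$purity)
    if (any(tab$purity < 0 | tab$purity > 1, na.rm = TRUE))
      oa_stop("purity outside [0, 1]", class = "oncoage_validation_error")
  }
  class(tab) <- c("clinical_table", "data.frame")
  tab
}

#' Write a data.frame as TSV with stable column order
#' @param df data.frame.
#' @param path output path.
#' @param metadata optional named list written as leading `# key: value`
#'   comment lines (run provenance).
#' @export
write_tsv <- function(df, path, metadata = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(metadata)) {
    writeLines(sprintf("# %s: %s", names(metadata),
                       vapply(metadata, format, "")), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
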