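#' Mutation-level metrics
#'
#' Burden, substitution-class fractions and hypermutation statistics from
#' a minimal MAF-style mutation table. The non-silent vocabulary, the
#' hypermutation cutoff (strictly more than 1000 non-silent mutations per
#' exome) and the young/old split at age 50 follow the conventions of
#' exome-wide tumour mutation analyses.
#'
#' @name mutations
NULL

.nonsilent_classes <- c(
  "Frame_Shift_Del", "Frame_Shift_Ins", "In_Frame_Del", "In_Frame_Ins",
  "Missense_Mutation", "Nonsense_Mutation", "Nonstop_Mutation",
  "Splice_Site", "Translation_Start_Site")

.substitution_classes <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Keep only non-silent variants
#'
#' Retains the nine protein-altering variant classifications
#' (frame-shift indels, in-frame indels, missense, nonsense, nonstop,
#' splice site, translation start site). Idempotent.
#'
#' @param table a [mutation_table].
#' @return filtered `mutation_table`.
#' @export
filter_nonsilent <- function(table) {
  table[table$variant_classification %in% .nonsilent_classes, ,
        drop = FALSE]
}

#' Per-sample mutation burden
#'
#' Burden is the count of (already non-silent-filtered) variants per
#' sample; `log_burden = log10(burden + 1)` so zero-burden samples remain
#' representable.
#'
#' @param table a non-silent-filtered [mutation_table].
#' @param samples optional character vector of samples to report
#'   (zero-burden samples included); defaults to samples present in the
#'   table.
#' @return data.frame with columns `sample`, `burden`, `log_burden`.
#' @export
mutation_burden <- function(table, samples = NULL) {
  samples <- samples %||% sort(unique(table$sample_id))
  counts <- table(factor(table$sample_id, levels = samples))
  data.frame(sample = samples, burden = as.integer(counts),
             log_burden = log10(as.integer(counts) + 1),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Hypermutation flag: strictly more than 1000 non-silent mutations
#' @param burden non-negative count vector.
#' @return logical vector.
#' @export
hypermutation_flag <- function(burden) {
  if (any(burden < 0)) oa_stop("negative burden")
  burden > 1000
}

#' Per-sample substitution-class fractions
#'
#' Single-base SNVs are collapsed to the six pyrimidine-reference
#' substitution classes (a purine-reference change is complemented, e.g.
#' G>A counts as C>T). Fractions sum to 1 for every sample with at least
#' one usable SNV. Multi-base or multi-allele records are skipped with a
#' warning; a record with `ref == alt` raises an error.
#'
#' @param table a [mutation_table].
#' @return data.frame: one row per sample with >= 1 SNV, columns `sample`
#'   then the six classes (`C.A` ... `T.G` syntactic names, ordered as
#'   C>A, C>G, C>T, T>A, T>C, T>G).
#' @export
substitution_fractions <- function(table) {
  ref <- toupper(table$reference_allele)
  alt <- toupper(table$alt_allele)
  bases <- c("A", "C", "G", "T")
  snv <- ref %in% bases & alt %in% bases
  if (any(snv & ref == alt))
    oa_stop("substitution_fractions: record with reference == alternate",
            class = "oncoage_validation_error")
  skipped <- table$variant_type == "SNP" & !snv
  if (any(skipped))
    warning(sprintf("%d multi-base/multi-allele SNV record(s) skipped",
                    sum(skipped)))
  ref <- ref[snv]; alt <- alt[snv]; sample <- table$sample_id[snv]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flip <- ref %in% c("A", "G")
  ref[flip] <- comp[ref[flip]]
  alt[flip] <- comp[alt[flip]]
  cls <- factor(paste0(ref, ">", alt), levels = .substitution_classes)
  tab <- table(factor(sample), cls)
  frac <- sweep(unclass(tab), 1, rowSums(tab), "/")
  out <- data.frame(sample = rownames(frac), frac, check.names = TRUE,
                    stringsAsFactors = FALSE, row.names = NULL)
  out
}

#' Binary gene-by-sample mutation matrix with a frequency floor
#'
#' Entry is 1 when the sample carries at least one variant in the gene.
#' Genes mutated in strictly more than `min_frequency` of the cohort are
#' kept. The input is expected to be non-silent-filtered and restricted
#' to the analysis cohort (non-hypermutated, non-MSI-H samples).
#'
#' @param table a [mutation_table].
#' @param samples character vector: the cohort (columns of the matrix).
#' @param min_frequency frequency floor, default 0.05 (strict `>`).
#' @return binary integer matrix, genes x samples.
#' @export
gene_mutation_matrix <- function(table, samples, min_frequency = 0.05) {
  if (length(samples) == 0)
    oa_stop("gene_mutation_matrix: empty cohort",
            class = "oncoage_validation_error")
  table <- table[table$sample_id %in% samples, , drop = FALSE]
  genes <- sort(unique(table$gene))
  m <- matrix(0L, nrow = length(genes), ncol = length(samples),
              dimnames = list(genes, samples))
  if (nrow(table))
    m[cbind(match(table$gene, genes), match(table$sample_id, samples))] <- 1L
  keep <- rowSums(m) / length(samples) > min_frequency
  m[keep, , drop = FALSE]
}

#' Young/old age-group labels (young: age <= 50)
#'
#' @param ages numeric vector; missing ages yield `NA` with a warning.
#' @return factor with levels `young`, `old`.
#' @export
age_group_split <- function(ages) {
  if (anyNA(ages)) warning("missing age(s) excluded from age grouping")
  factor(ifelse(ages <= 50, "young", "old"), levels = c("young", "old"))
}

#' Hypermutation enrichment between age groups
#'
#' Builds the 2x2 hypermutated-by-age-group contingency table, reports
#' per-group hypermutation proportions and the two-sided Fisher exact p
#' value (sum of hypergeometric probabilities of tables at most as
#' probable as the observed one).
#'
#' @param hyper logical vector of hypermutation flags.
#' @param age_group factor from [age_group_split], aligned with `hyper`.
#' @return list with `table` (2x2), `young_pct`, `old_pct` (percent,
#'   `NA` for an empty group), `fisher_p`.
#' @export
hypermutation_enrichment <- function(hyper, age_group) {
  stopifnot(length(hyper) == length(age_group))
  ok <- !is.na(hyper) & !is.na(age_group)
  tab <- table(age_group = age_group[ok],
               hyper = factor(hyper[ok], levels = c(TRUE, FALSE)))
  n_young <- sum(tab["young", ])
  n_old <- sum(tab["old", ])
  list(
    table = tab,
    young_pct = if (n_young) 100 * tab["young", "TRUE"] / n_young else NA_real_,
    old_pct = if (n_old) 100 * tab["old", "TRUE"] / n_old else NA_real_,
    fisher_p = if (n_young && n_old) stats::fisher.test(tab)$p.value
               else NA_real_
  )
}

#' Per-sample mutation summary
#'
#' Applies the non-silent filter, computes burden/log-burden and the
#' hypermutation flag, attaches substitution fractions and any supplied
#' MSI-H / POLE / POLD1 flags.
#'
#' @param table a raw [mutation_table].
#' @param samples optional full sample list (zero-burden samples kept).
#' @param msi_high optional named logical vector of MSI-H flags.
#' @param pole_mut,pold1_mut optional named logical flag vectors.
#' @return data.frame, one row per sample.
#' @export
mutation_summary <- function(table, samples = NULL, msi_high = NULL,
                             pole_mut = NULL, pold1_mut = NULL) {
  ns <- filter_nonsilent(table)
  out <- mutation_burden(ns, samples)
  out$hypermutated <- hypermutation_flag(out$burden)
  fr <- substitution_fractions(ns)
  out <- merge(out, fr, by = "sample", all.x = TRUE, sort = TRUE)
  add_flag <- function(out, flags, name) {
    out[[name]] <- if (is.null(flags)) NA else
      unname(flags[out$sample])
    out
  }
  out <- add_flag(out, msi_high, "msi_high")
  out <- add_flag(out, pole_mut, "pole_mut")
  add_flag(out, pold1_mut, "pold1_mut")
}
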