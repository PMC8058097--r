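#' SCNA event classification and hierarchical scores
#'
#' Copy-number events carried by a tumour are classified from their log2
#' ratio into integer classes, summed per level (focal, arm, chromosome)
#' into raw scores, and rank-normalised within each cancer-type cohort so
#' the most altered tumour of a cohort scores close to 1. The overall
#' SCNA score is the sum of the three normalised level scores.
#'
#' @name scna
NULL

#' Classify a log2 copy-number ratio into an integer class
#'
#' Five half-open bands: `>= 1` -> 2; `[0.25, 1)` -> 1; `[-0.25, 0.25)` ->
#' 0; `[-1, -0.25)` -> -1; `< -1` -> -2.
#'
#' @param ratio numeric vector of log2 ratios, finite.
#' @return integer vector in `{-2, -1, 0, 1, 2}`.
#' @export
classify_log2 <- function(ratio) {
  if (any(!is.finite(ratio)))
    oa_stop("classify_log2: non-finite log2 ratio",
            class = "oncoage_validation_error")
  ifelse(ratio >= 1, 2L,
  ifelse(ratio >= 0.25, 1L,
  ifelse(ratio >= -0.25, 0L,
  ifelse(ratio >= -1, -1L, -2L))))
}

#' Split broad per-arm values into chromosome- and arm-level events
#'
#' A chromosome whose two arms carry the same log2 ratio (within
#' tolerance `eps`) contributes one chromosome-level event; otherwise two
#' arm-level events. Chromosomes represented by a single arm (acrocentric)
#' contribute one arm-level event.
#'
#' @param broad long data.frame from [read_gistic_broad] (columns
#'   `sample`, `arm`, `chromosome`, `log2_ratio`).
#' @param arm_model an [arm_model].
#' @param eps equality tolerance on log2 values.
#' @return data.frame with columns `sample`, `level`
#'   (`"chromosome"`/`"arm"`), `locus`, `log2_ratio`, `score_class`.
#' @export
split_broad_events <- function(broad, arm_model, eps = 1e-9) {
  require_columns(broad, c("sample", "arm", "chromosome", "log2_ratio"),
                  "broad event table")
  parse_arm_label(broad$arm, arm_model)  # label validation
  pieces <- lapply(split(broad, list(broad$sample, broad$chromosome),
                         drop = TRUE), function(d) {
    if (nrow(d) == 2 && abs(d$log2_ratio[1] - d$log2_ratio[2]) <= eps) {
      data.frame(sample = d$sample[1], level = "chromosome",
                 locus = d$chromosome[1], log2_ratio = d$log2_ratio[1],
                 stringsAsFactors = FALSE)
    } else {
      data.frame(sample = d$sample, level = "arm", locus = d$arm,
                 log2_ratio = d$log2_ratio, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out$score_class <- classify_log2(out$log2_ratio)
  out
}

#' Raw SCNA score at one level for one sample
#'
#' @param events data.frame of events of one sample, all at `level`, with
#'   a `score_class` column.
#' @param level `"focal"`, `"arm"` or `"chromosome"`.
#' @return sum of `|score_class|` (non-negative integer).
#' @export
raw_level_score <- function(events, level = c("focal", "arm", "chromosome")) {
  level <- match.arg(level)
  if (nrow(events) == 0) return(0L)
  if ("level" %in% names(events) && any(events$level != level))
    oa_stop("raw_level_score: mixed event levels",
            class = "oncoage_validation_error")
  sum(abs(as.integer(events$score_class)))
}

#' Rank-based normalisation within a cohort
#'
#' Ascending ranks (average rank on ties) divided by the cohort size, so
#' values lie in `(0, 1]` and the unique maximum (if any) maps to 1.
#'
#' @param raw numeric vector of raw scores of one cancer-type cohort.
#' @return numeric vector of normalised scores.
#' @export
rank_normalize <- function(raw) {
  if (length(raw) == 0)
    oa_stop("rank_normalize: empty cohort",
            class = "oncoage_validation_error")
  rank(raw, ties.method = "average") / length(raw)
}

#' Per-sample hierarchical SCNA scores
#'
#' Computes raw focal/arm/chromosome scores per sample ([raw_level_score]
#' over classified events), rank-normalises each level independently
#' within each cancer-type cohort, and assembles `chrom_arm`
#' (arm + chromosome) and `overall` (all three) scores. Samples present in
#' the cohort assignment but absent from the event tables receive raw
#' score 0 and participate in the ranking.
#'
#' @param broad long broad table ([read_gistic_broad] layout) or `NULL`.
#' @param focal data.frame with columns `sample`, `log2_ratio` (plus any
#'   locus columns) or `NULL`.
#' @param cohorts data.frame with columns `sample`, `cancer_type`; every
#'   event sample must appear here.
#' @param arm_model an [arm_model].
#' @param eps chromosome-vs-arm equality tolerance, see
#'   [split_broad_events].
#' @return data.frame with columns `sample`, `cancer_type`, `focal_raw`,
#'   `arm_raw`, `chrom_raw`, `focal_norm`, `arm_norm`, `chrom_norm`,
#'   `chrom_arm`, `overall`.
#' @export
scna_scores <- function(broad, focal, cohorts, arm_model, eps = 1e-9) {
  require_columns(cohorts, c("sample", "cancer_type"), "cohort table")
  if (anyDuplicated(cohorts$sample))
    oa_stop("duplicate sample in cohort table",
            class = "oncoage_validation_error")
  raw_for <- function(samples, values) {
    # samples/values: per-event sample id and |class|; sum within sample
    out <- setNames(numeric(nrow(cohorts)), cohorts$sample)
    if (length(samples)) {
      unknown <- setdiff(unique(samples), cohorts$sample)
      if (length(unknown))
        oa_stop(sprintf("event sample(s) missing from cohort table: %s",
                        paste(unknown, collapse = ", ")),
                class = "oncoage_validation_error")
      agg <- tapply(values, samples, sum)
      out[names(agg)] <- agg
    }
    out
  }
  if (!is.null(broad) && nrow(broad)) {
    ev <- split_broad_events(broad, arm_model, eps)
    arm_ev <- ev[ev$level == "arm", ]
    chr_ev <- ev[ev$level == "chromosome", ]
    arm_raw <- raw_for(arm_ev$sample, abs(arm_ev$score_class))
    chrom_raw <- raw_for(chr_ev$sample, abs(chr_ev$score_class))
  } else {
    arm_raw <- chrom_raw <- raw_for(character(), numeric())
  }
  if (!is.null(focal) && nrow(focal)) {
    require_columns(focal, c("sample", "log2_ratio"), "focal event table")
    focal_raw <- raw_for(focal$sample, abs(classify_log2(focal$log2_ratio)))
  } else {
    focal_raw <- raw_for(character(), numeric())
  }
  out <- data.frame(sample = cohorts$sample,
                    cancer_type = cohorts$cancer_type,
                    focal_raw = as.vector(focal_raw),
                    arm_raw = as.vector(arm_raw),
                    chrom_raw = as.vector(chrom_raw),
                    stringsAsFactors = FALSE)
  for (lev in c("focal", "arm", "chrom")) {
    norm <- paste0(lev, "_norm")
    out[[norm]] <- NA_real_
    for (ct in unique(out$cancer_type)) {
      idx <- out$cancer_type == ct
      out[[norm]][idx] <- rank_normalize(out[[paste0(lev, "_raw")]][idx])
    }
  }
  out$chrom_arm <- out$arm_norm + out$chrom_norm
  out$overall <- out$focal_norm + out$chrom_arm
  out
}

#' Drop focal regions overlapping centromeres or telomeres
#'
#' Overlap tests use half-open intervals after converting the 1-based
#' inclusive input, so a region ending exactly where a window starts (or
#' starting just after one ends) is kept. Telomere windows are the first
#' and last `telomere_width` bases of each chromosome.
#'
#' @param regions data.frame with columns `chromosome`, `start`, `end`
#'   (1-based inclusive).
#' @param arm_model an [arm_model].
#' @param telomere_width window width in bases (default 10 kb).
#' @return the retained rows of `regions`.
#' @export
filter_focal_regions <- function(regions, arm_model, telomere_width = 1e4) {
  require_columns(regions, c("chromosome", "start", "end"), "region table")
  regions$chromosome <- normalize_chrom(regions$chromosome)
  i <- match(regions$chromosome, arm_model$chromosome)
  len <- arm_model$length[i]
  if (any(regions$start < 1 | regions$end > len | regions$end < regions$start))
    oa_stop("region outside chromosome extent",
            class = "oncoage_validation_error")
  # half-open internal coordinates: [start-1, end)
  r0 <- regions$start - 1
  r1 <- regions$end
  overlaps <- function(a0, a1) r0 < a1 & a0 < r1
  cen <- overlaps(arm_model$cen_start[i] - 1, arm_model$cen_end[i])
  tel <- overlaps(0, pmin(telomere_width, len)) |
    overlaps(pmax(len - telomere_width, 0), len)
  regions[!(cen | tel), , drop = FALSE]
}

#' Correlate gene-level SCNA with expression
#'
#' Pearson correlation between per-sample GISTIC gene scores and
#' log2(RSEM + 1) expression, per gene, with BH adjustment across the
#' genes that yield a defined correlation. Genes with zero variance in
#' either vector (or fewer than 3 paired samples) are flagged undefined
#' and excluded from the BH family.
#'
#' @param gene_scores genes x samples numeric matrix of GISTIC scores.
#' @param expression genes x samples matrix of RSEM values (same genes);
#'   transformed internally with `log2(x + 1)`.
#' @return data.frame with columns `gene`, `n`, `pearson_r`, `p`, `adj_p`,
#'   `defined`.
#' @export
scna_expr_correlation <- function(gene_scores, expression) {
  genes <- intersect(rownames(gene_scores), rownames(expression))
  samples <- intersect(colnames(gene_scores), colnames(expression))
  if (length(samples) < 3)
    oa_stop("scna_expr_correlation: fewer than 3 shared samples",
            class = "oncoage_validation_error")
  rows <- lapply(genes, function(g) {
    x <- as.numeric(gene_scores[g, samples])
    y <- log2(as.numeric(expression[g, samples]) + 1)
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) {
      return(data.frame(gene = g, n = sum(ok), pearson_r = NA_real_,
                        p = NA_real_, defined = FALSE))
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    data.frame(gene = g, n = sum(ok), pearson_r = unname(ct$estimate),
               p = ct$p.value, defined = TRUE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- NA_real_
  out$adj_p[out$defined] <- bh_adjust(out$p[out$defined])
  out
}
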