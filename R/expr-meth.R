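#' Coupled expression/methylation age analysis
#'
#' Per-gene age regressions on log2-transformed expression and on
#' methylation beta values, age-DEG/age-DMG calling at BH-adjusted
#' p < 0.05, one-to-one probe-to-gene mapping by most-negative
#' correlation with expression, overlap quadrant classification and
#' methylation-expression correlation grouping.
#'
#' @name expr_meth
NULL

#' Filter lowly expressed genes
#'
#' Keeps genes with a positive RSEM value in strictly more than
#' `min_fraction` of samples.
#'
#' @param expr expression [omics_matrix] (genes x samples).
#' @param min_fraction default 0.5.
#' @return filtered matrix.
#' @export
filter_expressed <- function(expr, min_fraction = 0.5) {
  if (!identical(attr(expr, "kind"), "expression"))
    oa_stop("filter_expressed: expression matrix required",
            class = "oncoage_validation_error")
  keep <- rowMeans(expr > 0, na.rm = TRUE) > min_fraction
  expr[keep, , drop = FALSE]
}

#' log2(x + 1) transform of an expression matrix
#'
#' @param expr non-negative expression matrix.
#' @return transformed matrix.
#' @export
log2_expr <- function(expr) {
  if (any(expr < 0, na.rm = TRUE))
    oa_stop("log2_expr: negative expression value",
            class = "oncoage_validation_error")
  out <- log2(expr + 1)
  attr(out, "kind") <- attr(expr, "kind")
  out
}

#' One-to-one probe-to-gene mapping by most-negative expression correlation
#'
#' For each gene with candidate probes, selects the probe whose Pearson
#' correlation between beta values and log2-transformed expression over
#' the shared samples is most negative; exact ties break to the
#' lexicographically smallest probe ID, making the choice independent of
#' input order. Genes with no probe, or with fewer than 3 complete paired
#' observations for every probe, are dropped.
#'
#' @param meth probe x sample methylation matrix (beta values).
#' @param probe_gene_map data.frame with columns `probe`, `gene`.
#' @param expr gene x sample expression matrix (RSEM; transformed
#'   internally).
#' @return list with `meth` (gene-level methylation matrix over shared
#'   samples) and `map` (data.frame `gene`, `probe`, `r`).
#' @export
map_probes <- function(meth, probe_gene_map, expr) {
  require_columns(probe_gene_map, c("probe", "gene"), "probe map")
  samples <- intersect(colnames(meth), colnames(expr))
  if (length(samples) < 3)
    oa_stop("map_probes: fewer than 3 shared samples",
            class = "oncoage_validation_error")
  le <- log2(expr[, samples, drop = FALSE] + 1)
  pm <- probe_gene_map[probe_gene_map$probe %in% rownames(meth) &
                       probe_gene_map$gene %in% rownames(expr), ,
                       drop = FALSE]
  genes <- sort(unique(pm$gene))
  rows <- lapply(genes, function(g) {
    probes <- sort(unique(pm$probe[pm$gene == g]))
    e <- as.numeric(le[g, ])
    rs <- vapply(probes, function(pb) {
      b <- as.numeric(meth[pb, samples])
      ok <- is.finite(b) & is.finite(e)
      if (sum(ok) < 3 || stats::sd(b[ok]) == 0 || stats::sd(e[ok]) == 0)
        return(NA_real_)
      stats::cor(b[ok], e[ok])
    }, 0)
    if (all(is.na(rs))) return(NULL)
    best <- probes[which(rs == min(rs, na.rm = TRUE))][1]  # probes sorted
    data.frame(gene = g, probe = best, r = rs[[best]],
               stringsAsFactors = FALSE)
  })
  map <- do.call(rbind, rows)
  if (is.null(map))
    oa_stop("map_probes: no mappable gene", class = "oncoage_validation_error")
  gm <- meth[map$probe, samples, drop = FALSE]
  rownames(gm) <- map$gene
  list(meth = gm, map = map)
}

#' Per-feature age regression over a matrix
#'
#' Ordinary least squares of each feature (row) on age plus covariates
#' (and an optional platform covariate), on complete cases shared by all
#' features. p values are BH-adjusted across the retained features of the
#' matrix; features with `adj_p < flag_cutoff` are flagged (age-DEG for
#' expression input, age-DMG for methylation input). Zero-variance
#' features are skipped and excluded from the BH family.
#'
#' All features are fit against one shared design matrix via a single QR
#' decomposition, so genome-scale matrices fit in seconds.
#'
#' @param mat feature x sample matrix, already transformed
#'   (log2 expression or beta values).
#' @param clinical data.frame with `sample_id`, `age` and covariates.
#' @param covariates covariate names (pre-selected via
#'   [covariate_select]).
#' @param platform optional name of a platform column in `clinical` to
#'   include as a covariate.
#' @param flag_cutoff adjusted-p threshold for flagging (default 0.05).
#' @return data.frame with columns `feature`, `coefficient` (per-year),
#'   `se`, `p`, `adj_p`, `flag` (logical), `direction` (`"up"`/`"down"`).
#' @export
age_feature_regression <- function(mat, clinical, covariates = character(),
                                   platform = NULL, flag_cutoff = 0.05) {
  require_columns(clinical, c("sample_id", "age"), "clinical table")
  covs <- c(covariates, platform)
  samples <- intersect(colnames(mat), clinical$sample_id)
  cl <- clinical[match(samples, clinical$sample_id), , drop = FALSE]
  cols <- c("age", intersect(covs, names(cl)))
  keep <- stats::complete.cases(cl[, cols, drop = FALSE])
  cl <- cl[keep, , drop = FALSE]
  samples <- samples[keep]
  mf <- build_model_frame(cbind(cl, .dummy_outcome = 0), ".dummy_outcome",
                          covs)
  X <- stats::model.matrix(
    stats::reformulate(c("age", mf$covariates)), mf$data)
  Y <- t(mat[, samples, drop = FALSE])
  ok_feature <- apply(Y, 2, function(y) all(is.finite(y)) && stats::sd(y) > 0)
  Y <- Y[, ok_feature, drop = FALSE]
  if (ncol(Y) == 0)
    oa_stop("age_feature_regression: no usable feature",
            class = "oncoage_validation_error")
  if (nrow(X) <= ncol(X))
    oa_stop("age_feature_regression: design has more parameters than samples",
            class = "oncoage_validation_error")
  qr_x <- qr(X)
  coefs <- qr.coef(qr_x, Y)
  res <- Y - X %*% coefs
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(res^2) / df
  xtxinv_age <- chol2inv(qr.R(qr_x))[2, 2]  # "age" is the 2nd column
  se <- sqrt(sigma2 * xtxinv_age)
  beta <- coefs["age", ]
  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), df)
  out <- data.frame(feature = colnames(Y), coefficient = as.numeric(beta),
                    se = as.numeric(se), p = as.numeric(p),
                    stringsAsFactors = FALSE)
  out$adj_p <- bh_adjust(out$p)
  out$flag <- out$adj_p < flag_cutoff
  out$direction <- ifelse(out$coefficient >= 0, "up", "down")
  rownames(out) <- NULL
  out
}

#' Classify the age-DEG / age-DMG overlap into sign quadrants
#'
#' Genes flagged in both analyses are assigned to the four quadrants of
#' (methylation direction, expression direction). The opposite-direction
#' percentage counts quadrants `meth_up_expr_down` and
#' `meth_down_expr_up`.
#'
#' @param expr_results,meth_results outputs of [age_feature_regression].
#' @return list with `quadrants` (data.frame `gene`, `quadrant`),
#'   `counts` (named integer vector over the four quadrants), `n_overlap`,
#'   `opposite_pct` (percent, `NA` when the overlap is empty), and
#'   `groups` (data.frame `gene`, `group` over the union universe:
#'   `age-DMGs-DEGs`, `age-DMGs only`, `age-DEGs only`, `others`).
#' @export
classify_overlap <- function(expr_results, meth_results) {
  universe <- union(expr_results$feature, meth_results$feature)
  e_flag <- universe %in% expr_results$feature[expr_results$flag]
  m_flag <- universe %in% meth_results$feature[meth_results$flag]
  group <- ifelse(e_flag & m_flag, "age-DMGs-DEGs",
           ifelse(m_flag, "age-DMGs only",
           ifelse(e_flag, "age-DEGs only", "others")))
  overlap <- universe[e_flag & m_flag]
  e_dir <- expr_results$direction[match(overlap, expr_results$feature)]
  m_dir <- meth_results$direction[match(overlap, meth_results$feature)]
  quadrant <- if (length(overlap)) paste0("meth_", m_dir, "_expr_", e_dir)
              else character(0)
  levels_q <- c("meth_down_expr_down", "meth_down_expr_up",
                "meth_up_expr_down", "meth_up_expr_up")
  counts <- table(factor(quadrant, levels = levels_q))
  opposite <- sum(counts[c("meth_up_expr_down", "meth_down_expr_up")])
  list(
    quadrants = data.frame(gene = overlap, quadrant = quadrant,
                           stringsAsFactors = FALSE),
    counts = counts,
    n_overlap = length(overlap),
    opposite_pct = if (length(overlap)) 100 * opposite / length(overlap)
                   else NA_real_,
    groups = data.frame(gene = universe, group = group,
                        stringsAsFactors = FALSE)
  )
}

#' Methylation-expression correlation by overlap group
#'
#' Computes the per-gene Pearson correlation between beta values and log2
#' expression over shared samples (complete cases per gene), partitions
#' genes into the four overlap groups from [classify_overlap], and
#' compares the correlation distributions with Kruskal-Wallis plus
#' pairwise Dunn tests (Bonferroni).
#'
#' @param expr gene x sample expression matrix (RSEM; transformed
#'   internally).
#' @param meth gene-level methylation matrix from [map_probes].
#' @param expr_results,meth_results outputs of [age_feature_regression].
#' @return list with `correlations` (data.frame `gene`, `group`, `r`) and
#'   `tests` (output of [rank_group_tests] across the groups).
#' @export
correlation_groups <- function(expr, meth, expr_results, meth_results) {
  samples <- intersect(colnames(expr), colnames(meth))
  if (length(samples) < 3)
    oa_stop("correlation_groups: fewer than 3 shared samples",
            class = "oncoage_validation_error")
  genes <- intersect(rownames(expr), rownames(meth))
  le <- log2(expr[genes, samples, drop = FALSE] + 1)
  mb <- meth[genes, samples, drop = FALSE]
  r <- vapply(genes, function(g) {
    x <- as.numeric(mb[g, ]); y <- as.numeric(le[g, ])
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(NA_real_)
    stats::cor(x[ok], y[ok])
  }, 0)
  grp <- classify_overlap(expr_results, meth_results)$groups
  cors <- data.frame(gene = genes,
                     group = grp$group[match(genes, grp$gene)],
                     r = as.numeric(r), stringsAsFactors = FALSE)
  cors <- cors[!is.na(cors$r) & !is.na(cors$group), , drop = FALSE]
  list(correlations = cors,
       tests = rank_group_tests(cors$r, cors$group, exact_max = 0))
}

#' Concordance of age coefficients between expression and methylation
#'
#' Pearson correlation, across the shared gene universe, between the
#' per-gene age coefficients of the two analyses.
#'
#' @param expr_results,meth_results outputs of [age_feature_regression].
#' @return list with `r`, `p`, `n`; `r` is `NA` (flagged undefined) when
#'   either coefficient vector is constant.
#' @export
coefficient_concordance <- function(expr_results, meth_results) {
  genes <- intersect(expr_results$feature, meth_results$feature)
  if (length(genes) < 3)
    oa_stop("coefficient_concordance: fewer than 3 shared genes",
            class = "oncoage_validation_error")
  x <- expr_results$coefficient[match(genes, expr_results$feature)]
  y <- meth_results$coefficient[match(genes, meth_results$feature)]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(list(r = NA_real_, p = NA_real_, n = length(genes)))
  ct <- stats::cor.test(x, y)
  list(r = unname(ct$estimate), p = ct$p.value, n = length(genes))
}

#' Ranked feature list for enrichment tools
#'
#' Features sorted by age coefficient, most positive first; exact ties
#' break lexicographically by feature ID.
#'
#' @param results output of [age_feature_regression].
#' @param path optional path; when given, the two-column (feature, score)
#'   list is written as TSV without header.
#' @return data.frame with columns `feature`, `score`.
#' @export
make_ranked_list <- function(results, path = NULL) {
  if (nrow(results) == 0)
    oa_stop("make_ranked_list: empty results",
            class = "oncoage_validation_error")
  ord <- order(-results$coefficient, results$feature)
  out <- data.frame(feature = results$feature[ord],
                    score = results$coefficient[ord],
                    stringsAsFactors = FALSE)
  if (!is.null(path))
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  out
}
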