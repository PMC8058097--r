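#' Age-association regression engine
#'
#' The statistical core of the package: per-cohort simple regressions of
#' an outcome on age, Benjamini-Hochberg screening across cohorts,
#' covariate-adjusted refits for the cohorts passing the screen, with
#' logistic models routed through separation detection and a
#' Firth-penalized fallback. Effect sizes for binary outcomes are odds
#' ratios per year of age with Wald 95% confidence intervals.
#'
#' @name association
NULL

#' Select covariates by missingness and information content
#'
#' Keeps candidate covariates whose missingness is strictly below
#' `max_missing` of the cohort and which take more than one distinct
#' non-missing value.
#'
#' @param clinical data.frame (typically a [clinical_table]).
#' @param candidates character vector of column names to consider;
#'   columns absent from `clinical` are ignored.
#' @param max_missing missingness threshold (default 0.10, strict `<`).
#' @return character vector of retained covariate names.
#' @export
covariate_select <- function(clinical, candidates, max_missing = 0.10) {
  if (length(candidates) == 0)
    oa_stop("covariate_select: empty candidate list")
  candidates <- intersect(candidates, names(clinical))
  keep <- vapply(candidates, function(v) {
    x <- clinical[[v]]
    mean(is.na(x)) < max_missing && length(unique(x[!is.na(x)])) > 1
  }, logical(1))
  candidates[keep]
}

# Categorical covariate preparation: pool levels carried by fewer than
# `min_level_n` samples into "other", set the most frequent level as the
# reference. Returns a factor, or NULL if only one level remains.
prepare_factor <- function(x, min_level_n = 5) {
  x <- as.character(x)
  counts <- table(x)
  rare <- names(counts)[counts < min_level_n]
  if (length(rare) && length(counts) > length(rare))
    x[x %in% rare] <- "other"
  counts <- sort(table(x), decreasing = TRUE)
  if (length(counts) < 2) return(NULL)
  factor(x, levels = names(counts))
}

# Build a complete-case model frame for outcome ~ predictor + covariates.
# Degenerate covariates (constant after complete-case filtering / rare-level
# pooling) are dropped with a warning.
build_model_frame <- function(data, outcome, covariates, predictor = "age") {
  require_columns(data, c(outcome, predictor), "model data")
  covariates <- intersect(covariates, names(data))
  cols <- c(outcome, predictor, covariates)
  d <- data[stats::complete.cases(data[, cols, drop = FALSE]), cols,
            drop = FALSE]
  used <- character()
  for (v in covariates) {
    if (is.numeric(d[[v]])) {
      if (stats::sd(d[[v]]) > 0) used <- c(used, v)
      else warning(sprintf("covariate '%s' constant; dropped", v))
    } else {
      f <- prepare_factor(d[[v]])
      if (is.null(f)) {
        warning(sprintf("covariate '%s' has a single level; dropped", v))
      } else {
        d[[v]] <- f
        used <- c(used, v)
      }
    }
  }
  list(data = d, covariates = used,
       formula = stats::reformulate(c(predictor, used), response = outcome))
}

association_row <- function(outcome, method, stage, n_used, coefficient,
                            se, p, binary, cohort = NA_character_,
                            adj_r_squared = NA_real_) {
  z <- stats::qnorm(0.975)
  data.frame(
    cohort = cohort, outcome = outcome, stage = stage, method = method,
    n_used = n_used, coefficient = coefficient, se = se,
    or_per_year = if (binary) exp(coefficient) else NA_real_,
    ci_low = if (binary) exp(coefficient - z * se) else coefficient - z * se,
    ci_high = if (binary) exp(coefficient + z * se) else coefficient + z * se,
    p = p, adj_p = NA_real_, adj_r_squared = adj_r_squared,
    stringsAsFactors = FALSE
  )
}

#' Ordinary least-squares age regression
#'
#' Fits `outcome ~ age + covariates` by OLS on complete cases and reports
#' the age term: per-year coefficient, two-sided t-test p, 95% CI and the
#' model's adjusted R-squared. Categorical covariates are dummy-expanded
#' with the most frequent level as reference (levels with fewer than 5
#' samples pooled into "other").
#'
#' @param data data.frame holding the outcome, `age` and covariates.
#' @param outcome outcome column name (continuous).
#' @param covariates character vector of covariate column names.
#' @param predictor predictor of interest (default `"age"`).
#' @return one-row data.frame (see [association] for the columns).
#' @export
fit_linear <- function(data, outcome, covariates = character(),
                       predictor = "age") {
  mf <- build_model_frame(data, outcome, covariates, predictor)
  d <- mf$data
  fit <- stats::lm(mf$formula, data = d)
  if (any(is.na(stats::coef(fit)))) {
    aliased <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    oa_stop(sprintf("rank-deficient design; aliased column(s): %s",
                    paste(aliased, collapse = ", ")),
            class = "oncoage_validation_error")
  }
  if (nrow(d) <= length(stats::coef(fit)))
    oa_stop("fit_linear: not enough complete cases for the design",
            class = "oncoage_validation_error")
  sm <- summary(fit)
  co <- sm$coefficients[predictor, ]
  association_row(outcome, "ols", NA_character_, nrow(d),
                  coefficient = co[["Estimate"]], se = co[["Std. Error"]],
                  p = co[["Pr(>|t|)"]], binary = FALSE,
                  adj_r_squared = sm$adj.r.squared)
}

#' Maximum-likelihood logistic age regression
#'
#' Fits `outcome ~ age + covariates` by ML logistic regression and
#' reports the age term as an odds ratio per year with Wald 95% CI and
#' two-sided Wald p. Errors when the outcome has a single class. When the
#' fit shows signs of separation, the returned row carries
#' `attr(, "separation") = TRUE`; callers should refit with [fit_firth].
#'
#' @inheritParams fit_linear
#' @param outcome binary (0/1 or logical) outcome column name.
#' @return one-row data.frame.
#' @export
fit_logistic <- function(data, outcome, covariates = character(),
                         predictor = "age") {
  mf <- build_model_frame(data, outcome, covariates, predictor)
  d <- mf$data
  y <- as.numeric(d[[outcome]])
  if (length(unique(y)) < 2)
    oa_stop("fit_logistic: outcome has a single class",
            class = "oncoage_validation_error")
  fit <- suppressWarnings(
    stats::glm(mf$formula, data = d, family = stats::binomial()))
  sm <- summary(fit)
  co <- sm$coefficients[predictor, ]
  out <- association_row(outcome, "logistic", NA_character_, nrow(d),
                         coefficient = co[["Estimate"]],
                         se = co[["Std. Error"]],
                         p = co[["Pr(>|z|)"]], binary = TRUE)
  X <- stats::model.matrix(mf$formula, d)
  attr(out, "separation") <- detect_separation_matrix(y, X)
  out
}

# Core Firth-penalized fit on a design matrix (first column = intercept).
# Newton iterations on the penalized score with hat-diagonal adjustment
# and step-halving; converges when the penalized score norm drops below
# `tol`.
firth_fit <- function(X, y, tol = 1e-8, max_iter = 50) {
  p <- ncol(X)
  beta <- numeric(p)
  penalized_loglik <- function(beta) {
    eta <- drop(X %*% beta)
    pi <- stats::plogis(eta)
    W <- pi * (1 - pi)
    I <- crossprod(X * W, X)
    sum(y * eta - log1p(exp(eta))) + 0.5 * determinant(I)$modulus
  }
  ll <- penalized_loglik(beta)
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    pi <- stats::plogis(eta)
    W <- pi * (1 - pi)
    XW <- X * W
    I <- crossprod(XW, X)
    # hat diagonal of W^(1/2) X (X'WX)^-1 X' W^(1/2)
    XI <- X %*% solve(I)
    h <- rowSums(XI * XW)
    U <- drop(crossprod(X, y - pi + h * (0.5 - pi)))
    if (max(abs(U)) < tol) {
      return(list(coefficients = beta, var = solve(I), iter = iter - 1,
                  converged = TRUE, loglik = ll))
    }
    step <- drop(solve(I, U))
    # step-halving to keep the penalized log-likelihood non-decreasing
    for (half in 0:25) {
      cand <- beta + step / 2^half
      ll_new <- penalized_loglik(cand)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
    }
    beta <- cand
    ll <- ll_new
  }
  # final score check after the last update
  eta <- drop(X %*% beta)
  pi <- stats::plogis(eta)
  W <- pi * (1 - pi)
  I <- crossprod(X * W, X)
  XI <- X %*% solve(I)
  h <- rowSums(XI * (X * W))
  U <- drop(crossprod(X, y - pi + h * (0.5 - pi)))
  if (max(abs(U)) < tol) {
    return(list(coefficients = beta, var = solve(I), iter = max_iter,
                converged = TRUE, loglik = ll))
  }
  oa_stop(sprintf(
    "Firth fit did not converge in %d iterations (score norm %.3g)",
    max_iter, max(abs(U))), class = "oncoage_convergence_error")
}

#' Firth-penalized logistic age regression
#'
#' Maximizes the penalized log-likelihood `l(beta) + 0.5 log|I(beta)|`
#' (Jeffreys-prior penalty) by Newton iterations on the hat-diagonal
#' adjusted score. Estimates are finite even under complete separation.
#' Wald 95% CIs are computed from the penalized-fit information matrix.
#'
#' @inheritParams fit_logistic
#' @param tol convergence tolerance on the penalized score norm.
#' @param max_iter Newton iteration cap.
#' @return one-row data.frame with `method = "firth"`.
#' @export
fit_firth <- function(data, outcome, covariates = character(),
                      predictor = "age", tol = 1e-8, max_iter = 50) {
  mf <- build_model_frame(data, outcome, covariates, predictor)
  d <- mf$data
  y <- as.numeric(d[[outcome]])
  if (length(unique(y)) < 2)
    oa_stop("fit_firth: outcome has a single class",
            class = "oncoage_validation_error")
  X <- stats::model.matrix(mf$formula, d)
  fit <- firth_fit(X, y, tol = tol, max_iter = max_iter)
  j <- match(predictor, colnames(X))
  se <- sqrt(diag(fit$var))[j]
  beta <- fit$coefficients[j]
  association_row(outcome, "firth", NA_character_, nrow(d),
                  coefficient = beta, se = se,
                  p = 2 * stats::pnorm(-abs(beta / se)), binary = TRUE)
}

# Separation check on an explicit design matrix: refit ML with two
# iteration budgets; infinite estimates keep growing on a standardized
# scale while the log-likelihood plateaus, finite estimates stabilise.
detect_separation_matrix <- function(y, X, bound = 15) {
  sds <- apply(X, 2, stats::sd)
  scale_to_sd <- ifelse(sds > 0, sds, 1)
  fit_at <- function(maxit) {
    f <- suppressWarnings(stats::glm.fit(
      X, y, family = stats::binomial(),
      control = stats::glm.control(maxit = maxit, epsilon = 1e-12)))
    f$coefficients * scale_to_sd
  }
  b50 <- fit_at(50)
  b100 <- fit_at(100)
  keep <- sds > 0  # ignore the intercept column for the bound
  grew <- max(abs(b100[keep] - b50[keep])) > 0.1
  max(abs(b100[keep])) > bound || (grew && max(abs(b100[keep])) > bound / 2)
}

#' Detect separation in a logistic design
#'
#' Diagnoses (quasi-)complete separation: the ML coefficient path
#' diverges, i.e. standardized coefficients grow beyond a bound while the
#' likelihood plateaus. Used to route fits to [fit_firth].
#'
#' @inheritParams fit_logistic
#' @param bound divergence bound on standardized coefficients.
#' @return logical.
#' @export
detect_separation <- function(data, outcome, covariates = character(),
                              predictor = "age", bound = 15) {
  mf <- build_model_frame(data, outcome, covariates, predictor)
  y <- as.numeric(mf$data[[outcome]])
  X <- stats::model.matrix(mf$formula, mf$data)
  detect_separation_matrix(y, X, bound)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param pvals numeric vector of p values in `[0, 1]` (`NA` allowed and
#'   propagated).
#' @return adjusted p values, clipped at 1.
#' @export
bh_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE))
    oa_stop("bh_adjust: p value outside [0, 1]",
            class = "oncoage_validation_error")
  stats::p.adjust(pvals, method = "BH")
}

#' Screen-then-adjust regression cascade
#'
#' Stage 1 fits the simple (age-only) model per cohort and adjusts the
#' stage-1 p values across cohorts by Benjamini-Hochberg. Cohorts with
#' stage-1 `adj_p < adj_cutoff` are refit in stage 2 with the covariates
#' retained by [covariate_select] plus tumour purity (when available).
#' Binary stage-2 models are routed through [detect_separation] and fall
#' back to [fit_firth] when separation is diagnosed.
#'
#' @param data data.frame with one row per sample: outcome, `age`, a
#'   cohort column, candidate covariates, optionally `purity`.
#' @param outcome outcome column name.
#' @param type `"continuous"` or `"binary"`.
#' @param cohort_col cohort (cancer type) column name.
#' @param candidates candidate covariate names for stage 2.
#' @param adj_cutoff BH-adjusted significance cutoff (default 0.05).
#' @param min_n smallest cohort size fitted (smaller cohorts skipped).
#' @return data.frame of association rows, stages labelled `screen` /
#'   `adjusted`; stage-1 rows carry the across-cohort `adj_p`.
#' @export
screen_then_adjust <- function(data, outcome,
                               type = c("continuous", "binary"),
                               cohort_col = "cancer_type",
                               candidates = c("gender", "race", "stage",
                                              "grade", "smoking", "alcohol"),
                               adj_cutoff = 0.05, min_n = 10) {
  type <- match.arg(type)
  require_columns(data, c(outcome, "age", cohort_col), "association data")
  cohorts <- split(data, data[[cohort_col]])
  fit_simple <- function(d) {
    if (type == "continuous") fit_linear(d, outcome)
    else if (detect_separation(d, outcome)) fit_firth(d, outcome)
    else fit_logistic(d, outcome)
  }
  stage1 <- list()
  for (ct in names(cohorts)) {
    d <- cohorts[[ct]]
    d <- d[!is.na(d[[outcome]]) & !is.na(d$age), , drop = FALSE]
    if (nrow(d) < min_n) next
    if (type == "binary" && length(unique(d[[outcome]])) < 2) next
    row <- fit_simple(d)
    row$cohort <- ct
    row$stage <- "screen"
    stage1[[ct]] <- row
  }
  if (length(stage1) == 0)
    oa_stop("screen_then_adjust: no fittable cohort",
            class = "oncoage_validation_error")
  s1 <- do.call(rbind, stage1)
  s1$adj_p <- bh_adjust(s1$p)
  hits <- s1$cohort[s1$adj_p < adj_cutoff]
  stage2 <- list()
  for (ct in hits) {
    d <- cohorts[[ct]]
    covs <- covariate_select(d, candidates)
    if ("purity" %in% names(d) &&
        mean(is.na(d$purity)) < 0.10) covs <- c(covs, "purity")
    row <- withCallingHandlers({
      if (type == "continuous") fit_linear(d, outcome, covs)
      else if (detect_separation(d, outcome, covs)) fit_firth(d, outcome, covs)
      else fit_logistic(d, outcome, covs)
    }, warning = function(w) invokeRestart("muffleWarning"))
    row$cohort <- ct
    row$stage <- "adjusted"
    stage2[[ct]] <- row
  }
  s2 <- if (length(stage2)) {
    s2 <- do.call(rbind, stage2)
    s2$adj_p <- bh_adjust(s2$p)  # BH across the promoted cohorts
    s2
  }
  out <- rbind(s1, s2)
  rownames(out) <- NULL
  out
}

# Exact permutation p for the Kruskal-Wallis statistic by enumeration of
# all distinct assignments of the pooled observations to the group sizes.
kw_exact_p <- function(values, groups) {
  n <- length(values)
  sizes <- table(groups)
  obs <- kw_stat(values, groups)
  idx <- seq_len(n)
  count <- 0L
  total <- 0L
  # enumerate assignments group by group via combinations
  recurse <- function(remaining, sizes_left, assign) {
    if (length(sizes_left) == 1) {
      assign[remaining] <- names(sizes_left)[1]
      total <<- total + 1L
      if (kw_stat(values, assign) >= obs - 1e-12) count <<- count + 1L
      return(invisible())
    }
    g <- names(sizes_left)[1]
    for (pick in utils::combn(length(remaining), sizes_left[[1]],
                              simplify = FALSE)) {
      assign2 <- assign
      assign2[remaining[pick]] <- g
      recurse(remaining[-pick], sizes_left[-1], assign2)
    }
  }
  recurse(idx, as.list(sizes), character(n))
  count / total
}

# Tie-corrected Kruskal-Wallis H statistic
kw_stat <- function(values, groups) {
  r <- rank(values)
  n <- length(values)
  g <- split(r, groups)
  H <- 12 / (n * (n + 1)) * sum(vapply(g, function(ri)
    sum(ri)^2 / length(ri), 0)) - 3 * (n + 1)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr > 0) H / corr else 0
}

#' Nonparametric group comparisons: Kruskal-Wallis, Dunn, Wilcoxon
#'
#' Tie-corrected Kruskal-Wallis H with its chi-square p value; pairwise
#' Dunn z tests on pooled ranks (tie-corrected, two-sided,
#' Bonferroni-multiplied p); for two groups additionally the Wilcoxon
#' rank-sum p. For small pooled samples (`n <= exact_max`) an exact
#' permutation p for H, obtained by full enumeration of group
#' assignments, is reported alongside the asymptotic one.
#'
#' @param values numeric vector.
#' @param groups group labels, aligned with `values`; at least two
#'   non-empty groups.
#' @param exact_max largest pooled n for which the exact permutation p is
#'   enumerated (default 10; `0` disables).
#' @return list with `kruskal_H`, `kw_p`, `kw_p_exact` (or `NA`), `dunn`
#'   (data.frame: `group1`, `group2`, `z`, `p`, `adj_p`), and
#'   `wilcoxon_p` for the two-group case.
#' @export
rank_group_tests <- function(values, groups, exact_max = 10) {
  if (!is.factor(groups)) groups <- factor(groups)
  if (nlevels(groups) < 2 || any(table(groups) == 0))
    oa_stop("rank_group_tests: need >= 2 non-empty groups",
            class = "oncoage_validation_error")
  stopifnot(length(values) == length(groups))
  if (length(unique(values)) == 1) {
    # fully tied input: no evidence of any group difference
    pairs <- utils::combn(levels(groups), 2, simplify = FALSE)
    dunn <- do.call(rbind, lapply(pairs, function(pr)
      data.frame(group1 = pr[1], group2 = pr[2], z = 0, p = 1, adj_p = 1,
                 stringsAsFactors = FALSE)))
    return(list(kruskal_H = 0, kw_p = 1, kw_p_exact = NA_real_, dunn = dunn,
                wilcoxon_p = if (nlevels(groups) == 2) 1 else NA_real_))
  }
  kw <- stats::kruskal.test(values, groups)
  n <- length(values)
  r <- rank(values)
  rbar <- tapply(r, groups, mean)
  sizes <- table(groups)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (n - 1))
  pairs <- utils::combn(levels(groups), 2, simplify = FALSE)
  dunn <- do.call(rbind, lapply(pairs, function(pr) {
    sigma <- sqrt((n * (n + 1) / 12 - tie_term) *
                  (1 / sizes[[pr[1]]] + 1 / sizes[[pr[2]]]))
    z <- (rbar[[pr[1]]] - rbar[[pr[2]]]) / sigma
    data.frame(group1 = pr[1], group2 = pr[2], z = z,
               p = 2 * stats::pnorm(-abs(z)), stringsAsFactors = FALSE)
  }))
  dunn$adj_p <- pmin(1, dunn$p * nrow(dunn))
  list(
    kruskal_H = unname(kw$statistic),
    kw_p = kw$p.value,
    kw_p_exact = if (n <= exact_max) kw_exact_p(values, groups) else NA_real_,
    dunn = dunn,
    wilcoxon_p = if (nlevels(groups) == 2)
      suppressWarnings(stats::wilcox.test(values ~ groups)$p.value)
    else NA_real_
  )
}
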