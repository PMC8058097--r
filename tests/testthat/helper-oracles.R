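# Independent oracles used to cross-check the package implementations.
# Everything here is written from the definitions, not from the package
# code paths it validates.

# Benjamini-Hochberg step-up from the definition: sort p ascending,
# q_(i) = min over j >= i of p_(j) * m / j, clipped at 1, unsorted.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  q <- ps * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  q <- pmin(q, 1)
  out <- numeric(m)
  out[o] <- q
  out
}

# Two-sided Fisher exact p by full enumeration of 2x2 tables with the
# observed margins: sum of hypergeometric probabilities not exceeding
# the observed table's probability.
fisher_oracle <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- a + b + c + d
  amin <- max(0, c1 - r2); amax <- min(r1, c1)
  probs <- vapply(amin:amax, function(x) stats::dhyper(x, r1, r2, c1), 0)
  obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Firth-penalized log-odds-ratio for a saturated 2x2 (binary predictor):
# equivalent to adding 0.5 to every cell.
firth_2x2_beta <- function(a, b, c, d) {
  log(((a + 0.5) * (d + 0.5)) / ((b + 0.5) * (c + 0.5)))
}

# Penalized log-likelihood of an intercept+slope logistic model, used for
# grid verification of the Firth maximizer.
firth_penalized_ll <- function(beta, X, y) {
  eta <- drop(X %*% beta)
  pi <- stats::plogis(eta)
  I <- crossprod(X * (pi * (1 - pi)), X)
  sum(y * eta - log1p(exp(eta))) + 0.5 * as.numeric(determinant(I)$modulus)
}

# Expand a 2x2 table (exposed/unexposed x case/control) into per-subject
# binary predictor x and outcome y.
expand_2x2 <- function(a, b, c, d) {
  # x = 1 rows: a cases, b controls; x = 0 rows: c cases, d controls
  list(x = c(rep(1, a + b), rep(0, c + d)),
       y = c(rep(1, a), rep(0, b), rep(1, c), rep(0, d)))
}

# Brute-force SCNA scores: independent recomputation from the raw event
# lists, enumerating events directly with explicit loops.
scna_brute <- function(broad, focal, cohorts, model, eps = 1e-9) {
  classify <- function(r) {
    if (r >= 1) 2 else if (r >= 0.25) 1 else if (r >= -0.25) 0
    else if (r >= -1) -1 else -2
  }
  res <- data.frame(sample = cohorts$sample,
                    cancer_type = cohorts$cancer_type,
                    focal_raw = 0, arm_raw = 0, chrom_raw = 0)
  for (i in seq_len(nrow(res))) {
    s <- res$sample[i]
    if (!is.null(focal)) {
      fs <- focal[focal$sample == s, , drop = FALSE]
      for (j in seq_len(nrow(fs)))
        res$focal_raw[i] <- res$focal_raw[i] + abs(classify(fs$log2_ratio[j]))
    }
    if (!is.null(broad)) {
      bs <- broad[broad$sample == s, , drop = FALSE]
      for (chrom in unique(bs$chromosome)) {
        cs <- bs[bs$chromosome == chrom, , drop = FALSE]
        if (nrow(cs) == 2 && abs(cs$log2_ratio[1] - cs$log2_ratio[2]) <= eps) {
          res$chrom_raw[i] <- res$chrom_raw[i] + abs(classify(cs$log2_ratio[1]))
        } else {
          for (j in seq_len(nrow(cs)))
            res$arm_raw[i] <- res$arm_raw[i] + abs(classify(cs$log2_ratio[j]))
        }
      }
    }
  }
  for (ct in unique(res$cancer_type)) {
    idx <- which(res$cancer_type == ct)
    for (lev in c("focal", "arm", "chrom")) {
      raw <- res[[paste0(lev, "_raw")]][idx]
      res[idx, paste0(lev, "_norm")] <- rank(raw) / length(raw)
    }
  }
  res$chrom_arm <- res$arm_norm + res$chrom_norm
  res$overall <- res$focal_norm + res$chrom_arm
  res
}

# Monte-Carlo permutation p value for the tie-corrected Kruskal-Wallis
# statistic (independent of the package's exact enumeration).
kw_perm_mc <- function(values, groups, B = 20000) {
  H <- function(v, g) {
    r <- rank(v); n <- length(v)
    s <- tapply(r, g, function(ri) sum(ri)^2 / length(ri))
    h <- 12 / (n * (n + 1)) * sum(s) - 3 * (n + 1)
    t <- table(v)
    corr <- 1 - sum(t^3 - t) / (n^3 - n)
    if (corr > 0) h / corr else 0
  }
  obs <- H(values, groups)
  hits <- 0L
  for (b in seq_len(B)) {
    if (H(values, sample(groups)) >= obs - 1e-12) hits <- hits + 1L
  }
  hits / B
}

# One-predictor (quasi-)complete separation check by direct inspection.
separable_1d <- function(x, y) {
  x1 <- x[y == 1]; x0 <- x[y == 0]
  max(x0) <= min(x1) || max(x1) <= min(x0)
}

# Small segment-profile constructor for metric tests.
make_profile <- function(states, lens, sample_id = "T1", chrom = "1",
                         wgd = NA) {
  starts <- cumsum(c(1, head(lens, -1)))
  segment_profile(sample_id, data.frame(
    chromosome = chrom, start = starts, end = starts + lens - 1,
    n_major = vapply(states, `[`, 0, 1),
    n_minor = vapply(states, `[`, 0, 2)), wgd = wgd)
}
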