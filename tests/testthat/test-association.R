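test_that("covariate selection applies the strict <10% missingness bar", {
  n <- 100
  clin <- data.frame(
    sample_id = paste0("S", 1:n), age = 50,
    keep9 = c(rep(NA, 9), sample(c("a", "b"), n - 9, TRUE)),
    drop10 = c(rep(NA, 10), sample(c("a", "b"), n - 10, TRUE)),
    constant = "x")
  got <- covariate_select(clin, c("keep9", "drop10", "constant", "absent"))
  expect_equal(got, "keep9")
})

test_that("linear fits report the age term exactly on noiseless data", {
  d <- data.frame(age = c(0, 1, 2), y = c(0, 1, 2))
  res <- suppressWarnings(fit_linear(d, "y"))  # noiseless fit warns in lm
  expect_equal(res$coefficient, 1)
  expect_equal(res$adj_r_squared, 1)
  expect_equal(res$n_used, 3)
  # aliased covariate is reported by name
  d2 <- data.frame(age = rnorm(20), y = rnorm(20))
  d2$age_copy <- d2$age
  expect_error(fit_linear(d2, "y", "age_copy"), "age_copy",
               class = "oncoage_validation_error")
})

test_that("null linear p values are uniform and planted slopes are covered", {
  set.seed(101)
  reps <- 300
  pvals <- numeric(reps)
  cover <- logical(reps)
  for (i in seq_len(reps)) {
    age <- runif(100, 30, 85)
    y_null <- rnorm(100)
    pvals[i] <- fit_linear(data.frame(age = age, y = y_null), "y")$p
    y_eff <- 0.2 * age + rnorm(100, 0, 2)
    r <- fit_linear(data.frame(age = age, y = y_eff), "y")
    cover[i] <- r$ci_low <= 0.2 && 0.2 <= r$ci_high
  }
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.001)
  expect_true(abs(mean(pvals < 0.05) - 0.05) < 0.04)
  expect_gt(mean(cover), 0.90)
})

test_that("logistic fit on a 2x2 recovers the ad/bc odds ratio", {
  dat <- expand_2x2(20, 10, 5, 25)
  res <- fit_logistic(data.frame(age = dat$x, y = dat$y), "y")
  expect_equal(res$or_per_year, (20 * 25) / (10 * 5), tolerance = 1e-6)
  expect_false(attr(res, "separation"))
  one_class <- data.frame(age = rnorm(10), y = 1)
  expect_error(fit_logistic(one_class, "y"),
               class = "oncoage_validation_error")
  # perfectly separated data raise the separation signal
  sep <- data.frame(age = c(1:5, 11:15), y = rep(c(0, 1), each = 5))
  expect_true(attr(fit_logistic(sep, "y"), "separation"))
})

test_that("separation detection matches a brute-force 1D separability check", {
  sep <- data.frame(age = c(1:5, 11:15), y = rep(c(0, 1), each = 5))
  expect_true(detect_separation(sep, "y"))
  set.seed(13)
  mixed <- data.frame(age = rnorm(60), y = rbinom(60, 1, 0.5))
  expect_false(detect_separation(mixed, "y"))
  checked <- 0
  while (checked < 30) {
    n <- sample(4:8, 1)
    x <- sample(1:10, n, replace = TRUE)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2 || sd(x) == 0) next
    # skip designs where x is constant within a class boundary ambiguity
    checked <- checked + 1
    expect_equal(detect_separation(data.frame(age = x, y = y), "y"),
                 separable_1d(x, y),
                 info = sprintf("x=%s y=%s", paste(x, collapse = ","),
                                paste(y, collapse = ",")))
  }
})

test_that("Firth fits match the 0.5-cell closed form and a grid search", {
  # quasi-separated table from the closed form
  dat <- expand_2x2(5, 0, 2, 10)
  res <- fit_firth(data.frame(age = dat$x, y = dat$y), "y")
  expect_equal(res$coefficient, firth_2x2_beta(5, 0, 2, 10),
               tolerance = 1e-7)
  expect_equal(res$coefficient, log((5.5 * 10.5) / (0.5 * 2.5)),
               tolerance = 1e-7)
  # grid verification: the fitted point maximizes the penalized likelihood
  X <- cbind(1, dat$x)
  fit <- oncoage:::firth_fit(X, dat$y)
  ll_hat <- firth_penalized_ll(fit$coefficients, X, dat$y)
  grid <- expand.grid(d0 = c(-0.1, 0, 0.1), d1 = c(-0.1, 0, 0.1))
  for (i in seq_len(nrow(grid))) {
    if (grid$d0[i] == 0 && grid$d1[i] == 0) next
    expect_lt(firth_penalized_ll(fit$coefficients + c(grid$d0[i], grid$d1[i]),
                                 X, dat$y), ll_hat)
  }
  # intercept-only fit equals the Jeffreys closed form log((k+.5)/(n-k+.5))
  y <- c(rep(1, 3), rep(0, 7))
  f <- oncoage:::firth_fit(matrix(1, 10, 1), y)
  expect_equal(f$coefficients, log(3.5 / 7.5), tolerance = 1e-8)
  # complete separation still yields finite estimates
  sep <- data.frame(age = c(1:5, 6:10), y = rep(c(0, 1), each = 5))
  expect_true(is.finite(fit_firth(sep, "y")$coefficient))
})

test_that("Firth and ML agree on large well-conditioned data", {
  set.seed(202)
  n <- 4000
  age <- runif(n, 30, 85)
  y <- rbinom(n, 1, plogis(-1.7 + 0.03 * age))
  d <- data.frame(age = age, y = y)
  ml <- fit_logistic(d, "y")
  fi <- fit_firth(d, "y")
  expect_lt(abs(ml$coefficient - fi$coefficient), 0.01)
})

test_that("BH adjustment equals the step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "oncoage_validation_error")
  set.seed(303)
  for (rep in 1:50) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(adj >= p & adj <= 1))
    # permutation equivariance
    o <- sample(length(p))
    expect_equal(bh_adjust(p[o]), adj[o])
  }
})

test_that("screen-then-adjust promotes only the cohort with a planted effect", {
  set.seed(404)
  hits <- 0
  reps <- 20
  for (r in seq_len(reps)) {
    cohorts <- lapply(1:6, function(k) {
      age <- runif(120, 30, 85)
      y <- if (k == 1) 0.08 * age + rnorm(120) else rnorm(120)
      data.frame(sample_id = sprintf("C%d_%03d", k, 1:120), age = age,
                 y = y, cancer_type = paste0("C", k),
                 gender = sample(c("f", "m"), 120, TRUE),
                 purity = rbeta(120, 5, 2))
    })
    res <- screen_then_adjust(do.call(rbind, cohorts), "y", "continuous")
    adj <- res[res$stage == "adjusted", ]
    if (nrow(adj) >= 1 && "C1" %in% adj$cohort) hits <- hits + 1
    # a cohort failing the screen never reaches stage 2
    failed <- res$cohort[res$stage == "screen" & res$adj_p >= 0.05]
    expect_false(any(failed %in% adj$cohort))
    expect_true(all(res$adj_p >= res$p - 1e-15))
  }
  expect_gte(hits / reps, 0.95)
})

test_that("binary cascades route separated cohorts through Firth", {
  set.seed(505)
  age <- c(30:59, 61:90)
  d <- data.frame(sample_id = paste0("S", seq_along(age)), age = age,
                  y = as.integer(age > 60), cancer_type = "A")
  res <- screen_then_adjust(d, "y", "binary")
  expect_equal(res$method[res$stage == "screen"], "firth")
  expect_true(all(is.finite(res$coefficient)))
  expect_true(all(res$ci_low <= res$or_per_year &
                  res$or_per_year <= res$ci_high))
})

test_that("rank group tests reproduce the H formula, Dunn z and Wilcoxon", {
  out <- rank_group_tests(c(1, 2, 3, 4, 5, 6),
                          rep(c("a", "b"), each = 3))
  expect_equal(out$kruskal_H, 12 / 42 * (36 / 3 + 225 / 3) - 21,
               tolerance = 1e-12)
  expect_equal(out$kruskal_H, 3.857, tolerance = 1e-3)
  expect_equal(out$wilcoxon_p,
               stats::wilcox.test(1:3, 4:6)$p.value)
  # identical constant groups: no evidence
  flat <- rank_group_tests(rep(2, 6), rep(c("a", "b"), 3))
  expect_equal(flat$kruskal_H, 0)
  expect_equal(flat$kw_p, 1)
  expect_error(rank_group_tests(1:3, c("a", "a", "a")),
               class = "oncoage_validation_error")
  # Dunn z against direct pooled-rank computation for 3 groups
  set.seed(606)
  v <- c(rnorm(4), rnorm(5, 1), rnorm(3, 2))
  g <- rep(c("g1", "g2", "g3"), c(4, 5, 3))
  out <- rank_group_tests(v, g, exact_max = 0)
  r <- rank(v); n <- length(v)
  sigma <- sqrt((n * (n + 1) / 12) * (1 / 4 + 1 / 5))  # no ties
  z_hand <- (mean(r[g == "g1"]) - mean(r[g == "g2"])) / sigma
  expect_equal(out$dunn$z[out$dunn$group1 == "g1" &
                          out$dunn$group2 == "g2"], z_hand,
               tolerance = 1e-12)
  expect_equal(out$dunn$adj_p, pmin(1, out$dunn$p * 3))
})

test_that("exact permutation p agrees with a Monte-Carlo oracle at small n", {
  set.seed(707)
  v <- c(1.2, 0.4, 2.2, 1.7, 0.1, 2.9, 1.1)
  g <- rep(c("a", "b"), c(3, 4))
  out <- rank_group_tests(v, g)
  mc <- kw_perm_mc(v, g, B = 20000)
  se <- sqrt(mc * (1 - mc) / 20000)
  expect_lt(abs(out$kw_p_exact - mc), 4 * se + 1e-6)
})
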