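test_that("log2 classification uses the five half-open bands", {
  expect_equal(classify_log2(c(1.0, 0.25, -0.25)), c(2L, 1L, 0L))
  expect_equal(classify_log2(c(-1.0, -1.001)), c(-1L, -2L))
  expect_equal(classify_log2(0), 0L)
  expect_equal(classify_log2(c(2.7, 0.9999, 0.2499, -0.9999, -5)),
               c(2L, 1L, 0L, -1L, -2L))
  expect_error(classify_log2(NaN), class = "oncoage_validation_error")
})

test_that("broad events split into chromosome- vs arm-level", {
  tm <- toy_arm_model()
  broad <- data.frame(sample = "S1", arm = c("1p", "1q"),
                      chromosome = "1", log2_ratio = c(0.5, 0.5))
  ev <- split_broad_events(broad, tm)
  expect_equal(ev$level, "chromosome")
  expect_equal(ev$log2_ratio, 0.5)

  broad$log2_ratio <- c(0.5, 0.0)
  ev <- split_broad_events(broad, tm)
  expect_equal(sort(ev$level), c("arm", "arm"))

  acro <- data.frame(sample = "S1", arm = "13q", chromosome = "13",
                     log2_ratio = -0.3)
  ev <- split_broad_events(acro, tm)
  expect_equal(ev$level, "arm")
  expect_equal(ev$score_class, -1L)
})

test_that("raw level scores sum absolute classes", {
  ev <- data.frame(level = "focal", score_class = classify_log2(c(1.3, -0.5)))
  expect_equal(raw_level_score(ev, "focal"), 3)
  expect_equal(raw_level_score(ev[0, ], "focal"), 0L)
  zero <- data.frame(level = "focal", score_class = rep(0L, 4))
  expect_equal(raw_level_score(zero, "focal"), 0)
  mixed <- data.frame(level = c("focal", "arm"), score_class = c(1L, 1L))
  expect_error(raw_level_score(mixed, "focal"),
               class = "oncoage_validation_error")
})

test_that("rank normalisation follows rank/N with average-rank ties", {
  expect_equal(rank_normalize(c(5, 1, 3)), c(1, 1/3, 2/3))
  expect_equal(rank_normalize(c(2, 2, 5)), c(0.5, 0.5, 1))
  expect_equal(rank_normalize(7), 1)
  expect_error(rank_normalize(numeric()), class = "oncoage_validation_error")
  # invariance under strictly monotone transforms
  set.seed(5)
  x <- rnorm(30)
  expect_equal(rank_normalize(x), rank_normalize(exp(2 * x + 1)))
  # mean is (N+1)/(2N) for distinct raw scores
  expect_equal(mean(rank_normalize(sample(100, 17))), 18 / 34)
})

test_that("scna_scores handles degenerate cohorts and the overall identity", {
  tm <- toy_arm_model()
  one <- data.frame(sample = "S1", cancer_type = "A")
  sc <- scna_scores(NULL, NULL, one, tm)
  expect_equal(sc$overall, 3)  # every level rank-normalises to 1

  # full tie: every *_norm is (N+1)/(2N)
  n <- 4
  cohorts <- data.frame(sample = paste0("S", 1:n), cancer_type = "A")
  broad <- do.call(rbind, lapply(cohorts$sample, function(s)
    data.frame(sample = s, arm = c("1p", "1q"), chromosome = "1",
               log2_ratio = c(0.5, 0.3))))
  sc <- scna_scores(broad, NULL, cohorts, tm)
  expect_equal(sc$arm_norm, rep((n + 1) / (2 * n), n))
  expect_equal(sc$overall, sc$focal_norm + sc$chrom_arm)

  # class-0 events change nothing
  broad0 <- rbind(broad, data.frame(sample = cohorts$sample, arm = "2p",
                                    chromosome = "2", log2_ratio = 0.1))
  expect_equal(scna_scores(broad0, NULL, cohorts, tm)$overall, sc$overall)

  # unknown event sample is an error
  bad <- data.frame(sample = "ghost", log2_ratio = 1)
  expect_error(scna_scores(NULL, bad, cohorts, tm),
               class = "oncoage_validation_error")
})

test_that("scores match a brute-force recomputation on random small cohorts", {
  tm <- toy_arm_model()
  set.seed(99)
  for (case in 1:40) {
    n <- sample(1:6, 1)
    cohorts <- data.frame(sample = paste0("S", 1:n),
                          cancer_type = sample(c("A", "B"), n, replace = TRUE))
    broad <- do.call(rbind, lapply(cohorts$sample, function(s) {
      arms <- sample(arm_labels(tm), sample(0:4, 1))
      if (!length(arms)) return(NULL)
      data.frame(sample = s, arm = arms, chromosome = sub("[pq]$", "", arms),
                 log2_ratio = sample(c(-1.2, -0.5, 0, 0.3, 0.5, 1.1),
                                     length(arms), replace = TRUE))
    }))
    focal <- do.call(rbind, lapply(cohorts$sample, function(s) {
      k <- sample(0:4, 1)
      if (!k) return(NULL)
      data.frame(sample = s,
                 log2_ratio = sample(c(-1.2, -0.5, 0.3, 1.1), k, TRUE))
    }))
    got <- scna_scores(broad, focal, cohorts, tm)
    want <- scna_brute(broad, focal, cohorts, tm)
    expect_equal(got[order(got$sample), c("focal_raw", "arm_raw", "chrom_raw",
                                          "focal_norm", "arm_norm",
                                          "chrom_norm", "overall")],
                 want[order(want$sample), c("focal_raw", "arm_raw",
                                            "chrom_raw", "focal_norm",
                                            "arm_norm", "chrom_norm",
                                            "overall")],
                 ignore_attr = TRUE)
  }
})

test_that("focal regions overlapping centromeres or telomeres are dropped", {
  tm <- toy_arm_model()  # chr1: len 1e6, cen [450001, 550000]
  regions <- data.frame(
    chromosome = "1",
    start = c(440000, 300000, 1, 990001, 560001, 100),
    end =   c(460000, 400000, 10000, 1000000, 980000, 9000),
    name = c("spans_cen", "mid_arm", "left_tel", "right_tel",
             "clears_both", "inside_tel"))
  kept <- filter_focal_regions(regions, tm, telomere_width = 1e4)
  expect_setequal(kept$name, c("mid_arm", "clears_both"))
  # region ending exactly at the telomere-window boundary is kept
  edge <- data.frame(chromosome = "1", start = 10001, end = 20000)
  expect_equal(nrow(filter_focal_regions(edge, tm, 1e4)), 1)
  outside <- data.frame(chromosome = "1", start = 999999, end = 1000001)
  expect_error(filter_focal_regions(outside, tm),
               class = "oncoage_validation_error")
})

test_that("SCNA-expression correlation matches the product-moment formula", {
  scores <- matrix(c(-1, 0, 1, 2), 1, dimnames = list("G1", paste0("S", 1:4)))
  le <- c(1, 1, 2, 4)                      # intended log2(RSEM + 1) values
  expr <- matrix(2^le - 1, 1, dimnames = dimnames(scores))
  res <- scna_expr_correlation(scores, expr)
  x <- scores[1, ]; y <- le
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$pearson_r, r_hand, tolerance = 1e-12)

  # exact linear relation gives r = 1
  lin <- matrix(2^(2 * scores[1, ] + 3) - 1, 1, dimnames = dimnames(scores))
  expect_equal(scna_expr_correlation(scores, lin)$pearson_r, 1)

  # constant expression is flagged undefined and leaves the BH family
  const <- matrix(5, 1, 4, dimnames = dimnames(scores))
  res <- scna_expr_correlation(scores, const)
  expect_false(res$defined)
  expect_true(is.na(res$adj_p))
})
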