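make_expr <- function(m) omics_matrix(m, "expression")

test_that("expression filter applies the strict >50% positive rule", {
  m <- matrix(0, 3, 100,
              dimnames = list(c("keep51", "drop50", "allzero"),
                              paste0("S", 1:100)))
  m["keep51", 1:51] <- 1
  m["drop50", 1:50] <- 1
  out <- filter_expressed(make_expr(m))
  expect_equal(rownames(out), "keep51")
  expect_error(filter_expressed(omics_matrix(
    matrix(0.5, 1, 3, dimnames = list("cg1", paste0("S", 1:3))),
    "methylation")), class = "oncoage_validation_error")
})

test_that("log2 transform is log2(x + 1) everywhere", {
  expect_equal(log2_expr(matrix(c(0, 1, 7))), matrix(c(0, 1, 3)))
  expect_error(log2_expr(matrix(-1)), class = "oncoage_validation_error")
})

test_that("probe mapping picks the most negative correlation deterministically", {
  set.seed(11)
  n <- 20
  e <- matrix(2^seq(1, 3, length.out = n) - 1, 1,
              dimnames = list("G1", paste0("S", 1:n)))
  le <- log2(e + 1)[1, ]
  strong <- 0.9 - 0.1 * (le - min(le)) / diff(range(le))  # r = -1 direction
  weak <- 0.5 + rnorm(n, 0, 0.2)
  mm <- rbind(cg_strong = pmin(1, pmax(0, strong)),
              cg_weak = pmin(1, pmax(0, weak)))
  colnames(mm) <- colnames(e)
  meth <- omics_matrix(mm, "methylation")
  map <- data.frame(probe = c("cg_weak", "cg_strong"), gene = "G1")
  got <- map_probes(meth, map, make_expr(e))
  expect_equal(got$map$probe, "cg_strong")
  expect_equal(rownames(got$meth), "G1")

  # single probe is selected unconditionally
  got1 <- map_probes(meth["cg_weak", , drop = FALSE],
                     data.frame(probe = "cg_weak", gene = "G1"),
                     make_expr(e))
  expect_equal(got1$map$probe, "cg_weak")

  # exact tie: duplicate probe values -> lexicographically smallest ID,
  # whatever the input row/map order
  tt <- rbind(cgB = strong, cgA = strong)
  colnames(tt) <- colnames(e)
  tie <- omics_matrix(tt, "methylation")
  for (ord in list(1:2, 2:1)) {
    got_tie <- map_probes(tie[ord, , drop = FALSE],
                          data.frame(probe = c("cgB", "cgA")[ord],
                                     gene = "G1"),
                          make_expr(e))
    expect_equal(got_tie$map$probe, "cgA")
  }
})

test_that("per-feature age regression equals the correlation t-test without covariates", {
  set.seed(12)
  n <- 60
  clin <- data.frame(sample_id = paste0("S", 1:n),
                     age = runif(n, 30, 85))
  m <- matrix(rnorm(5 * n), 5, n,
              dimnames = list(paste0("G", 1:5), clin$sample_id))
  res <- age_feature_regression(m, clin)
  for (g in rownames(m)) {
    ct <- stats::cor.test(m[g, ], clin$age)
    expect_equal(res$p[res$feature == g], ct$p.value, tolerance = 1e-10)
  }
  # constant features are skipped, absent from the results and BH family
  m2 <- rbind(m, CONST = 1)
  res2 <- age_feature_regression(m2, clin)
  expect_false("CONST" %in% res2$feature)
  expect_equal(res2$adj_p, bh_oracle(res2$p), tolerance = 1e-12)
  expect_equal(res2$direction, ifelse(res2$coefficient >= 0, "up", "down"))
})

test_that("overlap classification fills the four quadrants and the 84% case", {
  mk <- function(genes, coef, flag) {
    data.frame(feature = genes, coefficient = coef, se = 1, p = 0.5,
               adj_p = ifelse(flag, 0.01, 0.5), flag = flag,
               direction = ifelse(coef >= 0, "up", "down"))
  }
  genes <- sprintf("G%02d", 1:50)
  # 44 overlap genes: 37 opposite-direction, 7 same-direction; 6 non-overlap
  e_coef <- c(rep(1, 20), rep(-1, 17), rep(1, 7), rep(1, 6))
  m_coef <- c(rep(-1, 20), rep(1, 17), rep(1, 7), rep(1, 6))
  flag_e <- c(rep(TRUE, 44), rep(FALSE, 6))
  flag_m <- c(rep(TRUE, 44), rep(FALSE, 6))
  ov <- classify_overlap(mk(genes, e_coef, flag_e), mk(genes, m_coef, flag_m))
  expect_equal(ov$n_overlap, 44)
  expect_equal(sum(ov$counts), 44)
  expect_equal(round(ov$opposite_pct), 84)
  expect_equal(unname(ov$counts["meth_up_expr_up"]), 7L)
  # gene up in both lands in the meth_up_expr_up quadrant
  both_up <- classify_overlap(mk("X", 1, TRUE), mk("X", 0.5, TRUE))
  expect_equal(both_up$quadrants$quadrant, "meth_up_expr_up")
  # empty overlap: zero counts, undefined percentage
  none <- classify_overlap(mk("X", 1, FALSE), mk("X", 0.5, FALSE))
  expect_equal(none$n_overlap, 0)
  expect_true(is.na(none$opposite_pct))
  # groups partition the union universe
  expect_setequal(ov$groups$group[1:44], "age-DMGs-DEGs")
  expect_equal(sum(table(ov$groups$group)), 50)
})

test_that("coefficient concordance flags degenerate input and exact scaling", {
  res_e <- data.frame(feature = paste0("G", 1:5),
                      coefficient = c(0.5, -0.2, 0.1, 0.9, -0.7))
  res_m <- res_e
  res_m$coefficient <- -2 * res_e$coefficient
  cc <- coefficient_concordance(res_e, res_m)
  expect_equal(cc$r, -1)
  res_c <- res_e
  res_c$coefficient <- 3
  expect_true(is.na(coefficient_concordance(res_e, res_c)$r))
  expect_error(coefficient_concordance(res_e[1:2, ], res_m[1:2, ]),
               class = "oncoage_validation_error")
})

test_that("ranked lists sort by coefficient with lexicographic tie-break", {
  res <- data.frame(feature = c("A", "B", "C"),
                    coefficient = c(0.2, -0.1, 0.5))
  expect_equal(make_ranked_list(res)$feature, c("C", "A", "B"))
  ties <- data.frame(feature = c("z", "a", "m"), coefficient = 1)
  expect_equal(make_ranked_list(ties)$feature, c("a", "m", "z"))
  expect_error(make_ranked_list(res[0, ]), class = "oncoage_validation_error")
  path <- withr::local_tempfile(fileext = ".rnk")
  make_ranked_list(res, path)
  expect_equal(nrow(utils::read.delim(path, header = FALSE)), 3)
})

test_that("planted methylation-expression coupling shapes the group structure", {
  params <- sim_params(n_samples = 150, seed = 9, n_genes = 80,
                       n_age_genes = 15, n_meth_only = 8, n_expr_only = 8)
  clin <- simulate_clinical(params)
  om <- simulate_expr_meth(clin, params)
  expr <- filter_expressed(om$expression)
  mapped <- map_probes(om$methylation, om$probe_map, expr)
  er <- age_feature_regression(log2_expr(expr), clin)
  mr <- age_feature_regression(mapped$meth, clin)
  cg <- correlation_groups(expr, mapped$meth, er, mr)
  med <- tapply(cg$correlations$r, cg$correlations$group, mean)
  expect_true(all(c("age-DMGs-DEGs", "others") %in% names(med)))
  expect_lt(med[["age-DMGs-DEGs"]], med[["others"]])
  # coupled genes dominate the DMG/DEG overlap
  ov <- classify_overlap(er, mr)
  coupled <- om$truth$gene[om$truth$type == "coupled"]
  expect_gt(mean(coupled %in% ov$quadrants$gene), 0.9)
  expect_equal(unique(ov$quadrants$quadrant[ov$quadrants$gene %in% coupled]),
               "meth_up_expr_down")
  # one empty group is a precondition violation of the group tests
  expect_error(rank_group_tests(cg$correlations$r,
                                factor(cg$correlations$group,
                                       levels = c(unique(cg$correlations$group),
                                                  "ghost"))),
               class = "oncoage_validation_error")
})
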