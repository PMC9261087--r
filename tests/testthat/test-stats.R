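test_that("U and rank-biserial match brute-force pair counting", {
  mw <- mann_whitney_rbc(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$u_statistic, 0)
  expect_equal(mw$rbc, -1)
  mw <- mann_whitney_rbc(c(1, 2, 3), c(1, 2, 3))
  expect_equal(mw$rbc, 0)
  # antisymmetry under group swap
  set.seed(21)
  for (i in 1:20) {
    x <- rnorm(sample(2:15, 1)); y <- rnorm(sample(2:15, 1))
    if (i %% 3 == 0) { x <- round(x); y <- round(y) }  # force ties sometimes
    a <- mann_whitney_rbc(x, y); b <- mann_whitney_rbc(y, x)
    want <- oracle_u_rbc(x, y)
    expect_equal(a$u_statistic, want$u1)
    expect_equal(a$rbc, want$rbc)
    expect_equal(a$rbc, -b$rbc)
    expect_equal(a$rbc, 2 * a$u_statistic / (a$n1 * a$n2) - 1)
  }
  # fully tied groups: defined result
  mw <- mann_whitney_rbc(rep(1, 5), rep(1, 7))
  expect_equal(mw$p_value, 1)
  expect_equal(mw$rbc, 0)
})

test_that("exact and approximate p-values agree with the reference implementation", {
  set.seed(3)
  for (i in 1:10) {
    x <- rnorm(10); y <- rnorm(12)  # n1*n2 = 120 <= 400, no ties -> exact
    mw <- mann_whitney_rbc(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(mw$u_statistic, unname(ref$statistic))
    expect_equal(mw$p_value, ref$p.value)
  }
  x <- rnorm(25); y <- rnorm(25)   # 625 > 400 -> normal approximation
  mw <- mann_whitney_rbc(x, y)
  ref <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(mw$p_value, ref$p.value, tolerance = 1e-10)
  xt <- round(rnorm(8)); yt <- round(rnorm(9))  # ties -> corrected approx
  mw <- mann_whitney_rbc(xt, yt)
  ref <- suppressWarnings(wilcox.test(xt, yt, exact = FALSE, correct = TRUE))
  expect_equal(mw$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("type-I error is calibrated under a permutation null", {
  set.seed(2024)
  pooled <- rnorm(40)
  rejections <- replicate(1000, {
    idx <- sample.int(40, 20)
    mann_whitney_rbc(pooled[idx], pooled[-idx])$p_value < 0.05
  })
  expect_lt(abs(mean(rejections) - 0.05), 0.02)
})

test_that("Spearman matches hand-computed rank-Pearson and is monotone-invariant", {
  expect_equal(spearman_rho(1:5, (1:5)^3)$rho, 1)
  expect_equal(spearman_rho(1:5, -(1:5))$rho, -1)
  expect_equal(spearman_rho(c(1, 2, 3), c(3, 1, 2))$rho, -0.5)
  set.seed(6)
  x <- rnorm(30); y <- rnorm(30)
  base <- spearman_rho(x, y)
  ref <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(base$rho, unname(ref$estimate))
  # strictly monotone transforms change nothing
  tr <- spearman_rho(exp(x), y^3 + 5 * y)
  expect_equal(tr$rho, base$rho)
  expect_equal(tr$p_value, base$p_value)
  # zero-variance vector: flagged zero
  z <- spearman_rho(rep(1, 10), rnorm(10))
  expect_true(z$undefined)
  expect_equal(z$rho, 0)
})

test_that("Bonferroni adjustment divides the familywise level", {
  expect_equal(bonferroni(0.05, 1), 0.05)
  expect_equal(bonferroni(0.05, 100), 5e-4)
  expect_equal(bonferroni(0.05, 500), 1e-4)
  expect_error(bonferroni(0.05, 0))
})

test_that("VIF matches the normal-equations oracle and flags exact collinearity", {
  set.seed(31)
  x <- matrix(rnorm(300), ncol = 3,
              dimnames = list(NULL, c("f1", "f2", "f3")))
  expect_equal(vif(x), setNames(oracle_vif(x), colnames(x)),
               tolerance = 1e-8)
  # correlated design with known covariance
  x2 <- collinear_matrix(500, c("f1", "f2"),
                         list(list(name = "f3", of = c("f1", "f2"),
                                   coefs = c(1, 1), noise_sd = 0.5)),
                         seed = 12)
  expect_equal(vif(x2), setNames(oracle_vif(x2), colnames(x2)),
               tolerance = 1e-8)
  # exact linear combination
  x3 <- cbind(x[, 1:2], f3 = x[, 1] + x[, 2])
  expect_equal(unname(vif(x3)["f3"]), Inf)
  # independent orthogonal columns: VIF == 1
  ortho <- cbind(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1))
  expect_equal(unname(vif(ortho)), c(1, 1))
  # constant column dropped with warning
  expect_warning(v <- vif(cbind(x, k = 1)), "constant")
  expect_length(v, 3L)
})

test_that("stepwise VIF removes exactly the redundant feature and survivors pass", {
  set.seed(8)
  # noise sd chosen for population R^2 = 0.9 -> VIF near 10
  sd_for_r2 <- sqrt(2 * (1 - 0.9) / 0.9)
  x <- collinear_matrix(1000, c("f1", "f2"),
                        list(list(name = "f3", of = c("f1", "f2"),
                                  coefs = c(1, 1), noise_sd = sd_for_r2)),
                        seed = 77)
  expect_equal(unname(attr(x, "population_vif")["f3"]), 10)
  rep <- vif_stepwise(x, threshold = 5)
  expect_identical(rep$removed$feature, "f3")
  expect_length(rep$survivors, 2L)
  expect_true(all(oracle_vif(x[, rep$survivors]) < 5))
  # orthogonal set: nothing removed
  set.seed(9)
  o <- matrix(rnorm(200), ncol = 2, dimnames = list(NULL, c("a", "b")))
  rep <- vif_stepwise(o)
  expect_identical(nrow(rep$removed), 0L)
  # single feature trivially survives
  rep <- vif_stepwise(matrix(rnorm(10), ncol = 1,
                             dimnames = list(NULL, "only")))
  expect_identical(rep$survivors, "only")
  # termination bound and threshold invariant on a messy matrix
  set.seed(10)
  base <- matrix(rnorm(600), ncol = 3)
  messy <- cbind(base, base %*% matrix(rnorm(9), 3) +
                   matrix(rnorm(600, 0, 0.1), ncol = 3))
  colnames(messy) <- paste0("m", 1:6)
  rep <- vif_stepwise(messy, threshold = 5)
  expect_lte(nrow(rep$removed), 5L)
  if (length(rep$survivors) >= 2) {
    expect_true(all(oracle_vif(messy[, rep$survivors]) < 5))
  }
})

make_feature_table <- function(n = 40, seed = 1) {
  set.seed(seed)
  cols <- feature_columns()
  x <- matrix(rnorm(n * length(cols)), ncol = length(cols),
              dimnames = list(NULL, cols))
  data.frame(participant_id = paste0("p", seq_len(n)), task = "picture",
             x, check.names = FALSE, stringsAsFactors = FALSE)
}

test_that("layered VIF prunes within domains first, then across pools", {
  ft <- make_feature_table(60, seed = 2)
  # make two features from different stage-1 blocks near-duplicates:
  # they survive stage 1 but collide at the graph-type pooling stage
  ft$D_SEQ_NN <- ft$S_SEQ_LSCC + rnorm(60, 0, 0.05)
  reports <- layered_vif(ft)
  s1_names <- grep("^domain/", names(reports), value = TRUE)
  s1_surv <- unlist(lapply(reports[s1_names], `[[`, "survivors"))
  expect_true(all(c("D_SEQ_NN", "S_SEQ_LSCC") %in% s1_surv))
  type_rep <- reports[["type/picture/SEQ"]]
  expect_true(any(c("D_SEQ_NN", "S_SEQ_LSCC") %in% type_rep$removed$feature))
  final <- reports[["task/picture"]]$survivors
  expect_false(all(c("D_SEQ_NN", "S_SEQ_LSCC") %in% final))
  # output never contains a feature absent from its input
  for (r in reports) {
    expect_true(all(r$survivors %in% r$input))
    expect_true(all(r$removed$feature %in% r$input))
  }
})

test_that("layered VIF keeps orthogonal tables intact and drops duplicates early", {
  ft <- make_feature_table(80, seed = 3)
  reports <- layered_vif(ft)
  expect_setequal(reports[["task/picture"]]$survivors, feature_columns())
  # exact duplicate within one stage-1 block is removed there
  ft2 <- make_feature_table(80, seed = 4)
  ft2$S_SEQ_NE <- ft2$S_SEQ_NN
  reports2 <- layered_vif(ft2)
  dom <- reports2[["domain/picture/SEQ/S/size"]]
  expect_identical(dom$removed$feature[1], "S_SEQ_NN")  # tie broken by order
  expect_false(all(c("S_SEQ_NN", "S_SEQ_NE") %in%
                     reports2[["task/picture"]]$survivors))
})

test_that("run_analysis recovers a constructed group effect and assembles families", {
  set.seed(15)
  n <- 30
  ft <- make_feature_table(2 * n, seed = 5)
  ft$participant_id <- paste0("p", seq_len(2 * n))
  participants <- data.frame(
    participant_id = ft$participant_id,
    group = rep(c("PS+", "PS-"), each = n),
    BPRS = rnorm(2 * n, 40), stringsAsFactors = FALSE)
  # built-in effect: PS+ has lower dynamic semantic NN
  ft$D_AP_NN <- ft$D_AP_NN - 2 * (participants$group == "PS+")
  report <- run_analysis(ft, participants)
  row <- report$comparisons[report$comparisons$feature == "D_AP_NN", ]
  expect_gt(row$rbc, 0)  # group1 = PS- stochastically larger
  expect_lt(row$p_value, 0.05)
  expect_equal(report$alpha_comparisons, 0.05 / 36)
  expect_identical(nrow(report$comparisons), 36L)
  # single-feature table: one comparison per task
  ft1 <- ft[, c("participant_id", "task", "D_AP_NN")]
  rep1 <- run_analysis(ft1, participants)
  expect_identical(nrow(rep1$comparisons), 1L)
  # report files render
  dir <- withr::local_tempdir()
  write_report(report, dir)
  expect_true(file.exists(file.path(dir, "comparisons.csv")))
  expect_true(file.exists(file.path(dir, "vif_layers.csv")))
  expect_true(file.exists(file.path(dir, "correlations.csv")))
})

test_that("permuted group labels reject at roughly the nominal rate", {
  ft <- make_feature_table(40, seed = 6)
  set.seed(16)
  rates <- replicate(50, {
    participants <- data.frame(
      participant_id = ft$participant_id,
      group = sample(rep(c("PS+", "PS-"), each = 20)),
      stringsAsFactors = FALSE)
    rep <- run_analysis(ft, participants, clinical_measures = character(0))
    mean(rep$comparisons$p_value < 0.05)
  })
  expect_lt(abs(mean(rates) - 0.05), 0.03)
})
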