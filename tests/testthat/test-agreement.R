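test_that("Bland-Altman bias and LoA follow their definitions", {
  # constant difference: zero-width limits
  ba <- bland_altman(c(10, 20, 30) + 7, c(10, 20, 30))
  expect_equal(ba$bias, 7)
  expect_equal(ba$loa_upper, 7)
  expect_equal(ba$loa_lower, 7)
  # bias is exactly the difference of per-system means; LoA symmetric
  p <- pairs_with_means(65.3, 39.4)
  ba <- bland_altman(p$reference, p$test)
  expect_equal(ba$bias, mean(p$reference) - mean(p$test), tolerance = 1e-12)
  expect_equal(ba$loa_upper - ba$bias, ba$bias - ba$loa_lower,
               tolerance = 1e-12)
  expect_equal(ba$loa_upper - ba$bias,
               1.96 * stats::sd(p$reference - p$test), tolerance = 1e-12)
  expect_error(bland_altman(1, 1), "at least 2")
})

test_that("about 95% of normal differences fall inside the LoA", {
  set.seed(123)
  d <- rnorm(10000, 5, 10)
  ba <- bland_altman(d, numeric(10000))
  expect_equal(mean(d > ba$loa_lower & d < ba$loa_upper), 0.95,
               tolerance = 0.01)
})

test_that("ICC hits its anchor cases", {
  x <- c(3, 8, 1, 9, 4, 7, 2, 6)
  expect_equal(icc_two_way_mixed(x, x), 1)
  set.seed(4)
  expect_lt(abs(icc_two_way_mixed(rnorm(1000), rnorm(1000))), 0.1)
  expect_error(icc_two_way_mixed(rep(2, 5), rep(2, 5)), "zero total variance")
  expect_error(icc_two_way_mixed(c(1, 2), c(1, 2)), "at least 3")
})

test_that("ICC matches the brute-force ANOVA mean-squares oracle", {
  set.seed(11)
  for (i in 1:100) {
    n <- sample(3:10, 1)
    ref <- rnorm(n, 50, 10)
    test <- 0.8 * ref + rnorm(n, 5, 3)
    expect_equal(icc_two_way_mixed(ref, test),
                 oracle_icc(ref, test, "consistency"), tolerance = 1e-10)
    expect_equal(icc_two_way_mixed(ref, test, form = "agreement"),
                 oracle_icc(ref, test, "agreement"), tolerance = 1e-10)
  }
})

test_that("consistency ICC ignores a fixed offset; absolute form does not", {
  set.seed(2)
  ref <- rnorm(20, 100, 15)
  test <- ref + rnorm(20, 0, 2)
  icc_c <- icc_two_way_mixed(ref, test)
  icc_a <- icc_two_way_mixed(ref, test, form = "agreement")
  expect_equal(icc_two_way_mixed(ref, test + 25), icc_c, tolerance = 1e-12)
  expect_lt(icc_two_way_mixed(ref, test + 25, form = "agreement"),
            icc_a - 0.1)
})

test_that("RMSE matches a brute-force oracle and dominates |bias|", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(4, 5, 6) + 3, c(4, 5, 6)), 3)
  set.seed(9)
  ref <- rnorm(50); test <- rnorm(50)
  oracle <- sqrt(sum((ref - test)^2) / 50)
  expect_equal(rmse(ref, test), oracle, tolerance = 1e-12)
  d <- ref - test
  n <- length(d)
  expect_equal(rmse(ref, test)^2,
               mean(d)^2 + (n - 1) / n * stats::var(d), tolerance = 1e-12)
  expect_gte(rmse(ref, test), abs(mean(d)))
})

test_that("ICC bands use half-open intervals", {
  expect_equal(classify_icc(0.048), "poor")
  expect_equal(classify_icc(0.865), "good")
  expect_equal(classify_icc(c(0.5, 0.7, 0.9)),
               c("moderate", "good", "excellent"))
  expect_equal(classify_icc(c(0.499, 0.699, 0.899, 1)),
               c("poor", "moderate", "good", "excellent"))
})

test_that("heteroscedasticity check has correct size and useful power", {
  expect_error(heteroscedasticity_check(c(1, 2, 3), c(3, 2, 1)), "at least 5")
  set.seed(31)
  # null: constant variance; tau near zero, ~5% rejections
  null_rej <- mean(replicate(200, {
    mu <- runif(100, 10, 100)
    d <- rnorm(100, 0, 8)
    h <- heteroscedasticity_check(mu + d / 2, mu - d / 2)
    h$p_value < 0.05
  }))
  expect_lt(null_rej, 0.12)
  # alternative: SD of the differences proportional to the pair mean
  power <- mean(replicate(100, {
    mu <- runif(100, 10, 100)
    d <- rnorm(100, 0, 0.2 * mu)
    h <- heteroscedasticity_check(mu + d / 2, mu - d / 2)
    h$p_value < 0.05 && h$tau > 0
  }))
  expect_gt(power, 0.8)
})

test_that("agreement_stats assembles one consistent row", {
  p <- pairs_with_means(160.9, 112.7, sd = 12)
  st <- agreement_stats(p$reference, p$test)
  expect_equal(st$bias, st$ref_mean - st$test_mean, tolerance = 1e-12)
  expect_gte(st$loa_upper, st$bias)
  expect_gte(st$bias, st$loa_lower)
  expect_true(st$rmse_ge_bias)
  expect_equal(st$icc_band, classify_icc(st$icc))
  expect_equal(st$n, 24)
})

test_that("build_report lays out movement-by-outcome rows with TROM arcs", {
  mk <- function(system, seed, shift) {
    set.seed(seed)
    do.call(rbind, lapply(c("ABD", "ADD"), function(m) {
      data.frame(subject = 1:8, movement = m, system = system,
                 rom_deg = rnorm(8, if (m == "ABD") 160 else 40, 8) + shift,
                 pav_min_deg_s = -rnorm(8, 90, 5),
                 pav_max_deg_s = rnorm(8, 90, 5) + shift,
                 mav_deg_s = rnorm(8, 30, 3))
    }))
  }
  summaries <- rbind(mk("reference", 17, 0), mk("wearable", 18, 2))
  rep_ <- build_report(summaries)
  expect_setequal(unique(rep_$outcome), c("ROM", "PAV", "MAV", "TROM"))
  expect_true("ABD/ADD" %in% rep_$movement)
  trom <- rep_[rep_$movement == "ABD/ADD", ]
  expect_equal(trom$outcome, "TROM")
  rom <- rep_[rep_$outcome == "ROM" & rep_$movement %in% c("ABD", "ADD"), ]
  expect_equal(trom$ref_mean, sum(rom$ref_mean), tolerance = 1e-9)
  txt <- format_report_text(rep_)
  expect_true(any(grepl("Upper; lower LoA", txt)))
  expect_true(any(grepl("ABD/ADD", txt)))
})
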