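test_that("eGFR slope is the OLS slope of eGFR on time", {
  expect_equal(egfr_slope(c(0, 1), c(100, 99)), -1.0)
  expect_equal(egfr_slope(0:3, c(80, 78, 76, 74)), -2.0)

  set.seed(3)
  for (i in 1:20) {
    t <- sort(runif(4, 0, 5))
    y <- 90 - 2 * t + rnorm(4, 0, 3)
    expect_equal(egfr_slope(t, y), brute_ols_slope(t, y))
  }
  expect_error(egfr_slope(c(1, 1), c(90, 80)), "identical")
  expect_error(egfr_slope(1, 90), "2 time points")
})

test_that("progressor classification uses the decline cutoff", {
  expect_true(classify_progressor(-7.14))
  expect_false(classify_progressor(0.78))
  expect_false(classify_progressor(-1.1))              # default cutoff 1.9
  expect_true(classify_progressor(-1.1, cutoff = 1.0)) # literal published rule

  co <- load_cohort()
  expect_equal(sum(classify_progressor(co$egfr_slope)), 4L)
  expect_equal(sum(classify_progressor(co$egfr_slope, cutoff = 1.0)), 5L)
})

test_that("describe reproduces published group summaries", {
  prog_tcv <- describe(c(230, 914, 1295, 2201))
  expect_equal(prog_tcv$median, 1104.50)
  expect_equal(prog_tcv$q1, 743.00)
  expect_equal(prog_tcv$q3, 1521.50)

  b <- describe(c(163, 234))
  expect_equal(b$mean, 198.5)
  expect_equal(b$sd, 50.2, tolerance = 0.001)

  single <- describe(5)
  expect_equal(single$mean, 5)
  expect_equal(single$median, 5)
  expect_equal(single$q1, 5)
  expect_equal(single$q3, 5)
  expect_error(describe(numeric(0)), "non-empty")
})

test_that("describe quartiles equal a brute-force interpolation oracle", {
  set.seed(8)
  for (i in 1:200) {
    x <- runif(sample(2:40, 1), -50, 50)
    d <- describe(x)
    expect_equal(d$q1, brute_quantile(x, 0.25))
    expect_equal(d$median, brute_quantile(x, 0.5))
    expect_equal(d$q3, brute_quantile(x, 0.75))
  }
})

test_that("group comparison handles ties, forcing, and tiny groups", {
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3), test = "kruskal_wallis")
  expect_equal(same$p_value, 1)

  expect_error(compare_groups(c(1), c(2, 3, 4), test = "student_t"),
               "at least 2")

  forced <- compare_groups(rnorm(10), rnorm(10), test = "kruskal_wallis")
  expect_equal(forced$test_name, "kruskal_wallis")
  expect_true(forced$p_value >= 0 && forced$p_value <= 1)
})

test_that("the normality screen routes normal data to t, skewed to ranks", {
  set.seed(21)
  a <- rnorm(20); b <- rnorm(20, 0.5)
  expect_equal(compare_groups(a, b)$test_name, "student_t")

  a2 <- exp(rnorm(20, 0, 1.5)); b2 <- exp(rnorm(20, 0.5, 1.5))
  expect_equal(compare_groups(a2, b2)$test_name, "kruskal_wallis")

  # per-group screening remains available
  pg <- compare_groups(a2, b2, normality = "per_group")
  expect_equal(pg$test_name, "kruskal_wallis")
})

test_that("correlation picks Pearson/Spearman and matches a rank oracle", {
  x <- c(1, 2, 3, 4, 5, 6)
  p <- correlate(x, 2 * x + 1, method = "pearson")
  expect_equal(as.numeric(p), 1)

  s <- correlate(x, exp(x), method = "spearman")
  expect_equal(as.numeric(s), 1)

  set.seed(5)
  for (i in 1:20) {
    u <- rnorm(8); v <- rnorm(8)
    expect_equal(as.numeric(correlate(u, v, method = "spearman")),
                 brute_spearman(u, v))
  }
  expect_error(correlate(c(1, 1, 1), c(1, 2, 3)), "variance")
})

test_that("cohort report reproduces headline published aggregates", {
  rep <- summarize_cohort(load_cohort())
  expect_lt(abs(rep$overall$httkv$mean - 1893.3), 0.05 + 1e-9)
  expect_lt(abs(rep$by_class$tcv$class_2a$mean - 1703.6), 0.05 + 1e-9)
  expect_equal(rep$clinical$hypertension_n, 7L)
  expect_lt(abs(rep$prevalence_percent - 9.7), 0.05)
  expect_equal(rep$progressors$n_progressors, 4L)
  md <- cohort_table_md(load_cohort())
  expect_length(md, 15L)                       # header, rule, 12 rows, footer
  expect_match(md[3], "Pt1")
})
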