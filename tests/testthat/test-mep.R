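test_that("trimmed MEP mean drops one min and one max", {
  expect_equal(trimmed_mep_mean(1:12), 6.5)
  expect_equal(trimmed_mep_mean(rep(0.8, 12)), 0.8)
  expect_error(trimmed_mep_mean(c(1, 2)), "3 trials")
  expect_error(trimmed_mep_mean(c(-1, 2, 3)), ">= 0")
  # sort-and-slice oracle on random blocks, including ties
  set.seed(8)
  for (i in 1:200) {
    x <- round(stats::rlnorm(12, 0, 0.5), sample(0:3, 1))
    oracle <- mean(sort(x)[2:11])
    expect_equal(trimmed_mep_mean(x), oracle, tolerance = 1e-12)
  }
})

test_that("baseline normalization produces ratios and interval groupings", {
  session <- list(baseline = rep(1.0, 10),
                  intervals = stats::setNames(
                    lapply(c(0, 5, 10, 15, 20, 25, 30, 60, 90),
                           function(m) rep(0.79, 12)),
                    c(0, 5, 10, 15, 20, 25, 30, 60, 90)))
  r <- normalize_to_baseline(session)
  expect_equal(unname(r$ratios), rep(0.79, 9))
  expect_equal(r$overall, 0.79)
  session$intervals[["60"]] <- rep(1.2, 12)
  session$intervals[["90"]] <- rep(0.8, 12)
  r2 <- normalize_to_baseline(session)
  expect_equal(r2$late, 1.0)
  expect_equal(r2$early, 0.79)
  expect_error(normalize_to_baseline(list(baseline = rep(0, 10),
                                          intervals = session$intervals)),
               "baseline")
})

test_that("paired one-tailed t matches the textbook formula", {
  # identical vectors: degenerate, p = 0.5
  r0 <- paired_one_tailed_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r0$t, 0)
  expect_equal(r0$p, 0.5)
  expect_true(r0$degenerate)
  # near-constant negative differences
  set.seed(2)
  a <- rep(0.8, 4) + stats::rnorm(4, 0, 1e-4)
  b <- rep(1.8, 4)
  expect_lt(paired_one_tailed_t(a, b)$p, 0.005)
  # formula oracle over random pairs
  for (i in 1:100) {
    n <- sample(4:20, 1)
    x <- stats::rnorm(n); y <- stats::rnorm(n)
    d <- x - y
    tstat <- mean(d) / (stats::sd(d) / sqrt(n))
    pref <- stats::pt(tstat, n - 1)
    got <- paired_one_tailed_t(x, y)
    expect_equal(got$t, tstat, tolerance = 1e-10)
    expect_equal(got$df, n - 1)
    expect_equal(got$p, pref, tolerance = 1e-10)
  }
})

test_that("type-I error of the paired test is nominal under the null", {
  set.seed(33)
  rej <- mean(replicate(10000, {
    x <- stats::rnorm(12); y <- stats::rnorm(12)
    paired_one_tailed_t(x, y)$p < 0.05
  }))
  expect_gte(rej, 0.04)
  expect_lte(rej, 0.06)
})

test_that("exact binomial tail sums the exact mass", {
  expect_equal(exact_binomial_tail(10, 12, 22 / 53),
               stats::pbinom(9, 12, 22 / 53, lower.tail = FALSE),
               tolerance = 1e-14)
  expect_lt(exact_binomial_tail(10, 12, 22 / 53), 0.01)
  expect_lt(exact_binomial_tail(8, 12, 0.26), 0.004)
  expect_equal(exact_binomial_tail(12, 12, 1 - 1e-12), 1, tolerance = 1e-9)
  # complementary tails plus nothing double counted
  set.seed(9)
  for (i in 1:50) {
    n <- sample(1:30, 1); k <- sample(0:n, 1); p0 <- stats::runif(1, .05, .95)
    expect_equal(exact_binomial_tail(k, n, p0) +
                   (if (k > 0) exact_binomial_tail(k - 1, n, p0, "lower") else 0),
                 1, tolerance = 1e-12)
  }
  expect_error(exact_binomial_tail(13, 12, 0.5), "0..n")
})

test_that("cohort simulation is reproducible and recovers its parameters", {
  c1 <- simulate_cohort(cohort_spec(), seed = 42)
  c2 <- simulate_cohort(cohort_spec(), seed = 42)
  expect_identical(c1, c2)
  c3 <- simulate_cohort(cohort_spec(), seed = 43)
  expect_false(identical(c1$sessions, c3$sessions))
  # blocks have the study's trial counts
  s <- c1$sessions[[1]]$cathodal
  expect_length(s$baseline, 10)
  expect_true(all(lengths(s$intervals) == 12))
  expect_equal(as.numeric(names(s$intervals)),
               c(0, 5, 10, 15, 20, 25, 30, 60, 90))
  # parameter recovery at n = 500 (law of large numbers)
  co <- simulate_cohort(cohort_spec(n = 500), seed = 12)
  est <- sapply(c("cathodal", "anodal", "placebo"), function(cn)
    mean(sapply(seq_len(500), function(i)
      normalize_to_baseline(co$sessions[[i]][[cn]])$overall)))
  # tolerances ~3 standard errors of each condition mean at n = 500
  expect_lt(abs(est[["cathodal"]] - 0.79), 0.03)
  expect_lt(abs(est[["anodal"]] - 0.93), 0.015)
  expect_lt(abs(est[["placebo"]] - 1.10), 0.05)
})

test_that("full pipeline detects the cathodal effect in most cohorts", {
  set.seed(0)
  hits <- 0
  for (s in 1:60) {
    res <- analyze_cohort(simulate_cohort(cohort_spec(), seed = s))
    p <- res$tests$p[res$tests$window == "overall" &
                       res$tests$condition == "cathodal"]
    if (p < 0.05) hits <- hits + 1
  }
  expect_gt(hits / 60, 0.5)
})

test_that("cohort analysis reports contrasts, exclusions and binomials", {
  res <- analyze_cohort(simulate_cohort(cohort_spec(), seed = 3))
  expect_setequal(unique(res$tests$window), c("overall", "early", "late"))
  expect_true(all(res$tests$df == 11))
  resx <- analyze_cohort(simulate_cohort(cohort_spec(), seed = 3),
                         exclude = 11)
  expect_equal(resx$tests$df[resx$tests$window == "late"], c(10, 10))
  expect_true(all(res$binomial$p >= 0 & res$binomial$p <= 1))
  expect_equal(res$binomial$p0[res$binomial$condition == "cathodal"], 22 / 53)
})

test_that("cohort CSV round trip preserves the analysis", {
  co <- simulate_cohort(cohort_spec(n = 4), seed = 5)
  f <- tempfile(fileext = ".csv")
  write_cohort_csv(co, f)
  back <- read_cohort_csv(f)
  r1 <- analyze_cohort(co)
  r2 <- analyze_cohort(back)
  expect_equal(r1$ratios, r2$ratios, tolerance = 1e-12)
})
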