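# Hand-rolled formula oracles, independent of the implementation path.
pearson_oracle <- function(x, y) {
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    (stats::sd(x) * stats::sd(y) * (n - 1))
  tval <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tval), df = n - 2))
}

ols_oracle <- function(y, x) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  slope <- sum((x - mean(x)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(x)
  fitted <- intercept + slope * x
  r2 <- 1 - sum((y - fitted)^2) / sum((y - mean(y))^2)
  Fv <- (r2 / 1) / ((1 - r2) / (n - 2))
  list(slope = slope, intercept = intercept, r_squared = r2, F = Fv,
       p = stats::pf(Fv, 1, n - 2, lower.tail = FALSE))
}

test_that("pearson matches the covariance-formula oracle to 1e-10", {
  set.seed(101)
  for (i in 1:25) {
    n <- sample(4:20, 1)
    x <- rnorm(n); y <- 0.5 * x + rnorm(n)
    got <- pearson(x, y)
    want <- pearson_oracle(x, y)
    expect_equal(got$r, want$r, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
    expect_equal(got$df, n - 2)
  }
  expect_equal(pearson(1:5, 1:5)$r, 1)
  expect_error(pearson(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson(1:2, 1:2), "at least 3")
})

test_that("pearson is invariant under affine rescaling of either variable", {
  set.seed(7)
  x <- rnorm(30); y <- rnorm(30)
  base <- pearson(x, y)$r
  expect_equal(pearson(3 * x + 2, y)$r, base, tolerance = 1e-12)
  expect_equal(pearson(x, -0.5 * y + 7)$r, -base, tolerance = 1e-12)
})

test_that("simple OLS matches the normal-equation oracle to 1e-10", {
  set.seed(202)
  for (i in 1:25) {
    n <- sample(4:20, 1)
    x <- rnorm(n); y <- 1 + 2 * x + rnorm(n)
    got <- ols_simple(y, x)
    want <- ols_oracle(y, x)
    expect_equal(got$slope, want$slope, tolerance = 1e-10)
    expect_equal(got$intercept, want$intercept, tolerance = 1e-10)
    expect_equal(got$r_squared, want$r_squared, tolerance = 1e-10)
    expect_equal(got$F, want$F, tolerance = 1e-8)
    expect_equal(got$p, want$p, tolerance = 1e-10)
    expect_equal(c(got$df_model, got$df_residual), c(1L, n - 2L))
    # consistency: reported R^2 equals the matching correlation squared
    expect_equal(got$r_squared, pearson(x, y)$r^2, tolerance = 1e-10)
  }
  # hand-solved 4-point toy: x=(0,1,2,3), y=(1,1,3,3) -> slope 0.8, intercept 0.8
  toy <- ols_simple(c(1, 1, 3, 3), c(0, 1, 2, 3))
  expect_equal(toy$slope, 0.8)
  expect_equal(toy$intercept, 0.8)
  # exact fit (base lm warns about the perfect fit; the estimates are exact)
  exact <- suppressWarnings(ols_simple(2 * (1:6) + 1, 1:6))
  expect_equal(exact$slope, 2)
  expect_equal(exact$intercept, 1)
  expect_equal(exact$r_squared, 1)
  expect_error(ols_simple(1:5, rep(2, 5)), "zero variance")
})

test_that("OLS slope rescales as expected under rescaling of x", {
  set.seed(9)
  x <- rnorm(25); y <- 3 * x + rnorm(25)
  base <- ols_simple(y, x)$slope
  expect_equal(ols_simple(y, 10 * x)$slope, base / 10, tolerance = 1e-12)
})

test_that("paired t matches the mean/sd formula and rejects degenerate input", {
  # d = (1, 3): mean 2, sd sqrt(2), n 2 -> t = 2, df = 1
  got <- paired_t(c(2, 4), c(1, 1))
  expect_equal(got$t, 2)
  expect_equal(got$df, 1L)
  expect_equal(got$p, 2 * stats::pt(-2, df = 1), tolerance = 1e-12)
  set.seed(303)
  for (i in 1:10) {
    n <- sample(3:15, 1)
    a <- rnorm(n); b <- rnorm(n)
    d <- a - b
    tval <- mean(d) / (stats::sd(d) / sqrt(n))
    got <- paired_t(a, b)
    expect_equal(got$t, tval, tolerance = 1e-10)
    expect_equal(got$df, n - 1L)
    expect_equal(got$p, 2 * stats::pt(-abs(tval), n - 1), tolerance = 1e-10)
  }
  a <- rnorm(5)
  expect_error(paired_t(a, a), "identical")
})

test_that("class summaries reproduce the published counts and handle empties", {
  cc <- summarize_classes(px_domain_table())
  expect_equal(cc$n[cc$index == "mai"], c(31L, 15L, 3L))
  sel <- cc[cc$index == "selectivity", ]
  expect_equal(sel$n[match(c("absolute", "high", "medium", "low"), sel$class)],
               c(20L, 11L, 13L, 2L))
  empty <- tibble::tibble(name = character(), ligands = list(),
                          mai = character())
  cc0 <- summarize_classes(empty)
  expect_true(all(cc0$n == 0))
})

test_that("the battery mirrors the published degrees-of-freedom pattern", {
  bat <- run_paper_battery(px_domain_table())
  an <- tidy(bat)
  expect_equal(nrow(an), 5)
  pssmss <- an[an$response == "pss" & an$predictor == "mss", ]
  expect_equal(pssmss$n, 50)
  expect_equal(c(pssmss$df_model, pssmss$df_residual), c(1L, 48L))
  psslsi <- an[an$response == "pss" & an$predictor == "lsi", ]
  expect_equal(psslsi$n, 49)  # PXDC1 excluded by pairwise deletion
  expect_equal(psslsi$df_residual, 47L)
  # regression R^2 equals the matching correlation squared for every analysis
  expect_equal(an$r_squared, an$r^2, tolerance = 1e-10)
  g <- glance(bat)
  expect_equal(g$n_domains, 50)
  expect_equal(g$n_analyses, 5)
})

test_that("a table with no usable analyses fails informatively", {
  bad <- tibble::tibble(name = c("a", "b", "c"),
                        ligands = list("3", "3", "3"),
                        mss = c(NA_integer_, NA, NA),
                        pss = c(1L, 2L, 3L),
                        lsi = c(NA_integer_, NA, NA),
                        expression = c(NA_real_, NA, NA))
  expect_error(run_paper_battery(bad), "no analysis could be run")
  # a partially unusable table runs what it can and notes the rest
  semi <- bad
  semi$mss <- c(1L, 5L, 2L)
  semi$expression <- c(3, 9, 4)
  bat <- run_paper_battery(semi)
  expect_true(any(grepl("skipped", bat$notes)))
  expect_true(all(!grepl("lsi", tidy(bat)$predictor)))
})
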