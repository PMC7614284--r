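test_that("estimate-to-counts inversion recovers a known binomial experiment", {
  b <- qbeta(c(0.025, 0.975), 50.5, 50.5)
  cc <- counts_from_estimate(0.5, b[1], b[2])
  expect_lte(abs(cc$num - 50), 1)
  expect_lte(abs(cc$denom - 100), 1)
  b2 <- qbeta(c(0.025, 0.975), 10.5, 990.5)
  cc2 <- counts_from_estimate(0.01, b2[1], b2[2])
  expect_lte(abs(cc2$denom - 1000), 10)
})

test_that("wider intervals at the same estimate give smaller denominators", {
  narrow <- counts_from_estimate(0.2, 0.18, 0.22)
  wide <- counts_from_estimate(0.2, 0.1, 0.35)
  expect_lt(wide$denom, narrow$denom)
})

test_that("boundary and error cases of the inversion", {
  cc <- counts_from_estimate(0, 0, 0.05)
  expect_equal(cc$num, 0L)
  expect_gte(cc$denom, 1L)
  expect_error(counts_from_estimate(0.5, 0.6, 0.7), "outside")
  expect_error(counts_from_estimate(0.5, 0.5, 0.5), "zero-width")
})

test_that("reconstructed intervals match the originals across a grid", {
  for (n in c(50, 500, 5000)) for (est in c(0.02, 0.1, 0.4)) {
    y <- round(est * n)
    b <- qbeta(c(0.025, 0.975), y + 0.5, n - y + 0.5)
    cc <- counts_from_estimate(y / n, b[1], b[2])
    width0 <- b[2] - b[1]
    width1 <- cc$upper - cc$lower
    expect_lt(abs(width1 - width0) / width0, 0.10)
  }
})

test_that("disaggregation conserves group totals exactly", {
  set.seed(12)
  for (k in 1:5) {
    ng <- sample(4:10, 1)
    g <- data.frame(start = seq(0, by = 5, length.out = ng),
                    end = seq(5, by = 5, length.out = ng),
                    num = rpois(ng, 150),
                    denom = rpois(ng, 8000) + 500)
    d <- disaggregate_age_groups(g)
    gi <- findInterval(d$age, g$start)
    expect_identical(as.numeric(tapply(d$num, gi, sum)), as.numeric(g$num))
    expect_identical(as.numeric(tapply(d$denom, gi, sum)),
                     as.numeric(g$denom))
    expect_true(all(d$num <= d$denom))
    expect_true(all(d$num >= 0))
  }
})

test_that("disaggregated series are smooth under flat and trending inputs", {
  # flat neighbours: the middle group splits nearly uniformly
  g <- data.frame(start = c(45, 50, 55), end = c(50, 55, 60),
                  num = c(50, 50, 50), denom = rep(1000, 3))
  d <- disaggregate_age_groups(g)
  mid <- d$num[d$age %in% 50:54]
  expect_true(all(abs(mid - 10) <= 2))
  # linear trend across groups: yearly denominators near-monotone
  g2 <- data.frame(start = seq(0, 25, 5), end = seq(5, 30, 5),
                   num = 0, denom = round(seq(1000, 6000, length.out = 6)))
  d2 <- disaggregate_age_groups(g2)
  expect_true(all(d2$num == 0))
  viol <- sum(diff(d2$denom) < 0)
  expect_lte(viol, 2)
  expect_error(disaggregate_age_groups(
    data.frame(start = c(0, 10), end = c(5, 15), num = 0, denom = 10)),
    "contiguous")
})

test_that("remission probabilities round-trip through 10-year survival", {
  expect_equal(remission_from_survival(0), 0)
  expect_equal(remission_from_survival(1), 1)
  r <- 0.1
  s10 <- 1 - (1 - r)^10
  expect_equal(s10, 0.6513216, tolerance = 1e-7)
  expect_equal(remission_from_survival(s10), r, tolerance = 1e-12)
  # across the full range the ^10 round trip loses a few digits near r = 1
  rr <- seq(0, 1, by = 0.05)
  expect_equal(remission_from_survival(1 - (1 - rr)^10), rr,
               tolerance = 1e-5)
  expect_error(remission_from_survival(1.2), "0, 1")
})

test_that("area aggregation conserves totals", {
  data <- small_data()
  id <- setNames("all", "all")
  expect_equal(sum(aggregate_areas(data, id)$num), sum(data$num))
  d2 <- data
  d2$area <- rep(c("a", "b"), length.out = nrow(d2))
  mapping <- c(a = "region1", b = "region1")
  agg <- aggregate_areas(d2, mapping)
  expect_equal(sum(agg$num), sum(d2$num))
  expect_equal(sum(agg$denom), sum(d2$denom))
  expect_equal(unique(agg$area), "region1")
  expect_error(aggregate_areas(d2, c(a = "region1")), "unmapped.*b")
})

test_that("count CSVs round-trip and report schema errors by row", {
  data <- small_data()
  path <- tempfile(fileext = ".csv")
  write_results(data, path)
  back <- read_disease_data(path)
  expect_equal(as.data.frame(back), as.data.frame(data))
  bad <- as.data.frame(data)
  bad$measure[3] <- "wrong"
  write_results(bad, path)
  expect_error(read_disease_data(path), "row\\(s\\) 3")
  # missing optional columns default to one group
  minimal <- data.frame(age = 0:5, measure = "inc", num = 1, denom = 100)
  write_results(minimal, path)
  got <- read_disease_data(path)
  expect_equal(unique(got$area), "all")
  expect_equal(unique(got$gender), "all")
})

test_that("estimate-format tables convert to yearly counts", {
  set.seed(14)
  rows <- list()
  for (s in seq(40, 70, 5)) {
    n <- 4000; y <- rbinom(1, n, 0.05 + s / 1000)
    b <- qbeta(c(0.025, 0.975), y + 0.5, n - y + 0.5)
    rows[[length(rows) + 1]] <- data.frame(
      agegroup_start = s, agegroup_end = s + 5, measure = "prev",
      est = y / n, lower = b[1], upper = b[2])
  }
  est <- do.call(rbind, rows)
  cd <- estimates_to_counts(est)
  expect_s3_class(cd, "count_data")
  expect_equal(sort(unique(cd$age)), 40:74)
  # implied yearly proportions stay near the group-level estimates
  expect_true(all(abs(cd$num / cd$denom - mean(est$est)) < 0.08))
})
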