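# Insert-size tuples, Kaplan-Meier estimation, and CDF distances.

test_that("tuple geometry follows the flanking-anchor definitions", {
  w <- small_world()
  # synthetic pair on a 501-bp contig: read1 fwd at 0, read2 rev ending at 400
  ref1 <- w$ref
  ref1$contigs <- w$ref$contigs[flank_class == "short"][1L]
  p <- data.table::data.table(
    qname = "t1", mapped1 = TRUE, contig1 = 1L, start1 = 0L, end1 = 150L,
    strand1 = "+", mapq1 = 60L, mapped2 = TRUE, contig2 = 1L, start2 = 250L,
    end2 = 400L, strand2 = "-", mapq2 = 60L,
    start_l = 0L, end_r = 400L, proper = TRUE, t_o = 400L, contig = 1L)
  tu <- build_tuples(p, ref1)
  expect_identical(tu$t_o, 400L)
  expect_identical(tu$t_l, 501L)           # contig end minus leftmost base of read 1
  expect_identical(tu$t_r, 400L)           # rightmost base of read 2 to contig start
  expect_true(tu$t_o <= min(tu$t_l, tu$t_r))
  # single-end: mate1 fwd at 100 -> (missing, 401, missing)
  pse <- data.table::copy(p)
  pse[, `:=`(mapped2 = FALSE, proper = FALSE, t_o = NA_integer_,
             start1 = 100L, end1 = 250L,
             contig2 = NA_integer_, start2 = NA_integer_, end2 = NA_integer_,
             strand2 = NA_character_, mapq2 = NA_integer_)]
  tse <- build_tuples(pse, ref1)
  expect_identical(tse$t_l, 401L)
  expect_true(is.na(tse$t_o) && is.na(tse$t_r))
  # single-end reverse mate -> t_r only
  psr <- data.table::copy(pse)
  psr[, `:=`(strand1 = "-")]
  tsr <- build_tuples(psr, ref1)
  expect_identical(tsr$t_r, 250L)
  expect_true(is.na(tsr$t_l))
  # improper pairs yield no tuple
  pim <- data.table::copy(p)
  pim[, `:=`(proper = FALSE, contig2 = 2L)]
  expect_identical(nrow(build_tuples(pim, ref1)), 0L)
})

test_that("KM matches the hand-worked example and textbook survfit", {
  tu <- data.table::data.table(t_o = c(100L, 200L, NA), t_l = c(NA, NA, 150L),
                               t_r = NA_integer_)
  km <- km_estimate(tu)
  expect_equal(km$F, c(1 / 3, 1))
  expect_equal(km$Y, c(3, 1))
  # independent textbook implementation on the same (expanded) units
  sf <- survival::survfit(survival::Surv(c(100, 200, 150), c(1, 1, 0)) ~ 1)
  expect_equal(km$S, summary(sf, times = c(100, 200))$surv)
  # survfit oracle on a larger censored sample (events carry no bounds so
  # both paths see identical unit lists)
  tu2 <- simulate_insert_tuples(400L, 501L, seed = 9L)
  tu2_flat <- data.table::copy(tu2)
  tu2_flat[!is.na(t_o), `:=`(t_l = NA_integer_, t_r = NA_integer_)]
  km2 <- km_estimate(tu2_flat)
  status <- as.integer(!is.na(tu2_flat$t_o))
  bound <- ifelse(is.na(tu2_flat$t_l), tu2_flat$t_r, tu2_flat$t_l)
  times <- ifelse(status == 1L, tu2_flat$t_o, bound)
  sf2 <- survival::survfit(survival::Surv(times, status) ~ 1)
  expect_equal(km2$S, summary(sf2, times = km2$tau)$surv, tolerance = 1e-12)
})

test_that("KM properties: no-censoring ECDF equality, monotonicity, risk bounds, defect flag", {
  tu <- data.table::data.table(t_o = c(3L, 1L, 2L, 2L), t_l = 10L, t_r = 9L)
  km <- km_estimate(tu)
  nv <- naive_estimate(tu)
  expect_equal(km$F, nv$F)
  expect_equal(nv$F, c(0.25, 0.75, 1))
  # single observed event: step 0 -> 1
  km1 <- km_estimate(data.table::data.table(t_o = 300L, t_l = NA_integer_,
                                            t_r = NA_integer_))
  expect_equal(km1$F, 1)
  # random censored samples: S non-increasing, Y >= o + c at event times
  for (s in 1:5) {
    tux <- simulate_insert_tuples(300L, 501L, seed = 100L + s)
    kmx <- km_estimate(tux)
    expect_true(all(diff(kmx$S) <= 1e-12))
    expect_true(all(kmx$Y >= kmx$o + kmx$c))
    expect_true(all(kmx$S >= 0 & kmx$S <= 1))
  }
  # largest time censored -> defective, summaries renormalize with a flag
  tud <- data.table::data.table(t_o = c(100L, NA), t_l = c(NA, 500L), t_r = NA_integer_)
  kmd <- km_estimate(tud)
  expect_true(attr(kmd, "defective"))
  expect_true(insert_size_summary(kmd)$defective)
  # no events is an explicit error
  expect_error(km_estimate(data.table::data.table(t_o = NA_integer_, t_l = 400L,
                                                  t_r = NA_integer_)),
               "properly paired")
})

test_that("IPCW reformulation agrees with the product-limit form to 1e-10", {
  for (s in 1:5) {
    tu <- simulate_insert_tuples(500L, c(501L, 2001L), seed = 200L + s)
    km <- km_estimate(tu)
    ip <- ipcw_estimate(tu)
    expect_lt(max(abs(km$F - ip$F)), 1e-10)
  }
})

test_that("CDF distances: identities, extremes, and a brute-force integration oracle", {
  f1 <- data.table::data.table(tau = c(10, 20, 30), F = c(0.2, 0.5, 1))
  expect_equal(unname(distribution_distance(f1, f1)), c(0, 0))
  # unit step at 0 vs unit step at the max grid value
  s0 <- data.table::data.table(tau = 0, F = 1)
  s1 <- data.table::data.table(tau = 100, F = 1)
  d <- distribution_distance(s0, s1)
  expect_equal(unname(d), c(1, 1))
  # two explicit 3-step CDFs vs dense numeric integration
  f2 <- data.table::data.table(tau = c(5, 18, 40), F = c(0.4, 0.7, 1))
  d2 <- distribution_distance(f1, f2)
  grid <- seq(0, 40, by = 1e-4)
  ev <- function(dt, x) stats::stepfun(dt$tau, c(0, dt$F), right = FALSE)(x)
  diffs <- abs(ev(f1, grid) - ev(f2, grid))
  expect_equal(unname(d2["wasserstein_W"]), mean(diffs[-1]) * (40 / 40), tolerance = 1e-3)
  expect_equal(unname(d2["ks_D"]), max(diffs), tolerance = 1e-12)
})

test_that("KM removes censoring bias and is consistent; naive estimator is biased small", {
  tc <- function(t) trunc_normal_cdf(t, 350, 50, 300)
  tu <- simulate_insert_tuples(5000L, 501L, seed = 1L)
  km <- km_estimate(tu); nv <- naive_estimate(tu)
  dk <- distribution_distance(km, tc); dn <- distribution_distance(nv, tc)
  expect_lt(dk["ks_D"], dn["ks_D"])
  expect_lt(dk["wasserstein_W"], dn["wasserstein_W"])
  # naive CDF is stochastically larger (biased toward small inserts)
  grid <- sort(unique(nv$tau))
  ev <- function(dt, x) stats::stepfun(dt$tau, c(0, dt$F), right = FALSE)(x)
  expect_true(mean(ev(nv, grid) >= ev(km, grid)) > 0.95)
  # consistency: KM distance shrinks with n
  d_by_n <- vapply(c(500L, 5000L, 50000L), function(n) {
    distribution_distance(km_estimate(simulate_insert_tuples(n, 501L, seed = 99L)),
                          tc)[["ks_D"]]
  }, numeric(1))
  expect_true(d_by_n[3L] < d_by_n[1L])
})
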