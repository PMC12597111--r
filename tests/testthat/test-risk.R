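test_that("rate table partitions the population and computes rates", {
  # one cohort of 100, one case
  df <- do.call(rbind, lapply(seq_len(100), function(k)
    ped_row(sprintf("p%03d", k), "0", "0", "M", 1931,
            aff = as.integer(k == 1))))
  g <- genealogy(df)
  rt <- build_rate_table(g)
  expect_equal(nrow(rt), 1L)
  expect_equal(rt$rate, 0.01)
  expect_equal(rt$birth_interval, 1930)  # bins anchored at multiples of 5

  # no cases: all rates zero
  g0 <- set_affected(g, character(0))
  expect_true(all(build_rate_table(g0, character(0))$rate == 0))

  # two cohorts, cases only in one
  df2 <- rbind(df, do.call(rbind, lapply(seq_len(50), function(k)
    ped_row(sprintf("q%03d", k), "0", "0", "F", 1942))))
  g2 <- genealogy(df2)
  rt2 <- build_rate_table(g2)
  expect_equal(sum(rt2$n), 150L)
  expect_equal(sum(rt2$cases), 1L)
  expect_equal(rt2$rate[rt2$sex == "F"], 0)
  # every individual maps to exactly one cohort
  expect_equal(sum(rt2$n), nrow(g2$df))
  # per-individual lookup agrees with the table
  r <- cohort_rates(g2, rt2)
  expect_equal(unname(r["p001"]), 0.01)
  expect_equal(unname(r["q001"]), 0)
})

test_that("relative enumeration matches hand enumeration and stays disjoint", {
  g <- ped_extended()
  expect_setequal(enumerate_relatives(g, "c1", 1), c("p1", "p1w", "c2"))
  expect_setequal(enumerate_relatives(g, "c1", 2),
                  c("gf", "gm", "p2", "uncle2", "h1"))
  expect_setequal(enumerate_relatives(g, "c1", 3), "c3")
  # degree sets are pairwise disjoint and never contain the proband
  for (i in g$df$id) {
    sets <- lapply(1:3, function(d) enumerate_relatives(g, i, d))
    expect_false(i %in% unlist(sets))
    expect_equal(anyDuplicated(unlist(sets)), 0L)
  }
  # a lone founder has no kin at any degree
  g2 <- ped_sibs()
  for (d in 1:3) expect_length(enumerate_relatives(g2, "loner", d), 0)
  # half relations: h1 is degree 2 to c1 (half sib) but degree 2 to uncle2
  # as a full nibling, and degree 3 to c3 as a first cousin
  expect_true("h1" %in% enumerate_relatives(g, "c1", 2))
  expect_true("h1" %in% enumerate_relatives(g, "uncle2", 2))
  expect_true("c3" %in% enumerate_relatives(g, "h1", 3))
  # great-grandparents are degree 3
  g3 <- ped_second_cousins()
  expect_true("a" %in% enumerate_relatives(g3, "d1", 3))
})

test_that("observed/expected uses union semantics without duplication", {
  g <- ped_sibs()
  cases <- c("s1", "s2")
  g <- set_affected(g, cases)
  rt <- build_rate_table(g)
  oe <- observed_expected(g, cases, 1, rt)
  # union of {dad, mom, s2} and {dad, mom, s1}: four people, two affected
  expect_equal(oe$n_relatives, 4L)
  expect_equal(oe$observed, 2L)
  expect_equal(oe$expected, sum(cohort_rates(g, rt, c("dad", "mom", "s1", "s2"))))
  # no cases
  oe0 <- observed_expected(g, character(0), 1, rt)
  expect_equal(unlist(oe0), c(n_relatives = 0, observed = 0, expected = 0))
  # n_relatives never exceeds the per-case sum
  g2 <- random_pedigree(30, seed = 13)
  cs <- g2$df$id[c(10, 20, 25)]
  rt2 <- build_rate_table(g2, cs)
  for (d in 1:3) {
    oe2 <- observed_expected(g2, cs, d, rt2)
    per_case <- sum(vapply(cs, function(i)
      length(enumerate_relatives(g2, i, d)), numeric(1)))
    expect_lte(oe2$n_relatives, per_case)
  }
})

test_that("relative risk is observed over expected", {
  expect_equal(relative_risk(1, 1.6), 0.625)
  expect_equal(relative_risk(0, 2), 0)
  expect_equal(relative_risk(8, 0.6), 13 + 1 / 3)
  expect_error(relative_risk(1, 0), "expected")
})

test_that("Poisson upper tail matches closed forms and is monotone", {
  expect_equal(poisson_upper_p(2, 0.4), 1 - exp(-0.4) * 1.4, tolerance = 1e-12)
  expect_equal(poisson_upper_p(0, 5), 1)
  # strictly decreasing in expected for fixed observed >= 1
  for (o in c(1, 3, 7)) {
    ps <- vapply(c(0.2, 0.5, 1, 2, 5), function(e) poisson_upper_p(o, e),
                 numeric(1))
    expect_true(all(diff(ps) > 0))  # larger mean -> larger upper tail
  }
  # nonincreasing in observed for fixed expected
  for (e in c(0.3, 1, 4)) {
    ps <- vapply(0:8, function(o) poisson_upper_p(o, e), numeric(1))
    expect_true(all(diff(ps) <= 0))
  }
})

test_that("test-inversion CI brackets the estimate and beats the exact interval", {
  # observed 0: lower bound pinned at 0, positive upper bound
  ci0 <- agresti_min_ci(0, 1.5)
  expect_equal(unname(ci0["low"]), 0)
  expect_gt(ci0["high"], 0)
  # observed 1, expected 1.6: contains 0.625 and sits inside Garwood bounds
  ci <- agresti_min_ci(1, 1.6)
  garwood <- c(stats::qgamma(0.025, 1) / 1.6, stats::qgamma(0.975, 2) / 1.6)
  expect_lt(ci["low"], 0.625)
  expect_gt(ci["high"], 0.625)
  expect_gte(ci["low"], garwood[1] - 1e-9)
  expect_lte(ci["high"], garwood[2] + 1e-9)
  # the "exact" flavor reproduces the Garwood interval
  expect_equal(unname(agresti_min_ci(1, 1.6, flavor = "exact")), garwood,
               tolerance = 1e-9)
  # width shrinks as expected grows with observed/expected fixed
  widths <- vapply(c(1, 2, 4, 8, 16), function(k) {
    ci <- agresti_min_ci(2 * k, 1.6 * k)
    ci["high"] - ci["low"]
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
})

test_that("familial RR report combines the pieces per degree", {
  g <- ped_extended()
  cases <- c("c1", "c3")
  g <- set_affected(g, cases)
  rep <- familial_rr_report(g, cases)
  expect_equal(rep$degree, 1:3)
  oe1 <- observed_expected(g, cases, 1, build_rate_table(g))
  expect_equal(rep$n_relatives[1], oe1$n_relatives)
  expect_equal(rep$rr[1], oe1$observed / oe1$expected)
  expect_true(all(rep$ci_low <= rep$rr & rep$rr <= rep$ci_high,
                  na.rm = TRUE))
  expect_error(familial_rr_report(g, character(0)), "at least 1")
  # degenerate zero-expected degree is flagged as NA, not an error
  lone <- genealogy(rbind(ped_row("a", "0", "0", "M", 1900, aff = 1L),
                          ped_row("b", "0", "0", "F", 1950)))
  rep2 <- familial_rr_report(lone, "a")
  expect_true(all(rep2$observed == 0))
})
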