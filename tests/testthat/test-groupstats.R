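# Exact enumeration oracle for the one-sided rank-sum test (no ties).
ranksum_enum <- function(x, y) {
  n <- length(x) + length(y)
  w_obs <- sum(rank(c(x, y))[seq_along(x)])
  combos <- utils::combn(n, length(x))
  ws <- apply(combos, 2, sum)
  mean(ws >= w_obs)
}

test_that("one-tailed rank-sum matches exact enumeration", {
  r <- rank_sum_one_tailed(c(4, 5, 6), c(1, 2, 3))
  expect_equal(r$p_value, 1 / 20, tolerance = 1e-12)
  # wrong direction: the exact one-sided p is P(W >= w_obs) = 1, since the
  # observed arrangement is the minimum of the permutation distribution
  r_rev <- rank_sum_one_tailed(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r_rev$p_value, 1, tolerance = 1e-12)
  expect_equal(ranksum_enum(c(1, 2, 3), c(4, 5, 6)), 1)
  expect_gte(rank_sum_one_tailed(c(1, 2, 3), c(1, 2, 3))$p_value, 0.5)
  # random no-tie samples against the enumeration oracle
  set.seed(14)
  for (i in 1:4) {
    x <- sample(seq(1, 40), 5)
    y <- setdiff(seq(1, 40), x)[sample(35, 6)]
    expect_equal(rank_sum_one_tailed(x, y)$p_value, ranksum_enum(x, y),
                 tolerance = 1e-12)
  }
  expect_error(rank_sum_one_tailed(numeric(0), 1:3),
               class = "isa_insufficient_data")
})

test_that("two-tailed age comparison matches exact enumeration", {
  r <- age_comparison(c(20, 21, 22), c(60, 61, 62))
  expect_equal(r$p_value, 0.1, tolerance = 1e-12)
  expect_equal(age_comparison(25, 30)$p_value, 1)
  expect_gte(age_comparison(c(30, 40, 50), c(30, 40, 50))$p_value, 0.9)
})

test_that("BH adjustment matches the step-up procedure and stays monotone", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(rep(0.2, 5)), rep(0.2, 5))
  expect_equal(bh_fdr(0.03), 0.03)
  set.seed(2)
  for (i in 1:5) {
    p <- runif(10)
    adj <- bh_fdr(p)
    expect_true(all(adj >= p - 1e-12))
    expect_true(all(adj <= 1))
    expect_true(all(diff(adj[order(p)]) > -1e-12))
  }
  expect_error(bh_fdr(c(0.1, 1.2)), class = "isa_validation")
})

test_that("Cohen's d uses the pooled-SD convention", {
  expect_equal(cohens_d(c(1, 2, 3), c(2, 3, 4)), -1, tolerance = 1e-12)
  expect_equal(cohens_d(c(5, 6, 9), c(5, 6, 9)), 0)
  set.seed(9)
  e <- rnorm(20, 1); n <- rnorm(20)
  sp <- sqrt((19 * var(e) + 19 * var(n)) / 38)
  expect_equal(cohens_d(e, n), (mean(e) - mean(n)) / sp, tolerance = 1e-12)
  expect_error(cohens_d(c(1, 1), c(1, 1)), class = "isa_undefined_effect")
  expect_error(cohens_d(1, c(1, 2)), class = "isa_insufficient_data")
})

test_that("band comparison pools per group and corrects over bands", {
  roster <- data.frame(id = c(sprintf("E%02d", 1:6), sprintf("N%02d", 1:6)),
                       index = 1:12,
                       group = rep(c("Expert", "Novice"), each = 6),
                       sex = "M", age = 30)
  coh <- phase_level_cohort(roster, lags = rep(0, 8),
                            kappas = rep(2, 8), T = 80,
                            bands = c(0.02, 0.05), seed = 3)
  # inject group difference: regenerate novices with low concentration
  coh_n <- phase_level_cohort(roster[7:12, ], lags = rep(0, 8),
                              kappas = rep(0.3, 8), T = 80,
                              bands = c(0.02, 0.05), seed = 4)
  sm <- summarize_cohort(c(coh[1:6], coh_n), bands = c(0.02, 0.05))
  bc <- band_comparison(sm)
  expect_equal(nrow(bc), 2)
  expect_true(all(bc$p_fdr >= bc$p_raw))
  expect_true(all(bc$p_fdr < 0.05))
  expect_true(all(bc$cohens_d > 0))
  expect_equal(bc$n_expert, c(48, 48))
})

test_that("channel-wise comparison controls the null and detects strong contrasts", {
  roster <- data.frame(id = c(sprintf("E%02d", 1:6), sprintf("N%02d", 1:6)),
                       index = 1:12,
                       group = rep(c("Expert", "Novice"), each = 6),
                       sex = "M", age = 30)
  # null: identical concentration in both groups, many channels
  coh0 <- phase_level_cohort(roster, lags = rep(0, 40), kappas = rep(1, 40),
                             T = 60, bands = 0.03, seed = 6)
  sm0 <- summarize_cohort(coh0, bands = 0.03)
  cw0 <- channelwise_comparison(sm0, 0.03)
  expect_lt(cw0$frac_significant, 0.2)
  # strong contrast: expert concentration far above novice
  cohE <- phase_level_cohort(roster[1:6, ], rep(0, 16), rep(6, 16), 200, 0.03, 7)
  cohN <- phase_level_cohort(roster[7:12, ], rep(0, 16), rep(0.3, 16), 200, 0.03, 8)
  smc <- summarize_cohort(c(cohE, cohN), bands = 0.03)
  cw <- channelwise_comparison(smc, 0.03)
  expect_gt(cw$frac_significant, 0.9)
  expect_equal(cw$frac_significant_reverse, 0)
  expect_true(all(cw$table$cohens_d > 0))
  expect_error(channelwise_comparison(smc, 0.99), class = "isa_config")
})

test_that("the demographic filter retains males and young females", {
  roster <- data.frame(id = c("a", "b", "c"), sex = c("F", "F", "M"),
                       age = c(45, 30, 60))
  out <- participant_filter(roster)
  expect_equal(out$id, c("b", "c"))
  males <- data.frame(id = letters[1:4], sex = "M", age = c(20, 45, 60, 70))
  expect_equal(nrow(participant_filter(males)), 4)
  # default cohort roster: filtered pooled counts are n_remaining x channels
  roster_full <- make_participants(cohort_spec())
  out_full <- participant_filter(roster_full, n_channels = 64)
  n_rem <- attr(out_full, "n_remaining")
  expect_equal(attr(out_full, "pooled_n"), n_rem * 64)
  expect_equal(sum(n_rem), nrow(out_full))
  kept_f <- out_full[out_full$sex == "F", ]
  expect_true(all(kept_f$age <= 38))
  expect_true(all(roster_full$sex[roster_full$sex == "M" &
                                    roster_full$age > 38] == "M"))
  bad <- data.frame(id = "x", sex = NA, age = 30)
  expect_error(participant_filter(bad), class = "isa_metadata")
})

test_that("band-level test is calibrated under the group null", {
  set.seed(123)
  rate <- mean(vapply(1:500, function(i) {
    e <- vapply(1:32, function(j)
      Mod(mean(exp(1i * rvonmises(30, 1)))), numeric(1))
    n <- vapply(1:32, function(j)
      Mod(mean(exp(1i * rvonmises(30, 1)))), numeric(1))
    rank_sum_one_tailed(e, n)$p_value < 0.05
  }, logical(1)))
  expect_lt(abs(rate - 0.05), 0.02)
})
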