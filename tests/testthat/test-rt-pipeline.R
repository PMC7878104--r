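test_that("filter_correct keeps exactly the correct responses", {
  obs <- fixture_obs("P1", "baseline", "positive-neutral", 500 + 1:10,
                     correct = c(rep(TRUE, 7), rep(FALSE, 3)))
  kept <- filter_correct(obs)
  expect_equal(nrow(kept), 7L)
  expect_true(all(kept$correct))
  expect_equal(nrow(filter_correct(obs[obs$correct, ])), 7L)   # identity
  expect_equal(nrow(filter_correct(obs[!obs$correct, ])), 0L)  # empty
  expect_true(all(kept$rt_ms %in% obs$rt_ms))                  # subset
})

test_that("trimming removes a single extreme outlier (direct oracle)", {
  x <- c(rep(500, 9), 5000)
  # oracle: direct mean/SD computation on the 10 values
  m <- mean(x); s <- sd(x)
  expect_true(5000 > m + 1.5 * s)
  expect_true(all(500 >= m - 1.5 * s & 500 <= m + 1.5 * s))

  obs <- fixture_obs("P1", "baseline", "positive-neutral", x)
  out <- trim_outliers(obs)
  expect_equal(nrow(out), 9L)
  expect_true(all(out$rt_ms == 500))
  expect_equal(attr(out, "n_removed"), 1L)
})

test_that("trimming is contractive, single-pass and keeps zero-variance groups", {
  obs <- fixture_obs("P1", "baseline", "neutral-neutral", rep(750, 12))
  expect_equal(nrow(trim_outliers(obs)), 12L)  # sd = 0: nothing trimmed

  set.seed(31)
  big <- fixture_obs("P2", "baseline", "positive-neutral",
                     rexgauss(400, 2500))
  t1 <- trim_outliers(big)
  expect_true(nrow(t1) <= nrow(big))
  expect_true(all(t1$rt_ms %in% big$rt_ms))
  # single pass: the reference moments come from the untrimmed data, so
  # re-trimming the output trims further (i.e. the rule is not iterated)
  m <- mean(big$rt_ms); s <- sd(big$rt_ms)
  expect_setequal(t1$rt_ms,
                  big$rt_ms[big$rt_ms >= m - 1.5 * s &
                              big$rt_ms <= m + 1.5 * s])
})

test_that("groups with fewer than 2 observations warn and pass through", {
  obs <- fixture_obs("P1", "baseline", "positive-neutral", 900)
  expect_warning(out <- trim_outliers(obs), "fewer than 2")
  expect_equal(nrow(out), 1L)
})

test_that("retained fraction on large normal samples approaches 2*pnorm(1.5)-1", {
  target <- 2 * pnorm(1.5) - 1  # 0.8664
  set.seed(77)
  obs <- fixture_obs("P1", "baseline", "positive-neutral",
                     rnorm(1e5, 500, 50))
  frac <- nrow(trim_outliers(obs)) / nrow(obs)
  expect_lt(abs(frac - target), 0.01)
})

test_that("trimmed mean stays close to the untrimmed mean for symmetric RTs", {
  set.seed(13)
  obs <- fixture_obs("P1", "baseline", "positive-neutral",
                     rnorm(20000, 2500, 400))
  trimmed <- trim_outliers(obs)
  expect_lt(abs(mean(trimmed$rt_ms) - mean(obs$rt_ms)) / mean(obs$rt_ms),
            0.01)
})

test_that("pairing_means matches hand-computed toy arithmetic", {
  # two participants, one pairing type, two trials per cell
  obs <- rbind(
    fixture_obs("P1", "baseline", "positive-neutral", c(2000, 2200)),
    fixture_obs("P1", "posttraining", "positive-neutral", c(1500, 1700)),
    fixture_obs("P2", "baseline", "positive-neutral", c(3000, 3200)),
    fixture_obs("P2", "posttraining", "positive-neutral", c(2600, 2800))
  )
  pmt <- pairing_means(obs)
  row <- pmt[pmt$pairing_type == "positive-neutral", ]
  # participant means: P1 2100/1600, P2 3100/2700 (spreadsheet oracle)
  expect_equal(row$baseline_mean, mean(c(2100, 3100)))
  expect_equal(row$baseline_sd, sd(c(2100, 3100)))
  expect_equal(row$posttraining_mean, mean(c(1600, 2700)))
  expect_equal(row$delta_ms, 2600 - 2150)
  # paired t oracle on the two participant-level differences (500, 400)
  d <- c(500, 400)
  t_oracle <- mean(d) / (sd(d) / sqrt(2))
  expect_equal(row$t, t_oracle, tolerance = 1e-12)
  expect_equal(row$cohen_d, abs(t_oracle) / sqrt(2), tolerance = 1e-12)
  # table always carries the 4 canonical pairing types
  expect_equal(pmt$pairing_type,
               c("positive-neutral", "negative-neutral",
                 "positive-negative", "neutral-neutral"))
  expect_equal(row$n, 2L)
})

test_that("identical pre/post data give zero difference and t = 0", {
  obs <- rbind(
    fixture_obs("P1", "baseline", "negative-neutral", c(2000, 2100)),
    fixture_obs("P1", "posttraining", "negative-neutral", c(2000, 2100)),
    fixture_obs("P2", "baseline", "negative-neutral", c(2400, 2500)),
    fixture_obs("P2", "posttraining", "negative-neutral", c(2400, 2500))
  )
  row <- pairing_means(obs)[2, ]
  expect_equal(row$delta_ms, 0)
  expect_equal(row$t, 0)
})

test_that("participants missing a period are excluded pairwise", {
  obs <- rbind(
    fixture_obs("P1", "baseline", "positive-neutral", c(2000, 2200)),
    fixture_obs("P1", "posttraining", "positive-neutral", c(1500, 1700)),
    fixture_obs("P2", "baseline", "positive-neutral", c(3000, 3200)),
    fixture_obs("P3", "baseline", "positive-neutral", c(2500, 2600)),
    fixture_obs("P3", "posttraining", "positive-neutral", c(2100, 2200))
  )
  row <- pairing_means(obs)[1, ]
  expect_equal(row$n, 2L)  # P2 contributes no pair
  # but P2 still enters the baseline descriptive mean
  expect_equal(row$baseline_mean, mean(c(2100, 3100, 2550)))
})

test_that("accuracy_table counts correct/total per cell, NA when empty", {
  obs <- rbind(
    fixture_obs("P1", "baseline", "positive-negative", rep(500, 100),
                correct = rep(c(TRUE, FALSE), c(94, 6))),
    fixture_obs("P1", "posttraining", "positive-negative", rep(500, 50),
                correct = rep(TRUE, 50))
  )
  at <- accuracy_table(obs)
  pn_base <- at[at$pairing_type == "positive-negative" &
                  at$assessment_period == "baseline", ]
  expect_equal(pn_base$accuracy, 0.94)
  pn_post <- at[at$pairing_type == "positive-negative" &
                  at$assessment_period == "posttraining", ]
  expect_equal(pn_post$accuracy, 1.0)
  empty <- at[at$pairing_type == "neutral-neutral" &
                at$assessment_period == "baseline", ]
  expect_true(is.na(empty$accuracy))

  # hand-built 20-trial cell vs brute-force count
  set.seed(4)
  flags <- sample(c(TRUE, FALSE), 20, replace = TRUE)
  obs2 <- fixture_obs("P1", "baseline", "neutral-neutral", rep(400, 20),
                      correct = flags)
  at2 <- accuracy_table(obs2)
  cell <- at2[at2$pairing_type == "neutral-neutral" &
                at2$assessment_period == "baseline", ]
  expect_equal(cell$accuracy, sum(flags) / 20)
})

test_that("formatted pairing table uses publication precision", {
  obs <- rbind(
    fixture_obs("P1", "baseline", "positive-neutral", c(2000.4, 2200.4)),
    fixture_obs("P1", "posttraining", "positive-neutral", c(1500.2, 1700.2)),
    fixture_obs("P2", "baseline", "positive-neutral", c(3000, 3200)),
    fixture_obs("P2", "posttraining", "positive-neutral", c(2600, 2800))
  )
  tab <- format_pairing_table(pairing_means(obs))
  expect_equal(nrow(tab), 4L)
  expect_match(tab$baseline[1], "^\\d+ \\(\\d+\\)$")
  md <- render_markdown_table(tab)
  expect_match(md[1], "^\\| pairing \\|")
  expect_length(md, 6L)  # header, separator, 4 pairing rows
})
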