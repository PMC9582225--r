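test_that("investigation ratio encodes the 3:1 detection rule", {
  r <- score_two_choice(30, 10)
  expect_equal(r$investigation_ratio, 0.75)
  expect_true(r$detected)
  # any 3:1 pair sits exactly at threshold (scale invariance)
  for (k in c(0.1, 1, 7)) {
    rk <- score_two_choice(30 * k, 10 * k)
    expect_equal(rk$investigation_ratio, 0.75)
    expect_true(rk$detected)
  }
  eq <- score_two_choice(15, 15)
  expect_equal(eq$investigation_ratio, 0.5)
  expect_false(eq$detected)
  zero <- score_two_choice(0, 20)
  expect_equal(zero$investigation_ratio, 0)
  expect_false(zero$detected)
  expect_error(score_two_choice(-1, 5), "non-negative")
  expect_message(none <- score_two_choice(0, 0), "undefined")
  expect_true(is.na(none$investigation_ratio))
  expect_false(none$detected)
  # detection is monotone in odor sniffing at fixed mineral-oil sniffing
  detected <- vapply(seq(0, 90, by = 5),
                     function(o) score_two_choice(o, 10)$detected,
                     logical(1))
  expect_true(all(diff(detected) >= 0))
})

test_that("habituation and dishabituation are trial differences", {
  sniff <- rbind(water = c(8, 5, 3), almond = c(10, 4, 2),
                 mint = c(9, 6, 3), vanilla = c(7, 3, 1))
  sc <- score_habituation(sniff)
  expect_equal(unname(sc$habituation_s["mint"]), 3)    # 9 - 6
  expect_equal(unname(sc$habituation_s["almond"]), 6)  # 10 - 4
  expect_equal(unname(sc$dishabituation_s["almond->mint"]), 7)  # 9 - 2
  expect_equal(unname(sc$dishabituation_s["water->almond"]), 7) # 10 - 3
  expect_equal(sc$mean_habituation_s, mean(c(3, 6, 3, 4)))
  expect_length(sc$dishabituation_s, 3)  # transitions, not odorants

  # constant sniffing: no habituation, no dishabituation
  flat <- matrix(5, nrow = 4, ncol = 3,
                 dimnames = list(c("water", "almond", "mint", "vanilla"),
                                 NULL))
  sc0 <- score_habituation(flat)
  expect_true(all(sc0$habituation_s == 0))
  expect_true(all(sc0$dishabituation_s == 0))

  bad <- flat
  bad["mint", 2] <- NA
  expect_error(score_habituation(bad), "mint")
  expect_error(score_habituation(flat[, 1:2]), "3 trials")
})

test_that("buried-food scoring applies the timeout rule", {
  expect_true(score_buried_food(45)$passed)
  late <- score_buried_food(700)
  expect_false(late$passed)
  expect_equal(late$latency_s, 600)  # censored at the timeout
  grp <- vapply(c(45, 700, 120),
                function(l) score_buried_food(l)$passed, logical(1))
  expect_equal(mean(grp), 2 / 3)
  expect_error(score_buried_food(0), "positive")
})

test_that("the generator's ground truth is recovered from scored tables", {
  # zero noise: habituation and dishabituation recovered exactly
  gen0 <- generate_behavior_dataset(
    n_subjects_per_group = 2,
    groups = list(g = list(t1 = 10, rho = 0.4, J = 6, preference_ratio = 3,
                           buried_meanlog = log(60), buried_sdlog = 0.3,
                           digging_mean_s = 20)),
    sniff_noise_sd = 0, seed = 5)
  scores0 <- score_behavior_table(gen0$behavior)
  hab <- scores0[scores0$assay == "habituation", ]
  expect_equal(hab$mean_habituation_s, rep(6, 2))       # t1 (1 - rho)
  expect_equal(hab$mean_dishabituation_s, rep(6, 2))    # J
  tc <- scores0[scores0$assay == "two_choice", ]
  expect_equal(tc$investigation_ratio, rep(0.75, 2))
  expect_true(all(tc$detected))

  # with noise, group means converge to t1(1-rho) and J within the SEM
  gen <- generate_behavior_dataset(
    n_subjects_per_group = 50,
    groups = list(g = list(t1 = 10, rho = 0.5, J = 4, preference_ratio = 3,
                           buried_meanlog = log(60), buried_sdlog = 0.3,
                           digging_mean_s = 20)),
    sniff_noise_sd = 1, seed = 6)
  scores <- score_behavior_table(gen$behavior)
  habn <- scores[scores$assay == "habituation", ]
  sem_h <- sd(habn$mean_habituation_s) / sqrt(nrow(habn))
  sem_d <- sd(habn$mean_dishabituation_s) / sqrt(nrow(habn))
  expect_lt(abs(mean(habn$mean_habituation_s) - 10 * (1 - 0.5)), 2 * sem_h)
  expect_lt(abs(mean(habn$mean_dishabituation_s) - 4), 2 * sem_d)
})

test_that("a 1:1 preference group detects at the rule's false-positive rate", {
  gen <- generate_behavior_dataset(
    n_subjects_per_group = 60,
    groups = list(anosmic = list(t1 = 4, rho = 1, J = 0,
                                 preference_ratio = 1,
                                 buried_meanlog = log(900),
                                 buried_sdlog = 0.2, digging_mean_s = 20)),
    sniff_noise_sd = 2, seed = 8)
  scores <- score_behavior_table(gen$behavior)
  tc <- scores[scores$assay == "two_choice", ]
  # Monte-Carlo oracle for the >= 0.75 rule under the same sniffing model
  set.seed(8001)
  mo <- pmax(0, 20 + rnorm(20000, sd = 2))
  od <- pmax(0, 20 + rnorm(20000, sd = 2))
  fp_rate <- mean(od / (od + mo) >= 0.75)
  expect_lt(abs(mean(tc$detected) - fp_rate),
            3 * sqrt(0.5 * 0.5 / nrow(tc)) + 0.02)
  bf <- scores[scores$assay == "buried_food", ]
  expect_lt(mean(bf$passed), 0.25)  # anosmic group mostly times out
})
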