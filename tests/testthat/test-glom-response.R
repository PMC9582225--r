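test_that("trial averaging is the pointwise mean and reduces noise as 1/sqrt(n)", {
  tr <- make_step_trace(make_schedule()[1, ])
  expect_equal(average_trials(cbind(tr, tr, tr)), tr)
  expect_equal(average_trials(cbind(rep(0, 10), rep(2, 10))), rep(1, 10))
  expect_error(average_trials(list()), "empty")

  # trials of unequal length (one frame of slack) are trimmed
  expect_equal(average_trials(list(rep(1, 301), rep(3, 300))), rep(2, 300))

  set.seed(101)
  sigma <- 2
  mat <- matrix(rnorm(3000, sd = sigma), ncol = 3)
  expect_lt(abs(sd(average_trials(mat)) - sigma / sqrt(3)),
            0.1 * sigma / sqrt(3))
})

test_that("step response yields the textbook dF/F and the 3-SD rule gates it", {
  sched <- make_schedule()[1, ]
  step <- make_step_trace(sched, baseline = 100, step = 50)
  m <- compute_response(step, sched)
  expect_equal(m$dff_pct, 50)
  expect_true(m$is_responder)  # baseline SD 0 degrades to delta_f > 0
  expect_equal(m$baseline_sd, 0)
  expect_lte(m$latency_s, m$time_to_peak_s)

  # flat trace: no response, amplitude reported as zero by convention
  flat <- rep(100, 300)
  m0 <- compute_response(flat, sched)
  expect_false(m0$is_responder)
  expect_equal(m0$dff_pct, 0)
  expect_true(is.na(m0$latency_s))

  expect_error(compute_response(rep(0, 300), sched), "baseline")
})

test_that("responder calls and latency match independent brute-force oracles", {
  sched <- make_schedule(rate = 15)[1, ]
  cfg <- analysis_config()
  set.seed(202)
  n <- 300
  t <- (0:(n - 1)) / 15
  kern <- ifelse(t > 4, exp(-(t - 4)) - exp(-(t - 4) / 0.2), 0)
  kern <- kern / max(kern)
  for (amp in c(0, 1, 2, 5, 20)) {
    mat <- 100 + amp * kern + matrix(rnorm(3 * n, sd = 1.5), ncol = 3)
    avg <- average_trials(mat)
    m <- compute_response(avg, sched, cfg)
    expect_equal(m$is_responder,
                 oracle_is_responder(mat, 4, 15, 1, 3, 3))
    if (m$is_responder) {
      expect_equal(m$latency_s, oracle_latency(avg, 4, 15, 1, 3))
    }
  }
})

test_that("injected transient amplitude is recovered within the noise bound", {
  sched <- make_schedule(rate = 15)[1, ]
  set.seed(303)
  n <- 300
  t <- (0:(n - 1)) / 15
  kern <- ifelse(t > 4, exp(-(t - 4)) - exp(-(t - 4) / 0.2), 0)
  kern <- kern / max(kern)
  amp_pct <- 40
  sigma <- 1
  mat <- 100 * (1 + amp_pct / 100 * kern) +
    matrix(rnorm(3 * n, sd = sigma), ncol = 3)
  m <- compute_response(average_trials(mat), sched)
  expect_true(m$is_responder)
  expect_lt(abs(m$dff_pct - amp_pct), 3 * sigma / sqrt(3))
  expect_gt(m$integral_pct_s, 0)
})

test_that("blank subtraction shifts amplitudes and re-evaluates responders", {
  base <- data.frame(
    stimulus_label = c("odorA", "odorB", "odorC", "blank"),
    baseline_mean = 100, baseline_sd = 1,
    delta_f = c(10, 2, 0.5, 5), dff_pct = c(10, 2, 0.5, 5),
    is_responder = c(TRUE, TRUE, FALSE, TRUE),
    latency_s = NA_real_, time_to_peak_s = NA_real_,
    integral_pct_s = NA_real_, stringsAsFactors = FALSE)
  out <- blank_subtract(base, "blank")
  expect_equal(out$dff_blanksub_pct[1], 5)       # 10 - 5
  expect_equal(out$dff_blanksub_pct[2], -3)      # 2 - 5, sign preserved
  expect_false(out$is_responder[2])              # negative after subtraction
  expect_false(out$is_responder[3])              # was not a responder
  expect_true(is.na(out$dff_blanksub_pct[4]))    # blank row itself

  # non-responding blank (0%) leaves amplitudes untouched
  base$dff_pct[4] <- 0
  out0 <- blank_subtract(base, "blank")
  expect_equal(out0$dff_blanksub_pct[1:3], base$dff_pct[1:3])

  # full enumeration of sign cases: responder iff raw responder and
  # blank-subtracted amplitude positive
  for (odor_dff in c(0, 2, 5, 8)) {
    for (blank_dff in c(0, 2, 5, 8)) {
      d <- data.frame(stimulus_label = c("o", "blank"),
                      baseline_mean = 100, baseline_sd = 1,
                      delta_f = c(odor_dff, blank_dff),
                      dff_pct = c(odor_dff, blank_dff),
                      is_responder = c(odor_dff > 0, blank_dff > 0),
                      latency_s = NA_real_, time_to_peak_s = NA_real_,
                      integral_pct_s = NA_real_, stringsAsFactors = FALSE)
      o <- blank_subtract(d, "blank")
      expect_equal(o$is_responder[1],
                   odor_dff > 0 && (odor_dff - blank_dff) > 0)
    }
  }

  expect_error(blank_subtract(base[1:2, ], "blank"), "blank")
})

test_that("responder fractions per mouse match counts and ground truth", {
  sched <- make_schedule(c("odorA", "blank"), blanks = c(FALSE, TRUE))
  metrics <- data.frame(
    roi_id = sprintf("g%02d", 1:10), mouse_id = "m1",
    stimulus_label = "odorA",
    is_responder = c(rep(TRUE, 4), rep(FALSE, 6)),
    stringsAsFactors = FALSE)
  fr <- responder_fraction(metrics, sched)
  expect_equal(fr$fraction, 0.4)
  metrics$is_responder <- FALSE
  expect_equal(responder_fraction(metrics, sched)$fraction, 0)

  # high-SNR synthetic dataset: pipeline fractions equal ground truth
  cfg <- glom_gen_config("immature_like", n_mice = 2,
                         n_glomeruli_per_mouse = 20,
                         odorant_panel = c("eb", "hex"),
                         concentration_ladder = 0.10,
                         tuning_sparsity = 0.5, a_max_pct = 400,
                         gain_sdlog = 0.1, noise_sd = 0.5, seed = 17)
  gen <- generate_glom_dataset(cfg)
  m <- compute_response_metrics(gen$dataset)
  fr <- responder_fraction(m, gen$dataset$schedule)
  truth_fr <- aggregate(true_responder ~ mouse_id + stimulus_label,
                        data = gen$truth[gen$truth$odorant != "blank", ],
                        FUN = mean)
  merged <- merge(fr, truth_fr, by = c("mouse_id", "stimulus_label"))
  expect_equal(merged$fraction, merged$true_responder)
})

test_that("glomerular density is count per field area with unit homogeneity", {
  expect_equal(glomerular_density(30, 266^2), 30 / (266^2 * 1e-6))
  expect_equal(round(glomerular_density(30, 266^2), 1), 424.0)
  expect_equal(glomerular_density(0, 266^2), 0)
  expect_equal(glomerular_density(10, 2 * 1e5),
               glomerular_density(10, 1e5) / 2)
  expect_error(glomerular_density(10, 0), "positive")
})

test_that("detection is monotone in amplitude and dF/F is gain invariant", {
  sched <- make_schedule(rate = 15)[1, ]
  set.seed(404)
  n <- 300
  t <- (0:(n - 1)) / 15
  kern <- ifelse(t > 4, exp(-(t - 4)) - exp(-(t - 4) / 0.2), 0)
  kern <- kern / max(kern)
  noise <- matrix(rnorm(3 * n, sd = 1), ncol = 3)
  # monotonicity: increasing amplitude never flips responder TRUE -> FALSE
  was_responder <- FALSE
  for (amp in seq(0, 20, by = 0.5)) {
    m <- compute_response(average_trials(100 + amp * kern + noise), sched)
    expect_false(was_responder && !m$is_responder)
    was_responder <- m$is_responder
  }
  # gain invariance of dF/F (delta_f is not invariant)
  trace <- 100 + 30 * kern + noise[, 1]
  m1 <- compute_response(trace, sched)
  m2 <- compute_response(3.7 * trace, sched)
  expect_equal(m2$dff_pct, m1$dff_pct, tolerance = 1e-12)
  expect_equal(m2$delta_f, 3.7 * m1$delta_f, tolerance = 1e-12)
  # latency <= time to peak for every responder seen here
  expect_lte(m1$latency_s, m1$time_to_peak_s)
})
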