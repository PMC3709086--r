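test_that("training set collects normalized discharge-day observations", {
  obs <- rbind(obs_row("A", 0, hr = 70), obs_row("A", 30, hr = 85),
               obs_row("A", 40, hr = 90))
  obs$temp <- c(36.0, 36.4, 36.8); obs$rr <- c(14, 16, 18)
  obs$spo2 <- c(95, 97, 99); obs$sysbp <- c(110, 120, 130)
  co <- new_cohort(obs)
  np <- fit_normalization(co)
  X <- training_set(co, np)
  expect_equal(nrow(X), 2)  # both day-2 observations, none from day 1

  # tagged fixture: the returned rows are exactly the last-day rows
  co2 <- simulate_cohort(small_params(), seed = 20)
  np2 <- fit_normalization(co2)
  obs2 <- co2$observations
  day <- floor(obs2$time_h / 24) + 1
  last <- ave(day, obs2$patient_id, FUN = max)
  expect_equal(nrow(training_set(co2, np2)), sum(day == last))
  expect_error(training_set(new_cohort(obs[0, ]), np), "lack|empty")
})

test_that("nearest-neighbour bandwidth matches exhaustive computation", {
  X <- matrix(1, 5, 5)
  expect_error(estimate_bandwidth(X, k = 2), "identical")

  two <- rbind(rep(0, 5), c(3, 0, 0, 0, 0))
  expect_warning(bw <- estimate_bandwidth(two, k = 10), "k reduced")
  expect_equal(bw$sigma, 3)
  expect_equal(bw$k, 1L)

  # 12 unit-spaced points on a line in 5-D: brute-force all-pairs oracle
  X <- cbind(0:11, matrix(0, 12, 4))
  bw <- estimate_bandwidth(X, k = 3)
  d <- as.matrix(dist(X)); diag(d) <- Inf
  delta <- apply(d, 1, function(r) mean(sort(r)[1:3]))
  expect_equal(bw$delta, unname(delta))
  expect_equal(bw$sigma, mean(delta))

  # scaling: sigma(cX) = c sigma(X), exactly
  set.seed(22)
  X <- matrix(rnorm(60), 12, 5)
  s1 <- estimate_bandwidth(X, k = 4)$sigma
  expect_equal(estimate_bandwidth(2.5 * X, k = 4)$sigma, 2.5 * s1)

  # squared mode averages squared neighbour distances
  bs <- estimate_bandwidth(X, k = 4, mode = "squared")
  d <- as.matrix(dist(X)); diag(d) <- Inf
  dl <- apply(d, 1, function(r) mean(sort(r)[1:4]^2))
  expect_equal(bs$sigma, sqrt(mean(dl)))
})

test_that("the KDE matches its closed forms and direct summation", {
  m1 <- new_normality_model(matrix(0, 1, 5), sigma = 1)
  expect_equal(kde_likelihood(m1, rep(0, 5), normalized = TRUE),
               (2 * pi)^(-5 / 2), tolerance = 1e-12)
  expect_equal(novelty_score(m1, rep(0, 5), normalized = TRUE),
               2.5 * log(2 * pi), tolerance = 1e-12)
  expect_lt(kde_likelihood(m1, rep(100, 5), normalized = TRUE), 1e-300)
  # log-domain scoring stays finite far into the tail
  expect_true(is.finite(novelty_score(m1, rep(1000, 5), normalized = TRUE)))

  set.seed(23)
  C <- matrix(rnorm(20), 4, 5)
  m4 <- new_normality_model(C, sigma = 0.8)
  x <- rnorm(5)
  naive <- sum(exp(-colSums((t(C) - x)^2) / (2 * 0.8^2))) /
    (4 * (2 * pi)^(2.5) * 0.8^5)
  expect_equal(kde_likelihood(m4, x, normalized = TRUE), naive,
               tolerance = 1e-12)
  expect_equal(novelty_score(m4, x, normalized = TRUE), -log(naive),
               tolerance = 1e-10)
})

test_that("novelty is translation-consistent and monotone in likelihood", {
  set.seed(24)
  C <- matrix(rnorm(100), 20, 5)
  m <- new_normality_model(C, sigma = 0.6)
  x <- matrix(rnorm(25), 5, 5)
  shift <- rnorm(5)
  m2 <- new_normality_model(sweep(C, 2, shift, "+"), sigma = 0.6)
  z1 <- novelty_score(m, x, normalized = TRUE)
  z2 <- novelty_score(m2, sweep(x, 2, shift, "+"), normalized = TRUE)
  expect_equal(z1, z2, tolerance = 1e-10)
  ord <- order(kde_likelihood(m, x, normalized = TRUE))
  expect_equal(order(-z1), ord)
})

test_that("daily novelty averages per calendar day up to the event", {
  co <- simulate_cohort(small_params(), seed = 25)
  fit <- fit_normality(filter_by_stay(co))
  pid <- co$patients$patient_id[1]
  obs <- patient_observations(co, pid)
  d <- daily_novelty(fit, obs)
  z <- novelty_score(fit, obs)
  day <- floor(obs$time_h / 24) + 1
  expect_equal(d$z_mean, as.numeric(tapply(z, day, mean)))
  expect_equal(sum(d$n_obs), nrow(obs))

  # scoring stops at the event
  d2 <- daily_novelty(fit, obs, event_time_h = 47.9)
  expect_true(all(d2$day <= 2))
  expect_equal(d2$z_mean[1], d$z_mean[1])
})

test_that("group trajectories aggregate patients with SE over patients", {
  co <- filter_by_stay(simulate_cohort(small_params(), seed = 26))
  fit <- fit_normality(co)
  traj <- group_trajectory(co, fit)
  expect_true(all(c("group", "day", "mean_z", "se", "n_patients") %in%
                  names(traj)))

  # independent recomputation for one (group, day) cell
  pd <- attr(traj, "patient_daily")
  cell <- pd[pd$group == "normal" & pd$day == 2, ]
  row <- traj[traj$group == "normal" & traj$day == 2, ]
  expect_equal(row$mean_z, mean(cell$z_mean))
  expect_equal(row$se, sd(cell$z_mean) / sqrt(nrow(cell)))
  expect_equal(row$n_patients, nrow(cell))

  # truncation at the 75th percentile of stay / time to event
  nrm <- co$patients$length_of_stay_days[co$patients$outcome == "normal"]
  expect_lte(max(traj$day[traj$group == "normal"]),
             floor(quantile(nrm, 0.75)))

  # single-patient group: trajectory equals that patient's days, SE = 0
  one <- toy_cohort(c(A = 5))
  t1 <- group_trajectory(one, fit)
  d1 <- daily_novelty(fit, patient_observations(one, "A"))
  expect_equal(t1$mean_z, d1$z_mean[d1$day <= max(t1$day)])
  expect_true(all(t1$se == 0))

  # two patients with constant vitals: group mean is the midpoint each day
  t_seq <- seq(0, 5 * 24 - 1, by = 6)
  obs_u <- do.call(rbind, lapply(t_seq, function(t) obs_row("U", t)))
  obs_v <- do.call(rbind, lapply(t_seq, function(t)
    obs_row("V", t, hr = 92, sysbp = 105)))
  two <- new_cohort(rbind(obs_u, obs_v))
  two$patients$outcome <- "normal"
  t2 <- group_trajectory(two, fit)
  zu <- novelty_score(fit, obs_u[1, ]); zv <- novelty_score(fit, obs_v[1, ])
  expect_equal(t2$mean_z, rep((zu + zv) / 2, nrow(t2)), tolerance = 1e-10)
})

test_that("the alarm threshold is mu + multiplier * sd of normal scores", {
  co <- filter_by_stay(simulate_cohort(small_params(), seed = 27))
  groups <- split_by_outcome(co)
  fit <- fit_normality(co)
  z <- novelty_score(fit, groups$normal)
  th <- fit$threshold
  expect_equal(th$mu_z, mean(z), tolerance = 1e-12)
  expect_equal(th$sd_z, sd(z), tolerance = 1e-12)
  expect_equal(th$k_threshold, mean(z) + 3 * sd(z), tolerance = 1e-12)

  th0 <- novelty_threshold(fit, groups$normal, multiplier = 0)
  expect_equal(th0$k_threshold, th0$mu_z)

  thp <- novelty_threshold(fit, groups$normal, unit = "patient")
  zp <- tapply(z, groups$normal$observations$patient_id, mean)
  expect_equal(thp$k_threshold, mean(zp) + 3 * sd(zp), tolerance = 1e-12)

  # degenerate zero-variance reference: k equals the common score
  m1 <- new_normality_model(matrix(0, 1, 5), sigma = 1,
                            normalization = fit$normalization)
  const_obs <- do.call(rbind, lapply(c(0, 6, 12), function(t)
    obs_row("A", t)))
  cc <- new_cohort(const_obs,
                   data.frame(patient_id = "A", outcome = "normal",
                              event_time_h = NA_real_))
  thc <- novelty_threshold(m1, cc)
  expect_equal(thc$k_threshold, thc$mu_z)
})

test_that("predict and exceedance wrap the score consistently", {
  co <- filter_by_stay(simulate_cohort(small_params(), seed = 28))
  fit <- fit_normality(co)
  z <- predict(fit, co)
  expect_equal(z, novelty_score(fit, co))
  expect_equal(predict(fit, co, type = "likelihood"), exp(-z))
  expect_equal(predict(fit, co, type = "exceeds"),
               z > fit$threshold$k_threshold)
  ex <- threshold_exceedance(fit, co)
  expect_equal(nrow(ex), n_patients(co))
  expect_true(all(ex$exceeds == !is.na(ex$first_exceed_day)))
})

test_that("bandwidth and scores scale coherently with the data", {
  # multiplying training data by c > 0 multiplies sigma by c exactly
  set.seed(29)
  X <- matrix(rnorm(75), 15, 5)
  for (cc in c(0.5, 2, 10)) {
    expect_equal(estimate_bandwidth(cc * X, k = 5)$sigma,
                 cc * estimate_bandwidth(X, k = 5)$sigma,
                 tolerance = 1e-12)
  }
})
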