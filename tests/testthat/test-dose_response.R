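test_that("normalize_viability divides by the plate's control mean", {
  wells <- data.frame(sample = "s1", drug = "d", dose = c(1, 2, 4),
                      replicate = 1, signal = c(5000, 10000, 12000))
  out <- normalize_viability(wells, controls = c(9000, 10000, 11000))
  expect_equal(out$viability, c(0.5, 1.0, 1.2))

  # per-plate matching
  wells$plate <- c("p1", "p1", "p2")
  ctrl <- data.frame(plate = c("p1", "p1", "p2"),
                     signal = c(10000, 10000, 20000))
  out <- normalize_viability(wells, ctrl)
  expect_equal(out$viability, c(0.5, 1.0, 0.6))
})

test_that("normalize_viability validates controls", {
  wells <- data.frame(sample = "s1", drug = "d", dose = 1,
                      replicate = 1, signal = 5000)
  expect_error(normalize_viability(wells, numeric(0)), "invalid control")
  expect_error(normalize_viability(wells, c(-1000, 1000)), "invalid control")
  wells$plate <- "p9"
  expect_error(
    normalize_viability(wells, data.frame(plate = "p1", signal = 1e4)),
    "p9"
  )
})

test_that("fit recovers known parameters exactly from noiseless curves", {
  cases <- list(c(Dm = 2.0, m = 1.5), c(Dm = 0.05, m = 0.7),
                c(Dm = 10, m = 3))
  for (cs in cases) {
    doses <- cs[["Dm"]] * 2^(-2:2)
    fit <- fit_median_effect(exact_points(cs[["Dm"]], cs[["m"]], doses))
    expect_lt(abs(fit$Dm - cs[["Dm"]]) / cs[["Dm"]], 1e-9)
    expect_lt(abs(fit$m - cs[["m"]]) / cs[["m"]], 1e-9)
    expect_equal(fit$r_squared, 1)
  }
})

test_that("three collinear points force m = 1, Dm = 1", {
  # fa/fu = 1 at D = 1 and 10 at D = 10; third collinear point at D = 0.1
  pts <- data.frame(dose = c(0.1, 1, 10),
                    viability = 1 - c(1 / 11, 0.5, 10 / 11))
  fit <- fit_median_effect(pts)
  expect_equal(fit$m, 1, tolerance = 1e-9)
  expect_equal(fit$Dm, 1, tolerance = 1e-9)
})

test_that("boundary viabilities are excluded by fa clipping", {
  doses <- 2 * 2^(-2:2)
  pts <- exact_points(2, 1.5, doses)
  pts <- rbind(pts, data.frame(dose = 0.001, viability = 1.0))  # fa = 0
  fit <- fit_median_effect(pts)
  expect_equal(fit$n_used, length(doses))
  expect_lt(abs(fit$Dm - 2) / 2, 1e-9)
})

test_that("fit errors are informative", {
  expect_error(
    fit_median_effect(data.frame(dose = c(1, 2), viability = c(0.6, 0.4))),
    "insufficient points"
  )
  # viability rising with dose => negative median-effect slope
  expect_error(
    fit_median_effect(data.frame(dose = c(1, 2, 4),
                                 viability = c(0.2, 0.5, 0.8))),
    "non-monotone"
  )
  expect_error(
    fit_median_effect(data.frame(dose = c(0, 1, 2),
                                 viability = c(0.9, 0.5, 0.1))),
    "positive"
  )
})

test_that("replicates are averaged per dose before fitting", {
  doses <- 2 * 2^(-2:2)
  pts <- exact_points(2, 1.5, doses)
  jit <- rbind(
    transform(pts, viability = viability + 0.004, replicate = 1),
    transform(pts, viability = viability - 0.004, replicate = 2)
  )
  fit <- fit_median_effect(jit)
  expect_equal(fit$n_used, length(doses))
  expect_lt(abs(fit$Dm - 2) / 2, 1e-6)

  fit_pw <- fit_median_effect(jit, average_replicates = FALSE)
  expect_equal(fit_pw$n_used, 2L * length(doses))
})

test_that("predict_fa matches the printed definition", {
  fit <- median_effect_fit(Dm = 2, m = 1.5)
  expect_identical(predict_fa(fit, 2), 0.5)           # D = Dm => 50% effect
  expect_identical(predict_fa(fit, 0), 0)
  fit1 <- median_effect_fit(Dm = 5, m = 1)
  expect_equal(predict_fa(fit1, 15), 0.75)            # 3/(1+3)
  expect_error(predict_fa(fit, -1), "non-negative")
})

test_that("dose_for_effect inverts predict_fa", {
  fit <- median_effect_fit(Dm = 3, m = 2)
  expect_equal(dose_for_effect(fit, 0.5), 3)
  expect_equal(dose_for_effect(fit, 0.8), 6)          # (0.8/0.2)^(1/2) = 2
  expect_error(dose_for_effect(fit, 1.0), "open interval")
  expect_error(dose_for_effect(fit, 0), "open interval")

  # property: round-trip to 1e-9 over random fits and effect levels
  set.seed(11)
  for (i in 1:50) {
    f <- median_effect_fit(10^runif(1, -3, 3), runif(1, 0.3, 4))
    fa <- runif(1, 0.01, 0.99)
    expect_equal(predict_fa(f, dose_for_effect(f, fa)), fa,
                 tolerance = 1e-9)
  }
})

test_that("predict_fa is strictly increasing in dose", {
  set.seed(12)
  for (i in 1:20) {
    f <- median_effect_fit(10^runif(1, -2, 2), runif(1, 0.3, 4))
    # stay within 1.5 decades of Dm: beyond that fa saturates to 0/1 in
    # double precision and strictness is unobservable
    d <- f$Dm * 10^seq(-1.5, 1.5, length.out = 20)
    expect_true(all(diff(predict_fa(f, d)) > 0))
  }
})

test_that("noisy fits recover Dm within tolerance on average", {
  # 8 doses x 3 replicates, 5% multiplicative noise, 200 simulations
  rel_err <- vapply(1:200, function(i) {
    cfg <- sim_config(seed = 1000 + i, noise_cv = 0.05)
    tab <- gen_dose_response(2, 1.5, cfg)
    fit <- fit_median_effect(tab[tab$dose > 0, c("dose", "viability")])
    abs(fit$Dm - 2) / 2
  }, numeric(1))
  expect_lt(median(rel_err), 0.10)
})
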