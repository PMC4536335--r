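toy_model <- function(genes, weights) {
  structure(list(genes = genes, weights = weights,
                 center = rep(0, length(genes)),
                 scale = rep(1, length(genes)),
                 sign_convention = "sum_nonneg",
                 score_variance = NA_real_),
            class = "signature_model")
}

test_that("fit_pc1 gives unit-norm loadings and the top eigenvalue", {
  # two perfectly correlated genes: symmetry forces equal loadings
  x <- matrix(rnorm(10), 1)
  expr <- rbind(g1 = x[1, ], g2 = 2 * x[1, ] + 3)
  colnames(expr) <- paste0("s", 1:10)
  mod <- fit_pc1(expr)
  expect_equal(abs(mod$weights), rep(1 / sqrt(2), 2), tolerance = 1e-9)
  expect_equal(mod$score_variance, 2, tolerance = 1e-9)
  expect_equal(sum(mod$weights^2), 1, tolerance = 1e-12)

  # 3-gene toy: score variance = top eigenvalue of the correlation matrix
  set.seed(41)
  expr3 <- matrix(rnorm(3 * 15), 3,
                  dimnames = list(c("a", "b", "c"), paste0("s", 1:15)))
  expr3[2, ] <- expr3[1, ] * 0.5 + rnorm(15, sd = 0.5)
  mod3 <- fit_pc1(expr3)
  ev <- eigen(stats::cor(t(expr3)), symmetric = TRUE)$values[1]
  expect_equal(mod3$score_variance, ev, tolerance = 1e-9)
  expect_equal(sum(mod3$weights^2), 1, tolerance = 1e-12)

  # more genes than samples is allowed
  set.seed(42)
  wide <- matrix(rnorm(50 * 5), 50,
                 dimnames = list(sprintf("g%02d", 1:50), paste0("s", 1:5)))
  expect_equal(sum(fit_pc1(wide)$weights^2), 1, tolerance = 1e-12)
})

test_that("fit_pc1 rejects degenerate input", {
  expr <- matrix(rnorm(20), 4,
                 dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
  expr[3, ] <- 7
  expect_error(fit_pc1(expr), "zero-variance gene\\(s\\): g3")
  expect_error(fit_pc1(expr[1, , drop = FALSE]), "2 genes")
  expect_error(fit_pc1(expr[1:2, 1:2]), "3 samples")
})

test_that("fix_sign orients the loading sum non-negative, idempotently", {
  m <- toy_model(c("a", "b"), c(-0.8, -0.6))
  f1 <- fix_sign(m)
  expect_equal(f1$weights, c(0.8, 0.6))
  expect_equal(fix_sign(f1)$weights, f1$weights)        # idempotent
  m2 <- toy_model(c("a", "b"), c(0.8, -0.6))
  expect_equal(fix_sign(m2)$weights, m2$weights)        # already oriented
})

test_that("score_samples computes weighted standardized expression", {
  m <- toy_model(c("g1", "g2"), c(1, 0))
  expr <- matrix(c(2.3, -5), 2, dimnames = list(c("g1", "g2"), "s1"))
  expect_equal(unname(score_samples(m, expr)), 2.3)

  # scoring the training matrix reproduces the PC1 coordinates
  set.seed(43)
  tr <- matrix(rnorm(8 * 12), 8,
               dimnames = list(paste0("g", 1:8), paste0("s", 1:12)))
  mod <- fit_pc1(tr)
  z <- t(scale(t(tr)))
  pc1 <- as.numeric(t(mod$weights) %*% z)   # independent projection
  expect_equal(unname(score_samples(mod, tr)), pc1, tolerance = 1e-9)

  # sign flip negates scores, nothing else
  flipped <- mod
  flipped$weights <- -mod$weights
  expect_equal(score_samples(flipped, tr), -score_samples(mod, tr))
})

test_that("score_samples drops and renormalizes missing genes", {
  set.seed(44)
  tr <- matrix(rnorm(4 * 10), 4,
               dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  mod <- fit_pc1(tr)
  sc <- score_samples(mod, tr[c("g1", "g2"), , drop = FALSE])  # 50% present
  w <- mod$weights[1:2] / sqrt(sum(mod$weights[1:2]^2))
  z <- (tr[1:2, ] - mod$center[1:2]) / mod$scale[1:2]
  expect_equal(unname(sc), as.numeric(t(w) %*% z), tolerance = 1e-12)
  expect_error(score_samples(mod, tr[1, , drop = FALSE]), "50%")
})

test_that("median_split sends ties to the low group", {
  expect_equal(as.character(median_split(c(a = 1, b = 2, c = 3, d = 4))),
               c("low", "low", "high", "high"))
  expect_equal(as.character(median_split(c(a = 1, b = 2, c = 3))),
               c("low", "low", "high"))
  expect_error(median_split(c(5, 5, 5)), "degenerate")
  expect_error(median_split(7), "2 samples")
})

test_that("km_estimate reproduces hand-computed product limits", {
  # no events: survival stays at 1 (no steps)
  none <- data.frame(time = 1:4, event = 0)
  expect_equal(nrow(km_estimate(none)), 0L)

  # deaths at t=1 and t=2 among 4: S = 3/4 then 1/2
  km <- km_estimate(data.frame(time = c(1, 2, 3, 4), event = c(1, 1, 0, 0)))
  expect_equal(km$surv, c(3 / 4, 1 / 2))

  # death at 1 (of 4), censored at 1.5, death at 2 (of 2): (3/4)*(1/2)
  km2 <- km_estimate(data.frame(time = c(1, 1.5, 2, 3),
                                event = c(1, 0, 1, 0)))
  expect_equal(km2$surv, c(0.75, 0.375))

  expect_error(km_estimate(data.frame(time = -1, event = 1)), "non-negative")
})

test_that("km_estimate agrees with survival::survfit", {
  skip_if_not_installed("survival")
  set.seed(45)
  rec <- data.frame(time = round(rexp(60, 0.1), 1),
                    event = rbinom(60, 1, 0.7))
  km <- km_estimate(rec)
  sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = rec)
  idx <- match(km$time, sf$time)
  expect_equal(km$surv, sf$surv[idx], tolerance = 1e-12)
  expect_equal(km$n_risk, sf$n.risk[idx])
  # with no censoring KM equals the empirical survival function
  rec2 <- data.frame(time = c(2, 5, 5, 9), event = 1)
  expect_equal(km_estimate(rec2)$surv, c(0.75, 0.25, 0))
})

test_that("logrank_test matches oracles and is symmetric", {
  a <- data.frame(time = c(1, 2), event = 1)
  b <- data.frame(time = c(3, 4), event = 1)
  lr <- logrank_test(a, b)
  expect_equal(lr$chisq, oracle_logrank(a$time, a$event, b$time, b$event),
               tolerance = 1e-12)

  # identical groups: observed = expected
  same <- data.frame(time = c(1, 3, 5), event = c(1, 1, 0))
  lr0 <- logrank_test(same, same)
  expect_equal(lr0$chisq, 0)
  expect_equal(lr0$p, 1)

  set.seed(46)
  ga <- data.frame(time = round(rexp(40, 0.1), 1), event = rbinom(40, 1, 0.8))
  gb <- data.frame(time = round(rexp(40, 0.2), 1), event = rbinom(40, 1, 0.8))
  lr1 <- logrank_test(ga, gb)
  lr2 <- logrank_test(gb, ga)
  expect_equal(lr1$chisq, lr2$chisq, tolerance = 1e-12)
  expect_equal(lr1$chisq, oracle_logrank(ga$time, ga$event,
                                         gb$time, gb$event),
               tolerance = 1e-12)
  if (requireNamespace("survival", quietly = TRUE)) {
    dat <- rbind(cbind(ga, grp = "a"), cbind(gb, grp = "b"))
    sd <- survival::survdiff(survival::Surv(time, event) ~ grp, data = dat)
    expect_equal(lr1$chisq, sd$chisq, tolerance = 1e-9)
  }
  expect_error(logrank_test(data.frame(time = 1, event = 0),
                            data.frame(time = 2, event = 0)),
               "no events")
})

test_that("log-rank has power under hazard ratio 3", {
  groups <- rep(c("low", "high"), each = 200)
  pvals <- vapply(1:200, function(i) {
    cfg <- sim_config(seed = 5000 + i, hazard_ratio = 3,
                      censoring_rate = 0.2)
    sv <- gen_survival(groups, cfg)
    logrank_test(sv[sv$group == "low", ], sv[sv$group == "high", ])$p
  }, numeric(1))
  expect_gte(mean(pvals < 0.05), 0.95)
  expect_lt(median(pvals), 0.001)
})

test_that("sign flip leaves the survival association unchanged", {
  cfg <- sim_config(seed = 47, n_samples = 40L, n_signal_genes = 10L,
                    n_null_genes = 0L)
  ep <- gen_expression_phenotype(cfg)
  mod <- fit_pc1(ep$expr)
  sc <- score_samples(mod, ep$expr)
  grp <- median_split(sc)
  flipped <- mod
  flipped$weights <- -mod$weights
  grp_f <- median_split(score_samples(flipped, ep$expr))
  # memberships swap labels but partition identically
  expect_true(all((grp == "low") == (grp_f == "high")))
  sv <- gen_survival(stats::setNames(as.character(grp), names(grp)), cfg)
  p1 <- logrank_test(sv[sv$group == "low", ], sv[sv$group == "high", ])$p
  sv$group_f <- as.character(grp_f)[match(sv$sample, names(grp_f))]
  p2 <- logrank_test(sv[sv$group_f == "low", ],
                     sv[sv$group_f == "high", ])$p
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("end-to-end: hazard ratio 2.5 at n = 218 is detected", {
  # mirrors the clinical validation cohort size
  hits <- vapply(1:100, function(i) {
    cfg <- sim_config(seed = 6000 + i, n_samples = 218L,
                      n_signal_genes = 47L, n_null_genes = 0L,
                      hazard_ratio = 2.5, censoring_rate = 0.3)
    ep <- gen_expression_phenotype(cfg)
    mod <- fit_pc1(ep$expr)
    grp <- median_split(score_samples(mod, ep$expr))
    sv <- gen_survival(stats::setNames(as.character(grp), names(grp)), cfg)
    logrank_test(sv[sv$group == "low", ], sv[sv$group == "high", ])$p < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.90)
})
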