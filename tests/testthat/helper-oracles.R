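# Independent reference implementations used to cross-check the package.
# These are deliberately written from first principles and share no code
# with the functions they verify.

# combination index, every term recomputed from the raw parameters
oracle_ci <- function(dm_a, m_a, dm_b, m_b, dm_c, m_c, fraction_a, fa) {
  odds <- fa / (1 - fa)
  dx1 <- dm_a * odds^(1 / m_a)
  dx2 <- dm_b * odds^(1 / m_b)
  dc <- dm_c * odds^(1 / m_c)
  d1 <- fraction_a * dc
  d2 <- (1 - fraction_a) * dc
  d1 / dx1 + d2 / dx2 + (d1 * d2) / (dx1 * dx2)
}

# log-rank O/E/V tabulated through an explicit risk table
oracle_logrank <- function(ta, ea, tb, eb) {
  df <- data.frame(time = c(ta, tb), event = c(ea, eb),
                   grp = rep(c("a", "b"), c(length(ta), length(tb))))
  times <- sort(unique(df$time[df$event == 1]))
  oa <- exp_a <- vv <- 0
  for (tt in times) {
    risk <- df[df$time >= tt, ]
    na <- sum(risk$grp == "a")
    nt <- nrow(risk)
    dt <- sum(df$time == tt & df$event == 1)
    da <- sum(df$time == tt & df$event == 1 & df$grp == "a")
    oa <- oa + da
    exp_a <- exp_a + dt * na / nt
    if (nt > 1) {
      vv <- vv + dt * na * (nt - na) * (nt - dt) / (nt^2 * (nt - 1))
    }
  }
  (oa - exp_a)^2 / vv
}

# noiseless median-effect viability points
exact_points <- function(Dm, m, doses) {
  fa <- (doses / Dm)^m / (1 + (doses / Dm)^m)
  data.frame(dose = doses, viability = 1 - fa)
}

table_fixture <- function(name) {
  system.file("extdata", name, package = "synergysig", mustWork = TRUE)
}
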