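#' Simulation configuration
#'
#' Collects every knob the generators share. Defaults describe a typical
#' 384-well combination study and array-based screen: an 8-point
#' two-fold dilution series spanning the IC50, triplicate wells, 5%
#' multiplicative plate noise, 30 profiled samples, moderate censoring.
#'
#' @param seed integer seed; a fixed seed makes every generator
#'   deterministic.
#' @param dose_grid dose series (molar); default `2^(-3:4)`.
#' @param noise_cv coefficient of variation of multiplicative viability
#'   noise; default 0.05.
#' @param n_replicates wells per dose; default 3.
#' @param n_samples profiled samples for the expression screen; default 30.
#' @param n_signal_genes planted correlated genes; default 47.
#' @param n_null_genes independent null genes; default 103.
#' @param target_r planted gene-phenotype correlation in (0, 1);
#'   default 0.95.
#' @param hazard_ratio high-vs-low group hazard ratio; default 2.5.
#' @param censoring_rate approximate fraction censored; default 0.3.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, dose_grid = 2^(-3:4), noise_cv = 0.05,
                       n_replicates = 3L, n_samples = 30L,
                       n_signal_genes = 47L, n_null_genes = 103L,
                       target_r = 0.95, hazard_ratio = 2.5,
                       censoring_rate = 0.3) {
  stopifnot(length(seed) == 1L, is.finite(seed),
            all(dose_grid > 0), noise_cv >= 0,
            n_replicates >= 1L, n_samples >= 1L,
            n_signal_genes >= 1L, n_null_genes >= 0L,
            target_r > 0, target_r < 1,
            hazard_ratio > 0, censoring_rate >= 0, censoring_rate < 1)
  structure(list(seed = as.integer(seed), dose_grid = dose_grid,
                 noise_cv = noise_cv, n_replicates = as.integer(n_replicates),
                 n_samples = as.integer(n_samples),
                 n_signal_genes = as.integer(n_signal_genes),
                 n_null_genes = as.integer(n_null_genes),
                 target_r = target_r, hazard_ratio = hazard_ratio,
                 censoring_rate = censoring_rate),
            class = "sim_config")
}

# run expr with the RNG seeded from cfg, restoring global RNG state after
with_sim_seed <- function(cfg, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(cfg$seed)
  expr
}

#' Generate median-effect viability data
#'
#' Draws viability at each dose in the grid from the median-effect law,
#' viability = (1 - fa(D)) * (1 + eps) with eps ~ Normal(0, noise_cv),
#' with `n_replicates` wells per dose plus untreated control wells at
#' dose 0 (viability 1 times the same noise).
#'
#' @param Dm,m true median-effect parameters (> 0).
#' @param config a [sim_config()]; its `seed`, `dose_grid`, `noise_cv`
#'   and `n_replicates` are used.
#' @param sample,drug labels written into the table.
#' @return Viability table data.frame (`sample`, `drug`, `dose`,
#'   `replicate`, `viability`, `plate`), controls included as dose-0 rows.
#' @export
gen_dose_response <- function(Dm, m, config = sim_config(),
                              sample = "sim", drug = "drugA") {
  stopifnot(Dm > 0, m > 0, inherits(config, "sim_config"))
  if (all(config$dose_grid > Dm) || all(config$dose_grid < Dm)) {
    warning("dose grid lies entirely on one side of Dm; ",
            "the fit will be ill-conditioned")
  }
  with_sim_seed(config, {
    doses <- rep(config$dose_grid, each = config$n_replicates)
    fa <- (doses / Dm)^m / (1 + (doses / Dm)^m)
    noise <- stats::rnorm(length(doses), 0, config$noise_cv)
    tab <- data.frame(
      sample = sample, drug = drug, dose = doses,
      replicate = rep(seq_len(config$n_replicates),
                      times = length(config$dose_grid)),
      viability = pmax((1 - fa) * (1 + noise), 0),
      plate = "plate1", stringsAsFactors = FALSE
    )
    ctrl <- data.frame(
      sample = sample, drug = drug, dose = 0,
      replicate = seq_len(config$n_replicates),
      viability = pmax(1 + stats::rnorm(config$n_replicates, 0,
                                        config$noise_cv), 0),
      plate = "plate1", stringsAsFactors = FALSE
    )
    rbind(tab, ctrl)
  })
}

#' Solve the mixture Dm giving a target combination index
#'
#' Inverts the mutually nonexclusive CI equation at the 50% effect level:
#' with Dx1, Dx2 the single-agent IC50s and f the mixture fraction of
#' drug 1, the mixture dose Dc satisfying
#' (f/Dx1 + (1-f)/Dx2) Dc + f(1-f)/(Dx1 Dx2) Dc^2 = CI
#' is the positive quadratic root. Internal helper shared by
#' [gen_combination()] and tests.
#'
#' @param fit_a,fit_b single-agent `medfit`s.
#' @param fraction_a mixture fraction of drug 1, in (0, 1).
#' @param target_ci desired combination index at fa = 0.5 (> 0).
#' @return The mixture Dm (total concentration).
#' @export
solve_combo_dm <- function(fit_a, fit_b, fraction_a, target_ci) {
  stopifnot(target_ci > 0, fraction_a > 0, fraction_a < 1)
  dx1 <- fit_a$Dm
  dx2 <- fit_b$Dm
  a <- fraction_a * (1 - fraction_a) / (dx1 * dx2)
  b <- fraction_a / dx1 + (1 - fraction_a) / dx2
  dc <- (-b + sqrt(b^2 + 4 * a * target_ci)) / (2 * a)
  stopifnot(dc > 0)
  dc
}

#' Generate constant-ratio mixture viability data with known CI
#'
#' Constructs the mixture whose combination index at the 50% effect level
#' equals `target_ci` (via [solve_combo_dm()]) and generates its
#' viability table as in [gen_dose_response()], with doses recorded as
#' total mixture concentration.
#'
#' @param fit_a,fit_b single-agent `medfit`s.
#' @param fraction_a drug 1's fraction of the total mixture dose.
#' @param m_combo sigmoidicity of the mixture curve.
#' @param target_ci true combination index at fa = 0.5.
#' @param config a [sim_config()].
#' @param sample,drug labels for the table.
#' @return List with `table` (viability table), `Dm_combo` (the solved
#'   mixture Dm) and `target_ci`.
#' @export
gen_combination <- function(fit_a, fit_b, fraction_a, m_combo, target_ci,
                            config = sim_config(), sample = "sim",
                            drug = "comboAB") {
  dm_c <- solve_combo_dm(fit_a, fit_b, fraction_a, target_ci)
  cfg <- config
  # centre the grid on the mixture potency so the fit is well conditioned
  cfg$dose_grid <- dm_c * config$dose_grid / stats::median(config$dose_grid)
  list(table = gen_dose_response(dm_c, m_combo, cfg, sample, drug),
       Dm_combo = dm_c, target_ci = target_ci)
}

#' Generate an expression matrix with planted IC50-correlated genes
#'
#' Draws per-sample log10 IC50 from a normal distribution, standardizes
#' it to z, and plants each signal gene as r*z + sqrt(1-r^2)*noise so its
#' population correlation with log IC50 is `target_r`; null genes are
#' independent standard normals. Marginals are standard normal on the log
#' scale, consistent with normalized array intensities.
#'
#' @param config a [sim_config()]; uses `n_samples`, `n_signal_genes`,
#'   `n_null_genes`, `target_r`, `seed`.
#' @param signal_genes optional character vector of signal gene IDs
#'   (length `n_signal_genes`); defaults to `sig_001 ...`.
#' @param ic50_meanlog,ic50_sdlog mean and sd of log10 IC50
#'   (default 0.5 and 0.5: IC50s centred near 3 uM spanning roughly
#'   0.3-30 uM).
#' @return List: `expr` (gene x sample matrix), `ic50` (named vector,
#'   linear scale), `signal_genes`, `null_genes`.
#' @export
gen_expression_phenotype <- function(config = sim_config(),
                                     signal_genes = NULL,
                                     ic50_meanlog = 0.5, ic50_sdlog = 0.5) {
  stopifnot(inherits(config, "sim_config"), config$n_samples >= 4L)
  if (is.null(signal_genes)) {
    signal_genes <- sprintf("sig_%03d", seq_len(config$n_signal_genes))
  }
  stopifnot(length(signal_genes) == config$n_signal_genes,
            !anyDuplicated(signal_genes))
  null_genes <- sprintf("null_%04d", seq_len(config$n_null_genes))
  samples <- sprintf("sample_%03d", seq_len(config$n_samples))
  r <- config$target_r

  with_sim_seed(config, {
    log_ic50 <- stats::rnorm(config$n_samples, ic50_meanlog, ic50_sdlog)
    z <- as.numeric(scale(log_ic50))
    sig <- t(vapply(seq_len(config$n_signal_genes), function(i) {
      r * z + sqrt(1 - r^2) * stats::rnorm(config$n_samples)
    }, numeric(config$n_samples)))
    nul <- matrix(stats::rnorm(config$n_null_genes * config$n_samples),
                  nrow = config$n_null_genes, ncol = config$n_samples)
    expr <- rbind(sig, nul)
    rownames(expr) <- c(signal_genes, null_genes)
    colnames(expr) <- samples
    list(expr = expr,
         ic50 = stats::setNames(10^log_ic50, samples),
         signal_genes = signal_genes, null_genes = null_genes)
  })
}

#' Generate survival records with a group-dependent hazard
#'
#' Event times are exponential with the high group's hazard equal to
#' `hazard_ratio` times the low group's baseline; censoring times are
#' independent Uniform(0, tau) with tau solved numerically so the
#' expected censored fraction is approximately `censoring_rate`.
#'
#' @param groups named factor/character of `"low"`/`"high"` per sample.
#' @param config a [sim_config()]; uses `hazard_ratio`,
#'   `censoring_rate`, `seed`.
#' @param baseline_hazard low-group hazard per month; default
#'   `log(2) / 36` (36-month median survival, typical of advanced
#'   serous ovarian carcinoma).
#' @return data.frame with `sample`, `group`, `time` (months), `event`.
#' @export
gen_survival <- function(groups, config = sim_config(),
                         baseline_hazard = log(2) / 36) {
  stopifnot(inherits(config, "sim_config"))
  labels <- if (!is.null(names(groups))) {
    names(groups)
  } else {
    sprintf("sample_%03d", seq_along(groups))
  }
  groups <- as.character(groups)
  if (length(groups) == 0L) stop("empty group assignment")
  if (!all(groups %in% c("low", "high"))) {
    stop('groups must be "low" or "high"')
  }
  if (!any(groups == "low") || !any(groups == "high")) {
    stop("both groups must be non-empty")
  }
  hr <- config$hazard_ratio
  lam <- ifelse(groups == "high", baseline_hazard * hr, baseline_hazard)

  with_sim_seed(config, {
    t_event <- stats::rexp(length(lam), rate = lam)
    if (config$censoring_rate > 0) {
      # P(censored | tau) for exponential(lambda) events, U(0, tau) censor:
      # mean over subjects of (1 - exp(-lambda tau)) / (lambda tau) ... - rate
      p_cens <- function(tau) {
        mean((1 - exp(-lam * tau)) / (lam * tau)) - config$censoring_rate
      }
      tau <- stats::uniroot(p_cens, c(1e-6, 1e6))$root
      t_cens <- stats::runif(length(lam), 0, tau)
      data.frame(sample = labels, group = groups,
                 time = pmin(t_event, t_cens),
                 event = as.integer(t_event <= t_cens),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(sample = labels, group = groups,
                 time = t_event, event = 1L, stringsAsFactors = FALSE)
    }
  })
}
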