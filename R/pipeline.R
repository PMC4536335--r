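# Stage orchestration: each runner validates its config, reads the flat
# inputs, executes the stage and persists TSV/JSON outputs plus a run
# manifest. Identical config + inputs give byte-identical outputs (no
# timestamps are written).

#' Read and validate a run configuration
#'
#' Accepts a YAML (`.yaml`/`.yml`, requires the `yaml` package) or JSON
#' file, or a ready-made list. Unknown keys are rejected so typos fail
#' fast.
#'
#' @param config path or list.
#' @param allowed character vector of permitted keys.
#' @param required character vector of mandatory keys.
#' @return The validated config list.
#' @export
read_run_config <- function(config, allowed, required = character(0)) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE)) {
      if (!requireNamespace("yaml", quietly = TRUE)) {
        stop("the 'yaml' package is needed for YAML configs; use JSON")
      }
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  stopifnot(is.list(config))
  unknown <- setdiff(names(config), allowed)
  if (length(unknown) > 0L) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  miss <- setdiff(required, names(config))
  if (length(miss) > 0L) {
    stop("missing config key(s): ", paste(miss, collapse = ", "))
  }
  config
}

write_manifest <- function(out_dir, stage, config, inputs) {
  hashes <- vapply(inputs, function(p) {
    if (is.character(p) && file.exists(p)) unname(tools::md5sum(p))
    else NA_character_
  }, character(1))
  manifest <- list(
    stage = stage,
    package = "synergysig",
    package_version = as.character(utils::packageVersion("synergysig")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = config,
    input_md5 = as.list(hashes)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

fit_all_curves <- function(plate, fa_clip) {
  # viability path: dose-0 rows are controls, excluded from fitting
  if (!("viability" %in% names(plate))) {
    ctrl <- plate[plate$dose == 0, , drop = FALSE]
    if (nrow(ctrl) == 0L) {
      stop("raw-signal plate table needs dose-0 untreated control rows")
    }
    if (is.null(plate$plate)) plate$plate <- "plate1"
    plate <- normalize_viability(
      plate[plate$dose > 0, , drop = FALSE],
      ctrl[c("plate", "signal")]
    )
  }
  treated <- plate[plate$dose > 0, , drop = FALSE]
  key <- interaction(treated$sample, treated$drug, drop = TRUE)
  fits <- lapply(split(treated, key), function(d) {
    fit <- fit_median_effect(d[c("dose", "viability")], fa_clip = fa_clip)
    data.frame(sample = d$sample[1], drug = d$drug[1], Dm = fit$Dm,
               m = fit$m, n_used = fit$n_used, r_squared = fit$r_squared,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, fits)
  rownames(out) <- NULL
  out[order(out$sample, out$drug), , drop = FALSE]
}

#' Run the synergy stage
#'
#' Fits median-effect curves for every (sample, drug) series in the plate
#' table, then computes the combination index for each combination listed
#' in the design table at the summary effect level. Writes `fits.tsv`,
#' `ci.tsv` and `manifest.json` into the output directory.
#'
#' @param config list or YAML/JSON path with keys: `plates` (plate table
#'   path), `design` (design table path), `out_dir`; optional `fa_level`
#'   (default 0.5), `fa_clip` (default c(0.01, 0.99)), `additive_band`
#'   (default 0).
#' @return Invisible list with `fits` and `ci` data.frames.
#' @export
run_synergy <- function(config) {
  config <- read_run_config(
    config,
    allowed = c("plates", "design", "out_dir", "fa_level", "fa_clip",
                "additive_band"),
    required = c("plates", "design", "out_dir")
  )
  fa_level <- config$fa_level %||% 0.5
  fa_clip <- unlist(config$fa_clip %||% c(0.01, 0.99))
  band <- config$additive_band %||% 0

  plate <- read_plate_table(config$plates)
  design <- read_design_table(config$design)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  fits <- fit_all_curves(plate, fa_clip)

  ci_rows <- lapply(seq_len(nrow(design)), function(i) {
    row <- design[i, ]
    per_sample <- lapply(unique(fits$sample), function(s) {
      fs <- fits[fits$sample == s, , drop = FALSE]
      have <- c(row$drug_a, row$drug_b, row$combo) %in% fs$drug
      if (!all(have)) return(NULL)
      pick <- function(dr) {
        r <- fs[fs$drug == dr, ]
        median_effect_fit(r$Dm, r$m, r$n_used, r$r_squared)
      }
      exp <- combination_experiment(pick(row$drug_a), pick(row$drug_b),
                                    pick(row$combo), row$fraction_a)
      res <- combination_index(exp, fa_level, band)
      data.frame(sample = s, combo = row$combo, fa_level = res$effect_level,
                 ci = res$ci, classification = res$classification,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, per_sample)
  })
  ci_tab <- do.call(rbind, ci_rows)
  if (is.null(ci_tab) || nrow(ci_tab) == 0L) {
    stop("no design combination matched the fitted curves")
  }

  write_fit_table(fits, file.path(config$out_dir, "fits.tsv"))
  write_delim_file(ci_tab, file.path(config$out_dir, "ci.tsv"))
  write_manifest(config$out_dir, "synergy", config,
                 c(config$plates, config$design))
  invisible(list(fits = fits, ci = ci_tab))
}

#' Run the signature stage
#'
#' Correlation screen of expression against IC50, gene selection, PC1
#' signature fit, sample scoring, median dichotomization, Kaplan-Meier
#' estimation per group and the log-rank test. Writes `screen.tsv`,
#' `selected_genes.txt`, `scores.tsv`, `km_low.tsv`, `km_high.tsv`,
#' `survival_test.json` and `manifest.json`.
#'
#' @param config list or YAML/JSON path with keys: `expr` (expression
#'   matrix path), `phenotype` (sample/ic50 table), `survival`
#'   (sample/time/event table), `out_dir`; optional `p_threshold`
#'   (default 0.001) or `q_threshold` (exactly one used),
#'   `log10_phenotype` (default TRUE).
#' @return Invisible list with `screen`, `selected`, `model`, `scores`,
#'   `groups`, `test`.
#' @export
run_signature <- function(config) {
  config <- read_run_config(
    config,
    allowed = c("expr", "phenotype", "survival", "out_dir", "p_threshold",
                "q_threshold", "log10_phenotype"),
    required = c("expr", "phenotype", "survival", "out_dir")
  )
  if (is.null(config$p_threshold) && is.null(config$q_threshold)) {
    config$p_threshold <- 0.001
  }
  expr <- read_expression_matrix(config$expr)
  pheno <- read_phenotype_table(config$phenotype)
  surv <- read_survival_table(config$survival)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  screen <- pearson_screen(expr, pheno,
                           log10_phenotype = config$log10_phenotype %||% TRUE)
  selected <- select_genes(screen, p_threshold = config$p_threshold,
                           q_threshold = config$q_threshold)
  write_delim_file(screen, file.path(config$out_dir, "screen.tsv"))
  writeLines(selected, file.path(config$out_dir, "selected_genes.txt"))
  if (length(selected) < 2L) {
    stop("signature needs at least 2 selected genes (got ",
         length(selected), "); stopping before PCA")
  }

  model <- fit_pc1(expr[selected, , drop = FALSE])
  scores <- score_samples(model, expr)
  groups <- median_split(scores)
  score_tab <- data.frame(sample = names(scores), score = scores,
                          group = as.character(groups),
                          stringsAsFactors = FALSE)
  write_delim_file(score_tab, file.path(config$out_dir, "scores.tsv"))

  surv$group <- score_tab$group[match(surv$sample, score_tab$sample)]
  if (anyNA(surv$group)) {
    stop("survival sample(s) missing from the expression matrix: ",
         paste(surv$sample[is.na(surv$group)], collapse = ", "))
  }
  low <- surv[surv$group == "low", , drop = FALSE]
  high <- surv[surv$group == "high", , drop = FALSE]
  write_delim_file(as.data.frame(km_estimate(low)),
                   file.path(config$out_dir, "km_low.tsv"))
  write_delim_file(as.data.frame(km_estimate(high)),
                   file.path(config$out_dir, "km_high.tsv"))
  test <- logrank_test(low, high)
  jsonlite::write_json(
    list(chisq = test$chisq, p = test$p,
         n = as.list(test$n), events = as.list(test$events)),
    file.path(config$out_dir, "survival_test.json"),
    auto_unbox = TRUE, digits = NA
  )
  write_manifest(config$out_dir, "signature", config,
                 c(config$expr, config$phenotype, config$survival))
  invisible(list(screen = screen, selected = selected, model = model,
                 scores = scores, groups = groups, test = test))
}

#' Simulate a full scenario to disk
#'
#' Generates every input the analysis stages read — single-agent and
#' mixture viability tables, a design table, an expression matrix with a
#' planted signature, the IC50 phenotype and survival records — and a
#' `ground_truth.json` sidecar recording the planted parameters.
#'
#' @param scenario list or YAML/JSON path. Keys (all optional, defaults
#'   in parentheses): `seed` (1), `drug_a`/`drug_b` lists with `Dm`, `m`
#'   (1.0/1.2 and 4.0/1.2), `fraction_a` (0.5), `m_combo` (1.2),
#'   `target_ci` (0.5), `noise_cv` (0.05), `n_samples` (30),
#'   `n_signal_genes` (47), `n_null_genes` (103), `target_r` (0.95),
#'   `hazard_ratio` (2.5), `censoring_rate` (0.3).
#' @param out_dir output directory, created if needed.
#' @return Invisible list of written paths.
#' @export
simulate_scenario <- function(scenario = list(), out_dir) {
  scenario <- read_run_config(
    scenario,
    allowed = c("seed", "drug_a", "drug_b", "fraction_a", "m_combo",
                "target_ci", "noise_cv", "n_samples", "n_signal_genes",
                "n_null_genes", "target_r", "hazard_ratio",
                "censoring_rate")
  )
  s <- function(key, default) scenario[[key]] %||% default
  seed <- s("seed", 1L)
  da <- s("drug_a", list(Dm = 1.0, m = 1.2))
  db <- s("drug_b", list(Dm = 4.0, m = 1.2))
  fraction_a <- s("fraction_a", 0.5)
  m_combo <- s("m_combo", 1.2)
  target_ci <- s("target_ci", 0.5)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- sim_config(seed = seed, noise_cv = s("noise_cv", 0.05),
                    n_samples = s("n_samples", 30L),
                    n_signal_genes = s("n_signal_genes", 47L),
                    n_null_genes = s("n_null_genes", 103L),
                    target_r = s("target_r", 0.95),
                    hazard_ratio = s("hazard_ratio", 2.5),
                    censoring_rate = s("censoring_rate", 0.3))

  fit_a <- median_effect_fit(da$Dm, da$m)
  fit_b <- median_effect_fit(db$Dm, db$m)
  cfg_a <- cfg; cfg_a$seed <- cfg$seed + 101L
  cfg_a$dose_grid <- da$Dm * cfg$dose_grid / stats::median(cfg$dose_grid)
  cfg_b <- cfg; cfg_b$seed <- cfg$seed + 102L
  cfg_b$dose_grid <- db$Dm * cfg$dose_grid / stats::median(cfg$dose_grid)
  cfg_c <- cfg; cfg_c$seed <- cfg$seed + 103L
  tab_a <- gen_dose_response(da$Dm, da$m, cfg_a, drug = "drugA")
  tab_b <- gen_dose_response(db$Dm, db$m, cfg_b, drug = "drugB")
  combo <- gen_combination(fit_a, fit_b, fraction_a, m_combo, target_ci,
                           cfg_c, drug = "comboAB")
  plates <- rbind(tab_a, tab_b, combo$table)
  design <- data.frame(combo = "comboAB", drug_a = "drugA",
                       drug_b = "drugB", fraction_a = fraction_a,
                       stringsAsFactors = FALSE)

  cfg_e <- cfg; cfg_e$seed <- cfg$seed + 104L
  ep <- gen_expression_phenotype(cfg_e)
  expr_df <- data.frame(gene = rownames(ep$expr), ep$expr,
                        check.names = FALSE, stringsAsFactors = FALSE)

  # plant the survival split along the true signature so the scenario's
  # ground truth is self-consistent
  model <- fit_pc1(ep$expr[ep$signal_genes, , drop = FALSE])
  groups <- median_split(score_samples(model, ep$expr))
  cfg_s <- cfg; cfg_s$seed <- cfg$seed + 105L
  surv <- gen_survival(stats::setNames(as.character(groups), names(groups)),
                       cfg_s)

  paths <- list(
    plates = file.path(out_dir, "plates.tsv"),
    design = file.path(out_dir, "design.tsv"),
    expr = file.path(out_dir, "expression.tsv"),
    phenotype = file.path(out_dir, "phenotype.tsv"),
    survival = file.path(out_dir, "survival.tsv"),
    ground_truth = file.path(out_dir, "ground_truth.json")
  )
  write_delim_file(plates, paths$plates)
  write_delim_file(design, paths$design)
  write_delim_file(expr_df, paths$expr)
  write_delim_file(data.frame(sample = names(ep$ic50), ic50 = ep$ic50),
                   paths$phenotype)
  write_delim_file(surv[c("sample", "time", "event")], paths$survival)
  jsonlite::write_json(
    list(seed = seed, drug_a = da, drug_b = db, fraction_a = fraction_a,
         m_combo = m_combo, target_ci = target_ci,
         Dm_combo = combo$Dm_combo, signal_genes = ep$signal_genes,
         hazard_ratio = cfg$hazard_ratio),
    paths$ground_truth, auto_unbox = TRUE, digits = NA
  )
  invisible(paths)
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `fit`, `ci`, `screen-survive`
#' and `run-all`; see `pipeline_main(c("--help"))`. The installed script
#' `inst/cli/synergysig` wraps this function for shell use. Errors raise
#' an R condition (nonzero exit under Rscript).
#'
#' @param args character vector, default `commandArgs(trailingOnly=TRUE)`.
#' @return Invisibly, the result of the dispatched stage.
#' @export
pipeline_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: synergysig <command> [options]",
    "",
    "commands:",
    "  simulate --scenario S.yaml --out DIR    write synthetic inputs",
    "  fit --plates P.tsv --out DIR            fit median-effect curves",
    "  ci --plates P.tsv --design D.tsv --out DIR [--fa 0.5]",
    "                                          fits + combination indices",
    "  screen-survive --expr E.tsv --pheno I.tsv --surv V.tsv --out DIR",
    "                 [--p 0.001 | --fdr 0.2]  screen, score, survival",
    "  run-all --config C.yaml                 simulate then analyze",
    sep = "\n"
  )
  if (length(args) == 0L || args[1] %in% c("--help", "-h", "help")) {
    cat(usage, "\n")
    return(invisible(NULL))
  }
  cmd <- args[1]
  opts <- parse_cli_opts(args[-1])
  need <- function(key) {
    if (is.null(opts[[key]])) stop("missing required option --", key)
    opts[[key]]
  }

  res <- switch(
    cmd,
    simulate = simulate_scenario(
      if (is.null(opts$scenario)) list() else opts$scenario,
      out_dir = need("out")
    ),
    fit = {
      plate <- read_plate_table(need("plates"))
      dir.create(need("out"), showWarnings = FALSE, recursive = TRUE)
      fits <- fit_all_curves(plate, c(0.01, 0.99))
      write_fit_table(fits, file.path(opts$out, "fits.tsv"))
      invisible(fits)
    },
    ci = run_synergy(list(plates = need("plates"), design = need("design"),
                          out_dir = need("out"),
                          fa_level = as.numeric(opts$fa %||% 0.5))),
    `screen-survive` = run_signature(list(
      expr = need("expr"), phenotype = need("pheno"),
      survival = need("surv"), out_dir = need("out"),
      p_threshold = if (!is.null(opts$p)) as.numeric(opts$p),
      q_threshold = if (!is.null(opts$fdr)) as.numeric(opts$fdr)
    )),
    `run-all` = {
      cfg <- read_run_config(need("config"),
                             allowed = c("scenario", "out_dir"),
                             required = "out_dir")
      sim_dir <- file.path(cfg$out_dir, "sim")
      paths <- simulate_scenario(cfg$scenario %||% list(), sim_dir)
      syn <- run_synergy(list(plates = paths$plates, design = paths$design,
                              out_dir = file.path(cfg$out_dir, "synergy")))
      sig <- run_signature(list(expr = paths$expr,
                                phenotype = paths$phenotype,
                                survival = paths$survival,
                                out_dir = file.path(cfg$out_dir,
                                                    "signature")))
      invisible(list(synergy = syn, signature = sig))
    },
    stop("unknown command '", cmd, "'\n", usage)
  )
  invisible(res)
}

parse_cli_opts <- function(args) {
  opts <- list()
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--")) stop("unexpected argument: ", args[i])
    key <- substring(args[i], 3L)
    if (i + 1L > length(args) || startsWith(args[i + 1L], "--")) {
      opts[[key]] <- TRUE
      i <- i + 1L
    } else {
      opts[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  opts
}

`%||%` <- function(a, b) if (is.null(a)) b else a
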