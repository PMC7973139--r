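#' Default pipeline configuration
#'
#' A complete run configuration covering every stage: a two-group
#' whole-cell cohort, an MTSET retrieval experiment per group, the
#' Na+/NMDG+ substitution I/V protocol, and a single-channel patch. Values
#' mirror typical oocyte experiments (group means of a few uA, baseline
#' open probability 0.3, retrieval giving ~46% corrected remaining
#' fraction at 70 min for ENaC alone).
#'
#' @param seed Integer master seed.
#' @param out_dir Output directory.
#' @return A nested list of class `run_config`.
#' @export
default_config <- function(seed = 1L, out_dir = "enactraff_out") {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    stages = c("simulate", "analyze", "mtset", "iv", "patch", "report"),
    cohort = list(n_oocytes = 12, n_batches = 3, noise_sd = 5,
                  expression_cv = 0.5, batch_cv = 0.2,
                  groups = list(
                    list(name = "ENaC", mean_di_ami = 5000,
                         inhibition = 0, mean_di_camg = 0),
                    list(name = "ENaC+Cx30", mean_di_ami = 5000,
                         inhibition = 0.54, mean_di_camg = 900))),
    mtset = list(n_oocytes = 12, t_end = 70,
                 noise_frac = 0.02, n0 = 1000, unitary = 1,
                 groups = list(
                   list(name = "ENaC", remaining = 0.46, po = 0.3),
                   list(name = "ENaC+Cx30", remaining = 0.26, po = 0.2))),
    iv = list(noise_sd = 0, n_oocytes = 8,
              cx30 = list(conductance = 1.0,
                          erev = list(na = -10.0, nmdg = -43.1)),
              endogenous = list(conductance = 0.5,
                                erev = list(na = -35.2, nmdg = -35.2))),
    patch = list(n_channels = 2, p_open = 0.3, unitary_current = 0.38,
                 mean_open_ms = 150, noise_sd = 0.05, duration = 60,
                 dt = 2e-4, amiloride_tail = 5, holding = -70)
  ), class = "run_config")
}

#' Read a run configuration from YAML or JSON
#'
#' Values absent from the file fall back to [default_config()]. The format
#' is chosen by extension (`.yml`/`.yaml` or `.json`).
#'
#' @param path Config file path.
#' @return A `run_config` list.
#' @export
read_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yml = , yaml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported config extension: ", ext))
  cfg <- default_config()
  merge_in <- function(base, new) {
    for (nm in names(new)) {
      base[[nm]] <- if (is.list(new[[nm]]) && is.list(base[[nm]]) &&
                        !is.null(names(new[[nm]])))
        merge_in(base[[nm]], new[[nm]]) else new[[nm]]
    }
    base
  }
  structure(merge_in(unclass(cfg), raw), class = "run_config")
}

stage_mtset <- function(cfg, seed) {
  res <- list()
  for (gi in seq_along(cfg$mtset$groups)) {
    g <- cfg$mtset$groups[[gi]]
    lam <- log(1 / g$remaining) / cfg$mtset$t_end
    rows <- lapply(seq_len(cfg$mtset$n_oocytes), function(j) {
      set.seed(seed + gi * 1000L + j)
      scale <- rlnorm_cv(1, 0.5)
      params <- steady_state(trafficking_params(
        lambda_ret = lam, n0 = cfg$mtset$n0 * scale,
        po_baseline = g$po, unitary = cfg$mtset$unitary))
      series <- simulate_mtset_timecourse(
        params, sample_times = seq(0, cfg$mtset$t_end, by = 10),
        noise_sd = cfg$mtset$noise_frac * params$n0 * params$unitary,
        seed = seed + gi * 1000L + j)
      est <- retrieval_current(series)
      data.frame(group = g$name, oocyte = j,
                 di0 = di_at(series, 0),
                 di_end = di_at(series, cfg$mtset$t_end),
                 po_initial = est$po_initial,
                 di_retrieval = est$di_retrieval,
                 remaining_corrected = est$remaining_fraction_corrected)
    })
    tab <- do.call(rbind, rows)
    fit <- proportional_fit(tab$di0, tab$di_retrieval)
    res[[g$name]] <- list(estimates = tab,
                          k = fit$k, k_se = fit$se,
                          true_remaining = g$remaining,
                          mean_remaining = mean(tab$remaining_corrected))
  }
  res
}

stage_iv <- function(cfg, seed) {
  protocol <- step_protocol()
  curves <- list()
  for (cell in c("cx30", "endogenous")) {
    p <- cfg$iv[[cell]]
    for (bath in c("na", "nmdg")) {
      # test oocytes carry endogenous + Cx30 conductance in parallel
      traces <- if (cell == "cx30") {
        tr1 <- simulate_step_protocol(p$conductance, p$erev[[bath]],
                                      protocol, cfg$iv$noise_sd, seed)
        tr2 <- simulate_step_protocol(cfg$iv$endogenous$conductance,
                                      cfg$iv$endogenous$erev[[bath]],
                                      protocol, cfg$iv$noise_sd, seed + 1L)
        Map(function(a, b) ec_trace(a$current + b$current, a$dt, a$units,
                                    a$label), tr1, tr2)
      } else {
        simulate_step_protocol(p$conductance, p$erev[[bath]], protocol,
                               cfg$iv$noise_sd, seed + 2L)
      }
      curves[[paste(cell, bath, sep = "_")]] <- build_iv(traces, protocol)
    }
  }
  corr_na <- subtract_background(curves$cx30_na, curves$endogenous_na)
  corr_nmdg <- subtract_background(curves$cx30_nmdg, curves$endogenous_nmdg)
  shift <- estimate_reversal(corr_nmdg) - estimate_reversal(corr_na)
  list(curves = curves,
       erev = list(test_na = estimate_reversal(curves$cx30_na),
                   test_nmdg = estimate_reversal(curves$cx30_nmdg),
                   corrected_na = estimate_reversal(corr_na),
                   corrected_nmdg = estimate_reversal(corr_nmdg)),
       delta_erev_corrected = shift,
       permeability_ratio = permeability_ratio(shift))
}

stage_patch <- function(cfg, seed) {
  p <- cfg$patch
  sim <- simulate_single_channel(
    gating_spec(p$n_channels, p$p_open, p$unitary_current, p$mean_open_ms,
                p$noise_sd),
    duration = p$duration, dt = p$dt, amiloride_tail = p$amiloride_tail,
    seed = seed)
  res <- analyze_patch(sim$trace, sim$annotation, holding = p$holding)
  gated <- seq_len(round((p$duration - p$amiloride_tail) / p$dt))
  list(result = res, true_npo = npo_time_average(sim$open_count[gated]))
}

#' Run the full simulate -> analyze -> infer -> report pipeline
#'
#' Executes the configured stages on synthetic data and writes cohort and
#' estimate CSVs, a JSON results summary, and a provenance record (seed,
#' package version, config hash). Identical config + seed gives identical
#' outputs.
#'
#' @param config A `run_config` from [default_config()] or [read_config()].
#' @param out_dir Optional override of the configured output directory.
#' @return Invisibly, a list with all stage results and output paths.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL) {
  cfg <- config
  if (!is.null(out_dir)) cfg$out_dir <- out_dir
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed
  results <- list()
  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  if ("simulate" %in% cfg$stages || "analyze" %in% cfg$stages) {
    sim <- run_stage("simulate", function() {
      spec <- cohort_spec(cfg$cohort$n_oocytes, cfg$cohort$n_batches,
                          cfg$cohort$groups, cfg$cohort$expression_cv,
                          cfg$cohort$batch_cv, cfg$cohort$noise_sd, seed)
      generate_cohort(spec)
    })
    utils::write.csv(sim$cohort, file.path(cfg$out_dir, "cohort.csv"),
                     row.names = FALSE)
    results$cohort <- sim$cohort
  }
  if ("analyze" %in% cfg$stages) {
    results$analysis <- run_stage("analyze", function() {
      ctrl <- cfg$cohort$groups[[1L]]$name
      norm <- batch_normalize(results$cohort, ctrl)
      summ <- summarize_groups(norm, "normalized")
      summ$relative_inhibition <- relative_inhibition(summ$mean, 1)
      list(normalized = norm, summary = summ)
    })
    utils::write.csv(results$analysis$summary,
                     file.path(cfg$out_dir, "group_summary.csv"),
                     row.names = FALSE)
  }
  if ("mtset" %in% cfg$stages) {
    results$mtset <- run_stage("mtset", function() stage_mtset(cfg, seed))
    est <- do.call(rbind, lapply(results$mtset, `[[`, "estimates"))
    utils::write.csv(est, file.path(cfg$out_dir, "mtset_estimates.csv"),
                     row.names = FALSE)
  }
  if ("iv" %in% cfg$stages) {
    results$iv <- run_stage("iv", function() stage_iv(cfg, seed))
    ivtab <- do.call(rbind, lapply(names(results$iv$curves), function(nm) {
      cv <- results$iv$curves[[nm]]
      data.frame(curve = nm, potential = cv$potential,
                 current = cv$current)
    }))
    utils::write.csv(ivtab, file.path(cfg$out_dir, "iv.csv"),
                     row.names = FALSE)
  }
  if ("patch" %in% cfg$stages) {
    results$patch <- run_stage("patch", function() stage_patch(cfg, seed))
  }
  if ("report" %in% cfg$stages) {
    summary <- list(
      groups = if (!is.null(results$analysis))
        results$analysis$summary else NULL,
      mtset = if (!is.null(results$mtset))
        lapply(results$mtset, function(m)
          m[c("k", "k_se", "mean_remaining", "true_remaining")]) else NULL,
      iv = if (!is.null(results$iv))
        results$iv[c("erev", "delta_erev_corrected",
                     "permeability_ratio")] else NULL,
      patch = if (!is.null(results$patch))
        c(results$patch$result[c("i", "apparent_n", "npo", "po_app",
                                 "conductance_pS")],
          list(true_npo = results$patch$true_npo)) else NULL)
    jsonlite::write_json(summary, file.path(cfg$out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    cfg_file <- file.path(cfg$out_dir, "config.json")
    jsonlite::write_json(unclass(cfg), cfg_file, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    # hash the scientific config only (output location excluded)
    hash_file <- tempfile(fileext = ".json")
    hcfg <- unclass(cfg); hcfg$out_dir <- NULL
    jsonlite::write_json(hcfg, hash_file, auto_unbox = TRUE, digits = NA)
    on.exit(unlink(hash_file), add = TRUE)
    prov <- list(seed = seed,
                 package_version =
                   as.character(utils::packageVersion("enactraff")),
                 config_hash = unname(tools::md5sum(hash_file)),
                 timestamp = format(Sys.time(), tz = "UTC"))
    jsonlite::write_json(prov, file.path(cfg$out_dir, "provenance.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    results$provenance <- prov
  }
  invisible(results)
}

#' Command-line entry point
#'
#' Thin front end used by `inst/scripts/enactraff`:
#' `enactraff <simulate|analyze|iv|mtset|patch|report|all> [--config file]
#' [--seed n] [--out dir]`. Each subcommand runs the corresponding pipeline
#' stage (plus any stage it depends on); `all`/`report` runs everything.
#'
#' @param args Character vector of command-line arguments.
#' @return Invisibly, the [run_pipeline()] result.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args)) stop("usage: enactraff <subcommand> [--config file] ",
                          "[--seed n] [--out dir]")
  sub <- args[1L]; args <- args[-1L]
  getopt <- function(flag) {
    i <- which(args == flag)
    if (length(i)) args[i[1L] + 1L] else NULL
  }
  cfg <- if (!is.null(getopt("--config"))) read_config(getopt("--config"))
         else default_config()
  if (!is.null(getopt("--seed"))) cfg$seed <- as.integer(getopt("--seed"))
  if (!is.null(getopt("--out"))) cfg$out_dir <- getopt("--out")
  cfg$stages <- switch(sub,
    simulate = "simulate",
    analyze = c("simulate", "analyze"),
    mtset = "mtset",
    iv = "iv",
    patch = "patch",
    report = , all = c("simulate", "analyze", "mtset", "iv", "patch",
                       "report"),
    stop("unknown subcommand: ", sub))
  message("enactraff: running [", paste(cfg$stages, collapse = ", "),
          "] with seed ", cfg$seed, " -> ", cfg$out_dir)
  invisible(run_pipeline(cfg))
}
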