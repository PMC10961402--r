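#' Run the analysis pipeline end-to-end
#'
#' Orchestrates the stages of the trial analysis with reproducible seeding:
#' each stage writes delimited result tables into `outdir` and a manifest
#' records the configuration hash, seeds and stage status. Stage
#' dependencies are checked up front (fail fast); per-stage seeds are
#' derived deterministically from the base seed and the stage name so a
#' stage can be re-run in isolation with identical results.
#'
#' @param config A configuration list or the path of a YAML file with
#'   blocks `sim` (arguments to [sim_config()]), `pkpd` (e.g. `exclusion`),
#'   `eval` (`bootstrap_B`, `vpc_n_sim`), and `seed`.
#' @param stages Character subset of `"simulate"`, `"nca"`, `"pd"`,
#'   `"emax-fit"`, `"fit-pk"`, `"covariate-search"`, `"fit-pkpd"`,
#'   `"bootstrap"`, `"vpc"`, `"report"` (default: all, in order).
#' @param outdir Output directory (created if missing).
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the computed stage results.
#' @export
run_pipeline <- function(config = list(), stages = pipeline_stages(),
                         outdir = tempfile("pkpd_run_"), quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stages <- match.arg(stages, pipeline_stages(), several.ok = TRUE)
  deps <- list(
    "nca" = "simulate", "pd" = "simulate", "emax-fit" = "simulate",
    "fit-pk" = "simulate", "covariate-search" = "fit-pk",
    "fit-pkpd" = "fit-pk", "bootstrap" = "fit-pk", "vpc" = "fit-pk",
    "report" = "simulate")
  for (st in stages) {
    for (d in deps[[st]] %||% character()) {
      if (!d %in% stages) {
        abort(paste0("stage '", st, "' requires stage '", d,
                     "' in the same run"))
      }
    }
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  base_seed <- config$seed %||% 1
  say <- function(...) if (!quiet) inform(paste0(...))
  res <- list()
  t_start <- Sys.time()

  if ("simulate" %in% stages) {
    say("stage simulate")
    sim_args <- config$sim %||% list()
    sim_args$seed <- stage_seed(base_seed, "simulate")
    cfg <- do.call(sim_config, sim_args)
    res$sim <- simulate_trial(cfg)
    write_dataset(res$sim$dataset, file.path(outdir, "dataset.csv"))
    readr::write_csv(res$sim$truth$subjects,
                     file.path(outdir, "truth_subjects.csv"))
  }
  if ("nca" %in% stages) {
    say("stage nca")
    res$nca <- run_nca(res$sim$dataset)
    res$nca_summary <- nca_summary(res$nca)
    readr::write_csv(res$nca, file.path(outdir, "nca_subjects.csv"))
    readr::write_csv(res$nca_summary, file.path(outdir, "nca_summary.csv"))
  }
  if ("pd" %in% stages) {
    say("stage pd")
    res$dpp4 <- dpp4_summary(res$sim$dataset)
    res$glp1 <- glp1_summary(res$sim$dataset)
    res$ogtt <- run_ogtt(res$sim$dataset)
    res$efficacy <- efficacy_changes(res$sim$dataset)
    readr::write_csv(res$dpp4, file.path(outdir, "pd_dpp4.csv"))
    readr::write_csv(res$glp1, file.path(outdir, "pd_glp1.csv"))
    readr::write_csv(res$ogtt$changes, file.path(outdir, "pd_ogtt.csv"))
    readr::write_csv(res$efficacy, file.path(outdir, "pd_efficacy.csv"))
  }
  if ("emax-fit" %in% stages) {
    say("stage emax-fit")
    pairs <- emax_pairs(res$sim$dataset)
    res$emax <- fit_emax(pairs$conc, pairs$inhibition)
    readr::write_csv(tidy(res$emax), file.path(outdir, "emax_params.csv"))
  }
  if ("fit-pk" %in% stages) {
    say("stage fit-pk")
    res$pk_model <- pk_twocomp_model()
    res$pk_fit <- fit_population(res$sim$dataset, res$pk_model)
    readr::write_csv(tidy(res$pk_fit), file.path(outdir, "pk_params.csv"))
    readr::write_csv(cwres(res$pk_fit),
                     file.path(outdir, "pk_diagnostics.csv"))
  }
  if ("covariate-search" %in% stages) {
    say("stage covariate-search")
    res$covsearch <- stepwise_covariate_search(
      res$sim$dataset, res$pk_model,
      candidates = list(list(parameter = "v2", covariate = "TBIL")))
    readr::write_csv(res$covsearch$log,
                     file.path(outdir, "covariate_search.csv"))
  }
  if ("fit-pkpd" %in% stages) {
    say("stage fit-pkpd")
    excl <- config$pkpd$exclusion %||% 5
    res$pkpd_data <- build_pkpd_dataset(res$pk_fit, res$sim$dataset, excl)
    res$pkpd_fit <- fit_pkpd(res$pkpd_data)
    readr::write_csv(tidy(res$pkpd_fit),
                     file.path(outdir, "pkpd_params.csv"))
  }
  if ("bootstrap" %in% stages) {
    say("stage bootstrap")
    B <- config$eval$bootstrap_B %||% 1000
    res$bootstrap <- bootstrap_model(
      res$sim$dataset, update_inits(res$pk_model, res$pk_fit), B = B,
      seed = stage_seed(base_seed, "bootstrap"))
    readr::write_csv(res$bootstrap$summary,
                     file.path(outdir, "bootstrap.csv"))
  }
  if ("vpc" %in% stages) {
    say("stage vpc")
    n_sim <- config$eval$vpc_n_sim %||% 1000
    res$vpc <- vpc(res$pk_fit, n_sim = n_sim,
                   seed = stage_seed(base_seed, "vpc"))
    readr::write_csv(tibble::as_tibble(res$vpc),
                     file.path(outdir, "vpc.csv"))
  }
  if ("report" %in% stages) {
    say("stage report")
    # manifest: configuration hash + seeds + stage list
    cfg_file <- file.path(outdir, "config.yaml")
    yaml::write_yaml(config, cfg_file)
    manifest <- c(
      paste0("config_md5: ", unname(tools::md5sum(cfg_file))),
      paste0("seed: ", base_seed),
      paste0("stages: ", paste(stages, collapse = ",")),
      paste0("package: cetapkpd ",
             as.character(utils::packageVersion("cetapkpd"))))
    writeLines(manifest, file.path(outdir, "manifest.txt"))
  }
  say(sprintf("pipeline finished in %.1f s -> %s",
              as.numeric(difftime(Sys.time(), t_start, units = "secs")),
              outdir))
  invisible(res)
}

#' Pipeline stage names, in execution order
#' @return Character vector.
#' @export
pipeline_stages <- function() {
  c("simulate", "nca", "pd", "emax-fit", "fit-pk", "covariate-search",
    "fit-pkpd", "bootstrap", "vpc", "report")
}

#' Derive a per-stage seed from the base seed
#'
#' Deterministic fan-out so stages can re-run independently yet
#' reproducibly; stays below 2^31.
#'
#' @param base_seed Integer base seed.
#' @param stage Stage name.
#' @return Integer seed.
#' @export
stage_seed <- function(base_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(base_seed) * 10007 + h) %% 2147483629)
}

#' Day-14 DPP-4 inhibition summaries per arm
#'
#' Per-subject inhibition summaries on day 1 and day 14 (interval
#' statistics over the dosing interval, time-above-threshold over the full
#' sampled extent on day 14), then group means.
#'
#' @param ds A [study_dataset()].
#' @return Tibble: one row per subject x occasion joined with arm, plus
#'   summary columns via [nca_summary()]-style aggregation left to the
#'   caller; columns `r_max`, `auec_0_24`, `dur_80`, `e_24`, ...
#' @export
dpp4_summary <- function(ds) {
  act <- tibble::as_tibble(ds) %>%
    dplyr::filter(.data$EVID == 0L, .data$DVID == "dpp4_activity")
  last_dose_of <- function(sub_id) {
    dt <- ds$TIME[ds$ID == sub_id & ds$EVID == 1L]
    if (length(dt) == 0) 24 * 13 else max(dt)
  }
  rows <- list()
  for (id in unique(act$ID)) {
    a <- act[act$ID == id, ]
    base <- a$DV[which.min(a$TIME)]
    inh <- dpp4_inhibition(a$TIME, a$DV, base)
    t14 <- last_dose_of(id)
    for (occ in c("day1", "day14")) {
      sel <- a$OCC == occ
      if (sum(sel) < 2) next
      tt <- inh$time[sel]
      ii <- inh$inhibition[sel]
      t_ref <- if (occ == "day1") 0 else t14
      s <- inhibition_summary(tt - t_ref, ii, interval = c(0, 24),
                              dur_interval = c(0, max(tt - t_ref)))
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble::tibble(ID = id, ARM = a$ARM[1], occasion = occ), s)
    }
  }
  dplyr::bind_rows(rows)
}

#' Day-1/day-14 GLP-1 change-from-predose summaries
#'
#' @param ds A [study_dataset()].
#' @return Tibble of per-subject x occasion GLP-1 summary parameters.
#' @export
glp1_summary <- function(ds) {
  glp <- tibble::as_tibble(ds) %>%
    dplyr::filter(.data$EVID == 0L, .data$DVID == "glp1_active")
  rows <- list()
  for (id in unique(glp$ID)) {
    g <- glp[glp$ID == id, ]
    t14 <- max(ds$TIME[ds$ID == id & ds$EVID == 1L], 24 * 13)
    for (occ in c("day1", "day14")) {
      sel <- g$OCC == occ
      if (sum(sel) < 2) next
      t_ref <- if (occ == "day1") 0 else t14
      d <- tryCatch(delta_glp1(g$TIME[sel] - t_ref, g$DV[sel]),
                    error = function(e) NULL)
      if (is.null(d)) next
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble::tibble(ID = id, ARM = g$ARM[1], occasion = occ),
        d$summary)
    }
  }
  dplyr::bind_rows(rows)
}
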