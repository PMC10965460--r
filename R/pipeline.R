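#' Run the full LE/HALE estimation pipeline
#'
#' Orchestrates the stages end to end: obtain panel records (simulate
#' them or read a CSV), aggregate into age-grouped mortality counts and
#' baseline prevalence, build Chiang abridged life tables, compute
#' Sullivan LE/HALE/ratio per stratum, and optionally fit the
#' illness-death model and integrate state-specific life expectancies.
#' Every filtering step is logged with before/after record counts so the
#' exclusion cascade is auditable; any stage failure aborts with the
#' stage name and cause.
#'
#' The configuration is a named list (or the path of a YAML file with
#' the same structure) with components:
#' \describe{
#'   \item{simulate}{list passed to [simulation_config()]; mutually
#'     exclusive with `panel_csv`.}
#'   \item{panel_csv}{path of a panel-record CSV to read instead.}
#'   \item{counts_csv}{optional external mortality schedule for the
#'     Sullivan life table (e.g. a national surveillance schedule); by
#'     default the schedule is aggregated from the cohort's own records.}
#'   \item{prevalence_csv}{optional external prevalence table; by default
#'     baseline prevalence is aggregated from the records.}
#'   \item{age_breaks}{interval starts, default `c(65, 70, 75, 80, 85)`.}
#'   \item{radix}{life-table radix, default 100000.}
#'   \item{start_ages}{Sullivan reporting ages, default `c(65, 70, 75)`.}
#'   \item{multistate}{logical: fit the illness-death model (default
#'     `TRUE` when records carry any follow-up information).}
#'   \item{msm_ages}{starting ages for multistate life expectancies,
#'     default 65.}
#'   \item{grid_step_lik, grid_step_le, max_age}{numerical settings,
#'     defaults 0.25, 0.1, 110.}
#'   \item{seed}{overrides the simulation seed.}
#'   \item{out_dir}{if set, results are written there as
#'     `lifetable.csv`, `prevalence.csv`, `hale_sullivan.csv`,
#'     `msm_params.csv`, `msm_life_expectancy.csv`.}
#'   \item{margins}{logical: log the published screening cascade of the
#'     reference cohort (from [henan_margins()]) alongside the run.}
#' }
#'
#' @param config named list or YAML file path.
#' @param verbose emit progress/log lines (via `message`, i.e. stderr)?
#' @return invisibly, a list with `records`, `aggregates`, `lifetables`,
#'   `hale` (Sullivan results per stratum), and when enabled `fit` and
#'   `msm_life_expectancy`; plus the logged `cascade` data frame.
#' @export
run_pipeline <- function(config = list(), verbose = TRUE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  log_msg <- function(...) if (verbose) message("[idhale] ", ...)
  fmt <- function(n) format(n, big.mark = ",", trim = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  cfg <- function(name, default) if (!is.null(config[[name]])) config[[name]] else default
  age_breaks <- cfg("age_breaks", c(65, 70, 75, 80, 85))
  start_ages <- cfg("start_ages", c(65, 70, 75))

  if (isTRUE(cfg("margins", FALSE))) {
    mg <- henan_margins()
    log_msg("reference cohort cascade: ",
            fmt(mg$screening$n[1]), " screened -> ",
            fmt(mg$screening$n[5]), " analytic -> ",
            fmt(mg$followup$n[3]), " in the longitudinal panel")
  }

  records <- stage("records", {
    if (!is.null(config$panel_csv)) {
      log_msg("reading panel records from ", config$panel_csv)
      read_panel_csv(config$panel_csv)
    } else {
      sim_args <- cfg("simulate", list())
      if (!is.null(config$seed)) sim_args$seed <- config$seed
      sim_cfg <- do.call(simulation_config, sim_args)
      log_msg("simulating cohort of ", fmt(sim_cfg$cohort_size),
              " subjects (seed ", sim_cfg$seed, ")")
      simulate_cohort(sim_cfg)
    }
  })
  n_all <- nrow(records)
  n_lost <- sum(records$exit_kind == "lost")
  log_msg("records: ", fmt(n_all), " total; ", fmt(n_lost),
          " lost to follow-up; ", fmt(n_all - n_lost),
          " enter the longitudinal fit")
  cascade <- data.frame(
    stage = c("records", "lost_to_followup", "panel_analytic"),
    n = c(n_all, n_lost, n_all - n_lost))

  strata <- list(total = records,
                 men = records[records$sex == "male", ],
                 women = records[records$sex == "female", ])
  strata <- Filter(nrow, strata)

  external_counts <- if (!is.null(config$counts_csv))
    read_counts_csv(config$counts_csv) else NULL
  external_prev <- if (!is.null(config$prevalence_csv))
    read_prevalence_csv(config$prevalence_csv) else NULL

  # When the mortality schedule comes from the cohort's own records, the
  # terminal open-ended band must contain deaths in every stratum; trim
  # the banding to the ages the cohort actually supports (a short
  # follow-up cannot furnish a full old-age schedule -- that is what an
  # external surveillance schedule via counts_csv is for).
  if (is.null(external_counts)) {
    max_death <- min(vapply(strata, function(r) {
      suppressWarnings(max(r$exit_age[r$exit_kind == "death_exact"], -Inf))
    }, numeric(1)))
    supported <- age_breaks[age_breaks < max_death]
    if (length(supported) < 2L)
      stage("aggregate", stop("cohort has too few deaths to support an ",
                              "age-grouped mortality schedule; supply ",
                              "'counts_csv'"))
    if (length(supported) < length(age_breaks)) {
      log_msg("age banding trimmed to terminal interval ",
              supported[length(supported)],
              "+ (no deaths observed beyond in every stratum)")
      age_breaks <- supported
    }
  }
  aggregates <- stage("aggregate", lapply(strata, aggregate_counts,
                                          age_breaks = age_breaks))

  result <- list(records = records, aggregates = aggregates,
                 cascade = cascade)
  if (isTRUE(cfg("sullivan", TRUE))) {
    lifetables <- stage("lifetable", lapply(aggregates, function(agg) {
      build_abridged_life_table(
        if (is.null(external_counts)) agg$counts else external_counts,
        radix = cfg("radix", 1e5))
    }))
    start_ages <- start_ages[start_ages <= age_breaks[length(age_breaks)]]
    hale <- stage("sullivan", lapply(names(aggregates), function(s) {
      prev <- if (is.null(external_prev)) aggregates[[s]]$prevalence else external_prev
      out <- sullivan_hale(lifetables[[s]], prev, start_age = start_ages)
      out$stratum <- s
      out
    }))
    hale <- do.call(rbind, hale)
    log_msg("Sullivan HALE computed for strata: ",
            paste(names(aggregates), collapse = ", "))
    result$lifetables <- lifetables
    result$hale <- hale
  }

  if (isTRUE(cfg("multistate", TRUE))) {
    fit <- stage("fit-msm", fit_idd_model(
      records, grid_step = cfg("grid_step_lik", 0.25)))
    log_msg("illness-death model fitted on ", fmt(fit$n), " records (",
            fit$events[["deaths"]], " deaths, ",
            fit$events[["incident"]], " incident); converged: ",
            fit$converged)
    msm_le <- stage("life-expectancy", {
      grid <- expand.grid(age = cfg("msm_ages", 65), sex = c("female", "male"),
                          stringsAsFactors = FALSE)
      do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
        sle <- state_specific_life_expectancy(
          fit$model, grid$age[i], z = as.numeric(grid$sex[i] == "male"),
          grid_step = cfg("grid_step_le", 0.1), max_age = cfg("max_age", 110))
        data.frame(sex = grid$sex[i], age = grid$age[i], le = sle$le,
                   hale = sle$hale,
                   ratio_pct = hale_le_ratio(sle$le, sle$hale),
                   e22 = unname(sle$e[2, 2]))
      }))
    })
    result$fit <- fit
    result$msm_life_expectancy <- msm_le
  }

  if (!is.null(config$out_dir)) {
    stage("write", {
      dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
      out <- function(f) file.path(config$out_dir, f)
      pv <- do.call(rbind, lapply(names(aggregates), function(s) {
        cbind(stratum = s, aggregates[[s]]$prevalence)
      }))
      write_results_csv(pv, out("prevalence.csv"))
      if (!is.null(result$hale)) {
        lt <- do.call(rbind, lapply(names(result$lifetables), function(s) {
          cbind(stratum = s, as.data.frame(result$lifetables[[s]]))
        }))
        write_results_csv(lt, out("lifetable.csv"))
        write_results_csv(
          result$hale[c("stratum", "age", "le", "hale", "ratio_pct")],
          out("hale_sullivan.csv"))
      }
      if (!is.null(result$fit)) {
        write_results_csv(
          data.frame(parameter = names(result$fit$coefficients),
                     estimate = unname(result$fit$coefficients),
                     se = unname(result$fit$se)),
          out("msm_params.csv"))
        write_results_csv(result$msm_life_expectancy,
                          out("msm_life_expectancy.csv"))
      }
      log_msg("results written to ", config$out_dir)
    })
  }
  invisible(result)
}
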