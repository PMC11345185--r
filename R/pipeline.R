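#' Pipeline run configuration
#'
#' Assembles the stage parameters for [run_pfr_pipeline()] with every
#' threshold at its standard default: the 0.2 slope band, 12 s / 30-sample
#' Mx windows, 10 s / 30-sample PRx windows, 10-min perfusion gap tolerance,
#' quality-control limits (perfusion 130 sample / 95 five-min-mean ceilings,
#' 100 mmHg ICP plateau), the 0.43 joint-index discriminant coefficient,
#' the 0.15 neutral-Mx cut, and the conventional 0.3 single-index
#' impairment heuristic.
#'
#' @param seed Master seed; per-stage seeds are derived by fixed offsets.
#' @param simulate List: `n_epochs_per_regime`, `regimes`, `duration_min`,
#'   and `spec_args` forwarded to [synth_spec()]. Ignored when `input_dirs`
#'   is given.
#' @param input_dirs Optional character vector of epoch directories to read
#'   instead of simulating.
#' @param extract List of [extract_intervals()] arguments.
#' @param qc A [qc_rules()] object.
#' @param model An [inversion_config()].
#' @param classify List: `threshold`, `min_n`.
#' @param indices List of Mx/PRx window parameters.
#' @param analysis List: `discriminant_c`, `neutral_cut`, `ca_index_cut`.
#' @return A list of class `pfr_config` (schema version 1).
#' @export
pfr_config <- function(seed = 1L,
                       simulate = list(),
                       input_dirs = NULL,
                       extract = list(),
                       qc = qc_rules(),
                       model = inversion_config(),
                       classify = list(),
                       indices = list(),
                       analysis = list()) {
  defaults <- list(
    schema_version = 1L,
    seed = as.integer(seed),
    simulate = utils::modifyList(
      list(n_epochs_per_regime = 2L, regimes = c("pPFR", "zPFR", "nPFR"),
           duration_min = 120, spec_args = list()), simulate),
    input_dirs = input_dirs,
    extract = utils::modifyList(
      list(min_len = 100, max_len = 140, perf_gap_tol = 10), extract),
    qc = qc,
    model = model,
    classify = utils::modifyList(list(threshold = 0.2, min_n = 30), classify),
    indices = utils::modifyList(
      list(mx_avg = 12, mx_n = 30, prx_avg = 10, prx_n = 30, step = 60),
      indices),
    analysis = utils::modifyList(
      list(discriminant_c = 0.43, neutral_cut = 0.15, ca_index_cut = 0.3),
      analysis)
  )
  stopifnot(defaults$classify$threshold >= 0,
            defaults$extract$min_len <= defaults$extract$max_len)
  structure(defaults, class = "pfr_config")
}

stage_failed <- function(stage, id, err) {
  stop(sprintf("stage '%s' failed for %s: %s", stage, id,
               conditionMessage(err)), call. = FALSE)
}

#' Run the full pressure-flow-regime pipeline
#'
#' Orchestrates the stages in dependency order: simulate (or read) epochs,
#' extract nominally 2-h analysis intervals, screen them with the
#' quality-control rules, estimate model CBF and classify the pressure-flow
#' regime of each passing interval, compute Mx and PRx summaries, and
#' aggregate a cohort report with the regime proportions. Stage outputs are
#' pure functions of the configuration and seed; the returned manifest
#' carries content digests that reproduce exactly on a re-run.
#'
#' @param config A [pfr_config()].
#' @return A list of class `pfr_report`: `intervals` (one row per extracted
#'   interval with QC outcome, label, slope and index summaries),
#'   `proportions` (regime shares over QC-passing intervals, summing to
#'   100), `manifest`, and the `config`.
#' @export
run_pfr_pipeline <- function(config = pfr_config()) {
  stopifnot(inherits(config, "pfr_config"))

  # --- acquire epochs ------------------------------------------------------
  epochs <- if (!is.null(config$input_dirs)) {
    lapply(config$input_dirs, function(d) {
      tryCatch(list(epoch = read_epoch(d), truth = NULL, regime = NA_character_),
               error = function(e) stage_failed("ingest", d, e))
    })
  } else {
    sim <- config$simulate
    out <- list()
    for (ri in seq_along(sim$regimes)) {
      for (i in seq_len(sim$n_epochs_per_regime)) {
        seed_i <- config$seed + 1000L * ri + i
        args <- utils::modifyList(
          list(regime = sim$regimes[ri], duration_min = sim$duration_min,
               seed = seed_i),
          sim$spec_args)
        le <- tryCatch(generate_regime_epoch(do.call(synth_spec, args)),
                       error = function(e)
                         stage_failed("simulate", sprintf("%s#%d", sim$regimes[ri], i), e))
        out[[length(out) + 1L]] <- le
      }
    }
    out
  }

  # --- extract + QC + classify + indices ----------------------------------
  rows <- list()
  for (le in epochs) {
    ep <- le$epoch
    iv <- tryCatch(
      extract_intervals(ep, config$extract$min_len, config$extract$max_len,
                        config$extract$perf_gap_tol),
      error = function(e) stage_failed("extract", attr(ep, "epoch_id") %||% "?", e))
    for (k in seq_len(nrow(iv))) {
      id <- iv$interval_id[k]
      dat <- iv$data[[k]]
      qc <- qc_filter(dat, config$qc, abp_upper = iv$abp_q998[k])
      row <- tibble::tibble(
        interval_id = id, patient_id = iv$patient_id[k],
        epoch_id = iv$epoch_id[k], start = iv$start[k], end = iv$end[k],
        truth = le$regime %||% NA_character_,
        qc_passed = qc$passed,
        qc_rules = paste(unique(qc$reasons$rule), collapse = ";")
      )
      if (qc$passed) {
        cls <- tryCatch(
          classify_interval(dat, config$classify$threshold, config$model,
                            config$classify$min_n),
          error = function(e) stage_failed("classify", id, e))
        abp <- epoch_channel(dat, "ABP")
        icp <- epoch_channel(dat, "ICP")
        perf <- epoch_channel(dat, "PERF")
        idxcfg <- config$indices
        ix <- tryCatch({
          cpp_fine <- cpp_series(abp, icp, 1)
          list(
            mx = mx(perf, cpp_fine, idxcfg$mx_avg, idxcfg$mx_n, idxcfg$step),
            prx = prx(abp, icp, idxcfg$prx_avg, idxcfg$prx_n, idxcfg$step)
          )
        }, error = function(e) stage_failed("indices", id, e))
        row$label <- as.character(cls$label)
        row$m <- cls$m
        row$mx_mean <- index_mean(ix$mx)
        row$prx_mean <- index_mean(ix$prx)
        row$ca_impaired <- ca_impaired(row$prx_mean, row$mx_mean,
                                       config$analysis$discriminant_c)
      } else {
        row$label <- NA_character_
        row$m <- NA_real_
        row$mx_mean <- NA_real_
        row$prx_mean <- NA_real_
        row$ca_impaired <- NA
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  intervals <- dplyr::bind_rows(rows)

  # --- aggregate -----------------------------------------------------------
  passing <- intervals[!is.na(intervals$qc_passed) & intervals$qc_passed, ]
  if (nrow(passing) == 0L) {
    warning("no analyzable intervals after quality control")
    proportions <- tibble::tibble(label = character(), n = integer(),
                                  percent = numeric())
  } else {
    proportions <- passing |>
      dplyr::count(.data$label) |>
      dplyr::mutate(percent = 100 * .data$n / sum(.data$n))
  }

  manifest <- list(
    schema_version = config$schema_version,
    package_version = as.character(utils::packageVersion("icpfr")),
    seed = config$seed,
    config_digest = rlang::hash(config),
    intervals_digest = rlang::hash(intervals),
    proportions_digest = rlang::hash(proportions),
    n_epochs = length(epochs),
    n_intervals = nrow(intervals),
    n_passing = nrow(passing)
  )
  structure(list(intervals = intervals, proportions = proportions,
                 manifest = manifest, config = config),
            class = "pfr_report")
}

#' @export
print.pfr_report <- function(x, ...) {
  cat(sprintf("<pfr_report> %d epochs, %d intervals (%d passing QC)\n",
              x$manifest$n_epochs, x$manifest$n_intervals,
              x$manifest$n_passing))
  if (nrow(x$proportions) > 0L) print(x$proportions)
  invisible(x)
}

#' Per-interval results of a pipeline run
#'
#' @param x A `pfr_report`.
#' @param ... Unused.
#' @export
tidy.pfr_report <- function(x, ...) x$intervals

#' One-row summary of a pipeline run
#'
#' @param x A `pfr_report`.
#' @param ... Unused.
#' @export
glance.pfr_report <- function(x, ...) {
  tibble::tibble(
    n_epochs = x$manifest$n_epochs,
    n_intervals = x$manifest$n_intervals,
    n_passing = x$manifest$n_passing,
    config_digest = x$manifest$config_digest,
    intervals_digest = x$manifest$intervals_digest
  )
}
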