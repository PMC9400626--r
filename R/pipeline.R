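# Orchestration: per-cell serial-dependence analyses (inducer x condition x
# trial subset), moving-average curves for plotting, and a config-driven
# full-replication runner writing machine-readable result tables.

.INDUCERS <- c("cued", "imi", "C_on_next", "imi_on_C_within")
.SUBSETS <- c("all", "A_probed", "C_probed")

#' Run one serial-dependence analysis cell
#'
#' Selects the trials of one condition (and optionally one probe subset),
#' builds the (x, y) pairs for the requested inducer, and runs the
#' permutation test plus bootstrap CI. Inducers: `"cued"` (the retrocued
#' item), `"imi"` (the irrelevant memory item), `"C_on_next"` (item C's
#' influence on the next-trial recall), and `"imi_on_C_within"` (the
#' within-trial influence of the IMI on the recall of item C; requires
#' `subset = "C_probed"` since it uses the ABC reports of item C). Subsets:
#' `"all"`, `"A_probed"` (the retrocued item was probed on the ABC trial),
#' `"C_probed"` (item C was probed).
#'
#' @param data Preprocessed derived table (see [preprocess_trial_pairs()]).
#' @param inducer One of `"cued"`, `"imi"`, `"C_on_next"`,
#'   `"imi_on_C_within"`.
#' @param condition `"overlap"` or `"no_overlap"`.
#' @param subset One of `"all"`, `"A_probed"`, `"C_probed"`.
#' @param n_perm,n_boot,seed,alternative Passed to
#'   [permutation_test_serial_bias()].
#' @return A `bias_test` (see [permutation_test_serial_bias()]) with the cell
#'   description attached as `$cell`.
#' @export
run_serial_dependence_analysis <- function(data, inducer, condition,
                                           subset = "all", n_perm = 1000L,
                                           n_boot = 1000L, seed = NULL,
                                           alternative = "two.sided") {
  if (length(inducer) != 1L || !(inducer %in% .INDUCERS)) {
    .sb_stop("sb_invalid_spec", "unknown inducer '%s' (expected one of: %s)",
             paste(inducer, collapse = ","), paste(.INDUCERS, collapse = ", "))
  }
  if (length(condition) != 1L || !(condition %in% .CONDITIONS)) {
    .sb_stop("sb_invalid_spec", "unknown condition '%s'", condition)
  }
  if (length(subset) != 1L || !(subset %in% .SUBSETS)) {
    .sb_stop("sb_invalid_spec", "unknown subset '%s'", subset)
  }
  if (inducer == "imi_on_C_within" && subset != "C_probed") {
    .sb_stop("sb_invalid_spec",
             "imi_on_C_within uses the ABC reports of item C and requires subset = 'C_probed'")
  }
  keep <- data$included & data$condition == condition
  keep <- keep & switch(subset,
    all = TRUE,
    A_probed = data$abc_probe == "cued",
    C_probed = data$abc_probe == "C"
  )
  rows <- data[keep, , drop = FALSE]
  if (inducer == "imi_on_C_within") {
    rows <- rows[!is.na(rows$abc_resid_C), , drop = FALSE]
    x <- rows$x_imi_vs_C
    y <- rows$abc_resid_C
  } else {
    rows <- rows[!is.na(rows$residual_error), , drop = FALSE]
    x <- switch(inducer, cued = rows$x_cued, imi = rows$x_imi,
                C_on_next = rows$x_C)
    y <- rows$residual_error
  }
  if (nrow(rows) == 0L) {
    .sb_stop("sb_insufficient_data", "no rows selected for %s / %s / %s",
             inducer, condition, subset)
  }
  res <- permutation_test_serial_bias(.deg2rad(x), y, n_perm = n_perm,
                                      n_boot = n_boot, seed = seed,
                                      alternative = alternative)
  res$cell <- list(inducer = inducer, condition = condition, subset = subset)
  res
}

#' Moving-average curve of residual error against relative angle
#'
#' Sorts the data by `x` and averages over sliding windows of `window`
#' consecutive points advanced by `step` points, reporting the window means
#' of x and y and the standard error of the mean of y. This is the summary
#' curve conventionally plotted behind the DoG fit.
#'
#' @param x Relative angles (any unit; only their order and means are used).
#' @param y Residual errors.
#' @param window Window size in data points (default 200).
#' @param step Step size in data points (default 40).
#' @return A data.frame with `floor((n - window)/step) + 1` rows and columns
#'   `x_center`, `y_mean`, `y_sem`.
#' @export
moving_average_curve <- function(x, y, window = 200L, step = 40L) {
  window <- .check_count(window, "window", 1L)
  step <- .check_count(step, "step", 1L)
  if (length(x) != length(y)) {
    .sb_stop("sb_invalid_argument", "x and y must have equal length")
  }
  n <- length(x)
  if (n < window) {
    .sb_stop("sb_insufficient_data",
             "need at least `window` = %d points (got %d)", window, n)
  }
  ord <- order(x)
  x <- x[ord]; y <- y[ord]
  starts <- seq(1L, n - window + 1L, by = step)
  out <- data.frame(x_center = numeric(length(starts)),
                    y_mean = numeric(length(starts)),
                    y_sem = numeric(length(starts)))
  for (i in seq_along(starts)) {
    idx <- starts[i]:(starts[i] + window - 1L)
    out$x_center[i] <- mean(x[idx])
    out$y_mean[i] <- mean(y[idx])
    s <- stats::sd(y[idx])
    out$y_sem[i] <- if (is.na(s)) 0 else s / sqrt(window)
  }
  out
}

# ---- config-driven full replication -----------------------------------------

.cfg_get <- function(config, field, required = FALSE, default = NULL) {
  v <- config[[field]]
  if (is.null(v)) {
    if (required) .sb_stop("sb_config_error", "config field '%s' is required", field)
    return(default)
  }
  v
}

.sim_config_from_list <- function(lst, where = "simulation") {
  if (is.null(lst$n_subjects)) {
    .sb_stop("sb_config_error", "config field '%s.n_subjects' is required", where)
  }
  args <- lst[intersect(names(lst),
                        c("n_subjects", "blocks_per_condition",
                          "pairs_per_block", "noise_sd_1item", "noise_sd_abc",
                          "bias_kernels", "subject_sd", "seed"))]
  unknown <- setdiff(names(lst), names(args))
  if (length(unknown)) {
    .sb_stop("sb_config_error", "unknown config field(s) under '%s': %s",
             where, paste(unknown, collapse = ", "))
  }
  do.call(simulation_config, args)
}

#' Run a full replication analysis from a YAML config
#'
#' Drives the whole pipeline from one declarative configuration: load (or
#' simulate) a trial-pair dataset, preprocess it, run every requested
#' analysis cell with permutation test and bootstrap CI, optionally run the
#' between-condition difference test, the direct/indirect/null model
#' comparison per condition, and a power analysis, and write machine-readable
#' outputs (`results.csv`, `results.json`, and one moving-average curve CSV
#' per cell) to `out_dir`. With a fixed config and seed the outputs are
#' byte-identical across runs.
#'
#' Config fields: one of `dataset` (CSV path) or `simulation` (arguments of
#' [simulation_config()]); `seed`; optional `preprocess` (`n_sd`, `metric`,
#' `screen`), `n_perm`, `n_boot`, `cells` (list of `inducer` / `condition` /
#' `subset`), `condition_difference` (`inducer`), `model_comparison`
#' (logical), `power` (`inducer`, `condition`, `n_points`, `n_datasets`,
#' `n_perm`), `curve` (`window`, `step`), `out_dir`.
#'
#' @param config_path Path to a YAML configuration file, or an equivalent
#'   named list.
#' @param out_dir Output directory (overrides the config's `out_dir`; `NULL`
#'   suppresses file output).
#' @return A list with `results` (one data.frame row per cell),
#'   `condition_difference`, `model_comparison`, `power`, `curves`,
#'   `preprocessing`, and `config`, invisibly.
#' @export
run_full_replication <- function(config_path, out_dir = NULL) {
  config <- if (is.character(config_path)) {
    yaml::read_yaml(config_path)
  } else if (is.list(config_path)) {
    config_path
  } else {
    .sb_stop("sb_config_error", "config must be a YAML path or a named list")
  }
  seed <- .cfg_get(config, "seed", default = 1L)
  n_perm <- .cfg_get(config, "n_perm", default = 1000L)
  n_boot <- .cfg_get(config, "n_boot", default = 1000L)
  if (is.null(out_dir)) out_dir <- .cfg_get(config, "out_dir")

  seeds <- .derive_seeds(seed, 4L)

  # --- dataset ---
  if (!is.null(config$dataset)) {
    message("loading trial pairs from ", config$dataset)
    pairs <- load_trial_pairs(config$dataset)
  } else if (!is.null(config$simulation)) {
    sim_cfg <- .sim_config_from_list(config$simulation)
    message("simulating experiment: ", sim_cfg$n_subjects, " subjects")
    pairs <- simulate_experiment(sim_cfg, seed = seeds[[1]])
  } else {
    .sb_stop("sb_config_error",
             "config requires either field 'dataset' or field 'simulation'")
  }

  # --- preprocessing ---
  pp_cfg <- .cfg_get(config, "preprocess", default = list())
  pp <- preprocess_trial_pairs(
    pairs,
    n_sd = .cfg_get(pp_cfg, "n_sd", default = 2),
    metric = .cfg_get(pp_cfg, "metric", default = "signed"),
    screen = isTRUE(pp_cfg$screen)
  )
  message(sprintf("preprocessed %d trial pairs; %d excluded (mean error %.3f deg)",
                  pp$n_total, pp$n_removed, pp$mean_error))

  # --- analysis cells ---
  cells <- .cfg_get(config, "cells", default = list(
    list(inducer = "cued", condition = "overlap"),
    list(inducer = "cued", condition = "no_overlap"),
    list(inducer = "imi", condition = "overlap"),
    list(inducer = "imi", condition = "no_overlap")
  ))
  curve_cfg <- .cfg_get(config, "curve", default = list())
  window <- .cfg_get(curve_cfg, "window", default = 200L)
  step <- .cfg_get(curve_cfg, "step", default = 40L)

  cell_seeds <- .derive_seeds(seeds[[2]], max(1L, length(cells)))
  results <- list()
  curves <- list()
  for (i in seq_along(cells)) {
    cell <- cells[[i]]
    if (is.null(cell$inducer) || is.null(cell$condition)) {
      .sb_stop("sb_config_error",
               "config field 'cells[%d]' needs 'inducer' and 'condition'", i)
    }
    subset <- .cfg_get(cell, "subset", default = "all")
    res <- run_serial_dependence_analysis(
      pp$data, cell$inducer, cell$condition, subset,
      n_perm = n_perm, n_boot = n_boot, seed = cell_seeds[[i]]
    )
    label <- paste(cell$inducer, cell$condition, subset, sep = "_")
    message(sprintf("cell %-40s p2p = %+.3f deg, p = %.3f", label,
                    res$p2p, res$p_value))
    results[[i]] <- data.frame(
      inducer = cell$inducer, condition = cell$condition, subset = subset,
      n = res$n, a = res$fit$a, w = res$fit$w, p2p = res$p2p,
      p_value = res$p_value, ci_low = res$ci_low, ci_high = res$ci_high,
      stringsAsFactors = FALSE
    )
    sel <- pp$data[pp$data$included & pp$data$condition == cell$condition, ]
    if (cell$inducer != "imi_on_C_within" && nrow(sel) >= window) {
      xc <- switch(cell$inducer, cued = sel$x_cued, imi = sel$x_imi,
                   C_on_next = sel$x_C)
      curves[[label]] <- moving_average_curve(xc, sel$residual_error,
                                              window = window, step = step)
    }
  }
  results <- do.call(rbind, results)

  # --- condition difference ---
  cond_diff <- NULL
  cd_cfg <- .cfg_get(config, "condition_difference")
  if (!is.null(cd_cfg)) {
    inducer <- .cfg_get(cd_cfg, "inducer", default = "imi")
    xcol <- switch(inducer, cued = "x_cued", imi = "x_imi", C_on_next = "x_C")
    if (is.null(xcol)) {
      .sb_stop("sb_config_error",
               "config field 'condition_difference.inducer' must be cued, imi, or C_on_next")
    }
    d <- pp$data[pp$data$included, ]
    a <- d[d$condition == "no_overlap", ]
    b <- d[d$condition == "overlap", ]
    cond_diff <- permutation_test_condition_difference(
      .deg2rad(a[[xcol]]), a$residual_error,
      .deg2rad(b[[xcol]]), b$residual_error,
      n_perm = n_perm, seed = seeds[[3]]
    )
    cond_diff$inducer <- inducer
    message(sprintf("condition difference (%s): %+.3f deg, p = %.3f",
                    inducer, cond_diff$difference, cond_diff$p_value))
  }

  # --- model comparison per condition ---
  model_cmp <- NULL
  if (isTRUE(config$model_comparison)) {
    model_cmp <- lapply(stats::setNames(.CONDITIONS, .CONDITIONS), function(cond) {
      cmp <- compare_models(pp$data[pp$data$condition == cond, ])
      message(sprintf("model comparison (%s): best = %s", cond, cmp$best))
      cmp
    })
  }

  # --- power ---
  power_res <- NULL
  pw_cfg <- .cfg_get(config, "power")
  if (!is.null(pw_cfg)) {
    inducer <- .cfg_get(pw_cfg, "inducer", default = "imi")
    cond <- .cfg_get(pw_cfg, "condition", default = "overlap")
    xcol <- switch(inducer, cued = "x_cued", imi = "x_imi", C_on_next = "x_C")
    d <- pp$data[pp$data$included & pp$data$condition == cond, ]
    power_res <- estimate_power(
      x = .deg2rad(d[[xcol]]), y = d$residual_error,
      n_points = .cfg_get(pw_cfg, "n_points", default = nrow(d)),
      n_datasets = .cfg_get(pw_cfg, "n_datasets", default = 100L),
      n_perm = .cfg_get(pw_cfg, "n_perm", default = 100L),
      seed = seeds[[4]]
    )
    message(sprintf("power (%s, %s, %d points): %.2f", inducer, cond,
                    power_res$n_points, power_res$power))
  }

  bundle <- list(results = results, condition_difference = cond_diff,
                 model_comparison = model_cmp, power = power_res,
                 curves = curves,
                 preprocessing = pp[c("n_total", "n_removed", "mean_error",
                                      "removed_subjects")],
                 config = config, seed = seed)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(results, file.path(out_dir, "results.csv"),
                     row.names = FALSE)
    json <- list(
      seed = seed,
      preprocessing = bundle$preprocessing,
      cells = results,
      condition_difference = if (!is.null(cond_diff)) {
        list(inducer = cond_diff$inducer, difference = cond_diff$difference,
             p_value = cond_diff$p_value, p2p_no_overlap = cond_diff$p2p_a,
             p2p_overlap = cond_diff$p2p_b)
      },
      model_comparison = if (!is.null(model_cmp)) {
        lapply(model_cmp, function(m) {
          list(aicc_direct = m$aicc_direct, aicc_indirect = m$aicc_indirect,
               aicc_null = m$aicc_null, deltas = as.list(m$deltas),
               best = m$best)
        })
      },
      power = if (!is.null(power_res)) {
        power_res[c("power", "n_points", "n_datasets", "n_perm", "alpha")]
      }
    )
    jsonlite::write_json(json, file.path(out_dir, "results.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         dataframe = "rows")
    if (length(curves)) {
      curve_dir <- file.path(out_dir, "curves")
      dir.create(curve_dir, showWarnings = FALSE)
      for (label in names(curves)) {
        utils::write.csv(curves[[label]],
                         file.path(curve_dir, paste0(label, ".csv")),
                         row.names = FALSE)
      }
    }
    message("results written to ", out_dir)
  }
  invisible(bundle)
}
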