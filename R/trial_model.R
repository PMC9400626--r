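# Trial-pair tables for the paired ABC-retrocuing / 1-item delayed-recall
# design, plus preprocessing: derivation of signed relative angles and report
# errors, 2-SD outlier exclusion, and residualization (demeaning).

.TP_COLS <- c("subject_id", "session", "block", "pair_index", "condition",
              "loc_A", "loc_B", "loc_C", "ori_A", "ori_B", "ori_C",
              "cued_item", "abc_probe", "abc_report", "sample_1item",
              "report_1item")

.CONDITIONS <- c("overlap", "no_overlap")

# IMI = the uncued (irrelevant) item of the A/B pair
.uncued_loc <- function(df) ifelse(df$cued_item == "A", df$loc_B, df$loc_A)
.uncued_ori <- function(df) ifelse(df$cued_item == "A", df$ori_B, df$ori_A)
.cued_ori <- function(df) ifelse(df$cued_item == "A", df$ori_A, df$ori_B)

.fmt_rows <- function(idx) paste(utils::head(idx, 5L), collapse = ", ")

#' Validate a trial-pair table
#'
#' Checks the structural invariants of the paired-trial design: column set,
#' categorical levels, orientation and location ranges, distinct A/B
#' locations, and the location rule for item C (in the *overlap* condition C
#' occupies the IMI's location; in *no-overlap* it avoids both A and B).
#' Report columns may be `NA` (a design table before responses are
#' simulated or collected); non-missing reports must lie in \eqn{[0, 180)}.
#'
#' @param df A data.frame of trial pairs.
#' @return The validated data.frame, invisibly.
#' @export
validate_trial_pairs <- function(df) {
  if (!is.data.frame(df)) .sb_stop("sb_format_error", "expected a data.frame")
  missing_cols <- setdiff(.TP_COLS, names(df))
  if (length(missing_cols)) {
    .sb_stop("sb_format_error", "missing column(s): %s",
             paste(missing_cols, collapse = ", "))
  }
  if (nrow(df) == 0L) return(invisible(df))

  bad <- function(ok, what) {
    idx <- which(!ok)
    if (length(idx)) {
      .sb_stop("sb_format_error", "%s in row(s) %s", what, .fmt_rows(idx))
    }
  }
  int_in <- function(v, lo, hi) {
    is.finite(v) & v >= lo & v <= hi & v == round(v)
  }
  bad(df$condition %in% .CONDITIONS,
      sprintf("condition must be one of {%s}", paste(.CONDITIONS, collapse = ",")))
  bad(df$cued_item %in% c("A", "B"), "cued_item must be 'A' or 'B'")
  bad(df$abc_probe %in% c("cued", "C"), "abc_probe must be 'cued' or 'C'")
  for (loc in c("loc_A", "loc_B", "loc_C")) {
    bad(int_in(df[[loc]], 0, 5), sprintf("%s must be an integer in 0..5", loc))
  }
  for (ori in c("ori_A", "ori_B", "ori_C", "sample_1item")) {
    bad(int_in(df[[ori]], 0, 179),
        sprintf("%s must be an integer in 0..179", ori))
  }
  for (rep_col in c("abc_report", "report_1item")) {
    v <- df[[rep_col]]
    bad(is.na(v) | (is.finite(v) & v >= 0 & v < 180),
        sprintf("%s must be NA or in [0, 180)", rep_col))
  }
  bad(int_in(df$block, 1, .Machine$integer.max), "block must be an integer >= 1")
  bad(int_in(df$pair_index, 1, .Machine$integer.max),
      "pair_index must be an integer >= 1")
  bad(df$loc_A != df$loc_B, "loc_A must differ from loc_B")
  ov <- df$condition == "overlap"
  bad(!ov | df$loc_C == .uncued_loc(df),
      "overlap rows must place item C at the IMI's location")
  bad(ov | (df$loc_C != df$loc_A & df$loc_C != df$loc_B),
      "no_overlap rows must place item C away from both A and B")
  invisible(df)
}

#' Read / write trial-pair tables as CSV
#'
#' The on-disk format is a UTF-8 CSV with the exact header
#' `subject_id,session,block,pair_index,condition,loc_A,loc_B,loc_C,ori_A,ori_B,ori_C,cued_item,abc_probe,abc_report,sample_1item,report_1item`.
#' Real-valued report columns are written with six decimal places, which
#' makes `save_trial_pairs(load_trial_pairs(f), f)` byte-stable on canonical
#' files. Structural invariants are validated on load and save; violations
#' raise a format error naming the offending row(s).
#'
#' @param path File path.
#' @return `load_trial_pairs()` returns a validated data.frame of trial
#'   pairs; `save_trial_pairs()` returns `path` invisibly.
#' @export
load_trial_pairs <- function(path) {
  if (!file.exists(path)) .sb_stop("sb_format_error", "file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(subject_id = "character"))
  if (!identical(names(df), .TP_COLS)) {
    .sb_stop("sb_format_error",
             "header mismatch: expected exactly %s", paste(.TP_COLS, collapse = ","))
  }
  validate_trial_pairs(df)
  df
}

#' @rdname load_trial_pairs
#' @param df A trial-pair data.frame (see [validate_trial_pairs()]).
#' @export
save_trial_pairs <- function(df, path) {
  validate_trial_pairs(df)
  out <- df[, .TP_COLS]
  for (col in c("abc_report", "report_1item")) {
    out[[col]] <- ifelse(is.na(out[[col]]), "", sprintf("%.6f", out[[col]]))
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Derive signed angles and report errors from raw trial pairs
#'
#' Computes, for every trial pair with a 1-item response, the signed relative
#' angles of the candidate inducers with respect to the 1-item sample
#' (`x_cued`, `x_imi`, `x_C`, degrees in \eqn{[-90, 90)}), the within-trial
#' angle of the IMI relative to item C (`x_imi_vs_C`), the signed 1-item
#' report error (`error_1item`), and — for trials in which item C was probed
#' — the signed error of the ABC report of item C (`abc_err_C`). The
#' `included` flag and `residual_error` are placeholders until
#' [exclude_outlier_trials()] and [residualize_errors()] are applied.
#'
#' @param pairs Validated trial-pair data.frame with responses.
#' @return A data.frame with one row per responded trial pair.
#' @export
derive_trial_pairs <- function(pairs) {
  validate_trial_pairs(pairs)
  pairs <- pairs[!is.na(pairs$report_1item), , drop = FALSE]
  if (nrow(pairs) == 0L) {
    .sb_stop("sb_insufficient_data", "no trial pairs with 1-item responses")
  }
  ori_cued <- .cued_ori(pairs)
  ori_imi <- .uncued_ori(pairs)
  out <- data.frame(
    subject_id = pairs$subject_id,
    block = pairs$block,
    pair_index = pairs$pair_index,
    condition = pairs$condition,
    cued_item = pairs$cued_item,
    abc_probe = pairs$abc_probe,
    ori_C = pairs$ori_C,
    sample_1item = pairs$sample_1item,
    x_cued = wrap_angle_180(ori_cued - pairs$sample_1item),
    x_imi = wrap_angle_180(ori_imi - pairs$sample_1item),
    x_C = wrap_angle_180(pairs$ori_C - pairs$sample_1item),
    x_imi_vs_C = wrap_angle_180(ori_imi - pairs$ori_C),
    error_1item = signed_report_error(pairs$report_1item, pairs$sample_1item),
    stringsAsFactors = FALSE
  )
  out$abc_err_C <- NA_real_
  cp <- out$abc_probe == "C" & !is.na(pairs$abc_report)
  if (any(cp)) {
    out$abc_err_C[cp] <- signed_report_error(pairs$abc_report[cp],
                                             pairs$ori_C[cp])
  }
  out$included <- TRUE
  out$residual_error <- NA_real_
  out$abc_resid_C <- NA_real_
  out
}

#' Exclude outlier trials by the 2-SD rule
#'
#' Marks as excluded every trial whose 1-item report error deviates from the
#' mean error by strictly more than `n_sd` sample standard deviations,
#' computed over the merged dataset (all subjects pooled). The default uses
#' the signed error; `metric = "absolute"` applies the same rule to `|error|`
#' instead.
#'
#' @param rows Derived trial-pair table (see [derive_trial_pairs()]).
#' @param n_sd Exclusion threshold in standard deviations (default 2).
#' @param metric `"signed"` (default) or `"absolute"`.
#' @return A list with `rows` (the table with `included` updated) and
#'   `n_removed`.
#' @export
exclude_outlier_trials <- function(rows, n_sd = 2,
                                   metric = c("signed", "absolute")) {
  metric <- match.arg(metric)
  e <- rows$error_1item
  if (sum(is.finite(e)) < 3L) {
    .sb_stop("sb_insufficient_data",
             "need at least 3 finite report errors to apply the SD rule")
  }
  m <- if (metric == "absolute") abs(e) else e
  mu <- mean(m)
  s <- stats::sd(m)
  rows$included <- abs(m - mu) <= n_sd * s # strict ">" excludes
  rows$residual_error <- NA_real_
  rows$abc_resid_C <- NA_real_
  list(rows = rows, n_removed = sum(!rows$included))
}

#' Residualize report errors by subtracting the mean response error
#'
#' Removes the systematic (clockwise/counterclockwise) bias of recall by
#' subtracting the mean signed error over the included rows of the merged
#' dataset, yielding `residual_error` with mean exactly zero over included
#' rows. For trials in which item C was probed, the ABC report error of item
#' C is residualized the same way (over included C-probed rows) into
#' `abc_resid_C`.
#'
#' @param rows Derived table with exclusion applied.
#' @return The table with `residual_error` (and `abc_resid_C`) filled for
#'   included rows.
#' @export
residualize_errors <- function(rows) {
  inc <- rows$included
  if (!any(inc)) {
    .sb_stop("sb_insufficient_data", "no included rows to residualize")
  }
  rows$residual_error <- NA_real_
  rows$residual_error[inc] <- rows$error_1item[inc] - mean(rows$error_1item[inc])
  rows$abc_resid_C <- NA_real_
  cc <- inc & !is.na(rows$abc_err_C)
  if (any(cc)) {
    rows$abc_resid_C[cc] <- rows$abc_err_C[cc] - mean(rows$abc_err_C[cc])
  }
  rows
}

#' Screen subjects by average absolute recall error
#'
#' Optional pre-step mirroring subject-level exclusion: removes subjects
#' whose average absolute 1-item report error exceeds the group mean by more
#' than `n_sd` standard deviations.
#'
#' @param pairs Trial-pair table with responses.
#' @param n_sd Threshold in SDs (default 2).
#' @return List with `pairs` (rows of surviving subjects) and
#'   `removed_subjects` (character vector).
#' @export
screen_subjects <- function(pairs, n_sd = 2) {
  validate_trial_pairs(pairs)
  resp <- pairs[!is.na(pairs$report_1item), , drop = FALSE]
  abs_err <- abs(signed_report_error(resp$report_1item, resp$sample_1item))
  per_subj <- tapply(abs_err, resp$subject_id, mean)
  if (length(per_subj) < 3L) {
    return(list(pairs = pairs, removed_subjects = character(0)))
  }
  cutoff <- mean(per_subj) + n_sd * stats::sd(per_subj)
  removed <- names(per_subj)[per_subj > cutoff]
  list(pairs = pairs[!(pairs$subject_id %in% removed), , drop = FALSE],
       removed_subjects = removed)
}

#' Full preprocessing: derive, exclude outliers, residualize
#'
#' Convenience wrapper applying the three preprocessing stages in order on
#' the merged all-subjects dataset: angle/error derivation, the 2-SD trial
#' exclusion, and demeaning. Optionally screens subjects first.
#'
#' @inheritParams exclude_outlier_trials
#' @param pairs Trial-pair table with responses.
#' @param screen If `TRUE`, apply [screen_subjects()] before deriving.
#' @return List with `data` (preprocessed derived table), `n_removed`,
#'   `n_total`, `mean_error` (the subtracted mean, degrees), and
#'   `removed_subjects`.
#' @export
preprocess_trial_pairs <- function(pairs, n_sd = 2,
                                   metric = c("signed", "absolute"),
                                   screen = FALSE) {
  metric <- match.arg(metric)
  removed_subjects <- character(0)
  if (screen) {
    sc <- screen_subjects(pairs, n_sd = n_sd)
    pairs <- sc$pairs
    removed_subjects <- sc$removed_subjects
  }
  rows <- derive_trial_pairs(pairs)
  ex <- exclude_outlier_trials(rows, n_sd = n_sd, metric = metric)
  mean_error <- mean(ex$rows$error_1item[ex$rows$included])
  data <- residualize_errors(ex$rows)
  list(data = data, n_removed = ex$n_removed, n_total = nrow(rows),
       mean_error = mean_error, removed_subjects = removed_subjects)
}
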