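# Synthetic experiment generator for the paired ABC-retrocuing / 1-item
# delayed-recall design: design tables with the block, location and
# counterbalancing structure of the task, plus a response model with
# Gaussian-on-circle report noise and injectable DoG-shaped biases of known
# amplitude, width and sign.

.KERNEL_ROLES <- c("cued", "imi", "C", "imi_on_C")

#' Configuration for a synthetic experiment
#'
#' Collects the design constants and the response model of a simulated
#' experiment. The defaults reproduce the study design: 6 blocks of 20 trial
#' pairs per subject (3 blocks per condition, condition order counterbalanced
#' across subjects), orientations drawn uniformly with replacement from the
#' integers 0–179, and in the *overlap* condition item C placed at the IMI's
#' location.
#'
#' `bias_kernels` is a list of kernels, each a list with `role` (one of
#' `"cued"`, `"imi"`, `"C"`, `"imi_on_C"`), `condition` (`"overlap"`,
#' `"no_overlap"`, or `"both"`, the default), and DoG parameters `a`
#' (degrees) and `w` (1/radians). Roles `cued`, `imi` and `C` bias the 1-item
#' report toward (a > 0) or away from (a < 0) the corresponding inducer;
#' `imi_on_C` biases the stored orientation of item C by the IMI within the
#' ABC trial, which shifts the ABC report of item C and, when a `C` kernel is
#' also active, propagates to the next-trial recall (the indirect-influence
#' generative model).
#'
#' @param n_subjects Number of subjects (>= 0).
#' @param blocks_per_condition Blocks per condition per subject (default 3).
#' @param pairs_per_block Trial pairs per block (default 20).
#' @param noise_sd_1item SD of the Gaussian report noise on the 1-item task,
#'   degrees (default 10).
#' @param noise_sd_abc SD of the report noise on the ABC task, degrees
#'   (default 12).
#' @param bias_kernels List of injected bias kernels (see Details).
#' @param subject_sd Between-subject spread of the noise SDs, degrees
#'   (default 0): each subject's SDs are shifted by a common Gaussian offset,
#'   truncated at zero.
#' @param seed Default seed used by [simulate_experiment()].
#' @return Object of class `simulation_config`.
#' @examples
#' cfg <- simulation_config(
#'   n_subjects = 8,
#'   bias_kernels = list(
#'     list(role = "imi", condition = "overlap", a = -1.25, w = 2.24),
#'     list(role = "imi", condition = "no_overlap", a = 1.1, w = 2.24)
#'   )
#' )
#' @export
simulation_config <- function(n_subjects, blocks_per_condition = 3L,
                              pairs_per_block = 20L, noise_sd_1item = 10,
                              noise_sd_abc = 12, bias_kernels = list(),
                              subject_sd = 0, seed = NULL) {
  n_subjects <- .check_count(n_subjects, "n_subjects", 0L)
  blocks_per_condition <- .check_count(blocks_per_condition,
                                       "blocks_per_condition", 0L)
  pairs_per_block <- .check_count(pairs_per_block, "pairs_per_block", 0L)
  for (nm in c("noise_sd_1item", "noise_sd_abc", "subject_sd")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v < 0) {
      .sb_stop("sb_config_error", "%s must be a single number >= 0", nm)
    }
  }
  if (!is.list(bias_kernels)) {
    .sb_stop("sb_config_error", "bias_kernels must be a list of kernels")
  }
  bias_kernels <- lapply(bias_kernels, function(k) {
    if (!is.list(k) || is.null(k$role) || is.null(k$a) || is.null(k$w)) {
      .sb_stop("sb_config_error",
               "each kernel needs fields role, a, w (and optionally condition)")
    }
    if (!(k$role %in% .KERNEL_ROLES)) {
      .sb_stop("sb_config_error",
               "unknown kernel role '%s' (inducers are: %s)", k$role,
               paste(.KERNEL_ROLES, collapse = ", "))
    }
    cond <- if (is.null(k$condition)) "both" else k$condition
    if (!(cond %in% c(.CONDITIONS, "both"))) {
      .sb_stop("sb_config_error", "kernel condition must be %s, or 'both'",
               paste(.CONDITIONS, collapse = ", "))
    }
    params <- dog_params(k$a, k$w)
    list(role = k$role, condition = cond, a = params$a, w = params$w)
  })
  structure(list(
    n_subjects = n_subjects, blocks_per_condition = blocks_per_condition,
    pairs_per_block = pairs_per_block, noise_sd_1item = noise_sd_1item,
    noise_sd_abc = noise_sd_abc, bias_kernels = bias_kernels,
    subject_sd = subject_sd, seed = seed
  ), class = "simulation_config")
}

.empty_pairs <- function() {
  data.frame(subject_id = character(0), session = integer(0),
             block = integer(0), pair_index = integer(0),
             condition = character(0), loc_A = integer(0), loc_B = integer(0),
             loc_C = integer(0), ori_A = integer(0), ori_B = integer(0),
             ori_C = integer(0), cued_item = character(0),
             abc_probe = character(0), abc_report = numeric(0),
             sample_1item = integer(0), report_1item = numeric(0),
             stringsAsFactors = FALSE)
}

#' Generate the design of a synthetic experiment (responses empty)
#'
#' Builds the trial-pair table of a simulated experiment: per subject,
#' `blocks_per_condition` blocks of each condition of `pairs_per_block`
#' trial pairs, condition order alternating across subjects
#' (counterbalanced). Items A and B occupy distinct uniform locations among
#' the 6 placeholders; item C follows the condition rule (the IMI's location
#' under *overlap*, one of the four fresh locations under *no-overlap*). All
#' orientations are i.i.d. uniform integers in 0–179; the retro-cue and the
#' ABC probe are uniform coin flips. Report columns are `NA`.
#'
#' @param config A [simulation_config()].
#' @param seed Optional seed (defaults to `config$seed`).
#' @return A validated trial-pair data.frame.
#' @export
generate_design <- function(config, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  n_blocks <- 2L * config$blocks_per_condition
  n_per_subj <- n_blocks * config$pairs_per_block
  n <- config$n_subjects * n_per_subj
  if (n == 0L) return(.empty_pairs())

  .with_seed(seed, {
    subj <- rep(seq_len(config$n_subjects), each = n_per_subj)
    block <- rep(rep(seq_len(n_blocks), each = config$pairs_per_block),
                 times = config$n_subjects)
    pair_index <- rep(seq_len(config$pairs_per_block),
                      times = config$n_subjects * n_blocks)
    # counterbalance: odd subjects run overlap first, even subjects no_overlap
    first <- ifelse(subj %% 2L == 1L, "overlap", "no_overlap")
    second <- ifelse(first == "overlap", "no_overlap", "overlap")
    condition <- ifelse(block <= config$blocks_per_condition, first, second)

    loc_A <- sample(0:5, n, replace = TRUE)
    loc_B <- (loc_A + sample(1:5, n, replace = TRUE)) %% 6L
    cued_item <- sample(c("A", "B"), n, replace = TRUE)
    loc_imi <- ifelse(cued_item == "A", loc_B, loc_A)
    loc_C <- loc_imi
    no <- which(condition == "no_overlap")
    loc_C[no] <- vapply(no, function(i) {
      free <- setdiff(0:5, c(loc_A[i], loc_B[i]))
      free[sample.int(4L, 1L)]
    }, numeric(1))

    df <- data.frame(
      subject_id = sprintf("S%03d", subj), session = 1L,
      block = block, pair_index = pair_index, condition = condition,
      loc_A = loc_A, loc_B = loc_B, loc_C = loc_C,
      ori_A = sample(0:179, n, replace = TRUE),
      ori_B = sample(0:179, n, replace = TRUE),
      ori_C = sample(0:179, n, replace = TRUE),
      cued_item = cued_item,
      abc_probe = sample(c("cued", "C"), n, replace = TRUE),
      abc_report = NA_real_,
      sample_1item = sample(0:179, n, replace = TRUE),
      report_1item = NA_real_,
      stringsAsFactors = FALSE
    )
    validate_trial_pairs(df)
    df
  })
}

# summed kernel bias (degrees) of `role` for each row, 0 where inactive
.kernel_bias <- function(config, role, condition, x_deg) {
  bias <- numeric(length(x_deg))
  for (k in config$bias_kernels) {
    if (k$role != role) next
    active <- k$condition == "both" | condition == k$condition
    if (!any(active)) next
    bias[active] <- bias[active] +
      dog_predict(.deg2rad(x_deg[active]), list(a = k$a, w = k$w))
  }
  bias
}

#' Simulate responses for a synthetic design
#'
#' Fills the report columns of a design table under the response model the
#' analysis assumes. The 1-item report is the sample orientation plus the sum
#' of the active bias kernels (each evaluated at the wrapped inducer-minus-
#' sample angle) plus Gaussian noise, wrapped back to \eqn{[0, 180)}. The ABC
#' report reproduces the probed item (the cued item, or item C) with its own
#' Gaussian noise; an `imi_on_C` kernel shifts item C's stored orientation
#' before it is reported or, via a `C` kernel, before it biases the
#' next-trial recall.
#'
#' @param design Design table from [generate_design()].
#' @param config The [simulation_config()] used to generate it.
#' @param seed Optional seed.
#' @return The trial-pair table with `abc_report` and `report_1item` filled.
#' @export
simulate_responses <- function(design, config, seed = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  validate_trial_pairs(design)
  n <- nrow(design)
  if (n == 0L) return(design)

  .with_seed(seed, {
    ori_cued <- .cued_ori(design)
    ori_imi <- .uncued_ori(design)

    # stored orientation of item C, possibly biased by the IMI within-trial
    c_stored <- design$ori_C +
      .kernel_bias(config, "imi_on_C", design$condition,
                   wrap_angle_180(ori_imi - design$ori_C))

    sample1 <- design$sample_1item
    bias <- .kernel_bias(config, "cued", design$condition,
                         wrap_angle_180(ori_cued - sample1)) +
            .kernel_bias(config, "imi", design$condition,
                         wrap_angle_180(ori_imi - sample1)) +
            .kernel_bias(config, "C", design$condition,
                         wrap_angle_180(c_stored - sample1))

    # per-subject noise-level offset (a "good/bad subject" factor)
    subj <- match(design$subject_id, unique(design$subject_id))
    offs <- if (config$subject_sd > 0) {
      stats::rnorm(max(subj), 0, config$subject_sd)
    } else {
      numeric(max(subj))
    }
    sd1 <- pmax(0, config$noise_sd_1item + offs[subj])
    sda <- pmax(0, config$noise_sd_abc + offs[subj])

    noise1 <- if (all(sd1 == 0)) numeric(n) else stats::rnorm(n, 0, sd1)
    design$report_1item <- (sample1 + bias + noise1) %% 180

    probed <- ifelse(design$abc_probe == "cued", ori_cued, c_stored)
    noise_a <- if (all(sda == 0)) numeric(n) else stats::rnorm(n, 0, sda)
    design$abc_report <- (probed + noise_a) %% 180
    design
  })
}

#' Generate a complete synthetic experiment
#'
#' Convenience wrapper: [generate_design()] followed by
#' [simulate_responses()] under one seed.
#'
#' @inheritParams generate_design
#' @return A trial-pair table with responses.
#' @export
simulate_experiment <- function(config, seed = config$seed) {
  .with_seed(seed, simulate_responses(generate_design(config, seed = NULL),
                                      config, seed = NULL))
}
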