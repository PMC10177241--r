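#' Load the bundled per-subject human brachiation summary table
#'
#' Returns the published per-individual summary rows for the nine human
#' subjects: anthropometrics (height, weight, forelimb length and its ratio
#' to height, grip/weight ratio — missing for individual 5), stride counts,
#' and per-subject means and standard deviations of the spatiotemporal,
#' energetic and pendular variables. Two derived columns are added:
#' `grip_force_kg = grip_weight * weight_kg` and the contact-to-COM
#' pendulum length `L_m` recovered from the printed predicted period via
#' `L = g (T / 2 pi)^2`.
#'
#' @return A data.frame with one row per individual (9 rows).
#' @export
#' @examples
#' tab <- load_table1_fixture()
#' sum(tab$n)           # 80 strides in total
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_subject_summaries.csv",
                      package = "brachiate", mustWork = TRUE)
  tab <- read.csv(path)
  tab$grip_force_kg <- tab$grip_weight * tab$weight_kg
  tab$L_m <- G_ACCEL * (tab$predicted_period_s / (2 * pi))^2
  tab
}

#' Cohort grand summaries from per-subject rows
#'
#' Pools per-subject summary rows (as returned by [load_table1_fixture()]
#' or built from a processed cohort) into cohort grand means and standard
#' deviations. Stride-level variables (speed, duty factor, stance, swing,
#' stride frequency and length, recovery, observed period, excursions) are
#' pooled stride-count-weighted via [weighted_grand_mean()], with pooled
#' SDs from the within/between decomposition; subject-level variables
#' (anthropometrics, predicted period) are unweighted across subjects.
#' Both the sample (n-1) and population (n) SD conventions are emitted.
#'
#' @param subjects per-subject data.frame in the layout of
#'   [load_table1_fixture()].
#' @return A data.frame with columns `variable`, `pooling`, `mean`,
#'   `sd_sample`, `sd_population`.
#' @export
#' @examples
#' gs <- grand_summary(load_table1_fixture())
#' subset(gs, variable == "recovery_pct")$mean   # ~29.8
grand_summary <- function(subjects) {
  stopifnot(is.data.frame(subjects), "n" %in% names(subjects))
  stride_vars <- c(velocity_ms = "velocity_ms",
                   duty_pct = "duty_pct", stance_s = "stance_s",
                   swing_s = "swing_s", stride_hz = "stride_hz",
                   stride_m = "stride_m", recovery_pct = "recovery_pct",
                   period_s = "period_s", ml_m = "ml_m",
                   vertical_m = "vertical_m")
  subject_vars <- c("height_m", "weight_kg", "forelimb_m",
                    "forelimb_height", "grip_weight", "grip_force_kg",
                    "predicted_period_s")
  out <- list()
  for (v in stride_vars) {
    mcol <- paste0(v, "_mean"); scol <- paste0(v, "_sd")
    if (!all(c(mcol, scol) %in% names(subjects))) next
    sds <- pooled_sd(subjects[[mcol]], subjects[[scol]], subjects$n)
    out[[v]] <- data.frame(
      variable = v, pooling = "stride",
      mean = weighted_grand_mean(subjects[[mcol]], subjects$n),
      sd_sample = sds[["sample"]], sd_population = sds[["population"]])
  }
  for (v in subject_vars) {
    if (!v %in% names(subjects)) next
    x <- subjects[[v]][!is.na(subjects[[v]])]
    out[[v]] <- data.frame(
      variable = v, pooling = "subject", mean = mean(x),
      sd_sample = sd(x),
      sd_population = sqrt(mean((x - mean(x))^2)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Write an IMU trace as delimited text with a provenance header
#'
#' Comma-separated, UTF-8, header row, `.` decimal, missing values empty;
#' provenance (seed, sample rate, package version) in leading `#` comment
#' lines.
#'
#' @param trace an [imu_trace()].
#' @param path output file path.
#' @param seed optional integer recorded in the header.
#' @return `path`, invisibly.
#' @export
write_imu_trace <- function(trace, path, seed = NULL) {
  stopifnot(inherits(trace, "imu_trace"))
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    sprintf("# brachiate imu trace v%s",
            as.character(utils::packageVersion("brachiate"))),
    sprintf("# sample_rate_hz: %.10g", trace$sample_rate),
    sprintf("# seed: %s", if (is.null(seed)) "NA" else format(seed))), con)
  df <- data.frame(time_s = trace$time,
                   ax = trace$acceleration[, 1],
                   ay = trace$acceleration[, 2],
                   az = trace$acceleration[, 3],
                   roll_rad = trace$euler[, 1],
                   pitch_rad = trace$euler[, 2],
                   yaw_rad = trace$euler[, 3])
  write.csv(df, con, row.names = FALSE, na = "")
  invisible(path)
}

#' Read an IMU trace from delimited text
#'
#' Reads the format written by [write_imu_trace()], or a vendor-dialect
#' CSV via `column_map` naming the vendor columns for each canonical
#' channel.
#'
#' @param path input file path.
#' @param column_map optional named character vector mapping canonical
#'   names (`time_s`, `ax`, `ay`, `az`, `roll_rad`, `pitch_rad`,
#'   `yaw_rad`) to the file's column names.
#' @param sample_rate optional explicit rate, Hz; inferred from the time
#'   column when omitted.
#' @return An [imu_trace()].
#' @export
read_imu_trace <- function(path, column_map = NULL, sample_rate = NULL) {
  df <- read.csv(path, comment.char = "#")
  canon <- c("time_s", "ax", "ay", "az", "roll_rad", "pitch_rad", "yaw_rad")
  if (!is.null(column_map)) {
    missing_map <- setdiff(canon, names(column_map))
    if (length(missing_map)) {
      stop("column_map must name: ", paste(missing_map, collapse = ", "))
    }
    df <- df[, unname(column_map[canon])]
    names(df) <- canon
  }
  stopifnot(all(canon %in% names(df)))
  if (is.null(sample_rate)) sample_rate <- 1 / mean(diff(df$time_s))
  imu_trace(df$time_s, as.matrix(df[, c("ax", "ay", "az")]),
            as.matrix(df[, c("roll_rad", "pitch_rad", "yaw_rad")]),
            sample_rate)
}

#' Run the full brachiation analysis pipeline on a simulated cohort
#'
#' Simulates a cohort ([simulate_cohort()]), reconstructs per-stride COM
#' kinematics from each trial's sensor stream ([process_trial()], with the
#' fore-aft integration constant taken from the simulator's truth channel,
#' standing in for the digitized head track), computes spatiotemporal and
#' energetic stride variables, pools stride-count-weighted subject and
#' grand summaries, and (optionally) ranks the six candidate predictors of
#' energy recovery with the mixed-model AIC machinery.
#'
#' @param n_subjects,trials_per_subject,strides_per_trial,seed,noise_sd
#'   passed to [simulate_cohort()].
#' @param fit_models logical: run [fit_candidate_models()] on the stride
#'   table (needs >= 2 subjects).
#' @return A list with `strides` (tidy per-stride table), `subjects`
#'   (per-subject means), `grand` (grand summary data.frame), `ranking`
#'   (`model_ranking` or `NULL`), `importance` (named vector or `NULL`),
#'   and `anthropometrics`.
#' @export
run_pipeline <- function(n_subjects = 9, trials_per_subject = 5,
                         strides_per_trial = 2, seed = 1, noise_sd = 0.1,
                         fit_models = TRUE) {
  cohort <- simulate_cohort(n_subjects, trials_per_subject,
                            strides_per_trial, seed = seed,
                            noise_sd = noise_sd)
  anthro <- cohort$anthropometrics
  rows <- list()
  for (tr in cohort$trials) {
    truth <- tr$truth
    ev <- truth$stride_events
    complete <- which(!is.na(ev$next_touchdown_s))
    if (length(complete) == 0) next
    ev_c <- ev[complete, , drop = FALSE]
    td_idx <- vapply(ev_c$touchdown_s,
                     function(td) which.min(abs(truth$time - td)),
                     integer(1))
    v0 <- truth$velocity[td_idx, 1]
    kins <- process_trial(tr$imu, ev_c, v0_foreaft = v0)
    a_row <- anthro[anthro$subject == tr$subject, ]
    for (i in seq_along(kins)) {
      td <- ev_c$touchdown_s[i]; ntd <- ev_c$next_touchdown_s[i]
      stride_time <- ntd - td
      # traverse speed over the stride from the truth fore-aft displacement
      i0 <- which.min(abs(truth$time - td))
      i1 <- which.min(abs(truth$time - ntd))
      speed <- (truth$position[i1, 1] - truth$position[i0, 1]) / stride_time
      sm <- stride_metrics(
        stride_events(ev_c$limb[i], td, ev_c$liftoff_s[i], ntd), speed)
      en <- stride_energetics(kins[[i]], mass = a_row$mass_kg,
                              L = a_row$L_m, stride_time_s = stride_time)
      rows[[length(rows) + 1L]] <- cbind(
        data.frame(subject = tr$subject, trial = tr$trial, stride = i,
                   limb = ev_c$limb[i]),
        sm, en,
        data.frame(forelimb_height = a_row$forelimb_height,
                   grip_weight = a_row$grip_weight,
                   mass_kg = a_row$mass_kg, L_m = a_row$L_m))
    }
  }
  strides <- do.call(rbind, rows)

  agg_vars <- c(velocity_ms = "speed_ms", duty_pct = "duty_factor",
                stance_s = "contact_time_s", swing_s = "swing_time_s",
                stride_hz = "stride_frequency_hz",
                stride_m = "stride_length_m",
                recovery_pct = "recovery_pct", period_s = "observed_period_s",
                ml_m = "ml_excursion_m", vertical_m = "vertical_excursion_m")
  subj_split <- split(strides, strides$subject)
  subjects <- do.call(rbind, lapply(subj_split, function(d) {
    out <- data.frame(subject = d$subject[1], n = nrow(d))
    for (v in names(agg_vars)) {
      x <- d[[agg_vars[[v]]]]
      if (v == "duty_pct") x <- 100 * x
      out[[paste0(v, "_mean")]] <- mean(x)
      out[[paste0(v, "_sd")]] <- if (nrow(d) > 1) sd(x) else 0
    }
    out$predicted_period_s <- d$expected_period_s[1]
    out
  }))
  rownames(subjects) <- NULL
  subjects <- merge(subjects,
                    anthro[, c("subject", "height_m", "mass_kg",
                               "forelimb_m", "forelimb_height",
                               "grip_force_kg", "grip_weight", "L_m")],
                    by = "subject")
  names(subjects)[names(subjects) == "mass_kg"] <- "weight_kg"
  grand <- grand_summary(subjects)

  ranking <- importance <- NULL
  if (fit_models && n_subjects >= 2) {
    ranking <- fit_candidate_models(strides)
    importance <- variable_importance(ranking)
  }
  list(strides = strides, subjects = subjects, grand = grand,
       ranking = ranking, importance = importance,
       anthropometrics = anthro)
}
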