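# Atrial-fibrillation screening from the extracted indices.  Three index
# families separate AF from non-AF at rest: (1) the across-harmonic SD of
# heart rate, (2) the per-harmonic HRV (total and respiration-only), and
# (3) the per-harmonic respiration modulation.  Thresholds are
# configuration, not learned: the groups separate by non-overlapping
# ranges.

#' Collate the per-subject AF screening indices
#'
#' Pure collation of scalars already computed by the cardiac, respiration
#' and reconstruction stages.
#'
#' @param cardiac a [cardiac_metrics()] result.
#' @param resp a [resp_metrics()] result.
#' @param recon a [reconstruct()] result (for the pulse-waveform
#'   features).
#' @param label optional ground-truth label (`"AF"` / `"non-AF"`).
#' @return object of class `subject_indices`.
#' @export
compute_indices <- function(cardiac, resp, recon = NULL, label = NA_character_) {
  stopifnot(inherits(cardiac, "cardiac_metrics"),
            inherits(resp, "resp_metrics"))
  structure(list(
    HR = cardiac$HR, SD_HR = cardiac$SD_HR,
    HR_phi = cardiac$HR_phi, SD_HR_phi = cardiac$SD_HR_phi,
    rmse_hr = stats::setNames(cardiac$per_harmonic$rmse_hr,
                              paste0("h", cardiac$per_harmonic$order)),
    rmse_hr_phi = stats::setNames(cardiac$per_harmonic$rmse_hr_phi,
                                  paste0("h", cardiac$per_harmonic$order)),
    mean_b_phi = stats::setNames(resp$per_harmonic$mean_b_phi,
                                 paste0("h", resp$per_harmonic$order)),
    rr_phi = stats::setNames(resp$per_harmonic$rr_phi,
                             paste0("h", resp$per_harmonic$order)),
    RMSSD_x0 = unname(cardiac$RMSSD["x0"]),
    RMSSD_x1 = unname(cardiac$RMSSD["x1"]),
    amp_ratio = if (!is.null(recon)) recon$amp_ratio else NULL,
    phase_diff = if (!is.null(recon)) recon$phase_diff else NULL,
    phase_flag = if (!is.null(recon)) recon$phase_flag else NA,
    label = label),
    class = "subject_indices")
}

#' @export
print.subject_indices <- function(x, ...) {
  cat(sprintf("<subject_indices>%s\n",
              if (is.na(x$label)) "" else paste0(" [", x$label, "]")))
  cat(sprintf("  HR %.1f bpm, SD(HR) %.4f; HR_phi %.1f, SD(HR_phi) %.4f\n",
              x$HR, x$SD_HR, x$HR_phi, x$SD_HR_phi))
  cat(sprintf("  RMSE(HR_i): %s bpm\n",
              paste(signif(x$rmse_hr, 3), collapse = ", ")))
  cat(sprintf("  RMSE(HR_phi_i): %s bpm\n",
              paste(signif(x$rmse_hr_phi, 3), collapse = ", ")))
  cat(sprintf("  mean B_phi_i: %s Hz\n",
              paste(signif(x$mean_b_phi, 3), collapse = ", ")))
  invisible(x)
}

#' Classification thresholds for the three index families
#'
#' Defaults: the heart-rate-spread cut is the geometric mean of the
#' reported group extremes for the across-harmonic SD of heart rate
#' (0.23 bpm AF minimum versus 0.023 bpm non-AF maximum); the
#' respiration-only HRV and respiration-modulation cuts sit between the
#' values implied by physiological respiratory sinus arrhythmia in sinus
#' rhythm and the elevated, irregular modulation seen in AF.
#'
#' @param sd_hr bpm cut for `SD_HR`.
#' @param rmse_hr_phi bpm cut applied to the *minimum* over harmonics of
#'   the respiration-only HRV.
#' @param b_phi Hz cut applied to the mean over harmonics of the mean
#'   respiration modulation.
#' @param rule combination rule: `"majority"`, `"all"` or `"any"`.
#' @return object of class `af_thresholds`.
#' @export
af_thresholds <- function(sd_hr = sqrt(0.23 * 0.023),
                          rmse_hr_phi = 2.0,
                          b_phi = 0.09,
                          rule = c("majority", "all", "any")) {
  stopifnot(sd_hr > 0, rmse_hr_phi > 0, b_phi > 0)
  structure(list(sd_hr = sd_hr, rmse_hr_phi = rmse_hr_phi, b_phi = b_phi,
                 rule = match.arg(rule)),
            class = "af_thresholds")
}

#' Classify a subject as AF or non-AF
#'
#' One vote per index family: `SD_HR` above its cut, the minimum over
#' harmonics of the respiration-only HRV above its cut, and the mean over
#' harmonics of the respiration modulation above its cut.  Votes are
#' combined by the configured rule (majority by default).
#'
#' @param idx a [compute_indices()] result.
#' @param thr an [af_thresholds()].
#' @return list with `verdict` (`"AF"`, `"non-AF"` or `"abstain"`) and
#'   the named logical `votes`.
#' @export
classify_af <- function(idx, thr = af_thresholds()) {
  stopifnot(inherits(idx, "subject_indices"), inherits(thr, "af_thresholds"))
  votes <- c(
    sd_hr = if (is.finite(idx$SD_HR)) idx$SD_HR > thr$sd_hr else NA,
    rmse_hr_phi = if (all(is.finite(idx$rmse_hr_phi)))
      min(idx$rmse_hr_phi) > thr$rmse_hr_phi else NA,
    b_phi = if (all(is.finite(idx$mean_b_phi)))
      mean(idx$mean_b_phi) > thr$b_phi else NA)
  av <- votes[!is.na(votes)]
  if (!length(av)) return(list(verdict = "abstain", votes = votes))
  hit <- switch(thr$rule,
                majority = sum(av) > length(av) / 2,
                all = all(av),
                any = any(av))
  list(verdict = if (hit) "AF" else "non-AF", votes = votes)
}

#' Cohort-level index table and group summary
#'
#' @param indices list of [compute_indices()] results.
#' @param thr an [af_thresholds()] used to also report each subject's
#'   verdict.
#' @return object of class `cohort_report`: list with `table` (one row
#'   per subject), `group_summary` (per group and index: mean, SD,
#'   median, min, max) and `nonoverlap` (per index family, whether the
#'   two groups' observed ranges are disjoint; `NA` when a group is
#'   absent).
#' @export
cohort_report <- function(indices, thr = af_thresholds()) {
  stopifnot(length(indices) >= 1L)
  rows <- lapply(seq_along(indices), function(j) {
    x <- indices[[j]]
    cl <- classify_af(x, thr)
    data.frame(subject = j, label = x$label, verdict = cl$verdict,
               HR = x$HR, SD_HR = x$SD_HR,
               HR_phi = x$HR_phi, SD_HR_phi = x$SD_HR_phi,
               min_rmse_hr = min(x$rmse_hr),
               min_rmse_hr_phi = min(x$rmse_hr_phi),
               mean_b_phi = mean(x$mean_b_phi),
               RMSSD_x0 = x$RMSSD_x0, RMSSD_x1 = x$RMSSD_x1)
  })
  tab <- do.call(rbind, rows)
  idx_cols <- c("SD_HR", "SD_HR_phi", "min_rmse_hr", "min_rmse_hr_phi",
                "mean_b_phi", "RMSSD_x0", "RMSSD_x1")
  groups <- split(tab, tab$label)
  gs <- do.call(rbind, lapply(names(groups), function(g) {
    do.call(rbind, lapply(idx_cols, function(cn) {
      v <- groups[[g]][[cn]]
      data.frame(group = g, index = cn, mean = mean(v, na.rm = TRUE),
                 sd = stats::sd(v), median = stats::median(v, na.rm = TRUE),
                 min = suppressWarnings(min(v, na.rm = TRUE)),
                 max = suppressWarnings(max(v, na.rm = TRUE)))
    }))
  }))
  nonoverlap <- sapply(idx_cols, function(cn) {
    if (!all(c("AF", "non-AF") %in% names(groups))) return(NA)
    af <- groups[["AF"]][[cn]]; naf <- groups[["non-AF"]][[cn]]
    if (anyNA(af) || anyNA(naf)) return(NA)
    min(af) > max(naf) || max(af) < min(naf)
  })
  structure(list(table = tab, group_summary = gs, nonoverlap = nonoverlap),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report>\n")
  print(x$table, row.names = FALSE, digits = 4)
  cat("\nGroup summary:\n")
  print(x$group_summary, row.names = FALSE, digits = 4)
  cat("\nNon-overlapping index ranges:",
      paste(names(x$nonoverlap)[which(x$nonoverlap)], collapse = ", "), "\n")
  if (all(c("AF", "non-AF") %in% x$table$label)) {
    acc <- mean(x$table$verdict == x$table$label)
    cat(sprintf("Classification accuracy at current thresholds: %.1f%%\n",
                100 * acc))
  }
  invisible(x)
}
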