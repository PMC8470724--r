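# Single-patient statistical selection.
#
# Each feature of the patient of interest is compared against the other
# patients of the same batch: duplicate injections are averaged first,
# the fold change is patient mean over the median of the other patients'
# means, and a robust z-score uses the median/MAD of the reference with
# a floored denominator so constant references cannot produce infinite z.

#' Average duplicate injections into per-sample intensities
#'
#' One column per sample (arithmetic mean of its injections, ignoring
#' missing values); a cell where some but not all injections were observed
#' is flagged "partial". A sample whose injections are all missing for a
#' feature stays missing.
#'
#' @param im An [to_matrix()] intensity matrix.
#' @return A `sample_matrix`: list with `intensities` (features x samples),
#'   `partial` (logical matrix), `roles` (named character vector
#'   sample -> role), `features`, `ion_mode`.
#' @export
average_duplicates <- function(im) {
  wl <- im$worklist
  samples <- unique(wl$sample_id)
  x <- im$intensities
  out <- matrix(NA_real_, nrow(x), length(samples),
                dimnames = list(rownames(x), samples))
  partial <- matrix(FALSE, nrow(x), length(samples),
                    dimnames = dimnames(out))
  for (s in samples) {
    cols <- injection_id(s, wl$injection_index[wl$sample_id == s],
                         wl$ion_mode[wl$sample_id == s])
    if (!length(cols)) stop("sample without injections: ", s)
    sub <- x[, cols, drop = FALSE]
    nobs <- rowSums(!is.na(sub))
    out[, s] <- ifelse(nobs > 0, rowMeans(sub, na.rm = TRUE), NA_real_)
    partial[, s] <- nobs > 0 & nobs < length(cols)
  }
  roles <- vapply(samples, function(s) wl$role[wl$sample_id == s][1], "")
  structure(list(intensities = out, partial = partial, roles = roles,
                 features = im$features, ion_mode = attr(im, "ion_mode")),
            class = "sample_matrix")
}

# reference columns for a target sample: all patient-role samples
# except the target itself
.reference_samples <- function(sm, target) {
  setdiff(names(sm$roles)[sm$roles == "patient"], target)
}

#' Per-feature single-patient statistics
#'
#' For the sample of interest (a patient, or the validation plasma
#' processed identically) each feature receives: the sample's
#' duplicate-averaged intensity, the median of the other patients' means,
#' the fold change `patient / max(median_others, intensity_floor)`, a
#' robust z `(patient - median_others) / max(1.4826 MAD, 0.05 median,
#' floor)`, a two-sided normal p-value, and the altered flag / direction
#' per [select_altered()].
#'
#' A feature missing in the target but observed in at least half of the
#' reference patients is evaluated at the intensity floor, so absent
#' metabolites can still be flagged as decreased; features observed in
#' fewer than 3 reference patients get status `"insufficient_reference"`
#' and no statistics.
#'
#' @param sm A [average_duplicates()] sample matrix.
#' @param target_id Sample of interest.
#' @param config A [session_config()] supplying thresholds.
#' @return data.frame: `feature_id`, `mz`, `rt`, `ion_mode`, `target_id`,
#'   `patient_mean`, `reference_median`, `fold_change`, `z`, `p_value`,
#'   `altered`, `direction` (`"up"`/`"down"`/`NA`), `status`
#'   (`"ok"`, `"patient_missing"`, `"insufficient_reference"`,
#'   `"undefined"`), `partial`.
#' @export
feature_statistics <- function(sm, target_id, config = session_config()) {
  if (!target_id %in% colnames(sm$intensities))
    stop("unknown sample: ", target_id)
  refs <- .reference_samples(sm, target_id)
  if (length(refs) < 3)
    warning("fewer than 3 reference patients; statistics mostly undefined",
            call. = FALSE)
  x <- sm$intensities
  floor_i <- config$intensity_floor
  nfeat <- nrow(x)
  patient <- x[, target_id]
  ref <- x[, refs, drop = FALSE]
  n_ref <- rowSums(!is.na(ref))
  med <- apply(ref, 1, stats::median, na.rm = TRUE)
  madv <- apply(ref, 1, stats::mad, na.rm = TRUE)   # constant 1.4826

  status <- rep("ok", nfeat)
  status[n_ref < 3] <- "insufficient_reference"
  pm <- patient
  missing_target <- is.na(patient)
  # absent in target, present in >= half the reference: evaluate at floor
  eval_at_floor <- missing_target & n_ref >= length(refs) / 2 & n_ref >= 3
  pm[eval_at_floor] <- floor_i
  status[missing_target & !eval_at_floor & status == "ok"] <- "undefined"
  status[missing_target & eval_at_floor] <- "patient_missing"

  ok <- status %in% c("ok", "patient_missing")
  fc <- z <- p <- rep(NA_real_, nfeat)
  fc[ok] <- pm[ok] / pmax(med[ok], floor_i)
  denom <- pmax(madv, 0.05 * med, floor_i)
  z[ok] <- (pm[ok] - med[ok]) / denom[ok]
  p[ok] <- 2 * stats::pnorm(-abs(z[ok]))

  res <- data.frame(
    feature_id = sm$features$feature_id,
    mz = sm$features$mz, rt = sm$features$rt,
    ion_mode = sm$ion_mode, target_id = target_id,
    patient_mean = pm, reference_median = med, n_reference = n_ref,
    fold_change = fc, z = z, p_value = p,
    status = status, partial = sm$partial[, target_id],
    stringsAsFactors = FALSE
  )
  rownames(res) <- NULL
  select_altered(res, config)
}

#' Fold change of one sample against the batch
#'
#' `patient / max(median(others), intensity_floor)`, where `others` are
#' the duplicate-averaged intensities of all other patients (median over
#' observed values only). Scalar helper mirroring the vectorized path of
#' [feature_statistics()].
#'
#' @param patient_mean Target sample's averaged intensity.
#' @param others Other patients' averaged intensities (NAs allowed).
#' @param intensity_floor Denominator floor, counts.
#' @return The fold change, or `NA` with fewer than 3 observed references.
#' @export
patient_fold_change <- function(patient_mean, others, intensity_floor = 1000) {
  others <- others[!is.na(others)]
  if (length(others) < 3) return(NA_real_)
  patient_mean / max(stats::median(others), intensity_floor)
}

#' Robust z-score of one sample against the batch
#'
#' `(patient - median(others)) / max(1.4826 * MAD(others),
#' 0.05 * median(others), intensity_floor)`. The floored denominator keeps
#' z finite on (near-)constant references.
#'
#' @inheritParams patient_fold_change
#' @return The robust z, or `NA` with fewer than 3 observed references.
#' @export
robust_z <- function(patient_mean, others, intensity_floor = 1000) {
  others <- others[!is.na(others)]
  if (length(others) < 3) return(NA_real_)
  med <- stats::median(others)
  (patient_mean - med) / max(stats::mad(others), 0.05 * med, intensity_floor)
}

#' Two-sided standard-normal p-value for a z-score
#' @param z Finite z-score(s).
#' @return `2 * pnorm(-|z|)`.
#' @export
p_from_z <- function(z) 2 * stats::pnorm(-abs(z))

#' Flag altered features
#'
#' A feature is altered-up when `z >= z_min`, `fold_change >= fc_up` and
#' `patient_mean >= intensity_floor`; altered-down when `z <= -z_min` and
#' `fold_change <= fc_down`. Applied to a statistics table; rows without
#' defined statistics are never altered.
#'
#' @param stats_df Output of [feature_statistics()] (or any data.frame
#'   with `z`, `fold_change`, `patient_mean`).
#' @param config A [session_config()] with `z_min`, `fc_up`, `fc_down`,
#'   `intensity_floor`.
#' @return `stats_df` with `altered` (logical) and `direction` columns
#'   set.
#' @export
select_altered <- function(stats_df, config = session_config()) {
  z <- stats_df$z; fc <- stats_df$fold_change; pm <- stats_df$patient_mean
  up <- !is.na(z) & !is.na(fc) &
    z >= config$z_min & fc >= config$fc_up & pm >= config$intensity_floor
  down <- !is.na(z) & !is.na(fc) &
    z <= -config$z_min & fc <= config$fc_down
  stats_df$altered <- up | down
  stats_df$direction <- ifelse(up, "up", ifelse(down, "down", NA_character_))
  stats_df
}

#' Write a per-patient statistics table
#' @param stats_df A [feature_statistics()] result.
#' @param path Output TSV path.
#' @export
write_statistics <- function(stats_df, path) {
  utils::write.table(stats_df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
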