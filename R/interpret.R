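# Interpretation engine: mode concatenation, filtering, diagnostic
# preset, bar-plot data. Result columns are immutable once created;
# commentary belongs in the audit trail, not in the result table.

.RESULT_COLUMNS <- c("feature_id", "mz", "rt", "ion_mode", "target_id",
                     "patient_mean", "reference_median", "n_reference",
                     "fold_change", "z", "p_value", "status", "partial",
                     "altered", "direction", "level", "compound", "hmdb_id",
                     "adduct", "isotope", "ppm_error", "rt_delta")

#' Interpretation records for one sample
#'
#' Joins the per-feature statistics with the annotations (one output row
#' per statistics row x matching annotation; unannotated features keep one
#' row with NA annotation fields). The resulting table's result columns
#' are immutable: any attempt to overwrite them errors, safeguarding
#' result integrity; new columns may still be added (e.g. during review).
#'
#' @param stats_df A [feature_statistics()] table.
#' @param annotations An [annotate_features()] table for the same
#'   features.
#' @return An `interpretation_records` data.frame.
#' @export
interpretation_records <- function(stats_df, annotations) {
  ann <- annotations[c("feature_id", "level", "compound", "hmdb_id",
                       "adduct", "isotope", "ppm_error", "rt_delta")]
  out <- merge(stats_df, ann, by = "feature_id", all.x = TRUE, sort = FALSE)
  out <- out[order(match(out$feature_id, stats_df$feature_id)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("interpretation_records", "data.frame")
  out
}

.assert_mutable <- function(x, name) {
  if (inherits(x, "interpretation_records") && name %in% .RESULT_COLUMNS &&
      name %in% names(x))
    stop("result column '", name, "' is immutable; record review notes in ",
         "the audit trail instead", call. = FALSE)
}

#' @export
`$<-.interpretation_records` <- function(x, name, value) {
  .assert_mutable(x, name)
  NextMethod()
}

#' @export
`[[<-.interpretation_records` <- function(x, i, value) {
  if (is.character(i)) .assert_mutable(x, i)
  else if (is.numeric(i) && i <= length(x)) .assert_mutable(x, names(x)[i])
  NextMethod()
}

#' @export
`[<-.interpretation_records` <- function(x, i, j, value) {
  cols <- if (missing(j)) names(x) else if (is.character(j)) j
    else names(x)[j]
  for (cn in cols) .assert_mutable(x, cn)
  NextMethod()
}

#' Concatenate positive and negative ion mode results
#'
#' Ion modes are acquired and processed separately; interpretation views
#' them as one table. No cross-mode merging takes place: the output has
#' exactly `nrow(pos) + nrow(neg)` rows with mode labels preserved.
#'
#' @param records_pos,records_neg `interpretation_records` (either may
#'   have zero rows).
#' @return Combined `interpretation_records`.
#' @export
concatenate_modes <- function(records_pos, records_neg) {
  for (r in list(records_pos, records_neg))
    if (nrow(r) && (is.null(r$ion_mode) || anyNA(r$ion_mode)))
      stop("records lack ion mode labels")
  out <- rbind(as.data.frame(records_pos), as.data.frame(records_neg))
  rownames(out) <- NULL
  class(out) <- c("interpretation_records", "data.frame")
  out
}

#' Filter specification
#'
#' Conjunction of optional predicates over interpretation records. Absent
#' predicates are not applied; an empty spec is the identity filter.
#' The fold-change predicate is two-sided: a record passes with
#' `fold_change >= min_abs_fc` or `fold_change <= 1/min_abs_fc`, since
#' IEMs present both as accumulation and as deficiency.
#'
#' @param rt_range,mz_range Numeric length-2 ranges (min <= max).
#' @param max_p_value Upper bound on `p_value`.
#' @param min_abs_fc Two-sided fold-change bound (>= 1).
#' @param level Required annotation level (`"panel"` or `"mz_only"`).
#' @param require_panel Require at least a panel annotation
#'   (equivalent to `level = "panel"`).
#' @param direction Required direction (`"up"`/`"down"`).
#' @param altered Required altered flag.
#' @return A `filter_spec` list.
#' @export
filter_spec <- function(rt_range = NULL, mz_range = NULL, max_p_value = NULL,
                        min_abs_fc = NULL, level = NULL,
                        require_panel = FALSE, direction = NULL,
                        altered = NULL) {
  for (rng in list(rt_range, mz_range))
    if (!is.null(rng) && (length(rng) != 2L || rng[1] > rng[2]))
      stop("ranges must be length-2 with min <= max")
  if (!is.null(min_abs_fc) && min_abs_fc < 1)
    stop("min_abs_fc must be >= 1")
  structure(list(rt_range = rt_range, mz_range = mz_range,
                 max_p_value = max_p_value, min_abs_fc = min_abs_fc,
                 level = level, require_panel = require_panel,
                 direction = direction, altered = altered),
            class = "filter_spec")
}

.record_passes <- function(rec, spec) {
  keep <- rep(TRUE, nrow(rec))
  if (!is.null(spec$rt_range))
    keep <- keep & rec$rt >= spec$rt_range[1] & rec$rt <= spec$rt_range[2]
  if (!is.null(spec$mz_range))
    keep <- keep & rec$mz >= spec$mz_range[1] & rec$mz <= spec$mz_range[2]
  if (!is.null(spec$max_p_value))
    keep <- keep & !is.na(rec$p_value) & rec$p_value <= spec$max_p_value
  if (!is.null(spec$min_abs_fc))
    keep <- keep & !is.na(rec$fold_change) &
      (rec$fold_change >= spec$min_abs_fc |
         rec$fold_change <= 1 / spec$min_abs_fc)
  if (!is.null(spec$level))
    keep <- keep & rec$level %in% spec$level
  if (isTRUE(spec$require_panel))
    keep <- keep & rec$level %in% "panel"
  if (!is.null(spec$direction))
    keep <- keep & rec$direction %in% spec$direction
  if (!is.null(spec$altered))
    keep <- keep & rec$altered %in% spec$altered
  keep
}

#' Filter interpretation records
#'
#' Returns the subset satisfying every predicate of the spec, preserving
#' input order; idempotent, and composing two specs equals applying their
#' conjunction.
#'
#' @param records `interpretation_records`.
#' @param spec A [filter_spec()].
#' @return Filtered `interpretation_records`.
#' @export
apply_filters <- function(records, spec) {
  stopifnot(inherits(spec, "filter_spec"))
  out <- records[.record_passes(records, spec), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' The diagnostic filter preset
#'
#' The preset used for routine diagnostics: keep features flagged altered
#' that carry a high-confidence panel annotation.
#'
#' @return A [filter_spec()].
#' @export
diagnostic_preset <- function() {
  filter_spec(altered = TRUE, require_panel = TRUE)
}

#' Serialize / restore a filter spec
#' @param spec A [filter_spec()].
#' @param path JSON file path.
#' @export
write_filter_spec <- function(spec, path) {
  jsonlite::write_json(Filter(Negate(is.null), unclass(spec)), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_filter_spec
#' @export
read_filter_spec <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(filter_spec, raw)
}

#' Per-sample bar-plot data for one feature
#'
#' The duplicate-averaged intensity of the feature in every sample,
#' labeled by role, with the patient of interest singled out — the data
#' behind the interpretation tool's bar plot comparing a feature across
#' the batch.
#'
#' @param feature_id Feature to plot.
#' @param sm A [average_duplicates()] sample matrix.
#' @param target_id Patient of interest (labeled
#'   `"patient_of_interest"`; other patients are `"other_patient"`).
#' @return data.frame `sample_id`, `role`, `intensity`, ordered patients
#'   first, then QC pool, validation, blank.
#' @export
barplot_data <- function(feature_id, sm, target_id = NULL) {
  i <- match(feature_id, rownames(sm$intensities))
  if (is.na(i)) stop("unknown feature: ", feature_id)
  role <- unname(sm$roles)
  if (!is.null(target_id))
    role[names(sm$roles) == target_id] <- "patient_of_interest"
  role[role == "patient"] <- "other_patient"
  d <- data.frame(sample_id = names(sm$roles), role = role,
                  intensity = sm$intensities[i, ], stringsAsFactors = FALSE)
  ord <- order(match(d$role, c("patient_of_interest", "other_patient",
                               "qc_pool", "validation", "blank")),
               d$sample_id)
  d <- d[ord, , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Export interpretation records
#' @param records `interpretation_records`.
#' @param path Output TSV path.
#' @export
write_records <- function(records, path) {
  utils::write.table(as.data.frame(records), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}
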