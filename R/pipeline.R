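# End-to-end orchestration: align -> annotate -> statistics ->
# interpretation records, per ion mode, for one sample of interest.

#' Process one ion mode of a batch
#'
#' Aligns the mode's peak lists into features, annotates them against the
#' panel and library, averages duplicate injections, computes the
#' single-patient statistics for the target sample and assembles the
#' interpretation records.
#'
#' @param peaklists Named list of [peaklist()]s (all modes; filtered here).
#' @param wl The batch [worklist()].
#' @param target_id Sample of interest.
#' @param config A [session_config()].
#' @param mode Ion mode to process.
#' @param panel,library Panel / library tables (defaults: built-ins, or
#'   the paths in `config` when set).
#' @return List: `records` ([interpretation_records()]), `aligned`,
#'   `matrix`, `samples` (sample matrix), `stats`, `annotations`.
#' @export
process_mode <- function(peaklists, wl, target_id, config,
                         mode = c("positive", "negative"),
                         panel = NULL, library = NULL) {
  mode <- match.arg(mode)
  if (is.null(panel))
    panel <- if (!is.null(config$panel_path)) read_panel(config$panel_path)
      else builtin_panel()
  if (is.null(library))
    library <- if (!is.null(config$library_path))
      read_library(config$library_path) else builtin_library()

  pls <- Filter(function(p) attr(p, "ion_mode") == mode, peaklists)
  aligned <- align_features(pls, config$mz_tolerance_ppm,
                            config$rt_tolerance_min)
  im <- to_matrix(aligned, wl)
  ann <- annotate_features(aligned$features, panel, library, config, mode)
  sm <- average_duplicates(im)
  st <- feature_statistics(sm, target_id, config)
  rec <- interpretation_records(st, ann)
  list(records = rec, aligned = aligned, matrix = im, samples = sm,
       stats = st, annotations = ann)
}

#' Screen one sample against its batch
#'
#' Runs [process_mode()] for every mode in the session configuration and
#' concatenates the interpretation records, the complete
#' data-processing path of a diagnostic screen for one patient (or for
#' the validation plasma).
#'
#' @inheritParams process_mode
#' @return List: `records` (modes concatenated), `modes` (per-mode
#'   [process_mode()] results).
#' @export
screen_sample <- function(peaklists, wl, target_id, config,
                          panel = NULL, library = NULL) {
  modes <- intersect(config$mode_list, unique(wl$ion_mode))
  res <- lapply(modes, function(m)
    process_mode(peaklists, wl, target_id, config, m, panel, library))
  names(res) <- modes
  records <- Reduce(concatenate_modes, lapply(res, `[[`, "records"))
  list(records = records, modes = res)
}
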