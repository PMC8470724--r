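# Analytical QC, validation-plasma gating, diagnostics data and release
# regression comparison.

#' Define QC standards
#'
#' Internal standards are monitored in every sample; external standards
#' in dedicated QC injections. Thresholds: maximum retention-time
#' deviation (% of the median RT), maximum response CV (%), maximum
#' absolute mass error (ppm).
#'
#' @param name,formula,adduct,ion_mode,expected_rt,kind Vectors defining
#'   the standards (`kind` in `internal|external`).
#' @param max_rt_delta_pct,max_response_cv_pct,max_abs_ppm Pass/fail
#'   thresholds (all > 0).
#' @return data.frame of standard definitions.
#' @export
standard_defs <- function(name, formula, adduct, ion_mode, expected_rt,
                          kind = "external", max_rt_delta_pct = 10,
                          max_response_cv_pct = 30, max_abs_ppm = 5) {
  d <- data.frame(name = name, formula = formula, adduct = adduct,
                  ion_mode = ion_mode, expected_rt = expected_rt,
                  kind = kind, max_rt_delta_pct = max_rt_delta_pct,
                  max_response_cv_pct = max_response_cv_pct,
                  max_abs_ppm = max_abs_ppm, stringsAsFactors = FALSE)
  stopifnot(all(d$max_rt_delta_pct > 0), all(d$max_response_cv_pct > 0),
            all(d$max_abs_ppm > 0), all(d$kind %in% c("internal", "external")))
  d$theoretical_mz <- vapply(seq_len(nrow(d)), function(i)
    ion_mz(monoisotopic_mass(d$formula[i]), d$adduct[i]), numeric(1))
  d
}

#' Demonstration QC standards
#'
#' Mid-chromatogram endogenous compounds used as stand-ins for the
#' proprietary internal/external standard mix: relative RT repeatability
#' is only a meaningful criterion away from the void volume, so standards
#' eluting after ~3 min are used. Thresholds are the package defaults
#' (10% RT delta, 30% response CV, 5 ppm).
#'
#' @param ion_mode Ion mode of the standards.
#' @return A [standard_defs()] table.
#' @export
builtin_standards <- function(ion_mode = "positive") {
  standard_defs(
    name = c("Tryptophan_IS", "Hippurate_IS", "CholicAcid_ES"),
    formula = c("C11H12N2O2", "C9H9NO3", "C24H40O5"),
    adduct = if (ion_mode == "positive") "M+H" else "M-H",
    ion_mode = ion_mode,
    expected_rt = c(5.6, 6.1, 12.6),
    kind = c("internal", "internal", "external")
  )
}

#' Recover QC standards from peak lists
#'
#' For every injection and standard of matching ion mode, the best peak
#' within `mz_tol` ppm of the theoretical ion m/z and `rt_tol` minutes of
#' the expected RT (smallest |ppm|, then smallest |RT delta|, then input
#' order); absence is recorded, not raised.
#'
#' @param peaklists List of [peaklist()]s.
#' @param defs A [standard_defs()] table.
#' @param mz_tol ppm tolerance.
#' @param rt_tol RT tolerance, minutes.
#' @return data.frame: `standard`, `injection`, `found`, `rt`, `intensity`,
#'   `ppm_error`.
#' @export
recover_standards <- function(peaklists, defs, mz_tol, rt_tol) {
  stopifnot(nrow(defs) > 0)
  rows <- list()
  for (pl in peaklists) {
    inj <- attr(pl, "injection"); mode <- attr(pl, "ion_mode")
    p <- as.data.frame(pl)
    for (i in seq_len(nrow(defs))) {
      if (defs$ion_mode[i] != mode) next
      found <- FALSE; rt <- NA_real_; int <- NA_real_; pe <- NA_real_
      if (nrow(p)) {
        pes <- ppm_error(p$mz, defs$theoretical_mz[i])
        drs <- abs(p$rt - defs$expected_rt[i])
        cand <- which(abs(pes) <= mz_tol & drs <= rt_tol)
        if (length(cand)) {
          best <- cand[order(abs(pes[cand]), drs[cand], cand)][1]
          found <- TRUE; rt <- p$rt[best]; int <- p$intensity[best]
          pe <- pes[best]
        }
      }
      rows[[length(rows) + 1L]] <- data.frame(
        standard = defs$name[i], injection = inj, found = found,
        rt = rt, intensity = int, ppm_error = pe, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' QC metrics per standard
#'
#' Over the injections where a standard was recovered:
#' `rt_delta_pct = max |rt_i - median(rt)| / median(rt) * 100`,
#' `response_cv_pct = sd / mean * 100` (sample sd, n-1), and
#' `worst_abs_ppm = max |ppm_error|`; each compared against the standard's
#' thresholds. An external standard recovered in fewer than 2 injections
#' has undefined repeatability and fails overall.
#'
#' @param recoveries A [recover_standards()] table.
#' @param defs The matching [standard_defs()].
#' @return data.frame of QC rows: metrics, per-criterion pass flags and
#'   `overall_pass` (true iff all criteria pass).
#' @export
qc_metrics <- function(recoveries, defs) {
  rows <- lapply(seq_len(nrow(defs)), function(i) {
    r <- recoveries[recoveries$standard == defs$name[i] & recoveries$found, ,
                    drop = FALSE]
    n <- nrow(r)
    if (n >= 2) {
      med_rt <- stats::median(r$rt)
      rt_delta_pct <- max(abs(r$rt - med_rt)) / med_rt * 100
      cv <- stats::sd(r$intensity) / mean(r$intensity) * 100
    } else {
      rt_delta_pct <- NA_real_; cv <- NA_real_
    }
    worst_ppm <- if (n) max(abs(r$ppm_error)) else NA_real_
    rt_pass <- !is.na(rt_delta_pct) && rt_delta_pct <= defs$max_rt_delta_pct[i]
    cv_pass <- !is.na(cv) && cv <= defs$max_response_cv_pct[i]
    ppm_pass <- !is.na(worst_ppm) && worst_ppm <= defs$max_abs_ppm[i]
    repeatability_defined <- n >= 2
    overall <- if (defs$kind[i] == "external")
      repeatability_defined && rt_pass && cv_pass && ppm_pass
    else  # internal: per-sample recovery; repeatability judged when defined
      n >= 1 && ppm_pass &&
        (!repeatability_defined || (rt_pass && cv_pass))
    data.frame(standard = defs$name[i], kind = defs$kind[i], n_found = n,
               rt_delta_pct = rt_delta_pct, response_cv_pct = cv,
               worst_abs_ppm = worst_ppm, rt_pass = rt_pass,
               cv_pass = cv_pass, ppm_pass = ppm_pass,
               overall_pass = overall, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Validation-plasma report and gate
#'
#' The validation plasma — control plasma spiked with known IEM-related
#' metabolites — is processed identically to patients; its diagnostic
#' output must show every spiked metabolite as significantly increased.
#' One report row per panel-annotated feature of a spiked compound (m/z,
#' RT deviation from the panel RT in %, mean intensity, per-mode
#' increased flags); the gate passes iff every spiked compound is
#' altered-up in at least one of its expected modes.
#'
#' @param records [interpretation_records()] for the validation sample
#'   (modes concatenated), carrying panel annotations.
#' @param spiked data.frame `name`, `modes` (semicolon-separated
#'   `"positive"`/`"negative"`) of the spiked compounds.
#' @param panel The [read_panel()] table (to validate the spike list).
#' @return List: `rows` (report data.frame), `gate` (logical), `missing`
#'   (spiked compounds not significantly increased).
#' @export
validation_report <- function(records, spiked, panel) {
  absent <- setdiff(spiked$name, panel$name)
  if (length(absent))
    stop("spiked compound(s) not in the diagnostic panel: ",
         paste(absent, collapse = ", "))
  rec <- as.data.frame(records)
  rec <- rec[rec$level %in% "panel" & rec$compound %in% spiked$name, ,
             drop = FALSE]
  rows <- list(); ok <- logical(nrow(spiked))
  for (i in seq_len(nrow(spiked))) {
    modes <- strsplit(spiked$modes[i], ";", fixed = TRUE)[[1]]
    r <- rec[rec$compound == spiked$name[i], , drop = FALSE]
    if (nrow(r)) {
      rtref <- r$rt - r$rt_delta   # panel expected RT
      rows[[length(rows) + 1L]] <- data.frame(
        name = spiked$name[i],
        feature_mass = round(r$mz, 4),
        rt_delta_pct = abs(r$rt_delta) / rtref * 100,
        mean_intensity = r$patient_mean,
        increased_neg = r$ion_mode == "negative" & r$altered %in% TRUE &
          r$direction %in% "up",
        increased_pos = r$ion_mode == "positive" & r$altered %in% TRUE &
          r$direction %in% "up",
        stringsAsFactors = FALSE)
    }
    up_modes <- unique(r$ion_mode[r$altered %in% TRUE & r$direction %in% "up"])
    ok[i] <- any(modes %in% up_modes)
  }
  rows <- do.call(rbind, rows)
  if (is.null(rows))
    rows <- data.frame(name = character(0), feature_mass = numeric(0),
                       rt_delta_pct = numeric(0), mean_intensity = numeric(0),
                       increased_neg = logical(0), increased_pos = logical(0))
  list(rows = rows, gate = all(ok), missing = spiked$name[!ok])
}

#' Session gate
#'
#' A diagnostic interpretation session may only start when both the
#' analytical QC and the data-processing validation have passed.
#'
#' @param qc_rows A [qc_metrics()] table.
#' @param validation_gate Logical gate from [validation_report()].
#' @return `TRUE` iff all QC rows pass overall and the validation gate
#'   passes.
#' @export
session_gate <- function(qc_rows, validation_gate) {
  nrow(qc_rows) > 0 && all(qc_rows$overall_pass) && isTRUE(validation_gate)
}

#' Numerical data behind the run-diagnostics plots
#'
#' Computes (1) PCA scores per injection on centered log10 intensities of
#' the features observed in every injection, (2) the per-injection median
#' RT shift of assigned peaks relative to the feature consensus RTs, and
#' (3) extracted-ion point series (injection, RT, intensity) for requested
#' features. Numbers only; rendering is left to the caller.
#'
#' @param im An [to_matrix()] intensity matrix.
#' @param eic_features Feature ids for which EIC series are returned.
#' @param n_components Number of principal components (default 2).
#' @return List `pca` (scores data.frame + variance explained), `rt_shift`
#'   (data.frame injection, median_shift_min), `eic` (data.frame).
#' @export
diagnostics_data <- function(im, eic_features = character(0),
                             n_components = 2L) {
  x <- im$intensities
  complete <- stats::complete.cases(x)
  if (!any(complete))
    stop("no feature observed in all injections; PCA undefined")
  if (any(!complete))
    warning(sum(!complete), " feature(s) with missing injections excluded ",
            "from PCA", call. = FALSE)
  lx <- t(log10(x[complete, , drop = FALSE]))
  k <- min(n_components, ncol(lx), nrow(lx) - 1L)
  pc <- stats::prcomp(lx, center = TRUE, scale. = FALSE, rank. = k)
  scores <- data.frame(injection = rownames(lx), pc$x[, seq_len(k),
                                                      drop = FALSE],
                       row.names = NULL, stringsAsFactors = FALSE)
  varexp <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]

  a <- im$assignments
  cons_rt <- im$features$rt[match(a$feature_id, im$features$feature_id)]
  shift <- tapply(a$rt - cons_rt, a$injection, stats::median)
  rt_shift <- data.frame(injection = colnames(x),
                         median_shift_min =
                           as.numeric(shift[colnames(x)]),
                         stringsAsFactors = FALSE)

  eic <- a[a$feature_id %in% eic_features,
           c("feature_id", "injection", "rt", "intensity"), drop = FALSE]
  rownames(eic) <- NULL
  list(pca = list(scores = scores, variance_explained = varexp),
       rt_shift = rt_shift, eic = eic)
}

#' Compare two pipeline releases on the same batch
#'
#' For release validation, the same raw data are reprocessed with the new
#' pipeline version and the panel-annotated altered metabolite sets are
#' compared per patient; the regression passes only when no patient's
#' crucial-metabolite set changed and both runs cover the same patients.
#'
#' @param results_old,results_new data.frames `patient_id`, `compound`
#'   listing each patient's panel-annotated altered metabolites.
#' @return List: `pass`, `differences` (data.frame `patient_id`,
#'   `compound`, `side` in `old_only|new_only`), `missing_samples`.
#' @export
compare_sessions <- function(results_old, results_new) {
  po <- unique(results_old$patient_id); pn <- unique(results_new$patient_id)
  missing <- c(setdiff(po, pn), setdiff(pn, po))
  diffs <- list()
  for (p in union(po, pn)) {
    so <- unique(results_old$compound[results_old$patient_id == p])
    sn <- unique(results_new$compound[results_new$patient_id == p])
    onlyo <- setdiff(so, sn); onlyn <- setdiff(sn, so)
    if (length(onlyo) || length(onlyn))
      diffs[[length(diffs) + 1L]] <- data.frame(
        patient_id = p,
        compound = c(onlyo, onlyn),
        side = c(rep("old_only", length(onlyo)),
                 rep("new_only", length(onlyn))),
        stringsAsFactors = FALSE)
  }
  diffs <- do.call(rbind, diffs)
  if (is.null(diffs))
    diffs <- data.frame(patient_id = character(0), compound = character(0),
                        side = character(0))
  list(pass = nrow(diffs) == 0 && length(missing) == 0,
       differences = diffs, missing_samples = missing)
}

#' Write a QC or validation report
#'
#' TSV plus a JSON sidecar carrying the overall verdict, mirroring the
#' spreadsheet report of the production workflow.
#'
#' @param rows Report data.frame.
#' @param path Output TSV path (a `.json` sidecar is written next to it).
#' @param verdict Named list of overall results to store in the sidecar.
#' @export
write_report <- function(rows, path, verdict = list()) {
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  if (length(verdict))
    jsonlite::write_json(verdict, paste0(tools::file_path_sans_ext(path),
                                         ".json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(path)
}
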