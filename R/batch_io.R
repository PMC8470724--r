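# Worklist, peak-list, checksum and session-configuration I/O.
# Retention time unit is minutes everywhere; mzML scan times (seconds)
# are converted at read.

.ROLES <- c("patient", "qc_pool", "validation", "blank")
.ROLE_ALIASES <- c(
  patient = "patient",
  qc_pool = "qc_pool", qcpool = "qc_pool", qc = "qc_pool",
  validation = "validation",
  blank = "blank"
)

#' Injection identifier
#'
#' Canonical key `"<sample>.<injection>.<pos|neg>"` used as column names of
#' intensity matrices and as peak-list names.
#'
#' @param sample_id,injection_index,ion_mode Vectors, recycled.
#' @return Character vector of injection ids.
#' @export
injection_id <- function(sample_id, injection_index, ion_mode) {
  paste(sample_id, injection_index, substr(ion_mode, 1, 3), sep = ".")
}

.validate_worklist <- function(d) {
  need <- c("sample_id", "role", "injection_index", "ion_mode", "datafile")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("worklist lacks column(s): ", paste(miss, collapse = ", "))
  role <- .ROLE_ALIASES[tolower(gsub("[ _-]", "_", d$role))]
  if (anyNA(role)) {
    bad <- which(is.na(role))[1]
    stop("unknown sample role '", d$role[bad], "' in worklist row ", bad)
  }
  d$role <- unname(role)
  d$ion_mode <- tolower(d$ion_mode)
  if (!all(d$ion_mode %in% c("positive", "negative")))
    stop("ion_mode must be 'positive' or 'negative'")
  d$injection_index <- as.integer(d$injection_index)
  if (any(d$injection_index < 1)) stop("injection_index must be >= 1")
  key <- paste(d$sample_id, d$injection_index, d$ion_mode)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1]
    stop("duplicate (sample, injection, mode) entry in worklist: ", dup)
  }
  if (is.null(d$checksum)) d$checksum <- NA_character_
  d$checksum[!nzchar(trimws(ifelse(is.na(d$checksum), "", d$checksum)))] <-
    NA_character_
  for (m in unique(d$ion_mode)) {
    np <- length(unique(d$sample_id[d$role == "patient" & d$ion_mode == m]))
    if (np < 2)
      warning("fewer than 2 patient samples in ", m,
              " mode; batch statistics will be undefined", call. = FALSE)
  }
  d
}

#' Build or parse a worklist
#'
#' A worklist declares every injection of an analytical run: sample id,
#' role (patient / qc_pool / validation / blank, matched
#' case-insensitively with common aliases such as "QCpool"), injection
#' index for duplicate injections, ion mode, data file and an optional
#' SHA-256 checksum.
#'
#' @param entries data.frame with columns `sample_id`, `role`,
#'   `injection_index`, `ion_mode`, `datafile` and optionally `checksum`.
#' @param run_id Identifier of the analytical run.
#' @return A `worklist`: validated data.frame with attribute `run_id`.
#' @export
worklist <- function(entries, run_id = "run") {
  d <- .validate_worklist(as.data.frame(entries, stringsAsFactors = FALSE))
  rownames(d) <- NULL
  structure(d, run_id = run_id, class = c("worklist", "data.frame"))
}

#' @rdname worklist
#' @param path Path to a tab-separated worklist file. A `run_id` column,
#'   if present, must be constant and is lifted into the attribute.
#' @export
parse_worklist <- function(path) {
  if (!file.exists(path)) stop("worklist file not found: ", path)
  d <- utils::read.delim(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  run_id <- tools::file_path_sans_ext(basename(path))
  if (!is.null(d$run_id)) {
    stopifnot(length(unique(d$run_id)) == 1L)
    run_id <- d$run_id[1]
    d$run_id <- NULL
  }
  worklist(d, run_id = run_id)
}

#' @rdname worklist
#' @param wl A `worklist`.
#' @export
write_worklist <- function(wl, path) {
  d <- as.data.frame(wl)
  d$run_id <- attr(wl, "run_id")
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' SHA-256 digest of a file
#' @param path File path.
#' @return Lower-case hex digest string.
#' @export
checksum_file <- function(path) {
  digest::digest(path, algo = "sha256", file = TRUE)
}

#' Verify data-transfer checksums for a worklist
#'
#' Recomputes the SHA-256 digest of every data file and compares it with
#' the recorded checksum. Missing files and mismatches are reported as
#' failures, never raised; entries without a recorded checksum are
#' "unverified" and do not affect the overall verdict unless
#' `strict = TRUE`.
#'
#' @param wl A [worklist()].
#' @param base_dir Directory against which relative `datafile` paths are
#'   resolved.
#' @param strict Promote unverified entries to failures.
#' @return List with `entries` (data.frame: injection, datafile, status
#'   pass/fail/unverified/missing) and `pass` (logical).
#' @export
verify_checksums <- function(wl, base_dir = ".", strict = FALSE) {
  paths <- ifelse(grepl("^(/|[A-Za-z]:)", wl$datafile), wl$datafile,
                  file.path(base_dir, wl$datafile))
  status <- character(nrow(wl))
  for (i in seq_len(nrow(wl))) {
    if (is.na(wl$checksum[i])) {
      status[i] <- if (strict) "fail" else "unverified"
    } else if (!file.exists(paths[i])) {
      status[i] <- "missing"
    } else {
      status[i] <- if (identical(tolower(wl$checksum[i]),
                                 checksum_file(paths[i]))) "pass" else "fail"
    }
  }
  entries <- data.frame(
    injection = injection_id(wl$sample_id, wl$injection_index, wl$ion_mode),
    datafile = wl$datafile, status = status, stringsAsFactors = FALSE
  )
  list(entries = entries,
       pass = !any(status %in% c("fail", "missing")))
}

.validate_peaks <- function(p, where = "peak list") {
  need <- c("mz", "rt", "intensity")
  miss <- setdiff(need, names(p))
  if (length(miss))
    stop(where, " lacks column(s): ", paste(miss, collapse = ", "))
  p <- p[need]
  for (col in need) p[[col]] <- as.numeric(p[[col]])
  if (nrow(p)) {
    if (anyNA(p)) stop(where, " contains NA/NaN values")
    if (any(p$mz <= 0)) stop(where, ": m/z must be > 0")
    if (any(p$rt < 0)) stop(where, ": retention time must be >= 0")
    if (any(p$intensity < 0)) stop(where, ": intensity must be >= 0")
  }
  p
}

#' Construct a per-injection peak list
#'
#' @param peaks data.frame with numeric columns `mz` (> 0), `rt`
#'   (minutes, >= 0) and `intensity` (>= 0); may have zero rows (blanks).
#' @param injection Injection id, see [injection_id()].
#' @param ion_mode `"positive"` or `"negative"`.
#' @return A `peaklist` data.frame with attributes `injection`, `ion_mode`.
#' @export
peaklist <- function(peaks, injection, ion_mode) {
  p <- .validate_peaks(as.data.frame(peaks, stringsAsFactors = FALSE))
  rownames(p) <- NULL
  structure(p, injection = injection, ion_mode = match.arg(ion_mode,
            c("positive", "negative")), class = c("peaklist", "data.frame"))
}

#' Read a centroided peak list
#'
#' TSV files carry `mz`, `rt` (minutes), `intensity` columns and round-trip
#' exactly through [write_peaklist()]. mzML files are read with the `mzR`
#' package: every centroid of every MS1 spectrum becomes one peak at the
#' spectrum's retention time (converted from seconds to minutes), suitable
#' for downstream binning; profile-mode spectra are rejected.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"tsv"` or `"mzml"`.
#' @param injection Injection id recorded on the result (defaults to the
#'   file name without extension).
#' @param ion_mode Ion mode recorded on the result.
#' @return A [peaklist()].
#' @export
read_peaklist <- function(path, format = c("auto", "tsv", "mzml"),
                          injection = NULL,
                          ion_mode = c("positive", "negative")) {
  format <- match.arg(format)
  ion_mode <- match.arg(ion_mode)
  if (format == "auto")
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml" else "tsv"
  if (is.null(injection)) injection <- tools::file_path_sans_ext(basename(path))
  if (format == "tsv") {
    d <- utils::read.delim(path, stringsAsFactors = FALSE)
    return(peaklist(d, injection, ion_mode))
  }
  if (!requireNamespace("mzR", quietly = TRUE))
    stop("reading mzML requires the 'mzR' package")
  h <- NULL
  ms <- mzR::openMSfile(path)
  on.exit(mzR::close(ms))
  h <- mzR::header(ms)
  if (!is.null(h$centroided) && any(!h$centroided, na.rm = TRUE))
    stop("profile-mode mzML is not supported; centroid the data first")
  specs <- mzR::peaks(ms)
  if (is.matrix(specs)) specs <- list(specs)
  rows <- lapply(seq_along(specs), function(i) {
    s <- specs[[i]]
    if (!NROW(s)) return(NULL)
    data.frame(mz = s[, 1], rt = h$retentionTime[i] / 60,
               intensity = s[, 2])
  })
  d <- do.call(rbind, rows)
  if (is.null(d)) d <- data.frame(mz = numeric(0), rt = numeric(0),
                                  intensity = numeric(0))
  peaklist(d, injection, ion_mode)
}

#' @rdname read_peaklist
#' @param pl A [peaklist()].
#' @export
write_peaklist <- function(pl, path) {
  d <- as.data.frame(pl)
  # full double precision so read/write is a lossless roundtrip
  d$mz <- sprintf("%.17g", d$mz)
  d$rt <- sprintf("%.17g", d$rt)
  d$intensity <- sprintf("%.17g", d$intensity)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Session configuration
#'
#' One NGMS processing session is driven by a single configuration:
#' matching tolerances, significance thresholds for the single-patient
#' statistics, panel/library locations, the random seed, and the ion
#' modes to process. Sessions are persisted once to a read-only JSON file
#' for traceability.
#'
#' @param mz_tolerance_ppm m/z matching tolerance, ppm (> 0).
#' @param rt_tolerance_min Retention-time tolerance, minutes (> 0).
#' @param z_min Robust z-score threshold (> 0).
#' @param fc_up Up-regulation fold-change threshold (>= 1).
#' @param fc_down Down-regulation fold-change threshold (0 < fc_down <= 1).
#' @param intensity_floor Minimum meaningful intensity, counts (> 0).
#' @param panel_path,library_path Paths to the panel / library TSVs
#'   (optional; `NULL` means use the built-in tables).
#' @param random_seed Integer seed for any stochastic step.
#' @param mode_list Ion modes processed in this session.
#' @return A `session_config` list.
#' @export
session_config <- function(mz_tolerance_ppm = 5, rt_tolerance_min = 0.5,
                           z_min = 3, fc_up = 2, fc_down = 0.5,
                           intensity_floor = 1000,
                           panel_path = NULL, library_path = NULL,
                           random_seed = 1L,
                           mode_list = c("positive", "negative")) {
  cfg <- list(
    mz_tolerance_ppm = mz_tolerance_ppm, rt_tolerance_min = rt_tolerance_min,
    z_min = z_min, fc_up = fc_up, fc_down = fc_down,
    intensity_floor = intensity_floor,
    panel_path = panel_path, library_path = library_path,
    random_seed = as.integer(random_seed), mode_list = mode_list
  )
  .validate_session(cfg)
  structure(cfg, class = "session_config")
}

.validate_session <- function(cfg) {
  stopifnot(cfg$mz_tolerance_ppm > 0, cfg$rt_tolerance_min > 0,
            cfg$z_min > 0, cfg$intensity_floor > 0)
  if (cfg$fc_up < 1) stop("fc_up must be >= 1")
  if (cfg$fc_down > 1 || cfg$fc_down <= 0) stop("fc_down must be in (0, 1]")
  if (!all(cfg$mode_list %in% c("positive", "negative")))
    stop("mode_list entries must be 'positive' or 'negative'")
  invisible(cfg)
}

#' Persist / load a session configuration
#'
#' The session file is written once per session and made read-only;
#' attempting to write to an existing path is an error, which keeps the
#' recorded parameters immutable for the lifetime of the session.
#'
#' @param config A [session_config()].
#' @param path JSON file path; parent directory must exist.
#' @return `write_session` returns the path invisibly; `read_session`
#'   returns the `session_config`.
#' @export
write_session <- function(config, path) {
  .validate_session(config)
  if (file.exists(path))
    stop("session file already exists (sessions are write-once): ", path)
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  Sys.chmod(path, mode = "0444")
  invisible(path)
}

#' @rdname write_session
#' @export
read_session <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  session_config(
    mz_tolerance_ppm = raw$mz_tolerance_ppm,
    rt_tolerance_min = raw$rt_tolerance_min,
    z_min = raw$z_min, fc_up = raw$fc_up, fc_down = raw$fc_down,
    intensity_floor = raw$intensity_floor,
    panel_path = raw$panel_path, library_path = raw$library_path,
    random_seed = raw$random_seed, mode_list = raw$mode_list
  )
}
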