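# Deterministic simulator of an NGMS analytical batch.
#
# The simulator emulates one diagnostic run: ~20 patient plasma samples
# measured in duplicate, QC-pool injections, validation plasma with known
# compounds spiked, per-compound adduct and first-13C-isotopologue peaks,
# ppm-scale m/z noise, RT jitter, log-normal intensity variation and
# random peak dropout. Random streams are derived per injection from
# (seed, sample, injection), so adding samples never perturbs the peaks
# of existing ones; a fixed seed gives byte-identical output.

#' Built-in compound set
#'
#' Plasma metabolites used by the simulator, the demonstration diagnostic
#' panel and the demonstration library: nine long-chain acylcarnitines
#' (the VLCAD-deficiency profile), ten validation-plasma spike compounds,
#' and common endogenous background metabolites. Expected retention times
#' for the acylcarnitines and the validation compounds follow the
#' reversed-phase behaviour of the assay; base intensities are typical
#' QTOF responses. `in_panel` marks membership of the demonstration
#' diagnostic panel.
#'
#' @return data.frame: `name`, `formula`, `hmdb_id`, `rt_pos`, `rt_neg`,
#'   `adducts`, `max_isotope`, `base_intensity`, `in_panel`, `group`.
#' @export
ngms_compounds <- function() {
  acyl <- data.frame(
    name = c("Tetradecenoylcarnitine", "Dodecanoylcarnitine",
             "Tetradecadienoylcarnitine", "Tetradecanoylcarnitine",
             "Hexadecenoylcarnitine", "Palmitoylcarnitine",
             "Linoleoylcarnitine", "Oleoylcarnitine", "Stearoylcarnitine"),
    formula = c("C21H39NO4", "C19H37NO4", "C21H37NO4", "C21H41NO4",
                "C23H43NO4", "C23H45NO4", "C25H45NO4", "C25H47NO4",
                "C25H49NO4"),
    hmdb_id = c("HMDB0002014", "HMDB0002250", "HMDB0013331", "HMDB0005066",
                "HMDB0013207", "HMDB0000222", "HMDB0006469", "HMDB0013338",
                "HMDB0000848"),
    rt_pos = c(13.37, 12.24, 12.82, 13.82, 14.08, 14.52, 14.32, 14.69,
               15.08),
    rt_neg = NA_real_,
    adducts = "M+H;M+Na",
    max_isotope = 1L,
    base_intensity = c(2e5, 3e5, 1.5e5, 2e5, 2e5, 4e5, 2.5e5, 3e5, 2.5e5),
    in_panel = TRUE, group = "acylcarnitine", stringsAsFactors = FALSE
  )
  valid <- data.frame(
    name = c("Dihydrouracil", "Ornithine", "Xanthine", "Pimelic acid",
             "L-Phenylalanine", "L-Tyrosine", "N-Acetylmannosamine",
             "gamma-Glutamylphenylalanine", "Mesaconic acid"),
    formula = c("C4H6N2O2", "C5H12N2O2", "C5H4N4O2", "C7H12O4",
                "C9H11NO2", "C9H11NO3", "C8H15NO6", "C14H18N2O5",
                "C5H6O4"),
    hmdb_id = c("HMDB0000076", "HMDB0000214", "HMDB0000292", "HMDB0000857",
                "HMDB0000159", "HMDB0000158", "HMDB0001129", "HMDB0000594",
                "HMDB0000749"),
    rt_pos = c(1.8, 1.0, 2.6, 5.4, 4.9, 3.8, 2.1, 5.8, NA),
    rt_neg = c(NA, NA, 2.6, 5.4, 4.9, 3.8, 2.1, 5.8, 4.2),
    adducts = "M+H;M+Na;M-H;M+Cl",
    max_isotope = 1L,
    base_intensity = c(7e6, 3.5e6, 1.4e7, 1.7e6, 2.5e7, 8e6, 9.8e6, 2e7,
                      2e7),
    in_panel = TRUE, group = "validation", stringsAsFactors = FALSE
  )
  bg <- data.frame(
    name = c("Creatinine", "Creatine", "L-Carnitine", "Acetylcarnitine",
             "D-Glucose", "Uric acid", "Hippuric acid", "L-Tryptophan",
             "L-Leucine", "Citric acid", "Taurine", "L-Methionine",
             "Cholic acid"),
    formula = c("C4H7N3O", "C4H9N3O2", "C7H15NO3", "C9H17NO4", "C6H12O6",
                "C5H4N4O3", "C9H9NO3", "C11H12N2O2", "C6H13NO2", "C6H8O7",
                "C2H7NO3S", "C5H11NO2S", "C24H40O5"),
    hmdb_id = c("HMDB0000562", "HMDB0000064", "HMDB0000062", "HMDB0000201",
                "HMDB0000122", "HMDB0000289", "HMDB0000714", "HMDB0000929",
                "HMDB0000687", "HMDB0000094", "HMDB0000251", "HMDB0000696",
                "HMDB0000619"),
    rt_pos = c(1.1, 1.2, 1.3, 2.4, 1.5, 2.2, 6.1, 5.6, 4.1, 1.9, 0.9,
               3.2, 12.6),
    rt_neg = c(1.1, 1.2, 1.3, 2.4, 1.5, 2.2, 6.1, 5.6, 4.1, 1.9, 0.9,
               3.2, 12.6),
    adducts = "M+H;M+Na;M-H;M+Cl",
    max_isotope = 1L,
    base_intensity = c(2e7, 1.2e7, 1.5e7, 4e6, 3e7, 8e6, 2e6, 6e6, 2.2e7,
                      5e6, 9e6, 4e6, 1e6),
    in_panel = FALSE, group = "background", stringsAsFactors = FALSE
  )
  rbind(acyl, valid, bg)
}

#' Demonstration diagnostic panel / compound library
#'
#' The shipped panel holds the diagnostic compounds of the built-in set
#' (the production panel of 340 metabolites is proprietary; any user TSV
#' in the same layout is accepted by [read_panel()]). The library mimics
#' a small HMDB extract: every built-in compound plus isobaric compounds
#' that demonstrate multiple m/z-only annotations.
#'
#' @return data.frames in [read_panel()] / [read_library()] layout.
#' @export
builtin_panel <- function() {
  cc <- ngms_compounds()
  p <- cc[cc$in_panel, c("name", "formula", "hmdb_id", "rt_pos", "rt_neg",
                         "adducts", "max_isotope")]
  p$neutral_mass <- vapply(p$formula, monoisotopic_mass, numeric(1))
  rownames(p) <- NULL
  p
}

#' @rdname builtin_panel
#' @export
builtin_library <- function() {
  cc <- ngms_compounds()
  extra <- data.frame(
    name = c("L-Isoleucine", "3-Methylhistidine", "Fructose"),
    formula = c("C6H13NO2", "C7H11N3O2", "C6H12O6"),
    hmdb_id = c("HMDB0000172", "HMDB0000479", "HMDB0000660"),
    stringsAsFactors = FALSE
  )
  lib <- rbind(cc[c("name", "formula", "hmdb_id")], extra)
  out <- data.frame(id = lib$hmdb_id, name = lib$name, formula = lib$formula,
                    stringsAsFactors = FALSE)
  out$neutral_mass <- vapply(out$formula, monoisotopic_mass, numeric(1))
  rownames(out) <- NULL
  out
}

#' Simulation specification
#'
#' Parameters of one simulated analytical batch. Noise defaults reflect a
#' well-behaved UHPLC-QTOF run: 2 ppm m/z scatter, 0.05 min RT jitter and
#' a log-normal biological spread of sigma 0.2 (natural log) across
#' patients, with technical injection noise at a third of that. A spike
#' sets a compound's level in one sample to `base_intensity * fold`
#' (a known amount added, as in validation plasma), subject only to
#' technical noise.
#'
#' @param n_patients Number of patient samples (>= 4).
#' @param injections_per_sample Duplicate injections per patient and per
#'   validation sample (>= 1).
#' @param n_qc_pool QC-pool injections.
#' @param n_validation Validation-plasma injections.
#' @param compounds Compound table, see [ngms_compounds()].
#' @param mz_ppm_sd m/z noise sd, ppm.
#' @param rt_jitter_sd_min RT jitter sd, minutes.
#' @param intensity_sigma Biological log-normal sigma (natural log);
#'   technical sigma is a third of it.
#' @param isotope_fraction First-isotopologue intensity relative to the
#'   monoisotopic peak.
#' @param adduct_fractions Relative intensity of a compound's 1st, 2nd,
#'   ... adduct of a mode.
#' @param spikes data.frame `sample_id`, `compound`, `fold`, `mode`.
#' @param dropout_rate Per-peak dropout probability in `[0, 1)`.
#' @param ion_modes Modes to simulate.
#' @param seed Integer master seed.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(n_patients = 20L, injections_per_sample = 2L,
                     n_qc_pool = 3L, n_validation = 2L,
                     compounds = ngms_compounds(),
                     mz_ppm_sd = 2, rt_jitter_sd_min = 0.05,
                     intensity_sigma = 0.2, isotope_fraction = 0.20,
                     adduct_fractions = c(1, 0.25, 0.1),
                     spikes = NULL, dropout_rate = 0.01,
                     ion_modes = "positive", seed = 1L) {
  stopifnot(n_patients >= 4, injections_per_sample >= 1,
            n_qc_pool >= 0, n_validation >= 0,
            mz_ppm_sd >= 0, rt_jitter_sd_min >= 0, intensity_sigma >= 0,
            dropout_rate >= 0, dropout_rate < 1)
  if (is.null(spikes))
    spikes <- data.frame(sample_id = character(0), compound = character(0),
                         fold = numeric(0), mode = character(0))
  if (nrow(spikes)) {
    stopifnot(all(spikes$fold > 0))
    bad <- setdiff(spikes$compound, compounds$name)
    if (length(bad))
      stop("spike names unknown compound(s): ", paste(bad, collapse = ", "))
  }
  structure(list(n_patients = as.integer(n_patients),
                 injections_per_sample = as.integer(injections_per_sample),
                 n_qc_pool = as.integer(n_qc_pool),
                 n_validation = as.integer(n_validation),
                 compounds = compounds, mz_ppm_sd = mz_ppm_sd,
                 rt_jitter_sd_min = rt_jitter_sd_min,
                 intensity_sigma = intensity_sigma,
                 isotope_fraction = isotope_fraction,
                 adduct_fractions = adduct_fractions,
                 spikes = spikes, dropout_rate = dropout_rate,
                 ion_modes = ion_modes, seed = as.integer(seed)),
            class = "sim_spec")
}

# deterministic sub-stream seed from (master seed, keys...)
.stream_seed <- function(seed, ...) {
  h <- digest::digest(paste(seed, ..., sep = "\r"), algo = "sha256")
  strtoi(substr(h, 1, 7), base = 16L)
}

.sim_worklist <- function(spec) {
  rows <- list()
  pats <- sprintf("P%02d", seq_len(spec$n_patients))
  add <- function(sample, role, inj, mode) {
    rows[[length(rows) + 1L]] <<- data.frame(
      sample_id = sample, role = role, injection_index = inj,
      ion_mode = mode,
      datafile = paste0(injection_id(sample, inj, mode), ".tsv"),
      checksum = NA_character_, stringsAsFactors = FALSE)
  }
  for (mode in spec$ion_modes) {
    for (p in pats) for (i in seq_len(spec$injections_per_sample))
      add(p, "patient", i, mode)
    for (i in seq_len(spec$n_qc_pool)) add("QC_POOL", "qc_pool", i, mode)
    for (i in seq_len(spec$n_validation))
      add("VAL_PLASMA", "validation", i, mode)
  }
  worklist(do.call(rbind, rows), run_id = paste0("sim_seed", spec$seed))
}

# biological level multiplier for (sample, compound); QC pool is pooled
# material, so it has no biological spread
.bio_factors <- function(spec, sample) {
  n <- nrow(spec$compounds)
  if (sample == "QC_POOL") return(rep(1, n))
  set.seed(.stream_seed(spec$seed, sample, "bio"))
  exp(stats::rnorm(n, 0, spec$intensity_sigma))
}

#' Simulate an analytical batch
#'
#' Generates one peak list per worklist injection plus the ground truth.
#' Per injection and compound, one peak per allowed adduct of the mode
#' and isotopologue 0..1: m/z at the theoretical value times
#' `(1 + eps)`, `eps ~ N(0, mz_ppm_sd * 1e-6)`; a common RT per
#' compound-injection at the expected RT plus `N(0, rt_jitter_sd_min)`
#' (so adduct peaks co-elute); intensity `base * level * adduct fraction
#' * exp(N(0, sigma/3))`, where `level` is the biological draw shared by
#' a sample's duplicate injections, or the spike fold for spiked
#' (sample, compound, mode) entries; the first isotopologue at a fixed
#' fraction of the monoisotopic peak. Peaks are dropped independently
#' with probability `dropout_rate`.
#'
#' @param spec A [sim_spec()].
#' @return List: `peaklists` (named by injection id), `worklist`,
#'   `ground_truth` (list `sample_compound`, `ions`), `spec`.
#' @export
simulate_batch <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  wl <- .sim_worklist(spec)
  cc <- spec$compounds
  reg <- default_adducts()

  # theoretical ion table per compound and mode
  ions <- list()
  for (mode in spec$ion_modes) {
    rtcol <- if (mode == "positive") "rt_pos" else "rt_neg"
    for (i in seq_len(nrow(cc))) {
      if (is.na(cc[[rtcol]][i])) next
      allowed <- strsplit(cc$adducts[i], ";", fixed = TRUE)[[1]]
      allowed <- allowed[allowed %in% reg$name[reg$polarity == mode]]
      if (!length(allowed)) next
      mass <- monoisotopic_mass(cc$formula[i])
      for (ai in seq_along(allowed)) for (k in 0:1) {
        frac <- spec$adduct_fractions[min(ai, length(spec$adduct_fractions))]
        if (k == 1) frac <- frac * spec$isotope_fraction
        ions[[length(ions) + 1L]] <- data.frame(
          compound = cc$name[i], mode = mode, adduct = allowed[ai],
          isotope = k, mz = ion_mz(mass, allowed[ai], k, registry = reg),
          rel_abundance = frac, expected_rt = cc[[rtcol]][i],
          stringsAsFactors = FALSE)
      }
    }
  }
  ions <- do.call(rbind, ions)

  spike_key <- with(spec$spikes, paste(sample_id, compound, mode))
  peaklists <- list()
  truth_rows <- list()
  for (r in seq_len(nrow(wl))) {
    sample <- wl$sample_id[r]; mode <- wl$ion_mode[r]
    inj <- injection_id(sample, wl$injection_index[r], mode)
    bio <- .bio_factors(spec, sample)
    set.seed(.stream_seed(spec$seed, sample, wl$injection_index[r], mode))
    mi <- ions[ions$mode == mode, , drop = FALSE]
    comps <- unique(mi$compound)
    rows <- list()
    for (cmp in comps) {
      ci <- match(cmp, cc$name)
      sk <- match(paste(sample, cmp, mode), spike_key)
      level <- if (!is.na(sk)) spec$spikes$fold[sk] else bio[ci]
      tech <- exp(stats::rnorm(1, 0, spec$intensity_sigma / 3))
      rt_jit <- stats::rnorm(1, 0, spec$rt_jitter_sd_min)
      sub <- mi[mi$compound == cmp, , drop = FALSE]
      eps <- stats::rnorm(nrow(sub), 0, spec$mz_ppm_sd * 1e-6)
      drop <- stats::runif(nrow(sub)) < spec$dropout_rate
      keep <- !drop
      if (!any(keep)) next
      rows[[length(rows) + 1L]] <- data.frame(
        mz = sub$mz[keep] * (1 + eps[keep]),
        rt = pmax(sub$expected_rt[keep] + rt_jit, 0),
        intensity = cc$base_intensity[ci] * level * tech *
          sub$rel_abundance[keep],
        stringsAsFactors = FALSE)
    }
    pk <- do.call(rbind, rows)
    if (is.null(pk)) pk <- data.frame(mz = numeric(0), rt = numeric(0),
                                      intensity = numeric(0))
    peaklists[[inj]] <- peaklist(pk[order(pk$mz), , drop = FALSE], inj, mode)

    if (wl$injection_index[r] == 1L)  # truth is per (sample, compound, mode)
      for (cmp in comps) {
        sk <- match(paste(sample, cmp, mode), spike_key)
        truth_rows[[length(truth_rows) + 1L]] <- data.frame(
          sample_id = sample, compound = cmp, mode = mode,
          true_fold = if (!is.na(sk)) spec$spikes$fold[sk] else 1,
          expected_rt = mi$expected_rt[match(cmp, mi$compound)],
          spiked = !is.na(sk), expected_detected = TRUE,
          stringsAsFactors = FALSE)
      }
  }
  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  list(peaklists = peaklists, worklist = wl,
       ground_truth = list(sample_compound = truth, ions = ions),
       spec = spec)
}

#' Packaged VLCAD-deficiency batch scenario
#'
#' A 20-patient duplicate-injection batch in both ion modes. Patient
#' `P01` carries the nine long-chain acylcarnitines of a very long-chain
#' acyl-CoA dehydrogenase deficiency profile, elevated at the fold
#' changes observed in the index case (29 to 1227); the validation plasma
#' carries the ten data-processing validation compounds spiked at
#' `validation_fold`.
#'
#' @param seed Master seed.
#' @param validation_fold Spike fold for the validation compounds.
#' @param case_sample Sample id of the affected patient.
#' @return A [sim_spec()].
#' @export
vlcadd_scenario <- function(seed = 17L, validation_fold = 20,
                            case_sample = "P01") {
  cc <- ngms_compounds()
  acyl <- cc$name[cc$group == "acylcarnitine"]
  folds <- c(407.936, 51.387, 156.804, 354.890, 1227.147, 59.362, 66.594,
             74.586, 29.269)
  case_spikes <- data.frame(sample_id = case_sample, compound = acyl,
                            fold = folds, mode = "positive",
                            stringsAsFactors = FALSE)
  vcomp <- cc[cc$group == "validation" | cc$name == "Palmitoylcarnitine", ]
  vs <- list()
  for (i in seq_len(nrow(vcomp))) {
    modes <- c("positive", "negative")[!is.na(c(vcomp$rt_pos[i],
                                                vcomp$rt_neg[i]))]
    vs[[i]] <- data.frame(sample_id = "VAL_PLASMA", compound = vcomp$name[i],
                          fold = validation_fold, mode = modes,
                          stringsAsFactors = FALSE)
  }
  spikes <- rbind(case_spikes, do.call(rbind, vs))
  sim_spec(n_patients = 20L, injections_per_sample = 2L, n_qc_pool = 3L,
           n_validation = 2L, compounds = cc, spikes = spikes,
           ion_modes = c("positive", "negative"), seed = seed)
}

#' Compounds spiked into the validation plasma
#'
#' The ten data-processing validation compounds with their expected ion
#' modes, in the layout [validation_report()] expects.
#'
#' @return data.frame `name`, `modes` (semicolon-separated).
#' @export
validation_spikes <- function() {
  cc <- ngms_compounds()
  v <- cc[cc$group == "validation" | cc$name == "Palmitoylcarnitine", ]
  modes <- vapply(seq_len(nrow(v)), function(i)
    paste(c("positive", "negative")[!is.na(c(v$rt_pos[i], v$rt_neg[i]))],
          collapse = ";"), "")
  data.frame(name = v$name, modes = modes, stringsAsFactors = FALSE)
}

#' Write a simulated batch to disk
#'
#' TSV peak lists (one per injection), the worklist with SHA-256
#' checksums filled in, the ground-truth table and a session JSON.
#'
#' @param batch A [simulate_batch()] result.
#' @param dir Output directory (created if missing).
#' @param config Optional [session_config()] to persist alongside.
#' @return `dir`, invisibly.
#' @export
write_batch <- function(batch, dir, config = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wl <- batch$worklist
  sums <- character(nrow(wl))
  for (r in seq_len(nrow(wl))) {
    inj <- injection_id(wl$sample_id[r], wl$injection_index[r],
                        wl$ion_mode[r])
    path <- file.path(dir, wl$datafile[r])
    write_peaklist(batch$peaklists[[inj]], path)
    sums[r] <- checksum_file(path)
  }
  wl$checksum <- sums
  write_worklist(worklist(as.data.frame(wl), run_id = attr(wl, "run_id")),
                 file.path(dir, "worklist.tsv"))
  utils::write.table(batch$ground_truth$sample_compound,
                     file.path(dir, "ground_truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(config)) write_session(config, file.path(dir, "session.json"))
  invisible(dir)
}
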