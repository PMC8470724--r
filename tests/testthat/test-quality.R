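# Analytical QC, validation gate, session gate, diagnostics data and
# release comparison.

one_standard <- function(rt = 5.6) {
  standard_defs(name = "Trp", formula = "C11H12N2O2", adduct = "M+H",
                ion_mode = "positive", expected_rt = rt, kind = "internal")
}

std_peaklist <- function(inj, mz, rt, intensity, extra = NULL) {
  d <- data.frame(mz = mz, rt = rt, intensity = intensity)
  if (!is.null(extra)) d <- rbind(d, extra)
  peaklist(d, inj, "positive")
}

test_that("standards are recovered from in-tolerance peaks and reported absent otherwise", {
  defs <- one_standard()
  good <- std_peaklist("i1", defs$theoretical_mz * (1 + 2e-6), 5.65, 1e5)
  bad <- std_peaklist("i2", defs$theoretical_mz * (1 + 2e-5), 5.65, 1e5)
  rec <- recover_standards(list(good, bad), defs, 5, 0.5)
  expect_identical(rec$found, c(TRUE, FALSE))
  expect_true(abs(rec$ppm_error[1]) <= 5)
})

test_that("recovery equals the brute-force best-candidate search", {
  set.seed(51)
  defs <- one_standard()
  for (rep in 1:30) {
    n <- sample(5:60, 1)
    p <- data.frame(mz = defs$theoretical_mz * (1 + rnorm(n, 0, 5e-6)),
                    rt = defs$expected_rt + rnorm(n, 0, 0.4),
                    intensity = 10^runif(n, 3, 6))
    pl <- peaklist(p, "inj", "positive")
    rec <- recover_standards(list(pl), defs, 5, 0.5)
    pes <- ppm_error(p$mz, defs$theoretical_mz)
    drs <- abs(p$rt - defs$expected_rt)
    cand <- which(abs(pes) <= 5 & drs <= 0.5)
    if (!length(cand)) {
      expect_false(rec$found)
    } else {
      best <- cand[order(abs(pes[cand]), drs[cand], cand)][1]
      expect_true(rec$found)
      expect_identical(rec$rt, p$rt[best])
      expect_identical(rec$intensity, p$intensity[best])
    }
  }
})

test_that("QC metrics follow the stated formulas", {
  defs <- one_standard()
  rec <- data.frame(standard = "Trp", injection = c("i1", "i2", "i3"),
                    found = TRUE, rt = c(5.6, 5.6, 5.6),
                    intensity = c(90, 100, 110),
                    ppm_error = c(1, -2, 0.5), stringsAsFactors = FALSE)
  qc <- qc_metrics(rec, defs)
  expect_identical(qc$rt_delta_pct, 0)
  # sample-sd (n-1) CV convention: sd(90,100,110)/100 = 10%
  expect_equal(qc$response_cv_pct, 10, tolerance = 1e-9)
  expect_identical(qc$worst_abs_ppm, 2)
  expect_true(qc$overall_pass)

  rec$intensity <- 100
  expect_identical(qc_metrics(rec, defs)$response_cv_pct, 0)
})

test_that("QC metrics are invariant to injection order and non-negative", {
  set.seed(52)
  defs <- one_standard()
  rec <- data.frame(standard = "Trp", injection = sprintf("i%d", 1:6),
                    found = TRUE, rt = 5.6 + rnorm(6, 0, 0.02),
                    intensity = 10^rnorm(6, 5, 0.1),
                    ppm_error = rnorm(6, 0, 1), stringsAsFactors = FALSE)
  q1 <- qc_metrics(rec, defs)
  q2 <- qc_metrics(rec[sample(6), ], defs)
  expect_equal(q1, q2, tolerance = 1e-12)
  expect_gte(q1$rt_delta_pct, 0)
  expect_gte(q1$response_cv_pct, 0)
})

test_that("an external standard recovered once fails with undefined repeatability", {
  defs <- standard_defs(name = "ES", formula = "C24H40O5", adduct = "M+H",
                        ion_mode = "positive", expected_rt = 12.6,
                        kind = "external")
  rec <- data.frame(standard = "ES", injection = c("i1", "i2"),
                    found = c(TRUE, FALSE), rt = c(12.6, NA),
                    intensity = c(1e5, NA), ppm_error = c(0.5, NA),
                    stringsAsFactors = FALSE)
  qc <- qc_metrics(rec, defs)
  expect_true(is.na(qc$rt_delta_pct))
  expect_false(qc$overall_pass)
})

test_that("builtin standards pass QC on a simulated batch", {
  b <- simulate_batch(sim_spec(ion_modes = "positive", seed = 2))
  defs <- builtin_standards("positive")
  rec <- recover_standards(b$peaklists, defs, 5, 0.5)
  qc <- qc_metrics(rec, defs)
  expect_true(all(qc$overall_pass))
  expect_true(all(qc$worst_abs_ppm <= 5))
})

test_that("the validation gate fails naming the compound that is not increased", {
  recs <- structure(data.frame(
    feature_id = c("F1", "F2"), mz = c(100.1, 200.2), rt = c(2, 3),
    ion_mode = "positive", target_id = "VAL_PLASMA",
    patient_mean = c(1e6, 2e6), reference_median = 1e4, n_reference = 19L,
    fold_change = c(100, 1), z = c(20, 0), p_value = c(0, 1),
    status = "ok", partial = FALSE,
    altered = c(TRUE, FALSE), direction = c("up", NA),
    level = "panel", compound = c("CmpA", "CmpB"), hmdb_id = NA,
    adduct = "M+H", isotope = 0L, ppm_error = 0.1, rt_delta = 0.01,
    stringsAsFactors = FALSE), class = c("interpretation_records",
                                         "data.frame"))
  spiked <- data.frame(name = c("CmpA", "CmpB"), modes = "positive",
                       stringsAsFactors = FALSE)
  panel <- data.frame(name = c("CmpA", "CmpB"))
  vr <- validation_report(recs, spiked, panel)
  expect_false(vr$gate)
  expect_identical(vr$missing, "CmpB")
  # with only the detected compound spiked, the gate passes
  vr2 <- validation_report(recs, spiked[1, , drop = FALSE], panel)
  expect_true(vr2$gate)
  expect_identical(length(vr2$missing), 0L)
  # a spike absent from the panel is a configuration error
  expect_error(validation_report(recs, data.frame(name = "Ghost",
                                                  modes = "positive"),
                                 panel), "Ghost")
})

test_that("the validation gate is monotone in detections", {
  # turning CmpB's record into an up-flag can only improve the verdict
  base <- data.frame(
    feature_id = c("F1", "F2"), mz = c(100.1, 200.2), rt = c(2, 3),
    ion_mode = "positive", target_id = "VAL_PLASMA",
    patient_mean = 1e6, reference_median = 1e4, n_reference = 19L,
    fold_change = c(100, 100), z = c(20, 20), p_value = 0,
    status = "ok", partial = FALSE,
    altered = TRUE, direction = "up",
    level = "panel", compound = c("CmpA", "CmpB"), hmdb_id = NA,
    adduct = "M+H", isotope = 0L, ppm_error = 0.1, rt_delta = 0.01,
    stringsAsFactors = FALSE)
  recs <- structure(base, class = c("interpretation_records", "data.frame"))
  spiked <- data.frame(name = c("CmpA", "CmpB"), modes = "positive")
  panel <- data.frame(name = c("CmpA", "CmpB"))
  expect_true(validation_report(recs, spiked, panel)$gate)
})

test_that("the session gate blocks when either QC or validation fails", {
  qpass <- data.frame(overall_pass = c(TRUE, TRUE))
  qfail <- data.frame(overall_pass = c(TRUE, FALSE))
  expect_true(session_gate(qpass, TRUE))
  expect_false(session_gate(qfail, TRUE))
  expect_false(session_gate(qpass, FALSE))
  expect_false(session_gate(qpass[0, , drop = FALSE], TRUE))
})

test_that("identical injections get identical PCA scores", {
  x <- matrix(10^runif(12, 3, 5), 4, 3,
              dimnames = list(sprintf("F%05d", 1:4), c("a", "b", "c")))
  x[, "b"] <- x[, "a"]
  im <- structure(list(
    intensities = x,
    features = data.frame(feature_id = rownames(x), mz = 1:4 + 100,
                          rt = 1:4),
    assignments = data.frame(feature_id = rownames(x)[c(1, 1, 1)],
                             injection = c("a", "b", "c"),
                             rt = c(1, 1, 1), intensity = 1)),
    ion_mode = "positive", class = "intensity_matrix")
  d <- diagnostics_data(im)
  sc <- d$pca$scores
  expect_equal(as.numeric(sc[sc$injection == "a", -1]),
               as.numeric(sc[sc$injection == "b", -1]), tolerance = 1e-9)
})

test_that("PCA scores reproduce the covariance eigenstructure", {
  set.seed(53)
  x <- matrix(10^rnorm(5 * 6, 4, 0.3), 5, 6,
              dimnames = list(sprintf("F%05d", 1:5), sprintf("i%d", 1:6)))
  im <- structure(list(
    intensities = x,
    features = data.frame(feature_id = rownames(x), mz = 1:5 + 100,
                          rt = 1:5),
    assignments = data.frame(feature_id = "F00001",
                             injection = colnames(x), rt = 1,
                             intensity = 1)),
    ion_mode = "positive", class = "intensity_matrix")
  d <- diagnostics_data(im, n_components = 2L)
  # oracle: direct eigendecomposition of the covariance of centered log10
  lx <- scale(t(log10(x)), center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(lx))
  expect_equal(d$pca$variance_explained,
               (ev$values / sum(ev$values))[1:2], tolerance = 1e-9)
  # scores match projections up to the sign of each component
  for (k in 1:2) {
    proj <- as.numeric(lx %*% ev$vectors[, k])
    got <- d$pca$scores[[paste0("PC", k)]]
    expect_true(max(abs(got - proj)) < 1e-9 || max(abs(got + proj)) < 1e-9)
  }
})

test_that("a constant RT offset in one injection is estimated by the shift diagnostic", {
  spec <- sim_spec(n_patients = 4, injections_per_sample = 1, n_qc_pool = 0,
                   n_validation = 0, ion_modes = "positive", seed = 3,
                   rt_jitter_sd_min = 0, dropout_rate = 0)
  b <- simulate_batch(spec)
  shifted <- lapply(b$peaklists, function(pl) {
    d <- as.data.frame(pl)
    if (attr(pl, "injection") == "P01.1.pos") d$rt <- d$rt + 0.1
    peaklist(d, attr(pl, "injection"), attr(pl, "ion_mode"))
  })
  al <- align_features(shifted, 5, 0.5)
  im <- to_matrix(al, b$worklist)
  # features unseen in some injection are expected here (the 0.1 min
  # offset splits a few) and are excluded from the PCA with a warning
  d <- suppressWarnings(diagnostics_data(im))
  s <- d$rt_shift
  expect_equal(s$median_shift_min[s$injection == "P01.1.pos"], 0.1,
               tolerance = 0.02)
  expect_equal(max(abs(s$median_shift_min[s$injection != "P01.1.pos"])), 0,
               tolerance = 0.02)
})

test_that("release comparison reports exactly the symmetric difference", {
  old <- data.frame(patient_id = c("P01", "P01", "P02"),
                    compound = c("A", "B", "C"), stringsAsFactors = FALSE)
  expect_true(compare_sessions(old, old)$pass)

  new <- old[-2, ]
  cmp <- compare_sessions(old, new)
  expect_false(cmp$pass)
  expect_identical(cmp$differences$compound, "B")
  expect_identical(cmp$differences$side, "old_only")

  # missing sample on one side fails
  cmp2 <- compare_sessions(old, old[old$patient_id == "P01", ])
  expect_false(cmp2$pass)
  expect_identical(cmp2$missing_samples, "P02")
})

test_that("release comparison equals a brute-force set oracle on random sets", {
  set.seed(54)
  for (rep in 1:30) {
    pats <- sprintf("P%02d", 1:4)
    mk <- function() {
      n <- sample(0:12, 1)
      unique(data.frame(patient_id = sample(pats, n, TRUE),
                        compound = sample(LETTERS[1:6], n, TRUE),
                        stringsAsFactors = FALSE))
    }
    old <- mk(); new <- mk()
    cmp <- compare_sessions(old, new)
    ok <- setequal(unique(old$patient_id), unique(new$patient_id))
    for (p in union(old$patient_id, new$patient_id)) {
      so <- old$compound[old$patient_id == p]
      sn <- new$compound[new$patient_id == p]
      if (!setequal(so, sn)) ok <- FALSE
      expect_true(setequal(
        cmp$differences$compound[cmp$differences$patient_id == p &
                                   cmp$differences$side == "old_only"],
        setdiff(so, sn)))
    }
    expect_identical(cmp$pass, ok)
  }
})

test_that("QC reports are written as TSV with a JSON verdict sidecar", {
  dir <- withr::local_tempdir()
  rows <- data.frame(standard = "Trp", overall_pass = TRUE)
  path <- file.path(dir, "qc.tsv")
  write_report(rows, path, verdict = list(pass = TRUE))
  expect_true(file.exists(path))
  side <- jsonlite::read_json(file.path(dir, "qc.json"),
                              simplifyVector = TRUE)
  expect_true(side$pass)
})
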