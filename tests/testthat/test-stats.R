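# Single-patient statistics: duplicate averaging, fold change, robust z,
# altered selection.

# build a sample_matrix directly for focused tests
make_sm <- function(intensities, roles, partial = NULL) {
  feats <- data.frame(feature_id = rownames(intensities),
                      mz = seq_len(nrow(intensities)) + 100,
                      rt = seq_len(nrow(intensities)),
                      stringsAsFactors = FALSE)
  if (is.null(partial))
    partial <- matrix(FALSE, nrow(intensities), ncol(intensities),
                      dimnames = dimnames(intensities))
  structure(list(intensities = intensities, partial = partial,
                 roles = roles, features = feats, ion_mode = "positive"),
            class = "sample_matrix")
}

test_that("duplicate injections average arithmetically", {
  pls <- list(
    peaklist(data.frame(mz = 200, rt = 5, intensity = 100), "P01.1.pos",
             "positive"),
    peaklist(data.frame(mz = 200, rt = 5, intensity = 102), "P01.2.pos",
             "positive"),
    peaklist(data.frame(mz = 200, rt = 5, intensity = 50), "P02.1.pos",
             "positive")
  )
  wl <- worklist(data.frame(
    sample_id = c("P01", "P01", "P02"), role = "patient",
    injection_index = c(1L, 2L, 1L), ion_mode = "positive",
    datafile = "x.tsv", stringsAsFactors = FALSE))
  sm <- average_duplicates(to_matrix(align_features(pls, 5, 0.5), wl))
  expect_identical(unname(sm$intensities[1, "P01"]), 101)
  # single-injection sample is the identity
  expect_identical(unname(sm$intensities[1, "P02"]), 50)
  expect_false(any(sm$partial))
})

test_that("a half-observed duplicate pair averages over observed values and is flagged partial", {
  pls <- list(
    peaklist(data.frame(mz = 200, rt = 5, intensity = 100), "P01.1.pos",
             "positive"),
    peaklist(data.frame(mz = 300, rt = 7, intensity = 10), "P01.2.pos",
             "positive")
  )
  wl <- suppressWarnings(worklist(data.frame(
    sample_id = "P01", role = "patient", injection_index = c(1L, 2L),
    ion_mode = "positive", datafile = "x.tsv", stringsAsFactors = FALSE)))
  suppressWarnings(sm <- average_duplicates(
    to_matrix(align_features(pls, 5, 0.5), wl)))
  i200 <- which.min(abs(sm$features$mz - 200))
  expect_identical(unname(sm$intensities[i200, "P01"]), 100)
  expect_true(sm$partial[i200, "P01"])
})

test_that("fold change is patient over floored median of the others", {
  expect_identical(patient_fold_change(500, c(4, 5, 6, 5, 5),
                                       intensity_floor = 1), 100)
  expect_identical(patient_fold_change(5, c(4, 5, 6, 5, 5),
                                       intensity_floor = 1), 1)
  expect_true(is.na(patient_fold_change(500, c(4, 5), intensity_floor = 1)))
  # the floor binds when the reference is weaker than it
  expect_identical(patient_fold_change(5000, c(4, 5, 6),
                                       intensity_floor = 1000), 5)
})

test_that("robust z is zero at the median and finite on constant references", {
  expect_identical(robust_z(10, c(10, 10, 10, 10), intensity_floor = 1), 0)
  z <- robust_z(1e6, c(10, 10, 10, 10), intensity_floor = 1000)
  expect_true(is.finite(z))
  expect_equal(z, (1e6 - 10) / 1000, tolerance = 1e-12)
  expect_true(is.na(robust_z(10, c(1, 2), intensity_floor = 1)))
})

test_that("robust z agrees with direct formula evaluation on random rows", {
  set.seed(41)
  for (rep in 1:50) {
    others <- 10^runif(sample(3:20, 1), 3, 7)
    pm <- 10^runif(1, 3, 7)
    med <- median(others)
    denom <- max(1.4826 * median(abs(others - med)), 0.05 * med, 1000)
    expect_equal(robust_z(pm, others), (pm - med) / denom,
                 tolerance = 1e-12)
    expect_equal(patient_fold_change(pm, others), pm / max(med, 1000),
                 tolerance = 1e-12)
  }
})

test_that("p_from_z is the two-sided normal tail", {
  expect_identical(p_from_z(0), 1)
  expect_equal(p_from_z(1.959964), 0.05, tolerance = 1e-6)
  expect_identical(p_from_z(2.3), p_from_z(-2.3))
})

test_that("statistics are invariant under global intensity scaling", {
  set.seed(42)
  x <- matrix(10^runif(60, 3, 6), 6, 10,
              dimnames = list(sprintf("F%05d", 1:6), sprintf("P%02d", 1:10)))
  roles <- setNames(rep("patient", 10), colnames(x))
  cfg <- session_config()
  s1 <- feature_statistics(make_sm(x, roles), "P01", cfg)
  # scale both the data and the floor: a pure change of units
  cfg2 <- session_config(intensity_floor = cfg$intensity_floor * 10)
  s2 <- feature_statistics(make_sm(x * 10, roles), "P01", cfg2)
  expect_equal(s1$fold_change, s2$fold_change, tolerance = 1e-12)
  expect_equal(s1$z, s2$z, tolerance = 1e-12)
  expect_equal(s1$p_value, s2$p_value, tolerance = 1e-12)
  expect_identical(s1$altered, s2$altered)
})

test_that("statistics are invariant under reference permutation", {
  set.seed(43)
  x <- matrix(10^runif(50, 3, 6), 5, 10,
              dimnames = list(sprintf("F%05d", 1:5), sprintf("P%02d", 1:10)))
  roles <- setNames(rep("patient", 10), colnames(x))
  s1 <- feature_statistics(make_sm(x, roles), "P01")
  perm <- c("P01", sample(colnames(x)[-1]))
  s2 <- feature_statistics(make_sm(x[, perm], roles[perm]), "P01")
  expect_equal(s1$fold_change, s2$fold_change, tolerance = 1e-12)
  expect_equal(s1$z, s2$z, tolerance = 1e-12)
})

test_that("raising the patient mean never decreases fold change or z", {
  set.seed(44)
  others <- 10^runif(12, 3, 6)
  pms <- sort(10^runif(30, 3, 7))
  fcs <- vapply(pms, patient_fold_change, numeric(1), others = others)
  zs <- vapply(pms, robust_z, numeric(1), others = others)
  expect_true(!is.unsorted(fcs))
  expect_true(!is.unsorted(zs))
})

test_that("a patient at the reference median gives FC 1 and z 0", {
  # in both rows, P01 sits exactly at the median of the other patients
  x <- rbind(c(5000, 4000, 5000, 6000, 5000, 5000),
             c(8000, 6000, 8000, 10000, 8000, 8000))
  dimnames(x) <- list(c("F00001", "F00002"), sprintf("P%02d", 1:6))
  roles <- setNames(rep("patient", 6), colnames(x))
  st <- feature_statistics(make_sm(x, roles), "P01")
  expect_equal(st$fold_change, c(1, 1), tolerance = 1e-12)
  expect_equal(st$z, c(0, 0), tolerance = 1e-12)
  expect_equal(st$p_value, c(1, 1), tolerance = 1e-12)
})

test_that("altered flags equal a brute-force re-evaluation on a simulated batch", {
  spec <- sim_spec(n_patients = 8, ion_modes = "positive", seed = 9,
                   spikes = data.frame(sample_id = "P03",
                                       compound = "Palmitoylcarnitine",
                                       fold = 50, mode = "positive"))
  b <- simulate_batch(spec)
  cfg <- session_config(mode_list = "positive")
  sm <- average_duplicates(to_matrix(
    align_features(Filter(function(p) attr(p, "ion_mode") == "positive",
                          b$peaklists), cfg$mz_tolerance_ppm,
                   cfg$rt_tolerance_min), b$worklist))
  st <- feature_statistics(sm, "P03", cfg)
  redo_up <- !is.na(st$z) & !is.na(st$fold_change) &
    st$z >= cfg$z_min & st$fold_change >= cfg$fc_up &
    st$patient_mean >= cfg$intensity_floor
  redo_down <- !is.na(st$z) & !is.na(st$fold_change) &
    st$z <= -cfg$z_min & st$fold_change <= cfg$fc_down
  expect_identical(st$altered, redo_up | redo_down)
  expect_identical(st$direction,
                   ifelse(redo_up, "up", ifelse(redo_down, "down",
                                                NA_character_)))
  # the spiked compound's principal ion is among the flagged features
  expect_true(any(st$altered & st$direction == "up", na.rm = TRUE))
})

test_that("threshold gates act independently", {
  cfg <- session_config()
  d <- data.frame(z = c(10, 10, 2, -10, -10),
                  fold_change = c(400, 1.1, 400, 0.1, 0.9),
                  patient_mean = c(1e6, 1e6, 1e6, 1000, 1000))
  out <- select_altered(d, cfg)
  expect_identical(out$altered, c(TRUE, FALSE, FALSE, TRUE, FALSE))
  expect_identical(out$direction[1], "up")
  expect_identical(out$direction[4], "down")
})

test_that("missing and sparse features get the documented statuses", {
  x <- matrix(10^runif(40, 3.5, 4.5), 4, 10,
              dimnames = list(sprintf("F%05d", 1:4), sprintf("P%02d", 1:10)))
  # F1 missing in the patient but present in every reference -> floored
  x[1, "P01"] <- NA
  # F2 observed in only 2 references -> insufficient
  x[2, c(-1, -2, -3)] <- NA
  # F3 missing in the patient AND most references -> undefined
  x[3, c(1:7)] <- NA
  roles <- setNames(rep("patient", 10), colnames(x))
  st <- feature_statistics(make_sm(x, roles), "P01")
  expect_identical(st$status,
                   c("patient_missing", "insufficient_reference",
                     "undefined", "ok"))
  expect_identical(unname(st$patient_mean[1]), 1000)
  expect_true(is.na(st$fold_change[2]))
  expect_false(any(st$altered[2:3]))
})
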