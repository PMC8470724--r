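# Brute-force reference implementations used to cross-check the package's
# optimized paths. These deliberately use naive O(n^2) scans and explicit
# loops, independent of the package internals.

# exhaustive m/z scan: every ion within tol ppm, ordered like match_mz
oracle_match_mz <- function(observed, ions, tol) {
  pe <- (observed - ions$mz) / ions$mz * 1e6
  idx <- which(abs(pe) <= tol)
  idx <- idx[order(abs(pe[idx]), ions$mz[idx], idx)]
  out <- ions[idx, , drop = FALSE]
  out$ppm_error <- pe[idx]
  rownames(out) <- NULL
  out
}

# single-linkage connected components by repeated expansion over the full
# pairwise adjacency (edge: ppm at pair mean <= mz_tol AND dRT <= rt_tol)
oracle_components <- function(mz, rt, mz_tol, rt_tol) {
  n <- length(mz)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    ppm <- abs(mz[i] - mz[j]) / ((mz[i] + mz[j]) / 2) * 1e6
    adj[i, j] <- ppm <= mz_tol && abs(rt[i] - rt[j]) <= rt_tol
  }
  comp <- rep(NA_integer_, n); cid <- 0L
  for (i in seq_len(n)) {
    if (!is.na(comp[i])) next
    cid <- cid + 1L
    frontier <- i; comp[i] <- cid
    while (length(frontier)) {
      cur <- frontier[1]; frontier <- frontier[-1]
      nxt <- which(adj[cur, ] & is.na(comp))
      comp[nxt] <- cid
      frontier <- c(frontier, nxt)
    }
  }
  comp
}

# full alignment procedure with brute-force components: per-injection
# dedup (max intensity; ties lower mz, lower rt, lower row id), then
# iterative trimming of members outside tolerance of the consensus
# medians (worst relative excess removed first; ties larger mz, larger
# row id); displaced peaks re-enter the pool.
oracle_align_partition <- function(peaks, mz_tol, rt_tol) {
  pool <- seq_len(nrow(peaks))
  groups <- list()
  while (length(pool)) {
    comp <- oracle_components(peaks$mz[pool], peaks$rt[pool], mz_tol, rt_tol)
    released <- integer(0)
    for (cid in unique(comp)) {
      idx <- pool[comp == cid]
      o <- order(peaks$injection[idx], -peaks$intensity[idx],
                 peaks$mz[idx], peaks$rt[idx], idx)
      idx <- idx[o]
      dup <- duplicated(peaks$injection[idx])
      released <- c(released, idx[dup])
      kept <- idx[!dup]
      repeat {
        cmz <- median(peaks$mz[kept]); crt <- median(peaks$rt[kept])
        pe <- abs((peaks$mz[kept] - cmz) / cmz * 1e6)
        dr <- abs(peaks$rt[kept] - crt)
        bad <- pe > mz_tol | dr > rt_tol
        if (!any(bad)) break
        badness <- pmax(pe / mz_tol, dr / rt_tol)
        worst <- order(-badness, -peaks$mz[kept], -kept)[1]
        released <- c(released, kept[worst])
        kept <- kept[-worst]
      }
      groups[[length(groups) + 1L]] <- sort(kept)
    }
    pool <- sort(released)
  }
  groups
}

# canonical form of a partition: sorted list of sorted member vectors
canonical_partition <- function(groups) {
  groups <- lapply(groups, sort)
  groups[order(vapply(groups, `[`, numeric(1), 1))]
}

# double-filter panel annotation oracle
oracle_annotate_panel <- function(features, panel_index, mz_tol, rt_tol) {
  rows <- list()
  for (i in seq_len(nrow(features))) {
    for (j in seq_len(nrow(panel_index))) {
      pe <- (features$mz[i] - panel_index$mz[j]) / panel_index$mz[j] * 1e6
      dr <- features$rt[i] - panel_index$expected_rt[j]
      if (abs(pe) <= mz_tol && abs(dr) <= rt_tol)
        rows[[length(rows) + 1L]] <- data.frame(
          feature_id = features$feature_id[i],
          compound = panel_index$compound_name[j],
          adduct = panel_index$adduct[j], isotope = panel_index$isotope[j],
          ppm_error = pe, rt_delta = dr, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame(feature_id = character(0))
  out
}

# random peak cloud with planted clusters, for alignment property tests
random_peak_cloud <- function(n, n_centers = max(2L, n %/% 6L),
                              n_injections = 4L, ppm_sd = 3, rt_sd = 0.1) {
  centers_mz <- runif(n_centers, 100, 900)
  centers_rt <- runif(n_centers, 0.5, 15)
  pick <- sample.int(n_centers, n, replace = TRUE)
  data.frame(
    injection = paste0("inj", sample.int(n_injections, n, replace = TRUE)),
    mz = centers_mz[pick] * (1 + rnorm(n, 0, ppm_sd * 1e-6)),
    rt = pmax(0, centers_rt[pick] + rnorm(n, 0, rt_sd)),
    intensity = 10^runif(n, 3, 7),
    stringsAsFactors = FALSE
  )
}

# wrap a peaks data.frame into per-injection peaklist objects
peaks_to_peaklists <- function(peaks, mode = "positive") {
  lapply(split(peaks, peaks$injection), function(d)
    peaklist(d[c("mz", "rt", "intensity")], d$injection[1], mode))
}

# recover the member partition (original row ids) from an alignment,
# matching peaks back by (injection, mz, rt, intensity)
alignment_partition <- function(aligned, peaks) {
  key <- paste(peaks$injection, format(peaks$mz, digits = 15),
               format(peaks$rt, digits = 15),
               format(peaks$intensity, digits = 15))
  akey <- paste(aligned$assignments$injection,
                format(aligned$assignments$mz, digits = 15),
                format(aligned$assignments$rt, digits = 15),
                format(aligned$assignments$intensity, digits = 15))
  ids <- match(akey, key)
  stopifnot(!anyNA(ids))
  unname(split(ids, aligned$assignments$feature_id))
}
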