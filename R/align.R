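# Cross-injection mass-feature alignment.
#
# Two peaks are linkable when their m/z differ by at most mz_tol ppm
# (relative to the mean of the two m/z) AND their retention times differ
# by at most rt_tol minutes. Features are the connected components of
# that relation, refined so that (a) each injection contributes at most
# one peak per feature and (b) every member lies within tolerance of the
# feature's consensus (median m/z, median RT). Peaks displaced by the
# refinement re-enter the pool and are clustered again, so every input
# peak ends up in exactly one feature.

.link_ppm <- function(mz1, mz2) abs(mz1 - mz2) / ((mz1 + mz2) / 2) * 1e6

# connected components via m/z-sorted sweep + union-find
.components_sweep <- function(mz, rt, mz_tol, rt_tol) {
  n <- length(mz)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ord <- order(mz)
  smz <- mz[ord]; srt <- rt[ord]
  for (a in seq_len(n - 1L)) {
    b <- a + 1L
    # only peaks within the ppm window in sorted order can be linked
    while (b <= n && .link_ppm(smz[a], smz[b]) <= mz_tol) {
      if (abs(srt[a] - srt[b]) <= rt_tol) {
        ra <- find(ord[a]); rb <- find(ord[b])
        if (ra != rb) parent[ra] <- rb
      }
      b <- b + 1L
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Refine one component: per-injection dedup, then iterative trimming of
# members outside tolerance of the consensus. Returns indices kept and
# indices released back to the pool. Deterministic tie-breaks throughout.
.refine_component <- function(peaks, idx, mz_tol, rt_tol) {
  released <- integer(0)
  # one peak per injection: keep highest intensity; ties by lower m/z,
  # lower RT, then original input order
  o <- order(peaks$injection[idx], -peaks$intensity[idx],
             peaks$mz[idx], peaks$rt[idx], idx)
  idx <- idx[o]
  dup <- duplicated(peaks$injection[idx])
  released <- c(released, idx[dup])
  kept <- idx[!dup]
  repeat {
    cmz <- stats::median(peaks$mz[kept])
    crt <- stats::median(peaks$rt[kept])
    pe <- abs(ppm_error(peaks$mz[kept], cmz))
    dr <- abs(peaks$rt[kept] - crt)
    bad <- pe > mz_tol | dr > rt_tol
    if (!any(bad)) break
    badness <- pmax(pe / mz_tol, dr / rt_tol)
    worst <- order(-badness, -peaks$mz[kept], -kept)[1]
    released <- c(released, kept[worst])
    kept <- kept[-worst]
  }
  list(kept = kept, released = released)
}

.assign_features <- function(peaks, mz_tol, rt_tol, components_fun) {
  pool <- seq_len(nrow(peaks))
  groups <- list()
  while (length(pool)) {
    comp <- components_fun(peaks$mz[pool], peaks$rt[pool], mz_tol, rt_tol)
    released <- integer(0)
    for (cid in unique(comp)) {
      idx <- pool[comp == cid]
      r <- .refine_component(peaks, idx, mz_tol, rt_tol)
      groups[[length(groups) + 1L]] <- r$kept
      released <- c(released, r$released)
    }
    pool <- sort(released)
  }
  groups
}

#' Align per-injection peaks into batch-level mass features
#'
#' Groups peaks across injections into features by single-linkage
#' clustering in (m/z, RT) with the tolerances given, refined so that each
#' injection contributes at most one peak per feature (the more intense
#' peak wins; the loser re-enters the pool) and every member lies within
#' tolerance of the feature consensus. The consensus m/z and RT are the
#' medians of the member peaks. Every input peak is assigned to exactly
#' one feature; the procedure is deterministic.
#'
#' @param peaklists List of [peaklist()]s of a single ion mode; at least
#'   one must be non-empty.
#' @param mz_tol m/z tolerance in ppm (> 0).
#' @param rt_tol RT tolerance in minutes (> 0).
#' @return An `aligned_features` object: list with
#'   \describe{
#'     \item{features}{data.frame `feature_id`, `mz`, `rt`, `ion_mode`,
#'       `support` (number of contributing injections), sorted by
#'       (`mz`, `rt`).}
#'     \item{assignments}{data.frame mapping every input peak
#'       (`feature_id`, `injection`, `mz`, `rt`, `intensity`).}
#'   }
#' @export
align_features <- function(peaklists, mz_tol, rt_tol) {
  stopifnot(length(peaklists) >= 1, mz_tol > 0, rt_tol > 0)
  modes <- unique(vapply(peaklists, attr, "", "ion_mode"))
  if (length(modes) != 1L)
    stop("peak lists mix ion modes (", paste(modes, collapse = ", "),
         "); align each mode separately")
  peaks <- do.call(rbind, lapply(peaklists, function(pl) {
    d <- as.data.frame(pl)
    if (!nrow(d)) return(NULL)
    d$injection <- attr(pl, "injection")
    d
  }))
  if (is.null(peaks) || !nrow(peaks))
    stop("all peak lists are empty; nothing to align")
  rownames(peaks) <- NULL

  groups <- .assign_features(peaks, mz_tol, rt_tol, .components_sweep)

  cons <- t(vapply(groups, function(g) {
    c(stats::median(peaks$mz[g]), stats::median(peaks$rt[g]), length(g))
  }, numeric(3)))
  o <- order(cons[, 1], cons[, 2])
  groups <- groups[o]; cons <- cons[o, , drop = FALSE]
  ids <- sprintf("F%05d", seq_along(groups))

  features <- data.frame(
    feature_id = ids, mz = cons[, 1], rt = cons[, 2],
    ion_mode = modes, support = as.integer(cons[, 3]),
    stringsAsFactors = FALSE
  )
  assignments <- do.call(rbind, lapply(seq_along(groups), function(i) {
    g <- groups[[i]]
    data.frame(feature_id = ids[i], injection = peaks$injection[g],
               mz = peaks$mz[g], rt = peaks$rt[g],
               intensity = peaks$intensity[g], stringsAsFactors = FALSE)
  }))
  rownames(assignments) <- NULL
  structure(list(features = features, assignments = assignments),
            ion_mode = modes, mz_tol = mz_tol, rt_tol = rt_tol,
            class = "aligned_features")
}

#' @export
print.aligned_features <- function(x, ...) {
  cat("aligned_features:", nrow(x$features), "features from",
      nrow(x$assignments), "peaks across",
      length(unique(x$assignments$injection)), "injections (",
      attr(x, "ion_mode"), "mode )\n")
  invisible(x)
}

#' Feature-by-injection intensity matrix
#'
#' Builds the rectangular features x injections matrix from an alignment,
#' with columns ordered as in the worklist (restricted to the alignment's
#' ion mode) and unobserved cells encoded as `NA` (absent, not zero).
#'
#' @param aligned An [align_features()] result.
#' @param wl A [worklist()] covering every injection in `aligned`.
#' @return An `intensity_matrix` object: list with `intensities` (numeric
#'   matrix, rows = features, cols = injections), `features`, `worklist`
#'   (the mode-restricted worklist rows) and `assignments`.
#' @export
to_matrix <- function(aligned, wl) {
  mode <- attr(aligned, "ion_mode")
  wlm <- wl[wl$ion_mode == mode, , drop = FALSE]
  cols <- injection_id(wlm$sample_id, wlm$injection_index, wlm$ion_mode)
  unknown <- setdiff(unique(aligned$assignments$injection), cols)
  if (length(unknown))
    stop("injection(s) present in features but not in worklist: ",
         paste(unknown, collapse = ", "))
  m <- matrix(NA_real_, nrow = nrow(aligned$features), ncol = length(cols),
              dimnames = list(aligned$features$feature_id, cols))
  a <- aligned$assignments
  m[cbind(match(a$feature_id, rownames(m)), match(a$injection, cols))] <-
    a$intensity
  structure(list(intensities = m, features = aligned$features,
                 worklist = wlm, assignments = a),
            ion_mode = mode, class = "intensity_matrix")
}

#' Write / read a feature table
#'
#' TSV with feature metadata followed by one intensity column per
#' injection (empty cells = missing).
#'
#' @param im An [to_matrix()] result.
#' @param path Output TSV path.
#' @export
write_feature_table <- function(im, path) {
  d <- cbind(im$features,
             as.data.frame(im$intensities, check.names = FALSE))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
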