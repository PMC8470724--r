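# Two-tier metabolite annotation and within-batch adduct/isotopologue
# grouping.
#
# Panel annotations require both an m/z match (ppm) and a retention-time
# match against the panel's expected RT for the ion mode — high
# confidence. Library annotations match on m/z alone — lower confidence,
# and a feature may collect several.

#' Read a diagnostic panel table
#'
#' TSV columns: `name`, `formula`, `hmdb_id`, `rt_pos`, `rt_neg`
#' (expected RT in minutes per ion mode; empty = not observed in that
#' mode), `adducts` (semicolon-separated adduct names), `max_isotope`.
#' At least one of rt_pos/rt_neg must be present per entry.
#'
#' @param path TSV path.
#' @return data.frame of panel entries with a `neutral_mass` column added.
#' @export
read_panel <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "formula", "hmdb_id", "rt_pos", "rt_neg", "adducts",
            "max_isotope")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("panel table lacks column(s): ", paste(miss, collapse = ", "))
  d$rt_pos <- as.numeric(d$rt_pos); d$rt_neg <- as.numeric(d$rt_neg)
  if (any(is.na(d$rt_pos) & is.na(d$rt_neg)))
    stop("every panel entry needs an expected RT in at least one ion mode")
  d$neutral_mass <- vapply(seq_len(nrow(d)), function(i)
    tryCatch(monoisotopic_mass(d$formula[i]),
             error = function(e) stop("panel entry '", d$name[i], "': ",
                                      conditionMessage(e), call. = FALSE)),
    numeric(1))
  d
}

#' Read a compound library table
#'
#' TSV columns: `id`, `name`, `formula` (an HMDB-style extract). The
#' neutral monoisotopic mass is derived from the formula.
#'
#' @param path TSV path.
#' @return data.frame with `neutral_mass` added.
#' @export
read_library <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("id", "name", "formula"), names(d))
  if (length(miss))
    stop("library table lacks column(s): ", paste(miss, collapse = ", "))
  d$neutral_mass <- vapply(seq_len(nrow(d)), function(i)
    tryCatch(monoisotopic_mass(d$formula[i]),
             error = function(e) stop("library compound '", d$id[i], "': ",
                                      conditionMessage(e), call. = FALSE)),
    numeric(1))
  d
}

#' Ion index for a diagnostic panel
#'
#' One theoretical ion per (panel entry, allowed adduct of the mode,
#' isotope 0..max_isotope), each carrying the entry's expected RT for the
#' mode; entries with no expected RT in the mode are excluded.
#'
#' @param panel A [read_panel()] table.
#' @param mode Ion mode.
#' @param registry Adduct registry.
#' @return data.frame: `compound_id` (= name), `compound_name`, `hmdb_id`,
#'   `adduct`, `isotope`, `mz`, `expected_rt`, sorted by `mz`.
#' @export
panel_ion_index <- function(panel, mode = c("positive", "negative"),
                            registry = default_adducts()) {
  mode <- match.arg(mode)
  rtcol <- if (mode == "positive") "rt_pos" else "rt_neg"
  p <- panel[!is.na(panel[[rtcol]]), , drop = FALSE]
  if (!nrow(p))
    return(data.frame(compound_id = character(0), compound_name = character(0),
                      hmdb_id = character(0), adduct = character(0),
                      isotope = integer(0), mz = numeric(0),
                      expected_rt = numeric(0), stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(p)), function(i) {
    idx <- build_ion_index(
      data.frame(id = p$name[i], name = p$name[i],
                 neutral_mass = p$neutral_mass[i],
                 adducts = p$adducts[i], stringsAsFactors = FALSE),
      max_isotope = p$max_isotope[i], mode = mode, registry = registry)
    if (!nrow(idx)) return(NULL)
    idx$hmdb_id <- p$hmdb_id[i]
    idx$expected_rt <- p[[rtcol]][i]
    idx
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_annotations <- function() {
  data.frame(feature_id = character(0), level = character(0),
             compound = character(0), hmdb_id = character(0),
             adduct = character(0), isotope = integer(0),
             ppm_error = numeric(0), rt_delta = numeric(0),
             stringsAsFactors = FALSE)
}

#' High-confidence panel annotation of aligned features
#'
#' A feature is annotated with a panel ion when BOTH gates hold:
#' `|ppm_error| <= mz_tol` and `|rt - expected_rt| <= rt_tol`. Multiple
#' adducts/isotopologues of one entry may all match; annotations are
#' ranked per feature by `|ppm_error|`, then `isotope`.
#'
#' @param features data.frame with `feature_id`, `mz`, `rt` (e.g.
#'   `aligned$features`).
#' @param panel_index A [panel_ion_index()].
#' @param mz_tol ppm tolerance.
#' @param rt_tol RT tolerance, minutes.
#' @return Annotation data.frame (`level = "panel"`, `rt_delta` = observed
#'   minus expected RT); zero rows when nothing matches.
#' @export
annotate_panel <- function(features, panel_index, mz_tol, rt_tol) {
  out <- lapply(seq_len(nrow(features)), function(i) {
    hits <- match_mz(features$mz[i], panel_index, mz_tol)
    if (!nrow(hits)) return(NULL)
    rt_delta <- features$rt[i] - hits$expected_rt
    keep <- abs(rt_delta) <= rt_tol
    if (!any(keep)) return(NULL)
    hits <- hits[keep, , drop = FALSE]; rt_delta <- rt_delta[keep]
    o <- order(abs(hits$ppm_error), hits$isotope)
    data.frame(feature_id = features$feature_id[i], level = "panel",
               compound = hits$compound_name[o], hmdb_id = hits$hmdb_id[o],
               adduct = hits$adduct[o], isotope = hits$isotope[o],
               ppm_error = hits$ppm_error[o], rt_delta = rt_delta[o],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) res <- .empty_annotations()
  rownames(res) <- NULL
  res
}

#' Lower-confidence m/z-only library annotation
#'
#' All library ions within `mz_tol` ppm of the feature's m/z; no RT gate,
#' so a feature may be associated with one or more compounds. `rt_delta`
#' is `NA` at this level.
#'
#' @param features data.frame with `feature_id`, `mz`.
#' @param library_index A [build_ion_index()] over the library compounds.
#' @param mz_tol ppm tolerance.
#' @return Annotation data.frame (`level = "mz_only"`).
#' @export
annotate_library <- function(features, library_index, mz_tol) {
  out <- lapply(seq_len(nrow(features)), function(i) {
    hits <- match_mz(features$mz[i], library_index, mz_tol)
    if (!nrow(hits)) return(NULL)
    data.frame(feature_id = features$feature_id[i], level = "mz_only",
               compound = hits$compound_name, hmdb_id = NA_character_,
               adduct = hits$adduct, isotope = hits$isotope,
               ppm_error = hits$ppm_error, rt_delta = NA_real_,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) res <- .empty_annotations()
  rownames(res) <- NULL
  res
}

#' Group co-eluting features related by adduct / isotopologue mass deltas
#'
#' Within a window of co-elution, features whose pairwise m/z difference
#' equals a registered delta — the difference of two adduct shifts of the
#' same polarity, or a multiple of the 13C spacing, or a combination —
#' are grouped (connected components). Each group member is assigned the
#' (adduct, isotope) hypothesis that makes the group's inferred neutral
#' masses agree; features with no related partner stay singletons.
#'
#' @param features data.frame `feature_id`, `mz`, `rt` of one ion mode.
#' @param rt_window Co-elution window, minutes.
#' @param mz_tol Delta-matching tolerance, ppm (applied to the feature
#'   m/z).
#' @param mode Ion mode of the features.
#' @param max_isotope Highest isotopologue considered.
#' @param registry Adduct registry.
#' @return data.frame: `feature_id`, `group_id`, `adduct`, `isotope`,
#'   `neutral_mass` (`NA` adduct for unexplained singleton members).
#' @export
group_related_features <- function(features, rt_window, mz_tol,
                                   mode = c("positive", "negative"),
                                   max_isotope = 1L,
                                   registry = default_adducts()) {
  mode <- match.arg(mode)
  reg <- registry[registry$polarity == mode & registry$multiplier == 1 &
                    registry$charge == 1, , drop = FALSE]
  n <- nrow(features)
  if (!n) return(data.frame(feature_id = character(0), group_id = character(0),
                            adduct = character(0), isotope = integer(0),
                            neutral_mass = numeric(0)))
  # hypothesis table: every (adduct, isotope) role a feature could play
  roles <- expand.grid(adduct = reg$name, isotope = 0:max_isotope,
                       stringsAsFactors = FALSE)
  roles$shift <- reg$mass_shift[match(roles$adduct, reg$name)] +
    roles$isotope * mass_constants[["c13_delta"]]

  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  # pairwise: linked if co-eluting and some role pair implies the same neutral
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (abs(features$rt[i] - features$rt[j]) > rt_window) next
    ni <- features$mz[i] - roles$shift
    nj <- features$mz[j] - roles$shift
    d <- outer(ni, nj, "-")
    tol_da <- mz_tol * 1e-6 * max(features$mz[i], features$mz[j])
    if (any(abs(d) <= tol_da & outer(ni > 0, nj > 0, "&"))) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))

  out <- lapply(split(seq_len(n), comp), function(idx) {
    gid <- sprintf("G%04d", min(idx))
    if (length(idx) == 1L)
      return(data.frame(feature_id = features$feature_id[idx], group_id = gid,
                        adduct = NA_character_, isotope = NA_integer_,
                        neutral_mass = NA_real_, stringsAsFactors = FALSE))
    # anchor on the lowest-m/z member; pick the anchor role whose implied
    # neutral mass explains the most members (ties: smallest total |ppm|)
    anchor <- idx[which.min(features$mz[idx])]
    best <- NULL
    for (r in seq_len(nrow(roles))) {
      neutral <- features$mz[anchor] - roles$shift[r]
      if (neutral <= 0) next
      assign_r <- integer(length(idx)); ppm_tot <- 0; nok <- 0L
      for (k in seq_along(idx)) {
        cand_mz <- neutral + roles$shift
        pe <- ppm_error(features$mz[idx[k]], cand_mz)
        hit <- which(abs(pe) <= mz_tol)
        if (length(hit)) {
          h <- hit[which.min(abs(pe[hit]))]
          assign_r[k] <- h; ppm_tot <- ppm_tot + abs(pe[h]); nok <- nok + 1L
        }
      }
      if (is.null(best) || nok > best$nok ||
          (nok == best$nok && ppm_tot < best$ppm_tot))
        best <- list(neutral = neutral, assign = assign_r, nok = nok,
                     ppm_tot = ppm_tot)
    }
    data.frame(
      feature_id = features$feature_id[idx], group_id = gid,
      adduct = ifelse(best$assign > 0, roles$adduct[best$assign],
                      NA_character_),
      isotope = ifelse(best$assign > 0, roles$isotope[best$assign],
                       NA_integer_),
      neutral_mass = ifelse(best$assign > 0,
                            features$mz[idx] - roles$shift[pmax(best$assign, 1L)],
                            NA_real_),
      stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$group_id, res$feature_id), , drop = FALSE]
}

#' Annotate a feature table at both confidence levels
#'
#' Convenience wrapper combining [annotate_panel()] and
#' [annotate_library()] under one tolerance configuration.
#'
#' @param features Feature data.frame (`feature_id`, `mz`, `rt`).
#' @param panel A [read_panel()] table (or `NULL` to skip).
#' @param library A [read_library()] table (or `NULL` to skip).
#' @param config A [session_config()].
#' @param mode Ion mode of the features.
#' @param registry Adduct registry.
#' @return Combined annotation data.frame.
#' @export
annotate_features <- function(features, panel, library, config,
                              mode = c("positive", "negative"),
                              registry = default_adducts()) {
  mode <- match.arg(mode)
  parts <- list()
  if (!is.null(panel)) {
    pidx <- panel_ion_index(panel, mode, registry)
    parts$panel <- annotate_panel(features, pidx,
                                  config$mz_tolerance_ppm,
                                  config$rt_tolerance_min)
  }
  if (!is.null(library)) {
    lidx <- build_ion_index(library, max_isotope = 1L, mode = mode,
                            registry = registry)
    parts$lib <- annotate_library(features, lidx, config$mz_tolerance_ppm)
  }
  res <- do.call(rbind, parts)
  if (is.null(res)) res <- .empty_annotations()
  rownames(res) <- NULL
  res
}
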