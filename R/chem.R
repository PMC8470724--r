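# Elemental-formula mass arithmetic, adduct/isotopologue m/z and ppm matching.

# Monoisotopic atomic masses (Da), most abundant isotope (AME2020/IUPAC).
.MONO_MASS <- c(
  C  = 12.0,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  S  = 31.9720710015,
  P  = 30.9737616320,
  Na = 22.9897692809,
  K  = 38.9637064864,
  Cl = 34.9688527100
)

#' Physical constants for mass-spectrometric m/z arithmetic
#'
#' Monoisotopic masses in Da: the proton (charge carrier of M+H / M-H),
#' the electron (subtracted or added when a pre-charged species such as
#' Na+ attaches), and the 13C-12C mass difference that separates
#' successive carbon isotopologues.
#'
#' @format Named numeric vector with elements `proton`, `electron`,
#'   `c13_delta`.
#' @export
mass_constants <- c(
  proton    = 1.00727646688,
  electron  = 0.00054857990907,
  c13_delta = 1.003354838
)

#' Construct an elemental formula
#'
#' Parses a Hill-style formula string (e.g. `"C21H39NO4"`) or validates a
#' named count vector. Supported elements: C, H, N, O, S, P, Na, K, Cl.
#' Counts must be positive integers; zero counts are dropped, so the empty
#' formula (mass 0) is representable.
#'
#' @param x A formula string or a named integer vector of element counts.
#' @return An object of class `elemental_formula` (named integer vector).
#' @examples
#' elemental_formula("C21H39NO4")   # tetradecenoylcarnitine
#' @export
elemental_formula <- function(x) {
  if (inherits(x, "elemental_formula")) return(x)
  if (is.character(x)) {
    stopifnot(length(x) == 1L)
    counts <- .parse_formula_string(x)
  } else if (is.numeric(x)) {
    if (length(x) && is.null(names(x)))
      stop("formula counts must be a named vector")
    counts <- x
  } else stop("cannot interpret formula of class ", class(x)[1L])

  if (length(counts)) {
    bad <- setdiff(names(counts), names(.MONO_MASS))
    if (length(bad))
      stop("unsupported element symbol(s): ", paste(bad, collapse = ", "))
    if (any(counts < 0) || any(counts != round(counts)))
      stop("element counts must be non-negative integers")
    counts <- counts[counts > 0]
    # merge repeated symbols (e.g. "CH3COOH" style strings)
    counts <- tapply(counts, names(counts), sum)
    counts <- counts[order(names(counts))]
  }
  structure(as.integer(counts), names = names(counts),
            class = "elemental_formula")
}

.parse_formula_string <- function(s) {
  s <- gsub("[[:space:]]", "", s)
  if (!nzchar(s)) return(integer(0))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  tokens <- regmatches(s, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(s))
    stop("cannot parse formula string: ", s)
  sym <- sub("[0-9]*$", "", tokens)
  n <- sub("^[A-Za-z]+", "", tokens)
  counts <- ifelse(nzchar(n), as.integer(n), 1L)
  names(counts) <- sym
  counts
}

#' @export
print.elemental_formula <- function(x, ...) {
  if (!length(x)) cat("<empty formula>\n")
  else cat(paste0(names(x), ifelse(x > 1L, x, "")), sep = "")
  if (length(x)) cat("  (", format(monoisotopic_mass(x), digits = 10),
                     " Da)\n", sep = "")
  invisible(x)
}

#' Merge two elemental formulas
#'
#' Element-wise sum of counts; exact, so mass is additive.
#'
#' @param a,b `elemental_formula` objects (or strings).
#' @return An `elemental_formula`.
#' @export
formula_add <- function(a, b) {
  a <- elemental_formula(a); b <- elemental_formula(b)
  all_el <- union(names(a), names(b))
  counts <- vapply(all_el, function(e) {
    sum(a[names(a) == e], b[names(b) == e])
  }, numeric(1))
  elemental_formula(counts)
}

#' Monoisotopic mass of a formula
#'
#' Sum of count times monoisotopic atomic mass over all elements. The
#' empty formula has mass 0; any non-empty formula has strictly positive
#' mass.
#'
#' @param formula An `elemental_formula`, or a string parsed as one.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("C21H39NO4")  # 369.28791
#' @export
monoisotopic_mass <- function(formula) {
  f <- elemental_formula(formula)
  if (!length(f)) return(0)
  sum(.MONO_MASS[names(f)] * as.numeric(f))
}

#' Default electrospray adduct registry
#'
#' Each row defines how a neutral molecule M maps to an observed ion:
#' `mz = (multiplier * M + mass_shift + k * c13_delta) / charge`.
#' Mass shifts account for the electron: M+H adds a proton; M+Na adds a
#' sodium atom minus an electron; M-H removes a proton; M+Cl adds a
#' chlorine atom plus an electron.
#'
#' @return data.frame with columns `name`, `polarity`, `charge`,
#'   `mass_shift`, `multiplier`.
#' @export
default_adducts <- function() {
  e <- mass_constants[["electron"]]
  data.frame(
    name = c("M+H", "M+Na", "M+K", "M+NH4", "M-H", "M+Cl"),
    polarity = c("positive", "positive", "positive", "positive",
                 "negative", "negative"),
    charge = 1L,
    mass_shift = c(
      mass_constants[["proton"]],
      .MONO_MASS[["Na"]] - e,
      .MONO_MASS[["K"]] - e,
      monoisotopic_mass("NH4") - e,
      -mass_constants[["proton"]],
      .MONO_MASS[["Cl"]] + e
    ),
    multiplier = 1L,
    stringsAsFactors = FALSE
  )
}

#' Read an adduct registry from TSV
#'
#' Columns: name, polarity (positive|negative), charge (>= 1),
#' mass_shift (Da, signed), multiplier (>= 1, optional, default 1).
#'
#' @param path Path to a tab-separated file.
#' @return data.frame in the layout of [default_adducts()].
#' @export
read_adducts <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "polarity", "charge", "mass_shift")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("adduct table lacks column(s): ", paste(miss, collapse = ", "))
  if (is.null(d$multiplier)) d$multiplier <- 1L
  d$polarity <- match.arg(tolower(d$polarity),
                          c("positive", "negative"), several.ok = TRUE)
  if (any(d$charge < 1) || any(d$multiplier < 1))
    stop("adduct charge and multiplier must be >= 1")
  d[c("name", "polarity", "charge", "mass_shift", "multiplier")]
}

.get_adduct <- function(adduct, registry = default_adducts()) {
  if (is.data.frame(adduct)) {
    stopifnot(nrow(adduct) == 1L)
    return(adduct)
  }
  i <- match(adduct, registry$name)
  if (is.na(i)) stop("unknown adduct: ", adduct)
  registry[i, , drop = FALSE]
}

#' m/z of an adduct ion, optionally 13C-substituted
#'
#' `mz = (multiplier * M + mass_shift + isotope_index * 1.0033548) / charge`
#' where `isotope_index` counts 13C substitutions (0 = monoisotopic peak).
#'
#' @param neutral_mass Neutral monoisotopic mass M in Da (> 0).
#' @param adduct Adduct name looked up in `registry`, or a one-row
#'   adduct data.frame.
#' @param isotope_index Number of 13C substitutions (>= 0). Vectorized.
#' @param registry Adduct registry, see [default_adducts()].
#' @return m/z value(s).
#' @examples
#' ion_mz(monoisotopic_mass("C21H39NO4"), "M+H")  # 370.295
#' @export
ion_mz <- function(neutral_mass, adduct, isotope_index = 0L,
                   registry = default_adducts()) {
  if (any(neutral_mass <= 0)) stop("neutral_mass must be > 0")
  if (any(isotope_index < 0)) stop("isotope_index must be >= 0")
  a <- .get_adduct(adduct, registry)
  (a$multiplier * neutral_mass + a$mass_shift +
     isotope_index * mass_constants[["c13_delta"]]) / a$charge
}

#' Signed relative mass error in parts per million
#'
#' @param observed,theoretical m/z values; `theoretical` must be > 0.
#' @return `(observed - theoretical) / theoretical * 1e6`. Vectorized.
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be > 0")
  (observed - theoretical) / theoretical * 1e6
}

#' Match an observed m/z against a sorted ion index
#'
#' Returns every ion whose theoretical m/z lies within `tolerance` ppm of
#' `observed`, ordered by absolute ppm error (ties: ascending m/z, then
#' index order). Uses a binary-search window over the m/z-sorted index.
#'
#' @param observed A single observed m/z.
#' @param ions data.frame with at least an `mz` column (e.g. from
#'   [build_ion_index()]); need not be pre-sorted.
#' @param tolerance Matching tolerance in ppm (> 0).
#' @return The matching rows of `ions` with a `ppm_error` column appended;
#'   zero rows when nothing matches.
#' @export
match_mz <- function(observed, ions, tolerance) {
  stopifnot(length(observed) == 1L, tolerance > 0)
  if (!nrow(ions)) return(cbind(ions, ppm_error = numeric(0)))
  ord <- order(ions$mz)
  mz <- ions$mz[ord]
  lo <- observed / (1 + tolerance * 1e-6)
  hi <- observed / (1 - tolerance * 1e-6)
  i0 <- findInterval(lo, mz, left.open = TRUE) + 1L
  i1 <- findInterval(hi, mz)
  if (i0 > i1) return(cbind(ions[0, , drop = FALSE], ppm_error = numeric(0)))
  idx <- ord[i0:i1]
  pe <- ppm_error(observed, ions$mz[idx])
  keep <- abs(pe) <= tolerance
  idx <- idx[keep]; pe <- pe[keep]
  o <- order(abs(pe), ions$mz[idx], idx)
  out <- ions[idx[o], , drop = FALSE]
  out$ppm_error <- pe[o]
  rownames(out) <- NULL
  out
}

#' Theoretical ion index for a compound set
#'
#' One row per (compound, adduct, isotope 0..max_isotope) for adducts of
#' the requested polarity, sorted by m/z. Isotopologues are successive
#' 13C substitutions of the same adduct ion.
#'
#' @param compounds data.frame with columns `id`, `name`, `formula`
#'   (string) or a precomputed `neutral_mass`; an optional `adducts`
#'   column (semicolon-separated names) restricts per-compound adducts.
#' @param adducts Adduct names to use when a compound does not restrict
#'   them; defaults to all registry adducts of the given mode.
#' @param max_isotope Highest 13C isotopologue generated (>= 0).
#' @param mode `"positive"` or `"negative"`.
#' @param registry Adduct registry.
#' @return data.frame: `compound_id`, `compound_name`, `adduct`,
#'   `isotope`, `mz`, sorted ascending by `mz`.
#' @export
build_ion_index <- function(compounds, adducts = NULL, max_isotope = 1L,
                            mode = c("positive", "negative"),
                            registry = default_adducts()) {
  mode <- match.arg(mode)
  if (!nrow(compounds)) stop("compound list is empty")
  reg <- registry[registry$polarity == mode, , drop = FALSE]
  if (is.null(adducts)) adducts <- reg$name

  masses <- if (!is.null(compounds$neutral_mass)) compounds$neutral_mass else
    vapply(seq_len(nrow(compounds)), function(i) {
      tryCatch(monoisotopic_mass(compounds$formula[i]),
               error = function(e) stop("compound '", compounds$id[i], "': ",
                                        conditionMessage(e), call. = FALSE))
    }, numeric(1))

  rows <- vector("list", nrow(compounds))
  for (i in seq_len(nrow(compounds))) {
    want <- adducts
    if (!is.null(compounds$adducts) && nzchar(compounds$adducts[i]))
      want <- strsplit(compounds$adducts[i], ";", fixed = TRUE)[[1]]
    want <- intersect(trimws(want), reg$name)
    if (!length(want)) next
    grid <- expand.grid(adduct = want, isotope = 0:max_isotope,
                        stringsAsFactors = FALSE)
    grid$mz <- vapply(seq_len(nrow(grid)), function(k) {
      ion_mz(masses[i], grid$adduct[k], grid$isotope[k], registry = reg)
    }, numeric(1))
    rows[[i]] <- data.frame(
      compound_id = compounds$id[i],
      compound_name = if (!is.null(compounds$name)) compounds$name[i]
        else compounds$id[i],
      adduct = grid$adduct, isotope = grid$isotope, mz = grid$mz,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(compound_id = character(0), compound_name = character(0),
                      adduct = character(0), isotope = integer(0),
                      mz = numeric(0), stringsAsFactors = FALSE)
  out <- out[order(out$mz, out$compound_id, out$adduct, out$isotope), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
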