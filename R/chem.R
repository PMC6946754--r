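# Elemental formulas, monoisotopic cation masses, sum-formula annotation.

#' Monoisotopic atomic masses (u)
#'
#' CODATA/IUPAC monoisotopic masses of the light elements relevant to
#' proton-transfer-reaction VOC ions, plus selected heavy isotopes used as
#' internal calibrants. Isotopes are addressed with a bracketed mass-number
#' prefix, e.g. `"[18O]"`.
#'
#' @format Named numeric vector, masses in unified atomic mass units.
#' @export
atomic_masses <- c(
  "H"     = 1.0078250319,
  "C"     = 12.0,
  "N"     = 14.0030740052,
  "O"     = 15.9949146221,
  "S"     = 31.97207069,
  "[2H]"  = 2.0141017780,
  "[13C]" = 13.0033548378,
  "[15N]" = 15.0001088984,
  "[18O]" = 17.9991604
)

#' Electron mass in unified atomic mass units
#' @export
electron_mass <- 0.000548579909

#' Construct an ion formula
#'
#' An `ion_formula` is a named vector of non-negative element counts plus an
#' integer charge. All ions in PTR-ToF-MS headspace work are singly protonated
#' cations (charge +1), but the charge is kept explicit.
#'
#' @param counts named integer vector, element (or `[isotope]`) -> count.
#' @param charge integer charge; must be non-zero to have a defined m/z.
#' @return An object of class `ion_formula`.
#' @examples
#' ion_formula(c(C = 5, H = 9), charge = 1)  # protonated isoprene
#' @export
ion_formula <- function(counts, charge = 1L) {
  if (length(counts) == 0 || sum(counts) <= 0)
    stop("an ion formula needs at least one atom")
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("`counts` must be a named vector (element -> count)")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("element counts must be non-negative integers")
  unknown <- setdiff(names(counts), names(atomic_masses))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  counts <- counts[counts > 0]
  structure(list(counts = counts, charge = as.integer(charge)),
            class = "ion_formula")
}

#' Parse a formula string in Hill notation with trailing charge sign
#'
#' Accepts strings such as `"C5H9O+"`, `"H3[18O]+"` or `"C10H17+"`: element
#' symbols with optional counts in Hill order, bracketed isotopes allowed,
#' ending in `+` or `-` (absence means a neutral, charge 0).
#'
#' @param x formula string.
#' @return An `ion_formula`.
#' @export
parse_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1L, nzchar(x))
  s <- gsub("\\s", "", x)
  charge <- 0L
  if (grepl("[+-]$", s)) {
    charge <- if (endsWith(s, "+")) 1L else -1L
    s <- substr(s, 1L, nchar(s) - 1L)
  }
  m <- gregexpr("(\\[[0-9]+[A-Z][a-z]?\\]|[A-Z][a-z]?)([0-9]*)", s)[[1]]
  if (m[1] == -1L || sum(attr(m, "match.length")) != nchar(s))
    stop("cannot parse formula string: ", x)
  toks <- regmatches(s, list(m))[[1]]
  el <- sub("^(\\[[0-9]+[A-Z][a-z]?\\]|[A-Z][a-z]?)[0-9]*$", "\\1", toks)
  nn <- sub("^(\\[[0-9]+[A-Z][a-z]?\\]|[A-Z][a-z]?)([0-9]*)$", "\\2", toks)
  cnt <- ifelse(nzchar(nn), as.integer(nn), 1L)
  counts <- tapply(cnt, el, sum)
  ion_formula(stats::setNames(as.integer(counts), names(counts)), charge = charge)
}

#' Serialize an ion formula to Hill notation
#'
#' Carbon first, then hydrogen, then the remaining elements alphabetically;
#' trailing `+`/`-` for charged species.
#'
#' @param f an `ion_formula`.
#' @return Character scalar, e.g. `"C5H9O+"`.
#' @export
format_formula <- function(f) {
  stopifnot(inherits(f, "ion_formula"))
  counts <- f$counts
  els <- names(counts)
  hill <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  body <- paste0(vapply(hill, function(e) {
    n <- counts[[e]]
    paste0(e, if (n > 1L) n else "")
  }, character(1)), collapse = "")
  sign <- if (f$charge > 0) strrep("+", f$charge)
          else if (f$charge < 0) strrep("-", -f$charge) else ""
  paste0(body, sign)
}

#' @export
print.ion_formula <- function(x, ...) {
  cat("<ion_formula> ", format_formula(x), "\n", sep = "")
  invisible(x)
}

#' Theoretical m/z of an ion from monoisotopic masses
#'
#' Sums the monoisotopic masses of the constituent atoms, subtracts one
#' electron mass per unit of positive charge (adds for negative), and divides
#' by |z|. The electron-mass term matters at the 4th decimal for the light
#' cations measured here.
#'
#' @param formula an `ion_formula` or a formula string (`"C5H9O+"`).
#' @return m/z in Th.
#' @examples
#' monoisotopic_mz("C5H9O+")  # 85.0648
#' @export
monoisotopic_mz <- function(formula) {
  f <- if (inherits(formula, "ion_formula")) formula else parse_formula(formula)
  if (f$charge == 0L)
    stop("zero charge: m/z undefined for a neutral")
  mass <- sum(atomic_masses[names(f$counts)] * f$counts) -
    f$charge * electron_mass
  mass / abs(f$charge)
}

#' Ring and double bond equivalents of a formula
#'
#' RDBE = C + 1 + (N - H)/2, computed on the ion's atom counts (the protonated
#' species then lands on half-integer values; only used as a plausibility
#' filter with threshold >= 0).
#' @param f an `ion_formula`.
#' @return Numeric RDBE.
#' @export
rdbe <- function(f) {
  stopifnot(inherits(f, "ion_formula"))
  cnt <- function(e) if (e %in% names(f$counts)) f$counts[[e]] else 0L
  cnt("C") + 1 + (cnt("N") - cnt("H")) / 2
}

#' Annotate an observed m/z with candidate sum formulas
#'
#' Exhaustively enumerates singly charged cation formulas over a bounded
#' element lattice and returns all candidates whose theoretical m/z lies
#' within `tolerance` of the observed value, sorted by |observed -
#' theoretical| ascending; ties broken by fewer heteroatoms (non-C, non-H),
#' then lexicographically by Hill string. The internal mass accuracy of the
#' calibrated ToF axis (~1 mTh) is what makes this assignment unambiguous in
#' practice for small VOC ions.
#'
#' @param observed_mz observed m/z in Th.
#' @param tolerance match tolerance in Th (> 0).
#' @param element_bounds named integer vector of maximum element counts;
#'   default `c(C = 10, H = 20, O = 3, N = 2)`.
#' @param rdbe_filter if `TRUE`, drop candidates with RDBE < 0 (off by
#'   default; no such filter is applied in routine processing).
#' @return A data.frame with columns `formula` (Hill string),
#'   `theoretical_mz`, `delta_mz` (observed - theoretical); zero rows if
#'   nothing matches.
#' @examples
#' annotate_mz(69.0699, 0.005)           # C5H9+ first
#' annotate_mz(137.1328, 0.005)          # contains C10H17+
#' @export
annotate_mz <- function(observed_mz, tolerance,
                        element_bounds = c(C = 10, H = 20, O = 3, N = 2),
                        rdbe_filter = FALSE) {
  stopifnot(is.numeric(observed_mz), length(observed_mz) == 1L)
  if (!is.numeric(tolerance) || length(tolerance) != 1L || tolerance <= 0)
    stop("`tolerance` must be a positive scalar (Th)")
  if (any(!is.finite(element_bounds)) || any(element_bounds < 0))
    stop("element bounds must be finite and non-negative")
  unknown <- setdiff(names(element_bounds), names(atomic_masses))
  if (length(unknown))
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))

  els <- names(element_bounds)
  grid <- do.call(expand.grid, lapply(element_bounds, function(b) 0:b))
  grid <- grid[rowSums(grid) > 0, , drop = FALSE]
  mz <- as.matrix(grid) %*% atomic_masses[els] - electron_mass
  keep <- abs(mz - observed_mz) <= tolerance
  grid <- grid[keep, , drop = FALSE]
  mz <- mz[keep]
  if (!nrow(grid))
    return(data.frame(formula = character(), theoretical_mz = numeric(),
                      delta_mz = numeric(), stringsAsFactors = FALSE))

  forms <- lapply(seq_len(nrow(grid)), function(i) {
    cc <- as.integer(grid[i, ])
    names(cc) <- els
    ion_formula(cc[cc > 0], charge = 1L)
  })
  if (rdbe_filter) {
    ok <- vapply(forms, rdbe, numeric(1)) >= 0
    forms <- forms[ok]; mz <- mz[ok]
    if (!length(forms))
      return(data.frame(formula = character(), theoretical_mz = numeric(),
                        delta_mz = numeric(), stringsAsFactors = FALSE))
  }
  hill <- vapply(forms, format_formula, character(1))
  hetero <- vapply(forms, function(f)
    sum(f$counts[setdiff(names(f$counts), c("C", "H"))]), numeric(1))
  delta <- observed_mz - mz
  ord <- order(abs(delta), hetero, hill)
  data.frame(formula = hill[ord],
             theoretical_mz = as.numeric(mz)[ord],
             delta_mz = as.numeric(delta)[ord],
             stringsAsFactors = FALSE)
}

#' m/z of the H3O+ primary ion and of its 18-O isotopologue
#'
#' The hydronium primary ion saturates the detector at typical source
#' settings, so quantification conventionally measures the rare H3(18O)+
#' isotopologue at 21.0221 Th and scales by the isotope ratio.
#' @name primary-ion-mz
#' @export
mz_h3o <- function() monoisotopic_mz("H3O+")

#' @rdname primary-ion-mz
#' @export
mz_h3o18 <- function() monoisotopic_mz("H3[18O]+")
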