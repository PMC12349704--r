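# Package-local cache for the element tables.
.macromet_env <- new.env(parent = emptyenv())

#' Mass of a proton in Da
#'
#' Used for charge-state m/z arithmetic; the electron mass is neglected.
#' @export
PROTON_MASS <- 1.007276466

#' Element isotope and atomic-weight tables
#'
#' Returns the pinned element table shipped with the package: per element,
#' the isotope masses (Da) with their natural abundances, plus the standard
#' atomic weight used for average-mass computation. Isotope masses and
#' abundances follow the NIST compilation; standard atomic weights are
#' pinned to the 2005 IUPAC values so that average molecular weights of
#' reference peptides reproduce published two-decimal values.
#'
#' @return A list with components `isotopes` (data.frame with columns
#'   `element`, `mass`, `abundance`, sorted by mass within element) and
#'   `weights` (named numeric vector of standard atomic weights).
#' @export
element_table <- function() {
  if (is.null(.macromet_env$elements)) {
    iso <- utils::read.delim(
      system.file("extdata", "isotopes.tsv", package = "macromet"),
      stringsAsFactors = FALSE
    )
    iso <- iso[order(iso$element, iso$mass), ]
    # abundances must be normalized per element
    for (el in unique(iso$element)) {
      sel <- iso$element == el
      tot <- sum(iso$abundance[sel])
      stopifnot(abs(tot - 1) < 1e-6)
      iso$abundance[sel] <- iso$abundance[sel] / tot
    }
    wt <- utils::read.delim(
      system.file("extdata", "atomic_weights.tsv", package = "macromet"),
      stringsAsFactors = FALSE
    )
    weights <- stats::setNames(wt$weight, wt$element)
    .macromet_env$elements <- list(isotopes = iso, weights = weights)
  }
  .macromet_env$elements
}

#' Construct an elemental composition
#'
#' An elemental composition is a multiset of element symbols with strictly
#' positive integer counts, stored as a named integer vector of class
#' `"elemcomp"`. Zero counts are dropped; the empty composition is allowed
#' and has all masses equal to zero.
#'
#' @param ... Named integer counts, e.g. `comp(C = 2, H = 3, N = 1, O = 1)`.
#' @return An `elemcomp` object.
#' @examples
#' comp(H = 2, O = 1)
#' @export
comp <- function(...) {
  x <- c(...)
  if (length(x) == 0) return(structure(integer(0), class = "elemcomp"))
  if (is.null(names(x)) || any(names(x) == ""))
    stop("all counts must be named by element symbol")
  if (any(x < 0)) stop("negative element counts are not allowed")
  if (any(x != round(x))) stop("element counts must be integers")
  x <- x[x > 0]
  x <- tapply(as.integer(x), names(x), sum)
  structure(as.integer(x), names = names(x), class = "elemcomp")
}

as_comp <- function(x) {
  if (inherits(x, "elemcomp")) return(x)
  do.call(comp, as.list(x))
}

#' @export
print.elemcomp <- function(x, ...) {
  cat("<elemcomp> ", format_formula(x), "\n", sep = "")
  invisible(x)
}

#' Add two elemental compositions
#' @param e1,e2 `elemcomp` objects.
#' @export
"+.elemcomp" <- function(e1, e2) {
  els <- union(names(e1), names(e2))
  out <- stats::setNames(integer(length(els)), els)
  out[names(e1)] <- out[names(e1)] + unclass(e1)
  out[names(e2)] <- out[names(e2)] + unclass(e2)
  do.call(comp, as.list(out))
}

#' Subtract elemental compositions
#'
#' Errors if any resulting count would be negative: composition subtraction
#' is only defined when the right operand is contained in the left.
#' @param e1,e2 `elemcomp` objects.
#' @export
"-.elemcomp" <- function(e1, e2) {
  els <- union(names(e1), names(e2))
  out <- stats::setNames(integer(length(els)), els)
  out[names(e1)] <- out[names(e1)] + unclass(e1)
  out[names(e2)] <- out[names(e2)] - unclass(e2)
  if (any(out < 0))
    stop("composition subtraction would yield negative counts for: ",
         paste(names(out)[out < 0], collapse = ", "))
  do.call(comp, as.list(out))
}

#' Multiply a composition by a non-negative integer
#' @param x An `elemcomp`.
#' @param n Non-negative integer.
#' @export
comp_times <- function(x, n) {
  stopifnot(n >= 0, n == round(n))
  if (n == 0 || length(x) == 0) return(comp())
  do.call(comp, as.list(unclass(x) * as.integer(n)))
}

#' Parse a molecular formula string
#'
#' Accepts plain Hill notation (`"C76H104N18O19S2"`) as well as the
#' underscore-subscript dialect used in some publication tables
#' (`"C_76_H_104_N_18_O_19_S_2_"`). An omitted count means 1; an explicit
#' zero count is an error.
#'
#' @param text Formula string.
#' @return An `elemcomp`.
#' @examples
#' parse_formula("C76H104N18O19S2")
#' parse_formula("H2O")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  s <- gsub("_", "", trimws(text))
  if (!nzchar(s)) stop("empty formula string")
  if (!grepl("^([A-Z][a-z]?[0-9]*)+$", s))
    stop("malformed formula: ", text)
  m <- gregexpr("[A-Z][a-z]?[0-9]*", s)[[1]]
  toks <- regmatches(s, list(m))[[1]]
  known <- unique(element_table()$isotopes$element)
  counts <- list()
  for (tk in toks) {
    el <- sub("[0-9]*$", "", tk)
    ns <- sub("^[A-Za-z]+", "", tk)
    n <- if (nzchar(ns)) as.integer(ns) else 1L
    if (!el %in% known) stop("unknown element symbol: ", el)
    if (n == 0) stop("zero count not allowed for element ", el)
    counts[[el]] <- (if (is.null(counts[[el]])) 0L else counts[[el]]) + n
  }
  do.call(comp, counts)
}

#' Format a composition as a Hill-order formula string
#'
#' Carbon first, then hydrogen, then the remaining elements alphabetically
#' (plain alphabetical when no carbon is present).
#'
#' @param x An `elemcomp`.
#' @return A single string; `""` for the empty composition.
#' @export
format_formula <- function(x) {
  x <- as_comp(x)
  if (length(x) == 0) return("")
  els <- names(x)
  if ("C" %in% els) {
    ord <- c(intersect(c("C", "H"), els), sort(setdiff(els, c("C", "H"))))
  } else {
    ord <- sort(els)
  }
  paste0(ord, ifelse(unclass(x)[ord] > 1, unclass(x)[ord], ""), collapse = "")
}

#' Monoisotopic mass
#'
#' Sum over elements of count times the lightest-isotope mass, following
#' the convention that the monoisotopic species contains only the lightest
#' isotope of every element.
#'
#' @param x An `elemcomp` (or coercible named vector).
#' @return Mass in Da; 0 for the empty composition.
#' @examples
#' monoisotopic_mass(parse_formula("C76H104N18O19S2")) # 1636.7167
#' @export
monoisotopic_mass <- function(x) {
  x <- as_comp(x)
  if (length(x) == 0) return(0)
  iso <- element_table()$isotopes
  lightest <- tapply(iso$mass, iso$element, min)
  missing <- setdiff(names(x), names(lightest))
  if (length(missing))
    stop("element(s) missing from isotope table: ", paste(missing, collapse = ", "))
  sum(unclass(x) * lightest[names(x)])
}

#' Average (standard atomic weight) mass
#'
#' @param x An `elemcomp`.
#' @return Mass in Da computed with the pinned standard atomic weights.
#' @export
average_mass <- function(x) {
  x <- as_comp(x)
  if (length(x) == 0) return(0)
  w <- element_table()$weights
  missing <- setdiff(names(x), names(w))
  if (length(missing))
    stop("element(s) missing from atomic-weight table: ", paste(missing, collapse = ", "))
  sum(unclass(x) * w[names(x)])
}

# Per-element aggregated isotope distribution for a single atom:
# list(k = integer nominal shifts, ab = abundances, m = mean mass per bin).
.atom_dist <- function(el) {
  iso <- element_table()$isotopes
  rows <- iso[iso$element == el, ]
  if (nrow(rows) == 0) stop("element missing from isotope table: ", el)
  k <- as.integer(round(rows$mass - rows$mass[1]))
  ab <- tapply(rows$abundance, k, sum)
  msum <- tapply(rows$abundance * rows$mass, k, sum)
  kk <- as.integer(names(ab))
  list(k = kk, ab = as.numeric(ab), m = as.numeric(msum / ab))
}

# Convolve two aggregated distributions, pruning bins below `prune`.
.conv_dist <- function(a, b, prune) {
  ab <- outer(a$ab, b$ab)
  kk <- outer(a$k, b$k, "+")
  mm <- outer(a$m, b$m, "+")
  tot <- tapply(as.vector(ab), as.vector(kk), sum)
  msum <- tapply(as.vector(ab * mm), as.vector(kk), sum)
  k <- as.integer(names(tot))
  keep <- as.numeric(tot) > prune
  if (!any(keep)) keep[which.max(tot)] <- TRUE
  list(k = k[keep], ab = as.numeric(tot)[keep], m = as.numeric(msum)[keep] / as.numeric(tot)[keep])
}

# n-fold self-convolution by exponentiation-by-squaring.
.power_dist <- function(d, n, prune) {
  res <- NULL
  while (n > 0) {
    if (n %% 2 == 1) res <- if (is.null(res)) d else .conv_dist(res, d, prune)
    n <- n %/% 2
    if (n > 0) d <- .conv_dist(d, d, prune)
  }
  res
}

#' Aggregated isotope pattern of a composition
#'
#' Computes the isotopologue distribution aggregated by nominal mass shift
#' (M0, M+1, M+2, ...). Each aggregated peak carries the abundance-weighted
#' mean mass of the isotopologues falling into that nominal bin, which is
#' what a high-resolution (but not fine-structure resolving) instrument
#' observes for peptide-sized molecules. Computation is a per-element
#' multinomial expansion convolved element by element, with bins below the
#' pruning threshold dropped and abundances renormalized to sum to one.
#'
#' @param x An `elemcomp`; must be non-empty.
#' @param prune Absolute abundance pruning threshold in (0, 1e-3].
#' @return A data.frame of class `"isopattern"` with columns `k` (nominal
#'   shift index), `mass` (Da) and `abundance` (fractions summing to 1).
#' @examples
#' isotope_pattern(parse_formula("C6H12O6"))
#' @export
isotope_pattern <- function(x, prune = 1e-10) {
  x <- as_comp(x)
  if (length(x) == 0) stop("isotope pattern of an empty composition is undefined")
  stopifnot(prune > 0, prune <= 1e-3)
  d <- NULL
  for (el in names(x)) {
    de <- .power_dist(.atom_dist(el), unclass(x)[[el]], prune)
    d <- if (is.null(d)) de else .conv_dist(d, de, prune)
  }
  ord <- order(d$k)
  ab <- d$ab[ord] / sum(d$ab)
  out <- data.frame(k = d$k[ord], mass = d$m[ord], abundance = ab)
  class(out) <- c("isopattern", "data.frame")
  out
}

#' Most abundant mass (MaM)
#'
#' Mass of the highest-abundance aggregated isotopologue peak. For small
#' molecules this equals the monoisotopic mass; with growing size (mainly
#' through carbon count) the most abundant peak moves to higher nominal
#' shifts, which is the rationale for MaM-based peak targeting in
#' macromolecule MetID.
#'
#' @param x An `elemcomp`.
#' @param prune Pruning threshold passed to [isotope_pattern()].
#' @return Mass in Da; ties between bins are broken toward the lower shift.
#' @export
most_abundant_mass <- function(x, prune = 1e-10) {
  p <- isotope_pattern(x, prune)
  # which.max already prefers the first (lowest-k) bin on exact ties
  p$mass[which.max(p$abundance)]
}

#' m/z for a charge state
#'
#' @param neutral_mass Neutral mass in Da.
#' @param z Charge magnitude, a positive integer.
#' @param polarity `"+"` (protonation) or `"-"` (deprotonation).
#' @return The m/z value `(M ± z * 1.007276466) / z`.
#' @examples
#' mz_for_charge(1000, 2) # 501.007276
#' @export
mz_for_charge <- function(neutral_mass, z, polarity = c("+", "-")) {
  polarity <- match.arg(polarity)
  if (any(z < 1) || any(z != round(z))) stop("charge z must be a positive integer")
  sgn <- if (polarity == "+") 1 else -1
  (neutral_mass + sgn * z * PROTON_MASS) / z
}
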