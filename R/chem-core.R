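# Molecular-formula arithmetic, adduct m/z, theoretical isotope envelopes and
# the two scalar peak-quality scores every screening decision consumes.

.oeno_env <- new.env(parent = emptyenv())

#' Element isotope table
#'
#' Monoisotopic masses and isotope abundances (CODATA/IUPAC values) for the
#' elements supported by the formula arithmetic (C, H, N, O, S, P), pinned to
#' a constants table shipped with the package so results are bit-stable.
#'
#' @return A data frame with columns `element`, `shift` (nominal mass shift
#'   relative to the most abundant isotope), `mass` (Da) and `abundance`
#'   (fraction, renormalized per element).
#' @export
isotope_table <- function() {
  if (is.null(.oeno_env$isotopes)) {
    path <- system.file("extdata", "isotope_abundances.tsv",
                        package = "oenoscreen", mustWork = TRUE)
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    # renormalize abundances so each element sums to exactly 1
    for (el in unique(tab$element)) {
      i <- tab$element == el
      tab$abundance[i] <- tab$abundance[i] / sum(tab$abundance[i])
    }
    .oeno_env$isotopes <- tab
  }
  .oeno_env$isotopes
}

# proton mass used for electrospray adduct arithmetic (Da)
PROTON_MASS <- 1.007276466

# supported negative-mode adducts: name, neutral-mass offset (Da), charge.
# [M-2H]- covers flavylium cations (anthocyanins) losing two protons; electron
# bookkeeping is folded into the proton constant.
.adduct_table <- data.frame(
  name   = c("[M-H]-", "[M-2H]-", "[M+H2O-H]-"),
  delta  = c(-PROTON_MASS, -2 * PROTON_MASS, 18.0105646863 - PROTON_MASS),
  charge = c(-1L, -1L, -1L),
  stringsAsFactors = FALSE
)

#' Supported adducts
#'
#' @return Data frame of supported negative-mode adducts with their neutral
#'   mass offsets (Da) and charges.
#' @export
adduct_table <- function() .adduct_table

#' Parse a molecular formula
#'
#' @param formula Character scalar such as `"C15H14O6"`.  Only elements with
#'   tabulated isotope data (C, H, N, O, S, P) are allowed.
#' @return Named integer vector of element counts.
#' @export
parse_formula <- function(formula) {
  stopifnot(is.character(formula), length(formula) == 1L, nzchar(formula))
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, list(m))[[1]]
  parts <- parts[nzchar(parts)]
  if (!identical(paste(parts, collapse = ""), formula)) {
    stop("cannot parse molecular formula: ", formula)
  }
  els <- sub("[0-9]*$", "", parts)
  cnt <- as.integer(ifelse(grepl("[0-9]+$", parts),
                           sub("^[A-Za-z]+", "", parts), "1"))
  known <- unique(isotope_table()$element)
  bad <- setdiff(els, known)
  if (length(bad)) {
    stop("unknown element symbol(s) in formula: ", paste(bad, collapse = ", "))
  }
  counts <- tapply(cnt, els, sum)
  out <- as.integer(counts)
  names(out) <- names(counts)
  if (any(out <= 0L)) stop("element counts must be positive")
  out
}

#' Monoisotopic mass of a molecular formula
#'
#' @param formula Character formula (e.g. `"C15H14O6"`) or a named count
#'   vector from [parse_formula()].
#' @return Monoisotopic (principal-isotope) mass in Da.
#' @examples
#' monoisotopic_mass("C15H14O6")  # catechin, 290.0790
#' @export
monoisotopic_mass <- function(formula) {
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  iso <- isotope_table()
  mono <- iso[iso$shift == 0, ]
  mass <- mono$mass[match(names(counts), mono$element)]
  if (anyNA(mass)) stop("unknown element symbol")
  sum(mass * counts)
}

#' m/z of a negative-mode adduct ion
#'
#' @param formula Molecular formula (character or parsed counts).
#' @param adduct One of `"[M-H]-"`, `"[M-2H]-"`, `"[M+H2O-H]-"`.
#' @return The ion m/z in Da: (monoisotopic mass + offset) / |charge|.
#' @examples
#' adduct_mz("C30H26O12", "[M-H]-")  # procyanidin dimer, 577.1352
#' @export
adduct_mz <- function(formula, adduct = "[M-H]-") {
  i <- match(adduct, .adduct_table$name)
  if (is.na(i)) {
    stop("unsupported adduct '", adduct, "'; supported: ",
         paste(.adduct_table$name, collapse = ", "))
  }
  (monoisotopic_mass(formula) + .adduct_table$delta[i]) /
    abs(.adduct_table$charge[i])
}

#' Signed mass error in mDa
#'
#' @param observed_mz,theoretical_mz Positive m/z values (Da).
#' @return `(observed - theoretical) * 1000`, in mDa (signed).
#' @export
mass_error_mda <- function(observed_mz, theoretical_mz) {
  stopifnot(all(observed_mz > 0), all(theoretical_mz > 0))
  (observed_mz - theoretical_mz) * 1000
}

# distribution of aggregate nominal mass shifts for `n` atoms of one element
.element_shift_poly <- function(element, n, n_peaks) {
  iso <- isotope_table()
  sub <- iso[iso$element == element, ]
  base <- numeric(n_peaks)
  base[sub$shift + 1L] <- sub$abundance
  out <- c(1, numeric(n_peaks - 1L))  # identity polynomial
  for (k in seq_len(n)) {             # truncated convolution power
    acc <- numeric(n_peaks)
    for (j in seq_len(n_peaks)) {
      if (out[j] == 0) next
      top <- n_peaks - j + 1L
      acc[j:n_peaks] <- acc[j:n_peaks] + out[j] * base[1:top]
    }
    out <- acc
  }
  out
}

#' Theoretical isotope pattern of a formula
#'
#' Aggregates isotopologues by nominal mass shift (A, A+1, A+2, ...) rather
#' than fine structure, matching QToF resolving power, and normalizes to the
#' base peak.
#'
#' @param formula Molecular formula (character or parsed counts).
#' @param n_peaks Number of isotope clusters to return (>= 2).
#' @return An `isotope_pattern`: list with `offset` (Da from the monoisotopic
#'   peak, one nominal spacing per cluster) and `intensity` (relative to the
#'   base peak, base peak = 1).
#' @export
theoretical_isotope_pattern <- function(formula, n_peaks = 3L) {
  if (n_peaks < 2L) stop("n_peaks must be >= 2")
  key <- NULL
  if (is.character(formula)) {
    key <- paste0(formula, "#", n_peaks)
    hit <- .oeno_env$pattern_cache[[key]]
    if (!is.null(hit)) return(hit)
  }
  counts <- if (is.character(formula)) parse_formula(formula) else formula
  p <- c(1, numeric(n_peaks - 1L))
  for (el in names(counts)) {
    q <- .element_shift_poly(el, counts[[el]], n_peaks)
    acc <- numeric(n_peaks)
    for (j in seq_len(n_peaks)) {
      if (p[j] == 0) next
      top <- n_peaks - j + 1L
      acc[j:n_peaks] <- acc[j:n_peaks] + p[j] * q[1:top]
    }
    p <- acc
  }
  out <- isotope_pattern(offset = (seq_len(n_peaks) - 1L) * 1.0033548378,
                         intensity = p / max(p))
  if (!is.null(key)) {
    if (is.null(.oeno_env$pattern_cache)) .oeno_env$pattern_cache <- list()
    .oeno_env$pattern_cache[[key]] <- out
  }
  out
}

#' Construct an isotope pattern object
#'
#' @param offset Numeric, m/z offsets from the monoisotopic peak (Da),
#'   strictly increasing, first element 0.
#' @param intensity Relative intensities in (0, 1]; first element must be the
#'   base peak (1 after normalization to the maximum).
#' @return An object of class `isotope_pattern`.
#' @export
isotope_pattern <- function(offset, intensity) {
  stopifnot(length(offset) == length(intensity), length(offset) >= 1L)
  if (offset[1] != 0) stop("first isotope peak must have offset 0")
  if (any(diff(offset) <= 0)) stop("offsets must be strictly increasing")
  if (any(intensity < 0)) stop("intensities must be non-negative")
  structure(list(offset = offset, intensity = intensity / max(intensity)),
            class = "isotope_pattern")
}

#' Isotopic-pattern fit score (mSigma surrogate)
#'
#' A stand-in for Bruker's proprietary mSigma statistic: 1000 times the
#' root-mean-square deviation between base-peak-normalized theoretical and
#' observed relative intensities over the non-monoisotopic peaks among the
#' first three isotope clusters (A+1, A+2).  0 means a perfect match; the
#' conventional acceptance thresholds (<= 50 for targets, < 100 for suspects)
#' remain meaningful on realistic intensity noise.
#'
#' @param theoretical,observed `isotope_pattern` objects (or plain numeric
#'   vectors of base-peak-relative intensities starting at the monoisotopic
#'   peak).  Patterns of unequal length are compared over their common prefix.
#' @return Non-negative score (mSigma-like units).
#' @export
isotopic_fit_msigma <- function(theoretical, observed) {
  ti <- if (inherits(theoretical, "isotope_pattern")) theoretical$intensity else theoretical
  oi <- if (inherits(observed, "isotope_pattern")) observed$intensity else observed
  oi <- oi[!is.na(oi)]
  ti <- ti[!is.na(ti)]
  if (length(oi) < 2L) stop("insufficient envelope: observed pattern has < 2 peaks")
  if (length(ti) < 2L) stop("theoretical pattern has < 2 peaks")
  n <- min(length(ti), length(oi), 3L)
  d <- ti[2:n] - oi[2:n]
  1000 * sqrt(mean(d^2))
}

#' Chromatographic peak score
#'
#' Peak area divided by peak apex intensity; a chromatographic plausibility
#' filter (suspect screening requires > 4).
#'
#' @param area Peak area (counts).
#' @param intensity Peak apex intensity (counts), must be positive.
#' @return `area / intensity`.
#' @export
peak_score <- function(area, intensity) {
  if (any(intensity <= 0)) stop("degenerate peak: intensity must be positive")
  area / intensity
}
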