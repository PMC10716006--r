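#' Theoretical hexose MID from two-triose assembly (MIDA)
#'
#' Under [2-13C]glycerol infusion the triose-phosphate precursor pool
#' acquires a singly-labeled fraction `p`. A hexose (fructose
#' 1,6-bisphosphate) newly assembled from two independent draws of that
#' pool is then binomially labeled: m+0 = (1-p)^2, m+1 = 2p(1-p),
#' m+2 = p^2. This combinatorial pattern is what mass isotopomer
#' distribution analysis inverts.
#'
#' @param p Precursor (triose-phosphate) 13C enrichment in `[0, 1]`.
#' @return Named numeric vector `c(m0, m1, m2)`.
#' @examples
#' theoretical_hexose_mid(0.1)  # 0.81, 0.18, 0.01
#' @export
theoretical_hexose_mid <- function(p) {
  if (any(p < 0 | p > 1)) stop("p must be in [0, 1]", call. = FALSE)
  c(m0 = (1 - p)^2, m1 = 2 * p * (1 - p), m2 = p^2)
}

#' Estimate precursor enrichment from m+1/m+2 excesses
#'
#' For a hexose pool that is a mixture of pre-existing (unlabeled at
#' m+1/m+2) and newly synthesized material with the binomial pattern of
#' [theoretical_hexose_mid()], the ratio r = excess_m2 / excess_m1 equals
#' p / (2(1-p)) independently of the newly-synthesized fraction, so
#' p = 2r / (1 + 2r). The m+1/m+2 excesses must come from the carbon-only
#' derivatization channel so the [1-2H]galactose label cannot contaminate
#' m+1; the m+3/m+6 recycling products of the [U-13C]glucose tracer are
#' disjoint by mass.
#'
#' @param excess_m1 m+1 excess fraction (must exceed `floor`).
#' @param excess_m2 m+2 excess fraction, `>= 0`.
#' @param floor Noise floor below which p is indeterminate.
#' @return Precursor enrichment p.
#' @export
estimate_precursor_p <- function(excess_m1, excess_m2, floor = 1e-4) {
  if (any(excess_m2 < 0)) stop("negative m+2 excess", call. = FALSE)
  if (any(excess_m1 <= floor)) {
    stop(sprintf(
      "indeterminate p: m+1 excess at or below the noise floor (%g)", floor),
      call. = FALSE)
  }
  r <- excess_m2 / excess_m1
  2 * r / (1 + 2 * r)
}

#' Fractional gluconeogenic synthesis from MIDA
#'
#' The fraction `f` of the sampled hexose pool that is newly synthesized
#' from the triose-phosphate precursor: the measured doubly-labeled excess
#' divided by the theoretical m+2 abundance `p^2` of newly made hexose.
#' Values marginally above 1 (noise) are clipped to 1 with a warning.
#'
#' @param excess_m2 Measured m+2 excess fraction.
#' @param p Precursor enrichment from [estimate_precursor_p()] on the same
#'   sample.
#' @return Fractional synthesis f in `[0, 1]`.
#' @export
fractional_synthesis <- function(excess_m2, p) {
  if (any(excess_m2 < 0)) stop("negative m+2 excess", call. = FALSE)
  if (any(p == 0 & excess_m2 > 0)) {
    stop("inconsistent inputs: m+2 excess with zero precursor enrichment",
         call. = FALSE)
  }
  f <- ifelse(p == 0, 0, excess_m2 / p^2)
  if (any(f > 1)) {
    warning(sprintf("fractional synthesis %.4f > 1 clipped to 1", max(f)))
    f <- pmin(f, 1)
  }
  f
}

#' Full MIDA on one pair of excesses
#'
#' Convenience wrapper combining [estimate_precursor_p()] and
#' [fractional_synthesis()].
#'
#' @inheritParams estimate_precursor_p
#' @param analyte Analyte label carried through to the result.
#' @return List with elements `p`, `f`, `analyte`.
#' @export
mida <- function(excess_m1, excess_m2, floor = 1e-4,
                 analyte = c("blood_glucose", "udp_glucose")) {
  analyte <- match.arg(analyte)
  p <- estimate_precursor_p(excess_m1, excess_m2, floor = floor)
  f <- fractional_synthesis(excess_m2, p)
  list(p = p, f = f, analyte = analyte)
}
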