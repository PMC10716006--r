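#' Mass isotopomer distribution (MID) objects
#'
#' A MID is the vector of fractional abundances of an analyte's
#' isotopologues m+0, m+1, ..., m+K separated by nominal mass shift. It is
#' the universal currency of this package: raw GC-MS intensities are
#' normalized into MIDs, natural-abundance corrected, converted to tracer
#' excess fractions, and finally reduced to the scalar isotope parameters
#' that feed the flux model.
#'
#' Two derivatization channels are distinguished for glucose. The
#' aldonitrile pentaacetate derivative loses the hydrogen bound to C1
#' during derivatization, so its spectrum reports 13C labeling only
#' (`carbon_only`). The pentaacetate derivative retains that hydrogen, so
#' its m+1 also contains the [1-2H]galactose-derived deuterium signal
#' (`combined`). Subtracting the two m+1 excesses isolates the 2H
#' enrichment (see [deuterium_enrichment()]).
#'
#' @param abundances Numeric vector of fractional abundances m+0 ... m+K.
#'   Must be nonnegative; it is renormalized to sum to one.
#' @param analyte One of `"blood_glucose"` or `"udp_glucose"`.
#' @param channel One of `"carbon_only"` (aldonitrile pentaacetate) or
#'   `"combined"` (pentaacetate, 13C + 2H).
#'
#' @return An object of class `mid`: a numeric vector summing to one with
#'   `analyte` and `channel` attributes.
#' @examples
#' mid(c(0.9, 0.05, 0.03, 0, 0, 0, 0.02), "blood_glucose", "carbon_only")
#' @export
mid <- function(abundances,
                analyte = c("blood_glucose", "udp_glucose"),
                channel = c("carbon_only", "combined")) {
  analyte <- match.arg(analyte)
  channel <- match.arg(channel)
  x <- normalize_mid(abundances)
  structure(as.numeric(x), analyte = analyte, channel = channel,
            class = "mid")
}

#' @export
print.mid <- function(x, ...) {
  cat(sprintf("<mid> %s / %s\n", attr(x, "analyte"), attr(x, "channel")))
  v <- as.numeric(x)
  names(v) <- paste0("m", seq_along(v) - 1L)
  print(round(v, 6))
  invisible(x)
}

#' Normalize raw isotopologue intensities to fractional abundances
#'
#' Divides a vector of integrated isotopologue intensities by its sum so
#' that the result is a fractional abundance vector. Idempotent on
#' already-normalized input.
#'
#' @param raw_intensities Numeric vector with at least one strictly
#'   positive entry and no negative entries.
#' @return Numeric vector of the same length summing to one.
#' @examples
#' normalize_mid(c(2, 2, 0, 0, 0, 0, 0))
#' @export
normalize_mid <- function(raw_intensities) {
  x <- as.numeric(raw_intensities)
  if (length(x) == 0 || anyNA(x)) {
    stop("invalid measurement: empty or NA intensities", call. = FALSE)
  }
  if (any(x < 0)) {
    stop("invalid measurement: negative intensities", call. = FALSE)
  }
  s <- sum(x)
  if (s <= 0) {
    stop("invalid measurement: all intensities are zero", call. = FALSE)
  }
  x / s
}

#' Tracer excess above a baseline MID
#'
#' Element-wise difference between a corrected MID and a baseline MID
#' (pre-infusion sample, or the theoretical unlabeled distribution which,
#' after natural-abundance correction, is the unit vector at m+0). The
#' result isolates tracer-attributable enrichment. Negative differences —
#' measurement noise pushing an isotopologue below baseline — are clipped
#' to zero and the total clipped magnitude is recorded in the `clipped`
#' attribute.
#'
#' @param corrected Numeric MID (natural-abundance corrected, sums to 1).
#' @param baseline Numeric MID of the same length; defaults to the
#'   unlabeled distribution `c(1, 0, ..., 0)`.
#' @return Numeric vector of excess fractions (m+0 entry is the clipped
#'   `corrected - baseline` like the rest) with attribute `clipped`.
#' @export
excess_mid <- function(corrected, baseline = NULL) {
  x <- as.numeric(corrected)
  if (is.null(baseline)) {
    baseline <- c(1, rep(0, length(x) - 1L))
  }
  b <- as.numeric(baseline)
  if (length(x) != length(b)) {
    stop("corrected and baseline MIDs have different lengths", call. = FALSE)
  }
  d <- x - b
  clipped <- sum(pmax(-d, 0)[-1L])  # m+0 always drops as labels appear
  d <- pmax(d, 0)
  structure(d, clipped = clipped)
}

#' Deuterium (2H) m+1 enrichment from the two derivatization channels
#'
#' The pentaacetate (`combined`) channel carries both 13C and 2H signal at
#' m+1; the aldonitrile pentaacetate (`carbon_only`) channel lost the C1
#' hydrogen and carries only 13C. Their m+1 excess difference is the
#' [1-2H]galactose-derived enrichment, floored at zero.
#'
#' @param combined `mid` (or excess vector) from the pentaacetate channel.
#' @param carbon_only `mid` (or excess vector) from the aldonitrile channel.
#' @param is_excess If `FALSE` (default) the inputs are corrected MIDs and
#'   excesses are computed against the unlabeled baseline first.
#' @return Scalar 2H m+1 enrichment, `>= 0`.
#' @export
deuterium_enrichment <- function(combined, carbon_only, is_excess = FALSE) {
  a1 <- attr(combined, "analyte")
  a2 <- attr(carbon_only, "analyte")
  if (!is.null(a1) && !is.null(a2) && !identical(a1, a2)) {
    stop("channel mismatch: MIDs come from different analytes", call. = FALSE)
  }
  if (!is_excess) {
    combined <- excess_mid(combined)
    carbon_only <- excess_mid(carbon_only)
  }
  max(as.numeric(combined)[2L] - as.numeric(carbon_only)[2L], 0)
}
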