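#' Read a long-format isotopologue table
#'
#' Expected columns: `animal_id`, `group`, `time_min`, `matrix`
#' (`blood_spot` or `urine`), `channel` (`carbon_only` or `combined`),
#' `m0` ... `m6`. Values may be raw integrated intensities or fractional
#' abundances; rows are auto-detected by their sums and normalized either
#' way.
#'
#' @param path CSV or TSV file path.
#' @return Tibble in the canonical schema, `m0..m6` normalized.
#' @export
read_mid_table <- function(path) {
  delim <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  dat <- readr::read_delim(path, delim = delim, show_col_types = FALSE)
  validate_mid_table(dat)
}

mz_cols <- paste0("m", 0:6)

validate_mid_table <- function(dat) {
  required <- c("animal_id", "group", "time_min", "matrix", "channel",
                mz_cols)
  missing <- setdiff(required, names(dat))
  if (length(missing) > 0) {
    stop("input schema error: missing columns ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(dat) == 0) stop("input schema error: empty table", call. = FALSE)
  bad_matrix <- setdiff(unique(dat$matrix), c("blood_spot", "urine"))
  if (length(bad_matrix) > 0) {
    stop("input schema error: unknown matrix ", bad_matrix[1],
         call. = FALSE)
  }
  bad_channel <- setdiff(unique(dat$channel), c("carbon_only", "combined"))
  if (length(bad_channel) > 0) {
    stop("input schema error: unknown channel ", bad_channel[1],
         call. = FALSE)
  }
  m <- as.matrix(dat[mz_cols])
  sums <- rowSums(m)
  if (any(sums <= 0) || any(m < 0)) {
    stop("invalid measurement: nonpositive isotopologue rows",
         call. = FALSE)
  }
  dat[mz_cols] <- m / sums
  dat
}

matrix_to_analyte <- function(matrix) {
  ifelse(matrix == "blood_spot", "blood_glucose", "udp_glucose")
}

#' Natural-abundance correct a sample table
#'
#' Applies [correct_natural_abundance()] row-wise with the correction
#' matrix of each row's derivatization channel, and appends the residual
#' norm and (after excess computation) negative-clipping diagnostics.
#'
#' @param dat Table from [read_mid_table()] (or [simulate_experiment()]).
#' @param matrices Per-channel correction matrices; see
#'   [channel_matrices()].
#' @param residual_tol Relative residual warning threshold.
#' @return Tibble with corrected `m0..m6` (nonnegative least squares),
#'   the signed unconstrained solution `s0..s6` (unbiased under noise;
#'   feeds the pooled estimators), `residual_norm` and `fit_warning`.
#' @export
correct_mid_table <- function(dat, matrices = channel_matrices(),
                              residual_tol = 0.05) {
  dat <- validate_mid_table(dat)
  m <- as.matrix(dat[mz_cols])
  s <- m
  res <- numeric(nrow(dat))
  warn <- logical(nrow(dat))
  for (i in seq_len(nrow(dat))) {
    corr <- correct_natural_abundance(m[i, ], matrices[[dat$channel[i]]],
                                      residual_tol = residual_tol)
    m[i, ] <- as.numeric(corr)
    s[i, ] <- attr(corr, "signed")
    res[i] <- attr(corr, "residual_norm")
    warn[i] <- attr(corr, "fit_warning")
  }
  dat[mz_cols] <- m
  dat[paste0("s", 0:6)] <- s
  dat$residual_norm <- res
  dat$fit_warning <- warn
  dat
}

#' Per-sample primary isotope parameters
#'
#' Reduces a corrected sample table to one row per animal and time point
#' holding the six primary isotope parameters and diagnostics:
#' tracer dilutions `d_glc` (blood m+6 excess / purity) and `d_udpglc`
#' (urinary 2H m+1 enrichment / purity), exchange fractions `c_glc`
#' (UDP-glucose m+6 over blood m+6) and `c_udpglc` (blood 2H over
#' UDP-glucose 2H), MIDA fractions `f_glc` and `f_udpglc` with their
#' precursor enrichments `p_glc`, `p_udpglc`, and the `m3m6` recycling
#' ratios. MIDA m+1/m+2 excesses are taken from the carbon-only channel
#' so the galactose 2H label cannot contaminate m+1. Parameters that are
#' indeterminate at a time point (enrichment below the noise floor, e.g.
#' at t = 0) are `NA` rather than errors; steady-state averaging ignores
#' them.
#'
#' @param corrected Output of [correct_mid_table()].
#' @param purity Tracer isotopic purity.
#' @param floor Noise floor for denominators and MIDA m+1.
#' @param p_source `"per_analyte"` (default) estimates the MIDA precursor
#'   enrichment separately for blood and UDP-glucose; `"blood"` applies
#'   the blood-glucose p to the UDP-glucose f.
#' @return Tibble keyed by `animal_id`, `group`, `time_min`.
#' @export
sample_parameters <- function(corrected, purity = 0.99, floor = 1e-4,
                              p_source = c("per_analyte", "blood")) {
  p_source <- match.arg(p_source)
  corrected$analyte <- matrix_to_analyte(corrected$matrix)
  safe <- function(expr) tryCatch(expr, error = function(e) NA_real_)

  s_cols <- paste0("s", 0:6)
  has_signed <- all(s_cols %in% names(corrected))
  one_time <- function(df) {
    # df: all channel rows of one animal at one time point
    get_mid <- function(analyte, channel, signed = FALSE) {
      cols <- if (signed && has_signed) s_cols else mz_cols
      r <- df[df$analyte == analyte & df$channel == channel, cols]
      if (nrow(r) != 1) return(NULL)
      as.numeric(r[1, ])
    }
    out <- tibble::tibble(
      d_glc = NA_real_, d_udpglc = NA_real_, c_glc = NA_real_,
      c_udpglc = NA_real_, f_glc = NA_real_, f_udpglc = NA_real_,
      p_glc = NA_real_, p_udpglc = NA_real_,
      m3m6_glc = NA_real_, m3m6_udpglc = NA_real_,
      e6_glc = NA_real_, h1_udpglc = NA_real_,
      # signed excesses kept for pooled per-animal estimation
      x_b1 = NA_real_, x_b2 = NA_real_, x_b2c = NA_real_,
      x_b3 = NA_real_, x_b6 = NA_real_, x_hb = NA_real_,
      x_u1 = NA_real_, x_u2 = NA_real_, x_u2c = NA_real_,
      x_u3 = NA_real_, x_u6 = NA_real_, x_hu = NA_real_)
    bc <- get_mid("blood_glucose", "carbon_only")
    bb <- get_mid("blood_glucose", "combined")
    uc <- get_mid("udp_glucose", "carbon_only")
    ub <- get_mid("udp_glucose", "combined")
    sbc <- get_mid("blood_glucose", "carbon_only", signed = TRUE)
    sbb <- get_mid("blood_glucose", "combined", signed = TRUE)
    suc <- get_mid("udp_glucose", "carbon_only", signed = TRUE)
    sub <- get_mid("udp_glucose", "combined", signed = TRUE)
    base <- c(1, rep(0, 6))
    if (!is.null(bc)) {
      ex <- excess_mid(bc)
      sx <- sbc - base
      out$x_b1 <- sx[2L]; out$x_b2 <- sx[3L]
      out$x_b3 <- sx[4L]; out$x_b6 <- sx[7L]
      out$e6_glc <- ex[7L]
      out$d_glc <- safe(compute_dilution(ex[7L], purity))
      out$m3m6_glc <- safe(m3m6_ratio(ex, floor = floor))
      out$p_glc <- safe(estimate_precursor_p(ex[2L], ex[3L], floor = floor))
      if (!is.na(out$p_glc)) {
        out$f_glc <- safe(fractional_synthesis(ex[3L], out$p_glc))
      }
    }
    if (!is.null(bb)) {
      out$x_b2c <- (sbb - base)[3L]
      if (!is.null(bc)) out$x_hb <- sbb[2L] - sbc[2L]
    }
    if (!is.null(uc)) {
      ux <- excess_mid(uc)
      sx <- suc - base
      out$x_u1 <- sx[2L]; out$x_u2 <- sx[3L]
      out$x_u3 <- sx[4L]; out$x_u6 <- sx[7L]
      out$m3m6_udpglc <- safe(m3m6_ratio(ux, floor = floor))
      out$p_udpglc <- safe(estimate_precursor_p(ux[2L], ux[3L],
                                                floor = floor))
      p_for_f <- if (p_source == "blood" ||
                     (is.na(out$p_udpglc) && !is.na(out$p_glc))) {
        out$p_glc
      } else {
        out$p_udpglc
      }
      if (!is.na(p_for_f)) {
        out$f_udpglc <- safe(fractional_synthesis(ux[3L], p_for_f))
      }
      if (!is.null(bc)) {
        out$c_glc <- if (!is.na(out$e6_glc) && out$e6_glc > floor) {
          ux[7L] / out$e6_glc
        } else NA_real_
      }
    }
    if (!is.null(ub)) {
      out$x_u2c <- (sub - base)[3L]
      if (!is.null(uc)) {
        h_u <- deuterium_enrichment(ub, uc)
        out$x_hu <- sub[2L] - suc[2L]
        out$h1_udpglc <- h_u
        out$d_udpglc <- safe(compute_dilution(h_u, purity))
        if (!is.null(bb) && !is.null(bc)) {
          h_b <- deuterium_enrichment(bb, bc)
          out$c_udpglc <- if (h_u > floor) h_b / h_u else NA_real_
        }
      }
    }
    out
  }

  corrected |>
    dplyr::group_by(.data$animal_id, .data$group, .data$time_min) |>
    dplyr::group_modify(~ one_time(.x)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$animal_id, .data$time_min)
}

#' Isotopic steady-state window check
#'
#' Returns the fixed default window (240-360 min) together with a
#' plateau diagnostic: the relative drift of the enrichment across the
#' window, estimated by a linear fit over the in-window points, must stay
#' below `drift_threshold`. The window is never silently shrunk; a
#' failing series is flagged, not re-windowed.
#'
#' @param time_min,values Enrichment time series of one animal.
#' @param window Candidate window, default `c(240, 360)`.
#' @param drift_threshold Maximum tolerated |relative drift|, default 0.1.
#' @param animal_id Used in error messages.
#' @return List: `start`, `end`, `n`, `slope`, `drift`, `pass`.
#' @export
detect_steady_state <- function(time_min, values, window = c(240, 360),
                                drift_threshold = 0.1,
                                animal_id = "animal") {
  stopifnot(window[1] < window[2])
  keep <- time_min >= window[1] & time_min <= window[2] & !is.na(values)
  if (sum(keep) < 3) {
    stop(sprintf(
      "steady-state check for %s: fewer than 3 points in [%g, %g]",
      animal_id, window[1], window[2]), call. = FALSE)
  }
  t <- time_min[keep]; v <- values[keep]
  slope <- if (stats::sd(t) == 0) 0 else stats::cov(t, v) / stats::var(t)
  mu <- mean(v)
  drift <- if (mu == 0) 0 else slope * (window[2] - window[1]) / mu
  list(start = window[1], end = window[2], n = sum(keep),
       slope = slope, drift = drift,
       pass = abs(drift) < drift_threshold)
}

#' Average per-time parameters over the steady-state window
#'
#' Unweighted mean of every parameter over the in-window time points of
#' one animal, with the number of contributing points reported. A single
#' in-window point triggers a warning, not an error.
#'
#' @param params Per-time parameter table of one animal
#'   ([sample_parameters()] rows).
#' @param window Steady-state window, default `c(240, 360)`.
#' @return One-row tibble of averaged parameters plus `n_window`.
#' @export
average_window <- function(params, window = c(240, 360)) {
  keep <- params$time_min >= window[1] & params$time_min <= window[2]
  if (!any(keep)) stop("no samples inside the steady-state window",
                       call. = FALSE)
  sub <- params[keep, ]
  num <- vapply(sub, is.numeric, logical(1)) & names(sub) != "time_min"
  out <- tibble::as_tibble(lapply(sub[num], function(x) {
    mean(x, na.rm = TRUE)
  }))
  out$n_window <- sum(keep)
  if (sum(keep) == 1) {
    warning("single in-window sample: steady-state mean has n = 1")
  }
  out
}

#' Per-animal steady-state isotope parameters
#'
#' Reduces the per-time table to one row per animal. Linear quantities
#' (tracer excesses, 2H enrichments) are averaged over the steady-state
#' window and converted to `d`, `c` and `m3m6` parameters. The MIDA pair
#' `(p, f)` is estimated from pooled excesses rather than by averaging
#' per-time estimates: the m+2/m+1 excess ratio — which is invariant to
#' the approach to plateau because both isotopologues trace the same
#' newly synthesized material — is pooled over all informative time
#' points and both derivative channels to give `p`, and `f` is then
#' obtained from the window-mean m+1 excess via the binomial
#' `f = E[m+1] / (2 p (1-p))`. Pooling uses signed excesses, so noise is
#' not rectified into an upward bias, and sidesteps the heavy-tailed
#' error of single-sample `m+2 / p^2` estimates whose m+2 excess sits on
#' a much larger natural-abundance background.
#'
#' @param params Per-time parameter table ([sample_parameters()]).
#' @param window Steady-state window, default `c(240, 360)`.
#' @param purity Tracer isotopic purity.
#' @param floor Noise floor: time points whose m+1 excess is below it do
#'   not enter the pooled ratio.
#' @param p_source `"per_analyte"` or `"blood"` (use the blood-glucose
#'   precursor enrichment for the UDP-glucose MIDA fraction).
#' @param pooled_p Optional precomputed precursor enrichments (a list
#'   with `p_glc`, `p_udpglc`), typically from [pooled_precursor()] run
#'   on a whole treatment group; `NULL` estimates them from this
#'   animal's own samples.
#' @return One row per animal with the six primary parameters, precursor
#'   enrichments, `m3m6` ratios and `n_window`.
#' @export
animal_parameters <- function(params, window = c(240, 360),
                              purity = 0.99, floor = 1e-4,
                              p_source = c("per_analyte", "blood"),
                              pooled_p = NULL) {
  p_source <- match.arg(p_source)
  one_animal <- function(sub) {
    inw <- sub$time_min >= window[1] & sub$time_min <= window[2]
    if (!any(inw)) stop("no samples inside the steady-state window",
                        call. = FALSE)
    wmean <- function(col) mean(sub[[col]][inw], na.rm = TRUE)
    mida_f <- function(m1_col, p) {
      if (is.na(p)) return(NA_real_)
      if (p == 0) return(0)
      f <- wmean(m1_col) / (2 * p * (1 - p))
      if (is.na(f)) return(NA_real_)
      if (f > 1) warning(sprintf("fractional synthesis %.3f clipped to 1",
                                 f))
      min(max(f, 0), 1)
    }
    if (is.null(pooled_p)) pooled_p <- pooled_precursor(sub, floor)
    p_glc <- pooled_p$p_glc
    p_udp <- pooled_p$p_udpglc
    p_for_udp <- if (p_source == "blood" || is.na(p_udp)) p_glc else p_udp
    e6 <- wmean("x_b6"); u6 <- wmean("x_u6")
    hb <- wmean("x_hb"); hu <- wmean("x_hu")
    tibble::tibble(
      d_glc = compute_dilution(e6, purity),
      d_udpglc = compute_dilution(max(hu, 0), purity),
      c_glc = if (e6 > floor) max(u6, 0) / e6 else NA_real_,
      c_udpglc = if (hu > floor) max(hb, 0) / hu else NA_real_,
      f_glc = mida_f("x_b1", p_glc),
      f_udpglc = mida_f("x_u1", p_for_udp),
      p_glc = p_glc, p_udpglc = p_udp,
      m3m6_glc = tryCatch(m3m6_ratio(wmean("x_b3"), m6 = e6),
                          error = function(e) NA_real_),
      m3m6_udpglc = tryCatch(m3m6_ratio(wmean("x_u3"), m6 = u6),
                             error = function(e) NA_real_),
      n_window = sum(inw))
  }
  rows <- list()
  for (id in unique(params$animal_id)) {
    sub <- params[params$animal_id == id, ]
    rows[[id]] <- tibble::tibble(animal_id = id, group = sub$group[1],
                                 one_animal(sub))
  }
  dplyr::bind_rows(rows)
}

#' Pooled MIDA precursor enrichment
#'
#' Estimates the triose-phosphate precursor enrichment per analyte from
#' the pooled m+2/m+1 signed-excess ratio over every informative sample
#' in `params` (all time points whose m+1 excess clears the noise floor;
#' m+2 averaged over both derivative channels). Because m+1 and m+2 of
#' newly synthesized hexose scale together during the approach to
#' plateau, the ratio — and hence `p` — can draw on the full time course,
#' and pooling across the animals of a treatment group is appropriate
#' whenever they share the same infusate: the precursor enrichment is set
#' by the glycerol infusion against gluconeogenic dilution, not by the
#' sampling.
#'
#' @param params Per-time parameter rows ([sample_parameters()]) of one
#'   animal or one group.
#' @param floor m+1 excess noise floor.
#' @return List with `p_glc` and `p_udpglc` (either may be `NA` when no
#'   sample is informative).
#' @export
pooled_precursor <- function(params, floor = 1e-4) {
  one <- function(m1_col, m2_col, m2c_col) {
    m1 <- params[[m1_col]]
    m2 <- rowMeans(cbind(params[[m2_col]], params[[m2c_col]]),
                   na.rm = TRUE)
    use <- !is.na(m1) & m1 > floor & !is.na(m2)
    if (!any(use)) return(NA_real_)
    r <- max(sum(m2[use]) / sum(m1[use]), 0)
    2 * r / (1 + 2 * r)
  }
  list(p_glc = one("x_b1", "x_b2", "x_b2c"),
       p_udpglc = one("x_u1", "x_u2", "x_u2c"))
}

#' Per-animal steady-state parameters and fluxes
#'
#' Runs the steady-state window diagnostic and [animal_parameters()] for
#' every animal, then solves the flux balance per animal. Animals whose
#' parameter set is infeasible or incomplete are reported in the
#' `failures` attribute (with the reason), never silently dropped or
#' clipped; computation continues for the others.
#'
#' @param params Per-time parameter table ([sample_parameters()]).
#' @param protocol An [infusion_protocol()].
#' @param window Steady-state window.
#' @param closure Flux closure name.
#' @param blood_glucose Optional tibble `animal_id`, `blood_glucose_mM`
#'   used for clearance.
#' @param drift_threshold Plateau diagnostic threshold.
#' @param purity,floor,p_source Passed to [animal_parameters()].
#' @param p_pooling `"group"` (default) estimates each analyte's MIDA
#'   precursor enrichment from all animals of a treatment group pooled
#'   via [pooled_precursor()] — appropriate because the precursor
#'   enrichment is a property of the shared infusion protocol;
#'   `"animal"` estimates it per animal.
#' @return Tibble with one row per animal: the six parameters, window
#'   diagnostics, and the solved fluxes; failed animals in attribute
#'   `failures`.
#' @export
animal_fluxes <- function(params, protocol = infusion_protocol(),
                          window = c(240, 360), closure = "g6p_balance",
                          blood_glucose = NULL, drift_threshold = 0.1,
                          purity = 0.99, floor = 1e-4,
                          p_source = "per_analyte",
                          p_pooling = c("group", "animal")) {
  p_pooling <- match.arg(p_pooling)
  group_p <- if (p_pooling == "group") {
    lapply(split(params, params$group), pooled_precursor, floor = floor)
  } else NULL
  rows <- list(); fails <- list()
  for (id in unique(params$animal_id)) {
    sub <- params[params$animal_id == id, ]
    res <- tryCatch({
      diag <- detect_steady_state(sub$time_min, sub$d_glc, window,
                                  drift_threshold, animal_id = id)
      avg <- animal_parameters(sub, window = window, purity = purity,
                               floor = floor, p_source = p_source,
                               pooled_p = group_p[[sub$group[1]]])
      bg <- if (!is.null(blood_glucose)) {
        blood_glucose$blood_glucose_mM[blood_glucose$animal_id == id][1]
      } else NULL
      fx <- solve_fluxes(avg[c("d_glc", "d_udpglc", "c_glc", "c_udpglc",
                               "f_glc", "f_udpglc")],
                         protocol, closure = closure,
                         blood_glucose_mM = bg)
      tibble::tibble(avg, ss_drift = diag$drift, ss_pass = diag$pass,
                     tibble::as_tibble(unclass(fx)))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      fails[[length(fails) + 1L]] <- tibble::tibble(
        animal_id = id, reason = conditionMessage(res))
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "failures") <- dplyr::bind_rows(fails)
  out
}

#' Group summaries (mean +/- SEM)
#'
#' @param animal_table Per-animal table from [animal_fluxes()].
#' @param outcomes Columns to summarize; defaults to all numeric columns.
#' @return Long tibble: `group`, `outcome`, `n`, `mean`, `sem`.
#' @export
group_summary <- function(animal_table, outcomes = NULL) {
  if (is.null(outcomes)) {
    outcomes <- names(animal_table)[vapply(animal_table, is.numeric,
                                           logical(1))]
  }
  animal_table |>
    tidyr::pivot_longer(dplyr::all_of(outcomes), names_to = "outcome") |>
    dplyr::group_by(.data$group, .data$outcome) |>
    dplyr::summarise(
      n = sum(!is.na(.data$value)),
      mean = mean(.data$value, na.rm = TRUE),
      sem = stats::sd(.data$value, na.rm = TRUE) /
        sqrt(sum(!is.na(.data$value))),
      .groups = "drop")
}
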