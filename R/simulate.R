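#' Ground truth for a simulated triple-tracer experiment
#'
#' Defines the true hepatic fluxes, precursor enrichment, recycling
#' fraction, pool kinetics and noise model from which
#' [simulate_experiment()] forward-generates GC-MS isotopologue tables.
#' The five closure fluxes must satisfy the G6P balance
#' `GCK + GP + GNG_G6P = G6Pase + GS`; if `GP` is omitted it is filled in
#' from the identity.
#'
#' @param GCK,G6Pase,GS,GNG_G6P,GP True fluxes, umol/kg/min.
#' @param p True triose-phosphate precursor 13C enrichment.
#' @param recycling m+3/m+6 excess ratio injected into both pools
#'   (glycolytic recycling of the m+6 tracer).
#' @param blood_glucose_mM Blood glucose concentration.
#' @param tau_glc,tau_udpglc Mono-exponential time constants (min) of the
#'   approach of each pool's enrichment to isotopic steady state.
#' @param protocol An [infusion_protocol()].
#' @param noise_cv Multiplicative (log-normal) measurement CV per
#'   isotopologue intensity.
#' @param urine_lag_min Lag of the urinary UDP-glucose readout behind the
#'   hepatic pool (bladder accumulation), minutes.
#' @return A `synthetic_truth` list.
#' @export
synthetic_truth <- function(GCK, G6Pase, GS, GNG_G6P, GP = NULL,
                            p = 0.10, recycling = 0.15,
                            blood_glucose_mM = 6,
                            tau_glc = 45, tau_udpglc = 60,
                            protocol = infusion_protocol(),
                            noise_cv = 0.05,
                            urine_lag_min = 60) {
  if (is.null(GP)) GP <- G6Pase + GS - GCK - GNG_G6P
  fluxes <- c(GCK = GCK, G6Pase = G6Pase, GS = GS, GP = GP,
              GNG_G6P = GNG_G6P)
  if (any(fluxes < 0)) {
    stop("infeasible truth: negative flux", call. = FALSE)
  }
  if (abs(GCK + GP + GNG_G6P - (G6Pase + GS)) > 1e-9) {
    stop("infeasible truth: G6P balance identity violated", call. = FALSE)
  }
  stopifnot(p > 0, p < 1, recycling >= 0, blood_glucose_mM > 0,
            tau_glc > 0, tau_udpglc > 0, noise_cv >= 0)
  structure(list(fluxes = fluxes, p = p, recycling = recycling,
                 blood_glucose_mM = blood_glucose_mM,
                 tau_glc = tau_glc, tau_udpglc = tau_udpglc,
                 protocol = protocol, noise_cv = noise_cv,
                 urine_lag_min = urine_lag_min),
            class = "synthetic_truth")
}

#' Steady-state enrichments implied by a flux truth
#'
#' Algebraic inversion of the `"g6p_balance"` closure: from the true
#' fluxes and the protocol's tracer rates, the six primary isotope
#' parameters the pipeline should recover, and the plateau tracer-excess
#' MIDs of both pools and channels.
#'
#' The closure-defined parameters are exact inversions:
#' `c_glc = GCK/T`, `f_udpglc = GNG_G6P/T` with `T = G6Pase + GS`;
#' `d_glc = I6/Ra` with `Ra = I6 + G6Pase (1 - c_glc)` (the apparent
#' total appearance after glucose cycling); `d_udpglc = Igal/(GS + Igal)`.
#' The two reported-only parameters are derived from steady-state label
#' balances: `f_glc = G6Pase * GNG_G6P / (T * (I6 + G6Pase))` (blood
#' m+2 from G6Pase export of gluconeogenic G6P) and `c_udpglc` from a 2H
#' balance across the glucose/G6P cycle with last-in-first-out glycogen.
#'
#' @param truth A [synthetic_truth()].
#' @return List with `params` (the six parameters), `pools` (named list
#'   of plateau excess vectors m+0..m+6 per analyte and channel) and the
#'   tracer `rates`.
#' @export
steady_state_enrichments <- function(truth) {
  fx <- truth$fluxes
  rates <- tracer_rates(truth$protocol)
  purity <- truth$protocol$purity
  I6 <- rates$I6; Igal <- rates$Igal
  T_g6p <- fx[["G6Pase"]] + fx[["GS"]]
  c_glc <- fx[["GCK"]] / T_g6p
  f_udpglc <- fx[["GNG_G6P"]] / T_g6p
  EGP <- fx[["G6Pase"]] * (1 - c_glc)
  Ra <- EGP + I6
  d_glc <- I6 / Ra
  Ru <- fx[["GS"]] + Igal
  d_udpglc <- Igal / Ru
  # reported-only parameters from label balances
  Ra_true <- I6 + fx[["G6Pase"]]
  f_glc <- fx[["G6Pase"]] * fx[["GNG_G6P"]] / (T_g6p * Ra_true)
  # 2H: h_u fixed by galactose dilution; G6P receives 2H via GCK uptake of
  # labeled blood glucose and via phosphorolysis of freshly made glycogen
  h_u <- purity * d_udpglc
  denom <- T_g6p - fx[["GCK"]] * fx[["G6Pase"]] / Ra_true
  h_g <- fx[["GP"]] * h_u / denom
  h_b <- fx[["G6Pase"]] * h_g / Ra_true
  c_udpglc <- h_b / h_u
  params <- list(d_glc = d_glc, d_udpglc = d_udpglc,
                 c_glc = c_glc, c_udpglc = c_udpglc,
                 f_glc = f_glc, f_udpglc = f_udpglc)

  p <- truth$p
  e6 <- purity * d_glc
  u6 <- c_glc * e6
  bino <- theoretical_hexose_mid(p)
  # excess-space target: m+0 entry left at zero, filled in at sampling
  pool_excess <- function(m1, m2, m3, m6) c(0, m1, m2, m3, 0, 0, m6)
  pools <- list(
    blood_glucose = list(
      carbon_only = pool_excess(f_glc * bino[["m1"]], f_glc * bino[["m2"]],
                                truth$recycling * e6, e6),
      combined = pool_excess(f_glc * bino[["m1"]] + h_b,
                             f_glc * bino[["m2"]],
                             truth$recycling * e6, e6)
    ),
    udp_glucose = list(
      carbon_only = pool_excess(f_udpglc * bino[["m1"]],
                                f_udpglc * bino[["m2"]],
                                truth$recycling * u6, u6),
      combined = pool_excess(f_udpglc * bino[["m1"]] + h_u,
                             f_udpglc * bino[["m2"]],
                             truth$recycling * u6, u6)
    )
  )
  list(params = params, pools = pools, rates = rates)
}

label_mid_at_time <- function(excess, t, tau) {
  s <- 1 - exp(-t / tau)
  v <- excess * s
  v[1] <- 0
  v[1] <- 1 - sum(v)
  v
}

apply_noise <- function(v, cv) {
  if (cv <= 0) return(v)
  sdlog <- sqrt(log(1 + cv^2))
  noisy <- v * exp(stats::rnorm(length(v), -sdlog^2 / 2, sdlog))
  noisy / sum(noisy)
}

#' Forward-simulate one triple-tracer infusion experiment
#'
#' Generates the long-format isotopologue table of one animal: blood
#' spots and urine collected hourly over a 6 h infusion, each pool's
#' enrichment approaching its steady-state target as `1 - exp(-t/tau)`,
#' label MIDs convolved with the natural-abundance matrix of the
#' channel's derivative fragment, and multiplicative log-normal noise
#' applied per isotopologue before renormalization. The urinary readout
#' lags the hepatic UDP-glucose pool by `truth$urine_lag_min`.
#'
#' @param truth A [synthetic_truth()].
#' @param animal_id,group Identifiers written into the table.
#' @param times_blood,times_urine Sampling times (min).
#' @param matrices Correction matrices per channel, as produced by
#'   [channel_matrices()]; passed in so cohort simulation builds them
#'   once.
#' @return Tibble with columns `animal_id`, `group`, `time_min`,
#'   `matrix`, `channel`, `m0`..`m6`; the truth and its implied targets
#'   attached as attributes `truth` and `targets`.
#' @export
simulate_experiment <- function(truth, animal_id = "sim1", group = "sim",
                                times_blood = seq(0, 360, by = 60),
                                times_urine = seq(60, 360, by = 60),
                                matrices = channel_matrices()) {
  ss <- steady_state_enrichments(truth)
  rows <- list()
  emit <- function(analyte, sample_matrix, t, t_eff) {
    tau <- if (analyte == "blood_glucose") truth$tau_glc else truth$tau_udpglc
    for (ch in c("carbon_only", "combined")) {
      lab <- label_mid_at_time(ss$pools[[analyte]][[ch]], t_eff, tau)
      obs <- as.numeric(matrices[[ch]] %*% lab)
      obs <- apply_noise(obs, truth$noise_cv)
      rows[[length(rows) + 1L]] <<- tibble::tibble(
        animal_id = animal_id, group = group, time_min = t,
        matrix = sample_matrix, channel = ch,
        tibble::as_tibble(as.list(stats::setNames(obs,
                                                  paste0("m", 0:6)))))
    }
  }
  for (t in times_blood) emit("blood_glucose", "blood_spot", t, t)
  for (t in times_urine) {
    emit("udp_glucose", "urine", t, max(t - truth$urine_lag_min, 0))
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "truth") <- truth
  attr(out, "targets") <- ss
  out
}

#' Correction matrices for the two derivatization channels
#'
#' @param K Highest mass shift.
#' @param abundances See [natural_abundances()].
#' @return Named list `carbon_only`, `combined` of correction matrices.
#' @export
channel_matrices <- function(K = 6, abundances = natural_abundances()) {
  list(carbon_only = build_correction_matrix(
         glucose_aldonitrile_pentaacetate(), K, abundances),
       combined = build_correction_matrix(
         glucose_pentaacetate(), K, abundances))
}

#' Simulate a factorial cohort
#'
#' Draws `n_per_group` animals per group by jittering each group's truth
#' fluxes with a multiplicative between-animal CV (balance restored by
#' recomputing GP from the identity; infeasible draws are redrawn), then
#' simulates every animal with [simulate_experiment()].
#'
#' @param n_per_group Animals per group (>= 2).
#' @param group_truths Named list of [synthetic_truth()] objects.
#' @param between_animal_cv Log-normal CV applied to GCK, G6Pase, GS and
#'   GNG_G6P per animal.
#' @param seed Optional RNG seed for reproducibility.
#' @return Tibble of all samples; per-animal truth ledger in attribute
#'   `truth_ledger` (tibble with the true fluxes of every animal).
#' @export
simulate_cohort <- function(n_per_group, group_truths,
                            between_animal_cv = 0, seed = NULL) {
  stopifnot(n_per_group >= 2, length(group_truths) >= 1,
            !is.null(names(group_truths)))
  if (!is.null(seed)) set.seed(seed)
  matrices <- channel_matrices()
  data_rows <- list()
  ledger <- list()
  for (g in names(group_truths)) {
    base <- group_truths[[g]]
    for (i in seq_len(n_per_group)) {
      tr <- base
      if (between_animal_cv > 0) {
        sdlog <- sqrt(log(1 + between_animal_cv^2))
        for (attempt in 1:100) {
          jit <- exp(stats::rnorm(4, -sdlog^2 / 2, sdlog))
          fx <- base$fluxes[c("GCK", "G6Pase", "GS", "GNG_G6P")] * jit
          GP <- fx[["G6Pase"]] + fx[["GS"]] - fx[["GCK"]] - fx[["GNG_G6P"]]
          if (GP >= 0) break
        }
        if (GP < 0) stop("could not draw a feasible animal truth",
                         call. = FALSE)
        tr$fluxes <- c(fx[c("GCK", "G6Pase", "GS")], GP = GP,
                       GNG_G6P = fx[["GNG_G6P"]])
      }
      id <- sprintf("%s_%02d", g, i)
      dat <- simulate_experiment(tr, animal_id = id, group = g,
                                 matrices = matrices)
      data_rows[[length(data_rows) + 1L]] <- dat
      ledger[[length(ledger) + 1L]] <- tibble::tibble(
        animal_id = id, group = g,
        GCK = tr$fluxes[["GCK"]], G6Pase = tr$fluxes[["G6Pase"]],
        GS = tr$fluxes[["GS"]], GP = tr$fluxes[["GP"]],
        GNG_G6P = tr$fluxes[["GNG_G6P"]],
        p = tr$p, recycling = tr$recycling,
        blood_glucose_mM = tr$blood_glucose_mM)
    }
  }
  out <- dplyr::bind_rows(data_rows)
  attr(out, "truth_ledger") <- dplyr::bind_rows(ledger)
  out
}
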