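#' Triple-tracer infusion protocol
#'
#' Tracer identities, concentrations, pump rate and body weight, plus the
#' molecular masses of the labeled species, from which the per-kg molar
#' infusion rates are derived. Defaults are the standard mouse protocol:
#' [U-13C]glucose 2.5 mg/mL, [2-13C]glycerol 16 mg/mL, [1-2H]galactose
#' 6 mg/mL and paracetamol 2 mg/mL infused at 0.5 mL/h into an overnight-
#' fasted ~22 g animal.
#'
#' @param conc_mg_ml Named numeric: tracer concentrations in mg/mL for
#'   `glucose_u13c`, `glycerol_2_13c`, `galactose_1_2h`, `paracetamol`.
#' @param pump_rate_ml_h Infusion rate in mL/h.
#' @param body_weight_g Body weight in grams.
#' @param mol_mass_g_mol Molecular masses (g/mol) of the labeled tracers
#'   (not the unlabeled species).
#' @param purity Tracer isotopic purity (fraction), used to normalize
#'   dilutions.
#' @return An `infusion_protocol` list; see [tracer_rates()] for the
#'   derived molar rates.
#' @export
infusion_protocol <- function(conc_mg_ml = c(glucose_u13c = 2.5,
                                             glycerol_2_13c = 16,
                                             galactose_1_2h = 6,
                                             paracetamol = 2),
                              pump_rate_ml_h = 0.5,
                              body_weight_g = 22,
                              mol_mass_g_mol = c(glucose_u13c = 186.18,
                                                 glycerol_2_13c = 93.10,
                                                 galactose_1_2h = 181.16,
                                                 paracetamol = 151.16),
                              purity = 0.99) {
  stopifnot(all(conc_mg_ml > 0), pump_rate_ml_h > 0, body_weight_g > 0,
            all(mol_mass_g_mol > 0), purity > 0, purity <= 1)
  structure(list(conc_mg_ml = conc_mg_ml,
                 pump_rate_ml_h = pump_rate_ml_h,
                 body_weight_g = body_weight_g,
                 mol_mass_g_mol = mol_mass_g_mol,
                 purity = purity),
            class = "infusion_protocol")
}

#' Per-kg molar tracer infusion rates
#'
#' Converts protocol mass rates to umol per kg body weight per minute:
#' `I = conc * pump_rate / M / BW`.
#'
#' @param protocol An [infusion_protocol()].
#' @return Named list: `I6` ([U-13C]glucose), `Igal` ([1-2H]galactose),
#'   `Igly` ([2-13C]glycerol), all umol/kg/min.
#' @export
tracer_rates <- function(protocol) {
  rate_umol_min <- protocol$conc_mg_ml * protocol$pump_rate_ml_h /
    protocol$mol_mass_g_mol * 1000 / 60  # mg/h / (g/mol) -> umol/h -> /min
  per_kg <- rate_umol_min / (protocol$body_weight_g / 1000)
  list(I6 = unname(per_kg["glucose_u13c"]),
       Igal = unname(per_kg["galactose_1_2h"]),
       Igly = unname(per_kg["glycerol_2_13c"]))
}

#' Tracer dilution
#'
#' Fractional enrichment of the infused label in the sampled pool,
#' normalized by tracer isotopic purity: `d = excess / purity`. For blood
#' glucose the tracer excess is the m+6 excess of the [U-13C]glucose
#' label; for UDP-glucose it is the 2H m+1 excess of the [1-2H]galactose
#' label.
#'
#' @param tracer_excess Measured tracer excess fraction (> 0).
#' @param tracer_purity Isotopic purity of the infused tracer.
#' @return Dilution d in (0, 1].
#' @export
compute_dilution <- function(tracer_excess, tracer_purity = 0.99) {
  if (any(tracer_excess <= 0)) {
    stop("infinite dilution: tracer excess is zero", call. = FALSE)
  }
  if (any(tracer_excess > tracer_purity)) {
    stop("tracer excess exceeds tracer purity", call. = FALSE)
  }
  tracer_excess / tracer_purity
}

#' Exchange fractions between blood glucose and UDP-glucose
#'
#' `c_glc`, the fractional contribution of blood glucose to UDP-glucose
#' (direct pathway), is the m+6 enrichment of UDP-glucose over that of
#' blood glucose. `c_udpglc`, the contribution of UDP-glucose to blood
#' glucose (glycogen/UDP-glucose cycling), is the 2H m+1 enrichment of
#' blood glucose over that of UDP-glucose.
#'
#' @param m6_udpglc,m6_glc m+6 excess of UDP-glucose and blood glucose.
#' @param h1_glc,h1_udpglc 2H m+1 excess of blood glucose and UDP-glucose.
#' @param floor Noise floor for the denominators.
#' @return List with `c_glc` and `c_udpglc`.
#' @export
compute_exchange <- function(m6_udpglc, m6_glc, h1_glc, h1_udpglc,
                             floor = 1e-4) {
  if (any(m6_glc <= floor) || any(h1_udpglc <= floor)) {
    stop("indeterminate exchange: denominator enrichment below noise floor",
         call. = FALSE)
  }
  list(c_glc = m6_udpglc / m6_glc, c_udpglc = h1_glc / h1_udpglc)
}

#' Pool turnover from tracer dilution
#'
#' `turnover = I / d`: the total rate of appearance of the pool, tracer
#' infusion included. For the blood glucose pool the endogenous component
#' `EGP = turnover - I` is reported alongside.
#'
#' @param I Tracer infusion rate, umol/kg/min.
#' @param d Tracer dilution from [compute_dilution()].
#' @return List with `turnover` and `endogenous` (both umol/kg/min).
#' @export
compute_turnover <- function(I, d) {
  if (any(d <= 0) || any(d > 1)) stop("dilution must be in (0, 1]",
                                      call. = FALSE)
  if (any(I <= 0)) stop("infusion rate must be positive", call. = FALSE)
  list(turnover = I / d, endogenous = I / d - I)
}

#' Glucose clearance
#'
#' Total glucose turnover divided by the blood glucose concentration
#' (mM = umol/mL), giving mL/kg/min.
#'
#' @param Ra Total glucose turnover, umol/kg/min.
#' @param blood_glucose_mM Blood glucose concentration, mmol/L.
#' @return Clearance in mL/kg/min.
#' @export
compute_clearance <- function(Ra, blood_glucose_mM) {
  if (any(blood_glucose_mM <= 0)) {
    stop("blood glucose concentration must be positive", call. = FALSE)
  }
  Ra / blood_glucose_mM
}

#' m+3 / m+6 recycling ratio
#'
#' m+3 isotopologues of blood and UDP-glucose arise from the infused m+6
#' glucose after passage through glycolysis and triose recombination, so
#' the m+3/m+6 excess ratio indexes the contribution of glycolytic
#' intermediates to glucose and glycogen production.
#'
#' @param excess Numeric excess vector m+0 ... m+6, or `m3` if `m6` given.
#' @param m6 Optional m+6 excess when `excess` is the m+3 scalar.
#' @param floor Noise floor for the m+6 excess.
#' @return Ratio m+3/m+6.
#' @export
m3m6_ratio <- function(excess, m6 = NULL, floor = 1e-5) {
  if (is.null(m6)) {
    v <- as.numeric(excess)
    if (length(v) < 7) stop("excess vector must reach m+6", call. = FALSE)
    m3 <- v[4L]; m6 <- v[7L]
  } else {
    m3 <- as.numeric(excess)
  }
  if (any(m6 <= floor)) {
    stop("indeterminate ratio: m+6 excess below noise floor", call. = FALSE)
  }
  m3 / m6
}

# -- closure registry ---------------------------------------------------

the_closures <- new.env(parent = emptyenv())

#' Register or fetch a flux-balance closure
#'
#' A closure maps the six primary isotope parameters plus the tracer
#' rates to a full flux set. The shipped default is `"g6p_balance"`; user
#' closures (e.g. transcriptions of other published equation systems) can
#' be registered and selected by name in [solve_fluxes()].
#'
#' @param name Closure name.
#' @param fn Function `(params, rates)` returning a named list of fluxes.
#' @return `register_closure()` invisibly returns `fn`; `get_closure()`
#'   returns the registered function.
#' @export
register_closure <- function(name, fn) {
  stopifnot(is.character(name), is.function(fn))
  assign(name, fn, envir = the_closures)
  invisible(fn)
}

#' @rdname register_closure
#' @export
get_closure <- function(name) {
  if (!exists(name, envir = the_closures, inherits = FALSE)) {
    stop(sprintf("unknown closure '%s'", name), call. = FALSE)
  }
  get(name, envir = the_closures, inherits = FALSE)
}

closure_g6p_balance <- function(params, rates) {
  I6 <- rates$I6; Igal <- rates$Igal
  d_glc <- params$d_glc; d_udpglc <- params$d_udpglc
  c_glc <- params$c_glc; f_udpglc <- params$f_udpglc
  f_glc <- params$f_glc
  if (c_glc >= 1) stop("c_glc >= 1: domain error", call. = FALSE)
  Ra <- I6 / d_glc
  Ru <- Igal / d_udpglc
  EGP <- Ra - I6
  G6Pase <- EGP / (1 - c_glc)     # glucose-cycling correction
  GS <- Ru - Igal
  T_g6p <- G6Pase + GS            # total G6P turnover
  GCK <- c_glc * T_g6p
  GNG_G6P <- f_udpglc * T_g6p
  GP <- T_g6p - GCK - GNG_G6P
  list(Ra = Ra, Ru = Ru, EGP = EGP, G6Pase = G6Pase, GS = GS,
       GCK = GCK, GNG_G6P = GNG_G6P, GP = GP,
       GNG_blood = if (is.null(f_glc)) NA_real_ else f_glc * Ra,
       glucose_balance = G6Pase - GCK,
       glycogen_balance = GS - GP)
}

#' Solve the steady-state G6P flux balance
#'
#' From the six primary isotope parameters of one animal (tracer
#' dilutions `d`, exchange fractions `c`, MIDA fractions `f`, each
#' averaged over the isotopic steady state) and the infusion protocol,
#' computes the hepatic carbohydrate fluxes under the model in which the
#' fluxes toward glucose 6-phosphate (glucokinase, glycogen
#' phosphorylase, gluconeogenesis) balance the fluxes away from it
#' (glucose-6-phosphatase, glycogen synthase); glycolysis is not a model
#' flux. The default `"g6p_balance"` closure is:
#'
#' \deqn{Ra = I_6/d_{glc}; \quad Ru = I_{gal}/d_{UDPglc}; \quad
#'   EGP = Ra - I_6}
#' \deqn{G6Pase = EGP/(1 - c_{glc}); \quad GS = Ru - I_{gal}; \quad
#'   T = G6Pase + GS}
#' \deqn{GCK = c_{glc} T; \quad GNG_{G6P} = f_{UDPglc} T; \quad
#'   GP = T - GCK - GNG_{G6P}}
#'
#' with `GNG_blood = f_glc * Ra` (gluconeogenic appearance in blood),
#' `glucose_balance = G6Pase - GCK` (net hepatic glucose output) and
#' `glycogen_balance = GS - GP` (net glycogen deposition) reported
#' alongside. Every returned flux set satisfies
#' `GCK + GP + GNG_G6P = G6Pase + GS` identically.
#'
#' @param params Named list or one-row data frame with `d_glc`,
#'   `d_udpglc`, `c_glc`, `c_udpglc`, `f_glc`, `f_udpglc` (all in (0,1)).
#' @param protocol An [infusion_protocol()].
#' @param closure Closure name, default `"g6p_balance"`.
#' @param blood_glucose_mM Optional blood glucose concentration; when
#'   given, clearance (mL/kg/min) is included.
#' @param rates Optional named list with molar tracer rates `I6` and
#'   `Igal` (umol/kg/min), overriding `tracer_rates(protocol)`.
#' @return A `flux_set` list: fluxes in umol/kg/min plus `clearance`.
#'   Infeasible parameter sets (GP < 0, i.e. `c_glc + f_udpglc > 1`) are
#'   an error carrying the negative value — never silently clipped.
#' @examples
#' pr <- infusion_protocol()
#' p <- list(d_glc = 0.033, d_udpglc = 0.262, c_glc = 0.215,
#'           c_udpglc = 0.188, f_glc = 0.786, f_udpglc = 0.6651)
#' solve_fluxes(p, pr)
#' @export
solve_fluxes <- function(params, protocol = infusion_protocol(),
                         closure = "g6p_balance",
                         blood_glucose_mM = NULL,
                         rates = NULL) {
  params <- as.list(params)
  if (is.null(rates)) rates <- tracer_rates(protocol)
  for (nm in c("d_glc", "d_udpglc", "c_glc", "f_udpglc")) {
    if (is.null(params[[nm]]) || !is.finite(params[[nm]])) {
      stop(sprintf("missing or non-finite parameter '%s'", nm),
           call. = FALSE)
    }
  }
  fx <- get_closure(closure)(params, rates)
  if (fx$GP < -1e-9) {
    stop(sprintf(
      "infeasible parameters: glycogen phosphorylase flux %.4f < 0 (c_glc + f_udpglc = %.4f > 1)",
      fx$GP, params$c_glc + params$f_udpglc), call. = FALSE)
  }
  fx$GP <- max(fx$GP, 0)
  fx$clearance <- if (is.null(blood_glucose_mM)) NA_real_ else
    compute_clearance(fx$Ra, blood_glucose_mM)
  structure(fx, class = "flux_set", closure = closure)
}

#' @export
print.flux_set <- function(x, ...) {
  cat("<flux_set> (umol/kg/min; clearance mL/kg/min)\n")
  v <- unlist(x)
  print(round(v, 3))
  invisible(x)
}

# register default closure at load time
.onLoad <- function(libname, pkgname) {
  register_closure("g6p_balance", closure_g6p_balance)
}
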