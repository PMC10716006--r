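#' Published-style group mean isotope parameters
#'
#' Steady-state (240-360 min) group means of the six primary isotope
#' parameters reported for a 2x2 mouse study of acute hepatic glycogen
#' storage disease type Ib: shRNA against ChREBP or scrambled control
#' (shSCR), crossed with infusion of the G6P-transporter inhibitor S4048
#' or its vehicle, under the standard triple-tracer protocol (see
#' [infusion_protocol()]). Useful as a realistic worked example and as
#' group-level truth for cohort simulation.
#'
#' @return Tibble with columns `group`, `shrna`, `infusion`, `d_glc`,
#'   `d_udpglc`, `c_glc`, `c_udpglc`, `f_glc`, `f_udpglc`.
#' @examples
#' solve_fluxes(example_group_params()[1, ], infusion_protocol())
#' @export
example_group_params <- function() {
  tibble::tibble(
    group = c("shSCR_vehicle", "shChREBP_vehicle",
              "shSCR_S4048", "shChREBP_S4048"),
    shrna = c("shSCR", "shChREBP", "shSCR", "shChREBP"),
    infusion = c("vehicle", "vehicle", "S4048", "S4048"),
    d_glc = c(0.033, 0.031, 0.064, 0.059),
    d_udpglc = c(0.262, 0.242, 0.161, 0.123),
    c_glc = c(0.215, 0.3211, 0.0562, 0.0743),
    c_udpglc = c(0.188, 0.186, 0.201, 0.233),
    f_glc = c(0.786, 0.751, 0.756, 0.711),
    f_udpglc = c(0.6651, 0.6498, 0.7519, 0.7456)
  )
}

#' Group flux truths derived from the example parameters
#'
#' Solves the flux balance for each group of [example_group_params()] and
#' packages the results as [synthetic_truth()] objects, so a simulated
#' cohort reproduces the study's between-group structure.
#'
#' @param protocol An [infusion_protocol()].
#' @param ... Passed to [synthetic_truth()] (e.g. `noise_cv`, `tau_glc`).
#' @return Named list of `synthetic_truth` objects.
#' @export
example_group_truths <- function(protocol = infusion_protocol(), ...) {
  pars <- example_group_params()
  out <- list()
  for (i in seq_len(nrow(pars))) {
    fx <- solve_fluxes(pars[i, ], protocol)
    out[[pars$group[i]]] <- synthetic_truth(
      GCK = fx$GCK, G6Pase = fx$G6Pase, GS = fx$GS,
      GNG_G6P = fx$GNG_G6P, GP = fx$GP, protocol = protocol, ...)
  }
  out
}
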