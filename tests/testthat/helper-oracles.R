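# Independent oracles used across test files. These deliberately avoid
# the package's own convolution/inversion code paths.

# full isotopologue envelope of a fragment by polynomial expansion with
# stats::convolve (open convolution), untruncated until the final cut
oracle_envelope <- function(counts, abundances, K) {
  poly <- 1
  for (el in names(counts)) {
    n <- counts[[el]]
    if (n == 0) next
    for (i in seq_len(n)) {
      poly <- stats::convolve(poly, rev(abundances[[el]]), type = "open")
    }
  }
  out <- poly[seq_len(K + 1)]
  out[is.na(out)] <- 0
  out
}

# protocol engineered to give exact molar tracer rates I6 and Igal
protocol_with_rates <- function(I6, Igal) {
  pr <- infusion_protocol()
  fac <- pr$pump_rate_ml_h * 1000 / 60 / (pr$body_weight_g / 1000)
  conc <- pr$conc_mg_ml
  conc["glucose_u13c"] <- I6 * pr$mol_mass_g_mol[["glucose_u13c"]] / fac
  conc["galactose_1_2h"] <- Igal * pr$mol_mass_g_mol[["galactose_1_2h"]] / fac
  infusion_protocol(conc_mg_ml = conc,
                    pump_rate_ml_h = pr$pump_rate_ml_h,
                    body_weight_g = pr$body_weight_g)
}

# random feasible primary isotope parameter set (GP >= 0 guaranteed by
# construction: c_glc + f_udpglc < 1)
random_feasible_params <- function() {
  c_glc <- runif(1, 0.01, 0.6)
  f_udpglc <- runif(1, 0.01, 0.98 - c_glc)
  list(d_glc = runif(1, 0.01, 0.5),
       d_udpglc = runif(1, 0.01, 0.5),
       c_glc = c_glc,
       c_udpglc = runif(1, 0.05, 0.5),
       f_glc = runif(1, 0.05, 0.9),
       f_udpglc = f_udpglc)
}

# random sparse labeled MID over m+0..m+6 (dominant m+0 plus a few labels)
random_label_mid <- function() {
  x <- numeric(7)
  x[1] <- runif(1, 0.5, 1)
  k <- sample(2:7, 3)
  x[k] <- runif(3, 0, 0.2)
  x / sum(x)
}
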