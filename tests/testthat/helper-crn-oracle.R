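# Literal scalar transcription of the published CRN human atrial myocyte
# equations, written directly from the reference formulation and kept
# deliberately unoptimized. Serves as the independent oracle for the
# package's vectorized kernel; nothing here calls package internals.

crn_oracle_currents <- function(state, scales = NULL) {
  s <- as.numeric(state)
  names(s) <- c("vm", "m", "h", "j", "oa", "oi", "ua", "ui", "xr", "xs",
                "d", "f", "f_ca", "u", "v", "w", "na_i", "k_i", "ca_i",
                "ca_up", "ca_rel")
  if (is.null(scales)) scales <- rep(1, 8)
  sc <- as.numeric(scales)
  names(sc) <- c("na", "to", "cal", "kur", "k1", "ncx", "kr", "ks")

  R <- 8.3143; Temp <- 310; Fdy <- 96.4867; Cm <- 100
  Na_o <- 140; K_o <- 5.4; Ca_o <- 1.8
  V <- s[["vm"]]

  E_Na <- (R * Temp / Fdy) * log(Na_o / s[["na_i"]])
  E_K  <- (R * Temp / Fdy) * log(K_o / s[["k_i"]])
  E_Ca <- (R * Temp / (2 * Fdy)) * log(Ca_o / s[["ca_i"]])

  g_Na <- 7.8
  i_Na <- sc[["na"]] * g_Na * s[["m"]] * s[["m"]] * s[["m"]] * s[["h"]] *
    s[["j"]] * (V - E_Na)

  g_K1 <- 0.09
  i_K1 <- sc[["k1"]] * g_K1 * (V - E_K) / (1 + exp(0.07 * (V + 80)))

  g_to <- 0.1652
  i_to <- sc[["to"]] * g_to * s[["oa"]] * s[["oa"]] * s[["oa"]] *
    s[["oi"]] * (V - E_K)

  g_Kur <- 0.005 + 0.05 / (1 + exp(-(V - 15) / 13))
  i_Kur <- sc[["kur"]] * g_Kur * s[["ua"]] * s[["ua"]] * s[["ua"]] *
    s[["ui"]] * (V - E_K)

  g_Kr <- 0.029411765
  i_Kr <- sc[["kr"]] * g_Kr * s[["xr"]] * (V - E_K) /
    (1 + exp((V + 15) / 22.4))

  g_Ks <- 0.12941176
  i_Ks <- sc[["ks"]] * g_Ks * s[["xs"]] * s[["xs"]] * (V - E_K)

  g_CaL <- 0.12375
  i_CaL <- sc[["cal"]] * g_CaL * s[["d"]] * s[["f"]] * s[["f_ca"]] *
    (V - 65)

  i_NaK_max <- 0.59933874
  Km_Na_i <- 10; Km_K_o <- 1.5
  sigma <- (exp(Na_o / 67.3) - 1) / 7
  f_NaK <- 1 / (1 + 0.1245 * exp(-0.1 * Fdy * V / (R * Temp)) +
                0.0365 * sigma * exp(-Fdy * V / (R * Temp)))
  i_NaK <- i_NaK_max * f_NaK / (1 + (Km_Na_i / s[["na_i"]])^1.5) *
    K_o / (K_o + Km_K_o)

  i_NaCa_max <- 1600; gama <- 0.35; Km_Na <- 87.5; Km_Ca <- 1.38
  K_sat <- 0.1
  i_NaCa <- sc[["ncx"]] * i_NaCa_max *
    (exp(gama * Fdy * V / (R * Temp)) * s[["na_i"]] * s[["na_i"]] *
       s[["na_i"]] * Ca_o -
     exp((gama - 1) * Fdy * V / (R * Temp)) * Na_o * Na_o * Na_o *
       s[["ca_i"]]) /
    ((Km_Na * Km_Na * Km_Na + Na_o * Na_o * Na_o) * (Km_Ca + Ca_o) *
     (1 + K_sat * exp((gama - 1) * Fdy * V / (R * Temp))))

  g_B_Na <- 0.0006744375
  g_B_Ca <- 0.001131
  i_B_Na <- g_B_Na * (V - E_Na)
  i_B_Ca <- g_B_Ca * (V - E_Ca)
  i_PCa <- 0.275 * s[["ca_i"]] / (0.0005 + s[["ca_i"]])

  total <- i_Na + i_K1 + i_to + i_Kur + i_Kr + i_Ks + i_CaL + i_PCa +
    i_NaK + i_NaCa + i_B_Na + i_B_Ca
  c(na = i_Na, k1 = i_K1, to = i_to, kur = i_Kur, kr = i_Kr, ks = i_Ks,
    cal = i_CaL, p_ca = i_PCa, nak = i_NaK, ncx = i_NaCa, b_na = i_B_Na,
    b_ca = i_B_Ca, total = total)
}

# random valid CRN states inside the physiological invariant box
random_crn_states <- function(n, seed = 1) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                     .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  m <- cbind(
    vm = runif(n, -95, 45),
    matrix(runif(15 * n), n, 15,
           dimnames = list(NULL, c("m", "h", "j", "oa", "oi", "ua", "ui",
                                   "xr", "xs", "d", "f", "f_ca", "u",
                                   "v", "w"))),
    na_i = runif(n, 5, 20), k_i = runif(n, 110, 160),
    ca_i = runif(n, 5e-5, 5e-3), ca_up = runif(n, 0.2, 10),
    ca_rel = runif(n, 0.2, 10))
  m
}

# random scale factor sets
random_scales <- function(n, seed = 2) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                     .GlobalEnv) else NULL
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  matrix(runif(8 * n, 0.2, 2), n, 8,
         dimnames = list(NULL, c("na", "to", "cal", "kur", "k1", "ncx",
                                 "kr", "ks")))
}
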