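# Courtemanche-Ramirez-Nattel (CRN) human atrial ionic model, reference
# implementation. All membrane currents are expressed in pA/pF (Cm = 100 pF);
# concentrations in mM; time in ms; voltage in mV.

.crn <- list(
  Rgas = 8.3143, Temp = 310, Far = 96.4867,
  Cm = 100,
  Vi = 13668, Vup = 1109.52, Vrel = 96.48,
  Ko = 5.4, Nao = 140, Cao = 1.8,
  gNa = 7.8, gK1 = 0.09, gto = 0.1652,
  gKr = 0.029411765, gKs = 0.12941176,
  gCaL = 0.12375, gbCa = 0.00113, gbNa = 0.000674,
  INaK_max = 0.59933874, KmNai = 10, KmKo = 1.5,
  INaCa_max = 1600, KmNa = 87.5, KmCa = 1.38, ksat = 0.1, gam = 0.35,
  IpCa_max = 0.275,
  Krel = 30,
  Iup_max = 0.005, Kup = 0.00092, Caup_max = 15,
  Cmdn_max = 0.05, Trpn_max = 0.07, Csqn_max = 10,
  KmCmdn = 0.00238, KmTrpn = 0.0005, KmCsqn = 0.8,
  tau_tr = 180, tau_fca = 2, tau_u = 8, KQ10 = 3
)

#' Names of the ionic state variables
#'
#' Order used throughout the package (and by the compiled kernel): membrane
#' potential, Hodgkin-Huxley style gates, then intracellular and sarcoplasmic
#' reticulum concentrations.
#'
#' @return Character vector of the 21 state-variable names.
#' @export
crn_state_names <- function() {
  c("V", "m", "h", "j", "oa", "oi", "ua", "ui", "xr", "xs",
    "d", "f", "fca", "u", "v", "w", "Nai", "Ki", "Cai", "Caup", "Carel")
}

#' Initial (resting) state of the atrial cell model
#'
#' Standard quiescent initial conditions of the human atrial model
#' (resting potential about -81.2 mV).
#'
#' @return Named numeric vector of length 21 (see [crn_state_names()]).
#' @export
crn_initial_state <- function() {
  c(V = -81.18, m = 0.002908, h = 0.9649, j = 0.9775,
    oa = 0.03043, oi = 0.9992, ua = 0.004966, ui = 0.9986,
    xr = 3.29e-5, xs = 0.01869, d = 1.367e-4, f = 0.9996, fca = 0.7755,
    u = 0.0, v = 1.0, w = 0.9992,
    Nai = 11.17, Ki = 139.0, Cai = 1.013e-4, Caup = 1.488, Carel = 1.488)
}

#' Validate a cell state vector
#'
#' Checks finiteness, gate bounds and positivity of concentrations. Used at
#' simulation entry points and to signal numerical blow-up with the offending
#' field named.
#'
#' @param state named numeric vector as from [crn_initial_state()].
#' @param strict if `TRUE`, also require V within [-100, 60] mV.
#' @return `state`, invisibly, if valid; otherwise an error.
#' @export
validate_cell_state <- function(state, strict = TRUE) {
  nm <- crn_state_names()
  if (!all(nm %in% names(state)))
    stop("state is missing fields: ", paste(setdiff(nm, names(state)), collapse = ", "))
  state <- state[nm]
  bad <- nm[!is.finite(state)]
  if (length(bad))
    stop("non-finite state field(s): ", paste(bad, collapse = ", "),
         " (numerical blow-up)")
  gates <- nm[2:16]
  g <- state[gates]
  if (any(g < -1e-9 | g > 1 + 1e-9))
    stop("gate variable out of [0,1]: ",
         paste(gates[g < -1e-9 | g > 1 + 1e-9], collapse = ", "))
  conc <- c("Nai", "Ki", "Cai", "Caup", "Carel")
  if (any(state[conc] <= 0))
    stop("non-positive concentration: ",
         paste(conc[state[conc] <= 0], collapse = ", "))
  if (strict && (state[["V"]] < -100 || state[["V"]] > 60))
    stop("membrane potential out of range [-100, 60] mV: V = ", state[["V"]])
  invisible(state)
}

# Voltage-dependent gate kinetics. Returns list with x_inf and tau (ms) for
# every gated variable at potential V. `shift_na` moves the Na+ steady-state
# inactivation curves (h_inf, j_inf) in the depolarized direction by that many
# mV; time constants are left at their unshifted values.
crn_gates <- function(V, shift_na = 0) {
  KQ10 <- .crn$KQ10

  a_m <- if (abs(V + 47.13) < 1e-10) 3.2 else
    0.32 * (V + 47.13) / (1 - exp(-0.1 * (V + 47.13)))
  b_m <- 0.08 * exp(-V / 11)

  hj_ab <- function(V) {
    if (V >= -40) {
      a_h <- 0
      b_h <- 1 / (0.13 * (1 + exp(-(V + 10.66) / 11.1)))
      a_j <- 0
      b_j <- 0.3 * exp(-2.535e-7 * V) / (1 + exp(-0.1 * (V + 32)))
    } else {
      a_h <- 0.135 * exp(-(V + 80) / 6.8)
      b_h <- 3.56 * exp(0.079 * V) + 3.1e5 * exp(0.35 * V)
      a_j <- (-1.2714e5 * exp(0.2444 * V) - 3.474e-5 * exp(-0.04391 * V)) *
        (V + 37.78) / (1 + exp(0.311 * (V + 79.23)))
      b_j <- 0.1212 * exp(-0.01052 * V) / (1 + exp(-0.1378 * (V + 40.14)))
    }
    list(a_h = a_h, b_h = b_h, a_j = a_j, b_j = b_j)
  }
  ab <- hj_ab(V)
  tau_h <- 1 / (ab$a_h + ab$b_h)
  tau_j <- 1 / (ab$a_j + ab$b_j)
  ab_s <- hj_ab(V - shift_na)
  h_inf <- ab_s$a_h / (ab_s$a_h + ab_s$b_h)
  j_inf <- ab_s$a_j / (ab_s$a_j + ab_s$b_j)

  a_oa <- 0.65 / (exp(-(V + 10) / 8.5) + exp(-(V - 30) / 59))
  b_oa <- 0.65 / (2.5 + exp((V + 82) / 17))
  a_oi <- 1 / (18.53 + exp((V + 113.7) / 10.95))
  b_oi <- 1 / (35.56 + exp(-(V + 1.26) / 7.44))

  a_ua <- a_oa
  b_ua <- b_oa
  a_ui <- 1 / (21 + exp(-(V - 185) / 28))
  b_ui <- exp((V - 158) / 16)

  a_xr <- if (abs(V + 14.1) < 1e-10) 0.0015 else
    0.0003 * (V + 14.1) / (1 - exp(-(V + 14.1) / 5))
  b_xr <- if (abs(V - 3.3328) < 1e-10) 3.7836e-4 else
    7.3898e-5 * (V - 3.3328) / (exp((V - 3.3328) / 5.1237) - 1)
  a_xs <- if (abs(V - 19.9) < 1e-10) 6.8e-4 else
    4e-5 * (V - 19.9) / (1 - exp(-(V - 19.9) / 17))
  b_xs <- if (abs(V - 19.9) < 1e-10) 3.15e-4 else
    3.5e-5 * (V - 19.9) / (exp((V - 19.9) / 9) - 1)

  tau_d <- if (abs(V + 10) < 1e-10) 1 / (6.24 * 0.07) else
    (1 - exp(-(V + 10) / 6.24)) /
      (0.035 * (V + 10) * (1 + exp(-(V + 10) / 6.24)))
  tau_f <- 9 / (0.0197 * exp(-0.0337^2 * (V + 10)^2) + 0.02)

  tau_w <- if (abs(V - 7.9) < 1e-10) 6 / 6.5 else
    6 * (1 - exp(-(V - 7.9) / 5)) /
      ((1 + 0.3 * exp(-(V - 7.9) / 5)) * (V - 7.9))

  list(
    m = list(inf = a_m / (a_m + b_m), tau = 1 / (a_m + b_m)),
    h = list(inf = h_inf, tau = tau_h),
    j = list(inf = j_inf, tau = tau_j),
    oa = list(inf = 1 / (1 + exp(-(V + 20.47) / 17.54)),
              tau = 1 / ((a_oa + b_oa) * KQ10)),
    oi = list(inf = 1 / (1 + exp((V + 43.1) / 5.3)),
              tau = 1 / ((a_oi + b_oi) * KQ10)),
    ua = list(inf = 1 / (1 + exp(-(V + 30.3) / 9.6)),
              tau = 1 / ((a_ua + b_ua) * KQ10)),
    ui = list(inf = 1 / (1 + exp((V - 99.45) / 27.48)),
              tau = 1 / ((a_ui + b_ui) * KQ10)),
    xr = list(inf = 1 / (1 + exp(-(V + 14.1) / 6.5)),
              tau = 1 / (a_xr + b_xr)),
    xs = list(inf = 1 / sqrt(1 + exp(-(V - 19.9) / 12.7)),
              tau = 0.5 / (a_xs + b_xs)),
    d = list(inf = 1 / (1 + exp(-(V + 10) / 8)), tau = tau_d),
    f = list(inf = 1 / (1 + exp((V + 28) / 6.9)), tau = tau_f),
    w = list(inf = 1 - 1 / (1 + exp(-(V - 40) / 17)), tau = tau_w)
  )
}

#' Acetylcholine-activated potassium current
#'
#' Dose-dependent inward-rectifier K+ current carried by IKACh. The
#' conductance saturates with ACh concentration (half-maximal response near
#' 0.1 uM) and rectifies around -60 mV.
#'
#' @param V membrane potential (mV).
#' @param ACh acetylcholine concentration (uM), must be >= 0.
#' @param EK potassium reversal potential (mV).
#' @return Current density (pA/pF); 0 when `ACh = 0` or `V = EK`.
#' @export
ikach_current <- function(V, ACh, EK) {
  if (any(ACh < 0)) stop("ACh concentration must be non-negative")
  dose <- ifelse(ACh > 0, 10 / (1 + 9.13652 / ACh^0.477811), 0)
  rect <- 0.0517 + 0.4516 / (1 + exp((V + 59.53) / 17.18))
  dose * rect * (V - EK)
}

#' Time derivatives and currents of the atrial cell model
#'
#' Evaluates the full right-hand side of the human atrial ionic model with
#' the modifications carried by a [model_variant()]: conductance scalings of
#' ICaL, INaCa, IK1, Ito, IKur, IKr, IKs, a depolarizing shift of the Na+
#' steady-state inactivation curves, SR release/leak scalings, and the
#' ACh-activated K+ current added to the total K+ current.
#'
#' @param state named numeric state vector (see [crn_initial_state()]).
#' @param variant a [model_variant()]; defaults to the unmodified control.
#' @param istim stimulus current density (pA/pF); depolarizing pulses are
#'   negative by the outward-positive convention.
#' @param t time (ms), unused by the autonomous model but kept in the
#'   signature for ODE drivers.
#' @return List with `dstate` (named derivative vector, per ms) and
#'   `currents` (named vector of all current densities, pA/pF, plus SR fluxes
#'   in mM/ms).
#' @export
crn_derivatives <- function(state, variant = model_variant(), istim = 0, t = 0) {
  validate_cell_state(state, strict = FALSE)
  p <- .crn
  s <- as.list(state[crn_state_names()])
  RTF <- p$Rgas * p$Temp / p$Far

  ENa <- RTF * log(p$Nao / s$Nai)
  EK <- RTF * log(p$Ko / s$Ki)
  ECa <- RTF / 2 * log(p$Cao / s$Cai)

  g <- crn_gates(s$V, shift_na = variant$INa_inact_shift)

  INa <- p$gNa * s$m^3 * s$h * s$j * (s$V - ENa)
  IK1 <- variant$gK1_scale * p$gK1 * (s$V - EK) / (1 + exp(0.07 * (s$V + 80)))
  Ito <- variant$gto_scale * p$gto * s$oa^3 * s$oi * (s$V - EK)
  gKur <- 0.005 + 0.05 / (1 + exp(-(s$V - 15) / 13))
  IKur <- variant$gKur_scale * gKur * s$ua^3 * s$ui * (s$V - EK)
  IKr <- variant$gKr_scale * p$gKr * s$xr * (s$V - EK) /
    (1 + exp((s$V + 15) / 22.4))
  IKs <- variant$gKs_scale * p$gKs * s$xs^2 * (s$V - EK)
  ICaL <- variant$gCaL_scale * p$gCaL * s$d * s$f * s$fca * (s$V - 65)

  sig <- (exp(p$Nao / 67.3) - 1) / 7
  fNaK <- 1 / (1 + 0.1245 * exp(-0.1 * s$V / RTF) +
                 0.0365 * sig * exp(-s$V / RTF))
  INaK <- p$INaK_max * fNaK * (1 / (1 + (p$KmNai / s$Nai)^1.5)) *
    (p$Ko / (p$Ko + p$KmKo))

  e1 <- exp(p$gam * s$V / RTF)
  e2 <- exp((p$gam - 1) * s$V / RTF)
  INaCa <- variant$gNCX_scale * p$INaCa_max *
    (e1 * s$Nai^3 * p$Cao - e2 * p$Nao^3 * s$Cai) /
    ((p$KmNa^3 + p$Nao^3) * (p$KmCa + p$Cao) * (1 + p$ksat * e2))

  IbNa <- p$gbNa * (s$V - ENa)
  IbCa <- p$gbCa * (s$V - ECa)
  IpCa <- p$IpCa_max * s$Cai / (0.0005 + s$Cai)
  IKACh <- ikach_current(s$V, variant$ACh, EK)

  Irel <- variant$rel_scale * p$Krel * s$u^2 * s$v * s$w * (s$Carel - s$Cai)
  Iup <- p$Iup_max / (1 + p$Kup / s$Cai)
  Ileak <- variant$leak_scale * p$Iup_max * s$Caup / p$Caup_max
  Itr <- (s$Caup - s$Carel) / p$tau_tr

  # SR release trigger (Fn) uses currents in pA, hence the Cm factors
  Fn <- 1e-12 * p$Vrel * Irel -
    (5e-13 / p$Far) * (0.5 * ICaL * p$Cm - 0.2 * INaCa * p$Cm)
  u_inf <- 1 / (1 + exp(-(Fn - 3.4175e-13) / 1.367e-15))
  tau_v <- 1.91 + 2.09 / (1 + exp(-(Fn - 3.4175e-13) / 1.367e-15))
  v_inf <- 1 - 1 / (1 + exp(-(Fn - 6.835e-14) / 1.367e-15))
  fca_inf <- 1 / (1 + s$Cai / 0.00035)

  Iion <- INa + IK1 + Ito + IKur + IKr + IKs + ICaL + IpCa + INaK + INaCa +
    IbNa + IbCa + IKACh

  dV <- -(Iion + istim)
  dgate <- function(x, k) (k$inf - x) / k$tau

  dNai <- (-3 * INaK - 3 * INaCa - IbNa - INa) * p$Cm / (p$Far * p$Vi)
  dKi <- (2 * INaK - IK1 - Ito - IKur - IKr - IKs - IKACh) * p$Cm /
    (p$Far * p$Vi)
  B1 <- (2 * INaCa - IpCa - ICaL - IbCa) * p$Cm / (2 * p$Far * p$Vi) +
    (p$Vup * (Ileak - Iup) + Irel * p$Vrel) / p$Vi
  B2 <- 1 + p$Trpn_max * p$KmTrpn / (s$Cai + p$KmTrpn)^2 +
    p$Cmdn_max * p$KmCmdn / (s$Cai + p$KmCmdn)^2
  dCai <- B1 / B2
  dCaup <- Iup - Ileak - Itr * p$Vrel / p$Vup
  dCarel <- (Itr - Irel) /
    (1 + p$Csqn_max * p$KmCsqn / (s$Carel + p$KmCsqn)^2)

  dstate <- c(
    V = dV,
    m = dgate(s$m, g$m), h = dgate(s$h, g$h), j = dgate(s$j, g$j),
    oa = dgate(s$oa, g$oa), oi = dgate(s$oi, g$oi),
    ua = dgate(s$ua, g$ua), ui = dgate(s$ui, g$ui),
    xr = dgate(s$xr, g$xr), xs = dgate(s$xs, g$xs),
    d = dgate(s$d, g$d), f = dgate(s$f, g$f),
    fca = (fca_inf - s$fca) / p$tau_fca,
    u = (u_inf - s$u) / p$tau_u,
    v = (v_inf - s$v) / tau_v,
    w = dgate(s$w, g$w),
    Nai = dNai, Ki = dKi, Cai = dCai, Caup = dCaup, Carel = dCarel
  )
  currents <- c(
    INa = INa, IK1 = IK1, Ito = Ito, IKur = IKur, IKr = IKr, IKs = IKs,
    ICaL = ICaL, INaK = INaK, INaCa = INaCa, IbCa = IbCa, IbNa = IbNa,
    IpCa = IpCa, IKACh = IKACh, Irel = Irel, Iup = Iup, Ileak = Ileak,
    Itr = Itr, Istim = istim
  )
  list(dstate = dstate, currents = currents)
}

# Pure-R forward integrator over the reference derivatives. Slow; used as an
# independent oracle on short trajectories. Rush-Larsen for gates, forward
# Euler for V and concentrations (same scheme as the compiled kernel).
integrate_cell_r <- function(state, variant = model_variant(), duration,
                             dt = 0.02, stim_times = numeric(),
                             stim_amp = -30, stim_dur = 2,
                             record_every = 1) {
  n_steps <- round(duration / dt)
  rec_int <- max(1L, round(record_every / dt))
  nm <- crn_state_names()
  gates <- nm[2:16]
  out_t <- numeric(0); out_v <- numeric(0); out_cai <- numeric(0)
  s <- state[nm]
  for (k in seq_len(n_steps)) {
    t <- (k - 1) * dt
    istim <- if (length(stim_times) &&
                 any(t >= stim_times & t < stim_times + stim_dur)) stim_amp else 0
    # same ordering as the compiled kernel: voltage-gated variables advance
    # first (Rush-Larsen), currents are then evaluated with the new gates but
    # the old V, fca, u, v and concentrations
    g <- crn_gates(s[["V"]], shift_na = variant$INa_inact_shift)
    for (gn in c("m", "h", "j", "oa", "oi", "ua", "ui", "xr", "xs", "d", "f", "w")) {
      gi <- g[[gn]]
      s[[gn]] <- gi$inf + (s[[gn]] - gi$inf) * exp(-dt / gi$tau)
    }
    d <- crn_derivatives(s, variant, istim = istim)
    # fca, u, v: Rush-Larsen with their own (state-dependent) steady states
    cur <- d$currents
    fca_inf <- 1 / (1 + s[["Cai"]] / 0.00035)
    s[["fca"]] <- fca_inf + (s[["fca"]] - fca_inf) * exp(-dt / .crn$tau_fca)
    Fn <- 1e-12 * .crn$Vrel * cur[["Irel"]] -
      (5e-13 / .crn$Far) * (0.5 * cur[["ICaL"]] * .crn$Cm -
                              0.2 * cur[["INaCa"]] * .crn$Cm)
    ex <- exp(-(Fn - 3.4175e-13) / 1.367e-15)
    u_inf <- 1 / (1 + ex)
    tau_v <- 1.91 + 2.09 / (1 + ex)
    v_inf <- 1 - 1 / (1 + exp(-(Fn - 6.835e-14) / 1.367e-15))
    s[["u"]] <- u_inf + (s[["u"]] - u_inf) * exp(-dt / .crn$tau_u)
    s[["v"]] <- v_inf + (s[["v"]] - v_inf) * exp(-dt / tau_v)
    for (gn in c("V", "Nai", "Ki", "Cai", "Caup", "Carel"))
      s[[gn]] <- s[[gn]] + dt * d$dstate[[gn]]
    if (k %% rec_int == 0) {
      out_t <- c(out_t, k * dt); out_v <- c(out_v, s[["V"]])
      out_cai <- c(out_cai, s[["Cai"]])
    }
  }
  list(time = out_t, V = out_v, Cai = out_cai, state = s)
}
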