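# Independent reference implementation of the Courtemanche-lineage human
# atrial myocyte model as a deSolve right-hand side.  Used purely as a
# cross-check oracle for the compiled fixed-step implementation; written
# directly from the published equations, sharing no code with src/.

ctm_oracle_rhs <- function(t, y, parms) {
  with(as.list(c(y, parms)), {
    RTF <- 26.712832; Fd <- 96.4867; Cm <- 100
    Vi <- 13668; Vup <- 1109.52; Vrel <- 96.48
    Ko <- 5.4; Nao <- 140; Cao <- 1.8
    ENa <- RTF * log(Nao / Nai); EK <- RTF * log(Ko / Ki)
    ECa <- RTF / 2 * log(Cao / Cai)

    am <- if (abs(V + 47.13) < 1e-9) 3.2 else
      0.32 * (V + 47.13) / (1 - exp(-0.1 * (V + 47.13)))
    bm <- 0.08 * exp(-V / 11)
    if (V >= -40) {
      ah <- 0; bh <- 1 / (0.13 * (1 + exp(-(V + 10.66) / 11.1)))
      aj <- 0
      bj <- 0.3 * exp(-2.535e-7 * V) / (1 + exp(-0.1 * (V + 32)))
    } else {
      ah <- 0.135 * exp(-(V + 80) / 6.8)
      bh <- 3.56 * exp(0.079 * V) + 3.1e5 * exp(0.35 * V)
      aj <- (-1.2714e5 * exp(0.2444 * V) - 3.474e-5 * exp(-0.04391 * V)) *
        (V + 37.78) / (1 + exp(0.311 * (V + 79.23)))
      bj <- 0.1212 * exp(-0.01052 * V) / (1 + exp(-0.1378 * (V + 40.14)))
    }
    ina <- 7.8 * m^3 * h * j * (V - ENa)
    ik1 <- 0.09 * (V - EK) / (1 + exp(0.07 * (V + 80)))

    aoa <- 0.65 / (exp(-(V + 10) / 8.5) + exp(-(V - 30) / 59))
    boa <- 0.65 / (2.5 + exp((V + 82) / 17))
    oainf <- 1 / (1 + exp(-(V + 20.47) / 17.54))
    aoi <- 1 / (18.53 + exp((V + 113.7) / 10.95))
    boi <- 1 / (35.56 + exp(-(V + 1.26) / 7.44))
    oiinf <- 1 / (1 + exp((V + 43.1) / 5.3))
    ito <- 0.1652 * oa^3 * oi * (V - EK)

    aua <- aoa; bua <- boa
    uainf <- 1 / (1 + exp(-(V + 30.3) / 9.6))
    aui <- 1 / (21 + exp(-(V - 185) / 28))
    bui <- exp((V - 158) / 16)
    uiinf <- 1 / (1 + exp((V - 99.45) / 27.48))
    gkur <- 0.005 + 0.05 / (1 + exp(-(V - 15) / 13))
    ikur <- gkur * ua^3 * ui * (V - EK)

    axr <- 0.0003 * (V + 14.1) / (1 - exp(-(V + 14.1) / 5))
    bxr <- 7.3898e-5 * (V - 3.3328) / (exp((V - 3.3328) / 5.1237) - 1)
    xrinf <- 1 / (1 + exp(-(V + 14.1) / 6.5))
    ikr <- 0.029411765 * xr * (V - EK) / (1 + exp((V + 15) / 22.4))

    axs <- 4e-5 * (V - 19.9) / (1 - exp(-(V - 19.9) / 17))
    bxs <- 3.5e-5 * (V - 19.9) / (exp((V - 19.9) / 9) - 1)
    xsinf <- 1 / sqrt(1 + exp(-(V - 19.9) / 12.7))
    iks <- 0.12941176 * xs^2 * (V - EK)

    dinf <- 1 / (1 + exp(-(V + 10) / 8))
    taud <- (1 - exp(-(V + 10) / 6.24)) /
      (0.035 * (V + 10) * (1 + exp(-(V + 10) / 6.24)))
    finf <- 1 / (1 + exp((V + 28) / 6.9))
    tauf <- 9 / (0.0197 * exp(-0.0337^2 * (V + 10)^2) + 0.02)
    fcainf <- 1 / (1 + Cai / 0.00035)
    ical <- 0.12375 * d * f * fca * (V - 65)

    sigma <- (exp(Nao / 67.3) - 1) / 7
    fnak <- 1 / (1 + 0.1245 * exp(-0.1 * V / RTF) +
                   0.0365 * sigma * exp(-V / RTF))
    inak <- 0.59933874 * fnak / (1 + (10 / Nai)^1.5) * Ko / (Ko + 1.5)
    incx <- 1600 * (exp(0.35 * V / RTF) * Nai^3 * Cao -
                      exp(-0.65 * V / RTF) * Nao^3 * Cai) /
      ((87.5^3 + Nao^3) * (1.38 + Cao) *
         (1 + 0.1 * exp(-0.65 * V / RTF)))
    ipca <- 0.275 * Cai / (0.0005 + Cai)
    ibna <- 0.0006744375 * (V - ENa)
    ibca <- 0.00113 * (V - ECa)

    irel <- 30 * u^2 * vg * w * (Carel - Cai)
    fn <- 1e3 * (1e-15 * Vrel * irel -
                   1e-15 / (2 * Fd) * (0.5 * ical * Cm - 0.2 * incx * Cm))
    uinf <- 1 / (1 + exp(-(fn - 3.4175e-13) / 13.67e-16))
    vinf <- 1 - 1 / (1 + exp(-(fn - 6.835e-14) / 13.67e-16))
    tauv <- 1.91 + 2.09 / (1 + exp(-(fn - 3.4175e-13) / 13.67e-16))
    winf <- 1 - 1 / (1 + exp(-(V - 40) / 17))
    tauw <- if (abs(V - 7.9) < 1e-6) 6 * 0.2 / 1.3 else
      6 * (1 - exp(-(V - 7.9) / 5)) /
        ((1 + 0.3 * exp(-(V - 7.9) / 5)) * (V - 7.9))

    itr <- (Caup - Carel) / 180
    iup <- 0.005 / (1 + 0.00092 / Cai)
    iupleak <- 0.005 * Caup / 15

    istim <- if (t %% parms[["cl"]] >= 10 && t %% parms[["cl"]] < 12)
      parms[["amp"]] else 0

    cfac <- Cm / (Fd * Vi)
    b1 <- (2 * incx - ipca - ical - ibca) * 0.5 * cfac +
      (Vup * (iupleak - iup) + irel * Vrel) / Vi
    b2 <- 1 + 0.07 * 0.0005 / (Cai + 0.0005)^2 +
      0.05 * 0.00238 / (Cai + 0.00238)^2

    list(c(
      V = -(ina + ik1 + ito + ikur + ikr + iks + ical + ipca + inak +
              incx + ibna + ibca) + istim,
      m = am * (1 - m) - bm * m,
      h = ah * (1 - h) - bh * h,
      j = aj * (1 - j) - bj * j,
      # these gates pair independent steady-state curves with rate-derived
      # time constants (tau = 1/(K_Q10 (alpha + beta)))
      oa = (oainf - oa) * 3 * (aoa + boa),
      oi = (oiinf - oi) * 3 * (aoi + boi),
      ua = (uainf - ua) * 3 * (aua + bua),
      ui = (uiinf - ui) * 3 * (aui + bui),
      xr = (xrinf - xr) * (axr + bxr),
      xs = (xsinf - xs) * 2 * (axs + bxs),
      d = (dinf - d) / taud,
      f = (finf - f) / tauf,
      fca = (fcainf - fca) / 2,
      u = (uinf - u) / 8,
      vg = (vinf - vg) / tauv,
      w = (winf - w) / tauw,
      Nai = -(3 * inak + 3 * incx + ibna + ina) * cfac,
      Ki = (2 * inak - ik1 - ito - ikur - ikr - iks) * cfac,
      Cai = b1 / b2,
      Caup = iup - iupleak - itr * Vrel / Vup,
      Carel = (itr - irel) / (1 + 10 * 0.8 / (Carel + 0.8)^2)
    ))
  })
}

ctm_oracle_trace <- function(n_beats = 5, cl = 1000, amp = 25) {
  y0 <- c(V = -81.18, m = 0.002908, h = 0.9649, j = 0.9775, oa = 0.03043,
          oi = 0.9992, ua = 0.004966, ui = 0.9986, xr = 3.296e-5,
          xs = 0.01869, d = 1.367e-4, f = 0.9996, fca = 0.7755, u = 0,
          vg = 1, w = 0.9992, Nai = 11.17, Ki = 139, Cai = 1.013e-4,
          Caup = 1.488, Carel = 1.488)
  times <- seq(0, n_beats * cl, by = 0.5)
  # hmax bounds the step so the 2 ms stimulus pulse is never stepped over
  out <- deSolve::lsoda(y0, times, ctm_oracle_rhs, c(cl = cl, amp = amp),
                        rtol = 1e-8, atol = 1e-8, maxsteps = 1e6,
                        hmax = 0.5)
  tibble::tibble(time_ms = out[, "time"], v_mV = out[, "V"])
}
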