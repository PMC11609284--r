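# ERP templates: the forward model injects, per event, a spatial pattern
# times a time-limited waveform. Default templates mirror the components the
# task elicits, with condition gains set to the direction of the reported
# effects (magnitudes are configurable simulation choices, not measured
# values):
#   HEP  (R-locked,       300-400 ms, fronto-central): diastole < others
#   P2   (movement-locked, 200-300 ms, fronto-central): diastole > systole
#   N2   (stop-locked,     200-300 ms, fronto-central, negative):
#        diastole < others
#   P3   (commission-feedback-locked, 300-400 ms, central): systole > others

#' Construct an ERP template
#'
#' @param name template label.
#' @param eventType event type it locks to.
#' @param windowMs latency support (ms post event), half-open.
#' @param amplitude peak amplitude (microvolts; sign = polarity).
#' @param channelWeights named numeric of per-channel gains.
#' @param conditionGains named numeric of per-condition multipliers
#'   (conditions not named get gain 1).
#' @param shape "hann" (raised-cosine bump), "square", or "qrst" (sharp
#'   QRS-like deflection plus a slow T-range bow; used for the cardiac
#'   field artifact).
#' @param eventDetail optional detail filter (e.g. "commission" feedback).
#' @return an [ErpTemplate-class]
#' @export
erpTemplate <- function(name, eventType, windowMs, amplitude, channelWeights,
                        conditionGains = c(systole = 1, diastole = 1, none = 1),
                        shape = "hann", eventDetail = NA_character_) {
  new("ErpTemplate", name = name, eventType = eventType,
      eventDetail = eventDetail, windowMs = as.numeric(windowMs),
      amplitude = amplitude, shape = shape,
      channelWeights = channelWeights, conditionGains = conditionGains)
}

#' Evaluate a template waveform at latencies
#'
#' Zero outside the latency support (half-open \code{[start, end)}).
#'
#' @param template an [ErpTemplate-class].
#' @param tMs numeric latencies in ms post event.
#' @return numeric waveform in microvolts (before channel/condition gains)
#' @export
templateWaveform <- function(template, tMs) {
  w <- template@windowMs
  u <- (tMs - w[1]) / (w[2] - w[1])
  inside <- u >= 0 & u < 1
  y <- numeric(length(tMs))
  if (template@shape == "hann") {
    y[inside] <- template@amplitude * 0.5 * (1 - cos(2 * pi * u[inside]))
  } else if (template@shape == "square") {
    y[inside] <- template@amplitude
  } else {  # qrst
    a <- template@amplitude
    g <- function(c, amp, w) amp * exp(-0.5 * ((tMs - c) / w)^2)
    yy <- g(0, a, 10) + g(40, -0.3 * a, 14) + g(250, 0.25 * a, 45)
    y[inside] <- yy[inside]
  }
  y
}

#' Condition gain of a template
#' @param template an [ErpTemplate-class].
#' @param condition condition label.
#' @return numeric multiplier (1 if the condition is not listed)
#' @export
templateGain <- function(template, condition) {
  g <- template@conditionGains[condition]
  ifelse(is.na(g), 1, unname(g))
}

#' Gaussian spatial weights centered on an electrode
#'
#' @param montage montage data.frame (label, x_cm, y_cm, z_cm).
#' @param center electrode label at the peak.
#' @param sigmaCm spatial falloff (cm).
#' @return named numeric weights in (0, 1], one per montage channel
#' @export
spatialWeights <- function(montage, center, sigmaCm = 3.5) {
  i <- match(center, montage$label)
  if (is.na(i)) stop("unknown center electrode: ", center)
  xyz <- as.matrix(montage[, c("x_cm", "y_cm", "z_cm")])
  d <- sqrt(rowSums(sweep(xyz, 2, xyz[i, ])^2))
  w <- exp(-0.5 * (d / sigmaCm)^2)
  names(w) <- montage$label
  w
}

#' Default ERP templates for the simulated task
#'
#' @param montage montage data.frame.
#' @param hepGainDiastole,p2GainSystole,n2GainDiastole,p3GainSystole
#'   condition gains implementing the direction of the condition effects;
#'   set a gain to 1 to switch the corresponding effect off.
#' @return named list of [ErpTemplate-class] objects (HEP, P2, N2, P3)
#' @export
defaultErpTemplates <- function(montage,
                                hepGainDiastole = 0.7,
                                p2GainSystole = 0.7,
                                n2GainDiastole = 0.65,
                                p3GainSystole = 1.4) {
  list(
    HEP = erpTemplate("HEP", "r_peak", c(300, 400), amplitude = 2,
                      channelWeights = spatialWeights(montage, "FCz", 3.0),
                      conditionGains = c(systole = 1,
                                         diastole = hepGainDiastole,
                                         none = 1)),
    P2 = erpTemplate("P2", "distractor_move", c(200, 300), amplitude = 5,
                     channelWeights = spatialWeights(montage, "FCz", 4.5),
                     conditionGains = c(systole = p2GainSystole,
                                        diastole = 1, none = 1)),
    N2 = erpTemplate("N2", "stop_signal", c(200, 300), amplitude = -4,
                     channelWeights = spatialWeights(montage, "Fz", 3.0),
                     conditionGains = c(systole = 1,
                                        diastole = n2GainDiastole, none = 1)),
    P3 = erpTemplate("P3", "feedback", c(300, 400), amplitude = 6,
                     channelWeights = spatialWeights(montage, "CPz", 3.5),
                     conditionGains = c(systole = p3GainSystole,
                                        diastole = 1, none = 1),
                     eventDetail = "commission")
  )
}

#' Default cardiac-field-artifact template
#'
#' An R-locked artifact with a sharp QRS-like deflection and a slow T-range
#' bow, projected with a left-right scalp gradient (the cardiac dipole seen
#' from the scalp), identical in every condition.
#'
#' @param montage montage data.frame.
#' @param amplitude peak artifact amplitude (microvolts).
#' @return an [ErpTemplate-class] locked to r_peak events
#' @export
defaultCfaTemplate <- function(montage, amplitude = 15) {
  # lateral gradient plus a weak uniform part; never exactly zero anywhere
  w <- 0.75 * montage$y_cm / max(abs(montage$y_cm)) + 0.25
  names(w) <- montage$label
  erpTemplate("CFA", "r_peak", c(-50, 450), amplitude = amplitude,
              channelWeights = w, shape = "qrst")
}
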