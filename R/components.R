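# Linear component decomposition, ECG-coherence ranking and removal.
#
# The default decomposition uses the simulator's known forward model (one
# component per injected template plus per-channel residual components), so
# ranking, deletion and reconstruction are exercised on exact ground truth;
# a blind decomposition hook (PCA) is provided for data without ground
# truth. Reconstruction is lossless when nothing is removed.

#' Construct a ComponentSet
#'
#' @param sources components x samples matrix.
#' @param mixing channels x components matrix.
#' @param fs sampling rate (Hz).
#' @param channels channel labels.
#' @param componentNames labels per component.
#' @return a [ComponentSet-class]
#' @export
componentSet <- function(sources, mixing, fs, channels,
                         componentNames = NULL) {
  if (is.null(componentNames))
    componentNames <- paste0("IC", seq_len(nrow(sources)))
  new("ComponentSet", sources = sources, mixing = mixing, fs = fs,
      channels = channels, componentNames = componentNames,
      coherence = rep(NA_real_, nrow(sources)), rankOrder = integer(0))
}

#' Decompose a simulated session's EEG with its known forward model
#'
#' Components are the injected template sources (exact mixing weights from
#' the ground truth) plus one residual component per channel capturing
#' noise; mixing %*% sources reproduces the EEG exactly.
#'
#' @param session a [SimulatedSession-class] simulated with EEG.
#' @return a [ComponentSet-class]
#' @export
sessionComponentSet <- function(session) {
  gt <- groundTruth(session)
  if (is.null(gt$mixing))
    stop("session was simulated without EEG; no forward model available")
  eeg <- sessionEeg(session)
  resid <- eeg - gt$mixing %*% gt$sources
  nCh <- nrow(eeg)
  mixing <- cbind(gt$mixing, diag(nCh))
  sources <- rbind(gt$sources, resid)
  componentSet(sources, mixing, fs = sessionConfig(session)@eegFs,
               channels = rownames(eeg),
               componentNames = c(colnames(gt$mixing),
                                  paste0("resid_", rownames(eeg))))
}

#' Blind decomposition hook: principal components
#'
#' @param eeg channels x samples matrix.
#' @param fs sampling rate (Hz).
#' @return a [ComponentSet-class] with as many components as channels
#' @export
pcaComponentSet <- function(eeg, fs) {
  ctr <- rowMeans(eeg)
  X <- eeg - ctr
  sv <- svd(X)
  mixing <- sv$u %*% diag(sv$d)
  sources <- t(sv$v)
  # fold the channel means into the first component reconstruction offset
  mixing <- cbind(mixing, ctr)
  sources <- rbind(sources, rep(1, ncol(eeg)))
  componentSet(sources, mixing, fs = fs,
               channels = rownames(eeg),
               componentNames = c(paste0("PC", seq_len(nrow(eeg))), "mean"))
}

# Welch magnitude-squared coherence of two equally long series, averaged
# over a frequency band. Hamming-windowed segments with 50% overlap.
welchCoherence <- function(x, y, fs, bandHz = c(0.5, 10), segLenS = 4) {
  n <- length(x)
  L <- min(n, round(segLenS * fs))
  step <- max(1L, floor(L / 2))
  starts <- seq(1L, n - L + 1L, by = step)
  if (length(starts) < 2) starts <- c(1L, max(1L, n - L + 1L))
  w <- 0.54 - 0.46 * cos(2 * pi * seq_len(L) / (L + 1))
  Sxx <- Syy <- numeric(L)
  Sxy <- complex(L)
  for (s in starts) {
    xi <- fft((x[s:(s + L - 1L)] - mean(x[s:(s + L - 1L)])) * w)
    yi <- fft((y[s:(s + L - 1L)] - mean(y[s:(s + L - 1L)])) * w)
    Sxx <- Sxx + Mod(xi)^2
    Syy <- Syy + Mod(yi)^2
    Sxy <- Sxy + xi * Conj(yi)
  }
  f <- (seq_len(L) - 1) * fs / L
  band <- f >= bandHz[1] & f <= bandHz[2]
  if (!any(band)) return(NA_real_)
  msc <- Mod(Sxy[band])^2 / (Sxx[band] * Syy[band])
  mean(msc[is.finite(msc)])
}

#' Rank components by their coherence with the ECG
#'
#' Computes, per component, the magnitude-squared coherence between the
#' component time course and the ECG (Welch-averaged spectra, mean over
#' 0.5-10 Hz by default), or their absolute Pearson correlation, and ranks
#' components in descending order. Constant (degenerate) components have
#' undefined coherence and are ranked last.
#'
#' @param components a [ComponentSet-class].
#' @param ecg numeric ECG samples or an [EcgSignal-class]; linearly
#'   interpolated onto the component time grid when the rates differ.
#' @param ecgFs sampling rate of \code{ecg} when given as a plain vector.
#' @param bandHz coherence band (Hz).
#' @param method "coherence" (frequency-resolved) or "correlation" (scalar).
#' @param topN optional truncation: keep only the topN most coherent
#'   components in the ranking.
#' @return the [ComponentSet-class] with coherence scores and rank order
#' @export
rankComponentsByEcgCoherence <- function(components, ecg, ecgFs = NULL,
                                         bandHz = c(0.5, 10),
                                         method = c("coherence", "correlation"),
                                         topN = NULL) {
  method <- match.arg(method)
  if (is(ecg, "EcgSignal")) {
    ecgFs <- ecg@fs
    ecg <- ecg@samples
  }
  if (is.null(ecgFs)) stop("ecgFs required for a plain ECG vector")
  fs <- components@fs
  nS <- ncol(components@sources)
  if (ecgFs != fs || length(ecg) != nS) {
    tOut <- (seq_len(nS) - 1) / fs
    tIn <- (seq_along(ecg) - 1) / ecgFs
    ecg <- approx(tIn, ecg, xout = tOut, rule = 2)$y
  }
  coh <- vapply(seq_len(nrow(components@sources)), function(k) {
    s <- components@sources[k, ]
    if (sd(s) == 0) return(NA_real_)     # constant: undefined, ranked last
    if (method == "coherence") welchCoherence(s, ecg, fs, bandHz)
    else abs(stats::cor(s, ecg))
  }, 0)
  ord <- order(coh, decreasing = TRUE, na.last = TRUE)
  if (!is.null(topN)) ord <- head(ord, topN)
  initialize(components, coherence = coh, rankOrder = as.integer(ord))
}

#' Reconstruct EEG without selected components
#'
#' @param components a [ComponentSet-class].
#' @param indices integer indices (into the component set) to remove;
#'   empty restores the input signal.
#' @return channels x samples matrix
#' @export
removeComponents <- function(components, indices = integer(0)) {
  k <- nrow(components@sources)
  if (length(indices)) {
    if (any(indices < 1 | indices > k)) stop("component index out of range")
    if (length(unique(indices)) == k) {
      warning("removing all components; result is the zero signal")
      out <- matrix(0, nrow(components@mixing), ncol(components@sources))
      rownames(out) <- components@channels
      return(out)
    }
  }
  keep <- setdiff(seq_len(k), indices)
  out <- components@mixing[, keep, drop = FALSE] %*%
    components@sources[keep, , drop = FALSE]
  rownames(out) <- components@channels
  out
}
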