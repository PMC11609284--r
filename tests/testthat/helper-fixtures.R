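# Shared fixtures: all synthetic, built in code.

# a light session configuration for fast tests
tinyConfig <- function(conditions = c("systole", "diastole", "none"),
                       trialsPerBlock = 6L, goPerBlock = 4L,
                       stopPerBlock = 2L, eegFs = 250, ...) {
  sessionConfigNew(conditions = conditions, trialsPerBlock = trialsPerBlock,
                   goPerBlock = goPerBlock, stopPerBlock = stopPerBlock,
                   eegFs = eegFs, ...)
}

# constant-RR timeline (exactly periodic heart)
constantTimeline <- function(nBeats = 30, rrMs = 1000, t0 = 2) {
  cardiacTimeline(rep(rrMs, nBeats - 1), t0 = t0)
}

# minimal event table for renderEeg
eventTable <- function(times, type = "r_peak", condition = "none",
                       detail = NA_character_) {
  n <- length(times)
  data.frame(trial_id = rep(NA_integer_, n), block = rep(NA_integer_, n),
             condition = rep_len(condition, n),
             event_type = rep_len(type, n), detail = rep_len(detail, n),
             time_s = times, stringsAsFactors = FALSE)
}

# amplitude of a sinusoid in the steady-state interior of a signal
interiorAmplitude <- function(x, frac = 0.25) {
  n <- length(x)
  i <- seq(floor(n * frac), ceiling(n * (1 - frac)))
  (max(x[i]) - min(x[i])) / 2
}

# independent brute-force cluster machinery for small maps (R only, no
# shared code with the package): same-sign suprathreshold cells clustered
# by temporal adjacency and an explicit channel-neighbour list
bruteClusterSums <- function(tmap, thr, neighbours) {
  nch <- nrow(tmap); ns <- ncol(tmap)
  supra <- which(abs(tmap) > thr, arr.ind = TRUE)
  if (!nrow(supra)) return(numeric(0))
  key <- function(c, s) paste(c, s)
  unseen <- new.env()
  for (i in seq_len(nrow(supra))) assign(key(supra[i, 1], supra[i, 2]), TRUE, unseen)
  sums <- numeric(0)
  for (i in seq_len(nrow(supra))) {
    k0 <- key(supra[i, 1], supra[i, 2])
    if (!exists(k0, unseen)) next
    queue <- list(supra[i, ])
    rm(list = k0, envir = unseen)
    acc <- 0
    sgn <- sign(tmap[supra[i, 1], supra[i, 2]])
    while (length(queue)) {
      cell <- queue[[1]]; queue <- queue[-1]
      acc <- acc + tmap[cell[1], cell[2]]
      cand <- rbind(
        if (cell[2] > 1) c(cell[1], cell[2] - 1),
        if (cell[2] < ns) c(cell[1], cell[2] + 1),
        if (length(neighbours[[cell[1]]]))
          cbind(neighbours[[cell[1]]], cell[2]))
      for (j in seq_len(NROW(cand))) {
        cc <- cand[j, 1]; ss <- cand[j, 2]
        kk <- key(cc, ss)
        if (exists(kk, unseen) && sign(tmap[cc, ss]) == sgn &&
            abs(tmap[cc, ss]) > thr) {
          rm(list = kk, envir = unseen)
          queue[[length(queue) + 1]] <- c(cc, ss)
        }
      }
    }
    sums <- c(sums, acc)
  }
  sums
}

# plain dependent-samples t over subjects for each cell of a 3-D array pair
bruteTMap <- function(A, B) {
  n <- dim(A)[1]
  m <- matrix(0, dim(A)[2], dim(A)[3])
  for (c in seq_len(dim(A)[2])) for (s in seq_len(dim(A)[3])) {
    d <- A[, c, s] - B[, c, s]
    m[c, s] <- mean(d) / (sd(d) / sqrt(n))
  }
  m
}
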