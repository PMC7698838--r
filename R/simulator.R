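#' @title Synthetic polysomnography simulator
#' @description Generates hypnograms from a first-order Markov stage model
#'   and stage-conditioned multi-channel signals whose per-channel spectral
#'   content differs by stage (slow high-amplitude EEG in N3, minimal EMG in
#'   REM, large slow EOG deflections in REM, ...), so the classifier and
#'   every downstream module can be exercised without clinical recordings.
#' @name simulator
NULL

#' Default stage transition model
#'
#' A 5x5 row-stochastic transition matrix with strong sleep continuity
#' (every diagonal entry >= 0.55) and a qualitatively realistic structure:
#' N1 is the least stable stage, N3 is entered mainly from N2, REM returns
#' mostly to itself or light sleep. The initial distribution places most
#' mass on wake. The stationary distribution is roughly
#' W .22, N1 .08, N2 .37, N3 .18, REM .15.
#'
#' @return A list with `matrix` (5x5, rows = from-stage in W,N1,N2,N3,REM
#'   order) and `initial` (length-5 distribution), class
#'   `"transition_model"`.
#' @export
default_transition_model <- function() {
  A <- matrix(c(
    0.90, 0.07, 0.02, 0.00, 0.01,  # from W
    0.10, 0.55, 0.30, 0.00, 0.05,  # from N1
    0.02, 0.04, 0.85, 0.06, 0.03,  # from N2
    0.01, 0.00, 0.11, 0.88, 0.00,  # from N3
    0.03, 0.05, 0.04, 0.00, 0.88   # from REM
  ), nrow = 5, byrow = TRUE,
  dimnames = list(stage_labels(), stage_labels()))
  transition_model(A, initial = c(0.60, 0.20, 0.10, 0.05, 0.05))
}

#' Construct and validate a transition model
#' @param matrix 5x5 row-stochastic matrix (rows sum to 1, entries >= 0).
#' @param initial length-5 distribution over the starting stage.
#' @return A validated `"transition_model"` list.
#' @export
transition_model <- function(matrix, initial = rep(1 / 5, 5)) {
  matrix <- as.matrix(matrix)
  if (!all(dim(matrix) == c(5, 5))) stop("transition matrix must be 5x5")
  if (any(matrix < 0) || any(initial < 0)) {
    stop("transition probabilities must be nonnegative")
  }
  if (any(abs(rowSums(matrix) - 1) > 1e-9)) {
    stop("transition matrix rows must sum to 1 (tolerance 1e-9)")
  }
  if (abs(sum(initial) - 1) > 1e-9) stop("initial distribution must sum to 1")
  structure(list(matrix = matrix, initial = as.numeric(initial)),
            class = "transition_model")
}

#' Simulate a hypnogram from a stage transition model
#'
#' Draws per-epoch stages from a first-order Markov chain. Sleep staging is
#' strongly autocorrelated (an epoch's stage is usually its predecessor's),
#' which is exactly what the diagonal mass of the matrix encodes.
#'
#' @param model a `"transition_model"` (see [default_transition_model()]).
#' @param n_epochs number of 30-s epochs to draw (>= 1).
#' @param seed integer seed; fixed seed gives a reproducible hypnogram.
#' @return A [hypnogram()] of length `n_epochs`.
#' @export
simulate_hypnogram <- function(model, n_epochs, seed = 1L) {
  if (!inherits(model, "transition_model")) {
    model <- transition_model(model$matrix, model$initial)
  }
  n_epochs <- as.integer(n_epochs)
  if (n_epochs < 1L) stop("n_epochs must be >= 1")
  set.seed(seed)
  s <- integer(n_epochs)
  s[1L] <- sample.int(5L, 1L, prob = model$initial)
  if (n_epochs > 1L) {
    u <- stats::runif(n_epochs - 1L)
    cum <- t(apply(model$matrix, 1L, cumsum))
    for (t in 2:n_epochs) {
      s[t] <- findInterval(u[t - 1L], cum[s[t - 1L], ]) + 1L
    }
  }
  hypnogram(s - 1L)
}

#' Default stage-conditioned spectral profiles
#'
#' Encodes the qualitative AASM stage signatures per channel role:
#' \itemize{
#'   \item W: alpha-band (8-12 Hz) EEG, high broadband EMG tone;
#'   \item N1: theta (4-8 Hz) EEG, slow rolling EOG, reduced EMG;
#'   \item N2: theta background plus sigma-band (12-14 Hz) spindle energy;
#'   \item N3: high-amplitude slow-wave (0.5-4 Hz) EEG;
#'   \item REM: low-amplitude mixed-frequency EEG, large slow EOG
#'     deflections, minimal EMG.
#' }
#' Band powers are relative (unitless); `amplitude_scale` multiplies the
#' whole channel per stage (for example, REM EEG is low amplitude).
#'
#' @return Named list (one element per stage) of `"stage_profile"` objects
#'   with `band_powers` (per role: data.frame low/high/power) and
#'   `amplitude_scale` (named per role).
#' @export
default_stage_profiles <- function() {
  bp <- function(...) {
    m <- matrix(c(...), ncol = 3, byrow = TRUE)
    data.frame(low = m[, 1], high = m[, 2], power = m[, 3])
  }
  prof <- function(stage, eeg, eog, emg, amp) {
    structure(list(stage = stage,
                   band_powers = list(eeg = eeg, eog = eog, emg = emg),
                   amplitude_scale = amp),
              class = "stage_profile")
  }
  list(
    W = prof("W",
             eeg = bp(8, 12, 1.0, 1, 30, 0.3),
             eog = bp(0.5, 2, 0.4, 1, 15, 0.4),
             emg = bp(20, 45, 1.0),
             amp = c(eeg = 1.0, eog = 1.0, emg = 1.6)),
    N1 = prof("N1",
              eeg = bp(4, 8, 1.0, 8, 12, 0.2),
              eog = bp(0.3, 1, 0.8, 1, 10, 0.2),
              emg = bp(20, 45, 1.0),
              amp = c(eeg = 1.0, eog = 1.0, emg = 0.7)),
    N2 = prof("N2",
              eeg = bp(4, 8, 0.8, 12, 14, 0.8, 0.5, 2, 0.2),
              eog = bp(0.3, 2, 0.3, 1, 10, 0.2),
              emg = bp(20, 45, 1.0),
              amp = c(eeg = 1.1, eog = 0.6, emg = 0.5)),
    N3 = prof("N3",
              eeg = bp(0.5, 4, 2.0, 4, 8, 0.3),
              eog = bp(0.3, 2, 0.4),
              emg = bp(20, 45, 1.0),
              amp = c(eeg = 1.8, eog = 0.5, emg = 0.4)),
    REM = prof("REM",
               eeg = bp(2, 20, 0.6),
               eog = bp(0.3, 1, 1.5, 1, 5, 0.3),
               emg = bp(20, 45, 1.0),
               amp = c(eeg = 0.7, eog = 1.3, emg = 0.15))
  )
}

#' Simulator configuration
#'
#' @param n_subjects number of subjects (one recording each).
#' @param epochs_per_subject epochs per recording.
#' @param sampling_rate Hz; `epoch_seconds * sampling_rate` must be integer.
#' @param epoch_seconds scoring epoch length in seconds (30 by convention).
#' @param channels named character vector mapping channel name to role, one
#'   of "eeg", "eog", "emg"; e.g. `c(EEG = "eeg", EOG = "eog", EMG = "emg")`.
#' @param noise_sigma sd of additive white noise on informative channels.
#' @param uninformative_channels channel names carrying unit-variance white
#'   noise only (no stage information), used for attention ablations.
#' @param amplitude_jitter per-subject, per-channel uniform amplitude jitter
#'   half-width (0.1 = +/-10%), emulating inter-individual differences.
#' @param seed master seed; per-subject streams are derived from it.
#' @return A validated `"sim_config"` list.
#' @export
sim_config <- function(n_subjects = 6L, epochs_per_subject = 300L,
                       sampling_rate = 100, epoch_seconds = 30,
                       channels = c(EEG = "eeg", EOG = "eog", EMG = "emg"),
                       noise_sigma = 0.2,
                       uninformative_channels = character(0),
                       amplitude_jitter = 0.1, seed = 1L) {
  if (length(channels) < 1L || is.null(names(channels))) {
    stop("channels must be a non-empty named vector of roles")
  }
  if (!all(channels %in% c("eeg", "eog", "emg"))) {
    stop("channel roles must be one of 'eeg', 'eog', 'emg'")
  }
  spe <- epoch_seconds * sampling_rate
  if (abs(spe - round(spe)) > 1e-9) {
    stop("epoch_seconds * sampling_rate must be an integer")
  }
  if (!all(uninformative_channels %in% names(channels))) {
    stop("uninformative_channels must be a subset of channel names")
  }
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(
    n_subjects = as.integer(n_subjects),
    epochs_per_subject = as.integer(epochs_per_subject),
    sampling_rate = sampling_rate,
    epoch_seconds = epoch_seconds,
    channels = channels,
    noise_sigma = noise_sigma,
    uninformative_channels = uninformative_channels,
    amplitude_jitter = amplitude_jitter,
    seed = as.integer(seed)
  ), class = "sim_config")
}

# Unit-sd band-limited Gaussian noise, one column per epoch, via FFT masking.
band_limited_noise <- function(n, m, low, high, rate) {
  x <- matrix(stats::rnorm(n * m), n, m)
  f <- stats::mvfft(x)
  freq <- (seq_len(n) - 1) / n * rate
  freq <- pmin(freq, rate - freq)  # fold to two-sided magnitude
  f[!(freq >= low & freq <= high), ] <- 0
  y <- Re(stats::mvfft(f, inverse = TRUE)) / n
  sdv <- sqrt(pmax(colMeans(y^2) - colMeans(y)^2, 1e-24))
  sweep(y, 2L, sdv, "/")
}

#' Construct an epoch array
#' @param x numeric array `[n_epochs, samples_per_epoch, n_channels]`.
#' @param channels channel names (length = 3rd dim).
#' @param roles channel roles, same length.
#' @param sampling_rate Hz.
#' @param epoch_seconds epoch length (s).
#' @return The array with class `"epoch_array"` and metadata attributes.
#' @export
epoch_array <- function(x, channels, roles = NULL, sampling_rate,
                        epoch_seconds = 30) {
  stopifnot(length(dim(x)) == 3L, dim(x)[3] == length(channels))
  structure(x, channels = channels, roles = roles,
            sampling_rate = sampling_rate, epoch_seconds = epoch_seconds,
            class = "epoch_array")
}

#' @export
print.epoch_array <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<epoch_array> %d epochs x %d samples x %d channels (%g Hz)\n",
              d[1], d[2], d[3], attr(x, "sampling_rate")))
  cat("channels:", paste(attr(x, "channels"), collapse = ", "), "\n")
  invisible(x)
}

#' Synthesize stage-conditioned multi-channel signal epochs
#'
#' Each epoch of each informative channel is a sum of unit-variance
#' band-limited Gaussian noise components weighted by the square root of the
#' stage's relative band powers, plus white noise of sd `noise_sigma`, all
#' multiplied by the stage's per-role amplitude scale (and an optional
#' per-channel `jitter` factor). Channels listed in
#' `config$uninformative_channels` carry unit-variance white noise only.
#'
#' @param hyp a [hypnogram()].
#' @param config a [sim_config()].
#' @param profiles per-stage profiles as from [default_stage_profiles()].
#' @param jitter optional named numeric, per-channel amplitude multipliers.
#' @param seed seed for this synthesis (defaults to `config$seed`).
#' @return An [epoch_array()] of shape
#'   `[length(hyp), epoch_seconds * sampling_rate, n_channels]`.
#' @export
simulate_signals <- function(hyp, config, profiles = default_stage_profiles(),
                             jitter = NULL, seed = config$seed) {
  hyp <- hypnogram(hyp)
  missing <- setdiff(stage_labels(), names(profiles))
  if (length(missing)) {
    stop("missing stage profile(s): ", paste(missing, collapse = ", "))
  }
  n <- length(hyp)
  spe <- as.integer(round(config$epoch_seconds * config$sampling_rate))
  chn <- names(config$channels)
  C <- length(chn)
  if (is.null(jitter)) jitter <- stats::setNames(rep(1, C), chn)
  out <- array(0, c(n, spe, C))
  set.seed(seed)
  stages_present <- sort(unique(as.integer(hyp)))
  for (ci in seq_len(C)) {
    role <- config$channels[[ci]]
    if (chn[ci] %in% config$uninformative_channels) {
      out[, , ci] <- stats::rnorm(n * spe)
      next
    }
    for (st in stages_present) {
      idx <- which(as.integer(hyp) == st)
      prof <- profiles[[stage_labels()[st + 1L]]]
      bands <- prof$band_powers[[role]]
      sig <- matrix(0, spe, length(idx))
      for (b in seq_len(nrow(bands))) {
        if (bands$power[b] <= 0) next
        if (bands$low[b] >= bands$high[b]) stop("band must have low < high")
        sig <- sig + sqrt(bands$power[b]) *
          band_limited_noise(spe, length(idx), bands$low[b], bands$high[b],
                             config$sampling_rate)
      }
      if (config$noise_sigma > 0) {
        sig <- sig + config$noise_sigma *
          matrix(stats::rnorm(spe * length(idx)), spe, length(idx))
      }
      amp <- prof$amplitude_scale[[role]] * jitter[[chn[ci]]]
      out[idx, , ci] <- t(sig) * amp
    }
  }
  epoch_array(out, channels = chn, roles = unname(config$channels),
              sampling_rate = config$sampling_rate,
              epoch_seconds = config$epoch_seconds)
}

#' Construct a recording (signals + labels for one subject-night)
#' @param subject_id,night_id identifiers.
#' @param epochs an [epoch_array()].
#' @param labels a [hypnogram()] of matching length.
#' @return A `"recording"` list.
#' @export
recording <- function(subject_id, epochs, labels, night_id = "1") {
  labels <- hypnogram(labels)
  if (dim(epochs)[1] != length(labels)) {
    stop("number of label epochs (", length(labels),
         ") must match signal epochs (", dim(epochs)[1], ")")
  }
  structure(list(subject_id = as.character(subject_id),
                 night_id = as.character(night_id),
                 epochs = epochs, labels = labels),
            class = "recording")
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> subject %s night %s: %d epochs, %d channels\n",
              x$subject_id, x$night_id, length(x$labels),
              dim(x$epochs)[3]))
  invisible(x)
}

#' Generate a full synthetic dataset (one recording per subject)
#'
#' Per-subject seeds are derived deterministically from `config$seed`, so
#' the same configuration always yields bit-identical data. Per-subject
#' amplitude jitter (default +/-10% per channel) emulates inter-individual
#' amplitude differences.
#'
#' @param config a [sim_config()].
#' @param model a transition model (default [default_transition_model()]).
#' @param profiles stage profiles (default [default_stage_profiles()]).
#' @return List of `"recording"` objects with subject ids "S01", "S02", ...
#' @export
make_dataset <- function(config, model = default_transition_model(),
                         profiles = default_stage_profiles()) {
  stopifnot(inherits(config, "sim_config"))
  chn <- names(config$channels)
  lapply(seq_len(config$n_subjects), function(s) {
    base <- (config$seed %% 100000L) * 20011L + s * 101L
    hyp <- simulate_hypnogram(model, config$epochs_per_subject,
                              seed = base)
    set.seed(base + 1L)
    jit <- stats::setNames(
      stats::runif(length(chn), 1 - config$amplitude_jitter,
                   1 + config$amplitude_jitter), chn)
    sig <- simulate_signals(hyp, config, profiles, jitter = jit,
                            seed = base + 2L)
    recording(sprintf("S%02d", s), sig, hyp)
  })
}
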