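#' @title Data ingest and preprocessing
#' @description Stage-label harmonization (R&K six-stage to AASM
#'   five-stage), per-channel z-scoring, resampling to a common rate,
#'   epoching, leave-one-subject-out split planning, and a plain-text
#'   recording container (CSV signals + hypnogram text + JSON metadata).
#' @name dataio
NULL

RK_DROP_DEFAULT <- c("MOVEMENT", "UNSCORED", "?", "M")

#' Merge R&K six-stage labels into the AASM five-stage set
#'
#' N4 is merged into N3 (the slow-wave stage); unscored/movement markers are
#' dropped. The attribute `kept` on the result gives the indices of retained
#' epochs so callers can drop the matching signal epochs.
#'
#' @param raw_labels character vector over W, N1, N2, N3, N4, REM plus
#'   optional unscored markers.
#' @param drop markers treated as unscored and removed (with their epochs).
#' @return A [hypnogram()] with attribute `kept` (integer indices into
#'   `raw_labels`).
#' @export
merge_rk_stages <- function(raw_labels, drop = RK_DROP_DEFAULT) {
  raw_labels <- as.character(raw_labels)
  known <- c(stage_labels(), "N4", drop)
  bad <- setdiff(unique(raw_labels), known)
  if (length(bad)) {
    stop("unknown stage label(s): ", paste(bad, collapse = ", "))
  }
  keep <- which(!(raw_labels %in% drop))
  lab <- raw_labels[keep]
  lab[lab == "N4"] <- "N3"
  out <- hypnogram(lab)
  attr(out, "kept") <- keep
  out
}

#' Z-score each channel of a recording
#'
#' Normalizes every channel to mean 0 and sd 1 over the whole recording
#' (all epochs pooled), the per-subject, per-channel standardization applied
#' before the network sees the data.
#'
#' @param rec a [recording()].
#' @return The recording with standardized `epochs`.
#' @export
zscore_per_channel <- function(rec) {
  stopifnot(inherits(rec, "recording"))
  x <- rec$epochs
  d <- dim(x)
  for (ci in seq_len(d[3])) {
    v <- x[, , ci]
    mu <- mean(v)
    sdv <- stats::sd(as.vector(v))
    if (!is.finite(sdv) || sdv < 1e-12) {
      stop("channel ", attr(x, "channels")[ci],
           " has (near) zero variance; cannot z-score")
    }
    x[, , ci] <- (v - mu) / sdv
  }
  rec$epochs <- epoch_array(unclass(x), channels = attr(rec$epochs, "channels"),
                            roles = attr(rec$epochs, "roles"),
                            sampling_rate = attr(rec$epochs, "sampling_rate"),
                            epoch_seconds = attr(rec$epochs, "epoch_seconds"))
  rec
}

#' Resample a 1-D signal to a target rate
#'
#' Linear interpolation onto the target time grid; output length is
#' `round(length(x) * to_rate / from_rate)`. Downsampling is allowed (and
#' flagged with a message) but performs no anti-alias filtering.
#'
#' @param x numeric vector.
#' @param from_rate,to_rate sampling rates in Hz (> 0).
#' @param method `"linear"` (default) or `"constant"` (zero-order hold).
#' @return Resampled numeric vector.
#' @export
resample_channel <- function(x, from_rate, to_rate,
                             method = c("linear", "constant")) {
  method <- match.arg(method)
  if (from_rate <= 0 || to_rate <= 0) stop("rates must be > 0")
  if (to_rate < from_rate) {
    message("resample_channel: decimating ", from_rate, " Hz -> ",
            to_rate, " Hz by interpolation (no anti-alias filter)")
  }
  n_out <- as.integer(round(length(x) * to_rate / from_rate))
  if (from_rate == to_rate) return(x)
  t_in <- (seq_along(x) - 1) / from_rate
  t_out <- (seq_len(n_out) - 1) / to_rate
  stats::approx(t_in, x, xout = t_out, method = method, rule = 2)$y
}

#' Cut a continuous multi-channel signal into fixed-length epochs
#'
#' @param continuous numeric matrix `[n_samples, n_channels]` (a vector is
#'   treated as one channel).
#' @param rate sampling rate (Hz).
#' @param epoch_seconds epoch length (s), 30 by convention.
#' @param channels optional channel names.
#' @return An [epoch_array()]; a trailing partial epoch is dropped.
#' @export
epoch_signals <- function(continuous, rate, epoch_seconds = 30,
                          channels = NULL) {
  if (is.null(dim(continuous))) continuous <- matrix(continuous, ncol = 1)
  spe <- as.integer(round(rate * epoch_seconds))
  n <- nrow(continuous)
  n_epochs <- n %/% spe
  if (n_epochs < 1L) {
    stop("signal has ", n, " samples; need at least ", spe, " for one epoch")
  }
  C <- ncol(continuous)
  if (is.null(channels)) {
    channels <- colnames(continuous)
    if (is.null(channels)) channels <- paste0("ch", seq_len(C))
  }
  x <- continuous[seq_len(n_epochs * spe), , drop = FALSE]
  dim(x) <- c(spe, n_epochs, C)
  epoch_array(aperm(x, c(2, 1, 3)), channels = channels,
              sampling_rate = rate, epoch_seconds = epoch_seconds)
}

#' Flatten an epoch array back to a continuous signal matrix
#' @param ep an [epoch_array()].
#' @return Matrix `[n_epochs * samples_per_epoch, n_channels]`.
#' @export
flatten_epochs <- function(ep) {
  d <- dim(ep)
  x <- aperm(unclass(ep), c(2, 1, 3))
  dim(x) <- c(d[1] * d[2], d[3])
  colnames(x) <- attr(ep, "channels")
  x
}

#' Plan leave-one-subject-out cross-validation folds
#'
#' One fold per subject as the test set; the validation subject is the next
#' subject cyclically (a fixed deterministic rule); all remaining subjects
#' train. With S subjects this yields S folds of (S-2)/1/1.
#'
#' @param subjects ordered vector of subject identifiers (>= 3).
#' @return List of folds, each `list(train, val, test)`, class
#'   `"split_plan"`.
#' @export
make_loso_splits <- function(subjects) {
  subjects <- as.character(subjects)
  S <- length(subjects)
  if (S < 3L) stop("need at least 3 subjects for leave-one-subject-out")
  folds <- lapply(seq_len(S), function(i) {
    test <- subjects[i]
    val <- subjects[if (i == S) 1L else i + 1L]
    list(train = setdiff(subjects, c(test, val)), val = val, test = test)
  })
  structure(folds, class = "split_plan")
}

#' Write a recording as plain text (CSV + hypnogram + JSON metadata)
#'
#' Layout under `dir`: `signals.csv` (one row per sample, one column per
#' channel, epochs concatenated in order), `hypnogram.txt` (one stage label
#' per line), `meta.json` (rate, epoch length, channels, roles, ids).
#'
#' @param rec a [recording()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_recording <- function(rec, dir) {
  stopifnot(inherits(rec, "recording"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sig <- flatten_epochs(rec$epochs)
  utils::write.csv(as.data.frame(sig),
                   file.path(dir, "signals.csv"), row.names = FALSE)
  write_hypnogram(rec$labels, file.path(dir, "hypnogram.txt"))
  meta <- list(subject_id = rec$subject_id, night_id = rec$night_id,
               sampling_rate = attr(rec$epochs, "sampling_rate"),
               epoch_seconds = attr(rec$epochs, "epoch_seconds"),
               channels = attr(rec$epochs, "channels"),
               roles = attr(rec$epochs, "roles"))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a recording written by [write_recording()]
#' @param dir directory containing `signals.csv`, `hypnogram.txt`,
#'   `meta.json`.
#' @return A [recording()].
#' @export
read_recording <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  sig <- as.matrix(utils::read.csv(file.path(dir, "signals.csv")))
  ep <- epoch_signals(sig, rate = meta$sampling_rate,
                      epoch_seconds = meta$epoch_seconds,
                      channels = meta$channels)
  attr(ep, "roles") <- meta$roles
  recording(meta$subject_id, ep, read_hypnogram(file.path(dir, "hypnogram.txt")),
            night_id = meta$night_id)
}
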