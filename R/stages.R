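#' @title Sleep stage coding
#' @description Stage labels and their fixed integer coding used throughout
#'   the package: W = 0, N1 = 1, N2 = 2, N3 = 3, REM = 4 (AASM 5-class set,
#'   with the R&K N4 stage merged into N3 at ingest).
#' @name stage-coding
NULL

#' Canonical stage labels in coding order (W, N1, N2, N3, REM)
#' @return Character vector of length 5.
#' @export
stage_labels <- function() c("W", "N1", "N2", "N3", "REM")

N_STAGES <- 5L

#' Construct a hypnogram
#'
#' A hypnogram is the per-epoch sequence of sleep-stage labels across a
#' recording, stored as integers 0..4 (W=0, N1=1, N2=2, N3=3, REM=4).
#'
#' @param x integer vector in 0..4, or character vector of stage labels.
#' @return An integer vector of class `"hypnogram"`.
#' @export
hypnogram <- function(x) {
  if (is.character(x) || is.factor(x)) {
    x <- as.character(x)
    m <- match(x, stage_labels())
    if (anyNA(m)) {
      bad <- unique(x[is.na(m)])
      stop("unknown stage label(s): ", paste(bad, collapse = ", "))
    }
    x <- m - 1L
  }
  x <- as.integer(x)
  if (length(x) && (anyNA(x) || any(x < 0L | x > 4L))) {
    stop("hypnogram values must be integers in 0..4 (W=0 .. REM=4)")
  }
  structure(x, class = "hypnogram")
}

#' @export
print.hypnogram <- function(x, ...) {
  cat("<hypnogram> ", length(x), " epochs\n", sep = "")
  tab <- tabulate(unclass(x) + 1L, nbins = N_STAGES)
  names(tab) <- stage_labels()
  print(tab)
  invisible(x)
}

#' @export
`[.hypnogram` <- function(x, i, ...) hypnogram(unclass(x)[i])

#' @export
c.hypnogram <- function(...) {
  hypnogram(unlist(lapply(list(...), unclass), use.names = FALSE))
}

#' Convert integer-coded stages to labels
#' @param x hypnogram or integer vector in 0..4.
#' @return Character vector of labels.
#' @export
stage_names <- function(x) stage_labels()[as.integer(x) + 1L]

#' Read a hypnogram from a text file (one stage label per line)
#' @param path file with one of W/N1/N2/N3/REM (or digits 0..4) per line.
#' @return A [hypnogram()].
#' @export
read_hypnogram <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x)]
  if (all(grepl("^[0-4]$", x))) hypnogram(as.integer(x)) else hypnogram(x)
}

#' Write a hypnogram as text (one stage label per line)
#' @param hyp a [hypnogram()].
#' @param path output file path.
#' @export
write_hypnogram <- function(hyp, path) {
  writeLines(stage_names(hypnogram(hyp)), path)
  invisible(path)
}

one_hot_stages <- function(hyp) {
  hyp <- as.integer(hyp)
  m <- matrix(0, length(hyp), N_STAGES)
  m[cbind(seq_along(hyp), hyp + 1L)] <- 1
  m
}
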