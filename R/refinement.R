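#' @title Post-hoc hypnogram refinement baselines
#' @description Two traditional smoothing methods applied to a predicted
#'   hypnogram: a fixed expert-rule rewriting engine exploiting sleep
#'   continuity, and a hidden Markov model whose transition and emission
#'   probabilities are fitted by frequency counting on a validation split
#'   (hidden state = ground truth, observation = model prediction) and then
#'   decoded with the Viterbi algorithm on the test predictions.
#' @name refinement
NULL

# Triple rewrite rules (integer-coded, NA = wildcard X):
#   2: (W, REM, N2)  -> (W, N1, N2)
#   3: (N1, REM, N2) -> (N1, N1, N2)
#   4: (N2, X, N2)   -> (N2, N2, N2)
#   5: (REM, X, REM) -> (REM, REM, REM)
triple_rules <- function() {
  list(list(match = c(0L, 4L, 2L), replace = c(0L, 1L, 2L)),
       list(match = c(1L, 4L, 2L), replace = c(1L, 1L, 2L)),
       list(match = c(2L, NA, 2L), replace = c(2L, 2L, 2L)),
       list(match = c(4L, NA, 4L), replace = c(4L, 4L, 4L)))
}

#' Apply the expert smoothing rules to a hypnogram
#'
#' Rule 1 first: every REM epoch strictly before the first appearance of N2
#' becomes N1 — REM should not occur before the first light-sleep
#' consolidation. When N2 never appears there is no "first appearance" and
#' rule 1 does not fire. Then rules 2-5 are each applied as one full
#' left-to-right pass over consecutive triples, rewriting in place with
#' stride 1, so rewrites may cascade within a pass.
#'
#' @param hyp a [hypnogram()].
#' @return The refined [hypnogram()].
#' @export
apply_rules <- function(hyp) {
  s <- as.integer(hypnogram(hyp))
  n <- length(s)
  if (n == 0L) return(hypnogram(s))
  first_n2 <- match(2L, s)
  lim <- if (is.na(first_n2)) 0L else first_n2 - 1L
  if (lim >= 1L) {
    head_idx <- seq_len(lim)
    s[head_idx][s[head_idx] == 4L] <- 1L
  }
  if (n >= 3L) {
    for (rule in triple_rules()) {
      m <- rule$match
      for (t in seq_len(n - 2L)) {
        w <- s[t:(t + 2L)]
        if (all(w == m | is.na(m))) s[t:(t + 2L)] <- rule$replace
      }
    }
  }
  hypnogram(s)
}

#' Fit HMM parameters by frequency counting
#'
#' The hidden chain is the ground-truth staging, the observations are the
#' classifier's predictions on the same epochs (typically the validation
#' split). Transition counts never cross recording boundaries. A Laplace
#' pseudo-count keeps all probabilities positive.
#'
#' @param truth [hypnogram()] or list of hypnograms (one per recording).
#' @param observed predictions aligned with `truth`, same structure.
#' @param smoothing Laplace pseudo-count added to every cell (default 1).
#' @return An `"hmm_params"` list with `A` (5x5 hidden transitions), `B`
#'   (5x5 emission, hidden -> observed), `pi` (initial distribution), all
#'   row-stochastic.
#' @export
fit_hmm <- function(truth, observed, smoothing = 1) {
  if (!is.list(truth)) truth <- list(truth)
  if (!is.list(observed)) observed <- list(observed)
  if (length(truth) != length(observed)) {
    stop("truth and observed must have the same number of sequences")
  }
  A <- matrix(smoothing, N_STAGES, N_STAGES)
  B <- matrix(smoothing, N_STAGES, N_STAGES)
  pi0 <- rep(smoothing, N_STAGES)
  for (i in seq_along(truth)) {
    tr <- as.integer(hypnogram(truth[[i]])) + 1L
    ob <- as.integer(hypnogram(observed[[i]])) + 1L
    if (length(tr) != length(ob)) {
      stop("sequence ", i, ": truth length ", length(tr),
           " != observed length ", length(ob))
    }
    if (length(tr) >= 2L) {
      from <- tr[-length(tr)]
      to <- tr[-1L]
      for (j in seq_along(from)) A[from[j], to[j]] <- A[from[j], to[j]] + 1
    }
    for (j in seq_along(tr)) B[tr[j], ob[j]] <- B[tr[j], ob[j]] + 1
    pi0 <- pi0 + tabulate(tr, nbins = N_STAGES)
  }
  dimnames(A) <- dimnames(B) <- list(stage_labels(), stage_labels())
  structure(list(A = A / rowSums(A), B = B / rowSums(B),
                 pi = pi0 / sum(pi0)),
            class = "hmm_params")
}

#' Viterbi decoding of a predicted hypnogram
#'
#' Most probable hidden stage sequence in log space; ties are broken toward
#' the lowest stage index (W < N1 < N2 < N3 < REM).
#'
#' @param observed [hypnogram()] of classifier predictions.
#' @param params an `"hmm_params"` object (see [fit_hmm()]).
#' @return The decoded [hypnogram()].
#' @export
viterbi_decode <- function(observed, params) {
  ob <- as.integer(hypnogram(observed)) + 1L
  n <- length(ob)
  if (n == 0L) return(hypnogram(integer(0)))
  lA <- log(params$A)
  lB <- log(params$B)
  lpi <- log(params$pi)
  delta <- matrix(-Inf, n, N_STAGES)
  psi <- matrix(0L, n, N_STAGES)
  delta[1L, ] <- lpi + lB[, ob[1L]]
  if (n > 1L) {
    for (t in 2:n) {
      for (j in seq_len(N_STAGES)) {
        cand <- delta[t - 1L, ] + lA[, j]
        psi[t, j] <- which.max(cand)       # first max = lowest stage index
        delta[t, j] <- cand[psi[t, j]] + lB[j, ob[t]]
      }
    }
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  if (n > 1L) for (t in (n - 1L):1L) path[t] <- psi[t + 1L, path[t + 1L]]
  hypnogram(path - 1L)
}
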