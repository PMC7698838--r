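# Shared fixtures. Everything is generated in code; expensive objects are
# memoised in `.fixture_cache` so several test files can reuse them within
# one test run.

.fixture_cache <- new.env(parent = emptyenv())

cache_get <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, builder(), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# A backbone small enough that a 60-sample "epoch" survives all 5 blocks:
# 60 -> 19 -> 9 -> 7 -> 5 -> 4, feature dim 6.
micro_blocks <- function() {
  list(c(5L, 3L, 3L), c(3L, 2L, 4L), c(3L, 1L, 5L), c(3L, 1L, 4L),
       c(2L, 1L, 6L))
}

# Same layer geometry as the default backbone but narrow, sized for the
# 300-sample micro-world epochs: 300 -> 99 -> 32 -> 15 -> 13 -> 11.
micro_blocks2 <- function() {
  list(c(5L, 3L, 4L), c(5L, 3L, 4L), c(3L, 2L, 8L), c(3L, 1L, 8L),
       c(3L, 1L, 8L))
}

micro_model <- function(channels = c("a", "b"), fusion = "residual_attention",
                        use_refinement = TRUE, seed = 7, dropout = 0) {
  cfg <- model_config(60, channels, blocks = micro_blocks(),
                      fusion = fusion, use_refinement = use_refinement,
                      dropout = dropout, seed = seed)
  init_model(cfg)
}

micro_batch <- function(n = 4, C = 2, seed = 11) {
  set.seed(seed)
  X <- array(rnorm(n * 60 * C), c(n, 60, C))
  prev <- matrix(runif(n * 5), n)
  prev <- prev / rowSums(prev)
  y <- sample(0:4, n, replace = TRUE)
  list(X = X, prev = prev, y = y, Y = diag(5)[y + 1L, , drop = FALSE])
}

# Tiny synthetic world at 10 Hz (300-sample epochs) for pipeline tests.
micro_sim_config <- function(n_subjects = 3, epochs_per_subject = 40,
                             seed = 5, ...) {
  sim_config(n_subjects = n_subjects,
             epochs_per_subject = epochs_per_subject,
             sampling_rate = 10, epoch_seconds = 30, noise_sigma = 0.2,
             seed = seed, ...)
}

micro_recordings <- function() {
  cache_get("micro_recordings", function() {
    lapply(make_dataset(micro_sim_config()), zscore_per_channel)
  })
}

# Independent hand-rolled evaluation of the attention equations for one
# feature set (used as an oracle against the vectorized implementation).
attention_oracle <- function(vrows, ap) {
  C <- length(vrows)
  V <- unlist(vrows)
  s <- vapply(seq_len(C), function(i) {
    z <- as.vector(t(ap$W_iv[[i]]) %*% vrows[[i]]) +
      as.vector(t(ap$W) %*% V) + ap$b
    sum(ap$w_is[[i]] * pmax(z, 0))
  }, numeric(1))
  e <- exp(s - max(s))
  e / sum(e)
}

# Independent naive rewriting oracle for the smoothing rules, written over
# character labels with explicit position scanning.
rules_oracle <- function(labels) {
  labels <- stage_names(hypnogram(labels))
  n <- length(labels)
  if (n == 0) return(hypnogram(character(0)))
  first_n2 <- NA
  for (i in seq_len(n)) if (labels[i] == "N2") { first_n2 <- i; break }
  if (!is.na(first_n2)) {
    for (i in seq_len(n)) {
      if (i < first_n2 && labels[i] == "REM") labels[i] <- "N1"
    }
  }
  pats <- list(list(c("W", "REM", "N2"), c("W", "N1", "N2")),
               list(c("N1", "REM", "N2"), c("N1", "N1", "N2")),
               list(c("N2", "*", "N2"), c("N2", "N2", "N2")),
               list(c("REM", "*", "REM"), c("REM", "REM", "REM")))
  for (pr in pats) {
    i <- 1
    while (i <= n - 2) {
      w <- labels[i:(i + 2)]
      hit <- all(pr[[1]] == "*" | pr[[1]] == w)
      if (hit) labels[i:(i + 2)] <- pr[[2]]
      i <- i + 1
    }
  }
  hypnogram(labels)
}

# Exhaustive Viterbi oracle: enumerate all 5^L hidden paths. Path matrices
# are cached per length.
all_paths <- function(L) {
  cache_get(paste0("paths_", L), function() {
    as.matrix(expand.grid(rep(list(1:5), L)))
  })
}

viterbi_oracle <- function(obs, params) {
  obs <- as.integer(hypnogram(obs)) + 1L
  L <- length(obs)
  P <- all_paths(L)
  lA <- log(params$A); lB <- log(params$B); lpi <- log(params$pi)
  sc <- lpi[P[, 1]] + lB[cbind(P[, 1], obs[1])]
  if (L > 1) {
    for (t in 2:L) {
      sc <- sc + lA[cbind(P[, t - 1], P[, t])] + lB[cbind(P[, t], obs[t])]
    }
  }
  # with continuous random parameters the argmax is a.s. unique; tests also
  # compare path scores so an (improbable) tie cannot mislabel a failure
  list(path = hypnogram(P[which.max(sc), ] - 1L), score = max(sc))
}

path_log_prob <- function(path, obs, params) {
  path <- as.integer(hypnogram(path)) + 1L
  obs <- as.integer(hypnogram(obs)) + 1L
  L <- length(obs)
  s <- log(params$pi)[path[1]] + log(params$B)[path[1], obs[1]]
  if (L > 1) {
    for (t in 2:L) {
      s <- s + log(params$A)[path[t - 1], path[t]] +
        log(params$B)[path[t], obs[t]]
    }
  }
  s
}

random_hmm <- function(seed) {
  set.seed(seed)
  A <- matrix(rgamma(25, 1), 5)
  B <- matrix(rgamma(25, 1), 5)
  structure(list(A = A / rowSums(A), B = B / rowSums(B),
                 pi = as.vector(prop.table(rgamma(5, 1)))),
            class = "hmm_params")
}
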