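test_that("simulate_hypnogram follows the transition model", {
  # absorbing chain: identity matrix, all initial mass on N2
  tm <- transition_model(diag(5), initial = c(0, 0, 1, 0, 0))
  expect_equal(as.integer(simulate_hypnogram(tm, 10, seed = 3)), rep(2L, 10))

  # n = 1 draws from the initial distribution only
  tm1 <- transition_model(diag(5), initial = c(0, 0, 0, 0, 1))
  expect_equal(as.integer(simulate_hypnogram(tm1, 1, seed = 1)), 4L)

  # reproducibility
  tm2 <- default_transition_model()
  expect_identical(simulate_hypnogram(tm2, 200, seed = 9),
                   simulate_hypnogram(tm2, 200, seed = 9))

  # validation
  bad <- list(matrix = matrix(0.3, 5, 5), initial = rep(0.2, 5))
  expect_error(simulate_hypnogram(bad, 10), "sum to 1")
})

test_that("long chains reproduce the transition matrix and its stationary law", {
  tm <- default_transition_model()
  h <- as.integer(simulate_hypnogram(tm, 50000, seed = 42))
  # empirical transition frequencies within +/- 0.01 of matrix entries
  from <- h[-length(h)] + 1L
  to <- h[-1L] + 1L
  emp <- matrix(0, 5, 5)
  for (i in 1:5) {
    sel <- from == i
    emp[i, ] <- tabulate(to[sel], nbins = 5) / sum(sel)
  }
  expect_lt(max(abs(emp - tm$matrix)), 0.01)
  # stage frequencies near the stationary distribution
  ev <- eigen(t(tm$matrix))
  stat <- Re(ev$vectors[, 1]); stat <- stat / sum(stat)
  freq <- tabulate(h + 1L, nbins = 5) / length(h)
  expect_lt(max(abs(freq - stat)), 0.02)
})

test_that("transition-epoch fraction decreases with diagonal mass", {
  fractions <- vapply(c(0.6, 0.8, 0.95), function(diag_p) {
    off <- (1 - diag_p) / 4
    A <- matrix(off, 5, 5); diag(A) <- diag_p
    tm <- transition_model(A)
    mean(mark_transitions(simulate_hypnogram(tm, 5000, seed = 7)))
  }, numeric(1))
  expect_true(all(diff(fractions) < 0))
})

test_that("simulate_signals has the promised shape, determinism and spectra", {
  cfg <- sim_config(sampling_rate = 100, epoch_seconds = 30, seed = 2)
  hyp <- hypnogram(c(0, 3, 0, 3, 0, 3, 0, 3))
  sig <- simulate_signals(hyp, cfg)
  expect_equal(dim(sig), c(8L, 3000L, 3L))  # 30 s at 100 Hz -> 3000 samples
  expect_true(all(is.finite(sig)))
  expect_identical(attr(sig, "channels"), c("EEG", "EOG", "EMG"))
  expect_equal(unclass(simulate_signals(hyp, cfg)), unclass(sig),
               ignore_attr = TRUE)

  # N3 has strictly more 0.5-4 Hz EEG power than W (noise-free)
  cfg0 <- sim_config(sampling_rate = 100, noise_sigma = 0, seed = 2)
  sig0 <- simulate_signals(hyp, cfg0)
  band_power <- function(x, rate, lo, hi) {
    sp <- Mod(stats::fft(x))^2 / length(x)
    f <- (seq_along(x) - 1) / length(x) * rate
    f <- pmin(f, rate - f)
    mean(sp[f >= lo & f <= hi])
  }
  pw <- vapply(seq_along(hyp), function(i)
    band_power(sig0[i, , 1], 100, 0.5, 4), numeric(1))
  w_idx <- as.integer(hyp) == 0L
  expect_gt(min(pw[!w_idx]), max(pw[w_idx]))

  # identical profiles for all stages -> no stage information in spectra
  pr <- default_stage_profiles()
  for (s in stage_labels()) pr[[s]] <- pr$N1
  sig_flat <- simulate_signals(hyp, cfg0, profiles = pr)
  pw_flat <- vapply(seq_along(hyp), function(i)
    band_power(sig_flat[i, , 1], 100, 0.5, 4), numeric(1))
  rng <- range(tapply(pw_flat, w_idx, mean))
  expect_lt(rng[2] / rng[1], 2)  # no systematic separation left

  # missing profile errors
  expect_error(simulate_signals(hyp, cfg, profiles = pr[-1]), "missing stage")
})

test_that("uninformative channels carry white noise regardless of stage", {
  cfg <- sim_config(sampling_rate = 10, seed = 5, noise_sigma = 0,
                    channels = c(EEG = "eeg", AUX = "eeg"),
                    uninformative_channels = "AUX")
  hyp <- hypnogram(rep(c(0, 3), 10))
  sig <- simulate_signals(hyp, cfg)
  v_w <- as.vector(sig[as.integer(hyp) == 0, , 2])
  v_n3 <- as.vector(sig[as.integer(hyp) == 3, , 2])
  expect_lt(abs(sd(v_w) - sd(v_n3)), 0.1)
  expect_lt(abs(sd(v_w) - 1), 0.1)
})

test_that("make_dataset is deterministic and covers all stages", {
  cfg <- micro_sim_config(n_subjects = 3, epochs_per_subject = 200)
  ds1 <- make_dataset(cfg)
  expect_length(ds1, 3L)
  expect_equal(vapply(ds1, function(r) r$subject_id, character(1)),
               c("S01", "S02", "S03"))
  ds2 <- make_dataset(cfg)
  expect_identical(ds1, ds2)  # bit-identical for identical config
  pooled <- unlist(lapply(ds1, function(r) as.integer(r$labels)))
  expect_setequal(unique(pooled), 0:4)  # every stage appears
})

test_that("sim_config validates its inputs", {
  expect_error(sim_config(channels = character(0)), "non-empty")
  expect_error(sim_config(sampling_rate = 7, epoch_seconds = 0.3), "integer")
  expect_error(sim_config(uninformative_channels = "nope"), "subset")
})
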