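test_that("conv arithmetic and backbone shape chains match the architecture", {
  expect_equal(conv_output_length(3000, 5, 3), 999L)
  expect_equal(conv_output_length(163, 3, 1), 161L)
  expect_equal(conv_output_length(10, 1, 1), 10L)
  expect_error(conv_output_length(4, 5, 1), "shorter than kernel")
  expect_equal(backbone_shape_chain(3000), c(999L, 332L, 165L, 163L, 161L))
  expect_equal(backbone_shape_chain(3840), c(1279L, 425L, 212L, 210L, 208L))
})

test_that("extract_features produces deterministic nonnegative-pool features", {
  m <- micro_model(channels = "x")
  set.seed(1)
  ep <- matrix(rnorm(3 * 60), 3)
  f1 <- extract_features(m, ep)
  expect_equal(dim(f1), c(3L, 6L))
  expect_identical(f1, extract_features(m, ep))
  # ReLU before pooling forces nonnegative features for any input
  expect_true(all(f1 >= 0))
  expect_true(all(extract_features(m, matrix(0, 2, 60)) >= 0))
  expect_error(extract_features(m, matrix(0, 2, 59)), "input length 60")
  # a full-width backbone yields the canonical 256-length feature
  big <- init_model(model_config(3000, "EEG", seed = 1))
  expect_equal(ncol(extract_features(big, rnorm(3000))), 256L)
})

test_that("attention weights live on the simplex and match a naive oracle", {
  d <- 6
  # C = 1: softmax over one score is always 1
  ap1 <- attention_params(d, 1, seed = 2)
  expect_equal(as.vector(attention_weights(list(rnorm(d)), ap1)), 1.0)

  # identical features and shared per-channel parameters -> uniform weights
  ap <- attention_params(d, 3, seed = 3)
  ap$W_iv <- rep(ap$W_iv[1], 3)
  ap$w_is <- rep(ap$w_is[1], 3)
  v <- rnorm(d)
  a_sym <- attention_weights(list(v, v, v), ap)
  expect_equal(as.vector(a_sym), rep(1 / 3, 3), tolerance = 1e-12)

  # random features vs independent re-evaluation of the score equations
  set.seed(4)
  ap2 <- attention_params(d, 4, seed = 5)
  for (rep_i in 1:5) {
    vrows <- lapply(1:4, function(i) rnorm(d))
    a <- attention_weights(lapply(vrows, rbind), ap2)
    expect_equal(sum(a), 1, tolerance = 1e-6)
    expect_true(all(a >= 0))
    expect_equal(as.vector(a), attention_oracle(vrows, ap2),
                 tolerance = 1e-10)
  }
})

test_that("residual fusion obeys its forced identities", {
  d <- 5
  v <- rnorm(d)
  # identical channel features: v_avg + sum alpha_i v = 2v for any simplex alpha
  expect_equal(as.vector(fuse_residual(list(v, v, v), c(0.2, 0.5, 0.3))),
               2 * v, tolerance = 1e-12)
  # one-hot attention on channel j gives v_avg + v_j
  vl <- list(rnorm(d), rnorm(d), rnorm(d))
  expect_equal(as.vector(fuse_residual(vl, c(0, 1, 0))),
               (vl[[1]] + vl[[2]] + vl[[3]]) / 3 + vl[[2]], tolerance = 1e-12)
  expect_equal(as.vector(fuse_residual(list(rep(0, d), rep(0, d)),
                                       c(0.5, 0.5))), rep(0, d))
  expect_error(fuse_residual(vl, c(0.5, 0.5)), "channels")
})

test_that("fusion variants agree with their definitions", {
  d <- 6
  vl <- list(rep(1, d), rep(3, d))
  expect_equal(as.vector(fuse_variant(vl, "average")), rep(2, d))
  vl4 <- lapply(1:4, function(i) rnorm(256))
  expect_length(as.vector(fuse_variant(vl4, "concat")), 1024L)
  # attention_only = residual_attention - v_avg on the same inputs
  ap <- attention_params(d, 3, seed = 8)
  vl3 <- lapply(1:3, function(i) rnorm(d))
  ao <- fuse_variant(vl3, "attention_only", ap)
  ra <- fuse_variant(vl3, "residual_attention", ap)
  expect_equal(ra - ao, rbind(Reduce(`+`, vl3) / 3), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_error(fuse_variant(vl3, "votes"), "arg")
  expect_error(fuse_variant(vl3, "attention_only"), "attention params")
})

test_that("previous-stage encoding is a well-behaved affine map", {
  m <- micro_model()
  pars <- list(E = m$params$head$E, b_e = m$params$head$b_e)
  onehots <- diag(5)
  enc <- encode_previous_stage(onehots, pars)
  # distinct stages encode to distinct vectors under generic init
  expect_gt(min(dist(enc)), 1e-6)
  # zero vector returns the bias
  expect_equal(as.vector(encode_previous_stage(rep(0, 5), pars)), pars$b_e)
  # linearity: uniform vector = mean of the one-hot encodings
  expect_equal(as.vector(encode_previous_stage(rep(1 / 5, 5), pars)),
               colMeans(enc), tolerance = 1e-12)
  expect_error(encode_previous_stage(rep(0.3, 4), pars), "length")
  expect_error(encode_previous_stage(rep(0.9, 5), pars), "sum")
})

test_that("classifier logits decompose additively in the stage encoding", {
  m <- micro_model()
  head <- m$params$head
  d_enc <- ncol(head$E)
  d_fus <- nrow(head$Wc) - d_enc
  set.seed(21)
  v_c <- rnorm(d_enc)
  vf <- rnorm(d_fus)
  z <- function(a, b) classify(a, b, head, return_logits = TRUE)
  resid <- z(v_c, vf) - z(rep(0, d_enc), vf) - z(v_c, rep(0, d_fus)) +
    z(rep(0, d_enc), rep(0, d_fus))
  expect_lt(max(abs(resid)), 1e-5)
  # probabilities live on the simplex
  p <- classify(v_c, vf, head)
  expect_equal(sum(p), 1, tolerance = 1e-6)
  expect_true(all(p >= 0))
  # with zero fused features, different previous stages still change the
  # output: the refinement path is active
  p_w <- classify(encode_previous_stage(c(1, 0, 0, 0, 0),
                                        list(E = head$E, b_e = head$b_e)),
                  rep(0, d_fus), head)
  p_rem <- classify(encode_previous_stage(c(0, 0, 0, 0, 1),
                                          list(E = head$E, b_e = head$b_e)),
                    rep(0, d_fus), head)
  expect_gt(max(abs(p_w - p_rem)), 1e-6)
})

test_that("the full forward pass keeps its structural invariants", {
  m <- micro_model(channels = c("a", "b", "c"))
  b <- micro_batch(n = 5, C = 3)
  fw <- model_forward(m, b$X, b$prev)
  expect_equal(rowSums(fw$probs), rep(1, 5), tolerance = 1e-6)
  expect_equal(rowSums(fw$alpha), rep(1, 5), tolerance = 1e-6)
  expect_true(all(fw$alpha >= 0))
  # fused vector equals v_avg + sum alpha_i v_i elementwise
  recon <- Reduce(`+`, fw$v) / 3
  for (i in 1:3) recon <- recon + fw$alpha[, i] * fw$v[[i]]
  expect_lt(max(abs(recon - fw$fused)), 1e-5)
  expect_error(model_forward(m, b$X[, 1:59, ], b$prev), "input")
})

test_that("fusion is equivariant under consistent channel permutation", {
  m <- micro_model(channels = c("a", "b", "c"))
  b <- micro_batch(n = 3, C = 3)
  fw <- model_forward(m, b$X, b$prev)
  perm <- c(3, 1, 2)
  mp <- m
  mp$params$branches <- m$params$branches[perm]
  mp$params$attention$W_iv <- m$params$attention$W_iv[perm]
  mp$params$attention$w_is <- m$params$attention$w_is[perm]
  d <- m$config$feature_dim
  blocks <- lapply(seq_len(3), function(i) ((i - 1) * d + 1):(i * d))
  mp$params$attention$W <- m$params$attention$W[unlist(blocks[perm]), ]
  fwp <- model_forward(mp, b$X[, , perm, drop = FALSE], b$prev)
  expect_equal(fwp$fused, fw$fused, tolerance = 1e-10)
  expect_equal(fwp$alpha, fw$alpha[, perm], tolerance = 1e-10)
  expect_equal(fwp$probs, fw$probs, tolerance = 1e-10)
})

test_that("analytic gradients match finite differences", {
  m <- micro_model(channels = c("a", "b"))
  b <- micro_batch(n = 3, C = 2)
  lg <- sleepfusion:::model_loss_grads(m, b$X, b$prev, b$Y, train = TRUE)
  g <- sleepfusion:::params_flatten(lg$grads)
  theta0 <- sleepfusion:::params_flatten(m$params)
  lossfn <- function(theta) {
    mm <- m
    mm$params <- sleepfusion:::params_unflatten(mm$params, theta)
    fw <- model_forward(mm, b$X, b$prev, train = TRUE)
    -mean(rowSums(b$Y * log(pmax(fw$probs, 1e-12))))
  }
  set.seed(99)
  idx <- sample(seq_along(theta0), 40)
  num <- vapply(idx, function(i) {
    e <- 1e-5
    tp <- theta0; tp[i] <- tp[i] + e
    tm <- theta0; tm[i] <- tm[i] - e
    (lossfn(tp) - lossfn(tm)) / (2 * e)
  }, numeric(1))
  expect_lt(max(abs(num - g[idx]) / pmax(1e-6, abs(num) + abs(g[idx]))),
            1e-5)
})
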