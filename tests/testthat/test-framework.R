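test_that("the STFT front-end matches a direct per-frame DFT oracle", {
  set.seed(14)
  x <- rnorm(512)
  sp <- stft_spectrogram(x, 128, 32)
  expect_equal(dim(sp), c(1 + (512 - 128) %/% 32, 65))
  w <- 0.5 - 0.5 * cos(2 * pi * (0:127) / 127)
  for (t in c(1, 5, 13)) {
    s <- (t - 1) * 32
    ref <- Mod(fft(w * x[(s + 1):(s + 128)]))[1:65]
    expect_equal(sp[t, ], ref, tolerance = 1e-12)
  }

  expect_true(all(stft_spectrogram(numeric(256)) == 0))
  expect_error(stft_spectrogram(numeric(64)), "shorter")

  # a bin-centre sine concentrates its energy at that bin: the column is
  # the spectral argmax and the Hann mainlobe (three columns) holds > 90%
  f_bin <- 8 * 125 / 128  # bin 8 at fs = 125
  tone <- sin(2 * pi * f_bin * (0:511) / 125)
  sp2 <- stft_spectrogram(tone)
  energy <- colSums(sp2^2)
  expect_equal(which.max(energy), 9L)
  expect_gte(sum(energy[8:10]) / sum(energy), 0.9)
})

test_that("vector quantization picks nearest entries with low-index ties", {
  cb <- rbind(c(0, 0), c(1, 1), c(3, 3))
  hit <- vector_quantize(c(1, 1), cb)
  expect_equal(hit$indices, 2L)
  expect_equal(hit$zq, c(1, 1))

  # equidistant between the first and last entries: lowest index wins
  tie <- vector_quantize(1.5, rbind(0, 3))
  expect_equal(tie$indices, 1L)

  set.seed(15)
  Z <- matrix(rnorm(40), 20, 2)
  codes <- matrix(rnorm(12), 6, 2)
  vq <- vector_quantize(Z, codes)
  brute <- apply(Z, 1, function(z)
    which.min(colSums((t(codes) - z)^2)))
  expect_equal(vq$indices, unname(brute))
  expect_error(vector_quantize(Z, codes[0, , drop = FALSE]), "empty")
  expect_error(vector_quantize(Z, matrix(0, 2, 3)), "dimensions")
})

test_that("the attention gate scales skips by coefficients in (0, 1)", {
  set.seed(16)
  s <- matrix(rnorm(40), 5, 8)
  g <- matrix(rnorm(40), 5, 8)
  # saturating bias forces coefficients to 1: identity on the skip
  w1 <- list(w_s = 0, w_g = 0, w_v = 0, b1 = 0, b2 = 1000)
  out <- attention_gate(s, g, w1)
  expect_equal(out$output, s)
  expect_true(all(out$coefficients > 0.999))

  # zero gating with no skip coupling: a constant coefficient map
  w2 <- list(w_s = 0, w_g = rep(0.5, 8), w_v = rep(2, 8),
             b1 = rep(0.3, 8), b2 = rep(-0.1, 8))
  out2 <- attention_gate(s, matrix(0, 5, 8), w2)
  coef <- 1 / (1 + exp(-(2 * max(0.3, 0) + (-0.1))))
  expect_true(all(abs(out2$coefficients - coef) < 1e-12))
  expect_equal(out2$output, s * coef)

  expect_equal(dim(out$coefficients), dim(s))
  expect_error(attention_gate(s, g[, 1:4], w1), "same shape")
})

test_that("conv layers pass a finite-difference gradient check", {
  set.seed(17)
  X <- array(rnorm(2 * 32 * 3), c(2, 32, 3))
  ly <- cardiosynth:::.conv_init(5, 3, 4)
  fw <- cardiosynth:::.conv_fwd(X, ly, 5, 3, 4, 2L, 2L)
  loss <- function(par) {
    f <- cardiosynth:::.conv_fwd(X, par, 5, 3, 4, 2L, 2L)
    sum(f$Y^2) / 2
  }
  bw <- cardiosynth:::.conv_bwd(fw$Y, fw, ly, 5, 4)
  eps <- 1e-6
  for (idx in c(1, 7, 30)) {
    p2 <- ly; p2$W[idx] <- p2$W[idx] + eps
    expect_equal(bw$grads$W[idx], (loss(p2) - loss(ly)) / eps,
                 tolerance = 1e-3)
  }
  # input gradient via the scatter adjoint
  Xp <- X; Xp[1, 10, 2] <- Xp[1, 10, 2] + eps
  f2 <- cardiosynth:::.conv_fwd(Xp, ly, 5, 3, 4, 2L, 2L)
  expect_equal(bw$dX[1, 10, 2], (sum(f2$Y^2) / 2 - loss(ly)) / eps,
               tolerance = 1e-3)
})

bank <- make_segment_bank("rsr", 8, duration_s = 20, seed0 = 300)
P <- do.call(rbind, bank$ppg)
E <- do.call(rbind, bank$ecg)
half <- seq_len(nrow(P) %/% 2)

test_that("training reduces the PPG-to-ECG loss and is seed-reproducible", {
  cfg <- train_config(epochs = 8, seed = 3)
  ck <- cgan_train(P, E, cfg)
  h <- ck$history
  expect_equal(nrow(h), 8)
  expect_lt(h$p2e[8], h$p2e[1])
  expect_true(all(is.finite(h$total)))

  ck2 <- cgan_train(P, E, cfg)
  expect_identical(ck$history, ck2$history)
  expect_identical(ck$enc_p, ck2$enc_p)

  expect_error(cgan_train(P[1:5, ], E, cfg), "unpaired")
})

test_that("reconstruction runs encoder-of-G_P into decoder-of-G_E only", {
  cfg <- train_config(epochs = 8, seed = 3)
  ck <- cgan_train(P, E, cfg)
  rec <- cgan_reconstruct(P, ck)
  expect_equal(dim(rec), dim(P))
  expect_true(all(rec >= -1 & rec <= 1))
  expect_identical(rec, cgan_reconstruct(P, ck))

  # corrupting the unused halves must not change the inference output
  ck2 <- ck
  ck2$enc_e <- rapply(ck2$enc_e, function(p) p * 0 + 99, how = "replace")
  ck2$dec_p <- rapply(ck2$dec_p, function(p) p * 0 - 99, how = "replace")
  expect_identical(cgan_reconstruct(P, ck2), rec)

  # trained reconstruction beats an untrained one and the identity map
  ck0 <- cgan_train(P, E, train_config(epochs = 1, lr = 0, seed = 3))
  rec0 <- cgan_reconstruct(P, ck0)
  expect_lt(rmse(as.numeric(E), as.numeric(rec)),
            rmse(as.numeric(E), as.numeric(rec0)))
  expect_lt(rmse(as.numeric(E), as.numeric(rec)),
            rmse(as.numeric(E), as.numeric(P)))

  expect_error(cgan_reconstruct(P[, 1:256], ck), "window")
})

test_that("the no-adversarial ablation trains without discriminators", {
  cfg <- train_config(epochs = 2, seed = 5,
                      weights = loss_weights(beta = 0, gamma = 0))
  ck <- cgan_train(P[half, ], E[half, ], cfg)
  expect_null(ck$d_t)
  expect_null(ck$d_f)
  expect_true(all(ck$history$l_t == 0))
  # composite reduces to alpha * L_gen
  h <- ck$history
  lg <- h$contrast + h$p2p + h$e2e + h$p2e
  expect_equal(h$total, 30 * lg, tolerance = 1e-9)
})

test_that("the VQ generator kind trains with active codebooks", {
  cfg <- train_config(epochs = 3, seed = 7,
                      generator = generator_spec("vq_cnn", codebook_size = 32))
  ck <- cgan_train(P[half, ], E[half, ], cfg)
  expect_equal(dim(ck$codebook_p), c(32, 8))
  expect_gt(ck$history$vq_dict[1], 0)
  rec <- cgan_reconstruct(P[1:4, ], ck)
  expect_equal(dim(rec), c(4, 512))
  expect_true(all(is.finite(rec)))
})

test_that("the dense generator family also trains end to end", {
  cfg <- train_config(epochs = 10, seed = 9,
                      generator = generator_spec("dense"),
                      weights = loss_weights(beta = 0, gamma = 0))
  ck <- cgan_train(P[half, ], E[half, ], cfg)
  expect_lt(ck$history$p2e[10], ck$history$p2e[1])
  rec <- cgan_reconstruct(P[1:4, ], ck)
  expect_equal(dim(rec), c(4, 512))
})
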