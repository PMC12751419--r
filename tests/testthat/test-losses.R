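test_that("NT-Xent matches softmax closed forms", {
  # single positive pair: numerator equals the only denominator term
  z <- matrix(c(0.3, 0.4), 1)
  expect_equal(nt_xent(z, z, tau = 0.1), 0)

  # identical positives, orthogonal negatives, tau = 0.1
  zp <- rbind(c(1, 0), c(0, 1))
  expect_equal(nt_xent(zp, zp, tau = 0.1),
               -log(exp(10) / (exp(10) + exp(0))), tolerance = 1e-9)

  # all similarities equal -> uniform softmax -> log(N)
  same <- matrix(rep(c(1, 2), each = 8), 8, 2)
  expect_equal(nt_xent(same, same, tau = 0.1), log(8), tolerance = 1e-9)

  # loss decreases monotonically as the positive cosine rises while the
  # negative similarities stay fixed (third axis orthogonal throughout)
  ze <- rbind(c(1, 0, 0), c(0, 0, 1))
  losses <- vapply(seq(0.2, 1.4, by = 0.3), function(a) {
    zp <- rbind(c(cos(a), sin(a), 0), c(0, 0, 1))
    nt_xent(zp, ze, tau = 0.1)
  }, numeric(1))  # growing angle shrinks the positive cosine
  expect_true(all(diff(losses) > 0))

  expect_error(nt_xent(rbind(c(0, 0)), rbind(c(1, 0))), "zero-norm")
  expect_error(nt_xent(matrix(1, 2, 2), matrix(1, 3, 2)), "shape")
  expect_gte(nt_xent(matrix(rnorm(20), 5), matrix(rnorm(20), 5), 0.1), 0)
})

test_that("smooth-L1 follows the quadratic/linear split", {
  expect_equal(smooth_l1(1:5, 1:5), 0)
  expect_equal(smooth_l1(0.5, 0), 0.125)
  expect_equal(smooth_l1(2, 0), 1.5)
  expect_equal(smooth_l1(c(0.5, 2), c(0, 0)), (0.125 + 1.5) / 2)
  expect_error(smooth_l1(1:3, 1:4), "shape")
})

test_that("generation loss sums its components with the VQ weighting", {
  expect_equal(generation_loss(0, 0, 0, 0), 0)
  expect_equal(generation_loss(1, 1, 1, 1), 4)
  expect_equal(generation_loss(0, 0, 0, 0, vq_dictionary = 2,
                               vq_commitment = 4, lambda = 0.25), 3)
})

test_that("VQ losses honor the stop-gradient routing", {
  expect_equal(vq_loss(c(1, 2), c(1, 2))$total, 0)

  v <- vq_loss(c(2, 0), c(0, 0), lambda = 0.25)
  expect_equal(v$dictionary, 4)
  expect_equal(v$commitment, 1)

  # finite differences: the dictionary term's gradient lives on the
  # codebook, the commitment term's on the encoder
  ze <- c(0.3, -0.8, 1.1); e <- c(0.1, 0.2, 0.9)
  v <- vq_loss(ze, e, lambda = 0.25)
  eps <- 1e-6
  for (i in 1:3) {
    de <- replace(e, i, e[i] + eps)
    fd_dict <- (vq_loss(ze, de)$dictionary - vq_loss(ze, e)$dictionary) / eps
    expect_equal(as.numeric(v$grad_codebook)[i], fd_dict, tolerance = 1e-4)
    dz <- replace(ze, i, ze[i] + eps)
    fd_com <- (vq_loss(dz, e, 0.25)$commitment -
                 vq_loss(ze, e, 0.25)$commitment) / eps
    expect_equal(as.numeric(v$grad_encoder)[i], fd_com, tolerance = 1e-4)
  }
  expect_error(vq_loss(1:3, 1:4), "shape")
})

test_that("adversarial value functions match their closed forms", {
  l <- adversarial_losses(0.5, 0.5, 0.5, 0.5)
  expect_equal(l$time, -2 * log(2))
  expect_equal(l$freq, -2 * log(2))
  # a perfect discriminator attains the value-function optimum of 0
  expect_equal(adversarial_losses(1, 0, 1, 0)$time, 0)
  # batch estimate equals the per-sample mean oracle
  set.seed(3)
  dr <- runif(8, 0.1, 0.9); df <- runif(8, 0.1, 0.9)
  l2 <- adversarial_losses(dr, df, dr, df)
  expect_equal(l2$time, mean(log(dr)) + mean(log(1 - df)))
  expect_error(adversarial_losses(1.2, 0.5, 0.5, 0.5), "in \\(0, 1\\)")
  expect_error(adversarial_losses(0.5, -0.1, 0.5, 0.5), "in \\(0, 1\\)")
})

test_that("the composite loss applies the published weights", {
  expect_equal(composite_loss(1, 1, 1), 34)
  expect_equal(composite_loss(0, 0, 0), 0)
  w <- loss_weights()
  expect_equal(w$tau, 0.1)
  expect_equal(w$lambda, 0.25)
  # linearity in each argument
  expect_equal(composite_loss(2, 0, 0), 2 * composite_loss(1, 0, 0))
  expect_equal(composite_loss(0, 3, 0), 3 * composite_loss(0, 1, 0))
  expect_equal(composite_loss(1, 1, 1, loss_weights(beta = 0, gamma = 0)),
               30)  # generation-only ablation
  expect_error(loss_weights(tau = 0), "> 0")
})

test_that("the single-loop cycle loss decomposes into its two terms", {
  p <- matrix(rnorm(64), 4)
  ident <- function(x) x
  r <- cardiogan_recon(p, p, ident, ident)
  expect_equal(r$total, 0)

  g_e <- function(x) 0.8 * x + 0.1
  g_p <- function(x) x - 0.05
  e <- matrix(rnorm(64), 4)
  r2 <- cardiogan_recon(p, e, g_e, g_p)
  expect_gte(r2$midway, 0)
  expect_gte(r2$cycle, 0)
  expect_equal(r2$total,
               smooth_l1(g_e(p), e) + smooth_l1(g_p(g_e(p)), p))
})
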