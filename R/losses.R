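#' Loss weights of the composite objective
#'
#' @param tau contrastive temperature (default 0.1).
#' @param lambda commitment weight of the vector-quantization loss
#'   (default 0.25).
#' @param alpha,beta,gamma weights of the generation, time-adversarial and
#'   frequency-adversarial terms (defaults 30, 3, 1).
#' @return An object of class `loss_weights`.
#' @export
loss_weights <- function(tau = 0.1, lambda = 0.25,
                         alpha = 30, beta = 3, gamma = 1) {
  vals <- c(tau = tau, lambda = lambda, alpha = alpha,
            beta = beta, gamma = gamma)
  if (any(!is.finite(vals)) || tau <= 0 || lambda <= 0)
    stop("`tau` and `lambda` must be > 0 and all weights finite")
  if (alpha < 0 || beta < 0 || gamma < 0)
    stop("composite weights must be >= 0")
  structure(as.list(vals), class = "loss_weights")
}

# row-normalize a matrix to unit L2 norm, erroring on zero rows
.row_normalize <- function(z, what = "latent") {
  z <- as.matrix(z)
  nr <- sqrt(rowSums(z^2))
  if (any(nr == 0)) stop("zero-norm ", what, " vector")
  z / nr
}

#' NT-Xent contrastive loss
#'
#' Normalized temperature-scaled cross-entropy between index-aligned
#' positive pairs: for sample i,
#' `-log( exp(cos(zp_i, ze_i)/tau) / sum_k exp(cos(zp_i, ze_k)/tau) )`,
#' averaged over the batch. Cosine similarity is the dot product of the
#' L2-normalized vectors; the denominator runs over all batch items,
#' including the positive.
#'
#' @param zp,ze N x d matrices of PPG- and ECG-side latent vectors;
#'   rows with the same index are positives.
#' @param tau temperature (> 0), default 0.1.
#' @return Non-negative scalar; equals `log(N)` when all similarities are
#'   equal and 0 when N = 1 with matching pair.
#' @export
nt_xent <- function(zp, ze, tau = 0.1) {
  zp <- as.matrix(zp); ze <- as.matrix(ze)
  if (!all(dim(zp) == dim(ze))) stop("`zp` and `ze` must match in shape")
  if (tau <= 0) stop("`tau` must be > 0")
  s <- (.row_normalize(zp, "zp") %*% t(.row_normalize(ze, "ze"))) / tau
  # -pos + logsumexp per row, numerically stabilized
  m <- apply(s, 1, max)
  lse <- m + log(rowSums(exp(s - m)))
  mean(lse - diag(s))
}

#' Smooth-L1 (Huber-style) reconstruction loss
#'
#' Per element with difference d: `0.5 d^2 / beta` when `|d| < beta`, else
#' `|d| - 0.5 beta`; averaged over all elements.
#'
#' @param x,y numeric arrays of equal shape.
#' @param beta quadratic/linear transition point (default 1).
#' @return Non-negative scalar.
#' @export
smooth_l1 <- function(x, y, beta = 1) {
  if (length(x) != length(y)) stop("`x` and `y` must match in shape")
  d <- abs(as.numeric(x) - as.numeric(y))
  mean(ifelse(d < beta, 0.5 * d^2 / beta, d - 0.5 * beta))
}

#' Vector-quantization losses
#'
#' Dictionary term `||sg[ze] - e||^2` and commitment term
#' `lambda * ||ze - sg[e]||^2`, where `sg` is the stop-gradient operator:
#' identity in value, zero sensitivity. The dictionary term trains only the
#' codebook, the commitment term only the encoder; the reconstruction
#' gradient is copied straight through from the quantized to the continuous
#' latent. For matrices the squared norms are averaged over rows.
#'
#' @param ze encoder output (vector or N x d matrix).
#' @param e selected codebook vector(s), same shape.
#' @param lambda commitment weight (default 0.25).
#' @return List with `dictionary`, `commitment` and their `total`, plus the
#'   analytic gradients `grad_codebook` (of the dictionary term w.r.t. `e`)
#'   and `grad_encoder` (of the commitment term w.r.t. `ze`) that encode
#'   the stop-gradient routing.
#' @export
vq_loss <- function(ze, e, lambda = 0.25) {
  if (length(ze) != length(e)) stop("`ze` and `e` must match in shape")
  zem <- if (is.matrix(ze)) ze else matrix(as.numeric(ze), nrow = 1)
  em <- if (is.matrix(e)) e else matrix(as.numeric(e), nrow = 1)
  n <- nrow(zem)
  sq <- sum((zem - em)^2) / n
  list(dictionary = sq,
       commitment = lambda * sq,
       total = sq + lambda * sq,
       grad_codebook = 2 * (em - zem) / n,
       grad_encoder = 2 * lambda * (zem - em) / n)
}

#' Generation loss
#'
#' Sum of the contrastive loss and the three smooth-L1 reconstruction
#' losses (PPG-to-PPG, ECG-to-ECG, PPG-to-ECG); when the vector-quantized
#' generator is active, the dictionary term and the lambda-weighted
#' commitment term are added:
#' `L_gen = contrast + p2p + e2e + p2e + vq_dictionary + lambda * vq_commitment`.
#'
#' @param contrast,p2p,e2e,p2e non-negative loss components.
#' @param vq_dictionary codebook dictionary term `||sg[ze] - e||^2`
#'   (default 0, i.e. no VQ generator).
#' @param vq_commitment unweighted commitment term `||ze - sg[e]||^2`
#'   (default 0); scaled by `lambda` here.
#' @param lambda commitment weight (default 0.25).
#' @return Scalar generation loss.
#' @export
generation_loss <- function(contrast, p2p, e2e, p2e,
                            vq_dictionary = 0, vq_commitment = 0,
                            lambda = 0.25) {
  contrast + p2p + e2e + p2e + vq_dictionary + lambda * vq_commitment
}

#' Adversarial value functions of the dual discriminators
#'
#' Time-domain: `L_t = E[log D_t(real)] + E[log(1 - D_t(fake))]`;
#' frequency-domain `L_f` identically on STFT magnitude spectrograms.
#' The discriminators maximize these values; the generator minimizes the
#' fake term (see [cgan_train()] for the non-saturating option).
#'
#' @param d_real_t,d_fake_t time-discriminator outputs on real and
#'   generated ECG batches, each strictly inside (0, 1).
#' @param d_real_f,d_fake_f frequency-discriminator outputs.
#' @return List with `time` and `freq` value-function estimates.
#' @export
adversarial_losses <- function(d_real_t, d_fake_t, d_real_f, d_fake_f) {
  chk <- function(x, nm) {
    if (any(x < 0) || any(x > 1))
      stop("discriminator outputs `", nm, "` must lie in (0, 1)")
    x
  }
  list(time = mean(log(chk(d_real_t, "d_real_t"))) +
         mean(log(1 - chk(d_fake_t, "d_fake_t"))),
       freq = mean(log(chk(d_real_f, "d_real_f"))) +
         mean(log(1 - chk(d_fake_f, "d_fake_f"))))
}

#' Composite training loss
#'
#' `L_total = alpha * L_gen + beta * L_t + gamma * L_f` with default
#' weights (30, 3, 1). Setting `beta = gamma = 0` reduces the objective to
#' the pure generation loss (the no-adversarial ablation).
#'
#' @param l_gen,l_t,l_f loss components.
#' @param weights a [loss_weights()] object.
#' @return Scalar composite loss.
#' @export
composite_loss <- function(l_gen, l_t, l_f, weights = loss_weights()) {
  stopifnot(inherits(weights, "loss_weights"))
  weights$alpha * l_gen + weights$beta * l_t + weights$gamma * l_f
}

#' Single-loop cycle reconstruction loss
#'
#' The improved cycle objective for a dual-generator pair: a mid-way term
#' comparing `G_E(p)` with the true ECG plus a cycle term comparing
#' `G_P(G_E(p))` with the original PPG, both under smooth-L1.
#'
#' @param p,e paired PPG and ECG batches (vectors or matrices).
#' @param g_e,g_p generator functions mapping a batch to a batch.
#' @param beta smooth-L1 transition (default 1).
#' @return List with `midway`, `cycle` and `total`.
#' @export
cardiogan_recon <- function(p, e, g_e, g_p, beta = 1) {
  ep <- g_e(p)
  midway <- smooth_l1(ep, e, beta)
  cycle <- smooth_l1(g_p(ep), p, beta)
  list(midway = midway, cycle = cycle, total = midway + cycle)
}
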