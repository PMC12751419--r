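#' Short-time Fourier transform magnitude spectrogram
#'
#' Hann-windowed frames of `window_len` samples spaced `hop` samples apart;
#' frame count is `1 + floor((N - window_len) / hop)`. Returns the
#' one-sided magnitude (bins 0 .. window_len/2). This is the front-end of
#' the frequency-domain discriminator and of the default Frechet-distance
#' feature extractor.
#'
#' @param x numeric signal of length >= `window_len`.
#' @param window_len frame length in samples (default 128).
#' @param hop frame advance in samples (default 32).
#' @return Numeric matrix, frames x bins, of magnitudes.
#' @export
stft_spectrogram <- function(x, window_len = 128, hop = 32) {
  f <- .stft_forward(as.numeric(x), window_len, hop)
  f$mag
}

.hann <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / (n - 1))

# full forward pass keeping the complex frames for gradient propagation
.stft_forward <- function(x, window_len = 128, hop = 32) {
  n <- length(x)
  if (n < window_len)
    stop("signal shorter than the STFT window (", n, " < ", window_len, ")")
  nf <- 1L + (n - window_len) %/% hop
  w <- .hann(window_len)
  nb <- window_len %/% 2L + 1L
  C <- matrix(0 + 0i, nf, window_len)
  for (t in seq_len(nf)) {
    s <- (t - 1L) * hop
    C[t, ] <- fft(w * x[(s + 1L):(s + window_len)])
  }
  list(mag = abs(C[, 1:nb, drop = FALSE]), C = C,
       window_len = window_len, hop = hop, n = n)
}

# batched STFT over the rows of a matrix; magnitudes are flattened per row
# exactly like as.numeric(stft_spectrogram(row)) (frame index fastest)
.stft_mags_batch <- function(M, window_len = 128, hop = 32) {
  N <- nrow(M); n <- ncol(M)
  if (n < window_len) stop("signal shorter than the STFT window")
  nf <- 1L + (n - window_len) %/% hop
  nb <- window_len %/% 2L + 1L
  w <- .hann(window_len)
  mag <- array(0, c(N, nf, nb))
  C <- vector("list", nf)
  for (t in seq_len(nf)) {
    s <- (t - 1L) * hop
    seg <- t(M[, (s + 1L):(s + window_len), drop = FALSE]) * w
    Ct <- stats::mvfft(seg)            # window_len x N complex
    C[[t]] <- Ct
    mag[, t, ] <- t(Mod(Ct[1:nb, , drop = FALSE]))
  }
  dim(mag) <- c(N, nf * nb)
  list(mag = mag, C = C, nf = nf, nb = nb,
       window_len = window_len, hop = hop, n = n, N = N)
}

# adjoint of .stft_mags_batch: input-signal gradient from magnitude grads
.stft_backward_batch <- function(dmag, fw) {
  wl <- fw$window_len; hop <- fw$hop; nb <- fw$nb; nf <- fw$nf; N <- fw$N
  w <- .hann(wl)
  dim(dmag) <- c(N, nf, nb)
  dX <- matrix(0, N, fw$n)
  for (t in seq_len(nf)) {
    Ct <- fw$C[[t]][1:nb, , drop = FALSE]
    mg <- Mod(Ct)
    G <- t(dmag[, t, ]) * Conj(Ct) / (mg + (mg == 0))
    Gf <- matrix(0 + 0i, wl, N)
    Gf[1:nb, ] <- G
    dframe <- Re(stats::mvfft(Gf)) * w
    s <- (t - 1L) * hop
    dX[, (s + 1L):(s + wl)] <- dX[, (s + 1L):(s + wl)] + t(dframe)
  }
  dX
}

# gradient of a loss w.r.t. the input signal, given its gradient w.r.t.
# the one-sided magnitudes; fw is the .stft_forward() cache
.stft_backward <- function(dmag, fw) {
  wl <- fw$window_len; hop <- fw$hop
  nb <- wl %/% 2L + 1L
  w <- .hann(wl)
  dx <- numeric(fw$n)
  for (t in seq_len(nrow(dmag))) {
    g <- complex(real = rep(0, wl), imaginary = rep(0, wl))
    c1 <- fw$C[t, 1:nb]
    mag <- abs(c1)
    nz <- mag > 0
    g[1:nb][nz] <- dmag[t, nz] * Conj(c1[nz]) / mag[nz]
    dframe <- w * Re(fft(g))
    s <- (t - 1L) * hop
    dx[(s + 1L):(s + wl)] <- dx[(s + 1L):(s + wl)] + dframe
  }
  dx
}

#' Nearest-codebook vector quantization
#'
#' Maps each latent vector to its nearest codebook entry in Euclidean
#' distance; ties are broken towards the lowest index. In training the
#' quantized vectors carry the straight-through gradient contract of
#' [vq_loss()].
#'
#' @param ze latent vectors (N x d matrix or length-d vector).
#' @param codebook K x d matrix of codebook entries.
#' @return List with `zq` (quantized vectors, same shape as `ze`) and
#'   `indices` (1-based codebook rows).
#' @export
vector_quantize <- function(ze, codebook) {
  codebook <- as.matrix(codebook)
  if (nrow(codebook) < 1L) stop("empty codebook")
  vec_in <- !is.matrix(ze)
  zem <- if (vec_in) matrix(as.numeric(ze), nrow = 1) else as.matrix(ze)
  if (ncol(zem) != ncol(codebook))
    stop("latent and codebook dimensions differ")
  d2 <- outer(rowSums(zem^2), rep(1, nrow(codebook))) -
    2 * zem %*% t(codebook) +
    outer(rep(1, nrow(zem)), rowSums(codebook^2))
  idx <- max.col(-d2, ties.method = "first")
  zq <- codebook[idx, , drop = FALSE]
  if (vec_in) zq <- as.numeric(zq)
  list(zq = zq, indices = idx)
}

#' Additive attention gate
#'
#' Gates skip features by coefficients in (0, 1) computed from the skip and
#' gating features: `q = relu(skip * w_s + gating * w_g + b1)`,
#' `coef = sigmoid(q * w_v + b2)`, `output = skip * coef` (all operations
#' per feature unit). The coefficient map is returned for visualization.
#'
#' @param skip,gating feature matrices (N x h) or length-h vectors of equal
#'   shape.
#' @param weights list with per-unit vectors `w_s`, `w_g`, `w_v`, `b1`,
#'   `b2` (each length h or scalar), e.g. from [attention_weights()].
#' @return List with `output` (same shape as `skip`) and `coefficients`.
#' @export
attention_gate <- function(skip, gating, weights) {
  vec_in <- !is.matrix(skip)
  s <- if (vec_in) matrix(as.numeric(skip), nrow = 1) else as.matrix(skip)
  g <- if (vec_in) matrix(as.numeric(gating), nrow = 1) else as.matrix(gating)
  if (!all(dim(s) == dim(g)))
    stop("`skip` and `gating` must have the same shape")
  fw <- .gate_forward(s, g, weights)
  out <- fw$A * s
  if (vec_in) list(output = as.numeric(out),
                   coefficients = as.numeric(fw$A))
  else list(output = out, coefficients = fw$A)
}

#' Initialize attention-gate weights
#'
#' @param n_units number of feature units gated.
#' @param scale initialization scale for the linear maps.
#' @return Weight list for [attention_gate()].
#' @export
attention_weights <- function(n_units, scale = 0.1) {
  list(w_s = rnorm(n_units, 0, scale), w_g = rnorm(n_units, 0, scale),
       w_v = rnorm(n_units, 0, scale),
       b1 = rep(0, n_units), b2 = rep(0, n_units))
}

.bcast <- function(v, h) if (length(v) == 1L) rep(v, h) else v

.gate_forward <- function(s, g, w) {
  h <- ncol(s)
  qpre <- .addrow(.mulcol(s, .bcast(w$w_s, h)) + .mulcol(g, .bcast(w$w_g, h)),
                  .bcast(w$b1, h))
  q <- pmax(qpre, 0)
  r <- .addrow(.mulcol(q, .bcast(w$w_v, h)), .bcast(w$b2, h))
  A <- 1 / (1 + exp(-r))
  list(qpre = qpre, q = q, A = A)
}

# backward through M = g0 + A * s given dM; returns grads and the
# contributions to the skip (s) and gating (g0) features
.gate_backward <- function(dM, fw, s, g0, w) {
  h <- ncol(s)
  A <- fw$A
  dg0 <- dM
  dA <- dM * s
  ds <- dM * A
  dr <- dA * A * (1 - A)
  gw <- list(w_s = NULL, w_g = NULL, w_v = colSums(dr * fw$q),
             b1 = NULL, b2 = colSums(dr))
  dq <- .mulcol(dr, .bcast(w$w_v, h))
  dqpre <- dq * (fw$qpre > 0)
  gw$w_s <- colSums(dqpre * s)
  gw$w_g <- colSums(dqpre * g0)
  gw$b1 <- colSums(dqpre)
  ds <- ds + .mulcol(dqpre, .bcast(w$w_s, h))
  dg0 <- dg0 + .mulcol(dqpre, .bcast(w$w_g, h))
  list(ds = ds, dg0 = dg0, grads = gw)
}

## ---------------------------------------------------------------------
## 1-D convolution primitives (im2col in compiled code, GEMM in BLAS)
## ---------------------------------------------------------------------

.conv_init <- function(k, cin, cout) {
  l <- sqrt(6 / (k * cin + cout))
  list(W = matrix(runif(k * cin * cout, -l, l), k * cin, cout),
       b = rep(0, cout))
}

.conv_fwd <- function(X, par, k, cin, cout, stride, pad, dil = 1L) {
  d <- dim(X)
  M <- .im2col_cpp(X, d[1], d[2], d[3], k, stride, pad, dil)
  To <- (d[2] + 2L * pad - dil * (k - 1L) - 1L) %/% stride + 1L
  Y <- .coladd_cpp(M %*% par$W, par$b)
  dim(Y) <- c(d[1], To, cout)
  list(Y = Y, M = M, dims = c(d, To, pad, stride, dil))
}

.conv_bwd <- function(dY, fw, par, k, cout) {
  d <- fw$dims
  dYm <- dY; dim(dYm) <- c(d[1] * d[4], cout)
  g <- list(W = crossprod(fw$M, dYm), b = colSums(dYm))
  dM <- tcrossprod(dYm, par$W)
  list(grads = g,
       dX = .col2im_cpp(dM, d[1], d[2], d[3], k, d[6], d[5], d[7]))
}

.upsample <- function(X, r) X[, rep(seq_len(dim(X)[2]), each = r), ,
                             drop = FALSE]

.upsample_bwd <- function(dY, r) {
  d <- dim(dY)
  arr <- dY; dim(arr) <- c(d[1], r, d[2] %/% r, d[3])
  out <- arr[, 1, , , drop = FALSE]
  for (j in 2:r) out <- out + arr[, j, , , drop = FALSE]
  dim(out) <- c(d[1], d[2] %/% r, d[3])
  out
}

# flatten [N, T, C] to (N*T) x C and back (column-major safe)
.tc_mat <- function(X) { d <- dim(X); dim(X) <- c(d[1] * d[2], d[3]); X }
.tc_arr <- function(M, N, T, C) { dim(M) <- c(N, T, C); M }

## ---------------------------------------------------------------------
## Generator architectures
## ---------------------------------------------------------------------

.xavier <- function(nin, nout) {
  l <- sqrt(6 / (nin + nout))
  matrix(runif(nin * nout, -l, l), nin, nout)
}

# layer geometry of the convolutional encoder/decoder for a given spec
.cnn_arch <- function(spec, window) {
  if (window %% 4L != 0L)
    stop("the convolutional generator needs a window divisible by 4")
  k <- spec$kernel; p <- (k - 1L) %/% 2L
  cb <- spec$base_channels; cz <- spec$latent_channels
  tz <- window %/% 4L
  list(
    k = k, p = p, cb = cb, cz = cz, tz = tz, latent_dim = tz * cz,
    enc = list(
      e1 = list(k = k, cin = 1L, cout = cb, stride = 1L, pad = p, dil = 1L),
      e2 = list(k = k, cin = cb, cout = 2L * cb, stride = 4L, pad = p,
                dil = 1L),
      e3 = list(k = k, cin = 2L * cb, cout = 2L * cb, stride = 1L,
                pad = 4L * p, dil = 4L),
      ez = list(k = 1L, cin = 2L * cb, cout = cz, stride = 1L, pad = 0L,
                dil = 1L)),
    dec = list(
      d0 = list(k = 1L, cin = cz, cout = 2L * cb, stride = 1L, pad = 0L,
                dil = 1L),
      d1 = list(k = k, cin = 2L * cb, cout = 2L * cb, stride = 1L,
                pad = 4L * p, dil = 4L),
      d2 = list(k = 5L, cin = 2L * cb, cout = cb, stride = 1L, pad = 2L,
                dil = 1L),
      dout = list(k = k, cin = cb, cout = 1L, stride = 1L, pad = p,
                  dil = 1L)))
}

.init_encoder <- function(spec, window) {
  if (spec$family == "dense")
    return(list(W1 = .xavier(window, spec$hidden), b1 = rep(0, spec$hidden),
                W2 = .xavier(spec$hidden, spec$latent),
                b2 = rep(0, spec$latent)))
  a <- .cnn_arch(spec, window)$enc
  lapply(a, function(g) .conv_init(g$k, g$cin, g$cout))
}

.init_decoder <- function(spec, window) {
  if (spec$family == "dense") {
    dec <- list(W1 = .xavier(spec$latent, spec$hidden),
                b1 = rep(0, spec$hidden),
                W2 = .xavier(spec$hidden, window), b2 = rep(0, window))
    if (spec$attention) dec$gate <- attention_weights(spec$hidden)
    return(dec)
  }
  a <- .cnn_arch(spec, window)$dec
  dec <- lapply(a, function(g) .conv_init(g$k, g$cin, g$cout))
  if (spec$attention) dec$gate <- attention_weights(spec$base_channels)
  dec
}

.init_disc <- function(n_in, hidden) {
  list(W1 = .xavier(n_in, hidden), b1 = rep(0, hidden),
       W2 = .xavier(hidden, 1), b2 = 0)
}

.addrow <- function(m, b) {
  out <- .coladd_cpp(m, b)
  dim(out) <- dim(m)
  out
}
.mulcol <- function(m, v) {
  out <- .colmul_cpp(m, v)
  dim(out) <- dim(m)
  out
}

# encoder forward: returns the latent matrix Z (N x d), the skip features
# and the caches needed for the backward pass
.enc_forward <- function(X, enc, spec, arch = NULL) {
  if (spec$family == "dense") {
    H <- tanh(.addrow(X %*% enc$W1, enc$b1))
    Z <- .addrow(H %*% enc$W2, enc$b2)
    return(list(Z = Z, skip = H, cache = list(H = H)))
  }
  a <- arch$enc
  N <- nrow(X)
  X3 <- X; dim(X3) <- c(N, ncol(X), 1L)
  f1 <- .conv_fwd(X3, enc$e1, a$e1$k, a$e1$cin, a$e1$cout, a$e1$stride, a$e1$pad, a$e1$dil)
  a1 <- tanh(f1$Y)
  f2 <- .conv_fwd(a1, enc$e2, a$e2$k, a$e2$cin, a$e2$cout, a$e2$stride, a$e2$pad, a$e2$dil)
  a2 <- tanh(f2$Y)
  f3 <- .conv_fwd(a2, enc$e3, a$e3$k, a$e3$cin, a$e3$cout, a$e3$stride, a$e3$pad, a$e3$dil)
  a3 <- tanh(f3$Y)
  fz <- .conv_fwd(a3, enc$ez, a$ez$k, a$ez$cin, a$ez$cout, a$ez$stride, a$ez$pad, a$ez$dil)
  Z <- fz$Y; dim(Z) <- c(N, arch$latent_dim)
  list(Z = Z, skip = a1,
       cache = list(f1 = f1, a1 = a1, f2 = f2, a2 = a2, f3 = f3, a3 = a3,
                    fz = fz))
}

.enc_backward <- function(dZ, dSkip, X, fw, enc, spec, arch = NULL) {
  if (spec$family == "dense") {
    H <- fw$cache$H
    g <- list(W2 = t(H) %*% dZ, b2 = colSums(dZ))
    dH <- dZ %*% t(enc$W2)
    if (!is.null(dSkip)) dH <- dH + dSkip
    dpre <- dH * (1 - H^2)
    g$W1 <- t(X) %*% dpre
    g$b1 <- colSums(dpre)
    return(g)
  }
  a <- arch$enc
  cc <- fw$cache
  N <- nrow(X)
  dZarr <- dZ; dim(dZarr) <- c(N, arch$tz, arch$cz)
  bz <- .conv_bwd(dZarr, cc$fz, enc$ez, a$ez$k, a$ez$cout)
  b3 <- .conv_bwd(bz$dX * (1 - cc$a3^2), cc$f3, enc$e3, a$e3$k, a$e3$cout)
  b2 <- .conv_bwd(b3$dX * (1 - cc$a2^2), cc$f2, enc$e2, a$e2$k, a$e2$cout)
  da1 <- b2$dX
  if (!is.null(dSkip)) da1 <- da1 + dSkip
  b1 <- .conv_bwd(da1 * (1 - cc$a1^2), cc$f1, enc$e1, a$e1$k, a$e1$cout)
  list(e1 = b1$grads, e2 = b2$grads, e3 = b3$grads, ez = bz$grads)
}

# decoder forward: latent matrix (N x d) plus skip features to an output
# matrix (N x window)
.dec_forward <- function(Z, skip, dec, spec, arch = NULL) {
  if (spec$family == "dense") {
    G0 <- tanh(.addrow(Z %*% dec$W1, dec$b1))
    if (!is.null(dec$gate) && !is.null(skip)) {
      gw <- .gate_forward(skip, G0, dec$gate)
      M <- G0 + gw$A * skip
    } else { gw <- NULL; M <- G0 }
    O <- tanh(.addrow(M %*% dec$W2, dec$b2))
    return(list(O = O, cache = list(G0 = G0, gate = gw, M = M, O = O,
                                    Z = Z, skip = skip)))
  }
  a <- arch$dec
  N <- nrow(Z)
  Zarr <- Z; dim(Zarr) <- c(N, arch$tz, arch$cz)
  f0 <- .conv_fwd(Zarr, dec$d0, a$d0$k, a$d0$cin, a$d0$cout, a$d0$stride, a$d0$pad, a$d0$dil)
  a0 <- tanh(f0$Y)
  f1 <- .conv_fwd(a0, dec$d1, a$d1$k, a$d1$cin, a$d1$cout, a$d1$stride, a$d1$pad, a$d1$dil)
  a1 <- tanh(f1$Y)
  u2 <- .upsample(a1, 4L)
  f2 <- .conv_fwd(u2, dec$d2, a$d2$k, a$d2$cin, a$d2$cout, a$d2$stride, a$d2$pad, a$d2$dil)
  a2 <- tanh(f2$Y)
  if (!is.null(dec$gate) && !is.null(skip)) {
    gw <- .gate_forward(.tc_mat(skip), .tc_mat(a2), dec$gate)
    M <- a2 + .tc_arr(gw$A, dim(a2)[1], dim(a2)[2], dim(a2)[3]) * skip
  } else { gw <- NULL; M <- a2 }
  fo <- .conv_fwd(M, dec$dout, a$dout$k, a$dout$cin, a$dout$cout,
                  a$dout$stride, a$dout$pad, a$dout$dil)
  Oarr <- tanh(fo$Y)
  O <- Oarr; dim(O) <- c(N, dim(Oarr)[2])
  list(O = O, cache = list(f0 = f0, a0 = a0, f1 = f1, a1 = a1, f2 = f2,
                           a2 = a2, gate = gw, M = M, fo = fo,
                           Oarr = Oarr, Z = Z, skip = skip))
}

# returns parameter grads plus grads w.r.t. the latent and skip features
.dec_backward <- function(dO, fw, dec, spec, arch = NULL) {
  cc <- fw$cache
  if (spec$family == "dense") {
    dpre2 <- dO * (1 - cc$O^2)
    g <- list(W2 = t(cc$M) %*% dpre2, b2 = colSums(dpre2))
    dM <- dpre2 %*% t(dec$W2)
    dSkip <- NULL
    if (!is.null(cc$gate)) {
      gb <- .gate_backward(dM, cc$gate, cc$skip, cc$G0, dec$gate)
      dG0 <- gb$dg0; dSkip <- gb$ds; g$gate <- gb$grads
    } else dG0 <- dM
    dpre1 <- dG0 * (1 - cc$G0^2)
    g$W1 <- t(cc$Z) %*% dpre1
    g$b1 <- colSums(dpre1)
    return(list(grads = g, dZ = dpre1 %*% t(dec$W1), dSkip = dSkip))
  }
  a <- arch$dec
  d2 <- dim(cc$a2)
  dOarr <- dO; dim(dOarr) <- c(d2[1], d2[2], 1L)
  bo <- .conv_bwd(dOarr * (1 - cc$Oarr^2), cc$fo, dec$dout,
                  a$dout$k, a$dout$cout)
  dM <- bo$dX
  dSkip <- NULL
  g <- list()
  if (!is.null(cc$gate)) {
    gb <- .gate_backward(.tc_mat(dM), cc$gate, .tc_mat(cc$skip),
                         .tc_mat(cc$a2), dec$gate)
    da2 <- .tc_arr(gb$dg0, d2[1], d2[2], d2[3])
    dSkip <- .tc_arr(gb$ds, d2[1], d2[2], d2[3])
    g$gate <- gb$grads
  } else da2 <- dM
  b2 <- .conv_bwd(da2 * (1 - cc$a2^2), cc$f2, dec$d2, a$d2$k, a$d2$cout)
  du2 <- .upsample_bwd(b2$dX, 4L)
  b1 <- .conv_bwd(du2 * (1 - cc$a1^2), cc$f1, dec$d1, a$d1$k, a$d1$cout)
  b0 <- .conv_bwd(b1$dX * (1 - cc$a0^2), cc$f0, dec$d0, a$d0$k, a$d0$cout)
  dZ <- b0$dX; dim(dZ) <- c(d2[1], arch$latent_dim)
  g$d0 <- b0$grads; g$d1 <- b1$grads; g$d2 <- b2$grads; g$dout <- bo$grads
  list(grads = g, dZ = dZ, dSkip = dSkip)
}

.disc_forward <- function(X, disc) {
  H <- tanh(.addrow(X %*% disc$W1, disc$b1))
  S <- as.numeric(H %*% disc$W2 + disc$b2)
  P <- 1 / (1 + exp(-S))
  list(H = H, S = S, P = pmin(pmax(P, 1e-7), 1 - 1e-7))
}

# dS: gradient w.r.t. the pre-sigmoid score (length N)
.disc_backward <- function(dS, X, fw, disc, want_input = FALSE) {
  dS <- matrix(dS, ncol = 1)
  g <- list(W2 = t(fw$H) %*% dS, b2 = sum(dS))
  dH <- dS %*% t(disc$W2)
  dpre <- dH * (1 - fw$H^2)
  g$W1 <- t(X) %*% dpre
  g$b1 <- colSums(dpre)
  dX <- if (want_input) dpre %*% t(disc$W1) else NULL
  list(grads = g, dX = dX)
}

# smooth-L1 value and gradient w.r.t. X, mean reduction over all elements
.sl1 <- function(X, Y, beta = 1) {
  D <- X - Y
  a <- abs(D)
  val <- mean(ifelse(a < beta, 0.5 * a^2 / beta, a - 0.5 * beta))
  grad <- ifelse(a < beta, D / beta, sign(D)) / length(D)
  list(value = val, grad = grad)
}

# NT-Xent value and gradients w.r.t. the unnormalized latents
.ntxent <- function(zp, ze, tau) {
  np <- sqrt(rowSums(zp^2)); ne <- sqrt(rowSums(ze^2))
  if (any(np == 0) || any(ne == 0)) stop("zero-norm latent vector")
  zpn <- zp / np; zen <- ze / ne
  n <- nrow(zp)
  S <- (zpn %*% t(zen)) / tau
  m <- apply(S, 1, max)
  E <- exp(S - m)
  P <- E / rowSums(E)
  loss <- mean(m + log(rowSums(E)) - diag(S))
  dS <- (P - diag(n)) / n
  dzpn <- (dS %*% zen) / tau
  dzen <- (t(dS) %*% zpn) / tau
  # through the row normalization u = v/||v||
  unnorm <- function(du, un, nr) (du - un * rowSums(un * du)) / nr
  list(value = loss, dzp = unnorm(dzpn, zpn, np), dze = unnorm(dzen, zen, ne))
}

## Adam optimizer over nested lists of numeric arrays --------------------

.adam_init <- function(params) {
  rapply(params, function(p) list(m = p * 0, v = p * 0),
         how = "list", classes = "ANY")
}

.adam_step <- function(params, grads, state, lr, t,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  walk <- function(p, g, s) {
    if (is.list(p)) {
      out_p <- p; out_s <- s
      for (nm in names(p)) {
        r <- walk(p[[nm]], g[[nm]], s[[nm]])
        out_p[[nm]] <- r$p; out_s[[nm]] <- r$s
      }
      list(p = out_p, s = out_s)
    } else {
      s$m <- beta1 * s$m + (1 - beta1) * g
      s$v <- beta2 * s$v + (1 - beta2) * g^2
      mh <- s$m / (1 - beta1^t)
      vh <- s$v / (1 - beta2^t)
      list(p = p - lr * mh / (sqrt(vh) + eps), s = s)
    }
  }
  walk(params, grads, state)
}

.acc_grads <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  if (is.list(a)) {
    for (nm in names(a)) a[[nm]] <- .acc_grads(a[[nm]], b[[nm]])
    a
  } else a + b
}

## ---------------------------------------------------------------------

#' Generator architecture specification
#'
#' Two generator families are provided, each an encoder-decoder over
#' fixed-length windows with a tanh output in [-1, 1] and an optional
#' attention-gated skip connection from the encoder's first feature level
#' into the decoder's last:
#'
#' * `"cnn"` (default) / `"vq_cnn"`: a 1-D convolutional encoder (three
#'   conv levels, total downsampling 16x, then a 1x1 projection to
#'   `latent_channels` channels) mirrored by an upsampling convolutional
#'   decoder. Translation equivariance makes this the appropriate family
#'   for quasi-periodic waveforms.
#' * `"dense"` / `"vq_dense"`: a compact fully-connected variant (tanh
#'   hidden layer, linear latent).
#'
#' The `vq_*` kinds insert nearest-codebook vector quantization between
#' encoder and decoder (per latent time step for the convolutional family;
#' one codebook per generator) with the straight-through gradient contract
#' of [vq_loss()].
#'
#' @param kind `"cnn"`, `"vq_cnn"`, `"dense"` or `"vq_dense"`.
#' @param base_channels channels of the first convolutional level
#'   (default 16; deeper levels use twice as many).
#' @param latent_channels channels of the latent map (default 16).
#' @param kernel convolution kernel length, odd (default 9).
#' @param hidden hidden width of the dense family (default 192).
#' @param latent latent dimension of the dense family (default 64).
#' @param codebook_size codebook entries for the VQ kinds (>= 2,
#'   default 64).
#' @param attention enable the attention-gated skip (default `TRUE`).
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(kind = c("cnn", "vq_cnn", "dense", "vq_dense"),
                           base_channels = 16, latent_channels = 8,
                           kernel = 9, hidden = 192, latent = 64,
                           codebook_size = 64, attention = TRUE) {
  kind <- match.arg(kind)
  if (kernel %% 2 != 1) stop("`kernel` must be odd")
  use_vq <- kind %in% c("vq_cnn", "vq_dense")
  if (use_vq && codebook_size < 2) stop("`codebook_size` must be >= 2")
  if (hidden < 2 || latent < 1 || base_channels < 1 || latent_channels < 1)
    stop("invalid generator dimensions")
  structure(list(kind = kind,
                 family = if (kind %in% c("cnn", "vq_cnn")) "cnn" else "dense",
                 vq = use_vq,
                 base_channels = as.integer(base_channels),
                 latent_channels = as.integer(latent_channels),
                 kernel = as.integer(kernel),
                 hidden = as.integer(hidden), latent = as.integer(latent),
                 codebook_size = as.integer(codebook_size),
                 attention = isTRUE(attention)),
            class = "generator_spec")
}

#' Training configuration
#'
#' @param epochs training epochs.
#' @param batch_size minibatch size (default 32).
#' @param window segment length in samples; must match the preprocessing
#'   window (default 512).
#' @param lr Adam learning rate (default 1e-3; betas 0.9/0.999).
#' @param seed RNG seed controlling initialization and batch order.
#' @param weights a [loss_weights()] object.
#' @param generator a [generator_spec()].
#' @param d_hidden discriminator hidden width (default 64).
#' @param contrastive include the NT-Xent term (default `TRUE`; `FALSE`
#'   gives the no-contrastive-learning ablation).
#' @param saturating if `TRUE` (default) the generator minimizes
#'   `log(1 - D(fake))` exactly as in the value function; if `FALSE` it
#'   maximizes `log D(fake)` (non-saturating variant).
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 150, batch_size = 32, window = 512,
                         lr = 1e-3, seed = 1, weights = loss_weights(),
                         generator = generator_spec(), d_hidden = 64,
                         contrastive = TRUE, saturating = TRUE) {
  stopifnot(inherits(weights, "loss_weights"),
            inherits(generator, "generator_spec"))
  if (batch_size < 1 || epochs < 1 || window < 128) stop("invalid config")
  structure(list(epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 window = as.integer(window), lr = lr,
                 seed = as.integer(seed), weights = weights,
                 generator = generator, d_hidden = as.integer(d_hidden),
                 contrastive = isTRUE(contrastive),
                 saturating = isTRUE(saturating)),
            class = "train_config")
}

.as_segment_matrix <- function(x, window) {
  m <- if (inherits(x, "segment_set")) x$segments else as.matrix(x)
  if (ncol(m) != window)
    stop("segment length ", ncol(m), " does not match the window ", window)
  m
}

.latent_dim <- function(spec, window) {
  if (spec$family == "dense") spec$latent
  else (window %/% 4L) * spec$latent_channels
}

# reshape latent matrices to per-codeword rows: the convolutional family
# quantizes each latent time step's channel vector
.z_to_codes <- function(Z, spec, window) {
  if (spec$family == "dense") return(Z)
  n <- nrow(Z); tz <- window %/% 4L
  dim(Z) <- c(n * tz, spec$latent_channels)
  Z
}

.codes_to_z <- function(M, spec, window, n) {
  if (spec$family == "dense") return(M)
  dim(M) <- c(n, (window %/% 4L) * spec$latent_channels)
  M
}

#' Train the dual-generator reconstruction model
#'
#' Trains the PPG generator (encoder + decoder), the ECG generator, and —
#' when the adversarial weights are positive — the time- and
#' frequency-domain discriminators, by alternating discriminator and
#' generator updates on the composite objective
#' `alpha * L_gen + beta * L_t + gamma * L_f`. `L_gen` is the NT-Xent
#' contrastive loss between the two encoders' latents plus the three
#' smooth-L1 reconstruction losses (PPG-to-PPG, ECG-to-ECG, PPG-to-ECG),
#' plus the dictionary and commitment terms for the VQ generator kinds.
#' The fake sample seen by both discriminators is the PPG-to-ECG
#' reconstruction; the frequency discriminator sees one-sided STFT
#' magnitudes, through which the generator gradient is propagated exactly.
#'
#' Fully deterministic given the data and `config$seed`.
#'
#' @param ppg,ecg paired segments: [segment_signal()] results or matrices
#'   with one window per row, equal row counts.
#' @param config a [train_config()].
#' @param verbose print per-epoch losses.
#' @param on_epoch optional callback `function(epoch, checkpoint)` invoked
#'   after every epoch (e.g. for held-out monitoring); its return value is
#'   ignored.
#' @return An object of class `cgan_checkpoint`: the four networks, the
#'   discriminators, codebooks (VQ kinds), the config, and a per-epoch
#'   loss `history` data frame.
#' @export
cgan_train <- function(ppg, ecg, config = train_config(), verbose = FALSE,
                       on_epoch = NULL) {
  stopifnot(inherits(config, "train_config"))
  P <- .as_segment_matrix(ppg, config$window)
  E <- .as_segment_matrix(ecg, config$window)
  if (nrow(P) != nrow(E))
    stop("unpaired data: ", nrow(P), " PPG vs ", nrow(E), " ECG segments")
  if (nrow(P) < 2L) stop("need at least 2 segment pairs")
  n <- nrow(P)
  gs <- config$generator
  wts <- config$weights
  use_adv <- wts$beta > 0 || wts$gamma > 0
  arch <- if (gs$family == "cnn") .cnn_arch(gs, config$window) else NULL

  set.seed(config$seed)
  nets <- list(enc_p = .init_encoder(gs, config$window),
               dec_p = .init_decoder(gs, config$window),
               enc_e = .init_encoder(gs, config$window),
               dec_e = .init_decoder(gs, config$window))
  code_dim <- if (gs$family == "cnn") gs$latent_channels else gs$latent
  if (gs$vq) {
    nets$codebook_p <- matrix(rnorm(gs$codebook_size * code_dim, 0, 0.5),
                              gs$codebook_size, code_dim)
    nets$codebook_e <- matrix(rnorm(gs$codebook_size * code_dim, 0, 0.5),
                              gs$codebook_size, code_dim)
  }
  stft_dim <- (1L + (config$window - 128L) %/% 32L) * 65L
  discs <- if (use_adv)
    list(d_t = .init_disc(config$window, config$d_hidden),
         d_f = .init_disc(stft_dim, config$d_hidden))
  else list()

  opt_g <- .adam_init(nets)
  opt_d <- if (use_adv) .adam_init(discs) else NULL
  step_g <- 0L; step_d <- 0L
  hist <- NULL


  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep <- c(contrast = 0, p2p = 0, e2e = 0, p2e = 0,
            vq_dict = 0, vq_commit = 0, l_t = 0, l_f = 0, total = 0)
    nb <- 0L
    for (b0 in seq(1L, n, by = config$batch_size)) {
      idx <- ord[b0:min(b0 + config$batch_size - 1L, n)]
      if (length(idx) < 2L) next
      Pb <- P[idx, , drop = FALSE]; Eb <- E[idx, , drop = FALSE]
      nbatch <- length(idx)

      fp <- .enc_forward(Pb, nets$enc_p, gs, arch)
      fe <- .enc_forward(Eb, nets$enc_e, gs, arch)
      if (gs$vq) {
        cp <- .z_to_codes(fp$Z, gs, config$window)
        ce <- .z_to_codes(fe$Z, gs, config$window)
        vq_p <- vector_quantize(cp, nets$codebook_p)
        vq_e <- vector_quantize(ce, nets$codebook_e)
        zin_p <- .codes_to_z(vq_p$zq, gs, config$window, nbatch)
        zin_e <- .codes_to_z(vq_e$zq, gs, config$window, nbatch)
      } else {
        zin_p <- fp$Z; zin_e <- fe$Z
      }
      dp2p <- .dec_forward(zin_p, fp$skip, nets$dec_p, gs, arch)
      de2e <- .dec_forward(zin_e, fe$skip, nets$dec_e, gs, arch)
      dp2e <- .dec_forward(zin_p, fp$skip, nets$dec_e, gs, arch)
      Ep <- dp2e$O

      ## --- discriminator update ---------------------------------------
      l_t <- 0; l_f <- 0
      fake_stft <- NULL; fake_stft_cache <- NULL
      if (use_adv) {
        gd <- list()
        if (wts$beta > 0) {
          fr <- .disc_forward(Eb, discs$d_t)
          ff <- .disc_forward(Ep, discs$d_t)
          l_t <- mean(log(fr$P)) + mean(log(1 - ff$P))
          dSr <- (fr$P - 1) / nbatch   # minimize -log D(real)
          dSf <- ff$P / nbatch         # minimize -log(1 - D(fake))
          gd$d_t <- .acc_grads(.disc_backward(dSr, Eb, fr, discs$d_t)$grads,
                               .disc_backward(dSf, Ep, ff, discs$d_t)$grads)
        } else gd$d_t <- .adam_zero_disc(discs$d_t)
        if (wts$gamma > 0) {
          real_stft <- .stft_mags_batch(Eb)$mag
          fake_stft_cache <- .stft_mags_batch(Ep)
          fake_stft <- fake_stft_cache$mag
          fr <- .disc_forward(real_stft, discs$d_f)
          ff <- .disc_forward(fake_stft, discs$d_f)
          l_f <- mean(log(fr$P)) + mean(log(1 - ff$P))
          dSr <- (fr$P - 1) / nbatch
          dSf <- ff$P / nbatch
          gd$d_f <- .acc_grads(
            .disc_backward(dSr, real_stft, fr, discs$d_f)$grads,
            .disc_backward(dSf, fake_stft, ff, discs$d_f)$grads)
        } else gd$d_f <- .adam_zero_disc(discs$d_f)
        step_d <- step_d + 1L
        upd <- .adam_step(discs, gd[names(discs)], opt_d, config$lr, step_d)
        discs <- upd$p; opt_d <- upd$s
      }

      ## --- generator update -------------------------------------------
      slp <- .sl1(dp2p$O, Pb)
      sle <- .sl1(de2e$O, Eb)
      slx <- .sl1(Ep, Eb)
      ntx <- if (config$contrastive) .ntxent(fp$Z, fe$Z, wts$tau)
             else list(value = 0, dzp = 0 * fp$Z, dze = 0 * fe$Z)
      vq_terms <- if (gs$vq) {
        vp <- vq_loss(cp, vq_p$zq, wts$lambda)
        ve <- vq_loss(ce, vq_e$zq, wts$lambda)
        list(p = vp, e = ve,
             dictionary = vp$dictionary + ve$dictionary,
             commitment = vp$commitment + ve$commitment)
      } else NULL
      l_gen <- if (gs$vq)
        generation_loss(ntx$value, slp$value, sle$value, slx$value,
                        vq_dictionary = vq_terms$dictionary,
                        vq_commitment = vq_terms$dictionary,
                        lambda = wts$lambda)
      else generation_loss(ntx$value, slp$value, sle$value, slx$value)

      dEp <- wts$alpha * slx$grad
      if (use_adv && wts$beta > 0) {
        ff <- .disc_forward(Ep, discs$d_t)
        dS <- if (config$saturating) -ff$P / nbatch else (ff$P - 1) / nbatch
        dEp <- dEp + wts$beta *
          .disc_backward(dS, Ep, ff, discs$d_t, want_input = TRUE)$dX
      }
      if (use_adv && wts$gamma > 0) {
        ff <- .disc_forward(fake_stft, discs$d_f)
        dS <- if (config$saturating) -ff$P / nbatch else (ff$P - 1) / nbatch
        dFeat <- .disc_backward(dS, fake_stft, ff, discs$d_f,
                                want_input = TRUE)$dX
        dEp <- dEp + wts$gamma * .stft_backward_batch(dFeat, fake_stft_cache)
      }

      gg <- list()
      bp2p <- .dec_backward(wts$alpha * slp$grad, dp2p, nets$dec_p, gs, arch)
      be2e <- .dec_backward(wts$alpha * sle$grad, de2e, nets$dec_e, gs, arch)
      bp2e <- .dec_backward(dEp, dp2e, nets$dec_e, gs, arch)
      gg$dec_p <- bp2p$grads
      gg$dec_e <- .acc_grads(be2e$grads, bp2e$grads)

      # straight-through: decoder-input grads reach the continuous latents
      dZp <- bp2p$dZ + bp2e$dZ + wts$alpha * ntx$dzp
      dZe <- be2e$dZ + wts$alpha * ntx$dze
      if (gs$vq) {
        gcp <- wts$alpha * vq_terms$p$grad_encoder
        gce <- wts$alpha * vq_terms$e$grad_encoder
        dZp <- dZp + .codes_to_z(gcp, gs, config$window, nbatch)
        dZe <- dZe + .codes_to_z(gce, gs, config$window, nbatch)
        gcb_p <- 0 * nets$codebook_p
        gcb_e <- 0 * nets$codebook_e
        dict_p <- wts$alpha * vq_terms$p$grad_codebook
        dict_e <- wts$alpha * vq_terms$e$grad_codebook
        for (i in seq_along(vq_p$indices)) {
          gcb_p[vq_p$indices[i], ] <- gcb_p[vq_p$indices[i], ] + dict_p[i, ]
          gcb_e[vq_e$indices[i], ] <- gcb_e[vq_e$indices[i], ] + dict_e[i, ]
        }
        gg$codebook_p <- gcb_p
        gg$codebook_e <- gcb_e
      }
      gg$enc_p <- .enc_backward(dZp, .acc_grads(bp2p$dSkip, bp2e$dSkip),
                                Pb, fp, nets$enc_p, gs, arch)
      gg$enc_e <- .enc_backward(dZe, be2e$dSkip, Eb, fe, nets$enc_e, gs, arch)

      step_g <- step_g + 1L
      upd <- .adam_step(nets, gg[names(nets)], opt_g, config$lr, step_g)
      nets <- upd$p; opt_g <- upd$s

      ep <- ep + c(ntx$value, slp$value, sle$value, slx$value,
                   if (is.null(vq_terms)) c(0, 0)
                   else c(vq_terms$dictionary, vq_terms$commitment),
                   l_t, l_f,
                   composite_loss(l_gen, l_t, l_f, wts))
      nb <- nb + 1L
    }
    ep <- ep / max(nb, 1L)
    hist <- rbind(hist, data.frame(epoch = epoch, t(ep)))
    if (verbose)
      message(sprintf("epoch %3d  L_p2e %.4f  L_total %.3f",
                      epoch, ep[["p2e"]], ep[["total"]]))
    if (!is.null(on_epoch))
      on_epoch(epoch, structure(c(nets, discs,
                                  list(config = config, history = hist)),
                                class = "cgan_checkpoint"))
  }

  structure(c(nets, discs,
              list(config = config, history = hist)),
            class = "cgan_checkpoint")
}

.adam_zero_disc <- function(d) lapply(d, function(p) p * 0)

#' @export
print.cgan_checkpoint <- function(x, ...) {
  h <- x$history
  cat(sprintf(
    "<cgan_checkpoint> %s generator%s, %d epochs; final L_p2e %.4f\n",
    x$config$generator$kind,
    if (x$config$generator$attention) " with attention gate" else "",
    nrow(h), h$p2e[nrow(h)]))
  invisible(x)
}

#' Reconstruct ECG segments from PPG segments
#'
#' The inference path uses only the encoder of the PPG generator and the
#' decoder of the ECG generator (with the attention-gated skip between
#' them, and the PPG codebook for the VQ kinds); the ECG encoder and PPG
#' decoder play no part. Deterministic: repeated calls give identical
#' output, and values lie in [-1, 1].
#'
#' @param ppg [segment_signal()] result or matrix of PPG windows matching
#'   the training window length.
#' @param checkpoint a [cgan_train()] checkpoint.
#' @return Matrix of reconstructed ECG windows, same shape as the input.
#' @export
cgan_reconstruct <- function(ppg, checkpoint) {
  stopifnot(inherits(checkpoint, "cgan_checkpoint"))
  gs <- checkpoint$config$generator
  window <- checkpoint$config$window
  P <- .as_segment_matrix(ppg, window)
  arch <- if (gs$family == "cnn") .cnn_arch(gs, window) else NULL
  fp <- .enc_forward(P, checkpoint$enc_p, gs, arch)
  zin <- if (gs$vq) {
    codes <- .z_to_codes(fp$Z, gs, window)
    .codes_to_z(vector_quantize(codes, checkpoint$codebook_p)$zq,
                gs, window, nrow(P))
  } else fp$Z
  .dec_forward(zin, fp$skip, checkpoint$dec_e, gs, arch)$O
}
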