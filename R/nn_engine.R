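# Internal minibatch neural-network engine.
#
# Activations are 4D arrays [H, W, C, N] (column-major); convolutions are
# evaluated as a single BLAS matrix product over an im2col patch matrix
# whose gather indices are cached per (H, W, C, N, kernel) shape. Everything
# here is deterministic given the caller-controlled RNG state.

.idx_cache <- new.env(parent = emptyenv())

im2col_idx <- function(H, W, C, N, kh, kw) {
  key <- paste(H, W, C, N, kh, kw, sep = "x")
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  ph <- (kh - 1L) %/% 2L
  pw <- (kw - 1L) %/% 2L
  Hp <- H + 2L * ph
  Wp <- W + 2L * pw
  # patch top-left for output (i, j) sits at padded (i, j); offsets dr, dc
  v_ij <- as.vector(outer(seq_len(H), (seq_len(W) - 1L) * Hp, "+"))   # H*W
  v_row <- rep(v_ij, N) + rep((seq_len(N) - 1L) * Hp * Wp * C, each = H * W)
  off_col <- as.vector(outer(
    as.vector(outer(0:(kh - 1L), (0:(kw - 1L)) * Hp, "+")),
    (seq_len(C) - 1L) * Hp * Wp, "+"
  ))                                                                  # kh*kw*C
  idx <- outer(v_row, off_col, "+")
  out <- list(idx = idx, ph = ph, pw = pw, Hp = Hp, Wp = Wp,
              H = H, W = W, C = C, N = N, kh = kh, kw = kw)
  .idx_cache[[key]] <- out
  out
}

pad_input <- function(x, ph, pw) {
  d <- dim(x)
  if (ph == 0L && pw == 0L) return(x)
  xp <- array(0, c(d[1] + 2L * ph, d[2] + 2L * pw, d[3], d[4]))
  xp[(ph + 1L):(ph + d[1]), (pw + 1L):(pw + d[2]), , ] <- x
  xp
}

# K: (kh*kw*C) x F, b: length F. Returns pre-activation [H, W, F, N].
conv_fw <- function(x, K, b, kh, kw) {
  d <- dim(x)
  ic <- im2col_idx(d[1], d[2], d[3], d[4], kh, kw)
  xp <- pad_input(x, ic$ph, ic$pw)
  P <- matrix(xp[ic$idx], nrow = nrow(ic$idx))
  outM <- P %*% K
  outM <- outM + rep(b, each = nrow(outM))
  f <- ncol(K)
  out <- array(outM, c(d[1], d[2], d[4], f))
  list(out = aperm(out, c(1L, 2L, 4L, 3L)), P = P, ic = ic)
}

conv_bw <- function(dout, cache, K) {
  ic <- cache$ic
  d <- c(ic$H, ic$W, ic$C, ic$N)
  f <- ncol(K)
  doutM <- aperm(dout, c(1L, 2L, 4L, 3L))
  dim(doutM) <- c(ic$H * ic$W * ic$N, f)
  dK <- crossprod(cache$P, doutM)
  db <- colSums(doutM)
  dP <- tcrossprod(doutM, K)
  dxp <- numeric(ic$Hp * ic$Wp * ic$C * ic$N)
  idx <- ic$idx
  for (j in seq_len(ncol(idx))) {
    jj <- idx[, j]
    dxp[jj] <- dxp[jj] + dP[, j]
  }
  dim(dxp) <- c(ic$Hp, ic$Wp, ic$C, ic$N)
  dx <- dxp[(ic$ph + 1L):(ic$ph + ic$H), (ic$pw + 1L):(ic$pw + ic$W), , ,
            drop = FALSE]
  dim(dx) <- d
  list(dx = dx, dK = dK, db = db)
}

# Non-overlapping ph x pw pooling; H, W divisible by the window.
pool_fw <- function(x, ph, pw, kind = c("max", "avg")) {
  kind <- match.arg(kind)
  d <- dim(x)
  Ho <- d[1] %/% ph; Wo <- d[2] %/% pw
  xr <- x
  dim(xr) <- c(ph, Ho, pw, Wo, d[3], d[4])
  m <- aperm(xr, c(1L, 3L, 2L, 4L, 5L, 6L))
  rest <- Ho * Wo * d[3] * d[4]
  dim(m) <- c(ph * pw, rest)
  if (kind == "max") {
    am <- max.col(t(m), ties.method = "first")
    val <- m[(seq_len(rest) - 1L) * (ph * pw) + am]
    cache <- list(kind = kind, am = am, ph = ph, pw = pw, din = d,
                  Ho = Ho, Wo = Wo)
  } else {
    val <- .colMeans(m, ph * pw, rest)
    cache <- list(kind = kind, ph = ph, pw = pw, din = d, Ho = Ho, Wo = Wo)
  }
  list(out = array(val, c(Ho, Wo, d[3], d[4])), cache = cache)
}

pool_bw <- function(dout, cache) {
  ph <- cache$ph; pw <- cache$pw; d <- cache$din
  rest <- cache$Ho * cache$Wo * d[3] * d[4]
  dv <- as.vector(dout)
  dm <- matrix(0, ph * pw, rest)
  if (cache$kind == "max") {
    dm[(seq_len(rest) - 1L) * (ph * pw) + cache$am] <- dv
  } else {
    dm[] <- rep(dv, each = ph * pw) / (ph * pw)
  }
  dim(dm) <- c(ph, pw, cache$Ho, cache$Wo, d[3], d[4])
  dx <- aperm(dm, c(1L, 3L, 2L, 4L, 5L, 6L))
  dim(dx) <- d
  dx
}

# Squeeze-and-excitation over [H, W, C, N]; W1: (C/r) x C, W2: C x (C/r).
# Optional gate override (scalar or C-vector) replaces the learned gate --
# used for the "SE forced open" ablation check.
se_fw <- function(x, W1, W2, gate_override = NULL) {
  d <- dim(x)
  hw <- d[1] * d[2]
  xm <- x
  dim(xm) <- c(hw, d[3] * d[4])
  z <- matrix(.colMeans(xm, hw, d[3] * d[4]), d[3], d[4])
  pre1 <- W1 %*% z
  h <- pmax(pre1, 0)
  s <- 1 / (1 + exp(-(W2 %*% h)))
  if (!is.null(gate_override)) s <- matrix(gate_override, d[3], d[4])
  y <- x * rep(as.vector(s), each = hw)
  list(out = y, cache = list(x = x, z = z, pre1 = pre1, h = h, s = s,
                             hw = hw, d = d,
                             overridden = !is.null(gate_override)))
}

se_bw <- function(dy, cache, W1, W2) {
  d <- cache$d; hw <- cache$hw
  sv <- rep(as.vector(cache$s), each = hw)
  dx <- dy * sv
  prod <- as.vector(dy) * as.vector(cache$x)
  dim(prod) <- c(hw, d[3] * d[4])
  ds <- matrix(.colSums(prod, hw, d[3] * d[4]), d[3], d[4])
  if (cache$overridden) {
    dW1 <- array(0, dim(W1)); dW2 <- array(0, dim(W2))
  } else {
    dpre2 <- ds * cache$s * (1 - cache$s)
    dW2 <- tcrossprod(dpre2, cache$h)
    dh <- crossprod(W2, dpre2)
    dpre1 <- dh * (cache$pre1 > 0)
    dW1 <- tcrossprod(dpre1, cache$z)
    dz <- crossprod(W1, dpre1)
    dx <- dx + rep(as.vector(dz), each = hw) / hw
  }
  list(dx = dx, dW1 = dW1, dW2 = dW2)
}

dense_fw <- function(x, W, b) {
  W %*% x + b
}

# Adam with bias correction; state and grads mirror the param list.
adam_init <- function(params) {
  # p * 0 clones each parameter's shape and type (matrix stays matrix,
  # vector stays vector), which keeps the updates conformable.
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}
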