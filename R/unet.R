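# Untrained image-generator network (deep-image-prior style encoder-decoder
# with skip connections), written directly on BLAS matrix primitives.
#
# Activations are stored as N x C matrices (N = h*w pixels in column-major
# order). Convolutions are im2col gathers followed by a single matrix
# multiply; 2x2 mean pooling and bilinear upsampling use precomputed index
# maps / interpolation matrices, so forward and backward passes are exact
# adjoint pairs. The network maps a (real, imaginary) two-channel
# representation of a complex field to a refined two-channel field and adds
# the input back (residual), so a freshly initialized generator is close to
# the identity.

# ---- geometry caches ------------------------------------------------------

unet_geom_cache <- new.env(parent = emptyenv())

# 3x3 neighbourhood gather indices with zero padding (index n+1 = zero row).
conv3_idx <- function(h, w) {
  key <- paste0("c", h, "x", w)
  if (!is.null(unet_geom_cache[[key]])) return(unet_geom_cache[[key]])
  n <- h * w
  r <- rep.int(seq_len(h), w)
  cc <- rep(seq_len(w), each = h)
  idx <- matrix(n + 1L, n, 9L)
  k <- 0L
  for (dc in -1:1) for (dr in -1:1) {
    k <- k + 1L
    rr <- r + dr; ccc <- cc + dc
    ok <- rr >= 1L & rr <= h & ccc >= 1L & ccc <= w
    idx[ok, k] <- rr[ok] + (ccc[ok] - 1L) * h
  }
  unet_geom_cache[[key]] <- idx
  idx
}

# 2x2 mean-pool gather indices: (h*w/4) x 4.
pool_idx <- function(h, w) {
  key <- paste0("p", h, "x", w)
  if (!is.null(unet_geom_cache[[key]])) return(unet_geom_cache[[key]])
  h2 <- h %/% 2L; w2 <- w %/% 2L
  r2 <- rep.int(seq_len(h2), w2)
  c2 <- rep(seq_len(w2), each = h2)
  at <- function(dr, dc) (2L * r2 - 1L + dr) + (2L * c2 - 2L + dc) * h
  idx <- cbind(at(0L, 0L), at(1L, 0L), at(0L, 1L), at(1L, 1L))
  unet_geom_cache[[key]] <- idx
  idx
}

# 1-D bilinear x2 interpolation matrix (2n x n), half-pixel convention.
bilinear_mat <- function(n) {
  key <- paste0("b", n)
  if (!is.null(unet_geom_cache[[key]])) return(unet_geom_cache[[key]])
  xs <- (seq_len(2L * n) - 0.5) / 2 + 0.5 - 0.5  # source coordinate
  i0 <- floor(xs); tt <- xs - i0
  lo <- pmin(pmax(i0, 1L), n)
  hi <- pmin(pmax(i0 + 1L, 1L), n)
  m <- matrix(0, 2L * n, n)
  m[cbind(seq_len(2L * n), lo)] <- m[cbind(seq_len(2L * n), lo)] + (1 - tt)
  m[cbind(seq_len(2L * n), hi)] <- m[cbind(seq_len(2L * n), hi)] + tt
  unet_geom_cache[[key]] <- m
  m
}

# ---- primitive layers -----------------------------------------------------

conv3_fwd <- function(x, wt, b, idx) cpp_conv3_fwd(x, wt, b, idx)

conv3_bwd <- function(dy, x, wt, idx) cpp_conv3_bwd(dy, x, wt, idx)

lrelu_fwd <- function(x, slope = 0.1) pmax(x, 0) + slope * pmin(x, 0)
lrelu_bwd <- function(dy, x, slope = 0.1) dy * (slope + (1 - slope) * (x > 0))

# Instance normalization: each channel standardized over the pixels, then
# rescaled by learnable gain/offset. Stabilizes the untrained-network fit.
inorm_fwd <- function(x, gamma, delta, eps = 1e-5) {
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu)
  s <- sqrt(colMeans(xc^2) + eps)
  xhat <- sweep(xc, 2, s, `/`)
  y <- sweep(sweep(xhat, 2, gamma, `*`), 2, delta, `+`)
  list(y = y, xhat = xhat, s = s)
}

inorm_bwd <- function(dy, cache, gamma) {
  xhat <- cache$xhat
  dgamma <- colSums(dy * xhat)
  ddelta <- colSums(dy)
  dxhat <- sweep(dy, 2, gamma, `*`)
  m1 <- colMeans(dxhat)
  m2 <- colMeans(dxhat * xhat)
  dx <- sweep(dxhat, 2, m1) - sweep(xhat, 2, m2, `*`)
  dx <- sweep(dx, 2, cache$s, `/`)
  list(dx = dx, dgamma = dgamma, ddelta = ddelta)
}

pool_fwd <- function(x, idx) {
  (x[idx[, 1], , drop = FALSE] + x[idx[, 2], , drop = FALSE] +
     x[idx[, 3], , drop = FALSE] + x[idx[, 4], , drop = FALSE]) / 4
}

pool_bwd <- function(dy, idx, n_in) {
  dx <- matrix(0, n_in, ncol(dy))
  q <- dy / 4
  for (k in 1:4) dx[idx[, k], ] <- dx[idx[, k], , drop = FALSE] + q
  dx
}

upsample_fwd <- function(x, h, w) {
  ur <- bilinear_mat(h); uc <- bilinear_mat(w)
  out <- matrix(0, 4L * h * w, ncol(x))
  for (ch in seq_len(ncol(x)))
    out[, ch] <- as.vector(ur %*% matrix(x[, ch], h, w) %*% t(uc))
  out
}

upsample_bwd <- function(dy, h, w) {
  ur <- bilinear_mat(h); uc <- bilinear_mat(w)
  dx <- matrix(0, h * w, ncol(dy))
  for (ch in seq_len(ncol(dy)))
    dx[, ch] <- as.vector(crossprod(ur, matrix(dy[, ch], 2L * h, 2L * w)) %*% uc)
  dx
}

# ---- generator specification and initialization ---------------------------

#' Generator network specification
#'
#' Describes the untrained encoder-decoder used as the image generator: the
#' number of resolution levels, the channel widths, the width of the skip
#' connections, the activation, and the seed controlling the random
#' initialization. Channel width doubles per level from `base_channels`.
#'
#' @param depth number of resolution levels (>= 2); the grid is processed at
#'   scales 1, 1/2, ..., 1/2^(depth-1).
#' @param base_channels channels at the finest level.
#' @param skip_channels channels of each 1x1 skip projection.
#' @param activation activation name; `"lrelu"` (slope 0.1) is implemented.
#' @param seed RNG seed for the parameter initialization.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(depth = 3, base_channels = 8, skip_channels = 4,
                           activation = "lrelu", seed = 1) {
  stopifnot(depth >= 2, base_channels >= 1, skip_channels >= 1)
  if (!identical(activation, "lrelu"))
    stop("only the 'lrelu' activation is implemented")
  structure(
    list(depth = as.integer(depth), base_channels = as.integer(base_channels),
         skip_channels = as.integer(skip_channels), activation = activation,
         seed = as.integer(seed)),
    class = "generator_spec"
  )
}

unet_channels <- function(spec) spec$base_channels * 2^(seq_len(spec$depth) - 1L)

he_init <- function(n_in, n_out, fan_in, scale = 1) {
  matrix(stats::rnorm(n_in * n_out, 0, scale * sqrt(2 / fan_in)), n_in, n_out)
}

#' Initialize generator parameters
#'
#' Draws all convolution weights from a fan-in-scaled Gaussian (He
#' initialization) using the seed in the spec; biases start at zero and the
#' final projection starts near zero so that, together with the residual
#' connection, a fresh generator is approximately the identity map. The same
#' spec and seed always produce identical parameters.
#'
#' @param spec a [generator_spec()].
#' @return A parameter set (class `generator_theta`): nested list of weight
#'   matrices with the spec echoed in `$spec`.
#' @export
init_generator <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  ch <- unet_channels(spec)
  d <- spec$depth
  sk <- spec$skip_channels
  theta <- with_seed(spec$seed, {
    # conv + instance-norm parameter bundle (g/d are the norm gain/offset);
    # the plain output projection omits the norm parameters.
    conv <- function(cin, cout, k = 3L, scale = 1, norm = TRUE) {
      fan <- k * k * cin
      p <- list(w = he_init(k * k * cin, cout, fan, scale), b = numeric(cout))
      if (norm) { p$g <- rep(1, cout); p$d <- numeric(cout) }
      p
    }
    enc <- vector("list", d)
    cin <- 2L
    for (l in seq_len(d)) {
      enc[[l]] <- list(a = conv(cin, ch[l]), b = conv(ch[l], ch[l]))
      cin <- ch[l]
    }
    skip <- vector("list", d - 1L)
    for (l in seq_len(d - 1L)) skip[[l]] <- conv(ch[l], sk, k = 1L)
    dec <- vector("list", d - 1L)
    for (l in seq_len(d - 1L)) {
      cin_dec <- ch[l + 1L] + sk
      dec[[l]] <- list(a = conv(cin_dec, ch[l]), b = conv(ch[l], ch[l]))
    }
    out <- conv(ch[1L], 2L, k = 1L, scale = 0.01, norm = FALSE)
    list(enc = enc, skip = skip, dec = dec, out = out)
  })
  structure(c(theta, list(spec = spec)), class = "generator_theta")
}

#' Number of trainable parameters
#' @param theta a `generator_theta`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(theta) {
  length(flatten_theta(theta))
}

flatten_theta <- function(theta) {
  unlist(lapply(rapply(theta[c("enc", "skip", "dec", "out")],
                       identity, how = "unlist"), as.numeric))
}

# ---- forward / backward ---------------------------------------------------

# conv -> instance norm -> leaky ReLU, twice.
dconv_block_fwd <- function(x, blk, idx) {
  a1 <- conv3_fwd(x, blk$a$w, blk$a$b, idx)
  n1 <- inorm_fwd(a1, blk$a$g, blk$a$d)
  h1 <- lrelu_fwd(n1$y)
  a2 <- conv3_fwd(h1, blk$b$w, blk$b$b, idx)
  n2 <- inorm_fwd(a2, blk$b$g, blk$b$d)
  list(out = lrelu_fwd(n2$y), x = x, n1 = n1, h1 = h1, n2 = n2)
}

dconv_block_bwd <- function(dy, cache, blk, idx) {
  d2 <- lrelu_bwd(dy, cache$n2$y)
  i2 <- inorm_bwd(d2, cache$n2, blk$b$g)
  g2 <- conv3_bwd(i2$dx, cache$h1, blk$b$w, idx)
  d1 <- lrelu_bwd(g2$dx, cache$n1$y)
  i1 <- inorm_bwd(d1, cache$n1, blk$a$g)
  g1 <- conv3_bwd(i1$dx, cache$x, blk$a$w, idx)
  list(dx = g1$dx,
       grad = list(a = list(w = g1$dw, b = g1$db, g = i1$dgamma, d = i1$ddelta),
                   b = list(w = g2$dw, b = g2$db, g = i2$dgamma, d = i2$ddelta)))
}

# Forward pass through the generator. `x` is an N x 2 matrix for an h x w
# grid; returns the output and (optionally) the cache needed for backprop.
unet_forward <- function(theta, x, h, w, keep_cache = FALSE) {
  spec <- theta$spec
  d <- spec$depth
  if (h %% 2^(d - 1L) != 0L || w %% 2^(d - 1L) != 0L)
    stop("grid dimensions must be divisible by 2^(depth-1)")
  dims <- lapply(seq_len(d), function(l) c(h, w) %/% 2L^(l - 1L))
  enc_cache <- vector("list", d)
  cur <- x
  for (l in seq_len(d)) {
    idx <- conv3_idx(dims[[l]][1], dims[[l]][2])
    enc_cache[[l]] <- dconv_block_fwd(cur, theta$enc[[l]], idx)
    if (l < d) cur <- pool_fwd(enc_cache[[l]]$out, pool_idx(dims[[l]][1], dims[[l]][2]))
  }
  skip_cache <- vector("list", d - 1L)
  dec_cache <- vector("list", d - 1L)
  cur <- enc_cache[[d]]$out
  for (l in rev(seq_len(d - 1L))) {
    hw <- dims[[l + 1L]]
    up <- upsample_fwd(cur, hw[1], hw[2])
    sa <- enc_cache[[l]]$out %*% theta$skip[[l]]$w +
      rep(theta$skip[[l]]$b, each = nrow(enc_cache[[l]]$out))
    sn <- inorm_fwd(sa, theta$skip[[l]]$g, theta$skip[[l]]$d)
    sh <- lrelu_fwd(sn$y)
    skip_cache[[l]] <- list(n = sn)
    cat_in <- cbind(up, sh)
    idx <- conv3_idx(dims[[l]][1], dims[[l]][2])
    dec_cache[[l]] <- dconv_block_fwd(cat_in, theta$dec[[l]], idx)
    cur <- dec_cache[[l]]$out
  }
  y <- cur %*% theta$out$w + rep(theta$out$b, each = nrow(cur)) + x
  if (!keep_cache) return(list(y = y))
  list(y = y, enc = enc_cache, skip = skip_cache, dec = dec_cache,
       dec_top = cur, h = h, w = w)
}

# Backward pass: returns gradients in the same nesting as theta plus the
# gradient with respect to the input.
unet_backward <- function(theta, cache, dy) {
  spec <- theta$spec
  d <- spec$depth
  h <- cache$h; w <- cache$w
  dims <- lapply(seq_len(d), function(l) c(h, w) %/% 2L^(l - 1L))
  grad <- list(enc = vector("list", d), skip = vector("list", d - 1L),
               dec = vector("list", d - 1L), out = NULL)
  dx_input <- dy  # residual branch
  grad$out <- list(w = crossprod(cache$dec_top, dy), b = colSums(dy))
  dcur <- tcrossprod(dy, theta$out$w)
  denc_extra <- vector("list", d)  # gradients flowing into encoder outputs
  for (l in seq_len(d - 1L)) {
    idx <- conv3_idx(dims[[l]][1], dims[[l]][2])
    bb <- dconv_block_bwd(dcur, cache$dec[[l]], theta$dec[[l]], idx)
    grad$dec[[l]] <- bb$grad
    ch_up <- ncol(bb$dx) - spec$skip_channels
    dup <- bb$dx[, seq_len(ch_up), drop = FALSE]
    dsh <- bb$dx[, ch_up + seq_len(spec$skip_channels), drop = FALSE]
    dsn <- lrelu_bwd(dsh, cache$skip[[l]]$n$y)
    si <- inorm_bwd(dsn, cache$skip[[l]]$n, theta$skip[[l]]$g)
    dsa <- si$dx
    grad$skip[[l]] <- list(w = crossprod(cache$enc[[l]]$out, dsa),
                           b = colSums(dsa), g = si$dgamma, d = si$ddelta)
    denc_extra[[l]] <- tcrossprod(dsa, theta$skip[[l]]$w)
    hw <- dims[[l + 1L]]
    dcur <- upsample_bwd(dup, hw[1], hw[2])
  }
  # dcur now feeds the bottleneck encoder block output
  for (l in rev(seq_len(d))) {
    dout <- dcur
    if (!is.null(denc_extra[[l]])) dout <- dout + denc_extra[[l]]
    idx <- conv3_idx(dims[[l]][1], dims[[l]][2])
    bb <- dconv_block_bwd(dout, cache$enc[[l]], theta$enc[[l]], idx)
    grad$enc[[l]] <- bb$grad
    if (l > 1L) dcur <- pool_bwd(bb$dx, pool_idx(dims[[l - 1L]][1], dims[[l - 1L]][2]),
                                 prod(dims[[l - 1L]]))
    else dx_input <- dx_input + bb$dx
  }
  list(grad = grad, dx = dx_input)
}

#' Apply the generator to a complex field
#'
#' Runs the encoder-decoder on the (real, imaginary) channel representation
#' of `u` and returns the refined complex field of the same shape. Grid
#' dimensions must be divisible by `2^(depth-1)`.
#'
#' @param theta parameters from [init_generator()].
#' @param u complex matrix (or [complex_field()]).
#' @return Complex matrix of the same shape (or `complex_field` if one was
#'   supplied).
#' @export
generate <- function(theta, u) {
  stopifnot(inherits(theta, "generator_theta"))
  is_cf <- inherits(u, "complex_field")
  m <- if (is_cf) u$values else u
  if (any(!vapply(theta[c("enc", "dec")], function(p)
    all(rapply(p, function(v) all(is.finite(v)), how = "unlist")), logical(1))))
    stop("non-finite generator parameters (training divergence)")
  x <- cbind(as.vector(Re(m)), as.vector(Im(m)))
  y <- unet_forward(theta, x, nrow(m), ncol(m))$y
  out <- matrix(complex(real = y[, 1], imaginary = y[, 2]), nrow(m), ncol(m))
  if (is_cf) complex_field(out, u$pitch_um, u$wavelength_nm) else out
}

# ---- optimizer ------------------------------------------------------------

adam_init <- function() list(t = 0L, m = NULL, v = NULL)

# One Adam step over the flattened gradient structure; operates in place on
# the nested lists via mapply over leaves.
adam_step <- function(theta, grad, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  leaves_t <- rapply(theta[c("enc", "skip", "dec", "out")], identity, how = "unlist")
  leaves_g <- rapply(grad, identity, how = "unlist")
  if (is.null(state$m)) {
    state$m <- numeric(length(leaves_t))
    state$v <- numeric(length(leaves_t))
  }
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * leaves_g
  state$v <- beta2 * state$v + (1 - beta2) * leaves_g^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  new_leaves <- leaves_t - lr * mhat / (sqrt(vhat) + eps)
  theta2 <- relist_theta(new_leaves, theta)
  list(theta = theta2, state = state)
}

relist_theta <- function(leaves, theta) {
  skeleton <- theta[c("enc", "skip", "dec", "out")]
  refill <- function(node) {
    if (is.list(node)) return(lapply(node, refill))
    k <- length(node)
    vals <- leaves[pos + seq_len(k) - 1L]
    pos <<- pos + k
    if (is.matrix(node)) matrix(vals, nrow(node), ncol(node)) else vals
  }
  pos <- 1L
  out <- lapply(skeleton, refill)
  out$spec <- theta$spec
  class(out) <- "generator_theta"
  out
}

#' Save / load generator parameters
#'
#' The checkpoint is a plain RDS file containing the parameter list and the
#' spec; reloading is bit-reproducible.
#'
#' @param theta a `generator_theta`.
#' @param path file path.
#' @return `load_generator` returns the `generator_theta`.
#' @export
save_generator <- function(theta, path) {
  saveRDS(theta, path)
  invisible(path)
}

#' @rdname save_generator
#' @export
load_generator <- function(path) readRDS(path)
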