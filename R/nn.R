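# Minimal 2D convolutional network machinery used by the adversarial
# translator. Everything is plain R: tensors are (H, W, C) arrays, 3x3
# convolutions are im2col + one BLAS matrix product, and gradients are
# propagated manually in functional style (forward returns a cache,
# backward consumes it), so one network can appear several times in a loss
# graph with grads accumulated across uses. Desk-scale by design.

# column blocks are ordered offset-major (channel runs fastest inside each
# of the 9 offsets). The gather indices into the zero-padded array depend
# only on (H, W, C) and are cached across calls.
.nn_idx_cache <- new.env(parent = emptyenv())

nn_im2col_idx <- function(H, W, C) {
  key <- paste(H, W, C, sep = "_")
  idx <- .nn_idx_cache[[key]]
  if (is.null(idx)) {
    ii <- rep(seq_len(H), times = W)
    jj <- rep(seq_len(W), each = H)
    plane <- (H + 2L) * (W + 2L)
    idx <- matrix(0L, H * W, 9L * C)
    o <- 0L
    for (dx in 0:2) for (dy in 0:2) {
      base <- (dx + ii) + (dy + jj - 1L) * (H + 2L)
      for (c in seq_len(C))
        idx[, o * C + c] <- base + (c - 1L) * plane
      o <- o + 1L
    }
    .nn_idx_cache[[key]] <- idx
  }
  idx
}

nn_im2col <- function(x, H, W, C) {
  xp <- array(0, c(H + 2L, W + 2L, C))
  xp[2:(H + 1L), 2:(W + 1L), ] <- x
  idx <- nn_im2col_idx(H, W, C)
  out <- xp[idx]
  dim(out) <- dim(idx)
  out
}

# W rearranged so that the input gradient is itself a zero-padded 3x3
# convolution of dy: rows become offset-major over the flipped offsets with
# the OUTPUT channel fastest, columns are input channels.
nn_flip_weights <- function(W, cin, cout) {
  Warr <- W
  dim(Warr) <- c(cin, 9L, cout)
  Wback <- aperm(Warr[, 9:1, , drop = FALSE], c(3, 2, 1))
  dim(Wback) <- c(9L * cout, cin)
  Wback
}

# He-scaled init: keeps activation magnitudes stable through depth, which
# matters here because the networks carry no normalization layers
nn_conv_init <- function(cin, cout, sd = NULL) {
  if (is.null(sd)) sd <- sqrt(2 / (9 * cin))
  list(W = matrix(stats::rnorm(9L * cin * cout, 0, sd), 9L * cin, cout),
       b = rep(0, cout))
}

nn_conv_forward <- function(x, par) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  X <- nn_im2col(x, H, W, C)
  Y <- X %*% par$W
  Y <- sweep(Y, 2, par$b, `+`)
  list(y = array(Y, c(H, W, ncol(par$W))),
       cache = list(X = X, H = H, W = W, C = C))
}

nn_conv_backward <- function(dy, par, cache) {
  cout <- ncol(par$W)
  dYm <- matrix(dy, cache$H * cache$W, cout)
  Ycols <- nn_im2col(array(dy, c(cache$H, cache$W, cout)),
                     cache$H, cache$W, cout)
  dx <- Ycols %*% nn_flip_weights(par$W, cache$C, cout)
  list(dx = array(dx, c(cache$H, cache$W, cache$C)),
       grads = list(W = crossprod(cache$X, dYm), b = colSums(dYm)))
}

nn_pool_forward <- function(x) {
  d <- dim(x)
  stopifnot(d[1] %% 2L == 0L, d[2] %% 2L == 0L)
  i1 <- seq(1L, d[1], 2L); i2 <- seq(1L, d[2], 2L)
  y <- (x[i1, i2, , drop = FALSE] + x[i1 + 1L, i2, , drop = FALSE] +
        x[i1, i2 + 1L, , drop = FALSE] + x[i1 + 1L, i2 + 1L, , drop = FALSE]) / 4
  list(y = y, cache = d)
}

nn_pool_backward <- function(dy, d) {
  dx <- array(0, d)
  idx1 <- rep(seq_len(d[1] %/% 2L), each = 2L)
  idx2 <- rep(seq_len(d[2] %/% 2L), each = 2L)
  dx[] <- dy[idx1, idx2, , drop = FALSE] / 4
  dx
}

# A network is list(arch, params); arch entries are
# list(type = "conv"|"relu"|"lrelu"|"tanh"|"pool"|"res", cin, cout).
nn_build <- function(arch, final_sd = NULL) {
  params <- vector("list", length(arch))
  last_conv <- max(c(0L, which(vapply(arch, function(l)
    l$type %in% c("conv", "res"), logical(1)))))
  for (l in seq_along(arch)) {
    lay <- arch[[l]]
    if (lay$type == "conv") {
      sd <- if (l == last_conv && !is.null(final_sd)) final_sd else NULL
      params[[l]] <- nn_conv_init(lay$cin, lay$cout, sd)
    } else if (lay$type == "res") {
      params[[l]] <- list(c1 = nn_conv_init(lay$cin, lay$cout),
                          c2 = nn_conv_init(lay$cout, lay$cout))
    }
  }
  list(arch = arch, params = params)
}

nn_forward <- function(net, x) {
  caches <- vector("list", length(net$arch))
  for (l in seq_along(net$arch)) {
    lay <- net$arch[[l]]
    if (lay$type == "conv") {
      r <- nn_conv_forward(x, net$params[[l]])
      x <- r$y; caches[[l]] <- r$cache
    } else if (lay$type == "relu") {
      caches[[l]] <- x > 0
      x <- x * caches[[l]]
    } else if (lay$type == "lrelu") {
      caches[[l]] <- x > 0
      x <- 0.2 * x + 0.8 * x * caches[[l]]
    } else if (lay$type == "tanh") {
      x <- tanh(x)
      caches[[l]] <- x
    } else if (lay$type == "pool") {
      r <- nn_pool_forward(x)
      x <- r$y; caches[[l]] <- r$cache
    } else if (lay$type == "res") {
      p <- net$params[[l]]
      r1 <- nn_conv_forward(x, p$c1)
      m <- r1$y > 0
      a1 <- r1$y * m
      r2 <- nn_conv_forward(a1, p$c2)
      caches[[l]] <- list(c1 = r1$cache, mask = m, c2 = r2$cache)
      x <- x + r2$y
    } else stop("unknown layer type ", lay$type)
  }
  list(y = x, caches = caches)
}

nn_backward <- function(net, caches, dy) {
  grads <- vector("list", length(net$arch))
  for (l in rev(seq_along(net$arch))) {
    lay <- net$arch[[l]]
    if (lay$type == "conv") {
      r <- nn_conv_backward(dy, net$params[[l]], caches[[l]])
      dy <- r$dx; grads[[l]] <- r$grads
    } else if (lay$type == "relu") {
      dy <- dy * caches[[l]]
    } else if (lay$type == "lrelu") {
      dy <- 0.2 * dy + 0.8 * dy * caches[[l]]
    } else if (lay$type == "tanh") {
      dy <- dy * (1 - caches[[l]]^2)
    } else if (lay$type == "pool") {
      dy <- nn_pool_backward(dy, caches[[l]])
    } else if (lay$type == "res") {
      p <- net$params[[l]]; cc <- caches[[l]]
      r2 <- nn_conv_backward(dy, p$c2, cc$c2)
      da1 <- r2$dx * cc$mask
      r1 <- nn_conv_backward(da1, p$c1, cc$c1)
      grads[[l]] <- list(c1 = r1$grads, c2 = r2$grads)
      dy <- dy + r1$dx
    }
  }
  list(dx = dy, grads = grads)
}

# elementwise combination of nested grad/param structures
nn_map2 <- function(a, b, f) {
  if (is.list(a)) {
    out <- a
    for (k in seq_along(a)) {
      val <- if (is.null(a[[k]])) b[[k]]
             else if (is.null(b[[k]])) a[[k]]
             else nn_map2(a[[k]], b[[k]], f)
      out[k] <- list(val)   # preserves NULL elements
    }
    out
  } else f(a, b)
}

nn_grads_add <- function(a, b) {
  if (is.null(a)) return(b)
  if (is.null(b)) return(a)
  nn_map2(a, b, `+`)
}

nn_map <- function(a, f) {
  if (is.null(a)) return(NULL)
  if (is.list(a)) lapply(a, nn_map, f = f) else f(a)
}

# Adam optimizer over a nested param structure
nn_adam_init <- function(params)
  list(m = nn_map(params, function(p) p * 0),
       v = nn_map(params, function(p) p * 0), t = 0L)

nn_adam_step <- function(params, grads, state, lr, beta1 = 0.5,
                         beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- nn_map2(state$m, grads, function(m, g) beta1 * m + (1 - beta1) * g)
  state$v <- nn_map2(state$v, grads, function(v, g) beta2 * v + (1 - beta2) * g^2)
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- nn_map2(state$m, state$v,
                 function(m, v) lr * (m / bc1) / (sqrt(v / bc2) + eps))
  params <- nn_map2(params, upd, `-`)
  list(params = params, state = state)
}
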