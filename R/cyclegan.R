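#' Configuration of the adversarial translator
#'
#' Desk-scale CycleGAN recipe: residual generators and small patch
#' discriminators trained with least-squares adversarial losses, a
#' cycle-consistency term and an identity term. Although the package
#' produces paired data, the objective is unpaired (the pairing is never
#' used in the loss); a supervised L1 term is available as a clearly
#' non-default extension.
#'
#' @param input_size training slice side (square axial slices).
#' @param width generator base channel width.
#' @param n_res number of generator residual blocks.
#' @param disc_width discriminator base width.
#' @param lambda_cycle cycle-consistency weight (> 0).
#' @param lambda_identity identity-loss weight (>= 0).
#' @param lambda_supervised optional paired L1 weight, 0 (off) by default.
#' @param lr Adam learning rate; `beta1`, `beta2` its moment decays.
#' @param decay_start fraction of training after which the learning rate
#'   decays linearly toward zero (standard two-phase schedule; 0.5 keeps
#'   the rate constant for the first half).
#' @param epochs training epochs (>= 1).
#' @param buffer_size discriminator image-buffer length.
#' @param seed integer seed controlling initialization and data order.
#' @param slice_axis axis along which 2D training slices are taken.
#' @param brain_fraction minimum in-brain voxel fraction for a slice to be
#'   used for training.
#' @param max_slices cap on the number of training slices; qualifying
#'   slices are subsampled evenly (deterministically) down to this count.
#' @param val_slices number of held-out slices used for per-epoch
#'   validation metrics.
#' @return An object of class `gan_config`.
#' @export
gan_config <- function(input_size = 64L, width = 16L, n_res = 1L,
                       disc_width = 16L, lambda_cycle = 10,
                       lambda_identity = 5, lambda_supervised = 0,
                       lr = 1e-3, decay_start = 0.75,
                       beta1 = 0.5, beta2 = 0.999,
                       epochs = 16L, buffer_size = 50L, seed = 1L,
                       slice_axis = 3L, brain_fraction = 0.1,
                       max_slices = 40L, val_slices = 10L) {
  if (lambda_cycle <= 0) stop("`lambda_cycle` must be > 0")
  if (epochs < 1L) stop("`epochs` must be >= 1")
  if (width < 1L || disc_width < 1L) stop("widths must be >= 1")
  structure(list(input_size = as.integer(input_size),
                 width = as.integer(width), n_res = as.integer(n_res),
                 disc_width = as.integer(disc_width),
                 lambda_cycle = lambda_cycle,
                 lambda_identity = lambda_identity,
                 lambda_supervised = lambda_supervised,
                 lr = lr, decay_start = decay_start,
                 beta1 = beta1, beta2 = beta2,
                 epochs = as.integer(epochs),
                 buffer_size = as.integer(buffer_size),
                 seed = as.integer(seed),
                 slice_axis = as.integer(slice_axis),
                 brain_fraction = brain_fraction,
                 max_slices = as.integer(max_slices),
                 val_slices = as.integer(val_slices)),
            class = "gan_config")
}

#' Map a non-negative volume into [-1, 1] for network consumption
#'
#' The scale is the 99.5th-percentile intensity of the volume (robust to
#' hot voxels); values map by `2 min(v / scale, 1) - 1`. The returned
#' record inverts the mapping exactly for values at or below the scale.
#'
#' @param img a non-negative `volume_image` (or array).
#' @param record optional existing normalization record to reuse.
#' @return List with `values` (normalized array) and `record`
#'   (`list(scale)`).
#' @export
normalize_volume <- function(img, record = NULL) {
  v <- as_values(img)
  if (min(v) < 0) stop("input must be non-negative")
  if (is.null(record)) {
    scale <- stats::quantile(v, 0.995, names = FALSE, type = 7)
    if (scale <= 0) stop("cannot normalize an all-zero image")
    record <- list(scale = scale)
  }
  list(values = 2 * pmin(v / record$scale, 1) - 1, record = record)
}

#' Invert [normalize_volume()]
#'
#' @param values normalized array in [-1, 1] (small overshoot tolerated).
#' @param record the normalization record.
#' @return Array in original units, clipped at 0.
#' @export
denormalize_volume <- function(values, record) {
  pmax((values + 1) / 2 * record$scale, 0)
}

gen_arch <- function(width, n_res) {
  arch <- list(list(type = "conv", cin = 1L, cout = width),
               list(type = "relu"))
  for (i in seq_len(n_res))
    arch <- c(arch, list(list(type = "res", cin = width, cout = width)))
  c(arch, list(list(type = "conv", cin = width, cout = 1L)))
}

disc_arch <- function(width) {
  list(list(type = "conv", cin = 1L, cout = width),
       list(type = "lrelu"), list(type = "pool"),
       list(type = "conv", cin = width, cout = 2L * width),
       list(type = "lrelu"), list(type = "pool"),
       list(type = "conv", cin = 2L * width, cout = 1L))
}

#' Build the generator/discriminator bundle
#'
#' Two generators (G: uncorrected -> corrected, F: corrected ->
#' uncorrected) and two patch discriminators. Generators are residual
#' learners: `G(x) = x + tanh(net(x))` with a near-zero-initialized head,
#' so an untrained generator is close to the identity; discriminators are
#' downsampling patch classifiers with least-squares targets.
#'
#' @param config a `gan_config`; its seed fixes the initialization.
#' @return List with `G`, `F`, `D_pvc`, `D_nonpvc`, and `config`.
#' @export
build_models <- function(config = gan_config()) {
  withr_seed(config$seed, {
    list(G = nn_build(gen_arch(config$width, config$n_res), final_sd = 1e-3),
         F = nn_build(gen_arch(config$width, config$n_res), final_sd = 1e-3),
         D_pvc = nn_build(disc_arch(config$disc_width)),
         D_nonpvc = nn_build(disc_arch(config$disc_width)),
         config = config)
  })
}

#' Number of trainable parameters of a model bundle
#' @param bundle output of [build_models()] or [train_cyclegan()].
#' @return Named vector of parameter counts.
#' @export
parameter_counts <- function(bundle) {
  count <- function(net) {
    tot <- 0
    walk <- function(p) {
      if (is.null(p)) return(invisible())
      if (is.list(p)) lapply(p, walk) else tot <<- tot + length(p)
      invisible()
    }
    walk(net$params)
    tot
  }
  c(G = count(bundle$G), F = count(bundle$F),
    D_pvc = count(bundle$D_pvc), D_nonpvc = count(bundle$D_nonpvc))
}

# generator application with global residual skip; x is (H, W, 1)
gen_forward <- function(net, x) {
  r <- nn_forward(net, x)
  t <- tanh(r$y)
  list(y = x + t, cache = list(net = r$caches, t = t))
}

gen_backward <- function(net, cache, dy) {
  dpre <- dy * (1 - cache$t^2)
  r <- nn_backward(net, cache$net, dpre)
  list(dx = dy + r$dx, grads = r$grads)
}

slice_of <- function(arr, axis, k) {
  s <- switch(axis, arr[k, , ], arr[, k, ], arr[, , k])
  array(s, c(dim(s), 1L))
}

# extract normalized training slices from a list of paired samples
extract_slices <- function(samples, config) {
  xs <- list(); ys <- list()
  for (smp in samples) {
    nx <- normalize_volume(smp$nonpvc)
    ny <- normalize_volume(smp$reference_pvc)
    brain <- smp$atlas$labels > 0L
    nk <- dim(smp$nonpvc$values)[config$slice_axis]
    for (k in seq_len(nk)) {
      bf <- mean(slice_of(brain * 1.0, config$slice_axis, k))
      if (bf >= config$brain_fraction) {
        xs[[length(xs) + 1L]] <- slice_of(nx$values, config$slice_axis, k)
        ys[[length(ys) + 1L]] <- slice_of(ny$values, config$slice_axis, k)
      }
    }
  }
  if (length(xs) > config$max_slices) {
    keep <- round(seq(1, length(xs), length.out = config$max_slices))
    xs <- xs[keep]; ys <- ys[keep]
  }
  list(x = xs, y = ys)
}

# 2D SSIM used for per-slice validation (Gaussian window, sigma 1.5)
ssim2d <- function(a, b, data_range = NULL, sigma = 1.5, k1 = 0.01,
                   k2 = 0.03) {
  a <- drop(a); b <- drop(b)
  radius <- as.integer(round(3.5 * sigma))
  offs <- seq.int(-radius, radius)
  w <- exp(-offs^2 / (2 * sigma^2)); w <- w / sum(w)
  filt <- function(m) {
    n1 <- nrow(m); n2 <- ncol(m)
    out <- matrix(0, n1, n2)
    for (k in seq_along(offs)) {
      idx <- pmin(pmax(seq_len(n1) + offs[k], 1L), n1)
      out <- out + w[k] * m[idx, , drop = FALSE]
    }
    m <- out; out <- matrix(0, n1, n2)
    for (k in seq_along(offs)) {
      idx <- pmin(pmax(seq_len(n2) + offs[k], 1L), n2)
      out <- out + w[k] * m[, idx, drop = FALSE]
    }
    out
  }
  if (is.null(data_range)) {
    data_range <- max(a) - min(a)
    if (data_range == 0) data_range <- 1
  }
  c1 <- (k1 * data_range)^2; c2 <- (k2 * data_range)^2
  mu_a <- filt(a); mu_b <- filt(b)
  va <- filt(a * a) - mu_a^2; vb <- filt(b * b) - mu_b^2
  cab <- filt(a * b) - mu_a * mu_b
  mean(((2 * mu_a * mu_b + c1) * (2 * cab + c2)) /
       ((mu_a^2 + mu_b^2 + c1) * (va + vb + c2)))
}

val_metrics <- function(G, val_x, val_y) {
  rm <- sm <- numeric(length(val_x))
  for (i in seq_along(val_x)) {
    pred <- gen_forward(G, val_x[[i]])$y
    rm[i] <- sqrt(mean((pred - val_y[[i]])^2))
    sm[i] <- ssim2d(pred, val_y[[i]], data_range = 2)
  }
  c(rmse = stats::median(rm), ssim = stats::median(sm))
}

#' Train the cycle-consistent translator
#'
#' Least-squares adversarial objective plus weighted cycle-consistency and
#' identity terms, optimized with Adam; discriminators are refreshed from a
#' finite image buffer of past generator outputs. The data are consumed as
#' unpaired pools of uncorrected and reference-corrected slices (shuffled
#' independently every epoch), faithful to the unpaired formulation even
#' though paired references exist. Training is a pure function of
#' (data, config) on one device: the same seed reproduces the history
#' bit-for-bit.
#'
#' @param samples list of `paired_sample`s used for training.
#' @param config a `gan_config`.
#' @param val_samples optional held-out `paired_sample`s; their slices feed
#'   the per-epoch validation metrics.
#' @return The trained bundle: `G`, `F`, `D_pvc`, `D_nonpvc`, `config`,
#'   `history` (per-epoch data.frame) and `val0` (pre-training validation
#'   metrics).
#' @export
train_cyclegan <- function(samples, config = gan_config(),
                           val_samples = NULL) {
  if (length(samples) < 2L) stop("need at least 2 training samples")
  data <- extract_slices(samples, config)
  nx <- length(data$x)
  if (nx < 2L) stop("no usable training slices (check brain_fraction)")
  val <- if (!is.null(val_samples)) extract_slices(val_samples, config)
         else NULL
  if (!is.null(val) && length(val$x) > config$val_slices) {
    keep <- round(seq(1, length(val$x), length.out = config$val_slices))
    val$x <- val$x[keep]; val$y <- val$y[keep]
  }
  bundle <- build_models(config)
  G <- bundle$G; F_ <- bundle$F
  Dy <- bundle$D_pvc; Dx <- bundle$D_nonpvc
  adamG <- nn_adam_init(G$params); adamF <- nn_adam_init(F_$params)
  adamDy <- nn_adam_init(Dy$params); adamDx <- nn_adam_init(Dx$params)
  buf_y <- list(); buf_x <- list()
  hist <- data.frame()
  val0 <- if (!is.null(val)) val_metrics(G, val$x, val$y) else NULL
  lc <- config$lambda_cycle; li <- config$lambda_identity
  ls <- config$lambda_supervised

  withr_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      # two-phase schedule: constant, then linear decay to zero
      n_const <- ceiling(config$decay_start * config$epochs)
      lr_e <- if (epoch <= n_const) config$lr
              else config$lr * (config$epochs - epoch + 1L) /
                   (config$epochs - n_const + 1L)
      ord_x <- sample(nx); ord_y <- sample(nx)
      acc <- c(g_adv = 0, d = 0, cycle = 0, identity = 0)
      for (it in seq_len(nx)) {
        x <- data$x[[ord_x[it]]]
        y <- data$y[[ord_y[it]]]
        n_pix <- length(x)

        fy <- gen_forward(G, x)            # G(x): fake corrected
        cycx <- gen_forward(F_, fy$y)      # F(G(x))
        fx <- gen_forward(F_, y)           # F(y): fake uncorrected
        cycy <- gen_forward(G, fx$y)       # G(F(y))
        idty <- gen_forward(G, y)
        idtx <- gen_forward(F_, x)
        dfy <- nn_forward(Dy, fy$y)
        dfx <- nn_forward(Dx, fx$y)
        n_patch <- length(dfy$y)

        adv <- mean((dfy$y - 1)^2) + mean((dfx$y - 1)^2)
        cyc <- mean(abs(cycx$y - x)) + mean(abs(cycy$y - y))
        idt <- mean(abs(idty$y - y)) + mean(abs(idtx$y - x))
        if (!is.finite(adv + cyc + idt))
          stop("training diverged (non-finite loss) at epoch ", epoch,
               ", iteration ", it)
        acc["g_adv"] <- acc["g_adv"] + adv
        acc["cycle"] <- acc["cycle"] + cyc
        acc["identity"] <- acc["identity"] + idt

        # ---- generator gradients (D weights frozen on this pass) ----
        gG <- NULL; gF <- NULL
        b <- gen_backward(G, cycy$cache, lc * sign(cycy$y - y) / n_pix)
        gG <- nn_grads_add(gG, b$grads); dfx_cyc <- b$dx
        b <- gen_backward(G, idty$cache, li * sign(idty$y - y) / n_pix)
        gG <- nn_grads_add(gG, b$grads)
        dfy_total <- nn_backward(Dy, dfy$caches,
                                 2 * (dfy$y - 1) / n_patch)$dx
        b <- gen_backward(F_, cycx$cache, lc * sign(cycx$y - x) / n_pix)
        gF <- nn_grads_add(gF, b$grads)
        dfy_total <- dfy_total + b$dx
        if (ls > 0) dfy_total <- dfy_total + ls * sign(fy$y - y) / n_pix
        b <- gen_backward(G, fy$cache, dfy_total)
        gG <- nn_grads_add(gG, b$grads)

        dfx_total <- nn_backward(Dx, dfx$caches,
                                 2 * (dfx$y - 1) / n_patch)$dx + dfx_cyc
        b <- gen_backward(F_, fx$cache, dfx_total)
        gF <- nn_grads_add(gF, b$grads)
        b <- gen_backward(F_, idtx$cache, li * sign(idtx$y - x) / n_pix)
        gF <- nn_grads_add(gF, b$grads)

        st <- nn_adam_step(G$params, gG, adamG, lr_e, config$beta1,
                           config$beta2)
        G$params <- st$params; adamG <- st$state
        st <- nn_adam_step(F_$params, gF, adamF, lr_e, config$beta1,
                           config$beta2)
        F_$params <- st$params; adamF <- st$state

        # ---- discriminator updates from the image buffer ----
        pick <- function(buf, img) {
          if (length(buf) < config$buffer_size) {
            buf[[length(buf) + 1L]] <- img
            list(buf = buf, img = img)
          } else {
            k <- sample(config$buffer_size, 1L)
            out <- if (stats::runif(1) < 0.5) buf[[k]] else img
            buf[[k]] <- img
            list(buf = buf, img = out)
          }
        }
        py <- pick(buf_y, fy$y); buf_y <- py$buf
        px <- pick(buf_x, fx$y); buf_x <- px$buf

        upd_disc <- function(D, adamD, real, fake) {
          rr <- nn_forward(D, real)
          rf <- nn_forward(D, fake)
          loss <- 0.5 * (mean((rr$y - 1)^2) + mean(rf$y^2))
          g <- nn_grads_add(
            nn_backward(D, rr$caches, (rr$y - 1) / length(rr$y))$grads,
            nn_backward(D, rf$caches, rf$y / length(rf$y))$grads)
          st <- nn_adam_step(D$params, g, adamD, lr_e, config$beta1,
                             config$beta2)
          D$params <- st$params
          list(D = D, adam = st$state, loss = loss)
        }
        u <- upd_disc(Dy, adamDy, y, py$img)
        Dy <- u$D; adamDy <- u$adam; dl <- u$loss
        u <- upd_disc(Dx, adamDx, x, px$img)
        Dx <- u$D; adamDx <- u$adam
        acc["d"] <- acc["d"] + dl + u$loss
      }
      row <- data.frame(epoch = epoch,
                        g_adv = acc[["g_adv"]] / nx,
                        d_loss = acc[["d"]] / nx,
                        cycle = acc[["cycle"]] / nx,
                        identity = acc[["identity"]] / nx,
                        g_total = (acc[["g_adv"]] + lc * acc[["cycle"]] +
                                   li * acc[["identity"]]) / nx,
                        val_rmse = NA_real_, val_ssim = NA_real_)
      if (!is.null(val)) {
        vm <- val_metrics(G, val$x, val$y)
        row$val_rmse <- vm[["rmse"]]; row$val_ssim <- vm[["ssim"]]
      }
      hist <- rbind(hist, row)
    }
  })
  list(G = G, F = F_, D_pvc = Dy, D_nonpvc = Dx, config = config,
       history = hist, val0 = val0)
}

#' Apply the trained translator to a full volume
#'
#' Normalizes the volume (its own 99.5th-percentile record), runs the
#' uncorrected-to-corrected generator slice-by-slice along the configured
#' axis, denormalizes back to SUV units, and clips at zero.
#'
#' @param bundle a trained bundle from [train_cyclegan()].
#' @param img an uncorrected `volume_image`.
#' @return The predicted corrected `volume_image` on the same grid.
#' @export
predict_pvc <- function(bundle, img) {
  stopifnot(is_volume_image(img))
  cfg <- bundle$config
  d <- dim(img$values)
  if (any(d[-cfg$slice_axis] < 11L))
    stop("grid too small for the network's receptive field")
  nv <- normalize_volume(img)
  out <- array(0, d)
  for (k in seq_len(d[cfg$slice_axis])) {
    sl <- slice_of(nv$values, cfg$slice_axis, k)
    pr <- drop(gen_forward(bundle$G, sl)$y)
    if (cfg$slice_axis == 1L) out[k, , ] <- pr
    else if (cfg$slice_axis == 2L) out[, k, ] <- pr
    else out[, , k] <- pr
  }
  with_values(img, array(denormalize_volume(out, nv$record), d))
}

#' Five-fold cross-validation split utility
#'
#' @param n number of samples.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return List of k integer vectors (test indices per fold).
#' @export
cv_folds <- function(n, k = 5L, seed = 1L) {
  if (k < 2L || k > n) stop("`k` must be in [2, n]")
  idx <- withr_seed(seed, sample(n))
  split(idx, rep_len(seq_len(k), n))
}
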