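# Two-channel U-Net (MAB, LIB probability maps) with the adaptive triple
# Dice loss (ATDL). The compiled engine lives in src/unet.cpp; this file
# holds parameter initialization, the ATDL weight schedule, and the
# fit/predict interface.

unet_channels <- function(depth, base) base * 2^(seq_len(depth + 1L) - 1L)

he_mat <- function(nout, nin_eff, nin_cols) {
  matrix(rnorm(nout * nin_cols, 0, sqrt(2 / nin_eff)), nout, nin_cols)
}

bn_params <- function(c) {
  list(g = matrix(1, 1, c), b = matrix(0, 1, c),
       rm = matrix(0, 1, c), rv = matrix(1, 1, c))
}

#' Initialize U-Net parameters
#'
#' Encoder/decoder blocks of two 3x3 convolutions with batch normalization
#' and ReLU; 2x2 max pooling; 2x2 stride-2 transposed convolutions; a final
#' 1x1 convolution with sigmoid giving the two output channels (MAB and LIB
#' membership probabilities). The reference width is 32 base channels; the
#' `width_mult` default of 0.25 gives the desk-scale network.
#'
#' @param depth number of pooling stages (input size must be divisible by
#'   `2^depth`).
#' @param width_mult multiplier on the 32-channel reference width.
#' @param seed RNG seed for the He-normal initialization.
#' @return named list of parameter matrices (an `unet_params` object).
#' @export
unet_init <- function(depth = 4, width_mult = 0.25, seed = 1) {
  base <- max(2L, round(32 * width_mult))
  ch <- unet_channels(depth, base)
  with_seed(seed, {
    P <- list()
    add_bn <- function(P, name, c) {
      bp <- bn_params(c)
      P[[paste0(name, "_g")]] <- bp$g; P[[paste0(name, "_b")]] <- bp$b
      P[[paste0(name, "_rm")]] <- bp$rm; P[[paste0(name, "_rv")]] <- bp$rv
      P
    }
    cin <- 1L
    for (l in seq_len(depth)) {
      cl <- ch[l]
      P[[sprintf("enc%d_c1_W", l)]] <- he_mat(cl, 9 * cin, 9 * cin)
      P <- add_bn(P, sprintf("enc%d_n1", l), cl)
      P[[sprintf("enc%d_c2_W", l)]] <- he_mat(cl, 9 * cl, 9 * cl)
      P <- add_bn(P, sprintf("enc%d_n2", l), cl)
      cin <- cl
    }
    cb <- ch[depth + 1L]
    P[["bott_c1_W"]] <- he_mat(cb, 9 * cin, 9 * cin)
    P <- add_bn(P, "bott_n1", cb)
    P[["bott_c2_W"]] <- he_mat(cb, 9 * cb, 9 * cb)
    P <- add_bn(P, "bott_n2", cb)
    for (l in rev(seq_len(depth))) {
      cl <- ch[l]
      cbelow <- ch[l + 1L]
      P[[sprintf("up%d_W", l)]] <- he_mat(4 * cl, cbelow, cbelow)
      P[[sprintf("up%d_b", l)]] <- matrix(0, 1, cl)
      P[[sprintf("dec%d_c1_W", l)]] <- he_mat(cl, 9 * 2 * cl, 9 * 2 * cl)
      P <- add_bn(P, sprintf("dec%d_n1", l), cl)
      P[[sprintf("dec%d_c2_W", l)]] <- he_mat(cl, 9 * cl, 9 * cl)
      P <- add_bn(P, sprintf("dec%d_n2", l), cl)
    }
    P[["out_W"]] <- he_mat(2, ch[1L], ch[1L])
    # sparse-start bias: beginning near-empty predictions keeps the
    # sigmoid out of the saturated all-foreground attractor that the Dice
    # loss cannot escape (its gradient vanishes on saturated pixels)
    P[["out_b"]] <- matrix(-2, 1, 2)
    structure(P, depth = depth, base = base, class = "unet_params")
  })
}

zero_like <- function(P) lapply(P, function(m) matrix(0, nrow(m), ncol(m)))

#' Soft Dice loss
#'
#' `1 - 2 * sum(y * p) / (sum(y) + sum(p) + eps)` with `eps = 1e-6`;
#' the per-component loss entering the adaptive triple Dice loss.
#'
#' @param y binary label matrix.
#' @param p probability matrix of the same shape.
#' @return loss in \[0, 1\].
#' @export
soft_dice_loss <- function(y, p) {
  if (!all(dim(y) == dim(p))) stop("shape mismatch")
  1 - 2 * sum(y * p) / (sum(y) + sum(p) + 1e-6)
}

#' Create an adaptive triple-Dice-loss state
#'
#' Phase 1 uses uniform weights (1/3 each) so the network first localizes
#' the MAB and LIB. Once the smoothed MAB and LIB losses both drop below the
#' smoothed vessel-wall (CVW) loss — or after `warmup_steps` — phase 2
#' assigns weights proportional to the smoothed component losses (with a
#' 0.05 floor), which automatically emphasises the thin CVW component.
#'
#' @param warmup_steps step count after which phase 2 is forced.
#' @param decay exponential smoothing factor of the component losses.
#' @return list of class `atdl_state` with weights `a`, `b`, `c` (sum 1),
#'   `phase`, smoothed losses `lbar`, and a step counter.
#' @export
atdl_state <- function(warmup_steps = Inf, decay = 0.9) {
  structure(list(a = 1 / 3, b = 1 / 3, c = 1 / 3, phase = 1L,
                 lbar = NULL, step = 0L, warmup_steps = warmup_steps,
                 decay = decay),
            class = "atdl_state")
}

#' One adaptive-loss bookkeeping step
#'
#' Computes the total loss with the state's current weights, smooths the
#' component losses, and updates phase and weights.
#'
#' @param state an [atdl_state()].
#' @param losses numeric `c(mab, lib, cvw)` component Dice losses.
#' @return list with `total` (weighted loss) and the updated `state`.
#' @export
atdl_step <- function(state, losses) {
  losses <- as.numeric(losses)
  if (length(losses) != 3L || any(losses < 0))
    stop("losses must be 3 nonnegative values (MAB, LIB, CVW)")
  total <- state$a * losses[1L] + state$b * losses[2L] + state$c * losses[3L]
  state$step <- state$step + 1L
  state$lbar <- if (is.null(state$lbar)) losses
  else state$decay * state$lbar + (1 - state$decay) * losses
  if (state$phase == 1L &&
      ((state$lbar[1L] < state$lbar[3L] && state$lbar[2L] < state$lbar[3L]) ||
         state$step >= state$warmup_steps))
    state$phase <- 2L
  if (state$phase == 2L) {
    s <- sum(state$lbar)
    w <- if (s <= 0) rep(1 / 3, 3) else 0.05 + 0.85 * state$lbar / s
    state$a <- w[1L]; state$b <- w[2L]; state$c <- w[3L]
  } else {
    state$a <- state$b <- state$c <- 1 / 3
  }
  list(total = total, state = state)
}

#' Fit the two-channel U-Net with the adaptive triple Dice loss
#'
#' @param samples list of training samples, each
#'   `list(image = HxW matrix in [0,1], labels = HxWx2 binary array)` as
#'   produced by [make_slide_samples()] / [augment_training_set()].
#' @param depth,width_mult architecture, see [unet_init()].
#' @param epochs training epochs.
#' @param batch_size minibatch size.
#' @param lr Adam learning rate.
#' @param lr_warmup_steps the learning rate ramps linearly from 0 over this
#'   many steps; prevents the early sigmoid saturation that the Dice loss
#'   cannot recover from (its gradient vanishes on empty predictions).
#' @param warmup_epochs epochs after which the loss schedule is forced into
#'   phase 2 if the loss-ordering criterion has not triggered.
#' @param augment list of on-the-fly augmentation switches
#'   (`flip`, `translate`, `rotate`); `NULL` disables augmentation.
#' @param stop_loss optional early-stopping threshold: training ends once
#'   the epoch-mean weighted ATDL drops below this value.
#' @param seed RNG seed (shuffling, augmentation, initialization).
#' @param validation optional held-out sample list; total ATDL is tracked.
#' @param verbose print per-epoch losses.
#' @return object of class `carotid_unet` with elements `params`, `depth`,
#'   `atdl`, `history`, `config`.
#' @export
unet_fit <- function(samples, depth = 3, width_mult = 0.25, epochs = 4,
                     batch_size = 4, lr = 1e-3, lr_warmup_steps = 20,
                     warmup_epochs = 2,
                     augment = list(flip = TRUE, translate = TRUE,
                                    rotate = TRUE),
                     stop_loss = NULL,
                     seed = 1, validation = NULL, verbose = FALSE) {
  if (length(samples) == 0L) stop("no training samples")
  P <- unet_init(depth, width_mult, seed = seed)
  m <- zero_like(P); v <- zero_like(P)
  n <- length(samples)
  steps_per_epoch <- ceiling(n / batch_size)
  st <- atdl_state(warmup_steps = warmup_epochs * steps_per_epoch)
  history <- list()
  t <- 0L
  with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample(n)
      ep_losses <- c(0, 0, 0); nb <- 0L
      for (start in seq(1L, n, by = batch_size)) {
        idx <- ord[start:min(start + batch_size - 1L, n)]
        batch <- lapply(samples[idx], function(s)
          if (is.null(augment)) s else augment_sample(s, augment))
        t <- t + 1L
        lr_t <- lr * min(1, t / max(1L, lr_warmup_steps))
        res <- cpp_unet_train_step(
          P, m, v, depth,
          lapply(batch, `[[`, "image"), lapply(batch, `[[`, "labels"),
          c(st$a, st$b, st$c), lr_t, t)
        P <- res$params; m <- res$adam_m; v <- res$adam_v
        comp <- c(res$loss_mab, res$loss_lib, res$loss_cvw)
        up <- atdl_step(st, comp)
        st <- up$state
        ep_losses <- ep_losses + comp; nb <- nb + 1L
      }
      ep_losses <- ep_losses / nb
      val_loss <- NA_real_
      if (!is.null(validation)) {
        vp <- cpp_unet_forward(P, depth,
                               lapply(validation, `[[`, "image"))
        vl <- vapply(seq_along(validation), function(i) {
          lab <- validation[[i]]$labels
          pm <- vp[[i]][, , 1L]; pl <- vp[[i]][, , 2L]
          lm <- soft_dice_loss(lab[, , 1L], pm)
          ll <- soft_dice_loss(lab[, , 2L], pl)
          lc <- soft_dice_loss(lab[, , 1L] - lab[, , 2L],
                               pmax(pm - pl, 0))
          st$a * lm + st$b * ll + st$c * lc
        }, 1)
        val_loss <- mean(vl)
      }
      history[[ep]] <- c(mab = ep_losses[1L], lib = ep_losses[2L],
                         cvw = ep_losses[3L], phase = st$phase,
                         a = st$a, b = st$b, c = st$c, val = val_loss)
      if (verbose)
        message(sprintf(
          "epoch %d: L_MAB %.3f L_LIB %.3f L_CVW %.3f (phase %d)",
          ep, ep_losses[1L], ep_losses[2L], ep_losses[3L], st$phase))
      if (!is.null(stop_loss) &&
          st$a * ep_losses[1L] + st$b * ep_losses[2L] +
            st$c * ep_losses[3L] < stop_loss)
        break
    }
  })
  structure(list(params = P, depth = depth, atdl = st,
                 history = do.call(rbind, history),
                 config = list(depth = depth, width_mult = width_mult,
                               epochs = epochs, batch_size = batch_size,
                               lr = lr, warmup_epochs = warmup_epochs,
                               seed = seed, n_samples = n)),
            class = "carotid_unet")
}

#' @export
print.carotid_unet <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  cat(sprintf(
    "<carotid_unet> depth %d, %d training samples, %d epochs\n  final losses: MAB %.3f, LIB %.3f, CVW %.3f (ATDL phase %d; a=%.2f b=%.2f c=%.2f)\n",
    x$depth, x$config$n_samples, x$config$epochs,
    h[["mab"]], h[["lib"]], h[["cvw"]], x$atdl$phase,
    x$atdl$a, x$atdl$b, x$atdl$c))
  invisible(x)
}

#' Forward pass: per-pixel MAB/LIB probabilities
#'
#' @param object a fitted `carotid_unet`.
#' @param images list of preprocessed H x W matrices (or a single matrix).
#' @param ... unused.
#' @return list of H x W x 2 probability arrays.
#' @export
predict.carotid_unet <- function(object, images, ...) {
  if (is.matrix(images)) images <- list(images)
  cpp_unet_forward(object$params, object$depth, images)
}
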