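#' @title Tiny fully-convolutional segmenter
#'
#' @description A deliberately small (~1.3k parameter) encoder-decoder used
#' by the benchmark harness: 3x3 conv + ReLU, 2x2 mean-pool, 3x3 conv +
#' ReLU, 2x nearest-neighbour upsample, skip concatenation, and a 1x1 conv
#' to class logits with a final softmax. Forward and backward passes are
#' implemented directly in R (im2col + matrix multiply), so any loss in the
#' package can drive training through its analytic gradient. The harness's
#' claims are about losses, not architecture; the model only needs to be
#' differentiable and able to fit the synthetic tasks.
#'
#' @name segmenter
NULL

# cache of im2col index matrices, keyed by shape
.idx_cache <- new.env(parent = emptyenv())

.im2col_info <- function(B, H, W, Cin, k) {
  key <- paste(B, H, W, Cin, k, sep = "_")
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  pad <- (k - 1L) %/% 2L
  Hp <- H + 2L * pad; Wp <- W + 2L * pad
  pos <- expand.grid(h = seq_len(H), w = seq_len(W))          # h fastest
  col <- expand.grid(ki = seq_len(k), kj = seq_len(k), ci = seq_len(Cin))
  # linear offset into the zero-padded (B, Hp, Wp, Cin) array, without batch
  base <- outer(pos$h - 1L, col$ki - 1L, `+`) +
    Hp * outer(pos$w - 1L, col$kj - 1L, `+`) +
    Hp * Wp * matrix(rep(col$ci - 1L, each = H * W), nrow = H * W)
  baseExp <- base[rep(seq_len(H * W), each = B), , drop = FALSE]
  idx <- rep(seq_len(B), times = H * W) + B * baseExp
  info <- list(idx = idx, pad = pad, Hp = Hp, Wp = Wp,
               B = B, H = H, W = W, Cin = Cin, k = k)
  .idx_cache[[key]] <- info
  info
}

.pad_input <- function(x, info) {
  xp <- array(0, dim = c(info$B, info$Hp, info$Wp, info$Cin))
  xp[, info$pad + seq_len(info$H), info$pad + seq_len(info$W), ] <- x
  xp
}

# x: (B,H,W,Cin) -> list(out = (B*H*W) x Cout matrix, col = im2col matrix)
.conv_fwd <- function(x, Wm, bias, info) {
  xp <- .pad_input(x, info)
  col <- matrix(xp[info$idx], nrow = nrow(info$idx))
  out <- col %*% Wm
  out <- sweep(out, 2, bias, `+`)
  list(out = out, col = col)
}

.conv_bwd <- function(dout, col, Wm, info, need_dx = TRUE) {
  dW <- crossprod(col, dout)
  db <- colSums(dout)
  dx <- NULL
  if (need_dx) {
    # input gradient of a same-padded convolution = convolution of the
    # output gradient with the spatially flipped, channel-transposed kernel
    Cout <- ncol(Wm)
    douta <- array(dout, dim = c(info$B, info$H, info$W, Cout))
    info2 <- .im2col_info(info$B, info$H, info$W, Cout, info$k)
    dx <- .conv_fwd(douta, .flip_weights(Wm, info$k, info$Cin, Cout),
                    numeric(info$Cin), info2)$out
    dx <- array(dx, dim = c(info$B, info$H, info$W, info$Cin))
  }
  list(dW = dW, db = db, dx = dx)
}

# (k*k*Cin) x Cout weight matrix -> (k*k*Cout) x Cin matrix with both
# spatial kernel axes reversed
.flip_weights <- function(Wm, k, Cin, Cout) {
  Wa <- array(Wm, dim = c(k, k, Cin, Cout))
  Wa <- Wa[rev(seq_len(k)), rev(seq_len(k)), , , drop = FALSE]
  matrix(aperm(Wa, c(1, 2, 4, 3)), ncol = Cin)
}

.meanpool2_fwd <- function(x) {
  H <- dim(x)[2]; W <- dim(x)[3]
  o1 <- seq(1, H, 2); o2 <- seq(2, H, 2); p1 <- seq(1, W, 2); p2 <- seq(2, W, 2)
  (x[, o1, p1, , drop = FALSE] + x[, o2, p1, , drop = FALSE] +
     x[, o1, p2, , drop = FALSE] + x[, o2, p2, , drop = FALSE]) / 4
}

.meanpool2_bwd <- function(dout, H, W) {
  B <- dim(dout)[1]; C <- dim(dout)[4]
  dx <- array(0, dim = c(B, H, W, C))
  o1 <- seq(1, H, 2); o2 <- seq(2, H, 2); p1 <- seq(1, W, 2); p2 <- seq(2, W, 2)
  q <- dout / 4
  dx[, o1, p1, ] <- q; dx[, o2, p1, ] <- q
  dx[, o1, p2, ] <- q; dx[, o2, p2, ] <- q
  dx
}

.upsample2_fwd <- function(x) {
  h <- dim(x)[2]; w <- dim(x)[3]
  x[, rep(seq_len(h), each = 2), rep(seq_len(w), each = 2), , drop = FALSE]
}

.upsample2_bwd <- function(dout) {
  H <- dim(dout)[2]; W <- dim(dout)[3]
  o1 <- seq(1, H, 2); o2 <- seq(2, H, 2); p1 <- seq(1, W, 2); p2 <- seq(2, W, 2)
  dout[, o1, p1, , drop = FALSE] + dout[, o2, p1, , drop = FALSE] +
    dout[, o1, p2, , drop = FALSE] + dout[, o2, p2, , drop = FALSE]
}

# ---- model ------------------------------------------------------------------

#' Create a tiny segmenter specification
#'
#' @param num_classes Number of output classes C.
#' @param filters Length-2 integer vector: channels of the encoder and
#'   bottleneck convolutions.
#' @param kernel Odd convolution kernel size.
#' @return A `segmenter_spec`.
#' @export
tiny_segmenter <- function(num_classes = 2L, filters = c(8L, 16L),
                           kernel = 3L) {
  stopifnot(kernel %% 2 == 1, length(filters) == 2, num_classes >= 2)
  structure(list(num_classes = as.integer(num_classes),
                 filters = as.integer(filters), kernel = as.integer(kernel),
                 in_channels = 1L),
            class = "segmenter_spec")
}

# Xavier-uniform initialisation
.xavier <- function(fan_in, fan_out, n) {
  lim <- sqrt(6 / (fan_in + fan_out))
  stats::runif(n, -lim, lim)
}

.init_params <- function(spec) {
  k <- spec$kernel; f1 <- spec$filters[1]; f2 <- spec$filters[2]
  cin <- spec$in_channels; C <- spec$num_classes
  list(
    W1 = matrix(.xavier(k * k * cin, f1, k * k * cin * f1), ncol = f1),
    b1 = numeric(f1),
    W2 = matrix(.xavier(k * k * f1, f2, k * k * f1 * f2), ncol = f2),
    b2 = numeric(f2),
    W3 = matrix(.xavier(f1 + f2, C, (f1 + f2) * C), ncol = C),
    b3 = numeric(C))
}

.n_params <- function(params) sum(vapply(params, length, integer(1)))

# forward pass; returns probabilities plus everything backward needs
.segmenter_fwd <- function(params, x, spec) {
  B <- dim(x)[1]; H <- dim(x)[2]; W <- dim(x)[3]
  i1 <- .im2col_info(B, H, W, spec$in_channels, spec$kernel)
  c1 <- .conv_fwd(x, params$W1, params$b1, i1)
  a1 <- array(pmax(c1$out, 0), dim = c(B, H, W, spec$filters[1]))
  p1 <- .meanpool2_fwd(a1)
  i2 <- .im2col_info(B, H / 2, W / 2, spec$filters[1], spec$kernel)
  c2 <- .conv_fwd(p1, params$W2, params$b2, i2)
  a2 <- array(pmax(c2$out, 0), dim = c(B, H / 2, W / 2, spec$filters[2]))
  u2 <- .upsample2_fwd(a2)
  cat <- array(c(a1, u2), dim = c(B, H, W, sum(spec$filters)))
  catm <- matrix(cat, ncol = sum(spec$filters))
  logits <- sweep(catm %*% params$W3, 2, params$b3, `+`)
  rmax <- Reduce(pmax, lapply(seq_len(ncol(logits)), function(j) logits[, j]))
  pm <- exp(logits - rmax)
  pm <- pm / rowSums(pm)
  list(p = array(pm, dim = c(B, H, W, spec$num_classes)), pm = pm,
       catm = catm, a1 = a1, a2 = a2, c1 = c1, c2 = c2, i1 = i1, i2 = i2,
       B = B, H = H, W = W)
}

# backward pass from dL/dp (array); returns parameter gradients
.segmenter_bwd <- function(params, fwd, dLdp, spec) {
  B <- fwd$B; H <- fwd$H; W <- fwd$W
  dp <- matrix(dLdp, ncol = spec$num_classes)
  # softmax jacobian: dz = p * (dp - rowSums(p * dp))
  dz <- fwd$pm * (dp - rowSums(fwd$pm * dp))
  dW3 <- crossprod(fwd$catm, dz)
  db3 <- colSums(dz)
  dcat <- array(dz %*% t(params$W3), dim = c(B, H, W, sum(spec$filters)))
  f1 <- spec$filters[1]
  da1 <- dcat[, , , seq_len(f1), drop = FALSE]
  du2 <- dcat[, , , f1 + seq_len(spec$filters[2]), drop = FALSE]
  da2 <- .upsample2_bwd(du2)
  da2 <- da2 * (fwd$a2 > 0)
  g2 <- .conv_bwd(matrix(da2, ncol = spec$filters[2]), fwd$c2$col, params$W2,
                  fwd$i2, need_dx = TRUE)
  da1 <- da1 + .meanpool2_bwd(g2$dx, H, W)
  da1 <- da1 * (fwd$a1 > 0)
  g1 <- .conv_bwd(matrix(da1, ncol = f1), fwd$c1$col, params$W1, fwd$i1,
                  need_dx = FALSE)
  list(W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db, W3 = dW3, b3 = db3)
}

# ---- training ---------------------------------------------------------------

#' Train the tiny segmenter with a given loss
#'
#' Stochastic gradient descent with momentum, mirroring the conventional
#' segmentation training recipe at desk scale: the learning rate is
#' multiplied by `lr_factor` when the validation loss has not improved for
#' `lr_patience` epochs, training stops early after `stop_patience` stale
#' epochs, and the parameters with the lowest validation loss are kept.
#' An `epochs = 0` budget returns the untrained (initialised) model.
#'
#' If the training loss becomes non-finite the run is flagged
#' (`diverged = TRUE`) and the best parameters seen so far are returned.
#'
#' @param train,val `synthetic_task` objects (see [split_task()]).
#' @param loss A [seg_loss()] specification driving the gradient.
#' @param spec A [tiny_segmenter()] specification; its `num_classes` must
#'   match the task.
#' @param epochs Maximum number of epochs.
#' @param batch_size Minibatch size.
#' @param lr Initial learning rate.
#' @param momentum Momentum coefficient.
#' @param lr_patience,lr_factor,stop_patience Plateau schedule parameters.
#' @param seed Seed for initialisation and shuffling.
#' @return A `trained_segmenter`: list with `params`, `spec`, `loss`,
#'   `history` (tibble: epoch, train_loss, val_loss, lr), `epochs_run`,
#'   `diverged`, `seed`.
#' @export
train_segmenter <- function(train, val, loss, spec = NULL, epochs = 15,
                            batch_size = 8, lr = 0.1, momentum = 0.9,
                            lr_patience = 3, lr_factor = 0.5,
                            stop_patience = 6, seed = 1) {
  stopifnot(inherits(train, "synthetic_task"), inherits(val, "synthetic_task"),
            inherits(loss, "seg_loss_spec"))
  if (is.null(spec)) spec <- tiny_segmenter(num_classes = train$num_classes)
  C <- spec$num_classes
  set.seed(seed)
  params <- .init_params(spec)
  vel <- lapply(params, function(w) w * 0)
  n <- dim(train$masks)[1]
  y_all <- one_hot_encode(train$masks, C)
  yv_all <- one_hot_encode(val$masks, C)
  best <- list(params = params, val = Inf)
  history <- vector("list", epochs)
  stale <- 0L; lr_stale <- 0L; diverged <- FALSE; epochs_run <- 0L

  if (epochs > 0) {
    for (ep in seq_len(epochs)) {
      perm <- sample.int(n)
      starts <- seq(1, n, by = batch_size)
      tr_losses <- numeric(length(starts))
      for (s in seq_along(starts)) {
        idx <- perm[seq(starts[s], min(starts[s] + batch_size - 1, n))]
        x <- .subset_batch(train$images, idx)
        y <- .subset_batch(y_all, idx)
        fwd <- .segmenter_fwd(params, x, spec)
        lv <- compute_loss(loss, fwd$p, y)
        tr_losses[s] <- lv$value
        if (!is.finite(lv$value)) { diverged <- TRUE; break }
        dLdp <- loss_gradient(loss, fwd$p, y)
        grads <- .segmenter_bwd(params, fwd, dLdp, spec)
        for (nm in names(params)) {
          vel[[nm]] <- momentum * vel[[nm]] - lr * grads[[nm]]
          params[[nm]] <- params[[nm]] + vel[[nm]]
        }
      }
      epochs_run <- ep
      if (diverged) break
      val_loss <- .eval_loss(params, val$images, yv_all, loss, spec, batch_size)
      history[[ep]] <- tibble::tibble(epoch = ep,
                                      train_loss = mean(tr_losses),
                                      val_loss = val_loss, lr = lr)
      if (is.finite(val_loss) && val_loss < best$val - 1e-8) {
        best <- list(params = params, val = val_loss)
        stale <- 0L; lr_stale <- 0L
      } else {
        stale <- stale + 1L; lr_stale <- lr_stale + 1L
        if (lr_stale >= lr_patience) { lr <- lr * lr_factor; lr_stale <- 0L }
        if (stale >= stop_patience) break
      }
    }
  }
  structure(list(params = best$params, spec = spec, loss = loss,
                 history = dplyr::bind_rows(history[!vapply(history, is.null, logical(1))]),
                 epochs_run = epochs_run, diverged = diverged,
                 best_val_loss = best$val, seed = seed),
            class = "trained_segmenter")
}

.eval_loss <- function(params, images, y, loss, spec, batch_size) {
  n <- dim(images)[1]
  starts <- seq(1, n, by = batch_size)
  vals <- numeric(length(starts)); wts <- numeric(length(starts))
  for (s in seq_along(starts)) {
    idx <- seq(starts[s], min(starts[s] + batch_size - 1, n))
    fwd <- .segmenter_fwd(params, .subset_batch(images, idx), spec)
    vals[s] <- compute_loss(loss, fwd$p, .subset_batch(y, idx))$value
    wts[s] <- length(idx)
  }
  sum(vals * wts) / sum(wts)
}

#' @export
print.trained_segmenter <- function(x, ...) {
  cat(sprintf(
    "<trained_segmenter> %d params, loss %s, %d epoch(s) run, best val loss %.4g%s\n",
    .n_params(x$params), x$loss$label, x$epochs_run, x$best_val_loss,
    if (x$diverged) " [DIVERGED]" else ""))
  invisible(x)
}

#' @rdname tidiers
#' @export
tidy.trained_segmenter <- function(x, ...) x$history

#' @rdname tidiers
#' @export
glance.trained_segmenter <- function(x, ...) {
  tibble::tibble(loss = x$loss$label, epochs_run = x$epochs_run,
                 best_val_loss = x$best_val_loss, diverged = x$diverged,
                 n_params = .n_params(x$params), seed = x$seed)
}

#' Predict segmentations with a trained tiny segmenter
#'
#' @param object A [train_segmenter()] result.
#' @param images Image array `(batch, H, W, 1)` (e.g. a task's `$images`).
#' @param type `"label"` for argmax label masks, `"prob"` for the softmax
#'   probability map.
#' @param batch_size Forward-pass chunk size.
#' @param ... Unused.
#' @return Integer label array `(batch, H, W)` or probability array
#'   `(batch, H, W, C)`.
#' @export
predict.trained_segmenter <- function(object, images,
                                      type = c("label", "prob"),
                                      batch_size = 16, ...) {
  type <- match.arg(type)
  n <- dim(images)[1]
  starts <- seq(1, n, by = batch_size)
  chunks <- lapply(seq_along(starts), function(s) {
    idx <- seq(starts[s], min(starts[s] + batch_size - 1, n))
    .segmenter_fwd(object$params, .subset_batch(images, idx), object$spec)$p
  })
  C <- object$spec$num_classes
  p <- array(0, dim = c(n, dim(images)[2], dim(images)[3], C))
  at <- 1L
  for (ch in chunks) {
    b <- dim(ch)[1]
    p[seq(at, at + b - 1L), , , ] <- ch
    at <- at + b
  }
  if (type == "prob") p else .argmax_labels(p)
}
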