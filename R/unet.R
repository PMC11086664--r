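#' @title Trainable U-Net breast segmenter
#' @description A compact 2D U-Net (encoder-decoder with skip connections,
#'   3x3 convolutions, 2x2 max pooling, nearest-neighbor upsampling, sigmoid
#'   output) trained with the Adam optimizer and a binary cross-entropy loss.
#'   Convolutions are evaluated as im2col gathers followed by BLAS matrix
#'   products, which keeps desk-scale training (tens of projection images at
#'   128 x 128) tractable in plain R.
#' @name unet
NULL

# ---- spatial index tables (precomputed once per feature-map size) ----------

.conv_idx <- function(H, W) {
  Hp <- H + 2L
  r <- rep(seq_len(H), times = W)
  cc <- rep(seq_len(W), each = H)
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  idx <- matrix(0L, H * W, 9L)
  for (k in seq_len(9L)) {
    idx[, k] <- (cc + offs$dc[k]) * Hp + (r + offs$dr[k] + 1L)
  }
  idx
}

.pool_idx <- function(H, W) {
  Ho <- H %/% 2L; Wo <- W %/% 2L
  i <- rep(seq_len(Ho), times = Wo)
  j <- rep(seq_len(Wo), each = Ho)
  cbind((2L * j - 2L) * H + 2L * i - 1L,
        (2L * j - 2L) * H + 2L * i,
        (2L * j - 1L) * H + 2L * i - 1L,
        (2L * j - 1L) * H + 2L * i)
}

.up_idx <- function(H, W) {
  # maps output pixel (2H x 2W) to its source pixel (H x W)
  Ho <- 2L * H; Wo <- 2L * W
  r <- rep(seq_len(Ho), times = Wo)
  cc <- rep(seq_len(Wo), each = Ho)
  ((cc + 1L) %/% 2L - 1L) * H + (r + 1L) %/% 2L
}

.conv_fwd <- function(Xm, Wm, b, idx, Hp_len) {
  C <- ncol(Xm)
  P <- matrix(0, Hp_len, C)
  P[idx[, 5L], ] <- Xm
  Xcol <- matrix(P[as.vector(idx), ], nrow(Xm), 9L * C)
  out <- Xcol %*% Wm
  out <- sweep(out, 2L, b, "+")
  list(out = out, Xcol = Xcol)
}

.conv_bwd <- function(dOut, Xcol, Wm, idx, Hp_len, Cin) {
  Cout <- ncol(dOut)
  dW <- crossprod(Xcol, dOut)
  db <- colSums(dOut)
  # full correlation with 180-degree-rotated, channel-transposed kernels
  arr <- array(Wm, c(9L, Cin, Cout))[9:1, , , drop = FALSE]
  Wrot <- matrix(aperm(arr, c(1, 3, 2)), 9L * Cout, Cin)
  P <- matrix(0, Hp_len, Cout)
  P[idx[, 5L], ] <- dOut
  Dcol <- matrix(P[as.vector(idx), ], nrow(dOut), 9L * Cout)
  dX <- Dcol %*% Wrot
  list(dX = dX, dW = dW, db = db)
}

# ---- model ------------------------------------------------------------------

.unet_widths <- function(base_width, levels) base_width * 2L^(seq_len(levels) - 1L)

#' Initialize a U-Net model
#'
#' @param input_shape training image shape (rows, cols); both must be
#'   divisible by `2^(levels - 1)`.
#' @param base_width channels at the first encoder level; doubled per level.
#' @param levels encoder depth including the bottleneck (>= 2).
#' @param seed RNG seed for He-normal weight initialization.
#' @return An object of class `unet_model`.
#' @export
unet_init <- function(input_shape = c(128L, 128L), base_width = 8L,
                      levels = 3L, seed = 1L) {
  stopifnot(levels >= 2L, all(input_shape %% 2L^(levels - 1L) == 0L))
  w <- .unet_widths(base_width, levels)
  layer_plan <- list()
  for (l in seq_len(levels)) {
    cin <- if (l == 1L) 1L else w[l - 1L]
    layer_plan[[sprintf("e%d_1", l)]] <- c(cin, w[l])
    layer_plan[[sprintf("e%d_2", l)]] <- c(w[l], w[l])
  }
  for (l in rev(seq_len(levels - 1L))) {
    layer_plan[[sprintf("d%d_1", l)]] <- c(w[l] + w[l + 1L], w[l])
    layer_plan[[sprintf("d%d_2", l)]] <- c(w[l], w[l])
  }
  layer_plan[["out"]] <- c(w[1L], 1L)
  layers <- with_seed(seed, lapply(names(layer_plan), function(nm) {
    io <- layer_plan[[nm]]
    k <- if (nm == "out") 1L else 9L
    list(W = matrix(rnorm(k * io[1] * io[2], sd = sqrt(2 / (k * io[1]))),
                    k * io[1], io[2]),
         b = numeric(io[2]))
  }))
  names(layers) <- names(layer_plan)
  structure(list(layers = layers,
                 meta = list(input_shape = as.integer(input_shape),
                             base_width = as.integer(base_width),
                             levels = as.integer(levels), seed = as.integer(seed),
                             trained_epochs = 0L),
                 loss_history = numeric(0)),
            class = "unet_model")
}

# context of precomputed index tables for one input shape
.unet_ctx <- function(shape, levels) {
  ctx <- list()
  H <- shape[1]; W <- shape[2]
  for (l in seq_len(levels)) {
    ctx[[l]] <- list(H = H, W = W, idx = .conv_idx(H, W),
                     Hp_len = (H + 2L) * (W + 2L),
                     pool = if (l < levels) .pool_idx(H, W),
                     up = if (l < levels) .up_idx(H %/% 2L, W %/% 2L))
    H <- H %/% 2L; W <- W %/% 2L
  }
  ctx
}

.unet_forward <- function(model, Xm, ctx, keep_cache = FALSE) {
  L <- model$meta$levels
  cache <- list(convs = list())
  run_conv <- function(name, X, l) {
    cc <- ctx[[l]]
    f <- .conv_fwd(X, model$layers[[name]]$W, model$layers[[name]]$b, cc$idx, cc$Hp_len)
    a <- f$out * (f$out > 0)
    if (keep_cache) cache$convs[[name]] <<- list(Xcol = f$Xcol, mask = f$out > 0,
                                                 Cin = ncol(X), level = l)
    a
  }
  feats <- vector("list", L)
  X <- Xm
  pool_arg <- list()
  for (l in seq_len(L)) {
    if (l > 1L) {
      p <- ctx[[l - 1L]]$pool
      X1 <- X[p[, 1], , drop = FALSE]; X2 <- X[p[, 2], , drop = FALSE]
      X3 <- X[p[, 3], , drop = FALSE]; X4 <- X[p[, 4], , drop = FALSE]
      Xp <- pmax(X1, X2, X3, X4)
      if (keep_cache) pool_arg[[l - 1L]] <- list(X = X, out = Xp)
      X <- Xp
    }
    X <- run_conv(sprintf("e%d_1", l), X, l)
    X <- run_conv(sprintf("e%d_2", l), X, l)
    feats[[l]] <- X
  }
  skip_cols <- integer(L)
  for (l in rev(seq_len(L - 1L))) {
    X <- X[ctx[[l]]$up, , drop = FALSE]
    skip_cols[l] <- ncol(feats[[l]])
    X <- cbind(feats[[l]], X)
    X <- run_conv(sprintf("d%d_1", l), X, l)
    X <- run_conv(sprintf("d%d_2", l), X, l)
  }
  lay <- model$layers[["out"]]
  logits <- sweep(X %*% lay$W, 2L, lay$b, "+")
  if (keep_cache) {
    cache$pool <- pool_arg; cache$skip_cols <- skip_cols
    cache$out_in <- X
  }
  list(logits = logits, cache = cache)
}

.unet_backward <- function(model, ctx, cache, dlogits) {
  L <- model$meta$levels
  grads <- list()
  conv_back <- function(name, d) {
    cc <- cache$convs[[name]]
    d <- d * cc$mask
    g <- .conv_bwd(d, cc$Xcol, model$layers[[name]]$W,
                   ctx[[cc$level]]$idx, ctx[[cc$level]]$Hp_len, cc$Cin)
    grads[[name]] <<- list(W = g$dW, b = g$db)
    g$dX
  }
  grads[["out"]] <- list(W = crossprod(cache$out_in, dlogits), b = colSums(dlogits))
  dX <- dlogits %*% t(model$layers[["out"]]$W)
  dskip <- vector("list", L)
  for (l in seq_len(L - 1L)) {
    dX <- conv_back(sprintf("d%d_2", l), dX)
    dX <- conv_back(sprintf("d%d_1", l), dX)
    ns <- cache$skip_cols[l]
    dskip[[l]] <- dX[, seq_len(ns), drop = FALSE]
    dup <- dX[, -seq_len(ns), drop = FALSE]
    dX <- rowsum(dup, ctx[[l]]$up)          # upsample backward
  }
  for (l in rev(seq_len(L))) {
    if (l < L) dX <- dX + dskip[[l]]
    dX <- conv_back(sprintf("e%d_2", l), dX)
    dX <- conv_back(sprintf("e%d_1", l), dX)
    if (l > 1L) {
      pc <- cache$pool[[l - 1L]]
      p <- ctx[[l - 1L]]$pool
      dIn <- matrix(0, nrow(pc$X), ncol(pc$X))
      taken <- matrix(FALSE, nrow(pc$out), ncol(pc$out))
      for (q in 1:4) {
        Xq <- pc$X[p[, q], , drop = FALSE]
        sel <- (Xq == pc$out) & !taken
        taken <- taken | sel
        dIn[p[, q], ] <- dX * sel
      }
      dX <- dIn
    }
  }
  grads
}

.normalize_image <- function(img) {
  mx <- max(img)
  if (mx <= 0) img else img / mx
}

.resize_to <- function(img, shape, binary = FALSE) {
  if (all(dim(img) == shape)) return(img)
  out <- EBImage::resize(EBImage::Image(img), w = shape[1], h = shape[2])
  out <- matrix(as.numeric(out), shape[1], shape[2])
  if (binary) out >= 0.5 else out
}

#' Train the U-Net breast segmenter
#'
#' Optimizes binary cross-entropy with Adam over (projection image, reference
#' breast mask) pairs. Images are rescaled to the model's training shape and
#' normalized by their maximum; pairs with an empty reference mask are
#' rejected with a warning. Training is deterministic given `seed`.
#'
#' @param images list of numeric matrices (e.g. second post-contrast
#'   subtraction MIPs) or `projection_image` objects.
#' @param masks list of logical/0-1 matrices, the reference breast masks.
#' @param epochs_max maximum number of epochs.
#' @param lr Adam learning rate.
#' @param input_shape,base_width,levels architecture; see [unet_init()].
#' @param seed seed controlling initialization and shuffling.
#' @param verbose print per-epoch loss.
#' @return A trained `unet_model` with `loss_history` (mean epoch loss).
#' @export
train_segmenter <- function(images, masks, epochs_max = 20L, lr = 1e-3,
                            input_shape = c(128L, 128L), base_width = 8L,
                            levels = 3L, seed = 1L, verbose = FALSE) {
  stopifnot(length(images) == length(masks), length(images) >= 1L)
  images <- lapply(images, function(x) if (inherits(x, "projection_image")) x$data else x)
  keep <- vapply(masks, function(m) sum(m) > 0, TRUE)
  if (!all(keep)) {
    warning(sum(!keep), " training pair(s) with empty reference masks rejected")
    images <- images[keep]; masks <- masks[keep]
  }
  n <- length(images)
  if (n < 8L) warning("only ", n, " training pair(s); segmenter may underfit (>= 8 recommended)")
  model <- unet_init(input_shape, base_width, levels, seed = seed)
  ctx <- .unet_ctx(input_shape, levels)
  X <- lapply(images, function(im) {
    matrix(as.vector(.normalize_image(.resize_to(im, input_shape))), ncol = 1)
  })
  Y <- lapply(masks, function(m) {
    matrix(as.numeric(.resize_to(m * 1, input_shape, binary = TRUE)), ncol = 1)
  })
  # Adam state
  mstate <- lapply(model$layers, function(l) list(W = l$W * 0, b = l$b * 0))
  vstate <- mstate
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  step <- 0L
  loss_hist <- numeric(epochs_max)
  with_seed(seed + 1L, {
    for (ep in seq_len(epochs_max)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (i in ord) {
        fw <- .unet_forward(model, X[[i]], ctx, keep_cache = TRUE)
        p <- 1 / (1 + exp(-fw$logits))
        y <- Y[[i]]
        p_cl <- pmin(pmax(p, 1e-7), 1 - 1e-7)
        ep_loss <- ep_loss - mean(y * log(p_cl) + (1 - y) * log(1 - p_cl))
        dlogits <- (p - y) / length(y)
        grads <- .unet_backward(model, ctx, fw$cache, dlogits)
        step <- step + 1L
        corr <- sqrt(1 - b2^step) / (1 - b1^step)
        for (nm in names(grads)) {
          g <- grads[[nm]]
          mstate[[nm]]$W <- b1 * mstate[[nm]]$W + (1 - b1) * g$W
          mstate[[nm]]$b <- b1 * mstate[[nm]]$b + (1 - b1) * g$b
          vstate[[nm]]$W <- b2 * vstate[[nm]]$W + (1 - b2) * g$W^2
          vstate[[nm]]$b <- b2 * vstate[[nm]]$b + (1 - b2) * g$b^2
          model$layers[[nm]]$W <- model$layers[[nm]]$W -
            lr * corr * mstate[[nm]]$W / (sqrt(vstate[[nm]]$W) + eps)
          model$layers[[nm]]$b <- model$layers[[nm]]$b -
            lr * corr * mstate[[nm]]$b / (sqrt(vstate[[nm]]$b) + eps)
        }
      }
      loss_hist[ep] <- ep_loss / n
      if (verbose) message(sprintf("epoch %3d  loss %.5f", ep, loss_hist[ep]))
    }
  })
  model$loss_history <- loss_hist
  model$meta$trained_epochs <- epochs_max
  model
}

#' Predict a breast probability map
#'
#' @param model a trained `unet_model`.
#' @param mip a `projection_image` or numeric matrix.
#' @return A `probability_map` object: list with `data`, a matrix of values
#'   in \[0, 1\] with the input's shape.
#' @export
predict_probability <- function(model, mip) {
  stopifnot(inherits(model, "unet_model"))
  img <- if (inherits(mip, "projection_image")) mip$data else mip
  shape0 <- dim(img)
  shape <- model$meta$input_shape
  x <- matrix(as.vector(.normalize_image(.resize_to(img, shape))), ncol = 1)
  ctx <- .unet_ctx(shape, model$meta$levels)
  fw <- .unet_forward(model, x, ctx, keep_cache = FALSE)
  p <- matrix(1 / (1 + exp(-fw$logits)), shape[1], shape[2])
  p <- .resize_to(p, shape0)
  p <- pmin(pmax(p, 0), 1)
  structure(list(data = p), class = "probability_map")
}

#' @export
print.unet_model <- function(x, ...) {
  cat("<unet_model>", x$meta$levels, "levels, base width", x$meta$base_width,
      "| input", paste(x$meta$input_shape, collapse = "x"),
      "| trained epochs:", x$meta$trained_epochs, "\n")
  if (length(x$loss_history)) {
    cat("  final BCE loss:", signif(tail(x$loss_history, 1), 4), "\n")
  }
  invisible(x)
}

#' Save / load a U-Net model artifact as plain text (JSON)
#' @param model a `unet_model`.
#' @param path file path.
#' @return `load_segmenter` returns the `unet_model`.
#' @export
save_segmenter <- function(model, path) {
  obj <- list(meta = model$meta, loss_history = model$loss_history,
              layers = lapply(model$layers, function(l) {
                list(W = as.vector(l$W), dim = dim(l$W), b = l$b)
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_segmenter
#' @export
load_segmenter <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  layers <- lapply(obj$layers, function(l) {
    list(W = matrix(l$W, l$dim[1], l$dim[2]), b = as.numeric(l$b))
  })
  structure(list(layers = layers,
                 meta = list(input_shape = as.integer(obj$meta$input_shape),
                             base_width = as.integer(obj$meta$base_width),
                             levels = as.integer(obj$meta$levels),
                             seed = as.integer(obj$meta$seed),
                             trained_epochs = as.integer(obj$meta$trained_epochs)),
                 loss_history = as.numeric(obj$loss_history)),
            class = "unet_model")
}
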