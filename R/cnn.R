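#' Network structure specification
#'
#' The seven published compact structures share a fixed recipe: `n_conv`
#' blocks of conv(kernel 3, stride 1, length-preserving padding), ReLU,
#' then maxpool(2, stride 2); finally flatten, FC(512), FC(1). Only the
#' per-layer channel pairs differ. At the canonical depth 6 with input
#' length 2048 and 32 final channels the flatten dimension is
#' `32 * 2048 / 2^6 = 1024`, matching the published "1024-512, 512-1"
#' head. Depth variants (for the depth sweep, 3-10) truncate or extend
#' the channel chain, forcing the final output channels to 32.
#'
#' @param structure_id Integer 1..7 selecting a published channel layout,
#'   or `NULL` with explicit `channels`.
#' @param n_conv Number of conv blocks (default 6; sweep range 3-10).
#' @param channels Optional list of `c(in, out)` pairs overriding the
#'   catalog.
#' @return Object of class `"structure_spec"`.
#' @export
structure_spec <- function(structure_id = NULL, n_conv = 6L,
                           channels = NULL) {
  catalog <- list(
    `1` = c(16, 32, 32, 32, 32, 32),
    `2` = c(8, 32, 32, 32, 32, 32),
    `3` = c(8, 16, 32, 32, 32, 32),
    `4` = c(4, 32, 32, 32, 32, 32),
    `5` = c(4, 16, 32, 32, 32, 32),
    `6` = c(4, 8, 16, 32, 32, 32),
    `7` = c(2, 4, 8, 16, 32, 32)
  )
  if (is.null(channels)) {
    if (is.null(structure_id) || !structure_id %in% 1:7)
      stop("structure_id must be in 1..7 (or supply channels)")
    outs <- catalog[[as.character(structure_id)]]
    if (n_conv <= 6) {
      outs <- outs[seq_len(n_conv)]
      outs[n_conv] <- 32L           # depth variants keep 32 final channels
    } else {
      outs <- c(outs, rep(32L, n_conv - 6))
    }
    ins <- c(1L, outs[-length(outs)])
    channels <- Map(c, ins, outs)
  } else {
    n_conv <- length(channels)
    ins <- vapply(channels, function(p) as.numeric(p[1]), numeric(1))
    outs <- vapply(channels, function(p) as.numeric(p[2]), numeric(1))
    if (ins[1] != 1L) stop("first layer must take 1 input channel")
    if (any(ins[-1] != outs[-length(outs)]))
      stop("channel pairs must chain (layer k out = layer k+1 in)")
  }
  structure(list(structure_id = structure_id, n_conv = as.integer(n_conv),
                 channels = channels, kernel = 3L, pool = 2L,
                 pool_stride = 2L, fc_hidden = 512L),
            class = "structure_spec")
}

#' Flatten dimension of a structure at a given input length
#' @param structure A [structure_spec()].
#' @param input_length Input segment length.
#' @return Integer flatten size `final_channels * input_length / 2^n_conv`.
#' @export
flatten_dim <- function(structure, input_length) {
  final_c <- structure$channels[[structure$n_conv]][2]
  as.integer(final_c * input_length / 2^structure$n_conv)
}

#' @export
print.structure_spec <- function(x, ...) {
  ch <- vapply(x$channels, function(p) paste0(p[1], "-", p[2]), "")
  cat(sprintf("<structure %s: conv [%s], FC(->%d->1)>\n",
              ifelse(is.null(x$structure_id), "custom", x$structure_id),
              paste(ch, collapse = " "), x$fc_hidden))
  invisible(x)
}

#' Smooth L1 loss
#'
#' Piecewise objective: `0.5 x^2` for `|x| < 1`, `|x| - 0.5` otherwise.
#' Continuous at the knee (both branches give 0.5 at `|x| = 1`), robust to
#' outliers, with bounded gradient.
#'
#' @param residual Numeric residuals.
#' @param reduce `"mean"` (default) or `"none"`.
#' @return Scalar mean loss or elementwise values.
#' @export
smooth_l1 <- function(residual, reduce = c("mean", "none")) {
  reduce <- match.arg(reduce)
  ax <- abs(residual)
  v <- ifelse(ax < 1, 0.5 * residual^2, ax - 0.5)
  if (reduce == "mean") mean(v) else v
}

# derivative of smooth L1 wrt residual (clipped linear)
smooth_l1_grad <- function(residual) pmin(pmax(residual, -1), 1)

# -- parameter init -------------------------------------------------------

init_params <- function(structure, input_length) {
  params <- list()
  fan_uniform <- function(nr, nc, fan_in) {
    bound <- 1 / sqrt(fan_in)
    matrix(stats::runif(nr * nc, -bound, bound), nr, nc)
  }
  for (l in seq_len(structure$n_conv)) {
    ci <- structure$channels[[l]][1]; co <- structure$channels[[l]][2]
    fan <- ci * structure$kernel
    params[[paste0("Wc", l)]] <- fan_uniform(co, 3 * ci, fan)
    params[[paste0("bc", l)]] <- stats::runif(co, -1 / sqrt(fan), 1 / sqrt(fan))
  }
  fd <- flatten_dim(structure, input_length)
  params$W1 <- fan_uniform(structure$fc_hidden, fd, fd)
  params$b1 <- stats::runif(structure$fc_hidden, -1 / sqrt(fd), 1 / sqrt(fd))
  params$W2 <- fan_uniform(1, structure$fc_hidden, structure$fc_hidden)
  params$b2 <- stats::runif(1, -1 / sqrt(structure$fc_hidden),
                            1 / sqrt(structure$fc_hidden))
  params
}

# -- forward / backward ---------------------------------------------------

# im2col for kernel 3, same padding: A is (C, L, B) -> (3C, L*B)
im2col3 <- function(A) {
  d <- dim(A); C <- d[1]; L <- d[2]; B <- d[3]
  Apad <- array(0, c(C, L + 2, B))
  Apad[, 2:(L + 1), ] <- A
  rbind(matrix(Apad[, 1:L, , drop = FALSE], nrow = C),
        matrix(Apad[, 2:(L + 1), , drop = FALSE], nrow = C),
        matrix(Apad[, 3:(L + 2), , drop = FALSE], nrow = C))
}

# scatter dXcol (3C, L*B) back to (C, L, B)
col2im3 <- function(dXcol, C, L, B) {
  dApad <- array(0, c(C, L + 2, B))
  for (o in 1:3) {
    blk <- array(dXcol[((o - 1) * C + 1):(o * C), , drop = FALSE],
                 c(C, L, B))
    dApad[, o:(o + L - 1), ] <- dApad[, o:(o + L - 1), ] + blk
  }
  dApad[, 2:(L + 1), , drop = FALSE]
}

nn_forward <- function(params, structure, X, keep_cache = FALSE) {
  # X: input_length x batch matrix
  L <- nrow(X); B <- ncol(X)
  A <- array(X, c(1, L, B))
  cache <- if (keep_cache) list(layers = vector("list", structure$n_conv))
  for (l in seq_len(structure$n_conv)) {
    C_in <- dim(A)[1]; Ll <- dim(A)[2]
    Xcol <- im2col3(A)
    Y <- params[[paste0("Wc", l)]] %*% Xcol + params[[paste0("bc", l)]]
    relu_mask <- Y > 0
    Y[!relu_mask] <- 0
    C_out <- nrow(Y)
    Yr <- array(Y, c(C_out, 2, Ll / 2, B))
    e1 <- Yr[, 1, , , drop = FALSE]; dim(e1) <- c(C_out, Ll / 2, B)
    e2 <- Yr[, 2, , , drop = FALSE]; dim(e2) <- c(C_out, Ll / 2, B)
    arg1 <- e1 >= e2
    P <- pmax(e1, e2)
    if (keep_cache)
      cache$layers[[l]] <- list(Xcol = Xcol, relu_mask = relu_mask,
                                arg1 = arg1, C_in = C_in, L_in = Ll)
    A <- P
  }
  dA <- dim(A)
  flat <- matrix(A, nrow = dA[1] * dA[2], ncol = B)
  Z1 <- params$W1 %*% flat + params$b1
  H <- Z1; H[H < 0] <- 0
  yhat <- as.numeric(params$W2 %*% H + params$b2)
  if (keep_cache) {
    cache$flat <- flat; cache$H <- H; cache$Z1 <- Z1
    cache$flat_dims <- dA
    list(yhat = yhat, cache = cache)
  } else list(yhat = yhat)
}

nn_backward <- function(params, structure, cache, dyhat) {
  B <- length(dyhat)
  gy <- matrix(dyhat, 1, B)
  grads <- list()
  grads$W2 <- gy %*% t(cache$H)
  grads$b2 <- sum(gy)
  dH <- t(params$W2) %*% gy
  dH[cache$Z1 <= 0] <- 0
  grads$W1 <- dH %*% t(cache$flat)
  grads$b1 <- rowSums(dH)
  dflat <- t(params$W1) %*% dH
  dA <- array(dflat, cache$flat_dims)
  for (l in rev(seq_len(structure$n_conv))) {
    cl <- cache$layers[[l]]
    C_out <- dim(dA)[1]; L_half <- dim(dA)[2]; Bt <- dim(dA)[3]
    # un-pool: route to the argmax slot
    dYr <- array(0, c(C_out, 2, L_half, Bt))
    dYr[, 1, , ] <- dA * cl$arg1
    dYr[, 2, , ] <- dA * !cl$arg1
    dY <- matrix(dYr, nrow = C_out)          # C_out x (L_in * B)
    dY[!cl$relu_mask] <- 0
    grads[[paste0("Wc", l)]] <- dY %*% t(cl$Xcol)
    grads[[paste0("bc", l)]] <- rowSums(dY)
    if (l > 1) {
      dXcol <- t(params[[paste0("Wc", l)]]) %*% dY
      dA <- col2im3(dXcol, cl$C_in, cl$L_in, Bt)
    }
  }
  grads
}

# -- Adam optimizer -------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

#' Training configuration for the localizer
#'
#' Defaults follow the published hyperparameter table: batch size 64,
#' up to 1000 epochs, early-stop patience 30, smooth-L1 loss, learning
#' rate 1e-4 (the companion text states 1e-3; both are accepted values —
#' pass `lr = 1e-3` to use it). Labels are optimized in units of
#' `samples / label_scale` so that typical residuals straddle the
#' smooth-L1 knee at 1; predictions are always converted back to samples.
#'
#' @param lr Learning rate.
#' @param batch_size Mini-batch size (>= 1).
#' @param max_epochs Maximum epochs.
#' @param patience Early-stop patience in epochs (< max_epochs).
#' @param label_scale Label scaling constant in samples (default 100).
#' @param seed Integer seed controlling init and batch shuffling.
#' @return List of class `"train_config"`.
#' @export
train_config <- function(lr = 1e-4, batch_size = 64L, max_epochs = 1000L,
                         patience = 30L, label_scale = 100,
                         seed = 0L) {
  if (batch_size < 1) stop("batch_size must be >= 1")
  if (patience >= max_epochs) stop("patience must be < max_epochs")
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 label_scale = label_scale, seed = as.integer(seed)),
            class = "train_config")
}

#' Build an untrained localizer
#'
#' @param structure A [structure_spec()].
#' @param input_length Segment length; must be divisible by
#'   `2^n_conv` (2048 covers depths up to 11).
#' @param seed Optional seed for weight initialization (fan-in uniform).
#' @return Object of class `"cardiovib_localizer"` (untrained).
#' @export
build_localizer <- function(structure, input_length = 2048L, seed = NULL) {
  stopifnot(inherits(structure, "structure_spec"))
  div <- 2^structure$n_conv
  if (input_length %% div != 0)
    stop("input_length ", input_length, " not divisible by 2^",
         structure$n_conv, "; pad to ",
         ceiling(input_length / div) * div)
  if (!is.null(seed)) set.seed(seed)
  params <- init_params(structure, input_length)
  structure(list(structure = structure, input_length = as.integer(input_length),
                 params = params, feature = NA_character_,
                 history = numeric(0), config = NULL,
                 label_scale = 100), class = "cardiovib_localizer")
}

#' @export
print.cardiovib_localizer <- function(x, ...) {
  cat(sprintf("<localizer for %s: depth %d, input %d, %s>\n",
              ifelse(is.na(x$feature), "(unassigned)", x$feature),
              x$structure$n_conv, x$input_length,
              if (length(x$history)) sprintf("trained %d epochs",
                                             length(x$history))
              else "untrained"))
  invisible(x)
}

# extract the (input_length x n) matrix for a feature's band
dataset_matrix <- function(dataset, feature, which_split = NULL) {
  band <- feature_band(feature)
  keep <- if (is.null(which_split)) seq_along(dataset$segments) else
    which(dataset$split == which_split)
  X <- vapply(dataset$segments[keep], function(s) s$traces[[band]],
              numeric(length(dataset$segments[[1]]$traces[[band]])))
  y <- dataset$labels[keep, feature]
  list(X = X, y = as.numeric(y), idx = keep)
}

#' Train a localizer for one fiducial point
#'
#' Mini-batch Adam on smooth-L1 loss over the dataset's training split.
#' Each epoch's mean loss is recorded; training stops at `max_epochs` or
#' once the best epoch loss has not improved for `patience` consecutive
#' epochs, and the best-epoch weights are restored. Fully seeded and
#' deterministic in single-threaded BLAS mode.
#'
#' @param dataset A [attach_labels()] result with splits assigned
#'   (see [assign_split()]); segments feed the SCG band for the eight SCG
#'   targets and the PCG band for S1/S2.
#' @param feature Target feature name.
#' @param structure A [structure_spec()].
#' @param config A [train_config()].
#' @param verbose Print per-epoch loss every 10 epochs.
#' @return A trained `"cardiovib_localizer"` with `history`.
#' @export
train_localizer <- function(dataset, feature, structure,
                            config = train_config(), verbose = FALSE) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  if (!feature %in% dataset$features) stop("dataset lacks labels for ", feature)
  tr <- dataset_matrix(dataset, feature,
                       if (all(is.na(dataset$split))) NULL else "train")
  if (length(tr$y) == 0) stop("empty training split")
  L <- nrow(tr$X)
  set.seed(config$seed)
  params <- init_params(structure, L)
  state <- adam_init(params)
  y_s <- tr$y / config$label_scale
  n <- length(y_s)
  bs <- min(config$batch_size, n)
  best_loss <- Inf; best_params <- params; since_best <- 0L
  history <- numeric(0)
  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (start in seq(1, n, by = bs)) {
      ib <- ord[start:min(start + bs - 1, n)]
      fw <- nn_forward(params, structure, tr$X[, ib, drop = FALSE],
                       keep_cache = TRUE)
      res <- fw$yhat - y_s[ib]
      loss <- smooth_l1(res)
      dy <- smooth_l1_grad(res) / length(ib)
      grads <- nn_backward(params, structure, fw$cache, dy)
      up <- adam_step(params, grads, state, config$lr)
      params <- up$params; state <- up$state
      ep_loss <- ep_loss + loss * length(ib)
    }
    ep_loss <- ep_loss / n
    history <- c(history, ep_loss)
    if (ep_loss < best_loss) {
      best_loss <- ep_loss; best_params <- params; since_best <- 0L
    } else {
      since_best <- since_best + 1L
    }
    if (verbose && epoch %% 10 == 0)
      message(sprintf("epoch %d: loss %.5f (best %.5f)", epoch, ep_loss,
                      best_loss))
    if (since_best >= config$patience) break
  }
  structure(list(structure = structure, input_length = L,
                 params = best_params, feature = feature,
                 history = history, config = config,
                 label_scale = config$label_scale),
            class = "cardiovib_localizer")
}

#' Predict fiducial coordinates
#'
#' @param object A trained `"cardiovib_localizer"`.
#' @param newdata An `input_length x n` matrix of segments, a single
#'   trace, or a `"labeled_dataset"` (its matching band is extracted;
#'   use `which_split` to restrict).
#' @param which_split Optional split restriction for dataset input.
#' @param ... Unused.
#' @return data.frame with continuous `coord` (samples), rounded `index`
#'   clipped to `[0, L-1]`, and `out_of_range` flag.
#' @export
predict.cardiovib_localizer <- function(object, newdata,
                                        which_split = NULL, ...) {
  if (inherits(newdata, "labeled_dataset")) {
    newdata <- dataset_matrix(newdata, object$feature, which_split)$X
  }
  if (is.null(dim(newdata))) newdata <- matrix(newdata, ncol = 1)
  if (nrow(newdata) != object$input_length)
    stop("segment length ", nrow(newdata), " does not match model input ",
         object$input_length)
  # predict in batches to bound memory
  n <- ncol(newdata)
  coord <- numeric(n)
  bs <- 256L
  for (start in seq(1, n, by = bs)) {
    ib <- start:min(start + bs - 1, n)
    coord[ib] <- nn_forward(object$params, object$structure,
                            newdata[, ib, drop = FALSE])$yhat
  }
  coord <- coord * object$label_scale
  idx <- round(coord)
  oor <- idx < 0 | idx > object$input_length - 1
  idx <- pmin(pmax(idx, 0), object$input_length - 1)
  data.frame(coord = coord, index = as.integer(idx), out_of_range = oor)
}

#' Depth sweep over the number of conv layers
#'
#' Trains one model per depth (flatten size recomputed per depth; input
#' length 2048 divides 2^d for d up to 11) and reports test-split R².
#' Failures at a given depth are recorded, not fatal. The default
#' selection rule picks depth 6.
#'
#' @param dataset Labeled dataset with splits assigned.
#' @param feature Target feature.
#' @param depths Integer depths (default 3:10).
#' @param base_structure_id Structure whose channel chain seeds each
#'   depth variant (default 7, the lightest).
#' @param config A [train_config()].
#' @return data.frame: `depth`, `flatten`, `r2`, `error` (NA if ok),
#'   `selected` (TRUE for depth 6 if present).
#' @export
depth_sweep <- function(dataset, feature, depths = 3:10,
                        base_structure_id = 7L, config = train_config()) {
  res <- data.frame(depth = depths, flatten = NA_integer_, r2 = NA_real_,
                    error = NA_character_, selected = depths == 6L)
  L <- length(dataset$segments[[1]]$traces[[1]])
  for (i in seq_along(depths)) {
    d <- depths[i]
    out <- tryCatch({
      spec <- structure_spec(base_structure_id, n_conv = d)
      res$flatten[i] <- flatten_dim(spec, L)
      model <- train_localizer(dataset, feature, spec, config)
      te <- dataset_matrix(dataset, feature, "test")
      pred <- predict(model, te$X)
      r2(te$y, pred$coord)
    }, error = function(e) e)
    if (inherits(out, "error")) res$error[i] <- conditionMessage(out)
    else res$r2[i] <- out
  }
  res
}
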