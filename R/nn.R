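# Internal minimal CNN engine: sequential layer graphs with valid (unpadded)
# 2-D convolutions, max pooling, dropout and a softmax dense head, trained by
# mini-batch Adam on categorical cross-entropy. Convolution and pooling hot
# paths are compiled (see src/conv.cpp); everything else is plain R.
#
# Batches are stored column-major as (h, w, c, n) arrays; dense activations
# as features x n matrices.

relu <- function(z) {
  z[z < 0] <- 0
  z
}

softmax_cols <- function(z) {
  z <- z - rep(apply(z, 2, max), each = nrow(z))
  e <- exp(z)
  e / rep(colSums(e), each = nrow(e))
}

# ---- initialization ---------------------------------------------------------

nn_init <- function(spec, seed = 1L) {
  shapes <- propagate_shapes(spec)
  set.seed(seed)
  params <- vector("list", length(spec$layers))
  in_shape <- spec$input_shape
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    if (ly$kind == "conv2d") {
      fan_in <- prod(ly$kernel) * in_shape[3]
      W <- array(stats::rnorm(prod(ly$kernel) * in_shape[3] * ly$filters,
                              sd = sqrt(2 / fan_in)),
                 c(ly$kernel[1], ly$kernel[2], in_shape[3], ly$filters))
      params[[i]] <- list(W = W, b = numeric(ly$filters))
    } else if (ly$kind == "dense") {
      fan_in <- in_shape[1]
      W <- matrix(stats::rnorm(fan_in * ly$units,
                               sd = sqrt(2 / (fan_in + ly$units))),
                  fan_in, ly$units)
      params[[i]] <- list(W = W, b = numeric(ly$units))
    }
    in_shape <- shapes[[i]]
  }
  params
}

# ---- forward / backward -----------------------------------------------------

nn_forward <- function(spec, params, x, training = FALSE) {
  caches <- vector("list", length(spec$layers))
  for (i in seq_along(spec$layers)) {
    ly <- spec$layers[[i]]
    if (ly$kind == "conv2d") {
      p <- params[[i]]
      z <- .conv2d_fw(x, dim(x), p$W, dim(p$W), p$b, ly$stride[1], ly$stride[2])
      mask <- NULL
      if (identical(ly$activation, "relu")) {
        mask <- z > 0
        z <- z * mask
      }
      caches[[i]] <- list(x = x, mask = mask)
      x <- z
    } else if (ly$kind == "maxpool2d") {
      r <- .maxpool_fw(x, dim(x), ly$pool[1], ly$pool[2])
      caches[[i]] <- list(idx = r$idx, xlen = length(x), xdim = dim(x))
      x <- r$out
    } else if (ly$kind == "flatten") {
      d <- dim(x)
      caches[[i]] <- list(xdim = d)
      dim(x) <- c(prod(d[1:3]), d[4])
    } else if (ly$kind == "dropout") {
      if (training && ly$rate > 0) {
        mask <- (stats::runif(length(x)) >= ly$rate) / (1 - ly$rate)
        if (is.matrix(x)) mask <- matrix(mask, nrow(x), ncol(x))
        else dim(mask) <- dim(x)
        caches[[i]] <- list(mask = mask)
        x <- x * mask
      } else {
        caches[[i]] <- list(mask = NULL)
      }
    } else if (ly$kind == "dense") {
      p <- params[[i]]
      z <- crossprod(p$W, x) + p$b
      caches[[i]] <- list(x = x)
      x <- switch(ly$activation %||% "linear",
                  softmax = softmax_cols(z),
                  relu = relu(z),
                  z)
    } else stop("unknown layer kind: ", ly$kind)
  }
  list(out = x, caches = caches)
}

# dz: gradient at the output of the final layer. For the softmax +
# cross-entropy head, pass (probs - onehot)/n so the dense backward is exact.
nn_backward <- function(spec, params, caches, dz) {
  grads <- vector("list", length(spec$layers))
  for (i in rev(seq_along(spec$layers))) {
    ly <- spec$layers[[i]]
    cache <- caches[[i]]
    if (ly$kind == "dense") {
      grads[[i]] <- list(W = cache$x %*% t(dz), b = rowSums(dz))
      dz <- params[[i]]$W %*% dz
    } else if (ly$kind == "dropout") {
      if (!is.null(cache$mask)) dz <- dz * cache$mask
    } else if (ly$kind == "flatten") {
      dim(dz) <- cache$xdim
    } else if (ly$kind == "maxpool2d") {
      dz <- .maxpool_bw(cache$idx, dz, cache$xlen)
      dim(dz) <- cache$xdim
    } else if (ly$kind == "conv2d") {
      if (!is.null(cache$mask)) dz <- dz * cache$mask
      p <- params[[i]]
      # the input gradient of the first layer is never consumed
      g <- .conv2d_bw(cache$x, dim(cache$x), p$W, dim(p$W), dz,
                      ly$stride[1], ly$stride[2], need_dx = i > 1L)
      grads[[i]] <- list(W = g$dw, b = g$db)
      if (i > 1L) {
        dz <- g$dx
        dim(dz) <- dim(cache$x)
      }
    }
  }
  grads
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  list(t = 0L,
       m = rapply(params, function(p) p * 0, how = "replace"),
       v = rapply(params, function(p) p * 0, how = "replace"))
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    if (is.null(params[[i]])) next
    for (nm in names(params[[i]])) {
      g <- grads[[i]][[nm]]
      state$m[[i]][[nm]] <- beta1 * state$m[[i]][[nm]] + (1 - beta1) * g
      state$v[[i]][[nm]] <- beta2 * state$v[[i]][[nm]] + (1 - beta2) * g^2
      params[[i]][[nm]] <- params[[i]][[nm]] -
        lr * (state$m[[i]][[nm]] / c1) / (sqrt(state$v[[i]][[nm]] / c2) + eps)
    }
  }
  list(params = params, state = state)
}

# ---- training loop ----------------------------------------------------------

xent_loss <- function(probs, y_int) {
  -mean(log(pmax(probs[cbind(y_int, seq_along(y_int))], 1e-12)))
}

# x: (h, w, c, n) array; y_int: integer class 1..K
nn_train <- function(spec, x, y_int, config) {
  K <- spec$class_count
  n <- dim(x)[4]
  set.seed(config$seed)
  params <- nn_init(spec, seed = config$seed)
  state <- adam_init(params)

  val_idx <- integer(0)
  if (!is.null(config$patience)) {
    # stratified validation split carved from the training data
    val_idx <- unlist(lapply(split(seq_len(n), y_int), function(ix) {
      nv <- max(1L, round(config$val_fraction * length(ix)))
      sample(ix, nv)
    }), use.names = FALSE)
  }
  tr_idx <- setdiff(seq_len(n), val_idx)

  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best <- list(loss = Inf, params = params, since = 0L)

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample(tr_idx)
    total <- 0
    for (start in seq(1, length(ord), by = config$batch_size)) {
      bi <- ord[start:min(start + config$batch_size - 1L, length(ord))]
      xb <- x[, , , bi, drop = FALSE]
      yb <- y_int[bi]
      fwd <- nn_forward(spec, params, xb, training = TRUE)
      total <- total + xent_loss(fwd$out, yb) * length(bi)
      dz <- fwd$out
      dz[cbind(yb, seq_along(yb))] <- dz[cbind(yb, seq_along(yb))] - 1
      dz <- dz / length(bi)
      grads <- nn_backward(spec, params, fwd$caches, dz)
      upd <- adam_step(params, grads, state, lr = config$learning_rate)
      params <- upd$params
      state <- upd$state
    }
    train_loss <- total / length(ord)
    val_loss <- NA_real_
    if (length(val_idx)) {
      vp <- nn_predict_probs(spec, params, x[, , , val_idx, drop = FALSE])
      val_loss <- xent_loss(t(vp), y_int[val_idx])
      if (val_loss < best$loss - 1e-6) {
        best <- list(loss = val_loss, params = params, since = 0L)
      } else {
        best$since <- best$since + 1L
        if (best$since >= config$patience) {
          history <- rbind(history, data.frame(epoch = epoch,
                                               train_loss = train_loss,
                                               val_loss = val_loss))
          params <- best$params
          break
        }
      }
    }
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = train_loss,
                                         val_loss = val_loss))
    if (isTRUE(config$verbose))
      message(sprintf("epoch %d  train loss %.4f%s", epoch, train_loss,
                      if (is.na(val_loss)) "" else sprintf("  val loss %.4f", val_loss)))
  }
  if (length(val_idx) && best$loss < Inf && is.finite(best$loss))
    params <- best$params
  list(params = params, history = history)
}

# predictions in chunks; returns n x K probability matrix
nn_predict_probs <- function(spec, params, x, chunk = 256L) {
  n <- dim(x)[4]
  K <- spec$class_count
  out <- matrix(NA_real_, n, K)
  for (start in seq(1, n, by = chunk)) {
    ix <- start:min(start + chunk - 1L, n)
    fwd <- nn_forward(spec, params, x[, , , ix, drop = FALSE], training = FALSE)
    out[ix, ] <- t(fwd$out)
  }
  out
}
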