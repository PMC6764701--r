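# Minimal convolutional-network engine on base R arrays.
#
# Feature maps are numeric arrays dim = c(H, W, C); vectors after flatten.
# Layers are environments holding parameters, so optimiser steps and
# running-statistic updates mutate in place. Forward passes return the output
# plus a cache consumed by the matching backward pass. Convolution uses
# im2col gathers with BLAS matmuls; gather index matrices are memoised per
# geometry.

.px_geom_cache <- new.env(parent = emptyenv())

conv_out_dim <- function(n, k, stride, pad) (n + 2L * pad - k) %/% stride + 1L

# Linear gather indices into the zero-padded array: rows index patch offsets
# (dh fastest, then dw, then channel), columns index output positions
# (output row fastest).
im2col_idx <- function(H, W, C, kh, kw, stride, pad) {
  key <- paste(H, W, C, kh, kw, stride, pad, sep = "_")
  hit <- .px_geom_cache[[key]]
  if (!is.null(hit)) return(hit)
  Hp <- H + 2L * pad
  Wp <- W + 2L * pad
  Ho <- conv_out_dim(H, kh, stride, pad)
  Wo <- conv_out_dim(W, kw, stride, pad)
  stopifnot(Ho >= 1L, Wo >= 1L)
  off <- as.vector(outer(0:(kh - 1L), (0:(kw - 1L)) * Hp, `+`))
  off <- as.vector(outer(off, (0:(C - 1L)) * (Hp * Wp), `+`))
  base_h <- (seq_len(Ho) - 1L) * stride + 1L
  base_w <- (seq_len(Wo) - 1L) * stride + 1L
  pos <- as.vector(outer(base_h, (base_w - 1L) * Hp, `+`))
  idx <- outer(as.integer(off), as.integer(pos), `+`)
  out <- list(idx = idx, Ho = Ho, Wo = Wo, Hp = Hp, Wp = Wp)
  assign(key, out, envir = .px_geom_cache)
  out
}

pad_array <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  xp <- array(0, c(d[1] + 2L * pad, d[2] + 2L * pad, d[3]))
  xp[pad + seq_len(d[1]), pad + seq_len(d[2]), ] <- x
  xp
}

unpad_array <- function(xp, pad, H, W) {
  if (pad == 0L) return(xp)
  xp[pad + seq_len(H), pad + seq_len(W), , drop = FALSE]
}

new_layer <- function(type, ...) {
  ly <- new.env(parent = emptyenv())
  ly$type <- type
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = ly)
  class(ly) <- c(paste0("px_", type), "px_layer")
  ly
}

ly_conv <- function(kh, kw, c_in, c_out, stride = 1L, pad = NULL,
                    trainable = TRUE) {
  if (is.null(pad)) pad <- kh %/% 2L
  k <- kh * kw * c_in
  new_layer("conv",
    kh = as.integer(kh), kw = as.integer(kw),
    c_in = as.integer(c_in), c_out = as.integer(c_out),
    stride = as.integer(stride), pad = as.integer(pad),
    W = matrix(stats::rnorm(k * c_out, sd = sqrt(2 / k)), k, c_out),
    b = numeric(c_out), trainable = trainable)
}

ly_bn <- function(channels, eps = 1e-5, momentum = 0.1) {
  new_layer("bn",
    channels = as.integer(channels), eps = eps, momentum = momentum,
    gamma = rep(1, channels), beta = numeric(channels),
    run_mean = numeric(channels), run_var = rep(1, channels),
    trainable = TRUE)
}

ly_relu <- function() new_layer("relu")
ly_tanh <- function() new_layer("tanh")
ly_sigmoid <- function() new_layer("sigmoid")
ly_flatten <- function() new_layer("flatten")
ly_gap <- function() new_layer("gap")
ly_maxpool <- function(k, stride = k, pad = 0L)
  new_layer("maxpool", k = as.integer(k), stride = as.integer(stride),
            pad = as.integer(pad))
ly_avgpool <- function(k, stride = k)
  new_layer("avgpool", k = as.integer(k), stride = as.integer(stride))
# Stack the top and bottom halves of the map channel-wise, plus their
# elementwise product, so later 1x1 convolutions see the TF-half and
# target-half features at aligned positions together with an explicit
# co-activation (bilinear) term.
ly_fold <- function() new_layer("fold")
ly_dropout <- function(p) new_layer("dropout", p = p)

ly_fc <- function(d_in, d_out, init = c("he", "xavier")) {
  init <- match.arg(init)
  sd <- if (init == "he") sqrt(2 / d_in) else sqrt(1 / d_in)
  new_layer("fc",
    d_in = as.integer(d_in), d_out = as.integer(d_out),
    W = matrix(stats::rnorm(d_in * d_out, sd = sd), d_in, d_out),
    b = numeric(d_out), trainable = TRUE)
}

ly_residual <- function(branch, shortcut = NULL)
  new_layer("residual", branch = branch, shortcut = shortcut)

# ---- forward -----------------------------------------------------------

layer_forward <- function(ly, x, training = FALSE) {
  switch(ly$type,
    conv = {
      d <- dim(x)
      g <- im2col_idx(d[1], d[2], d[3], ly$kh, ly$kw, ly$stride, ly$pad)
      xp <- pad_array(x, ly$pad)
      cols <- xp[g$idx]
      dim(cols) <- dim(g$idx)
      out <- crossprod(ly$W, cols) + ly$b
      list(out = array(t(out), c(g$Ho, g$Wo, ly$c_out)),
           cache = list(cols = cols, g = g, in_dim = d))
    },
    bn = {
      d <- dim(x)
      n_sp <- if (is.null(d)) 1L else d[1] * d[2]
      # Per-feature statistics need a spatial extent; vector inputs (the FC
      # head) keep the initial running stats, so bn there is the learnable
      # affine transform.
      if (training && n_sp > 1L) {
        xm <- matrix(x, n_sp, ly$channels)
        m_now <- colMeans(xm)
        v_now <- colMeans(xm^2) - m_now^2
        ly$run_mean <- (1 - ly$momentum) * ly$run_mean + ly$momentum * m_now
        ly$run_var <- (1 - ly$momentum) * ly$run_var + ly$momentum * v_now
      }
      inv <- 1 / sqrt(ly$run_var + ly$eps)
      xhat <- (x - rep(ly$run_mean, each = n_sp)) * rep(inv, each = n_sp)
      out <- xhat * rep(ly$gamma, each = n_sp) + rep(ly$beta, each = n_sp)
      list(out = out, cache = list(xhat = xhat, inv = inv, n_sp = n_sp))
    },
    relu = list(out = pmax(x, 0), cache = list(mask = x > 0)),
    tanh = {
      out <- tanh(x)
      list(out = out, cache = list(out = out))
    },
    sigmoid = {
      out <- 1 / (1 + exp(-x))
      list(out = out, cache = list(out = out))
    },
    flatten = list(out = as.vector(x), cache = list(d = dim(x))),
    gap = {
      d <- dim(x)
      list(out = colMeans(matrix(x, d[1] * d[2], d[3])),
           cache = list(d = d))
    },
    maxpool = {
      d <- dim(x)
      g <- im2col_idx(d[1], d[2], 1L, ly$k, ly$k, ly$stride, ly$pad)
      out <- array(0, c(g$Ho, g$Wo, d[3]))
      amax <- matrix(0L, g$Ho * g$Wo, d[3])
      for (c in seq_len(d[3])) {
        xp <- pad_array(x[, , c, drop = FALSE], ly$pad)
        # padding with -Inf so border maxima are genuine
        if (ly$pad > 0L) {
          mask <- array(-Inf, dim(xp))
          mask[ly$pad + seq_len(d[1]), ly$pad + seq_len(d[2]), ] <- 0
          xp <- xp + mask
        }
        cols <- xp[g$idx]
        dim(cols) <- dim(g$idx)
        w <- max.col(t(cols), ties.method = "first")
        out[, , c] <- cols[cbind(w, seq_along(w))]
        amax[, c] <- g$idx[cbind(w, seq_along(w))]
      }
      list(out = out, cache = list(g = g, amax = amax, in_dim = d))
    },
    avgpool = {
      d <- dim(x)
      g <- im2col_idx(d[1], d[2], 1L, ly$k, ly$k, ly$stride, 0L)
      out <- array(0, c(g$Ho, g$Wo, d[3]))
      for (c in seq_len(d[3])) {
        cols <- x[, , c][g$idx]
        dim(cols) <- dim(g$idx)
        out[, , c] <- colMeans(cols)
      }
      list(out = out, cache = list(g = g, in_dim = d))
    },
    fold = {
      d <- dim(x)
      h <- d[1] %/% 2L
      top <- x[seq_len(h), , , drop = FALSE]
      bottom <- x[h + seq_len(h), , , drop = FALSE]
      out <- array(0, c(h, d[2], 3L * d[3]))
      out[, , seq_len(d[3])] <- top
      out[, , d[3] + seq_len(d[3])] <- bottom
      out[, , 2L * d[3] + seq_len(d[3])] <- top * bottom
      list(out = out, cache = list(d = d, top = top, bottom = bottom))
    },
    dropout = {
      if (!training || ly$p <= 0) return(list(out = x, cache = NULL))
      mask <- (stats::runif(length(x)) >= ly$p) / (1 - ly$p)
      list(out = x * mask, cache = list(mask = mask))
    },
    fc = list(out = drop(crossprod(ly$W, x)) + ly$b, cache = list(x = x)),
    residual = {
      br <- nn_forward(ly$branch, x, training = training)
      if (is.null(ly$shortcut)) {
        sc <- list(out = x, caches = NULL)
      } else {
        sc <- nn_forward(ly$shortcut, x, training = training)
      }
      pre <- br$out + sc$out
      list(out = pmax(pre, 0),
           cache = list(br = br$caches, sc = sc$caches, mask = pre > 0))
    },
    stop("unknown layer type: ", ly$type)
  )
}

nn_forward <- function(layers, x, training = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    step <- layer_forward(layers[[i]], x, training = training)
    x <- step$out
    caches[[i]] <- step$cache
  }
  list(out = x, caches = caches)
}

# ---- backward ----------------------------------------------------------

scatter_add <- function(values, idx, n) {
  acc <- rowsum(values, group = idx)
  out <- numeric(n)
  out[as.integer(rownames(acc))] <- acc
  out
}

layer_backward <- function(ly, cache, dout) {
  switch(ly$type,
    conv = {
      g <- cache$g
      dmat <- t(matrix(dout, g$Ho * g$Wo, ly$c_out))
      grads <- if (isTRUE(ly$trainable)) {
        list(W = cache$cols %*% t(dmat), b = rowSums(dmat))
      } else NULL
      dcols <- ly$W %*% dmat
      d <- cache$in_dim
      dxp <- scatter_add(as.vector(dcols), as.vector(g$idx),
                         g$Hp * g$Wp * d[3])
      dim(dxp) <- c(g$Hp, g$Wp, d[3])
      list(dx = unpad_array(dxp, ly$pad, d[1], d[2]), grads = grads)
    },
    bn = {
      n_sp <- cache$n_sp
      dm <- matrix(dout, n_sp, ly$channels)
      xh <- matrix(cache$xhat, n_sp, ly$channels)
      grads <- list(gamma = colSums(dm * xh), beta = colSums(dm))
      dx <- dout * rep(ly$gamma * cache$inv, each = n_sp)
      list(dx = dx, grads = grads)
    },
    relu = list(dx = dout * cache$mask, grads = NULL),
    tanh = list(dx = dout * (1 - cache$out^2), grads = NULL),
    sigmoid = list(dx = dout * cache$out * (1 - cache$out), grads = NULL),
    flatten = {
      dim(dout) <- cache$d
      list(dx = dout, grads = NULL)
    },
    gap = {
      d <- cache$d
      list(dx = array(rep(dout / (d[1] * d[2]), each = d[1] * d[2]), d),
           grads = NULL)
    },
    maxpool = {
      d <- cache$in_dim
      g <- cache$g
      dxp <- array(0, c(g$Hp, g$Wp, d[3]))
      np <- g$Hp * g$Wp
      for (c in seq_len(d[3])) {
        dxp[(c - 1L) * np + cache$amax[, c]] <-
          dxp[(c - 1L) * np + cache$amax[, c]] + as.vector(dout[, , c])
      }
      list(dx = unpad_array(dxp, ly$pad, d[1], d[2]), grads = NULL)
    },
    avgpool = {
      d <- cache$in_dim
      g <- cache$g
      k2 <- ly$k^2
      dx <- array(0, d)
      for (c in seq_len(d[3])) {
        dx[, , c] <- scatter_add(
          rep(as.vector(dout[, , c]) / k2, each = k2),
          as.vector(g$idx), d[1] * d[2])
      }
      list(dx = dx, grads = NULL)
    },
    fold = {
      d <- cache$d
      h <- d[1] %/% 2L
      c_in <- d[3]
      dprod <- dout[, , 2L * c_in + seq_len(c_in), drop = FALSE]
      dx <- array(0, d)
      dx[seq_len(h), , ] <- dout[, , seq_len(c_in), drop = FALSE] +
        dprod * cache$bottom
      dx[h + seq_len(h), , ] <- dout[, , c_in + seq_len(c_in), drop = FALSE] +
        dprod * cache$top
      list(dx = dx, grads = NULL)
    },
    dropout = {
      if (is.null(cache)) return(list(dx = dout, grads = NULL))
      list(dx = dout * cache$mask, grads = NULL)
    },
    fc = list(dx = drop(ly$W %*% dout),
              grads = list(W = outer(cache$x, dout), b = dout)),
    residual = {
      dpre <- dout * cache$mask
      br <- nn_backward(ly$branch, cache$br, dpre)
      if (is.null(ly$shortcut)) {
        dx_sc <- dpre
      } else {
        sc <- nn_backward(ly$shortcut, cache$sc, dpre)
        dx_sc <- sc$dx
      }
      list(dx = br$dx + dx_sc, grads = NULL)
    },
    stop("unknown layer type: ", ly$type)
  )
}

nn_backward <- function(layers, caches, dout) {
  for (i in rev(seq_along(layers))) {
    step <- layer_backward(layers[[i]], caches[[i]], dout)
    dout <- step$dx
    if (!is.null(step$grads)) {
      stash_grads(layers[[i]], step$grads)
    }
  }
  list(dx = dout)
}

# Gradients accumulate on the layer (field .grad_<name>) until sgd_step
# applies and clears them; residual sublayers accumulate through recursion.
stash_grads <- function(ly, grads) {
  for (nm in names(grads)) {
    slot <- paste0(".grad_", nm)
    prev <- if (!is.null(ly[[slot]])) ly[[slot]] else 0
    assign(slot, prev + grads[[nm]], envir = ly)
  }
  invisible(NULL)
}

walk_layers <- function(layers, fn) {
  for (ly in layers) {
    fn(ly)
    if (ly$type == "residual") {
      walk_layers(ly$branch, fn)
      if (!is.null(ly$shortcut)) walk_layers(ly$shortcut, fn)
    }
  }
  invisible(NULL)
}

sgd_step <- function(layers, lr, scale = 1) {
  walk_layers(layers, function(ly) {
    for (nm in c("W", "b", "gamma", "beta")) {
      slot <- paste0(".grad_", nm)
      if (!is.null(ly[[slot]])) {
        assign(nm, ly[[nm]] - lr * scale * ly[[slot]], envir = ly)
        rm(list = slot, envir = ly)
      }
    }
  })
}

clear_grads <- function(layers) {
  walk_layers(layers, function(ly) {
    slots <- grep("^\\.grad_", ls(ly, all.names = TRUE), value = TRUE)
    if (length(slots)) rm(list = slots, envir = ly)
  })
}

# Snapshot / restore trainable parameters (used for checkpointing).
collect_params <- function(layers) {
  out <- list()
  i <- 0L
  walk_layers(layers, function(ly) {
    i <<- i + 1L
    out[[i]] <<- mget(intersect(c("W", "b", "gamma", "beta", "run_mean",
                                  "run_var"), ls(ly)), envir = ly)
  })
  out
}

restore_params <- function(layers, snapshot) {
  i <- 0L
  walk_layers(layers, function(ly) {
    i <<- i + 1L
    for (nm in names(snapshot[[i]])) assign(nm, snapshot[[i]][[nm]], envir = ly)
  })
  invisible(NULL)
}

# ---- shape inference ---------------------------------------------------

layer_out_shape <- function(ly, shape) {
  if (ly$type %in% c("relu", "tanh", "sigmoid", "dropout", "bn")) return(shape)
  switch(ly$type,
    conv = c(conv_out_dim(shape[1], ly$kh, ly$stride, ly$pad),
             conv_out_dim(shape[2], ly$kw, ly$stride, ly$pad), ly$c_out),
    maxpool = c(conv_out_dim(shape[1], ly$k, ly$stride, ly$pad),
                conv_out_dim(shape[2], ly$k, ly$stride, ly$pad), shape[3]),
    avgpool = c(conv_out_dim(shape[1], ly$k, ly$stride, 0L),
                conv_out_dim(shape[2], ly$k, ly$stride, 0L), shape[3]),
    fold = c(shape[1] %/% 2L, shape[2], 3L * shape[3]),
    gap = shape[3],
    flatten = prod(shape),
    fc = ly$d_out,
    residual = nn_out_shape(ly$branch, shape),
    stop("unknown layer type: ", ly$type)
  )
}

nn_out_shape <- function(layers, shape) {
  for (ly in layers) shape <- layer_out_shape(ly, shape)
  shape
}
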