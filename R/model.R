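# Instantiation of architecture plans as trainable models. The model handle
# is an environment holding the parameter arrays, batch-norm running stats and
# optimizer state; it supports single-step fitting, prediction and trainable
# parameter counting.

#' Instantiate an architecture plan as a trainable model
#'
#' Builds the parameter arrays described by the plan (Glorot-uniform weight
#' initialization; LSTM forget-gate biases start at 1) and returns an opaque
#' handle supporting [fit_one_step()], [predict.genarch_model()] and
#' [trainable_count()]. The handle is faithful to the plan: layer order,
#' leaky-ReLU activations on convolution outputs, batch-norm momentum, dropout
#' rates, residual shortcuts, and reverse-complement fusion through shared
#' trunk weights with embedding concatenation.
#'
#' @param plan A `genarch_plan` from [build_plan()].
#' @param seed Optional integer seed for weight initialization.
#' @param optimizer Gradient-descent algorithm; defaults to the plan's.
#' @param learning_rate Initial learning rate; defaults to the plan's.
#' @return An environment of class `genarch_model`.
#' @export
instantiate <- function(plan, seed = NULL,
                        optimizer = plan$optimizer %||% "adam",
                        learning_rate = plan$learning_rate %||% 1e-3) {
  stopifnot(inherits(plan, "genarch_plan"))
  optimizer <- match.arg(optimizer, c("adam", "adagrad", "rmsprop", "sgd"))
  check_plan(plan)
  build <- function() {
    params <- list()
    bn <- list()
    in_ch <- plan$alphabet_size
    li <- 0L
    for (b in seq_along(plan$conv_blocks)) {
      block_in <- in_ch
      for (ly in plan$conv_blocks[[b]]$layers) {
        li <- li + 1L
        id <- paste0("c", li)
        params[[paste0(id, ".W")]] <- glorot(ly$kernel * in_ch, ly$filters,
                                             fan_in = ly$kernel * in_ch,
                                             fan_out = ly$kernel * ly$filters)
        params[[paste0(id, ".b")]] <- numeric(ly$filters)
        params[[paste0(id, ".gamma")]] <- rep(1, ly$filters)
        params[[paste0(id, ".beta")]] <- numeric(ly$filters)
        bn[[id]] <- new.env(parent = emptyenv())
        bn[[id]]$r_mu <- numeric(ly$filters)
        bn[[id]]$r_var <- numeric(ly$filters)
        bn[[id]]$t <- 0L
        in_ch <- ly$filters
      }
      if (plan$residual && block_in != in_ch) {
        id <- paste0("proj", b)
        params[[paste0(id, ".W")]] <- glorot(block_in, in_ch)
        params[[paste0(id, ".b")]] <- numeric(in_ch)
      }
    }
    if (plan$head$kind == "rnn") {
      r <- plan$head$rnn_stack
      g <- if (r$type == "lstm") 4L else 3L
      dirs <- if (r$bidirectional) c("f", "r") else "f"
      inp <- in_ch
      for (l in seq_len(r$n_layers)) {
        for (dd in dirs) {
          id <- paste0("rnn", l, dd)
          params[[paste0(id, ".Wx")]] <- glorot(inp, g * r$units)
          params[[paste0(id, ".Wh")]] <- glorot(r$units, g * r$units)
          bias <- numeric(g * r$units)
          if (r$type == "lstm") bias[(r$units + 1):(2 * r$units)] <- 1
          params[[paste0(id, ".b")]] <- bias
        }
        inp <- r$units * length(dirs)
      }
    }
    width <- embedding_width(plan) * (if (plan$use_reverse_complement) 2L else 1L)
    for (i in seq_along(plan$dense_stack)) {
      d <- plan$dense_stack[[i]]
      id <- paste0("d", i)
      params[[paste0(id, ".W")]] <- glorot(width, d$units)
      params[[paste0(id, ".b")]] <- numeric(d$units)
      width <- d$units
    }
    params[["out.W"]] <- glorot(width, plan$n_classes)
    params[["out.b"]] <- numeric(plan$n_classes)
    list(params = params, bn = bn)
  }
  built <- if (!is.null(seed)) withr::with_seed(seed, build()) else build()
  m <- new.env(parent = emptyenv())
  m$plan <- plan
  m$params <- built$params
  m$bn <- built$bn
  m$optimizer <- optimizer
  m$lr <- learning_rate
  m$opt_state <- list()
  m$step <- 0L
  m$idx_cache <- new.env(parent = emptyenv())
  class(m) <- "genarch_model"
  m
}

check_plan <- function(plan) {
  st <- plan$structure
  if (st$N_c != st$N_cb * st$s_cb) rlang::abort("plan violates N_c = N_cb * s_cb")
  for (b in plan$conv_blocks) {
    fl <- vapply(b$layers, `[[`, integer(1), "filters")
    if (plan$residual && length(unique(fl)) != 1L) {
      rlang::abort("residual blocks require a constant filter count within each block")
    }
    if (any(b$pool_after < 1) || any(bitwAnd(b$pool_after, b$pool_after - 1L) != 0)) {
      rlang::abort("pooling factors must be powers of two")
    }
  }
  if (plan$head$kind == "gap") {
    taps <- plan$head$gap_taps
    if (length(taps) == 0L) rlang::abort("GAP stage must tap at least one block")
    if (!identical(as.integer(taps),
                   seq(length(plan$conv_blocks) - length(taps) + 1L,
                       length(plan$conv_blocks)))) {
      rlang::abort("GAP taps must be a contiguous suffix of blocks")
    }
  }
  invisible(plan)
}

#' Number of trainable parameters of an instantiated model
#'
#' @param model A `genarch_model`.
#' @return Integer scalar; equals `count_parameters(plan)$total`.
#' @export
trainable_count <- function(model) {
  stopifnot(inherits(model, "genarch_model"))
  sum(vapply(model$params, length, integer(1)))
}

#' @export
print.genarch_model <- function(x, ...) {
  cat(sprintf("<genarch_model> %s, lr %.3g, %d trainable parameters\n",
              x$optimizer, x$lr, trainable_count(x)))
  invisible(x)
}

# reverse-complement of a one-hot batch: reverse positions, swap A<->T, C<->G
rc_batch <- function(X) {
  d <- dim(X)
  X[, d[2]:1, 4:1, drop = FALSE]
}

# --- trunk (conv blocks + embedding stage) ----------------------------------

trunk_forward <- function(m, X, training) {
  plan <- m$plan
  caches <- list()
  A <- X
  li <- 0L
  block_out <- list()
  for (b in seq_along(plan$conv_blocks)) {
    bl <- plan$conv_blocks[[b]]
    A_in <- A
    for (l in seq_along(bl$layers)) {
      li <- li + 1L
      ly <- bl$layers[[l]]
      id <- paste0("c", li)
      cv <- conv1d_forward(A, m$params[[paste0(id, ".W")]],
                           m$params[[paste0(id, ".b")]], ly$kernel, ly$dilation,
                           idx_env = m$idx_cache,
                           key = paste0(id, "_", dim(A)[1], "_", dim(A)[2]))
      bnr <- bn_forward(cv$Y, m$params[[paste0(id, ".gamma")]],
                        m$params[[paste0(id, ".beta")]], m$bn[[id]],
                        ly$batchnorm_momentum, training)
      ac <- leaky_relu_forward(bnr$Y, ly$leaky_alpha)
      pl <- maxpool_forward(ac$Y, bl$pool_after[l])
      caches[[id]] <- list(conv = cv$cache, bn = bnr$cache, act = ac$cache,
                           pool = pl$cache, alpha = ly$leaky_alpha)
      A <- pl$Y
    }
    if (plan$residual) {
      prod_pool <- prod(bl$pool_after)
      skip <- if (prod_pool > 1L) maxpool_forward(A_in, as.integer(prod_pool)) else
        list(Y = A_in, cache = NULL)
      pid <- paste0("proj", b)
      if (!is.null(m$params[[paste0(pid, ".W")]])) {
        pr <- conv1d_forward(skip$Y, m$params[[paste0(pid, ".W")]],
                             m$params[[paste0(pid, ".b")]], 1L, 1L)
        caches[[paste0("res", b)]] <- list(pool = skip$cache, proj = pr$cache,
                                           projected = TRUE)
        A <- A + pr$Y
      } else {
        caches[[paste0("res", b)]] <- list(pool = skip$cache, projected = FALSE)
        A <- A + skip$Y
      }
    }
    if (plan$head$kind == "gap" && b %in% plan$head$gap_taps) {
      block_out[[as.character(b)]] <- A
    }
  }
  if (plan$head$kind == "gap") {
    embs <- list()
    for (b in plan$head$gap_taps) {
      g <- gap_forward(block_out[[as.character(b)]])
      caches[[paste0("gap", b)]] <- g$cache
      embs[[as.character(b)]] <- g$Y
    }
    emb <- do.call(cbind, unname(embs))
  } else {
    r <- plan$head$rnn_stack
    fwd <- if (r$type == "lstm") lstm_forward else gru_forward
    H <- A
    for (l in seq_len(r$n_layers)) {
      idf <- paste0("rnn", l, "f")
      of <- fwd(H, m$params[[paste0(idf, ".Wx")]], m$params[[paste0(idf, ".Wh")]],
                m$params[[paste0(idf, ".b")]])
      caches[[idf]] <- of$cache
      if (r$bidirectional) {
        idr <- paste0("rnn", l, "r")
        Hrev <- H[, dim(H)[2]:1, , drop = FALSE]
        orv <- fwd(Hrev, m$params[[paste0(idr, ".Wx")]],
                   m$params[[paste0(idr, ".Wh")]], m$params[[paste0(idr, ".b")]])
        caches[[idr]] <- orv$cache
        Yr <- orv$Y[, dim(orv$Y)[2]:1, , drop = FALSE]
        d1 <- dim(of$Y)
        H <- array(0, c(d1[1], d1[2], 2L * d1[3]))
        H[, , seq_len(d1[3])] <- of$Y
        H[, , d1[3] + seq_len(d1[3])] <- Yr
      } else {
        H <- of$Y
      }
    }
    caches[["flatten_dims"]] <- dim(H)
    emb <- H
    dim(emb) <- c(dim(H)[1], dim(H)[2] * dim(H)[3])
  }
  list(emb = emb, caches = caches)
}

trunk_backward <- function(m, demb, caches) {
  plan <- m$plan
  grads <- list()
  nb_blocks <- length(plan$conv_blocks)
  if (plan$head$kind == "gap") {
    # split demb into per-tap gradients; dA accumulates backwards over blocks
    taps <- plan$head$gap_taps
    widths <- vapply(taps, function(b) {
      ly <- plan$conv_blocks[[b]]$layers
      ly[[length(ly)]]$filters
    }, integer(1))
    offs <- c(0L, cumsum(widths))
    dtap <- list()
    for (i in seq_along(taps)) {
      dY <- demb[, (offs[i] + 1L):offs[i + 1L], drop = FALSE]
      dtap[[as.character(taps[i])]] <- gap_backward(dY, caches[[paste0("gap", taps[i])]])
    }
    dA <- NULL
  } else {
    r <- plan$head$rnn_stack
    bwd <- if (r$type == "lstm") lstm_backward else gru_backward
    dH <- demb
    dim(dH) <- caches[["flatten_dims"]]
    for (l in rev(seq_len(r$n_layers))) {
      idf <- paste0("rnn", l, "f")
      if (r$bidirectional) {
        idr <- paste0("rnn", l, "r")
        U <- caches[[idf]]$U
        dHf <- dH[, , seq_len(U), drop = FALSE]
        dHr <- dH[, , U + seq_len(U), drop = FALSE]
        dHr <- dHr[, dim(dHr)[2]:1, , drop = FALSE]
        gf <- bwd(dHf, m$params[[paste0(idf, ".Wx")]],
                  m$params[[paste0(idf, ".Wh")]], caches[[idf]])
        gr <- bwd(dHr, m$params[[paste0(idr, ".Wx")]],
                  m$params[[paste0(idr, ".Wh")]], caches[[idr]])
        grads[[paste0(idf, ".Wx")]] <- gf$dWx
        grads[[paste0(idf, ".Wh")]] <- gf$dWh
        grads[[paste0(idf, ".b")]] <- gf$db
        grads[[paste0(idr, ".Wx")]] <- gr$dWx
        grads[[paste0(idr, ".Wh")]] <- gr$dWh
        grads[[paste0(idr, ".b")]] <- gr$db
        dH <- gf$dX + gr$dX[, dim(gr$dX)[2]:1, , drop = FALSE]
      } else {
        gf <- bwd(dH, m$params[[paste0(idf, ".Wx")]],
                  m$params[[paste0(idf, ".Wh")]], caches[[idf]])
        grads[[paste0(idf, ".Wx")]] <- gf$dWx
        grads[[paste0(idf, ".Wh")]] <- gf$dWh
        grads[[paste0(idf, ".b")]] <- gf$db
        dH <- gf$dX
      }
    }
    dA <- dH
    dtap <- list()
  }

  li <- sum(vapply(plan$conv_blocks, function(b) length(b$layers), integer(1)))
  for (b in rev(seq_len(nb_blocks))) {
    bl <- plan$conv_blocks[[b]]
    tap_grad <- dtap[[as.character(b)]]
    if (!is.null(tap_grad)) dA <- if (is.null(dA)) tap_grad else dA + tap_grad
    if (is.null(dA)) {
      # block beyond the last tapped one cannot occur (taps are a suffix);
      # defensive zero gradient
      dA <- array(0, dim(tap_grad))
    }
    dskip_in <- NULL
    if (plan$residual) {
      rc <- caches[[paste0("res", b)]]
      dskip <- dA
      if (rc$projected) {
        pid <- paste0("proj", b)
        pb <- conv1d_backward(dskip, m$params[[paste0(pid, ".W")]], rc$proj)
        grads[[paste0(pid, ".W")]] <- pb$dW
        grads[[paste0(pid, ".b")]] <- pb$db
        dskip <- pb$dA
      }
      dskip_in <- maxpool_backward(dskip, rc$pool)
    }
    for (l in rev(seq_along(bl$layers))) {
      id <- paste0("c", li)
      cc <- caches[[id]]
      dA <- maxpool_backward(dA, cc$pool)
      dA <- leaky_relu_backward(dA, cc$alpha, cc$act)
      bb <- bn_backward(dA, m$params[[paste0(id, ".gamma")]], cc$bn)
      grads[[paste0(id, ".gamma")]] <- bb$dgamma
      grads[[paste0(id, ".beta")]] <- bb$dbeta
      cb <- conv1d_backward(bb$dA, m$params[[paste0(id, ".W")]], cc$conv)
      grads[[paste0(id, ".W")]] <- cb$dW
      grads[[paste0(id, ".b")]] <- cb$db
      dA <- cb$dA
      li <- li - 1L
    }
    if (!is.null(dskip_in)) dA <- dA + dskip_in
  }
  list(dX = dA, grads = grads)
}

# --- full forward / backward ------------------------------------------------

model_forward <- function(m, X, labels = NULL, training = FALSE) {
  plan <- m$plan
  t1 <- trunk_forward(m, X, training)
  if (plan$use_reverse_complement) {
    t2 <- trunk_forward(m, rc_batch(X), training)
    emb <- cbind(t1$emb, t2$emb)
  } else {
    t2 <- NULL
    emb <- t1$emb
  }
  dcaches <- list()
  A <- emb
  for (i in seq_along(plan$dense_stack)) {
    d <- plan$dense_stack[[i]]
    id <- paste0("d", i)
    df <- dense_forward(A, m$params[[paste0(id, ".W")]],
                        m$params[[paste0(id, ".b")]], d$activation)
    dr <- dropout_forward(df$Y, d$dropout, training)
    dcaches[[id]] <- list(dense = df$cache, drop = dr$cache)
    A <- dr$Y
  }
  of <- dense_forward(A, m$params[["out.W"]], m$params[["out.b"]], "linear")
  if (is.null(labels)) {
    return(list(probs = softmax_rows(of$Y)))
  }
  sx <- softmax_xent(of$Y, labels)
  list(probs = sx$P, loss = sx$loss, dlogits = sx$dlogits,
       trunk1 = t1, trunk2 = t2, dense_caches = dcaches, out_cache = of$cache,
       emb_width = ncol(t1$emb))
}

model_backward <- function(m, fwd) {
  plan <- m$plan
  grads <- list()
  ob <- dense_backward(fwd$dlogits, m$params[["out.W"]], fwd$out_cache)
  grads[["out.W"]] <- ob$dW
  grads[["out.b"]] <- ob$db
  dA <- ob$dX
  for (i in rev(seq_along(plan$dense_stack))) {
    id <- paste0("d", i)
    dc <- fwd$dense_caches[[id]]
    dA <- dropout_backward(dA, dc$drop)
    db_ <- dense_backward(dA, m$params[[paste0(id, ".W")]], dc$dense)
    grads[[paste0(id, ".W")]] <- db_$dW
    grads[[paste0(id, ".b")]] <- db_$db
    dA <- db_$dX
  }
  if (plan$use_reverse_complement) {
    w <- fwd$emb_width
    g1 <- trunk_backward(m, dA[, seq_len(w), drop = FALSE], fwd$trunk1$caches)
    g2 <- trunk_backward(m, dA[, w + seq_len(w), drop = FALSE], fwd$trunk2$caches)
    for (nm in names(g1$grads)) {
      grads[[nm]] <- g1$grads[[nm]] + g2$grads[[nm]]
    }
  } else {
    g1 <- trunk_backward(m, dA, fwd$trunk1$caches)
    grads <- c(grads, g1$grads)
  }
  grads
}

# --- optimizers -------------------------------------------------------------

apply_gradients <- function(m, grads) {
  m$step <- m$step + 1L
  lr <- m$lr
  eps <- 1e-8
  for (nm in names(m$params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    g <- as.numeric(g)
    p <- m$params[[nm]]
    st <- m$opt_state[[nm]]
    upd <- switch(m$optimizer,
      sgd = lr * g,
      adagrad = {
        if (is.null(st)) st <- list(G = numeric(length(g)))
        st$G <- st$G + g^2
        lr * g / (sqrt(st$G) + eps)
      },
      rmsprop = {
        if (is.null(st)) st <- list(v = numeric(length(g)))
        st$v <- 0.9 * st$v + 0.1 * g^2
        lr * g / (sqrt(st$v) + eps)
      },
      adam = {
        if (is.null(st)) st <- list(mo = numeric(length(g)), v = numeric(length(g)), t = 0L)
        st$t <- st$t + 1L
        st$mo <- 0.9 * st$mo + 0.1 * g
        st$v <- 0.999 * st$v + 0.001 * g^2
        mhat <- st$mo / (1 - 0.9^st$t)
        vhat <- st$v / (1 - 0.999^st$t)
        lr * mhat / (sqrt(vhat) + eps)
      })
    m$opt_state[[nm]] <- st
    dim(upd) <- dim(p)
    m$params[[nm]] <- p - upd
  }
  invisible(m)
}

#' Run one training step
#'
#' Performs a forward pass in training mode, backpropagates the multi-class
#' cross-entropy loss and applies one update of the model's gradient-descent
#' algorithm at the model's current learning rate.
#'
#' @param model A `genarch_model`.
#' @param x One-hot input batch, array of dim `(batch, L, 4)`.
#' @param labels Integer class labels in `1..n_classes`.
#' @return The batch loss (invisibly `NaN`-safe: callers should abort on
#'   non-finite values).
#' @export
fit_one_step <- function(model, x, labels) {
  stopifnot(inherits(model, "genarch_model"))
  fwd <- model_forward(model, x, labels = labels, training = TRUE)
  if (is.finite(fwd$loss)) {
    grads <- model_backward(model, fwd)
    apply_gradients(model, grads)
  }
  fwd$loss
}

#' Predict class probabilities
#'
#' @param object A `genarch_model`.
#' @param x One-hot input batch, array of dim `(batch, L, 4)`, or a
#'   `genarch_batch`.
#' @param ... Unused.
#' @return Matrix of per-class scores, rows summing to 1.
#' @export
predict.genarch_model <- function(object, x, ...) {
  if (inherits(x, "genarch_batch")) x <- x$one_hot
  model_forward(object, x, training = FALSE)$probs
}
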