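# Numerical core: batched valid convolution via im2col, max-pooling,
# dense ReLU head, two sigmoid outputs, backpropagation and Adam.
#
# Batch representation: a "flat" matrix of shape (len * depth) x n, each
# column the column-major flattening of one (len x depth) input. Conv
# weights W are (filter_length * depth) x n_filters with row index
# j = (d - 1) * L + l for filter position l in channel d, so a filter
# response is the standard sliding dot product W' x + b.

# Gather indices mapping a (len x depth) input to its im2col matrix:
# idx[i, (d-1)*L + l] = flat index of position (i + l - 1, d).
im2col_indices <- function(len, depth, L) {
  out_len <- len - L + 1L
  offs <- as.vector(vapply(seq_len(depth), function(d)
    (d - 1L) * len + seq_len(L), integer(L)))     # one offset per (l, d)
  outer(seq_len(out_len) - 1L, offs, `+`)         # out_len x (L * depth)
}

# One conv layer forward. X: (len*depth) x n flat batch.
# Returns pooled flat output plus caches needed for backprop.
conv_forward <- function(X, W, b, len, depth, L, pool, n, keep = FALSE) {
  out_len <- len - L + 1L
  idx <- im2col_indices(len, depth, L)
  LD <- L * depth
  A <- X[as.vector(idx), , drop = FALSE]              # (out_len*LD) x n
  Mcol <- array(A, dim = c(out_len, LD, n))
  Mcol <- aperm(Mcol, c(1L, 3L, 2L))                  # out_len, n, LD
  dim(Mcol) <- c(out_len * n, LD)
  Z <- Mcol %*% W
  Z <- Z + rep(b, each = nrow(Z))
  Amap <- Z
  Amap[Amap < 0] <- 0                                 # ReLU
  p <- max(pool, 1L)
  out_p <- out_len %/% p
  nF <- ncol(W)
  if (p == 1L) {
    pooled <- Amap                                    # (out_len*n) x F
    amax <- NULL
  } else {
    v <- as.vector(array(Amap, dim = c(out_len, n, nF))[seq_len(out_p * p), , ,
                                                        drop = FALSE])
    vm <- matrix(v, nrow = p)                         # cols: (group, n, F)
    best <- vm[1L, ]
    amax <- rep(1L, ncol(vm))
    for (i in seq_len(p)[-1L]) {
      upd <- vm[i, ] > best
      best[upd] <- vm[i, upd]
      amax[upd] <- i
    }
    pooled <- array(best, dim = c(out_p, n, nF))      # group, n, F
    pooled <- matrix(pooled, nrow = out_p * n, ncol = nF)
  }
  # flat output for the next layer / flatten: (out_p * F) x n, channel-major
  Parr <- array(pooled, dim = c(out_p, n, nF))
  Xout <- aperm(Parr, c(1L, 3L, 2L))
  dim(Xout) <- c(out_p * nF, n)
  res <- list(Xout = Xout, out_len = out_len, out_p = out_p, p = p)
  if (keep) {
    res$Mcol <- Mcol
    res$Amap <- Amap
    res$amax <- amax
    res$idx <- idx
    res$len <- len
    res$depth <- depth
  }
  res
}

# Backward through one conv layer. dXout: gradient w.r.t. the layer's flat
# output, (out_p * F) x n. Returns dW, db and (optionally) dX for the
# layer below.
conv_backward <- function(cache, W, dXout, n, need_dx = FALSE) {
  nF <- ncol(W)
  out_p <- cache$out_p
  out_len <- cache$out_len
  p <- cache$p
  # back to pooled order (out_p*n) x F
  dP <- array(dXout, dim = c(out_p, nF, n))
  dP <- aperm(dP, c(1L, 3L, 2L))
  dP <- matrix(dP, nrow = out_p * n, ncol = nF)
  if (p == 1L) {
    dA <- dP
  } else {
    dA <- matrix(0, nrow = out_len * n, ncol = nF)
    cidx <- seq_len(out_p * n * nF)
    g <- (cidx - 1L) %% out_p
    rest <- (cidx - 1L) %/% out_p
    s <- rest %% n
    f <- rest %/% n
    pos <- g * p + cache$amax                        # 1-based within out_len
    target <- pos + s * out_len + f * (out_len * n)
    dA[target] <- as.vector(dP)
  }
  dA[cache$Amap <= 0] <- 0                           # ReLU gate
  dW <- crossprod(cache$Mcol, dA)
  db <- colSums(dA)
  dX <- NULL
  if (need_dx) {
    dMcol <- dA %*% t(W)                             # (out_len*n) x LD
    LD <- ncol(dMcol)
    dMa <- array(dMcol, dim = c(out_len, n, LD))
    dX <- matrix(0, nrow = cache$len * cache$depth, ncol = n)
    for (j in seq_len(LD)) {
      rows <- cache$idx[, j]
      dX[rows, ] <- dX[rows, ] + dMa[, , j]
    }
  }
  list(dW = dW, db = db, dX = dX)
}

# Full forward pass over a flat batch. Returns sigmoid scores (n x 2) and,
# with keep = TRUE, every cache required by nn_backward().
nn_forward <- function(model, X, keep = FALSE) {
  spec <- model$spec
  n <- ncol(X)
  len <- spec$input_length
  depth <- 4L
  caches <- if (keep) vector("list", length(spec$conv_layers)) else NULL
  for (i in seq_along(spec$conv_layers)) {
    ly <- spec$conv_layers[[i]]
    cf <- conv_forward(X, model$conv[[i]]$W, model$conv[[i]]$b,
                       len, depth, ly$filter_length, ly$pool_size, n,
                       keep = keep)
    if (keep) caches[[i]] <- cf
    X <- cf$Xout
    len <- cf$out_p
    depth <- ly$n_filters
  }
  Xf <- t(X)                                         # n x features
  Hpre <- Xf %*% model$dense$W
  Hpre <- Hpre + rep(model$dense$b, each = n)
  H <- Hpre
  H[H < 0] <- 0
  Zo <- H %*% model$output$W
  Zo <- Zo + rep(model$output$b, each = n)
  S <- 1 / (1 + exp(-Zo))
  colnames(S) <- c("promoter", "nonpromoter")
  if (!keep) return(list(scores = S))
  list(scores = S, caches = caches, Xf = Xf, H = H)
}

# Categorical cross-entropy on sum-normalized sigmoid outputs, as the
# paper's framework applies it to a non-softmax head. targets: n x 2
# one-hot; weights: optional per-sample weights (mean-normalized).
nn_loss_grad <- function(S, targets, weights = NULL) {
  n <- nrow(S)
  eps <- 1e-12
  w <- if (is.null(weights)) rep(1, n) else weights * n / sum(weights)
  rs <- rowSums(S)
  P <- S / rs
  loss <- -sum(w * rowSums(targets * log(pmax(P, eps)))) / n
  dS <- (w / n) * (-targets / pmax(S, eps) + 1 / rs)
  dZ <- dS * S * (1 - S)
  list(loss = loss, dZ = dZ)
}

# Backward pass; fw must come from nn_forward(keep = TRUE).
nn_backward <- function(model, fw, dZ) {
  n <- nrow(dZ)
  grads <- list()
  grads$output <- list(W = crossprod(fw$H, dZ), b = colSums(dZ))
  dH <- dZ %*% t(model$output$W)
  dH[fw$H <= 0] <- 0
  grads$dense <- list(W = crossprod(fw$Xf, dH), b = colSums(dH))
  dXf <- dH %*% t(model$dense$W)
  dX <- t(dXf)                                       # features x n
  grads$conv <- vector("list", length(model$conv))
  for (i in rev(seq_along(model$conv))) {
    cb <- conv_backward(fw$caches[[i]], model$conv[[i]]$W, dX, n,
                        need_dx = i > 1L)
    grads$conv[[i]] <- list(W = cb$dW, b = cb$db)
    dX <- cb$dX
  }
  grads
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(model) {
  zero_like <- function(x) list(W = x$W * 0, b = x$b * 0)
  list(t = 0L,
       m = list(conv = lapply(model$conv, zero_like),
                dense = zero_like(model$dense),
                output = zero_like(model$output)),
       v = list(conv = lapply(model$conv, zero_like),
                dense = zero_like(model$dense),
                output = zero_like(model$output)))
}

adam_step_one <- function(par, g, m, v, lr_t, beta1, beta2, eps) {
  for (nm in c("W", "b")) {
    m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * g[[nm]]
    v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * g[[nm]]^2
    par[[nm]] <- par[[nm]] - lr_t * m[[nm]] / (sqrt(v[[nm]]) + eps)
  }
  list(par = par, m = m, v = v)
}

adam_update <- function(model, grads, state, lr, beta1, beta2, eps) {
  state$t <- state$t + 1L
  lr_t <- lr * sqrt(1 - beta2^state$t) / (1 - beta1^state$t)
  for (i in seq_along(model$conv)) {
    u <- adam_step_one(model$conv[[i]], grads$conv[[i]],
                       state$m$conv[[i]], state$v$conv[[i]],
                       lr_t, beta1, beta2, eps)
    model$conv[[i]] <- u$par; state$m$conv[[i]] <- u$m
    state$v$conv[[i]] <- u$v
  }
  for (part in c("dense", "output")) {
    u <- adam_step_one(model[[part]], grads[[part]],
                       state$m[[part]], state$v[[part]],
                       lr_t, beta1, beta2, eps)
    model[[part]] <- u$par; state$m[[part]] <- u$m; state$v[[part]] <- u$v
  }
  list(model = model, state = state)
}
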