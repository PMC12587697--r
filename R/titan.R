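#' Configuration for the memory-augmented attention predictor
#'
#' Defaults are the tuned full-size values: hidden width 512, 8 layers,
#' 8 heads, dropout 0.1567, learning rate 1.75e-4, 31 epochs, batch 1024,
#' early-stopping patience 4.  `profile = "reduced"` gives a narrow variant
#' (hidden 64, 2 layers, 4 heads, 10 epochs, batch 256, learning rate 1e-3)
#' whose learning rate is scaled up to compensate for the much smaller number
#' of optimizer steps; it is the profile used by the package's benchmark
#' runs.
#'
#' @param hidden hidden width `d` (divisible by `heads`).
#' @param layers number of residual attention blocks `L`.
#' @param heads number of attention heads.
#' @param dropout dropout rate in `[0, 1)`, also used for MC-dropout passes.
#' @param lr Adam learning rate.
#' @param epochs maximum training epochs.
#' @param batch_size minibatch size.
#' @param patience early-stopping patience (non-improving validation epochs).
#' @param kernel width of the 1-D convolution over the feature axis.
#' @param memory_slots number of memory slots `m` (default 1: one global
#'   vector).
#' @param ff_mult feed-forward expansion factor (inner width = `ff_mult * d`).
#' @param seed integer RNG seed for initialization/shuffling/dropout.
#' @param profile `"full"` or `"reduced"`; explicit arguments override the
#'   profile values.
#' @return an object of class `titan_config`.
#' @export
titan_config <- function(hidden = NULL, layers = NULL, heads = NULL,
                         dropout = 0.1567, lr = NULL, epochs = NULL,
                         batch_size = NULL, patience = 4, kernel = 3,
                         memory_slots = 1, ff_mult = 2, seed = 1L,
                         profile = c("full", "reduced")) {
  profile <- match.arg(profile)
  base <- if (profile == "full") {
    list(hidden = 512L, layers = 8L, heads = 8L, lr = 1.75e-4,
         epochs = 31L, batch_size = 1024L)
  } else {
    list(hidden = 64L, layers = 2L, heads = 4L, lr = 1e-3,
         epochs = 10L, batch_size = 256L)
  }
  cfg <- list(hidden = as.integer(hidden %||% base$hidden),
              layers = as.integer(layers %||% base$layers),
              heads = as.integer(heads %||% base$heads),
              dropout = dropout, lr = lr %||% base$lr,
              epochs = as.integer(epochs %||% base$epochs),
              batch_size = as.integer(batch_size %||% base$batch_size),
              patience = as.integer(patience), kernel = as.integer(kernel),
              memory_slots = as.integer(memory_slots),
              ff_mult = ff_mult, seed = as.integer(seed), profile = profile)
  assert_that(cfg$hidden %% cfg$heads == 0,
              "`hidden` must be divisible by `heads`")
  assert_that(dropout >= 0 && dropout < 1, "`dropout` must be in [0, 1)")
  structure(cfg, class = "titan_config")
}

#' Scaled dot-product attention weights
#'
#' `softmax(Q K' / sqrt(d_k))`: each row of the result is a probability
#' vector over the key positions.
#'
#' @param Q,K conformable numeric matrices (rows = positions).
#' @param d_k positive key dimension used for scaling.
#' @return a row-stochastic matrix.
#' @export
attention_weights <- function(Q, K, d_k) {
  assert_that(d_k > 0, "`d_k` must be positive")
  s <- (Q %*% t(K)) / sqrt(d_k)
  s <- sweep(s, 1, apply(s, 1, max), "-")
  e <- exp(s)
  sweep(e, 1, rowSums(e), "/")
}

#' Gated memory update
#'
#' `g = sigmoid(W_g z + b_g)`; `M_new = g * M_old + (1 - g) * z`,
#' elementwise.  Every coordinate of `M_new` lies in the closed interval
#' between the old memory value and the incoming representation.
#'
#' @param z representation vector (length `d`).
#' @param memory current memory vector (length `d`).
#' @param gate_params list with matrix `W_g` (`d x d`) and vector `b_g`.
#' @return list with the gate `g` and the updated memory `M_new`.
#' @export
memory_update <- function(z, memory, gate_params) {
  assert_that(length(z) == length(memory), "`z`/`memory` width mismatch")
  g <- sigmoid(as.numeric(gate_params$W_g %*% z) + gate_params$b_g)
  list(g = g, M_new = g * memory + (1 - g) * z)
}

# ---- parameter initialization -------------------------------------------

titan_init_params <- function(config, n_features) {
  d <- config$hidden
  dff <- as.integer(config$ff_mult * d)
  gl <- function(nr, nc) {
    matrix(rnorm(nr * nc, 0, sqrt(2 / (nr + nc))), nr, nc)
  }
  layers <- lapply(seq_len(config$layers), function(l) {
    list(Wq = gl(d, d), Wk = gl(d, d), Wv = gl(d, d),
         Wo = gl(d, d), bo = numeric(d),
         W1 = gl(d, dff), b1 = numeric(dff),
         W2 = gl(dff, d), b2 = numeric(d))
  })
  list(conv_w = gl(config$kernel, d), conv_b = numeric(d),
       layers = layers,
       Wg = gl(d, d), bg = numeric(d),
       w_out = rnorm(2 * d, 0, sqrt(1 / (2 * d))), b_out = 0)
}

# ---- forward pass --------------------------------------------------------

layer_norm_rows <- function(x, eps = 1e-6) {
  mu <- rowMeans(x)
  xc <- x - mu
  sig <- sqrt(rowMeans(xc^2) + eps)
  list(y = xc / sig, sig = sig)
}

# x: B x p input; returns pooled representation plus caches for backward.
# Z tensors are stored as (B*p) x d matrices with position-major blocks:
# rows (pos-1)*B + 1:B hold position `pos`.
titan_encode_batch <- function(params, config, x, training = FALSE,
                               keep_cache = FALSE) {
  B <- nrow(x)
  p <- ncol(x)
  d <- config$hidden
  k <- config$kernel
  half <- (k - 1L) %/% 2L
  drop_rate <- if (training) config$dropout else 0
  # Conv1D over the feature axis (single input channel, d output channels)
  xpad <- cbind(matrix(0, B, half), x, matrix(0, B, half))
  Z <- matrix(0, B * p, d)
  for (pos in seq_len(p)) {
    rows <- (pos - 1L) * B + seq_len(B)
    Z[rows, ] <- xpad[, pos:(pos + k - 1L), drop = FALSE] %*% params$conv_w
    Z[rows, ] <- sweep(Z[rows, , drop = FALSE], 2, params$conv_b, "+")
  }
  caches <- vector("list", config$layers)
  h <- config$heads
  dk <- d %/% h
  for (l in seq_len(config$layers)) {
    lp <- params$layers[[l]]
    Zin <- Z
    Q <- Z %*% lp$Wq; K <- Z %*% lp$Wk; V <- Z %*% lp$Wv
    attn <- matrix(0, B * p, d)
    A_list <- vector("list", h)
    for (hh in seq_len(h)) {
      cols <- (hh - 1L) * dk + seq_len(dk)
      S <- array(0, c(B, p, p))
      for (i in seq_len(p)) {
        qi <- Q[(i - 1L) * B + seq_len(B), cols, drop = FALSE]
        for (j in seq_len(p)) {
          kj <- K[(j - 1L) * B + seq_len(B), cols, drop = FALSE]
          S[, i, j] <- rowSums(qi * kj) / sqrt(dk)
        }
      }
      A <- array(0, c(B, p, p))
      for (i in seq_len(p)) {
        si <- S[, i, , drop = FALSE]
        dim(si) <- c(B, p)
        si <- si - apply(si, 1, max)
        e <- exp(si)
        A[, i, ] <- e / rowSums(e)
      }
      for (i in seq_len(p)) {
        oi <- matrix(0, B, dk)
        for (j in seq_len(p)) {
          vj <- V[(j - 1L) * B + seq_len(B), cols, drop = FALSE]
          oi <- oi + A[, i, j] * vj
        }
        attn[(i - 1L) * B + seq_len(B), cols] <- oi
      }
      A_list[[hh]] <- A
    }
    attn_proj <- sweep(attn %*% lp$Wo, 2, lp$bo, "+")
    if (drop_rate > 0) {
      mask1 <- matrix(rbinom(length(attn_proj), 1, 1 - drop_rate),
                      nrow(attn_proj)) / (1 - drop_rate)
      attn_proj <- attn_proj * mask1
    } else mask1 <- NULL
    ln1 <- layer_norm_rows(Zin + attn_proj)
    H_pre <- sweep(ln1$y %*% lp$W1, 2, lp$b1, "+")
    H <- pmax(H_pre, 0)
    ffn <- sweep(H %*% lp$W2, 2, lp$b2, "+")
    if (drop_rate > 0) {
      mask2 <- matrix(rbinom(length(ffn), 1, 1 - drop_rate), nrow(ffn)) /
        (1 - drop_rate)
      ffn <- ffn * mask2
    } else mask2 <- NULL
    ln2 <- layer_norm_rows(ln1$y + ffn)
    Z <- ln2$y
    if (keep_cache) {
      caches[[l]] <- list(Zin = Zin, Q = Q, K = K, V = V, A = A_list,
                          attn = attn, mask1 = mask1, ln1 = ln1,
                          H_pre = H_pre, H = H, mask2 = mask2, ln2 = ln2)
    }
  }
  # mean-pool over the p positions
  zbar <- matrix(0, B, d)
  for (pos in seq_len(p)) {
    zbar <- zbar + Z[(pos - 1L) * B + seq_len(B), , drop = FALSE]
  }
  zbar <- zbar / p
  list(zbar = zbar, Z = Z, caches = caches, B = B, p = p)
}

# backward through the encoder given d(loss)/d(zbar); returns gradient list
# mirroring the parameter structure
titan_encode_backward <- function(params, config, x, fwd, d_zbar) {
  B <- fwd$B; p <- fwd$p; d <- config$hidden
  h <- config$heads; dk <- d %/% h
  k <- config$kernel; half <- (k - 1L) %/% 2L
  grads <- list(conv_w = matrix(0, k, d), conv_b = numeric(d),
                layers = vector("list", config$layers))
  dZ <- matrix(0, B * p, d)
  for (pos in seq_len(p)) {
    dZ[(pos - 1L) * B + seq_len(B), ] <- d_zbar / p
  }
  ln_backward <- function(dy, y, sig) {
    # x-normalized layer norm (no affine): dx = (dy - mean(dy) - y*mean(dy*y))/sig
    m1 <- rowMeans(dy)
    m2 <- rowMeans(dy * y)
    (dy - m1 - y * m2) / sig
  }
  for (l in rev(seq_len(config$layers))) {
    lp <- params$layers[[l]]
    cc <- fwd$caches[[l]]
    g <- list(Wq = matrix(0, d, d), Wk = matrix(0, d, d),
              Wv = matrix(0, d, d), Wo = matrix(0, d, d), bo = numeric(d),
              W1 = NULL, b1 = NULL, W2 = NULL, b2 = NULL)
    # LN2
    d_res2 <- ln_backward(dZ, cc$ln2$y, cc$ln2$sig)
    d_ln1y <- d_res2
    d_ffn <- d_res2
    if (!is.null(cc$mask2)) d_ffn <- d_ffn * cc$mask2
    g$W2 <- t(cc$H) %*% d_ffn
    g$b2 <- colSums(d_ffn)
    dH <- d_ffn %*% t(lp$W2)
    dH[cc$H_pre <= 0] <- 0
    g$W1 <- t(cc$ln1$y) %*% dH
    g$b1 <- colSums(dH)
    d_ln1y <- d_ln1y + dH %*% t(lp$W1)
    # LN1
    d_res1 <- ln_backward(d_ln1y, cc$ln1$y, cc$ln1$sig)
    dZin <- d_res1
    d_attn_proj <- d_res1
    if (!is.null(cc$mask1)) d_attn_proj <- d_attn_proj * cc$mask1
    g$Wo <- t(cc$attn) %*% d_attn_proj
    g$bo <- colSums(d_attn_proj)
    d_attn <- d_attn_proj %*% t(lp$Wo)
    dQ <- matrix(0, B * p, d); dK <- matrix(0, B * p, d)
    dV <- matrix(0, B * p, d)
    for (hh in seq_len(h)) {
      cols <- (hh - 1L) * dk + seq_len(dk)
      A <- cc$A[[hh]]
      dA <- array(0, c(B, p, p))
      for (i in seq_len(p)) {
        doi <- d_attn[(i - 1L) * B + seq_len(B), cols, drop = FALSE]
        for (j in seq_len(p)) {
          vj <- cc$V[(j - 1L) * B + seq_len(B), cols, drop = FALSE]
          dA[, i, j] <- rowSums(doi * vj)
          dV[(j - 1L) * B + seq_len(B), cols] <-
            dV[(j - 1L) * B + seq_len(B), cols] + A[, i, j] * doi
        }
      }
      for (i in seq_len(p)) {
        Ai <- A[, i, , drop = FALSE]; dim(Ai) <- c(B, p)
        dAi <- dA[, i, , drop = FALSE]; dim(dAi) <- c(B, p)
        dS <- Ai * (dAi - rowSums(dAi * Ai))   # softmax backward per row
        for (j in seq_len(p)) {
          kj <- cc$K[(j - 1L) * B + seq_len(B), cols, drop = FALSE]
          qi <- cc$Q[(i - 1L) * B + seq_len(B), cols, drop = FALSE]
          dQ[(i - 1L) * B + seq_len(B), cols] <-
            dQ[(i - 1L) * B + seq_len(B), cols] + dS[, j] * kj / sqrt(dk)
          dK[(j - 1L) * B + seq_len(B), cols] <-
            dK[(j - 1L) * B + seq_len(B), cols] + dS[, j] * qi / sqrt(dk)
        }
      }
    }
    g$Wq <- t(cc$Zin) %*% dQ
    g$Wk <- t(cc$Zin) %*% dK
    g$Wv <- t(cc$Zin) %*% dV
    dZin <- dZin + dQ %*% t(lp$Wq) + dK %*% t(lp$Wk) + dV %*% t(lp$Wv)
    dZ <- dZin
    grads$layers[[l]] <- g
  }
  # conv gradients
  xpad <- cbind(matrix(0, B, half), x, matrix(0, B, half))
  for (pos in seq_len(p)) {
    rows <- (pos - 1L) * B + seq_len(B)
    xs <- xpad[, pos:(pos + k - 1L), drop = FALSE]
    grads$conv_w <- grads$conv_w + t(xs) %*% dZ[rows, , drop = FALSE]
    grads$conv_b <- grads$conv_b + colSums(dZ[rows, , drop = FALSE])
  }
  grads
}

# ---- Adam ----------------------------------------------------------------

adam_init <- function(params) {
  walk_zero <- function(x) {
    if (is.list(x)) lapply(x, walk_zero) else x * 0
  }
  list(m = walk_zero(params), v = walk_zero(params), t = 0)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  tt <- state$t
  upd <- function(p, g, m, v) {
    if (is.list(p)) {
      out_p <- p; out_m <- m; out_v <- v
      for (nm in seq_along(p)) {
        if (is.null(g[[nm]])) next
        r <- upd(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        out_p[[nm]] <- r$p; out_m[[nm]] <- r$m; out_v[[nm]] <- r$v
      }
      return(list(p = out_p, m = out_m, v = out_v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^tt)
    vhat <- v / (1 - beta2^tt)
    list(p = p - lr * mhat / (sqrt(vhat) + eps), m = m, v = v)
  }
  r <- upd(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = tt))
}

# ---- training ------------------------------------------------------------

#' Train the memory-augmented attention predictor
#'
#' Minimizes mean binary cross-entropy with Adam, early-stopping on
#' validation loss after `patience` non-improving epochs.  The treatment
#' must be encoded among the input columns (by convention the column named
#' in `treatment_col`); counterfactual predictions later override it.  The
#' external memory is updated sequentially in a seeded shuffled order during
#' training and frozen afterwards.
#'
#' @param x numeric matrix or data frame of inputs (covariates + treatment),
#'   already preprocessed/scaled.
#' @param y binary outcome vector.
#' @param config a [titan_config()].
#' @param treatment_col name of the treatment column in `x` (default `"T"`).
#' @param x_val,y_val optional validation split for early stopping; when
#'   omitted, a random 20% of the rows is held out.
#' @return an object of class `titan_model` with elements `params`, `memory`,
#'   `config`, `feature_names`, `treatment_col` and a `loss_trace` tibble
#'   (epoch, train BCE, validation BCE).
#' @export
titan_train <- function(x, y, config = titan_config(profile = "reduced"),
                        treatment_col = "T", x_val = NULL, y_val = NULL) {
  x <- as.matrix(x)
  assert_that(all(y %in% c(0, 1)), "`y` must be binary")
  assert_that(treatment_col %in% colnames(x),
              "`treatment_col` must be a column of `x`")
  if (length(unique(y)) < 2) warn("single-class labels: training anyway")
  set.seed(config$seed)
  if (is.null(x_val)) {
    n <- nrow(x)
    idx_val <- sample.int(n, max(1L, floor(0.2 * n)))
    x_val <- x[idx_val, , drop = FALSE]; y_val <- y[idx_val]
    x <- x[-idx_val, , drop = FALSE]; y <- y[-idx_val]
  } else {
    x_val <- as.matrix(x_val)
  }
  n <- nrow(x)
  params <- titan_init_params(config, ncol(x))
  opt <- adam_init(params)
  memory <- numeric(config$hidden)
  best <- list(params = params, memory = memory, val = Inf, stale = 0L)
  trace <- list()
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
    ep_loss <- 0
    for (idx in batches) {
      xb <- x[idx, , drop = FALSE]
      yb <- y[idx]
      B <- nrow(xb)
      fwd <- titan_encode_batch(params, config, xb, training = TRUE,
                                keep_cache = TRUE)
      zb <- fwd$zbar
      # sequential gated memory update across the batch
      d <- config$hidden
      Mprev <- matrix(0, B, d); G <- matrix(0, B, d); Mrow <- matrix(0, B, d)
      for (i in seq_len(B)) {
        Mprev[i, ] <- memory
        mu <- memory_update(zb[i, ], memory,
                            list(W_g = params$Wg, b_g = params$bg))
        G[i, ] <- mu$g
        memory <- mu$M_new
        Mrow[i, ] <- memory
      }
      w1 <- params$w_out[seq_len(d)]
      w2 <- params$w_out[d + seq_len(d)]
      logits <- as.numeric(zb %*% w1 + Mrow %*% w2 + params$b_out)
      prob <- sigmoid(logits)
      ep_loss <- ep_loss + sum(bce(prob, yb))
      dlogit <- (prob - yb) / B
      g_wout <- c(colSums(zb * dlogit), colSums(Mrow * dlogit))
      g_bout <- sum(dlogit)
      dM <- outer(dlogit, w2)                       # B x d
      d_zb <- outer(dlogit, w1) + dM * (1 - G)      # direct + memory paths
      dG <- dM * (Mprev - zb)
      dG_pre <- dG * G * (1 - G)
      g_Wg <- t(dG_pre) %*% zb
      g_bg <- colSums(dG_pre)
      d_zb <- d_zb + dG_pre %*% params$Wg
      grads <- titan_encode_backward(params, config, xb, fwd, d_zb)
      grads$Wg <- g_Wg; grads$bg <- g_bg
      grads$w_out <- g_wout; grads$b_out <- g_bout
      st <- adam_step(params, grads, opt, config$lr)
      params <- st$params; opt <- st$state
    }
    model_now <- structure(
      list(params = params, memory = memory, config = config,
           feature_names = colnames(x), treatment_col = treatment_col),
      class = "titan_model")
    val_prob <- titan_predict(model_now, x_val)
    val_loss <- mean(bce(val_prob, y_val))
    trace[[epoch]] <- tibble::tibble(epoch = epoch,
                                     train_bce = ep_loss / n,
                                     val_bce = val_loss)
    if (val_loss < best$val - 1e-6) {
      best <- list(params = params, memory = memory, val = val_loss,
                   stale = 0L)
    } else {
      best$stale <- best$stale + 1L
      if (best$stale >= config$patience) break
    }
  }
  structure(list(params = best$params, memory = best$memory, config = config,
                 feature_names = colnames(x), treatment_col = treatment_col,
                 loss_trace = dplyr::bind_rows(trace)),
            class = "titan_model")
}

#' @export
print.titan_model <- function(x, ...) {
  cat("titan_model: hidden", x$config$hidden, "| layers", x$config$layers,
      "| heads", x$config$heads, "|", length(x$feature_names), "features\n")
  invisible(x)
}

#' Encode inputs into pooled representations
#'
#' Runs the convolution and the stack of residual attention blocks and
#' returns the position-pooled representation `z^(L)` (width = hidden size).
#'
#' @param model a fitted or initialized `titan_model`.
#' @param x input matrix/data frame (same columns as at training).
#' @param dropout if TRUE the pass is stochastic (dropout active).
#' @return a matrix with one row per input row and `hidden` columns.
#' @export
titan_encode <- function(model, x, dropout = FALSE) {
  x <- as.matrix(x)[, model$feature_names, drop = FALSE]
  titan_encode_batch(model$params, model$config, x,
                     training = dropout, keep_cache = FALSE)$zbar
}

#' Predict outcome probabilities
#'
#' `yhat = sigmoid(w_o [z || M] + b_o)` with the frozen training memory `M`.
#' Deterministic in eval mode; pass `dropout = TRUE` for a stochastic
#' (MC-dropout) forward pass.
#'
#' @inheritParams titan_encode
#' @return numeric vector of probabilities in `(0, 1)`.
#' @export
titan_predict <- function(model, x, dropout = FALSE) {
  zb <- titan_encode(model, x, dropout = dropout)
  d <- model$config$hidden
  w1 <- model$params$w_out[seq_len(d)]
  w2 <- model$params$w_out[d + seq_len(d)]
  logits <- as.numeric(zb %*% w1 + sum(model$memory * w2) + model$params$b_out)
  sigmoid(logits)
}

#' Counterfactual prediction for a treatment arm
#'
#' Overrides the treatment input column with `arm` and returns
#' [titan_predict()]: the estimated outcome probability had every unit been
#' assigned that arm.
#'
#' @inheritParams titan_encode
#' @param arm treatment level (scalar) to impose on all rows.
#' @return numeric vector of probabilities.
#' @export
titan_counterfactual <- function(model, x, arm, dropout = FALSE) {
  x <- as.matrix(x)[, model$feature_names, drop = FALSE]
  x[, model$treatment_col] <- arm
  titan_predict(model, x, dropout = dropout)
}
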