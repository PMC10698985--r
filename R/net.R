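#' Base network configuration
#'
#' Architecture hyperparameters of one base classifier. The defaults are
#' the reference configuration: three 1-D convolution stages (kernel 5,
#' 8 kernels, stride 1, same-length zero padding, each followed by ReLU
#' and size-3 stride-1 max pooling), 4 attention heads of dimension 16,
#' and a fully connected head of 1024/256/1 units with batch
#' normalization, ReLU and dropout 0.5 after the first two layers.
#'
#' @param window Context window half-width W (the window spans 2W+1
#'   residues). Default 32.
#' @param fmod Feature module index (0, 1 or 2).
#' @param conv_layers Number of convolution stages (default 3).
#' @param kernel_size Convolution kernel width (odd; default 5).
#' @param n_kernels Kernels per convolution layer (default 8).
#' @param pool_size Max-pooling width (odd; default 3).
#' @param heads Attention heads (default 4).
#' @param head_dim Per-head attention dimension (default 16).
#' @param fc_sizes Fully connected layer sizes (default 1024, 256, 1).
#' @param dropout_rate Dropout probability after FC layers 1-2.
#' @param attention `FALSE` builds the convolution-only ablation in
#'   which pooling aggregates the convolution output alone.
#' @param params [feature_params] (fixes the module-2 feature dimension).
#' @return An object of class `net_config`.
#' @export
net_config <- function(window = 32, fmod = 0, conv_layers = 3,
                       kernel_size = 5, n_kernels = 8, pool_size = 3,
                       heads = 4, head_dim = 16, fc_sizes = c(1024, 256, 1),
                       dropout_rate = 0.5, attention = TRUE,
                       params = feature_params()) {
  stopifnot(window >= 1, fmod %in% 0:2, conv_layers >= 1,
            kernel_size %% 2 == 1, pool_size %% 2 == 1,
            heads >= 1, head_dim >= 1, length(fc_sizes) == 3,
            fc_sizes[3] == 1, dropout_rate >= 0, dropout_rate < 1)
  d_in <- fmod_dims(params)[fmod + 1]
  d_agg <- n_kernels + if (attention) heads * head_dim else 0L
  structure(list(window = as.integer(window), fmod = as.integer(fmod),
                 conv_layers = as.integer(conv_layers),
                 kernel_size = as.integer(kernel_size),
                 n_kernels = as.integer(n_kernels),
                 pool_size = as.integer(pool_size),
                 heads = as.integer(heads), head_dim = as.integer(head_dim),
                 fc_sizes = as.integer(fc_sizes),
                 dropout_rate = dropout_rate, attention = isTRUE(attention),
                 d_in = d_in, d_agg = as.integer(d_agg),
                 d_fc_in = as.integer(d_agg + d_in), params = params),
            class = "net_config")
}

#' Initialize a base network
#'
#' Fan-in-scaled random normal initialization with a recorded seed;
#' biases and batch-norm shifts start at zero, batch-norm scales at one.
#'
#' @param config A [net_config].
#' @param seed Integer seed.
#' @return An object of class `base_net` with elements `config`, `params`
#'   (named list of weight arrays), `bn` (running batch-norm statistics)
#'   and `trained` flag.
#' @export
net_init <- function(config, seed = 1) {
  stopifnot(inherits(config, "net_config"))
  cfg <- config
  params <- with_seed(seed, {
    p <- list()
    cin <- cfg$d_in
    for (l in seq_len(cfg$conv_layers)) {
      fan_in <- cfg$kernel_size * cin
      p[[paste0("conv", l, "_W")]] <-
        matrix(rnorm(fan_in * cfg$n_kernels, sd = sqrt(2 / fan_in)),
               fan_in, cfg$n_kernels)
      p[[paste0("conv", l, "_b")]] <- numeric(cfg$n_kernels)
      cin <- cfg$n_kernels
    }
    if (cfg$attention) {
      for (h in seq_len(cfg$heads)) {
        for (nm in c("Wq", "Wk", "Wv")) {
          p[[paste0("attn", h, "_", nm)]] <-
            matrix(rnorm(cfg$head_dim * cfg$n_kernels,
                         sd = sqrt(1 / cfg$n_kernels)),
                   cfg$head_dim, cfg$n_kernels)
        }
      }
    }
    din <- cfg$d_fc_in
    for (l in 1:2) {
      dout <- cfg$fc_sizes[l]
      p[[paste0("fc", l, "_W")]] <- matrix(rnorm(din * dout,
                                                 sd = sqrt(2 / din)),
                                           din, dout)
      p[[paste0("fc", l, "_b")]] <- numeric(dout)
      p[[paste0("fc", l, "_gamma")]] <- rep(1, dout)
      p[[paste0("fc", l, "_beta")]] <- numeric(dout)
      din <- dout
    }
    p[["fc3_W"]] <- matrix(rnorm(din, sd = sqrt(1 / din)), din, 1)
    p[["fc3_b"]] <- 0
    p
  })
  bn <- list()
  for (l in 1:2) {
    bn[[paste0("fc", l)]] <- list(mean = numeric(cfg$fc_sizes[l]),
                                  var = rep(1, cfg$fc_sizes[l]))
  }
  structure(list(config = cfg, params = params, bn = bn,
                 trained = FALSE, seed = as.integer(seed)),
            class = "base_net")
}

#' @export
print.base_net <- function(x, ...) {
  cfg <- x$config
  cat("<base_net> feature module ", cfg$fmod, ", W = ", cfg$window,
      ", ", cfg$conv_layers, " conv stages x ", cfg$n_kernels, " kernels, ",
      if (cfg$attention) paste0(cfg$heads, " attention heads x ",
                                cfg$head_dim) else "no attention",
      ", FC ", paste(cfg$fc_sizes, collapse = "/"),
      if (x$trained) " [trained]" else " [untrained]", "\n", sep = "")
  invisible(x)
}

# ---- low-level batched layers (arrays are B x L x C) ----------------------

conv1d_forward <- function(X, W, b) {
  dm <- dim(X)
  B <- dm[1]; L <- dm[2]; C <- dm[3]
  k <- nrow(W) / C
  pad <- (k - 1) / 2
  Xp <- array(0, c(B, L + 2 * pad, C))
  Xp[, pad + seq_len(L), ] <- X
  cols <- matrix(0, B * L, k * C)
  for (kk in seq_len(k)) {
    cols[, (kk - 1) * C + seq_len(C)] <-
      matrix(Xp[, (kk - 1) + seq_len(L), , drop = FALSE], B * L, C)
  }
  out <- cols %*% W
  out <- out + rep(b, each = nrow(out))
  list(out = array(out, c(B, L, ncol(W))), cols = cols)
}

conv1d_backward <- function(dOut, cols, W, B, L, C) {
  k <- nrow(W) / C
  pad <- (k - 1) / 2
  D <- ncol(W)
  dOutM <- matrix(dOut, B * L, D)
  dW <- crossprod(cols, dOutM)
  db <- colSums(dOutM)
  dcols <- tcrossprod(dOutM, W)
  dXp <- array(0, c(B, L + 2 * pad, C))
  for (kk in seq_len(k)) {
    dXp[, (kk - 1) + seq_len(L), ] <-
      dXp[, (kk - 1) + seq_len(L), , drop = FALSE] +
      array(dcols[, (kk - 1) * C + seq_len(C)], c(B, L, C))
  }
  list(dX = dXp[, pad + seq_len(L), , drop = FALSE], dW = dW, db = db)
}

maxpool_forward <- function(X, size = 3) {
  dm <- dim(X)
  B <- dm[1]; L <- dm[2]; C <- dm[3]
  pad <- (size - 1) / 2
  Xp <- array(-Inf, c(B, L + 2 * pad, C))
  Xp[, pad + seq_len(L), ] <- X
  win <- lapply(seq_len(size), function(kk) {
    Xp[, (kk - 1) + seq_len(L), , drop = FALSE]
  })
  M <- Reduce(pmax, win)
  # route gradient to the first maximum in each window
  sel <- vector("list", size)
  taken <- array(FALSE, dim(M))
  for (kk in seq_len(size)) {
    sel[[kk]] <- (win[[kk]] == M) & !taken
    taken <- taken | sel[[kk]]
  }
  list(out = M, sel = sel, size = size)
}

maxpool_backward <- function(dOut, pool) {
  dm <- dim(dOut)
  B <- dm[1]; L <- dm[2]; C <- dm[3]
  size <- pool$size
  pad <- (size - 1) / 2
  dXp <- array(0, c(B, L + 2 * pad, C))
  for (kk in seq_len(size)) {
    dXp[, (kk - 1) + seq_len(L), ] <-
      dXp[, (kk - 1) + seq_len(L), , drop = FALSE] + dOut * pool$sel[[kk]]
  }
  dXp[, pad + seq_len(L), , drop = FALSE]
}

bn_forward <- function(U, gamma, beta, running, training, eps = 1e-5,
                       momentum = 0.1) {
  n <- nrow(U)
  if (training) {
    mu <- colMeans(U)
    centered <- U - rep(mu, each = n)
    v <- colMeans(centered^2)
    running$mean <- (1 - momentum) * running$mean + momentum * mu
    running$var <- (1 - momentum) * running$var + momentum * v
  } else {
    mu <- running$mean
    v <- running$var
    centered <- U - rep(mu, each = n)
  }
  istd <- 1 / sqrt(v + eps)
  xhat <- centered * rep(istd, each = n)
  out <- xhat * rep(gamma, each = n) + rep(beta, each = n)
  list(out = out, xhat = xhat, centered = centered, istd = istd,
       running = running)
}

bn_backward <- function(dY, cache, gamma) {
  n <- nrow(dY)
  dgamma <- colSums(dY * cache$xhat)
  dbeta <- colSums(dY)
  dxhat <- dY * rep(gamma, each = n)
  istd <- cache$istd
  dvar <- colSums(dxhat * cache$centered) * (-0.5) * istd^3
  dmu <- colSums(dxhat) * (-istd) + dvar * colMeans(-2 * cache$centered)
  dU <- dxhat * rep(istd, each = n) +
    cache$centered * rep(2 * dvar / n, each = n) +
    rep(dmu / n, each = n)
  list(dU = dU, dgamma = dgamma, dbeta = dbeta)
}

# ---- full forward pass (batched) ------------------------------------------

# X: B x L x d_in, mask: B x L logical (TRUE = padded), Ftr: B x d_in
forward_batch <- function(model, X, mask, Ftr, training = FALSE,
                          keep_cache = FALSE) {
  cfg <- model$config
  p <- model$params
  dm <- dim(X)
  B <- dm[1]; L <- dm[2]
  if (L < 1 || B < 1) stop("empty input", call. = FALSE)
  if (any(rowSums(!mask) == 0)) {
    stop("at least one non-padded window position is required",
         call. = FALSE)
  }
  # padded rows carry no information: force them to zero on entry so the
  # output is invariant to whatever content they might hold
  X <- X * array(!mask, dim(X))

  cache <- list(B = B, L = L)
  # convolution block
  Z <- X
  conv_caches <- vector("list", cfg$conv_layers)
  for (l in seq_len(cfg$conv_layers)) {
    cv <- conv1d_forward(Z, p[[paste0("conv", l, "_W")]],
                         p[[paste0("conv", l, "_b")]])
    relu_mask <- cv$out > 0
    act <- cv$out * relu_mask
    pool <- maxpool_forward(act, cfg$pool_size)
    conv_caches[[l]] <- list(cols = cv$cols, relu = relu_mask, pool = pool,
                             cin = dim(Z)[3])
    Z <- pool$out
  }
  cache$conv <- conv_caches
  D <- cfg$n_kernels
  Zm <- matrix(Z, B * L, D)

  # masked multi-head self-attention
  if (cfg$attention) {
    dmh <- cfg$head_dim
    H <- cfg$heads
    Am <- matrix(0, B * L, dmh * H)
    attn <- vector("list", H)
    for (h in seq_len(H)) {
      Qm <- tcrossprod(Zm, p[[paste0("attn", h, "_Wq")]])
      Km <- tcrossprod(Zm, p[[paste0("attn", h, "_Wk")]])
      Vm <- tcrossprod(Zm, p[[paste0("attn", h, "_Wv")]])
      Warr <- array(0, c(L, L, B))
      for (b in seq_len(B)) {
        idx <- b + (seq_len(L) - 1L) * B
        Eb <- tcrossprod(Qm[idx, , drop = FALSE],
                         Km[idx, , drop = FALSE]) / sqrt(dmh)
        Eb[mask[b, ], ] <- Eb[mask[b, ], ] - 1e9   # penalize padded rows i
        Ee <- exp(Eb - max(Eb))                    # stabilized softmax
        Wb <- Ee * rep(1 / colSums(Ee), each = L)  # columns sum to 1
        Warr[, , b] <- Wb
        Am[idx, (h - 1) * dmh + seq_len(dmh)] <-
          crossprod(Wb, Vm[idx, , drop = FALSE])   # h_j = sum_i w_ij v_i
      }
      attn[[h]] <- list(Qm = Qm, Km = Km, Vm = Vm, Warr = Warr)
    }
    cache$attn <- attn
    Sm <- cbind(Zm, Am)
  } else {
    Sm <- Zm
  }
  cache$Zm <- Zm

  # average pooling over non-padded positions
  nn <- rowSums(!mask)
  wmat <- (!mask) / nn                 # B x L weights
  wvec <- as.vector(wmat)              # matches row order of Sm (b fastest)
  group <- rep(seq_len(B), times = L)
  f_agg <- rowsum(Sm * wvec, group)    # B x d_agg
  cache$wvec <- wvec
  cache$group <- group

  f_prot <- cbind(f_agg, Ftr)
  cache$f_prot <- f_prot

  # fully connected head
  Hcur <- f_prot
  fc_caches <- vector("list", 2)
  for (l in 1:2) {
    U <- Hcur %*% p[[paste0("fc", l, "_W")]]
    U <- U + rep(p[[paste0("fc", l, "_b")]], each = nrow(U))
    bnr <- bn_forward(U, p[[paste0("fc", l, "_gamma")]],
                      p[[paste0("fc", l, "_beta")]],
                      model$bn[[paste0("fc", l)]], training)
    if (training) model$bn[[paste0("fc", l)]] <- bnr$running
    Y <- bnr$out
    relu_mask <- Y > 0
    R <- Y * relu_mask
    if (training && cfg$dropout_rate > 0) {
      keep <- matrix(runif(length(R)) >= cfg$dropout_rate, nrow(R), ncol(R))
      Dp <- R * keep / (1 - cfg$dropout_rate)
    } else {
      keep <- NULL
      Dp <- R
    }
    fc_caches[[l]] <- list(input = Hcur, bn = bnr, relu = relu_mask,
                           keep = keep)
    Hcur <- Dp
  }
  cache$fc <- fc_caches
  logits <- as.numeric(Hcur %*% p[["fc3_W"]]) + p[["fc3_b"]]
  prob <- plogis(logits)
  cache$H2 <- Hcur
  out <- list(prob = prob, logits = logits, model = model)
  if (keep_cache) out$cache <- cache
  out
}

backward_batch <- function(model, cache, dlogit) {
  cfg <- model$config
  p <- model$params
  B <- cache$B; L <- cache$L
  g <- list()
  dlog <- matrix(dlogit, B, 1)
  g[["fc3_W"]] <- crossprod(cache$H2, dlog)
  g[["fc3_b"]] <- sum(dlogit)
  dH <- dlog %*% t(p[["fc3_W"]])
  for (l in 2:1) {
    fcc <- cache$fc[[l]]
    if (!is.null(fcc$keep)) {
      dH <- dH * fcc$keep / (1 - cfg$dropout_rate)
    }
    dY <- dH * fcc$relu
    bnb <- bn_backward(dY, fcc$bn, p[[paste0("fc", l, "_gamma")]])
    g[[paste0("fc", l, "_gamma")]] <- bnb$dgamma
    g[[paste0("fc", l, "_beta")]] <- bnb$dbeta
    dU <- bnb$dU
    g[[paste0("fc", l, "_W")]] <- crossprod(fcc$input, dU)
    g[[paste0("fc", l, "_b")]] <- colSums(dU)
    dH <- tcrossprod(dU, p[[paste0("fc", l, "_W")]])
  }
  df_prot <- dH
  d_agg <- cfg$d_agg
  df_agg <- df_prot[, seq_len(d_agg), drop = FALSE]
  dSm <- df_agg[cache$group, , drop = FALSE] * cache$wvec
  D <- cfg$n_kernels
  dZm <- dSm[, seq_len(D), drop = FALSE]
  if (cfg$attention) {
    dmh <- cfg$head_dim
    dAm <- dSm[, D + seq_len(cfg$heads * dmh), drop = FALSE]
    Zm <- cache$Zm
    for (h in seq_len(cfg$heads)) {
      at <- cache$attn[[h]]
      dQm <- matrix(0, B * L, dmh)
      dKm <- matrix(0, B * L, dmh)
      dVm <- matrix(0, B * L, dmh)
      dHm <- dAm[, (h - 1) * dmh + seq_len(dmh), drop = FALSE]
      for (b in seq_len(B)) {
        idx <- b + (seq_len(L) - 1L) * B
        dHb <- dHm[idx, , drop = FALSE]
        Wb <- at$Warr[, , b]
        Vb <- at$Vm[idx, , drop = FALSE]
        dWb <- tcrossprod(Vb, dHb)
        dVm[idx, ] <- Wb %*% dHb
        cj <- colSums(Wb * dWb)
        dEb <- Wb * (dWb - rep(cj, each = L))
        dEb <- dEb / sqrt(dmh)
        dQm[idx, ] <- dEb %*% at$Km[idx, , drop = FALSE]
        dKm[idx, ] <- crossprod(dEb, at$Qm[idx, , drop = FALSE])
      }
      g[[paste0("attn", h, "_Wq")]] <- crossprod(dQm, Zm)
      g[[paste0("attn", h, "_Wk")]] <- crossprod(dKm, Zm)
      g[[paste0("attn", h, "_Wv")]] <- crossprod(dVm, Zm)
      dZm <- dZm + dQm %*% p[[paste0("attn", h, "_Wq")]] +
        dKm %*% p[[paste0("attn", h, "_Wk")]] +
        dVm %*% p[[paste0("attn", h, "_Wv")]]
    }
  }
  dZ <- array(dZm, c(B, L, D))
  for (l in cfg$conv_layers:1) {
    cc <- cache$conv[[l]]
    dAct <- maxpool_backward(dZ, cc$pool)
    dPre <- dAct * cc$relu
    cb <- conv1d_backward(dPre, cc$cols, p[[paste0("conv", l, "_W")]],
                          B, L, cc$cin)
    g[[paste0("conv", l, "_W")]] <- cb$dW
    g[[paste0("conv", l, "_b")]] <- cb$db
    dZ <- cb$dX
  }
  g
}

# ---- public single-sample operations --------------------------------------

#' Convolution block forward pass
#'
#' Runs the window context matrix through the stacked 1-D convolution /
#' ReLU / max-pooling stages. Same-length zero padding keeps the output
#' length equal to the input length; max pooling uses stride 1 with
#' same-length padding.
#'
#' @param model A [base_net].
#' @param f_ctx Context matrix, (2W+1) x d rows.
#' @return Matrix (2W+1) x `n_kernels`.
#' @export
conv_block_forward <- function(model, f_ctx) {
  f_ctx <- as.matrix(f_ctx)
  if (nrow(f_ctx) == 0) stop("context matrix has zero rows", call. = FALSE)
  cfg <- model$config
  Z <- array(f_ctx, c(1, nrow(f_ctx), ncol(f_ctx)))
  for (l in seq_len(cfg$conv_layers)) {
    cv <- conv1d_forward(Z, model$params[[paste0("conv", l, "_W")]],
                         model$params[[paste0("conv", l, "_b")]])
    act <- cv$out * (cv$out > 0)
    Z <- maxpool_forward(act, cfg$pool_size)$out
  }
  matrix(Z, dim(Z)[2], dim(Z)[3])
}

#' Masked multi-head self-attention
#'
#' For each head, queries/keys/values are linear projections of the
#' convolution output; energies are the scaled query-key products with a
#' large negative penalty (1e9) added at padded positions of the
#' summed-over index; weights are column-normalized softmax (each column
#' sums to 1) and each output position is the weight-averaged value
#' vector. Head outputs are concatenated.
#'
#' @param model A [base_net] with attention enabled.
#' @param Z Matrix L x `n_kernels` (convolution block output).
#' @param pad_mask Logical vector of length L, `TRUE` = padded.
#' @return Matrix L x (`heads` * `head_dim`).
#' @export
masked_multihead_attention <- function(model, Z, pad_mask) {
  cfg <- model$config
  if (!cfg$attention) stop("model was built without attention",
                           call. = FALSE)
  Z <- as.matrix(Z)
  L <- nrow(Z)
  if (L < 1) stop("empty input", call. = FALSE)
  if (all(pad_mask)) stop("all positions are padded", call. = FALSE)
  dmh <- cfg$head_dim
  out <- matrix(0, L, dmh * cfg$heads)
  for (h in seq_len(cfg$heads)) {
    Q <- tcrossprod(Z, model$params[[paste0("attn", h, "_Wq")]])
    K <- tcrossprod(Z, model$params[[paste0("attn", h, "_Wk")]])
    V <- tcrossprod(Z, model$params[[paste0("attn", h, "_Wv")]])
    E <- tcrossprod(Q, K) / sqrt(dmh)
    E[pad_mask, ] <- E[pad_mask, ] - 1e9
    E <- sweep(E, 2, apply(E, 2, max))
    Ee <- exp(E)
    W <- sweep(Ee, 2, colSums(Ee), "/")
    out[, (h - 1) * dmh + seq_len(dmh)] <- crossprod(W, V)
  }
  out
}

#' Aggregate convolution and attention features
#'
#' Rowwise concatenation of the convolution output and the attention
#' output, then the arithmetic mean over non-padded rows.
#'
#' @param Z Matrix L x D (convolution output).
#' @param A Matrix L x d_a (attention output), or `NULL` for the
#'   convolution-only ablation.
#' @param pad_mask Logical vector of length L.
#' @return Numeric vector of length D + d_a.
#' @export
aggregate_features <- function(Z, A = NULL, pad_mask) {
  Z <- as.matrix(Z)
  S <- if (is.null(A)) Z else cbind(Z, as.matrix(A))
  if (!is.null(A) && nrow(as.matrix(A)) != nrow(Z)) {
    stop("Z and A must have the same number of rows", call. = FALSE)
  }
  keep <- !pad_mask
  if (!any(keep)) stop("no non-padded rows to aggregate", call. = FALSE)
  colMeans(S[keep, , drop = FALSE])
}

#' Predictor head forward pass
#'
#' Inference-mode pass of the fully connected head on one protein
#' feature vector: affine(1024) -> batch-norm -> ReLU -> affine(256) ->
#' batch-norm -> ReLU -> affine(1) -> sigmoid. Dropout is active only
#' during training; batch-norm uses the stored running statistics here.
#'
#' @param model A [base_net].
#' @param f_prot Numeric vector of length `d_agg + d_in`.
#' @return Probability in (0, 1).
#' @export
predictor_forward <- function(model, f_prot) {
  cfg <- model$config
  if (length(f_prot) != cfg$d_fc_in) {
    stop("expected a feature vector of length ", cfg$d_fc_in, ", got ",
         length(f_prot), call. = FALSE)
  }
  H <- matrix(f_prot, 1)
  p <- model$params
  for (l in 1:2) {
    U <- H %*% p[[paste0("fc", l, "_W")]] + p[[paste0("fc", l, "_b")]]
    bnr <- bn_forward(U, p[[paste0("fc", l, "_gamma")]],
                      p[[paste0("fc", l, "_beta")]],
                      model$bn[[paste0("fc", l)]], training = FALSE)
    H <- bnr$out * (bnr$out > 0)
  }
  as.numeric(plogis(H %*% p[["fc3_W"]] + p[["fc3_b"]]))
}

#' Full base-network forward pass for one residue
#'
#' Convolution block, masked attention (if enabled), masked average
#' pooling, concatenation with the untransformed targeted residue
#' feature, and the predictor head.
#'
#' @param model A [base_net].
#' @param feature_set A [build_residue_feature_set] result whose `fmod`
#'   matches the model's.
#' @return Probability in (0, 1).
#' @export
net_forward <- function(model, feature_set) {
  cfg <- model$config
  if (!identical(as.integer(feature_set$fmod), cfg$fmod)) {
    stop("feature set is for module ", feature_set$fmod,
         " but the model expects module ", cfg$fmod, call. = FALSE)
  }
  res <- forward_batch(model,
                       array(feature_set$f_ctx,
                             c(1, nrow(feature_set$f_ctx),
                               ncol(feature_set$f_ctx))),
                       matrix(feature_set$pad_mask, 1),
                       matrix(feature_set$f_tr, 1),
                       training = FALSE)
  res$prob
}

# softmax weight matrix of one attention head (columns sum to 1);
# diagnostic helper shared by tests
attention_weights <- function(model, Z, pad_mask, head = 1) {
  cfg <- model$config
  Z <- as.matrix(Z)
  dmh <- cfg$head_dim
  Q <- tcrossprod(Z, model$params[[paste0("attn", head, "_Wq")]])
  K <- tcrossprod(Z, model$params[[paste0("attn", head, "_Wk")]])
  E <- tcrossprod(Q, K) / sqrt(dmh)
  E[pad_mask, ] <- E[pad_mask, ] - 1e9
  E <- sweep(E, 2, apply(E, 2, max))
  Ee <- exp(E)
  sweep(Ee, 2, colSums(Ee), "/")
}

# evaluation-mode probabilities over a featurized set, in chunks
eval_probs <- function(model, feats, batch = 1024) {
  N <- length(feats$y)
  probs <- numeric(N)
  at <- 1L
  while (at <= N) {
    idx <- at:min(N, at + batch - 1L)
    probs[idx] <- forward_batch(
      model,
      feats$X[idx, , , drop = FALSE],
      feats$mask[idx, , drop = FALSE],
      feats$ftr[idx, , drop = FALSE],
      training = FALSE)$prob
    at <- at + batch
  }
  probs
}

#' Predict site probabilities for records
#'
#' @param object A trained [base_net].
#' @param records List of [protein_record] objects.
#' @param ... Unused.
#' @return Data frame with `id`, `position` (1-based), `score`.
#' @export
predict.base_net <- function(object, records, ...) {
  feats <- featurize_records(records, object$config$fmod,
                             object$config$window, object$config$params)
  data.frame(id = feats$id, position = feats$position,
             score = eval_probs(object, feats), stringsAsFactors = FALSE)
}

#' Save / load a base network checkpoint
#'
#' Checkpoints are RDS files holding the parameter list with the
#' configuration embedded.
#'
#' @param model A [base_net].
#' @param path File path.
#' @return `save_model` returns `path` invisibly; `load_model` returns
#'   the restored [base_net].
#' @export
save_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "base_net"))
  model
}
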