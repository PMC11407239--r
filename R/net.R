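#' Normalize a volume by its masked standard deviation
#'
#' Divides every voxel by the population standard deviation computed over
#' the masked voxels (the network's input/target conditioning; the IoU
#' threshold of 1 then means one standard deviation).
#'
#' @param v A `recon_volume`, `fluor_map`, or array.
#' @param mask Logical array (required when `v` is a bare array).
#' @return Same type as `v`, normalized; `recon_volume`s get
#'   `normalized = TRUE`.
#' @export
normalize_volume <- function(v, mask = NULL) {
  if (inherits(v, "recon_volume")) {
    vals <- normalize_volume(v$values, v$grid$mask)
    return(recon_volume(vals, v$grid, normalized = TRUE))
  }
  if (inherits(v, "fluor_map")) {
    v$values <- normalize_volume(v$values, v$grid$mask)
    return(v)
  }
  if (is.null(mask)) stop("mask required for a bare array")
  x <- v[mask]
  s <- sqrt(mean(x^2) - mean(x)^2)   # population standard deviation
  if (!is.finite(s) || s <= 0) stop("zero standard deviation over the mask")
  v / s
}

#' Masked sum-of-squares loss
#'
#' `sum((pred - target)^2)` over the masked voxels only (voxels outside the
#' cylindrical model never contribute).
#'
#' @param pred,target Arrays of equal shape.
#' @param mask Logical array of the same shape.
#' @return Scalar loss.
#' @export
masked_sse_loss <- function(pred, target, mask) {
  stopifnot(all(dim(pred) == dim(target)), all(dim(pred) == dim(mask)))
  if (!any(mask)) stop("empty mask")
  d <- (pred - target)[mask]
  sum(d * d)
}

#' Network architecture configuration
#'
#' A 3D residual encoder-decoder (U-Net): per resolution level two 3x3x3
#' convolution + ReLU blocks (the deepest level gets two extra, widening the
#' receptive field at 1/8 the fine-level cost), 2x average-pool downsampling,
#' nearest-neighbor upsampling followed by a 1x1x1 channel-mixing projection,
#' skip concatenation at matching resolutions, and a zero-initialized final
#' convolution so the untrained network is exactly the identity (the network
#' learns a residual correction added to its input).
#'
#' @param dims Input volume dimensions (integer triple).
#' @param depth Number of resolution levels (>= 1).
#' @param channels Integer vector of per-level channel counts (length =
#'   `depth`).
#' @param preset `"full"` (depth 4, channels 16/32/64/128) or `"scaled"`
#'   (depth 2, channels 8/16) — overrides `depth`/`channels` when given.
#' @return Object of class `net_config`. Dimensions not divisible by
#'   `2^(depth-1)` are handled by symmetric zero-padding to the nearest
#'   valid size (cropped on output).
#' @export
net_config <- function(dims, depth = 2, channels = c(8L, 16L), preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("full", "scaled"))
    if (preset == "full") { depth <- 4L; channels <- c(16L, 32L, 64L, 128L) }
    else { depth <- 2L; channels <- c(8L, 16L) }
  }
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3L, all(dims >= 1L), depth >= 1L,
            length(channels) == depth)
  div <- 2L^(depth - 1L)
  workdims <- as.integer(ceiling(dims / div) * div)
  if (any(workdims / div < 1))
    stop("volume too small for the requested depth")
  structure(list(dims = dims, depth = as.integer(depth),
                 channels = as.integer(channels), workdims = workdims),
            class = "net_config")
}

#' Training configuration
#'
#' @param batch_size Mini-batch size (default 16).
#' @param max_epochs Maximum epochs (default 200).
#' @param patience Early-stopping patience: stop when the validation loss
#'   has not decreased for this many consecutive epochs (default 5).
#' @param lr Adam learning rate (default 1e-3).
#' @param seed RNG seed for shuffling (and weight init when the model is
#'   built inside [train_denoiser()]).
#' @return Object of class `train_config`.
#' @export
train_config <- function(batch_size = 16L, max_epochs = 200L, patience = 5L,
                         lr = 1e-3, seed = 1L) {
  stopifnot(batch_size >= 1L, patience < max_epochs)
  structure(list(batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), lr = lr,
                 seed = as.integer(seed)),
            class = "train_config")
}

lin3 <- function(i, j, k, pd) i + (j - 1L) * pd[1] + (k - 1L) * pd[1] * pd[2]

level_convs <- function(l, depth) {
  if (l == depth) c("a", "b", "c", "d") else c("a", "b")
}

# execution plan for a given batch size: padded layouts, shift tables,
# core/pad row indices and pool/upsample maps for every resolution level
build_plan <- function(cfg, batch) {
  depth <- cfg$depth
  levels <- vector("list", depth)
  ld <- cfg$workdims
  for (l in seq_len(depth)) {
    pd <- ld + 2L
    nvp <- prod(pd)
    off <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
    shifts <- as.integer(off[, 1] + off[, 2] * pd[1] + off[, 3] * pd[1] * pd[2])
    maxoff <- max(shifts)
    N <- batch * nvp
    core1 <- as.integer(lin3(
      rep(2:(ld[1] + 1L), times = ld[2] * ld[3]),
      rep(rep(2:(ld[2] + 1L), each = ld[1]), times = ld[3]),
      rep(2:(ld[3] + 1L), each = ld[1] * ld[2]), pd))
    core <- as.integer(outer(core1, (seq_len(batch) - 1L) * nvp, `+`))
    iscore <- logical(N); iscore[core] <- TRUE
    levels[[l]] <- list(dims = ld, pd = pd, nvp = nvp, N = N,
                        shifts = shifts, lo = maxoff + 1L, hi = N - maxoff,
                        core = core, iscore = iscore)
    ld <- ld %/% 2L
  }
  # pool maps: children (level l) of each level-(l+1) core voxel
  pool <- vector("list", depth)
  if (depth > 1) for (l in seq_len(depth - 1L)) {
    cd <- levels[[l + 1]]$dims
    pdf <- levels[[l]]$pd
    ic <- rep(seq_len(cd[1]), times = cd[2] * cd[3])
    jc <- rep(rep(seq_len(cd[2]), each = cd[1]), times = cd[3])
    kc <- rep(seq_len(cd[3]), each = cd[1] * cd[2])
    ch <- vector("list", 8L)
    q <- 0L
    for (c3 in 0:1) for (c2 in 0:1) for (c1 in 0:1) {
      q <- q + 1L
      lin <- lin3(2L * ic - 1L + c1 + 1L, 2L * jc - 1L + c2 + 1L,
                  2L * kc - 1L + c3 + 1L, pdf)
      ch[[q]] <- as.integer(outer(lin, (seq_len(batch) - 1L) * levels[[l]]$nvp,
                                  `+`))
    }
    pool[[l]] <- ch
  }
  # placement of original (possibly non-divisible) volumes in the level-1
  # work layout, centered
  od <- cfg$dims
  sh <- (cfg$workdims - od) %/% 2L
  pd1 <- levels[[1]]$pd
  i0 <- rep(seq_len(od[1]), times = od[2] * od[3])
  j0 <- rep(rep(seq_len(od[2]), each = od[1]), times = od[3])
  k0 <- rep(seq_len(od[3]), each = od[1] * od[2])
  in1 <- lin3(i0 + sh[1] + 1L, j0 + sh[2] + 1L, k0 + sh[3] + 1L, pd1)
  input_rows <- as.integer(outer(in1, (seq_len(batch) - 1L) * levels[[1]]$nvp,
                                 `+`))
  list(batch = batch, levels = levels, pool = pool, input_rows = input_rows,
       nvox = prod(od))
}

he_init <- function(cin, cout, k = 27L) {
  array(stats::rnorm(cin * cout * k, 0, sqrt(2 / (k * cin))),
        dim = c(cin, cout, k))
}

#' Build the denoising network
#'
#' Initializes weights (He-normal) for the architecture described in
#' [net_config()]. The final convolution is zero-initialized, so a freshly
#' built network maps any volume to itself through the global residual
#' path.
#'
#' @param cfg A [net_config()].
#' @param seed RNG seed for weight initialization.
#' @return Object of class `denoise_net`: `cfg`, `params` (named list of
#'   `W`/`b`), and a plan cache. `n_parameters` attribute reports the size.
#' @export
build_network <- function(cfg, seed = 1L) {
  stopifnot(inherits(cfg, "net_config"))
  set.seed(seed)
  ch <- cfg$channels; depth <- cfg$depth
  params <- list()
  cin <- 1L
  for (l in seq_len(depth)) {
    # two convs per level; the bottleneck level gets two more, which widens
    # the receptive field cheaply (1/2^(3(depth-1)) of the fine-level cost)
    for (ab in level_convs(l, depth)) {
      params[[paste0("enc", l, ab)]] <- list(W = he_init(cin, ch[l]),
                                             b = numeric(ch[l]))
      cin <- ch[l]
    }
  }
  if (depth > 1) for (l in seq(depth - 1L, 1L)) {
    # channel-mixing 1x1x1 projection after nearest-neighbor upsampling
    params[[paste0("up", l)]] <- list(W = he_init(ch[l + 1], ch[l], k = 1L),
                                      b = numeric(ch[l]))
    params[[paste0("dec", l)]] <- list(W = he_init(2L * ch[l], ch[l]),
                                       b = numeric(ch[l]))
  }
  params[["final"]] <- list(W = array(0, c(ch[1], 1L, 27L)), b = numeric(1L))
  net <- structure(list(cfg = cfg, params = params,
                        plans = new.env(parent = emptyenv())),
                   class = "denoise_net")
  attr(net, "n_parameters") <- sum(vapply(params, function(p)
    length(p$W) + length(p$b), numeric(1)))
  net
}

#' @export
print.denoise_net <- function(x, ...) {
  cat(sprintf("Residual 3D encoder-decoder: depth %d, channels (%s), %d parameters\n",
              x$cfg$depth, paste(x$cfg$channels, collapse = ", "),
              attr(x, "n_parameters")))
  invisible(x)
}

get_plan <- function(net, batch) {
  key <- as.character(batch)
  if (is.null(net$plans[[key]]))
    net$plans[[key]] <- build_plan(net$cfg, batch)
  net$plans[[key]]
}

conv_fwd <- function(X, par, lev, relu = TRUE) {
  sh <- if (dim(par$W)[3] == 1L) 0L else lev$shifts
  .Call(C_conv_fwd, X, par$W, par$b, sh, lev$lo, lev$hi,
        lev$iscore, as.integer(relu))
}

# forward pass; when keep = TRUE returns all intermediates for backprop
net_forward <- function(net, xcore, plan, keep = FALSE) {
  depth <- net$cfg$depth
  L <- plan$levels
  P <- net$params
  X1 <- matrix(0, L[[1]]$N, 1L)
  X1[plan$input_rows, 1L] <- xcore
  cache <- if (keep) list(X1 = X1) else NULL
  h <- X1
  enc <- vector("list", depth)
  pre <- list()   # inputs and relu masks per conv layer
  for (l in seq_len(depth)) {
    if (l > 1L) {                    # average pool from level l-1
      ch <- plan$pool[[l - 1L]]
      acc <- h[ch[[1]], , drop = FALSE]
      for (q in 2:8) acc <- acc + h[ch[[q]], , drop = FALSE]
      hp <- matrix(0, L[[l]]$N, ncol(h))
      hp[L[[l]]$core, ] <- acc[] / 8
      h <- hp
    }
    for (ab in level_convs(l, depth)) {
      nm <- paste0("enc", l, ab)
      z <- conv_fwd(h, P[[nm]], L[[l]])
      if (keep) pre[[nm]] <- list(x = h, y = z)
      h <- z
    }
    enc[[l]] <- h
  }
  d <- enc[[depth]]
  if (depth > 1L) for (l in seq(depth - 1L, 1L)) {
    ch <- plan$pool[[l]]
    u <- matrix(0, L[[l]]$N, ncol(d))
    dc <- d[L[[l + 1L]]$core, , drop = FALSE]
    for (q in 1:8) u[ch[[q]], ] <- dc
    nm <- paste0("up", l)
    z <- conv_fwd(u, P[[nm]], L[[l]])
    if (keep) pre[[nm]] <- list(x = u, y = z)
    uo <- z
    cat_ <- cbind(enc[[l]], uo)
    nm <- paste0("dec", l)
    z <- conv_fwd(cat_, P[[nm]], L[[l]])
    if (keep) pre[[nm]] <- list(x = cat_, y = z)
    d <- z
  }
  z <- conv_fwd(d, P[["final"]], L[[1]], relu = FALSE)
  if (keep) pre[["final"]] <- list(x = d, y = NULL)
  out <- z[plan$input_rows, 1L] + xcore   # global residual
  if (keep) list(out = out, pre = pre, enc = enc, cache = cache)
  else list(out = out)
}

# backward pass: returns gradients for every parameter
net_backward <- function(net, fwd, gout, plan) {
  depth <- net$cfg$depth
  L <- plan$levels
  P <- net$params
  grads <- list()
  conv_bwd <- function(nm, dZ, lev, want_dx = TRUE) {
    pr <- fwd$pre[[nm]]
    relu <- !is.null(pr$y)
    sh <- if (dim(P[[nm]]$W)[3] == 1L) 0L else lev$shifts
    res <- .Call(C_conv_bwd, pr$x, dZ, if (relu) pr$y else dZ, P[[nm]]$W,
                 sh, lev$lo, lev$hi, lev$iscore, as.integer(relu),
                 as.integer(want_dx))
    grads[[nm]] <<- list(W = res$gW, b = res$gb)
    res$dX
  }
  dOut <- matrix(0, L[[1]]$N, 1L)
  dOut[plan$input_rows, 1L] <- gout
  # decoder backward: forward ran l = depth-1 .. 1, so reverse l = 1 .. depth-1;
  # `dd` is the gradient w.r.t. the decoder state d_l entering stage l
  dd <- conv_bwd("final", dOut, L[[1]])
  denc <- vector("list", depth)      # gradients into the skip (enc) outputs
  if (depth > 1L) {
    for (l in seq_len(depth - 1L)) {
      dcat <- conv_bwd(paste0("dec", l), dd, L[[l]])
      c1 <- ncol(fwd$enc[[l]])
      denc[[l]] <- dcat[, seq_len(c1), drop = FALSE]
      duo <- dcat[, -seq_len(c1), drop = FALSE]
      du <- conv_bwd(paste0("up", l), duo, L[[l]])
      # nearest-upsample backward: sum the 8 children into the coarse core
      ch <- plan$pool[[l]]
      acc <- du[ch[[1]], , drop = FALSE]
      for (q in 2:8) acc <- acc + du[ch[[q]], , drop = FALSE]
      dd <- matrix(0, L[[l + 1L]]$N, ncol(du))
      dd[L[[l + 1L]]$core, ] <- acc[]
    }
    denc[[depth]] <- dd              # d_depth = enc[[depth]]
  } else {
    denc[[1]] <- dd
  }
  # encoder backward, deepest level first; skip gradients join after each
  # pool backward
  dh <- denc[[depth]]
  for (l in seq(depth, 1L)) {
    if (l < depth) dh <- dh + denc[[l]]
    for (ab in rev(level_convs(l, depth))) {
      nm <- paste0("enc", l, ab)
      dh <- conv_bwd(nm, dh, L[[l]], want_dx = !(l == 1L && ab == "a"))
    }
    if (l > 1L) {                     # average-pool backward
      ch <- plan$pool[[l - 1L]]
      dcore <- dh[L[[l]]$core, , drop = FALSE] / 8
      dfine <- matrix(0, L[[l - 1L]]$N, ncol(dh))
      for (q in 1:8) dfine[ch[[q]], ] <- dcore
      dh <- dfine
    }
  }
  grads
}

adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(params)) {
    for (slot in c("W", "b")) {
      g <- grads[[nm]][[slot]]
      state$m[[nm]][[slot]] <- beta1 * state$m[[nm]][[slot]] + (1 - beta1) * g
      state$v[[nm]][[slot]] <- beta2 * state$v[[nm]][[slot]] + (1 - beta2) * g^2
      mhat <- state$m[[nm]][[slot]] / (1 - beta1^t)
      vhat <- state$v[[nm]][[slot]] / (1 - beta2^t)
      params[[nm]][[slot]] <- params[[nm]][[slot]] -
        lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = state)
}

#' Early-stopping rule
#'
#' Given per-epoch validation losses and a patience, returns the epoch at
#' which training stops (the first epoch after which the best validation
#' loss has not improved for `patience` consecutive epochs, or the last
#' epoch) and the best epoch.
#'
#' @param val_losses Numeric vector of validation losses per epoch.
#' @param patience Consecutive non-improving epochs tolerated.
#' @return List `stop_epoch`, `best_epoch`.
#' @export
early_stop_epoch <- function(val_losses, patience) {
  best <- Inf; best_ep <- 0L; streak <- 0L
  for (e in seq_along(val_losses)) {
    if (val_losses[e] < best) {
      best <- val_losses[e]; best_ep <- e; streak <- 0L
    } else {
      streak <- streak + 1L
      if (streak >= patience) return(list(stop_epoch = e, best_epoch = best_ep))
    }
  }
  list(stop_epoch = length(val_losses), best_epoch = best_ep)
}

# stack a list of volumes (arrays or core vectors) into a batch core vector
as_core_vec <- function(v) if (is.array(v)) as.vector(v) else v

#' Train the denoising network
#'
#' Optimizes the masked sum-of-squares loss with Adam, evaluating the
#' validation loss after every epoch; stops at `max_epochs` or when the
#' validation loss has not decreased for `patience` consecutive epochs, and
#' restores the best-validation weights.
#'
#' @param net A [build_network()] model.
#' @param inputs,targets Lists of volumes (arrays matching `cfg$dims`),
#'   already std-normalized.
#' @param mask Logical cylinder-mask array (loss support).
#' @param train_idx,val_idx Integer indices into `inputs`.
#' @param cfg A [train_config()].
#' @param verbose Print per-epoch losses.
#' @return List: `net` (trained, best-validation weights), `history`
#'   (data.frame epoch/train_loss/val_loss), `stop_epoch`, `best_epoch`.
#' @export
train_denoiser <- function(net, inputs, targets, mask, train_idx, val_idx,
                           cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(net, "denoise_net"), inherits(cfg, "train_config"))
  set.seed(cfg$seed)
  maskv <- as.vector(mask)
  n_tr <- length(train_idx)
  B <- min(cfg$batch_size, n_tr)
  state <- list(
    m = lapply(net$params, function(p) list(W = array(0, dim(p$W)),
                                            b = numeric(length(p$b)))),
    v = lapply(net$params, function(p) list(W = array(0, dim(p$W)),
                                            b = numeric(length(p$b)))))
  nvox <- prod(net$cfg$dims)
  batch_loss <- function(idx, update, t0) {
    plan <- get_plan(net, length(idx))
    x <- unlist(lapply(inputs[idx], as_core_vec), use.names = FALSE)
    y <- unlist(lapply(targets[idx], as_core_vec), use.names = FALSE)
    mrep <- rep(maskv, length(idx))
    fwd <- net_forward(net, x, plan, keep = update)
    r <- (fwd$out - y) * mrep
    loss <- sum(r * r)
    if (update) {
      grads <- net_backward(net, fwd, 2 * r, plan)
      st <- adam_step(net$params, grads, state, cfg$lr, t0)
      net$params <<- st$params
      state <<- st$state
    }
    loss
  }
  eval_split <- function(idx) {
    tot <- 0
    for (b in split(idx, ceiling(seq_along(idx) / B)))
      tot <- tot + batch_loss(b, update = FALSE, t0 = 0)
    tot / length(idx)
  }
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best_val <- Inf; best_params <- net$params; best_ep <- 0L; streak <- 0L
  t_adam <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    ord <- sample(train_idx)
    tot <- 0
    for (b in split(ord, ceiling(seq_along(ord) / B))) {
      t_adam <- t_adam + 1L
      tot <- tot + batch_loss(b, update = TRUE, t0 = t_adam)
    }
    tr_loss <- tot / n_tr
    if (!is.finite(tr_loss)) {
      warning("training diverged (non-finite loss); aborting with history")
      break
    }
    val_loss <- if (length(val_idx)) eval_split(val_idx) else tr_loss
    history <- rbind(history, data.frame(epoch = epoch, train_loss = tr_loss,
                                         val_loss = val_loss))
    if (verbose)
      message(sprintf("epoch %3d  train %.5g  val %.5g", epoch, tr_loss,
                      val_loss))
    if (val_loss < best_val) {
      best_val <- val_loss; best_params <- net$params; best_ep <- epoch
      streak <- 0L
    } else {
      streak <- streak + 1L
      if (streak >= cfg$patience) break
    }
  }
  net$params <- best_params
  list(net = net, history = history, stop_epoch = nrow(history),
       best_epoch = best_ep)
}

#' Apply the denoiser to one or more volumes
#'
#' Single forward pass; voxels outside the cylinder mask are zeroed on
#' output.
#'
#' @param net A trained `denoise_net`.
#' @param volume A std-normalized array (matching the configured dims), a
#'   `recon_volume`, or a list of either.
#' @param mask Logical cylinder mask (taken from the volume's grid when a
#'   `recon_volume` is given).
#' @return Array (or `recon_volume`, or list) of enhanced volumes.
#' @export
denoise <- function(net, volume, mask = NULL) {
  if (is.list(volume) && !inherits(volume, "recon_volume"))
    return(lapply(volume, function(v) denoise(net, v, mask)))
  if (inherits(volume, "recon_volume")) {
    if (!volume$normalized)
      stop("volume must be std-normalized before denoising")
    out <- denoise(net, volume$values, volume$grid$mask)
    return(recon_volume(out, volume$grid, normalized = TRUE))
  }
  if (!all(dim(volume) == net$cfg$dims)) stop("volume shape mismatch")
  if (is.null(mask)) mask <- array(TRUE, dim(volume))
  plan <- get_plan(net, 1L)
  fwd <- net_forward(net, as.vector(volume), plan, keep = FALSE)
  out <- array(fwd$out, dim(volume))
  out[!mask] <- 0
  out
}

#' Save / load network weights as JSON sidecar text
#'
#' Checkpoints are plain JSON (configuration + flattened weights), portable
#' and diffable.
#' @param net A `denoise_net`.
#' @param path Output path.
#' @return `path` invisibly (`save`); the restored network (`load`).
#' @export
save_network_json <- function(net, path) {
  obj <- list(cfg = unclass(net$cfg),
              params = lapply(net$params, function(p)
                list(W = as.vector(p$W), dimW = dim(p$W), b = p$b)))
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_network_json
#' @export
load_network_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- net_config(obj$cfg$dims, obj$cfg$depth, obj$cfg$channels)
  net <- build_network(cfg)
  for (nm in names(net$params)) {
    net$params[[nm]]$W <- array(as.numeric(obj$params[[nm]]$W),
                                obj$params[[nm]]$dimW)
    net$params[[nm]]$b <- as.numeric(obj$params[[nm]]$b)
  }
  net
}
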