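# 3D U-Net attention network. Feature maps are (channels x voxels) matrices
# (voxels flattened x-fastest); convolutions, instance norm, pooling and
# upsampling are the compiled kernels in src/ops.cpp. The forward pass keeps
# the per-layer activations needed for the hand-written backward pass.

.IN_EPS <- 1e-5

#' Attention network configuration
#'
#' Architecture and output hyperparameters of the 3D U-Net that maps a
#' stacked (fixed, moving) image pair to shrink/expand/background maps.
#' Depth and width are free hyperparameters sized for desk-scale volumes;
#' the SoftMax temperature `tau` makes the output maps near-binary (with
#' `tau = 100`, a pre-SoftMax logit gap of 0.06 already gives the winning
#' channel probability >= 0.995).
#'
#' @param depth number of resolution levels (each level beyond the first
#'   halves the grid; input extents must be divisible by `2^(depth-1)`,
#'   other extents are zero-padded internally).
#' @param base_channels feature channels at the finest level; doubled per
#'   level.
#' @param tau SoftMax temperature applied as `logits * tau`.
#' @param seed integer seed for weight initialization.
#' @return list of class `attention_net_config`.
#' @export
attention_net_config <- function(depth = 3, base_channels = 8, tau = 100,
                                 seed = 42) {
  stopifnot(depth >= 1, base_channels >= 1, tau > 0)
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 in_channels = 2L, out_channels = 3L,
                 tau = tau, seed = as.integer(seed)),
            class = "attention_net_config")
}

conv_param_names <- function(prefix) {
  c(paste0(prefix, c(".conv1.W", ".conv1.b", ".in1.gamma", ".in1.beta",
                     ".conv2.W", ".conv2.b", ".in2.gamma", ".in2.beta")))
}

init_conv <- function(cin, cout) {
  W <- matrix(stats::rnorm(cout * cin * 27, sd = sqrt(2 / (cin * 27))),
              nrow = cout)
  list(W = W, b = rep(0, cout))
}

init_block <- function(params, prefix, cin, cout) {
  for (i in 1:2) {
    cv <- init_conv(if (i == 1) cin else cout, cout)
    params[[paste0(prefix, ".conv", i, ".W")]] <- cv$W
    params[[paste0(prefix, ".conv", i, ".b")]] <- cv$b
    params[[paste0(prefix, ".in", i, ".gamma")]] <- rep(1, cout)
    params[[paste0(prefix, ".in", i, ".beta")]] <- rep(0, cout)
  }
  params
}

#' Initialize an attention network
#'
#' He-initialized convolution weights, unit instance-norm gains, and a
#' small-variance head so initial logits are near zero (maximally soft
#' attention). Deterministic given `config$seed`.
#'
#' @param config an [attention_net_config()].
#' @return list of class `attention_net` with elements `params`, `config`.
#' @export
init_attention_net <- function(config) {
  ch <- config$base_channels * 2^(seq_len(config$depth) - 1L)
  params <- local_seed(config$seed, {
    p <- list()
    for (l in seq_len(config$depth)) {
      cin <- if (l == 1L) config$in_channels else ch[l - 1L]
      p <- init_block(p, paste0("enc", l), cin, ch[l])
    }
    for (l in rev(seq_len(config$depth - 1L)))
      p <- init_block(p, paste0("dec", l), ch[l + 1L] + ch[l], ch[l])
    hw <- matrix(stats::rnorm(config$out_channels * ch[1], sd = 0.01),
                 nrow = config$out_channels)
    p[["head.W"]] <- hw
    p[["head.b"]] <- rep(0, config$out_channels)
    p
  })
  structure(list(params = params, config = config), class = "attention_net")
}

#' @export
print.attention_net <- function(x, ...) {
  np <- sum(vapply(x$params, length, 1))
  cat(sprintf("attention_net: depth %d, base %d channels, tau %g, %d parameters\n",
              x$config$depth, x$config$base_channels, x$config$tau, np))
  invisible(x)
}

block_forward <- function(params, prefix, x, dims) {
  cache <- list(x = x, dims = dims)
  h <- x
  for (i in 1:2) {
    W <- params[[paste0(prefix, ".conv", i, ".W")]]
    b <- params[[paste0(prefix, ".conv", i, ".b")]]
    g <- params[[paste0(prefix, ".in", i, ".gamma")]]
    be <- params[[paste0(prefix, ".in", i, ".beta")]]
    cache[[paste0("cin", i)]] <- h
    cv <- .conv3d_fwd(h, W, b, dims[1], dims[2], dims[3])
    nm <- .instnorm_fwd(cv, g, be, .IN_EPS)
    cache[[paste0("xhat", i)]] <- nm$xhat
    cache[[paste0("invstd", i)]] <- nm$invstd
    h <- nm$y * (nm$y > 0)
    cache[[paste0("r", i)]] <- h
  }
  list(out = h, cache = cache)
}

block_backward <- function(params, prefix, cache, gout, grads) {
  dims <- cache$dims
  g <- gout
  for (i in 2:1) {
    g <- g * (cache[[paste0("r", i)]] > 0)
    gam <- params[[paste0(prefix, ".in", i, ".gamma")]]
    nb <- .instnorm_bwd(g, cache[[paste0("xhat", i)]],
                        cache[[paste0("invstd", i)]], gam)
    grads[[paste0(prefix, ".in", i, ".gamma")]] <-
      grads[[paste0(prefix, ".in", i, ".gamma")]] + nb$dgamma
    grads[[paste0(prefix, ".in", i, ".beta")]] <-
      grads[[paste0(prefix, ".in", i, ".beta")]] + nb$dbeta
    W <- params[[paste0(prefix, ".conv", i, ".W")]]
    cb <- .conv3d_bwd(cache[[paste0("cin", i)]], W, nb$dx,
                      dims[1], dims[2], dims[3])
    grads[[paste0(prefix, ".conv", i, ".W")]] <-
      grads[[paste0(prefix, ".conv", i, ".W")]] + cb$dW
    grads[[paste0(prefix, ".conv", i, ".b")]] <-
      grads[[paste0(prefix, ".conv", i, ".b")]] + as.numeric(cb$db)
    g <- cb$dx
  }
  list(dx = g, grads = grads)
}

# core forward on an already-stacked (2 x N) input; dims must be divisible
# by 2^(depth-1)
unet_forward <- function(net, x, dims) {
  cfg <- net$config
  p <- net$params
  enc <- vector("list", cfg$depth)
  dims_l <- vector("list", cfg$depth)
  h <- x
  d <- dims
  for (l in seq_len(cfg$depth)) {
    bf <- block_forward(p, paste0("enc", l), h, d)
    enc[[l]] <- bf
    dims_l[[l]] <- d
    if (l < cfg$depth) {
      h <- .avgpool2_fwd(bf$out, d[1], d[2], d[3])
      d <- d %/% 2L
    }
  }
  cur <- enc[[cfg$depth]]$out
  dec <- vector("list", cfg$depth)
  for (l in rev(seq_len(cfg$depth - 1L))) {
    dl <- dims_l[[l]]
    up <- .upsample2_fwd(cur, dl[1] %/% 2L, dl[2] %/% 2L, dl[3] %/% 2L)
    cat_in <- rbind(up, enc[[l]]$out)
    bf <- block_forward(p, paste0("dec", l), cat_in, dl)
    dec[[l]] <- bf
    cur <- bf$out
  }
  logits <- p[["head.W"]] %*% cur + p[["head.b"]]
  list(logits = logits, head_in = cur, enc = enc, dec = dec,
       dims_l = dims_l)
}

unet_backward <- function(net, fw, g_logits) {
  cfg <- net$config
  p <- net$params
  grads <- lapply(p, function(z) z * 0)
  grads[["head.W"]] <- g_logits %*% t(fw$head_in)
  grads[["head.b"]] <- rowSums(g_logits)
  g <- t(p[["head.W"]]) %*% g_logits
  for (l in seq_len(cfg$depth - 1L)) {
    bb <- block_backward(p, paste0("dec", l), fw$dec[[l]]$cache, g, grads)
    grads <- bb$grads
    dl <- fw$dims_l[[l]]
    cu <- nrow(fw$dec[[l]]$cache$x) - nrow(fw$enc[[l]]$out)
    g_up <- bb$dx[seq_len(cu), , drop = FALSE]
    g_skip <- bb$dx[-seq_len(cu), , drop = FALSE]
    g_coarse <- .upsample2_bwd(g_up, dl[1] %/% 2L, dl[2] %/% 2L, dl[3] %/% 2L)
    bb2 <- block_backward(p, paste0("enc", l), fw$enc[[l]]$cache, g_skip, grads)
    grads <- bb2$grads
    # gradient flowing to the pooled encoder path continues upward through
    # the deeper levels; accumulate after their own backward below
    fw$enc[[l]]$g_input <- bb2$dx
    fw$enc[[l]]$g_coarse <- g_coarse
    g <- g_coarse
  }
  # deepest encoder block
  bbL <- block_backward(p, paste0("enc", cfg$depth),
                        fw$enc[[cfg$depth]]$cache, g, grads)
  grads <- bbL$grads
  g <- bbL$dx
  for (l in rev(seq_len(cfg$depth - 1L))) {
    dl <- fw$dims_l[[l]]
    g_pool <- .avgpool2_bwd(g, dl[1], dl[2], dl[3])
    # total gradient into enc block l output = skip path (already done) +
    # pooled path; redo block backward on the pooled contribution
    bb <- block_backward(p, paste0("enc", l), fw$enc[[l]]$cache, g_pool, grads)
    grads <- bb$grads
    g <- bb$dx + fw$enc[[l]]$g_input
  }
  list(grads = grads, dx = g)
}
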