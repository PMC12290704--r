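# User-facing attention model interface: normalization, padding to a
# pool-able extent, temperature SoftMax, checkpoints.

zscore_volume <- function(vol) {
  v <- vol$values
  s <- stats::sd(v)
  if (s == 0) s <- 1
  scalar_volume((v - mean(v)) / s, vol$grid)
}

# temperature softmax over the rows of a (3 x N) logit matrix
softmax_temp <- function(logits, tau) {
  z <- logits * tau
  zmax <- pmax(z[1, ], z[2, ], z[3, ])
  e <- exp(sweep(z, 2, zmax, "-"))
  sweep(e, 2, colSums(e), "/")
}

# d(loss)/d(logits) given d(loss)/d(probs) and the probs, through the
# temperature softmax
softmax_temp_backward <- function(gprobs, probs, tau) {
  dot <- colSums(gprobs * probs)
  tau * probs * sweep(gprobs, 2, dot, "-")
}

pad_multiple <- function(dims, k) as.integer(ceiling(dims / k) * k)

#' Run the attention network on an image pair
#'
#' Stacks the (optionally z-scored) fixed and moving volumes, runs the
#' U-Net, and applies the temperature SoftMax, yielding near-binary
#' shrink/expand/background maps on the input grid. Extents not divisible
#' by `2^(depth-1)` are zero-padded internally and the output cropped back.
#'
#' @param net an `attention_net` (see [init_attention_net()]).
#' @param fixed,moving [scalar_volume()] objects on one grid.
#' @param normalize z-score each volume before stacking (default TRUE; set
#'   FALSE when inputs are already normalized, e.g. by [augment_pair()]).
#' @param want_cache keep intermediate activations for backprop (training).
#' @return an [attention_maps()] object; with `want_cache = TRUE`, a list
#'   `(att, fw, x, dims)` for use by the training loop.
#' @export
attention_forward <- function(net, fixed, moving, normalize = TRUE,
                              want_cache = FALSE) {
  stop_if_grid_mismatch(fixed$grid, moving$grid, "fixed and moving volumes")
  if (normalize) {
    fixed <- zscore_volume(fixed)
    moving <- zscore_volume(moving)
  }
  grid <- fixed$grid
  dims <- grid$shape
  k <- 2L^(net$config$depth - 1L)
  pdims <- pad_multiple(dims, k)
  fa <- fixed$values
  ma <- moving$values
  if (!all(pdims == dims)) {
    fp <- array(0, pdims); mp <- array(0, pdims)
    fp[seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3])] <- fa
    mp[seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3])] <- ma
    fa <- fp; ma <- mp
  }
  x <- rbind(as.numeric(fa), as.numeric(ma))
  fw <- unet_forward(net, x, pdims)
  probs <- softmax_temp(fw$logits, net$config$tau)
  ch <- array(0, c(dims, 3L))
  keep <- NULL
  if (!all(pdims == dims)) {
    keep <- as.numeric(array(seq_len(prod(pdims)), pdims)[
      seq_len(dims[1]), seq_len(dims[2]), seq_len(dims[3])])
  }
  for (c3 in 1:3) {
    pc <- probs[c3, ]
    if (!is.null(keep)) pc <- pc[keep]
    ch[, , , c3] <- pc
  }
  att <- attention_maps(ch, grid, check = FALSE)
  if (!want_cache) return(att)
  list(att = att, fw = fw, probs = probs, dims = pdims, grid_dims = dims,
       keep = keep)
}

# backward from d(loss)/d(probs) on the unpadded grid (3 x N_unpadded)
attention_backward <- function(net, cache, gprobs_unpadded) {
  npad <- ncol(cache$probs)
  if (!is.null(cache$keep)) {
    gp <- matrix(0, 3, npad)
    gp[, cache$keep] <- gprobs_unpadded
  } else gp <- gprobs_unpadded
  glogits <- softmax_temp_backward(gp, cache$probs, net$config$tau)
  unet_backward(net, cache$fw, glogits)$grads
}

#' Save / load a model checkpoint
#'
#' Serializes network weights with the configuration (and an optional
#' training log) embedded.
#'
#' @param net an `attention_net`.
#' @param path file path (`.rds`).
#' @param log optional training log to embed.
#' @return `path` invisibly / the restored `attention_net`.
#' @export
save_checkpoint <- function(net, path, log = NULL) {
  saveRDS(list(params = net$params, config = net$config, log = log), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  net <- structure(list(params = obj$params, config = obj$config),
                   class = "attention_net")
  attr(net, "log") <- obj$log
  net
}
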