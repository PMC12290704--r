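# Two-branch training of the attention network. Both branches share one
# parameter store (a single weight list); per step the two pairs of a
# quadruple are forwarded, the STO losses of both branches and the RISI
# loss of the branch pair are combined, and gradients from both branches
# accumulate into the shared parameters.

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Training configuration
#'
#' @param epochs training epochs.
#' @param lr Adam learning rate.
#' @param batch_size quadruples per optimizer step.
#' @param quad_cap maximum quadruples sampled per subject per epoch.
#' @param weights a [loss_weights()]; `w_risi = 0` gives the STO-only
#'   ablation.
#' @param bins a [risi_bins()].
#' @param alpha logit/sigmoid scale applied to fractional volume changes in
#'   both losses.
#' @param augment an [augment_config()].
#' @param qc_threshold SSIM threshold below which a subject's scan pairs
#'   are excluded from training (NULL disables QC).
#' @param seed seed controlling sampling and augmentation.
#' @return list of class `train_config`.
#' @export
train_config <- function(epochs = 10, lr = 1e-5, batch_size = 4,
                         quad_cap = 25, weights = loss_weights(),
                         bins = risi_bins(), alpha = 50,
                         augment = augment_config(), qc_threshold = 0.6,
                         seed = 1L) {
  structure(list(epochs = as.integer(epochs), lr = lr,
                 batch_size = as.integer(batch_size),
                 quad_cap = as.integer(quad_cap), weights = weights,
                 bins = bins, alpha = alpha, augment = augment,
                 qc_threshold = qc_threshold, seed = as.integer(seed)),
            class = "train_config")
}

# forward one (augmented) pair and return the quantities needed for the
# losses plus the backprop closure inputs
branch_forward <- function(net, pair) {
  fwd <- attention_forward(net, pair$fixed, pair$moving, normalize = FALSE,
                           want_cache = TRUE)
  jac <- jacobian_determinant(pair$field)
  dv <- voxel_volume(pair$field$grid)
  wmap <- as.numeric(jac$det - 1) * dv
  s_shr <- as.numeric(attention_channel(fwd$att, "shrink"))
  s_exp <- as.numeric(attention_channel(fwd$att, "expand"))
  a_shr <- sum(s_shr * wmap)
  a_exp <- sum(s_exp * wmap)
  v_base <- (sum(s_shr) + sum(s_exp)) * dv
  vb <- v_base + dv  # one-voxel epsilon guards an empty attention region
  list(cache = fwd, wmap = wmap, a_shr = a_shr, a_exp = a_exp,
       v_base = v_base, vb = vb, dv = dv,
       an_shr = a_shr / vb, an_exp = a_exp / vb)
}

# gradient of the loss w.r.t. the attention probabilities of one branch,
# given d(loss)/d(normalized changes). v_base is part of the graph: adding
# attention to uninformative voxels dilutes the fractional change and is
# penalized, which is what drives the maps to concentrate on regions of
# systematic change.
branch_gprobs <- function(br, d_an_shr, d_an_exp, dv) {
  n <- length(br$wmap)
  gp <- matrix(0, 3, n)
  common <- -(d_an_shr * br$an_shr + d_an_exp * br$an_exp) * dv / br$vb
  gp[1, ] <- (d_an_shr / br$vb) * br$wmap + common
  gp[2, ] <- (d_an_exp / br$vb) * br$wmap + common
  gp
}

#' Train the attention network on a phantom cohort
#'
#' Enumerates nested quadruples per training subject, optionally drops
#' SSIM-failing scan pairs, and optimizes the shared-weight two-branch
#' model with Adam. Per quadruple, both pairs are augmented independently
#' (the two scans and the field of one pair always share a transform),
#' forwarded through the same parameter store, and the weighted STO + RISI
#' loss is backpropagated.
#'
#' @param cohort an `rda_cohort` (see [generate_cohort()]).
#' @param subjects indices of training subjects (default all).
#' @param net_config an [attention_net_config()].
#' @param config a [train_config()].
#' @param verbose print per-epoch loss means.
#' @return list of class `rda_fit`: `net` (trained `attention_net`), `log`
#'   (per-step data.frame of STO/RISI/total losses), `subjects`, `qc_log`.
#' @export
train_rda <- function(cohort, subjects = seq_along(cohort$subjects),
                      net_config = attention_net_config(),
                      config = train_config(), verbose = FALSE) {
  net <- init_attention_net(net_config)
  state <- adam_init(net$params)
  qc_log <- NULL
  excluded <- list()  # per subject, matrix of excluded (t1, t2) orderings
  if (!is.null(config$qc_threshold)) {
    # SSIM depends only on the unordered scan pair; score each once and
    # reject both orderings
    rows <- list()
    for (j in subjects) {
      sid <- cohort$subjects[[j]]$id
      ntp <- length(cohort$subjects[[j]]$times)
      scans <- lapply(seq_len(ntp), function(tp) cohort_scan(cohort, j, tp))
      for (t1 in seq_len(ntp - 1L)) for (t2 in (t1 + 1L):ntp) {
        sc <- ssim3d(scans[[t1]], scans[[t2]])
        rej <- sc < config$qc_threshold
        rows[[length(rows) + 1L]] <- data.frame(
          subject = sid, t1 = c(t1, t2), t2 = c(t2, t1), ssim = sc,
          rejected = rej)
      }
    }
    qc_log <- do.call(rbind, rows)
    bad <- qc_log[qc_log$rejected, , drop = FALSE]
    for (j in subjects) {
      sid <- cohort$subjects[[j]]$id
      excluded[[sid]] <- as.matrix(bad[bad$subject == sid, c("t1", "t2")])
    }
  }
  quads <- lapply(subjects, function(j)
    enumerate_quadruples(cohort$subjects[[j]]$times, config$bins))
  names(quads) <- as.character(subjects)
  # drop quadruples touching a QC-rejected ordered pair
  if (length(excluded)) {
    for (j in subjects) {
      sid <- cohort$subjects[[j]]$id
      ex <- excluded[[sid]]
      if (is.null(ex) || nrow(ex) == 0) next
      q <- quads[[as.character(j)]]
      bad_pair <- function(a, b) {
        any(ex[, 1] == a & ex[, 2] == b)
      }
      keep <- !mapply(function(i1, i2, i3, i4)
        bad_pair(i1, i2) || bad_pair(i3, i4),
        q$i1, q$i2, q$i3, q$i4)
      quads[[as.character(j)]] <- q[keep, , drop = FALSE]
    }
  }
  n_avail <- sum(vapply(quads, nrow, 1L))
  if (n_avail == 0L) stop("no valid training quadruples in the cohort")
  log <- list()
  local_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      sched <- list()
      for (j in subjects) {
        q <- quads[[as.character(j)]]
        if (nrow(q) == 0L) next
        take <- sample.int(nrow(q), min(config$quad_cap, nrow(q)))
        for (r in take) sched[[length(sched) + 1L]] <- list(j = j, row = q[r, ])
      }
      sched <- sched[sample.int(length(sched))]
      nb <- ceiling(length(sched) / config$batch_size)
      for (bi in seq_len(nb)) {
        items <- sched[((bi - 1L) * config$batch_size + 1L):
                         min(bi * config$batch_size, length(sched))]
        grads <- NULL
        for (it in items) {
          r <- it$row
          pA <- augment_pair(cohort_pair(cohort, it$j, r$i1, r$i2),
                             config$augment, sample.int(.Machine$integer.max, 1))
          pB <- augment_pair(cohort_pair(cohort, it$j, r$i3, r$i4),
                             config$augment, sample.int(.Machine$integer.max, 1))
          brA <- branch_forward(net, pA)
          brB <- branch_forward(net, pB)
          stoA <- sto_loss(brA$an_shr, brA$an_exp, r$y1, config$alpha, grad = TRUE)
          stoB <- sto_loss(brB$an_shr, brB$an_exp, r$y2, config$alpha, grad = TRUE)
          ris <- risi_loss(brA$an_shr, brB$an_shr, brA$an_exp, brB$an_exp,
                           r$ratio, config$bins, grad = TRUE)
          tot <- total_loss(stoA$loss, stoB$loss, ris$loss, config$weights)
          w <- config$weights
          gA <- branch_gprobs(brA,
                              w$w_sto * stoA$d_a_shr + w$w_risi * ris$d_a1_shr,
                              w$w_sto * stoA$d_a_exp + w$w_risi * ris$d_a1_exp,
                              brA$dv)
          gB <- branch_gprobs(brB,
                              w$w_sto * stoB$d_a_shr + w$w_risi * ris$d_a2_shr,
                              w$w_sto * stoB$d_a_exp + w$w_risi * ris$d_a2_exp,
                              brB$dv)
          g1 <- attention_backward(net, brA$cache, gA)
          g2 <- attention_backward(net, brB$cache, gB)
          sample_grads <- mapply(`+`, g1, g2, SIMPLIFY = FALSE)
          grads <- if (is.null(grads)) sample_grads
                   else mapply(`+`, grads, sample_grads, SIMPLIFY = FALSE)
          log[[length(log) + 1L]] <- data.frame(
            epoch = epoch, sto = stoA$loss + stoB$loss, risi = ris$loss,
            total = tot)
        }
        grads <- lapply(grads, function(g) g / length(items))
        upd <- adam_step(net$params, grads, state, config$lr)
        net$params <- upd$params
        state <- upd$state
      }
      if (verbose) {
        dl <- do.call(rbind, log)
        dl <- dl[dl$epoch == epoch, , drop = FALSE]
        message(sprintf("epoch %d: sto %.4f risi %.4f total %.4f",
                        epoch, mean(dl$sto), mean(dl$risi), mean(dl$total)))
      }
    }
  })
  structure(list(net = net, log = do.call(rbind, log), subjects = subjects,
                 qc_log = qc_log, train_config = config),
            class = "rda_fit")
}

#' @export
print.rda_fit <- function(x, ...) {
  last <- x$log[x$log$epoch == max(x$log$epoch), , drop = FALSE]
  cat(sprintf("rda_fit: %d subjects, %d epochs, final mean loss %.4f\n",
              length(x$subjects), max(x$log$epoch), mean(last$total)))
  invisible(x)
}
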