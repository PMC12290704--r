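# Self-supervised temporal losses over attention-region volume changes.
#
# Conventions: changes fed to the losses are fractional (divided by the
# fixed-image attention-region volume) so the sigmoid scale alpha is
# dimensionless. A negative shrink-region change and positive expand-region
# change correspond to the correct (forward) temporal order.

#' RISI category bins
#'
#' The relative interscan interval task classifies the absolute interval
#' ratio of two scan pairs into the four ranges `[0, 0.5]`, `(0.5, 1]`,
#' `(1, 2]` and `(2, Inf)`. `alpha` governs the softness of the sigmoid
#' decision boundaries between the categories (on fractional volume
#' changes); large `alpha` approaches hard binning.
#'
#' @param boundaries strictly increasing positive boundary ratios.
#' @param alpha sigmoid scale (> 0).
#' @return list of class `risi_bins`.
#' @export
risi_bins <- function(boundaries = c(0.5, 1, 2), alpha = 50) {
  if (any(diff(boundaries) <= 0) || any(boundaries <= 0))
    stop("boundaries must be strictly increasing and positive")
  if (alpha <= 0) stop("alpha must be > 0")
  structure(list(boundaries = as.numeric(boundaries), alpha = alpha),
            class = "risi_bins")
}

#' Loss weights
#' @param w_sto,w_risi nonnegative weights of the two loss terms.
#' @return list of class `loss_weights`.
#' @export
loss_weights <- function(w_sto = 1, w_risi = 1) {
  if (w_sto < 0 || w_risi < 0) stop("loss weights must be >= 0")
  structure(list(w_sto = w_sto, w_risi = w_risi), class = "loss_weights")
}

# cross entropy of a 2-logit vector against class index k (1-based),
# numerically stable; also returns d(loss)/d(logits)
ce2 <- function(logits, k) {
  m <- max(logits)
  lse <- m + log(sum(exp(logits - m)))
  p <- exp(logits - lse)
  grad <- p
  grad[k] <- grad[k] - 1
  list(loss = lse - logits[k], grad = grad)
}

#' Scan temporal order loss
#'
#' Cross-entropy of the logit pairs `[-a_shr, a_shr]` and `[a_exp, -a_exp]`
#' against the order label: for `y = +1` (correct order) the loss is
#' minimized by strongly negative shrink change and strongly positive
#' expand change; for `y = -1` the opposite. Zero changes give the
#' uninformative value `2 log 2`. Changes are multiplied by `alpha` before
#' the softmax.
#'
#' @param a_shr,a_exp fractional attention-region volume changes.
#' @param y order label, +1 (forward) or -1 (reversed).
#' @param alpha logit scale.
#' @param grad also return derivatives w.r.t. `a_shr`, `a_exp`.
#' @return nonnegative loss; with `grad = TRUE`, list
#'   `(loss, d_a_shr, d_a_exp)`.
#' @export
sto_loss <- function(a_shr, a_exp, y, alpha = 50, grad = FALSE) {
  if (!is.finite(a_shr) || !is.finite(a_exp)) stop("changes must be finite")
  if (!(identical(as.numeric(y), 1) || identical(as.numeric(y), -1)))
    stop("order label y must be +1 or -1")
  k <- if (y > 0) 1L else 2L  # class 1 <=> correct order
  shr <- ce2(alpha * c(-a_shr, a_shr), k)
  exp_ <- ce2(alpha * c(a_exp, -a_exp), k)
  loss <- shr$loss + exp_$loss
  if (!grad) return(loss)
  list(loss = loss,
       d_a_shr = alpha * (shr$grad[2] - shr$grad[1]),
       d_a_exp = alpha * (exp_$grad[1] - exp_$grad[2]))
}

# cone component table for 4 categories with boundary ratios (b1, b2, b3):
# each category's probability is the max over its cone components of a
# product of two sigmoids of linear forms in (a1, a2). Forms use the
# smallest-integer scaling of the boundary lines (for the defaults:
# 2a1 +/- a2, a1 +/- a2, a1 +/- 2a2).
boundary_form <- function(b) if (b < 1) c(1 / b, 1) else c(1, b)

risi_cones <- function(bins) {
  b <- bins$boundaries
  f <- lapply(b, boundary_form)  # (p, q): line p*|a1| = q*|a2|
  cones <- vector("list", 4L)
  p1 <- f[[1]][1]; q1 <- f[[1]][2]
  p2 <- f[[2]][1]; q2 <- f[[2]][2]
  p3 <- f[[3]][1]; q3 <- f[[3]][2]
  # category 1 (ratio <= b1): below line 1; one cone per sign of a2
  cones[[1]] <- list(list(c(p1, q1), c(-p1, q1)),
                     list(c(-p1, -q1), c(p1, -q1)))
  # middle categories: above the lower line and below the upper line; one
  # cone per sign quadrant
  mid <- function(pl, ql, pu, qu) {
    out <- list()
    for (s1 in c(1, -1)) for (s2 in c(1, -1))
      out[[length(out) + 1L]] <- list(c(pl * s1, -ql * s2), c(-pu * s1, qu * s2))
    out
  }
  cones[[2]] <- mid(p1, q1, p2, q2)
  cones[[3]] <- mid(p2, q2, p3, q3)
  # category 4 (ratio > b3): above line 3; one cone per sign of a1
  cones[[4]] <- list(list(c(p3, -q3), c(p3, q3)),
                     list(c(-p3, q3), c(-p3, -q3)))
  cones
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' RISI category probabilities
#'
#' Maps a pair of (fractional) volume changes for two scan pairs to soft
#' probabilities over the four interval-ratio categories. Each category is
#' a union of cone-shaped regions of the `(a1, a2)` plane bounded by the
#' lines `|a1|/|a2| = 0.5, 1, 2`; its raw score is the maximum over its
#' cones of the product of boundary sigmoids, and the four scores are
#' renormalized to sum to one. The map is continuous and invariant under
#' the simultaneous sign flip `(a1, a2) -> (-a1, -a2)`.
#'
#' @param a1,a2 volume changes of pair 1 and pair 2 (same region type).
#' @param bins a [risi_bins()].
#' @param grad also return derivatives of each probability.
#' @return numeric vector of 4 probabilities summing to 1; with
#'   `grad = TRUE`, list `(probs, d_a1, d_a2)` with the per-category
#'   derivative vectors.
#' @export
risi_category_probs <- function(a1, a2, bins = risi_bins(), grad = FALSE) {
  if (!is.finite(a1) || !is.finite(a2)) stop("changes must be finite")
  al <- bins$alpha
  cones <- risi_cones(bins)
  M <- numeric(4)
  dM1 <- numeric(4)
  dM2 <- numeric(4)
  for (k in 1:4) {
    best <- -Inf; bg1 <- 0; bg2 <- 0
    for (comp in cones[[k]]) {
      f1 <- comp[[1]]; f2 <- comp[[2]]
      s1 <- sigmoid(al * (f1[1] * a1 + f1[2] * a2))
      s2 <- sigmoid(al * (f2[1] * a1 + f2[2] * a2))
      v <- s1 * s2
      if (v > best) {
        best <- v
        if (grad) {
          g1 <- al * s1 * (1 - s1) * s2
          g2 <- al * s2 * (1 - s2) * s1
          bg1 <- g1 * f1[1] + g2 * f2[1]
          bg2 <- g1 * f1[2] + g2 * f2[2]
        }
      }
    }
    M[k] <- best
    dM1[k] <- bg1
    dM2[k] <- bg2
  }
  S <- sum(M)
  probs <- M / S
  if (!grad) return(probs)
  d_a1 <- dM1 / S - M * sum(dM1) / S^2
  d_a2 <- dM2 / S - M * sum(dM2) / S^2
  list(probs = probs, d_a1 = d_a1, d_a2 = d_a2)
}

#' Bin of a true interval ratio
#'
#' Boundary values are assigned to the lower bin (documented tie-break):
#' a ratio of exactly 1 falls in `(0.5, 1]`.
#'
#' @param ratio positive finite interval ratio.
#' @param bins a [risi_bins()].
#' @return integer bin index in 1..4.
#' @export
risi_target_bin <- function(ratio, bins = risi_bins()) {
  if (!is.finite(ratio) || ratio <= 0) stop("true_ratio must be positive and finite")
  1L + sum(ratio > bins$boundaries)
}

#' Relative interscan interval loss
#'
#' Cross-entropy of the soft category probabilities against the bin of the
#' true interval ratio, summed over the shrink and expand region types.
#'
#' @param a1_shr,a2_shr shrink-region changes of pair 1 and pair 2.
#' @param a1_exp,a2_exp expand-region changes of pair 1 and pair 2.
#' @param true_ratio `|interval of pair 1| / |interval of pair 2|`.
#' @param bins a [risi_bins()].
#' @param grad also return derivatives w.r.t. the four changes.
#' @return nonnegative loss; with `grad = TRUE`, a list with elements
#'   `loss`, `d_a1_shr`, `d_a2_shr`, `d_a1_exp`, `d_a2_exp`.
#' @export
risi_loss <- function(a1_shr, a2_shr, a1_exp, a2_exp, true_ratio,
                      bins = risi_bins(), grad = FALSE) {
  k <- risi_target_bin(true_ratio, bins)
  eps <- 1e-12
  part <- function(a1, a2) {
    r <- risi_category_probs(a1, a2, bins, grad = grad)
    if (!grad) return(list(loss = -log(r[k] + eps)))
    p <- r$probs[k]
    list(loss = -log(p + eps),
         d1 = -r$d_a1[k] / (p + eps),
         d2 = -r$d_a2[k] / (p + eps))
  }
  s <- part(a1_shr, a2_shr)
  e <- part(a1_exp, a2_exp)
  if (!grad) return(s$loss + e$loss)
  list(loss = s$loss + e$loss,
       d_a1_shr = s$d1, d_a2_shr = s$d2,
       d_a1_exp = e$d1, d_a2_exp = e$d2)
}

#' Combined training loss
#'
#' Weighted sum of the per-branch STO losses (already summed over the
#' shrink and expand terms within each branch) and the RISI loss of the
#' branch pair.
#'
#' @param sto_branch1,sto_branch2 STO losses of the two branches.
#' @param risi RISI loss of the branch pair.
#' @param weights a [loss_weights()].
#' @return scalar loss.
#' @export
total_loss <- function(sto_branch1, sto_branch2, risi,
                       weights = loss_weights()) {
  out <- weights$w_sto * (sto_branch1 + sto_branch2) + weights$w_risi * risi
  if (!is.finite(out)) stop("non-finite training loss")
  out
}
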