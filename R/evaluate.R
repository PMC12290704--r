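# Temporal-inference accuracy, rate-based group statistics, and attention
# heatmap aggregation in a common template space.

#' Run inference on one scan pair
#'
#' @param net a trained `attention_net`.
#' @param fixed,moving [scalar_volume()] objects.
#' @param field the [displacement_field()] for this ordering.
#' @param interval signed interscan interval, years.
#' @return list with the [attention_maps()] (`att`) and the `pair_change`
#'   (`change`).
#' @export
infer_pair <- function(net, fixed, moving, field, interval) {
  att <- attention_forward(net, fixed, moving, normalize = TRUE)
  list(att = att, change = pair_change(att, field, interval))
}

#' Evaluate a model over cohort subjects
#'
#' Runs inference on every ordered scan pair of the given subjects (both
#' orderings, each with its own registration direction, counted as separate
#' trials), and derives per-pair records, nested-quadruple records for the
#' relative-interval task, and per-subject annualized rates from
#' baseline-anchored forward pairs.
#'
#' @param net a trained `attention_net`.
#' @param cohort an `rda_cohort`.
#' @param subjects subject indices to evaluate (default all).
#' @param keep_attention also return the per-pair attention maps and
#'   template warps (needed for [aggregate_heatmap()]); memory scales with
#'   the number of pairs.
#' @return list of class `rda_eval`: `pair_records` (data.frame with one
#'   row per ordered pair: subject, timepoints, interval, a_shr, a_exp,
#'   a_pooled, v_base, true rate, order correctness), `quad_records`,
#'   `rates` (per-subject data.frame with estimated and true rates, age),
#'   and optionally `attention` / `warps` for baseline-anchored forward
#'   pairs.
#' @export
evaluate_cohort <- function(net, cohort, subjects = seq_along(cohort$subjects),
                            keep_attention = FALSE) {
  pair_rows <- list()
  attn <- list()
  warps <- list()
  rate_rows <- list()
  for (j in subjects) {
    s <- cohort$subjects[[j]]
    ntp <- length(s$times)
    results <- vector("list", ntp * ntp)
    for (t1 in seq_len(ntp)) for (t2 in seq_len(ntp)) {
      if (t1 == t2) next
      p <- cohort_pair(cohort, j, t1, t2)
      res <- infer_pair(net, p$fixed, p$moving, p$field, p$interval)
      results[[(t1 - 1L) * ntp + t2]] <- res
      ch <- res$change
      pair_rows[[length(pair_rows) + 1L]] <- data.frame(
        subject = s$id, t1 = t1, t2 = t2, interval = p$interval,
        a_shr = ch$a_shr, a_exp = ch$a_exp, a_pooled = ch$a_pooled,
        v_base = ch$v_base, rate = s$rate,
        correct = sign(-ch$a_pooled) == sign(p$interval))
      if (keep_attention && t1 == 1L && t2 > 1L) {
        key <- sprintf("%s_%d_%d", s$id, t1, t2)
        attn[[key]] <- res$att
        warps[[key]] <- cohort_template_warp(cohort, j, t1)
      }
    }
    changes <- lapply(2:ntp, function(t2) {
      ch <- results[[t2]]$change  # (1, t2) pairs
      ch$anchor <- 1L
      ch
    })
    rate_rows[[length(rate_rows) + 1L]] <- data.frame(
      subject = s$id, rate_est = annualized_rate(changes),
      rate_true = s$rate, age = s$age)
  }
  pair_records <- do.call(rbind, pair_rows)
  quad_rows <- list()
  for (j in subjects) {
    s <- cohort$subjects[[j]]
    q <- enumerate_quadruples(s$times)
    if (nrow(q) == 0L) next
    look <- function(i1, i2) {
      r <- pair_records[pair_records$subject == s$id &
                          pair_records$t1 == i1 & pair_records$t2 == i2, ]
      r$a_pooled[1]
    }
    for (r in seq_len(nrow(q))) {
      a1 <- look(q$i1[r], q$i2[r])
      a2 <- look(q$i3[r], q$i4[r])
      quad_rows[[length(quad_rows) + 1L]] <- data.frame(
        subject = s$id, i1 = q$i1[r], i2 = q$i2[r], i3 = q$i3[r],
        i4 = q$i4[r], ratio = q$ratio[r],
        a_pooled_1 = a1, a_pooled_2 = a2)
    }
  }
  structure(list(pair_records = pair_records,
                 quad_records = do.call(rbind, quad_rows),
                 rates = do.call(rbind, rate_rows),
                 attention = if (keep_attention) attn,
                 warps = if (keep_attention) warps),
            class = "rda_eval")
}

#' Scan temporal order accuracy
#'
#' Fraction of ordered scan pairs for which the sign of the pooled change
#' matches the true temporal order (negative pooled change for forward
#' time under this package's sign convention). Zero pooled change counts
#' as incorrect.
#'
#' @param records data.frame with columns `a_pooled` and `interval`
#'   (signed), e.g. `pair_records` from [evaluate_cohort()].
#' @param groups optional group label per record; per-group accuracies are
#'   then reported, `NA` for empty groups.
#' @return list with `overall` accuracy and optionally `by_group`.
#' @export
sto_accuracy <- function(records, groups = NULL) {
  if (nrow(records) == 0L) stop("no records")
  ok <- sign(-records$a_pooled) == sign(records$interval)
  out <- list(overall = mean(ok))
  if (!is.null(groups)) {
    lv <- unique(groups)
    out$by_group <- stats::setNames(
      vapply(lv, function(g) if (!any(groups == g)) NA_real_
             else mean(ok[groups == g]), 1), lv)
  }
  out
}

#' Relative interscan interval accuracy
#'
#' Fraction of nested quadruples for which the pair with the longer
#' interval shows the larger absolute pooled change; ties count as
#' failures.
#'
#' @param quad_records data.frame with `ratio` (interval of pair 1 over
#'   pair 2) and `a_pooled_1`, `a_pooled_2`.
#' @return accuracy in `[0, 1]`.
#' @export
risi_accuracy <- function(quad_records) {
  if (nrow(quad_records) == 0L) stop("no quadruple records")
  longer_is_1 <- quad_records$ratio > 1
  a_long <- ifelse(longer_is_1, abs(quad_records$a_pooled_1),
                   abs(quad_records$a_pooled_2))
  a_short <- ifelse(longer_is_1, abs(quad_records$a_pooled_2),
                    abs(quad_records$a_pooled_1))
  # equal-interval quadruples carry no RISI ordering information
  keep <- quad_records$ratio != 1
  mean((a_long > a_short)[keep])
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation via midranks: ties contribute 1/2. For the
#' temporal-order task the conventional score is `-a_pooled` against the
#' label "true order forward".
#'
#' @param scores numeric scores, larger = more confidently positive.
#' @param labels binary labels (logical or 0/1); both classes must occur.
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0L || n0 == 0L) stop("both classes must be present")
  r <- rank(scores)  # midranks
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Group differences in progression rates
#'
#' One-sided unpaired Wilcoxon rank-sum tests of each comparison group
#' against a reference group, with the alternative that the comparison
#' group progresses faster (more negative adjusted rate), plus the AUC of
#' `-rate` for separating each group from the reference. Exact p-values
#' are used for combined n <= 25 without ties, the normal approximation
#' with continuity/tie correction otherwise.
#'
#' @param rates numeric per-subject (adjusted) rates, negative = atrophy.
#' @param groups group label per subject.
#' @param reference label of the reference group.
#' @return data.frame with group, n, p_value, auc. Empty comparison groups
#'   are reported with NA.
#' @export
group_difference <- function(rates, groups, reference) {
  if (!any(groups == reference)) stop("reference group is empty")
  ref <- rates[groups == reference]
  others <- setdiff(unique(groups), reference)
  rows <- lapply(others, function(g) {
    x <- rates[groups == g]
    if (length(x) == 0L)
      return(data.frame(group = g, n = 0L, p_value = NA_real_, auc = NA_real_))
    exact <- (length(x) + length(ref)) <= 25 &&
      !any(duplicated(c(x, ref)))
    p <- suppressWarnings(stats::wilcox.test(
      x, ref, alternative = "less", exact = exact, correct = TRUE)$p.value)
    data.frame(group = g, n = length(x), p_value = p,
               auc = roc_auc(-c(x, ref),
                             c(rep(TRUE, length(x)), rep(FALSE, length(ref)))))
  })
  do.call(rbind, rows)
}

#' Aggregate attention maps into template-space heatmaps
#'
#' Warps the binarized (threshold 0.5) shrink and expand attention maps of
#' each test pair into the common template space through the supplied
#' warps and accumulates, per voxel, the frequency of being identified as
#' shrinkage (resp. expansion), normalized by the per-voxel coverage count
#' (how many warped pairs sampled that voxel). Coverage masking keeps
#' frequencies in `[0, 1]` even at the template periphery.
#'
#' @param attention named list of [attention_maps()].
#' @param warps named list of [displacement_field()] objects (template ->
#'   fixed-image space), matching `attention` by name; pairs without a
#'   warp are skipped with a warning.
#' @param template_grid the template [image_grid()].
#' @param threshold binarization threshold on the attention channels.
#' @return list of class `rda_heatmap`: `shrink`, `expand` (frequency
#'   arrays), `coverage` (counts), `grid`.
#' @export
aggregate_heatmap <- function(attention, warps, template_grid,
                              threshold = 0.5) {
  num_s <- array(0, template_grid$shape)
  num_e <- array(0, template_grid$shape)
  cov <- array(0, template_grid$shape)
  for (key in names(attention)) {
    w <- warps[[key]]
    if (is.null(w)) {
      warning(sprintf("no template warp for pair '%s'; skipped", key))
      next
    }
    att <- attention[[key]]
    ws <- warp_volume(array(as.numeric(attention_channel(att, "shrink") >= threshold),
                            att$grid$shape), w)
    we <- warp_volume(array(as.numeric(attention_channel(att, "expand") >= threshold),
                            att$grid$shape), w)
    num_s <- num_s + ws$volume$values
    num_e <- num_e + we$volume$values
    cov <- cov + ws$inside
  }
  freq <- function(num) {
    f <- num * 0
    f[cov > 0] <- num[cov > 0] / cov[cov > 0]
    pmin(pmax(f, 0), 1)
  }
  structure(list(shrink = freq(num_s), expand = freq(num_e),
                 coverage = cov, grid = template_grid),
            class = "rda_heatmap")
}

#' Heatmap enrichment inside a reference region
#'
#' Ratio of the mean heatmap frequency inside a binary region to the mean
#' frequency outside it (both restricted to covered voxels).
#'
#' @param heatmap an `rda_heatmap`.
#' @param mask binary 3D array on the template grid.
#' @param channel "shrink" or "expand".
#' @return scalar enrichment ratio (Inf when the outside mean is zero).
#' @export
heatmap_enrichment <- function(heatmap, mask, channel = c("shrink", "expand")) {
  channel <- match.arg(channel)
  f <- heatmap[[channel]]
  covered <- heatmap$coverage > 0
  inside <- covered & mask > 0.5
  outside <- covered & mask <= 0.5
  mi <- mean(f[inside])
  mo <- mean(f[outside])
  if (mo == 0) return(Inf)
  mi / mo
}

#' Restrict pair records to a follow-up window
#'
#' Longitudinal study scenarios are emulated by selecting, per subject,
#' follow-up pairs whose absolute interval falls inside a window (the
#' conventional windows being 180-400 and 400-800 days from baseline).
#'
#' @param records pair records data.frame with an `interval` column in
#'   years.
#' @param window_days numeric `c(min, max)` in days.
#' @return the filtered data.frame.
#' @export
filter_interval_window <- function(records, window_days) {
  d <- abs(records$interval) * 365.25
  records[d >= window_days[1] & d <= window_days[2], , drop = FALSE]
}
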