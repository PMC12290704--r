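#' Attention-weighted volume change of a scan pair
#'
#' Integrates the deformation-induced volume change over the shrink and
#' expand attention regions: `a_shr` and `a_exp` are the moving-minus-fixed
#' volumes of the two regions (mm^3), and the pooled change is
#' `a_pooled = a_shr - a_exp`. Under atrophy and forward time order, a
#' well-trained model yields `a_shr < 0`, `a_exp > 0`, hence `a_pooled < 0`
#' (the sign convention used throughout this package). `v_base` is the
#' fixed-image volume of the two attention regions combined, the
#' normalization used for fractional changes and rate estimates.
#'
#' @param att an [attention_maps()] object.
#' @param field a [displacement_field()] on the same grid.
#' @param interval signed interscan interval in years (t2 - t1).
#' @param jacobian optional precomputed [jacobian_map()] of `field`.
#' @return list of class `pair_change`: `a_shr`, `a_exp`, `a_pooled`,
#'   `v_base` (mm^3), `interval` (years).
#' @export
pair_change <- function(att, field, interval, jacobian = NULL) {
  stop_if_grid_mismatch(att$grid, field$grid, "attention maps and field")
  if (is.null(jacobian)) jacobian <- jacobian_determinant(field)
  shr <- region_volumes(att, field, "shrink", jacobian)
  exp_ <- region_volumes(att, field, "expand", jacobian)
  a_shr <- unname(shr["v_moving"] - shr["v_fixed"])
  a_exp <- unname(exp_["v_moving"] - exp_["v_fixed"])
  structure(list(a_shr = a_shr, a_exp = a_exp,
                 a_pooled = a_shr - a_exp,
                 v_base = unname(shr["v_fixed"] + exp_["v_fixed"]),
                 interval = interval),
            class = "pair_change")
}

#' @export
print.pair_change <- function(x, ...) {
  cat(sprintf(
    "pair_change: a_shr %.2f, a_exp %.2f, a_pooled %.2f mm^3 over %.2f yr (v_base %.1f mm^3)\n",
    x$a_shr, x$a_exp, x$a_pooled, x$interval, x$v_base))
  invisible(x)
}

as_change_frame <- function(changes) {
  if (inherits(changes, "pair_change")) changes <- list(changes)
  if (is.data.frame(changes)) return(changes)
  do.call(rbind, lapply(changes, function(ch)
    data.frame(a_pooled = ch$a_pooled, v_base = ch$v_base,
               interval = ch$interval,
               anchor = if (is.null(ch$anchor)) NA else ch$anchor)))
}

#' Annualized atrophy rate for one subject
#'
#' With a single baseline-anchored pair the rate is
#' `(a_pooled / v_base) / interval`. With several pairs (all sharing the
#' subject's baseline scan as fixed image) an ordinary least-squares line
#' of `a_pooled` against interval is fit and its slope (mm^3/yr) divided by
#' the `v_base` of the baseline (shortest-interval) pair. Negative values
#' indicate atrophy.
#'
#' @param changes a `pair_change`, a list of them, or a data.frame with
#'   columns `a_pooled`, `v_base`, `interval` (and optionally `anchor`, the
#'   id of the shared fixed scan — mixed anchors are rejected).
#' @param intercept include a free intercept in the multi-pair fit
#'   (default TRUE); FALSE forces the line through the origin.
#' @return rate as a fraction of baseline attention-region volume per year.
#' @export
annualized_rate <- function(changes, intercept = TRUE) {
  df <- as_change_frame(changes)
  if (is.null(df) || nrow(df) == 0L) stop("no pair changes supplied")
  if (any(!is.finite(df$interval)) || any(df$interval <= 0))
    stop("intervals must be positive (pairs anchored at baseline, forward order)")
  if ("anchor" %in% names(df) && length(unique(stats::na.omit(df$anchor))) > 1L)
    stop("mixed anchoring: all pairs must share the subject's baseline scan")
  if (nrow(df) == 1L)
    return(df$a_pooled / df$v_base / df$interval)
  fit <- if (intercept) stats::lm(a_pooled ~ interval, data = df)
         else stats::lm(a_pooled ~ 0 + interval, data = df)
  slope <- unname(stats::coef(fit)[["interval"]])
  v0 <- df$v_base[which.min(df$interval)]
  slope / v0
}

#' Age adjustment of subject rates
#'
#' Fits `rate ~ age` by least squares on a reference group and returns, for
#' every subject, the residual of the observed rate from the fitted
#' group-wise age trend.
#'
#' @param rates numeric vector of per-subject rates.
#' @param ages numeric vector of ages (years), same length.
#' @param reference indices (or logical mask) of the reference group used
#'   to fit the trend; default all subjects. Needs >= 3 subjects with
#'   non-constant age.
#' @return numeric vector of adjusted rates (residuals).
#' @export
age_adjust <- function(rates, ages, reference = seq_along(rates)) {
  if (length(rates) != length(ages)) stop("rates and ages lengths differ")
  if (is.logical(reference)) reference <- which(reference)
  if (length(reference) < 3L) stop("reference group must have >= 3 subjects")
  if (stats::sd(ages[reference]) == 0)
    stop("constant age in reference group: age trend not identifiable")
  fit <- stats::lm(r ~ a, data = data.frame(r = rates[reference],
                                            a = ages[reference]))
  unname(rates - stats::predict(fit, newdata = data.frame(a = ages)))
}
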