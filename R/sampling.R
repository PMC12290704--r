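#' Enumerate valid pair-of-pairs (quadruples) for one subject
#'
#' The relative-interval task compares two scan pairs of one subject whose
#' interscan intervals are nested: the shorter interval's endpoints must lie
#' within the longer's, and at most one endpoint may be shared (so the two
#' pairs span three or four distinct scans). Every valid unordered interval
#' pair is emitted with both role orders (which pair is branch 1) and both
#' temporal orientations of each pair, in a deterministic order.
#'
#' @param times numeric vector of scan dates (years) for one subject,
#'   strictly increasing.
#' @param bins a [risi_bins()] defining the target categories.
#' @return data.frame with one row per quadruple template: timepoint
#'   indices `i1, i2` (branch-1 pair, fixed = `i1`), `i3, i4` (branch-2
#'   pair), order labels `y1, y2`, the true interval ratio
#'   `|t2 - t1| / |t4 - t3|`, and its target `bin`. Empty for fewer than 3
#'   usable timepoints.
#' @export
enumerate_quadruples <- function(times, bins = risi_bins()) {
  n <- length(times)
  empty <- data.frame(i1 = integer(), i2 = integer(), i3 = integer(),
                      i4 = integer(), y1 = integer(), y2 = integer(),
                      ratio = numeric(), bin = integer())
  if (n < 2L) return(empty)
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  ints <- utils::combn(n, 2)  # unordered intervals, columns (lo, hi)
  rows <- list()
  nI <- ncol(ints)
  for (a in seq_len(nI)) {
    for (b in seq_len(nI)) {
      if (a == b) next
      lo1 <- ints[1, a]; hi1 <- ints[2, a]
      lo2 <- ints[1, b]; hi2 <- ints[2, b]
      # nesting of the time intervals (either containment direction)
      nested <- (times[lo1] >= times[lo2] && times[hi1] <= times[hi2]) ||
                (times[lo2] >= times[lo1] && times[hi2] <= times[hi1])
      if (!nested) next
      shared <- length(intersect(c(lo1, hi1), c(lo2, hi2)))
      if (shared > 1L) next
      if (a > b) next  # emit each unordered interval pair once, both roles below
      for (role in 1:2) {
        A <- if (role == 1L) c(lo1, hi1) else c(lo2, hi2)
        B <- if (role == 1L) c(lo2, hi2) else c(lo1, hi1)
        ratio <- abs(times[A[2]] - times[A[1]]) / abs(times[B[2]] - times[B[1]])
        for (oA in 1:2) for (oB in 1:2) {
          pa <- if (oA == 1L) A else rev(A)
          pb <- if (oB == 1L) B else rev(B)
          rows[[length(rows) + 1L]] <- data.frame(
            i1 = pa[1], i2 = pa[2], i3 = pb[1], i4 = pb[2],
            y1 = sign(times[pa[2]] - times[pa[1]]),
            y2 = sign(times[pb[2]] - times[pb[1]]),
            ratio = ratio, bin = risi_target_bin(ratio, bins))
        }
      }
    }
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

#' SSIM quality-control filter for scan pairs
#'
#' Computes the structural similarity between the fixed and moving scans of
#' each pair and removes pairs scoring below the threshold (0.6 is the
#' conventional cut for misregistered or artifact-laden pairs).
#'
#' @param pairs list of `pair_sample` objects (see [cohort_pair()]).
#' @param threshold minimum SSIM score to keep a pair.
#' @return list with `pairs` (the retained pairs) and `log` (data.frame of
#'   subject, timepoints, score and the rejection flag for every input
#'   pair).
#' @export
qc_filter <- function(pairs, threshold = 0.6) {
  scores <- vapply(pairs, function(p) ssim3d(p$fixed, p$moving), 1)
  log <- data.frame(
    subject = vapply(pairs, function(p) as.character(p$subject), ""),
    t1 = vapply(pairs, function(p) p$t1, 1L),
    t2 = vapply(pairs, function(p) p$t2, 1L),
    ssim = scores,
    rejected = scores < threshold)
  list(pairs = pairs[!log$rejected], log = log)
}
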