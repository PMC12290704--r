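# Synthetic longitudinal phantom cohorts: two ellipsoidal structures (a
# "tissue" region that shrinks and a "fluid" region that expands) with
# subject-specific annual rates, analytic ground-truth displacement fields
# (exact radial scaling inside each region, smoothly blended to identity
# across a support shell), and optional time-independent confounds.

# evaluate an expression under a temporary RNG state
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Confound configuration for synthetic scans
#'
#' Time-independent (nonsystematic) perturbations emulating head motion,
#' scanner artifacts and physiological noise: a small random smooth warp
#' and/or a random intensity artifact (patch of constant intensity plus
#' alternating stripes). Parameters are drawn independently of acquisition
#' time, so confounds carry no temporal signal.
#'
#' @param warp_amplitude peak displacement of the random smooth warp, mm.
#' @param warp_sigma spatial scale of the warp bumps, mm.
#' @param n_bumps number of Gaussian bumps composing the warp.
#' @param artifact_prob probability that an intensity artifact is applied.
#' @param artifact_intensity artifact amplitude as a fraction of the image
#'   dynamic range (1 = full range).
#' @param artifact_frac linear size of the corrupted patch as a fraction of
#'   the volume extent.
#' @param stripes also overlay alternating plane stripes when an artifact
#'   fires.
#' @return a list of class `confound_config`.
#' @export
confound_config <- function(warp_amplitude = 0, warp_sigma = 8, n_bumps = 3,
                            artifact_prob = 0, artifact_intensity = 0.75,
                            artifact_frac = 0.3, stripes = TRUE) {
  stopifnot(warp_amplitude >= 0, warp_sigma > 0, n_bumps >= 1,
            artifact_prob >= 0, artifact_prob <= 1,
            artifact_intensity >= 0, artifact_frac > 0, artifact_frac <= 1)
  structure(list(warp_amplitude = warp_amplitude, warp_sigma = warp_sigma,
                 n_bumps = as.integer(n_bumps), artifact_prob = artifact_prob,
                 artifact_intensity = artifact_intensity,
                 artifact_frac = artifact_frac, stripes = stripes),
            class = "confound_config")
}

#' Phantom cohort specification
#'
#' Defines the geometry, intensity model and longitudinal design of a
#' synthetic cohort. The tissue ellipsoid loses volume linearly in time at a
#' subject-specific annual rate `r` (fraction of baseline volume per year);
#' the fluid ellipsoid gains volume at `fluid_coupling * r`. The default
#' rate range 0.5%-8%/yr spans control-like to late-MCI-like regimes.
#'
#' @param grid_shape voxel counts (default 48^3).
#' @param spacing voxel size, mm.
#' @param tissue,fluid lists with `center` (voxel units, 0-based) and
#'   `radii` (mm) of the two ellipsoids; regions must be disjoint including
#'   their maximal growth and support shells.
#' @param intensity named levels for tissue, fluid and background.
#' @param noise_sigma additive Gaussian noise, as a fraction of the tissue
#'   intensity.
#' @param texture_amplitude amplitude (fraction of tissue intensity) of a
#'   smooth static per-subject texture shared by all of a subject's
#'   timepoints — the stand-in for subject anatomy that makes same-subject
#'   scan pairs structurally similar (SSIM in the 0.7-0.9 range typical of
#'   well-registered pairs) while independent volumes remain dissimilar.
#' @param texture_sigma_mm spatial correlation length of the texture.
#' @param rate_range interval for sampling subject annual tissue-volume-loss
#'   rates (fraction/yr).
#' @param fluid_coupling ratio of fluid expansion rate to tissue loss rate.
#' @param n_timepoints integer range `c(min, max)` of scans per subject.
#' @param interval_range years from baseline spanned by follow-up scans;
#'   follow-ups are drawn on a 0.25-year lattice so scans are distinct.
#' @param shell outer boundary (in units of the normalized ellipsoid radius)
#'   of the blending shell over which the deformation decays to identity.
#' @param edge_mm softness of the rendered region boundary, mm.
#' @param confound a [confound_config()]; the default applies none.
#' @return a list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(48, 48, 48), spacing = c(1, 1, 1),
                         tissue = list(center = c(17, 23, 23), radii = c(9, 10, 8)),
                         fluid = list(center = c(35, 23, 23), radii = c(5, 6, 7)),
                         intensity = c(tissue = 1, fluid = 0.35, background = 0.1),
                         noise_sigma = 0.05,
                         texture_amplitude = 0.16,
                         texture_sigma_mm = 3,
                         rate_range = c(0.005, 0.08),
                         fluid_coupling = 1,
                         n_timepoints = c(3, 4),
                         interval_range = c(0.25, 6),
                         shell = 1.3,
                         edge_mm = 0.7,
                         confound = confound_config()) {
  spec <- structure(list(
    grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing),
    tissue = tissue, fluid = fluid, intensity = intensity,
    noise_sigma = noise_sigma, texture_amplitude = texture_amplitude,
    texture_sigma_mm = texture_sigma_mm,
    rate_range = as.numeric(rate_range),
    fluid_coupling = fluid_coupling,
    n_timepoints = as.integer(rep(n_timepoints, length.out = 2)),
    interval_range = as.numeric(interval_range), shell = shell,
    edge_mm = edge_mm, confound = confound), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (any(spec$n_timepoints < 2L)) stop("n_timepoints must be >= 2")
  if (spec$rate_range[1] < 0 || spec$rate_range[2] < spec$rate_range[1])
    stop("rate_range must be a nondecreasing nonnegative interval")
  max_t <- spec$interval_range[2]
  if (spec$rate_range[2] * max_t >= 1)
    stop(sprintf(
      "rate %.3f/yr over %.2g yr would exhaust the tissue region (non-positive volume)",
      spec$rate_range[2], max_t))
  if (spec$shell <= 1) stop("shell must exceed 1")
  grid <- phantom_grid(spec)
  qt <- ellipsoid_q(grid, spec$tissue)
  qf <- ellipsoid_q(grid, spec$fluid)
  fmax <- (1 + spec$fluid_coupling * spec$rate_range[2] * max_t)^(1 / 3)
  if (any(qt <= 1 & qf <= fmax * spec$shell) ||
      any(qf <= fmax & qt <= spec$shell))
    stop("tissue and fluid regions (including growth and support shells) overlap")
  invisible(spec)
}

phantom_grid <- function(spec) image_grid(spec$grid_shape, spec$spacing)

# normalized elliptical radius at every grid voxel (0 at center, 1 on the
# region surface at baseline scale)
ellipsoid_q <- function(grid, region) {
  co <- grid_coordinates(grid)
  ctr <- grid$origin + region$center * grid$spacing
  sqrt(((co$x - ctr[1]) / region$radii[1])^2 +
       ((co$y - ctr[2]) / region$radii[2])^2 +
       ((co$z - ctr[3]) / region$radii[3])^2)
}

# linear volume model: isotropic scale of a region at elapsed time t
region_scale <- function(spec, which, rate, t) {
  if (which == "tissue") (1 - rate * t)^(1 / 3)
  else (1 + spec$fluid_coupling * rate * t)^(1 / 3)
}

smoothstep_down <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  1 - t * t * (3 - 2 * t)
}

# radial scaling displacement for one region between scales s1 -> s2:
# exact u = (s2/s1 - 1) (x - c) inside the scaled region (q <= s1), decaying
# to zero across the shell q in [s1, s1*shell]
region_field_arrays <- function(grid, region, spec, s1, s2) {
  co <- grid_coordinates(grid)
  ctr <- grid$origin + region$center * grid$spacing
  q <- ellipsoid_q(grid, region) / s1
  w <- ifelse(q <= 1, 1, smoothstep_down((q - 1) / (spec$shell - 1)))
  lam <- s2 / s1 - 1
  list(w * lam * (co$x - ctr[1]),
       w * lam * (co$y - ctr[2]),
       w * lam * (co$z - ctr[3]))
}

# binary ground-truth region masks on the fixed grid at elapsed time t
pair_masks <- function(spec, rate, t, grid) {
  st <- region_scale(spec, "tissue", rate, t)
  sf <- region_scale(spec, "fluid", rate, t)
  list(
    shrink = array(as.numeric(ellipsoid_q(grid, spec$tissue) / st <= 1), grid$shape),
    expand = array(as.numeric(ellipsoid_q(grid, spec$fluid) / sf <= 1), grid$shape))
}

# analytic ground-truth field for a subject with annual rate `rate`,
# between elapsed times t1 (fixed) and t2 (moving)
make_pair_field <- function(spec, rate, t1, t2) {
  grid <- phantom_grid(spec)
  ut <- region_field_arrays(grid, spec$tissue, spec,
                            region_scale(spec, "tissue", rate, t1),
                            region_scale(spec, "tissue", rate, t2))
  uf <- region_field_arrays(grid, spec$fluid, spec,
                            region_scale(spec, "fluid", rate, t1),
                            region_scale(spec, "fluid", rate, t2))
  arr <- array(0, c(grid$shape, 3L))
  for (k in 1:3) arr[, , , k] <- ut[[k]] + uf[[k]]
  displacement_field(arr, grid)
}

# noiseless analytic image at elapsed time t
render_scan_clean <- function(spec, rate, t) {
  grid <- phantom_grid(spec)
  st <- region_scale(spec, "tissue", rate, t)
  sf <- region_scale(spec, "fluid", rate, t)
  qt <- ellipsoid_q(grid, spec$tissue) / st
  qf <- ellipsoid_q(grid, spec$fluid) / sf
  soft <- function(q, radii, s) {
    k <- mean(radii) * s / spec$edge_mm
    1 / (1 + exp((q - 1) * k))
  }
  iv <- spec$intensity
  vals <- iv[["background"]] +
    (iv[["tissue"]] - iv[["background"]]) * soft(qt, spec$tissue$radii, st) +
    (iv[["fluid"]] - iv[["background"]]) * soft(qf, spec$fluid$radii, sf)
  scalar_volume(array(vals, dim = grid$shape), grid)
}

# smooth static texture field, unit variance before scaling
subject_texture <- function(spec, texture_seed) {
  d <- spec$grid_shape
  white <- local_seed(texture_seed, stats::rnorm(prod(d)))
  sig <- spec$texture_sigma_mm / mean(spec$spacing)
  tex <- .gaussian_blur3(white, d[1], d[2], d[3], sig,
                         max(1L, as.integer(ceiling(3 * sig))))
  tex <- tex / stats::sd(tex)
  array(tex, dim = d)
}

render_scan <- function(spec, rate, t, noise_seed, texture_seed = NULL) {
  vol <- render_scan_clean(spec, rate, t)
  if (spec$texture_amplitude > 0 && !is.null(texture_seed)) {
    vol$values <- vol$values + spec$texture_amplitude *
      spec$intensity[["tissue"]] * subject_texture(spec, texture_seed)
  }
  if (spec$noise_sigma > 0) {
    noise <- local_seed(noise_seed,
      array(stats::rnorm(prod(spec$grid_shape),
                         sd = spec$noise_sigma * spec$intensity[["tissue"]]),
            dim = spec$grid_shape))
    vol$values <- vol$values + noise
  }
  vol
}

#' Generate a synthetic longitudinal cohort
#'
#' Samples per-subject annual atrophy rates, scan times (baseline plus
#' follow-ups on a 0.25-year lattice) and ages, all deterministically from
#' `seed`. Scans, ground-truth pair fields and masks are rendered lazily and
#' reproducibly via [cohort_scan()] and [cohort_pair()], so a cohort object
#' stays small.
#'
#' @param spec a [phantom_spec()].
#' @param n_subjects number of subjects.
#' @param seed integer seed; identical spec + seed give an identical cohort.
#' @return an object of class `rda_cohort`.
#' @export
generate_cohort <- function(spec, n_subjects, seed) {
  validate_phantom_spec(spec)
  subjects <- local_seed(seed, lapply(seq_len(n_subjects), function(j) {
    rate <- stats::runif(1, spec$rate_range[1], spec$rate_range[2])
    ntp <- if (spec$n_timepoints[1] == spec$n_timepoints[2]) spec$n_timepoints[1]
           else sample(spec$n_timepoints[1]:spec$n_timepoints[2], 1)
    lattice <- seq(spec$interval_range[1], spec$interval_range[2], by = 0.25)
    times <- c(0, sort(lattice[sample.int(length(lattice), ntp - 1L)]))
    list(id = sprintf("S%03d", j), rate = rate,
         age = stats::runif(1, 65, 85), times = times,
         scan_seeds = sample.int(.Machine$integer.max - 1L, ntp),
         confound_seeds = sample.int(.Machine$integer.max - 1L, ntp),
         texture_seed = sample.int(.Machine$integer.max - 1L, 1))
  }))
  structure(list(spec = spec, seed = seed, grid = phantom_grid(spec),
                 subjects = subjects),
            class = "rda_cohort")
}

#' @export
print.rda_cohort <- function(x, ...) {
  ntp <- vapply(x$subjects, function(s) length(s$times), 1L)
  cat(sprintf("rda_cohort: %d subjects, %d-%d timepoints, rates %.3f-%.3f /yr, seed %d\n",
              length(x$subjects), min(ntp), max(ntp),
              min(vapply(x$subjects, `[[`, 1, "rate")),
              max(vapply(x$subjects, `[[`, 1, "rate")), x$seed))
  invisible(x)
}

#' True subject rates of a cohort
#' @param cohort an `rda_cohort`.
#' @return data.frame with subject, rate (fraction/yr), age, n_timepoints.
#' @export
cohort_subjects <- function(cohort) {
  data.frame(
    subject = vapply(cohort$subjects, `[[`, "", "id"),
    rate = vapply(cohort$subjects, `[[`, 1, "rate"),
    age = vapply(cohort$subjects, `[[`, 1, "age"),
    n_timepoints = vapply(cohort$subjects, function(s) length(s$times), 1L))
}

#' Render one scan of a cohort
#'
#' @param cohort an `rda_cohort`.
#' @param subject subject index.
#' @param timepoint timepoint index (1 = baseline).
#' @return a [scalar_volume()] with noise (and confounds, when the spec's
#'   confound configuration enables them) applied deterministically.
#' @export
cohort_scan <- function(cohort, subject, timepoint) {
  s <- cohort$subjects[[subject]]
  vol <- render_scan(cohort$spec, s$rate, s$times[timepoint],
                     s$scan_seeds[timepoint], s$texture_seed)
  cf <- cohort$spec$confound
  if (cf$warp_amplitude > 0 || cf$artifact_prob > 0)
    vol <- add_nonsystematic_confound(vol, cf, s$confound_seeds[timepoint])
  vol
}

#' Ground-truth sample for an ordered scan pair
#'
#' Returns the fixed/moving scans, the analytic ground-truth displacement
#' field for that ordering (fixed = first index), the binary ground-truth
#' shrink/expand masks on the fixed grid, and interval metadata.
#'
#' @param cohort an `rda_cohort`.
#' @param subject subject index.
#' @param t1,t2 timepoint indices for fixed and moving scans.
#' @return list of class `pair_sample` with elements `fixed`, `moving`,
#'   `field`, `masks` (list `shrink`, `expand`), `interval` (years, signed
#'   t2 - t1), `y` (order label, +1 forward), `subject`, `t1`, `t2`.
#' @export
cohort_pair <- function(cohort, subject, t1, t2) {
  s <- cohort$subjects[[subject]]
  if (t1 == t2) stop("t1 and t2 must differ")
  spec <- cohort$spec
  time1 <- s$times[t1]; time2 <- s$times[t2]
  grid <- cohort$grid
  masks <- pair_masks(spec, s$rate, time1, grid)
  structure(list(
    fixed = cohort_scan(cohort, subject, t1),
    moving = cohort_scan(cohort, subject, t2),
    field = make_pair_field(spec, s$rate, time1, time2),
    masks = masks,
    interval = time2 - time1,
    y = sign(time2 - time1),
    subject = s$id, subject_index = subject,
    t1 = as.integer(t1), t2 = as.integer(t2),
    time1 = time1, time2 = time2), class = "pair_sample")
}

#' Template warp for heatmap aggregation
#'
#' The phantom-native common space is the baseline (t = 0) geometry shared
#' by all subjects. This returns the analytic map psi from template space to
#' the fixed image of a pair (elapsed time `t1`), used to pull attention
#' maps back into template space.
#'
#' @param cohort an `rda_cohort`.
#' @param subject subject index.
#' @param t1 timepoint index of the pair's fixed image.
#' @return a [displacement_field()] on the template grid.
#' @export
cohort_template_warp <- function(cohort, subject, t1) {
  s <- cohort$subjects[[subject]]
  make_pair_field(cohort$spec, s$rate, 0, s$times[t1])
}

#' Apply a time-independent confound to a scan
#'
#' Applies a small random smooth warp (sum of Gaussian bumps, peak
#' displacement `warp_amplitude`) and, with probability `artifact_prob`, an
#' intensity artifact (random constant patch, optionally with alternating
#' plane stripes). All draws are independent of acquisition time and
#' deterministic given `seed`. With an all-zero configuration the scan is
#' returned unchanged.
#'
#' @param scan a [scalar_volume()].
#' @param config a [confound_config()].
#' @param seed integer seed.
#' @return a [scalar_volume()] on the same grid.
#' @export
add_nonsystematic_confound <- function(scan, config, seed) {
  if (config$warp_amplitude == 0 && config$artifact_prob == 0) return(scan)
  grid <- scan$grid
  local_seed(seed, {
    vol <- scan
    if (config$warp_amplitude > 0) {
      co <- grid_coordinates(grid)
      extent <- grid$origin + (grid$shape - 1) * grid$spacing
      u <- array(0, c(grid$shape, 3L))
      for (b in seq_len(config$n_bumps)) {
        ctr <- stats::runif(3, grid$origin, extent)
        amp <- stats::rnorm(3)
        amp <- amp / max(abs(amp)) * config$warp_amplitude
        g <- exp(-((co$x - ctr[1])^2 + (co$y - ctr[2])^2 + (co$z - ctr[3])^2) /
                   (2 * config$warp_sigma^2))
        for (k in 1:3) u[, , , k] <- u[, , , k] + amp[k] * g
      }
      peak <- sqrt(max(rowSums(matrix(u, ncol = 3)^2)))
      if (peak > config$warp_amplitude)
        u <- u * (config$warp_amplitude / peak)
      fld <- displacement_field(u, grid)
      fill <- stats::median(vol$values)
      vol <- warp_volume(vol, fld, fill = fill)$volume
    }
    if (config$artifact_prob > 0 && stats::runif(1) < config$artifact_prob) {
      rng <- range(vol$values)
      amp <- config$artifact_intensity * (rng[2] - rng[1])
      d <- grid$shape
      side <- pmax(2L, as.integer(round(config$artifact_frac * d)))
      start <- vapply(1:3, function(k)
        sample.int(max(1L, d[k] - side[k] + 1L), 1), 1L)
      level <- stats::runif(1, rng[1] - amp, rng[2] + amp)
      vol$values[start[1]:(start[1] + side[1] - 1L),
                 start[2]:(start[2] + side[2] - 1L),
                 start[3]:(start[3] + side[3] - 1L)] <- level
      if (config$stripes) {
        ax <- sample.int(3, 1)
        planes <- seq(sample.int(2, 1), d[ax], by = 2L)
        idx <- lapply(d, seq_len)
        idx[[ax]] <- planes
        vol$values <- do.call(`[<-`, c(list(vol$values), idx,
          list(do.call(`[`, c(list(vol$values), idx)) + amp * 0.5)))
      }
    }
    vol
  })
}
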