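# On-disk cohort layout for the command-line interface: NIfTI scans, masks
# and per-ordered-pair ground-truth fields plus a CSV manifest and a JSON
# cohort descriptor (spec + seed) from which the cohort can be regenerated
# in memory.

#' Write a phantom cohort to disk
#'
#' Writes every scan (NIfTI), the baseline-grid ground-truth shrink/expand
#' masks per fixed timepoint, the analytic displacement field for each
#' ordered scan pair, a `manifest.csv` (subject, timepoint, years from
#' baseline, true rate, age, file paths) and a `cohort.json` descriptor.
#'
#' @param cohort an `rda_cohort`.
#' @param dir output directory (created if needed).
#' @param fields write per-pair displacement fields (all ordered pairs;
#'   set FALSE to write scans and manifest only).
#' @return the manifest data.frame, invisibly.
#' @export
write_cohort <- function(cohort, dir, fields = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "scans"), showWarnings = FALSE)
  dir.create(file.path(dir, "masks"), showWarnings = FALSE)
  if (fields) dir.create(file.path(dir, "fields"), showWarnings = FALSE)
  rows <- list()
  for (j in seq_along(cohort$subjects)) {
    s <- cohort$subjects[[j]]
    for (tp in seq_along(s$times)) {
      scan_path <- file.path("scans", sprintf("%s_t%d.nii.gz", s$id, tp))
      write_volume(cohort_scan(cohort, j, tp), file.path(dir, scan_path))
      mk <- pair_masks(cohort$spec, s$rate, s$times[tp], cohort$grid)
      shr_path <- file.path("masks", sprintf("%s_t%d_shrink.nii.gz", s$id, tp))
      exp_path <- file.path("masks", sprintf("%s_t%d_expand.nii.gz", s$id, tp))
      write_volume(scalar_volume(mk$shrink, cohort$grid),
                   file.path(dir, shr_path))
      write_volume(scalar_volume(mk$expand, cohort$grid),
                   file.path(dir, exp_path))
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s$id, timepoint = tp, years = s$times[tp],
        rate = s$rate, age = s$age, scan = scan_path,
        shrink_mask = shr_path, expand_mask = exp_path)
    }
    if (fields) {
      ntp <- length(s$times)
      for (t1 in seq_len(ntp)) for (t2 in seq_len(ntp)) {
        if (t1 == t2) next
        fp <- file.path("fields", sprintf("%s_t%d_t%d.nii.gz", s$id, t1, t2))
        write_field(make_pair_field(cohort$spec, s$rate, s$times[t1],
                                    s$times[t2]), file.path(dir, fp))
      }
    }
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  desc <- list(seed = cohort$seed, n_subjects = length(cohort$subjects),
               spec = unclass_spec(cohort$spec))
  writeLines(jsonlite::toJSON(desc, auto_unbox = TRUE, digits = NA),
             file.path(dir, "cohort.json"))
  invisible(manifest)
}

unclass_spec <- function(spec) {
  out <- unclass(spec)
  out$confound <- unclass(out$confound)
  out$intensity <- as.list(out$intensity)
  out
}

#' Rebuild a cohort from its JSON descriptor
#'
#' @param path path to a `cohort.json` written by [write_cohort()].
#' @return the regenerated `rda_cohort` (bitwise identical to the
#'   original, since cohorts are deterministic in spec + seed).
#' @export
read_cohort <- function(path) {
  desc <- jsonlite::fromJSON(path)
  sp <- desc$spec
  spec <- phantom_spec(
    grid_shape = sp$grid_shape, spacing = sp$spacing,
    tissue = list(center = sp$tissue$center, radii = sp$tissue$radii),
    fluid = list(center = sp$fluid$center, radii = sp$fluid$radii),
    intensity = unlist(sp$intensity),
    noise_sigma = sp$noise_sigma,
    texture_amplitude = sp$texture_amplitude,
    texture_sigma_mm = sp$texture_sigma_mm,
    rate_range = sp$rate_range, fluid_coupling = sp$fluid_coupling,
    n_timepoints = sp$n_timepoints, interval_range = sp$interval_range,
    shell = sp$shell, edge_mm = sp$edge_mm,
    confound = do.call(confound_config, sp$confound))
  generate_cohort(spec, desc$n_subjects, desc$seed)
}

#' Write attention maps as a 4D NIfTI
#'
#' Channels are stored as the 4th dimension in the order shrink, expand,
#' background.
#'
#' @param att an [attention_maps()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_attention <- function(att, path) {
  img <- RNifti::asNifti(att$channels,
    reference = list(pixdim = c(-1, att$grid$spacing, 1, 1, 0, 0)))
  img <- RNifti::`sform<-`(img, structure(.grid_affine(att$grid), code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
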