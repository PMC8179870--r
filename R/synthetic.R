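# Synthetic multi-rater cohort generator.
#
# Ground truth glands are superellipsoids with a band-limited radial
# perturbation (smooth low-order spherical-harmonic field), the transition
# zone a nested concentric blob at a requested volume fraction. Raters are
# emulated by smooth random radial displacement fields applied to the true
# boundary -- spatially correlated along the contour, as real contouring
# disagreement is -- plus an optional constant inward/outward bias, with
# amplitude inflated on the apical and basal thirds. Because masks are
# star-shaped level sets of a radial function, simulated masks are always
# connected. Everything is a pure function of (spec, seed).

# counter-based seed stream: mixing is iterative (31 * s + k), so adding
# later cases or raters never perturbs earlier streams
derive_seed <- function(seed, ...) {
  ks <- c(seed, ...)
  s <- 0
  for (k in ks) s <- (s * 31 + as.numeric(k) + 1) %% 2147483629
  as.integer(s)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

# low-order real spherical-harmonic-style basis on unit vectors
sphere_basis <- function(ux, uy, uz) {
  list(ux, uy, uz,
       ux * uy, uy * uz, uz * ux,
       ux^2 - uy^2, 3 * uz^2 - 1)
}

# unit-RMS smooth field on the sphere defined by 8 coefficients; RMS is
# normalised over a fixed Fibonacci point set so it is grid-independent
sphere_field <- function(coefs, ux, uy, uz) {
  stopifnot(length(coefs) == 8)
  n <- 256
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  fx <- sin(phi) * cos(theta); fy <- sin(phi) * sin(theta); fz <- cos(phi)
  ref <- Reduce(`+`, Map(`*`, coefs, sphere_basis(fx, fy, fz)))
  scale <- sqrt(mean(ref^2))
  if (scale < 1e-12) scale <- 1
  Reduce(`+`, Map(`*`, coefs, sphere_basis(ux, uy, uz))) / scale
}

#' Default rater roster
#'
#' Seven raters in three experience groups (3 experts, 2 seniors, 2
#' juniors) with group-level boundary-noise defaults of 1.0 / 1.2 / 1.3 mm
#' RMS and no systematic bias, chosen so simulated between-group agreement
#' differences stay small, as observed in reader studies of prostate
#' contouring.
#'
#' @return data.frame with columns `rater_id`, `group`,
#'   `boundary_noise_mm`, `bias_mm`
#' @export
default_raters <- function() {
  data.frame(
    rater_id = sprintf("r%d", 1:7),
    group = c("expert", "expert", "expert", "senior", "senior",
              "junior", "junior"),
    boundary_noise_mm = c(1.0, 1.0, 1.0, 1.2, 1.2, 1.3, 1.3),
    bias_mm = 0,
    stringsAsFactors = FALSE)
}

#' Specification of a synthetic multi-rater cohort
#'
#' Defaults emulate a 40-case, 7-rater prostate reader study: gland
#' volumes log-uniform over 15-199 cm^3, transition zone occupying 25-55%
#' of the gland, anisotropic voxel spacing, squared TZ-to-PZ contrast over
#' 0.02-0.40, and boundary noise inflated by
#' `extreme_slice_noise_multiplier` on the apical and basal thirds (where
#' contouring is anatomically hardest). `contrast_noise_coupling > 0`
#' additionally scales each case's boundary noise by
#' `1 + coupling * (1 - sqrt(contrast))`, making poorly differentiated
#' glands harder to contour.
#'
#' @param n_cases number of cases
#' @param raters data.frame as [default_raters()]
#' @param volume_range_cm3 min/max gland volume, sampled log-uniformly
#' @param tz_fraction_range min/max TZ fraction of the gland volume
#' @param spacing_mm voxel spacing (x, y, z) in mm
#' @param contrast_range min/max target squared TZ-to-PZ contrast
#' @param extreme_slice_noise_multiplier factor (>= 1) applied to boundary
#'   noise on the apical and basal thirds
#' @param contrast_noise_coupling nonnegative coupling of boundary noise to
#'   poor zonal contrast (0 = fixed absolute noise)
#' @param sequence_type label recorded in manifests
#' @param seed integer; the whole cohort is a pure function of the spec
#' @return object of class `cohort_spec`
#' @export
cohort_spec <- function(n_cases = 40,
                        raters = default_raters(),
                        volume_range_cm3 = c(15, 199),
                        tz_fraction_range = c(0.25, 0.55),
                        spacing_mm = c(0.6, 0.6, 1.2),
                        contrast_range = c(0.02, 0.40),
                        extreme_slice_noise_multiplier = 1.5,
                        contrast_noise_coupling = 0,
                        sequence_type = "3D_T2W",
                        seed = 1) {
  stopifnot(n_cases >= 1,
            is.data.frame(raters),
            all(c("rater_id", "group", "boundary_noise_mm", "bias_mm") %in%
                  names(raters)),
            all(is.finite(raters$boundary_noise_mm)),
            all(raters$boundary_noise_mm >= 0),
            all(is.finite(raters$bias_mm)),
            length(volume_range_cm3) == 2, all(volume_range_cm3 > 0),
            volume_range_cm3[1] <= volume_range_cm3[2],
            length(tz_fraction_range) == 2,
            all(tz_fraction_range > 0), all(tz_fraction_range < 1),
            tz_fraction_range[1] <= tz_fraction_range[2],
            length(spacing_mm) == 3, all(spacing_mm > 0),
            length(contrast_range) == 2,
            all(contrast_range >= 0), all(contrast_range <= 1),
            extreme_slice_noise_multiplier >= 1,
            contrast_noise_coupling >= 0,
            length(seed) == 1, is.finite(seed))
  bad <- setdiff(unique(raters$group), experience_groups)
  if (length(bad))
    stop(sprintf("unknown experience group(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  structure(list(n_cases = as.integer(n_cases), raters = raters,
                 volume_range_cm3 = volume_range_cm3,
                 tz_fraction_range = tz_fraction_range,
                 spacing_mm = spacing_mm, contrast_range = contrast_range,
                 extreme_slice_noise_multiplier = extreme_slice_noise_multiplier,
                 contrast_noise_coupling = contrast_noise_coupling,
                 sequence_type = sequence_type, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf("<cohort_spec> %d cases x %d raters, volumes %g-%g cm^3, spacing %g x %g x %g mm, seed %d\n",
              x$n_cases, nrow(x$raters), x$volume_range_cm3[1],
              x$volume_range_cm3[2], x$spacing_mm[1], x$spacing_mm[2],
              x$spacing_mm[3], x$seed))
  invisible(x)
}

# radial geometry of a perturbed superellipsoid on the case grid:
# r = distance to the centre, rho = true boundary radius along each
# voxel's direction, so (r - rho) is the signed radial distance in mm
radial_geometry <- function(xs, ys, zs, dims, center, radii, coefs, expo,
                            shape_rms) {
  X <- array(rep(xs - center[1], times = dims[2] * dims[3]), dims)
  Y <- array(rep(rep(ys - center[2], each = dims[1]), times = dims[3]), dims)
  Z <- array(rep(zs - center[3], each = dims[1] * dims[2]), dims)
  r <- sqrt(X^2 + Y^2 + Z^2)
  g0 <- (abs(X / radii[1])^expo + abs(Y / radii[2])^expo +
           abs(Z / radii[3])^expo)^(1 / expo)
  rs <- pmax(r, 1e-9)
  ux <- X / rs; uy <- Y / rs; uz <- Z / rs
  delta <- shape_rms * sphere_field(coefs, ux, uy, uz)
  rho <- ifelse(g0 > 1e-12, r / g0, max(radii)) * (1 + delta)
  list(r = r, rho = rho, ux = ux, uy = uy, uz = uz)
}

#' Generate one ground-truth case
#'
#' Draws the case's latent parameters (volume, TZ fraction, contrast,
#' shape) from streams derived from `(spec$seed, case_index)`, voxelises
#' the gland and nested TZ on the spec's grid with volume-calibration
#' passes so realised volumes land within a few percent of their targets,
#' and builds the two-zone intensity image whose noiseless squared
#' contrast equals the case's target exactly.
#'
#' @param spec a [cohort_spec()]
#' @param case_index 1-based case counter
#' @return object of class `ground_truth_case`: `true_wg`, `true_tz`
#'   ([label_volume()]s), `intensity` ([intensity_volume()]),
#'   `true_volume_cm3`, `target_volume_cm3`, `true_tz_fraction`,
#'   `true_contrast`, `si_tz`, `si_pz`, plus internal geometry consumed by
#'   [simulate_rater()]
#' @export
make_truth <- function(spec, case_index) {
  stopifnot(inherits(spec, "cohort_spec"), case_index >= 1)
  pars <- with_seed(derive_seed(spec$seed, case_index, 101), {
    list(vol_cm3 = exp(stats::runif(1, log(spec$volume_range_cm3[1]),
                                    log(spec$volume_range_cm3[2]))),
         tz_frac = stats::runif(1, spec$tz_fraction_range[1],
                                spec$tz_fraction_range[2]),
         contrast = stats::runif(1, spec$contrast_range[1],
                                 spec$contrast_range[2]),
         expo = stats::runif(1, 2.0, 2.6),
         ax = stats::runif(1, 0.9, 1.2),    # left-right
         ay = stats::runif(1, 0.85, 1.1),   # antero-posterior
         az = stats::runif(1, 0.7, 0.95),   # cranio-caudal
         coefs_wg = stats::rnorm(8),
         coefs_tz = stats::rnorm(8),
         tz_off_y = stats::runif(1, -0.20, -0.08),
         tz_off_z = stats::runif(1, 0.0, 0.10))
  })
  sp <- spec$spacing_mm
  v_mm3 <- pars$vol_cm3 * 1000
  rbase <- (3 * v_mm3 / (4 * pi * pars$ax * pars$ay * pars$az))^(1 / 3)
  radii <- rbase * c(pars$ax, pars$ay, pars$az)
  shape_rms <- 0.07

  amp_max <- max(spec$raters$boundary_noise_mm) *
    (1 + spec$contrast_noise_coupling) *
    spec$extreme_slice_noise_multiplier * 3 + max(abs(spec$raters$bias_mm))
  pad <- 6 + amp_max
  half_n <- ceiling((max(radii) * (1 + 3 * shape_rms) + pad) / sp)
  dims <- 2L * as.integer(half_n) + 1L
  c0 <- (dims + 1) / 2
  xs <- (seq_len(dims[1]) - c0[1]) * sp[1]
  ys <- (seq_len(dims[2]) - c0[2]) * sp[2]
  zs <- (seq_len(dims[3]) - c0[3]) * sp[3]
  voxvol <- prod(sp)

  gw <- radial_geometry(xs, ys, zs, dims, c(0, 0, 0), radii,
                        pars$coefs_wg, pars$expo, shape_rms)
  # calibrate the radial scale so the voxelised volume hits the target
  s <- 1
  for (pass in 1:3) {
    n_fg <- sum(gw$r <= s * gw$rho)
    if (n_fg == 0) stop("degenerate gland: no foreground voxels", call. = FALSE)
    s <- s * (v_mm3 / (n_fg * voxvol))^(1 / 3)
  }
  rho_wg <- s * gw$rho
  signed_wg <- gw$r - rho_wg
  wg <- signed_wg <= 0

  # nested transition zone: concentric blob, calibrated to the volume
  # fraction after clipping to the gland
  center_tz <- c(0, pars$tz_off_y * radii[2] * s, pars$tz_off_z * radii[3] * s)
  gt <- radial_geometry(xs, ys, zs, dims, center_tz, radii * s,
                        pars$coefs_tz, pars$expo, shape_rms)
  n_wg <- sum(wg)
  st <- pars$tz_frac^(1 / 3)
  for (pass in 1:4) {
    frac <- sum(gt$r <= st * gt$rho & wg) / n_wg
    if (frac <= 0)
      stop("requested TZ fraction incompatible with gland shape", call. = FALSE)
    st <- st * (pars$tz_frac / frac)^(1 / 3)
  }
  rho_tz <- st * gt$rho
  signed_tz <- gt$r - rho_tz
  tz <- (signed_tz <= 0) & wg

  # two-zone intensity image hitting the target squared contrast exactly
  sq <- sqrt(pars$contrast)
  si_pz <- 100
  si_tz <- si_pz * (1 - sq) / (1 + sq) # TZ hypointense relative to PZ on T2
  img <- array(30, dims)
  img[wg] <- si_pz
  img[tz] <- si_tz
  noise <- with_seed(derive_seed(spec$seed, case_index, 202),
                     stats::rnorm(prod(dims), sd = 4))
  img_noisy <- img + array(noise, dims)

  # per-slice noise multiplier: extreme (apical/basal) thirds of each
  # structure's cranio-caudal extent get spec$extreme_slice_noise_multiplier
  slice_mult <- function(mask) {
    prof <- apply(mask, 3, sum) > 0
    m <- rep(spec$extreme_slice_noise_multiplier, dims[3])
    if (any(prof)) {
      ext <- range(which(prof))
      L <- ext[2] - ext[1] + 1
      if (L >= 3) {
        n3 <- L %/% 3
        mid <- (ext[1] + n3):(ext[2] - n3)
        m[mid] <- 1
      }
    }
    m
  }

  structure(list(
    true_wg = label_volume(array(as.integer(wg), dims), sp),
    true_tz = label_volume(array(as.integer(tz), dims), sp),
    intensity = intensity_volume(img_noisy, sp),
    intensity_noiseless = intensity_volume(img, sp),
    true_volume_cm3 = sum(wg) * voxvol / 1000,
    target_volume_cm3 = pars$vol_cm3,
    true_tz_fraction = sum(tz) / sum(wg),
    true_contrast = pars$contrast,
    si_tz = si_tz, si_pz = si_pz,
    case_index = case_index,
    geometry = list(
      signed_wg = signed_wg, signed_tz = signed_tz,
      dirs_wg = list(ux = gw$ux, uy = gw$uy, uz = gw$uz),
      dirs_tz = list(ux = gt$ux, uy = gt$uy, uz = gt$uz),
      mult_wg = slice_mult(wg), mult_tz = slice_mult(tz),
      extreme_mult = spec$extreme_slice_noise_multiplier,
      coupling = spec$contrast_noise_coupling,
      dims = dims)),
    class = "ground_truth_case")
}

#' @export
print.ground_truth_case <- function(x, ...) {
  cat(sprintf("<ground_truth_case> #%d: WG %.1f cm^3 (target %.1f), TZ fraction %.2f, contrast %.3f\n",
              x$case_index, x$true_volume_cm3, x$target_volume_cm3,
              x$true_tz_fraction, x$true_contrast))
  invisible(x)
}

# drop the large geometry arrays once rater masks have been simulated
trim_truth <- function(truth) {
  truth$geometry <- NULL
  truth$intensity_noiseless <- NULL
  truth
}

simulate_structure <- function(truth, structure, amp, bias, seed_struct) {
  g <- truth$geometry
  if (is.null(g))
    stop("truth has been trimmed; regenerate it with make_truth()", call. = FALSE)
  signed <- if (structure == "WG") g$signed_wg else g$signed_tz
  dirs <- if (structure == "WG") g$dirs_wg else g$dirs_tz
  multz <- if (structure == "WG") g$mult_wg else g$mult_tz
  coefs <- with_seed(seed_struct, stats::rnorm(8))
  field <- sphere_field(coefs, dirs$ux, dirs$uy, dirs$uz)
  mult <- array(rep(multz, each = g$dims[1] * g$dims[2]), g$dims)
  signed <= amp * mult * field + bias
}

#' Simulate one rater's mask for one structure
#'
#' Applies a smooth random radial displacement field (RMS amplitude
#' `boundary_noise_mm`, inflated on the apical/basal thirds) plus the
#' rater's constant bias to the true boundary. The simulated TZ is clipped
#' to the same rater's simulated WG. With zero noise and zero bias the
#' mask equals the truth.
#'
#' @param truth a [make_truth()] result (untrimmed)
#' @param rater one row of the roster (list or 1-row data.frame with
#'   `boundary_noise_mm` and `bias_mm`)
#' @param structure `"WG"` or `"TZ"`
#' @param seed integer stream for this (case, rater)
#' @return a [label_volume()]
#' @export
simulate_rater <- function(truth, rater, structure = c("WG", "TZ"), seed) {
  structure <- match.arg(structure)
  simulate_rater_case(truth, rater, seed)[[structure]]
}

#' Simulate one rater's WG and TZ masks for a case
#'
#' @inheritParams simulate_rater
#' @return list with [label_volume()]s `WG` and `TZ`
#' @export
simulate_rater_case <- function(truth, rater, seed) {
  stopifnot(inherits(truth, "ground_truth_case"))
  g <- truth$geometry
  amp <- rater$boundary_noise_mm *
    (1 + g$coupling * (1 - sqrt(truth$true_contrast)))
  wg <- simulate_structure(truth, "WG", amp, rater$bias_mm,
                           derive_seed(seed, 1))
  tz <- simulate_structure(truth, "TZ", amp, rater$bias_mm,
                           derive_seed(seed, 2)) & wg
  sp <- truth$true_wg$spacing
  list(WG = label_volume(array(as.integer(wg), g$dims), sp),
       TZ = label_volume(array(as.integer(tz), g$dims), sp))
}

#' Simulate a full cohort in memory
#'
#' @param spec a [cohort_spec()]
#' @param keep_geometry keep each truth's internal geometry arrays (large;
#'   default FALSE)
#' @return object of class `synthetic_cohort`: per-case list with `truth`
#'   and `raters[[rater_id]] = list(WG, TZ)`, plus the spec
#' @export
simulate_cohort <- function(spec, keep_geometry = FALSE) {
  stopifnot(inherits(spec, "cohort_spec"))
  cases <- vector("list", spec$n_cases)
  names(cases) <- sprintf("case%03d", seq_len(spec$n_cases))
  for (ci in seq_len(spec$n_cases)) {
    truth <- make_truth(spec, ci)
    raters <- list()
    for (ri in seq_len(nrow(spec$raters))) {
      raters[[spec$raters$rater_id[ri]]] <-
        simulate_rater_case(truth, spec$raters[ri, ],
                            derive_seed(spec$seed, ci, 300 + ri))
    }
    if (!keep_geometry) truth <- trim_truth(truth)
    cases[[ci]] <- list(truth = truth, raters = raters)
  }
  structure(list(cases = cases, spec = spec), class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort> %d cases x %d raters (seed %d)\n",
              length(x$cases), nrow(x$spec$raters), x$spec$seed))
  invisible(x)
}

#' Write a synthetic cohort to disk with its manifest
#'
#' Writes every rater mask (and per-case intensity image and ground-truth
#' masks under `truth/`) in the requested format, plus `manifest.csv` in
#' the cohort-manifest schema and `cohort_summary.csv` with the latent
#' per-case parameters.
#'
#' @param spec a [cohort_spec()]
#' @param out_dir output directory (created if needed)
#' @param format `"nii.gz"`, `"nii"`, `"nrrd"` or `"mha"`
#' @return the manifest data.frame, invisibly
#' @export
generate_cohort <- function(spec, out_dir, format = c("nii.gz", "nii", "nrrd", "mha")) {
  format <- match.arg(format)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "truth"), showWarnings = FALSE)
  rows <- list()
  summ <- list()
  for (ci in seq_len(spec$n_cases)) {
    cid <- sprintf("case%03d", ci)
    truth <- make_truth(spec, ci)
    write_volume(truth$true_wg, file.path(out_dir, "truth",
                                          sprintf("%s_WG.%s", cid, format)))
    write_volume(truth$true_tz, file.path(out_dir, "truth",
                                          sprintf("%s_TZ.%s", cid, format)))
    write_volume(truth$intensity, file.path(out_dir, "truth",
                                            sprintf("%s_T2W.%s", cid, format)))
    for (ri in seq_len(nrow(spec$raters))) {
      rat <- spec$raters[ri, ]
      masks <- simulate_rater_case(truth, rat,
                                   derive_seed(spec$seed, ci, 300 + ri))
      for (st in c("WG", "TZ")) {
        fn <- sprintf("%s_%s_%s.%s", cid, rat$rater_id, st, format)
        write_volume(masks[[st]], file.path(out_dir, fn))
        rows[[length(rows) + 1]] <- data.frame(
          case_id = cid, rater_id = rat$rater_id,
          experience_group = rat$group, structure = st,
          sequence_type = spec$sequence_type, path = fn,
          stringsAsFactors = FALSE)
      }
    }
    summ[[ci]] <- data.frame(case_id = cid,
                             true_volume_cm3 = truth$true_volume_cm3,
                             target_volume_cm3 = truth$target_volume_cm3,
                             true_tz_fraction = truth$true_tz_fraction,
                             true_contrast = truth$true_contrast,
                             stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  utils::write.csv(do.call(rbind, summ),
                   file.path(out_dir, "cohort_summary.csv"), row.names = FALSE)
  message(sprintf("wrote %d masks for %d cases to %s", nrow(manifest),
                  spec$n_cases, out_dir))
  invisible(manifest)
}
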