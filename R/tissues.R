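#' Dielectric ranges of the simulated tissues at 1 GHz
#'
#' Relative permittivity and conductivity (S/m) intervals for the three
#' healthy breast tissues, malignant tissue, and the lossless coupling
#' background. Healthy-tissue ranges follow the standard large-scale
#' ex-vivo characterisation of breast tissue dielectrics; tumor tissue is
#' drawn uniformly from a narrow high-permittivity/high-conductivity band
#' sitting at and above the top of the fibro-glandular range.
#'
#' @return a tibble with columns `tissue`, `label` (integer code used in
#'   label maps), `eps_min`, `eps_max`, `sigma_min`, `sigma_max`.
#' @export
tissue_table <- function() {
  tibble::tibble(
    tissue    = c("background", "adipose", "transitional", "fibroglandular", "tumor"),
    label     = c(0L, 1L, 2L, 3L, 4L),
    eps_min   = c(15,    1,  7, 37, 57),
    eps_max   = c(15,    8, 38, 58, 63),
    sigma_min = c(0,     0, 0.11, 0.56, 1.1),
    sigma_max = c(0,  0.12, 0.58, 1.22, 1.3)
  )
}

# label codes
.LBL <- c(background = 0L, adipose = 1L, transitional = 2L,
          fibroglandular = 3L, tumor = 4L)

#' Phantom-generator configuration
#'
#' Collects every tunable of the stochastic breast-phantom generator. The
#' defaults reproduce the study conditions of the simulated database: breast
#' outline an ellipse with axis lengths uniform in \[6.5, 12\] cm and
#' orientation uniform in \[0, 2 pi); four density classes defined by the
#' fibro-glandular area fraction (A: \[5, 20)%, B: \[20, 30)%, C: \[30, 40)%,
#' D: \[40, 65\]%); tumors (one to three per pathological profile) with area
#' uniform in \[0.2, 9\] cm^2 placed strictly inside fibro-glandular tissue.
#'
#' @param grid an [grid_spec()] object.
#' @param ellipse_axis_range full axis lengths (cm) of the outer ellipse.
#' @param orientation_range ellipse orientation interval (radians).
#' @param center_jitter max |offset| (cm) of the ellipse centre from the
#'   origin (default 0: centred).
#' @param class_bins named list of fibro-glandular fraction bins (fractions,
#'   not percent). Convention: half-open `[lo, hi)` except class D closed at
#'   its upper edge.
#' @param fg_blob_count range (min, max) of fibro-glandular blobs.
#' @param fg_harmonics,fg_amplitude Fourier boundary-perturbation order and
#'   relative amplitude of the random blob shapes.
#' @param transition_width_range width (cm) of the transitional band grown
#'   around fibro-glandular regions.
#' @param tumor_count_probs probabilities of 1, 2, 3 tumors per pathological
#'   profile.
#' @param tumor_area_range tumor area interval (cm^2).
#' @param dielectric_texture `"uniform"` (independent per-pixel draws over
#'   each tissue range) or `"correlated"` (spatially smooth field mapped into
#'   the range).
#' @param texture_scale correlation length (cm) for the correlated mode.
#' @param max_retries bounded-retry limit for class-bin targeting and tumor
#'   placement.
#' @return an object of class `mwt_generator_config` (a named list).
#' @export
generator_config <- function(grid = grid_spec(15, 108),
                             ellipse_axis_range = c(6.5, 12),
                             orientation_range = c(0, 2 * pi),
                             center_jitter = 0,
                             class_bins = list(A = c(0.05, 0.20),
                                               B = c(0.20, 0.30),
                                               C = c(0.30, 0.40),
                                               D = c(0.40, 0.65)),
                             fg_blob_count = c(2L, 5L),
                             fg_harmonics = 4L,
                             fg_amplitude = 0.25,
                             transition_width_range = c(0.25, 0.7),
                             tumor_count_probs = c(0.7, 0.2, 0.1),
                             tumor_area_range = c(0.2, 9),
                             dielectric_texture = c("uniform", "correlated"),
                             texture_scale = 0.8,
                             max_retries = 100L) {
  stopifnot(inherits(grid, "mwt_grid"))
  if (diff(ellipse_axis_range) < 0 || ellipse_axis_range[1] <= 0)
    abort("`ellipse_axis_range` must be a nonempty positive interval.",
          class = "mwtomo_bad_config")
  if (max(ellipse_axis_range) > grid$side_length)
    abort("largest ellipse axis exceeds the imaging domain; no placement is possible.",
          class = "mwtomo_bad_config")
  edges <- unlist(class_bins)
  if (any(diff(edges) < 0))
    abort("class bins must be ordered and non-overlapping.", class = "mwtomo_bad_config")
  if (abs(sum(tumor_count_probs) - 1) > 1e-8 || any(tumor_count_probs < 0))
    abort("`tumor_count_probs` must be a probability vector.", class = "mwtomo_bad_config")
  if (diff(tumor_area_range) < 0 || tumor_area_range[1] <= 0)
    abort("`tumor_area_range` must be a nonempty positive interval.",
          class = "mwtomo_bad_config")
  structure(
    list(grid = grid,
         ellipse_axis_range = ellipse_axis_range,
         orientation_range = orientation_range,
         center_jitter = center_jitter,
         class_bins = class_bins,
         fg_blob_count = as.integer(fg_blob_count),
         fg_harmonics = as.integer(fg_harmonics),
         fg_amplitude = fg_amplitude,
         transition_width_range = transition_width_range,
         tumor_count_probs = tumor_count_probs,
         tumor_area_range = tumor_area_range,
         dielectric_texture = match.arg(dielectric_texture),
         texture_scale = texture_scale,
         max_retries = as.integer(max_retries)),
    class = "mwt_generator_config"
  )
}
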