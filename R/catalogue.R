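#' Land cover class catalogue
#'
#' The twelve-class scheme used throughout the pipeline, with the mapping of
#' each class to its general class. The four swamp/bog classes form the
#' Peatland general class; plantations (coconut, rubber, oil palm) form
#' Plantation; built-up and bare surface form Artificial and bare areas.
#'
#' @return a data.frame with columns `class` and `general`, one row per class,
#'   of class `class_catalogue`.
#' @export
class_catalogue <- function() {
  cat <- data.frame(
    class = c("mangrove swamp", "mixed swamp", "palm swamp", "bog plain",
              "natural forest", "sparse vegetation",
              "coconut", "rubber", "oil palm",
              "built-up", "bare surface", "water"),
    general = c(rep("Peatland", 4), "Forest", "Sparse",
                rep("Plantation", 3),
                rep("Artificial and bare areas", 2), "Hydrology"),
    stringsAsFactors = FALSE)
  class(cat) <- c("class_catalogue", "data.frame")
  cat
}

#' Names of the four peatland classes
#' @return character vector of length 4.
#' @export
peatland_classes <- function() {
  cc <- class_catalogue()
  cc$class[cc$general == "Peatland"]
}

OPTICAL_BANDS <- c("Blue", "Green", "Red", "RedEdge1", "RedEdge2", "RedEdge3",
                   "RedEdge4", "NIR", "SWIR1", "SWIR2")
# layers used only by the cloud score, analogous to the coastal-aerosol and
# cirrus detector channels of the optical instrument
CLOUD_PROXY_BANDS <- c("Aerosol", "Cirrus")
SAR_BANDS <- c("VV", "VH")

#' Per-class spectral/backscatter signature
#'
#' Encodes what makes a class separable in the simulator: mean optical
#' reflectance and its standard deviation per band, mean radar backscatter in
#' dB for VV/VH, the equivalent number of looks controlling speckle variance,
#' the elevation interval (m) where the class preferentially occurs, and the
#' per-band amplitude of a sinusoidal annual cycle.
#'
#' @param class class name (must belong to the catalogue).
#' @param optical_mean named numeric, mean reflectance in `[0, 1]` for the 10
#'   optical bands.
#' @param optical_sd per-band reflectance standard deviation (recycled).
#' @param sar_mean_db named numeric, mean backscatter (dB) for VV and VH.
#' @param speckle_looks positive number of looks (>= 1).
#' @param elevation_range_m length-2 `(low, high)` in metres.
#' @param seasonal_amplitude per-band sinusoid amplitude (recycled).
#' @return an object of class `class_signature`.
#' @export
class_signature <- function(class, optical_mean, optical_sd = 0.02,
                            sar_mean_db = c(VV = -10, VH = -16),
                            speckle_looks = 5,
                            elevation_range_m = c(0, 100),
                            seasonal_amplitude = 0.01) {
  optical_mean <- rep_len(optical_mean, length(OPTICAL_BANDS))
  names(optical_mean) <- OPTICAL_BANDS
  if (any(optical_mean < 0 | optical_mean > 1)) {
    stop("optical_mean must lie in [0, 1]", call. = FALSE)
  }
  optical_sd <- rep_len(optical_sd, length(OPTICAL_BANDS))
  if (any(optical_sd < 0)) stop("optical_sd must be >= 0", call. = FALSE)
  if (speckle_looks < 1) stop("speckle_looks must be >= 1", call. = FALSE)
  if (elevation_range_m[1] > elevation_range_m[2]) {
    stop("elevation_range_m must satisfy low <= high", call. = FALSE)
  }
  structure(list(class = class,
                 optical_mean = optical_mean,
                 optical_sd = stats::setNames(optical_sd, OPTICAL_BANDS),
                 sar_mean_db = sar_mean_db,
                 speckle_looks = speckle_looks,
                 elevation_range_m = as.numeric(elevation_range_m),
                 seasonal_amplitude = stats::setNames(
                   rep_len(seasonal_amplitude, length(OPTICAL_BANDS)),
                   OPTICAL_BANDS)),
            class = "class_signature")
}

#' Default class signatures for the simulator
#'
#' Fixture values, not estimates of any real landscape: reflectance means
#' follow broad expectations (water dark in NIR/SWIR, vegetation with a high
#' NIR plateau, bare/built-up bright in visible and SWIR), backscatter means
#' separate smooth water (low), volume-scattering forest canopies (high VH)
#' and the intermediate classes, and elevation intervals place water and the
#' peatland classes in valley bottoms, plantations and forest upslope.
#'
#' @return named list of [class_signature()] objects, one per catalogue class.
#' @export
default_signatures <- function() {
  # optical_mean order: Blue, Green, Red, RE1, RE2, RE3, RE4, NIR, SWIR1, SWIR2
  sig <- list(
    class_signature("mangrove swamp",
      c(.023, .046, .030, .065, .180, .220, .235, .245, .115, .045),
      optical_sd = .012, sar_mean_db = c(VV = -8.0, VH = -14.0),
      elevation_range_m = c(0, 6), seasonal_amplitude = .008),
    class_signature("mixed swamp",
      c(.026, .055, .038, .080, .230, .290, .305, .315, .150, .062),
      optical_sd = .013, sar_mean_db = c(VV = -7.2, VH = -12.8),
      elevation_range_m = c(1, 9), seasonal_amplitude = .010),
    class_signature("palm swamp",
      c(.030, .062, .045, .095, .260, .330, .345, .355, .175, .075),
      optical_sd = .013, sar_mean_db = c(VV = -6.8, VH = -12.0),
      elevation_range_m = c(2, 11), seasonal_amplitude = .012),
    class_signature("bog plain",
      c(.040, .080, .070, .130, .240, .280, .290, .300, .210, .110),
      optical_sd = .015, sar_mean_db = c(VV = -10.5, VH = -17.5),
      elevation_range_m = c(2, 12), seasonal_amplitude = .020),
    class_signature("natural forest",
      c(.021, .050, .032, .075, .280, .380, .400, .410, .160, .058),
      optical_sd = .012, sar_mean_db = c(VV = -7.5, VH = -12.5),
      elevation_range_m = c(18, 70), seasonal_amplitude = .008),
    class_signature("sparse vegetation",
      c(.055, .095, .110, .160, .230, .260, .270, .280, .260, .160),
      optical_sd = .018, sar_mean_db = c(VV = -11.5, VH = -18.5),
      elevation_range_m = c(6, 45), seasonal_amplitude = .030),
    class_signature("coconut",
      c(.033, .068, .052, .105, .250, .310, .325, .335, .195, .085),
      optical_sd = .013, sar_mean_db = c(VV = -8.8, VH = -14.8),
      elevation_range_m = c(4, 25), seasonal_amplitude = .010),
    class_signature("rubber",
      c(.028, .060, .042, .090, .265, .345, .360, .370, .170, .068),
      optical_sd = .013, sar_mean_db = c(VV = -8.2, VH = -13.6),
      elevation_range_m = c(12, 45), seasonal_amplitude = .025),
    class_signature("oil palm",
      c(.031, .064, .048, .100, .270, .350, .365, .375, .185, .078),
      optical_sd = .013, sar_mean_db = c(VV = -8.5, VH = -13.2),
      elevation_range_m = c(8, 38), seasonal_amplitude = .010),
    class_signature("built-up",
      c(.120, .140, .155, .170, .185, .195, .200, .205, .240, .220),
      optical_sd = .025, sar_mean_db = c(VV = -5.5, VH = -11.0),
      elevation_range_m = c(5, 35), seasonal_amplitude = .004),
    class_signature("bare surface",
      c(.095, .120, .150, .180, .210, .225, .230, .235, .310, .270),
      optical_sd = .022, sar_mean_db = c(VV = -12.0, VH = -19.5),
      elevation_range_m = c(4, 50), seasonal_amplitude = .006),
    class_signature("water",
      c(.035, .045, .030, .025, .018, .014, .012, .010, .005, .003),
      optical_sd = .006, sar_mean_db = c(VV = -17.0, VH = -24.0),
      elevation_range_m = c(0, 4), seasonal_amplitude = .003)
  )
  stats::setNames(sig, vapply(sig, function(s) s$class, ""))
}

#' Synthetic scene configuration
#'
#' Defines a simulated multi-sensor acquisition: grid size, pixel sizes,
#' numbers of optical and radar dates, cloud contamination, the per-class
#' signatures and the spatial correlation length of class patches.
#'
#' @param rows,cols grid dimensions of the analysis grid (positive).
#' @param pixel_size analysis pixel size in metres (default 20, consistent
#'   with the red-edge band resolution the classification is run at).
#' @param dem_pixel_size elevation model pixel size in metres (default 30).
#' @param n_optical number of optical acquisition dates.
#' @param n_radar number of radar acquisition dates.
#' @param cloud_fraction per-date cloudy fraction in `[0, 1]`.
#' @param seed integer random seed; the scene is a pure function of the config.
#' @param signatures named list of [class_signature()]; default
#'   [default_signatures()].
#' @param patch_scale correlation length of class patches, in pixels.
#' @param target_proportions named numeric of desired class shares (summing
#'   to 1); default equal shares. The generator calibrates per-class bias
#'   toward these targets while keeping the elevation conditioning.
#' @param relief_m total elevation range of the synthetic terrain (m).
#' @param roughness_m sd of the small-scale terrain roughness (m).
#' @return an object of class `scene_config`.
#' @export
scene_config <- function(rows = 200, cols = 200, pixel_size = 20,
                         dem_pixel_size = 30,
                         n_optical = 12, n_radar = 12,
                         cloud_fraction = 0.2, seed = 1,
                         signatures = default_signatures(),
                         patch_scale = 12,
                         target_proportions = NULL,
                         relief_m = 60, roughness_m = 4) {
  if (rows < 1 || cols < 1) stop("grid dimensions must be positive", call. = FALSE)
  if (cloud_fraction < 0 || cloud_fraction > 1) {
    stop("cloud_fraction must lie in [0, 1]", call. = FALSE)
  }
  known <- class_catalogue()$class
  bad <- setdiff(names(signatures), known)
  if (length(bad)) {
    stop(sprintf("unknown class in signatures: %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  if (length(signatures) == 0) stop("at least one signature required", call. = FALSE)
  if (is.null(target_proportions)) {
    target_proportions <- stats::setNames(
      rep(1 / length(signatures), length(signatures)), names(signatures))
  }
  if (!setequal(names(target_proportions), names(signatures))) {
    stop("target_proportions must name exactly the signature classes",
         call. = FALSE)
  }
  target_proportions <- target_proportions / sum(target_proportions)
  structure(list(rows = as.integer(rows), cols = as.integer(cols),
                 pixel_size = pixel_size, dem_pixel_size = dem_pixel_size,
                 n_optical = as.integer(n_optical), n_radar = as.integer(n_radar),
                 cloud_fraction = cloud_fraction, seed = as.integer(seed),
                 signatures = signatures, patch_scale = patch_scale,
                 target_proportions = target_proportions,
                 relief_m = relief_m, roughness_m = roughness_m),
            class = "scene_config")
}
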