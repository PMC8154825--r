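# CT Hounsfield-unit to density conversion and model-vs-reference
# comparison metrics.

#' Calibration constants for the HU-to-density conversion
#'
#' @param hu_slope_divisor HU per g/cm^3 of ash density (calibration-phantom
#'   relation `rho_ash = HU / hu_slope_divisor`).  Default 895.93.
#' @param ash_to_app_ratio Ratio `rho_ash / rho_app` between ash and
#'   apparent (dry bone) density.  Default 0.55.
#' @param clamp_negative_hu Clamp negative HU (air, marrow) to zero ash
#'   density before conversion?  Default `TRUE` (negative mass density is
#'   unphysical).
#' @return Object of class `calibration_constants`.
#' @export
calibration_constants <- function(hu_slope_divisor = 895.93,
                                  ash_to_app_ratio = 0.55,
                                  clamp_negative_hu = TRUE) {
  if (hu_slope_divisor <= 0 || ash_to_app_ratio <= 0)
    stop("calibration constants must be > 0")
  structure(list(hu_slope_divisor = hu_slope_divisor,
                 ash_to_app_ratio = ash_to_app_ratio,
                 clamp_negative_hu = clamp_negative_hu),
            class = "calibration_constants")
}

#' Convert Hounsfield units to ash density
#'
#' `rho_ash = max(HU, 0) / divisor` (negative HU clamped by default).
#'
#' @param HU Hounsfield units, finite (vectorised).
#' @param constants A [calibration_constants()].
#' @return Ash density (g/cm^3).
#' @examples
#' hu_to_ash(895.93)  # 1.0
#' @export
hu_to_ash <- function(HU, constants = calibration_constants()) {
  if (any(!is.finite(HU))) stop("HU values must be finite")
  if (constants$clamp_negative_hu) HU <- pmax(HU, 0)
  HU / constants$hu_slope_divisor
}

#' Convert ash density to apparent density
#'
#' `rho_app = rho_ash / ratio` with the fixed ash-to-apparent ratio.
#'
#' @param rho_ash Ash density (g/cm^3), >= 0 (vectorised).
#' @param constants A [calibration_constants()].
#' @return Apparent density (g/cm^3).  Values exceeding the remodelling
#'   upper bound are reported as-is: validation compares measurements, not
#'   simulation state.
#' @export
ash_to_apparent <- function(rho_ash, constants = calibration_constants()) {
  if (any(rho_ash < 0)) stop("ash density must be >= 0")
  rho_ash / constants$ash_to_app_ratio
}

# Containing femur element of each query point (barycentric test with a
# small tolerance); 0 when outside.
locate_elements <- function(mesh, points, tol = 1e-9) {
  pts <- as.matrix(points)
  femur_ids <- which(mesh$region == "FEMUR")
  n <- mesh$nodes; e <- mesh$elements
  out <- integer(nrow(pts))
  for (pi in seq_len(nrow(pts))) {
    px <- pts[pi, 1]; py <- pts[pi, 2]
    for (el in femur_ids) {
      x1 <- n[e[el, 1], 1]; y1 <- n[e[el, 1], 2]
      x2 <- n[e[el, 2], 1]; y2 <- n[e[el, 2], 2]
      x3 <- n[e[el, 3], 1]; y3 <- n[e[el, 3], 2]
      d <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
      l1 <- ((y2 - y3) * (px - x3) + (x3 - x2) * (py - y3)) / d
      l2 <- ((y3 - y1) * (px - x3) + (x1 - x3) * (py - y3)) / d
      l3 <- 1 - l1 - l2
      if (l1 >= -tol && l2 >= -tol && l3 >= -tol) {
        out[pi] <- el
        break
      }
    }
  }
  out
}

#' RMS error and mean deviation against a reference point set
#'
#' Samples the predicted elementwise density at each reference point (the
#' containing element's constant value, consistent with the elementwise
#' field) and computes the root-mean-square error and the mean absolute
#' deviation of predicted minus reference.
#'
#' @param predicted_field Density per femur element (g/cm^3).
#' @param mesh A [bone_mesh()].
#' @param reference_points Data frame with columns `x_mm`, `y_mm` and either
#'   `density_gcm3` or `hu` (converted on the fly via `constants`).
#' @param constants A [calibration_constants()] for HU conversion.
#' @return List: `rms` (g/cm^3), `mean_deviation` (g/cm^3), `n` points,
#'   `differences` (predicted - reference).
#' @export
rms_and_mean_deviation <- function(predicted_field, mesh, reference_points,
                                   constants = calibration_constants()) {
  rp <- as.data.frame(reference_points)
  if (!all(c("x_mm", "y_mm") %in% names(rp)))
    stop("reference_points needs columns x_mm, y_mm")
  if (!nrow(rp)) stop("reference point set is empty")
  ref <- if ("density_gcm3" %in% names(rp)) rp$density_gcm3
         else if ("hu" %in% names(rp))
           ash_to_apparent(hu_to_ash(rp$hu, constants), constants)
         else stop("reference_points needs a density_gcm3 or hu column")
  if (any(ref < 0)) stop("reference densities must be >= 0")
  femur <- mesh$region == "FEMUR"
  if (length(predicted_field) != sum(femur))
    stop("predicted_field must have one value per femur element")
  loc <- locate_elements(mesh, rp[, c("x_mm", "y_mm")])
  if (any(loc == 0L))
    stop("reference point(s) outside the mesh: rows ",
         paste(which(loc == 0L), collapse = ", "))
  full <- rep(NA_real_, length(femur))
  full[femur] <- predicted_field
  pred <- full[loc]
  d <- pred - ref
  list(rms = sqrt(mean(d^2)), mean_deviation = mean(abs(d)),
       n = length(d), differences = d)
}
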