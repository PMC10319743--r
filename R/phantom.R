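#' Cylindrical arm phantom
#'
#' Describes the concentric-layer arm phantom used by the forward scan model:
#' a bone core wrapped in muscle, fat and skin annuli. Default dimensions are
#' the realized-phantom values (bone radius 15 mm; muscle, fat, skin
#' thicknesses 4, 6, 2 mm, i.e. layer radii 15/19/25/27 mm; length 280 mm).
#' Layer thicknesses are the natural knobs for sensitivity scenarios (e.g.
#' skin 2 -> 2.5 mm).
#'
#' @param bone_radius_mm Bone core radius (mm).
#' @param muscle_mm,fat_mm,skin_mm Layer thicknesses (mm), all > 0.
#' @param length_mm Phantom length (mm).
#' @param tissues Tissue registry ([tissue_registry()]); dielectric overrides
#'   go through its `overrides` argument.
#' @param crack Optional [crack_spec()].
#' @return An `arm_phantom` list with `radii_mm` (named: bone, muscle, fat,
#'   skin), `length_mm`, `tissues`, `crack`.
#' @examples
#' arm_phantom()
#' arm_phantom(skin_mm = 2.5, crack = crack_spec())
#' @export
arm_phantom <- function(bone_radius_mm = 15, muscle_mm = 4, fat_mm = 6,
                        skin_mm = 2, length_mm = 280,
                        tissues = tissue_registry(), crack = NULL) {
  th <- c(bone_radius_mm, muscle_mm, fat_mm, skin_mm)
  if (any(!is.finite(th)) || any(th <= 0))
    abort("All radii/thicknesses must be finite and > 0 (degenerate phantoms with zero-thickness layers are rejected).")
  if (!is.null(crack) && !inherits(crack, "crack_spec"))
    abort("`crack` must be a crack_spec() or NULL.")
  radii <- cumsum(th)
  names(radii) <- c("bone", "muscle", "fat", "skin")
  structure(
    list(radii_mm = radii, length_mm = length_mm, tissues = tissues,
         crack = crack),
    class = "arm_phantom"
  )
}

#' @export
print.arm_phantom <- function(x, ...) {
  cat("<arm_phantom> layer radii (mm):",
      paste(names(x$radii_mm), x$radii_mm, sep = "=", collapse = ", "),
      "| length", x$length_mm, "mm\n")
  if (!is.null(x$crack)) {
    cat("  crack:", x$crack$orientation,
        if (x$crack$orientation == "inclined")
          paste0("(", x$crack$angle_deg, " deg)") else "",
        "width", x$crack$width_mm, "mm, extent", x$crack$extent_mm,
        "mm, at d0 =", x$crack$center_d_mm, "mm, alpha0 =",
        x$crack$center_alpha_deg, "deg\n")
  } else cat("  no crack (healthy)\n")
  invisible(x)
}

#' Bone-crack specification
#'
#' A crack is a thin blood-filled gap in the bone. Its orientation is stated
#' relative to the bone axis: `"transverse"` (fracture plane perpendicular to
#' the axis — modelled as a blood disc spanning the bone cross-section),
#' `"longitudinal"` (a slab along the axis at one azimuth), or `"inclined"`
#' with an angle in degrees between the two (0 = transverse, 90 =
#' longitudinal).
#'
#' @param width_mm Crack width along its discriminating axis (mm), > 0.
#' @param extent_mm Crack extent along its long axis (mm).
#' @param orientation `"transverse"`, `"longitudinal"` or `"inclined"`.
#' @param angle_deg Inclination angle in `[0, 90]`; required (meaningful) only
#'   for `"inclined"`.
#' @param center_d_mm,center_alpha_deg Crack centre in scan coordinates: axial
#'   position d (mm) and azimuth alpha (degrees).
#' @param fill Tissue filling the crack (name or one-row tissue tibble);
#'   default blood.
#' @return A `crack_spec` list.
#' @export
crack_spec <- function(width_mm = 1, extent_mm = 20,
                       orientation = c("transverse", "longitudinal", "inclined"),
                       angle_deg = 45, center_d_mm = 0, center_alpha_deg = 0,
                       fill = "blood") {
  orientation <- match.arg(orientation)
  if (!is.finite(width_mm) || width_mm <= 0) abort("`width_mm` must be > 0.")
  if (!is.finite(extent_mm) || extent_mm <= 0) abort("`extent_mm` must be > 0.")
  if (orientation == "inclined" && (angle_deg < 0 || angle_deg > 90))
    abort("`angle_deg` must lie in [0, 90].")
  structure(
    list(width_mm = width_mm, extent_mm = extent_mm,
         orientation = orientation,
         angle_deg = switch(orientation, transverse = 0,
                            longitudinal = 90, inclined = angle_deg),
         center_d_mm = center_d_mm, center_alpha_deg = center_alpha_deg,
         fill = fill),
    class = "crack_spec"
  )
}

#' Diametric transmit-receive path through the arm
#'
#' The ordered tissue segments crossed by a ray from a transmitter on one side
#' of the arm to a receiver diametrically opposite: skin, fat, muscle, the
#' full bone diameter, then muscle, fat, skin again. Segment lengths are
#' derived from the phantom radii (each annular layer is crossed twice, the
#' bone once across its diameter); the total equals the full arm diameter.
#'
#' @param phantom An [arm_phantom()].
#' @return A [layer_path()] tibble (7 segments).
#' @examples
#' sum(diametric_path(arm_phantom())$length_mm)  # 54
#' @export
diametric_path <- function(phantom) {
  stopifnot(inherits(phantom, "arm_phantom"))
  r <- phantom$radii_mm
  skin <- r[["skin"]] - r[["fat"]]
  fat <- r[["fat"]] - r[["muscle"]]
  muscle <- r[["muscle"]] - r[["bone"]]
  bone <- 2 * r[["bone"]]
  tis <- function(nm) get_tissue(nm, phantom$tissues)
  layer_path(
    bind_rows(tis("skin"), tis("fat"), tis("muscle"), tis("bone"),
              tis("muscle"), tis("fat"), tis("skin")),
    lengths_mm = c(skin, fat, muscle, bone, muscle, fat, skin),
    double_pass = FALSE
  )
}
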