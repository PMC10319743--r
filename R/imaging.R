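# Phase-difference image construction and crack-orientation classification.

wrap_deg <- function(x) {
  # wrap to (-180, 180]
  y <- (x + 180) %% 360 - 180
  ifelse(y == -180, 180, y)
}

#' Transmission-phase difference image
#'
#' Builds the 2-D image of `wrap(angle(S21_scan) - angle(S21_baseline))` over
#' the (d, alpha) grid for one polarization. The baseline is a scan of the
#' healthy (crack-free) reference; a healthy-vs-healthy pair gives the
#' all-zero image. Both datasets must share the grid and be single-frequency
#' (use [sample_at_frequency()] first if needed).
#'
#' @param dataset,baseline_dataset `scan_dataset` tibbles on matching grids.
#' @param pol Which polarization to image, `"x"` or `"y"`.
#' @return A `phase_image` object: list with `phase_deg` (matrix, rows = d,
#'   columns = alpha), `d_mm`, `alpha_deg`, `pol`, `baseline` description.
#' @export
phase_image <- function(dataset, baseline_dataset, pol = "y") {
  pol_ <- match.arg(pol, c("x", "y"))
  pick <- function(ds) {
    if (!"pol" %in% names(ds)) abort("Not a scan dataset.")
    out <- ds %>% filter(.data$pol == pol_) %>%
      arrange(.data$alpha_deg, .data$d_mm)
    if (!nrow(out)) abort(paste0("No records for polarization '", pol_, "'."))
    if (length(unique(out$freq_hz)) != 1L)
      abort("Multi-frequency dataset: restrict with sample_at_frequency() first.")
    out
  }
  a <- pick(dataset); b <- pick(baseline_dataset)
  if (nrow(a) != nrow(b) ||
      !isTRUE(all.equal(a$d_mm, b$d_mm)) ||
      !isTRUE(all.equal(a$alpha_deg, b$alpha_deg)))
    abort("Scan and baseline grids do not match.")
  d_ax <- sort(unique(a$d_mm)); al_ax <- sort(unique(a$alpha_deg))
  dphi <- wrap_deg((Arg(a$s21) - Arg(b$s21)) * 180 / pi)
  img <- matrix(dphi, nrow = length(d_ax), ncol = length(al_ax),
                dimnames = list(d_mm = d_ax, alpha_deg = al_ax))
  structure(
    list(phase_deg = img, d_mm = d_ax, alpha_deg = al_ax, pol = pol_,
         baseline = "healthy-reference phase difference"),
    class = "phase_image"
  )
}

#' @export
print.phase_image <- function(x, ...) {
  cat("<phase_image>", length(x$d_mm), "x", length(x$alpha_deg),
      "(d x alpha), pol =", x$pol,
      sprintf("| peak |dphi| = %.2f deg\n", max(abs(x$phase_deg))))
  invisible(x)
}

#' @rdname phase_image
#' @param x A `phase_image`.
#' @param ... Unused.
#' @return `tidy()`: a long tibble (`d_mm`, `alpha_deg`, `phase_diff_deg`).
#' @export
tidy.phase_image <- function(x, ...) {
  tidyr::expand_grid(alpha_deg = x$alpha_deg, d_mm = x$d_mm) %>%
    mutate(phase_diff_deg = as.vector(x$phase_deg),
           pol = x$pol) %>%
    select("d_mm", "alpha_deg", "pol", "phase_diff_deg")
}

#' Plot a phase-difference image
#'
#' @param object A `phase_image`.
#' @param ... Unused.
#' @return A ggplot raster of the phase difference over (d, alpha).
#' @export
autoplot.phase_image <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$d_mm, y = .data$alpha_deg,
                                   fill = .data$phase_diff_deg)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = expression(Delta * angle * S[21] ~ "(deg)")) +
    ggplot2::labs(
      x = "longitudinal position d (mm)", y = expression(alpha ~ "(deg)"),
      title = paste0("Transmission-phase difference image (", object$pol,
                     "-pol)")
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Classify crack presence and orientation from a dual-polarized image pair
#'
#' The per-image contrast is the peak absolute phase difference. Neither image
#' above `threshold_deg` means no crack; only the y-polarized image above
#' threshold indicates a transverse crack (azimuthal E tangential to the
#' fracture plane), only the x-polarized image a longitudinal crack, and both
#' an inclined crack. The location estimate is the argmax pixel of the
#' dominant image (for a transverse crack the blood disc spans all azimuths,
#' so only the axial coordinate d is physically identifiable).
#'
#' @param image_x,image_y `phase_image`s of the same grid for x and y
#'   polarization.
#' @param threshold_deg Detection threshold on the phase contrast (degrees).
#' @return A one-row tibble of class `crack_classification`: `orientation`
#'   (`"none"`, `"transverse"`, `"longitudinal"`, `"inclined"`), estimated
#'   `d0_mm` and `alpha0_deg` (NA when no crack), and the two contrasts.
#' @export
classify_crack <- function(image_x, image_y, threshold_deg = 2) {
  stopifnot(inherits(image_x, "phase_image"), inherits(image_y, "phase_image"))
  if (!identical(image_x$d_mm, image_y$d_mm) ||
      !identical(image_x$alpha_deg, image_y$alpha_deg))
    abort("Image grids do not match.")
  cx <- max(abs(image_x$phase_deg))
  cy <- max(abs(image_y$phase_deg))
  orientation <- if (cx < threshold_deg && cy < threshold_deg) "none"
    else if (cy >= threshold_deg && cx < threshold_deg) "transverse"
    else if (cx >= threshold_deg && cy < threshold_deg) "longitudinal"
    else "inclined"
  if (orientation == "none") {
    loc <- c(NA_real_, NA_real_)
  } else {
    dom <- if (orientation == "transverse") image_y
      else if (orientation == "longitudinal") image_x
      else if (cy >= cx) image_y else image_x
    ij <- which(abs(dom$phase_deg) == max(abs(dom$phase_deg)),
                arr.ind = TRUE)[1, ]
    loc <- c(dom$d_mm[ij[1]], dom$alpha_deg[ij[2]])
  }
  out <- tibble(
    orientation = orientation, d0_mm = loc[1], alpha0_deg = loc[2],
    contrast_x_deg = cx, contrast_y_deg = cy, threshold_deg = threshold_deg
  )
  class(out) <- c("crack_classification", class(out))
  out
}

#' @rdname classify_crack
#' @param x A `crack_classification`.
#' @param ... Unused.
#' @return `glance()`: the one-row classification tibble (without subclass).
#' @export
glance.crack_classification <- function(x, ...) {
  as_tibble(unclass(x))
}
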