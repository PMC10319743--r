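#' Human-tissue dielectric properties
#'
#' `tissue_properties()` constructs a single-tissue record; `tissue_registry()`
#' returns the built-in registry of arm tissues at 2.45 GHz (skin, fat, muscle,
#' bone, blood) as a tibble, one row per tissue.
#'
#' The registry values are the commonly tabulated arm-tissue parameters at the
#' 2.45 GHz ISM band. Each row carries the real permittivity `eps_real`, the
#' tabulated loss factor `eps_imag`, the conductivity `sigma` (S/m), the
#' one-way layer thickness `thickness_mm`, plus two reference-only columns:
#' `alpha_ref` (a previously tabulated attenuation coefficient, Np/m) and
#' `loss_fraction`, the approximate fractional power loss of a two-pass
#' traversal of the layer used by [cascade_power_budget()].
#'
#' Tabulated `eps_imag` and `sigma` are mutually inconsistent at a single
#' frequency (they come from rounded measurements); `sigma` is authoritative
#' for all propagation computations and `eps_imag` is retained as metadata.
#' Use [eps_imag_discrepancy()] to quantify the disagreement.
#'
#' @param name Tissue label.
#' @param eps_real Relative permittivity, dimensionless, >= 1.
#' @param sigma Conductivity in S/m, >= 0.
#' @param thickness_mm One-way layer thickness in mm, > 0.
#' @param eps_imag Optional tabulated loss factor; if `NA` it is derivable as
#'   `sigma / (omega * eps0)` at a given frequency.
#' @param alpha_ref Optional tabulated attenuation coefficient (Np/m), kept as
#'   metadata only.
#' @param loss_fraction Optional approximate two-pass fractional power loss in
#'   `[0, 1]`.
#' @return A one-row (or, for the registry, multi-row) tibble of class
#'   `tissue_tbl`.
#' @examples
#' tissue_registry()
#' tissue_properties("skin", eps_real = 38, sigma = 1.462, thickness_mm = 2)
#' @export
tissue_properties <- function(name, eps_real, sigma, thickness_mm,
                              eps_imag = NA_real_, alpha_ref = NA_real_,
                              loss_fraction = NA_real_) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(eps_real) || eps_real < 1)
    abort("`eps_real` must be finite and >= 1.")
  if (!is.finite(sigma) || sigma < 0)
    abort("`sigma` must be finite and >= 0.")
  if (!is.finite(thickness_mm) || thickness_mm <= 0)
    abort("`thickness_mm` must be finite and > 0.")
  if (!is.na(loss_fraction) && (loss_fraction < 0 || loss_fraction > 1))
    abort("`loss_fraction` must lie in [0, 1].")
  out <- tibble(
    tissue = name, eps_real = eps_real, eps_imag = eps_imag,
    sigma = sigma, thickness_mm = thickness_mm,
    alpha_ref = alpha_ref, loss_fraction = loss_fraction
  )
  class(out) <- c("tissue_tbl", class(out))
  out
}

#' @rdname tissue_properties
#' @param overrides Optional named list of per-tissue overrides, e.g.
#'   `list(skin = list(thickness_mm = 2.5))`.
#' @export
tissue_registry <- function(overrides = NULL) {
  reg <- bind_rows(
    tissue_properties("skin",   38,   1.462,  2, eps_imag = 11,   alpha_ref = 43.7, loss_fraction = 0.20),
    tissue_properties("fat",    5.28, 0.116,  6, eps_imag = 0.8,  alpha_ref = 8.52, loss_fraction = 0.10),
    tissue_properties("muscle", 52.7, 1.744,  4, eps_imag = 13,   alpha_ref = 43.9, loss_fraction = 0.30),
    tissue_properties("bone",   11.4, 0.39,  15, eps_imag = 3,    alpha_ref = 21.9, loss_fraction = 0.50),
    tissue_properties("blood",  58.2, 2.54,  15, eps_imag = 18.7, alpha_ref = 63.5, loss_fraction = 0.85)
  )
  if (!is.null(overrides)) {
    stopifnot(is.list(overrides))
    for (nm in names(overrides)) {
      i <- match(nm, reg$tissue)
      if (is.na(i)) abort(paste0("Unknown tissue in overrides: '", nm, "'."))
      for (fld in names(overrides[[nm]])) {
        if (!fld %in% names(reg))
          abort(paste0("Unknown tissue field in overrides: '", fld, "'."))
        reg[[fld]][i] <- overrides[[nm]][[fld]]
      }
    }
  }
  class(reg) <- c("tissue_tbl", class(reg))
  reg
}

#' Look up one tissue from a registry
#'
#' @param tissue Tissue name.
#' @param registry A `tissue_tbl`, by default [tissue_registry()].
#' @return A one-row tissue tibble.
#' @export
get_tissue <- function(tissue, registry = tissue_registry()) {
  i <- match(tissue, registry$tissue)
  if (is.na(i)) abort(paste0("Unknown tissue: '", tissue, "'."))
  registry[i, ]
}

#' Relative discrepancy between tabulated loss factor and conductivity
#'
#' At a single frequency the tabulated loss factor eps'' and the conductivity
#' sigma imply each other through eps'' = sigma / (omega * eps0). Tabulated
#' values disagree; this reports `|eps_imag - sigma/(omega eps0)| / eps_imag`
#' per tissue rather than silently reconciling the two.
#'
#' @param registry A `tissue_tbl`.
#' @param freq Frequency in Hz.
#' @return The registry with columns `eps_imag_derived` and `eps_imag_rel_disc`.
#' @export
eps_imag_discrepancy <- function(registry = tissue_registry(), freq = 2.45e9) {
  stopifnot(freq > 0)
  w <- 2 * pi * freq
  registry %>%
    mutate(
      eps_imag_derived = .data$sigma / (w * .eps0),
      eps_imag_rel_disc = ifelse(
        is.na(.data$eps_imag), NA_real_,
        abs(.data$eps_imag - .data$eps_imag_derived) / abs(.data$eps_imag)
      )
    )
}
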