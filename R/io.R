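# Scan/image CSV formats and YAML run configuration.

#' Scan dataset CSV round-trip
#'
#' Long-format CSV with columns `d_mm, alpha_deg, pol, freq_hz, s11_re,
#' s11_im, s21_re, s21_im` in full double precision and deterministic column
#' order; an empty dataset writes a header-only file.
#'
#' @param dataset A `scan_dataset` tibble.
#' @param path Output path.
#' @return `write_scan_csv()`: `path` invisibly. `read_scan_csv()`: the
#'   dataset tibble with complex `s11`, `s21` columns.
#' @export
write_scan_csv <- function(dataset, path) {
  flat <- tibble(
    d_mm = dataset$d_mm, alpha_deg = dataset$alpha_deg,
    pol = dataset$pol, freq_hz = dataset$freq_hz,
    s11_re = Re(dataset$s11), s11_im = Im(dataset$s11),
    s21_re = Re(dataset$s21), s21_im = Im(dataset$s21)
  )
  readr::write_csv(flat, path)
  invisible(path)
}

#' @rdname write_scan_csv
#' @export
read_scan_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  flat <- readr::read_csv(
    path,
    col_types = readr::cols(
      d_mm = "d", alpha_deg = "d", pol = "c", freq_hz = "d",
      s11_re = "d", s11_im = "d", s21_re = "d", s21_im = "d"
    )
  )
  out <- flat %>%
    mutate(
      s11 = complex(real = .data$s11_re, imaginary = .data$s11_im),
      s21 = complex(real = .data$s21_re, imaginary = .data$s21_im)
    ) %>%
    select("d_mm", "alpha_deg", "pol", "freq_hz", "s11", "s21")
  class(out) <- c("scan_dataset", class(out))
  out
}

#' Phase-image CSV round-trip
#'
#' Matrix layout: first column the d axis, header row the alpha axis.
#' NaN/NA-masked pixels are preserved as empty cells.
#'
#' @param image A `phase_image`.
#' @param path Output path.
#' @param pol Polarization tag used when reading (stored nowhere in the
#'   matrix file).
#' @return `write_image_csv()`: `path` invisibly. `read_image_csv()`: a
#'   `phase_image`.
#' @export
write_image_csv <- function(image, path) {
  stopifnot(inherits(image, "phase_image"))
  num <- function(x) ifelse(is.na(x), "", formatC(x, format = "g", digits = 17))
  header <- paste(c("d_mm\\alpha_deg", num(image$alpha_deg)), collapse = ",")
  rows <- vapply(seq_along(image$d_mm), function(i)
    paste(c(num(image$d_mm[i]), num(image$phase_deg[i, ])), collapse = ","),
    character(1))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_image_csv
#' @export
read_image_csv <- function(path, pol = "y") {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  lines <- readLines(path)
  split_num <- function(ln) {
    f <- strsplit(ln, ",", fixed = TRUE)[[1]]
    suppressWarnings(as.numeric(f))
  }
  alpha <- split_num(lines[1])[-1]
  body <- lapply(lines[-1], split_num)
  d <- vapply(body, `[`, numeric(1), 1)
  mat <- do.call(rbind, lapply(body, function(v) {
    row <- v[-1]
    length(row) <- length(alpha)  # trailing empty cells -> NA
    row
  }))
  dimnames(mat) <- list(d_mm = d, alpha_deg = alpha)
  structure(
    list(phase_deg = mat, d_mm = d, alpha_deg = alpha, pol = pol,
         baseline = "read from CSV"),
    class = "phase_image"
  )
}

#' Run configuration
#'
#' A serializable description of a forward-model run: frequency grid, tissue
#' overrides, phantom geometry, crack, scan grid (preset or explicit), noise
#' parameters, seed and output directory. `read_run_config()` /
#' `write_run_config()` round-trip losslessly through YAML;
#' `build_from_config()` instantiates the phantom and grid.
#'
#' @param freq_hz Frequency grid (Hz).
#' @param tissue_overrides Named list of per-tissue field overrides.
#' @param phantom Named list of [arm_phantom()] geometry arguments.
#' @param crack `NULL` or named list of [crack_spec()] arguments.
#' @param grid Either `list(preset = "sim")` or explicit `d_mm`, `alpha_deg`,
#'   `pol`.
#' @param noise_sd_amp_db,noise_sd_phase_deg Noise levels.
#' @param seed Integer seed.
#' @param out_dir Output directory.
#' @return A `run_config` list.
#' @export
run_config <- function(freq_hz = 2.45e9, tissue_overrides = NULL,
                       phantom = list(), crack = NULL,
                       grid = list(preset = "sim"),
                       noise_sd_amp_db = 0, noise_sd_phase_deg = 0,
                       seed = 1L, out_dir = ".") {
  structure(
    list(freq_hz = freq_hz, tissue_overrides = tissue_overrides,
         phantom = phantom, crack = crack, grid = grid,
         noise_sd_amp_db = noise_sd_amp_db,
         noise_sd_phase_deg = noise_sd_phase_deg,
         seed = seed, out_dir = out_dir),
    class = "run_config"
  )
}

config_fields <- c("freq_hz", "tissue_overrides", "phantom", "crack", "grid",
                   "noise_sd_amp_db", "noise_sd_phase_deg", "seed", "out_dir")

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  bad <- setdiff(names(raw), config_fields)
  if (length(bad))
    abort(paste0("Invalid config key(s): ", paste(bad, collapse = ", "), "."))
  cfg <- run_config()
  cfg[names(raw)] <- raw
  cfg
}

#' @rdname run_config
#' @param cfg A `run_config`.
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname run_config
#' @export
build_from_config <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  tissues <- tissue_registry(overrides = cfg$tissue_overrides)
  crack <- if (!is.null(cfg$crack)) do.call(crack_spec, cfg$crack)
  phantom <- do.call(arm_phantom, c(cfg$phantom,
                                    list(tissues = tissues, crack = crack)))
  grid <- if (!is.null(cfg$grid$preset)) scan_grid(cfg$grid$preset)
    else do.call(scan_grid, cfg$grid)
  list(phantom = phantom, grid = grid)
}
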