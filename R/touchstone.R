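# Touchstone v1 two-port reader/writer (.s2p). No R package on the system
# reads this interchange format, so it is implemented here: option line
# "# <unit> S <format> R <ref>", one row per frequency with S11 S21 S12 S22
# in RI, MA or DB triplets, '!' comments.

ts_unit_mult <- c(hz = 1, khz = 1e3, mhz = 1e6, ghz = 1e9)

#' Read a Touchstone v1 two-port file
#'
#' Parses a `.s2p` file: frequency unit (Hz/kHz/MHz/GHz) and data format
#' (RI, MA or DB) are honoured from the option line; data rows carry
#' S11, S21, S12, S22 (Touchstone two-port column order) as value pairs.
#' Malformed option or data lines raise an error naming the line number.
#'
#' @param path File path.
#' @return A tibble with `freq_hz` and complex `s11`, `s21`, `s12`, `s22`;
#'   attribute `z0` holds the reference impedance.
#' @export
read_touchstone <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- sub("!.*$", "", lines)
  keep <- which(trimws(lines) != "")
  unit <- "ghz"; fmt <- "ma"; z0 <- 50
  data_rows <- list()
  for (i in keep) {
    ln <- trimws(lines[i])
    if (startsWith(ln, "#")) {
      toks <- tolower(strsplit(trimws(sub("^#", "", ln)), "\\s+")[[1]])
      if (length(toks) > 0 && toks[1] %in% names(ts_unit_mult)) unit <- toks[1]
      else if (length(toks) > 0)
        abort(paste0("Line ", i, ": unknown frequency unit '", toks[1], "'."))
      if (length(toks) >= 2 && toks[2] != "s")
        abort(paste0("Line ", i, ": only S-parameter files are supported."))
      if (length(toks) >= 3) {
        if (!toks[3] %in% c("ri", "ma", "db"))
          abort(paste0("Line ", i, ": unknown format '", toks[3], "'."))
        fmt <- toks[3]
      }
      ri <- match("r", toks)
      if (!is.na(ri) && length(toks) > ri) z0 <- as.numeric(toks[ri + 1])
      next
    }
    vals <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1]]))
    if (length(vals) != 9L || anyNA(vals))
      abort(paste0("Line ", i, ": expected 9 numeric fields (freq + 4 S pairs), got '",
                   lines[i], "'."))
    data_rows[[length(data_rows) + 1L]] <- vals
  }
  if (!length(data_rows)) abort(paste0("No data rows in ", path))
  m <- do.call(rbind, data_rows)
  pair_to_c <- function(a, b) {
    switch(fmt,
      ri = complex(real = a, imaginary = b),
      ma = complex(modulus = a, argument = b * pi / 180),
      db = complex(modulus = 10^(a / 20), argument = b * pi / 180)
    )
  }
  out <- tibble(
    freq_hz = m[, 1] * ts_unit_mult[[unit]],
    s11 = pair_to_c(m[, 2], m[, 3]),
    s21 = pair_to_c(m[, 4], m[, 5]),
    s12 = pair_to_c(m[, 6], m[, 7]),
    s22 = pair_to_c(m[, 8], m[, 9])
  )
  attr(out, "z0") <- z0
  out
}

#' Write a Touchstone v1 two-port file
#'
#' Writes `# GHz S RI R 50` files (frequency in GHz, real/imaginary pairs) in
#' full double precision, so [read_touchstone()] round-trips bit-identically.
#'
#' @param records Tibble with `freq_hz` and complex `s11`, `s21`, `s12`,
#'   `s22` (missing S columns are written as zeros).
#' @param path Output path.
#' @param z0 Reference impedance (ohms).
#' @return `path`, invisibly.
#' @export
write_touchstone <- function(records, path, z0 = 50) {
  stopifnot(is.data.frame(records), "freq_hz" %in% names(records))
  get_col <- function(nm) {
    if (nm %in% names(records)) as.complex(records[[nm]])
    else rep(0 + 0i, nrow(records))
  }
  cols <- lapply(c("s11", "s21", "s12", "s22"), get_col)
  num <- function(x) formatC(x, format = "g", digits = 17)
  rows <- vapply(seq_len(nrow(records)), function(i) {
    paste(c(num(records$freq_hz[i] / 1e9),
            unlist(lapply(cols, function(cc) c(num(Re(cc[i])), num(Im(cc[i])))))),
          collapse = " ")
  }, character(1))
  writeLines(c("! two-port S-parameters", paste("# GHz S RI R", z0), rows),
             path)
  invisible(path)
}
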