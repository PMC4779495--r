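## Plain-text spectrum/curve CSV I/O and ENVI-style cube I/O (text header +
## raw binary).  CSV formats: spectra carry a "# kind=..." comment line above
## a "wavelength_nm,value" header; absorption curves use the header
## "wavelength_nm,mu_a_per_cm", one file per chromophore.

#' Read and write spectrum CSV files
#'
#' A spectrum CSV holds a `# kind=<kind>` comment line, a
#' `wavelength_nm,value` header, and one row per band (UTF-8, `.` decimal
#' separator).  Reading enforces the grid invariants and reports the
#' offending line on failure.
#'
#' @param path CSV file path.
#' @param spec a [spectrum].
#' @return `read_spectrum_csv` returns a [spectrum]; `write_spectrum_csv`
#'   returns `path` invisibly.
#' @export
read_spectrum_csv <- function(path) {
  if (!file.exists(path)) stop_data("spectrum file not found: %s", path)
  lines <- readLines(path)
  kind_line <- grep("^#\\s*kind=", lines)
  if (length(kind_line) == 0)
    stop_data("%s: missing '# kind=<kind>' comment line", path)
  kind <- sub("^#\\s*kind=\\s*", "", lines[kind_line[1]])
  kind <- trimws(kind)
  if (!kind %in% SPECTRUM_KINDS)
    stop_data("%s: unknown spectrum kind '%s' (line %d)", path, kind, kind_line[1])
  body <- grep("^#", lines, invert = TRUE)
  body <- body[nzchar(trimws(lines[body]))]
  if (length(body) < 2L) stop_data("%s: no data rows", path)
  header <- strsplit(trimws(lines[body[1]]), ",")[[1]]
  if (!identical(trimws(header), c("wavelength_nm", "value")))
    stop_data("%s: expected header 'wavelength_nm,value' on line %d",
              path, body[1])
  rows <- body[-1]
  parts <- strsplit(lines[rows], ",")
  for (i in seq_along(parts))
    if (length(parts[[i]]) != 2L)
      stop_data("%s: malformed row on line %d", path, rows[i])
  wl <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 1L)))
  v <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 2L)))
  if (anyNA(wl) || anyNA(v)) {
    i <- which(is.na(wl) | is.na(v))[1]
    stop_data("%s: non-numeric value on line %d", path, rows[i])
  }
  if (any(diff(wl) <= 0)) {
    i <- which(diff(wl) <= 0)[1] + 1L
    stop_data("%s: wavelengths not strictly increasing at line %d (%.6g after %.6g)",
              path, rows[i], wl[i], wl[i - 1L])
  }
  spectrum(wl, v, kind)
}

#' @rdname read_spectrum_csv
#' @export
write_spectrum_csv <- function(spec, path) {
  stopifnot(inherits(spec, "spectrum"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# kind=%s", spec$kind), con)
  writeLines("wavelength_nm,value", con)
  writeLines(sprintf("%.10g,%.10g", spec$wavelength, spec$value), con)
  invisible(path)
}

#' Read and write absorption-curve CSV files
#'
#' One file per chromophore with header `wavelength_nm,mu_a_per_cm`.  The
#' chromophore label defaults to the file's base name (e.g. `water.csv`).
#'
#' @param path CSV file path.
#' @param curve an [absorption_curve].
#' @param chromophore label; default taken from the file name.
#' @return `read_absorption_csv` returns an [absorption_curve];
#'   `write_absorption_csv` returns `path` invisibly.
#' @export
read_absorption_csv <- function(path, chromophore = NULL) {
  if (!file.exists(path)) stop_data("absorption-curve file not found: %s", path)
  lines <- readLines(path)
  body <- grep("^#", lines, invert = TRUE)
  body <- body[nzchar(trimws(lines[body]))]
  if (length(body) < 2L) stop_data("%s: no data rows", path)
  header <- trimws(strsplit(trimws(lines[body[1]]), ",")[[1]])
  if (!identical(header, c("wavelength_nm", "mu_a_per_cm")))
    stop_data("%s: expected header 'wavelength_nm,mu_a_per_cm' on line %d",
              path, body[1])
  rows <- body[-1]
  parts <- strsplit(lines[rows], ",")
  wl <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 1L)))
  mu <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 2L)))
  if (anyNA(wl) || anyNA(mu)) {
    i <- which(is.na(wl) | is.na(mu))[1]
    stop_data("%s: non-numeric value on line %d", path, rows[i])
  }
  if (any(diff(wl) <= 0)) {
    i <- which(diff(wl) <= 0)[1] + 1L
    stop_data("%s: wavelengths not strictly increasing at line %d", path, rows[i])
  }
  if (is.null(chromophore))
    chromophore <- tools::file_path_sans_ext(basename(path))
  absorption_curve(wl, mu, chromophore)
}

#' @rdname read_absorption_csv
#' @export
write_absorption_csv <- function(curve, path) {
  stopifnot(inherits(curve, "absorption_curve"))
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines("wavelength_nm,mu_a_per_cm", con)
  writeLines(sprintf("%.10g,%.10g", curve$wavelength, curve$value), con)
  invisible(path)
}

#' Read a directory of chromophore curves
#'
#' Loads `water.csv`, `protein.csv` and `fat.csv` from `dir` into the named
#' list the mixing and simulation functions expect.
#'
#' @param dir directory containing the three CSV files.
#' @return named list of [absorption_curve]s.
#' @export
read_curve_dir <- function(dir) {
  need <- c("water", "protein", "fat")
  paths <- file.path(dir, paste0(need, ".csv"))
  missing <- !file.exists(paths)
  if (any(missing))
    stop_data("curve directory %s is missing: %s", dir,
              paste(basename(paths[missing]), collapse = ", "))
  stats::setNames(lapply(seq_along(need), function(i)
    read_absorption_csv(paths[i], need[i])), need)
}

#' Read a composition table CSV
#'
#' Header `water,protein,fat`, one sample per row (mass fractions).
#'
#' @param path CSV file path.
#' @return list of [composition] objects (named by row if a `sample` column
#'   is present).
#' @export
read_composition_csv <- function(path) {
  if (!file.exists(path)) stop_data("composition file not found: %s", path)
  df <- utils::read.csv(path, comment.char = "#")
  need <- c("water", "protein", "fat")
  if (!all(need %in% names(df)))
    stop_data("%s: composition table needs columns water, protein, fat", path)
  out <- lapply(seq_len(nrow(df)), function(i)
    composition(df$water[i], df$protein[i], df$fat[i]))
  names(out) <- if ("sample" %in% names(df)) as.character(df$sample)
                else paste0("sample", seq_len(nrow(df)))
  out
}

#' @rdname read_composition_csv
#' @param compositions list of [composition] objects.
#' @export
write_composition_csv <- function(compositions, path) {
  if (inherits(compositions, "composition")) compositions <- list(compositions)
  df <- data.frame(
    sample = names(compositions) %||% paste0("sample", seq_along(compositions)),
    water = vapply(compositions, `[[`, numeric(1), "water"),
    protein = vapply(compositions, `[[`, numeric(1), "protein"),
    fat = vapply(compositions, `[[`, numeric(1), "fat"))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

## ---- ENVI cube I/O ---------------------------------------------------------
## Header: text key=value file `<base>.hdr`; data: raw binary `<base>.img`.
## Supported data types: 4 (float32), 5 (float64), 12 (uint16); interleaves
## BSQ and BIL; little-endian only (byte order = 0).

envi_dtype <- function(code) {
  switch(as.character(code),
         "4" = list(what = "double", size = 4L, signed = TRUE),
         "5" = list(what = "double", size = 8L, signed = TRUE),
         "12" = list(what = "integer", size = 2L, signed = FALSE),
         stop_data("unsupported ENVI data type %s (supported: 4, 5, 12)", code))
}

#' Write a hyperspectral cube in ENVI format
#'
#' Writes `<base>.hdr` (text header with the wavelength array) and
#' `<base>.img` (raw little-endian binary).  DV cubes are stored as unsigned
#' 16-bit integers (ENVI data type 12) with the bit depth recorded in the
#' header; reflectance/absorbance cubes as 64-bit floats (type 5) so
#' round-trips are lossless.
#'
#' @param cube a `hyper_cube`.
#' @param base path without extension.
#' @param interleave `"bsq"` (band-sequential) or `"bil"`
#'   (band-interleaved-by-line).
#' @return `base`, invisibly.
#' @export
write_envi <- function(cube, base, interleave = c("bsq", "bil")) {
  stopifnot(inherits(cube, "hyper_cube"))
  interleave <- match.arg(interleave)
  d <- dim(cube$data)   # (rows, cols, bands)
  dtype <- if (cube$kind == "dv") 12L else 5L
  hdr <- c(
    "ENVI",
    "description = { nirsim hyperspectral cube }",
    sprintf("samples = %d", d[2]),
    sprintf("lines = %d", d[1]),
    sprintf("bands = %d", d[3]),
    "header offset = 0",
    "file type = ENVI Standard",
    sprintf("data type = %d", dtype),
    sprintf("interleave = %s", interleave),
    "byte order = 0",
    "wavelength units = Nanometers",
    sprintf("cube kind = %s", cube$kind),
    if (!is.null(cube$bit_depth)) sprintf("data bit depth = %d", cube$bit_depth),
    sprintf("wavelength = { %s }", paste(sprintf("%.10g", cube$wavelength),
                                         collapse = ", ")))
  writeLines(hdr, paste0(base, ".hdr"))
  ## reorder to on-disk order: bsq = [sample, line, band]; bil = [sample, band, line]
  arr <- if (interleave == "bsq") aperm(cube$data, c(2, 1, 3))
         else aperm(cube$data, c(2, 3, 1))
  con <- file(paste0(base, ".img"), "wb")
  on.exit(close(con))
  t <- envi_dtype(dtype)
  if (t$what == "integer")
    writeBin(as.integer(arr), con, size = t$size, endian = "little")
  else
    writeBin(as.numeric(arr), con, size = t$size, endian = "little")
  invisible(base)
}

parse_envi_header <- function(hdr_path) {
  lines <- readLines(hdr_path)
  txt <- paste(lines, collapse = "\n")
  vals <- list()
  ## match "key = value" where value may be a { } block spanning lines
  pat <- "(?m)^\\s*([a-zA-Z][a-zA-Z0-9 _]*?)\\s*=\\s*(\\{[^}]*\\}|[^\n]*)"
  m <- gregexpr(pat, txt, perl = TRUE)[[1]]
  if (m[1] == -1) stop_data("%s: no key = value entries found", hdr_path)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  for (i in seq_along(starts)) {
    entry <- substr(txt, starts[i], starts[i] + lens[i] - 1L)
    key <- trimws(sub("=.*$", "", entry))
    val <- trimws(sub("^[^=]*=", "", entry))
    vals[[tolower(key)]] <- val
  }
  vals
}

#' Read a hyperspectral cube in ENVI format
#'
#' Counterpart of [write_envi()]; accepts a path with or without the `.hdr`
#' extension.  A JSON sidecar layout (`{rows, cols, bands, dtype,
#' interleave, wavelengths}` next to a flat `.img`) is also accepted via
#' [read_flat_cube()].
#'
#' @param base path without extension (or the `.hdr` path).
#' @return a `hyper_cube`.
#' @export
read_envi <- function(base) {
  base <- sub("\\.hdr$", "", base)
  hdr_path <- paste0(base, ".hdr")
  img_path <- paste0(base, ".img")
  if (!file.exists(hdr_path)) stop_data("ENVI header not found: %s", hdr_path)
  if (!file.exists(img_path)) stop_data("ENVI data file not found: %s", img_path)
  h <- parse_envi_header(hdr_path)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  for (k in need)
    if (is.null(h[[k]])) stop_data("%s: missing header field '%s'", hdr_path, k)
  cols <- as.integer(h$samples); rows <- as.integer(h$lines)
  bands <- as.integer(h$bands)
  if (!is.null(h[["byte order"]]) && as.integer(h[["byte order"]]) != 0L)
    stop_data("%s: only little-endian (byte order = 0) is supported", hdr_path)
  interleave <- tolower(h$interleave)
  if (!interleave %in% c("bsq", "bil"))
    stop_data("%s: unsupported interleave '%s' (bsq or bil)", hdr_path, interleave)
  t <- envi_dtype(as.integer(h[["data type"]]))
  wl <- if (!is.null(h$wavelength)) {
    as.numeric(strsplit(gsub("[{}]", "", h$wavelength), ",")[[1]])
  } else stop_data("%s: missing wavelength array", hdr_path)
  if (length(wl) != bands)
    stop_data("%s: wavelength array has %d entries for %d bands",
              hdr_path, length(wl), bands)
  n <- rows * cols * bands
  con <- file(img_path, "rb")
  on.exit(close(con))
  raw <- readBin(con, t$what, n = n, size = t$size, signed = t$signed,
                 endian = "little")
  if (length(raw) != n)
    stop_data("%s: expected %d values, read %d", img_path, n, length(raw))
  data <- if (interleave == "bsq") aperm(array(raw, c(cols, rows, bands)), c(2, 1, 3))
          else aperm(array(raw, c(cols, bands, rows)), c(3, 1, 2))
  kind <- h[["cube kind"]] %||% if (t$what == "integer") "dv" else "reflectance"
  if (kind == "dv") {
    bd <- as.integer(h[["data bit depth"]] %||% "12")
    dv_cube(data, wl, bd)
  } else cube_new(data, wl, kind)
}

#' Read a flat binary cube with a JSON sidecar
#'
#' Fallback cube format: a raw little-endian binary file next to a JSON
#' sidecar `<base>.json` with fields `rows`, `cols`, `bands`, `dtype`
#' (`"float64"` or `"uint16"`), `interleave` (`"bsq"`/`"bil"`),
#' `wavelengths`, and optionally `kind` and `bit_depth`.
#'
#' @param base path without extension; expects `<base>.json` and
#'   `<base>.img`.
#' @return a `hyper_cube`.
#' @export
read_flat_cube <- function(base) {
  js_path <- paste0(base, ".json")
  img_path <- paste0(base, ".img")
  if (!file.exists(js_path)) stop_data("sidecar not found: %s", js_path)
  meta <- jsonlite::read_json(js_path, simplifyVector = TRUE)
  dtype <- switch(meta$dtype,
                  float64 = list(what = "double", size = 8L, signed = TRUE),
                  uint16 = list(what = "integer", size = 2L, signed = FALSE),
                  stop_data("%s: unsupported dtype '%s'", js_path, meta$dtype))
  n <- meta$rows * meta$cols * meta$bands
  con <- file(img_path, "rb")
  on.exit(close(con))
  raw <- readBin(con, dtype$what, n = n, size = dtype$size,
                 signed = dtype$signed, endian = "little")
  if (length(raw) != n)
    stop_data("%s: expected %d values, read %d", img_path, n, length(raw))
  data <- if (tolower(meta$interleave) == "bsq")
    aperm(array(raw, c(meta$cols, meta$rows, meta$bands)), c(2, 1, 3))
  else aperm(array(raw, c(meta$cols, meta$bands, meta$rows)), c(3, 1, 2))
  kind <- meta$kind %||% if (dtype$what == "integer") "dv" else "reflectance"
  if (kind == "dv") dv_cube(data, meta$wavelengths, meta$bit_depth %||% 12)
  else cube_new(data, meta$wavelengths, kind)
}
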