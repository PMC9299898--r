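# Containers and file I/O for temperature-resolved CD / absorbance spectra.
#
# A spectral series is stored long: one row per (wavelength, temperature)
# pair, with the measurement columns `cd` (delta-epsilon per residue) and
# optionally `absorbance`. Metadata (construct label, repeat count, path
# length, residue molarity, current CD unit) live in the "meta" attribute.

#' Conversion factor between mean residue ellipticity and delta-epsilon
#'
#' `theta_MRE = 3298.2 * delta_epsilon` (deg cm^2 dmol^-1 per M^-1 cm^-1).
#' @export
MRE_PER_DELTA_EPSILON <- 3298.2

.WL_RANGE <- c(170, 320)   # nm, plausible far-UV CD window
.T_RANGE <- c(250, 400)    # K

#' Construct a temperature-resolved spectral series
#'
#' @param wavelengths Strictly ascending wavelengths in nm (170--320).
#' @param temperatures Strictly ascending temperatures in kelvin (250--400).
#' @param cd Numeric matrix `length(wavelengths) x length(temperatures)` of CD
#'   values (delta-epsilon per residue, M^-1 cm^-1, unless `meta$unit` says
#'   otherwise).
#' @param absorbance Optional absorbance matrix of the same shape.
#' @param meta Named list of metadata. Recognised fields: `construct`,
#'   `n_repeats`, `path_cm`, `residue_molarity`, `unit` (one of
#'   `"delta_epsilon"`, `"mean_residue_ellipticity"`, `"millidegrees"`;
#'   default `"delta_epsilon"`), `seed`.
#'
#' @return A tibble of class `cd_series` with columns `wavelength_nm`,
#'   `temperature_K`, `cd` and, when supplied, `absorbance`.
#' @export
#' @examples
#' s <- spectral_series(c(200, 210), c(283.15, 293.15),
#'                      cd = matrix(c(-1, -2, -0.5, -1.5), nrow = 2))
#' series_matrix(s)
spectral_series <- function(wavelengths, temperatures, cd, absorbance = NULL,
                            meta = list()) {
  wavelengths <- as.numeric(wavelengths)
  temperatures <- as.numeric(temperatures)
  cd <- as.matrix(cd)
  if (!is.null(absorbance)) absorbance <- as.matrix(absorbance)
  if (is.null(meta$unit)) meta$unit <- "delta_epsilon"

  tbl <- tibble::tibble(
    wavelength_nm = rep(wavelengths, times = length(temperatures)),
    temperature_K = rep(temperatures, each = length(wavelengths)),
    cd = as.vector(cd)
  )
  if (!is.null(absorbance)) tbl$absorbance <- as.vector(absorbance)
  out <- new_cd_series(tbl, meta)
  validate_cd_series(out, n_wl = length(wavelengths), n_t = length(temperatures),
                     cd_len = length(cd),
                     abs_len = if (is.null(absorbance)) NULL else length(absorbance))
  out
}

new_cd_series <- function(tbl, meta = list()) {
  structure(tbl, meta = meta,
            class = c("cd_series", class(tibble::tibble())))
}

validate_cd_series <- function(x, n_wl = NULL, n_t = NULL, cd_len = NULL,
                               abs_len = NULL) {
  wl <- series_wavelengths(x)
  tk <- series_temperatures(x)
  if (!is.null(n_wl) && length(wl) != n_wl)
    stop("duplicate wavelengths in series", call. = FALSE)
  if (!is.null(n_t) && length(tk) != n_t)
    stop("duplicate temperatures in series", call. = FALSE)
  if (!is.null(cd_len) && cd_len != length(wl) * length(tk))
    stop("cd matrix shape does not match wavelength/temperature grids",
         call. = FALSE)
  if (!is.null(abs_len) && abs_len != length(wl) * length(tk))
    stop("absorbance matrix shape does not match the CD block", call. = FALSE)
  if (any(!is.finite(x$cd)))
    stop("non-finite CD values in series", call. = FALSE)
  if (!is.null(x[["absorbance"]]) && any(!is.finite(x[["absorbance"]])))
    stop("non-finite absorbance values in series", call. = FALSE)
  if (any(wl < .WL_RANGE[1] | wl > .WL_RANGE[2]))
    stop(sprintf("wavelengths outside [%g, %g] nm", .WL_RANGE[1], .WL_RANGE[2]),
         call. = FALSE)
  if (any(tk < .T_RANGE[1] | tk > .T_RANGE[2]))
    stop(sprintf("temperatures outside [%g, %g] K", .T_RANGE[1], .T_RANGE[2]),
         call. = FALSE)
  invisible(x)
}

#' @rdname spectral_series
#' @param x A `cd_series`.
#' @export
series_wavelengths <- function(x) sort(unique(x$wavelength_nm))

#' @rdname spectral_series
#' @export
series_temperatures <- function(x) sort(unique(x$temperature_K))

#' @rdname spectral_series
#' @param field `"cd"` or `"absorbance"`.
#' @export
series_matrix <- function(x, field = "cd") {
  if (is.null(x[[field]]))
    stop(sprintf("series has no '%s' block", field), call. = FALSE)
  wl <- series_wavelengths(x)
  tk <- series_temperatures(x)
  o <- order(x$temperature_K, x$wavelength_nm)
  matrix(x[[field]][o], nrow = length(wl), ncol = length(tk),
         dimnames = list(NULL, NULL))
}

#' @rdname spectral_series
#' @export
series_meta <- function(x) attr(x, "meta") %||% list()

#' Construct a single basis spectrum
#'
#' A basis spectrum is a pure-species (or derived) spectrum on a wavelength
#' grid: the resolved CD or absorptivity spectrum of one conformational
#' species, or a simulated differential-scattering spectrum.
#'
#' @param wavelengths Strictly ascending wavelengths, nm.
#' @param values Numeric values, same length.
#' @param label Species name, e.g. `"disordered"`, `"beta_turn"`, `"assembly"`.
#' @param kind One of `"cd"`, `"absorbance"`, `"scattering"`.
#' @return A tibble of class `cd_basis` with columns `wavelength_nm`, `value`.
#' @export
basis_spectrum <- function(wavelengths, values, label, kind = "cd") {
  wavelengths <- as.numeric(wavelengths)
  values <- as.numeric(values)
  if (length(wavelengths) != length(values))
    stop("wavelengths and values differ in length", call. = FALSE)
  if (is.unsorted(wavelengths, strictly = TRUE))
    stop("wavelengths must be strictly ascending", call. = FALSE)
  if (!nzchar(label)) stop("label must be nonempty", call. = FALSE)
  kind <- match.arg(kind, c("cd", "absorbance", "scattering"))
  if (any(!is.finite(values))) stop("non-finite basis values", call. = FALSE)
  structure(tibble::tibble(wavelength_nm = wavelengths, value = values),
            label = label, kind = kind,
            class = c("cd_basis", class(tibble::tibble())))
}

#' @rdname basis_spectrum
#' @param x A `cd_basis`.
#' @export
basis_label <- function(x) attr(x, "label")

#' @rdname basis_spectrum
#' @export
basis_kind <- function(x) attr(x, "kind")

# --- delimited-text parsing ------------------------------------------------

.detect_delim <- function(line, line_no = NA) {
  counts <- c("\t" = lengths(regmatches(line, gregexpr("\t", line, fixed = TRUE))),
              "," = lengths(regmatches(line, gregexpr(",", line, fixed = TRUE))),
              ";" = lengths(regmatches(line, gregexpr(";", line, fixed = TRUE))))
  if (all(counts == 0))
    stop(sprintf(paste("malformed header on line %s: no tab/comma/semicolon",
                       "delimiter found"), line_no), call. = FALSE)
  names(counts)[which.max(counts)]
}

.num_or_stop <- function(x, line_no, what = "cell") {
  v <- suppressWarnings(as.numeric(x))
  if (any(is.na(v) | !is.finite(v)))
    stop(sprintf("non-numeric %s on line %d", what, line_no), call. = FALSE)
  v
}

# Parse one wide block: header (wavelength label + temperatures in degC) plus
# data rows. `lines` carries attribute-free text; `line_nos` the file line
# numbers for error messages.
.parse_wide_block <- function(lines, line_nos, delim) {
  header <- strsplit(lines[1], delim, fixed = TRUE)[[1]]
  if (length(header) < 2)
    stop(sprintf("malformed header on line %d", line_nos[1]), call. = FALSE)
  temps_c <- .num_or_stop(header[-1], line_nos[1], "header temperature")
  rows <- lapply(seq_along(lines)[-1], function(i) {
    f <- strsplit(lines[i], delim, fixed = TRUE)[[1]]
    if (length(f) != length(header))
      stop(sprintf("wrong field count on line %d", line_nos[i]), call. = FALSE)
    .num_or_stop(f, line_nos[i])
  })
  m <- do.call(rbind, rows)
  wl <- m[, 1]
  if (anyDuplicated(wl)) {
    dup <- which(duplicated(wl))[1]
    stop(sprintf("duplicate wavelength %g on line %d", wl[dup],
                 line_nos[-1][dup]), call. = FALSE)
  }
  list(wavelengths = wl, temperatures_C = temps_c, values = m[, -1, drop = FALSE])
}

#' Read a temperature-resolved spectral series from delimited text
#'
#' Two layouts are supported. *Wide*: header row `wavelength_nm` followed by
#' temperatures in degrees Celsius, one row per wavelength; an optional
#' absorbance block is introduced by a `# block=absorbance` marker line (the
#' CD block may carry `# block=cd`). *Long*: columns `wavelength_nm`,
#' `temperature_C`, `cd_delta_epsilon` and optionally `absorbance`, any row
#' order. The delimiter is auto-detected among tab, comma and semicolon.
#' Temperatures are converted to kelvin (`K = degC + 273.15`) and rows and
#' columns sorted ascending.
#'
#' @param path File path.
#' @param layout `"wide"` or `"long"`.
#' @param meta Metadata list passed on to [spectral_series()].
#' @return A [spectral_series()] tibble.
#' @export
read_spectral_series <- function(path, layout = c("wide", "long"), meta = list()) {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(raw))
  lines <- raw[keep]
  line_nos <- which(keep)
  if (length(lines) < 2) stop("file too short to contain a spectral series",
                              call. = FALSE)
  if (layout == "wide") {
    is_marker <- grepl("^#\\s*block=", lines)
    block_id <- cumsum(is_marker)
    if (!any(is_marker)) block_id <- rep(1L, length(lines))
    blocks <- split(seq_along(lines), block_id)
    blocks <- blocks[vapply(blocks, function(ix) any(!is_marker[ix]), logical(1))]
    parsed <- list()
    for (ix in blocks) {
      mk <- ix[is_marker[ix]]
      name <- if (length(mk)) sub("^#\\s*block=\\s*", "", trimws(lines[mk[1]])) else "cd"
      body <- ix[!is_marker[ix]]
      delim <- .detect_delim(lines[body[1]], line_nos[body[1]])
      parsed[[name]] <- .parse_wide_block(lines[body], line_nos[body], delim)
    }
    if (is.null(parsed$cd)) stop("no CD block found in wide file", call. = FALSE)
    cdb <- parsed$cd
    ord_w <- order(cdb$wavelengths); ord_t <- order(cdb$temperatures_C)
    cd <- cdb$values[ord_w, ord_t, drop = FALSE]
    absorb <- NULL
    if (!is.null(parsed$absorbance)) {
      ab <- parsed$absorbance
      if (!identical(dim(ab$values), dim(cdb$values)) ||
          max(abs(sort(ab$wavelengths) - sort(cdb$wavelengths))) > 1e-9 ||
          max(abs(sort(ab$temperatures_C) - sort(cdb$temperatures_C))) > 1e-9)
        stop("absorbance block does not match the CD block grids", call. = FALSE)
      absorb <- ab$values[order(ab$wavelengths), order(ab$temperatures_C),
                          drop = FALSE]
    }
    spectral_series(cdb$wavelengths[ord_w], cdb$temperatures_C[ord_t] + 273.15,
                    cd, absorb, meta)
  } else {
    delim <- .detect_delim(lines[1], line_nos[1])
    header <- strsplit(lines[1], delim, fixed = TRUE)[[1]]
    need <- c("wavelength_nm", "temperature_C", "cd_delta_epsilon")
    if (!all(need %in% header))
      stop(sprintf("malformed header on line %d: need columns %s",
                   line_nos[1], paste(need, collapse = ", ")), call. = FALSE)
    rows <- lapply(seq_along(lines)[-1], function(i) {
      f <- strsplit(lines[i], delim, fixed = TRUE)[[1]]
      if (length(f) != length(header))
        stop(sprintf("wrong field count on line %d", line_nos[i]), call. = FALSE)
      .num_or_stop(f, line_nos[i])
    })
    m <- do.call(rbind, rows)
    colnames(m) <- header
    tbl <- tibble::as_tibble(m)
    if (anyDuplicated(tbl[c("wavelength_nm", "temperature_C")]))
      stop("duplicate (wavelength, temperature) rows in long file", call. = FALSE)
    wl <- sort(unique(tbl$wavelength_nm))
    tc <- sort(unique(tbl$temperature_C))
    if (nrow(tbl) != length(wl) * length(tc))
      stop("long file is not a complete wavelength x temperature grid",
           call. = FALSE)
    o <- order(tbl$temperature_C, tbl$wavelength_nm)
    cd <- matrix(tbl$cd_delta_epsilon[o], nrow = length(wl))
    absorb <- if ("absorbance" %in% header)
      matrix(tbl$absorbance[o], nrow = length(wl)) else NULL
    spectral_series(wl, tc + 273.15, cd, absorb, meta)
  }
}

#' Write a spectral series to delimited text
#'
#' Inverse of [read_spectral_series()]; round-trips to within 1e-12 relative
#' tolerance (values are written with 17 significant digits).
#'
#' @param series A `cd_series`.
#' @param path Output path.
#' @param layout `"wide"` or `"long"`.
#' @param delim Field delimiter (default tab).
#' @return `path`, invisibly.
#' @export
write_spectral_series <- function(series, path, layout = c("wide", "long"),
                                  delim = "\t") {
  layout <- match.arg(layout)
  wl <- series_wavelengths(series)
  tk <- series_temperatures(series)
  tc <- tk - 273.15
  cd <- series_matrix(series, "cd")
  has_abs <- !is.null(series[["absorbance"]])
  fmt <- function(x) formatC(x, format = "g", digits = 17)
  lines <- character(0)
  if (layout == "wide") {
    wide_block <- function(m) {
      c(paste(c("wavelength_nm", fmt(tc)), collapse = delim),
        vapply(seq_along(wl), function(i)
          paste(fmt(c(wl[i], m[i, ])), collapse = delim), character(1)))
    }
    if (has_abs) {
      lines <- c("# block=cd", wide_block(cd), "# block=absorbance",
                 wide_block(series_matrix(series, "absorbance")))
    } else {
      lines <- wide_block(cd)
    }
  } else {
    header <- c("wavelength_nm", "temperature_C", "cd_delta_epsilon")
    if (has_abs) header <- c(header, "absorbance")
    grid <- expand.grid(w = seq_along(wl), t = seq_along(tk))
    ab <- if (has_abs) series_matrix(series, "absorbance")
    rows <- vapply(seq_len(nrow(grid)), function(r) {
      i <- grid$w[r]; j <- grid$t[r]
      vals <- c(wl[i], tc[j], cd[i, j])
      if (has_abs) vals <- c(vals, ab[i, j])
      paste(fmt(vals), collapse = delim)
    }, character(1))
    lines <- c(paste(header, collapse = delim), rows)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a basis spectrum
#'
#' Basis spectra are stored as two-column delimited text (`wavelength_nm`,
#' `value`) preceded by a `# label=..., kind=...` comment line.
#'
#' @param path File path.
#' @return A [basis_spectrum()].
#' @export
read_basis_spectrum <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- readLines(path, warn = FALSE)
  label <- "unknown"; kind <- "cd"
  hdr <- grep("^#", raw, value = TRUE)
  if (length(hdr)) {
    m <- regmatches(hdr[1], regexec("label=([^,[:space:]]+)", hdr[1]))[[1]]
    if (length(m) == 2) label <- m[2]
    m <- regmatches(hdr[1], regexec("kind=([^,[:space:]]+)", hdr[1]))[[1]]
    if (length(m) == 2) kind <- m[2]
  }
  body <- raw[!grepl("^#", raw) & nzchar(trimws(raw))]
  body_nos <- which(!grepl("^#", raw) & nzchar(trimws(raw)))
  delim <- .detect_delim(body[1], body_nos[1])
  first <- strsplit(body[1], delim, fixed = TRUE)[[1]]
  has_header <- is.na(suppressWarnings(as.numeric(first[1])))
  if (has_header) { body <- body[-1]; body_nos <- body_nos[-1] }
  m <- do.call(rbind, lapply(seq_along(body), function(i)
    .num_or_stop(strsplit(body[i], delim, fixed = TRUE)[[1]], body_nos[i])))
  o <- order(m[, 1])
  basis_spectrum(m[o, 1], m[o, 2], label = label, kind = kind)
}

#' @rdname read_basis_spectrum
#' @param x A `cd_basis`.
#' @param delim Field delimiter.
#' @export
write_basis_spectrum <- function(x, path, delim = "\t") {
  fmt <- function(v) formatC(v, format = "g", digits = 17)
  lines <- c(sprintf("# label=%s, kind=%s", basis_label(x), basis_kind(x)),
             paste(c("wavelength_nm", "value"), collapse = delim),
             vapply(seq_len(nrow(x)), function(i)
               paste(fmt(c(x$wavelength_nm[i], x$value[i])), collapse = delim),
               character(1)))
  writeLines(lines, path)
  invisible(path)
}

# --- unit conversion -------------------------------------------------------

.UNIT_LEVELS <- c("millidegrees", "mean_residue_ellipticity", "delta_epsilon")

# factor taking a value in `unit` to delta-epsilon
.to_deps_factor <- function(unit, meta) {
  switch(unit,
    delta_epsilon = 1,
    mean_residue_ellipticity = 1 / MRE_PER_DELTA_EPSILON,
    millidegrees = {
      if (is.null(meta$path_cm) || is.null(meta$residue_molarity))
        stop(paste("conversion from millidegrees needs meta fields",
                   "'path_cm' and 'residue_molarity'"), call. = FALSE)
      1 / (10 * meta$path_cm * meta$residue_molarity) / MRE_PER_DELTA_EPSILON
    })
}

#' Convert the CD unit of a spectral series
#'
#' Standard CD conversions: `theta_MRE = theta_mdeg / (10 * path_cm *
#' residue_molarity)` and `delta_epsilon = theta_MRE / 3298.2`. Conversions
#' are exact and mutually inverse; the absorbance block is untouched.
#'
#' @param series A `cd_series`.
#' @param from Source unit; defaults to the series' `meta$unit`.
#' @param to Target unit.
#' @return The converted series (with `meta$unit` updated).
#' @export
convert_units <- function(series, from = NULL,
                          to = c("delta_epsilon", "mean_residue_ellipticity",
                                 "millidegrees")) {
  to <- match.arg(to)
  meta <- series_meta(series)
  if (is.null(from)) from <- meta$unit %||% "delta_epsilon"
  from <- match.arg(from, .UNIT_LEVELS)
  factor <- .to_deps_factor(from, meta) / .to_deps_factor(to, meta)
  out <- series
  out$cd <- series$cd * factor
  meta$unit <- to
  attr(out, "meta") <- meta
  out
}

# --- resampling ------------------------------------------------------------

#' Resample a spectrum onto a new wavelength grid
#'
#' Linear interpolation per temperature column (for a series) or of the value
#' column (for a basis spectrum). The target grid must lie inside the source
#' wavelength range; no extrapolation is performed.
#'
#' @param x A `cd_series` or `cd_basis`.
#' @param grid Target wavelengths, nm, strictly ascending.
#' @return Object of the same class on the new grid.
#' @export
resample_to_grid <- function(x, grid) {
  UseMethod("resample_to_grid")
}

.check_grid <- function(grid, src) {
  if (is.unsorted(grid, strictly = TRUE))
    stop("target grid must be strictly ascending", call. = FALSE)
  if (min(grid) < min(src) - 1e-9 || max(grid) > max(src) + 1e-9)
    stop("target grid outside the source wavelength range", call. = FALSE)
}

#' @export
resample_to_grid.cd_basis <- function(x, grid) {
  .check_grid(grid, x$wavelength_nm)
  v <- stats::approx(x$wavelength_nm, x$value, xout = grid)$y
  basis_spectrum(grid, v, label = basis_label(x), kind = basis_kind(x))
}

#' @export
resample_to_grid.cd_series <- function(x, grid) {
  wl <- series_wavelengths(x)
  .check_grid(grid, wl)
  tk <- series_temperatures(x)
  interp_cols <- function(m)
    apply(m, 2, function(col) stats::approx(wl, col, xout = grid)$y)
  cd <- interp_cols(series_matrix(x, "cd"))
  absorb <- if (!is.null(x[["absorbance"]]))
    interp_cols(series_matrix(x, "absorbance")) else NULL
  spectral_series(grid, tk, cd, absorb, series_meta(x))
}

#' Default wavelength grid for synthetic work
#'
#' 185--260 nm in 0.5 nm steps (151 points), the far-UV window over which
#' polypeptide CD spectra are typically recorded and fitted here.
#' @export
default_grid <- function() seq(185, 260, by = 0.5)

`%||%` <- function(a, b) if (is.null(a)) b else a
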