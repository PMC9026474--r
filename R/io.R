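# Readers and writers for every external representation: delimited XT tables,
# multi-page grayscale TIFF stacks, float-TIFF / PNG map rasters, CSV event
# tables and a JSON run manifest.  CSV numeric precision is fixed at 9
# significant digits and missing values are spelled NA, avoiding locale
# ambiguity.

#' Read XT data from a delimited text file
#'
#' One [time_series()] is returned per selected value column.  The delimiter
#' (comma, tab or semicolon) is autodetected, a header row is autodetected,
#' and decimal commas are accepted with `decimal_comma = TRUE`.  Exactly one
#' time source must be resolved: either `time_col` names/indexes a column of
#' the file, or `dt` builds a synthetic time axis `0, dt, 2 dt, ...` and all
#' columns are treated as channels.
#'
#' @param path Path to the file.
#' @param time_col Column index or name holding time (default 1).  Ignored
#'   when `dt` is given.
#' @param dt Optional sampling interval replacing a time column.
#' @param unit Time unit tag (default `"ms"`).
#' @param decimal_comma Set `TRUE` for files using `,` as decimal mark
#'   (the field delimiter must then be tab or semicolon).
#' @param channels Optional indices or names of the value columns to keep
#'   (default: every non-time column).
#' @return A list of [time_series()], named by channel.
#' @export
read_xt <- function(path, time_col = 1, dt = NULL, unit = "ms",
                    decimal_comma = FALSE, channels = NULL) {
  if (!file.exists(path)) pm_input_error("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) pm_input_error("need at least 3 data rows in ", path)
  probe <- lines[seq_len(min(5L, length(lines)))]
  seps <- c("\t" = "\t", ";" = ";", "," = ",")
  if (decimal_comma) seps <- seps[c("\t", ";")]
  counts <- vapply(seps, function(s)
    min(vapply(probe, function(l) length(gregexpr(s, l, fixed = TRUE)[[1L]]) *
                 (regexpr(s, l, fixed = TRUE) > 0), numeric(1L))), numeric(1L))
  sep <- if (all(counts == 0)) "" else seps[[which.max(counts)]]
  dec <- if (decimal_comma) "," else "."
  first <- utils::read.table(text = lines[1L], sep = sep, dec = dec,
                             colClasses = "character")
  has_header <- any(is.na(suppressWarnings(as.numeric(gsub(",", ".",
                    unlist(first), fixed = TRUE)))))
  df <- utils::read.table(text = paste(lines, collapse = "\n"), sep = sep,
                          dec = dec, header = has_header,
                          colClasses = "character",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!has_header) names(df) <- paste0("V", seq_along(df))
  num <- lapply(df, function(col) {
    if (decimal_comma) col <- gsub(",", ".", col, fixed = TRUE)
    suppressWarnings(as.numeric(col))
  })
  for (j in seq_along(num)) {
    bad <- which(is.na(num[[j]]))
    if (length(bad))
      pm_input_error("non-numeric or missing value at row ", bad[1L],
                     ", column '", names(df)[j], "' of ", path)
  }
  n <- length(num[[1L]])
  if (n < 3L) pm_input_error("need at least 3 data rows in ", path)

  if (!is.null(dt)) {
    times <- seq(0, by = dt, length.out = n)
    value_cols <- seq_along(num)
  } else {
    tc <- if (is.character(time_col)) match(time_col, names(df)) else as.integer(time_col)
    if (is.na(tc) || tc < 1L || tc > length(num))
      pm_input_error("time column '", time_col, "' not found")
    times <- num[[tc]]
    value_cols <- setdiff(seq_along(num), tc)
  }
  if (!length(value_cols)) pm_input_error("no value columns in ", path)
  if (!is.null(channels)) {
    sel <- if (is.character(channels)) match(channels, names(df)) else as.integer(channels)
    if (anyNA(sel) || !all(sel %in% value_cols))
      pm_input_error("requested channel(s) not present")
    value_cols <- sel
  }
  out <- lapply(value_cols, function(j)
    time_series(times, num[[j]], label = names(df)[j], unit = unit))
  names(out) <- names(df)[value_cols]
  out
}

#' Read an image stack from a multi-page grayscale TIFF
#'
#' Pages become frames, in file order.  Integer data are kept unscaled;
#' float data pass through unchanged.  RGB or multi-sample pages are not
#' supported (convert to single-channel grayscale upstream).
#'
#' @param path Path to a multi-page TIFF.
#' @param dt Frame interval (time units), required.
#' @param pixel_pitch Optional physical pixel size.
#' @param mask Optional path to a single-page TIFF/PNG mask (nonzero = in
#'   region of interest) or an H x W matrix.
#' @param unit Time unit tag.
#' @return An [image_stack()].
#' @export
read_stack <- function(path, dt, pixel_pitch = NULL, mask = NULL,
                       unit = "ms") {
  if (!file.exists(path)) pm_input_error("file not found: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = TRUE),
                    error = function(e) tiff::readTIFF(path, all = TRUE))
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) < 3L) pm_input_error("stack has fewer than 3 frames")
  for (p in pages) {
    if (length(dim(p)) != 2L)
      pm_input_error("unsupported format: multi-sample (RGB/RGBA) pages; ",
                     "convert to single-channel grayscale upstream")
  }
  d1 <- dim(pages[[1L]])
  if (!all(vapply(pages, function(p) all(dim(p) == d1), logical(1L))))
    pm_input_error("pages differ in size")
  frames <- array(0, dim = c(length(pages), d1[1L], d1[2L]))
  for (f in seq_along(pages)) frames[f, , ] <- pages[[f]]
  mask_m <- NULL
  if (!is.null(mask)) {
    mask_m <- if (is.matrix(mask)) mask != 0 else read_mask(mask)
    if (!all(dim(mask_m) == d1))
      pm_input_error("mask size ", paste(dim(mask_m), collapse = "x"),
                     " does not match frames ", paste(d1, collapse = "x"))
    if (!any(mask_m)) pm_input_error("mask selects no pixels (all zero)")
  }
  image_stack(frames, dt = dt, pixel_pitch = pixel_pitch, mask = mask_m,
              unit = unit)
}

read_mask <- function(path) {
  if (!file.exists(path)) pm_input_error("mask file not found: ", path)
  m <- if (grepl("\\.png$", path, ignore.case = TRUE)) png::readPNG(path)
       else tryCatch(tiff::readTIFF(path, as.is = TRUE),
                     error = function(e) tiff::readTIFF(path))
  if (length(dim(m)) == 3L) m <- m[, , 1L]  # first channel decides membership
  m != 0
}

#' Write matrices as a 32-bit float multi-page TIFF
#'
#' Values are stored as native-unit IEEE 754 single-precision floats,
#' uncompressed, little-endian, with `NaN` marking invalid pixels -- the
#' interchange form of every map this package produces.  Installed TIFF
#' readers (including [tiff::readTIFF()]) read the values back verbatim.
#'
#' @param pages A numeric matrix or list of equally sized matrices.
#' @param path Output path.
#' @return The path, invisibly.
#' @seealso [read_float_tiff()]
#' @export
write_float_tiff <- function(pages, path) {
  if (is.matrix(pages)) pages <- list(pages)
  if (!length(pages)) pm_input_error("no pages to write")
  con <- file(path, "wb")
  on.exit(close(con))
  wr2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  wr4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  writeChar("II", con, eos = NULL); wr2(42L); wr4(8L)
  offset <- 8L
  npg <- length(pages)
  for (p in seq_len(npg)) {
    m <- pages[[p]]
    vals <- as.numeric(m)
    vals[is.na(vals)] <- NaN
    h <- nrow(m); w <- ncol(m)
    nbytes <- 4L * h * w
    ntags <- 10L
    data_off <- offset + 2L + ntags * 12L + 4L
    next_ifd <- if (p < npg) data_off + nbytes else 0L
    tag <- function(id, type, count, value) { wr2(id); wr2(type); wr4(count); wr4(value) }
    wr2(ntags)
    tag(256L, 3L, 1L, w)          # ImageWidth
    tag(257L, 3L, 1L, h)          # ImageLength
    tag(258L, 3L, 1L, 32L)        # BitsPerSample
    tag(259L, 3L, 1L, 1L)         # no compression
    tag(262L, 3L, 1L, 1L)         # BlackIsZero
    tag(273L, 4L, 1L, data_off)   # StripOffsets
    tag(277L, 3L, 1L, 1L)         # SamplesPerPixel
    tag(278L, 3L, 1L, h)          # RowsPerStrip
    tag(279L, 4L, 1L, nbytes)     # StripByteCounts
    tag(339L, 3L, 1L, 3L)         # SampleFormat = IEEE float
    wr4(next_ifd)
    writeBin(as.vector(t(matrix(vals, h, w))), con, size = 4,
             endian = "little")   # row-major strips
    offset <- data_off + nbytes
  }
  invisible(path)
}

#' Read a float TIFF back into matrices
#'
#' Thin wrapper over [tiff::readTIFF()] returning a matrix (single page) or
#' list of matrices, values verbatim.
#'
#' @param path Path to a TIFF written by [write_float_tiff()].
#' @return A matrix or list of matrices.
#' @export
read_float_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) == 1L) pages[[1L]] else pages
}

format_csv_number <- function(x) {
  out <- formatC(x, digits = 9, format = "g")
  out[!is.finite(x)] <- "NA"
  out
}

write_table_csv <- function(df, path) {
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- format_csv_number(out[[j]])
  utils::write.table(out, path, sep = ",", row.names = FALSE,
                     quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

vector_field_table <- function(vf) {
  H <- nrow(vf$vx); W <- ncol(vf$vx)
  data.frame(
    x = rep(seq_len(W) - 1L, each = H),
    y = rep(seq_len(H) - 1L, times = W),
    vx = as.vector(vf$vx), vy = as.vector(vf$vy),
    speed = as.vector(vf$speed),
    valid = as.integer(as.vector(vf$valid)))
}

#' Write analysis artifacts and a run manifest
#'
#' Writes every supplied artifact under `destination` -- event tables as CSV
#' (UTF-8, comma, header, 9 significant digits, `NA` for invalid values),
#' maps as native-unit float TIFF plus a rendered PNG, vector fields as CSV
#' (`x, y, vx, vy, speed, valid`) -- and a `manifest.json` recording input
#' hashes, the effective configuration, the package version and the MD5 of
#' every artifact, enabling exact re-runs.  Re-running the same input with
#' the manifest's configuration reproduces every CSV and TIFF byte for byte.
#'
#' @param destination Output directory (created if needed).
#' @param tables Named list of `event_table` / data.frame objects.
#' @param maps Named list of `activation_map` / `parameter_map` objects (or
#'   plain matrices).
#' @param vectors Named list of `vector_field` objects.
#' @param renders Named list of `map_render` rasters to write as PNG (maps
#'   passed via `maps` also get a default render).
#' @param config Configuration echoed into the manifest (any
#'   JSON-serializable list).
#' @param inputs Character vector of input file paths to hash into the
#'   manifest.
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
write_outputs <- function(destination, tables = list(), maps = list(),
                          vectors = list(), renders = list(), config = NULL,
                          inputs = character()) {
  dir.create(destination, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(destination))
    pm_input_error("cannot create destination ", destination)
  artifacts <- character()
  add <- function(p) artifacts <<- c(artifacts, p)

  for (nm in names(tables)) {
    p <- file.path(destination, paste0(nm, ".csv"))
    write_table_csv(as.data.frame(tables[[nm]]), p)
    add(p)
  }
  for (nm in names(maps)) {
    m <- maps[[nm]]
    vals <- map_values(m)
    p_tif <- file.path(destination, paste0(nm, ".tif"))
    write_float_tiff(vals, p_tif); add(p_tif)
    p_png <- file.path(destination, paste0(nm, ".png"))
    png::writePNG(unclass(render_map(m)), p_png); add(p_png)
  }
  for (nm in names(vectors)) {
    p <- file.path(destination, paste0(nm, ".csv"))
    write_table_csv(vector_field_table(vectors[[nm]]), p)
    add(p)
  }
  for (nm in names(renders)) {
    p <- file.path(destination, paste0(nm, ".png"))
    png::writePNG(unclass(renders[[nm]]), p)
    add(p)
  }
  manifest <- list(
    tool = "peakmap",
    version = as.character(utils::packageVersion("peakmap")),
    inputs = if (length(inputs)) {
      data.frame(path = inputs, md5 = unname(tools::md5sum(inputs)),
                 stringsAsFactors = FALSE)
    } else NULL,
    config = config,
    n_table_rows = vapply(tables, nrow, integer(1L)),
    artifacts = data.frame(path = basename(artifacts),
                           md5 = unname(tools::md5sum(artifacts)),
                           stringsAsFactors = FALSE))
  jsonlite::write_json(manifest, file.path(destination, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
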