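# Minimal multi-page grayscale TIFF support (uncompressed, little-endian,
# one strip per page, 32-bit float samples). Universal enough for ImageJ and
# tifffile to open; no external imaging dependency is available in R here.

tiff_types <- c(SHORT = 3L, LONG = 4L)

write_u <- function(con, x, size) writeBin(as.integer(x), con, size = size, endian = "little")

#' Write a z-stack as a multi-page TIFF with a JSON metadata sidecar
#'
#' One page per z-slice, 32-bit float grayscale, uncompressed. Acquisition
#' metadata (pixel size, z positions, channel, magnification, optional seed)
#' goes to `<path>.json`.
#'
#' @param stack a [zstack()] of [camera_frame()]s (or bare matrices).
#' @param path output `.tif` path.
#' @param seed optional seed to embed in the sidecar for provenance.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, seed = NULL) {
  frames <- lapply(stack$frames, frame_raster)
  nz <- length(frames)
  stopifnot(nz >= 1)
  dims <- dim(frames[[1]])
  if (!all(vapply(frames, function(f) all(dim(f) == dims), logical(1))))
    stop("all frames must share dimensions")
  h <- dims[1]; w <- dims[2]
  page_bytes <- w * h * 4
  ifd0 <- 8 + nz * page_bytes
  ifd_size <- 2 + 9 * 12 + 4

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("II"), con)
  write_u(con, 42, 2)
  write_u(con, ifd0, 4)
  for (f in frames)
    writeBin(as.numeric(t(f)), con, size = 4, endian = "little")
  entry <- function(tag, type, count, value) {
    write_u(con, tag, 2); write_u(con, type, 2); write_u(con, count, 4)
    if (type == tiff_types["SHORT"] && count == 1) {
      write_u(con, value, 2); write_u(con, 0, 2)
    } else write_u(con, value, 4)
  }
  for (i in seq_len(nz)) {
    write_u(con, 9, 2)  # entry count
    entry(256, 4L, 1, w)                       # ImageWidth
    entry(257, 4L, 1, h)                       # ImageLength
    entry(258, 3L, 1, 32)                      # BitsPerSample
    entry(259, 3L, 1, 1)                       # Compression: none
    entry(262, 3L, 1, 1)                       # Photometric: BlackIsZero
    entry(273, 4L, 1, 8 + (i - 1) * page_bytes) # StripOffsets
    entry(278, 4L, 1, h)                       # RowsPerStrip
    entry(279, 4L, 1, page_bytes)              # StripByteCounts
    entry(339, 3L, 1, 3)                       # SampleFormat: IEEE float
    write_u(con, if (i < nz) ifd0 + i * ifd_size else 0, 4)
  }

  meta <- list(pixel_size_um = if (inherits(stack$frames[[1]], "camera_frame"))
                 stack$frames[[1]]$pixel_size else NA,
               z_positions_um = stack$z_positions,
               channel = if (inherits(stack$frames[[1]], "camera_frame"))
                 stack$frames[[1]]$channel else NA,
               magnification_name = if (inherits(stack$frames[[1]], "camera_frame"))
                 stack$frames[[1]]$magnification_name else NA,
               n_pages = nz, seed = seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

read_u <- function(raw, off, size) {
  v <- 0
  for (k in seq_len(size) - 1) v <- v + as.numeric(raw[off + 1 + k]) * 256^k
  v
}

#' Read a multi-page TIFF stack written by [write_stack()]
#'
#' Parses little-endian, uncompressed, single-strip grayscale TIFFs (8/16-bit
#' unsigned or 32-bit float). The JSON sidecar is required and must list
#' `pixel_size_um`, `z_positions_um` and `channel`; a page count that
#' disagrees with the sidecar's z list is a format error.
#'
#' @param path `.tif` path with `<path>.json` sidecar alongside.
#' @return A [zstack()] of [camera_frame()]s with metadata attached.
#' @export
read_stack <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("missing metadata sidecar ", sidecar,
         " (required fields: pixel_size_um, z_positions_um, channel)")
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  need <- c("pixel_size_um", "z_positions_um", "channel")
  missing <- need[!need %in% names(meta) | vapply(meta[need], is.null, NA)]
  if (length(missing))
    stop("sidecar missing required field(s): ", paste(missing, collapse = ", "))

  raw <- readBin(path, "raw", file.info(path)$size)
  if (!identical(rawToChar(raw[1:2]), "II")) stop("only little-endian TIFF supported")
  if (read_u(raw, 2, 2) != 42) stop("not a TIFF file")
  off <- read_u(raw, 4, 4)
  frames <- list()
  while (off != 0) {
    n <- read_u(raw, off, 2)
    tags <- list()
    for (e in seq_len(n)) {
      base <- off + 2 + (e - 1) * 12
      tag <- read_u(raw, base, 2)
      type <- read_u(raw, base + 2, 2)
      val <- if (type == 3) read_u(raw, base + 8, 2) else read_u(raw, base + 8, 4)
      tags[[as.character(tag)]] <- val
    }
    w <- tags[["256"]]; h <- tags[["257"]]
    bits <- tags[["258"]]; fmt <- if (is.null(tags[["339"]])) 1 else tags[["339"]]
    if (!is.null(tags[["259"]]) && tags[["259"]] != 1) stop("compressed TIFF unsupported")
    so <- tags[["273"]]; sb <- tags[["279"]]
    bytes <- raw[(so + 1):(so + sb)]
    vals <- if (fmt == 3 && bits == 32) {
      readBin(bytes, "numeric", n = w * h, size = 4, endian = "little")
    } else if (fmt == 1 && bits %in% c(8, 16)) {
      readBin(bytes, "integer", n = w * h, size = bits / 8, signed = FALSE,
              endian = "little")
    } else stop("unsupported sample format (", fmt, "/", bits, " bits)")
    frames[[length(frames) + 1]] <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
    off <- read_u(raw, off + 2 + n * 12, 4)
  }
  zp <- meta$z_positions_um
  if (length(frames) != length(zp))
    stop("format error: ", length(frames), " TIFF pages but ",
         length(zp), " z positions in sidecar")
  frames <- lapply(seq_along(frames), function(i)
    camera_frame(frames[[i]],
                 magnification_name = if (is.null(meta$magnification_name)) NA else meta$magnification_name,
                 pixel_size = meta$pixel_size_um,
                 z_position = zp[i], channel = meta$channel))
  zstack(frames, zp)
}

#' Write / read per-worm automation records as JSON lines
#'
#' One JSON object per line; streamable. `read_records` restores the list of
#' records (as plain lists).
#'
#' @param records list of `automation_record`.
#' @param path output file.
#' @return `path` / list of records.
#' @export
write_records <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in records) {
    r$phantom_after <- NULL  # ground truth is serialized separately if needed
    writeLines(jsonlite::toJSON(unclass(r), auto_unbox = TRUE, digits = NA,
                                null = "null", na = "null"), con)
  }
  invisible(path)
}

#' @rdname write_records
#' @export
read_records <- function(path) {
  lapply(readLines(path), function(l)
    jsonlite::fromJSON(l, simplifyVector = TRUE, simplifyDataFrame = FALSE))
}

#' Export a run summary as CSV
#'
#' @param summary a `run_summary` from [attrition_summary()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_summary_csv <- function(summary, path) {
  df <- data.frame(step = c(names(summary$rejections), "success"),
                   count = c(unname(summary$rejections), summary$n_success),
                   fraction_of_total = c(unname(summary$rejection_fractions),
                                         summary$success_fraction),
                   remaining_percent = c(unname(summary$remaining_percent), NA))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
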