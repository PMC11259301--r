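# Minimal ImageJ ROI reader --------------------------------------------------
#
# Binary layout follows ImageJ's RoiDecoder: big-endian, magic "Iout",
# type byte at offset 6, bounding box shorts at 8..15, n coordinates at 16,
# options at 50 (bit 7 = sub-pixel resolution), header2 offset at 60.
# Integer coordinates (shorts relative to the bounding box) start at 64;
# with sub-pixel resolution, absolute float coordinates follow them.
# Only the ROI kinds the pipeline consumes are decoded: multipoint
# selections (cells) and polyline / segmented-line / freehand / polygon
# traces (the delineated cochlear axis).

.roi_types <- c(`0` = "polygon", `3` = "line", `4` = "polyline",
                `5` = "polyline", `7` = "freehand", `10` = "point")

#' Read ImageJ ROI files
#'
#' Decodes a single `.roi` file or a `.zip` archive of ROIs as written by
#' ImageJ/Fiji's ROI Manager. Supports multipoint, polyline, segmented-line,
#' freehand and polygon ROIs, including sub-pixel-resolution coordinates.
#'
#' @param path Path to a `.roi` or `.zip` file.
#' @return A list of ROIs; each is a list with elements `name`, `type`
#'   (`"point"`, `"polyline"`, `"polygon"`, ...) and `coords`, a tibble of
#'   `x`, `y` pixel coordinates.
#' @export
read_imagej_roi <- function(path) {
  if (grepl("\\.zip$", path, ignore.case = TRUE)) {
    exdir <- tempfile("rois")
    files <- unzip(path, exdir = exdir)
    on.exit(unlink(exdir, recursive = TRUE), add = TRUE)
    rois <- purrr::map(sort(files), .decode_roi_file)
    return(purrr::compact(rois))
  }
  purrr::compact(list(.decode_roi_file(path)))
}

.decode_roi_file <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  .decode_roi(raw, fallback_name = sub("\\.roi$", "", basename(path),
                                       ignore.case = TRUE))
}

.rshort <- function(raw, off, n = 1, signed = TRUE) {
  readBin(raw[(off + 1):(off + 2 * n)], "integer", n = n, size = 2,
          signed = signed, endian = "big")
}
.rint <- function(raw, off, n = 1) {
  readBin(raw[(off + 1):(off + 4 * n)], "integer", n = n, size = 4,
          endian = "big")
}
.rfloat <- function(raw, off, n = 1) {
  readBin(raw[(off + 1):(off + 4 * n)], "double", n = n, size = 4,
          endian = "big")
}

.decode_roi <- function(raw, fallback_name = "") {
  if (length(raw) < 64 || rawToChar(raw[1:4]) != "Iout") {
    abort("Not an ImageJ ROI file (missing 'Iout' magic).",
          class = "cochleogram_format_error")
  }
  version <- .rshort(raw, 4)
  type <- as.integer(raw[7])
  type_name <- .roi_types[as.character(type)]
  if (is.na(type_name)) return(NULL)  # unsupported ROI kind: skip
  top <- .rshort(raw, 8); left <- .rshort(raw, 10)
  n <- .rshort(raw, 16, signed = FALSE)
  options <- .rshort(raw, 50, signed = FALSE)
  sub_pixel <- version >= 222 && bitwAnd(options, 128L) != 0
  if (n <= 0) return(NULL)
  if (sub_pixel) {
    x <- .rfloat(raw, 64 + 4 * n, n)
    y <- .rfloat(raw, 64 + 4 * n + 4 * n, n)
  } else {
    x <- left + .rshort(raw, 64, n)
    y <- top + .rshort(raw, 64 + 2 * n, n)
  }
  h2 <- .rint(raw, 60)
  name <- fallback_name
  if (h2 > 0 && h2 + 64 <= length(raw)) {
    name_off <- .rint(raw, h2 + 16)
    name_len <- .rint(raw, h2 + 20)
    if (name_off > 0 && name_len > 0 &&
        name_off + 2 * name_len <= length(raw)) {
      chars <- .rshort(raw, name_off, name_len, signed = FALSE)
      name <- intToUtf8(chars)
    }
  }
  list(name = name, type = unname(type_name),
       coords = tibble(x = as.numeric(x), y = as.numeric(y)))
}
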