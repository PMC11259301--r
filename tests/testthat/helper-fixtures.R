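# Fixtures are built in code: small CSVs via the package writers, ImageJ ROI
# files byte-by-byte following the published binary layout (big-endian,
# "Iout" magic, integer coordinates relative to the bounding box, ROI name
# in the header2 block). The ROI writer is deliberately independent of the
# package's reader so cross-format tests compare two separate routes.

write_csv_fixture <- function(df, path = tempfile(fileext = ".csv")) {
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# type: 10 = multipoint, 5 = polyline (segmented line)
write_imagej_roi_fixture <- function(x, y, name, type = 10L,
                                     path = tempfile(fileext = ".roi")) {
  n <- length(x)
  stopifnot(n == length(y), n >= 1)
  xi <- as.integer(round(x)); yi <- as.integer(round(y))
  left <- min(xi); top <- min(yi)
  h2 <- 64L + 4L * n
  name_utf16 <- utf8ToInt(name)
  con <- file(path, open = "wb")
  on.exit(close(con))
  wshort <- function(v) writeBin(as.integer(v), con, size = 2, endian = "big")
  wint <- function(v) writeBin(as.integer(v), con, size = 4, endian = "big")
  writeBin(charToRaw("Iout"), con)
  wshort(226)                     # version
  writeBin(as.raw(c(type, 0)), con)
  wshort(c(top, left, max(yi), max(xi)))   # bounding box
  wshort(n)
  writeBin(rep(as.raw(0), 16), con)        # x1,y1,x2,y2 floats (unused)
  wshort(0)                                # stroke width
  wint(0); wint(0); wint(0)                # shape size, stroke/fill colour
  wshort(0); wshort(0)                     # subtype, options (no sub-pixel)
  writeBin(as.raw(c(0, 0)), con)           # arrow style/head
  wshort(0)                                # rounded rect arc
  wint(0)                                  # position
  wint(h2)                                 # header2 offset
  wshort(xi - left)
  wshort(yi - top)
  # header2: 64 bytes; name offset at +16, name length at +20
  wint(rep(0, 4))
  wint(h2 + 64L)
  wint(length(name_utf16))
  wint(rep(0, 10))
  wshort(name_utf16)
  path
}

# Minimal ZIP writer (stored entries, no compression) so ROI archives can be
# built without an external zip tool.
crc32 <- local({
  # 32-bit ops on doubles (base bitwXor is limited to signed ints)
  xor32 <- function(a, b) {
    bitwXor(a %/% 65536, b %/% 65536) * 65536 + bitwXor(a %% 65536, b %% 65536)
  }
  tab <- vapply(0:255, function(n) {
    c <- as.numeric(n)
    for (k in 1:8) {
      c <- if (c %% 2 == 1) xor32(3988292384, c %/% 2) else c %/% 2
    }
    c
  }, numeric(1))
  function(raw) {
    c <- 4294967295
    for (b in as.integer(raw)) {
      c <- xor32(tab[xor32(c, b) %% 256 + 1], c %/% 256)
    }
    xor32(c, 4294967295)
  }
})

write_zip_fixture <- function(files, path = tempfile(fileext = ".zip")) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  w16 <- function(v) writeBin(as.integer(v), con, size = 2, endian = "little")
  w32 <- function(v) {
    v <- as.numeric(v) %% 2^32
    writeBin(as.integer(c(v %% 2^16, v %/% 2^16)), con, size = 2,
             endian = "little")
  }
  offsets <- integer(length(files))
  info <- list()
  pos <- 0L
  for (i in seq_along(files)) {
    nm <- names(files)[i]
    data <- readBin(files[[i]], "raw", n = file.info(files[[i]])$size)
    crc <- crc32(data)
    offsets[i] <- pos
    writeBin(charToRaw("PK\x03\x04"), con); w16(20); w16(0); w16(0)
    w16(0); w16(0)                       # mod time/date
    w32(crc); w32(length(data)); w32(length(data))
    w16(nchar(nm, "bytes")); w16(0)
    writeBin(charToRaw(nm), con)
    writeBin(data, con)
    pos <- pos + 30L + nchar(nm, "bytes") + length(data)
    info[[i]] <- list(name = nm, crc = crc, size = length(data))
  }
  cd_start <- pos
  for (i in seq_along(files)) {
    e <- info[[i]]
    writeBin(charToRaw("PK\x01\x02"), con); w16(20); w16(20); w16(0); w16(0)
    w16(0); w16(0)
    w32(e$crc); w32(e$size); w32(e$size)
    w16(nchar(e$name, "bytes")); w16(0); w16(0); w16(0); w16(0)
    w32(0); w32(offsets[i])
    writeBin(charToRaw(e$name), con)
    pos <- pos + 46L + nchar(e$name, "bytes")
  }
  writeBin(charToRaw("PK\x05\x06"), con); w16(0); w16(0)
  w16(length(files)); w16(length(files))
  w32(pos - cd_start); w32(cd_start); w16(0)
  path
}

# straight axis along the x direction, from the origin
straight_axis <- function(L = 1000, n = 11) {
  as_axis_polyline(seq(0, L, length.out = n), rep(0, n))
}

# quarter circle of radius r sampled every `by` degrees
quarter_circle_axis <- function(r = 1000, by = 1) {
  theta <- seq(0, pi / 2, by = by * pi / 180)
  as_axis_polyline(r * cos(theta), r * sin(theta))
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

# profile object with arbitrary per-type fraction values, built through the
# profile CSV reader so tests can exercise downstream operations on exactly
# known curves
profile_from_values <- function(position_um, fractions) {
  df <- purrr::imap_dfr(fractions, function(f, ct) {
    tibble::tibble(position_um = position_um, cell_type = ct, fraction = f,
                   density_cells_per_um = f * 0.118)
  })
  path <- tempfile(fileext = ".csv")
  readr::write_csv(df, path)
  read_profile(path)
}

# nearest point on the curve by brute force over a fine arc-length
# discretization of the fitted axis (independent of project_points)
brute_force_s <- function(axis, points, ds = 0.25) {
  grid <- axis_point(axis, seq(0, axis_length(axis), by = ds))
  vapply(seq_len(nrow(points)), function(k) {
    d2 <- (points$x[k] - grid$x)^2 + (points$y[k] - grid$y)^2
    grid$s[which.min(d2)]
  }, numeric(1))
}
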