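#' Read a georeferenced tracer sample table
#'
#' Reads a CSV of pooled foliar samples for one plot: plot-local coordinates in
#' metres plus the three tracers used throughout this package — N concentration
#' (g N/kg), delta-15N and delta-13C (both permil). Records with any missing
#' tracer are rejected, as are duplicated sampling locations (the kriging
#' system requires unique coordinates).
#'
#' @param path CSV file with a header row.
#' @param columns Named character vector mapping the canonical names
#'   `x, y, n_conc, d15N, d13C` (optionally `id`) to the file's column names.
#' @return A `sample_table`: a data.frame with columns
#'   `x, y, n_conc, d15N, d13C` (and `id` if mapped), row order preserved.
#' @export
read_samples <- function(path,
                         columns = c(x = "x", y = "y", n_conc = "n_conc",
                                     d15N = "d15N", d13C = "d13C")) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  needed <- c("x", "y", "n_conc", "d15N", "d13C")
  if (!all(needed %in% names(columns))) {
    stop("column map must name: ", paste(needed, collapse = ", "), call. = FALSE)
  }
  missing_cols <- setdiff(unname(columns[needed]), names(raw))
  if (length(missing_cols)) {
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  cols <- lapply(needed, function(nm) {
    col <- raw[[columns[[nm]]]]
    num <- suppressWarnings(as.numeric(col))
    bad <- which(is.na(num) & !is.na(col) & col != "")
    if (length(bad)) {
      stop(sprintf("non-numeric value in column '%s' at data row %d: '%s'",
                   columns[[nm]], bad[1], col[bad[1]]), call. = FALSE)
    }
    num
  })
  names(cols) <- needed
  if ("id" %in% names(columns) && columns[["id"]] %in% names(raw)) {
    cols$id <- raw[[columns[["id"]]]]
  }
  as_sample_table(as.data.frame(cols))
}

#' Validate a data frame as a sample table
#'
#' @param df Data frame with columns `x, y, n_conc, d15N, d13C`.
#' @return The validated `sample_table`.
#' @export
as_sample_table <- function(df) {
  needed <- c("x", "y", "n_conc", "d15N", "d13C")
  stopifnot(is.data.frame(df), all(needed %in% names(df)))
  tracer_na <- !stats::complete.cases(df[, needed])
  if (any(tracer_na)) {
    stop(sprintf("%d record(s) with missing coordinate or tracer (first at row %d)",
                 sum(tracer_na), which(tracer_na)[1]), call. = FALSE)
  }
  dup <- duplicated(df[, c("x", "y")])
  if (any(dup)) {
    stop(sprintf("duplicated sampling coordinates at row %d (x=%g, y=%g)",
                 which(dup)[1], df$x[which(dup)[1]], df$y[which(dup)[1]]),
         call. = FALSE)
  }
  if (any(df$n_conc <= 0)) {
    stop("n_conc must be positive (g N/kg)", call. = FALSE)
  }
  class(df) <- c("sample_table", "data.frame")
  df
}

#' Write a sample table to CSV
#' @param samples A `sample_table`.
#' @param path Output path.
#' @export
write_samples <- function(samples, path) {
  utils::write.csv(as.data.frame(samples), path, row.names = FALSE)
  invisible(path)
}

# ---- canopy polygons ---------------------------------------------------------

#' Canopy polygon set
#'
#' A list of simple polygons (closed rings, plot-local metres) describing the
#' invader's canopies. An empty set is valid and represents an uninvaded plot.
#'
#' @param polygons List of two-column matrices (x, y); rings may be given open
#'   (first vertex not repeated) and are closed internally.
#' @return An object of class `canopy_set`.
#' @export
canopy_set <- function(polygons = list()) {
  polys <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    if (ncol(p) != 2 || nrow(p) < 3) {
      stop("each polygon needs >= 3 vertices of (x, y)", call. = FALSE)
    }
    storage.mode(p) <- "double"
    colnames(p) <- c("x", "y")
    # drop a repeated closing vertex; rings are stored open
    if (nrow(p) > 3 && all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
    if (ring_self_intersects(p)) {
      stop("self-intersecting canopy polygon", call. = FALSE)
    }
    p
  })
  structure(list(polygons = polys), class = "canopy_set")
}

#' @export
print.canopy_set <- function(x, ...) {
  cat(sprintf("<canopy_set> %d polygon(s), total area %.2f m2\n",
              length(x$polygons), canopy_area(x)))
  invisible(x)
}

#' Total canopy area (shoelace formula, m2)
#' @param canopies A [canopy_set()].
#' @return Numeric scalar.
#' @export
canopy_area <- function(canopies) {
  stopifnot(inherits(canopies, "canopy_set"))
  sum(vapply(canopies$polygons, function(p) {
    n <- nrow(p)
    j <- c(2:n, 1)
    abs(sum(p[, 1] * p[j, 2] - p[j, 1] * p[, 2])) / 2
  }, numeric(1)))
}

# segment-intersection test over non-adjacent edges; O(n^2), rings are short
ring_self_intersects <- function(p) {
  n <- nrow(p)
  if (n < 4) return(FALSE)
  a1 <- p
  a2 <- p[c(2:n, 1), , drop = FALSE]
  for (i in seq_len(n - 2)) {
    for (j in (i + 2):n) {
      if (i == 1 && j == n) next  # adjacent through the closure
      if (segments_cross(a1[i, ], a2[i, ], a1[j, ], a2[j, ])) return(TRUE)
    }
  }
  FALSE
}

segments_cross <- function(p1, p2, q1, q2) {
  o <- function(a, b, c) sign((b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
  o1 <- o(p1, p2, q1); o2 <- o(p1, p2, q2)
  o3 <- o(q1, q2, p1); o4 <- o(q1, q2, p2)
  (o1 != o2) && (o3 != o4) && all(c(o1, o2, o3, o4) != 0)
}

#' Read canopy polygons from GeoJSON or WKT
#'
#' Accepts a GeoJSON file (Polygon, MultiPolygon, Feature or FeatureCollection;
#' outer rings only, holes are not supported) or a text file of WKT
#' `POLYGON`/`MULTIPOLYGON` literals, one per line. Coordinates are taken as
#' plot-local metres.
#'
#' @param path File path; format is sniffed from the first non-blank character
#'   (`{` means GeoJSON).
#' @return A [canopy_set()].
#' @export
read_canopies <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  first <- substr(trimws(txt), 1, 1)
  if (first == "{") canopies_from_geojson(txt) else canopies_from_wkt(txt)
}

canopies_from_geojson <- function(txt) {
  g <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  polys <- list()
  add_geom <- function(geom) {
    if (is.null(geom)) return()
    if (identical(geom$type, "Polygon")) {
      ring <- geom$coordinates[[1]]  # outer ring only
      polys[[length(polys) + 1]] <<- do.call(rbind, lapply(ring, unlist))
    } else if (identical(geom$type, "MultiPolygon")) {
      for (poly in geom$coordinates) {
        polys[[length(polys) + 1]] <<- do.call(rbind, lapply(poly[[1]], unlist))
      }
    } else {
      stop("unsupported GeoJSON geometry: ", geom$type, call. = FALSE)
    }
  }
  if (identical(g$type, "FeatureCollection")) {
    for (f in g$features) add_geom(f$geometry)
  } else if (identical(g$type, "Feature")) {
    add_geom(g$geometry)
  } else {
    add_geom(g)
  }
  canopy_set(polys)
}

canopies_from_wkt <- function(txt) {
  lines <- trimws(strsplit(txt, "\n", fixed = TRUE)[[1]])
  lines <- lines[nzchar(lines)]
  polys <- list()
  parse_ring <- function(s) {
    pts <- strsplit(trimws(strsplit(s, ",", fixed = TRUE)[[1]]), "\\s+")
    do.call(rbind, lapply(pts, function(p) as.numeric(p[1:2])))
  }
  for (ln in lines) {
    up <- toupper(ln)
    if (startsWith(up, "POLYGON")) {
      body <- sub("^POLYGON\\s*\\(\\((.*)\\)\\)\\s*$", "\\1", ln, ignore.case = TRUE)
      polys[[length(polys) + 1]] <- parse_ring(strsplit(body, "\\)\\s*,\\s*\\(")[[1]][1])
    } else if (startsWith(up, "MULTIPOLYGON")) {
      body <- sub("^MULTIPOLYGON\\s*\\(\\(\\((.*)\\)\\)\\)\\s*$", "\\1", ln, ignore.case = TRUE)
      for (part in strsplit(body, "\\)\\s*\\)\\s*,\\s*\\(\\s*\\(")[[1]]) {
        polys[[length(polys) + 1]] <- parse_ring(strsplit(part, "\\)\\s*,\\s*\\(")[[1]][1])
      }
    } else {
      stop("unsupported WKT geometry: ", ln, call. = FALSE)
    }
  }
  canopy_set(polys)
}

#' Write canopy polygons as GeoJSON
#' @param canopies A [canopy_set()].
#' @param path Output path.
#' @export
write_canopies <- function(canopies, path) {
  stopifnot(inherits(canopies, "canopy_set"))
  feats <- lapply(canopies$polygons, function(p) {
    ring <- rbind(p, p[1, , drop = FALSE])
    list(type = "Feature", properties = stats::setNames(list(), character(0)),
         geometry = list(type = "Polygon",
                         coordinates = list(lapply(seq_len(nrow(ring)),
                                                   function(i) c(ring[i, 1], ring[i, 2])))))
  })
  obj <- list(type = "FeatureCollection", features = feats)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), path)
  invisible(path)
}

# ---- raster I/O --------------------------------------------------------------

#' Write a raster layer to file
#'
#' `"ascii"` writes an ESRI ASCII grid (plain text, full double precision;
#' reading it back with [read_raster()] reproduces values, grid and missing
#' mask exactly). `"tiff"` writes a 32-bit float TIFF plus an ESRI world file
#' (`.tfw`) carrying the plot-local transform; values round-trip at single
#' precision only.
#'
#' @param raster A [raster_layer()].
#' @param path Output path.
#' @param format `"ascii"` or `"tiff"`.
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path, format = c("ascii", "tiff")) {
  stopifnot(inherits(raster, "raster_layer"))
  if (!is.character(format) || !format[1] %in% c("ascii", "tiff")) {
    stop("unknown raster format '", format[1],
         "'; supported formats: ascii, tiff", call. = FALSE)
  }
  format <- format[1]
  if (format == "ascii") write_ascii_grid(raster, path) else write_tiff_raster(raster, path)
  invisible(path)
}

write_ascii_grid <- function(raster, path) {
  g <- raster$grid
  nodata <- -9999
  v <- raster$values
  if (any(v[!is.na(v)] == nodata)) nodata <- min(v, na.rm = TRUE) - 1e6
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write raster to ", path,
                                           call. = FALSE),
                  warning = function(w) stop("cannot write raster to ", path,
                                             call. = FALSE))
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", g$n_cols),
               sprintf("nrows %d", g$n_rows),
               sprintf("xllcorner %s", format(g$extent$x_min, digits = 17)),
               sprintf("yllcorner %s", format(g$extent$y_min, digits = 17)),
               sprintf("cellsize %s", format(g$resolution, digits = 17)),
               sprintf("NODATA_value %s", format(nodata, digits = 17)),
               sprintf("units %s", raster$units)), con)
  # ESRI ASCII stores the top row first
  for (r in rev(seq_len(g$n_rows))) {
    row <- v[r, ]
    row[is.na(row)] <- nodata
    writeLines(paste(sprintf("%.17g", row), collapse = " "), con)
  }
}

#' Read a raster layer written by [write_raster()]
#'
#' @param path ESRI ASCII grid (or basename of a TIFF written with its world
#'   file).
#' @return A [raster_layer()].
#' @export
read_raster <- function(path) {
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) return(read_tiff_raster(path))
  lines <- readLines(path)
  hdr <- list(); i <- 1
  repeat {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (!key %in% c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
                    "nodata_value", "units")) break
    hdr[[key]] <- if (key == "units") paste(parts[-1], collapse = " ") else as.numeric(parts[2])
    i <- i + 1
    if (i > length(lines)) break
  }
  n_rows <- as.integer(hdr$nrows); n_cols <- as.integer(hdr$ncols)
  ext <- plot_extent(hdr$xllcorner, hdr$yllcorner,
                     hdr$xllcorner + n_cols * hdr$cellsize,
                     hdr$yllcorner + n_rows * hdr$cellsize)
  grid <- plot_grid(ext, hdr$cellsize)
  vals <- as.numeric(unlist(strsplit(trimws(lines[i:length(lines)]), "\\s+")))
  m <- matrix(vals, nrow = n_rows, ncol = n_cols, byrow = TRUE)
  m <- m[rev(seq_len(n_rows)), , drop = FALSE]  # back to row 1 = lowest y
  if (!is.null(hdr$nodata_value)) m[m == hdr$nodata_value] <- NA
  raster_layer(grid, m, units = if (is.null(hdr$units)) "" else hdr$units)
}

write_tiff_raster <- function(raster, path) {
  g <- raster$grid
  v <- raster$values[rev(seq_len(g$n_rows)), , drop = FALSE]  # image origin top-left
  # the TIFF writer expects samples in [0, 1]: store min-max normalized values
  # (range kept in the description tag) with an alpha plane as the missing mask
  rng <- range(v, na.rm = TRUE, finite = TRUE)
  if (!all(is.finite(rng))) rng <- c(0, 1)
  span <- if (diff(rng) > 0) diff(rng) else 1
  vn <- (v - rng[1]) / span
  alpha <- ifelse(is.na(v), 0, 1)
  vn[is.na(vn)] <- 0
  img <- array(c(vn, alpha), dim = c(nrow(v), ncol(v), 2))
  tiff::writeTIFF(img, path, bits.per.sample = 32)
  # world file: cell size, rotation, centre of the upper-left cell; lines
  # 7-9 extend the standard six with the value range and units (readers of
  # plain world files use the first six only)
  tfw <- sub("\\.tiff?$", ".tfw", path, ignore.case = TRUE)
  writeLines(c(sprintf("%.17g", c(g$resolution, 0, 0, -g$resolution,
                                  g$extent$x_min + g$resolution / 2,
                                  g$extent$y_min + (g$n_rows - 0.5) * g$resolution,
                                  rng[1], span)),
               raster$units),
             tfw)
  invisible(path)
}

read_tiff_raster <- function(path) {
  # libtiff flags the 2-channel (gray + mask) layout as untyped ExtraSamples;
  # the message is informational and the layout is read back correctly
  img <- suppressWarnings(tiff::readTIFF(path))
  units <- ""
  if (length(dim(img)) == 3) {
    v <- img[, , 1]
    v[img[, , 2] < 0.5] <- NA
  } else v <- img
  tfw <- sub("\\.tiff?$", ".tfw", path, ignore.case = TRUE)
  if (!file.exists(tfw)) stop("world file not found: ", tfw, call. = FALSE)
  lines <- readLines(tfw)
  w <- suppressWarnings(as.numeric(lines))
  if (length(w) >= 8 && all(is.finite(w[7:8]))) {
    v <- v * w[8] + w[7]
    if (length(lines) >= 9) units <- lines[9]
  }
  res <- w[1]
  n_rows <- nrow(v); n_cols <- ncol(v)
  x_min <- w[5] - res / 2
  y_min <- w[6] + res / 2 - n_rows * res
  grid <- plot_grid(plot_extent(x_min, y_min, x_min + n_cols * res,
                                y_min + n_rows * res), res)
  raster_layer(grid, v[rev(seq_len(n_rows)), , drop = FALSE], units = units)
}
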