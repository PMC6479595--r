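#' Construct a PointCloud
#'
#' @param points numeric N x 3 matrix or data frame with columns x, y, z.
#' @param colors optional N x 3 RGB matrix (0-255).
#' @param frame `"raw"` (reconstruction units) or `"metric"` (meters).
#' @return a [PointCloud-class] object.
#' @examples
#' pc <- pointCloud(matrix(rnorm(30), ncol = 3))
#' nPoints(pc)
#' @export
pointCloud <- function(points, colors = NULL, frame = c("raw", "metric")) {
  frame <- match.arg(frame)
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  dimnames(points) <- NULL
  if (!is.null(colors)) {
    colors <- as.matrix(colors)
    dimnames(colors) <- NULL
  }
  new("PointCloud", points = points, colors = colors, frame = frame)
}

## ---- readers / writers -----------------------------------------------------

#' Read a point cloud from PLY, XYZ or CSV
#'
#' PLY support covers ASCII and binary-little-endian files with vertex
#' properties `x, y, z` and optional `red, green, blue`. XYZ files are
#' whitespace-separated `x y z` per line; CSV files need a header with
#' columns `x, y, z`. Point order is preserved.
#'
#' @param path file path.
#' @param format `"auto"` (from extension), `"ply"`, `"xyz"` or `"csv"`.
#' @return a [PointCloud-class] with `frame = "raw"`.
#' @seealso [writeCloud()], [scaleCloud()], [cropCloud()]
#' @export
readCloud <- function(path, format = c("auto", "ply", "xyz", "csv")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, ply = "ply", xyz = "xyz", csv = "csv", txt = "xyz",
      stop("cannot infer format from extension '", ext, "'"))
  }
  cloud <- switch(format,
    ply = readPly(path),
    xyz = {
      m <- tryCatch(as.matrix(utils::read.table(path)),
        error = function(e) stop("malformed XYZ file '", path, "': ",
          conditionMessage(e)))
      if (ncol(m) < 3L) stop("XYZ file must have >= 3 columns")
      pointCloud(m[, 1:3, drop = FALSE])
    },
    csv = {
      d <- tryCatch(utils::read.csv(path),
        error = function(e) stop("malformed CSV file '", path, "': ",
          conditionMessage(e)))
      need <- c("x", "y", "z")
      if (!all(need %in% names(d)))
        stop("CSV must have header columns x,y,z (got: ",
          paste(names(d), collapse = ","), ")")
      if (nrow(d) < 1L) stop("empty point cloud in ", path)
      pointCloud(as.matrix(d[, need]))
    })
  cloud
}

readPly <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header is ASCII regardless of body encoding
  header <- character()
  repeat {
    line <- readBinLine(con)
    header <- c(header, line)
    if (identical(line, "end_header")) break
    if (length(header) > 500) stop("malformed PLY '", path,
      "': no end_header within 500 lines")
  }
  if (!identical(header[1], "ply")) stop("malformed PLY '", path,
    "': missing 'ply' magic (line 1)")
  fmt <- grep("^format ", header, value = TRUE)
  if (!length(fmt)) stop("malformed PLY '", path, "': missing format line")
  binary <- grepl("binary_little_endian", fmt[1])
  if (!binary && !grepl("ascii", fmt[1]))
    stop("unsupported PLY format: ", fmt[1])

  # parse elements/properties; only 'vertex' is consumed
  elLines <- grep("^element ", header)
  if (!length(elLines)) stop("malformed PLY '", path, "': no element lines")
  elems <- lapply(seq_along(elLines), function(i) {
    tok <- strsplit(header[elLines[i]], "\\s+")[[1]]
    to <- if (i < length(elLines)) elLines[i + 1] - 1 else length(header) - 1
    props <- header[(elLines[i] + 1):to]
    props <- grep("^property ", props, value = TRUE)
    list(name = tok[2], count = as.integer(tok[3]),
      props = lapply(strsplit(props, "\\s+"), function(p) p[-1]))
  })
  vi <- which(vapply(elems, function(e) e$name, "") == "vertex")
  if (!length(vi)) stop("malformed PLY '", path, "': no vertex element")
  if (vi[1] != 1L) stop("PLY with non-leading vertex element unsupported")
  v <- elems[[vi[1]]]
  if (v$count < 1L) stop("empty point cloud in ", path)
  pnames <- vapply(v$props, function(p) p[length(p)], "")
  ptypes <- vapply(v$props, function(p) p[1], "")
  if (any(ptypes == "list")) stop("list properties on vertex unsupported")
  if (!all(c("x", "y", "z") %in% pnames))
    stop("malformed PLY '", path, "': vertex needs x,y,z properties")

  sizes <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
    short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
    int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
    float = 4L, float32 = 4L, double = 8L, float64 = 8L)
  if (binary) {
    sz <- sizes[ptypes]
    if (any(is.na(sz))) stop("unknown PLY property type")
    stride <- sum(sz)
    raw <- readBin(con, "raw", n = stride * v$count)
    if (length(raw) < stride * v$count)
      stop("malformed PLY '", path, "': truncated vertex data")
    offs <- cumsum(c(0L, sz[-length(sz)]))
    readProp <- function(j) {
      idx <- outer(seq_len(sz[j]), (seq_len(v$count) - 1L) * stride +
        offs[j], "+")
      bytes <- raw[as.vector(idx)]
      ty <- ptypes[j]
      if (ty %in% c("float", "float32"))
        readBin(bytes, "double", n = v$count, size = 4, endian = "little")
      else if (ty %in% c("double", "float64"))
        readBin(bytes, "double", n = v$count, size = 8, endian = "little")
      else if (ty %in% c("uchar", "uint8", "char", "int8"))
        as.numeric(readBin(bytes, "integer", n = v$count, size = 1,
          signed = ty %in% c("char", "int8"), endian = "little"))
      else
        as.numeric(readBin(bytes, "integer", n = v$count, size = sizes[ty],
          endian = "little"))
    }
    cols <- lapply(seq_along(pnames), readProp)
  } else {
    txt <- readLines(con, warn = FALSE)
    txt <- txt[nzchar(trimws(txt))]
    if (length(txt) < v$count) stop("malformed PLY '", path,
      "': expected ", v$count, " vertex lines, found ", length(txt))
    toks <- strsplit(trimws(txt[seq_len(v$count)]), "\\s+")
    bad <- which(lengths(toks) < length(pnames))
    if (length(bad)) stop("malformed PLY '", path, "': vertex record ",
      bad[1], " has too few fields")
    m <- matrix(as.numeric(unlist(lapply(toks,
      function(t) t[seq_along(pnames)]))), ncol = length(pnames), byrow = TRUE)
    cols <- lapply(seq_along(pnames), function(j) m[, j])
  }
  names(cols) <- pnames
  pts <- cbind(cols$x, cols$y, cols$z)
  colors <- NULL
  if (all(c("red", "green", "blue") %in% pnames))
    colors <- cbind(cols$red, cols$green, cols$blue)
  pointCloud(pts, colors = colors)
}

readBinLine <- function(con) {
  out <- raw()
  repeat {
    b <- readBin(con, "raw", n = 1L)
    if (!length(b) || b == as.raw(10L)) break
    out <- c(out, b)
  }
  sub("\r$", "", rawToChar(out))
}

#' Write a point cloud to PLY, XYZ or CSV
#'
#' @param cloud a [PointCloud-class].
#' @param path output path.
#' @param format `"auto"`, `"ply"`, `"xyz"` or `"csv"`.
#' @param binary write binary-little-endian PLY instead of ASCII.
#' @return `path`, invisibly.
#' @export
writeCloud <- function(cloud, path, format = c("auto", "ply", "xyz", "csv"),
                       binary = FALSE) {
  stopifnot(is(cloud, "PointCloud"))
  format <- match.arg(format)
  if (format == "auto")
    format <- switch(tolower(tools::file_ext(path)), ply = "ply",
      xyz = "xyz", csv = "csv", stop("cannot infer format from extension"))
  p <- cloud@points
  if (format == "ply") {
    hasCol <- !is.null(cloud@colors)
    hdr <- c("ply",
      sprintf("format %s 1.0",
        if (binary) "binary_little_endian" else "ascii"),
      sprintf("element vertex %d", nrow(p)),
      "property double x", "property double y", "property double z",
      if (hasCol) c("property uchar red", "property uchar green",
        "property uchar blue"),
      "end_header")
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    if (binary) {
      if (hasCol) {
        for (i in seq_len(nrow(p))) {
          writeBin(p[i, ], con, size = 8, endian = "little")
          writeBin(as.integer(cloud@colors[i, ]), con, size = 1,
            endian = "little")
        }
      } else {
        writeBin(as.vector(t(p)), con, size = 8, endian = "little")
      }
    } else {
      body <- if (hasCol)
        sprintf("%.9g %.9g %.9g %d %d %d", p[, 1], p[, 2], p[, 3],
          cloud@colors[, 1], cloud@colors[, 2], cloud@colors[, 3])
      else sprintf("%.9g %.9g %.9g", p[, 1], p[, 2], p[, 3])
      writeLines(body, con, sep = "\n")
    }
  } else if (format == "xyz") {
    utils::write.table(p, path, row.names = FALSE, col.names = FALSE)
  } else {
    utils::write.csv(data.frame(x = p[, 1], y = p[, 2], z = p[, 3]),
      path, row.names = FALSE)
  }
  invisible(path)
}

## ---- scaling and cropping --------------------------------------------------

#' Scale a raw cloud to metric units
#'
#' Multiplies every coordinate by `trueLen / measuredLen`, where
#' `measuredLen` is a reference length measured in the raw cloud and
#' `trueLen` its real-world value in meters. Marks the cloud metric.
#'
#' @param cloud a [PointCloud-class].
#' @param measuredLen reference length in raw units (> 0).
#' @param trueLen the same length in meters (> 0).
#' @return metric [PointCloud-class].
#' @export
scaleCloud <- function(cloud, measuredLen, trueLen) {
  stopifnot(is(cloud, "PointCloud"))
  if (!is.finite(measuredLen) || measuredLen <= 0)
    stop("measuredLen must be > 0")
  if (!is.finite(trueLen) || trueLen <= 0) stop("trueLen must be > 0")
  pointCloud(cloud@points * (trueLen / measuredLen), colors = cloud@colors,
    frame = "metric")
}

#' Crop specification: axis-aligned box plus optional soil threshold
#'
#' @param xlim,ylim,zlim length-2 numeric (min, max) in meters; min < max.
#' @param soilZ optional elevation; points with z <= soilZ are discarded.
#' @return a `CropSpec` list.
#' @export
cropSpec <- function(xlim = c(-Inf, Inf), ylim = c(-Inf, Inf),
                     zlim = c(-Inf, Inf), soilZ = NULL) {
  for (lim in list(xlim, ylim, zlim))
    if (length(lim) != 2L || !(lim[1] < lim[2]))
      stop("each axis limit must be (min, max) with min < max")
  structure(list(xlim = xlim, ylim = ylim, zlim = zlim, soilZ = soilZ),
    class = "CropSpec")
}

#' Crop a cloud to the plant region
#'
#' Keeps exactly the points inside the axis-aligned box and, if `soilZ` is
#' given, strictly above it. Kept + removed always partitions the input.
#'
#' @param cloud metric [PointCloud-class].
#' @param spec a [cropSpec()].
#' @param returnIndex also return the kept indices.
#' @return cropped [PointCloud-class]; with `returnIndex = TRUE`, a list
#'   `(cloud, kept)`.
#' @export
cropCloud <- function(cloud, spec, returnIndex = FALSE) {
  stopifnot(is(cloud, "PointCloud"), inherits(spec, "CropSpec"))
  if (cloud@frame != "metric")
    stop("cropCloud requires a metric cloud; call scaleCloud() first")
  p <- cloud@points
  keep <- p[, 1] >= spec$xlim[1] & p[, 1] <= spec$xlim[2] &
          p[, 2] >= spec$ylim[1] & p[, 2] <= spec$ylim[2] &
          p[, 3] >= spec$zlim[1] & p[, 3] <= spec$zlim[2]
  if (!is.null(spec$soilZ)) keep <- keep & p[, 3] > spec$soilZ
  if (!any(keep)) stop("crop removed all points: no plant in region")
  out <- pointCloud(p[keep, , drop = FALSE],
    colors = if (is.null(cloud@colors)) NULL
      else cloud@colors[keep, , drop = FALSE],
    frame = "metric")
  if (returnIndex) list(cloud = out, kept = which(keep)) else out
}

#' Subset a PointCloud by index
#' @param cloud a [PointCloud-class]
#' @param idx integer or logical index
#' @return a [PointCloud-class]
#' @export
subsetCloud <- function(cloud, idx) {
  stopifnot(is(cloud, "PointCloud"))
  pointCloud(cloud@points[idx, , drop = FALSE],
    colors = if (is.null(cloud@colors)) NULL
      else cloud@colors[idx, , drop = FALSE],
    frame = cloud@frame)
}
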