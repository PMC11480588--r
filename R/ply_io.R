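#' Read a PLY point cloud
#'
#' Supports ASCII and binary little/big-endian PLY with a `vertex` element
#' carrying at least `x`, `y`, `z`; a `label` property (any integer type) is
#' read into the semantic labels and an `instance` property into instance
#' ids. Faces and other elements are ignored.
#'
#' @param path path to a `.ply` file.
#' @return A [PointCloud-class].
#' @export
readPly <- function(path) {
  stopIfNot(file.exists(path), sprintf("file not found: %s", path))
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    line <- readBinLine(con)
    header <- c(header, line)
    if (identical(trimws(line), "end_header")) break
    if (length(header) > 500L) stop("malformed PLY header", call. = FALSE)
  }
  fmtLine <- grep("^format ", header, value = TRUE)
  stopIfNot(length(fmtLine) == 1L, "PLY header lacks a format line")
  fmt <- strsplit(trimws(fmtLine), "[[:space:]]+")[[1L]][2L]
  endian <- switch(fmt,
    ascii = NA_character_,
    binary_little_endian = "little",
    binary_big_endian = "big",
    stop("unsupported PLY format: ", fmt, call. = FALSE)
  )

  # parse elements/properties in order
  elems <- list()
  cur <- NULL
  for (line in header) {
    tok <- strsplit(trimws(line), "[[:space:]]+")[[1L]]
    if (tok[1L] == "element") {
      if (!is.null(cur)) elems[[cur$name]] <- cur
      cur <- list(name = tok[2L], count = as.integer(tok[3L]),
                  props = character(0), types = character(0), listProp = logical(0))
    } else if (tok[1L] == "property" && !is.null(cur)) {
      if (tok[2L] == "list") {
        cur$props <- c(cur$props, tok[5L])
        cur$types <- c(cur$types, paste(tok[3L], tok[4L]))
        cur$listProp <- c(cur$listProp, TRUE)
      } else {
        cur$props <- c(cur$props, tok[3L])
        cur$types <- c(cur$types, tok[2L])
        cur$listProp <- c(cur$listProp, FALSE)
      }
    }
  }
  if (!is.null(cur)) elems[[cur$name]] <- cur
  stopIfNot("vertex" %in% names(elems), "PLY file has no vertex element")

  readElement <- function(el) {
    if (is.na(endian)) {
      rows <- matrix(NA_real_, el$count, length(el$props))
      for (i in seq_len(el$count)) {
        tok <- strsplit(trimws(readBinLine(con)), "[[:space:]]+")[[1L]]
        if (any(el$listProp)) {
          # list properties only supported for skipped elements
          vals <- as.numeric(tok)
          rows[i, ] <- vals[seq_along(el$props)]
        } else rows[i, ] <- as.numeric(tok)
      }
      rows
    } else {
      rows <- matrix(NA_real_, el$count, length(el$props))
      for (i in seq_len(el$count)) {
        for (j in seq_along(el$props)) {
          if (el$listProp[j]) {
            cntType <- strsplit(el$types[j], " ")[[1L]]
            cnt <- readPlyScalar(con, cntType[1L], endian)
            for (z in seq_len(cnt)) readPlyScalar(con, cntType[2L], endian)
            rows[i, j] <- NA_real_
          } else {
            rows[i, j] <- readPlyScalar(con, el$types[j], endian)
          }
        }
      }
      rows
    }
  }

  vert <- NULL
  for (el in elems) {
    m <- readElement(el)
    if (el$name == "vertex") { vert <- m; colnames(vert) <- el$props; break }
  }
  need <- c("x", "y", "z")
  stopIfNot(all(need %in% colnames(vert)), "vertex element lacks x/y/z")
  pointCloud(vert[, need, drop = FALSE],
    semanticLabels = if ("label" %in% colnames(vert)) as.integer(vert[, "label"]) else NULL,
    instanceIds = if ("instance" %in% colnames(vert)) as.integer(vert[, "instance"]) else NULL
  )
}

readBinLine <- function(con) {
  out <- raw(0)
  repeat {
    b <- readBin(con, "raw", 1L)
    if (!length(b) || b == as.raw(10L)) break
    if (b != as.raw(13L)) out <- c(out, b)
  }
  rawToChar(out)
}

plyTypeInfo <- function(type) {
  switch(type,
    char = , int8 = list(what = "integer", size = 1L, signed = TRUE),
    uchar = , uint8 = list(what = "integer", size = 1L, signed = FALSE),
    short = , int16 = list(what = "integer", size = 2L, signed = TRUE),
    ushort = , uint16 = list(what = "integer", size = 2L, signed = FALSE),
    int = , int32 = list(what = "integer", size = 4L, signed = TRUE),
    uint = , uint32 = list(what = "integer", size = 4L, signed = TRUE),
    float = , float32 = list(what = "numeric", size = 4L, signed = TRUE),
    double = , float64 = list(what = "numeric", size = 8L, signed = TRUE),
    stop("unsupported PLY property type: ", type, call. = FALSE)
  )
}

readPlyScalar <- function(con, type, endian) {
  info <- plyTypeInfo(type)
  as.numeric(readBin(con, info$what, 1L, size = info$size, signed = info$signed,
                     endian = endian))
}

#' Write a point cloud (or mesh) as PLY
#'
#' Vertices carry `x`, `y`, `z` as `float64` plus `label`/`instance`
#' properties when the cloud has them; an optional triangle index matrix is
#' written as a `face` element.
#'
#' @param cloud a [PointCloud-class].
#' @param path output path.
#' @param triangles optional integer matrix (rows = triangles, 1-based vertex
#'   indices), e.g. from [bpaLeafArea()].
#' @param binary write `binary_little_endian` (default) or ASCII.
#' @return `path`, invisibly.
#' @export
writePly <- function(cloud, path, triangles = NULL, binary = TRUE) {
  stopIfNot(is(cloud, "PointCloud"), "cloud must be a PointCloud")
  p <- cloud@points
  n <- nrow(p)
  hasLab <- length(cloud@semanticLabels) > 0L
  hasInst <- length(cloud@instanceIds) > 0L
  header <- c(
    "ply",
    sprintf("format %s 1.0", if (binary) "binary_little_endian" else "ascii"),
    sprintf("element vertex %d", n),
    "property float64 x", "property float64 y", "property float64 z",
    if (hasLab) "property int32 label",
    if (hasInst) "property int32 instance",
    if (!is.null(triangles)) sprintf("element face %d", nrow(triangles)),
    if (!is.null(triangles)) "property list uchar int32 vertex_indices",
    "end_header"
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  if (binary) {
    for (i in seq_len(n)) {
      writeBin(as.numeric(p[i, ]), con, size = 8L, endian = "little")
      if (hasLab) writeBin(cloud@semanticLabels[i], con, size = 4L, endian = "little")
      if (hasInst) writeBin(cloud@instanceIds[i], con, size = 4L, endian = "little")
    }
    if (!is.null(triangles)) {
      for (t in seq_len(nrow(triangles))) {
        writeBin(as.raw(3L), con)
        writeBin(as.integer(triangles[t, ] - 1L), con, size = 4L, endian = "little")
      }
    }
  } else {
    cols <- list(
      format(p[, 1L], digits = 17, trim = TRUE, scientific = FALSE),
      format(p[, 2L], digits = 17, trim = TRUE, scientific = FALSE),
      format(p[, 3L], digits = 17, trim = TRUE, scientific = FALSE)
    )
    if (hasLab) cols <- c(cols, list(cloud@semanticLabels))
    if (hasInst) cols <- c(cols, list(cloud@instanceIds))
    writeLines(do.call(paste, cols), con)
    if (!is.null(triangles))
      writeLines(paste(3L, triangles[, 1L] - 1L, triangles[, 2L] - 1L,
                       triangles[, 3L] - 1L), con)
  }
  invisible(path)
}
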