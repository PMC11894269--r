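#' Construct a triangle mesh
#'
#' Minimal triangulated-surface container used for dental scans: a vertex
#' matrix in mm and a triangle index matrix.
#'
#' @param vertices n x 3 numeric matrix (mm).
#' @param triangles m x 3 integer matrix of 1-based vertex indices.
#' @return A `tri_mesh` list with elements `vertices` and `triangles`.
#' @export
tri_mesh <- function(vertices, triangles) {
  vertices <- as.matrix(vertices)
  triangles <- as.matrix(triangles)
  storage.mode(vertices) <- "double"
  storage.mode(triangles) <- "integer"
  if (ncol(vertices) != 3 || ncol(triangles) != 3) {
    ms_validation_error("vertices and triangles must have 3 columns")
  }
  if (nrow(triangles) > 0 &&
      (min(triangles) < 1 || max(triangles) > nrow(vertices))) {
    ms_validation_error("triangle indices out of range")
  }
  colnames(vertices) <- c("x", "y", "z")
  structure(list(vertices = vertices, triangles = triangles),
            class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("Triangle mesh: %d vertices, %d triangles\n",
              nrow(x$vertices), nrow(x$triangles)))
  invisible(x)
}

# STL stores float32; quantize doubles through a float32 round trip so
# binary and ASCII encodings of the same mesh parse identically.
as_float32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4), "numeric",
          n = length(x), size = 4)
}

triangle_soup <- function(mesh) {
  t(cbind(mesh$vertices[mesh$triangles[, 1], , drop = FALSE],
          mesh$vertices[mesh$triangles[, 2], , drop = FALSE],
          mesh$vertices[mesh$triangles[, 3], , drop = FALSE]))  # 9 x m
}

facet_normals <- function(soup) {
  # soup is 9 x m: v1, v2, v3 stacked
  u <- soup[4:6, , drop = FALSE] - soup[1:3, , drop = FALSE]
  v <- soup[7:9, , drop = FALSE] - soup[1:3, , drop = FALSE]
  n <- rbind(u[2, ] * v[3, ] - u[3, ] * v[2, ],
             u[3, ] * v[1, ] - u[1, ] * v[3, ],
             u[1, ] * v[2, ] - u[2, ] * v[1, ])
  len <- sqrt(colSums(n^2))
  len[len == 0] <- 1
  sweep(n, 2, len, "/")
}

#' Write a mesh as STL
#'
#' Writes binary (default) or ASCII stereolithography. Coordinates are
#' quantized to float32 (the STL storage type) in both encodings, so the
#' two produce bit-identical geometry on re-read.
#'
#' @param mesh A [tri_mesh()].
#' @param path Output file path.
#' @param format `"binary"` or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_stl <- function(mesh, path, format = c("binary", "ascii")) {
  format <- match.arg(format)
  if (!inherits(mesh, "tri_mesh")) ms_validation_error("mesh must be a tri_mesh")
  m <- nrow(mesh$triangles)
  soup <- matrix(as_float32(triangle_soup(mesh)), nrow = 9)
  normals <- matrix(as_float32(facet_normals(soup)), nrow = 3)
  if (format == "binary") {
    con <- tryCatch(file(path, "wb"), error = function(e) NULL)
    if (is.null(con)) ms_io_error(paste0("cannot write ", path))
    on.exit(close(con))
    header <- charToRaw(sprintf("%-80s", "monson tri_mesh binary STL"))[1:80]
    writeBin(header, con)
    writeBin(as.integer(m), con, size = 4, endian = "little")
    floats <- rbind(normals, soup)  # 12 floats per facet
    fr <- writeBin(as.numeric(floats), raw(), size = 4, endian = "little")
    rec <- rbind(matrix(fr, nrow = 48), matrix(as.raw(0), nrow = 2, ncol = m))
    writeBin(as.vector(rec), con)
  } else {
    lines <- character(2 + 7 * m)
    lines[1] <- "solid monson"
    lines[length(lines)] <- "endsolid monson"
    if (m > 0) {
      fmt <- function(v) sprintf("%.9g %.9g %.9g", v[1, ], v[2, ], v[3, ])
      block <- rbind(
        paste0("  facet normal ", fmt(normals)),
        "    outer loop",
        paste0("      vertex ", fmt(soup[1:3, , drop = FALSE])),
        paste0("      vertex ", fmt(soup[4:6, , drop = FALSE])),
        paste0("      vertex ", fmt(soup[7:9, , drop = FALSE])),
        "    endloop",
        "  endfacet")
      lines[2:(1 + 7 * m)] <- as.vector(block)
    }
    ok <- tryCatch({ writeLines(lines, path); TRUE },
                   error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok) ms_io_error(paste0("cannot write ", path))
  }
  invisible(path)
}

#' Read an STL file
#'
#' Reads ASCII or binary stereolithography (auto-detected), merges
#' duplicated vertices, and drops degenerate triangles (repeated vertex
#' or zero area) with a message reporting the count.
#'
#' @param path Path to the STL file.
#' @return A [tri_mesh()].
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) ms_io_error(paste0("file not found: ", path))
  size <- file.info(path)$size
  soup <- NULL
  if (size >= 84) {
    con <- file(path, "rb")
    readBin(con, raw(), n = 80)
    m <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    if (!is.na(m) && m >= 0 && size == 84 + 50 * m) {
      rec <- matrix(readBin(con, raw(), n = 50 * m), nrow = 50)
      floats <- readBin(as.vector(rec[1:48, , drop = FALSE]), "numeric",
                        n = 12 * m, size = 4, endian = "little")
      fm <- matrix(floats, nrow = 12)
      soup <- fm[4:12, , drop = FALSE]  # drop stored normals
    }
    close(con)
  }
  if (is.null(soup)) soup <- read_stl_ascii(path)
  if (ncol(soup) == 0) ms_io_error(paste0("no triangles in STL file: ", path))
  soup_to_mesh(soup)
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^\\s*solid", lines[1])) {
    ms_io_error(paste0("unrecognised STL file: ", path))
  }
  vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vl) %% 3 != 0) {
    ms_io_error(paste0("malformed ASCII STL (vertex count not a multiple of 3): ",
                       path))
  }
  nums <- suppressWarnings(vapply(strsplit(trimws(vl), "\\s+"), function(f) {
    as.numeric(f[2:4])
  }, numeric(3)))
  if (any(is.na(nums))) ms_io_error(paste0("non-numeric vertex in ", path))
  matrix(as.vector(nums), nrow = 9)
}

soup_to_mesh <- function(soup) {
  m <- ncol(soup)
  verts <- matrix(as.vector(soup), ncol = 3, byrow = TRUE)  # 3m x 3
  key <- paste(verts[, 1], verts[, 2], verts[, 3])
  uid <- match(key, key[!duplicated(key)])
  uverts <- verts[!duplicated(key), , drop = FALSE]
  tri <- matrix(uid, ncol = 3, byrow = TRUE)
  # degenerate: repeated vertex index or zero area
  repeated <- tri[, 1] == tri[, 2] | tri[, 2] == tri[, 3] | tri[, 1] == tri[, 3]
  u <- uverts[tri[, 2], , drop = FALSE] - uverts[tri[, 1], , drop = FALSE]
  v <- uverts[tri[, 3], , drop = FALSE] - uverts[tri[, 1], , drop = FALSE]
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  zero_area <- rowSums(cr^2) == 0
  drop <- repeated | zero_area
  if (any(drop)) {
    message(sprintf("read_mesh: dropped %d degenerate triangle(s)", sum(drop)))
    tri <- tri[!drop, , drop = FALSE]
  }
  if (nrow(tri) == 0) ms_io_error("no non-degenerate triangles in STL file")
  tri_mesh(uverts, tri)
}
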