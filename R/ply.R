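## PLY input/output for colored point clouds and triangle meshes.
## Supported dialects: format ascii 1.0 and format binary_little_endian 1.0;
## vertex properties x,y,z as float/double and red,green,blue as uchar or
## float.  8-bit colors are rescaled to [0,1] on read and written back as
## round(255 * c).

PLY_TYPE_SIZE <- c(char = 1L, int8 = 1L, uchar = 1L, uint8 = 1L,
                   short = 2L, int16 = 2L, ushort = 2L, uint16 = 2L,
                   int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_is_float <- function(type) type %in% c("float", "float32", "double", "float64")
ply_is_unsigned <- function(type) type %in% c("uchar", "uint8", "ushort", "uint16", "uint", "uint32")

parse_ply_header <- function(raw) {
  ## locate "end_header\n" in the raw bytes
  marker <- charToRaw("end_header")
  limit <- min(length(raw), 65536L)
  hit <- NA_integer_
  cand <- which(raw[seq_len(limit)] == marker[1])
  for (s in cand) {
    if (s + length(marker) - 1L <= length(raw) &&
        identical(raw[s:(s + length(marker) - 1L)], marker)) {
      hit <- s
      break
    }
  }
  if (is.na(hit)) {
    stop_trayphen("not a PLY file: no end_header found",
                  class = "trayphen_ply_parse")
  }
  ## body begins after the newline terminating "end_header"
  body_start <- hit + length(marker)
  while (body_start <= length(raw) &&
         raw[body_start] %in% as.raw(c(0x0d, 0x0a))) {
    body_start <- body_start + 1L
    if (raw[body_start - 1L] == as.raw(0x0a)) break
  }
  header_txt <- rawToChar(raw[seq_len(hit - 1L)])
  lines <- strsplit(header_txt, "\r?\n")[[1]]
  if (length(lines) == 0L || trimws(lines[1]) != "ply") {
    stop_trayphen("not a PLY file: first line is not 'ply'",
                  class = "trayphen_ply_parse")
  }
  format <- NULL
  elements <- list()
  cur <- NULL
  for (ln in lines[-1]) {
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(tok) == 0L || tok[1] == "comment" || tok[1] == "obj_info") next
    if (tok[1] == "format") {
      if (length(tok) < 2L ||
          !tok[2] %in% c("ascii", "binary_little_endian")) {
        stop_trayphen("unsupported PLY format line: '", ln, "'",
                      class = "trayphen_ply_parse")
      }
      format <- tok[2]
    } else if (tok[1] == "element") {
      if (length(tok) != 3L || is.na(suppressWarnings(as.integer(tok[3])))) {
        stop_trayphen("garbled PLY element line: '", ln, "'",
                      class = "trayphen_ply_parse")
      }
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = tok[2], count = as.integer(tok[3]),
                  properties = list())
    } else if (tok[1] == "property") {
      if (is.null(cur)) {
        stop_trayphen("PLY property before any element: '", ln, "'",
                      class = "trayphen_ply_parse")
      }
      if (tok[2] == "list") {
        if (length(tok) != 5L) {
          stop_trayphen("garbled PLY list property: '", ln, "'",
                        class = "trayphen_ply_parse")
        }
        cur$properties[[tok[5]]] <- list(name = tok[5], list = TRUE,
                                         count_type = tok[3],
                                         value_type = tok[4])
      } else {
        if (length(tok) != 3L || !tok[2] %in% names(PLY_TYPE_SIZE)) {
          stop_trayphen("garbled PLY property line: '", ln, "'",
                        class = "trayphen_ply_parse")
        }
        cur$properties[[tok[3]]] <- list(name = tok[3], list = FALSE,
                                         type = tok[2])
      }
    } else if (tok[1] != "end_header") {
      stop_trayphen("unrecognized PLY header line: '", ln, "'",
                    class = "trayphen_ply_parse")
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(format)) {
    stop_trayphen("PLY header has no format line",
                  class = "trayphen_ply_parse")
  }
  list(format = format, elements = elements, body_start = body_start)
}

read_binary_scalars <- function(raw, offset0, n, record_size, prop_offset, type) {
  size <- PLY_TYPE_SIZE[[type]]
  base <- offset0 + (seq_len(n) - 1L) * record_size + prop_offset
  idx <- rep(base, each = size) + seq_len(size)
  bytes <- raw[idx]
  if (ply_is_float(type)) {
    readBin(bytes, "double", n = n, size = size, endian = "little")
  } else {
    readBin(bytes, "integer", n = n, size = size,
            signed = !ply_is_unsigned(type) || size >= 4L, endian = "little")
  }
}

read_ply_vertices <- function(raw, hdr) {
  vx <- hdr$elements[["vertex"]]
  if (is.null(vx)) {
    stop_trayphen("PLY file has no vertex element",
                  class = "trayphen_ply_parse")
  }
  if (names(hdr$elements)[1] != "vertex") {
    stop_trayphen("unsupported PLY layout: vertex is not the first element",
                  class = "trayphen_ply_parse")
  }
  if (any(vapply(vx$properties, function(p) isTRUE(p$list), logical(1)))) {
    stop_trayphen("list properties on the vertex element are not supported",
                  class = "trayphen_ply_parse")
  }
  pnames <- names(vx$properties)
  need_xyz <- c("x", "y", "z")
  if (!all(need_xyz %in% pnames)) {
    stop_trayphen("PLY vertex element lacks x/y/z properties",
                  class = "trayphen_ply_parse")
  }
  n <- vx$count
  vals <- list()
  if (hdr$format == "ascii") {
    txt <- rawToChar(raw[hdr$body_start:length(raw)])
    lines <- strsplit(txt, "\r?\n")[[1]]
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) < n) {
      stop_trayphen("PLY body has fewer vertex rows (", length(lines),
                    ") than declared (", n, ")", class = "trayphen_ply_parse")
    }
    if (n > 0L) {
      tokens <- scan(text = paste(lines[seq_len(n)], collapse = "\n"),
                     what = numeric(), quiet = TRUE)
      if (length(tokens) != n * length(pnames)) {
        stop_trayphen("PLY vertex rows do not match the declared properties",
                      class = "trayphen_ply_parse")
      }
      m <- matrix(tokens, nrow = n, byrow = TRUE)
      for (j in seq_along(pnames)) vals[[pnames[j]]] <- m[, j]
    } else {
      for (nm in pnames) vals[[nm]] <- numeric(0)
    }
  } else {
    types <- vapply(vx$properties, `[[`, character(1), "type")
    sizes <- PLY_TYPE_SIZE[types]
    record <- sum(sizes)
    offs <- c(0L, cumsum(sizes))[seq_along(sizes)]
    if (length(raw) - hdr$body_start + 1L < n * record) {
      stop_trayphen("PLY binary body is shorter than the declared vertex data",
                    class = "trayphen_ply_parse")
    }
    for (j in seq_along(pnames)) {
      vals[[pnames[j]]] <- read_binary_scalars(
        raw, hdr$body_start - 1L, n, record, offs[j], types[j])
    }
  }
  vals
}

#' Read a colored point cloud from a PLY file
#'
#' Accepts ASCII and binary little-endian PLY with a `vertex` element holding
#' `x,y,z` coordinates and `red,green,blue` colors.  8-bit integer colors are
#' rescaled to `[0,1]`; float colors are taken as-is.  Ids are assigned
#' `0..N-1` in file order.
#'
#' @param path path to a PLY file.
#' @return a [colored_point_cloud()].
#' @export
read_ply <- function(path) {
  if (!file.exists(path)) {
    stop_trayphen("file not found: ", path, class = "trayphen_io")
  }
  raw <- readBin(path, "raw", n = file.size(path))
  hdr <- parse_ply_header(raw)
  vx <- hdr$elements[["vertex"]]
  vals <- read_ply_vertices(raw, hdr)
  need_rgb <- c("red", "green", "blue")
  if (!all(need_rgb %in% names(vals))) {
    stop_trayphen("PLY file has no color: vertex element lacks red/green/blue",
                  class = "trayphen_ply_no_color")
  }
  pts <- cbind(vals$x, vals$y, vals$z)
  cols <- cbind(vals$red, vals$green, vals$blue)
  ctypes <- vapply(vx$properties[need_rgb], function(p) {
    if (hdr$format == "ascii" && is.null(p$type)) "uchar" else p$type %||% "uchar"
  }, character(1))
  if (!all(ply_is_float(ctypes))) cols <- cols / 255
  colored_point_cloud(pts, pmin(pmax(cols, 0), 1))
}

#' Write a colored point cloud as PLY
#'
#' Coordinates are stored as doubles, colors as 8-bit integers
#' `round(255 * c)`.
#'
#' @param cloud a [colored_point_cloud()].
#' @param path output path.
#' @param encoding `"binary"` (little-endian, default) or `"ascii"`.
#' @return `path`, invisibly.
#' @export
write_ply <- function(cloud, path, encoding = c("binary", "ascii")) {
  encoding <- match.arg(encoding)
  stopifnot(inherits(cloud, "colored_point_cloud"))
  n <- n_points(cloud)
  fmt <- if (encoding == "ascii") "ascii" else "binary_little_endian"
  header <- c("ply",
              paste("format", fmt, "1.0"),
              paste("element vertex", n),
              "property double x", "property double y", "property double z",
              "property uchar red", "property uchar green",
              "property uchar blue",
              "end_header")
  bytes <- as.integer(round(255 * cloud$colors))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con, sep = "\n")
  if (n == 0L) return(invisible(path))
  if (encoding == "ascii") {
    rows <- sprintf("%.17g %.17g %.17g %d %d %d",
                    cloud$points[, 1], cloud$points[, 2], cloud$points[, 3],
                    bytes[seq_len(n)], bytes[n + seq_len(n)],
                    bytes[2L * n + seq_len(n)])
    writeLines(rows, con, sep = "\n")
  } else {
    coord_raw <- writeBin(as.vector(t(cloud$points)), raw(),
                          size = 8L, endian = "little")
    coord_mat <- matrix(coord_raw, nrow = 24L)   # one column per point
    col_mat <- matrix(as.raw(bytes[as.vector(t(matrix(seq_len(3L * n), n)))]),
                      nrow = 3L)
    writeBin(as.vector(rbind(coord_mat, col_mat)), con)
  }
  invisible(path)
}

#' Triangle mesh
#'
#' Vertices in millimetres and consistently oriented triangular faces;
#' watertightness is verified by [mesh_volume()].
#'
#' @param vertices numeric `V x 3` matrix.
#' @param faces integer `F x 3` matrix of 1-based vertex indices.
#' @return an object of class `triangle_mesh`.
#' @export
triangle_mesh <- function(vertices, faces) {
  vertices <- as_coord_matrix(vertices, "vertices")
  faces <- as.matrix(faces)
  if (ncol(faces) != 3L) {
    stop_trayphen("faces must be an F x 3 matrix of vertex indices",
                  class = "trayphen_invalid_mesh")
  }
  storage.mode(faces) <- "integer"
  if (nrow(faces) && (min(faces) < 1L || max(faces) > nrow(vertices))) {
    stop_trayphen("face indices out of range", class = "trayphen_invalid_mesh")
  }
  structure(list(vertices = vertices, faces = faces), class = "triangle_mesh")
}

#' Read a triangle mesh from a PLY file
#'
#' Supports ASCII meshes and binary little-endian meshes whose face element
#' stores uniform 3-vertex lists.
#'
#' @param path path to a PLY file with `vertex` and `face` elements.
#' @return a [triangle_mesh()].
#' @export
read_ply_mesh <- function(path) {
  if (!file.exists(path)) {
    stop_trayphen("file not found: ", path, class = "trayphen_io")
  }
  raw <- readBin(path, "raw", n = file.size(path))
  hdr <- parse_ply_header(raw)
  vx <- hdr$elements[["vertex"]]
  fc <- hdr$elements[["face"]]
  if (is.null(vx) || is.null(fc)) {
    stop_trayphen("PLY mesh needs vertex and face elements",
                  class = "trayphen_ply_parse")
  }
  vals <- read_ply_vertices(raw, hdr)
  verts <- cbind(vals$x, vals$y, vals$z)
  nface <- fc$count
  lp <- fc$properties[[1]]
  if (is.null(lp) || !isTRUE(lp$list)) {
    stop_trayphen("PLY face element must hold a vertex index list",
                  class = "trayphen_ply_parse")
  }
  if (hdr$format == "ascii") {
    txt <- rawToChar(raw[hdr$body_start:length(raw)])
    lines <- strsplit(txt, "\r?\n")[[1]]
    lines <- lines[nzchar(trimws(lines))]
    face_lines <- lines[vx$count + seq_len(nface)]
    toks <- scan(text = paste(face_lines, collapse = "\n"), what = numeric(),
                 quiet = TRUE)
    out <- matrix(NA_integer_, nface, 3L)
    pos <- 1L
    for (i in seq_len(nface)) {
      cnt <- toks[pos]
      if (is.na(cnt) || cnt != 3) {
        stop_trayphen("only triangular faces are supported (face ", i,
                      " has ", cnt, " vertices)", class = "trayphen_ply_parse")
      }
      out[i, ] <- as.integer(toks[pos + 1:3]) + 1L
      pos <- pos + 4L
    }
    faces <- out
  } else {
    vtypes <- vapply(vx$properties, `[[`, character(1), "type")
    voffset <- hdr$body_start - 1L + vx$count * sum(PLY_TYPE_SIZE[vtypes])
    csize <- PLY_TYPE_SIZE[[lp$count_type]]
    isize <- PLY_TYPE_SIZE[[lp$value_type]]
    record <- csize + 3L * isize
    counts <- read_binary_scalars(raw, voffset, nface, record, 0L,
                                  lp$count_type)
    if (nface && any(counts != 3L)) {
      stop_trayphen("only triangular faces are supported in binary meshes",
                    class = "trayphen_ply_parse")
    }
    faces <- matrix(NA_integer_, nface, 3L)
    for (j in 1:3) {
      faces[, j] <- read_binary_scalars(raw, voffset, nface, record,
                                        csize + (j - 1L) * isize,
                                        lp$value_type) + 1L
    }
  }
  triangle_mesh(verts, faces)
}
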