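## Point-cloud file I/O: PLY (ascii and binary little-endian), PCD (ascii)
## and XYZ (whitespace-separated columns). Coordinates are taken as
## millimetres as-is; no unit autodetection.

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_float_types <- c("float", "float32", "double", "float64")

infer_format <- function(path, format = NULL) {
  if (!is.null(format)) return(match.arg(tolower(format), c("ply", "pcd", "xyz")))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("ply", "pcd", "xyz")) return(ext)
  stop("cannot infer point-cloud format from extension '", ext,
       "'; pass format = \"ply\", \"pcd\" or \"xyz\"", call. = FALSE)
}

#' Read a point cloud from PLY, PCD or XYZ
#'
#' PLY files may be `ascii` or `binary_little_endian`; vertex properties
#' `x`, `y`, `z` are required, `nx`/`ny`/`nz` and `curvature`/`provenance`
#' are picked up when present and float-typed, and any other property is
#' ignored. PCD support covers the common `DATA ascii` layout. XYZ files are
#' whitespace-separated numeric columns (first three used; six columns are
#' read as coordinates plus normals). Point order is preserved.
#'
#' @param path File path.
#' @param format `"ply"`, `"pcd"` or `"xyz"`; inferred from the extension
#'   when `NULL`.
#' @return A [point_cloud()].
#' @seealso [write_cloud()]
#' @export
read_cloud <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  format <- infer_format(path, format)
  switch(format,
         xyz = read_xyz(path),
         pcd = read_pcd(path),
         ply = read_ply(path))
}

read_xyz <- function(path) {
  first <- readLines(path, n = 50, warn = FALSE)
  if (!any(nzchar(trimws(first)))) {
    return(point_cloud(matrix(numeric(0), ncol = 3)))
  }
  df <- tryCatch(
    utils::read.table(path, header = FALSE, colClasses = "numeric"),
    error = function(e) stop("malformed XYZ file '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (ncol(df) < 3) stop("XYZ file needs at least 3 columns, found ", ncol(df),
                         call. = FALSE)
  bad <- which(!stats::complete.cases(df[, 1:3]))
  if (length(bad)) stop("malformed XYZ record at line ", bad[1], call. = FALSE)
  cl <- point_cloud(as.matrix(df[, 1:3]))
  if (ncol(df) >= 6) {
    nm <- as.matrix(df[, 4:6])
    len <- sqrt(rowSums(nm^2))
    if (all(abs(len - 1) < 1e-3)) {
      nm <- nm / len
      cl$nx <- nm[, 1]; cl$ny <- nm[, 2]; cl$nz <- nm[, 3]
    }
  }
  cl
}

read_pcd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  dl <- grep("^DATA", lines)[1]
  if (is.na(dl)) stop("not a PCD file (no DATA line): ", path, call. = FALSE)
  hdr <- lines[seq_len(dl)]
  get_field <- function(key) {
    ln <- grep(paste0("^", key, "\\b"), hdr, value = TRUE)
    if (!length(ln)) return(NULL)
    strsplit(trimws(ln[1]), "\\s+")[[1]][-1]
  }
  if (!identical(tolower(get_field("DATA")), "ascii")) {
    stop("only DATA ascii PCD files are supported", call. = FALSE)
  }
  fields <- get_field("FIELDS")
  npts <- as.integer(get_field("POINTS")[1])
  body <- lines[-seq_len(dl)]
  body <- body[nzchar(trimws(body))]
  con <- textConnection(body)
  on.exit(close(con))
  df <- tryCatch(
    utils::read.table(con, header = FALSE),
    error = function(e) stop("malformed PCD body in '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (!is.na(npts) && nrow(df) != npts) {
    stop("PCD declares ", npts, " points but body has ", nrow(df), call. = FALSE)
  }
  names(df)[seq_along(fields)] <- fields
  if (!all(c("x", "y", "z") %in% names(df))) {
    stop("PCD file lacks x/y/z fields", call. = FALSE)
  }
  cl <- point_cloud(df[c("x", "y", "z")])
  if (all(c("normal_x", "normal_y", "normal_z") %in% names(df))) {
    nm <- cbind(df$normal_x, df$normal_y, df$normal_z)
    cl$nx <- nm[, 1]; cl$ny <- nm[, 2]; cl$nz <- nm[, 3]
  }
  cl
}

parse_ply_header <- function(con) {
  magic <- readLines(con, n = 1)
  if (!identical(trimws(magic), "ply")) stop("not a PLY file", call. = FALSE)
  fmt <- NULL; elements <- list(); current <- NULL
  repeat {
    ln <- readLines(con, n = 1)
    if (!length(ln)) stop("unexpected end of PLY header", call. = FALSE)
    tok <- strsplit(trimws(ln), "\\s+")[[1]]
    if (!length(tok)) next
    if (tok[1] == "comment") next
    if (tok[1] == "format") fmt <- tok[2]
    if (tok[1] == "element") {
      current <- tok[2]
      elements[[current]] <- list(count = as.integer(tok[3]),
                                  prop_names = character(), prop_types = character(),
                                  list_props = logical())
    }
    if (tok[1] == "property") {
      if (is.null(current)) stop("PLY property before element", call. = FALSE)
      if (tok[2] == "list") {
        elements[[current]]$prop_names <- c(elements[[current]]$prop_names, tok[5])
        elements[[current]]$prop_types <- c(elements[[current]]$prop_types,
                                            paste(tok[3], tok[4]))
        elements[[current]]$list_props <- c(elements[[current]]$list_props, TRUE)
      } else {
        elements[[current]]$prop_names <- c(elements[[current]]$prop_names, tok[3])
        elements[[current]]$prop_types <- c(elements[[current]]$prop_types, tok[2])
        elements[[current]]$list_props <- c(elements[[current]]$list_props, FALSE)
      }
    }
    if (tok[1] == "end_header") break
  }
  if (is.null(fmt)) stop("PLY header lacks a format line", call. = FALSE)
  list(format = fmt, elements = elements)
}

ply_vertex_cloud <- function(vals, vert) {
  ## vals: named list of numeric vectors per scalar property
  need <- c("x", "y", "z")
  if (!all(need %in% names(vals))) stop("PLY vertex element lacks x/y/z", call. = FALSE)
  cl <- point_cloud(cbind(vals$x, vals$y, vals$z))
  float_ok <- function(p) {
    i <- match(p, vert$prop_names)
    !is.na(i) && !vert$list_props[i] && vert$prop_types[i] %in% ply_float_types
  }
  if (all(vapply(c("nx", "ny", "nz"), float_ok, logical(1)))) {
    nm <- cbind(vals$nx, vals$ny, vals$nz)
    len <- sqrt(rowSums(nm^2))
    if (all(abs(len - 1) < 1e-3)) {
      nm <- nm / len
      cl$nx <- nm[, 1]; cl$ny <- nm[, 2]; cl$nz <- nm[, 3]
    }
  }
  if (float_ok("curvature")) cl$curvature <- vals$curvature
  if ("provenance" %in% names(vals)) cl$provenance <- as.integer(vals$provenance)
  cl
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- parse_ply_header(con)
  vert <- hdr$elements[["vertex"]]
  if (is.null(vert)) stop("PLY file has no vertex element", call. = FALSE)
  if (any(vert$list_props)) stop("list-typed vertex properties are unsupported",
                                 call. = FALSE)
  if (hdr$format == "ascii") {
    body <- readLines(con)
    body <- body[nzchar(trimws(body))]
    if (length(body) < vert$count) {
      stop("PLY declares ", vert$count, " vertices, body has ", length(body),
           " rows", call. = FALSE)
    }
    rows <- strsplit(trimws(body[seq_len(vert$count)]), "\\s+")
    np <- length(vert$prop_names)
    bad <- which(lengths(rows) != np)
    if (length(bad)) stop("malformed PLY vertex at element index ", bad[1],
                          call. = FALSE)
    m <- matrix(suppressWarnings(as.numeric(unlist(rows))), ncol = np, byrow = TRUE)
    if (anyNA(m[, match(c("x", "y", "z"), vert$prop_names)])) {
      stop("non-numeric coordinate in PLY vertex element", call. = FALSE)
    }
    vals <- stats::setNames(lapply(seq_len(np), function(j) m[, j]), vert$prop_names)
    return(ply_vertex_cloud(vals, vert))
  }
  if (hdr$format != "binary_little_endian") {
    stop("unsupported PLY format: ", hdr$format, call. = FALSE)
  }
  sizes <- ply_type_size[vert$prop_types]
  if (anyNA(sizes)) stop("unknown PLY property type", call. = FALSE)
  rec <- sum(sizes)
  raw <- readBin(con, "raw", n = rec * vert$count)
  if (length(raw) < rec * vert$count) stop("truncated binary PLY body", call. = FALSE)
  offs <- cumsum(c(0L, sizes[-length(sizes)]))
  vals <- list()
  for (j in seq_along(vert$prop_names)) {
    ty <- vert$prop_types[j]; sz <- sizes[j]
    idx <- as.vector(outer(seq_len(sz), (seq_len(vert$count) - 1L) * rec + offs[j], `+`))
    bytes <- raw[idx]
    vals[[vert$prop_names[j]]] <- switch(
      ty,
      float = , float32 = readBin(bytes, "double", vert$count, size = 4, endian = "little"),
      double = , float64 = readBin(bytes, "double", vert$count, size = 8, endian = "little"),
      char = , int8 = readBin(bytes, "integer", vert$count, size = 1, signed = TRUE, endian = "little"),
      uchar = , uint8 = readBin(bytes, "integer", vert$count, size = 1, signed = FALSE, endian = "little"),
      short = , int16 = readBin(bytes, "integer", vert$count, size = 2, signed = TRUE, endian = "little"),
      ushort = , uint16 = readBin(bytes, "integer", vert$count, size = 2, signed = FALSE, endian = "little"),
      readBin(bytes, "integer", vert$count, size = 4, endian = "little"))
  }
  ply_vertex_cloud(vals, vert)
}

#' Write a point cloud to PLY, PCD or XYZ
#'
#' The written file round-trips through [read_cloud()] with coordinates
#' equal within 1e-6 mm. Normals are persisted in PLY and PCD; XYZ drops
#' them with a warning. The `provenance` column, when present, is written to
#' PLY as an integer vertex property.
#'
#' @param cloud A point cloud (or anything [as_point_cloud()] accepts).
#' @param path Output file path.
#' @param format As in [read_cloud()].
#' @param binary Write `binary_little_endian` PLY instead of ascii.
#' @return `path`, invisibly.
#' @export
write_cloud <- function(cloud, path, format = NULL, binary = FALSE) {
  cloud <- as_point_cloud(cloud)
  format <- infer_format(path, format)
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir, call. = FALSE)
  switch(format,
         xyz = write_xyz(cloud, path),
         pcd = write_pcd(cloud, path),
         ply = write_ply(cloud, path, binary = binary))
  invisible(path)
}

has_normals <- function(cloud) all(c("nx", "ny", "nz") %in% names(cloud))

num_fmt <- function(x) sprintf("%.9g", x)

write_xyz <- function(cloud, path) {
  if (has_normals(cloud)) {
    warning("XYZ format does not carry normals; dropping them", call. = FALSE)
  }
  m <- as_xyz(cloud)
  writeLines(sprintf("%s %s %s", num_fmt(m[, 1]), num_fmt(m[, 2]), num_fmt(m[, 3])),
             path)
}

write_pcd <- function(cloud, path) {
  m <- as_xyz(cloud)
  fields <- c("x", "y", "z")
  body <- cbind(m)
  if (has_normals(cloud)) {
    fields <- c(fields, "normal_x", "normal_y", "normal_z")
    body <- cbind(body, cloud$nx, cloud$ny, cloud$nz)
  }
  nf <- length(fields)
  hdr <- c("# .PCD v0.7 - Point Cloud Data file format",
           "VERSION 0.7",
           paste("FIELDS", paste(fields, collapse = " ")),
           paste("SIZE", paste(rep(8, nf), collapse = " ")),
           paste("TYPE", paste(rep("F", nf), collapse = " ")),
           paste("COUNT", paste(rep(1, nf), collapse = " ")),
           paste("WIDTH", nrow(body)),
           "HEIGHT 1",
           "VIEWPOINT 0 0 0 1 0 0 0",
           paste("POINTS", nrow(body)),
           "DATA ascii")
  rows <- apply(body, 1, function(r) paste(num_fmt(r), collapse = " "))
  writeLines(c(hdr, rows), path)
}

write_ply <- function(cloud, path, binary = FALSE) {
  m <- as_xyz(cloud)
  props <- list(x = m[, 1], y = m[, 2], z = m[, 3])
  if (has_normals(cloud)) {
    props$nx <- cloud$nx; props$ny <- cloud$ny; props$nz <- cloud$nz
  }
  if ("curvature" %in% names(cloud)) props$curvature <- cloud$curvature
  prov <- if ("provenance" %in% names(cloud)) as.integer(cloud$provenance)
  hdr <- c("ply",
           paste("format", if (binary) "binary_little_endian" else "ascii", "1.0"),
           "comment written by symfruit",
           paste("element vertex", nrow(m)),
           paste("property double", names(props)),
           if (!is.null(prov)) "property int provenance",
           "end_header")
  if (!binary) {
    body <- do.call(cbind, props)
    rows <- apply(body, 1, function(r) paste(num_fmt(r), collapse = " "))
    if (!is.null(prov)) rows <- paste(rows, prov)
    writeLines(c(hdr, rows), path)
    return(invisible(path))
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  nprop <- length(props)
  block <- matrix(unlist(props, use.names = FALSE), ncol = nprop)
  if (is.null(prov)) {
    writeBin(as.vector(t(block)), con, size = 8, endian = "little")
  } else {
    for (i in seq_len(nrow(block))) {
      writeBin(block[i, ], con, size = 8, endian = "little")
      writeBin(prov[i], con, size = 4, endian = "little")
    }
  }
  invisible(path)
}
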