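#' Read a triangle mesh from file
#'
#' Supports the FreeSurfer binary triangle-surface dialect (magic bytes
#' `0xFF 0xFF 0xFE`, big-endian payload, as written for `?h.white` /
#' `?h.pial`), ASCII OFF, and ASCII / binary-little-endian PLY.
#'
#' @param path file path.
#' @param format one of `"freesurfer_surface"`, `"off"`, `"ply"`; inferred
#'   from the extension when `NULL` (`.off`, `.ply`, anything else FreeSurfer).
#' @return a [triangle_mesh()].
#' @export
read_mesh <- function(path, format = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- format %||% infer_mesh_format(path)
  switch(format,
         freesurfer_surface = read_fs_surface(path),
         off = read_off(path),
         ply = read_ply(path),
         stop("unknown mesh format: ", format))
}

#' Write a triangle mesh to file
#'
#' @param mesh a [triangle_mesh()].
#' @param path output path.
#' @param format as in [read_mesh()].
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = NULL) {
  format <- format %||% infer_mesh_format(path)
  switch(format,
         freesurfer_surface = write_fs_surface(mesh, path),
         off = write_off(mesh, path),
         ply = write_ply(mesh, path),
         stop("unknown mesh format: ", format))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

infer_mesh_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "off") "off" else if (ext == "ply") "ply" else "freesurfer_surface"
}

# ---- FreeSurfer binary triangle surface ------------------------------------

TRIANGLE_FILE_MAGIC <- as.raw(c(0xff, 0xff, 0xfe))

read_fs_surface <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  if (!identical(magic, TRIANGLE_FILE_MAGIC))
    stop(sprintf("not a FreeSurfer triangle surface (bad magic at byte offset 0): %s",
                 paste(sprintf("0x%02X", as.integer(magic)), collapse = " ")))
  # creation comment terminated by "\n\n"
  comment <- raw(0)
  prev_nl <- FALSE
  repeat {
    b <- readBin(con, "raw", 1)
    if (length(b) == 0) stop("truncated FreeSurfer surface header (no \\n\\n terminator)")
    if (b == as.raw(0x0a)) {
      if (prev_nl) break
      prev_nl <- TRUE
    } else prev_nl <- FALSE
    comment <- c(comment, b)
  }
  counts <- readBin(con, "integer", 2, size = 4, endian = "big")
  v <- counts[1]; f <- counts[2]
  if (is.na(v) || is.na(f) || v < 0 || f < 0)
    stop(sprintf("invalid FreeSurfer element counts at byte offset %d", 3 + length(comment) + 2))
  verts <- readBin(con, "numeric", 3 * v, size = 4, endian = "big")
  faces <- readBin(con, "integer", 3 * f, size = 4, endian = "big")
  if (length(verts) < 3 * v || length(faces) < 3 * f)
    stop("truncated FreeSurfer surface payload")
  vertices <- matrix(verts, ncol = 3, byrow = TRUE)
  faces <- matrix(faces, ncol = 3, byrow = TRUE) + 1L
  triangle_mesh(vertices, faces)
}

write_fs_surface <- function(mesh, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(TRIANGLE_FILE_MAGIC, con)
  writeBin(charToRaw("created by cortexflow\n\n"), con)
  writeBin(as.integer(c(nrow(mesh$vertices), nrow(mesh$faces))), con,
           size = 4, endian = "big")
  writeBin(as.numeric(t(mesh$vertices)), con, size = 4, endian = "big")
  writeBin(as.integer(t(mesh$faces) - 1L), con, size = 4, endian = "big")
  # volume-geometry footer with identity transform (world == surface mm frame)
  writeBin(as.integer(c(2, 0)), con, size = 4, endian = "big")
  invisible(path)
}

# ---- OFF -------------------------------------------------------------------

read_off <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) < 2 || trimws(lines[1]) != "OFF")
    stop("malformed OFF header at byte offset 0 (expected 'OFF')")
  counts <- scan(text = lines[2], quiet = TRUE)
  nv <- counts[1]; nf <- counts[2]
  if (length(lines) < 2 + nv + nf) stop("truncated OFF file: element counts exceed content")
  vertices <- matrix(scan(text = lines[3:(2 + nv)], quiet = TRUE),
                     ncol = 3, byrow = TRUE)
  fl <- lapply(lines[(3 + nv):(2 + nv + nf)], function(l) scan(text = l, quiet = TRUE))
  faces <- t(vapply(fl, function(x) {
    if (x[1] != 3) stop("non-triangular face in OFF file")
    x[2:4]
  }, numeric(3))) + 1
  mesh <- triangle_mesh(vertices, faces, validate = FALSE)
  tryCatch(validate_mesh(mesh),
           error = function(e) stop("OFF format error: ", conditionMessage(e)))
  mesh
}

write_off <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(mesh$vertices), nrow(mesh$faces)), con)
  writeLines(apply(mesh$vertices, 1, function(r) paste(format(r, digits = 17), collapse = " ")), con)
  writeLines(apply(mesh$faces - 1L, 1, function(r) paste(c(3L, r), collapse = " ")), con)
  invisible(path)
}

# ---- PLY -------------------------------------------------------------------

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_hline <- function() {
    out <- raw(0)
    repeat {
      b <- readBin(con, "raw", 1)
      if (length(b) == 0) stop("truncated PLY header")
      if (b == as.raw(0x0a)) break
      out <- c(out, b)
    }
    sub("\r$", "", rawToChar(out))
  }
  if (read_hline() != "ply") stop("malformed PLY magic at byte offset 0 (expected 'ply')")
  fmt <- NULL; nv <- NULL; nf <- NULL
  vprops <- character(0)
  in_vertex <- FALSE
  repeat {
    l <- read_hline()
    tok <- strsplit(trimws(l), "\\s+")[[1]]
    if (tok[1] == "format") fmt <- tok[2]
    else if (tok[1] == "element") {
      in_vertex <- tok[2] == "vertex"
      if (tok[2] == "vertex") nv <- as.integer(tok[3])
      if (tok[2] == "face") nf <- as.integer(tok[3])
    } else if (tok[1] == "property" && in_vertex && tok[2] != "list") {
      vprops <- c(vprops, tok[2])  # property types, in order
    } else if (tok[1] == "end_header") break
  }
  if (is.null(fmt) || is.null(nv) || is.null(nf))
    stop("malformed PLY header: missing format/element declarations")
  npv <- length(vprops)
  if (npv < 3) stop("PLY vertex element has fewer than 3 properties")
  if (fmt == "ascii") {
    txt <- readLines(con, warn = FALSE)
    txt <- txt[nzchar(trimws(txt))]
    vdat <- matrix(scan(text = txt[seq_len(nv)], quiet = TRUE), ncol = npv, byrow = TRUE)
    vertices <- vdat[, 1:3, drop = FALSE]
    faces <- t(vapply(txt[nv + seq_len(nf)], function(l) {
      x <- scan(text = l, quiet = TRUE)
      if (x[1] != 3) stop("non-triangular face in PLY file")
      x[2:4]
    }, numeric(3), USE.NAMES = FALSE)) + 1
  } else if (fmt == "binary_little_endian") {
    sz <- function(tp) switch(tp, float = 4L, float32 = 4L, double = 8L,
                              int = 4L, int32 = 4L, uint = 4L, uint32 = 4L,
                              uchar = 1L, uint8 = 1L, char = 1L, int8 = 1L,
                              short = 2L, ushort = 2L,
                              stop("unsupported PLY property type: ", tp))
    vertices <- matrix(0, nv, 3)
    for (i in seq_len(nv)) {
      for (j in seq_len(npv)) {
        tp <- vprops[j]
        val <- if (tp %in% c("float", "float32")) readBin(con, "numeric", 1, 4, endian = "little")
        else if (tp == "double") readBin(con, "numeric", 1, 8, endian = "little")
        else readBin(con, "integer", 1, sz(tp), endian = "little")
        if (j <= 3) vertices[i, j] <- val
      }
    }
    faces <- matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      cnt <- as.integer(readBin(con, "integer", 1, 1, signed = FALSE, endian = "little"))
      if (cnt != 3) stop("non-triangular face in PLY file")
      faces[i, ] <- readBin(con, "integer", 3, 4, endian = "little")
    }
    faces <- faces + 1L
  } else stop("unsupported PLY format: ", fmt)
  mesh <- triangle_mesh(vertices, faces, validate = FALSE)
  tryCatch(validate_mesh(mesh),
           error = function(e) stop("PLY format error: ", conditionMessage(e)))
  mesh
}

write_ply <- function(mesh, path, binary = TRUE) {
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("ply",
           if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
           "comment written by cortexflow",
           sprintf("element vertex %d", nrow(mesh$vertices)),
           "property float x", "property float y", "property float z",
           sprintf("element face %d", nrow(mesh$faces)),
           "property list uchar int vertex_indices",
           "end_header")
  writeBin(charToRaw(paste0(paste(hdr, collapse = "\n"), "\n")), con)
  if (binary) {
    writeBin(as.numeric(t(mesh$vertices)), con, size = 4, endian = "little")
    f0 <- t(mesh$faces) - 1L
    for (i in seq_len(ncol(f0))) {
      writeBin(as.raw(3), con)
      writeBin(as.integer(f0[, i]), con, size = 4, endian = "little")
    }
  } else {
    vtxt <- apply(mesh$vertices, 1, function(r) paste(format(r, digits = 9), collapse = " "))
    ftxt <- apply(mesh$faces - 1L, 1, function(r) paste(c(3L, r), collapse = " "))
    writeBin(charToRaw(paste0(paste(c(vtxt, ftxt), collapse = "\n"), "\n")), con)
  }
  invisible(path)
}

# ---- per-vertex scalar fields ----------------------------------------------

#' Read / write FreeSurfer curv files
#'
#' The "new-format" binary curv dialect (magic `0xFF 0xFF 0xFF`, big-endian
#' float32 values), used for per-vertex scalar maps such as curvature or
#' thickness.
#'
#' @param path file path.
#' @param field a [vertex_scalar_field()] (for writing).
#' @param n_faces face count stored in the header (metadata only).
#' @param name field name to attach on read.
#' @return [vertex_scalar_field()] on read; `path` invisibly on write.
#' @export
read_curv <- function(path, name = "curv") {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3)
  if (!identical(magic, as.raw(c(0xff, 0xff, 0xff))))
    stop("not a new-format curv file (bad magic at byte offset 0)")
  hdr <- readBin(con, "integer", 3, size = 4, endian = "big")
  vals <- readBin(con, "numeric", hdr[1], size = 4, endian = "big")
  vertex_scalar_field(vals, name)
}

#' @rdname read_curv
#' @export
write_curv <- function(field, path, n_faces = 0L) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0xff, 0xff, 0xff)), con)
  writeBin(as.integer(c(length(field$values), n_faces, 1L)), con,
           size = 4, endian = "big")
  writeBin(as.numeric(field$values), con, size = 4, endian = "big")
  invisible(path)
}

#' Read / write vertex fields as CSV
#'
#' Two-column CSV (`vertex`, value) keyed by 1-based vertex index.
#'
#' @inheritParams read_curv
#' @export
write_field_csv <- function(field, path) {
  df <- data.frame(vertex = seq_along(field$values), value = field$values)
  names(df)[2] <- field$name
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_field_csv
#' @export
read_field_csv <- function(path) {
  df <- read.csv(path)
  vertex_scalar_field(df[[2]], names(df)[2])
}
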