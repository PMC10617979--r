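# Triangle-mesh file I/O: ascii OBJ, ascii and binary little-endian PLY,
# per-vertex segmentation files, and population directories with a manifest.

#' Read a triangle mesh from OBJ or PLY
#'
#' @param path File path ending in `.obj` or `.ply`.
#' @return List with `vertices` (N x 3 numeric) and `faces`
#'   (n_faces x 3 integer, 1-based).
#' @export
read_mesh <- function(path) {
  if (!file.exists(path)) stop2("cannot read mesh file '%s'", path)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         obj = read_obj(path),
         ply = read_ply(path),
         stop2("unsupported mesh format '.%s' (expected .obj or .ply)", ext))
}

#' Write a triangle mesh to OBJ or PLY
#'
#' @param vertices N x 3 numeric matrix.
#' @param faces n_faces x 3 integer matrix (1-based).
#' @param path Output path; the extension selects the format.
#' @param binary For PLY, write `binary_little_endian` (float32 coordinates)
#'   instead of ascii.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(vertices, faces, path, binary = FALSE) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         obj = write_obj(vertices, faces, path),
         ply = write_ply(vertices, faces, path, binary = binary),
         stop2("unsupported mesh format '.%s'", ext))
  invisible(path)
}

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  if (length(vl) == 0) stop2("OBJ file '%s' contains no vertices", path)
  verts <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(t)
    as.numeric(t[2:4])))
  faces <- lapply(strsplit(trimws(fl), "\\s+"), function(t) {
    idx <- vapply(t[-1], function(tok)
      as.integer(strsplit(tok, "/", fixed = TRUE)[[1]][1]), integer(1))
    if (length(idx) != 3)
      stop2("OBJ file '%s' has a non-triangular face (%d vertices)",
            path, length(idx))
    idx
  })
  list(vertices = verts, faces = do.call(rbind, faces))
}

write_obj <- function(vertices, faces, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g",
                     vertices[, 1], vertices[, 2], vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", faces[, 1], faces[, 2], faces[, 3]), con)
}

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_read_scalar <- function(con, type) {
  sz <- ply_type_size[[type]]
  if (type %in% c("float", "float32", "double", "float64"))
    readBin(con, "double", 1, size = sz, endian = "little")
  else if (type %in% c("uchar", "uint8", "ushort", "uint16", "uint", "uint32"))
    readBin(con, "integer", 1, size = sz, signed = sz < 4, endian = "little")
  else
    readBin(con, "integer", 1, size = sz, endian = "little")
}

ply_read_line <- function(con) {
  out <- raw(0)
  repeat {
    b <- readBin(con, "raw", 1)
    if (length(b) == 0) return(NULL)
    if (b == as.raw(10)) break
    out <- c(out, b)
  }
  sub("\r$", "", rawToChar(out))
}

read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header is ascii regardless of body format
  hdr <- character(0)
  repeat {
    ln <- ply_read_line(con)
    if (is.null(ln)) stop2("PLY file '%s': unexpected end of header", path)
    hdr <- c(hdr, ln)
    if (trimws(ln) == "end_header") break
  }
  if (trimws(hdr[1]) != "ply") stop2("'%s' is not a PLY file", path)
  fmt_ln <- grep("^format", hdr, value = TRUE)[1]
  fmt <- strsplit(trimws(fmt_ln), "\\s+")[[1]][2]
  if (!fmt %in% c("ascii", "binary_little_endian"))
    stop2("PLY format '%s' not supported", fmt)
  elements <- list(); cur <- NULL
  for (ln in hdr) {
    t <- strsplit(trimws(ln), "\\s+")[[1]]
    if (t[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = t[2], count = as.integer(t[3]), props = list())
    } else if (t[1] == "property" && !is.null(cur)) {
      if (t[2] == "list")
        cur$props[[length(cur$props) + 1]] <-
          list(name = t[5], list = TRUE, count_type = t[3], type = t[4])
      else
        cur$props[[length(cur$props) + 1]] <-
          list(name = t[3], list = FALSE, type = t[2])
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex) || is.null(elements$face))
    stop2("PLY file '%s' lacks vertex/face elements", path)

  if (fmt == "ascii") {
    body <- readLines(path, warn = FALSE)[-seq_along(hdr)]
    body <- body[nzchar(trimws(body))]
    nv <- elements$vertex$count
    vp <- vapply(elements$vertex$props, function(p) p$name, character(1))
    vmat <- do.call(rbind, lapply(body[seq_len(nv)], function(ln)
      as.numeric(strsplit(trimws(ln), "\\s+")[[1]])))
    verts <- vmat[, match(c("x", "y", "z"), vp), drop = FALSE]
    nf <- elements$face$count
    faces <- do.call(rbind, lapply(body[nv + seq_len(nf)], function(ln) {
      t <- as.integer(strsplit(trimws(ln), "\\s+")[[1]])
      if (t[1] != 3) stop2("PLY file '%s' has a non-triangular face", path)
      t[2:4] + 1L
    }))
  } else {
    nv <- elements$vertex$count
    props <- elements$vertex$props
    types <- vapply(props, function(p) p$type, character(1))
    if (all(types %in% c("float", "float32")) ||
        all(types %in% c("double", "float64"))) {
      sz <- ply_type_size[[types[1]]]
      vals <- readBin(con, "double", nv * length(props), size = sz,
                      endian = "little")
      vmat <- matrix(vals, nv, length(props), byrow = TRUE)
    } else {
      vmat <- matrix(0, nv, length(props))
      for (i in seq_len(nv))
        for (j in seq_along(props))
          vmat[i, j] <- ply_read_scalar(con, props[[j]]$type)
    }
    vp <- vapply(props, function(p) p$name, character(1))
    verts <- vmat[, match(c("x", "y", "z"), vp), drop = FALSE]
    nf <- elements$face$count
    fprop <- elements$face$props[[1]]
    if (ply_type_size[[fprop$count_type]] == 1L &&
        fprop$type %in% c("int", "int32", "uint", "uint32")) {
      blk <- readBin(con, "raw", nf * 13L)
      if (length(blk) < nf * 13L)
        stop2("PLY file '%s': truncated face block", path)
      bm <- matrix(blk, nrow = 13L)
      if (any(bm[1, ] != as.raw(3)))
        stop2("PLY file '%s' has a non-triangular face", path)
      idx <- readBin(as.vector(bm[-1, ]), "integer", nf * 3L, size = 4,
                     endian = "little")
      faces <- matrix(idx, nf, 3, byrow = TRUE) + 1L
    } else {
      faces <- matrix(0L, nf, 3)
      for (i in seq_len(nf)) {
        cnt <- ply_read_scalar(con, fprop$count_type)
        if (cnt != 3) stop2("PLY file '%s' has a non-triangular face", path)
        faces[i, ] <- vapply(1:3, function(k)
          as.integer(ply_read_scalar(con, fprop$type)), integer(1)) + 1L
      }
    }
  }
  list(vertices = verts, faces = faces)
}

write_ply <- function(vertices, faces, path, binary = FALSE) {
  nv <- nrow(vertices); nf <- nrow(faces)
  hdr <- c("ply",
           sprintf("format %s 1.0",
                   if (binary) "binary_little_endian" else "ascii"),
           sprintf("element vertex %d", nv),
           sprintf("property %s x", if (binary) "float" else "double"),
           sprintf("property %s y", if (binary) "float" else "double"),
           sprintf("property %s z", if (binary) "float" else "double"),
           sprintf("element face %d", nf),
           "property list uchar int vertex_indices",
           "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    vt <- t(vertices)
    writeBin(as.vector(vt), con, size = 4, endian = "little")
    idx_raw <- writeBin(as.integer(t(faces) - 1L), raw(), size = 4,
                        endian = "little")
    blk <- rbind(matrix(rep(as.raw(3), nf), nrow = 1),
                 matrix(idx_raw, nrow = 12L))
    writeBin(as.vector(blk), con)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(hdr, con)
    writeLines(sprintf("%.9g %.9g %.9g",
                       vertices[, 1], vertices[, 2], vertices[, 3]), con)
    writeLines(sprintf("3 %d %d %d",
                       faces[, 1] - 1L, faces[, 2] - 1L, faces[, 3] - 1L), con)
  }
  invisible(path)
}

#' Read / write a per-vertex segmentation
#'
#' Plain-text files hold one integer label per line; `.json` files a single
#' integer array. Labels on disk may be 0- or 1-based; they are normalized to
#' 1-based on read.
#'
#' @param path File path (`.txt` or `.json`).
#' @return Integer label vector (1-based).
#' @export
read_segmentation <- function(path) {
  ext <- tolower(tools::file_ext(path))
  labs <- if (ext == "json") as.integer(jsonlite::fromJSON(path))
  else as.integer(readLines(path, warn = FALSE))
  if (length(labs) && min(labs) == 0L) labs <- labs + 1L
  labs
}

#' @rdname read_segmentation
#' @param labels Integer labels, one per vertex.
#' @export
write_segmentation <- function(labels, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") jsonlite::write_json(as.integer(labels), path)
  else writeLines(as.character(as.integer(labels)), path)
  invisible(path)
}

#' Write a shape population to a directory
#'
#' Emits one PLY per shape, the segmentation (if any), and an `index.json`
#' manifest recording file names and split tags.
#'
#' @param pop A `shape_population`.
#' @param dir Output directory (created if missing).
#' @param binary Write binary PLY shapes.
#' @return `dir`, invisibly.
#' @export
write_population <- function(pop, dir, binary = FALSE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- dim(pop$vertices)[1]
  files <- sprintf("shape_%04d.ply", seq_len(n))
  for (i in seq_len(n))
    write_ply(pop$vertices[i, , ], pop$topology$faces,
              file.path(dir, files[i]), binary = binary)
  manifest <- list(n_shapes = n, files = files, split = pop$split)
  if (!is.null(pop$topology$attribute_labels)) {
    write_segmentation(pop$topology$attribute_labels,
                       file.path(dir, "segmentation.txt"))
    manifest$segmentation <- "segmentation.txt"
  }
  jsonlite::write_json(manifest, file.path(dir, "index.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Read a population directory written by [write_population()]
#'
#' @param dir Directory containing `index.json`.
#' @return A `shape_population`.
#' @export
read_population <- function(dir) {
  idx_path <- file.path(dir, "index.json")
  if (!file.exists(idx_path))
    stop2("'%s' is not a population directory (no index.json)", dir)
  manifest <- jsonlite::fromJSON(idx_path)
  meshes <- lapply(manifest$files, function(f) read_mesh(file.path(dir, f)))
  topo <- mesh_topology(meshes[[1]]$faces,
                        n_vertices = nrow(meshes[[1]]$vertices))
  if (!is.null(manifest$segmentation))
    topo <- set_attribute_labels(
      topo, read_segmentation(file.path(dir, manifest$segmentation)))
  pop <- shape_population(meshes, topology = topo)
  pop$split <- as.character(manifest$split)
  pop
}
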