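# Triangle-mesh and landmark I/O. Supports the de facto surface-scan formats:
# OBJ (ascii), PLY (ascii + binary little-endian) and STL (ascii + binary).
# All coordinates are interpreted as millimetres.

#' Construct a triangle mesh
#'
#' The basic geometry container of the package: an n x 3 vertex matrix (mm)
#' and an m x 3 integer face matrix of 1-based vertex indices.
#'
#' @param vertices Numeric n x 3 matrix of vertex coordinates in mm.
#' @param faces Integer m x 3 matrix of 1-based vertex indices.
#' @param metadata Named list of free-form metadata (source path, subject id,
#'   age in months, sex, ...).
#' @return An object of class `cranio_mesh`.
#' @export
cranio_mesh <- function(vertices, faces, metadata = list()) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  if (ncol(vertices) != 3L) stop("vertices must be an n x 3 matrix", call. = FALSE)
  if (ncol(faces) != 3L) stop("faces must be an m x 3 matrix", call. = FALSE)
  if (nrow(faces) == 0L) stop("mesh has zero faces", call. = FALSE)
  if (!all(is.finite(vertices))) stop("vertex coordinates must be finite", call. = FALSE)
  if (min(faces) < 1L || max(faces) > nrow(vertices))
    stop("face indices out of range", call. = FALSE)
  structure(list(vertices = vertices, faces = faces, metadata = metadata),
            class = "cranio_mesh")
}

#' @export
print.cranio_mesh <- function(x, ...) {
  bb <- apply(x$vertices, 2, range)
  cat(sprintf("<cranio_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  cat(sprintf("  bbox extent (mm): %.1f x %.1f x %.1f\n",
              diff(bb[, 1]), diff(bb[, 2]), diff(bb[, 3])))
  if (length(x$metadata))
    cat("  metadata:", paste(names(x$metadata), collapse = ", "), "\n")
  invisible(x)
}

#' Construct a landmark set
#'
#' Nasion and both tragi; the three points define the anatomical reference
#' plane and its centroid is the initial registration anchor.
#'
#' @param nasion,tragus_left,tragus_right Length-3 numeric points (mm).
#' @return An object of class `cranio_landmarks`.
#' @export
cranio_landmarks <- function(nasion, tragus_left, tragus_right) {
  pts <- rbind(nasion = as.numeric(nasion),
               tragus_left = as.numeric(tragus_left),
               tragus_right = as.numeric(tragus_right))
  if (ncol(pts) != 3L || !all(is.finite(pts)))
    stop("each landmark must be a finite 3D point", call. = FALSE)
  # non-collinearity: triangle area above tolerance
  area <- vnorm(cross3(pts[2, ] - pts[1, ], pts[3, ] - pts[1, ])) / 2
  if (area < 1e-6)
    stop("landmarks are collinear (triangle area ", signif(area, 3),
         " mm^2)", call. = FALSE)
  structure(list(nasion = pts[1, ], tragus_left = pts[2, ],
                 tragus_right = pts[3, ]),
            class = "cranio_landmarks")
}

#' @export
print.cranio_landmarks <- function(x, ...) {
  cat("<cranio_landmarks>\n")
  for (nm in c("nasion", "tragus_left", "tragus_right"))
    cat(sprintf("  %-13s %8.2f %8.2f %8.2f\n", nm, x[[nm]][1], x[[nm]][2], x[[nm]][3]))
  invisible(x)
}

landmark_matrix <- function(lm) {
  rbind(nasion = lm$nasion, tragus_left = lm$tragus_left,
        tragus_right = lm$tragus_right)
}

infer_format <- function(path, format = "auto") {
  format <- match.arg(tolower(format), c("auto", "obj", "ply", "stl"))
  if (format != "auto") return(format)
  ext <- tolower(tools::file_ext(path))
  if (!ext %in% c("obj", "ply", "stl"))
    stop("cannot infer mesh format from extension '", ext, "'", call. = FALSE)
  ext
}

#' Read a triangle mesh
#'
#' Reads OBJ (ascii), PLY (ascii or binary little-endian) or STL (ascii or
#' binary). STL stores vertices per facet; duplicated positions are merged
#' (tolerance 1e-6 mm) so watertightness can be assessed. Vertices referenced
#' by no face are dropped.
#'
#' @param path File path.
#' @param format One of `"auto"`, `"obj"`, `"ply"`, `"stl"`.
#' @return A [cranio_mesh()] with `metadata$source` set.
#' @export
read_mesh <- function(path, format = "auto") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  format <- infer_format(path, format)
  parsed <- switch(format,
    obj = read_obj(path),
    ply = read_ply(path),
    stl = read_stl(path))
  v <- parsed$vertices; f <- parsed$faces
  if (is.null(f) || nrow(f) == 0L) stop("mesh has zero faces: ", path, call. = FALSE)
  # drop unreferenced vertices, remap faces
  used <- sort(unique(as.integer(f)))
  if (length(used) < nrow(v)) {
    remap <- integer(nrow(v)); remap[used] <- seq_along(used)
    v <- v[used, , drop = FALSE]
    f <- matrix(remap[f], ncol = 3L)
  }
  mesh <- cranio_mesh(v, f, metadata = list(source = path, format = format))
  message(sprintf("read_mesh: %s [%s] %d vertices, %d faces",
                  path, format, nrow(v), nrow(f)))
  mesh
}

# ---- OBJ ----

read_obj <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  if (!length(vl)) stop("no vertices in OBJ file: ", path, call. = FALSE)
  v <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vl)), "\\s+"),
                             function(x) as.numeric(x[1:3])))
  faces <- list()
  for (ln in fl) {
    toks <- strsplit(trimws(sub("^f", "", ln)), "\\s+")[[1]]
    idx <- as.integer(vapply(strsplit(toks, "/"), `[`, "", 1L))
    if (any(is.na(idx)) || any(idx < 0))
      stop("unsupported OBJ face record: ", ln, call. = FALSE)
    # fan-triangulate polygons
    if (length(idx) >= 3L)
      for (k in 2:(length(idx) - 1L))
        faces[[length(faces) + 1L]] <- c(idx[1L], idx[k], idx[k + 1L])
  }
  list(vertices = v, faces = do.call(rbind, faces))
}

write_obj <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# exported by craniometrics", con)
  writeLines(sprintf("v %.9g %.9g %.9g",
                     mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d",
                     mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]), con)
}

# ---- PLY ----

ply_type_size <- c(char = 1L, uchar = 1L, int8 = 1L, uint8 = 1L,
                   short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L,
                   int = 4L, uint = 4L, int32 = 4L, uint32 = 4L,
                   float = 4L, float32 = 4L, double = 8L, float64 = 8L)

ply_read_scalar <- function(con, type) {
  sz <- ply_type_size[[type]]
  if (type %in% c("float", "float32", "double", "float64"))
    readBin(con, "numeric", n = 1L, size = sz, endian = "little")
  else
    readBin(con, "integer", n = 1L, size = sz, endian = "little",
            signed = !(sz < 4L && grepl("^u", type)))
}

read_ply <- function(path) {
  con <- file(path, "rb"); on.exit(close(con))
  # header is ascii-terminated by 'end_header'
  header <- character()
  repeat {
    ln <- readLines(con, n = 1L, warn = FALSE)
    if (!length(ln)) stop("PLY header truncated: ", path, call. = FALSE)
    header <- c(header, ln)
    if (trimws(ln) == "end_header") break
  }
  if (!grepl("^ply", header[1])) stop("not a PLY file: ", path, call. = FALSE)
  fmt_line <- grep("^format ", header, value = TRUE)[1]
  binary <- grepl("binary_little_endian", fmt_line)
  if (!binary && !grepl("ascii", fmt_line))
    stop("unsupported PLY format: ", fmt_line, call. = FALSE)

  # parse elements and their properties in declaration order
  elements <- list(); cur <- NULL
  for (ln in header) {
    toks <- strsplit(trimws(ln), "\\s+")[[1]]
    if (toks[1] == "element") {
      if (!is.null(cur)) elements[[cur$name]] <- cur
      cur <- list(name = toks[2], n = as.integer(toks[3]), props = list())
    } else if (toks[1] == "property" && !is.null(cur)) {
      cur$props[[length(cur$props) + 1L]] <-
        if (toks[2] == "list") list(list = TRUE, count_type = toks[3],
                                    item_type = toks[4], name = toks[5])
        else list(list = FALSE, type = toks[2], name = toks[3])
    }
  }
  if (!is.null(cur)) elements[[cur$name]] <- cur
  if (is.null(elements$vertex) || is.null(elements$face))
    stop("PLY must declare vertex and face elements: ", path, call. = FALSE)

  if (binary) {
    read_element <- function(el) {
      rows <- vector("list", el$n)
      for (i in seq_len(el$n)) {
        row <- list()
        for (p in el$props) {
          if (p$list) {
            cnt <- ply_read_scalar(con, p$count_type)
            row[[p$name]] <- vapply(seq_len(cnt), function(k)
              ply_read_scalar(con, p$item_type), numeric(1))
          } else row[[p$name]] <- ply_read_scalar(con, p$type)
        }
        rows[[i]] <- row
      }
      rows
    }
    out <- list()
    for (el in elements) out[[el$name]] <- read_element(el)
  } else {
    body <- readLines(con, warn = FALSE)
    body <- body[nzchar(trimws(body))]
    pos <- 0L; out <- list()
    for (el in elements) {
      rows <- vector("list", el$n)
      for (i in seq_len(el$n)) {
        pos <- pos + 1L
        vals <- as.numeric(strsplit(trimws(body[pos]), "\\s+")[[1]])
        row <- list(); j <- 1L
        for (p in el$props) {
          if (p$list) {
            cnt <- vals[j]; row[[p$name]] <- vals[(j + 1L):(j + cnt)]
            j <- j + 1L + cnt
          } else { row[[p$name]] <- vals[j]; j <- j + 1L }
        }
        rows[[i]] <- row
      }
      out[[el$name]] <- rows
    }
  }
  v <- t(vapply(out$vertex, function(r) c(r$x, r$y, r$z), numeric(3)))
  face_key <- if (!is.null(out$face[[1]]$vertex_indices)) "vertex_indices" else "vertex_index"
  faces <- list()
  for (r in out$face) {
    idx <- as.integer(r[[face_key]]) + 1L  # PLY is 0-based
    if (length(idx) >= 3L)
      for (k in 2:(length(idx) - 1L))
        faces[[length(faces) + 1L]] <- c(idx[1L], idx[k], idx[k + 1L])
  }
  list(vertices = v, faces = do.call(rbind, faces))
}

write_ply <- function(mesh, path, binary = FALSE) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  header <- c("ply",
              if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
              "comment exported by craniometrics",
              sprintf("element vertex %d", nv),
              "property double x", "property double y", "property double z",
              sprintf("element face %d", nf),
              "property list uchar int vertex_indices",
              "end_header")
  if (binary) {
    con <- file(path, "wb"); on.exit(close(con))
    writeLines(header, con)
    writeBin(as.numeric(t(mesh$vertices)), con, size = 8L, endian = "little")
    f0 <- mesh$faces - 1L
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f0[i, ]), con, size = 4L, endian = "little")
    }
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(header, con)
    writeLines(sprintf("%.12g %.12g %.12g",
                       mesh$vertices[, 1], mesh$vertices[, 2], mesh$vertices[, 3]), con)
    writeLines(sprintf("3 %d %d %d",
                       mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
  }
}

# ---- STL ----

# STL stores three explicit vertices per facet; merge positions within
# 1e-6 mm so shared edges are recovered and watertightness is checkable.
merge_stl_vertices <- function(tri_coords) {
  key <- apply(round(tri_coords / 1e-6), 1, paste, collapse = ",")
  idx <- match(key, unique(key))
  v <- tri_coords[!duplicated(key), , drop = FALSE]
  f <- matrix(idx, ncol = 3L, byrow = TRUE)
  list(vertices = v, faces = f)
}

read_stl <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  head_raw <- raw[seq_len(min(512L, length(raw)))]
  is_ascii <- !any(head_raw == as.raw(0L)) &&
    grepl("facet", rawToChar(head_raw)) &&
    grepl("^\\s*solid", rawToChar(head_raw))
  if (is_ascii) {
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
    coords <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                    function(x) as.numeric(x[2:4])))
  } else {
    n_tri <- readBin(raw[81:84], "integer", size = 4L, endian = "little")
    expect <- 84L + n_tri * 50L
    if (length(raw) < expect) stop("binary STL truncated: ", path, call. = FALSE)
    # bytes 13..48 of each 50-byte facet record are the 9 vertex floats
    off <- rep((seq_len(n_tri) - 1L) * 50L + 84L, each = 36L) + rep(13:48, n_tri)
    coords <- matrix(readBin(raw[off], "numeric", n = n_tri * 9L, size = 4L,
                             endian = "little"),
                     ncol = 3L, byrow = TRUE)
  }
  if (is.null(coords) || nrow(coords) < 3L)
    stop("no facets in STL file: ", path, call. = FALSE)
  merge_stl_vertices(coords)
}

write_stl <- function(mesh, path, binary = FALSE) {
  v <- mesh$vertices; f <- mesh$faces
  normals <- t(apply(f, 1, function(tr) {
    n <- cross3(v[tr[2], ] - v[tr[1], ], v[tr[3], ] - v[tr[1], ])
    ln <- vnorm(n); if (ln < 1e-12) c(0, 0, 0) else n / ln
  }))
  if (binary) {
    con <- file(path, "wb"); on.exit(close(con))
    writeBin(as.raw(rep(0L, 80L)), con)
    writeBin(as.integer(nrow(f)), con, size = 4L, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(c(normals[i, ], t(v[f[i, ], ]))), con, size = 4L,
               endian = "little")
      writeBin(as.raw(c(0L, 0L)), con)
    }
  } else {
    con <- file(path, "w"); on.exit(close(con))
    writeLines("solid craniometrics", con)
    for (i in seq_len(nrow(f))) {
      writeLines(sprintf("  facet normal %.9g %.9g %.9g",
                         normals[i, 1], normals[i, 2], normals[i, 3]), con)
      writeLines("    outer loop", con)
      for (k in 1:3)
        writeLines(sprintf("      vertex %.9g %.9g %.9g",
                           v[f[i, k], 1], v[f[i, k], 2], v[f[i, k], 3]), con)
      writeLines(c("    endloop", "  endfacet"), con)
    }
    writeLines("endsolid craniometrics", con)
  }
}

#' Write a triangle mesh
#'
#' @param mesh A [cranio_mesh()].
#' @param path Output path; format inferred from extension unless given.
#' @param format One of `"auto"`, `"obj"`, `"ply"`, `"stl"`.
#' @param binary Write binary PLY/STL instead of ascii (ignored for OBJ).
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, format = "auto", binary = FALSE) {
  stopifnot(inherits(mesh, "cranio_mesh"))
  format <- infer_format(path, format)
  switch(format,
    obj = write_obj(mesh, path),
    ply = write_ply(mesh, path, binary = binary),
    stl = write_stl(mesh, path, binary = binary))
  message(sprintf("write_mesh: %s [%s] %d vertices, %d faces",
                  path, format, nrow(mesh$vertices), nrow(mesh$faces)))
  invisible(path)
}

#' Read a landmark file (JSON or CSV)
#'
#' JSON is the canonical format: an object with keys `nasion`, `tragus_left`,
#' `tragus_right`, each a 3-element array in mm. The CSV alternative has
#' columns `name,x,y,z` with the same three names.
#'
#' @param path File path (`.json` or `.csv`).
#' @return A [cranio_landmarks()].
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  required <- c("nasion", "tragus_left", "tragus_right")
  if (ext == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    missing <- setdiff(required, names(obj))
    if (length(missing))
      stop("landmark file missing: ", paste(missing, collapse = ", "), call. = FALSE)
    lm <- cranio_landmarks(obj$nasion, obj$tragus_left, obj$tragus_right)
  } else if (ext == "csv") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("name", "x", "y", "z") %in% names(df)))
      stop("landmark CSV needs columns name,x,y,z", call. = FALSE)
    missing <- setdiff(required, df$name)
    if (length(missing))
      stop("landmark file missing: ", paste(missing, collapse = ", "), call. = FALSE)
    row <- function(nm) unlist(df[match(nm, df$name), c("x", "y", "z")], use.names = FALSE)
    lm <- cranio_landmarks(row("nasion"), row("tragus_left"), row("tragus_right"))
  } else stop("unsupported landmark format: .", ext, call. = FALSE)
  message("read_landmarks: ", path)
  lm
}

#' Write a landmark file (JSON)
#' @param landmarks A [cranio_landmarks()].
#' @param path Output `.json` path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  stopifnot(inherits(landmarks, "cranio_landmarks"))
  jsonlite::write_json(lapply(unclass(landmarks), as.numeric), path,
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Validate mesh geometry before measurement
#'
#' Report-only checks: watertightness (every edge shared by exactly two
#' faces), connected-component count, degenerate (near-zero-area) faces,
#' bounding box, and a unit heuristic — head scans should have a maximum
#' extent within 120-400 mm; anything outside suggests metres or centimetres.
#'
#' @param mesh A [cranio_mesh()].
#' @return A list of class `cranio_validation` with fields `watertight`,
#'   `n_components`, `n_degenerate_faces`, `bbox_extent`, `unit_warning`.
#' @export
validate_mesh <- function(mesh) {
  stopifnot(inherits(mesh, "cranio_mesh"))
  f <- mesh$faces; v <- mesh$vertices
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  watertight <- all(table(key) == 2L)
  g <- igraph::graph_from_edgelist(unique(cbind(pmin(e[, 1], e[, 2]),
                                                pmax(e[, 1], e[, 2]))),
                                   directed = FALSE)
  comp <- igraph::components(g)
  # only vertices that carry faces count as components
  n_components <- length(unique(comp$membership[sort(unique(as.integer(f)))]))
  a <- v[f[, 1], , drop = FALSE]
  ab <- v[f[, 2], , drop = FALSE] - a
  ac <- v[f[, 3], , drop = FALSE] - a
  cx <- ab[, 2] * ac[, 3] - ab[, 3] * ac[, 2]
  cy <- ab[, 3] * ac[, 1] - ab[, 1] * ac[, 3]
  cz <- ab[, 1] * ac[, 2] - ab[, 2] * ac[, 1]
  areas <- sqrt(cx^2 + cy^2 + cz^2) / 2
  bbox <- apply(v, 2, range)
  extent <- bbox[2, ] - bbox[1, ]
  structure(list(watertight = watertight,
                 n_components = n_components,
                 n_degenerate_faces = sum(areas < 1e-10),
                 bbox_extent = extent,
                 unit_warning = max(extent) < 120 || max(extent) > 400),
            class = "cranio_validation")
}

#' @export
print.cranio_validation <- function(x, ...) {
  cat("<cranio_validation>\n")
  cat("  watertight:       ", x$watertight, "\n")
  cat("  components:       ", x$n_components, "\n")
  cat("  degenerate faces: ", x$n_degenerate_faces, "\n")
  cat(sprintf("  bbox extent (mm):  %.1f x %.1f x %.1f\n",
              x$bbox_extent[1], x$bbox_extent[2], x$bbox_extent[3]))
  if (x$unit_warning)
    cat("  ! max extent outside 120-400 mm: check units (m or cm input?)\n")
  invisible(x)
}
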