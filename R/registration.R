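# Rigid registration of a head mesh to the canonical anatomical frame:
# nasion-tragi plane mapped to z = 0 with the vertex above it, left-right
# tragus direction along +x, nasion on the +y half-axis, and the in-plane
# origin anchored at the centroid of the largest-circumference axial slice.

#' Construct a rigid transform
#'
#' Represents `p -> R p + t`. Rotation must be orthonormal with
#' determinant +1 (tolerance 1e-9).
#'
#' @param rotation 3 x 3 rotation matrix.
#' @param translation Length-3 translation (mm).
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- matrix(as.numeric(rotation), 3, 3)
  translation <- as.numeric(translation)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9 ||
      abs(det(rotation) - 1) > 1e-9)
    stop("rotation must be orthonormal with determinant +1", call. = FALSE)
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("<rigid_transform>\n  rotation:\n")
  print(round(x$rotation, 6))
  cat("  translation:", sprintf("%.4f", x$translation), "\n")
  invisible(x)
}

#' Compose two rigid transforms
#'
#' `compose_transforms(b, a)` applies `a` first, then `b`.
#' @param b,a `rigid_transform` objects.
#' @return The composed `rigid_transform`.
#' @export
compose_transforms <- function(b, a) {
  rigid_transform(b$rotation %*% a$rotation,
                  as.numeric(b$rotation %*% a$translation) + b$translation)
}

#' Invert a rigid transform
#' @param transform A `rigid_transform`.
#' @return Its inverse.
#' @export
invert_transform <- function(transform) {
  rt <- t(transform$rotation)
  rigid_transform(rt, -as.numeric(rt %*% transform$translation))
}

transform_points <- function(points, transform) {
  points <- rbind(points)  # accept a single point
  sweep(points %*% t(transform$rotation), 2, -transform$translation)
}

#' Apply a rigid transform to a mesh
#' @param mesh A [cranio_mesh()].
#' @param transform A [rigid_transform()].
#' @return The transformed mesh (faces unchanged).
#' @export
apply_transform <- function(mesh, transform) {
  stopifnot(inherits(mesh, "cranio_mesh"), inherits(transform, "rigid_transform"))
  cranio_mesh(transform_points(mesh$vertices, transform), mesh$faces,
              metadata = mesh$metadata)
}

#' Apply a rigid transform to a landmark set
#' @param landmarks A [cranio_landmarks()].
#' @param transform A [rigid_transform()].
#' @return Transformed landmarks.
#' @export
transform_landmarks <- function(landmarks, transform) {
  p <- transform_points(landmark_matrix(landmarks), transform)
  cranio_landmarks(p[1, ], p[2, ], p[3, ])
}

#' Build the canonical anatomical frame from the three landmarks
#'
#' Returns the transform that maps the landmark centroid to the origin, the
#' nasion-tragi plane to z = 0 (normal toward the cranial vertex mapped to
#' +z), the in-plane left-to-right tragus direction to +x and consequently
#' the nasion onto the +y half-axis. Handedness is resolved by the landmark
#' labels, so the rotation always has determinant +1.
#'
#' @param landmarks A [cranio_landmarks()].
#' @return A [rigid_transform()] (source to canonical).
#' @export
build_landmark_frame <- function(landmarks) {
  stopifnot(inherits(landmarks, "cranio_landmarks"))
  p <- landmark_matrix(landmarks)
  centroid <- colMeans(p)
  ex <- unit3(landmarks$tragus_right - landmarks$tragus_left, "tragus axis")
  ey_raw <- landmarks$nasion - centroid
  ez <- unit3(cross3(ex, ey_raw), "plane normal")
  ey <- cross3(ez, ex)
  rot <- rbind(ex, ey, ez)
  rigid_transform(rot, -as.numeric(rot %*% centroid))
}

#' Register a head mesh into the canonical anatomical frame
#'
#' Applies [build_landmark_frame()], then searches axial planes (parallel to
#' z = 0, stepped by `slice_step` over the cranial side) for the slice with
#' the largest contour perimeter — the head circumference — and translates
#' in-plane so that slice's contour centroid sits at x = y = 0. The z
#' coordinate is left untouched so the nasion-tragi plane stays at z = 0.
#'
#' @param mesh A [cranio_mesh()].
#' @param landmarks The matching [cranio_landmarks()].
#' @param slice_step Axial search step in mm (default 1).
#' @return An object of class `registered_head` with fields `mesh`,
#'   `landmarks`, `transform` (source to canonical), and `anchor` (canonical
#'   origin expressed in source coordinates).
#' @export
register_head <- function(mesh, landmarks, slice_step = 1) {
  stopifnot(inherits(mesh, "cranio_mesh"), inherits(landmarks, "cranio_landmarks"))
  t1 <- build_landmark_frame(landmarks)
  m1 <- apply_transform(mesh, t1)
  lm1 <- transform_landmarks(landmarks, t1)

  # advisory: landmarks should sit on or near the scanned surface
  for (nm in c("nasion", "tragus_left", "tragus_right")) {
    d <- sqrt(min(rowSums(sweep(m1$vertices, 2, lm1[[nm]])^2)))
    if (d > 15)
      warning(sprintf("%s is %.1f mm from the mesh surface", nm, d), call. = FALSE)
  }

  z_max <- max(m1$vertices[, 3])
  if (z_max <= 0)
    stop("orientation error: mesh lies entirely below the nasion-tragi plane",
         call. = FALSE)
  zs <- seq(0, z_max - 1e-6, by = slice_step)
  best <- NULL
  for (z in zs) {
    contour <- tryCatch(
      intersect_plane(m1, cutting_plane(c(0, 0, z), c(0, 0, 1), "axial")),
      error = function(e) NULL)
    if (is.null(contour)) next
    per <- contour_perimeter(contour)
    if (is.null(best) || per > best$per + 1e-12) best <- list(per = per, contour = contour)
  }
  if (is.null(best))
    stop("orientation error: no axial slice found above the reference plane",
         call. = FALSE)
  ctr <- contour_centroid_2d(best$contour)
  t2 <- rigid_transform(diag(3), c(-ctr[1], -ctr[2], 0))
  total <- compose_transforms(t2, t1)
  structure(list(mesh = apply_transform(mesh, total),
                 landmarks = transform_landmarks(landmarks, total),
                 transform = total,
                 anchor = as.numeric(transform_points(c(0, 0, 0),
                                                      invert_transform(total)))),
            class = "registered_head")
}

#' @export
print.registered_head <- function(x, ...) {
  cat("<registered_head>\n")
  print(x$mesh)
  print(x$landmarks)
  invisible(x)
}

#' Serialize a rigid transform to JSON
#' @param transform A [rigid_transform()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_transform <- function(transform, path) {
  jsonlite::write_json(list(rotation = as.numeric(t(transform$rotation)),
                            translation = transform$translation),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a rigid transform from JSON
#' @param path JSON path written by [write_transform()].
#' @return A [rigid_transform()].
#' @export
read_transform <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(matrix(obj$rotation, 3, 3, byrow = TRUE), obj$translation)
}
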