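#' Rigid transforms
#'
#' A rigid transform maps source coordinates into reference coordinates:
#' `x -> R x + t`, with `R` a proper rotation (orthonormal, det = +1) and `t`
#' a translation in mm. Composition and inversion are closed.
#'
#' @param rotation 3 x 3 rotation matrix.
#' @param translation length-3 vector (mm).
#' @return an object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3, 3))) stop("rotation must be 3 x 3")
  if (length(translation) != 3) stop("translation must be length 3")
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-6)
    stop("rotation is not orthonormal")
  if (det(rotation) < 0) stop("rotation must be proper (det = +1)")
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' @rdname rigid_transform
#' @param tf,a,b rigid transforms.
#' @param points n x 3 matrix of points (mm).
#' @export
apply_transform <- function(tf, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  sweep(points %*% t(tf$rotation), 2, tf$translation, "+")
}

#' @rdname rigid_transform
#' @export
compose_transform <- function(a, b) {
  # (a o b): apply b first, then a
  rigid_transform(a$rotation %*% b$rotation,
                  as.numeric(a$rotation %*% b$translation) + a$translation)
}

#' @rdname rigid_transform
#' @export
invert_transform <- function(tf) {
  rigid_transform(t(tf$rotation),
                  as.numeric(-t(tf$rotation) %*% tf$translation))
}

#' @exportS3Method base::print
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle_deg(x$rotation)
  cat(sprintf("rigid_transform: rotation %.4f deg, translation (%.4f, %.4f, %.4f) mm\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Rotation helpers
#'
#' `rotation_about_axis` builds the rotation of `angle_deg` degrees about a
#' (not necessarily unit) axis via Rodrigues' formula. `rotation_angle_deg`
#' returns the total rotation angle of a rotation matrix.
#'
#' @param axis length-3 axis vector.
#' @param angle_deg rotation angle in degrees.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  axis <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' @rdname rotation_about_axis
#' @param rotation 3 x 3 rotation matrix.
#' @export
rotation_angle_deg <- function(rotation) {
  ctheta <- (sum(diag(rotation)) - 1) / 2
  acos(max(-1, min(1, ctheta))) * 180 / pi
}

# Nearest rotation matrix (polar factor); keeps ICP updates orthonormal.
orthonormalize <- function(m) {
  s <- svd(m)
  r <- s$u %*% t(s$v)
  if (det(r) < 0) {
    s$v[, 3] <- -s$v[, 3]
    r <- s$u %*% t(s$v)
  }
  r
}

# small-angle rotation vector -> rotation matrix (Rodrigues)
rotation_from_vector <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-300) return(diag(3))
  rotation_about_axis(w / th, th * 180 / pi)
}

#' Serialize transforms as JSON
#'
#' Row-major rotation plus translation in mm.
#'
#' @param tf a `rigid_transform`.
#' @param path file path.
#' @export
write_transform_json <- function(tf, path) {
  jsonlite::write_json(
    list(rotation = as.numeric(t(tf$rotation)),
         translation = tf$translation),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_transform_json
#' @export
read_transform_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rigid_transform(matrix(x$rotation, 3, 3, byrow = TRUE), x$translation)
}
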