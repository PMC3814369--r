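#' Construct a rigid-body transform
#'
#' @param rotation 3x3 proper orthonormal matrix.
#' @param translation length-3 numeric vector (Angstrom).
#' @return a [RigidTransform-class].
#' @export
RigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation))
}

#' @rdname RigidTransform
#' @export
identityTransform <- function() RigidTransform()

#' Compose two rigid transforms
#'
#' Returns the transform equivalent to applying `first` and then
#' `second`: rotation `R2 R1`, translation `R2 t1 + t2`.
#'
#' @param second,first [RigidTransform-class] objects.
#' @return a [RigidTransform-class].
#' @export
composeTransforms <- function(second, first) {
  RigidTransform(second@rotation %*% first@rotation,
                 as.numeric(second@rotation %*% first@translation) +
                   second@translation)
}

#' Invert a rigid transform
#'
#' @param transform a [RigidTransform-class].
#' @return the inverse transform (`R^T`, `-R^T t`).
#' @export
invertTransform <- function(transform) {
  Rt <- t(transform@rotation)
  RigidTransform(Rt, -as.numeric(Rt %*% transform@translation))
}

# apply transform to an n x 3 coordinate matrix (rows are points)
transformCoords <- function(xyz, transform) {
  stopifnot(is(transform, "RigidTransform"))
  out <- xyz %*% t(transform@rotation)
  out <- sweep(out, 2, transform@translation, "+")
  dimnames(out) <- dimnames(xyz)
  out
}

#' @export
setMethod("show", "RigidTransform", function(object) {
  cat("RigidTransform\n  rotation:\n")
  print(round(object@rotation, 6))
  cat("  translation:", paste(round(object@translation, 4), collapse = " "),
      "\n")
})

# rotation matrix from a unit quaternion (w, x, y, z)
quaternionToRotation <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

#' Draw a uniformly distributed random rotation
#'
#' Samples a unit quaternion from an isotropic Gaussian (uniform over the
#' rotation group) and converts it to a rotation matrix. Uses the current
#' RNG state; seed externally for reproducibility.
#'
#' @return a 3x3 proper rotation matrix.
#' @export
randomRotation <- function() {
  quaternionToRotation(stats::rnorm(4))
}

#' Rotation matrix from an axis and angle
#'
#' @param axis length-3 axis (normalized internally).
#' @param angle rotation angle in radians.
#' @return a 3x3 rotation matrix.
#' @export
axisAngleRotation <- function(axis, angle) {
  a <- axis / sqrt(sum(axis^2))
  q <- c(cos(angle / 2), sin(angle / 2) * a)
  quaternionToRotation(q)
}

# run expr with a local, seeded RNG, restoring global state afterwards
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}
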