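#' Rigid-body transforms and least-squares superposition
#'
#' `rigid_transform()` bundles a proper rotation and a translation;
#' `kabsch_fit()` computes the least-squares rigid superposition of two
#' paired point sets by singular value decomposition of the cross-covariance
#' matrix, with the reflection branch excluded so the result is always a
#' proper rotation.
#'
#' @param rotation 3x3 proper rotation matrix (determinant +1).
#' @param translation length-3 numeric translation vector, Angstrom.
#' @return `rigid_transform()` returns an object of class `rigid_transform`
#'   with elements `rotation` and `translation`.
#' @examples
#' tf <- rigid_transform(diag(3), c(1, 0, 0))
#' transform_coords(matrix(0, 1, 3), tf)
#' @export
rigid_transform <- function(rotation, translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (abs(det(rotation) - 1) > 1e-9) {
    stop("rotation must be proper (determinant +1)", call. = FALSE)
  }
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-9) {
    stop("rotation must be orthonormal", call. = FALSE)
  }
  structure(list(rotation = rotation, translation = as.numeric(translation)),
            class = "rigid_transform")
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat("Rigid transform\n  rotation:\n")
  print(round(x$rotation, 6))
  cat("  translation:", paste(sprintf("%.4f", x$translation), collapse = " "), "\n")
  invisible(x)
}

#' Identity transform
#' @rdname rigid_transform
#' @export
identity_transform <- function() rigid_transform(diag(3), c(0, 0, 0))

#' Invert a rigid transform
#' @param tf a `rigid_transform`.
#' @rdname rigid_transform
#' @export
invert_transform <- function(tf) {
  stopifnot(inherits(tf, "rigid_transform"))
  rigid_transform(t(tf$rotation), -as.numeric(t(tf$rotation) %*% tf$translation))
}

#' Compose two rigid transforms (apply `first`, then `second`)
#' @param first,second `rigid_transform` objects.
#' @rdname rigid_transform
#' @export
compose_transforms <- function(second, first) {
  rigid_transform(second$rotation %*% first$rotation,
                  as.numeric(second$rotation %*% first$translation) +
                    second$translation)
}

#' Apply a rigid transform to an N x 3 coordinate matrix
#' @param xyz numeric matrix with one row per point.
#' @rdname rigid_transform
#' @export
transform_coords <- function(xyz, tf) {
  stopifnot(inherits(tf, "rigid_transform"))
  xyz <- rbind(xyz)
  sweep(xyz %*% t(tf$rotation), 2, tf$translation, "+")
}

#' Least-squares rigid superposition (Kabsch algorithm)
#'
#' Finds the proper rotation and translation minimizing the RMSD of the
#' transformed mobile coordinates against the fixed coordinates. Rows of the
#' two matrices must correspond one-to-one.
#'
#' @param coords_mobile,coords_fixed N x 3 coordinate matrices (N >= 3).
#' @return list with `transform` (a [rigid_transform()] mapping mobile onto
#'   fixed) and `rmsd` (Angstrom, over all N pairs).
#' @examples
#' a <- matrix(rnorm(30), 10, 3)
#' R <- rotation_about_axis(c(0, 0, 1), 25)
#' b <- a %*% t(R)
#' kabsch_fit(a, b)$rmsd  # ~0
#' @export
kabsch_fit <- function(coords_mobile, coords_fixed) {
  a <- rbind(coords_mobile)
  b <- rbind(coords_fixed)
  if (nrow(a) != nrow(b)) stop("point sets must have equal size", call. = FALSE)
  if (nrow(a) < 3) stop("need at least 3 point pairs", call. = FALSE)
  if (any(!is.finite(a)) || any(!is.finite(b))) {
    stop("non-finite coordinates", call. = FALSE)
  }
  ca <- colMeans(a)
  cb <- colMeans(b)
  a0 <- sweep(a, 2, ca)
  b0 <- sweep(b, 2, cb)
  sv <- svd(crossprod(a0, b0))
  # collinear point sets leave the rotation about the line undetermined
  if (sv$d[2] < 1e-8 * max(sv$d[1], 1e-12)) {
    stop("degenerate (collinear) point sets: superposition ill-defined",
         call. = FALSE)
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tr <- cb - as.numeric(rot %*% ca)
  tf <- rigid_transform(rot, tr)
  fitted <- transform_coords(a, tf)
  list(transform = tf, rmsd = coord_rmsd(fitted, b))
}

#' Plain coordinate RMSD between two paired coordinate matrices (no fitting)
#' @param a,b N x 3 matrices with corresponding rows.
#' @return RMSD in Angstrom.
#' @export
coord_rmsd <- function(a, b) {
  a <- rbind(a)
  b <- rbind(b)
  stopifnot(nrow(a) == nrow(b))
  sqrt(mean(rowSums((a - b)^2)))
}
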