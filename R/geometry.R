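#' Rigid-body transform
#'
#' Carrier for a proper rotation plus translation, used by superposition and
#' Monte-Carlo moves. The rotation is validated to be orthogonal with
#' determinant +1 (no reflections).
#'
#' @param rotation 3x3 proper orthogonal matrix.
#' @param translation Length-3 numeric vector (\eqn{\AA}).
#' @return Object of class `rigid_transform`.
#' @export
rigid_transform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  stopifnot(all(dim(rotation) == c(3, 3)), length(translation) == 3)
  if (max(abs(crossprod(rotation) - diag(3))) > 1e-8) {
    stop("rotation matrix is not orthogonal")
  }
  if (abs(det(rotation) - 1) > 1e-8) {
    stop("rotation matrix is not proper (det != +1)")
  }
  structure(list(rotation = rotation, translation = translation),
            class = "rigid_transform")
}

#' Apply a rigid transform to coordinates
#'
#' @param transform A [rigid_transform()].
#' @param coords n x 3 coordinate matrix (or length-3 vector).
#' @return Transformed coordinates, same shape as the input.
#' @export
apply_transform <- function(transform, coords) {
  stopifnot(inherits(transform, "rigid_transform"))
  vec <- is.null(dim(coords))
  m <- if (vec) matrix(coords, 1, 3) else as.matrix(coords)
  out <- m %*% t(transform$rotation) +
    matrix(transform$translation, nrow(m), 3, byrow = TRUE)
  if (vec) as.numeric(out) else out
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(x$rotation)) - 1) / 2))) * 180 / pi
  cat(sprintf("<rigid_transform> rotation %.2f deg, translation (%.2f, %.2f, %.2f) A\n",
              ang, x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

# Rotation matrix about an arbitrary unit axis (Rodrigues form).
rotation_about_axis <- function(axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, axis[3], -axis[2],
                -axis[3], 0, axis[1],
                axis[2], -axis[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Uniform random rotation with angle drawn uniformly on [0, max_angle] about
# a uniformly distributed axis. Uses the calling frame's RNG stream.
random_rotation <- function(max_angle) {
  if (max_angle <= 0) return(diag(3))
  z <- stats::runif(1, -1, 1)
  phi <- stats::runif(1, 0, 2 * pi)
  axis <- c(sqrt(1 - z^2) * cos(phi), sqrt(1 - z^2) * sin(phi), z)
  rotation_about_axis(axis, stats::runif(1, 0, max_angle))
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' paired points of a mobile and a reference set. Reflections are excluded by
#' the usual determinant correction, so the result is always a rigid motion.
#'
#' @param mobile n x 3 matrix of mobile coordinates.
#' @param reference n x 3 matrix of reference coordinates.
#' @param pairing Optional two-column integer matrix of (mobile, reference)
#'   row indices; by default rows are paired positionally.
#' @return List with `transform` (a [rigid_transform()] mapping mobile onto
#'   reference) and `rmsd` (\eqn{\AA}) after superposition.
#' @export
superpose <- function(mobile, reference, pairing = NULL) {
  P <- as.matrix(mobile)
  Q <- as.matrix(reference)
  if (!is.null(pairing)) {
    pairing <- as.matrix(pairing)
    stopifnot(ncol(pairing) == 2)
    P <- P[pairing[, 1], , drop = FALSE]
    Q <- Q[pairing[, 2], , drop = FALSE]
  }
  if (nrow(P) != nrow(Q)) stop("paired point sets differ in size")
  if (nrow(P) < 3) stop("superposition needs at least 3 paired points")
  if (ncol(P) != 3 || ncol(Q) != 3) stop("coordinates must be n x 3")
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  sv_q <- svd(Qc)$d
  sv_p <- svd(Pc)$d
  if (sv_q[2] <= 1e-8 * max(sv_q[1], 1) || sv_p[2] <= 1e-8 * max(sv_p[1], 1)) {
    stop("degenerate (collinear) point configuration")
  }
  H <- crossprod(Pc, Qc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fit <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((fit - Qc)^2)))
  list(
    transform = rigid_transform(R, as.numeric(cq - R %*% cp)),
    rmsd = rmsd
  )
}

#' Root-mean-square coordinate deviation of paired points
#'
#' @param a,b n x 3 coordinate matrices, paired row-wise.
#' @return RMSD in the same units as the coordinates.
#' @export
rmsd <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  stopifnot(all(dim(a) == dim(b)))
  sqrt(mean(rowSums((a - b)^2)))
}

#' Calpha RMSD between two models after alignment on a reference region
#'
#' Superposes model A onto model B using the Calpha atoms of `align_on`, then
#' reports the Calpha RMSD over `measure_on` without re-fitting. This is the
#' standard way of quantifying the displacement of one subunit (e.g. a
#' mobile CSN subunit) between two conformers of a complex that share a
#' rigid core such as the C-terminal helical bundle.
#'
#' @param modelA,modelB `xl_structure` or `bead_model` objects.
#' @param align_on,measure_on Selection strings (see [parse_selection()]);
#'   `measure_on` defaults to `align_on`.
#' @return List with `rmsd` (\eqn{\AA}), `transform` (fit of A onto B) and
#'   `align_rmsd` over the alignment region.
#' @export
rmsd_between <- function(modelA, modelB, align_on, measure_on = align_on) {
  keysA <- resolve_selection(modelA, align_on)
  keysB <- resolve_selection(modelB, align_on)
  check_matched_keys(keysA, keysB, "alignment")
  mkeysA <- resolve_selection(modelA, measure_on)
  mkeysB <- resolve_selection(modelB, measure_on)
  check_matched_keys(mkeysA, mkeysB, "measurement")
  fit <- superpose(ca_coords(modelA, keysA), ca_coords(modelB, keysB))
  moved <- apply_transform(fit$transform, ca_coords(modelA, mkeysA))
  list(
    rmsd = rmsd(moved, ca_coords(modelB, mkeysB)),
    transform = fit$transform,
    align_rmsd = fit$rmsd
  )
}

check_matched_keys <- function(keysA, keysB, what) {
  ka <- paste0(keysA$chain, ":", keysA$resno)
  kb <- paste0(keysB$chain, ":", keysB$resno)
  if (length(ka) != length(kb) || any(ka != kb)) {
    miss <- c(setdiff(ka, kb), setdiff(kb, ka))
    stop(what, " selection does not match between models; unmatched: ",
         paste(utils::head(miss, 10), collapse = ", "),
         if (length(miss) > 10) " ..." else "")
  }
  invisible(TRUE)
}
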