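#' Coarse-grain a structure into a one-bead-per-residue model
#'
#' Each residue becomes a single bead at its Calpha position (centroid of the
#' residue's atoms when no Calpha exists, with a warning). Beads are
#' partitioned into rigid bodies, each flagged mobile or stationary; mobile
#' bodies are the ones a placement run is allowed to move.
#'
#' @param structure An `xl_structure`.
#' @param bodies Named list defining the rigid-body partition: each element is
#'   a list with `select` (selection string, see [parse_selection()]) and
#'   `mobile` (logical, default `FALSE`); element names are the body ids.
#'   Every residue of the structure must be covered by exactly one body.
#' @param radius Bead radius in \eqn{\AA} (default 3.5, a typical residue
#'   sphere; only the excluded-volume term uses it).
#' @return A `bead_model`: data frame with columns `chain`, `resno`, `x`,
#'   `y`, `z`, `radius`, `body`, `mobile` and one row per residue.
#' @export
coarse_grain <- function(structure, bodies, radius = 3.5) {
  stopifnot(inherits(structure, "xl_structure"))
  if (is.null(names(bodies)) || any(!nzchar(names(bodies)))) {
    stop("every rigid body must be named")
  }
  res <- unique(structure$atoms[, c("chain", "resno")])
  assigned <- rep(NA_character_, nrow(res))
  mobile_of <- logical(length(bodies))
  names(mobile_of) <- names(bodies)
  for (bn in names(bodies)) {
    b <- bodies[[bn]]
    mobile_of[bn] <- isTRUE(b$mobile)
    keys <- resolve_selection(structure, b$select)
    idx <- match(paste(keys$chain, keys$resno), paste(res$chain, res$resno))
    dup <- idx[!is.na(assigned[idx])]
    if (length(dup) > 0) {
      stop("residue ", res$chain[dup[1]], ":", res$resno[dup[1]],
           " assigned to two rigid bodies ('", assigned[dup[1]], "' and '",
           bn, "')")
    }
    assigned[idx] <- bn
  }
  if (anyNA(assigned)) {
    k <- which(is.na(assigned))[1]
    stop("residue ", res$chain[k], ":", res$resno[k],
         " not covered by any rigid body")
  }
  pos <- ca_coords_warn(structure, res)
  out <- data.frame(
    chain = res$chain, resno = res$resno,
    x = pos[, 1], y = pos[, 2], z = pos[, 3],
    radius = radius,
    body = assigned,
    mobile = mobile_of[assigned],
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("bead_model", "data.frame")
  out
}

# ca_coords with a warning whenever the centroid fallback is taken.
ca_coords_warn <- function(structure, keys) {
  at <- structure$atoms
  akey <- paste(at$chain, at$resno)
  has_ca <- tapply(at$elety == "CA" & !(at$element %in% c("CA", "Ca")),
                   akey, any)
  kk <- paste(keys$chain, keys$resno)
  miss <- kk[!has_ca[kk]]
  if (length(miss) > 0) {
    warning("no Calpha for ", length(miss),
            " residue(s); using atom centroid: ",
            paste(utils::head(sub(" ", ":", miss), 5), collapse = ", "),
            if (length(miss) > 5) " ..." else "")
  }
  ca_coords(structure, keys)
}

#' Construct a bead model directly from bead coordinates
#'
#' Mostly used by the synthetic-data generator; [coarse_grain()] is the entry
#' point for real structures.
#'
#' @param chain,resno Residue keys (recycled chain allowed).
#' @param xyz n x 3 coordinate matrix.
#' @param body Rigid-body id per bead.
#' @param mobile Logical, mobile flag per bead (constant within a body).
#' @param radius Bead radius (\eqn{\AA}).
#' @return A `bead_model`.
#' @export
bead_model <- function(chain, resno, xyz, body, mobile, radius = 3.5) {
  xyz <- as.matrix(xyz)
  n <- nrow(xyz)
  out <- data.frame(
    chain = rep_len(as.character(chain), n),
    resno = as.integer(resno),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    radius = rep_len(radius, n),
    body = rep_len(as.character(body), n),
    mobile = rep_len(as.logical(mobile), n),
    stringsAsFactors = FALSE
  )
  key <- paste(out$chain, out$resno)
  if (anyDuplicated(key)) stop("duplicate (chain, resno) bead keys")
  for (b in unique(out$body)) {
    if (length(unique(out$mobile[out$body == b])) != 1L) {
      stop("mobile flag must be constant within body ", b)
    }
  }
  class(out) <- c("bead_model", "data.frame")
  out
}

#' @export
print.bead_model <- function(x, ...) {
  bd <- unique(x[, c("body", "mobile")])
  cat("<bead_model> ", nrow(x), " beads in ", nrow(bd), " rigid bodies (",
      sum(bd$mobile), " mobile)\n", sep = "")
  for (k in seq_len(nrow(bd))) {
    nb <- sum(x$body == bd$body[k])
    cat(sprintf("  %-12s %4d beads  %s\n", bd$body[k], nb,
                if (bd$mobile[k]) "mobile" else "stationary"))
  }
  invisible(x)
}

# Matrix of bead coordinates.
bead_xyz <- function(model) as.matrix(model[, c("x", "y", "z")])

# Centroid of the beads of one body.
body_centroid <- function(model, body) {
  colMeans(bead_xyz(model[model$body == body, , drop = FALSE]))
}

# Apply a rigid transform to the beads of one body, in place.
transform_body <- function(model, body, transform) {
  sel <- model$body == body
  xyz <- apply_transform(transform, bead_xyz(model[sel, , drop = FALSE]))
  model$x[sel] <- xyz[, 1]
  model$y[sel] <- xyz[, 2]
  model$z[sel] <- xyz[, 3]
  model
}
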