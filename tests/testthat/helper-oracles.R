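# Independent oracles: deliberately separate implementations used to verify
# the package's computations on small instances.

# Best planar superposition by exhaustive rotation about z at `step_deg`
# resolution (centroids matched). Exact up to grid resolution for z = 0
# point sets.
grid_superpose_rmsd <- function(P, Q, step_deg = 0.5) {
  Pc <- sweep(P, 2, colMeans(P))
  Qc <- sweep(Q, 2, colMeans(Q))
  best <- Inf
  for (deg in seq(0, 360 - step_deg, by = step_deg)) {
    a <- deg * pi / 180
    R <- matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
    r <- sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
    if (r < best) best <- r
  }
  best
}

# Direct re-summation of the placement score: plain loops, no shared code
# with score_model().
oracle_score <- function(model, restraints, params) {
  viol <- 0
  for (k in seq_len(nrow(restraints))) {
    a <- model[model$chain == restraints$protein1[k] &
               model$resno == restraints$residue1[k], c("x", "y", "z")]
    b <- model[model$chain == restraints$protein2[k] &
               model$resno == restraints$residue2[k], c("x", "y", "z")]
    d <- sqrt(sum((as.numeric(a) - as.numeric(b))^2))
    ex <- d - restraints$upper_bound[k]
    if (ex > 0) viol <- viol + params$violation_weight * ex^2
  }
  # EV spheres: groups of ev_resolution consecutive beads per body
  spheres <- list()
  for (b in unique(model$body)) {
    rows <- which(model$body == b)
    grp <- rep(seq_len(ceiling(length(rows) / params$ev_resolution)),
               each = params$ev_resolution)[seq_along(rows)]
    for (g in unique(grp)) {
      sub <- model[rows[grp == g], ]
      spheres[[length(spheres) + 1]] <- list(
        body = b,
        center = c(mean(sub$x), mean(sub$y), mean(sub$z)),
        radius = sub$radius[1] * nrow(sub)^(1 / 3)
      )
    }
  }
  ev <- 0
  if (length(spheres) > 1) {
    for (i in 1:(length(spheres) - 1)) {
      for (j in (i + 1):length(spheres)) {
        if (spheres[[i]]$body == spheres[[j]]$body) next
        d <- sqrt(sum((spheres[[i]]$center - spheres[[j]]$center)^2))
        ov <- spheres[[i]]$radius + spheres[[j]]$radius - d
        if (ov > 0) ev <- ev + params$ev_weight * ov^2
      }
    }
  }
  c(total = viol + ev, violation = viol, ev = ev)
}

# Exhaustive translation-only search: move each mobile body on a cubic grid
# and return the minimum total score.
grid_translation_min <- function(model, restraints, params, span = 6,
                                 step = 1) {
  mobile <- unique(model$body[model$mobile])
  stopifnot(length(mobile) == 1)
  offs <- seq(-span, span, by = step)
  best <- Inf
  for (dx in offs) for (dy in offs) for (dz in offs) {
    m <- model
    sel <- m$body == mobile
    m$x[sel] <- m$x[sel] + dx
    m$y[sel] <- m$y[sel] + dy
    m$z[sel] <- m$z[sel] + dz
    s <- score_model(m, restraints, params)["total"]
    if (s < best) best <- s
  }
  unname(best)
}

# Numerical mass-balance solver for the 1:1 equilibrium: root of
# Ka * (P - PL) * (L - PL) - PL on [0, min(P, L)]. Independent of the
# closed-form quadratic.
numeric_bound_fraction <- function(L_tot, P_tot, Ka) {
  if (L_tot == 0) return(0)
  f <- function(PL) Ka * (P_tot - PL) * (L_tot - PL) - PL
  hi <- min(P_tot, L_tot)
  root <- stats::uniroot(f, lower = 0, upper = hi, tol = 1e-18 * P_tot,
                         extendInt = "no")$root
  root / P_tot
}

centroid_of <- function(model, body) {
  colMeans(as.matrix(model[model$body == body, c("x", "y", "z")]))
}

random_rigid <- function() {
  ang <- stats::runif(3, -pi, pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(ang[1]), sin(ang[1]),
                 0, -sin(ang[1]), cos(ang[1])), 3, 3)
  Ry <- matrix(c(cos(ang[2]), 0, -sin(ang[2]), 0, 1, 0,
                 sin(ang[2]), 0, cos(ang[2])), 3, 3)
  Rz <- matrix(c(cos(ang[3]), sin(ang[3]), 0,
                 -sin(ang[3]), cos(ang[3]), 0, 0, 0, 1), 3, 3)
  rigid_transform(Rx %*% Ry %*% Rz, stats::runif(3, -20, 20))
}

transform_model <- function(model, tf) {
  xyz <- apply_transform(tf, as.matrix(model[, c("x", "y", "z")]))
  model$x <- xyz[, 1]; model$y <- xyz[, 2]; model$z <- xyz[, 3]
  model
}
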