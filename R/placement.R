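#' Monte-Carlo placement parameters
#'
#' Defaults follow the parametrisation used for cross-link-guided placement
#' of mobile subunits onto a fixed scaffold: 1000 outer iterations of 10
#' Metropolis steps, rigid-body moves of at most 2 A translation per
#' component and 0.1 rad rotation, and excluded-volume spheres grouping 20
#' consecutive residues.
#'
#' @param n_iterations Outer iterations (default 1000).
#' @param num_mc_steps Metropolis steps per iteration (default 10).
#' @param rb_max_trans Max rigid-body translation per component, \eqn{\AA}
#'   (default 2).
#' @param rb_max_rot Max rigid-body rotation, radians (default 0.1).
#' @param bead_max_trans Max flexible-bead translation, \eqn{\AA} (default
#'   0.5); retained for configuration compatibility but inactive — bodies
#'   are fully rigid here.
#' @param ev_resolution Residues per excluded-volume sphere (default 20).
#' @param violation_weight Weight of the restraint-violation term per
#'   \eqn{\AA^2} (default 1).
#' @param ev_weight Weight of the excluded-volume term (default 1).
#' @param temperature Metropolis temperature (default 1).
#' @param seed Optional RNG seed; a run with a given seed is exactly
#'   reproducible.
#' @return A `placement_params` list.
#' @export
placement_params <- function(n_iterations = 1000, num_mc_steps = 10,
                             rb_max_trans = 2, rb_max_rot = 0.1,
                             bead_max_trans = 0.5, ev_resolution = 20,
                             violation_weight = 1, ev_weight = 1,
                             temperature = 1, seed = NULL) {
  p <- list(n_iterations = n_iterations, num_mc_steps = num_mc_steps,
            rb_max_trans = rb_max_trans, rb_max_rot = rb_max_rot,
            bead_max_trans = bead_max_trans, ev_resolution = ev_resolution,
            violation_weight = violation_weight, ev_weight = ev_weight,
            temperature = temperature, seed = seed)
  num <- p[setdiff(names(p), c("seed", "rb_max_trans", "rb_max_rot"))]
  if (any(!vapply(num, function(v) is.numeric(v) && v > 0, TRUE))) {
    stop("placement parameters must be positive numbers")
  }
  if (rb_max_trans < 0 || rb_max_rot < 0) {
    stop("move magnitudes must be non-negative")
  }
  structure(p, class = "placement_params")
}

# Excluded-volume spheres: groups of ev_resolution consecutive beads per
# body. Sphere radius conserves the summed bead volume: R = r * n^(1/3).
ev_groups <- function(model, ev_resolution) {
  idx <- seq_len(nrow(model))
  out <- list()
  for (b in unique(model$body)) {
    rows <- idx[model$body == b]
    chunks <- split(rows, ceiling(seq_along(rows) / ev_resolution))
    for (ch in chunks) {
      out[[length(out) + 1L]] <- list(
        rows = ch, body = b,
        radius = model$radius[ch[1]] * length(ch)^(1 / 3)
      )
    }
  }
  out
}

ev_penalty <- function(xyz, groups) {
  ng <- length(groups)
  if (ng < 2) return(0)
  centers <- t(vapply(groups, function(g) colMeans(xyz[g$rows, , drop = FALSE]),
                      numeric(3)))
  radii <- vapply(groups, `[[`, numeric(1), "radius")
  bodies <- vapply(groups, `[[`, character(1), "body")
  pen <- 0
  for (i in seq_len(ng - 1)) {
    for (j in seq(i + 1, ng)) {
      if (bodies[i] == bodies[j]) next
      d <- sqrt(sum((centers[i, ] - centers[j, ])^2))
      ov <- radii[i] + radii[j] - d
      if (ov > 0) pen <- pen + ov^2
    }
  }
  pen
}

# Resolve restraint endpoints to bead row indices; error on unmapped.
restraint_indices <- function(model, restraints) {
  kk <- paste(model$chain, model$resno)
  i1 <- match(paste(restraints$protein1, restraints$residue1), kk)
  i2 <- match(paste(restraints$protein2, restraints$residue2), kk)
  if (anyNA(i1) || anyNA(i2)) {
    bad <- which(is.na(i1) | is.na(i2))
    stop("restraint endpoint(s) not mappable onto the model: ",
         paste0(restraints$protein1[bad], ":", restraints$residue1[bad],
                "--", restraints$protein2[bad], ":",
                restraints$residue2[bad], collapse = ", "))
  }
  cbind(i1, i2)
}

score_xyz <- function(xyz, ridx, bounds, groups, params) {
  d <- sqrt(rowSums((xyz[ridx[, 1], , drop = FALSE] -
                     xyz[ridx[, 2], , drop = FALSE])^2))
  viol <- params$violation_weight * sum(pmax(0, d - bounds)^2)
  ev <- params$ev_weight * ev_penalty(xyz, groups)
  c(total = viol + ev, violation = viol, ev = ev)
}

#' Score a bead model against a restraint set
#'
#' Total score = harmonic upper-bound violation term (sum over restraints of
#' `weight * max(0, d - bound)^2`) plus a soft-sphere excluded-volume term
#' (sum of squared overlaps between excluded-volume spheres of different
#' rigid bodies). Zero iff every restraint is within its bound and no
#' spheres overlap.
#'
#' @param model A `bead_model`.
#' @param restraints A `crosslink_table`; every restraint must map onto the
#'   model (error otherwise).
#' @param params [placement_params()].
#' @return Named numeric vector `total`, `violation`, `ev`.
#' @export
score_model <- function(model, restraints, params = placement_params()) {
  ridx <- restraint_indices(model, restraints)
  score_xyz(bead_xyz(model), ridx, restraints$upper_bound,
            ev_groups(model, params$ev_resolution), params)
}

#' Propose a random rigid-body move
#'
#' Each mobile body is perturbed by a random rotation about its centroid
#' (uniform axis, angle uniform on `[0, rb_max_rot]`) followed by a random
#' translation with each component uniform on `[-rb_max_trans,
#' rb_max_trans]`. Stationary bodies are untouched and the internal geometry
#' of every body is preserved exactly. Uses the current RNG stream.
#'
#' @param model A `bead_model` with at least one mobile body.
#' @param params [placement_params()].
#' @return The perturbed `bead_model`.
#' @export
propose_move <- function(model, params = placement_params()) {
  mobile <- unique(model$body[model$mobile])
  if (length(mobile) == 0L) stop("model has no mobile rigid bodies")
  for (b in mobile) {
    R <- random_rotation(params$rb_max_rot)
    tr <- stats::runif(3, -params$rb_max_trans, params$rb_max_trans)
    cen <- body_centroid(model, b)
    # rotate about the body centroid, then translate
    tf <- rigid_transform(R, as.numeric(cen - R %*% cen) + tr)
    model <- transform_body(model, b, tf)
  }
  model
}

#' Cross-link-guided Monte-Carlo placement of mobile rigid bodies
#'
#' Runs `n_iterations` outer iterations of `num_mc_steps` Metropolis steps.
#' Each step proposes rigid moves of every mobile body ([propose_move()]) and
#' accepts when the score does not increase, otherwise with probability
#' `exp(-delta/temperature)`. The best-scoring model ever visited is tracked
#' and returned together with its per-restraint distances and a satisfaction
#' report at the restraint bounds.
#'
#' @param model Starting `bead_model` (mobile bodies start at their input
#'   coordinates).
#' @param restraints A `crosslink_table` fully mappable onto the model.
#' @param params [placement_params()]; `params$seed` (when non-`NULL`) makes
#'   the run exactly reproducible.
#' @return A `placement_result`: list with `best_model`, `best_score`,
#'   `score_breakdown`, `distances` (per restraint on the best model),
#'   `satisfaction` ([classify_satisfaction()] report), `trajectory`
#'   (best-so-far total score after each outer iteration, non-increasing),
#'   `acceptance_rate`, `seed` and `params`.
#' @export
mc_place <- function(model, restraints, params = placement_params()) {
  if (!is.null(params$seed)) set.seed(params$seed)
  mobile <- unique(model$body[model$mobile])
  if (length(mobile) == 0L) stop("model has no mobile rigid bodies")
  ridx <- restraint_indices(model, restraints)
  bounds <- restraints$upper_bound
  groups <- ev_groups(model, params$ev_resolution)
  body_rows <- lapply(mobile, function(b) which(model$body == b))
  names(body_rows) <- mobile

  xyz <- bead_xyz(model)
  cur <- score_xyz(xyz, ridx, bounds, groups, params)
  best_xyz <- xyz
  best <- cur
  accepted <- 0L
  total_steps <- params$n_iterations * params$num_mc_steps
  trajectory <- numeric(params$n_iterations)

  for (it in seq_len(params$n_iterations)) {
    for (st in seq_len(params$num_mc_steps)) {
      prop <- xyz
      for (b in mobile) {
        rows <- body_rows[[b]]
        R <- random_rotation(params$rb_max_rot)
        tr <- stats::runif(3, -params$rb_max_trans, params$rb_max_trans)
        sub <- prop[rows, , drop = FALSE]
        cen <- colMeans(sub)
        sub <- sweep(sub, 2, cen) %*% t(R)
        prop[rows, ] <- sweep(sub, 2, cen + tr, `+`)
      }
      cand <- score_xyz(prop, ridx, bounds, groups, params)
      delta <- cand["total"] - cur["total"]
      if (delta <= 0 ||
          stats::runif(1) < exp(-delta / params$temperature)) {
        xyz <- prop
        cur <- cand
        accepted <- accepted + 1L
        if (cur["total"] < best["total"]) {
          best <- cur
          best_xyz <- xyz
        }
      }
    }
    trajectory[it] <- best["total"]
  }

  best_model <- model
  best_model$x <- best_xyz[, 1]
  best_model$y <- best_xyz[, 2]
  best_model$z <- best_xyz[, 3]
  distances <- crosslink_distance(best_model, restraints)
  structure(
    list(
      best_model = best_model,
      best_score = unname(best["total"]),
      score_breakdown = best,
      distances = distances,
      satisfaction = classify_satisfaction(best_model, restraints),
      trajectory = trajectory,
      acceptance_rate = accepted / total_steps,
      seed = params$seed,
      params = params
    ),
    class = "placement_result"
  )
}

#' @export
print.placement_result <- function(x, ...) {
  cat(sprintf("<placement_result> best score %.4f (violation %.4f, ev %.4f)\n",
              x$best_score, x$score_breakdown["violation"],
              x$score_breakdown["ev"]))
  cat(sprintf("  %d restraints: %d satisfied, %d violated; acceptance %.1f%%",
              length(x$distances), x$satisfaction$counts["satisfied"],
              x$satisfaction$counts["violated"], 100 * x$acceptance_rate))
  if (!is.null(x$seed)) cat("; seed ", x$seed, sep = "")
  cat("\n")
  invisible(x)
}

#' @export
plot.placement_result <- function(x, ...) {
  graphics::plot(seq_along(x$trajectory), x$trajectory, type = "s",
                 xlab = "iteration", ylab = "best-so-far score",
                 main = "Monte-Carlo placement trajectory", ...)
  invisible(x)
}

#' Select the best placement among replicate runs
#'
#' Minimal total score wins; ties are broken by fewer violated experimental
#' restraints, then by input (seed) order.
#'
#' @param results List of `placement_result` objects.
#' @return The selected `placement_result`.
#' @export
select_best <- function(results) {
  if (length(results) == 0L) stop("no placement results to select from")
  stopifnot(all(vapply(results, inherits, TRUE, "placement_result")))
  scores <- vapply(results, `[[`, numeric(1), "best_score")
  nviol <- vapply(results, function(r) {
    exp_links <- r$satisfaction$links$kind == "experimental"
    sum(r$satisfaction$links$status[exp_links] == "violated")
  }, numeric(1))
  ord <- order(scores, nviol, seq_along(results))
  results[[ord[1]]]
}
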