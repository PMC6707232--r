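#' Generate a toy multi-body bead complex with known poses
#'
#' Builds `n_bodies` self-avoiding bead chains (3.8 A spacing, protein-like
#' Calpha geometry), assembles them without inter-body clashes, and returns
#' both the assembled ground-truth model and a start model in which every
#' mobile body has been displaced by a recorded, seed-controlled rigid
#' transform. Mirroring the way dissected mobile domains remain covalently
#' tied to the scaffold they came from, each mobile body is grown as a
#' chain continuation of a stationary host body: its first bead sits one
#' Calpha step (3.8 A) beyond the host's last bead, and the junction pair
#' is reported as a covalent-tether topology entry suitable for
#' [build_restraints()]. The truth record is sufficient to recompute every
#' emitted observable.
#'
#' @param n_bodies Number of rigid bodies (default 3).
#' @param residues_per_body Beads per body (default 20; recycled).
#' @param mobile Logical vector or body indices flagging mobile bodies
#'   (default: the last body). At least one stationary and one mobile body
#'   are required.
#' @param scramble_trans Displacement magnitude (\eqn{\AA}) applied to each
#'   mobile body in the start model (default 15).
#' @param scramble_rot Max rotation (radians) applied to each mobile body in
#'   the start model (default `pi/2`).
#' @param separation Approximate centroid spacing between stationary bodies
#'   (\eqn{\AA}, default 22).
#' @param clash_distance Minimum allowed inter-body bead distance
#'   (\eqn{\AA}, default 3.5; the covalent junction itself sits at the
#'   3.8 A chain step).
#' @param seed RNG seed; identical inputs give bitwise-identical outputs.
#' @param max_retry Assembly retries before giving up (default 50).
#' @return List with `truth` (`bead_model` at the true pose), `start`
#'   (`bead_model` with mobile bodies displaced) and `truth_record` (a list
#'   with per-mobile-body [rigid_transform()]s `poses`, true `centroids`,
#'   the `tether` data frame of covalent junction pairs, `mobile` flags,
#'   `seed` and the generating `spec`).
#' @export
make_toy_complex <- function(n_bodies = 3, residues_per_body = 20,
                             mobile = n_bodies, scramble_trans = 15,
                             scramble_rot = pi / 2, separation = 22,
                             clash_distance = 3.5, seed = 1,
                             max_retry = 50) {
  if (n_bodies < 2) stop("need at least 2 bodies")
  nres <- rep_len(residues_per_body, n_bodies)
  mob <- logical(n_bodies)
  if (is.logical(mobile)) mob <- rep_len(mobile, n_bodies) else mob[mobile] <- TRUE
  if (!any(mob) || all(mob)) {
    stop("need at least one mobile and one stationary body")
  }
  set.seed(seed)
  body_names <- paste0("B", seq_len(n_bodies))
  stat_idx <- which(!mob)
  # stationary body centroids on a jittered circle so a mobile body sees
  # restraint anchors from well-separated directions
  ns <- length(stat_idx)
  r <- if (ns > 1) separation / (2 * sin(pi / ns)) else 0
  theta <- 2 * pi * (seq_len(ns) - 1) / ns
  anchors <- cbind(r * cos(theta), r * sin(theta),
                   stats::runif(ns, -3, 3))
  # each mobile body continues the chain of a host stationary body
  hosts <- stat_idx[1 + (seq_len(sum(mob)) - 1) %% ns]
  for (attempt in seq_len(max_retry)) {
    chains <- vector("list", n_bodies)
    for (k in seq_len(ns)) {
      ch <- self_avoiding_chain(nres[stat_idx[k]])
      chains[[stat_idx[k]]] <- sweep(ch, 2, colMeans(ch)) +
        matrix(anchors[k, ], nres[stat_idx[k]], 3, byrow = TRUE)
    }
    for (m in seq_along(which(mob))) {
      body <- which(mob)[m]
      host <- chains[[hosts[m]]]
      end <- host[nrow(host), ]
      u <- end - colMeans(host)          # grow outward from the host
      u <- u / sqrt(sum(u^2))
      ch <- self_avoiding_chain(nres[body])
      chains[[body]] <- ch + matrix(end + 3.8 * u, nres[body], 3,
                                    byrow = TRUE)
    }
    if (!any_interbody_clash(chains, clash_distance)) break
    if (attempt == max_retry) {
      stop("could not assemble clash-free bodies after ", max_retry,
           " attempts; increase separation")
    }
  }
  xyz <- do.call(rbind, chains)
  truth <- bead_model(
    chain = rep(body_names, nres),
    resno = unlist(lapply(nres, seq_len)),
    xyz = xyz,
    body = rep(body_names, nres),
    mobile = rep(mob, nres)
  )
  tether <- data.frame(
    protein1 = body_names[hosts], residue1 = nres[hosts],
    protein2 = body_names[mob], residue2 = 1L,
    stringsAsFactors = FALSE
  )
  start <- truth
  poses <- list()
  for (b in body_names[mob]) {
    R <- random_rotation(scramble_rot)
    z <- stats::runif(1, -1, 1)
    phi <- stats::runif(1, 0, 2 * pi)
    dir <- c(sqrt(1 - z^2) * cos(phi), sqrt(1 - z^2) * sin(phi), z)
    cen <- body_centroid(truth, b)
    tf <- rigid_transform(R, as.numeric(cen - R %*% cen) +
                               scramble_trans * dir)
    start <- transform_body(start, b, tf)
    poses[[b]] <- tf
  }
  list(
    truth = truth,
    start = start,
    truth_record = list(
      poses = poses,
      centroids = lapply(stats::setNames(body_names, body_names),
                         function(b) body_centroid(truth, b)),
      tether = tether,
      mobile = stats::setNames(mob, body_names),
      seed = seed,
      spec = list(n_bodies = n_bodies, residues_per_body = nres,
                  scramble_trans = scramble_trans,
                  scramble_rot = scramble_rot, separation = separation,
                  clash_distance = clash_distance)
    )
  )
}

# Self-avoiding random walk with fixed 3.8 A steps; rejects steps closer
# than 0.9 * step to any previous bead.
self_avoiding_chain <- function(n, step = 3.8, max_tries = 2000) {
  xyz <- matrix(0, n, 3)
  for (i in seq_len(n)[-1]) {
    placed <- FALSE
    for (tr in seq_len(max_tries)) {
      z <- stats::runif(1, -1, 1)
      phi <- stats::runif(1, 0, 2 * pi)
      dir <- c(sqrt(1 - z^2) * cos(phi), sqrt(1 - z^2) * sin(phi), z)
      cand <- xyz[i - 1, ] + step * dir
      d <- sqrt(rowSums((xyz[seq_len(i - 1), , drop = FALSE] -
                         matrix(cand, i - 1, 3, byrow = TRUE))^2))
      if (all(d >= 0.9 * step)) {
        xyz[i, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("self-avoiding walk stalled at bead ", i)
  }
  xyz
}

any_interbody_clash <- function(chains, clash_distance) {
  nb <- length(chains)
  for (i in seq_len(nb - 1)) {
    for (j in seq(i + 1, nb)) {
      di <- chains[[i]]; dj <- chains[[j]]
      for (k in seq_len(nrow(di))) {
        d <- sqrt(rowSums((dj - matrix(di[k, ], nrow(dj), 3,
                                       byrow = TRUE))^2))
        if (any(d < clash_distance)) return(TRUE)
      }
    }
  }
  FALSE
}

#' Simulate a cross-link table from a ground-truth model
#'
#' True links are drawn between residues of each mobile body and residues of
#' stationary bodies whose ground-truth distance is at most `max_dist`
#' (default 30 A, comfortably inside the 35 A experimental bound). Optional
#' decoys are drawn uniformly over inter-body residue pairs regardless of
#' distance and flagged in the truth record.
#'
#' @param truth A `bead_model` at the true pose.
#' @param n_per_mobile True links per mobile body (default 4).
#' @param max_dist Max ground-truth distance of a true link (\eqn{\AA},
#'   default 30).
#' @param min_dist_frac True links are drawn from pairs with ground-truth
#'   distance in `[min_dist_frac * max_dist, max_dist]` (default 0.85).
#'   Links near the distance budget are the ones that constrain a pose;
#'   short links are satisfied almost anywhere within the 35 A bound and
#'   carry no placement information. Set to 0 to draw uniformly over all
#'   pairs within `max_dist`.
#' @param decoy_fraction Fraction of emitted links that are decoys, in
#'   `[0, 1)` (default 0).
#' @param seed RNG seed.
#' @return A `crosslink_table` (experimental kind, 35 A bound) with a
#'   `truth` attribute: data frame of per-link ground-truth distance and
#'   `is_decoy` flag.
#' @export
simulate_crosslinks <- function(truth, n_per_mobile = 4, max_dist = 30,
                                min_dist_frac = 0.85,
                                decoy_fraction = 0, seed = 1) {
  stopifnot(inherits(truth, "bead_model"))
  if (decoy_fraction < 0 || decoy_fraction >= 1) {
    stop("decoy_fraction must lie in [0, 1)")
  }
  if (max_dist > XL_DEFAULT_BOUND) {
    stop("max true distance must not exceed the experimental bound")
  }
  set.seed(seed)
  xyz <- bead_xyz(truth)
  mobile_bodies <- unique(truth$body[truth$mobile])
  stat_rows <- which(!truth$mobile)
  picks <- list()
  for (b in mobile_bodies) {
    rows_b <- which(truth$body == b)
    pairs <- expand.grid(i = rows_b, j = stat_rows)
    d <- sqrt(rowSums((xyz[pairs$i, , drop = FALSE] -
                       xyz[pairs$j, , drop = FALSE])^2))
    ok <- which(d <= max_dist & d >= min_dist_frac * max_dist)
    if (length(ok) < n_per_mobile) {
      stop("only ", length(ok), " eligible residue pairs (",
           round(min_dist_frac * max_dist, 1), "-", max_dist,
           " A) for body ", b, "; use larger bodies or smaller separation")
    }
    # stratify links across stationary partner bodies and along the mobile
    # chain, so links attach across the whole body and pull from
    # well-separated directions (surface lysines linking a domain to its
    # several neighbours do); strata without an eligible pair fall back to
    # the global pool
    block <- ceiling(match(pairs$i[ok], rows_b) /
                     (length(rows_b) / n_per_mobile))
    partner <- truth$body[pairs$j[ok]]
    partners <- unique(partner)
    sel <- integer(0)
    for (bl in seq_len(n_per_mobile)) {
      want_partner <- partners[1 + (bl - 1) %% length(partners)]
      cand <- setdiff(ok[block == bl & partner == want_partner], sel)
      if (length(cand) == 0) cand <- setdiff(ok[partner == want_partner], sel)
      if (length(cand) == 0) cand <- setdiff(ok, sel)
      sel <- c(sel, if (length(cand) == 1) cand else sample(cand, 1))
    }
    picks[[b]] <- data.frame(i = pairs$i[sel], j = pairs$j[sel],
                             dist = d[sel], decoy = FALSE)
  }
  links <- do.call(rbind, picks)
  n_true <- nrow(links)
  n_decoy <- round(n_true * decoy_fraction / (1 - decoy_fraction))
  if (n_decoy > 0) {
    body_of <- truth$body
    repeat {
      i <- sample(nrow(truth), n_decoy, replace = TRUE)
      j <- sample(nrow(truth), n_decoy, replace = TRUE)
      if (all(body_of[i] != body_of[j])) break
    }
    dd <- sqrt(rowSums((xyz[i, , drop = FALSE] - xyz[j, , drop = FALSE])^2))
    links <- rbind(links, data.frame(i = i, j = j, dist = dd, decoy = TRUE))
  }
  out <- crosslinks(
    protein1 = truth$chain[links$i], residue1 = truth$resno[links$i],
    protein2 = truth$chain[links$j], residue2 = truth$resno[links$j]
  )
  attr(out, "truth") <- data.frame(true_distance = links$dist,
                                   is_decoy = links$decoy)
  out
}

#' Simulate a PLIMSTEX titration series
#'
#' Generates replicate uptake observations from [binding_isotherm()] plus
#' Gaussian noise at the standard design: receptor fixed (default 250 nM)
#' and ligand titrated at molar ratios of the receptor concentration
#' (default 0, 0.1, 0.5, 1, 2).
#'
#' @param D0 True uptake at zero ligand, Da.
#' @param dD True saturating uptake change, Da (negative = protection).
#' @param Kd True dissociation constant, molar.
#' @param P_tot Receptor concentration, molar (default 250e-9).
#' @param ratios Ligand:receptor molar ratios; must include 0 (default
#'   `c(0, 0.1, 0.5, 1, 2)`).
#' @param noise_sd Replicate noise SD, Da (default 0.05).
#' @param replicates Replicates per concentration (default 3).
#' @param seed RNG seed.
#' @return A [titration_series()] with a `truth` attribute holding
#'   `(D0, dD, Kd)`.
#' @export
simulate_titration <- function(D0, dD, Kd, P_tot = 250e-9,
                               ratios = c(0, 0.1, 0.5, 1, 2),
                               noise_sd = 0.05, replicates = 3, seed = 1) {
  if (Kd <= 0) stop("Kd must be positive")
  if (!(0 %in% ratios)) stop("titration design must include the 0 ratio")
  if (any(ratios < 0) || anyDuplicated(ratios)) {
    stop("ratios must be distinct and non-negative")
  }
  if (replicates < 1) stop("need at least one replicate")
  set.seed(seed)
  L <- rep(P_tot * sort(ratios), each = replicates)
  mu <- binding_isotherm(L, P_tot, 1 / Kd, D0, dD)
  uptake <- mu + stats::rnorm(length(L), 0, noise_sd)
  out <- titration_series(L, uptake, P_tot = P_tot,
                          replicate = rep(seq_len(replicates),
                                          length(sort(ratios))))
  attr(out, "truth") <- list(D0 = D0, dD = dD, Kd = Kd,
                             noise_sd = noise_sd, seed = seed)
  out
}

#' Simulate a differential HDX-MS experiment
#'
#' Tiles a protein with overlapping peptides, assigns each a saturating
#' exponential baseline uptake curve, and produces replicate-level apo and
#' bound state tables at the standard design (exposures 15/300/1800 s,
#' triplicate). Peptides overlapping an effect region (any residue overlap)
#' have the region's signed shift added to their bound-state mean.
#'
#' @param n_residues Protein length (default 200).
#' @param effect_regions List of `list(start, end, shift)` elements; shift
#'   in Da (positive = destabilised in the bound state).
#' @param timepoints Exposures in seconds (default `c(15, 300, 1800)`).
#' @param replicates Replicates per state/timepoint (default 3).
#' @param noise_sd Replicate noise SD in Da (default 0.05).
#' @param peptide_stride Start-to-start spacing of tiled peptides (default
#'   5).
#' @param peptide_length Range of peptide lengths, drawn uniformly (default
#'   `c(8, 16)`, within the usual 5-30 residue window).
#' @param protein Protein label (default `"SIM1"`).
#' @param seed RNG seed.
#' @return List with `apo` and `bound` (replicate-level data frames in the
#'   state-export dialect, see [write_state_table()]) and `truth_record`
#'   (peptide table with per-peptide true shift, plus all parameters).
#' @export
simulate_hdx_tables <- function(n_residues = 200, effect_regions = list(),
                                timepoints = c(15, 300, 1800),
                                replicates = 3, noise_sd = 0.05,
                                peptide_stride = 5,
                                peptide_length = c(8, 16),
                                protein = "SIM1", seed = 1) {
  for (r in effect_regions) {
    if (r$start < 1 || r$end > n_residues || r$start > r$end) {
      stop("effect region outside the tiled range")
    }
  }
  set.seed(seed)
  aa <- c("A", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "Q", "R",
          "S", "T", "V", "W", "Y")
  seqchars <- sample(aa, n_residues, replace = TRUE)
  starts <- seq(1, max(1, n_residues - peptide_length[1]),
                by = peptide_stride)
  len <- sample(seq(peptide_length[1], peptide_length[2]),
                length(starts), replace = TRUE)
  ends <- pmin(starts + len - 1, n_residues)
  if (max(ends) < n_residues) {  # close the tail of the tiling
    starts <- c(starts, n_residues - peptide_length[1] + 1)
    ends <- c(ends, n_residues)
  }
  covered <- logical(n_residues)
  for (k in seq_along(starts)) covered[starts[k]:ends[k]] <- TRUE
  if (!all(covered)) {
    warning("peptide tiling leaves ", sum(!covered),
            " residue(s) uncovered")
  }
  npep <- length(starts)
  plen <- ends - starts + 1
  # saturating-exponential exchange kinetics, qualitative only
  d_inf <- 0.7 * pmax(plen - 2, 1)
  rate <- 10^stats::runif(npep, -3, -1)
  shift <- numeric(npep)
  for (r in effect_regions) {
    hit <- starts <= r$end & ends >= r$start
    shift[hit] <- shift[hit] + r$shift
  }
  seqs <- vapply(seq_len(npep), function(k) {
    paste(seqchars[starts[k]:ends[k]], collapse = "")
  }, character(1))
  grid <- expand.grid(pep = seq_len(npep), t = timepoints,
                      rep = seq_len(replicates))
  base_mu <- d_inf[grid$pep] * (1 - exp(-rate[grid$pep] * grid$t))
  mk <- function(state, mu) {
    data.frame(
      protein = protein, sequence = seqs[grid$pep],
      start = starts[grid$pep], end = ends[grid$pep],
      state = state, exposure = grid$t, replicate = grid$rep,
      uptake = mu + stats::rnorm(nrow(grid), 0, noise_sd),
      stringsAsFactors = FALSE
    )
  }
  apo <- mk("apo", base_mu)
  bound <- mk("bound", base_mu + shift[grid$pep])
  list(
    apo = apo,
    bound = bound,
    truth_record = list(
      peptides = data.frame(sequence = seqs, start = starts, end = ends,
                            d_inf = d_inf, rate = rate, shift = shift,
                            stringsAsFactors = FALSE),
      effect_regions = effect_regions,
      timepoints = timepoints, replicates = replicates,
      noise_sd = noise_sd, seed = seed
    )
  )
}
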