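#' Default cross-link distance threshold
#'
#' 35 angstroms for a BS3 lysine-lysine cross-link measured between Calpha
#' positions: two lysine side chains (15), the BS3 spacer (10), plus 10 for
#' domain-level flexibility.
#' @export
XL_DEFAULT_BOUND <- 35

#' Construct a cross-link table
#'
#' A cross-link is an unordered pair of residue keys (protein/chain id plus
#' author residue number) carrying an upper-bound distance. Experimental BS3
#' links default to the 35 A threshold; pseudo-links encode covalent topology
#' with tighter bounds (see [build_restraints()]).
#'
#' @param protein1,residue1,protein2,residue2 Endpoint keys (vectors).
#' @param kind `"experimental"` or `"pseudo"`.
#' @param upper_bound Upper-bound distance(s) in \eqn{\AA}; defaults to 35
#'   for experimental links.
#' @param provenance Free-text provenance tag per link.
#' @return A `crosslink_table` data frame.
#' @export
crosslinks <- function(protein1, residue1, protein2, residue2,
                       kind = "experimental", upper_bound = NULL,
                       provenance = kind) {
  n <- length(protein1)
  if (is.null(upper_bound)) upper_bound <- XL_DEFAULT_BOUND
  out <- data.frame(
    protein1 = as.character(protein1), residue1 = as.integer(residue1),
    protein2 = as.character(protein2), residue2 = as.integer(residue2),
    kind = rep_len(as.character(kind), n),
    upper_bound = rep_len(as.numeric(upper_bound), n),
    provenance = rep_len(as.character(provenance), n),
    stringsAsFactors = FALSE
  )
  if (any(!is.finite(out$upper_bound) | out$upper_bound <= 0)) {
    stop("upper_bound must be positive and finite")
  }
  self <- out$protein1 == out$protein2 & out$residue1 == out$residue2
  if (any(self)) {
    stop("self cross-link rejected: ",
         paste0(out$protein1[self], ":", out$residue1[self], collapse = ", "))
  }
  class(out) <- c("crosslink_table", "data.frame")
  out
}

# Canonical unordered pair key.
xl_pair_key <- function(links) {
  a <- paste0(links$protein1, ":", links$residue1)
  b <- paste0(links$protein2, ":", links$residue2)
  ifelse(a < b, paste(a, b, sep = "--"), paste(b, a, sep = "--"))
}

#' Read a cross-link table from delimited text
#'
#' Accepts comma- or tab-delimited files with a header naming at least
#' `protein1, residue1, protein2, residue2` (an optional `score` column is
#' kept). Duplicate unordered pairs are collapsed to one link with a message.
#'
#' @param path File path.
#' @param kind,upper_bound Passed to [crosslinks()].
#' @return A `crosslink_table`.
#' @export
read_crosslinks <- function(path, kind = "experimental", upper_bound = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, strip.white = TRUE)
  need <- c("protein1", "residue1", "protein2", "residue2")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("cross-link table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(df) == 0L) {
    return(crosslinks(character(0), integer(0), character(0), integer(0),
                      kind = kind, upper_bound = upper_bound))
  }
  for (col in c("residue1", "residue2")) {
    num <- suppressWarnings(as.numeric(as.character(df[[col]])))
    v <- suppressWarnings(as.integer(num))
    bad <- which(is.na(v) | num != v)
    if (length(bad) > 0) {
      stop("non-integer ", col, " at row ", bad[1], " of ", path)
    }
    df[[col]] <- v
  }
  out <- crosslinks(df$protein1, df$residue1, df$protein2, df$residue2,
                    kind = kind, upper_bound = upper_bound)
  if ("score" %in% names(df)) out$score <- as.numeric(df$score)
  key <- xl_pair_key(out)
  if (anyDuplicated(key)) {
    ndup <- sum(duplicated(key))
    message("collapsed ", ndup, " duplicate cross-link pair(s)")
    out <- out[!duplicated(key), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Write a cross-link table as delimited text
#'
#' @param links A `crosslink_table`.
#' @param path Output path; `.tsv` extension selects tab separation.
#' @return `path`, invisibly.
#' @export
write_crosslinks <- function(links, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  utils::write.table(as.data.frame(links), path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Inter- and intra-protein cross-link counts
#'
#' @param links A `crosslink_table`.
#' @return Named integer vector with `inter`, `intra` and `total` counts.
#' @export
count_crosslinks <- function(links) {
  intra <- sum(links$protein1 == links$protein2)
  c(inter = nrow(links) - intra, intra = intra, total = nrow(links))
}

#' Euclidean Calpha/bead distances of cross-links on a model
#'
#' @param model `bead_model` or `xl_structure`.
#' @param links A `crosslink_table` (or any data frame with the four endpoint
#'   columns).
#' @param chain_map Optional named character vector translating table protein
#'   names to model chain ids (default: names used as-is).
#' @return Numeric vector of distances (\eqn{\AA}); `NA` where an endpoint is
#'   absent from the model (unmapped), never an error.
#' @export
crosslink_distance <- function(model, links, chain_map = NULL) {
  mapname <- function(p) {
    if (is.null(chain_map)) p
    else ifelse(p %in% names(chain_map), unname(chain_map[p]), p)
  }
  keys <- if (inherits(model, "bead_model")) {
    data.frame(chain = model$chain, resno = model$resno)
  } else {
    unique(model$atoms[, c("chain", "resno")])
  }
  kk <- paste(keys$chain, keys$resno)
  i1 <- match(paste(mapname(links$protein1), links$residue1), kk)
  i2 <- match(paste(mapname(links$protein2), links$residue2), kk)
  ok <- !is.na(i1) & !is.na(i2)
  d <- rep(NA_real_, nrow(links))
  if (any(ok)) {
    keysub <- function(i) keys[i, , drop = FALSE]
    a <- ca_coords(model, keysub(i1[ok]))
    b <- ca_coords(model, keysub(i2[ok]))
    d[ok] <- sqrt(rowSums((a - b)^2))
  }
  d
}

#' Classify cross-link satisfaction on a model
#'
#' A mapped link is satisfied when its measured Calpha/bead distance is less
#' than or equal to its upper bound (boundary inclusive, so a link at exactly
#' the published threshold passes); links with an endpoint absent from the
#' model are reported as unmapped, never dropped.
#'
#' @param model `bead_model` or `xl_structure`.
#' @param links A `crosslink_table`.
#' @param bound Optional single bound (\eqn{\AA}) overriding the per-link
#'   `upper_bound`.
#' @param inclusive Treat distance equal to the bound as satisfied
#'   (default `TRUE`).
#' @param chain_map See [crosslink_distance()].
#' @return A `satisfaction_report`: list with `links` (per-link data frame
#'   with `distance` and `status`), `counts` (satisfied/violated/unmapped),
#'   `max_distance` over mapped links (`NA` when none map) and `bound_used`.
#' @export
classify_satisfaction <- function(model, links, bound = NULL,
                                  inclusive = TRUE, chain_map = NULL) {
  d <- crosslink_distance(model, links, chain_map = chain_map)
  ub <- if (is.null(bound)) links$upper_bound else rep(bound, nrow(links))
  ok <- if (inclusive) d <= ub else d < ub
  status <- ifelse(is.na(d), "unmapped",
                   ifelse(ok, "satisfied", "violated"))
  per <- as.data.frame(links)
  per$distance <- d
  per$bound <- ub
  per$status <- status
  structure(
    list(
      links = per,
      counts = c(satisfied = sum(status == "satisfied"),
                 violated = sum(status == "violated"),
                 unmapped = sum(status == "unmapped")),
      max_distance = if (any(!is.na(d))) max(d, na.rm = TRUE) else NA_real_,
      bound_used = if (is.null(bound)) NA_real_ else bound
    ),
    class = "satisfaction_report"
  )
}

#' @export
print.satisfaction_report <- function(x, ...) {
  cat("<satisfaction_report> ", sum(x$counts), " cross-links: ",
      x$counts["satisfied"], " satisfied, ",
      x$counts["violated"], " violated, ",
      x$counts["unmapped"], " unmapped\n", sep = "")
  if (!is.na(x$max_distance)) {
    cat(sprintf("  max mapped distance: %.2f A\n", x$max_distance))
  }
  viol <- x$links[x$links$status == "violated", , drop = FALSE]
  if (nrow(viol) > 0) {
    cat("  violated:\n")
    for (k in seq_len(nrow(viol))) {
      cat(sprintf("    %s:%d -- %s:%d  %.2f A > %.1f A\n",
                  viol$protein1[k], viol$residue1[k],
                  viol$protein2[k], viol$residue2[k],
                  viol$distance[k], viol$bound[k]))
    }
  }
  invisible(x)
}

#' Two-conformer exclusive-satisfaction ensemble test
#'
#' Partitions cross-links by where they are satisfied at a common bound:
#' only in model A, only in model B, in both, or in neither. Links satisfied
#' exclusively in each of two conformers indicate that both conformations
#' are sampled in solution (an ensemble), since no single rigid model can
#' account for the whole link set.
#'
#' @param modelA,modelB Two conformers as `bead_model`/`xl_structure`.
#' @param links A `crosslink_table`.
#' @param bound Common distance bound (\eqn{\AA}), default 35.
#' @param chain_map See [crosslink_distance()].
#' @return List with index sets `only_in_A`, `only_in_B`, `both`, `neither`
#'   (row indices into `links`), `unmapped` (unmapped in either model, kept
#'   out of the partition), logical `ensemble_flag` (`TRUE` iff both
#'   exclusive sets are non-empty) and the per-model distances.
#' @export
exclusive_satisfaction <- function(modelA, modelB, links,
                                   bound = XL_DEFAULT_BOUND,
                                   chain_map = NULL) {
  dA <- crosslink_distance(modelA, links, chain_map = chain_map)
  dB <- crosslink_distance(modelB, links, chain_map = chain_map)
  unmapped <- which(is.na(dA) | is.na(dB))
  mapped <- setdiff(seq_len(nrow(links)), unmapped)
  sA <- dA[mapped] <= bound
  sB <- dB[mapped] <= bound
  only_in_A <- mapped[sA & !sB]
  only_in_B <- mapped[!sA & sB]
  list(
    only_in_A = only_in_A,
    only_in_B = only_in_B,
    both = mapped[sA & sB],
    neither = mapped[!sA & !sB],
    unmapped = unmapped,
    ensemble_flag = length(only_in_A) > 0 && length(only_in_B) > 0,
    distance_A = dA,
    distance_B = dB
  )
}

#' Assemble a restraint set from experimental links and topology pseudo-links
#'
#' Pseudo-links encode covalent topology that must hold regardless of the
#' experiment: chain continuity across a dissected domain boundary gets a 5 A
#' bound (mimicking a covalent bond), an isopeptide attachment gets 10 A
#' (7.5 A lysine side chain plus ~3 A glycine C-terminus), and
#' interface-integrity links holding a subcomplex together get a configurable
#' bound defaulting to the experimental-scale 35 A.
#'
#' @param experimental A `crosslink_table` of experimental links (bound 35 A
#'   unless already set).
#' @param topology List with optional elements `covalent`, `isopeptide`,
#'   `interface`, each a data frame with columns
#'   `protein1, residue1, protein2, residue2`.
#' @param interface_bound Bound for interface-integrity pseudo-links
#'   (\eqn{\AA}).
#' @param model Optional model; when given, every topology endpoint must be
#'   present in it (error otherwise).
#' @return A `crosslink_table` with a `provenance` column taking values
#'   `experimental`, `topology-pseudo`, `isopeptide-pseudo`.
#' @export
build_restraints <- function(experimental = NULL, topology = list(),
                             interface_bound = XL_DEFAULT_BOUND,
                             model = NULL) {
  parts <- list()
  if (!is.null(experimental) && nrow(experimental) > 0) {
    e <- experimental
    e$provenance <- "experimental"
    parts$experimental <- e
  }
  mk <- function(df, bound, prov) {
    crosslinks(df$protein1, df$residue1, df$protein2, df$residue2,
               kind = "pseudo", upper_bound = bound, provenance = prov)
  }
  if (!is.null(topology$covalent) && nrow(topology$covalent) > 0) {
    parts$covalent <- mk(topology$covalent, 5, "topology-pseudo")
  }
  if (!is.null(topology$isopeptide) && nrow(topology$isopeptide) > 0) {
    parts$isopeptide <- mk(topology$isopeptide, 10, "isopeptide-pseudo")
  }
  if (!is.null(topology$interface) && nrow(topology$interface) > 0) {
    parts$interface <- mk(topology$interface, interface_bound,
                          "topology-pseudo")
  }
  if (length(parts) == 0L) {
    return(crosslinks(character(0), integer(0), character(0), integer(0)))
  }
  cols <- c("protein1", "residue1", "protein2", "residue2",
            "kind", "upper_bound", "provenance")
  out <- do.call(rbind, lapply(parts, function(p) as.data.frame(p)[, cols]))
  rownames(out) <- NULL
  key <- xl_pair_key(out)
  if (anyDuplicated(key)) {
    conflicting <- any(tapply(out$upper_bound, key,
                              function(v) length(unique(v)) > 1))
    if (conflicting) {
      stop("duplicate restraint pair(s) with conflicting bounds")
    }
    out <- out[!duplicated(key), , drop = FALSE]
  }
  class(out) <- c("crosslink_table", "data.frame")
  if (!is.null(model)) {
    pseudo <- out$kind == "pseudo"
    if (any(pseudo)) {
      d <- crosslink_distance(model, out[pseudo, , drop = FALSE])
      if (anyNA(d)) {
        bad <- which(pseudo)[is.na(d)]
        stop("topology pseudo-link references residue(s) absent from model: ",
             paste0(out$protein1[bad], ":", out$residue1[bad], "--",
                    out$protein2[bad], ":", out$residue2[bad],
                    collapse = ", "))
      }
    }
  }
  out
}
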