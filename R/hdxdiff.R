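#' Read a state-export uptake table
#'
#' Reads the per-peptide, per-timepoint, per-replicate deuterium uptake
#' ("state") export dialect: delimited text with columns `Protein`,
#' `Sequence`, `Start`, `End`, `State`, `Exposure`, `Uptake` (and optionally
#' `Replicate`); column names are matched case-insensitively. Replicate rows
#' are aggregated to means and standard deviations.
#'
#' @param path File path (comma- or tab-delimited, header required).
#' @return An `uptake_table` data frame with columns `protein`, `sequence`,
#'   `start`, `end`, `state`, `exposure` (s), `n`, `mean`, `sd` (Da).
#' @export
read_state_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  names(df) <- tolower(names(df))
  need <- c("protein", "sequence", "start", "end", "state", "exposure",
            "uptake")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("state table missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(df) == 0L) {
    out <- data.frame(protein = character(0), sequence = character(0),
                      start = integer(0), end = integer(0),
                      state = character(0), exposure = numeric(0),
                      n = integer(0), mean = numeric(0), sd = numeric(0))
    class(out) <- c("uptake_table", "data.frame")
    return(out)
  }
  bounds <- unique(df[, c("protein", "sequence", "start", "end")])
  dup <- duplicated(bounds[, c("protein", "sequence")])
  if (any(dup)) {
    bad <- bounds[dup, , drop = FALSE][1, ]
    stop("inconsistent start/end for peptide ", bad$sequence,
         " of ", bad$protein)
  }
  if (any(df$start > df$end)) stop("peptide with start > end")
  key <- interaction(df$protein, df$sequence, df$start, df$end, df$state,
                     df$exposure, drop = TRUE)
  agg <- do.call(rbind, lapply(split(df, key), function(d) {
    data.frame(
      protein = d$protein[1], sequence = d$sequence[1],
      start = d$start[1], end = d$end[1], state = d$state[1],
      exposure = d$exposure[1], n = nrow(d),
      mean = mean(d$uptake),
      sd = if (nrow(d) > 1) stats::sd(d$uptake) else 0,
      stringsAsFactors = FALSE
    )
  }))
  agg <- agg[order(agg$state, agg$exposure, agg$start, agg$end), ,
             drop = FALSE]
  rownames(agg) <- NULL
  class(agg) <- c("uptake_table", "data.frame")
  agg
}

#' Write replicate-level uptake records in the state-export dialect
#'
#' @param df Data frame with columns `protein`, `sequence`, `start`, `end`,
#'   `state`, `exposure`, `replicate`, `uptake`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_state_table <- function(df, path) {
  out <- data.frame(
    Protein = df$protein, Sequence = df$sequence, Start = df$start,
    End = df$end, State = df$state, Exposure = df$exposure,
    Replicate = df$replicate, Uptake = df$uptake
  )
  utils::write.table(out, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

peptide_key <- function(x) {
  paste(x$protein, x$sequence, x$start, x$end, sep = "|")
}

#' Differential uptake between two states
#'
#' For each peptide/exposure present in both states computes
#' `delta = mean(bound) - mean(apo)` and the propagated
#' `sd_diff = sqrt(sd_bound^2 + sd_apo^2)`. Peptides covered in only one
#' state are reported in the `uncovered` attribute (lack of proteomic
#' coverage), never silently dropped.
#'
#' @param bound,apo `uptake_table`s for the two states (e.g. complex and
#'   apo).
#' @return A `hdx_diff` data frame with columns `protein`, `sequence`,
#'   `start`, `end`, `exposure`, `delta` (Da), `sd_diff` (Da), `n_bound`,
#'   `n_apo`, `sd_bound`, `sd_apo`; attribute `uncovered`.
#' @export
compute_diff <- function(bound, apo) {
  kb <- paste(peptide_key(bound), bound$exposure)
  ka <- paste(peptide_key(apo), apo$exposure)
  shared <- intersect(kb, ka)
  if (length(shared) == 0L) stop("no shared peptide/exposure pairs")
  ib <- match(shared, kb)
  ia <- match(shared, ka)
  out <- data.frame(
    protein = bound$protein[ib], sequence = bound$sequence[ib],
    start = bound$start[ib], end = bound$end[ib],
    exposure = bound$exposure[ib],
    delta = bound$mean[ib] - apo$mean[ia],
    sd_diff = sqrt(bound$sd[ib]^2 + apo$sd[ia]^2),
    n_bound = bound$n[ib], n_apo = apo$n[ia],
    sd_bound = bound$sd[ib], sd_apo = apo$sd[ia],
    stringsAsFactors = FALSE
  )
  out <- out[order(out$exposure, out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "uncovered") <- sort(unique(c(
    setdiff(unique(peptide_key(bound)), unique(peptide_key(apo))),
    setdiff(unique(peptide_key(apo)), unique(peptide_key(bound)))
  )))
  class(out) <- c("hdx_diff", "data.frame")
  out
}

#' Blanket confidence-interval significance threshold
#'
#' Computes, per exposure timepoint, the deuterium-uptake threshold DU such
#' that the interval `0 +/- DU` is the two-sided confidence interval of a
#' null uptake difference at the given level, pooling replicate variances
#' across all peptides of the timepoint:
#' `DU = q * pooled_SD * sqrt(1/n1 + 1/n2)` with `q` the two-sided normal
#' quantile (`q = 2.326` at the 98% level) and `pooled_SD^2` the mean of
#' the per-peptide replicate variances of both states.
#'
#' @param diffs A [compute_diff()] result.
#' @param level Confidence level in (0, 1), default 0.98.
#' @param quantile `"normal"` (default) or `"t"` (Student quantile at
#'   `n1 + n2 - 2` degrees of freedom).
#' @return A `significance_threshold` data frame: one row per exposure with
#'   `exposure`, `DU` (Da), `pooled_sd`, `n1`, `n2`; attribute `level`.
#' @export
confidence_threshold <- function(diffs, level = 0.98,
                                 quantile = c("normal", "t")) {
  quantile <- match.arg(quantile)
  if (!is.numeric(level) || level <= 0 || level >= 1) {
    stop("confidence level must lie in (0, 1)")
  }
  out <- do.call(rbind, lapply(split(diffs, diffs$exposure), function(d) {
    if (nrow(d) < 2) {
      stop("need at least 2 peptides per timepoint (exposure ",
           d$exposure[1], ")")
    }
    pooled_var <- mean(c(d$sd_bound^2, d$sd_apo^2))
    n1 <- round(stats::median(d$n_bound))
    n2 <- round(stats::median(d$n_apo))
    q <- if (quantile == "normal") {
      stats::qnorm(1 - (1 - level) / 2)
    } else {
      stats::qt(1 - (1 - level) / 2, df = n1 + n2 - 2)
    }
    data.frame(exposure = d$exposure[1],
               DU = q * sqrt(pooled_var) * sqrt(1 / n1 + 1 / n2),
               pooled_sd = sqrt(pooled_var), n1 = n1, n2 = n2)
  }))
  rownames(out) <- NULL
  attr(out, "level") <- level
  class(out) <- c("significance_threshold", "data.frame")
  out
}

#' Classify differential uptake records (Woods-plot semantics)
#'
#' A record is `stabilised` when `delta < -DU`, `destabilised` when
#' `delta > +DU`, and `non-significant` otherwise. The comparison is strict:
#' a delta exactly on the interval boundary is inside `0 +/- DU` and hence
#' null-consistent.
#'
#' @param diffs A [compute_diff()] result.
#' @param threshold A [confidence_threshold()] result covering every
#'   exposure present in `diffs`.
#' @return `diffs` with columns `DU` and `class` added, plus a
#'   `class_counts` attribute (per-exposure class tallies).
#' @export
classify_peptides <- function(diffs, threshold) {
  idx <- match(diffs$exposure, threshold$exposure)
  if (anyNA(idx)) {
    stop("threshold missing for exposure(s): ",
         paste(unique(diffs$exposure[is.na(idx)]), collapse = ", "))
  }
  DU <- threshold$DU[idx]
  cls <- ifelse(diffs$delta > DU, "destabilised",
                ifelse(diffs$delta < -DU, "stabilised", "non-significant"))
  out <- diffs
  out$DU <- DU
  out$class <- cls
  attr(out, "class_counts") <- table(exposure = out$exposure,
                                     class = out$class)
  class(out) <- c("hdx_classified", class(diffs))
  out
}

#' Aggregate per-timepoint classes to one call per peptide
#'
#' A peptide is called stabilised/destabilised when significant in at least
#' one timepoint (an interpretation of per-protein summary colouring;
#' conflicting directions across timepoints are reported as `"mixed"`).
#'
#' @param classified A [classify_peptides()] result.
#' @return Data frame with one row per peptide and a `class` column in
#'   `stabilised`, `destabilised`, `mixed`, `non-significant`.
#' @export
aggregate_classes <- function(classified) {
  key <- peptide_key(classified)
  out <- do.call(rbind, lapply(split(classified, key), function(d) {
    sig <- unique(d$class[d$class != "non-significant"])
    cls <- if (length(sig) == 0) "non-significant"
           else if (length(sig) == 1) sig else "mixed"
    data.frame(protein = d$protein[1], sequence = d$sequence[1],
               start = d$start[1], end = d$end[1], class = cls,
               stringsAsFactors = FALSE)
  }))
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export classified differences in Woods-plot format
#'
#' One row per peptide-timepoint with `start`, `end`, `delta`, `DU` and
#' `class`, sorted by start position — ready for segment plotting.
#'
#' @param classified A [classify_peptides()] result.
#' @param path Optional output path; when given, the table is written as
#'   comma-delimited text.
#' @return The Woods table, invisibly when `path` is given.
#' @export
woods_export <- function(classified, path = NULL) {
  out <- classified[order(classified$start, classified$end,
                          classified$exposure),
                    c("protein", "sequence", "start", "end", "exposure",
                      "delta", "sd_diff", "DU", "class")]
  rownames(out) <- NULL
  if (!is.null(path)) {
    utils::write.table(out, path, sep = ",", row.names = FALSE,
                       quote = FALSE)
    return(invisible(out))
  }
  out
}

#' Woods plot of classified differential uptake
#'
#' Horizontal segments per peptide (residue span vs uptake difference) with
#' the blanket confidence band; stabilised segments blue, destabilised red,
#' non-significant grey.
#'
#' @param classified A [classify_peptides()] result.
#' @param exposure Which exposure to plot (default: first present).
#' @param ... Passed to [graphics::plot()].
#' @return The plotted subset, invisibly.
#' @export
plot_woods <- function(classified, exposure = NULL, ...) {
  if (is.null(exposure)) exposure <- sort(unique(classified$exposure))[1]
  d <- classified[classified$exposure == exposure, , drop = FALSE]
  if (nrow(d) == 0) stop("no records at exposure ", exposure)
  du <- d$DU[1]
  ylim <- range(c(d$delta, du, -du)) * 1.15
  graphics::plot(NA, xlim = range(c(d$start, d$end)), ylim = ylim,
                 xlab = "residue", ylab = expression(Delta * "uptake (Da)"),
                 main = sprintf("Woods plot, %gs exposure", exposure), ...)
  graphics::rect(graphics::par("usr")[1], -du, graphics::par("usr")[2], du,
                 col = grDevices::adjustcolor("grey80", 0.5), border = NA)
  graphics::abline(h = 0, lty = 2)
  col <- c(stabilised = "blue", destabilised = "red",
           `non-significant` = "grey40")[d$class]
  graphics::segments(d$start, d$delta, d$end, d$delta, col = col, lwd = 2)
  invisible(d)
}
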