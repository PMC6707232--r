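#' Predicted deuterium uptake under the exact 1:1 binding model
#'
#' Solves the 1:1 mass-balance quadratic for the complex concentration
#' `[PL]` (smaller root, so ligand depletion is respected — essential when
#' the receptor concentration is comparable to Kd, as in titrations run at
#' 250 nM receptor against nanomolar affinities), takes the bound fraction
#' `f = [PL]/P_tot`, and returns `D0 + dD * f`.
#'
#' @param L_tot Total ligand concentration(s), molar. Vectorised.
#' @param P_tot Total receptor concentration, molar (> 0).
#' @param Ka Association constant, 1/molar (`Kd = 1/Ka`).
#' @param D0 Uptake at zero ligand, Da.
#' @param dD Maximum uptake change at saturation, Da (negative for the
#'   protection typically seen at an interface).
#' @return Predicted uptake in Da, same length as `L_tot`.
#' @export
binding_isotherm <- function(L_tot, P_tot, Ka, D0, dD) {
  if (any(L_tot < 0) || P_tot <= 0) {
    stop("concentrations must be non-negative (P_tot > 0)")
  }
  if (Ka <= 0) stop("Ka must be positive")
  f <- bound_fraction(L_tot, P_tot, Ka)
  D0 + dD * f
}

# Bound fraction [PL]/P_tot from the exact mass-balance quadratic
#   Ka*PL^2 - (Ka*(P+L) + 1)*PL + Ka*P*L = 0
# taking the physically admissible (smaller) root in the cancellation-free
# conjugate form 2PL/(b + sqrt(b^2 - 4PL)), accurate also at weak binding.
bound_fraction <- function(L_tot, P_tot, Ka) {
  b <- P_tot + L_tot + 1 / Ka
  disc <- pmax(0, b^2 - 4 * P_tot * L_tot)
  PL <- 2 * P_tot * L_tot / (b + sqrt(disc))
  pmin(pmax(PL / P_tot, 0), 1)
}

#' Construct a titration series
#'
#' Replicate-level deuterium uptake as a function of total ligand
#' concentration at a fixed receptor concentration and a single labelling
#' time — the design of a PLIMSTEX experiment.
#'
#' @param ligand_conc Total ligand concentration per observation, molar.
#' @param uptake Observed uptake per observation, Da.
#' @param P_tot Total receptor concentration, molar.
#' @param replicate Optional replicate index per observation.
#' @param peptide,start,end Optional peptide annotation.
#' @param labeling_time_s Optional labelling time, seconds.
#' @return A `titration_series` data frame (attributes `P_tot`, `peptide`,
#'   `start`, `end`, `labeling_time_s`).
#' @export
titration_series <- function(ligand_conc, uptake, P_tot,
                             replicate = NULL, peptide = NA_character_,
                             start = NA_integer_, end = NA_integer_,
                             labeling_time_s = NA_real_) {
  stopifnot(length(ligand_conc) == length(uptake))
  if (any(ligand_conc < 0)) stop("ligand concentrations must be non-negative")
  if (P_tot <= 0) stop("P_tot must be positive")
  if (any(!is.finite(uptake))) stop("uptake values must be finite")
  out <- data.frame(
    ligand_conc = as.numeric(ligand_conc),
    replicate = if (is.null(replicate)) {
      stats::ave(seq_along(uptake), ligand_conc, FUN = seq_along)
    } else as.integer(replicate),
    uptake = as.numeric(uptake)
  )
  out <- out[order(out$ligand_conc, out$replicate), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "P_tot") <- P_tot
  attr(out, "peptide") <- peptide
  attr(out, "start") <- start
  attr(out, "end") <- end
  attr(out, "labeling_time_s") <- labeling_time_s
  class(out) <- c("titration_series", "data.frame")
  out
}

# Pooled within-concentration replicate SD of a series (0 when every
# concentration has a single replicate).
pooled_replicate_sd <- function(series) {
  v <- tapply(series$uptake, series$ligand_conc, stats::var)
  v <- v[!is.na(v)]
  if (length(v) == 0) 0 else sqrt(mean(v))
}

#' Fit a titration series with the 1:1 binding model
#'
#' Nonlinear least squares over the three parameters of
#' [binding_isotherm()]: `D0`, `dD` and `Ka` (log-parameterised, bounded to
#' `[1e3, 1e12]` 1/M). Initial guesses are `D0` = mean uptake at zero
#' ligand, `dD` = uptake change to the highest ligand concentration, and
#' `Kd` = the middle titrated concentration. Fitting is unweighted by
#' default, matching a plain root-mean-square residual objective;
#' inverse-variance weighting by replicate spread is available.
#'
#' @param series A [titration_series()] with at least 4 distinct ligand
#'   concentrations.
#' @param weighted Use inverse-variance per-concentration weights
#'   (default `FALSE`).
#' @return A `plimstex_fit` with components `coefficients` (`D0`, `dD`,
#'   `Ka`), `Kd` (`1/Ka`; `NA` when unidentifiable), `rms_residual` (Da),
#'   `converged`, `identifiable`, `series` and the underlying `nls` object.
#'   Non-convergence is reported through the flag, not an error.
#' @export
fit_plimstex <- function(series, weighted = FALSE) {
  stopifnot(inherits(series, "titration_series"))
  concs <- sort(unique(series$ligand_conc))
  if (length(concs) < 4) {
    stop("need at least 4 distinct ligand concentrations, got ",
         length(concs))
  }
  P_tot <- attr(series, "P_tot")
  mean_at <- function(L) mean(series$uptake[series$ligand_conc == L])
  D0_0 <- if (0 %in% concs) mean_at(0) else mean_at(concs[1])
  dD_0 <- mean_at(max(concs)) - D0_0
  if (dD_0 == 0) dD_0 <- -1e-3
  kd_mid <- stats::median(concs[concs > 0])
  logKa_0 <- min(max(log10(1 / kd_mid), 3), 12)
  wts <- if (weighted) {
    v <- tapply(series$uptake, series$ligand_conc, stats::var)
    v[is.na(v) | v == 0] <- max(v, 1e-12, na.rm = TRUE)
    1 / as.numeric(v[as.character(series$ligand_conc)])
  } else {
    rep(1, nrow(series))
  }
  dat <- data.frame(L = series$ligand_conc, y = series$uptake, w = wts)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ D0 + dD * bound_fraction(L, P_tot, 10^logKa),
      data = dat, weights = dat$w,
      start = list(D0 = D0_0, dD = dD_0, logKa = logKa_0),
      lower = c(-Inf, -Inf, 3), upper = c(Inf, Inf, 12),
      control = minpack.lm::nls.lm.control(maxiter = 200)
    ),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    out <- list(coefficients = c(D0 = D0_0, dD = dD_0, Ka = 10^logKa_0),
                Kd = NA_real_, rms_residual = NA_real_,
                converged = FALSE, identifiable = FALSE,
                message = conditionMessage(fit),
                series = series, nls = NULL)
    class(out) <- "plimstex_fit"
    return(out)
  }
  cf <- stats::coef(fit)
  Ka <- unname(10^cf["logKa"])
  pred <- binding_isotherm(series$ligand_conc, P_tot, Ka,
                           cf["D0"], cf["dD"])
  rmsr <- sqrt(mean((series$uptake - pred)^2))
  pool_sd <- pooled_replicate_sd(series)
  at_bound <- cf["logKa"] <= 3 + 1e-6 || cf["logKa"] >= 12 - 1e-6
  identifiable <- abs(cf["dD"]) >= 2 * pool_sd && !at_bound
  out <- list(
    coefficients = c(D0 = unname(cf["D0"]), dD = unname(cf["dD"]), Ka = Ka),
    Kd = if (identifiable) 1 / Ka else NA_real_,
    Kd_raw = 1 / Ka,
    rms_residual = rmsr,
    converged = TRUE,
    identifiable = unname(identifiable),
    ka_at_bound = unname(at_bound),
    pooled_sd = pool_sd,
    series = series,
    nls = fit
  )
  class(out) <- "plimstex_fit"
  out
}

#' Root-mean-square residual of a binding fit
#'
#' `sqrt(mean((observed - predicted)^2))` over all titration points, the
#' standard quality measure for a PLIMSTEX fit.
#'
#' @param series A [titration_series()].
#' @param fit A converged `plimstex_fit` (or a named vector/list with `D0`,
#'   `dD`, `Ka`).
#' @return RMS residual in Da.
#' @export
fit_quality <- function(series, fit) {
  cf <- if (inherits(fit, "plimstex_fit")) {
    if (!fit$converged) stop("fit did not converge")
    fit$coefficients
  } else {
    unlist(fit)[c("D0", "dD", "Ka")]
  }
  pred <- binding_isotherm(series$ligand_conc, attr(series, "P_tot"),
                           cf[["Ka"]], cf[["D0"]], cf[["dD"]])
  sqrt(mean((series$uptake - pred)^2))
}

#' @export
coef.plimstex_fit <- function(object, ...) object$coefficients

#' @export
predict.plimstex_fit <- function(object, newdata = NULL, ...) {
  L <- if (is.null(newdata)) {
    object$series$ligand_conc
  } else if (is.data.frame(newdata)) {
    newdata$ligand_conc
  } else {
    as.numeric(newdata)
  }
  cf <- object$coefficients
  binding_isotherm(L, attr(object$series, "P_tot"),
                   cf[["Ka"]], cf[["D0"]], cf[["dD"]])
}

#' @export
residuals.plimstex_fit <- function(object, ...) {
  object$series$uptake - predict(object)
}

#' @export
fitted.plimstex_fit <- function(object, ...) predict(object)

#' @export
print.plimstex_fit <- function(x, ...) {
  pep <- attr(x$series, "peptide")
  cat("<plimstex_fit>", if (!is.na(pep)) paste0(" peptide ", pep), "\n",
      sep = "")
  if (!x$converged) {
    cat("  fit did not converge: ", x$message, "\n", sep = "")
    return(invisible(x))
  }
  cf <- x$coefficients
  cat(sprintf("  D0 = %.3f Da, dD = %.3f Da, Ka = %.3g 1/M\n",
              cf[["D0"]], cf[["dD"]], cf[["Ka"]]))
  if (is.na(x$Kd)) {
    cat(sprintf("  Kd undetermined (not identifiable%s)\n",
                if (isTRUE(x$ka_at_bound)) "; Ka at optimiser bound" else ""))
  } else {
    cat(sprintf("  Kd = %.1f nM\n", 1e9 * x$Kd))
  }
  cat(sprintf("  rms residual = %.4f Da over %d points\n",
              x$rms_residual, nrow(x$series)))
  invisible(x)
}

#' @export
summary.plimstex_fit <- function(object, ...) {
  out <- list(
    coefficients = object$coefficients,
    Kd_nM = 1e9 * object$Kd,
    rms_residual = object$rms_residual,
    converged = object$converged,
    identifiable = object$identifiable,
    n_points = nrow(object$series),
    n_concentrations = length(unique(object$series$ligand_conc))
  )
  class(out) <- "summary.plimstex_fit"
  out
}

#' @export
print.summary.plimstex_fit <- function(x, ...) {
  cat("1:1 binding-isotherm fit (PLIMSTEX)\n")
  cat(sprintf("  %d points over %d ligand concentrations\n",
              x$n_points, x$n_concentrations))
  cat(sprintf("  D0 %.3f Da  dD %.3f Da  Ka %.3g 1/M  Kd %.1f nM\n",
              x$coefficients[["D0"]], x$coefficients[["dD"]],
              x$coefficients[["Ka"]], x$Kd_nM))
  cat(sprintf("  rms residual %.4f Da; converged %s; identifiable %s\n",
              x$rms_residual, x$converged, x$identifiable))
  invisible(x)
}

#' @export
plot.plimstex_fit <- function(x, ...) {
  s <- x$series
  graphics::plot(1e9 * s$ligand_conc, s$uptake, pch = 16,
                 xlab = "ligand concentration (nM)",
                 ylab = "deuterium uptake (Da)",
                 main = "PLIMSTEX titration", ...)
  if (x$converged) {
    L <- seq(0, max(s$ligand_conc), length.out = 200)
    graphics::lines(1e9 * L, predict(x, L))
  }
  invisible(x)
}

#' Read a titration table
#'
#' Delimited text with columns `peptide, start, end, receptor_conc_M,
#' ligand_conc_M, replicate, uptake_Da` (comma or tab separated).
#'
#' @param path File path.
#' @return List of [titration_series()], one per peptide.
#' @export
read_titration <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- readLines(path, n = 1L)
  sep <- if (grepl("\t", hdr)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need <- c("peptide", "start", "end", "receptor_conc_M", "ligand_conc_M",
            "replicate", "uptake_Da")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("titration table missing column(s): ", paste(miss, collapse = ", "))
  }
  out <- lapply(split(df, df$peptide), function(d) {
    titration_series(d$ligand_conc_M, d$uptake_Da,
                     P_tot = d$receptor_conc_M[1],
                     replicate = d$replicate,
                     peptide = d$peptide[1],
                     start = d$start[1], end = d$end[1])
  })
  out[order(vapply(out, function(s) attr(s, "start"), 1L))]
}

#' Write a titration series (or list of them) as a delimited table
#'
#' Inverse of [read_titration()].
#'
#' @param series A [titration_series()] or list of them.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_titration <- function(series, path) {
  if (inherits(series, "titration_series")) series <- list(series)
  rows <- lapply(series, function(s) {
    data.frame(
      peptide = attr(s, "peptide"), start = attr(s, "start"),
      end = attr(s, "end"), receptor_conc_M = attr(s, "P_tot"),
      ligand_conc_M = s$ligand_conc, replicate = s$replicate,
      uptake_Da = s$uptake, stringsAsFactors = FALSE
    )
  })
  utils::write.table(do.call(rbind, rows), path, sep = ",",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Fit every peptide of a titration table and summarise the Kd range
#'
#' Per-region affinities are reported as a min-max Kd interval across the
#' peptides with an identifiable fit, mirroring the range-style reporting
#' used for local binding interfaces.
#'
#' @param series_list List of [titration_series()] (e.g. from
#'   [read_titration()]).
#' @param ... Passed to [fit_plimstex()].
#' @return List with `fits` (per-peptide `plimstex_fit`s), `table` (one row
#'   per peptide: coefficients, Kd in nM, rms residual, flags) and
#'   `kd_range_nM` (min-max over identifiable fits).
#' @export
fit_plimstex_table <- function(series_list, ...) {
  fits <- lapply(series_list, fit_plimstex, ...)
  tab <- do.call(rbind, lapply(fits, function(f) {
    data.frame(
      peptide = attr(f$series, "peptide"),
      start = attr(f$series, "start"), end = attr(f$series, "end"),
      D0 = f$coefficients[["D0"]], dD = f$coefficients[["dD"]],
      Ka = f$coefficients[["Ka"]], Kd_nM = 1e9 * f$Kd,
      rms_residual = f$rms_residual,
      converged = f$converged, identifiable = f$identifiable,
      stringsAsFactors = FALSE
    )
  }))
  rownames(tab) <- NULL
  kds <- tab$Kd_nM[tab$identifiable & !is.na(tab$Kd_nM)]
  list(
    fits = fits,
    table = tab,
    kd_range_nM = if (length(kds) > 0) range(kds) else c(NA_real_, NA_real_)
  )
}
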