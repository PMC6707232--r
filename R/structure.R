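#' Read an atomic model from PDB or mmCIF
#'
#' Reads all chains, residues and atoms of the first model in the file,
#' preserving author residue numbering. Waters are dropped and only the first
#' alternate-location conformer of each atom is kept.
#'
#' @param path Path to a coordinate file.
#' @param format One of `"auto"`, `"pdb"`, `"mmcif"`. With `"auto"` the format
#'   is taken from the file extension (`.cif`/`.mmcif` vs anything else).
#' @return An object of class `xl_structure`: a list with components
#'   \describe{
#'     \item{atoms}{data frame with columns `chain`, `resno`, `resname`,
#'       `elety` (atom name), `element`, `x`, `y`, `z` (\eqn{\AA}).}
#'     \item{subunits}{data frame with columns `chain`, `name`, one row per
#'       chain in file order.}
#'   }
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("file not found: ", path)
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  atoms <- switch(format,
    pdb   = read_atoms_pdb(path),
    mmcif = read_atoms_mmcif(path)
  )
  if (nrow(atoms) == 0L) {
    stop("no atoms found in ", path)
  }
  new_structure(atoms)
}

new_structure <- function(atoms) {
  stopifnot(all(c("chain", "resno", "resname", "elety", "element",
                  "x", "y", "z") %in% names(atoms)))
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite coordinates in structure")
  }
  rownames(atoms) <- NULL
  chains <- unique(atoms$chain)
  structure(
    list(
      atoms = atoms,
      subunits = data.frame(chain = chains, name = chains,
                            stringsAsFactors = FALSE)
    ),
    class = "xl_structure"
  )
}

WATER_RESNAMES <- c("HOH", "WAT", "DOD", "H2O")

read_atoms_pdb <- function(path) {
  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = FALSE, verbose = FALSE),
    error = function(e) stop("failed to parse PDB file ", path, ": ",
                             conditionMessage(e))
  )
  at <- pdb$atom
  keep <- !(at$resid %in% WATER_RESNAMES)
  # first alternate location only
  keep <- keep & (is.na(at$alt) | at$alt %in% c("", "A"))
  at <- at[keep, , drop = FALSE]
  data.frame(
    chain = ifelse(is.na(at$chain), " ", at$chain),
    resno = as.integer(at$resno),
    resname = at$resid,
    elety = at$elety,
    element = ifelse(is.na(at$elesy), "", at$elesy),
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE
  )
}

# Minimal mmCIF atom_site reader (loop_ records only; first model, first
# altloc, waters removed). Handles quoted values and values spanning the
# standard one-line-per-record layout.
read_atoms_mmcif <- function(path) {
  lines <- readLines(path, warn = FALSE)
  i <- 1L
  n <- length(lines)
  fields <- character(0)
  rows <- list()
  while (i <= n) {
    if (grepl("^\\s*loop_\\s*$", lines[i])) {
      j <- i + 1L
      hdr <- character(0)
      while (j <= n && grepl("^\\s*_", lines[j])) {
        hdr <- c(hdr, sub("^\\s*(\\S+).*$", "\\1", lines[j]))
        j <- j + 1L
      }
      if (length(hdr) > 0 && all(startsWith(hdr, "_atom_site."))) {
        fields <- sub("^_atom_site\\.", "", hdr)
        while (j <= n && !grepl("^\\s*(loop_|_|#|data_)", lines[j]) &&
               nzchar(trimws(lines[j]))) {
          rows[[length(rows) + 1L]] <- cif_tokens(lines[j])
          j <- j + 1L
        }
        i <- j
        break
      }
      i <- j
    } else {
      i <- i + 1L
    }
  }
  if (length(fields) == 0L || length(rows) == 0L) {
    stop("no _atom_site loop found in mmCIF file ", path)
  }
  bad <- which(vapply(rows, length, 1L) != length(fields))
  if (length(bad) > 0) {
    stop("mmCIF atom_site row ", bad[1],
         " has wrong field count in ", path)
  }
  m <- do.call(rbind, rows)
  colnames(m) <- fields
  getf <- function(primary, fallback = NULL) {
    if (primary %in% fields) return(m[, primary])
    if (!is.null(fallback) && fallback %in% fields) return(m[, fallback])
    rep(NA_character_, nrow(m))
  }
  grp <- getf("group_PDB")
  model <- getf("pdbx_PDB_model_num")
  alt <- getf("label_alt_id")
  resname <- getf("auth_comp_id", "label_comp_id")
  keep <- rep(TRUE, nrow(m))
  if (!all(is.na(grp))) keep <- keep & grp %in% c("ATOM", "HETATM")
  if (!all(is.na(model))) keep <- keep & model == model[1]
  keep <- keep & (is.na(alt) | alt %in% c(".", "", "A"))
  keep <- keep & !(resname %in% WATER_RESNAMES)
  resno <- suppressWarnings(as.integer(getf("auth_seq_id", "label_seq_id")))
  if (any(is.na(resno[keep]))) {
    stop("non-integer residue number in mmCIF atom_site of ", path)
  }
  xyz <- suppressWarnings(cbind(as.numeric(getf("Cartn_x")),
                                as.numeric(getf("Cartn_y")),
                                as.numeric(getf("Cartn_z"))))
  if (any(is.na(xyz[keep, ]))) {
    stop("non-numeric coordinate in mmCIF atom_site of ", path)
  }
  data.frame(
    chain = getf("auth_asym_id", "label_asym_id")[keep],
    resno = resno[keep],
    resname = resname[keep],
    elety = getf("auth_atom_id", "label_atom_id")[keep],
    element = getf("type_symbol")[keep],
    x = xyz[keep, 1], y = xyz[keep, 2], z = xyz[keep, 3],
    stringsAsFactors = FALSE
  )
}

cif_tokens <- function(line) {
  out <- character(0)
  rest <- trimws(line)
  while (nzchar(rest)) {
    ch <- substr(rest, 1, 1)
    if (ch == "'" || ch == '"') {
      close <- regexpr(paste0(ch, "(\\s|$)"), substr(rest, 2, nchar(rest)))
      if (close < 0) close <- nchar(rest)
      out <- c(out, substr(rest, 2, close))
      rest <- trimws(substr(rest, close + 2, nchar(rest)))
    } else {
      sp <- regexpr("\\s", rest)
      if (sp < 0) {
        out <- c(out, rest)
        rest <- ""
      } else {
        out <- c(out, substr(rest, 1, sp - 1))
        rest <- trimws(substr(rest, sp, nchar(rest)))
      }
    }
  }
  out
}

#' Write a structure or bead model as a PDB file
#'
#' Bead models are written with one CA pseudo-atom per bead so they can be
#' inspected in any molecular viewer and round-trip through
#' [read_structure()].
#'
#' @param x An `xl_structure` or `bead_model`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(x, path) {
  if (inherits(x, "bead_model")) {
    at <- data.frame(
      chain = x$chain, resno = x$resno, resname = "ALA", elety = "CA",
      element = "C", x = x$x, y = x$y, z = x$z, stringsAsFactors = FALSE
    )
  } else if (inherits(x, "xl_structure")) {
    at <- x$atoms
  } else {
    stop("cannot write object of class ", paste(class(x), collapse = "/"))
  }
  xyz <- as.numeric(t(as.matrix(at[, c("x", "y", "z")])))
  bio3d::write.pdb(
    file = path, xyz = xyz,
    type = rep("ATOM", nrow(at)),
    resno = at$resno, resid = at$resname, chain = at$chain,
    elety = at$elety, eleno = seq_len(nrow(at))
  )
  invisible(path)
}

#' @export
print.xl_structure <- function(x, ...) {
  nres <- nrow(unique(x$atoms[, c("chain", "resno")]))
  cat("<xl_structure> ", length(x$subunits$chain), " chain(s), ",
      nres, " residues, ", nrow(x$atoms), " atoms\n", sep = "")
  cat("  chains:", paste(x$subunits$chain, collapse = ", "), "\n")
  invisible(x)
}

#' Parse a residue selection string
#'
#' Selections use the form `"CHAIN"` (whole chain) or `"CHAIN:start-end"`
#' (inclusive author-numbering range), and may be combined as a character
#' vector or comma-separated string.
#'
#' @param sel Selection string(s).
#' @return Data frame with columns `chain`, `from`, `to` (`NA` = whole chain).
#' @export
parse_selection <- function(sel) {
  parts <- unlist(strsplit(sel, ","), use.names = FALSE)
  parts <- trimws(parts[nzchar(trimws(parts))])
  if (length(parts) == 0L) stop("empty selection")
  out <- lapply(parts, function(p) {
    if (grepl(":", p, fixed = TRUE)) {
      bits <- strsplit(p, ":", fixed = TRUE)[[1]]
      if (length(bits) != 2L || !grepl("^-?[0-9]+--?[0-9]+$|^-?[0-9]+$", bits[2]))
        stop("malformed selection: ", p)
      rng <- as.integer(strsplit(bits[2], "-(?=[0-9])", perl = TRUE)[[1]])
      if (length(rng) == 1L) rng <- c(rng, rng)
      if (rng[1] > rng[2]) stop("selection range reversed: ", p)
      data.frame(chain = bits[1], from = rng[1], to = rng[2],
                 stringsAsFactors = FALSE)
    } else {
      data.frame(chain = p, from = NA_integer_, to = NA_integer_,
                 stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, out)
}

# Resolve a selection to (chain, resno) keys present in a structure or bead
# model, in chain/resno order.
resolve_selection <- function(x, sel) {
  res <- if (inherits(x, "bead_model")) {
    unique(data.frame(chain = x$chain, resno = x$resno,
                      stringsAsFactors = FALSE))
  } else {
    unique(x$atoms[, c("chain", "resno")])
  }
  spec <- parse_selection(sel)
  keep <- rep(FALSE, nrow(res))
  for (k in seq_len(nrow(spec))) {
    hit <- res$chain == spec$chain[k]
    if (!is.na(spec$from[k])) {
      hit <- hit & res$resno >= spec$from[k] & res$resno <= spec$to[k]
    }
    keep <- keep | hit
  }
  out <- res[keep, , drop = FALSE]
  out[order(out$chain, out$resno), , drop = FALSE]
}

# Calpha coordinates (one row per residue) for the given (chain, resno) keys.
# Falls back to the residue centroid when no CA atom exists.
ca_coords <- function(x, keys) {
  if (inherits(x, "bead_model")) {
    idx <- match(paste(keys$chain, keys$resno),
                 paste(x$chain, x$resno))
    if (anyNA(idx)) {
      miss <- keys[is.na(idx), , drop = FALSE]
      stop("residues absent from model: ",
           paste(paste0(miss$chain, ":", miss$resno), collapse = ", "))
    }
    return(as.matrix(x[idx, c("x", "y", "z")]))
  }
  at <- x$atoms
  out <- matrix(NA_real_, nrow(keys), 3)
  akey <- paste(at$chain, at$resno)
  ca <- at$elety == "CA" & !(at$element %in% c("CA", "Ca"))
  for (k in seq_len(nrow(keys))) {
    kk <- paste(keys$chain[k], keys$resno[k])
    hit <- which(akey == kk & ca)
    if (length(hit) >= 1L) {
      out[k, ] <- as.numeric(at[hit[1], c("x", "y", "z")])
    } else {
      hit <- which(akey == kk)
      if (length(hit) == 0L) {
        stop("residue absent from model: ", kk)
      }
      out[k, ] <- colMeans(at[hit, c("x", "y", "z")])
    }
  }
  out
}
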