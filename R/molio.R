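# Molecular structure and coupling-table I/O: standard XYZ plus the
# champs-scalar-coupling CSV dialect (structures.csv / train.csv / test.csv /
# submission). Atom indices in records are 0-based on disk and in record
# tables (the dialect's convention); R-level geometry functions take 1-based
# indices.

#' Construct a molecule
#'
#' @param name character identifier.
#' @param elements character vector of element symbols (subset of
#'   [GAANN_ELEMENTS]).
#' @param coords numeric matrix `n x 3` of Cartesian coordinates in Angstrom.
#' @return An object of class `"molecule"`: a list with `name`, `elements`,
#'   `coords`.
#' @export
molecule <- function(name, elements, coords) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (length(elements) < 1L) stop("molecule must contain at least one atom")
  if (nrow(coords) != length(elements) || ncol(coords) != 3L) {
    stop("coords must be a length(elements) x 3 matrix")
  }
  bad <- !elements %in% GAANN_ELEMENTS
  if (any(bad)) {
    stop("unsupported element symbol(s): ", paste(unique(elements[bad]), collapse = ", "))
  }
  if (anyDuplicated(coords)) {
    stop("molecule '", name, "' has two atoms at identical coordinates")
  }
  dimnames(coords) <- list(NULL, c("x", "y", "z"))
  structure(list(name = as.character(name), elements = as.character(elements),
                 coords = coords),
            class = "molecule")
}

#' @export
print.molecule <- function(x, ...) {
  cat("<molecule> ", x$name, ": ", length(x$elements), " atoms (",
      paste(names(table(x$elements)), table(x$elements), sep = "", collapse = " "),
      ")\n", sep = "")
  invisible(x)
}

#' Read a molecule from a standard XYZ file
#'
#' Line 1 is the atom count, line 2 a comment (used as the molecule name when
#' non-empty), then one `element x y z` line per atom (Angstrom).
#'
#' @param path file path.
#' @return A [molecule()].
#' @export
read_xyz <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 2L) stop("XYZ file too short: ", path)
  n <- suppressWarnings(as.integer(trimws(lines[1L])))
  if (is.na(n) || n < 1L) stop("invalid atom count on line 1 of ", path)
  body <- lines[-(1:2)]
  nonblank <- which(nzchar(trimws(body)))
  if (length(nonblank) != n) {
    stop("XYZ file declares ", n, " atoms but lists ", length(nonblank),
         " atom lines: ", path)
  }
  elements <- character(n)
  coords <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    ln <- nonblank[i]
    tok <- strsplit(trimws(body[ln]), "[[:space:]]+")[[1L]]
    if (length(tok) < 4L) stop("malformed atom line ", ln + 2L, " in ", path)
    if (!tok[1L] %in% GAANN_ELEMENTS) {
      stop("unknown element symbol '", tok[1L], "' on line ", ln + 2L, " of ", path)
    }
    xyz <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(xyz)) stop("non-numeric coordinate on line ", ln + 2L, " of ", path)
    elements[i] <- tok[1L]
    coords[i, ] <- xyz
  }
  name <- trimws(lines[2L])
  if (!nzchar(name)) name <- sub("\\.xyz$", "", basename(path))
  molecule(name, elements, coords)
}

#' Write a molecule to a standard XYZ file
#'
#' @param mol a [molecule()].
#' @param path output file path.
#' @param comment comment line (defaults to the molecule name).
#' @return `path`, invisibly.
#' @export
write_xyz <- function(mol, path, comment = mol$name) {
  lines <- c(as.character(length(mol$elements)), comment,
             sprintf("%s %.10f %.10f %.10f", mol$elements,
                     mol$coords[, 1L], mol$coords[, 2L], mol$coords[, 3L]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a structures table (champs dialect)
#'
#' Expects columns `molecule_name, atom_index, atom, x, y, z` with 0-based
#' `atom_index` dense per molecule.
#'
#' @param path CSV file path.
#' @return Named list of [molecule()] objects.
#' @export
read_structures_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("molecule_name", "atom_index", "atom", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("structures file missing column(s): ", paste(miss, collapse = ", "))
  out <- lapply(split(df, df$molecule_name), function(d) {
    d <- d[order(d$atom_index), , drop = FALSE]
    if (anyDuplicated(d$atom_index)) {
      stop("duplicate atom_index in molecule ", d$molecule_name[1L])
    }
    if (!identical(as.integer(d$atom_index), seq_len(nrow(d)) - 1L)) {
      stop("atom_index of molecule ", d$molecule_name[1L],
           " is not dense from 0")
    }
    molecule(d$molecule_name[1L], d$atom, cbind(d$x, d$y, d$z))
  })
  out[order(names(out))]
}

#' Write a structures table (champs dialect)
#'
#' @param molecules named list of [molecule()] objects.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_structures_csv <- function(molecules, path) {
  rows <- lapply(molecules, function(m) {
    data.frame(molecule_name = m$name,
               atom_index = seq_along(m$elements) - 1L,
               atom = m$elements,
               x = m$coords[, 1L], y = m$coords[, 2L], z = m$coords[, 3L],
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a coupling table (champs dialect)
#'
#' Expects columns `molecule_name, atom_index_0, atom_index_1, type` and,
#' when `labelled = TRUE`, `scalar_coupling_constant` (Hz). Type strings are
#' canonicalised so the H element letter comes first.
#'
#' @param path CSV file path.
#' @param labelled require the label column?
#' @return data.frame of coupling records with columns `id, molecule_name,
#'   atom_index_0, atom_index_1, type, scc` (`scc` is `NA` when unlabelled).
#' @export
read_couplings_csv <- function(path, labelled = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("molecule_name", "atom_index_0", "atom_index_1", "type")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("coupling file missing column(s): ", paste(miss, collapse = ", "))
  if (labelled && !"scalar_coupling_constant" %in% names(df)) {
    stop("labelled = TRUE but column scalar_coupling_constant is missing")
  }
  if (nrow(df) == 0L) {
    return(data.frame(id = integer(), molecule_name = character(),
                      atom_index_0 = integer(), atom_index_1 = integer(),
                      type = character(), scc = numeric(),
                      stringsAsFactors = FALSE))
  }
  parsed <- parse_coupling_type(df$type)
  scc <- if ("scalar_coupling_constant" %in% names(df)) {
    as.numeric(df$scalar_coupling_constant)
  } else NA_real_
  data.frame(id = if ("id" %in% names(df)) df$id else seq_len(nrow(df)) - 1L,
             molecule_name = df$molecule_name,
             atom_index_0 = as.integer(df$atom_index_0),
             atom_index_1 = as.integer(df$atom_index_1),
             type = parsed$type,
             scc = scc,
             stringsAsFactors = FALSE)
}

#' Write predictions in submission shape
#'
#' @param records coupling record data.frame (provides the row ids).
#' @param predictions numeric vector, one prediction per record (Hz).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_predictions_csv <- function(records, predictions, path) {
  if (nrow(records) != length(predictions)) {
    stop("got ", length(predictions), " predictions for ", nrow(records), " records")
  }
  df <- data.frame(id = records$id, scalar_coupling_constant = predictions)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Assemble and validate a coupling dataset
#'
#' Checks every record against its molecule: the molecule exists, atom
#' indices are in range and distinct, and the elements at the two indices
#' match the type's element letters. Records are canonicalised so the
#' hydrogen atom sits at `atom_index_0` (for heteronuclear types).
#'
#' @param molecules named list of [molecule()] objects (names may be taken
#'   from the molecules themselves).
#' @param records coupling record data.frame as from [read_couplings_csv()].
#' @return An object of class `"scc_dataset"`: list with `molecules` and
#'   `records`.
#' @export
scc_dataset <- function(molecules, records) {
  if (is.null(names(molecules)) || any(!nzchar(names(molecules)))) {
    names(molecules) <- vapply(molecules, function(m) m$name, "")
  }
  unknown <- setdiff(unique(records$molecule_name), names(molecules))
  if (length(unknown)) {
    stop("record(s) reference unknown molecule(s): ", paste(unknown, collapse = ", "))
  }
  if (nrow(records)) {
    parsed <- parse_coupling_type(records$type)
    n_atoms <- vapply(molecules, function(m) length(m$elements), 1L)
    na <- n_atoms[records$molecule_name]
    i0 <- records$atom_index_0; i1 <- records$atom_index_1
    if (any(i0 < 0L | i1 < 0L | i0 >= na | i1 >= na)) {
      stop("coupling record atom index out of range")
    }
    if (any(i0 == i1)) stop("coupling record with identical atom indices")
    el0 <- mapply(function(m, i) molecules[[m]]$elements[i + 1L],
                  records$molecule_name, i0)
    el1 <- mapply(function(m, i) molecules[[m]]$elements[i + 1L],
                  records$molecule_name, i1)
    ok_fwd <- el0 == parsed$el0 & el1 == parsed$el1
    ok_rev <- el0 == parsed$el1 & el1 == parsed$el0
    if (any(!(ok_fwd | ok_rev))) {
      stop("coupling record element mismatch with type string (",
           sum(!(ok_fwd | ok_rev)), " record(s))")
    }
    flip <- !ok_fwd & ok_rev
    if (any(flip)) {
      tmp <- records$atom_index_0[flip]
      records$atom_index_0[flip] <- records$atom_index_1[flip]
      records$atom_index_1[flip] <- tmp
    }
    records$type <- parsed$type
  }
  structure(list(molecules = molecules, records = records),
            class = "scc_dataset")
}

#' @export
print.scc_dataset <- function(x, ...) {
  cat("<scc_dataset> ", length(x$molecules), " molecules, ",
      nrow(x$records), " coupling records (",
      sum(!is.na(x$records$scc)), " labelled)\n", sep = "")
  if (nrow(x$records)) {
    print(table(x$records$type))
  }
  invisible(x)
}
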