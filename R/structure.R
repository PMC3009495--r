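#' Parsed protein structure
#'
#' An \code{structure3d} holds the coordinate content of a PDB entry as a
#' flat atom table: one row per atom per model. Residues are identified by
#' author numbering (chain id, residue number, insertion code), the
#' convention used in all user-facing input and output of this package.
#'
#' @param id character label for the structure (e.g. a PDB id or file stem).
#' @param atoms data.frame with columns \code{model} (integer, 1-based),
#'   \code{chain}, \code{resno} (integer author number), \code{insert}
#'   (insertion code, \code{""} when absent), \code{resid} (3-letter
#'   amino-acid type), \code{elety} (atom name, e.g. \code{"CA"}),
#'   \code{alt} (alternate-location id, \code{""} when absent), \code{occ}
#'   (occupancy), \code{x}, \code{y}, \code{z} (orthogonal coordinates in
#'   Angstrom) and \code{het} (logical, TRUE for heterogen records).
#'
#' @return an object of class \code{"structure3d"}.
#' @export
new_structure <- function(id, atoms) {
  required <- c("model", "chain", "resno", "insert", "resid", "elety",
                "alt", "occ", "x", "y", "z", "het")
  miss <- setdiff(required, names(atoms))
  if (length(miss) > 0)
    stop("atoms table lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0)
    stop("no coordinates: atoms table is empty")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz)))
    stop("non-finite coordinates in atoms table")
  atoms$model  <- as.integer(atoms$model)
  atoms$resno  <- as.integer(atoms$resno)
  atoms$chain  <- as.character(atoms$chain)
  atoms$insert <- as.character(atoms$insert)
  atoms$resid  <- as.character(atoms$resid)
  atoms$elety  <- as.character(atoms$elety)
  atoms$alt    <- as.character(atoms$alt)
  rownames(atoms) <- NULL
  # residue keys must be unique within a model: the same (chain, resno,
  # insert) may not carry two different residue types
  key <- paste(atoms$model, atoms$chain, atoms$resno, atoms$insert, sep = "\r")
  tab <- tapply(atoms$resid, key, function(r) length(unique(r)))
  if (any(tab > 1))
    stop("duplicate residue key with conflicting residue type in model")
  structure(list(id = id, atoms = atoms), class = "structure3d")
}

#' Number of models in a structure
#' @param x an \code{structure3d}.
#' @return integer count of coordinate models.
#' @export
n_models <- function(x) {
  stopifnot(inherits(x, "structure3d"))
  length(unique(x$atoms$model))
}

#' Chain identifiers present in a structure
#' @param x an \code{structure3d}.
#' @param model model number (default 1).
#' @return character vector of chain ids in order of appearance.
#' @export
chain_ids <- function(x, model = 1L) {
  stopifnot(inherits(x, "structure3d"))
  unique(x$atoms$chain[x$atoms$model == model])
}

#' @export
print.structure3d <- function(x, ...) {
  a <- x$atoms[x$atoms$model == x$atoms$model[1], ]
  nres <- nrow(unique(a[, c("chain", "resno", "insert")]))
  cat(sprintf("<structure '%s': %d model(s), %d chain(s), %d residues, %d atoms/model>\n",
              x$id, n_models(x), length(unique(a$chain)), nres, nrow(a)))
  invisible(x)
}

# fixed-width coordinate fields of an ATOM/HETATM record (wwPDB v3.3)
.coord_fields <- function(line) {
  c(substr(line, 31, 38), substr(line, 39, 46), substr(line, 47, 54))
}

#' Parse PDB-format text into a structure
#'
#' Reads ATOM/HETATM/MODEL/ENDMDL records (wwPDB v3.3 fixed-width layout).
#' Waters (HOH) are always excluded; selenomethionine (MSE) is remapped to
#' MET and treated as a standard residue; other heterogens are retained and
#' flagged. All alternate locations are retained here -- they are resolved
#' at site-selection time (see \code{\link{select_sites}}).
#'
#' @param lines character vector of PDB-format lines.
#' @param id label for the structure.
#' @return an \code{\link{new_structure}} object of class \code{"structure3d"}.
#' @seealso \code{\link{read_structure}} to read from a file.
#' @export
parse_structure <- function(lines, id = "structure") {
  rec <- substr(lines, 1, 6)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  if (!any(is_atom))
    stop("no coordinates: input contains no ATOM/HETATM records")
  # record-level validation with line numbers; bio3d is permissive here
  for (ln in which(is_atom)) {
    fld <- suppressWarnings(as.numeric(.coord_fields(lines[ln])))
    if (any(is.na(fld)) || any(!is.finite(fld)))
      stop(sprintf("malformed coordinate field at line %d", ln))
  }
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(lines, tmp)
  pdb <- bio3d::read.pdb(tmp, multi = TRUE, rm.alt = FALSE, verbose = FALSE)
  at <- pdb$atom
  nmod <- nrow(pdb$xyz)
  blank <- function(v) ifelse(is.na(v), "", as.character(v))
  base <- data.frame(
    chain  = blank(at$chain),
    resno  = as.integer(at$resno),
    insert = blank(at$insert),
    resid  = as.character(at$resid),
    elety  = as.character(at$elety),
    alt    = blank(at$alt),
    occ    = ifelse(is.na(at$o), 1, at$o),
    het    = at$type == "HETATM",
    stringsAsFactors = FALSE
  )
  # MSE is a routine crystallographic substitution: treat as methionine
  mse <- base$resid == "MSE"
  base$resid[mse] <- "MET"
  base$het[mse] <- FALSE
  keep <- base$resid != "HOH"
  rows <- vector("list", nmod)
  for (m in seq_len(nmod)) {
    co <- matrix(pdb$xyz[m, ], ncol = 3, byrow = TRUE)
    am <- base
    am$model <- m
    am$x <- co[, 1]; am$y <- co[, 2]; am$z <- co[, 3]
    rows[[m]] <- am[keep, ]
  }
  atoms <- do.call(rbind, rows)
  new_structure(id, atoms)
}

#' Read a structure from a PDB file
#'
#' @param file path to a PDB-format coordinate file.
#' @param id label; defaults to the file name without extension.
#' @return an object of class \code{"structure3d"}.
#' @export
read_structure <- function(file, id = NULL) {
  if (!file.exists(file)) stop("file not found: ", file)
  if (is.null(id)) id <- sub("\\.(pdb|ent)$", "", basename(file))
  parse_structure(readLines(file, warn = FALSE), id = id)
}

#' Write a structure to a PDB file
#'
#' Emits fixed-width ATOM/HETATM records (and MODEL/ENDMDL blocks for
#' multi-model structures) via bio3d. Coordinates keep the PDB's three
#' decimal places; author residue numbering and insertion codes are
#' preserved verbatim.
#'
#' @param x an \code{structure3d}.
#' @param file destination path.
#' @return \code{file}, invisibly.
#' @export
write_structure <- function(x, file) {
  stopifnot(inherits(x, "structure3d"))
  models <- sort(unique(x$atoms$model))
  none <- function(v) ifelse(v == "", NA_character_, v)
  lines <- character(0)
  for (m in models) {
    a <- x$atoms[x$atoms$model == m, ]
    tmp <- tempfile(fileext = ".pdb")
    bio3d::write.pdb(
      file = tmp,
      xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
      type = ifelse(a$het, "HETATM", "ATOM"),
      resno = a$resno, resid = a$resid, chain = a$chain,
      insert = none(a$insert), alt = none(a$alt),
      elety = a$elety, o = a$occ, b = rep(0, nrow(a))
    )
    body <- readLines(tmp, warn = FALSE)
    unlink(tmp)
    body <- body[substr(body, 1, 6) %in% c("ATOM  ", "HETATM", "TER   ", "TER")]
    if (length(models) > 1)
      body <- c(sprintf("MODEL     %4d", m), body, "ENDMDL")
    lines <- c(lines, body)
  }
  writeLines(c(lines, "END"), file)
  invisible(file)
}

#' Fetch a PDB entry from the wwPDB (network helper)
#'
#' Thin convenience wrapper used by the command-line interface and by
#' worked examples; the core computation never requires network access.
#'
#' @param id 4-character PDB identifier.
#' @param destfile destination path (default: \code{<id>.pdb} in a tempdir).
#' @param base_url download URL prefix.
#' @param quiet passed to \code{\link[utils]{download.file}}.
#' @return path to the downloaded file.
#' @export
fetch_pdb <- function(id, destfile = NULL,
                      base_url = "https://files.rcsb.org/download/",
                      quiet = TRUE) {
  id <- toupper(id)
  if (!grepl("^[0-9][A-Za-z0-9]{3}$", id))
    stop("not a valid PDB id: ", id)
  if (is.null(destfile)) destfile <- file.path(tempdir(), paste0(id, ".pdb"))
  url <- paste0(base_url, id, ".pdb")
  status <- tryCatch(
    utils::download.file(url, destfile, quiet = quiet, mode = "wb"),
    error = function(e) stop("could not fetch ", id, ": ", conditionMessage(e)),
    warning = function(w) stop("could not fetch ", id, ": ", conditionMessage(w))
  )
  if (!identical(status, 0L) || !file.exists(destfile))
    stop("could not fetch ", id)
  destfile
}
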