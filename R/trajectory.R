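## Trajectory container and file I/O.
##
## A trajectory is an atom table plus a frames x atoms x 3 coordinate
## array (nm), per-frame orthorhombic box edges (nm) and a frame spacing
## dt (ps). Atom indexing is 0-based in the `index` column (and only
## there); residue numbering is 1-based as in PDB.

MOL_CLASSES <- c("protein", "solvent", "ion")

#' Atom table constructor
#'
#' @param name Atom names (short strings).
#' @param resid 1-based residue numbers.
#' @param resname Residue names.
#' @param mol_id Integer molecule ids (unique per molecule).
#' @param mol_class One of "protein", "solvent", "ion" per atom.
#' @param element Element symbols; inferred from `name` when missing.
#' @return A data.frame with a 0-based `index` column.
#' @export
atom_table <- function(name, resid, resname, mol_id, mol_class,
                       element = NULL) {
  n <- length(name)
  if (is.null(element)) element <- infer_element(name)
  df <- data.frame(index = seq_len(n) - 1L,
                   name = as.character(name),
                   element = as.character(element),
                   resid = as.integer(resid),
                   resname = as.character(resname),
                   mol_id = as.integer(mol_id),
                   mol_class = as.character(mol_class),
                   stringsAsFactors = FALSE)
  validate_atoms(df)
  df
}

infer_element <- function(name) {
  el <- sub("^[0-9]*", "", name)
  el <- sub("([A-Za-z]).*", "\\1", el)
  toupper(el)
}

validate_atoms <- function(atoms) {
  stopifnot(is.data.frame(atoms))
  need <- c("index", "name", "element", "resid", "resname", "mol_id",
            "mol_class")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(atoms$index)) stop("atom indices must be unique")
  if (any(atoms$resid < 1L)) stop("residue numbers must be >= 1")
  bad <- setdiff(unique(atoms$mol_class), MOL_CLASSES)
  if (length(bad)) stop("unknown mol_class: ", paste(bad, collapse = ", "))
  invisible(atoms)
}

#' Trajectory constructor
#'
#' @param atoms Atom table (see [atom_table()]).
#' @param coords Numeric array, frames x atoms x 3, in nm.
#' @param box Orthorhombic box edge lengths in nm: either length-3 vector
#'   (constant box) or a frames x 3 matrix.
#' @param dt Frame spacing in ps (> 0).
#' @param origin_time Time of the first frame in ps.
#' @return An object of class `solv_trajectory`.
#' @export
trajectory <- function(atoms, coords, box, dt, origin_time = 0) {
  validate_atoms(atoms)
  if (length(dim(coords)) != 3L || dim(coords)[3] != 3L)
    stop("coords must be a frames x atoms x 3 array")
  if (dim(coords)[2] != nrow(atoms))
    stop("coords atom dimension (", dim(coords)[2],
         ") does not match atom table (", nrow(atoms), ")")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  nf <- dim(coords)[1]
  if (is.null(dim(box))) box <- matrix(box, nrow = nf, ncol = 3, byrow = TRUE)
  if (nrow(box) != nf || ncol(box) != 3L)
    stop("box must be a length-3 vector or frames x 3 matrix")
  if (any(!is.finite(box)) || any(box <= 0))
    stop("box edge lengths must be finite and > 0")
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("dt must be a single positive number (ps)")
  structure(list(atoms = atoms, coords = coords, box = box,
                 dt = dt, origin_time = origin_time),
            class = "solv_trajectory")
}

#' @export
print.solv_trajectory <- function(x, ...) {
  cat("<solv_trajectory> ", n_frames(x), " frames x ", n_atoms(x),
      " atoms, dt = ", x$dt, " ps\n", sep = "")
  cat("  molecules: ",
      paste(sprintf("%s=%d", names(table(x$atoms$mol_class[!duplicated(x$atoms$mol_id)])),
                    table(x$atoms$mol_class[!duplicated(x$atoms$mol_id)])),
            collapse = ", "), "\n", sep = "")
  cat("  box (frame 1): ", paste(signif(x$box[1, ], 5), collapse = " x "),
      " nm\n", sep = "")
  invisible(x)
}

#' @export
n_frames <- function(traj) UseMethod("n_frames")
#' @export
n_frames.solv_trajectory <- function(traj) dim(traj$coords)[1]
#' @export
n_atoms <- function(traj) UseMethod("n_atoms")
#' @export
n_atoms.solv_trajectory <- function(traj) dim(traj$coords)[2]

#' Frame times of a trajectory (ps)
#' @param traj A `solv_trajectory`.
#' @return Numeric vector of frame times.
#' @export
frame_times <- function(traj) {
  traj$origin_time + (seq_len(n_frames(traj)) - 1) * traj$dt
}

## ---------------------------------------------------------------------
## Minimum image

#' Minimum-image displacement under orthorhombic periodic boundaries
#'
#' Returns b - a wrapped into the primary image, each component in
#' (-box/2, box/2].
#'
#' @param a,b Positions (length-3 vectors or n x 3 matrices), nm.
#' @param box Box edge lengths (length-3 vector or n x 3 matrix), nm.
#' @return Displacement(s), same shape as the inputs.
#' @export
#' @examples
#' min_image_displacement(c(0, 0, 0), c(0.9, 0, 0), c(1, 1, 1)) # -0.1 0 0
min_image_displacement <- function(a, b, box) {
  a <- if (is.null(dim(a))) matrix(a, ncol = 3) else as.matrix(a)
  b <- if (is.null(dim(b))) matrix(b, ncol = 3) else as.matrix(b)
  n <- max(nrow(a), nrow(b))
  if (nrow(a) == 1L && n > 1L) a <- a[rep(1L, n), , drop = FALSE]
  if (nrow(b) == 1L && n > 1L) b <- b[rep(1L, n), , drop = FALSE]
  if (!all(is.finite(a)) || !all(is.finite(b)) || !all(is.finite(box)))
    stop("non-finite input to min_image_displacement")
  bx <- if (is.null(dim(box))) matrix(box, n, 3, byrow = TRUE) else as.matrix(box)
  if (any(bx <= 0)) stop("box edge lengths must be > 0")
  d <- b - a
  w <- d - bx * round(d / bx)
  flip <- w <= -bx / 2  # round() ties can land on -L/2; convention is (-L/2, L/2]
  w[flip] <- w[flip] + bx[flip]
  if (n == 1L) drop(w) else w
}

#' Unwrap periodic coordinates along the time axis
#'
#' Reconstructs continuous particle paths from wrapped coordinates by
#' min-imaging successive frame-to-frame increments and accumulating
#' them. Valid while no particle moves more than half a box edge per
#' frame.
#'
#' @param coords frames x atoms x 3 wrapped coordinate array (nm).
#' @param box frames x 3 (or length-3) box edges (nm).
#' @return Unwrapped array of the same shape.
#' @export
unwrap_coords <- function(coords, box) {
  nf <- dim(coords)[1]
  if (nf < 2L) return(coords)
  if (is.null(dim(box))) box <- matrix(box, nf, 3, byrow = TRUE)
  out <- coords
  for (k in 1:3) {
    d <- coords[-1, , k, drop = FALSE] - coords[-nf, , k, drop = FALSE]
    d <- array(d, dim = dim(d)[1:2])
    L <- box[-1, k]
    d <- d - L * round(d / L)       # L recycles down columns (frames)
    out[, , k] <- apply(rbind(coords[1, , k], d), 2, cumsum)
  }
  out
}

## ---------------------------------------------------------------------
## Plain-text fixture trajectory format
##
## header:  "solvshell-traj 1", natoms, dt, origin_time
## atom table (one line per atom), then per frame: "frame Lx Ly Lz"
## followed by natoms coordinate lines written with 9 decimals.

#' Write a trajectory in the package's plain-text fixture format
#'
#' A deliberately simple line-oriented format so that tests and examples
#' never require binary trajectory readers. Coordinates are written with
#' nine decimals; a written file re-read with [read_traj_text()] and
#' written again is byte-identical.
#'
#' @param traj A `solv_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_traj_text <- function(traj, path) {
  con <- file(path, "w")
  on.exit(close(con))
  a <- traj$atoms
  writeLines(c("solvshell-traj 1",
               paste("natoms", nrow(a)),
               paste("dt", format(traj$dt, digits = 12)),
               paste("origin_time", format(traj$origin_time, digits = 12)),
               "atoms"), con)
  writeLines(sprintf("%d %s %s %d %s %d %s", a$index, a$name, a$element,
                     a$resid, a$resname, a$mol_id, a$mol_class), con)
  for (f in seq_len(n_frames(traj))) {
    writeLines(paste("frame", paste(sprintf("%.9f", traj$box[f, ]),
                                    collapse = " ")), con)
    xyz <- traj$coords[f, , , drop = FALSE]
    writeLines(sprintf("%.9f %.9f %.9f", xyz[1, , 1], xyz[1, , 2],
                       xyz[1, , 3]), con)
  }
  invisible(path)
}

#' Read a plain-text fixture trajectory
#'
#' @param path File written by [write_traj_text()].
#' @return A `solv_trajectory`.
#' @export
read_traj_text <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  if (!startsWith(lines[1], "solvshell-traj"))
    stop("not a solvshell fixture trajectory: ", path)
  nat <- as.integer(strsplit(lines[2], " ")[[1]][2])
  dt <- as.numeric(strsplit(lines[3], " ")[[1]][2])
  ot <- as.numeric(strsplit(lines[4], " ")[[1]][2])
  stopifnot(lines[5] == "atoms")
  at <- utils::read.table(text = lines[6:(5 + nat)],
                          col.names = c("index", "name", "element", "resid",
                                        "resname", "mol_id", "mol_class"),
                          colClasses = c("integer", "character", "character",
                                         "integer", "character", "integer",
                                         "character"))
  body <- lines[-(1:(5 + nat))]
  per <- nat + 1L
  nf <- length(body) %/% per
  if (nf * per != length(body)) stop("truncated fixture trajectory: ", path)
  box <- matrix(0, nf, 3)
  coords <- array(0, dim = c(nf, nat, 3))
  for (f in seq_len(nf)) {
    blk <- body[((f - 1L) * per + 1L):(f * per)]
    box[f, ] <- as.numeric(strsplit(blk[1], " ")[[1]][2:4])
    m <- matrix(scan(text = blk[-1], quiet = TRUE), ncol = 3, byrow = TRUE)
    coords[f, , ] <- m
  }
  trajectory(at, coords, box, dt, ot)
}

## ---------------------------------------------------------------------
## Structure/trajectory readers (PDB via bio3d, GRO parsed here, DCD via
## bio3d). Source units: PDB/DCD Angstrom -> /10; GRO already nm.

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "HID", "HIE", "HIP", "ILE", "LEU", "LYS", "MET",
                 "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL")

#' Default residue-name classification rules
#'
#' Maps residue names to molecule classes: standard amino acids to
#' protein, common water/organic-solvent residue names to solvent, and
#' monatomic ions to ion. Extend or override via the
#' `classification_rules` argument of [read_system()].
#'
#' @return Named character vector (resname -> mol_class).
#' @export
default_classification_rules <- function() {
  c(setNames(rep("protein", length(STANDARD_AA)), STANDARD_AA),
    SOL = "solvent", HOH = "solvent", WAT = "solvent", TIP3 = "solvent",
    SPC = "solvent", ACN = "solvent", MCN = "solvent", BUT = "solvent",
    NBU = "solvent", TBU = "solvent", CHX = "solvent", CYH = "solvent",
    SLV = "solvent",
    "NA" = "ion", CL = "ion", SOD = "ion", CLA = "ion", K = "ion")
}

classify_atoms <- function(resname, rules) {
  cls <- unname(rules[resname])
  if (anyNA(cls)) {
    unknown <- sort(unique(resname[is.na(cls)]))
    stop("no classification rule for residue name(s): ",
         paste(unknown, collapse = ", "))
  }
  cls
}

assign_mol_ids <- function(resid, resname, mol_class) {
  ## protein atoms form one molecule; each solvent/ion residue is its own
  key <- ifelse(mol_class == "protein", "PROT",
                paste(resname, resid, cumsum(c(TRUE, diff(resid) != 0))))
  as.integer(factor(key, levels = unique(key)))
}

parse_gro <- function(path) {
  lines <- readLines(path)
  frames <- list(); boxes <- list(); at <- NULL
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    nat <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(nat)) stop("malformed GRO file (atom count): ", path)
    rows <- lines[(i + 2L):(i + 1L + nat)]
    resid <- as.integer(substr(rows, 1, 5))
    resname <- trimws(substr(rows, 6, 10))
    name <- trimws(substr(rows, 11, 15))
    xyz <- cbind(as.numeric(substr(rows, 21, 28)),
                 as.numeric(substr(rows, 29, 36)),
                 as.numeric(substr(rows, 37, 44)))
    bvec <- scan(text = lines[i + 2L + nat], quiet = TRUE)
    if (length(bvec) > 3 && any(abs(bvec[4:length(bvec)]) > 1e-9))
      stop("triclinic boxes are not supported (GRO off-diagonal elements)")
    if (is.null(at)) at <- data.frame(resid = resid, resname = resname,
                                      name = name, stringsAsFactors = FALSE)
    frames[[length(frames) + 1L]] <- xyz
    boxes[[length(boxes) + 1L]] <- bvec[1:3]
    i <- i + 3L + nat
  }
  nf <- length(frames)
  coords <- array(0, dim = c(nf, nrow(at), 3))
  for (f in seq_len(nf)) coords[f, , ] <- frames[[f]]
  list(atoms = at, coords = coords, box = do.call(rbind, boxes))
}

parse_pdb <- function(path) {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  xyz <- cbind(a$x, a$y, a$z) / 10          # Angstrom -> nm
  box <- NULL
  cry <- grep("^CRYST1", readLines(path), value = TRUE)
  if (length(cry)) {
    v <- scan(text = substr(cry[1], 7, 54), quiet = TRUE)
    if (length(v) >= 6 && all(is.finite(v[1:3])) && all(v[1:3] > 0)) {
      if (any(abs(v[4:6] - 90) > 1e-6))
        stop("triclinic boxes are not supported (CRYST1 angles != 90)")
      box <- v[1:3] / 10
    }
  }
  list(atoms = data.frame(resid = a$resno, resname = trimws(a$resid),
                          name = trimws(a$elety), stringsAsFactors = FALSE),
       coords = array(xyz, dim = c(1, nrow(a), 3)),
       box = box)
}

#' Read a structure plus optional coordinate trajectory
#'
#' Reads a topology (PDB or GRO; the GRO file may itself hold multiple
#' frames) and, optionally, a separate coordinate trajectory (DCD or the
#' package's plain-text fixture format). Coordinates are stored in nm and
#' times in ps regardless of the source format. Molecules are grouped by
#' residue; solvent and ion molecules are identified through
#' `classification_rules`.
#'
#' XTC input is not supported and raises a structured error; convert to
#' DCD or multi-frame GRO upstream.
#'
#' @param topology_path PDB or GRO file.
#' @param trajectory_path Optional DCD / multi-frame GRO / fixture file.
#' @param classification_rules Named character vector resname ->
#'   mol_class; defaults to [default_classification_rules()].
#' @param dt Frame spacing in ps for formats that do not carry one
#'   (PDB/GRO/DCD). Default 1.
#' @param box Fallback box edges (nm) when the source carries none.
#' @return A `solv_trajectory`.
#' @export
read_system <- function(topology_path, trajectory_path = NULL,
                        classification_rules = default_classification_rules(),
                        dt = 1, box = NULL) {
  if (!file.exists(topology_path)) stop("no such file: ", topology_path)
  ext <- tolower(tools::file_ext(topology_path))
  top <- switch(ext,
                gro = parse_gro(topology_path),
                pdb = parse_pdb(topology_path),
                stop("unsupported topology format: .", ext))
  coords <- top$coords
  boxes <- top$box
  if (!is.null(trajectory_path)) {
    if (!file.exists(trajectory_path)) stop("no such file: ", trajectory_path)
    text <- tolower(tools::file_ext(trajectory_path))
    if (text == "xtc")
      stop("XTC trajectories are not supported; supply DCD, multi-frame ",
           "GRO or the plain-text fixture format")
    if (text == "dcd") {
      xyz <- bio3d::read.dcd(trajectory_path, verbose = FALSE)
      nat <- ncol(xyz) / 3
      if (nat != nrow(top$atoms))
        stop("atom-count mismatch: topology has ", nrow(top$atoms),
             " atoms but trajectory has ", nat)
      nf <- nrow(xyz)
      coords <- array(0, dim = c(nf, nat, 3))
      for (k in 1:3) coords[, , k] <- xyz[, seq(k, by = 3,
                                                length.out = nat)] / 10
      boxes <- NULL
    } else if (text %in% c("gro")) {
      g <- parse_gro(trajectory_path)
      if (nrow(g$atoms) != nrow(top$atoms))
        stop("atom-count mismatch: topology has ", nrow(top$atoms),
             " atoms but trajectory has ", nrow(g$atoms))
      coords <- g$coords; boxes <- g$box
    } else {
      tr <- read_traj_text(trajectory_path)
      if (n_atoms(tr) != nrow(top$atoms))
        stop("atom-count mismatch: topology has ", nrow(top$atoms),
             " atoms but trajectory has ", n_atoms(tr))
      coords <- tr$coords; boxes <- tr$box; dt <- tr$dt
    }
  }
  if (is.null(boxes)) {
    if (is.null(box)) {
      ## no box information anywhere: enclose the system with 1 nm margin
      span <- apply(coords, 3, function(m) diff(range(m)))
      box <- span + 2
      warning("no box information in input; using extent + 2 nm")
    }
    boxes <- box
  }
  cls <- classify_atoms(top$atoms$resname, classification_rules)
  atoms <- atom_table(name = top$atoms$name, resid = top$atoms$resid,
                      resname = top$atoms$resname,
                      mol_id = assign_mol_ids(top$atoms$resid,
                                              top$atoms$resname, cls),
                      mol_class = cls)
  trajectory(atoms, coords, boxes, dt)
}

## ---------------------------------------------------------------------
## Result tables

#' Write a result table to CSV or JSON
#'
#' Numeric fields survive a write/read cycle at >= 12 significant digits.
#'
#' @param records A non-empty data.frame.
#' @param path Output path.
#' @param format "csv" or "json".
#' @return `path`, invisibly.
#' @export
write_table <- function(records, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (!is.data.frame(records) || nrow(records) == 0L)
    stop("records must be a non-empty data.frame")
  if (format == "csv") {
    out <- records
    num <- vapply(out, is.numeric, logical(1))
    out[num] <- lapply(out[num], function(v) format(v, digits = 15,
                                                    trim = TRUE,
                                                    scientific = FALSE))
    tryCatch(utils::write.csv(out, path, row.names = FALSE, quote = FALSE),
             error = function(e) stop("cannot write table to ", path, ": ",
                                      conditionMessage(e)))
  } else {
    tryCatch(jsonlite::write_json(records, path, digits = NA, dataframe = "rows"),
             error = function(e) stop("cannot write table to ", path, ": ",
                                      conditionMessage(e)))
  }
  invisible(path)
}

#' Read a result table written by [write_table()]
#' @param path File path.
#' @param format "csv" or "json".
#' @return A data.frame.
#' @export
read_table <- function(path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") utils::read.csv(path, stringsAsFactors = FALSE)
  else as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
}
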