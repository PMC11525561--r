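#' Trajectory frames container
#'
#' Holds the atom roster and per-frame coordinates of a (possibly
#' multi-replicate) molecular-dynamics-like trajectory. The roster is fixed
#' across frames: every frame carries the same (chain, residue number, atom
#' name) keys, which is what makes per-residue time series well defined.
#'
#' @param atoms data.frame with columns `chain`, `resno`, `resname`, `atom`
#'   (one row per atom in the roster).
#' @param coords numeric array of dimension `c(n_frames, n_atoms, 3)`,
#'   coordinates in Angstrom (PDB convention).
#' @param times numeric vector of per-frame timestamps in ns, strictly
#'   increasing.
#' @param source_label character tag identifying the trajectory (file name,
#'   replicate id, ...).
#'
#' @return An object of class `trajectory_frames`.
#' @export
trajectory_frames <- function(atoms, coords, times, source_label = "") {
  stopifnot(is.data.frame(atoms),
            all(c("chain", "resno", "resname", "atom") %in% names(atoms)))
  if (length(dim(coords)) != 3L) stop("coords must be an n_frames x n_atoms x 3 array")
  n_frames <- dim(coords)[1L]
  if (dim(coords)[2L] != nrow(atoms)) stop("coords second dimension must match the atom roster")
  if (dim(coords)[3L] != 3L) stop("coords third dimension must be 3 (x, y, z)")
  if (n_frames < 1L) stop("at least one frame is required")
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (any(atoms$resno < 1L)) stop("residue numbers must be >= 1")
  if (length(times) != n_frames) stop("times must have one entry per frame")
  if (n_frames > 1L && any(diff(times) <= 0)) stop("times must be strictly increasing")
  structure(
    list(atoms = atoms, coords = coords, times = as.numeric(times),
         source_label = source_label),
    class = "trajectory_frames"
  )
}

#' @export
print.trajectory_frames <- function(x, ...) {
  cat(sprintf("<trajectory_frames> %d frames, %d atoms, t = [%g, %g] ns%s\n",
              n_frames(x), nrow(x$atoms), x$times[1L], x$times[n_frames(x)],
              if (nzchar(x$source_label)) paste0(" (", x$source_label, ")") else ""))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param frames a `trajectory_frames` object
#' @return integer frame count
#' @export
n_frames <- function(frames) dim(frames$coords)[1L]

# Open a text connection that transparently handles gzip; gzfile() reads
# plain files unchanged.
open_text <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gzfile(path, open = "rt")
}

parse_atom_line <- function(line, lineno) {
  # PDB fixed columns: name 13-16, altLoc 17, resName 18-20, chain 22,
  # resSeq 23-26, x 31-38, y 39-46, z 47-54
  if (nchar(line) < 54L)
    stop(sprintf("unparseable ATOM line %d: too short", lineno))
  xyz <- suppressWarnings(as.numeric(c(substr(line, 31, 38),
                                       substr(line, 39, 46),
                                       substr(line, 47, 54))))
  resno <- suppressWarnings(as.integer(substr(line, 23, 26)))
  if (anyNA(xyz) || is.na(resno))
    stop(sprintf("unparseable ATOM line %d: non-numeric coordinate or residue field", lineno))
  list(atom    = trimws(substr(line, 13, 16)),
       altloc  = substr(line, 17, 17),
       resname = trimws(substr(line, 18, 20)),
       chain   = substr(line, 22, 22),
       resno   = resno,
       xyz     = xyz)
}

#' Read a multi-model PDB file as trajectory frames
#'
#' Each MODEL/ENDMDL block becomes one frame; a file without MODEL records is
#' treated as a single frame. The atom roster (chain, residue number, atom
#' name) must be identical in every model. Alternate locations: atoms with
#' altLoc blank or "A" are kept, others dropped. Input may be
#' gzip-compressed.
#'
#' @param path path to a PDB file (plain or .gz).
#' @param times optional numeric vector of per-frame timestamps (ns); when
#'   `NULL`, frames are stamped `(0, dt, 2*dt, ...)`.
#' @param dt frame spacing in ns used when `times` is absent (default 1).
#' @return a [trajectory_frames] object.
#' @export
read_multimodel_pdb <- function(path, times = NULL, dt = 1) {
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)

  model_starts <- grep("^MODEL", lines)
  frames_raw <- list()
  if (length(model_starts) == 0L) {
    frames_raw[[1L]] <- list(lines = grep("^(ATOM  |HETATM)", lines),
                             offset = 0L)
    atom_idx <- list(grep("^(ATOM  |HETATM)", lines))
  } else {
    model_ends <- grep("^ENDMDL", lines)
    if (length(model_ends) < length(model_starts))
      model_ends <- c(model_ends, length(lines) + 1L)
    atom_idx <- lapply(seq_along(model_starts), function(i) {
      block <- seq(model_starts[i] + 1L, model_ends[i] - 1L)
      block[grepl("^(ATOM  |HETATM)", lines[block])]
    })
  }

  parse_block <- function(idx) {
    recs <- lapply(idx, function(j) parse_atom_line(lines[j], j))
    keep <- vapply(recs, function(r) r$altloc %in% c(" ", "", "A"), logical(1L))
    recs[keep]
  }

  blocks <- lapply(atom_idx, parse_block)
  if (length(blocks) == 0L || length(blocks[[1L]]) == 0L)
    stop("no ATOM records found in ", path)

  roster_key <- function(recs)
    vapply(recs, function(r) paste(r$chain, r$resno, r$atom, sep = "|"), character(1L))

  ref_key <- roster_key(blocks[[1L]])
  for (i in seq_along(blocks)) {
    key <- roster_key(blocks[[i]])
    if (length(key) != length(ref_key) || any(key != ref_key))
      stop(sprintf("atom roster mismatch: frame %d differs from frame 1", i))
  }

  atoms <- data.frame(
    chain   = vapply(blocks[[1L]], `[[`, character(1L), "chain"),
    resno   = vapply(blocks[[1L]], `[[`, integer(1L), "resno"),
    resname = vapply(blocks[[1L]], `[[`, character(1L), "resname"),
    atom    = vapply(blocks[[1L]], `[[`, character(1L), "atom"),
    stringsAsFactors = FALSE
  )
  nf <- length(blocks); na <- nrow(atoms)
  coords <- array(NA_real_, dim = c(nf, na, 3L))
  for (i in seq_len(nf))
    coords[i, , ] <- t(vapply(blocks[[i]], `[[`, numeric(3L), "xyz"))

  if (is.null(times)) times <- (seq_len(nf) - 1L) * dt
  if (length(times) != nf)
    stop(sprintf("times has %d entries but the file holds %d frames", length(times), nf))
  trajectory_frames(atoms, coords, times, source_label = basename(path))
}

#' Write trajectory frames as a multi-model PDB file
#'
#' Inverse of [read_multimodel_pdb()]: one MODEL/ENDMDL block per frame,
#' standard fixed-width ATOM records (coordinates to 0.001 Angstrom).
#'
#' @param frames a [trajectory_frames] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(frames, path) {
  stopifnot(inherits(frames, "trajectory_frames"))
  a <- frames$atoms
  # atom names shorter than 4 chars start in column 14 by PDB convention
  name_field <- ifelse(nchar(a$atom) < 4L, sprintf(" %-3s", a$atom), a$atom)
  out <- character(0)
  for (i in seq_len(n_frames(frames))) {
    xyz <- frames$coords[i, , , drop = FALSE]
    atom_lines <- sprintf("ATOM  %5d %4s %-3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                          seq_len(nrow(a)), name_field, a$resname, a$chain, a$resno,
                          xyz[1L, , 1L], xyz[1L, , 2L], xyz[1L, , 3L])
    out <- c(out, sprintf("MODEL %8d", i), atom_lines, "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

#' Read a two-column time/distance table
#'
#' Accepts a delimited file (comma, tab or whitespace; optional header) with
#' a time column in ns and a distance column. The unit is taken from a
#' header annotation (`distance_nm` or `distance_angstrom`/`distance_A`)
#' when present, otherwise nm. Rows are sorted by time. Input may be
#' gzip-compressed.
#'
#' @param path path to the table.
#' @param unit override for the distance unit; `NULL` (default) means infer
#'   from the header, falling back to `"nm"`.
#' @param pair_label label for the residue pair (stored on the series).
#' @param replicate_id replicate tag (stored on the series).
#' @return a [distance_series] object.
#' @export
read_distance_table <- function(path, unit = NULL, pair_label = "",
                                replicate_id = "") {
  con <- open_text(path)
  on.exit(close(con))
  lines <- readLines(con, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty distance table: ", path)

  split_row <- function(x) strsplit(trimws(x), "[,\t ]+")[[1L]]
  first <- split_row(lines[1L])
  has_header <- anyNA(suppressWarnings(as.numeric(first)))
  header <- if (has_header) first else NULL
  body <- if (has_header) lines[-1L] else lines
  if (length(body) < 2L) stop("distance table needs at least 2 data rows")

  rows <- lapply(seq_along(body), function(i) {
    v <- suppressWarnings(as.numeric(split_row(body[i])))
    if (length(v) < 2L || anyNA(v[1:2]))
      stop(sprintf("non-numeric cell in distance table row %d", i + has_header))
    v[1:2]
  })
  m <- do.call(rbind, rows)

  if (is.null(unit)) {
    unit <- "nm"
    if (!is.null(header) && length(header) >= 2L) {
      h <- tolower(header[2L])
      if (grepl("angstrom|_a$|\\bang\\b", h)) unit <- "angstrom"
      else if (grepl("nm", h)) unit <- "nm"
    }
  }
  ord <- order(m[, 1L])
  distance_series_new(times = m[ord, 1L], values = m[ord, 2L], unit = unit,
                      pair_label = pair_label, replicate_id = replicate_id)
}

#' Extract the alpha-carbon coordinate series of one residue
#'
#' @param frames a [trajectory_frames] object.
#' @param residue_number residue sequence number (PDB numbering; mature-LCAT
#'   numbering puts CYS at 50 and ASN at 65).
#' @param chain_id optional chain; may be omitted when the residue number is
#'   unique across chains.
#' @return numeric matrix `n_frames x 3` of CA coordinates (Angstrom), one
#'   row per frame in frame order.
#' @export
get_alpha_carbon <- function(frames, residue_number, chain_id = NULL) {
  stopifnot(inherits(frames, "trajectory_frames"))
  a <- frames$atoms
  hit <- a$atom == "CA" & a$resno == residue_number
  if (!is.null(chain_id)) hit <- hit & a$chain == chain_id
  idx <- which(hit)
  if (length(idx) == 0L) {
    avail <- sort(unique(a$resno[a$atom == "CA"]))
    stop(sprintf("residue %d not found (CA atoms present for residues: %s)",
                 residue_number, paste(avail, collapse = ", ")))
  }
  if (length(idx) > 1L)
    stop(sprintf("residue %d is ambiguous across chains %s; supply chain_id",
                 residue_number,
                 paste(unique(a$chain[idx]), collapse = ", ")))
  m <- frames$coords[, idx, , drop = FALSE]
  matrix(m, ncol = 3L, dimnames = list(NULL, c("x", "y", "z")))
}
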