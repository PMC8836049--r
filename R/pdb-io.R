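# ---- structure / trajectory containers --------------------------------------

new_structure <- function(atoms, models) {
  stopifnot(is.data.frame(atoms), is.list(models), length(models) >= 1L)
  n <- nrow(atoms)
  for (m in models) {
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != 3L)
      stop("every model must be an n_atoms x 3 coordinate matrix")
    if (!all(is.finite(m))) stop("coordinates must be finite")
  }
  structure(list(atoms = atoms, models = models), class = "mdu_structure")
}

#' Number of atoms, models and residues in a structure
#'
#' @param x an object of class `mdu_structure`.
#' @return An integer count.
#' @export
n_atoms <- function(x) nrow(x$atoms)

#' @rdname n_atoms
#' @export
n_models <- function(x) length(x$models)

#' @rdname n_atoms
#' @export
n_residues <- function(x) length(unique(x$atoms$resid))

#' @export
print.mdu_structure <- function(x, ...) {
  cat(sprintf("<mdu_structure> %d atoms, %d residues, %d model(s)\n",
              n_atoms(x), n_residues(x), n_models(x)))
  ch <- unique(x$atoms$chain)
  cat("  chains:", paste(ch, collapse = ", "), "\n")
  invisible(x)
}

#' Build a trajectory from a structure's models
#'
#' A multi-model structure (e.g. frames stored as PDB MODEL blocks) is
#' reinterpreted as a trajectory. Model 1 becomes the topology and the
#' reference frame at time zero. Times are either uniformly spaced at
#' `dt` ns per frame or supplied explicitly.
#'
#' @param struct an `mdu_structure`.
#' @param dt time spacing between frames in ns (default 0.25).
#' @param times optional numeric vector of frame times in ns; overrides `dt`.
#' @return An object of class `mdu_trajectory` with fields `topology`
#'   (single-model structure), `times` (ns) and `coords` (list of
#'   n_atoms x 3 matrices).
#' @export
as_trajectory <- function(struct, dt = 0.25, times = NULL) {
  stopifnot(inherits(struct, "mdu_structure"))
  nf <- n_models(struct)
  if (is.null(times)) times <- (seq_len(nf) - 1) * dt
  if (length(times) != nf) stop("length(times) must equal the number of models")
  if (nf > 1 && any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  topo <- new_structure(struct$atoms, struct$models[1])
  structure(list(topology = topo, times = as.numeric(times),
                 coords = struct$models),
            class = "mdu_trajectory")
}

#' @export
print.mdu_trajectory <- function(x, ...) {
  cat(sprintf("<mdu_trajectory> %d frames (%.4g..%.4g ns), %d atoms, %d residues\n",
              length(x$times), min(x$times), max(x$times),
              n_atoms(x$topology), n_residues(x$topology)))
  invisible(x)
}

n_frames <- function(traj) length(traj$times)

# ---- PDB reader -------------------------------------------------------------

.substr_trim <- function(x, a, b) trimws(substr(x, a, b))

.guess_element <- function(name) {
  # strip leading digits (e.g. "1HB"), take leading alpha run
  nm <- sub("^[0-9]+", "", name)
  first <- substr(nm, 1L, 1L)
  two <- toupper(substr(nm, 1L, 2L))
  if (two %in% c("FE", "ZN", "MG", "CL", "NA", "BR", "SE", "MN", "CU")) return(two)
  toupper(first)
}

#' Read a PDB file
#'
#' Parses ATOM/HETATM records in fixed-column PDB layout. Each MODEL/ENDMDL
#' block becomes one coordinate set; a file without MODEL records yields a
#' single implicit model. Hydrogens are retained and flagged non-heavy via
#' the element field. The first alternate location of an atom is kept and
#' later altlocs are dropped; insertion codes are rejected with an error.
#'
#' Residues receive two indices: `resno`, the author residue number from the
#' file (the numbering used in region configs), and `resid`, a 1-based
#' sequential index assigned in file order.
#'
#' @param path path to a PDB file.
#' @return An `mdu_structure`.
#' @export
read_pdb <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  is_model <- startsWith(rec, "MODEL")
  is_endmdl <- startsWith(rec, "ENDMDL")
  if (!any(is_atom)) stop("empty structure: no ATOM/HETATM records in ", path)

  # model id per line: 0 before any MODEL record (implicit single model)
  model_id <- cumsum(is_model)
  atom_lines <- which(is_atom)
  mid <- model_id[atom_lines]
  if (all(mid == 0)) mid <- rep(1L, length(mid))

  txt <- lines[atom_lines]
  xs <- substr(txt, 31, 38); ys <- substr(txt, 39, 46); zs <- substr(txt, 47, 54)
  x <- suppressWarnings(as.numeric(xs))
  y <- suppressWarnings(as.numeric(ys))
  z <- suppressWarnings(as.numeric(zs))
  bad <- which(is.na(x) | is.na(y) | is.na(z))
  if (length(bad))
    stop(sprintf("malformed coordinate field at line %d of %s",
                 atom_lines[bad[1]], path))

  icode <- substr(txt, 27, 27)
  if (any(icode != " "))
    stop(sprintf("insertion codes are not supported (line %d of %s)",
                 atom_lines[which(icode != " ")[1]], path))

  name <- .substr_trim(txt, 13, 16)
  altloc <- substr(txt, 17, 17)
  resname <- .substr_trim(txt, 18, 20)
  chain <- substr(txt, 22, 22)
  resno <- suppressWarnings(as.integer(.substr_trim(txt, 23, 26)))
  if (anyNA(resno))
    stop(sprintf("malformed residue number at line %d of %s",
                 atom_lines[which(is.na(resno))[1]], path))
  serial <- suppressWarnings(as.integer(.substr_trim(txt, 7, 11)))
  elem <- toupper(.substr_trim(txt, 77, 78))

  models <- sort(unique(mid))
  first <- mid == models[1]

  # drop all but the first altloc of each atom within the first model,
  # and remember which atom keys were kept so later models match
  key <- paste(chain, resno, name, sep = "|")
  keep1 <- which(first)
  kf <- key[keep1]
  dup <- duplicated(kf) & altloc[keep1] != " "
  keep1 <- keep1[!dup]

  atoms <- data.frame(
    serial = serial[keep1],
    name = name[keep1],
    element = ifelse(elem[keep1] == "" | is.na(elem[keep1]),
                     vapply(name[keep1], .guess_element, character(1)),
                     elem[keep1]),
    resname = resname[keep1],
    chain = chain[keep1],
    resno = resno[keep1],
    stringsAsFactors = FALSE
  )
  if (any(atoms$element == ""))
    stop("could not determine element for some atoms in ", path)
  # sequential residue index in file order
  rkey <- paste(atoms$chain, atoms$resno, sep = "|")
  atoms$resid <- cumsum(c(TRUE, rkey[-1] != rkey[-length(rkey)]))

  na <- nrow(atoms)
  coord_list <- vector("list", length(models))
  kept_keys <- key[keep1]
  for (k in seq_along(models)) {
    if (k == 1) {
      sel <- keep1
    } else {
      sel <- which(mid == models[k])
    }
    if (k > 1) {
      # keep the same altloc-filtered atom set, in order
      kk <- key[sel]
      drop <- duplicated(kk) & altloc[sel] != " "
      sel <- sel[!drop]
      if (length(sel) != na || any(key[sel] != kept_keys))
        stop(sprintf("model %d atom records do not match model 1 in %s",
                     models[k], path))
    }
    coord_list[[k]] <- cbind(x[sel], y[sel], z[sel])
  }
  new_structure(atoms, coord_list)
}

# ---- PDB writer -------------------------------------------------------------

.fmt_atom_name <- function(name, element) {
  # standard PDB convention: element right-justified in cols 13-14
  if (nchar(name) >= 4L) return(substr(sprintf("%-4s", name), 1, 4))
  if (nchar(element) == 2L) sprintf("%-4s", name) else sprintf(" %-3s", name)
}

#' Write a structure to a PDB file
#'
#' Multi-model structures are serialized as MODEL/ENDMDL blocks. Coordinates
#' are written with the PDB `%8.3f` format, so a read/write round trip
#' preserves them to three decimals.
#'
#' @param struct an `mdu_structure`.
#' @param path output file path.
#' @return Invisibly, `path`.
#' @export
write_pdb <- function(struct, path) {
  stopifnot(inherits(struct, "mdu_structure"))
  con <- tryCatch(file(path, "w"), error = function(e)
    stop("cannot open for writing: ", path))
  on.exit(close(con))
  a <- struct$atoms
  nm <- vapply(seq_len(nrow(a)),
               function(i) .fmt_atom_name(a$name[i], a$element[i]), character(1))
  multi <- n_models(struct) > 1L
  for (k in seq_len(n_models(struct))) {
    if (multi) writeLines(sprintf("MODEL     %4d", k), con)
    xyz <- struct$models[[k]]
    recs <- sprintf(
      "ATOM  %5d %s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      a$serial %% 100000L, nm, a$resname, a$chain, a$resno,
      xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, sprintf("%2s", a$element))
    writeLines(recs, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Read a trajectory from a multi-model PDB (plus optional times sidecar)
#'
#' @param path multi-model PDB file (one MODEL block per frame).
#' @param dt uniform frame spacing in ns used when no sidecar is given.
#' @param times_file optional plain-text file with one frame time (ns) per line.
#' @return An `mdu_trajectory`.
#' @export
read_trajectory <- function(path, dt = 0.25, times_file = NULL) {
  s <- read_pdb(path)
  times <- NULL
  if (!is.null(times_file)) {
    times <- as.numeric(readLines(times_file, warn = FALSE))
    if (anyNA(times)) stop("non-numeric entry in times file ", times_file)
  }
  as_trajectory(s, dt = dt, times = times)
}

#' Write a trajectory as a multi-model PDB
#'
#' @param traj an `mdu_trajectory`.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_trajectory <- function(traj, path) {
  write_pdb(new_structure(traj$topology$atoms, traj$coords), path)
}
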