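#' Conformational ensemble container
#'
#' An `ensemble` bundles an ordered list of coordinate frames with the atom
#' metadata (topology) they share. Every frame is an `n_atoms x 3` matrix of
#' Cartesian coordinates in Angstrom, in the same atom order as the topology.
#'
#' @param topology data.frame with columns `serial`, `atom_name`, `element`,
#'   `residue_name`, `chain_id`, `residue_number`, `insertion_code`,
#'   `occupancy`, `altloc`, `record`. Residue numbering is author numbering
#'   (1-based); insertion codes are honoured. Internal lookups always key on
#'   `(chain_id, residue_number, insertion_code)`, never on row position.
#' @param frames list of numeric `n_atoms x 3` matrices (Angstrom).
#' @param frame_interval optional time per frame in ps.
#' @return object of class `ensemble`.
#' @export
ensemble <- function(topology, frames, frame_interval = NULL) {
  required <- c("serial", "atom_name", "element", "residue_name", "chain_id",
                "residue_number", "insertion_code", "occupancy", "altloc",
                "record")
  missing <- setdiff(required, names(topology))
  if (length(missing) > 0L)
    stop("topology is missing column(s): ", paste(missing, collapse = ", "))
  if (!is.list(frames) || length(frames) < 1L)
    stop("an ensemble needs at least one frame")
  n_atoms <- nrow(topology)
  for (i in seq_along(frames)) {
    f <- frames[[i]]
    if (!is.matrix(f) || ncol(f) != 3L || nrow(f) != n_atoms)
      stop("frame ", i, " is not an ", n_atoms, " x 3 coordinate matrix")
    if (!all(is.finite(f)))
      stop("frame ", i, " contains non-finite coordinates")
    dimnames(frames[[i]]) <- NULL
  }
  key <- paste(topology$chain_id, topology$residue_number,
               topology$insertion_code, topology$atom_name, topology$altloc)
  if (anyDuplicated(key))
    stop("duplicate atom identity in topology: ",
         key[which(duplicated(key))[1L]])
  structure(list(topology = topology, frames = frames,
                 frame_interval = frame_interval),
            class = "ensemble")
}

#' @export
print.ensemble <- function(x, ...) {
  cat("Conformational ensemble:", length(x$frames), "frame(s),",
      nrow(x$topology), "atoms,",
      length(unique(x$topology$chain_id)), "chain(s)\n")
  if (!is.null(x$frame_interval))
    cat("Frame interval:", x$frame_interval, "ps\n")
  invisible(x)
}

#' Number of frames / atoms in an ensemble
#' @param x an `ensemble`.
#' @return integer count.
#' @export
n_frames <- function(x) length(x$frames)

#' @rdname n_frames
#' @export
n_atoms <- function(x) nrow(x$topology)

#' Extract one coordinate frame
#' @param x an `ensemble`.
#' @param i frame index.
#' @return `n_atoms x 3` numeric matrix (Angstrom).
#' @export
get_frame <- function(x, i) {
  if (i < 1L || i > length(x$frames)) stop("frame index out of range: ", i)
  x$frames[[i]]
}

# Residue identity key "chain:resnum[icode]" for each atom row.
atom_residue_keys <- function(topology) {
  paste0(topology$chain_id, ":", topology$residue_number,
         ifelse(topology$insertion_code == "", "",
                topology$insertion_code))
}

# Sortable key so tie-breaks order residues by (chain, number, icode),
# not by the quirks of string comparison on "A:10" vs "A:2".
residue_sort_keys <- function(keys) {
  m <- regmatches(keys, regexec("^(.+):(-?[0-9]+)([A-Za-z]?)$", keys))
  vapply(m, function(g) {
    if (length(g) != 4L) stop("malformed residue key: ", g[1L])
    sprintf("%s|%08d|%s", g[2L], as.integer(g[3L]) + 10000L, g[4L])
  }, character(1L))
}

#' Residue table of a topology
#'
#' One row per distinct `(chain, residue_number, insertion_code)` in topology
#' order, with the residue key used throughout the package.
#'
#' @param topology an ensemble topology data.frame.
#' @return data.frame with `key`, `chain_id`, `residue_number`,
#'   `insertion_code`, `residue_name`.
#' @export
residue_table <- function(topology) {
  key <- atom_residue_keys(topology)
  first <- !duplicated(key)
  data.frame(key = key[first],
             chain_id = topology$chain_id[first],
             residue_number = topology$residue_number[first],
             insertion_code = topology$insertion_code[first],
             residue_name = topology$residue_name[first],
             stringsAsFactors = FALSE)
}
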