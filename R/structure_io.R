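# Multi-model PDB ingestion and tabular inputs.
#
# Fixed-column PDB layout (1-based): record 1-6, serial 7-11, name 13-16,
# altLoc 17, resName 18-20, chainID 22, resSeq 23-26, iCode 27, x 31-38,
# y 39-46, z 47-54, occupancy 55-60, element 77-78.

#' Read a multi-model PDB file into an ensemble
#'
#' Frames follow MODEL order; a file without MODEL records is read as a
#' single implicit model. Alternate locations are resolved by keeping the
#' highest-occupancy conformer (ties broken toward altloc 'A', then
#' lexicographically), so ingestion is deterministic. All MODELs must share
#' one atom topology.
#'
#' @param path PDB file path.
#' @param keep_hetatm keep HETATM records (waters, ligands)? Default `FALSE`:
#'   networks and geometry operate on protein atoms unless asked otherwise.
#' @return an [ensemble].
#' @export
read_multimodel_pdb <- function(path, keep_hetatm = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  is_model <- startsWith(rec, "MODEL")
  is_atom <- rec == "ATOM  " | (keep_hetatm & rec == "HETATM")

  # Assign each atom line to a model (0 => implicit single model).
  model_id <- cumsum(is_model)
  atom_idx <- which(is_atom)
  if (length(atom_idx) == 0L) stop("no ATOM records in ", path)
  mid <- model_id[atom_idx]
  if (any(mid == 0L) && any(mid > 0L))
    stop("ATOM records found outside MODEL blocks in a multi-model file")

  parse_block <- function(idx) {
    ln <- lines[idx]
    num <- function(s, what) {
      v <- suppressWarnings(as.numeric(s))
      bad <- which(!is.finite(v))
      if (length(bad) > 0L)
        stop("malformed ", what, " field at line ", idx[bad[1L]],
             ": '", trimws(s[bad[1L]]), "'")
      v
    }
    df <- data.frame(
      serial = as.integer(num(substr(ln, 7L, 11L), "serial")),
      atom_name = trimws(substr(ln, 13L, 16L)),
      altloc = trimws(substr(ln, 17L, 17L)),
      residue_name = trimws(substr(ln, 18L, 20L)),
      chain_id = trimws(substr(ln, 22L, 22L)),
      residue_number = as.integer(num(substr(ln, 23L, 26L), "residue number")),
      insertion_code = trimws(substr(ln, 27L, 27L)),
      occupancy = {
        o <- suppressWarnings(as.numeric(substr(ln, 55L, 60L)))
        ifelse(is.finite(o), o, 1)
      },
      element = trimws(substr(ln, 77L, 78L)),
      record = trimws(substr(ln, 1L, 6L)),
      stringsAsFactors = FALSE)
    df$element <- ifelse(df$element == "",
                         sub("^[0-9]*", "", substr(df$atom_name, 1L, 1L)),
                         df$element)
    xyz <- cbind(num(substr(ln, 31L, 38L), "x"),
                 num(substr(ln, 39L, 46L), "y"),
                 num(substr(ln, 47L, 54L), "z"))
    list(meta = df, xyz = xyz)
  }

  apply_altloc <- function(block) {
    df <- block$meta
    if (all(df$altloc == ""))
      return(block)
    id <- paste(df$chain_id, df$residue_number, df$insertion_code,
                df$atom_name)
    # highest occupancy wins; ties -> 'A' then lexicographic ('' sorts first)
    pref <- order(id, -df$occupancy, df$altloc != "A", df$altloc)
    keep_first <- !duplicated(id[pref])
    keep <- sort(pref[keep_first])
    df <- df[keep, , drop = FALSE]
    df$altloc <- ""
    list(meta = df, xyz = block$xyz[keep, , drop = FALSE])
  }

  models <- unique(mid)
  blocks <- lapply(models, function(m) apply_altloc(parse_block(atom_idx[mid == m])))

  topo_sig <- function(df)
    paste(df$chain_id, df$residue_number, df$insertion_code, df$atom_name)
  ref <- blocks[[1L]]$meta
  ref_sig <- topo_sig(ref)
  for (b in seq_along(blocks)[-1L]) {
    sig <- topo_sig(blocks[[b]]$meta)
    if (length(sig) != length(ref_sig) || any(sig != ref_sig)) {
      off <- if (length(sig) < length(ref_sig)) {
        setdiff(ref_sig, sig)[1L]
      } else if (length(sig) > length(ref_sig)) {
        setdiff(sig, ref_sig)[1L]
      } else {
        sig[which(sig != ref_sig)[1L]]
      }
      stop("topology mismatch: MODEL ", b,
           " differs from MODEL 1 at atom '", off, "'")
    }
  }

  rownames(ref) <- NULL
  ensemble(ref, lapply(blocks, `[[`, "xyz"))
}

#' Write an ensemble as a multi-model PDB file
#'
#' One MODEL/ENDMDL block per frame, fixed-width records, coordinates to
#' three decimals (the format's precision, hence the round-trip tolerance).
#'
#' @param x an [ensemble].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_multimodel_pdb <- function(x, path) {
  stopifnot(inherits(x, "ensemble"))
  t <- x$topology
  if (any(t$residue_number > 9999L | t$residue_number < -999L))
    stop("residue number out of PDB fixed-width range (max 9999)")
  if (any(abs(unlist(x$frames)) >= 10000))
    stop("coordinate out of PDB fixed-width range")
  # atom names shorter than 4 chars start in column 14 by convention
  name4 <- ifelse(nchar(t$atom_name) < 4L,
                  sprintf(" %-3s", t$atom_name),
                  substr(t$atom_name, 1L, 4L))
  serial <- pmin(t$serial, 99999L)
  rec <- sprintf("%-6s", ifelse(t$record == "HETATM", "HETATM", "ATOM"))
  con <- try(file(path, "w"), silent = TRUE)
  if (inherits(con, "try-error")) stop("cannot open for writing: ", path)
  on.exit(close(con))
  for (i in seq_along(x$frames)) {
    writeLines(sprintf("MODEL     %4d", i), con)
    f <- x$frames[[i]]
    writeLines(sprintf(
      "%s%5d %s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rec, serial, name4, substr(paste0(t$altloc, " "), 1L, 1L),
      t$residue_name, t$chain_id, t$residue_number,
      substr(paste0(t$insertion_code, " "), 1L, 1L),
      f[, 1L], f[, 2L], f[, 3L], t$occupancy, 0,
      toupper(t$element)), con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

# Sniff the delimiter of a small delimited text file from its header line.
detect_sep <- function(path) {
  hdr <- readLines(path, n = 1L)
  if (lengths(regmatches(hdr, gregexpr("\t", hdr))) > 0L) "\t" else ","
}

read_delim_checked <- function(path, required, what) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = detect_sep(path),
                          stringsAsFactors = FALSE, check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "))
  if (nrow(df) == 0L) stop(what, " has a header but no rows")
  df
}

#' Read a per-frame MM-PBSA component energy table
#'
#' Delimited text (TSV or CSV, auto-detected) whose header must name the
#' columns `E_vdw`, `E_ele`, `E_int`, `G_psolv`, `G_npsolv` (kcal/mol). Any
#' additional numeric columns are kept and treated as a per-residue energy
#' decomposition.
#'
#' @param path file path.
#' @return data.frame of class `energy_table`.
#' @export
read_energy_table <- function(path) {
  req <- c("E_vdw", "E_ele", "E_int", "G_psolv", "G_npsolv")
  df <- read_delim_checked(path, req, "energy table")
  for (cn in names(df)) {
    if (!is.numeric(df[[cn]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[cn]]))))[1L]
      stop("non-numeric value in column '", cn, "' at data row ",
           if (is.na(bad)) 1L else bad)
    }
    if (!all(is.finite(df[[cn]])))
      stop("non-finite value in column '", cn, "' at data row ",
           which(!is.finite(df[[cn]]))[1L])
  }
  class(df) <- c("energy_table", "data.frame")
  df
}

#' Read a ligand score table for screening evaluation
#'
#' Delimited text with required columns `ligand_id`, `score`, `label`
#' (`active` / `decoy`). Lower scores mean stronger predicted binding by
#' default (docking-energy convention). Extra columns are kept as metadata.
#' A single-class table is accepted here; ROC construction rejects it later.
#'
#' @param path file path.
#' @return data.frame of class `score_table`.
#' @export
read_score_table <- function(path) {
  df <- read_delim_checked(path, c("ligand_id", "score", "label"),
                           "score table")
  if (anyDuplicated(df$ligand_id))
    stop("duplicate ligand_id: ", df$ligand_id[which(duplicated(df$ligand_id))[1L]])
  if (!is.numeric(df$score)) {
    bad <- which(is.na(suppressWarnings(as.numeric(df$score))))[1L]
    stop("non-numeric score at data row ", bad)
  }
  if (!all(df$label %in% c("active", "decoy")))
    stop("label must be 'active' or 'decoy'; first offender at row ",
         which(!df$label %in% c("active", "decoy"))[1L])
  class(df) <- c("score_table", "data.frame")
  df
}

#' Define a residue selection
#'
#' Selections always address residues by chain and author residue number
#' (plus optional insertion code and residue-name check); atom row indices
#' are never part of the public interface.
#'
#' @param chain character vector of chain ids.
#' @param resnum integer vector of residue numbers (recycled against chain).
#' @param resname optional residue names to verify against the topology.
#' @param icode optional insertion codes (default none).
#' @param label optional selection label, e.g. `"PPI_pocket"`.
#' @return data.frame of class `residue_selection`.
#' @export
residue_selection <- function(chain, resnum, resname = NULL, icode = NULL,
                              label = NULL) {
  n <- max(length(chain), length(resnum))
  df <- data.frame(chain = rep_len(as.character(chain), n),
                   resnum = rep_len(as.integer(resnum), n),
                   icode = if (is.null(icode)) rep_len("", n)
                           else rep_len(icode, n),
                   stringsAsFactors = FALSE)
  if (!is.null(resname)) df$resname <- rep_len(as.character(resname), n)
  if (anyDuplicated(df[c("chain", "resnum", "icode")]))
    stop("duplicate entries in residue selection")
  attr(df, "label") <- label
  class(df) <- c("residue_selection", "data.frame")
  df
}

#' Read a residue selection from TSV
#'
#' Expects columns `chain`, `resnum` and optionally `resname`.
#'
#' @param path file path.
#' @param label optional label attached to the selection.
#' @return a [residue_selection].
#' @export
read_selection_tsv <- function(path, label = NULL) {
  df <- read_delim_checked(path, c("chain", "resnum"), "selection file")
  residue_selection(df$chain, df$resnum,
                    resname = if ("resname" %in% names(df)) df$resname,
                    label = label)
}

#' Residue keys of a selection
#' @param selection a [residue_selection].
#' @return character vector of `"chain:resnum"` keys.
#' @export
selection_keys <- function(selection) {
  paste0(selection$chain, ":", selection$resnum,
         ifelse(selection$icode == "", "", selection$icode))
}

#' Resolve a residue selection to atom indices
#'
#' @param topology an ensemble topology (or an [ensemble]).
#' @param selection a [residue_selection].
#' @param atoms atom class restriction: `"all"`, `"backbone"` (N, CA, C, O),
#'   `"calpha"`, or `"sidechain"` (everything else, heavy atoms only unless
#'   `include_hydrogens`).
#' @param include_hydrogens include hydrogens in `"sidechain"`/`"all"`?
#' @return named list, one integer vector of atom row indices per residue
#'   key, in selection order.
#' @export
select_residues <- function(topology, selection,
                            atoms = c("all", "backbone", "calpha", "sidechain"),
                            include_hydrogens = FALSE) {
  if (inherits(topology, "ensemble")) topology <- topology$topology
  atoms <- match.arg(atoms)
  if (nrow(selection) == 0L) return(structure(list(), names = character(0)))
  topo_key <- atom_residue_keys(topology)
  keep <- switch(atoms,
    all = rep(TRUE, nrow(topology)),
    backbone = topology$atom_name %in% c("N", "CA", "C", "O"),
    calpha = topology$atom_name == "CA",
    sidechain = !(topology$atom_name %in% c("N", "CA", "C", "O", "OXT")))
  if (!include_hydrogens && atoms %in% c("all", "sidechain"))
    keep <- keep & topology$element != "H"
  keys <- selection_keys(selection)
  out <- vector("list", length(keys))
  names(out) <- keys
  for (i in seq_along(keys)) {
    hit <- which(topo_key == keys[i])
    if (length(hit) == 0L)
      stop("selection entry not found in topology: ", keys[i])
    if (!is.null(selection$resname)) {
      found <- topology$residue_name[hit[1L]]
      if (found != selection$resname[i])
        stop("residue name mismatch at ", keys[i], ": selection says ",
             selection$resname[i], ", topology has ", found)
    }
    out[[i]] <- hit[keep[hit]]
  }
  out
}

#' Flatten a grouped atom-index selection
#' @param sel result of [select_residues()].
#' @return sorted integer vector of atom indices.
#' @export
selection_atoms <- function(sel) sort(unique(unlist(sel, use.names = FALSE)))

#' Load a generic-numbering annotation map
#'
#' Two-column TSV `key<TAB>generic` mapping residue keys (e.g. `"A:195"`) to
#' display labels such as Ballesteros-Weinstein numbers (`"5.34"`). The map
#' is display-only: selection logic never consults it.
#'
#' @param path file path.
#' @return named character vector.
#' @export
read_generic_numbering <- function(path) {
  df <- read_delim_checked(path, c("key", "generic"), "numbering map")
  stats::setNames(as.character(df$generic), df$key)
}
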