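# MM-PBSA component bookkeeping: gas-phase and solvation combination,
# binding free energy, nonpolar term, per-residue hot spots.
#
# The entropy term is deliberately not modelled: end-state analyses of
# relative binding strength routinely omit -T*S, and polar solvation is
# always an input column here (the Poisson-Boltzmann solve happens
# upstream).

#' Combine per-frame MM-PBSA components
#'
#' Adds the derived columns row-wise and exactly:
#' `E_gas = E_int + E_ele + E_vdw`, `G_sol = G_psolv + G_npsolv`,
#' `G = E_gas + G_sol`.
#'
#' @param table an `energy_table` (or data.frame) with columns `E_vdw`,
#'   `E_ele`, `E_int`, `G_psolv`, `G_npsolv` in kcal/mol.
#' @param role bookkeeping tag: which end state the table describes.
#' @return data.frame of class `energy_components` with the derived columns
#'   and a `role` attribute.
#' @export
combine_components <- function(table,
                               role = c("delta", "complex", "receptor",
                                        "ligand")) {
  role <- match.arg(role)
  req <- c("E_vdw", "E_ele", "E_int", "G_psolv", "G_npsolv")
  missing <- setdiff(req, names(table))
  if (length(missing) > 0L)
    stop("missing energy column(s): ", paste(missing, collapse = ", "))
  if (nrow(table) == 0L) stop("empty energy table")
  out <- as.data.frame(table)
  out$E_gas <- out$E_int + out$E_ele + out$E_vdw
  out$G_sol <- out$G_psolv + out$G_npsolv
  out$G <- out$E_gas + out$G_sol
  attr(out, "role") <- role
  class(out) <- c("energy_components", "data.frame")
  out
}

energy_summary_stats <- function(df) {
  cols <- c("E_vdw", "E_ele", "E_int", "E_gas", "G_npsolv", "G_psolv",
            "G_sol", "G")
  data.frame(component = cols,
             mean = vapply(cols, function(cn) mean(df[[cn]]), 0),
             sd = vapply(cols, function(cn) stats::sd(df[[cn]]), 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Binding free energy from end-state component tables
#'
#' Single-trajectory convention: complex, receptor and ligand tables come
#' from the same frames, so the per-frame difference
#' `dG = G_complex - (G_receptor + G_ligand)` is formed first and then
#' summarised as mean +/- sd (n-1 denominator). A pre-differenced table can
#' be passed alone. With `multi_trajectory = TRUE`, frame counts may differ
#' and means are differenced instead (sd combined in quadrature).
#'
#' @param complex an [combine_components()] result (or a pre-differenced
#'   delta table when `receptor` and `ligand` are `NULL`).
#' @param receptor,ligand matching component tables, or `NULL`.
#' @param multi_trajectory allow unequal frame counts?
#' @return object of class `energy_summary`: list with `dG` (mean), `sd`,
#'   `n_frames`, `components` (per-component mean/sd table), `per_frame`.
#' @export
binding_energy <- function(complex, receptor = NULL, ligand = NULL,
                           multi_trajectory = FALSE) {
  if (!inherits(complex, "energy_components"))
    complex <- combine_components(complex)
  if (is.null(receptor) != is.null(ligand))
    stop("supply both receptor and ligand tables, or neither")
  if (is.null(receptor)) {
    delta <- complex
  } else {
    if (!inherits(receptor, "energy_components"))
      receptor <- combine_components(receptor, role = "receptor")
    if (!inherits(ligand, "energy_components"))
      ligand <- combine_components(ligand, role = "ligand")
    same_n <- nrow(complex) == nrow(receptor) && nrow(complex) == nrow(ligand)
    if (!same_n && !multi_trajectory)
      stop("frame counts differ (", nrow(complex), "/", nrow(receptor), "/",
           nrow(ligand), "); use multi_trajectory = TRUE if intended")
    cols <- c("E_vdw", "E_ele", "E_int", "G_psolv", "G_npsolv", "E_gas",
              "G_sol", "G")
    if (same_n) {
      delta <- as.data.frame(lapply(stats::setNames(cols, cols), function(cn)
        complex[[cn]] - receptor[[cn]] - ligand[[cn]]))
      class(delta) <- c("energy_components", "data.frame")
    } else {
      comp_means <- function(df) vapply(cols, function(cn) mean(df[[cn]]), 0)
      comp_sds <- function(df) vapply(cols, function(cn) stats::sd(df[[cn]]), 0)
      m <- comp_means(complex) - comp_means(receptor) - comp_means(ligand)
      s <- sqrt(comp_sds(complex)^2 + comp_sds(receptor)^2 + comp_sds(ligand)^2)
      out <- structure(list(dG = unname(m["G"]), sd = unname(s["G"]),
                            n_frames = c(complex = nrow(complex),
                                         receptor = nrow(receptor),
                                         ligand = nrow(ligand)),
                            components = data.frame(component = cols,
                                                    mean = unname(m),
                                                    sd = unname(s),
                                                    stringsAsFactors = FALSE),
                            per_frame = NULL),
                       class = "energy_summary")
      return(out)
    }
  }
  structure(list(dG = mean(delta$G), sd = stats::sd(delta$G),
                 n_frames = nrow(delta),
                 components = energy_summary_stats(delta),
                 per_frame = delta$G),
            class = "energy_summary")
}

#' @export
print.energy_summary <- function(x, digits = 2, ...) {
  cat("Binding free energy (kcal/mol):",
      sprintf("%.*f +/- %.*f", digits, x$dG, digits,
              if (is.na(x$sd)) 0 else x$sd),
      "over", paste(x$n_frames, collapse = "/"), "frame(s)\n")
  comp <- x$components
  comp$mean <- round(comp$mean, digits)
  comp$sd <- round(comp$sd, digits)
  print.data.frame(comp, row.names = FALSE)
  invisible(x)
}

#' Nonpolar solvation energy from surface area
#'
#' `G_npsolv = gamma * SASA` with the standard surface-tension coefficient
#' `gamma = 0.0072` kcal/(mol Angstrom^2) by default.
#'
#' @param sasa_value solvent-accessible surface area in Angstrom^2 (>= 0).
#' @param gamma surface-tension coefficient in kcal/(mol Angstrom^2).
#' @return energy in kcal/mol.
#' @export
nonpolar_solvation <- function(sasa_value, gamma = 0.0072) {
  if (any(sasa_value < 0)) stop("SASA must be non-negative")
  gamma * sasa_value
}

#' Hot-spot residues from a per-residue energy decomposition
#'
#' Residues whose mean contribution is strictly below the threshold
#' (default -1 kcal/mol; a residue at exactly the threshold is excluded),
#' ordered most favourable first.
#'
#' @param table data.frame with a `residue` column and either an `energy`
#'   column (pre-averaged) or one numeric column per frame; alternatively a
#'   named numeric vector.
#' @param threshold hot-spot cutoff in kcal/mol (default -1).
#' @return data.frame (`residue`, `energy`) of hot residues, sorted
#'   ascending by energy.
#' @export
hot_residues <- function(table, threshold = -1) {
  if (is.numeric(table) && !is.null(names(table))) {
    res <- names(table)
    val <- unname(table)
  } else {
    if (!"residue" %in% names(table))
      stop("per-residue table needs a 'residue' column")
    res <- as.character(table$residue)
    num <- table[setdiff(names(table), "residue")]
    if (ncol(num) == 0L) stop("per-residue table has no energy columns")
    val <- rowMeans(as.matrix(num))
  }
  if (length(res) == 0L) stop("empty per-residue table")
  if (!all(is.finite(val))) stop("non-finite per-residue energy")
  keep <- val < threshold
  out <- data.frame(residue = res[keep], energy = val[keep],
                    stringsAsFactors = FALSE)
  out[order(out$energy, out$residue), , drop = FALSE]
}
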