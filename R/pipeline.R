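# End-to-end orchestration from a single config (R list or YAML file).
# Every stage is a pure function of its inputs plus the config seeds, so a
# re-run with the same config reproduces the report byte for byte.

config_selection <- function(x, label = NULL) {
  if (is.character(x) && length(x) == 1L) return(read_selection_tsv(x, label))
  if (is.list(x) && !is.null(x$chain) && !is.null(x$resnum))
    return(residue_selection(unlist(x$chain), unlist(x$resnum), label = label))
  stop("selection must be a TSV path or a list with 'chain' and 'resnum'")
}

#' Validate a pipeline configuration
#'
#' Checks stage toggles, required fields and referenced paths, collecting
#' every problem before failing, so a bad config is reported in one pass.
#'
#' @param config R list, or path to a YAML file.
#' @return the normalised config list, invisibly classed `run_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("config must be a list or a YAML file path")
  problems <- character(0)
  need_path <- function(p, field) {
    if (is.null(p)) problems <<- c(problems, paste0("missing field: ", field))
    else if (!file.exists(p))
      problems <<- c(problems, paste0(field, ": file not found: ", p))
  }
  if (is.null(config$seed)) config$seed <- 1L
  enabled <- function(st) isTRUE(config[[st]]$enabled) || (!is.null(config[[st]]) &&
                                                            is.null(config[[st]]$enabled))
  needs_ensemble <- any(vapply(c("cluster", "psn", "geometry"), function(st)
    !is.null(config[[st]]) && enabled(st), TRUE))
  if (needs_ensemble) {
    if (is.null(config$ensemble))
      problems <- c(problems, "missing field: ensemble (required by an enabled stage)")
    else if (!is.null(config$ensemble$path))
      need_path(config$ensemble$path, "ensemble.path")
    else if (is.null(config$ensemble$simulate))
      problems <- c(problems, "ensemble needs either 'path' or 'simulate'")
  }
  if (!is.null(config$psn) && enabled("psn")) {
    for (f in c("source_pocket", "sink_pocket"))
      if (is.null(config$psn[[f]]))
        problems <- c(problems, paste0("missing field: psn.", f))
      else if (is.character(config$psn[[f]]))
        need_path(config$psn[[f]], paste0("psn.", f))
  }
  if (!is.null(config$energetics) && enabled("energetics"))
    need_path(config$energetics$delta_table, "energetics.delta_table")
  if (!is.null(config$screening) && enabled("screening"))
    need_path(config$screening$scores, "screening.scores")
  if (length(problems) > 0L)
    stop("invalid configuration:\n  ", paste(problems, collapse = "\n  "))
  class(config) <- c("run_config", "list")
  invisible(config)
}

pipeline_ensemble <- function(cfg, seed) {
  ec <- cfg$ensemble
  if (!is.null(ec$path))
    return(read_multimodel_pdb(ec$path, keep_hetatm = isTRUE(ec$keep_hetatm)))
  n_frames <- if (is.null(ec$n_frames)) 100L else as.integer(ec$n_frames)
  switch(ec$simulate,
    gnm = make_gnm_ensemble(
      n_residues = if (is.null(ec$n_residues)) 30L else as.integer(ec$n_residues),
      n_frames = n_frames,
      n_chains = if (is.null(ec$n_chains)) 1L else as.integer(ec$n_chains),
      seed = seed),
    dimer = {
      spec <- planted_path_spec(
        persistence = if (is.null(ec$persistence)) 1 else ec$persistence,
        decoy_density = if (is.null(ec$decoy_density)) 0.3 else ec$decoy_density)
      make_planted_path_dimer(spec, n_frames = n_frames, seed = seed)
    },
    stop("unknown ensemble.simulate mode: ", ec$simulate))
}

#' Run the analysis pipeline from a config
#'
#' Executes the enabled stages in dependency order (ensemble ingestion or
#' simulation, clustering, structure network + cross-correlation + pathway
#' tally, interface geometry, energy bookkeeping, screening evaluation) and
#' returns a report echoing every effective parameter, so under-specified
#' method constants (interaction cutoff, correlation threshold,
#' normalization mode) are always visible. If `config$out_dir` is set, the
#' report is also written there as JSON alongside per-stage tables.
#'
#' @param config R list or YAML path accepted by [validate_config()].
#' @return the run report (list), invisibly classed `run_report`.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  seed <- as.integer(cfg$seed)
  report <- list(seed = seed, stages = character(0))
  enabled <- function(st) !is.null(cfg[[st]]) &&
    (is.null(cfg[[st]]$enabled) || isTRUE(cfg[[st]]$enabled))

  ens <- NULL
  if (any(vapply(c("cluster", "psn", "geometry"), enabled, TRUE))) {
    ens <- pipeline_ensemble(cfg, seed)
    report$ensemble <- list(n_frames = n_frames(ens), n_atoms = n_atoms(ens),
                            source = if (!is.null(cfg$ensemble$path))
                              cfg$ensemble$path else cfg$ensemble$simulate)
  }

  if (enabled("cluster")) {
    cc <- cfg$cluster
    sel <- if (is.null(cc$selection)) NULL
           else selection_atoms(select_residues(ens, config_selection(cc$selection),
                                                atoms = "backbone"))
    k <- if (is.null(cc$k)) 8L else as.integer(cc$k)
    rm <- pairwise_rmsd(ens, sel)
    cl <- kmeans_frames(rm, k = k, seed = seed + 11L,
                        n_init = if (is.null(cc$n_init)) 10L else as.integer(cc$n_init))
    report$cluster <- list(k = cl$k, populations = cl$populations,
                           medoids = cl$medoids)
    report$stages <- c(report$stages, "cluster")
  }

  if (enabled("psn")) {
    pc <- cfg$psn
    config_psn <- psn_config(
      distance_cutoff = if (is.null(pc$distance_cutoff)) 4.5 else pc$distance_cutoff,
      i_min = if (is.null(pc$i_min)) 3.0 else pc$i_min)
    corr_min <- if (is.null(pc$corr_min)) 0.3 else pc$corr_min
    freq_min <- if (is.null(pc$freq_min)) 0.30 else pc$freq_min
    graphs <- psn_per_frame(ens, config_psn)
    dcc <- if (isTRUE(pc$use_dcc)) dcc_matrix(ens) else NULL
    tally <- tally_paths(graphs,
                         config_selection(pc$source_pocket, "source"),
                         config_selection(pc$sink_pocket, "sink"),
                         dcc = dcc, corr_min = corr_min, freq_min = freq_min)
    report$psn <- list(
      distance_cutoff = config_psn$distance_cutoff, i_min = config_psn$i_min,
      normalization = config_psn$normalization, corr_min = corr_min,
      freq_min = freq_min, use_dcc = isTRUE(pc$use_dcc),
      n_paths = nrow(tally), n_above = attr(tally, "n_above"),
      top_path = attr(tally, "top_path"),
      top_frequency = if (nrow(tally) > 0L) tally$frequency[1L])
    report$stages <- c(report$stages, "psn")
    attr(report, "tally") <- tally
  }

  if (enabled("geometry")) {
    gc <- cfg$geometry
    topo <- ens$topology
    a_idx <- which(topo$chain_id == (if (is.null(gc$chain_a)) "A" else gc$chain_a))
    b_idx <- which(topo$chain_id == (if (is.null(gc$chain_b)) "B" else gc$chain_b))
    frame_ids <- if (is.null(gc$frames)) seq_len(n_frames(ens))
                 else as.integer(unlist(gc$frames))
    geo <- lapply(frame_ids, function(f) {
      xyz <- get_frame(ens, f)
      out <- list(frame = f,
                  centroid_distance = centroid_distance(xyz, a_idx, b_idx))
      if (isTRUE(gc$contact_area))
        out$contact_area <- contact_area(xyz, topo, a_idx, b_idx)
      if (!is.null(gc$pocket))
        out$pocket_volume <- pocket_volume(
          xyz, topo,
          lining = selection_atoms(select_residues(ens,
                                                   config_selection(gc$pocket$lining))),
          radius = if (is.null(gc$pocket$radius)) 8 else gc$pocket$radius,
          spacing = if (is.null(gc$pocket$spacing)) 0.5 else gc$pocket$spacing)
      out
    })
    report$geometry <- list(frames = frame_ids,
                            centroid_distance = vapply(geo, `[[`, 0, "centroid_distance"))
    if (isTRUE(gc$contact_area))
      report$geometry$contact_area <- vapply(geo, `[[`, 0, "contact_area")
    if (!is.null(gc$pocket))
      report$geometry$pocket_volume <- vapply(geo, `[[`, 0, "pocket_volume")
    report$stages <- c(report$stages, "geometry")
  }

  if (enabled("energetics")) {
    tab <- read_energy_table(cfg$energetics$delta_table)
    summ <- binding_energy(combine_components(tab))
    report$energetics <- list(dG = summ$dG, sd = summ$sd,
                              n_frames = summ$n_frames,
                              components = summ$components)
    report$stages <- c(report$stages, "energetics")
  }

  if (enabled("screening")) {
    sc <- read_score_table(cfg$screening$scores)
    curve <- roc_points(sc, higher_better = isTRUE(cfg$screening$higher_better))
    report$screening <- list(auc = auc(curve),
                             n_active = attr(curve, "n_active"),
                             n_decoy = attr(curve, "n_decoy"))
    report$stages <- c(report$stages, "screening")
  }

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (!is.null(attr(report, "tally")))
      utils::write.table(as.data.frame(attr(report, "tally")),
                         file.path(cfg$out_dir, "paths.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
  }
  class(report) <- c("run_report", "list")
  invisible(report)
}
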