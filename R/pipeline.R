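#' Assemble a pipeline run configuration
#'
#' Collects every tunable of the analysis in one place. Defaults are the
#' conventions the package is built around: 4 Angstrom / 120 degree hydrogen
#' bonds, 5 Angstrom salt bridges, occupancy pruning at 0.15 (binding-pocket
#' reports; use 0.10 for finger-region reports), replica exclusion at 4
#' Angstrom mean tail RMSD, and tail slicing to the trailing 1000 frames.
#'
#' @param topology a topology (annotated, or it will be annotated with the
#'   default role table).
#' @param trajectories list of replica trajectories, or character paths
#'   (PDB/DCD) loaded against `topology`.
#' @param reference reference coordinates for RMSD/QC; default the
#'   topology's xyz, else the first frame.
#' @param fit_selection,calc_selection alignment and report selections.
#' @param hbond_dist,hbond_angle,salt_dist detector cutoffs.
#' @param prune occupancy pruning threshold.
#' @param qc_threshold replica exclusion threshold (Angstrom).
#' @param tail_frames trailing frames kept per replica (NULL: keep all).
#' @param node_map node labels per atom; default residue granularity.
#' @param basepairs optional pairing data.frame for groove analysis.
#' @param ring_a,ring_b optional ring selections for the centroid-distance
#'   stage.
#' @param output_dir report directory.
#' @param seed seed recorded with the run.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(topology, trajectories, reference = NULL,
                            fit_selection = "protein and name CA",
                            calc_selection = "dna",
                            hbond_dist = 4.0, hbond_angle = 120,
                            salt_dist = 5.0, prune = 0.15,
                            qc_threshold = 4.0, tail_frames = 1000,
                            node_map = NULL, basepairs = NULL,
                            ring_a = NULL, ring_b = NULL,
                            output_dir = tempfile("dyadmd_run_"),
                            seed = 1) {
  if (is.character(trajectories))
    trajectories <- lapply(seq_along(trajectories), function(i)
      load_trajectory(topology, trajectories[i],
                      replica_id = paste0("r", i)))
  structure(list(topology = topology, trajectories = trajectories,
                 reference = reference,
                 fit_selection = fit_selection,
                 calc_selection = calc_selection,
                 hbond_dist = hbond_dist, hbond_angle = hbond_angle,
                 salt_dist = salt_dist, prune = prune,
                 qc_threshold = qc_threshold, tail_frames = tail_frames,
                 node_map = node_map, basepairs = basepairs,
                 ring_a = ring_a, ring_b = ring_b,
                 output_dir = output_dir, seed = seed),
            class = "pipeline_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full post-processing pipeline
#'
#' Stages: replica QC (exclusion by mean tail RMSD) -> tail slicing and
#' merging of the passing replicas -> contact detection and time series ->
#' occupancy-pruned interaction network -> RMSD traces and RMSF profile ->
#' groove widths (skipped with a notice when no base-pair map is
#' configured) -> ring-centroid distances (when configured). Every table is
#' written as TSV into `output_dir`, the network additionally as GraphML,
#' and a machine-readable `summary.json` records the resolved scalar
#' configuration plus MD5 hashes of every written table. Identical config
#' and inputs yield byte-identical tables.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) list with the QC table, merged series, network,
#'   RMSF profile, groove profile (or NULL) and the summary.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  top <- config$topology
  if (!any(top$atoms$donor) && !any(!is.na(top$atoms$charge_group)))
    top <- annotate_chemistry(top)
  ref <- config$reference %||% top$xyz %||%
    frame_xyz(config$trajectories[[1]], 1)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop_dyadmd("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }

  qc <- stage("qc", qc_replicas(config$trajectories, config$fit_selection,
                                config$calc_selection, reference = ref,
                                threshold = config$qc_threshold,
                                tail_frames = config$tail_frames))
  write_tsv(qc, file.path(config$output_dir, "qc_report.tsv"))
  passing <- config$trajectories[qc$status == "pass"]
  if (!length(passing)) stop_dyadmd("pipeline stage 'qc' failed: no replica passed QC")

  sliced <- stage("slice", lapply(passing, function(tr) {
    if (is.null(config$tail_frames)) tr
    else slice_tail(tr, last_n_frames = min(config$tail_frames, n_frames(tr)))
  }))

  series <- stage("contacts", {
    per_rep <- lapply(sliced, function(tr) {
      tr$topology <- top
      contact_time_series(tr, hbond_dist = config$hbond_dist,
                          hbond_angle = config$hbond_angle,
                          salt_dist = config$salt_dist)
    })
    merge_series(per_rep)
  })
  write_tsv(series_table(series),
            file.path(config$output_dir, "contact_series.tsv"))

  node_map <- config$node_map %||% make_node_map(top)
  network <- stage("network", build_network(series, node_map,
                                            prune_occupancy = config$prune))
  write_tsv(as.data.frame(network),
            file.path(config$output_dir, "network_edges.tsv"))
  export_network(network, file.path(config$output_dir, "network.graphml"),
                 "graphml")

  rmsd_tabs <- stage("rmsd", lapply(sliced, function(tr)
    cbind(replica_id = tr$replica_id,
          rmsd_series(tr, config$fit_selection, config$calc_selection,
                      reference = ref))))
  write_tsv(do.call(rbind, rmsd_tabs),
            file.path(config$output_dir, "rmsd.tsv"))

  merged <- stage("merge", merge_trajectories(sliced))
  merged$topology <- top
  rmsf <- stage("rmsf", rmsf_profile(merged, config$fit_selection))
  write_tsv(as.data.frame(rmsf), file.path(config$output_dir, "rmsf.tsv"))

  grooves <- NULL
  if (!is.null(config$basepairs)) {
    grooves <- stage("grooves", {
      pm <- assign_base_pairs(top, config$basepairs)
      groove_widths(merged, pm)
    })
    write_tsv(grooves$summary, file.path(config$output_dir, "grooves.tsv"))
  } else {
    message("run_pipeline: no base-pair map configured; groove stage skipped")
  }

  ringdist <- NULL
  if (!is.null(config$ring_a) && !is.null(config$ring_b)) {
    ringdist <- stage("ringdist",
                      ring_distance_series(merged, config$ring_a, config$ring_b))
    write_tsv(data.frame(frame = seq_along(ringdist$samples),
                         distance = ringdist$samples),
              file.path(config$output_dir, "ring_distances.tsv"))
  }

  tables <- list.files(config$output_dir, pattern = "\\.tsv$|\\.graphml$",
                       full.names = TRUE)
  hashes <- tools::md5sum(sort(tables))
  names(hashes) <- basename(names(hashes))
  resolved <- config[!(names(config) %in%
                       c("topology", "trajectories", "reference",
                         "node_map", "basepairs"))]
  resolved <- lapply(resolved, function(x) if (is.null(x)) NA else x)
  summary <- list(config = resolved,
                  n_replicas = length(config$trajectories),
                  n_excluded = sum(qc$status == "excluded"),
                  n_frames_merged = series$n_frames,
                  n_edges = nrow(network),
                  table_md5 = as.list(hashes))
  jsonlite::write_json(summary, file.path(config$output_dir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  yaml::write_yaml(resolved, file.path(config$output_dir, "config.yaml"))
  invisible(list(qc = qc, series = series, network = network, rmsf = rmsf,
                 grooves = grooves, ringdist = ringdist, summary = summary))
}
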