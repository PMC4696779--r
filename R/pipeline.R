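# Config-driven end-to-end pipeline: align -> fluctuation -> DCCM/PCA/
# clustering -> network/communities/paths, with a machine-readable
# summary.  Identical config + seed gives a byte-identical summary.

#' Assemble and validate a pipeline configuration
#'
#' @param trajectory path to a multi-model PDB file, or an
#'   [md_trajectory()] object.
#' @param contact_cutoff contact distance cutoff, Angstrom.
#' @param persistence_min minimum contact fraction for an edge
#'   (fraction of the trajectory, in [0, 1]).
#' @param contact_mode `"anchor"` or `"heavy"`.
#' @param exclude_neighbors sequence-neighbor exclusion for edges.
#' @param cluster_k number of conformer clusters.
#' @param cluster_components PC indices spanning the clustering space.
#' @param elbow_k_max largest k in the elbow scan (NULL to skip).
#' @param path_source,path_target node labels for path analysis (NULL
#'   to skip paths).
#' @param path_delta suboptimal tolerance (NULL for 0.2 * L_opt).
#' @param group_a,group_b optional node-label groups (e.g. the two
#'   lobes); when given, block statistics of the DCCM and the distance
#'   deviation map are reported.
#' @param reference_frame alignment reference.
#' @param seed RNG seed, recorded in every output.
#' @param out_dir output directory (NULL: nothing written).
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(trajectory,
                            contact_cutoff = 4.5,
                            persistence_min = 0.75,
                            contact_mode = "anchor",
                            exclude_neighbors = 1L,
                            cluster_k = 4L,
                            cluster_components = c(1L, 2L),
                            elbow_k_max = 8L,
                            path_source = NULL,
                            path_target = NULL,
                            path_delta = NULL,
                            group_a = NULL,
                            group_b = NULL,
                            reference_frame = 1L,
                            seed = 1L,
                            out_dir = NULL) {
  cfg <- list(trajectory = trajectory, contact_cutoff = contact_cutoff,
              persistence_min = persistence_min, contact_mode = contact_mode,
              exclude_neighbors = as.integer(exclude_neighbors),
              cluster_k = as.integer(cluster_k),
              cluster_components = as.integer(cluster_components),
              elbow_k_max = if (is.null(elbow_k_max)) NULL else as.integer(elbow_k_max),
              path_source = path_source, path_target = path_target,
              path_delta = path_delta, group_a = group_a, group_b = group_b,
              reference_frame = as.integer(reference_frame),
              seed = as.integer(seed), out_dir = out_dir)
  validate_pipeline_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_pipeline_config <- function(cfg) {
  stopifnot_scalar_number(cfg$contact_cutoff, "contact_cutoff", lower = 1e-6)
  if (!is.numeric(cfg$persistence_min) || cfg$persistence_min < 0 ||
      cfg$persistence_min > 1)
    stop("invalid config: persistence_min must be a fraction in [0, 1]")
  if (!cfg$contact_mode %in% c("anchor", "heavy"))
    stop("invalid config: contact_mode must be 'anchor' or 'heavy'")
  if (cfg$exclude_neighbors < 0)
    stop("invalid config: exclude_neighbors must be >= 0")
  if (cfg$cluster_k < 1) stop("invalid config: cluster_k must be >= 1")
  if (any(cfg$cluster_components < 1))
    stop("invalid config: cluster_components must be positive indices")
  if (xor(is.null(cfg$path_source), is.null(cfg$path_target)))
    stop("invalid config: path_source and path_target must be given together")
  invisible(cfg)
}

config_fingerprint <- function(cfg) {
  ser <- cfg[setdiff(names(cfg), c("trajectory", "out_dir"))]
  ser$trajectory <- if (is.character(cfg$trajectory)) basename(cfg$trajectory)
  else "in-memory"
  fnv1a(jsonlite::toJSON(ser, auto_unbox = TRUE, digits = 12, null = "null"))
}

pipeline_log <- function(stage, msg, logfile = NULL) {
  line <- sprintf("[%s] %-10s %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
  message(line)
  if (!is.null(logfile)) cat(line, "\n", file = logfile, append = TRUE)
}

#' Run the full trajectory-analysis pipeline
#'
#' Stages: read/validate input, superpose onto the reference frame,
#' RMSD/RMSF, distance deviation map, DCCM, covariance PCA with
#' clustering and elbow scan, contact-persistence network,
#' Girvan-Newman communities, betweenness, critical nodes, and
#' (when endpoints are configured) optimal/suboptimal paths.  A failed
#' stage halts the pipeline with the stage name and cause.
#'
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_report` with all stage results and a
#'   `summary` list (written as `summary.json` with TSV companions when
#'   `out_dir` is set).
#' @export
run_pipeline <- function(config) {
  validate_pipeline_config(config)
  cfg <- config
  out_dir <- cfg$out_dir
  logfile <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    logfile <- file.path(out_dir, "run.log")
    cat(sprintf("pipeline run, seed %d, config %s\n",
                cfg$seed, config_fingerprint(cfg)), file = logfile)
  }
  stage <- function(name, expr) {
    pipeline_log(name, "start", logfile)
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }

  traj <- stage("input", {
    if (inherits(cfg$trajectory, "md_trajectory")) cfg$trajectory
    else read_trajectory(cfg$trajectory)
  })
  nmap <- stage("nodes", build_node_map(traj$topology))
  aligned <- stage("align", align_trajectory(traj,
                                             reference_frame = cfg$reference_frame))
  rmsd <- stage("rmsd", rmsd_series(aligned, reference = cfg$reference_frame,
                                    align = FALSE))
  rmsf <- stage("rmsf", rmsf_profile(aligned, aligned = TRUE))
  devmap <- stage("devmap", distance_deviation_map(traj, nmap))
  cmat <- stage("dccm", dccm(aligned, nmap, align = FALSE))
  pca <- stage("pca", pca_fit(aligned, nmap, align = FALSE))
  proj <- pca$projections[, cfg$cluster_components, drop = FALSE]
  clus <- stage("cluster", kmeans_cluster(proj, cfg$cluster_k, seed = cfg$seed))
  hclus <- stage("cluster", hierarchical_cluster(proj, cfg$cluster_k))
  elbow <- if (!is.null(cfg$elbow_k_max) && cfg$elbow_k_max >= 2)
    stage("elbow", elbow_scan(proj, cfg$elbow_k_max, seed = cfg$seed)) else NULL
  contacts <- stage("contacts", contact_persistence(
    traj, nmap, cutoff = cfg$contact_cutoff, mode = cfg$contact_mode))
  net <- stage("network", build_network(contacts, cmat,
                                        persistence_min = cfg$persistence_min,
                                        exclude_neighbors = cfg$exclude_neighbors))
  comm <- stage("community", girvan_newman(net))
  centr <- stage("betweenness", network_betweenness(net))
  crit <- stage("critical", critical_nodes(net, comm, centr))
  paths <- NULL
  if (!is.null(cfg$path_source))
    paths <- stage("paths", suboptimal_paths(net, cfg$path_source,
                                             cfg$path_target,
                                             delta = cfg$path_delta))

  block <- NULL
  if (!is.null(cfg$group_a) && !is.null(cfg$group_b)) {
    ia <- match(cfg$group_a, nmap$label); ib <- match(cfg$group_b, nmap$label)
    if (anyNA(ia) || anyNA(ib))
      stop("pipeline stage 'blocks' failed: unknown node label in group_a/group_b")
    block <- list(
      dccm_inter_mean = mean(cmat[ia, ib]),
      dccm_intra_a_mean = mean(cmat[ia, ia][upper.tri(cmat[ia, ia])]),
      dccm_intra_b_mean = mean(cmat[ib, ib][upper.tri(cmat[ib, ib])]),
      deviation_ratio = block_deviation_ratio(devmap, cfg$group_a, cfg$group_b))
  }

  round10 <- function(x) round(x, 10)
  summary <- list(
    seed = cfg$seed,
    config_hash = config_fingerprint(cfg),
    n_frames = n_frames(traj),
    n_nodes = nrow(nmap),
    rmsd = list(mean = round10(mean(rmsd)), min = round10(min(rmsd)),
                max = round10(max(rmsd))),
    rmsf = list(mean = round10(mean(rmsf$rmsf)), max = round10(max(rmsf$rmsf))),
    dccm = list(mean_offdiag = round10(mean(cmat[upper.tri(cmat)])),
                min = round10(min(cmat)), block = lapply(block, round10)),
    pca = list(fractions = round10(pca$fractions[seq_len(min(10, length(pca$fractions)))]),
               total_variance = round10(pca$total_variance)),
    clustering = list(k = clus$k, bss_tss = round10(clus$bss_tss),
                      method_agreement_ari =
                        round10(adjusted_rand_index(clus$labels, hclus$labels)),
                      elbow_suggested_k = if (is.null(elbow)) NULL else elbow$suggested_k,
                      elbow_low_confidence = if (is.null(elbow)) NULL else elbow$low_confidence),
    network = list(n_edges = nrow(net$edges),
                   n_communities = comm$n_communities,
                   modularity = round10(comm$modularity),
                   critical_nodes = crit),
    paths = if (is.null(paths)) NULL else list(
      source = paths$source, target = paths$target,
      n_paths = length(paths$paths),
      optimal = paths$optimal,
      optimal_length = round10(paths$optimal_length),
      delta = round10(paths$delta),
      truncated = paths$truncated))

  if (!is.null(out_dir)) {
    stage("write", {
      hdr <- sprintf("# seed=%d config=%s", cfg$seed, summary$config_hash)
      write_tsv <- function(df, name) {
        path <- file.path(out_dir, name)
        cat(hdr, "\n", file = path)
        suppressWarnings(utils::write.table(df, path, sep = "\t", quote = FALSE,
                                            row.names = FALSE, append = TRUE))
        path
      }
      write_tsv(data.frame(frame = seq_along(rmsd), rmsd = rmsd), "rmsd.tsv")
      write_tsv(data.frame(label = nmap$label[match(rmsf$atom, nmap$atom)],
                           rmsf = rmsf$rmsf), "rmsf.tsv")
      utils::write.table(format(unclass(cmat), digits = 8),
                         file.path(out_dir, "dccm.tsv"),
                         sep = "\t", quote = FALSE)
      write_tsv(data.frame(rank = seq_along(pca$values),
                           eigenvalue = pca$values,
                           fraction = pca$fractions,
                           cumulative = cumsum(pca$fractions)), "scree.tsv")
      write_tsv(data.frame(frame = seq_along(clus$labels),
                           kmeans = clus$labels, hierarchical = hclus$labels),
                "clusters.tsv")
      write_tsv(data.frame(node = names(comm$membership),
                           community = as.vector(comm$membership)),
                "communities.tsv")
      write_network(net, graphml = file.path(out_dir, "network.graphml"),
                    edges = file.path(out_dir, "edges.tsv"))
      if (!is.null(paths))
        write_tsv(data.frame(rank = seq_along(paths$paths),
                             length = paths$lengths,
                             path = vapply(paths$paths, paste, character(1),
                                           collapse = "-")), "paths.tsv")
      jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                           auto_unbox = TRUE, digits = NA, null = "null",
                           pretty = TRUE)
    })
  }
  pipeline_log("done", "pipeline complete", logfile)
  structure(list(config = cfg, summary = summary, trajectory = aligned,
                 node_map = nmap, rmsd = rmsd, rmsf = rmsf,
                 deviation_map = devmap, dccm = cmat, pca = pca,
                 clusters = clus, hclusters = hclus, elbow = elbow,
                 contacts = contacts, network = net, communities = comm,
                 centrality = centr, critical_nodes = crit, paths = paths),
            class = "pipeline_report")
}

#' Write a named synthetic fixture to disk
#'
#' Generates one of the built-in synthetic worlds, writes the
#' trajectory as a multi-model PDB and the planted ground truth as JSON
#' (node groups, bridge labels or planted covariance summary), for use
#' by test harnesses and as pipeline input.
#'
#' Available specs: `"two-lobe-default"` (clamshell + twist two-lobe
#' mechanism) and `"gaussian-antiblock"` (two-block Gaussian ensemble
#' with anti-correlated blocks).
#'
#' @param name fixture name.
#' @param seed RNG seed override.
#' @param out_dir output directory.
#' @param overrides named list of spec-field overrides.
#' @return invisibly, list with `trajectory` and `truth` file paths and
#'   the truth object.
#' @export
simulate_fixture <- function(name, seed = 1L, out_dir = ".",
                             overrides = list()) {
  known <- c("two-lobe-default", "gaussian-antiblock")
  if (!name %in% known)
    stop("unknown fixture spec '", name, "'; available: ",
         paste(known, collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (name == "two-lobe-default") {
    args <- utils::modifyList(list(seed = as.integer(seed)), overrides)
    spec <- do.call(two_lobe_spec, args)
    traj <- generate_two_lobe_trajectory(spec)
    truth <- attr(traj, "truth")
  } else {
    n_half <- overrides$n_half %||% 20L
    n_frames <- overrides$n_frames %||% 2000L
    plant <- planted_block_covariance(c(n_half, n_half),
                                      intra = overrides$intra %||% 0.7,
                                      inter = overrides$inter %||% -0.6,
                                      var = overrides$var %||% 0.25)
    mean_structure <- grid_cluster(2L * n_half, spacing = 3.8)
    spec <- gaussian_ensemble_spec(mean_structure, plant$covariance,
                                   n_frames = n_frames, seed = as.integer(seed))
    traj <- generate_gaussian_ensemble(spec)
    ev_min <- min(eigen(plant$covariance, symmetric = TRUE,
                        only.values = TRUE)$values)
    truth <- list(block = plant$block,
                  node_correlation_intra = overrides$intra %||% 0.7,
                  node_correlation_inter = overrides$inter %||% -0.6,
                  covariance_min_eigenvalue = ev_min,
                  labels = paste0("ALA", seq_len(2L * n_half)),
                  seed = as.integer(seed))
  }
  traj_path <- file.path(out_dir, paste0(name, ".pdb"))
  truth_path <- file.path(out_dir, paste0(name, "-truth.json"))
  write_trajectory(traj, traj_path)
  jsonlite::write_json(truth, truth_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(trajectory = traj_path, truth = truth_path,
                 truth_data = truth))
}
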