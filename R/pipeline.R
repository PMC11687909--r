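# End-to-end orchestration: acquire tracks (synthetic render, label-mask
# stacks on disk, or a tracker CSV), filter by duration, extract the
# per-cell feature table, cluster morphologies, discriminate clusters in
# speed-persistence space, and classify subtypes. Artifacts are plain CSV
# / JSON; the manifest records seeds, per-stage counts and file hashes so
# any run can be reproduced or resumed.

#' Per-cell feature table from tracks
#'
#' Joins first-frame morphology (when region masks are available) and
#' whole-track motility for every track. Tracks shorter than 2 frames are
#' skipped (speed is undefined).
#'
#' @param tracks a `track_list`.
#' @return Data frame with one row per cell: identifiers, duration, the
#'   four morphology descriptors (NA without masks) and the three
#'   motility scalars.
#' @export
feature_table <- function(tracks) {
  rows <- lapply(tracks, function(tr) {
    if (length(tr$frames) < 2L) return(NULL)
    mo <- motility_features(tr)
    mf <- if (!is.null(tr$regions)) {
      morph_features(tr)
    } else {
      data.frame(eccentricity = NA_real_, solidity = NA_real_,
                 compactness = NA_real_, cell_size = NA_real_)
    }
    cbind(data.frame(cell_id = tr$cell_id, parent_label = tr$parent_label,
                     n_frames = length(tr$frames),
                     duration_min = tr$duration_min),
          mf,
          data.frame(speed = mo$speed_final,
                     persistence = mo$persistence_final,
                     hull_area = mo$hull_area_px2))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Pipeline run configuration
#'
#' @param mode `"synthetic"` (render label stacks in memory), `"masks"`
#'   (read label stacks from disk) or `"tracks"` (read a tracker CSV).
#' @param out_dir output directory for artifacts.
#' @param seed global seed; stages derive their own seeds from it by
#'   fixed offsets so each stage is independently reproducible.
#' @param synthetic named list of [synthetic_config()] objects (one per
#'   parent label); `NULL` in synthetic mode builds small M0/M1/M2
#'   defaults.
#' @param mask_paths named character vector of stack paths per parent
#'   label (masks mode).
#' @param tracks_csv tracker CSV path (tracks mode).
#' @param frame_interval_min frame interval for masks/tracks input.
#' @param min_minutes track-duration filter.
#' @param k,k_range clustering controls (see [cluster_morphology()]).
#' @param classifier_seeds CV seeds for [compare_feature_sets()];
#'   `NULL` skips the classifier stage comparison and runs a single CV
#'   per feature set.
#' @export
pipeline_config <- function(mode = c("synthetic", "masks", "tracks"),
                            out_dir,
                            seed = 0L,
                            synthetic = NULL,
                            mask_paths = NULL,
                            tracks_csv = NULL,
                            frame_interval_min = 5,
                            min_minutes = 60,
                            k = NULL, k_range = 2:5,
                            classifier_seeds = NULL) {
  mode <- match.arg(mode)
  if (mode == "masks" && is.null(mask_paths))
    stop_macmot("masks mode needs mask_paths")
  if (mode == "tracks" && is.null(tracks_csv))
    stop_macmot("tracks mode needs tracks_csv")
  structure(list(mode = mode, out_dir = out_dir, seed = as.integer(seed),
                 synthetic = synthetic, mask_paths = mask_paths,
                 tracks_csv = tracks_csv,
                 frame_interval_min = frame_interval_min,
                 min_minutes = min_minutes, k = k, k_range = k_range,
                 classifier_seeds = classifier_seeds),
            class = "pipeline_config")
}

stage <- function(name, out_dir, expr) {
  tryCatch(expr, error = function(e) {
    marker <- file.path(out_dir, paste0(name, ".failed"))
    try(writeLines(conditionMessage(e), marker), silent = TRUE)
    stop_macmot("stage '", name, "' failed: ", conditionMessage(e))
  })
}

#' Run the full analysis pipeline
#'
#' Executes acquire -> filter -> features -> cluster -> discriminate ->
#' classify, writing `features.csv`, `clusters.csv`, `silhouette.csv`,
#' `qda_pairs.csv`, `classifier_<set>.json` and `manifest.json` into
#' `config$out_dir`. Deterministic given `config$seed`. A failing stage
#' aborts with a stage-named error and leaves a `<stage>.failed` marker;
#' artifacts of completed stages are retained.
#'
#' @param config a [pipeline_config()].
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()

  tracks <- stage("acquire", config$out_dir, {
    if (config$mode == "synthetic") {
      cfgs <- config$synthetic %||% default_synthetic_panel(config$seed)
      all <- list()
      for (pl in names(cfgs)) {
        coh <- render_cohort(cfgs[[pl]])
        tr <- link_tracks(extract_regions(coh$stack),
                          parent_label = pl)
        all <- c(all, tr)
      }
      structure(all, class = "track_list")
    } else if (config$mode == "masks") {
      all <- list()
      for (pl in names(config$mask_paths)) {
        st <- read_label_stack(config$mask_paths[[pl]],
                               config$frame_interval_min)
        all <- c(all, link_tracks(extract_regions(st), parent_label = pl))
      }
      structure(all, class = "track_list")
    } else {
      read_track_table(config$tracks_csv, config$frame_interval_min)
    }
  })
  counts$tracks_raw <- length(tracks)

  tracks <- stage("filter", config$out_dir,
                  filter_min_duration(tracks, config$min_minutes))
  counts$tracks_kept <- length(tracks)
  if (!counts$tracks_kept)
    stop_macmot("stage 'filter' failed: no track survives the ",
                config$min_minutes, "-minute filter")

  feats <- stage("features", config$out_dir, {
    ft <- feature_table(tracks)
    ft$cell_id <- seq_len(nrow(ft))     # re-key across parents
    write.csv(ft, file.path(config$out_dir, "features.csv"),
              row.names = FALSE)
    ft
  })
  counts$cells <- nrow(feats)

  clus <- stage("cluster", config$out_dir, {
    if (any(is.na(feats$compactness))) {
      NULL    # tracks-only input without masks: no morphology stage
    } else {
      cl <- cluster_morphology(feats, k = config$k, k_range = config$k_range,
                               seed = config$seed + 101L)
      write.csv(cl$table, file.path(config$out_dir, "clusters.csv"),
                row.names = FALSE)
      if (!is.null(cl$silhouette_by_k))
        write.csv(data.frame(k = as.integer(names(cl$silhouette_by_k)),
                             mean_silhouette = cl$silhouette_by_k),
                  file.path(config$out_dir, "silhouette.csv"),
                  row.names = FALSE)
      cl
    }
  })
  if (!is.null(clus)) counts$k <- clus$k

  qda <- stage("discriminate", config$out_dir, {
    tab <- if (!is.null(clus)) clus$table else feats
    grouping <- if (!is.null(clus)) "cluster_name" else "parent_label"
    res <- suppressWarnings(
      run_pairwise_discrimination(tab, grouping = grouping,
                                  seed = config$seed + 202L))
    if (!is.null(res))
      write.csv(res[, c("pair", "n_a", "n_b", "mean_accuracy")],
                file.path(config$out_dir, "qda_pairs.csv"),
                row.names = FALSE)
    res
  })

  reports <- stage("classify", config$out_dir, {
    have_morph <- !any(is.na(feats$compactness))
    sets <- if (have_morph) c("morphology", "motility", "combined") else "motility"
    out <- list()
    for (fs in sets) {
      rep <- run_cv_experiment(feats, feature_set = fs,
                               seed = config$seed + 303L)
      jsonlite::write_json(
        list(feature_set = fs,
             overall_accuracy = rep$overall_accuracy,
             per_class_accuracy = as.list(rep$per_class_accuracy),
             confusion_pct = as.data.frame(unclass(rep$confusion_pct)),
             config = rep$config),
        file.path(config$out_dir, paste0("classifier_", fs, ".json")),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      out[[fs]] <- rep
    }
    out
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("macmot")),
    r_version = as.character(getRversion()),
    seed = config$seed,
    mode = config$mode,
    counts = counts,
    classifier_overall = lapply(reports, `[[`, "overall_accuracy"),
    artifacts = local({
      fs <- list.files(config$out_dir, full.names = TRUE,
                       pattern = "\\.(csv|json)$")
      fs <- fs[basename(fs) != "manifest.json"]
      as.list(setNames(unname(tools::md5sum(fs)), basename(fs)))
    })
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# small default M0/M1/M2 synthetic panel for smoke runs
default_synthetic_panel <- function(seed, n_cells = 12L, n_frames = 15L,
                                    image_size_px = c(768L, 768L)) {
  list(
    M0 = synthetic_config("M0", n_cells = n_cells, n_frames = n_frames,
                          image_size_px = image_size_px, rng_seed = seed + 1L),
    M1 = synthetic_config("M1", n_cells = n_cells, n_frames = n_frames,
                          image_size_px = image_size_px, rng_seed = seed + 2L),
    M2 = synthetic_config("M2", n_cells = n_cells, n_frames = n_frames,
                          image_size_px = image_size_px, rng_seed = seed + 3L)
  )
}
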