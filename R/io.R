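#' Read and validate a track table
#'
#' Strictly validated CSV reader for per-cell, per-frame 3D tracks. The
#' header must be exactly `cell_id, identity, frame, t_min, x_um, y_um,
#' z_um` (unit suffixes assert um/minutes; an optional trailing `area_um2`
#' column is accepted). Frames must be strictly increasing with a constant
#' interval within each cell, identities constant per cell, and
#' `(cell_id, frame)` unique; violations are reported with row numbers.
#'
#' @param path CSV file path.
#' @return validated track table data.frame.
#' @export
read_track_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- read.csv(path, stringsAsFactors = FALSE)
  validate_track_table(tab)
  tab
}

#' @rdname read_track_table
#' @param table a track table data.frame.
#' @export
validate_track_table <- function(table) {
  req <- c("cell_id", "identity", "frame", "t_min", "x_um", "y_um", "z_um")
  if (!all(req %in% names(table)))
    stop("track table must have columns ", paste(req, collapse = ", "),
         "; missing: ", paste(setdiff(req, names(table)), collapse = ", "))
  extra <- setdiff(names(table), c(req, "area_um2"))
  if (length(extra) > 0)
    stop("unexpected track-table column(s): ", paste(extra, collapse = ", "))
  key <- paste(table$cell_id, table$frame)
  if (anyDuplicated(key)) {
    rows <- which(duplicated(key))
    stop("duplicated (cell_id, frame) at row(s) ",
         paste(head(rows, 5), collapse = ", "))
  }
  if (!all(table$identity %in% c("leader", "follower")))
    stop("identity must be 'leader' or 'follower'")
  for (cid in unique(table$cell_id)) {
    idx <- which(table$cell_id == cid)
    fr <- table$frame[idx]
    o <- order(fr)
    if (any(diff(fr[o]) <= 0))
      stop("cell ", cid, ": frames not strictly increasing (rows ",
           paste(head(idx[o][which(diff(fr[o]) <= 0)], 3), collapse = ", "),
           ")")
    tt <- table$t_min[idx][o]
    if (length(tt) > 2 && max(abs(diff(tt) - diff(tt)[1])) > 1e-6)
      stop("cell ", cid, ": inconsistent frame interval")
    if (length(unique(table$identity[idx])) != 1)
      stop("cell ", cid, ": identity changes between frames")
  }
  invisible(table)
}

#' @rdname read_track_table
#' @export
write_track_table <- function(table, path) {
  validate_track_table(table)
  write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export a simulated trajectory as a track table
#'
#' Converts a [trajectory()] to the tidy track-table format shared with
#' the in vivo data (`z_um` emitted as 0).
#'
#' @param traj a `tnc_trajectory`.
#' @return a track table data.frame.
#' @export
as_track_table <- function(traj) {
  df <- as.data.frame(traj)
  df$cell_id <- sprintf("sim_%03d", df$cell_id)
  df
}

#' Derive a stage seed from the master seed
#'
#' Stable integer hash of (master seed, stage name, replicate index); all
#' randomness in the pipeline flows from the master seed through this
#' function, and the result always fits in a 32-bit integer.
#'
#' @param master integer master seed.
#' @param stage stage name.
#' @param index replicate index.
#' @return integer seed.
#' @export
derive_seed <- function(master, stage, index = 0) {
  h <- 0
  for (ch in utf8ToInt(as.character(stage)))
    h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(master) %% 2147483647 + h * 7919 +
                as.numeric(index) * 104729) %% 2147483647)
}

#' Run the end-to-end analysis pipeline
#'
#' Executes the configured stages in order (`synth`, `simulate`, `score`,
#' `metrics`, `lda`, `cellcycle`), each consuming the previous stage's
#' outputs, writing CSV/JSON results plus a run manifest into `out_dir`.
#' The configuration is validated before any computation; reruns with the
#' same config and seed produce byte-identical numeric outputs.
#'
#' @param config path to a JSON configuration file, or an equivalent
#'   list. Keys: `seed` (integer), `stages` (character vector), and
#'   optional per-stage settings (`simulate`: `composition`, `n_cells`;
#'   `synth`: `n_leaders`, `n_followers`, `n_cells_cycle`).
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (is.character(config)) {
    if (!file.exists(config)) stop("no such config file: ", config)
    jsonlite::read_json(config, simplifyVector = TRUE)
  } else config
  known <- c("synth", "simulate", "score", "metrics", "lda", "cellcycle")
  if (is.null(cfg$stages) || length(cfg$stages) == 0)
    stop("configuration error: no stages declared")
  bad <- setdiff(cfg$stages, known)
  if (length(bad) > 0)
    stop("configuration error: unknown stage(s) ",
         paste(bad, collapse = ", "))
  if (is.null(cfg$seed)) stop("configuration error: missing 'seed'")
  needs <- list(score = "simulate", lda = c("synth", "metrics"),
                metrics = "synth", cellcycle = "synth")
  for (st in cfg$stages) {
    pre <- needs[[st]]
    if (!is.null(pre) && !all(pre %in% cfg$stages))
      stop("configuration error: stage '", st, "' requires stage(s) ",
           paste(setdiff(pre, cfg$stages), collapse = ", "))
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)
  arena_ <- arena()
  gcfg <- generator_config(seed)
  results <- list()

  for (st in cfg$stages) {
    if (st == "synth") {
      nl <- cfg$synth$n_leaders %||% 15
      nf <- cfg$synth$n_followers %||% 45
      tracks <- gen_tracks(nl, nf, gcfg, seed = derive_seed(seed, "synth", 1))
      write_track_table(tracks, file.path(out_dir, "synthetic_tracks.csv"))
      states <- rbind(
        gen_phase_sequences("leader", cfg$synth$n_cells_cycle %||% 20, gcfg,
                            seed = derive_seed(seed, "synth", 2)),
        gen_phase_sequences("follower", cfg$synth$n_cells_cycle %||% 20,
                            gcfg, seed = derive_seed(seed, "synth", 3)))
      write.csv(states, file.path(out_dir, "synthetic_states.csv"),
                row.names = FALSE, quote = FALSE)
      results$tracks <- tracks
      results$states <- states
    } else if (st == "simulate") {
      comp <- composition_preset(cfg$simulate$composition %||% "1:3",
                                 cfg$simulate$n_cells %||% 8)
      traj <- simulate_chain(comp, arena_, model_params(),
                             seed = derive_seed(seed, "simulate", 1))
      write_track_table(as_track_table(traj),
                        file.path(out_dir, "simulated_tracks.csv"))
      results$trajectory <- traj
    } else if (st == "score") {
      rep_ <- score_all(results$trajectory, arena_)
      jsonlite::write_json(
        lapply(rep_[1:5], function(r) lapply(r, unclass)),
        file.path(out_dir, "score_report.json"), auto_unbox = TRUE,
        digits = NA)
      results$score <- rep_
    } else if (st == "metrics") {
      sm <- summarize_tracks(results$tracks)
      write.csv(sm$cells, file.path(out_dir, "cell_metrics.csv"),
                row.names = FALSE, quote = FALSE)
      jsonlite::write_json(sm$aggregates,
                           file.path(out_dir, "identity_aggregates.json"),
                           auto_unbox = TRUE, digits = NA)
      results$metrics <- sm
    } else if (st == "lda") {
      feat <- data.frame(ventral_distance = results$metrics$cells$ventral_distance,
                         mean_speed = results$metrics$cells$mean_speed,
                         directionality = results$metrics$cells$directionality,
                         label = results$metrics$cells$identity)
      model <- fit_lda(feat)
      out <- list(ranking = rank_features(model),
                  coefficients = as.list(model$coefficients),
                  coefficients_raw = as.list(model$coefficients_raw),
                  separation = model$separation)
      jsonlite::write_json(out, file.path(out_dir, "lda_summary.json"),
                           auto_unbox = TRUE, digits = NA)
      results$lda <- model
    } else if (st == "cellcycle") {
      dur <- durations_from_states(results$states)
      write.csv(dur, file.path(out_dir, "phase_durations.csv"),
                row.names = FALSE, quote = FALSE)
      g1 <- dur$G1[dur$identity == "follower" & !is.na(dur$G1)]
      mix <- if (length(g1) >= 10)
        fit_mixture(g1, seed = derive_seed(seed, "cellcycle", 1)) else NULL
      if (!is.null(mix))
        jsonlite::write_json(
          list(k = mix$k, weights = mix$weights, means = mix$means,
               sds = mix$sds, minor_weight = mix$minor_weight),
          file.path(out_dir, "follower_g1_mixture.json"),
          auto_unbox = TRUE, digits = NA)
      results$cellcycle <- dur
    }
  }

  manifest <- list(command = "run_pipeline",
                   config_hash = config_hash(cfg),
                   master_seed = seed,
                   package_version = as.character(packageVersion("crestchain")),
                   stages = cfg$stages,
                   out_dir = normalizePath(out_dir),
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Order-independent structural hash of the configuration.
config_hash <- function(cfg) {
  s <- jsonlite::toJSON(cfg[order(names(cfg))], auto_unbox = TRUE)
  h <- 0
  for (ch in utf8ToInt(as.character(s))) h <- (h * 131 + ch) %% 2147483647
  sprintf("%08x", h)
}
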