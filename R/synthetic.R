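#' Default configuration of the synthetic-data generators
#'
#' All defaults are the published summary statistics of the in vivo
#' measurements: cell-cycle phase durations (leaders: G1 3.2 +/- 0.6 h,
#' S 8.7 +/- 1.3 h, G2 1.6 +/- 0.4 h, M 0.6 +/- 0.1 h; followers: G2
#' 1.5 +/- 0.3 h, M 0.5 +/- 0.1 h), two-component follower G1/S mixtures
#' whose minor components coincide with the leader peaks (26% of followers
#' in G1, 31% in S), onset-phase probabilities (79% of leaders initiate
#' migration in S, 77% of followers in G1), and division areas
#' (asymmetric: 102 +/- 20 and 72 +/- 9 um^2; symmetric: 87 +/- 27 um^2).
#' The follower G1 major component (8.9, 1.13) is derived so that the
#' 0.26/0.74 mixture reproduces the printed overall 7.4 +/- 2.7 h; the S
#' major mean 2.76 h likewise reproduces the printed overall mean 4.6 h
#' (the printed overall SD 2.8 h is not exactly attainable; the default
#' major sd 1.0 gives 2.96 h). Track-generator contrasts are calibration
#' choices shaped to reproduce the in vivo orderings (leaders faster, more
#' ventrally biased, straighter).
#'
#' @param seed default seed carried in the config.
#' @return nested list of class `tnc_generator_config`.
#' @export
generator_config <- function(seed = 1) {
  cfg <- list(
    cellcycle = list(
      leader = list(
        G1 = list(mean = 3.2, sd = 0.6),
        S = list(mean = 8.7, sd = 1.3),
        G2 = list(mean = 1.6, sd = 0.4),
        M = list(mean = 0.6, sd = 0.1)
      ),
      follower = list(
        G1 = list(mixture = list(minor_weight = 0.26, minor_mean = 3.2,
                                 minor_sd = 0.6, major_mean = 8.9,
                                 major_sd = 1.13)),
        S = list(mixture = list(minor_weight = 0.31, minor_mean = 8.7,
                                minor_sd = 1.3, major_mean = 2.76,
                                major_sd = 1.0)),
        G2 = list(mean = 1.5, sd = 0.3),
        M = list(mean = 0.5, sd = 0.1)
      ),
      notch_inhibited = list(
        G1 = list(mean = 7.4, sd = 1.42),
        S = list(mean = 4.6, sd = 1.38),
        G2 = list(mean = 1.5, sd = 0.3),
        M = list(mean = 0.5, sd = 0.1)
      )
    ),
    onset = list(leader = list(p_onset_in_S = 0.79),
                 follower = list(p_onset_in_S = 0.23)),
    tracks = list(
      leader = list(speed_mean = 45, speed_sd = 8, ventral_bias = 0.8,
                    heading_noise = 0.6),
      follower = list(speed_mean = 32, speed_sd = 8, ventral_bias = 0.35,
                      heading_noise = 1.2)
    ),
    areas = list(
      asym = list(larger_mean = 102, larger_sd = 20, smaller_mean = 72,
                  smaller_sd = 9),
      sym = list(mean = 87, sd = 27)
    ),
    seed = seed
  )
  class(cfg) <- "tnc_generator_config"
  cfg
}

# Truncated-normal (> lower) draws by rejection; all durations and areas
# are strictly positive.
rtruncnorm_pos <- function(n, mean, sd, lower = 0) {
  out <- rnorm(n, mean, sd)
  bad <- which(out <= lower)
  while (length(bad) > 0) {
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] <= lower]
  }
  out
}

#' Draw synthetic cell-cycle phase durations
#'
#' Truncated-normal (> 0) draws from the configured per-identity,
#' per-phase distribution; follower G1 and S use the configured
#' two-component mixture (minor component = leader-like peak).
#'
#' @param identity `"leader"`, `"follower"` or `"notch_inhibited"`.
#' @param phase `"G1"`, `"S"`, `"G2"` or `"M"`.
#' @param n number of draws.
#' @param cfg a [generator_config()].
#' @param seed optional seed (`NULL` continues the current stream).
#' @return numeric vector of durations (hours).
#' @export
gen_cellcycle <- function(identity, phase, n, cfg = generator_config(),
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n >= 1)
  spec <- cfg$cellcycle[[identity]][[phase]]
  if (is.null(spec)) stop("no generator for ", identity, "/", phase)
  if (!is.null(spec$mixture)) {
    mx <- spec$mixture
    minor <- runif(n) < mx$minor_weight
    out <- numeric(n)
    out[minor] <- rtruncnorm_pos(sum(minor), mx$minor_mean, mx$minor_sd)
    out[!minor] <- rtruncnorm_pos(sum(!minor), mx$major_mean, mx$major_sd)
    out
  } else {
    rtruncnorm_pos(n, spec$mean, spec$sd)
  }
}

#' Generate per-frame phase-state sequences
#'
#' Builds PCNA-like labelled state sequences at the imaging cadence: each
#' cell gets `n_cycles` complete cycles (phase frame counts =
#' `max(1, round(duration * 60 / frame_interval))`), preceded by a short M
#' run and followed by one G1 frame so every interior phase run is bounded
#' by known phases. Optionally marks a migration-onset frame drawn
#' according to the configured onset-phase probabilities (uniformly within
#' the chosen phase's first run), and optionally left-censors a random
#' prefix.
#'
#' @param identity `"leader"`, `"follower"` or `"notch_inhibited"`.
#' @param n_cells number of cells.
#' @param cfg a [generator_config()].
#' @param frame_interval minutes per frame.
#' @param n_cycles complete cycles per cell.
#' @param onset if `TRUE`, add an `onset` column.
#' @param censor_prob probability that a cell's sequence is left-censored
#'   (loses a random prefix of its first G1 run).
#' @param seed integer seed.
#' @return data.frame with columns `cell_id`, `identity`, `frame`,
#'   `label`, and `onset` (logical) when requested.
#' @export
gen_phase_sequences <- function(identity, n_cells, cfg = generator_config(),
                                frame_interval = 5, n_cycles = 1,
                                onset = TRUE, censor_prob = 0, seed = 1) {
  set.seed(seed)
  onset_id <- if (identity == "notch_inhibited") "follower" else identity
  p_S <- cfg$onset[[onset_id]]$p_onset_in_S
  out <- vector("list", n_cells)
  for (cell in seq_len(n_cells)) {
    labels <- rep("M", 2)  # leading partial M run (left-unbounded)
    for (cy in seq_len(n_cycles)) {
      for (ph in c("G1", "S", "G2", "M")) {
        dur <- gen_cellcycle(identity, ph, 1, cfg)
        labels <- c(labels, rep(ph, max(1, round(dur * 60 / frame_interval))))
      }
    }
    labels <- c(labels, "G1")  # bound the final M run
    if (censor_prob > 0 && runif(1) < censor_prob) {
      first_g1 <- which(labels == "G1")[1]
      g1_len <- rle(labels[first_g1:length(labels)])$lengths[1]
      drop <- sample.int(g1_len, 1)
      labels <- labels[-seq_len(first_g1 - 1 + drop)]
    }
    df <- data.frame(cell_id = sprintf("%s_%03d", identity, cell),
                     identity = identity, frame = seq_along(labels) - 1L,
                     label = labels, stringsAsFactors = FALSE)
    if (onset) {
      target <- if (runif(1) < p_S) "S" else "G1"
      runs <- rle(df$label)
      ends <- cumsum(runs$lengths)
      ri <- which(runs$values == target)[1]
      idx <- if (is.na(ri)) 1L else
        ends[ri] - runs$lengths[ri] + sample.int(runs$lengths[ri], 1)
      df$onset <- seq_len(nrow(df)) == idx
    }
    out[[cell]] <- df
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate synthetic biased-random-walk tracks
#'
#' In-vivo-style track tables sampled every 5 minutes: each cell performs
#' a biased random walk whose per-frame direction blends a ventral unit
#' vector (weight = ventral bias) with a noisy heading, with per-cell
#' speeds drawn from a truncated normal. Leaders are configured faster,
#' more ventrally biased and straighter than followers. With
#' `ventral_bias = 1` and `heading_noise = 0` tracks are perfectly
#' straight (directionality 1).
#'
#' @param n_leaders,n_followers cell counts.
#' @param cfg a [generator_config()].
#' @param n_frames frames per track (default 192 = 16 h at 5 min).
#' @param frame_interval minutes per frame.
#' @param seed integer seed.
#' @return a track table data.frame (`cell_id`, `identity`, `frame`,
#'   `t_min`, `x_um`, `y_um`, `z_um`).
#' @export
gen_tracks <- function(n_leaders, n_followers, cfg = generator_config(),
                       n_frames = 192, frame_interval = 5, seed = 1) {
  set.seed(seed)
  stopifnot(n_leaders >= 0, n_followers >= 0)
  ids <- c(rep("leader", n_leaders), rep("follower", n_followers))
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    tc <- cfg$tracks[[ids[i]]]
    speed_hr <- rtruncnorm_pos(1, tc$speed_mean, tc$speed_sd)
    step_len <- speed_hr * frame_interval / 60
    xy <- matrix(0, n_frames, 2)
    xy[1, ] <- c(runif(1, 0, 30), 0)
    for (f in 2:n_frames) {
      ang <- pi / 2 + rnorm(1, 0, tc$heading_noise)
      dir <- tc$ventral_bias * c(0, 1) +
        (1 - tc$ventral_bias) * c(cos(ang), sin(ang))
      nrm <- sqrt(sum(dir^2))
      if (nrm < 1e-12) dir <- c(0, 1) else dir <- dir / nrm
      xy[f, ] <- xy[f - 1, ] + step_len * dir
    }
    out[[i]] <- data.frame(
      cell_id = sprintf("%s_%03d", ids[i], i), identity = ids[i],
      frame = seq_len(n_frames) - 1L,
      t_min = (seq_len(n_frames) - 1) * frame_interval,
      x_um = xy[, 1], y_um = xy[, 2], z_um = 0, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Generate paired daughter-cell areas
#'
#' Asymmetric divisions draw the larger (prospective leader) and smaller
#' (follower) daughter areas from the configured truncated normals;
#' symmetric divisions draw both daughters from the common follower-pair
#' distribution.
#'
#' @param kind `"asym"` or `"sym"`.
#' @param n_pairs number of division pairs.
#' @param cfg a [generator_config()].
#' @param seed integer seed.
#' @return data.frame `pair`, `daughter_1`, `daughter_2` (um^2;
#'   `daughter_1` is the larger-daughter distribution for `"asym"`).
#' @export
gen_division_areas <- function(kind = c("asym", "sym"), n_pairs,
                               cfg = generator_config(), seed = 1) {
  kind <- match.arg(kind)
  set.seed(seed)
  stopifnot(n_pairs >= 1)
  if (kind == "asym") {
    a <- cfg$areas$asym
    d1 <- rtruncnorm_pos(n_pairs, a$larger_mean, a$larger_sd)
    d2 <- rtruncnorm_pos(n_pairs, a$smaller_mean, a$smaller_sd)
  } else {
    a <- cfg$areas$sym
    d1 <- rtruncnorm_pos(n_pairs, a$mean, a$sd)
    d2 <- rtruncnorm_pos(n_pairs, a$mean, a$sd)
  }
  data.frame(pair = seq_len(n_pairs), daughter_1 = d1, daughter_2 = d2)
}
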