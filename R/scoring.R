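#' Configuration of the five-criterion chain score
#'
#' Thresholds for the multi-objective score deciding whether a simulated
#' chain matches in vivo TNC behaviour: a maximum adjacent-cell distance of
#' 57 um (chain cohesion) and single-file arrangement in at least 80% of
#' frames are the two published thresholds; the remaining settings
#' operationalise "followers rearrange", "leaders retain the front" and
#' "the chain reaches the end of the path" and are calibration choices.
#'
#' @param cohesion_max maximum allowed distance between chain-order
#'   neighbours (um).
#' @param singlefile_min_fraction minimum fraction of single-file frames.
#' @param front_retention_min_fraction minimum fraction of frames the
#'   designated leader must be the most ventral cell.
#' @param overmigration_margin distance beyond `y_end` tolerated before the
#'   chain counts as over-migrated (um); default one leader diameter.
#' @param overtake_delta ventral lead (um) a cell must hold to count as
#'   ahead of another for overtaking/swap detection.
#' @param overtake_min_frames consecutive frames the lead must be held
#'   (3 frames = 15 min at the default sampling).
#' @param cohesion_strict if `TRUE` (default) a single frame over
#'   `cohesion_max` fails cohesion; if `FALSE` up to 5% of frames may
#'   exceed it.
#' @param sidebyside_gap extra centre distance (um) within which a pair can
#'   count as side by side.
#' @return an object of class `tnc_score_config`.
#' @export
score_config <- function(cohesion_max = 57, singlefile_min_fraction = 0.80,
                         front_retention_min_fraction = 0.95,
                         overmigration_margin = 11.4, overtake_delta = 2,
                         overtake_min_frames = 3, cohesion_strict = TRUE,
                         sidebyside_gap = 2) {
  stopifnot(cohesion_max > 0,
            singlefile_min_fraction > 0, singlefile_min_fraction <= 1,
            front_retention_min_fraction > 0,
            front_retention_min_fraction <= 1,
            overmigration_margin >= 0, overtake_delta >= 0,
            overtake_min_frames >= 1)
  structure(list(cohesion_max = cohesion_max,
                 singlefile_min_fraction = singlefile_min_fraction,
                 front_retention_min_fraction = front_retention_min_fraction,
                 overmigration_margin = overmigration_margin,
                 overtake_delta = overtake_delta,
                 overtake_min_frames = overtake_min_frames,
                 cohesion_strict = cohesion_strict,
                 sidebyside_gap = sidebyside_gap),
            class = "tnc_score_config")
}

#' Chain-cohesion score
#'
#' At each sampled frame cells are ordered by ventral position and the
#' Euclidean distance between chain-order neighbours is measured; the chain
#' is cohesive when no adjacent gap exceeds `cohesion_max` (57 um by
#' default).
#'
#' @param traj a [trajectory()].
#' @param cfg a [score_config()].
#' @return list with `pass` and `max_adjacent_gap` (um).
#' @export
score_cohesion <- function(traj, cfg = score_config()) {
  pos <- traj$positions
  n <- dim(pos)[2]
  if (n < 2) stop("cohesion is not defined for a single-cell trajectory")
  gaps <- apply(pos, 1, function(fr) {
    ord <- order(fr[, 2], decreasing = TRUE)
    xy <- fr[ord, , drop = FALSE]
    max(sqrt(rowSums((xy[-1, , drop = FALSE] -
                        xy[-n, , drop = FALSE])^2)))
  })
  if (cfg$cohesion_strict) {
    pass <- max(gaps) <= cfg$cohesion_max
  } else {
    pass <- mean(gaps > cfg$cohesion_max) <= 0.05
  }
  list(pass = pass, max_adjacent_gap = max(gaps))
}

# Frame-wise single-file predicate: a pair is side by side when the cells
# overlap in their dorsoventral extent (|dy| < min radius) while being in
# near-contact laterally.
single_file_frames <- function(pos, radius, gap) {
  n <- dim(pos)[2]
  pairs <- which(upper.tri(matrix(TRUE, n, n)), arr.ind = TRUE)
  apply(pos, 1, function(fr) {
    dx <- fr[pairs[, 1], 1] - fr[pairs[, 2], 1]
    dy <- fr[pairs[, 1], 2] - fr[pairs[, 2], 2]
    d <- sqrt(dx^2 + dy^2)
    rmin <- pmin(radius[pairs[, 1]], radius[pairs[, 2]])
    rsum <- radius[pairs[, 1]] + radius[pairs[, 2]]
    !any(abs(dy) < rmin & d < rsum + gap)
  })
}

#' Single-file score
#'
#' A frame is single file when no pair of cells is side by side (in lateral
#' near-contact with overlapping dorsoventral extents); the score passes
#' when at least `singlefile_min_fraction` (80% by default) of frames are
#' single file.
#'
#' @inheritParams score_cohesion
#' @return list with `pass` and `fraction`.
#' @export
score_single_file <- function(traj, cfg = score_config()) {
  if (dim(traj$positions)[2] < 2)
    stop("single-file score is not defined for a single-cell trajectory")
  sf <- single_file_frames(traj$positions, traj$radius, cfg$sidebyside_gap)
  frac <- mean(sf)
  list(pass = frac >= cfg$singlefile_min_fraction, fraction = frac)
}

# Sustained-lead detector: does `lead` (a logical/numeric series of frames
# where a cell holds the required ventral lead) contain a run of at least
# min_frames consecutive TRUE values?
sustained_run <- function(lead, min_frames) {
  r <- rle(lead)
  any(r$values & r$lengths >= min_frames)
}

#' Overtaking events and the leader's overtaken category
#'
#' The designated front cell is the most ventral cell at frame 0. A cell
#' overtakes it when its ventral position exceeds the front cell's by more
#' than `overtake_delta` for at least `overtake_min_frames` consecutive
#' frames. The count of distinct overtakers is mapped to the categories
#' `"0"`, `"1"`, `">1"`. Sustained rank swaps between follower pairs
#' (detected by the same rule, relative to their frame-0 order) are
#' returned for the rearrangement score.
#'
#' @inheritParams score_cohesion
#' @return list with `front_cell` (index), `overtakers` (indices),
#'   `category` (`"0"`, `"1"` or `">1"`), and `follower_swaps` (count of
#'   sustained follower-follower rank swaps).
#' @export
detect_overtakings <- function(traj, cfg = score_config()) {
  pos <- traj$positions
  n <- dim(pos)[2]
  y <- pos[, , 2, drop = FALSE][, , 1]
  if (is.null(dim(y))) y <- matrix(y, ncol = n)
  front <- which.max(y[1, ])
  overtakers <- integer(0)
  for (j in seq_len(n)) {
    if (j == front) next
    if (sustained_run(y[, j] > y[, front] + cfg$overtake_delta,
                      cfg$overtake_min_frames))
      overtakers <- c(overtakers, j)
  }
  category <- if (length(overtakers) == 0) "0"
    else if (length(overtakers) == 1) "1" else ">1"
  followers <- setdiff(which(traj$identities == "follower"), front)
  swaps <- 0L
  if (length(followers) >= 2) {
    fo <- followers[order(y[1, followers], decreasing = TRUE)]
    for (a in seq_along(fo)[-1]) for (b in seq_len(a - 1)) {
      # fo[b] starts ahead of fo[a]; a sustained reversal is a swap
      if (sustained_run(y[, fo[a]] > y[, fo[b]] + cfg$overtake_delta,
                        cfg$overtake_min_frames))
        swaps <- swaps + 1L
    }
  }
  list(front_cell = front, overtakers = overtakers, category = category,
       follower_swaps = swaps)
}

#' Leader-front retention score
#'
#' Passes when the designated leader (most ventral cell at frame 0) is the
#' most ventral cell in at least `front_retention_min_fraction` of frames
#' and is never durably overtaken (category `"0"`).
#'
#' @inheritParams score_cohesion
#' @return list with `pass`, `retention_fraction`, `overtaken_category`.
#' @export
score_leader_front <- function(traj, cfg = score_config()) {
  ov <- detect_overtakings(traj, cfg)
  y <- traj$positions[, , 2]
  if (is.null(dim(y))) y <- matrix(y, ncol = dim(traj$positions)[2])
  retention <- mean(apply(y, 1, which.max) == ov$front_cell)
  list(pass = retention >= cfg$front_retention_min_fraction &&
         ov$category == "0",
       retention_fraction = retention,
       overtaken_category = ov$category)
}

#' Path-completion score
#'
#' Passes when the designated leader reaches the end of the migratory path
#' (`y_end`); additionally flags over-migration when the front cell's final
#' position lies beyond `y_end + overmigration_margin`.
#'
#' @inheritParams score_cohesion
#' @param arena_ a [arena()].
#' @return list with `pass`, `reached`, `over_migrated`, `final_front_y`.
#' @export
score_path_completion <- function(traj, arena_ = arena(),
                                  cfg = score_config()) {
  y <- traj$positions[, , 2]
  if (is.null(dim(y))) y <- matrix(y, ncol = dim(traj$positions)[2])
  leader_idx <- which.max(y[1, ])
  reached <- max(y[, leader_idx]) >= arena_$y_end
  final_front <- max(y[nrow(y), ])
  over <- final_front > arena_$y_end + cfg$overmigration_margin
  list(pass = reached, reached = reached, over_migrated = over,
       final_front_y = final_front)
}

#' Full five-criterion score report
#'
#' Aggregates cohesion, single-file, follower rearrangement (at least one
#' sustained follower-follower swap), leader-front retention and path
#' completion into one report; `all_pass` is their conjunction.
#'
#' @inheritParams score_path_completion
#' @return an object of class `tnc_score_report`.
#' @export
score_all <- function(traj, arena_ = arena(), cfg = score_config()) {
  coh <- score_cohesion(traj, cfg)
  sf <- score_single_file(traj, cfg)
  ov <- detect_overtakings(traj, cfg)
  rearr <- list(pass = ov$follower_swaps >= 1, swap_count = ov$follower_swaps)
  lf <- score_leader_front(traj, cfg)
  pc <- score_path_completion(traj, arena_, cfg)
  rep <- list(cohesion = coh, single_file = sf,
              follower_rearrangement = rearr, leader_front = lf,
              path_completion = pc,
              all_pass = coh$pass && sf$pass && rearr$pass && lf$pass &&
                pc$pass)
  class(rep) <- "tnc_score_report"
  rep
}

#' @export
print.tnc_score_report <- function(x, ...) {
  pf <- function(p) if (p) "pass" else "FAIL"
  cat(sprintf("cohesion      %s (max gap %.1f um)\n", pf(x$cohesion$pass),
              x$cohesion$max_adjacent_gap))
  cat(sprintf("single file   %s (%.0f%% of frames)\n", pf(x$single_file$pass),
              100 * x$single_file$fraction))
  cat(sprintf("rearrangement %s (%d swaps)\n",
              pf(x$follower_rearrangement$pass),
              x$follower_rearrangement$swap_count))
  cat(sprintf("leader front  %s (retention %.2f, overtaken %s)\n",
              pf(x$leader_front$pass), x$leader_front$retention_fraction,
              x$leader_front$overtaken_category))
  cat(sprintf("path complete %s (over-migrated: %s)\n",
              pf(x$path_completion$pass), x$path_completion$over_migrated))
  cat(sprintf("ALL: %s\n", pf(x$all_pass)))
  invisible(x)
}

#' Locate the cohesion pass/fail boundary by bisection
#'
#' Builds static two-cell chains at controlled separations, scores each,
#' and bisects between a passing and a failing separation until the
#' boundary is bracketed to `tol` um.
#'
#' @param lo,hi initial bracket (um); `lo` must pass and `hi` fail.
#' @param tol bracket width at which to stop (um).
#' @param cfg a [score_config()].
#' @return the boundary separation (um).
#' @export
locate_cohesion_boundary <- function(lo = 40, hi = 70, tol = 1e-4,
                                     cfg = score_config()) {
  sep_pass <- function(d) {
    tr <- static_pair_trajectory(d)
    score_cohesion(tr, cfg)$pass
  }
  if (!sep_pass(lo) || sep_pass(hi))
    stop("initial bracket does not straddle the boundary")
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (sep_pass(mid)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# Static two-cell fixture: cells at a fixed dorsoventral separation for
# 10 frames.
static_pair_trajectory <- function(separation, n_frames = 10) {
  pos <- array(0, dim = c(n_frames, 2, 2))
  pos[, 1, 1] <- 10; pos[, 2, 1] <- 10
  pos[, 1, 2] <- 50 + separation
  pos[, 2, 2] <- 50
  trajectory(pos, identities = c("leader", "follower"))
}

#' Locate the single-file pass threshold by scanning controlled fractions
#'
#' Builds 100-frame two-cell trajectories in which exactly `k` frames
#' satisfy the single-file predicate, for `k` in `0:100`, scores each, and
#' returns the smallest passing fraction as a percentage.
#'
#' @param n_frames number of frames in each fixture.
#' @param cfg a [score_config()].
#' @return smallest passing single-file percentage.
#' @export
locate_single_file_threshold <- function(n_frames = 100,
                                         cfg = score_config()) {
  for (k in 0:n_frames) {
    tr <- controlled_single_file_trajectory(k, n_frames)
    if (score_single_file(tr, cfg)$pass) return(100 * k / n_frames)
  }
  NA_real_
}

# Two follower-sized cells: side by side (same y, centres nearly touching)
# in the first n_frames - k frames, strung out along y in the last k.
controlled_single_file_trajectory <- function(k, n_frames = 100) {
  pos <- array(0, dim = c(n_frames, 2, 2))
  single <- seq_len(n_frames) > (n_frames - k)
  # single-file frames: strung out along y; others: lateral near-contact
  pos[, 1, 1] <- ifelse(single, 10, 5)    # x of cell 1
  pos[, 1, 2] <- ifelse(single, 10, 20)   # y of cell 1
  pos[, 2, 1] <- ifelse(single, 10, 14)   # x of cell 2
  pos[, 2, 2] <- ifelse(single, 30, 20)   # y of cell 2
  trajectory(pos, identities = c("follower", "follower"))
}
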