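#' Instantaneous speed between two 3D positions
#'
#' Implements exactly the tracking convention used for the in vivo data:
#' `((SQRT((X1-X2)^2+(Y1-Y2)^2+(Z1-Z2)^2))/T)*60`, i.e. displacement (um)
#' per frame interval (minutes), converted to um/hr.
#'
#' @param p1,p2 numeric 3-vectors (um), or matrices with 3 columns.
#' @param T frame interval (minutes), > 0.
#' @return speed(s) in um/hr.
#' @export
#' @examples
#' instantaneous_speed(c(0, 0, 0), c(3, 4, 0), T = 5)  # 60 um/hr
instantaneous_speed <- function(p1, p2, T) {
  if (any(T <= 0)) stop("T must be positive")
  p1 <- rbind(p1); p2 <- rbind(p2)
  unname((sqrt(rowSums((p1 - p2)^2)) / T) * 60)
}

#' Track directionality
#'
#' Net displacement divided by total path length of one cell's track,
#' computed in 3D; equals 1 only for a strictly collinear monotone path and
#' 0 for a track returning to its start.
#'
#' @param track matrix or data.frame of per-frame positions with columns
#'   x, y(, z), ordered by frame.
#' @return dimensionless value in `[0, 1]`, or `NA` when the path length
#'   is zero.
#' @export
directionality <- function(track) {
  m <- as.matrix(track)
  if (ncol(m) == 2) m <- cbind(m, 0)
  if (nrow(m) < 2) stop("directionality needs at least 2 frames")
  seg <- diff(m)
  path <- sum(sqrt(rowSums(seg^2)))
  if (path <= 0) return(NA_real_)
  net <- sqrt(sum((m[nrow(m), ] - m[1, ])^2))
  net / path
}

#' Ventral distance of a track
#'
#' Straight-line dorsoventral distance from the dorsal edge to the cell's
#' position at the end of the track.
#'
#' @param track matrix/data.frame with a y column (second column), ordered
#'   by frame.
#' @param dorsal_edge_y dorsal edge reference (um), default 0.
#' @return distance (um).
#' @export
ventral_distance <- function(track, dorsal_edge_y = 0) {
  m <- as.matrix(track)
  if (nrow(m) == 0) stop("track is empty")
  m[nrow(m), 2] - dorsal_edge_y
}

#' Per-cell metrics and identity-level aggregates
#'
#' Applies the shared metric suite to a track table: mean instantaneous
#' speed (um/hr), directionality, ventral distance, final position and
#' overtaken category per cell, plus per-identity means/SDs. When the
#' table carries an `area_um2` column, the leader/follower mean-area ratio
#' is included in the aggregates.
#'
#' @param table a track table (see [read_track_table()] for the format):
#'   columns `cell_id`, `identity`, `frame`, `t_min`, `x_um`, `y_um`,
#'   `z_um`, optional `area_um2`.
#' @param dorsal_edge_y dorsal edge reference (um).
#' @param cfg a [score_config()] (for the overtaking rule).
#' @return list with `cells` (one row per cell) and `aggregates` (one row
#'   per identity; `area_ratio` attribute when areas are supplied).
#' @export
summarize_tracks <- function(table, dorsal_edge_y = 0,
                             cfg = score_config()) {
  validate_track_table(table)
  ids <- unique(table$cell_id)
  per_cell <- lapply(ids, function(cid) {
    tr <- table[table$cell_id == cid, ]
    tr <- tr[order(tr$frame), ]
    m <- as.matrix(tr[, c("x_um", "y_um", "z_um")])
    sp <- if (nrow(m) > 1)
      mean(instantaneous_speed(m[-nrow(m), , drop = FALSE],
                               m[-1, , drop = FALSE], diff(tr$t_min)))
    else NA_real_
    data.frame(cell_id = cid, identity = tr$identity[1],
               mean_speed = sp,
               directionality = if (nrow(m) > 1) directionality(m) else NA,
               ventral_distance = ventral_distance(m, dorsal_edge_y),
               final_x = m[nrow(m), 1], final_y = m[nrow(m), 2],
               stringsAsFactors = FALSE)
  })
  cells <- do.call(rbind, per_cell)
  # overtaken categories need a common frame grid
  frames <- sort(unique(table$frame))
  if (all(table(table$cell_id) == length(frames)) && length(ids) > 1) {
    y <- sapply(ids, function(cid) {
      tr <- table[table$cell_id == cid, ]
      tr$y_um[order(tr$frame)]
    })
    pos <- array(0, dim = c(length(frames), length(ids), 2))
    pos[, , 2] <- y
    tr_ <- trajectory(pos,
                      identities = cells$identity,
                      times = sort(unique(table$t_min)))
    ov <- detect_overtakings(tr_, cfg)
    cells$overtaken_category <- NA_character_
    cells$overtaken_category[ov$front_cell] <- ov$category
  }
  agg <- lapply(c("leader", "follower"), function(id) {
    sub <- cells[cells$identity == id, ]
    if (nrow(sub) == 0) {
      warning("no cells with identity '", id, "'; aggregate omitted")
      return(NULL)
    }
    data.frame(identity = id, n = nrow(sub),
               mean_speed = mean(sub$mean_speed, na.rm = TRUE),
               sd_speed = sd(sub$mean_speed, na.rm = TRUE),
               mean_directionality = mean(sub$directionality, na.rm = TRUE),
               sd_directionality = sd(sub$directionality, na.rm = TRUE),
               mean_ventral_distance = mean(sub$ventral_distance),
               sd_ventral_distance = sd(sub$ventral_distance),
               stringsAsFactors = FALSE)
  })
  aggregates <- do.call(rbind, agg)
  out <- list(cells = cells, aggregates = aggregates)
  if ("area_um2" %in% names(table)) {
    areas <- unique(table[, c("cell_id", "identity", "area_um2")])
    ml <- mean(areas$area_um2[areas$identity == "leader"])
    mf <- mean(areas$area_um2[areas$identity == "follower"])
    out$area <- list(leader_mean = ml, follower_mean = mf,
                     area_ratio = ml / mf)
  }
  out
}
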