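#' Phase durations from per-frame cell-cycle state sequences
#'
#' Extracts phase durations from labelled state sequences (e.g. derived
#' from PCNA nuclear-pattern classification at a 5-minute imaging cadence).
#' A phase run's duration is its frame count times the frame interval, and
#' is reported only when the run is bounded on both sides by a different
#' known phase (partially observed runs at the sequence edges are censored,
#' not imputed). Unknown frames inside a run of one phase are absorbed
#' into it. The total cycle length is the time between two successive
#' M-to-G1 transitions, when two are observed. Consecutive distinct known
#' phases must follow the cyclic order G1 -> S -> G2 -> M -> G1.
#'
#' @param states data.frame with columns `cell_id`, `identity`, `frame`,
#'   `label` (values `G1`, `S`, `G2`, `M`, `unknown`), optionally `onset`
#'   (logical, one `TRUE` frame per cell marking migration initiation).
#' @param frame_interval minutes per frame.
#' @return data.frame with one row per cell: `cell_id`, `identity`,
#'   durations `G1`, `S`, `G2`, `M` (hours; mean over fully observed runs,
#'   `NA` when none) and `total` (hours, `NA` unless two M->G1 transitions
#'   are observed).
#' @export
durations_from_states <- function(states, frame_interval = 5) {
  stopifnot(frame_interval > 0)
  req <- c("cell_id", "identity", "frame", "label")
  if (!all(req %in% names(states)))
    stop("states needs columns ", paste(req, collapse = ", "))
  phases <- c("G1", "S", "G2", "M")
  succ <- c(G1 = "S", S = "G2", G2 = "M", M = "G1")
  out <- lapply(split(states, states$cell_id), function(df) {
    df <- df[order(df$frame), ]
    lab <- as.character(df$label)
    if (!all(lab %in% c(phases, "unknown")))
      stop("unknown phase label(s): ",
           paste(setdiff(lab, c(phases, "unknown")), collapse = ", "))
    known <- lab != "unknown"
    # absorb unknown frames into the current phase run
    filled <- lab
    for (i in seq_along(filled))
      if (filled[i] == "unknown" && i > 1) filled[i] <- filled[i - 1]
    filled <- filled[filled != "unknown"]
    first_known <- which(known)[1]
    r <- rle(filled)
    if (length(r$values) > 1) {
      for (k in 2:length(r$values)) {
        if (succ[[r$values[k - 1]]] != r$values[k]) {
          bad <- df$frame[first_known - 1 + sum(r$lengths[1:(k - 1)]) + 1]
          stop("cell ", df$cell_id[1], ": phase order violated at frame ",
               bad, " (", r$values[k - 1], " -> ", r$values[k], ")")
        }
      }
    }
    durs <- setNames(rep(NA_real_, 4), phases)
    if (length(r$values) > 2) {
      for (ph in phases) {
        idx <- which(r$values == ph)
        idx <- idx[idx > 1 & idx < length(r$values)]  # bounded both sides
        if (length(idx) > 0)
          durs[ph] <- mean(r$lengths[idx]) * frame_interval / 60
      }
    }
    # total: between successive M -> G1 transitions
    g1_starts <- which(r$values == "G1" & c(FALSE, head(r$values, -1) == "M"))
    total <- NA_real_
    if (length(g1_starts) >= 2) {
      starts <- cumsum(c(1, r$lengths))[g1_starts]
      total <- mean(diff(starts)) * frame_interval / 60
    }
    data.frame(cell_id = df$cell_id[1], identity = df$identity[1],
               G1 = durs[["G1"]], S = durs[["S"]], G2 = durs[["G2"]],
               M = durs[["M"]], total = total, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(match(res$cell_id, unique(states$cell_id))), , drop = FALSE]
}

#' Cell-cycle phase at migration onset
#'
#' Maps the phase label at the migration-initiation frame to the
#' two-colour FUCCI classes: `G1` (red) versus `S_or_G2` (green, which
#' includes S, G2 and M under the geminin reporter).
#'
#' @param states state sequences as in [durations_from_states()], with an
#'   `onset` column, or a per-cell data.frame subset.
#' @return data.frame `cell_id`, `identity`, `onset_class` (`"G1"`,
#'   `"S_or_G2"`, or `NA` when the label at onset is unknown).
#' @export
onset_phase <- function(states) {
  if (!"onset" %in% names(states))
    stop("states needs an 'onset' column marking migration initiation")
  out <- lapply(split(states, states$cell_id), function(df) {
    df <- df[order(df$frame), ]
    i <- which(df$onset)
    if (length(i) != 1)
      stop("cell ", df$cell_id[1], ": exactly one onset frame required")
    lab <- as.character(df$label[i])
    cls <- if (lab == "G1") "G1"
      else if (lab %in% c("S", "G2", "M")) "S_or_G2"
      else NA_character_
    data.frame(cell_id = df$cell_id[1], identity = df$identity[1],
               onset_class = cls, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(match(res$cell_id, unique(states$cell_id))), , drop = FALSE]
}

#' Ratio of dispersions
#'
#' Simple ratio `sd_after / sd_before`, used to quantify the collapse of
#' phase-duration variability (e.g. in followers after Notch inhibition).
#'
#' @param sd_before,sd_after positive standard deviations (hours).
#' @return dimensionless ratio.
#' @export
#' @examples
#' dispersion_ratio(2.7, 1.42)  # ~0.53
dispersion_ratio <- function(sd_before, sd_after) {
  if (any(c(sd_before, sd_after) <= 0))
    stop("standard deviations must be positive")
  sd_after / sd_before
}
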