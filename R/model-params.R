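#' Dorsoventral migration corridor
#'
#' Geometry of the confined space the chain migrates through. The y axis
#' increases ventrally: the premigratory band occupies `[0, y_premigratory]`,
#' the neural tube/notochord boundary sits at `y_ntnot` (the ~65 um in vivo
#' landmark) and the migratory path ends at `y_end`. The corridor extends
#' dorsally to `y_min` (< 0) so that chains longer than the premigratory band
#' can be initialised with their front inside it, and ventrally to `y_max`
#' (> `y_end`) so that over-migration beyond the path end is observable.
#' All walls are reflective.
#'
#' The default width of 15 um keeps a migrating chain essentially single
#' file: two cells can only sit abreast by compressing, so rearrangements
#' happen as occasional squeeze-past events rather than persistent
#' side-by-side pairs.
#'
#' @param width corridor width along the anteroposterior axis (um).
#' @param y_min dorsal wall position (um, negative).
#' @param y_premigratory ventral edge of the premigratory band (um).
#' @param y_ntnot neural tube/notochord boundary (um).
#' @param y_end end of the migratory path (um).
#' @param y_max ventral wall position (um, beyond `y_end`).
#' @param boundary_mode boundary handling; only `"reflect"` is implemented.
#' @return an object of class `tnc_arena`.
#' @export
#' @examples
#' arena()
arena <- function(width = 15, y_min = -125, y_premigratory = 25,
                  y_ntnot = 65, y_end = 150, y_max = 220,
                  boundary_mode = "reflect") {
  boundary_mode <- match.arg(boundary_mode, "reflect")
  stopifnot(width > 0, y_min < 0)
  if (!(0 < y_premigratory && y_premigratory < y_ntnot && y_ntnot < y_end))
    stop("arena requires 0 < y_premigratory < y_ntnot < y_end")
  if (y_max <= y_end) stop("arena requires y_max > y_end")
  structure(list(width = width, y_min = y_min,
                 y_premigratory = y_premigratory, y_ntnot = y_ntnot,
                 y_end = y_end, y_max = y_max,
                 boundary_mode = boundary_mode),
            class = "tnc_arena")
}

#' Low/medium/high level values for swept model parameters
#'
#' Numeric values behind the qualitative low/medium/high settings used in
#' parameter sweeps. CIL intensity levels are repolarisation turn angles
#' (radians per contact), co-attraction levels are displacement magnitudes
#' (um/min) towards the neighbourhood centroid, and cell-size levels are
#' leader radii (um; medium equals the default leader radius derived from
#' the 102 um^2 leader area, low equals the follower radius). These are
#' calibration constants of this model, not published measurements.
#'
#' @return named list of named numeric vectors with levels
#'   `low < medium < high` in effect magnitude.
#' @export
level_map <- function() {
  list(
    cil_intensity = c(low = pi / 12, medium = pi / 2, high = 2.2),
    coattraction = c(low = 0.1, medium = 0.25, high = 0.4),
    cell_size = c(low = 4.79, medium = 5.70, high = 6.84)
  )
}

#' Chain composition of migratory identities
#'
#' A composition is the ordered sequence of identities in the chain, front
#' (most ventral at initialisation) first. `composition()` parses a pattern
#' string of `L`/`F` characters; `composition_preset()` builds the named
#' presets used throughout the analysis.
#'
#' @param pattern character string of `L` (leader) and `F` (follower),
#'   front first, or a character vector of `"leader"`/`"follower"`.
#' @return an object of class `tnc_composition`: character vector of
#'   identities, front first.
#' @export
#' @examples
#' composition("LFFF")
#' composition_preset("1:3", n_cells = 8)
composition <- function(pattern) {
  if (length(pattern) == 1 && is.character(pattern) &&
      !pattern %in% c("leader", "follower")) {
    chars <- strsplit(pattern, "")[[1]]
    if (!all(chars %in% c("L", "F")))
      stop("composition pattern must contain only 'L' and 'F'")
    ids <- ifelse(chars == "L", "leader", "follower")
  } else {
    ids <- match.arg(pattern, c("leader", "follower"), several.ok = TRUE)
  }
  if (length(ids) == 0) stop("composition must be non-empty")
  structure(ids, class = "tnc_composition")
}

#' @rdname composition
#' @param name preset name: `"all_leader"`, `"all_follower"`,
#'   `"single_leader"`, `"1:1"`, `"1:2"` or `"1:3"`. Ratio presets repeat
#'   the pattern (`LF`, `LFF`, `LFFF`) from the front and truncate to
#'   `n_cells`.
#' @param n_cells chain length for the presets.
#' @export
composition_preset <- function(name, n_cells = 8) {
  name <- match.arg(name, c("all_leader", "all_follower", "single_leader",
                            "1:1", "1:2", "1:3"))
  stopifnot(n_cells >= 1)
  pat <- switch(name,
    all_leader = rep("L", n_cells),
    all_follower = rep("F", n_cells),
    single_leader = c("L", rep("F", n_cells - 1)),
    "1:1" = rep(c("L", "F"), length.out = n_cells),
    "1:2" = rep(c("L", "F", "F"), length.out = n_cells),
    "1:3" = rep(c("L", "F", "F", "F"), length.out = n_cells)
  )
  composition(paste(pat, collapse = ""))
}

#' Model parameters for the chain simulator
#'
#' @param cil_mode contact-inhibition mode: `"differential"` (only contacts
#'   between unlike identities repolarise, the mechanism supported by the
#'   in vivo data), `"all_pairs"`, or `"off"`.
#' @param cil_intensity named map identity -> level name (from
#'   [level_map()]`$cil_intensity`) or numeric turn angle in radians.
#' @param coattraction_strength level name (from
#'   [level_map()]`$coattraction`) or numeric displacement (um/min).
#' @param coattraction_range interaction range of co-attraction (um).
#' @param cell_radius named map identity -> radius (um). Defaults are
#'   `sqrt(area/pi)` of the measured leader (102 um^2) and follower
#'   (72 um^2) areas.
#' @param zeta heading-noise standard deviation (radians per step).
#' @param base_speed named map identity -> intrinsic speed (um/min).
#' @param dt integration step (minutes).
#' @param n_steps number of steps (default 960 = 16 h at 1 min).
#' @param sample_every record every this many steps (default 5, mirroring
#'   the 5-minute imaging cadence).
#' @param contact_tol extra centre distance (um) counted as contact for CIL.
#' @param cil_persist steps a repolarised heading is protected from noise.
#' @param cil_sustained if `TRUE`, the repolarisation is applied at every
#'   step a contact persists (so a cell pressed from one side keeps
#'   turning away); if `FALSE` only at contact onset.
#' @param cil_push_scale converts a CIL turn angle (radians) into the
#'   sustained contact-recoil speed (um/min per radian): while two unlike
#'   cells remain in contact each recoils away from the partner at
#'   `cil_push_scale * theta`, so chain drive scales with the number of
#'   leader/follower interfaces.
#' @param exclusion_passes spring-relaxation passes of the volume
#'   exclusion per step.
#' @param exclusion_strength fraction of a pair's overlap recovered per
#'   pass; values < 1 make cells effectively deformable so that pressed
#'   cells can transiently compress and squeeze past one another.
#' @param exclusion_tol pair overlap regarded as admissible deformation
#'   (um); the non-overlap invariant is stated up to this tolerance.
#' @param pack_gap surface-to-surface spacing (um) between neighbours at
#'   initialisation; the chain starts pre-strung rather than compressed.
#' @param levels level map resolving qualitative settings to numbers.
#' @return an object of class `tnc_params`.
#' @export
model_params <- function(cil_mode = c("differential", "all_pairs", "off"),
                         cil_intensity = c(leader = "medium",
                                           follower = "low"),
                         coattraction_strength = "high",
                         coattraction_range = 60,
                         cell_radius = c(leader = 5.70, follower = 4.79),
                         zeta = 0.17,
                         base_speed = c(leader = 0.7, follower = 0.55),
                         dt = 1, n_steps = 960, sample_every = 5,
                         contact_tol = 1, cil_persist = 16,
                         cil_push_scale = 0.45, cil_sustained = TRUE,
                         exclusion_passes = 1, exclusion_strength = 0.4,
                         exclusion_tol = 6, pack_gap = 5,
                         levels = level_map()) {
  cil_mode <- match.arg(cil_mode)
  stopifnot(dt > 0, n_steps >= 1, zeta >= 0, sample_every >= 1,
            coattraction_range >= 0, cil_persist >= 0)
  for (nm in c("leader", "follower")) {
    if (!nm %in% names(cil_intensity) || !nm %in% names(cell_radius) ||
        !nm %in% names(base_speed))
      stop("cil_intensity, cell_radius and base_speed need entries for ",
           "'leader' and 'follower'")
  }
  stopifnot(all(cell_radius > 0), all(base_speed >= 0))
  p <- structure(list(cil_mode = cil_mode, cil_intensity = cil_intensity,
                      coattraction_strength = coattraction_strength,
                      coattraction_range = coattraction_range,
                      cell_radius = cell_radius, zeta = zeta,
                      base_speed = base_speed, dt = dt, n_steps = n_steps,
                      sample_every = sample_every, contact_tol = contact_tol,
                      cil_persist = cil_persist,
                      cil_push_scale = cil_push_scale,
                      cil_sustained = cil_sustained,
                      exclusion_passes = exclusion_passes,
                      exclusion_strength = exclusion_strength,
                      exclusion_tol = exclusion_tol, pack_gap = pack_gap,
                      levels = levels),
                 class = "tnc_params")
  resolve_level(p, "check")  # fail early on unknown level names
  p
}

# Resolve a qualitative level name to its numeric value.
resolve_level <- function(params, what = c("check", "theta", "eps")) {
  what <- match.arg(what)
  lv <- params$levels
  as_num <- function(x, table, label) {
    if (is.numeric(x)) return(unname(x))
    if (!x %in% names(table))
      stop("unknown ", label, " level '", x, "'")
    unname(table[[x]])
  }
  theta <- vapply(c("leader", "follower"), function(id)
    as_num(params$cil_intensity[[id]], lv$cil_intensity, "cil_intensity"),
    numeric(1))
  eps <- as_num(params$coattraction_strength, lv$coattraction, "coattraction")
  switch(what, check = invisible(NULL), theta = theta, eps = eps)
}

# Per-identity numeric lookup helpers used across the simulator.
identity_vec <- function(map, identities) unname(map[identities])
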