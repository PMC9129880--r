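#' Enumerate a full factorial grid of parameter levels
#'
#' Cartesian product of the low/medium/high settings of the requested
#' parameters, in a deterministic order (last parameter varying fastest).
#'
#' @param levels a [level_map()]-like list.
#' @param swept character vector of parameter names to covary (subset of
#'   `names(levels)`); an empty vector yields the single default
#'   combination.
#' @param comp a [composition()] attached to every combination.
#' @return data.frame with one row per combination: `combination` index,
#'   one column per swept parameter (level name), and a `composition`
#'   pattern string.
#' @export
#' @examples
#' nrow(enumerate_grid(level_map(), c("cil_intensity", "coattraction",
#'                                    "cell_size"), composition("LFFF")))
enumerate_grid <- function(levels = level_map(),
                           swept = c("cil_intensity", "coattraction",
                                     "cell_size"),
                           comp = composition_preset("1:3")) {
  unknown <- setdiff(swept, names(levels))
  if (length(unknown) > 0)
    stop("unknown swept parameter(s): ", paste(unknown, collapse = ", "))
  pattern <- paste(ifelse(as.character(comp) == "leader", "L", "F"),
                   collapse = "")
  if (length(swept) == 0) {
    return(data.frame(combination = 1L, composition = pattern,
                      stringsAsFactors = FALSE))
  }
  grid <- expand.grid(rev(lapply(levels[swept], names)),
                      stringsAsFactors = FALSE)[, rev(seq_along(swept)),
                                                drop = FALSE]
  names(grid) <- swept
  grid <- grid[do.call(order, grid[swept]), , drop = FALSE]
  rownames(grid) <- NULL
  cbind(combination = seq_len(nrow(grid)), grid,
        composition = pattern, stringsAsFactors = FALSE)
}

# Apply one grid row's levels to a params object.
apply_levels <- function(params, row) {
  if ("cil_intensity" %in% names(row))
    params$cil_intensity[["leader"]] <- row[["cil_intensity"]]
  if ("coattraction" %in% names(row))
    params$coattraction_strength <- row[["coattraction"]]
  if ("cell_size" %in% names(row))
    params$cell_radius[["leader"]] <-
      params$levels$cell_size[[row[["cell_size"]]]]
  params
}

#' Run a parameter sweep
#'
#' Simulates every grid combination `n_reps` times with seeds derived only
#' from the master seed and the combination index (so results are
#' independent of execution order), scores each replicate with the
#' five-criterion score, and summarises per-score pass fractions. A
#' combination "matches" when every score's pass fraction is at least
#' `match_threshold`.
#'
#' @param grid output of [enumerate_grid()].
#' @param arena_ a [arena()].
#' @param params base [model_params()] that grid levels are applied to.
#' @param n_reps replicates per combination.
#' @param master_seed integer master seed.
#' @param match_threshold minimum per-score pass fraction for a
#'   combination to match.
#' @param cfg a [score_config()].
#' @return an object of class `tnc_sweep`: the grid, a long data.frame of
#'   per-replicate pass flags, per-combination pass fractions, and
#'   `combination_matches`.
#' @export
run_sweep <- function(grid, arena_ = arena(), params = model_params(),
                      n_reps = 20, master_seed = 1, match_threshold = 0.7,
                      cfg = score_config()) {
  stopifnot(n_reps >= 1)
  score_names <- c("cohesion", "single_file", "follower_rearrangement",
                   "leader_front", "path_completion")
  rows <- list()
  for (ci in seq_len(nrow(grid))) {
    p <- apply_levels(params, grid[ci, ])
    comp <- composition(grid$composition[ci])
    for (ri in seq_len(n_reps)) {
      seed <- derive_seed(master_seed, paste0("combo", ci), ri)
      rec <- tryCatch({
        rep_ <- score_all(simulate_chain(comp, arena_, p, seed = seed),
                          arena_, cfg)
        vapply(score_names, function(s) rep_[[s]]$pass, logical(1))
      }, error = function(e) {
        warning("replicate ", ri, " of combination ", ci, " failed: ",
                conditionMessage(e))
        setNames(rep(NA, 5), score_names)
      })
      rows[[length(rows) + 1]] <-
        data.frame(combination = ci, replicate = ri, seed = seed,
                   t(as.data.frame(rec)), row.names = NULL)
    }
  }
  per_rep <- do.call(rbind, rows)
  rownames(per_rep) <- NULL
  frac <- aggregate(per_rep[score_names],
                    by = list(combination = per_rep$combination),
                    FUN = function(x) mean(x, na.rm = TRUE))
  matches <- apply(frac[score_names] >= match_threshold, 1, all)
  structure(list(grid = grid, per_replicate = per_rep,
                 pass_fraction = frac,
                 combination_matches = unname(matches),
                 n_reps = n_reps, match_threshold = match_threshold,
                 master_seed = master_seed),
            class = "tnc_sweep")
}

#' Count combinations fulfilling a score
#'
#' Number of parameter combinations whose pass fraction meets the match
#' threshold for one score, or for the conjunction of all five
#' (`"all"`).
#'
#' @param sweep a [run_sweep()] result.
#' @param score one of the five score names or `"all"`.
#' @return integer count.
#' @export
count_passing <- function(sweep, score = "all") {
  score_names <- c("cohesion", "single_file", "follower_rearrangement",
                   "leader_front", "path_completion")
  if (score == "all") return(sum(sweep$combination_matches))
  if (!score %in% score_names) stop("unknown score name '", score, "'")
  sum(sweep$pass_fraction[[score]] >= sweep$match_threshold)
}

#' @export
print.tnc_sweep <- function(x, ...) {
  cat(sprintf("tnc_sweep: %d combinations x %d replicates (%s)\n",
              nrow(x$grid), x$n_reps, x$grid$composition[1]))
  for (s in c("cohesion", "single_file", "follower_rearrangement",
              "leader_front", "path_completion", "all"))
    cat(sprintf("  %-24s %d\n", s, count_passing(x, s)))
  invisible(x)
}
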