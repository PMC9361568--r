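#' Read a linear-timescale effective-size CSV
#'
#' Expects a CSV with a time column (`generation`/`gen`, or `years` together
#' with an explicit `generation_time`) and an `ne` column, both on linear
#' scales. Rows are sorted ascending in generations; duplicate times are
#' collapsed keeping the last occurrence.
#'
#' @param path File path.
#' @param generation_time Years per generation, required when the file's
#'   timescale is years; no default is assumed.
#' @return An [ne_trajectory()].
#' @export
read_ne_csv <- function(path, generation_time = NULL) {
  d <- read.table(path, header = TRUE, sep = ",", stringsAsFactors = FALSE)
  names(d) <- tolower(names(d))
  ne_col <- intersect(c("ne", "n_e", "size"), names(d))[1L]
  if (is.na(ne_col)) stop("no Ne column found (expected 'ne')")
  gen_col <- intersect(c("generation", "generations", "gen", "g"), names(d))[1L]
  if (!is.na(gen_col)) {
    gen <- d[[gen_col]]
  } else {
    yr_col <- intersect(c("years", "year", "time_years"), names(d))[1L]
    if (is.na(yr_col)) stop("no generation or years column found")
    if (is.null(generation_time)) {
      stop("file uses a years timescale; supply generation_time explicitly")
    }
    gen <- d[[yr_col]] / generation_time
  }
  gen <- suppressWarnings(as.numeric(gen))
  ne <- suppressWarnings(as.numeric(d[[ne_col]]))
  if (any(is.na(gen)) || any(is.na(ne))) {
    stop(sprintf("%s: non-numeric cells in time or Ne column", path))
  }
  o <- order(gen, seq_along(gen))
  gen <- gen[o]; ne <- ne[o]
  keep <- rev(!duplicated(rev(gen)))   # collapse duplicate times, keep last
  ne_trajectory(gen[keep], ne[keep])
}

#' Write a trajectory as a linear two-column CSV
#' @param traj An [ne_trajectory()].
#' @param path Output file.
#' @export
write_ne_csv <- function(traj, path) {
  write.table(data.frame(generation = traj$gen, ne = traj$ne), path,
              sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Merge a recent and a distant demographic trajectory
#'
#' Concatenates a recent trajectory (e.g. generations 4-50 from IBD-based
#' inference) with a distant one (e.g. starting at generation 260 from
#' sequential-coalescent inference) whose domains must not overlap, filling
#' the intervening gap per `bridge`:
#' * `"geometric"` (default): `log N` linear in `log g` between the last
#'   recent and first distant knot, so the value at the gap's log-midpoint
#'   generation is the geometric mean of the boundary values;
#' * `"hold"`: constant at the last recent value (plain-concatenation
#'   semantics).
#'
#' @param recent,distant [ne_trajectory()]s with
#'   `max(recent$gen) < min(distant$gen)`.
#' @param bridge Gap policy.
#' @param bridge_knots Number of interior knots written into the gap for the
#'   piecewise-constant representation (default 16, geometrically spaced;
#'   ignored for `"hold"`).
#' @return An [ne_trajectory()] whose restriction to either input domain is
#'   identical to that input; attribute `source` marks each knot as
#'   `"recent"`, `"bridge"` or `"distant"`.
#' @export
merge_trajectories <- function(recent, distant, bridge = c("geometric", "hold"),
                               bridge_knots = 16) {
  bridge <- match.arg(bridge)
  g1 <- max(recent$gen); g2 <- min(distant$gen)
  if (g1 >= g2) stop("recent and distant domains overlap; refusing to pick silently")
  n1 <- recent$ne[which.max(recent$gen)]
  n2 <- distant$ne[which.min(distant$gen)]
  if (bridge == "hold" || bridge_knots < 1) {
    gk <- numeric(0); nk <- numeric(0)
  } else {
    gk <- exp(seq(log(g1), log(g2), length.out = bridge_knots + 2L))
    gk <- gk[-c(1L, length(gk))]
    nk <- exp(log(n1) + (log(gk) - log(g1)) / (log(g2) - log(g1)) * (log(n2) - log(n1)))
  }
  out <- ne_trajectory(c(recent$gen, gk, distant$gen),
                       c(recent$ne, nk, distant$ne))
  attr(out, "source") <- c(rep("recent", nrow(recent)),
                           rep("bridge", length(gk)),
                           rep("distant", nrow(distant)))
  attr(out, "bridge") <- bridge
  attr(out, "bridge_bounds") <- c(g1, g2)
  out
}

#' Evaluate a trajectory at arbitrary generations
#'
#' Piecewise-constant evaluation (value of the most recent knot at or
#' before `g`); inside a merged trajectory's gap the bridge policy formula
#' is evaluated exactly rather than from the sampled knots.
#'
#' @param traj An [ne_trajectory()].
#' @param g Generations before present.
#' @return Effective sizes at `g`.
#' @export
ne_at <- function(traj, g) {
  bb <- attr(traj, "bridge_bounds")
  out <- traj$ne[pmax(findInterval(g, traj$gen), 1L)]
  if (!is.null(bb) && identical(attr(traj, "bridge"), "geometric")) {
    in_gap <- g > bb[1L] & g < bb[2L]
    if (any(in_gap)) {
      n1 <- traj$ne[traj$gen == bb[1L]][1L]
      n2 <- traj$ne[match(bb[2L], traj$gen)]
      out[in_gap] <- exp(log(n1) + (log(g[in_gap]) - log(bb[1L])) /
                           (log(bb[2L]) - log(bb[1L])) * (log(n2) - log(n1)))
    }
  }
  out
}

#' Write a merged demography as epochs JSON
#'
#' Emits the piecewise-constant representation (change times in generations
#' and sizes) consumed by demography-aware downstream tools.
#'
#' @param traj An [ne_trajectory()].
#' @param path Output file.
#' @export
write_epochs_json <- function(traj, path) {
  jsonlite::write_json(list(generations = traj$gen, ne = traj$ne),
                       path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}
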