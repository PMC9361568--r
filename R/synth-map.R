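#' Specify a hotspot-punctuated synthetic genetic map
#'
#' @param chrom_length_bp Chromosome length in bp (> 0).
#' @param background_rate Background per-bp per-generation recombination
#'   probability (> 0; 1e-8 is 1 cM/Mb).
#' @param hotspot_rate Expected hotspots per Mb (>= 0); hotspot centres are
#'   placed by a homogeneous Poisson process.
#' @param hotspot_width_bp Hotspot width in bp.
#' @param intensity_fold Rate multiplier over background inside a hotspot
#'   (>= 1).
#' @param chrom Chromosome name.
#' @return A `genetic_map_spec` list, input to [synth_map()].
#' @export
genetic_map_spec <- function(chrom_length_bp, background_rate = 2e-9,
                             hotspot_rate = 10, hotspot_width_bp = 2000,
                             intensity_fold = 100, chrom = "1") {
  if (chrom_length_bp <= 0) stop("chrom_length_bp must be positive")
  if (background_rate <= 0) stop("background_rate must be positive")
  if (hotspot_rate < 0) stop("hotspot_rate must be non-negative")
  if (intensity_fold < 1) stop("intensity_fold must be >= 1")
  if (hotspot_width_bp <= 0) stop("hotspot_width_bp must be positive")
  structure(list(chrom_length_bp = chrom_length_bp,
                 background_rate = background_rate,
                 hotspot_rate = hotspot_rate,
                 hotspot_width_bp = hotspot_width_bp,
                 intensity_fold = intensity_fold,
                 chrom = chrom),
            class = "genetic_map_spec")
}

# Build the piecewise-constant map from a spec and a vector of hotspot centres.
map_from_centers <- function(spec, centers) {
  L <- spec$chrom_length_bp
  centers <- sort(centers)
  hs <- data.frame(center = centers,
                   start = pmax(0, centers - spec$hotspot_width_bp / 2),
                   end = pmin(L, centers + spec$hotspot_width_bp / 2))
  # union of (possibly overlapping) hotspot intervals for the rate profile
  bounds <- c(0, L)
  if (nrow(hs)) {
    m <- hs[order(hs$start), ]
    u_start <- m$start[1L]; u_end <- m$end[1L]
    us <- numeric(0); ue <- numeric(0)
    for (i in seq_len(nrow(m))[-1L]) {
      if (m$start[i] <= u_end) u_end <- max(u_end, m$end[i])
      else { us <- c(us, u_start); ue <- c(ue, u_end); u_start <- m$start[i]; u_end <- m$end[i] }
    }
    us <- c(us, u_start); ue <- c(ue, u_end)
    bounds <- sort(unique(c(0, L, us, ue)))
    hot_iv <- cbind(us, ue)
  } else hot_iv <- NULL
  start <- bounds[-length(bounds)]; end <- bounds[-1L]
  rate <- rep(spec$background_rate, length(start))
  if (!is.null(hot_iv)) {
    mid <- (start + end) / 2
    in_hot <- vapply(mid, function(p) any(p >= hot_iv[, 1L] & p < hot_iv[, 2L]), logical(1))
    rate[in_hot] <- spec$background_rate * spec$intensity_fold
  }
  m <- recomb_map(spec$chrom, start, end, rate, hotspots = hs)
  attr(m, "map_spec") <- spec
  m
}

#' Generate a hotspot-punctuated recombination map
#'
#' Hotspot centres follow a homogeneous Poisson process with intensity
#' `hotspot_rate` per Mb; the rate inside a hotspot is
#' `intensity_fold * background_rate` and `background_rate` elsewhere.
#' Deterministic given `seed`.
#'
#' @param spec A [genetic_map_spec()].
#' @param seed Integer seed.
#' @return A [recomb_map()] carrying its hotspot table and spec as
#'   attributes.
#' @export
synth_map <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "genetic_map_spec"))
  with_seed(seed, {
    lambda <- spec$hotspot_rate * spec$chrom_length_bp / 1e6
    n_hot <- rpois(1L, lambda)
    centers <- sort(runif(n_hot, 0, spec$chrom_length_bp))
    map_from_centers(spec, centers)
  })
}

#' Derive a sibling map sharing a fraction of hotspots
#'
#' Produces a second map over the same chromosome that keeps each hotspot of
#' the input independently with probability `shared_fraction`, drops the
#' rest, and adds new private hotspots so the expected hotspot count is
#' preserved. The background rate, hotspot width and intensity are carried
#' over. With `shared_fraction = 1` the output's hotspot set equals the
#' input's and nothing new is added.
#'
#' For a fixed `seed`, retention is coupled across values of
#' `shared_fraction` (a hotspot kept at a lower fraction is also kept at any
#' higher one, and private additions nest the other way), so a series of
#' sibling maps at increasing `shared_fraction` converges monotonically to
#' the input map.
#'
#' @param map A map produced by [synth_map()] (must carry hotspot
#'   annotation).
#' @param shared_fraction Probability in \[0, 1\] of retaining each hotspot.
#' @param seed Integer seed.
#' @return A [recomb_map()].
#' @export
derive_sibling_map <- function(map, shared_fraction, seed = NULL) {
  hs <- attr(map, "hotspots")
  spec <- attr(map, "map_spec")
  if (is.null(hs) || is.null(spec)) {
    stop("input map carries no hotspot annotation; derive it from synth_map()")
  }
  if (shared_fraction < 0 || shared_fraction > 1) stop("shared_fraction must be in [0, 1]")
  n <- nrow(hs)
  with_seed(seed, {
    u_keep <- runif(n)
    kept <- hs$center[u_keep < shared_fraction]
    # Poisson count of private hotspots, quantile-coupled so the count
    # decreases as shared_fraction rises; candidates come from a common pool.
    u_n <- runif(1L)
    lambda_new <- n * (1 - shared_fraction)
    k_new <- if (lambda_new > 0) qpois(u_n, lambda_new) else 0L
    pool_size <- max(qpois(1 - 1e-12, n), k_new)
    pool <- runif(pool_size, 0, spec$chrom_length_bp)
    centers <- c(kept, if (k_new > 0) pool[seq_len(k_new)])
    map_from_centers(spec, centers)
  })
}

#' Sample crossover positions from a genetic map
#'
#' The number of crossovers per meiosis is Poisson with mean equal to the
#' map's total genetic length in Morgans (no interference); positions are
#' uniform on the genetic (cM) axis and mapped back to bp by inverting the
#' cumulative map, so crossovers concentrate where the rate is high.
#'
#' @param map A [recomb_map()].
#' @param seed Optional integer seed.
#' @return Sorted numeric vector of crossover positions (bp).
#' @export
sample_crossovers <- function(map, seed = NULL) {
  total_cm <- map_total_cm(map)
  if (total_cm <= 0) stop("map has zero genetic length")
  with_seed(seed, {
    k <- rpois(1L, total_cm / 100)
    if (k == 0L) return(numeric(0))
    sort(interp_bp(map, runif(k, 0, total_cm)))
  })
}
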