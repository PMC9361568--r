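#' IBD length spectrum
#'
#' Bins IBD segment genetic lengths for effective-population-size inference.
#'
#' @param segments An [ibd_segments()] table (or a numeric vector of lengths
#'   in cM).
#' @param bin_edges Ascending cM bin edges; the last may be `Inf` (default:
#'   0.5-cM bins from 3 to 20 cM plus an open tail).
#' @param n_pairs Number of haplotype pairs the segments were called over.
#' @param genome_cm Total genetic length analysed, in cM (summed over
#'   chromosomes).
#' @return An `ibd_spectrum` list: `bin_edges`, `counts`, `n_pairs`,
#'   `genome_cm`.
#' @export
ibd_spectrum <- function(segments, n_pairs, genome_cm,
                         bin_edges = c(seq(3, 20, by = 0.5), Inf)) {
  if (any(diff(bin_edges) <= 0)) stop("bin edges must be strictly increasing")
  len <- if (is.numeric(segments)) segments else segments$length_cm
  len <- len[len >= bin_edges[1L]]
  counts <- as.numeric(table(cut(len, bin_edges, right = FALSE)))
  structure(list(bin_edges = bin_edges, counts = counts, n_pairs = n_pairs,
                 genome_cm = genome_cm),
            class = "ibd_spectrum")
}

#' Effective number of haplotype pairs for one ancestry
#'
#' Ancestry-specific IBD only accrues where both haplotypes of a pair carry
#' the ancestry, so the pair count entering the spectrum model is the full
#' pair count scaled by the cohort-mean dual-ancestry genome fraction
#' (approximated as the squared mean haplotype ancestry fraction).
#'
#' @param n_haplotypes Total haplotypes analysed.
#' @param ancestry_fraction Mean genome fraction of the ancestry per
#'   haplotype.
#' @return Effective pair count.
#' @export
effective_pairs <- function(n_haplotypes, ancestry_fraction = 1) {
  choose(n_haplotypes, 2) * ancestry_fraction^2
}

#' Piecewise-constant effective population size trajectories
#'
#' @param generations Ascending integer generations before present.
#' @param ne Effective diploid population size per generation (> 0).
#' @param lwr,upr Optional 95% bounds.
#' @return An `ne_trajectory` data.frame.
#' @export
ne_trajectory <- function(generations, ne, lwr = NULL, upr = NULL) {
  if (any(ne <= 0)) stop("ne must be positive")
  if (any(diff(generations) <= 0)) stop("generations must be ascending")
  d <- data.frame(gen = generations, ne = ne)
  if (!is.null(lwr)) d$lwr <- lwr
  if (!is.null(upr)) d$upr <- upr
  if (!is.null(lwr) && !is.null(upr) &&
      any(d$lwr > d$ne + 1e-9 | d$upr < d$ne - 1e-9, na.rm = TRUE)) {
    stop("bounds must bracket the point estimate")
  }
  structure(d, class = c("ne_trajectory", "data.frame"))
}

# Coalescence mass per generation for a trajectory extended by a constant
# ancient epoch (N = last grid value) up to g_cap.
coalescence_mass <- function(gens, ne, g_cap, g_floor = NULL) {
  g_start <- min(g_floor %||% gens[1L], gens[1L])
  g_all <- seq.int(g_start, g_cap)
  n_all <- c(rep(ne[1L], gens[1L] - g_start),              # backward extension
             ne[match(gens[1L]:gens[length(gens)], gens)], # contiguous grid
             rep(ne[length(ne)], g_cap - gens[length(gens)]))
  if (anyNA(n_all)) stop("trajectory grid must be contiguous in generations")
  haz <- 1 / (2 * n_all)
  surv <- cumprod(1 - haz)
  q <- haz * c(1, surv[-length(surv)])
  list(g = g_all, q = q)
}

#' Expected IBD length spectrum under a demographic trajectory
#'
#' Moment model linking recent population size to the IBD length spectrum:
#' a haplotype pair coalesces at generation `g` with probability
#' `q_g = 1/(2 N_g) * prod_(k<g) (1 - 1/(2 N_k))`; given coalescence at
#' `g`, IBD segments of genetic length `u` Morgans occur with density
#' `L (2g)^2 exp(-2 g u)` where `L` is the analysed genome length in
#' Morgans (interior approximation, no chromosome-end terms). Coalescence
#' mass beyond the grid is closed with a constant ancient epoch at the last
#' grid size (`ancient = "extend"`), or discarded (`"truncate"`). The bin
#' integral is evaluated in closed form.
#'
#' @param traj An [ne_trajectory()] on a contiguous integer grid.
#' @param n_pairs Number of haplotype pairs.
#' @param genome_cm Analysed genome length in cM (ignored when `chrom_cm`
#'   is given).
#' @param bin_edges Ascending cM bin edges (last may be `Inf`).
#' @param ancient `"extend"` (default) or `"truncate"`.
#' @param chrom_cm Optional vector of per-chromosome genetic lengths (cM).
#'   When supplied, the exact finite-chromosome segment law is used instead
#'   of the interior approximation: the `(L - u)` position factor,
#'   chromosome-end segments, and the whole-chromosome no-recombination
#'   atom are all accounted for. Recommended whenever bin lengths are not
#'   negligible against chromosome lengths.
#' @param g_floor Optional generation floor below the grid: when given
#'   (e.g. 1), coalescence mass is modelled from `g_floor` onward with the
#'   population size tied to the first grid value, so segments produced by
#'   very recent (close-kin) coalescences are accounted for even though the
#'   reporting grid starts later.
#' @return Numeric vector of expected counts per bin.
#' @export
expected_spectrum <- function(traj, n_pairs, genome_cm, bin_edges,
                              ancient = c("extend", "truncate"),
                              chrom_cm = NULL, g_floor = NULL) {
  ancient <- match.arg(ancient)
  if (any(traj$ne <= 0)) stop("ne must be positive")
  if (length(bin_edges) < 2L) stop("need at least one bin")
  a <- bin_edges[-length(bin_edges)] / 100   # Morgans
  b <- bin_edges[-1L] / 100
  g_max <- traj$gen[nrow(traj)]
  g_cap <- if (ancient == "extend") {
    # beyond this, exp(-2 g min_edge) makes contributions negligible
    max(g_max, ceiling(25 / max(a[1L], 1e-6)))
  } else g_max
  cm <- coalescence_mass(traj$gen, traj$ne, g_cap, g_floor = g_floor)
  two_g <- 2 * cm$g
  if (is.null(chrom_cm)) {
    L <- genome_cm / 100
    # interior approximation: count in [a, b) = L * 2g * (e^(-2ga) - e^(-2gb))
    ea <- exp(-outer(two_g, a))              # g x bin
    eb <- exp(-outer(two_g, b))
    eb[, !is.finite(b)] <- 0
    per_g <- (ea - eb) * two_g * L
    return(as.numeric(n_pairs * colSums(per_g * cm$q)))
  }
  # exact law per chromosome of length Lc Morgans, breakpoints Poisson(2g):
  #  interior: int_a^b (Lc - u) (2g)^2 e^(-2gu) du
  #  ends:     2 int_a^b 2g e^(-2gu) du
  #  atom:     e^(-2g Lc) if Lc in [a, b)
  tab <- base::table(chrom_cm / 100)
  Lcs <- as.numeric(names(tab)); mult <- as.numeric(tab)
  total <- numeric(length(a))
  for (ci in seq_along(Lcs)) {
    Lc <- Lcs[ci]
    aa <- pmin(a, Lc); bb <- pmin(b, Lc)
    E1 <- exp(-outer(two_g, aa)); E2 <- exp(-outer(two_g, bb))
    ta <- outer(two_g, aa); tb <- outer(two_g, bb)
    per_g <- Lc * two_g * (E1 - E2) + E1 * (1 - ta) - E2 * (1 - tb)
    atom <- as.numeric(Lc >= a & Lc < b)
    per_g <- per_g + outer(exp(-two_g * Lc), atom)
    per_g[per_g < 0] <- 0
    total <- total + mult[ci] * colSums(per_g * cm$q)
  }
  as.numeric(n_pairs * total)
}

#' Fit a recent effective population size trajectory to an IBD spectrum
#'
#' Minimizes the Poisson negative log-likelihood of the binned segment
#' counts under [expected_spectrum()], over `log N_g` on the generation
#' grid, plus a smoothness penalty
#' `smooth_penalty * sum (log N_(g+1) - log N_g)^2`. The optimizer starts
#' from a flat trajectory whose constant size matches the observed total
#' segment count (method of moments), making the fit deterministic.
#'
#' @param spectrum An [ibd_spectrum()] with at least one nonzero bin.
#' @param grid Ascending contiguous integer generations (default 4:50; the
#'   grid starts at 4 to avoid coalescences reflecting close genealogical
#'   relationships rather than population size).
#' @param smooth_penalty Weight of the squared log-difference penalty
#   (default 200).
#' @param ancient Ancient-epoch closure passed to [expected_spectrum()].
#' @param reltol Relative objective-change convergence tolerance (default
#'   1e-6).
#' @param chrom_cm Optional per-chromosome genetic lengths (cM) switching
#'   [expected_spectrum()] to the exact finite-chromosome law.
#' @param g_floor Generation floor passed to [expected_spectrum()] (default
#'   1): close-kin coalescences more recent than the grid are modelled at
#'   the first grid size rather than ignored, which keeps them from
#'   contaminating the recent estimates.
#' @return An [ne_trajectory()]; attributes `objective` and `convergence`.
#' @export
fit_ne <- function(spectrum, grid = 4:50, smooth_penalty = 200,
                   ancient = "extend", reltol = 1e-6, chrom_cm = NULL,
                   g_floor = 1L) {
  counts <- spectrum$counts
  if (sum(counts) == 0) stop("insufficient IBD: spectrum has no segments")
  edges <- spectrum$bin_edges
  obj_parts <- function(logn) {
    mu <- expected_spectrum(ne_trajectory(grid, exp(logn)), spectrum$n_pairs,
                            spectrum$genome_cm, edges, ancient = ancient,
                            chrom_cm = chrom_cm, g_floor = g_floor)
    mu <- pmax(mu, 1e-12)
    sum(mu - counts * log(mu))
  }
  objective <- function(logn) {
    obj_parts(logn) + smooth_penalty * sum(diff(logn)^2)
  }
  # method-of-moments start: constant N matching the total expected count
  total_at <- function(log10n) {
    sum(expected_spectrum(ne_trajectory(grid, rep(10^log10n, length(grid))),
                          spectrum$n_pairs, spectrum$genome_cm, edges,
                          ancient = ancient, chrom_cm = chrom_cm,
                          g_floor = g_floor)) - sum(counts)
  }
  lo <- 0.5; hi <- 8
  start_log10 <- tryCatch(uniroot(total_at, c(lo, hi))$root,
                          error = function(e) 3)
  start <- rep(start_log10 * log(10), length(grid))
  fit <- optim(start, objective, method = "L-BFGS-B",
               lower = log(2), upper = log(1e9),
               control = list(maxit = 1000, factr = reltol / .Machine$double.eps))
  if (fit$convergence != 0 && fit$convergence != 1) {
    stop(sprintf("fit_ne failed to converge (code %d): %s",
                 fit$convergence, fit$message))
  }
  out <- ne_trajectory(grid, exp(fit$par))
  attr(out, "objective") <- fit$value
  attr(out, "convergence") <- fit$convergence
  out
}

#' Bootstrap confidence intervals for the fitted trajectory
#'
#' Resamples genomic chunks (typically chromosomes) with replacement,
#' refits, and reports percentile 2.5/97.5 bounds per generation around the
#' full-data point estimate.
#'
#' @param chunks List (length >= 2) of per-chunk [ibd_segments()] tables or
#'   length vectors; each element must carry attributes or entries
#'   `genome_cm` via `chunk_cm`.
#' @param chunk_cm Numeric vector of each chunk's genetic length (cM).
#' @param n_pairs Haplotype pair count (shared by all chunks).
#' @param n_boot Number of bootstrap replicates (>= 2).
#' @param seed Integer seed.
#' @param grid,smooth_penalty,bin_edges,ancient Passed to [fit_ne()] /
#'   [ibd_spectrum()].
#' @param finite_chrom Treat each chunk as a chromosome and use the exact
#'   finite-chromosome law (default `FALSE`).
#' @return An [ne_trajectory()] with `lwr` and `upr` columns.
#' @export
bootstrap_ne <- function(chunks, chunk_cm, n_pairs, n_boot = 50, seed = NULL,
                         grid = 4:50, smooth_penalty = 200,
                         bin_edges = c(seq(3, 20, by = 0.5), Inf),
                         ancient = "extend", finite_chrom = FALSE) {
  if (length(chunks) < 2L) stop("need at least 2 chunks to bootstrap")
  if (n_boot < 2L) stop("n_boot must be >= 2")
  if (length(chunk_cm) != length(chunks)) stop("chunk_cm must match chunks")
  lens <- lapply(chunks, function(x) if (is.numeric(x)) x else x$length_cm)
  full <- fit_ne(ibd_spectrum(unlist(lens), n_pairs, sum(chunk_cm), bin_edges),
                 grid = grid, smooth_penalty = smooth_penalty, ancient = ancient,
                 chrom_cm = if (finite_chrom) chunk_cm else NULL)
  reps <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      pick <- sample.int(length(chunks), replace = TRUE)
      sp <- ibd_spectrum(unlist(lens[pick]), n_pairs, sum(chunk_cm[pick]), bin_edges)
      fit_ne(sp, grid = grid, smooth_penalty = smooth_penalty,
             ancient = ancient,
             chrom_cm = if (finite_chrom) chunk_cm[pick] else NULL)$ne
    }, numeric(length(grid)))
  })
  ne_trajectory(grid, full$ne,
                lwr = pmin(apply(reps, 1L, quantile, 0.025), full$ne),
                upr = pmax(apply(reps, 1L, quantile, 0.975), full$ne))
}

#' Read / write effective-size tables in the GEN/NE/LWR/UPR dialect
#'
#' Whitespace-separated table with header `GEN NE LWR UPR` (bounds
#' optional), matching the output convention of IBD-based demography tools
#' so that externally produced tables and internal fits are interchangeable.
#'
#' @param path File path.
#' @return [read_ne_table()] returns an [ne_trajectory()].
#' @export
read_ne_table <- function(path) {
  d <- read.table(path, header = TRUE, stringsAsFactors = FALSE)
  names(d) <- toupper(names(d))
  if (!all(c("GEN", "NE") %in% names(d))) stop("expected columns GEN and NE")
  ne_trajectory(d$GEN, d$NE,
                lwr = if ("LWR" %in% names(d)) d$LWR,
                upr = if ("UPR" %in% names(d)) d$UPR)
}

#' @param traj An [ne_trajectory()] for [write_ne_table()].
#' @rdname read_ne_table
#' @export
write_ne_table <- function(traj, path) {
  d <- data.frame(GEN = traj$gen, NE = traj$ne)
  if (!is.null(traj$lwr)) { d$LWR <- traj$lwr; d$UPR <- traj$upr }
  write.table(format(d, digits = 10, scientific = FALSE, trim = TRUE), path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
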