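#' Recombination map objects
#'
#' A `recomb_map` is a piecewise-constant recombination rate map for a single
#' chromosome: ordered, contiguous, 0-based half-open intervals, each with a
#' per-base-pair per-generation recombination probability, plus the cumulative
#' genetic position (cM) at every interval start.
#'
#' @param chrom Chromosome name (single string).
#' @param start,end Integer-valued interval bounds in bp (0-based half-open).
#'   Intervals must be sorted, non-overlapping and contiguous.
#' @param rate Per-bp per-generation recombination probability per interval
#'   (a rate of 1e-8 corresponds to 1 cM/Mb).
#' @param hotspots Optional data.frame of hotspot intervals
#'   (columns `center`, `start`, `end`) carried as an attribute; used by
#'   map-derivation and concordance utilities.
#' @return An object of class `recomb_map`: a data.frame with columns
#'   `chrom`, `start`, `end`, `rate`, `cm_start`, `cm_end`.
#' @export
recomb_map <- function(chrom, start, end, rate, hotspots = NULL) {
  if (length(unique(chrom)) != 1L) stop("a recomb_map covers a single chromosome")
  o <- order(start)
  start <- as.numeric(start)[o]; end <- as.numeric(end)[o]; rate <- as.numeric(rate)[o]
  if (any(end <= start)) stop("map intervals must have end > start")
  if (any(rate < 0)) stop("negative recombination rate")
  if (length(start) > 1L && any(start[-1L] != end[-length(end)])) {
    stop("map intervals must be contiguous")
  }
  cm <- c(0, cumsum(rate * (end - start) * 100))
  m <- data.frame(
    chrom = rep(chrom[[1L]], length(start)),
    start = start, end = end, rate = rate,
    cm_start = cm[-length(cm)] , cm_end = cm[-1L],
    stringsAsFactors = FALSE
  )
  structure(m, class = c("recomb_map", "data.frame"), hotspots = hotspots)
}

#' @export
print.recomb_map <- function(x, ...) {
  cat(sprintf(
    "recomb_map: %s, %d intervals, span [%.0f, %.0f) bp, %.4f cM%s\n",
    x$chrom[1L], nrow(x), x$start[1L], x$end[nrow(x)], map_total_cm(x),
    if (!is.null(attr(x, "hotspots"))) sprintf(", %d hotspots", nrow(attr(x, "hotspots"))) else ""
  ))
  invisible(x)
}

#' Total genetic length of a map in cM
#' @param map A [recomb_map()].
#' @export
map_total_cm <- function(map) map$cm_end[nrow(map)]

#' Physical span of a map
#' @param map A [recomb_map()].
#' @return Numeric length-2 vector `c(start, end)` in bp.
#' @export
map_span <- function(map) c(map$start[1L], map$end[nrow(map)])

#' Interpolate cumulative genetic position
#'
#' Linear interpolation of the cumulative genetic map (cM) at physical
#' positions. Because the rate is piecewise constant the cumulative map is
#' piecewise linear, so interpolation within an interval is exact.
#'
#' @param map A [recomb_map()].
#' @param pos Physical positions (bp).
#' @param clamp If `TRUE`, positions outside the map span are clamped to its
#'   ends; if `FALSE` (default) they raise an error.
#' @return Cumulative genetic positions in cM.
#' @export
interp_cm <- function(map, pos, clamp = FALSE) {
  sp <- map_span(map)
  out_of_span <- pos < sp[1L] | pos > sp[2L]
  if (any(out_of_span)) {
    if (!clamp) stop(sprintf("position %g outside map span [%g, %g]",
                             pos[which(out_of_span)[1L]], sp[1L], sp[2L]))
    pos <- pmin(pmax(pos, sp[1L]), sp[2L])
  }
  knots_bp <- c(map$start, sp[2L])
  knots_cm <- c(map$cm_start, map_total_cm(map))
  approx(knots_bp, knots_cm, xout = pos, method = "linear", ties = "ordered")$y
}

# Inverse of interp_cm: physical position at a cumulative cM value.
interp_bp <- function(map, cm) {
  sp <- map_span(map)
  knots_bp <- c(map$start, sp[2L])
  knots_cm <- c(map$cm_start, map_total_cm(map))
  # cumulative cM can be flat over zero-rate intervals; ties = "ordered" picks
  # the leftmost bp, which is a measure-zero event for continuous draws
  approx(knots_cm, knots_bp, xout = cm, method = "linear", ties = "ordered")$y
}

#' Read a genetic map
#'
#' Reads either of two text dialects into a [recomb_map()]:
#' * `"hapmap"`: whitespace-separated columns `Position(bp)`, `Rate(cM/Mb)`,
#'   `Map(cM)`, with an optional leading `Chromosome` column. The rate on a
#'   row applies from that row's position to the next row's position. Rates
#'   are converted from cM/Mb to per-bp probabilities (x 1e-8), and the `Map`
#'   column is cross-checked against the cumulative map recomputed from the
#'   rates (tolerance 1e-6 cM).
#' * `"interval"`: tab-separated columns `chrom`, `start`, `end`, `rate`
#'   with a per-bp per-generation rate, 0-based half-open.
#'
#' @param path File path.
#' @param dialect `"hapmap"` or `"interval"`.
#' @return A [recomb_map()].
#' @export
read_map <- function(path, dialect = c("hapmap", "interval")) {
  dialect <- match.arg(dialect)
  if (dialect == "interval") {
    d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    need <- c("chrom", "start", "end", "rate")
    if (!all(need %in% names(d))) stop("interval map must have columns chrom, start, end, rate")
    if (length(unique(d$chrom)) != 1L) {
      stop("map file contains multiple chromosomes; split per chromosome first")
    }
    return(recomb_map(d$chrom, d$start, d$end, d$rate))
  }
  d <- read.table(path, header = TRUE, stringsAsFactors = FALSE,
                  check.names = FALSE, comment.char = "")
  cols <- tolower(names(d))
  pos_i <- grep("^position", cols)[1L]
  rate_i <- grep("^rate", cols)[1L]
  map_i <- grep("^map", cols)[1L]
  chrom_i <- grep("^chr", cols)[1L]
  if (is.na(pos_i) || is.na(rate_i)) stop("hapmap dialect needs Position and Rate columns")
  chrom <- if (!is.na(chrom_i)) as.character(d[[chrom_i]]) else "chr"
  if (length(unique(chrom)) != 1L) {
    stop("map file contains multiple chromosomes; split per chromosome first")
  }
  pos <- as.numeric(d[[pos_i]])
  if (any(diff(pos) <= 0)) {
    stop_format(path, which(diff(pos) <= 0)[1L] + 2L, "positions not strictly increasing")
  }
  rate_cm_mb <- as.numeric(d[[rate_i]])
  if (any(rate_cm_mb < 0)) {
    stop_format(path, which(rate_cm_mb < 0)[1L] + 1L, "negative recombination rate")
  }
  n <- length(pos)
  m <- recomb_map(chrom[1L], pos[-n], pos[-1L], rate_cm_mb[-n] * 1e-8)
  if (!is.na(map_i)) {
    given <- as.numeric(d[[map_i]])
    recomputed <- c(m$cm_start, map_total_cm(m)) + given[1L]
    bad <- which(abs(recomputed - given) > 1e-6)
    if (length(bad)) {
      stop_format(path, bad[1L] + 1L,
                  sprintf("Map column inconsistent with rates (off by %.3g cM)",
                          recomputed[bad[1L]] - given[bad[1L]]))
    }
  }
  m
}

#' Write a genetic map
#'
#' @param map A [recomb_map()].
#' @param path Output file.
#' @param dialect `"hapmap"` or `"interval"` (see [read_map()]).
#' @export
write_map <- function(map, path, dialect = c("hapmap", "interval")) {
  dialect <- match.arg(dialect)
  if (dialect == "interval") {
    d <- data.frame(chrom = map$chrom, start = map$start, end = map$end,
                    rate = map$rate)
    write.table(format(d, digits = 17, scientific = FALSE, trim = TRUE),
                path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    n <- nrow(map)
    d <- data.frame(
      Chromosome = c(map$chrom, map$chrom[n]),
      `Position(bp)` = c(map$start, map$end[n]),
      `Rate(cM/Mb)` = c(map$rate * 1e8, 0),
      `Map(cM)` = c(map$cm_start, map$cm_end[n]),
      check.names = FALSE
    )
    write.table(format(d, digits = 17, scientific = FALSE, trim = TRUE),
                path, sep = " ", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Bin a map's recombination rate at fixed physical resolution
#'
#' Computes the mean rate (cM/Mb) in consecutive physical bins anchored at
#' position 0. The per-bin value is the cumulative-cM difference across the
#' bin divided by the bin width in Mb, which is exact regardless of how the
#' map's intervals align with the bins. Bins with no map coverage are `NA`
#' (missing, not zero); a partially covered edge bin uses the covered cM over
#' the full bin width only when `partial = "scale"` (default drops it).
#'
#' @param map A [recomb_map()].
#' @param bin_width Bin width in bp (default 2000, a 2-kb resolution).
#' @param partial How to treat bins only partially covered by the map:
#'   `"drop"` (default, value `NA`) or `"scale"` (mean rate over the covered
#'   part).
#' @return A `binned_map`: data.frame with columns `bin` (0-based index),
#'   `start`, `end`, `value` (cM/Mb); attributes `bin_width`, `chrom`.
#' @export
bin_rates <- function(map, bin_width = 2000, partial = c("drop", "scale")) {
  partial <- match.arg(partial)
  if (bin_width <= 0) stop("bin_width must be positive")
  sp <- map_span(map)
  first_bin <- floor(sp[1L] / bin_width)
  last_bin <- ceiling(sp[2L] / bin_width) - 1L
  bins <- seq.int(first_bin, last_bin)
  lo <- bins * bin_width
  hi <- lo + bin_width
  clo <- pmax(lo, sp[1L]); chi <- pmin(hi, sp[2L])
  cm <- interp_cm(map, chi) - interp_cm(map, clo)
  covered <- (chi - clo)
  value <- ifelse(covered > 0, cm / (covered / 1e6), NA_real_)
  if (partial == "drop") value[covered < bin_width] <- NA_real_
  out <- data.frame(bin = bins, start = lo, end = hi, value = value)
  structure(out, class = c("binned_map", "data.frame"),
            bin_width = bin_width, chrom = map$chrom[1L])
}

#' Pairwise Spearman correlation between binned maps
#'
#' Rank correlation deliberately ignores the magnitude of the recombination
#' rate in favour of its qualitative profile, so maps whose rates differ by
#' any monotone rescaling correlate perfectly.
#'
#' @param binned Named list of `binned_map` objects produced by [bin_rates()]
#'   at identical `bin_width`.
#' @param min_overlap Minimum number of pairwise complete bins for an entry
#'   to be computed; pairs below it are `NA` (flagged missing, never 0).
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(binned, min_overlap = 100) {
  if (is.null(names(binned))) names(binned) <- paste0("map", seq_along(binned))
  bw <- vapply(binned, attr, numeric(1), "bin_width")
  if (length(unique(bw)) != 1L) stop("all maps must be binned at the same width")
  all_bins <- sort(unique(unlist(lapply(binned, `[[`, "bin"))))
  vals <- vapply(binned, function(b) {
    v <- rep(NA_real_, length(all_bins))
    v[match(b$bin, all_bins)] <- b$value
    v
  }, numeric(length(all_bins)))
  k <- ncol(vals)
  out <- matrix(NA_real_, k, k, dimnames = list(colnames(vals), colnames(vals)))
  for (i in seq_len(k)) {
    out[i, i] <- 1
    for (j in seq_len(k)[-seq_len(i)]) {
      ok <- stats::complete.cases(vals[, c(i, j)])
      if (sum(ok) >= min_overlap) {
        out[i, j] <- out[j, i] <-
          cor(vals[ok, i], vals[ok, j], method = "spearman")
      }
    }
  }
  out
}

#' Order maps by hierarchical clustering of their correlation matrix
#'
#' Average-linkage hierarchical clustering on the distance `1 - rho`.
#'
#' @param mat Symmetric correlation matrix without missing entries.
#' @return List with `order` (leaf labels left to right), `hclust` (the
#'   clustering object) and `merge_heights`.
#' @export
cluster_order <- function(mat) {
  if (any(is.na(mat))) {
    stop("correlation matrix has missing entries; impute or raise map overlap before clustering")
  }
  # reorder rows/cols by label so the result is independent of input order
  lab <- sort(rownames(mat))
  mat <- mat[lab, lab]
  hc <- hclust(as.dist(1 - mat), method = "average")
  list(order = lab[hc$order], hclust = hc, merge_heights = hc$height)
}

#' Call recombination hotspots against a local background
#'
#' Flags maximal runs of map intervals whose rate is at least `fold` times
#' the local background, where the background at an interval is the
#' length-weighted median rate over flanking windows of `bg_window_bp` on
#' each side. Runs narrower than `min_width_bp` are discarded. Calls are
#' invariant to any global rescaling of the map's rates.
#'
#' @param map A [recomb_map()].
#' @param bg_window_bp Flanking window for the background median (default
#'   1e5).
#' @param fold Rate multiple over background required (default 10, must
#'   exceed 1).
#' @param min_width_bp Minimum call width (default 500 bp).
#' @return data.frame of hotspot intervals (`start`, `end`, `peak_rate`,
#'   `background`).
#' @export
call_hotspots <- function(map, bg_window_bp = 1e5, fold = 10, min_width_bp = 500) {
  if (fold <= 1) stop("fold must exceed 1")
  widths <- map$end - map$start
  # the flanking window must be able to contain at least one full interval
  if (nrow(map) > 1L && bg_window_bp < min(widths)) {
    stop("bg_window_bp is smaller than the map's interval resolution")
  }
  n <- nrow(map)
  bg <- numeric(n)
  for (i in seq_len(n)) {
    lo <- map$start[i] - bg_window_bp; hi <- map$end[i] + bg_window_bp
    j <- which(map$end > lo & map$start < hi)
    j <- setdiff(j, i)
    if (!length(j)) { bg[i] <- map$rate[i]; next }
    w <- pmin(map$end[j], hi) - pmax(map$start[j], lo)
    bg[i] <- weighted_median(map$rate[j], w)
  }
  hot <- map$rate >= fold * bg & bg > 0
  r <- rle(hot)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  out <- data.frame(start = numeric(0), end = numeric(0),
                    peak_rate = numeric(0), background = numeric(0))
  for (k in which(r$values)) {
    i0 <- starts[k]; i1 <- ends[k]
    s <- map$start[i0]; e <- map$end[i1]
    if (e - s >= min_width_bp) {
      out <- rbind(out, data.frame(
        start = s, end = e,
        peak_rate = max(map$rate[i0:i1]),
        background = stats::median(bg[i0:i1])
      ))
    }
  }
  out
}

weighted_median <- function(x, w) {
  o <- order(x); x <- x[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  x[which(cw >= 0.5)[1L]]
}

#' Concordance between two hotspot call sets
#'
#' Two calls are shared when their reciprocal overlap is at least
#' `min_reciprocal` of each call's width.
#'
#' @param calls_a,calls_b Hotspot tables from [call_hotspots()].
#' @param min_reciprocal Reciprocal-overlap fraction (default 0.5).
#' @return List with counts `n_a`, `n_b`, `shared_a`, `shared_b` and the
#'   shared fraction per side.
#' @export
hotspot_concordance <- function(calls_a, calls_b, min_reciprocal = 0.5) {
  shared <- function(a, b) {
    if (!nrow(a)) return(0L)
    hits <- vapply(seq_len(nrow(a)), function(i) {
      ov <- pmin(a$end[i], b$end) - pmax(a$start[i], b$start)
      any(ov >= min_reciprocal * (a$end[i] - a$start[i]) &
            ov >= min_reciprocal * (b$end - b$start))
    }, logical(1))
    sum(hits)
  }
  n_a <- nrow(calls_a); n_b <- nrow(calls_b)
  sa <- if (n_b) shared(calls_a, calls_b) else 0L
  sb <- if (n_a) shared(calls_b, calls_a) else 0L
  list(n_a = n_a, n_b = n_b, shared_a = sa, shared_b = sb,
       frac_a = if (n_a) sa / n_a else NA_real_,
       frac_b = if (n_b) sb / n_b else NA_real_)
}
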