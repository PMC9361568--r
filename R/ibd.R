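#' IBD segment tables
#'
#' An `ibd_segments` table has one row per identity-by-descent segment
#' between two haplotypes: columns `sample_a`, `hap_a`, `sample_b`, `hap_b`
#' (haplotype index 0/1), `chrom`, `start`, `end` (bp, 0-based half-open),
#' `score` (caller quality, may be `NA`), `length_cm`, and optionally
#' `ancestry` and `founder_id`. The haplotype pair is stored in canonical
#' order: `(sample_a, hap_a) <= (sample_b, hap_b)` lexicographically.
#'
#' @param d data.frame with at least the columns above.
#' @return A canonicalized `ibd_segments` data.frame.
#' @export
ibd_segments <- function(d) {
  need <- c("sample_a", "hap_a", "sample_b", "hap_b", "chrom", "start", "end",
            "score", "length_cm")
  if (!all(need %in% names(d))) {
    stop("ibd segments need columns ", paste(setdiff(need, names(d)), collapse = ", "))
  }
  if (any(d$end <= d$start)) stop("IBD segment with end <= start")
  if (any(d$length_cm < 0, na.rm = TRUE)) stop("negative genetic length")
  ka <- paste(d$sample_a, d$hap_a, sep = "\r")
  kb <- paste(d$sample_b, d$hap_b, sep = "\r")
  swap <- kb < ka
  if (any(swap)) {
    tmp_s <- d$sample_a[swap]; tmp_h <- d$hap_a[swap]
    d$sample_a[swap] <- d$sample_b[swap]; d$hap_a[swap] <- d$hap_b[swap]
    d$sample_b[swap] <- tmp_s; d$hap_b[swap] <- tmp_h
  }
  d <- d[order(d$sample_a, d$hap_a, d$sample_b, d$hap_b, d$start), ]
  rownames(d) <- NULL
  structure(as.data.frame(d), class = c("ibd_segments", "data.frame"))
}

#' Read an IBD segment table
#'
#' Parses the whitespace-separated caller dialect with columns
#' `id1 hap1 id2 hap2 chrom start end score length_cm` (haplotypes coded
#' 1/2, converted to 0/1 internally; physical coordinates taken as 0-based
#' half-open). When `map` is supplied, genetic lengths are recomputed from
#' it; otherwise the file's values are retained.
#'
#' @param path File path.
#' @param map Optional [recomb_map()].
#' @return An [ibd_segments()] table.
#' @export
read_ibd <- function(path, map = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(ibd_segments(data.frame(
      sample_a = character(0), hap_a = integer(0), sample_b = character(0),
      hap_b = integer(0), chrom = character(0), start = numeric(0),
      end = numeric(0), score = numeric(0), length_cm = numeric(0))))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(fields) != 9L)
  if (length(bad)) stop_format(path, bad[1L], "expected 9 whitespace-separated columns")
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.numeric(m[, 6L]))
  end <- suppressWarnings(as.numeric(m[, 7L]))
  num_bad <- which(is.na(start) | is.na(end))
  if (length(num_bad)) stop_format(path, num_bad[1L], "non-numeric coordinates")
  if (any(start >= end)) stop_format(path, which(start >= end)[1L], "start >= end")
  d <- data.frame(
    sample_a = m[, 1L], hap_a = as.integer(m[, 2L]) - 1L,
    sample_b = m[, 3L], hap_b = as.integer(m[, 4L]) - 1L,
    chrom = m[, 5L], start = start, end = end,
    score = suppressWarnings(as.numeric(m[, 8L])),
    length_cm = suppressWarnings(as.numeric(m[, 9L])),
    stringsAsFactors = FALSE
  )
  if (!is.null(map)) {
    d$length_cm <- interp_cm(map, d$end, clamp = TRUE) -
      interp_cm(map, d$start, clamp = TRUE)
  }
  ibd_segments(d)
}

#' Write an IBD segment table in the caller dialect
#' @param segments An [ibd_segments()] table.
#' @param path Output file.
#' @export
write_ibd <- function(segments, path) {
  lines <- sprintf("%s\t%d\t%s\t%d\t%s\t%s\t%s\t%s\t%.6f",
                   segments$sample_a, segments$hap_a + 1L,
                   segments$sample_b, segments$hap_b + 1L, segments$chrom,
                   format(segments$start, scientific = FALSE, trim = TRUE),
                   format(segments$end, scientific = FALSE, trim = TRUE),
                   ifelse(is.na(segments$score), "NA",
                          format(segments$score, trim = TRUE)),
                   segments$length_cm)
  writeLines(lines, path)
  invisible(path)
}

#' Merge gapped IBD segments of the same haplotype pair
#'
#' For every haplotype pair, consecutive segments whose intervening gap is
#' no larger than both `max_gap_cm` (genetic) and `max_gap_bp` (physical)
#' are fused into one segment spanning both; the fused genetic length is
#' recomputed from `map` when given, else summed plus the closed gaps'
#' pro-rata lengths. Abutting segments (gap 0) always fuse. The operation
#' is idempotent and never decreases total covered length.
#'
#' @param segments [ibd_segments()] on one chromosome.
#' @param max_gap_cm Maximum genetic gap in cM (default 0.6).
#' @param max_gap_bp Maximum physical gap in bp (default `Inf`).
#' @param map Optional [recomb_map()] for genetic gap measurement and
#'   recomputation of fused lengths. Without a map, genetic gaps are
#'   approximated by linear interpolation from each segment's own bp-to-cM
#'   ratio.
#' @return An [ibd_segments()] table.
#' @export
merge_ibd_gaps <- function(segments, max_gap_cm = 0.6, max_gap_bp = Inf,
                           map = NULL) {
  if (max_gap_cm < 0 || max_gap_bp < 0) stop("gap thresholds must be non-negative")
  if (!nrow(segments)) return(segments)
  if (length(unique(segments$chrom)) > 1L) {
    stop("merge_ibd_gaps expects segments of a single chromosome")
  }
  dt <- data.table::as.data.table(segments)
  dt$key <- paste(dt$sample_a, dt$hap_a, dt$sample_b, dt$hap_b, sep = "\r")
  data.table::setorderv(dt, c("key", "start", "end"))
  # running end of the fused segment so far within each pair
  run_end <- dt[, list(v = data.table::shift(cummax(end))), by = "key"]$v
  gap_bp <- dt$start - run_end
  gap_cm <- if (!is.null(map)) {
    interp_cm(map, pmax(dt$start, run_end, na.rm = TRUE), clamp = TRUE) -
      interp_cm(map, pmin(dt$start, run_end, na.rm = TRUE), clamp = TRUE)
  } else {
    # no map: price the gap at the mean cM/bp of the two flanking segments
    ratio <- dt$length_cm / (dt$end - dt$start)
    pmax(gap_bp, 0) * (ratio + data.table::shift(ratio, fill = ratio[1L])) / 2
  }
  mergeable <- gap_bp <= 0 | (gap_bp <= max_gap_bp & gap_cm <= max_gap_cm)
  new_grp <- is.na(gap_bp) | !mergeable
  dt$grp <- cumsum(new_grp)
  dt$gap_fill_cm <- ifelse(new_grp | gap_bp <= 0, 0, pmax(gap_cm, 0))
  dt$gap_fill_cm[is.na(dt$gap_fill_cm)] <- 0
  agg <- dt[, list(
    sample_a = sample_a[1L], hap_a = hap_a[1L],
    sample_b = sample_b[1L], hap_b = hap_b[1L], chrom = chrom[1L],
    start = min(start), end = max(end),
    score = if (all(is.na(score))) NA_real_ else max(score, na.rm = TRUE),
    length_sum = sum(length_cm) + sum(gap_fill_cm),
    founder_id = if ("founder_id" %in% names(dt)) founder_id[1L] else NA_integer_
  ), by = "grp"]
  agg$length_cm <- if (!is.null(map)) {
    interp_cm(map, agg$end, clamp = TRUE) - interp_cm(map, agg$start, clamp = TRUE)
  } else agg$length_sum
  agg$grp <- NULL; agg$length_sum <- NULL
  if (!"founder_id" %in% names(segments)) agg$founder_id <- NULL
  ibd_segments(as.data.frame(agg))
}

# Per-ancestry length of a segment over which BOTH haplotypes carry that
# ancestry, from two per-haplotype tract tables restricted to the segment.
dual_coverage <- function(seg_start, seg_end, ta, tb, alphabet) {
  bounds <- sort(unique(c(seg_start, seg_end,
                          ta$start[ta$start > seg_start & ta$start < seg_end],
                          tb$start[tb$start > seg_start & tb$start < seg_end])))
  lo <- bounds[-length(bounds)]; hi <- bounds[-1L]
  la <- ta$ancestry[findInterval(lo, ta$start)]
  lb <- tb$ancestry[findInterval(lo, tb$start)]
  w <- hi - lo
  out <- setNames(numeric(length(alphabet)), alphabet)
  both <- la == lb
  if (any(both)) {
    s <- tapply(w[both], la[both], sum)
    out[names(s)] <- s
  }
  out
}

#' Dual-coverage fractions of IBD segments per ancestry
#'
#' For every segment and every alphabet ancestry, the fraction of the
#' segment over which *both* haplotypes carry that ancestry. Rows sum to at
#' most 1 (strictly less where the two haplotypes disagree).
#'
#' @param segments An [ibd_segments()] table.
#' @param tracts A [tract_set()] covering both haplotypes of every segment.
#' @return Numeric matrix, segments x ancestries.
#' @export
ibd_dual_coverage <- function(segments, tracts) {
  alphabet <- attr(tracts, "alphabet")
  key_t <- paste(tracts$sample, tracts$hap, tracts$chrom, sep = "\r")
  idx <- split(seq_len(nrow(tracts)), key_t)
  out <- matrix(0, nrow(segments), length(alphabet),
                dimnames = list(NULL, alphabet))
  for (i in seq_len(nrow(segments))) {
    ka <- paste(segments$sample_a[i], segments$hap_a[i], segments$chrom[i], sep = "\r")
    kb <- paste(segments$sample_b[i], segments$hap_b[i], segments$chrom[i], sep = "\r")
    if (is.null(idx[[ka]])) stop(sprintf("haplotype %s/%s has no tracts",
                                         segments$sample_a[i], segments$hap_a[i]))
    if (is.null(idx[[kb]])) stop(sprintf("haplotype %s/%s has no tracts",
                                         segments$sample_b[i], segments$hap_b[i]))
    ta <- tracts[idx[[ka]], ]; ta <- ta[order(ta$start), ]
    tb <- tracts[idx[[kb]], ]; tb <- tb[order(tb$start), ]
    out[i, ] <- dual_coverage(segments$start[i], segments$end[i], ta, tb,
                              alphabet) / (segments$end[i] - segments$start[i])
  }
  out
}

#' Assign an ancestry label to each IBD segment
#'
#' For every segment, computes the length over which *both* haplotypes carry
#' each ancestry (dual coverage) and labels the segment with the ancestry
#' whose dual-coverage fraction is at least `min_fraction`; segments where
#' no ancestry reaches the threshold, or where two tie at the maximum, are
#' labelled `"unassigned"`. Segments are labelled whole, never split at
#' ancestry switch points, so the segment length spectrum is preserved.
#'
#' @param segments An [ibd_segments()] table.
#' @param tracts A [tract_set()] covering both haplotypes of every segment.
#' @param min_fraction Dual-coverage fraction required (default 0.9).
#' @return `segments` with an `ancestry` column plus a `dual_fraction`
#'   column holding the winning coverage fraction.
#' @export
assign_ibd_ancestry <- function(segments, tracts, min_fraction = 0.9) {
  alphabet <- attr(tracts, "alphabet")
  key_t <- paste(tracts$sample, tracts$hap, tracts$chrom, sep = "\r")
  tract_idx <- split(seq_len(nrow(tracts)), key_t)
  get_tracts <- function(sample, hap, chrom) {
    k <- paste(sample, hap, chrom, sep = "\r")
    i <- tract_idx[[k]]
    if (is.null(i)) {
      stop(sprintf("haplotype %s/%s has no tracts on chromosome %s", sample, hap, chrom))
    }
    g <- tracts[i, ]
    g[order(g$start), ]
  }
  n <- nrow(segments)
  label <- character(n); frac <- numeric(n)
  for (i in seq_len(n)) {
    ta <- get_tracts(segments$sample_a[i], segments$hap_a[i], segments$chrom[i])
    tb <- get_tracts(segments$sample_b[i], segments$hap_b[i], segments$chrom[i])
    cov <- dual_coverage(segments$start[i], segments$end[i], ta, tb, alphabet)
    f <- cov / (segments$end[i] - segments$start[i])
    best <- max(f)
    winners <- which(f == best)
    if (best >= min_fraction && length(winners) == 1L) {
      label[i] <- alphabet[winners]
    } else {
      label[i] <- "unassigned"
    }
    frac[i] <- best
  }
  segments$ancestry <- label
  segments$dual_fraction <- frac
  segments
}

#' Partition labelled IBD segments by ancestry
#'
#' Drops `"unassigned"` segments and segments shorter than `min_cm`
#' (default 3 cM, the conventional minimum reliable IBD length for
#' recent-demography inference), then groups the remainder by label.
#'
#' @param segments Labelled segments from [assign_ibd_ancestry()].
#' @param min_cm Minimum genetic length in cM.
#' @return Named list of [ibd_segments()] tables, one per ancestry present.
#' @export
partition_by_ancestry <- function(segments, min_cm = 3) {
  if (is.null(segments$ancestry)) stop("segments carry no ancestry labels")
  keep <- segments$ancestry != "unassigned" & segments$length_cm >= min_cm
  s <- segments[keep, ]
  lapply(split(seq_len(nrow(s)), s$ancestry), function(i) {
    g <- s[i, ]
    rownames(g) <- NULL
    structure(g, class = c("ibd_segments", "data.frame"))
  })
}
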