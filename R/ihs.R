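#' Phased haplotype matrices
#'
#' Sites x haplotypes matrix of 0/1 alleles with 1 = derived, plus strictly
#' increasing physical positions.
#'
#' @param alleles Integer 0/1 matrix, sites in rows.
#' @param positions Strictly increasing bp positions, one per row.
#' @param chrom Chromosome name.
#' @return A `hap_matrix`.
#' @export
hap_matrix <- function(alleles, positions, chrom = "1") {
  alleles <- as.matrix(alleles)
  if (!all(alleles %in% c(0L, 1L))) stop("alleles must be 0/1")
  if (length(positions) != nrow(alleles)) stop("one position per site required")
  if (any(diff(positions) <= 0)) stop("positions must be strictly increasing")
  storage.mode(alleles) <- "integer"
  structure(alleles, positions = as.numeric(positions), chrom = chrom,
            class = c("hap_matrix", "matrix"))
}

#' @export
print.hap_matrix <- function(x, ...) {
  cat(sprintf("hap_matrix: %d sites x %d haplotypes, chrom %s, span [%g, %g]\n",
              nrow(x), ncol(x), attr(x, "chrom"),
              min(attr(x, "positions")), max(attr(x, "positions"))))
  invisible(x)
}

#' Extended haplotype homozygosity from a core site
#'
#' Walks outward from the core site among the carriers of one allele class,
#' refining the partition of carriers into distinct extended haplotypes at
#' each informative site. At each visited site,
#' `EHH = sum_h C(n_h, 2) / C(n, 2)` over extension classes `h`;
#' `EHH = 1` at the core. The walk stops once EHH drops below `cutoff`
#' (the crossing value is included) or the data end.
#'
#' @param hapmat A [hap_matrix()].
#' @param core_site Row index of the core site.
#' @param carrier_class `"derived"` (allele 1) or `"ancestral"` (allele 0).
#' @param direction `"left"` or `"right"`.
#' @param cutoff EHH recording cutoff (default 0.05).
#' @return data.frame with columns `site` (row index), `pos`, `ehh`; the
#'   first row is the core. `NULL` when the class has fewer than 2
#'   carriers.
#' @export
ehh <- function(hapmat, core_site, carrier_class = c("derived", "ancestral"),
                direction = c("left", "right"), cutoff = 0.05) {
  carrier_class <- match.arg(carrier_class)
  direction <- match.arg(direction)
  target <- if (carrier_class == "derived") 1L else 0L
  carriers <- which(hapmat[core_site, ] == target)
  n <- length(carriers)
  if (n < 2L) return(NULL)
  pos <- attr(hapmat, "positions")
  idx <- if (direction == "left") rev(seq_len(core_site - 1L)) else
    seq_len(nrow(hapmat))[-seq_len(core_site)]
  denom <- n * (n - 1) / 2
  site_out <- integer(length(idx) + 1L)
  ehh_out <- numeric(length(idx) + 1L)
  site_out[1L] <- core_site; ehh_out[1L] <- 1
  m <- 1L
  groups <- rep.int(1L, n)
  cur <- 1
  for (s in idx) {
    a <- hapmat[s, carriers]
    if (any(a != a[1L])) {
      key <- groups * 2L + a
      groups <- match(key, unique(key))
      tab <- tabulate(groups)
      cur <- sum(tab * (tab - 1) / 2) / denom
    }
    m <- m + 1L
    site_out[m] <- s
    ehh_out[m] <- cur
    if (cur < cutoff) break
  }
  data.frame(site = site_out[seq_len(m)], pos = pos[site_out[seq_len(m)]],
             ehh = ehh_out[seq_len(m)])
}

#' Integrate an EHH curve over genetic distance
#'
#' Trapezoidal integral of EHH against the cumulative genetic map, both
#' truncated at the cutoff crossing (linearly interpolated to the exact
#' crossing). Physical gaps between consecutive curve sites are policed:
#' a gap larger than `max_gap` censors the statistic (returned as `NA` with
#' a reason), and a gap larger than `scale_gap` has its trapezoid's
#' contribution scaled by `scale_gap / gap`.
#'
#' @param curve An [ehh()] curve (first row = core).
#' @param map A [recomb_map()].
#' @param cutoff EHH truncation value (default 0.05).
#' @param max_gap Censoring physical gap in bp (default 2e5).
#' @param scale_gap Gap-penalty scale in bp (default 2e4).
#' @param require_decay Censor cores whose EHH never reaches the cutoff
#'   before the data end (default `TRUE`, mirroring common scan-tool
#'   behaviour).
#' @return Numeric iHH in cM, or `NA` with attribute `reason`.
#' @export
ihh <- function(curve, map, cutoff = 0.05, max_gap = 2e5, scale_gap = 2e4,
                require_decay = TRUE) {
  if (is.null(curve) || nrow(curve) < 2L) {
    if (!is.null(curve) && nrow(curve) == 1L && !require_decay) return(0)
    return(structure(NA_real_, reason = "no_extension"))
  }
  reached <- curve$ehh[nrow(curve)] < cutoff
  if (!reached && require_decay) {
    return(structure(NA_real_, reason = "end_of_data"))
  }
  gcm <- interp_cm(map, curve$pos, clamp = TRUE)
  n <- nrow(curve)
  e1 <- curve$ehh[-n]; e2 <- curve$ehh[-1L]
  d <- abs(gcm[-1L] - gcm[-n])
  gap <- abs(curve$pos[-1L] - curve$pos[-n])
  cross <- which(e2 < cutoff)[1L]   # by construction only the last point
  last <- if (is.na(cross)) n - 1L else cross
  if (any(gap[seq_len(last)] > max_gap)) {
    return(structure(NA_real_, reason = "max_gap"))
  }
  scale <- ifelse(gap > scale_gap, scale_gap / gap, 1)
  area <- scale * (e1 + e2) / 2 * d
  if (!is.na(cross)) {
    # truncate the crossing trapezoid at the cutoff, linearly interpolated
    frac <- if (e1[cross] > e2[cross]) (e1[cross] - cutoff) / (e1[cross] - e2[cross]) else 1
    area[cross] <- scale[cross] * (e1[cross] + cutoff) / 2 * d[cross] * frac
  }
  sum(area[seq_len(last)])
}

#' Integrated haplotype scores for a haplotype matrix
#'
#' For every site passing the minor-allele-frequency filter, integrates the
#' derived- and ancestral-class EHH curves in both directions against the
#' genetic map and reports `ihs_unstd = ln(iHH_ancestral / iHH_derived)`
#' (positive after standardization marks extended derived haplotypes).
#' Sites failing frequency, carrier-count, or gap rules carry a reason flag
#' and an `NA` score. Monomorphic sites carry no haplotype-splitting
#' information and are ignored as walk steps.
#'
#' Precompute EHH curves for every qualifying site
#'
#' The EHH walk depends only on the haplotypes, never on the genetic map,
#' so when the same cohort is scanned under several maps the curves can be
#' computed once and integrated repeatedly; pass the result to
#' [ihs_scores()] via its `curves` argument.
#'
#' @param hapmat A [hap_matrix()].
#' @param maf_min Minimum minor allele frequency (default 0.05).
#' @param cutoff EHH cutoff (default 0.05).
#' @return An `ihs_curves` list: polymorphic-site table and per-site EHH
#'   curves.
#' @export
ihs_curves <- function(hapmat, maf_min = 0.05, cutoff = 0.05) {
  freq <- rowMeans(hapmat)
  poly <- freq > 0 & freq < 1
  hm <- hap_matrix(hapmat[poly, , drop = FALSE],
                   attr(hapmat, "positions")[poly], attr(hapmat, "chrom"))
  freq <- freq[poly]
  n_site <- nrow(hm)
  curves <- vector("list", n_site)
  flag <- character(n_site)
  for (s in seq_len(n_site)) {
    if (pmin(freq[s], 1 - freq[s]) < maf_min) { flag[s] <- "maf"; next }
    cs <- list()
    for (cls in c("derived", "ancestral")) {
      for (dir in c("left", "right")) {
        cs[[paste(cls, dir, sep = "_")]] <- ehh(hm, s, cls, dir, cutoff = cutoff)
      }
    }
    curves[[s]] <- cs
    flag[s] <- "ok"
  }
  structure(list(positions = attr(hm, "positions"), derived_freq = freq,
                 flag = flag, curves = curves, chrom = attr(hm, "chrom"),
                 maf_min = maf_min, cutoff = cutoff),
            class = "ihs_curves")
}

#' @param hapmat A [hap_matrix()] (ignored when `curves` is given).
#' @param map A [recomb_map()].
#' @param maf_min Minimum minor allele frequency (default 0.05).
#' @param cutoff,max_gap,scale_gap,require_decay See [ihh()].
#' @param curves Optional precomputed [ihs_curves()].
#' @return An `ihs_table` data.frame: `site`, `pos`, `derived_freq`,
#'   `ihh_derived`, `ihh_ancestral`, `ihs_unstd`, `flag`.
#' @export
ihs_scores <- function(hapmat, map, maf_min = 0.05, cutoff = 0.05,
                       max_gap = 2e5, scale_gap = 2e4, require_decay = TRUE,
                       curves = NULL) {
  if (is.null(curves)) curves <- ihs_curves(hapmat, maf_min, cutoff)
  n_site <- length(curves$flag)
  freq <- curves$derived_freq
  ihh_d <- ihh_a <- score <- rep(NA_real_, n_site)
  flag <- curves$flag
  for (s in seq_len(n_site)) {
    if (flag[s] != "ok") next
    cs <- curves$curves[[s]]
    vals <- numeric(2); ok <- TRUE; why <- ""
    for (ci in 1:2) {
      cls <- c("derived", "ancestral")[ci]
      tot <- 0
      for (dir in c("left", "right")) {
        v <- ihh(cs[[paste(cls, dir, sep = "_")]], map, cutoff = cutoff,
                 max_gap = max_gap, scale_gap = scale_gap,
                 require_decay = require_decay)
        if (is.na(v)) { ok <- FALSE; why <- attr(v, "reason") %||% "censored"; break }
        tot <- tot + v
      }
      if (!ok) break
      vals[ci] <- tot
    }
    if (!ok) { flag[s] <- why; next }
    ihh_d[s] <- vals[1L]; ihh_a[s] <- vals[2L]
    if (vals[1L] <= 0 || vals[2L] <= 0) { flag[s] <- "zero_ihh"; next }
    score[s] <- log(vals[2L] / vals[1L])
  }
  structure(data.frame(site = seq_len(n_site), pos = curves$positions,
                       derived_freq = freq, ihh_derived = ihh_d,
                       ihh_ancestral = ihh_a, ihs_unstd = score,
                       flag = flag, stringsAsFactors = FALSE),
            class = c("ihs_table", "data.frame"), chrom = curves$chrom)
}

#' Standardize iHS within derived-frequency bins
#'
#' Subtracts the bin mean and divides by the bin standard deviation within
#' equal-width derived-frequency bins (default 20), removing the systematic
#' dependence of the unstandardized score on allele frequency. Bins with
#' fewer than 2 scored sites are merged with their nearest occupied
#' neighbour.
#'
#' @param table An `ihs_table` from [ihs_scores()].
#' @param n_freq_bins Number of equal-width frequency bins (default 20).
#' @return The table with an `ihs_std` column (NA for unscored sites).
#' @export
standardize_ihs <- function(table, n_freq_bins = 20) {
  scored <- which(!is.na(table$ihs_unstd))
  if (length(scored) < 2L) stop("too few scored sites to standardize")
  edges <- seq(0, 1, length.out = n_freq_bins + 1L)
  bin <- findInterval(table$derived_freq[scored], edges, rightmost.closed = TRUE)
  # merge under-filled bins into the nearest occupied neighbour
  repeat {
    tab <- base::table(bin)
    small <- as.integer(names(tab))[tab < 2L]
    if (!length(small) || length(tab) == 1L) break
    b <- small[1L]
    others <- setdiff(as.integer(names(tab)), b)
    bin[bin == b] <- others[which.min(abs(others - b))]
  }
  z <- rep(NA_real_, nrow(table))
  for (b in unique(bin)) {
    i <- scored[bin == b]
    s <- sd(table$ihs_unstd[i])
    if (length(i) >= 2L && (is.na(s) || s == 0)) {
      if (length(unique(bin)) == 1L) stop("degenerate standardization: zero variance in the only bin")
      s <- 1
    }
    z[i] <- (table$ihs_unstd[i] - mean(table$ihs_unstd[i])) / s
  }
  table$ihs_std <- z
  table
}

#' Top-scoring sites by |iHS|
#'
#' Sites whose absolute standardized score reaches the `(1 - fraction)`
#' empirical quantile; ties at the threshold are all included.
#'
#' @param table A standardized `ihs_table`.
#' @param fraction Upper fraction retained (default 0.01, the top 1%).
#' @return The subset of rows selected, ordered by decreasing `|ihs_std|`.
#' @export
top_hits <- function(table, fraction = 0.01) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (is.null(table$ihs_std)) stop("standardize the table first")
  a <- abs(table$ihs_std)
  if (!any(!is.na(a))) stop("empty table: no scored sites")
  thr <- quantile(a, 1 - fraction, na.rm = TRUE, names = FALSE)
  out <- table[!is.na(a) & a >= thr, ]
  out[order(-abs(out$ihs_std)), ]
}

#' Read a gene range list
#'
#' Four whitespace-separated columns: `chrom`, `start`, `end`, `symbol`.
#'
#' @param path File path.
#' @return data.frame of gene ranges.
#' @export
read_gene_ranges <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(trimws(lines), "[ \t]+")
  bad <- which(lengths(fields) != 4L)
  if (length(bad)) stop_format(path, bad[1L], "expected 4 columns (chrom start end symbol)")
  m <- do.call(rbind, fields)
  start <- suppressWarnings(as.numeric(m[, 2L]))
  end <- suppressWarnings(as.numeric(m[, 3L]))
  nb <- which(is.na(start) | is.na(end) | start >= end)
  if (length(nb)) stop_format(path, nb[1L], "malformed gene range")
  data.frame(chrom = m[, 1L], start = start, end = end, symbol = m[, 4L],
             stringsAsFactors = FALSE)
}

#' Annotate hit sites with overlapping genes
#'
#' @param sites Numeric positions (bp), or a table with a `pos` column.
#' @param gene_ranges data.frame from [read_gene_ranges()].
#' @param flank Symmetric flank added to each gene range (default 0 bp).
#' @param chrom Optional chromosome filter applied to `gene_ranges`.
#' @return Sorted character vector of deduplicated gene symbols containing
#'   at least one hit site.
#' @export
annotate_genes <- function(sites, gene_ranges, flank = 0, chrom = NULL) {
  pos <- if (is.data.frame(sites)) sites$pos else as.numeric(sites)
  g <- gene_ranges
  if (!is.null(chrom)) g <- g[g$chrom == chrom, ]
  if (!nrow(g) || !length(pos)) return(character(0))
  hit <- vapply(seq_len(nrow(g)), function(i) {
    any(pos >= g$start[i] - flank & pos <= g$end[i] + flank)
  }, logical(1))
  sort(unique(g$symbol[hit]))
}

#' Compare two iHS scans of the same sites under different genetic maps
#'
#' Takes the site intersection of the two standardized tables, extracts
#' each table's top-|iHS| hits, annotates them with genes, and reports the
#' candidate-gene overlap (shared / unique per run) together with the
#' per-SNP Pearson correlation of the standardized scores on jointly
#' scored sites.
#'
#' @param table_a,table_b Standardized `ihs_table`s.
#' @param gene_ranges data.frame of gene ranges.
#' @param fraction Top fraction for [top_hits()] (default 0.01).
#' @param flank Gene flank in bp (default 0).
#' @return A list: `n_shared_sites`, `pearson_r`, `genes_a`, `genes_b`,
#'   `shared_genes`, `unique_a`, `unique_b`, and `overlap_fraction`
#'   (shared / union).
#' @export
compare_runs <- function(table_a, table_b, gene_ranges, fraction = 0.01,
                         flank = 0) {
  common <- intersect(table_a$pos, table_b$pos)
  if (!length(common)) stop("the two tables share no sites")
  a <- table_a[match(common, table_a$pos), ]
  b <- table_b[match(common, table_b$pos), ]
  ok <- !is.na(a$ihs_std) & !is.na(b$ihs_std)
  ga <- annotate_genes(top_hits(a, fraction), gene_ranges, flank = flank)
  gb <- annotate_genes(top_hits(b, fraction), gene_ranges, flank = flank)
  shared <- intersect(ga, gb)
  uni <- union(ga, gb)
  list(n_shared_sites = length(common),
       n_scored_both = sum(ok),
       pearson_r = if (sum(ok) >= 2) cor(a$ihs_std[ok], b$ihs_std[ok]) else NA_real_,
       genes_a = ga, genes_b = gb, shared_genes = shared,
       unique_a = setdiff(ga, gb), unique_b = setdiff(gb, ga),
       overlap_fraction = if (length(uni)) length(shared) / length(uni) else NA_real_)
}

#' Generate a synthetic tiling gene range list
#'
#' Utility for simulation studies: non-overlapping gene ranges of fixed
#' width tiling a chromosome with regular spacing, named `G0001`, ...
#'
#' @param chrom_length_bp Chromosome length.
#' @param gene_width_bp Width of each synthetic gene (default 3e4).
#' @param spacing_bp Distance between consecutive gene starts (default 5e4).
#' @param chrom Chromosome name.
#' @return data.frame of gene ranges.
#' @export
synthetic_gene_ranges <- function(chrom_length_bp, gene_width_bp = 3e4,
                                  spacing_bp = 5e4, chrom = "1") {
  starts <- seq(0, chrom_length_bp - gene_width_bp, by = spacing_bp)
  data.frame(chrom = chrom, start = starts, end = starts + gene_width_bp,
             symbol = sprintf("G%04d", seq_along(starts)),
             stringsAsFactors = FALSE)
}
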