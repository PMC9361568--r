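#' Extract truth IBD segments from a simulated cohort
#'
#' For every haplotype pair, reports the maximal intervals over which both
#' haplotypes descend from the same founder haplotype (identity of founder
#' block, not allele identity). Genetic lengths are measured on the cohort's
#' own map; segments shorter than `min_cm` are dropped. A long stretch of
#' shared descent through a recent common ancestor appears here as abutting
#' segments that switch founder id in both haplotypes at the same point;
#' [merge_ibd_gaps()] fuses those downstream, mirroring the gap-removal step
#' real IBD callers apply.
#'
#' @param cohort A `cohort` from [simulate_admixture()].
#' @param min_cm Minimum genetic length in cM (>= 0).
#' @return An [ibd_segments()] table with an extra `founder_id` column,
#'   sorted by (sample_a, hap_a, sample_b, hap_b, start).
#' @export
extract_true_ibd <- function(cohort, min_cm = 0) {
  if (min_cm < 0) stop("min_cm must be non-negative")
  n_hap <- length(cohort$haps)
  blocks <- data.table::rbindlist(lapply(seq_len(n_hap), function(h) {
    hp <- cohort$haps[[h]]
    data.table::data.table(hid = h, start = hp$pos,
                           end = c(hp$pos[-1L], cohort$chrom_length),
                           fid = hp$id)
  }))
  pieces <- ibd_pieces(blocks)
  if (!nrow(pieces)) {
    return(ibd_segments(data.frame(
      sample_a = character(0), hap_a = integer(0), sample_b = character(0),
      hap_b = integer(0), chrom = character(0), start = numeric(0),
      end = numeric(0), score = numeric(0), length_cm = numeric(0),
      founder_id = integer(0))))
  }
  pieces$length_cm <- interp_cm(cohort$map, pieces$end) -
    interp_cm(cohort$map, pieces$start)
  pieces <- pieces[pieces$length_cm >= min_cm, ]
  d <- data.frame(
    sample_a = cohort$samples[(pieces$hid1 + 1L) %/% 2L],
    hap_a = (pieces$hid1 - 1L) %% 2L,
    sample_b = cohort$samples[(pieces$hid2 + 1L) %/% 2L],
    hap_b = (pieces$hid2 - 1L) %% 2L,
    chrom = rep(cohort$chrom, nrow(pieces)),
    start = pieces$start, end = pieces$end,
    score = rep(NA_real_, nrow(pieces)),
    length_cm = pieces$length_cm,
    founder_id = pieces$fid,
    stringsAsFactors = FALSE
  )
  ibd_segments(d)
}

#' Mean pairwise founder-sharing fraction of truth IBD
#'
#' In a finite-depth pedigree simulation, a crossover moves a lineage onto
#' the parent's other haplotype, which may itself descend from the same
#' founder; founder-block IBD segments are therefore systematically longer
#' than coalescent-model IBD segments by a factor of about
#' `1 / (1 - pi)`, where `pi` is the probability that a random haplotype
#' pair shares founder descent at a random locus. This function measures
#' `pi` directly from the complete (unfiltered) truth IBD: total segment
#' genetic length over all pairs divided by `n_pairs * genome_cm`. Deflate
#' segment lengths (and chromosome lengths) by `1 - pi` before fitting the
#' coalescent spectrum model to pedigree truth IBD.
#'
#' @param segments Truth [ibd_segments()] extracted with `min_cm = 0`.
#' @param n_pairs Number of haplotype pairs the segments cover.
#' @param genome_cm Genetic length of the analysed genome in cM.
#' @return Sharing fraction in \[0, 1\].
#' @export
founder_sharing_fraction <- function(segments, n_pairs, genome_cm) {
  sum(segments$length_cm) / (n_pairs * genome_cm)
}

# Overlap pieces between blocks of different haplotypes sharing a founder id.
# blocks: data.table(hid, start, end, fid). Returns data.table(hid1, hid2,
# start, end, fid) with hid1 < hid2.
ibd_pieces <- function(blocks) {
  start <- end <- fid <- hid <- NULL # data.table NSE
  x <- data.table::copy(blocks)
  data.table::setkey(x, fid, start, end)
  ov <- data.table::foverlaps(x, x, by.x = c("fid", "start", "end"),
                              type = "any", which = TRUE)
  ov <- ov[ov$xid < ov$yid, ]
  if (!nrow(ov)) return(data.table::data.table())
  a <- x[ov$xid]; b <- x[ov$yid]
  keep <- a$hid != b$hid
  a <- a[keep]; b <- b[keep]
  if (!nrow(a)) return(data.table::data.table())
  ps <- pmax(a$start, b$start); pe <- pmin(a$end, b$end)
  ok <- pe > ps
  out <- data.table::data.table(
    hid1 = pmin(a$hid, b$hid)[ok], hid2 = pmax(a$hid, b$hid)[ok],
    start = ps[ok], end = pe[ok], fid = a$fid[ok])
  data.table::setorderv(out, c("hid1", "hid2", "start"))
  out
}
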