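# Independent brute-force oracles. These deliberately re-derive results by
# the most direct method available (per-position scans, string enumeration,
# exhaustive pair loops) and share no code with the implementation paths
# they check.

# Brute-force truth IBD: walk every haplotype pair over the union of block
# boundaries and emit maximal runs of equal founder id.
bf_true_ibd <- function(cohort, min_cm = 0) {
  n <- length(cohort$haps)
  rows <- list()
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    hi <- cohort$haps[[i]]; hj <- cohort$haps[[j]]
    bounds <- sort(unique(c(hi$pos, hj$pos)))
    id_i <- hi$id[findInterval(bounds, hi$pos)]
    id_j <- hj$id[findInterval(bounds, hj$pos)]
    same <- id_i == id_j
    # runs where ids are equal AND the shared id is constant
    k <- 1L
    while (k <= length(bounds)) {
      if (same[k]) {
        m <- k
        while (m < length(bounds) && same[m + 1L] && id_i[m + 1L] == id_i[k]) m <- m + 1L
        s <- bounds[k]
        e <- if (m < length(bounds)) bounds[m + 1L] else cohort$chrom_length
        len <- interp_cm(cohort$map, e) - interp_cm(cohort$map, s)
        if (len >= min_cm) {
          rows[[length(rows) + 1L]] <- data.frame(
            sample_a = cohort$samples[(i + 1L) %/% 2L], hap_a = (i - 1L) %% 2L,
            sample_b = cohort$samples[(j + 1L) %/% 2L], hap_b = (j - 1L) %% 2L,
            chrom = cohort$chrom, start = s, end = e, score = NA_real_,
            length_cm = len, founder_id = id_i[k], stringsAsFactors = FALSE)
        }
        k <- m + 1L
      } else k <- k + 1L
    }
  }
  if (!length(rows)) {
    return(data.frame(sample_a = character(0), hap_a = integer(0),
                      sample_b = character(0), hap_b = integer(0),
                      chrom = character(0), start = numeric(0),
                      end = numeric(0), score = numeric(0),
                      length_cm = numeric(0), founder_id = integer(0)))
  }
  out <- do.call(rbind, rows)
  out[order(out$sample_a, out$hap_a, out$sample_b, out$hap_b, out$start), ]
}

# Brute-force EHH at every flanking site by enumerating extended haplotypes
# as strings. Returns the recorded curve including the cutoff crossing.
bf_ehh_curve <- function(hapmat, core, allele, direction, cutoff = 0.05) {
  carriers <- which(hapmat[core, ] == allele)
  n <- length(carriers)
  if (n < 2L) return(NULL)
  pos <- attr(hapmat, "positions")
  idx <- if (direction == "left") rev(seq_len(core - 1L)) else
    seq.int(core + 1L, length.out = nrow(hapmat) - core)
  out <- data.frame(site = core, pos = pos[core], ehh = 1)
  for (d in seq_along(idx)) {
    span <- if (direction == "left") idx[d]:core else core:idx[d]
    strs <- apply(hapmat[span, carriers, drop = FALSE], 2L, paste, collapse = "")
    tab <- base::table(strs)
    e <- sum(choose(tab, 2)) / choose(n, 2)
    out <- rbind(out, data.frame(site = idx[d], pos = pos[idx[d]], ehh = e))
    if (e < cutoff) break
  }
  out
}

# Brute-force trapezoid integration with the same cutoff/gap rules, written
# as a plain loop.
bf_ihh <- function(curve, map, cutoff = 0.05, max_gap = 2e5, scale_gap = 2e4,
                   require_decay = TRUE) {
  if (is.null(curve)) return(NA_real_)
  if (nrow(curve) < 2L) return(if (require_decay) NA_real_ else 0)
  if (curve$ehh[nrow(curve)] >= cutoff && require_decay) return(NA_real_)
  g <- interp_cm(map, curve$pos, clamp = TRUE)
  total <- 0
  for (i in seq_len(nrow(curve) - 1L)) {
    gap <- abs(curve$pos[i + 1L] - curve$pos[i])
    if (gap > max_gap) return(NA_real_)
    sc <- min(1, scale_gap / gap)
    d <- abs(g[i + 1L] - g[i])
    e1 <- curve$ehh[i]; e2 <- curve$ehh[i + 1L]
    if (e2 < cutoff) {
      fr <- if (e1 > e2) (e1 - cutoff) / (e1 - e2) else 1
      return(total + sc * (e1 + cutoff) / 2 * d * fr)
    }
    total <- total + sc * (e1 + e2) / 2 * d
  }
  total
}

# Full brute-force unstandardized iHS for every polymorphic site.
bf_ihs_table <- function(hapmat, map, maf_min = 0.05, cutoff = 0.05,
                         max_gap = 2e5, scale_gap = 2e4, require_decay = TRUE) {
  freq <- rowMeans(hapmat)
  keep <- freq > 0 & freq < 1
  hm <- hap_matrix(hapmat[keep, , drop = FALSE],
                   attr(hapmat, "positions")[keep], attr(hapmat, "chrom"))
  freq <- freq[keep]
  score <- rep(NA_real_, nrow(hm))
  for (s in seq_len(nrow(hm))) {
    if (min(freq[s], 1 - freq[s]) < maf_min) next
    v <- c(derived = 0, ancestral = 0)
    bad <- FALSE
    for (cls in c("derived", "ancestral")) {
      al <- if (cls == "derived") 1L else 0L
      for (dir in c("left", "right")) {
        cv <- bf_ehh_curve(hm, s, al, dir, cutoff)
        ii <- bf_ihh(cv, map, cutoff, max_gap, scale_gap, require_decay)
        if (is.na(ii)) { bad <- TRUE; break }
        v[cls] <- v[cls] + ii
      }
      if (bad) break
    }
    if (!bad && v["derived"] > 0 && v["ancestral"] > 0) {
      score[s] <- log(v[["ancestral"]] / v[["derived"]])
    }
  }
  data.frame(pos = attr(hm, "positions"), ihs_unstd = score)
}

# Per-base-pair accuracy oracle for integer-coordinate tract sets.
bf_accuracy_per_base <- function(truth, inferred) {
  key_t <- paste(truth$sample, truth$hap, truth$chrom)
  key_i <- paste(inferred$sample, inferred$hap, inferred$chrom)
  agree <- 0; total <- 0
  per_anc_n <- per_anc_d <- setNames(numeric(length(attr(truth, "alphabet"))),
                                     attr(truth, "alphabet"))
  for (k in unique(key_t)) {
    gt <- truth[key_t == k, ]; gi <- inferred[key_i == k, ]
    lab_t <- rep(gt$ancestry[order(gt$start)], gt$end[order(gt$start)] - gt$start[order(gt$start)])
    lab_i <- rep(gi$ancestry[order(gi$start)], gi$end[order(gi$start)] - gi$start[order(gi$start)])
    eq <- lab_t == lab_i
    agree <- agree + sum(eq); total <- total + length(eq)
    for (a in names(per_anc_n)) {
      sel <- lab_t == a
      per_anc_n[a] <- per_anc_n[a] + sum(eq[sel])
      per_anc_d[a] <- per_anc_d[a] + sum(sel)
    }
  }
  list(global = agree / total, recall = per_anc_n / per_anc_d)
}
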