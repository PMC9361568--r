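#' Local-ancestry tract sets
#'
#' A `tract_set` stores per-haplotype local-ancestry intervals: one row per
#' maximal constant-ancestry interval, with 0-based half-open coordinates.
#' Within every (sample, haplotype, chromosome) the intervals must be
#' sorted, non-overlapping and tiling (no gaps).
#'
#' @param entries data.frame with columns `sample`, `hap` (0 or 1), `chrom`,
#'   `start`, `end`, `ancestry`.
#' @param alphabet Ordered character vector of admissible ancestry labels
#'   (defaults to the labels present).
#' @param extent Optional numeric `c(start, end)` every haplotype must tile;
#'   defaults to each haplotype's own span.
#' @return A `tract_set` data.frame.
#' @export
tract_set <- function(entries, alphabet = NULL, extent = NULL) {
  need <- c("sample", "hap", "chrom", "start", "end", "ancestry")
  if (!all(need %in% names(entries))) {
    stop("tract entries need columns sample, hap, chrom, start, end, ancestry")
  }
  entries <- as.data.frame(entries)[need]
  if (is.null(alphabet)) alphabet <- sort(unique(entries$ancestry))
  if (!all(entries$ancestry %in% alphabet)) {
    stop(sprintf("ancestry label '%s' not in alphabet",
                 setdiff(entries$ancestry, alphabet)[1L]))
  }
  x <- structure(entries, class = c("tract_set", "data.frame"),
                 alphabet = alphabet, extent = extent)
  validate_tracts(x)
  x
}

#' @export
print.tract_set <- function(x, ...) {
  cat(sprintf("tract_set: %d tracts, %d haplotypes, alphabet {%s}\n",
              nrow(x), nrow(unique(x[c("sample", "hap", "chrom")])),
              paste(attr(x, "alphabet"), collapse = ", ")))
  invisible(x)
}

#' Check the tiling invariant of a tract set
#'
#' Errors unless, for every (sample, haplotype, chromosome), the tract
#' intervals are sorted, non-overlapping and tile the haplotype extent with
#' no gaps.
#'
#' @param tracts A [tract_set()].
#' @return Invisibly `TRUE`.
#' @export
validate_tracts <- function(tracts) {
  if (any(tracts$end <= tracts$start)) stop("tract with end <= start")
  key <- paste(tracts$sample, tracts$hap, tracts$chrom, sep = "\r")
  ext <- attr(tracts, "extent")
  for (k in unique(key)) {
    g <- tracts[key == k, ]
    g <- g[order(g$start), ]
    if (nrow(g) > 1L && any(g$start[-1L] != g$end[-nrow(g)])) {
      stop(sprintf("tracts of %s do not tile (gap or overlap)", gsub("\r", "/", k)))
    }
    if (!is.null(ext) && (g$start[1L] != ext[1L] || g$end[nrow(g)] != ext[2L])) {
      stop(sprintf("tracts of %s do not span the declared extent", gsub("\r", "/", k)))
    }
  }
  invisible(TRUE)
}

# Merge adjacent same-ancestry tracts; returns a clean tract_set.
normalize_tracts <- function(tracts) {
  key <- paste(tracts$sample, tracts$hap, tracts$chrom, sep = "\r")
  parts <- lapply(split(seq_len(nrow(tracts)), key), function(i) {
    g <- tracts[i, ][order(tracts$start[i]), ]
    r <- collapse_runs(g$start, g$ancestry)
    data.frame(sample = g$sample[1L], hap = g$hap[1L], chrom = g$chrom[1L],
               start = r$starts, end = c(r$starts[-1L], g$end[nrow(g)]),
               ancestry = r$values, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  tract_set(out, alphabet = attr(tracts, "alphabet"), extent = attr(tracts, "extent"))
}

#' Read local-ancestry calls in the msp window dialect
#'
#' Parses the windowed local-ancestry output dialect (`msp.tsv`): a first
#' comment line declaring `Subpopulation order/codes: Label=0 Label=1 ...`,
#' a second header line naming `#chm spos epos sgpos egpos n snps` followed
#' by two columns per sample (`sample.0`, `sample.1`) of integer ancestry
#' codes per window. Windows must tile; runs of identical codes are merged
#' into maximal tracts. Coordinates are taken as 0-based half-open.
#'
#' @param path File path.
#' @return A [tract_set()]; the alphabet comes from the header codes.
#' @export
read_local_ancestry <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop_format(path, 1L, "truncated msp file")
  m <- regmatches(lines[1L], gregexpr("([^ :\t]+)=([0-9]+)", lines[1L]))[[1L]]
  if (!length(m)) stop_format(path, 1L, "missing subpopulation codes header")
  codes <- as.integer(sub(".*=", "", m))
  labels <- sub("=.*", "", m)
  alphabet <- labels[order(codes)]
  hdr <- strsplit(sub("^#", "", lines[2L]), "\t")[[1L]]
  hap_cols <- hdr[-(1:6)]
  sample <- sub("\\.[01]$", "", hap_cols)
  hap <- as.integer(sub("^.*\\.", "", hap_cols))
  if (length(lines) == 2L) {
    return(tract_set(data.frame(sample = character(0), hap = integer(0),
                                chrom = character(0), start = numeric(0),
                                end = numeric(0), ancestry = character(0)),
                     alphabet = alphabet))
  }
  body <- read.table(text = lines[-(1:2)], sep = "\t", stringsAsFactors = FALSE)
  if (ncol(body) != length(hdr)) stop_format(path, 3L, "column count does not match header")
  chrom <- as.character(body[[1L]])
  spos <- as.numeric(body[[2L]]); epos <- as.numeric(body[[3L]])
  if (any(epos <= spos)) {
    stop_format(path, which(epos <= spos)[1L] + 2L, "window with epos <= spos")
  }
  bad <- which(chrom[-1L] == chrom[-length(chrom)] & spos[-1L] != epos[-length(epos)])
  if (length(bad)) stop_format(path, bad[1L] + 3L, "windows do not tile")
  out <- vector("list", length(hap_cols))
  for (j in seq_along(hap_cols)) {
    code <- as.integer(body[[j + 6L]])
    if (any(!code %in% codes)) {
      stop_format(path, which(!code %in% codes)[1L] + 2L,
                  sprintf("unknown ancestry code %d", code[!code %in% codes][1L]))
    }
    parts <- lapply(split(seq_along(code), chrom), function(i) {
      r <- collapse_runs(spos[i], code[i])
      data.frame(sample = sample[j], hap = hap[j], chrom = chrom[i][1L],
                 start = r$starts, end = c(r$starts[-1L], epos[i[length(i)]]),
                 ancestry = alphabet[match(r$values, sort(codes))],
                 stringsAsFactors = FALSE)
    })
    out[[j]] <- do.call(rbind, parts)
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  tract_set(out, alphabet = alphabet)
}

#' Write local-ancestry tracts in the msp window dialect
#'
#' Windows are the union of tract boundaries across all haplotypes per
#' chromosome, so reading the file back recovers the same tracts.
#'
#' @param tracts A [tract_set()].
#' @param path Output file.
#' @param map Optional [recomb_map()] used to fill the genetic-position
#'   columns (otherwise 0).
#' @export
write_msp <- function(tracts, path, map = NULL) {
  alphabet <- attr(tracts, "alphabet")
  hdr1 <- paste0("#Subpopulation order/codes: ",
                 paste(sprintf("%s=%d", alphabet, seq_along(alphabet) - 1L), collapse = "\t"))
  key <- paste(tracts$sample, tracts$hap, sep = ".")
  hap_ids <- unique(key[order(tracts$sample, tracts$hap)])
  hdr2 <- paste(c("#chm", "spos", "epos", "sgpos", "egpos", "n snps", hap_ids),
                collapse = "\t")
  rows <- character(0)
  for (ch in unique(tracts$chrom)) {
    g <- tracts[tracts$chrom == ch, ]
    bounds <- sort(unique(c(g$start, g$end)))
    ws <- bounds[-length(bounds)]; we <- bounds[-1L]
    gk <- paste(g$sample, g$hap, sep = ".")
    codemat <- vapply(hap_ids, function(h) {
      gh <- g[gk == h, ]
      gh <- gh[order(gh$start), ]
      idx <- findInterval(ws, gh$start)
      match(gh$ancestry[idx], alphabet) - 1L
    }, integer(length(ws)))
    codemat <- matrix(codemat, nrow = length(ws))
    sg <- if (!is.null(map)) sprintf("%.6f", interp_cm(map, ws, clamp = TRUE)) else rep("0", length(ws))
    eg <- if (!is.null(map)) sprintf("%.6f", interp_cm(map, we, clamp = TRUE)) else rep("0", length(ws))
    rows <- c(rows, paste(ch, format(ws, scientific = FALSE, trim = TRUE),
                          format(we, scientific = FALSE, trim = TRUE), sg, eg, "0",
                          apply(codemat, 1L, paste, collapse = "\t"), sep = "\t"))
  }
  writeLines(c(hdr1, hdr2, rows), path)
  invisible(path)
}

#' Read / write the internal tract table dialect
#'
#' A plain TSV with columns `sample`, `hap`, `chrom`, `start`, `end`,
#' `ancestry`; the round trip is bit-exact.
#'
#' @param path File path.
#' @param alphabet Optional explicit alphabet for [read_tracts()].
#' @return [read_tracts()] returns a [tract_set()].
#' @export
read_tracts <- function(path, alphabet = NULL) {
  d <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                  colClasses = c(sample = "character", chrom = "character"))
  tract_set(d, alphabet = alphabet)
}

#' @param tracts A [tract_set()] for [write_tracts()].
#' @rdname read_tracts
#' @export
write_tracts <- function(tracts, path) {
  d <- as.data.frame(tracts)
  d$start <- format(d$start, scientific = FALSE, trim = TRUE)
  d$end <- format(d$end, scientific = FALSE, trim = TRUE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-individual global ancestry proportions
#'
#' Sums tract length per ancestry over an individual's two haplotypes and
#' divides by twice the genome length, giving the genome-fraction of each
#' ancestry (rows sum to 1). The result is ready for ternary plotting in
#' three-way admixed cohorts.
#'
#' @param tracts A [tract_set()].
#' @return data.frame: one row per sample, one column per alphabet label.
#' @export
global_proportions <- function(tracts) {
  validate_tracts(tracts)
  alphabet <- attr(tracts, "alphabet")
  len <- tracts$end - tracts$start
  tot <- tapply(len, tracts$sample, sum)
  out <- vapply(alphabet, function(a) {
    s <- tapply(len * (tracts$ancestry == a), tracts$sample, sum)
    as.numeric(s / tot)
  }, numeric(length(tot)))
  out <- matrix(out, nrow = length(tot),
                dimnames = list(names(tot), alphabet))
  as.data.frame(out)
}

#' Score inferred local ancestry against truth
#'
#' Computes, by interval intersection (never per-base loops), the
#' genome-length-weighted agreement between truth and inferred tracts:
#' * `global_accuracy`: fraction of total haplotype length with agreeing
#'   labels;
#' * `global_accuracy_by_individual`: the same computed per individual and
#'   then averaged (reported alongside, as the two averaging conventions
#'   differ in unbalanced cohorts);
#' * `per_ancestry_recall`: for each ancestry, agreeing length within truth
#'   tracts of that ancestry divided by total truth length of that ancestry;
#' * `per_individual_fractions`: [global_proportions()] of the inferred
#'   tracts.
#'
#' Haplotypes are compared as phased; switch-error-tolerant diploid scoring
#' is not applied (truth and inference share the simulator's phase).
#'
#' @param truth,inferred [tract_set()]s over the same samples, haplotypes
#'   and chromosome extents.
#' @return An `accuracy_report` list.
#' @export
lai_accuracy <- function(truth, inferred) {
  kt <- unique(paste(truth$sample, truth$hap, truth$chrom, sep = "\r"))
  ki <- unique(paste(inferred$sample, inferred$hap, inferred$chrom, sep = "\r"))
  if (!setequal(kt, ki)) {
    stop(sprintf("sample/haplotype sets differ between truth and inferred: %s",
                 paste(gsub("\r", "/", c(setdiff(kt, ki), setdiff(ki, kt))),
                       collapse = ", ")))
  }
  key_t <- paste(truth$sample, truth$hap, truth$chrom, sep = "\r")
  key_i <- paste(inferred$sample, inferred$hap, inferred$chrom, sep = "\r")
  alphabet <- attr(truth, "alphabet")
  agree_len <- 0; total_len <- 0
  recall_num <- setNames(numeric(length(alphabet)), alphabet)
  recall_den <- setNames(numeric(length(alphabet)), alphabet)
  ind_agree <- list(); ind_total <- list()
  for (k in kt) {
    gt <- truth[key_t == k, ]; gi <- inferred[key_i == k, ]
    gt <- gt[order(gt$start), ]; gi <- gi[order(gi$start), ]
    if (gt$start[1L] != gi$start[1L] || gt$end[nrow(gt)] != gi$end[nrow(gi)]) {
      stop(sprintf("extents differ for %s", gsub("\r", "/", k)))
    }
    bounds <- sort(unique(c(gt$start, gt$end, gi$start, gi$end)))
    lo <- bounds[-length(bounds)]; hi <- bounds[-1L]
    lab_t <- gt$ancestry[findInterval(lo, gt$start)]
    lab_i <- gi$ancestry[findInterval(lo, gi$start)]
    w <- hi - lo
    agree <- w * (lab_t == lab_i)
    agree_len <- agree_len + sum(agree); total_len <- total_len + sum(w)
    for (a in alphabet) {
      sel <- lab_t == a
      recall_num[a] <- recall_num[a] + sum(agree[sel])
      recall_den[a] <- recall_den[a] + sum(w[sel])
    }
    smp <- gt$sample[1L]
    ind_agree[[smp]] <- (ind_agree[[smp]] %||% 0) + sum(agree)
    ind_total[[smp]] <- (ind_total[[smp]] %||% 0) + sum(w)
  }
  by_ind <- mapply(`/`, ind_agree, ind_total[names(ind_agree)])
  structure(list(
    global_accuracy = agree_len / total_len,
    global_accuracy_by_individual = mean(unlist(by_ind)),
    per_ancestry_recall = recall_num / recall_den,
    truth_ancestry_length = recall_den,
    per_individual_fractions = global_proportions(inferred)
  ), class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("global accuracy: %.4f (by-individual mean %.4f)\n",
              x$global_accuracy, x$global_accuracy_by_individual))
  for (a in names(x$per_ancestry_recall)) {
    cat(sprintf("  %s recall: %.4f\n", a, x$per_ancestry_recall[[a]]))
  }
  invisible(x)
}

#' Corrupt ancestry tracts with switch errors
#'
#' Emulates local-ancestry miscalls: error windows are seeded by a Poisson
#' process at `switch_error_per_mb` errors per Mb per haplotype; within each
#' window of width `window_bp` every position's label is rotated to a
#' different alphabet label (a per-window random offset). The tiling
#' invariant is preserved exactly.
#'
#' @param tracts A [tract_set()].
#' @param switch_error_per_mb Error-window rate per Mb (>= 0).
#' @param seed Integer seed.
#' @param window_bp Width of each miscalled window (default 5e5).
#' @return A corrupted [tract_set()] over the same haplotypes.
#' @export
corrupt_tracts <- function(tracts, switch_error_per_mb, seed = NULL,
                           window_bp = 5e5) {
  if (switch_error_per_mb < 0) stop("switch_error_per_mb must be >= 0")
  alphabet <- attr(tracts, "alphabet")
  if (length(alphabet) < 2L && switch_error_per_mb > 0) {
    stop("cannot corrupt a single-ancestry alphabet")
  }
  if (switch_error_per_mb == 0) return(tracts)
  K <- length(alphabet)
  key <- paste(tracts$sample, tracts$hap, tracts$chrom, sep = "\r")
  with_seed(seed, {
    parts <- lapply(split(seq_len(nrow(tracts)), key), function(i) {
      g <- tracts[i, ][order(tracts$start[i]), ]
      lo0 <- g$start[1L]; hi0 <- g$end[nrow(g)]
      n_err <- rpois(1L, switch_error_per_mb * (hi0 - lo0) / 1e6)
      if (n_err == 0L) return(g)
      ws <- runif(n_err, lo0, hi0)
      offs <- sample.int(K - 1L, n_err, replace = TRUE)
      starts <- g$start; labs <- g$ancestry
      for (e in seq_len(n_err)) {
        wlo <- ws[e]; whi <- min(ws[e] + window_bp, hi0)
        pts <- sort(unique(c(starts, wlo, whi)))
        pts <- pts[pts < hi0]
        lab <- labs[findInterval(pts, starts)]
        in_w <- pts >= wlo & pts < whi
        idx <- match(lab[in_w], alphabet)
        lab[in_w] <- alphabet[1L + (idx - 1L + offs[e]) %% K]
        r <- collapse_runs(pts, lab)
        starts <- r$starts; labs <- r$values
      }
      data.frame(sample = g$sample[1L], hap = g$hap[1L], chrom = g$chrom[1L],
                 start = starts, end = c(starts[-1L], hi0), ancestry = labs,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, parts)
    rownames(out) <- NULL
    tract_set(out, alphabet = alphabet, extent = attr(tracts, "extent"))
  })
}
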