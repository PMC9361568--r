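# Haplotypes are stored as founder-block mosaics: a list(pos, id) where `pos`
# is the sorted vector of block start positions (pos[1] == 0) and `id` the
# parallel vector of founder haplotype ids; block ends are implicit (the next
# start, or the chromosome length). Adjacent blocks never share an id.

# Recombine two parental haplotypes at the given crossover positions.
# `first` selects which parent contributes the leftmost segment.
splice_blocks <- function(h1, h2, cuts, first) {
  if (length(cuts) == 0L) return(if (first == 1L) h1 else h2)
  par <- if (first == 1L) list(h1, h2) else list(h2, h1)
  lo <- c(0, cuts)
  n_seg <- length(lo)
  out_pos <- vector("list", n_seg)
  out_id <- vector("list", n_seg)
  for (k in seq_len(n_seg)) {
    h <- par[[1L + (k - 1L) %% 2L]]
    p <- h$pos
    i0 <- findInterval(lo[k], p)
    i1 <- if (k < n_seg) findInterval(cuts[k], p) else length(p)
    seg <- p[i0:i1]
    seg[1L] <- lo[k]
    out_pos[[k]] <- seg
    out_id[[k]] <- h$id[i0:i1]
  }
  pos <- unlist(out_pos, use.names = FALSE)
  id <- unlist(out_id, use.names = FALSE)
  keep <- c(TRUE, id[-1L] != id[-length(id)])
  list(pos = pos[keep], id = id[keep])
}

# Normalize a migrant source (founder_panel or cohort) into the simulator's
# internal form, remapping founder ids into a global namespace.
as_source <- function(x, ancestry, id_offset) {
  if (inherits(x, "founder_panel")) {
    if (!ancestry %in% x$ancestries) {
      stop(sprintf("founder panel has no ancestry '%s'", ancestry))
    }
    n_hap <- 2L * x$n_per_pop
    haps <- lapply(seq_len(n_hap), function(j) list(pos = 0, id = id_offset + j))
    alleles <- if (length(x$positions)) x$haplotypes[[ancestry]] else NULL
    list(type = "panel", haps = haps, n_hap = n_hap, n_ind = x$n_per_pop,
         n_founders = n_hap, ancestry_of = rep(ancestry, n_hap),
         alleles = alleles, positions = x$positions)
  } else if (inherits(x, "cohort")) {
    n_f <- length(x$founder_ancestry)
    haps <- lapply(x$haps, function(h) list(pos = h$pos, id = h$id + id_offset))
    list(type = "cohort", haps = haps, n_hap = length(haps),
         n_ind = length(haps) %/% 2L, n_founders = n_f,
         ancestry_of = rep(ancestry, n_f),
         alleles = x$founder_alleles, positions = x$positions)
  } else stop("migrant sources must be founder panels or cohorts")
}

#' Simulate an admixed cohort by forward-time random mating
#'
#' Founds a population of `n_individuals` diploids from the base-ancestry
#' founder pool and evolves it for `n_generations` of random mating
#' (selfing excluded). At each offspring generation, every parental slot is
#' independently filled by a migrant diploid of source ancestry `s` with
#' probability equal to that source's active per-generation fraction, and by
#' a random individual of the previous generation otherwise. Each offspring
#' haplotype is a crossover mosaic of its parent's two haplotypes, with
#' crossovers drawn from the genetic map by [sample_crossovers()]'s model.
#' Founder-block pedigree, and with it the truth ancestry tracts, is
#' propagated exactly through every meiosis.
#'
#' Migrant (and base) pools may be raw [generate_founders()] panels - each
#' migrant is a fresh pairing of two distinct panel haplotypes, drawn with
#' replacement across migrants - or entire previously simulated cohorts
#' (via `migrant_pools`), which lets source populations carry their own
#' internal drift history.
#'
#' @param founders A [generate_founders()] panel (used for every ancestry
#'   not overridden in `migrant_pools`).
#' @param schedule A [gene_flow_schedule()].
#' @param map A [recomb_map()] covering `[0, chrom_length)`.
#' @param n_individuals Diploid population size (>= 2), constant across
#'   generations.
#' @param n_generations Number of meiosis rounds (>= max event start).
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#' @param migrant_pools Optional named list mapping ancestry labels to
#'   `cohort` or `founder_panel` objects overriding `founders`.
#' @return A `cohort` object carrying the haplotype mosaics, founder
#'   ancestry and allele tables, site positions, and the map.
#' @export
simulate_admixture <- function(founders, schedule, map, n_individuals,
                               n_generations, seed = NULL,
                               migrant_pools = NULL) {
  stopifnot(inherits(schedule, "gene_flow_schedule"))
  if (n_individuals < 2) stop("population size must be at least 2")
  ev <- schedule$events
  if (nrow(ev) && max(ev$start_gen) > n_generations) {
    stop("schedule events start before the founding generation; raise n_generations")
  }
  labels <- c(schedule$base, ev$ancestry)
  chrom_length <- map_span(map)[2L]

  with_seed(seed, {
    sources <- list()
    offset <- 0L
    for (anc in labels) {
      pool <- migrant_pools[[anc]] %||% founders
      if (is.null(pool)) stop(sprintf("no founder pool for ancestry '%s'", anc))
      s <- as_source(pool, anc, offset)
      if (s$n_hap < 2L) stop(sprintf("empty or degenerate founder pool for ancestry '%s'", anc))
      offset <- offset + s$n_founders
      sources[[anc]] <- s
    }
    founder_ancestry <- unlist(lapply(sources, `[[`, "ancestry_of"), use.names = FALSE)
    have_alleles <- all(vapply(sources, function(s) !is.null(s$alleles), logical(1)))
    positions <- sources[[1L]]$positions
    founder_alleles <- NULL
    if (have_alleles && length(positions)) {
      if (!all(vapply(sources, function(s) identical(s$positions, positions), logical(1)))) {
        stop("all founder pools must share the same site positions")
      }
      founder_alleles <- do.call(cbind, lapply(sources, `[[`, "alleles"))
    }

    draw_migrant <- function(src) {
      if (src$type == "panel") {
        i1 <- sample.int(src$n_hap, 1L)
        i2 <- sample.int(src$n_hap - 1L, 1L)
        if (i2 >= i1) i2 <- i2 + 1L
        list(src$haps[[i1]], src$haps[[i2]])
      } else {
        i <- sample.int(src$n_ind, 1L)
        list(src$haps[[2L * i - 1L]], src$haps[[2L * i]])
      }
    }

    n_hap <- 2L * n_individuals
    base_src <- sources[[schedule$base]]
    pop <- vector("list", n_hap)
    for (i in seq_len(n_individuals)) {
      ind <- draw_migrant(base_src)
      pop[[2L * i - 1L]] <- ind[[1L]]
      pop[[2L * i]] <- ind[[2L]]
    }

    total_cm <- map_total_cm(map)
    n_ev <- nrow(ev)
    for (t in rev(seq_len(n_generations)) - 1L) {
      # events contribute to offspring born at times start_gen-1 .. 0
      active_frac <- if (n_ev) ev$fraction * (ev$start_gen >= t + 1L) else numeric(0)
      resid <- 1 - sum(active_frac)
      cats <- if (n_ev) {
        sample.int(n_ev + 1L, n_hap, replace = TRUE, prob = c(active_frac, resid))
      } else rep.int(n_ev + 1L, n_hap)
      res_idx <- sample.int(n_individuals, n_hap, replace = TRUE)
      # exclude selfing: the two resident parents of an offspring must differ
      for (o in seq_len(n_individuals)) {
        a <- 2L * o - 1L; b <- 2L * o
        if (cats[a] > n_ev && cats[b] > n_ev) {
          while (res_idx[b] == res_idx[a]) res_idx[b] <- sample.int(n_individuals, 1L)
        }
      }
      counts <- rpois(n_hap, total_cm / 100)
      all_cuts <- if (sum(counts) > 0L) {
        interp_bp(map, runif(sum(counts), 0, total_cm))
      } else numeric(0)
      cut_at <- c(0L, cumsum(counts))
      firsts <- sample.int(2L, n_hap, replace = TRUE)
      newpop <- vector("list", n_hap)
      for (s in seq_len(n_hap)) {
        if (cats[s] <= n_ev) {
          par <- draw_migrant(sources[[ev$ancestry[cats[s]]]])
          h1 <- par[[1L]]; h2 <- par[[2L]]
        } else {
          h1 <- pop[[2L * res_idx[s] - 1L]]
          h2 <- pop[[2L * res_idx[s]]]
        }
        k <- counts[s]
        newpop[[s]] <- if (k == 0L) {
          if (firsts[s] == 1L) h1 else h2
        } else {
          splice_blocks(h1, h2, sort(all_cuts[(cut_at[s] + 1L):cut_at[s + 1L]]),
                        firsts[s])
        }
      }
      pop <- newpop
    }

    structure(list(
      chrom = map$chrom[1L], chrom_length = chrom_length, map = map,
      haps = pop, founder_ancestry = founder_ancestry,
      founder_alleles = founder_alleles, positions = positions,
      samples = sprintf("ind%03d", seq_len(n_individuals)),
      n_generations = n_generations, schedule = schedule
    ), class = "cohort")
  })
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d diploids, chrom %s (%.0f bp), %d sites, %d generations\n",
              length(x$samples), x$chrom, x$chrom_length, length(x$positions),
              x$n_generations))
  invisible(x)
}

#' Restrict a cohort to a subset of individuals
#' @param cohort A `cohort`.
#' @param individuals Integer indices of the diploids to keep.
#' @export
cohort_subset <- function(cohort, individuals) {
  idx <- as.integer(rbind(2L * individuals - 1L, 2L * individuals))
  cohort$haps <- cohort$haps[idx]
  cohort$samples <- cohort$samples[individuals]
  cohort
}

#' Truth local-ancestry tracts of a simulated cohort
#'
#' Maps every founder block to its founder's ancestry and merges adjacent
#' same-ancestry blocks, yielding per-haplotype tracts that tile
#' `[0, chrom_length)` exactly.
#'
#' @param cohort A `cohort` from [simulate_admixture()].
#' @return A [tract_set()].
#' @export
cohort_tracts <- function(cohort) {
  n_hap <- length(cohort$haps)
  rows <- vector("list", n_hap)
  for (h in seq_len(n_hap)) {
    hp <- cohort$haps[[h]]
    anc <- cohort$founder_ancestry[hp$id]
    r <- collapse_runs(hp$pos, anc)
    rows[[h]] <- data.table::data.table(
      sample = cohort$samples[(h + 1L) %/% 2L],
      hap = (h - 1L) %% 2L,
      chrom = cohort$chrom,
      start = r$starts,
      end = c(r$starts[-1L], cohort$chrom_length),
      ancestry = r$values
    )
  }
  d <- as.data.frame(data.table::rbindlist(rows))
  tract_set(d, alphabet = sort(unique(cohort$founder_ancestry)),
            extent = c(0, cohort$chrom_length))
}

#' Founder-block pedigree of a simulated cohort
#'
#' @param cohort A `cohort`.
#' @return data.frame with one row per founder block: `sample`, `hap`,
#'   `chrom`, `start`, `end`, `founder_id`.
#' @export
cohort_pedigree <- function(cohort) {
  n_hap <- length(cohort$haps)
  rows <- vector("list", n_hap)
  for (h in seq_len(n_hap)) {
    hp <- cohort$haps[[h]]
    rows[[h]] <- data.table::data.table(
      sample = cohort$samples[(h + 1L) %/% 2L],
      hap = (h - 1L) %% 2L,
      chrom = cohort$chrom,
      start = hp$pos,
      end = c(hp$pos[-1L], cohort$chrom_length),
      founder_id = hp$id
    )
  }
  as.data.frame(data.table::rbindlist(rows))
}

#' Allele matrix of a simulated cohort
#'
#' Copies founder alleles through the block pedigree: every site's allele on
#' a haplotype is the allele of the founder haplotype whose block covers it.
#'
#' @param cohort A `cohort` simulated from founder panels with sites.
#' @return Integer 0/1 matrix, sites x haplotypes; attributes `positions`
#'   and `chrom`. Column names are `sample.hap`.
#' @export
cohort_alleles <- function(cohort) {
  if (is.null(cohort$founder_alleles)) {
    stop("cohort carries no founder alleles (pedigree-only simulation)")
  }
  n_hap <- length(cohort$haps)
  n_site <- length(cohort$positions)
  out <- matrix(0L, nrow = n_site, ncol = n_hap)
  for (h in seq_len(n_hap)) {
    hp <- cohort$haps[[h]]
    block <- findInterval(cohort$positions, hp$pos)
    out[, h] <- cohort$founder_alleles[cbind(seq_len(n_site), hp$id[block])]
  }
  colnames(out) <- paste0(rep(cohort$samples, each = 2L), ".", rep(0:1, length(cohort$samples)))
  hap_matrix(out, positions = cohort$positions, chrom = cohort$chrom)
}
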