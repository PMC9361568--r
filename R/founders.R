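#' Generate differentiated founder haplotype panels
#'
#' Draws biallelic founder haplotypes for several source ancestries under the
#' Balding-Nichols model: each site has an ancestral frequency
#' `p ~ Uniform(0.05, 0.95)`, and each ancestry's site frequency is drawn
#' from `Beta(p (1 - fst) / fst, (1 - p) (1 - fst) / fst)`, so `fst` controls
#' the differentiation between ancestries. Alleles are sampled independently
#' per haplotype; site positions are uniform, sorted and distinct.
#'
#' @param n_per_pop Diploid founders per ancestry (>= 1); each contributes
#'   two haplotypes.
#' @param n_sites Number of polymorphic sites shared by all ancestries. May
#'   be 0 for pedigree-only simulations (no allele matrices).
#' @param fst Differentiation parameter in (0, 1).
#' @param length_bp Chromosome length in bp.
#' @param seed Integer seed.
#' @param ancestries Character vector of ancestry labels.
#' @return A `founder_panel`: list with `ancestries`, `positions`,
#'   `length_bp`, `freqs` (site x ancestry matrix), `anc_freq`, and
#'   `haplotypes` (ancestry-named list of site x haplotype 0/1 matrices).
#' @export
generate_founders <- function(n_per_pop, n_sites, fst, length_bp, seed = NULL,
                              ancestries = c("KhoeSan", "European", "Bantu")) {
  if (n_per_pop < 1) stop("n_per_pop must be >= 1")
  if (fst <= 0 || fst >= 1) stop("fst must be in (0, 1)")
  if (n_sites > length_bp) stop("n_sites exceeds the number of distinct positions")
  with_seed(seed, {
    positions <- sort(sample.int(length_bp, n_sites))
    p <- runif(n_sites, 0.05, 0.95)
    k <- (1 - fst) / fst
    freqs <- matrix(NA_real_, nrow = n_sites, ncol = length(ancestries),
                    dimnames = list(NULL, ancestries))
    for (a in ancestries) {
      if (n_sites > 0L) freqs[, a] <- rbeta(n_sites, p * k, (1 - p) * k)
    }
    haps <- lapply(ancestries, function(a) {
      m <- matrix(rbinom(n_sites * 2L * n_per_pop, 1L, rep(freqs[, a], 2L * n_per_pop)),
                  nrow = n_sites)
      storage.mode(m) <- "integer"
      m
    })
    names(haps) <- ancestries
    structure(list(ancestries = ancestries, positions = positions,
                   length_bp = length_bp, anc_freq = p, freqs = freqs,
                   haplotypes = haps, n_per_pop = n_per_pop),
              class = "founder_panel")
  })
}

#' Hudson estimator of FST from two frequency vectors
#'
#' Ratio-of-averages Hudson estimator computed from population allele
#' frequencies and haploid sample sizes; used to verify that generated
#' founder panels carry the requested differentiation.
#'
#' @param p1,p2 Allele frequency vectors.
#' @param n1,n2 Haploid sample sizes the frequencies were estimated from.
#' @return Single FST estimate over sites.
#' @export
fst_hudson <- function(p1, p2, n1, n2) {
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  sum(num) / sum(den)
}

#' Continuous gene-flow schedule
#'
#' Describes recurring admixture: each event contributes `fraction` of every
#' offspring generation's parents from `ancestry`, starting `start_gen`
#' generations before present and continuing to the present. The residual
#' parent fraction each generation comes from the existing population, whose
#' founders carry `base` ancestry.
#'
#' @param events data.frame with columns `ancestry`, `start_gen` (>= 1) and
#'   `fraction` (in \[0, 1\]); may have zero rows.
#' @param base Label of the ancestry founding the recipient population.
#' @return A `gene_flow_schedule`.
#' @export
gene_flow_schedule <- function(events = data.frame(ancestry = character(),
                                                   start_gen = integer(),
                                                   fraction = numeric()),
                               base) {
  stopifnot(all(c("ancestry", "start_gen", "fraction") %in% names(events)))
  if (nrow(events)) {
    if (any(events$start_gen < 1)) stop("event start_gen must be >= 1")
    if (any(events$fraction < 0 | events$fraction > 1)) stop("fractions must be in [0, 1]")
    worst <- sum(events$fraction)
    if (worst >= 1) stop("per-generation migrant fractions must sum to < 1")
    if (base %in% events$ancestry) stop("base ancestry cannot also be a migrant source")
  }
  structure(list(events = events, base = base), class = "gene_flow_schedule")
}

#' Expected ancestry fractions under a gene-flow schedule
#'
#' Closed-form expectation of the simulator's continuous gene-flow model: at
#' each offspring generation every parental lineage is replaced by a migrant
#' of source `s` with probability equal to that source's active fraction
#' (mutually exclusive across sources), else retained. A lineage's ancestry
#' is the source of its most recent replacement. With a single event of
#' fraction `f` active for `T` generations this reduces to `1 - (1 - f)^T`.
#'
#' @param schedule A [gene_flow_schedule()].
#' @return Named numeric vector of expected present-day ancestry fractions
#'   (including the base ancestry), summing to 1.
#' @export
expected_ancestry_fractions <- function(schedule) {
  ev <- schedule$events
  labels <- unique(c(schedule$base, ev$ancestry))
  out <- setNames(numeric(length(labels)), labels)
  if (!nrow(ev)) { out[schedule$base] <- 1; return(out) }
  horizon <- max(ev$start_gen)
  surv <- 1
  # walk backwards from the present: generation t (1 = most recent meiosis)
  for (t in seq_len(horizon)) {
    active <- ev$start_gen >= t
    f <- ev$fraction * active
    for (i in seq_len(nrow(ev))) out[ev$ancestry[i]] <- out[ev$ancestry[i]] + surv * f[i]
    surv <- surv * (1 - sum(f))
  }
  out[schedule$base] <- 1 - sum(out[ev$ancestry])
  out
}
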