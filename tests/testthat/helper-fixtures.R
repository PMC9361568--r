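# Small deterministic fixtures shared across test files.

uniform_map <- function(length_bp = 1e6, rate = 1e-8, chrom = "1") {
  recomb_map(chrom, 0, length_bp, rate)
}

# A tract_set built from a compact spec list: list(sample, hap, starts,
# labels); ends are implied by the next start and `len`.
tracts_from_runs <- function(runs, len, alphabet, chrom = "1") {
  rows <- lapply(runs, function(r) {
    data.frame(sample = r$sample, hap = r$hap, chrom = chrom,
               start = r$starts, end = c(r$starts[-1L], len),
               ancestry = r$labels, stringsAsFactors = FALSE)
  })
  tract_set(do.call(rbind, rows), alphabet = alphabet, extent = c(0, len))
}

# A small admixed cohort used by several test files (pedigree + alleles).
small_admixed_cohort <- function(seed = 42, n_ind = 30, n_gen = 12,
                                 length_bp = 5e6, n_sites = 400) {
  map <- synth_map(genetic_map_spec(length_bp, background_rate = 2e-8,
                                    hotspot_rate = 2), seed = seed)
  f <- generate_founders(40, n_sites, 0.2, length_bp, seed = seed + 1,
                         ancestries = c("A", "B", "C"))
  sched <- gene_flow_schedule(
    data.frame(ancestry = c("B", "C"),
               start_gen = pmax(1L, pmin(c(8L, 12L), as.integer(n_gen))),
               fraction = c(0.05, 0.03)), base = "A")
  coh <- simulate_admixture(f, sched, map, n_ind, n_gen, seed = seed + 2)
  list(map = map, founders = f, schedule = sched, cohort = coh)
}

random_hap_matrix <- function(n_sites, n_haps, length_bp = 5e5, seed = 1) {
  withr_seed <- seed
  set.seed(withr_seed)
  pos <- sort(sample.int(length_bp, n_sites))
  m <- matrix(rbinom(n_sites * n_haps, 1L, runif(n_sites, 0.15, 0.85)),
              nrow = n_sites)
  hap_matrix(m, positions = pos)
}
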