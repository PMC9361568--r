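# Stage registry: what each pipeline stage needs and provides. Inputs can be
# satisfied by an earlier stage's product or by a file override in
# config$inputs; the dependency walk runs before any stage executes.
stage_registry <- list(
  simulate = list(needs = character(0),
                  provides = c("map_main", "map_sibling", "cohort",
                               "truth_tracts", "truth_ibd")),
  ancestry = list(needs = c("truth_tracts"), provides = c("inferred_tracts")),
  ibd = list(needs = c("truth_ibd", "inferred_tracts", "map_main"),
             provides = c("ibd_by_ancestry")),
  ne = list(needs = c("ibd_by_ancestry", "map_main"), provides = c("ne_tables")),
  demography = list(needs = c("ne_tables"), provides = c("merged_demography")),
  recmap = list(needs = c("map_main", "map_sibling"), provides = c("map_report")),
  ihs = list(needs = c("cohort", "map_main", "map_sibling"),
             provides = c("ihs_report"))
)

# File-override keys understood in config$inputs, with their readers.
input_readers <- list(
  map_main = function(p) read_map(p, "interval"),
  map_sibling = function(p) read_map(p, "interval"),
  truth_tracts = function(p) read_tracts(p),
  inferred_tracts = function(p) read_tracts(p),
  truth_ibd = function(p) read_ibd(p),
  distant_ne = function(p) read_ne_csv(p),
  gene_ranges = function(p) read_gene_ranges(p)
)

#' Default pipeline configuration
#'
#' Returns the full default parameter set of [run_pipeline()]; any file or
#' YAML config is merged over it. Defaults describe a compact three-way
#' admixed cohort (Khoe-San base with European and Bantu continuous gene
#' flow) on a single hotspot-punctuated chromosome.
#'
#' @return Nested list of stage parameter blocks.
#' @export
default_config <- function() {
  list(
    stages = c("simulate", "ancestry", "ibd", "ne", "demography", "recmap", "ihs"),
    seed = 1L,
    simulate = list(
      chrom_length_bp = 2e7, background_rate = 2e-9, hotspot_rate = 10,
      hotspot_width_bp = 2000, intensity_fold = 100,
      shared_fraction = 0.8,
      n_per_pop = 11L, n_sites = 2000L, fst = 0.15,
      base = "KhoeSan",
      events = list(list(ancestry = "European", start_gen = 8L, fraction = 0.01),
                    list(ancestry = "Bantu", start_gen = 14L, fraction = 0.02)),
      n_individuals = 50L, n_generations = 20L
    ),
    ancestry = list(switch_error_per_mb = 0.05, window_bp = 5e5),
    ibd = list(min_cm_extract = 1, max_gap_cm = 0.6, max_gap_bp = Inf,
               min_fraction = 0.9, min_cm = 3, use_truth_tracts = TRUE),
    ne = list(grid_min = 4L, grid_max = 50L, smooth_penalty = 200,
              n_boot = 0L, n_chunks = 5L),
    demography = list(bridge = "geometric", distant_gens = c(260, 1000, 5000),
                      distant_ne = c(4000, 10000, 21000), ancestry = NULL),
    recmap = list(bin_width = 2000L, min_overlap = 100L,
                  bg_window_bp = 1e5, fold = 10, min_width_bp = 500),
    ihs = list(maf_min = 0.05, cutoff = 0.05, max_gap = 2e5, scale_gap = 2e4,
               require_decay = FALSE, n_freq_bins = 20L, fraction = 0.01,
               gene_width_bp = 3e4, gene_spacing_bp = 5e4),
    inputs = list()
  )
}

merge_config <- function(base, override) {
  for (k in names(override)) {
    base[[k]] <- if (is.list(base[[k]]) && is.list(override[[k]]) &&
                     !is.null(names(base[[k]]))) {
      merge_config(base[[k]], override[[k]])
    } else override[[k]]
  }
  base
}

write_manifest <- function(outdir, stage, params, seed, outputs) {
  files <- unlist(outputs, use.names = FALSE)
  sums <- as.list(tools::md5sum(files))
  jsonlite::write_json(
    list(stage = stage, seed = seed, parameters = params,
         outputs = outputs, md5 = sums),
    file.path(outdir, sprintf("manifest_%s.json", stage)),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in dependency order on synthetic data
#' (or on externally produced files supplied via `config$inputs`):
#' simulate an admixed cohort over a hotspot map pair, emulate and score
#' local-ancestry inference, merge and ancestry-label IBD segments,
#' fit per-ancestry recent effective sizes, merge with a distant
#' trajectory, compare the map pair, and run the dual-map iHS scan.
#' Every stage writes its dialect outputs plus a JSON manifest (parameters,
#' seed, output checksums); re-running with an identical config reproduces
#' identical files.
#'
#' @param config A nested list, or path to a YAML file, merged over
#'   [default_config()].
#' @param outdir Output directory (created if needed).
#' @param seed Optional seed overriding `config$seed`.
#' @return Invisibly, a run manifest list: per-stage outputs and checksums.
#' @export
run_pipeline <- function(config = list(), outdir, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_config(), config)
  if (!is.null(seed)) cfg$seed <- seed
  if (is.null(cfg$seed)) stop("a seed is mandatory (stochastic stages)")
  stages <- cfg$stages

  unknown <- setdiff(stages, names(stage_registry))
  if (length(unknown)) stop("unknown stage(s): ", paste(unknown, collapse = ", "))
  # dependency walk before any stage runs
  have <- names(cfg$inputs)
  for (st in stages) {
    missing <- setdiff(stage_registry[[st]]$needs, have)
    if (length(missing)) {
      stop(sprintf("stage '%s' is missing input(s) %s: run the providing stage or supply config$inputs",
                   st, paste(missing, collapse = ", ")))
    }
    have <- union(have, stage_registry[[st]]$provides)
  }
  for (k in names(cfg$inputs)) {
    if (!file.exists(cfg$inputs[[k]])) {
      stop(sprintf("input override '%s' does not exist: %s", k, cfg$inputs[[k]]))
    }
  }

  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  ctx <- new.env(parent = emptyenv())
  for (k in names(cfg$inputs)) {
    rd <- input_readers[[k]]
    if (is.null(rd)) stop(sprintf("no reader for input override '%s'", k))
    assign(k, rd(cfg$inputs[[k]]), envir = ctx)
  }
  manifest <- list()
  for (st in stages) {
    res <- tryCatch(
      switch(st,
             simulate = stage_simulate(cfg, ctx, outdir),
             ancestry = stage_ancestry(cfg, ctx, outdir),
             ibd = stage_ibd(cfg, ctx, outdir),
             ne = stage_ne(cfg, ctx, outdir),
             demography = stage_demography(cfg, ctx, outdir),
             recmap = stage_recmap(cfg, ctx, outdir),
             ihs = stage_ihs(cfg, ctx, outdir)),
      error = function(e) stop(sprintf("stage '%s' failed: %s", st,
                                       conditionMessage(e)), call. = FALSE))
    write_manifest(outdir, st, cfg[[st]], cfg$seed, res)
    manifest[[st]] <- res
  }
  jsonlite::write_json(manifest, file.path(outdir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

stage_simulate <- function(cfg, ctx, outdir) {
  p <- cfg$simulate
  seed <- derive_seed(cfg$seed, "simulate")
  spec <- genetic_map_spec(p$chrom_length_bp, p$background_rate, p$hotspot_rate,
                           p$hotspot_width_bp, p$intensity_fold)
  map <- synth_map(spec, seed = seed)
  sib <- derive_sibling_map(map, p$shared_fraction, seed = derive_seed(seed, "sib"))
  ev <- do.call(rbind, lapply(p$events, as.data.frame))
  schedule <- gene_flow_schedule(ev, base = p$base)
  founders <- generate_founders(p$n_per_pop, p$n_sites, p$fst, p$chrom_length_bp,
                                seed = derive_seed(seed, "founders"),
                                ancestries = unique(c(p$base, ev$ancestry)))
  cohort <- simulate_admixture(founders, schedule, map, p$n_individuals,
                               p$n_generations, seed = derive_seed(seed, "cohort"))
  tracts <- cohort_tracts(cohort)
  ibd <- extract_true_ibd(cohort, min_cm = cfg$ibd$min_cm_extract)
  assign("map_main", map, envir = ctx)
  assign("map_sibling", sib, envir = ctx)
  assign("cohort", cohort, envir = ctx)
  assign("truth_tracts", tracts, envir = ctx)
  assign("truth_ibd", ibd, envir = ctx)
  out <- list(
    map_main_interval = file.path(outdir, "map_main.interval.tsv"),
    map_main_hapmap = file.path(outdir, "map_main.hapmap.txt"),
    map_sibling_interval = file.path(outdir, "map_sibling.interval.tsv"),
    truth_tracts = file.path(outdir, "truth_tracts.tsv"),
    truth_msp = file.path(outdir, "truth.msp.tsv"),
    truth_ibd = file.path(outdir, "truth_ibd.tsv"),
    haplotypes_vcf = file.path(outdir, "cohort.vcf"),
    haplotypes_tsv = file.path(outdir, "cohort.hap.tsv")
  )
  write_map(map, out$map_main_interval, "interval")
  write_map(map, out$map_main_hapmap, "hapmap")
  write_map(sib, out$map_sibling_interval, "interval")
  write_tracts(tracts, out$truth_tracts)
  write_msp(tracts, out$truth_msp, map = map)
  write_ibd(ibd, out$truth_ibd)
  hm <- cohort_alleles(cohort)
  write_phased_vcf(hm, out$haplotypes_vcf, samples = cohort$samples)
  write_hap_tsv(hm, out$haplotypes_tsv)
  out
}

stage_ancestry <- function(cfg, ctx, outdir) {
  p <- cfg$ancestry
  truth <- get("truth_tracts", envir = ctx)
  inferred <- corrupt_tracts(truth, p$switch_error_per_mb,
                             seed = derive_seed(cfg$seed, "ancestry"),
                             window_bp = p$window_bp)
  report <- lai_accuracy(truth, inferred)
  assign("inferred_tracts", inferred, envir = ctx)
  out <- list(inferred_tracts = file.path(outdir, "inferred_tracts.tsv"),
              accuracy = file.path(outdir, "lai_accuracy.json"),
              proportions = file.path(outdir, "ancestry_proportions.tsv"))
  write_tracts(inferred, out$inferred_tracts)
  jsonlite::write_json(list(
    global_accuracy = report$global_accuracy,
    global_accuracy_by_individual = report$global_accuracy_by_individual,
    per_ancestry_recall = as.list(report$per_ancestry_recall)),
    out$accuracy, auto_unbox = TRUE, digits = NA)
  write.table(cbind(sample = rownames(report$per_individual_fractions),
                    report$per_individual_fractions),
              out$proportions, sep = "\t", quote = FALSE, row.names = FALSE)
  out
}

stage_ibd <- function(cfg, ctx, outdir) {
  p <- cfg$ibd
  segs <- get("truth_ibd", envir = ctx)
  map <- get("map_main", envir = ctx)
  tracts <- if (isTRUE(p$use_truth_tracts) && exists("truth_tracts", envir = ctx)) {
    get("truth_tracts", envir = ctx)
  } else get("inferred_tracts", envir = ctx)
  merged <- merge_ibd_gaps(segs, p$max_gap_cm, p$max_gap_bp, map = map)
  labelled <- assign_ibd_ancestry(merged, tracts, min_fraction = p$min_fraction)
  parts <- partition_by_ancestry(labelled, min_cm = p$min_cm)
  assign("ibd_by_ancestry", parts, envir = ctx)
  assign("ibd_labelled", labelled, envir = ctx)
  out <- list(labelled = file.path(outdir, "ibd_labelled.tsv"))
  lab <- labelled
  write.table(as.data.frame(lab), out$labelled, sep = "\t", quote = FALSE,
              row.names = FALSE)
  for (anc in names(parts)) {
    f <- file.path(outdir, sprintf("ibd_%s.tsv", anc))
    write_ibd(parts[[anc]], f)
    out[[paste0("ibd_", anc)]] <- f
  }
  out
}

stage_ne <- function(cfg, ctx, outdir) {
  p <- cfg$ne
  parts <- get("ibd_by_ancestry", envir = ctx)
  map <- get("map_main", envir = ctx)
  genome_cm <- map_total_cm(map)
  cohort <- if (exists("cohort", envir = ctx)) get("cohort", envir = ctx) else NULL
  n_hap <- if (!is.null(cohort)) length(cohort$haps) else {
    tr <- get("inferred_tracts", envir = ctx)
    2L * length(unique(tr$sample))
  }
  tracts <- if (exists("truth_tracts", envir = ctx)) get("truth_tracts", envir = ctx)
            else get("inferred_tracts", envir = ctx)
  props <- global_proportions(tracts)
  grid <- seq.int(p$grid_min, p$grid_max)
  out <- list()
  fits <- list()
  for (anc in names(parts)) {
    frac <- mean(props[[anc]])
    n_pairs <- effective_pairs(n_hap, frac)
    fit <- tryCatch({
      if (p$n_boot >= 2L && p$n_chunks >= 2L) {
        chunk_edges <- seq(0, map_span(map)[2L], length.out = p$n_chunks + 1L)
        ch <- cut(parts[[anc]]$start, chunk_edges, labels = FALSE,
                  include.lowest = TRUE)
        chunks <- lapply(seq_len(p$n_chunks), function(k) {
          parts[[anc]]$length_cm[which(ch == k)]
        })
        chunk_cm <- diff(interp_cm(map, chunk_edges))
        bootstrap_ne(chunks, chunk_cm, n_pairs, n_boot = p$n_boot,
                     seed = derive_seed(cfg$seed, paste0("boot_", anc)),
                     grid = grid, smooth_penalty = p$smooth_penalty)
      } else {
        fit_ne(ibd_spectrum(parts[[anc]], n_pairs, genome_cm), grid = grid,
               smooth_penalty = p$smooth_penalty)
      }
    }, error = function(e) NULL)
    if (is.null(fit)) next
    f <- file.path(outdir, sprintf("ne_%s.tsv", anc))
    write_ne_table(fit, f)
    out[[paste0("ne_", anc)]] <- f
    fits[[anc]] <- fit
  }
  if (!length(fits)) stop("insufficient IBD in every ancestry partition")
  assign("ne_tables", fits, envir = ctx)
  out
}

stage_demography <- function(cfg, ctx, outdir) {
  p <- cfg$demography
  fits <- get("ne_tables", envir = ctx)
  anc <- p$ancestry %||% names(fits)[1L]
  recent <- fits[[anc]]
  distant <- if (exists("distant_ne", envir = ctx)) get("distant_ne", envir = ctx)
             else ne_trajectory(p$distant_gens, p$distant_ne)
  merged <- merge_trajectories(recent, distant, bridge = p$bridge)
  assign("merged_demography", merged, envir = ctx)
  out <- list(merged_csv = file.path(outdir, "demography_merged.csv"),
              epochs_json = file.path(outdir, "demography_epochs.json"))
  write_ne_csv(merged, out$merged_csv)
  write_epochs_json(merged, out$epochs_json)
  out
}

stage_recmap <- function(cfg, ctx, outdir) {
  p <- cfg$recmap
  a <- get("map_main", envir = ctx); b <- get("map_sibling", envir = ctx)
  binned <- list(main = bin_rates(a, p$bin_width), sibling = bin_rates(b, p$bin_width))
  mat <- spearman_matrix(binned, min_overlap = p$min_overlap)
  ord <- if (!any(is.na(mat))) cluster_order(mat)$order else rownames(mat)
  hot_a <- call_hotspots(a, p$bg_window_bp, p$fold, p$min_width_bp)
  hot_b <- call_hotspots(b, p$bg_window_bp, p$fold, p$min_width_bp)
  conc <- hotspot_concordance(hot_a, hot_b)
  out <- list(spearman = file.path(outdir, "map_spearman.tsv"),
              report = file.path(outdir, "map_report.json"),
              hotspots_main = file.path(outdir, "hotspots_main.tsv"),
              hotspots_sibling = file.path(outdir, "hotspots_sibling.tsv"))
  write.table(mat, out$spearman, sep = "\t", quote = FALSE)
  write.table(hot_a, out$hotspots_main, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(hot_b, out$hotspots_sibling, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(spearman_main_sibling = mat["main", "sibling"],
                            cluster_order = ord, hotspot_concordance = conc),
                       out$report, auto_unbox = TRUE, digits = NA)
  assign("map_report", conc, envir = ctx)
  out
}

stage_ihs <- function(cfg, ctx, outdir) {
  p <- cfg$ihs
  cohort <- get("cohort", envir = ctx)
  a <- get("map_main", envir = ctx); b <- get("map_sibling", envir = ctx)
  hm <- cohort_alleles(cohort)
  genes <- if (exists("gene_ranges", envir = ctx)) get("gene_ranges", envir = ctx)
           else synthetic_gene_ranges(cohort$chrom_length, p$gene_width_bp,
                                      p$gene_spacing_bp, chrom = cohort$chrom)
  curves <- ihs_curves(hm, maf_min = p$maf_min, cutoff = p$cutoff)
  scan <- function(map) {
    standardize_ihs(ihs_scores(hm, map, cutoff = p$cutoff,
                               max_gap = p$max_gap, scale_gap = p$scale_gap,
                               require_decay = p$require_decay,
                               curves = curves),
                    n_freq_bins = p$n_freq_bins)
  }
  ta <- scan(a); tb <- scan(b)
  rep <- compare_runs(ta, tb, genes, fraction = p$fraction)
  out <- list(ihs_main = file.path(outdir, "ihs_main.tsv"),
              ihs_sibling = file.path(outdir, "ihs_sibling.tsv"),
              hits_main = file.path(outdir, "hits_main.bed"),
              report = file.path(outdir, "ihs_report.json"))
  write.table(ta, out$ihs_main, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(tb, out$ihs_sibling, sep = "\t", quote = FALSE, row.names = FALSE)
  hits <- top_hits(ta, p$fraction)
  write.table(data.frame(chrom = attr(ta, "chrom") %||% cohort$chrom,
                         start = hits$pos - 1, end = hits$pos,
                         score = hits$ihs_std),
              out$hits_main, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  jsonlite::write_json(list(
    n_shared_sites = rep$n_shared_sites, n_scored_both = rep$n_scored_both,
    pearson_r = rep$pearson_r,
    n_genes_main = length(rep$genes_a), n_genes_sibling = length(rep$genes_b),
    n_shared_genes = length(rep$shared_genes),
    overlap_fraction = rep$overlap_fraction),
    out$report, auto_unbox = TRUE, digits = NA)
  assign("ihs_report", rep, envir = ctx)
  out
}
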