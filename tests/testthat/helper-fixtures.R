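# Shared fixtures: cached genome/cytobands, reduced-size simulation
# helpers, and a random-diagnosis generator for property-style tests.

GENOME <- genome_model()
CYTO <- cytoband_table()

disomic <- cell_karyotype(genome = GENOME)

karyo <- function(notation) {
  cell_karyotype(parse_mosaic_notation(notation, GENOME, CYTO),
                 genome = GENOME)
}

# exact-fraction two-line mixture: `fraction` abnormal cells
mixture <- function(notation, fraction, n_cells = 5L) {
  if (fraction == 0) return(biopsy_truth(list(disomic), 1, n_cells))
  if (fraction == 1) return(biopsy_truth(list(karyo(notation)), 1, n_cells))
  biopsy_truth(list(disomic, karyo(notation)), c(1 - fraction, fraction),
               n_cells)
}

flat_weights <- function(genome = GENOME, tile_kb = 1000) {
  simulate_mda(genome, tile_kb = tile_kb, sigma_log = 0, seed = 1)
}

# noiseless SNP rendering at reduced marker density
snp_noiseless <- function(truth, n_markers = 40000, genome = GENOME) {
  render_snp(truth, flat_weights(genome), n_markers = n_markers,
             sigma_lrr = 0, sigma_baf = 0, nocall_prob = 0,
             genome = genome, seed = 7)
}

# exact (expectation-valued) NGS rendering: no GC curve, no count noise
ngs_exact <- function(truth, genome = GENOME, bin_kb = 1000) {
  render_ngs(truth, flat_weights(genome), bin_kb = bin_kb,
             gc_coeffs = c(0, 0), overdispersion = 0, exact = TRUE,
             genome = genome, seed = 7)
}

# one random event on a random chromosome; segments drawn from cytobands
random_event <- function(genome = GENOME, cytobands = CYTO,
                         mosaic = NA) {
  chrom <- sample(genome$chrom[1:22], 1)
  scope <- sample(c("whole", "p", "q", "segment"), 1)
  direction <- sample(c("gain", "loss"), 1)
  if (is.na(mosaic)) mosaic <- sample(c(TRUE, FALSE), 1)
  if (scope == "segment") {
    bands <- cytobands[cytobands$chrom == chrom, ]
    picks <- bands[sample(nrow(bands), 2, replace = TRUE), ]
    cn_event(chrom, "segment", direction, mosaic = mosaic,
             start = min(picks$start), end = max(picks$end),
             genome = genome)
  } else {
    cn_event(chrom, scope, direction, mosaic = mosaic, genome = genome)
  }
}

# random diagnosis: <= 1 event per chromosome so whole/arm coexistence
# invariants hold by construction
random_diagnosis <- function(platform = "SNP", n_events = NULL,
                             mosaic = NA, genome = GENOME,
                             cytobands = CYTO) {
  if (is.null(n_events)) n_events <- sample(1:3, 1)
  evs <- list(); used <- character()
  while (length(evs) < n_events) {
    ev <- random_event(genome, cytobands, mosaic = mosaic)
    if (ev$chrom %in% used) next
    used <- c(used, ev$chrom)
    evs[[length(evs) + 1L]] <- ev
  }
  ev_tbl <- dplyr::bind_rows(evs)
  if (platform == "NGS" && any(ev_tbl$mosaic)) {
    lv <- ifelse(ev_tbl$mosaic, sample(20:80, nrow(ev_tbl), replace = TRUE),
                 NA_real_)
    ev_tbl$level_percent <- lv
  }
  platform_diagnosis(platform, ev_tbl)
}
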