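# Small programmatic fixtures shared across tests.

toy_map <- function(m = 6, chroms = c("01", "02")) {
  per <- ceiling(m / length(chroms))
  data.frame(marker_id = paste0("m", seq_len(m)),
             chrom = rep(chroms, each = per)[seq_len(m)],
             cm = rep(seq_len(per), length(chroms))[seq_len(m)] * 10,
             bp = seq_len(m) * 1000L,
             stringsAsFactors = FALSE)
}

toy_panel <- function(n = 40, m = 6, seed = 1, years = NULL) {
  set.seed(seed)
  G <- matrix(rbinom(n * m, 2, 0.4), n, m,
              dimnames = list(paste0("v", seq_len(n)), paste0("m", seq_len(m))))
  if (is.null(years)) years <- rep(seq_len(max(2, n %/% 4)), length.out = n)
  genotype_panel(G, toy_map(m),
                 data.frame(variety_id = paste0("v", seq_len(n)),
                            year = years, stringsAsFactors = FALSE))
}

# small simulated program panel reused by several test files (cached)
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- genome_spec(chrom_lengths_cm = c(100, 120), marker_spacing_cm = 0.5)
      cfg <- breeding_config(rils_per_cross = 30)
      cache <<- simulate_panel_pair(spec = spec, seed = 42, config = cfg,
                                    founder_persistence = 0.5)
    }
    cache
  }
})
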