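#' Breeding-program configuration
#'
#' Defaults reproduce the simulated recurrent-selection program: 65
#' generations of which the first 15 are burn-in, 16 bi-parental crosses
#' per generation each yielding 100 F6 RILs of which 2 are kept, parents
#' drawn from the pool 6-10 generations back, and 8 varieties retained per
#' post-burn-in generation (a 400-variety panel over 50 years).
#'
#' @param total_generations,burnin,crosses_per_gen,rils_per_cross
#'   program dimensions.
#' @param keep_per_cross RILs kept per cross (top-2 by phenotype when
#'   `selection`, random otherwise).
#' @param varieties_per_gen varieties retained per post-burn-in generation.
#' @param pool_min_back,pool_max_back parent pool window in generations.
#' @param selection logical; phenotypic truncation selection within cross.
#' @return list of class `breeding_config`.
#' @export
breeding_config <- function(total_generations = 65L, burnin = 15L,
                            crosses_per_gen = 16L, rils_per_cross = 100L,
                            keep_per_cross = 2L, varieties_per_gen = 8L,
                            pool_min_back = 6L, pool_max_back = 10L,
                            selection = TRUE) {
  cfg <- list(total_generations = as.integer(total_generations),
              burnin = as.integer(burnin),
              crosses_per_gen = as.integer(crosses_per_gen),
              rils_per_cross = as.integer(rils_per_cross),
              keep_per_cross = as.integer(keep_per_cross),
              varieties_per_gen = as.integer(varieties_per_gen),
              pool_min_back = as.integer(pool_min_back),
              pool_max_back = as.integer(pool_max_back),
              selection = isTRUE(selection))
  stopifnot(cfg$burnin < cfg$total_generations,
            cfg$keep_per_cross <= cfg$rils_per_cross,
            cfg$varieties_per_gen <= cfg$crosses_per_gen * cfg$keep_per_cross)
  class(cfg) <- "breeding_config"
  cfg
}

# map helper: integer chromosome codes + lengths for the C++ layer
.map_codes <- function(map, chrom_lengths = NULL) {
  chroms <- unique(map$chrom)
  code <- match(map$chrom, chroms) - 1L
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(chroms, function(ch) max(map$cm[map$chrom == ch]),
                            numeric(1))
  }
  list(code = code, len = as.numeric(chrom_lengths), chroms = chroms)
}

#' Simulate one meiosis
#'
#' Produces a single gamete from two parental haplotypes under a
#' Poisson/no-interference crossover model (count ~ Poisson(length in
#' Morgans) per chromosome, breakpoints uniform, starting strand random).
#'
#' @param hap_a,hap_b binary haplotype vectors over the map's markers.
#' @param map marker map (`marker_id`, `chrom`, `cm`).
#' @param chrom_lengths optional chromosome lengths in cM (defaults to the
#'   last marker position per chromosome).
#' @return binary gamete vector.
#' @export
meiosis <- function(hap_a, hap_b, map, chrom_lengths = NULL) {
  stopifnot(length(hap_a) == nrow(map), length(hap_b) == nrow(map))
  mc <- .map_codes(map, chrom_lengths)
  .cpp_meiosis(as.integer(hap_a), as.integer(hap_b), mc$code, map$cm, mc$len)
}

#' Derive F6 recombinant inbred lines from two inbred parents
#'
#' Each RIL is formed as F1 -> F2 -> four generations of single-seed
#' selfing (F6); residual heterozygosity is retained.
#'
#' @param parent1,parent2 inbred genotype vectors (entries 0/2).
#' @param n_rils number of RILs.
#' @param map marker map.
#' @param chrom_lengths optional chromosome lengths in cM.
#' @return n_rils x m allele-count matrix (entries 0/1/2).
#' @export
derive_rils <- function(parent1, parent2, n_rils, map, chrom_lengths = NULL) {
  if (any(parent1 == 1) || any(parent2 == 1))
    stop("input error: parents must be fully inbred (entries 0/2)")
  mc <- .map_codes(map, chrom_lengths)
  .cpp_derive_rils(as.integer(parent1 / 2), as.integer(parent2 / 2),
                   as.integer(n_rils), mc$code, map$cm, mc$len)
}

#' Run the breeding program
#'
#' Simulates the recurrent-selection program: early generations from
#' random founder crosses, later generations from 16 crosses among 32
#' parents sampled 6-10 generations back, 2 RILs kept per cross (top
#' phenotype under selection, random otherwise), burn-in discarded, and 8
#' random lines retained per remaining generation with year set to the
#' post-burn-in generation index.
#'
#' @param founders founder set from [simulate_founders()].
#' @param qtl QTL model from [assign_qtls()].
#' @param map marker map from [build_genome()].
#' @param config a [breeding_config()].
#' @param chrom_lengths optional chromosome lengths in cM.
#' @return A [genotype_panel()] with extra elements `phenotype` (named
#'   vector), `genetic_value` and `truth` (the QTL model).
#' @export
run_program <- function(founders, qtl, map, config = breeding_config(),
                        chrom_lengths = NULL) {
  mc <- .map_codes(map, chrom_lengths)
  res <- .cpp_run_program(founders$haplotypes, mc$code, map$cm, mc$len,
                          as.integer(qtl$qtl_index - 1L), qtl$scaled_effect,
                          sqrt(qtl$residual_var), config$selection,
                          config$total_generations, config$burnin,
                          config$crosses_per_gen, config$rils_per_cross,
                          config$keep_per_cross, config$varieties_per_gen,
                          config$pool_min_back, config$pool_max_back)
  n <- length(res$year)
  vid <- sprintf("v%03d_y%02d", seq_len(n), res$year)
  G <- res$genotypes
  dimnames(G) <- list(vid, map$marker_id)
  pan <- genotype_panel(G, map,
                        data.frame(variety_id = vid, year = res$year,
                                   stringsAsFactors = FALSE))
  pan$phenotype <- stats::setNames(res$phenotype, vid)
  pan$genetic_value <- stats::setNames(res$genetic_value, vid)
  pan$truth <- qtl
  pan
}

#' Simulate a selected/unselected panel pair
#'
#' Convenience wrapper: one founder set and QTL model, then two program
#' runs sharing them, one with and one without selection.
#'
#' @param spec a [genome_spec()].
#' @param seed integer seed.
#' @param config base [breeding_config()] (its `selection` field is
#'   overridden for each member of the pair).
#' @param founder_persistence carrier-set persistence passed to
#'   [simulate_founders()].
#' @return list with `selected`, `unselected`, `map`, `qtl`, `founders`.
#' @export
simulate_panel_pair <- function(spec = genome_spec(), seed = 1L,
                                config = breeding_config(),
                                founder_persistence = 0.98) {
  set.seed(seed)
  map <- build_genome(spec)
  founders <- simulate_founders(map, persistence = founder_persistence)
  qtl <- assign_qtls(founders)
  cfg_s <- config; cfg_s$selection <- TRUE
  cfg_u <- config; cfg_u$selection <- FALSE
  sel <- run_program(founders, qtl, map, cfg_s,
                     chrom_lengths = spec$chrom_lengths_cm)
  uns <- run_program(founders, qtl, map, cfg_u,
                     chrom_lengths = spec$chrom_lengths_cm)
  list(selected = sel, unselected = uns, map = map, qtl = qtl,
       founders = founders)
}

#' Markers to exclude from scans of a simulated panel
#'
#' Mirrors the simulation-study filters: the QTL markers themselves and
#' any marker with squared correlation above `r2` to a QTL column in the
#' panel.
#'
#' @param panel simulated [genotype_panel()] with a `truth` element.
#' @param r2 exclusion threshold on squared correlation to any QTL.
#' @return integer vector of marker column indices to drop.
#' @export
qtl_linked_markers <- function(panel, r2 = 0.99) {
  qidx <- panel$truth$qtl_index
  G <- panel$genotypes
  qg <- G[, qidx, drop = FALSE]
  keepq <- apply(qg, 2, stats::sd) > 0
  out <- qidx
  if (any(keepq)) {
    cc <- suppressWarnings(stats::cor(G, qg[, keepq, drop = FALSE]))
    cc[is.na(cc)] <- 0
    linked <- which(apply(cc^2, 1, max) > r2)
    out <- union(out, linked)
  }
  sort(out)
}
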