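#' Construct a genotype panel
#'
#' A `genotype_panel` bundles an allele-count matrix (varieties x markers,
#' values 0/1/2 with `NA` allowed), a marker map and a variety metadata
#' table. It is the common input container for every scan in the package.
#'
#' @param genotypes numeric matrix of allele counts in \{0, 1, 2\} with
#'   varieties in rows and markers in columns; `NA` marks missing calls.
#'   Row names are variety ids, column names marker ids.
#' @param map data.frame with columns `marker_id`, `chrom`, `cm` and
#'   optionally `bp` (1-based physical position).
#' @param varieties data.frame with columns `variety_id`, `year` and
#'   optionally `country`.
#' @return An object of class `genotype_panel` with elements `genotypes`,
#'   `map` and `varieties`, markers ordered chromosome-then-cM and rows
#'   aligned to `varieties$variety_id`.
#' @export
genotype_panel <- function(genotypes, map, varieties) {
  genotypes <- as.matrix(genotypes)
  map <- as.data.frame(map)
  varieties <- as.data.frame(varieties)
  need_map <- c("marker_id", "chrom", "cm")
  if (!all(need_map %in% names(map)))
    stop("map must have columns: ", paste(need_map, collapse = ", "))
  if (!"bp" %in% names(map)) map$bp <- NA_integer_
  if (!all(c("variety_id", "year") %in% names(varieties)))
    stop("varieties must have columns variety_id, year")
  if (!"country" %in% names(varieties)) varieties$country <- NA_character_
  map$marker_id <- as.character(map$marker_id)
  map$chrom <- as.character(map$chrom)
  varieties$variety_id <- as.character(varieties$variety_id)

  if (anyDuplicated(map$marker_id))
    stop("duplicated marker ids in map")
  if (anyDuplicated(varieties$variety_id))
    stop("duplicated variety ids")
  if (!all(is.finite(map$cm)) || any(map$cm < 0))
    stop("cm positions must be finite and non-negative")
  if (!all(is.finite(varieties$year)))
    stop("year must be finite")

  if (is.null(colnames(genotypes)) || is.null(rownames(genotypes)))
    stop("genotypes must carry variety row names and marker column names")
  miss_m <- setdiff(map$marker_id, colnames(genotypes))
  if (length(miss_m))
    stop("alignment error: markers in map but not in genotypes: ",
         paste(utils::head(miss_m, 5), collapse = ", "))
  miss_v <- setdiff(varieties$variety_id, rownames(genotypes))
  if (length(miss_v))
    stop("alignment error: varieties in metadata but not in genotypes: ",
         paste(utils::head(miss_v, 5), collapse = ", "))

  # align by id, not file order; markers chromosome-then-cm (then bp)
  ord <- order(map$chrom, map$cm, map$bp, method = "radix")
  map <- map[ord, , drop = FALSE]
  rownames(map) <- NULL
  genotypes <- genotypes[varieties$variety_id, map$marker_id, drop = FALSE]

  bad <- which(!(genotypes %in% c(0, 1, 2) | is.na(genotypes)))
  if (length(bad)) {
    i <- ((bad[1] - 1) %% nrow(genotypes)) + 1
    j <- ((bad[1] - 1) %/% nrow(genotypes)) + 1
    stop(sprintf(
      "format error: genotype value %s at variety '%s', marker '%s' (allowed: 0/1/2/NA)",
      genotypes[bad[1]], rownames(genotypes)[i], colnames(genotypes)[j]))
  }
  structure(list(genotypes = genotypes, map = map, varieties = varieties),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d varieties x %d markers, %d chromosome(s), years %d-%d\n",
              nrow(x$genotypes), ncol(x$genotypes),
              length(unique(x$map$chrom)),
              min(x$varieties$year), max(x$varieties$year)))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$genotypes)

#' Read a genotype panel from tab-separated files
#'
#' @param genotype_path TSV with first column `variety_id` and one column
#'   per marker holding allele counts 0/1/2 (empty or NA for missing).
#' @param map_path TSV with columns `marker_id`, `chrom`, `cm` and
#'   optionally `bp`.
#' @param meta_path TSV with columns `variety_id`, `year` and optionally
#'   `country`.
#' @return A [genotype_panel()].
#' @export
read_panel <- function(genotype_path, map_path, meta_path) {
  for (p in c(genotype_path, map_path, meta_path))
    if (!file.exists(p)) stop("file not found: ", p)
  geno <- utils::read.delim(genotype_path, check.names = FALSE,
                            colClasses = NA, stringsAsFactors = FALSE)
  if (names(geno)[1] != "variety_id")
    stop("genotype file must start with a variety_id column")
  gm <- as.matrix(geno[, -1, drop = FALSE])
  storage.mode(gm) <- "double"
  rownames(gm) <- as.character(geno$variety_id)
  map <- utils::read.delim(map_path, stringsAsFactors = FALSE)
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  genotype_panel(gm, map, meta)
}

#' Import a genotype panel from a VCF
#'
#' Biallelic sites are converted to ALT-allele dosages (0/1/2, phase
#' ignored); other sites are skipped and counted. When no genetic map is
#' available, cM positions are approximated as bp / 1e6 and flagged.
#'
#' @param vcf_path path to a VCF (v4.x) with a GT field.
#' @param meta_path TSV of variety metadata as in [read_panel()].
#' @return A [genotype_panel()] with attribute `cm_approximate = TRUE` and
#'   attribute `skipped_sites` holding the non-biallelic count.
#' @export
import_vcf <- function(vcf_path, meta_path) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  alt <- fix[, "ALT"]
  biall <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) & nchar(alt) > 0
  n_skip <- sum(!biall)
  if (!any(biall)) stop("empty panel: VCF contains no biallelic sites")
  gt <- vcfR::extract.gt(v, element = "GT")[biall, , drop = FALSE]
  dose <- function(g) {
    ifelse(is.na(g) | g %in% c(".", "./.", ".|."), NA_real_,
           vapply(strsplit(gsub("\\|", "/", g), "/", fixed = TRUE),
                  function(a) sum(a == "1"), numeric(1)))
  }
  gm <- apply(gt, 2, dose)
  if (is.null(dim(gm))) gm <- matrix(gm, nrow = 1,
                                     dimnames = list(NULL, colnames(gt)))
  gm <- t(gm)  # varieties x markers
  id <- fix[biall, "ID"]
  id[is.na(id) | id == "."] <- paste0(fix[biall, "CHROM"], "_",
                                      fix[biall, "POS"])[is.na(id) | id == "."]
  colnames(gm) <- id
  map <- data.frame(marker_id = id,
                    chrom = fix[biall, "CHROM"],
                    cm = as.numeric(fix[biall, "POS"]) / 1e6,
                    bp = as.integer(fix[biall, "POS"]),
                    stringsAsFactors = FALSE)
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  pan <- genotype_panel(gm, map, meta)
  attr(pan, "cm_approximate") <- TRUE
  attr(pan, "skipped_sites") <- n_skip
  pan
}

#' Write a result table as TSV
#'
#' Deterministic column order (as given), floats at 6 significant digits.
#'
#' @param table nonempty data.frame.
#' @param path output path.
#' @export
write_results <- function(table, path) {
  table <- as.data.frame(table)
  if (nrow(table) == 0L) stop("refusing to write an empty table")
  num <- vapply(table, is.double, logical(1))
  table[num] <- lapply(table[num], signif, digits = 6)
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a genotype panel to three TSV files
#'
#' Inverse of [read_panel()]: writes the genotype matrix, marker map and
#' variety metadata.
#'
#' @param panel a [genotype_panel()].
#' @param genotype_path,map_path,meta_path output paths.
#' @export
write_panel <- function(panel, genotype_path, map_path, meta_path) {
  g <- data.frame(variety_id = rownames(panel$genotypes),
                  panel$genotypes, check.names = FALSE)
  utils::write.table(g, genotype_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_results(panel$map, map_path)
  utils::write.table(panel$varieties, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(panel)
}

#' Attach a trait table to the varieties of a panel
#'
#' @param panel a [genotype_panel()].
#' @param traits data.frame with a `variety_id` column and one numeric
#'   column per trait; ids must be a subset of the panel's varieties.
#' @return the trait matrix (varieties x traits) aligned to the panel rows,
#'   `NA` where a variety has no record.
#' @export
align_traits <- function(panel, traits) {
  traits <- as.data.frame(traits)
  if (!"variety_id" %in% names(traits)) stop("traits need a variety_id column")
  extra <- setdiff(traits$variety_id, panel$varieties$variety_id)
  if (length(extra))
    stop("trait table contains unknown varieties: ",
         paste(utils::head(extra, 5), collapse = ", "))
  tm <- as.matrix(traits[, setdiff(names(traits), "variety_id"), drop = FALSE])
  out <- matrix(NA_real_, nrow(panel$genotypes), ncol(tm),
                dimnames = list(rownames(panel$genotypes), colnames(tm)))
  out[match(traits$variety_id, rownames(out)), ] <- tm
  out
}
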