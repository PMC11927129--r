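#' Genotype panel: allele counts plus a SNP map
#'
#' Bundles an animals x SNPs matrix of allele counts (0, 1, 2, with `NA`
#' allowed for missing genotypes) with its SNP map. Columns follow map order;
#' the map must be sorted by chromosome with strictly increasing base-pair
#' position within each chromosome.
#'
#' @param counts Integer matrix, animals in rows, SNPs in columns; entries in
#'   `{0, 1, 2, NA}`.
#' @param map Data frame with columns `chromosome`, `snp_id`, `position`
#'   (1-based bp), one row per column of `counts`.
#' @param animal_ids Character vector of animal identifiers, one per row of
#'   `counts`; defaults to `rownames(counts)`.
#' @return An object of class `genotype_panel`: a list with elements `counts`
#'   (rownames = animal ids, colnames = SNP ids), `map` (tibble) and
#'   `animal_ids`.
#' @export
genotype_panel <- function(counts, map, animal_ids = rownames(counts)) {
  counts <- as.matrix(counts)
  map <- as_tibble(map)
  required <- c("chromosome", "snp_id", "position")
  if (!all(required %in% names(map))) {
    stop_gwablup("map must have columns %s", paste(required, collapse = ", "))
  }
  if (is.null(animal_ids)) {
    stop_gwablup("animal_ids are required (or set rownames on `counts`)")
  }
  animal_ids <- as.character(animal_ids)
  if (nrow(counts) != length(animal_ids)) {
    stop_gwablup("counts has %d rows but there are %d animal ids",
                 nrow(counts), length(animal_ids))
  }
  if (ncol(counts) != nrow(map)) {
    stop_gwablup("counts has %d columns but the map has %d SNPs",
                 ncol(counts), nrow(map))
  }
  if (anyDuplicated(animal_ids)) stop_gwablup("duplicated animal ids")
  if (anyDuplicated(map$snp_id)) stop_gwablup("duplicated snp ids in map")
  bad <- !(counts %in% c(0L, 1L, 2L) | is.na(counts))
  if (any(bad)) {
    stop_gwablup("allele counts must be 0, 1, 2 or NA (%d offending entries)",
                 sum(bad))
  }
  validate_map_sorted(map)
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(animal_ids, map$snp_id)
  structure(
    list(counts = counts, map = map, animal_ids = animal_ids),
    class = "genotype_panel"
  )
}

validate_map_sorted <- function(map) {
  # chromosome blocks must be contiguous and positions strictly increasing
  chrom <- as.character(map$chromosome)
  if (anyDuplicated(rle(chrom)$values)) {
    stop_gwablup("map chromosomes must form contiguous blocks")
  }
  by_chr <- split(map$position, factor(chrom, levels = unique(chrom)))
  for (nm in names(by_chr)) {
    pos <- by_chr[[nm]]
    if (length(pos) > 1 && any(diff(pos) <= 0)) {
      stop_gwablup("positions must be strictly increasing within chromosome %s", nm)
    }
  }
  invisible(map)
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("<genotype_panel> %d animals x %d SNPs on %d chromosome(s)\n",
              nrow(x$counts), ncol(x$counts),
              length(unique(x$map$chromosome))))
  n_miss <- sum(is.na(x$counts))
  if (n_miss > 0) cat(sprintf("  missing genotypes: %d\n", n_miss))
  invisible(x)
}

#' @export
dim.genotype_panel <- function(x) dim(x$counts)

#' Read and write genotype panels
#'
#' `read_genotypes()` reads an allele-count matrix plus its SNP map;
#' `write_genotypes()` writes them back in the `tsv_matrix` layout. Two input
#' layouts are supported: `tsv_matrix` (header row of SNP ids; one row per
#' animal: animal id then integer counts) and `plink_raw` (a PLINK
#' `--recode A`-style table with FID/IID leader columns and `_X`
#' allele-suffixed SNP columns). The map file is a TSV with columns
#' `chromosome`, `snp_id`, `position`.
#'
#' @param path Path to the genotype matrix file.
#' @param map_path Path to the SNP map TSV.
#' @param format `"tsv_matrix"` or `"plink_raw"`.
#' @return `read_genotypes()` returns a [genotype_panel()];
#'   `write_genotypes()` returns the panel invisibly.
#' @export
read_genotypes <- function(path, map_path, format = c("tsv_matrix", "plink_raw")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop_gwablup("genotype file not found: %s", path)
  if (!file.exists(map_path)) stop_gwablup("map file not found: %s", map_path)
  map <- readr::read_tsv(map_path, show_col_types = FALSE,
                         col_types = readr::cols(
                           chromosome = readr::col_character(),
                           snp_id = readr::col_character(),
                           position = readr::col_integer()))
  if (format == "tsv_matrix") {
    tab <- readr::read_tsv(path, show_col_types = FALSE,
                           col_types = readr::cols(
                             .default = readr::col_integer(),
                             animal_id = readr::col_character()))
    prob <- readr::problems(tab)
    if (nrow(prob) > 0) {
      stop_gwablup("malformed genotype file %s at line %d", path, prob$row[1] + 1L)
    }
    ids <- tab$animal_id
    counts <- as.matrix(tab[, setdiff(names(tab), "animal_id"), drop = FALSE])
  } else {
    tab <- readr::read_table(path, show_col_types = FALSE)
    leader <- intersect(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"), names(tab))
    ids <- as.character(tab$IID)
    counts <- as.matrix(tab[, setdiff(names(tab), leader), drop = FALSE])
    colnames(counts) <- sub("_[ACGT0-9]+$", "", colnames(counts))
  }
  if (!setequal(colnames(counts), map$snp_id)) {
    stop_gwablup("SNP ids in %s do not match the map", path)
  }
  counts <- counts[, map$snp_id, drop = FALSE]  # deterministic map order
  genotype_panel(counts, map, animal_ids = ids)
}

#' @param panel A [genotype_panel()].
#' @rdname read_genotypes
#' @export
write_genotypes <- function(panel, path, map_path) {
  stopifnot(inherits(panel, "genotype_panel"))
  tab <- as_tibble(panel$counts)
  tab <- dplyr::bind_cols(tibble(animal_id = panel$animal_ids), tab)
  readr::write_tsv(tab, path)
  readr::write_tsv(panel$map, map_path)
  invisible(panel)
}

#' Read and write phenotype tables
#'
#' Phenotype TSVs have one row per animal: `animal_id`, one numeric column per
#' trait (yield deviations), and a positive `weight` column holding the record
#' weight of the yield deviation (the model takes the residual covariance of
#' animal i as R / w_i).
#'
#' @param path File path.
#' @return A tibble with columns `animal_id`, the traits, and `weight`.
#' @export
read_phenotypes <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(animal_id = readr::col_character()))
  if (!all(c("animal_id", "weight") %in% names(tab))) {
    stop_gwablup("phenotype file must have animal_id and weight columns")
  }
  if (any(!is.finite(tab$weight)) || any(tab$weight <= 0)) {
    stop_gwablup("record weights must be positive")
  }
  tab
}

#' @param phenotypes Tibble as returned by `read_phenotypes()`.
#' @rdname read_phenotypes
#' @export
write_phenotypes <- function(phenotypes, path) {
  readr::write_tsv(phenotypes, path)
  invisible(phenotypes)
}

#' Read and write trait covariance matrices
#'
#' A covariance TSV is a square numeric table whose header row carries the
#' trait names (used for both G, the genetic covariance, and R, the residual
#' covariance).
#'
#' @param path File path.
#' @return `read_covariance()` returns a named symmetric matrix.
#' @export
read_covariance <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, col_types = readr::cols())
  S <- as.matrix(tab)
  rownames(S) <- colnames(S)
  assert_symmetric(S, "covariance", tol = 1e-6)
  S
}

#' @param S Square symmetric matrix with trait-name dimnames.
#' @rdname read_covariance
#' @export
write_covariance <- function(S, path) {
  readr::write_tsv(as_tibble(S), path)
  invisible(S)
}

#' Center genotypes on training allele frequencies
#'
#' Computes allele frequencies `p_j` from the reference (training) animals
#' only, drops SNPs monomorphic in the reference, imputes missing genotypes to
#' their mean `2 p_j`, and centers every animal's counts (training and
#' validation alike) by `2 p_j`. The returned `scale_sum` is
#' `sum(2 p_j (1 - p_j))` over retained SNPs, the divisor turning the trait
#' genetic covariance G into the per-SNP prior covariance.
#'
#' @param panel A [genotype_panel()].
#' @param reference_ids Animals whose genotypes define the allele frequencies;
#'   defaults to all animals. Must be non-empty and present in the panel.
#' @return An object of class `centered_genotypes`: list with `matrix`
#'   (all animals x retained SNPs, centered), `allele_freq`, `scale_sum`,
#'   `map` (retained SNPs), `reference_ids`, `n_dropped_monomorphic`,
#'   `n_imputed`.
#' @export
center_genotypes <- function(panel, reference_ids = panel$animal_ids) {
  stopifnot(inherits(panel, "genotype_panel"))
  reference_ids <- as.character(reference_ids)
  if (length(reference_ids) == 0) stop_gwablup("reference_ids must be non-empty")
  missing_ids <- setdiff(reference_ids, panel$animal_ids)
  if (length(missing_ids) > 0) {
    stop_gwablup("reference ids not in panel: %s",
                 paste(utils::head(missing_ids, 3), collapse = ", "))
  }
  ref <- panel$counts[match(reference_ids, panel$animal_ids), , drop = FALSE]
  p <- colMeans(ref, na.rm = TRUE) / 2
  poly <- is.finite(p) & p > 0 & p < 1
  n_dropped <- sum(!poly)
  if (n_dropped > 0) {
    message(sprintf("center_genotypes: dropped %d SNP(s) monomorphic in the reference set",
                    n_dropped))
  }
  p <- p[poly]
  X <- panel$counts[, poly, drop = FALSE]
  storage.mode(X) <- "double"
  n_imputed <- sum(is.na(X))
  X <- sweep(X, 2, 2 * p)   # centered; missing stay NA
  if (n_imputed > 0) {
    X[is.na(X)] <- 0        # mean imputation: 2 p_j before centering
    message(sprintf("center_genotypes: imputed %d missing genotype(s) to the mean",
                    n_imputed))
  }
  structure(
    list(matrix = X,
         allele_freq = p,
         scale_sum = sum(2 * p * (1 - p)),
         map = panel$map[poly, , drop = FALSE],
         reference_ids = reference_ids,
         n_dropped_monomorphic = n_dropped,
         n_imputed = n_imputed),
    class = "centered_genotypes"
  )
}

#' @export
print.centered_genotypes <- function(x, ...) {
  cat(sprintf("<centered_genotypes> %d animals x %d SNPs (scale_sum = %.4f, %d reference animals)\n",
              nrow(x$matrix), ncol(x$matrix), x$scale_sum, length(x$reference_ids)))
  invisible(x)
}

# rows of the centered matrix for a set of animals, in the given order
centered_rows <- function(centered, ids) {
  idx <- match(as.character(ids), rownames(centered$matrix))
  if (anyNA(idx)) stop_gwablup("animals not present in centered genotypes")
  centered$matrix[idx, , drop = FALSE]
}
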