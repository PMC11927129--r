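#' Run the full multitrait GWABLUP workflow
#'
#' Orchestrates the whole analysis on one data set: mask the validation
#' animals, center genotypes on the training animals, canonically transform
#' the training phenotypes, run the single-SNP scan, build the GWAS-derived
#' SNP weights, fit the multitrait SNP-BLUP under each requested weighting
#' scheme, predict the validation animals and score reliability, inflation
#' slope, and (for two or more schemes) bootstrap significance of the
#' reliability differences. Validation phenotypes are touched only in the
#' final scoring step.
#'
#' @param panel A [genotype_panel()].
#' @param phenotypes Tibble with `animal_id`, one column per trait, `weight`,
#'   and either a `cohort` column (`"training"` / `"validation"`) or none, in
#'   which case `validation_ids` must be given.
#' @param traits A [trait_model()].
#' @param schemes Weighting schemes to fit (any of `"unweighted"`,
#'   `"equal_weights"`, `"trait_specific"`).
#' @param validation_ids Animal ids to hold out; overrides the `cohort`
#'   column.
#' @param pi,half_window Weighting parameters (see [snp_weights()]).
#' @param epsilon,tolerance,max_iter Solver parameters (see [fit_snpblup()]).
#' @param n_boot,seed Bootstrap parameters (see [validate_predictions()]).
#' @return Object of class `gwablup_run`: list with `transform`, `gwas`,
#'   `weights`, `fits` (named list of [fit_snpblup()] results),
#'   `predictions` (named list of validation prediction matrices), `report`
#'   (a [validate_predictions()] result, `NULL` without validation animals),
#'   `training_ids`, `validation_ids`.
#' @export
run_gwablup <- function(panel, phenotypes, traits,
                        schemes = c("unweighted", "equal_weights", "trait_specific"),
                        validation_ids = NULL, pi = 0.001, half_window = 2,
                        epsilon = 0.01, tolerance = 1e-9, max_iter = 10000L,
                        n_boot = 10000L, seed = NULL) {
  stopifnot(inherits(panel, "genotype_panel"), inherits(traits, "trait_model"))
  schemes <- match.arg(schemes, several.ok = TRUE)
  phenotypes <- as_tibble(phenotypes)
  if (is.null(validation_ids)) {
    validation_ids <- if ("cohort" %in% names(phenotypes)) {
      phenotypes$animal_id[phenotypes$cohort == "validation"]
    } else character(0)
  }
  validation_ids <- as.character(validation_ids)
  training_ids <- setdiff(phenotypes$animal_id, validation_ids)
  if (length(training_ids) < 3) stop_gwablup("too few training animals")
  train <- phenotypes[match(training_ids, phenotypes$animal_id), , drop = FALSE]
  trait_names <- traits$trait_names
  if (!all(trait_names %in% names(phenotypes))) {
    stop_gwablup("phenotypes must contain the trait columns: %s",
                 paste(trait_names, collapse = ", "))
  }
  Y_train <- as_trait_matrix(train, trait_names)
  rownames(Y_train) <- train$animal_id
  w_train <- train$weight %||% rep(1, nrow(train))

  centered <- center_genotypes(panel, reference_ids = training_ids)
  transform <- canonical_transform(traits)
  Y_can <- transform_phenotypes(Y_train, transform)
  gwas <- single_snp_scan(centered, Y_can, record_weight = w_train)
  weights <- snp_weights(gwas, transform, pi = pi, half_window = half_window)

  fits <- purrr::map(stats::setNames(schemes, schemes), function(scheme) {
    prior <- build_prior(scheme, traits, centered$scale_sum, weights = weights)
    fit_snpblup(centered, Y_train, traits, prior, record_weight = w_train,
                epsilon = epsilon, tolerance = tolerance, max_iter = max_iter)
  })

  predictions <- NULL
  report <- NULL
  if (length(validation_ids) > 0) {
    predictions <- purrr::map(fits, predict, centered = centered,
                              animal_ids = validation_ids)
    val <- phenotypes[match(validation_ids, phenotypes$animal_id), , drop = FALSE]
    Y_val <- as_trait_matrix(val, trait_names)
    if (length(fits) >= 1) {
      report <- validate_predictions(Y_val, predictions, n_boot = n_boot,
                                     seed = seed)
    }
  }
  structure(
    list(transform = transform, gwas = gwas, weights = weights, fits = fits,
         predictions = predictions, report = report,
         training_ids = training_ids, validation_ids = validation_ids),
    class = "gwablup_run"
  )
}

#' @export
print.gwablup_run <- function(x, ...) {
  cat(sprintf("<gwablup_run> %d training / %d validation animals; schemes: %s\n",
              length(x$training_ids), length(x$validation_ids),
              paste(names(x$fits), collapse = ", ")))
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}

#' Tidy the validation metrics of a run
#'
#' @param x A `gwablup_run`.
#' @param ... Unused.
#' @return The per-scheme, per-trait metrics tibble (empty if the run had no
#'   validation animals).
#' @export
tidy.gwablup_run <- function(x, ...) {
  if (is.null(x$report)) return(tibble())
  x$report$metrics
}

#' One-row-per-scheme solver summary of a run
#'
#' @param x A `gwablup_run`.
#' @param ... Unused.
#' @return Tibble of [glance.gwablup_fit()] rows.
#' @export
glance.gwablup_run <- function(x, ...) {
  purrr::map_dfr(x$fits, glance)
}
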