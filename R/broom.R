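## broom-style accessors for fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a co-expression fit
#'
#' One row per transcript: module assignment joined with the module's
#' trait correlation and the transcript's kME when available.
#'
#' @param x A `coexpr_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.coexpr_fit <- function(x, ...) {
  out <- x$modules |>
    dplyr::left_join(dplyr::select(x$module_trait, "module", "trait_cor",
                                   "trait_p"),
                     by = "module")
  out
}

#' One-row summary of a co-expression fit
#'
#' @param x A `coexpr_fit`.
#' @param ... Unused.
#' @return A tibble with the soft threshold, its scale-free fit, module
#'   counts and grey (unassigned) size.
#' @export
glance.coexpr_fit <- function(x, ...) {
  tibble::tibble(
    n_transcripts = nrow(x$modules),
    n_modules = length(setdiff(unique(x$modules$module), "grey")),
    n_grey = sum(x$modules$module == "grey"),
    beta = x$params$beta,
    scale_free_r2 = x$soft_threshold$scale_free_r2,
    n_sig_trait_modules = sum(x$module_trait$sig)
  )
}

#' Tidy a ceRNA network
#'
#' @param x A `cerna_network`.
#' @param ... Unused.
#' @return The tested-pair tibble (`shared_mirnas` flattened to a
#'   comma-separated string).
#' @export
tidy.cerna_network <- function(x, ...) {
  dplyr::mutate(x$pairs,
                shared_mirnas = vapply(x$pairs$shared_mirnas, paste,
                                       character(1), collapse = ","))
}

#' One-row summary of a ceRNA network
#'
#' @param x A `cerna_network`.
#' @param ... Unused.
#' @return A tibble with pair, eTM and universe counts.
#' @export
glance.cerna_network <- function(x, ...) {
  tibble::tibble(
    n_tested = nrow(x$pairs),
    n_significant = sum(x$pairs$significant),
    n_etm_records = nrow(x$etms),
    n_etm_lncrna = dplyr::n_distinct(x$etms$lncrna_id),
    n_mirna_universe = x$n_universe
  )
}
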