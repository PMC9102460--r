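## Internal helpers shared across modules.

#' Build a balanced stage/replicate sample design
#'
#' Samples are named `S{stage}R{replicate}`, the naming convention used by
#' every expression table in the package.
#'
#' @param stages Number of developmental stages (>= 2).
#' @param replicates Biological replicates per stage.
#' @return A tibble with columns `sample`, `stage`, `replicate`.
#' @export
#' @examples
#' stage_design(5, 3)
stage_design <- function(stages = 5, replicates = 3) {
  stopifnot(stages >= 2, replicates >= 1)
  tidyr::expand_grid(stage = seq_len(stages), replicate = seq_len(replicates)) |>
    dplyr::mutate(sample = sprintf("S%dR%d", .data$stage, .data$replicate)) |>
    dplyr::select("sample", "stage", "replicate")
}

#' Recover a stage/replicate design from sample names
#'
#' Parses `S{stage}R{replicate}` sample identifiers back into a design table.
#'
#' @param samples Character vector of sample names.
#' @return A tibble with columns `sample`, `stage`, `replicate`.
#' @export
design_from_names <- function(samples) {
  ok <- grepl("^S[0-9]+R[0-9]+$", samples)
  if (!all(ok)) {
    abort(paste0(
      "sample names not in S{stage}R{replicate} form: ",
      paste(samples[!ok], collapse = ", ")
    ))
  }
  tibble::tibble(
    sample = samples,
    stage = as.integer(sub("^S([0-9]+)R.*$", "\\1", samples)),
    replicate = as.integer(sub("^S[0-9]+R([0-9]+)$", "\\1", samples))
  )
}

## Expression tables are tibbles: first column `transcript_id`, remaining
## columns one per sample. The measurement unit travels as attr "unit".

expr_samples <- function(expr) setdiff(names(expr), "transcript_id")

expr_matrix <- function(expr) {
  m <- as.matrix(expr[, expr_samples(expr), drop = FALSE])
  rownames(m) <- expr$transcript_id
  storage.mode(m) <- "double"
  m
}

expr_unit <- function(expr) attr(expr, "unit") %||% NA_character_

set_expr_unit <- function(expr, unit) {
  attr(expr, "unit") <- unit
  expr
}

resolve_design <- function(expr, design = NULL) {
  if (is.null(design)) design <- design_from_names(expr_samples(expr))
  missing <- setdiff(expr_samples(expr), design$sample)
  if (length(missing) > 0) {
    abort(paste0("samples absent from design: ", paste(missing, collapse = ", ")))
  }
  design
}

## Per-transcript stage means of a (transcripts x samples) matrix.
stage_means <- function(m, design) {
  stages <- sort(unique(design$stage))
  out <- vapply(stages, function(s) {
    cols <- design$sample[design$stage == s]
    rowMeans(m[, cols, drop = FALSE])
  }, numeric(nrow(m)))
  out <- matrix(out, nrow = nrow(m), ncol = length(stages),
                dimnames = list(rownames(m), paste0("S", stages)))
  out
}

## Stable numeric log-sum-exp.
logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (length(x) == 0) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}

## Adjusted Rand index between two label vectors (used by recovery checks).
adjusted_rand <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_comb <- function(x) sum(choose(x, 2))
  idx <- sum_comb(tab)
  row_c <- sum_comb(rowSums(tab))
  col_c <- sum_comb(colSums(tab))
  expected <- row_c * col_c / choose(n, 2)
  max_idx <- (row_c + col_c) / 2
  if (max_idx == expected) return(1)
  (idx - expected) / (max_idx - expected)
}
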