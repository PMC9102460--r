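## Consensus lncRNA/mRNA classification from four coding-potential
## evidence channels, plus transcript characterization and stage-presence
## profiling.

#' Voting thresholds for coding-potential consensus classification
#'
#' A channel votes "noncoding" when its score falls strictly below its
#' threshold (CPC < 0, CNCI < 0, txCdsPredict < 500, Pfam hit absent);
#' scores exactly at a threshold count as coding. A transcript is
#' confirmed as lncRNA (or mRNA) only when at least `votes_required` of
#' the four channels agree.
#'
#' @param cpc_cut,cnci_cut,txcds_cut Channel score thresholds.
#' @param votes_required Channel agreement needed to confirm a class
#'   (1-4).
#' @return A list of class `vote_thresholds`.
#' @export
vote_thresholds <- function(cpc_cut = 0, cnci_cut = 0, txcds_cut = 500,
                            votes_required = 3) {
  if (votes_required < 1 || votes_required > 4) {
    abort("vote_thresholds: `votes_required` must be between 1 and 4")
  }
  structure(list(cpc_cut = cpc_cut, cnci_cut = cnci_cut,
                 txcds_cut = txcds_cut, votes_required = votes_required),
            class = "vote_thresholds")
}

check_evidence <- function(evidence) {
  need <- c("transcript_id", "cpc_score", "cnci_score", "txcds_score",
            "pfam_hit")
  missing <- setdiff(need, names(evidence))
  if (length(missing) > 0) {
    abort(paste0("evidence table missing channel(s): ",
                 paste(missing, collapse = ", ")))
  }
  num <- evidence[, c("cpc_score", "cnci_score", "txcds_score")]
  if (anyNA(num) || anyNA(evidence$pfam_hit) ||
      !all(vapply(num, function(x) all(is.finite(x)), logical(1)))) {
    abort("evidence table has missing or non-finite channel values (no imputation)")
  }
  if (anyDuplicated(evidence$transcript_id)) {
    abort("evidence table must have one row per transcript")
  }
  invisible(evidence)
}

#' Consensus biotype vote from four evidence channels
#'
#' @param evidence Tibble with `transcript_id`, `cpc_score`, `cnci_score`,
#'   `txcds_score`, `pfam_hit` (one row per transcript, no missing
#'   channels).
#' @param thresholds A [vote_thresholds()].
#' @return The evidence tibble with `votes_noncoding` (0-4) and `biotype`
#'   (`lncRNA`, `mRNA` or `uncertain`) columns appended.
#' @export
#' @examples
#' ev <- tibble::tibble(transcript_id = "t1", cpc_score = -1,
#'                      cnci_score = -0.5, txcds_score = 300,
#'                      pfam_hit = TRUE)
#' vote_biotype(ev)$biotype  # 3 noncoding votes -> lncRNA
vote_biotype <- function(evidence, thresholds = vote_thresholds()) {
  check_evidence(evidence)
  stopifnot(inherits(thresholds, "vote_thresholds"))
  nc <- (evidence$cpc_score < thresholds$cpc_cut) +
    (evidence$cnci_score < thresholds$cnci_cut) +
    (evidence$txcds_score < thresholds$txcds_cut) +
    (!evidence$pfam_hit)
  v <- thresholds$votes_required
  evidence |>
    dplyr::mutate(
      votes_noncoding = as.integer(nc),
      biotype = dplyr::case_when(
        nc >= v ~ "lncRNA",
        (4 - nc) >= v ~ "mRNA",
        TRUE ~ "uncertain"
      )
    )
}

#' Retain lncRNA candidates strictly longer than a minimum length
#'
#' lncRNAs are defined as transcripts of more than `min_len` nucleotides,
#' so a transcript of exactly `min_len` is excluded.
#'
#' @param records Annotation tibble with a `length` column.
#' @param min_len Minimum length in nt (exclusive); default 200.
#' @return The filtered tibble.
#' @export
length_filter <- function(records, min_len = 200) {
  dplyr::filter(records, .data$length > min_len)
}

#' Assign consensus biotypes to an annotation
#'
#' Combines [vote_biotype()] with the lncRNA length rule: transcripts
#' voted lncRNA but not longer than `min_len` are set to `uncertain`.
#'
#' @param records Annotation tibble.
#' @param evidence Coding-potential evidence table.
#' @param thresholds A [vote_thresholds()].
#' @param min_len Minimum lncRNA length in nt (exclusive).
#' @return `records` with the `biotype` column filled in.
#' @export
assign_biotypes <- function(records, evidence,
                            thresholds = vote_thresholds(), min_len = 200) {
  votes <- vote_biotype(evidence, thresholds)
  missing <- setdiff(records$transcript_id, votes$transcript_id)
  if (length(missing) > 0) {
    abort(paste0("assign_biotypes: no evidence for ",
                 length(missing), " transcript(s)"))
  }
  records |>
    dplyr::mutate(
      biotype = votes$biotype[match(.data$transcript_id, votes$transcript_id)],
      biotype = dplyr::if_else(.data$biotype == "lncRNA" &
                                 .data$length <= min_len,
                               "uncertain", .data$biotype)
    )
}

#' Stage-presence profile of each transcript
#'
#' A transcript is present in a stage when its mean FPKM over that stage's
#' replicates reaches `floor`. Categories: `all-stages` (present in every
#' stage), `stage-specific` (exactly one stage), `partial` (more than one
#' but not all), `absent` (none).
#'
#' @param fpkm Expression tibble in FPKM (unit attribute checked when
#'   present).
#' @param floor Presence floor on the stage-mean FPKM; default 0.5.
#' @param design Optional design tibble.
#' @return A tibble: `transcript_id`, one logical `present_S*` column per
#'   stage, `n_stages_present`, `specific_stage` (NA unless
#'   stage-specific), `category`. The floor used is recorded as attribute
#'   `floor`.
#' @export
stage_presence <- function(fpkm, floor = 0.5, design = NULL) {
  unit <- expr_unit(fpkm)
  if (!is.na(unit) && unit == "counts") {
    abort("stage_presence: presence floor is defined on FPKM, not counts")
  }
  design <- resolve_design(fpkm, design)
  sm <- stage_means(expr_matrix(fpkm), design)
  present <- sm >= floor
  n_present <- rowSums(present)
  n_stages <- ncol(present)
  specific <- ifelse(n_present == 1, apply(present, 1, which.max), NA_integer_)
  out <- dplyr::bind_cols(
    tibble::tibble(transcript_id = fpkm$transcript_id),
    tibble::as_tibble(`colnames<-`(present, paste0("present_", colnames(sm))))
  ) |>
    dplyr::mutate(
      n_stages_present = as.integer(n_present),
      specific_stage = as.integer(specific),
      category = dplyr::case_when(
        n_present == n_stages ~ "all-stages",
        n_present == 1 ~ "stage-specific",
        n_present == 0 ~ "absent",
        TRUE ~ "partial"
      )
    )
  attr(out, "floor") <- floor
  out
}

#' Summarize a stage-presence profile
#'
#' @param presence Output of [stage_presence()].
#' @return A list with `categories` (counts per category), `by_stage`
#'   (stage-specific counts per stage), and `fractions`: percentage of
#'   transcripts present in all stages and its complement, rounded to 2
#'   decimals.
#' @export
presence_summary <- function(presence) {
  n <- nrow(presence)
  n_all <- sum(presence$category == "all-stages")
  list(
    categories = dplyr::count(presence, .data$category, name = "n"),
    by_stage = presence |>
      dplyr::filter(.data$category == "stage-specific") |>
      dplyr::count(stage = .data$specific_stage, name = "n"),
    fractions = tibble::tibble(
      n_transcripts = n,
      n_all_stages = n_all,
      pct_all_stages = round(100 * n_all / n, 2),
      pct_not_all_stages = round(100 * (n - n_all) / n, 2)
    )
  )
}

#' Characterize transcripts by biotype
#'
#' Summary tables contrasting lncRNAs and mRNAs: length distribution over
#' the bins 200-500 nt and > 500 nt (plus medians), exon-count
#' distribution, transcripts-per-gene distribution, and (when FPKM is
#' given) per-biotype expression level. Empty biotype classes yield empty
#' tables, not errors.
#'
#' @param records Annotation tibble with `biotype` assigned.
#' @param fpkm Optional FPKM expression tibble.
#' @return A list of tibbles: `lengths`, `exons`, `transcripts_per_gene`,
#'   and optionally `expression`. Bin edges are recorded as attribute
#'   `length_bins`.
#' @export
characterize <- function(records, fpkm = NULL) {
  lengths <- records |>
    dplyr::group_by(.data$biotype) |>
    dplyr::summarise(
      n = dplyr::n(),
      n_200_500 = sum(.data$length >= 200 & .data$length <= 500),
      n_above_500 = sum(.data$length > 500),
      median_length = median(.data$length),
      .groups = "drop"
    )
  exons <- records |>
    dplyr::count(.data$biotype, .data$n_exons, name = "n_transcripts")
  tpg <- records |>
    dplyr::count(.data$biotype, .data$gene_id, name = "n_transcripts") |>
    dplyr::count(.data$biotype, .data$n_transcripts, name = "n_genes")
  out <- list(lengths = lengths, exons = exons, transcripts_per_gene = tpg)
  if (!is.null(fpkm)) {
    m <- expr_matrix(fpkm)
    mean_fpkm <- rowMeans(m)
    out$expression <- records |>
      dplyr::mutate(mean_fpkm = mean_fpkm[match(.data$transcript_id,
                                                rownames(m))]) |>
      dplyr::filter(!is.na(.data$mean_fpkm)) |>
      dplyr::group_by(.data$biotype) |>
      dplyr::summarise(n = dplyr::n(),
                       median_fpkm = median(.data$mean_fpkm),
                       mean_fpkm = mean(.data$mean_fpkm),
                       .groups = "drop")
  }
  attr(out, "length_bins") <- c(200, 500, Inf)
  out
}
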