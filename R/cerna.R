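## ceRNA network inference: miRNA-target ingestion or seed-match
## prediction, hypergeometric shared-miRNA enrichment, FDR filtering and
## eTM designation.

#' Upper tail of the hypergeometric distribution
#'
#' \eqn{P(X \ge k)} for \eqn{X \sim} Hypergeometric(N, K, n): the number
#' of shared elements when a size-`n` set is drawn from a universe of `N`
#' containing `K` marked elements. Computed by log-space summation of
#' `lchoose` terms (numerically stable for any N), vectorized over `k`.
#'
#' @param k Observed overlap(s).
#' @param K Marked elements (miRNAs targeting the lncRNA).
#' @param n Draw size (miRNAs targeting the mRNA).
#' @param N Universe size.
#' @return \eqn{P(X \ge k)}, in \[0, 1\].
#' @export
#' @examples
#' hyper_tail(3, 4, 5, 10)  # 66/252
hyper_tail <- function(k, K, n, N) {
  stopifnot(length(K) == 1, length(n) == 1, length(N) == 1)
  if (K > N || n > N || K < 0 || n < 0 || N < 1) {
    abort("hyper_tail: need 0 <= K, n <= N")
  }
  j_lo <- max(0, n - (N - K))  # support minimum
  j_hi <- min(K, n)
  j <- j_lo:j_hi
  log_terms <- lchoose(K, j) + lchoose(N - K, n - j) - lchoose(N, n)
  ## suffix log-sum-exp: tail[i] = log P(X >= j[i])
  tail_log <- numeric(length(j))
  acc <- -Inf
  for (i in rev(seq_along(j))) {
    acc <- logsumexp(c(acc, log_terms[i]))
    tail_log[i] <- acc
  }
  vapply(k, function(ki) {
    if (ki <= j_lo) return(1)
    if (ki > j_hi) return(0)
    min(1, exp(tail_log[ki - j_lo + 1]))
  }, numeric(1))
}

target_sets <- function(targets) {
  split(targets$mirna_id, targets$transcript_id)
}

#' Shared-miRNA enrichment test for one lncRNA-mRNA pair
#'
#' The pair is tested only when the two transcripts share at least
#' `min_shared` miRNAs; otherwise it is returned untested (no p-value).
#' N is the miRNA universe of the table, K the miRNAs targeting the
#' lncRNA, n those targeting the mRNA, and p the hypergeometric upper
#' tail at the observed overlap.
#'
#' @param targets Interaction tibble (`mirna_id`, `transcript_id`,
#'   `score`); the universe is its distinct miRNA set (or attribute
#'   `mirna_universe` when present).
#' @param lncrna,mrna Transcript ids, both present in the table.
#' @param min_shared Minimum shared miRNAs to test (default 3).
#' @return A one-row tibble: `lncrna_id`, `mrna_id`, `shared_mirnas`
#'   (list-column), `k_shared`, `k_lnc`, `n_mrna`, `n_universe`,
#'   `tested`, `p`.
#' @export
shared_mirna_test <- function(targets, lncrna, mrna, min_shared = 3) {
  sets <- target_sets(targets)
  if (!lncrna %in% names(sets)) {
    abort(paste0("shared_mirna_test: ", lncrna, " absent from target table"))
  }
  if (!mrna %in% names(sets)) {
    abort(paste0("shared_mirna_test: ", mrna, " absent from target table"))
  }
  universe <- attr(targets, "mirna_universe") %||% unique(targets$mirna_id)
  shared <- intersect(sets[[lncrna]], sets[[mrna]])
  k <- length(shared)
  tested <- k >= min_shared
  tibble::tibble(
    lncrna_id = lncrna, mrna_id = mrna,
    shared_mirnas = list(sort(shared)), k_shared = k,
    k_lnc = length(sets[[lncrna]]), n_mrna = length(sets[[mrna]]),
    n_universe = length(universe), tested = tested,
    p = if (tested) hyper_tail(k, length(sets[[lncrna]]),
                               length(sets[[mrna]]), length(universe))
        else NA_real_
  )
}

#' Build the lncRNA-miRNA-mRNA ceRNA network
#'
#' All lncRNA x mRNA pairs sharing at least `min_shared` miRNAs are
#' tested for shared-miRNA enrichment; p-values are Benjamini-Hochberg
#' adjusted across all tested pairs (one family) and pairs with FDR at
#' most `fdr_max` are significant. Each significant pair expands into
#' one eTM record per shared miRNA.
#'
#' @param targets Interaction tibble (`mirna_id`, `transcript_id`,
#'   `score`).
#' @param lncrna_ids,mrna_ids Candidate transcript ids of each class.
#' @param min_shared Minimum shared miRNAs to test (default 3).
#' @param fdr_max FDR threshold (default 0.05).
#' @return An object of class `cerna_network`: list with `pairs` (all
#'   tested pairs with `p`, `fdr`, `significant`), `etms` (one row per
#'   (lncRNA, miRNA, mRNA) of each significant pair), `mirna_degree`
#'   (per-miRNA target counts: total = lncRNA + mRNA), and `n_universe`.
#' @export
build_network <- function(targets, lncrna_ids, mrna_ids, min_shared = 3,
                          fdr_max = 0.05) {
  universe <- attr(targets, "mirna_universe") %||% unique(targets$mirna_id)
  if (length(universe) == 0) abort("build_network: empty miRNA universe")
  lncrna_ids <- intersect(lncrna_ids, targets$transcript_id)
  mrna_ids <- intersect(mrna_ids, targets$transcript_id)

  ## incidence matrix (transcripts x miRNAs) for fast shared counts
  tx <- c(lncrna_ids, mrna_ids)
  sub <- targets[targets$transcript_id %in% tx, ]
  inc <- matrix(0L, length(tx), length(universe),
                dimnames = list(tx, universe))
  inc[cbind(match(sub$transcript_id, tx), match(sub$mirna_id, universe))] <- 1L
  shared_counts <- inc[lncrna_ids, , drop = FALSE] %*%
    t(inc[mrna_ids, , drop = FALSE])
  deg <- rowSums(inc)

  idx <- which(shared_counts >= min_shared, arr.ind = TRUE)
  pairs <- tibble::tibble(
    lncrna_id = lncrna_ids[idx[, 1]],
    mrna_id = mrna_ids[idx[, 2]],
    k_shared = as.integer(shared_counts[idx]),
    k_lnc = as.integer(deg[lncrna_ids[idx[, 1]]]),
    n_mrna = as.integer(deg[mrna_ids[idx[, 2]]]),
    n_universe = length(universe)
  )
  if (nrow(pairs) > 0) {
    pairs$shared_mirnas <- purrr::map2(pairs$lncrna_id, pairs$mrna_id,
                                       function(l, m) {
      sort(universe[inc[l, ] == 1L & inc[m, ] == 1L])
    })
    pairs$p <- purrr::pmap_dbl(
      list(pairs$k_shared, pairs$k_lnc, pairs$n_mrna),
      function(k, K, n) hyper_tail(k, K, n, length(universe))
    )
    pairs$fdr <- bh_adjust(pairs$p)
    pairs$significant <- pairs$fdr <= fdr_max
    pairs <- dplyr::arrange(pairs, .data$fdr, .data$lncrna_id, .data$mrna_id)
  } else {
    pairs$shared_mirnas <- list()
    pairs$p <- numeric(0)
    pairs$fdr <- numeric(0)
    pairs$significant <- logical(0)
  }

  sig <- pairs[pairs$significant, ]
  etms <- if (nrow(sig) > 0) {
    purrr::pmap_dfr(list(sig$lncrna_id, sig$mrna_id, sig$shared_mirnas,
                         sig$fdr),
                    function(l, m, shared, fdr) {
                      tibble::tibble(lncrna_id = l, mirna_id = shared,
                                     mrna_id = m, pair_fdr = fdr)
                    })
  } else {
    tibble::tibble(lncrna_id = character(0), mirna_id = character(0),
                   mrna_id = character(0), pair_fdr = numeric(0))
  }

  typed <- dplyr::bind_rows(
    tibble::tibble(transcript_id = lncrna_ids, type = "lncRNA"),
    tibble::tibble(transcript_id = mrna_ids, type = "mRNA")
  )
  mirna_degree <- sub |>
    dplyr::left_join(typed, by = "transcript_id") |>
    dplyr::group_by(.data$mirna_id) |>
    dplyr::summarise(
      n_total = dplyr::n(),
      n_lncrna = sum(.data$type == "lncRNA"),
      n_mrna = sum(.data$type == "mRNA"),
      .groups = "drop"
    )

  structure(list(pairs = pairs, etms = etms, mirna_degree = mirna_degree,
                 n_universe = length(universe),
                 params = list(min_shared = min_shared, fdr_max = fdr_max)),
            class = "cerna_network")
}

#' @export
print.cerna_network <- function(x, ...) {
  cat("<cerna_network> ", nrow(x$pairs), " tested pairs, ",
      sum(x$pairs$significant), " significant (FDR <= ", x$params$fdr_max,
      "), ", nrow(x$etms), " eTM records, universe of ", x$n_universe,
      " miRNAs\n", sep = "")
  invisible(x)
}

#' Predict miRNA targets by seed complementarity
#'
#' A stand-in for external target predictors when only sequences are at
#' hand: an interaction is recorded iff the reverse complement of the
#' miRNA seed (positions 2-8 from the 5' end) occurs in the transcript;
#' the score is the number of distinct match sites. RNA and DNA alphabets
#' are accepted (U and T are equivalent).
#'
#' @param mirnas Named character vector of miRNA sequences (>= 8 nt).
#' @param transcripts Named character vector of transcript sequences.
#' @return An interaction tibble (`mirna_id`, `transcript_id`, `score`)
#'   with the full miRNA set as attribute `mirna_universe`.
#' @export
seed_match_targets <- function(mirnas, transcripts) {
  if (is.null(names(mirnas)) || is.null(names(transcripts))) {
    abort("seed_match_targets: sequences must be named")
  }
  norm <- function(x, what) {
    x <- chartr("uU", "tT", toupper(x))
    bad <- grepl("[^ACGT]", x)
    if (any(bad)) {
      abort(paste0("seed_match_targets: invalid characters in ", what, " ",
                   names(x)[bad][1]))
    }
    x
  }
  mirnas <- norm(mirnas, "miRNA")
  transcripts <- norm(transcripts, "transcript")
  if (any(nchar(mirnas) < 8)) {
    abort("seed_match_targets: miRNAs must be at least 8 nt")
  }
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    abort("seed_match_targets requires the Biostrings package")
  }
  seeds <- substr(mirnas, 2, 8)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seeds)))
  tx_set <- Biostrings::DNAStringSet(transcripts)
  purrr::imap_dfr(rc, function(site, mid) {
    counts <- Biostrings::vcountPattern(site, tx_set)
    hit <- counts > 0
    tibble::tibble(mirna_id = mid, transcript_id = names(transcripts)[hit],
                   score = counts[hit])
  }) -> out
  attr(out, "mirna_universe") <- names(mirnas)
  out
}
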