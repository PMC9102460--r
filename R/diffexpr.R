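## Pairwise stage differential expression on counts, with the pooled
## two-proportion z-test, Benjamini-Hochberg adjustment, fold-change and
## adjusted-p filters, tallies/intersections and K-means profile
## clustering.

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin wrapper over [stats::p.adjust()] with input validation; kept as a
#' named operation because the DE filter is defined on adjusted p-values.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the original order.
#' @export
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
bh_adjust <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    abort("bh_adjust: p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Two-stage differential expression on pooled counts
#'
#' Replicates of each stage are pooled by summation into per-transcript
#' counts \eqn{C_a, C_b} with stage library sizes \eqn{N_a, N_b} (total
#' pooled counts). The statistic is the two-proportion z-test under the
#' pooled binomial null \eqn{\hat p = (C_a + C_b)/(N_a + N_b)}:
#' \deqn{z = (C_b/N_b - C_a/N_a) / \sqrt{\hat p (1-\hat p)(1/N_a + 1/N_b)}}
#' with a two-sided normal p-value and Benjamini-Hochberg adjustment
#' across all transcripts of the comparison. The fold change is computed
#' on pseudocounted proportions, \eqn{\log_2((C_b + c_0)/N_b) -
#' \log_2((C_a + c_0)/N_a)}; the pseudocount never enters the test. A
#' transcript is significant iff \eqn{|log2fc| \ge \log_2(fc_{min})} and
#' \eqn{p_{adj} \le \alpha}.
#'
#' @param counts Expression tibble of raw counts.
#' @param a,b Stage indices to compare (`b` relative to `a`).
#' @param design Optional design tibble.
#' @param fc_min Fold-change threshold (default 2).
#' @param alpha Adjusted p-value threshold (default 0.001).
#' @param pseudocount Pseudocount `c0` for the fold change only (default 1).
#' @return A tibble: `transcript_id`, `comparison`, `count_a`, `count_b`,
#'   `log2fc`, `z`, `p`, `p_adj`, `direction`, `significant`.
#' @export
de_test <- function(counts, a, b, design = NULL, fc_min = 2, alpha = 0.001,
                    pseudocount = 1) {
  unit <- expr_unit(counts)
  if (!is.na(unit) && unit != "counts") {
    abort("de_test: the test is defined on raw counts")
  }
  design <- resolve_design(counts, design)
  if (!a %in% design$stage) abort(paste0("de_test: stage ", a, " absent from design"))
  if (!b %in% design$stage) abort(paste0("de_test: stage ", b, " absent from design"))
  m <- expr_matrix(counts)
  ca <- unname(rowSums(m[, design$sample[design$stage == a], drop = FALSE]))
  cb <- unname(rowSums(m[, design$sample[design$stage == b], drop = FALSE]))
  na <- sum(ca)
  nb <- sum(cb)
  if (na == 0 || nb == 0) abort("de_test: zero library size in a pooled stage")

  log2fc <- log2((cb + pseudocount) / nb) - log2((ca + pseudocount) / na)
  phat <- (ca + cb) / (na + nb)
  se <- sqrt(phat * (1 - phat) * (1 / na + 1 / nb))
  z <- ifelse(se > 0, (cb / nb - ca / na) / se, 0)
  p <- 2 * pnorm(-abs(z))
  p_adj <- bh_adjust(p)
  tibble::tibble(
    transcript_id = rownames(m),
    comparison = sprintf("S%d_vs_S%d", a, b),
    count_a = ca, count_b = cb,
    log2fc = log2fc, z = z, p = p, p_adj = p_adj,
    direction = ifelse(log2fc > 0, "up", "down"),
    significant = abs(log2fc) >= log2(fc_min) & p_adj <= alpha
  )
}

#' Up/down tallies and intersections across comparisons
#'
#' @param results A DE result tibble (rows from one or more [de_test()]
#'   calls bound together; the `comparison` column distinguishes them).
#' @return A list with `tallies` (per comparison: significant, up, down
#'   counts and percentages rounded to 1 decimal) and `intersections`
#'   (for every non-empty subset of comparisons, the intersection
#'   cardinality `n_common` of significant sets and the exclusive Venn
#'   partition count `n_exclusive`).
#' @export
comparison_sets <- function(results) {
  comps <- unique(results$comparison)
  if (length(comps) == 0) abort("comparison_sets: no comparisons")
  tallies <- results |>
    dplyr::group_by(.data$comparison) |>
    dplyr::summarise(
      n_tested = dplyr::n(),
      n_sig = sum(.data$significant),
      n_up = sum(.data$significant & .data$direction == "up"),
      n_down = sum(.data$significant & .data$direction == "down"),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      up_pct = round(100 * .data$n_up / .data$n_sig, 1),
      down_pct = round(100 * .data$n_down / .data$n_sig, 1)
    )
  sig_sets <- lapply(comps, function(cc) {
    results$transcript_id[results$comparison == cc & results$significant]
  })
  names(sig_sets) <- comps
  subsets <- purrr::map(seq_len(2^length(comps) - 1), function(mask) {
    comps[bitwAnd(mask, 2^(seq_along(comps) - 1)) > 0]
  })
  intersections <- purrr::map_dfr(subsets, function(ss) {
    common <- Reduce(intersect, sig_sets[ss])
    others <- setdiff(comps, ss)
    excl <- if (length(others) > 0) {
      setdiff(common, Reduce(union, sig_sets[others]))
    } else {
      common
    }
    tibble::tibble(comparisons = paste(ss, collapse = "&"),
                   size = length(ss),
                   n_common = length(common),
                   n_exclusive = length(excl))
  })
  list(tallies = tallies, intersections = intersections)
}

## k-means++ seeding: first center uniform, then proportional to the
## squared distance to the nearest chosen center.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  d2 <- rowSums((x - matrix(x[centers[1], ], n, ncol(x), byrow = TRUE))^2)
  for (i in seq_len(k - 1)) {
    prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[i + 1] <- sample.int(n, 1, prob = prob)
    d2 <- pmin(d2, rowSums((x - matrix(x[centers[i + 1], ], n, ncol(x),
                                       byrow = TRUE))^2))
  }
  x[centers, , drop = FALSE]
}

#' K-means clustering of per-stage expression profiles
#'
#' Each transcript's profile is its per-stage mean of log2(FPKM + 1),
#' z-scored across stages (constant profiles are kept unscaled and
#' flagged). Euclidean K-means with k-means++ initialization is restarted
#' `nstart` times under the given seed and the solution with the lowest
#' total within-cluster sum of squares is kept; cluster labels are
#' renumbered by descending cluster size for determinism.
#'
#' @param fpkm FPKM expression tibble.
#' @param ids Transcript ids to cluster (e.g. the DEL set).
#' @param k Number of clusters (default 6).
#' @param design Optional design tibble.
#' @param seed Integer seed.
#' @param nstart Number of k-means++ restarts (default 50).
#' @return A tibble: `transcript_id`, `cluster`, `scaled` flag, and one
#'   `profile_S*` column per stage; cluster centers as attribute
#'   `centers`.
#' @export
kmeans_profiles <- function(fpkm, ids, k = 6, design = NULL, seed = 1,
                            nstart = 50) {
  if (length(ids) == 0) abort("kmeans_profiles: empty transcript set")
  missing <- setdiff(ids, fpkm$transcript_id)
  if (length(missing) > 0) {
    abort(paste0("kmeans_profiles: ids absent from expression: ",
                 paste(head(missing, 3), collapse = ", ")))
  }
  if (k > length(ids)) abort("kmeans_profiles: k exceeds number of transcripts")
  design <- resolve_design(fpkm, design)
  m <- expr_matrix(fpkm)[ids, , drop = FALSE]
  prof <- stage_means(log2(m + 1), design)
  sds <- apply(prof, 1, sd)
  scaled <- sds > 0
  zprof <- prof
  zprof[scaled, ] <- t(scale(t(prof[scaled, , drop = FALSE])))

  set.seed(seed)
  best <- NULL
  for (r in seq_len(nstart)) {
    centers <- kmeanspp_centers(zprof, k)
    fit <- suppressWarnings(
      kmeans(zprof, centers = centers, iter.max = 100, algorithm = "Lloyd")
    )
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  ## renumber by descending size (ties by smallest original label)
  sizes <- tabulate(best$cluster, nbins = k)
  remap <- integer(k)
  remap[order(-sizes, seq_len(k))] <- seq_len(k)
  out <- dplyr::bind_cols(
    tibble::tibble(transcript_id = ids,
                   cluster = remap[best$cluster],
                   scaled = scaled),
    tibble::as_tibble(`colnames<-`(zprof, paste0("profile_", colnames(zprof))))
  )
  centers <- best$centers[order(-sizes, seq_len(k)), , drop = FALSE]
  rownames(centers) <- seq_len(k)
  attr(out, "centers") <- centers
  out
}
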