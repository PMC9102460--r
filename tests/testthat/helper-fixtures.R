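# Shared fixtures and independent oracles.

.cache <- new.env(parent = emptyenv())

# Default synthetic study, generated once per test run.
default_study <- function() {
  if (is.null(.cache$study)) {
    .cache$study <- generate_receptacle_study(synth_config(seed = 101))
  }
  .cache$study
}

# Module-recovery fixture: only the three planted modules carry signal.
module_study <- function() {
  if (is.null(.cache$module_study)) {
    .cache$module_study <- generate_receptacle_study(synth_config(
      de_fraction = 0, frac_stage_specific = 0, frac_cis_lnc = 0,
      n_etm = 0, seed = 202
    ))
  }
  .cache$module_study
}

small_config <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(n_coding_genes = 60, n_lncrna = 40, n_mirna = 20,
         n_planted_modules = 1, planted_module_sizes = 12,
         n_etm = 2, seed = seed),
    list(...)
  )
  do.call(synth_config, args)
}

# Brute-force BH step-up, written directly from the definition.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    rank_i <- which(ord == i)
    cands <- vapply(rank_i:m, function(r) m * p[ord[r]] / r, numeric(1))
    q[i] <- min(1, min(cands))
  }
  q
}

# Hypergeometric upper tail by direct term summation with choose().
hyper_oracle <- function(k, K, n, N) {
  j_hi <- min(K, n)
  if (k > j_hi) return(0)
  j <- max(k, max(0, n - (N - K))):j_hi
  sum(choose(K, j) * choose(N - K, n - j)) / choose(N, n)
}

# TOM by the O(n^3) triple loop.
tom_oracle <- function(a) {
  n <- nrow(a)
  k <- rowSums(a)
  w <- matrix(1, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    l <- sum(a[i, ] * a[, j]) - a[i, i] * a[i, j] - a[i, j] * a[j, j]
    w[i, j] <- (l + a[i, j]) / (min(k[i], k[j]) + 1 - a[i, j])
  }
  w
}

# Cis-window candidates by checking every (lncRNA, gene) pair.
window_oracle <- function(lncrnas, genes, up_bp = 10000, down_bp = 20000) {
  out <- list()
  for (i in seq_len(nrow(lncrnas))) for (j in seq_len(nrow(genes))) {
    if (lncrnas$chrom[i] != genes$chrom[j]) next
    ls <- lncrnas$start[i]; le <- lncrnas$end[i]
    gs <- genes$start[j]; ge <- genes$end[j]
    gap <- max(0, gs - le, ls - ge)
    if (gap == 0) {
      rel <- "overlapping"
    } else if ((genes$strand[j] == "+") == (le <= gs)) {
      rel <- "upstream"
    } else {
      rel <- "downstream"
    }
    hit <- rel == "overlapping" ||
      (rel == "upstream" && gap <= up_bp) ||
      (rel == "downstream" && gap <= down_bp)
    if (hit) {
      out[[length(out) + 1]] <- tibble::tibble(
        lncrna_id = lncrnas$transcript_id[i], gene_id = genes$gene_id[j],
        relation = rel,
        signed_distance = as.integer(if (rel == "upstream") -gap else gap)
      )
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(lncrna_id = character(0), gene_id = character(0),
                          relation = character(0),
                          signed_distance = integer(0)))
  }
  dplyr::arrange(dplyr::bind_rows(out), lncrna_id, gene_id)
}

# Random interval fixture for the window sweep/oracle comparison.
random_loci <- function(n_genes, n_lnc, n_chrom = 2, span = 2e5) {
  g <- tibble::tibble(
    gene_id = paste0("g", seq_len(n_genes)),
    chrom = paste0("chr", sample(n_chrom, n_genes, replace = TRUE)),
    start = sample.int(span, n_genes),
    strand = sample(c("+", "-"), n_genes, replace = TRUE)
  )
  g$end <- g$start + sample(500:20000, n_genes, replace = TRUE)
  l <- tibble::tibble(
    transcript_id = paste0("l", seq_len(n_lnc)),
    chrom = paste0("chr", sample(n_chrom, n_lnc, replace = TRUE)),
    start = sample.int(span, n_lnc),
    strand = sample(c("+", "-"), n_lnc, replace = TRUE)
  )
  l$end <- l$start + sample(200:2000, n_lnc, replace = TRUE)
  list(genes = g, lncrnas = l)
}

# Expression tibble from a plain matrix.
expr_from_matrix <- function(m, unit = "FPKM") {
  out <- dplyr::bind_cols(tibble::tibble(transcript_id = rownames(m)),
                          tibble::as_tibble(m))
  attr(out, "unit") <- unit
  out
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
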