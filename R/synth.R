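## Synthetic receptacle-study generator.
##
## Emulates the structure of a 5-stage x 3-replicate thermogenic receptacle
## RNA-seq design with planted ground truth: known lncRNA/mRNA biotypes,
## stage-specific transcripts, differential-expression sets, trait-tracking
## co-expression modules, cis lncRNA-gene pairs, and eTM triples. Every
## downstream module of the pipeline can be exercised against this truth.

#' Configuration for the synthetic receptacle study
#'
#' Defaults describe the emulated study conditions: five developmental
#' stages with three biological replicates, a receptacle temperature trend
#' peaking at stage 3, lncRNAs mostly 200-500 nt and single-exon, mRNAs
#' mostly above 500 nt, and planted regulatory structure at scales chosen
#' for desk-scale recovery analysis.
#'
#' @param n_coding_genes Number of protein-coding genes.
#' @param n_lncrna Number of lncRNA loci (one transcript each).
#' @param n_mirna Number of miRNAs in the interaction universe.
#' @param stages Number of developmental stages (>= 2).
#' @param replicates Biological replicates per stage.
#' @param frac_stage_specific Fraction of lncRNAs expressed in exactly one
#'   stage.
#' @param n_planted_modules Number of planted co-expression modules.
#' @param planted_module_sizes Integer vector of module sizes (length
#'   `n_planted_modules`).
#' @param de_fraction Fraction of transcripts planted as differentially
#'   expressed between stage 1 and one later stage.
#' @param de_log2fc Planted absolute log2 fold change.
#' @param dispersion Negative-binomial overdispersion of counts; 0 gives
#'   Poisson (pure count-sampling) noise.
#' @param library_size_mean Expected per-sample library size (total counts).
#' @param seed Integer seed; all four generators are deterministic given it.
#' @param n_chrom Number of chromosomes.
#' @param lncrna_short_frac Fraction of lncRNAs with length in \[200, 500\] nt.
#' @param frac_cis_lnc Fraction of lncRNAs planted inside the cis window of a
#'   coding gene, with correlated expression.
#' @param n_etm Number of planted eTM lncRNA-miRNA-mRNA triples.
#' @param channel_error Length-4 numeric: per-channel error rate of the
#'   coding-potential evidence (cpc, cnci, txcds, pfam).
#' @param mirna_bg_density Background density of miRNA-transcript
#'   interactions (probability per miRNA x transcript pair).
#' @param trait Per-stage receptacle temperature trend (degrees C); length
#'   must equal `stages`.
#' @return A validated list of class `synth_config`.
#' @export
#' @examples
#' cfg <- synth_config(n_coding_genes = 50, n_lncrna = 30, seed = 1)
synth_config <- function(n_coding_genes = 600,
                         n_lncrna = 400,
                         n_mirna = 60,
                         stages = 5,
                         replicates = 3,
                         frac_stage_specific = 0.10,
                         n_planted_modules = 3,
                         planted_module_sizes = c(40, 60, 80),
                         de_fraction = 0.10,
                         de_log2fc = 2,
                         dispersion = 0.05,
                         library_size_mean = 5e5,
                         seed = 1,
                         n_chrom = 8,
                         lncrna_short_frac = 0.80,
                         frac_cis_lnc = 0.15,
                         n_etm = 5,
                         channel_error = c(cpc = 0.05, cnci = 0.05,
                                           txcds = 0.05, pfam = 0.05),
                         mirna_bg_density = 0.005,
                         trait = c(18, 30, 35, 30, 20)) {
  cfg <- list(
    n_coding_genes = n_coding_genes, n_lncrna = n_lncrna, n_mirna = n_mirna,
    stages = stages, replicates = replicates,
    frac_stage_specific = frac_stage_specific,
    n_planted_modules = n_planted_modules,
    planted_module_sizes = planted_module_sizes,
    de_fraction = de_fraction, de_log2fc = de_log2fc,
    dispersion = dispersion, library_size_mean = library_size_mean,
    seed = seed, n_chrom = n_chrom, lncrna_short_frac = lncrna_short_frac,
    frac_cis_lnc = frac_cis_lnc, n_etm = n_etm,
    channel_error = channel_error, mirna_bg_density = mirna_bg_density,
    trait = trait
  )
  counts <- c("n_coding_genes", "n_lncrna", "n_mirna", "replicates",
              "n_chrom", "library_size_mean")
  for (f in counts) {
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0) {
      abort(paste0("synth_config: `", f, "` must be a positive count"))
    }
  }
  if (stages < 2) abort("synth_config: `stages` must be >= 2")
  for (f in c("frac_stage_specific", "de_fraction", "lncrna_short_frac",
              "frac_cis_lnc", "mirna_bg_density")) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) {
      abort(paste0("synth_config: `", f, "` must lie in [0, 1]"))
    }
  }
  if (any(channel_error < 0) || any(channel_error > 1) ||
      length(channel_error) != 4) {
    abort("synth_config: `channel_error` must be 4 rates in [0, 1]")
  }
  if (de_log2fc <= 0) abort("synth_config: `de_log2fc` must be positive")
  if (dispersion < 0) abort("synth_config: `dispersion` must be >= 0")
  if (length(planted_module_sizes) != n_planted_modules) {
    abort("synth_config: `planted_module_sizes` length must equal `n_planted_modules`")
  }
  if (n_planted_modules > stages - 1) {
    abort("synth_config: at most `stages` - 1 mutually distinguishable modules can be planted")
  }
  if (length(trait) != stages) {
    abort("synth_config: `trait` length must equal `stages`")
  }
  if (abs(seed) >= 2^31 - 16) abort("synth_config: `seed` out of integer range")
  structure(cfg, class = "synth_config")
}

## Stage profiles for M planted modules: columns are mutually orthogonal,
## unit-sd vectors whose correlation with the standardized trait is exactly
## 1/sqrt(M) (module signs are applied by the caller). M = 1 returns the
## trait profile itself.
module_profiles <- function(trait, M) {
  S <- length(trait)
  z <- as.numeric(scale(trait))
  if (M == 1) return(matrix(z, ncol = 1))
  stopifnot(M <= S - 1)
  base <- cbind(z, stats::poly(seq_len(S), M - 1))
  Q <- qr.Q(qr(base))
  if (sum(Q[, 1] * z) < 0) Q <- -Q
  H <- qr.Q(qr(cbind(rep(1, M), diag(M)[, seq_len(M - 1), drop = FALSE])))
  if (H[1, 1] < 0) H <- -H
  V <- Q %*% t(H)
  scale(V, center = TRUE, scale = apply(V, 2, sd))
}

## Split a total exonic length into n parts of >= 30 nt each.
split_exons <- function(total, n) {
  if (n == 1) return(total)
  if (total < 30 * n) n <- max(1L, total %/% 30L)
  if (n == 1) return(total)
  w <- runif(n, 0.5, 1.5)
  parts <- floor(total * w / sum(w))
  parts[1] <- parts[1] + (total - sum(parts))
  pmax(parts, 30L)
}

## Lay out exon intervals (0-based half-open) from a genomic start.
layout_exons <- function(start, exon_lens) {
  n <- length(exon_lens)
  introns <- if (n > 1) round(runif(n - 1, 60, 1500)) else integer(0)
  starts <- start + c(0, cumsum(exon_lens[-n] + introns))
  tibble::tibble(start = as.integer(starts),
                 end = as.integer(starts + exon_lens))
}

#' Generate a synthetic transcript annotation with planted ground truth
#'
#' Coding genes (mostly multi-exon, lengths mostly > 500 nt, occasionally
#' multiple isoforms) and lncRNA loci (mostly single-exon, 200-500 nt) are
#' laid out on `n_chrom` chromosomes with wide intergenic gaps, so that the
#' only lncRNAs inside a coding gene's cis window are the planted ones.
#' All regulatory ground truth (biotypes, stage-specific set, DE sets,
#' module membership, cis pairs, eTM triples) is decided here and consumed
#' by the other generators.
#'
#' @param config A [synth_config()].
#' @return A list with `annotation` (tibble of transcripts: `transcript_id`,
#'   `gene_id`, `chrom`, `start`, `end` (0-based half-open), `strand`,
#'   `length`, `n_exons`, `exons` list-column, `biotype = "unset"`) and
#'   `truth` (list of class `ground_truth`).
#' @export
generate_annotation <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)

  ## --- coding transcripts ------------------------------------------------
  gene_ids <- sprintf("GENE%05d", seq_len(config$n_coding_genes))
  n_tx_per_gene <- sample(1:3, config$n_coding_genes, replace = TRUE,
                          prob = c(0.80, 0.15, 0.05))
  coding <- purrr::map2_dfr(gene_ids, n_tx_per_gene, function(g, k) {
    tibble::tibble(
      gene_id = g,
      transcript_id = sprintf("%s.t%d", g, seq_len(k)),
      length = pmax(250L, as.integer(round(rlnorm(k, log(1500), 0.7)))),
      n_exons = 1L + rpois(k, 2),
      class = "mRNA"
    )
  })

  ## --- lncRNA transcripts ------------------------------------------------
  lnc_ids <- sprintf("LNC%05d", seq_len(config$n_lncrna))
  short <- runif(config$n_lncrna) < config$lncrna_short_frac
  lnc <- tibble::tibble(
    gene_id = sprintf("LNCG%05d", seq_len(config$n_lncrna)),
    transcript_id = lnc_ids,
    length = as.integer(ifelse(short,
                               sample(201:500, config$n_lncrna, replace = TRUE),
                               sample(501:2000, config$n_lncrna, replace = TRUE))),
    n_exons = ifelse(runif(config$n_lncrna) < 0.85, 1L, 2L),
    class = "lncRNA"
  )

  ## --- ground-truth planting --------------------------------------------
  n_cis <- min(round(config$frac_cis_lnc * config$n_lncrna),
               config$n_coding_genes)
  n_ss <- round(config$frac_stage_specific * config$n_lncrna)
  lnc_pool <- sample(lnc_ids)
  cis_lnc <- lnc_pool[seq_len(n_cis)]
  lnc_pool <- setdiff(lnc_pool, cis_lnc)
  ss_lnc <- lnc_pool[seq_len(n_ss)]
  lnc_pool <- setdiff(lnc_pool, ss_lnc)

  cis_hosts <- sample(gene_ids, n_cis)
  cis_pairs <- tibble::tibble(lncrna_id = cis_lnc, gene_id = cis_hosts)
  host_tx <- coding$transcript_id[coding$gene_id %in% cis_hosts]

  ## modules mix lncRNAs (~30%) and coding transcripts (~70%)
  mod_tbl <- tibble::tibble(transcript_id = character(0),
                            module = integer(0), sign = integer(0))
  mrna_pool <- sample(setdiff(coding$transcript_id, host_tx))
  if (config$n_planted_modules > 0) {
    for (m in seq_len(config$n_planted_modules)) {
      size <- config$planted_module_sizes[m]
      n_l <- min(round(0.3 * size), length(lnc_pool))
      n_m <- size - n_l
      if (n_m > length(mrna_pool)) {
        abort("generate_annotation: not enough transcripts for planted modules")
      }
      members <- c(lnc_pool[seq_len(n_l)], mrna_pool[seq_len(n_m)])
      if (n_l > 0) lnc_pool <- lnc_pool[-seq_len(n_l)]
      if (n_m > 0) mrna_pool <- mrna_pool[-seq_len(n_m)]
      mod_tbl <- dplyr::bind_rows(mod_tbl, tibble::tibble(
        transcript_id = members, module = m,
        sign = if (m %% 2 == 1) 1L else -1L
      ))
    }
  }

  ## DE planting over remaining free transcripts
  free <- c(lnc_pool, mrna_pool)
  n_de <- round(config$de_fraction * (nrow(coding) + nrow(lnc)))
  n_de <- min(n_de, length(free))
  de_ids <- sample(free, n_de)
  de_tbl <- tibble::tibble(
    transcript_id = de_ids,
    comparison = sprintf("S1_vs_S%d",
                         (2:config$stages)[sample.int(config$stages - 1,
                                                      n_de, replace = TRUE)]),
    direction = sample(c("up", "down"), n_de, replace = TRUE)
  )

  ## eTM triples: each pair shares 3-5 miRNAs
  free_lnc <- setdiff(lnc_pool, de_ids)
  free_mrna <- setdiff(mrna_pool, de_ids)
  n_etm <- min(config$n_etm, length(free_lnc), length(free_mrna))
  mirna_ids <- sprintf("miR%03d", seq_len(config$n_mirna))
  etm <- tibble::tibble(lncrna_id = character(0), mirna_id = character(0),
                        mrna_id = character(0))
  if (n_etm > 0) {
    el <- sample(free_lnc, n_etm)
    em <- sample(free_mrna, n_etm)
    etm <- purrr::map_dfr(seq_len(n_etm), function(i) {
      shared <- sample(mirna_ids, sample(3:5, 1))
      tibble::tibble(lncrna_id = el[i], mirna_id = shared, mrna_id = em[i])
    })
  }

  ## --- genomic layout ----------------------------------------------------
  all_tx <- dplyr::bind_rows(coding, lnc)
  all_tx$strand <- sample(c("+", "-"), nrow(all_tx), replace = TRUE)
  ## one strand per gene
  all_tx <- all_tx |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::mutate(strand = .data$strand[1]) |>
    dplyr::ungroup()

  gene_order <- unique(all_tx$gene_id)
  cis_set <- setNames(cis_pairs$gene_id, cis_pairs$lncrna_id)
  ## cis lncRNA loci are positioned relative to their host, all others
  ## sequentially with >= 50 kb gaps
  seq_genes <- setdiff(gene_order, all_tx$gene_id[all_tx$transcript_id %in% cis_lnc])
  chrom_of <- setNames(sample(seq_len(config$n_chrom), length(seq_genes),
                              replace = TRUE), seq_genes)
  cursor <- rep(10000L, config$n_chrom)

  rows <- vector("list", nrow(all_tx))
  gene_span <- list()
  for (g in seq_genes) {
    idx <- which(all_tx$gene_id == g)
    ch <- chrom_of[[g]]
    gstart <- cursor[ch]
    ends <- integer(0)
    for (i in idx) {
      lens <- split_exons(all_tx$length[i], all_tx$n_exons[i])
      ex <- layout_exons(gstart, lens)
      rows[[i]] <- list(start = min(ex$start), end = max(ex$end), exons = ex,
                        chrom = paste0("chr", ch),
                        length = as.integer(sum(ex$end - ex$start)),
                        n_exons = nrow(ex))
      ends <- c(ends, max(ex$end))
    }
    gene_span[[g]] <- c(gstart, max(ends), ch)
    cursor[ch] <- as.integer(max(ends) + round(runif(1, 50000, 80000)))
  }

  ## place cis lncRNAs inside their host's strand-aware window
  for (l in cis_lnc) {
    i <- which(all_tx$transcript_id == l)
    host <- cis_set[[l]]
    sp <- gene_span[[host]]
    host_strand <- all_tx$strand[match(host, all_tx$gene_id)][1]
    lens <- split_exons(all_tx$length[i], all_tx$n_exons[i])
    span <- sum(lens) + (length(lens) - 1) * 800  # generous span bound
    upstream <- runif(1) < 0.5
    gap <- if (upstream) round(runif(1, 500, 8000)) else round(runif(1, 500, 17000))
    left <- if ((host_strand == "+") == upstream) {
      sp[1] - gap - span  # 5' side of a + gene / 3' side handled below
    } else {
      sp[2] + gap
    }
    ex <- layout_exons(max(0L, as.integer(left)), lens)
    rows[[i]] <- list(start = min(ex$start), end = max(ex$end), exons = ex,
                      chrom = paste0("chr", sp[3]),
                      length = as.integer(sum(ex$end - ex$start)),
                      n_exons = nrow(ex))
  }

  annotation <- all_tx |>
    dplyr::mutate(
      chrom = purrr::map_chr(rows, "chrom"),
      start = as.integer(purrr::map_dbl(rows, "start")),
      end = as.integer(purrr::map_dbl(rows, "end")),
      length = as.integer(purrr::map_dbl(rows, "length")),
      n_exons = as.integer(purrr::map_dbl(rows, "n_exons")),
      exons = purrr::map(rows, "exons"),
      biotype = "unset"
    ) |>
    dplyr::select("transcript_id", "gene_id", "chrom", "start", "end",
                  "strand", "length", "n_exons", "biotype", "exons")

  stage_specific <- tibble::tibble(
    transcript_id = ss_lnc,
    stage = if (n_ss > 0) sample(seq_len(config$stages), n_ss, replace = TRUE)
            else integer(0)
  )

  truth <- structure(list(
    biotype = tibble::tibble(transcript_id = all_tx$transcript_id,
                             biotype = all_tx$class),
    stage_specific = stage_specific,
    de = de_tbl,
    modules = mod_tbl,
    cis_pairs = cis_pairs,
    etm_triples = etm,
    mirna_universe = mirna_ids
  ), class = "ground_truth")

  list(annotation = annotation, truth = truth)
}

#' Generate count and FPKM matrices plus the temperature trait
#'
#' Counts follow a negative-binomial model with stage-dependent means:
#' planted DE transcripts are shifted by `de_log2fc` between stage 1 and
#' their target stage, planted modules follow (or mirror, for
#' negative-sign modules) the standardized temperature trend, planted cis
#' pairs share a random stage profile with their host gene, and
#' stage-specific transcripts have non-background expression in exactly
#' one stage. FPKM is `1e9 * count / (length * library_size)` with the
#' per-sample library size taken as the column total.
#'
#' @param annotation,truth Output of [generate_annotation()].
#' @param config The same [synth_config()].
#' @return A list with `counts` and `fpkm` expression tibbles
#'   (`transcript_id` + `S{stage}R{rep}` columns, unit attribute set),
#'   `trait` (tibble `stage`, `temperature`) and `design`.
#' @export
generate_expression <- function(annotation, truth, config) {
  stopifnot(inherits(config, "synth_config"), inherits(truth, "ground_truth"))
  if (!all(truth$biotype$transcript_id %in% annotation$transcript_id)) {
    abort("generate_expression: truth references transcripts absent from annotation")
  }
  set.seed(config$seed + 1L)
  n_tx <- nrow(annotation)
  stages <- config$stages
  design <- stage_design(stages, config$replicates)

  mu0 <- rlnorm(n_tx, log(100), 1)
  lambda <- matrix(mu0, n_tx, stages)
  rownames(lambda) <- annotation$transcript_id

  ## stage-specific transcripts: background everywhere but one stage
  if (nrow(truth$stage_specific) > 0) {
    for (i in seq_len(nrow(truth$stage_specific))) {
      t <- truth$stage_specific$transcript_id[i]
      lambda[t, ] <- 0.02
      lambda[t, truth$stage_specific$stage[i]] <- mu0[match(t, annotation$transcript_id)]
    }
  }

  ## planted DE: shift the target stage relative to stage 1
  if (nrow(truth$de) > 0) {
    k <- as.integer(sub("^S1_vs_S", "", truth$de$comparison))
    fc <- 2^(config$de_log2fc * ifelse(truth$de$direction == "up", 1, -1))
    for (i in seq_len(nrow(truth$de))) {
      lambda[truth$de$transcript_id[i], k[i]] <-
        lambda[truth$de$transcript_id[i], k[i]] * fc[i]
    }
  }

  ## Planted modules get mutually orthogonal stage profiles that each
  ## project equally onto the standardized temperature trend (correlation
  ## 1/sqrt(M), times the module sign), so modules are separable from one
  ## another yet all trait-correlated with the planted sign.
  if (nrow(truth$modules) > 0) {
    profs <- module_profiles(config$trait, max(truth$modules$module))
    for (m in sort(unique(truth$modules$module))) {
      ids <- truth$modules$transcript_id[truth$modules$module == m]
      sgn <- truth$modules$sign[truth$modules$module == m][1]
      mult <- 2^(1.5 * sgn * profs[, m])
      lambda[ids, ] <- sweep(lambda[ids, , drop = FALSE], 2, mult, `*`)
    }
  }

  ## planted cis pairs share a random stage profile with their host gene
  if (nrow(truth$cis_pairs) > 0) {
    for (i in seq_len(nrow(truth$cis_pairs))) {
      prof <- 2^(1.2 * as.numeric(scale(rnorm(stages))))
      ids <- c(truth$cis_pairs$lncrna_id[i],
               annotation$transcript_id[annotation$gene_id ==
                                          truth$cis_pairs$gene_id[i]])
      lambda[ids, ] <- sweep(lambda[ids, , drop = FALSE], 2, prof, `*`)
    }
  }

  ## scale so the expected library size matches the configuration
  lambda <- lambda * config$library_size_mean / mean(colSums(lambda))

  size_factor <- exp(rnorm(nrow(design), 0, 0.1))
  counts <- matrix(0, n_tx, nrow(design),
                   dimnames = list(annotation$transcript_id, design$sample))
  for (j in seq_len(nrow(design))) {
    mu <- lambda[, design$stage[j]] * size_factor[j]
    counts[, j] <- if (config$dispersion > 0) {
      rnbinom(n_tx, mu = mu, size = 1 / config$dispersion)
    } else {
      rpois(n_tx, mu)
    }
  }

  lib <- colSums(counts)
  if (any(lib == 0)) abort("generate_expression: empty library")
  fpkm <- 1e9 * sweep(counts, 2, lib, `/`) / annotation$length

  to_tbl <- function(m, unit) {
    out <- dplyr::bind_cols(
      tibble::tibble(transcript_id = rownames(m)),
      tibble::as_tibble(m)
    )
    set_expr_unit(out, unit)
  }
  list(
    counts = to_tbl(counts, "counts"),
    fpkm = to_tbl(fpkm, "FPKM"),
    trait = tibble::tibble(stage = seq_len(stages),
                           temperature = config$trait),
    design = design
  )
}

#' Generate a four-channel coding-potential evidence table
#'
#' For true lncRNAs each channel falls on the noncoding side of its
#' threshold (CPC < 0, CNCI < 0, txCdsPredict < 500, no Pfam hit) except
#' with an independent per-channel error rate; for true mRNAs the
#' converse.
#'
#' @param annotation,truth Output of [generate_annotation()].
#' @param config The same [synth_config()].
#' @param channel_error Optional override of the per-channel error rates
#'   (length 4: cpc, cnci, txcds, pfam).
#' @return A tibble: `transcript_id`, `cpc_score`, `cnci_score`,
#'   `txcds_score`, `pfam_hit`.
#' @export
generate_coding_evidence <- function(annotation, truth, config,
                                     channel_error = config$channel_error) {
  stopifnot(inherits(config, "synth_config"))
  if (length(channel_error) != 4 || any(channel_error < 0) ||
      any(channel_error > 1)) {
    abort("generate_coding_evidence: `channel_error` must be 4 rates in [0, 1]")
  }
  set.seed(config$seed + 2L)
  n <- nrow(annotation)
  is_lnc <- truth$biotype$biotype[match(annotation$transcript_id,
                                        truth$biotype$transcript_id)] == "lncRNA"
  ## channel "votes noncoding" flag, flipped with the channel error rate
  flip <- function(e) runif(n) < e
  nc <- cbind(is_lnc != flip(channel_error[1]),
              is_lnc != flip(channel_error[2]),
              is_lnc != flip(channel_error[3]),
              is_lnc != flip(channel_error[4]))
  tibble::tibble(
    transcript_id = annotation$transcript_id,
    cpc_score = ifelse(nc[, 1], runif(n, -3, -0.05), runif(n, 0.05, 3)),
    cnci_score = ifelse(nc[, 2], runif(n, -3, -0.05), runif(n, 0.05, 3)),
    txcds_score = ifelse(nc[, 3], runif(n, 100, 499), runif(n, 501, 1500)),
    pfam_hit = !nc[, 4]
  )
}

#' Generate a miRNA-transcript interaction table
#'
#' Every planted eTM triple appears (so its lncRNA and mRNA share at least
#' three miRNAs); background interactions are drawn independently at
#' `mirna_bg_density` per miRNA x transcript pair.
#'
#' @param annotation,truth Output of [generate_annotation()].
#' @param config The same [synth_config()].
#' @param density Optional override of the background interaction density.
#' @return A tibble: `mirna_id`, `transcript_id`, `score` (site count),
#'   with the miRNA universe as attribute `mirna_universe`.
#' @export
generate_mirna_targets <- function(annotation, truth, config,
                                   density = config$mirna_bg_density) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed + 3L)
  planted <- dplyr::bind_rows(
    dplyr::select(truth$etm_triples, mirna_id = "mirna_id",
                  transcript_id = "lncrna_id"),
    dplyr::select(truth$etm_triples, mirna_id = "mirna_id",
                  transcript_id = "mrna_id")
  ) |>
    dplyr::distinct() |>
    dplyr::mutate(score = sample(1:3, dplyr::n(), replace = TRUE))

  bg <- tibble::tibble(mirna_id = character(0), transcript_id = character(0),
                       score = integer(0))
  if (density > 0) {
    n_cell <- config$n_mirna * nrow(annotation)
    n_bg <- rbinom(1, n_cell, density)
    if (n_bg > 0) {
      cells <- sample.int(n_cell, n_bg)
      bg <- tibble::tibble(
        mirna_id = truth$mirna_universe[(cells - 1) %% config$n_mirna + 1],
        transcript_id = annotation$transcript_id[(cells - 1) %/% config$n_mirna + 1],
        score = 1L
      )
    }
  }
  out <- dplyr::bind_rows(planted, bg) |>
    dplyr::distinct(.data$mirna_id, .data$transcript_id, .keep_all = TRUE) |>
    dplyr::arrange(.data$mirna_id, .data$transcript_id)
  attr(out, "mirna_universe") <- truth$mirna_universe
  out
}

#' Generate the full synthetic receptacle study
#'
#' Convenience wrapper running all four generators under one configuration.
#'
#' @param config A [synth_config()].
#' @return A list: `annotation`, `truth`, `counts`, `fpkm`, `trait`,
#'   `design`, `evidence`, `targets`, `config`.
#' @export
#' @examples
#' study <- generate_receptacle_study(synth_config(
#'   n_coding_genes = 60, n_lncrna = 40, n_planted_modules = 1,
#'   planted_module_sizes = 12, seed = 7
#' ))
#' names(study)
generate_receptacle_study <- function(config = synth_config()) {
  ann <- generate_annotation(config)
  expr <- generate_expression(ann$annotation, ann$truth, config)
  evidence <- generate_coding_evidence(ann$annotation, ann$truth, config)
  targets <- generate_mirna_targets(ann$annotation, ann$truth, config)
  c(ann, expr, list(evidence = evidence, targets = targets, config = config))
}
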