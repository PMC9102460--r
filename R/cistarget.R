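## Cis target assignment: strand-aware genomic window search around
## protein-coding genes, dual Spearman/Pearson correlation gate, and
## multiplicity statistics.

#' Collapse an annotation to per-gene spans
#'
#' @param annotation Annotation tibble.
#' @param biotype Optional biotype to restrict to (e.g. `"mRNA"`).
#' @return A tibble: `gene_id`, `chrom`, `start`, `end`, `strand`
#'   (0-based half-open union span over the gene's transcripts).
#' @export
gene_spans <- function(annotation, biotype = NULL) {
  if (!is.null(biotype)) {
    annotation <- annotation[annotation$biotype %in% biotype, ]
  }
  annotation |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(chrom = .data$chrom[1], start = min(.data$start),
                     end = max(.data$end), strand = .data$strand[1],
                     .groups = "drop")
}

#' lncRNAs within the cis window of protein-coding genes
#'
#' For each coding gene the window runs from `up_bp` before the gene's
#' strand-aware start to `down_bp` after its strand-aware end (mirrored
#' for minus-strand genes). Any lncRNA whose span intersects the window
#' on the same chromosome is a candidate, whatever its own strand. The
#' gap distance between closest span edges is 0 for overlapping pairs;
#' `signed_distance` is negative when the lncRNA lies upstream of the
#' gene.
#'
#' @param lncrnas Tibble of lncRNA records (`transcript_id`, `chrom`,
#'   `start`, `end`, `strand`), 0-based half-open.
#' @param genes Tibble of gene spans ([gene_spans()]).
#' @param up_bp,down_bp Window extents in nt (defaults 10,000 upstream and
#'   20,000 downstream).
#' @return Candidate tibble: `lncrna_id`, `gene_id`, `chrom`, `relation`
#'   (`upstream`/`downstream`/`overlapping`), `signed_distance`,
#'   `same_strand`.
#' @export
window_candidates <- function(lncrnas, genes, up_bp = 10000, down_bp = 20000) {
  if (up_bp < 0 || down_bp < 0) {
    abort("window_candidates: window extents must be non-negative")
  }
  if (nrow(lncrnas) == 0 || nrow(genes) == 0) {
    return(tibble::tibble(lncrna_id = character(0), gene_id = character(0),
                          chrom = character(0), relation = character(0),
                          signed_distance = integer(0),
                          same_strand = logical(0)))
  }
  win_start <- ifelse(genes$strand == "+", genes$start - up_bp,
                      genes$start - down_bp)
  win_end <- ifelse(genes$strand == "+", genes$end + down_bp,
                    genes$end + up_bp)

  hits <- purrr::map_dfr(unique(genes$chrom), function(ch) {
    gi <- which(genes$chrom == ch)
    li <- which(lncrnas$chrom == ch)
    if (length(gi) == 0 || length(li) == 0) return(NULL)
    ## half-open [s, e) -> closed [s + 1, e] for IRanges; the window is
    ## widened by 1 nt on each side so that a gap of exactly up_bp/down_bp
    ## is still seen, then the per-relation bound below trims precisely
    wr <- IRanges::IRanges(start = win_start[gi], end = win_end[gi] + 1L)
    lr <- IRanges::IRanges(start = lncrnas$start[li] + 1L,
                           end = lncrnas$end[li])
    ov <- IRanges::findOverlaps(lr, wr)
    tibble::tibble(l = li[S4Vectors::queryHits(ov)],
                   g = gi[S4Vectors::subjectHits(ov)])
  })
  if (nrow(hits) == 0) {
    return(tibble::tibble(lncrna_id = character(0), gene_id = character(0),
                          chrom = character(0), relation = character(0),
                          signed_distance = integer(0),
                          same_strand = logical(0)))
  }
  ls <- lncrnas$start[hits$l]; le <- lncrnas$end[hits$l]
  gs <- genes$start[hits$g]; ge <- genes$end[hits$g]
  gstrand <- genes$strand[hits$g]
  gap <- pmax(0L, pmax(gs - le, ls - ge))
  left_of_gene <- le <= gs
  relation <- dplyr::case_when(
    gap == 0 ~ "overlapping",
    (gstrand == "+") == left_of_gene ~ "upstream",
    TRUE ~ "downstream"
  )
  out <- tibble::tibble(
    lncrna_id = lncrnas$transcript_id[hits$l],
    gene_id = genes$gene_id[hits$g],
    chrom = lncrnas$chrom[hits$l],
    relation = relation,
    signed_distance = as.integer(ifelse(relation == "upstream", -gap, gap)),
    same_strand = lncrnas$strand[hits$l] == gstrand
  )
  ## findOverlaps against the full window over-reaches on the short side:
  ## enforce the per-relation bound
  out <- out[out$relation == "overlapping" |
               (out$relation == "upstream" & abs(out$signed_distance) <= up_bp) |
               (out$relation == "downstream" & out$signed_distance <= down_bp), ]
  dplyr::arrange(out, .data$lncrna_id, .data$gene_id)
}

#' Dual correlation gate on cis candidates
#'
#' Spearman (average-rank ties) and Pearson correlations are computed
#' between the lncRNA's FPKM and its candidate gene's FPKM across all
#' samples; a pair is retained iff both reach their thresholds.
#' Gene-level expression is the sum of the gene's transcript FPKMs when
#' an annotation is supplied, otherwise gene ids must appear directly in
#' the expression table. Pairs with a zero-variance vector are dropped
#' with a recorded reason.
#'
#' @param candidates Output of [window_candidates()].
#' @param fpkm FPKM expression tibble (transcript level).
#' @param annotation Optional annotation tibble used to aggregate gene
#'   expression over isoforms.
#' @param rho_min,r_min Spearman and Pearson thresholds (defaults 0.6,
#'   both one-sided positive).
#' @return The retained pairs with `spearman` and `pearson` columns;
#'   dropped zero-variance pairs are recorded in attribute `dropped`.
#' @export
correlation_gate <- function(candidates, fpkm, annotation = NULL,
                             rho_min = 0.6, r_min = 0.6) {
  if (nrow(candidates) == 0) {
    out <- dplyr::mutate(candidates, spearman = numeric(0), pearson = numeric(0))
    attr(out, "dropped") <- candidates[0, ]
    return(out)
  }
  m <- expr_matrix(fpkm)
  gene_m <- if (!is.null(annotation)) {
    map <- annotation[annotation$transcript_id %in% rownames(m),
                      c("transcript_id", "gene_id")]
    rowsum(m[map$transcript_id, , drop = FALSE], group = map$gene_id)
  } else {
    m
  }
  missing <- !(candidates$lncrna_id %in% rownames(m)) |
    !(candidates$gene_id %in% rownames(gene_m))
  if (any(missing)) {
    abort(paste0("correlation_gate: ", sum(missing),
                 " candidate pair(s) absent from expression"))
  }
  x <- m[candidates$lncrna_id, , drop = FALSE]
  y <- gene_m[candidates$gene_id, , drop = FALSE]
  sp <- pe <- numeric(nrow(candidates))
  degenerate <- logical(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    if (sd(x[i, ]) == 0 || sd(y[i, ]) == 0) {
      degenerate[i] <- TRUE
      next
    }
    sp[i] <- cor(x[i, ], y[i, ], method = "spearman")
    pe[i] <- cor(x[i, ], y[i, ], method = "pearson")
  }
  out <- candidates |>
    dplyr::mutate(spearman = sp, pearson = pe) |>
    dplyr::filter(!degenerate, sp >= rho_min, pe >= r_min)
  dropped <- candidates[degenerate, ] |>
    dplyr::mutate(reason = "zero-variance expression (correlation undefined)")
  attr(out, "dropped") <- dropped
  out
}

#' Multiplicity statistics of a cis pair set
#'
#' @param pairs Cis pair tibble (`lncrna_id`, `gene_id`).
#' @return A list with `totals` (pairs, distinct lncRNAs/genes,
#'   multi-target lncRNAs, multi-regulated genes) and the two degree
#'   tables.
#' @export
multiplicity_stats <- function(pairs) {
  lnc_deg <- dplyr::count(pairs, .data$lncrna_id, name = "n_targets")
  gene_deg <- dplyr::count(pairs, .data$gene_id, name = "n_regulators")
  list(
    totals = tibble::tibble(
      n_pairs = nrow(pairs),
      n_lncrna = nrow(lnc_deg),
      n_genes = nrow(gene_deg),
      n_lncrna_multi_target = sum(lnc_deg$n_targets >= 2),
      n_genes_multi_regulated = sum(gene_deg$n_regulators >= 2)
    ),
    lncrna_degree = lnc_deg,
    gene_degree = gene_deg
  )
}
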