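## Readers and writers for the formats the pipeline touches. All readers
## validate strictly and error rather than coerce; all writers are
## deterministic given identical in-memory state. Genomic coordinates are
## 0-based half-open internally and 1-based inclusive on disk (GTF).

parse_gtf_attributes <- function(attr, lineno) {
  get1 <- function(key) {
    m <- regmatches(attr, regexec(paste0(key, ' "([^"]*)"'), attr))[[1]]
    if (length(m) < 2) NA_character_ else m[2]
  }
  tid <- get1("transcript_id")
  if (is.na(tid)) {
    abort(paste0("read_gtf: missing transcript_id at line ", lineno))
  }
  gid <- get1("gene_id")
  if (is.na(gid)) {
    abort(paste0("read_gtf: missing gene_id at line ", lineno))
  }
  c(transcript_id = tid, gene_id = gid)
}

#' Read a transcript/exon GTF into an annotation tibble
#'
#' Accepts the GTF 2.2 dialect with `transcript` and `exon` features and
#' `gene_id`/`transcript_id` attributes. Exon coordinates are converted
#' from 1-based inclusive to 0-based half-open; the stable input order of
#' transcripts is preserved.
#'
#' @param path Path to a GTF file.
#' @return An annotation tibble (`transcript_id`, `gene_id`, `chrom`,
#'   `start`, `end`, `strand`, `length`, `n_exons`, `biotype`, `exons`
#'   list-column), coordinates 0-based half-open.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) abort(paste0("read_gtf: no such file: ", path))
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  linenos <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 9)
  if (length(bad) > 0) {
    abort(paste0("read_gtf: malformed line ", linenos[bad[1]],
                 " (expected 9 tab-separated fields)"))
  }
  m <- do.call(rbind, fields)
  start1 <- suppressWarnings(as.integer(m[, 4]))
  end1 <- suppressWarnings(as.integer(m[, 5]))
  if (anyNA(start1) || anyNA(end1)) {
    abort(paste0("read_gtf: non-numeric coordinates at line ",
                 linenos[which(is.na(start1) | is.na(end1))[1]]))
  }
  if (any(end1 < start1)) {
    abort(paste0("read_gtf: end < start at line ",
                 linenos[which(end1 < start1)[1]]))
  }
  if (!all(m[, 7] %in% c("+", "-"))) {
    abort(paste0("read_gtf: invalid strand at line ",
                 linenos[which(!m[, 7] %in% c("+", "-"))[1]]))
  }
  ids <- t(vapply(seq_len(nrow(m)),
                  function(i) parse_gtf_attributes(m[i, 9], linenos[i]),
                  character(2)))
  feat <- tibble::tibble(
    feature = m[, 3], chrom = m[, 1], strand = m[, 7],
    start = start1 - 1L, end = end1,  # to 0-based half-open
    transcript_id = ids[, 1], gene_id = ids[, 2],
    lineno = linenos
  )
  exons <- feat[feat$feature == "exon", ]
  txf <- feat[feat$feature == "transcript", ]
  if (nrow(exons) == 0) abort("read_gtf: no exon features found")

  tx_order <- unique(exons$transcript_id)
  recs <- purrr::map(tx_order, function(tid) {
    ex <- exons[exons$transcript_id == tid, ]
    ex <- ex[order(ex$start), ]
    if (nrow(ex) > 1 && any(ex$start[-1] < ex$end[-nrow(ex)])) {
      abort(paste0("read_gtf: overlapping exons for transcript ", tid))
    }
    if (length(unique(ex$chrom)) > 1 || length(unique(ex$strand)) > 1) {
      abort(paste0("read_gtf: exons of ", tid, " on multiple chromosomes/strands"))
    }
    span <- txf[txf$transcript_id == tid, ]
    if (nrow(span) > 0 &&
        (min(ex$start) < span$start[1] || max(ex$end) > span$end[1])) {
      abort(paste0("read_gtf: exon outside transcript span for ", tid))
    }
    tibble::tibble(
      transcript_id = tid, gene_id = ex$gene_id[1], chrom = ex$chrom[1],
      start = min(ex$start), end = max(ex$end), strand = ex$strand[1],
      length = sum(ex$end - ex$start), n_exons = nrow(ex),
      biotype = "unset",
      exons = list(tibble::tibble(start = ex$start, end = ex$end))
    )
  })
  dplyr::bind_rows(recs)
}

#' Write an annotation tibble as GTF
#'
#' Emits one `transcript` and per-exon `exon` features, 1-based inclusive
#' coordinates, `gene_id`/`transcript_id` attributes. Deterministic: row
#' order follows the annotation.
#'
#' @param annotation Annotation tibble as returned by [read_gtf()] or
#'   [generate_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path) {
  lines <- unlist(purrr::pmap(annotation, function(transcript_id, gene_id,
                                                   chrom, start, end, strand,
                                                   exons, ...) {
    attrs <- sprintf('gene_id "%s"; transcript_id "%s";', gene_id, transcript_id)
    c(
      paste(chrom, "thermolnc", "transcript", start + 1L, end, ".", strand,
            ".", attrs, sep = "\t"),
      paste(chrom, "thermolnc", "exon", exons$start + 1L, exons$end, ".",
            strand, ".", attrs, sep = "\t")
    )
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Read an expression matrix TSV
#'
#' Expects a header of sample identifiers and a first column of transcript
#' ids. Negative values, duplicate transcript ids, samples missing from
#' the design and empty data sections are all rejected.
#'
#' @param path Path to a tab-separated table (first column transcript id).
#' @param design Optional design tibble (`sample`, `stage`, `replicate`);
#'   defaults to parsing the header as `S{stage}R{rep}`.
#' @param unit Measurement unit of the values, `"counts"` or `"FPKM"`.
#' @return An expression tibble with attribute `unit`.
#' @export
read_expression <- function(path, design = NULL, unit = c("counts", "FPKM")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) abort(paste0("read_expression: no such file: ", path))
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0) abort("read_expression: empty data section")
  names(df)[1] <- "transcript_id"
  if (anyDuplicated(df$transcript_id)) {
    abort(paste0("read_expression: duplicated transcript id: ",
                 df$transcript_id[duplicated(df$transcript_id)][1]))
  }
  vals <- df[, -1, drop = FALSE]
  if (!all(vapply(vals, is.numeric, logical(1)))) {
    abort("read_expression: non-numeric expression values")
  }
  if (any(as.matrix(vals) < 0)) abort("read_expression: negative value")
  out <- tibble::as_tibble(df)
  design <- resolve_design(out, design)
  extra <- setdiff(expr_samples(out), design$sample)
  if (length(extra) > 0) {
    abort(paste0("read_expression: samples not in design: ",
                 paste(extra, collapse = ", ")))
  }
  set_expr_unit(out, unit)
}

#' Write an expression tibble as TSV
#'
#' @param expr Expression tibble (`transcript_id` + sample columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path) {
  utils::write.table(expr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a miRNA-target interaction table
#'
#' @param path TSV with columns `mirna_id`, `transcript_id`, `score`.
#' @return A tibble of interactions; duplicate (miRNA, transcript) pairs
#'   are rejected.
#' @export
read_targets <- function(path) {
  if (!file.exists(path)) abort(paste0("read_targets: no such file: ", path))
  df <- tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  need <- c("mirna_id", "transcript_id", "score")
  if (!all(need %in% names(df))) {
    abort(paste0("read_targets: required columns: ", paste(need, collapse = ", ")))
  }
  if (anyDuplicated(df[, c("mirna_id", "transcript_id")])) {
    abort("read_targets: duplicate (miRNA, transcript) interaction")
  }
  df
}

#' Write a ceRNA network as a tri-partite edge list
#'
#' One row per edge with type `lncRNA-miRNA`, `miRNA-mRNA` or
#' `lncRNA-mRNA`; a significant pair with k shared miRNAs yields 2k + 1
#' edges. Rows are sorted by FDR, then ids, so output is byte-identical
#' across runs.
#'
#' @param pairs Significant ceRNA pair tibble (from [build_network()]:
#'   columns `lncrna_id`, `mrna_id`, `shared_mirnas` list-column, `p`, `fdr`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_network <- function(pairs, path) {
  edges <- tibble::tibble(source = character(0), target = character(0),
                          edge_type = character(0), p = numeric(0),
                          fdr = numeric(0))
  if (nrow(pairs) > 0) {
    edges <- purrr::pmap_dfr(
      list(pairs$lncrna_id, pairs$mrna_id, pairs$shared_mirnas,
           pairs$p, pairs$fdr),
      function(l, m, shared, p, fdr) {
        shared <- sort(shared)
        dplyr::bind_rows(
          tibble::tibble(source = l, target = shared,
                         edge_type = "lncRNA-miRNA", p = p, fdr = fdr),
          tibble::tibble(source = shared, target = m,
                         edge_type = "miRNA-mRNA", p = p, fdr = fdr),
          tibble::tibble(source = l, target = m,
                         edge_type = "lncRNA-mRNA", p = p, fdr = fdr)
        )
      }
    ) |>
      dplyr::arrange(.data$fdr, .data$source, .data$target, .data$edge_type)
  }
  utils::write.table(edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a generic tibble as TSV (deterministic, unquoted)
#' @param x A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  x <- tibble::as_tibble(x)
  x <- x[, !vapply(x, is.list, logical(1)), drop = FALSE]
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
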