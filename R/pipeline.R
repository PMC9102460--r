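## End-to-end orchestration: synth -> classify -> diffexpr -> cistarget ->
## coexpr -> cerna, from one configuration, with a JSON manifest of every
## parameter and seed used.

#' Pipeline configuration
#'
#' Defaults are the study thresholds: lncRNA length > 200 nt, 3-of-4
#' consensus votes, fold change >= 2 with adjusted p <= 0.001, K-means
#' k = 6, cis window 10 kb upstream / 20 kb downstream, Spearman and
#' Pearson >= 0.6, >= 3 shared miRNAs with FDR <= 0.05.
#'
#' @param ... Overrides of the defaults (unknown keys are rejected).
#' @return A list of class `pipeline_config`.
#' @export
#' @examples
#' cfg <- pipeline_config(seed = 42, fc_min = 2)
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1,
    min_len = 200, votes = 3, floor = 0.5,
    fc_min = 2.0, alpha = 0.001, k = 6,
    up_bp = 10000, down_bp = 20000, rho_min = 0.6, r_min = 0.6,
    beta = "auto", r2_min = 0.8, min_size = 10, cut_height = 0.7,
    kme_min = 0.9,
    min_shared = 3, fdr_max = 0.05,
    synth = list()
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(defaults))
  if (length(unknown) > 0) {
    abort(paste0("pipeline_config: unknown key(s): ",
                 paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, dots)
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path Path to a YAML file whose keys match [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full pipeline on synthetic data
#'
#' Generates the synthetic receptacle study under the configured seed,
#' then runs biotype classification, stage-presence profiling,
#' stage-1-anchored differential expression with K-means profile
#' clustering of the DELs, cis-target assignment, co-expression module
#' detection with trait correlation, and ceRNA network inference. All
#' stage outputs are written as TSV (plus the annotation as GTF and the
#' network edge list), together with a JSON manifest recording
#' thresholds, seeds and per-stage record counts. Reruns with the same
#' configuration produce identical outputs (manifest timestamp aside).
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created; must be empty or absent).
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  if (dir.exists(out_dir) && length(list.files(out_dir)) > 0) {
    abort("run_pipeline: `out_dir` must be empty or absent")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  created <- character(0)
  emit <- function(x, name, writer = write_tsv_table) {
    path <- file.path(out_dir, name)
    writer(x, path)
    created <<- c(created, path)
    path
  }
  stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      unlink(created)
      abort(paste0("pipeline stage '", name, "' failed: ",
                   conditionMessage(e)))
    })
  }

  scfg <- do.call(synth_config, utils::modifyList(list(seed = config$seed),
                                                  config$synth))
  study <- stage("synth", function() {
    study <- generate_receptacle_study(scfg)
    emit(study$annotation, "annotation.gtf", write_gtf)
    emit(study$counts, "counts.tsv", write_expression)
    emit(study$fpkm, "fpkm.tsv", write_expression)
    emit(study$trait, "trait.tsv")
    emit(study$evidence, "coding_evidence.tsv")
    emit(study$targets, "mirna_targets.tsv")
    emit(study$truth$biotype, "truth_biotype.tsv")
    study
  })

  classified <- stage("classify", function() {
    records <- assign_biotypes(study$annotation, study$evidence,
                               vote_thresholds(votes_required = config$votes),
                               min_len = config$min_len)
    presence <- stage_presence(study$fpkm, floor = config$floor,
                               design = study$design)
    summary <- presence_summary(presence)
    emit(records, "biotypes.tsv")
    emit(presence, "stage_presence.tsv")
    emit(summary$fractions, "presence_fractions.tsv")
    chars <- characterize(records, study$fpkm)
    emit(chars$lengths, "length_summary.tsv")
    list(records = records, presence = presence, summary = summary,
         characterization = chars)
  })

  de <- stage("diffexpr", function() {
    results <- purrr::map_dfr(2:scfg$stages, function(k) {
      de_test(study$counts, 1, k, design = study$design,
              fc_min = config$fc_min, alpha = config$alpha)
    })
    sets <- comparison_sets(results)
    lnc_ids <- classified$records$transcript_id[
      classified$records$biotype == "lncRNA"]
    dels <- unique(results$transcript_id[results$significant &
                                           results$transcript_id %in% lnc_ids])
    clusters <- NULL
    if (length(dels) >= config$k) {
      clusters <- kmeans_profiles(study$fpkm, dels, k = config$k,
                                  design = study$design, seed = config$seed)
      emit(clusters, "del_clusters.tsv")
    }
    emit(results, "de_results.tsv")
    emit(sets$tallies, "de_tallies.tsv")
    emit(sets$intersections, "de_intersections.tsv")
    list(results = results, sets = sets, dels = dels, clusters = clusters)
  })

  cis <- stage("cistarget", function() {
    genes <- gene_spans(classified$records, biotype = "mRNA")
    lnc <- classified$records[classified$records$biotype == "lncRNA", ]
    cands <- window_candidates(lnc, genes, up_bp = config$up_bp,
                               down_bp = config$down_bp)
    pairs <- correlation_gate(cands, study$fpkm,
                              annotation = classified$records,
                              rho_min = config$rho_min, r_min = config$r_min)
    stats <- multiplicity_stats(pairs)
    emit(pairs, "cis_pairs.tsv")
    emit(stats$totals, "cis_multiplicity.tsv")
    list(candidates = cands, pairs = pairs, stats = stats)
  })

  coexpr <- stage("coexpr", function() {
    fit <- run_coexpr(study$fpkm, study$trait,
                      biotype = classified$records[, c("transcript_id",
                                                       "biotype")],
                      design = study$design, beta = config$beta,
                      r2_min = config$r2_min, min_size = config$min_size,
                      cut_height = config$cut_height,
                      kme_min = config$kme_min)
    emit(fit$modules, "modules.tsv")
    emit(fit$module_trait, "module_trait.tsv")
    emit(fit$hubs, "module_hubs.tsv")
    emit(fit$trans_pairs, "trans_targets.tsv")
    fit
  })

  cerna <- stage("cerna", function() {
    lnc_ids <- classified$records$transcript_id[
      classified$records$biotype == "lncRNA"]
    mrna_ids <- classified$records$transcript_id[
      classified$records$biotype == "mRNA"]
    net <- build_network(study$targets, lnc_ids, mrna_ids,
                         min_shared = config$min_shared,
                         fdr_max = config$fdr_max)
    emit(net$pairs, "cerna_pairs.tsv")
    emit(net$etms, "cerna_etms.tsv")
    emit(net$mirna_degree, "mirna_degree.tsv")
    emit(net$pairs[net$pairs$significant, ], "cerna_edges.tsv", write_network)
    net
  })

  manifest <- list(
    package = "thermolnc",
    version = as.character(utils::packageVersion("thermolnc")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    thresholds = unclass(config)[setdiff(names(config), c("synth", "seed"))],
    synth = unclass(scfg),
    record_counts = list(
      transcripts = nrow(study$annotation),
      lncrna = sum(classified$records$biotype == "lncRNA"),
      mrna = sum(classified$records$biotype == "mRNA"),
      uncertain = sum(classified$records$biotype == "uncertain"),
      dels = length(de$dels),
      cis_pairs = nrow(cis$pairs),
      modules = length(setdiff(unique(coexpr$modules$module), "grey")),
      cerna_pairs_tested = nrow(cerna$pairs),
      cerna_pairs_significant = sum(cerna$pairs$significant),
      etm_records = nrow(cerna$etms)
    ),
    input_checksums = as.list(tools::md5sum(sort(created)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(study = study, classify = classified, diffexpr = de,
                 cistarget = cis, coexpr = coexpr, cerna = cerna,
                 manifest = manifest))
}
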