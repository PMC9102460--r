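test_that("generators are deterministic under a fixed seed", {
  cfg <- small_config(seed = 5)
  a1 <- generate_annotation(cfg)
  a2 <- generate_annotation(cfg)
  expect_identical(a1, a2)
  e1 <- generate_expression(a1$annotation, a1$truth, cfg)
  e2 <- generate_expression(a2$annotation, a2$truth, cfg)
  expect_identical(e1$counts, e2$counts)
  expect_identical(e1$fpkm, e2$fpkm)
  ev1 <- generate_coding_evidence(a1$annotation, a1$truth, cfg)
  ev2 <- generate_coding_evidence(a1$annotation, a1$truth, cfg)
  expect_identical(ev1, ev2)
  t1 <- generate_mirna_targets(a1$annotation, a1$truth, cfg)
  t2 <- generate_mirna_targets(a1$annotation, a1$truth, cfg)
  expect_identical(t1, t2)
})

test_that("annotation conserves parents and resolves every truth id", {
  cfg <- small_config(seed = 9)
  ann <- generate_annotation(cfg)
  expect_equal(dplyr::n_distinct(ann$annotation$gene_id),
               cfg$n_coding_genes + cfg$n_lncrna)
  tr <- ann$truth
  all_ids <- ann$annotation$transcript_id
  expect_true(all(tr$biotype$transcript_id %in% all_ids))
  expect_true(all(tr$stage_specific$transcript_id %in% all_ids))
  expect_true(all(tr$de$transcript_id %in% all_ids))
  expect_true(all(tr$modules$transcript_id %in% all_ids))
  expect_true(all(tr$cis_pairs$lncrna_id %in% all_ids))
  expect_true(all(tr$cis_pairs$gene_id %in% ann$annotation$gene_id))
  expect_true(all(c(tr$etm_triples$lncrna_id, tr$etm_triples$mrna_id) %in%
                    all_ids))
  # exons sorted, non-overlapping, within span, lengths consistent
  for (i in sample(nrow(ann$annotation), 20)) {
    ex <- ann$annotation$exons[[i]]
    expect_true(all(diff(ex$start) > 0))
    expect_true(all(ex$end > ex$start))
    if (nrow(ex) > 1) expect_true(all(ex$start[-1] >= ex$end[-nrow(ex)]))
    expect_gte(min(ex$start), ann$annotation$start[i])
    expect_lte(max(ex$end), ann$annotation$end[i])
    expect_equal(sum(ex$end - ex$start), ann$annotation$length[i])
  }
})

test_that("lncRNA length mode matches the configured short fraction", {
  cfg <- synth_config(n_lncrna = 1000, n_coding_genes = 50,
                      n_planted_modules = 0,
                      planted_module_sizes = integer(0), seed = 7)
  ann <- generate_annotation(cfg)
  lnc <- ann$annotation[grepl("^LNC", ann$annotation$transcript_id), ]
  frac_short <- mean(lnc$length >= 200 & lnc$length <= 500)
  expect_lt(abs(frac_short - cfg$lncrna_short_frac), 0.05)
  mrna <- ann$annotation[!grepl("^LNC", ann$annotation$transcript_id), ]
  expect_gt(mean(mrna$length > 500), 0.85)
  expect_gt(mean(lnc$n_exons == 1), 0.75)
})

test_that("frac_stage_specific = 0 plants no stage-specific transcripts", {
  cfg <- small_config(seed = 2, frac_stage_specific = 0)
  ann <- generate_annotation(cfg)
  expect_equal(nrow(ann$truth$stage_specific), 0)
})

test_that("trait length must match the stage count", {
  expect_error(synth_config(stages = 4), "trait")
  cfg4 <- synth_config(stages = 4, trait = c(18, 30, 35, 22),
                       n_planted_modules = 2,
                       planted_module_sizes = c(20, 30),
                       n_coding_genes = 60, n_lncrna = 40)
  expect_s3_class(cfg4, "synth_config")
})

test_that("FPKM is zero exactly where counts are zero", {
  study <- default_study()
  cm <- as.matrix(study$counts[, -1])
  fm <- as.matrix(study$fpkm[, -1])
  expect_true(all((cm == 0) == (fm == 0)))
  # FPKM formula: 1e9 * count / (length * library size)
  lib <- colSums(cm)
  len <- study$annotation$length
  expect_equal(fm, 1e9 * sweep(cm, 2, lib, `/`) / len, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("null expression yields no DE at the default filter", {
  cfg <- small_config(seed = 31, de_fraction = 0, frac_stage_specific = 0,
                      frac_cis_lnc = 0, n_planted_modules = 0,
                      planted_module_sizes = integer(0), dispersion = 0)
  ann <- generate_annotation(cfg)
  ex <- generate_expression(ann$annotation, ann$truth, cfg)
  res <- de_test(ex$counts, 1, 3, design = ex$design)
  # false positives bounded by the nominal level of the configured filter
  expect_lte(sum(res$significant), qbinom(0.999, nrow(res), 0.001) + 1)
})

test_that("a planted trait-profile module is recovered with a strong eigengene", {
  cfg <- synth_config(n_coding_genes = 300, n_lncrna = 200,
                      n_planted_modules = 1, planted_module_sizes = 40,
                      de_fraction = 0, frac_stage_specific = 0,
                      frac_cis_lnc = 0, n_etm = 0, seed = 17)
  study <- generate_receptacle_study(cfg)
  fit <- suppressWarnings(run_coexpr(study$fpkm, study$trait, biotype = study$truth$biotype,
                    design = study$design))
  planted <- study$truth$modules$transcript_id
  det <- fit$modules$module[match(planted, fit$modules$transcript_id)]
  main <- names(sort(table(det), decreasing = TRUE))[1]
  expect_false(main == "grey")
  eg <- fit$eigengenes[, main]
  trait_per_sample <- study$trait$temperature[
    study$design$stage[match(names(eg), study$design$sample)]]
  expect_gt(cor(eg, trait_per_sample), 0.9)
})

test_that("channel evidence respects thresholds at zero error", {
  cfg <- small_config(seed = 13)
  ann <- generate_annotation(cfg)
  ev <- generate_coding_evidence(ann$annotation, ann$truth, cfg,
                                 channel_error = rep(0, 4))
  voted <- vote_biotype(ev)
  truth <- ann$truth$biotype$biotype[match(voted$transcript_id,
                                           ann$truth$biotype$transcript_id)]
  expect_identical(voted$biotype, truth)
})

test_that("one fully corrupted channel cannot break the 3-of-4 consensus", {
  cfg <- small_config(seed = 13)
  ann <- generate_annotation(cfg)
  ev <- generate_coding_evidence(ann$annotation, ann$truth, cfg,
                                 channel_error = c(0, 0.3, 0, 0))
  voted <- vote_biotype(ev)
  truth <- ann$truth$biotype$biotype[match(voted$transcript_id,
                                           ann$truth$biotype$transcript_id)]
  expect_identical(voted$biotype, truth)
})

test_that("fully random channels carry no information", {
  cfg <- synth_config(n_coding_genes = 700, n_lncrna = 500, seed = 23)
  ann <- generate_annotation(cfg)
  ev <- generate_coding_evidence(ann$annotation, ann$truth, cfg,
                                 channel_error = rep(0.5, 4))
  voted <- vote_biotype(ev)
  truth <- ann$truth$biotype$biotype[match(voted$transcript_id,
                                           ann$truth$biotype$transcript_id)]
  conf <- voted$biotype != "uncertain"
  agree <- mean(voted$biotype[conf] == truth[conf])
  # no-information baseline: agreement indistinguishable from 0.5
  expect_lt(abs(agree - 0.5), 3.5 * sqrt(0.25 / sum(conf)))
})

test_that("planted eTM triples share at least three miRNAs in the table", {
  study <- default_study()
  tr <- study$truth$etm_triples
  sets <- split(study$targets$mirna_id, study$targets$transcript_id)
  for (p in unique(paste(tr$lncrna_id, tr$mrna_id))) {
    ids <- strsplit(p, " ")[[1]]
    expect_gte(length(intersect(sets[[ids[1]]], sets[[ids[2]]])), 3)
  }
})
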