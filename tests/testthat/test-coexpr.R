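block_expr <- function(n_per_block = 12, n_blocks = 2, noise = 0) {
  design <- stage_design(5, 3)
  # uncorrelated stage profiles (centered versions are orthogonal)
  profiles <- rbind(c(4, 1, 0, 1, 4), c(0, 1, 2, 3, 4))[
    seq_len(n_blocks), , drop = FALSE]
  m <- profiles[rep(seq_len(n_blocks), each = n_per_block),
                rep(1:5, each = 3)]
  m <- m + matrix(rnorm(length(m), 0, noise), nrow(m))
  rownames(m) <- paste0("t", seq_len(nrow(m)))
  colnames(m) <- design$sample
  expr_from_matrix(m, "FPKM")
}

test_that("adjacency is a monotone power of |cor| with unit within-module values", {
  expr <- block_expr(n_per_block = 5, n_blocks = 1)
  a1 <- adjacency_matrix(expr, 1)
  expect_true(all(abs(a1[upper.tri(a1)] - 1) < 1e-12))
  expect_true(all(diag(a1) == 0))
  expr2 <- block_expr(n_per_block = 6, n_blocks = 2, noise = 0.5)
  a_lo <- adjacency_matrix(expr2, 2)
  a_hi <- adjacency_matrix(expr2, 6)
  expect_true(all(a_hi <= a_lo + 1e-12))
})

test_that("TOM matches hand evaluation and the triple-loop oracle", {
  a <- matrix(0.5, 3, 3)
  diag(a) <- 0
  w <- tom_similarity(a)
  expect_equal(w[1, 2], 0.5)
  expect_equal(diag(w), rep(1, 3))

  z <- matrix(0, 4, 4)
  expect_equal(tom_similarity(z), diag(4))

  set.seed(21)
  for (rep in 1:5) {
    a <- matrix(runif(400, 0, 0.9), 20)
    a <- (a + t(a)) / 2
    diag(a) <- 0
    expect_lt(max(abs(tom_similarity(a) - tom_oracle(a))), 1e-12)
  }
  bad <- matrix(runif(9), 3)
  expect_error(tom_similarity(bad), "symmetric")
})

test_that("module detection separates clean blocks and leaves noise grey", {
  set.seed(33)
  expr <- block_expr(n_per_block = 12, n_blocks = 2, noise = 1e-6)
  a <- adjacency_matrix(expr, 6)
  rownames(a) <- colnames(a) <- expr$transcript_id
  mods <- detect_modules(tom_similarity(a))
  expect_equal(length(setdiff(unique(mods$module), "grey")), 2)
  truth <- rep(1:2, each = 12)[match(mods$transcript_id,
                                     expr$transcript_id)]
  expect_equal(ari(mods$module, truth), 1)
  # larger block gets the first color
  expect_error(detect_modules(tom_similarity(a), min_size = 1), "min_size")
})

test_that("independent noise transcripts are left unassigned", {
  set.seed(44)
  design <- stage_design(5, 3)
  m <- matrix(rnorm(200 * 15), 200, 15,
              dimnames = list(paste0("t", 1:200), design$sample))
  expr <- expr_from_matrix(m, "FPKM")
  a <- adjacency_matrix(expr, 6)
  mods <- detect_modules(tom_similarity(a))
  expect_gte(mean(mods$module == "grey"), 0.95)
})

test_that("module membership is invariant to transcript input order", {
  set.seed(55)
  expr <- block_expr(n_per_block = 12, n_blocks = 2, noise = 0.3)
  a <- adjacency_matrix(expr, 6)
  tom <- tom_similarity(a)
  rownames(tom) <- colnames(tom) <- expr$transcript_id
  m1 <- detect_modules(tom)
  perm <- sample(nrow(tom))
  m2 <- detect_modules(tom[perm, perm])
  expect_identical(dplyr::arrange(m1, transcript_id),
                   dplyr::arrange(m2, transcript_id))
})

test_that("eigengene sign, scaling and PCA ordering behave", {
  design <- stage_design(5, 3)
  v <- rep(c(2, 1, 0, -1, -2), each = 3)
  m <- rbind(a = v, b = v, c = v)
  colnames(m) <- design$sample
  expr <- expr_from_matrix(m, "FPKM")
  e <- eigengene(expr, c("a", "b", "c"))
  shared <- as.numeric(scale(v))
  expect_equal(unname(e), shared / sd(shared), tolerance = 1e-8)
  # flipping every member's profile flips the eigengene
  expr_neg <- expr_from_matrix(`rownames<-`(-m, rownames(m)), "FPKM")
  e_neg <- eigengene(expr_neg, c("a", "b", "c"))
  expect_equal(unname(e_neg), -unname(e), tolerance = 1e-8)
  # single-member module: that member's standardized profile
  e1 <- eigengene(expr, "a")
  expect_equal(unname(e1), as.numeric(scale(v)), tolerance = 1e-8)
  expect_equal(sd(e), 1, tolerance = 1e-8)
  expect_error(eigengene(expr, character(0)), "empty")
})

test_that("module-trait correlation uses stage expansion and t-test p", {
  design <- stage_design(5, 3)
  v <- rep(c(1, -1, 0, 0, 0), each = 3)
  m <- rbind(a = v, b = v)
  colnames(m) <- design$sample
  expr <- expr_from_matrix(m, "FPKM")
  e <- eigengene(expr, c("a", "b"))
  # trait equal to the eigengene's stage pattern: correlation 1
  mt <- module_trait(list(mod = e), c(1, -1, 0, 0, 0), design)
  expect_equal(mt$trait_cor, 1, tolerance = 1e-8)
  # orthogonal trait: correlation ~ 0, p ~ 1
  mt0 <- module_trait(list(mod = e), c(0, 0, 1, -1, 0), design)
  expect_lt(abs(mt0$trait_cor), 1e-8)
  expect_gt(mt0$trait_p, 0.99)
  expect_error(module_trait(list(mod = e), rep(1, 5), design), "constant")
})

test_that("hubs require kME and modules without lncRNAs give no trans pairs", {
  design <- stage_design(5, 3)
  v <- rep(c(2, 1, 0, -1, -2), each = 3)
  set.seed(3)
  m <- rbind(lncA = v, mB = v + rnorm(15, 0, 0.05),
             mC = rnorm(15))
  colnames(m) <- design$sample
  expr <- expr_from_matrix(m, "FPKM")
  members <- c("lncA", "mB", "mC")
  bio <- tibble::tibble(transcript_id = members,
                        biotype = c("lncRNA", "mRNA", "mRNA"))
  e <- eigengene(expr, c("lncA", "mB"))
  res <- hubs_and_trans_targets(expr, members, e, bio)
  expect_true(all(c("lncA", "mB") %in% res$hubs$transcript_id))
  expect_false("mC" %in% res$hubs$transcript_id)
  expect_gte(res$kme$kme[res$kme$transcript_id == "lncA"], 0.99)
  expect_equal(res$trans_pairs$lncrna_id, "lncA")
  expect_equal(res$trans_pairs$mrna_id, "mB")
  # no lncRNA members -> zero trans pairs
  bio2 <- dplyr::mutate(bio, biotype = "mRNA")
  res2 <- hubs_and_trans_targets(expr, members, e, bio2)
  expect_equal(nrow(res2$trans_pairs), 0)
})

test_that("module composition totals equal the biotype split", {
  mods <- tibble::tibble(transcript_id = paste0("t", 1:7),
                         module = c(rep("pink", 4), rep("purple", 3)))
  bio <- tibble::tibble(transcript_id = paste0("t", 1:7),
                        biotype = c("lncRNA", "mRNA", "mRNA", "mRNA",
                                    "lncRNA", "lncRNA", "mRNA"))
  comp <- module_composition(mods, bio)
  expect_equal(comp$n_members, comp$n_lncrna + comp$n_mrna)
})

test_that("planted modules are recovered with matching trait signs", {
  study <- module_study()
  fit <- suppressWarnings(run_coexpr(study$fpkm, study$trait, biotype = study$truth$biotype,
                    design = study$design))
  truth_lab <- setNames(rep("grey", nrow(study$annotation)),
                        study$annotation$transcript_id)
  truth_lab[study$truth$modules$transcript_id] <-
    paste0("M", study$truth$modules$module)
  det <- setNames(fit$modules$module, fit$modules$transcript_id)
  expect_gte(ari(truth_lab[names(det)], det), 0.8)
  for (m in unique(study$truth$modules$module)) {
    mem <- study$truth$modules$transcript_id[study$truth$modules$module == m]
    dm <- names(sort(table(det[mem]), decreasing = TRUE))[1]
    expect_false(dm == "grey")
    sgn <- study$truth$modules$sign[study$truth$modules$module == m][1]
    row <- fit$module_trait[fit$module_trait$module == dm, ]
    expect_equal(sign(row$trait_cor), sgn)
    expect_lte(row$trait_p, 0.05)
  }
})
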