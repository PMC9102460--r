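toy_counts <- function(ca, cb, na = 10000, nb = 10000) {
  m <- rbind(t1 = c(ca, cb), filler = c(na - ca, nb - cb))
  colnames(m) <- c("S1R1", "S2R1")
  expr_from_matrix(m, "counts")
}

test_that("equal proportions give z = 0, p = 1, and stage swap negates z", {
  res <- de_test(toy_counts(20, 20), 1, 2, pseudocount = 0)
  expect_equal(res$z[1], 0)
  expect_equal(res$p[1], 1)
  expect_false(res$significant[1])

  a <- de_test(toy_counts(10, 40), 1, 2, pseudocount = 0)
  b <- de_test(toy_counts(40, 10), 1, 2, pseudocount = 0)
  expect_equal(a$z, -b$z)
  expect_equal(a$p, b$p)
  expect_equal(a$p_adj, b$p_adj)
  expect_identical(a$direction[1], "up")
  expect_identical(b$direction[1], "down")
})

test_that("the toy z-test agrees with the exact binomial oracle", {
  res <- de_test(toy_counts(10, 40), 1, 2, pseudocount = 0)
  t1 <- res[res$transcript_id == "t1", ]
  expect_equal(t1$log2fc, 2)
  # conditional on the 50 pooled counts, the null is Binomial(50, 1/2)
  exact <- stats::binom.test(40, 50, 0.5)$p.value
  expect_lt(t1$p, 1e-4)
  expect_lt(abs(log10(t1$p) - log10(exact)), 0.5)
  expect_true(t1$significant)
})

test_that("de_test validates stages and libraries", {
  cc <- toy_counts(10, 40)
  expect_error(de_test(cc, 1, 7), "absent")
  zero <- expr_from_matrix(matrix(c(0, 0, 5, 5), 2, 2,
                                  dimnames = list(c("a", "b"),
                                                  c("S1R1", "S2R1"))),
                           "counts")
  zero[, 2] <- c(0, 0)
  expect_error(de_test(zero, 1, 2), "zero library")
})

test_that("BH adjustment matches the brute-force step-up rule", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  set.seed(7)
  for (m in 1:6) {
    p <- round(runif(m), 3)
    all_perms <- function(v) {
      if (length(v) == 1) return(list(v))
      out <- list()
      for (i in seq_along(v)) {
        for (rest in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
      }
      out
    }
    for (pp in all_perms(p)) {
      expect_equal(bh_adjust(pp), bh_oracle(pp), tolerance = 1e-12)
    }
    # monotone in raw p
    q <- bh_adjust(p)
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

test_that("tallies conserve and intersections follow set algebra", {
  mk <- function(comp, ids_sig_up, ids_sig_down, ids_ns) {
    tibble::tibble(
      transcript_id = c(ids_sig_up, ids_sig_down, ids_ns),
      comparison = comp,
      direction = c(rep("up", length(ids_sig_up)),
                    rep("down", length(ids_sig_down)),
                    rep("down", length(ids_ns))),
      significant = c(rep(TRUE, length(ids_sig_up) + length(ids_sig_down)),
                      rep(FALSE, length(ids_ns)))
    )
  }
  res <- dplyr::bind_rows(
    mk("S1_vs_S2", c("a", "b"), c("c"), c("x")),
    mk("S1_vs_S3", c("a"), c("c", "d"), c("y"))
  )
  cs <- comparison_sets(res)
  expect_equal(cs$tallies$n_sig, cs$tallies$n_up + cs$tallies$n_down)
  both <- cs$intersections[cs$intersections$size == 2, ]
  expect_equal(both$n_common, 2)  # {a, c}

  # identical significant sets: full intersection equals the common size
  res2 <- dplyr::bind_rows(
    mk("c1", c("a"), c("b", "c"), character(0)),
    mk("c2", c("a"), c("b", "c"), character(0)),
    mk("c3", c("a"), c("b", "c"), character(0))
  )
  cs2 <- comparison_sets(res2)
  expect_equal(cs2$intersections$n_common[cs2$intersections$size == 3], 3)
  # disjoint sets: all multi-way intersections zero
  res3 <- dplyr::bind_rows(
    mk("c1", c("a"), character(0), character(0)),
    mk("c2", c("b"), character(0), character(0))
  )
  cs3 <- comparison_sets(res3)
  expect_equal(cs3$intersections$n_common[cs3$intersections$size == 2], 0)
})

test_that("down-regulated percentage is reported to one decimal", {
  res <- tibble::tibble(
    transcript_id = paste0("t", 1:10),
    comparison = "S1_vs_S3",
    direction = c(rep("up", 3), rep("down", 7)),
    significant = TRUE
  )
  tal <- comparison_sets(res)$tallies
  expect_equal(tal$down_pct, 70)
  expect_equal(tal$up_pct, 30)
})

test_that("planted DE is recovered with high sensitivity", {
  study <- default_study()
  res <- dplyr::bind_rows(lapply(2:5, function(k) {
    de_test(study$counts, 1, k, design = study$design)
  }))
  hit <- dplyr::inner_join(study$truth$de, res,
                           by = c("transcript_id", "comparison"))
  expect_equal(nrow(hit), nrow(study$truth$de))
  expect_gte(mean(hit$significant), 0.9)
  # planted direction matches the called one among significant hits
  ok <- hit$significant
  expect_gt(mean(hit$direction.x[ok] == hit$direction.y[ok]), 0.95)
})

test_that("K-means recovers archetypal profiles and is seed-stable", {
  design <- stage_design(5, 3)
  arch <- rbind(c(5, 0, 0, 0, 0), c(0, 0, 5, 0, 0), c(0, 0, 0, 0, 5))
  m <- arch[rep(1:3, each = 20), rep(1:5, each = 3)]
  m <- 2^m - 1  # log2(FPKM + 1) recovers the archetype exactly
  rownames(m) <- paste0("t", seq_len(nrow(m)))
  colnames(m) <- design$sample
  fpkm <- expr_from_matrix(m, "FPKM")
  cl <- kmeans_profiles(fpkm, rownames(m), k = 3, seed = 1)
  truth <- rep(1:3, each = 20)
  expect_equal(ari(cl$cluster, truth), 1)
  # same seed: identical; different seeds: identical partition
  cl2 <- kmeans_profiles(fpkm, rownames(m), k = 3, seed = 1)
  expect_identical(cl$cluster, cl2$cluster)
  for (s in 2:10) {
    cls <- kmeans_profiles(fpkm, rownames(m), k = 3, seed = s)
    expect_equal(ari(cls$cluster, cl$cluster), 1)
  }
  # labels ordered by descending cluster size
  uneven <- kmeans_profiles(fpkm, rownames(m)[1:50], k = 2, seed = 1)
  expect_gte(sum(uneven$cluster == 1), sum(uneven$cluster == 2))
  # k = 1 puts everything in one cluster
  one <- kmeans_profiles(fpkm, rownames(m), k = 1, seed = 1)
  expect_true(all(one$cluster == 1))
  expect_error(kmeans_profiles(fpkm, rownames(m)[1:2], k = 3, seed = 1), "k")
})
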