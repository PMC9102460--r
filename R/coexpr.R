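## Lightweight weighted co-expression analysis: unsigned soft-threshold
## adjacency, topological overlap, static-cut hierarchical modules,
## eigengenes, module-trait correlation, hubs and trans targets.

## Canonical module color sequence (size rank order).
wgcna_colors <- c(
  "turquoise", "blue", "brown", "yellow", "green", "red", "black", "pink",
  "magenta", "purple", "greenyellow", "tan", "salmon", "cyan",
  "midnightblue", "lightcyan", "grey60", "lightgreen", "lightyellow",
  "royalblue"
)

#' Unsigned soft-threshold adjacency
#'
#' \eqn{a_{ij} = |cor(x_i, x_j)|^\beta} with zero diagonal.
#'
#' @param expr Expression tibble (transcripts x samples).
#' @param beta Positive integer soft-thresholding power.
#' @param cor_matrix Optional precomputed transcript correlation matrix.
#' @return The adjacency matrix.
#' @export
adjacency_matrix <- function(expr, beta, cor_matrix = NULL) {
  if (beta < 1) abort("adjacency_matrix: `beta` must be >= 1")
  if (is.null(cor_matrix)) {
    m <- expr_matrix(expr)
    if (nrow(m) < 3) abort("adjacency_matrix: need at least 3 transcripts")
    cor_matrix <- cor(t(m))
  }
  a <- abs(cor_matrix)^beta
  diag(a) <- 0
  a
}

#' Pick the soft-thresholding power by scale-free topology fit
#'
#' For each candidate power the unsigned adjacency and connectivity
#' \eqn{k_i = \sum_{j \ne i} a_{ij}} are computed; the scale-free fit
#' R-squared is the r-squared of the regression of log10 p(k) on log10 k
#' over connectivity bins. The smallest power reaching `r2_min` is
#' chosen; if none does, the power with maximal fit is returned with a
#' warning.
#'
#' @param expr Expression tibble (>= 8 samples, >= 3 transcripts).
#' @param candidates Candidate powers (default 1:20).
#' @param r2_min Required scale-free fit (default 0.8).
#' @param n_bins Connectivity bins for the fit (default 10).
#' @return A list of class `soft_threshold`: `beta`, `scale_free_r2`,
#'   `mean_connectivity`, and the per-candidate `fit_table`.
#' @export
pick_beta <- function(expr, candidates = 1:20, r2_min = 0.8, n_bins = 10) {
  m <- expr_matrix(expr)
  if (nrow(m) < 3) abort("pick_beta: need at least 3 transcripts")
  if (ncol(m) < 8) abort("pick_beta: need at least 8 samples")
  cm <- cor(t(m))
  fit_one <- function(beta) {
    a <- abs(cm)^beta
    diag(a) <- 0
    k <- rowSums(a)
    ## scale-free fit: log10 p(k) ~ log10 k over equal-width bins
    pos <- k > 0
    if (sum(pos) < 2 || diff(range(k[pos])) == 0) {
      return(c(r2 = 0, mean_k = mean(k)))
    }
    bins <- cut(k[pos], breaks = n_bins)
    pk <- tapply(k[pos], bins, length) / sum(pos)
    mk <- tapply(k[pos], bins, mean)
    ok <- !is.na(pk) & pk > 0 & mk > 0
    if (sum(ok) < 3) return(c(r2 = 0, mean_k = mean(k)))
    fit <- lm(log10(pk[ok]) ~ log10(mk[ok]))
    c(r2 = summary(fit)$r.squared, mean_k = mean(k))
  }
  tab <- t(vapply(candidates, fit_one, c(r2 = 0, mean_k = 0)))
  fit_table <- tibble::tibble(beta = candidates, scale_free_r2 = tab[, "r2"],
                              mean_connectivity = tab[, "mean_k"])
  hit <- which(fit_table$scale_free_r2 >= r2_min)
  if (length(hit) > 0) {
    i <- hit[1]
  } else {
    i <- which.max(fit_table$scale_free_r2)
    warning("pick_beta: no candidate reached r2_min = ", r2_min,
            "; using the best fit (beta = ", fit_table$beta[i], ")")
  }
  structure(list(beta = fit_table$beta[i],
                 scale_free_r2 = fit_table$scale_free_r2[i],
                 mean_connectivity = fit_table$mean_connectivity[i],
                 fit_table = fit_table),
            class = "soft_threshold")
}

#' Topological overlap similarity
#'
#' \eqn{\omega_{ij} = (\ell_{ij} + a_{ij}) / (\min(k_i, k_j) + 1 -
#' a_{ij})} with \eqn{\ell_{ij} = \sum_u a_{iu} a_{uj}}; the diagonal is
#' defined as 1.
#'
#' @param adjacency Symmetric adjacency matrix, zero diagonal, entries in
#'   \[0, 1\].
#' @return The TOM similarity matrix.
#' @export
tom_similarity <- function(adjacency) {
  if (!isSymmetric(unname(adjacency), tol = 1e-10)) {
    abort("tom_similarity: adjacency must be symmetric")
  }
  if (any(diag(adjacency) != 0)) {
    abort("tom_similarity: adjacency diagonal must be zero")
  }
  if (any(adjacency < 0) || any(adjacency > 1)) {
    abort("tom_similarity: adjacency entries must lie in [0, 1]")
  }
  l <- adjacency %*% adjacency
  k <- rowSums(adjacency)
  min_k <- outer(k, k, pmin)
  omega <- (l + adjacency) / (min_k + 1 - adjacency)
  diag(omega) <- 1
  omega
}

#' Detect modules by static-cut hierarchical clustering of 1 - TOM
#'
#' Average-linkage hierarchical clustering on the TOM dissimilarity
#' 1 - \eqn{\omega}, cut statically at `cut_height`; clusters smaller
#' than `min_size` are assigned to `"grey"`. Surviving modules are
#' labelled with the canonical color sequence in order of descending
#' size. Transcripts are sorted lexicographically before clustering so
#' membership does not depend on input order.
#'
#' @param tom TOM similarity matrix with transcript ids as dimnames.
#' @param min_size Minimum module size (>= 2, default 10).
#' @param cut_height Static cut height on the dissimilarity dendrogram
#'   (default 0.7: a transcript cluster survives only where average topological overlap within it exceeds 0.3).
#' @return A tibble: `transcript_id`, `module` (color or `"grey"`).
#' @export
detect_modules <- function(tom, min_size = 10, cut_height = 0.7) {
  if (min_size < 2) abort("detect_modules: `min_size` must be >= 2")
  ids <- rownames(tom)
  if (is.null(ids)) abort("detect_modules: TOM must carry transcript ids as dimnames")
  ord <- order(ids)
  d <- 1 - tom[ord, ord]
  tree <- hclust(as.dist(d), method = "average")
  raw <- cutree(tree, h = cut_height)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_size]
  ## order surviving clusters by descending size, ties by smallest member id
  first_id <- vapply(keep, function(cl) min(ids[ord][raw == cl]), character(1))
  keep <- keep[order(-as.integer(sizes[keep]), first_id)]
  labels <- c(wgcna_colors, paste0("module", seq_len(max(0, length(keep) -
                                                           length(wgcna_colors)))))
  map <- setNames(labels[seq_along(keep)], keep)
  module <- ifelse(as.character(raw) %in% keep, map[as.character(raw)], "grey")
  tibble::tibble(transcript_id = ids[ord], module = unname(module))
}

#' Module eigengene
#'
#' First principal component of the module's standardized expression
#' (samples x members), scaled to unit variance, with the sign chosen so
#' the eigengene correlates positively with the module's mean
#' standardized profile. A single-member module returns that member's
#' standardized profile.
#'
#' @param expr Expression tibble.
#' @param members Transcript ids of the module (non-empty).
#' @return Named per-sample numeric vector with unit variance.
#' @export
eigengene <- function(expr, members) {
  if (length(members) == 0) abort("eigengene: empty module")
  m <- expr_matrix(expr)[members, , drop = FALSE]
  z <- t(scale(t(m)))  # standardize each transcript across samples
  z[is.nan(z)] <- 0    # constant members contribute nothing
  if (length(members) == 1) {
    e <- z[1, ]
  } else {
    pc <- prcomp(t(z), center = FALSE, scale. = FALSE)
    e <- pc$x[, 1]
  }
  if (sd(e) > 0) e <- e / sd(e)
  mean_profile <- colMeans(z)
  if (sum(e * mean_profile) < 0) e <- -e
  setNames(as.numeric(e), colnames(m))
}

#' Module-trait correlation
#'
#' The per-stage trait is expanded to samples through the design (each
#' stage value repeated across its replicates) and Pearson-correlated
#' with each module eigengene; two-sided p-values come from the
#' t-distribution with n - 2 degrees of freedom.
#'
#' @param eigengenes Named list (or matrix, samples x modules) of
#'   eigengenes.
#' @param trait Tibble (`stage`, `temperature`) or numeric per-stage
#'   vector.
#' @param design Design tibble mapping samples to stages.
#' @param alpha Significance level for the `sig` flag (default 0.05).
#' @return A tibble: `module`, `trait_cor`, `trait_p`, `sig`, `direction`.
#' @export
module_trait <- function(eigengenes, trait, design, alpha = 0.05) {
  if (is.matrix(eigengenes)) {
    eigengenes <- setNames(lapply(seq_len(ncol(eigengenes)),
                                  function(j) eigengenes[, j]),
                           colnames(eigengenes))
  }
  tv <- if (is.data.frame(trait)) {
    setNames(trait$temperature, trait$stage)
  } else {
    setNames(trait, seq_along(trait))
  }
  if (length(unique(tv)) == 1) abort("module_trait: constant trait")
  purrr::imap_dfr(eigengenes, function(e, name) {
    samples <- names(e)
    x <- tv[as.character(design$stage[match(samples, design$sample)])]
    ct <- cor.test(e, as.numeric(x), method = "pearson")
    tibble::tibble(module = name,
                   trait_cor = unname(ct$estimate),
                   trait_p = ct$p.value,
                   sig = ct$p.value <= alpha,
                   direction = ifelse(ct$estimate >= 0, "positive", "negative"))
  })
}

#' Hub transcripts and trans-target pairs of a module
#'
#' kME is the correlation of each member's profile with the module
#' eigengene. Hubs are members with kME at least `kme_min`, capped at
#' `top_n` by kME. A trans pair is declared for every lncRNA and mRNA in
#' the module whose kMEs both reach `kme_min` (location-independent).
#'
#' @param expr Expression tibble.
#' @param members Module member ids.
#' @param eg Module eigengene (from [eigengene()]).
#' @param biotype Tibble (`transcript_id`, `biotype`) typing the members.
#' @param kme_min kME threshold (default 0.9).
#' @param top_n Hub cap (default 10).
#' @return A list with `kme` (all members), `hubs`, and `trans_pairs`
#'   (`lncrna_id`, `mrna_id`, both kMEs).
#' @export
hubs_and_trans_targets <- function(expr, members, eg, biotype,
                                   kme_min = 0.9, top_n = 10) {
  m <- expr_matrix(expr)[members, , drop = FALSE]
  kme <- apply(m, 1, function(x) {
    if (sd(x) == 0) return(0)
    cor(x, eg[colnames(m)])
  })
  kme_tbl <- tibble::tibble(transcript_id = members, kme = as.numeric(kme)) |>
    dplyr::left_join(biotype, by = "transcript_id") |>
    dplyr::arrange(dplyr::desc(.data$kme))
  hubs <- kme_tbl |>
    dplyr::filter(.data$kme >= kme_min) |>
    dplyr::slice_head(n = top_n)
  eligible <- dplyr::filter(kme_tbl, .data$kme >= kme_min)
  lnc <- dplyr::filter(eligible, .data$biotype == "lncRNA")
  mrna <- dplyr::filter(eligible, .data$biotype == "mRNA")
  trans_pairs <- tidyr::expand_grid(lncrna_id = lnc$transcript_id,
                                    mrna_id = mrna$transcript_id) |>
    dplyr::mutate(
      lncrna_kme = lnc$kme[match(.data$lncrna_id, lnc$transcript_id)],
      mrna_kme = mrna$kme[match(.data$mrna_id, mrna$transcript_id)]
    )
  list(kme = kme_tbl, hubs = hubs, trans_pairs = trans_pairs)
}

#' Per-module member composition by biotype
#'
#' @param modules Module membership tibble (`transcript_id`, `module`).
#' @param biotype Tibble (`transcript_id`, `biotype`).
#' @return A tibble per module: `n_members`, `n_lncrna`, `n_mrna`
#'   (members typed otherwise are counted in `n_other`).
#' @export
module_composition <- function(modules, biotype) {
  modules |>
    dplyr::left_join(biotype, by = "transcript_id") |>
    dplyr::group_by(.data$module) |>
    dplyr::summarise(
      n_members = dplyr::n(),
      n_lncrna = sum(.data$biotype == "lncRNA", na.rm = TRUE),
      n_mrna = sum(.data$biotype == "mRNA", na.rm = TRUE),
      n_other = .data$n_members - .data$n_lncrna - .data$n_mrna,
      .groups = "drop"
    )
}

#' Run the full co-expression analysis
#'
#' Soft-threshold selection (unless `beta` is fixed), TOM, static-cut
#' module detection, eigengenes, module-trait correlation and per-module
#' hubs/trans targets.
#'
#' @param expr Expression tibble (FPKM recommended; transcripts with zero
#'   variance are dropped before correlation).
#' @param trait Per-stage trait (tibble `stage`/`temperature` or vector).
#' @param biotype Tibble (`transcript_id`, `biotype`).
#' @param design Optional design tibble.
#' @param beta `"auto"` (default) or a fixed power.
#' @param r2_min,min_size,cut_height,kme_min,top_n Tuning parameters, see
#'   the individual operations.
#' @return An object of class `coexpr_fit`: list with `modules`,
#'   `eigengenes` (samples x modules matrix), `module_trait`, `hubs`,
#'   `trans_pairs`, `soft_threshold`, `params`.
#' @export
run_coexpr <- function(expr, trait, biotype, design = NULL, beta = "auto",
                       r2_min = 0.8, min_size = 10, cut_height = 0.7,
                       kme_min = 0.9, top_n = 10) {
  design <- resolve_design(expr, design)
  m <- expr_matrix(expr)
  keep <- apply(m, 1, sd) > 0
  expr_v <- expr[keep, ]
  log_expr <- expr_v
  log_expr[, expr_samples(expr_v)] <- log2(expr_v[, expr_samples(expr_v)] + 1)

  st <- if (identical(beta, "auto")) {
    pick_beta(log_expr, r2_min = r2_min)
  } else {
    structure(list(beta = beta, scale_free_r2 = NA_real_,
                   mean_connectivity = NA_real_, fit_table = NULL),
              class = "soft_threshold")
  }
  a <- adjacency_matrix(log_expr, st$beta)
  tom <- tom_similarity(a)
  modules <- detect_modules(tom, min_size = min_size, cut_height = cut_height)

  mod_names <- setdiff(unique(modules$module), "grey")
  egs <- lapply(mod_names, function(mod) {
    eigengene(log_expr, modules$transcript_id[modules$module == mod])
  })
  names(egs) <- mod_names
  eg_mat <- if (length(egs) > 0) do.call(cbind, egs) else
    matrix(numeric(0), nrow = length(expr_samples(expr)), ncol = 0)

  mt <- if (length(egs) > 0) {
    module_trait(egs, trait, design)
  } else {
    tibble::tibble(module = character(0), trait_cor = numeric(0),
                   trait_p = numeric(0), sig = logical(0),
                   direction = character(0))
  }
  hub_res <- purrr::map(mod_names, function(mod) {
    hubs_and_trans_targets(log_expr,
                           modules$transcript_id[modules$module == mod],
                           egs[[mod]], biotype, kme_min, top_n)
  })
  names(hub_res) <- mod_names
  hubs <- purrr::imap_dfr(hub_res, ~ dplyr::mutate(.x$hubs, module = .y,
                                                   .before = 1))
  trans <- purrr::imap_dfr(hub_res, ~ dplyr::mutate(.x$trans_pairs,
                                                    module = .y, .before = 1))
  structure(list(
    modules = modules, eigengenes = eg_mat, module_trait = mt,
    hubs = hubs, trans_pairs = trans, soft_threshold = st,
    params = list(beta = st$beta, r2_min = r2_min, min_size = min_size,
                  cut_height = cut_height, kme_min = kme_min, top_n = top_n)
  ), class = "coexpr_fit")
}

#' @export
print.coexpr_fit <- function(x, ...) {
  n_mod <- length(setdiff(unique(x$modules$module), "grey"))
  cat("<coexpr_fit> ", nrow(x$modules), " transcripts, ", n_mod,
      " modules (beta = ", x$params$beta, ", cut = ", x$params$cut_height,
      ")\n", sep = "")
  if (nrow(x$module_trait) > 0) {
    print(x$module_trait)
  }
  invisible(x)
}
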