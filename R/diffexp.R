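#' Median-of-ratios size factors
#'
#' Per-sample scaling factors computed against a gene-wise geometric-mean
#' pseudo-reference: for each sample, the factor is the median over genes of
#' `count / reference`, using genes with non-zero counts in every sample.
#' Factors are rescaled to geometric mean 1, so only their ratios are
#' meaningful (sample B with twice sample A's counts gets twice the factor).
#'
#' @param counts count matrix (genes x samples).
#' @param pseudo_reference if TRUE, fall back to a positive-count geometric
#'   mean (computed over the non-zero entries of each gene) when no gene is
#'   non-zero in all samples, instead of failing.
#' @return named numeric vector of positive size factors, geometric mean 1.
#' @export
size_factors <- function(counts, pseudo_reference = FALSE) {
  stopifnot(is.matrix(counts), ncol(counts) >= 1L)
  all_pos <- rowSums(counts == 0) == 0L
  if (!any(all_pos)) {
    if (!pseudo_reference)
      stop("no gene has non-zero counts in all samples; ",
           "re-run with pseudo_reference = TRUE")
    some_pos <- rowSums(counts > 0) > 0L
    log_ref <- apply(counts[some_pos, , drop = FALSE], 1L, function(x)
      mean(log(x[x > 0])))
    sub <- counts[some_pos, , drop = FALSE]
  } else {
    log_ref <- rowMeans(log(counts[all_pos, , drop = FALSE]))
    sub <- counts[all_pos, , drop = FALSE]
  }
  lsf <- apply(log(sub) - log_ref, 2L, function(r)
    median(r[is.finite(r)]))
  sf <- exp(lsf - mean(lsf))
  setNames(sf, colnames(counts))
}

# Gene-wise method-of-moments dispersion on size-factor-normalised counts,
# pooled within groups, with a DESeq-style 1/mean + asymptote trend. With
# >= 3 replicates per group the working dispersion is the maximum of the
# gene estimate and the trend (conservative sharing); with 1-2 replicates
# the gene-wise estimates are too noisy to use individually and the fitted
# trend itself is used, estimated blind across all samples pooled.
estimate_dispersions <- function(norm_counts, group, sf) {
  ng <- nrow(norm_counts)
  groups <- unique(group)
  n_rep <- table(group)[groups]
  # gene-wise estimates come from within-group spread whenever possible so
  # the trend is not inflated by real between-group signal; only with no
  # replication at all is the spread taken blind across every sample
  blind <- all(n_rep < 2L)
  # at 1-2 replicates per group the gene-wise estimates are too noisy to
  # use individually: the fitted trend itself becomes the dispersion
  trend_only <- all(n_rep < 3L)
  if (blind) {
    base_mean <- rowMeans(norm_counts)
    v <- apply(norm_counts, 1L, var)
    xim <- mean(1 / sf)
  } else {
    use <- groups[n_rep >= 2L]
    mats <- lapply(use, function(g) norm_counts[, group == g, drop = FALSE])
    base_mean <- rowMeans(norm_counts)
    # pooled within-group variance
    ssq <- Reduce(`+`, lapply(mats, function(m)
      apply(m, 1L, var) * (ncol(m) - 1L)))
    df <- sum(vapply(mats, ncol, integer(1L))) - length(use)
    v <- ssq / df
    xim <- mean(1 / sf[group %in% use])
  }
  disp_mom <- (v - xim * base_mean) / base_mean^2
  disp_mom[!is.finite(disp_mom)] <- NA

  ok <- is.finite(disp_mom) & disp_mom > 0 & base_mean > 1
  if (sum(ok) >= 10L) {
    fit <- lm(disp_mom[ok] ~ I(1 / base_mean[ok]))
    a0 <- max(coef(fit)[1L], 1e-6)
    a1 <- max(coef(fit)[2L], 0)
  } else {
    a0 <- max(mean(disp_mom[ok], na.rm = TRUE), 0.01)
    if (!is.finite(a0)) a0 <- 0.1
    a1 <- 1
  }
  trend <- a0 + a1 / pmax(base_mean, 1e-8)
  disp <- if (trend_only) trend
          else pmax(ifelse(is.na(disp_mom), trend, disp_mom), trend)
  list(dispersion = pmin(disp, 10), trend = trend, gene_wise = disp_mom,
       base_mean = base_mean, blind = blind, trend_only = trend_only,
       coef = c(asymptote = a0, per_read = a1))
}

# Two-sided exact-style NB test on the group sums of one gene, conditional on
# the total: the sums K_A, K_B are moment-matched to single NB variables and
# every split (a, b) with a + b = K_A + K_B that is no more probable than the
# observed one contributes to the p-value.
nb_exact_p <- function(kA, kB, muA, muB, varA, varB) {
  k <- kA + kB
  if (k == 0L) return(1.0)
  sizeA <- if (varA > muA) muA^2 / (varA - muA) else 1e8
  sizeB <- if (varB > muB) muB^2 / (varB - muB) else 1e8
  a <- 0:k
  pa <- dnbinom(a, mu = muA, size = sizeA)
  pb <- dnbinom(k - a, mu = muB, size = sizeB)
  joint <- pa * pb
  tot <- sum(joint)
  if (tot <= 0) return(1.0)
  p_obs <- joint[kA + 1L]
  min(1, sum(joint[joint <= p_obs * (1 + 1e-7)]) / tot)
}

#' Pairwise negative-binomial differential-expression test
#'
#' A simplified NB test between two temperature groups: counts are
#' normalised by median-of-ratios size factors; gene-wise dispersions are
#' estimated by the method of moments and stabilised against a fitted
#' mean-dispersion trend (with no replication anywhere, the trend is fitted
#' across all samples pooled, blind to the groups); each gene's group sums
#' are then compared by a two-sided conditional exact-style NB test, and
#' Benjamini-Hochberg adjustment is applied within the comparison.
#' Externally computed p-values can be substituted via `pvals` so any DE
#' engine can drive the downstream consistency logic.
#'
#' @param counts count matrix (genes x samples).
#' @param design data.frame with `sample_id` and `group`.
#' @param groupA,groupB group labels to compare; fold changes are A over B.
#' @param alpha adjusted-p significance threshold.
#' @param pvals optional named per-gene p-value vector to use instead of the
#'   internal test (names must match rownames of `counts`).
#' @param pseudo_reference passed to [size_factors()].
#' @return data.frame of class `de_result`: gene_id, base_mean, mean_A,
#'   mean_B, lfc (log2 A/B, moderated by +0.5), p_value, adj_p, significant,
#'   direction (`up_in_A`/`down_in_A`/`none`). Attributes: `comparison`,
#'   `alpha`, `size_factors`.
#' @export
test_pairwise <- function(counts, design, groupA, groupB, alpha = 0.05,
                          pvals = NULL, pseudo_reference = FALSE) {
  for (g in c(groupA, groupB))
    if (!any(design$group == g)) stop("group '", g, "' has no samples")
  sel <- design$group %in% c(groupA, groupB)
  samples <- design$sample_id[sel]
  group <- design$group[sel]
  cm <- counts[, samples, drop = FALSE]

  sf <- size_factors(cm, pseudo_reference = pseudo_reference)
  norm <- sweep(cm, 2L, sf, "/")
  in_A <- group == groupA
  mean_A <- rowMeans(norm[, in_A, drop = FALSE])
  mean_B <- rowMeans(norm[, !in_A, drop = FALSE])
  base_mean <- rowMeans(norm)
  lfc <- log2((mean_A + 0.5) / (mean_B + 0.5))
  all_zero <- rowSums(cm) == 0L

  if (is.null(pvals)) {
    est <- estimate_dispersions(norm, group, sf)
    disp <- est$dispersion
    sfA <- sf[in_A]
    sfB <- sf[!in_A]
    q <- base_mean  # pooled per-gene expression level under the null
    p <- rep(1.0, nrow(cm))
    kA_all <- rowSums(cm[, in_A, drop = FALSE])
    kB_all <- rowSums(cm[, !in_A, drop = FALSE])
    for (i in which(!all_zero)) {
      muA_j <- q[i] * sfA
      muB_j <- q[i] * sfB
      varA <- sum(muA_j + disp[i] * muA_j^2)
      varB <- sum(muB_j + disp[i] * muB_j^2)
      p[i] <- nb_exact_p(kA_all[i], kB_all[i], sum(muA_j), sum(muB_j),
                         varA, varB)
    }
  } else {
    if (is.null(names(pvals)) || !all(rownames(cm) %in% names(pvals)))
      stop("'pvals' must be named for every gene in 'counts'")
    p <- unname(pvals[rownames(cm)])
    est <- NULL
  }

  adj <- rep(NA_real_, length(p))
  testable <- !all_zero
  adj[testable] <- p.adjust(p[testable], method = "BH")
  adj[all_zero] <- 1
  p[all_zero] <- 1
  if (any(all_zero))
    message(sum(all_zero), " all-zero gene(s) excluded from the BH denominator")

  significant <- adj < alpha
  direction <- ifelse(!significant | lfc == 0, "none",
                      ifelse(lfc > 0, "up_in_A", "down_in_A"))
  res <- data.frame(gene_id = rownames(cm), base_mean = base_mean,
                    mean_A = mean_A, mean_B = mean_B, lfc = lfc,
                    p_value = p, adj_p = adj, significant = significant,
                    direction = direction, stringsAsFactors = FALSE,
                    row.names = NULL)
  structure(res, comparison = c(groupA, groupB), alpha = alpha,
            size_factors = sf, dispersion_fit = est,
            class = c("de_result", "data.frame"))
}

#' Genes differentially expressed in all low-vs-high comparisons
#'
#' The consistency filter: given one DE result per comparison of a low
#' temperature group against each high group, returns the genes significant
#' in every comparison, with their per-comparison directions and a flag for
#' a consistent sign across all of them. Restricting to such genes lowers
#' the false-positive rate of the candidate cold-acclimation list.
#'
#' @param de_results named list of `de_result` objects (one per high group),
#'   all over the same gene universe, each with fold change low-over-high.
#' @param low_group label of the low group (recorded in the output).
#' @return data.frame of class `consistent_degs`: gene_id, one direction
#'   column per comparison, `consistent_direction`, `direction` (the shared
#'   sign where consistent, else `"mixed"`).
#' @export
consistent_degs <- function(de_results, low_group = "low") {
  stopifnot(length(de_results) >= 1L)
  universes <- lapply(de_results, `[[`, "gene_id")
  for (i in seq_along(universes))
    if (!identical(sort(universes[[1L]]), sort(universes[[i]])))
      stop("DE results have mismatched gene universes")
  if (is.null(names(de_results)))
    names(de_results) <- paste0("cmp", seq_along(de_results))

  sig_sets <- lapply(de_results, function(d) d$gene_id[d$significant])
  members <- sort(Reduce(intersect, sig_sets))
  dirs <- matrix(NA_character_, nrow = length(members),
                 ncol = length(de_results),
                 dimnames = list(NULL, names(de_results)))
  for (nm in names(de_results)) {
    d <- de_results[[nm]]
    dirs[, nm] <- d$direction[match(members, d$gene_id)]
  }
  consistent <- if (length(members))
    apply(dirs, 1L, function(r) length(unique(r)) == 1L) else logical(0)
  shared <- if (length(members))
    ifelse(consistent, dirs[, 1L], "mixed") else character(0)
  out <- data.frame(gene_id = members, stringsAsFactors = FALSE)
  for (nm in names(de_results)) out[[paste0("dir_", nm)]] <- dirs[, nm]
  out$consistent_direction <- consistent
  out$direction <- shared
  structure(out, low_group = low_group, high_groups = names(de_results),
            class = c("consistent_degs", "data.frame"))
}

#' Overlap report between two consistent DEG sets
#'
#' Summarises how the consistent DEG sets of two low-temperature groups
#' relate: set sizes, their intersection, and how many members of each set
#' are also significant in the direct comparison between the two low groups.
#' When the per-comparison DE results are supplied, Venn membership-pattern
#' counts across the high-group comparisons are included for each set.
#'
#' @param set_a,set_b `consistent_degs` objects (or character vectors).
#' @param de_direct optional `de_result` for the direct low-vs-low comparison.
#' @param de_results_a,de_results_b optional named lists of `de_result`
#'   objects used to build each set (for the Venn pattern counts).
#' @return list with counts (`n_a`, `n_b`, `n_intersect`,
#'   `n_a_sig_direct`, `n_b_sig_direct`), the shared gene ids, and optional
#'   `venn_a`/`venn_b` pattern tables.
#' @export
overlap_analysis <- function(set_a, set_b, de_direct = NULL,
                             de_results_a = NULL, de_results_b = NULL) {
  ids_a <- if (is.data.frame(set_a)) set_a$gene_id else set_a
  ids_b <- if (is.data.frame(set_b)) set_b$gene_id else set_b
  shared <- intersect(ids_a, ids_b)
  out <- list(n_a = length(ids_a), n_b = length(ids_b),
              n_intersect = length(shared), shared_gene_ids = sort(shared))
  if (!is.null(de_direct)) {
    sig_direct <- de_direct$gene_id[de_direct$significant]
    out$n_a_sig_direct <- length(intersect(ids_a, sig_direct))
    out$n_b_sig_direct <- length(intersect(ids_b, sig_direct))
  }
  venn <- function(de_list) {
    sets <- lapply(de_list, function(d) d$gene_id[d$significant])
    all_ids <- sort(unique(unlist(sets)))
    if (!length(all_ids)) return(table(factor(character(0))))
    pattern <- apply(
      sapply(sets, function(s) all_ids %in% s), 1L,
      function(r) paste(names(de_list)[r], collapse = "&"))
    table(pattern)
  }
  if (!is.null(de_results_a)) out$venn_a <- venn(de_results_a)
  if (!is.null(de_results_b)) out$venn_b <- venn(de_results_b)
  out
}

#' Export a log10(FPKM + 1) matrix for a gene set
#'
#' Plain heatmap-ready export of the expression of selected genes (rows)
#' across samples, on the log10(FPKM + 1) scale.
#'
#' @param fpkm FPKM matrix.
#' @param gene_ids genes to include (order preserved).
#' @return numeric matrix `log10(FPKM + 1)` restricted to `gene_ids`.
#' @export
deg_expression_matrix <- function(fpkm, gene_ids) {
  missing <- setdiff(gene_ids, rownames(fpkm))
  if (length(missing))
    stop("gene(s) absent from FPKM matrix: ", paste(head(missing, 5L),
                                                    collapse = ", "))
  log10(fpkm[gene_ids, , drop = FALSE] + 1)
}
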