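# Build a genes-in-rows logical membership matrix from a go_annotation (or
# a plain data.frame with gene_id/go_id) restricted to a background set.
membership_matrix <- function(annotation, background) {
  g2g <- if (inherits(annotation, "go_annotation")) annotation$gene2group
         else annotation
  # the group universe comes from the full annotation, so groups with no
  # background gene keep an (all-zero) column
  groups <- if (inherits(annotation, "go_annotation"))
    annotation$groups$go_id else sort(unique(g2g$go_id))
  g2g <- g2g[g2g$gene_id %in% background, , drop = FALSE]
  m <- matrix(FALSE, nrow = length(background), ncol = length(groups),
              dimnames = list(background, groups))
  if (nrow(g2g))
    m[cbind(match(g2g$gene_id, background), match(g2g$go_id, groups))] <- TRUE
  m
}

#' Null distribution of per-group gene counts under random sampling
#'
#' Draws `n_iter` random gene sets of size `sample_size` from the
#' expressed-gene background (without replacement by default) and counts,
#' for each functional group, how many drawn genes carry the group. These
#' null counts are what an observed DEG count is compared against.
#'
#' @param background character vector of background (expressed) gene ids.
#' @param annotation a `go_annotation` or data.frame with gene_id/go_id;
#'   background genes without any group are allowed and count in no group.
#' @param sample_size genes per draw (the number of DEGs).
#' @param n_iter number of random draws.
#' @param seed RNG seed.
#' @param replace draw with replacement instead (the without-replacement
#'   default makes the hypergeometric distribution the exact reference).
#' @return integer matrix, `n_iter` x groups, of null counts.
#' @export
resample_null <- function(background, annotation, sample_size,
                          n_iter = 10000L, seed = 1L, replace = FALSE) {
  n_bg <- length(background)
  if (n_bg == 0L) stop("empty background")
  if (!replace && sample_size > n_bg)
    stop("sample_size (", sample_size, ") exceeds background size (", n_bg, ")")
  m <- membership_matrix(annotation, background)
  set.seed(seed)
  idx <- matrix(0L, nrow = sample_size, ncol = n_iter)
  for (it in seq_len(n_iter))
    idx[, it] <- sample.int(n_bg, sample_size, replace = replace)
  iter_of <- rep(seq_len(n_iter), each = sample_size)
  genevec <- as.vector(idx)
  counts <- matrix(0L, nrow = n_iter, ncol = ncol(m),
                   dimnames = list(NULL, colnames(m)))
  for (j in seq_len(ncol(m))) {
    hit <- m[genevec, j]
    counts[, j] <- tabulate(iter_of[hit], nbins = n_iter)
  }
  counts
}

#' Resampling significance test for GO functional groups among DEGs
#'
#' For each functional group, the observed number of DEGs carrying the group
#' is compared with the counts obtained by randomly sampling gene sets of
#' the same size from all expressed genes (`n_iter` draws). The empirical
#' two-sided p-value is `2 * min(P(X <= obs), P(X >= obs))` with add-one
#' smoothing `(extreme + 1) / (n_iter + 1)` per tail, capped at 1.
#' Significance uses a Bonferroni-corrected level `alpha / m`, where `m` is
#' the number of groups with at least one background gene; the direction
#' records whether the group is over- (`higher`) or under-represented
#' (`lower`) among the DEGs relative to the null mean.
#'
#' @param deg_set character vector of DEG ids (must lie in `background`).
#' @param background expressed-gene background ids.
#' @param annotation a `go_annotation` or gene_id/go_id data.frame.
#' @param n_iter resampling iterations.
#' @param alpha family-wise significance level before Bonferroni division.
#' @param seed RNG seed.
#' @param replace passed to [resample_null()].
#' @return data.frame of class `enrichment_result`: go_id, namespace,
#'   group_size (background genes in group), observed, null_mean, null_sd,
#'   emp_p, bonferroni_alpha, significant, direction. Attributes `n_iter`,
#'   `seed`, `m_tests`.
#' @export
enrichment_test <- function(deg_set, background, annotation,
                            n_iter = 10000L, alpha = 0.05, seed = 1L,
                            replace = FALSE) {
  if (length(deg_set) == 0L) stop("empty DEG set")
  if (length(background) == 0L) stop("empty background")
  if (!all(deg_set %in% background))
    stop("DEG set contains genes outside the background")
  m <- membership_matrix(annotation, background)
  bg_size <- colSums(m)
  tested <- bg_size >= 1L
  m_tests <- sum(tested)
  if (m_tests == 0L) stop("no functional group has background genes")

  null_counts <- resample_null(background, annotation, length(deg_set),
                               n_iter = n_iter, seed = seed, replace = replace)
  obs <- colSums(m[deg_set, , drop = FALSE])
  null_mean <- colMeans(null_counts)
  null_sd <- apply(null_counts, 2L, sd)

  p_low <- (colSums(sweep(null_counts, 2L, obs, "<=")) + 1) / (n_iter + 1)
  p_up <- (colSums(sweep(null_counts, 2L, obs, ">=")) + 1) / (n_iter + 1)
  emp_p <- pmin(1, 2 * pmin(p_low, p_up))
  bonf <- alpha / m_tests

  ns <- if (inherits(annotation, "go_annotation"))
    annotation$groups$namespace[match(colnames(m), annotation$groups$go_id)]
  else rep(NA_character_, ncol(m))

  res <- data.frame(go_id = colnames(m), namespace = ns,
                    group_size = as.integer(bg_size),
                    observed = as.integer(obs),
                    null_mean = null_mean, null_sd = null_sd,
                    emp_p = emp_p, bonferroni_alpha = bonf,
                    significant = tested & emp_p < bonf,
                    direction = ifelse(obs > null_mean, "higher", "lower"),
                    stringsAsFactors = FALSE, row.names = NULL)
  res <- res[tested, , drop = FALSE]
  rownames(res) <- NULL
  structure(res, n_iter = n_iter, seed = seed, m_tests = m_tests,
            sample_size = length(deg_set), background_size = length(background),
            class = c("enrichment_result", "data.frame"))
}

#' Exact hypergeometric two-sided p-value
#'
#' The exact reference for the without-replacement resampling null: with
#' `group_size` annotated genes in a background of `background_size`, and a
#' random sample of `sample_size`, the in-group count is hypergeometric.
#' Returns `2 * min(P(X <= obs), P(X >= obs))` capped at 1.
#'
#' @param obs observed in-group count.
#' @param group_size annotated genes in the background.
#' @param background_size background size.
#' @param sample_size sample (DEG-set) size.
#' @return exact two-sided p-value.
#' @export
hypergeom_pvalue <- function(obs, group_size, background_size, sample_size) {
  if (group_size > background_size || sample_size > background_size)
    stop("inconsistent sizes: group and sample must fit in the background")
  if (obs < max(0L, sample_size - (background_size - group_size)) ||
      obs > min(group_size, sample_size))
    stop("inconsistent sizes: 'obs' outside the hypergeometric support")
  lower <- phyper(obs, group_size, background_size - group_size, sample_size)
  upper <- phyper(obs - 1, group_size, background_size - group_size,
                  sample_size, lower.tail = FALSE)
  min(1, 2 * min(lower, upper))
}

#' Per-group annotation percentages for one or more gene sets
#'
#' The classification bar-chart table: for each functional group (grouped by
#' namespace) and each named gene set, the percentage of the set's genes
#' annotated to the group, with significance markers joined from an
#' [enrichment_test()] result where supplied.
#'
#' @param annotation a `go_annotation` or gene_id/go_id data.frame.
#' @param gene_sets named list of character vectors (e.g. list(all = ...,
#'   DEG = ...)).
#' @param enrichment optional `enrichment_result` whose `significant` and
#'   `direction` columns are joined as a star column.
#' @return data.frame: go_id, namespace, one percentage column per set, and
#'   (if `enrichment` given) `star` (`"*higher"`, `"*lower"` or `""`).
#' @export
go_class_table <- function(annotation, gene_sets, enrichment = NULL) {
  stopifnot(is.list(gene_sets), !is.null(names(gene_sets)))
  universe <- unique(unlist(gene_sets))
  m <- membership_matrix(annotation, universe)
  ns <- if (inherits(annotation, "go_annotation"))
    annotation$groups$namespace[match(colnames(m), annotation$groups$go_id)]
  else rep(NA_character_, ncol(m))
  out <- data.frame(go_id = colnames(m), namespace = ns,
                    stringsAsFactors = FALSE)
  for (nm in names(gene_sets)) {
    s <- gene_sets[[nm]]
    out[[paste0("pct_", nm)]] <- if (length(s))
      100 * colSums(m[s, , drop = FALSE]) / length(s) else 0
  }
  if (!is.null(enrichment)) {
    i <- match(out$go_id, enrichment$go_id)
    out$star <- ifelse(!is.na(i) & enrichment$significant[i],
                       paste0("*", enrichment$direction[i]), "")
  }
  out[order(out$namespace, out$go_id), , drop = FALSE]
}
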