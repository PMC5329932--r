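#' FPKM from a fragment-count matrix
#'
#' Fragments per kilobase of transcript per million mapped fragments:
#' `FPKM[g,s] = count[g,s] * 1e9 / (length[g] * total[s])`, where `total[s]`
#' is the sample's total fragment count. Full transcript length is used, not
#' effective length.
#'
#' @param counts non-negative integer matrix, genes x samples, with rownames.
#' @param lengths per-gene transcript length in bases (named, or in row order).
#' @return numeric matrix of FPKM values, same shape as `counts`.
#' @export
compute_fpkm <- function(counts, lengths) {
  stopifnot(is.matrix(counts), all(counts >= 0))
  if (!is.null(names(lengths)) && !is.null(rownames(counts)))
    lengths <- lengths[rownames(counts)]
  if (length(lengths) != nrow(counts))
    stop("'lengths' must have one entry per gene")
  if (any(lengths <= 0)) stop("gene lengths must be positive")
  totals <- colSums(counts)
  zero <- totals == 0
  if (any(zero))
    stop("sample(s) with zero total count: ",
         paste(colnames(counts)[zero], collapse = ", "))
  sweep(counts / lengths, 2, totals, "/") * 1e9
}

#' Sequencing-depth saturation diagnostic
#'
#' Asks at what fraction of sequencing depth FPKM estimates stabilise: for
#' each percentage `p` of the library, per-gene counts are thinned binomially
#' at rate `p/100` (the gene-level equivalent of uniformly subsampling mapped
#' reads), FPKM is recomputed on the thinned library, and the fraction of
#' genes whose thinned FPKM lies within `tolerance` (relative) of the
#' full-depth FPKM is recorded, averaged over `n_reps` thinning replicates.
#' A curve that flattens near 1 indicates sufficient depth; restricting to
#' genes above an FPKM floor (`fpkm_threshold`) shows where well-expressed
#' genes saturate.
#'
#' @param counts count matrix (genes x samples).
#' @param lengths per-gene lengths (bases).
#' @param sample_id column to diagnose.
#' @param percentages increasing grid in (0, 100].
#' @param tolerance relative tolerance around the full-depth value (0.10 =
#'   within 10 percent).
#' @param fpkm_threshold genes with full-depth FPKM <= this are excluded when
#'   the threshold is > 0.
#' @param n_reps thinning replicates per percentage.
#' @param seed RNG seed for the thinning draws.
#' @return data.frame with columns `percentage` and `fraction_within`;
#'   attribute `n_genes` gives the size of the included gene set.
#' @export
saturation_curve <- function(counts, lengths, sample_id,
                             percentages = seq(5, 100, by = 5),
                             tolerance = 0.10, fpkm_threshold = 0,
                             n_reps = 10L, seed = 1L) {
  stopifnot(sample_id %in% colnames(counts))
  if (is.unsorted(percentages, strictly = TRUE) ||
      any(percentages <= 0 | percentages > 100))
    stop("'percentages' must be strictly increasing within (0, 100]")
  if (!is.null(names(lengths)) && !is.null(rownames(counts)))
    lengths <- lengths[rownames(counts)]
  x <- counts[, sample_id]
  lengths <- as.numeric(lengths)
  total <- as.numeric(sum(x))
  if (total == 0) stop("sample ", sample_id, " has zero total count")
  final_fpkm <- x * 1e9 / (lengths * total)
  keep <- if (fpkm_threshold > 0) final_fpkm > fpkm_threshold
          else rep(TRUE, length(x))
  if (!any(keep)) stop("no genes pass the FPKM threshold ", fpkm_threshold)
  xk <- x[keep]
  lk <- lengths[keep]
  fk <- final_fpkm[keep]

  set.seed(seed)
  frac <- vapply(percentages, function(p) {
    if (p == 100) return(1.0)
    rate <- p / 100
    mean(vapply(seq_len(n_reps), function(r) {
      thinned <- rbinom(length(xk), xk, rate)
      tt <- as.numeric(sum(thinned))
      if (tt == 0) return(mean(fk == 0))
      fpkm_t <- thinned * 1e9 / (lk * tt)
      mean(abs(fpkm_t - fk) <= tolerance * fk)
    }, numeric(1L)))
  }, numeric(1L))
  structure(data.frame(percentage = percentages, fraction_within = frac),
            n_genes = sum(keep), sample_id = sample_id,
            tolerance = tolerance, fpkm_threshold = fpkm_threshold)
}

#' Per-group density summary of log10 gene expression
#'
#' Summarises, for each temperature group, the distribution over genes of
#' log10 group-mean FPKM (genes with zero group-mean FPKM excluded), as a
#' normalised histogram on one fixed grid so groups are directly comparable.
#'
#' @param fpkm FPKM matrix (genes x samples).
#' @param design data.frame with `sample_id` and `group` covering all columns.
#' @param breaks histogram breaks on the log10 scale, or a number of bins.
#' @return long data.frame: group, bin midpoint, proportion of the group's
#'   expressed genes in the bin.
#' @export
density_summary <- function(fpkm, design, breaks = 40L) {
  if (!all(colnames(fpkm) %in% design$sample_id))
    stop("design does not cover all samples in the FPKM matrix")
  groups <- unique(design$group)
  means <- sapply(groups, function(g) {
    cols <- design$sample_id[design$group == g]
    rowMeans(fpkm[, cols, drop = FALSE])
  })
  logvals <- log10(means)
  logvals[!is.finite(logvals)] <- NA
  rng <- range(logvals, na.rm = TRUE)
  if (length(breaks) == 1L)
    breaks <- seq(rng[1] - 1e-9, rng[2] + 1e-9, length.out = breaks + 1L)
  mids <- (head(breaks, -1L) + breaks[-1L]) / 2
  out <- do.call(rbind, lapply(groups, function(g) {
    v <- logvals[, g]
    v <- v[!is.na(v)]
    h <- hist(v, breaks = breaks, plot = FALSE)
    data.frame(group = g, log10_fpkm = mids,
               proportion = h$counts / max(1L, length(v)),
               stringsAsFactors = FALSE)
  }))
  attr(out, "group_means") <- colMeans(logvals, na.rm = TRUE)
  out
}

#' Relative expression by the 2^-ddCq method
#'
#' For each target gene and sample, `dCq = Cq_target - Cq_reference` within
#' the sample; `ddCq = dCq - mean dCq` of the calibrator-condition samples
#' for that gene; relative expression is `2^-ddCq` (1 in the calibrator by
#' construction when a single calibrator sample is used).
#'
#' @param cq data.frame with columns `sample_id`, `gene_id`, `Cq`, `role`
#'   (`"target"` or `"reference"`) and `condition`.
#' @param calibrator_condition value of `condition` identifying the
#'   calibrator samples.
#' @return data.frame: gene_id, sample_id, condition, dCq, ddCq, rel_expr.
#' @export
ddcq <- function(cq, calibrator_condition) {
  need <- c("sample_id", "gene_id", "Cq", "role", "condition")
  if (!all(need %in% names(cq)))
    stop("Cq table must have columns: ", paste(need, collapse = ", "))
  refs <- cq[cq$role == "reference", ]
  if (nrow(refs) == 0L) stop("no reference-gene Cq entries present")
  ref_cq <- tapply(refs$Cq, refs$sample_id, mean)
  targets <- cq[cq$role == "target", ]
  missing_ref <- setdiff(unique(targets$sample_id), names(ref_cq))
  if (length(missing_ref))
    stop("sample(s) lack a reference Cq: ", paste(missing_ref, collapse = ", "))
  targets$dCq <- targets$Cq - as.numeric(ref_cq[targets$sample_id])

  cal <- targets[targets$condition == calibrator_condition, ]
  if (nrow(cal) == 0L)
    stop("no samples with calibrator condition '", calibrator_condition, "'")
  cal_dcq <- tapply(cal$dCq, cal$gene_id, mean)
  missing_cal <- setdiff(unique(targets$gene_id), names(cal_dcq))
  if (length(missing_cal))
    stop("gene(s) lack a calibrator entry: ",
         paste(missing_cal, collapse = ", "))
  targets$ddCq <- targets$dCq - as.numeric(cal_dcq[targets$gene_id])
  targets$rel_expr <- 2^(-targets$ddCq)
  targets[, c("gene_id", "sample_id", "condition", "dCq", "ddCq", "rel_expr")]
}

#' @importFrom graphics hist
NULL
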