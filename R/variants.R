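# sample ids carried by a site table (columns ref_<s> / alt_<s>)
site_samples <- function(sites) {
  s <- attr(sites, "samples")
  if (!is.null(s)) return(s)
  sub("^ref_", "", grep("^ref_", names(sites), value = TRUE))
}

as_site_table <- function(df, samples = NULL) {
  structure(df, samples = samples %||% site_samples(df),
            class = c("site_table", "data.frame"))
}

#' Quality-filter variant records
#'
#' Retains records with `QUAL >= qual_min` and `QD >= qd_min` (both
#' thresholds inclusive); a record failing either threshold is removed.
#' Records lacking a QUAL or QD value pass with a warning.
#'
#' @param sites a `site_table` (data.frame with qual and qd columns).
#' @param qual_min,qd_min inclusive retention thresholds.
#' @return the filtered `site_table`.
#' @export
quality_filter <- function(sites, qual_min = 30.0, qd_min = 5.0) {
  if (nrow(sites) == 0L) return(sites)
  missing <- is.na(sites$qual) | is.na(sites$qd)
  if (any(missing))
    warning(sum(missing), " record(s) lack QUAL/QD and pass unfiltered")
  keep <- missing | (sites$qual >= qual_min & sites$qd >= qd_min)
  as_site_table(sites[keep, , drop = FALSE])
}

#' Select biallelic, well-covered sites for genotyping
#'
#' Keeps sites with at most `max_alleles` observed alleles and a total read
#' depth of at least `min_reads_per_sample` in every sample (or, with
#' `min_samples_covered`, in at least that many samples), so that every tip
#' of the genetic-structure tree can be genotyped.
#'
#' @param sites a `site_table`.
#' @param max_alleles maximum observed alleles (ref + alt with reads).
#' @param min_reads_per_sample minimum per-sample total depth.
#' @param min_samples_covered if not NULL, relax the depth rule to this many
#'   samples instead of all of them.
#' @return the filtered `site_table`.
#' @export
select_sites <- function(sites, max_alleles = 2L, min_reads_per_sample = 6L,
                         min_samples_covered = NULL) {
  if (nrow(sites) == 0L) return(sites)
  samples <- site_samples(sites)
  refm <- as.matrix(sites[, paste0("ref_", samples), drop = FALSE])
  altm <- as.matrix(sites[, paste0("alt_", samples), drop = FALSE])
  n_alleles <- (rowSums(refm) > 0) + (rowSums(altm) > 0)
  # multi-allelic inputs may list extra alleles comma-separated in `alt`
  extra <- lengths(strsplit(sites$alt, ",", fixed = TRUE)) - 1L
  n_alleles <- n_alleles + extra
  depth_ok_n <- rowSums(refm + altm >= min_reads_per_sample)
  need <- min_samples_covered %||% length(samples)
  keep <- n_alleles <= max_alleles & depth_ok_n >= need
  as_site_table(sites[keep, , drop = FALSE])
}

#' Genotype one or more samples at biallelic sites with IUPAC codes
#'
#' A sample is called heterozygous (the two-allele ambiguity code) when both
#' alleles are seen at a fraction of the site depth of at least
#' `het_min_fraction`; otherwise the majority allele's base is called.
#'
#' @param ref,alt single-base allele vectors (recycled per site).
#' @param ref_depth,alt_depth read depths supporting each allele.
#' @param het_min_fraction minimum minor-allele fraction for a heterozygous
#'   call.
#' @return character vector of IUPAC codes (A,C,G,T,R,Y,S,W,K,M).
#' @export
call_iupac <- function(ref, alt, ref_depth, alt_depth,
                       het_min_fraction = 0.2) {
  n <- max(length(ref_depth), length(alt_depth))
  total <- ref_depth + alt_depth
  if (any(total == 0))
    stop("zero-depth genotype call requested; filter sites first")
  frac_ref <- ref_depth / total
  frac_alt <- alt_depth / total
  het <- frac_ref >= het_min_fraction & frac_alt >= het_min_fraction
  out <- ifelse(het, iupac_pair_codes[paste0(ref, alt)],
                ifelse(ref_depth >= alt_depth, ref, alt))
  unname(out)
}

#' Build a samples x sites IUPAC genotype matrix
#'
#' Genotypes every sample at every (optionally subsampled) site and returns
#' the matrix that feeds distance/tree construction and the NEXUS/PHYLIP/
#' FASTA exports. Sites are ordered by (gene_id, pos); the subsample is
#' uniform without replacement.
#'
#' @param sites a filtered, biallelic `site_table` (only single-base
#'   ref/alt records are genotyped; others are dropped with a message).
#' @param n_subsample number of sites to draw (NULL = all).
#' @param seed RNG seed for the subsample.
#' @param het_min_fraction passed to [call_iupac()].
#' @return character matrix of class `genotype_matrix`, samples in rows,
#'   site ids (`gene:pos`) in columns.
#' @export
build_genotype_matrix <- function(sites, n_subsample = NULL, seed = 1L,
                                  het_min_fraction = 0.2) {
  snp <- nchar(sites$ref) == 1L & nchar(sites$alt) == 1L
  if (!all(snp)) {
    message(sum(!snp), " non-SNP record(s) dropped from the genotype matrix")
    sites <- as_site_table(sites[snp, , drop = FALSE])
  }
  if (!is.null(n_subsample)) {
    if (n_subsample > nrow(sites))
      stop("n_subsample (", n_subsample, ") exceeds the ", nrow(sites),
           " eligible sites")
    set.seed(seed)
    sites <- as_site_table(sites[sample.int(nrow(sites), n_subsample), ,
                                 drop = FALSE])
  }
  ord <- order(sites$gene_id, sites$pos)
  sites <- sites[ord, , drop = FALSE]
  samples <- site_samples(sites)
  m <- matrix(NA_character_, nrow = length(samples), ncol = nrow(sites),
              dimnames = list(samples, paste0(sites$gene_id, ":", sites$pos)))
  for (s in samples) {
    m[s, ] <- call_iupac(sites$ref, sites$alt,
                         sites[[paste0("ref_", s)]],
                         sites[[paste0("alt_", s)]],
                         het_min_fraction = het_min_fraction)
  }
  structure(m, class = c("genotype_matrix", class(m)))
}

#' @rdname build_genotype_matrix
#' @param x a `genotype_matrix`.
#' @param file output path.
#' @export
write_genotype_nexus <- function(x, file) {
  ape::write.nexus.data(split(x, row(x)) |>
                          setNames(rownames(x)) |>
                          lapply(tolower),
                        file = file, format = "dna", interleaved = FALSE)
  # drop the writer's timestamp comment so identical matrices give
  # byte-identical files
  lines <- readLines(file)
  lines <- lines[!grepl("^\\[Data written by", lines)]
  writeLines(lines, file)
  invisible(file)
}

#' @rdname build_genotype_matrix
#' @export
read_genotype_nexus <- function(file) {
  d <- ape::read.nexus.data(file)
  m <- do.call(rbind, lapply(d, function(s) toupper(s)))
  structure(m, class = c("genotype_matrix", class(m)))
}

#' @rdname build_genotype_matrix
#' @export
write_genotype_fasta <- function(x, file) {
  seqs <- apply(x, 1L, paste, collapse = "")
  writeLines(paste0(">", rownames(x), "\n", seqs), file)
  invisible(file)
}

#' @rdname build_genotype_matrix
#' @export
write_genotype_phylip <- function(x, file) {
  lines <- c(paste(nrow(x), ncol(x)),
             paste(format(rownames(x), width = 10L),
                   apply(x, 1L, paste, collapse = "")))
  writeLines(lines, file)
  invisible(file)
}

#' Classify coding effects of SNPs against CDS annotations
#'
#' For each single-base variant falling inside an annotated CDS, substitutes
#' the alternate base into its codon (honouring strand by reverse
#' complementation) and compares the translated amino acids under the
#' standard genetic code. Variants outside every CDS are `non_coding`.
#' A CDS whose length is not a multiple of 3 triggers a warning and its
#' trailing partial codon is ignored.
#'
#' @param sites a `site_table` (non-SNP records are skipped).
#' @param sequences named character vector of transcript sequences.
#' @param cds data.frame: seq_id, start, end, strand (1-based inclusive,
#'   start codon at `start` for `+`, at `end` for `-`).
#' @return data.frame: gene_id, pos, ref, alt, effect
#'   (synonymous/non_synonymous/non_coding), codon_ref, codon_alt, aa_ref,
#'   aa_alt.
#' @export
coding_effect <- function(sites, sequences, cds) {
  snp <- nchar(sites$ref) == 1L & nchar(sites$alt) == 1L
  sites <- sites[snp, , drop = FALSE]
  gc_map <- Biostrings::GENETIC_CODE
  translate1 <- function(codon) unname(gc_map[codon])

  bad_len <- (cds$end - cds$start + 1L) %% 3L != 0L
  if (any(bad_len))
    warning(sum(bad_len), " CDS record(s) have length not divisible by 3; ",
            "trailing partial codons ignored")

  n <- nrow(sites)
  effect <- rep("non_coding", n)
  codon_ref <- codon_alt <- aa_ref <- aa_alt <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    g <- sites$gene_id[i]
    pos <- sites$pos[i]
    hits <- cds[cds$seq_id == g & cds$start <= pos & cds$end >= pos, ,
                drop = FALSE]
    if (nrow(hits) == 0L || is.na(match(g, names(sequences)))) next
    h <- hits[1L, ]
    seq <- sequences[[g]]
    n_codons <- (h$end - h$start + 1L) %/% 3L
    if (h$strand == "+") {
      offset <- pos - h$start
      ci <- offset %/% 3L
      if (ci >= n_codons) next  # trailing partial codon
      cstart <- h$start + 3L * ci
      codon <- substr(seq, cstart, cstart + 2L)
      within <- offset %% 3L + 1L
      calt <- codon
      substr(calt, within, within) <- sites$alt[i]
    } else {
      offset <- h$end - pos
      ci <- offset %/% 3L
      if (ci >= n_codons) next
      cend <- h$end - 3L * ci
      codon_fwd <- substr(seq, cend - 2L, cend)
      codon <- reverse_complement(codon_fwd)
      within <- offset %% 3L + 1L
      calt <- codon
      substr(calt, within, within) <- reverse_complement(sites$alt[i])
    }
    a1 <- translate1(codon)
    a2 <- translate1(calt)
    if (is.na(a1) || is.na(a2)) next  # ambiguous bases in the codon
    effect[i] <- if (a1 == a2) "synonymous" else "non_synonymous"
    codon_ref[i] <- codon; codon_alt[i] <- calt
    aa_ref[i] <- a1; aa_alt[i] <- a2
  }
  data.frame(gene_id = sites$gene_id, pos = sites$pos, ref = sites$ref,
             alt = sites$alt, effect = effect, codon_ref = codon_ref,
             codon_alt = codon_alt, aa_ref = aa_ref, aa_alt = aa_alt,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Per-gene non-synonymous / synonymous SNP ratio
#'
#' @param effects output of [coding_effect()].
#' @return data.frame: gene_id, n_synonymous, n_non_synonymous, ratio
#'   (`Inf` when synonymous = 0 and non-synonymous > 0; `NA` when both 0).
#' @export
ratio_by_gene <- function(effects) {
  coding <- effects[effects$effect != "non_coding", , drop = FALSE]
  genes <- sort(unique(effects$gene_id))
  n_syn <- vapply(genes, function(g)
    sum(coding$gene_id == g & coding$effect == "synonymous"), integer(1L))
  n_non <- vapply(genes, function(g)
    sum(coding$gene_id == g & coding$effect == "non_synonymous"), integer(1L))
  ratio <- ifelse(n_syn > 0, n_non / n_syn,
                  ifelse(n_non > 0, Inf, NA_real_))
  data.frame(gene_id = genes, n_synonymous = n_syn,
             n_non_synonymous = n_non, ratio = ratio,
             stringsAsFactors = FALSE, row.names = NULL)
}

# per-pair score of two genotype codes: 0 identical allele pairs, 0.5 when
# the encoded allele pairs share exactly one allele, 1 when disjoint
genotype_score_table <- function() {
  codes <- names(iupac_allele_sets)
  s <- matrix(NA_real_, length(codes), length(codes),
              dimnames = list(codes, codes))
  for (a in codes) for (b in codes) {
    sa <- sort(iupac_allele_sets[[a]])
    sb <- sort(iupac_allele_sets[[b]])
    s[a, b] <- if (identical(sa, sb)) 0
               else if (length(intersect(sa, sb)) > 0) 0.5 else 1
  }
  s
}

#' Ambiguity-aware pairwise distances between genotype rows
#'
#' Per-site allele-sharing score: 0 for identical genotypes, 0.5 when the
#' two genotypes share one allele (e.g. `R` = A/G versus homozygous `A`),
#' 1 when they share none. The distance between two samples is the mean
#' score over sites; sites with missing data (`N`, `-` or NA) in either
#' sample are skipped pairwise.
#'
#' @param x a `genotype_matrix` (samples x sites).
#' @return a `dist` object over samples.
#' @export
genotype_distance <- function(x) {
  score <- genotype_score_table()
  samples <- rownames(x)
  n <- length(samples)
  d <- matrix(0, n, n, dimnames = list(samples, samples))
  valid <- x %in% names(iupac_allele_sets)
  dim(valid) <- dim(x)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- valid[i, ] & valid[j, ]
    if (!any(ok)) { d[i, j] <- d[j, i] <- NA_real_; next }
    d[i, j] <- d[j, i] <- mean(score[cbind(x[i, ok], x[j, ok])])
  }
  stats::as.dist(d)
}

#' Neighbour-joining tree from a genotype distance matrix
#'
#' Desk-scale genetic-structure check: an unrooted NJ tree built from the
#' ambiguity-aware distances (the exported NEXUS matrix remains available
#' for full Bayesian inference in external tools).
#'
#' @param d a `dist` object (>= 3 samples).
#' @return an `ape::phylo` tree.
#' @export
nj_tree <- function(d) {
  if (attr(d, "Size") < 3L) stop("at least 3 samples are required")
  ape::nj(d)
}

#' Do samples of each population form a single clade?
#'
#' @param tree an unrooted `phylo` tree.
#' @param population named vector: sample -> population label.
#' @return TRUE when every population is monophyletic in the unrooted tree.
#' @export
populations_monophyletic <- function(tree, population) {
  pops <- unique(population)
  all(vapply(pops, function(p) {
    tips <- names(population)[population == p]
    outgroup <- setdiff(tree$tip.label, tips)
    if (length(outgroup) == 0L) return(TRUE)
    # root outside the population so the bipartition test is well defined
    rooted <- ape::root(tree, outgroup = outgroup[1L], resolve.root = TRUE)
    ape::is.monophyletic(rooted, tips)
  }, logical(1L)))
}
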