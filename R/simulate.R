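#' Simulation configuration for the synthetic cold-acclimation dataset
#'
#' Builds a validated configuration for the synthetic-data generators. The
#' defaults emulate the design of a leaf-transcriptome survey along an air
#' temperature gradient: five temperature groups (2-18 degC), a minority of
#' genes up-regulated at the low-temperature groups, negative-binomial counts
#' with log-normal library sizes, a GO-style functional classification with
#' one planted enriched group among the responsive genes, biallelic SNP
#' pileups from two diverged populations, and transcripts carrying planted
#' SSR motifs and coding frames.
#'
#' @param n_genes number of genes.
#' @param n_samples_per_group biological samples per temperature group.
#' @param groups named numeric vector: group label -> representative air
#'   temperature (degC). Groups below `cold_cutoff` are the "low" groups where
#'   responsive genes change expression.
#' @param cold_cutoff temperature (degC) below which responsive genes respond.
#' @param frac_responsive fraction of genes responsive at low temperatures.
#' @param responsive_min_count minimum expected baseline fragments per sample
#'   for a gene to be eligible as responsive (a response planted below the
#'   detection floor would be unobservable at any analysis setting).
#' @param frac_down fraction of responsive genes down- rather than up-regulated.
#' @param frac_coldest_only fraction of responsive genes that respond only in
#'   the single coldest group (the rest respond in every low group).
#' @param lfc_mean,lfc_sd mean and sd of the absolute log2 fold change of
#'   responsive genes at low groups.
#' @param nb_dispersion negative-binomial dispersion (0 gives Poisson counts).
#' @param library_size_mean expected total fragments per sample.
#' @param library_size_cv log-scale sd of the log-normal library sizes.
#' @param n_go_groups number of functional groups in the synthetic annotation.
#' @param planted_odds named numeric vector of enrichment odds for planted
#'   groups, keyed by group id (`sprintf("G%03d", i)`); odds 10 means a
#'   responsive gene is 10-fold (on the odds scale) more likely to carry the
#'   group than a background gene.
#' @param n_snp_sites number of variant sites in the synthetic pileups.
#' @param frac_indel fraction of variant sites that are InDels rather than SNPs.
#' @param coverage_mean mean sequencing coverage (reads/site/sample).
#' @param sequencing_error per-read probability of reading the other allele.
#' @param n_populations number of planted populations.
#' @param n_samples_per_pop genotyped samples per population.
#' @param fst_like_divergence fraction of SNP sites fixed for different
#'   alleles between the two populations.
#' @param n_transcripts,transcript_length number and length (bases) of
#'   synthetic transcript sequences.
#' @param frac_low_qual fraction of variant records given a failing QUAL or QD.
#' @param seed top-level integer seed; per-stage streams are derived from it.
#'
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 10000L,
                       n_samples_per_group = 2L,
                       groups = c(T2 = 2, T5 = 5, T10 = 10, T14 = 14, T18 = 18),
                       cold_cutoff = 10,
                       frac_responsive = 0.10,
                       responsive_min_count = 20,
                       frac_down = 0.10,
                       frac_coldest_only = 0.5,
                       lfc_mean = 2,
                       lfc_sd = 0.5,
                       nb_dispersion = 0.05,
                       library_size_mean = 1e6,
                       library_size_cv = 0.3,
                       n_go_groups = 25L,
                       planted_odds = c(G001 = 10),
                       n_snp_sites = 1000L,
                       frac_indel = 0.05,
                       coverage_mean = 20,
                       sequencing_error = 0.01,
                       n_populations = 2L,
                       n_samples_per_pop = 4L,
                       fst_like_divergence = 0.3,
                       n_transcripts = 100L,
                       transcript_length = 2000L,
                       frac_low_qual = 0.05,
                       seed = 1L) {
  cfg <- list(
    n_genes = as.integer(n_genes),
    n_samples_per_group = as.integer(n_samples_per_group),
    groups = groups, cold_cutoff = cold_cutoff,
    frac_responsive = frac_responsive,
    responsive_min_count = responsive_min_count,
    frac_down = frac_down,
    frac_coldest_only = frac_coldest_only,
    lfc_mean = lfc_mean, lfc_sd = lfc_sd,
    nb_dispersion = nb_dispersion,
    library_size_mean = library_size_mean, library_size_cv = library_size_cv,
    n_go_groups = as.integer(n_go_groups), planted_odds = planted_odds,
    n_snp_sites = as.integer(n_snp_sites), frac_indel = frac_indel,
    coverage_mean = coverage_mean, sequencing_error = sequencing_error,
    n_populations = as.integer(n_populations),
    n_samples_per_pop = as.integer(n_samples_per_pop),
    fst_like_divergence = fst_like_divergence,
    n_transcripts = as.integer(n_transcripts),
    transcript_length = as.integer(transcript_length),
    frac_low_qual = frac_low_qual,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  props <- c("frac_responsive", "frac_down", "frac_coldest_only", "frac_indel",
             "sequencing_error", "fst_like_divergence", "frac_low_qual")
  for (p in props) {
    v <- cfg[[p]]
    if (!is.numeric(v) || v < 0 || v > 1)
      stop("configuration error: '", p, "' must be a proportion in [0,1]")
  }
  counts <- c("n_genes", "n_samples_per_group", "n_go_groups", "n_snp_sites",
              "n_populations", "n_samples_per_pop", "n_transcripts",
              "transcript_length")
  for (p in counts) {
    if (cfg[[p]] < 1L)
      stop("configuration error: '", p, "' must be a positive count")
  }
  if (length(cfg$groups) == 0L || is.null(names(cfg$groups)))
    stop("configuration error: 'groups' must be a non-empty named vector")
  if (cfg$nb_dispersion < 0)
    stop("configuration error: 'nb_dispersion' must be >= 0")
  if (cfg$library_size_mean <= 0)
    stop("configuration error: 'library_size_mean' must be positive")
  if (cfg$coverage_mean <= 0)
    stop("configuration error: 'coverage_mean' must be positive")
  if (any(cfg$planted_odds <= 0))
    stop("configuration error: enrichment odds must be positive")
  invisible(cfg)
}

#' Simulate a fragment-count matrix with a planted cold response
#'
#' Draws negative-binomial counts for `n_genes` genes across all samples of
#' the configured temperature groups. A fraction of genes is responsive:
#' their expected expression is multiplied by `2^lfc` in every group whose
#' representative temperature is below `cold_cutoff` (a configurable subset
#' responds only in the single coldest group, and a configurable fraction is
#' down- instead of up-regulated). Library sizes are log-normal so that
#' normalisation is non-trivial.
#'
#' @param config a [sim_config()] object.
#' @return list with `counts` (integer matrix, genes x samples), `lengths`
#'   (named transcript lengths in bases), `design` (data.frame: sample_id,
#'   group, temperature_C), and `truth` (responsive gene ids, per-gene signed
#'   log2 fold change, the groups each gene responds in).
#' @export
sim_counts <- function(config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "counts"))
  ng <- config$n_genes
  gene_ids <- sprintf("gene%05d", seq_len(ng))

  groups <- config$groups
  design <- data.frame(
    sample_id = unlist(lapply(names(groups), function(g)
      sprintf("%s_r%d", g, seq_len(config$n_samples_per_group)))),
    group = rep(names(groups), each = config$n_samples_per_group),
    temperature_C = rep(unname(groups), each = config$n_samples_per_group),
    stringsAsFactors = FALSE
  )
  ns <- nrow(design)

  lengths <- as.integer(pmin(pmax(round(rlnorm(ng, log(800), 0.5)), 200L),
                             20000L))
  names(lengths) <- gene_ids

  # relative expression levels; gamma tail gives a realistic dynamic range
  q <- rgamma(ng, shape = 0.6, rate = 1)
  q <- q / sum(q)

  # responsive genes are drawn from genes with a detectable baseline: a
  # temperature response planted on a gene sequenced at a handful of
  # fragments is unobservable (cf. the saturation diagnostic, where only
  # genes above a few FPKM have stable estimates), so eligibility requires
  # an expected baseline count of `responsive_min_count` per sample
  n_resp <- round(ng * config$frac_responsive)
  eligible <- which(q * config$library_size_mean >= config$responsive_min_count)
  if (n_resp > length(eligible))
    stop("configuration error: fewer than n_genes * frac_responsive genes ",
         "meet the baseline-expression floor for responsiveness")
  responsive <- if (n_resp > 0) sort(sample(eligible, n_resp)) else integer(0)
  sign_g <- rep(1, n_resp)
  if (n_resp > 0) {
    n_down <- round(n_resp * config$frac_down)
    if (n_down > 0) sign_g[sample.int(n_resp, n_down)] <- -1
  }
  coldest_only <- rep(FALSE, n_resp)
  if (n_resp > 0) {
    n_co <- round(n_resp * config$frac_coldest_only)
    if (n_co > 0) coldest_only[sample.int(n_resp, n_co)] <- TRUE
  }
  lfc_abs <- pmax(abs(rnorm(n_resp, config$lfc_mean, config$lfc_sd)), 0.25)
  lfc <- lfc_abs * sign_g

  low_groups <- names(groups)[groups < config$cold_cutoff]
  coldest <- names(groups)[which.min(groups)]

  # per-gene multiplier in each group
  mult <- matrix(1, nrow = ng, ncol = length(groups),
                 dimnames = list(gene_ids, names(groups)))
  if (n_resp > 0) {
    for (i in seq_len(n_resp)) {
      gs <- if (coldest_only[i]) coldest else low_groups
      mult[responsive[i], gs] <- 2^lfc[i]
    }
  }

  lib <- rlnorm(ns, log(config$library_size_mean) - config$library_size_cv^2 / 2,
                config$library_size_cv)
  mu <- mult[, design$group, drop = FALSE] * outer(q, lib)
  counts <- if (config$nb_dispersion > 0) {
    matrix(rnbinom(ng * ns, mu = mu, size = 1 / config$nb_dispersion),
           nrow = ng)
  } else {
    matrix(rpois(ng * ns, lambda = mu), nrow = ng)
  }
  storage.mode(counts) <- "integer"
  dimnames(counts) <- list(gene_ids, design$sample_id)

  truth <- list(
    responsive_gene_ids = gene_ids[responsive],
    lfc = setNames(lfc, gene_ids[responsive]),
    responds_in = setNames(
      lapply(seq_len(n_resp), function(i)
        if (coldest_only[i]) coldest else low_groups),
      gene_ids[responsive]),
    low_groups = low_groups
  )
  list(counts = counts, lengths = lengths, design = design, truth = truth)
}

#' Simulate a GO-style functional-group annotation
#'
#' Assigns each gene zero or more functional groups. Group base rates are
#' uniform on (0.02, 0.12); in planted groups the odds of membership for
#' responsive genes are multiplied by the configured enrichment odds, which
#' mimics a functional class (such as transmembrane transporter activity)
#' over-represented among cold-responsive genes.
#'
#' @param gene_ids character vector of gene ids to annotate.
#' @param truth the `truth` element of [sim_counts()] (uses
#'   `responsive_gene_ids`); may be NULL for a null annotation.
#' @param config a [sim_config()] object.
#' @return list of class `go_annotation`: `gene2group` (data.frame gene_id,
#'   go_id, namespace), `groups` (data.frame go_id, label, namespace), and a
#'   `planted` attribute with the planted group ids.
#' @export
sim_annotation <- function(gene_ids, truth, config) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "annotation"))
  ng <- length(gene_ids)
  k <- config$n_go_groups
  go_ids <- sprintf("G%03d", seq_len(k))
  namespaces <- rep(c("BP", "CC", "MF"), length.out = k)
  groups <- data.frame(go_id = go_ids,
                       label = sprintf("functional group %d", seq_len(k)),
                       namespace = namespaces, stringsAsFactors = FALSE)

  unknown <- setdiff(names(config$planted_odds), go_ids)
  if (length(unknown))
    stop("configuration error: planted group(s) not in annotation: ",
         paste(unknown, collapse = ", "))

  responsive <- if (is.null(truth)) character(0) else truth$responsive_gene_ids
  is_resp <- gene_ids %in% responsive

  base_rate <- runif(k, 0.02, 0.12)
  rows <- vector("list", k)
  for (j in seq_len(k)) {
    p <- rep(base_rate[j], ng)
    odds <- config$planted_odds[go_ids[j]]
    if (!is.na(odds) && odds != 1) {
      p_enr <- odds * base_rate[j] / (1 - base_rate[j] + odds * base_rate[j])
      if (p_enr >= 0.95)
        stop("configuration error: enrichment odds ", odds,
             " incompatible with group base rate ", round(base_rate[j], 3))
      p[is_resp] <- p_enr
    }
    member <- runif(ng) < p
    if (any(member)) {
      rows[[j]] <- data.frame(gene_id = gene_ids[member], go_id = go_ids[j],
                              namespace = namespaces[j],
                              stringsAsFactors = FALSE)
    }
  }
  gene2group <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(gene2group) <- NULL
  structure(list(gene2group = gene2group, groups = groups),
            planted = intersect(names(config$planted_odds), go_ids),
            class = "go_annotation")
}

#' Simulate per-sample allele-depth pileups from two planted populations
#'
#' Generates biallelic variant sites for samples from `n_populations`
#' populations. A configurable fraction of SNP sites is fixed for different
#' alleles between the two populations (an Fst-like divergence); the rest
#' share a common allele frequency. Per-sample read depths are Poisson with
#' mean `coverage_mean`; each read carries the wrong allele with probability
#' `sequencing_error`. Heterozygotes therefore produce both alleles near
#' 50:50. A fraction of records is given failing QUAL/QD to exercise the
#' quality filter, and a fraction is InDels (length-differing alleles).
#'
#' @param config a [sim_config()] object.
#' @param transcripts optional named character vector of sequences; when
#'   given, SNP sites are anchored on these sequences (ref allele = the base
#'   at the site) so coding-effect classification is consistent.
#' @return list with `sites` (a `site_table`) and `truth` (true two-allele
#'   genotypes per sample per site, population assignment).
#' @export
sim_pileups <- function(config, transcripts = NULL) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "pileups"))
  nsite <- config$n_snp_sites
  npop <- config$n_populations
  samples <- unlist(lapply(seq_len(npop), function(p)
    sprintf("P%d_s%d", p, seq_len(config$n_samples_per_pop))))
  pop_of <- rep(seq_len(npop), each = config$n_samples_per_pop)
  names(pop_of) <- samples
  nsamp <- length(samples)
  bases <- c("A", "C", "G", "T")

  if (!is.null(transcripts)) {
    gene <- sample(names(transcripts), nsite, replace = TRUE)
    pos <- vapply(gene, function(g)
      sample.int(nchar(transcripts[[g]]), 1L), integer(1L), USE.NAMES = FALSE)
    ref <- substr(unname(transcripts[gene]), pos, pos)
    bad <- !ref %in% bases
    ref[bad] <- sample(bases, sum(bad), replace = TRUE)
  } else {
    gene <- sprintf("gene%05d", sample.int(max(50L, nsite %/% 5L), nsite,
                                           replace = TRUE))
    pos <- sample.int(2000L, nsite, replace = TRUE)
    ref <- sample(bases, nsite, replace = TRUE)
  }
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1L),
                USE.NAMES = FALSE)
  is_indel <- runif(nsite) < config$frac_indel
  if (any(is_indel)) {
    ins <- vapply(which(is_indel), function(i)
      paste(sample(bases, 1L + sample.int(3L, 1L), replace = TRUE),
            collapse = ""), character(1L))
    alt[is_indel] <- paste0(ref[is_indel], ins)
  }

  # allele frequencies (of the alt allele) per population
  fixed_diff <- !is_indel & runif(nsite) < config$fst_like_divergence
  freq <- matrix(rep(runif(nsite, 0.1, 0.9), npop), ncol = npop)
  if (npop >= 2L && any(fixed_diff)) {
    freq[fixed_diff, 1L] <- 0
    freq[fixed_diff, 2L] <- 1
    if (npop > 2L)
      freq[fixed_diff, 3:npop] <- round(freq[fixed_diff, 3:npop])
  }

  # true genotypes: number of alt alleles per sample per site
  n_alt <- matrix(0L, nsite, nsamp, dimnames = list(NULL, samples))
  for (s in seq_len(nsamp))
    n_alt[, s] <- rbinom(nsite, 2L, freq[, pop_of[s]])

  depth <- matrix(rpois(nsite * nsamp, config$coverage_mean), nsite, nsamp,
                  dimnames = list(NULL, samples))
  alt_reads <- matrix(0L, nsite, nsamp, dimnames = list(NULL, samples))
  p_alt_read <- (n_alt / 2) * (1 - config$sequencing_error) +
    (1 - n_alt / 2) * config$sequencing_error
  alt_reads[] <- rbinom(nsite * nsamp, depth, p_alt_read)
  ref_reads <- depth - alt_reads

  low_q <- runif(nsite) < config$frac_low_qual
  qual <- ifelse(low_q & runif(nsite) < 0.5, runif(nsite, 0, 29.9),
                 runif(nsite, 30, 2000))
  qd <- ifelse(low_q & qual >= 30, runif(nsite, 0, 4.9), runif(nsite, 5, 40))

  sites <- data.frame(gene_id = gene, pos = pos, ref = ref, alt = alt,
                      qual = round(qual, 2), qd = round(qd, 2),
                      stringsAsFactors = FALSE)
  for (s in samples) {
    sites[[paste0("ref_", s)]] <- ref_reads[, s]
    sites[[paste0("alt_", s)]] <- alt_reads[, s]
  }
  sites <- structure(sites, samples = samples, class = c("site_table",
                                                         "data.frame"))
  geno <- matrix(paste0(
    ifelse(n_alt == 2L, alt, ref),
    "/",
    ifelse(n_alt >= 1L, alt, ref)), nsite, nsamp,
    dimnames = list(paste0(gene, ":", pos), samples))
  list(sites = sites,
       truth = list(genotypes = geno, n_alt = n_alt, population = pop_of,
                    is_indel = is_indel, alt_freq = freq))
}

# Mutate single bases so that no perfect tandem run in `x` (a character
# vector of bases) reaches the SSR detection threshold for any unit size.
cap_ssr_runs <- function(x, min_repeats) {
  bases <- c("A", "C", "G", "T")
  n <- length(x)
  for (pass in 1:4) {
    changed <- FALSE
    for (k in seq_along(min_repeats)) {
      limit <- k * (min_repeats[k] - 1L)  # equality-run length at threshold
      if (n <= k) next
      eq <- x[seq_len(n - k)] == x[(k + 1L):n]
      r <- rle(eq)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      hit <- which(r$values & r$lengths >= limit)
      for (h in hit) {
        pos <- starts[h] + limit - 1L  # break the run just before threshold
        x[pos] <- sample(setdiff(bases, c(x[pos], x[pos + k],
                                          if (pos > k) x[pos - k])), 1L)
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  x
}

# codons of the standard genetic code that do not terminate translation
non_stop_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

#' Simulate transcript sequences with planted SSRs and coding frames
#'
#' Generates random-background sequences whose incidental tandem runs are
#' capped below the SSR detection thresholds, then inserts perfect SSRs (and
#' occasional nearby pairs that a scanner should merge into compound records)
#' and open reading frames at recorded coordinates.
#'
#' @param config a [sim_config()] object.
#' @param min_repeats minimum repeat number per unit size 1-6 used for the
#'   background cap (should match the scanner's thresholds).
#' @return list with `sequences` (named character vector), `ssr_truth`
#'   (data.frame seq_id, motif, unit_size, repeats, start, end), and
#'   `cds_truth` (data.frame seq_id, start, end, strand).
#' @export
sim_transcripts <- function(config,
                            min_repeats = c(10L, 6L, 5L, 5L, 5L, 5L)) {
  validate_sim_config(config)
  set.seed(derive_seed(config$seed, "transcripts"))
  bases <- c("A", "C", "G", "T")
  nt <- config$n_transcripts
  len <- config$transcript_length
  ids <- sprintf("tx%04d", seq_len(nt))

  units <- all_ssr_units()
  seqs <- character(nt)
  ssr_rows <- list()
  cds_rows <- list()

  for (i in seq_len(nt)) {
    x <- cap_ssr_runs(sample(bases, len, replace = TRUE), min_repeats)

    # plant an ORF in the middle half of most transcripts
    if (runif(1) < 0.8 && len >= 400L) {
      n_codon <- sample(60:150, 1L)
      cds_len <- 3L * n_codon
      start <- sample.int(len - cds_len - 10L, 1L) + 5L
      body <- sample(non_stop_codons(), n_codon - 2L, replace = TRUE)
      orf <- c("ATG", body, sample(c("TAA", "TAG", "TGA"), 1L))
      strand <- sample(c("+", "-"), 1L, prob = c(0.8, 0.2))
      orf_seq <- paste(orf, collapse = "")
      if (strand == "-") orf_seq <- reverse_complement(orf_seq)
      x[start:(start + cds_len - 1L)] <- strsplit(orf_seq, "")[[1L]]
      cds_rows[[length(cds_rows) + 1L]] <- data.frame(
        seq_id = ids[i], start = start, end = start + cds_len - 1L,
        strand = strand, stringsAsFactors = FALSE)
      # the ORF bases were not run-capped
      x <- cap_ssr_runs(x, min_repeats)
    }

    # plant one or two SSRs in ~70% of transcripts
    n_plant <- sample(0:2, 1L, prob = c(0.3, 0.5, 0.2))
    if (n_plant > 0L) {
      cursor <- sample.int(max(1L, len %/% 3L), 1L)
      for (p in seq_len(n_plant)) {
        u <- sample(units, 1L)
        k <- nchar(u)
        reps <- min_repeats[k] + sample(0:5, 1L)
        run <- strrep(u, reps)
        start <- cursor + sample(5:30, 1L)
        end <- start + nchar(run) - 1L
        if (end + k + 1L > len) break
        x[start:end] <- strsplit(run, "")[[1L]]
        # hard flank breaks so the run cannot extend into the background
        first <- substr(u, 1L, 1L)
        lastb <- substr(u, k, k)
        if (start > 1L) x[start - 1L] <- sample(setdiff(bases, lastb), 1L)
        x[end + 1L] <- sample(setdiff(bases, first), 1L)
        ssr_rows[[length(ssr_rows) + 1L]] <- data.frame(
          seq_id = ids[i], motif = u, unit_size = k, repeats = reps,
          start = start, end = end, stringsAsFactors = FALSE)
        cursor <- end + sample(3:10, 1L)  # next plant may be mergeably close
      }
    }
    seqs[i] <- paste(x, collapse = "")
  }
  names(seqs) <- ids
  list(sequences = seqs,
       ssr_truth = do.call(rbind, ssr_rows) %||%
         data.frame(seq_id = character(), motif = character(),
                    unit_size = integer(), repeats = integer(),
                    start = integer(), end = integer()),
       cds_truth = do.call(rbind, cds_rows) %||%
         data.frame(seq_id = character(), start = integer(),
                    end = integer(), strand = character()))
}
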