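test_that("invalid configurations are rejected", {
  expect_error(sim_config(frac_responsive = 1.2), "proportion")
  expect_error(sim_config(n_genes = 0), "positive count")
  expect_error(sim_config(nb_dispersion = -1), "dispersion")
  expect_error(sim_config(groups = numeric(0)), "groups")
})

test_that("count simulation is deterministic under a fixed seed", {
  cfg <- sim_config(n_genes = 200, n_snp_sites = 50, n_transcripts = 5,
                    seed = 42)
  a <- sim_counts(cfg)
  b <- sim_counts(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
  expect_identical(sim_pileups(cfg)$sites, sim_pileups(cfg)$sites)
  expect_identical(sim_transcripts(cfg)$sequences,
                   sim_transcripts(cfg)$sequences)
})

test_that("no gene responds when frac_responsive is zero", {
  cfg <- sim_config(n_genes = 100, frac_responsive = 0, seed = 1)
  cd <- sim_counts(cfg)
  expect_length(cd$truth$responsive_gene_ids, 0)
})

test_that("responsive genes show the configured fold change at low temperature", {
  # law-of-large-numbers check: Poisson counts, no library-size noise,
  # lfc fixed at 2 so the low/high group mean ratio should be ~4
  cfg <- sim_config(n_genes = 200, n_samples_per_group = 200,
                    groups = c(T2 = 2, T18 = 18), frac_responsive = 0.3,
                    frac_down = 0, frac_coldest_only = 0, lfc_mean = 2,
                    lfc_sd = 1e-9, nb_dispersion = 0, library_size_cv = 0,
                    library_size_mean = 2e5, seed = 3)
  cd <- sim_counts(cfg)
  low <- cd$design$sample_id[cd$design$group == "T2"]
  high <- cd$design$sample_id[cd$design$group == "T18"]
  m_low <- rowMeans(cd$counts[, low])
  m_high <- rowMeans(cd$counts[, high])
  resp <- rownames(cd$counts) %in% cd$truth$responsive_gene_ids
  well_expressed <- m_high >= 5
  ratio <- m_low[resp & well_expressed] / m_high[resp & well_expressed]
  expect_gt(length(ratio), 20)
  expect_lt(abs(mean(ratio) - 4), 0.4)        # aggregate within 10%
  expect_gt(mean(abs(ratio - 4) <= 0.4), 0.9) # nearly all genes within 10%
  # non-responsive genes stay flat
  flat <- m_low[!resp & well_expressed] / m_high[!resp & well_expressed]
  expect_lt(abs(mean(flat) - 1), 0.05)
})

test_that("planted annotation enrichment odds are recovered from the tables", {
  cfg <- sim_config(n_genes = 10000, planted_odds = c(G002 = 10), seed = 9)
  cd <- sim_counts(cfg)
  ann <- sim_annotation(rownames(cd$counts), cd$truth, cfg)
  resp <- rownames(cd$counts) %in% cd$truth$responsive_gene_ids
  in_g <- rownames(cd$counts) %in%
    ann$gene2group$gene_id[ann$gene2group$go_id == "G002"]
  tab <- table(resp, in_g)
  or <- (tab[2, 2] / tab[2, 1]) / (tab[1, 2] / tab[1, 1])
  expect_gt(or, 7)   # within 30% of the planted odds of 10
  expect_lt(or, 13)
  # odds 1 everywhere: membership independent of responsiveness
  cfg0 <- sim_config(n_genes = 10000, planted_odds = c(G002 = 1), seed = 9)
  ann0 <- sim_annotation(rownames(cd$counts), cd$truth, cfg0)
  in_g0 <- rownames(cd$counts) %in%
    ann0$gene2group$gene_id[ann0$gene2group$go_id == "G002"]
  tab0 <- table(resp, in_g0)
  or0 <- (tab0[2, 2] / tab0[2, 1]) / (tab0[1, 2] / tab0[1, 1])
  expect_lt(abs(log(or0)), log(1.7))
})

test_that("genes may carry zero groups and then count in no group", {
  cfg <- sim_config(n_genes = 500, seed = 2)
  cd <- sim_counts(cfg)
  ann <- sim_annotation(rownames(cd$counts), cd$truth, cfg)
  unannotated <- setdiff(rownames(cd$counts), unique(ann$gene2group$gene_id))
  expect_gt(length(unannotated), 0)
  m <- coldacc:::membership_matrix(ann, rownames(cd$counts))
  expect_true(all(rowSums(m[unannotated, , drop = FALSE]) == 0))
})

test_that("pileups reflect the true genotypes", {
  cfg <- sim_config(n_snp_sites = 400, coverage_mean = 100,
                    sequencing_error = 0, frac_indel = 0, seed = 21)
  pil <- sim_pileups(cfg)
  samples <- attr(pil$sites, "samples")
  refm <- as.matrix(pil$sites[, paste0("ref_", samples)])
  altm <- as.matrix(pil$sites[, paste0("alt_", samples)])
  hom_ref <- pil$truth$n_alt == 0L
  hom_alt <- pil$truth$n_alt == 2L
  het <- pil$truth$n_alt == 1L
  # error 0: homozygotes show exactly one allele
  expect_true(all(altm[hom_ref] == 0))
  expect_true(all(refm[hom_alt] == 0))
  # heterozygotes: minor-allele fraction concentrates around 1/2
  tot <- refm + altm
  frac <- altm[het & tot > 0] / tot[het & tot > 0]
  expect_gt(mean(frac >= 0.35 & frac <= 0.65), 0.95)
})

test_that("planted SSR and CDS truth records are internally consistent", {
  cfg <- sim_config(n_transcripts = 40, seed = 13)
  tx <- sim_transcripts(cfg)
  truth <- tx$ssr_truth
  expect_true(all(truth$end - truth$start + 1L ==
                    truth$unit_size * truth$repeats))
  # each planted run is literally present in the sequence
  for (i in seq_len(nrow(truth))) {
    s <- substr(tx$sequences[[truth$seq_id[i]]], truth$start[i], truth$end[i])
    expect_identical(s, strrep(truth$motif[i], truth$repeats[i]))
  }
  # planted coding frames translate without internal stops
  for (i in seq_len(nrow(tx$cds_truth))) {
    cd <- tx$cds_truth[i, ]
    s <- substr(tx$sequences[[cd$seq_id]], cd$start, cd$end)
    if (cd$strand == "-")
      s <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(s)))
    expect_false(grepl("\\*", substr(aa, 1, nchar(aa) - 1L)))
    expect_identical(substr(aa, nchar(aa), nchar(aa)), "*")
  }
})

test_that("run-capped background contains no detectable SSRs", {
  cfg <- sim_config(n_transcripts = 30, transcript_length = 2000, seed = 17)
  set.seed(99)
  seqs <- vapply(1:30, function(i)
    paste(coldacc:::cap_ssr_runs(sample(c("A", "C", "G", "T"), 2000,
                                        replace = TRUE),
                                 c(10L, 6L, 5L, 5L, 5L, 5L)), collapse = ""),
    character(1))
  names(seqs) <- sprintf("bg%02d", 1:30)
  expect_identical(nrow(ssr_regex_oracle(seqs)), 0L)
  expect_identical(nrow(find_ssrs(seqs)), 0L)
})
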