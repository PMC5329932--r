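two_sample_sites <- function() {
  make_sites(
    gene_id = c("u1", "u1", "u2", "u3"),
    pos = c(10L, 40L, 7L, 3L),
    ref = c("A", "C", "G", "T"),
    alt = c("G", "T", "A", "C"),
    qual = c(100, 29.9, 50, 31),
    qd = c(10, 10, 4.9, 5.0),
    depths = list(s1 = c(6L, 6L), s2 = c(12L, 0L)))
}

test_that("quality filtering removes records failing either threshold", {
  sites <- two_sample_sites()
  kept <- quality_filter(sites)
  # QUAL 29.9 fails even with good QD; QD 4.9 fails even with good QUAL
  expect_identical(kept$gene_id, c("u1", "u3"))
  # boundary values 30.0 / 5.0 are retained
  expect_true("u3" %in% kept$gene_id)
  # idempotent; empty in, empty out
  expect_identical(quality_filter(kept), kept)
  empty <- kept[0, ]
  expect_identical(nrow(quality_filter(empty)), 0L)
})

test_that("site selection enforces biallelism and per-sample depth", {
  sites <- make_sites(
    gene_id = c("a", "b", "c"), pos = c(1L, 2L, 3L),
    ref = c("A", "A", "A"), alt = c("G", "G,T", "G"),
    qual = 100, qd = 10,
    depths = list(s1 = matrix(c(6, 6, 6, 6, 3, 2), ncol = 2, byrow = TRUE),
                  s2 = matrix(c(10, 0, 8, 4, 9, 9), ncol = 2, byrow = TRUE)))
  kept <- select_sites(sites)
  expect_identical(kept$gene_id, "a")  # b is triallelic, c has depth 5 in s1
  relaxed <- select_sites(sites, min_samples_covered = 1L)
  expect_identical(relaxed$gene_id, c("a", "c"))
  expect_identical(select_sites(kept), kept)
})

test_that("IUPAC genotype calls follow the depth-fraction rule", {
  expect_identical(call_iupac("A", "G", 6L, 6L), "R")
  expect_identical(call_iupac("A", "G", 12L, 0L), "A")
  # minor fraction 1/12 < 0.2: homozygous majority call
  expect_identical(call_iupac("A", "G", 11L, 1L), "A")
  # 3/12 = 0.25 >= 0.2: heterozygous
  expect_identical(call_iupac("A", "G", 9L, 3L), "R")
  expect_identical(call_iupac("C", "T", 0L, 10L), "T")
  expect_error(call_iupac("A", "G", 0L, 0L), "zero-depth")
})

test_that("the genotype matrix is ordered, subsampled reproducibly, and exported", {
  cfg <- sim_config(n_snp_sites = 120, frac_indel = 0, frac_low_qual = 0,
                    seed = 31)
  pil <- sim_pileups(cfg)
  sites <- select_sites(pil$sites)
  gm_all <- build_genotype_matrix(sites)
  expect_identical(ncol(gm_all), nrow(sites))
  ord <- order(sites$gene_id, sites$pos)
  expect_identical(colnames(gm_all),
                   paste0(sites$gene_id, ":", sites$pos)[ord])
  gm1 <- build_genotype_matrix(sites, n_subsample = 50, seed = 5)
  gm2 <- build_genotype_matrix(sites, n_subsample = 50, seed = 5)
  expect_identical(gm1, gm2)
  expect_error(build_genotype_matrix(sites, n_subsample = 1e6), "exceeds")

  nex <- tempfile(fileext = ".nex")
  write_genotype_nexus(gm1, nex)
  back <- read_genotype_nexus(nex)
  expect_identical(unname(unclass(back)), unname(unclass(gm1)))
  expect_identical(rownames(back), rownames(gm1))
})

test_that("identical samples give identical rows and zero distance", {
  sites <- make_sites(gene_id = c("g", "g"), pos = c(1L, 5L),
                      ref = c("A", "C"), alt = c("G", "T"),
                      qual = 100, qd = 10,
                      depths = list(x = c(10L, 10L), y = c(10L, 10L),
                                    z = c(20L, 0L)))
  gm <- build_genotype_matrix(sites)
  expect_identical(gm["x", ], gm["y", ])
  d <- as.matrix(genotype_distance(gm))
  expect_equal(d["x", "y"], 0)
})

test_that("ambiguity-aware distance scores shared alleles as half matches", {
  gm <- structure(rbind(a = c("A", "R"), b = c("A", "A")),
                  class = c("genotype_matrix", "matrix"))
  d <- genotype_distance(gm)
  expect_equal(as.numeric(d), 0.25, tolerance = 1e-12)  # (0 + 0.5) / 2
  # disjoint genotypes are full mismatches
  gm2 <- structure(rbind(a = c("A", "R"), b = c("C", "Y")),
                   class = c("genotype_matrix", "matrix"))
  expect_equal(as.numeric(genotype_distance(gm2)), 1)
})

test_that("neighbour joining recovers the additive four-taxon topology", {
  # additive distances on the unrooted tree ((a,b),(c,d)) with internal
  # branch 0.3; the four-point condition identifies the true split
  dm <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  dm["a", "b"] <- dm["b", "a"] <- 0.2
  dm["c", "d"] <- dm["d", "c"] <- 0.2
  for (p in c("a", "b")) for (q in c("c", "d"))
    dm[p, q] <- dm[q, p] <- 0.5
  s_ab <- dm["a", "b"] + dm["c", "d"]
  s_ac <- dm["a", "c"] + dm["b", "d"]
  s_ad <- dm["a", "d"] + dm["b", "c"]
  expect_true(s_ab < s_ac && s_ab < s_ad)  # oracle: split {a,b}|{c,d}
  tree <- nj_tree(as.dist(dm))
  expect_true(populations_monophyletic(
    tree, c(a = "p1", b = "p1", c = "p2", d = "p2")))
  expect_error(nj_tree(dist(matrix(0, 2, 2))), "3 samples")
})

test_that("codon substitution classifies synonymous and non-synonymous SNPs", {
  # transcript: 5' pad of 4 bases, then CDS ATG GCT AAA TAA
  seqs <- c(u1 = "CCCCATGGCTAAATAAGG")
  cds <- data.frame(seq_id = "u1", start = 5L, end = 16L, strand = "+")
  sites <- make_sites(gene_id = rep("u1", 3), pos = c(10L, 11L, 2L),
                      ref = c("T", "A", "C"), alt = c("C", "G", "A"),
                      qual = 100, qd = 10, depths = list(s1 = c(5L, 5L)))
  eff <- coding_effect(sites, seqs, cds)
  # GCT -> GCC: both alanine
  expect_identical(eff$effect[1], "synonymous")
  expect_identical(eff$aa_ref[1], "A")
  # AAA -> GAA: Lys -> Glu
  expect_identical(eff$effect[2], "non_synonymous")
  expect_identical(c(eff$aa_ref[2], eff$aa_alt[2]), c("K", "E"))
  # outside the CDS
  expect_identical(eff$effect[3], "non_coding")
})

test_that("minus-strand CDS are classified on the reverse complement", {
  # reverse complement of ATG AAA TAA laid on the + strand
  seqs <- c(u2 = paste0("GG", "TTATTTCAT", "AA"))
  cds <- data.frame(seq_id = "u2", start = 3L, end = 11L, strand = "-")
  # + strand position 8 is the first base of the middle minus-strand codon AAA
  sites <- make_sites(gene_id = "u2", pos = 8L, ref = "T", alt = "C",
                      qual = 100, qd = 10, depths = list(s1 = c(5L, 5L)))
  eff <- coding_effect(sites, seqs, cds)
  expect_identical(eff$codon_ref, "AAA")
  expect_identical(eff$codon_alt, "GAA")
  expect_identical(eff$effect, "non_synonymous")  # AAA(K) -> GAA(E)
})

test_that("per-gene non-synonymous/synonymous ratios handle all margins", {
  eff <- data.frame(
    gene_id = c("a", "a", "a", "b", "b", "c", "d"),
    pos = 1:7, ref = "A", alt = "G",
    effect = c("non_synonymous", "synonymous", "synonymous",
               "synonymous", "synonymous", "non_synonymous", "non_coding"),
    stringsAsFactors = FALSE)
  rr <- ratio_by_gene(eff)
  expect_equal(rr$ratio[rr$gene_id == "a"], 0.5)
  expect_equal(rr$ratio[rr$gene_id == "b"], 0)      # 2 syn, 0 non-syn
  expect_identical(rr$ratio[rr$gene_id == "c"], Inf)
  expect_true(is.na(rr$ratio[rr$gene_id == "d"]))
})

test_that("a CDS with a trailing partial codon warns and is truncated", {
  seqs <- c(u3 = "ATGGCTAAATA")  # 11 bases: 3 codons + 2 leftover
  cds <- data.frame(seq_id = "u3", start = 1L, end = 11L, strand = "+")
  sites <- make_sites(gene_id = c("u3", "u3"), pos = c(5L, 10L),
                      ref = c("C", "T"), alt = c("G", "A"),
                      qual = 100, qd = 10, depths = list(s1 = c(5L, 5L)))
  expect_warning(eff <- coding_effect(sites, seqs, cds), "divisible by 3")
  expect_identical(eff$effect[1], "non_synonymous")  # GCT -> GGT, Ala -> Gly
  expect_identical(eff$effect[2], "non_coding")      # in the partial codon
})
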