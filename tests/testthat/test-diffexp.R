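test_that("size factors respect scale relations", {
  counts <- matrix(c(10L, 20L, 5L, 10L, 20L, 5L), ncol = 2,
                   dimnames = list(c("a", "b", "c"), c("s1", "s2")))
  expect_equal(unname(size_factors(counts)), c(1, 1))
  counts2 <- counts
  counts2[, 2] <- counts2[, 2] * 2L
  sf <- size_factors(counts2)
  expect_equal(unname(sf["s2"] / sf["s1"]), 2)
  expect_equal(exp(mean(log(sf))), 1)  # geometric mean 1
})

test_that("size factors recover equal true libraries on NB data", {
  cfg <- sim_config(n_genes = 5000, n_samples_per_group = 3,
                    groups = c(A = 2, B = 18), frac_responsive = 0,
                    library_size_cv = 0, seed = 12)
  cd <- sim_counts(cfg)
  sf <- size_factors(cd$counts, pseudo_reference = TRUE)
  expect_true(all(abs(sf - 1) < 0.05))
})

test_that("size factors fail informatively without an all-positive gene", {
  counts <- matrix(c(0L, 5L, 3L, 0L), ncol = 2,
                   dimnames = list(c("a", "b"), c("s1", "s2")))
  expect_error(size_factors(counts), "pseudo_reference")
  expect_length(size_factors(counts, pseudo_reference = TRUE), 2)
})

test_that("identical groups yield no differential expression", {
  set.seed(30)
  base <- matrix(rnbinom(200 * 2, mu = 50, size = 10), ncol = 2)
  counts <- cbind(base, base)
  dimnames(counts) <- list(sprintf("g%03d", 1:200),
                           c("A_r1", "A_r2", "B_r1", "B_r2"))
  design <- data.frame(sample_id = colnames(counts),
                       group = c("A", "A", "B", "B"))
  de <- test_pairwise(counts, design, "A", "B")
  expect_true(all(de$p_value == 1))
  expect_false(any(de$significant))
})

test_that("external p-values can drive the comparison", {
  set.seed(31)
  counts <- matrix(rnbinom(100 * 4, mu = 30, size = 5), ncol = 4,
                   dimnames = list(sprintf("g%03d", 1:100),
                                   c("A_r1", "A_r2", "B_r1", "B_r2")))
  design <- data.frame(sample_id = colnames(counts),
                       group = c("A", "A", "B", "B"))
  pv <- setNames(runif(100), rownames(counts))
  pv[1:5] <- 1e-8
  de <- test_pairwise(counts, design, "A", "B", pvals = pv)
  expect_equal(de$p_value, unname(pv))
  expect_equal(de$adj_p, unname(p.adjust(pv, "BH")))
  expect_true(all(de$significant[1:5]))
})

test_that("BH adjustment is monotone and bounded", {
  set.seed(32)
  counts <- matrix(rnbinom(500 * 6, mu = 40, size = 8), ncol = 6,
                   dimnames = list(sprintf("g%03d", 1:500),
                                   paste0(rep(c("A", "B"), each = 3),
                                          "_r", 1:3)))
  design <- data.frame(sample_id = colnames(counts),
                       group = rep(c("A", "B"), each = 3))
  de <- test_pairwise(counts, design, "A", "B")
  expect_true(all(de$adj_p >= de$p_value - 1e-12))
  expect_true(all(de$adj_p <= 1))
  ord <- order(de$p_value)
  expect_true(all(diff(de$adj_p[ord]) >= -1e-12))
})

test_that("the consistency filter matches hand-built expectations", {
  universe <- sprintf("g%02d", 1:20)
  d1 <- fake_de(universe, c("g01", "g02", "g03"))
  d2 <- fake_de(universe, c("g01", "g02", "g05"))
  d3 <- fake_de(universe, c("g01", "g02", "g07"),
                direction = c(g01 = "up_in_A", g02 = "down_in_A",
                              g07 = "up_in_A"))
  cons <- consistent_degs(list(h1 = d1, h2 = d2, h3 = d3), low_group = "T5")
  # significant in all three comparisons only
  expect_setequal(cons$gene_id, c("g01", "g02"))
  expect_true(cons$consistent_direction[cons$gene_id == "g01"])
  expect_identical(cons$direction[cons$gene_id == "g01"], "up_in_A")
  # g02 is up in two comparisons, down in one: kept but flagged mixed
  expect_false(cons$consistent_direction[cons$gene_id == "g02"])
  expect_identical(cons$direction[cons$gene_id == "g02"], "mixed")
})

test_that("consistency filter handles empty sets and rejects universe mismatch", {
  universe <- sprintf("g%02d", 1:10)
  empty <- consistent_degs(list(a = fake_de(universe, character(0)),
                                b = fake_de(universe, "g01")))
  expect_identical(nrow(empty), 0L)
  expect_error(
    consistent_degs(list(a = fake_de(universe, "g01"),
                         b = fake_de(universe[-1], "g02"))),
    "universe")
})

test_that("overlap analysis counts sets, intersections and direct significance", {
  universe <- sprintf("g%02d", 1:30)
  set_a <- c("g01", "g02", "g03", "g04")
  set_b <- c("g03", "g04", "g05")
  direct <- fake_de(universe, c("g01", "g03", "g05"))
  ov <- overlap_analysis(set_a, set_b, de_direct = direct)
  expect_identical(ov$n_a, 4L)
  expect_identical(ov$n_b, 3L)
  expect_identical(ov$n_intersect, 2L)
  expect_identical(ov$shared_gene_ids, c("g03", "g04"))
  expect_identical(ov$n_a_sig_direct, 2L)
  expect_identical(ov$n_b_sig_direct, 2L)
  # degenerate cases
  expect_identical(overlap_analysis("g01", "g02")$n_intersect, 0L)
  expect_identical(overlap_analysis(set_a, set_a)$n_intersect, 4L)
})

test_that("permuting group labels on null data keeps the significant fraction at alpha", {
  cfg <- sim_config(n_genes = 2000, n_samples_per_group = 3,
                    groups = c(A = 2, B = 18), frac_responsive = 0, seed = 44)
  cd <- sim_counts(cfg)
  frac <- vapply(1:5, function(r) {
    set.seed(100 + r)
    design <- cd$design
    design$group <- sample(design$group)
    de <- test_pairwise(cd$counts, design, "A", "B")
    mean(de$significant)
  }, numeric(1))
  expect_true(all(frac <= 0.05 + 0.01))
})

test_that("the default synthetic study recovers its planted cold-responsive genes", {
  cfg <- sim_config(seed = 1)
  cd <- sim_counts(cfg)
  high <- c("T10", "T14", "T18")
  des <- lapply(high, function(hg)
    suppressMessages(test_pairwise(cd$counts, cd$design, "T2", hg)))
  names(des) <- high
  cons <- consistent_degs(des, low_group = "T2")
  responds_t2 <- names(cd$truth$responds_in)[
    vapply(cd$truth$responds_in, function(g) "T2" %in% g, logical(1))]
  hits <- intersect(cons$gene_id, responds_t2)
  expect_gte(length(hits) / length(responds_t2), 0.8)   # sensitivity
  expect_lte(1 - length(hits) / nrow(cons), 0.1)        # FDR
})

test_that("the DEG expression export applies the log10(FPKM + 1) transform", {
  cfg <- sim_config(n_genes = 100, seed = 3)
  cd <- sim_counts(cfg)
  fpkm <- compute_fpkm(cd$counts, cd$lengths)
  genes <- rownames(fpkm)[1:5]
  em <- deg_expression_matrix(fpkm, genes)
  expect_equal(em, log10(fpkm[genes, ] + 1))
  expect_error(deg_expression_matrix(fpkm, "nope"), "absent")
})
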