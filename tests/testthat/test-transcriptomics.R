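make_ds <- function(mat, scale = "log2p1",
                    stiffness = NULL, region = NULL, tumor = NULL) {
  ann <- data.frame(sample_id = colnames(mat), stringsAsFactors = FALSE)
  if (!is.null(stiffness)) ann$stiffness_class <- stiffness
  if (!is.null(region)) ann$region <- region
  if (!is.null(tumor)) ann$tumor_id <- tumor
  expression_dataset(mat, ann, scale = scale)
}

test_that("log2p1 maps 0,1,3 to 0,1,2 and refuses double transforms", {
  m <- matrix(c(0, 1, 3, 7), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  ds <- make_ds(m, scale = "linear")
  lg <- log2p1(ds)
  expect_equal(as.numeric(lg$mat), c(0, 1, 2, 3))
  expect_equal(lg$scale, "log2p1")
  expect_error(log2p1(lg), "already")
})

test_that("per-gene standardization yields mean 0 / sd 1, drops flat genes, idempotent", {
  set.seed(31)
  m <- matrix(rnorm(50 * 8, 5, 2), 50, 8,
              dimnames = list(sprintf("g%02d", 1:50), sprintf("s%d", 1:8)))
  m[3, ] <- 4  # constant gene
  ds <- make_ds(m)
  expect_warning(z <- standardize_genes(ds), "zero-variance")
  expect_equal(nrow(z$mat), 49)
  expect_lt(max(abs(rowMeans(z$mat))), 1e-12)
  expect_lt(max(abs(apply(z$mat, 1, sd) - 1)), 1e-12)
  z2 <- standardize_genes(z)
  expect_equal(z2$mat, z$mat, tolerance = 1e-12)
})

test_that("merging standardized datasets concatenates shared genes with provenance", {
  set.seed(32)
  mk <- function(samples, genes = 40) {
    m <- matrix(rnorm(genes * length(samples)), genes, length(samples),
                dimnames = list(sprintf("g%02d", 1:genes), samples))
    standardize_genes(make_ds(m))
  }
  a <- mk(c("a1", "a2", "a3"))
  b <- mk(c("b1", "b2"))
  ab <- merge_standardized(a, b)
  expect_equal(ncol(ab$mat), 5)
  expect_equal(ab$annotations$source, c("A", "A", "A", "B", "B"))
  ba <- merge_standardized(b, a)
  expect_equal(ab$mat[, sort(colnames(ab$mat))],
               ba$mat[, sort(colnames(ba$mat))])
  expect_identical(merge_standardized(a, NULL)$mat, a$mat)
  expect_error(merge_standardized(a, mk(c("c1", "c2"), genes = 10)), "overlap")
})

test_that("two samples split into two clusters; synthetic labels recovered exactly", {
  ex <- generate_expression_dataset(n_genes = 500, seed = 17)
  hl <- standardize_genes(log2p1(ex$human))
  expect_error(cluster_subtypes(
    expression_dataset(hl$mat[, 1, drop = FALSE],
                       hl$annotations[1, , drop = FALSE], "linear"),
    ex$truth$signature), "2 samples")
  two <- expression_dataset(hl$mat[, 1:2], hl$annotations[1:2, ], "linear")
  cl2 <- cluster_subtypes(two, ex$truth$signature)
  expect_equal(sort(unique(cl2$cluster)), c(1, 2))

  cl <- cluster_subtypes(hl, ex$truth$signature)
  expect_equal(cl$subtype, ex$truth$samples$subtype)

  expect_error(cluster_subtypes(
    expression_dataset(hl$mat[-1, ], hl$annotations, "linear"),
    ex$truth$signature), "missing signature")
})

test_that("zero signature effect is a negative control near chance agreement", {
  agree <- vapply(1:20, function(s) {
    ex <- generate_expression_dataset(n_genes = 200, signature_effect_sd = 0,
                                      n_de = 0, seed = s)
    cl <- cluster_subtypes(standardize_genes(log2p1(ex$human)),
                           ex$truth$signature)
    mean(cl$subtype == ex$truth$samples$subtype)
  }, numeric(1))
  expect_lt(mean(agree), 0.8)  # far from the 1.0 of the planted-effect case
})

test_that("unpaired t matches the closed-form pooled-variance oracle", {
  set.seed(33)
  genes <- sprintf("g%02d", 1:30)
  m <- matrix(rnorm(30 * 10, 6, 0.5), 30, 10,
              dimnames = list(genes, sprintf("s%d", 1:10)))
  ds <- make_ds(m)
  de <- differential_expression(ds, paste0("s", 1:5), paste0("s", 6:10))
  for (g in c(1, 7, 30)) {
    want <- bf_t_unpaired(m[g, 1:5], m[g, 6:10])
    expect_equal(de$t[g], want$t, tolerance = 1e-10)
    expect_equal(de$p[g], want$p, tolerance = 1e-10)
  }
  expect_true(all(de$fc >= 1))
  expect_equal(de$pass, de$p <= 0.05 & de$fc > 1.2)
})

test_that("paired t pairs columns by tumor and matches the oracle", {
  set.seed(34)
  genes <- sprintf("g%02d", 1:20)
  m <- matrix(rnorm(20 * 8, 6, 0.5), 20, 8,
              dimnames = list(genes, sprintf("s%d", 1:8)))
  ds <- make_ds(m, tumor = rep(sprintf("T%d", 1:4), 2))
  de <- differential_expression(ds, paste0("s", 1:4), paste0("s", 8:5),
                                paired_by = "tumor_id")
  for (g in c(2, 11)) {
    want <- bf_t_paired(m[g, 1:4], m[g, c(5, 6, 7, 8)])
    expect_equal(de$t[g], want$t, tolerance = 1e-10)
    expect_equal(de$p[g], want$p, tolerance = 1e-10)
  }
  ds_bad <- make_ds(m, tumor = c(sprintf("T%d", 1:4), sprintf("T%d", c(1, 2, 3, 5))))
  expect_error(differential_expression(ds_bad, paste0("s", 1:4),
                                       paste0("s", 5:8),
                                       paired_by = "tumor_id"),
               "pairing")
})

test_that("identical groups yield no fold change and no passing gene", {
  genes <- sprintf("g%02d", 1:10)
  half <- matrix(rnorm(10 * 3, 5, 0.3), 10, 3)
  m <- cbind(half, half)
  dimnames(m) <- list(genes, sprintf("s%d", 1:6))
  de <- differential_expression(make_ds(m), paste0("s", 1:3), paste0("s", 4:6))
  expect_true(all(de$mean_log2_diff == 0))
  expect_true(all(de$fc == 1))
  expect_false(any(de$pass))
  expect_error(differential_expression(make_ds(m), paste0("s", 1:3),
                                       paste0("s", 3:6)), "overlap")
})

test_that("filter_de partitions passing genes by direction, bookkeeping exact", {
  de <- data.frame(gene_id = sprintf("g%d", 1:6),
                   direction = c("up", "up", "down", "down", "up", "down"),
                   pass = c(TRUE, FALSE, TRUE, FALSE, TRUE, TRUE))
  f <- filter_de(de)
  expect_equal(f$up, c("g1", "g5"))
  expect_equal(f$down, c("g3", "g6"))
  expect_equal(unname(f$counts), c(2, 2, 6))
  empty <- filter_de(de[0, ])
  expect_length(empty$up, 0)
})

test_that("the six contrasts route planted stromal genes to stroma lists only", {
  ex <- generate_expression_dataset(n_mes = 10, n_nonmes = 2, n_genes = 500,
                                    n_de = 20, seed = 19)
  de <- de_contrast_suite(log2p1(ex$human), log2p1(ex$mouse))
  expect_named(de, c("epithelium_center_vs_soft", "epithelium_periphery_vs_soft",
                     "epithelium_center_vs_periphery", "stroma_center_vs_soft",
                     "stroma_periphery_vs_soft", "stroma_center_vs_periphery"))
  planted <- ex$truth$de_genes$gene_id
  expect_gt(mean(planted %in% de$stroma_center_vs_soft$up), 0.9)
  expect_gt(mean(planted %in% de$stroma_center_vs_periphery$up), 0.9)
  # epithelium contrasts see no planted stromal signal beyond chance
  expect_lt(mean(planted %in% de$epithelium_center_vs_soft$up), 0.3)

  # swapping the groups swaps the up/down lists
  ann <- ex$mouse$annotations
  ml <- log2p1(ex$mouse)
  soft <- ann$sample_id[ann$stiffness_class == "soft"]
  ctr <- ann$sample_id[ann$stiffness_class == "stiff" & ann$region == "center"]
  ab <- filter_de(differential_expression(ml, ctr, soft))
  ba <- filter_de(differential_expression(ml, soft, ctr))
  expect_equal(sort(ab$up), sort(ba$down))
  expect_equal(sort(ab$down), sort(ba$up))
})

test_that("expression generator: counts, pairing and determinism", {
  ex <- generate_expression_dataset(n_de = 50, n_genes = 200, seed = 4)
  expect_equal(nrow(ex$truth$de_genes), 50)
  expect_length(c(ex$truth$signature$correlated,
                  ex$truth$signature$anticorrelated), 36)
  # every paired sample id appears exactly once per region
  expect_false(anyDuplicated(ex$truth$pairing$center_sample) > 0)
  expect_false(anyDuplicated(ex$truth$pairing$periphery_sample) > 0)
  expect_true(all(ex$human$mat >= 0))  # linear scale
  ex2 <- generate_expression_dataset(n_de = 50, n_genes = 200, seed = 4)
  expect_identical(ex$human$mat, ex2$human$mat)
  expect_identical(ex$mouse$mat, ex2$mouse$mat)
  expect_error(generate_expression_dataset(n_genes = 40, n_de = 50),
               "36")
})
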