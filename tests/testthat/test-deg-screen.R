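test_that("collapse_probes keeps the highest-mean probe per symbol", {
  m <- matrix(c(5, 5, 5, 5,
                7, 7, 7, 7,
                2, 2, 2, 2,
                1, 1, 1, 1),
              nrow = 4, byrow = TRUE,
              dimnames = list(paste0("p", 1:4),
                              c("a", "b", "c", "d")))
  ann <- c(p1 = "GENE1", p2 = "GENE1", p3 = "GENE2", p4 = NA)
  ds <- expression_dataset(m, c("case", "case", "control", "control"),
                           annotation = ann)
  out <- collapse_probes(ds)
  expect_equal(sort(rownames(out$matrix)), c("GENE1", "GENE2"))
  expect_equal(unname(out$matrix["GENE1", 1]), 7)  # mean-7 probe retained
  # unmapped probe p4 absent
  expect_false(any(out$matrix == 1))
  # one-to-one annotation: identity on row count
  ds2 <- expression_dataset(m, c("case", "case", "control", "control"),
                            annotation = c(p1 = "A", p2 = "B", p3 = "C",
                                           p4 = "D"))
  expect_equal(nrow(collapse_probes(ds2)$matrix), 4L)
  ds$annotation <- NULL
  expect_error(collapse_probes(ds), "annotation")
})

test_that("moderated t agrees with limma and with the pooled-t oracle", {
  sim <- simulate_expression(300, 5, 5, 30, 1.5, 0.6, seed = 9)
  deg <- moderated_t(sim)
  fit <- limma::eBayes(limma::lmFit(sim$matrix,
                                    cbind(1, sim$groups == "case")))
  tt <- limma::topTable(fit, coef = 2, number = Inf, sort.by = "none")
  expect_equal(deg$log2fc, tt$logFC, tolerance = 1e-10)
  expect_equal(deg$t, tt$t, tolerance = 1e-10)
  expect_equal(deg$p, tt$P.Value, tolerance = 1e-10)
  # shrinkage disabled: ordinary pooled two-sample t
  ds <- toy_expression()
  deg0 <- moderated_t(ds, prior_df = 0)
  vary <- c("G1", "G2", "G3", "G5")   # G4 is constant (t.test would refuse)
  oracle <- vapply(vary, function(g)
    t.test(ds$matrix[g, 1:3], ds$matrix[g, 4:6],
           var.equal = TRUE)$statistic, 0)
  expect_equal(deg0$t[match(vary, deg0$gene)], unname(oracle),
               tolerance = 1e-10)
})

test_that("constant genes give t = 0, p = 1 without crashing", {
  ds <- toy_expression()   # G4 is constant
  deg <- moderated_t(ds)
  g4 <- deg[deg$gene == "G4", ]
  expect_equal(g4$log2fc, 0)
  expect_equal(g4$t, 0)
  expect_equal(g4$p, 1)
  expect_true(all(is.finite(deg$t)))
})

test_that("BH adjustment is monotone and bounded by p", {
  sim <- simulate_expression(500, 4, 4, 50, 2, 0.5, seed = 13)
  deg <- moderated_t(sim)
  expect_true(all(deg$adj_p >= deg$p - 1e-15))
  ord <- order(deg$p)
  expect_true(all(diff(deg$adj_p[ord]) >= -1e-15))
})

test_that("screen_degs applies strict thresholds and never overlaps", {
  rec <- data.frame(
    gene = paste0("G", 1:5),
    log2fc = c(1.2, 1.0, -1.4, -0.9, 2.5),
    adj_p = c(0.01, 0.001, 0.04, 0.01, 0.06))
  scr <- screen_degs(rec)
  expect_equal(scr$up, "G1")            # G2 fails strict >, G5 fails alpha
  expect_equal(scr$down, "G3")
  expect_length(intersect(scr$up, scr$down), 0)
  # brute-force filter agrees
  expect_equal(sort(c(scr$up, scr$down)),
               sort(rec$gene[abs(rec$log2fc) > 1 & rec$adj_p < 0.05]))
  expect_error(screen_degs(rec[0, ]), "non-empty")
})

test_that("consensus rule counts datasets, not directions", {
  sets <- list(c("a", "b"), c("b", "c"), c("c", "b"))
  expect_equal(consensus_degs(sets, k = 2), c("B", "C"))
  # equals union of pairwise intersections (enumeration oracle)
  pw <- unique(c(intersect(sets[[1]], sets[[2]]),
                 intersect(sets[[1]], sets[[3]]),
                 intersect(sets[[2]], sets[[3]])))
  expect_setequal(consensus_degs(sets, 2), toupper(pw))
  expect_equal(consensus_degs(sets, 1), c("A", "B", "C"))   # union
  expect_equal(consensus_degs(sets, 3), "B")                # intersection
  # up/down pooled per dataset before counting
  sets2 <- list(list(up = "g1", down = "g2"), list(up = "g2", down = "g1"))
  expect_equal(consensus_degs(sets2, 2), c("G1", "G2"))
  expect_error(consensus_degs(sets, k = 4), "exceeds")
})

test_that("series-matrix and TSV round-trips feed the DEG stage", {
  tmp <- withr::local_tempdir()
  sim <- simulate_expression(50, 3, 3, 5, 2, 0.5, seed = 2)
  tsv <- file.path(tmp, "expr.tsv")
  df <- data.frame(gene = rownames(sim$matrix), sim$matrix,
                   check.names = FALSE)
  write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  m <- read_expression_tsv(tsv)
  expect_equal(m, sim$matrix)
  # synthetic GEO series-matrix block
  smf <- file.path(tmp, "series.txt")
  writeLines(c("!Series_title\t\"synthetic\"",
               "!series_matrix_table_begin",
               paste(c("ID_REF", colnames(sim$matrix)), collapse = "\t"),
               apply(df, 1, paste, collapse = "\t"),
               "!series_matrix_table_end"), smf)
  m2 <- read_series_matrix(smf)
  expect_equal(unname(m2), unname(sim$matrix), tolerance = 1e-6)
})
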