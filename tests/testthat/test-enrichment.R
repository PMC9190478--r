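test_that("hypergeometric tail matches the exact closed form", {
  # all 5 query genes inside a 5-member set from a 20-gene universe:
  # p = 1 / C(20,5)
  universe <- sprintf("U%02d", 1:20)
  coll <- gene_set_collection(list(s1 = universe[1:5]), universe = universe)
  rec <- enrich(universe[1:5], coll)
  expect_equal(rec$p, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(rec$k, 5)
})

test_that("enrichment p equals one-sided Fisher exact on random tables", {
  set.seed(31)
  for (i in 1:50) {
    N <- sample(20:200, 1)
    K <- sample(2:(N - 2), 1)
    n <- sample(2:(N - 2), 1)
    universe <- sprintf("G%04d", 1:N)
    members <- sample(universe, K)
    query <- sample(universe, n)
    k <- length(intersect(query, members))
    if (k == 0) next
    coll <- gene_set_collection(list(s = members), universe = universe)
    rec <- enrich(query, coll)
    fish <- fisher.test(matrix(c(k, n - k, K - k, N - K - n + k), 2),
                        alternative = "greater")$p.value
    expect_equal(rec$p, fish, tolerance = 1e-12)
  }
})

test_that("p is monotone non-increasing in the overlap k", {
  ps <- vapply(1:10, function(k)
    phyper(k - 1, 20, 80, 15, lower.tail = FALSE), 0)
  expect_true(all(diff(ps) <= 0))
  # package path gives the same values
  universe <- sprintf("G%03d", 1:100)
  coll <- gene_set_collection(list(s = universe[1:20]), universe = universe)
  rec <- enrich(c(universe[1:5], universe[21:30]), coll)  # k=5, n=15
  expect_equal(rec$p, ps[5], tolerance = 1e-12)
})

test_that("untested and out-of-universe genes are handled as documented", {
  universe <- sprintf("G%03d", 1:50)
  coll <- gene_set_collection(list(hit = universe[1:10],
                                   miss = universe[41:50]),
                              universe = universe)
  rec <- enrich(universe[1:5], coll)
  expect_equal(rec$set_id, "hit")      # k = 0 set absent from output
  expect_message(enrich(c(universe[1:5], "NOT_A_GENE"), coll), "dropped")
  expect_error(enrich("NOT_A_GENE", coll), "universe")
})

test_that("set order does not change p-values or the significant set", {
  universe <- sprintf("G%03d", 1:60)
  sets <- list(a = universe[1:10], b = universe[5:20], c = universe[30:45])
  q <- universe[c(1:8, 31:33)]
  r1 <- enrich(q, gene_set_collection(sets, universe = universe))
  r2 <- enrich(q, gene_set_collection(rev(sets), universe = universe))
  expect_equal(r1[order(r1$set_id), c("p", "adj_p", "q")],
               r2[order(r2$set_id), c("p", "adj_p", "q")],
               ignore_attr = TRUE)
})

test_that("filter_significant is strict on both thresholds", {
  rec <- data.frame(set_id = paste0("s", 1:4),
                    p = c(0.01, 0.04, 0.049, 0.2),
                    q = c(0.04, 0.05, 0.01, 0.01))
  out <- filter_significant(rec)
  expect_equal(out$set_id, c("s1", "s3"))  # s2 fails strict q, s4 fails p
})

test_that("Storey q-values are valid and fall back to BH when unstable", {
  set.seed(41)
  p <- c(runif(50, 0, 0.01), runif(450))   # mixed signal + null
  q <- netpharm:::storey_qvalue(p)
  expect_true(all(q >= 0 & q <= 1))
  expect_true(all(diff(q[order(p)]) >= -1e-12))
  # q <= BH when pi0 < 1 (Storey is less conservative)
  expect_true(all(q <= p.adjust(p, "BH") + 1e-12))
  # too few p-values: fallback path inside enrich()
  universe <- sprintf("G%02d", 1:30)
  coll <- gene_set_collection(list(s = universe[1:10]), universe = universe)
  rec <- enrich(universe[1:5], coll)
  expect_equal(rec$q, rec$adj_p)
})

test_that("key-target intersection is case-insensitive and reproduces the study's five chemokines", {
  expect_equal(key_target_intersection("ccl5", "CCL5"), "CCL5")
  expect_length(key_target_intersection(c("A", "B"), c("C", "D")), 0)
  fx <- load_fixtures()
  expect_equal(key_target_intersection(fx$hub27, fx$pathway30),
               c("CCL5", "CXCL10", "CXCL11", "CXCL6", "CXCL9"))
})

test_that("GMT round-trip keeps ids, names and members", {
  coll <- read_gmt(ra_pathways_gmt())
  expect_s3_class(coll, "gene_set_collection")
  expect_length(coll$sets, 6)
  expect_equal(unname(coll$set_names["hsa05323"]), "Rheumatoid arthritis")
  expect_length(coll$universe, 30)   # union of Table-style pathway members
  expect_true("CCL5" %in% coll$sets$hsa04668)
  tmp <- withr::local_tempfile(fileext = ".gmt")
  writeLines("onefield", tmp)
  expect_error(read_gmt(tmp), "fewer than 3")
})
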