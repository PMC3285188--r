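test_that("combined gene set is a stable, order-invariant union", {
  expect_equal(combine_gene_set(c("A", "B"), c("B", "C")), c("A", "B", "C"))
  expect_equal(combine_gene_set(c("B", "A"), c("D", "C")),
               c("A", "B", "C", "D"))
  expect_equal(combine_gene_set(c("A", "B"), c("B", "C")),
               combine_gene_set(c("B", "C"), c("A", "B")))
  expect_error(combine_gene_set(character(0), character(0)), "empty")
})

test_that("merging recovers planted near-duplicate pairs and averages them", {
  # six samples per timepoint built as three noisy duplicate pairs
  set.seed(14)
  G <- 60L
  base <- matrix(rnorm(G * 3, 8), G, 3)
  mk <- function() {
    m <- cbind(base[, c(1, 1, 2, 2, 3, 3)] + matrix(rnorm(G * 6, 0, 0.05), G))
    m
  }
  m <- cbind(mk(), mk())
  dimnames(m) <- list(sprintf("g%03d", 1:G),
                      c(paste0("IF", 1:6, "_pre"), paste0("IF", 1:6, "_post")))
  design <- data.frame(sample_id = colnames(m),
                       patient_id = rep(paste0("IF", 1:6), 2),
                       group = "IF",
                       timepoint = rep(c("pre", "post"), each = 6))
  study <- expression_study(m, design)
  merged <- suppressMessages(merge_similar_samples(study, "IF", 3L))
  map <- attr(merged, "merge_map")

  # recovered pairing matches construction: {1,2}, {3,4}, {5,6}
  got <- lapply(seq_len(nrow(map)), function(i)
    sort(sub("_.*", "", c(map$member1[i], map$member2[i]))))
  expect_true(all(vapply(got, function(p)
    paste(p, collapse = "+") %in% c("IF1+IF2", "IF3+IF4", "IF5+IF6"),
    logical(1))))

  # merged profile equals the arithmetic mean of its members
  for (i in seq_len(nrow(map))) {
    expect_equal(merged$matrix[, map$merged_id[i]],
                 rowMeans(study$matrix[, c(map$member1[i], map$member2[i])]))
  }

  # identical members: merged profile equals either
  m2 <- m
  m2[, "IF2_pre"] <- m2[, "IF1_pre"]
  study2 <- expression_study(m2, design)
  merged2 <- suppressMessages(merge_similar_samples(study2, "IF", 3L))
  map2 <- attr(merged2, "merge_map")
  row <- map2[map2$member1 == "IF1_pre", ]
  expect_equal(merged2$matrix[, row$merged_id], m2[, "IF1_pre"])
})

test_that("merging rejects sample counts that cannot be paired down", {
  study <- toy_study(n_genes = 10L, n_patients = c(IF = 5L))
  expect_error(suppressMessages(merge_similar_samples(study, "IF", 3L)),
               "cannot pair")
})

test_that("connectivity matches the O(n^2) loop oracle to 1e-12", {
  study <- toy_study(n_genes = 20L, n_patients = c(IF = 3L), seed = 16L)
  net <- build_network(study, "IF", "pre", rownames(study$matrix))
  expect_equal(net$K, loop_connectivity(condition_slice(study, "IF", "pre")),
               tolerance = 1e-12)
  expect_equal(net$k, net$K / max(net$K), tolerance = 1e-15)
})

test_that("normalized connectivity peaks at exactly 1, ties included", {
  study <- toy_study(n_genes = 15L, n_patients = c(IF = 4L), seed = 17L)
  net <- build_network(study, "IF", "pre", rownames(study$matrix))
  expect_equal(max(net$k), 1)
  expect_true(all(net$k >= 0))
  # two perfectly correlated genes: both attain k = 1
  m <- matrix(rnorm(9), 3, 3)
  m <- rbind(m, m[3, ] * 2 + 1)  # gene 4 collinear with gene 3
  dimnames(m) <- list(paste0("g", 1:4), paste0("IF", 1:3, "_pre"))
  full <- cbind(m, m + rnorm(12, 0, 0.1))
  colnames(full) <- c(paste0("IF", 1:3, "_pre"), paste0("IF", 1:3, "_post"))
  st <- expression_study(full, data.frame(
    sample_id = colnames(full), patient_id = rep(paste0("IF", 1:3), 2),
    group = "IF", timepoint = rep(c("pre", "post"), each = 3)))
  net2 <- build_network(st, "IF", "pre", paste0("g", 1:4))
  expect_equal(unname(net2$k[c("g3", "g4")]), c(1, 1))
})

test_that("zero-variance genes are dropped with a warning", {
  study <- toy_study(n_genes = 6L, n_patients = c(IF = 3L), seed = 18L)
  study$matrix["g001", c("IF1_pre", "IF2_pre", "IF3_pre")] <- 5
  expect_warning(
    net <- build_network(study, "IF", "pre", rownames(study$matrix)),
    "zero variance")
  expect_false("g001" %in% net$genes)
  expect_error(build_network(toy_study(n_patients = c(IF = 2L, ID = 2L)),
                             "IF", "pre", "g001"),
               ">= 3 profiles")
})

test_that("DiffK is zero for identical states and bounded in [-1, 1]", {
  study <- toy_study(n_genes = 12L, n_patients = c(IF = 3L), seed = 19L)
  study$matrix[, paste0("IF", 1:3, "_post")] <-
    study$matrix[, paste0("IF", 1:3, "_pre")]
  pre <- build_network(study, "IF", "pre", rownames(study$matrix))
  post <- build_network(study, "IF", "post", rownames(study$matrix))
  dk <- diffk(pre, post)
  expect_true(all(dk$diffk == 0))

  study2 <- toy_study(n_genes = 12L, n_patients = c(IF = 3L), seed = 20L)
  dk2 <- diffk(build_network(study2, "IF", "pre", rownames(study2$matrix)),
               build_network(study2, "IF", "post", rownames(study2$matrix)))
  expect_true(all(dk2$diffk >= -1 & dk2$diffk <= 1))
})

test_that("permutation p is in (0, 1] and equals 1 on pre = post data", {
  study <- toy_study(n_genes = 10L, n_patients = c(IF = 4L), seed = 21L)
  study$matrix[, paste0("IF", 1:4, "_post")] <-
    study$matrix[, paste0("IF", 1:4, "_pre")]
  dk <- diffk_pvalues(study, "IF", rownames(study$matrix),
                      n_perm = 100L, seed = 1L)
  expect_true(all(dk$p == 1))
  expect_true(all(dk$diffk == 0))
  expect_error(diffk_pvalues(study, "IF", rownames(study$matrix),
                             n_perm = 50L), "n_perm")
})

test_that("hub calls are invariant to gene ordering", {
  spec <- simulation_spec(n_genes = 60L, n_patients = c(IF = 6L),
                          de_fraction = 0, delta = 0,
                          modules = list(list(size = 10L, r_pre = 0.9,
                                              r_post = 0.1)),
                          seed = 22L)
  study <- simulate_expression(spec)$study
  genes <- rownames(study$matrix)[1:30]
  dk1 <- classify_sectors(diffk_pvalues(study, "IF", genes,
                                        n_perm = 100L, seed = 7L))
  dk2 <- classify_sectors(diffk_pvalues(study, "IF", rev(genes),
                                        n_perm = 100L, seed = 7L))
  dk2 <- dk2[match(dk1$gene, dk2$gene), ]
  expect_equal(dk1$diffk, dk2$diffk)
  expect_equal(dk1$hub, dk2$hub)
})

test_that("sector numbering puts hubs in sectors 1 and 3", {
  rec <- data.frame(gene = letters[1:6],
                    diffk = c(0.25, 0.25, -0.5, -0.5, 0.0, 0.0),
                    p = c(0.01, 0.5, 0.001, 0.5, 0.5, 0.01))
  out <- classify_sectors(rec)
  expect_equal(out$sector, c(1L, 2L, 3L, 4L, 5L, 6L))
  expect_equal(out$hub, c(TRUE, FALSE, TRUE, FALSE, FALSE, FALSE))
})

test_that("edge export filters by |r| and keeps signs", {
  r <- matrix(c(1, 0.9, -0.9,
                0.9, 1, 0.1,
                -0.9, 0.1, 1), 3, 3,
              dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
  state <- structure(list(condition = "IF-pre", genes = paste0("g", 1:3),
                          cor = r, K = colSums(abs(r)) - 1,
                          k = (colSums(abs(r)) - 1) / max(colSums(abs(r)) - 1),
                          n_profiles = 3L),
                     class = "NetworkState")
  out <- export_network(state, edge_threshold = 0.8)
  expect_equal(nrow(out$edges), 2L)
  expect_equal(sort(out$edges$sign), c("negative", "positive"))
  # threshold 1.0 keeps only perfect correlations
  expect_equal(nrow(export_network(state, edge_threshold = 1)$edges), 0L)
  expect_error(export_network(state, edge_threshold = 1.2), "edge_threshold")
})

test_that("mean degree decreases monotonically with the edge threshold", {
  study <- toy_study(n_genes = 25L, n_patients = c(IF = 4L), seed = 23L)
  state <- build_network(study, "IF", "pre", rownames(study$matrix))
  degrees <- sapply(c(0.2, 0.4, 0.6, 0.8, 0.99), function(thr)
    nrow(export_network(state, edge_threshold = thr)$edges))
  expect_true(all(diff(degrees) <= 0))
})
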