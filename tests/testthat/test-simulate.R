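test_that("simulation specs are validated", {
  expect_error(simulation_spec(modules = list(list(size = 2L, r_pre = 0.5,
                                                   r_post = 0.5))),
               "sizes must be >= 3")
  expect_error(simulation_spec(n_genes = 10L,
                               modules = list(list(size = 11L, r_pre = 0.5,
                                                   r_post = 0.5))),
               "larger than n_genes")
  expect_error(simulation_spec(modules = list(list(size = 5L, r_pre = 1,
                                                   r_post = 0))),
               "\\[0, 1\\)")
  expect_error(simulation_spec(de_fraction = 1.5), "de_fraction")
})

test_that("a fixed seed reproduces the study exactly", {
  spec <- simulation_spec(n_genes = 50L, seed = 33L)
  a <- simulate_expression(spec)
  b <- simulate_expression(spec)
  expect_identical(a$study$matrix, b$study$matrix)
  expect_identical(a$truth, b$truth)

  c1 <- simulate_clinical(seed = 5L)
  c2 <- simulate_clinical(seed = 5L)
  expect_identical(c1, c2)
})

test_that("the cohort shape matches the spec and truth is consistent", {
  spec <- simulation_spec(n_genes = 40L, de_fraction = 0.25, delta = 2,
                          modules = list(list(size = 5L, r_pre = 0.8,
                                              r_post = 0)),
                          seed = 1L)
  sim <- simulate_expression(spec)
  d <- sim$study$design
  expect_equal(sum(d$group == "IF" & d$timepoint == "pre"), 6L)
  expect_equal(sum(d$group == "ID" & d$timepoint == "pre"), 3L)
  expect_equal(nrow(sim$truth$de), 10L)
  expect_equal(sort(unique(sim$truth$de$effect)), c(-2, 2))
  expect_equal(sim$truth$expected_hubs$gene, sprintf("g%04d", 1:5))
  expect_true(all(sim$truth$expected_hubs$diffk_sign == -1))
})

test_that("planted shifts appear in the paired differences", {
  spec <- simulation_spec(n_genes = 200L, n_patients = c(IF = 10L),
                          de_fraction = 0.2, delta = 2, seed = 8L)
  sim <- simulate_expression(spec)
  d <- paired_differences(sim$study, "IF")
  est <- rowMeans(d)
  truth <- sim$truth$de
  expect_equal(unname(est[truth$gene]), truth$effect, tolerance = 0.5)
  null_genes <- setdiff(rownames(d), truth$gene)
  expect_lt(max(abs(est[null_genes])), 2)
})

test_that("module construction yields the planted correlation levels", {
  spec <- simulation_spec(n_genes = 100L, n_patients = c(IF = 40L),
                          de_fraction = 0, delta = 0,
                          modules = list(list(size = 10L, r_pre = 0.9,
                                              r_post = 0)),
                          seed = 9L)
  sim <- simulate_expression(spec)
  mod <- sim$truth$modules[[1L]]$genes
  pre <- condition_slice(sim$study, "IF", "pre", mod)
  post <- condition_slice(sim$study, "IF", "post", mod)
  r_pre <- cor(t(pre)); r_post <- cor(t(post))
  off <- upper.tri(r_pre)
  expect_equal(mean(r_pre[off]), 0.9, tolerance = 0.1)
  expect_lt(abs(mean(r_post[off])), 0.15)
})

test_that("difference variances follow the inverse-gamma prior", {
  spec <- simulation_spec(n_genes = 5000L, n_patients = c(IF = 6L),
                          de_fraction = 0, delta = 0, seed = 10L)
  sim <- simulate_expression(spec)
  s2 <- apply(paired_differences(sim$study, "IF"), 1L, var)
  fit <- rvm_fit(s2, 5L)
  expect_lt(abs(fit$a - spec$prior_a) / spec$prior_a, 0.15)
  expect_lt(abs(fit$b - spec$prior_b) / spec$prior_b, 0.15)
})

test_that("clinical simulation plants separation and stays calibrated", {
  base <- simulate_clinical(seed = 2L)
  expect_equal(nrow(base), 9L)
  expect_equal(sum(base$group == "IF"), 6L)
  expect_true(all(base$gada > 0))

  # complete separation: the exact p hits the 1/C(9,3) floor
  shifted <- simulate_clinical(seed = 2L, effects = list(insulin_12mo = 10))
  p <- mann_whitney_exact(shifted$insulin_12mo[shifted$group == "IF"],
                          shifted$insulin_12mo[shifted$group == "ID"])$p.value
  expect_equal(p, 1 / choose(9, 3))

  # zero effects: group-comparison p controls its level
  ps <- sapply(1:100, function(s) {
    tab <- simulate_clinical(seed = 100L + s)
    mann_whitney_exact(tab$cpeptide_pre[tab$group == "IF"],
                       tab$cpeptide_pre[tab$group == "ID"])$p.value
  })
  expect_lte(mean(ps <= 0.05 + 1e-9), 0.1)
  expect_gt(mean(ps), 0.3)

  expect_error(simulate_clinical(effects = list(insulin_12mo = Inf)),
               "finite")
  expect_error(simulate_clinical(effects = list(nope = 1)), "unknown")
})

test_that("a planted rewired module loses connectivity pre to post", {
  # a stable anchor module keeps the normalization maximum comparable
  # between the two states; the rewired module then shows its drop
  spec <- simulation_spec(n_genes = 80L, n_patients = c(IF = 20L),
                          de_fraction = 0, delta = 0,
                          modules = list(list(size = 10L, r_pre = 0.9,
                                              r_post = 0.9),
                                         list(size = 12L, r_pre = 0.9,
                                              r_post = 0)),
                          seed = 11L)
  sim <- simulate_expression(spec)
  genes <- rownames(sim$study$matrix)[1:50]
  pre <- build_network(sim$study, "IF", "pre", genes)
  post <- build_network(sim$study, "IF", "post", genes)
  dk <- diffk(pre, post)
  mod <- sim$truth$modules[[2L]]$genes
  expect_true(all(dk$diffk[dk$gene %in% mod] < 0))
  # the rewiring empties the network: mean connectivity drops
  expect_lt(mean(post$k), mean(pre$k))
})
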