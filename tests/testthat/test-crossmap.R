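fake_result <- function(ids, d) data.frame(probeset_id = ids, d = d,
                                           stringsAsFactors = FALSE)

test_that("alignment joins on probeset identifiers", {
  a <- fake_result(sprintf("p%02d", 1:20), rnorm(20))
  b <- fake_result(sprintf("p%02d", 20:1), rnorm(20))
  paired <- align_by_id(a, b)
  expect_equal(nrow(paired), 20)
  expect_equal(paired$d_b, b$d[match(paired$probeset_id, b$probeset_id)])

  # platform subset: pairs at the smaller set's size
  half <- fake_result(sprintf("p%02d", 1:10), rnorm(10))
  expect_equal(nrow(align_by_id(half, a)), 10)
  expect_equal(attr(align_by_id(a, half), "n_unmatched_a"), 10)

  disjoint <- fake_result(sprintf("q%02d", 1:10), rnorm(10))
  expect_error(align_by_id(a, disjoint), "in common")
})

test_that("concordance recovers exact and symmetric correlations", {
  set.seed(71)
  d <- rnorm(200)
  ids <- sprintf("p%03d", 1:200)
  same <- dstat_concordance(align_by_id(fake_result(ids, d), fake_result(ids, d)))
  expect_equal(same$r, 1, tolerance = 1e-12)
  neg <- dstat_concordance(align_by_id(fake_result(ids, d), fake_result(ids, -d)))
  expect_equal(neg$r, -1, tolerance = 1e-12)
  expect_identical(neg$p_label, "<1e-300")
  expect_equal(neg$p_value, 1e-300)

  e <- rnorm(200)
  ab <- dstat_concordance(align_by_id(fake_result(ids, d), fake_result(ids, e)))
  ba <- dstat_concordance(align_by_id(fake_result(ids, e), fake_result(ids, d)))
  expect_equal(ab$r, ba$r, tolerance = 1e-12)
  expect_equal(ab$r, cor(d, e), tolerance = 1e-12)

  expect_error(dstat_concordance(align_by_id(fake_result(ids[1:5], d[1:5]),
                                             fake_result(ids[1:5], d[1:5]))),
               "at least 10")
})

test_that("paired generators give concordance ordered by the shared fraction", {
  d_for <- function(cohort) {
    f <- filter_low_expression(cohort$matrix, 4)
    des <- sam_design(f, c("AU", "AI"), by = "phenotype")
    base <- compute_d(f, des, s0 = 0)
    s0 <- as.numeric(choose_s0(base$r, base$s))
    compute_d(f, des, s0 = s0)
  }
  r_at <- sapply(c(0, 0.5, 1), function(share) {
    cfg <- sim_config(n_genes = 3000, n_de = 200, effect_size = 2,
                      effect_size_unit = "gene_sd",
                      cross_dataset_share = share, seed = 72)
    pair <- generate_paired_datasets(cfg)
    paired <- align_by_id(d_for(pair$a), d_for(pair$b))
    dstat_concordance(paired)$r
  })
  expect_true(all(diff(r_at) > 0))
  expect_lt(abs(r_at[1]), 0.1)   # no shared effects: near-null correlation
  expect_gt(r_at[3], 0.3)        # fully shared effects: clear concordance
})

test_that("shift tests detect planted shifts with the right direction", {
  set.seed(73)
  ids <- sprintf("p%04d", 1:3000)
  d <- rnorm(3000)
  set_ids <- sample(ids, 100)
  d[match(set_ids, ids)] <- d[match(set_ids, ids)] + 1.0
  res <- fake_result(ids, d)
  for (m in c("ranksum", "ks", "perm")) {
    sh <- geneset_shift_test(res, set_ids, method = m, n_perm = 2000, seed = 5)
    expect_identical(sh$direction, "increased")
    expect_lt(sh$p_value, 0.001)
  }
  down <- geneset_shift_test(fake_result(ids, -d), set_ids)
  expect_identical(down$direction, "decreased")
})

test_that("degenerate and invalid sets are refused or defined", {
  ids <- sprintf("p%03d", 1:100)
  res <- fake_result(ids, rnorm(100))
  expect_error(geneset_shift_test(res, ids[1:3]), "fewer than 5")
  expect_error(geneset_shift_test(res, ids, method = "ranksum"), "complement")
  whole <- geneset_shift_test(res, ids, method = "perm")
  expect_equal(whole$p_value, 1)
  expect_error(geneset_shift_test(res, ids[1:20], method = "bogus"))
})

test_that("shift-test p-values are calibrated under the null", {
  set.seed(74)
  p <- numeric(400)
  k <- 0
  for (i in 1:8) {
    d <- rnorm(2500)
    ids <- sprintf("p%04d", 1:2500)
    res <- fake_result(ids, d)
    for (j in 1:50) {
      k <- k + 1
      p[k] <- geneset_shift_test(res, sample(ids, 100))$p_value
    }
  }
  rej <- mean(p < 0.05)
  ci <- 0.05 + c(-1, 1) * 1.96 * sqrt(0.05 * 0.95 / 400)
  expect_gte(rej, ci[1] - 1e-9)
  expect_lte(rej, ci[2] + 1e-9)
  # rank-sum p-values are mildly discrete, so exact-tie warnings are expected
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.01)
})

test_that("density summaries integrate to one and shift with the set", {
  set.seed(75)
  ids <- sprintf("p%04d", 1:2000)
  d <- rnorm(2000)
  set_ids <- sample(ids, 150)
  d[match(set_ids, ids)] <- d[match(set_ids, ids)] + 2
  curves <- shift_density_summary(fake_result(ids, d),
                                  list(planted = set_ids, all = ids))
  dx <- diff(curves$d[1:2])
  for (col in c("all_genes", "planted", "all"))
    expect_equal(sum(curves[[col]]) * dx, 1, tolerance = 1e-3)
  expect_equal(curves$all, curves$all_genes, tolerance = 1e-12)
  mode_set <- curves$d[which.max(curves$planted)]
  mode_bg <- curves$d[which.max(curves$all_genes)]
  expect_gt(mode_set, mode_bg + 1)
  expect_error(shift_density_summary(fake_result(ids, d), list(s = set_ids),
                                     n_grid = 1), "grid")
})

test_that("list overlap counts, fractions and enrichment are exact", {
  uni <- sprintf("g%02d", 1:20)
  a <- uni[1:8]
  ov <- list_overlap(a, a, uni)
  expect_equal(ov$frac_a_in_b, 1)
  expect_equal(ov$frac_b_in_a, 1)

  b <- uni[9:12]
  ov2 <- list_overlap(a, b, uni)
  expect_equal(ov2$n_overlap, 0)
  expect_equal(ov2$frac_a_in_b, 0)
  expect_equal(ov2$p_hyper, oracle_hyper_tail(0, 8, 20, 4), tolerance = 1e-12)

  sub <- a[1:3]
  expect_equal(list_overlap(sub, a, uni)$frac_a_in_b, 1)
  # exact enumeration oracle on a non-trivial overlap
  c_ <- uni[c(1:3, 9:13)]
  ov3 <- list_overlap(a, c_, uni)
  expect_equal(ov3$n_overlap, 3)
  expect_equal(ov3$p_hyper, oracle_hyper_tail(3, 8, 20, 8), tolerance = 1e-12)
  expect_error(list_overlap(a, b, character(0)), "universe")
})
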