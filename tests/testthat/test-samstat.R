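test_that("d matches the hand-evaluated formula and the pooled t-statistic", {
  v <- rbind(g = c(1, 2, 3, 4, 5, 6))
  x <- expression_matrix(matrix(as.numeric(v), 1, 6,
                                dimnames = list("g", paste0("s", 1:6))))
  des <- sam_design(setNames(rep(c("A", "B"), each = 3), paste0("s", 1:6)),
                    c("A", "B"))
  out <- compute_d(x, des, s0 = 0)
  expect_equal(out$r, -3)
  expect_equal(out$s, sqrt((1 / 3 + 1 / 3) * (2 + 2) / 4), tolerance = 1e-12)
  expect_equal(out$d, -3 / 0.81649658, tolerance = 1e-7)  # -3.674 by hand

  # identical group means: d exactly zero
  v2 <- matrix(c(1, 2, 3, 3, 2, 1), 1, dimnames = list("g", paste0("s", 1:6)))
  expect_equal(compute_d(expression_matrix(v2), des, s0 = 0)$d, 0)
})

test_that("d equals an independent direct-formula oracle and t.test", {
  x <- null_matrix(50, 8, 8, seed = 31)
  des <- sam_design(null_groups(8, 8), c("A", "B"))
  for (s0 in c(0, 0.2, 1)) {
    got <- compute_d(x, des, s0 = s0)
    want <- oracle_d(x$values, 1:8, 9:16, s0 = s0)
    expect_equal(got$d, unname(want[, "d"]), tolerance = 1e-12)
  }
  got0 <- compute_d(x, des, s0 = 0)
  tt <- apply(x$values, 1, function(row)
    t.test(row[1:8], row[9:16], var.equal = TRUE)$statistic)
  expect_equal(got0$d, unname(tt), tolerance = 1e-10)
})

test_that("large s0 shrinks every |d| monotonically toward zero", {
  x <- null_matrix(30, 4, 4, seed = 32)
  des <- sam_design(null_groups(4, 4), c("A", "B"))
  d1 <- abs(compute_d(x, des, s0 = 0.5)$d)
  d2 <- abs(compute_d(x, des, s0 = 5)$d)
  d3 <- abs(compute_d(x, des, s0 = 500)$d)
  expect_true(all(d2 < d1))
  expect_true(all(d3 < d2))
  expect_lt(max(d3), 0.01)
})

test_that("degenerate designs and variances are handled", {
  x <- null_matrix(5, 2, 3, seed = 33)
  expect_error(sam_design(setNames(c("A", "B", "B"), paste0("s", 1:3)),
                          c("A", "B")), "at least 2")
  v <- matrix(c(1, 1, 1, 2, 2, 2), 1, dimnames = list("g", paste0("s", 1:6)))
  des <- sam_design(setNames(rep(c("A", "B"), each = 3), paste0("s", 1:6)),
                    c("A", "B"))
  expect_warning(out <- compute_d(expression_matrix(v), des, s0 = 0), "infinite")
  expect_identical(out$d, -Inf)
})

test_that("s0 selection matches an independent grid-search oracle", {
  set.seed(41)
  n <- 2000
  # scatter tracks the spread of r (heterogeneous true variances): d = r/s is
  # already flat across scatter windows, so the selection stays at the bottom
  s_track <- runif(n, 0.1, 2)
  r_track <- rnorm(n, 0, s_track)
  pick <- choose_s0(r_track, s_track)
  orc <- oracle_s0(r_track, s_track)
  expect_equal(as.numeric(pick), unname(orc$s0), tolerance = 1e-12)
  expect_lte(attr(pick, "percentile"), 10)

  # scatter unrelated to the spread of r: low-scatter genes dominate d and a
  # positive s0 flattens the CV
  s_free <- runif(n, 0.05, 1)
  r_free <- rnorm(n, 0, 0.2)
  pick2 <- choose_s0(r_free, s_free)
  expect_gt(as.numeric(pick2), 0)
  tab <- attr(pick2, "cv_table")
  expect_lte(tab$cv[tab$s0 == as.numeric(pick2)][1], tab$cv[1])
  orc2 <- oracle_s0(r_free, s_free)
  expect_equal(as.numeric(pick2), unname(orc2$s0), tolerance = 1e-12)

  expect_equal(as.numeric(choose_s0(r_track, s_track, candidate_percentiles = 50)),
               unname(quantile(s_track, 0.5)))
  expect_warning(z <- choose_s0(r_track, rep(1, n)), "degenerate")
  expect_equal(as.numeric(z), 0)
})

test_that("permutation null enumerates small designs and is seed-stable", {
  x <- null_matrix(100, 3, 3, seed = 51)
  des <- sam_design(null_groups(3, 3), c("A", "B"))
  null <- permute_null(x, des, B = 1000, seed = 1, s0 = 0)
  expect_equal(null$B, choose(6, 3))  # 20 distinct assignments
  null2 <- permute_null(x, des, B = 1000, seed = 99, s0 = 0)
  expect_identical(null$d_sorted, null2$d_sorted)  # enumeration ignores seed

  x8 <- null_matrix(100, 8, 8, seed = 52)
  des8 <- sam_design(null_groups(8, 8), c("A", "B"))
  a <- permute_null(x8, des8, B = 50, seed = 7, s0 = 0)
  b <- permute_null(x8, des8, B = 50, seed = 7, s0 = 0)
  expect_identical(a$dbar, b$dbar)
  expect_equal(ncol(a$d_sorted), 50)
  expect_error(permute_null(x8, des8, B = 0), "at least 1")
})

test_that("null data hugs the expected order statistics", {
  x <- null_matrix(2000, 8, 8, seed = 53)
  des <- sam_design(null_groups(8, 8), c("A", "B"))
  d <- compute_d(x, des, s0 = 0)$d
  null <- permute_null(x, des, B = 200, seed = 3, s0 = 0)
  dev <- sort(d) - null$dbar
  expect_lt(median(abs(dev)), 0.05)
  expect_gt(cor(sort(d), null$dbar), 0.99)
})

test_that("the delta table behaves at its edges and is monotone", {
  x <- null_matrix(1000, 8, 8, seed = 54)
  des <- sam_design(null_groups(8, 8), c("A", "B"))
  d <- compute_d(x, des, s0 = 0)$d
  null <- permute_null(x, des, B = 100, seed = 5, s0 = 0)
  tab <- estimate_fdr_table(d, null)
  # delta = 0 on null data: essentially everything called, FDR near 1
  expect_gt(tab$fdr_raw[1], 0.8)
  # largest delta: no calls, FDR undefined
  expect_identical(tab$n_called[nrow(tab)], 0L)
  expect_true(is.na(tab$fdr[nrow(tab)]))
  # monotonicity: calls shrink and monotonized FDR never rises with delta
  expect_true(all(diff(tab$n_called) <= 0))
  ok <- !is.na(tab$fdr)
  expect_true(all(diff(tab$fdr[ok]) <= 1e-12))
  expect_true(all(diff(tab$cut_up[is.finite(tab$cut_up)]) >= 0))
})

test_that("significance calls are nested across FDR targets", {
  cfg <- sim_config(n_genes = 3000, group_sizes = c("A-S" = 8, "B-S" = 8),
                    de_groups = "A-S", frac_low_expressed = 0, n_de = 150,
                    effect_size = 2, effect_size_unit = "gene_sd",
                    array_effect_sd = 0, seed = 55)
  co <- generate_cohort(cfg)
  des <- sam_design(co$matrix, c("A", "B"), by = "phenotype")
  res <- sam(co$matrix, des, fdr = c(0.01, 0.05, 0.1), B = 100, seed = 6)
  ids <- lapply(res$calls, function(cl) cl$calls$probeset_id)
  expect_true(all(ids[["0.01"]] %in% ids[["0.05"]]))
  expect_true(all(ids[["0.05"]] %in% ids[["0.1"]]))
  # direction: planted genes were up-shifted in group A half the time;
  # every call's direction matches the sign of its d
  cl <- res$calls[["0.05"]]$calls
  expect_identical(cl$direction, ifelse(cl$d > 0, "increased", "decreased"))
})

test_that("a zero FDR target on null data calls nothing", {
  x <- null_matrix(500, 8, 8, seed = 56)
  des <- sam_design(null_groups(8, 8), c("A", "B"))
  d <- compute_d(x, des, s0 = 0)$d
  null <- permute_null(x, des, B = 50, seed = 2, s0 = 0)
  tab <- estimate_fdr_table(d, null)
  expect_message(cl <- call_significant(tab, d, 0,
                                        probeset_ids = rownames(x$values)),
                 "zero calls")
  expect_equal(cl$n_called, 0L)
})

test_that("Monte-Carlo and enumerated FDR agree on a 3v3 design", {
  cfg <- sim_config(n_genes = 1500, group_sizes = c("A-S" = 3, "B-S" = 3),
                    de_groups = "A-S", frac_low_expressed = 0, n_de = 100,
                    effect_size = 3, effect_size_unit = "gene_sd",
                    array_effect_sd = 0, seed = 57)
  co <- generate_cohort(cfg)
  des <- sam_design(co$matrix, c("A", "B"), by = "phenotype")
  d <- compute_d(co$matrix, des, s0 = 0)$d
  enum <- permute_null(co$matrix, des, B = 20, seed = 1, s0 = 0,
                       method = "enumerate")
  mc <- permute_null(co$matrix, des, B = 1000, seed = 2, s0 = 0,
                     method = "sample")
  deltas <- seq(0, 2, by = 0.1)
  t_enum <- estimate_fdr_table(d, enum, deltas = deltas)
  t_mc <- estimate_fdr_table(d, mc, deltas = deltas)
  both <- !is.na(t_enum$fdr) & !is.na(t_mc$fdr)
  expect_true(any(both))
  expect_lt(max(abs(t_enum$fdr[both] - t_mc$fdr[both])), 0.02)
})
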