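test_that("auc_se implements the b-1 divisor standard error", {
  expect_equal(auc_se(rep(0.8, 10)), 0)
  expect_equal(auc_se(c(0.8, 0.9)), 0.070710678, tolerance = 1e-8)
  expect_equal(auc_se(c(0.7, 0.8, 0.9)), 0.1, tolerance = 1e-12)
  expect_error(auc_se(0.5), "at least two")
  set.seed(200)
  for (i in 1:50) {
    x <- runif(sample(2:40, 1))
    expect_equal(auc_se(x), sd(x), tolerance = 1e-12)
  }
})

test_that("identity resamples give identical replicates and zero se", {
  mt <- rand_table(6, 6, p = 4, seed = 210)
  cod <- plsdafuse:::code_response(mt$groups)
  idx <- matrix(rep(0:11, 2), ncol = 2)  # two identity "resamples"
  res <- plsdafuse:::cpp_bootstrap(mt$values, cod$y, idx, 3L,
                                   TRUE, TRUE, FALSE, TRUE, FALSE)
  expect_equal(res$auc[1], res$auc[2])
  expect_equal(auc_se(res$auc), 0)
  expect_equal(res$vip[1, ], res$vip[2, ])
})

test_that("bootstrap runs are reproducible and within bounds", {
  mt <- rand_table(8, 8, p = 6, seed = 220)
  a <- bootstrap_plsda(mt, B = 50, seed = 5)
  b <- bootstrap_plsda(mt, B = 50, seed = 5)
  expect_identical(a$auc, b$auc)
  expect_identical(a$vip_mean, b$vip_mean)
  expect_identical(a$sr_mean, b$sr_mean)
  expect_true(all(a$auc >= 0 & a$auc <= 1))
  expect_length(a$auc, 50L)
  expect_gte(a$auc_se, 0)
  c <- bootstrap_plsda(mt, B = 50, seed = 6)
  expect_false(identical(a$auc, c$auc))
})

test_that("strong planted separation yields high out-of-bag AUC", {
  sp <- synthetic_spec(n_group_a = 30, n_group_b = 30,
                       planted = planted_five(3.0), seed = 230)
  mt <- generate_cohort(sp)
  parts <- split_tables(mt, balanced_split(mt))
  run <- bootstrap_plsda(parts$model, B = 200, seed = 7,
                         collect = "none")
  expect_gte(run$auc_mean, 0.95)
})

test_that("label permutation brings the mean bootstrap AUC to chance", {
  sp <- synthetic_spec(n_group_a = 60, n_group_b = 60,
                       planted = planted_five(3.0), seed = 240)
  mt <- generate_cohort(sp)
  set.seed(8)
  mt$groups <- sample(mt$groups)
  parts <- split_tables(mt, balanced_split(mt))
  run <- bootstrap_plsda(parts$model, B = 200, seed = 9,
                         collect = "none")
  expect_lt(abs(run$auc_mean - 0.5), 0.1)
})

test_that("VIP selection keeps a lone variable and honours a zero cutoff", {
  mt1 <- rand_table(6, 6, p = 1, seed = 250)
  sel1 <- vip_selection_rounds(mt1, B = 20, seed = 1)
  expect_identical(sel1$retained, colnames(mt1$values))
  mt <- rand_table(8, 8, p = 5, seed = 251)
  sel0 <- vip_selection_rounds(mt, cutoff = 0, rounds = 2, B = 20,
                               seed = 2)
  expect_setequal(sel0$retained, colnames(mt$values))
})

test_that("raising a cutoff never enlarges the retained set", {
  sp <- synthetic_spec(n_group_a = 15, n_group_b = 15,
                       block_sizes = c(serum = 12),
                       planted = c(serum__v2 = 1.5, serum__v7 = 2),
                       seed = 260)
  mt <- generate_cohort(sp)
  vips <- lapply(c(0.6, 0.8, 1.0), function(co) {
    tryCatch(vip_selection_rounds(mt, cutoff = co, rounds = 2, B = 40,
                                  seed = 3),
             error = function(e) list(retained = character(0)))
  })
  expect_true(all(vips[[2]]$retained %in% vips[[1]]$retained))
  expect_true(all(vips[[3]]$retained %in% vips[[2]]$retained))
  srs <- lapply(c(0.05, 0.2, 0.8), function(co) {
    tryCatch(sr_selection(mt, cutoff = co, B = 40, seed = 3),
             error = function(e) list(retained = character(0)))
  })
  expect_true(all(srs[[2]]$retained %in% srs[[1]]$retained))
  expect_true(all(srs[[3]]$retained %in% srs[[2]]$retained))
})

test_that("SR selection boundary cutoffs behave as documented", {
  mt <- rand_table(8, 8, p = 5, seed = 270)
  all_in <- sr_selection(mt, cutoff = 0, B = 20, seed = 4)
  expect_setequal(all_in$retained, colnames(mt$values))
  expect_error(sr_selection(mt, cutoff = Inf, B = 20, seed = 4),
               "no variable reaches")
})

test_that("selection runs are reproducible end to end", {
  sp <- synthetic_spec(n_group_a = 12, n_group_b = 12,
                       block_sizes = c(serum = 8),
                       planted = c(serum__v1 = 2), seed = 280)
  mt <- generate_cohort(sp)
  s1 <- vip_selection_rounds(mt, B = 30, seed = 11)
  s2 <- vip_selection_rounds(mt, B = 30, seed = 11)
  expect_identical(s1$retained, s2$retained)
  expect_identical(s1$audit[[1]]$vip_mean, s2$audit[[1]]$vip_mean)
  r1 <- sr_selection(mt, B = 30, seed = 12)
  r2 <- sr_selection(mt, B = 30, seed = 12)
  expect_identical(r1$retained, r2$retained)
  expect_identical(r1$cutoff, r2$cutoff)
})

test_that("MCCR is flat near 50% for pure-noise variables", {
  # large cohort so accidental group differences (which SR binning sorts
  # to the top intervals) stay small
  mt <- rand_table(200, 200, p = 30, seed = 290)
  run <- bootstrap_plsda(mt, B = 10, seed = 13, collect = "sr")
  curve <- diva_mccr(run, mt, intervals = 4, reps = 200, seed = 14)
  occupied <- !is.na(curve$mccr)
  expect_true(all(abs(curve$mccr[occupied] - 50) < 5))
})

test_that("MCCR increases with SR under graded planted effects", {
  rhos <- vapply(1:50, function(i) {
    grad <- setNames(c(0.5, 1, 1.5, 2, 2.5),
                     paste0("serum__v", c(2, 5, 8, 11, 14)))
    sp <- synthetic_spec(n_group_a = 15, n_group_b = 15,
                         block_sizes = c(serum = 16), planted = grad,
                         seed = 300 + i)
    mt <- generate_cohort(sp)
    run <- bootstrap_plsda(mt, B = 30, seed = 300 + i, collect = "sr")
    curve <- diva_mccr(run, mt, intervals = 5, reps = 100,
                       seed = 400 + i)
    keep <- !is.na(curve$mccr)
    suppressWarnings(cor(seq_along(curve$mccr)[keep], curve$mccr[keep],
                         method = "spearman"))
  }, numeric(1))
  expect_gt(mean(rhos, na.rm = TRUE), 0.5)
  expect_gt(mean(rhos > 0, na.rm = TRUE), 0.9)
})

test_that("a single SR interval reports the pooled rate", {
  mt <- rand_table(10, 10, p = 6, seed = 310)
  run <- bootstrap_plsda(mt, B = 20, seed = 15, collect = "sr")
  curve <- diva_mccr(run, mt, intervals = 1, reps = 100, seed = 16)
  expect_length(curve$mccr, 1L)
  expect_equal(curve$mccr, 100 * mean(curve$per_variable_ccr),
               ignore_attr = TRUE)
})

test_that("interval count is capped by the number of variables", {
  mt <- rand_table(10, 10, p = 3, seed = 320)
  run <- bootstrap_plsda(mt, B = 20, seed = 17, collect = "sr")
  expect_message(curve <- diva_mccr(run, mt, intervals = 10, reps = 50,
                                    seed = 18),
                 "more intervals")
  expect_length(curve$mccr, 3L)
})
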