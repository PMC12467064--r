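test_that("accuracy delta and parameter variation are plain differences", {
  expect_equal(accuracy_delta(93.56, 93.53), 0.03)
  expect_equal(accuracy_delta(50, 50), 0)
  expect_equal(accuracy_delta(94.83, 95.04), -0.21)
  expect_equal(parameters_variation(100, 100), 0)
  expect_equal(parameters_variation(200, 100), 100)
  expect_equal(parameters_variation(278459, 1236877), -77.49, tolerance = 0.01 / 77)
  expect_error(parameters_variation(10, 0), class = "gaitphase_config_error")
})

test_that("the logistic compression has the right midpoint, asymptotes and antisymmetry", {
  expect_equal(pvc(0), 0)
  expect_equal(pvc(-1e6), 1, tolerance = 1e-12)
  expect_equal(pvc(1e6), -1, tolerance = 1e-12)
  expect_equal(pvc(-77.49, 1, 0.05), 0.959, tolerance = 0.001 / 0.959)
  v <- seq(-120, 120, by = 7.5)
  expect_equal(pvc(v), -pvc(-v))
  expect_error(pvc(1, L = 0), class = "gaitphase_config_error")
})

test_that("TOS reproduces the worked selection-surface examples", {
  pr <- count_parameters(build_full_bilstm())
  r1 <- tos(93.56, 93.53, count_parameters(build_pruned_bilstm(15, 53)), pr)
  expect_equal(gaitphase:::round_half_away(r1$tos, 2), 0.49)
  r2 <- tos(93.78, 93.53, count_parameters(build_pruned_bilstm(50, 100)), pr)
  expect_equal(gaitphase:::round_half_away(r2$tos, 2), 0.35)
  r3 <- tos(94.83, 95.04, count_parameters(build_pruned_bilstm(27, 57)), pr)
  expect_equal(gaitphase:::round_half_away(r3$tos, 2), 0.37)
  # self-comparison is exactly zero
  self <- tos(93.53, 93.53, pr, pr)
  expect_identical(self$tos, 0)
  # the -1% floor excludes
  ex <- tos(91, 93.53, 1000, pr)
  expect_true(ex$excluded)
  expect_true(is.na(ex$tos))
  # the normalization assumes |Ad| <= 1
  expect_warning(tos(96, 93.53, 1000, pr), "exceeds 1 percentage point")
})

test_that("TOS is monotone in accuracy and parameter count and bounded for |Ad| <= 1", {
  pr <- 1e6
  accs <- seq(92.6, 94.5, by = 0.1)
  scores <- vapply(accs, function(a) tos(a, 93.5, 5e5, pr)$tos, numeric(1))
  expect_true(all(diff(scores) > 0))
  pcs <- seq(1e5, 2e6, length.out = 20)
  scores <- vapply(pcs, function(p) tos(93.5, 93.5, p, pr)$tos, numeric(1))
  expect_true(all(diff(scores) < 0))
  ad <- seq(-1, 1, by = 0.05)
  pv <- seq(-200, 200, by = 10)
  all_scores <- outer(ad, pv, function(a, v) (a + pvc(v)) / 2)
  expect_true(all(all_scores >= -1 & all_scores <= 1))
})

test_that("ranking reproduces the published winner and applies floor and tie-break", {
  pub <- published_candidates("kinematics")
  ranked <- rank_candidates(pub$candidates, pub$reference)
  expect_identical(ranked$name[1], "[15 53]")
  expect_equal(ranked$tos_2dp, c(0.49, 0.35))
  # floor exclusion
  with_bad <- dplyr::bind_rows(pub$candidates,
                               tibble::tibble(name = "bad", accuracy = 91.53,
                                              n_parameters = 1000))
  expect_false("bad" %in% rank_candidates(with_bad, pub$reference)$name)
  # tie-break toward fewer parameters
  tied <- tibble::tibble(name = c("big", "small"), accuracy = c(93.53, 93.53),
                         n_parameters = c(5e5, 5e5))
  tied$n_parameters <- c(5e5, 4e5)
  tied$accuracy <- c(93.53, 93.53)
  ranked_tied <- rank_candidates(tied, list(accuracy = 93.53, n_parameters = 5e5))
  expect_identical(ranked_tied$name[1], "small")
  expect_error(rank_candidates(pub$candidates[0, ], pub$reference),
               class = "gaitphase_data_error")
})

test_that("the winner flips exactly when alpha drops below 0.01", {
  kin <- published_candidates("kinematics")
  wk <- alpha_sensitivity(kin$candidates, kin$reference)
  expect_identical(wk$winner[wk$alpha %in% c(0.01, 0.05)], rep("[15 53]", 2))
  expect_identical(wk$winner[wk$alpha %in% c(0.001, 0.005)], rep("[50 100]", 2))

  sh <- published_candidates("shifted")
  ws <- alpha_sensitivity(sh$candidates, sh$reference)
  expect_identical(ws$winner[ws$alpha %in% c(0.01, 0.05)], rep("[27 57]", 2))
  expect_identical(ws$winner[ws$alpha %in% c(0.001, 0.005)], rep("Full-BiLSTM", 2))
  expect_true(all(ws$reference_wins[ws$alpha < 0.01]))

  # very large slope: any smaller candidate above the floor beats the reference
  big <- alpha_sensitivity(tibble::tibble(name = "c", accuracy = 93.0,
                                          n_parameters = 1e5),
                           list(name = "r", accuracy = 93.5, n_parameters = 1e6),
                           alphas = 50)
  expect_identical(big$winner, "c")
})
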