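test_that("parameter accounting reproduces the published architecture counts", {
  expect_identical(count_parameters(build_full_bilstm()), 1236877)
  expect_identical(count_parameters(build_small_bilstm()), 184602)
  expect_identical(count_parameters(build_gru()), 54252)
  expect_identical(count_parameters(build_res_tcn()), 768834)
  expect_identical(count_parameters(build_attention()), 149890)
  expect_identical(format_parameter_count(count_parameters(build_full_bilstm())), "1.2 M")
  expect_identical(format_parameter_count(count_parameters(build_small_bilstm())), "184.6 k")
  expect_identical(format_parameter_count(count_parameters(build_gru())), "54.2 k")
  expect_identical(format_parameter_count(count_parameters(build_res_tcn())), "768.8 k")
  expect_identical(format_parameter_count(count_parameters(build_attention())), "149.8 k")
  expect_lt(count_parameters(build_gru()), count_parameters(build_small_bilstm()))
  expect_lt(count_parameters(build_small_bilstm()), count_parameters(build_full_bilstm()))
})

test_that("pruned-family counts match the published search-surface values", {
  expect_identical(count_parameters(build_pruned_bilstm(15, 53)), 278459)
  expect_identical(count_parameters(build_pruned_bilstm(27, 57)), 325127)
  expect_identical(count_parameters(build_pruned_bilstm(50, 100)), 994852)
  expect_identical(trunc(count_parameters(build_pruned_bilstm(15, 53)) / 1e3), 278)
  expect_identical(trunc(count_parameters(build_pruned_bilstm(27, 57)) / 1e3), 325)
  expect_identical(trunc(count_parameters(build_pruned_bilstm(50, 100)) / 1e3), 994)
  expect_warning(build_pruned_bilstm(10, 53), "outside the search box")
  expect_error(build_pruned_bilstm(0, 10), class = "gaitphase_config_error")
})

test_that("dense counting and structural invariants hold", {
  frag <- model_spec("frag", list(layer_input(64L), layer_dense(2L), layer_softmax()))
  expect_identical(count_parameters(frag), 130)
  expect_identical(memory_footprint(frag), 520)
  expect_identical(memory_footprint(build_pruned_bilstm(27, 57)), 4 * 325127)
  # blocks 2 and 3 of the Res-TCN hold identical counts (same shapes)
  tcn <- build_res_tcn()
  kinds <- vapply(tcn$layers, function(l) l$kind, character(1))
  block_edges <- which(kinds == "add_skip")
  block_count <- function(j) {
    idx <- (block_edges[j] - 5L):block_edges[j]
    sub <- model_spec("b", c(list(layer_input(64L)), tcn$layers[idx],
                             list(layer_dense(2L), layer_softmax())))
    count_parameters(sub) - 130
  }
  expect_identical(block_count(2), block_count(3))
  # attention block sub-sum
  att_only <- count_parameters(build_attention()) -
    count_parameters(model_spec("rest", list(
      layer_input(4L), layer_dense(128L), layer_relu(), layer_dropout(0.4),
      layer_layer_norm(), layer_layer_norm(),
      layer_dense(128L), layer_relu(), layer_dropout(0.4),
      layer_dense(2L), layer_softmax())))
  expect_identical(att_only, 131968)
  expect_error(model_spec("bad", list(layer_input(4L), layer_dense(3L), layer_softmax())),
               class = "gaitphase_spec_error")
  expect_error(layer_dropout(1.5), class = "gaitphase_config_error")
})

test_that("the receptive-field rule matches empirical dependency tracing", {
  expect_identical(receptive_field(1, 2, 1, 3), 3)
  expect_identical(receptive_field(2, 2, 3, 37), 505)
  expect_identical(receptive_field(2, 2, 3, 36), 491)

  grid <- expand.grid(c = 1:3, b = 2:3, N = 1:3, k = c(2, 5, 9))
  grid <- grid[withr::with_seed(4, sample(nrow(grid), 12)), ]  # spot-check a dozen combinations
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    expect_identical(empirical_receptive_field(g$c, g$b, g$N, g$k),
                     as.integer(receptive_field(g$c, g$b, g$N, g$k)),
                     info = paste(g, collapse = ","))
  }
})

test_that("kernel selection minimizes the receptive-field mismatch", {
  expect_identical(select_kernel(500, 2, 2, 3), 37L)
  hit <- receptive_field(2, 2, 3, 5)
  expect_identical(select_kernel(hit, 2, 2, 3), 5L)
  # brute-force scan oracle
  for (target in c(100, 333, 500, 701)) {
    errs <- abs(sapply(1:200, function(k) receptive_field(2, 2, 3, k)) - target)
    expect_identical(select_kernel(target, 2, 2, 3), which.min(errs))
  }
})
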