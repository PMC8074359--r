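# Architecture plans, parameter counts, the convolution cost model and the
# compiled layers.

test_that("block plans follow the reference layout and the removal rule", {
  p13 <- block_plan(model_config(alpha = 1, beta = 13))
  expect_identical(sum(p13$kind == "depthwise_conv"), 13L)
  expect_identical(sum(p13$kind == "pointwise_conv"), 13L)
  # five identical 512->512 stride-1 blocks in the reference
  expect_identical(sum(p13$kind == "pointwise_conv" & p13$in_ch == 512 &
                         p13$out_ch == 512 & p13$stride == 1), 5L)
  p10 <- block_plan(model_config(alpha = 0.75, beta = 10))
  expect_identical(sum(p10$kind == "depthwise_conv"), 10L)
  # 2 of the five identical (now 384-channel) blocks remain
  expect_identical(sum(p10$kind == "pointwise_conv" & p10$in_ch == 384 &
                         p10$out_ch == 384), 2L)
  # all other blocks intact: output-channel sequence
  pw10 <- p10[p10$kind == "pointwise_conv", ]
  expect_identical(pw10$out_ch,
                   as.integer(round(0.75 * c(64, 128, 128, 256, 256, 512,
                                             512, 512, 1024, 1024))))
  # stem width scales with alpha
  expect_identical(p10$out_ch[p10$kind == "standard_conv"], 24L)
  expect_identical(block_plan(model_config(0.5, 8))$out_ch[1], 16L)
  expect_error(model_config(beta = 14), "beta")
  expect_error(model_config(beta = 7), "beta")
  expect_error(model_config(alpha = 0), "alpha")
})

test_that("parameter counts reproduce the published shrinking grid", {
  count_m <- function(alpha, beta)
    attr(count_params(block_plan(model_config(alpha, beta))), "millions")
  expect_equal(count_m(0.75, 12), 1.67)
  expect_equal(count_m(0.75, 10), 1.36)
  expect_equal(count_m(0.75, 8), 1.05, tolerance = 0.011)
  expect_equal(count_m(0.5, 10), 0.61)
})

test_that("count_params applies the declared convention layer by layer", {
  dense_only <- data.frame(kind = "dense", k = 0L, stride = 1L,
                           in_ch = 768L, out_ch = 4L)
  expect_identical(as.numeric(count_params(dense_only)), 3076)
  bn_only <- data.frame(kind = "batch_norm", k = 0L, stride = 1L,
                        in_ch = 32L, out_ch = 32L)
  expect_identical(as.numeric(count_params(bn_only)), 64)
  conv_only <- data.frame(kind = "standard_conv", k = 3L, stride = 2L,
                          in_ch = 1L, out_ch = 24L)
  expect_identical(as.numeric(count_params(conv_only)), 216)
})

test_that("parameter counts increase strictly in width and depth", {
  grid <- expand.grid(alpha = c(0.5, 0.75), beta = c(8, 10, 12))
  counts <- mapply(function(a, b)
    as.numeric(count_params(block_plan(model_config(a, b)))),
    grid$alpha, grid$beta)
  for (a in c(0.5, 0.75)) {
    cc <- counts[grid$alpha == a][order(grid$beta[grid$alpha == a])]
    expect_true(all(diff(cc) > 0))
  }
  for (b in c(8, 10, 12)) {
    cc <- counts[grid$beta == b][order(grid$alpha[grid$beta == b])]
    expect_true(all(diff(cc) > 0))
  }
})

test_that("convolution cost formulas are exact", {
  expect_identical(conv_cost_standard(conv_cost_spec(1, 1, 1, 1, 1)), 1)
  expect_identical(conv_cost_ds(conv_cost_spec(1, 1, 1, 1, 1)), 2)
  s <- conv_cost_spec(32, 32, 16, 3, 64)
  expect_identical(conv_cost_standard(s), 9437184)
  expect_identical(conv_cost_ds(s), 147456 + 1048576)
  # doubling M doubles the standard cost
  s2 <- conv_cost_spec(32, 32, 16, 3, 128)
  expect_identical(conv_cost_standard(s2), 2 * conv_cost_standard(s))
  expect_equal(cost_ratio(conv_cost_spec(1, 1, 1, 1, 1)), 2)
  expect_equal(cost_ratio(s), 1 / 64 + 1 / 9, tolerance = 1e-12)
  expect_error(conv_cost_spec(0, 1, 1, 1, 1), "positive")
})

test_that("cost ratio equals 1/M + 1/k^2 independent of map size", {
  set.seed(2)
  for (i in 1:200) {
    w <- sample(64, 1); h <- sample(64, 1); N <- sample(128, 1)
    k <- sample(7, 1); M <- sample(128, 1)
    s <- conv_cost_spec(w, h, N, k, M)
    # integer identity: ds * M * k^2 == std * (k^2 + M)
    expect_identical(conv_cost_ds(s) * M * k^2,
                     conv_cost_standard(s) * (k^2 + M))
    expect_equal(cost_ratio(s), 1 / M + 1 / k^2, tolerance = 1e-12)
  }
  fixed <- function(w, h, N) cost_ratio(conv_cost_spec(w, h, N, 3, 64))
  expect_identical(fixed(8, 8, 4), fixed(32, 32, 64))
  # the separable form is cheaper whenever 1/M + 1/k^2 < 1
  s_cheap <- conv_cost_spec(8, 8, 4, 3, 8)
  expect_lt(conv_cost_ds(s_cheap), conv_cost_standard(s_cheap))
})

test_that("built models report their plan's parameter count and 4 scores", {
  cfg <- model_config(0.75, 10, input_rows = 189, input_cols = 126)
  model <- build_model(block_plan(cfg), seed = 1)
  expect_identical(model$n_params,
                   as.integer(count_params(block_plan(cfg))))
  x <- array(rnorm(189 * 126), dim = c(189, 126, 1))
  scores <- lungsounds:::model_scores(model, x)
  expect_identical(dim(scores), c(4L, 1L))
  expect_true(all(is.finite(scores)))
  # same seed, same weights
  model2 <- build_model(block_plan(cfg), seed = 1)
  expect_identical(model$weights, model2$weights)
})

test_that("the depthwise layer matches a brute-force 2-D convolution", {
  set.seed(8)
  for (stride in c(1L, 2L)) {
    x <- matrix(rnorm(25), 5, 5)
    w <- matrix(rnorm(9), 3, 3)
    got <- lungsounds:::cpp_conv2d_same(x, as.numeric(w), 3L, stride)
    want <- conv2d_same_oracle(x, w, stride)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("depthwise + identity pointwise reproduces per-channel convolution", {
  set.seed(9)
  C <- 3
  x <- array(rnorm(5 * 5 * C), dim = c(5, 5, C))
  wd <- array(rnorm(9 * C), dim = c(3, 3, C))
  wp <- diag(C)  # identity channel mixing
  got <- lungsounds:::cpp_ds_pair(x, as.numeric(wd), as.numeric(wp),
                                  3L, 1L, C, C)
  for (c in 1:C) {
    want <- conv2d_same_oracle(x[, , c], wd[, , c], 1)
    expect_equal(got[, , c], want, tolerance = 1e-6)
  }
})

test_that("layer plans serialize to JSON", {
  plan <- block_plan(model_config(0.75, 8))
  p <- withr::local_tempfile(fileext = ".json")
  write_plan(plan, p)
  back <- jsonlite::read_json(p, simplifyVector = TRUE)
  expect_identical(nrow(back$layers), nrow(plan))
  expect_equal(back$config$alpha, 0.75)
})
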