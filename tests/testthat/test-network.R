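test_that("primitive parameter-count formulas match hand calculations", {
  # k^2 * in * out + out
  expect_equal(conv2dParamCount(3, 64, 3), 1792)
  expect_equal(conv2dParamCount(64, 64, 3), 36928)
  expect_equal(conv2dParamCount(64, 1, 1), 65)
  expect_equal(conv2dParamCount(1, 1, 1), 2)
  expect_equal(transposeConvParamCount(2048, 1024, 2), 8389632)
  expect_equal(transposeConvParamCount(1024, 512, 2), 2097664)
  expect_equal(transposeConvParamCount(256, 256, 2), 262400)
  expect_identical(batchNormParamCount(2048),
                   c(total = 8192, trainable = 4096))
  expect_error(conv2dParamCount(0, 64, 3), "positive")
  expect_error(batchNormParamCount(0), ">= 1")
})

test_that("the full-width layer report reproduces every published count", {
  rep <- layerReport(networkSpec())
  got <- rep$params[rep$params > 0]
  expect_equal(got, TABLE1_PARAMS)
  expect_length(got, 39)
  # spot-check shapes chain through the bottleneck and back out
  expect_identical(rep$input_shape[1], "256x256x3")
  midBN <- rep[rep$block == "Middle Layer" &
                 rep$layer == "BatchNormalization", ]
  expect_identical(midBN$output_shape, "8x8x2048")
  expect_identical(rep$output_shape[nrow(rep)], "256x256x1")
  # shapes are consistent: each layer's input is the previous row's output
  # within the serial chain (concatenate rows change channels by design)
  for (r in 2:nrow(rep)) {
    if (rep$layer[r] %in% c("Concatenate", "Conv2DTranspose")) next
    expect_identical(rep$input_shape[r], rep$output_shape[r - 1])
  }
})

test_that("full-width totals match the published architecture", {
  cnt <- countParameters(networkSpec())
  expect_equal(cnt$trainable, TABLE1_TRAINABLE_TOTAL)
  expect_equal(cnt$total, 122491649)
  expect_equal(cnt$total - cnt$trainable, 11136)
  # non-trainable = 2 running stats per BN channel
  bnCh <- sum(cnt$report$params[cnt$report$layer == "BatchNormalization"]) / 4
  expect_equal(cnt$total - cnt$trainable, 2 * bnCh)
})

test_that("analytic counts equal counts of actually allocated weights", {
  for (wm in c(1 / 16, 1 / 8)) {
    spec <- networkSpec(64, 64, widthMultiplier = wm)
    cnt <- countParameters(spec)
    got <- countModelParameters(buildNetwork(spec, init = "zeros"))
    expect_equal(got[["total"]], cnt$total, info = paste("wm", wm))
    expect_equal(got[["trainable"]], cnt$trainable, info = paste("wm", wm))
  }
})

test_that("full-width allocated weights match the analytic total", {
  model <- buildNetwork(networkSpec(), init = "zeros")
  got <- countModelParameters(model)
  expect_equal(got[["trainable"]], TABLE1_TRAINABLE_TOTAL)
  expect_equal(got[["total"]], 122491649)
})

test_that("parameter totals scale monotonically with width", {
  tot <- vapply(c(1 / 16, 1 / 8, 1 / 4, 1),
                function(w) countParameters(
                  networkSpec(widthMultiplier = w))$total, numeric(1))
  expect_true(all(diff(tot) > 0))
})

test_that("spec validity enforces divisibility and integer channels", {
  expect_error(networkSpec(100, 100), "divisible")
  expect_error(networkSpec(256, 100), "divisible")
  expect_s4_class(networkSpec(32, 32), "NetworkSpec")
  # width multipliers yielding fractional channel counts are rejected
  expect_error(networkSpec(widthMultiplier = 1 / 1000), "positive integer")
})

test_that("buildNetwork is seed-deterministic and init-sensible", {
  spec <- networkSpec(32, 32, widthMultiplier = 1 / 16)
  m1 <- buildNetwork(spec, seed = 3)
  m2 <- buildNetwork(spec, seed = 3)
  m3 <- buildNetwork(spec, seed = 4)
  expect_identical(m1@weights, m2@weights)
  expect_false(identical(m1@weights$enc1_c1_W, m3@weights$enc1_c1_W))
  # canonical batch-norm init: scale 1, shift 0, running mean 0 / var 1
  expect_true(all(m1@weights$enc1_bn_g == 1))
  expect_true(all(m1@weights$enc1_bn_b == 0))
  expect_true(all(m1@weights$enc1_bn_rm == 0))
  expect_true(all(m1@weights$enc1_bn_rv == 1))
})

test_that("forward pass yields a full-resolution probability map", {
  spec <- networkSpec(64, 64, widthMultiplier = 1 / 16)
  model <- buildNetwork(spec, seed = 1)
  x <- matrix(runif(64 * 64), 64, 64)
  p <- unetForward(model, x)
  expect_identical(dim(p), c(64L, 64L))
  expect_true(all(p > 0 & p < 1))
  # deterministic inference
  expect_identical(unetForward(model, x), p)
  # batched input: list in, list out, first element identical
  pl <- unetForward(model, list(x, 1 - x))
  expect_length(pl, 2)
  expect_equal(pl[[1]], p)
})
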