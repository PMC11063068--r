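test_that("block structure resolves requested depth into equal-depth blocks", {
  expect_equal(resolve_block_structure(9, 7),
               list(N_cb = 7L, s_cb = 1L, N_c = 7L))
  expect_equal(resolve_block_structure(1, 10),
               list(N_cb = 1L, s_cb = 1L, N_c = 1L))
  expect_equal(resolve_block_structure(20, 3),
               list(N_cb = 3L, s_cb = 7L, N_c = 21L))
  # the ratio rounds half away from zero
  expect_equal(resolve_block_structure(3, 2),
               list(N_cb = 2L, s_cb = 2L, N_c = 4L))
})

test_that("filter counts interpolate exponentially, block-wise under residual", {
  st <- list(N_cb = 2L, s_cb = 2L, N_c = 4L)
  expect_equal(filters_per_layer(4, 32, st, res_block = TRUE), c(4L, 4L, 32L, 32L))
  expect_equal(filters_per_layer(4, 32, st, res_block = FALSE), c(4L, 8L, 16L, 32L))
  expect_equal(filters_per_layer(32, 32, st, res_block = FALSE), rep(32L, 4))
  one <- list(N_cb = 1L, s_cb = 1L, N_c = 1L)
  expect_equal(filters_per_layer(5.3, 60, one, res_block = FALSE), 6L)
  # degenerate residual case: one block means no interpolation
  single_block <- list(N_cb = 1L, s_cb = 3L, N_c = 3L)
  expect_equal(filters_per_layer(4, 32, single_block, res_block = TRUE),
               rep(4L, 3))
})

test_that("kernel sizes interpolate exponentially and ceil", {
  expect_equal(kernels_per_layer(16, 128, 4), c(16L, 32L, 64L, 128L))
  expect_equal(kernels_per_layer(33, 33, 5), rep(33L, 5))
  expect_equal(kernels_per_layer(17.2, 17.2, 1), 18L)
})

test_that("dilation grows exponentially within each block", {
  expect_equal(dilations_per_layer(8, list(N_cb = 1L, s_cb = 4L, N_c = 4L)),
               c(1L, 2L, 4L, 8L))
  expect_equal(dilations_per_layer(8, list(N_cb = 2L, s_cb = 4L, N_c = 8L)),
               rep(c(1L, 2L, 4L, 8L), 2))
  expect_equal(dilations_per_layer(1, list(N_cb = 2L, s_cb = 3L, N_c = 6L)),
               rep(1L, 6))
  # single-layer blocks never dilate
  expect_equal(dilations_per_layer(16, list(N_cb = 4L, s_cb = 1L, N_c = 4L)),
               rep(1L, 4))
})

test_that("pooling spreads power-of-two factors with remainder to later sites", {
  expect_equal(plan_pooling(1, 5), rep(1L, 5))
  expect_equal(plan_pooling(16, 2), c(4L, 4L))
  expect_equal(plan_pooling(8, 2), c(2L, 4L))
  expect_equal(plan_pooling(16, 6), c(1L, 1L, 2L, 2L, 2L, 2L))
  # product conservation for fractional p_end
  for (p_end in c(1.3, 2.7, 6, 12.1)) {
    for (n in 1:6) {
      expect_equal(prod(plan_pooling(p_end, n)), 2^round(log2(p_end)))
    }
  }
})

test_that("the GAP stage taps the last blocks per the skip ratio", {
  expect_equal(pooled_block_count(0.72, 7), 2L)
  expect_equal(pooled_block_count(0, 5), 5L)
  expect_equal(pooled_block_count(1, 5), 1L)
})

test_that("interpolation formulas agree with an independent brute-force oracle", {
  withr::with_seed(99, {
    for (rep in 1:300) {
      n_c <- sample(1:20, 1)
      n_cb <- sample(1:10, 1)
      st <- resolve_block_structure(n_c, n_cb)
      ost <- oracle_block_structure(n_c, n_cb)
      expect_equal(st$N_cb, ost$N_cb)
      expect_equal(st$s_cb, ost$s_cb)
      expect_equal(st$N_c, ost$N_c)
      f0 <- exp(runif(1, log(2), log(64))); fe <- exp(runif(1, log(2), log(64)))
      k0 <- exp(runif(1, log(16), log(2048))); ke <- exp(runif(1, log(16), log(2048)))
      de <- exp(runif(1, 0, log(128)))
      res <- sample(c(TRUE, FALSE), 1)
      expect_equal(filters_per_layer(f0, fe, st, res),
                   as.integer(oracle_filters(f0, fe, st$N_cb, st$s_cb, res)))
      expect_equal(kernels_per_layer(k0, ke, st$N_c),
                   as.integer(oracle_kernels(k0, ke, st$N_c)))
      expect_equal(dilations_per_layer(de, st),
                   as.integer(oracle_dilations(de, st$N_cb, st$s_cb)))
    }
  })
})

test_that("plans assemble the three-stage template deterministically", {
  sp <- define_search_space(150, "gap")
  cfg <- buildable_config(sp)
  cfg$n_conv_layers <- 9L
  cfg$n_conv_blocks <- 7L
  cfg$skip_ratio <- 0.72
  cfg$n_dense_layers <- 2L
  cfg$dense_activation <- "tanh"
  plan <- build_plan(cfg, sp, n_classes = 3)

  expect_equal(plan$structure$N_c, 7L)
  expect_length(plan$conv_blocks, 7L)
  expect_equal(plan$head$gap_taps, c(6L, 7L))
  expect_length(plan$dense_stack, 2L)
  expect_true(all(vapply(plan$dense_stack, `[[`, character(1), "activation") == "tanh"))

  # byte-identical serialization for equal configurations
  plan2 <- build_plan(cfg, sp, n_classes = 3)
  expect_identical(plan_to_json(plan), plan_to_json(plan2))

  # serialization round-trip preserves the plan
  js <- plan_to_json(plan)
  expect_equal(unclass(plan_from_json(js)), unclass(plan), tolerance = 1e-12)
})

test_that("a zero-depth dense stack connects the head to the output", {
  sp <- define_search_space(150, "gap")
  cfg <- buildable_config(sp)
  cfg$n_dense_layers <- 0L
  plan <- build_plan(cfg, sp, n_classes = 3)
  expect_length(plan$dense_stack, 0)
  pc <- count_parameters(plan)
  expect_equal(pc$by_stage$dense, 0)
  m <- instantiate(plan, seed = 1)
  expect_equal(trainable_count(m), pc$total)
})

test_that("oversized receptive extents raise a build error naming the layer", {
  sp <- define_search_space(150, "gap")
  cfg <- buildable_config(sp)
  cfg$kernel_size_0 <- 200
  cfg$kernel_size_end <- 200
  expect_error(build_plan(cfg, sp, 3), "conv layer 1",
               class = "genarch_receptive_error")
})

test_that("parameter counting matches hand arithmetic", {
  plan <- tiny_test_plan(n_dense = 0L)
  # two conv layers: (3*4+1)*3 + 2*3 = 45; (3*3+1)*3 + 2*3 = 36; GAP -> out 3*(3+1)
  pc <- count_parameters(plan)
  expect_equal(pc$by_stage$conv, 45 + 36)
  expect_equal(pc$by_stage$head, 0)
  expect_equal(pc$by_stage$dense, 0)
  expect_equal(pc$by_stage$output, 12)
  expect_equal(pc$total, 93)
  expect_equal(pc$total, Reduce(`+`, pc$by_stage))

  # single conv layer worked example: (16 x 4 + 1) x 8 weights + 16 batch-norm
  single <- tiny_test_plan(n_dense = 0L, input_length = 32L)
  single$structure <- list(N_cb = 1L, s_cb = 1L, N_c = 1L)
  single$conv_blocks <- list(list(
    layers = list(list(filters = 8L, kernel = 16L, dilation = 1L,
                       batchnorm_momentum = 0.5, leaky_alpha = 0.1)),
    pool_after = 1L))
  expect_equal(count_parameters(single)$by_stage$conv, 536)
})

test_that("count_parameters equals the instantiated trainable count across variants", {
  variants <- list(
    tiny_test_plan(),
    tiny_test_plan(residual = TRUE),
    tiny_test_plan(rc = TRUE),
    tiny_test_plan(head_kind = "rnn", rnn_type = "lstm"),
    tiny_test_plan(head_kind = "rnn", rnn_type = "gru", bidir = TRUE),
    tiny_test_plan(head_kind = "rnn", rnn_type = "lstm", bidir = TRUE, n_dense = 0L)
  )
  for (plan in variants) {
    m <- instantiate(plan, seed = 1)
    expect_equal(trainable_count(m), count_parameters(plan)$total)
  }
})

test_that("reverse-complement fusion only doubles the first dense input width", {
  p0 <- tiny_test_plan(rc = FALSE)
  p1 <- tiny_test_plan(rc = TRUE)
  c0 <- count_parameters(p0)
  c1 <- count_parameters(p1)
  first_dense_units <- p0$dense_stack[[1]]$units
  emb <- 3L  # one tapped block of 3 filters
  expect_equal(c1$total - c0$total, emb * first_dense_units)
  expect_equal(c1$by_stage$conv, c0$by_stage$conv)
  expect_equal(c1$by_stage$output, c0$by_stage$output)
})

test_that("instantiated models honour the prediction contract", {
  for (plan in list(tiny_test_plan(), tiny_test_plan(head_kind = "rnn"),
                    tiny_test_plan(rc = TRUE))) {
    m <- instantiate(plan, seed = 5)
    X <- withr::with_seed(6, array(runif(3 * plan$input_length * 4),
                                   c(3, plan$input_length, 4)))
    P <- predict(m, X)
    expect_equal(dim(P), c(3L, 3L))
    expect_equal(rowSums(P), rep(1, 3), tolerance = 1e-6)
  }
})

test_that("plans violating invariants are refused at instantiation", {
  bad <- tiny_test_plan(residual = TRUE)
  bad$conv_blocks[[1]]$layers[[2]]$filters <- 5L
  expect_error(instantiate(bad), "constant filter count")
  bad2 <- tiny_test_plan()
  bad2$conv_blocks[[1]]$pool_after <- c(1L, 3L)
  expect_error(instantiate(bad2), "powers of two")
  bad3 <- tiny_test_plan()
  bad3$head$gap_taps <- integer(0)
  expect_error(instantiate(bad3), "at least one block")
})

test_that("analytic gradients match finite differences across layer types", {
  gradcheck <- function(plan, seed = 3, eps = 1e-5) {
    m <- instantiate(plan, seed = seed)
    X <- withr::with_seed(seed, array(runif(4 * plan$input_length * 4),
                                      c(4, plan$input_length, 4)))
    y <- withr::with_seed(seed + 1, sample(1:3, 4, replace = TRUE))
    fwd <- genarch:::model_forward(m, X, labels = y, training = TRUE)
    grads <- genarch:::model_backward(m, fwd)
    worst <- 0
    withr::with_seed(seed + 2, {
      for (nm in names(m$params)) {
        g <- as.numeric(grads[[nm]])
        p <- m$params[[nm]]
        for (i in sample(length(p), min(3, length(p)))) {
          m$params[[nm]][i] <- p[i] + eps
          lp <- genarch:::model_forward(m, X, labels = y, training = TRUE)$loss
          m$params[[nm]][i] <- p[i] - eps
          lm <- genarch:::model_forward(m, X, labels = y, training = TRUE)$loss
          m$params[[nm]][i] <- p[i]
          num <- (lp - lm) / (2 * eps)
          # conv biases are absorbed by batch norm: both sides are ~0
          if (abs(num) < 1e-8 && abs(g[i]) < 1e-8) next
          worst <- max(worst, abs(num - g[i]) / max(1e-6, abs(num) + abs(g[i])))
        }
      }
    })
    worst
  }
  expect_lt(gradcheck(tiny_test_plan(residual = TRUE, rc = TRUE)), 1e-4)
  expect_lt(gradcheck(tiny_test_plan(head_kind = "rnn", rnn_type = "lstm",
                                     bidir = TRUE)), 1e-4)
  expect_lt(gradcheck(tiny_test_plan(head_kind = "rnn", rnn_type = "gru")), 1e-4)
})
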