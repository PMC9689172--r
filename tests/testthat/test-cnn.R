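test_that("closed-form parameter count matches the layer-wise arithmetic", {
  cfg <- cnn_config()
  # independent arithmetic: conv (k*Cin+1)*Cout, fc (Win+1)*Wout
  conv <- (3 * 1 + 1) * 4 + (3 * 4 + 1) * 8 + (3 * 8 + 1) * 16 + (3 * 16 + 1) * 16
  flat <- 16 * 1024 / 4^4
  fc <- (flat + 1) * 128 + (128 + 1) * 38 + (38 + 1) * 4 + (4 + 1) * 2
  expect_identical(conv, 1304)
  expect_identical(fc, 13388)
  expect_identical(count_parameters(cfg), as.integer(conv + fc))
  expect_identical(count_parameters(cfg), 14692L)
})

test_that("closed-form count equals instantiated totals on random configs", {
  set.seed(20)
  for (i in 1:20) {
    p <- sample(c(2L, 4L), 1)
    cfg <- cnn_config(input_len = p^4 * sample(1:4, 1),
                      conv_channels = sample(1:24, 4, replace = TRUE),
                      kernel_size = sample(c(1L, 3L, 5L, 7L), 1),
                      pool_size = p,
                      fc_widths = sample(2:64, 3, replace = TRUE),
                      n_out = sample(2:5, 1))
    m <- build_model(cfg, init_seed = i)
    # independent tally straight off the weight arrays
    tally <- sum(vapply(c(m$net$conv, m$net$fc),
                        function(l) length(l$W) + length(l$b), numeric(1)))
    expect_identical(count_parameters(cfg), as.integer(tally))
    expect_identical(m$parameter_count, as.integer(tally))
  }
})

test_that("invalid geometries are rejected", {
  expect_error(cnn_config(input_len = 1000), "divisible")
  expect_error(cnn_config(kernel_size = 4), "odd")
  expect_error(cnn_config(conv_channels = c(4, 8, 16)), "four conv")
  expect_error(cnn_config(fc_widths = c(128, 38)), "three hidden")
})

test_that("weight initialisation is deterministic under the seed", {
  m1 <- build_model(small_cnn(), init_seed = 3)
  m2 <- build_model(small_cnn(), init_seed = 3)
  m3 <- build_model(small_cnn(), init_seed = 4)
  expect_identical(m1$net, m2$net)
  expect_false(identical(m1$net, m3$net))
})

test_that("pooling halves the spatial length by pool_size at each stage", {
  cfg <- cnn_config()  # input 1024, pool 4
  m <- build_model(cfg, 1)
  x <- matrix(stats::runif(3 * 1024), 3)
  fwd <- fibrocnn:::net_forward(m$net, x, cfg, keep_cache = TRUE)
  lens <- vapply(fwd$caches, function(c) dim(c$pool$out)[1L], numeric(1))
  expect_identical(lens, c(256, 64, 16, 4))
})

test_that("forward pass yields one score pair per segment", {
  m <- build_model(cnn_config(), 1)
  x <- matrix(stats::runif(256 * 1024), 256)
  s <- cnn_forward(m, x)
  expect_identical(dim(s), c(256L, 2L))
  expect_true(all(is.finite(s)))
  # softmax rows sum to 1
  p <- predict(m, x, type = "prob")
  expect_equal(rowSums(p), rep(1, 256))
  # single segment
  expect_identical(dim(cnn_forward(m, x[1, ])), c(1L, 2L))
  expect_error(cnn_forward(m, x[, 1:100]), "expects")
})

test_that("forward pass is batch-equivariant and deterministic", {
  cfg <- small_cnn()
  m <- build_model(cfg, 5)
  set.seed(21)
  x <- matrix(runif(40 * 256), 40)
  s1 <- cnn_forward(m, x)
  expect_identical(s1, cnn_forward(m, x))
  perm <- sample(40)
  expect_equal(cnn_forward(m, x[perm, ]), s1[perm, ])
})

test_that("analytic gradients agree with numerical differentiation", {
  cfg <- cnn_config(input_len = 16, conv_channels = c(2, 3, 2, 2),
                    pool_size = 2, fc_widths = c(5, 4, 3))
  m <- build_model(cfg, 42)
  set.seed(7)
  x <- matrix(runif(5 * 16), 5)
  y <- c(0L, 1L, 1L, 0L, 1L)
  loss_at <- function(net) {
    s <- fibrocnn:::net_forward(net, x, cfg)$scores
    fibrocnn:::softmax_xent(s, y)$loss
  }
  fwd <- fibrocnn:::net_forward(m$net, x, cfg, keep_cache = TRUE)
  sx <- fibrocnn:::softmax_xent(fwd$scores, y)
  gr <- fibrocnn:::net_backward(m$net, fwd, sx$dscores, cfg)
  eps <- 1e-6
  set.seed(8)
  for (grp in c("conv", "fc")) for (i in seq_along(m$net[[grp]])) {
    P <- m$net[[grp]][[i]]$W
    for (j in sample(length(P), min(6, length(P)))) {
      net2 <- m$net
      net2[[grp]][[i]]$W[j] <- P[j] + eps; lp <- loss_at(net2)
      net2[[grp]][[i]]$W[j] <- P[j] - eps; lm <- loss_at(net2)
      expect_equal(gr[[grp]][[i]]$W[j], (lp - lm) / (2 * eps),
                   tolerance = 1e-4)
    }
  }
})
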