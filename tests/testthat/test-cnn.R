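test_that("convolution matches direct evaluation on small examples", {
  # 1x1 identity kernel reproduces the input
  x <- matrix(1:9, 3, 3)
  out <- conv2d_forward(x, conv_layer_spec(1L, 1L), array(1, c(1, 1, 1, 1)))
  expect_equal(out, x, ignore_attr = TRUE)
  # hand-computed 2x2 example: diagonal kernel picks 1*1 + 4*1
  out2 <- conv2d_forward(matrix(c(1, 3, 2, 4), 2, 2), conv_layer_spec(2L, 1L),
                         array(c(1, 0, 0, 1), c(2, 2, 1, 1)))
  expect_equal(as.vector(out2), 5)
  # zero kernels produce zero maps
  out3 <- conv2d_forward(matrix(rnorm(25), 5, 5), conv_layer_spec(3L, 2L),
                         array(0, c(3, 3, 1, 2)))
  expect_true(all(out3 == 0))
  expect_error(conv2d_forward(x, conv_layer_spec(3L, 1L),
                              array(1, c(3, 3, 2, 1))), "incompatible")
})

test_that("conv, pool and activation match brute-force oracles exactly", {
  cases <- expand.grid(side = c(4L, 6L, 8L), channels = c(1L, 2L),
                       kernel = c(1L, 3L), stride = c(1L, 2L))
  n_done <- 0L
  for (r in seq_len(nrow(cases))) {
    side <- cases$side[r]; ch <- cases$channels[r]
    k <- cases$kernel[r]; s <- cases$stride[r]
    if (side < k) next
    for (rep in 1:5) {
      n_done <- n_done + 1L
      x <- withr::with_seed(n_done, {
        array(sample(-9:9, side * side * ch, TRUE), c(side, side, ch))
      })
      w <- withr::with_seed(n_done + 1000L, {
        array(sample(-3:3, k * k * ch * 2L, TRUE), c(k, k, ch, 2L))
      })
      got <- conv2d_forward(x, conv_layer_spec(k, 2L, stride = s), w)
      expect_identical(got, oracle_conv2d(x, w, stride = s))
      if (side >= 2L) {
        got_p <- max_pool(x, 2L, 2L)
        expect_identical(got_p, oracle_max_pool(x, 2L, 2L))
      }
    }
  }
  expect_gte(n_done, 100L)
  # pooling examples and errors
  expect_equal(as.vector(max_pool(matrix(c(1, 3, 2, 4), 2, 2), 2L)), 4)
  expect_equal(max_pool(matrix(5, 4, 4), 2L), matrix(5, 2, 2),
               ignore_attr = TRUE)
  expect_error(max_pool(matrix(1, 2, 2), 3L), "larger than input")
})

test_that("activations implement their closed forms", {
  expect_equal(activate(c(-1, 2)), c(0, 2))
  expect_equal(activate(0, "sigmoid"), 0.5)
  expect_equal(activate(0, "tanh"), 0)
  expect_error(activate(1, "softsign"))
})

test_that("forward pass stays on the probability simplex", {
  m <- compact_cnn(16L, 3L, conv_specs = list(conv_layer_spec(3L, 4L)),
                   seed = 1L)
  imgs <- lapply(1:5, function(i) {
    withr::with_seed(i, matrix(sample(0:255, 256, TRUE), 16, 16))
  })
  p <- cnn_forward(m, imgs)
  expect_equal(rowSums(p), rep(1, 5), tolerance = 1e-9)
  expect_true(all(p >= 0))
  expect_identical(p, cnn_forward(m, imgs))
  # all-zero final weights give uniform class probabilities
  m0 <- m
  m0$fc$w[] <- 0
  m0$fc$b[] <- 0
  p0 <- cnn_forward(m0, imgs[[1]])
  expect_equal(as.vector(p0), rep(1 / 3, 3), tolerance = 1e-12)
  expect_error(cnn_forward(m, matrix(0, 8, 8)), "input side")
})

test_that("training is seeded, inert at lr 0, and learns separable classes", {
  # two visually distinct synthetic patterns: bright top vs bright bottom
  make_img <- function(class_a, seed) {
    withr::with_seed(seed, {
      px <- matrix(sample(0:40, 256, TRUE), 16, 16)
      if (class_a) px[1:8, ] <- px[1:8, ] + 180 else px[9:16, ] <- px[9:16, ] + 180
      pmin(px, 255)
    })
  }
  imgs <- c(lapply(1:40, function(i) make_img(TRUE, i)),
            lapply(41:80, function(i) make_img(FALSE, i)))
  labs <- rep(c("a", "b"), each = 40)
  m <- compact_cnn(16L, 2L, conv_specs = list(conv_layer_spec(3L, 4L)),
                   seed = 2L)
  frozen <- cnn_train(m, imgs, labs, epochs = 3L, lr = 0, seed = 1L)
  expect_identical(frozen$model$fc$w, m$fc$w)
  expect_identical(frozen$model$stages[[1]]$w, m$stages[[1]]$w)

  fit1 <- cnn_train(m, imgs, labs, epochs = 8L, seed = 3L)
  fit2 <- cnn_train(m, imgs, labs, epochs = 8L, seed = 3L)
  expect_identical(fit1$history, fit2$history)
  expect_gte(tail(fit1$history$accuracy, 1), 0.95)
  expect_lt(tail(fit1$history$loss, 1), fit1$history$loss[1])
  expect_error(cnn_train(m, imgs, rep("a", 80), seed = 1L), "at least 2")
})

test_that("ensemble fusion is a renormalized weighted average", {
  p1 <- matrix(c(1, 0), 1)
  p2 <- matrix(c(0, 1), 1)
  even <- ensemble_fuse(list(p1, p2), fusion_params(c(0.5, 0.5)))
  expect_equal(as.vector(even), c(0.5, 0.5))
  only1 <- ensemble_fuse(list(p1, p2), fusion_params(c(1, 0)))
  expect_equal(as.vector(only1), c(1, 0))
  single <- ensemble_fuse(list(p1), fusion_params(1))
  expect_equal(as.vector(single), c(1, 0))
  expect_error(fusion_params(c(0, 0)), "at least one weight")
  expect_error(ensemble_fuse(list(p1, matrix(1:6 / 21, 2, 3)),
                             fusion_params(c(1, 1))), "same class count")
})

test_that("pretrained backbone hook exposes published input sizes", {
  # the hook refuses politely without local weights
  err <- expect_error(load_pretrained_backbone("alexnet"), "optional feature")
  expect_error(load_pretrained_backbone("vgg16"), "unknown backbone")
  # with a stand-in weights file the shell reports the published size
  fake <- withr::local_tempfile(fileext = ".bin")
  writeLines("synthetic stand-in weights", fake)
  sides <- c(alexnet = 227L, darknet19 = 256L, googlenet = 224L,
             resnet50 = 224L, squeezenet = 227L)
  for (nm in names(sides)) {
    m <- load_pretrained_backbone(nm, n_classes = 2L, weights_path = fake)
    expect_identical(m$input_side, sides[[nm]])
  }
})
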