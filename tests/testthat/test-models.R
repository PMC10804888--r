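test_that("structural net shape chain matches the printed arithmetic", {
  s <- build_adj_cnnm()
  sh <- propagate_shapes(s)
  expect_equal(sh[[1]], c(1L, 478L, 64L))   # floor((1000-45)/2)+1 = 478
  expect_equal(sh[[2]], c(1L, 9L, 64L))     # floor(478/50) = 9
  expect_equal(sh[[3]], 576L)
  expect_equal(sh[[5]], 4L)
  expect_error(build_adj_cnnm(input_shape = c(21, 1000, 1)), "kernel height")
})

test_that("PLV net shape chain matches the printed arithmetic", {
  s <- build_plv_cnnm()
  sh <- propagate_shapes(s)
  expect_equal(sh[[1]], c(20L, 20L, 32L))
  expect_equal(sh[[2]], c(10L, 10L, 32L))
  expect_equal(sh[[3]], c(8L, 8L, 64L))
  expect_equal(sh[[5]], 4096L)
  expect_error(build_plv_cnnm(input_shape = c(22, 21, 1)), "square")
})

test_that("instantiated forward shapes match the symbolic propagation", {
  ns <- asNamespace("graphmi")
  for (s in list(build_adj_cnnm(c(22, 200, 1), 4,
                                kernel = c(22, 45)),
                 build_plv_cnnm(),
                 build_ablation_baseline("no_plv_graph", c(22, 200, 1)))) {
    set.seed(1)
    x <- array(rnorm(prod(s$input_shape) * 2), c(s$input_shape, 2))
    p <- ns$nn_init(s, 1)
    shapes <- propagate_shapes(s)
    out <- ns$nn_forward(s, p, x)$out
    expect_equal(nrow(out), utils::tail(shapes, 1)[[1]])
    expect_equal(colSums(out), rep(1, 2), tolerance = 1e-6)
  }
})

test_that("default training regimes carry the canonical settings", {
  a <- build_adj_cnnm()$default_config
  expect_equal(a$learning_rate, 1e-4)
  expect_equal(a$batch_size, 128L)
  expect_equal(a$max_epochs, 1000L)
  expect_equal(a$patience, 250L)
  p <- build_plv_cnnm()$default_config
  expect_equal(p$learning_rate, 1e-3)
  expect_equal(p$batch_size, 64L)
  expect_equal(p$max_epochs, 800L)
  expect_null(p$patience)
})

test_that("ablation baselines differ from the canonical nets as documented", {
  a <- build_ablation_baseline("no_adj_graph")
  ref <- build_adj_cnnm()
  expect_equal(a$layers, ref$layers)          # identical architecture
  expect_false(identical(a$name, ref$name))   # only the data path differs
  b <- build_ablation_baseline("no_plv_graph")
  expect_equal(b$input_shape, c(22L, 1000L, 1L))
  expect_equal(b$layers[[1]]$kernel, c(3L, 45L))
  expect_equal(utils::tail(propagate_shapes(b), 1)[[1]], 4L)
  expect_error(build_ablation_baseline("nope"))
})

test_that("fixed seed gives identical weights and first-epoch loss", {
  ns <- asNamespace("graphmi")
  s <- build_plv_cnnm(c(8, 8, 1), 3, filters = c(4, 8))
  set.seed(99)
  x <- array(rnorm(8 * 8 * 1 * 30), c(8, 8, 1, 30))
  y <- rep(1:3, 10)
  cfg <- train_config(max_epochs = 1, batch_size = 10, seed = 5)
  f1 <- ns$nn_train(s, x, y, cfg)
  f2 <- ns$nn_train(s, x, y, cfg)
  expect_identical(f1$params, f2$params)
  expect_identical(f1$history$train_loss, f2$history$train_loss)
})

test_that("training on an easy fixture decreases the loss over 5 epochs", {
  set.seed(7)
  n <- 60
  x <- array(rnorm(12 * 12 * n, sd = 0.1), c(n, 12, 12))
  y <- factor(rep(c("a", "b"), each = n / 2))
  x[y == "b", 3:5, 4:9] <- x[y == "b", 3:5, 4:9] + 1
  spec <- build_plv_cnnm(c(12, 12, 1), 2, filters = c(4, 8))
  fit <- cnnm(x, y, spec = spec,
              config = train_config(max_epochs = 5, batch_size = 20, seed = 2))
  expect_equal(nrow(fit$history), 5)
  expect_true(all(diff(fit$history$train_loss) < 0))
  # predictions: factor levels preserved, probabilities sum to 1
  pr <- predict(fit, x, type = "prob")
  expect_equal(rowSums(pr), rep(1, n), tolerance = 1e-6)
  expect_gt(mean(predict(fit, x) == y), 0.9)
})

test_that("cnnm validates shapes and label counts", {
  x <- array(rnorm(5 * 6 * 7), c(5, 6, 7))
  expect_error(cnnm(x), "labels")
  spec <- build_plv_cnnm(c(9, 9, 1), 2, filters = c(2, 2))
  expect_error(cnnm(x, factor(rep(1:2, length.out = 5)), spec = spec),
               "does not match")
})

test_that("feature maps have full-height kernels collapsed to one row", {
  ts <- tone_trials(n = 3, samples = 200)
  g <- default_graph()
  emb <- embed_trials(ts, g)
  spec <- build_adj_cnnm(c(22, 200, 1), 2)
  fit <- cnnm(emb, spec = spec,
              config = train_config(max_epochs = 1, batch_size = 3, seed = 1))
  maps <- export_feature_maps(fit, emb)
  expect_equal(dim(maps)[1:2], c(3L, 1L))   # trials x height(=1)
  expect_equal(dim(maps)[4], 64L)           # kernel count
  # ReLU on all-zero input responds with at most the (rectified) bias
  z <- emb; z$signals[] <- 0
  mz <- export_feature_maps(fit, z)
  b <- pmax(fit$params[[1]]$b, 0)
  expect_lte(max(sweep(mz, 4, b, "-")), 1e-12)
  # CSV export writes one block per kernel
  csv <- withr::local_tempfile(fileext = ".csv")
  export_feature_maps(fit, emb, file = csv)
  tab <- utils::read.csv(csv)
  expect_equal(sort(unique(tab$kernel)), 1:64)
})

test_that("model specs serialize to JSON with the layer list intact", {
  js <- jsonlite::fromJSON(spec_to_json(build_plv_cnnm()),
                           simplifyDataFrame = FALSE)
  expect_equal(js$name, "plv_cnnm_f32.64_k3x3")
  expect_length(js$layers, 6)
  expect_equal(js$layers[[1]]$kind, "conv2d")
  expect_equal(js$default_config$learning_rate, 1e-3)
})
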