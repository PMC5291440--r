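# Model construction, forward pass, classification and serialization.

test_that("parameter shapes follow the architecture and initialization is seeded", {
  spec <- parse_architecture("8, 5, 2", 40, dense_units = 6)
  m1 <- build_model(spec, seed = 3)
  m2 <- build_model(spec, seed = 3)
  m3 <- build_model(spec, seed = 4)
  expect_equal(dim(m1$conv[[1]]$W), c(5 * 4, 8))
  expect_equal(dim(m1$dense$W), c((40 - 5 + 1) %/% 2 * 8, 6))
  expect_equal(dim(m1$output$W), c(6, 2))
  expect_identical(m1$conv[[1]]$W, m2$conv[[1]]$W)
  expect_false(identical(m1$conv[[1]]$W, m3$conv[[1]]$W))
})

test_that("forward activation map equals the brute-force sliding dot product", {
  # 1-layer, 1-filter, no-pool model against an independent oracle
  spec <- model_spec(81, conv_layer(1, 7, 0), dense_units = 2)
  m <- build_model(spec, seed = 10)
  for (s in random_dna(20, 81, seed = 55)) {
    X <- encode_one_hot(s)
    oracle <- pmax(brute_conv(X, m$conv[[1]]$W, m$conv[[1]]$b, 7L), 0)
    fw <- promcnn:::conv_forward(matrix(as.vector(X), ncol = 1),
                                 m$conv[[1]]$W, m$conv[[1]]$b,
                                 81L, 4L, 7L, 0L, 1L)
    expect_equal(as.vector(fw$Xout), oracle, tolerance = 1e-6)
  }
})

test_that("scores have the right shape and ignore batch composition", {
  spec <- model_spec(30, conv_layer(4, 5, 3), dense_units = 4)
  m <- build_model(spec, seed = 2)
  m$output$W[] <- rnorm(8, sd = 0.3)   # non-degenerate scores
  seqs <- random_dna(7, 30, seed = 8)
  sc <- forward_scores(m, seqs)
  expect_equal(dim(sc), c(7, 2))
  expect_true(all(sc >= 0 & sc <= 1))
  # permuting and chunking the batch leaves each sequence's scores fixed
  perm <- c(4, 1, 7, 3, 6, 2, 5)
  expect_equal(forward_scores(m, seqs[perm], chunk_size = 3), sc[perm, ])
  expect_identical(forward_scores(m, seqs), sc)
})

test_that("a hand-built motif filter scores motif sequences higher", {
  # single filter = one-hot of TATAAA, large scale, so the conv output
  # spikes only where the motif sits; dense/output wired by hand
  spec <- model_spec(40, conv_layer(1, 6, 35), dense_units = 1)
  m <- build_model(spec, seed = 1)
  motif <- "TATAAA"
  W <- matrix(0, nrow = 24, ncol = 1)
  idx <- match(strsplit(motif, "")[[1]], c("A", "T", "G", "C"))
  for (l in 1:6) W[(idx[l] - 1) * 6 + l, 1] <- 10
  m$conv[[1]]$W <- W
  m$conv[[1]]$b <- -50        # fires only on >= 5.1 of 6 matches
  m$dense$W <- matrix(1, 1, 1)
  m$dense$b <- 0
  m$output$W <- matrix(c(1, -1), nrow = 1)
  m$output$b <- c(0, 0)
  with_motif <- paste0(strrep("C", 10), motif, strrep("G", 24))
  without <- strrep("C", 40)
  sc <- forward_scores(m, c(with_motif, without))
  expect_gt(sc[1, "promoter"], sc[2, "promoter"])
  expect_equal(classify(sc)$class, c("promoter", "nonpromoter"))
})

test_that("classification compares scores and breaks ties conservatively", {
  calls <- classify(rbind(c(0.9, 0.1), c(0.2, 0.8), c(0.5, 0.5)))
  expect_equal(calls$class, c("promoter", "nonpromoter", "nonpromoter"))
  expect_equal(calls$score, c(0.9, 0.2, 0.5))
})

test_that("mismatched input lengths name the offending record", {
  spec <- model_spec(30, conv_layer(2, 5, 0), dense_units = 2)
  m <- build_model(spec, seed = 1)
  recs <- sequence_records(c("good", "short"),
                           c(strrep("A", 30), strrep("A", 29)))
  expect_error(forward_scores(m, recs), "short",
               class = "promcnn_data_error")
})

test_that("save/load round trips scores bit-exactly with metadata", {
  spec <- parse_architecture("6, 7, 4", 50, dense_units = 8)
  m <- build_model(spec, seed = 31)
  m$output$W[] <- rnorm(16, sd = 0.2)
  m$selected_epoch <- 5L
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  seqs <- random_dna(100, 50, seed = 77)
  expect_identical(forward_scores(m2, seqs), forward_scores(m, seqs))
  expect_identical(m2$arch, "6, 7, 4")
  expect_identical(m2$seed, 31L)
  expect_identical(m2$selected_epoch, 5L)
})

test_that("corrupt model files raise explicit load errors", {
  path <- withr::local_tempfile(fileext = ".rds")
  spec <- model_spec(20, conv_layer(2, 3, 0), dense_units = 2)
  save_model(build_model(spec, 1), path)
  raw <- readBin(path, "raw", n = file.size(path))
  writeBin(raw[1:20], path)    # truncate
  expect_error(load_model(path), class = "promcnn_data_error")
  saveRDS(list(not = "a model"), path)
  expect_error(load_model(path), class = "promcnn_data_error")
})

test_that("multi-layer forward pass matches a naive re-implementation", {
  # independent oracle: direct per-sequence loops over layers
  spec <- model_spec(24, list(conv_layer(3, 5, 2), conv_layer(2, 4, 0)),
                     dense_units = 4)
  m <- build_model(spec, seed = 9)
  m$output$W[] <- rnorm(8, sd = 0.3)
  s <- random_dna(1, 24, seed = 12)
  X <- encode_one_hot(s)
  relu <- function(x) pmax(x, 0)
  # layer 1: 20 positions x 3 filters, pool 2 -> 10 x 3
  A1 <- sapply(1:3, function(f) {
    w <- m$conv[[1]]$W[, f]
    relu(sapply(1:20, function(i) {
      acc <- m$conv[[1]]$b[f]
      for (d in 1:4) for (l in 1:5)
        acc <- acc + w[(d - 1) * 5 + l] * X[i + l - 1, d]
      acc
    }))
  })
  P1 <- apply(A1, 2, function(col)
    sapply(1:10, function(g) max(col[(2 * g - 1):(2 * g)])))
  # layer 2: depth 3, length 4 -> 7 positions x 2 filters
  A2 <- sapply(1:2, function(f) {
    w <- m$conv[[2]]$W[, f]
    relu(sapply(1:7, function(i) {
      acc <- m$conv[[2]]$b[f]
      for (d in 1:3) for (l in 1:4)
        acc <- acc + w[(d - 1) * 4 + l] * P1[i + l - 1, d]
      acc
    }))
  })
  feats <- as.vector(A2)    # position-major within filter
  H <- relu(as.vector(feats %*% m$dense$W) + m$dense$b)
  Z <- as.vector(H %*% m$output$W) + m$output$b
  oracle <- 1 / (1 + exp(-Z))
  got <- forward_scores(m, s)
  expect_equal(as.vector(got), oracle, tolerance = 1e-10)
})

test_that("analytic gradients match finite differences on a small model", {
  spec <- model_spec(24, list(conv_layer(3, 5, 2), conv_layer(4, 3, 0)),
                     dense_units = 5)
  m <- build_model(spec, seed = 3)
  m$output$W[] <- rnorm(10, sd = 0.2)
  seqs <- random_dna(4, 24, seed = 6)
  Xb <- promcnn:::as_flat_batch(seqs, 24L)
  Tb <- cbind(c(1, 0, 1, 0), c(0, 1, 0, 1))
  lossfn <- function(mm)
    promcnn:::nn_loss_grad(promcnn:::nn_forward(mm, Xb)$scores, Tb)$loss
  fw <- promcnn:::nn_forward(m, Xb, keep = TRUE)
  lg <- promcnn:::nn_loss_grad(fw$scores, Tb)
  gr <- promcnn:::nn_backward(m, fw, lg$dZ)
  eps <- 1e-6
  set.seed(40)
  blocks <- list(
    list(g = gr$conv[[1]]$W, get = function() m$conv[[1]]$W,
         set = function(v) { mm <- m; mm$conv[[1]]$W[] <- v; mm }),
    list(g = gr$conv[[2]]$W, get = function() m$conv[[2]]$W,
         set = function(v) { mm <- m; mm$conv[[2]]$W[] <- v; mm }),
    list(g = gr$conv[[1]]$b, get = function() m$conv[[1]]$b,
         set = function(v) { mm <- m; mm$conv[[1]]$b[] <- v; mm }),
    list(g = gr$dense$W, get = function() m$dense$W,
         set = function(v) { mm <- m; mm$dense$W[] <- v; mm }),
    list(g = gr$output$W, get = function() m$output$W,
         set = function(v) { mm <- m; mm$output$W[] <- v; mm }))
  for (blk in blocks) {
    p <- blk$get()
    for (k in sample(length(p), min(10, length(p)))) {
      pp <- p; pp[k] <- pp[k] + eps
      pm <- p; pm[k] <- pm[k] - eps
      num <- (lossfn(blk$set(pp)) - lossfn(blk$set(pm))) / (2 * eps)
      expect_equal(as.vector(blk$g)[k], num, tolerance = 1e-5)
    }
  }
})
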