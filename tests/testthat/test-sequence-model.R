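test_that("attention rows are stochastic and maps have full shape", {
  m <- tinyModel()
  ids <- randomIdSeq(20, seed = 1)
  fwd <- seqForward(m, ids)
  cfg <- modelConfig(m)
  expect_length(fwd$attention, cfg$n_layers)
  expect_length(fwd$attention[[1]], cfg$n_heads)
  for (l in seq_len(cfg$n_layers)) for (h in seq_len(cfg$n_heads)) {
    A <- fwd$attention[[l]][[h]]
    expect_equal(dim(A), c(21L, 21L))
    expect_equal(rowSums(A), rep(1, 21), tolerance = 1e-5)
    expect_true(all(A >= 0))
  }
})

test_that("padding changes nothing: same [CLS] at padded lengths 64 and 128", {
  m <- tinyModel()
  ids <- randomIdSeq(40, seed = 2)
  f64 <- seqForward(m, c(ids, rep(0L, 64 - length(ids))))
  f128 <- seqForward(m, c(ids, rep(0L, 128 - length(ids))))
  f <- seqForward(m, ids)
  expect_equal(f64$cls, f$cls, tolerance = 1e-5)
  expect_equal(max(abs(f64$cls - f128$cls)), 0, tolerance = 1e-9)
  # padded keys get zero attention mass from real positions
  A <- f128$attention[[1]][[1]]
  expect_true(all(A[seq_along(ids), (length(ids) + 1):128] == 0))
})

test_that("position embeddings make the model order sensitive", {
  m <- tinyModel()
  ids <- randomIdSeq(15, seed = 3)
  swapped <- ids
  swapped[c(4, 9)] <- swapped[c(9, 4)]
  stopifnot(swapped[4] != swapped[9])
  f1 <- seqForward(m, ids); f2 <- seqForward(m, swapped)
  expect_gt(max(abs(f1$cls - f2$cls)), 0)
})

test_that("inference is deterministic and input validation fires", {
  m <- tinyModel()
  ids <- randomIdSeq(10, seed = 4)
  expect_identical(seqForward(m, ids)$hidden, seqForward(m, ids)$hidden)
  expect_error(seqForward(m, c(2L, 99L)), "vocabulary")
  expect_error(seqForward(m, rep(4L, 200)), "max_len")
})

test_that("classification head is sigmoid(C.W + b) exactly", {
  m <- tinyModel()
  ids <- randomIdSeq(12, seed = 5)
  fwd <- seqForward(m, ids)
  # W = 0 at init -> probability 0.5
  expect_equal(classifyPathway(m, fwd), 0.5)
  set.seed(6)
  m@params$cls$w <- rnorm(modelConfig(m)$hidden_size)
  m@params$cls$b <- 0.3
  p <- classifyPathway(m, fwd)
  manual <- 1 / (1 + exp(-(sum(fwd$cls * m@params$cls$w) + 0.3)))
  expect_equal(p, manual, tolerance = 1e-6)
  # saturation: logit -> +Inf gives probability 1
  m@params$cls$w <- fwd$cls * 1e9
  m@params$cls$b <- 0
  expect_equal(classifyPathway(m, seqForward(m, ids)), 1.0)
})

test_that("masked-code scores: finite everywhere, ~ln(V) entropy at init", {
  V <- 454L
  m <- initSeqModel(seqModelConfig(preset = "desk", vocab_size = V), seed = 8)
  ids <- c(2L, sample(4:(V - 1L), 60, replace = TRUE))
  fwd <- seqForward(m, ids, want_attention = FALSE)
  logits <- mlmLogits(m, fwd)
  expect_equal(dim(logits), c(61L, V))
  expect_true(all(is.finite(logits)))
  # cross-entropy of a near-uniform random init is ~ ln V
  P <- exp(logits - apply(logits, 1, max))
  P <- P / rowSums(P)
  ce <- mean(-log(P[cbind(seq_along(ids), ids + 1L)]))
  expect_equal(ce, log(V), tolerance = 0.05 * log(V))
})

test_that("cross-layer sharing reduces the parameter count", {
  shared <- initSeqModel(seqModelConfig(preset = "desk", n_layers = 6L,
                                        vocab_size = 100L), 1)
  unshared <- initSeqModel(seqModelConfig(preset = "desk", n_layers = 6L,
                                          vocab_size = 100L,
                                          share_layer_parameters = FALSE), 1)
  expect_lt(parameterCount(shared), parameterCount(unshared))
  # factorized embeddings: V x E and E x H, not V x H
  expect_equal(dim(shared@params$tok_emb), c(100L, 32L))
  expect_equal(dim(shared@params$emb_proj), c(32L, 64L))
  # unshared model still runs forward
  expect_length(seqForward(unshared, randomIdSeq(8, V = 100, seed = 1),
                           want_attention = FALSE)$cls, 64L)
})

test_that("backprop matches finite differences on a toy batch", {
  cp <- asNamespace("codepaths")
  cfg <- seqModelConfig(preset = "desk", vocab_size = 30L)
  m <- initSeqModel(cfg, seed = 42)
  params <- m@params
  set.seed(9)
  params$cls$w <- rnorm(cfg$hidden_size, 0, 0.05)
  ids <- randomIdSeq(25, V = 30, seed = 10)
  lg <- cp$clsLossGrad(params, cfg, ids, 1)
  eps <- 1e-5
  numgrad <- function(mut) {
    p2 <- mut(params, eps); l1 <- cp$clsLossGrad(p2, cfg, ids, 1)$loss
    p2 <- mut(params, -eps); l0 <- cp$clsLossGrad(p2, cfg, ids, 1)$loss
    (l1 - l0) / (2 * eps)
  }
  # classifier weight (the BCE/W check), an attention weight, an embedding
  gn <- numgrad(function(p, e) { p$cls$w[3] <- p$cls$w[3] + e; p })
  expect_equal(lg$grads$cls$w[3], gn, tolerance = 1e-4)
  gn <- numgrad(function(p, e) { p$layers[[1]]$Wo[2, 3] <-
    p$layers[[1]]$Wo[2, 3] + e; p })
  expect_equal(lg$grads$layers[[1]]$Wo[2, 3], gn, tolerance = 1e-4)
  gn <- numgrad(function(p, e) { p$tok_emb[ids[2] + 1L, 1] <-
    p$tok_emb[ids[2] + 1L, 1] + e; p })
  expect_equal(lg$grads$tok_emb[ids[2] + 1L, 1], gn, tolerance = 1e-4)
})

test_that("compiled training path equals the R reference implementation", {
  cp <- asNamespace("codepaths")
  cfg <- seqModelConfig(preset = "desk", vocab_size = 60L)
  m <- initSeqModel(cfg, seed = 11)
  params <- m@params
  set.seed(12)
  params$cls$w <- rnorm(cfg$hidden_size, 0, 0.05)
  seqs <- lapply(1:4, function(i)
    c(2L, sample(4:59, sample(20:40, 1), replace = TRUE)))
  ys <- c(0, 1, 1, 0)
  keyedMax <- function(a, b) {
    mx <- 0
    for (k in names(a)) {
      if (is.list(a[[k]])) {
        for (i in seq_along(a[[k]]))
          mx <- max(mx, keyedMax(a[[k]][[i]], b[[k]][[i]]))
      } else mx <- max(mx, max(abs(a[[k]] - b[[k]])))
    }
    mx
  }
  # classification loss + gradients, batch of 4
  exs <- Map(function(s, y) list(ids = s, y = y), seqs, ys)
  fast <- cp$clsBatchGrad(params, cfg, exs)
  ref <- cp$avgLossGrads(lapply(exs, function(e)
    cp$clsLossGradR(params, cfg, e$ids, e$y)))
  expect_equal(fast$loss, ref$loss, tolerance = 1e-12)
  expect_lt(keyedMax(ref$grads, fast$grads), 1e-10)
  # masked-code loss + gradients
  set.seed(13)
  mexs <- lapply(seqs, makeMlmExample, vocab_size = 60L)
  fastm <- cp$mlmBatchGrad(params, cfg, mexs)
  refm <- cp$avgLossGrads(lapply(mexs, function(e)
    cp$mlmLossGradR(params, cfg, e)))
  expect_equal(fastm$loss, refm$loss, tolerance = 1e-12)
  expect_lt(keyedMax(refm$grads, fastm$grads), 1e-10)
  # inference scores match the R forward + sigmoid head
  m@params <- params
  expect_equal(scorePathways(m, seqs),
               vapply(seqs, function(s)
                 classifyPathway(m, seqForward(m, s)), numeric(1)),
               tolerance = 1e-12)
})
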