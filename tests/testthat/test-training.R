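test_that("MLM corruption marginals are 12% [MASK] and 1.5% random", {
  V <- 454L
  set.seed(1)
  n_pos <- 0L; n_mask <- 0L; n_rand <- 0L; n_sel <- 0L
  for (i in 1:800) {
    ids <- c(2L, sample(4:(V - 1L), 150, replace = TRUE))
    ex <- makeMlmExample(ids, V)
    n_pos <- n_pos + length(ids) - 1L
    n_sel <- n_sel + length(ex$positions)
    n_mask <- n_mask + sum(ex$input[ex$positions] == 3L)
    n_rand <- n_rand + sum(ex$input[ex$positions] != 3L &
                             ex$input[ex$positions] != ex$targets)
  }
  expect_gte(n_pos, 100000L)
  expect_equal(n_mask / n_pos, 0.12, tolerance = 0.01 / 0.12)
  expect_equal(n_rand / n_pos, 0.015, tolerance = 0.005 / 0.015)
  expect_equal(n_sel / n_pos, 0.15, tolerance = 0.01 / 0.15)
})

test_that("corruption marginals hold for a small vocabulary too", {
  V <- 14L  # 10 group tokens
  set.seed(2)
  n_pos <- 0L; n_mask <- 0L
  for (i in 1:700) {
    ids <- c(2L, sample(4:(V - 1L), 150, replace = TRUE))
    ex <- makeMlmExample(ids, V)
    n_pos <- n_pos + length(ids) - 1L
    n_mask <- n_mask + sum(ex$input[ex$positions] == 3L)
  }
  expect_equal(n_mask / n_pos, 0.12, tolerance = 0.01 / 0.12)
})

test_that("[CLS] and [PAD] are never selected for masking", {
  seen <- FALSE
  for (s in 1:200) {
    set.seed(s)
    ex <- makeMlmExample(c(2L, 5L, 0L, 0L), 10L)
    expect_false(1L %in% ex$positions)  # [CLS] position
    expect_false(any(ex$positions >= 3L))  # [PAD] positions
    if (length(ex$positions)) seen <- TRUE
  }
  expect_true(seen)  # the one maskable position does get selected sometimes
  # zero maskable positions -> empty selection
  set.seed(1)
  ex <- makeMlmExample(c(2L, 0L), 10L)
  expect_length(ex$positions, 0L)
})

test_that("planned step count is floor(n * epochs / batch)", {
  expect_equal(planSteps(13029, 60, 2), 390870L)
  expect_equal(planSteps(8, 1, 8), 1L)
  expect_equal(planSteps(7, 1, 2), 3L)
  expect_error(planSteps(10, 1, 0), "positive")
})

test_that("pretraining reduces MLM loss from the ln(V) baseline", {
  V <- 30L
  set.seed(11)
  seqs <- replicate(60, c(2L, sample(4:9, 30, replace = TRUE)),
                    simplify = FALSE)
  m <- initSeqModel(seqModelConfig(preset = "desk", vocab_size = V), 3)
  out <- pretrainModel(m, seqs, trainPlan(batch_size = 4, epochs = 5,
                                          lr = 1e-3, seed = 5))
  expect_equal(mean(head(out$loss_trace, 10)), log(V),
               tolerance = 0.05 * log(V))
  expect_lt(mean(tail(out$loss_trace, 10)), mean(head(out$loss_trace, 10)))
  expect_equal(out$planned_steps, planSteps(60, 5, 4))
})

test_that("checkpoints reload to bit-identical forward results", {
  m <- tinyModel(seed = 12)
  f <- withr::local_tempfile(fileext = ".rds")
  saveModel(m, f)
  m2 <- loadModel(f)
  ids <- randomIdSeq(20, seed = 13)
  expect_identical(seqForward(m, ids)$cls, seqForward(m2, ids)$cls)
})

test_that("fine-tuning learns a separable toy and reports restarts", {
  V <- 20L
  set.seed(14)
  # label 1 sequences contain token 5, label 0 contain token 6
  mk <- function(y) c(2L, sample(c(if (y) 5L else 6L,
                                   sample(7:19, 14, replace = TRUE))))
  ys <- rep(c(0, 1), 15)
  seqs <- lapply(ys, mk)
  m <- initSeqModel(seqModelConfig(preset = "desk", vocab_size = V), 15)
  plan <- trainPlan(batch_size = 8, epochs = 10, lr = 2e-3, seed = 16,
                    restarts = 2)
  ft <- finetuneModel(m, seqs, ys, plan, seqs, ys)
  expect_equal(nrow(ft$restart_report), 2L)
  expect_equal(sum(ft$restart_report$selected), 1L)
  expect_equal(ft$restart_report$batch_size, c(8L, 8L))
  expect_equal(ft$restart_report$epochs, c(10L, 10L))
  expect_gte(max(ft$restart_report$eval_auroc), 0.9)
  # the selected restart is the evaluation-AUROC maximiser
  expect_equal(which(ft$restart_report$selected),
               which.max(ft$restart_report$eval_auroc))
  # identical plan -> identical selected model (restart seeds derive from
  # the plan seed)
  ft2 <- finetuneModel(m, seqs, ys, plan, seqs, ys)
  expect_identical(ft$model@params, ft2$model@params)
  expect_error(finetuneModel(m, seqs, rep(1, 30), plan, seqs, ys),
               "both classes")
})

test_that("count featurizer conserves token totals and destroys order", {
  v <- buildVocabulary(c("A", "B", "C"))
  X <- featurizeCounts(list(c("A", "A", "B"), c("B", "A", "A"),
                            character(0)), v)
  expect_equal(X[1, ], c(A = 2, B = 1, C = 0))
  expect_equal(X[1, ], X[2, ])  # order destroyed
  expect_equal(unname(rowSums(X)), c(3, 3, 0))
  Xb <- featurizeCounts(list(c("A", "A", "B")), v, binary = TRUE)
  expect_equal(Xb[1, ], c(A = 1, B = 1, C = 0))
})

test_that("count LR separates a separable set; permuted labels are null", {
  set.seed(17)
  n <- 200
  X <- matrix(rpois(n * 12, 3), n, 12,
              dimnames = list(NULL, paste0("G", 1:12)))
  y <- as.integer(X[, 1] + X[, 2] > 6)
  fit <- trainCountsBaseline(X, y, seed = 18)
  acc_auc <- aurocScore(predictCountsBaseline(fit, X), y)
  expect_gte(acc_auc, 0.97)
  # determinism
  fit2 <- trainCountsBaseline(X, y, seed = 18)
  expect_identical(predictCountsBaseline(fit, X),
                   predictCountsBaseline(fit2, X))
  # permutation null: held-out AUROC ~ 0.5 (averaged over permutations)
  half <- seq_len(n / 2)
  auc_p <- vapply(1:3, function(k) {
    yp <- sample(y)
    fitp <- trainCountsBaseline(X[half, ], yp[half], seed = 19 + k)
    aurocScore(predictCountsBaseline(fitp, X[-half, ]), yp[-half])
  }, numeric(1))
  expect_lt(abs(mean(auc_p) - 0.5), 0.08)
  expect_error(trainCountsBaseline(matrix(1, 40, 3), rep(c(0, 1), 20)),
               "degenerate")
})
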