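#' Describe a training run
#'
#' @param batch_size sequences per optimiser step (study values: 2 for
#'   pretraining, 8 for fine-tuning).
#' @param epochs passes over the training set (study values: ~60 pretrain,
#'   4 fine-tune).
#' @param lr peak Adam learning rate. Defaults follow the pretrain /
#'   fine-tune split (1e-4 / 2e-5) at study scale; reduced "desk" models
#'   train with proportionally larger rates set explicitly by the caller.
#' @param warmup fraction of planned steps spent in linear learning-rate
#'   warm-up.
#' @param seed integer seed governing shuffling, masking and restarts.
#' @param restarts number of fine-tuning random restarts.
#' @return a train-plan list; `planned_steps` is filled in by the trainers
#'   as `floor(n_examples * epochs / batch_size)`.
#' @export
trainPlan <- function(batch_size = 8L, epochs = 4L, lr = 2e-5,
                      warmup = 0.1, seed = 1L, restarts = 5L) {
  stopifnot(batch_size >= 1L, epochs >= 1L, lr > 0, restarts >= 1L,
            warmup >= 0, warmup < 1)
  list(batch_size = as.integer(batch_size), epochs = as.integer(epochs),
       lr = lr, warmup = warmup, seed = as.integer(seed),
       restarts = as.integer(restarts))
}

#' Optimiser steps implied by a training plan
#'
#' @param n_examples,epochs,batch_size positive integers.
#' @return `floor(n_examples * epochs / batch_size)`.
#' @examples
#' planSteps(13029, 60, 2)  # 390870
#' @export
planSteps <- function(n_examples, epochs, batch_size) {
  stopifnot(n_examples >= 1, epochs >= 1)
  if (batch_size < 1) stop("batch_size must be a positive integer")
  as.integer(floor(as.numeric(n_examples) * epochs / batch_size))
}

#' Corrupt a token sequence for masked-code pretraining
#'
#' Follows the BERT recipe: 15% of maskable positions (group-token
#' positions; `[CLS]`/`[PAD]` and other specials are never selected) are
#' selected for prediction; of those, 80% are replaced by `[MASK]`, 10% by
#' a uniformly random group token and 10% left unchanged. Marginally this
#' masks 12% of the medical codes and randomises 1.5%, the corruption
#' rates used in the study. Draws from the current RNG stream.
#'
#' @param ids 0-based id sequence (`[CLS]` first).
#' @param vocab_size total vocabulary size (specials included).
#' @param select_prob probability a maskable position is selected.
#' @return list with `input` (corrupted ids), `positions` (1-based selected
#'   positions, possibly empty) and `targets` (original ids there).
#' @export
makeMlmExample <- function(ids, vocab_size, select_prob = 0.15) {
  ids <- as.integer(ids)
  maskable <- which(ids >= 4L)
  sel <- maskable[stats::runif(length(maskable)) < select_prob]
  input <- ids
  if (length(sel)) {
    u <- stats::runif(length(sel))
    to_mask <- sel[u < 0.8]
    to_rand <- sel[u >= 0.8 & u < 0.9]
    input[to_mask] <- MASK_ID
    if (length(to_rand))
      input[to_rand] <- as.integer(
        sample(4L:(vocab_size - 1L), length(to_rand), replace = TRUE))
  }
  list(input = input, positions = sel, targets = ids[sel])
}

## ---- nested-list parameter algebra -------------------------------------

zeroLike <- function(x) {
  if (is.list(x)) lapply(x, zeroLike) else x * 0
}

# Recursions over nested parameter lists are keyed on the names of the
# first argument where names exist, so gradient structures built in a
# different element order still line up with the parameters.
listKeys <- function(a) {
  nm <- names(a)
  if (!is.null(nm) && all(nzchar(nm))) nm else seq_along(a)
}

addLists <- function(a, b) {
  if (is.list(a)) {
    ks <- listKeys(a)
    out <- lapply(ks, function(k) addLists(a[[k]], b[[k]]))
    names(out) <- names(a)
    out
  } else a + b
}

adamUpdate <- function(p, g, m, v, lr, t, b1 = 0.9, b2 = 0.999, eps = 1e-8) {
  if (is.list(p)) {
    ks <- listKeys(p)
    out <- lapply(ks, function(k)
      adamUpdate(p[[k]], g[[k]], m[[k]], v[[k]], lr, t, b1, b2, eps))
    res <- list(p = lapply(out, `[[`, "p"), m = lapply(out, `[[`, "m"),
                v = lapply(out, `[[`, "v"))
    for (s in names(res)) names(res[[s]]) <- names(p)
    res
  } else {
    m2 <- b1 * m + (1 - b1) * g
    v2 <- b2 * v + (1 - b2) * g * g
    list(p = p - lr * (m2 / (1 - b1^t)) / (sqrt(v2 / (1 - b2^t)) + eps),
         m = m2, v = v2)
  }
}

lrAt <- function(step, total, peak, warmup) {
  w <- max(1, floor(total * warmup))
  if (step <= w) peak * step / w else peak
}

# loss and parameter gradient for one masked-code example. The compiled
# batched path mirrors the R reference implementation (mlmLossGradR) and
# is used whenever dropout is off; the two are cross-checked in the
# test-suite.
mlmLossGrad <- function(params, cfg, ex) {
  if (!length(ex$positions)) return(NULL)
  if (cfg$dropout == 0)
    return(.cpp_mlm_batch_grad(params, cfg, list(as.integer(ex$input)),
                               list(as.integer(ex$positions)),
                               list(as.integer(ex$targets))))
  mlmLossGradR(params, cfg, ex)
}

# batched versions used by the trainers: return the batch-mean loss and
# batch-mean gradients, or NULL if the batch contributes nothing
mlmBatchGrad <- function(params, cfg, exs) {
  exs <- exs[vapply(exs, function(e) length(e$positions) > 0L, logical(1))]
  if (!length(exs)) return(NULL)
  if (cfg$dropout == 0)
    return(.cpp_mlm_batch_grad(params, cfg,
                               lapply(exs, function(e) as.integer(e$input)),
                               lapply(exs, function(e) as.integer(e$positions)),
                               lapply(exs, function(e) as.integer(e$targets))))
  avgLossGrads(lapply(exs, function(e) mlmLossGradR(params, cfg, e)))
}

clsBatchGrad <- function(params, cfg, exs) {
  if (cfg$dropout == 0)
    return(.cpp_cls_batch_grad(params, cfg,
                               lapply(exs, function(e) as.integer(e$ids)),
                               vapply(exs, function(e) as.numeric(e$y),
                                      numeric(1))))
  avgLossGrads(lapply(exs, function(e) clsLossGradR(params, cfg, e$ids, e$y)))
}

avgLossGrads <- function(lgs) {
  n <- length(lgs)
  g <- Reduce(addLists, lapply(lgs, `[[`, "grads"))
  list(loss = mean(vapply(lgs, `[[`, numeric(1), "loss")),
       grads = rapply(g, function(x) x / n, how = "replace"))
}

mlmLossGradR <- function(params, cfg, ex) {
  if (!length(ex$positions)) return(NULL)
  fwd <- fwdOne(params, cfg, ex$input, want_attn = FALSE, want_cache = TRUE,
                drop_rate = cfg$dropout)
  head <- mlmHeadFwd(params, fwd$hidden, ex$positions)
  n <- length(ex$positions)
  P <- softmaxRows(head$logits)
  tgt <- cbind(seq_len(n), ex$targets + 1L)
  loss <- -mean(log(pmax(P[tgt], 1e-12)))
  dLogit <- P
  dLogit[tgt] <- dLogit[tgt] - 1
  dLogit <- dLogit / n
  g <- list(mlm = list())
  g$mlm$out_bias <- colSums(dLogit)
  dZn <- dLogit %*% params$tok_emb
  dTokHead <- crossprod(dLogit, head$ln$Y)     # V x E from tied decoder
  lnb <- layernormBwd(dZn, head$ln, params$mlm$ln_g)
  g$mlm$ln_g <- lnb$dg; g$mlm$ln_b <- lnb$db
  dZ1 <- lnb$dX * geluGrad(head$Z1)
  g$mlm$dense <- crossprod(head$Hm, dZ1)
  g$mlm$bias <- colSums(dZ1)
  dHidden <- matrix(0, nrow(fwd$hidden), cfg$hidden_size)
  dHidden[ex$positions, ] <- tcrossprod(dZ1, params$mlm$dense)
  enc <- seqBackward(params, cfg, fwd, dHidden)
  enc$tok_emb <- enc$tok_emb + dTokHead
  enc$mlm <- g$mlm
  enc$cls <- list(w = params$cls$w * 0, b = 0)
  list(loss = loss, grads = enc)
}

# loss and parameter gradient for one labelled pathway (BCE on the [CLS]
# logistic head, gradients through the whole encoder); compiled fast path
# with the R reference (clsLossGradR) as fallback and cross-check.
clsLossGrad <- function(params, cfg, ids, y) {
  if (cfg$dropout == 0) {
    out <- .cpp_cls_batch_grad(params, cfg, list(as.integer(ids)), y)
    return(list(loss = out$loss, grads = out$grads, prob = out$probs[1]))
  }
  clsLossGradR(params, cfg, ids, y)
}

clsLossGradR <- function(params, cfg, ids, y) {
  fwd <- fwdOne(params, cfg, ids, want_attn = FALSE, want_cache = TRUE,
                drop_rate = cfg$dropout)
  z <- sum(fwd$cls * params$cls$w) + if (cfg$classifier_bias) params$cls$b else 0
  p <- sigmoid(z)
  loss <- -(y * log(pmax(p, 1e-12)) + (1 - y) * log(pmax(1 - p, 1e-12)))
  dz <- p - y
  dHidden <- matrix(0, nrow(fwd$hidden), cfg$hidden_size)
  dHidden[1L, ] <- dz * params$cls$w
  enc <- seqBackward(params, cfg, fwd, dHidden)
  enc$mlm <- zeroLike(params$mlm)
  enc$cls <- list(w = dz * fwd$cls, b = if (cfg$classifier_bias) dz else 0)
  list(loss = loss, grads = enc, prob = p)
}

runAdamEpochs <- function(params, cfg, examples, plan, batchGradFn,
                          shuffle_seed) {
  n <- length(examples)
  total <- max(1L, planSteps(n, plan$epochs, plan$batch_size))
  state <- list(m = zeroLike(params), v = zeroLike(params))
  step <- 0L
  trace <- numeric(0)
  set.seed(shuffle_seed)
  for (ep in seq_len(plan$epochs)) {
    ord <- sample.int(n)
    i <- 1L
    while (i <= n) {
      batch <- ord[i:min(i + plan$batch_size - 1L, n)]
      lg <- batchGradFn(params, cfg, examples[batch])
      if (!is.null(lg)) {
        step <- step + 1L
        if (!is.finite(lg$loss))
          stop("non-finite training loss at step ", step)
        upd <- adamUpdate(params, lg$grads, state$m, state$v,
                          lr = lrAt(step, total, plan$lr, plan$warmup),
                          t = step)
        params <- upd$p; state$m <- upd$m; state$v <- upd$v
        trace <- c(trace, lg$loss)
      }
      i <- i + plan$batch_size
    }
  }
  list(params = params, trace = trace, steps = step)
}

#' Pretrain the encoder by masked-code prediction
#'
#' Each pathway (kept ending with its diagnostic code, so the relation
#' between the endpoint diagnosis and the preceding codes is learned) is
#' corrupted with [makeMlmExample()] once per epoch and the cross-entropy
#' at the selected positions is minimised with Adam under linear warm-up.
#'
#' @param model an initialised [SeqModel-class].
#' @param id_sequences list of 0-based id sequences (`[CLS]` first).
#' @param plan a [trainPlan()]; study-scale pretraining used batch size 2.
#' @return list with the trained `model`, the per-step `loss_trace`, and
#'   `planned_steps`.
#' @export
pretrainModel <- function(model, id_sequences, plan) {
  cfg <- model@config
  n <- length(id_sequences)
  if (!n) stop("no pretraining sequences")
  batchGradFn <- function(params, cfg, seqs)
    mlmBatchGrad(params, cfg,
                 lapply(seqs, makeMlmExample, vocab_size = cfg$vocab_size))
  out <- runAdamEpochs(model@params, cfg, id_sequences, plan, batchGradFn,
                       shuffle_seed = plan$seed)
  model@params <- out$params
  list(model = model,
       loss_trace = out$trace,
       planned_steps = planSteps(n, plan$epochs, plan$batch_size))
}

#' Fine-tune with a logistic classification head and random restarts
#'
#' Joint fine-tuning of all encoder parameters plus the `[CLS]` logistic
#' head under binary cross-entropy. Because fine-tuning can be unstable,
#' `plan$restarts` runs are made from the same pretrained checkpoint with
#' different data shuffling and classifier initialisation, and the restart
#' with the highest evaluation-set AUROC is kept.
#'
#' @param model a pretrained [SeqModel-class].
#' @param id_sequences,labels training sequences (label codes already
#'   stripped) and 0/1 labels.
#' @param plan a [trainPlan()]; study defaults are batch size 8, 4 epochs.
#' @param eval_ids,eval_labels held-out evaluation set used only for
#'   restart selection (study size: 600 pathways).
#' @return list with the selected `model`, `restart_report` (one row per
#'   restart: seed, final smoothed loss, evaluation AUROC, selected flag),
#'   and the plan actually used.
#' @export
finetuneModel <- function(model, id_sequences, labels, plan,
                          eval_ids, eval_labels) {
  stopifnot(length(id_sequences) == length(labels))
  if (length(unique(labels)) < 2L)
    stop("fine-tuning requires both classes in the training set")
  cfg <- model@config
  examples <- Map(function(s, y) list(ids = s, y = y), id_sequences, labels)
  best <- NULL
  rows <- vector("list", plan$restarts)
  for (r in seq_len(plan$restarts)) {
    rseed <- deriveSeed(plan$seed, paste0("restart", r))
    params <- model@params
    set.seed(rseed)
    params$cls$w <- stats::rnorm(cfg$hidden_size, 0, 0.02)
    params$cls$b <- 0
    out <- runAdamEpochs(params, cfg, examples, plan, clsBatchGrad,
                         shuffle_seed = rseed)
    cand <- model
    cand@params <- out$params
    scores <- scorePathways(cand, eval_ids)
    ev <- aurocScore(scores, eval_labels)
    rows[[r]] <- data.frame(
      restart = r, seed = rseed,
      batch_size = plan$batch_size, epochs = plan$epochs,
      final_loss = mean(utils::tail(out$trace, 20L)),
      eval_auroc = ev)
    if (is.null(best) || ev > best$ev) best <- list(model = cand, ev = ev, r = r)
  }
  report <- do.call(rbind, rows)
  report$selected <- report$restart == best$r
  list(model = best$model, restart_report = report, plan = plan)
}

#' Save / load a model checkpoint
#'
#' Checkpoints reload to bit-identical forward results.
#'
#' @param model a [SeqModel-class].
#' @param path file path.
#' @return `loadModel` returns the [SeqModel-class].
#' @export
saveModel <- function(model, path) {
  saveRDS(list(config = model@config, params = model@params), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  x <- readRDS(path)
  methods::new("SeqModel", config = x$config, params = x$params)
}

#' Bag-of-codes feature vectors
#'
#' Destroys all order information: entry `g` counts occurrences of group
#' `g` in the pathway's tokens. This is the feature map of the comparator
#' logistic-regression model.
#'
#' @param pathways a [PathwaySet-class] or list of token character vectors.
#' @param vocabulary a [Vocabulary-class] fixing column order.
#' @param binary count presence (0/1) instead of multiplicity.
#' @return an `n x |groups|` matrix with one row per pathway.
#' @export
featurizeCounts <- function(pathways, vocabulary, binary = FALSE) {
  toks <- if (is(pathways, "PathwaySet")) pathways@tokens else pathways
  lev <- vocabTokens(vocabulary)
  X <- t(vapply(toks, function(tt)
    tabulate(factor(tt, levels = lev), nbins = length(lev)),
    numeric(length(lev))))
  colnames(X) <- lev
  if (binary) X <- (X > 0) + 0
  X
}

#' Fit the bag-of-codes logistic-regression comparator
#'
#' Ridge-penalised (L2) logistic regression on code-count features, with
#' the penalty chosen by 5-fold cross-validation.
#'
#' @param X feature matrix from [featurizeCounts()].
#' @param y 0/1 labels.
#' @param nfolds folds for `glmnet::cv.glmnet`.
#' @param seed seed fixing the fold assignment.
#' @return an object of class `countsLR`; use [predictCountsBaseline()].
#' @export
trainCountsBaseline <- function(X, y, nfolds = 5L, seed = 1L) {
  if (length(unique(y)) < 2L) stop("need both classes")
  if (all(apply(X, 2L, function(c) length(unique(c)) == 1L)))
    stop("degenerate features: all columns constant")
  set.seed(seed)
  foldid <- sample(rep_len(seq_len(nfolds), length(y)))
  fit <- glmnet::cv.glmnet(X, y, family = "binomial", alpha = 0,
                           foldid = foldid, standardize = TRUE)
  structure(list(fit = fit, lambda = fit$lambda.min), class = "countsLR")
}

#' @rdname trainCountsBaseline
#' @param object a fitted `countsLR` model.
#' @param newx feature matrix to score.
#' @export
predictCountsBaseline <- function(object, newx) {
  as.numeric(stats::predict(object$fit, newx = newx, s = object$lambda,
                            type = "response"))
}
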