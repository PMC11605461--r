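#' Configure the pathway sequence encoder
#'
#' The encoder is a small BERT-family transformer in the "lite" (ALBERT)
#' parameterisation: token embeddings are factorized through a low-rank
#' projection (`V x E` then `E x H`) and one set of encoder-block weights
#' is shared across all layers. Inputs are flat, temporally ordered curated
#' code sequences prefixed with `[CLS]`; the final-layer hidden state of
#' `[CLS]` is the whole-pathway representation used by the classification
#' head.
#'
#' The default configuration mirrors the study scale (6 layers, 12 heads,
#' hidden size 768, embedding size 128, maximum length 512, vocabulary 454
#' = 450 curated groups + 4 special tokens). The `"desk"` preset (2 layers,
#' 4 heads, hidden 64, embedding 32, maximum length 128) is a first-class
#' reduced configuration used for tests and examples.
#'
#' @param preset `"paper"` (default) or `"desk"`.
#' @param n_layers,n_heads,hidden_size,embedding_size,intermediate_size,max_len
#'   architecture dimensions; `hidden_size` must be divisible by `n_heads`.
#' @param vocab_size total token-id count including the 4 special tokens.
#' @param dropout dropout rate applied to attention and feed-forward
#'   outputs during training (0 disables, the default, as in ALBERT).
#' @param share_layer_parameters share one encoder block across layers.
#' @param classifier_bias include a bias term in the logistic head (set
#'   `FALSE` for the strict `sigmoid(C.W)` form).
#' @return a validated config list.
#' @export
seqModelConfig <- function(preset = c("paper", "desk"),
                           n_layers = NULL, n_heads = NULL,
                           hidden_size = NULL, embedding_size = NULL,
                           intermediate_size = NULL, max_len = NULL,
                           vocab_size = 454L, dropout = 0,
                           share_layer_parameters = TRUE,
                           classifier_bias = TRUE) {
  preset <- match.arg(preset)
  def <- if (preset == "paper") {
    list(n_layers = 6L, n_heads = 12L, hidden_size = 768L,
         embedding_size = 128L, max_len = 512L)
  } else {
    list(n_layers = 2L, n_heads = 4L, hidden_size = 64L,
         embedding_size = 32L, max_len = 128L)
  }
  cfg <- list(
    preset = preset,
    n_layers = as.integer(n_layers %||% def$n_layers),
    n_heads = as.integer(n_heads %||% def$n_heads),
    hidden_size = as.integer(hidden_size %||% def$hidden_size),
    embedding_size = as.integer(embedding_size %||% def$embedding_size),
    max_len = as.integer(max_len %||% def$max_len),
    vocab_size = as.integer(vocab_size),
    dropout = dropout,
    share_layer_parameters = isTRUE(share_layer_parameters),
    classifier_bias = isTRUE(classifier_bias))
  cfg$intermediate_size <-
    as.integer(intermediate_size %||% (4L * cfg$hidden_size))
  if (cfg$hidden_size %% cfg$n_heads != 0L)
    stop("hidden_size must be divisible by n_heads")
  if (cfg$hidden_size %% 2L != 0L)
    stop("hidden_size must be even")
  if (cfg$embedding_size > cfg$hidden_size)
    stop("embedding_size must not exceed hidden_size")
  if (cfg$vocab_size < 5L)
    stop("vocab_size must cover the 4 special tokens plus >=1 group")
  if (cfg$dropout < 0 || cfg$dropout >= 1) stop("dropout must be in [0,1)")
  cfg
}

#' Initialise a sequence encoder
#'
#' Weights are drawn N(0, 0.02^2) (the BERT-family initialiser), layer-norm
#' gains 1 and biases 0, classifier weights 0 so a fresh model scores every
#' pathway 0.5. Position embeddings are *learned* but start from a
#' sinusoidal pattern (amplitude 0.05) rather than noise: at small model
#' scale this makes positional structure linearly salient from the first
#' step and markedly shortens the plateau before order-dependent signal is
#' picked up, while leaving the embeddings free to adapt.
#'
#' @param config from [seqModelConfig()].
#' @param seed integer seed for the weight draw.
#' @return a [SeqModel-class] object.
#' @export
initSeqModel <- function(config, seed = 1L) {
  set.seed(seed)
  sd0 <- 0.02
  H <- config$hidden_size; E <- config$embedding_size
  V <- config$vocab_size; f <- config$intermediate_size
  rnd <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, sd0), nr, nc)
  sinusoidalPos <- function(P) {
    ang <- outer(seq_len(P), 10000^(-(0:(H / 2 - 1)) * 2 / H))
    0.05 * cbind(sin(ang), cos(ang))
  }
  mkLayer <- function() list(
    Wq = rnd(H, H), bq = numeric(H), Wk = rnd(H, H), bk = numeric(H),
    Wv = rnd(H, H), bv = numeric(H), Wo = rnd(H, H), bo = numeric(H),
    ln1_g = rep(1, H), ln1_b = numeric(H),
    W1 = rnd(H, f), b1 = numeric(f), W2 = rnd(f, H), b2 = numeric(H),
    ln2_g = rep(1, H), ln2_b = numeric(H))
  ngroups <- if (config$share_layer_parameters) 1L else config$n_layers
  params <- list(
    tok_emb = rnd(V, E),
    emb_proj = rnd(E, H),
    pos_emb = sinusoidalPos(config$max_len),
    ln_emb_g = rep(1, H), ln_emb_b = numeric(H),
    layers = lapply(seq_len(ngroups), function(i) mkLayer()),
    mlm = list(dense = rnd(H, E), bias = numeric(E),
               ln_g = rep(1, E), ln_b = numeric(E), out_bias = numeric(V)),
    cls = list(w = numeric(H), b = 0))
  methods::new("SeqModel", config = config, params = params)
}

#' @describeIn SeqModel-class the model configuration list.
#' @export
setMethod("modelConfig", "SeqModel", function(object) object@config)

#' @describeIn SeqModel-class total number of trainable scalars.
#' @export
setMethod("parameterCount", "SeqModel", function(object) {
  n <- 0
  count <- function(x) {
    for (el in x) {
      if (is.list(el)) count(el) else n <<- n + length(el)
    }
  }
  count(object@params)
  n
})

setMethod("show", "SeqModel", function(object) {
  cfg <- object@config
  cat(sprintf(
    "SeqModel (%s preset): %d layers x %d heads, H=%d, E=%d, max_len=%d, V=%d\n",
    cfg$preset, cfg$n_layers, cfg$n_heads, cfg$hidden_size,
    cfg$embedding_size, cfg$max_len, cfg$vocab_size))
  cat(sprintf("  cross-layer sharing: %s; parameters: %s\n",
              cfg$share_layer_parameters,
              format(parameterCount(object), big.mark = ",")))
})

LN_EPS <- 1e-12

layernormFwd <- function(X, g, b) {
  n <- nrow(X); m <- ncol(X)
  mu <- .rowMeans(X, n, m)
  xc <- X - mu
  invstd <- 1 / sqrt(.rowMeans(xc * xc, n, m) + LN_EPS)
  xhat <- xc * invstd
  list(Y = xhat * rep(g, each = n) + rep(b, each = n),
       xhat = xhat, invstd = invstd)
}

layernormBwd <- function(dY, cache, g) {
  n <- nrow(dY); m <- ncol(dY)
  xhat <- cache$xhat
  dxhat <- dY * rep(g, each = n)
  dX <- cache$invstd *
    (dxhat - .rowMeans(dxhat, n, m) - xhat * .rowMeans(dxhat * xhat, n, m))
  list(dX = dX, dg = .colSums(dY * xhat, n, m), db = .colSums(dY, n, m))
}

# Forward pass for one id sequence (0-based ids, [CLS] first). Returns the
# final hidden states, per-layer per-head attention maps, and (optionally)
# every intermediate needed by seqBackward.
fwdOne <- function(params, cfg, ids, mask = NULL, want_attn = TRUE,
                   want_cache = FALSE, drop_rate = 0) {
  N <- length(ids)
  if (N > cfg$max_len) stop("sequence longer than max_len")
  if (any(ids < 0L) || any(ids >= cfg$vocab_size))
    stop("token id outside vocabulary")
  if (is.null(mask)) mask <- ids != PAD_ID
  H <- cfg$hidden_size; nh <- cfg$n_heads; dh <- H %/% nh
  idx <- ids + 1L
  tokRows <- params$tok_emb[idx, , drop = FALSE]
  X0 <- tokRows %*% params$emb_proj + params$pos_emb[seq_len(N), , drop = FALSE]
  ln0 <- layernormFwd(X0, params$ln_emb_g, params$ln_emb_b)
  X <- ln0$Y
  padded <- any(!mask)
  keyBias <- ifelse(mask, 0, -Inf)
  attn <- if (want_attn) vector("list", cfg$n_layers) else NULL
  caches <- if (want_cache) vector("list", cfg$n_layers) else NULL
  for (l in seq_len(cfg$n_layers)) {
    p <- params$layers[[if (cfg$share_layer_parameters) 1L else l]]
    Q <- X %*% p$Wq + rep(p$bq, each = N)
    K <- X %*% p$Wk + rep(p$bk, each = N)
    Vm <- X %*% p$Wv + rep(p$bv, each = N)
    ctx <- matrix(0, N, H)
    A_heads <- vector("list", nh)
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      S <- tcrossprod(Q[, cols, drop = FALSE], K[, cols, drop = FALSE]) / sqrt(dh)
      if (padded) S <- S + rep(keyBias, each = N)
      A <- softmaxRows(S)
      A_heads[[h]] <- A
      ctx[, cols] <- A %*% Vm[, cols, drop = FALSE]
    }
    AO <- ctx %*% p$Wo + rep(p$bo, each = N)
    dm1 <- NULL
    if (drop_rate > 0) {
      dm1 <- matrix(stats::rbinom(N * H, 1L, 1 - drop_rate), N, H) /
        (1 - drop_rate)
      AO <- AO * dm1
    }
    ln1 <- layernormFwd(X + AO, p$ln1_g, p$ln1_b)
    X1 <- ln1$Y
    Z1 <- X1 %*% p$W1 + rep(p$b1, each = N)
    gt <- geluT(Z1)
    G <- gt$y
    FF <- G %*% p$W2 + rep(p$b2, each = N)
    dm2 <- NULL
    if (drop_rate > 0) {
      dm2 <- matrix(stats::rbinom(N * H, 1L, 1 - drop_rate), N, H) /
        (1 - drop_rate)
      FF <- FF * dm2
    }
    ln2 <- layernormFwd(X1 + FF, p$ln2_g, p$ln2_b)
    if (want_attn) {
      attn[[l]] <- if (padded) lapply(A_heads, function(A) {
        A[, !mask] <- 0  # zero mass on padded keys in the exposed maps
        A
      }) else A_heads
    }
    if (want_cache)
      caches[[l]] <- list(X = X, Q = Q, K = K, V = Vm, A = A_heads,
                          ctx = ctx, ln1 = ln1, X1 = X1, Z1 = Z1, G = G,
                          gelu_t = gt$t, dm1 = dm1, dm2 = dm2)
    X <- ln2$Y
    if (want_cache) caches[[l]]$ln2 <- ln2
  }
  out <- list(hidden = X, cls = X[1L, ], attention = attn, mask = mask,
              ids = ids)
  if (want_cache) {
    out$cache <- list(layers = caches, ln0 = ln0, tokRows = tokRows,
                      idx = idx, keyBias = keyBias, N = N)
  }
  out
}

# Backpropagate dHidden (gradient w.r.t. the final hidden states) through
# the encoder, returning a gradient structure matching params.
seqBackward <- function(params, cfg, fwd, dHidden) {
  H <- cfg$hidden_size; nh <- cfg$n_heads; dh <- H %/% nh
  N <- fwd$cache$N
  shared <- cfg$share_layer_parameters
  ngroups <- length(params$layers)
  zeroLayer <- function(p) lapply(p, function(x) x * 0)
  g <- list(layers = lapply(params$layers, zeroLayer))
  dX <- dHidden
  for (l in rev(seq_len(cfg$n_layers))) {
    gi <- if (shared) 1L else l
    p <- params$layers[[gi]]
    cc <- fwd$cache$layers[[l]]
    lg <- g$layers[[gi]]
    b2v <- layernormBwd(dX, cc$ln2, p$ln2_g)
    lg$ln2_g <- lg$ln2_g + b2v$dg; lg$ln2_b <- lg$ln2_b + b2v$db
    dRes2 <- b2v$dX                       # grad w.r.t. X1 + FF
    dFF <- if (!is.null(cc$dm2)) dRes2 * cc$dm2 else dRes2
    lg$W2 <- lg$W2 + crossprod(cc$G, dFF)
    lg$b2 <- lg$b2 + colSums(dFF)
    dG <- tcrossprod(dFF, p$W2)
    dZ1 <- dG * geluGradT(cc$Z1, cc$gelu_t)
    lg$W1 <- lg$W1 + crossprod(cc$ln1$Y, dZ1)
    lg$b1 <- lg$b1 + colSums(dZ1)
    dX1 <- dRes2 + tcrossprod(dZ1, p$W1)
    b1v <- layernormBwd(dX1, cc$ln1, p$ln1_g)
    lg$ln1_g <- lg$ln1_g + b1v$dg; lg$ln1_b <- lg$ln1_b + b1v$db
    dRes1 <- b1v$dX                       # grad w.r.t. X + AO
    dAO <- if (!is.null(cc$dm1)) dRes1 * cc$dm1 else dRes1
    lg$Wo <- lg$Wo + crossprod(cc$ctx, dAO)
    lg$bo <- lg$bo + colSums(dAO)
    dCtx <- tcrossprod(dAO, p$Wo)
    dQ <- matrix(0, N, H); dK <- matrix(0, N, H); dV <- matrix(0, N, H)
    for (h in seq_len(nh)) {
      cols <- ((h - 1L) * dh + 1L):(h * dh)
      A <- cc$A[[h]]
      dCh <- dCtx[, cols, drop = FALSE]
      dA <- tcrossprod(dCh, cc$V[, cols, drop = FALSE])
      dV[, cols] <- crossprod(A, dCh)
      dS <- (dA - rowSums(dA * A)) * A / sqrt(dh)
      dQ[, cols] <- dS %*% cc$K[, cols, drop = FALSE]
      dK[, cols] <- crossprod(dS, cc$Q[, cols, drop = FALSE])
    }
    lg$Wq <- lg$Wq + crossprod(cc$X, dQ); lg$bq <- lg$bq + colSums(dQ)
    lg$Wk <- lg$Wk + crossprod(cc$X, dK); lg$bk <- lg$bk + colSums(dK)
    lg$Wv <- lg$Wv + crossprod(cc$X, dV); lg$bv <- lg$bv + colSums(dV)
    dX <- dRes1 + tcrossprod(dQ, p$Wq) + tcrossprod(dK, p$Wk) +
      tcrossprod(dV, p$Wv)
    g$layers[[gi]] <- lg
  }
  b0 <- layernormBwd(dX, fwd$cache$ln0, params$ln_emb_g)
  g$ln_emb_g <- b0$dg; g$ln_emb_b <- b0$db
  dX0 <- b0$dX
  g$pos_emb <- matrix(0, cfg$max_len, H)
  g$pos_emb[seq_len(N), ] <- dX0
  g$emb_proj <- crossprod(fwd$cache$tokRows, dX0)
  dTokRows <- tcrossprod(dX0, params$emb_proj)
  g$tok_emb <- matrix(0, cfg$vocab_size, cfg$embedding_size)
  acc <- rowsum(dTokRows, fwd$cache$idx)
  g$tok_emb[as.integer(rownames(acc)), ] <- acc
  g
}

#' Run the encoder forward
#'
#' @param model a [SeqModel-class].
#' @param ids an integer vector of 0-based token ids (single sequence,
#'   `[CLS]` first) or a list of such vectors.
#' @param mask optional logical vector marking real (non-`[PAD]`) positions;
#'   derived from the ids by default. Padded keys receive zero attention
#'   mass from real positions, so a sequence gives the same `[CLS]` vector
#'   at any padded length.
#' @param want_attention return per-layer, per-head attention maps
#'   (row-stochastic `N x N` matrices).
#' @return for a single sequence, a list with `hidden` (`N x H` final
#'   hidden states), `cls` (the `[CLS]` vector), `attention`
#'   (`list[layer][head]`), `mask`, `ids`; for a list input, a list of such
#'   outputs.
#' @export
seqForward <- function(model, ids, mask = NULL, want_attention = TRUE) {
  stopifnot(is(model, "SeqModel"))
  if (is.list(ids))
    return(lapply(ids, function(s)
      fwdOne(model@params, model@config, as.integer(s),
             want_attn = want_attention)))
  fwdOne(model@params, model@config, as.integer(ids), mask = mask,
         want_attn = want_attention)
}

# Masked-code prediction head applied to selected rows of the final hidden
# states. The decoder weight is tied to the (factorized) token embedding.
mlmHeadFwd <- function(params, hidden, positions) {
  Hm <- hidden[positions, , drop = FALSE]
  n <- length(positions)
  Z1 <- Hm %*% params$mlm$dense + rep(params$mlm$bias, each = n)
  G <- gelu(Z1)
  ln <- layernormFwd(G, params$mlm$ln_g, params$mlm$ln_b)
  logits <- tcrossprod(ln$Y, params$tok_emb) +
    rep(params$mlm$out_bias, each = n)
  list(logits = logits, Z1 = Z1, ln = ln, Hm = Hm)
}

#' Per-position masked-code prediction scores
#'
#' Applies the prediction head (dense + GELU + layer norm, decoder tied to
#' the token embedding) to every position of a forward output.
#'
#' @param model a [SeqModel-class].
#' @param forward_output result of [seqForward()] for one sequence.
#' @return an `N x V` matrix of unnormalised scores.
#' @export
mlmLogits <- function(model, forward_output) {
  mlmHeadFwd(model@params, forward_output$hidden,
             seq_len(nrow(forward_output$hidden)))$logits
}

#' Score a batch of id sequences
#'
#' Inference-only convenience: runs the encoder forward and applies the
#' logistic head to each sequence, using the compiled fast path. Equal to
#' `classifyPathway(model, seqForward(model, ids))` for every sequence.
#'
#' @param model a [SeqModel-class].
#' @param id_sequences list of 0-based id sequences.
#' @return numeric vector of probabilities.
#' @export
scorePathways <- function(model, id_sequences) {
  .cpp_cls_scores(model@params, model@config, id_sequences)
}

#' Lung-cancer probability from the logistic head
#'
#' `sigmoid(C \%*\% W + b)` on the final-layer `[CLS]` representation `C`;
#' the bias is dropped when the model was configured with
#' `classifier_bias = FALSE`.
#'
#' @param model a [SeqModel-class].
#' @param forward_output result of [seqForward()] for one sequence, or a
#'   list of results.
#' @return probability (or vector of probabilities) in `[0, 1]`.
#' @export
classifyPathway <- function(model, forward_output) {
  one <- function(fo) {
    z <- sum(fo$cls * model@params$cls$w)
    if (model@config$classifier_bias) z <- z + model@params$cls$b
    sigmoid(z)
  }
  if (!is.null(forward_output$cls)) one(forward_output)
  else vapply(forward_output, one, numeric(1))
}
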