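#' Whole-pathway embedding from the [CLS] token
#'
#' The final-layer hidden state of the `[CLS]` position — the same vector
#' the classification head consumes — is used as the deep pathway
#' representation for clustering.
#'
#' @param model a fine-tuned [SeqModel-class].
#' @param ids one 0-based id sequence, or a list of them.
#' @return an H-vector, or an `n x H` matrix for a list input.
#' @export
clsEmbedding <- function(model, ids) {
  if (is.list(ids)) {
    .cpp_cls_embed(model@params, model@config,
                   lapply(ids, as.integer))
  } else {
    fwdOne(model@params, model@config, as.integer(ids),
           want_attn = FALSE)$cls
  }
}

#' Attention profile of a pathway
#'
#' How much the model attends to each medical code when forming the
#' pathway representation: the final-layer attention row of the `[CLS]`
#' query, averaged over all heads, with special-token positions dropped
#' and the weights renormalised to sum to 1.
#'
#' @param model a [SeqModel-class].
#' @param ids one 0-based id sequence (`[CLS]` first).
#' @param layer encoder layer to read (default: final layer).
#' @return numeric vector of length = number of non-special tokens, named
#'   by token position id.
#' @export
attentionProfile <- function(model, ids, layer = NULL) {
  ids <- as.integer(ids)
  keep <- which(ids >= 4L)
  if (!length(keep)) stop("pathway has no medical-code tokens")
  layer <- layer %||% model@config$n_layers
  fwd <- fwdOne(model@params, model@config, ids, want_attn = TRUE)
  heads <- fwd$attention[[layer]]
  row <- Reduce(`+`, lapply(heads, function(A) A[1L, ])) / length(heads)
  w <- row[keep]
  w / sum(w)
}

#' Cluster pathway embeddings with k-means
#'
#' k-means (multiple restarts, best inertia kept) on `[CLS]` embeddings —
#' never on the 2-D layout, which is cosmetic. Embedding dimensions are
#' standardised (centred, unit variance) before clustering by default:
#' learned embeddings carry a few high-variance directions unrelated to
#' patient content that otherwise dominate the Euclidean metric. A k-scan
#' (total within-cluster sum of squares and mean silhouette for
#' k = 2..10) is returned to make the choice of k auditable; the study
#' chose k = 6 for a combination of robustness and separation.
#'
#' @param embeddings `n x H` matrix from [clsEmbedding()].
#' @param k number of clusters (default 6).
#' @param seed integer seed.
#' @param n_init k-means restarts.
#' @param k_scan range of k values to profile (`NULL` disables).
#' @param standardize scale each embedding dimension to zero mean, unit
#'   variance before clustering (constant dimensions are left alone).
#' @return list with `assignments`, `centers` and `inertia` (both in the
#'   clustered — by default standardised — space), `sizes` (+ fractions),
#'   `k_scan`, and the `standardize` flag used.
#' @export
clusterPathways <- function(embeddings, k = 6L, seed = 1L, n_init = 10L,
                            k_scan = 2:10, standardize = TRUE) {
  n <- nrow(embeddings)
  if (k > n) stop("k exceeds number of embeddings")
  X <- as.matrix(embeddings)
  if (standardize) {
    sds <- apply(X, 2L, stats::sd)
    sds[sds == 0 | is.na(sds)] <- 1
    X <- scale(X, center = TRUE, scale = sds)
  }
  set.seed(seed)
  km <- stats::kmeans(X, centers = k, nstart = n_init, iter.max = 100L)
  scan <- NULL
  if (!is.null(k_scan)) {
    k_scan <- k_scan[k_scan <= n - 1L & k_scan >= 2L]
    d <- stats::dist(X)
    scan <- do.call(rbind, lapply(k_scan, function(kk) {
      km2 <- stats::kmeans(X, centers = kk, nstart = n_init,
                           iter.max = 100L)
      sil <- mean(cluster::silhouette(km2$cluster, d)[, "sil_width"])
      data.frame(k = kk, inertia = km2$tot.withinss, silhouette = sil)
    }))
  }
  sizes <- as.integer(table(km$cluster))
  list(assignments = km$cluster, centers = km$centers,
       inertia = km$tot.withinss, clustered = X,
       sizes = data.frame(cluster = seq_len(k), n = sizes,
                          fraction = sizes / n),
       k_scan = scan, standardize = standardize)
}

#' Per-cluster code prevalence and attention summaries
#'
#' For each cluster: the fraction of member pathways containing each code
#' group, and the mean attention mass the model places on each group —
#' both sorted descending, the tables used to characterise clusters
#' clinically.
#'
#' @param assignments integer cluster per pathway.
#' @param pathways a [PathwaySet-class] or list of token vectors (same
#'   order as `assignments`).
#' @param attention_profiles optional list of per-pathway named attention
#'   vectors; names must be the token strings (see
#'   [attentionProfileTokens()]); `NULL` skips attention tables.
#' @return named list of clusters, each with `prevalence` and `attention`
#'   data frames.
#' @export
clusterCodeSummary <- function(assignments, pathways,
                               attention_profiles = NULL) {
  toks <- if (is(pathways, "PathwaySet")) pathwayTokens(pathways) else pathways
  out <- lapply(sort(unique(assignments)), function(cl) {
    i <- which(assignments == cl)
    tab <- sort(table(unlist(lapply(toks[i], unique))) / length(i),
                decreasing = TRUE)
    prev <- data.frame(group_id = names(tab), prevalence = as.numeric(tab),
                       stringsAsFactors = FALSE)
    att <- NULL
    if (!is.null(attention_profiles)) {
      acc <- unlist(lapply(i, function(j) attention_profiles[[j]]))
      s <- tapply(acc, names(acc), sum) / length(i)
      s <- sort(s, decreasing = TRUE)
      att <- data.frame(group_id = names(s), mean_attention = as.numeric(s),
                        stringsAsFactors = FALSE)
    }
    list(n = length(i), prevalence = prev, attention = att)
  })
  names(out) <- paste0("cluster", sort(unique(assignments)))
  out
}

#' Attention profile keyed by token
#'
#' Convenience wrapper around [attentionProfile()] returning the weights
#' named by their token strings, as [clusterCodeSummary()] expects.
#'
#' @inheritParams attentionProfile
#' @param vocabulary the [Vocabulary-class] used to encode `ids`.
#' @export
attentionProfileTokens <- function(model, ids, vocabulary, layer = NULL) {
  w <- attentionProfile(model, ids, layer)
  names(w) <- idToToken(vocabulary, ids[ids >= 4L])
  w
}
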