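# Shared fixtures and independent oracles, built in code at test time.

# random corpus with labels containing spaces/punctuation (no tab/newline)
random_corpus <- function(n_scenes = 20, seed = 1) {
  set.seed(seed)
  alphabet <- c("coffee table", "bath-tub", "sky", "traffic light",
                "book.case", "pot (plant)", "window pane", "door",
                "légume", "stair rail")
  annotation_corpus(lapply(seq_len(n_scenes), function(i)
    sample(alphabet, sample(2:6, 1))))
}

# small labelled embedding for encoding fixtures
random_embedding <- function(n_cat = 18, dim = 4, seed = 1,
                             prefix = "cat") {
  set.seed(seed)
  embedding_table(matrix(rnorm(n_cat * dim), n_cat, dim),
                  sprintf("%s%02d", prefix, seq_len(n_cat)))
}

# exact CBOW with a full-softmax objective, trained by batch gradient
# descent: the independent oracle for co-occurrence structure (no sampling,
# no SGD schedule).
softmax_cbow_oracle <- function(corpus, dim = 5, iters = 2000, lr = 0.1,
                                seed = 1) {
  labels <- names(corpus$vocabulary)
  V <- length(labels)
  set.seed(seed)
  U <- matrix(runif(V * dim, -0.1, 0.1), V, dim, dimnames = list(labels))
  W <- matrix(0, V, dim, dimnames = list(labels))
  pairs <- list()
  for (s in corpus$scenes) {
    if (length(s) < 2) next
    for (t in seq_along(s))
      pairs[[length(pairs) + 1L]] <- list(t = s[t], c = s[-t])
  }
  for (it in seq_len(iters)) {
    gU <- U * 0; gW <- W * 0
    for (pr in pairs) {
      h <- colMeans(U[pr$c, , drop = FALSE])
      sc <- W %*% h
      p <- exp(sc - max(sc)); p <- p / sum(p)
      y <- rep(0, V); y[match(pr$t, labels)] <- 1
      gW <- gW + outer(as.vector(y - p), h)
      gh <- as.vector(t(W) %*% (y - p)) / length(pr$c)
      gU[pr$c, ] <- sweep(gU[pr$c, , drop = FALSE], 2L, gh, `+`)
    }
    U <- U + lr * gU / length(pairs)
    W <- W + lr * gW / length(pairs)
  }
  U
}

cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# mean within- and between-context cosine of (row-normalized) embeddings
context_cosines <- function(emb, label_context) {
  e <- unclass(emb)
  en <- e / sqrt(rowSums(e^2))
  cs <- en %*% t(en)
  ctx <- label_context[rownames(e)]
  same <- outer(ctx, ctx, `==`)
  ut <- upper.tri(cs)
  list(within = mean(cs[same & ut]), between = mean(cs[!same & ut]),
       per_context = vapply(sort(unique(ctx)), function(k) {
         inK <- ctx == k
         c(within = mean(cs[outer(inK, inK, `&`) & ut]),
           between = mean(cs[outer(inK, !inK, `&`)]))
       }, numeric(2)))
}

# sparse-sampling block corpus: two disjoint context vocabularies, each
# scene draws a strict subset of one block so that same-block labels share
# context objects
block_corpus <- function(n_scenes = 500, block_size = 8, scene_size = 3,
                         seed = 1) {
  set.seed(seed)
  blocks <- list(sprintf("a%02d", seq_len(block_size)),
                 sprintf("b%02d", seq_len(block_size)))
  scenes <- lapply(seq_len(n_scenes), function(i)
    sample(blocks[[1 + i %% 2]], scene_size))
  list(corpus = annotation_corpus(scenes),
       label_context = setNames(rep(1:2, each = block_size),
                                unlist(blocks)))
}

# brute-force Benjamini-Hochberg: p * m / rank with running minimum
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(q, 1)[order(o)]
}

# encoding fixture: responses exactly/noisily linear in a model
encoding_fixture <- function(n_cat = 18, n_vox = 30, p = 3, n_folds = 3,
                             noise_sd = 0, seed = 1) {
  set.seed(seed)
  cats <- sprintf("cat%02d", seq_len(n_cat))
  M <- matrix(rnorm(n_cat * p), n_cat, p,
              dimnames = list(cats, sprintf("f%d", seq_len(p))))
  W <- matrix(rnorm(p * n_vox), p, n_vox)
  b0 <- rnorm(n_vox)
  Y <- t(M %*% W + rep(b0, each = n_cat)) +
    matrix(rnorm(n_vox * n_cat, sd = noise_sd), n_vox, n_cat)
  rownames(Y) <- sprintf("v%03d", seq_len(n_vox))
  colnames(Y) <- cats
  folds <- make_folds(cats, n_folds)
  list(model = M, Y = Y, folds = folds, weights = t(W), intercept = b0)
}
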