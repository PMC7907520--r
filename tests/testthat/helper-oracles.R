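# Independent oracles used across tests. These deliberately use naive
# scalar loops so they share no code path with the package implementation.

# AUC by exhaustive (positive, negative) pair counting.
auc_bruteforce <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (sp in pos) {
    for (sn in neg) {
      total <- total + if (sp > sn) 1 else if (sp == sn) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# Squeeze-excite-scale composition with scalar loops.
se_block_bruteforce <- function(u, W1, W2) {
  d <- dim(u)
  C <- d[3]
  Cr <- nrow(W1)
  z <- numeric(C)
  for (c in seq_len(C)) z[c] <- mean(u[, , c])
  h <- numeric(Cr)
  for (i in seq_len(Cr)) {
    acc <- 0
    for (c in seq_len(C)) acc <- acc + W1[i, c] * z[c]
    h[i] <- max(acc, 0)
  }
  s <- numeric(C)
  for (c in seq_len(C)) {
    acc <- 0
    for (i in seq_len(Cr)) acc <- acc + W2[c, i] * h[i]
    s[c] <- 1 / (1 + exp(-acc))
  }
  out <- u
  for (c in seq_len(C)) out[, , c] <- u[, , c] * s[c]
  out
}

# Small synthetic table with catalog-style names for selection tests:
# first feature separates the classes perfectly, the rest are pure noise.
make_separable_table <- function(n = 200, p = 50, seed = 1) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  x <- matrix(rnorm(n * p), n, p)
  x[, 1] <- ifelse(y == 1, 5, -5) + 0.01 * rnorm(n)
  cat_names <- feature_catalog()$name
  colnames(x) <- cat_names[seq_len(p)]
  rownames(x) <- sprintf("S%03d", seq_len(n))
  list(table = feature_table(x), labels = y, separating = colnames(x)[1])
}

# Tiny, quickly trainable model configuration (8x8 mappings).
tiny_conv_config <- function(use_se = TRUE) {
  conv_stack_config(input_side = 8, filters = c(4, 8), kernel_size = 3,
                    pool_size = 2, se_reduction = 2, dropout_rate = 0.2,
                    dense_units = 8, use_se = use_se)
}

# Tiny separable cohort already shaped as feature mappings.
make_tiny_mapset <- function(n = 60, side = 8, d = 3, seed = 2) {
  set.seed(seed)
  k <- side * side
  y <- rep(c(0L, 1L), length.out = n)
  x <- matrix(rnorm(n * k), n, k)
  x[, 1:6] <- x[, 1:6] + ifelse(y == 1, d / 2, -d / 2)
  cat_names <- feature_catalog()$name[seq_len(k)]
  colnames(x) <- cat_names
  rownames(x) <- sprintf("T%03d", seq_len(n))
  tab <- feature_table(x)
  sel <- structure(list(names = cat_names, k = k), class = "selected_features")
  nm <- fit_normalizer(tab, cat_names)
  maps <- build_feature_maps(tab, sel, nm, spiral_layout(side))
  list(maps = maps, labels = y, table = tab)
}
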