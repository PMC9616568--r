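# Shared fixture builders; everything is generated in code under fixed seeds.

# Brute-force oracle for the inter-PN distance: explicit double loop.
brute_inter_pn <- function(a, b) {
  if (nrow(a) > nrow(b)) { tmp <- a; a <- b; b <- tmp }
  mins <- numeric(nrow(a))
  for (i in seq_len(nrow(a))) {
    best <- Inf
    for (j in seq_len(nrow(b))) {
      d2 <- sum((a[i, ] - b[j, ])^2)
      if (d2 < best) best <- d2
    }
    mins[i] <- best
  }
  sqrt(mean(mins))
}

random_points <- function(n, center = c(0, 0, 0), sd = 1) {
  sweep(matrix(rnorm(3 * n, 0, sd), ncol = 3), 2, center, `+`)
}

# Random valid skeleton: node i > 1 attaches to a uniformly chosen earlier node.
random_skeleton <- function(n, neuron_id = "rnd", sd = 5) {
  parent <- c(-1L, vapply(seq_len(n - 1L), function(i) sample.int(i, 1L), integer(1)))
  nodes <- data.frame(node_id = seq_len(n), structure = 0L,
                      x = rnorm(n, 0, sd), y = rnorm(n, 0, sd), z = rnorm(n, 0, sd),
                      radius = runif(n, 0.1, 2), parent_id = parent)
  skeleton(neuron_id, nodes)
}

# Distance-matrix wrapper around plain coordinates.
dist_matrix_of <- function(pts, ids = NULL, neuropil = "AL") {
  ids <- ids %||% paste0("n", seq_len(nrow(pts)))
  m <- as.matrix(dist(pts))
  dimnames(m) <- list(ids, ids)
  structure(m, neuropil = neuropil, class = c("pn_distance_matrix", "matrix"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

blob3 <- function(n, center, sd = 0.5) {
  sweep(matrix(rnorm(3 * n, 0, sd), ncol = 3), 2, center, `+`)
}

# Small well-separated population reused across clustering/stats tests.
toy_population <- function(seed = 42, homotypes = c("DA1", "DL5", "VA2", "DM1"),
                           n_neurons = c(3, 4, 2, 4), sigma = 1.5, ...) {
  generate_population(bundle_spec(homotypes, n_neurons, sigma), seed = seed, ...)
}

# Adjusted Rand index for planted-truth recovery checks.
ari <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab)); si <- sum(ch2(rowSums(tab))); sj <- sum(ch2(colSums(tab)))
  n2 <- ch2(length(a))
  expected <- si * sj / n2
  mx <- (si + sj) / 2
  if (mx == expected) return(1)
  (sij - expected) / (mx - expected)
}

# Fig-9-style schematic: homotypes A..E over partners 1..7.
# A-{1,2,3}; B,C-{2,3,5}; D-{6,7} (both exclusive); E-{4}.
fig9_matrix <- function() {
  C <- rbind(A = c(1, 1, 1, 0, 0, 0, 0),
             B = c(0, 1, 1, 0, 1, 0, 0),
             C = c(0, 1, 1, 0, 1, 0, 0),
             D = c(0, 0, 0, 0, 0, 1, 1),
             E = c(0, 0, 0, 1, 0, 0, 0))
  colnames(C) <- as.character(1:7)
  storage.mode(C) <- "integer"
  C
}
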