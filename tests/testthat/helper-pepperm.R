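# Shared fixtures, built once per test run and cached in the session.

fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(fixture_cache[[name]])) fixture_cache[[name]] <- builder()
  fixture_cache[[name]]
}

# a light model configuration used throughout the tests
tiny_config <- function(...) {
  args <- list(d_model = 8, heads = 2, layers_per_block = 1,
               ffn_width = 12, n_max = 16, channels = c(6, 6), kernel = 3,
               max_len = 6, desc_hidden = 4, fp_hidden = 5, latent = 4,
               fusion_hidden = 4)
  override <- list(...)
  args[names(override)] <- override
  do.call(pepperm_config, args)
}

# a hand-built model-ready sample row (no chemistry backend involved)
toy_sample <- function(cf, n = 4, L = 3, seed = 42, offset = 0L) {
  set.seed(seed)
  node <- matrix(runif(n * 30), n, 30)
  bond <- matrix(0, n, cf$n_max)
  b <- matrix(runif(n * n), n, n); b <- (b + t(b)) / 2; diag(b) <- 0
  bond[, 1:n] <- b
  mk_strength <- function() {
    d <- as.matrix(stats::dist(matrix(rnorm(n * 3), n, 3)))
    s <- 1 / d; s[!is.finite(s)] <- 0; s <- pmin(s, 1); diag(s) <- 1
    s
  }
  mono <- matrix(0, cf$max_len, 16)
  mono[offset + seq_len(L), ] <- matrix(rnorm(L * 16), L, 16)
  list(node = node, bond = bond, sg = mk_strength(), sc = mk_strength(),
       mono = mono, span_offset = as.integer(offset), span_len = as.integer(L),
       desc = rnorm(16), fp = as.numeric(runif(2048) < 0.05), label = -6.2)
}

# small synthetic cohort + replica features, shared across test files
small_synth <- function() fixture("small_synth", function() {
  make_dataset(synth_config(n_peptides = 12, seed = 101))
})

small_features <- function() fixture("small_features", function() {
  build_replicas(small_synth()$records, r = 2, seed = 7)
})

# the 500-peptide study cohort with single-replica features (built once;
# shared by the capacity and recovery acceptance tests)
acceptance_cohort500 <- function() fixture("cohort500", function() {
  ds <- make_dataset(synth_config(n_peptides = 500, seed = 1))
  list(ds = ds, feats = build_replicas(ds$records, r = 1, seed = 1))
})

subset_replica_records <- function(features, ids) {
  features$records <- features$records[
    vapply(features$records, `[[`, "", "id") %in% ids]
  features
}

subset_replica_index <- function(features, indices) {
  subset_replicas(features, indices)
}

# independent breadth-first-search oracle for graph distances
bfs_distances <- function(adj) {
  n <- nrow(adj)
  out <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in which(adj[v, ] > 0)) {
        if (dist[w] > dist[v] + 1) {
          dist[w] <- dist[v] + 1
          queue <- c(queue, w)
        }
      }
    }
    out[s, ] <- dist
  }
  out
}

# naive reference implementation of the Kennard-Stone greedy rule
ks_naive <- function(x, k) {
  d <- as.matrix(stats::dist(x))
  n <- nrow(d)
  pair <- which(d == max(d), arr.ind = TRUE)
  pair <- pair[order(pair[, 1], pair[, 2]), , drop = FALSE][1, ]
  sel <- c(min(pair), max(pair))
  while (length(sel) < k) {
    rest <- setdiff(seq_len(n), sel)
    mind <- vapply(rest, function(i) min(d[i, sel]), numeric(1))
    sel <- c(sel, rest[which.max(mind)])
  }
  sel
}
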