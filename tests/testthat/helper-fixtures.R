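# Shared fixtures (built once per test run) and independent oracles.

.fx <- new.env(parent = emptyenv())

fx_cfg <- function() synth_config(n_compounds = 120L, seed = 42L)

fx_library <- function() {
  if (is.null(.fx$lib)) .fx$lib <- generate_library(fx_cfg())
  .fx$lib
}

fx_activity <- function() {
  if (is.null(.fx$act)) .fx$act <- assign_activities(fx_library(), fx_cfg())
  .fx$act
}

fx_decoys <- function() {
  if (is.null(.fx$dec)) .fx$dec <- generate_decoys(150L, seed = 99L)
  .fx$dec
}

# separable planted-signal modelling data: path fingerprints + labels
fx_sep <- function() {
  if (is.null(.fx$sep)) {
    lib <- fx_library()
    keys <- make_std_key(lib$smiles)
    .fx$sep <- list(X = path_fp(keys),
                    y = ifelse(lib$has_pharmacophore, "active", "inactive"),
                    keys = keys)
  }
  .fx$sep
}

# brute-force popcount Tanimoto oracle
oracle_tanimoto <- function(x, y) {
  s <- 0; a <- 0; b <- 0
  for (i in seq_along(x)) {
    if (x[i] == 1 && y[i] == 1) s <- s + 1
    if (x[i] == 1) a <- a + 1
    if (y[i] == 1) b <- b + 1
  }
  if (a + b - s == 0) return(0)
  s / (a + b - s)
}

# exhaustive average-linkage agglomerator (lowest-index pair on exact ties);
# returns cluster membership after cutting: merges only at distance <= cut
oracle_avg_cluster <- function(D, cut) {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  repeat {
    if (length(clusters) == 1L) break
    best <- NULL; best_d <- Inf
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        d <- mean(D[clusters[[i]], clusters[[j]]])
        if (d < best_d - 1e-12) { best_d <- d; best <- c(i, j) }
      }
    }
    if (best_d > cut) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  memb <- integer(n)
  for (k in seq_along(clusters)) memb[clusters[[k]]] <- k
  memb
}

# partitions equal up to relabeling?
same_partition <- function(a, b) {
  length(a) == length(b) &&
    identical(as.integer(factor(paste(a))) ,
              as.integer(factor(paste(b)))) ||
    all(outer(a, a, "==") == outer(b, b, "=="))
}
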