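# Independent brute-force oracles used across the suite.

# random sparse fingerprint
rand_fp <- function(nbits = 64L, density = 0.2) {
  fingerprint(which(runif(nbits) < density), nbits)
}

# union-find single-linkage clustering over the full pairwise TC matrix
oracle_cluster <- function(fps, cutoff) {
  n <- length(fps)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && tanimoto(fps[[i]], fps[[j]]) >= cutoff) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# element-wise mTC via scalar tanimoto calls
oracle_mtc <- function(fp, template_fps, w) {
  tcs <- vapply(template_fps, function(tl) tanimoto(fp, tl), numeric(1))
  w * mean(tcs) + (1 - w) * max(tcs)
}

# Riemann sum of the accumulative curve on the per-compound grid
oracle_auac <- function(ranked, tp) {
  n <- length(ranked)
  found <- cumsum(ranked %in% tp) / length(tp)
  area <- 0
  prev <- 0
  for (i in seq_len(n)) {
    area <- area + (prev + found[i]) / 2 * (1 / n)
    prev <- found[i]
  }
  area
}

# write a tiny SMILES file; returns the path
write_smi <- function(smiles, ids = names(smiles), dir = tempdir()) {
  path <- tempfile("lib", tmpdir = dir, fileext = ".smi")
  writeLines(paste(smiles, ids, sep = "\t"), path)
  path
}
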