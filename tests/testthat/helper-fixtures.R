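# Shared fixture builders and independent oracles used across test files.

# best mean per-column Pearson correlation between fitted and true basis
# over all column permutations (brute force; k small)
bestPermColumnCor <- function(Wfit, Wtrue) {
  k <- ncol(Wtrue)
  perms <- permutationsOf(seq_len(k))
  max(vapply(
    perms,
    function(p) mean(diag(stats::cor(Wfit[, p, drop = FALSE], Wtrue))),
    numeric(1)
  ))
}

permutationsOf <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutationsOf(x[-i])) {
      out[[length(out) + 1L]] <- c(x[i], rest)
    }
  }
  out
}

# brute-force pairwise cosine distance between columns i and j
bruteCosineDist <- function(a, b) {
  1 - sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
}

# write a yaml config to a temp file, returning its path (for CLI tests)
writeLines_yaml <- function(cfg) {
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path)
  path
}

# small rank-3 mixture fixture with an identifiable (iid-uniform) basis
identifiableMixture <- function(seed, nProbes = 200, nSamples = 60,
                                noiseSd = 0, k = 3) {
  W <- makeSignatureBasis(nProbes, k, seed = seed)
  makeBulkMixtures(W, nSamples, rep(1, k), noiseSd = noiseSd,
    seed = seed + 100L
  )
}
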