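# Fixtures are built in code at test time.

# Small table with nontrivial correlation structure.
make_table <- function(p = 10, n = 30, seed = 1) {
  generate_base_table(p = p, n = n, seed = seed)
}

# Duplicate a table into an isometric second study with permuted feature
# order; returns the pair and the ground-truth matching.
duplicate_permuted_pair <- function(base, seed = 1) {
  p <- n_features(base)
  perm <- withr_seed(seed, sample(p))
  t2 <- feature_table(
    feature_ids = paste0(base$feature_ids[perm], "_y"),
    mz = base$mz[perm], rt = base$rt[perm],
    intensities = base$intensities[perm, , drop = FALSE],
    sample_ids = base$sample_ids
  )
  m_star <- matrix(0L, p, p)
  m_star[cbind(seq_len(p), match(seq_len(p), perm))] <- 1L
  list(t1 = base, t2 = t2, perm = perm, m_star = m_star)
}

withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  expr
}

# Check that all pairwise distances in a matrix are distinct (so the
# distortion minimum over matchings is unique).
distances_distinct <- function(D, digits = 8) {
  ut <- round(D[upper.tri(D)], digits)
  length(unique(ut)) == length(ut)
}

write_toy_csv <- function(tab, path) {
  write_feature_table(tab, path)
  path
}
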