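# Shared fixtures and independent oracles. Simulations are cached per
# session so several test files can reuse the same realization.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

sim_smoke <- function() {
  cached("sim_smoke", simulate_screens(smoke_config(rng_seed = 7)))
}

sim_study <- function() {
  # full study-scale realization used by the acceptance suite
  cached("sim_study", simulate_screens(sim_config(rng_seed = 2026)))
}

tiny_es <- function(scores, level = "shrna", entities = NULL) {
  scores <- as.matrix(scores)
  if (is.null(entities)) entities <- paste0("e", seq_len(nrow(scores)))
  if (is.null(colnames(scores))) colnames(scores) <- paste0("c", seq_len(ncol(scores)))
  rownames(scores) <- entities
  es_from_matrix(scores, level)
}

# --- exhaustive-enumeration oracles (independent of the package path) ---

oracle_ranksum <- function(a, b, sidedness) {
  pooled <- c(a, b)
  n <- length(pooled)
  n1 <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n, n1)
  us <- apply(combs, 2, function(ix) sum(r[ix])) - n1 * (n1 + 1) / 2
  p_less <- mean(us <= u_obs)
  p_greater <- mean(us >= u_obs)
  switch(sidedness,
         one_sided_less = p_less,
         one_sided_greater = p_greater,
         two_sided = min(1, 2 * min(p_less, p_greater)))
}

oracle_signedrank <- function(d, sidedness) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  vs <- as.vector(signs %*% r)
  p_less <- mean(vs <= v_obs)
  p_greater <- mean(vs >= v_obs)
  switch(sidedness,
         one_sided_less = p_less,
         one_sided_greater = p_greater,
         two_sided = min(1, 2 * min(p_less, p_greater)))
}

oracle_garp <- function(m, members) {
  # sort-and-average brute force on one gene: mean of the two smallest
  # non-missing values per column, the single value if only one remains
  apply(m[members, , drop = FALSE], 2, function(v) {
    v <- sort(v[!is.na(v)])
    if (length(v) == 0) return(NA_real_)
    mean(v[seq_len(min(2, length(v)))])
  })
}
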