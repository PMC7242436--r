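# Shared helpers for the suite: permutation-aligned similarity between
# estimated and true topics, and small corpus constructors.

perms3 <- list(1:3, c(1L, 3L, 2L), c(2L, 1L, 3L), c(2L, 3L, 1L),
               c(3L, 1L, 2L), c(3L, 2L, 1L))

col_cosine <- function(A, B) {
  An <- sweep(A, 2L, sqrt(colSums(A^2)), "/")
  Bn <- sweep(B, 2L, sqrt(colSums(B^2)), "/")
  diag(t(An) %*% Bn)
}

# best-permutation mean cosine between estimated and true per-type topics,
# returning the permutation so psi can be aligned the same way
best_phi_alignment <- function(phi_hat, phi_true) {
  best <- -Inf
  bperm <- NULL
  for (pm in perms3) {
    s <- mean(vapply(seq_along(phi_hat), function(t)
      mean(col_cosine(phi_hat[[t]][, pm, drop = FALSE], phi_true[[t]])),
      1.0))
    if (s > best) {
      best <- s
      bperm <- pm
    }
  }
  list(cosine = best, perm = bperm)
}

empty_counts <- function() data.frame(patient = integer(0), type = integer(0),
                                      feature = integer(0), count = integer(0))
empty_labs <- function() data.frame(patient = integer(0), lab = integer(0),
                                    state = integer(0), freq = integer(0))

# corpus with a single patient holding one token and nothing else
one_token_corpus <- function(W = 2L) {
  mixehr_corpus(data.frame(patient = 1L, type = 1L, feature = 1L, count = 1L),
                empty_labs(), n_patients = 1L, n_features = W,
                n_states = integer(0))
}

fixture_hyper <- function(K = 2L) {
  fx <- make_fixture()
  default_hyper(K, fx$corpus)
}

max_stats_dev <- function(a, b) {
  max(max(abs(a$n_jk - b$n_jk)), max(abs(a$m_jk - b$m_jk)),
      max(abs(a$p - b$p)), max(abs(a$q - b$q)),
      max(mapply(function(x, y) max(abs(x - y)), a$n_wk, b$n_wk)),
      max(mapply(function(x, y) max(abs(x - y)), a$m_lkv, b$m_lkv)))
}
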