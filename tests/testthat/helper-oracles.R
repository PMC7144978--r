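# Independent oracles. These deliberately avoid the code paths they check:
# the hypergeometric tail is summed from log-factorials, the chi-squared
# survival uses the closed-form even-df series, and descendant closures use a
# plain breadth-first walk over an adjacency list.

# one-sided Fisher p by direct factorial arithmetic:
# P(X >= a), X ~ Hypergeom(N = n_cases + n_controls, K = a + c, n = n_cases)
hyper_tail_oracle <- function(a, n_cases, c, n_controls) {
  N <- n_cases + n_controls
  K <- a + c
  lfact <- function(x) lgamma(x + 1)
  lchoose2 <- function(n, k) lfact(n) - lfact(k) - lfact(n - k)
  xs <- seq(a, min(K, n_cases))
  if (length(xs) == 0 || a <= 0) return(1)
  xs <- xs[(K - xs) <= n_controls]
  sum(exp(lchoose2(n_cases, xs) + lchoose2(n_controls, K - xs) -
            lchoose2(N, K)))
}

# chi-squared survival for even df = 2k: exp(-x/2) * sum_{i<k} (x/2)^i / i!
chisq_sf_even_oracle <- function(x, df) {
  stopifnot(df %% 2 == 0)
  k <- df / 2
  i <- 0:(k - 1)
  exp(-x / 2) * sum(exp(i * log(x / 2) - lgamma(i + 1)))
}

# standard-normal log survival by the Mills-ratio asymptotic expansion
# (valid for large z); used to check the large-Z HGF path
normal_log_sf_mills <- function(z) {
  -z^2 / 2 - log(z * sqrt(2 * pi)) + log(1 - 1 / z^2 + 3 / z^4)
}

# reflexive descendant closure by BFS over a children adjacency list
bfs_descendants_oracle <- function(children, id) {
  seen <- character(0)
  queue <- id
  while (length(queue)) {
    x <- queue[1]; queue <- queue[-1]
    if (x %in% seen) next
    seen <- c(seen, x)
    queue <- c(queue, children[[x]])
  }
  seen
}

# random DAG as OBO text + its children adjacency list; node 1 is the root,
# every other node gets 1-2 parents among lower-numbered nodes
random_dag_obo <- function(n, seed) {
  withr::with_seed(seed, {
    ids <- sprintf("HP:%07d", seq_len(n))
    children <- stats::setNames(rep(list(character(0)), n), ids)
    lines <- character(0)
    for (i in seq_len(n)) {
      lines <- c(lines, "[Term]", paste0("id: ", ids[i]),
                 paste0("name: node ", i))
      if (i > 1) {
        np <- sample(1:min(2, i - 1), 1)
        for (p in sample(i - 1, np)) {
          lines <- c(lines, paste0("is_a: ", ids[p]))
          children[[ids[p]]] <- c(children[[ids[p]]], ids[i])
        }
      }
      lines <- c(lines, "")
    }
    list(obo = lines, children = lapply(children, unique), ids = ids)
  })
}
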