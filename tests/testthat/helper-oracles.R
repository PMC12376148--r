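# Independent brute-force oracles used across test files.

# O(n^3) Ward agglomeration from first principles: at each step merge the
# pair of clusters whose ward.D2 cost sqrt(2|A||B|/(|A|+|B|)) * ||cA - cB||
# is smallest (first pair on ties), tracking member sets and heights.
brute_force_ward <- function(x) {
  clusters <- lapply(seq_len(nrow(x)), function(i) i)
  heights <- numeric(0)
  merges <- list()
  while (length(clusters) > 1) {
    best <- NULL
    best_cost <- Inf
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq((i + 1), length(clusters))) {
        A <- clusters[[i]]; B <- clusters[[j]]
        cA <- colMeans(x[A, , drop = FALSE])
        cB <- colMeans(x[B, , drop = FALSE])
        cost <- sqrt(2 * length(A) * length(B) / (length(A) + length(B)) *
                       sum((cA - cB)^2))
        if (cost < best_cost - 1e-12) {
          best_cost <- cost
          best <- c(i, j)
        }
      }
    }
    merges[[length(merges) + 1L]] <- sort(unlist(clusters[best]))
    heights <- c(heights, best_cost)
    clusters[[best[1]]] <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters[[best[2]]] <- NULL
  }
  list(merges = merges, heights = heights)
}

# member sets created by each merge of an hclust-style linkage
linkage_merge_sets <- function(lk) {
  sets <- vector("list", nrow(lk$merge))
  for (i in seq_len(nrow(lk$merge))) {
    members <- function(v) if (v < 0) -v else sets[[v]]
    sets[[i]] <- sort(c(members(lk$merge[i, 1]), members(lk$merge[i, 2])))
  }
  sets
}
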