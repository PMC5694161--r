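# Naive O(n^3) agglomeration oracle over an explicit distance matrix,
# independent of stats::hclust.
naive_agglomerate <- function(D, linkage = "complete") {
  n <- nrow(D)
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  link <- function(a, b) {
    d <- D[a, b, drop = FALSE]
    switch(linkage, complete = max(d), single = min(d), average = mean(d))
  }
  while (length(clusters) > 1) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i >= j) next
        d <- link(clusters[[i]], clusters[[j]])
        if (d < best_d) { best_d <- d; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best[2]]
  }
  heights
}
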