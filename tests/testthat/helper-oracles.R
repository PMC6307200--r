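# Independent oracles shared between unit and acceptance tests. Each is a
# deliberately different route to the same quantity as the implementation.

# HWE exact test via the closed-form conditional probability (normalised
# analytically by the allele-count multinomial, not numerically)
hwe_oracle <- function(nAA, nAa, naa) {
  n <- nAA + nAa + naa
  nA <- 2 * nAA + nAa
  hs <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  pr <- vapply(hs, function(h) {
    exp(lgamma(n + 1) - lgamma((nA - h) / 2 + 1) - lgamma(h + 1) -
          lgamma((2 * n - nA - h) / 2 + 1) + h * log(2) +
          lgamma(nA + 1) + lgamma(2 * n - nA + 1) - lgamma(2 * n + 1))
  }, numeric(1))
  sum(pr[pr <= pr[hs == nAa] * (1 + 1e-12)])
}

# normalised betweenness by explicit BFS shortest-path counting over all
# ordered pairs (dynamic programming on BFS layers)
brute_betweenness <- function(adj) {
  n <- nrow(adj)
  bfs <- function(s) {
    dist <- rep(Inf, n); sigma <- rep(0, n)
    dist[s] <- 0; sigma[s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) for (w in which(adj[v, ])) {
        if (is.infinite(dist[w])) { dist[w] <- dist[v] + 1
          nxt <- c(nxt, w) }
        if (dist[w] == dist[v] + 1) sigma[w] <- sigma[w] + sigma[v]
      }
      frontier <- unique(nxt)
    }
    list(dist = dist, sigma = sigma)
  }
  info <- lapply(1:n, bfs)
  btw <- numeric(n)
  for (v in 1:n) for (s in 1:(n - 1)) for (t in (s + 1):n) {
    if (s == v || t == v) next
    ds <- info[[s]]; dt <- info[[t]]
    if (is.infinite(ds$dist[t])) next
    if (ds$dist[v] + dt$dist[v] == ds$dist[t])
      btw[v] <- btw[v] + ds$sigma[v] * dt$sigma[v] / ds$sigma[t]
  }
  btw * 2 / ((n - 1) * (n - 2))
}

# reference greedy clumping, coded over a p-sorted merged table rather
# than the package's index-scan loop; returns sorted member sets by index
ref_clump <- function(assoc, g, window_kb, r2_min) {
  out <- list()
  tab <- merge(assoc, g$map, by.x = "SNP", by.y = "snp")
  tab <- tab[!is.na(tab$P), ]
  tab <- tab[order(tab$P, tab$chrom, tab$pos), ]
  taken <- character(0)
  repeat {
    left <- tab[!tab$SNP %in% taken, ]
    if (!nrow(left)) break
    idx <- left[1, ]
    cand <- left[left$chrom == idx$chrom &
                   abs(left$pos - idx$pos) <= window_kb * 1000 &
                   left$SNP != idx$SNP, ]
    r2s <- vapply(cand$SNP, function(s)
      suppressWarnings(cor(g$dosage[, idx$SNP], g$dosage[, s],
                           use = "pairwise.complete.obs")^2), numeric(1))
    memb <- c(idx$SNP, cand$SNP[!is.na(r2s) & r2s >= r2_min])
    taken <- c(taken, memb)
    out[[idx$SNP]] <- sort(memb)
  }
  out
}
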