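# Small in-code fixtures shared across test files.

tiny_dataset <- function(n_row = 4, n_col = 4, n_genes = 20, seed = 1) {
  spec <- fixture_spec(grid = c(n_row, n_col), n_domains = 2, n_genes = n_genes,
                       n_marker_per_domain = 5, seed = seed)
  simulate_domain_slide(spec)
}

# brute-force k-NN neighbour sets by full pairwise distance enumeration
brute_force_knn <- function(coords, k) {
  n <- nrow(coords)
  lapply(seq_len(n), function(i) {
    d <- sqrt(rowSums((coords - matrix(coords[i, ], n, 2, byrow = TRUE))^2))
    d[i] <- Inf
    sort(order(d)[seq_len(k)])
  })
}

# scalar-by-scalar contrastive BCE oracle
contrastive_loss_oracle <- function(Z, Zp, g, W) {
  n <- nrow(Z)
  phi <- function(z, s) 1 / (1 + exp(-sum(z * (W %*% s))))
  gsum <- function(M) {
    t(sapply(seq_len(n), function(i) {
      nbr <- g$neighbor_sets[[i]]
      plogis(colMeans(M[nbr, , drop = FALSE]))
    }))
  }
  G1 <- gsum(Z); G2 <- gsum(Zp)
  l1 <- 0; l2 <- 0
  for (i in seq_len(n)) {
    l1 <- l1 - log(phi(Z[i, ], G1[i, ])) - log(1 - phi(Zp[i, ], G1[i, ]))
    l2 <- l2 - log(phi(Zp[i, ], G2[i, ])) - log(1 - phi(Z[i, ], G2[i, ]))
  }
  list(scl = l1 / (2 * n), scl_corrupt = l2 / (2 * n))
}

# loop-based oracle for the spatially informed mapping objective
mapping_objective_oracle <- function(H_s, H_prime, g, alpha, beta, tau) {
  n <- nrow(H_s)
  cosim <- function(a, b) {
    na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
    if (na == 0 || nb == 0) return(0)
    sum(a * b) / (na * nb)
  }
  term1 <- 0
  for (i in seq_len(n)) {
    denom <- 0
    for (p in seq_len(n)) {
      if (p != i) denom <- denom + exp(cosim(H_prime[i, ], H_s[p, ]) / tau)
    }
    for (j in g$neighbor_sets[[i]]) {
      term1 <- term1 - alpha *
        log(exp(cosim(H_prime[i, ], H_s[j, ]) / tau) / denom)
    }
  }
  term1 + beta * sum((H_s - H_prime)^2)
}

# exhaustive pair-counting ARI oracle
ari_pair_oracle <- function(a, b) {
  n <- length(a)
  s00 <- s01 <- s10 <- s11 <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]; sb <- b[i] == b[j]
    if (sa && sb) s11 <- s11 + 1
    else if (sa && !sb) s10 <- s10 + 1
    else if (!sa && sb) s01 <- s01 + 1
    else s00 <- s00 + 1
  }
  tot <- s11 + s10 + s01 + s00
  exp_idx <- (s11 + s10) * (s11 + s01) / tot
  max_idx <- ((s11 + s10) + (s11 + s01)) / 2
  (s11 - exp_idx) / (max_idx - exp_idx)
}
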