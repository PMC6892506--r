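# Independent oracles used across the suite. These deliberately avoid the
# package's computational paths: stationary vectors come from a dense
# least-squares solve, the reduced-matrix split from a full dense eigen
# decomposition, and rankings from base sort().

# stationary vector of a dense column-stochastic matrix by direct solve
oracle_stationary <- function(G) {
  n <- nrow(G)
  drop(qr.solve(rbind(diag(n) - G, rep(1, n)), c(rep(0, n), 1)))
}

# dense Google matrix straight from the definition (no package operators)
oracle_google <- function(graph, alpha = 0.85) {
  n <- graph$n_nodes
  A <- matrix(0, n, n)
  if (nrow(graph$edges) > 0) {
    A[cbind(graph$edges$target + 1, graph$edges$source + 1)] <- 1
  }
  S <- matrix(0, n, n)
  for (j in seq_len(n)) {
    kj <- sum(A[, j])
    S[, j] <- if (kj > 0) A[, j] / kj else 1 / n
  }
  alpha * S + (1 - alpha) / n
}

# full REGOMAX decomposition via dense eigen decomposition of G_ss
oracle_reduce <- function(graph, subset, alpha = 0.85) {
  G <- oracle_google(graph, alpha)
  n <- nrow(G)
  r <- subset + 1
  s <- setdiff(seq_len(n), r)
  Grr <- G[r, r, drop = FALSE]
  Gss <- G[s, s, drop = FALSE]
  Gsr <- G[s, r, drop = FALSE]
  Grs <- G[r, s, drop = FALSE]
  GR <- Grr + Grs %*% solve(diag(length(s)) - Gss, Gsr)
  ev <- eigen(Gss)
  i1 <- which.max(Re(ev$values))
  lam <- Re(ev$values[i1])
  psiR <- Re(ev$vectors[, i1])
  evL <- eigen(t(Gss))
  psiL <- Re(evL$vectors[, which.max(Re(evL$values))])
  plr <- sum(psiL * psiR)
  Gpr <- (Grs %*% psiR) %*% (t(psiL) %*% Gsr) / (plr * (1 - lam))
  Q <- diag(length(s)) - psiR %*% t(psiL) / plr
  Gqr <- Grs %*% Q %*% solve(diag(length(s)) - Q %*% Gss %*% Q, Q %*% Gsr)
  list(G_R = GR, G_rr = Grr, G_pr = Gpr, G_qr = Gqr, lambda_c = lam)
}

# sparse Erdos-Renyi style directed test graph, guaranteed non-empty
random_graph <- function(n, p = 0.08, seed = 1) {
  set.seed(seed)
  ed <- expand.grid(s = 0:(n - 1), t = 0:(n - 1))
  ed <- ed[ed$s != ed$t, ]
  ed <- ed[runif(nrow(ed)) < p, ]
  if (nrow(ed) == 0) ed <- data.frame(s = 0, t = 1)
  directed_graph(data.frame(source = ed$s, target = ed$t), n_nodes = n)
}

random_stochastic <- function(n, seed = 1) {
  set.seed(seed)
  m <- matrix(runif(n * n), n, n)
  sweep(m, 2, colSums(m), "/")
}
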