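# Shared fixtures and independent oracles, all built in code.

tree_abc <- function() ape::read.tree(text = "((A:1,B:1):1,C:2);")

# a molting and a non-molting observation
molt_spring <- function() molt_observation(TRUE, c("February", "March", "April"),
                                           "partial", c("head", "body"))
molt_none <- function() molt_observation(FALSE)

# independent matrix-exponential oracle: truncated power series
expm_series <- function(Q, t, nterm = 80) {
  A <- Q * t
  term <- diag(nrow(Q))
  out <- term
  for (k in seq_len(nterm)) {
    term <- term %*% A / k
    out <- out + term
  }
  out
}

# brute-force pruning oracle: sum over all internal-state assignments
enum_loglik <- function(tree, pair, Q, rootp = rep(0.25, 4)) {
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  nn <- tr$Nnode
  states <- setNames(1 + 2 * pair$x + pair$y, pair$taxa)
  tipst <- states[tr$tip.label]
  P <- lapply(seq_len(nrow(tr$edge)),
              function(e) transition_probabilities(Q, tr$edge.length[e]))
  grid <- as.matrix(expand.grid(rep(list(1:4), nn)))
  tot <- 0
  for (g in seq_len(nrow(grid))) {
    asg <- unname(c(tipst, grid[g, ]))  # node i (ape numbering) -> state
    pr <- rootp[asg[ntip + 1]]
    for (e in seq_len(nrow(tr$edge)))
      pr <- pr * P[[e]][asg[tr$edge[e, 1]], asg[tr$edge[e, 2]]]
    tot <- tot + pr
  }
  log(tot)
}

# independent 2-state pruning oracle for one binary trait (gain rate alpha,
# loss rate beta), uniform 1/2 root
prune2_loglik <- function(tree, states01, alpha, beta) {
  Q <- matrix(c(-alpha, alpha, beta, -beta), 2, byrow = TRUE)
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tr$tip.label)
  L <- matrix(1, ntip + tr$Nnode, 2)
  for (i in seq_len(ntip)) L[i, ] <- as.numeric(c(0, 1) == states01[tr$tip.label[i]])
  for (e in seq_len(nrow(tr$edge))) {
    P <- expm_series(Q, tr$edge.length[e])
    v <- P %*% L[tr$edge[e, 2], ]
    L[tr$edge[e, 1], ] <- L[tr$edge[e, 1], ] * as.vector(v)
  }
  log(sum(0.5 * L[ntip + 1, ]))
}

# yule tree relabeled with a species table's names
study_tree <- function(table, seed = 1L) {
  tr <- simulate_yule_tree(nrow(table), seed = seed)
  tr$tip.label <- sample(table$species)
  tr
}
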