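# Fixture builders shared across test files; everything is generated in
# code so the suite needs no data files.

# the 3-taxon x 2-fauna table from the reader contract
tiny_matrix <- function() {
  occurrence_matrix(rbind(t1 = c(1L, 1L), t2 = c(0L, 1L), t3 = c(1L, 0L)),
                    faunas = c("A", "B"))
}

# perfectly nested succession: fauna k holds taxa {k, k+1}
nested_matrix <- function(nf = 6) {
  nt <- nf + 1
  inc <- matrix(0L, nt, nf,
                dimnames = list(sprintf("t%02d", 1:nt), sprintf("F%02d", 1:nf)))
  for (k in seq_len(nf)) inc[c(k, k + 1), k] <- 1L
  occurrence_matrix(inc)
}

# random binary matrix with no empty taxa/faunas
random_matrix <- function(nt, nf, p = 0.4, seed = 1) {
  set.seed(seed)
  repeat {
    inc <- matrix(rbinom(nt * nf, 1, p), nt, nf,
                  dimnames = list(sprintf("t%02d", 1:nt),
                                  sprintf("F%02d", 1:nf)))
    if (all(rowSums(inc) > 0) && all(colSums(inc) > 0))
      return(occurrence_matrix(inc))
  }
}

write_temp_csv <- function(df, envir = parent.frame()) {
  path <- withr::local_tempfile(fileext = ".csv", .local_envir = envir)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# truly nested succession: fauna k contains taxa 1..k
nested_subset_matrix <- function(nf = 6) {
  inc <- matrix(0L, nf, nf,
                dimnames = list(sprintf("t%02d", 1:nf), sprintf("F%02d", 1:nf)))
  inc[upper.tri(inc, diag = TRUE)] <- 1L
  occurrence_matrix(inc)
}

same_topology <- function(a, b) {
  isTRUE(ape::all.equal.phylo(a, b, use.edge.length = FALSE))
}

# brute-force small-parsimony oracle: minimise changes over every
# assignment of internal states, forbidding 1->0 when irreversible
brute_parsimony <- function(tree, m, irreversible = FALSE) {
  X <- t(unclass(m))[tree$tip.label, , drop = FALSE]
  nn <- ape::Ntip(tree) + tree$Nnode
  internals <- (ape::Ntip(tree) + 1):nn
  root <- ape::Ntip(tree) + 1
  total <- 0
  for (ch in seq_len(ncol(X))) {
    best <- Inf
    for (code in 0:(2^length(internals) - 1)) {
      st <- integer(nn)
      st[seq_len(ape::Ntip(tree))] <- X[, ch]
      st[internals] <- bitwAnd(bitwShiftR(code, seq_along(internals) - 1), 1)
      cost <- 0
      for (k in seq_len(nrow(tree$edge))) {
        a <- st[tree$edge[k, 1]]; b <- st[tree$edge[k, 2]]
        if (a == b) next
        if (irreversible && a == 1 && b == 0) { cost <- Inf; break }
        cost <- cost + 1
      }
      if (irreversible && st[root] == 1) cost <- cost + 1 # origin at root edge
      best <- min(best, cost)
    }
    total <- total + best
  }
  total
}
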