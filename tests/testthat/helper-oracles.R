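# Independent oracles shared between module tests and the acceptance suite.
# Each deliberately re-derives the quantity by a different route than the
# implementation under test.

# Linear-scan region merger (counts merged regions).
merge_oracle <- function(windows, flagged, gap) {
  idx <- which(flagged)
  if (!length(idx)) return(0L)
  n <- 1L
  for (k in seq_along(idx)[-1]) {
    prev <- idx[k - 1L]; cur <- idx[k]
    if (windows$chrom[cur] != windows$chrom[prev] ||
        windows$start[cur] - windows$end[prev] >= gap) n <- n + 1L
  }
  n
}

# Exhaustive minimum spanning tree weight by enumerating all n^(n-2)
# labeled trees through their Pruefer sequences.
mst_weight_oracle <- function(d) {
  n <- nrow(d)
  decode_weight <- function(pruefer) {
    degree <- rep(1L, n)
    for (v in pruefer) degree[v] <- degree[v] + 1L
    w <- 0
    for (v in pruefer) {
      leaf <- which(degree == 1L)[1L]
      w <- w + d[leaf, v]
      degree[leaf] <- 0L
      degree[v] <- degree[v] - 1L
    }
    last <- which(degree == 1L)
    w + d[last[1L], last[2L]]
  }
  seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2L)))
  min(apply(seqs, 1L, decode_weight))
}

# Dense mixed-model equations with a single fixed mean, additive + boar +
# permanent-environment blocks, built with base matrices and solve().
dense_mme_oracle <- function(phen, ped, vc) {
  ped <- as_pedigree(ped)
  A <- numerator_relationship_matrix(ped)
  n_a <- nrow(ped); N <- nrow(phen)
  X <- matrix(1, N, 1)
  Zu <- matrix(0, N, n_a); Zm <- matrix(0, N, n_a)
  sows <- sort(unique(as.character(phen$sow)))
  Zp <- matrix(0, N, length(sows))
  for (i in seq_len(N)) {
    Zu[i, match(phen$sow[i], ped$id)] <- 1
    Zm[i, match(phen$boar[i], ped$id)] <- 1
    Zp[i, match(phen$sow[i], sows)] <- 1
  }
  W <- cbind(X, Zu, Zm, Zp)
  C <- crossprod(W)
  Ai <- solve(A)
  iu <- 1 + seq_len(n_a)
  im <- 1 + n_a + seq_len(n_a)
  ip <- 1 + 2 * n_a + seq_along(sows)
  C[iu, iu] <- C[iu, iu] + Ai * vc$sigma_e2 / vc$sigma_u2
  C[im, im] <- C[im, im] + Ai * vc$sigma_e2 / vc$sigma_m2
  C[ip, ip] <- C[ip, ip] + diag(length(sows)) * vc$sigma_e2 / vc$sigma_p2
  sol <- solve(C, crossprod(W, phen$tnb))
  list(beta = sol[1], ebv = setNames(sol[iu], ped$id),
       boar = setNames(sol[im], ped$id), pe = setNames(sol[ip], sows))
}
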