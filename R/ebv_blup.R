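#' Normalize and topologically sort a pedigree
#'
#' Accepts a data.frame with columns `id`, `sire`, `dam`; unknown parents
#' coded `NA`, `0` or `""`. Parents referenced but absent as records are
#' added as founders. Records are re-ordered so parents precede offspring;
#' a cycle raises an error naming the animals involved.
#'
#' @param ped data.frame (`id`, `sire`, `dam`).
#' @return a `pedigree` data.frame (`id`, `sire`, `dam`, character ids,
#'   `NA` unknown), topologically sorted.
#' @export
as_pedigree <- function(ped) {
  clean <- function(x) {
    x <- as.character(x)
    x[x %in% c("0", "", "NA")] <- NA
    x
  }
  id <- clean(ped$id); sire <- clean(ped$sire); dam <- clean(ped$dam)
  if (anyNA(id)) stop("missing individual id in pedigree")
  if (anyDuplicated(id)) stop("duplicate individual ids in pedigree")
  parents <- setdiff(stats::na.omit(c(sire, dam)), id)
  id <- c(parents, id)
  sire <- c(rep(NA_character_, length(parents)), sire)
  dam <- c(rep(NA_character_, length(parents)), dam)
  if (any(!is.na(sire) & sire == id) || any(!is.na(dam) & dam == id))
    stop("cycle detected: individual is its own parent")
  n <- length(id)
  si <- match(sire, id); di <- match(dam, id)
  # Kahn topological sort
  indeg <- integer(n)
  kids <- vector("list", n)
  for (j in seq_len(n)) for (p in c(si[j], di[j])) if (!is.na(p)) {
    indeg[j] <- indeg[j] + 1L
    kids[[p]] <- c(kids[[p]], j)
  }
  queue <- which(indeg == 0L)
  ord <- integer(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    ord <- c(ord, v)
    for (k in kids[[v]]) {
      indeg[k] <- indeg[k] - 1L
      if (indeg[k] == 0L) queue <- c(queue, k)
    }
  }
  if (length(ord) < n)
    stop("pedigree cycle involving: ",
         paste(id[setdiff(seq_len(n), ord)], collapse = ", "))
  out <- data.frame(id = id[ord], sire = sire[ord], dam = dam[ord])
  class(out) <- c("pedigree", "data.frame")
  out
}

#' Numerator relationship matrix (tabular method)
#'
#' `a_ij = 0.5 (a_is + a_id)` for j newer with parents (s, d), unknown
#' parents contributing 0; `a_jj = 1 + 0.5 a_sd`. Dense; adequate for the
#' pedigree sizes this package targets.
#'
#' @param ped a pedigree (passed through [as_pedigree()]).
#' @return symmetric matrix `A` with dimnames = ids, diagonal >= 1.
#' @export
numerator_relationship_matrix <- function(ped) {
  ped <- as_pedigree(ped)
  n <- nrow(ped)
  si <- match(ped$sire, ped$id); di <- match(ped$dam, ped$id)
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (j in seq_len(n)) {
    s <- si[j]; d <- di[j]
    if (j > 1L) {
      older <- seq_len(j - 1L)
      as_ <- if (!is.na(s)) A[older, s] else 0
      ad_ <- if (!is.na(d)) A[older, d] else 0
      aj <- 0.5 * (as_ + ad_)
      A[older, j] <- aj
      A[j, older] <- aj
    }
    A[j, j] <- 1 + if (!is.na(s) && !is.na(d)) 0.5 * A[s, d] else 0
  }
  A
}

#' Sparse inverse of the numerator relationship matrix
#'
#' Henderson's rules with Quaas' inbreeding adjustment: for each animal j
#' with Mendelian-sampling variance
#' `d_j = 0.5 - 0.25 (F_s + F_d)` (both parents known; `0.75 - 0.25 F_p` for
#' one, `1` for none), add `1/d_j` patterns over (j, s, d). Inbreeding
#' coefficients come from the tabular diagonal.
#'
#' @param ped a pedigree.
#' @return sparse `Matrix::dsCMatrix` A-inverse with dimnames = ids.
#' @export
a_inverse <- function(ped) {
  ped <- as_pedigree(ped)
  n <- nrow(ped)
  si <- match(ped$sire, ped$id); di <- match(ped$dam, ped$id)
  Fcoef <- diag(numerator_relationship_matrix(ped)) - 1
  ii <- jj <- integer(0); xx <- numeric(0)
  add <- function(i, j, x) {
    ii <<- c(ii, i); jj <<- c(jj, j); xx <<- c(xx, x)
  }
  for (j in seq_len(n)) {
    s <- si[j]; d <- di[j]
    dj <- if (!is.na(s) && !is.na(d)) 0.5 - 0.25 * (Fcoef[s] + Fcoef[d])
          else if (!is.na(s)) 0.75 - 0.25 * Fcoef[s]
          else if (!is.na(d)) 0.75 - 0.25 * Fcoef[d]
          else 1
    w <- 1 / dj
    add(j, j, w)
    for (p in c(s, d)) if (!is.na(p)) {
      add(p, j, -0.5 * w); add(j, p, -0.5 * w)
      add(p, p, 0.25 * w)
    }
    if (!is.na(s) && !is.na(d)) {
      add(s, d, 0.25 * w); add(d, s, 0.25 * w)
    }
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                       dimnames = list(ped$id, ped$id))
}

#' Variance components for the repeated-records animal model
#'
#' @param sigma_u2 additive genetic variance (A-structured sow effect).
#' @param sigma_m2 mating-boar variance (A-structured).
#' @param sigma_p2 permanent-environment variance (identity-structured).
#' @param sigma_e2 residual variance (> 0).
#' @return a `variance_components` list.
#' @export
variance_components <- function(sigma_u2 = 1, sigma_m2 = 0.3,
                                sigma_p2 = 0.5, sigma_e2 = 8) {
  stopifnot(sigma_u2 >= 0, sigma_m2 >= 0, sigma_p2 >= 0, sigma_e2 > 0)
  structure(list(sigma_u2 = sigma_u2, sigma_m2 = sigma_m2,
                 sigma_p2 = sigma_p2, sigma_e2 = sigma_e2),
            class = "variance_components")
}

#' Solve Henderson's mixed-model equations for the litter-size animal model
#'
#' Model: `y = Xb + Z_u u + Z_m m + Z_p p + e` with fixed parity and
#' year-season effects (first level of each factor dropped), additive sow
#' effect `u ~ N(0, A sigma_u2)` and mating-boar effect `m ~ N(0, A sigma_m2)`
#' over all pedigree animals, permanent environment `p ~ N(0, I sigma_p2)`
#' over sows with records, residual `e ~ N(0, I sigma_e2)`. Zero-variance
#' components drop their block with a warning. Boars absent from the
#' pedigree are added as phantom founders.
#'
#' @param phen data.frame (`sow`, `parity`, `yearseason`, `boar`, `tnb`).
#' @param ped pedigree data.frame.
#' @param vc a [variance_components()].
#' @return list: `beta` (named fixed-effect solutions), `ebv` (named vector
#'   over all pedigree animals — the TNB_EBV table), `boar` (named), `pe`
#'   (named), `pedigree` (the sorted pedigree used).
#' @export
solve_mme <- function(phen, ped, vc) {
  need <- c("sow", "parity", "yearseason", "boar", "tnb")
  if (!all(need %in% names(phen))) stop("phenotype table must have columns ",
                                        paste(need, collapse = ", "))
  extra <- setdiff(unique(as.character(phen$boar)), as.character(ped$id))
  if (length(extra))
    ped <- rbind(ped[, c("id", "sire", "dam")],
                 data.frame(id = extra, sire = NA, dam = NA))
  ped <- as_pedigree(ped)
  if (any(!phen$sow %in% ped$id)) stop("phenotyped sow missing from pedigree")
  n_a <- nrow(ped)
  N <- nrow(phen)
  y <- phen$tnb
  # fixed effects: intercept + treatment-coded parity and year-season
  fpar <- factor(phen$parity)
  fys <- factor(phen$yearseason)
  terms <- c(if (nlevels(fpar) > 1L) "fpar", if (nlevels(fys) > 1L) "fys")
  fml <- stats::reformulate(if (length(terms)) terms else "1")
  X <- Matrix::sparse.model.matrix(fml, data.frame(fpar = fpar, fys = fys))
  colnames(X) <- sub("^f", "", colnames(X))
  use_u <- vc$sigma_u2 > 0
  use_m <- vc$sigma_m2 > 0
  use_p <- vc$sigma_p2 > 0
  if (!use_u) warning("sigma_u2 = 0: additive block dropped; no EBVs")
  if (!use_m) warning("sigma_m2 = 0: boar block dropped")
  if (!use_p) warning("sigma_p2 = 0: permanent-environment block dropped")
  inc <- function(ids) Matrix::sparseMatrix(
    i = seq_len(N), j = match(as.character(ids), ped$id),
    x = 1, dims = c(N, n_a))
  Zu <- inc(phen$sow)
  Zm <- inc(phen$boar)
  sows <- sort(unique(as.character(phen$sow)))
  Zp <- Matrix::sparseMatrix(i = seq_len(N),
                             j = match(as.character(phen$sow), sows),
                             x = 1, dims = c(N, length(sows)))
  Ainv <- if (use_u || use_m) a_inverse(ped) else NULL
  blocks <- list(list(Z = X, G = NULL))
  if (use_u) blocks <- c(blocks, list(list(Z = Zu,
                                           G = Ainv * (vc$sigma_e2 / vc$sigma_u2))))
  if (use_m) blocks <- c(blocks, list(list(Z = Zm,
                                           G = Ainv * (vc$sigma_e2 / vc$sigma_m2))))
  if (use_p) blocks <- c(blocks, list(list(Z = Zp,
                                           G = Matrix::Diagonal(length(sows)) *
                                             (vc$sigma_e2 / vc$sigma_p2))))
  W <- do.call(cbind, lapply(blocks, `[[`, "Z"))
  C <- Matrix::crossprod(W)
  off <- 0L
  for (b in blocks) {
    k <- ncol(b$Z)
    if (!is.null(b$G)) {
      idx <- off + seq_len(k)
      C[idx, idx] <- C[idx, idx] + b$G
    }
    off <- off + k
  }
  rhs <- Matrix::crossprod(W, y)
  sol <- tryCatch(as.numeric(Matrix::solve(C, rhs)),
                  error = function(e) stop("singular mixed-model equations (",
                                           conditionMessage(e),
                                           "); check fixed-effect constraints"))
  off <- ncol(X)
  beta <- stats::setNames(sol[seq_len(off)], colnames(X))
  ebv <- stats::setNames(rep(0, n_a), ped$id)
  boar <- NULL; pe <- NULL
  if (use_u) { ebv <- stats::setNames(sol[off + seq_len(n_a)], ped$id); off <- off + n_a }
  if (use_m) { boar <- stats::setNames(sol[off + seq_len(n_a)], ped$id); off <- off + n_a }
  if (use_p) { pe <- stats::setNames(sol[off + seq_len(length(sows))], sows) }
  list(beta = beta, ebv = ebv, boar = boar, pe = pe, pedigree = ped)
}
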