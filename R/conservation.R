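# Moiety-conservation analysis: integer basis of the left null space of the
# stoichiometric matrix, computed by exact (fraction-free) elimination so
# that the answer never depends on floating-point pivoting.

# Integer row echelon form by fraction-free elimination.  Entries must be
# (and stay) exactly representable integers; rows are reduced by their gcd
# after every combination step to keep magnitudes small.
int_row_echelon <- function(M) {
  M <- round(M)
  nr <- nrow(M); nc <- ncol(M)
  pivots <- integer(0)
  row <- 1L
  for (col in seq_len(nc)) {
    if (row > nr) break
    sub <- which(M[row:nr, col] != 0) + row - 1L
    if (!length(sub)) next
    # deterministic pivot: smallest absolute value, then lowest row index
    piv <- sub[order(abs(M[sub, col]), sub)][1]
    if (piv != row) M[c(row, piv), ] <- M[c(piv, row), ]
    for (i in seq_len(nr)[-seq_len(row)]) {
      if (M[i, col] == 0) next
      M[i, ] <- M[row, col] * M[i, ] - M[i, col] * M[row, ]
      g <- vec_gcd(M[i, ])
      if (g > 1) M[i, ] <- M[i, ] / g
      if (max(abs(M[i, ])) > 2^50) {
        stop_numerical("integer elimination overflow; stoichiometry too large")
      }
    }
    g <- vec_gcd(M[row, ])
    if (g > 1) M[row, ] <- M[row, ] / g
    pivots <- c(pivots, col)
    row <- row + 1L
  }
  list(M = M, pivots = pivots)
}

# Exact rational back-substitution for one kernel vector of an echelon
# matrix: free column `f` set to 1, other free columns 0.  Fractions are
# carried as numerator/denominator pairs and cleared at the end, returning
# a primitive integer vector.
kernel_vector <- function(ech, f) {
  M <- ech$M; pivots <- ech$pivots
  nc <- ncol(M)
  num <- numeric(nc); den <- rep(1, nc)
  num[f] <- 1
  for (r in rev(seq_along(pivots))) {
    p <- pivots[r]
    # a_rp x_p = - sum_{c > p} a_rc x_c
    sn <- 0; sd <- 1
    for (c in seq_len(nc)[-seq_len(p)]) {
      if (M[r, c] == 0 || num[c] == 0) next
      tn <- M[r, c] * num[c]; td <- den[c]
      sn <- sn * td + tn * sd
      sd <- sd * td
      g <- vec_gcd(c(sn, sd)); sn <- sn / g; sd <- sd / g
    }
    num[p] <- -sn
    den[p] <- sd * M[r, p]
    g <- vec_gcd(c(num[p], den[p])); num[p] <- num[p] / g; den[p] <- den[p] / g
  }
  scale <- Reduce(function(a, b) a * b / vec_gcd(c(a, b)), den)  # lcm
  v <- num * (scale / den)
  g <- vec_gcd(v)
  v <- v / max(g, 1)
  if (sum(v < 0) > sum(v > 0)) v <- -v
  round(v)
}

# Integer basis of {v : v %*% S == 0}.
left_null_basis <- function(S) {
  ech <- int_row_echelon(t(S))
  free_cols <- setdiff(seq_len(ncol(ech$M)), ech$pivots)
  vecs <- lapply(free_cols, kernel_vector, ech = ech)
  basis <- do.call(rbind, c(vecs, list(matrix(0, 0, ncol(ech$M)))))
  colnames(basis) <- rownames(S)
  basis
}

#' Conserved moieties of a network
#'
#' Computes an integer basis of the left null space of the stoichiometric
#' matrix by exact rational elimination, verifies every declared
#' conservation law against it, and reports conserved combinations that the
#' model does not declare (these are auto-named).
#'
#' @param network an `mra_network`.
#' @return list of [conservation_law()] objects spanning the left null
#'   space: the declared laws first, then auto-named completions.  The
#'   auto-named subset is attached as attribute `"undeclared"`.
#' @export
conserved_moieties <- function(network) {
  S <- stoichiometric_matrix(network)
  sp <- rownames(S)
  basis <- left_null_basis(S)
  declared <- network$conservation
  for (law in declared) {
    v <- law_vector(law, sp)
    if (any(abs(v %*% S) > 1e-9)) {
      stop_definition("declared conservation law for '%s' is not conserved", law$total)
    }
  }
  if (nrow(basis) == 0) {
    if (length(declared)) {
      stop_definition("declared conservation laws exist but stoichiometry is full rank")
    }
    return(structure(list(), undeclared = list()))
  }
  laws <- declared
  span <- do.call(rbind, c(lapply(declared, law_vector, sp_names = sp),
                           list(matrix(0, 0, length(sp)))))
  auto <- list()
  k <- 0L
  for (i in seq_len(nrow(basis))) {
    cand <- rbind(span, basis[i, ])
    if (qr(cand)$rank > qr(span)$rank) {
      span <- cand
      k <- k + 1L
      v <- basis[i, ]
      name <- auto_total_name(network, v, k)
      auto <- c(auto, list(structure(list(coef = v[v != 0], total = name),
                                     class = "retromra_conservation_law")))
    }
  }
  structure(c(laws, auto), undeclared = auto)
}

# Name an undeclared conserved total from module hints when every carrying
# species shares one, else fall back to a positional name.
auto_total_name <- function(network, v, k) {
  hints <- vapply(network$species, function(s) s$module %||% NA_character_, "")
  names(hints) <- species_names(network)
  mods <- unique(hints[names(v)[v != 0]])
  if (length(mods) == 1 && !is.na(mods)) paste0(mods, "_tot") else paste0("conserved_", k)
}
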