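#' Evaluate a univariate Legendre polynomial
#'
#' Standard (unnormalized) Legendre polynomials on `[-1, 1]`, the orthogonal
#' family under the uniform measure: `P_0(x) = 1`, `P_1(x) = x`,
#' `P_2(x) = (3 x^2 - 1) / 2`, and so on via the three-term recurrence
#' `(l + 1) P_{l+1}(x) = (2 l + 1) x P_l(x) - l P_{l-1}(x)`.
#'
#' @param degree Non-negative integer degree.
#' @param x Numeric vector of evaluation points in `[-1, 1]`.
#' @return Numeric vector, `P_degree(x)`.
#' @examples
#' legendre_poly(2, 0.5) # (3 * 0.25 - 1) / 2 = -0.125
#' @export
legendre_poly <- function(degree, x) {
  degree <- check_count(degree, "degree")
  stopifnot(is.numeric(x))
  if (any(abs(x) > 1 + 1e-12, na.rm = TRUE)) {
    rlang::abort("`x` must lie in [-1, 1].")
  }
  if (degree == 0L) return(rep(1, length(x)))
  if (degree == 1L) return(as.numeric(x))
  p_prev <- rep(1, length(x))
  p_cur <- as.numeric(x)
  for (l in 1:(degree - 1L)) {
    p_next <- ((2 * l + 1) * x * p_cur - l * p_prev) / (l + 1)
    p_prev <- p_cur
    p_cur <- p_next
  }
  p_cur
}

# Monomial coefficients of P_degree (constant term first); exact recurrence
# in double precision, used by the closed-form inner-product path.
legendre_coefs <- function(degree) {
  if (degree == 0L) return(1)
  if (degree == 1L) return(c(0, 1))
  pad <- function(v, n) c(v, numeric(n - length(v)))
  c_prev <- 1
  c_cur <- c(0, 1)
  for (l in 1:(degree - 1L)) {
    c_next <- ((2 * l + 1) * c(0, c_cur) - l * pad(c_prev, l + 2)) / (l + 1)
    c_prev <- c_cur
    c_cur <- c_next
  }
  c_cur
}

check_count <- function(x, name, min = 0L) {
  if (length(x) != 1L || !is.numeric(x) || is.na(x) || x != as.integer(x) || x < min) {
    rlang::abort(sprintf("`%s` must be a single integer >= %d.", name, min))
  }
  as.integer(x)
}

#' Truncated multivariate Legendre chaos basis
#'
#' Enumerates all multi-indices of total degree at most `order` over `n_dims`
#' germ dimensions. Each multi-index `l = (l_1, ..., l_n)` labels the basis
#' function `Psi(xi) = prod_d P_{l_d}(xi_d)`; the truncation keeps
#' `(n_dims + order)! / (n_dims! order!)` functions.
#'
#' The ordering is canonical: position 0 is the constant function; degree-1
#' functions follow in dimension order; within each higher total-degree block,
#' functions involving fewer dimensions come first (so the pure `xi_d^2`
#' terms precede the `xi_i xi_j` cross terms), ties broken by dimension
#' order. With `n_dims = 4`, `order = 2` this places the `xi_1^2` function at
#' position 5, the layout assumed by the two-term Sobol gather.
#'
#' @param n_dims Number of germ dimensions (independent Uniform`[-1,1]`
#'   random variables), at least 1.
#' @param order Maximum total polynomial degree, at least 0.
#' @return An object of class `pc_basis`: a list with `n_dims`, `order`,
#'   `indices` (one row per basis function), and `norms_sq`, the squared
#'   norms `<Psi_i, Psi_i> = prod_d 1 / (2 l_{i,d} + 1)` under the uniform
#'   product measure.
#' @examples
#' b <- pc_basis(4, 2)
#' nrow(b$indices) # 15
#' @export
pc_basis <- function(n_dims, order) {
  n_dims <- check_count(n_dims, "n_dims", min = 1L)
  order <- check_count(order, "order", min = 0L)
  grid <- as.matrix(expand.grid(rep(list(0:order), n_dims)))
  dimnames(grid) <- NULL
  deg <- rowSums(grid)
  idx <- grid[deg <= order, , drop = FALSE]
  deg <- rowSums(idx)
  active <- rowSums(idx > 0)
  keys <- c(list(deg, active), lapply(seq_len(n_dims), function(d) -idx[, d]))
  idx <- idx[do.call(base::order, keys), , drop = FALSE]
  storage.mode(idx) <- "integer"
  structure(
    list(
      n_dims = n_dims,
      order = order,
      indices = idx,
      norms_sq = apply(1 / (2 * idx + 1), 1, prod)
    ),
    class = "pc_basis"
  )
}

#' @export
print.pc_basis <- function(x, ...) {
  cat(sprintf(
    "<pc_basis> %d Legendre chaos functions (n_dims = %d, order = %d)\n",
    nrow(x$indices), x$n_dims, x$order
  ))
  invisible(x)
}

#' @export
format.pc_basis <- function(x, ...) {
  sprintf("pc_basis(n_dims = %d, order = %d)", x$n_dims, x$order)
}

#' Evaluate one multivariate basis function
#'
#' @param basis A [pc_basis()].
#' @param i Basis function position, 1-based (position 1 is the constant).
#' @param point Numeric vector of length `basis$n_dims` with entries in
#'   `[-1, 1]`; or a matrix with that many columns for several points.
#' @return Numeric vector of basis-function values.
#' @export
eval_basis_function <- function(basis, i, point) {
  stopifnot(inherits(basis, "pc_basis"))
  i <- check_count(i, "i", min = 1L)
  if (i > nrow(basis$indices)) {
    rlang::abort(sprintf("`i` exceeds the basis size (%d).", nrow(basis$indices)))
  }
  if (is.null(dim(point))) point <- matrix(point, nrow = 1)
  if (ncol(point) != basis$n_dims) {
    rlang::abort(sprintf("`point` must have %d entries per row.", basis$n_dims))
  }
  out <- rep(1, nrow(point))
  degs <- basis$indices[i, ]
  for (d in which(degs > 0L)) {
    out <- out * legendre_poly(degs[d], point[, d])
  }
  out
}

# Evaluate the whole basis at a matrix of germ points: returns
# n_points x n_basis matrix. Shared by the chaos-vs-sampling checks.
eval_basis_matrix <- function(basis, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = basis$n_dims)
  P <- nrow(basis$indices)
  uni <- lapply(seq_len(basis$n_dims), function(d) {
    vapply(0:basis$order, function(l) legendre_poly(l, points[, d]),
           numeric(nrow(points)))
  })
  out <- matrix(1, nrow(points), P)
  for (i in seq_len(P)) {
    for (d in which(basis$indices[i, ] > 0L)) {
      out[, i] <- out[, i] * uni[[d]][, basis$indices[i, d] + 1L]
    }
  }
  out
}

# Univariate moment tables E[P_a P_b (P_c (P_d))] under density 1/2 on [-1,1].
# Quadrature path: Gauss-Legendre, degree-exact for 4-way products.
univariate_moment_tables <- function(order, method = c("quadrature", "exact")) {
  method <- match.arg(method)
  q <- order + 1L
  if (method == "quadrature") {
    n_nodes <- ceiling((4 * order + 1) / 2) + 1
    gl <- pracma::gaussLegendre(max(n_nodes, 2), -1, 1)
    w <- gl$w / 2
    V <- vapply(0:order, function(l) legendre_poly(l, gl$x), numeric(length(gl$x)))
    M2 <- crossprod(V, w * V)
    M3 <- array(0, dim = c(q, q, q))
    M4 <- array(0, dim = c(q, q, q, q))
    for (a in 1:q) {
      for (b in 1:q) {
        vab <- V[, a] * V[, b]
        M3[a, b, ] <- crossprod(V, w * vab)
        for (cc in 1:q) {
          M4[a, b, cc, ] <- crossprod(V, w * vab * V[, cc])
        }
      }
    }
  } else {
    # closed form: convolve monomial coefficients, then exact monomial
    # moments E[x^k] = 1/(k+1) for even k, 0 for odd k
    coefs <- lapply(0:order, legendre_coefs)
    mono_moment <- function(cf) {
      k <- seq_along(cf) - 1
      sum(cf[k %% 2 == 0] / (k[k %% 2 == 0] + 1))
    }
    conv <- function(a, b) {
      out <- numeric(length(a) + length(b) - 1)
      for (i in seq_along(a)) {
        out[i:(i + length(b) - 1)] <- out[i:(i + length(b) - 1)] + a[i] * b
      }
      out
    }
    M2 <- matrix(0, q, q)
    M3 <- array(0, dim = c(q, q, q))
    M4 <- array(0, dim = c(q, q, q, q))
    for (a in 1:q) {
      for (b in 1:q) {
        cab <- conv(coefs[[a]], coefs[[b]])
        M2[a, b] <- mono_moment(cab)
        for (cc in 1:q) {
          cabc <- conv(cab, coefs[[cc]])
          M3[a, b, cc] <- mono_moment(cabc)
          for (d in 1:q) {
            M4[a, b, cc, d] <- mono_moment(conv(cabc, coefs[[d]]))
          }
        }
      }
    }
  }
  # canonicalize: every entry equals the one at its sorted degree tuple, so
  # permutation symmetry holds bit-for-bit in the assembled tensors
  g3 <- as.matrix(expand.grid(a = 1:q, b = 1:q, c = 1:q))
  M3[g3] <- M3[t(apply(g3, 1, sort))]
  g4 <- as.matrix(expand.grid(a = 1:q, b = 1:q, c = 1:q, d = 1:q))
  M4[g4] <- M4[t(apply(g4, 1, sort))]
  M2[lower.tri(M2)] <- t(M2)[lower.tri(M2)]
  list(M2 = M2, M3 = M3, M4 = M4)
}

#' Inner-product tensors of a Legendre chaos basis
#'
#' Builds the 2-, 3-, and 4-way inner products of basis functions under the
#' uniform product measure on `[-1, 1]^n`:
#' `E2[i] = <Psi_i, Psi_i>`, `E3[i, j, L] = <Psi_i Psi_j, Psi_L>`, and
#' `E4[i, j, k, L] = <Psi_i Psi_j Psi_k, Psi_L>`. These are the only
#' integrals the Galerkin projection needs. By the tensor-product structure
#' each entry is a product over dimensions of univariate moments
#' `E[P_a P_b ...]`, computed either by Gauss-Legendre quadrature
#' (degree-exact with margin; the default) or from exact monomial moments of
#' the Legendre coefficient expansion (`method = "exact"`). Entries with
#' magnitude below `1e-14` are zeroed to stabilize downstream sums.
#'
#' @param basis A [pc_basis()].
#' @param method Univariate integration path, `"quadrature"` or `"exact"`.
#' @return A list of class `pc_tensors` with elements `E2` (vector), `E3`
#'   (3-d array) and `E4` (4-d array), all indexed by basis position.
#' @export
inner_product_tensors <- function(basis, method = c("quadrature", "exact")) {
  stopifnot(inherits(basis, "pc_basis"))
  method <- match.arg(method)
  mt <- univariate_moment_tables(basis$order, method)
  idx <- basis$indices
  P <- nrow(idx)
  E3 <- array(1, dim = c(P, P, P))
  E4 <- array(1, dim = c(P, P, P, P))
  i3 <- slice.index(E3, 1); j3 <- slice.index(E3, 2); L3 <- slice.index(E3, 3)
  i4 <- slice.index(E4, 1); j4 <- slice.index(E4, 2)
  k4 <- slice.index(E4, 3); L4 <- slice.index(E4, 4)
  for (d in seq_len(basis$n_dims)) {
    dd <- idx[, d] + 1L
    E3 <- E3 * mt$M3[cbind(dd[i3], dd[j3], dd[L3])]
    E4 <- E4 * mt$M4[cbind(dd[i4], dd[j4], dd[k4], dd[L4])]
  }
  E3[abs(E3) < 1e-14] <- 0
  E4[abs(E4) < 1e-14] <- 0
  E2 <- vapply(seq_len(P), function(i) prod(mt$M2[cbind(idx[i, ] + 1L, idx[i, ] + 1L)]),
               numeric(1))
  structure(list(E2 = E2, E3 = E3, E4 = E4, order = basis$order,
                 n_dims = basis$n_dims),
            class = "pc_tensors")
}

#' @export
print.pc_tensors <- function(x, ...) {
  cat(sprintf(
    "<pc_tensors> inner products for %d basis functions (E4 holds %d entries)\n",
    length(x$E2), length(x$E4)
  ))
  invisible(x)
}
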