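test_that("univariate Legendre polynomials match their closed forms", {
  x <- seq(-1, 1, by = 0.25)
  expect_equal(legendre_poly(0, x), rep(1, length(x)))
  expect_equal(legendre_poly(1, 0.5), 0.5)
  expect_equal(legendre_poly(2, 0.5), -0.125)
  expect_equal(legendre_poly(2, x), (3 * x^2 - 1) / 2)
  expect_equal(legendre_poly(3, x), (5 * x^3 - 3 * x) / 2)
  # all Legendre polynomials equal 1 at x = 1
  for (l in 0:6) expect_equal(legendre_poly(l, 1), 1)
  expect_error(legendre_poly(-1, 0))
  expect_error(legendre_poly(2, 1.5), "\\[-1, 1\\]")
})

test_that("basis size matches the binomial count and exhaustive enumeration", {
  expect_equal(nrow(pc_basis(4, 2)$indices), 15)
  expect_equal(nrow(pc_basis(1, 0)$indices), 1)
  expect_equal(nrow(pc_basis(3, 2)$indices), 10)
  for (n in 1:6) {
    for (p in 0:4) {
      b <- pc_basis(n, p)
      # independent enumeration of degree tuples
      count <- sum(rowSums(as.matrix(expand.grid(rep(list(0:p), n)))) <= p)
      expect_equal(nrow(b$indices), count)
      expect_equal(nrow(b$indices), choose(n + p, p))
      expect_false(anyDuplicated(b$indices) > 0)
      expect_true(all(rowSums(b$indices) <= p))
    }
  }
})

test_that("basis ordering is canonical and norms follow 1/(2l+1) products", {
  b <- pc_basis(4, 2)
  expect_equal(b$indices[1, ], rep(0L, 4)) # constant first
  expect_equal(b$indices[2:5, ], diag(4L)[, 1:4] * 1L, ignore_attr = TRUE)
  expect_equal(b$indices[6, ], c(2L, 0L, 0L, 0L)) # xi_1^2 at position 6 (index 5)
  expect_equal(b$indices[10, ], c(1L, 1L, 0L, 0L)) # first cross term
  expect_equal(b$norms_sq[1], 1)
  expect_equal(b$norms_sq[2], 1 / 3)
  expect_equal(b$norms_sq[6], 1 / 5)
  expect_equal(b$norms_sq[10], 1 / 9)
  expect_equal(b$norms_sq,
               apply(1 / (2 * b$indices + 1), 1, prod))
  expect_error(pc_basis(0, 2))
  expect_error(pc_basis(2.5, 2))
})

test_that("multivariate basis functions evaluate as products of Legendre polys", {
  b <- pc_basis(4, 2)
  pt <- c(0.5, 0.2, 0.9, -1)
  expect_equal(eval_basis_function(b, 1, pt), 1)
  i_cross <- which(apply(b$indices, 1, function(r) all(r == c(1, 1, 0, 0))))
  expect_equal(eval_basis_function(b, i_cross, pt), 0.5 * 0.2)
  i_sq <- which(apply(b$indices, 1, function(r) all(r == c(2, 0, 0, 0))))
  expect_equal(eval_basis_function(b, i_sq, c(1, 0, 0, 0)), 1)
  expect_error(eval_basis_function(b, 16, pt), "basis size")
  expect_error(eval_basis_function(b, 2, c(0, 0)), "entries")
})

test_that("univariate moments match frozen quadrature-oracle values", {
  mt <- epichaos:::univariate_moment_tables(2)
  expect_equal(mt$M2[1, 1], 1) # E[1] under density 1/2
  expect_equal(mt$M2[2, 2], 1 / 3) # E[P1 P1]
  expect_equal(mt$M3[2, 2, 3], 2 / 15) # E[P1 P1 P2] = 3/10 - 1/6
  # independent high-resolution quadrature agrees
  expect_equal(uni_moment_quad(c(1, 1)), 1 / 3, tolerance = 1e-13)
  expect_equal(uni_moment_quad(c(1, 1, 2)), 2 / 15, tolerance = 1e-13)
  expect_equal(uni_moment_quad(c(2, 2, 2)), mt$M3[3, 3, 3], tolerance = 1e-13)
})

test_that("quadrature and closed-form tensor paths agree to 1e-12", {
  for (n in c(2, 4)) {
    for (p in c(2, 3)) {
      b <- pc_basis(n, p)
      tq <- inner_product_tensors(b, method = "quadrature")
      te <- inner_product_tensors(b, method = "exact")
      expect_lt(max(abs(tq$E2 - te$E2)), 1e-12)
      expect_lt(max(abs(tq$E3 - te$E3)), 1e-12)
      expect_lt(max(abs(tq$E4 - te$E4)), 1e-12)
    }
  }
})

test_that("inner-product tensors satisfy orthogonality and symmetry", {
  b <- pc_basis(4, 2)
  tn <- inner_product_tensors(b)
  P <- length(tn$E2)
  expect_equal(tn$E2[1], 1) # constant function has unit norm
  expect_equal(tn$E2, b$norms_sq, tolerance = 1e-14)
  # orthogonality: <Psi_j, Psi_L> = E3 contracted with the constant
  for (j in seq_len(P)) {
    for (L in seq_len(P)) {
      expect_equal(tn$E3[1, j, L], if (j == L) tn$E2[j] else 0,
                   tolerance = 1e-12)
      # E3[i, j, 1] reduces to the 2-way inner product
      expect_equal(tn$E3[j, L, 1], if (j == L) tn$E2[j] else 0,
                   tolerance = 1e-12)
    }
  }
  # full permutation symmetry, exact as stored
  expect_identical(tn$E3, aperm(tn$E3, c(2, 1, 3)))
  expect_identical(tn$E3, aperm(tn$E3, c(3, 2, 1)))
  expect_identical(tn$E4, aperm(tn$E4, c(2, 1, 3, 4)))
  expect_identical(tn$E4, aperm(tn$E4, c(1, 2, 4, 3)))
  expect_identical(tn$E4, aperm(tn$E4, c(4, 3, 2, 1)))
  # contracting E4 with the constant reduces to E3
  expect_equal(tn$E4[1, , , ], tn$E3, tolerance = 1e-13)
})

test_that("tidy() lays the basis out one row per function", {
  b <- pc_basis(3, 2)
  td <- tidy(b)
  expect_equal(nrow(td), 10)
  expect_equal(td$total_degree, rowSums(b$indices))
  expect_equal(td$norm_sq, b$norms_sq)
})
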