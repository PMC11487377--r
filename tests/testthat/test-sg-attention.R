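test_that("group reshape folds layers into channels bijectively", {
  set.seed(1)
  x <- array(rnorm(1 * 4 * 2 * 3 * 3), c(1, 4, 2, 3, 3))
  g <- groupReshape(x, 2)
  expect_equal(dim(g), c(1, 2, 4, 3, 3))
  expect_identical(groupUnreshape(g, 2, C = 2, L = 4), x)
  # channel blocks are contiguous per folded layer: block j holds layer j
  expect_equal(g[1, 1, 1:2, , ], x[1, 1, 1:2, , ])
  expect_equal(g[1, 1, 3:4, , ], x[1, 2, 1:2, , ])

  expect_identical(groupReshape(x, 1), x)

  # indivisible L: padded by repeating the final layer
  x5 <- array(rnorm(1 * 5 * 2 * 2 * 2), c(1, 5, 2, 2, 2))
  g5 <- groupReshape(x5, 2)
  expect_equal(dim(g5), c(1, 3, 4, 2, 2))
  expect_equal(g5[1, 3, 3:4, , ], x5[1, 5, 1:2, , ])  # padded slot = layer 5
  expect_identical(groupUnreshape(g5, 2, C = 2, L = 5), x5)
})

test_that("directional attention factorizes rank-1 and sits in (0,1)", {
  set.seed(2)
  withSubstream(1, "w", p <- initGroupModule(2L, 2L))
  cg <- array(rnorm(2 * 2 * 4 * 3 * 5), c(2, 2, 4, 3, 5))
  att <- directionalAttention(cg, p)
  expect_true(all(att$AH > 0 & att$AH < 1))
  expect_true(all(att$AW > 0 & att$AW < 1))
  for (b in 1:2) for (g in 1:2) for (c in 1:4)
    expect_equal(att$Aprime[b, g, c, , ],
                 outer(att$AH[b, g, c, ], att$AW[b, g, c, ]),
                 tolerance = 1e-12)

  # zero weights: sigmoid(0) = 0.5 everywhere, product 0.25
  p0 <- initGroupModule(2L, 2L)
  for (q in list(p0$W1, p0$b1)) q$value[] <- 0
  att0 <- directionalAttention(cg, p0)
  expect_true(all(att0$AH == 0.5))
  expect_true(all(att0$Aprime == 0.25))
})

test_that("group module matches the nested-loop oracle and its zero-weight closed form", {
  set.seed(3)
  for (n in c(1L, 2L)) {
    p <- initGroupModule(2L, n)
    x <- array(rnorm(2 * 4 * 2 * 2 * 2), c(2, 4, 2, 2, 2))
    expect_equal(groupModule(x, n, p), oracle_group_module(x, p),
                 tolerance = 1e-6)
  }
  # indivisible L goes through the padding policy in both implementations
  p3 <- initGroupModule(2L, 3L)
  x5 <- array(rnorm(1 * 5 * 2 * 2 * 2), c(1, 5, 2, 2, 2))
  expect_equal(groupModule(x5, 3L, p3), oracle_group_module(x5, p3),
               tolerance = 1e-6)

  pz <- initGroupModule(3L, 2L)
  for (q in list(pz$W1, pz$b1, pz$Wg, pz$bg)) q$value[] <- 0
  x <- array(rnorm(2 * 4 * 3 * 4 * 4), c(2, 4, 3, 4, 4))
  expect_equal(groupModule(x, 2L, pz), x / 2, tolerance = 1e-12)
  expect_equal(dim(groupModule(x, 2L, pz)), dim(x))
})

test_that("selective attention matches the oracle, preserves shape and normalizes z", {
  set.seed(4)
  sg <- initSelectiveAttention(2L, c(1L, 2L), reduction = 2L, minWidth = 2L)
  x <- array(rnorm(2 * 4 * 2 * 2 * 2), c(2, 4, 2, 2, 2))
  out <- selectiveAttention(x, params = sg)
  expect_equal(unclass(out), oracle_selective(x, sg), tolerance = 1e-6,
               ignore_attr = TRUE)

  z <- attr(out, "z")
  expect_equal(apply(z, c(1, 2), sum), matrix(1, 2, 2), tolerance = 1e-6)
  expect_true(all(z >= 0))

  # shape preservation across assorted geometries
  for (d in list(c(1, 3, 8, 4, 4), c(2, 7, 8, 5, 3))) {
    xi <- array(rnorm(prod(d)), d)
    oi <- selectiveAttention(xi, c(1L, 2L, 4L),
                             initSelectiveAttention(d[3], c(1L, 2L, 4L)))
    expect_equal(dim(oi), d)
  }
})

test_that("a single branch passes through and tied branches split evenly", {
  set.seed(5)
  sg1 <- initSelectiveAttention(3L, 2L)
  x <- array(rnorm(1 * 4 * 3 * 3 * 3), c(1, 4, 3, 3, 3))
  out1 <- selectiveAttention(x, params = sg1)
  expect_equal(unclass(out1), groupModule(x, 2L, sg1$branches[[1]]),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_true(all(attr(out1, "z") == 1))

  # two branches with identical n and tied parameters: z = 0.5 by symmetry
  sg2 <- initSelectiveAttention(3L, c(2L, 2L))
  for (nm in c("W1", "b1", "Wg", "bg"))
    sg2$branches[[2]][[nm]]$value <- sg2$branches[[1]][[nm]]$value
  sg2$Wfc2[[2]]$value <- sg2$Wfc2[[1]]$value
  sg2$bfc2[[2]]$value <- sg2$bfc2[[1]]$value
  out2 <- selectiveAttention(x, params = sg2)
  expect_equal(as.vector(attr(out2, "z")), rep(0.5, 6), tolerance = 1e-12)

  expect_error(initSelectiveAttention(3L, integer(0)), "non-empty")
})

test_that("attention output is bounded by the branch sum and gates are in (0,1)", {
  set.seed(6)
  sg <- initSelectiveAttention(4L, c(1L, 2L))
  x <- array(rnorm(1 * 4 * 4 * 3 * 3), c(1, 4, 4, 3, 3))
  Fk <- lapply(sg$branches, function(br) groupModule(x, br$n, br))
  out <- selectiveAttention(x, params = sg)
  bound <- Reduce(`+`, lapply(Fk, abs))
  expect_true(all(abs(out) <= bound + 1e-12))
  # each group module shrinks the input (multiplicative sigmoid gate)
  for (Fm in Fk) expect_true(all(abs(Fm) <= abs(x) + 1e-12))
})

test_that("every attention parameter receives gradient on a random batch", {
  ns <- asNamespace("sgknee")
  set.seed(7)
  sg <- initSelectiveAttention(3L, c(1L, 2L, 4L))
  x <- ns$.param(array(rnorm(2 * 5 * 3 * 4 * 4), c(2, 5, 3, 4, 4)))
  params <- ns$.collect_params(sg)
  y <- ns$.td_selective(x, sg)
  loss <- ns$.td_mean_dim(ns$.td_reshape(ns$.td_mul(y, y),
                                         c(length(y$value), 1L)), 1L)
  ns$.td_backward(loss)
  for (p in c(list(x), params)) {
    expect_false(is.null(p$grad))
    expect_gt(max(abs(p$grad)), 0)
  }
})
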