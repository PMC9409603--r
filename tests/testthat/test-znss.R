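make_small <- function() {
  znss(c("y", "n"), c("e1", "e2"),
       list(e1 = list(y = c(0.5, 0.8), n = c(0.5, 0.8)),
            e2 = list(y = c(0.9, 0.9), n = c(0.1, 0.9))))
}

test_that("construction validates labels, columns and value ranges", {
  s <- make_small()
  expect_s3_class(s, "znss")
  expect_identical(present_parameters(s), c("e1", "e2"))
  expect_identical(s$mu["y", "e2"], 0.9)

  expect_error(znss(c("y", "y"), "e1", list()), "duplicate alternative")
  expect_error(znss(c("y", "n"), c("e1", "e1"), list()), "duplicate parameter")
  # nonempty parameters with an empty cell map: every column absent is legal,
  # but a partially filled column is ragged and must name the missing cell
  expect_error(znss(c("y", "n"), "e1", list(e1 = list(y = c(0.5, 0.5)))),
               "ragged column.*'e1'.*'n'")
  expect_error(znss(c("y", "n"), "e1",
                    list(e1 = list(y = c(1.2, 0.5), n = c(0.5, 0.5)))),
               "\\(y, e1\\)")
  expect_error(znss("y", "e1", list(e2 = list(y = c(0.1, 0.1)))),
               "undeclared parameter")
})

test_that("declared-but-absent parameters are carried, not imputed", {
  t1 <- paper_fixture("influenza_model_t1")
  expect_identical(t1$parameters, paste0("e", 1:5))
  expect_identical(present_parameters(t1), c("e1", "e2", "e3", "e5"))
  expect_identical(dim(t1$mu), c(5L, 4L))
  expect_identical(t1$mu["d1", "e1"], 0.2)
})

test_that("set-level complement negates labels and cells and is involutive", {
  t1 <- paper_fixture("influenza_model_t1")
  t2 <- znss_complement(t1)
  expect_identical(present_parameters(t2),
                   c("not e1", "not e2", "not e3", "not e5"))
  expect_true("not e4" %in% t2$parameters)
  expect_true(znss_equal(znss_complement(t2), t1))

  crisp <- znss_grid(matrix(1, 2, 2, dimnames = list(c("a", "b"), c("p", "q"))),
                     matrix(0, 2, 2, dimnames = list(c("a", "b"), c("p", "q"))))
  flipped <- znss_complement(crisp)
  expect_true(all(flipped$mu == 0) && all(flipped$r == 1))
})

test_that("union keeps single-operand columns and combines shared ones", {
  f <- paper_fixture("influenza_model_t1")
  g <- paper_fixture("subset_example_G")
  u <- znss_union(f, g)
  expect_identical(present_parameters(u), paste0("e", 1:5))
  expect_equal(u$mu["d1", "e1"], 0.28)
  expect_equal(u$r["d1", "e1"], 0.7)
  # e4 is absent in the first operand: the second operand's column is copied
  expect_identical(u$mu[, "e4"], g$mu[, "e4"])
  expect_identical(u$r[, "e4"], g$r[, "e4"])
  # e3 present only in the first operand
  expect_identical(u$mu[, "e3"], f$mu[, "e3"])

  s <- make_small()
  expect_znss_close(znss_union(s, s, norm = "minmax"), s, tol = 0)
})

test_that("intersection restricts to shared parameters", {
  f <- paper_fixture("influenza_model_t1")
  g <- paper_fixture("subset_example_G")
  i <- znss_intersection(f, g)
  expect_identical(present_parameters(i), c("e1", "e2"))
  expect_equal(i$mu["d1", "e1"], 0.02)
  expect_equal(i$r["d1", "e1"], 0.2)

  a <- random_znss(3, 2, seed = 1)
  b <- a
  colnames(b$mu) <- colnames(b$r) <- c("p1", "p2")
  b$parameters <- c("p1", "p2")
  empty <- znss_intersection(a, b)
  expect_length(present_parameters(empty), 0)
})

test_that("binary operations reject mismatched universes by name", {
  a <- random_znss(3, 2, seed = 5)
  b <- random_znss(2, 2, seed = 6)
  expect_error(znss_union(a, b), "universes differ.*x3")
  # same labels, different order: aligned by name, commutes exactly
  perm <- a
  idx <- c(3, 1, 2)
  perm$universe <- a$universe[idx]
  perm$mu <- a$mu[idx, , drop = FALSE]
  perm$r <- a$r[idx, , drop = FALSE]
  expect_znss_close(znss_union(a, perm), znss_union(a, a), tol = 0)
})

test_that("subset and equality follow the componentwise definitions", {
  f <- paper_fixture("influenza_model_t1")
  g <- paper_fixture("subset_example_G")
  # the companion example set is NOT a soft subset: it presents e4, which the
  # reference set lacks, and its (d4, e2) reliability 0.9 exceeds 0.1
  expect_false(znss_subset(g, f))
  expect_true(znss_subset(znss_intersection(f, f), f))
  expect_true(znss_subset(f, znss_union(f, f)))

  s <- make_small()
  expect_true(znss_equal(s, s))
  perturbed <- s
  perturbed$mu["y", "e1"] <- perturbed$mu["y", "e1"] + 0.01
  expect_false(znss_equal(s, perturbed))
  dropped <- znss(s$universe, "e1",
                  list(e1 = list(y = c(0.5, 0.8), n = c(0.5, 0.8))))
  expect_false(znss_equal(s, dropped))
  expect_true(znss_subset(dropped, s))
})

test_that("null and absolute sets hold their defining cells and absorb", {
  nl <- null_znss(c("y", "n"), "e1")
  expect_true(all(nl$mu == 0) && all(nl$r == 1))
  ab <- absolute_znss(c("y", "n"), "e1")
  expect_true(all(ab$mu == 1) && all(ab$r == 1))

  s <- make_small()
  ab2 <- absolute_znss(s$universe, present_parameters(s))
  expect_znss_close(znss_union(s, ab2), ab2, tol = 0)
  expect_znss_close(znss_intersection(s, ab2), s, tol = 0)
  # with the null set the membership component behaves classically; the
  # reliability component deliberately does not (null cells carry r = 1)
  nl2 <- null_znss(s$universe, present_parameters(s))
  expect_identical(znss_intersection(s, nl2)$mu, nl2$mu)
  expect_identical(znss_union(s, nl2)$mu, s$mu)
})

test_that("matrix form round-trips and handles degenerate sizes", {
  t1 <- paper_fixture("influenza_model_t1")
  m <- as_znss_matrix(t1)
  expect_identical(dim(m$mu), c(5L, 4L))
  expect_identical(m$mu[1, 1], 0.2)
  expect_identical(m$absent, "e4")
  back <- as_znss(m)
  expect_true(znss_equal(back, t1))
  expect_identical(back$parameters, t1$parameters)

  empty <- znss(character(), character(), list())
  m0 <- as_znss_matrix(empty)
  expect_identical(dim(m0$mu), c(0L, 0L))
  expect_true(znss_equal(as_znss(m0), empty))

  bad <- m
  bad$rows <- bad$rows[-1]
  expect_error(as_znss(bad), "labels give")
})
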