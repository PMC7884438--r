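test_that("edge-to-edge equals the brute-force minimum and is symmetric", {
  withr::local_seed(101)
  for (target in c(5, 7.4, 12)) {
    fx <- make_pair(target, seed = as.integer(target * 10))
    pg <- extract_pigments(fx$model)
    d <- edge_to_edge(pg[[1]], pg[[2]])
    expect_equal(d, oracle_min_dist(pg[[1]]$conj_xyz, pg[[2]]$conj_xyz),
                 tolerance = 1e-12)
    expect_equal(d, edge_to_edge(pg[[2]], pg[[1]]))
    expect_equal(d, fx$ledger$d_edge[1, 2], tolerance = 1e-9)
  }
  pg <- extract_pigments(make_pair(6, seed = 1)$model)
  expect_equal(edge_to_edge(pg[[1]], pg[[1]]), 0)
})

test_that("an empty conjugated set is an explicit error naming the pigment", {
  p <- point_pigment("Lhca1", 601, c(0, 0, 0))
  q <- p
  q$conj_xyz <- q$conj_xyz[0, , drop = FALSE]
  q$pid <- "Lhca1:CLA:999"
  expect_error(edge_to_edge(p, q), "Lhca1:CLA:999")
})

test_that("Mg--Mg distances come from the Mg atoms or are NA", {
  fx <- make_pair(9, seed = 6)
  pg <- extract_pigments(fx$model)
  expect_equal(mg_mg(pg[[1]], pg[[2]]), fx$ledger$d_mg[1, 2],
               tolerance = 1e-9)
  expect_equal(mg_mg(pg[[1]], pg[[1]]), 0)
  nomg <- pg[[1]]
  nomg$mg <- NULL
  expect_true(is.na(mg_mg(nomg, pg[[2]])))
})

test_that("the distance table matches brute force, sorts, and filters", {
  fx <- make_grid(5, 12, seed = 31)
  pg <- extract_pigments(fx$model)
  tab <- distance_table(pg)
  expect_equal(nrow(tab), choose(5, 2))
  expect_false(is.unsorted(tab$d_edge))
  for (i in seq_len(nrow(tab))) {
    a <- pg[[tab$pid_a[i]]]
    b <- pg[[tab$pid_b[i]]]
    expect_equal(tab$d_edge[i], oracle_min_dist(a$conj_xyz, b$conj_xyz),
                 tolerance = 1e-12)
  }
  # ledger agreement over the whole matrix
  idx <- t(combn(5, 2))
  led <- fx$ledger$d_edge[idx]
  expect_lt(max(abs(sort(led) - tab$d_edge)), 1e-9)
  # cutoff below the minimum -> empty
  expect_equal(nrow(distance_table(pg, max_d = min(tab$d_edge) - 0.5)), 0L)
})

test_that("the centroid pre-filter never loses a qualifying pair", {
  for (n in c(10, 25, 50)) {
    pg <- extract_pigments(make_grid(n, 10, seed = n)$model)
    full <- distance_table(pg)
    for (max_d in c(5, 12, 20)) {
      filt <- distance_table(pg, max_d = max_d)
      want <- full[full$d_edge <= max_d, c("pid_a", "pid_b", "d_edge")]
      rownames(want) <- NULL
      expect_equal(filt[, c("pid_a", "pid_b", "d_edge")], want)
    }
  }
})

test_that("class filters drop the excluded classes from the table", {
  pg <- extract_pigments(make_grid(4, 12, seed = 4)$model)
  car <- point_pigment("Lhca1", 701, c(6, 0, 0), klass = "CAR_BCR",
                       comp_id = "BCR")
  tab <- distance_table(c(pg, list(car)), classes = c("CHL_A", "CHL_B"))
  expect_false(any(grepl("BCR", c(tab$pid_a, tab$pid_b))))
  expect_equal(nrow(tab), choose(4, 2))
})

test_that("self-superposition is the identity and small fits error", {
  b <- make_two_belt_fixture(seed = 9)
  sp <- superpose(b$reference, b$reference, c("PsaA", "PsaB"))
  expect_lt(sp$rmsd, 1e-9)
  expect_lt(max(abs(sp$R - diag(3))), 1e-6)
  expect_equal(det(sp$R), 1, tolerance = 1e-6)
  one_atom <- b$reference
  one_atom$atoms <- one_atom$atoms[1:2, ]
  expect_error(superpose(one_atom, b$reference, c("PsaA", "PsaB")),
               "at least 3")
})

test_that("superposition recovers a planted rigid transform", {
  withr::local_seed(77)
  ref <- make_two_belt_fixture(seed = 2, site_shift = 0)$reference
  for (i in 1:10) {
    tr <- random_rigid()
    mob <- apply_transform(ref, tr)
    sp <- superpose(mob, ref, c("PsaA", "PsaB"))
    expect_lt(sp$rmsd, 1e-6)
    # recovered transform is the inverse of the planted one
    inv <- invert_transform(tr)
    expect_lt(max(abs(sp$R - inv$R)), 1e-6)
    expect_lt(max(abs(sp$t - inv$t)), 1e-6)
  }
})

test_that("transforms compose, invert, and leave edge distances invariant", {
  withr::local_seed(55)
  fx <- make_pair(7.4, seed = 12)
  pg <- extract_pigments(fx$model)
  d0 <- edge_to_edge(pg[[1]], pg[[2]])
  tr1 <- random_rigid()
  tr2 <- random_rigid()

  m1 <- apply_transform(fx$model, tr1)
  pg1 <- extract_pigments(m1)
  expect_lt(abs(edge_to_edge(pg1[[1]], pg1[[2]]) - d0), 1e-9)

  # identity and inverse round trip
  ident <- list(R = diag(3), t = c(0, 0, 0))
  expect_equal(apply_transform(fx$model, ident)$atoms$x, fx$model$atoms$x)
  back <- apply_transform(m1, invert_transform(tr1))
  expect_lt(max(abs(back$atoms$x - fx$model$atoms$x)), 1e-9)

  # composition agrees with the matrix-product oracle
  m12 <- apply_transform(m1, tr2)
  comp <- compose_transform(tr2, tr1)
  m12b <- apply_transform(fx$model, comp)
  expect_lt(max(abs(as.matrix(m12$atoms[, c("x", "y", "z")]) -
                      as.matrix(m12b$atoms[, c("x", "y", "z")]))), 1e-9)
  R_oracle <- tr2$R %*% tr1$R
  t_oracle <- as.numeric(tr2$R %*% tr1$t) + tr2$t
  expect_lt(max(abs(comp$R - R_oracle)), 1e-12)
  expect_lt(max(abs(comp$t - t_oracle)), 1e-12)
})
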