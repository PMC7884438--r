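test_that("identical pigment sets match perfectly with zero displacement", {
  pg <- extract_pigments(make_grid(5, 12, seed = 51)$model)
  mm <- match_pigments(pg, pg)
  expect_true(all(mm$status == "matched"))
  expect_true(all(mm$displacement == 0))
})

test_that("an exactly transformed copy matches with tiny displacement after superposition", {
  b <- make_two_belt_fixture(seed = 52, site_shift = 0)
  sp <- superpose(b$mobile, b$reference, c("PsaA", "PsaB"))
  mob <- extract_pigments(apply_transform(b$mobile, sp))
  ref <- extract_pigments(b$reference)
  mm <- match_pigments(ref, mob)
  matched <- mm[mm$status == "matched", ]
  expect_lt(max(matched$displacement), 1e-6)
  # the planted deletion is the one lost pigment
  lost <- mm[mm$status == "lost_in_mobile", ]
  expect_equal(lost$ref_pid, b$ledger$deleted_pid)
})

test_that("greedy matching equals the optimal assignment on separated point sets", {
  withr::local_seed(606)
  thr <- 3.5
  for (trial in 1:60) {
    nr <- sample(3:6, 1)
    # reference points far apart relative to the threshold; mobile points
    # are jittered copies (some dropped), so the optimal assignment is
    # unambiguous and greedy must find exactly it
    rc <- matrix(runif(nr * 3, 0, 100), ncol = 3)
    while (min(dist(rc)) < 4 * thr) {
      rc <- matrix(runif(nr * 3, 0, 100), ncol = 3)
    }
    keep <- sort(sample(nr, sample(2:nr, 1)))
    mc <- rc[keep, , drop = FALSE] +
      matrix(runif(length(keep) * 3, -thr / 4, thr / 4), ncol = 3)
    ref <- lapply(seq_len(nr), function(i) {
      point_pigment("Lhca1", 600 + i, rc[i, ])
    })
    mob <- lapply(seq_along(keep), function(j) {
      point_pigment("Lhca1", 700 + j, mc[j, ])
    })
    mm <- match_pigments(ref, mob, threshold = thr)
    got <- mm[mm$status == "matched", c("ref_pid", "mob_pid")]
    opt <- oracle_optimal_assignment(rc, mc, thr)
    expect_equal(nrow(got), nrow(opt))
    got_pairs <- sort(paste(got$ref_pid, got$mob_pid))
    opt_pairs <- sort(paste(
      sprintf("Lhca1:CLA:%d", 600 + opt[, "ref"]),
      sprintf("Lhca1:CLA:%d", 700 + opt[, "mob"])
    ))
    expect_equal(got_pairs, opt_pairs)
    expect_equal(sum(mm$status == "lost_in_mobile"), nr - nrow(opt))
  }
})

test_that("swapping reference and mobile swaps lost and gained", {
  b <- make_two_belt_fixture(seed = 53)
  sp <- superpose(b$mobile, b$reference, c("PsaA", "PsaB"))
  mob <- extract_pigments(apply_transform(b$mobile, sp))
  ref <- extract_pigments(b$reference)
  fwd <- match_pigments(ref, mob)
  rev <- match_pigments(mob, ref)
  expect_equal(sum(fwd$status == "lost_in_mobile"),
               sum(rev$status == "gained_in_mobile"))
  fp <- sort(paste(fwd$ref_pid[fwd$status == "matched"],
                   fwd$mob_pid[fwd$status == "matched"]))
  rp <- sort(paste(rev$mob_pid[rev$status == "matched"],
                   rev$ref_pid[rev$status == "matched"]))
  expect_equal(fp, rp)
})

test_that("a planted site shift dominates the shift ranking at its planted size", {
  b <- make_two_belt_fixture(seed = 54, site_shift = 3, shifted_site = 2)
  sp <- superpose(b$mobile, b$reference, c("PsaA", "PsaB"))
  mob <- extract_pigments(apply_transform(b$mobile, sp))
  ref <- extract_pigments(b$reference)
  mm <- match_pigments(ref, mob)
  rank <- subunit_shift_ranking(mm)
  expect_equal(rank$subunit[1], "Lhca5")
  expect_equal(rank$mean_disp[1], 3, tolerance = 1e-5)
  expect_lt(max(rank$mean_disp[-1]), 1e-5)

  # zero shift: all means ~0, rows in stable name order
  b0 <- make_two_belt_fixture(seed = 54, site_shift = 0)
  sp0 <- superpose(b0$mobile, b0$reference, c("PsaA", "PsaB"))
  mm0 <- match_pigments(extract_pigments(b0$reference),
                        extract_pigments(apply_transform(b0$mobile, sp0)))
  rank0 <- subunit_shift_ranking(mm0)
  expect_lt(max(rank0$mean_disp), 1e-6)
  expect_setequal(rank0$subunit, c("Lhca1", "Lhca5", "Lhca2", "Lhca3"))

  # exact zeros (self-comparison on integer coordinates): ties ordered
  # deterministically by subunit name
  pg <- unlist(lapply(c("Lhca1", "Lhca5", "Lhca2", "Lhca3"), function(s) {
    lapply(1:2, function(i) {
      point_pigment(s, 600 + i, c(match(s, subunit_vocabulary()) * 30,
                                  i * 15, 0))
    })
  }), recursive = FALSE)
  rank_self <- subunit_shift_ranking(match_pigments(pg, pg))
  expect_true(all(rank_self$mean_disp == 0))
  expect_equal(rank_self$subunit, sort(rank_self$subunit))
})

test_that("shift statistics ignore pigment enumeration order", {
  b <- make_two_belt_fixture(seed = 55)
  sp <- superpose(b$mobile, b$reference, c("PsaA", "PsaB"))
  mob <- extract_pigments(apply_transform(b$mobile, sp))
  ref <- extract_pigments(b$reference)
  r1 <- subunit_shift_ranking(match_pigments(ref, mob))
  r2 <- subunit_shift_ranking(match_pigments(rev(ref), rev(mob)))
  expect_equal(r1, r2)
})

test_that("pairing tables validate subunits and drive occupancy diffs", {
  pg <- extract_pigments(make_grid(3, 12, seed = 56)$model)
  mm <- match_pigments(pg, pg)
  bad <- data.frame(site = "pos1", ref_subunit = "Lhca7",
                    mob_subunit = "Lhca7", stringsAsFactors = FALSE)
  expect_error(subunit_shift_ranking(mm, bad), "unknown subunit")

  inv1 <- build_inventory(pg)
  pairing <- data.frame(site = "pos1", ref_subunit = "Lhca1",
                        mob_subunit = "Lhca1", stringsAsFactors = FALSE)
  zd <- site_occupancy_diff(inv1, inv1, pairing)
  expect_true(all(zd$diff == 0))

  extra <- c(pg, list(point_pigment("Lhca1", 900, c(99, 0, 0),
                                    klass = "CAR_BCR", comp_id = "BCR")))
  inv2 <- build_inventory(extra)
  d <- site_occupancy_diff(inv2, inv1, pairing)
  expect_equal(d$diff[d$class == "CAR_BCR"], 1)
  expect_equal(sum(d$diff != 0), 1L)
})
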