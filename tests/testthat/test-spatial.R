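test_that("nearest-neighbour distances: basic geometry and edge cases", {
  expect_equal(nn_distances(cbind(0, 0), cbind(c(3, 10), c(4, 0))), 5)
  expect_equal(nn_distances(cbind(5, 5), cbind(5, 5),
                            ref_ids = "a", target_ids = "b"), 0)
  expect_error(nn_distances(cbind(0, 0), cbind(numeric(0), numeric(0))),
               "no target cells")
  expect_length(nn_distances(cbind(numeric(0), numeric(0)), cbind(1, 1)), 0)
  expect_warning(
    d <- nn_distances(cbind(1, 1), cbind(1, 1), ref_ids = "a",
                      target_ids = "a"),
    "no other target")
  expect_true(is.na(d))
})

test_that("blocked search equals the exhaustive O(n^2) oracle on random instances", {
  set.seed(2024)
  for (i in 1:100) {
    n <- sample(1:200, 1)
    m <- sample(1:200, 1)
    ref <- cbind(runif(n, 0, 931), runif(n, 0, 698))
    tgt <- cbind(runif(m, 0, 931), runif(m, 0, 698))
    expect_equal(nn_distances(ref, tgt), bf_nn(ref, tgt), tolerance = 0)
  }
  # with overlapping identities (self-exclusion)
  for (i in 1:10) {
    n <- sample(2:100, 1)
    pts <- cbind(runif(n), runif(n))
    ids <- as.character(seq_len(n))
    expect_equal(nn_distances(pts, pts, ids, ids), bf_nn(pts, pts, ids, ids),
                 tolerance = 0)
  }
})

test_that("distances are translation and rotation invariant, and monotone in targets", {
  set.seed(9)
  ref <- cbind(runif(50, 100, 800), runif(50, 100, 600))
  tgt <- cbind(runif(80, 100, 800), runif(80, 100, 600))
  d0 <- nn_distances(ref, tgt)
  shift <- function(p, dx, dy) cbind(p[, 1] + dx, p[, 2] + dy)
  expect_equal(nn_distances(shift(ref, 13, -7), shift(tgt, 13, -7)), d0)
  th <- 0.7
  rot <- function(p) cbind(cos(th) * p[, 1] - sin(th) * p[, 2],
                           sin(th) * p[, 1] + cos(th) * p[, 2])
  expect_equal(nn_distances(rot(ref), rot(tgt)), d0, tolerance = 1e-9)
  d1 <- nn_distances(ref, rbind(tgt, cbind(450, 350)))
  expect_true(all(d1 <= d0 + 1e-12))
})

test_that("median radius and close/far classification follow the boundary-inclusive rule", {
  expect_equal(median_radius(100), 100)
  expect_equal(median_radius(c(10, 20, 30)), 20)
  expect_error(median_radius(numeric(0)), "no defined median")
  expect_equal(classify_proximity(241.96, 241.96), "close")
  expect_equal(classify_proximity(0, 50), "close")
  expect_equal(classify_proximity(50 + 1e-9, 50), "far")
})

test_that("proximity matrix on hand-placed cells matches hand computation", {
  # two CK+ cells and two CD3+ cells at known positions in one ROI
  ct <- make_ct(c(0, 10, 3, 100), c(0, 0, 4, 0),
                markers = list(CK = c(1, 1, 0, 0), CD3 = c(0, 0, 1, 1)))
  panel <- panel_spec("t", c("CK", "CD3"), list("CK+", "CD3+"))
  pr <- proximity_summary(ct, panel, ref_phenotypes = "CK+",
                          target_phenotypes = "CD3+")
  # NN distances: cell1 -> (3,4) = 5; cell2 -> (3,4) = sqrt(49+16)
  expect_equal(pr$pairs$median_distance, median(c(5, sqrt(65))))
  expect_equal(pr$pairs$n_ref, 2)
  expect_equal(unname(pr$matrix["CK+", "CD3+"]), median(c(5, sqrt(65))))
})

test_that("self-overlapping phenotypes use the nearest-other rule on the diagonal", {
  ct <- make_ct(c(0, 3), c(0, 4), markers = list(CK = c(1, 1), CD3 = c(0, 0)))
  panel <- panel_spec("t", c("CK", "CD3"), list("CK+", "CD3+"))
  pr <- proximity_summary(ct, panel, ref_phenotypes = "CK+",
                          target_phenotypes = "CK+")
  expect_equal(pr$pairs$median_distance, 5)  # each cell's nearest OTHER cell
})

test_that("empty-target pairs are NULL entries, not errors", {
  ct <- make_ct(c(1, 2), c(1, 2), markers = list(CK = c(1, 1), CD3 = c(0, 0)))
  panel <- panel_spec("t", c("CK", "CD3"), list("CK+", "CD3+"))
  expect_message(
    pr <- proximity_summary(ct, panel, ref_phenotypes = "CK+",
                            target_phenotypes = "CD3+"),
    "no co-occurring")
  expect_true(is.na(pr$pairs$median_distance))
})

test_that("infiltrated cohorts shorten the CK -> CD3 matrix entry", {
  panel <- default_panels(1)[["1"]]
  entry <- function(m) {
    ct <- simulate_roi(sim_config(mixing = m), panel, seed = 55)
    pr <- proximity_summary(ct, panel, ref_phenotypes = "CK+",
                            target_phenotypes = "CD3+")
    pr$pairs$median_distance
  }
  expect_lt(entry(1), entry(0))
})

test_that("cohort median radius equals brute-force recomputation from raw tables", {
  co <- mini_cohort(seed = 31, n_samples = 2, n_rois = 2)
  panel <- default_panels(1)[["1"]]
  ct <- co$tables[["1"]]$week1
  pr <- proximity_summary(ct, panel)
  r <- median_radius(pr$pairs)

  # independent recomputation: loop frames, brute-force NN, pool, median
  mem <- assign_phenotypes(ct, panel)
  key <- paste(ct$sample_id, ct$roi_id, ct$timepoint)
  refs <- rownames(pr$matrix); tgts <- colnames(pr$matrix)
  meds <- c()
  for (rp in refs) for (tp in tgts) {
    pool <- c()
    for (fk in unique(key)) {
      i <- which(key == fk)
      ri <- i[mem[i, rp]]; ti <- i[mem[i, tp]]
      if (length(ri) == 0 || length(ti) == 0) next
      pool <- c(pool, bf_nn(cbind(ct$x_um, ct$y_um)[ri, , drop = FALSE],
                            cbind(ct$x_um, ct$y_um)[ti, , drop = FALSE],
                            ct$cell_id[ri], ct$cell_id[ti]))
    }
    if (length(pool) > 0) meds <- c(meds, median(pool))
  }
  expect_equal(r, median(meds))
})
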