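test_that("compositional center closes the geometric means", {
  x <- table1_center()
  one <- composition_set(matrix(as.numeric(x), 1, dimnames = list(NULL, names(x))),
                         total = 1440)
  expect_equal(as.numeric(compositional_center(one)), as.numeric(x))

  # hand-computed geometric means: first part gm = sqrt(2 * 8) = 4
  m <- rbind(c(2, 1, 1) / 4, c(8, 1, 1) / 10)
  colnames(m) <- c("a", "b", "c")
  ctr <- compositional_center(composition_set(m, total = 1))
  gm <- c(sqrt(2 / 4 * 8 / 10), sqrt(1 / 4 * 1 / 10), sqrt(1 / 4 * 1 / 10))
  expect_equal(as.numeric(ctr), gm / sum(gm), tolerance = 1e-12)

  # invariance to per-row rescaling: closure of rows changes nothing
  set.seed(8)
  rows <- random_composition_matrix(20)
  d1 <- composition_set(rows, total = 1440)
  d2 <- composition_set(rows / 1440 * 100, total = 100)
  expect_equal(as.numeric(compositional_center(d1)) / 1440,
               as.numeric(compositional_center(d2)) / 100, tolerance = 1e-12)
})

test_that("the center re-expresses across units without losing ratios", {
  x <- table1_center()
  pct <- closure(as.numeric(x), total = 100, names = names(x))
  hrs <- closure(as.numeric(x), total = 24, names = names(x))
  expect_equal(round(pct[["Sleep"]]), 43)
  expect_equal(round(hrs[["Sleep"]], 1), 10.3)
  expect_equal(pct[["PA"]] / pct[["Sleep"]], hrs[["PA"]] / hrs[["Sleep"]],
               tolerance = 1e-12)
})

test_that("variation array holds logratio variances, means and the center", {
  data <- cohort_with_center(table1_center())
  va <- variation_array(data)
  # symmetric pairs constructed around the printed center recover it exactly
  expect_equal(as.numeric(va$center), c(617.5, 553.1, 269.4), tolerance = 1e-9)
  expect_equal(round(va$means["PA", "Sleep"], 2), -0.83)
  expect_equal(round(va$means["SB", "Sleep"], 2), -0.11)
  # exp of the mean logratio scales one center part into another
  expect_equal(exp(va$means["PA", "Sleep"]) * va$center[["Sleep"]],
               va$center[["PA"]], tolerance = 1e-9)

  # structural invariants
  expect_equal(va$variances, t(va$variances))
  expect_true(all(va$variances >= 0) && all(diag(va$variances) == 0))
  expect_equal(va$means, -t(va$means))
  lnc <- log(as.numeric(va$center))
  expect_equal(va$means, outer(lnc, lnc, "-"), tolerance = 1e-12,
               ignore_attr = TRUE)

  same <- composition_set(matrix(rep(c(600, 500, 340), each = 4), 4,
                                 dimnames = list(NULL, c("a", "b", "c"))),
                          total = 1440)
  expect_true(all(variation_array(same)$variances < 1e-20))
  expect_error(variation_array(composition_set(
    matrix(c(600, 500, 340), 1, dimnames = list(NULL, c("a", "b", "c"))),
    total = 1440)), "n >= 2")
})

test_that("variation_table lays variances above and means below the diagonal", {
  data <- cohort_with_center(table1_center())
  va <- variation_array(data)
  tab <- variation_table(va)
  expect_equal(tab["Sleep", "SB"], va$variances["Sleep", "SB"])
  expect_equal(tab["SB", "Sleep"], va$means["SB", "Sleep"])
  expect_equal(unname(tab[, "center"]), as.numeric(va$center))
})

test_that("Aitchison distance is a perturbation-invariant clr metric", {
  set.seed(9)
  x <- random_composition(); y <- random_composition(); p <- random_composition()
  expect_equal(aitchison_distance(x, x), 0)
  expect_equal(aitchison_distance(x, y), aitchison_distance(y, x))
  expect_equal(aitchison_distance(perturb(x, p), perturb(y, p)),
               aitchison_distance(x, y), tolerance = 1e-10)
  expect_equal(aitchison_distance(closure(c(a = 2, b = 1, c = 1), 1),
                                  closure(c(a = 1, b = 2, c = 1), 1)),
               sqrt(2) * log(2), tolerance = 1e-12)
})

test_that("the center minimises mean squared Aitchison distance", {
  set.seed(10)
  data <- composition_set(random_composition_matrix(15), total = 1440)
  ctr <- compositional_center(data)
  msd <- function(comp) mean(vapply(seq_len(n_rows(data)), function(i)
    aitchison_distance(comp_row(data, i), comp)^2, numeric(1)))
  at_center <- msd(ctr)
  for (rep in 1:25) {
    probe <- perturb(ctr, powering(random_composition(), 0.2))
    expect_gte(msd(probe), at_center - 1e-12)
  }
})

test_that("change index normalises Aitchison distances to [0, 1]", {
  ref <- table1_center()
  same <- composition_set(matrix(rep(as.numeric(ref), each = 3), 3,
                                 dimnames = list(NULL, names(ref))), 1440)
  expect_equal(change_index(same, ref), rep(0, 3))

  set.seed(12)
  data <- composition_set(random_composition_matrix(30, D = 3), total = 1440)
  ref2 <- closure(c(480, 480, 480), 1440, names = part_names(data))
  idx <- change_index(data, ref2)
  expect_true(all(idx >= 0 & idx <= 1))
  expect_equal(max(idx), 1)
  d <- vapply(seq_len(n_rows(data)), function(i)
    aitchison_distance(comp_row(data, i), ref2), numeric(1))
  expect_equal(order(idx), order(d))  # monotone in the raw distance
  # user-supplied normaliser
  expect_equal(change_index(data, ref2, max_distance = 2 * max(d)), idx / 2)
})

test_that("predictive regions nest, stay in the simplex and respect symmetry", {
  set.seed(13)
  data <- small_cohort(n = 600)
  pr <- predictive_region(data, level = c(0.75, 0.95, 0.99), n_points = 90)
  parts <- part_names(data)
  expect_true(all(pr[parts] > 0))
  expect_equal(unname(rowSums(pr[parts])), rep(1440, nrow(pr)), tolerance = 1e-9)

  # nesting: measured in coordinate space, the 99% curve is farther out
  fit <- region_fit(data)
  mah <- function(lv) {
    z <- pivot_coordinates(
      composition_set(as.matrix(pr[pr$level == lv, parts]), 1440), fit$basis)
    stats::mahalanobis(z, fit$mean, fit$cov)
  }
  expect_true(all(mah(0.99) > mah(0.95) + 1e-8))
  expect_true(all(mah(0.95) > mah(0.75) + 1e-8))
  expect_equal(unname(mah(0.95)), rep(stats::qchisq(0.95, 2), 90),
               tolerance = 1e-8)
  expect_error(predictive_region(data, level = 1.2), "level")
})

test_that("spherical coordinate covariance gives a circular boundary", {
  # draw coordinates iid -> fitted ellipse is near-circular around the mean
  set.seed(14)
  b <- pivot_basis(c("a", "b", "c"))
  z <- matrix(rnorm(4000, sd = 0.3), ncol = 2)
  data <- composition_set(inverse_pivot(z, b, 1440), total = 1440)
  fit <- region_fit(data)
  pr <- predictive_region(data, level = 0.95, n_points = 120)
  zb <- pivot_coordinates(
    composition_set(as.matrix(pr[part_names(data)]), 1440), fit$basis)
  r <- sqrt(rowSums(sweep(zb, 2, fit$mean)^2))
  expect_lt((max(r) - min(r)) / mean(r), 0.1)
})

test_that("ternary coordinates map the simplex onto the unit triangle", {
  eq <- neutral_composition(c("a", "b", "c"))
  expect_equal(unname(ternary_xy(eq)), c(0.5, sqrt(3) / 6), tolerance = 1e-12)
  # vertices: nearly all mass in one part lands at the matching corner
  corners <- list(c(1e9, 1e-9, 1e-9), c(1e-9, 1e9, 1e-9), c(1e-9, 1e-9, 1e9))
  target <- list(c(0, 0), c(1, 0), c(0.5, sqrt(3) / 2))
  for (i in 1:3) {
    x <- closure(stats::setNames(corners[[i]], c("a", "b", "c")), 1)
    expect_equal(unname(ternary_xy(x)), target[[i]], tolerance = 1e-6)
  }
  # barycentric affinity: midpoint of proportions maps to planar midpoint
  set.seed(15)
  x <- random_composition(); y <- random_composition()
  mid <- closure((as.numeric(x) + as.numeric(y)) / 2, 1440,
                 names = part_names(x))
  expect_equal(unname(ternary_xy(mid)),
               unname((ternary_xy(x) + ternary_xy(y)) / 2), tolerance = 1e-12)
  expect_error(ternary_xy(random_composition(D = 4)), "three parts")
})
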