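test_that("balance_plan reproduces the published upsampling counts", {
  plan <- balance_plan(15472, c(1445, 3183, 553, 421))
  expect_equal(plan$add_per_image, c(9L, 3L, 26L, 35L))
  expect_equal(plan$total, c(14450L, 12732L, 14931L, 15156L))

  expect_equal(balance_plan(100, 100)$add_per_image, 0L)
  expect_equal(balance_plan(100, 100)$total, 100L)
  expect_equal(balance_plan(100, 33)$add_per_image, 2L)
  expect_equal(balance_plan(100, 33)$total, 99L)

  expect_error(balance_plan(100, c(50, 0)), class = "fundusdr_invalid_counts")
  expect_error(balance_plan(100, 101), class = "fundusdr_invalid_counts")
})

test_that("floored add counts never overshoot the majority class", {
  withr::with_seed(201, {
    for (rep in 1:200) {
      n0 <- sample(10:5000, 1)
      ni <- sample(seq_len(n0), 1)
      plan <- balance_plan(n0, ni)
      slack <- n0 - ni * (plan$add_per_image + 1L)
      expect_gte(slack, 0L)
      expect_lt(slack, ni)
      expect_lte(plan$total, n0)
    }
  })
})

test_that("flips reverse the right axis and are involutions", {
  row <- array(0, dim = c(1, 3, 3))
  row[1, , 1] <- c(10, 20, 30)
  expect_equal(flip_lr(row)[1, , 1], c(30, 20, 10))

  col <- array(0, dim = c(3, 1, 3))
  col[, 1, 2] <- c(1, 2, 3)
  expect_equal(flip_ud(col)[, 1, 2], c(3, 2, 1))

  withr::with_seed(202, {
    g <- random_grid(7, 11)
    expect_identical(flip_lr(flip_lr(g)), g)
    expect_identical(flip_ud(flip_ud(g)), g)
    # composing the two flips is an exact 180-degree rotation
    expect_identical(flip_lr(flip_ud(g)),
                     g[dim(g)[1]:1, dim(g)[2]:1, , drop = FALSE])
  })

  sym <- disc_fixture(side = 15, border = 3)
  expect_identical(flip_lr(sym), sym)
  expect_identical(flip_ud(sym), sym)
})

test_that("random rotation is seeded, preserves zeros and disc interiors", {
  g <- random_grid(20, 20)
  expect_identical(rotate_random(g, seed = 9), rotate_random(g, seed = 9))

  zero <- array(0, dim = c(12, 12, 3))
  expect_identical(rotate_random(zero, seed = 1), zero)

  disc <- disc_fixture(side = 41, border = 6, value = 120)
  rot <- rotate_by(disc, 37)
  expect_identical(dim(rot), dim(disc))
  # interior of a centered uniform disc survives rotation up to interpolation
  cy <- 21; r_in <- (41 - 12) / 2 - 3
  for (i in seq(8, 34, by = 3)) for (j in seq(8, 34, by = 3))
    if ((i - cy)^2 + (j - cy)^2 <= r_in^2)
      expect_lte(max(abs(rot[i, j, ] - disc[i, j, ])), 2)
})

test_that("remove_unnecessary_area is the square-circle mask", {
  g <- random_grid(21, 21)
  expect_identical(remove_unnecessary_area(g), inscribe_circle_mask(g))
  expect_identical(remove_unnecessary_area(remove_unnecessary_area(g)),
                   remove_unnecessary_area(g))
  expect_error(remove_unnecessary_area(random_grid(5, 6)),
               class = "fundusdr_not_square")

  # rotated bright-corner artifacts are wiped
  art <- disc_fixture(side = 21, border = 4)
  art[1, 1, ] <- 200; art[21, 21, ] <- 200
  cleaned <- remove_unnecessary_area(art)
  expect_equal(cleaned[1, 1, ], rep(0, 3))
  expect_equal(cleaned[21, 21, ], rep(0, 3))
})

test_that("remove_unnecessary_area keeps exactly the oracle's surviving pixels", {
  g <- array(100, dim = c(299, 299, 3))
  survivors <- sum(remove_unnecessary_area(g)[, , 1] > 0)
  cy <- (299 - 1) / 2
  d2 <- outer((0:298 - cy)^2, (0:298 - cy)^2, `+`)
  expect_equal(survivors, sum(d2 <= (299 / 2)^2))
})

test_that("upsample_class allocates flips first, rotations after, all re-masked", {
  g <- disc_fixture(side = 16, border = 3)
  up <- upsample_class(list(g), add_per_image = 5, seed = 3)
  expect_length(up$images, 6)
  expect_equal(up$provenance$transform,
               c("source", "flip_lr", "flip_ud", "rotate", "rotate", "rotate"))
  expect_true(all(is.na(up$provenance$angle[1:3])))
  expect_true(all(!is.na(up$provenance$angle[4:6])))
  # every output is re-masked (corners zero on a square grid)
  for (img in up$images) expect_equal(img[1, 1, ], rep(0, 3))

  none <- upsample_class(list(g, g), add_per_image = 0)
  expect_length(none$images, 2)
  expect_equal(none$provenance$transform, rep("source", 2))
})

test_that("upsample_class output counts match the balance plan exactly", {
  withr::with_seed(203, {
    for (rep in 1:5) {
      n_src <- sample(1:6, 1)
      add <- sample(0:7, 1)
      imgs <- replicate(n_src, random_grid(10, 10), simplify = FALSE)
      up <- upsample_class(imgs, add, seed = rep)
      expect_length(up$images, n_src * (add + 1))
      # provenance is complete: every output traceable to exactly one source
      expect_equal(nrow(up$provenance), n_src * (add + 1))
      expect_equal(sort(unique(up$provenance$source)), seq_len(n_src))
      expect_equal(unname(table(up$provenance$source)),
                   rep(add + 1, n_src), ignore_attr = TRUE)
    }
  })
})

test_that("class weights are inverse-frequency and average to one", {
  balanced <- class_weights(rep(0:4, each = 20))
  expect_equal(balanced$weight, rep(1, 5))

  counts <- c(15472, 1445, 3183, 553, 421)
  w <- class_weights(rep(0:4, times = counts))
  expect_equal(w$weight, 21074 / (5 * counts), tolerance = 1e-12)
  expect_equal(w$weight[1], 0.2724, tolerance = 1e-4)
  expect_equal(w$weight[5], 10.0114, tolerance = 1e-4)
  # count-weighted mean of the weights is exactly 1
  expect_equal(sum(w$count * w$weight) / sum(w$count), 1, tolerance = 1e-12)

  expect_error(class_weights(c(0, 1, 2, 3)), class = "fundusdr_missing_class")
})
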