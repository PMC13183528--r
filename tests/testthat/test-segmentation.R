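test_that("gray histograms count every pixel and normalize to one", {
  img <- matrix(c(0, 0, 255, 255), 2, 2)
  h <- gray_histogram(img)
  expect_equal(h$ph[1], 0.5)
  expect_equal(h$ph[256], 0.5)
  expect_equal(sum(h$ph), 1)
  expect_equal(sum(h$counts), 4)
  for (s in 1:3) {
    expect_equal(sum(gray_histogram(bimodal_image(seed = s))$ph), 1)
  }
  px <- array(0, c(1, 1, 3)); px[1, 1, 1] <- 255
  hr <- gray_histogram(px)
  expect_equal(hr$counts[76 + 1], 1L) # pure red lands in luminance bin 76
})

test_that("kapur entropy matches closed forms and degenerate cases", {
  ph <- c(rep(0.25, 4), rep(0, 252))
  expect_equal(kapur_objective(ph, 2), 2 * log(2)) # each class: entropy ln 2
  one <- rep(0, 256); one[101] <- 1
  expect_equal(kapur_objective(one, 128), 0) # single occupied bin
  img <- bimodal_image(seed = 3)
  h <- gray_histogram(img)
  expect_equal(kapur_objective(h, c(200, 90)), kapur_objective(h, c(90, 200)))
  expect_gte(kapur_objective(h, 90), 0)
})

test_that("kapur entropy is non-negative, zero iff single-outcome classes", {
  withr::with_seed(31, {
    for (i in 1:20) {
      ph <- runif(256) * rbinom(256, 1, 0.05)
      if (sum(ph) == 0) ph[7] <- 1
      ph <- ph / sum(ph)
      th <- sort(sample(1:254, 2))
      expect_gte(kapur_objective(ph, th), 0)
    }
  })
  two <- rep(0, 256); two[c(10, 200)] <- 0.5
  expect_equal(kapur_objective(two, 100), 0) # one occupied bin per class
  expect_gt(kapur_objective(two, 250), 0)    # both bins in one class
})

test_that("the optimizer-driven threshold search attains the exhaustive optimum", {
  img <- bimodal_image(seed = 7)
  ex2 <- exhaustive_thresholds(img, 2)
  th2 <- find_thresholds(img, 2, igwo_config(seed = 11), repeats = 5)
  expect_equal(attr(th2, "J"), attr(ex2, "J"), tolerance = 1e-9)
  ex3 <- exhaustive_thresholds(img, 3)
  th3 <- find_thresholds(img, 3, igwo_config(seed = 12), repeats = 5)
  expect_lte(attr(th3, "J"), attr(ex3, "J") + 1e-12) # never above the oracle
  expect_equal(attr(th3, "J"), attr(ex3, "J"), tolerance = 1e-6)
  expect_equal(length(th3), 2L)
  expect_true(all(diff(th3) > 0))
  expect_error(find_thresholds(img, 1), "at least 2")
})

test_that("threshold application uses the upper-class boundary convention", {
  img <- matrix(c(0, 127, 128, 255), 2, 2)
  cls <- apply_thresholds(img, 128)
  expect_equal(as.vector(cls), c(1L, 1L, 2L, 2L)) # v >= th -> upper class
  full <- matrix(0:255, 16, 16)
  cls3 <- apply_thresholds(full, c(85, 170))
  expect_setequal(unique(as.vector(cls3)), 1:3)
  expect_equal(sum(cls3 == 1), 85)  # 0..84
  expect_equal(sum(cls3 == 2), 85)  # 85..169
  expect_equal(sum(cls3 == 3), 86)  # 170..255
  expect_lte(length(unique(as.vector(cls3))), 3)
})

test_that("lesion segmentation recovers the generated ground truth", {
  les <- make_lesion_image(benign_lesion_params(96), seed = 5)
  pp <- preprocess_image(les$image)
  mask <- segment_lesion(pp, opt = igwo_config(pop_size = 20, max_iter = 60,
                                               seed = 3), repeats = 3)
  expect_gte(mask_iou(mask, les$mask), 0.9)
  expect_lte(max(label_components(mask)), 1L) # single connected component
})

test_that("bright-foreground mode mirrors the dark case exactly", {
  les <- make_lesion_image(benign_lesion_params(64), seed = 6)
  pp <- preprocess_image(les$image, hair_element = 0)
  g <- rgb_to_gray(pp)
  dark <- segment_lesion(g, opt = igwo_config(pop_size = 15, max_iter = 40,
                                              seed = 2), repeats = 3)
  bright <- segment_lesion(255 - g, foreground = "bright",
                           opt = igwo_config(pop_size = 15, max_iter = 40,
                                             seed = 2), repeats = 3)
  expect_equal(mask_iou(dark, les$mask), mask_iou(bright, les$mask))
})

test_that("isolated dark pixels leave an empty mask with a warning", {
  # salt noise: the dark class exists but every member is isolated, so the
  # morphological opening erases the entire foreground
  img <- withr::with_seed(13, {
    x <- matrix(quant8(200 + rnorm(256, sd = 8)), 16, 16)
    for (r in seq(2, 16, by = 3)) for (cc in seq(2, 16, by = 3)) {
      x[r, cc] <- quant8(40 + rnorm(1, sd = 8))
    }
    x
  })
  expect_warning(m <- segment_lesion(img, opt = igwo_config(pop_size = 10,
                                                            max_iter = 30,
                                                            seed = 1),
                                     repeats = 2),
                 "empty foreground")
  expect_false(any(m))
})

test_that("mask IoU behaves at the boundaries", {
  a <- matrix(c(TRUE, FALSE, FALSE, FALSE), 2, 2)
  expect_equal(mask_iou(a, a), 1)
  expect_equal(mask_iou(a, !a), 0)
  e <- matrix(FALSE, 2, 2)
  expect_equal(mask_iou(e, e), 1)
})
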