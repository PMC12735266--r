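# Small hand-built fixture: 7x7 maps, one provided annotation, kernel 3.
pl_fixture <- function(cpre) {
  loc <- matrix(0, 7, 7); loc[2, 2] <- 1
  cgt <- make_count_map(loc, 3)
  list(cgt = cgt, mask = positive_mask(cgt),
       losses = unlabeled_losses(cpre, cgt))
}

with_posterior <- function(peaks, post) {
  peaks$posterior <- post
  peaks
}

test_that("a silent prediction leaves only provided positives and clear negatives", {
  cpre <- matrix(0, 7, 7)
  f <- pl_fixture(cpre)
  pk <- with_posterior(find_peaks(matrix(0, 7, 7), 3), numeric(0))
  part <- partition_unlabeled(pk, f$losses, f$mask)
  expect_equal(unname(part$counts["predicted_positive"]), 0)
  expect_equal(unname(part$counts["provided_positive"]), 9)
  expect_equal(unname(part$counts["clear_negative"]), 49 - 9)
  expect_equal(unname(part$counts["ignored"]), 0)
})

test_that("confident peaks become predicted positives, doubtful ones are ignored", {
  # a strong response far from the annotation
  ppre <- matrix(0, 7, 7); ppre[6, 6] <- 1
  cpre <- make_count_map(ppre, 3)
  f <- pl_fixture(cpre)
  pk <- find_peaks(ppre, 3)
  part <- partition_unlabeled(with_posterior(pk, 0.99), f$losses, f$mask,
                              tau_pos = 0.95, tau_neg = 0.05)
  expect_equal(part$codes[6, 6], "predicted_positive")
  part2 <- partition_unlabeled(with_posterior(pk, 0.5), f$losses, f$mask)
  expect_equal(part2$codes[6, 6], "ignored")
  part3 <- partition_unlabeled(with_posterior(pk, 0.01), f$losses, f$mask)
  expect_equal(part3$codes[6, 6], "predicted_negative")
  expect_error(partition_unlabeled(with_posterior(pk, 0.5), f$losses,
                                   f$mask, tau_pos = 0.2, tau_neg = 0.5),
               "tau")
})

test_that("provided labels win over coinciding or adjacent peaks", {
  ppre <- matrix(0, 7, 7); ppre[2, 2] <- 1   # peak on the annotation
  cpre <- make_count_map(ppre, 3)
  f <- pl_fixture(cpre)
  pk <- find_peaks(ppre, 3)
  part <- partition_unlabeled(with_posterior(pk, 0.99), f$losses, f$mask)
  expect_equal(part$peaks$set, "provided_positive")
  expect_equal(unname(part$counts["predicted_positive"]), 0)
  # a peak just within ceil(r/2) of the annotation is absorbed too
  ppre2 <- matrix(0, 7, 7); ppre2[4, 3] <- 1
  f2 <- pl_fixture(make_count_map(ppre2, 3))
  pk2 <- find_peaks(ppre2, 3)
  part2 <- partition_unlabeled(with_posterior(pk2, 0.99), f2$losses,
                               f2$mask)
  expect_equal(part2$peaks$set, "provided_positive")
})

test_that("the partition is a disjoint cover of the grid", {
  set.seed(31)
  for (i in 1:10) {
    ppre <- matrix(runif(49) * (runif(49) < 0.2), 7, 7)
    cpre <- make_count_map(ppre, 3)
    f <- pl_fixture(cpre)
    pk <- find_peaks(ppre, 3, min_value = 1e-6)
    pk <- with_posterior(pk, runif(nrow(pk)))
    part <- partition_unlabeled(pk, f$losses, f$mask,
                                tau_pos = 0.7, tau_neg = 0.3)
    expect_equal(sum(part$counts), 49)   # codes cover every coordinate
    expect_true(all(part$codes %in% pulocalize:::PART_LEVELS))
  }
})

test_that("the refinement loss matches hand evaluation and ignores the ignored", {
  codes <- matrix("predicted_negative", 5, 5)
  codes[2, 2] <- "provided_positive"
  part <- structure(list(codes = codes), class = "pseudo_partition")
  cpre <- matrix(0, 5, 5)
  expect_equal(pn_loss(cpre, part), 1 / 25)
  cpre[2, 2] <- 1
  expect_equal(pn_loss(cpre, part), 0)
  # an ignored coordinate contributes nothing
  codes2 <- codes; codes2[5, 5] <- "ignored"
  part2 <- structure(list(codes = codes2), class = "pseudo_partition")
  cpre2 <- cpre; cpre2[5, 5] <- 3
  expect_equal(pn_loss(cpre2, part2), pn_loss(cpre, part))
  # empty positive set is signaled
  part3 <- structure(list(codes = matrix("clear_negative", 5, 5)),
                     class = "pseudo_partition")
  expect_error(pn_loss(cpre, part3), class = "pulocalize_no_positives")
})

test_that("the loss falls as counts move toward their targets", {
  codes <- matrix("predicted_negative", 5, 5)
  codes[c(3, 18)] <- "predicted_positive"
  part <- structure(list(codes = codes), class = "pseudo_partition")
  base <- matrix(0.4, 5, 5)
  steps_pos <- vapply(seq(0.4, 1, by = 0.2), function(v) {
    m <- base; m[codes == "predicted_positive"] <- v; pn_loss(m, part)
  }, numeric(1))
  expect_true(all(diff(steps_pos) < 0))
  steps_neg <- vapply(seq(0.4, 0, by = -0.2), function(v) {
    m <- base; m[codes == "predicted_negative"] <- v; pn_loss(m, part)
  }, numeric(1))
  expect_true(all(diff(steps_neg) < 0))
  # gradient agrees with finite differences
  g <- pulocalize:::pn_loss_with_grad(base, part)
  h <- 1e-6
  for (idx in c(3, 7, 18)) {
    bp <- base; bp[idx] <- base[idx] + h
    bm <- base; bm[idx] <- base[idx] - h
    expect_equal(g$grad[idx], (pn_loss(bp, part) - pn_loss(bm, part)) / (2 * h),
                 tolerance = 1e-5)
  }
})

test_that("partition audit dumps are readable CSV", {
  ppre <- matrix(0, 7, 7); ppre[6, 6] <- 1
  f <- pl_fixture(make_count_map(ppre, 3))
  pk <- with_posterior(find_peaks(ppre, 3), 0.99)
  part <- partition_unlabeled(pk, f$losses, f$mask)
  path <- tempfile(fileext = ".csv")
  write_partition_csv(part, path)
  df <- read.csv(path)
  expect_equal(names(df), c("row", "col", "set"))
  expect_true("predicted_positive" %in% df$set)
  expect_equal(sum(df$set == "provided_positive"), 9)
})

test_that("an oracle posterior reduces refinement to supervised PN labels", {
  # perfect predictor: the location map equals the full ground truth
  sc <- generate_scene(scene_config(height = 48, width = 48,
                                    n_objects = 6, labeled_count = 2,
                                    noise_sd = 0), seed = 17)
  loc_full <- location_map_from_points(sc$centers, 48, 48)
  loc_part <- location_map_from_points(sc$labeled, 48, 48)
  r <- 5
  cpre <- make_count_map(loc_full, r)
  cgt <- make_count_map(loc_part, r)
  mask <- positive_mask(cgt)
  losses <- unlabeled_losses(cpre, cgt)
  pk <- find_peaks(loc_full, r)
  key <- paste(sc$labeled$row, sc$labeled$col)
  is_lab <- paste(pk$row, pk$col) %in% key
  pk$posterior <- ifelse(is_lab, 0, 1)   # oracle: hidden positives = 1
  part <- partition_unlabeled(pk, losses, mask)
  # every true center ends up in the positive set
  pos <- part$codes[cbind(sc$centers$row + 1, sc$centers$col + 1)]
  expect_true(all(pos %in% c("provided_positive", "predicted_positive")))
  expect_equal(unname(part$counts["predicted_positive"]),
               nrow(sc$centers) - nrow(sc$labeled))
})
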