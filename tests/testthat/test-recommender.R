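test_that("the product-moment correlation matches closed forms and the base oracle", {
  x <- c(1, 5, 2, 9)
  expect_equal(pearson(x, x), 1.0, tolerance = 1e-12)
  expect_equal(pearson(x, -x), -1.0, tolerance = 1e-12)
  # frozen from the independent oracle stats::cor()
  expect_equal(pearson(c(1, 2, 3, 4), c(2, 4, 5, 4)), 0.7181848, tolerance = 1e-3)
  set.seed(1)
  a <- stats::rnorm(50)
  b <- stats::rnorm(50)
  expect_equal(pearson(a, b), stats::cor(a, b), tolerance = 1e-12)
  expect_error(pearson(a, b[1:10]), "unequal")
  expect_error(pearson(rep(1, 5), 1:5), "zero variance")
})

test_that("the linkage map recovers planted correlations and is symmetric", {
  cfg <- synth_config(
    n_subjects = 4, n_samples = 64, noise_sd = 0,
    corr_spec = list(list("sleep", "hrv", 1.0))
  )
  lm0 <- build_linkage_map(generate_dataset(cfg, seed = 1))
  expect_equal(lm0$r["sleep", "hrv"], 1.0, tolerance = 1e-9)
  expect_identical(lm0$r, t(lm0$r))
  expect_equal(unname(diag(lm0$r)), rep(1, 5))

  cfg2 <- synth_config(
    n_subjects = 500, n_samples = 256, noise_sd = 0.5,
    corr_spec = list(list("sleep", "hrv", 0.7))
  )
  lm2 <- build_linkage_map(generate_dataset(cfg2, seed = 2))
  expect_lt(abs(lm2$r["sleep", "hrv"] - 0.7), 0.08)
  # unplanted pairs stay near zero (orthogonal base frequencies)
  expect_lt(abs(lm2$r["motion", "blood"]), 0.1)
  expect_error(build_linkage_map(generate_dataset(tiny_synth(1), seed = 1)), ">= 2 subjects")
})

test_that("the summary-mode linkage map accepts a custom summarizer", {
  ds <- generate_dataset(tiny_synth(10), seed = 3)
  lm <- build_linkage_map(ds, method = "summary", summarizer = function(s) max(s$values))
  expect_identical(dim(lm$r), c(5L, 5L))
  expect_identical(lm$r, t(lm$r))
})

test_that("fuzzy c-means recovers planted clouds with normalised memberships", {
  set.seed(10)
  pts <- rbind(
    matrix(stats::rnorm(40, mean = 0, sd = 0.05), 20, 2),
    matrix(stats::rnorm(40, mean = 5, sd = 0.05), 20, 2)
  )
  res <- fcm(pts, k = 2, seed = 1)
  expect_equal(rowSums(res$membership), rep(1, 40), tolerance = 1e-9)
  expect_true(all(apply(res$membership, 1, max) >= 0.99))
  expect_length(unique(res$cluster[1:20]), 1L)
  expect_length(unique(res$cluster[21:40]), 1L)
  expect_true(res$cluster[1] != res$cluster[21])
  # objective is non-increasing at every iteration
  expect_true(all(diff(res$objective) <= 1e-8))
})

test_that("fuzzy c-means agrees with an independent implementation on clean data", {
  skip_if_not_installed("e1071")
  set.seed(11)
  pts <- rbind(
    matrix(stats::rnorm(30, mean = -3, sd = 0.1), 15, 2),
    matrix(stats::rnorm(30, mean = 3, sd = 0.1), 15, 2)
  )
  ours <- fcm(pts, k = 2, seed = 2)
  ref <- e1071::cmeans(pts, centers = 2, m = 2)
  ref_cent <- ref$centers[order(ref$centers[, 1]), ]
  our_cent <- ours$centroids[order(ours$centroids[, 1]), ]
  expect_equal(unname(our_cent), unname(ref_cent), tolerance = 1e-3)
})

test_that("fcm objective decreases monotonically on unstructured data", {
  set.seed(12)
  pts <- stats::rnorm(40)
  for (s in 1:5) {
    res <- fcm(pts, k = 3, seed = s)
    expect_equal(rowSums(res$membership), rep(1, 40), tolerance = 1e-9)
    expect_true(all(diff(res$objective) <= 1e-8))
  }
  expect_error(fcm(1:5, k = 6), "at least k")
  expect_error(fcm(1:5, k = 1), "k must be")
})

test_that("support parameters follow the cluster-geometry formulas", {
  mk_fcm <- function(points, cluster, centroids) {
    structure(
      list(
        centroids = centroids, cluster = cluster,
        membership = NULL, objective = 0, fuzziness = 2,
        points = matrix(points, ncol = 1L)
      ),
      class = "fcm_result"
    )
  }
  # two singleton clusters at distance 3: Minter = 9, Mintra = 0,
  # Fsup = 0 -> Minsup hits the 0.01 floor
  f <- mk_fcm(c(0, 3), c(1L, 2L), matrix(c(0, 3), 2, 1))
  sp <- expect_warning(support_params(f, c(0.2, 0.8)), NA)
  expect_equal(sp$Minter, 9)
  expect_equal(sp$Mintra, 0)
  expect_equal(sp$Fsup, 0)
  expect_equal(sp$Minsup, 0.01)

  # STD(x) == VAR(x) (sd = 1) makes the dispersion ratio 1: Minsup = Fsup
  x_unit <- c(0, 2) / sqrt(2) # sd exactly 1
  f2 <- mk_fcm(c(0, 1, 10, 11), c(1L, 1L, 2L, 2L), matrix(c(0.5, 10.5), 2, 1))
  sp2 <- support_params(f2, x_unit)
  expect_equal(sp2$Fsup, (1 + 1) / 100)
  expect_equal(sp2$Minsup, sp2$Fsup)

  # random instance against a direct pairwise-loop oracle
  set.seed(13)
  pts <- stats::rnorm(20)
  res <- fcm(pts, k = 2, seed = 3)
  sp3 <- support_params(res, pts)
  minter <- sum((res$centroids[1, ] - res$centroids[2, ])^2)
  mintra <- 0
  for (j in 1:2) {
    idx <- which(res$cluster == j)
    if (length(idx) >= 2) {
      for (a in seq_len(length(idx) - 1)) {
        for (b in (a + 1):length(idx)) {
          mintra <- mintra + (pts[idx[a]] - pts[idx[b]])^2
        }
      }
    }
  }
  expect_equal(sp3$Minter, minter, tolerance = 1e-10)
  expect_equal(sp3$Mintra, mintra, tolerance = 1e-10)
  expect_equal(sp3$Fsup, mintra / minter, tolerance = 1e-10)

  # coincident centroids are an error
  f4 <- mk_fcm(c(0, 1), c(1L, 2L), matrix(c(2, 2), 2, 1))
  expect_error(support_params(f4, c(0.5)), "Minter")
})

test_that("apriori respects unanimity, downward closure and brute-force equality", {
  tx <- list(c("a", "b"), c("a", "b", "c"), c("a", "c"))
  full <- apriori(tx, minsup = 1.0)
  expect_identical(itemset_keys(full)$keys, "a") # only 'a' is in every transaction

  set.seed(14)
  for (case in 1:30) {
    n_items <- sample(3:8, 1)
    items <- letters[seq_len(n_items)]
    tx <- lapply(seq_len(sample(5:15, 1)), function(i) {
      sample(items, sample.int(n_items, 1))
    })
    minsup <- sample(c(0.2, 0.34, 0.5), 1)
    got <- apriori(tx, minsup)
    # downward closure: every subset of a frequent set is frequent
    keys <- vapply(got$items, paste, "", collapse = ",")
    for (j in seq_len(nrow(got))) {
      s <- got$items[[j]]
      if (length(s) > 1) {
        for (drop in seq_along(s)) {
          expect_true(paste(s[-drop], collapse = ",") %in% keys)
        }
      }
    }
    ref <- oracle_apriori(tx, minsup)
    gotk <- itemset_keys(got)
    expect_identical(gotk$keys, ref$keys)
    expect_equal(gotk$support, ref$support, tolerance = 1e-12)
  }
  expect_identical(nrow(apriori(list(), 0.5)), 0L)
  expect_error(apriori(list("a"), 0), "minsup")
})

test_that("itemization requires both deviation and a correlated linkage cell", {
  summaries <- rbind(
    S1 = c(sleep = 5, hrv = 0, motion = 9),
    S2 = c(sleep = 0, hrv = 0, motion = 0),
    S3 = c(sleep = 0, hrv = 0, motion = 0),
    S4 = c(sleep = 0, hrv = 0, motion = 9)
  )
  r <- diag(1, 3)
  dimnames(r) <- list(colnames(summaries), colnames(summaries))
  r["sleep", "hrv"] <- r["hrv", "sleep"] <- 0.9
  linkage <- structure(
    list(categories = colnames(summaries), r = r, n = r * 0 + 4),
    class = "linkage_map"
  )
  tx <- build_transactions(summaries, linkage, minsup = 0.5)
  # sleep deviates for S1 and is in a correlated cell -> item;
  # motion deviates but sits in no correlated cell -> never an item
  expect_identical(tx$S1, "sleep")
  expect_identical(tx$S2, character(0))
  expect_identical(tx$S4, character(0))
})

test_that("red/blue flagging partitions categories and respects co-occurrence", {
  linkage <- structure(
    list(categories = c("a", "b", "c"), r = diag(1, 3), n = diag(3)),
    class = "linkage_map"
  )
  summaries <- matrix(
    c(1, 0, 0, 2, 0, 0), 2, 3,
    byrow = TRUE, dimnames = list(c("S1", "S2"), c("a", "b", "c"))
  )
  its <- apriori(list(c("a"), c("a")), 0.5)
  tx <- list(S1 = "a", S2 = "a")

  # all predictions LE: nothing co-occurs with ME/HE -> everything blue
  preds_le <- data.frame(effect = c(1L, 1L), effect_label = c("LE", "LE"))
  rep_le <- flag_and_recommend(linkage, its, preds_le, tx, summaries)
  expect_identical(rep_le$red, character(0))
  expect_identical(sort(rep_le$blue), c("a", "b", "c"))
  expect_identical(nrow(rep_le$suggestions), 0L)

  # one HE subject carrying the itemset turns 'a' red
  preds_he <- data.frame(effect = c(3L, 1L), effect_label = c("HE", "LE"))
  rep_he <- flag_and_recommend(linkage, its, preds_he, tx, summaries)
  expect_identical(rep_he$red, "a")
  expect_identical(sort(c(rep_he$red, rep_he$blue)), c("a", "b", "c"))
  expect_length(intersect(rep_he$red, rep_he$blue), 0L)
  # only the above-median subject gets a suggestion, red-linked get weight 2
  expect_identical(rep_he$suggestions$subject_id, "S2")
  expect_equal(unname(rep_he$weights), c(2, 2))
  expect_error(
    flag_and_recommend(linkage, its, preds_he[0, ], tx, summaries),
    "no predictions"
  )
})
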