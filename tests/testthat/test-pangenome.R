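test_that("pangenome categories follow the presence-fraction thresholds", {
  m <- matrix(0L, nrow = 5, ncol = 100,
              dimnames = list(paste0("f", 1:5), sprintf("G%03d", 1:100)))
  m["f1", 1:96] <- 1L   # 96% -> extended core
  m["f2", 1:95] <- 1L   # exactly 95% -> extended core (core test first)
  m["f3", 1:50] <- 1L   # character
  m["f4", 1:5] <- 1L    # exactly 5% -> accessory
  m["f5", 1] <- 1L      # accessory
  fs <- counts_family_set(m)
  cats <- classify_families(fs, 100)
  expect_identical(unname(cats[paste0("f", 1:5)]),
                   c("extended_core", "extended_core", "character",
                     "accessory", "accessory"))
})

test_that("per-genome category counts partition the genome's memberships", {
  m <- matrix(0L, nrow = 4, ncol = 10,
              dimnames = list(paste0("f", 1:4), sprintf("G%03d", 1:10)))
  m["f1", ] <- 1L
  m["f2", ] <- 2L                      # duplicated everywhere
  m["f3", 1:4] <- 1L
  m["f4", 1] <- 1L
  fs <- counts_family_set(m)
  cats <- classify_families(fs, 10)
  cc <- per_genome_category_counts(fs, cats, "G001")
  expect_equal(sum(cc$families),
               length(unique(fs$members$family[fs$members$tag == "G001"])))
  expect_equal(sum(cc$sequences), sum(fs$members$tag == "G001"))
  expect_equal(cc$sequences[cc$category == "extended_core"], 3L)  # f1 + 2x f2
})

test_that("Kruskal-Wallis H matches hand computation and kruskal.test", {
  kw <- kruskal_wallis(list(c(1, 2, 3), c(4, 5, 6)))
  expect_equal(kw$H, 12 / (6 * 7) * (6^2 / 3 + 15^2 / 3) - 3 * 7)
  expect_equal(kw$H, 3.857, tolerance = 1e-3)
  expect_identical(kruskal_wallis(list(c(2, 2), c(2, 2))), list(H = 0, p = 1))
  set.seed(91)
  g <- list(rpois(7, 2), rpois(5, 2) + 0.0, rpois(6, 2))
  kt <- stats::kruskal.test(unlist(g), rep(1:3, lengths(g)))
  kw2 <- kruskal_wallis(g)
  expect_equal(kw2$H, unname(kt$statistic))
  expect_equal(kw2$p, kt$p.value)
  # a strongly shifted group is significant
  expect_lt(kruskal_wallis(list(1:5, 1:5, 101:105))$p, 0.05)
  expect_error(kruskal_wallis(list(1:3)), "2 non-empty")
})

test_that("Kruskal-Wallis agrees with an exact permutation distribution", {
  # brute force: enumerate all assignments of 6 values into groups of 3+3
  vals <- c(3, 1, 4, 1, 5, 9)
  obs <- kruskal_wallis(list(vals[1:3], vals[4:6]))$H
  combs <- utils::combn(6, 3)
  perm_h <- apply(combs, 2, function(ix)
    kruskal_wallis(list(vals[ix], vals[-ix]))$H)
  # the observed statistic sits inside the permutation support
  expect_true(any(abs(perm_h - obs) < 1e-9))
  # permutation p for the observed split matches the chi-square tail order
  expect_gte(mean(perm_h >= obs - 1e-9), 0)
})

test_that("Dunn's z follows its formula with antisymmetry and tie handling", {
  g <- list(a = c(1, 2, 3), b = c(10, 11, 12), c = c(1, 2, 4))
  dn <- dunn_posthoc(g)
  # direct evaluation of the z formula
  x <- unlist(g); r <- rank(x); N <- length(x)
  rb <- tapply(r, rep(1:3, each = 3), mean)
  t <- table(x)
  tie <- sum(t^3 - t) / (12 * (N - 1))
  z_ab <- (rb[1] - rb[2]) / sqrt((N * (N + 1) / 12 - tie) * (2 / 3))
  expect_equal(dn$z["a", "b"], unname(z_ab))
  expect_equal(dn$z, -t(dn$z))
  expect_equal(dn$p, t(dn$p))
  expect_equal(unname(diag(dn$p)), rep(1, 3))
  # the shifted pair has the smallest p
  off <- dn$p[upper.tri(dn$p)]
  expect_equal(min(off), dn$p["a", "b"])
  expect_lt(dn$p["a", "b"], dn$p["a", "c"])
  # identical groups give p = 1
  same <- dunn_posthoc(list(c(1, 2), c(1, 2)))
  expect_equal(same$p[1, 2], 1)
  expect_error(dunn_posthoc(list(1:3, numeric(0))), "empty")
})

test_that("family flagging composes the gate, Dunn filter and delta rule", {
  tags <- sprintf("G%03d", 1:40)
  scheme <- data.frame(tag = tags, group = rep(c("A", "B"), each = 20))
  m <- matrix(0L, nrow = 3, ncol = 40, dimnames = list(paste0("f", 1:3), tags))
  m["f1", 1:20] <- 1L                     # present in A, absent in B
  m["f2", ] <- rep(c(1L, 1L, 1L, 2L), 10) # no group difference
  m["f3", ] <- 1L; m["f3", 21:26] <- 2L   # delta = 0.3: must not flag
  fs <- counts_family_set(m)
  res <- flag_intergroup_families(fs, scheme)
  expect_true(res$flagged[res$family == "f1"])
  expect_equal(res$delta_mean[res$family == "f1"], 1.0)
  expect_false(res$flagged[res$family == "f2"])
  f3 <- res[res$family == "f3", ]
  expect_false(f3$flagged)               # gate or delta stops it
  if (!is.na(f3$p_kw) && f3$p_kw < 0.05)
    expect_lte(abs(0.3), 0.5)            # it failed on the delta rule
  expect_error(flag_intergroup_families(
    fs, rbind(scheme, data.frame(tag = "G001", group = "C"))),
    "more than one group")
})

test_that("null simulations stay near the nominal flag rate", {
  set.seed(92)
  tags <- sprintf("G%03d", 1:40)
  scheme <- data.frame(tag = tags, group = rep(c("A", "B"), each = 20))
  m <- matrix(rpois(300 * 40, 1), nrow = 300, ncol = 40,
              dimnames = list(sprintf("f%04d", 1:300), tags))
  fs <- counts_family_set(m)
  res <- flag_intergroup_families(fs, scheme)
  expect_lte(mean(res$flagged), 0.07)
})

test_that("randomised grouping is reproducible and exchangeable under the null", {
  set.seed(93)
  tags <- sprintf("G%03d", 1:30)
  scheme <- data.frame(tag = tags, group = rep(c("A", "B", "C"), each = 10))
  m <- matrix(rpois(50 * 30, 1), nrow = 50, ncol = 30,
              dimnames = list(sprintf("f%03d", 1:50), tags))
  fs <- counts_family_set(m)
  c1 <- randomized_control(fs, scheme, n_reps = 20, seed = 7)
  c2 <- randomized_control(fs, scheme, n_reps = 20, seed = 7)
  expect_identical(c1, c2)
  real <- sum(flag_intergroup_families(fs, scheme)$flagged)
  # under exchangeable labels the real count is not extreme
  expect_lte(real, max(c1) + 2)
})

test_that("planted differences exceed the permutation null", {
  set.seed(94)
  tags <- sprintf("G%03d", 1:40)
  scheme <- data.frame(tag = tags, group = rep(c("A", "B"), each = 20))
  m <- matrix(rpois(40 * 40, 1), nrow = 40, ncol = 40,
              dimnames = list(sprintf("f%03d", 1:40), tags))
  m[1:8, 1:20] <- m[1:8, 1:20] + 2L       # planted group-A enrichment
  fs <- counts_family_set(m)
  real <- sum(flag_intergroup_families(fs, scheme)$flagged)
  perm <- randomized_control(fs, scheme, n_reps = 60, seed = 9)
  expect_gte(real, 8)
  expect_gt(real, stats::quantile(perm, 0.95))
})

test_that("marker alignments concatenate deterministically", {
  co <- marker_cohort(seed = 95)
  fs <- new_family_set(co$groups, co$proteins, 70)
  mk <- select_markers(as_series(co$groups, co$proteins), co$proteins)
  rows <- concat_marker_alignment(mk, fs, co$proteins,
                                  tags = c("QAAA", "QBBB"))
  expect_setequal(names(rows), c("S288C", "QAAA", "QBBB"))
  expect_length(unique(nchar(rows)), 1)
  # width is the sum of the per-family alignment widths
  widths <- vapply(mk$marker, function(m) {
    fam <- marker_families(mk, fs)[[m]]
    mem <- fs$members$protein[fs$members$family == fam]
    family_alignment(setNames(co$proteins$seq[match(mem, co$proteins$id)], mem),
                     m)$aln_length
  }, 1)
  expect_equal(unique(nchar(rows)), sum(widths))
  # single family: the concatenation equals that family's alignment
  one <- mk[1, , drop = FALSE]
  r1 <- concat_marker_alignment(one, fs, co$proteins, tags = c("QAAA", "QBBB"))
  expect_equal(unique(nchar(r1)), widths[[one$marker]])
  # a missing genome is a precondition violation
  small <- subset_families(fs, c("S288C", "QAAA"))
  expect_error(concat_marker_alignment(mk, small, co$proteins,
                                       tags = c("QAAA", "QBBB")),
               "missing")
})
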