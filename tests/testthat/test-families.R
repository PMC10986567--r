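test_that("pairwise similarity follows the identity/coverage definitions", {
  set.seed(61)
  p <- random_protein(100)
  tab <- data.frame(id = c("full", "twin", "half"),
                    seq = c(p, p, substr(p, 1, 50)))
  e <- pairwise_search(tab)
  twin <- e[e$a == "full" & e$b == "twin", ]
  expect_equal(twin$identity, 100)
  expect_equal(twin$a_cov, 100)
  expect_equal(twin$b_cov, 100)
  half <- e[e$a == "full" & e$b == "half", ]
  expect_equal(half$identity, 100)
  expect_equal(half$a_cov, 50)
  expect_equal(half$b_cov, 100)
  # no self-hits, one row per unordered pair
  expect_equal(nrow(e), 3)
  expect_false(any(e$a == e$b))
})

test_that("unrelated proteins never qualify at cutoff 50", {
  set.seed(62)
  tab <- data.frame(id = paste0("u", 1:6),
                    seq = vapply(1:6, function(i) random_protein(100), ""))
  e <- pairwise_search(tab)
  qual <- e$identity > 50 & e$a_cov > 50 & e$b_cov > 50
  expect_false(any(qual))
})

test_that("single linkage chains strictly-qualifying edges", {
  ids <- c("A", "B", "C")
  edges <- data.frame(a = c("A", "B"), b = c("B", "C"),
                      identity = c(95, 92), a_cov = c(96, 91),
                      b_cov = c(97, 94))
  expect_equal(single_linkage(ids, edges, 90), list(c("A", "B", "C")))
  expect_equal(single_linkage(ids, edges, 93), list(c("A", "B"), "C"))
  expect_equal(single_linkage(ids, edges[0, ], 50),
               list("A", "B", "C"))
  # boundary: identity exactly at the cutoff does not qualify
  eq <- data.frame(a = "A", b = "B", identity = 90, a_cov = 95, b_cov = 95)
  expect_equal(single_linkage(c("A", "B"), eq, 90), list("A", "B"))
})

test_that("blastn proteins join their parent's family regardless of identity", {
  set.seed(63)
  ref <- data.frame(id = c("g1", "g2"), tag = "S288C",
                    seq = c(random_protein(100), random_protein(100)))
  # deliberately unrelated sequence, but parented to g1
  bl <- data.frame(id = "q1_g1", tag = "Q001", seq = random_protein(100),
                   parent = "g1")
  groups <- build_initial_families(ref, bl, bl[0, ], cutoff = 70)
  fam_of_g1 <- groups[[which(vapply(groups, function(g) "g1" %in% g, TRUE))]]
  expect_true("q1_g1" %in% fam_of_g1)
  bad <- data.frame(id = "qx", tag = "Q001", seq = random_protein(50),
                    parent = "nope")
  expect_error(build_initial_families(ref, bad, bad[0, ], 70),
               "unknown parent")
})

test_that("maker proteins join their best qualifying reference family", {
  set.seed(64)
  g1 <- random_protein(120); g2 <- random_protein(120)
  ref <- data.frame(id = c("g1", "g2"), tag = "S288C", seq = c(g1, g2))
  mk <- data.frame(id = c("m_near", "m_far", "m_twin1", "m_twin2"),
                   tag = "Q001",
                   seq = c(mutate_protein(g1, 0.1),   # close to g1
                           random_protein(120),        # no reference hit
                           rep(random_protein(110), 2)),
                   parent = NA_character_)
  groups <- build_initial_families(ref, ref[0, ], mk, cutoff = 70)
  fam_of <- function(x) which(vapply(groups, function(g) x %in% g, TRUE))
  expect_equal(fam_of("m_near"), fam_of("g1"))
  expect_true(fam_of("m_far") != fam_of("g1") && fam_of("m_far") != fam_of("g2"))
  # the two leftover identical maker proteins cluster together
  expect_equal(fam_of("m_twin1"), fam_of("m_twin2"))
})

test_that("related initial families merge through qualifying member pairs", {
  set.seed(65)
  base <- random_protein(150)
  # two families whose representatives are ~88% identical; a member pair is
  # nearly identical, so the pair must merge at cutoff 90 via prefilter > 80
  fam_a <- c(rep1 = paste0(base, random_protein(30)),       # longest: rep
             close = mutate_protein(base, 0.005))
  fam_b <- c(rep2 = paste0(mutate_protein(base, 0.12), random_protein(25)),
             close2 = mutate_protein(base, 0.01))
  prot <- data.frame(id = c(names(fam_a), names(fam_b)), tag = "T",
                     seq = c(unname(fam_a), unname(fam_b)))
  groups <- list(c("rep1", "close"), c("rep2", "close2"))
  merged <- merge_related_families(groups, prot, cutoff = 90)
  expect_length(merged, 1)
  expect_setequal(merged[[1]], prot$id)
  # a single family passes through unchanged
  expect_identical(merge_related_families(groups[1], prot, 90), groups[1])
})

test_that("the representative prefilter blocks distant family pairs", {
  set.seed(66)
  # representatives far below cutoff - 10: families must never be compared,
  # even though a member pair would qualify
  shared <- random_protein(100)
  prot <- data.frame(
    id = c("longA", "memA", "longB", "memB"), tag = "T",
    seq = c(paste0(random_protein(200)), shared,
            paste0(random_protein(210)), mutate_protein(shared, 0.01)))
  groups <- list(c("longA", "memA"), c("longB", "memB"))
  with_pf <- merge_related_families(groups, prot, cutoff = 90)
  expect_length(with_pf, 2)
  no_pf <- merge_related_families(groups, prot, cutoff = 90, prefilter = FALSE)
  expect_length(no_pf, 1)
})

test_that("family counts are non-decreasing in the cutoff", {
  set.seed(67)
  prot <- random_protein_set(n_seed = 5, copies_frac = c(0.05, 0.2, 0.4),
                             len = 100)
  series <- build_scf(prot, cutoffs = c(50, 60, 70, 80, 90))
  counts <- vapply(series, function(fs) length(unique(fs$members$family)), 1L)
  expect_true(all(diff(counts) >= 0))
  # partition property at every cutoff
  for (fs in series) {
    expect_setequal(fs$members$protein, prot$id)
    expect_false(anyDuplicated(fs$members$protein) > 0)
  }
})

test_that("identical proteomes collapse identically at every cutoff", {
  set.seed(68)
  seqs <- vapply(1:4, function(i) random_protein(90), "")
  prot <- do.call(rbind, lapply(c("G1", "G2", "G3"), function(tg)
    data.frame(id = paste0(tg, "_p", 1:4), tag = tg, seq = seqs,
               origin = "maker", parent = NA_character_)))
  series <- build_scf(prot, cutoffs = c(50, 90))
  counts <- vapply(series, function(fs) length(unique(fs$members$family)), 1L)
  expect_equal(unname(counts[1]), unname(counts[2]))
  expect_equal(unname(counts[1]), 4)
})

test_that("two-step clustering equals brute-force components (oracle)", {
  set.seed(69)
  for (rep in 1:6) {
    prot <- random_protein_set(n_seed = sample(3:5, 1),
                               copies_frac = c(0.03, 0.15, 0.35, 0.6),
                               len = sample(c(80, 120), 1))
    prot$origin <- sample(c("reference", "maker"), nrow(prot), replace = TRUE)
    if (!any(prot$origin == "reference")) prot$origin[1] <- "reference"
    edges <- pairwise_search(prot)
    for (cutoff in c(50, 70, 90)) {
      series <- build_scf(prot, cutoffs = cutoff, prefilter = FALSE,
                          edges = edges)
      got <- unname(family_groups <- split(series[[1]]$members$protein,
                                           series[[1]]$members$family))
      got <- lapply(got, sort)
      got <- got[order(vapply(got, `[[`, "", 1L))]
      expect_equal(got, components_oracle(prot$id, edges, cutoff))
    }
  }
})

test_that("the merge step never splits families", {
  set.seed(70)
  prot <- random_protein_set(n_seed = 4, copies_frac = c(0.05, 0.3), len = 100)
  prot$origin <- "maker"; prot$origin[1] <- "reference"
  edges <- pairwise_search(prot)
  for (cutoff in c(60, 80)) {
    initial <- build_initial_families(
      prot[prot$origin == "reference", ], prot[0, ],
      prot[prot$origin == "maker", ], cutoff, edges = edges)
    merged <- merge_related_families(initial, prot, cutoff, edges = edges)
    for (g in initial) {
      host <- vapply(merged, function(m) all(g %in% m), TRUE)
      expect_equal(sum(host), 1)
    }
  }
})

test_that("family tables round-trip through the TAB/| dialect", {
  set.seed(71)
  prot <- random_protein_set(n_seed = 3, copies_frac = c(0.02, 0.1), len = 80,
                             tags = c("S288C", "AAAA", "BBBB", "BCCC"))
  # a second homolog in the same assembly forces a multi-member cell
  extra <- prot[1, ]
  extra$id <- "p_dup"
  extra$seq <- mutate_protein(prot$seq[1], 0.02)
  prot <- rbind(prot, extra)
  fs <- build_scf(prot, cutoffs = 70)[[1]]
  path <- withr::local_tempfile(fileext = ".tsv")
  write_family_table(fs, path)
  back <- read_family_table(path)
  expect_equal(back$cutoff, 70)
  o <- function(m) m[order(m$family, m$tag, m$protein), ]
  expect_equal(o(back$members), o(fs$members), ignore_attr = TRUE)
  # multi-homolog cells use the pipe separator
  line <- readLines(path)
  expect_true(any(grepl("|", line, fixed = TRUE)))
})

test_that("subsetting a family set drops members and empty families", {
  members <- data.frame(
    family = c("SCF70_00001", "SCF70_00001", "SCF70_00002"),
    tag = c("AAAA", "BBBB", "BBBB"),
    protein = c("p1", "p2", "p3"))
  fs <- structure(list(cutoff = 70, label = "SCF70", members = members),
                  class = "family_set")
  sub <- subset_families(fs, "AAAA")
  expect_equal(sub$members$protein, "p1")
  expect_false("SCF70_00002" %in% sub$members$family)
  expect_equal(subset_families(fs, c("AAAA", "BBBB"))$members, members,
               ignore_attr = TRUE)
  expect_error(subset_families(fs, "ZZZZ"), "subset")
})
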