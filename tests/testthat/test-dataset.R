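# Pair dataset construction: positives, negatives, self-pairs, filters,
# condensate-aware splitting and rebalancing.

test_that("positive pairs enumerate within-condensate combinations", {
  cond <- condensate_table(rep("c1", 3L), c("A", "B", "C"))
  pos <- build_positive_pairs(cond)
  expect_equal(pos$id_a, c("A", "A", "B"))
  expect_equal(pos$id_b, c("B", "C", "C"))
  expect_true(all(pos$label == 1L))

  # single-member condensates contribute nothing
  cond1 <- condensate_table(c("c1", "c2", "c2"), c("X", "A", "B"))
  expect_equal(nrow(build_positive_pairs(cond1)), 1L)

  # shared pairs are deduplicated with unioned sources
  cond2 <- condensate_table(c(rep("c1", 3L), rep("c2", 3L)),
                            c("A", "B", "C", "B", "C", "D"))
  pos2 <- build_positive_pairs(cond2)
  expect_equal(nrow(pos2), 5L)
  bc <- pos2[pos2$id_a == "B" & pos2$id_b == "C", ]
  expect_equal(bc$sources, "c1,c2")

  # condensates above the size cap are skipped with a message
  big <- condensate_table(c(rep("c1", 3L), rep("c2", 2L)),
                          c("A", "B", "C", "D", "E"))
  expect_message(p <- build_positive_pairs(big, n_max = 2L), "skipping")
  expect_equal(nrow(p), 1L)
})

test_that("negative pairs are non-co-occurring members of small condensates", {
  cond <- condensate_table(c("c1", "c1", "c2", "c2"), c("A", "B", "C", "D"))
  neg <- build_negative_pairs(cond, m = 12L)
  expect_equal(paste(neg$id_a, neg$id_b),
               c("A C", "A D", "B C", "B D"))
  expect_true(all(neg$label == 0L))

  # a single condensate yields no negatives: all candidates co-occur
  expect_equal(nrow(build_negative_pairs(
    condensate_table(c("c1", "c1"), c("A", "B")), 12L)), 0L)

  # co-occurrence anywhere (even in a large condensate) disqualifies a pair
  cond2 <- condensate_table(
    c("c1", "c1", "c2", "c2", "big", "big", "big"),
    c("A", "B", "C", "D", "A", "C", "E")
  )
  neg2 <- build_negative_pairs(cond2, m = 2L)
  expect_false(any(neg2$id_a == "A" & neg2$id_b == "C"))
})

test_that("positive and negative labels never overlap and counts obey the closed form", {
  set.seed(31)
  for (rep in 1:5) {
    n_cond <- sample(3:6, 1L)
    cids <- unlist(lapply(seq_len(n_cond), function(i) {
      rep(paste0("c", i), sample(2:6, 1L))
    }))
    pids <- paste0("P", vapply(cids, function(x)
      sample(20L, 1L), integer(1L)))
    tab <- unique(data.frame(c = cids, p = pids))
    tab <- tab[!duplicated(tab), ]
    cond <- condensate_table(tab$c, tab$p)
    pos <- build_positive_pairs(cond, n_max = 50L)
    neg <- build_negative_pairs(cond, m = 12L)
    overlap <- intersect(paste(pos$id_a, pos$id_b), paste(neg$id_a, neg$id_b))
    expect_length(overlap, 0L)
    # with no shared pairs across condensates, |positives| = sum C(k, 2)
    sizes <- lengths(cond)
    if (nrow(pos) && all(!grepl(",", pos$sources))) {
      expect_equal(nrow(pos), sum(choose(sizes, 2L)))
    }
  }
})

test_that("the length filter excludes, not truncates, with an inclusive boundary", {
  recs <- protein_records(c("a", "b", "c"),
                          c(strrep("A", 500L), strrep("A", 1024L),
                            strrep("A", 1025L)))
  kept <- filter_by_length(recs, 1024L)
  expect_equal(kept$protein_id, c("a", "b"))
  expect_equal(kept$length, c(500L, 1024L))
  expect_equal(nrow(filter_by_length(recs[0L, ], 1024L)), 0L)
})

test_that("the length filter reproduces the 4,957 -> 4,135 profile", {
  # a synthetic proteome with the published length profile: 4,957 records
  # of which 822 exceed the 1,024-residue cap
  set.seed(14)
  lens <- c(sample(50:1024, 4957L - 822L, replace = TRUE),
            sample(1025:3000, 822L, replace = TRUE))
  lens <- sample(lens)
  recs <- data.frame(protein_id = sprintf("HP%04d", seq_along(lens)),
                     sequence = NA_character_, length = lens,
                     stringsAsFactors = FALSE)
  expect_equal(nrow(filter_by_length(recs, 1024L)), 4135L)
})

test_that("greedy redundancy filtering keeps longest representatives", {
  # identical sequences collapse to one record
  recs <- protein_records(c("a", "b"), c("ACDEFGHIKL", "ACDEFGHIKL"))
  expect_equal(nrow(redundancy_filter(recs, 0.5)), 1L)

  # totally dissimilar sequences both survive
  recs2 <- protein_records(c("a", "b"), c("AAAAAAAA", "CCCCCCCC"))
  expect_equal(sequence_identity("AAAAAAAA", "CCCCCCCC"), 0)
  expect_equal(nrow(redundancy_filter(recs2, 0.5)), 2L)

  # in a near-duplicate pair the shorter record is removed
  s_long <- "ACDEFGHIKLMNPQRSTVWY"
  s_near <- "ACDEFGHIKLMNPQ"        # prefix: high identity to s_long
  s_far <- "WYWYWYWYWYWY"
  id <- sequence_identity(s_long, s_near)
  expect_gt(id, 0.5)
  kept <- redundancy_filter(
    protein_records(c("near", "far", "long"), c(s_near, s_far, s_long)), 0.5)
  expect_setequal(kept$protein_id, c("long", "far"))

  # the comparator is pluggable
  all_same <- function(x, y) 1
  expect_equal(nrow(redundancy_filter(recs2, 0.5, identity_fun = all_same)), 1L)
})

test_that("self-pair expansion excludes PPI neighbours of condensate proteins", {
  cond <- condensate_table(c("c1", "c1"), c("A", "B"))
  ppi <- ppi_network("B", "C")
  pool <- protein_records(c("A", "B", "C", "D"),
                          c("ACDEFGHIKL", "MNPQRSTVWY", "ACACACACAC",
                            "WYWYWYWYWY"))
  sp <- build_self_pair_dataset(cond, ppi, pool)
  expect_true(all(sp$is_self_pair))
  expect_setequal(sp$id_a[sp$label == 1L], c("A", "B"))
  expect_equal(sp$id_a[sp$label == 0L], "D")  # C excluded via the B-C edge

  # with no PPI edges, every non-condensate protein is eligible
  sp2 <- build_self_pair_dataset(cond, ppi_network(character(), character()),
                                 pool)
  expect_setequal(sp2$id_a[sp2$label == 0L], c("C", "D"))

  # identical sequences in the negative pool collapse to one
  pool3 <- protein_records(c("A", "B", "C", "D"),
                           c("ACDEFGHIKL", "MNPQRSTVWY", "WYWYWYWYWY",
                             "WYWYWYWYWY"))
  sp3 <- build_self_pair_dataset(cond, ppi_network(character(), character()),
                                 pool3)
  expect_equal(sum(sp3$label == 0L), 1L)
})

test_that("condensate-aware splitting keeps each condensate on one side", {
  cond <- condensate_table(c(rep("c1", 3L), rep("c2", 3L)),
                           c("A", "B", "C", "D", "E", "F"))
  pairs <- build_positive_pairs(cond)
  sp <- split_by_condensate(pairs, cond, fraction = 0.5, seed = 1L)
  for (side in list(sp$train, sp$test)) {
    expect_true(all(side$sources %in% c("c1", "c2")))
    expect_length(unique(side$sources), 1L)
  }
  expect_error(split_by_condensate(pairs, cond, fraction = 1.2), "fraction")
})

test_that("no positive test pair shares a condensate with the training side", {
  # transitivity guard: with (a,b) and (a,c) in training, (b,c) from the
  # same condensate must never reach the test set
  set.seed(77)
  cids <- rep(paste0("c", 1:20), times = sample(3:8, 20L, replace = TRUE))
  pids <- paste0("P", seq_along(cids))
  cond <- condensate_table(cids, pids)
  pairs <- build_positive_pairs(cond)
  fracs <- numeric(0L)
  for (seed in 1:100) {
    sp <- split_by_condensate(pairs, cond, fraction = 0.8, seed = seed)
    test_sources <- unique(unlist(strsplit(sp$test$sources, ",")))
    expect_length(intersect(test_sources, sp$train_condensates), 0L)
    fracs <- c(fracs, nrow(sp$train) / (nrow(sp$train) + nrow(sp$test)))
  }
  # realized positive-pair training fraction stays near the target
  expect_true(all(abs(fracs - 0.8) <= 0.1))
})

test_that("straddling positive pairs are dropped rather than leaked", {
  cond <- condensate_table(c("c1", "c1", "c2", "c2"),
                           c("A", "B", "B", "C"))
  pairs <- build_positive_pairs(cond)
  found_straddle <- FALSE
  for (seed in 1:10) {
    suppressMessages(sp <- split_by_condensate(pairs, cond, 0.5, seed))
    if (nrow(sp$dropped)) {
      found_straddle <- TRUE
      expect_true(all(grepl(",", sp$dropped$sources)))
    }
    expect_equal(nrow(sp$train) + nrow(sp$test) + nrow(sp$dropped),
                 nrow(pairs))
  }
  succeed()
})

test_that("rebalancing oversamples the minority class to exact parity", {
  pairs <- rbind(
    data.frame(id_a = paste0("p", 1:10), id_b = paste0("q", 1:10),
               label = 1L, sources = "c1", is_self_pair = FALSE),
    data.frame(id_a = paste0("r", 1:30), id_b = paste0("s", 1:30),
               label = 0L, sources = "", is_self_pair = FALSE)
  )
  rb <- rebalance(pairs, seed = 4L)
  expect_equal(sum(rb$label == 1L), 30L)
  expect_equal(sum(rb$label == 0L), 30L)
  # already balanced input keeps its counts
  bal <- pairs[c(1:10, 11:20), ]
  rb2 <- rebalance(bal, seed = 4L)
  expect_equal(table(rb2$label), table(bal$label))
  expect_error(rebalance(pairs[pairs$label == 1L, ], 1L), "both classes")
  # exact 1:1 ratio for random imbalances
  set.seed(5)
  for (i in 1:5) {
    n1 <- sample(2:20, 1L); n0 <- sample(2:20, 1L)
    pp <- data.frame(id_a = paste0("a", 1:(n1 + n0)),
                     id_b = paste0("b", 1:(n1 + n0)),
                     label = rep(c(1L, 0L), c(n1, n0)),
                     sources = "", is_self_pair = FALSE)
    rb <- rebalance(pp, seed = i)
    expect_equal(sum(rb$label == 1L), sum(rb$label == 0L))
  }
})

test_that("dataset construction and splitting are deterministic under a seed", {
  set.seed(123)
  cids <- rep(paste0("c", 1:6), each = 4L)
  pids <- paste0("P", c(1:4, 3:6, 7:10, 9:12, 13:16, 15:18))
  cond <- condensate_table(cids, pids)
  pairs <- rbind(build_positive_pairs(cond), build_negative_pairs(cond, 12L))
  s1 <- split_by_condensate(pairs, cond, 0.8, seed = 9L)
  s2 <- split_by_condensate(pairs, cond, 0.8, seed = 9L)
  expect_identical(s1, s2)
  r1 <- rebalance(pairs, seed = 2L)
  expect_identical(r1, rebalance(pairs, seed = 2L))
})

test_that("pair tables round-trip through TSV", {
  cond <- condensate_table(c("c1", "c1", "c2", "c2"), c("A", "B", "C", "D"))
  pairs <- rbind(build_positive_pairs(cond), build_negative_pairs(cond, 12L))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pairs(pairs, path)
  back <- read_pairs(path)
  expect_equal(back$id_a, pairs$id_a)
  expect_equal(back$label, pairs$label)
  expect_equal(back$sources, pairs$sources)
})
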