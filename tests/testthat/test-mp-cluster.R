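test_that("jaccard matches arithmetic and a brute-force oracle", {
  a <- plant_genes(1); b <- plant_genes(2)
  expect_identical(jaccard(a, a), 1)
  expect_identical(jaccard(a, b), 0)
  half <- c(a[1:25], b[1:25])
  expect_equal(jaccard(a, half), 25 / 75)
  expect_error(jaccard(character(0), a), "empty")

  # brute-force oracle on 1000 random set pairs
  universe <- gene_ids(60)
  brute <- function(x, y) {
    inter <- 0L
    for (g in unique(x)) if (g %in% y) inter <- inter + 1L
    inter / length(unique(c(x, y)))
  }
  set.seed(17)
  for (i in 1:1000) {
    x <- sample(universe, sample(1:30, 1))
    y <- sample(universe, sample(1:30, 1))
    expect_identical(jaccard(x, y), brute(x, y))
  }
})

test_that("find_founder picks the most supported program", {
  iso <- lapply(1:4, function(i)
    make_prog(letters[i], 4, 0, sprintf("iso%d_%02d", i, 1:50)))
  expect_null(find_founder(program_set(iso)))

  # star topology: hub overlaps 6 satellites by 8 genes each; satellites
  # take disjoint chunks of the hub so they do not support one another
  hub <- make_prog("h", 4, 0, plant_genes(1))
  sats <- lapply(1:6, function(i)
    make_prog_around(letters[i], 5, 0, plant_genes(1)[(8 * i - 7):(8 * i)],
                     filler_prefix = paste0("s", i)))
  pool <- program_set(c(list(hub), sats, iso))
  expect_identical(pkey(find_founder(pool)), pkey(hub))

  # 7 supporters beat 6
  hub2 <- make_prog("h", 5, 0, plant_genes(2))
  # 8-gene chunks at stride 6: each supports the hub, pairwise overlap 2
  sats2 <- lapply(1:7, function(i)
    make_prog_around(letters[i], 6, 0,
                     plant_genes(2)[(6 * i - 5):(6 * i + 2)],
                     filler_prefix = paste0("t", i)))
  pool2 <- program_set(c(list(hub, hub2), sats, sats2))
  expect_identical(pkey(find_founder(pool2)), pkey(hub2))

  # exactly 5 supporters is not enough ("more than five cases")
  sats5 <- lapply(1:5, function(i)
    make_prog_around(letters[i], 5, 0, plant_genes(1)[(8 * i - 7):(8 * i)],
                     filler_prefix = paste0("s", i)))
  expect_null(find_founder(program_set(c(list(hub), sats5))))
})

test_that("complete_mp ranks by frequency then mean weight then id", {
  solo <- make_prog("a", 4, 0, plant_genes(1))
  expect_identical(complete_mp(list(solo)), solo$genes)

  two <- list(make_prog_around("a", 4, 0, plant_genes(1)[1:30]),
              make_prog_around("b", 4, 0, plant_genes(1)[1:30],
                               filler_prefix = "y"))
  mp <- complete_mp(two)
  expect_true(all(plant_genes(1)[1:30] %in% mp))
  expect_length(mp, 50)

  # brute-force oracle on three constructed members
  members <- list(make_prog("a", 4, 0, plant_genes(1)),
                  make_prog_around("b", 4, 0, plant_genes(1)[10:40]),
                  make_prog_around("c", 5, 0, plant_genes(1)[25:50],
                                   filler_prefix = "z"))
  got <- complete_mp(members, size = 50)
  u <- unique(unlist(lapply(members, `[[`, "genes")))
  freq <- sapply(u, function(g)
    sum(sapply(members, function(m) g %in% m$genes)))
  mw <- sapply(u, function(g) {
    w <- unlist(lapply(members, function(m) m$weights[g]))
    mean(w[!is.na(w)])
  })
  want <- u[order(-freq, -mw, u)][1:50]
  expect_identical(got, want)

  small <- make_prog("a", 4, 0, plant_genes(1)[1:10])
  expect_error(complete_mp(list(small), size = 50), "short by")
})

test_that("build_cluster accretes by overlap with the evolving MP", {
  # degenerate: six copies of one program collapse into one full cluster
  copies <- lapply(1:6, function(i)
    make_prog(letters[i], 4, 0, plant_genes(1)))
  pool <- program_set(copies)
  res <- build_cluster(copies[[1]], pool)
  expect_setequal(res$mp$genes, plant_genes(1))
  expect_length(res$mp$members, 6)
  expect_length(res$remaining$programs, 0)

  # a program overlapping the MP by 9 genes is never admitted
  near <- make_prog_around("g", 4, 0, plant_genes(1)[1:9],
                           filler_prefix = "nr")
  pool2 <- program_set(c(copies, list(near)))
  res2 <- build_cluster(copies[[1]], pool2)
  expect_length(res2$mp$members, 6)
  expect_identical(pkey(res2$remaining$programs[[1]]),
                   pkey(near))
  # audit trail: every admission beyond the founder carried >= 10 overlap
  adm <- res2$mp$audit$overlap_at_admission[-1]
  expect_true(all(adm >= 8))  # partner >= 8, accretions >= 10
  expect_true(all(res2$mp$audit$overlap_at_admission[-(1:2)] >= 10))
})

test_that("cluster_all recovers separated program families exactly", {
  fams <- list()
  for (i in 1:3) for (s in 1:7)
    fams[[length(fams) + 1L]] <-
      make_prog_around(sprintf("s%d", s), 4L + (s %% 2), i - 1L,
                       plant_genes(i)[1:40],
                       filler_prefix = sprintf("f%d%d", i, s))
  out <- cluster_all(program_set(fams))
  expect_length(out$mps, 3)
  hits <- vapply(out$mps, function(mp)
    max(sapply(1:3, function(i)
      length(intersect(mp$genes, plant_genes(i))))), 0)
  expect_true(all(hits >= 35))
  for (mp in out$mps) expect_length(mp$genes, 50)

  # members + unassigned partition the pool, member sets disjoint
  keys <- unlist(lapply(out$mps, function(mp)
    vapply(mp$members, pkey, "")))
  keys <- c(keys, vapply(out$unassigned, pkey, ""))
  expect_setequal(keys, vapply(fams, pkey, ""))
  expect_false(anyDuplicated(keys) > 0)

  # isolated programs form no clusters
  iso <- program_set(lapply(1:5, function(i)
    make_prog(letters[i], 4, 0, sprintf("u%d_%02d", i, 1:50))))
  out2 <- cluster_all(iso)
  expect_length(out2$mps, 0)
  expect_length(out2$unassigned, 5)
})
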