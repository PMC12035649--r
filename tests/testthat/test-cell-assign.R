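# small expression fixture with a planted signature
planted_sample <- function(n_genes = 120, n_cells = 300, seed = 8,
                           effect = 8, rate = 0.3) {
  p <- planted_program("P1", plant_genes(1, 30), activity_rate = rate,
                       effect_size = effect)
  cc <- cohort_config(n_samples = 1, n_genes = n_genes,
                      cells_per_sample = n_cells,
                      shared_programs = list(p), baseline_mean = 1,
                      seed = seed)
  sim <- simulate_cohort(cc)
  list(m = sim$samples[[1]],
       active = sim$truth$active_programs == "P1")
}

test_that("signature scores separate active from inactive cells", {
  fx <- planted_sample()
  sc <- signature_score(fx$m, plant_genes(1, 30), seed = 2)
  expect_length(sc, 300)
  expect_lt(stats::wilcox.test(sc[fx$active], sc[!fx$active],
                               alternative = "greater")$p.value, 1e-6)
})

test_that("self-controlled and degenerate scores vanish", {
  m <- sample_matrix(make_counts(90, 40, seed = 5), "s")
  # signature = all genes with full-bin controls: exact cancellation
  sc <- signature_score(m, rownames(m$counts), n_bins = 9, n_ctrl = 1e4)
  expect_true(all(abs(sc) < 1e-10))
  # constant matrix: centring leaves nothing
  cm <- sample_matrix(matrix(3, 20, 10,
                             dimnames = list(gene_ids(20),
                                             sprintf("c%d", 1:10))), "c")
  expect_true(all(signature_score(cm, gene_ids(5)) == 0))
  expect_error(signature_score(m, c("nope1", "nope2")), "no signature gene")
})

test_that("scores are deterministic under a seed and permutation-invariant", {
  # well-separated gene means keep expression bins unambiguous
  set.seed(9)
  counts <- matrix(rpois(100 * 50, 5), 100,
                   dimnames = list(gene_ids(100), sprintf("c%03d", 1:50)))
  counts <- counts + 2L * seq_len(100)
  m <- sample_matrix(counts, "s")
  sig <- gene_ids(100)[5:34]
  s1 <- signature_score(m, sig, seed = 7)
  expect_identical(s1, signature_score(m, sig, seed = 7))
  # permute genes and cells; scores follow the cells
  set.seed(31)
  gp <- sample(nrow(m$counts)); cp <- sample(ncol(m$counts))
  mp <- sample_matrix(as.matrix(m$counts)[gp, cp], "s")
  s2 <- signature_score(mp, sig, seed = 7)
  expect_equal(s2[names(s1)], s1)
})

test_that("MP scoring enforces the 25-gene conservation rule", {
  fx <- planted_sample()
  genes_present <- rownames(fx$m$counts)
  mp_ok <- mk_mp("MPok", c(plant_genes(1, 30), genes_present[80:99]))
  # 20 of 50 genes in the matrix: excluded
  mp_out <- mk_mp("MPout", c(genes_present[1:20], sprintf("abs%02d", 1:30)))
  # exactly 25 present: boundary passes
  mp_edge <- mk_mp("MPedge", c(genes_present[40:64], sprintf("abs%02d", 31:55)))
  sc <- score_cells(fx$m, list(mp_ok, mp_out, mp_edge))
  expect_identical(colnames(sc), c("MPok", "MPedge"))
  expect_identical(attr(sc, "excluded_mps"), "MPout")
  expect_error(score_cells(fx$m, list(mp_out)), "conserved")
})

test_that("assignment applies arg-max and the 5% prevalence rule", {
  sc <- matrix(0, 100, 3, dimnames = list(sprintf("c%03d", 1:100),
                                          c("MPa", "MPb", "MPc")))
  sc[1:90, "MPa"] <- 1
  sc[91:94, "MPb"] <- 2   # tops 4 cells: below 5% -> unresolved
  sc[95:99, "MPc"] <- 2   # tops exactly 5 cells: retained at the boundary
  # cell 100 ties across all: first column wins
  a <- assign_cells(sc)
  expect_setequal(a$retained_mps, c("MPa", "MPc"))
  expect_identical(unname(a$labels[91]), "unresolved")
  expect_identical(sum(a$labels == "unresolved"), 4L)
  expect_identical(unname(a$labels[95]), "MPc")
  expect_identical(unname(a$labels[100]), "MPa")
  # every retained MP labels >= 5% of cells
  for (id in a$retained_mps)
    expect_gte(mean(a$labels == id), 0.05)
  expect_identical(length(a$labels), nrow(sc))

  # one MP topping everywhere: no unresolved cells
  one <- matrix(runif(60), 20, 3,
                dimnames = list(sprintf("c%d", 1:20), c("A", "B", "C")))
  one[, 1] <- 10
  a2 <- assign_cells(one)
  expect_true(all(a2$labels == "A"))
})

test_that("module scores match per-signature scoring and rank the truth", {
  # heterogeneous per-gene baselines, as in real data: the signature's
  # expression bins then contain genuine control genes rather than only
  # the signature itself
  set.seed(44)
  n_genes <- 300; n_cells <- 300
  mu <- exp(rnorm(n_genes, 0, 1))
  ids <- gene_ids(n_genes)
  sig <- ids[seq(5, 150, by = 5)]          # 30 genes across the mean range
  active <- rep(c(TRUE, FALSE), c(100, 200))
  boost <- matrix(1, n_genes, n_cells)
  boost[match(sig, ids), active] <- 8
  counts <- matrix(rnbinom(n_genes * n_cells, mu = mu * boost, size = 2),
                   n_genes, dimnames = list(ids, sprintf("c%03d",
                                                         1:n_cells)))
  m <- sample_matrix(counts, "s")
  mps <- list(mk_mp("MP1", sig), mk_mp("MP2", ids[seq(4, 149, by = 5)]))
  ms <- mp_module_scores(m, mps, seed = 3)
  expect_identical(ms[, "MP1"],
                   signature_score(m, sig, n_bins = 24, seed = 3))
  # active cells rank their own MP above the expression-matched decoy
  contrast <- ms[active, "MP1"] - ms[active, "MP2"]
  expect_gt(median(contrast), 0)
  expect_lt(stats::wilcox.test(ms[active, "MP1"], ms[!active, "MP1"],
                               alternative = "greater")$p.value, 1e-6)
})

test_that("MP correlation matrix matches the closed-form oracle", {
  set.seed(12)
  sc <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("M", 1:4)))
  r <- mp_correlation_matrix(sc)
  expect_equal(r, t(r))
  expect_true(all(diag(r) == 1))
  oracle <- function(x, y) {
    mean((x - mean(x)) * (y - mean(y))) /
      sqrt(mean((x - mean(x))^2) * mean((y - mean(y))^2))
  }
  for (i in 1:4) for (j in 1:4)
    expect_equal(r[i, j], oracle(sc[, i], sc[, j]), tolerance = 1e-12)

  # identical and anti-correlated columns
  sc2 <- cbind(a = sc[, 1], b = sc[, 1], c = -sc[, 1])
  r2 <- mp_correlation_matrix(sc2)
  expect_equal(r2["a", "b"], 1)
  expect_equal(r2["a", "c"], -1)

  # zero variance is flagged, not silently zeroed
  sc3 <- cbind(sc, flat = rep(1, 10))
  expect_warning(r3 <- mp_correlation_matrix(sc3), "zero-variance")
  expect_true(is.na(r3["M1", "flat"]))
})
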