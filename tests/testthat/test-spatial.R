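# tiny deterministic grid with hand-set weights
toy_grid <- function(nr = 4, nc = 5, fib = NULL, tumour = NULL) {
  coords <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  coords <- coords[order(coords$row, coords$col), ]
  ids <- sprintf("s%d_%d", coords$row, coords$col)
  n <- nrow(coords)
  w <- cbind(fibroblast = if (is.null(fib)) rep(0.1, n) else fib,
             T_cell = rep(0.2, n))
  spot_grid(data.frame(spot_id = ids, row = coords$row, col = coords$col),
            is_tumour = if (is.null(tumour)) rep(TRUE, n) else tumour,
            weights = w)
}

test_that("neighbourhood geometry: 8 interior, 5 edge, 3 corner, symmetric", {
  g <- toy_grid(4, 5)
  expect_length(neighbourhood(g, "s2_3"), 8)  # interior
  expect_length(neighbourhood(g, "s1_3"), 5)  # edge
  expect_length(neighbourhood(g, "s1_1"), 3)  # corner
  expect_false("s2_3" %in% neighbourhood(g, "s2_3"))
  # symmetry over every pair
  for (a in g$spots$spot_id) for (b in neighbourhood(g, a))
    expect_true(a %in% neighbourhood(g, b))
  # single spot: empty neighbourhood
  g1 <- spot_grid(data.frame(spot_id = "only", row = 1, col = 1),
                  is_tumour = TRUE,
                  weights = matrix(0.5, 1, 1,
                                   dimnames = list(NULL, "fibroblast")))
  expect_length(neighbourhood(g1, "only"), 0)
})

test_that("hex mode yields the six Visium-style neighbours", {
  coords <- expand.grid(row = 1:5, col = 1:10)
  ok <- (coords$row + coords$col) %% 2 == 0   # checkerboard array positions
  coords <- coords[ok, ]
  ids <- sprintf("s%d_%d", coords$row, coords$col)
  g <- spot_grid(data.frame(spot_id = ids, row = coords$row,
                            col = coords$col),
                 is_tumour = rep(TRUE, nrow(coords)),
                 weights = matrix(0.1, nrow(coords), 1,
                                  dimnames = list(NULL, "fibroblast")))
  nb <- neighbourhood(g, "s3_5", mode = "hex")
  expect_setequal(nb, c("s3_3", "s3_7", "s2_4", "s2_6", "s4_4", "s4_6"))
})

test_that("neighbourhood score sums adjacent weights exactly", {
  g <- toy_grid(4, 5)
  expect_equal(neighbourhood_score(g, "s2_3", "fibroblast"), 0.8)
  expect_equal(neighbourhood_score(g, "s1_1", "fibroblast"), 0.3)
  z <- toy_grid(4, 5, fib = rep(0, 20))
  expect_equal(neighbourhood_score(z, "s2_3", "fibroblast"), 0)
  # linearity in the weights
  set.seed(3)
  fib <- runif(20, 0, 0.3)
  s1 <- neighbourhood_score(toy_grid(4, 5, fib = fib), "s2_2",
                            "fibroblast")
  s2 <- neighbourhood_score(toy_grid(4, 5, fib = 2 * fib), "s2_2",
                            "fibroblast")
  expect_equal(s2, 2 * s1, tolerance = 1e-12)
  # non-tumour spots have no neighbourhood score
  gt <- toy_grid(4, 5, tumour = c(FALSE, rep(TRUE, 19)))
  expect_error(neighbourhood_score(gt, "s1_1", "fibroblast"),
               "not a tumour spot")
  expect_error(neighbourhood_score(g, "s2_3", "missing_col"), "neither")
})

test_that("neighbourhood score table matches a brute-force double loop", {
  set.seed(23)
  sp <- simulate_spatial(spatial_config(n_rows = 12, n_cols = 12,
                                        seed = 4))
  g <- sp$grid
  tab <- neighbourhood_score_table(g)
  # independent oracle: scan all spots, Chebyshev distance 1
  for (s in sample(g$spots$spot_id, 40)) {
    i <- match(s, g$spots$spot_id)
    for (ct in colnames(g$weights)) {
      acc <- 0
      for (j in seq_len(nrow(g$spots))) {
        if (j == i) next
        if (max(abs(g$spots$row[j] - g$spots$row[i]),
                abs(g$spots$col[j] - g$spots$col[i])) == 1)
          acc <- acc + g$weights[j, ct]
      }
      expect_equal(unname(tab[s, ct]), acc, tolerance = 1e-12)
    }
  }
})

test_that("tumour spots take the arg-max MP with first-column ties", {
  mp_genes <- list(MP_a = sprintf("a%02d", 1:30),
                   MP_b = sprintf("b%02d", 1:30))
  # spots expressing only MP_a's genes
  n_genes <- 100
  genes <- c(mp_genes$MP_a, mp_genes$MP_b,
             sprintf("f%02d", 1:(n_genes - 60)))
  nr <- 3; nc <- 3
  ids <- sprintf("s%d_%d", rep(1:nr, each = nc), rep(1:nc, nr))
  set.seed(6)
  expr <- matrix(rpois(n_genes * 9, 2), n_genes,
                 dimnames = list(genes, ids))
  expr[mp_genes$MP_a, c("s1_1", "s1_2")] <-
    expr[mp_genes$MP_a, c("s1_1", "s1_2")] + 30L
  expr[mp_genes$MP_b, "s2_1"] <- expr[mp_genes$MP_b, "s2_1"] + 30L
  g <- spot_grid(data.frame(spot_id = ids,
                            row = rep(1:nr, each = nc),
                            col = rep(1:nc, nr)),
                 is_tumour = c(rep(TRUE, 6), rep(FALSE, 3)),
                 weights = matrix(0.2, 9, 1,
                                  dimnames = list(NULL, "fibroblast")),
                 expression = expr)
  mps <- list(mk_mp("MP_a", mp_genes$MP_a), mk_mp("MP_b", mp_genes$MP_b))
  g2 <- assign_spot_mp(g, mps)
  expect_identical(unname(g2$mp_label[c("s1_1", "s1_2")]),
                   c("MP_a", "MP_a"))
  expect_identical(unname(g2$mp_label["s2_1"]), "MP_b")
  # non-tumour spots never labelled
  expect_false(any(c("s3_1", "s3_2", "s3_3") %in% names(g2$mp_label)))
  # identical scores tie to the first MP in input order
  flat <- g
  flat$expression <- matrix(5L, n_genes, 9, dimnames = list(genes, ids))
  g3 <- assign_spot_mp(flat, mps)
  expect_true(all(g3$mp_label == "MP_a"))
})

test_that("planted spatial associations are recovered and nulls stay flat", {
  cfg <- spatial_config(
    n_rows = 32, n_cols = 32,
    association = list(
      list(mp_id = "MP_a", cell_type = "fibroblast", slope = 6),
      list(mp_id = "MP_b", cell_type = "T_cell", slope = 0)),
    seed = 14)
  sp <- simulate_spatial(cfg)
  res <- mp_tme_correlation(sp$grid)
  expect_gte(res$n_spots, 1000)
  r <- res$pooled["MP_a", "fibroblast"]
  expect_gt(r, 0)
  n <- res$n_spots
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  expect_lt(2 * stats::pt(-abs(tstat), n - 2), 0.05)
  expect_lt(abs(res$pooled["MP_b", "T_cell"]), 0.1)
  # single slide: pooled equals the per-slide matrix
  expect_equal(res$pooled, res$per_slide[[1]])
  # two slides pool their spots
  sp2 <- simulate_spatial(spatial_config(
    n_rows = 32, n_cols = 32,
    association = cfg$association, seed = 15))
  both <- mp_tme_correlation(list(sp$grid, sp2$grid))
  expect_identical(both$n_spots, 2L * res$n_spots)
  expect_gt(both$pooled["MP_a", "fibroblast"], 0)
})
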