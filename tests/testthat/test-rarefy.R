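test_that("averaged rarefied columns sum exactly to the target depth", {
  sim <- tiny_experiment(seed = 3)
  rare <- rarefy_mean(sim$counts, depth = 2000, n_rep = 25, seed = 1)
  sums <- colSums(counts_matrix(rare))
  expect_true(all(abs(sums - 2000) < 1e-9))
})

test_that("a sample at exactly the depth is returned unchanged", {
  m <- matrix(c(120, 60, 20, 300, 100, 0), nrow = 3,
              dimnames = list(paste0("t", 1:3), c("s1", "s2")))
  rare <- rarefy_mean(count_table(m), depth = 200, n_rep = 10, seed = 1)
  expect_equal(counts_matrix(rare)[, "s1"], m[, "s1"])
})

test_that("averaged counts match the hypergeometric expectation", {
  m <- matrix(c(8000, 4000), nrow = 2,
              dimnames = list(c("t1", "t2"), "s1"))
  n_rep <- 500
  rare <- rarefy_mean(count_table(m), depth = 6000, n_rep = n_rep, seed = 7)
  got <- counts_matrix(rare)["t1", "s1"]
  # Hypergeometric: mean 6000 * 8000/12000 = 4000
  v <- 6000 * (8000 / 12000) * (4000 / 12000) * (12000 - 6000) / (12000 - 1)
  se <- sqrt(v / n_rep)
  expect_lt(abs(got - 4000), 3 * se)
})

test_that("rarefaction agrees with an independent without-replacement oracle", {
  set.seed(42)
  counts <- c(a = 900, b = 70, c = 30)
  rare <- rarefy_mean(count_table(matrix(counts, 3,
                                         dimnames = list(names(counts), "s"))),
                      depth = 100, n_rep = 400, seed = 3)
  oracle <- rowMeans(replicate(400, {
    drawn <- sample(rep(seq_along(counts), counts), 100)
    tabulate(drawn, nbins = 3)
  }))
  se <- sqrt(100 * (counts / 1000) * (1 - counts / 1000) / 400)
  expect_true(all(abs(counts_matrix(rare)[, 1] - oracle) < 3 * sqrt(2) * se))
})

test_that("shallow samples are dropped with a warning; all-shallow errors", {
  m <- matrix(c(50, 10, 2000, 1000), nrow = 2,
              dimnames = list(c("t1", "t2"), c("shallow", "deep")))
  expect_warning(rare <- rarefy_mean(count_table(m), depth = 100, n_rep = 5),
                 "shallow")
  expect_equal(setdiff(names(rare), "otu_id"), "deep")
  expect_error(
    suppressWarnings(rarefy_mean(count_table(m), depth = 1e6, n_rep = 5)),
    "shallower"
  )
  expect_error(rarefy_mean(count_table(m), depth = 0, n_rep = 5), "depth")
  expect_error(rarefy_mean(count_table(m), depth = 10, n_rep = 0), "n_rep")
})

test_that("rarefied relative abundances converge to input relative abundances", {
  set.seed(9)
  counts <- rpois(30, lambda = exp(runif(30, 1, 6)))
  counts[counts == 0] <- 1
  m <- matrix(counts, 30, dimnames = list(paste0("t", 1:30), "s"))
  rare <- rarefy_mean(count_table(m), depth = 1000, n_rep = 1000, seed = 5)
  p_in <- counts / sum(counts)
  p_out <- counts_matrix(rare)[, 1] / 1000
  se <- sqrt(p_in * (1 - p_in) / 1000 / 1000)
  expect_true(all(abs(p_out - p_in) <= 3 * se + 1e-9))
})

test_that("Hill diversity reproduces hand and vegan values", {
  expect_equal(hill_diversity(c(3, 0, 1, 2), q = 0), 3)
  expect_equal(hill_diversity(rep(7, 12), q = 0), 12)
  expect_equal(hill_diversity(rep(7, 12), q = 1), 12)
  expect_equal(hill_diversity(rep(7, 12), q = 2), 12)
  expect_equal(round(hill_diversity(c(0.5, 0.3, 0.2), q = 2), 4), 2.6316)
  p <- c(10, 40, 25, 5, 20)
  expect_equal(hill_diversity(p, 1),
               exp(vegan::diversity(p, index = "shannon")))
  expect_equal(hill_diversity(p, 2),
               vegan::diversity(p, index = "invsimpson"))
  expect_error(hill_diversity(c(0, 0), 1), "all-zero")
  expect_error(hill_diversity(c(1, 2), -1), "q")
})

test_that("Hill numbers are non-increasing in the order q", {
  set.seed(11)
  for (i in 1:20) {
    x <- rexp(15) * rpois(15, 40)
    x[x == 0] <- 0.5
    qs <- c(0, 0.5, 1, 1.5, 2, 3)
    h <- vapply(qs, function(q) hill_diversity(x, q), numeric(1))
    expect_true(all(diff(h) <= 1e-8))
  }
})

test_that("rarefied alpha diversity regresses on raw with slope near one", {
  # deep samples (>= 5x the rarefaction depth)
  sim <- tiny_experiment(seed = 6, n_taxa = 40)
  rare <- rarefy_mean(sim$counts, depth = 1000, n_rep = 200, seed = 2)
  for (q in 0:2) {
    raw_h <- hill_diversity_table(sim$counts, q = q)$diversity
    rar_h <- hill_diversity_table(rare, q = q)$diversity
    slope <- coef(lm(rar_h ~ raw_h))[2]
    expect_gt(slope, 0.9)
    expect_lt(slope, 1.1)
  }
})
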