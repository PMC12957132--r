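test_that("contingency tables match hand counts and brute-force classification", {
  pm <- list(p1 = c("m1", "m2"), p2 = "m1", p3 = "m2", p4 = character())
  expect_equal(unname(contingency_table("m1", "m2", pm)), c(1, 1, 1, 1))
  expect_error(contingency_table("m1", "m1", pm), "differ")

  # a mutation absent everywhere gives an empty A margin
  tab <- contingency_table("absent", "m1", pm)
  expect_equal(unname(tab[c("a", "b")]), c(0, 0))

  set.seed(21)
  for (rep in 1:10) {
    ids <- paste0("m", 1:6)
    pm <- replicate(50, sample(ids, rbinom(1, 4, 0.3)), simplify = FALSE)
    names(pm) <- paste0("p", seq_along(pm))
    got <- contingency_table("m1", "m2", pm)
    a <- b <- c2 <- d <- 0
    for (p in pm) {
      A <- "m1" %in% p; B <- "m2" %in% p
      if (A && B) a <- a + 1 else if (A) b <- b + 1
      else if (B) c2 <- c2 + 1 else d <- d + 1
    }
    expect_equal(unname(got), c(a, b, c2, d))
    expect_equal(sum(got), length(pm))
  }
})

test_that("exact test reproduces worked cases and the cross-product odds ratio", {
  r <- fisher_exact_two_sided(1, 1, 1, 1)
  expect_equal(r$odds_ratio, 1)
  expect_equal(r$p_value, 1)

  r <- fisher_exact_two_sided(2, 0, 0, 2)
  expect_equal(r$odds_ratio, Inf)
  expect_equal(r$p_value, 1 / 3, tolerance = 1e-12)

  expect_equal(fisher_exact_two_sided(0, 2, 2, 0)$odds_ratio, 0)
  expect_true(is.nan(fisher_exact_two_sided(0, 0, 0, 5)$odds_ratio))
  expect_error(fisher_exact_two_sided(-1, 0, 0, 2), "non-negative")
})

test_that("exact-test p-values agree with stats::fisher.test on random tables", {
  set.seed(99)
  for (rep in 1:200) {
    cells <- rmultinom(1, sample(5:120, 1), runif(4, 0.05, 1))[, 1]
    mine <- fisher_exact_two_sided(cells[1], cells[2], cells[3], cells[4])
    ref <- stats::fisher.test(matrix(cells, 2, byrow = TRUE))
    expect_equal(mine$p_value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("BH adjustment matches its definition and is monotone", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_error(bh_adjust(c(0.1, 1.4)), "\\[0,1\\]")

  set.seed(5)
  for (rep in 1:50) {
    p <- runif(sample(1:100, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p))
    expect_true(all(q >= p))
    perm <- sample(seq_along(p))
    expect_equal(sort(bh_adjust(p[perm])), sort(q))
  }
})

test_that("screen results are symmetric in pair order and complete", {
  set.seed(13)
  ids <- paste0("m", 1:5)
  pm <- replicate(80, sample(ids, rbinom(1, 3, 0.4)), simplify = FALSE)
  names(pm) <- paste0("p", seq_along(pm))
  screen <- comutation_screen(ids, pm)
  expect_equal(nrow(screen), choose(5, 2))
  # symmetry: the screen's cells equal the direct table in either order
  for (r in seq_len(nrow(screen))) {
    tab <- contingency_table(screen$mut1[r], screen$mut2[r], pm)
    rev <- contingency_table(screen$mut2[r], screen$mut1[r], pm)
    expect_equal(unname(tab), c(screen$a[r], screen$b[r], screen$c[r],
                                screen$d[r]))
    expect_equal(unname(rev[c("a", "c", "b", "d")]),
                 c(screen$a[r], screen$b[r], screen$c[r], screen$d[r]))
    ft <- fisher_exact_two_sided(tab[1], tab[2], tab[3], tab[4])
    ftr <- fisher_exact_two_sided(rev[1], rev[2], rev[3], rev[4])
    expect_equal(ft$p_value, ftr$p_value)
  }
  expect_error(comutation_screen("m1", pm), ">= 2")
})

test_that("two mutations only: fdr equals the raw p-value", {
  pm <- list(p1 = c("m1", "m2"), p2 = "m1", p3 = "m2", p4 = character(),
             p5 = c("m1", "m2"))
  screen <- comutation_screen(c("m1", "m2"), pm)
  expect_equal(nrow(screen), 1)
  expect_equal(screen$fdr, screen$p_value)
})

test_that("a strongly planted pair is the unique significant hit with co-occurring direction", {
  # m1 and m2 co-carried in 30/100 patients, otherwise absent; six noise
  # mutations carried independently
  set.seed(77)
  pm <- lapply(1:100, function(i) {
    mut <- character()
    if (i <= 30) mut <- c("m1", "m2")
    noise <- paste0("n", 1:6)[runif(6) < 0.15]
    c(mut, noise)
  })
  names(pm) <- paste0("p", 1:100)
  screen <- comutation_screen(c("m1", "m2", paste0("n", 1:6)), pm)
  sig <- screen[screen$significant, ]
  expect_equal(nrow(sig), 1)
  expect_setequal(c(sig$mut1, sig$mut2), c("m1", "m2"))
  expect_equal(sig$direction, "co_occurring")
  expect_equal(sig$odds_ratio, Inf)
})

test_that("triangular matrix export carries log-OR and FDR with finite caps", {
  pm <- list(p1 = c("m1", "m2"), p2 = c("m1", "m2"), p3 = "m3",
             p4 = character())
  screen <- comutation_screen(c("m1", "m2", "m3"), pm)
  mat <- comutation_matrix(screen)
  expect_equal(dim(mat), c(3, 3))
  expect_true(all(is.na(diag(mat))))
  expect_true(all(is.finite(mat[upper.tri(mat)])))
  # lower triangle holds the FDR values
  r <- screen[screen$mut1 == "m1" & screen$mut2 == "m2", ]
  expect_equal(mat["m2", "m1"], r$fdr)
})
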