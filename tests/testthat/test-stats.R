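make_design <- function(n = 7, shrna_eff = 0, infusion_eff = 0, sd = 1) {
  g <- expand.grid(shrna = c("ctrl", "kd"),
                   infusion = c("vehicle", "drug"),
                   rep = seq_len(n), stringsAsFactors = FALSE)
  g$y <- stats::rnorm(nrow(g), sd = sd) +
    shrna_eff * (g$shrna == "kd") +
    infusion_eff * (g$infusion == "drug")
  tibble::as_tibble(g)
}

test_that("a strong infusion effect is flagged only in the infusion family", {
  set.seed(101)
  tab <- make_design(n = 7, infusion_eff = 3)
  res <- compare_groups(tab, "y")$y
  expect_equal(nrow(res$contrasts), 4)
  inf <- res$contrasts[res$contrasts$family == "infusion_within_shrna", ]
  sh <- res$contrasts[res$contrasts$family == "shrna_within_infusion", ]
  expect_true(all(inf$significant))
  expect_false(any(sh$significant))
  expect_lt(res$anova$p[res$anova$term == "infusion"], 0.05)
})

test_that("identical groups yield no flags and swapped factors are symmetric", {
  set.seed(202)
  tab <- make_design(n = 7)
  res <- compare_groups(tab, "y")$y
  expect_false(any(res$contrasts$significant))
  # symmetry: relabeling the factors transposes the two families
  swapped <- dplyr::rename(tab, shrna = infusion, infusion = shrna)
  res2 <- compare_groups(swapped, "y")$y
  p1 <- sort(res$contrasts$p_adj)
  p2 <- sort(res2$contrasts$p_adj)
  expect_equal(p1, p2, tolerance = 1e-9)
})

test_that("cell summaries report mean and SEM per cell", {
  set.seed(303)
  tab <- make_design(n = 5)
  res <- compare_groups(tab, "y")$y
  expect_equal(nrow(res$cells), 4)
  expect_true(all(res$cells$n == 5))
  cell <- tab[tab$shrna == "ctrl" & tab$infusion == "vehicle", ]
  got <- res$cells[res$cells$shrna == "ctrl" &
                     res$cells$infusion == "vehicle", ]
  expect_equal(got$mean, mean(cell$y))
  expect_equal(got$sem, stats::sd(cell$y) / sqrt(5))
})

test_that("degenerate designs are rejected", {
  tab <- make_design(n = 3)
  expect_error(compare_groups(dplyr::select(tab, -shrna), "y"),
               "missing factor")
  expect_error(compare_groups(tab[tab$shrna == "ctrl", ], "y"),
               "2 levels")
  expect_error(compare_groups(tab[-(1:3), ][1:5, ], "y"), ">= 2")
})
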