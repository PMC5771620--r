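grouped <- function(values_by_group) {
  tibble::tibble(
    value = unlist(values_by_group, use.names = FALSE),
    group = rep(names(values_by_group), lengths(values_by_group))
  )
}

test_that("variability index is 0 for identical groups and 3.6 for the 2x case", {
  same <- grouped(list(A = 1:10, B = 1:10, C = 1:10, D = 1:10))
  expect_equal(glance(variability_index(same))$variability_index, 0,
               tolerance = 1e-12)
  # three groups {1..10} and one doubled: each decile contributes
  # sd(q,q,q,2q)/mean(q,q,q,2q) = (q/2)/(5q/4) = 0.4; nine deciles -> 3.6
  vi <- variability_index(grouped(list(A = 1:10, B = 1:10, C = 1:10,
                                       D = 2 * (1:10))))
  expect_equal(vi$variability_index, 3.6, tolerance = 1e-12)
  expect_equal(nrow(vi$per_decile), 9L)
  expect_equal(vi$per_decile$dispersion, rep(0.4, 9), tolerance = 1e-12)
})

test_that("variability index is scale- and relabel-invariant", {
  set.seed(43)
  g <- grouped(list(A = rexp(40), B = rexp(40, 0.5), C = rexp(40, 2),
                    D = rexp(40)))
  vi <- variability_index(g)$variability_index
  scaled <- dplyr::mutate(g, value = value * 17.3)
  expect_equal(variability_index(scaled)$variability_index, vi,
               tolerance = 1e-10)
  relabeled <- dplyr::mutate(g, group = chartr("ABCD", "DCBA", group))
  expect_equal(variability_index(relabeled)$variability_index, vi,
               tolerance = 1e-12)
})

test_that("variability index guards its preconditions", {
  expect_error(variability_index(grouped(list(A = 1:10))), "2 non-empty groups")
  expect_error(variability_index(grouped(list(A = 1:10, B = 1:5))),
               "fewer than 10")
  # a zero decile mean flags the index undefined
  z <- grouped(list(A = rep(0, 10), B = rep(0, 10)))
  expect_true(is.na(variability_index(z)$variability_index))
  # filtering a subset and recomputing is routine
  g <- grouped(list(A = 1:20, B = 21:40))
  sub <- g[g$value %% 2 == 0, ]
  expect_s3_class(variability_index(sub), "tf_variability")
})

test_that("compact letters: identical groups share, separated groups differ", {
  same <- grouped(list(A = rep(c(1, 2, 3), 8), B = rep(c(1, 2, 3), 8)))
  kl <- kruskal_letters(same)
  expect_equal(kl$letters$letters, c("a", "a"))

  apart <- grouped(list(A = 1:20, B = 101:120))
  kl2 <- kruskal_letters(apart)
  expect_equal(sort(kl2$letters$letters), c("a", "b"))
  expect_lt(kl2$p.value, 0.05)

  # all values tied across all groups: omnibus p 1, single shared letter
  tied <- grouped(list(A = rep(5, 10), B = rep(5, 10), C = rep(5, 10)))
  kl3 <- kruskal_letters(tied)
  expect_equal(kl3$p.value, 1)
  expect_equal(unique(kl3$letters$letters), "a")

  # middle group bridging two separated ones shares a letter with both
  bridge <- grouped(list(A = rnorm(30), B = rnorm(30, 1.2), C = rnorm(30, 2.4)))
  set.seed(61)
  bridge$value <- c(rnorm(30), rnorm(30, 1.2), rnorm(30, 2.4))
  kl4 <- kruskal_letters(bridge)
  la <- kl4$letters$letters
  expect_true(all(nchar(la) >= 1))
})

test_that("two-group Dunn decision matches the Mann-Whitney normal test", {
  set.seed(53)
  for (shift in c(0, 0.3, 1, 2)) {
    v <- c(rnorm(25), rnorm(25, shift))
    d <- tibble::tibble(value = v, group = rep(c("A", "B"), each = 25))
    kl <- kruskal_letters(d)
    mw <- stats::wilcox.test(value ~ group, data = d, exact = FALSE,
                             correct = FALSE)$p.value
    expect_equal(kl$pairwise$p.value, mw, tolerance = 1e-9)
    expect_equal(length(unique(kl$letters$letters)) == 2, mw < 0.05)
  }
})

test_that("Kruskal-Wallis omnibus holds its type-I error on null groups", {
  set.seed(71)
  n_sim <- 600
  rej <- vapply(seq_len(n_sim), function(i) {
    v <- rnorm(200)
    kruskal.test(v, rep(1:4, each = 50))$p.value < 0.05
  }, logical(1))
  expect_gt(mean(rej), 0.03)
  expect_lt(mean(rej), 0.07)
})

test_that("two-way ANOVA on extremes isolates the constructed effect", {
  reps <- paste0("r", 1:4)
  base <- c(1.0, 1.4, 0.8, 1.2)   # identical replicate pattern in each group
  cells <- tidyr::expand_grid(group = c("G1", "G2", "G3"),
                              extremum = c("max", "min"),
                              replicate = reps)
  cells$value <- base[match(cells$replicate, reps)] +
    2 * (cells$extremum == "max")
  res <- amplitude_anova(cells)
  p <- setNames(res$p.value, res$term)
  expect_lt(p[["extremum"]], 1e-6)
  expect_equal(p[["group"]], 1)            # group SS is exactly 0
  expect_equal(p[["group:extremum"]], 1)

  # zero-variance degenerate table: all effects p = 1
  flat <- dplyr::mutate(cells, value = 3)
  pf <- setNames(amplitude_anova(flat)$p.value, amplitude_anova(flat)$term)
  expect_equal(unname(pf[c("group", "extremum", "group:extremum")]),
               c(1, 1, 1))

  expect_error(amplitude_anova(cells[cells$group != "G1" |
                                       cells$extremum != "max", ]),
               "cell")
})

test_that("ANOVA F statistics match the balanced-design closed form", {
  set.seed(83)
  d <- tidyr::expand_grid(group = c("G1", "G2", "G3", "G4"),
                          extremum = c("max", "min"), replicate = 1:5)
  d$value <- rnorm(nrow(d)) + 2 * (d$extremum == "max") +
    0.5 * (d$group == "G2")
  res <- amplitude_anova(d)

  # classical balanced two-way decomposition, computed from scratch
  a <- length(unique(d$group)); b <- 2; r <- 5
  gm <- mean(d$value)
  ma <- tapply(d$value, d$group, mean)
  mb <- tapply(d$value, d$extremum, mean)
  mab <- tapply(d$value, list(d$group, d$extremum), mean)
  ss_a <- b * r * sum((ma - gm)^2)
  ss_b <- a * r * sum((mb - gm)^2)
  ss_ab <- r * sum((mab - outer(ma - gm, mb - gm, `+`) - gm)^2)
  ss_e <- sum((d$value - mab[cbind(d$group, d$extremum)])^2)
  f_a <- (ss_a / (a - 1)) / (ss_e / (a * b * (r - 1)))
  f_b <- (ss_b / (b - 1)) / (ss_e / (a * b * (r - 1)))
  f_ab <- (ss_ab / ((a - 1) * (b - 1))) / (ss_e / (a * b * (r - 1)))

  fs <- setNames(res$statistic, res$term)
  expect_equal(unname(fs[c("group", "extremum", "group:extremum")]),
               c(f_a, f_b, f_ab), tolerance = 1e-6)
})

test_that("location composition test and core clock list are available", {
  genes <- core_clock_genes()
  expect_true(all(c("Per1", "Per2", "Dbp") %in% genes))
  expect_gte(length(genes), 10L)

  set.seed(91)
  fake <- tibble::tibble(
    output_class = factor(sample(c("RIN_PHI", "AR"), 200, TRUE),
                          levels = c("RIN_PHI", "RO_PHI", "AR", "NE",
                                     "POST_TRANSCRIPTIONAL", "LOW_EXPRESSION",
                                     "NO_SIGNAL")),
    location = factor(sample(c("TSS", "GENE_BODY"), 200, TRUE),
                      levels = c("TSS", "GENE_BODY", "EXTENDED_PROMOTER",
                                 "INTERGENIC"))
  )
  out <- location_chisq(fake)
  expect_s3_class(out, "htest")
  expect_true(out$p.value >= 0 && out$p.value <= 1)
})
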