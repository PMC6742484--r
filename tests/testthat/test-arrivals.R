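# hand-built arrival tables with a prescribed site census
make_table <- function(arrivals_by_class, n_molecules, replicate = 1L) {
  rows <- list()
  mol <- 1L
  for (cl in names(arrivals_by_class)) {
    n <- arrivals_by_class[[cl]]
    if (n == 0) next
    k <- switch(cl, edge = 2L, lattice = 4L, excluded = 1L, face = 1L)
    rows[[cl]] <- data.frame(
      replicate = replicate, molecule = mol:(mol + n - 1),
      status = "arrived", site_id = 1L, site_class = cl, k = k,
      n_steps = 100)
    mol <- mol + n
  }
  n_arr <- mol - 1L
  esc <- data.frame(replicate = replicate,
                    molecule = mol:(n_molecules),
                    status = "escaped", site_id = NA_integer_,
                    site_class = NA_character_, k = NA_integer_,
                    n_steps = 50)
  do.call(rbind, c(rows, list(esc)))
}

fake_sites <- function(n_edge, n_lattice) {
  data.frame(classification = c(rep("edge", n_edge),
                                rep("lattice", n_lattice)))
}

test_that("per-site fractions reproduce hand arithmetic", {
  tab <- make_table(list(edge = 10, lattice = 2), 1000)
  fr <- per_site_class_fractions(tab, fake_sites(5, 100))
  e <- fr[fr$class == "edge", ]; l <- fr[fr$class == "lattice", ]
  expect_equal(e$fraction, (10 / 1000) / 5)      # 0.002
  expect_equal(l$fraction, (2 / 1000) / 100)     # 2e-5
  fold <- edge_lattice_fold(tab, fake_sites(5, 100))
  expect_equal(fold$fold, 100)
  # zero arrivals give zero fractions
  tab0 <- make_table(list(), 100)
  fr0 <- per_site_class_fractions(tab0, fake_sites(5, 100))
  expect_true(all(fr0$fraction == 0))
  # zero available sites is an error
  expect_error(per_site_class_fractions(tab, fake_sites(0, 100)), "zero")
})

test_that("fractions match a groupby-free double-loop oracle", {
  set.seed(50)
  classes <- c("edge", "lattice", "excluded")
  sdf <- data.frame(classification = sample(classes, 60, replace = TRUE))
  n <- 500
  st <- sample(c("arrived", "escaped"), n, replace = TRUE, prob = c(.2, .8))
  cl <- ifelse(st == "arrived", sample(classes, n, replace = TRUE),
               NA_character_)
  tab <- data.frame(replicate = 1L, molecule = 1:n, status = st,
                    site_id = NA_integer_, site_class = cl,
                    k = NA_integer_, n_steps = 1)
  fr <- per_site_class_fractions(tab, sdf)
  for (cc in classes) {
    arr <- 0
    for (i in seq_len(n))
      if (st[i] == "arrived" && !is.na(cl[i]) && cl[i] == cc)
        arr <- arr + 1
    ns <- 0
    for (j in seq_len(nrow(sdf)))
      if (sdf$classification[j] == cc) ns <- ns + 1
    expect_equal(fr$fraction[fr$class == cc], (arr / n) / ns)
  }
})

test_that("fractions are invariant to replicate splitting", {
  tab <- rbind(make_table(list(edge = 6, lattice = 3), 500, 1L),
               make_table(list(edge = 4, lattice = 1), 500, 2L))
  sdf <- fake_sites(5, 100)
  whole <- per_site_class_fractions(tab, sdf)
  parts <- lapply(split(tab, tab$replicate), per_site_class_fractions,
                  sites = sdf)
  # equal molecule counts: the average of per-replicate fractions equals
  # the pooled fraction
  avg <- (parts[[1]]$fraction + parts[[2]]$fraction) / 2
  expect_equal(whole$fraction, avg)
})

test_that("configuration comparison reports percent change and p-values", {
  ta <- make_table(list(edge = 133), 4000)
  tb <- make_table(list(edge = 100), 4000)
  cmp <- compare_configurations(ta, tb, n_boot = 200)
  expect_equal(cmp$percent_change, 33, tolerance = 1e-9)
  same <- compare_configurations(tb, tb, n_boot = 200)
  expect_equal(same$percent_change, 0)
  expect_gt(same$p_value, 0.9)
})

test_that("binomial p-value matches exact enumeration for small counts", {
  ta <- make_table(list(edge = 7), 50)
  tb <- make_table(list(edge = 2), 50)
  cmp <- compare_configurations(ta, tb, n_boot = 50)
  # exact two-sided binomial enumeration, p0 = 1/2
  k <- 7; m <- 9
  probs <- dbinom(0:m, m, 0.5)
  p_exact <- sum(probs[probs <= dbinom(k, m, 0.5) + 1e-12])
  expect_equal(cmp$p_value, p_exact, tolerance = 1e-9)
})

test_that("EM bead calculators reproduce the worked examples", {
  st <- em_bead_statistics(list(lattice = 74, defect_or_sheet = 128))
  expect_equal(st$raw_fold, 128 / 74)
  expect_equal(round(st$raw_fold, 1), 1.7)
  st2 <- em_bead_statistics(list(lattice = 74, defect_or_sheet = 128,
                                 sheet_edge = 7, sheet_middle = 1))
  expect_equal(st2$per_site_edge_preference, 7 * 14 / 2)
  # the alternative middle:edge normalization
  st3 <- em_bead_statistics(list(lattice = 74, defect_or_sheet = 128,
                                 sheet_edge = 7, sheet_middle = 1),
                            middle_normalization = TRUE)
  expect_equal(st3$per_site_edge_preference, 7 * 12 / 2)
  # equal counts and lengths: every fold is 1
  st4 <- em_bead_statistics(list(lattice = 50, defect_or_sheet = 50,
                                 sheet_edge = 10, sheet_middle = 10),
                            lengths = list(lattice = 5, defect_or_sheet = 5))
  expect_equal(st4$raw_fold, 1)
  expect_equal(st4$length_normalized_fold, 1)
  expect_equal(st4$edge_middle_ratio, 1)
  expect_error(em_bead_statistics(list(lattice = 0, defect_or_sheet = 5)),
               "positive")
})

test_that("length normalization follows the stated formula", {
  st <- em_bead_statistics(list(lattice = 74, defect_or_sheet = 128),
                           lengths = list(lattice = 10,
                                          defect_or_sheet = 4.5))
  expect_equal(st$length_normalized_fold, (128 / 4.5) / (74 / 10))
})

test_that("arrival map export writes matching CSV and a valid image", {
  mt <- fx("mt_small")
  sites <- enumerate_sites(mt, "pocket")
  tab <- data.frame(replicate = 1L, molecule = 1:3,
                    status = c("arrived", "escaped", "arrived"),
                    site_id = c(5L, NA, 9L),
                    site_class = c("lattice", NA, "edge"),
                    k = c(4L, NA, 2L), n_steps = 1)
  stem <- tempfile()
  export_arrival_map(tab, mt, sites, stem)
  got <- read.csv(paste0(stem, ".csv"))
  expect_equal(nrow(got), 2)
  expect_equal(got$x[1], sites[[5]]$site_center[1])
  expect_true(file.exists(paste0(stem, ".png")))
  expect_gt(file.info(paste0(stem, ".png"))$size, 0)
  # empty table still produces valid outputs
  stem2 <- tempfile()
  export_arrival_map(tab[tab$status == "escaped", ], mt, sites, stem2)
  expect_equal(nrow(read.csv(paste0(stem2, ".csv"))), 0)
  expect_true(file.exists(paste0(stem2, ".png")))
})
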