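test_that("probe-to-class assignment reconciles 1-based points with BED intervals", {
  track <- tibble::tibble(chrom = 1L, start = c(99L, 200L),
                          end = c(100L, 300L),
                          class = c("Island", "N_Shore"))
  probes <- tibble::tibble(probe_id = c("a", "b", "c", "d"),
                           chrom = 1L, pos = c(100L, 101L, 250L, 301L))
  cm <- assign_probe_class(probes, track)
  # 1-based 100 -> 0-based 99, inside [99, 100)
  expect_equal(cm$class, c("Island", "Sea", "N_Shore", "Sea"))
  # unknown chromosome flagged and excluded
  p2 <- dplyr::bind_rows(probes,
                         tibble::tibble(probe_id = "x", chrom = 9L, pos = 5L))
  expect_warning(cm2 <- assign_probe_class(p2, track), "absent")
  expect_false("x" %in% cm2$probe_id)
})

test_that("class assignment matches an IRanges overlap oracle", {
  skip_if_not_installed("IRanges")
  withr::with_seed(95, {
    starts <- sort(sample.int(1e6, 50)) * 10L
    track <- tibble::tibble(chrom = 1L, start = starts,
                            end = starts + 500L, class = "covered")
    probes <- tibble::tibble(probe_id = sprintf("p%04d", 1:2000),
                             chrom = 1L, pos = sample.int(1.2e7, 2000))
  })
  cm <- assign_probe_class(probes, track, background = "open")
  ir <- IRanges::IRanges(start = track$start + 1L, end = track$end)
  hits <- IRanges::overlapsAny(IRanges::IRanges(probes$pos, probes$pos), ir)
  expect_equal(cm$class == "covered", hits)
})

test_that("uniform probes land in a class proportionally to its coverage", {
  # one class covering ~30% of a 1 Mb chromosome
  starts <- seq(0L, 999999L, by = 10000L)
  track <- tibble::tibble(chrom = 1L, start = starts, end = starts + 3000L,
                          class = "cov")
  withr::with_seed(96, {
    probes <- tibble::tibble(probe_id = sprintf("p%05d", 1:20000),
                             chrom = 1L, pos = sample.int(1e6, 20000, TRUE))
  })
  cm <- assign_probe_class(probes, track)
  expect_lt(abs(mean(cm$class == "cov") - 0.3), 0.02)
})

test_that("permutation enrichment reproduces 2x2 arithmetic and p floors", {
  universe <- sprintf("u%04d", 1:1000)
  cmap <- tibble::tibble(probe_id = universe,
                         class = rep(c("inClass", "out"), c(200, 800)))
  # test 100, of which 40 in class: OR = (40*740)/(60*160)
  test_set <- c(universe[1:40], universe[201:260])
  res <- perm_enrichment(test_set, cmap, universe, B = 500, seed = 3)
  row <- res[res$class == "inClass", ]
  expect_equal(row$odds_ratio, (40 * 740) / (60 * 160))
  expect_equal(row$observed, 40)
  expect_equal(row$expected, 100 * 200 / 1000)
  expect_equal(row$fold, 40 / 20)

  # test set entirely inside a class covering half the universe
  cmap2 <- tibble::tibble(probe_id = universe,
                          class = rep(c("half", "rest"), each = 500))
  res2 <- perm_enrichment(universe[1:100], cmap2, universe, B = 500, seed = 3)
  r2 <- res2[res2$class == "half", ]
  expect_true(r2$infinite)
  expect_equal(r2$p_perm, 1 / 501)
})

test_that("a uniformly drawn test set shows no enrichment", {
  universe <- sprintf("u%04d", 1:2000)
  cmap <- tibble::tibble(probe_id = universe,
                         class = rep(c("A", "B", "C", "D"), 500))
  ps <- purrr::map_dfr(1:10, function(s) {
    ts <- withr::with_seed(600 + s, sample(universe, 200))
    perm_enrichment(ts, cmap, universe, B = 200, seed = s)
  })
  expect_lt(abs(mean(ps$odds_ratio) - 1), 0.15)
  expect_gt(mean(ps$p_perm > 0.05), 0.8)
})

test_that("Fisher gene-set arithmetic reproduces the printed worked example", {
  # reference 18607 genes, 101 in the class; test 1020 genes, 27 in class
  universe <- sprintf("g%05d", 1:18607)
  class_genes <- c(universe[1:27], universe[1100:1173])        # 101 genes
  test_genes <- universe[1:1020]                               # 27 in class
  res <- fisher_gene_set(list(Homeodomain = class_genes), universe, test_genes)
  expect_equal(round(res$expected, 1), 5.5)
  expect_equal(round(res$fold, 1), 4.9)
  expect_equal(res$observed, 27)
})

test_that("Fisher p equals a direct hypergeometric tail oracle", {
  universe <- sprintf("g%05d", 1:18607)
  class_genes <- universe[1:101]
  test_genes <- c(universe[1:27], universe[200:1192])          # 1020 genes
  res <- fisher_gene_set(list(cl = class_genes), universe, test_genes)
  # two-sided Fisher p: sum of hypergeometric point masses <= that of the
  # observed table (a successes among 1020 draws from 101/18506)
  dens <- stats::dhyper(0:101, 101, 18607 - 101, 1020)
  p_oracle <- sum(dens[dens <= stats::dhyper(27, 101, 18607 - 101, 1020) *
                         (1 + 1e-7)])
  expect_equal(res$p, p_oracle, tolerance = 1e-10)
})

test_that("fold enrichment is exactly 1 when the test set is the reference", {
  universe <- sprintf("g%03d", 1:500)
  sets <- list(a = universe[1:50], b = universe[51:300])
  res <- fisher_gene_set(sets, universe, universe)
  expect_equal(res$fold, c(1, 1))
  expect_equal(res$p, c(1, 1))
})

test_that("BH q-values are monotone in the sorted p-values", {
  universe <- sprintf("g%04d", 1:3000)
  withr::with_seed(97, {
    sets <- purrr::map(1:12, ~ sample(universe, sample(50:300, 1)))
    names(sets) <- paste0("set", 1:12)
    test_genes <- c(sample(universe[1:300], 150), sample(universe, 100))
  })
  res <- fisher_gene_set(sets, universe, unique(test_genes))
  o <- order(res$p)
  expect_true(all(diff(res$q[o]) >= -1e-12))
  expect_equal(res$q, p.adjust(res$p, "BH"))
})

test_that("permutation and Fisher routes agree on the odds ratio", {
  universe <- sprintf("u%04d", 1:800)
  cmap <- tibble::tibble(probe_id = universe,
                         class = rep(c("A", "B"), c(300, 500)))
  ts <- c(universe[1:90], universe[301:340])
  pe <- perm_enrichment(ts, cmap, universe, B = 100, seed = 1)
  fe <- fisher_gene_set(split(cmap$probe_id, cmap$class), universe, ts)
  expect_equal(dplyr::arrange(pe, class)$odds_ratio,
               dplyr::arrange(fe, class)$odds_ratio)
})

test_that("nearest gene mapping minimizes distance with start tie-break", {
  genes <- tibble::tibble(gene = c("g1", "g2", "g3"),
                          chrom = c(1L, 1L, 2L),
                          start = c(100L, 500L, 10L), end = c(200L, 700L, 50L))
  probes <- tibble::tibble(probe_id = c("pa", "pb", "pc"),
                           chrom = c(1L, 1L, 2L), pos = c(150L, 350L, 400L))
  nn <- nearest_gene(probes, genes)
  expect_equal(nn$gene, c("g1", "g1", "g3"))
  expect_equal(nn$distance, c(0, 150, 350))
})
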