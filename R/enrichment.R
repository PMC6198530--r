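#' Assign probes to annotation classes by genomic position
#'
#' Probe positions are 1-based points; annotation intervals are 0-based
#' half-open (BED convention). A probe at 1-based position `p` falls in
#' interval `[start, end)` when `start <= p - 1 < end`. Probes matching no
#' interval get the `background` class; probes on a chromosome absent from
#' the track are flagged and excluded.
#'
#' @param probes Tibble with columns `probe_id`, `chrom`, `pos` (1-based).
#' @param track Tibble with columns `chrom`, `start`, `end` (0-based
#'   half-open) and `class`. Intervals of one scheme must not overlap.
#' @param background Class label for unmatched probes (default `"Sea"`).
#' @return A tibble `probe_id`, `class`.
#' @export
assign_probe_class <- function(probes, track, background = "Sea") {
  .assert(all(c("probe_id", "chrom", "pos") %in% names(probes)),
          "probes needs probe_id, chrom, pos")
  .assert(all(c("chrom", "start", "end", "class") %in% names(track)),
          "track needs chrom, start, end, class")
  .assert(all(track$end > track$start), "intervals must have positive length")
  unknown <- !(probes$chrom %in% track$chrom)
  if (any(unknown)) {
    warn(sprintf("%d probe(s) on chromosomes absent from the track excluded",
                 sum(unknown)))
    probes <- probes[!unknown, ]
  }
  out <- purrr::map(split(probes, probes$chrom), function(pc) {
    tr <- track[track$chrom == pc$chrom[1], ]
    tr <- tr[order(tr$start), ]
    p0 <- pc$pos - 1L                         # to 0-based point
    k <- findInterval(p0, tr$start)           # last interval with start <= p0
    cls <- rep(background, nrow(pc))
    hit <- k >= 1L
    hit[hit] <- p0[hit] < tr$end[k[hit]]
    cls[hit] <- tr$class[k[hit]]
    tibble::tibble(probe_id = pc$probe_id, class = cls)
  })
  comb <- dplyr::bind_rows(out)
  comb[match(probes$probe_id, comb$probe_id), ]
}

#' Permutation enrichment of a probe set in annotation classes
#'
#' For every class, forms the 2x2 table (in test set x in class) over the
#' universe and computes its odds ratio; the null distribution is obtained
#' by drawing `|test set|` probes uniformly from the universe `B` times.
#' The empirical p-value uses the add-one correction, so its floor is
#' `1/(B+1)`.
#'
#' @param test_set Probe ids, a subset of `universe`.
#' @param class_map Tibble `probe_id`, `class` covering the universe (see
#'   [assign_probe_class()]).
#' @param universe Probe ids defining the reference set.
#' @param B Number of permutations (default 30000).
#' @param seed Integer seed.
#' @param alternative `"greater"` for one-sided enrichment (default) or
#'   `"two.sided"` (symmetric tail doubling, capped at 1).
#' @return A tibble of class `enrich_result`: `class`, `observed`,
#'   `expected`, `fold`, `odds_ratio`, `p_perm`, `infinite`.
#' @export
perm_enrichment <- function(test_set, class_map, universe, B = 30000L,
                            seed = 1L,
                            alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  .assert(all(test_set %in% universe), "test_set must be inside the universe")
  cls <- class_map$class[match(universe, class_map$probe_id)]
  .assert(!anyNA(cls), "class_map must cover the universe")
  classes <- sort(unique(cls))
  n_u <- length(universe); n_t <- length(unique(test_set))
  in_t <- universe %in% test_set

  # with fixed margins the whole 2x2 table is determined by the count a of
  # test-set probes in the class, so only a is drawn per permutation
  or_from_a <- function(a, K) {
    b <- n_t - a; c_ <- K - a; d <- n_u - n_t - c_
    ifelse(b * c_ == 0, Inf, (a * d) / (b * c_))
  }
  perm_a <- withr::with_seed(seed, {
    vapply(seq_len(B), function(k) {
      idx <- sample.int(n_u, n_t)
      vapply(classes, function(cl) sum(cls[idx] == cl), integer(1))
    }, integer(length(classes)))
  })
  perm_a <- matrix(perm_a, nrow = length(classes))
  rows <- purrr::map(seq_along(classes), function(ci) {
    cl <- classes[ci]
    in_c <- cls == cl
    if (!any(in_c)) {
      warn(sprintf("class '%s' empty in the universe; skipped", cl))
      return(NULL)
    }
    K <- sum(in_c)
    obs_ct <- sum(in_t & in_c)
    obs_or <- or_from_a(obs_ct, K)
    perm_or <- or_from_a(perm_a[ci, ], K)
    p_up <- (sum(perm_or >= obs_or) + 1) / (B + 1)
    p <- if (alternative == "greater") p_up
         else min(1, 2 * min(p_up, (sum(perm_or <= obs_or) + 1) / (B + 1)))
    expected <- n_t * sum(in_c) / n_u
    tibble::tibble(class = cl, observed = obs_ct, expected = expected,
                   fold = obs_ct / expected, odds_ratio = obs_or,
                   p_perm = p, infinite = is.infinite(obs_or))
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("enrich_result", class(out))
  attr(out, "B") <- B
  out
}

#' Gene-set over-representation by Fisher's exact test
#'
#' For each gene set (class), tests the 2x2 table of membership in the
#' test gene list x membership in the class over the reference universe
#' with a two-sided Fisher's exact test, and adjusts p-values across
#' classes by Benjamini-Hochberg. `expected` is the class size scaled by
#' the test fraction, and `fold = observed / expected`.
#'
#' @param gene_sets Named list of character vectors (class -> genes), or a
#'   tibble with columns `class` and `gene`.
#' @param universe Reference gene universe (character).
#' @param test_genes Genes to test, a subset of `universe`.
#' @return A tibble of class `enrich_result`: `class`, `observed`,
#'   `expected`, `fold`, `odds_ratio`, `p`, `q`.
#' @export
fisher_gene_set <- function(gene_sets, universe, test_genes) {
  if (is.data.frame(gene_sets))
    gene_sets <- split(gene_sets$gene, gene_sets$class)
  .assert(is.list(gene_sets) && !is.null(names(gene_sets)),
          "gene_sets must be a named list or a class/gene tibble")
  .assert(all(test_genes %in% universe),
          "test_genes must be inside the universe")
  test_genes <- unique(test_genes)
  n_u <- length(unique(universe)); n_t <- length(test_genes)
  rows <- purrr::imap(gene_sets, function(genes, cl) {
    genes <- intersect(unique(genes), universe)
    if (length(genes) == 0) return(NULL)      # class absent from reference
    a <- length(intersect(test_genes, genes))
    b <- n_t - a
    c_ <- length(genes) - a
    d <- n_u - n_t - c_
    ft <- fisher.test(matrix(c(a, b, c_, d), 2, 2, byrow = TRUE))
    expected <- length(genes) * n_t / n_u
    tibble::tibble(class = cl, observed = a, expected = expected,
                   fold = a / expected,
                   odds_ratio = if (b * c_ == 0) Inf else (a * d) / (b * c_),
                   p = ft$p.value)
  })
  out <- dplyr::bind_rows(rows)
  out$q <- p.adjust(out$p, method = "BH")
  class(out) <- c("enrich_result", class(out))
  out
}

#' Map probes to their nearest gene
#'
#' Distance is the minimal absolute distance between the probe position
#' and the gene body `[start, end]` (zero when the probe lies inside);
#' ties are broken by the smaller gene start.
#'
#' @param probes Tibble `probe_id`, `chrom`, `pos`.
#' @param genes Tibble `gene`, `chrom`, `start`, `end`.
#' @return A tibble `probe_id`, `gene`, `distance`.
#' @export
nearest_gene <- function(probes, genes) {
  .assert(all(c("probe_id", "chrom", "pos") %in% names(probes)),
          "probes needs probe_id, chrom, pos")
  .assert(all(c("gene", "chrom", "start", "end") %in% names(genes)),
          "genes needs gene, chrom, start, end")
  rows <- purrr::pmap(probes, function(probe_id, chrom, pos, ...) {
    g <- genes[genes$chrom == chrom, ]
    if (nrow(g) == 0)
      return(tibble::tibble(probe_id = probe_id, gene = NA_character_,
                            distance = NA_real_))
    d <- pmax(g$start - pos, pos - g$end, 0)
    best <- which(d == min(d))
    if (length(best) > 1) best <- best[which.min(g$start[best])]
    tibble::tibble(probe_id = probe_id, gene = g$gene[best],
                   distance = d[best])
  })
  dplyr::bind_rows(rows)
}
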