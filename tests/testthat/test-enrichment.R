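# independent oracles: an exhaustive enumeration over labeled draws for
# tiny urns, and the closed-form binomial-coefficient ratio elsewhere
enum_pmf <- function(k, N, K, n) {
  draws <- utils::combn(N, n)
  mean(colSums(draws <= K) == k)
}
choose_pmf <- function(k, N, K, n) {
  choose(K, k) * choose(N - K, n - k) / choose(N, n)
}

test_that("hypergeometric pmf matches hand and closed-form values", {
  expect_equal(hypergeom_pmf(1, 5, 2, 2), 0.6)
  expect_equal(hypergeom_pmf(2, 5, 2, 2), 0.1)
  expect_error(hypergeom_pmf(3, 5, 2, 2), "k cannot exceed")
  expect_error(hypergeom_pmf(1, 5, 6, 2), "invalid")
})

test_that("pmf and tail agree with exhaustive enumeration on tiny urns", {
  for (N in c(6, 9, 12)) {
    for (K in c(2, N %/% 2)) {
      for (n in c(2, N %/% 3)) {
        for (k in 0:min(K, n)) {
          expect_equal(hypergeom_pmf(k, N, K, n), enum_pmf(k, N, K, n),
                       tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("pmf and tail agree with the combinatorial formula for all tuples N <= 60", {
  set.seed(51)
  grid <- expand.grid(N = c(5, 17, 31, 46, 60), Kf = c(0.2, 0.5, 0.9),
                      nf = c(0.1, 0.4, 0.8))
  for (i in seq_len(nrow(grid))) {
    N <- grid$N[i]
    K <- max(1, round(grid$Kf[i] * N))
    n <- max(1, round(grid$nf[i] * N))
    for (k in 0:min(K, n)) {
      expect_equal(hypergeom_pmf(k, N, K, n), choose_pmf(k, N, K, n),
                   tolerance = 1e-12)
      tail_oracle <- sum(vapply(k:min(K, n), choose_pmf, 1, N = N, K = K, n = n))
      expect_equal(hypergeom_upper_tail(k, N, K, n), tail_oracle,
                   tolerance = 1e-12)
    }
  }
})

test_that("pmf sums to one, is symmetric in (K, n), and the tail closes properly", {
  cases <- list(c(100, 30, 12), c(1263, 523, 49), c(5000, 800, 120))
  for (cs in cases) {
    N <- cs[1]; K <- cs[2]; n <- cs[3]
    ks <- 0:min(K, n)
    expect_equal(sum(vapply(ks, hypergeom_pmf, 1, N = N, K = K, n = n)), 1,
                 tolerance = 1e-12)
    expect_equal(hypergeom_pmf(5, N, K, n), hypergeom_pmf(5, N, n, K),
                 tolerance = 1e-12)
  }
  expect_equal(hypergeom_upper_tail(0, 50, 10, 5), 1)
  expect_equal(hypergeom_upper_tail(5, 50, 10, 5),
               hypergeom_pmf(5, 50, 10, 5), tolerance = 1e-15)
})

test_that("term enrichment builds the contingency right and adjusts monotonically", {
  universe <- sprintf("g%03d", 1:60)
  ann <- rbind(
    data.frame(gene_id = universe[1:10], term_id = "T1"),
    data.frame(gene_id = universe[8:30], term_id = "T2"),
    data.frame(gene_id = universe[31:32], term_id = "T3"),
    data.frame(gene_id = universe[60], term_id = "T4") # below min_reference
  )
  query <- universe[c(1:8, 31)]
  res <- term_enrichment(query, universe, ann)
  expect_false("T4" %in% res$term_id)
  r1 <- res[res$term_id == "T1", ]
  expect_equal(r1$query_hits, 8)
  expect_equal(r1$reference_hits, 10)
  expect_equal(r1$p_raw, hypergeom_upper_tail(8, 60, 10, 9), tolerance = 1e-12)
  expect_equal(r1$pmf, hypergeom_pmf(8, 60, 10, 9), tolerance = 1e-12)
  # BY adjustment keeps ranks and dominates raw p
  expect_true(all(res$p_fdr >= res$p_raw))
  expect_false(is.unsorted(res$p_fdr[order(res$p_raw)]))
  # the BY correction equals p.adjust on the same vector
  expect_equal(res$p_fdr, stats::p.adjust(res$p_raw, "BY"))

  # query = universe: every term has raw p 1
  res_all <- term_enrichment(universe, universe, ann)
  expect_true(all(res_all$p_raw == 1))

  # a query exactly covering one term achieves its minimal possible p
  resT3 <- term_enrichment(universe[31:32], universe, ann)
  r3 <- resT3[resT3$term_id == "T3", ]
  expect_equal(r3$p_raw, 1 / choose(60, 2), tolerance = 1e-12)

  expect_warning(e <- term_enrichment(character(0), universe, ann), "empty")
  expect_equal(nrow(e), 0)
  expect_error(term_enrichment("nope", universe, ann), "subset")
})

test_that("the field trait-link test reproduces the printed drought-study values", {
  # constructed merged network with 1263 genes, 523 linked to RWC and 628
  # to OP, and a field list giving n = 49 with k = 28 in both cases
  genes <- sprintf("G%04d", 1:1263)
  edges <- rbind(
    data.frame(gene = genes[1:523], phenotype = "RWC", score = 0.8,
               sign = "pos", scenario = "both", stringsAsFactors = FALSE),
    data.frame(gene = genes[c(1:28, 524:1123)], phenotype = "OP", score = -0.7,
               sign = "neg", scenario = "FDS", stringsAsFactors = FALSE),
    data.frame(gene = genes[1124:1263], phenotype = "E", score = 0.7,
               sign = "pos", scenario = "FIS", stringsAsFactors = FALSE)
  )
  net <- structure(list(edges = edges,
                        genes = data.frame(gene = genes, membership = "shared",
                                           stringsAsFactors = FALSE),
                        phenotypes = c("RWC", "OP", "E"), threshold = 0.65),
                   class = "assoc_network")
  # 28 genes linked to both RWC and OP, plus 21 E-only genes -> n = 49
  field <- genes[c(1:28, 1124:1144)]
  rwc <- trait_link_enrichment(field, net, "RWC")
  expect_equal(c(rwc$N, rwc$K, rwc$n, rwc$k), c(1263, 523, 49, 28))
  expect_equal(round(rwc$pmf, 3), 0.009)
  op <- trait_link_enrichment(field, net, "OP")
  expect_equal(c(op$K, op$k), c(628, 28))
  # agreement at the printed precision (the published 0.066 truncates
  # the exact point probability 0.06655)
  expect_lt(abs(op$pmf - 0.066), 1e-3)
  expect_error(trait_link_enrichment(field, net, "CID"), "unknown trait")
  expect_error(trait_link_enrichment("absent", net, "RWC"), "undefined")

  # field list fully trait-linked: k = n and the tail collapses to the pmf
  full <- trait_link_enrichment(genes[1:40], net, "RWC")
  expect_equal(full$k, full$n)
  expect_equal(full$p_upper,
               sum(vapply(full$k:min(full$K, full$n), hypergeom_pmf, 1,
                          N = full$N, K = full$K, n = full$n)),
               tolerance = 1e-12)
})

test_that("the null field test is calibrated: upper-tail p near-uniform", {
  set.seed(52)
  genes <- sprintf("G%03d", 1:400)
  edges <- data.frame(gene = genes[1:150], phenotype = "RWC", score = 0.8,
                      sign = "pos", scenario = "both", stringsAsFactors = FALSE)
  net <- structure(list(edges = edges,
                        genes = data.frame(gene = genes, membership = "shared",
                                           stringsAsFactors = FALSE),
                        phenotypes = "RWC", threshold = 0.65),
                   class = "assoc_network")
  ps <- vapply(1:500, function(i) {
    trait_link_enrichment(sample(genes, 60), net, "RWC")$p_upper
  }, 1)
  # discrete p-values are stochastically >= uniform; check the one-sided
  # departure (anti-conservatism) only
  expect_gt(suppressWarnings(
    stats::ks.test(ps, "punif", alternative = "greater")$p.value), 0.01)
})

test_that("field subnetworks inherit attributes and handle edge cases", {
  ds <- simulate_dataset(small_config(seed = 53))
  run <- run_pipeline(ds$expr, ds$samples, ds$phenotypes, ds$field_genes,
                      pool_variance = FALSE)
  merged <- run$merged
  sub <- field_subnetwork(ds$field_genes, merged)
  expect_true(all(sub$genes$gene %in% ds$field_genes))
  expect_true(all(sub$edges$gene %in% sub$genes$gene))
  expect_identical(names(sub$genes), names(merged$genes))
  inherited <- merged$genes[match(sub$genes$gene, merged$genes$gene), ]
  rownames(inherited) <- NULL
  expect_identical(sub$genes, inherited)
  # disjoint list: empty subnetwork with warning
  expect_warning(empty <- field_subnetwork("not_a_gene", merged), "intersect")
  expect_equal(nrow(empty$edges), 0)
  # full list: subnetwork equals the network
  full <- field_subnetwork(merged$genes$gene, merged)
  expect_identical(full$edges, merged$edges)
})
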